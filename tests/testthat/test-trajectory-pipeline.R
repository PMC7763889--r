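test_that("consecutive measurements pair only within the eligibility gap", {
  pats <- make_patient("A")
  m <- make_measurements("A", c(0, 24, 48), c(500, 400, 300))
  p <- pair_measurements(m, pats)
  expect_equal(nrow(p), 2)
  expect_equal(p$delta_hours, c(24, 24))
  expect_equal(p$creat_a, c(500, 400))
  # a 48 h gap is ineligible
  m2 <- make_measurements("A", c(0, 48), c(500, 300))
  expect_equal(nrow(pair_measurements(m2, pats)), 0)
  # a single measurement yields nothing
  m3 <- make_measurements("A", 24, 400)
  expect_equal(nrow(pair_measurements(m3, pats)), 0)
})

test_that("pairs spanning a dialysis session are flagged", {
  pats <- make_patient("A", dialysis_hours = 30)
  m <- make_measurements("A", c(0, 24, 48), c(500, 400, 300))
  p <- pair_measurements(m, pats)
  expect_identical(p$straddles_dialysis, c(FALSE, TRUE))
})

test_that("POD assignment takes the closest measurement, earliest on ties", {
  pats <- make_patient("A")
  # two candidates for POD1: 22 h (dev 2) and 30 h (dev 6) -> 22 h wins
  m <- make_measurements("A", c(2, 22, 30, 49), c(600, 500, 480, 400))
  pods <- assign_pod(m, pats)
  expect_equal(pods$pod, c(0, 1, 2))
  expect_equal(pods$scr_umol_l, c(600, 500, 400))
  # equidistant candidates: the earlier one wins
  m2 <- make_measurements("A", c(20, 28), c(500, 480))
  pods2 <- assign_pod(m2, pats)
  expect_equal(nrow(pods2), 1)
  expect_equal(pods2$scr_umol_l, 500)
  # beyond the last acute-phase window: unassigned
  m3 <- make_measurements("A", 140, 400)
  expect_equal(nrow(assign_pod(m3, pats)), 0)
})

test_that("constant creatinine collapses both estimators to the anchor", {
  pats <- make_patient("A", age = 50, sex = "male")
  m <- make_measurements("A", c(2, 24, 48, 72, 96, 120), rep(200, 6))
  est <- estimate_daily(m, pats)
  crcl <- ckd_epi(200, 50, "male")
  expect_equal(nrow(est), 10) # 5 PODs x 2 methods
  expect_equal(est$value, rep(crcl, 10), tolerance = 1e-9)
})

test_that("falling creatinine puts the kinetic estimate above CKD-EPI", {
  pats <- make_patient("A", age = 50, sex = "male")
  m <- make_measurements("A", c(2, 24), c(600, 420))
  est <- estimate_daily(m, pats)
  k <- est$value[est$method == "KeGFR" & est$pod == 1]
  c <- est$value[est$method == "CKD-EPI" & est$pod == 1]
  # hand evaluation of both formulas on this trajectory
  crcl <- ckd_epi(600, 50, "male")
  dt <- 22
  k_hand <- (1 - (24 * (420 - 600)) / (dt * 133)) * 600 * crcl /
    (0.5 * (420 + 600))
  expect_equal(k, k_hand, tolerance = 1e-12)
  expect_equal(c, ckd_epi(420, 50, "male"), tolerance = 1e-12)
  expect_gt(k, c)
})

test_that("creatinine rising at the assumed maximum zeroes the kinetic estimate", {
  pats <- make_patient("A")
  rise <- 22 * 133 / 24 # exactly the per-day bound over 22 h
  m <- make_measurements("A", c(2, 24), c(300, 300 + rise))
  est <- estimate_daily(m, pats)
  expect_equal(est$value[est$method == "KeGFR" & est$pod == 1], 0,
    tolerance = 1e-9
  )
})

test_that("group slope fits recover exact linear and constant inputs", {
  fake_estimates <- tidyr::expand_grid(
    patient_id = sprintf("P%02d", 1:6), pod = 1:5
  ) |>
    dplyr::mutate(
      method = "KeGFR", value = 10 + 3 * pod,
      clamped = FALSE, scr_umol_l = 100, pair_delta_hours = 24
    )
  fake_labels <- tibble::tibble(
    patient_id = sprintf("P%02d", 1:6),
    status = factor(rep(c("SGF", "non-SGF"), 3),
      levels = c("SGF", "non-SGF", "indeterminate")
    ),
    analyzed = TRUE
  )
  pipe <- structure(
    list(
      estimates = fake_estimates, labels = fake_labels,
      pod_scr = fake_estimates[, c("patient_id", "pod", "scr_umol_l")]
    ),
    class = "kegfr_pipeline"
  )
  fits <- fit_group_slopes(pipe, "kegfr")
  expect_equal(fits$slope, rep(3, 3), tolerance = 1e-12)
  expect_equal(fits$intercept, rep(10, 3), tolerance = 1e-12)
  # constant series: zero slope
  pipe$estimates$value <- 42
  fits0 <- fit_group_slopes(pipe, "kegfr")
  expect_equal(fits0$slope, rep(0, 3), tolerance = 1e-12)
  # raw creatinine route fits the pod_scr table
  fits_scr <- fit_group_slopes(pipe, "scr")
  expect_equal(fits_scr$slope, rep(0, 3), tolerance = 1e-12)
})

test_that("slope fits recover a generating coefficient from noisy series", {
  withr::with_seed(21, {
    n <- 120
    dat <- tidyr::expand_grid(patient_id = sprintf("P%03d", 1:n), pod = 1:5) |>
      dplyr::mutate(
        method = "KeGFR",
        value = 20 + 2.7 * pod + rnorm(dplyr::n(), 0, 6),
        clamped = FALSE, scr_umol_l = 100, pair_delta_hours = 24
      )
    labs <- tibble::tibble(
      patient_id = sprintf("P%03d", 1:n),
      status = factor("non-SGF", levels = c("SGF", "non-SGF", "indeterminate")),
      analyzed = TRUE
    )
    pipe <- structure(
      list(estimates = dat, labels = labs,
           pod_scr = dat[, c("patient_id", "pod", "scr_umol_l")]),
      class = "kegfr_pipeline"
    )
    fit <- fit_group_slopes(pipe, "kegfr")
    all_row <- fit[fit$group == "all", ]
    se <- 6 / sqrt(n * 5 * 2) # OLS slope SE: sd / sqrt(Sxx), Sxx = 2 per patient
    expect_lt(abs(all_row$slope - 2.7), 4 * se)
    expect_lt(all_row$p_value, 1e-6)
  })
})

test_that("follow-up windows assign by nearest-to-centre with absence propagating", {
  pats <- make_patient("A", age = 50, sex = "male")
  m <- make_measurements(
    "A", c(2, 24, 90 * 24, 365 * 24), c(500, 400, 140, 120)
  )
  fu <- join_followup(m, pats)
  expect_equal(fu$window, c("m3", "m12"))
  expect_equal(fu$egfr[2], ckd_epi(120, 50, "male"))
  # two candidates in one window: nearest to the centre day wins
  m2 <- make_measurements("A", c(340 * 24, 370 * 24), c(150, 130))
  fu2 <- join_followup(m2, pats)
  expect_equal(nrow(fu2), 1)
  expect_equal(fu2$scr_umol_l, 130)
  # no follow-up at all: the patient is simply absent
  m3 <- make_measurements("A", c(2, 24), c(500, 400))
  expect_equal(nrow(join_followup(m3, pats)), 0)
})

test_that("exclusion bookkeeping is conserved on a cohort with missingness", {
  cfg <- cohort_config(
    n_patients = 250, seed = 19,
    missing_baseline = 0.1, missing_daily = 0.1
  )
  co <- generate_cohort(cfg)
  pipe <- run_pipeline(co$measurements, co$patients)
  m <- pipe$manifest
  expect_equal(
    m$screened,
    m$analyzed + m$excluded_no_pod1_kegfr + m$excluded_no_sgf_status
  )
  expect_gt(m$excluded_no_pod1_kegfr, 0)
  # a patient without a POD1 kinetic estimate is never analyzed
  expect_true(all(pipe$labels$has_pod1_kegfr[pipe$labels$analyzed]))
})

test_that("re-running the pipeline on the same input is identical", {
  co <- generate_cohort(cohort_config(n_patients = 60, seed = 4))
  p1 <- run_pipeline(co$measurements, co$patients)
  p2 <- run_pipeline(co$measurements, co$patients)
  expect_identical(p1$estimates, p2$estimates)
  expect_identical(p1$labels, p2$labels)
  # at most one estimate per patient, POD and method
  dup <- p1$estimates |>
    dplyr::count(patient_id, pod, method) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(dup), 0)
})
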