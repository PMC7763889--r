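# ---- synthetic transplant cohort ----------------------------------------
#
# Latent creatinine follows a one-compartment mass balance
#   V dc/dt = G - k g(t) c,   k = 1.44 L/day per mL/min,
# with G the creatinine generation rate (umol/day), V an effective
# distribution volume (L) and g(t) the true GFR trajectory. Per patient,
# G is chosen so that the long-term steady state is consistent with the
# CKD-EPI equation (CKD-EPI(c_ss) = true one-year GFR), and V = G / r_max
# where r_max is the configured maximal anuric creatinine rise. The latent
# rise at zero GFR therefore never exceeds r_max, keeping the simulator
# inside the regime the kinetic formula's daily-rise bound assumes.

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  x
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  x <- rlnorm(n, meanlog, sdlog)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- rlnorm(sum(bad), meanlog, sdlog)
  }
  x
}

#' Configuration of the synthetic transplant cohort
#'
#' Returns the full parameter set of the cohort simulator. The defaults
#' emulate a European adult kidney-transplant cohort: recipient age around
#' a median of 53 years, roughly 61% male, about 40% living donation, a
#' slow-graft-function (SGF) phenotype in about 23% of patients and
#' dialysis-requiring delayed graft function (DGF) in about 2%, with the
#' SGF phenotype carrying a -10 mL/min/1.73 m^2 one-year eGFR deficit.
#' Phenotype frequencies are specified conditionally on donor type so that
#' SGF is concentrated in deceased donation, as observed clinically.
#'
#' @param n_patients Cohort size (default 326).
#' @param seed Integer seed; mandatory, every draw derives from it.
#' @param donor_type_probs Named probabilities for living/DBD/DCD donation.
#' @param phenotype_probs Matrix of phenotype probabilities (columns IGF,
#'   SGF, DGF) by donor type (rows living, DBD, DCD); rows sum to one.
#'   The default marginals are about 0.75/0.23/0.02.
#' @param recipient_age,donor_age Truncated-normal parameters
#'   (mean, sd, min, max) in years.
#' @param male_fraction Probability of male sex.
#' @param preemptive_prob,abo_incompatible_prob Bernoulli probabilities.
#' @param baseline_creatinine Truncated-lognormal parameters (meanlog,
#'   sdlog, min, max) of serum creatinine at transplantation, umol/L.
#' @param one_year_gfr Truncated-normal parameters of the true one-year
#'   GFR before phenotype effects, mL/min/1.73 m^2.
#' @param sgf_effect_1yr,dgf_effect_1yr Additive one-year true-GFR effect
#'   of the SGF / DGF phenotype (default -10 / -15 mL/min/1.73 m^2).
#' @param igf_target_creatinine Uniform range (umol/L) of the early
#'   equilibrium creatinine of immediate graft function (IGF): an IGF
#'   graft is one whose creatinine normalises promptly, so its early GFR
#'   plateau is set to clear creatinine to this target (never below the
#'   one-year GFR). Early function above the one-year level reflects
#'   initial hyperfiltration before maintenance immunosuppression settles.
#' @param igf_tau_days Time constant of the IGF GFR rise (days).
#' @param sgf_g0,sgf_rise Uniform ranges of the SGF starting GFR
#'   (mL/min/1.73 m^2) and linear daily rise over the acute phase.
#' @param dgf_gfr Uniform range of the near-zero DGF GFR.
#' @param dialysis_days Dialysis session times for DGF patients (days).
#' @param dialysis_drop Instantaneous fractional creatinine reduction per
#'   dialysis session (default 0.4).
#' @param max_anuric_rise Maximal latent creatinine rise at zero GFR,
#'   umol/L/day; sets V = G / max_anuric_rise (default 120, inside the
#'   133 umol/L/day bound assumed by the kinetic formula).
#' @param noise_sd Standard deviation of the multiplicative lognormal
#'   measurement noise (default 0.05, a typical Jaffe assay CV).
#' @param lab_jitter_hours Uniform jitter of the daily morning lab around
#'   24k hours.
#' @param missing_baseline,missing_daily,missing_followup Per-measurement
#'   missingness probabilities.
#' @param followup_days Nominal follow-up visit days.
#' @param followup_jitter_days Uniform jitter of follow-up visits.
#' @param solver_step Fixed integration step of the mass-balance solver in
#'   days (default 0.01).
#' @param steady_state Generate steady-state patients only: constant true
#'   GFR, creatinine started at its equilibrium, no measurement noise.
#'   Under these conditions the kinetic and steady-state estimators
#'   coincide exactly (a null configuration for pipeline testing).
#' @param start_date Base date for transplantation times.
#' @return A list of class `kegfr_sim_config`.
#' @export
cohort_config <- function(n_patients = 326,
                          seed,
                          donor_type_probs = c(
                            living = 0.40, DBD = 0.565, DCD = 0.035
                          ),
                          phenotype_probs = rbind(
                            living = c(IGF = 0.905, SGF = 0.090, DGF = 0.005),
                            DBD = c(IGF = 0.672, SGF = 0.317, DGF = 0.011),
                            DCD = c(IGF = 0.200, SGF = 0.450, DGF = 0.350)
                          ),
                          recipient_age = c(mean = 53, sd = 14, min = 18, max = 85),
                          male_fraction = 0.61,
                          donor_age = c(mean = 53, sd = 13, min = 10, max = 85),
                          preemptive_prob = 0.126,
                          abo_incompatible_prob = 0.069,
                          baseline_creatinine = c(
                            meanlog = log(650), sdlog = 0.35, min = 200, max = 1500
                          ),
                          one_year_gfr = c(mean = 57, sd = 16, min = 15, max = 110),
                          sgf_effect_1yr = -10,
                          dgf_effect_1yr = -15,
                          igf_target_creatinine = c(65, 90),
                          igf_tau_days = 0.25,
                          sgf_g0 = c(8, 15),
                          sgf_rise = c(6, 10),
                          dgf_gfr = c(0.5, 4),
                          dialysis_days = c(1.7, 3.7, 5.7),
                          dialysis_drop = 0.4,
                          max_anuric_rise = 120,
                          noise_sd = 0.05,
                          lab_jitter_hours = 6,
                          missing_baseline = 0.02,
                          missing_daily = 0.02,
                          missing_followup = 0.10,
                          followup_days = c(90, 182, 365),
                          followup_jitter_days = 10,
                          solver_step = 0.01,
                          steady_state = FALSE,
                          start_date = as.POSIXct("2010-01-01 08:00:00",
                            tz = "UTC"
                          )) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("A `seed` is mandatory: the cohort must be reproducible.")
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "kegfr_sim_config")
}

validate_sim_config <- function(config) {
  if (!inherits(config, "kegfr_sim_config")) {
    abort("`config` must be built by cohort_config().")
  }
  if (config$n_patients < 2) abort("`n_patients` must be at least 2.")
  if (abs(sum(config$donor_type_probs) - 1) > 1e-8) {
    abort("`donor_type_probs` must sum to 1.")
  }
  pp <- config$phenotype_probs
  if (!is.matrix(pp) || any(pp < 0) ||
      any(abs(rowSums(pp) - 1) > 1e-8)) {
    abort("`phenotype_probs` rows must be non-negative and sum to 1.")
  }
  if (!setequal(rownames(pp), c("living", "DBD", "DCD"))) {
    abort("`phenotype_probs` needs rows living, DBD, DCD.")
  }
  for (nm in c("max_anuric_rise", "solver_step", "dialysis_drop",
               "igf_tau_days")) {
    if (config[[nm]] <= 0) abort(sprintf("`%s` must be positive.", nm))
  }
  if (config$noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (config$solver_step > 0.01) {
    abort("`solver_step` must be at most 0.01 day.")
  }
  invisible(config)
}

# fixed-step RK4 integration of the creatinine mass balance for a vector
# of patients; times is the full grid (days), events optional
integrate_cohort <- function(c0, g_fun, G, V, times, events = NULL) {
  n <- length(c0)
  y0 <- setNames(c0, sprintf("y%d", seq_len(n)))
  deriv <- function(t, y, p) list((G - 1.44 * g_fun(t) * y) / V)
  ev <- NULL
  if (!is.null(events) && nrow(events) > 0) {
    ev <- list(data = data.frame(
      var = sprintf("y%d", events$patient),
      time = events$time,
      value = events$value,
      method = "multiply"
    ))
  }
  deSolve::ode(
    y = y0, times = times, func = deriv, parms = NULL,
    method = "rk4", events = ev
  )
}

#' Simulate a latent creatinine trajectory by mass balance
#'
#' Integrates `V dc/dt = G - 1.44 g(t) c` with a fixed-step fourth-order
#' Runge-Kutta scheme (step at most 0.01 day by default) and samples the
#' latent concentration at the requested times under multiplicative
#' lognormal measurement noise. Dialysis sessions, if any, apply an
#' instantaneous fractional reduction of the latent creatinine. With a
#' constant GFR the trajectory converges to the analytic steady state
#' `G / (1.44 g)`.
#'
#' @param g True GFR trajectory: a function of time in days returning
#'   mL/min/1.73 m^2, or a single constant.
#' @param G Creatinine generation rate, umol/day (positive).
#' @param V Effective distribution volume, L (positive).
#' @param c0 Initial serum creatinine, umol/L (positive).
#' @param schedule Sampling times in days (non-negative).
#' @param dialysis_days Dialysis session times in days (optional).
#' @param dialysis_drop Fractional creatinine reduction per session.
#' @param step Integration step in days (default 0.01).
#' @param noise_sd Lognormal measurement noise SD (default 0: none).
#' @return A list: `latent` (tibble `time`, `creatinine` on the solver
#'   grid) and `sampled` (tibble `time`, `scr_umol_l` at `schedule`).
#' @examples
#' tr <- simulate_creatinine(g = 50, G = 8000, V = 65, c0 = 600,
#'                           schedule = c(1, 2, 3))
#' tail(tr$sampled)
#' @export
simulate_creatinine <- function(g, G, V, c0, schedule,
                                dialysis_days = NULL, dialysis_drop = 0.4,
                                step = 0.01, noise_sd = 0) {
  if (G < 0 || V <= 0 || c0 <= 0 || step <= 0) {
    abort("`G` must be non-negative and `V`, `c0`, `step` positive.")
  }
  if (any(schedule < 0)) abort("`schedule` times must be non-negative.")
  g_fun <- if (is.function(g)) g else function(t) g
  if (!is.function(g) && g < 0) abort("A constant `g` must be non-negative.")
  t_max <- max(schedule, dialysis_days, step)
  times <- sort(unique(round(c(
    seq(0, t_max, by = step), t_max, schedule, dialysis_days
  ), 10)))
  events <- NULL
  if (length(dialysis_days)) {
    events <- data.frame(
      patient = 1L, time = dialysis_days, value = 1 - dialysis_drop
    )
  }
  out <- integrate_cohort(c0, function(t) g_fun(t), G, V, times, events)
  latent <- tibble::tibble(time = out[, 1], creatinine = out[, 2])
  idx <- match(round(schedule, 10), round(latent$time, 10))
  sampled <- latent$creatinine[idx]
  if (noise_sd > 0) {
    sampled <- sampled * exp(rnorm(length(sampled), 0, noise_sd))
  }
  list(
    latent = latent,
    sampled = tibble::tibble(time = schedule, scr_umol_l = sampled)
  )
}

#' Generate a synthetic transplant cohort
#'
#' Draws demographics, donor types and graft-function phenotypes, builds
#' phenotype-specific true-GFR trajectories (IGF: fast exponential rise
#' within hours; SGF: slow linear rise; DGF: near-zero GFR with dialysis
#' sessions), integrates the creatinine mass balance over the acute phase
#' (postoperative days 0-5), and emits noisy measurements on a realistic
#' schedule: an immediate post-operative value, one morning lab per
#' postoperative day 1-5, and follow-up visits around days 90/182/365.
#' Follow-up creatinine is drawn from the long-term steady state, which is
#' constructed to be consistent with the CKD-EPI equation. Output tables
#' use exactly the file dialect of [read_measurements()] /
#' [read_patients()], and the same seed reproduces the tables
#' byte-identically.
#'
#' @param config A [cohort_config()].
#' @return A list of class `kegfr_cohort`: `measurements`, `patients`,
#'   `true_state` (phenotype and ground-truth GFR per patient), `config`.
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  id <- sprintf("P%04d", seq_len(n))

  # demographics and transplant times
  ra <- config$recipient_age
  age <- round(rtrunc_norm(n, ra["mean"], ra["sd"], ra["min"], ra["max"]))
  sex <- ifelse(runif(n) < config$male_fraction, "male", "female")
  donor_type <- sample(names(config$donor_type_probs), n,
    replace = TRUE, prob = config$donor_type_probs
  )
  da <- config$donor_age
  donor_age <- round(rtrunc_norm(n, da["mean"], da["sd"], da["min"], da["max"]))
  preemptive <- runif(n) < config$preemptive_prob
  abo_incompatible <- runif(n) < config$abo_incompatible_prob
  transplant_time <- config$start_date + round(runif(n, 0, 8 * 365)) * 86400 +
    round(runif(n, -6, 6)) * 3600

  # phenotype conditional on donor type
  pp <- config$phenotype_probs
  u <- runif(n)
  cum1 <- pp[donor_type, "IGF"]
  cum2 <- cum1 + pp[donor_type, "SGF"]
  phenotype <- ifelse(u < cum1, "IGF", ifelse(u < cum2, "SGF", "DGF"))

  # ground truth scales
  og <- config$one_year_gfr
  g1_base <- rtrunc_norm(n, og["mean"], og["sd"], og["min"], og["max"])
  effect <- c(
    IGF = 0, SGF = config$sgf_effect_1yr, DGF = config$dgf_effect_1yr
  )[phenotype]
  g1 <- pmax(g1_base + effect, 8)
  c1 <- invert_ckd_epi(g1, age, sex)
  G <- 1.44 * g1 * c1
  V <- G / config$max_anuric_rise

  # acute-phase trajectory parameters; the IGF early plateau clears
  # creatinine to a normal-range target (equilibrium c = G / (1.44 g))
  c_target <- runif(
    n, config$igf_target_creatinine[1], config$igf_target_creatinine[2]
  )
  g_early <- pmax(G / (1.44 * c_target), g1)
  g0 <- runif(n, config$sgf_g0[1], config$sgf_g0[2])
  rise <- runif(n, config$sgf_rise[1], config$sgf_rise[2])
  g_dgf <- runif(n, config$dgf_gfr[1], config$dgf_gfr[2])
  bc <- config$baseline_creatinine
  c0 <- rtrunc_lnorm(n, bc["meanlog"], bc["sdlog"], bc["min"], bc["max"])

  noise_sd <- config$noise_sd
  if (config$steady_state) {
    c0 <- c1
    noise_sd <- 0
  }

  g_of_t <- function(t) {
    if (config$steady_state) {
      return(g1)
    }
    out <- numeric(n)
    igf <- phenotype == "IGF"
    sgf <- phenotype == "SGF"
    dgf <- phenotype == "DGF"
    out[igf] <- g_early[igf] * (1 - exp(-t / config$igf_tau_days))
    out[sgf] <- pmin(g0[sgf] + rise[sgf] * t, 1.5 * g1[sgf])
    out[dgf] <- g_dgf[dgf]
    out
  }

  # sampling schedule (days, aligned to the solver grid)
  step <- config$solver_step
  t0 <- 0.08 # immediate post-operative sample, ~2 h
  jit <- config$lab_jitter_hours
  daily <- outer(rep(1, n), 1:5) +
    round(matrix(runif(n * 5, -jit, jit), n, 5) / 24 / step) * step
  keep_t0 <- runif(n) >= config$missing_baseline
  keep_daily <- matrix(runif(n * 5) >= config$missing_daily, n, 5)
  fu_days <- outer(rep(1, n), config$followup_days) +
    round(matrix(
      runif(n * length(config$followup_days),
        -config$followup_jitter_days, config$followup_jitter_days
      ),
      n, length(config$followup_days)
    ))
  keep_fu <- matrix(
    runif(n * length(config$followup_days)) >= config$missing_followup,
    n, length(config$followup_days)
  )

  # integrate the acute phase on the common grid
  ev_days <- if (config$steady_state) numeric(0) else config$dialysis_days
  t_max <- max(daily) + step
  grid <- sort(unique(round(c(
    seq(0, t_max, by = step), t_max, t0, as.numeric(daily),
    ev_days[ev_days <= t_max]
  ), 10)))
  events <- NULL
  if (any(phenotype == "DGF") && length(ev_days)) {
    ev <- expand.grid(
      patient = which(phenotype == "DGF"),
      time = ev_days[ev_days <= t_max]
    )
    events <- data.frame(
      patient = ev$patient, time = ev$time, value = 1 - config$dialysis_drop
    )
  }
  sol <- integrate_cohort(c0, g_of_t, G, V, grid, events)
  grid_r <- round(sol[, 1], 10)
  latent_at <- function(tm, i) {
    sol[cbind(match(round(tm, 10), grid_r), i + 1L)]
  }

  # assemble acute measurements
  acute <- dplyr::bind_rows(
    tibble::tibble(
      i = which(keep_t0), time = t0,
      latent = latent_at(rep(t0, sum(keep_t0)), which(keep_t0))
    ),
    dplyr::bind_rows(lapply(1:5, function(k) {
      idx <- which(keep_daily[, k])
      tibble::tibble(
        i = idx, time = daily[idx, k], latent = latent_at(daily[idx, k], idx)
      )
    }))
  )
  # follow-up from the CKD-EPI-consistent steady state
  fu <- dplyr::bind_rows(lapply(seq_along(config$followup_days), function(k) {
    idx <- which(keep_fu[, k])
    tibble::tibble(i = idx, time = fu_days[idx, k], latent = c1[idx])
  }))
  meas <- dplyr::bind_rows(acute, fu)
  noise <- if (noise_sd > 0) exp(rnorm(nrow(meas), 0, noise_sd)) else 1
  measurements <- tibble::tibble(
    patient_id = id[meas$i],
    timestamp = transplant_time[meas$i] + round(meas$time * 86400),
    scr_umol_l = round(meas$latent * noise, 1)
  ) |>
    dplyr::arrange(.data$patient_id, .data$timestamp)

  dial <- lapply(seq_len(n), function(i) {
    if (phenotype[i] == "DGF" && !config$steady_state) {
      transplant_time[i] + round(config$dialysis_days * 86400)
    } else {
      as.POSIXct(character(), tz = "UTC")
    }
  })
  patients <- tibble::tibble(
    patient_id = id,
    transplant_time = transplant_time,
    age = age, sex = sex, donor_type = donor_type,
    preemptive = preemptive, abo_incompatible = abo_incompatible,
    donor_age = donor_age,
    dialysis_times = dial
  )

  pod1_time <- daily[, 1]
  true_state <- tibble::tibble(
    patient_id = id,
    phenotype = phenotype,
    true_gfr_pod1 = vapply(
      seq_len(n), function(i) g_of_t(pod1_time[i])[i], numeric(1)
    ),
    true_gfr_1yr = g1,
    generation_rate = G,
    volume = V,
    creatinine_at_transplant = c0,
    steady_state_creatinine = c1
  )
  structure(
    list(
      measurements = measurements, patients = patients,
      true_state = true_state, config = config
    ),
    class = "kegfr_cohort"
  )
}

#' @export
print.kegfr_cohort <- function(x, ...) {
  cat(sprintf(
    "<kegfr_cohort> %d patients, %d measurements (seed %d)\n",
    nrow(x$patients), nrow(x$measurements), x$config$seed
  ))
  print(table(x$true_state$phenotype))
  invisible(x)
}

#' End-to-end recovery report on a synthetic cohort
#'
#' Generates a cohort, runs the full estimation pipeline and labelling,
#' and reports how well each estimator recovers the simulated ground
#' truth: the POD1 mean absolute error against the true POD1 GFR, the
#' POD1 discrimination (AUC, DeLong) for SGF, the labelled SGF incidence
#' and its agreement with the generating phenotype, and the follow-up
#' regression estimate of the injected one-year SGF eGFR deficit.
#'
#' @param config A [cohort_config()].
#' @param pipeline_cfg A [pipeline_config()] (the default applies the
#'   published labelling rule).
#' @param n_boot Bootstrap replicates for AUC intervals (default 500).
#' @return A list of class `kegfr_recovery` with elements
#'   `discrimination` (see [evaluate_cohort()]), `mae_kegfr`,
#'   `mae_ckdepi`, `sgf_incidence`, `phenotype_agreement`, `regression`,
#'   `sgf_effect`, `sgf_effect_ci`, `manifest`.
#' @export
recovery_suite <- function(config, pipeline_cfg = pipeline_config(),
                           n_boot = 500) {
  cohort <- generate_cohort(config)
  pipe <- run_pipeline(cohort$measurements, cohort$patients, pipeline_cfg)
  disc <- evaluate_cohort(pipe,
    pod = 1, n_boot = n_boot,
    seed = config$seed + 1L
  )
  truth <- dplyr::select(
    cohort$true_state, "patient_id", "phenotype", "true_gfr_pod1"
  )
  sc <- dplyr::inner_join(disc$scores, truth, by = "patient_id")
  mae_k <- mean(abs(sc$KeGFR - sc$true_gfr_pod1))
  mae_c <- mean(abs(sc$`CKD-EPI` - sc$true_gfr_pod1))
  lab <- dplyr::inner_join(
    dplyr::filter(pipe$labels, .data$analyzed),
    truth,
    by = "patient_id"
  )
  agreement <- mean(
    (lab$status == "SGF") == (lab$phenotype == "SGF")
  )
  incidence <- mean(lab$status == "SGF")

  fu <- join_followup(cohort$measurements, cohort$patients, pipeline_cfg)
  fu12 <- fu |>
    dplyr::filter(.data$window == "m12") |>
    dplyr::select("patient_id", egfr_12m = "egfr")
  dat <- pipe$labels |>
    dplyr::filter(.data$analyzed, .data$status %in% c("SGF", "non-SGF")) |>
    dplyr::transmute(
      patient_id = .data$patient_id, sgf = .data$status == "SGF"
    ) |>
    dplyr::inner_join(
      dplyr::select(
        cohort$patients, "patient_id", "age", "sex", "donor_type"
      ),
      by = "patient_id"
    ) |>
    dplyr::inner_join(fu12, by = "patient_id") |>
    dplyr::mutate(
      donor_type = factor(.data$donor_type, levels = c("living", "DBD", "DCD"))
    )
  reg <- followup_regression(dat, egfr_12m ~ sgf + age + sex + donor_type)
  sgf_row <- reg[reg$term == "sgfTRUE", ]
  structure(
    list(
      discrimination = disc,
      mae_kegfr = mae_k, mae_ckdepi = mae_c,
      sgf_incidence = incidence,
      phenotype_agreement = agreement,
      regression = reg,
      sgf_effect = sgf_row$estimate,
      sgf_effect_ci = c(sgf_row$conf_low, sgf_row$conf_high),
      manifest = pipe$manifest
    ),
    class = "kegfr_recovery"
  )
}

#' @export
print.kegfr_recovery <- function(x, ...) {
  cat("<kegfr_recovery>\n")
  cat(sprintf(
    "  POD1 MAE vs true GFR: KeGFR %.1f, CKD-EPI %.1f mL/min/1.73m2\n",
    x$mae_kegfr, x$mae_ckdepi
  ))
  cat(sprintf(
    "  POD1 AUC: KeGFR %.3f, CKD-EPI %.3f (DeLong p = %.3g)\n",
    x$discrimination$roc_kegfr$auc, x$discrimination$roc_ckdepi$auc,
    x$discrimination$comparison$p_value
  ))
  cat(sprintf(
    "  SGF incidence %.1f%%, phenotype agreement %.1f%%\n",
    100 * x$sgf_incidence, 100 * x$phenotype_agreement
  ))
  cat(sprintf(
    "  one-year SGF effect: %.1f (95%% CI %.1f to %.1f)\n",
    x$sgf_effect, x$sgf_effect_ci[1], x$sgf_effect_ci[2]
  ))
  invisible(x)
}
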