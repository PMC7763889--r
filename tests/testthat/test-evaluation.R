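test_that("AUC handles separation, ties and declared orientation", {
  # lower score => positive
  expect_equal(roc_auc(1:4, c(TRUE, TRUE, FALSE, FALSE), n_boot = 0)$auc, 1)
  expect_equal(
    roc_auc(rep(2, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
      n_boot = 0
    )$auc, 0.5
  )
  # orientation is declared, not auto-flipped: reversing it mirrors the AUC
  s <- c(1, 5, 2, 8, 3, 9)
  l <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  a_low <- roc_auc(s, l, direction = "lower", n_boot = 0)$auc
  a_high <- roc_auc(s, l, direction = "higher", n_boot = 0)$auc
  expect_equal(a_low + a_high, 1)
  expect_equal(a_low, 1)
  expect_error(roc_auc(1:4, rep(TRUE, 4), n_boot = 0), "single class")
})

test_that("AUC equals exhaustive pair counting on randomized inputs", {
  withr::with_seed(31, {
    for (i in 1:12) {
      n <- sample(10:200, 1)
      # integer grid forces plenty of ties
      s <- sample(0:25, n, replace = TRUE)
      l <- stats::runif(n) < 0.4
      if (all(l) || !any(l)) l[1:2] <- c(TRUE, FALSE)
      expect_equal(
        roc_auc(s, l, n_boot = 0)$auc, pair_count_auc(s, l),
        tolerance = 1e-12
      )
    }
  })
})

test_that("the ROC curve is monotone in (1 - Sp, Se) space", {
  withr::with_seed(12, {
    s <- rnorm(80)
    l <- stats::runif(80) < 0.35
    cv <- roc_auc(s, l, n_boot = 0)
    o <- order(1 - cv$specificity, cv$sensitivity)
    expect_true(all(diff(cv$sensitivity[o]) >= 0))
    expect_true(all(cv$auc >= 0 & cv$auc <= 1))
  })
})

test_that("the bootstrap interval is seeded, ordered and covers the estimate", {
  withr::with_seed(2, {
    s <- c(rnorm(40, 0), rnorm(60, 1.2))
    l <- rep(c(TRUE, FALSE), c(40, 60))
  })
  r1 <- roc_auc(s, l, n_boot = 300, seed = 9)
  r2 <- roc_auc(s, l, n_boot = 300, seed = 9)
  expect_identical(r1$auc_ci, r2$auc_ci)
  expect_lt(r1$auc_ci[1], r1$auc)
  expect_gt(r1$auc_ci[2], r1$auc)
  expect_error(roc_auc(s, l, n_boot = 10), "seed")
})

test_that("bootstrap interval coverage is nominal for a known true AUC", {
  # positives ~ N(0,1), negatives ~ N(d,1), lower => positive, so the
  # population AUC is pnorm(d / sqrt(2))
  d <- 1.2
  truth <- pnorm(d / sqrt(2))
  n_rep <- 200
  covered <- withr::with_seed(77, {
    vapply(seq_len(n_rep), function(i) {
      s <- c(rnorm(45, 0), rnorm(75, d))
      l <- rep(c(TRUE, FALSE), c(45, 75))
      ci <- roc_auc(s, l, n_boot = 400, seed = i)$auc_ci
      ci[1] <= truth && truth <= ci[2]
    }, logical(1))
  })
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("DeLong comparison is symmetric and null on identical scores", {
  withr::with_seed(5, {
    s <- rnorm(60)
    l <- stats::runif(60) < 0.4
  })
  ra <- roc_auc(s, l, n_boot = 0)
  self <- delong_compare(ra, ra)
  expect_equal(self$z, 0)
  expect_equal(self$p_value, 1)
  withr::with_seed(6, s2 <- s + rnorm(60, 0, 0.8))
  rb <- roc_auc(s2, l, n_boot = 0)
  ab <- delong_compare(ra, rb)
  ba <- delong_compare(rb, ra)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(
    delong_compare(ra, roc_auc(s2, !l, n_boot = 0)), "paired"
  )
})

test_that("DeLong agrees with the reference implementation in pROC", {
  withr::with_seed(41, {
    for (i in 1:5) {
      n <- 80
      l <- rep(c(TRUE, FALSE), c(30, 50))
      sa <- ifelse(l, rnorm(n, 0), rnorm(n, 1))
      sb <- sa + rnorm(n, 0, 0.7)
      ra <- roc_auc(sa, l, n_boot = 0)
      rb <- roc_auc(sb, l, n_boot = 0)
      ours <- delong_compare(ra, rb)
      ref <- pROC::roc.test(
        pROC::roc(l, sa, direction = ">", quiet = TRUE),
        pROC::roc(l, sb, direction = ">", quiet = TRUE),
        method = "delong", paired = TRUE
      )
      expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-8)
    }
  })
})

test_that("DeLong p-values are uniform under the null", {
  p <- withr::with_seed(55, {
    vapply(1:200, function(i) {
      l <- rep(c(TRUE, FALSE), c(30, 50))
      base <- ifelse(l, rnorm(80, 0), rnorm(80, 0.8))
      sa <- base + rnorm(80, 0, 0.5)
      sb <- base + rnorm(80, 0, 0.5)
      delong_compare(
        roc_auc(sa, l, n_boot = 0), roc_auc(sb, l, n_boot = 0)
      )$p_value
    }, numeric(1))
  })
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("the ROC01 cutoff is never beaten by any observed threshold", {
  withr::with_seed(13, {
    for (i in 1:10) {
      n <- sample(20:150, 1)
      s <- round(c(rnorm(n, 0), rnorm(n, 1.1)), 1)
      l <- rep(c(TRUE, FALSE), c(n, n))
      cv <- roc_auc(s, l, n_boot = 0)
      cut <- roc01_cutoff(cv)
      d_best <- sqrt((1 - cut$sensitivity)^2 + (1 - cut$specificity)^2)
      expect_equal(d_best, roc01_scan(s, l), tolerance = 1e-12)
    }
  })
})

test_that("ROC01 endpoints: perfect separation and degenerate ties", {
  cv <- roc_auc(c(1, 2, 10, 11), c(TRUE, TRUE, FALSE, FALSE), n_boot = 0)
  cut <- roc01_cutoff(cv)
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)
  expect_equal(cut$ppv, 1)
  deg <- roc_auc(rep(3, 8), rep(c(TRUE, FALSE), 4), n_boot = 0)
  cut_deg <- roc01_cutoff(deg)
  expect_equal(cut_deg$sensitivity + cut_deg$specificity, 1)
})

test_that("Bland-Altman bias and limits follow the defining arithmetic", {
  ba0 <- bland_altman(c(5, 8, 13), c(5, 8, 13))
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_lower, ba0$loa_upper), c(0, 0))
  # differences {-1, 0, 1}: sample sd is exactly 1
  ba <- bland_altman(c(9, 10, 11), c(10, 10, 10))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_upper, 1.96)
  expect_equal(ba$loa_lower, -1.96)
  # antisymmetry under swapping the inputs
  x <- c(12, 30, 44, 51)
  y <- c(15, 28, 40, 60)
  expect_equal(bland_altman(x, y)$bias, -bland_altman(y, x)$bias)
  expect_error(bland_altman(c(1, 2), c(1, 2)), "3")
})

test_that("single-covariate regression equals the group mean difference", {
  withr::with_seed(9, {
    sgf <- rep(c(TRUE, FALSE), c(30, 70))
    y <- ifelse(sgf, 45, 55) + rnorm(100, 0, 8)
  })
  dat <- data.frame(egfr = y, sgf = sgf)
  fit <- followup_regression(dat, egfr ~ sgf)
  expect_equal(
    fit$estimate[fit$term == "sgfTRUE"],
    mean(y[sgf]) - mean(y[!sgf]),
    tolerance = 1e-12
  )
})

test_that("rank deficiency is reported, not silently dropped", {
  dat <- data.frame(y = rnorm(20), a = rnorm(20))
  dat$b <- dat$a # aliased copy
  expect_warning(fit <- followup_regression(dat, y ~ a + b), "aliased")
  expect_true(any(is.na(fit$estimate)))
})

test_that("cohort summary reproduces the exact Fisher and Holm arithmetic", {
  # a 10/0 vs 0/10 cross-classification: the two-sided exact p is the
  # hypergeometric mass of the two extreme tables
  dat <- data.frame(
    group = rep(c("SGF", "non-SGF"), each = 10),
    exposed = rep(c(TRUE, FALSE), each = 10),
    age = c(seq(40, 58, 2), seq(60, 78, 2))
  )
  out <- cohort_summary(dat, "group")
  p_fisher <- out$p_value[out$variable == "exposed"]
  expect_equal(p_fisher, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(
    p_fisher,
    fisher_enum_p(table(dat$exposed, dat$group)),
    tolerance = 1e-12
  )
  # Holm adjustment across the table rows matches the step-down by hand
  expect_equal(out$p_holm, holm_by_hand(out$p_value), tolerance = 1e-12)
  expect_true(all(out$p_holm >= out$p_value))
})

test_that("identical group distributions give uninformative p-values", {
  dat <- data.frame(
    group = rep(c("SGF", "non-SGF"), each = 30),
    age = rep(seq(30, 70, length.out = 30), 2),
    male = rep(rep(c(TRUE, FALSE), 15), 2)
  )
  out <- cohort_summary(dat, "group")
  expect_true(all(out$p_value > 0.9))
  expect_true(all(out$p_holm >= out$p_value))
})

test_that("stratified analysis reduces to the global one for one stratum", {
  withr::with_seed(17, {
    n <- 120
    l <- stats::runif(n) < 0.3
    dat <- data.frame(
      ka = ifelse(l, rnorm(n, 10, 4), rnorm(n, 30, 8)),
      cc = ifelse(l, rnorm(n, 12, 5), rnorm(n, 20, 8)),
      sgf = l,
      one = "all"
    )
  })
  strat <- subgroup_roc(dat, "ka", "cc", "sgf", "one")
  ra <- roc_auc(dat$ka, dat$sgf, n_boot = 0)
  rb <- roc_auc(dat$cc, dat$sgf, n_boot = 0)
  glob <- delong_compare(ra, rb)
  expect_equal(nrow(strat), 1)
  expect_equal(strat$auc_a, glob$auc_a)
  expect_equal(strat$p_value, glob$p_value)
  # disjoint copies of one cohort give identical per-stratum AUCs
  two <- rbind(
    transform(dat, one = "s1"), transform(dat, one = "s2")
  )
  st2 <- subgroup_roc(two, "ka", "cc", "sgf", "one")
  expect_equal(st2$auc_a[1], st2$auc_a[2])
  expect_equal(st2$auc_b[1], st2$auc_b[2])
  # a single-class stratum is skipped with a message
  dat2 <- dat
  dat2$one[dat2$sgf] <- "mixed"
  dat2$one[!dat2$sgf] <- "pure"
  expect_message(
    st3 <- subgroup_roc(dat2, "ka", "cc", "sgf", "one"), "single"
  )
  expect_equal(nrow(st3), 0)
})
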