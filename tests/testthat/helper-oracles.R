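# Independent oracles used across the suite. Each reimplements the target
# quantity by a different route (enumeration, closed form, published
# piecewise table) so the package code is checked against something it
# does not share an implementation with.

# 2009 CKD-EPI creatinine equation in its published four-branch piecewise
# form (sex- and range-specific rows), written independently of the
# package's single min/max expression. Creatinine in mg/dL.
ref_ckd_epi_mgdl <- function(scr_mgdl, age, sex, black = FALSE) {
  stopifnot(length(scr_mgdl) == 1)
  base <- if (sex == "female") {
    if (scr_mgdl <= 0.7) {
      141 * 1.018 * (scr_mgdl / 0.7)^(-0.329)
    } else {
      141 * 1.018 * (scr_mgdl / 0.7)^(-1.209)
    }
  } else {
    if (scr_mgdl <= 0.9) {
      141 * (scr_mgdl / 0.9)^(-0.411)
    } else {
      141 * (scr_mgdl / 0.9)^(-1.209)
    }
  }
  base * 0.993^age * if (black) 1.159 else 1
}

# AUC by exhaustive positive/negative pair counting, ties worth one half.
# Orientation: lower score indicates the positive class.
pair_count_auc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  total <- 0
  for (p in pos) {
    total <- total + sum(p < neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Exhaustive ROC01 scan: evaluate every candidate threshold directly from
# the prediction rule (score <= t => positive) and return the minimal
# distance to the (0, 1) corner.
roc01_scan <- function(score, label) {
  thresholds <- c(-Inf, sort(unique(score)), Inf)
  best <- Inf
  for (t in thresholds) {
    pred <- score <= t
    se <- mean(pred[label])
    sp <- mean(!pred[!label])
    d <- sqrt((1 - se)^2 + (1 - sp)^2)
    if (d < best) best <- d
  }
  best
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables with fixed margins that are no more
# probable than the observed one.
fisher_enum_p <- function(tab) {
  stopifnot(dim(tab) == c(2, 2))
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x_obs, m, n, k)
  sum(dens[dens <= p_obs * (1 + 1e-7)])
}

# Permutation oracle for the paired AUC comparison: under the null the
# two methods are exchangeable within patient, so the reference
# distribution of the AUC difference is generated by random per-patient
# swaps of the two scores.
permutation_auc_p <- function(score_a, score_b, label, n_perm = 10000,
                              seed = 1) {
  auc_of <- function(s) {
    r <- rank(-s) # lower score => positive orientation
    m <- sum(label)
    (sum(r[label]) - m * (m + 1) / 2) / (m * sum(!label))
  }
  obs <- abs(auc_of(score_a) - auc_of(score_b))
  n <- length(label)
  withr::with_seed(seed, {
    hits <- 0
    for (i in seq_len(n_perm)) {
      swap <- stats::runif(n) < 0.5
      sa <- ifelse(swap, score_b, score_a)
      sb <- ifelse(swap, score_a, score_b)
      if (abs(auc_of(sa) - auc_of(sb)) >= obs - 1e-12) hits <- hits + 1
    }
    (1 + hits) / (1 + n_perm)
  })
}

# Holm's step-down adjustment applied by hand (sort, multiply by the
# number of remaining hypotheses, enforce monotonicity, cap at one).
holm_by_hand <- function(p) {
  k <- length(p)
  o <- order(p)
  adj <- pmin(p[o] * (k - seq_len(k) + 1), 1)
  adj <- cummax(adj)
  out <- numeric(k)
  out[o] <- adj
  out
}

# Small deterministic cohort tables built in code for pipeline tests:
# one patient with measurements at given hours after transplant.
make_measurements <- function(patient_id, hours, scr,
                              t0 = as.POSIXct("2020-03-01 08:00:00",
                                tz = "UTC"
                              )) {
  tibble::tibble(
    patient_id = patient_id,
    timestamp = t0 + hours * 3600,
    scr_umol_l = scr
  )
}

make_patient <- function(patient_id, age = 50, sex = "male",
                         donor_type = "living", dialysis_hours = numeric(0),
                         t0 = as.POSIXct("2020-03-01 08:00:00", tz = "UTC")) {
  tibble::tibble(
    patient_id = patient_id,
    transplant_time = t0,
    age = age, sex = sex, donor_type = donor_type,
    preemptive = FALSE, abo_incompatible = FALSE,
    donor_age = 45,
    dialysis_times = list(if (length(dialysis_hours)) {
      t0 + dialysis_hours * 3600
    } else {
      as.POSIXct(character(), tz = "UTC")
    })
  )
}
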