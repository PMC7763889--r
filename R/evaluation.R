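# ---- ROC machinery -------------------------------------------------------
#
# Orientation is declared, never auto-flipped: with direction = "lower"
# (the default here) a LOWER score marks the positive class, and a case is
# predicted positive when score <= threshold. An AUC below 0.5 is therefore
# a meaningful result, not an error.

# AUC = P(score_pos "beats" score_neg) + 0.5 P(tie), by midranks,
# on scores oriented so that HIGHER means positive.
auc_midrank <- function(oriented_score, positive) {
  m <- sum(positive)
  n <- sum(!positive)
  r <- rank(oriented_score)
  (sum(r[positive]) - m * (m + 1) / 2) / (m * n)
}

#' ROC curve and AUC for a graft-function score
#'
#' Builds the empirical ROC curve of a continuous score against a binary
#' label, with the area under the curve computed by the midrank
#' Mann-Whitney statistic (ties count one half) and a patient-level
#' bootstrap percentile confidence interval.
#'
#' The threshold set is the observed score values plus infinite sentinels;
#' with `direction = "lower"` a case is predicted positive when
#' `score <= threshold` (low eGFR suggests slow graft function).
#'
#' @param score Numeric score per patient (e.g. a POD1 eGFR estimate).
#' @param label Logical (TRUE = positive class), or a factor/character
#'   interpreted via `positive`.
#' @param positive Value of `label` marking the positive class (default
#'   `"SGF"`; ignored for logical labels).
#' @param direction `"lower"`: lower scores indicate the positive class
#'   (default); `"higher"` for the opposite orientation.
#' @param n_boot Bootstrap replicates for the AUC confidence interval
#'   (default 2000; 0 skips the interval).
#' @param seed Seed for the bootstrap (required when `n_boot > 0`).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `kegfr_roc`: thresholds, sensitivity,
#'   specificity, `auc`, `auc_ci`, plus the (complete-case) scores and
#'   labels used.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE), n_boot = 0)$auc
#' @export
roc_auc <- function(score, label, positive = "SGF",
                    direction = c("lower", "higher"),
                    n_boot = 2000, seed = NULL, conf_level = 0.95) {
  direction <- match.arg(direction)
  if (!is.logical(label)) label <- as.character(label) == positive
  keep <- complete.cases(score, label)
  score <- score[keep]
  label <- label[keep]
  if (length(score) == 0 || all(label) || !any(label)) {
    abort("ROC analysis needs both classes present; got a single class.")
  }
  # orient so that higher oriented score indicates the positive class
  oriented <- if (direction == "lower") -score else score
  auc <- auc_midrank(oriented, label)
  thresholds <- c(-Inf, sort(unique(score)), Inf)
  pos_cdf <- ecdf(score[label])
  neg_cdf <- ecdf(score[!label])
  if (direction == "lower") {
    se <- pos_cdf(thresholds)       # P(score_pos <= t)
    sp <- 1 - neg_cdf(thresholds)   # P(score_neg >  t)
  } else {
    se <- vapply(thresholds, function(t) mean(score[label] >= t), numeric(1))
    sp <- vapply(thresholds, function(t) mean(score[!label] < t), numeric(1))
  }
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    if (is.null(seed)) abort("A `seed` is required for the bootstrap interval.")
    n <- length(score)
    ci <- withr::with_seed(seed, {
      reps <- vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        if (all(label[idx]) || !any(label[idx])) return(NA_real_)
        auc_midrank(oriented[idx], label[idx])
      }, numeric(1))
      alpha <- (1 - conf_level) / 2
      unname(quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE))
    })
  }
  structure(
    list(
      thresholds = thresholds, sensitivity = se, specificity = sp,
      auc = auc, auc_ci = ci, conf_level = conf_level,
      direction = direction, score = score, label = label,
      n_pos = sum(label), n_neg = sum(!label), n_boot = n_boot, seed = seed
    ),
    class = "kegfr_roc"
  )
}

#' @export
print.kegfr_roc <- function(x, ...) {
  cat(sprintf(
    "<kegfr_roc> AUC %.3f", x$auc
  ))
  if (!is.na(x$auc_ci[1])) {
    cat(sprintf(" (%.0f%% CI %.3f-%.3f, %d bootstrap reps)",
      100 * x$conf_level, x$auc_ci[1], x$auc_ci[2], x$n_boot
    ))
  }
  cat(sprintf(
    "\n  %d positives / %d negatives, direction: %s score => positive\n",
    x$n_pos, x$n_neg, x$direction
  ))
  invisible(x)
}

#' Compare two paired AUCs by the DeLong method
#'
#' Nonparametric comparison of the AUCs of two scores measured on the same
#' patients with the same labels, using the DeLong structural-components
#' covariance estimate and a two-sided normal reference for the difference.
#' Swapping the two curves negates the z statistic and leaves the p-value
#' unchanged; identical scores give z = 0, p = 1.
#'
#' @param curve_a,curve_b `kegfr_roc` objects built from the same patients
#'   (identical labels, same orientation).
#' @return A list of class `kegfr_auc_comparison`: `auc_a`, `auc_b`,
#'   `auc_diff`, `z`, `p_value`, `method`.
#' @export
delong_compare <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "kegfr_roc"), inherits(curve_b, "kegfr_roc"))
  if (length(curve_a$label) != length(curve_b$label) ||
      !identical(curve_a$label, curve_b$label)) {
    abort("The two curves must be paired: same patients, same labels.")
  }
  if (curve_a$direction != curve_b$direction) {
    abort("The two curves must use the same score orientation.")
  }
  label <- curve_a$label
  orient <- function(cv) if (cv$direction == "lower") -cv$score else cv$score
  sa <- orient(curve_a)
  sb <- orient(curve_b)
  m <- sum(label)
  n <- sum(!label)
  psi <- function(x, y) {
    outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  }
  pa <- psi(sa[label], sa[!label])
  pb <- psi(sb[label], sb[!label])
  auc_a <- mean(pa)
  auc_b <- mean(pb)
  v10 <- cbind(rowMeans(pa), rowMeans(pb)) # placements of positives
  v01 <- cbind(colMeans(pa), colMeans(pb)) # placements of negatives
  s10 <- stats::cov(v10)
  s01 <- stats::cov(v01)
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_diff <= 0 || !is.finite(var_diff)) {
    z <- 0
    p <- 1
  } else {
    z <- (auc_a - auc_b) / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(
    list(
      auc_a = auc_a, auc_b = auc_b, auc_diff = auc_a - auc_b,
      z = z, p_value = p, method = "delong_paired", n_pos = m, n_neg = n
    ),
    class = "kegfr_auc_comparison"
  )
}

#' @export
print.kegfr_auc_comparison <- function(x, ...) {
  cat(sprintf(
    "<kegfr_auc_comparison> AUC %.3f vs %.3f (diff %+.3f), z = %.2f, p = %.3g\n",
    x$auc_a, x$auc_b, x$auc_diff, x$z, x$p_value
  ))
  invisible(x)
}

#' Optimal cutpoint by the ROC01 criterion
#'
#' Selects the threshold minimising the Euclidean distance of the ROC
#' point to perfect classification (the (0, 1) corner in (1 - specificity,
#' sensitivity) space). Ties are broken towards higher sensitivity, then
#' the lower threshold. The positive predictive value is computed from the
#' confusion table at the selected cutoff.
#'
#' @param curve A `kegfr_roc` object.
#' @return A tibble `cutoff`, `sensitivity`, `specificity`, `ppv`,
#'   `criterion`.
#' @export
roc01_cutoff <- function(curve) {
  stopifnot(inherits(curve, "kegfr_roc"))
  d <- sqrt((1 - curve$sensitivity)^2 + (1 - curve$specificity)^2)
  ord <- order(d, -curve$sensitivity, curve$thresholds)
  i <- ord[1]
  cut <- curve$thresholds[i]
  pred_pos <- if (curve$direction == "lower") {
    curve$score <= cut
  } else {
    curve$score >= cut
  }
  tp <- sum(pred_pos & curve$label)
  fp <- sum(pred_pos & !curve$label)
  tibble::tibble(
    cutoff = cut,
    sensitivity = curve$sensitivity[i],
    specificity = curve$specificity[i],
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    criterion = "roc01"
  )
}

#' Bland-Altman agreement analysis
#'
#' Paired-difference agreement between two measurements of the same
#' quantity: bias = mean(x - y) and limits of agreement
#' bias +/- 1.96 * sd(x - y) (sample standard deviation). Incomplete pairs
#' are dropped; fewer than three complete pairs is an error.
#'
#' @param x,y Paired numeric vectors (e.g. a POD1 estimate and the
#'   one-year eGFR).
#' @return A list of class `kegfr_bland_altman`: `bias`, `loa_lower`,
#'   `loa_upper`, `sd`, `n`, plus the per-pair `means` and `differences`.
#' @examples
#' bland_altman(c(10, 20, 30), c(11, 20, 29))
#' @export
bland_altman <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) {
    abort("Bland-Altman analysis needs at least 3 complete pairs.")
  }
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(
      bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
      sd = s, n = length(d), means = (x + y) / 2, differences = d
    ),
    class = "kegfr_bland_altman"
  )
}

#' @export
print.kegfr_bland_altman <- function(x, ...) {
  cat(sprintf(
    "<kegfr_bland_altman> bias %.1f, limits of agreement [%.1f, %.1f], n = %d\n",
    x$bias, x$loa_lower, x$loa_upper, x$n
  ))
  invisible(x)
}

#' Multivariable linear regression of follow-up eGFR
#'
#' Ordinary least squares of an outcome (typically one-year eGFR) on SGF
#' status and covariates, on complete cases. Rank-deficient fits are
#' reported: aliased terms appear with `NA` estimates and a warning is
#' raised rather than silently dropping them.
#'
#' @param data A data frame containing the model variables.
#' @param formula Model formula, e.g.
#'   `egfr_12m ~ sgf + age + sex + donor_type`.
#' @param conf_level Confidence level for the intervals (default 0.95).
#' @return A tibble `term`, `estimate`, `conf_low`, `conf_high`,
#'   `p_value`, with the fitted `lm` object as attribute `"model"`.
#' @export
followup_regression <- function(data, formula, conf_level = 0.95) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  fit <- lm(formula, data = mf)
  cf <- coef(fit)
  aliased <- names(cf)[is.na(cf)]
  if (length(aliased)) {
    warn(paste0(
      "Rank-deficient fit; aliased term(s): ",
      paste(aliased, collapse = ", ")
    ))
  }
  s <- summary(fit)$coefficients
  ci <- confint(fit, level = conf_level)
  out <- tibble::tibble(
    term = names(cf),
    estimate = unname(cf),
    conf_low = ci[names(cf), 1],
    conf_high = ci[names(cf), 2],
    p_value = ifelse(names(cf) %in% rownames(s),
      s[match(names(cf), rownames(s)), "Pr(>|t|)"], NA_real_
    )
  )
  attr(out, "model") <- fit
  out
}

#' Baseline cohort description with group comparisons
#'
#' Describes each variable by SGF group the way transplant baseline tables
#' do: continuous variables as median (Q1, Q3) compared by the Wilcoxon
#' rank-sum test; categorical variables as count (%) compared by Fisher's
#' exact test. P-values are Holm-adjusted across all rows of the table.
#' Variables that are constant or missing in a group are skipped with a
#' message.
#'
#' @param data Per-patient data frame.
#' @param group Name of a two-level grouping column (e.g. label status
#'   restricted to SGF / non-SGF).
#' @param vars Character vector of variable names to summarise (default:
#'   all columns except `group` and identifiers).
#' @return A tibble `variable`, `type`, one summary column per group
#'   level, `test`, `p_value`, `p_holm`.
#' @export
cohort_summary <- function(data, group, vars = NULL) {
  g <- data[[group]]
  if (is.factor(g)) g <- droplevels(g)
  g <- as.factor(g)
  if (nlevels(g) != 2) {
    abort("`group` must have exactly two observed levels.")
  }
  if (is.null(vars)) {
    vars <- setdiff(names(data), c(group, "patient_id"))
  }
  lv <- levels(g)
  rows <- lapply(vars, function(v) {
    x <- data[[v]]
    ok <- !is.na(x) & !is.na(g)
    x <- x[ok]
    gg <- droplevels(g[ok])
    if (length(x) == 0 || nlevels(gg) < 2) {
      inform(sprintf("Skipping '%s': empty in at least one group.", v))
      return(NULL)
    }
    if (is.numeric(x)) {
      summ <- vapply(lv, function(l) {
        q <- quantile(x[gg == l], c(0.5, 0.25, 0.75))
        sprintf("%.1f (%.1f, %.1f)", q[1], q[2], q[3])
      }, character(1))
      # ties trigger the routine switch to the normal approximation
      p <- tryCatch(suppressWarnings(wilcox.test(x ~ gg)$p.value),
        error = function(e) NA_real_
      )
      test <- "wilcoxon"
      type <- "continuous"
    } else {
      if (is.logical(x)) x <- factor(x, levels = c(FALSE, TRUE))
      x <- droplevels(as.factor(x))
      if (nlevels(x) < 2) {
        inform(sprintf("Skipping '%s': constant.", v))
        return(NULL)
      }
      tab <- table(x, gg)
      summ <- vapply(lv, function(l) {
        cnt <- tab[, l]
        tot <- sum(cnt)
        lev <- if (nlevels(x) == 2) 2 else which.max(cnt)
        sprintf("%d (%.1f%%)", cnt[lev], 100 * cnt[lev] / tot)
      }, character(1))
      p <- tryCatch(fisher.test(tab)$p.value, error = function(e) NA_real_)
      test <- "fisher"
      type <- "categorical"
    }
    out <- tibble::tibble(variable = v, type = type)
    out[[paste0("summary_", lv[1])]] <- summ[1]
    out[[paste0("summary_", lv[2])]] <- summ[2]
    out$test <- test
    out$p_value <- p
    out
  })
  res <- dplyr::bind_rows(rows)
  res$p_holm <- p.adjust(res$p_value, method = "holm")
  res
}

#' Stratified AUC comparison
#'
#' Runs [roc_auc()] for both scores and [delong_compare()] within each
#' stratum of a grouping variable (sex, donor type, ...). Strata with a
#' single outcome class are skipped with a message.
#'
#' @param data Per-patient data frame with two score columns, a label
#'   column and the stratifier.
#' @param score_a,score_b Names of the two score columns.
#' @param label Name of the label column (logical, or matched against
#'   `positive`).
#' @param stratifier Name of the stratification column.
#' @inheritParams roc_auc
#' @return A tibble with one row per usable stratum: `stratum`, `n`,
#'   `n_pos`, `auc_a`, `auc_b`, `auc_diff`, `z`, `p_value`.
#' @export
subgroup_roc <- function(data, score_a, score_b, label, stratifier,
                         positive = "SGF", direction = "lower",
                         n_boot = 0, seed = NULL) {
  strata <- split(data, data[[stratifier]], drop = TRUE)
  rows <- lapply(names(strata), function(sname) {
    d <- strata[[sname]]
    lab <- d[[label]]
    if (!is.logical(lab)) lab <- as.character(lab) == positive
    keep <- complete.cases(d[[score_a]], d[[score_b]], lab)
    if (sum(lab[keep]) == 0 || sum(!lab[keep]) == 0) {
      inform(sprintf("Skipping stratum '%s': single outcome class.", sname))
      return(NULL)
    }
    ra <- roc_auc(d[[score_a]][keep], lab[keep],
      direction = direction, n_boot = n_boot, seed = seed
    )
    rb <- roc_auc(d[[score_b]][keep], lab[keep],
      direction = direction, n_boot = n_boot, seed = seed
    )
    cmp <- delong_compare(ra, rb)
    tibble::tibble(
      stratum = sname, n = sum(keep), n_pos = sum(lab[keep]),
      auc_a = cmp$auc_a, auc_b = cmp$auc_b, auc_diff = cmp$auc_diff,
      z = cmp$z, p_value = cmp$p_value
    )
  })
  dplyr::bind_rows(rows)
}

#' Head-to-head discrimination report at a postoperative day
#'
#' Assembles the per-patient scores of both estimators at a given POD for
#' the analyzed patients with a determinate label, and computes ROC/AUC
#' for each, the paired DeLong comparison, and the ROC01 optimal cutoffs.
#' Scores are oriented so that a lower eGFR indicates slow graft function.
#'
#' @param pipeline A `kegfr_pipeline` from [run_pipeline()].
#' @param pod Postoperative day to evaluate (default 1).
#' @param n_boot Bootstrap replicates for the AUC intervals.
#' @param seed Seed for the bootstrap.
#' @return A list of class `kegfr_discrimination`: `scores` (tibble),
#'   `roc_kegfr`, `roc_ckdepi`, `comparison`, `cutoff_kegfr`,
#'   `cutoff_ckdepi`, `pod`, `n`.
#' @export
evaluate_cohort <- function(pipeline, pod = 1, n_boot = 2000, seed = 1L) {
  stopifnot(inherits(pipeline, "kegfr_pipeline"))
  lab <- pipeline$labels |>
    dplyr::filter(.data$analyzed) |>
    dplyr::select("patient_id", "status")
  wide <- pipeline$estimates |>
    dplyr::filter(.data$pod == !!pod) |>
    dplyr::select("patient_id", "method", "value") |>
    tidyr::pivot_wider(names_from = "method", values_from = "value") |>
    dplyr::inner_join(lab, by = "patient_id")
  if (!all(c("KeGFR", "CKD-EPI") %in% names(wide))) {
    abort(sprintf("No estimates available at POD %d.", pod))
  }
  scores <- wide |>
    dplyr::filter(
      !is.na(.data$KeGFR), !is.na(.data$`CKD-EPI`),
      .data$status %in% c("SGF", "non-SGF")
    ) |>
    dplyr::mutate(sgf = .data$status == "SGF")
  roc_k <- roc_auc(scores$KeGFR, scores$sgf,
    direction = "lower", n_boot = n_boot, seed = seed
  )
  roc_c <- roc_auc(scores$`CKD-EPI`, scores$sgf,
    direction = "lower", n_boot = n_boot, seed = seed
  )
  structure(
    list(
      scores = scores,
      roc_kegfr = roc_k,
      roc_ckdepi = roc_c,
      comparison = delong_compare(roc_k, roc_c),
      cutoff_kegfr = roc01_cutoff(roc_k),
      cutoff_ckdepi = roc01_cutoff(roc_c),
      pod = pod, n = nrow(scores)
    ),
    class = "kegfr_discrimination"
  )
}

#' @export
print.kegfr_discrimination <- function(x, ...) {
  cat(sprintf("<kegfr_discrimination> POD %d, n = %d (%d SGF)\n",
    x$pod, x$n, sum(x$scores$sgf)
  ))
  cat(sprintf("  KeGFR   AUC %.3f (CI %.3f-%.3f)\n",
    x$roc_kegfr$auc, x$roc_kegfr$auc_ci[1], x$roc_kegfr$auc_ci[2]
  ))
  cat(sprintf("  CKD-EPI AUC %.3f (CI %.3f-%.3f)\n",
    x$roc_ckdepi$auc, x$roc_ckdepi$auc_ci[1], x$roc_ckdepi$auc_ci[2]
  ))
  cat(sprintf("  DeLong: z = %.2f, p = %.3g\n",
    x$comparison$z, x$comparison$p_value
  ))
  cat(sprintf("  ROC01 cutoffs: KeGFR %.1f, CKD-EPI %.1f mL/min/1.73m2\n",
    x$cutoff_kegfr$cutoff, x$cutoff_ckdepi$cutoff
  ))
  invisible(x)
}
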