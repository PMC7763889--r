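#' Pipeline configuration
#'
#' Collects the tunable rules of the estimation pipeline in one list so a
#' run is fully described by its configuration.
#'
#' @param max_gap_hours Maximal spacing of a creatinine pair eligible for
#'   the kinetic estimate, in hours (default 36).
#' @param pod_window_hours Half-width of the window used to assign a
#'   measurement to postoperative day k (centred on k*24 h; default 12).
#' @param max_pod Last acute postoperative day considered (default 5).
#' @param sgf_definition `"primary"` (CRR rule) or `"humar"` (POD5 rule).
#' @param crr_comparator Direction of the CRR comparison in the primary
#'   rule; see [label_sgf_primary()].
#' @param exclude_dgf Strict labelling mode; see [label_cohort()].
#' @param exclude_dialysis_pairs Drop creatinine pairs spanning a dialysis
#'   session from the kinetic estimate (creatinine is then removed
#'   non-renally; default TRUE).
#' @param max_delta_pcr Maximal daily creatinine rise assumed by the
#'   kinetic formula, micromol/L/day (default 133).
#' @param clamp_negative Clamp negative kinetic estimates to zero.
#' @param anchor `"first_post_transplant"` (default): the anchor creatinine
#'   is the first value recorded after transplantation; `"baseline"`: the
#'   last value before transplantation, when available.
#' @param followup_windows Named list of `c(lower, upper, centre)` day
#'   windows for the 3/6/12-month follow-up visits.
#' @return A list of class `kegfr_config`.
#' @export
pipeline_config <- function(max_gap_hours = 36,
                            pod_window_hours = 12,
                            max_pod = 5,
                            sgf_definition = c("primary", "humar"),
                            crr_comparator = c("gt", "lt"),
                            exclude_dgf = FALSE,
                            exclude_dialysis_pairs = TRUE,
                            max_delta_pcr = 133,
                            clamp_negative = TRUE,
                            anchor = c("first_post_transplant", "baseline"),
                            followup_windows = list(
                              m3 = c(60, 120, 90),
                              m6 = c(150, 210, 180),
                              m12 = c(330, 400, 365)
                            )) {
  cfg <- list(
    max_gap_hours = max_gap_hours,
    pod_window_hours = pod_window_hours,
    max_pod = max_pod,
    sgf_definition = match.arg(sgf_definition),
    crr_comparator = match.arg(crr_comparator),
    exclude_dgf = exclude_dgf,
    exclude_dialysis_pairs = exclude_dialysis_pairs,
    max_delta_pcr = max_delta_pcr,
    clamp_negative = clamp_negative,
    anchor = match.arg(anchor),
    followup_windows = followup_windows
  )
  structure(cfg, class = "kegfr_config")
}

#' Read the measurement and patient tables
#'
#' The pipeline consumes two comma-separated tables with a header row.
#' `measurements`: `patient_id`, `timestamp` (ISO-8601), `scr_umol_l`.
#' `patients`: `patient_id`, `transplant_time` (ISO-8601), `age`, `sex`,
#' `donor_type` (living/DBD/DCD), `preemptive`, `abo_incompatible`,
#' `donor_age`, `dialysis_times` (semicolon-separated ISO-8601, empty for
#' none). Duplicate (patient, timestamp) rows are dropped keeping the
#' first; rows are returned sorted.
#'
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_measurements <- function(path) {
  m <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    timestamp = readr::col_datetime(),
    scr_umol_l = readr::col_double()
  ), progress = FALSE)
  if (any(m$scr_umol_l <= 0, na.rm = TRUE)) {
    abort("Measurement table contains non-positive creatinine values.")
  }
  m |>
    dplyr::arrange(.data$patient_id, .data$timestamp) |>
    dplyr::distinct(.data$patient_id, .data$timestamp, .keep_all = TRUE)
}

#' @rdname read_measurements
#' @export
read_patients <- function(path) {
  p <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    transplant_time = readr::col_datetime(),
    age = readr::col_double(),
    sex = readr::col_character(),
    donor_type = readr::col_character(),
    preemptive = readr::col_logical(),
    abo_incompatible = readr::col_logical(),
    donor_age = readr::col_double(),
    dialysis_times = readr::col_character()
  ), progress = FALSE)
  bad <- setdiff(unique(p$donor_type), c("living", "DBD", "DCD"))
  if (length(bad)) {
    abort(paste0("Unknown donor_type value(s): ", paste(bad, collapse = ", ")))
  }
  p$dialysis_times <- lapply(p$dialysis_times, parse_dialysis_times)
  dplyr::arrange(p, .data$patient_id)
}

parse_dialysis_times <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(as.POSIXct(character(), tz = "UTC"))
  }
  as.POSIXct(strsplit(x, ";", fixed = TRUE)[[1]],
    tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ"
  )
}

format_dialysis_times <- function(x) {
  if (length(x) == 0) return("")
  paste(format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"), collapse = ";")
}

#' Write a cohort to the pipeline's file dialect
#'
#' Serialises the measurement, patient and (when present) true-state
#' tables of a cohort as CSV in `dir`. The on-disk dialect is exactly what
#' [read_measurements()] and [read_patients()] consume, so a write/read
#' round trip reproduces the tables.
#'
#' @param cohort A list with elements `measurements`, `patients` and
#'   optionally `true_state` (as returned by [generate_cohort()]).
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$measurements, file.path(dir, "measurements.csv"))
  p <- cohort$patients
  p$dialysis_times <- vapply(p$dialysis_times, format_dialysis_times, character(1))
  readr::write_csv(p, file.path(dir, "patients.csv"))
  if (!is.null(cohort$true_state)) {
    readr::write_csv(cohort$true_state, file.path(dir, "true_state.csv"))
  }
  invisible(dir)
}

#' Assign measurements to postoperative days
#'
#' POD k is the measurement closest to `transplant_time + k * 24 h` within
#' a +/- `pod_window_hours` window; when several qualify the earliest wins.
#' Measurements before transplantation are not assigned.
#'
#' @param measurements Measurement table (see [read_measurements()]).
#' @param patients Patient table (for `transplant_time`).
#' @param config A [pipeline_config()].
#' @return A tibble `patient_id`, `pod` (0..max_pod), `hours`
#'   (since transplantation), `scr_umol_l`, at most one row per patient and
#'   POD.
#' @export
assign_pod <- function(measurements, patients, config = pipeline_config()) {
  m <- measurements |>
    dplyr::inner_join(
      dplyr::select(patients, "patient_id", "transplant_time"),
      by = "patient_id"
    ) |>
    dplyr::mutate(
      hours = as.numeric(difftime(.data$timestamp, .data$transplant_time,
        units = "hours"
      ))
    ) |>
    dplyr::filter(.data$hours >= 0)
  m |>
    dplyr::mutate(
      pod = round(.data$hours / 24),
      dev = abs(.data$hours - 24 * .data$pod)
    ) |>
    dplyr::filter(
      .data$dev <= config$pod_window_hours,
      .data$pod >= 0, .data$pod <= config$max_pod
    ) |>
    dplyr::arrange(.data$patient_id, .data$pod, .data$dev, .data$hours) |>
    dplyr::distinct(.data$patient_id, .data$pod, .keep_all = TRUE) |>
    dplyr::select("patient_id", "pod", "hours", "scr_umol_l") |>
    dplyr::arrange(.data$patient_id, .data$pod)
}

#' Pair consecutive creatinine measurements for the kinetic estimate
#'
#' Forms all consecutive-measurement pairs per patient whose spacing is at
#' most `max_gap_hours` (36 h by default: wider pairs are ineligible for
#' the kinetic formula). Pairs spanning a dialysis session are flagged;
#' they are excluded from kinetic estimation by default because dialysis
#' removes creatinine non-renally.
#'
#' @inheritParams assign_pod
#' @return A tibble `patient_id`, `hours_a`, `hours_b`, `creat_a`,
#'   `creat_b`, `delta_hours`, `straddles_dialysis`.
#' @export
pair_measurements <- function(measurements, patients,
                              config = pipeline_config()) {
  m <- measurements |>
    dplyr::inner_join(
      dplyr::select(patients, "patient_id", "transplant_time"),
      by = "patient_id"
    ) |>
    dplyr::mutate(
      hours = as.numeric(difftime(.data$timestamp, .data$transplant_time,
        units = "hours"
      ))
    ) |>
    dplyr::filter(.data$hours >= 0) |>
    dplyr::arrange(.data$patient_id, .data$hours)
  pairs <- m |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      hours_a = dplyr::lag(.data$hours),
      creat_a = dplyr::lag(.data$scr_umol_l)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$hours_a)) |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      hours_a = .data$hours_a,
      hours_b = .data$hours,
      creat_a = .data$creat_a,
      creat_b = .data$scr_umol_l,
      delta_hours = .data$hours - .data$hours_a
    ) |>
    dplyr::filter(.data$delta_hours > 0,
                  .data$delta_hours <= config$max_gap_hours)
  # flag pairs spanning a dialysis session
  dial <- patients |>
    dplyr::select("patient_id", "transplant_time", "dialysis_times") |>
    tidyr::unnest_longer("dialysis_times", values_to = "dialysis_time") |>
    dplyr::filter(!is.na(.data$dialysis_time)) |>
    dplyr::mutate(
      dial_hours = as.numeric(difftime(.data$dialysis_time,
        .data$transplant_time,
        units = "hours"
      ))
    ) |>
    dplyr::select("patient_id", "dial_hours")
  if (nrow(dial) > 0 && nrow(pairs) > 0) {
    flagged <- pairs |>
      dplyr::inner_join(dial, by = "patient_id",
                        relationship = "many-to-many") |>
      dplyr::filter(.data$dial_hours > .data$hours_a,
                    .data$dial_hours <= .data$hours_b) |>
      dplyr::distinct(.data$patient_id, .data$hours_b) |>
      dplyr::mutate(straddles_dialysis = TRUE)
    pairs <- pairs |>
      dplyr::left_join(flagged, by = c("patient_id", "hours_b")) |>
      dplyr::mutate(
        straddles_dialysis = !is.na(.data$straddles_dialysis)
      )
  } else {
    pairs$straddles_dialysis <- logical(nrow(pairs))
  }
  pairs
}

# anchor creatinine and clearance per patient (SSPCr / CrCl)
anchor_context <- function(measurements, patients, config) {
  m <- measurements |>
    dplyr::inner_join(
      dplyr::select(patients, "patient_id", "transplant_time", "age", "sex"),
      by = "patient_id"
    ) |>
    dplyr::mutate(
      hours = as.numeric(difftime(.data$timestamp, .data$transplant_time,
        units = "hours"
      ))
    )
  m <- if (config$anchor == "baseline") {
    # last pre-transplant value; fall back to first post-transplant
    pre <- m |>
      dplyr::filter(.data$hours < 0) |>
      dplyr::arrange(.data$patient_id, dplyr::desc(.data$hours)) |>
      dplyr::distinct(.data$patient_id, .keep_all = TRUE)
    post <- m |>
      dplyr::filter(.data$hours >= 0, !.data$patient_id %in% pre$patient_id) |>
      dplyr::arrange(.data$patient_id, .data$hours) |>
      dplyr::distinct(.data$patient_id, .keep_all = TRUE)
    dplyr::bind_rows(pre, post)
  } else {
    m |>
      dplyr::filter(.data$hours >= 0) |>
      dplyr::arrange(.data$patient_id, .data$hours) |>
      dplyr::distinct(.data$patient_id, .keep_all = TRUE)
  }
  m |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      ss_pcr = .data$scr_umol_l,
      crcl = ckd_epi(.data$scr_umol_l, .data$age, .data$sex),
      anchor_hours = .data$hours
    ) |>
    dplyr::arrange(.data$patient_id)
}

#' Per-patient daily estimate series
#'
#' For every postoperative day k in 1..`max_pod`, computes the CKD-EPI
#' eGFR from the POD k creatinine and the kinetic eGFR from the eligible
#' pair ending at the POD k measurement (the immediately preceding
#' measurement within `max_gap_hours`, skipping pairs that span dialysis
#' when so configured). The kinetic anchor (`ss_pcr`, `crcl`) follows the
#' configured anchor rule.
#'
#' @inheritParams assign_pod
#' @return A tidy tibble with one row per patient, POD and method:
#'   `patient_id`, `pod`, `method` ("KeGFR"/"CKD-EPI"), `value`,
#'   `clamped`, `scr_umol_l`, `pair_delta_hours` (NA for CKD-EPI).
#' @export
estimate_daily <- function(measurements, patients,
                           config = pipeline_config()) {
  pods <- assign_pod(measurements, patients, config)
  anchors <- anchor_context(measurements, patients, config)
  demo <- dplyr::select(patients, "patient_id", "age", "sex")

  ckd <- pods |>
    dplyr::filter(.data$pod >= 1) |>
    dplyr::inner_join(demo, by = "patient_id") |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      pod = .data$pod,
      method = "CKD-EPI",
      value = ckd_epi(.data$scr_umol_l, .data$age, .data$sex),
      clamped = FALSE,
      scr_umol_l = .data$scr_umol_l,
      pair_delta_hours = NA_real_
    )

  pairs <- pair_measurements(measurements, patients, config)
  if (config$exclude_dialysis_pairs) {
    pairs <- dplyr::filter(pairs, !.data$straddles_dialysis)
  }
  kin <- pods |>
    dplyr::filter(.data$pod >= 1) |>
    dplyr::inner_join(pairs, by = c("patient_id", "hours" = "hours_b")) |>
    dplyr::inner_join(anchors, by = "patient_id")
  if (nrow(kin) > 0) {
    est <- kegfr(kin$creat_a, kin$creat_b, kin$delta_hours,
      kin$ss_pcr, kin$crcl,
      max_delta_pcr = config$max_delta_pcr,
      max_gap_hours = config$max_gap_hours,
      clamp = config$clamp_negative
    )
    kin <- kin |>
      dplyr::mutate(value = est$value, clamped = est$clamped) |>
      dplyr::transmute(
        patient_id = .data$patient_id,
        pod = .data$pod,
        method = "KeGFR",
        value = .data$value,
        clamped = .data$clamped,
        scr_umol_l = .data$scr_umol_l,
        pair_delta_hours = .data$delta_hours
      )
  } else {
    kin <- ckd[0, ]
  }
  dplyr::bind_rows(kin, ckd) |>
    dplyr::arrange(.data$patient_id, .data$pod, .data$method)
}

#' Run the full estimation pipeline on a cohort
#'
#' Computes the daily estimate series, labels graft function, and applies
#' the study's exclusion flow: patients without a POD1 kinetic estimate are
#' excluded first, then patients whose SGF status is indeterminate. The
#' returned manifest preserves the bookkeeping
#' (`screened = analyzed + excluded_no_pod1_kegfr + excluded_no_sgf_status`).
#'
#' @inheritParams assign_pod
#' @return A list of class `kegfr_pipeline`: `estimates` (all patients),
#'   `labels` (with an `analyzed` flag), `pod_scr`, `manifest`, `config`.
#' @export
run_pipeline <- function(measurements, patients,
                         config = pipeline_config()) {
  estimates <- estimate_daily(measurements, patients, config)
  pod_scr <- assign_pod(measurements, patients, config)
  labels <- label_cohort(pod_scr, patients,
    definition = config$sgf_definition,
    crr_comparator = config$crr_comparator,
    exclude_dgf = config$exclude_dgf
  )
  has_pod1_kegfr <- estimates |>
    dplyr::filter(.data$pod == 1, .data$method == "KeGFR", !is.na(.data$value)) |>
    dplyr::pull("patient_id") |>
    unique()
  labels <- labels |>
    dplyr::mutate(
      has_pod1_kegfr = .data$patient_id %in% has_pod1_kegfr,
      analyzed = .data$has_pod1_kegfr & .data$status != "indeterminate"
    )
  manifest <- list(
    screened = nrow(patients),
    excluded_no_pod1_kegfr = sum(!labels$has_pod1_kegfr),
    excluded_no_sgf_status = sum(labels$has_pod1_kegfr &
      labels$status == "indeterminate"),
    analyzed = sum(labels$analyzed),
    config = config
  )
  structure(
    list(
      estimates = estimates, labels = labels, pod_scr = pod_scr,
      manifest = manifest, config = config
    ),
    class = "kegfr_pipeline"
  )
}

#' @export
print.kegfr_pipeline <- function(x, ...) {
  m <- x$manifest
  cat("<kegfr_pipeline>\n")
  cat(sprintf("  screened: %d\n", m$screened))
  cat(sprintf("  excluded (no POD1 KeGFR): %d\n", m$excluded_no_pod1_kegfr))
  cat(sprintf("  excluded (SGF status indeterminate): %d\n",
              m$excluded_no_sgf_status))
  cat(sprintf("  analyzed: %d\n", m$analyzed))
  cat(sprintf("  SGF among analyzed: %d (%.1f%%)\n",
    sum(x$labels$status == "SGF" & x$labels$analyzed),
    100 * mean(x$labels$status[x$labels$analyzed] == "SGF")
  ))
  invisible(x)
}

#' Pooled linear trajectory fits by group
#'
#' Ordinary-least-squares fit of an estimator (or raw creatinine) against
#' postoperative day, pooled over patients within each SGF stratum and
#' overall. The slope is in units per day. Groups with a single distinct
#' POD are reported with `NA` slope rather than dropped.
#'
#' @param pipeline A `kegfr_pipeline` (from [run_pipeline()]).
#' @param value `"kegfr"`, `"ckdepi"` or `"scr"`.
#' @param pods PODs entering the fit (default 1:5).
#' @param analyzed_only Restrict to analyzed patients (default TRUE).
#' @return A tibble `group`, `value`, `slope`, `intercept`, `p_value`,
#'   `n_points`.
#' @export
fit_group_slopes <- function(pipeline, value = c("kegfr", "ckdepi", "scr"),
                             pods = 1:5, analyzed_only = TRUE) {
  value <- match.arg(value)
  dat <- if (value == "scr") {
    pipeline$pod_scr |>
      dplyr::transmute(
        patient_id = .data$patient_id, pod = .data$pod,
        y = .data$scr_umol_l
      )
  } else {
    meth <- if (value == "kegfr") "KeGFR" else "CKD-EPI"
    pipeline$estimates |>
      dplyr::filter(.data$method == meth) |>
      dplyr::transmute(
        patient_id = .data$patient_id, pod = .data$pod, y = .data$value
      )
  }
  lab <- dplyr::select(pipeline$labels, "patient_id", "status", "analyzed")
  dat <- dat |>
    dplyr::filter(.data$pod %in% pods) |>
    dplyr::inner_join(lab, by = "patient_id")
  if (analyzed_only) dat <- dplyr::filter(dat, .data$analyzed)
  groups <- list(
    all = dat,
    SGF = dplyr::filter(dat, .data$status == "SGF"),
    `non-SGF` = dplyr::filter(dat, .data$status == "non-SGF")
  )
  dplyr::bind_rows(lapply(names(groups), function(g) {
    d <- groups[[g]]
    if (nrow(d) < 2 || length(unique(d$pod)) < 2) {
      return(tibble::tibble(
        group = g, value = value, slope = NA_real_, intercept = NA_real_,
        p_value = NA_real_, n_points = nrow(d)
      ))
    }
    fit <- lm(y ~ pod, data = d)
    # summary.lm warns on residual-free (exactly linear) input; that is a
    # legitimate degenerate case here, not a problem
    s <- suppressWarnings(summary(fit))$coefficients
    tibble::tibble(
      group = g, value = value,
      slope = s["pod", "Estimate"],
      intercept = s["(Intercept)", "Estimate"],
      p_value = s["pod", "Pr(>|t|)"],
      n_points = nrow(d)
    )
  }))
}

#' Follow-up eGFR at 3, 6 and 12 months
#'
#' Assigns post-discharge creatinine measurements to the 3/6/12-month
#' follow-up windows (in days: [60,120), [150,210), [330,400) by default)
#' and computes the CKD-EPI eGFR. Within a window the measurement nearest
#' the window centre wins (ties: earlier). Missing windows are simply
#' absent from the output.
#'
#' @inheritParams assign_pod
#' @return A tibble `patient_id`, `window` ("m3"/"m6"/"m12"), `day`,
#'   `scr_umol_l`, `egfr`.
#' @export
join_followup <- function(measurements, patients,
                          config = pipeline_config()) {
  wins <- config$followup_windows
  m <- measurements |>
    dplyr::inner_join(
      dplyr::select(patients, "patient_id", "transplant_time", "age", "sex"),
      by = "patient_id"
    ) |>
    dplyr::mutate(
      day = as.numeric(difftime(.data$timestamp, .data$transplant_time,
        units = "days"
      ))
    )
  out <- dplyr::bind_rows(lapply(names(wins), function(w) {
    lo <- wins[[w]][1]; hi <- wins[[w]][2]; centre <- wins[[w]][3]
    m |>
      dplyr::filter(.data$day >= lo, .data$day < hi) |>
      dplyr::mutate(dev = abs(.data$day - centre)) |>
      dplyr::arrange(.data$patient_id, .data$dev, .data$day) |>
      dplyr::distinct(.data$patient_id, .keep_all = TRUE) |>
      dplyr::transmute(
        patient_id = .data$patient_id,
        window = w,
        day = .data$day,
        scr_umol_l = .data$scr_umol_l,
        egfr = ckd_epi(.data$scr_umol_l, .data$age, .data$sex)
      )
  }))
  dplyr::arrange(out, .data$patient_id, .data$day)
}
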