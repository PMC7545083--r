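#' Sensitivity (d') from hit and false-alarm rates
#'
#' Equal-variance signal-detection sensitivity,
#' \eqn{d' = z(HR) - z(FAR)}, with `z` the standard normal quantile.
#' A d' of 0 is chance performance. Rates must lie strictly inside
#' (0, 1): correct extreme rates first (see [compute_rates()]).
#'
#' @param hr,far Hit and false-alarm rates, strictly in (0, 1);
#'   vectorised.
#' @return Numeric vector of sensitivities.
#' @examples
#' dprime(0.8, 0.3)
#' @export
dprime <- function(hr, far) {
  check_rates(hr, far)
  qnorm(hr) - qnorm(far)
}

#' Response criterion (c) from hit and false-alarm rates
#'
#' Response-bias measure \eqn{c = -(z(HR) + z(FAR)) / 2}. Negative values
#' indicate a liberal bias toward "signal present"; positive values a
#' conservative bias toward "signal absent"; 0 is unbiased.
#'
#' @inheritParams dprime
#' @return Numeric vector of criteria.
#' @examples
#' criterion(0.8, 0.3)
#' @export
criterion <- function(hr, far) {
  check_rates(hr, far)
  -(qnorm(hr) + qnorm(far)) / 2
}

check_rates <- function(hr, far) {
  if (any(hr <= 0 | hr >= 1 | far <= 0 | far >= 1)) {
    abort(paste("Rates must lie strictly in (0, 1);",
                "apply the log-linear correction to extreme rates first."))
  }
  invisible(TRUE)
}

#' Per-condition hit and false-alarm rates from a trial log
#'
#' Counts hits and false alarms within each grouping cell and converts
#' them to rates with the log-linear correction applied uniformly to all
#' cells: `HR = (hits + 0.5) / (n_signal + 1)`,
#' `FAR = (fa + 0.5) / (n_noise + 1)`. Uniform application keeps rates
#' strictly inside (0, 1) -- so the z transform is always defined -- and
#' avoids conditioning the correction on the observed data. Practice
#' trials are excluded.
#'
#' @param log A trial-log tibble with `stimulus_type` and `response`
#'   columns (plus the grouping columns).
#' @param groups Character vector of grouping columns.
#' @return A tibble with one row per group: trial counts, raw counts of
#'   hits and false alarms, corrected `hr` and `far`, and their normal
#'   quantiles `zhr`, `zfar`.
#' @export
compute_rates <- function(log,
                          groups = c("subject_id", "category",
                                     "visual_field")) {
  if (nrow(log) == 0L) abort("`log` is empty.")
  if ("practice" %in% names(log)) log <- log[!log$practice, ]
  out <- log |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n_signal = sum(.data$stimulus_type == "signal"),
      n_noise = sum(.data$stimulus_type == "noise_only"),
      hits = sum(.data$stimulus_type == "signal" &
                   .data$response == "present"),
      false_alarms = sum(.data$stimulus_type == "noise_only" &
                           .data$response == "present"),
      .groups = "drop"
    )
  if (any(out$n_signal == 0L) || any(out$n_noise == 0L)) {
    abort("Every group must contain at least one signal and one noise trial.")
  }
  out$hr <- (out$hits + 0.5) / (out$n_signal + 1)
  out$far <- (out$false_alarms + 0.5) / (out$n_noise + 1)
  out$zhr <- qnorm(out$hr)
  out$zfar <- qnorm(out$far)
  out
}

#' Mean reaction times for correct (and incorrect) responses per condition
#'
#' The reaction-time summary averages RTs over correct responses only;
#' the incorrect-response mean is reported alongside as a speed-accuracy
#' audit. Practice trials and forced-guess trials (diffusion walks that
#' hit the time cap) are excluded. Cells with no correct trial are
#' flagged rather than erroring.
#'
#' @inheritParams compute_rates
#' @return A tibble per group: `n_correct`, `n_incorrect`,
#'   `mean_rt_correct`, `mean_rt_incorrect`, `missing` (no correct trial
#'   in the cell).
#' @export
rt_summary <- function(log,
                       groups = c("subject_id", "category",
                                  "visual_field")) {
  if (nrow(log) == 0L) abort("`log` is empty.")
  if ("practice" %in% names(log)) log <- log[!log$practice, ]
  if ("forced_guess" %in% names(log)) log <- log[!log$forced_guess, ]
  out <- log |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n_correct = sum(.data$correct),
      n_incorrect = sum(!.data$correct),
      mean_rt_correct = mean(.data$rt_s[.data$correct]),
      mean_rt_incorrect = mean(.data$rt_s[!.data$correct]),
      .groups = "drop"
    )
  out$missing <- out$n_correct == 0L
  out$mean_rt_correct[out$missing] <- NA_real_
  out
}

#' Per-subject, per-condition signal-detection summary
#'
#' Joins the corrected rates, the d'/criterion estimates and the
#' correct-trial reaction-time means into one row per
#' subject x category x visual field -- the analysis table the
#' group-level statistics consume.
#'
#' @inheritParams compute_rates
#' @return A tibble per group with rate, `dprime`, `criterion` and RT
#'   columns.
#' @examples
#' \donttest{
#' cohort <- sample_cohort(cohort_spec(n_subjects = 2), seed = 1)
#' sched <- dplyr::bind_rows(lapply(1:2, function(i)
#'   build_trial_schedule(1, i, virtual_manifest(), seed = i)))
#' log <- run_cohort_experiment(cohort, sched, seed = 9)
#' subject_condition_summary(log)
#' }
#' @export
subject_condition_summary <- function(log,
                                      groups = c("subject_id", "category",
                                                 "visual_field")) {
  rates <- compute_rates(log, groups)
  rates$dprime <- dprime(rates$hr, rates$far)
  rates$criterion <- criterion(rates$hr, rates$far)
  rts <- rt_summary(log, groups)
  dplyr::left_join(rates, rts, by = groups)
}
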