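#' Remove abnormally short and long reading times
#'
#' Words with raw reading times below `low` or above `high` ms are removed
#' (strict inequalities: values exactly at either boundary are kept). With
#' default generator settings this loses well under 1% of the data.
#'
#' @param records A tibble of trial records with an `rt_raw` column.
#' @param low,high Exclusion boundaries in ms (`low < high`).
#' @return A list with `records` (the kept rows), `loss_fraction`,
#'   `n_removed` and `n_total`.
#' @export
#' @examples
#' d <- generate_dataset(build_design_exp1(n_subjects = 2), seed = 1)
#' exclude_rts(d)$loss_fraction
exclude_rts <- function(records, low = 100, high = 2000) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_config("`records` must be a nonempty data frame.")
  }
  if (!is.numeric(low) || !is.numeric(high) || low >= high) {
    abort_config("exclusion bounds must satisfy `low < high`.")
  }
  keep <- records$rt_raw >= low & records$rt_raw <= high
  list(
    records = records[keep, , drop = FALSE],
    loss_fraction = mean(!keep),
    n_removed = sum(!keep),
    n_total = length(keep)
  )
}

#' Length-correct reading times with a mixed regression
#'
#' Fits raw RTs on word length by linear mixed-effects regression with a
#' by-subject random intercept and a by-subject random slope for length
#' (REML), over all remaining words (criticals and fillers). The residuals
#' of this model -- length-corrected RTs -- are attached as `rt_resid` and
#' serve as the dependent variable of all downstream analyses. If the mixed
#' model cannot be fit, the function falls back to per-subject ordinary
#' least squares of RT on length, with a warning. A degenerate dataset with
#' constant word length is handled by dropping the length term.
#'
#' @param records Trial records after exclusion.
#' @return `records` with an `rt_resid` column; the fit summary is attached
#'   as attribute `"length_fit"` (method, fixed effects, convergence flag).
#' @export
length_correct <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort_config("`records` must be a nonempty data frame.")
  }
  records <- tibble::as_tibble(records)
  const_length <- stats::var(records$word_length) < 1e-12
  fit <- NULL
  method <- "lmm"
  form <- if (const_length) {
    rt_raw ~ 1 + (1 | subject_id)
  } else {
    rt_raw ~ word_length + (1 + word_length | subject_id)
  }
  fit <- tryCatch(
    suppressWarnings(suppressMessages(lme4::lmer(
      form, data = records, REML = TRUE,
      control = lme4::lmerControl(optimizer = "bobyqa", calc.derivs = FALSE,
                                  check.conv.singular = "ignore")
    ))),
    error = function(e) NULL
  )
  converged <- !is.null(fit) && mixed_converged(fit)
  if (!is.null(fit) && converged) {
    records$rt_resid <- stats::residuals(fit)
    fixefs <- lme4::fixef(fit)
  } else {
    warning("length-correction mixed model did not converge; ",
            "falling back to per-subject OLS of RT on length.",
            call. = FALSE)
    method <- "per_subject_ols"
    resids <- unlist(lapply(split(records, records$subject_id), function(d) {
      stats::residuals(stats::lm(rt_raw ~ word_length, data = d))
    }), use.names = FALSE)
    records <- records[order(records$subject_id), ]
    records$rt_resid <- resids
    fixefs <- c(`(Intercept)` = mean(records$rt_raw))
  }
  attr(records, "length_fit") <- list(
    method = method,
    fixef = fixefs,
    converged = isTRUE(converged)
  )
  records
}

#' Aggregate length-corrected RTs to subject-by-item regions
#'
#' One row per subject, critical item, and sentence region, holding the
#' region means of `rt_resid` and `rt_raw` along with the trial's condition
#' labels, orders, and `rc_seen` (how many RC sentences the subject has read
#' up to and including this trial -- the evidence count used by the
#' continuous blocked-design analysis). `item_key` identifies the stimulus
#' slot (list x item position) for by-item random intercepts.
#'
#' @param records Length-corrected records (must have `rt_resid`).
#' @return A region-level tibble.
#' @export
aggregate_regions <- function(records) {
  if (!"rt_resid" %in% names(records)) {
    abort_config("`records` must be length-corrected first (no rt_resid).")
  }
  trial_level <- dplyr::distinct(
    records, .data$subject_id, .data$stimulus_order, .data$kind,
    .data$structure
  )
  trial_level <- dplyr::arrange(trial_level, .data$subject_id,
                                .data$stimulus_order)
  trial_level <- dplyr::group_by(trial_level, .data$subject_id)
  trial_level <- dplyr::mutate(
    trial_level,
    rc_seen = cumsum(.data$kind == "critical" &
                       !is.na(.data$structure) & .data$structure == "RC")
  )
  trial_level <- dplyr::ungroup(trial_level)
  crit <- dplyr::filter(records, .data$kind == "critical")
  crit <- dplyr::left_join(
    crit, trial_level[, c("subject_id", "stimulus_order", "rc_seen")],
    by = c("subject_id", "stimulus_order")
  )
  out <- dplyr::summarise(
    dplyr::group_by(crit, .data$subject_id, .data$list_id, .data$group,
                    .data$block, .data$structure, .data$ambiguity,
                    .data$item_order, .data$stimulus_order, .data$rc_seen,
                    .data$region),
    rt_resid = mean(.data$rt_resid),
    rt_raw = mean(.data$rt_raw),
    n_words = dplyr::n(),
    .groups = "drop"
  )
  out$item_key <- sprintf("L%d_I%02d", out$list_id, out$item_order)
  out
}
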