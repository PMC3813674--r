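#' Run the exclusion / length-correction / aggregation chain
#'
#' Convenience wrapper applying [exclude_rts()], [length_correct()] and
#' [aggregate_regions()] in sequence. Counts are reconciled at every stage
#' boundary so no trial can be dropped silently.
#'
#' @param records Word-level trial records.
#' @param low,high Exclusion bounds, ms.
#' @return A list with `region_table`, `loss_fraction` and `length_fit`.
#' @export
preprocess_trials <- function(records, low = 100, high = 2000) {
  excl <- exclude_rts(records, low = low, high = high)
  if (nrow(excl$records) + excl$n_removed != excl$n_total) {
    stop("exclusion stage lost rows unaccountably.", call. = FALSE)
  }
  corrected <- length_correct(excl$records)
  if (nrow(corrected) != nrow(excl$records)) {
    stop("length-correction stage lost rows unaccountably.", call. = FALSE)
  }
  list(
    region_table = aggregate_regions(corrected),
    loss_fraction = excl$loss_fraction,
    length_fit = attr(corrected, "length_fit")
  )
}

#' Sign-recovery and null-calibration simulation
#'
#' Repeatedly generates synthetic mixed-exposure datasets and runs the full
#' analysis chain, recording the focal coefficients: the three-way sentence
#' type : ambiguity : item order interaction and the per-structure
#' ambiguity : item order simple effects. With adaptation on this measures
#' how reliably the pipeline recovers the predicted signs (positive
#' three-way; negative RC slope; near-zero MV slope). With
#' `adaptation = FALSE` the generator is run with a frozen prior
#' (`alpha0 = 1e9`) and all region effects disabled (`rt_slope = 0`), so the
#' rejection rate of the focal interactions estimates the analysis's type-I
#' error.
#'
#' @param n_replicates Number of simulated datasets (>= 2).
#' @param seed Integer seed; each replicate derives its own stream.
#' @param n_subjects Simulated subjects per dataset.
#' @param adaptation Logical; `FALSE` switches to null generation.
#' @param prior,link,outlier_fraction Passed to [generate_dataset()] (prior
#'   and link are overridden as above when `adaptation = FALSE`).
#' @param random Random-effects setting for the replicate fits; intercepts
#'   only by default (the generator draws no by-subject slopes for the focal
#'   factors).
#' @param simple_effects_too Also fit the RC and MV simple-effects models.
#' @return A list of class `recovery_report`: `replicates` (per-replicate
#'   coefficient tibble) and `summary` (sign-recovery and rejection rates).
#' @export
sign_recovery <- function(n_replicates, seed = 1, n_subjects = 72,
                          adaptation = TRUE, prior = prior_config(),
                          link = link_params(), outlier_fraction = 0.005,
                          random = "intercepts", simple_effects_too = TRUE) {
  if (!is.numeric(n_replicates) || n_replicates < 2) {
    abort_config("`n_replicates` must be >= 2.")
  }
  if (!adaptation) {
    prior <- prior_config(prior$base_probs[["MV"]], prior$base_probs[["RC"]],
                          alpha0 = 1e9)
    link$rt_slope <- 0
    link$unambig_offset <- 0
  }
  one_rep <- function(r) {
    rseed <- derive_seed(seed, 5000L + r)
    design <- build_design_exp1(n_subjects = n_subjects, seed = rseed)
    records <- generate_dataset(design, prior = prior, link = link,
                                seed = rseed,
                                outlier_fraction = outlier_fraction)
    region_table <- preprocess_trials(records)$region_table
    full <- fit_adaptation_model(region_table, random = random)
    cf <- full$coefficients
    three <- cf[cf$predictor == "Sentence type : Ambiguity : Item order", ]
    row <- tibble::tibble(
      replicate = r,
      three_way_beta = three$beta,
      three_way_t = three$t_value
    )
    if (simple_effects_too) {
      rc <- simple_effects(region_table, "RC", random = random)$coefficients
      mv <- simple_effects(region_table, "MV", random = random)$coefficients
      rc_i <- rc[rc$predictor == "Ambiguity : Item order", ]
      mv_i <- mv[mv$predictor == "Ambiguity : Item order", ]
      row$rc_slope_beta <- rc_i$beta
      row$rc_slope_t <- rc_i$t_value
      row$mv_slope_beta <- mv_i$beta
      row$mv_slope_t <- mv_i$t_value
    }
    row
  }
  reps <- dplyr::bind_rows(lapply(seq_len(n_replicates), one_rep))
  summary <- list(
    n_replicates = n_replicates,
    adaptation = adaptation,
    three_way_positive_rate = mean(reps$three_way_beta > 0),
    three_way_rejection_rate = mean(abs(reps$three_way_t) >= 1.96),
    mean_three_way_beta = mean(reps$three_way_beta)
  )
  if (simple_effects_too) {
    summary$mean_rc_slope <- mean(reps$rc_slope_beta)
    summary$mean_mv_slope <- mean(reps$mv_slope_beta)
    summary$rc_negative_rate <- mean(reps$rc_slope_beta < 0)
  }
  structure(list(replicates = reps, summary = summary),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  s <- x$summary
  cat("<recovery_report>", s$n_replicates, "replicates;",
      if (s$adaptation) "adaptation on" else "null (adaptation off)", "\n")
  cat(sprintf("  three-way positive-sign rate: %.3f\n",
              s$three_way_positive_rate))
  cat(sprintf("  three-way |t|>=1.96 rate:     %.3f\n",
              s$three_way_rejection_rate))
  if (!is.null(s$mean_rc_slope)) {
    cat(sprintf("  mean RC ambiguity x order slope: %.2f ms/item\n",
                s$mean_rc_slope))
    cat(sprintf("  mean MV ambiguity x order slope: %.2f ms/item\n",
                s$mean_mv_slope))
  }
  invisible(x)
}
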