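#' Parameters of the surprisal-to-reading-time link and generative RT model
#'
#' Reading times at the disambiguating region are assumed to grow linearly
#' with the surprisal of the resolved structure. `link_params` also carries
#' the nuisance parameters of the generative model used for synthetic data:
#' a global task-adaptation speed-up in log stimulus order, per-subject
#' baseline and word-length-sensitivity variation, and trial noise. The
#' ms-per-bit slope default (20) is a fixture convention, not an estimate;
#' no published ms/bit scaling exists for this paradigm.
#'
#' @param rt_intercept Baseline word reading time, ms.
#' @param rt_slope Surprisal sensitivity, ms per bit (>= 0; 0 disables all
#'   region effects, used for null/type-I simulations).
#' @param unambig_offset Constant disambiguating-region cost in unambiguous
#'   conditions, ms (default 0).
#' @param task_adapt_coef Coefficient on log stimulus order, ms (<= 0): the
#'   practice speed-up that affects every word regardless of structure.
#' @param noise_sd Gaussian trial noise on the ms scale.
#' @param subj_intercept_sd SD of by-subject baseline deviations, ms.
#' @param subj_length_slope_mean,subj_length_slope_sd Mean and SD of the
#'   by-subject word-length slope, ms per character.
#' @return An object of class `link_params`.
#' @export
#' @examples
#' link_params()
link_params <- function(rt_intercept = 350, rt_slope = 20, unambig_offset = 0,
                        task_adapt_coef = -30, noise_sd = 60,
                        subj_intercept_sd = 40, subj_length_slope_mean = 15,
                        subj_length_slope_sd = 5) {
  check_scalar_number(rt_intercept, "rt_intercept")
  check_scalar_number(rt_slope, "rt_slope", lower = 0)
  check_scalar_number(unambig_offset, "unambig_offset")
  check_scalar_number(task_adapt_coef, "task_adapt_coef", upper = 0)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(subj_intercept_sd, "subj_intercept_sd", lower = 0)
  check_scalar_number(subj_length_slope_mean, "subj_length_slope_mean")
  check_scalar_number(subj_length_slope_sd, "subj_length_slope_sd", lower = 0)
  structure(
    list(rt_intercept = rt_intercept, rt_slope = rt_slope,
         unambig_offset = unambig_offset, task_adapt_coef = task_adapt_coef,
         noise_sd = noise_sd, subj_intercept_sd = subj_intercept_sd,
         subj_length_slope_mean = subj_length_slope_mean,
         subj_length_slope_sd = subj_length_slope_sd),
    class = "link_params"
  )
}

#' Predicted reading time for a given surprisal
#'
#' The log-linear link: `rt_intercept + rt_slope * surprisal`.
#'
#' @param surprisal Surprisal in bits (>= 0); vectorised.
#' @param params A [link_params()].
#' @return Predicted reading times, ms.
#' @export
#' @examples
#' predicted_rt(surprisal_bits(0.008), link_params())
predicted_rt <- function(surprisal, params = link_params()) {
  stopifnot(inherits(params, "link_params"))
  if (!is.numeric(surprisal) || any(!is.finite(surprisal)) || any(surprisal < 0)) {
    stop("`surprisal` must be nonnegative.", call. = FALSE)
  }
  params$rt_intercept + params$rt_slope * surprisal
}

#' Predicted garden-path (ambiguity) effect at the disambiguating region
#'
#' The predicted ambiguous-minus-unambiguous reading-time difference when the
#' ambiguity resolves to a structure the reader currently assigns probability
#' `p_structure`: `rt_slope * surprisal_bits(p_structure) - unambig_offset`.
#' Strictly decreasing in `p_structure`, so as belief updating raises the
#' probability of a structure its garden-path effect shrinks.
#'
#' @param p_structure Current predictive probability of the resolved
#'   structure, in (0, 1]; vectorised.
#' @inheritParams predicted_rt
#' @return Predicted effect in ms.
#' @export
#' @examples
#' ambiguity_effect(c(0.008, 0.5), link_params())
ambiguity_effect <- function(p_structure, params = link_params()) {
  stopifnot(inherits(params, "link_params"))
  params$rt_slope * surprisal_bits(p_structure) - params$unambig_offset
}
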