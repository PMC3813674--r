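trial_csv_columns <- function() {
  c("subject_id", "list_id", "group", "block", "stimulus_order", "item_order",
    "kind", "structure", "ambiguity", "region", "word_index", "word_length",
    "rt_raw")
}

critical_region_words <- function() {
  c(preamble = 3L, ambiguous_region = 4L, disambiguating_region = 3L,
    final_word = 1L)
}

# Predictive probability of each critical trial's own structure, evaluated
# just before that trial is read (beliefs update at sentence offset). Closed
# form of the Dirichlet-multinomial update, vectorised over the list's
# critical stream.
own_structure_probs <- function(structure, prior) {
  n_before <- seq_along(structure) - 1L
  same_before <- stats::ave(rep(1, length(structure)), structure,
                            FUN = cumsum) - 1
  (prior$alpha0 * prior$base_probs[structure] + same_before) /
    (prior$alpha0 + n_before)
}

# Word-level template for one counterbalancing list: sentence shapes, word
# lengths and per-trial belief probabilities are properties of the list's
# stimuli, so they are drawn once per list, not per subject.
expand_list_words <- function(design, list_id, prior, seed,
                              word_length_range) {
  tr <- design$trials[design$trials$list_id == list_id, ]
  tr <- tr[order(tr$stimulus_order), ]
  is_crit <- tr$kind == "critical"
  tr$p_own <- NA_real_
  tr$p_own[is_crit] <- own_structure_probs(tr$structure[is_crit], prior)

  set.seed(derive_seed(seed, 500L + list_id))
  n_words <- ifelse(is_crit, sum(critical_region_words()),
                    sample(8:14, nrow(tr), replace = TRUE))
  regions <- rep(names(critical_region_words()),
                 times = critical_region_words())
  words <- tr[rep(seq_len(nrow(tr)), times = n_words), ]
  words$word_index <- unlist(lapply(n_words, seq_len), use.names = FALSE)
  words$region <- ifelse(
    words$kind == "critical",
    regions[words$word_index],
    "filler_body"
  )
  lo <- as.integer(word_length_range[1]); hi <- as.integer(word_length_range[2])
  words$word_length <- if (lo == hi) rep(lo, nrow(words)) else
    sample(lo:hi, nrow(words), replace = TRUE)
  tibble::as_tibble(words)
}

#' Generate a synthetic word-by-word self-paced-reading dataset
#'
#' Inverts the analysis model: each word's raw reading time is the sum of a
#' by-subject baseline, a by-subject word-length effect, a task-practice
#' speed-up in log stimulus order, a region effect, and Gaussian noise. At
#' the disambiguating region of ambiguous critical sentences the region
#' effect is [ambiguity_effect()] evaluated at the reader's current
#' predictive probability of the resolved structure, with beliefs updated
#' after every critical sentence -- so the garden-path effect shrinks (or
#' grows) over exposure exactly as the belief model predicts. Unambiguous
#' criticals receive the constant `unambig_offset`. A small fraction of
#' words is replaced by out-of-range reading times (below 100 or above
#' 2000 ms) to exercise exclusion rules.
#'
#' Each subject has an independent seeded random stream derived from `seed`,
#' so adding subjects never perturbs earlier subjects' data.
#'
#' @param design An [build_design_exp1()] or [build_design_exp2()] design.
#' @param prior A [prior_config()]; `alpha0 = 1e9` effectively disables
#'   adaptation.
#' @param link A [link_params()].
#' @param seed Integer seed.
#' @param outlier_fraction Fraction of words given out-of-range RTs.
#' @param word_length_range Integer range words' character counts are drawn
#'   from (a degenerate range gives constant lengths, useful for exact
#'   algebraic checks).
#' @return A tibble of word-level trial records in the trial CSV column
#'   order (see [write_trials()]).
#' @export
#' @examples
#' d <- build_design_exp1(n_subjects = 2, seed = 1)
#' generate_dataset(d, seed = 1)
generate_dataset <- function(design, prior = prior_config(),
                             link = link_params(), seed = 1,
                             outlier_fraction = 0.005,
                             word_length_range = c(2L, 12L)) {
  stopifnot(inherits(design, "spr_design"), inherits(prior, "prior_config"),
            inherits(link, "link_params"))
  check_scalar_number(outlier_fraction, "outlier_fraction", lower = 0,
                      upper = 1)
  templates <- lapply(seq_len(design$n_lists), function(l) {
    expand_list_words(design, l, prior, seed, word_length_range)
  })
  per_subject <- lapply(seq_len(design$n_subjects), function(sid) {
    list_id <- design$subjects$list_id[design$subjects$subject_id == sid]
    w <- templates[[list_id]]
    n <- nrow(w)
    set.seed(derive_seed(seed, 1000L + sid))
    subj_intercept <- link$rt_intercept +
      stats::rnorm(1, 0, link$subj_intercept_sd)
    subj_len_slope <- stats::rnorm(1, link$subj_length_slope_mean,
                                   link$subj_length_slope_sd)
    region_effect <- rep(0, n)
    disamb <- w$region == "disambiguating_region" & w$kind == "critical"
    amb <- disamb & w$ambiguity == "ambiguous"
    unamb <- disamb & w$ambiguity == "unambiguous"
    if (any(amb)) {
      region_effect[amb] <- ambiguity_effect(w$p_own[amb], link) +
        link$unambig_offset
    }
    region_effect[unamb] <- link$unambig_offset
    rt <- subj_intercept + subj_len_slope * w$word_length +
      link$task_adapt_coef * log(w$stimulus_order) + region_effect +
      stats::rnorm(n, 0, link$noise_sd)
    is_out <- stats::runif(n) < outlier_fraction
    out_low <- is_out & stats::runif(n) < 0.5
    out_high <- is_out & !out_low
    rt[out_low] <- stats::runif(sum(out_low), 20, 99)
    rt[out_high] <- stats::runif(sum(out_high), 2001, 2999)
    w$rt_raw <- pmax(rt, 1)
    w$subject_id <- sid
    w
  })
  out <- dplyr::bind_rows(per_subject)
  out[, trial_csv_columns()]
}

#' Write / read trial records in the package's CSV dialect
#'
#' The dialect has exactly these columns, in order: `subject_id`, `list_id`,
#' `group`, `block`, `stimulus_order`, `item_order`, `kind`, `structure`,
#' `ambiguity`, `region`, `word_index`, `word_length`, `rt_raw`. Missing
#' values (e.g. `item_order` on fillers) are written as empty fields. The
#' round trip is lossless.
#'
#' @param records A tibble of trial records.
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns a tibble of records.
#' @export
write_trials <- function(records, path) {
  missing_cols <- setdiff(trial_csv_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(records[, trial_csv_columns()], path, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  spec <- readr::cols(
    subject_id = readr::col_integer(),
    list_id = readr::col_integer(),
    group = readr::col_character(),
    block = readr::col_integer(),
    stimulus_order = readr::col_integer(),
    item_order = readr::col_integer(),
    kind = readr::col_character(),
    structure = readr::col_character(),
    ambiguity = readr::col_character(),
    region = readr::col_character(),
    word_index = readr::col_integer(),
    word_length = readr::col_integer(),
    rt_raw = readr::col_double()
  )
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing_cols <- setdiff(trial_csv_columns(), header)
  if (length(missing_cols) > 0) {
    stop("trial file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # parsing issues are re-raised as errors below, so silence readr's warning
  records <- suppressWarnings(readr::read_csv(path, col_types = spec, na = "",
                                              show_col_types = FALSE))
  probs <- readr::problems(records)
  if (nrow(probs) > 0) {
    stop(sprintf("malformed trial file: parse error at line %d (expected %s)",
                 probs$row[1], probs$expected[1]), call. = FALSE)
  }
  tibble::as_tibble(records)[, trial_csv_columns()]
}
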