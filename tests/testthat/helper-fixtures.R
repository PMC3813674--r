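# Shared fixtures, built once per test run and cached in this environment.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A mid-sized mixed-exposure dataset with adaptation on, preprocessed.
fixture_exp1_pre <- function() {
  cached("exp1_pre", function() {
    design <- build_design_exp1(n_subjects = 36, seed = 11)
    records <- generate_dataset(design, seed = 11)
    preprocess_trials(records)
  })
}

# A small two-group blocked-design dataset, preprocessed.
fixture_exp2_pre <- function() {
  cached("exp2_pre", function() {
    cfg <- run_config("exp2", n_subjects = 24, seed = 12)
    records <- cmd_generate(cfg, out_path = tempfile(fileext = ".csv"))
    preprocess_trials(records)
  })
}

# Minimal hand-built word records for exclusion/aggregation unit checks.
tiny_records <- function(rts, subject_id = 1L) {
  n <- length(rts)
  tibble::tibble(
    subject_id = subject_id,
    list_id = 1L,
    group = NA_character_,
    block = NA_integer_,
    stimulus_order = 1L,
    item_order = 1L,
    kind = "critical",
    structure = "RC",
    ambiguity = "ambiguous",
    region = "preamble",
    word_index = seq_len(n),
    word_length = 5L,
    rt_raw = rts
  )
}

# A deterministic generator setting: no noise, no subject variation,
# frozen symmetric beliefs, constant word length -- every RT is an exact
# linear function of the design.
exact_link <- function(rt_slope = 20, task_adapt_coef = -30) {
  link_params(rt_slope = rt_slope, noise_sd = 0, subj_intercept_sd = 0,
              subj_length_slope_sd = 0, task_adapt_coef = task_adapt_coef)
}

frozen_symmetric_prior <- function() {
  prior_config(p_mv = 0.5, p_rc = 0.5, alpha0 = 1e9)
}
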