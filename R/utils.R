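# internal helpers shared across modules

#' @importFrom rlang .data
NULL

structure_levels <- function() c("MV", "RC", "OTHER")

# Deterministic stream splitting: derive a child seed from (seed, salt) so
# that e.g. each simulated subject gets its own stream and adding subjects
# never perturbs earlier ones. Kept below 2^31 - 1.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(salt) * 16807) %% 2147483629)
}

abort_config <- function(msg) stop(msg, call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number.", name))
  }
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper) {
    abort_config(sprintf("`%s` = %g is out of range.", name, x))
  }
  invisible(x)
}

check_category <- function(category) {
  if (!is.character(category) || !all(category %in% structure_levels())) {
    stop("unknown structure category; must be one of ",
         paste(structure_levels(), collapse = ", "), call. = FALSE)
  }
  category
}

# mean-center, returning a plain numeric
center <- function(x) x - mean(x)

# +/-.5 contrast for a two-level factor given the level mapped to +.5
contrast_half <- function(x, positive_level) {
  ifelse(x == positive_level, 0.5, -0.5)
}
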