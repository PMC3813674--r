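predictor_labels <- function() {
  c(lso_c = "Log stimulus order",
    amb_c = "Ambiguity",
    st_c = "Sentence type",
    io_c = "Item order",
    grp_c = "Group",
    blk_c = "Block",
    rcs_c = "Item order",
    `st_c:amb_c` = "Sentence type : Ambiguity",
    `st_c:io_c` = "Sentence type : Item order",
    `amb_c:io_c` = "Ambiguity : Item order",
    `st_c:amb_c:io_c` = "Sentence type : Ambiguity : Item order",
    `amb_c:grp_c` = "Ambiguity : Group",
    `amb_c:blk_c` = "Ambiguity : Block",
    `amb_c:rcs_c` = "Ambiguity : Item order")
}

label_terms <- function(terms) {
  labs <- predictor_labels()
  # term order within interactions can come out either way
  var_order <- c("st_c", "amb_c", "io_c", "grp_c", "blk_c", "rcs_c", "lso_c")
  canonical <- vapply(strsplit(terms, ":"), function(parts) {
    paste(parts[order(match(parts, var_order))], collapse = ":")
  }, character(1))
  out <- labs[canonical]
  out[is.na(out)] <- terms[is.na(out)]
  unname(out)
}

check_not_aliased <- function(data, fixed_rhs) {
  mm <- stats::model.matrix(stats::as.formula(paste("~", fixed_rhs)), data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design: aliased predictor(s) ",
         paste(label_terms(aliased), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# Optimizer success: clean exit code and no lme4 convergence messages.
# Singular fits pass (zero variance components are legitimate here).
mixed_converged <- function(fit) {
  opt_code <- fit@optinfo$conv$opt
  (is.null(opt_code) || opt_code == 0) &&
    length(fit@optinfo$conv$lme4$messages) == 0
}

# Fit rt_resid on a fixed-effects formula with a random-effects ladder,
# backing off when the fit fails to converge: full by-subject slopes with
# correlations, then without correlations, then main-effect slopes only,
# then intercepts only. Singular fits count as converged (variance
# components estimated at zero are legitimate for synthetic data with no
# such variance). `random = "intercepts"` starts at the last rung.
fit_ladder <- function(data, fixed_rhs, slope_terms, main_slope_terms,
                       random = c("maximal", "intercepts"),
                       sig_threshold = 1.96, label = "model",
                       region = NA_character_) {
  random <- match.arg(random)
  check_not_aliased(data, fixed_rhs)
  has_items <- length(unique(data$item_key)) > 1
  item_re <- if (has_items) " + (1 | item_key)" else ""
  rungs <- c(
    sprintf("(1 + %s | subject_id)%s", slope_terms, item_re),
    sprintf("(1 + %s || subject_id)%s", slope_terms, item_re),
    sprintf("(1 + %s || subject_id)%s", main_slope_terms, item_re),
    sprintf("(1 | subject_id)%s", item_re),
    "(1 | subject_id)" # degenerate designs: item intercepts unidentifiable
  )
  if (random == "intercepts") rungs <- rungs[4:5]
  fit <- NULL
  used_rung <- NA_character_
  converged <- FALSE
  for (re in rungs) {
    f <- stats::as.formula(paste("rt_resid ~", fixed_rhs, "+", re))
    cand <- tryCatch(
      suppressWarnings(suppressMessages(lme4::lmer(
        f, data = data, REML = TRUE,
        control = lme4::lmerControl(optimizer = "bobyqa",
                                    calc.derivs = FALSE,
                                    check.conv.singular = "ignore")
      ))),
      error = function(e) NULL
    )
    if (!is.null(cand) && mixed_converged(cand)) {
      fit <- cand
      used_rung <- re
      converged <- TRUE
      break
    }
    if (!is.null(cand) && is.null(fit)) {
      fit <- cand # keep best-effort fit in case no rung converges
      used_rung <- re
    }
  }
  if (is.null(fit)) {
    stop("no mixed model could be fit for ", label, call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  coefs <- tibble::tibble(
    predictor = label_terms(rownames(sm)),
    beta = unname(sm[, "Estimate"]),
    t_value = unname(sm[, "t value"]),
    significant = unname(abs(sm[, "t value"]) >= sig_threshold)
  )
  structure(
    list(coefficients = coefs, converged = converged,
         n_observations = nrow(data), re_formula = used_rung,
         sig_threshold = sig_threshold, analysis = label, region = region),
    class = "adaptation_fit"
  )
}

#' @export
print.adaptation_fit <- function(x, ...) {
  cat("<adaptation_fit>", x$analysis,
      if (!is.na(x$region)) paste0("[", x$region, "]"), "\n")
  cat("  n =", x$n_observations, "| random effects:", x$re_formula,
      if (!x$converged) "(did not converge)", "\n")
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

prepare_region_data <- function(region_table, region) {
  data <- region_table[region_table$region == region, , drop = FALSE]
  if (nrow(data) == 0) {
    abort_config(sprintf("no rows for region '%s'.", region))
  }
  data
}

#' Factorial adaptation analysis of region-level reading times
#'
#' Regresses length-corrected RTs at one sentence region onto the full
#' factorial of sentence type (MV vs. RC), ambiguity, and item order, plus a
#' main effect of log stimulus order, all predictors mean-centered (factors
#' coded +/-.5 before centering; MV and ambiguous map to +.5). The fit uses
#' by-subject and by-item random intercepts and, at the maximal setting,
#' by-subject random slopes for the within-subject factors, backing off
#' (correlations first, then interaction slopes, then main-effect slopes)
#' until convergence. The three-way sentence type : ambiguity : item order
#' coefficient is the adaptation estimate: a shrinking RC garden path shows
#' up as a positive three-way coefficient. |t| >= 1.96 is flagged as
#' significant.
#'
#' @param region_table Output of [aggregate_regions()] containing both
#'   structures.
#' @param region Sentence region to analyse.
#' @param random `"maximal"` for the full random-effects ladder,
#'   `"intercepts"` to fit random intercepts only (used in large replicate
#'   loops).
#' @return An `adaptation_fit`: coefficient table (`predictor`, `beta`,
#'   `t_value`, `significant`), convergence flag, number of observations,
#'   and the random-effects formula retained.
#' @export
fit_adaptation_model <- function(region_table,
                                 region = "disambiguating_region",
                                 random = c("maximal", "intercepts")) {
  data <- prepare_region_data(region_table, region)
  data$st_c <- center(contrast_half(data$structure, "MV"))
  data$amb_c <- center(contrast_half(data$ambiguity, "ambiguous"))
  data$io_c <- center(data$item_order)
  data$lso_c <- center(log(data$stimulus_order))
  fit_ladder(
    data,
    fixed_rhs = "st_c * amb_c * io_c + lso_c",
    slope_terms = "st_c * amb_c * io_c",
    main_slope_terms = "st_c + amb_c + io_c",
    random = random,
    label = "factorial adaptation model",
    region = region
  )
}

#' Simple-effects analysis within one sentence type
#'
#' Subsets the region table to one structure and fits ambiguity x item order
#' (plus log stimulus order), with the same coding, centering, and
#' random-effects conventions as [fit_adaptation_model()]. The ambiguity :
#' item order coefficient measures how that structure's garden-path effect
#' changes with exposure (negative = shrinking).
#'
#' @inheritParams fit_adaptation_model
#' @param structure `"RC"` or `"MV"`.
#' @return An `adaptation_fit`.
#' @export
simple_effects <- function(region_table, structure,
                           region = "disambiguating_region",
                           random = c("maximal", "intercepts")) {
  check_category(structure)
  data <- prepare_region_data(region_table, region)
  data <- data[data$structure == structure, , drop = FALSE]
  if (nrow(data) == 0) abort_config("empty subset for requested structure.")
  data$amb_c <- center(contrast_half(data$ambiguity, "ambiguous"))
  data$io_c <- center(data$item_order)
  data$lso_c <- center(log(data$stimulus_order))
  fit_ladder(
    data,
    fixed_rhs = "amb_c * io_c + lso_c",
    slope_terms = "amb_c * io_c",
    main_slope_terms = "amb_c + io_c",
    random = random,
    label = paste(structure, "simple effects"),
    region = region
  )
}

#' Blocked-design group analyses
#'
#' The three analyses of the two-group blocked design, each on length-
#' corrected RTs at one region (factors coded +/-.5 then centered; ambiguous
#' and the RC-First group map to +.5):
#' \describe{
#'   \item{Q1}{Block-3 MVs: ambiguity x group. A positive interaction means
#'     the MV garden path is larger for readers pre-exposed to RCs.}
#'   \item{Q2}{RC-First blocks 1-2: ambiguity x block (block 2 = +.5), plus
#'     a continuous re-analysis of ambiguity x RC-evidence count
#'     (`rc_seen`) with log stimulus order; the continuous interaction is
#'     Bonferroni-corrected for the two tests.}
#'   \item{Q3}{Block-2 RCs in both groups: ambiguity x group. A negative
#'     interaction means RC pre-exposure shrinks the RC garden path beyond
#'     task practice.}
#' }
#'
#' @inheritParams fit_adaptation_model
#' @param question `"Q1"`, `"Q2"`, or `"Q3"`.
#' @return For Q1/Q3 an `adaptation_fit`; for Q2 a list with elements
#'   `blocked` and `continuous`.
#' @export
exp2_analyses <- function(region_table, question = c("Q1", "Q2", "Q3"),
                          region = "disambiguating_region",
                          random = c("maximal", "intercepts")) {
  question <- match.arg(question)
  data <- prepare_region_data(region_table, region)
  if (all(is.na(data$group))) {
    abort_config("region table has no group labels; not a two-group design.")
  }
  if (question == "Q1") {
    d <- data[!is.na(data$block) & data$block == 3L, , drop = FALSE]
    if (nrow(d) == 0) abort_config("empty block-3 subset.")
    d$amb_c <- center(contrast_half(d$ambiguity, "ambiguous"))
    d$grp_c <- center(contrast_half(d$group, "RC_First"))
    return(fit_ladder(
      d, fixed_rhs = "amb_c * grp_c",
      slope_terms = "amb_c", main_slope_terms = "amb_c",
      random = random, label = "Q1: block-3 MV ambiguity x group",
      region = region
    ))
  }
  if (question == "Q3") {
    d <- data[!is.na(data$block) & data$block == 2L, , drop = FALSE]
    if (nrow(d) == 0) abort_config("empty block-2 subset.")
    d$amb_c <- center(contrast_half(d$ambiguity, "ambiguous"))
    d$grp_c <- center(contrast_half(d$group, "RC_First"))
    return(fit_ladder(
      d, fixed_rhs = "amb_c * grp_c",
      slope_terms = "amb_c", main_slope_terms = "amb_c",
      random = random, label = "Q3: block-2 RC ambiguity x group",
      region = region
    ))
  }
  # Q2
  d <- data[data$group == "RC_First" & !is.na(data$block) &
              data$block %in% 1:2, , drop = FALSE]
  if (nrow(d) == 0) abort_config("empty RC-First block-1/2 subset.")
  d$amb_c <- center(contrast_half(d$ambiguity, "ambiguous"))
  d$blk_c <- center(contrast_half(as.character(d$block), "2"))
  blocked <- fit_ladder(
    d, fixed_rhs = "amb_c * blk_c",
    slope_terms = "amb_c * blk_c", main_slope_terms = "amb_c + blk_c",
    random = random, label = "Q2: RC ambiguity x block",
    region = region
  )
  d$rcs_c <- center(d$rc_seen)
  d$lso_c <- center(log(d$stimulus_order))
  continuous <- fit_ladder(
    d, fixed_rhs = "amb_c * rcs_c + lso_c",
    slope_terms = "amb_c * rcs_c", main_slope_terms = "amb_c + rcs_c",
    random = random,
    sig_threshold = stats::qnorm(1 - 0.05 / 4), # Bonferroni over 2 tests
    label = "Q2 (continuous): RC ambiguity x RCs seen",
    region = region
  )
  list(blocked = blocked, continuous = continuous)
}

#' Flatten fit results to an exportable table
#'
#' @param fits An `adaptation_fit` or a (possibly nested) list of them.
#' @return A tibble with columns `region`, `predictor`, `beta`, `t_value`,
#'   `significant`.
#' @export
results_table <- function(fits) {
  if (inherits(fits, "adaptation_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    if (inherits(f, "adaptation_fit")) {
      out <- f$coefficients
      out$predictor <- paste0(
        if (!f$analysis %in% c("factorial adaptation model", "model"))
          paste0(sub(":.*$", "", f$analysis), ": ") else "",
        out$predictor
      )
      out$region <- f$region
      out[, c("region", "predictor", "beta", "t_value", "significant")]
    } else {
      results_table(f)
    }
  })
  dplyr::bind_rows(rows)
}

#' Write a results table to CSV
#'
#' @inheritParams results_table
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(fits, path) {
  readr::write_csv(results_table(fits), path)
  invisible(path)
}
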