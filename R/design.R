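#' @name spr_design
#' @title Self-paced-reading experiment designs
#' @description A design object holds, per counterbalancing list, the ordered
#'   stream of stimuli a subject reads: critical MV/RC sentences (crossed
#'   with ambiguity) interleaved with fillers. `stimulus_order` indexes every
#'   sentence (task practice); `item_order` indexes critical sentences only
#'   (syntactic evidence). Subjects are assigned to lists round-robin.
NULL

new_spr_design <- function(trials, n_subjects, n_lists, experiment,
                           group = NA_character_) {
  subjects <- tibble::tibble(
    subject_id = seq_len(n_subjects),
    list_id = ((seq_len(n_subjects) - 1L) %% n_lists) + 1L
  )
  structure(
    list(trials = trials, subjects = subjects, n_subjects = n_subjects,
         n_lists = n_lists, experiment = experiment, group = group),
    class = "spr_design"
  )
}

#' @export
print.spr_design <- function(x, ...) {
  cat("<spr_design>", x$experiment,
      if (!is.na(x$group)) paste0("(", x$group, ")"), "\n")
  cat(" ", x$n_subjects, "subjects over", x$n_lists, "list(s);",
      nrow(x$trials) / x$n_lists, "stimuli per subject\n")
  invisible(x)
}

shuffle_rows <- function(df, seed) {
  set.seed(seed)
  df[sample.int(nrow(df)), , drop = FALSE]
}

finalize_order <- function(trials) {
  trials$stimulus_order <- seq_len(nrow(trials))
  is_crit <- trials$kind == "critical"
  trials$item_order <- NA_integer_
  trials$item_order[is_crit] <- seq_len(sum(is_crit))
  trials
}

#' Build the mixed-exposure (50/50 RC/MV) design
#'
#' 36 critical items -- 18 RC and 18 MV sentences, half of each temporarily
#' ambiguous -- interleaved with 50 fillers. Conditions rotate over items
#' across 4 counterbalancing lists (a Latin square over the
#' structure-by-ambiguity quadruplet), so within every list half of the
#' ambiguous criticals resolve to the a-priori-rare RC structure. Each list
#' gets its own seeded pseudo-random interleaving.
#'
#' @param n_subjects Number of subjects (>= 1); default 72.
#' @param seed Integer seed; equal seeds give identical designs.
#' @return An `spr_design`.
#' @export
#' @examples
#' build_design_exp1(n_subjects = 4, seed = 1)
build_design_exp1 <- function(n_subjects = 72, seed = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort_config("`n_subjects` must be >= 1.")
  }
  conditions <- tibble::tibble(
    structure = c("MV", "MV", "RC", "RC"),
    ambiguity = c("ambiguous", "unambiguous", "ambiguous", "unambiguous")
  )
  lists <- lapply(1:4, function(list_id) {
    cond <- ((seq_len(36L) + list_id - 2L) %% 4L) + 1L
    criticals <- tibble::tibble(
      kind = "critical",
      structure = conditions$structure[cond],
      ambiguity = conditions$ambiguity[cond]
    )
    fillers <- tibble::tibble(
      kind = rep("filler", 50L),
      structure = NA_character_,
      ambiguity = NA_character_
    )
    trials <- shuffle_rows(dplyr::bind_rows(criticals, fillers),
                           derive_seed(seed, 100L + list_id))
    trials <- finalize_order(trials)
    trials$list_id <- list_id
    trials$block <- NA_integer_
    trials$group <- NA_character_
    trials
  })
  trials <- dplyr::bind_rows(lists)
  trials <- trials[, c("list_id", "stimulus_order", "item_order", "kind",
                       "structure", "ambiguity", "block", "group")]
  new_spr_design(trials, as.integer(n_subjects), 4L, "exp1")
}

exp2_block_composition <- function(group) {
  list(
    block1 = if (group == "RC_First") {
      tibble::tibble(kind = "critical", structure = "RC",
                     ambiguity = rep(c("ambiguous", "unambiguous"), 8L))
    } else {
      tibble::tibble(kind = rep("filler", 16L), structure = NA_character_,
                     ambiguity = NA_character_)
    },
    block2 = dplyr::bind_rows(
      tibble::tibble(kind = "critical", structure = "RC",
                     ambiguity = rep(c("ambiguous", "unambiguous"), 5L)),
      tibble::tibble(kind = rep("filler", 20L), structure = NA_character_,
                     ambiguity = NA_character_)
    ),
    block3 = dplyr::bind_rows(
      tibble::tibble(kind = "critical", structure = "MV",
                     ambiguity = rep(c("ambiguous", "unambiguous"), 5L)),
      tibble::tibble(kind = rep("filler", 15L), structure = NA_character_,
                     ambiguity = NA_character_)
    )
  )
}

#' Build the blocked two-group exposure design
#'
#' 71 sentences over three implicit blocks. The RC-First group reads 16 RCs
#' (8 ambiguous) in block 1; the Filler-First group reads 16 fillers instead.
#' Both groups then read identical blocks: 10 RCs (5 ambiguous) + 20 fillers
#' (block 2) and 10 MVs (5 ambiguous) + 15 fillers (block 3). The block
#' structure leaves no marker in the trial stream. Ambiguity assignment is
#' counterbalanced over 2 lists per group; stimuli are shuffled within block
#' with a seeded stream per list.
#'
#' @param group `"RC_First"` or `"Filler_First"`.
#' @param n_subjects Subjects in this group; default 40.
#' @param seed Integer seed.
#' @return An `spr_design`.
#' @export
#' @examples
#' build_design_exp2("RC_First", n_subjects = 4, seed = 1)
build_design_exp2 <- function(group = c("RC_First", "Filler_First"),
                              n_subjects = 40, seed = 1) {
  group <- match.arg(group)
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort_config("`n_subjects` must be >= 1.")
  }
  blocks <- exp2_block_composition(group)
  lists <- lapply(1:2, function(list_id) {
    per_block <- lapply(seq_along(blocks), function(b) {
      blk <- blocks[[b]]
      if (list_id == 2L) {
        # second list swaps the ambiguity assignment of criticals
        amb <- blk$ambiguity
        blk$ambiguity[amb == "ambiguous"] <- "unambiguous"
        blk$ambiguity[amb == "unambiguous"] <- "ambiguous"
      }
      blk <- shuffle_rows(blk, derive_seed(seed, 200L + 10L * list_id + b))
      blk$block <- b
      blk
    })
    trials <- finalize_order(dplyr::bind_rows(per_block))
    trials$list_id <- list_id
    trials$group <- group
    trials
  })
  trials <- dplyr::bind_rows(lists)
  trials <- trials[, c("list_id", "stimulus_order", "item_order", "kind",
                       "structure", "ambiguity", "block", "group")]
  new_spr_design(trials, as.integer(n_subjects), 2L, "exp2", group = group)
}

#' Extract the syntactic-evidence sequence of a design list
#'
#' Critical sentences, in presentation order, as belief-model evidence.
#' Fillers never carry MV/RC evidence.
#'
#' @param design An `spr_design`.
#' @param list_id Which counterbalancing list (default 1).
#' @return A tibble with columns `category` and `block`.
#' @export
evidence_sequence <- function(design, list_id = 1L) {
  stopifnot(inherits(design, "spr_design"))
  tr <- design$trials
  tr <- tr[tr$list_id == list_id & tr$kind == "critical", ]
  tr <- tr[order(tr$stimulus_order), ]
  tibble::tibble(category = tr$structure, block = tr$block)
}
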