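#' The codon-improvement algorithm
#'
#' For a missense or nonsense variant that cannot be reverted by direct
#' editing, the mutant codon may still be editable into a third codon whose
#' amino acid improves on the mutant one. The algorithm enumerates every
#' A>G / C>T edit subset of the mutant codon ([enumerate_edits()]), discards
#' candidates that would create a stop codon, scores each candidate amino
#' acid against the reference amino acid, keeps the candidates scoring
#' strictly better than the mutant amino acid, and returns the best score,
#' preferring the minimum number of simultaneous edits and then the
#' lexicographically smallest codon for determinism.
#'
#' Two scorer modes are supported. *Matrix* mode scores candidates with a
#' substitution matrix (BLOSUM62 by default) via [matrix_score()]; the stop
#' policy guarantees that any escape from a mutant stop codon qualifies.
#' *Site-table* mode uses per-site tolerance scores in `[0,1]` (SIFT-style,
#' 0 = deleterious, 1 = tolerated): the baseline is the mutant amino acid's
#' score (0 for a mutant stop), and candidates at or below `tolerance_floor`
#' (default 0.05, the conventional deleteriousness cut-off) are discarded.
#'
#' @name improvement
NULL

#' Matrix-mode scorer
#' @param matrix Substitution matrix, default [blosum62()].
#' @return Scorer object for [improve_codon()].
#' @export
scorer_matrix <- function(matrix = blosum62()) {
  structure(list(kind = "matrix", matrix = matrix), class = "be_scorer")
}

#' Site-table scorer
#'
#' @param site_scores Named numeric vector: tolerance score in `[0,1]` for
#'   each amino acid at this protein site.
#' @param tolerance_floor Candidates scoring at or below this are dropped
#'   (default 0.05).
#' @return Scorer object for [improve_codon()].
#' @export
scorer_site_table <- function(site_scores, tolerance_floor = 0.05) {
  if (any(site_scores < 0 | site_scores > 1, na.rm = TRUE)) {
    be_stop("site scores must be in [0,1]")
  }
  if (tolerance_floor < 0 || tolerance_floor >= 1) be_stop("tolerance_floor must be in [0,1)")
  structure(list(kind = "site_table", site_scores = site_scores,
                 tolerance_floor = tolerance_floor), class = "be_scorer")
}

score_aa <- function(scorer, ref_aa, aa) {
  if (scorer$kind == "matrix") {
    matrix_score(ref_aa, aa, scorer$matrix)
  } else {
    if (aa == "*") return(0)
    s <- scorer$site_scores[aa]
    if (is.na(s)) 0 else unname(s)
  }
}

#' Best base-editing improvement of a mutant codon
#'
#' See [improvement] for the algorithm. Returns `NULL` when no candidate
#' improves on the mutant amino acid (including codons with no editable
#' base).
#'
#' @param ref_codon Reference codon (what the protein should encode).
#' @param mut_codon Mutant codon observed in the patient; must differ from
#'   `ref_codon` and must not be synonymous with it.
#' @param scorer [scorer_matrix()] or [scorer_site_table()].
#' @param chemistries Chemistries the editor can deploy, default both.
#' @return `NULL`, or a list with `ref_codon`, `mut_codon`, `novel_codon`,
#'   `ref_aa`, `mut_aa`, `novel_aa`, `edit_ops` (data.frame row of
#'   [enumerate_edits()]), `n_edits`, `mut_score`, `novel_score`,
#'   `mode_label` (`"A_only"`, `"C_only"` or `"combined"`),
#'   `protein_level_correction` (novel amino acid equals the reference one)
#'   and `ptm_risk` (the substitution could disrupt a phosphorylation or
#'   methylation/acetylation site).
#' @examples
#' improve_codon("TAT", "TCT", scorer_matrix())$novel_codon  # "TTT"
#' @export
improve_codon <- function(ref_codon, mut_codon, scorer = scorer_matrix(),
                          chemistries = edit_chemistries()) {
  if (!inherits(scorer, "be_scorer")) be_stop("scorer must be a be_scorer")
  ref_aa <- translate_codon(ref_codon)
  mut_aa <- translate_codon(mut_codon)
  if (ref_codon == mut_codon) be_stop("mutant codon equals reference codon")
  if (ref_aa == "*") be_stop("stop-lost variants are outside the improvement analysis")
  if (ref_aa == mut_aa) be_stop("synonymous variants are outside the improvement analysis")
  cands <- enumerate_edits(mut_codon, chemistries)
  if (nrow(cands) == 0) return(NULL)
  cands$aa <- translate_codon(cands$novel)
  cands <- cands[cands$aa != "*", , drop = FALSE]  # never create a stop
  if (nrow(cands) == 0) return(NULL)
  baseline <- score_aa(scorer, ref_aa, mut_aa)
  cands$score <- vapply(cands$aa, function(a) score_aa(scorer, ref_aa, a), 0)
  if (scorer$kind == "site_table") {
    cands <- cands[cands$score > scorer$tolerance_floor, , drop = FALSE]
  }
  cands <- cands[cands$score > baseline, , drop = FALSE]
  if (nrow(cands) == 0) return(NULL)
  ord <- order(-cands$score, cands$n_edits, cands$novel)
  best <- cands[ord[1], , drop = FALSE]
  pos <- best$positions[[1]]
  from <- strsplit(mut_codon, "")[[1]][pos]
  mode_label <- if (all(from == "A")) "A_only" else if (all(from == "C")) "C_only" else "combined"
  novel_aa <- best$aa
  ptm_risk <- (mut_aa %in% c("S", "T", "Y") && novel_aa %in% c("G", "A", "C")) ||
              (mut_aa == "K" && novel_aa %in% c("R", "G"))
  list(ref_codon = ref_codon, mut_codon = mut_codon, novel_codon = best$novel,
       ref_aa = ref_aa, mut_aa = mut_aa, novel_aa = novel_aa,
       edit_ops = best$ops, n_edits = best$n_edits,
       mut_score = baseline, novel_score = best$score,
       mode_label = mode_label,
       protein_level_correction = novel_aa == ref_aa,
       ptm_risk = ptm_risk)
}

#' Improve one annotated variant
#'
#' Delegates to [improve_codon()] using the record's reference and mutant
#' codons (from [attach_cds_context()]). The record must be an improvement
#' candidate: a missense or nonsense variant whose transcript-oriented
#' mismatch is not directly editable (`G>A`, `T>C`).
#'
#' @param record One-row variant table with `codon`, `mut_codon`,
#'   `consequence`.
#' @param scorer,chemistries As [improve_codon()].
#' @return `NULL` or a one-row data.frame: the [improve_codon()] result plus
#'   `variant_id` and `score_delta`.
#' @export
improve_variant <- function(record, scorer = scorer_matrix(),
                            chemistries = edit_chemistries()) {
  record <- transcript_alleles(record)
  if (!all(c("codon", "mut_codon") %in% names(record)) ||
      is.na(record$codon[1]) || is.na(record$mut_codon[1])) {
    be_stop("record lacks codon context; run attach_cds_context() first")
  }
  mm <- paste0(record$t_ref[1], ">", record$t_alt[1])
  if (mm %in% DIRECT_TYPES) {
    be_stop("record is revertible by direct editing, not an improvement candidate")
  }
  if (!record$consequence[1] %in% c("missense", "nonsense")) {
    be_stop("improvement is defined for missense and nonsense variants only")
  }
  res <- improve_codon(record$codon[1], record$mut_codon[1], scorer, chemistries)
  if (is.null(res)) return(NULL)
  data.frame(variant_id = record$variant_id[1],
             ref_codon = res$ref_codon, mut_codon = res$mut_codon,
             novel_codon = res$novel_codon, ref_aa = res$ref_aa,
             mut_aa = res$mut_aa, novel_aa = res$novel_aa,
             edit_ops = res$edit_ops, n_edits = res$n_edits,
             mut_score = res$mut_score, novel_score = res$novel_score,
             score_delta = res$novel_score - res$mut_score,
             mode_label = res$mode_label,
             protein_level_correction = res$protein_level_correction,
             ptm_risk = res$ptm_risk,
             scorer_kind = scorer$kind,
             stringsAsFactors = FALSE)
}

#' Summarise improvement score gains
#'
#' @param results data.frame of [improve_variant()] rows from a single scorer
#'   mode.
#' @return List with `n`, `mean_delta` and `mode_counts` (named counts over
#'   `A_only`/`C_only`/`combined`). Empty input yields an empty summary.
#' @export
score_delta_distribution <- function(results) {
  if (is.null(results) || nrow(results) == 0) {
    return(list(n = 0L, mean_delta = NA_real_,
                mode_counts = c(A_only = 0L, C_only = 0L, combined = 0L)))
  }
  if (length(unique(results$scorer_kind)) > 1) {
    be_stop("mixed scorer modes in one summary")
  }
  modes <- c(A_only = 0L, C_only = 0L, combined = 0L)
  tab <- table(results$mode_label)
  modes[names(tab)] <- as.integer(tab)
  list(n = nrow(results),
       mean_delta = mean(results$score_delta),
       mode_counts = modes)
}
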