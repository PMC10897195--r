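#' End-to-end helpers over the module functions
#'
#' Convenience wrappers that chain the module surfaces in the order of the
#' analysis: exclusion cascade, pathogenicity filter, CDS annotation,
#' editability calls, per-variant sequence context, improvement, summaries.
#'
#' @name pipeline
NULL

#' Run the variant filtering cascade
#'
#' [apply_exclusions()], then [filter_pathogenic()], then
#' [attach_cds_context()], collecting the three filter reports.
#'
#' @param raw Raw variant table.
#' @param cds_fasta Transcript set for [attach_cds_context()].
#' @param keep_unresolved_conflicts See [filter_pathogenic()].
#' @return List with `records` and `reports` (named list of filter_report).
#' @export
filter_cascade <- function(raw, cds_fasta, keep_unresolved_conflicts = FALSE) {
  ex <- apply_exclusions(raw)
  pa <- filter_pathogenic(ex$records, keep_unresolved_conflicts)
  an <- attach_cds_context(pa$records, cds_fasta)
  list(records = an$records,
       reports = list(exclusions = ex$report, pathogenic = pa$report,
                      cds = an$report))
}

# mutant-substituted context window of one record, or NA when absent
mutant_context <- function(record) {
  ctx <- record$context_seq[1]; off <- record$context_offset[1]
  if (is.na(ctx) || is.na(off)) return(NULL)
  substr(ctx, off, off) <- record$t_alt[1]
  list(seq = ctx, target = off)
}

#' Per-variant sequence-context report
#'
#' For every record with a context window, evaluates the checks relevant to
#' its editability call: the ADAR 5' motif (A-to-I direct targets), RNA
#' bystander counts within `rna_flank` of the target (direct RNA targets,
#' counted on the mutant sequence), NGG PAM discovery at
#' `pam_distance_range`, and DNA bystander counts inside the first accepted
#' editing window. When a predictor table is supplied, coding RNA bystanders
#' are annotated with predicted-pathogenic counts.
#'
#' @param records Classified variant table (after [call_editability()]).
#' @param predictor Optional predictor table from [read_predictor_table()]
#'   (or a compatible data.frame with a `key` column).
#' @param pam,pam_distance_range,rna_flank Context parameters (defaults
#'   `"NGG"`, `c(12,16)`, 10).
#' @return data.frame keyed by `variant_id`: `adar_ok`, `five_prime_base`,
#'   `n_pams`, `pam_distances` (comma-joined), `n_bystanders_rna`,
#'   `n_predicted_pathogenic`, `n_bystanders_dna`.
#' @export
context_report <- function(records, predictor = NULL, pam = "NGG",
                           pam_distance_range = c(12L, 16L), rna_flank = 10) {
  records <- transcript_alleles(records)
  n <- nrow(records)
  out <- data.frame(variant_id = records$variant_id,
                    adar_ok = NA, five_prime_base = NA_character_,
                    n_pams = NA_integer_, pam_distances = NA_character_,
                    n_bystanders_rna = NA_integer_,
                    n_predicted_pathogenic = NA_integer_,
                    n_bystanders_dna = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    rec <- records[i, , drop = FALSE]
    mc <- mutant_context(rec)
    if (is.null(mc)) next
    mm <- paste0(rec$t_ref, ">", rec$t_alt)
    if (mm == "G>A") {
      am <- adar_motif(mc$seq, mc$target)
      out$adar_ok[i] <- am$motif_ok
      out$five_prime_base[i] <- am$five_prime_base
    }
    pams <- find_ngg_pams(mc$seq, mc$target, pam = pam,
                          distance_range = pam_distance_range)
    out$n_pams[i] <- nrow(pams)
    out$pam_distances[i] <- paste(pams$distance, collapse = ",")
    if (mm %in% c("G>A", "T>C")) {
      eb <- if (mm == "G>A") "A" else "C"
      rep_rna <- count_bystanders_rna(mc$seq, mc$target, eb, flank = rna_flank)
      out$n_bystanders_rna[i] <- rep_rna$n_bystanders
      if (!is.null(predictor) && !is.na(rec$cds_offset[1])) {
        ann <- annotate_bystander_pathogenicity(rep_rna, rec$transcript_id[1],
                                                rec$cds_offset[1], mc$target,
                                                predictor)
        out$n_predicted_pathogenic[i] <- ann$n_predicted_pathogenic
      }
      if (nrow(pams) > 0) {
        rep_dna <- count_bystanders_dna(mc$seq, mc$target,
                                        pams[1, , drop = FALSE], eb)
        out$n_bystanders_dna[i] <- rep_dna$n_bystanders
      }
    }
  }
  out
}

#' Improve all candidate variants
#'
#' Runs [improve_variant()] over the records flagged `improvement_candidate`
#' with codon context. In site-table mode, each record's per-amino-acid
#' scores are looked up in `site_table` (columns `variant_id`, `amino_acid`,
#' `score`); records without any site entry are skipped.
#'
#' @param records Classified, annotated variant table.
#' @param scorer `"matrix"` (default: BLOSUM62) or `"site_table"`.
#' @param site_table Required for site-table mode.
#' @param tolerance_floor See [scorer_site_table()].
#' @return data.frame of improvement results (zero rows if none).
#' @export
improve_cohort <- function(records, scorer = c("matrix", "site_table"),
                           site_table = NULL, tolerance_floor = 0.05) {
  scorer <- match.arg(scorer)
  if (scorer == "site_table" && is.null(site_table)) {
    be_stop("site_table mode needs a site_table")
  }
  cand <- which(records$improvement_candidate & !is.na(records$codon) &
                records$consequence %in% c("missense", "nonsense"))
  res <- list()
  for (i in cand) {
    rec <- records[i, , drop = FALSE]
    sc <- if (scorer == "matrix") {
      scorer_matrix()
    } else {
      rows <- site_table[site_table$variant_id == rec$variant_id[1], , drop = FALSE]
      if (nrow(rows) == 0) next
      scorer_site_table(stats::setNames(rows$score, rows$amino_acid),
                        tolerance_floor)
    }
    r <- improve_variant(rec, sc)
    if (!is.null(r)) res[[length(res) + 1L]] <- r
  }
  if (length(res) == 0) {
    return(data.frame(variant_id = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
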