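#' Cohort summaries and clinical-relevance stratifications
#'
#' Aggregation of per-variant editability calls into headline tables
#' (counts and fractions per editing category, optionally crossed with
#' mismatch type and molecular consequence) and the stratification filters:
#' submitter support, population-frequency presence, guide specificity
#' (MIT score) and tissue-restricted gene expression.
#'
#' @name summarize
NULL

#' Tabulate editing categories
#'
#' Partitions classified records over the primary categories `direct`,
#' `complementary`, `improvable`, `not_amendable`. When improvement results
#' are supplied, records in the `improvable` candidate pool whose improvement
#' failed (no scoring candidate) are reassigned to `not_amendable`, so the
#' `improvable` count reflects variants actually improved.
#'
#' @param calls Variant table from [call_editability()].
#' @param improvements Optional data.frame of [improve_variant()] results.
#' @return List with `n`, `counts`, `fractions` (both named over the four
#'   categories) and `by_type` (mismatch type x category contingency table).
#' @export
tabulate_editability <- function(calls, improvements = NULL) {
  if (nrow(calls) == 0) {
    cats <- c(direct = 0L, complementary = 0L, improvable = 0L, not_amendable = 0L)
    return(list(n = 0L, counts = cats, fractions = cats * NA_real_,
                by_type = NULL))
  }
  if (any(calls$dna_direct & calls$dna_complementary)) {
    be_stop("invariant violation: record flagged both direct and complementary")
  }
  cat <- calls$edit_category
  if (!is.null(improvements)) {
    improved <- calls$variant_id %in% improvements$variant_id
    cat[cat == "improvable" & !improved] <- "not_amendable"
  }
  lev <- c("direct", "complementary", "improvable", "not_amendable")
  counts <- stats::setNames(integer(4), lev)
  tab <- table(factor(cat, levels = lev))
  counts[names(tab)] <- as.integer(tab)
  mm <- paste0(calls$ref, ">", calls$alt)
  list(n = nrow(calls), counts = counts, fractions = counts / nrow(calls),
       by_type = table(mismatch = mm, category = factor(cat, levels = lev)))
}

#' Keep variants with broad submitter support
#'
#' @param records Variant table with `n_submitters`.
#' @param k Minimum number of distinct submitters, default 3.
#' @return Subset of `records`; rows with missing submitter counts are
#'   dropped with a warning.
#' @export
filter_by_submitters <- function(records, k = 3) {
  miss <- is.na(records$n_submitters)
  if (any(miss)) warning(sum(miss), " record(s) lack submitter counts; dropped")
  records[!miss & records$n_submitters >= k, , drop = FALSE]
}

#' Keep variants present in a population-frequency table
#'
#' Presence means a reported allele frequency strictly greater than zero.
#'
#' @param records Variant table.
#' @param freq_table data.frame with `chrom`, `pos`, `ref`, `alt`, `af`.
#' @return Subset of `records`.
#' @export
filter_by_frequency_presence <- function(records, freq_table) {
  if (nrow(freq_table) == 0) return(records[0, , drop = FALSE])
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  af <- freq_table$af[match(key(records), key(freq_table))]
  records[!is.na(af) & af > 0, , drop = FALSE]
}

#' Keep variants whose guide passes the specificity threshold
#'
#' @param records Variant table.
#' @param mit_table data.frame with `variant_id` and `score` in `[0,100]`
#'   (an MIT-style aggregate guide-uniqueness score).
#' @param threshold Keep scores strictly above this, default 50.
#' @return Subset of `records`; the number of records without a score is
#'   attached as attribute `"n_missing_score"`.
#' @export
filter_by_specificity <- function(records, mit_table, threshold = 50) {
  if (any(mit_table$score < 0 | mit_table$score > 100, na.rm = TRUE)) {
    be_stop("MIT scores must be in [0,100]")
  }
  sc <- mit_table$score[match(records$variant_id, mit_table$variant_id)]
  out <- records[!is.na(sc) & sc > threshold, , drop = FALSE]
  attr(out, "n_missing_score") <- sum(is.na(sc))
  out
}

#' Genes expressed in one tissue but quiet elsewhere
#'
#' Selects genes with expression strictly above `high` (transcripts per
#' million) in `tissue` and mean expression strictly below `other_avg` across
#' all other tissues. Genes at exactly the thresholds are rejected.
#'
#' @param expr Numeric matrix or data.frame, genes x tissues, non-negative,
#'   unique rownames.
#' @param tissue Column name of the tissue of interest.
#' @param high,other_avg Thresholds in TPM, both default 10.
#' @return Character vector of gene identifiers (possibly empty).
#' @export
tissue_genes <- function(expr, tissue, high = 10, other_avg = 10) {
  expr <- as.matrix(expr)
  if (!tissue %in% colnames(expr)) be_stop(paste("unknown tissue:", tissue))
  if (nrow(expr) == 0) return(character(0))
  if (any(expr < 0)) be_stop("expression values must be non-negative")
  if (anyDuplicated(rownames(expr))) be_stop("gene identifiers must be unique")
  others <- expr[, setdiff(colnames(expr), tissue), drop = FALSE]
  sel <- expr[, tissue] > high & rowMeans(others) < other_avg
  rownames(expr)[sel]
}
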