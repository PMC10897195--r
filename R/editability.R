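#' Editability classification
#'
#' A deaminase can only perform A>G and C>T conversions, so of the 12
#' mismatch types only `G>A` and `T>C` variants can be reverted by editing
#' the mutant base itself (*direct* editing: the mutant A is deaminated back
#' to G, or the mutant C is read as T). At the DNA level the complementary
#' strand is also available, which extends correction to `C>T` and `A>G`
#' variants (*complementary* editing). The remaining eight mismatch types
#' cannot be corrected; missense and nonsense variants among them are
#' candidates for the codon-improvement algorithm (see [improve_variant()]).
#'
#' RNA editors act on the transcript: cytoplasmic mRNA editing requires the
#' variant to be in a coding region, while nuclear RNA editing (e.g. via the
#' ADAR p110 isoform) also reaches non-coding transcribed regions. RNA calls
#' always use the transcript-oriented mismatch. DNA calls use the orientation
#' selected by `orientation`: `"genomic"` (default, reproducing censuses of
#' reported mismatch types) or `"transcript"`. Under `"transcript"` the
#' hierarchy `rna_direct_cytoplasmic => rna_direct_nuclear => dna_direct`
#' holds by construction.
#'
#' @name editability
NULL

DIRECT_TYPES <- c("G>A", "T>C")
COMPLEMENTARY_TYPES <- c("C>T", "A>G")

#' Classify base-editing options for each variant
#'
#' Adds per-variant flags `rna_direct_cytoplasmic`, `rna_direct_nuclear`,
#' `dna_direct`, `dna_complementary`, the `chemistry` used for direct editing
#' (`"A_to_I"`, `"C_to_U"` or `"none"`), `improvement_candidate` (no direct
#' option and consequence missense/nonsense) and the primary `edit_category`
#' (`"direct"`, `"complementary"`, `"improvable"`, `"not_amendable"`).
#' Intergenic records receive no flags (out of the gene-scoped analysis).
#'
#' @param records Variant table (transcript alleles are derived if absent).
#' @param orientation Orientation for the DNA-level calls; see Details.
#' @return The table with classification columns added.
#' @export
call_editability <- function(records, orientation = c("genomic", "transcript")) {
  orientation <- match.arg(orientation)
  records <- transcript_alleles(records)
  if (nrow(records) == 0) return(records)
  mm_t <- paste0(records$t_ref, ">", records$t_alt)
  mm_g <- paste0(records$ref, ">", records$alt)
  mm_dna <- if (orientation == "genomic") mm_g else mm_t
  region <- records$region
  genic <- !is.na(region) & region %in% c("coding", "gene_noncoding")
  valid <- records$ref %in% DNA_BASES & records$alt %in% DNA_BASES &
           records$ref != records$alt

  rna_direct <- valid & genic & mm_t %in% DIRECT_TYPES
  records$rna_direct_nuclear <- rna_direct
  records$rna_direct_cytoplasmic <- rna_direct & region == "coding"
  records$dna_direct <- valid & genic & mm_dna %in% DIRECT_TYPES
  records$dna_complementary <- valid & genic & mm_dna %in% COMPLEMENTARY_TYPES
  # chemistry actually deployed: the deaminase for the direct call, or for the
  # complementary-strand call when only that is available (C>T is fixed by
  # deaminating the complementary A; A>G by deaminating the complementary C)
  chem_of <- function(mm) ifelse(mm %in% c("G>A", "C>T"), "A_to_I",
                          ifelse(mm %in% c("T>C", "A>G"), "C_to_U", "none"))
  mm_eff <- ifelse(rna_direct, mm_t, mm_dna)
  records$chemistry <- ifelse(rna_direct | records$dna_direct | records$dna_complementary,
                              chem_of(mm_eff), "none")
  records$chemistry[!valid | !genic] <- "none"
  no_direct <- !records$rna_direct_cytoplasmic & !records$rna_direct_nuclear &
               !records$dna_direct
  records$improvement_candidate <- valid & genic & no_direct &
    !is.na(records$consequence) & records$consequence %in% c("missense", "nonsense")
  records$edit_category <- ifelse(records$dna_direct | records$rna_direct_nuclear,
                                  "direct",
                           ifelse(records$dna_complementary, "complementary",
                           ifelse(records$improvement_candidate, "improvable",
                                  "not_amendable")))
  records$edit_category[!valid | !genic] <- "not_amendable"
  records
}

#' Census of mismatch types
#'
#' Exhaustive partition of the records over the 12 ordered mismatch types.
#'
#' @param records Variant table.
#' @param orientation Count reported (genomic) or transcript-oriented
#'   mismatches.
#' @return Named integer vector over [mismatch_types()]; sums to `nrow(records)`
#'   (records with invalid alleles are counted under `"invalid"`).
#' @export
mismatch_census <- function(records, orientation = c("genomic", "transcript")) {
  orientation <- match.arg(orientation)
  if (orientation == "transcript") records <- transcript_alleles(records)
  mm <- if (nrow(records) == 0) character(0)
        else if (orientation == "genomic") paste0(records$ref, ">", records$alt)
        else paste0(records$t_ref, ">", records$t_alt)
  counts <- stats::setNames(integer(12), mismatch_types())
  tab <- table(mm[mm %in% mismatch_types()])
  counts[names(tab)] <- as.integer(tab)
  n_invalid <- sum(!mm %in% mismatch_types())
  if (n_invalid > 0) counts <- c(counts, invalid = n_invalid)
  counts
}
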