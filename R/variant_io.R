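#' Variant tables, parsing dialects and the filtering cascade
#'
#' Variants are held in a plain data.frame ("variant table") with one row per
#' reported SNV and a fixed set of columns (see [variant_columns()]).
#' Coordinates are 1-based inclusive throughout (VCF convention); BED-style
#' 0-based half-open inputs are converted on read. `ref`/`alt` are stored as
#' reported (plus genomic strand); the transcript-oriented alleles used by the
#' RNA analyses are derived by complementation for minus-strand transcripts.
#'
#' @name variant_io
NULL

REGIONS <- c("coding", "gene_noncoding", "intergenic")
CONSEQUENCES <- c("missense", "nonsense", "synonymous", "initiator_codon",
                  "stop_lost", "splice", "intron", "UTR", "upstream",
                  "downstream", "other", "none")

#' Columns of a variant table
#' @return Character vector of required column names.
#' @export
variant_columns <- function() {
  c("variant_id", "chrom", "pos", "ref", "alt", "gene", "transcript_id",
    "cds_offset", "region", "consequence", "clin_sig", "submitter_sigs",
    "n_submitters", "strand")
}

#' Coerce and validate a variant table
#'
#' Fills optional columns with `NA`, assigns `variant_id`s where missing and
#' checks types. Does not apply any filter: rows that violate SNV invariants
#' (e.g. `ref == alt`, multi-base alleles) are retained so the exclusion
#' cascade can count them.
#'
#' @param df data.frame with at least `chrom`, `pos`, `ref`, `alt`.
#' @return Validated variant table.
#' @export
as_variant_table <- function(df) {
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) be_stop(paste("missing columns:", paste(miss, collapse = ", ")))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  defaults <- list(variant_id = NA_character_, gene = NA_character_,
                   transcript_id = NA_character_, cds_offset = NA_integer_,
                   region = NA_character_, consequence = NA_character_,
                   clin_sig = NA_character_, submitter_sigs = NA_character_,
                   n_submitters = NA_integer_, strand = "+")
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- rep(defaults[[nm]], nrow(df))
  }
  df$pos <- as.integer(df$pos)
  df$cds_offset <- as.integer(df$cds_offset)
  df$n_submitters <- as.integer(df$n_submitters)
  no_id <- is.na(df$variant_id)
  if (any(no_id)) df$variant_id[no_id] <- sprintf("VAR%06d", which(no_id))
  if (anyDuplicated(df$variant_id)) be_stop("duplicated variant_id")
  extra <- setdiff(names(df), variant_columns())
  df[, c(variant_columns(), extra), drop = FALSE]
}

#' Transcript-oriented alleles
#'
#' Adds `t_ref`/`t_alt` columns: the reported alleles complemented for rows on
#' minus-strand transcripts, i.e. the mismatch as seen on the mRNA sense
#' strand. Rows with unknown strand are treated as plus.
#'
#' @param records Variant table.
#' @return The table with `t_ref` and `t_alt` columns added.
#' @export
transcript_alleles <- function(records) {
  minus <- !is.na(records$strand) & records$strand == "-"
  ok <- records$ref %in% DNA_BASES & records$alt %in% DNA_BASES
  records$t_ref <- ifelse(minus & ok, complement_base(records$ref), records$ref)
  records$t_alt <- ifelse(minus & ok, complement_base(records$alt), records$alt)
  records
}

# ---- filter reports --------------------------------------------------------

new_filter_report <- function(n_input, removed, extra = list()) {
  removed <- vapply(removed, as.integer, 0L)
  rep <- structure(list(n_input = as.integer(n_input),
                        removed = removed,
                        n_retained = as.integer(n_input) - sum(removed),
                        extra = extra),
                   class = "filter_report")
  stopifnot(rep$n_retained >= 0)
  rep
}

#' @exportS3Method base::print
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: %d in, %d retained\n", x$n_input, x$n_retained))
  for (nm in names(x$removed)) cat(sprintf("  removed %-24s %d\n", nm, x$removed[[nm]]))
  invisible(x)
}

#' @exportS3Method base::as.list
as.list.filter_report <- function(x, ...) {
  list(n_input = x$n_input, n_retained = x$n_retained,
       removed = as.list(x$removed))
}

# ---- parsing ---------------------------------------------------------------

#' Read a variant table
#'
#' Supported dialects: `"tsv"` (the package's own 1-based tab-separated
#' dialect, as written by [write_variant_table()]), `"bed"` (UCSC track style:
#' 0-based half-open `chromStart`/`chromEnd`, converted to 1-based positions)
#' and `"vcf"` (via \pkg{vcfR}; pulls `CLNSIG`, `CLNSIGCONF`, `GENEINFO` and
#' `MC` from INFO when present). Malformed rows (unparseable position) are
#' collected in the `"malformed"` attribute, not silently dropped.
#'
#' @param path File path.
#' @param dialect One of `"tsv"`, `"bed"`, `"vcf"`.
#' @param column_map Optional named list mapping package field names to input
#'   column names for the tabular dialects.
#' @return Variant table (possibly with 0 rows; a warning is emitted for an
#'   empty file).
#' @export
read_variant_table <- function(path, dialect = c("tsv", "bed", "vcf"),
                               column_map = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "vcf") return(read_clinvar_vcf(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) {
    warning("empty variant file: ", path)
    return(as_variant_table(data.frame(chrom = character(0), pos = integer(0),
                                       ref = character(0), alt = character(0))))
  }
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      if (!column_map[[nm]] %in% names(df)) be_stop(paste("column not found:", column_map[[nm]]))
      names(df)[names(df) == column_map[[nm]]] <- nm
    }
  }
  if (dialect == "bed") {
    if (!"start" %in% names(df) && "chromStart" %in% names(df)) df$start <- df$chromStart
    if (!"chrom" %in% names(df)) be_stop("unparseable header: no chrom column")
    if (!"start" %in% names(df)) be_stop("unparseable header: no start/chromStart column")
    df$pos <- suppressWarnings(as.integer(df$start)) + 1L
  }
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(df))) {
    be_stop("unparseable header: need chrom, pos/start, ref, alt")
  }
  pos_num <- suppressWarnings(as.integer(df$pos))
  malformed <- df[is.na(pos_num), , drop = FALSE]
  df <- df[!is.na(pos_num), , drop = FALSE]
  out <- as_variant_table(df)
  attr(out, "malformed") <- malformed
  out
}

# molecular-consequence strings (SO terms or ClinVar MC text) -> package terms
map_consequence <- function(x) {
  x <- tolower(x)
  out <- rep("other", length(x))
  pat <- c(missense = "missense", nonsense = "nonsense|stop_gained",
           synonymous = "synonymous", initiator_codon = "initiator|start_lost",
           stop_lost = "stop_lost", splice = "splice", intron = "intron",
           UTR = "utr", upstream = "upstream", downstream = "downstream")
  for (nm in names(pat)) out[grepl(pat[[nm]], x)] <- nm
  out[is.na(x) | x == ""] <- "none"
  out
}

read_clinvar_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    warning("empty VCF: ", path)
    return(as_variant_table(data.frame(chrom = character(0), pos = integer(0),
                                       ref = character(0), alt = character(0))))
  }
  info1 <- function(key) {
    v <- vcfR::extract.info(vcf, element = key)
    if (is.null(v)) rep(NA_character_, nrow(fix)) else v
  }
  clnsig <- gsub("_", " ", info1("CLNSIG"))
  conf <- info1("CLNSIGCONF")
  conf <- ifelse(is.na(conf), NA_character_,
                 gsub("_", " ", gsub("\\(\\d+\\)", "", gsub("%3B|\\|", ";", conf))))
  geneinfo <- sub(":.*$", "", info1("GENEINFO"))
  mc <- info1("MC")
  df <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                   ref = fix$REF, alt = fix$ALT,
                   gene = geneinfo, clin_sig = clnsig,
                   submitter_sigs = conf,
                   consequence = map_consequence(mc),
                   stringsAsFactors = FALSE)
  as_variant_table(df)
}

#' Write / re-read the package's variant TSV dialect
#'
#' @param records Variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# ---- the filtering cascade -------------------------------------------------

#' Structural exclusions applied to reported SNVs
#'
#' Removes, in order: downstream and upstream transcript variants; variants
#' with no sequence alteration (`ref == alt`); variants with no molecular
#' consequence; variants misclassified as SNVs (allele length != 1 or outside
#' `{A,C,G,T}`); mitochondrial variants. Each rule's removal count is
#' reported; retained + removed always equals the input count.
#'
#' @param records Variant table.
#' @return `list(records = retained subset, report = filter_report)`.
#' @export
apply_exclusions <- function(records) {
  n0 <- nrow(records)
  removed <- c(downstream = 0L, upstream = 0L, no_sequence_alteration = 0L,
               no_consequence = 0L, misclassified_snv = 0L, mitochondrial = 0L)
  drop_rule <- function(flag, rule) {
    flag[is.na(flag)] <- FALSE
    removed[[rule]] <<- sum(flag)
    records <<- records[!flag, , drop = FALSE]
  }
  drop_rule(records$consequence == "downstream", "downstream")
  drop_rule(records$consequence == "upstream", "upstream")
  drop_rule(records$ref == records$alt, "no_sequence_alteration")
  drop_rule(is.na(records$consequence) | records$consequence %in% c("", "none"),
            "no_consequence")
  drop_rule(nchar(records$ref) != 1 | nchar(records$alt) != 1 |
            !records$ref %in% DNA_BASES | !records$alt %in% DNA_BASES,
            "misclassified_snv")
  drop_rule(records$chrom %in% c("MT", "chrM", "chrMT", "M"), "mitochondrial")
  list(records = records, report = new_filter_report(n0, removed))
}

has_pathogenic_entry <- function(sigs) {
  if (is.na(sigs) || sigs == "") return(NA)
  any(grepl("pathogenic", strsplit(sigs, ";")[[1]], ignore.case = TRUE))
}

#' Keep clinically pathogenic variants
#'
#' A record is kept when its significance string contains the case-insensitive
#' substring `"pathogenic"` (so `"Pathogenic"`, `"Likely pathogenic"`,
#' `"Pathogenic/Likely pathogenic"` are all kept). Records reported as
#' conflicting interpretations of pathogenicity are kept only when at least
#' one per-submitter significance entry is itself pathogenic; conflicting
#' records with no submitter data are dropped (or kept, with
#' `keep_unresolved_conflicts = TRUE`) and counted separately.
#'
#' @param records Variant table.
#' @param keep_unresolved_conflicts Keep conflicting records lacking
#'   per-submitter data? Default `FALSE`.
#' @return `list(records, report)`.
#' @export
filter_pathogenic <- function(records, keep_unresolved_conflicts = FALSE) {
  n0 <- nrow(records)
  sig <- tolower(ifelse(is.na(records$clin_sig), "", records$clin_sig))
  conflicting <- grepl("conflicting interpretations of pathogenicity", sig)
  substr_hit <- grepl("pathogenic", sig)
  sub_path <- vapply(records$submitter_sigs, has_pathogenic_entry, NA)
  keep <- (substr_hit & !conflicting) |
          (conflicting & !is.na(sub_path) & sub_path) |
          (conflicting & is.na(sub_path) & keep_unresolved_conflicts)
  unresolved <- conflicting & is.na(sub_path)
  removed <- c(not_pathogenic = sum(!keep & !unresolved),
               conflicting_unresolved = sum(!keep & unresolved))
  list(records = records[keep, , drop = FALSE],
       report = new_filter_report(n0, removed,
                                  extra = list(conflicting_unresolved_kept =
                                                 sum(keep & unresolved))))
}

#' Attach CDS codon context from a transcript FASTA
#'
#' For coding records, reads the CDS base at `cds_offset` from the matching
#' transcript, verifies it equals the transcript-oriented reference allele,
#' and annotates the containing reading-frame codon (`codon`), the 1-based
#' position of the variant within it (`codon_pos`), the mutant codon
#' (`mut_codon`) and a transcript sequence window of `flank` nt per side
#' (`context_seq`, with the variant at `context_offset`, truncated at
#' transcript ends). Coding records whose stored reference disagrees with the
#' CDS, or whose transcript is absent from the FASTA, are dropped and counted.
#' Non-coding records pass through unchanged.
#'
#' @param records Variant table.
#' @param cds_fasta A named [Biostrings::DNAStringSet] keyed by transcript id,
#'   or the path to a CDS FASTA (ids taken up to the first whitespace).
#' @param flank Context half-width in nt (default 20).
#' @return `list(records, report)`.
#' @export
attach_cds_context <- function(records, cds_fasta, flank = 20) {
  if (is.character(cds_fasta) && length(cds_fasta) == 1 && file.exists(cds_fasta)) {
    cds_fasta <- Biostrings::readDNAStringSet(cds_fasta)
  }
  nm <- names(cds_fasta)
  seqs <- as.character(cds_fasta)  # strips attributes, including names
  names(seqs) <- sub("\\s.*$", "", nm)
  records <- transcript_alleles(records)
  n0 <- nrow(records)
  records$codon <- NA_character_
  records$codon_pos <- NA_integer_
  records$mut_codon <- NA_character_
  records$context_seq <- if ("context_seq" %in% names(records))
    records$context_seq else NA_character_
  records$context_offset <- if ("context_offset" %in% names(records))
    records$context_offset else NA_integer_
  coding <- !is.na(records$region) & records$region == "coding"
  drop <- logical(n0)
  n_missing <- 0L; n_mismatch <- 0L
  for (i in which(coding)) {
    tx <- records$transcript_id[i]; off <- records$cds_offset[i]
    if (is.na(tx) || !tx %in% names(seqs) || is.na(off)) {
      drop[i] <- TRUE; n_missing <- n_missing + 1L; next
    }
    cds <- seqs[[tx]]
    if (off < 1 || off > nchar(cds) ||
        substr(cds, off, off) != records$t_ref[i]) {
      drop[i] <- TRUE; n_mismatch <- n_mismatch + 1L; next
    }
    cstart <- ((off - 1L) %/% 3L) * 3L + 1L
    codon <- substr(cds, cstart, cstart + 2L)
    cpos <- (off - 1L) %% 3L + 1L
    mut <- codon
    substr(mut, cpos, cpos) <- records$t_alt[i]
    records$codon[i] <- codon
    records$codon_pos[i] <- cpos
    records$mut_codon[i] <- mut
    lo <- max(1L, off - as.integer(flank))
    hi <- min(nchar(cds), off + as.integer(flank))
    records$context_seq[i] <- substr(cds, lo, hi)
    records$context_offset[i] <- off - lo + 1L
  }
  list(records = records[!drop, , drop = FALSE],
       report = new_filter_report(n0, c(transcript_missing = n_missing,
                                        cds_mismatch = n_mismatch)))
}
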