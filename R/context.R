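#' Sequence-context analysis around a target base
#'
#' Per-variant context checks used when designing a base editor: the ADAR
#' 5' neighbour motif (ADAR disfavours a G immediately 5' of the edited A),
#' NGG PAM discovery at the distances compatible with the Cas9 editing
#' window, enumeration of bystander-editable bases, and annotation of
#' bystander edits with pathogenicity predictions from a pluggable table.
#'
#' All indices are 1-based. The "distance" between a target base and a PAM is
#' the number of nucleotides strictly between the target and the nearest base
#' of the PAM trinucleotide; the editing window is the run of protospacer
#' positions at distances `pam_distance_range` from the PAM, which by
#' construction contains every accepted target.
#'
#' @name context
NULL

#' ADAR 5'-neighbour motif check
#'
#' Inspects the base immediately 5' of the edited A. The motif is satisfied
#' when that base is present and is not a G.
#'
#' @param seq Transcript-sense DNA sequence (character scalar).
#' @param target_index 1-based index of the edited A within `seq`.
#' @return List with `five_prime_base` (`NA` at the 5' boundary), `motif_ok`
#'   and `boundary` (TRUE when there is no 5' neighbour, in which case
#'   `motif_ok` is FALSE and the result is flagged).
#' @export
adar_motif <- function(seq, target_index) {
  assert_dna(seq)
  if (target_index < 1 || target_index > nchar(seq)) be_stop("target_index out of range")
  if (target_index == 1) {
    return(list(five_prime_base = NA_character_, motif_ok = FALSE, boundary = TRUE))
  }
  b <- substr(seq, target_index - 1, target_index - 1)
  list(five_prime_base = b, motif_ok = b != "G", boundary = FALSE)
}

# all match start positions of an IUPAC-ish motif (only N supported) in seq
motif_starts <- function(seq, motif) {
  pat <- gsub("N", "[ACGT]", motif)
  m <- gregexpr(sprintf("(?=%s)", pat), seq, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Find NGG PAM sites serviceable for a target base
#'
#' Scans both orientations of `seq` for the PAM motif and keeps occurrences
#' whose distance from the target base (see Details of [context]) falls in
#' `distance_range`. On the plus orientation the PAM lies 3' of the target
#' (`distance = pam_start - target_index - 1`); on the minus orientation the
#' motif appears as its reverse complement 5' of the target. Each hit carries
#' its editing window: the protospacer positions at distances
#' `distance_range[1]..distance_range[2]` from the PAM, which always contains
#' the target.
#'
#' @param seq DNA sequence (character scalar).
#' @param target_index 1-based index of the target base.
#' @param pam PAM motif, default `"NGG"` (`N` matches any base).
#' @param distance_range Inclusive distance bounds, default `c(12, 16)`.
#' @return data.frame with columns `strand` (`"+"`/`"-"` relative to `seq`),
#'   `pam_start` (1-based index of the first PAM base as laid out on `seq`),
#'   `distance`, `window_start`, `window_end` (1-based inclusive, clipped to
#'   the sequence). Zero rows when no PAM qualifies.
#' @export
find_ngg_pams <- function(seq, target_index, pam = "NGG",
                          distance_range = c(12L, 16L)) {
  assert_dna(seq)
  if (target_index < 1 || target_index > nchar(seq)) be_stop("target_index out of range")
  dmin <- as.integer(distance_range[1]); dmax <- as.integer(distance_range[2])
  if (dmin > dmax || dmin < 0) be_stop("invalid distance_range")
  w <- nchar(pam)
  hits <- list()
  # plus orientation: PAM 3' of target; nearest PAM base is its first
  for (p in motif_starts(seq, pam)) {
    d <- p - target_index - 1L
    if (d >= dmin && d <= dmax) {
      hits[[length(hits) + 1L]] <- data.frame(
        strand = "+", pam_start = p, distance = d,
        window_start = max(1L, p - dmax - 1L),
        window_end = min(nchar(seq), p - dmin - 1L),
        stringsAsFactors = FALSE)
    }
  }
  # minus orientation: motif on the reverse strand appears as its reverse
  # complement on seq, 5' of the target; nearest PAM base is its last
  rc <- paste(rev(strsplit(chartr("ACGTN", "TGCAN", pam), "")[[1]]), collapse = "")
  for (q in motif_starts(seq, rc)) {
    d <- target_index - (q + w - 1L) - 1L
    if (d >= dmin && d <= dmax) {
      hits[[length(hits) + 1L]] <- data.frame(
        strand = "-", pam_start = q, distance = d,
        window_start = max(1L, q + w - 1L + dmin + 1L),
        window_end = min(nchar(seq), q + w - 1L + dmax + 1L),
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(strand = character(0), pam_start = integer(0),
                      distance = integer(0), window_start = integer(0),
                      window_end = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$pam_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bystander-editable bases around an RNA target
#'
#' Counts occurrences of the editable base (A for A-to-I targets, C for
#' C-to-U) within `flank` positions either side of the target, excluding the
#' target itself. The window is truncated at sequence ends.
#'
#' @param seq DNA sequence.
#' @param target_index 1-based target position.
#' @param editable_base `"A"` or `"C"`.
#' @param flank Half-window in nt, default 10.
#' @return List with `editable_base`, `positions` (1-based indices) and
#'   `n_bystanders`.
#' @export
count_bystanders_rna <- function(seq, target_index, editable_base, flank = 10) {
  assert_dna(seq)
  if (!editable_base %in% c("A", "C")) be_stop("editable_base must be A or C")
  lo <- max(1L, target_index - as.integer(flank))
  hi <- min(nchar(seq), target_index + as.integer(flank))
  idx <- setdiff(seq.int(lo, hi), target_index)
  bases <- strsplit(substr(seq, lo, hi), "")[[1]]
  pos <- idx[bases[idx - lo + 1L] == editable_base]
  list(editable_base = editable_base, positions = pos, n_bystanders = length(pos))
}

#' Bystander-editable bases inside a PAM editing window
#'
#' Counts the editable base within the editing window of a PAM hit from
#' [find_ngg_pams()] on the same sequence, excluding the target itself.
#'
#' @param seq DNA sequence.
#' @param target_index 1-based target position.
#' @param hit One row of a [find_ngg_pams()] result.
#' @param editable_base `"A"` or `"C"`.
#' @return As [count_bystanders_rna()].
#' @export
count_bystanders_dna <- function(seq, target_index, hit, editable_base) {
  assert_dna(seq)
  if (!editable_base %in% c("A", "C")) be_stop("editable_base must be A or C")
  ws <- hit$window_start[1]; we <- hit$window_end[1]
  if (ws < 1 || we > nchar(seq)) be_stop("editing window outside sequence bounds")
  idx <- setdiff(seq.int(ws, we), target_index)
  bases <- strsplit(substr(seq, ws, we), "")[[1]]
  pos <- idx[bases[idx - ws + 1L] == editable_base]
  list(editable_base = editable_base, positions = pos, n_bystanders = length(pos))
}

#' Read a per-site pathogenicity predictor table
#'
#' TSV with columns `transcript_id`, `cds_offset`, `ref`, `alt`, `score`
#' (in `[0,1]`) and `class` (`likely_benign`, `ambiguous`,
#' `likely_pathogenic`), as published by proteome-wide missense predictors.
#'
#' @param path TSV path.
#' @return data.frame keyed by (transcript_id, cds_offset, alt).
#' @export
read_predictor_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "cds_offset", "alt", "score", "class")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) be_stop(paste("predictor table missing:", paste(miss, collapse = ", ")))
  if (any(df$score < 0 | df$score > 1, na.rm = TRUE)) be_stop("predictor scores must be in [0,1]")
  key <- paste(df$transcript_id, df$cds_offset, df$alt, sep = ":")
  if (anyDuplicated(key)) be_stop("duplicate predictor-table keys")
  df$key <- key
  df
}

#' Annotate bystander edits with predicted pathogenicity
#'
#' For each bystander position the implied edit is the deaminase conversion of
#' that base (A>G or C>T); the predictor table is consulted at
#' (transcript_id, cds_offset of the bystander, implied alt). Positions absent
#' from the table count as not pathogenic (the number of misses is returned,
#' since missense-only predictors do not cover every change).
#'
#' @param report Result of [count_bystanders_rna()]/[count_bystanders_dna()],
#'   with positions expressed in the same coordinate system as `target_index`.
#' @param transcript_id,cds_offset Transcript and CDS coordinate of the
#'   *target* variant; bystander CDS offsets are derived by position offset.
#' @param target_index Target position in the sequence the report was
#'   computed on.
#' @param table Predictor table from [read_predictor_table()].
#' @return The report extended with `n_predicted_pathogenic` and `n_missing`.
#' @export
annotate_bystander_pathogenicity <- function(report, transcript_id, cds_offset,
                                             target_index, table) {
  if (report$n_bystanders == 0) {
    report$n_predicted_pathogenic <- 0L
    report$n_missing <- 0L
    return(report)
  }
  alt <- if (report$editable_base == "A") "G" else "T"
  offs <- cds_offset + (report$positions - target_index)
  keys <- paste(transcript_id, offs, alt, sep = ":")
  idx <- match(keys, table$key)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    message(sprintf("%d bystander edit(s) absent from predictor table; counted as not pathogenic",
                    n_missing))
  }
  cls <- table$class[idx[!is.na(idx)]]
  report$n_predicted_pathogenic <- sum(cls == "likely_pathogenic")
  report$n_missing <- n_missing
  report
}
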