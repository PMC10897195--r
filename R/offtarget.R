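#' Off-target search for guide-adhesion sequences
#'
#' The guide RNA of an RNA base editor adheres to the sequence surrounding
#' the variant, so transcriptomic regions highly similar to that neighbourhood
#' are candidate off-target sites. The query is the variant's flanking
#' sequence carrying the *mutant* allele (the guide is designed against the
#' patient sequence); it is aligned locally against every subject sequence
#' and its reverse complement, and the best alignment per subject/orientation
#' is reported as a hit when it reaches both thresholds: identity >= 0.85
#' and alignment length >= 20 columns. Identity is matches divided by
#' alignment columns (gap columns included). Alignment scoring: match +1,
#' mismatch -1, linear gap penalty -2 per gap column.
#'
#' The search is *seeded*, like the word-based aligners used for this kind of
#' scan: a reported alignment must contain at least `min_seed_words`
#' non-overlapping perfect runs of `seed_word` nt (defaults 2 x 11, the
#' classic tile size and tile count). Alignments without such seeds cannot be
#' found by a word-indexed aligner, and admitting them would flood the census
#' with short spurious matches that arise between random sequences at these
#' identity/length thresholds. Set `seed_word = 0` to disable.
#'
#' The alignment covering the query's own source locus is flagged `is_self`
#' and excluded from off-target counts.
#'
#' @name offtarget
NULL

#' Build the guide-adhesion query around a variant
#'
#' A window of `flank` nt either side of the variant plus the variant base
#' itself (41 nt at the default flank of 20), truncated at transcript ends,
#' with the mutant allele substituted at the target position.
#'
#' @param record One-row variant table with codon context (needs
#'   `transcript_id`, `cds_offset`, `t_alt`).
#' @param transcript_seq CDS/transcript sequence of the record's transcript.
#' @param flank Half-width in nt, default 20.
#' @return List with `seq`, `target_offset` (1-based index of the variant in
#'   `seq`), `source` (`transcript_id`, `start`, `end`, `cds_offset`) and
#'   `truncated` flag.
#' @export
build_query <- function(record, transcript_seq, flank = 20) {
  assert_dna(transcript_seq, "transcript")
  record <- transcript_alleles(record)
  off <- record$cds_offset[1]
  L <- nchar(transcript_seq)
  if (is.na(off) || off < 1 || off > L) be_stop("variant not located on transcript")
  lo <- max(1L, off - as.integer(flank))
  hi <- min(L, off + as.integer(flank))
  q <- substr(transcript_seq, lo, hi)
  toff <- off - lo + 1L
  substr(q, toff, toff) <- record$t_alt[1]
  list(seq = q, target_offset = toff,
       source = list(transcript_id = record$transcript_id[1],
                     start = lo, end = hi, cds_offset = off),
       truncated = (hi - lo + 1L) < (2L * flank + 1L))
}

sw_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                         baseOnly = TRUE)
    }
    cache
  }
})

# number of non-overlapping perfect seed words in an alignment, from the
# gapped pattern/subject strings of the optimal local alignment
count_seed_words <- function(pat, sub, word) {
  pc <- strsplit(pat, "")[[1]]; sc <- strsplit(sub, "")[[1]]
  if (length(pc) == 0) return(0L)
  eq <- pc == sc & pc != "-" & sc != "-"
  r <- rle(eq)
  sum(r$lengths[r$values] %/% word)
}

# best local alignment of one query against a DNAStringSet (data.frame of
# per-subject score/identity/coords in the orientation supplied)
best_local <- function(query, subjects, word) {
  pat <- Biostrings::DNAStringSet(rep(query, length(subjects)))
  aln <- Biostrings::pairwiseAlignment(pat, subjects,
                                       substitutionMatrix = sw_submat(),
                                       gapOpening = 0, gapExtension = 2,
                                       type = "local")
  pa <- as.character(Biostrings::pattern(aln))
  sa <- as.character(Biostrings::subject(aln))
  data.frame(score = Biostrings::score(aln),
             nmatch = Biostrings::nmatch(aln),
             aln_len = nchar(pa),
             start = BiocGenerics::start(Biostrings::subject(aln)),
             end = BiocGenerics::end(Biostrings::subject(aln)),
             seed_words = mapply(count_seed_words, pa, sa,
                                 MoreArgs = list(word = max(1L, word)),
                                 USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

# k-mer index over both strands of a subject set: kmer -> integer vector of
# subject indices (positive = plus strand, negative = minus), with multiplicity
build_seed_index <- function(subjects, word) {
  strands <- list(`1` = as.character(subjects),
                  `-1` = as.character(Biostrings::reverseComplement(subjects)))
  kmer <- character(0); owner <- integer(0)
  for (sgn in c(1L, -1L)) {
    ss <- strands[[as.character(sgn)]]
    for (j in seq_along(ss)) {
      L <- nchar(ss[j])
      if (L < word) next
      km <- substring(ss[j], 1:(L - word + 1L), word:L)
      kmer <- c(kmer, km)
      owner <- c(owner, rep(sgn * j, length(km)))
    }
  }
  structure(split(owner, kmer), word = word)
}

# subject indices sharing >= min_words seed-word occurrences with the query
# on the given strand (necessary condition for the post-alignment seed rule;
# speed only)
seeded_subjects <- function(query, n_subjects, word, min_words, index,
                            strand = 1L) {
  n <- nchar(query)
  if (word == 0 || n < word) return(seq_len(n_subjects))
  kmers <- unique(substring(query, 1:(n - word + 1L), word:n))
  own <- unlist(index[kmers], use.names = FALSE)
  if (is.null(own)) own <- integer(0)
  own <- own[sign(own) == strand]
  tab <- tabulate(abs(own), nbins = n_subjects)
  which(tab >= min_words)
}

#' Search subject sequences for off-target-capable regions
#'
#' See [offtarget] for the alignment model, seed rule and hit definition.
#'
#' @param query Result of [build_query()] (or a list with `seq` and optional
#'   `source`).
#' @param subjects Named character vector or [Biostrings::DNAStringSet].
#' @param min_identity Identity threshold, default 0.85.
#' @param min_len Alignment-length threshold in columns, default 20.
#' @param seed_word Seed word size, default 11; 0 disables seeding.
#' @param min_seed_words Minimum non-overlapping seed words per hit, default 2.
#' @param seed_index Optional precomputed subject k-mer index (built
#'   internally by [offtarget_census()]; speed only).
#' @return data.frame of hits: `subject_id`, `strand`, `start`, `end`
#'   (1-based inclusive, plus-strand subject coordinates), `identity`,
#'   `aln_len`, `score`, `is_self`; ordered by (subject_id, start).
#' @export
search_offtargets <- function(query, subjects, min_identity = 0.85, min_len = 20,
                              seed_word = 11, min_seed_words = 2,
                              seed_index = NULL) {
  if (length(subjects) == 0) be_stop("subjects must be nonempty")
  if (is.character(subjects)) subjects <- Biostrings::DNAStringSet(subjects)
  if (is.null(names(subjects))) names(subjects) <- sprintf("SUBJ%04d", seq_along(subjects))
  seed_word <- as.integer(seed_word)
  use_seed <- seed_word > 0 && nchar(query$seq) >= seed_word
  if (use_seed && is.null(seed_index)) {
    seed_index <- build_seed_index(subjects, seed_word)
  }
  L <- Biostrings::width(subjects)
  rows <- list()
  scan <- function(subj, strand) {
    keep <- if (use_seed) {
      seeded_subjects(query$seq, length(subj), seed_word, min_seed_words,
                      index = seed_index, strand = if (strand == "+") 1L else -1L)
    } else seq_along(subj)
    if (length(keep) == 0) return()
    df <- best_local(query$seq, subj[keep], seed_word)
    df$subject_id <- names(subjects)[keep]
    df$strand <- strand
    if (strand == "-") { # map reverse-complement coords back to plus strand
      s <- L[keep] - df$end + 1L; e <- L[keep] - df$start + 1L
      df$start <- s; df$end <- e
    }
    df$identity <- ifelse(df$aln_len > 0, df$nmatch / df$aln_len, 0)
    rows[[length(rows) + 1L]] <<- df
  }
  scan(subjects, "+")
  scan(Biostrings::reverseComplement(subjects), "-")
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(score = numeric(0), nmatch = integer(0), aln_len = integer(0),
               start = integer(0), end = integer(0), seed_words = integer(0),
               subject_id = character(0), strand = character(0),
               identity = numeric(0), stringsAsFactors = FALSE)
  ok <- out$aln_len >= min_len & out$identity >= min_identity
  if (use_seed) ok <- ok & out$seed_words >= min_seed_words
  out <- out[ok, , drop = FALSE]
  src <- query$source
  out$is_self <- logical(nrow(out))
  if (!is.null(src) && nrow(out) > 0) {
    out$is_self <- out$subject_id == src$transcript_id &
      out$start <= src$end & out$end >= src$start
  }
  out <- out[order(out$subject_id, out$start, out$strand),
             c("subject_id", "strand", "start", "end", "identity",
               "aln_len", "score", "is_self"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-variant off-target census
#'
#' Builds the guide-adhesion query for each record and counts non-self hits
#' against the subject set.
#'
#' @param records Variant table with CDS context (coding records with
#'   `transcript_id` and `cds_offset`).
#' @param subjects Transcript set: named character vector or DNAStringSet.
#'   Queries are built from the subject carrying each record's transcript.
#' @param flank,min_identity,min_len,seed_word,min_seed_words See
#'   [build_query()] and [search_offtargets()].
#' @return data.frame with `variant_id`, `n_offtargets`; the fraction of
#'   records with zero hits is attached as attribute `"zero_hit_fraction"`.
#' @export
offtarget_census <- function(records, subjects, flank = 20,
                             min_identity = 0.85, min_len = 20,
                             seed_word = 11, min_seed_words = 2) {
  if (is.character(subjects)) subjects <- Biostrings::DNAStringSet(subjects)
  seqs <- as.character(subjects)
  records <- transcript_alleles(records)
  n <- nrow(records)
  counts <- integer(n)
  index <- if (seed_word > 0) build_seed_index(subjects, as.integer(seed_word)) else NULL
  for (i in seq_len(n)) {
    tx <- records$transcript_id[i]
    if (is.na(tx) || !tx %in% names(seqs)) be_stop(paste("transcript missing for", records$variant_id[i]))
    q <- build_query(records[i, , drop = FALSE], seqs[[tx]], flank = flank)
    hits <- search_offtargets(q, subjects, min_identity = min_identity,
                              min_len = min_len, seed_word = seed_word,
                              min_seed_words = min_seed_words,
                              seed_index = index)
    counts[i] <- sum(!hits$is_self)
  }
  out <- data.frame(variant_id = records$variant_id, n_offtargets = counts,
                    stringsAsFactors = FALSE)
  attr(out, "zero_hit_fraction") <- if (n > 0) mean(counts == 0) else NA_real_
  out
}
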