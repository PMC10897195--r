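#' Genetic-code and codon-editing primitives
#'
#' Codon-level building blocks used throughout the package: translation under
#' the standard genetic code, reverse complementation, and enumeration of the
#' codon variants reachable by deaminase base editing. Deaminases support
#' exactly two chemistries: adenine deamination reads as an A>G change and
#' cytosine deamination as a C>T change (U is represented as T; all sequences
#' are handled in the DNA alphabet on the transcript sense strand).
#'
#' @name seqcore
NULL

#' One-letter amino-acid alphabet
#'
#' The 20 standard amino acids plus `"*"` for the translation stop.
#' @return Character vector of length 21.
#' @export
amino_acids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
    "M", "F", "P", "S", "T", "W", "Y", "V", "*")
}

#' All 64 codons in lexicographic ACGT order
#' @return Character vector of length 64.
#' @export
all_codons <- function() {
  g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3))
}

#' The two deaminase chemistries
#'
#' @return `c("A>G", "C>T")` — the only base conversions a deaminase-based
#'   editor can perform.
#' @export
edit_chemistries <- function() c("A>G", "C>T")

check_chemistries <- function(chemistries) {
  if (length(chemistries) == 0) be_stop("chemistries must be nonempty")
  bad <- setdiff(chemistries, edit_chemistries())
  if (length(bad) > 0) {
    be_stop(paste0("unsupported chemistry: ", paste(bad, collapse = ", "),
                   " (deaminases can only perform A>G and C>T)"))
  }
  unique(chemistries)
}

#' Translate codons under the standard genetic code
#'
#' @param codon Character vector of 3-letter codons over `{A,C,G,T}`.
#' @return Character vector of one-letter amino acids; the three stop codons
#'   `TAA`, `TAG`, `TGA` translate to `"*"`.
#' @examples
#' translate_codon(c("GGG", "TGA", "TGG"))  # "G" "*" "W"
#' @export
translate_codon <- function(codon) {
  if (any(nchar(codon) != 3)) be_stop("codons must have exactly 3 bases")
  assert_dna(codon, "codon")
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Reverse complement of DNA sequences
#'
#' Thin wrapper around [Biostrings::reverseComplement()] restricted to the
#' strict `{A,C,G,T}` alphabet used in this package.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of the Watson-Crick reverse complements.
#' @export
revcomp <- function(seq) {
  assert_dna(seq, "sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Enumerate codon variants reachable by base editing
#'
#' Lists every nonempty subset of editable positions of a codon (positions
#' holding `A` when the A>G chemistry is allowed, `C` under C>T) together
#' with the novel codon obtained by applying those edits simultaneously.
#' With `k` editable positions the result has `2^k - 1` rows.
#'
#' @param codon Single 3-letter codon.
#' @param chemistries Subset of [edit_chemistries()]; nonempty.
#' @return A data.frame with columns `novel` (edited codon), `n_edits`,
#'   `positions` (list column of 1-based codon positions edited) and `ops`
#'   (human-readable edit description, e.g. `"1:A>G+3:C>T"`), ordered by
#'   `n_edits` then lexicographically by `novel`. Zero rows when the codon
#'   has no editable base.
#' @examples
#' enumerate_edits("AAC", "A>G")$novel  # "AGC" "GAC" "GGC"
#' @export
enumerate_edits <- function(codon, chemistries = edit_chemistries()) {
  if (length(codon) != 1 || nchar(codon) != 3) be_stop("codon must be a single 3-base string")
  assert_dna(codon, "codon")
  chemistries <- check_chemistries(chemistries)
  bases <- strsplit(codon, "")[[1]]
  editable <- which((bases == "A" & "A>G" %in% chemistries) |
                    (bases == "C" & "C>T" %in% chemistries))
  empty <- data.frame(novel = character(0), n_edits = integer(0),
                      ops = character(0), stringsAsFactors = FALSE)
  empty$positions <- list()
  if (length(editable) == 0) return(empty)
  rows <- list()
  for (k in seq_along(editable)) {
    # combn(x, k) on a scalar x would enumerate seq_len(x)
    sets <- if (length(editable) == 1) list(editable)
            else utils::combn(editable, k, simplify = FALSE)
    for (s in sets) {
      nb <- bases
      nb[s] <- ifelse(nb[s] == "A", "G", "T")
      rows[[length(rows) + 1L]] <- list(
        novel = paste(nb, collapse = ""),
        n_edits = k,
        positions = s,
        ops = paste(sprintf("%d:%s>%s", s, bases[s], nb[s]), collapse = "+"))
    }
  }
  out <- data.frame(novel = vapply(rows, `[[`, "", "novel"),
                    n_edits = vapply(rows, `[[`, 0L, "n_edits"),
                    ops = vapply(rows, `[[`, "", "ops"),
                    stringsAsFactors = FALSE)
  out$positions <- lapply(rows, `[[`, "positions")
  ord <- order(out$n_edits, out$novel)
  out <- out[ord, c("novel", "n_edits", "positions", "ops")]
  rownames(out) <- NULL
  out
}

#' Amino-acid substitution reachability under base editing
#'
#' For every codon, unions the translations of all codons reachable by
#' [enumerate_edits()] and aggregates per source amino acid. This is the
#' codon-level substitution landscape of a deaminase editor: e.g. under A>G
#' alone a stop codon can only reach tryptophan, and no sense codon can
#' reach a stop.
#'
#' @inheritParams enumerate_edits
#' @param drop_synonymous Drop target amino acids identical to the source
#'   (default `TRUE`).
#' @return Named list mapping each source amino acid (including `"*"`) to the
#'   sorted character vector of reachable amino acids.
#' @export
substitution_map <- function(chemistries = edit_chemistries(),
                             drop_synonymous = TRUE) {
  chemistries <- check_chemistries(chemistries)
  out <- list()
  for (cdn in all_codons()) {
    src <- translate_codon(cdn)
    reach <- enumerate_edits(cdn, chemistries)$novel
    if (length(reach) == 0) next
    aa <- unique(translate_codon(reach))
    if (drop_synonymous) aa <- setdiff(aa, src)
    if (length(aa) == 0) next
    out[[src]] <- sort(unique(c(out[[src]], aa)))
  }
  out
}
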