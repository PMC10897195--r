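# Embedded BLOSUM62 and the stop-codon scoring policy.
#
# BLOSUM62 does not define scores for translation stops, but the improvement
# algorithm must rank candidates for nonsense variants (mutant amino acid =
# stop). The policy used throughout: a pair of stops scores -Inf and a
# stop/amino-acid pair scores a large negative sentinel above it, so escaping
# a premature stop always beats retaining it, while the sentinels stay far
# below every genuine BLOSUM62 value (-4..11) and never mix into comparisons
# among real substitutions.

STOP_STOP_SCORE <- -Inf
STOP_AA_SCORE <- -1000

.blosum_cache <- new.env(parent = emptyenv())

#' The embedded BLOSUM62 substitution matrix
#'
#' Parses the NCBI-format matrix shipped with the package (once per session)
#' and returns its 20x20 core over the standard amino acids. Entries range
#' from -4 to 11; the matrix is symmetric.
#'
#' @return Integer matrix with amino-acid dimnames.
#' @export
blosum62 <- function() {
  if (!is.null(.blosum_cache$m)) return(.blosum_cache$m)
  path <- system.file("extdata", "BLOSUM62.txt", package = "bescope")
  if (path == "") path <- file.path("inst", "extdata", "BLOSUM62.txt")
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  colnames(m) <- sub("^X\\.$", "*", colnames(m))
  rownames(m) <- colnames(m)
  aa20 <- setdiff(amino_acids(), "*")
  m <- m[aa20, aa20]
  storage.mode(m) <- "integer"
  .blosum_cache$m <- m
  m
}

#' Score an amino-acid substitution
#'
#' Symmetric lookup in a substitution matrix, with the package's stop policy:
#' stop/stop pairs score `-Inf` and stop/amino-acid pairs score a sentinel
#' (-1000) above it but below every real matrix value, so any substitution
#' escaping a premature stop ranks above retaining it.
#'
#' @param a,b One-letter amino acids (may include `"*"`); vectorised.
#' @param matrix Substitution matrix, default [blosum62()].
#' @return Numeric score vector.
#' @examples
#' matrix_score("W", "W")  # 11
#' matrix_score("Y", "F")  # 3
#' @export
matrix_score <- function(a, b, matrix = blosum62()) {
  ok <- amino_acids()
  if (!all(a %in% ok) || !all(b %in% ok)) {
    be_stop("unknown amino-acid symbol", class = "bescope_alphabet_error")
  }
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- numeric(n)
  both_stop <- a == "*" & b == "*"
  one_stop <- xor(a == "*", b == "*")
  plain <- !both_stop & !one_stop
  out[both_stop] <- STOP_STOP_SCORE
  out[one_stop] <- STOP_AA_SCORE
  if (any(plain)) out[plain] <- matrix[cbind(a[plain], b[plain])]
  out
}
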