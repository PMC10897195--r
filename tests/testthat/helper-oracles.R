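# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive everything with plain loops and their own
# arithmetic; they never call the functions they check.

# full Smith-Waterman local alignment, match +1 / mismatch -1 / linear gap -2,
# with traceback (diagonal preferred, then gap-in-subject, then gap-in-query)
sw_local_oracle <- function(q, s, match = 1, mismatch = -1, gap = 2) {
  qb <- strsplit(q, "")[[1]]; sb <- strsplit(s, "")[[1]]
  m <- length(qb); n <- length(sb)
  H <- matrix(0, m + 1, n + 1)
  for (i in 1:m) {
    sc <- ifelse(qb[i] == sb, match, mismatch)
    for (j in 1:n) {
      H[i + 1, j + 1] <- max(0, H[i, j] + sc[j], H[i, j + 1] - gap, H[i + 1, j] - gap)
    }
  }
  smax <- max(H)
  if (smax == 0) {
    return(list(score = 0, nmatch = 0L, aln_len = 0L, start = NA, end = NA,
                seed_runs = integer(0)))
  }
  best <- unname(which(H == smax, arr.ind = TRUE)[1, ])
  i <- best[1] - 1L; j <- best[2] - 1L
  pat <- character(0); sub <- character(0)
  while (i > 0 && j > 0 && H[i + 1, j + 1] > 0) {
    sc <- if (qb[i] == sb[j]) match else mismatch
    if (H[i + 1, j + 1] == H[i, j] + sc) {
      pat <- c(qb[i], pat); sub <- c(sb[j], sub); i <- i - 1L; j <- j - 1L
    } else if (H[i + 1, j + 1] == H[i, j + 1] - gap) {
      pat <- c(qb[i], pat); sub <- c("-", sub); i <- i - 1L
    } else {
      pat <- c("-", pat); sub <- c(sb[j], sub); j <- j - 1L
    }
  }
  eq <- pat == sub
  runs <- rle(eq)
  list(score = smax, nmatch = sum(eq), aln_len = length(pat),
       start = j + 1L, end = as.integer(best[2] - 1L),
       seed_runs = runs$lengths[runs$values])
}

# hit decision applied to an oracle alignment (same rule as the package:
# thresholds plus the two-seed-word requirement)
oracle_hit <- function(aln, min_identity = 0.85, min_len = 20,
                       seed_word = 11, min_seed_words = 2) {
  if (aln$aln_len == 0) return(FALSE)
  id <- aln$nmatch / aln$aln_len
  words <- sum(aln$seed_runs %/% seed_word)
  aln$aln_len >= min_len && id >= min_identity && words >= min_seed_words
}

# brute-force NGG PAM scan: every trinucleotide, both orientations, with the
# editing window re-derived position by position from the distance definition
brute_pam_oracle <- function(seq, t, dmin = 12, dmax = 16) {
  n <- nchar(seq)
  hits <- list()
  for (p in seq_len(max(0, n - 2))) {
    if (substr(seq, p + 1, p + 2) == "GG") {      # plus: N at p
      d <- p - t - 1L
      if (d >= dmin && d <= dmax) {
        win <- Filter(function(x) (p - x - 1L) >= dmin && (p - x - 1L) <= dmax, 1:n)
        hits[[length(hits) + 1L]] <- list(strand = "+", pam_start = p, distance = d,
                                          window = range(win))
      }
    }
    if (substr(seq, p, p + 1) == "CC") {          # minus: rc(NGG) = CCN
      d <- t - (p + 2L) - 1L
      if (d >= dmin && d <= dmax) {
        win <- Filter(function(x) (x - (p + 2L) - 1L) >= dmin && (x - (p + 2L) - 1L) <= dmax, 1:n)
        hits[[length(hits) + 1L]] <- list(strand = "-", pam_start = p, distance = d,
                                          window = range(win))
      }
    }
  }
  hits
}

# exhaustive codon-improvement search over all 7 nonempty position subsets,
# with its own chemistry check, translation and tie-breaking
improve_oracle_matrix <- function(ref_codon, mut_codon, b62) {
  code <- Biostrings::GENETIC_CODE
  rb <- strsplit(ref_codon, "")[[1]]; mb <- strsplit(mut_codon, "")[[1]]
  ref_aa <- unname(code[ref_codon]); mut_aa <- unname(code[mut_codon])
  if (ref_aa == "*" || ref_aa == mut_aa || ref_codon == mut_codon) return(NULL)
  baseline <- if (mut_aa == "*") -1000 else b62[ref_aa, mut_aa]
  best <- NULL
  for (mask in 1:7) {
    pos <- which(bitwAnd(mask, c(1L, 2L, 4L)) > 0)
    if (!all(mb[pos] %in% c("A", "C"))) next
    nb <- mb
    nb[pos] <- ifelse(nb[pos] == "A", "G", "T")
    novel <- paste(nb, collapse = "")
    aa <- unname(code[novel])
    if (aa == "*") next
    sc <- b62[ref_aa, aa]
    if (sc <= baseline) next
    cand <- list(novel = novel, aa = aa, score = sc, n_edits = length(pos))
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score && cand$n_edits < best$n_edits) ||
        (cand$score == best$score && cand$n_edits == best$n_edits &&
         cand$novel < best$novel)) {
      best <- cand
    }
  }
  best
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
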