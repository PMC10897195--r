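# internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

#' The 12 ordered mismatch types
#'
#' All ordered `ref>alt` pairs of distinct DNA bases, in a fixed order used
#' by [mismatch_census()] and the synthetic generator.
#'
#' @return Character vector of length 12, e.g. `"G>A"`.
#' @export
mismatch_types <- function() {
  out <- character(0)
  for (r in DNA_BASES) for (a in DNA_BASES) if (r != a) out <- c(out, paste0(r, ">", a))
  out
}

# stop with a consistent error class
be_stop <- function(msg, class = "bescope_error", call. = FALSE) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    be_stop(sprintf("%s contains characters outside {A,C,G,T}: %s",
                    what, paste(utils::head(x[bad], 3), collapse = ", ")),
            class = "bescope_alphabet_error")
  }
  invisible(x)
}

complement_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[b])
}

# per-stage RNG sub-seed: fixed offsets keep named streams independent of the
# order in which generator stages are called; kept < 2^31
derive_seed <- function(seed, stream) {
  offsets <- c(transcriptome = 101L, variants = 211L, contexts = 307L,
               offtarget = 401L, predictor = 503L, mit = 601L,
               frequency = 701L, expression = 811L, submitters = 907L,
               site_scores = 1009L, decoys = 1103L)
  if (!stream %in% names(offsets)) be_stop(paste("unknown RNG stream:", stream))
  (as.integer(seed) %% 1000000L) * 2000L + offsets[[stream]]
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
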