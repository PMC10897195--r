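test_that("ADAR motif inspects the 5' neighbour of the edited A", {
  # premature-stop context ...TGA...: the edited A sits 3' of a G
  seq <- "CCTGACC"
  res <- adar_motif(seq, 5)  # the A of TGA
  expect_identical(res$five_prime_base, "G")
  expect_false(res$motif_ok)
  # a C neighbour satisfies the motif
  expect_true(adar_motif("CCCAACC", 4)$motif_ok)
  # 5' boundary: no neighbour, flagged, motif not satisfied
  b <- adar_motif("ACGT", 1)
  expect_true(b$boundary)
  expect_false(b$motif_ok)
  expect_true(is.na(b$five_prime_base))
  expect_error(adar_motif("ACGT", 9), "out of range")
})

test_that("NGG PAM discovery honours the distance band on both orientations", {
  base <- strsplit(paste(rep("T", 60), collapse = ""), "")[[1]]
  t <- 30L
  plant <- function(pos, bases) {
    s <- base
    s[pos] <- bases
    paste(s, collapse = "")
  }
  # plus orientation: N at 30+14+1, GG after it
  s <- plant(c(45L, 46L, 47L), c("A", "G", "G"))
  hits <- find_ngg_pams(s, t)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$strand, "+")
  expect_identical(hits$distance, 14L)
  expect_true(t >= hits$window_start && t <= hits$window_end)
  expect_identical(hits$window_end - hits$window_start + 1L, 5L)
  # minus orientation: CCN 5' of the target
  s2 <- plant(c(13L, 14L, 15L), c("C", "C", "A"))
  h2 <- find_ngg_pams(s2, t)
  expect_identical(h2$strand, "-")
  expect_identical(h2$distance, 14L)
  expect_true(t >= h2$window_start && t <= h2$window_end)
  # distance 11 is outside the 12-16 band
  s3 <- plant(c(42L, 43L, 44L), c("A", "G", "G"))
  expect_identical(nrow(find_ngg_pams(s3, t)), 0L)
  # nothing in a poly-T sequence
  expect_identical(nrow(find_ngg_pams(paste(base, collapse = ""), t)), 0L)
})

test_that("PAM scan agrees with a brute-force trinucleotide oracle", {
  set.seed(202)
  for (r in 1:300) {
    s <- rand_seq(100)
    t <- sample(5:95, 1)
    got <- find_ngg_pams(s, t)
    want <- brute_pam_oracle(s, t)
    expect_identical(nrow(got), length(want))
    if (length(want) > 0) {
      want <- want[order(vapply(want, `[[`, 0L, "pam_start"),
                         vapply(want, `[[`, "", "strand"))]
      expect_identical(got$pam_start, vapply(want, `[[`, 0L, "pam_start"))
      expect_identical(got$strand, vapply(want, `[[`, "", "strand"))
      expect_identical(got$distance, vapply(want, function(w) as.integer(w$distance), 0L))
      for (k in seq_len(nrow(got))) {
        expect_identical(c(got$window_start[k], got$window_end[k]),
                         as.integer(want[[k]]$window))
        # constructive invariant: the target lies inside every editing window
        expect_true(t >= got$window_start[k] && t <= got$window_end[k])
      }
    }
  }
})

test_that("RNA bystander counts cover a truncated 10-nt flank, excluding the target", {
  s <- "GGGGAAGAGAGGGGGGGGGGG"  # A at 5,6,8,10; target at 6
  r <- count_bystanders_rna(s, 6, "A")
  expect_identical(r$n_bystanders, 3L)
  expect_setequal(r$positions, c(5L, 8L, 10L))
  # near the 5' end the window truncates without error
  r2 <- count_bystanders_rna("AAAAGGGGGGGGGGGGGGG", 3, "A")
  expect_identical(r2$n_bystanders, 3L)
  # all-G window
  expect_identical(count_bystanders_rna("GGGGGGG", 4, "A")$n_bystanders, 0L)
  expect_error(count_bystanders_rna("GGGG", 2, "G"), "must be A or C")
})

test_that("DNA bystander counts are confined to the editing window", {
  # construct a sequence with a PAM at distance 12 and known window content
  s <- paste0(paste(rep("G", 29), collapse = ""), "AATAC",
              paste(rep("T", 10), collapse = ""), "AGG",
              paste(rep("T", 10), collapse = ""))
  t <- 32L  # the T>C-style target inside "AATAC" (the middle T is index 32)
  hits <- find_ngg_pams(s, t)
  expect_true(nrow(hits) >= 1)
  h <- hits[hits$strand == "+", , drop = FALSE][1, , drop = FALSE]
  expect_identical(c(h$window_start, h$window_end), c(28L, 32L))
  r <- count_bystanders_dna(s, t, h, "A")
  expect_identical(r$n_bystanders, 2L)  # the two A's of AATAC
  # consistency with the flank counter restricted to the same 5 positions
  set.seed(77)
  for (k in 1:50) {
    s2 <- rand_seq(80)
    t2 <- 40L
    h2 <- find_ngg_pams(s2, t2)
    if (nrow(h2) == 0) next
    h2 <- h2[1, , drop = FALSE]
    d <- count_bystanders_dna(s2, t2, h2, "A")
    rflank <- count_bystanders_rna(s2, t2, "A", flank = 40)
    expect_identical(sort(d$positions),
                     sort(intersect(rflank$positions, h2$window_start:h2$window_end)))
  }
})

test_that("bystander counts are reverse-complement symmetric", {
  # the A's of a window appear as T's at mirrored indices on the reverse
  # complement: counting A around the mirrored target on revcomp(s) must
  # equal a literal count of T around the target on s, and the mirrored
  # positions must coincide
  set.seed(31)
  for (k in 1:50) {
    s <- rand_seq(41)
    t <- sample(11L:31L, 1)
    rc <- revcomp(s)
    tm <- nchar(s) - t + 1L
    mir <- count_bystanders_rna(rc, tm, "A")
    sb <- strsplit(s, "")[[1]]
    t_near <- setdiff(which(sb == "T"), t)
    t_near <- t_near[abs(t_near - t) <= 10]
    expect_identical(mir$n_bystanders, length(t_near))
    expect_setequal(nchar(s) - mir$positions + 1L, t_near)
  }
})

test_that("bystander pathogenicity annotation counts predictor classes", {
  tab <- data.frame(transcript_id = "TX1", cds_offset = c(8L, 12L, 14L),
                    ref = "A", alt = "G", score = c(0.9, 0.1, 0.2),
                    class = c("likely_pathogenic", "likely_benign", "likely_benign"),
                    stringsAsFactors = FALSE)
  tab$key <- paste(tab$transcript_id, tab$cds_offset, tab$alt, sep = ":")
  rep <- list(editable_base = "A", positions = c(8L, 12L, 14L), n_bystanders = 3L)
  ann <- annotate_bystander_pathogenicity(rep, "TX1", 10L, 10L, tab)
  expect_identical(ann$n_predicted_pathogenic, 1L)
  expect_true(ann$n_predicted_pathogenic <= ann$n_bystanders)
  # missing entries count as not pathogenic, with a message
  empty <- tab[0, ]
  expect_message(ann0 <- annotate_bystander_pathogenicity(rep, "TX1", 10L, 10L, empty),
                 "absent from predictor")
  expect_identical(ann0$n_predicted_pathogenic, 0L)
  expect_identical(ann0$n_missing, 3L)
})

test_that("predictor tables are validated on read", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(transcript_id = "TX1", cds_offset = 1:2, ref = "A", alt = "G",
                   score = c(0.5, 0.6), class = "likely_benign")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  pt <- read_predictor_table(tmp)
  expect_identical(nrow(pt), 2L)
  df$score[1] <- 1.5
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_predictor_table(tmp), "\\[0,1\\]")
})
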