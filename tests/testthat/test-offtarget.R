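mk_query_record <- function(tx_seq, off, alt, tx = "TXQ") {
  as_variant_table(data.frame(chrom = "chr1", pos = off, ref = substr(tx_seq, off, off),
                              alt = alt, region = "coding", consequence = "missense",
                              transcript_id = tx, cds_offset = off,
                              stringsAsFactors = FALSE))
}

test_that("guide-adhesion queries carry the mutant allele and truncate at ends", {
  set.seed(5)
  tx <- rand_seq(200)
  rec <- mk_query_record(tx, 100L, "A")
  q <- build_query(rec, tx)
  expect_identical(nchar(q$seq), 41L)
  expect_identical(q$target_offset, 21L)
  expect_identical(substr(q$seq, 21, 21), "A")  # the mutant base, not the reference
  expect_false(q$truncated)
  # variant close to the transcript start: left flank truncated
  rec2 <- mk_query_record(tx, 6L, "A")
  q2 <- build_query(rec2, tx)
  expect_identical(nchar(q2$seq), 26L)
  expect_identical(q2$target_offset, 6L)
  expect_true(q2$truncated)
  expect_error(build_query(mk_query_record(tx, 100L, "A"), ""), "not located")
})

test_that("planted duplicates are found and threshold cases behave", {
  set.seed(6)
  tx <- rand_seq(300)
  rec <- mk_query_record(tx, 150L, "A")
  q <- build_query(rec, tx)
  # exact copy in another subject: one non-self hit at identity 1
  decoy <- paste0(rand_seq(40), q$seq, rand_seq(40))
  subj <- c(TXQ = tx, OTHER = decoy)
  hits <- search_offtargets(q, subj)
  non_self <- hits[!hits$is_self, ]
  expect_identical(nrow(non_self), 1L)
  expect_identical(non_self$subject_id, "OTHER")
  expect_identical(non_self$identity, 1)
  expect_identical(non_self$aln_len, 41L)
  expect_identical(non_self$start, 41L)
  # the self alignment is flagged and excluded
  expect_true(any(hits$is_self & hits$subject_id == "TXQ"))
  # 7 mismatches over 41 nt: identity 0.829, below the 0.85 threshold
  mm7 <- q$seq
  for (p in c(12L, 24L, 27L, 30L, 33L, 36L, 39L)) {
    substr(mm7, p, p) <- setdiff(c("A", "C", "G", "T"), substr(mm7, p, p))[1]
  }
  subj7 <- c(TXQ = tx, OTHER = paste0(rand_seq(40), mm7, rand_seq(40)))
  h7 <- search_offtargets(q, subj7)
  expect_identical(nrow(h7[!h7$is_self, ]), 0L)
  # the same copy is accepted when the identity threshold is lowered
  h7b <- search_offtargets(q, subj7, min_identity = 0.75)
  expect_identical(nrow(h7b[!h7b$is_self, ]), 1L)
  # reverse-complement symmetry: complementing a subject mirrors coordinates
  rc <- c(TXQ = tx, OTHER = revcomp(subj[["OTHER"]]))
  hrc <- search_offtargets(q, rc)
  nrc <- hrc[!hrc$is_self, ]
  expect_identical(nrow(nrc), 1L)
  expect_identical(nrc$strand, "-")
  expect_identical(nrc$start, nchar(subj[["OTHER"]]) - non_self$end + 1L)
  # a subject set holding only the source transcript yields no off-targets
  only_self <- search_offtargets(q, c(TXQ = tx))
  expect_identical(nrow(only_self[!only_self$is_self, ]), 0L)
})

test_that("hit counts are monotone in the identity and length thresholds", {
  set.seed(8)
  tx <- rand_seq(300)
  q <- build_query(mk_query_record(tx, 150L, "A"), tx)
  mm4 <- q$seq
  for (p in c(12L, 24L, 27L, 30L)) {
    substr(mm4, p, p) <- setdiff(c("A", "C", "G", "T"), substr(mm4, p, p))[1]
  }
  subj <- c(TXQ = tx, D1 = paste0(rand_seq(30), q$seq, rand_seq(30)),
            D2 = paste0(rand_seq(30), mm4, rand_seq(30)))
  prev <- Inf
  for (mi in c(0.75, 0.85, 0.95, 1.0)) {
    n <- sum(!search_offtargets(q, subj, min_identity = mi)$is_self)
    expect_lte(n, prev)
    prev <- n
  }
  prev <- Inf
  for (ml in c(10, 20, 41, 42)) {
    n <- sum(!search_offtargets(q, subj, min_len = ml)$is_self)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("the search agrees with a dynamic-programming local-alignment oracle", {
  set.seed(9)
  n_inst <- 250
  for (r in seq_len(n_inst)) {
    qs <- rand_seq(25)
    subj <- if (r %% 3 == 0) {
      # planted near-duplicate with 0-3 mismatches
      copy <- qs
      nmm <- r %% 4
      for (p in utils::head(c(12L, 24L, 5L), nmm)) {
        substr(copy, p, p) <- setdiff(c("A", "C", "G", "T"), substr(copy, p, p))[1]
      }
      paste0(rand_seq(15), copy, rand_seq(15))
    } else {
      rand_seq(55)
    }
    got <- search_offtargets(list(seq = qs), c(S1 = subj), min_len = 15)
    want <- sw_local_oracle(qs, subj)
    want_hit <- oracle_hit(want, min_len = 15)
    expect_identical(nrow(got) == 1L, want_hit)
    if (nrow(got) == 1L && want_hit) {
      expect_identical(got$score, want$score)
      expect_identical(got$aln_len, want$aln_len)
      expect_identical(c(got$start, got$end), c(want$start, want$end))
      expect_equal(got$identity, want$nmatch / want$aln_len)
    }
  }
})

test_that("the per-variant census recovers planted duplicate counts exactly", {
  co <- small_cohort()
  fc <- filter_cascade(co$raw, co$transcripts)
  calls <- call_editability(fc$records)
  sub <- calls[calls$variant_id %in% co$truth$offtarget_census_ids, ]
  cen <- offtarget_census(sub, co$subjects)
  m <- merge(cen, co$truth$variants[, c("variant_id", "offtarget_planted_hits")],
             by = "variant_id")
  expect_identical(m$n_offtargets, m$offtarget_planted_hits)
  expect_equal(attr(cen, "zero_hit_fraction"), co$truth$zero_offtarget_fraction)
})

test_that("the seed rule suppresses spurious hits between unrelated sequences", {
  set.seed(4242)
  subs <- stats::setNames(vapply(1:40, function(i) rand_seq(600), ""),
                          sprintf("R%02d", 1:40))
  n_hits <- 0L
  for (r in 1:25) {
    q <- list(seq = rand_seq(41))
    n_hits <- n_hits + nrow(search_offtargets(q, subs))
  }
  expect_identical(n_hits, 0L)
})
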