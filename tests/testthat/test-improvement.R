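test_that("worked clinical examples choose the expected novel codons", {
  # Tyr->Ser missense (TAT->TCT): C-to-T editing yields Phe (TTT),
  # improving BLOSUM62 from -2 (Y,S) to 3 (Y,F) with a single edit
  r <- improve_codon("TAT", "TCT", scorer_matrix(), chemistries = "C>T")
  expect_identical(r$novel_codon, "TTT")
  expect_identical(r$novel_aa, "F")
  expect_identical(r$n_edits, 1L)
  expect_identical(r$mut_score, -2)
  expect_identical(r$novel_score, 3)
  # His->Gln missense (CAC->CAA): with site scores Gln 0.05 / Trp 0.25, the
  # combined chemistry rewrites all three bases at once to TGG
  r2 <- improve_codon("CAC", "CAA",
                      scorer_site_table(c(Q = 0.05, W = 0.25, R = 0.0)))
  expect_identical(r2$novel_codon, "TGG")
  expect_identical(r2$n_edits, 3L)
  expect_identical(r2$mode_label, "combined")
  expect_equal(r2$novel_score - r2$mut_score, 0.20)
  # premature stop (Tyr codon TAC mutated to TAG): A-to-G editing escapes
  # the stop to tryptophan
  r3 <- improve_codon("TAC", "TAG", scorer_matrix(), chemistries = "A>G")
  expect_identical(r3$novel_codon, "TGG")
  expect_identical(r3$novel_aa, "W")
  expect_true(r3$novel_score > r3$mut_score)
  # nothing editable in GGG
  expect_null(improve_codon("AAA", "GGG"))
})

test_that("synonymous restoration is allowed but flagged", {
  # Leu (TTA) mutated to Ser (TCA): C-to-T restores the reference codon
  # itself; kept as a protein-level correction
  r <- improve_codon("TTA", "TCA", scorer_matrix())
  expect_identical(r$novel_codon, "TTA")
  expect_true(r$protein_level_correction)
})

test_that("precondition violations are rejected", {
  expect_error(improve_codon("GGG", "GGG"), "equals reference")
  expect_error(improve_codon("CTA", "CTG"), "synonymous")      # both Leu
  expect_error(improve_codon("TAA", "AAA"), "stop-lost")       # reference stop
  rec <- toy_record("G", "A", codon = "GGG", codon_pos = 1)
  expect_error(improve_variant(rec), "revertible")
  rec2 <- toy_record("A", "C", consequence = "synonymous", codon = "GCA", codon_pos = 3)
  expect_error(improve_variant(rec2), "missense and nonsense")
  rec3 <- toy_record("A", "C")  # no codon context attached
  expect_error(improve_variant(rec3), "codon context")
})

test_that("improve_codon matches the exhaustive oracle on all codon pairs", {
  b62 <- blosum62()
  code <- translate_codon(all_codons())
  n_checked <- 0L
  for (ref in all_codons()) {
    if (code[match(ref, all_codons())] == "*") next
    for (mut in all_codons()) {
      if (mut == ref) next
      if (code[match(mut, all_codons())] == code[match(ref, all_codons())]) next
      got <- improve_codon(ref, mut, scorer_matrix())
      want <- improve_oracle_matrix(ref, mut, b62)
      if (is.null(want)) {
        expect_null(got)
      } else {
        expect_identical(got$novel_codon, want$novel)
        expect_identical(got$novel_aa, want$aa)
        expect_identical(got$n_edits, want$n_edits)
        expect_equal(got$novel_score, as.numeric(want$score))
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 3000)
})

test_that("results never worsen the score, never create stops, and respect chemistry", {
  for (ref in c("TAT", "CAC", "AAA", "TGG", "GCT")) {
    for (mut in all_codons()) {
      ra <- translate_codon(ref); ma <- translate_codon(mut)
      if (mut == ref || ra == ma || ra == "*") next
      r <- improve_codon(ref, mut)
      if (is.null(r)) next
      expect_gt(r$novel_score, r$mut_score)
      expect_false(r$novel_aa == "*")
      expect_true(r$novel_codon != mut)
      expect_true(r$n_edits %in% 1:3)
      # every edit converts a matching base with a legal chemistry
      mb <- strsplit(mut, "")[[1]]; nb <- strsplit(r$novel_codon, "")[[1]]
      ch <- which(mb != nb)
      expect_identical(length(ch), as.integer(r$n_edits))
      expect_true(all((mb[ch] == "A" & nb[ch] == "G") |
                      (mb[ch] == "C" & nb[ch] == "T")))
      expect_true(r$mode_label %in% c("A_only", "C_only", "combined"))
      if (r$mode_label == "combined") {
        expect_true(any(mb[ch] == "A") && any(mb[ch] == "C"))
      }
    }
  }
})

test_that("site-table mode applies the tolerance floor", {
  # candidate above the mutant score but at the floor is discarded
  r <- improve_codon("CAC", "CAA",
                     scorer_site_table(c(Q = 0.02, W = 0.05, R = 0.04)))
  expect_null(r)
  expect_error(scorer_site_table(c(Q = 1.2)), "\\[0,1\\]")
  expect_error(scorer_site_table(c(Q = 0.5), tolerance_floor = 1), "tolerance_floor")
})

test_that("score-gain summaries aggregate per mode and reject mixed scorers", {
  res <- data.frame(variant_id = c("a", "b"), score_delta = c(0.1, 0.3),
                    mode_label = c("A_only", "A_only"),
                    scorer_kind = "site_table", stringsAsFactors = FALSE)
  s <- score_delta_distribution(res)
  expect_equal(s$mean_delta, 0.2)
  expect_identical(unname(s$mode_counts["A_only"]), 2L)
  empty <- score_delta_distribution(res[0, ])
  expect_identical(empty$n, 0L)
  res$scorer_kind <- c("matrix", "site_table")
  expect_error(score_delta_distribution(res), "mixed scorer")
})

test_that("planted site-score improvements are recovered exactly", {
  co <- small_cohort()
  fc <- filter_cascade(co$raw, co$transcripts)
  calls <- call_editability(fc$records)
  imps <- improve_cohort(calls, scorer = "site_table",
                         site_table = co$tables$site_scores)
  s <- score_delta_distribution(imps)
  expect_equal(s$mean_delta, co$truth$tables$site_mean_delta)
  m <- merge(imps, co$truth$tables$site, by = "variant_id")
  expect_identical(nrow(m), nrow(co$truth$tables$site))
  expect_identical(m$novel_aa.x, m$novel_aa.y)
  expect_equal(m$score_delta, m$delta)
})
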