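test_that("tabular parsing handles the TSV and BED dialects", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(chrom = c("chr1", "chr2", "chr3"), pos = c(100, 200, 300),
                   ref = c("G", "AT", "C"), alt = c("A", "A", "T"),
                   clin_sig = "Pathogenic")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_variant_table(tmp, "tsv")
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$pos, c(100L, 200L, 300L))
  # the deletion row is retained here and counted by the exclusion cascade
  ex <- apply_exclusions(as_variant_table(transform(rec, consequence = "missense")))
  expect_identical(unname(ex$report$removed[["misclassified_snv"]]), 1L)

  bed <- withr::local_tempfile(fileext = ".bed")
  write.table(data.frame(chrom = "chr1", chromStart = 99, chromEnd = 100,
                         ref = "G", alt = "A"),
              bed, sep = "\t", quote = FALSE, row.names = FALSE)
  rb <- read_variant_table(bed, "bed")
  expect_identical(rb$pos, 100L)  # 0-based half-open converted to 1-based

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom\tpos\tref\talt", empty)
  expect_warning(re <- read_variant_table(empty, "tsv"), "empty")
  expect_identical(nrow(re), 0L)
})

test_that("ClinVar-style VCF round-trips through the writer and vcfR", {
  rec <- as_variant_table(data.frame(
    chrom = c("chr1", "chr7", "chrX"), pos = c(101L, 202L, 303L),
    ref = c("G", "C", "T"), alt = c("A", "T", "C"),
    gene = c("FGFR3", "CFTR", NA),
    clin_sig = c("Pathogenic", "Conflicting interpretations of pathogenicity", "Benign"),
    submitter_sigs = c(NA, "Pathogenic;Benign", NA),
    consequence = c("missense", "nonsense", "synonymous"),
    stringsAsFactors = FALSE))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_clinvar_vcf(rec, vcf)
  back <- read_variant_table(vcf, "vcf")
  expect_identical(back$chrom, rec$chrom)
  expect_identical(back$pos, rec$pos)
  expect_identical(paste0(back$ref, ">", back$alt), paste0(rec$ref, ">", rec$alt))
  expect_identical(back$clin_sig, rec$clin_sig)
  expect_identical(back$submitter_sigs[2], "Pathogenic;Benign")
  expect_identical(back$consequence, rec$consequence)
  expect_identical(back$gene[1:2], rec$gene[1:2])
})

test_that("pathogenicity filtering follows the substring and submitter rules", {
  rec <- as_variant_table(data.frame(
    chrom = "chr1", pos = 1:6, ref = "G", alt = "A",
    clin_sig = c("Pathogenic", "Likely pathogenic", "Benign",
                 "Conflicting interpretations of pathogenicity",
                 "Conflicting interpretations of pathogenicity",
                 "Conflicting interpretations of pathogenicity"),
    submitter_sigs = c(NA, NA, NA, "Benign;Pathogenic", "Benign;Likely benign", NA),
    stringsAsFactors = FALSE))
  fp <- filter_pathogenic(rec)
  expect_identical(fp$records$pos, c(1L, 2L, 4L))
  expect_identical(unname(fp$report$removed[["not_pathogenic"]]), 2L)
  expect_identical(unname(fp$report$removed[["conflicting_unresolved"]]), 1L)
  # unresolved conflicting records can be kept by configuration
  fp2 <- filter_pathogenic(rec, keep_unresolved_conflicts = TRUE)
  expect_identical(fp2$records$pos, c(1L, 2L, 4L, 6L))
  # "Pathogenic/Likely pathogenic" matches the substring rule
  one <- as_variant_table(data.frame(chrom = "chr1", pos = 9L, ref = "G", alt = "A",
                                     clin_sig = "Pathogenic/Likely pathogenic"))
  expect_identical(nrow(filter_pathogenic(one)$records), 1L)
})

test_that("the exclusion cascade removes one row per rule and conserves counts", {
  rec <- as_variant_table(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chrM", "chr2"),
    pos = 1:7,
    ref = c("G", "G", "A", "G", "AT", "G", "G"),
    alt = c("A", "A", "A", "A", "A", "A", "A"),
    consequence = c("downstream", "upstream", "missense", "none",
                    "missense", "missense", "missense"),
    stringsAsFactors = FALSE))
  ex <- apply_exclusions(rec)
  expect_identical(nrow(ex$records), 1L)
  expect_true(all(ex$report$removed[c("downstream", "upstream",
                                      "no_sequence_alteration", "no_consequence",
                                      "misclassified_snv", "mitochondrial")] == 1L))
  expect_identical(ex$report$n_input,
                   ex$report$n_retained + sum(ex$report$removed))
  # idempotence: re-filtering removes nothing
  ex2 <- apply_exclusions(ex$records)
  expect_identical(sum(ex2$report$removed), 0L)
  expect_identical(ex2$records$variant_id, ex$records$variant_id)
})

test_that("CDS context annotation reads the frame and drops mismatches", {
  fa <- c(TX1 = "ATGGGGTAA")
  mk <- function(off, ref = substr(fa[[1]], off, off), alt = "A") {
    as_variant_table(data.frame(chrom = "chr1", pos = off, ref = ref, alt = alt,
                                region = "coding", consequence = "missense",
                                transcript_id = "TX1", cds_offset = off,
                                stringsAsFactors = FALSE))
  }
  an <- attach_cds_context(mk(5), fa)
  expect_identical(an$records$codon, "GGG")
  expect_identical(an$records$codon_pos, 2L)        # second base of its codon
  expect_identical(an$records$mut_codon, "GAG")
  # boundary: first base, 5' window truncated
  an1 <- attach_cds_context(mk(1, alt = "G"), fa)
  expect_identical(an1$records$codon, "ATG")
  expect_identical(an1$records$codon_pos, 1L)
  expect_identical(an1$records$context_offset, 1L)
  expect_identical(an1$records$context_seq, fa[[1]])  # 9 nt, right-truncated
  # stored ref disagreeing with the CDS is dropped and counted
  bad <- mk(5, ref = "C")
  anb <- attach_cds_context(bad, fa)
  expect_identical(nrow(anb$records), 0L)
  expect_identical(unname(anb$report$removed[["cds_mismatch"]]), 1L)
  # missing transcript is dropped and counted separately
  mi <- mk(5); mi$transcript_id <- "NOPE"
  anm <- attach_cds_context(mi, fa)
  expect_identical(unname(anm$report$removed[["transcript_missing"]]), 1L)
})

test_that("variant tables round-trip through the internal TSV dialect", {
  co <- small_cohort()
  rec <- utils::head(co$raw, 50)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(rec, tmp)
  back <- read_variant_table(tmp, "tsv")
  for (cl in variant_columns()) {
    expect_equal(back[[cl]], rec[[cl]], info = cl)
  }
})

test_that("minus-strand records derive transcript-oriented alleles by complement", {
  rec <- as_variant_table(data.frame(chrom = "chr1", pos = c(1L, 2L),
                                     ref = c("C", "C"), alt = c("T", "T"),
                                     strand = c("-", "+")))
  tr <- transcript_alleles(rec)
  expect_identical(paste0(tr$t_ref, ">", tr$t_alt), c("G>A", "C>T"))
})
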