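# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# small cohort for module-level recovery tests
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- gen_cohort(seed = 42, n = 400, n_transcripts = 14,
                                  cds_length = 600)
  }
  .fixtures$small
}

# one-row variant table with codon context, for editability / improvement tests
toy_record <- function(ref, alt, region = "coding", consequence = "missense",
                       codon = NA, codon_pos = NA, strand = "+",
                       transcript_id = "TX0001", cds_offset = 10L) {
  rec <- as_variant_table(data.frame(
    chrom = "chr1", pos = 1000L, ref = ref, alt = alt, region = region,
    consequence = consequence, strand = strand, transcript_id = transcript_id,
    cds_offset = cds_offset, clin_sig = "Pathogenic", stringsAsFactors = FALSE))
  if (!is.na(codon)) {
    rec$codon <- codon
    rec$codon_pos <- codon_pos
    mut <- codon
    substr(mut, codon_pos, codon_pos) <- alt
    rec$mut_codon <- mut
  }
  rec
}
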