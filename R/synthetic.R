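#' Deterministic synthetic cohorts with a ground-truth manifest
#'
#' The generator emulates the external resources the pipeline consumes — a
#' transcriptome (CDS FASTA), a reported-variant table with junk rows for the
#' exclusion cascade, and predictor / guide-specificity / allele-frequency /
#' tissue-expression tables — while *constructing* every planted property
#' (mismatch composition, ADAR 5' contexts, PAM distances including
#' out-of-range decoys, near-duplicate off-target segments straddling the
#' identity threshold, score-table class fractions) so that recovery tests
#' against the returned manifest are exact, with no statistical slack.
#'
#' A single integer seed drives one named pseudo-random stream per stage, so
#' adding a stage never perturbs earlier ones; regeneration from the same
#' seed is identical.
#'
#' @name synthetic_data
NULL

SENSE_CODONS <- NULL  # initialised on first use
sense_codons <- function() {
  cds <- all_codons()
  cds[Biostrings::GENETIC_CODE[cds] != "*"]
}
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate a toy transcriptome
#'
#' Random CDS sequences: ATG start, single terminal stop codon, no internal
#' stop in frame.
#'
#' @param n_transcripts Number of transcripts (>= 1).
#' @param cds_length CDS length in nt (>= 102, divisible by 3).
#' @param seed Integer seed.
#' @return Named character vector of sequences (`TX0001`, ...) with an
#'   `"index"` attribute: data.frame of `transcript_id`, `gene`, `chrom`.
#' @export
gen_transcriptome <- function(n_transcripts = 24, cds_length = 750, seed = 1) {
  if (n_transcripts < 1) be_stop("n_transcripts must be >= 1")
  if (cds_length < 102 || cds_length %% 3 != 0) {
    be_stop("cds_length must be >= 102 and divisible by 3")
  }
  with_seed(derive_seed(seed, "transcriptome"), {
    sense <- sense_codons()
    n_mid <- cds_length / 3 - 2
    seqs <- vapply(seq_len(n_transcripts), function(i) {
      paste0("ATG", paste(sample(sense, n_mid, replace = TRUE), collapse = ""),
             sample(STOP_CODONS, 1))
    }, "")
    names(seqs) <- sprintf("TX%04d", seq_len(n_transcripts))
    attr(seqs, "index") <- data.frame(
      transcript_id = names(seqs),
      gene = sprintf("GENE%03d", seq_len(n_transcripts)),
      chrom = paste0("chr", (seq_len(n_transcripts) - 1L) %% 22L + 1L),
      stringsAsFactors = FALSE)
    seqs
  })
}

#' Default planted cohort composition
#'
#' Counts per mismatch type, region and molecular consequence for the default
#' study cohort of 2000 gene-located pathogenic SNVs: 30% directly editable
#' (`G>A` + `T>C`), 29% editable on the complementary strand (`C>T` + `A>G`),
#' 80% coding / 20% gene-non-coding, with nonsense quotas restricted to the
#' mismatch types that can create a stop codon.
#'
#' @param n Total cohort size; counts are scaled from the base-2000 table and
#'   re-balanced to sum to `n`.
#' @return data.frame with `mismatch`, `region`, `consequence`, `n`.
#' @export
default_composition <- function(n = 2000) {
  base <- rbind(
    data.frame(mismatch = "G>A", consequence = c("missense", "nonsense", "synonymous"),
               n = c(300L, 80L, 20L)),
    data.frame(mismatch = "T>C", consequence = c("missense", "synonymous"), n = c(70L, 10L)),
    data.frame(mismatch = "C>T", consequence = c("missense", "nonsense", "synonymous"),
               n = c(270L, 90L, 20L)),
    data.frame(mismatch = "A>G", consequence = c("missense", "synonymous"), n = c(86L, 10L)),
    data.frame(mismatch = "G>C", consequence = c("missense", "synonymous"), n = c(80L, 10L)),
    data.frame(mismatch = "G>T", consequence = c("missense", "nonsense"), n = c(70L, 10L)),
    data.frame(mismatch = "A>C", consequence = c("missense", "synonymous"), n = c(80L, 4L)),
    data.frame(mismatch = "A>T", consequence = c("missense", "nonsense"), n = c(70L, 10L)),
    data.frame(mismatch = "C>A", consequence = c("missense", "nonsense"), n = c(70L, 10L)),
    data.frame(mismatch = "C>G", consequence = c("missense", "nonsense"), n = c(70L, 10L)),
    data.frame(mismatch = "T>A", consequence = c("missense", "nonsense"), n = c(70L, 5L)),
    data.frame(mismatch = "T>G", consequence = c("missense", "nonsense"), n = c(70L, 5L)))
  base$region <- "coding"
  nc <- data.frame(mismatch = c("G>A", "T>C", "C>T", "A>G", "G>C", "G>T",
                                "A>C", "A>T", "C>A", "C>G", "T>A", "T>G"),
                   consequence = "intron",
                   n = c(100L, 20L, 80L, 24L, 22L, 22L, 22L, 22L, 22L, 22L, 22L, 22L),
                   region = "gene_noncoding")
  comp <- rbind(base, nc)[, c("mismatch", "region", "consequence", "n")]
  if (n != 2000) {
    comp$n <- pmax(0L, as.integer(round(comp$n * n / 2000)))
    diff <- as.integer(n - sum(comp$n))
    comp$n[1] <- comp$n[1] + diff  # absorb rounding in the largest class
  }
  comp
}

#' Default planted context parameters
#'
#' ADAR-motif fractions among `G>A` variants (coding and non-coding planted
#' separately), the PAM boundary design (planted NGG distances straddling the
#' accepted 12-16 range), the off-target duplicate design (fraction of the
#' RNA-direct coding subset receiving a planted near-duplicate, planted
#' mismatch counts over the 41-nt query: 0 and 4 give identities 1.0 and
#' 0.902, above the 0.85 threshold; decoys with 7 mismatches give 0.829,
#' below it), and junk-row counts for the filtering cascade.
#'
#' @return Named list of parameters.
#' @export
default_contexts <- function() {
  list(adar_ok_fraction_coding = 0.70,
       adar_ok_fraction_noncoding = 0.60,
       pam_distances = c(11L, 12L, 16L, 17L),
       pam_per_distance = 5L,
       offtarget_fraction = 0.10,
       offtarget_census_size = 200L,
       offtarget_mismatches = c(0L, 4L),   # alternated over planted copies
       offtarget_decoy_mismatches = 7L,
       n_offtarget_decoys = 10L,
       junk = c(upstream = 8L, downstream = 6L, no_sequence_alteration = 5L,
                no_consequence = 7L, misclassified_snv = 4L, mitochondrial = 9L,
                benign = 120L, conflicting_dropped = 10L,
                conflicting_unresolved = 5L, cds_mismatch = 5L,
                transcript_missing = 3L))
}

# ---- PAM-dedicated transcripts --------------------------------------------

# independent trinucleotide scan used only to validate construction: all NGG
# distances (both orientations) from position t
scan_pam_distances <- function(seq, t) {
  n <- nchar(seq)
  ds <- integer(0)
  for (p in seq_len(n - 2)) {
    tri <- substr(seq, p, p + 2)
    if (substr(tri, 2, 3) == "GG") ds <- c(ds, p - t - 1L)       # plus
    if (substr(tri, 1, 2) == "CC") ds <- c(ds, t - (p + 2L) - 1L) # minus
  }
  ds[ds >= 0]
}

# build a 120-nt CDS carrying one G>A missense target at offset 58 (codon
# GGC -> AGC, 5' neighbour C so the ADAR motif holds) with exactly one NGG
# PAM at the requested distance and no other NGG/CCN at distances 10..18
build_pam_transcript <- function(distance, range = c(12L, 16L)) {
  t <- 58L
  sense <- sense_codons()
  for (attempt in 1:200) {
    codons <- c("ATG", sample(sense, 38, replace = TRUE), sample(STOP_CODONS, 1))
    codons[19] <- "TCC"  # positions 55-57; 5' neighbour of t is C
    codons[20] <- "GGC"  # positions 58-60; target G at 58
    seq <- paste(codons, collapse = "")
    # scrub candidate PAMs near the in-range band on both sides
    ok <- TRUE
    for (pass in 1:10) {
      offend <- integer(0)
      for (i in (t + 9):(t + 24)) {           # plus-strand GG
        if (substr(seq, i, i + 1) == "GG") offend <- c(offend, i + 1L)
      }
      for (i in (t - 24):(t - 9)) {           # minus-strand CC
        if (substr(seq, i, i + 1) == "CC") offend <- c(offend, i + 1L)
      }
      if (length(offend) == 0) break
      for (j in offend) {
        for (repl in c("A", "T", "C", "G")) {
          if (repl == substr(seq, j, j)) next
          cand <- seq
          substr(cand, j, j) <- repl
          cstart <- ((j - 1L) %/% 3L) * 3L + 1L
          if (substr(cand, cstart, cstart + 2) %in% STOP_CODONS) next
          if (substr(cand, j, j + 1) %in% c("GG", "CC")) next
          if (j > 1 && substr(cand, j - 1, j) %in% c("GG", "CC")) next
          seq <- cand
          break
        }
      }
    }
    # plant the PAM: N at p, GG at p+1..p+2; keep p and p+3 non-G
    p <- t + distance + 1L
    substr(seq, p, p) <- "A"
    substr(seq, p + 1, p + 2) <- "GG"
    if (substr(seq, p + 3, p + 3) == "G") substr(seq, p + 3, p + 3) <- "A"
    # validate: frame still stop-free, target intact, planted distance unique
    cods <- substring(seq, seq(1, 118, 3), seq(3, 120, 3))
    if (any(cods[2:39] %in% STOP_CODONS)) next
    if (substr(seq, t, t) != "G" || substr(seq, t - 1, t - 1) != "C") next
    ds <- scan_pam_distances(seq, t)
    in_range <- ds[ds >= range[1] & ds <= range[2]]
    want <- if (distance >= range[1] && distance <= range[2]) distance else integer(0)
    if (!distance %in% ds) next
    if (!identical(sort(unique(in_range)), sort(unique(want)))) next
    return(seq)
  }
  be_stop("failed to construct PAM-dedicated transcript")
}

# ---- variant planting ------------------------------------------------------

# classify the consequence of base alt at 1-based CDS position pos
plant_consequence <- function(codon, cpos, alt) {
  mut <- codon
  substr(mut, cpos, cpos) <- alt
  ref_aa <- Biostrings::GENETIC_CODE[codon]
  mut_aa <- Biostrings::GENETIC_CODE[mut]
  if (mut_aa == "*") "nonsense" else if (ref_aa == mut_aa) "synonymous" else "missense"
}

# enumerate all interior coding positions of a transcript set
coding_candidates <- function(seqs) {
  out <- list()
  for (tx in names(seqs)) {
    s <- seqs[[tx]]
    L <- nchar(s)
    n_cod <- L / 3
    pos <- seq.int(4L, L - 3L)  # interior codons only
    bases <- strsplit(substr(s, 4, L - 3), "")[[1]]
    cstart <- ((pos - 1L) %/% 3L) * 3L + 1L
    out[[tx]] <- data.frame(
      transcript_id = tx, pos = pos, base = bases,
      codon = substring(s, cstart, cstart + 2L),
      cpos = (pos - 1L) %% 3L + 1L,
      prev = strsplit(substr(s, 3, L - 4), "")[[1]],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

mutate_at <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

rand_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

#' Generate a planted variant cohort
#'
#' Places every variant requested by `composition` on the transcriptome so
#' that each planted attribute holds by construction (see [synthetic_data]),
#' appends purpose-built transcripts carrying the PAM boundary cases and
#' decoy subjects carrying planted off-target duplicates, and wraps the clean
#' cohort in a raw table with junk rows for each exclusion rule.
#'
#' @param transcriptome Result of [gen_transcriptome()].
#' @param composition data.frame as [default_composition()].
#' @param contexts List as [default_contexts()].
#' @param seed Integer seed.
#' @return List with `variants` (clean annotated cohort), `raw` (cohort plus
#'   junk rows, shuffled), `transcripts` (transcriptome plus PAM-dedicated
#'   transcripts), `decoys` (off-target decoy subjects), and `truth` (the
#'   manifest: per-variant planted attributes and cohort-level expectations).
#' @export
gen_variants <- function(transcriptome, composition = default_composition(),
                         contexts = default_contexts(), seed = 1) {
  with_seed(derive_seed(seed, "variants"), {
    seqs <- c(transcriptome)
    index <- attr(transcriptome, "index")

    # --- PAM-dedicated transcripts (carved out of the coding G>A missense quota)
    pam_rows <- list()
    n_pam <- length(contexts$pam_distances) * contexts$pam_per_distance
    ga_mis <- composition$mismatch == "G>A" & composition$region == "coding" &
              composition$consequence == "missense"
    if (n_pam > 0) {
      if (!any(ga_mis) || composition$n[ga_mis] < n_pam) {
        be_stop("composition infeasible: coding G>A missense quota smaller than PAM design")
      }
      composition$n[ga_mis] <- composition$n[ga_mis] - n_pam
      k <- 0L
      for (d in contexts$pam_distances) {
        for (r in seq_len(contexts$pam_per_distance)) {
          k <- k + 1L
          tx <- sprintf("PAMTX%03d", k)
          seqs[[tx]] <- build_pam_transcript(d)
          index <- rbind(index, data.frame(
            transcript_id = tx, gene = sprintf("PAMGENE%03d", k),
            chrom = paste0("chr", (k - 1L) %% 22L + 1L)))
          pam_rows[[k]] <- list(transcript_id = tx, pos = 58L, distance = d)
        }
      }
    }

    cand <- coding_candidates(seqs)
    used <- character(0)  # "tx:pos" keys already carrying a variant
    take <- function(pool, n, label) {
      pool <- pool[!paste(pool$transcript_id, pool$pos) %in% used, , drop = FALSE]
      if (nrow(pool) < n) {
        be_stop(sprintf("composition infeasible: need %d %s, pool has %d",
                        n, label, nrow(pool)))
      }
      sel <- pool[sample.int(nrow(pool), n), , drop = FALSE]
      used <<- c(used, paste(sel$transcript_id, sel$pos))
      sel
    }

    rows <- list()
    add_row <- function(transcript_id, pos, ref, alt, region, consequence,
                        adar = NA, pam_distance = NA_integer_, context_seq = NA_character_,
                        context_offset = NA_integer_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        transcript_id = transcript_id, cds_offset = pos, ref = ref, alt = alt,
        region = region, consequence = consequence, adar_planted = adar,
        pam_distance = pam_distance, context_seq = context_seq,
        context_offset = context_offset, stringsAsFactors = FALSE)
    }

    for (pr in pam_rows) {
      used <- c(used, paste(pr$transcript_id, pr$pos))
      add_row(pr$transcript_id, pr$pos, "G", "A", "coding", "missense",
              adar = TRUE, pam_distance = pr$distance)
    }

    # --- coding variants by search over constructed pools
    for (i in which(composition$region == "coding")) {
      mm <- composition$mismatch[i]
      ref <- substr(mm, 1, 1); alt <- substr(mm, 3, 3)
      n_want <- composition$n[i]
      if (n_want == 0) next
      pool <- cand[cand$base == ref, , drop = FALSE]
      cons <- vapply(seq_len(nrow(pool)), function(j)
        plant_consequence(pool$codon[j], pool$cpos[j], alt), "")
      pool <- pool[cons == composition$consequence[i], , drop = FALSE]
      if (mm == "G>A") {  # partition by planted ADAR status
        n_ok <- round(contexts$adar_ok_fraction_coding *
                        (n_want + if (composition$consequence[i] == "missense") n_pam else 0L)) -
                (if (composition$consequence[i] == "missense") n_pam else 0L)
        n_ok <- max(0L, min(n_want, n_ok))
        sel_ok <- take(pool[pool$prev != "G", , drop = FALSE], n_ok,
                       paste("coding G>A", composition$consequence[i], "ADAR-ok"))
        sel_bad <- take(pool[pool$prev == "G", , drop = FALSE], n_want - n_ok,
                        paste("coding G>A", composition$consequence[i], "ADAR-bad"))
        for (j in seq_len(nrow(sel_ok)))
          add_row(sel_ok$transcript_id[j], sel_ok$pos[j], ref, alt, "coding",
                  composition$consequence[i], adar = TRUE)
        for (j in seq_len(nrow(sel_bad)))
          add_row(sel_bad$transcript_id[j], sel_bad$pos[j], ref, alt, "coding",
                  composition$consequence[i], adar = FALSE)
      } else {
        sel <- take(pool, n_want, paste("coding", mm, composition$consequence[i]))
        for (j in seq_len(nrow(sel)))
          add_row(sel$transcript_id[j], sel$pos[j], ref, alt, "coding",
                  composition$consequence[i])
      }
    }

    # --- non-coding variants with generated transcript-sense contexts
    nc_gene_cycle <- index$transcript_id[index$transcript_id %in% names(transcriptome)]
    nci <- 0L
    for (i in which(composition$region == "gene_noncoding")) {
      mm <- composition$mismatch[i]
      ref <- substr(mm, 1, 1); alt <- substr(mm, 3, 3)
      n_want <- composition$n[i]
      if (n_want == 0) next
      n_ok <- if (mm == "G>A") round(contexts$adar_ok_fraction_noncoding * n_want) else NA
      for (j in seq_len(n_want)) {
        nci <- nci + 1L
        ctx <- rand_dna(41)
        ctx <- mutate_at(ctx, 21L, ref)
        adar <- NA
        if (mm == "G>A") {
          adar <- j <= n_ok
          nb <- if (adar) sample(c("A", "C", "T"), 1) else "G"
          ctx <- mutate_at(ctx, 20L, nb)
        }
        add_row(nc_gene_cycle[(nci - 1L) %% length(nc_gene_cycle) + 1L],
                NA_integer_, ref, alt, "gene_noncoding", composition$consequence[i],
                adar = adar, context_seq = ctx, context_offset = 21L)
      }
    }

    variants <- do.call(rbind, rows)
    n <- nrow(variants)
    variants$variant_id <- sprintf("VAR%06d", seq_len(n))
    variants$gene <- index$gene[match(variants$transcript_id, index$transcript_id)]
    variants$chrom <- index$chrom[match(variants$transcript_id, index$transcript_id)]
    variants$strand <- "+"
    # unique genomic positions per chromosome
    variants$pos <- 100000L + as.integer(stats::ave(seq_len(n), variants$chrom,
                                                    FUN = seq_along)) * 97L
    # clinical significance mix (all kept by the pathogenicity filter)
    sig <- sample(c("Pathogenic", "Likely pathogenic", "Pathogenic/Likely pathogenic",
                    "Conflicting interpretations of pathogenicity"),
                  n, replace = TRUE, prob = c(0.80, 0.10, 0.05, 0.05))
    variants$clin_sig <- sig
    variants$submitter_sigs <- ifelse(
      sig == "Conflicting interpretations of pathogenicity",
      "Pathogenic;Benign;Uncertain significance", NA_character_)
    # submitter support: exactly 19.4% with >= 3 submitters
    n_high <- round(0.194 * n)
    subm <- c(sample(3:8, n_high, replace = TRUE), sample(1:2, n - n_high, replace = TRUE))
    variants$n_submitters <- sample(subm)
    variants <- as_variant_table(variants)

    # --- planted off-target duplicates for a designated census subset of the
    # RNA-direct coding variants. Census members are kept >= 45 nt apart on
    # each transcript so no member's 41-nt query overlaps another member's
    # source window (overlapping queries would legitimately match each
    # other's planted copies and spoil the exact zero-hit fraction).
    mm_all <- paste0(variants$ref, ">", variants$alt)
    rd <- which(variants$region == "coding" & mm_all %in% c("G>A", "T>C") &
                !is.na(variants$cds_offset))
    full_q <- rd[vapply(rd, function(i) {
      L <- nchar(seqs[[variants$transcript_id[i]]])
      variants$cds_offset[i] >= 21 && variants$cds_offset[i] <= L - 20
    }, TRUE)]
    census <- integer(0)
    for (i in sample(full_q)) {
      same <- census[variants$transcript_id[census] == variants$transcript_id[i]]
      if (all(abs(variants$cds_offset[same] - variants$cds_offset[i]) >= 45)) {
        census <- c(census, i)
      }
      if (length(census) >= contexts$offtarget_census_size) break
    }
    n_planted <- round(contexts$offtarget_fraction * length(census))
    planted <- if (n_planted > 0) sample(census, n_planted) else integer(0)
    rest <- setdiff(census, planted)
    n_dec <- min(contexts$n_offtarget_decoys, length(rest))
    decoy_only <- if (n_dec > 0) sample(rest, n_dec) else integer(0)

    make_copy <- function(i, n_mm) {
      tx <- variants$transcript_id[i]; off <- variants$cds_offset[i]
      q <- substr(seqs[[tx]], off - 20L, off + 20L)
      q <- mutate_at(q, 21L, variants$alt[i])  # mutant allele, like the guide
      if (n_mm > 0) {
        # mismatch layout preserves two perfect 11-mer seed words (runs 1-11
        # and 13-23) so the copy stays discoverable by a word-seeded search
        mmpos <- c(12L, 24L, 27L, 30L, 33L, 36L, 39L)[seq_len(n_mm)]
        for (p in mmpos) {
          q <- mutate_at(q, p, sample(setdiff(DNA_BASES, substr(q, p, p)), 1))
        }
      }
      q
    }
    variants$offtarget_planted_hits <- NA_integer_
    variants$offtarget_planted_hits[census] <- 0L
    copies <- character(0)
    for (i in planted) {
      nm <- contexts$offtarget_mismatches[(match(i, planted) - 1L) %%
                                            length(contexts$offtarget_mismatches) + 1L]
      copies <- c(copies, make_copy(i, nm))
      variants$offtarget_planted_hits[i] <- 1L
    }
    for (i in decoy_only) copies <- c(copies, make_copy(i, contexts$offtarget_decoy_mismatches))
    # pack planted copies into decoy subjects, 8 per subject, random spacers
    decoys <- character(0)
    if (length(copies) > 0) {
      grp <- split(copies, (seq_along(copies) - 1L) %/% 8L)
      decoys <- vapply(grp, function(g) {
        paste0(rand_dna(30), paste(vapply(g, function(x) paste0(x, rand_dna(30)), ""),
                                   collapse = ""))
      }, "")
      names(decoys) <- sprintf("DECOY%02d", seq_along(decoys))
    }

    # --- raw table with junk rows for the exclusion cascade
    junk <- contexts$junk
    jrows <- list()
    jadd <- function(n_j, ...) {
      if (n_j == 0) return()
      for (q in seq_len(n_j)) {
        defaults <- list(chrom = "chr1", pos = 999000L + length(jrows) * 13L,
                         ref = "G", alt = "T", region = NA_character_,
                         consequence = "missense", clin_sig = "Pathogenic",
                         submitter_sigs = NA_character_, transcript_id = NA_character_,
                         cds_offset = NA_integer_, n_submitters = 1L, strand = "+")
        over <- list(...)
        for (nm in names(over)) defaults[[nm]] <- over[[nm]]
        jrows[[length(jrows) + 1L]] <<- as.data.frame(defaults, stringsAsFactors = FALSE)
      }
    }
    jadd(junk[["upstream"]], consequence = "upstream")
    jadd(junk[["downstream"]], consequence = "downstream")
    jadd(junk[["no_sequence_alteration"]], ref = "A", alt = "A")
    jadd(junk[["no_consequence"]], consequence = "none")
    jadd(junk[["misclassified_snv"]], ref = "AT", alt = "A")
    jadd(junk[["mitochondrial"]], chrom = "chrM")
    jadd(junk[["benign"]], clin_sig = "Benign")
    jadd(junk[["conflicting_dropped"]],
         clin_sig = "Conflicting interpretations of pathogenicity",
         submitter_sigs = "Benign;Likely benign")
    jadd(junk[["conflicting_unresolved"]],
         clin_sig = "Conflicting interpretations of pathogenicity")
    # coding rows whose stored ref contradicts the CDS (dropped at annotation)
    for (q in seq_len(junk[["cds_mismatch"]])) {
      tx <- names(transcriptome)[1]
      off <- 30L + 3L * q
      true_base <- substr(seqs[[tx]], off, off)
      wrong <- sample(setdiff(DNA_BASES, true_base), 1)
      jadd(1L, transcript_id = tx, cds_offset = off, region = "coding",
           ref = wrong, alt = sample(setdiff(DNA_BASES, wrong), 1))
    }
    jadd(junk[["transcript_missing"]], transcript_id = "TXMISSING",
         cds_offset = 10L, region = "coding")
    junk_df <- as_variant_table(do.call(rbind, jrows))
    junk_df$variant_id <- sprintf("JUNK%05d", seq_len(nrow(junk_df)))
    junk_df$context_seq <- NA_character_
    junk_df$context_offset <- NA_integer_
    raw_cols <- c(variant_columns(), "context_seq", "context_offset")
    raw <- rbind(variants[, raw_cols], junk_df[, raw_cols])
    raw <- raw[sample.int(nrow(raw)), , drop = FALSE]
    rownames(raw) <- NULL

    # --- manifest
    mm <- paste0(variants$ref, ">", variants$alt)
    direct <- mm %in% c("G>A", "T>C")
    compl <- mm %in% c("C>T", "A>G")
    truth <- list(
      seed = seed,
      contexts = contexts,
      composition = stats::aggregate(list(n = rep(1L, n)),
                                     by = list(mismatch = mm, region = variants$region,
                                               consequence = variants$consequence),
                                     FUN = sum),
      n_cohort = n,
      n_raw = nrow(raw),
      fraction_direct = mean(direct),
      fraction_complementary = mean(compl),
      adar_ok_fraction_coding =
        mean(variants$adar_planted[mm == "G>A" & variants$region == "coding"]),
      adar_ok_fraction_noncoding =
        mean(variants$adar_planted[mm == "G>A" & variants$region == "gene_noncoding"]),
      pam_variants = variants$variant_id[!is.na(variants$pam_distance)],
      offtarget_census_ids = variants$variant_id[census],
      zero_offtarget_fraction = 1 - n_planted / length(census),
      junk = junk,
      high_submitter_ids = variants$variant_id[variants$n_submitters >= 3],
      variants = variants[, c("variant_id", "transcript_id", "cds_offset", "region",
                              "consequence", "adar_planted", "pam_distance",
                              "offtarget_planted_hits")])
    truth$variants$mismatch <- mm

    list(variants = variants, raw = raw, transcripts = seqs, decoys = decoys,
         truth = truth)
  })
}

# ---- score / annotation tables --------------------------------------------

#' Default parameters for the generated annotation tables
#'
#' @return Named list: planted fraction of bystander edits classed likely
#'   pathogenic, fraction of editable variants passing the guide-specificity
#'   threshold, fraction of the cohort present in the frequency table, the
#'   number of variants receiving a planted site-score improvement and the
#'   planted mean score gain, and the tissue panel with planted
#'   tissue-restricted gene counts.
#' @export
default_table_params <- function() {
  list(bystander_pathogenic_fraction = 0.25,
       mit_pass_fraction = 0.77,
       freq_presence_fraction = 0.24,
       n_site_variants = 100L,
       site_delta_pair = c(0.12, 0.32),  # mean 0.22 by construction
       tissues = c("liver", "brain", "heart", "lung", "muscle"),
       n_liver_genes = 3L,
       n_brain_genes = 5L)
}

#' Generate predictor, specificity, frequency, expression and site-score tables
#'
#' Builds the annotation tables the summarisation and context stages consume,
#' consistent with the planted cohort, and extends the manifest with their
#' expectations: per-variant bystander counts and predicted-pathogenic
#' bystander counts, the identities passing the specificity and frequency
#' filters, the planted tissue-restricted gene sets, and the planted
#' site-score improvement subset with its exact mean score gain.
#'
#' @param cohort Result of [gen_variants()].
#' @param params List as [default_table_params()].
#' @param seed Integer seed.
#' @return List with `predictor`, `mit`, `frequency`, `expression` (matrix),
#'   `site_scores` and `truth` (table-level manifest entries).
#' @export
gen_tables <- function(cohort, params = default_table_params(), seed = 1) {
  variants <- cohort$variants
  seqs <- cohort$transcripts
  mm <- paste0(variants$ref, ">", variants$alt)

  # --- bystander enumeration + predictor table (stream: predictor)
  predictor_truth <- with_seed(derive_seed(seed, "predictor"), {
    class_map <- new.env(parent = emptyenv())  # key -> class, shared across variants
    prows <- list(); byst <- list()
    rd <- which(variants$region == "coding" & mm %in% c("G>A", "T>C"))
    for (i in rd) {
      tx <- variants$transcript_id[i]; off <- variants$cds_offset[i]
      s <- mutate_at(seqs[[tx]], off, variants$alt[i])  # mutant transcript
      eb <- if (mm[i] == "G>A") "A" else "C"
      ealt <- if (eb == "A") "G" else "T"
      lo <- max(1L, off - 10L); hi <- min(nchar(s), off + 10L)
      win <- strsplit(substr(s, lo, hi), "")[[1]]
      pos <- setdiff(which(win == eb) + lo - 1L, off)
      n_patho <- 0L
      for (p in pos) {
        key <- paste(tx, p, ealt, sep = ":")
        if (is.null(class_map[[key]])) {
          patho <- stats::runif(1) < params$bystander_pathogenic_fraction
          class_map[[key]] <- if (patho) "likely_pathogenic" else "likely_benign"
          prows[[length(prows) + 1L]] <- data.frame(
            transcript_id = tx, cds_offset = p, ref = eb, alt = ealt,
            score = if (patho) stats::runif(1, 0.7, 1) else stats::runif(1, 0, 0.3),
            class = class_map[[key]], stringsAsFactors = FALSE)
        }
        if (class_map[[key]] == "likely_pathogenic") n_patho <- n_patho + 1L
      }
      byst[[length(byst) + 1L]] <- data.frame(
        variant_id = variants$variant_id[i], n_bystanders = length(pos),
        n_predicted_pathogenic = n_patho, stringsAsFactors = FALSE)
    }
    list(table = if (length(prows) > 0) do.call(rbind, prows) else
           data.frame(transcript_id = character(0), cds_offset = integer(0),
                      ref = character(0), alt = character(0),
                      score = numeric(0), class = character(0)),
         per_variant = if (length(byst) > 0) do.call(rbind, byst) else NULL)
  })

  # --- guide specificity scores over the editable variants (stream: mit)
  editable <- variants$variant_id[mm %in% c("G>A", "T>C", "C>T", "A>G")]
  mit <- with_seed(derive_seed(seed, "mit"), {
    n_pass <- round(params$mit_pass_fraction * length(editable))
    pass_ids <- sample(editable, n_pass)
    data.frame(variant_id = editable,
               score = ifelse(editable %in% pass_ids,
                              stats::runif(length(editable), 50.5, 100),
                              stats::runif(length(editable), 0, 49.5)),
               stringsAsFactors = FALSE)
  })
  mit_pass_ids <- mit$variant_id[mit$score > 50]

  # --- allele-frequency presence (stream: frequency)
  frequency <- with_seed(derive_seed(seed, "frequency"), {
    n_present <- round(params$freq_presence_fraction * nrow(variants))
    present <- sample(seq_len(nrow(variants)), n_present)
    absent_zero <- sample(setdiff(seq_len(nrow(variants)), present), 3)
    rbind(
      data.frame(chrom = variants$chrom[present], pos = variants$pos[present],
                 ref = variants$ref[present], alt = variants$alt[present],
                 af = stats::runif(n_present, 1e-5, 1e-2), stringsAsFactors = FALSE),
      # zero-frequency rows: present in the table but not in the population
      data.frame(chrom = variants$chrom[absent_zero], pos = variants$pos[absent_zero],
                 ref = variants$ref[absent_zero], alt = variants$alt[absent_zero],
                 af = 0, stringsAsFactors = FALSE))
  })
  freq_ids <- variants$variant_id[match(
    paste(frequency$chrom, frequency$pos, frequency$ref, frequency$alt)[frequency$af > 0],
    paste(variants$chrom, variants$pos, variants$ref, variants$alt))]

  # --- tissue expression matrix (stream: expression)
  expression <- with_seed(derive_seed(seed, "expression"), {
    tissues <- params$tissues
    genes <- unique(variants$gene[!is.na(variants$gene)])
    m <- matrix(stats::runif(length(genes) * length(tissues), 0, 8),
                nrow = length(genes), dimnames = list(genes, tissues))
    add_gene <- function(m, name, vals) rbind(m, matrix(vals, 1, dimnames = list(name, tissues)))
    liver_genes <- sprintf("LIVER_ONLY_%d", seq_len(params$n_liver_genes))
    for (g in liver_genes) {
      v <- stats::runif(length(tissues), 0, 5); v[tissues == "liver"] <- stats::runif(1, 20, 80)
      m <- add_gene(m, g, v)
    }
    brain_genes <- sprintf("BRAIN_ONLY_%d", seq_len(params$n_brain_genes))
    for (g in brain_genes) {
      v <- stats::runif(length(tissues), 0, 5); v[tissues == "brain"] <- stats::runif(1, 20, 80)
      m <- add_gene(m, g, v)
    }
    # boundary decoys: rejected on either side of the strict thresholds
    m <- add_gene(m, "BORDER_HIGH_OTHERS", c(12, 11, 11, 11, 11))
    m <- add_gene(m, "BORDER_AT_THRESHOLD", c(10, 2, 2, 2, 2))
    attr(m, "liver_genes") <- liver_genes
    attr(m, "brain_genes") <- brain_genes
    m
  })

  # --- site-score tables planting an exact mean improvement (stream: site_scores)
  site <- with_seed(derive_seed(seed, "site_scores"), {
    cand <- which(variants$region == "coding" & variants$consequence == "missense" &
                  !mm %in% c("G>A", "T>C") & !is.na(variants$cds_offset))
    rows <- list(); chosen <- list()
    deltas <- rep(params$site_delta_pair,
                  length.out = min(params$n_site_variants, length(cand)))
    if (length(deltas) %% 2 == 1) deltas <- deltas[-length(deltas)]  # keep exact mean
    ci <- 0L
    for (i in sample(cand)) {
      if (ci >= length(deltas)) break
      tx <- variants$transcript_id[i]; off <- variants$cds_offset[i]
      cstart <- ((off - 1L) %/% 3L) * 3L + 1L
      codon <- substr(seqs[[tx]], cstart, cstart + 2L)
      mut <- mutate_at(codon, (off - 1L) %% 3L + 1L, variants$alt[i])
      ref_aa <- Biostrings::GENETIC_CODE[codon]
      mut_aa <- Biostrings::GENETIC_CODE[mut]
      reach <- setdiff(unique(Biostrings::GENETIC_CODE[enumerate_edits(mut)$novel]),
                       c("*", mut_aa, ref_aa))
      if (length(reach) == 0) next
      ci <- ci + 1L
      target_aa <- sample(reach, 1)
      b <- stats::runif(1, 0.1, 0.4)
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = rep(variants$variant_id[i], 2),
        amino_acid = c(mut_aa, target_aa),
        score = c(b, b + deltas[ci]), stringsAsFactors = FALSE)
      chosen[[length(chosen) + 1L]] <- data.frame(
        variant_id = variants$variant_id[i], novel_aa = target_aa,
        delta = deltas[ci], stringsAsFactors = FALSE)
    }
    list(table = if (length(rows) > 0) do.call(rbind, rows) else NULL,
         truth = if (length(chosen) > 0) do.call(rbind, chosen) else NULL)
  })

  truth <- list(bystanders = predictor_truth$per_variant,
                mit_pass_ids = mit_pass_ids,
                mit_pass_fraction = length(mit_pass_ids) / length(editable),
                freq_present_ids = freq_ids,
                liver_genes = attr(expression, "liver_genes"),
                brain_genes = attr(expression, "brain_genes"),
                site = site$truth,
                site_mean_delta = if (!is.null(site$truth)) mean(site$truth$delta) else NA_real_)

  list(predictor = predictor_truth$table, mit = mit, frequency = frequency,
       expression = expression, site_scores = site$table, truth = truth)
}

#' Generate a complete synthetic study cohort
#'
#' Convenience wrapper running [gen_transcriptome()], [gen_variants()] and
#' [gen_tables()] under one seed and merging the manifests.
#'
#' @param seed Integer seed.
#' @param n Cohort size (default 2000).
#' @param n_transcripts,cds_length Transcriptome dimensions.
#' @param contexts,table_params Parameter lists; see [default_contexts()] and
#'   [default_table_params()].
#' @return List with `transcripts`, `subjects` (transcripts plus off-target
#'   decoy subjects), `raw`, `variants`, `tables` and `truth`.
#' @export
gen_cohort <- function(seed = 1, n = 2000, n_transcripts = 24, cds_length = 750,
                       contexts = default_contexts(),
                       table_params = default_table_params()) {
  txp <- gen_transcriptome(n_transcripts, cds_length, seed)
  cohort <- gen_variants(txp, default_composition(n), contexts, seed)
  tables <- gen_tables(cohort, table_params, seed)
  truth <- cohort$truth
  truth$tables <- tables$truth
  list(transcripts = cohort$transcripts,
       subjects = c(cohort$transcripts, cohort$decoys),
       raw = cohort$raw, variants = cohort$variants,
       tables = tables, truth = truth)
}

#' Write a cohort to the on-disk dialects the pipeline reads
#'
#' Emits the CDS FASTA, the raw variant TSV, a ClinVar-style VCF carrying
#' significance and per-submitter fields, the annotation-table TSVs, the
#' expression TSV and the manifest JSON.
#'
#' @param cohort Result of [gen_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cohort$transcripts),
                              file.path(dir, "transcripts.fa"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cohort$subjects),
                              file.path(dir, "subjects.fa"))
  write_variant_table(cohort$raw, file.path(dir, "variants_raw.tsv"))
  write_clinvar_vcf(cohort$raw, file.path(dir, "variants.vcf"))
  for (nm in c("predictor", "mit", "frequency", "site_scores")) {
    tab <- cohort$tables[[nm]]
    if (!is.null(tab)) {
      utils::write.table(tab, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  expr <- cohort$tables$expression
  utils::write.table(data.frame(gene = rownames(expr), expr, check.names = FALSE),
                     file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- cohort$truth
  manifest$variants <- NULL  # per-variant frame kept in R, not in JSON
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write a minimal ClinVar-style VCF
#'
#' One biallelic SNV row per record; CLNSIG carries the significance string
#' and CLNSIGCONF the per-submitter strings (both with spaces encoded as
#' underscores, as in the real dialect). Rows with invalid alleles are
#' skipped (a VCF cannot represent them as SNVs).
#'
#' @param records Variant table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinvar_vcf <- function(records, path) {
  ok <- records$ref %in% DNA_BASES & records$alt %in% DNA_BASES
  rec <- records[ok, , drop = FALSE]
  enc <- function(x) gsub(" ", "_", x)
  info <- paste0("CLNSIG=", enc(rec$clin_sig))
  has_sub <- !is.na(rec$submitter_sigs)
  info[has_sub] <- paste0(info[has_sub], ";CLNSIGCONF=",
                          enc(gsub(";", "|", rec$submitter_sigs[has_sub])))
  has_gene <- !is.na(rec$gene)
  info[has_gene] <- paste0(info[has_gene], ";GENEINFO=", rec$gene[has_gene], ":0")
  has_cons <- !is.na(rec$consequence)
  info[has_cons] <- paste0(info[has_cons], ";MC=SO:0000000|",
                           rec$consequence[has_cons], "_variant")
  lines <- c("##fileformat=VCFv4.2",
             "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance\">",
             "##INFO=<ID=CLNSIGCONF,Number=.,Type=String,Description=\"Per-submitter significance\">",
             "##INFO=<ID=GENEINFO,Number=1,Type=String,Description=\"Gene symbol:id\">",
             "##INFO=<ID=MC,Number=.,Type=String,Description=\"Molecular consequence\">",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             paste(rec$chrom, rec$pos, rec$variant_id, rec$ref, rec$alt,
                   ".", ".", info, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
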