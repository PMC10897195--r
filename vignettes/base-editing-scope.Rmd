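---
title: "Assessing the scope of DNA and RNA base editing for pathogenic SNVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing the scope of DNA and RNA base editing for pathogenic SNVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(bescope)
```

# The question and the model

Deaminase-based base editors can perform exactly two chemistries: adenosine
deamination, read by the cell as an A>G change, and cytidine deamination,
read as C>T. `bescope` asks, for a cohort of pathogenic single-nucleotide
variants (SNVs), what each editor class can do about each variant:

* **Direct editing** targets the mutant base itself. Only `G>A` variants
  (mutant A reverted to G) and `T>C` variants (mutant C read as U/T) are
  correctable this way. RNA editors (Cas13-guided or endogenous-ADAR-recruiting)
  can only act directly; cytoplasmic mRNA editing requires a coding variant,
  while nuclear RNA editing also reaches transcribed non-coding regions.
* **Complementary editing** is available to DNA editors only: because DNA is
  base-paired, a `C>T` variant can be fixed by deaminating the A on the
  opposite strand, and `A>G` by deaminating the opposite C, with mismatch
  repair completing the correction.
* The remaining eight mismatch types cannot be corrected. For missense and
  nonsense variants among them the package runs a **codon-improvement
  algorithm**: it enumerates every A>G / C>T edit subset of the mutant codon
  (all `2^k - 1` subsets of its editable positions), discards any candidate
  that would create a stop codon, scores each candidate amino acid against
  the reference amino acid, and keeps the best candidate that strictly
  improves on the mutant amino acid — preferring the highest score, then the
  fewest simultaneous edits, then the lexicographically smallest codon so
  results are deterministic.

Around these calls the package implements the practical design checks: the
ADAR 5'-neighbour motif, NGG PAM discovery with its editing window, bystander
enumeration with pluggable per-site pathogenicity predictions, a seeded
local-alignment off-target search, and the clinical stratifications
(submitter support, population-frequency presence, guide specificity,
tissue-restricted expression).

# Scoring amino-acid substitutions

Two scorer modes drive the improvement algorithm.

**Matrix mode** uses the embedded BLOSUM62 matrix (shipped as a plain-text
NCBI-format file and parsed at load; entries span -4..11). BLOSUM62 has no
stop rows, so the package adds a stop policy: a stop/stop pair scores
`-Inf` and a stop/amino-acid pair scores a sentinel of -1000 — far below any
genuine matrix entry, so escaping a premature stop always qualifies as an
improvement while the sentinels can never leak into comparisons among real
substitutions. The published material does not say how stop escapes were
ranked against matrix values numerically; the sentinel construction is this
package's choice and keeps the two regimes ordered but separate.

```{r}
improve_codon("TAT", "TCT", scorer_matrix(), chemistries = "C>T")[
  c("novel_codon", "novel_aa", "mut_score", "novel_score")]
```

**Site-table mode** uses per-site tolerance scores in [0, 1] (SIFT-style:
0 deleterious, 1 tolerated). The baseline is the mutant amino acid's score
(0 for a mutant stop, the most deleterious value), and candidates scoring at
or below the `tolerance_floor` (default 0.05, the conventional
deleteriousness cut-off) are discarded before comparison.

A novel codon that restores the *reference* amino acid (or even the
reference codon itself, e.g. mutant TCA edited back to reference TTA) is
allowed and flagged `protein_level_correction` rather than excluded:
refusing a perfect protein-level restoration would be perverse, and the flag
lets downstream reports count either way. A `ptm_risk` flag marks
substitutions that could disrupt phosphorylation (Ser/Thr/Tyr lost to
Gly/Ala/Cys) or lysine methylation/acetylation sites, which is a caveat of
the approach, not a filter.

# Sequence-context parameters

All indices in the package are 1-based; BED-style 0-based inputs are
converted on read.

* **ADAR motif** (`adar_motif()`): satisfied when the base immediately 5' of
  the edited A exists and is not G. A target at the very start of its
  sequence is flagged as a boundary case and fails the motif.
* **PAM discovery** (`find_ngg_pams()`, default motif `NGG`): the stated
  requirement is a PAM 12-16 bases away from the target. The anchor is not
  specified further, so the package measures the *gap* in nucleotides
  between the target base and the nearest base of the PAM trinucleotide,
  inclusive range [12, 16]; `distance_range` is a configuration knob for
  sensitivity checks. The 5-base editing window is defined as the
  protospacer positions at distances 12-16 from the PAM — the window and the
  distance filter are deliberately one constraint, so an accepted target
  always lies inside its window.
* **Bystanders**: for RNA targets, the editable base is counted within 10 nt
  per side of the target ("20 nucleotides surrounding" is read as 10 + 10;
  `rna_bystander_flank` is configurable), truncated at sequence ends,
  excluding the target. For DNA targets the count is confined to a PAM hit's
  editing window. Bystander edits are looked up in a predictor table keyed
  by (transcript, CDS offset, implied alt); positions absent from the table
  count as not pathogenic, because missense-only predictors do not cover
  every change — misses are reported.

# The off-target search

The guide adheres to the sequence around the variant, so the query is the
flanking window carrying the *mutant* allele — "40 bases surrounding" is
interpreted as 20 per side plus the variant base, a 41-nt query (`flank` is
configurable; the alternative 40-total reading is noted as ambiguous).
Queries are aligned locally (match +1, mismatch -1, linear gap -2 per
column) against every subject and its reverse complement; the best alignment
per subject/orientation is a hit when identity >= 0.85 (matches over all
alignment columns, gaps included) and length >= 20 columns. The hit covering
the query's own source locus is flagged `is_self` and excluded from counts.

The search is *seeded*: a reported alignment must contain at least two
non-overlapping perfect 11-mer runs (the classic tile size and tile count of
word-indexed aligners; `seed_word`/`min_seed_words` are configurable, 0
disables). This is not an optimisation detail but part of the hit
definition: short 20-column windows at 85% identity arise between unrelated
random sequences often enough to contaminate a per-variant census, while a
word-indexed aligner cannot find such alignments at all, because they
contain no perfect seed word. The test suite probes this property directly:
random query/subject pairs yield no hits under the seed rule, and the
planted decoy layouts keep two seed words intact so threshold behaviour
stays observable.
Genuine near-duplicates at or above the identity threshold are expected to
carry seed words; sparsely diverged decoys just below the threshold are
still found (and rejected on identity), which is what makes the threshold
behaviour testable.

# The synthetic cohort generator

`gen_cohort()` emulates the external resources a cohort-scale analysis
would consume: a CDS transcriptome, a reported-variant table (with junk rows
exercising every exclusion rule and the conflicting-significance logic), a
ClinVar-style VCF, and predictor / guide-specificity / allele-frequency /
tissue-expression tables. Every planted property is *constructed*, not
sampled and re-measured, so recovery tests against the returned manifest are
exact:

* Default cohort: 2000 gene-located pathogenic SNVs — 30% directly editable
  (`G>A` + `T>C`), 29% complementarily editable (`C>T` + `A>G`), 80% coding,
  with nonsense quotas only in the mismatch types that can create a stop.
* ADAR contexts: 70% of coding and 60% of non-coding `G>A` variants are
  placed at sites whose 5' neighbour is not G (values in the neighbourhood
  of the fractions reported for real cohorts).
* PAM boundary cases: 5 variants per planted distance in {11, 12, 16, 17},
  each on a purpose-built transcript scrubbed of competing NGG/CCN motifs,
  so the 12-16 acceptance band is probed exactly at its edges.
* Off-target duplicates: a designated census subset of 200 RNA-direct coding
  variants, kept >= 45 nt apart so no member's query overlaps another's
  source window; 10% receive a planted copy at identity 1.0 or 0.902 (0 or 4
  mismatches over 41 nt), and further decoys carry 7 mismatches (identity
  0.829, just below the threshold). Mismatch positions preserve two 11-mer
  seed words so decoys are found-and-rejected rather than silently missed.
* Tables: bystander pathogenicity classes planted per implied edit (fraction
  0.25), guide-specificity passes planted at 77%, frequency presence at 24%,
  three liver- and five brain-restricted genes planted among background
  genes with boundary decoys at the exact thresholds, and site-score tables
  planting one reachable improvement per chosen variant with deltas of exact
  mean 0.22.

A single integer seed drives one named random stream per stage, so adding a
stage never perturbs earlier ones and regeneration is bit-identical.

What the generator does **not** emulate: real codon usage, transcript length
and GC heterogeneity, paralogy (off-target hits here are planted, not
emergent from gene families), strand-negative transcripts (all synthetic
transcripts are plus-strand, so genomic and transcript orientations
coincide), splicing structure, and the long-tailed submitter and frequency
distributions of real archives. Passing recovery tests therefore shows the
machinery is correct under controlled conditions, not that cohort-scale
figures from real archives are reproduced; those require the pinned external
resources and are out of desk scope by design.

```{r, eval = FALSE}
co <- gen_cohort(seed = 1)
fc <- filter_cascade(co$raw, co$transcripts)
calls <- call_editability(fc$records)
tabulate_editability(calls)$fractions
```

# Numerical and design choices

* **Coordinates**: 1-based inclusive internally (VCF convention).
* **Orientation**: RNA calls always use the transcript-oriented mismatch;
  DNA calls default to the reported (genomic) orientation to reproduce
  census-style tables, with `orientation = "transcript"` available — under
  it the hierarchy cytoplasmic RNA => nuclear RNA => direct DNA holds by
  construction. Which orientation underlies published census tables is not
  stated; the switch records the choice instead of hiding it.
* **Pathogenicity matching** is a case-insensitive substring rule
  ("pathogenic" anywhere in the significance string), deliberately not
  excluding strings that also mention "benign"; records reported as
  conflicting interpretations are decided by the per-submitter rule, and
  conflicting records without submitter data are dropped by default
  (configurable) and counted separately.
* **Strict thresholds**: "above 10 TPM" / "below 10 TPM", "score above 50"
  and "frequency present" (> 0) are strict inequalities; boundary values are
  rejected on both sides and the synthetic tables plant decoys exactly at
  the boundaries to pin the behaviour.
* **Tie-breaks**: candidate improvements are ordered by score, then edit
  count, then lexicographic codon; off-target hits by subject then position.
  Degenerate inputs (empty cohorts, empty tables, all-missing scores) return
  empty results rather than errors, except where an input violates a
  declared invariant (scores outside [0, 100] or [0, 1]), which errors.
* **Problem sizes**: tests run the full 64 x 64 codon-pair oracle, 1000
  random instances each for the alignment and PAM oracles, and a
  2000-variant cohort recovery on a 24-transcript x 750-nt transcriptome —
  sizes chosen so the whole suite completes in a few minutes on one core
  while every planted attribute is still probed exactly.

# Limitations

* Editing efficiency, position-dependent window weighting, non-NGG Cas
  variants (beyond the motif string), prime editing and transversion editors
  are out of scope.
* The off-target search scans supplied subject sets (transcriptomes);
  genome-scale indexed search and MIT-style specificity scoring are not
  implemented — specificity scores are consumed as a precomputed table and
  only the threshold filter is applied.
* Improvement scoring treats the codon in isolation; effects on splicing,
  RNA structure, or post-translational modification sites are surfaced only
  as the `ptm_risk` flag.
* Mitochondrial variants are excluded by the cascade, mirroring the scope of
  the underlying analysis.
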