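---
title: "Methods: allelic imbalance of somatic mutations between genome and transcriptome"
author: "aimut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allelic imbalance of somatic mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aimut)
```

## The problem

A somatic mutation observed in a tumor's exome need not be transcribed
in proportion to its DNA abundance. Comparing the variant allele
frequency measured in whole-exome sequencing (DNA-VAF) with the one
measured in RNA-seq of the same specimen (RNA-VAF) exposes *cis*-acting
transcriptional and post-transcriptional effects: nonsense-mediated
decay (NMD) depletes transcripts carrying premature termination codons
(PTCs), intron retention at disrupted splice sites over-represents the
mutant allele, and some missense alleles in cancer genes are
preferentially expressed. `aimut` implements this comparison end to
end: per-mutation allelic-imbalance calls, transcript-geometry
annotation of NMD sensitivity, splice-site classification and the
downstream enrichment statistics, together with a synthetic-cohort
generator that stands in for controlled-access tumor sequencing data.

## The allelic-imbalance statistic

For a mutation with `alt`/`ref` read counts in DNA and RNA, the VAF is
`alt / (alt + ref)` in each assay and the allelic fraction difference
is `AFD = RNA-VAF − DNA-VAF ∈ [−1, 1]`. Significance is assessed by a
Bayesian two-sample binomial test. Writing $k_D$ of $n_D$ and $k_R$ of
$n_R$ for the mutant read counts, the two hypotheses are

* $H_0$: one shared mutant fraction $p \sim \mathrm{Beta}(\alpha,\beta)$
  generates both counts;
* $H_1$: independent fractions $p_D, p_R \sim \mathrm{Beta}(\alpha,\beta)$.

With conjugate priors both marginal likelihoods are Beta functions and
the Bayes factor is

$$
BF_{10} = \frac{B(\alpha+k_D,\;\beta+n_D-k_D)\,
                B(\alpha+k_R,\;\beta+n_R-k_R)}
               {B(\alpha,\beta)\,
                B(\alpha+k_D+k_R,\;\beta+n_D+n_R-k_D-k_R)},
$$

computed in log space via `lbeta` (`log10_bayes_factor()`). A mutation
is `sig_pos_afd` when `AFD > 0` and `BF10` strictly exceeds the
threshold, `sig_neg_afd` when `AFD < 0` and the threshold is exceeded,
otherwise `no_sig`; an AFD of exactly zero is never significant. The
cited testing framework does not fix prior hyperparameters, so the
package declares uniform `Beta(1, 1)` priors and equal prior odds as
its default — configurable through `bf_params()` — and treats a Bayes
factor exactly equal to the threshold (default 10) as non-significant,
matching the strict "greater than" reading of the decision rule. Under
this default the test is conservative: in null simulations at depth 50
about 0.5% of mutations exceed BF 10, far below the 5% bound the test
suite asserts.

## Preprocessing funnel

The filters mirror standard practice for paired WES/RNA-seq cohorts
and run in this order:

1. **Depth**: keep mutations with at least 10 reads in both assays
   (inclusive bound; both defaults configurable).
2. **Hypermutated samples**: drop samples exceeding 10 mutations/Mb
   (strict inequality). The rate denominator is a nominal captured
   exome of 38 Mb; the source analyses never state their denominator,
   so it is exposed as `exome_size_mb`.
3. **Multi-mutant genes**: within each sample, drop every mutation of
   a gene mutated two or more times in that sample. The discard is
   scoped per sample — a gene mutated once in each of two samples is
   kept in both — because a cohort-wide reading would delete nearly
   every recurrently mutated cancer gene.
4. **Copy-number neutrality** (missense analysis only): keep mutations
   inside a same-sample segment with log2 ratio strictly between
   −0.15 and 0.15. Mutations covered by no segment are treated as
   non-neutral and removed, the conservative choice for uncharacterized
   loci.

Every filter returns a `filter_report` so the funnel is auditable;
`records_in = records_out + removed` is asserted as a property test.

## NMD geometry and the 50-nt rule

All PTC geometry is computed in spliced (mature mRNA) coordinates,
because the exon-junction-complex model of NMD concerns junctions on
the mature transcript, not genomic distances. For a nonsense SNV the
PTC is the codon containing the mutated base, anchored at the codon's
first nucleotide; for frameshift indels the caller supplies
`ptc_cds_pos` (mirroring upstream annotation tools), with a fallback
that naively re-translates the edited coding sequence to its first
stop when the transcript model carries a `cds_sequence`.

`annotate_ptc()` reports the distance from the PTC to the 3′-most
exon–exon junction, to the start codon, and to the nearest downstream
junction, plus a region label (`last_exon`, `penultimate_ge50`,
`penultimate_lt50`, `other` — a partition) and the NMD class. A PTC in
the last exon always escapes; elsewhere it is NMD-sensitive when it
lies at least 50 nt upstream of the last junction. The boundary at
exactly 50 nt is genuinely ambiguous in the source material (the
figure groups "≥ 50 nt" with sensitive; the text says "more than 50");
the package includes 50 by default and exposes
`boundary_inclusive = FALSE` for the other convention.

Isoform choice can flip the 50-nt classification and the source
analyses never state how an isoform was selected per gene; when an
annotation file carries several transcripts for a gene, the one with
the longest CDS is kept and the choice is logged.

Splice-site classification is restricted to the canonical ±2 intronic
positions: donor offsets +1/+2 (expected G/T) after an exon end in
transcript orientation, acceptor offsets −2/−1 (expected A/G) before
the next exon. Deeper intronic positions are rejected rather than
guessed.

## Downstream statistics

* `paired_vaf_test()`: one-tailed paired t of RNA-VAF against DNA-VAF
  (`stats::t.test`), the test used to demonstrate mutant-transcript
  depletion in the NMD-sensitive class.
* `fisher_exact_2x2()`: exact hypergeometric p computed directly from
  `stats::dhyper` over the conditional support, using the same
  two-sided rule as `stats::fisher.test` (summing all tables whose
  conditional probability does not exceed the observed one); this form
  is fast enough to sweep hundreds of thousands of tables and is
  verified against both full enumeration and `fisher.test` in the test
  suite.
* `spectrum_class()` / `ts_tv()`: the six strand-symmetric
  substitution classes and the transition/transversion split.
* `cumulative_ratio_curve()`: cumulative left-closed bins
  (`value < k·width`), the construction used for distance-to-junction
  and covariate curves; empty bins report an undefined ratio rather
  than zero.
* `gene_ai_enrichment()`: per gene, a one-sided Fisher test of the
  focal AI class against the background of all other genes in the same
  result set. The background choice is not specified upstream; "all
  other genes in the analyzed set" is the declared convention, applied
  per tumor type when results are analyzed per tumor type. Raw p-values
  are reported with a `−log10 p > 2.5` display convention and a
  Benjamini–Hochberg column alongside (emitted for the user, never used
  to filter), and `export_ranked_list()` writes the
  descending-`−log10 p` ranked file consumed by preranked gene-set
  enrichment tools, with alphabetical tie-breaks for determinism.

## The synthetic cohort generator

The generator (`simulation_config()`, `simulate_transcripts()`,
`simulate_cohort()`) emulates the features of a paired WES/RNA-seq
cohort that the pipeline is sensitive to, with known ground truth:

* **Transcripts**: 2–12 exons (uniform), exon lengths 60–400 nt,
  intron lengths 200–2,000 nt, random strand, CDS covering ≥ 60% of
  the spliced length with no internal stop codon.
* **Category mixture**: six mutation categories drawn with the
  per-tumor-type proportions of a large published pan-cancer cohort
  (presets `BRCA`, `HNSC`, `KIRC`, `LUAD`, `STAD`; breast-cancer-like
  defaults). Mutations are placed at category-appropriate coordinates,
  so truncating mutations acquire their *true* NMD sensitivity from
  the actual transcript geometry (labelled by an independent
  brute-force walk, not by the annotator under test).
* **Allelic effects**: the NMD effect is modeled as a per-transcript
  survival factor `r`: mutant transcripts of an NMD-sensitive
  truncating mutation survive at rate `r`, giving the RNA mutant
  fraction `r·p / (r·p + (1 − p))` (`rna_fraction_under_nmd()`);
  default `r = 0.25`. Splice-site mutations are up-weighted through
  the same odds transform with boost 2 (intron retention stabilizes
  the mutant transcript). All other mutations transcribe at their DNA
  fraction.
* **True DNA fractions**: `Beta(50, 50)` — clonal heterozygous
  mutations in a pure diploid genome, tightly centered at 0.5. Tumor
  purity and subclonal architecture are deliberately out of scope, so
  the generator does not smear fractions downward the way a real
  impure cohort would; consequences are discussed below.
* **Depths**: negative-binomial around means 80/80 with size 10,
  emulating uneven exome capture; analyses of depth-cutoff behavior
  use size 2 for the RNA side of the argument, reflecting the much
  stronger expression dependence of RNA-seq coverage.
* **Copy number**: 3–8 segments per chromosome and sample covering the
  whole gene space, 80% copy-neutral, the rest at |log2 ratio| 0.2–1.
* **Hypermutators**: 3% of samples by default, drawn with mutation
  counts comfortably above the 10/Mb exclusion threshold.

A single seeded RNG stream (isolated from the caller's RNG state)
makes every output bit-reproducible per seed; mutation positions are
unique per sample so that (sample, chromosome, position) is a usable
record key.

### What passing tests do and do not show

The simulator draws read counts from exactly the binomial model the
Bayes-factor test assumes. Recovery results (≥ 80% of truly
NMD-affected truncating mutations called sig-neg-AFD at depth 80,
≤ 0.5% false calls under the null) therefore demonstrate correctness
and calibration of the statistical machinery, not performance on real
tumors, where overdispersed counts, mapping bias toward the reference
allele, impure and aneuploid samples, and isoform mixtures all erode
the separation. The geometry tests, by contrast, are exact statements:
distances and 50-nt classifications agree with a nucleotide-level walk
on arbitrary transcripts.

## Numerical and degenerate-input choices

* Bayes factors, Beta functions and hypergeometric probabilities are
  computed in log space; no factorials are formed.
* Zero total depth makes a VAF undefined and is an error — the depth
  filter must run first.
* A paired test on differences with (numerically) zero variance, an
  all-zero contingency table and a chi-square with a zero marginal are
  errors, not NaNs.
* Cumulative-curve bins with no observations report `NA` ratios.
* Ranked-list ties break alphabetically; GTF output orders genes
  alphabetically and exons genomically, so equal inputs give
  byte-identical files.
* `threshold_grid()` computes VAFs and Bayes factors once and re-applies
  only the depth mask per cutoff pair, which is exactly equivalent to
  re-running the test per cell.

## Problem sizes used in the checks

The bundled analyses and acceptance checks run at desk scale, chosen
so each stage still has the sample sizes its statistics need: cohorts
of 160–200 samples with ~80–100 mutations each (≈13,000–20,000
mutations, of which ≈1,000 truncating mutations are truly
NMD-sensitive), 10,000-replicate null calibrations, the full
Bayes-factor grid with totals ≤ 30 against quadrature, all 2×2 tables
with total ≤ 60 against enumeration, and 1,000 random transcripts
against the brute-force geometry walk. These sizes are the package's
declared study conditions; the generator scales to larger cohorts by
configuration.

## Known limitations

* Binomial counts only: no overdispersion, reference-mapping bias or
  RNA-editing noise in either the generator or the test's likelihood.
* One transcript per gene; no isoform-aware PTC calling.
* Frameshift re-translation is a naive single-edit scan of the coding
  sequence; compound indels and splice-altering indels are out of
  scope.
* The copy-neutral filter trusts segment calls; subclonal copy-number
  events inside "neutral" segments can still masquerade as allelic
  imbalance, as the source analyses themselves caution.
* Running gene-set enrichment on the exported ranked list is left to
  external tools.
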