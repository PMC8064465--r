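---
title: "Methods: integrative variant prioritization for a single gene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative variant prioritization for a single gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varprior)
```

## The problem

Genes whose damaging variants sit in the 0.1–2% allele-frequency range are
awkward for both classical rare-disease filtering (which discards anything
that common) and GWAS (which cannot reach genome-wide significance for
them). varprior implements an integrative prioritization workflow for a
single gene of interest that combines four independent evidence layers:

1. **Evolutionary scoring** of every residue from an in-frame codon
   alignment of vertebrate orthologs.
2. **Additive and combined impact scoring** of coding variants from
   categorical effect-predictor calls.
3. **Regulatory-evidence scoring** of noncoding variants from annotation
   peak overlaps weighted by CADD.
4. **Cohort enrichment** of carrier frequencies in a phenotyped
   rare-disease cohort against population databases.

Because all four layers normally depend on external databases and
licensed tools, the package ships a seeded synthetic-data generator that
emulates the statistical structure of those inputs with known ground
truth, so the whole chain is testable offline.

## Evolutionary scoring

The substrate is a codon alignment: a multiple alignment of coding DNA
kept in frame, so each column triple encodes one amino-acid position.
Gaps must tile whole codons; the standard nuclear code is used and stop
codons translate to `"*"`, treated as a 21st residue class (a column of
stops is biologically meaningful at the C-terminus, a gap is not).

For each column with profile counts over amino acids and codons:

- **Conservation fraction** `c` is the fraction of non-gap rows carrying
  the reference residue. Gap rows are excluded from the denominator:
  missing sequence is not evidence of divergence. An all-gap column
  scores 0 by convention.
- **Wobble statistic** `s` measures synonymous-codon diversity of the
  modal amino acid: `s = (observed synonymous codons - 1) / (possible
  synonymous codons - 1)`. The normalization by the size of the
  synonymous set makes 2-codon and 6-codon amino acids comparable;
  single-codon amino acids (Met, Trp) contribute 0. Modal ties break to
  the alphabetically first residue so the statistic is deterministic.
- **Selection z** standardizes `s` against the gene-wide distribution
  using the population (n-denominator) standard deviation; a
  zero-variance track yields z = 0 everywhere. A high z flags a residue
  whose codon wobbled across species while the amino acid never changed
  — purifying selection acting on the protein.
- **Residue score** `r = c + clamp(z/2, 0, 1)`, bounded on [0, 2]. The
  linear z/2 map saturating at 1 is a *calibration*, not a canonical
  form: the score's ceiling of 2 and the single anchor point (full
  conservation with z = 0.5 giving 1.25) underdetermine the mapping, and
  the simplest function consistent with both was chosen. Anyone needing
  a different z mapping can recompute `r` from the `c` and `z` columns
  of the score track.
- **Window score** `w` is the mean of `r` over a 21-codon window (10
  before, the site, 10 after; `half_width` is tunable). Windows truncate
  at the termini rather than padding with zeros — padding would
  artifactually depress terminal motifs, and C-terminal regions are
  exactly where gain-of-function truncating alleles of such genes
  cluster.

Residue and codon indices are 0-based internally (motif calls report
0-based half-open `start_codon`/`end_codon`); all user-facing tables use
1-based protein numbering.

**Motif calling** greedily selects up to `top_k = 6` non-overlapping
windows of maximal `w`, clipping each call's span against previous calls
and discarding spans shorter than `min_span = 5` codons. All ties break
toward the lower codon index, so the calls are deterministic.

## Coding-variant scoring

Each missense variant carries categorical calls from four effect
predictors, mapped to points:

| Predictor  | Categories and points                          | Max |
|------------|------------------------------------------------|-----|
| PolyPhen2  | probably = 1, possibly = 0.5, benign = 0       | 1   |
| Provean    | Deleterious = 1, Neutral = 0                   | 1   |
| SIFT       | Damaging = 1, Tolerated = 0                    | 1   |
| align-GVGD | C65/C55 = 1, C45/C35 = 0.5, C25/C15 = 0.25, C0 = 0 | 1 |

The **additive score** is the sum of tool points plus the residue score
`r`, with a maximum of 6. A missing predictor call imputes 0 points but
is counted in the `n_imputed` output column, since real annotation
sources are incomplete per variant; an *unknown* category string is an
error, never silently zero. The **combined impact score** multiplies the
additive score by the 21-codon window score and by the allele frequency
of one designated database column (default gnomAD, configurable via
`freq_db`): it prioritizes variants that are predicted damaging, sit in
conserved neighborhoods, and are common enough in the population to
matter. Frequencies are stored as fractions throughout; percent notation
appears only in reports, which avoids a ×100 ambiguity that plagues
mixed-source variant tables.

CADD is carried through as a passthrough column, never a summand — it
corroborates but does not enter the additive score. Nonsense and
frameshift variants get no additive score (the predictors are
missense-only) and pass through flagged `non_missense`. Condel-style
meta-predictors are deliberately excluded from the map: the four-tool
sum plus conservation is the scoring contract.

Ranking is by combined impact descending, with ties broken by additive
score then variant id, giving a stable total order.

## Regulatory-variant scoring

Noncoding variants are scored as `evidence_total × cadd`, where
`evidence_total` sums (a) the number of overlapping peaks per interval
track (ENCODE/Roadmap/GeneHancer-style BED annotations) and (b) any
per-source integer evidence counts supplied in `evidence_*` columns
(RegulomeDB-style line counts, which are not intervals). Treating every
source as contributing a count is the only reading that admits a uniform
sum; GeneHancer elements enter as intervals and their internal scores
are ignored. Overlapping peaks within one source are *not* deduplicated
— each record counts once.

Coordinates follow the half-open, 0-based BED convention for tracks and
1-based VCF-style positions for variants; the conversion lives in one
internal function (`variant_points()`), so a variant at position `pos`
is the 0-based point `pos - 1` and a point on an interval's start is
inside while a point on its end is not. Indels anchor at their leftmost
reference base. Raw PHRED-scaled CADD is used unrescaled. Scores above
500 are flagged as high (configurable reporting threshold).

`top_per_block()` reduces each LD block to its maximal-score variant(s).
LD block ids are inputs — the package does no LD imputation — and
all-zero blocks are reported in full with a `zero_score` flag rather
than dropped, since "no evidence" and "absent" are different answers.
`tissue_eqtl_tally()` histograms how many variants are eQTLs in exactly
k tissues from a supplied eQTL table; duplicate (variant, tissue) rows
collapse with a warning.

## Cohort enrichment

For each variant: carrier frequency = 100 × carriers / cohort size;
population frequency = unweighted mean of the selected database allele
frequencies in percent; fold = carrier % / population %. All three are
rounded **half away from zero to 2 decimals, before the ratio**. The
rounding convention is load-bearing: a mean of 0.205% must report as
0.21%, and 0.68/0.21 must give 3.24 — unrounded arithmetic gives 3.32
for the same inputs. Because the mathematical tie 0.205 is stored
fractionally below 0.205 in doubles, the rounding pre-rounds at 9
decimals before applying the half-away rule. No p-value is attached to
the fold: it is a descriptive ratio.

One caveat is flagged rather than corrected: the numerator counts
*individuals* carrying the variant while the denominator counts
*alleles*. This mixed basis is the screening convention the workflow
reproduces, and every enrichment table carries a
`freq_basis_mismatch = TRUE` column to keep it visible. Carrier counting
treats any genotype-positive individual (heterozygous or homozygous) as
one carrier.

`region_outliers()` flags variants whose HPO profile count AND CADD both
strictly exceed the region's empirical quantiles (default 0.99 each,
type-7 linear-interpolation quantiles, fixed and documented). Strict
exceedance means a constant axis can never produce outliers.

## The synthetic-data generator

The generator defines the study conditions; its defaults mirror the
scale of the screen: 220 sequences × 461 codons, six planted 21-codon
motifs at conservation 1.0 over a 0.4 background, a wobble column at
each motif centre, 100 coding and 200 noncoding variants, three peak
tracks of 50 intervals, 10 LD blocks, a cohort of 17,928 phenotyped
individuals, and a hit planted at 3.24-fold enrichment over a mean
population frequency of 0.205% (0.23% and 0.18% in the two database
columns) — which makes the planted carrier count exactly 122.

Column construction: each column has a planted modal amino acid carried
by each row with probability equal to the conservation level, other rows
diverging to a uniformly drawn different residue. Outside wobble columns
the modal amino acid keeps a single codon for the whole column — the
selection null is "no synonymous divergence", making the wobble signal
controllable — while wobble columns hold the residue fully conserved and
cycle the entire synonymous codon set across rows (s = 1 by
construction). The codon a column uses is drawn from a configurable
codon-usage table (uniform by default). Gaps are planted per column at a
configurable rate (default 0) and always as whole codons. HPO profile
counts are opaque labels with negative-binomial counts (size 1, mean 2
by default, exposed in the config): no ontology semantics are simulated,
and the distribution across variants is a modelling choice, not an
empirical fit.

The planted cohort hit's carrier count is derived from the *reported*
(2-decimal percent) mean population frequency — carriers =
round(cohort × fold × reported_AF% / 100), rounded half away from zero —
because that is the arithmetic that the enrichment layer inverts; the
recovery tests then get the planted fold back exactly whenever the
carrier count is integral, and within one carrier-rounding step
otherwise.

What the generator does **not** emulate: phylogenetic correlation
between sequences (rows are exchangeable, which is why permutation
invariance is testable), indel realism, LD structure beyond block
membership, site-specific codon bias, or the long-tailed allele
frequency spectra of real databases. Passing recovery tests therefore
demonstrates correctness of the scoring arithmetic and the planted-signal
detectability, not performance on real orthologs.

## Problem sizes and determinism

The test suite runs the full chain at reduced sizes (typically 30–150
sequences, 60–200 codons, ≤1000 variants) and the motif-recovery
property over 100 seeds at 100 sequences × 120 codons; the analysis
scripts run the full default scale. Every generator and the pipeline are
seeded and deterministic: identical configurations produce byte-identical
output files, which the tests verify by hashing.

## Known limitations

- The z/2 calibration of the residue score is anchored by a single
  point; alternative mappings are plausible and the score track exposes
  `c` and `z` so they can be applied downstream.
- The enrichment fold inherits the individual-vs-allele frequency-basis
  mismatch of the screening convention (flagged, not corrected); a
  binomial CI around the carrier frequency would be a natural extension
  but is intentionally not reported alongside the ratio.
- Effect predictors and CADD are consumed as annotations, never run;
  alignment construction, ORF trimming, PTM prediction, LD imputation,
  Hi-C looping and expression analyses are out of scope.
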