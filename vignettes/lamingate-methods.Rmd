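---
title: "Methods: somatic hypermutation quantification and Lamin B1 domain dynamics"
author: "lamingate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic hypermutation quantification and Lamin B1 domain dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamingate)
```

# Scope

`lamingate` implements two quantitative analyses that arise when studying how
the nuclear lamina gates somatic hypermutation (SHM) of immunoglobulin
variable (IgV) genes:

1. **SHM quantification** from clonal Sanger-style sequencing of a V-region
   amplicon: global alignment of each cloned sequence against the reference,
   substitution calling, AID hotspot (WRCY/RGYW) classification, the
   mutations-per-base-pair statistic with a minimum-coverage rule, and exact
   rate-ratio contrasts between experimental conditions.
2. **Lamin B1 domain analysis** from binned ChIP/input count tracks:
   depth matching, log-ratio computation, discretised maximal-scoring-segment
   domain calling with permutation significance (the "enriched domain
   detector" family of algorithms), and differential analysis between
   conditions — per-chromosome binding profiles, canyon/mesa detection,
   overlap of canyons with annotated IgV clusters, and locus-level fold
   changes.

A synthetic-data module generates every input the pipeline consumes, so all
behaviour is verifiable from seeds alone, with no external downloads.

# The SHM model and its estimator

## Mutation model

Each clone is mutated independently from the reference (clones are
independent bacterial colonies; there is no clonal phylogeny). Position $i$
of a clone substitutes with probability

$$p_i = \mu \cdot h^{[i \in H]} \cdot a,$$

where $\mu$ is the background substitution rate per bp per clone, $H$ is the
set of AID hotspot positions, $h \ge 1$ the hotspot rate multiplier, and
$a = 1$ for AID-proficient conditions or a small residual factor
(`aid_null_multiplier`, default 0.02) for AID-null conditions — loss of the
deaminase nearly abolishes both background and induced mutation. The
substituted base is drawn from a configurable 4x4 spectrum matrix (uniform
by default; an AID-like preset upweights C→T/G→A). Single-base indels are
off by default since the statistic of interest counts nucleotide
substitutions.

With $n$ reference positions of which $n_h$ are hotspots, the expected
fraction of substitutions falling in hotspots has the closed form

$$\frac{n_h h}{n_h h + n - n_h},$$

which the test suite uses as a recovery target.

## Hotspot definition

A position is a hotspot when it is the **C of a WRCY motif** or the **G of
an RGYW motif** (W = A/T, R = A/G, Y = C/T); RGYW is the same motif read on
the opposite strand, and only the deaminated C (or its complementary-strand
G) is labelled. Motif windows that would extend past either sequence end
never match. WRCY is checked first; since WRCY labels C positions and RGYW
labels G positions the two labels can never compete at a single position,
but the precedence is fixed for robustness.

## Alignment and the mutation statistic

Clones are full-length amplicons, so alignment is global (Needleman–Wunsch)
with affine gaps; defaults are match +1, mismatch −1, gap open −4, gap
extend −1, and a gap of length $L$ costs $\mathrm{open} + L \cdot
\mathrm{extend}$. The alignment engine is `Biostrings::pairwiseAlignment`;
it returns one deterministic optimal alignment, and the package does not
impose a particular tie-break among co-optimal alignments (for
substitution-only clones, the dominant case in this assay, the optimum is
unique).

Substitutions are mismatched base–base columns in reference coordinates;
indel columns are excluded from the numerator and reported separately. The
condition-level statistic is

$$\text{mut/bp} = \frac{\#\text{substitutions}}{\text{total aligned bp}},$$

and a condition passes QC only when at least 10,000 aligned base pairs were
assessed; below that the summary is still returned but flagged. Clone-level
QC discards likely cloning artifacts (>10% mismatches over aligned bases or
<80% of the reference length, both configurable); exact duplicate clones are
kept but flagged, with an optional collapse.

## Condition contrasts

Rates are compared with an exact conditional binomial test: given
$N = n_a + n_b$ substitutions, under equal per-bp rates $n_b \sim
\mathrm{Binomial}(N,\ \mathrm{bp}_b / (\mathrm{bp}_a + \mathrm{bp}_b))$.
The test and the rate-ratio confidence interval come from
`stats::poisson.test` on the two counts with their exposures; this is exact,
exposure-normalised, and makes no large-sample assumptions — appropriate for
the small substitution counts typical of clonal assays.

# LAD calling

## From counts to scores

ChIP and input tracks are integer counts over fixed-width bins (fixtures use
10 kb bins, a conventional scale for lamina-associated domains, so that a
2,000-bin genome stays desk-sized). To avoid normalisation bias the deeper
track is subsampled without replacement — a multivariate hypergeometric draw
across bins — so both totals match exactly, mirroring read-level
downsampling of the larger library; this preserves per-bin proportions in
expectation. The per-bin signal is $\log_2((c_i + \mathrm{pc}) / (i_i +
\mathrm{pc}))$ with pseudocount 1; bins with no reads in either track carry
no evidence and are masked.

Bins at or above a threshold score +1, all others −g. The threshold defaults
to the genome-wide 66.7th percentile of unmasked ratios (a minority of the
genome is lamina-associated) and the gap penalty to g = 3; both are exposed
in the configuration since the appropriate stringency depends on signal-to-
noise. Masked bins score −g: strong flanks can absorb them, but they can
never seed a domain.

## Maximal scoring segments and significance

Candidate domains are the all-maximal-scoring subsequences of the bin scores
(Ruzzo–Tompa): contiguous runs whose score cannot be improved by extension
or trimming and which are not contained in a higher-scoring overlapping run.
The implementation is the linear-time stack algorithm; the test suite checks
it against an independent brute-force interval enumeration.

Significance is Monte-Carlo: bin scores are permuted uniformly **within each
chromosome** (chromosome-scale shifts in binding are themselves a result of
interest, so they must not leak into the null), the maximal segment score of
each permutation is recorded, and a domain's p-value is
$(1 + \#\{\text{perm max} \ge \text{score}\}) / (n_{\mathrm{perm}} + 1)$,
followed by Benjamini–Hochberg adjustment across all candidate segments.

One numerical point deserves emphasis: the attainable p-value floor is
$1/(n_{\mathrm{perm}}+1)$, and all candidate segments — including the many
trivial one-bin runs a noisy genome produces — enter the BH correction. For
$m$ candidates and $k$ true domains, significance at level $\alpha$ requires
$1/(n_{\mathrm{perm}}+1) < \alpha k / m$. With $m$ of order 400 candidates
and a handful of true domains, 500 permutations are mathematically unable to
reach $q < 0.05$; the default is therefore `n_perm = 2000`. This is a
resolution requirement of the estimator, not a sensitivity tuning.

Known boundary behaviour: under overdispersed noise a domain's edge bins
occasionally fall below the threshold, and with gap penalty 3 two such dips
near a boundary trim that edge permanently. Planted-domain recovery is
therefore excellent but not exact at edges (bin-space Jaccard typically
0.94–1.0 per simulation).

# Differential binding

Differential analysis operates on the **ratio tracks**, not on domain calls:
the delta track is $\Delta_i = r^B_i - r^A_i$, masked where either input is
masked. Canyons (binding loss in B) are maximal runs of at least `min_width`
bins with $\Delta \le -\delta$; mesas are symmetric with $\Delta \ge
+\delta$ (defaults $\delta = 0.5$ log2 units, `min_width` 3 bins). Working
at bin level lets a canyon be detected even when it sits inside a broader
region of increased binding, which domain-set subtraction cannot represent.
Swapping the two conditions exchanges canyon and mesa calls exactly.

Overlap of called regions with an annotation (e.g. IgV clusters) is
summarised in bp with a Jaccard index, and calibrated by **circular
permutation**: regions are rotated within their chromosome by uniform random
offsets, which preserves their number, lengths and spacing — a much more
faithful null than scattering bins independently. Enrichment is
observed/expected overlap and the empirical p-value uses the same
$(1 + k)/(n + 1)$ estimator. Per-annotation Jaccard is computed against the
regions intersecting that annotation, matching the per-locus question
("does this cluster sit in a canyon?") rather than a genome-wide one.

Locus-level change is reported on the linear scale:
$\mathrm{fold} = \overline{2^{r^A}} / \overline{2^{r^B}}$ over the bins of
the interval, described as an x-fold reduction when above 1. A caveat worth
knowing: because depth matching rescales the whole ChIP library, a condition
with more total enrichment mass has all its ratios slightly compressed, so a
planted 3-fold drop at a locus reads out marginally below 3 when the
differential locus is a large fraction of the genome. The effect shrinks
with locus fraction and counts; simulations with a small locus recover 3.0
within Monte-Carlo error.

# The synthetic fixture set

`write_fixture_set()` emits, per configuration: the reference amplicon
(565 bp, GC 0.5 — the length of the V4-39 reporter fragment this kind of
assay sequences), one clone FASTA per SHM condition, ChIP/input bedGraphs
per binding condition, the planted-domain truth BED, the synthetic Ig
cluster BED, the resolved configuration and an MD5 manifest. Counts are
negative binomial with configurable dispersion (Poisson in the
$\mathrm{size} \to \infty$ limit), since overdispersion is typical of ChIP
bins and the Poisson limit keeps tests clean.

The default conditions emulate the study design: an unstimulated condition
at $\mu = 8 \times 10^{-4}$ subs/bp, a stimulated condition at 4.5x that
rate, and an AID-null twin of the stimulated condition; $h = 8$,
50 clones per condition (~28 kb assessed, well above the 10 kb rule and
chosen for the power of the AID-null contrast); a four-chromosome 10 kb-
binned genome where three Ig loci lose two-thirds of their Lamin B1
enrichment upon induction (a 3-fold drop), other domains persist, and the
fourth chromosome gains binding — so Ig-bearing chromosomes lose net
coverage and the smallest chromosome gains, echoing chromosome-scale
redistribution.

What the generator deliberately does **not** emulate: read-level sequencing
error and PCR artifacts (clones are error-free apart from the mutation
model), mappability and GC biases in ChIP bins, correlated noise along the
genome, and clonal phylogenies. Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to every artefact of real libraries.

# Worked example

```{r example, eval = FALSE}
config <- default_config(seed = 1)
out <- run_pipeline("report", config, out_dir = "lamingate_out")

# SHM: per-condition summaries and the induction fold change
out$shm$summaries$stimulated
out$shm$fold_changes$stimulated

# LADs and differential analysis
head(out$lads$control$domains)
out$diff$overlap
sapply(out$diff$locus_folds, `[[`, "fold")
```

Problem sizes used throughout the examples and tests — 565 bp references,
30–50 clones per condition, 2,000-bin genomes, 100 simulation replicates,
20-seed recovery studies, 2,000 permutations — are the package's chosen
desk-scale study conditions; they satisfy the assay's own coverage rule and
give Monte-Carlo errors comfortably below the effect sizes of interest.

# Limitations

* Domain boundaries are bin-resolution and subject to the edge-trimming
  behaviour described above.
* The exact conditional rate-ratio test conditions on total substitutions;
  it does not model clone-level overdispersion of mutation counts.
* Circular permutation preserves spacing within a chromosome but assumes
  the annotation is fixed; it does not condition on GC or mappability.
* The depth-matching compression of fold changes is inherent to
  input-normalised ratio tracks and is documented rather than corrected.
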