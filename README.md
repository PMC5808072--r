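# lamingate

Quantitative analysis of **somatic hypermutation (SHM)** in immunoglobulin
V-region clone sets and of **Lamin B1 lamina-associated domains (LADs)**
from ChIP/input binned tracks, with a fully seed-deterministic synthetic
data generator so every result is reproducible on a desk with no downloads.

The package is aimed at B-cell immunologists and regulatory genomicists who
ask two linked questions: how strongly is an IgV reporter mutating under a
given stimulus, and is the nuclear lamina releasing (or re-capturing) the
corresponding loci?

## What it computes

**SHM quantification** (`align_clone`, `call_substitutions`,
`classify_hotspot`, `summarize_condition`, `compare_conditions`)

* Global affine-gap alignment of each cloned amplicon against the reference;
  substitutions are mismatched base–base columns in reference coordinates,
  indels are counted separately.
* AID hotspot classification: a substitution is hotspot-associated when it
  hits the C of **WRCY** or the G of **RGYW** (W = A/T, R = A/G, Y = C/T;
  RGYW is WRCY read on the opposite strand).
* The condition statistic `mut/bp = substitutions / aligned bp`, flagged
  unless ≥ 10,000 aligned bp were assessed, plus substitution spectrum,
  C/G fraction and hotspot fraction.
* Exact conditional rate-ratio test between conditions: given
  `N = n_a + n_b`, under the null `n_b ~ Binomial(N, bp_b/(bp_a+bp_b))`,
  with exact CI on the rate ratio.

**LAD calling** (`match_depth`, `compute_log_ratio`, `score_bins`,
`maximal_segments`, `assign_significance`, `call_lads`)

* Exact depth matching by hypergeometric subsampling of the deeper library;
  per-bin `log2((chip+pc)/(input+pc))`; discretisation to +1 / −g scores at
  a percentile threshold; all maximal-scoring segments (Ruzzo–Tompa); and
  within-chromosome permutation p-values with BH correction.

**Differential binding** (`detect_canyons_mesas`,
`chromosome_binding_profile`, `overlap_annotation`, `locus_fold_change`)

* Bin-level delta tracks between conditions; **canyons** (runs of
  `delta <= -0.5` log2 units, ≥ 3 bins) and **mesas** (symmetric gains);
  per-chromosome coverage shifts; circular-permutation overlap enrichment of
  canyons with annotated Ig variable clusters; linear-scale locus fold
  changes.

**Synthetic data** (`generate_reference`, `simulate_clones`,
`simulate_binding_tracks`, `write_fixture_set`) — an AID-biased mutation
model over a 565 bp amplicon and negative-binomial ChIP/input tracks with
planted domains, all pure functions of (config, seed).

## Worked example

```r
library(lamingate)
out <- run_pipeline("report", default_config(seed = 1),
                    out_dir = "lamingate_out")

out$shm$summaries$stimulated
#> mutation_summary 'stimulated': 50 clones, 28250 bp assessed
#>   141 substitutions (0.00499 per bp), hotspot fraction 0.369

out$shm$fold_changes$stimulated
#> fold change stimulated vs unstimulated: 4.55 (95% CI 3.07-6.94), p = 5.83e-18

out$diff$overlap
#> overlap_report: 680000 bp overlap, Jaccard 0.283, enrichment 5.65, p = 0.002

out$diff$locus_folds$IGH_synthetic
#> locus_fold_change: 2.93-fold reduction over 30 bins
```

Reading the numbers: the stimulated condition mutates at ~5.0 × 10⁻³
substitutions per aligned bp — a 4.55-fold induction over the unstimulated
condition, with an exact 95% CI excluding 1. Canyons of Lamin B1 binding
are 5.7-fold enriched over the synthetic Ig clusters relative to a circular-
permutation null, and the synthetic IGH locus shows a ~3-fold binding
reduction, matching the planted 6x→2x enrichment drop.

The same stages are available from a shell:

```sh
Rscript inst/cli/lamingate.R report --seed 1 --out lamingate_out
```

Stage outputs are TSV/BED/bedGraph files with `#` headers carrying the tool
version, configuration hash and seed (JSON outputs carry a `_meta` field);
identical (config, seed) runs are byte-identical.

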