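# paleodup

Duplicate genes are the raw material of plant genome evolution: ancient
whole-genome duplications (WGDs, polyploidy) leave thousands of paralog
pairs whose survival is non-random, while small-scale (tandem) duplication
continuously creates young copies. Testing hypotheses about *biased
retention* — e.g. the Gene Balance Hypothesis prediction that
dosage-sensitive genes such as transcription factors survive WGD but not
tandem duplication — requires a pipeline that (i) finds paralog pairs,
(ii) classifies each pair's duplication mechanism from gene order,
(iii) dates pairs by synonymous divergence, and (iv) tests gene-function
categories for over-representation within mechanism- and age-defined
groups of paralogs.

`paleodup` implements that pipeline for R, plus a synthetic-genome
simulator with a known duplication history so every stage can be verified
against ground truth without any external database.

## What it computes

* **Homology** — all-vs-all protein similarity (internal BLOSUM62
  affine-gap aligner with a Karlin–Altschul e-value surrogate, or
  ingested BLAST outfmt-6 files), filtered at e-value ≤ 1e-20, identity
  ≥ 50%, alignment length > 300 bp, mismatches < 550, gap opens < 30,
  self hits removed, both genes in the same family.
* **Mechanism** — DAGchainer-style dynamic programming over gene-rank
  anchors finds collinear chains (WGD); same-chromosome pairs with ≤ 10
  intervening genes are tandem; the rest undefined.
* **Divergence** — protein-guided codon alignment, then Ks/Ka by
  counting methods: a YN00-style estimator (kappa from
  fourfold-degenerate sites, F3x4-weighted mutational-opportunity site
  counts, pathway-averaged difference counts, multiple hits corrected by
  inverting the expected counts under the fitted codon model) and
  classic NG86 (Jukes–Cantor). Retention filter: Ks ≤ 2 and SE < 0.5.
* **Pairing** — each gene keeps its lowest-Ks pair, preferring WGD over
  tandem over undefined pairs (rules I–III).
* **Age statistics** — Ks histograms; a Kolmogorov–Smirnov test against
  the constant birth–death null (exponential age density truncated to
  (0, 2], rate fitted by ML, p by Lilliefors-style parametric
  bootstrap); SiZer maps (local-linear Gaussian kernel regression of
  histogram counts, bandwidths h ∈ [0.05, 5]) classifying each (x, h)
  cell as significantly increasing / decreasing / flat / sparse.
* **Enrichment** — hypergeometric over/under-representation of GO terms
  (annotations propagated up the is_a/part_of DAG) in eight paralog
  groups: WGD, tandem, and Ks ranges A (0,0.5], B (0.5,1], C (1,1.5],
  D (1.5,2], E (0,1], F (1,2]; background set size ≥ 10,
  Benjamini–Hochberg correction.

## Worked example

Simulate a genome with one WGD at Ks 1.0 that retains transcription
factors (GO:0003700) with probability 0.9 vs 0.4 baseline, plus tandem
duplication, and analyse it:

```r
library(paleodup)

cfg <- sim_config(n_chromosomes = 2, n_ancestral_genes = 300,
                  wgd_events = list(wgd_event(1.0, 0.4, 0.9, "GO:0003700")),
                  tandem_rate = 0.15, seed = 42)
sim  <- simulate_genome(cfg)
b    <- sim$bundle
core <- paralog_pipeline_core(b$proteins, b$cds, b$coords, b$families)
genome_summary(core, nrow(b$coords))
#> $initial_genes    : 516
#> $duplicate_pairs  : 267
#> $mechanism        : WGD 171, tandem 73, undefined 23
#> $ks_ranges        : (0,0.5] 13, (0.5,1] 72, (1,1.5] 95, (1.5,2] 5, >2 0
#> $failed_estimates : 82     # saturated pairs, mostly compound ages > 2
```

The mechanism counts partition the 267 candidate pairs, Table-1 style.
The Ks age distribution rejects constant duplicate birth and death:

```r
ks_gof_test(core$ks_filtered$ks[core$ks_filtered$ks > 0], n_boot = 200)
#> Kolmogorov-Smirnov test vs constant birth-death null (one-sample)
#>   D = 0.255, p = 0.004975 (200 bootstraps), fitted decay rate = -0.02687, n = 183
```

and the biased GO term is recovered as over-represented among
WGD-derived paralogs:

```r
onto <- read_obo(system.file("extdata", "mini_go.obo", package = "paleodup"))
anno <- propagate_annotations(b$go, onto)
enr  <- ora_all_groups(build_groups(core$rep_pairs), annotations = anno,
                       exclude_terms = onto$roots)
subset(enr, group == "WGD" & term == "GO:0003700")
#>         term group  k   n  K   N       raw_p corrected_p direction
#> 1 GO:0003700   WGD 55 246 61 323 0.002194826  0.01316896      over
```

A SiZer map of the WGD subset (`sizer_map(core$ks_filtered$ks[
core$ks_filtered$label == "WGD"])`) shows the significantly increasing
gradient approaching Ks 1.0 and the decreasing gradient after it — the
signature of a WGD peak.

For file-based runs use `run_pipeline()` with a YAML/JSON config (see
`?run_pipeline`), or the CLI wrapper `inst/cli/paleodup.R` with
subcommands `simulate`, `run`, `homology`, `mechanism`, `ks`,
`agestats`, `enrich`.

## Vignette

`vignettes/paleodup-methods.Rmd` documents the models and the numerical
choices: the codon substitution model and its Ks calibration, why the
default multiple-hit correction inverts model expectations instead of
the pooled Kimura closed form, the truncated-exponential reading of the
birth–death null, SiZer confidence-interval details, what the simulator
does and does not emulate, and known limitations.
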