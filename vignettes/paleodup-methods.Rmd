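---
title: "Models and methods behind paleodup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind paleodup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`paleodup` analyses duplicate-gene retention in (plant) genomes: it
detects paralog pairs, classifies their duplication mechanism from gene
order, dates them by synonymous divergence (Ks), and tests paralog
groups for biased functional retention. This vignette documents the
models, the tunable parameters, and the numerical decisions — the things
a maintainer or reviewer would want spelled out.

## The synthetic world

Real inputs for this kind of analysis are genome-database releases that
cannot be bundled with a package. The simulator
(`sim_config()`/`simulate_genome()`) therefore generates genomes with a
*known* duplication history, and all quantitative checks in the test
suite measure recovery of that ground truth.

The simulated genome is a set of chromosomes carrying ordered
protein-coding genes (default: 5 chromosomes, 2000 ancestral genes of
150–400 codons). Ancestral sequences are uniform random sense codons
behind an ATG. Three event types shape the duplicate content:

* **WGD**: every chromosome is duplicated; the new copy of each gene
  survives with probability `retention_baseline`, or
  `retention_prob_biased` when the gene carries the designated GO term.
  Survivors keep their ancestral order on the duplicated chromosome, so
  collinear chains exist by construction. The event's age (`target_ks`,
  default 1.0) gets a per-pair lognormal jitter (sdlog 0.1), producing
  peaks of realistic width rather than spikes.
* **Tandem duplication**: Poisson per gene lineage (default rate 0.1),
  ages uniform on (0, 2], the copy inserted 0–2 genes downstream. The
  uniform ages produce the descending-slope shape of tandem Ks
  distributions as an emergent property.
* **Sequence divergence** happens along the resulting duplication
  genealogy: each duplication evolves the parent sequence down two
  branches, and a per-gene divergence-depth ledger records, for every
  truth pair, the realized expected pairwise divergence on the
  genealogy (so a gene that later duplicates again correctly inflates
  the age of its earlier pair).

What the simulator does **not** emulate: intergenic DNA, introns,
transposable elements, chromosome rearrangements, gene loss outside
duplication events, rate variation among sites/genes, and alignment
ambiguity from repetitive sequence. A green recovery test therefore
establishes correctness of the pipeline's logic and statistics under a
clean model of duplication — not robustness to annotation noise or
assembly artefacts in real genomes.

### The codon model and the meaning of `target_ks`

Sequences evolve under a GY-style codon process: single-nucleotide
changes between sense codons, rate multiplied by `kappa` (default 2) for
transitions and by `omega` (default 0.1) for nonsynonymous changes; stop
codons are unreachable (equivalently, substitutions creating stops are
rejected). Descendant states are drawn exactly from the matrix
exponential of the rate matrix, not by event-by-event simulation.

`target_ks` is defined as the expected number of synonymous
substitutions per *synonymous site*, where sites are counted as
mutational opportunity — kappa- and frequency-weighted, stops excluded —
i.e. the same currency the YN00-style estimator reports. This makes
estimator recovery a meaningful end-to-end oracle: the simulator draws
stochastic realizations of the process, the estimator counts differences
and inverts them, and the two agree only if both are right.

`omega = 0.1` (strong purifying selection, typical of retained plant
duplicates) is also what keeps the oldest simulated pairs (Ks near 2)
above the 50% protein-identity homology filter; with `omega` much above
0.2 the oldest tandem pairs would silently fall out of the candidate
universe.

## Homology

`align_all_vs_all()` performs global affine-gap alignment (BLOSUM62, gap
open 11, extend 1) for every within-family pair (all pairs when no
family map is given), and reports the standard 12 tabular-hit columns.
The e-value surrogate uses the Karlin–Altschul form with the published
gapped BLOSUM62 constants (λ = 0.267, K = 0.041) and query-length ×
database-residues as search space; for a global aligner this is a
calibration convenience, not a rigorous statistic, which is fine because
the filters are what consume it and real BLAST output can be supplied
instead (`parse_hits()`).

The filters and their exact inclusivity: e-value ≤ 1e-20, identity ≥
50%, alignment length strictly > 300 bp (aligned protein columns × 3;
for nucleotide-level hits the reported length is used directly),
mismatches < 550, gap opens < 30, self hits removed, both genes in the
same family. When reciprocal hits pass, the lower e-value (tie: higher
bitscore, then lexicographic query) becomes the pair's source hit.

## Mechanism classification

Anchors are candidate pairs placed in gene-rank coordinates (ordinal
position along the chromosome, not base pairs, so synthetic and real
genomes are treated identically). Chains are found per chromosome pair
by highest-scoring-chain dynamic programming: both indices must strictly
advance (a mirrored pass finds reverse/antiparallel chains), per-axis
gaps are capped at 20 genes, gap cost is 1 per skipped gene per axis,
anchor score is min(50, −log10 e-value) floored at 1, chains need ≥ 5
anchors, and chains are extracted greedily best-first with used anchors
removed. These numbers restate DAGchainer-style defaults in gene-index
space; they are a documented reconstruction, all configurable via
`chain_params()`. For within-chromosome self-comparison, anchors with
|Δrank| ≤ 11 are excluded so tandem arrays cannot masquerade as
collinear segments.

Labels: chain member → WGD; else same chromosome with ≤ 10 intervening
genes → tandem; else undefined. Chain membership deliberately beats the
tandem window (a configurable choice; the original tool chain is
ambiguous on this point). Pairs with missing coordinates are labelled
undefined with a warning.

## Ks estimation

`codon_align()` aligns the translated proteins globally and
back-translates onto codons; columns with a gap in either row, and
codons containing ambiguity characters, are dropped.

`estimate_ks()` implements two counting estimators:

* **NG86**: equal-weight site fractions (stop changes excluded from
  numerator and denominator) and equal-weight pathway averaging for
  multi-nucleotide codon differences, Jukes–Cantor corrected, with the
  standard delta-method variance.
* **YN00-style** (default): kappa estimated from fourfold-degenerate
  third positions via the Kimura two-parameter decomposition; site
  counts weighted by kappa and F3x4 codon frequencies; differences
  counted by pathway averaging split into transitions and
  transversions.

For the multiple-hit correction, the classic route — pooling all
synonymous sites into one Kimura two-parameter site class
(`correction = "k80"`) — is *systematically inconsistent* for codon
data: twofold-degenerate sites accept only transitions, fourfold sites
accept everything, and correcting the pooled proportions overshoots.
Computing the exact expectation under the generating model shows +2.5%
bias at Ks 0.5, +10% at 1.0 and +47% at 1.5. The default
(`correction = "model"`) therefore solves for the divergence time at
which the *expected* per-codon synonymous difference count under an
HKY-type codon model — built from the estimated kappa, omega and F3x4
frequencies, with omega (and kappa, when fourfold sites are saturated)
iterated to convergence — matches the observed count. This is still a
distance/counting method (two moments, no likelihood surface), remains
within the "approximation of maximum likelihood" family, and recovers
simulated Ks within a few percent across (0, 1.5]. The SE is the
delta-method standard error of the observed synonymous proportion
divided through the slope of the expectation curve; it reduces to the
familiar closed forms in the low-divergence limit. Saturation (observed
differences at the plateau of the expectation curve) is flagged and the
pair excluded downstream — on compound duplication histories (a tandem
copy of a WGD duplicate) this happens routinely and mirrors the
real-world "Ks > 2 excluded" bookkeeping.

Retention filter inclusivity: Ks ≤ 2 (inclusive), SE < 0.5 (strict).
Pairs with Ks exactly 0 (identical sequences) pass this filter but are
excluded from the age statistics, whose domain is (0, 2].

## Representative pairs

Per gene: a WGD-labelled pair beats tandem beats undefined, and within
the winning class the lowest-Ks pair is kept (Ks ties break to the
lexicographically smaller partner id — the underlying method
description is silent, determinism decides). A pair is never blocked
because its partner was claimed under another rule, so the output is
the union of per-gene winners, deduplicated; one pair per gene is
emitted. Re-running selection on its own output is the identity.

## Age statistics

Histograms use right-closed bins of width 0.05 on (0, 2] (the bin width
is a visual-granularity choice; sources typically do not print one).

**Goodness of fit.** Constant duplicate birth with constant per-pair
death gives an exponential age density for surviving duplicates;
truncated to the observable window (0, 2] it becomes the null model.
The decay rate is fitted by maximum likelihood (the mean is a monotone
function of the rate; negative rates, i.e. increasing densities, are
allowed). Because the rate is estimated from the data, the classic K-S
p-value would be conservative; the p comes instead from a
Lilliefors-style parametric bootstrap that refits the rate on every
simulated dataset. A two-sample variant (data vs one simulated null
sample) is available; one-sample is the default. Calibration is checked
in the acceptance suite: type-I error at the 5% level within
[0.03, 0.08] over 500 null replicates.

**SiZer.** Following the scatterplot-smoother formulation (inputs are
histogram bin centers and counts, matching the conventional R call with
`degree = 1, derv = 1`), each cell of a log-spaced bandwidth grid
(default 21 bandwidths in [0.05, 5]) × linear location grid (default 41
points) gets a local-linear Gaussian-weighted slope with a pointwise
t-interval (local residual variance; degrees of freedom from the
effective sample size ESS = Σw/K(0); `bonferroni = TRUE` gives the
simultaneous-band variant). States: increasing if the CI lower bound is
positive, decreasing if the upper bound is negative, flat otherwise,
sparse where ESS < 5. A numerical floor of 1e-12 on the slope SE keeps
exactly-constant data from being classified by floating-point residue.

## Enrichment

Groups: WGD, tandem (from mechanism labels) and the Ks ranges A–F
(regardless of mechanism — undefined pairs contribute; the method
description implies but does not state this, so it is a flagged,
configurable reading). Gene sets are unions of both pair members,
deduplicated (the binary-ORA reduction of "best scoring replicate
treatment").

The default background is the duplicate universe itself (all genes in
any filtered pair), matching an analysis restricted to duplicates; a
whole-genome background is available. Per term with background count
K ≥ 10: hypergeometric upper tail for over-representation, lower tail
for under-representation, reported direction is the smaller side;
Benjamini–Hochberg correction within each group. Annotations are
propagated up the ontology (is_a and part_of); root terms are excluded
from testing. The OBO parser is minimal by design (id/name/namespace,
the two edge types, obsolete filtering) and detects cycles by DFS,
naming the cycle.

## Determinism and seeds

`simulate_genome()` seeds R's RNG from its config (byte-identical
bundles for equal configs); `run_pipeline()` seeds from its config's
`seed`. All stochastic tests fix seeds. The acceptance false-positive
check builds its 100 replicate universes from the truth tables of
sequence-free simulations: the enrichment stage's error level is what
that criterion measures, and sequence-level noise is exercised by the
power half of the same test, which runs the full pipeline.

## Known limitations

* The internal aligner is global; highly length-discordant paralogs
  (e.g. domain losses) get lower identity than a local aligner would
  report, and the e-value surrogate is a calibration, not a statistic.
  Real BLAST tabular input is the intended path for real genomes.
* The YN00-style estimator omits codon-usage weighting of pathway
  choices; with strongly biased codon usage its Ks can drift by a few
  percent (F3x4 site weighting captures the first-order effect).
* Chain extraction is greedy; pathological anchor sets could split one
  true chain into two, though the DP itself is exact per extraction
  (verified against brute force).
* The birth–death null assumes a constant death rate; age-dependent
  loss (diploidization) is precisely the alternative the test is meant
  to detect, not something it models.
* Multi-WGD configurations are supported, but cross-event sibling pairs
  make the truth table's direct-pair view of "mechanism" increasingly
  partial as events accumulate.
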