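---
title: "Methods: the two-site APA model and its surrounding pipeline"
author: "apashift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-site APA model and its surrounding pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apashift)
```

# The two-site model

Alternative polyadenylation (APA) with two sites leaves a characteristic
step in RNA-seq coverage over the 3′ UTR: upstream of the proximal cleavage
site both isoforms contribute reads, downstream only the distal (long)
isoform does. `fit_two_site_model()` models per-base coverage $c_i$,
$i = 1..L$, as

$$E[c_i] = w_\text{long} + w_\text{short}\,\mathbf 1(i < b), \qquad
  w_\text{long}, w_\text{short} \ge 0,$$

with a single change point $b$ shared across all samples of a gene. For a
fixed $b$, the non-negative least-squares weights have the closed form
$w_\text{long} = \max(0, \overline{c_{i \ge b}})$ and
$w_\text{short} = \max(0, \overline{c_{i<b}} - w_\text{long})$, evaluated
per sample. $b$ is chosen by exhaustive search over
$[m, L - m)$ (edge margin $m = \max(10, \lceil 0.01 L\rceil)$ nt, so the
change point is identifiable on both sides), minimising the summed squared
error with each sample's contribution divided by its total coverage.
The normalisation stops deep samples from dominating the shared
breakpoint; it also means the objective is scale-free per sample, and a
sample's own fitted PDUI is exactly invariant to rescaling its coverage.
Ties in the objective go to the smallest $b$ (shortest proximal UTR), a
determinism convention. The Percentage Distal poly(A) site Usage Index is
$\mathrm{PDUI} = w_\text{long} / (w_\text{long} + w_\text{short}) \in
[0, 1]$: 1 when all reads are distal-consistent, 0 when all are proximal.
When $w_\text{long} + w_\text{short} = 0$ the PDUI is undefined and
propagates as missing, excluded from group means and tests.

Exhaustive search is the production algorithm, not an approximation: with
cumulative sums each candidate costs $O(1)$ per sample, so a gene costs
$O(L \cdot n_\text{samples})$ and a 200-gene, 12-sample cohort fits in
about a second.

**Assumptions.** Exactly two sites; the annotated UTR end is the distal
site (no de-novo extension beyond the annotation — a known blind spot of
coverage-based methods); coverage noise roughly homoscedastic on the scale
of the normalised objective. Genes violating the two-site assumption get a
compromise breakpoint; their PDUI remains a usable one-number summary of
proximal-vs-distal mass.

**Coverage gating.** Samples with mean coverage below `min_mean_coverage`
(default 30 reads/base) are excluded from the fit; a gene with fewer than
2 surviving samples in either group is reported as `insufficient_coverage`.
The default is this package's choice of a conservative gate and is fully
configurable; analyses of shallow data should lower it deliberately rather
than silently.

# Differential testing

`differential_apa()` converts each gene's fit into a 2×2 table of
isoform-attributable *read mass*: per group, $\sum_s w_\text{long,s}(L-b)$
vs $\sum_s w_\text{short,s}\, b$, rounded to integers. A two-sided Fisher
exact test is applied and Benjamini–Hochberg adjustment made across all
tested genes. Because read mass grows with depth and UTR length, the test
is extremely powerful, and nearly any real usage difference reaches tiny
p-values; the biological filter is the companion requirement
$|\Delta \mathrm{PDUI}| > 0.2$ between group means. A gene is flagged
significant only when adjusted $p < \alpha$ (default 0.05) **and** the
PDUI difference exceeds `min_diff` (default 0.2). The contingency
construction from fitted weights (rather than raw read counts) is this
package's explicit design choice; both thresholds are exposed. The test is
two-sided; direction is carried by the sign of `pdui_diff` and assessed at
cohort level by the KS shift test, keeping the per-gene and group-level
questions separate.

# TIN quality control

The Transcript Integrity Number of a track with coverage proportions
$p_i$ is $100\,e^{H}/k$ with $H = -\sum p_i \ln p_i$: 100 for perfectly
uniform coverage, $100/k$ for a single covered base, 0 by convention for an
uncovered transcript. It is computed densely at every base (the
dense-sampling limit of the usual sampled formula), making it exact,
scale-invariant and permutation-invariant. The two filters follow the
standard order with strict inequalities: samples whose mean TIN — zeros
removed before averaging — is below 40 are dropped first; then any gene
with TIN below 60 in at least one retained sample is dropped. Zero TINs
are excluded from the sample mean yet still trigger the per-transcript
filter, a literal reading of the rule. TIN is computed on whatever
interval the gene-model file provides (here, 3′ UTRs); with whole-transcript
models the same code applies unchanged.

# Poly(A) evidence

Reads that end in an untemplated adenosine run are direct evidence of a
cleavage site. `trim_polya()` removes the maximal terminal A-run iff it is
at least `min_a = 3` long — internal runs are never touched, and trimming a
read whose templated end is itself A-rich can legitimately expose another
run (the operation is not idempotent by design). `call_polya_sites()`
single-linkage-clusters templated 3′ ends within 10 nt per
(chromosome, strand), positions each cluster at its modal end (ties to the
smallest coordinate) and discards clusters with support below 2.
`validate_proximal_site()` accepts a predicted site when a cluster lies
within ±50 nt (nearest cluster wins; ties to higher support, then smaller
coordinate). Tail-length, window and support thresholds are exposed
parameters with conservative defaults, not claims about any particular
dataset. Genome re-alignment of trimmed reads is out of scope: at package
scale the read origins are supplied (by the simulator's FASTA headers, or
by any aligner in real use), and the validation logic operates on
coordinates.

# Cohort-level statistics

* `ks_group_shift()` reduces the PDUI matrix (typically restricted to
  significant genes) to one mean per gene per group and applies a
  one-sided two-sample KS test between the two distributions of gene-level
  means. This is the coherent-direction question — do significant events
  collectively prefer longer 3′ UTRs in one group?
* `variance_contrast()` compares per-gene across-sample PDUI variances of
  two cohorts with a one-sided Wilcoxon rank-sum test (e.g. gray-matter
  cohorts show larger PDUI variability than white-matter ones).
* `variability_quartiles()` ranks genes by the absolute group-mean PDUI
  difference, cuts the top and bottom `floor(n/4)` (ties broken by gene id
  for determinism) and compares within-control-group PDUI standard
  deviations of the two quartiles, one-sided (top > bottom).

The Wilcoxon policy throughout: exact when both sides have ≤ 25
observations and no ties, tie-corrected normal approximation otherwise. A
fully tied input makes the tie-corrected variance zero (0/0); that
degenerate case is reported as no dominance, $p = 0.5$.

# Enrichment

The expressed background is genes with across-sample median TPM strictly
greater than 1 (`tpm_from_counts()`, `expressed_background()`). Overlap
tests are upper-tail hypergeometric. `length_aware_enrichment()` corrects
for length bias with a probability-weighting function estimated by
isotonic regression of the hit indicator on gene length — monotone,
parameter-free and deterministic, in place of a spline fit; the null is
either weighted resampling without replacement (default, 10,000 draws) or
a Wallenius non-central hypergeometric approximation evaluated by its
one-dimensional integral representation with category odds taken from the
mean weight inside vs outside the category.

`gsea_pdui()` scores genes by the difference of group-mean PDUIs — stable
for groups as small as 2–3 samples, where signal-to-noise metrics are
erratic (signal-to-noise is available as an option with SD floors) —
ranks them, and scores each set with the unweighted KS running-sum
enrichment score ($\pm 1$ bounds, antisymmetric under ranking reversal).
Sets with fewer than 10 tested genes are excluded. Significance uses
phenotype-label permutation when ≥ 7 samples exist, otherwise gene-set
permutation (logged). Note the granularity floor of phenotype permutation:
with 6 + 6 samples, the ~8% of label splits nearly aligned with the true
grouping reproduce a genuine module's signal, so even a perfect set cannot
reach $p \ll 0.08$ in that mode; the FDR q follows the standard
normalised-ES procedure.

`scan_motif()` does exact IUPAC matching (default motif: the CRE consensus
TGACGTCA) on both strands, mapping reverse-complement hits to forward
coordinates and counting a doubly-matched position once — for the
palindromic default, "complement" and "reverse complement" coincide, so
the reading is observationally neutral.

# The synthetic cohort generator

`simulate_cohort()` inverts the two-site model: expected coverage `depth`
before the true breakpoint and `depth * pdui` after, times an optional
degradation profile and multiplicative log-normal noise (unit mean), then
rounded to non-negative integers. Its defaults *are* the study conditions
of the test suite: 200 genes, UTRs of 300–1500 nt with breakpoints at
30–70% of the UTR, 6 + 6 samples, depth 50 reads/base (Gamma-distributed
across samples, squared CV 0.1), true PDUIs Beta-distributed with group
means 0.4 (control-like) and 0.55 (case-like, a distal shift) at
concentration κ = 20, noise SD 0.1, no degradation bias. Where no
quantitative effect size is established for such cohorts, these values
were chosen once as realistic for post-mortem brain RNA-seq — modest
shift, substantial between-sample heterogeneity — and are documented
defaults, not estimates. Lowering κ emulates the greater PDUI variability
of gray-matter cohorts; `degradation_tin_target` grades a one-parameter
5′→3′ exponential decay whose rate is solved by bisection against the TIN
formula itself (feasible targets are $(100/L, 100]$; the all-ones profile
is returned at 100).

A-tailed reads (50 nt, ending at a true cleavage site with 3–10
untemplated A's) are emitted at each of the two sites at rate
Poisson(`polya_read_rate` × depth) per sample, *independent of isoform
usage*, so that both true sites carry evidence at any PDUI and the
validation invariant — every true site recovered at window 10 on clean
data — is a property of the pipeline, not of a lucky parameter draw.
Per-gene RNG streams are derived from the root seed by counter: outputs
are byte-identical for a fixed seed and adding genes never reshuffles
existing ones.

**What the generator does not emulate:** read-level artifacts
(fragmentation, GC bias, sequencing error, internal priming), multi-site
(> 2) UTRs, unannotated distal extensions, expression-level confounding
between groups, and correlated gene modules. Passing recovery and
calibration tests on this generator therefore demonstrates correctness of
the estimator and tests under the model's own assumptions — not
performance on real tissue, where mapping artifacts and annotation error
dominate.

# Numerical and design choices

* Coordinates are 0-based half-open everywhere internally (bedGraph/BED
  native); 1-based tabular inputs are converted on read. Minus-strand
  coverage is stored 5′→3′ in transcript orientation so a breakpoint index
  always means distance from the UTR start; the reversal is an involution
  exercised by round-trip tests.
* Missing bedGraph positions are coverage 0 (bedGraph semantics), not
  missing data.
* Fisher tables are rounded to integer read mass; a zero-margin table
  yields $p = 1$ by convention.
* Simulated coverage is rounded to integers, so noise-free inversion is
  exact only where `depth * pdui` is integral; recovery tests use such
  grids, and the stochastic recovery criterion (median PDUI error < 0.05)
  covers the general case.
* Results tables are written with 6-significant-digit floats and rows
  ordered by gene id, making re-runs byte-identical; the pipeline manifest
  records md5 hashes, seed and package version.
* Problem sizes used by the test suite — 200-gene cohorts for recovery,
  null calibration and directional detection; 200 replicates for the
  quartile-null calibration; 10,000 resamples for the bias-free
  enrichment limit — were chosen to make Monte-Carlo error small relative
  to the tested tolerances while keeping the default suite fast.

# Known limitations

Two sites per gene; annotated distal ends only; no internal-priming
filter on poly(A) evidence (flagged, not implemented); enrichment
corrects length bias only (no GC or mappability weighting); the Fisher
read-mass test inherits Fisher's anti-conservativeness under
between-sample overdispersion, which is why the PDUI-difference filter is
mandatory for significance calls.
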