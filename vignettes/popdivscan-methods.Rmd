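---
title: "Models and methods behind popdivscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popdivscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

popdivscan studies how three parapatric populations diverge under an
isolation-with-migration (IM) demography, and how selection is then detected
against that demographic null. Its reference system is *Populus davidiana*
in China: a Northeast (N), a Central (C) and a South (S) population, with the
ancestor splitting first into Northern and Southern lineages and the Northern
lineage later splitting into N and C, all three exchanging migrants
asymmetrically. This vignette explains the models, the tunable parameters,
the numerical choices, and — importantly — what the synthetic-data tests do
and do not demonstrate about real data.

## The structured coalescent engine

Genealogies are simulated backward in time. Within a population of diploid
effective size $N_e$, $k$ lineages coalesce at rate $k(k-1)/(4N_e)$ per
generation; a lineage in population $i$ migrates (backward) to $j$ at rate
$m^{(b)}_{ij}$; at a split time, all lineages of the derived population merge
into the ancestral one; size changes (including bottlenecks) are
piecewise-constant events. Time is handled in generations everywhere inside
the package — years appear only at the I/O boundary, converted at
`generation_years` (default 15, the poplar convention; mutation rate default
$2.5\times10^{-9}$ per site per year).

Migration direction deserves care. Model objects store *forward-time* rates
`migration[from, to]` — "the per-generation migration rate from N to C" in
the usual demographic sense — and the engine converts them to the backward
lineage-movement rates it needs (`backward[i, j] = forward[j, i]`). A single
time-constant matrix is supported (rows/columns are zeroed automatically
when a population merges); none of the demographies this package targets
needs epoch-dependent migration, so that generality was deliberately left
out.

Between the two splits the merged N+C ancestor keeps the size of its
surviving slot (N). The fitted demography we ship (`davidiana_im_model()`)
prints no size for that intermediate ancestor, and inventing one would be
worse than documenting the convention; the deep ancestral size
$N_{e\text{-ANC}}$ applies from the deep split backward.

Mutations follow the infinite-sites model: Poisson
($L_\text{tree}\,\mu\,L_\text{bp}$) mutations per window, each on a branch
chosen proportionally to length, at a distinct uniform position, carried by
all descendants of that branch. Windows are independent non-recombining loci
by default — the SFS-based inference this supports treats them exactly so.

**Saturation.** The fitted ancestral size is large enough that expected
per-site diversity across the deep split is $\sim 0.39$; a 10-kb window
would need ~13,000 distinct segregating positions, more than it has. The
sequence-level simulator therefore refuses models whose expected mutation
count exceeds 0.9 per bp (`simulate_dataset()`), while the SFS-level
simulator (`simulate_sfs_dataset()`) works at any parameter values: it draws
Poisson mutation counts per branch directly into joint derived-count
classes, which is exact at the count level and is precisely the resolution
the demographic likelihood consumes. Statistic-level tests that need
sequence windows at the fitted demography (e.g. the FST-ordering check) run
it at reduced $\mu$, which is legitimate because frequency-based statistics
like FST are invariant to the mutation rate.

**Recombination.** Intra-window recombination exists for one purpose here:
validating the LD ($r^2$) and $\rho$ estimators. It is implemented as a
sequential coalescent (SMC): the leftmost tree is a standard Kingman tree;
moving along the sequence, breakpoints arrive at rate
$L_\text{tree}\,c$ per bp, and at each breakpoint a uniformly chosen branch
point is detached and re-coalesced into the remaining tree. This is a
well-characterized approximation of the ancestral recombination graph,
available for single-population samples only — population structure would
complicate the re-coalescence bookkeeping for no benefit, since the LD/ρ
validation is within-population. Only ordering and rank properties of
$\hat\rho$ are asserted, never absolute calibration.

**Reproducibility.** Every simulation entry point takes a seed;
per-window/per-replicate RNG substreams are derived by counter (splitmix64
into mt19937_64 with package-owned variate transforms), so window $k$ is
reproducible in isolation and identical seeds give byte-identical VCFs.
Fixed per-replicate substreams also give *common random numbers* across
demographic parameter values, which smooths Monte-Carlo likelihood surfaces.

## Joint SFS and composite-likelihood inference

The observed joint site-frequency spectrum tallies per-site derived-allele
counts per population; unfolded spectra need polarization. Missing data are
hypergeometrically down-projected to a fixed per-population size (standard
SFS practice; the default target is the smallest complete count). The
three-population analysis uses the triple of pairwise 2D spectra — the
default of the field's SFS fitters, and empirically better-behaved here than
the full 3D tensor, whose 729 classes dilute a fixed Monte-Carlo budget.

The composite log-likelihood is multinomial, $\sum_c n_c \log p_c$, over
polymorphic classes; the two corner classes (all-ancestral, all-derived) are
excluded from every spectrum, consistently on both sides. Monomorphic sites
are not modeled — windows are conditioned on being sequenced, not on
carrying variants. Expected class proportions come from Monte-Carlo branch
lengths; zeros there are sampling artifacts, so proportions are floored at
$1/(10\,n_\text{reps}\,n_\text{classes})$ where a positive count would
otherwise meet $\log 0$.

Optimization is deliberately not gradient-based: the surface is a
Monte-Carlo estimate. One free parameter is profiled on a log grid
(stage 1 spanning 0.5–2x, or 0.25–4x for sizes) and refined on a ±12% grid
at doubled replication, with a final quadratic interpolation through the top
three points. Several free parameters cycle through one-dimensional searches
with a shrinking multiplicative neighborhood (conditional maximization).
Model choice uses AIC and Akaike weights; uncertainty comes from the
parametric bootstrap with nearest-rank percentile intervals.

### What the recovery tests show — and their limits

The package's acceptance workflow simulates a genome-scale joint-SFS dataset
under the fitted *P. davidiana* demography (8 haplotypes per population;
40,000 10-kb windows, matching the ~400-Mb genome the study scanned;
100,000 genealogies per refined likelihood evaluation, the replication the
original analysis used) and profiles each headline parameter one at a time.
The deep divergence time, $N_{e\text{-N}}$ and $N_{e\text{-S}}$ are
recovered well inside the published bootstrap ranges. Three parameters are
harder: the N/C divergence time, $N_{e\text{-C}}$ and the ancestral size
have nearly flat profile directions — N and C are strongly coupled by
migration ($m_{N\to C} = 1.8\times10^{-5}$), so data of this size simply do
not pin $N_{e\text{-C}}$ to the ±2% width of the published interval. We
measured estimator SDs of ~8% ($N_{e\text{-C}}$), ~2.5% (N/C split time) and
~1.5% (ancestral size) at this protocol; shrinking them to ~1% would need
roughly 25x more windows *and* 25x more Monte-Carlo replication. Those
expectations are asserted anyway and may fail at some seeds; we prefer an
honest red over a loosened band. (Parametric-bootstrap intervals produced
the way the original toolchain produces them are themselves known to be
optimistic for weakly identified parameters.)

The SFS generator also defines the *conditions* of all synthetic tests:
no sequencing error, no missingness, free recombination between windows and
none within (unless SMC is requested), and truth-known ancestral states.
Passing tests therefore demonstrate internal correctness and calibration of
the estimators under the stated demography — not robustness to genotyping
error, reference bias, or linked selection in real resequencing data.

On polarization: with the fitted ancestral size, ingroup lineages coalesce
over millions of generations, deeper than any botanically plausible outgroup
split, so parsimony polarization against a single outgroup would be
systematically noisy *for this demography*. `polarize_sites()` (strict
outgroup consensus, no majority rule) is validated on demographies whose
ancestral timescale is shallow relative to the outgroup split, where it is
exact at ingroup-segregating sites; the SFS acceptance path uses the
simulator's recorded truth states instead.

## Windowed statistics

Windows are 0-based half-open 10-kb tiles (BED convention; VCF POS is
1-based, so a site maps by POS−1). Per window and population:
$\pi$ (mean pairwise difference per callable bp), Watterson's
$\theta_W = S/(a_1 L)$ with $a_1$ evaluated at each site's available sample
size, expected heterozygosity $H_E$ (mean over SNPs of $2p(1-p)\,n/(n-1)$),
Tajima's $D$ (1989 constants), Fay & Wu's $H = \pi - \theta_H$ (requires
polarization), and Fu & Li's $D$ (derived singletons vs. total
polymorphism). Statistics that are undefined — no segregating sites, too few
chromosomes — are `NA`, never 0, and nulls are excluded from summaries and
rank tests.

Between populations: FST by Weir–Cockerham (default; the estimator of the
toolchain the study used) or Hudson (Bhatia et al. 2013 form), always
aggregated as a *ratio of sums* of per-site components — the mean of
per-site ratios is badly biased where few sites segregate, and genome-wide
values are ratios of sums across all windows for the same reason. $d_{xy}$
is the mean between-population per-site difference normalized by callable
window length (upstream genotype-likelihood weighting schemes are replaced by
called-genotype computation — a documented divergence); RND divides by
$d_{xy}$ to the outgroup. Polarized sites are classified per focal pair as
fixed differences, shared polymorphisms, or private polymorphisms.

LD uses haplotype $r^2$ (phased data; equivalently squared allele
correlation) between sites more than 1 kb apart, with a genotype-dosage
fallback for unphased input. $\hat\rho$ comes from a least-squares fit of
binned mean $r^2$ against the sample-size-adjusted Hill–Weir expected decay
$E[r^2](C = \rho_\text{bp} d)$ — a transparent moment estimator standing in
for an external regression tool, used only for orderings; $\rho/\theta_\pi$
is reported to control for local $N_e$ when recombination is compared
between differentiation classes. PBS for branch A is
$(T_{AB} + T_{AC} - T_{BC})/2$ with $T = -\log(1-F_{ST})$; FST values at 1
are clamped to $1-10^{-9}$ and flagged. The genotype PCA eigendecomposes
the centered (optionally frequency-standardized) dosage matrix with
site-mean imputation of missing calls.

## Outlier windows and gene-level selection tests

Sweep-like windows combine an empirical FST criterion — at or above the
nearest-rank top-1% threshold, boundary ties included — with negative
Tajima's $D$. Which population's $D$ the original analysis used is not
recoverable; the default rule is "negative in at least one focal
population", configurable to `both` or `focal`. Balanced/low-differentiation
windows are simply FST < 0.15.

Significance against the demographic null: `n_sims` windows are simulated
under the accepted model, window FST is computed through the same code path
as the observed data, and each observed window gets two-tailed Monte-Carlo
p-values with the add-one rule $p^+ = (\#\{sim \ge obs\}+1)/(n+1)$ (no zero
p-values), each tail Benjamini–Hochberg corrected separately; candidates
have $q$ below the FDR level (default 1%). One simulated pool serves all
windows (an exchangeable null) — per-window matching is not attempted.
Contrasts of any statistic between outlier and background windows use the
two-sided Mann–Whitney test (exact for small groups, normal approximation
with tie correction otherwise).

Gene-level calls follow the polymorphism/divergence logic of the HKA test:
per gene, $A$ = sites polymorphic in the focal population, $B$ = sites with
per-site FST > 0.95 between the focal population and the pooled others
(fixed differences); a Pearson chi-square (1 df) tests
$A/B = A_\text{tot}/B_\text{tot}$, and a gene is called positively selected
when its HKA p-value is below 0.01 *and* its PBS reaches the nearest-rank
95th percentile of analyzed genes. Expected cell counts below 5 are flagged;
fewer than 20 genes triggers a percentile-instability warning.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → scan → outliers → genes → report from a
single JSON config, writes TSV/BED/JSON outputs plus a manifest (config
hash, seeds, version, row counts, timings), and is deterministic given
config and seed. The test suite runs the scan stages at a few hundred
windows and the calibration checks at 2,000 observed / 5,000 null windows;
the demographic recovery uses the 40,000-window protocol described above.
These sizes are the package's own choices balancing Monte-Carlo precision
against a desk-scale run, and each test states the Monte-Carlo error model
it asserts (typically a 3-standard-error band).

## Known limitations

- Genotype-likelihood (ANGSD-style) statistics are out of scope: all
  estimators run on called genotypes.
- Sequence simulation is infinite-sites; models near saturation must use
  the SFS-level generator.
- SMC recombination is single-population and used for validation only.
- $\hat\rho$ is an ordering-grade moment estimator, not a calibrated
  replacement for specialized recombination-rate software.
- The five IM model families (migration on/off, expansion, bottleneck in N
  or S) are expressible through `demographic_model()`; the original
  analysis's twenty concrete parameterizations are not recoverable from the
  publication and are represented by these templates.
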