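---
title: "Methods: post-processing LD-based recombination maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-processing LD-based recombination maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rholandscape)
```

# The problem

Patterns of linkage disequilibrium in a population sample carry the imprint
of historical recombination. Composite-likelihood estimators in the
LDhat/LDhelmet family turn a set of phased haplotypes into a
piecewise-constant map of the population-scaled recombination rate
$\rho = 4 N_e r$ per base pair between adjacent SNPs. This package covers
everything *around* such an estimator for a wild-population study — it
does not estimate $\rho$ itself. The stages are:

1. assembling estimator output into chromosome-scale maps
   (`read_rho_map()`, `stitch_windows()`);
2. summarizing and comparing maps against pedigree-based linkage maps
   (`weighted_mean_rho()`, `anchor_to_centimorgans()`, `window_series()`,
   `correlate_windows()`, `estimate_ne()`);
3. quantifying fine-scale heterogeneity (`lorenz_gini()`) and calling
   recombination hotspots with a randomization test of their overlap with
   external interval sets such as double-strand-break (DSB) maps
   (`call_hotspots()`, `randomized_overlap_null()`);
4. the quality-control machinery such a study needs upstream: phasing
   switch-error measurement via pseudofemales (`make_pseudofemale()`,
   `switch_error_rate()`, `inject_switch_errors()`), site filtering with an
   exact Hardy–Weinberg test (`filter_sites()`, `hwe_exact_test()`), and
   ancestral-allele polarization with a mutation matrix
   (`assign_ancestral_prior()`, `build_mutation_model()`);
5. gene-level correlates of recombination: diversity and divergence at
   fourfold degenerate sites (`annotate_fourfold_sites()`,
   `gene_diversity_divergence()`, `kendall_tau()`);
6. synthetic-data generators giving every stage a known ground truth
   (`simulate_landscape()`, `simulate_haplotypes()`,
   `simulate_polarization_sites()`, `simulate_gene_table()`).

# Data model and coordinate conventions

A `rho_map` holds strictly increasing 1-based SNP positions and one
non-negative rate per inter-SNP interval, matching estimator output.
Interval sets (`interval_set`) use BED semantics: 0-based, half-open
`[start, end)`; abutting intervals do not overlap. These are the two
conventions of the file formats involved, and all conversions between them
happen inside this package (IRanges is used internally for overlap
queries, with the +1 shift applied at the boundary). Rate tables may be
per-bp (LDhelmet) or per-kbp (LDhat); the unit is an explicit flag on
`read_rho_map()` and is never guessed, because a silent factor of 1000 is
the dominant failure mode for these files.

Estimators are typically run on overlapping SNP windows (e.g. 4400 SNPs
overlapping by 200). `stitch_windows()` removes the duplicate copies by
splitting each overlap at its midpoint, taking the left half of the shared
intervals from the earlier window. Any deterministic rule works here; the
midpoint split is symmetric and makes the stitched map independent of
processing order. With identical rates in the overlap (the common case,
since the windows saw the same data there) the tie-break is immaterial,
which the tests verify.

Gap handling on read is strict by default; with `gap_tolerant = TRUE` a
missing row becomes a bridging interval of rate 0, recorded in the map's
provenance, so missing estimator rows can never silently inflate the
genetic length of a map.

# Map summaries and anchoring

All regional summaries are frequency-weighted means: each inter-SNP
interval contributes its rate weighted by its physical length (bp),
because SNP spacing is irregular. `anchor_to_centimorgans()` converts
cumulative weighted $\rho$ to centimorgans by pinning the chromosome total
to an external linkage-map length; the transform is proportional, so it
preserves the rank order of local rates exactly and the endpoint lands on
the anchor without rounding error.

`window_series()` tiles half-open windows anchored at coordinate 0.
Nonoverlapping series keep a final partial window, flagged by its
`coverage`; sliding series report fully contained windows only. Windows
below a coverage floor (default 50%) are *missing*, never zero, and
`correlate_windows()` drops missing windows pairwise rather than imputing.
Windows are weighted equally in correlations, not by SNP count; this is a
choice, documented rather than inherited.

`estimate_ne()` inverts $\rho = 4 N_e r$ with $r$ taken from a cM/Mb rate
($r = \text{cM/Mb} \times 10^{-8}$ per bp). The bundled
`mouse_chromosome_rates()` table carries published per-chromosome values
for three house-mouse maps; the package's worked examples recompute its
$N_e$ column and the cross-map correlation from the printed rates.

# Heterogeneity: Lorenz curves and Gini coefficients

`lorenz_gini()` sorts intervals by rate (ties broken by position, with no
effect on the result) and accumulates physical fraction against genetic
fraction. The Gini coefficient is one minus twice the trapezoidal area
under the polyline. On equal-length intervals this equals the normalized
mean absolute pairwise difference of the rates, which the tests use as an
independent oracle at $10^{-12}$ tolerance. Weighting by physical length
rather than counting intervals equally is deliberate: the axes of the
curve are physical versus genetic distance, and intervals differ greatly
in span. Raw map intervals are used as the units of the curve; no
re-binning is applied.

# Hotspot calling and the overlap null

`call_hotspots()` implements an operational hotspot definition: 2 kb
nonoverlapping windows, flagged when their weighted mean rate is at least
5× the rate of the surrounding 80 kb (40 kb per side, focal window
excluded — including it would dilute the signal being tested), with runs
of adjacent flagged windows merged. The threshold is inclusive at exactly
5×. Flanks are truncated at chromosome ends and require a minimum covered
fraction (default 50%); a window with positive focal rate over a
zero-rate background is flagged and annotated `"zero-background"` rather
than dropped or given an infinite quiet score.

`randomized_overlap_null()` builds the chance expectation for the overlap
between two interval sets by re-placing each query interval uniformly on
its own chromosome (lengths preserved, placements independent, collisions
among placed intervals allowed — at hotspot densities the collision
correction is negligible and independence keeps the null exactly
enumerable in the single-interval case, which the tests exploit). The
maximum count across 1000 replicates serves as an approximate 0.1%
significance threshold. Overlap counts are target-side: how many target
(e.g. DSB) intervals are hit by at least one query interval. A
`permute_chrom` flag additionally randomizes chromosome assignment
(probability proportional to length) for users who read "randomized with
respect to chromosome" as between-chromosome shuffling; the default is
within-chromosome re-placement.

# Phasing quality control

Two haploid X chromosomes merged into a "pseudofemale" give a diploid
whose true phase is known; re-phasing its genotypes and comparing against
the truth measures the switch-error rate of the phasing pipeline.
`switch_error_rate()` orients the inferred pair against the truth at every
heterozygous site and counts orientation flips between consecutive sites;
it is invariant to a global haplotype relabeling. The primary rate divides
by the number of heterozygous sites; the conventional denominator
($n-1$ adjacent pairs) is reported alongside, since both conventions
circulate and they differ by a factor $(n-1)/n$.

`inject_switch_errors()` is the inverse operation for simulation studies:
each site independently toggles a running swap state with probability $e$,
so each event creates exactly one orientation flip — the signature of a
spurious crossover. Measured back through `switch_error_rate()`, the
expected rate is $e(n-1)/n$; the tests verify recovery within three
binomial standard errors at $n = 10^5$ for $e$ spanning 0.001–0.05.

# Site filtering and the exact HWE test

`filter_sites()` applies the selection used before map inference:
biallelic SNPs only, a variant quality floor (default QUAL ≥ 30), an
any-individual genotype-quality rule (default GQ ≥ 15: one failing
individual removes the site), optional depth bounds (off by default), and
an exact Hardy–Weinberg test at $P < 0.002$. Sites are charged to the
first rule they fail, and the report itemizes removals per rule so filter
grids can be explored. `hwe_exact_test()` is the standard exact
conditional test with probability-ordering two-sided p-values, computed
in log space by the ratio recurrence; the tests compare it against direct
multinomial-coefficient enumeration for every genotype configuration up
to 20 individuals. CpG-prone sites are *not* removed here: excluding them
would discard roughly half of a murid dataset, so CpG handling is confined
to the mutation-matrix estimation step.

# Ancestral inference

A site is CpG-prone if preceded by C or followed by G in the focal species
or either outgroup; missing context counts as not-C/not-G for that
species. Polarization is two-outgroup agreement parsimony with explicit
uncertainty: agreement puts prior 0.91 on the shared base and 0.03 on each
alternative; disagreement or a gap in either outgroup yields the
stationary distribution of the mutation matrix as the prior.

`build_mutation_model()` fills the off-diagonal of the matrix with the
conditional spectrum of derived bases given each ancestral base, estimated
from resolved non-CpG-prone SNPs. Downstream estimators differ in the
diagonal convention they expect, so the total off-diagonal row mass is a
parameter (`off_mass`, default 0.1) — and because uniform row-wise damping
does not move a chain's fixed point, the stationary distribution is
invariant to it (tested to $10^{-10}$). The stationary vector is computed
by eigen-decomposition and cross-verified by power iteration inside the
constructor; an ancestral base with zero observations is a hard error
suggesting pseudocounts rather than a silent uniform row.

# Gene-level correlates

`annotate_fourfold_sites()` keeps third codon positions whose codon family
is fourfold degenerate in the focal species and both outgroups; a
non-fourfold codon in any one species vetoes the site. Minus-strand genes
are evaluated on the reverse complement, and the tests check that the
site set matches the pre-reverse-complemented presentation of the same
gene. Per-site diversity comes from allele counts:
$\pi = 1 - \sum_b \binom{c_b}{2} / \binom{n}{2}$, which for a biallelic
site equals the unbiased $2p(1-p)\,n/(n-1)$. Divergence from rat is the
fraction of comparable sites whose focal *consensus* (majority) base
mismatches the rat base — with polymorphism in the sample some convention
is needed, and the consensus is the one used here. Genes with more than
80% of fourfold sites missing, or whose comparable non-CpG sites all
mismatch rat (a misalignment signature), are excluded with a reason code,
never silently NaN. All statistics are reported twice, for all sites and
for non-CpG-prone sites only, since CpG hypermutability inflates both
$\pi$ and $d$. Per-gene $\bar\rho$ is computed over the gene span only,
without flanks. Correlations use tie-corrected Kendall $\tau_b$.

# The synthetic-data generators

The generators produce every input the pipeline consumes, with ground
truth retained, so each stage can be tested end-to-end without any
external data. They emulate a neutral-equilibrium study design:
$\theta = 0.01$ per bp (the approximate genome-wide diversity of wild
house mice), samples of 20 haplotypes, and $\rho$ spanning
$2\times10^{-6}$ to $2\times10^{1}$ per bp.

**Landscapes** (`simulate_landscape()`): gamma-distributed background
rates on fixed intervals (shape 5 by default — moderate heterogeneity,
chosen once as realistic for fine-scale maps outside hotspots) with
hotspot intervals placed uniformly subject to a minimum gap. A planted
hotspot's rate is its intensity multiplier times the weighted mean
*background* rate of the surrounding 80 kb, so the planted focal/flank
contrast equals the multiplier by construction rather than inheriting the
noise of a single background draw. The recall property of the caller
(recall 1 at ≥ 6×, no false calls in flat background) is tested on
isolated hotspots (minimum gap 42 kb at 5 hotspots/Mb), a geometry chosen
so that each 40 kb flank is hotspot-free; at genome-like densities
(15/Mb) hotspots shade each other's backgrounds and perfect recall is not
a property any caller of this design has.

**Haplotypes** (`simulate_haplotypes()`): a sequentially Markovian
coalescent written in R. The genealogy at the left end is a Kingman tree;
breakpoints arrive along the sequence at rate $\rho(x) L_T/2$ per bp
(times in units of $2N_e$ generations), and at each breakpoint a
uniformly chosen point of the tree is detached and re-coalesced with the
remainder. Marginal genealogies are exactly Kingman, so
$\mathbb{E}[\pi] = \theta$ per bp holds without approximation — the SMC
approximation affects only the correlation structure between nearby
genealogies, which none of the tested statistics depend on at desk scale.
Mutations are Poisson on each constant-genealogy segment, strictly
biallelic (infinite sites; integer-position clashes are dropped), with
bases optionally assigned from a `mutation_model`.
`write_estimator_input()` emits the sites/locs text files a downstream
composite-likelihood estimator expects; actually running such an
estimator is deliberately outside the test surface.

**Polarization quartets and gene tables**: quartet sites draw ancestral
bases from the model's stationary distribution and perturb outgroups
independently at a configurable error rate (at error rate 1 the
resolution rate has the closed form 1/3, used as a test); gene tables
draw $(\bar\rho, \pi)$ from a Gaussian copula with
$r = \sin(\pi\tau/2)$ so the population Kendall $\tau$ equals the target
exactly for the continuous gamma marginals used.

What the generators do *not* emulate: selection and demography (both
violated in real data and both known to bias LD-based estimates),
genotyping error, the read-level origin of phase information, and the
estimator itself. Passing tests therefore demonstrate that the
*post-processing* is correct, not that any particular upstream inference
is unbiased on real data.

# Numerical choices and problem sizes

Randomness is always behind an explicit `seed` argument, executed via
`withr::with_seed` so the caller's RNG state is untouched; generators are
bit-reproducible under a fixed seed. Degenerate inputs error early and
specifically: zero-total maps cannot be anchored or Lorenz-transformed,
empty region intersections are distinct from zero rates, and genotype
mismatches between truth and inferred phasings are errors rather than
switches. The test suite runs at desk scale by design: coalescent checks
use 20–50 kb sequences with 10–20 haplotypes and ~50 replicates,
switch-error round trips use $10^5$ sites, matrix recovery $10^5$ sites,
and gene-table recovery 2000 genes — sizes at which every stochastic
tolerance is a pre-computed 3-standard-error band. The whole suite
completes in under a minute on one core.

# Known limitations

* The SMC generator is not a substitute for a full ancestral recombination
  graph when statistics sensitive to long-range genealogical correlations
  are of interest.
* `estimate_ne()` assumes the external cM/Mb estimate and the LD-based
  $\bar\rho$ describe the same sex-averaged process; sex differences in
  recombination are not modeled anywhere in the package.
* The hotspot caller's fixed 2 kb grid means a hotspot straddling a window
  boundary is recovered by the merge rule but its score dilutes across two
  windows; sub-window localization is out of scope.
* `d_rat` uses the focal consensus base; alternatives (reference base,
  fixed-difference counting) would shift gene-level divergence slightly
  for highly polymorphic genes.
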