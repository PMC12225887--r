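---
title: "Quantifying conformational heterogeneity of chromatin ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conformational heterogeneity of chromatin ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromhet)
```

## The problem

Ensembles of single-cell 3D chromatin models — one bead-chain conformation
per nucleus — are now produced routinely, from bulk Hi-C-constrained
structure selection, from single-cell Hi-C-based polymer relaxation, and
from confined polymer dynamics. Comparing such ensembles is harder than
comparing their contact maps: two ensembles can reproduce the same Hi-C map
while differing substantially in how much their structures vary from cell
to cell. `chromhet` condenses that cell-to-cell variability into one number
per genomic scale.

## The metric and its assumptions

For a chain of $n$ beads of equal genomic size, each cell $k$ contributes a
curve of average inter-locus distances
$$\langle R_s^{(k)}\rangle = \frac{1}{n-s}\sum_{i=1}^{n-s}
  \lVert \mathbf r_{i+s} - \mathbf r_i \rVert, \qquad s = 1,\dots,n-1 .$$
Averaging over all pairs at fixed $s$ deliberately washes out
*intra*-nuclear variability so that the ensemble statistic isolates
*inter*-nuclear variability. Conformational Heterogeneity is the
population (divide-by-$n$) standard deviation of these per-cell values
across cells; Relative C.H. applies the same formula to curves divided by
the ensemble mean at each $s$. We use the population form because the
defining expression is a spread over the cells actually in hand, not an
inference about a larger population; replicate error bars (below) use the
sample form (divide by $n_\mathrm{rep}-1$) because replicates *are* draws
from a larger pool.

Assumptions worth keeping in mind:

* separations are counted in equal-genomic-size beads; the `resolution_kb`
  of the ensemble (118 kb per TAD bead in the fruit-fly X-chromosome models
  this package is aimed at, 10 kb for single-cell-Hi-C-based models)
  converts bead counts to kb. Chains with per-bead genomic sizes are
  carried through I/O, but the heterogeneity computation operates on the
  declared uniform bead grid;
* the chain is contiguous (a single chromosome arm); pairs never straddle
  declared gaps because none are modelled;
* at the largest separation only one bead pair exists, so per-cell values
  become single distances and both C.H. and Relative C.H. rise sharply near
  the chain end. This is a property of the estimator, not of chromatin;
* absolute C.H. comparisons require a common length unit; Relative C.H. is
  dimensionless and also invariant under any global rescaling of all
  coordinates, which the test suite asserts exactly.

Dividing by the per-$s$ ensemble mean makes the per-$s$ average of Relative
curves exactly 1, so Relative C.H. $\equiv$ C.H.$/\overline{\langle
R_s\rangle}$; the package computes both routes and the tests pin their
agreement at $10^{-10}$.

## Replicate error bars

`subsample_replicates()` draws $n_\mathrm{rep}$ (default 10) subsets of $k$
cells without replacement — a set of conformations is a subset, not a
bootstrap — and `replicate_errorbars()` reports the per-$s$ mean and sample
standard deviation of the metric across replicates. Trajectory ensembles
are reduced to single cells by `sample_trajectory_cells()`: each trajectory
is divided into 50 equal intervals and one of the 50 boundary snapshots is
drawn uniformly. Since 50 segments strictly have 51 boundaries while the
candidate count is 50, we define the candidates as 50 evenly spaced frames
including the first and last (`round(j (T-1)/49)`, $j=0..49$); the choice
of candidate rule is exposed through `n_intervals` because the equivalent
equilibration-exclusion convention cannot be recovered from the published
description.

## MC-TAD: permissible paths through a TAD

A TAD is modelled as a cube of $N^3$ bins (cube edge 1 a.u.; bin spacing
$1/N$); a chromatin conformation is a path over bin centers that traverses
$N^3-1$ full segments per cube before entering the neighboring TAD. The
permissibility rules are configurable through `mctad_rules()`; the
defaults are the calibrated configuration that reproduces the reference
unique-path counts (384 for one $2^3$ cube, 98,304 for two):

* axis-aligned unit steps between bin centers;
* no lattice edge traversed twice;
* no geometric crossing of segments except at a bin center;
* at most one bin visited twice, and only the path's *entry bin* — the
  single permitted self-contact where the chain crosses itself at a bin
  center. Exhaustive enumeration shows that the looser "any bin may be
  revisited once" rule yields 624 directed paths at $N=2$, while
  restricting the revisit to the entry bin yields exactly
  $144\ (\text{Hamiltonian}) + 240 = 384$;
* two-cube ensembles pair every first-cube path with every second-cube
  path whose *starting-face axis* (the axis of the first step) differs —
  the face constraint. Since starting axes are uniform by symmetry, the
  constraint keeps exactly $2/3$ of the $384^2$ ordered pairs:
  $384 \times 256 = 98{,}304$. The inter-TAD linker joins the first path's
  end to the second path's start and is exempt from the lattice rules.

Paths are directional (a path and its reversal are distinct), consistent
with the directionality of the chromatin chain between TADs; the
deduplication key is the exact ordered vertex sequence.

### The spread σ and its physical conversion

For every two-cube path, all windows of $N^3$ consecutive segments (the
genomic content of one TAD, e.g. $8 \times 14.75\,\mathrm{kb} = 118$ kb at
$N=2$) give subchain end-to-end distances in cube-edge units. σ is the
*across-conformation* spread of these distances: the variance across paths
is taken at each window position and averaged over positions before the
square root. This matches what σ is used for — the spread of per-cell
curves at the TAD separation — and makes σ of an ensemble of identical
paths exactly zero; on the full symmetric path ensemble it coincides with
the pooled standard deviation because every window position has the same
marginal distribution. `sigma_to_physical()` converts to microns via
$\Sigma = C_\mathrm{conv}\,\sigma$; the default
$C_\mathrm{conv} = 0.147\ \mu\mathrm m$ per cube edge is back-solved from
the reference pair $\Sigma(2\,\mathrm{kb}) = 0.05\ \mu\mathrm m$ with
$\sigma(4{\times}4{\times}4)=0.34$ and should be overridden whenever a
model-specific unit conversion is available.

### Generation modes, convergence, problem sizes

For $N\le 2$ the path set is enumerated exhaustively, and the stochastic
mode must (and does, in the tests) converge to the identical set.
Stochastic generation grows paths by randomized depth-first search with a
small backtracking budget, de-duplicates, and declares convergence once
`stagnation_limit` consecutive attempts yield no new unique path (default
`max(1e4, 50 * current unique count)`). For $N\ge 3$ the unique-path space
is far too large to converge, so σ is estimated from a fixed sample of
unique paths with a block-wise Monte-Carlo standard error, as reported by
`sigma_subchain()`. The package's own checks use 1.5–2×10⁴ unique paths
per cube and 3–4×10⁴ pairs at $N=3$, and 800–3,000 paths at $N=4$ — sizes
chosen so the Monte-Carlo error on σ (a few 10⁻⁴ at $N=3$) is negligible
against the tolerances being tested. Growth-order sampling is not exactly
uniform over unique paths; the de-duplicated sample inherits a mild bias
toward high-probability paths that is invisible at the reported
Monte-Carlo precision but is the main caveat on sampled-σ values.

## Resolution up-conversion

TAD-resolution models have essentially zero spread at their resolution
limit; to emulate a finer model, one offset per cell is drawn from
$\mathcal N(0, \Sigma)$ and added to that cell's entire analytic curve
(`shift = "whole"`, the default). Shifting the whole curve — rather than
only the value at the TAD separation (`shift = "at_source"`, provided for
comparison) — reproduces both target behaviors: the intended spread
appears at the TAD-size separation, and the Relative C.H. at much larger
separations is nearly unchanged because Σ is small against the large-$s$
spread. An empirical-offset mode resampling actual MC-TAD subchain
distances is available through the `distances` field of
`upconversion_spec()`; the normal approximation is the default. Shifted
values below zero are clamped to zero (distances cannot be negative) and
the clamp count is reported.

The connecting segment from the target resolution to the first analytic
point is an *eye guide only*: anchored at a configurable value (1.00 for
Relative curves via `relative_anchor()`), flagged `is_guide`, and excluded
from profiles and fits — a contract the tests verify by recomputation. The
anchor value (default 0.1 μm at 14 kb) is a free plotting parameter.

## Baseline ensembles

**Freely jointed chains** use isotropic unit steps obtained by normalizing
3D Gaussian draws (the sampler is not dictated by theory; normalized
Gaussians are exact and cheap). Under the normal approximation for the
end-to-end distance (mean $l\sqrt s$, spread $l\sqrt{s/3}$), the
spread-to-mean ratio is $1/\sqrt3 \approx 0.577$ independent of $s$ —
`fjc_relative_ch_limit()`, conventionally printed as 0.57. The exact
end-to-end distance of an ideal chain is Maxwell-distributed, for which the
ratio would be $\sqrt{3\pi/8-1}\approx0.42$; the package reports the
normal-approximation bound as the reference value and records the
discrepancy here. Finite chains stay below the bound, which the tests
check away from the noisy chain end.

**Orientation-random space-filling curves** model territorial, fractal
chromatin packing. Each replica is a bijective ordering of the $8^p$ cells
of the $2^p$ cube built recursively: the eight octants are traversed along
a reoriented copy of the canonical 8-point template, and each octant's
sub-curve is re-anchored so that its entry and exit corners keep every
step at unit length. A fresh random cube symmetry fixes the top-level
orientation, and the remaining freedom — which of the valid
octant-orderings and corner tables to use — is resolved randomly at every
internal node, giving wide replica diversity. A design note: applying a
per-level random symmetry *without* re-anchoring produces occasional
discontinuities proportional to the subcube size, which would break the
bounded-step property; we therefore chose exact re-anchoring, so our
curves are strictly continuous (every step length 1, trivially within the
$\le\sqrt3$ bound) and their spread at the single-bead separation is
exactly zero. Locality is preserved: per-replica log–log fits of
$\langle R_s\rangle$ over $s\in[2,400]$ sit near the space-filling value
$\alpha = 1/3$ (the test suite asserts the band $0.311\pm0.029$), while
FJC replicas sit near the random-walk value $\alpha = 1/2$ (band
$0.513\pm0.055$). Fits are unweighted ordinary least squares on
$\log\langle R_s\rangle$ vs $\log s$; no weighting scheme is imposed
because none is canonical for this diagnostic. `coarse_grain_chain()`
keeps even-indexed beads (phase 0; the phase is immaterial for the
statistics and a fixed convention keeps results reproducible) and assigns
10 kb per retained segment, turning a 4096-point curve into the 2048-bead,
~20 Mb fractal-like chain used for comparisons.

**Synthetic heterogeneous ensembles** scale one base conformation by
per-cell factors $1+\varepsilon_k$, $\varepsilon_k \sim \mathcal
N(0,\tau^2)$ truncated at $\varepsilon > -0.9$ (a scale factor must stay
positive; the truncation is immaterial for the τ values used). Because
every cell's curve is a constant multiple of the base curve, Relative C.H.
equals the population spread of the normalized factors at *every* $s$ —
an exactly known ground truth. What this generator emulates is a single,
global compaction difference between nuclei; it does **not** emulate
locus-specific variability, chain-topology differences, confinement, or
the $s$-dependence of real heterogeneity profiles. Passing
parameter-recovery tests on it therefore demonstrates estimator
correctness, not realism of any chromatin model: a 50-cell ensemble
recovers τ only up to the ~10% sampling error of a 50-draw standard
deviation, which is why recovery is judged on the replicate mean.

## Numerical and interface choices

* File round-trips print 17 significant digits, so coordinates survive
  read/write losslessly; bead indices are explicit and 0-based in files to
  keep dialects honest, and readers reject gaps, missing columns and
  non-finite values by cell and bead.
* Homolog-pair merging places bead $i$ at the unweighted midpoint of the
  two homolog beads and keeps the original bead radius.
* Degenerate inputs: relative curves are refused when the ensemble mean is
  zero at any $s$; heterogeneity needs at least two cells; σ needs a
  two-cube ensemble and a contour no longer than the path.
* Segment-crossing checks solve the two-segment closest-approach problem
  with a $10^{-9}$ tolerance; intersections exactly at bin centers are the
  single allowed self-contact.
* All stochastic entry points take a seed and reseed R's RNG, so every
  result in this vignette, the tests, and the acceptance script is
  reproducible bit-for-bit; the CLI writes version, seed and parameters
  into every output header.

## Known limitations

* The permissibility rule set is calibrated to the printed $N=2$ path
  counts; the published description underdetermines some details (how the
  one permitted self-crossing is anchored, the exact form of the face
  constraint), and alternatives that reproduce the same counts can shift
  sampled σ values by a few percent. The rules are therefore fully
  configurable and the calibration is documented above.
* The two-cube construction covers exactly two TADs; heterogeneity
  injected by up-conversion ignores longer-range intra-TAD correlations.
* Sampled σ at $N\ge3$ carries the growth-sampling bias discussed above.
* The metric is defined for one contiguous chain; multi-chromosome
  ensembles must be analyzed arm by arm (or merged to single chains
  first).
* Relative C.H. is a second-moment summary; ensembles can differ in
  higher moments of the $\langle R_s\rangle$ distribution while agreeing
  in Relative C.H.
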