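---
title: "Models of transcriptional activation, repression and duality: methods"
author: "txduality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of transcriptional activation, repression and duality: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txduality)
```

## The problem

Many transcription factors (TFs) behave as activators in some contexts and
repressors in others, and some switch between the two as their own
concentration rises (a nonmonotonic dose response). This package implements
a family of mechanistic models for asking *when* such behavior is possible:
under which regulatory modes, at or away from thermodynamic equilibrium,
and how TF-DNA binding affinity and binding-site number tune the direction
of the response while the molecular context stays fixed.

All models describe gene regulation as a continuous-time Markov process on
a graph: vertices are molecular states of the regulatory region (what is
bound, where the polymerase sits in its cycle), directed edges carry
transition rates, and every edge label is affine in the TF concentration
`x` (`rate + x_coeff * x`), so TF-binding edges scale with `x` and all
other transitions are constant. The steady-state transcription rate is
either a probability-weighted sum of per-state transcription rates
(recruitment models) or the probability flux through an irreversible step
(cycle models). The quantity of interest is the fold change
`F(x) = r(x) / r(0)`: mRNA decay cancels in this ratio, so it never enters
the models.

## Steady states on graphs

Two production solvers compute the stationary distribution.

**Equilibrium path products.** When the Kolmogorov cycle condition holds
(around every cycle, the product of forward rates equals the product of
backward rates), the chain is reversible and the steady state follows from
ratios alone: pick a reference state with weight 1, multiply forward/backward
rate ratios along any path to state *i*, normalize. The cycle condition is
tested on a cycle basis built from a spanning tree of the undirected support
(sufficient for reversible graphs), with relative tolerance `1e-9` on each
basis cycle's forward/backward product; graphs with an edge lacking its
reverse fail immediately, with the offending edges reported.

**Spanning-tree (Matrix-Tree) summation.** Away from equilibrium the
unnormalized weight of state *i* is the sum over all spanning trees rooted
at *i* (edges directed toward the root) of the product of tree edge rates.
Trees are enumerated exhaustively for graphs up to 12 vertices — at model
scale (4 to 12 states) this is cheap and mirrors the defining formula
literally — and the solver falls back to the nullspace method with a
warning beyond that. Products are accumulated in log space and pooled with
log-sum-exp. This is the package's answer to the precision problem: tree
products across rate scales spanning many orders of magnitude underflow in
naive double arithmetic, whereas sums of logs are exact to machine relative
precision at any scale. The naive product path is retained behind
`log_space = FALSE` for comparison. If every tree weight vanishes (for
example all rates zero at the evaluated `x`), the solver raises an
underflow error rather than returning garbage.

**Oracles.** Two independent verification routes exist for tests: the
kernel of the master-equation Laplacian computed by
Grassmann–Taksar–Heyman (GTH) elimination, and long-time integration of
`dP/dt = L P` with `deSolve::lsoda` from the uniform distribution until
`max |dP/dt| < 1e-13`, plus one confirmation decade of time so a small
residual cannot mask a slowly relaxing metastable mode. GTH was chosen
over an SVD kernel because it uses only nonnegative sums and products (no
cancellation) and therefore achieves *entrywise* relative accuracy: steady
states here routinely have components spanning ten or more decades, where
an SVD kernel is only accurate in norm. The three routes agree to better
than `1e-7` per component (components above `1e-12`) over hundreds of
random graphs; in practice the observed disagreement is near `1e-12`.

Zero-rate edges are handled structurally: connectivity is assessed on
declared edges, so at `x = 0` a TF-bound layer simply receives zero tree
weight and exactly zero probability — the basal steady state emerges from
the same code path with no special casing.

## The recruitment model

Four states — empty, TF bound, Pol bound, both — with TF binding rates
`aT, aT_p` (1/(nM s)), unbinding `bT, bT_Tp` (1/s), Pol binding `ap, ap_T`
(1/s, Pol concentration absorbed), Pol unbinding `bp, bp_Tp` (1/s), and
transcription rates `q3` (Pol alone) and `q4 = epsilon * q3` (Pol with
TF). At equilibrium only ratios survive: affinity `KT = aT/bT` (1/nM),
Pol affinity `Kp = ap/bp`, TF–Pol cooperativity
`omega = (aT_p/bT_Tp)/(aT/bT)`, and the closed form

    r(x) = q3 (Kp + eps Kp KT w x) / (1 + KT x + Kp + Kp KT w x)

whose derivative sign equals the sign of `Kp w (eps - 1) + eps w - 1`
for every `x`: equilibrium single-site responses are monotone, and the
TF-DNA affinity `KT` does not appear — affinity cannot tune direction at
equilibrium. Both facts are enforced as tests: the closed form against the
graph solver to `1e-10` over hundreds of balanced parameter sets, and the
sign condition against end-to-end fold changes wherever the expression is
bounded away from zero (`|expr| > 1e-6`, below which the sign is not
numerically meaningful).

Away from equilibrium (cycle condition broken) the same graph is solved by
spanning trees. The reference incoherent configuration — TF enhancing Pol
recruitment while reducing its activity — produces increasing, nonmonotonic
or decreasing responses depending on the unbinding rate `bT`, with the
nonmonotonic peak moving to higher concentration as affinity falls.

## The transcription-cycle model

A three-state Pol cycle (recruitment `k1` with reverse `k1r`; initiation
`k2` and termination `k3`, irreversible, as befits a Pol that has escaped
the promoter), duplicated into TF-unbound and TF-bound layers connected by
binding (`aT x`) and unbinding (`bT`) on every cycle state, with
state-independent binding as the baseline model. While bound, the TF
multiplies cycle rate *i* by `epsilon_i > 0`. The transcription rate is
the flux out of state 3 summed over layers, `k3 P(3,-) + e3 k3 P(3,T)`,
with the proportionality constant set to 1 since only fold changes are
reported. Coherent regulation (all non-unit effects accelerating, or all
decelerating, the cycle) gives monotone responses; incoherent regulation
(the reference set accelerates initiation 15-fold and slows termination
100-fold) yields all three classes over the `(bT, x)` plane — even with
`e1 = e1r = 1`, when the TF/Pol binding subsystem alone satisfies detailed
balance and the only dissipation is the cycle's own irreversibility.

## Multisite models

**Occupancy-averaged.** TF binding to `N` equal independent sites is
assumed fast enough to equilibrate; the mean bound count is
`a = N KT x / (1 + KT x)`, computed as the binomial configuration sum with
weight `(KT x)^i` for `i` bound sites (the package states the sum with
exponent `i`; the equivalent closed form and a brute-force enumeration
over all `2^N` configurations pin it down in tests). Each regulated rate
responds to occupancy through a saturable Hill-type function
`k(a) = k0 + (ksat - k0) a^h / (s^h + a^h)`, bounded between its basal and
saturating values; modulation applies to `k2` and `k3` (regulating
recruitment this way is possible but off by default). The steady-state
mRNA uses the closed form
`m = k3 k1 k2 / (k2 k3 + k3 k1r + k1 k3 + k1 k2)` and the fold change is
`m(a)/m(0)`, exactly 1 at zero occupancy. Site number acts like
concentration: both raise `a`, and with incoherent modulation the
response versus `N` switches from activating through bell-shaped to
repressive as `KT` rises.

**Explicit binding.** The cycle graph generalizes to `3(N+1)` states
indexed by (cycle state, number bound), with binomial binding kinetics
(`(N-k) aT x` up, `(k+1) bT` down). With `k` sites bound a *regulated*
rate is multiplied by `k * epsilon_i`; a rate with `epsilon_i = 1` is
untouched at every occupancy — otherwise mere binding would rescale
unregulated kinetics, which would contradict the equilibrium-binding
analysis where the TF leaves `k1, k1r` alone. At `N = 1` the explicit
graph reduces exactly to the two-layer cycle model (verified to `1e-10`).

## Response classification and regime maps

Classification operates on `log F`, making it invariant to monotone
rescaling. Successive differences with `|d log F| <= rtol` (default
`1e-6`) count as zero; curves are flat, increasing, decreasing, or
nonmonotonic, and a single rise-then-fall records its peak location.
Curves use 50-point log-spaced grids by default; regime maps classify the
inner-axis curve at each of 25 outer-axis values. Axis ranges for the
reference maps — `x` in `[0.1, 1000]` nM, `bT` in `[1e-3, 1e2]` 1/s,
`KT` in `[1e-3, 1e2]` 1/nM, `N` in `0..6` — were chosen once to contain
all three regimes for the reference parameter sets and are ordinary
function arguments. Site-number curves are normalized to `N = 0` (the
bare cycle). Parameter sampling for the property suites is log-uniform
within ranges bracketing the reference values by roughly two orders of
magnitude; the coherent-regime samplers constrain every TF effect to one
side so that the monotonicity suites exclude incoherence under either
published definition (opposed binding/activity effects, or opposed
on/off-rate effects).

## The synthetic MPRA

The generator emulates a massively parallel reporter assay probing TF
duality: designs combine 1–6 identical binding sites at one of 6 affinity
levels, 3 orientations and 3 spacings, each built in 3 random-sequence
backgrounds, plus 417 random-DNA-only controls. A design's true activity
is the log fold change of the occupancy-averaged multisite mechanism at
its (N, KT); orientation and spacing carry no true effect (the analysis
averages over them, and the generator can be configured otherwise).
Observed activity adds a baseline, a per-construct background effect
(sd `sigma_bg = 0.1`) and measurement noise (sd `sigma_e = 0.05`), in
log(RNA/DNA) units — background variation dominating measurement error,
consistent with the high technical-replicate correlations such assays
achieve. Normalization subtracts the mean control activity, so 0 marks
the activity of average random DNA; it is idempotent and recomputed from
raw values. Everything is deterministic under one seed.

The affinity map assigns the six levels `KT = 10^seq(-3.3, 0.7)` 1/nM —
log-spaced across four decades, anchored so that two levels sit inside
each response regime of the default mechanism (activating, bell, repressive),
with every level at least ten cell-mean standard errors from a regime
boundary. A map with a level on a boundary would make that level's true
trend class undefined at assay resolution.

What the generator does *not* emulate: barcode-count sampling noise,
sequencing error, real position-weight-matrix binding energetics, or
sequence-dependent true effects of orientation and spacing. Passing
recovery tests therefore demonstrate that the analysis recovers trends
from activity-scale noise of realistic magnitude, not that it is robust
to count-level artifacts.

## Trend analysis by shape-constrained least squares

Activity versus site count is fitted, per affinity level, with four
candidate shapes: flat (grand mean), isotonic increasing, isotonic
decreasing, and unimodal ("bell": isotonic up to a peak, then down, best
peak by residual sum of squares). Isotonic fits use weighted
pool-adjacent-violators on per-N cell means, which is exactly equivalent
to isotonic least squares on the raw observations. Controls enter each
fit as site count 0: normalization pins their mean to the scale's zero,
making them the natural basal anchor. Fits are compared by Gaussian AIC,
`n log(RSS/n) + 2 (p + 1)`.

Two design choices matter here. First, the parameter count `p` of a
shape-constrained fit is its mean-parameter *capacity* (K, the number of
site-count levels, for either monotone shape; K+1 for the bell, whose
peak position is estimated) rather than the number of blocks the fit
happens to realize. Block counting looks natural — the divergence of an
isotonic fit equals its block count — but the blocks are selected by the
data, and with 2 AIC points per realized block the selection among four
shapes calls roughly a quarter of pure-noise levels non-flat; capacity
counting restores type-I control (~95% of pure-noise tables yield all-flat
verdicts) while leaving power essentially untouched, because at these
sample sizes a real trend beats flat by hundreds of AIC points and the
penalty difference is constant. Second, the bell is restricted to interior
peaks: a "bell" peaking at either end *is* monotone, and admitting it
would nest both monotone models inside the bell and inflate its selection.

The per-affinity verdict is the AIC-minimal shape — flat is never excluded
by fiat — and the summary reports whether the affinity-ordered verdicts
exhibit the activating → bell → repressive switch. The expected ("truth")
classes of a mechanism are its noise-free log fold changes over the same
site counts, classified at `rtol = 0.02` (log-activity differences below
~2% are below what the assay design resolves) and mapped onto the shape
vocabulary (nonmonotonic → bell).

## Problem sizes and runtime

The test and acceptance suites use: 200 random graphs (3–8 vertices) for
three-way solver agreement; 200 reversible graphs and 500 balanced
recruitment parameter sets for equilibrium consistency; 1000 parameter
sets each for the direction condition and for the four monotonicity
suites (equilibrium single-site, coherent recruitment, coherent cycle,
coherent multisite); 25×25 regime maps; 120 occupancy oracle points
(N ≤ 6); and 100 synthetic-assay replicates per condition. These sizes
run in a few minutes on one CPU while leaving the statistical conclusions
comfortably determined.

## Known limitations

* Spanning-tree enumeration is exponential in principle; beyond 12
  vertices the solver switches to the nullspace route, losing the
  tree-sum's structural transparency (not its accuracy).
* Edge labels are affine in a single scalar input; multi-input regulation
  (two TFs, a TF plus a chromatin regulator) is out of scope.
* The occupancy-averaged model assumes TF binding equilibrates fast
  relative to the cycle; the explicit-binding graph relaxes this but is
  limited to `N <= 8`.
* Heterogeneous site affinities and TF–TF cooperativity between sites are
  not modeled.
* The shape analysis substitutes isotonic/unimodal least squares for
  shape-constrained additive models; it reproduces the decision structure
  (four shapes compared by AIC) but not spline-level smoothness, and its
  AIC values are not comparable to a GAM's.
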