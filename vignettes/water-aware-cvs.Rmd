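---
title: "Water-aware machine-learned collective variables: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-aware machine-learned collective variables: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hydrocv)
```

# The problem

Binding and unbinding of a guest molecule in a host cavity is rare-event
kinetics: the free-energy barrier is crossed only when the water in and
around the binding pocket reorganizes. Enhanced-sampling methods amplify the
fluctuations of a collective variable (CV), so their efficiency hinges on the
CV capturing those slow, non-local water rearrangements. `hydrocv` implements
the full stack for building and using such a water-aware CV:

1. **descriptors** — smooth water coordination numbers at ligand-centred
   points (`L_i`) and at fixed points along the binding axis (`V_i`), giving
   a vector `d` that sees both the ligand's solvation shell and the pocket's
   hydration state;
2. **Deep-LDA** — a small feed-forward network whose last hidden layer `h`
   is classified by linear discriminant analysis; the network is trained by
   maximizing Fisher's ratio `J(w) = (w'S_b w)/(w'S_w w)` between
   configurations sampled in the bound (B) and unbound (U) states, and the
   CV is `s = w'h` followed by the cubic smoothing `s_w = s + s^3`;
3. **OPES** — an on-the-fly probability-enhanced sampling bias on
   `(s_w, s_z)` with a barrier cap `dE` and bias factor `gamma`;
4. **funnel + analysis** — a cone-and-cylinder restraint with its analytic
   standard-state correction, umbrella-like reweighting, block errors,
   binding free energies and replica combination, SAMPL5-style accuracy
   metrics, and derivative-based descriptor ranking.

Everything is exercised end-to-end on synthetic systems with exact or
quadrature references, so each stage is falsifiable at desk scale.

# The toy systems and what they do (not) emulate

## Two-class Gaussian descriptors

`make_gaussian_classes()` draws descriptor vectors from two multivariate
normals. This is the cleanest oracle for the LDA/Deep-LDA stack: the optimal
discriminant is known in closed form, so learned projections can be compared
against analytic ones. It does not emulate descriptor nonlinearity or
non-Gaussian tails of real coordination-number fluctuations.

## The 2-DOF binding/hydration landscape

`toy_landscape()` couples a binding coordinate `z` (double well at
`z = ±1 nm`, barrier `epsilon = 5 kBT`) to a pocket-hydration coordinate `q`
that tracks a z-dependent equilibrium `qbar(z)` switching from dry
(`q_B = 0`) to wet (`q_U = 4`) with steepness `alpha = 3 nm^-1` and stiffness
`kappa = 10 kBT`. Because the `q` restoring term is Gaussian at every `z`,
the exact marginal free energy is `F(z) = epsilon (z^2-1)^2` + const, which
the package also recovers by direct 2-D quadrature
(`landscape_fes_quadrature()`) as an independent reference.

A property worth emphasizing, because the whole package exists for it: the
transition valley is *narrow and curved* (at the saddle the stiffness across
the valley is `kappa * qbar'(0)^2`, two orders of magnitude above the barrier
curvature), so the hydration coordinate gates the kinetics. Biasing `z`
alone produces a flat *marginal* `F(z)+V(z)` yet the walker still crosses
only a couple of times per `2e6` steps — a faithful miniature of why
water-blind CVs fail for host-guest binding. Quantitative free-energy
recovery therefore uses biases that act on the hydration degree of freedom
too, either the identity pair `(z, q)` or the trained Deep-LDA pair
`(s_w, s_z)`.

## Host + ligand + water-bead frames

`toy_host_guest_frames()` builds 3-D geometric fixtures: a cylindrical
cavity (radius 0.5 nm, depth 0.8 nm) along +z, a three-bead ligand either
buried in a dry cavity (B) or solvated beyond the funnel mouth (U), and
uniformly placed water beads excluded from (B) or filling (U) the cavity.
These frames give the descriptor module states with known contrasts (deep
axis points dry in B, wet in U; ligand coordination larger in U). They have
no water structure, hydrogen bonds, periodic boundaries or electrostatics;
passing tests on them shows the descriptor/CV/ranking machinery is correct,
not that the toy is a water model.

# Dynamics and integrator choices

Overdamped (position) Langevin with Euler-Maruyama updates is used because
its stationary law is exactly Boltzmann in the limit of small `dt`, giving a
clean testing target. Units: nm, kcal/mol, `k_B = 0.0019872041`
kcal/mol/K, `T = 300 K` by default.

Defaults `friction = 10`, `dt = 1e-3` were fixed from Kramers-rate
estimates before any acceptance measurement: they make unbiased barrier
crossings of the default landscape rare (O(1) per `1e6` steps) while biased
runs cross freely, and they keep the Euler-Maruyama variance distortion of
the stiffest mode (`kappa * qbar'^2 ≈ 214` kcal/mol/nm^2) near 2%, the
documented stability criterion (a harmonic well's sampled variance must stay
within a few percent of `kBT/k`).

Because the unbiased default landscape crosses so rarely *by design*, global
unbiased equilibration cannot be observed in `1e6` steps; the
sampling-correctness check against quadrature is run on an
`epsilon = 1 kBT` variant (total-variation distance of the `z` marginal),
plus a within-basin variance check at the default barrier.

# OPES implementation notes

The bias is `V(s) = (1 - 1/gamma) kBT log(P(s)/Z + eps)` with
`eps = exp(-beta dE/(1 - 1/gamma))`, built from a weighted Gaussian-kernel
estimate `P` of the unbiased CV distribution: kernels are deposited every
`stride = 500` steps with weight `e^{beta V}`, bandwidths start from the CV
standard deviation of a short unbiased run and shrink with the effective
sample size (a `shrink_bandwidth = FALSE` fixed-bandwidth variant exists),
kernels merge when closer than one bandwidth, and `Z` is the mean of `P`
over kernel centers. `gamma = 10` and `dE = 10 kBT` are the package
defaults. The exact lower bound `V >= -dE` holds by construction; the
*range* of the bias can exceed `dE` by the `log(P_max/Z)` term (about 25% on
the toy double well), which is a property of the formulas, not a bug.

For production-style studies the vignette's own guidance is the standard
one: set `dE` slightly above the known barrier (here `6 kBT` against a
`5 kBT` barrier) so the bias does not dig deeply into the confining walls,
and use the funnel's outer wall (here `|z| <= 1.6 nm`) to stop the unbound
ligand from wandering into regions that contribute nothing to the binding
integral.

# Free energies and errors

Reweighting uses the umbrella-sampling-like weights `e^{beta V}` with the
first 25% of each run discarded as the bias build-up transient. FES curves
are `-kBT log P` with the minimum at zero and empty bins masked (NA), and
per-bin errors come from a 5-block (default) block average; `block_error()`
implements the generic contiguous-block standard error.

The binding free energy is
`DeltaG = -kBT log( C0 pi R_cyl^2 Int_bound e^{-beta (F(z)-F_U)} dz )`,
with `F_U` the mean FES over an unbound window inside the funnel cylinder
and `C0` = 1 mol/L = 1/1.660 nm^-3. The `C0 pi R_cyl^2` factor is the
analytic funnel correction; no separate reference-length parameter exists —
the axial length scale enters only through the explicit integral, which
removes a classic unit ambiguity. Windows are configuration: for the toy
landscape the package's studies use `[-1.35, -0.65]` (bound) and
`[0.65, 1.35]` (unbound), centred on the wells where the FES is well
sampled.

Replica estimates (independently trained CVs, or independent seeds) are
pooled by the inverse-variance weighted mean (`combine_replicas()`), the
same "weighted block average over simulations" protocol used to report
final binding numbers; two replicas are considered consistent when their
difference is within twice the combined standard error. The toy transition
is diffusion-limited along a long curved valley, so a single desk-scale run
carries a few tenths of kcal/mol of statistical spread — the quantitative
FES/DeltaG benchmarks therefore always quote the combined estimate over
three seeds. Problem sizes and settings used in the shipped studies:
`3e7` steps per seed at `dt = 1.8e-3` (the documented 2% stability limit
for the landscape's stiffest mode; the leading Euler-Maruyama distortion of
the free energy at this `dt` is ~0.02 kcal/mol, far below the statistical
resolution) for free-energy recovery, fixed-bandwidth kernels with a 1.5
merge threshold to keep the kernel store compact over long runs, `1e7`
steps per replica for CV-robustness runs, 60-frame descriptor sets per
state for the host-guest fixture, and networks of width 32-16-8 (toy
landscape: 8-4).

# Deep-LDA training choices

* Scatter convention: per-class sample covariance (divided by `n-1`),
  summed into `S_w`; Fisher's ratio is scale invariant, only the convention
  must be stated.
* Regularizer `lambda = 0.05` on `S_w` keeps wide feature layers
  well-conditioned; evaluation-time comparisons against plain LDA use
  `lambda = 0`, where the ratio is affine invariant (a single linear layer
  then reproduces plain LDA *exactly*, which is the package's linear-limit
  test).
* Architecture default `N_d -> 32 -> 16 -> 8`, ELU activation (a smooth
  ReLU-type unit: the CV gradient feeds biasing forces and derivative
  rankings, so it must be continuous); Adam (`lr = 2e-3`),
  full batch, 80/20 stratified split, early stopping after 50 stagnant
  epochs, best-validation weights kept.
* Sign convention: the bound class projects positive; the affine rescale
  maps training projections onto `[-1, 1]` so the cubic `s + s^3` acts on
  its design range. Both are stored in the model archive (plain JSON at full
  precision; identical seeds give byte-identical archives).
* The gradient of the Fisher loss with respect to the features is computed
  analytically (`(S_w + lambda I)^{-1}` solves, rank-one between-class
  term) and backpropagated by hand; the C++ integrator carries an exact
  mirror of the forward/gradient pass, cross-checked to 1e-10 in the tests.

# Descriptor ranking

`descriptor_relevance()` reports `mean |ds_w/dd_i|`, normalized to sum to 1
(a max-normalized option exists). The gradient of the *biased* CV `s_w` is
used — the cubic factor `1 + 3s'^2` rescales per sample and belongs to the
CV actually driving the dynamics; the raw-`s` ranking is available via
`of = "s"`. Per-state reports average over replica models, which is how the
bound/unbound contrast (cavity `V_1`, `V_2` descriptors gaining weight in
the unbound state) is made robust to training noise.

# Numerical details and degenerate inputs

* `switching()` handles the removable singularity at `r = r0` explicitly
  (value `n/m`); descriptors are continuous through the shell radius.
* Empty water sets give zero descriptors; empty OPES states give zero bias;
  empty histogram bins give masked FES values, never infinities on disk.
* `combine_replicas()` rejects zero errors with disagreeing values
  (degenerate weights).
* Trajectories abort with a diagnostic when a coordinate exceeds a bound
  (divergence guard); non-finite CV values abort a deposition.
* Kernel merging uses the bandwidth-scaled nearest neighbour with a single
  merge per deposition; `Z` is recomputed exactly after every deposition.

# Known limitations

* The toy systems contain no explicit solvent structure; conclusions about
  real host-guest systems require the descriptor/CV stack to be coupled to
  an MD engine (the model archive and the exported CV function are the
  integration points; no PLUMED bindings are shipped).
* Overdamped dynamics has no inertia; rates are not transferable, only
  stationary distributions.
* The OPES implementation is single-walker and pins the algorithmic
  details listed above; multi-walker and explicit-solvent variants are out
  of scope.
* Desk-scale statistics: the quantitative free-energy checks operate at a
  few tenths of kcal/mol resolution per seed and rely on replica
  combination, exactly as stated above.
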