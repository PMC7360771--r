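---
title: "Learned additive exchange-correlation functionals: model, training, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned additive exchange-correlation functionals: model, training, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nxcr)
```

## The model

`nxcr` implements a machine-learned *additive* correction to a
density-functional baseline. The corrected functional is

$$E_{\mathrm{NXC}}[\rho] = E_{\mathrm{base}}[\rho] + E_{\mathrm{ML}}[\rho],
\qquad
V_{\mathrm{NXC}}[\rho] = V_{\mathrm{base}}[\rho] + V_{\mathrm{ML}}[\rho],$$

so a null correction reproduces the baseline exactly, and the correction
can drive self-consistent field (SCF) calculations through its functional
derivative.

The learned part is built in four stages.

**Projection.** The density is projected onto an orthonormal atom-centered
basis $\psi_{nlm}(\mathbf r - \mathbf R_I) = Y_{lm}(\hat r)\,\zeta_n(r)$:

$$c^I_{nlm} = \int \rho(\mathbf r)\,
  \psi_{nlm}(\mathbf r - \mathbf R_I)\, d\mathbf r .$$

The raw radial functions are $\tilde\zeta_n(r) \propto r^2 (r_o - r)^{n+2}$
inside an outer cutoff $r_o$ and zero beyond it (the inner cutoff is fixed
at zero); they vanish at both $r = 0$ and $r = r_o$, so every basis
function -- and hence the assembled potential -- is continuous and strictly
confined to the cutoff spheres. Each raw function is normalized to unit
$L^2$ norm under the measure $r^2\,dr$ and the set is orthogonalized by the
symmetric (Loewdin) transformation $S^{-1/2}$, which is basis-order
independent and deterministic. Real spherical harmonics are used in a
fixed, Condon--Shortley-phase-free convention with $m = -l,\dots,l$; the
convention matters only for serialized coefficients, because the invariants
below do not depend on it.

**Symmetrization.** Rotation and reflection invariance is obtained from the
diagonal power spectrum of each $m$-block:

$$d^I_{nl} = \sum_{m=-l}^{l} \left(c^I_{nlm}\right)^2 .$$

No cross-$(n,n')$ or bispectrum channels are used.

**Atomic networks.** A per-species feed-forward network $\epsilon_\alpha$
with sigmoid hidden layers and a linear head maps each atom's preprocessed
invariants to an atomic energy, and the total is
$E_{\mathrm{ML}} = \sum_I \epsilon_{\alpha_I}(\mathbf d^I)$. Summing
identical per-species networks makes the energy invariant under any
permutation of same-species atoms by construction. The head's trainable
bias acts as a per-species constant shift (an atomic reference energy);
it is on by default.

**Potential.** Because the coefficients are linear functionals of the
density, the functional derivative collapses to a finite linear
combination of the basis functions,

$$V_{\mathrm{ML}}(\mathbf r)
  = \sum_\beta \frac{\partial E_{\mathrm{ML}}}{\partial c_\beta}\,
    \psi_\beta(\mathbf r),
\qquad
\frac{\partial E_{\mathrm{ML}}}{\partial c_{nlm}}
  = 2\,\frac{\partial E_{\mathrm{ML}}}{\partial d_{nl}}\, c_{nlm},$$

with $\beta = (I, n, l, m)$. All derivatives -- through the network, the
preprocessing pipeline (affine plus an orthogonal projection) and the power
spectrum -- are computed analytically, never by finite differences: a
conservative potential requires exact $\partial E/\partial c$. The
potential vanishes identically outside the union of cutoff spheres.

A model can consume either the full density $\rho$ or the neutral
difference density $\delta\rho = \rho - \rho_{\mathrm{atm}}$, where
$\rho_{\mathrm{atm}}$ superposes spherical atomic profiles carrying the
species' valence charges ($\delta\rho$ integrates to zero). Because
$\rho_{\mathrm{atm}}$ does not depend on $\rho$, the coefficient
derivatives -- and therefore potential assembly -- are identical either
way; the choice is a recorded model flag. The atomic profile is the
(non-negative) first raw radial function — the simplest spherical profile
consistent with filling the basis with valence charges; any other smooth
choice only shifts the correction the network learns. Its scale is fixed
on the target grid's *own* quadrature rather than the analytic radial
integral: coarse uniform grids integrate the peaked profile with
$10^{-5}$-level relative error, which would leak into the neutrality of
$\delta\rho$; discrete normalization makes
$\int \delta\rho\,d\mathbf r = 0$ hold to machine precision on every
backend, and the continuum normalization is recovered under grid
refinement.

## Delta learning

Given triplets of baseline energies, reference energies and baseline
densities, training minimizes

$$\mathcal L = \sum_i \left[\left(E^{(i)}_{\mathrm{ref}}
  - E^{(i)}_{\mathrm{base}}\right) - E_{\mathrm{ML}}[\rho^{(i)}]\right]^2,$$

which is invariant under adding any constant to both energy columns.
Preprocessing per species: a variance filter (threshold $10^{-10}$) drops
numerically constant features; survivors are standardized to zero mean and
unit variance; principal-component projection retains the smallest axis
count reaching an explained variance $\gamma \in [0.95, 1]$. A $\gamma$
below one regularizes: it removes exactly the low-variance directions in
which whitening would otherwise amplify the network's input sensitivity --
and therefore the learned potential -- without data to constrain it.

Optimization is full-batch Adam with the conventional rates
($\alpha = 10^{-3}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$) by default;
mini-batching is unnecessary at these dataset sizes. Two knobs extend the
plain optimizer and are logged with every run: an optional per-epoch
learning-rate decay factor (`lrDecay`), used when an experiment needs
convergence to tight absolute tolerances (constant-rate Adam stalls at a
parameter error proportional to its learning rate), and an optional
internal 10% validation split with early stopping (best parameters
restored; patience in validation checks). The $\ell_2$ penalty applies to
trainable weights only, never biases. Hyperparameters ($\gamma$, rate,
penalty, width) are selected by $k$-fold cross-validation with
deterministic, seed-derived folds: $k = 5$ below 100 samples, else
$k = 3$; exact ties break toward the earlier grid entry; the winner is
retrained on the full set.

### Iterative (freeze-and-grow) training

A functional altered by a correction changes its own self-consistent
densities, so the accuracy of a model *used self-consistently* is lower
than its fit accuracy. Iterative training remedies this: iteration 1
trains on baseline densities; iteration $n+1$ re-projects densities made
self-consistent with model $n$, freezes every existing hidden layer, and
appends one new trainable hidden layer of the same width. Training stops
when the self-consistent MAE changes by less than 1% (configurable)
across two subsequent iterations, or after five iterations.

Two design choices here were genuinely open and deserve their rationale:

* **Where the new layer goes and how it starts.** The new sigmoid layer is
  inserted immediately before the linear head *as a skip connection*: the
  head sees both the previous top activations and the new layer's outputs,
  and its weights on the new block start at zero. The grown model is
  therefore *function-identical* to iteration $n$ before any training.
  The obvious alternative -- plain insertion with a re-initialized head --
  was tried and discards what iteration $n$ learned; on the built-in
  benchmark it made the self-consistent error increase monotonically.
* **Pipelines are fitted once, in iteration 1, and reused.** Refitting
  center/scale/principal axes on the drifted descriptors would silently
  rescale the inputs of frozen layers trained in the old coordinates,
  defeating the point of freezing. Feature drift between iterations is
  small (the correction is a perturbation); the frozen coordinates absorb
  it.
* **The moving target.** For iterations $\ge 2$ the loss compares
  $E_{\mathrm{ref}}$ with $E_{\mathrm{base}}[\rho] + E_{\mathrm{ML}}[\rho]$
  evaluated at the *same* current density: the baseline energy is
  re-evaluated at each sample's latest self-consistent density rather than
  frozen at its original value. Otherwise the model is asked to reproduce
  an energy difference that no longer corresponds to the densities it
  sees.

## The toy self-consistent solver

To exercise the potential pathway without a production DFT host, the
package ships a deliberately minimal Kohn--Sham-like solver: spinless
electrons in a hard-wall cubic box, $H = -\tfrac12\nabla^2 + v_{\mathrm{ext}}
+ v_{\mathrm{base}}[\rho]$ with Gaussian external wells, a 7-point
finite-difference Laplacian, and one electron per lowest eigenstate. The
baseline functional is a local density power,
$E_{\mathrm{base,loc}} = c\int \rho^{4/3}$, chosen because it is cheap,
smooth, has the analytic derivative $\tfrac43 c\,\rho^{1/3}$, and is
clearly distinct from anything the correction learns. Densities are full
3-D fields on grids up to $64^3$ so the projector and potential code paths
run verbatim -- there is no special-cased 1-D mathematics anywhere.

Eigenpairs come from ARPACK (smallest-algebraic, via `igraph`); the
solver's random starting vector is drawn from R's RNG under a fixed
per-call seed, which makes every diagonalization -- and hence the whole
SCF trajectory -- bitwise reproducible. The SCF loop uses damped linear
density mixing (default coefficient 0.3) accelerated by one step of
Anderson extrapolation. Plain linear mixing was the first implementation;
it cannot converge the learned-potential map when the fitted curvature
makes the fixed point only marginally contracting (a residual plateau at
$\sim 10^{-4}$ electrons was observed), while the single-history Anderson
step solves the same systems in 15--40 cycles to the $10^{-8}$-electron
residual target. The extrapolation coefficient is clamped to $[-30, 30]$
and falls back to plain mixing when the residual difference is degenerate,
so the null-correction path remains bit-identical to the baseline path.
Non-convergence either raises an error carrying the residual history or,
in driver mode, flags the sample and continues.

## The synthetic benchmark

The generator stands in for an external reference dataset. Geometries are
a three-center "molecule" (one heavy, two light atoms, separations
$\approx 5.6$ Bohr so cutoff spheres stay disjoint) deformed by seeded
Gaussian noise (s.d. 0.15 Bohr per coordinate). Densities are per-atom
anisotropic Gaussians -- base widths drawn from $[0.5, 1.1]$ Bohr, per-axis
scalings from $[0.75, 1.3]$, random orientation -- normalized to the
species' valence charges. Reference energies derive from a known analytic
target functional

$$E_t[\rho] = \sum_j a_j \int \rho^{p_j}
  + a_{\mathrm{nl}} \sum_a \Big(\int \rho\, g_a\Big)^2,$$

with local powers $p = \{4/3, 3\}$ ($a = \{0.05, 0.02\}$) and per-atom
Gaussian overlap weights $g_a$ of width 1.1 Bohr
($a_{\mathrm{nl}} = 0.25$). Two properties of this choice matter:

* every term decomposes over atoms, so an additive per-atom model *can*
  represent it (an early draft with a single molecule-centered overlap
  squared coupled different atoms and was unlearnable by construction --
  an architectural impossibility, not a capacity statement);
* the squared overlaps are quadratic in the projection coefficients with
  cross-radial products, so they are *not* linear in the power-spectrum
  invariants, and network depth is required for full recovery.

One honest caveat, encountered while calibrating: a *linear* readout of
the $\sim$34 invariants is already a rich function class on this data,
because the features are themselves nonlinear functions of a roughly
ten-dimensional latent space of geometry and width parameters -- a
hyperplane restricted to a curved feature manifold interpolates smooth
functions well. Under the frozen conditions the linear model plateaus
near 3% of the target standard deviation (far above any full-recovery
tolerance) while the width-8 network reaches about 0.5%; the
depth-is-required property is therefore asserted as a factor-$\ge 4$ error
ratio rather than as the linear model failing some absolute bar. The
generator emulates smooth valence densities responding to deformation; it
does not emulate core cusps, shell structure, inter-atomic charge
transfer, or any published dataset's distribution -- passing tests here
show the machinery is correct and the capacity adequate, not that any
particular chemistry is reproduced.

Reference noise defaults to zero (clean recovery); a noisy preset
(`noiseSd > 0`) exercises regularization and $\gamma$ selection.

The self-consistency benchmark (`makeToyBenchmark()`) uses two-well
systems with two electrons; reference energies come from solving the
target functional *self-consistently* (its derivative is analytic), so
reference densities genuinely differ from baseline ones and the
iteration-1 model starts with a self-consistency gap of roughly an order
of magnitude between fit error and self-consistent error -- the regime
iterative training addresses. The training conditions for this study
($\gamma = 0.95$, $\ell_2 = 0.05$, width 6) also keep the fitted
functional's curvature small enough that the corrected SCF map stays
contracting; with negligible regularization a model fitted on 32 atomic
environments can acquire spurious curvature that makes its own SCF
unstable -- the observation, at toy scale, of why self-consistent accuracy
and fit accuracy are different things.

## Grids, quadrature, and numerical choices

Two interchangeable grid backends carry all integrals:

* **Uniform voxel grids** (cube-file compatible; weights are the voxel
  volume). Midpoint quadrature of smooth, decaying integrands converges
  super-algebraically; the default generation grid ($52^3$ over a 22 Bohr
  box) keeps density normalization errors below $10^{-6}$ relative for
  the narrowest default widths. Projection on uniform grids carries a
  looser effective tolerance ($\sim 10^{-4}$ for basis orthonormality at
  typical SCF spacings) -- adequate for learning, and exactly consistent
  between projection and potential assembly because both use the same
  discrete quadrature.
* **Atom-centered product quadrature**: per-atom Gauss--Legendre radial
  rule crossed with a spherical product rule (Gauss--Legendre in
  $\cos\theta$, trapezoid in $\phi$), which integrates spherical
  harmonics exactly up to the rule's degree. Per-atom basis Gram matrices
  are identity to $\sim 10^{-11}$ here. A tabulated Lebedev rule would
  save about a factor of two in angular points; the product rule was
  chosen because it is exact, transparent, and a few lines of code.
  Atom-centered grids require disjoint cutoff spheres (an error
  otherwise); overlapping-sphere systems use the uniform backend. Becke
  partitioning was deliberately not implemented.

Other numerical decisions, stated once: Loewdin orthogonalization is
computed from the eigendecomposition of the raw radial overlap with a
conditioning guard (error above condition number $10^{14}$); periodic
grids use the minimum-image convention and refuse cutoff diameters
exceeding the shortest cell vector rather than silently double-counting;
principal-axis signs are fixed (largest-magnitude component positive) so
serialized pipelines are reproducible; all randomness flows from seeds
held below $2^{31}$; units are Bohr and Hartree internally, with Debye and
Angstrom appearing only in the moments report and eV only at the CLI
boundary.

Problem sizes used by the shipped tests and the acceptance script are the
package's standard study conditions: $16^3$ SCF grids with 16 benchmark
systems for the self-consistency study, $n = 500$ training / 100 held-out
samples for the recovery experiment, five seeds for the learning curve,
and 20 random rigid motions for the invariance suite.

## Density moments

For diagnostics, `densityMoments()` reports the dipole, the traceless
quadrupole tensor (Buckingham convention, nuclei as point charges at the
atomic positions carrying the species' valence charge -- consistent with a
valence-only density description), the rotation-invariant scalar
$Q_T = \tfrac12(q_{\max} - q_{\min})$ of that tensor, and the
charge-weighted second radial moment
$\langle r^2\rangle = -\int r^2 \rho_{\mathrm{val}}$ (negative by the
electron-charge sign convention). Dipoles are printed in Debye and
second moments in Debye-Angstrom. For non-neutral systems the dipole is
origin-dependent; the function warns and records the origin instead of
refusing.

## Serialization, interfaces, provenance

Models and descriptor sets serialize to hierarchical RDS archives holding
pipeline statistics, principal axes, layer weights, the species map, the
$\delta\rho$ flag, and a basis hash; loading a model restores bit-identical
energies, and evaluating a model against descriptors from a different
basis is an integrity error, not a warning. Densities interchange as
Gaussian cube files (Bohr dialect written; both sign conventions read),
geometries as XYZ (Angstrom on disk, Bohr in memory), basis sets and run
configuration as YAML, and energy tables as TSV. Every CLI artifact is
written next to a resolved-config snapshot and content hash. The command
line (`inst/cli/nxcr`, a thin wrapper over `cliDispatch()`) exposes
`generate`, `project`, `train`, `cv`, `iterate`, `evaluate`, `scf-toy`
and `moments`, with distinct exit codes for usage/validation (2),
integrity (3) and runtime (1) failures.

## Known limitations

* No nuclear forces: the Hellmann--Feynman pathway needs a host SCF code's
  machinery. No spin polarization, no plane-wave or atomic-orbital density
  representations, no pseudopotential construction.
* The toy solver makes no claim of chemical realism; it exists so the
  potential pathway and iterative training are exercisable end to end.
* Transferability of a trained model is only as good as the overlap
  between training and evaluation feature distributions; the learned
  potential is reliable where data constrained it, and $\gamma < 1$ plus
  $\ell_2$ regularization are the honest guard rails, not a cure.
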