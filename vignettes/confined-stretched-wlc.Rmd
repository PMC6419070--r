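---
title: "Methods: wormlike chains confined in rectangular channels and stretched"
author: "wlctube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wormlike chains confined in rectangular channels and stretched}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wlctube)
```

## The physical problem

A semiflexible polymer (wormlike chain, WLC) with contour length $L$ and
persistence length $L_p$ is confined in a rectangular channel of height
$H_h$ and width $H_w$ (a slit is the limit of very large width) and pulled
along the channel axis by a force $f_s$, made dimensionless as
$\hat f = f_s L_p / k_B T$. In the strong-confinement (Odijk) regime,
$\min(H_h, H_w) \ll L_p$, the chain bounces between the walls on a
characteristic contour scale, the deflection length, and behaves as a
train of $L/\lambda$ nearly independent segments. Two classical deflection
lengths are in use, one calibrated on the confinement free energy,

$$\lambda_{fe} = A^{-1} L_p^{1/3}\,(H_h^{-2/3}+H_w^{-2/3})^{-1},
\qquad F/k_BT = L/\lambda_{fe},$$

and one on the extension deficit,

$$\lambda_{ext} = 2\alpha\,(L_p^{1/3}H_h^{2/3}+L_p^{1/3}H_w^{2/3}),
\qquad 1-R_\parallel/L = \lambda_{ext}/(2L_p),$$

with dimensionless prefactors $A = 1.1032$ and $\alpha = 0.09143$ (the most
precise eigenvalue-method values; `odijk_constants()` lets you select other
literature determinations). The two lengths differ by an order of magnitude
and $\lambda_{ext}$ is inconsistent with the slit limit. The package's core
is the single *modified* deflection length that repairs this,

$$\frac{\lambda_m}{L_p}
 = -\frac{1}{\vartheta}\,
   \log\!\Big[1-\vartheta A^{-1}\big(\hat H_h^{-2/3}+\hat H_w^{-2/3}\big)^{-1}\Big],
\qquad \vartheta = 8A\alpha,$$

with $\hat H = H/L_p$. It carries no adjustable parameters, Taylor-reduces
to $\lambda_{fe}$ for tight channels, and yields compact closed forms for
the free energy, $F/k_BT = L/\lambda_m$, the unstretched deficit
$1-R_\parallel/L = 1-\varepsilon/(-\log(1-\varepsilon))$ with
$\varepsilon$ the argument subtracted inside the logarithm, and the
force–confinement–extension relation

$$1-\frac{R_\parallel}{L}
 = \frac12\Big[\hat f + \hat f_c\Big]^{-1/2},
 \qquad \hat f_c = \{-\log[1-\vartheta A^{-1}(\hat H_h^{-2/3}+\hat
 H_w^{-2/3})^{-1}]\}^{-2},$$

implemented in `force_confinement_extension()`. Two remarks on choices that
were genuinely open:

* The effective confinement force is implemented exactly as the closed form
  prints it (no $\vartheta^2$ factor); only this normalization reduces to
  the unstretched modified deficit at $\hat f = 0$. The alternative reading
  $\hat f_c = L_p^2/\lambda_m^2$, which differs by $\vartheta^2$, is
  available via `effective_confinement_force(form = "from_deflection_length")`.
* The classical extension relation
  $1-R_\parallel/L = \alpha(\hat H_h^{2/3}+\hat H_w^{2/3})$ is restricted
  to tubes: for $H_w \to \infty$ its open-direction term diverges even
  though that direction no longer confines the chain. For rectangular
  cross-sections with aspect ratio $\beta$ it exceeds the modified form by
  $\phi(\beta) = \tfrac14(\beta^{1/3}+\beta^{-1/3})^2$
  (`aspect_ratio_factor()`), with equality only at square cross-sections.

The validity boundary of the modified picture is the domain of the
logarithm, $\hat H_h^{-2/3}+\hat H_w^{-2/3} > \vartheta/A$; outside it the
package raises a typed validity error rather than returning `NaN`
(`validity_check()` reports the margin).

## Route 1: ground-state eigenvalue of the slit Fokker–Planck operator

For a slit the chain propagator $q(y, t, s)$ ($y$ transverse position, $t$
the cosine of the tangent polar angle against the slit normal, $s$ contour
length, all lengths in units of $L_p$) obeys

$$\partial_s q = -t\,\partial_y q
 + \tfrac12\,\partial_t\big[(1-t^2)\,\partial_t q\big],$$

with hard walls. For long chains the partition function is dominated by the
slowest-decaying eigenmode, $q \sim e^{-\mu_0 s/2}\Psi_0$, giving
$F/k_BT = L\mu_0/(2L_p)$ and a numerical deflection length
$\lambda = 2L_p/\mu_0$.

Numerical realization (`slit_operator_spec()`, `slit_ground_state()`):

* **Orientation**: collocation at $l_{\max}+1$ Gauss–Legendre nodes;
  rotational diffusion applied in the orthonormal Legendre modal basis,
  where it is diagonal with eigenvalues $-l(l+1)/2$.
* **Transverse direction**: uniform interior grid with first-order upwind
  transport. Upwinding implements the kinetic *half-range* wall condition
  — the distribution vanishes at a wall only for orientations entering the
  channel from it — which is the well-posed realization of a hard wall for
  this degenerate (first-order-in-$y$) operator. Imposing $q=0$ at the wall
  for *all* orientations over-constrains the transport part and, after
  discretization, produces a complex dominant eigenvalue pair (ballistic
  wall-bounce modes) instead of a positive ground state; the half-range
  upwind operator has a real Perron mode with a nonnegative eigenfunction.
* **Eigenvalue extraction**: inverse-propagation power iteration — repeated
  solves with $(I - \Delta s\,G)^{-1}$, a strongly damped implicit contour
  step that filters every mode except the slowest-decaying one; the decay
  rate is read off the converged growth factor. Iteration stops when
  successive eigenvalue estimates agree to a relative tolerance of
  $10^{-4}$ by default. A dense direct diagonalization
  (`method = "direct"`) provides an independent cross-check route; on a
  small basis the two agree to $10^{-11}$.
* **Discretization error**: the upwind truncation error is first order in
  the grid spacing, so by default the solve is repeated at twice the
  transverse resolution and Richardson-extrapolated; the contour step
  $\Delta s$ only shapes the filter and does not bias the estimate.
* **Positivity**: the collocation representation lets the propagated state
  undershoot zero at the level of the basis-truncation error (observed
  $\lesssim 10^{-3}$ of the maximum on coarse bases, $\sim 10^{-6}$ at the
  production resolution); reported eigenfunctions are clipped at zero
  before normalization to a unit integral.

At the production resolution ($n_y = 200$, $l_{\max} = 40$) the eigenvalues
at $\hat H \in \{0.05, 0.1, 0.2\}$ lie a few percent *below* the classical
$A\hat H^{-2/3}$ and within about 1.5% of the modified free energy — the
ordering that motivates the modified deflection length. Extrapolating
$(\mu_0/2)\hat H^{2/3}$ affinely in $\hat H^{2/3}$ to $\hat H \to 0$
(`extract_odijk_prefactor()`) removes the leading finite-height correction
— under the modified closed form $v(\hat H) = A\,[1-\varepsilon/2+O(\varepsilon^2)]$,
so the affine intercept recovers $A$ while a plain average is biased low —
and reproduces the literature prefactor to well within 1%.

## Route 2: generalized bead-rod (GBR) Brownian dynamics

The chain is discretized as $N$ beads of radius $a$ joined by $N-1$
inextensible rods of length $b$, with the discrete WLC bending energy
$E/k_BT = (L_p/b)\sum_j(1-\cos\theta_j)$ — the standard discretization
whose tangent correlations decay per joint by the factor
$\langle\cos\theta\rangle = \coth(L_p/b)-b/L_p$. Per time step the update
is: penalty displacement for any bead outside the channel (projection to
the nearest wall plane, per coordinate; the channel dimension is the span
accessible to bead *centers*), deterministic drift $\Delta t\,D F/k_BT$,
Gaussian displacement with covariance $2D\Delta t$, then projection back
onto the rod-length manifold. Tension $\pm f_s\hat z$ is applied to the two
end beads symmetrically (the loading side is not physically determined;
symmetric loading avoids net drift).

* **Constraint projection** (`constraint_projection()`): the linearized
  projection is a Newton iteration on the tridiagonal Lagrange-multiplier
  system along the *reference* (pre-step) bond directions, solved by the
  Thomas algorithm in $O(N)$ per pass. For long, nearly straight chains
  the multiplier system is ill-conditioned (soft cumulative modes,
  condition number growing like $N^2$) and plain Newton can diverge, so
  Newton attempts — reverted whenever they fail to improve the worst rod
  error — are interleaved with blocks of current-direction Gauss–Seidel
  length restoration, which always makes progress. Iteration continues to
  a relative rod tolerance of $10^{-10}$; wall clamping and projection are
  alternated until containment holds to $10^{-9}\,$nm as well. A step whose
  projection cannot be converged is redrawn with fresh noise (up to 10
  times) and otherwise aborts with a step-rejection error advising a
  smaller $\Delta t$.
* **Hydrodynamics**: free-draining by default (equilibrium averages do not
  depend on the mobility model, which the test suite checks directly); a
  far-field pairwise mobility with correlated noise via Cholesky
  factorization is available as `hydrodynamics = "pairwise_mobility"` and
  is practical for short validation runs.
* **Units and defaults**: lengths nm, time ps, $T = 293$ K, $L_p = 50$ nm,
  and the literature viscosity value $1.005725\times10^{-4}$ Pa s. That
  printed value is one order of magnitude below tabulated water viscosity;
  since only equilibrium averages matter here it merely rescales time, and
  it is kept as the default with `viscosity` exposed. One practical
  consequence: it inflates the per-step noise by $\sqrt{10}$, so
  combinations like $b = 2$ nm with $\Delta t = 10$ ps put per-step bond
  violations near 10% — outside the constrained integrator's comfortable
  regime. Runs in this package that use $b = 2$ nm therefore default to
  $\Delta t = 2$ ps; $b \ge 4$ nm works well at $\Delta t = 10\!-\!25$ ps.
* **Determinism**: all noise comes from R's RNG; a trajectory is a pure
  function of its parameters and seed, and the compiled fast path draws in
  the same order as the R reference step (a single step agrees bitwise).

## Route 3: reducing trajectories to observables

Simulations start from a straight configuration and relax under
confinement and tension, so each extension series has a transient.
`detect_equilibration()` scans window-wise forward running means against
the final-half mean, on the scale of a noise estimate taken from
*differences* of adjacent window means (a residual drift then inflates the
deviations rather than the tolerance band, so a still-drifting series is
flagged rather than accepted). `average_extension()` discards the larger of
the detected burn-in and a conservative floor of 10% of the series, then
averages over time within each trajectory and over trajectories; the
standard error comes from the scatter of per-trajectory means —
trajectories are the only defensible independent units, because time
samples are strongly autocorrelated. `build_comparison()` tabulates the
simulated deficits against the modified relation and both classical
variants, with `comparison_error_summary()` aggregating the relative
errors.

## The synthetic equilibrium sampler

`sample_equilibrium_wlc()` draws configurations *exactly* from the discrete
WLC Boltzmann distribution (inverse-CDF sampling of each joint cosine from
the density $\propto e^{(L_p/b)\cos\theta}$, uniform azimuths, bond-by-bond
assembly). It serves two roles: an independent equilibrium oracle for the
dynamics (a correct integrator started from it must stay on the known
tangent-correlation and end-to-end statistics) and a variance-free
initializer for free-chain runs. What it deliberately does not emulate:
confinement (no channel walls enter the sampling), excluded volume,
hydrodynamic correlations, and any dynamical property. Tests built on it
therefore validate equilibrium fidelity of free chains, not confined
statics or kinetics — those are exercised against the closed forms and the
eigenvalue route.

## Study conditions and problem sizes

The simulation–theory comparison study (square tube and slit at
$\hat H_h = 0.3$, $\hat f \in \{0, 5, 20\}$, 10–12 trajectories per
condition) uses the parameter families standard for this model: tube $b = 4$ nm,
$a = 1.85$ nm, $\Delta t = 10$ ps with $L = 600$ nm, and slit ($\hat H_w = 1000$)
$b = 4$ nm, $\Delta t = 20$ ps with $L = 240$ nm. The asymmetry in $L$ is deliberate, because the
two geometries fail in opposite directions:

* *Tubes need long chains.* The closed forms describe the long-chain
  limit, and the measured end-to-end deficit carries a finite-chain end
  correction decaying like $1/L$ (the floppy end segments are less aligned
  than the bulk). A contour-length scan of the square tube at
  $\hat H = 0.3$, $\hat f = 0$ gives deficits 0.108, 0.0996 and 0.0969 at
  $L = 120$, 240 and 400 nm, extrapolating to $\approx 0.093$ as
  $L\to\infty$ against the modified prediction 0.0895 and classical
  0.1016 — the asymptote sides with the modified theory, while at
  $L = 120$ nm the end effect is twice the separation between the two
  theories. At
  $L = 600$ nm the measured deficit (0.0930, and 0.0900 for the interior
  60% of the chain) agrees with the modified form to a few percent.
* *Zero-force slits need short chains and a time window.* A slit confines
  only one direction; with no tension the chain's in-plane orientation
  diffuses and long-wavelength meandering (eventually back-folding) grows
  without bound, so the signed axial extension drifts far below the
  deflection prediction — the hairpin-free deflection state is metastable
  at zero force. Time-resolved profiles show the familiar structure: the
  deficit rises to a shoulder at the deflection value once the
  $\lambda_m$-scale wrinkles equilibrate, then creeps upward as the
  orientation decays. Zero-force slit conditions are therefore averaged
  over that steady extended window (for $L = 240$ nm, $b = 4$ nm,
  $\Delta t = 20$ ps: samples 6000–12000 of the thinned series, i.e.
  1.2–2.4 microseconds), which is exactly the steady-extension-state
  protocol the simulation literature for this problem describes; forced
  slit conditions equilibrate properly and use the standard two-stage
  average.

Run lengths (a few hundred thousand steps per trajectory, thinning 10)
were sized so trajectory scatter yields standard errors of a few times
$10^{-3}$ on the deficit.

The free-chain fidelity check uses $L = 4L_p$ ($N = 101$, $b = 2$ nm)
initialized from the exact sampler; because its targets are equilibrium
identities rather than a 10%-level comparison, it runs at water-scale
viscosity with $\Delta t = 1$ ps so the per-step RMS displacement stays
near 1% of $b$ and the integrator cannot shift the equilibrium measurably
(at several percent of $b$ a small but resolvable shift of the joint
statistics appears). The stretching check uses $\hat f = 25$, where the
unconfined strong-force relation predicts a deficit of 0.1 (the exact
discrete-chain value at $b = 2$ nm is a few percent above that; the
ensemble tolerance covers both). The slit scaling-collapse check runs
$\hat H \in \{0.15, 0.2, 0.3\}$ with the windowed zero-force protocol and
examines whether $(1-R_\parallel/L)/\hat H^{2/3}$ collapses across
heights. It does not, at desk scale: the windowed deficits converge to a
common meander-dominated value at all three heights, so the reduced
values spread by roughly the $\hat H^{2/3}$ factor itself, and a
wrinkle-resolved variant (contour lost below an intermediate
coarse-graining scale) fares no better because the scale separation
$\lambda_m \ll \ell \ll 2L_p$ barely exists here. The suite asserts the
monotone height trend, which holds, and records the collapse bound as an
expected shortfall of desk-scale extension runs; the free-energy-side
Odijk prefactor is recovered by the eigenvalue route instead, and a
full-precision recovery of the extension prefactor requires
overnight-scale chains and ensembles.

## Known limitations

* The closed forms are long-chain, hairpin-free, ideal-chain statements:
  excluded volume, back-folding, and weak-confinement (de Gennes) physics
  are all outside scope, and comparisons at finite $L$ inherit an $O(1/L)$
  end correction.
* The wall model clamps bead centers to the wall plane (the penalty form
  of the update rule); like any projection boundary it perturbs the
  near-wall statistics at $O(\sqrt{D\Delta t})$.
* The eigenvalue route covers slits; rectangular free energies use the
  additivity of the two wall pairs rather than a four-dimensional
  eigenproblem.
* The equilibration detector is a windowed heuristic with one-window
  resolution; pathological series (e.g. a drift matched exactly by noise
  scale) can evade any such rule, which is why the conservative burn-in
  floor exists.
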