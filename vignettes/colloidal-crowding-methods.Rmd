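---
title: "Colloidal modelling of crowded protein solutions: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colloidal modelling of crowded protein solutions: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colloidcrowd)
```

`colloidcrowd` treats a crowded solution of a globular, oligomeric protein
as a suspension of polydisperse hard spheres carrying a weak short-ranged
attraction, and implements the full multi-technique analysis that such a
model supports: dilute-solution sizing (DLS, SAXS), interaction
characterization (gradient diffusion, virial coefficients), crowded-state
dynamics (two-mode relaxation, microrheology, dynamical arrest), and
structure (forward scattering, structure factors from theory and
simulation). This vignette records the model assumptions, the parameters
that matter, what the synthetic-data generators do and do not emulate, the
numerical choices, and the known limitations.

## The size model

All stages share one polydispersity model, the Schulz (gamma)
distribution, `schulz_dist(mean_radius, sigma_star)`, with density

$$P(R) = \frac{(R/b)^{c-1} e^{-R/b}}{b\,\Gamma(c)},\qquad
c = 1/\sigma^{*2},\quad b = \langle R\rangle / c,$$

parameterized by the number-average radius (nm) and the normalized
standard deviation $\sigma^*$ (dimensionless, in $[0,1)$). Its raw moments
are closed-form (`schulz_moment()`), which makes the scattering-weighted
sizes exact:

* z-average hydrodynamic radius $R_h = \langle R^6\rangle/\langle
  R^5\rangle$ — what DLS measures in a dilute ensemble;
* intensity-averaged radius of gyration $R_g = \sqrt{3\langle
  R^8\rangle/5\langle R^6\rangle}$ — what a Guinier analysis of the
  polydisperse form factor returns.

Both are linear in $\langle R\rangle$ at fixed $\sigma^*$, so an observed
$R_g$ pins the number-average radius analytically
(`mean_radius_from_rg()`); a SAXS form-factor fit can then leave only
$\sigma^*$, a scale and a background free. Two working polydispersities
coexist deliberately: the DLS estimate ($\sigma^* \approx 0.3$) and the
SAXS fit ($\sigma^* \approx 0.475$) probe different weightings of the same
broad ensemble, and the package exposes $\sigma^*$ as a parameter
everywhere rather than hard-coding either value.

The shape layer (`shape_model()`, `ellipsoid_hydro_radius()`,
`ellipsoid_gyration_radius()`, `rh_rg_ratio_map()`) uses the
stick-boundary Perrin friction factors for ellipsoids of revolution —
validated in the tests against numerical Oberbeck integrals — and treats
polydispersity of ellipsoids as a common Schulz scale factor on both
semi-axes at fixed aspect ratio. The resulting $R_h/R_g$ map has its
maximum $\sqrt{5/3} \approx 1.29$ at monodisperse spheres; both
nonsphericity and polydispersity lower it, so a measured ratio *above*
1.29 indicates extra hydrodynamic size (e.g. a corrugated surface), not a
smooth ellipsoid.

## The interaction model

The attraction is carried in two interchangeable forms:

* **Baxter stickiness $\tau$** for the analytic relations: gradient
  diffusion $K_d = (1.454 - 1.125/\tau)\,\nu_\mathrm{eff}$ (hydrodynamic
  interactions included), the virial ratio $B_2/B_2^{HS} = 1 - 1/(4\tau)$,
  and the short-time self-diffusion slope $D_s/D_0 = 1 - (1.8315 +
  0.295/\tau)\,\phi$, valid for $\phi \lesssim 0.3$ (a warning, not an
  error, beyond that — the relation is a linear truncation).
  A measured $K_d \approx 0$ pins $\tau = 1.125/1.454 = 0.7737$
  *independently of the voluminosity* because the relation factorizes.
* **Square well** (depth $u$ in $k_BT$, outer range $\lambda$ times
  contact) for the simulation: $B_2/B_2^{HS} = 1 - (\lambda^3-1)(e^u-1)$.
  With $\lambda = 1.25$, matching the sticky-sphere virial ratio of 0.677
  requires $u \approx 0.287$; the conventional working depth $u = 0.289$
  gives 0.6806. The package reports both numbers instead of hiding the
  ~0.5% mismatch.

Volume fractions come from the effective voluminosity,
$\phi = c\,\nu_\mathrm{eff}$. Two estimates are implemented
(`voluminosity_estimates()`): the packing route
$\nu = \phi_\mathrm{arrest}/c_\mathrm{arrest}$ with
$\phi_\mathrm{arrest} = 0.64$ (random close packing, overridable), and the
hydrodynamic route $\nu = V_z N_A / M_w$ with $V_z = \frac{4\pi}{3}\langle
R^3\rangle$ for the Schulz ensemble rescaled so its z-average radius
matches the dilute $R_h$. They disagree at the ten-percent level because
they probe different physics (steric packing versus dragged water); the
report keeps both and a chosen intermediate working value (default
1.7 mL/g). The hydrodynamic estimate is rounding-sensitive: $R_h = 6.5$ nm
gives $V_z = 485.3\ \mathrm{nm}^3$, while 6.52 nm gives
$489.8\ \mathrm{nm}^3$; the exact moments make this explicit.

## Structure: theory

`carnahan_starling_s0()` gives the monodisperse hard-sphere forward
structure factor. For the polydisperse mixture, `polydisperse_hs_s0()`
computes the *measurable* zero-q limit
$$S_M(0) = \frac{\sum_{ij} f_i f_j \sqrt{x_i x_j}\, S_{ij}(0)}
               {\sum_i x_i f_i^2},\qquad f_i \propto d_i^3,$$
on an equal-count quantile discretization of the Schulz distribution. The
partial structure factors come from the exact compressibility relation
$[S(0)^{-1}]_{ij} = \sqrt{\rho_i\rho_j}\,\partial\beta\mu_i/\partial\rho_j$
applied to the BMCSL mixture equation of state (numerical Hessian of its
closed-form free-energy density). This route was chosen over the
multicomponent Percus–Yevick solution (kept as `method = "py"`, via
Baxter's factor functions) because PY's compressibility-route $S(0)$
deviates from Carnahan–Starling by ~4% already at $\phi = 0.3$ in the
monodisperse limit, while the BMCSL route reduces to it exactly; the two
routes bracket the simulation results. The $d^3$ amplitude weighting
emphasizes the large-radius tail, so the quantile ladder defaults to 150
species (the value is converged to ~1% there).

The monodisperse square-well $S(q)$
(`sw_structure_factor_mono()`) is the analytic PY hard-sphere solution
plus a first-order (random-phase) perturbation for the well,
$1/S = 1/S_{PY} - \rho\,\hat c_\mathrm{att}(q)$; it reduces to PY at
$u = 0$ and its low-q limit rises with attraction. It is used only
comparatively — the simulation is the ground truth for attractive
structure. Numerical note: the trigonometric PY coefficients lose all
precision below $qd \approx 0.01$ (differences of O(1) terms leaving
O($q^4$)); the code switches to the analytic $q \to 0$ limit there.

## Structure: event-driven simulation

`src/edmd.cpp` implements exact piecewise-ballistic dynamics of $N$
polydisperse spheres (equal unit masses, $k_BT = 1$, periodic cubic box)
with four event types: elastic core collisions at $R_i + R_j$; well entry
at $(1+\delta)(R_i+R_j)$ with a radial speed-up from the depth $-u$; well
exit attempts that escape (slow-down) only if the radial kinetic energy
$\tfrac{1}{2}\mu v_r^2$ exceeds $u$ and otherwise bounce; and cell-boundary
crossings. Events live in a binary heap with lazy invalidation via
per-particle counters; cells are at least one interaction range wide.
Total energy (kinetic plus $-u$ per bonded pair) is conserved to
floating-point accuracy (the suite demands $10^{-6}$ over $10^4$ events
and observes $\sim 10^{-14}$). A cell crossing carries its axis and
direction in the event itself and snaps the coordinate to the boundary —
recomputing the cell from the position can livelock when a particle sits
exactly on a boundary.

Design choices the physics does not dictate:

* **Equal masses** for all species: equilibrium structure is
  mass-independent, and the event algebra stays simple.
* **Initialization** sets the box from the requested volume fraction
  exactly, places particles at 20% of their final radii at random, and
  alternates small radius inflations with iterative push-apart sweeps of
  overlapping pairs until full size. This replaces an event-driven growth
  run: it reaches $\phi = 0.5$ at $\sigma^* = 0.3$ in seconds, is
  trivially verifiable (a full pairwise overlap check runs afterwards),
  and any structural memory of the protocol is erased by the
  equilibration run that follows.
* **Equilibration** demands the potential energy per particle be
  stationary between consecutive 200-events-per-particle windows (1%
  relative, or 0.01 kT per particle absolute — the absolute branch matters
  in dilute systems where |PE| is a handful of bonds).
* **Discretization**: 10 equal-count quantile species by default; the
  realized sample σ* is within 5% of the target.
* **Desk scale**: tests and the analysis scripts run at $N = 500$ (the
  acceptance-style energy checks at $N = 256$), with $N = 2000$ available
  through the same functions for production-size runs.

The measurable structure factor uses only box-commensurate wavevectors
$q = 2\pi|\mathbf n|/L$, sphere amplitudes $f_i(q) = V_i\,3(\sin qR_i -
qR_i\cos qR_i)/(qR_i)^3$, and averages over lattice directions and
snapshots. Two estimator details matter: some integer shells are
direction-poor (e.g. $|\mathbf n|^2 = 16$ has only the (4,0,0) family) and
anisotropy there masquerades as noise, so S(q) curves can aggregate
neighbouring shells into bins (`bin_halfwidth`); and $S(0)$ is estimated
as the mean of the five lowest-q points (`low_q_plateau_s0()`), a
convention shared with the experimental-curve analysis. Because $S(q)$
rises away from $q = 0$ for these systems, the plateau estimate carries a
small positive bias at finite box size; comparisons against theory in the
tests allow for it.

## Time-correlation analysis

All DLS fits work on $g_2(q,t) = b + a\,g_1(q,t)^2$ directly (the Siegert
relation), fitting the contrast $a \in (0, 1.3]$ and baseline
$b \in [0.98, 1.05]$ in the same error-weighted least-squares step as the
physical parameters (`minpack.lm`, bounded Levenberg–Marquardt,
deterministic multi-start from five log-spaced rate guesses). Lag times
are microseconds throughout; `rate_to_diffusion()` documents its units
explicitly (a rate in 1/µs at q in 1/nm gives D in m²/s).

* **Cumulant fit**: $g_1 = \exp(-t/\tau_0 + \mu t^2/2)$ on $t \le$ a
  truncation time, with $\sigma^* = \sqrt{\mu}\,\tau_0$ and negative
  $\mu$ clipped to zero with a flag. The truncation scan
  (`truncation_scan()`) repeats the fit over a ladder and flags the
  plateau region where $\sigma^*$ varies by less than 10% over a factor
  two. An important statistical caveat, verified in the tests: for a
  polydisperse ensemble the cumulant $\sigma^*$ estimates the
  *intensity-weighted rate spread*, which for Schulz sizes with $R^6$
  weights and Stokes–Einstein rates is
  $\sqrt{(5+c)/(4+c) - 1} = 0.257$ at size-$\sigma^* = 0.3$ — a
  systematically smaller number than the size polydispersity. The
  estimator is also positively biased near $\mu = 0$ (it is a square
  root) and, at the percent noise level, the baseline–curvature
  correlation makes single-correlogram $\sigma^*$ values scatter broadly;
  the truncation scan is the designed mitigation.
* **Two-mode KWW fit**: $g_1 = c\,e^{-(t/\tau_1)^{\alpha_1}} +
  (1-c)\,e^{-(t/\tau_2)^{\alpha_2}}$, with initial scales read directly
  off the decay (where it first drops below 0.7 and 0.05 of its range)
  and multi-start factors around both; $\alpha_1$ can be pinned to 1.
  Mode collapse ($\tau_2/\tau_1 < 3$ or a vanishing amplitude fraction)
  is flagged rather than silently reported. The mean slow time is
  $\bar\tau = (\tau_2/\alpha_2)\Gamma(1/\alpha_2)$.
* **Nonergodicity screen** (`is_nonergodic()`): near arrest the intercept
  drops and the baseline drifts; such correlograms are excluded from the
  ergodic chain, mirroring how arrested samples must be treated.
* **NSE**: initial-slope single-exponential fits restricted to
  correlation times below 50 ns give $D(q) = 1/(\tau_s q^2)$;
  `band_average_diffusion()` forms inverse-variance-weighted means over
  the high-q band (1.8–2.2 1/nm) and a cage band around the
  structure-factor peak.
* **Microrheology**: 300 nm-diameter tracers dominate the signal; a
  single-exponential rate plus Stokes–Einstein returns the solution
  viscosity, and a reduced-chi-square screen flags protein-scattering
  leakage (a second mode) in the tracer correlogram.
* **Arrest**: $\log\eta_r = -\gamma\log(1 - c/c^*)$ is fitted in log
  space with both $c^*$ and $\gamma$ free (log space stabilizes the
  divergence; the initial $c^*$ must exceed the largest concentration).
  Normalized slow times $\bar\tau/\tau_0$ are accepted as
  viscosity-equivalent data. The classification $\gamma < 3$
  (hard-sphere-like) versus $\gamma \ge 3$ (strong attraction) is
  reported exactly as that threshold comparison.

## Synthetic data

Every generator is the exact forward model of its analysis counterpart,
with all randomness drawn from a single integer seed (bit-identical
regeneration):

* `synth_dls_correlogram()` sums exponentials over a 256-node quadrature
  of the Schulz ensemble with intensity weights $\propto P(R)R^6$ and
  Stokes–Einstein rates, so the intensity-weighted mean rate equals
  $q^2 k_BT / (6\pi\eta R_h^{(z)})$ exactly (a moment identity the tests
  assert).
* Correlogram noise is multiplicative Gaussian with a lag-dependent
  floor, $\mathrm{sd} = \mathrm{noise}\,(a\,g_1^2 + 0.3a)$: the floor
  mimics correlator counting statistics, whose baseline noise does not
  vanish with the decayed signal. Per-point errors equal the generating
  standard deviations, emulating triplicate-repeat error bars.
* `synth_saxs_curve()` builds $I(q) = \mathrm{scale}\cdot c_p\cdot
  P_\mathrm{poly}(q)\, S(q) + \mathrm{background}$; the structure factor
  is 1 (dilute), the monodisperse square-well theory at the
  volume-equivalent diameter, or an interpolated simulation curve. The
  linear-in-$c_p$ construction makes the concentration-ratio structure
  factor extraction an exact inverse on clean data.
* `synth_nse_set()` produces $e^{-D(q)q^2t}$ on quasi-log time grids
  truncated at the three echo windows (598, 248, 91 ns from low to high
  q), with a configurable low-q upturn in $D(q)$ mimicking
  rotational/internal contributions.
* `synth_viscosity_series()` is the arrest power law with multiplicative
  noise.

What the generators do **not** emulate: instrument resolution functions,
multiple scattering, detector smearing, aggregation tails, or any
deviation of the true ensemble from the Schulz/hard-sphere model. A green
recovery test therefore shows that the estimators are correct and
well-conditioned under the model's own assumptions at realistic noise —
not that the model describes any particular real protein.

## Numerical choices and degenerate inputs

* Schulz densities are evaluated in log-space (`dgamma`), so small
  $\sigma^*$ cannot overflow $\Gamma(c)$; below $\sigma^* = 0.02$ the code
  switches to the monodisperse branch.
* The form-factor quadrature is a fixed 256-node Gauss–Legendre rule on
  $[0, 10\langle R\rangle]$: deterministic, hence reproducible fits.
* The sphere amplitude uses its series below $x = 10^{-3}$ against
  cancellation.
* Guinier windows iterate to $qR_g \le 1$ (configurable) and refuse flat
  curves, rising low-q intensity, sharp upturns above the fitted line,
  and curves where no valid window exists (an oversized low-q component
  pushes $R_g$ up until every measured q violates the window criterion —
  the practical aggregation signature).
* Fits report covariance-based uncertainties where available; degenerate
  designs (single concentration, too-narrow fit ranges, too few early
  NSE times) are hard errors with explicit messages.

## Known limitations

* The sticky-sphere relations are leading-order in $\phi$; the package
  warns rather than extrapolates silently.
* The square-well RPA $S(q)$ loses positivity at strong coupling
  (large $u$ at high $\phi$) and then fails loudly; simulation is the
  intended tool there.
* At $\phi = 0.5$ the attraction-induced rise of $S(0)$ over the pure
  hard-sphere value ($\sim$2–3% by the perturbation estimate) is below
  the statistical resolution of desk-scale simulation, so that ordering
  is only demonstrable at low and intermediate volume fractions.
* The finite-box plateau estimator biases simulated $S(0)$ slightly
  upward; production-size runs ($N = 2000$) shrink both the bias and the
  lowest accessible q.
* Dynamics observables (mean-squared displacements, simulated $D(q)$) are
  intentionally out of scope for the simulation layer: structure only.
  Hydrodynamic interactions appear only through the analytic
  sticky-sphere relations.
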