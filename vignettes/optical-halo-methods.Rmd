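---
title: "Simulating and inverting ring-trap microrheology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and inverting ring-trap microrheology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halorheo)
library(dplyr)
```

## The system

A micron-scale probe bead is held by a ring-shaped ("halo") optical trap:
a harmonic restoring force of stiffness $\kappa_r$ pulls it towards a
circle of radius $R$ in the focal plane, a stiffness $\kappa_z$ confines it
axially, and — the defining feature — the azimuthal direction is force-free
($\kappa_\theta \equiv 0$). The bead therefore diffuses freely along the
ring indefinitely while staying in focus, so the azimuthal channel behaves
like an unbounded 1D random walk whose statistics carry the suspending
fluid's linear viscoelasticity down to arbitrarily low frequencies, while
the radial and axial channels behave like conventional optical-tweezers
channels whose compliance is capped by the trap.

The fluid is modelled as a single-mode Jeffreys medium: a solvent dashpot
$\eta_1$ in parallel with a Maxwell element (spring $G$, dashpot $\eta_2$),
relaxation time $\tau = \eta_2/G$ and complex modulus

$$G^*(\omega) = i\omega\eta_1 + \frac{i\omega G \tau}{1 + i\omega\tau}
  = G\frac{\omega^2\tau^2}{1+\omega^2\tau^2}
  + i\,G\omega\Big[\tau_1 + \frac{\tau}{1+\omega^2\tau^2}\Big],
  \qquad \tau_1 = \eta_1/G .$$

$\eta_2 = 0$ degenerates to a Newtonian fluid, and every operation in the
package honours that reduction.

## Dimensionless formulation

All integration happens in natural units: length in units of the radial
thermal width $\sqrt{k_BT/\kappa_r}$ and time in units of the inverse
corner frequency $\zeta_0/\kappa_r$, with $\zeta_0 = 6\pi a \eta_1$ the
solvent Stokes drag (`unit_system()` converts both ways). For the
reference configuration used throughout (water, $a = 1\,\mu$m bead,
$\kappa_r = 10^{-6}$ N/m, $R = 10\,\mu$m, 298 K) these units are
$6.41\times10^{-8}$ m and $1.88\times10^{-2}$ s, giving $\hat a = 15.6$
and $\hat R = 155.9$.

The dynamics depend on at most four groups: $\hat R$, $\kappa_z/\kappa_r$,
$\kappa^*/\kappa_r$ with $\kappa^* = 6\pi a G$ the Maxwell-spring
stiffness seen by the bead, and the Deborah number
$\mathrm{De} = \tau\kappa^*/\zeta_0 = \eta_2/\eta_1$. A second number
$\mathrm{De}_2 = \tau\kappa_r/\zeta_0$ refers the fluid's relaxation to
the actual trap. Note the package also exposes a *different*,
observation-based Deborah ratio in `feasibility_diagnostics()` — the
diffusion time across the spatial resolution over the frame interval —
which is kept in a separate type precisely because the two are easy to
conflate.

## Stochastic model and integrator

For a Newtonian fluid the overdamped dimensionless dynamics are

$$d\hat x = -(1 - \hat R/\hat\rho)\,\hat x\,d\hat t + \sqrt2\,dW_x,$$

and likewise for $\hat y$; $d\hat z = -(\kappa_z/\kappa_r)\hat z\,d\hat t +
\sqrt2\,dW_z$, with $\hat\rho = \sqrt{\hat x^2+\hat y^2}$. For the
Jeffreys fluid the exponential-memory generalized Langevin equation is
embedded as a Markovian system with one auxiliary variable $\hat Q$ per
axis; each position equation carries two Wiener increments with amplitudes
$\sqrt{2/(\mathrm{De}+1)}$ and $\sqrt{2\mathrm{De}/(\mathrm{De}+1)}$, the
second being *shared* with the paired $\hat Q$ equation, whose own noise
amplitude is $\sqrt{2(\mathrm{De}+1)/\mathrm{De}}$.

Because a printed noise table is an easy place for a transcription error
to hide, we verified the scheme analytically before implementing it: the
stationary Lyapunov equation of the linear $(z, Q)$ pair gives
$\mathrm{var}(\hat z) = \kappa_r/\kappa_z$ and
$\mathrm{var}(\hat Q) = \kappa_r/\kappa^*$ *independently of*
$\mathrm{De}$ and $\kappa^*/\kappa_r$ (equipartition), and the
velocity-correlation calculation gives a terminal azimuthal diffusivity
reduced by $1/(1+\mathrm{De})$ — the zero-shear viscosity
$\eta_1(1+\mathrm{De})$. Both results are asserted by simulation tests,
so the noise transcription is locked by physics rather than trusted.

Numerical choices:

* **Integrator.** Euler–Maruyama in compiled code. The SDEs are
  overdamped with additive noise; weak order 1 suffices for the
  ensemble statistics of interest. The default step is
  $d\hat t = \min(0.01,\ 0.05\,\lambda_{\min})$ where $\lambda_{\min}$ is
  the fastest relaxation time among the radial mode (1), the axial mode
  ($\kappa_r/\kappa_z$) and, for Jeffreys runs, the auxiliary-variable
  time $\mathrm{De}/((\mathrm{De}+1)\kappa^*/\kappa_r)$. An explicit
  `dt_hat` violating the guard is an error, never silently adjusted.
  Weak-order bias is visible in very precise statistics: the integrator
  test therefore checks the simulated MSD both against the *exact law of
  the discrete chain* (all lags, validating stepping and RNG at machine
  statistics) and against the continuum form $2(1-e^{-\hat t})$ over lags
  where Monte-Carlo error dominates the $O(d\hat t)$ bias.
* **RNG.** One splitmix64 counter stream per particle, derived
  deterministically from the master seed, with an inline Box–Muller.
  Ensembles are therefore bit-reproducible regardless of execution order
  and of the compiler's `std::normal_distribution` implementation.
  R-level randomness (initial states) runs inside `withr::with_seed()`.
* **Initialisation and burn-in.** Positions start on the ring at uniform
  azimuth with Gaussian radial/axial offsets at their stationary
  variances; $\hat Q$ starts at the deterministic fixed point of its own
  equation (zero Maxwell-branch force) — a parameter-free choice made
  immaterial by the burn-in, which defaults to 10 time units (Newtonian)
  or ten fluid relaxation times
  $\max(10, 10\,\mathrm{De}\,\kappa_r/\kappa^*)$ (Jeffreys).
* **z-axis guard.** The toroidal force is undefined on the axis; the
  integrator aborts if $\hat\rho < 10^{-12}$. For $\hat R \gtrsim 10$
  this is astronomically unlikely, so an abort flags a configuration
  error rather than being clamped away.

## Trajectory statistics

`cylindrical_decompose()` produces the three independent channels: the
radial fluctuation $\hat r - \hat R$, the axial position, and the
azimuthal arc length $s = \hat R\,\theta_{\rm unwrapped}$. Two deliberate
conventions:

* **Arc length at the fixed trap radius**, not the instantaneous particle
  radius. This makes the azimuthal MSD independent of ring size and
  exactly comparable to 1D free diffusion. (Decomposition with
  `unwrap = FALSE` skips the azimuth entirely; small rings occasionally
  pass near the axis, where an azimuthal step is ill-defined, and the
  confined-channel analyses do not need it.)
* **No mean subtraction** in the radial autocorrelation
  $A_r(\tau) = \langle u(t)u(t+\tau)\rangle/\langle u^2\rangle$ with
  $u = \hat r - \hat R$. The cross-section of a small torus has more area
  outside the generator circle than inside
  ($A_i/A_o = (2R-b)/(2R+b)$), so the stationary density
  $p(\hat r)\propto \hat r\,e^{-(\hat r-\hat R)^2/2}$ sits slightly
  outside the ring: $\langle u\rangle = 1/\hat R$ exactly. Keeping the
  mean is what produces the long-time plateau
  $A_r(\infty) = \langle u\rangle^2/\langle u^2\rangle \simeq 1/\hat R^2$
  — the $\propto R^{-2}$ anisotropy scaling — which mean-removal would
  erase. The same outward excess makes the moment skewness of $u$
  slightly *positive* (about $+2/\hat R^3$; the mirrored, inward-positive
  coordinate $\hat R - \hat r$ is correspondingly negatively skewed).

Estimators average over all time origins and all particles. Lags follow a
pseudo-logarithmic grid (every interval up to 16 samples, then factor
1.25), and lags beyond 64 sample intervals are computed on a
power-of-two-decimated series (the multi-tau device): long-lag origins are
strongly correlated, so the statistical cost is nil while the computation
stays bounded. Standard errors are the spread of per-particle time
averages across the ensemble — particles are genuinely independent, so
these are honest Monte-Carlo errors. The identity $\Pi = 1 - A$ between
the normalised MSD and the normalised autocorrelation of a stationary
channel is asserted within estimator error rather than imposed.

## From statistics to moduli

The inversion needs the unilateral Fourier transform of discretely
sampled, non-uniformly spaced data. `ft_piecewise_linear()` evaluates the
transform of the piecewise-linear interpolant in closed form, extended
below the first sample by a stated value-at-zero and initial gradient and
beyond the last sample by a terminal gradient, with any jump between the
initial ramp and the first sample handled explicitly (this matters when
the sampling is coarser than the fastest relaxation: the unresolved rise
is then correctly represented as a step). The transform is exact on
piecewise-linear data — a sampled ramp transforms to $1/(i\omega)^2$ to
machine precision — and frequencies outside
$[2\pi/T,\ \pi/\Delta t_{\min}]$ are flagged, never silently
extrapolated.

Three inversion routes are provided:

* **Free channel** (azimuthal): $G^*(\omega) = n_{\rm dim}k_BT /
  (3\pi a\, i\omega\,\widehat{\Delta x^2}(\omega))$, inertia neglected.
  The printed three-dimensional form uses $6k_BT$; the azimuthal channel
  is one-dimensional, so $2k_BT$ per dimension is used. This factor is
  the single most dangerous silent-error site in the stack, so it is
  pinned by a mandatory test: an exactly diffusive input
  $\mathrm{MSD} = 2Dt$ with $D = k_BT/6\pi a\eta$ must return
  $G^* = i\omega\eta$ to machine precision. The terminal gradient is fit
  on the last decade of lags and the initial gradient on the first four
  points; both can be overridden — for a *confined* channel pushed
  through this route the true terminal gradient is zero, and fitting it
  from a still-relaxing tail visibly biases the low-frequency moduli.
* **Trapped channel**: with known stiffness $\kappa$,
  $G^*(\omega)\,6\pi a/\kappa = 1/(i\omega\hat\Pi) - 1 \equiv
  (1/(i\omega\hat A)-1)^{-1} \equiv \hat A/\hat\Pi$; the three forms are
  algebraically identical through $i\omega\hat\Pi = 1 - i\omega\hat A$
  and agree to machine precision in `gser_trapped_forms()`. Frequencies
  where the recovered $|G^*|\,6\pi a/\kappa < 0.05$ are flagged
  trap-dominated (the trap's compliance overshadows the fluid's there).
  Storage and loss moduli always come from one complex expression; no
  Kramers–Kronig reconstruction is attempted.
* **Compliance route**: $J(t) = (3\pi a/ n_{\rm dim} k_BT)\,
  \mathrm{MSD}(t)$ and $G^* = 1/(i\omega\hat J)$, identical to the free
  route on the same transform (asserted to machine precision).

For the trapped Jeffreys channel the frequency-domain solution of the
generalized Langevin equation equates the analytic modulus to
$(\kappa/6\pi a)\,i\omega\hat A/(1-i\omega\hat A)$;
`jeffreys_gser_identity()` evaluates both sides, and an independent
time-domain oracle (the two-mode autocorrelation from the
eigendecomposition of the linear pair, used in the tests) closes the loop
from trajectory statistics to $G^*$ without touching the same algebra.

`fit_jeffreys()` recovers $(G, \tau, \eta_1)$ from a modulus curve by
Levenberg–Marquardt in log-parameter space, with residuals scaled by
$|G^*|$ per frequency so storage and loss are weighted evenly across
decades; `tidy()`/`glance()` expose the results.

## What the experiments reproduce, and at what scale

`run_experiment()` drives preset pipelines at desk scale (reference
ensembles are 1000 particles; `scale` multiplies that):

* `fig3_newtonian`: a large ring ($\hat R = 150$,
  $\kappa_z/\kappa_r \in \{1/9, 1/3, 1\}$, span 200 time units) plus
  small rings ($\hat R = 5, 10, 20$, span 600) for the anisotropy
  scaling. Expected structure: azimuthal MSD slope 2 at every lag
  (slope is read on short lags, where the estimator is sharpest, which
  is legitimate *only* because free diffusion is lag-free); radial and
  axial MSD plateaus 2 and $2\kappa_r/\kappa_z$; axial master curves
  collapse when lags are scaled by $\kappa_z/\kappa_r$ and the MSD by
  the axial variance; $A_r(\infty) \propto \hat R^{-2}$.
* `fig4_jeffreys_stiff` / `soft` / `fig5_sweep`: the
  $(\mathrm{De}, \kappa^*/\kappa_r)$ regimes. Jeffreys spans are sized
  so that the frequency band covers two decades around
  $\omega\tau = 1$ (span $\ge 64\tau$), the sampling resolves the
  Maxwell memory time $\mathrm{De}/((\mathrm{De}+1)\kappa^*/\kappa_r)$
  with at least 8 samples (coarser sampling visibly distorts the
  high-frequency loss modulus), and the lag window covers several
  relaxation times of the *slowest axial mode* of the $(z, Q)$ pair —
  the trapped-channel plateaus are unreadable before that mode has
  decayed.
* `fig6_actin`: the actin-solution-like scenario, $G = 10^{-3}$ Pa
  ($\kappa^*/\kappa_r \simeq 1.88\times10^{-2}$), water solvent. The
  fluid-faithful $\tau = 1000$ s gives $\mathrm{De} = 1000$; the desk
  default runs $\mathrm{De} = 100$ (the physics of the regime —
  $\kappa^* \ll \kappa_z < \kappa_r$, relaxation far beyond the trap
  corner — is unchanged, while the span shrinks tenfold), with
  `si_faithful = TRUE` exposing the long-running configuration. Here
  only the azimuthal channel recovers $G^*$ down to the terminal
  region; the radial and axial channels, inverted as if free, plateau
  at the apparent trap moduli $\kappa_r/6\pi a$ and $\kappa_z/6\pi a$.

A note on reading trap plateaus in the *soft*-fluid regimes
($\kappa^*/\kappa_r = 0.25$): the apparent low-frequency storage modulus
of a confined channel is exactly $\kappa/6\pi a + G'(\omega)$, so the
reading is clean only at frequencies where the fluid has relaxed
($\omega\tau \ll 1$). At desk-scale spans the supported band of the
$\mathrm{De}=10$, $\kappa^*/\kappa_r = 0.25$ run bottoms out near
$\omega\tau \approx 0.4$, where the fluid still contributes 10–30% —
physics, not estimator error — so the plateau checks are made on
configurations whose terminal regime lies inside the band (the stiff
fluid, and the actin-like scenario).

## What the synthetic data do and do not show

The generator emulates an ideal experiment: a perfectly harmonic,
perfectly circular trap, a single non-interacting sphere, Gaussian
thermal noise, and instantaneous, noise-free position detection. Passing
tests therefore validate the *method* — the integrator, the estimator
conventions, the transform, the GSER routes and their prefactors — under
the model's own assumptions. They do not probe camera blur and dynamic
error, localisation noise, drift, trap anharmonicity away from the ring
centre-line, hydrodynamic wall effects, or fluid behaviour beyond a
single-mode Jeffreys law, all of which a real instrument would add.

## Known limitations

* No inertial (underdamped) dynamics: apparent moduli above ~MHz-scale
  frequencies for micron beads would need the $m\omega^2$ term that is
  deliberately dropped here.
* Single-mode Jeffreys only; no multi-mode or fractional models.
* No power-spectral-density or Lorentzian-fit route, by design: those
  are Newtonian-only tools and an easy way to mislead oneself on
  viscoelastic data.
* Weak-order-1 integration: statistics with precision much better than
  $O(d\hat t)$ (large ensembles, long records) will resolve the
  discretization bias; halve `dt_hat` when that matters.
* Trajectory persistence is plain CSV with an embedded JSON provenance
  header — adequate for desk-scale runs, with regeneration from the
  provenance block the intended path for large ensembles.
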