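---
title: "Reverse engineering two-time correlation maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse engineering two-time correlation maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xpcsre)
```

## The problem

X-ray photon correlation spectroscopy (XPCS) watches a coherent speckle
pattern decorrelate and summarizes non-equilibrium dynamics in the two-time
correlation function (TTC)

$$G(q, t_1, t_2) \;=\;
  \frac{\mathrm{cov}_p\!\left[I(q, t_1),\, I(q, t_2)\right]}
       {\sigma_p\!\left[I(q, t_1)\right]\,\sigma_p\!\left[I(q, t_2)\right]},$$

where the covariance and standard deviations run over detector pixels $p$
inside a ring $|q_p - q| \le \Delta q$.  For a phase-separating protein
solution the TTC carries rich structure beyond the diagonal relaxation:
a *modulation* of the correlation width along the diagonal, off-diagonal
*tail* stripes, a *square* block of frozen-in correlation between early and
late epochs, and fluctuations of the near-diagonal *contrast*.  The point of
this package is to regenerate each of those features from the simplest
kinetic ingredient that produces it — growth, dissolution, shape or
concentration change, Brownian motion, detector noise — so that an observed
TTC can be read back ("reverse engineered") into statements about the
kinetics.

Two complementary simulators feed the same analysis chain:

* a rescaled 2D **Cahn–Hilliard** (CH) phase-field model with
  temperature-jump quench — the equation-based reference for spinodal
  decomposition; and
* a **particle-based heuristic model** — phase domains as disks/ellipses
  with hand-scheduled radii, shapes, concentrations and motion, rasterized
  to the same kind of concentration map.

Both produce a real-space field series $u(\mathbf r, t)$; speckle synthesis
then takes $I(\mathbf q, t) = |\mathrm{FFT}_2[u - \bar u]|^2$, and the
correlation and feature modules operate purely in reciprocal space.

## The Cahn–Hilliard solver

The solver integrates the rescaled equation

$$\frac{\partial u}{\partial t} =
  \nabla\cdot\!\left[m(u)\,\nabla\!\left(u^{3} - a\,u -
  \kappa \nabla^{2} u\right)\right],$$

with $u \in [-1, 1]$ the rescaled concentration (positive = dense phase),
$a = (T_c - T)/T_c \in [0, 1]$ the dimensionless quench depth, $\kappa$ the
interface coefficient and $m(u)$ the mobility.  Defaults: a $512^2$ periodic
grid, $dx = 1$, $dt = 0.05$, $\kappa = 1$, and $a = 0.7$ — a deep quench
well inside the spinodal for the symmetric mixture $u_0 = 0$.  Time is in
rescaled (arbitrary) units throughout; presets expose an explicit grid and
step count rather than pretending to a physical seconds mapping.

Numerics:

* **Constant mobility** uses a semi-implicit Fourier-spectral step: the
  stiff linear terms ($-a\nabla^2 u$, $\kappa\nabla^4 u$) are treated
  implicitly in Fourier space and the cubic term explicitly.  This is
  unconditionally stable at the default step; the conserved mean of $u$ is
  preserved to machine precision because the $k = 0$ mode is untouched.
* **Gel mobility** models gelation of the dense phase by a sharp threshold:
  $m(u) = 1$ for $u < u_g$, $m_{\min}$ above it (defaults $u_g = 0.5$,
  $m_{\min} = 0.05$).  The variable-mobility flux divergence is evaluated
  explicitly; stability is restored by adding and subtracting the
  maximum-mobility biharmonic term and treating it implicitly.  Gel runs
  still want $dt \lesssim 0.02$.
* The Ginzburg–Landau free energy
  $F[u] = \int [-\tfrac a2 u^2 + \tfrac14 u^4 +
  \tfrac\kappa2 |\nabla u|^2]\,d\mathbf r$ is a Lyapunov functional of the
  constant-mobility flow and is exposed (`freeEnergy()`) as the solver's
  built-in correctness diagnostic; the test suite asserts monotonicity along
  stored trajectories.
* The Nyquist mode is zeroed in first-derivative operators (its odd
  derivative is not representable on an even grid).

Two field-level modifications mirror the reverse-engineering workflow:
`binarize()` maps $u > 0 \mapsto +1$, $u \le 0 \mapsto -1$ (the tie at
exactly zero goes to the dilute side — a measure-zero convention), and
`dilateDomains()` applies $k \times$ `pixelsPerFrame` iterations of
4-neighbour morphological dilation to frame $k$, emulating an increased
growth-to-dissolution rate ratio (the gelation signature that strengthens
the square feature).

## The particle model

`particleEnsembleSpec()` describes domains as disks with
piecewise-linear schedules (`schedule()`) for the mean radius, the ellipse
axis ratio, the interior/background concentrations and the random-walk step.
Conventions worth knowing:

* Interiors default to $u_{\mathrm{in}} = -1$ (dilute droplets) on a
  $u_{\mathrm{out}} = +1$ dense background; overlaps are resolved as a
  union (interior wins), so merging is visual rather than mechanical, and
  there are no interaction forces.
* Per-particle size dispersion is a normal offset (SD `radiusSpread`,
  truncated so initial radii stay positive) added to the schedule; several
  schedules with population fractions support Ostwald-like scenarios.
* Ellipses preserve the equivalent-disk area
  ($a = r/\sqrt\rho$, $b = r\sqrt\rho$), so shape change is isolated from
  size change; orientations are fixed per particle, drawn uniformly.
* Brownian motion is an uncorrelated Gaussian step per frame and axis,
  wrapped periodically; the mean-squared displacement is exactly
  $2 n \sigma^2$ after $n$ steps.  The inverse-size coupling of mobility is
  *not* hard-coded; the `early_stage_llps` preset approximates it with a
  decreasing step schedule.
* Everything — placement (uniform, with optional minimum separation by
  rejection sampling), size draw, trajectories — is derived from one seed,
  so `(spec, seed, nFrames)` determines the output bit for bit.

`buildScenario()` bundles the reference scenarios (linear and nonlinear
growth, size-dispersed growth, two-step growth–dissolution with a
`rateRatio` knob, shape change, concentration ramp, Brownian motion with
and without growth, and an early-stage preset with decaying motion).  The
scenario boxes ($256^2$), particle counts (40–200) and schedule values are
the package's reference choices — the phenomena they produce are generic,
and none of them is quantitative beyond its own definition.  Notable
choices:

* The `brownian` preset places 200 disks of radius 6 px with a minimum
  separation of 13 px.  Non-overlapping droplets are what give the
  scattering pattern a structure-factor peak; the analysis ring is centred
  on that peak, as in the experimental protocol.
* The `two_step_growth_dissolution` preset grows all radii from 2 to 14 px
  over 40 frames and then dissolves at `0.3/rateRatio` px/frame for the
  remaining 80 frames, clamping at zero.  At `rateRatio = 1` the
  dissolution therefore *completes* — the regime in which the square
  feature disappears; at `Inf` nothing dissolves and the frozen-in block is
  maximal.
* `brownian_plus_growth` fixes the walk step at 0.25 px/frame so that the
  motion-driven relaxation time, roughly $2/(q^2\sigma^2) \approx 50$
  frames at the reference ring, lies inside the 120-frame window: motion is
  visible without erasing everything — the prerequisite for studying the
  growth/motion dominance crossover.

## Speckle synthesis and the analysis chain

Speckle frames are the squared magnitude of the unnormalized 2D FFT of the
concentration *fluctuations* (mean removed, so the central pixel is zero),
with the zero frequency shifted to the centre.  The q-map is
$2\pi k/(N\,dx)$ in simulation units, or physical nm$^{-1}$ via a
`geometry()` (wavelength from $\lambda[\mathrm{Å}] = 12.398419843/E[\mathrm{keV}]$,
exact $q = (4\pi/\lambda)\sin\theta$ with
$2\theta = \arctan(d\,\mathrm{pixel}/\mathrm{distance})$).

* `radialProfile()` bins azimuthally (equal-width bins, default $N/4$);
  `xiUsaxs()` returns $\xi = 2\pi/q_{\mathrm{peak}}$ from the profile
  maximum, with a moving-average smooth (3 bins) and a quadratic sub-bin
  refinement; a maximum on a boundary bin raises an error — the peak has
  left the measurement window, which is precisely the failure mode that
  motivates size extraction from TTC tails instead.
* `addNoise()` adds i.i.d. uniform noise on $[0, f \cdot I_{\max}]$, with
  $I_{\max}$ the maximum over the *whole series* — constant amplitude in
  time while the signal evolves, which is what turns a varying
  signal-to-noise ratio into contrast fluctuations.  Uniform (not Gaussian)
  keeps intensities non-negative; $f = 0.04$ is the reference level.
* `computeTTC()` uses the Pearson (normalized covariance) estimator over
  ring pixels, for which the limiting values are exact: frozen speckle
  gives $G \equiv 1$ and decorrelated frames $G \approx 0$ with noise
  $\sim 1/\sqrt{n_{\mathrm{ring}}}$.  An unnormalized
  $\langle I_1 I_2\rangle / (\langle I_1\rangle\langle I_2\rangle)$ variant
  is available for comparison with other XPCS software.  By default each
  ring pixel is first divided by the per-frame azimuthal mean of its
  q-sub-shell (flat-fielding by the smooth $I(|q|)$ profile): without it, a
  ring wide enough to span a sloping radial profile correlates that static
  trend between otherwise independent frames and biases the decorrelated
  limit upward.  Frames with zero ring variance (homogeneous fields) are
  masked to zero and flagged rather than propagating `NaN`.

## Feature extraction

* The **contrast profile** is $G(k, k+1)$ against the pair midpoint age;
  tails are its interior local maxima above a topographic prominence
  (default 0.05; the preset analyses in this package use 0.1, which
  rejects the shallow secondary ripple that appears at form-factor zero
  crossings).
* The **integer-multiple rule** assigns the $k$-th detected tail the length
  $\xi = (n_0 + k)\,2\pi/q$: during growth the successive orders of the
  intensity profile sweep through the analysis ring, and each passage
  revives the contrast.  $n_0$ anchors the first tail and is user-supplied
  or estimated from an independent early size (`anchorTailIndex()`).  A
  caveat the test suite documents explicitly: for ideal constant-interior
  disks the contrast maxima sit where the disk form factor
  $|J_1(qR)/qR|^2$ peaks, i.e. at mean diameter $(n + 0.7)\,2\pi/q$ — the
  *spacing* between consecutive tails is exactly $2\pi/q$, while the
  absolute phase is shape-dependent.  Sizes read from tails are therefore
  most trustworthy as increments, which is how the growth-curve
  concatenation across q-rings uses them.
* **Square strength** is the mean of $G$ over the off-diagonal block
  $\{t_1 < t_{\mathrm{split}} < t_2\}$; the split defaults to the maximum
  curvature of the smoothed contrast profile and should be placed at the
  kinetic transition.  Because frames at equal radii and static positions
  are *identical*, a growth–dissolution cycle retains a genuine frozen-in
  ridge even when dissolution is fast; the block mean consequently has a
  physical floor well above pure estimator noise.  Comparisons across
  `rateRatio` values are meaningful; absolute comparisons against an
  i.i.d. null are not.
* `modulationSpacing()` summarizes gaps between consecutive maxima and
  flags non-uniform spacing (SD/mean > 0.25) as the signature of
  non-constant growth speed; `fitPowerLaw()` is an ordinary least-squares
  line on $\log \xi$ vs $\log t$, with the $1/3$ exponent of
  diffusive/coalescence coarsening as the reference value.
* `relaxationTime()` offers the $1/e$ threshold (linearly interpolated) and
  a Kohlrausch fit $G(\tau) = \exp[-2(\tau/\tau_r)^\gamma]$ — the factor 2
  is the intensity-correlation convention — returning a no-decay signal,
  distinct from a fit failure, when the cut never crosses the threshold.

## What the generators do and do not emulate

The synthetic scenarios reproduce the *mechanisms* behind the TTC features:
kinetic sweeps of the structure through a fixed ring, loss of positional
memory, frozen-in configurations, SNR-driven contrast.  They do not emulate
hydrodynamic coupling, 3D structure, interparticle forces, coalescence
mechanics, photon counting statistics, detector gaps or flat-field errors.
Tests passing on these generators therefore validate the analysis chain and
the feature–mechanism links, not quantitative agreement with any particular
experimental system; the experimental TTC of a real protein system can be
read through, but not fitted by, these presets.

## Problem sizes and reproducibility

The reference computations are sized for a single desktop core: coarsening
runs use a $256^2$ grid for $2\times10^4$ steps; TTC studies use $256^2$
maps with 100–120 frames and rings of order $10^3$ pixels; unit tests use
$64^2$–$128^2$ fixtures built in code.  Every stochastic step (initial
noise, placement, walks, detector noise) flows from explicit seeds, and the
pipeline writes a provenance log (config, derived stage seeds, package
version) sufficient to replay a run exactly.  Persistence uses multi-page
32-bit float TIFF stacks with a JSON sidecar (times, grid spacing, affine
scale): a deliberately plain, language-neutral format; TTC matrices and
feature tables export as CSV/JSON.

```{r example, eval = FALSE}
spec <- buildScenario("linear_growth")
fields <- simulateParticles(spec)
speckle <- speckleSeries(fields)
ring <- makeQRing(speckle, qCenter = 2 * pi / 8,
                  qHalfwidth = 1.5 * 2 * pi / 256)
ttc <- computeTTC(speckle, ring)
featureReport(ttc, prominence = 0.1, tSplit = NA)
```
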