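---
title: "Tip growth under a cell wall thickness gradient: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tip growth under a cell wall thickness gradient: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipwall)
```

# The biological and mechanical problem

Tip-growing walled cells — pollen tubes, root hairs, fungal hyphae, and the
apical cells of filamentous brown algae — elongate by deforming only the
dome at their apex. Because the dome is more curved than the cylindrical
shank, elementary shell mechanics puts *less* stress on the tip than on the
shank for a wall of uniform thickness: growth happens where the driving
force is weakest. Most species solve this paradox by softening the apical
wall (secreting wall-loosening agents, so that extensibility and yield
threshold vary along the cell). The system modelled here is different: a
slow-growing alga whose apical wall is some sixteen times *thinner* at the
very tip (≈36 nm) than on the shanks (≈590 nm). The thickness gradient
alone concentrates wall stress at the tip, so that a wall with *uniform*
mechanical properties suffices to explain tip growth.

`tipwall` implements the full quantitative chain behind that claim:

1. geometry — from traced cell outlines to an averaged meridional profile
   with both principal curvatures;
2. wall thickness — correcting apparent transmission electron microscopy
   (TEM) thickness for off-meridian sectioning and fitting a gradient
   model δ(s);
3. turgor — incipient-plasmolysis estimation with shrink correction;
4. mechanics — axisymmetric thin-shell stresses, the expected strain rate
   under self-similar growth, and Lockhart-law inference;
5. simulation — forward viscoplastic growth of the discretized meridian,
   self-similarity scoring and parameter optimisation;
6. flux — the wall-deposition field needed to maintain the gradient;
7. statistics — bootstrap robustness, bead-trajectory orthogonality, FRAP
   recovery fitting;
8. synthetic data — generators for every input, with known ground truth.

# Geometry

An axisymmetric cell is described by its half-meridian: arc length $s$ from
the tip, axial coordinate $x$, distance to the axis $r$, the angle $\varphi$
between the axis and the outward normal, and the two principal curvatures
$\kappa_s$ (meridional) and $\kappa_\theta = \sin\varphi / r$
(circumferential). At the tip, circular symmetry forces
$\kappa_\theta = \kappa_s$; on a cylinder $\kappa_s = 0$ and
$\kappa_\theta = 1/r$.

Traced contours are smoothed coordinate-wise with cubic smoothing splines
against arc length and resampled at 50 nm. The smoothing bandwidth is
*fixed* — one equivalent degree of freedom per 1.5 µm of contour — rather
than chosen by cross-validation. Generalized cross-validation is
structurally attractive but empirically unreliable here: on jittered traces
it intermittently collapses to near-interpolation, and the resulting
high-frequency wiggles inflate the apparent tip curvature severalfold
(curvature involves second derivatives, which amplify position noise by
the inverse square of the resolution). A fixed bandwidth tied to arc
length resolves dome-scale features (radius of curvature ≥ 2 µm) while
rejecting tracing noise, and recovers the tip curvature of synthetic
contours to within ~1–2 % at realistic noise (30 nm tracing jitter, 3 %
cell-to-cell shape variation). An explicit penalty and pure interpolation
remain available through the `smoothing` argument.

Curvature series from many cells are averaged with a pair of sliding
windows (width 200 nm, step 50 nm) moving away from the tip on both sides;
all values falling in a window are pooled, which folds each cell's two
sides into one symmetric profile. The average $\kappa_s(s)$ is then
integrated ($\mathrm d\varphi = \kappa_s\,\mathrm d s$,
$\mathrm d r = \cos\varphi\,\mathrm d s$,
$\mathrm d x = -\sin\varphi\,\mathrm d s$) with a fourth-order corrected
trapezoid scheme to rebuild the average shape. Near the tip the analytic
limit $\kappa_\theta \to \kappa_s$ replaces the $0/0$ ratio.

# Wall thickness

A longitudinal section cut a distance $d$ off the true meridional plane
shows the wall thicker than it is. Modelling the cell locally as a
cylinder of radius $R = 3.27$ µm, the apparent inner radius $a$ and
apparent thickness $w$ determine the true thickness exactly:
$\delta = R - \sqrt{a^2 + R^2 - (a+w)^2}$. The correction can only shrink
the measurement ($\delta \le w$, with equality for a true meridional
section), so oblique sectioning never biases the gradient downward.

Corrected values are pooled over cells and fitted by nonlinear least
squares with three interchangeable inverted-bell families (all reach the
midpoint $(\delta_{\min}+\delta_{\max})/2$ at $s_{1/2}$):

* Gauss: $\delta_{\max} - (\delta_{\max}-\delta_{\min})
  e^{-(s/s_{1/2})^2 \ln 2}$
* Lorentz: $\delta_{\max} - (\delta_{\max}-\delta_{\min})
  \left[1+(s/s_{1/2})^2\right]^{-1}$
* Pearson: $\delta_{\max} - (\delta_{\max}-\delta_{\min})
  \left[1+3(s/s_{1/2})^2\right]^{-1/2}$

The residual standard error is reported in µm as
$\sqrt{\mathrm{SSR}/(n-3)}$. On data generated from the Pearson model the
family ordering (Pearson < Lorentz < Gauss) is recovered, mirroring the
ordering observed on real measurements.

# Turgor

Filaments are exposed to a ladder of external osmolarities and the
fraction of plasmolyzed apical cells is counted. The limit-plasmolysis
concentration $c_{pl}$ — where half the cells are plasmolyzed — is read
off a binomial logistic fit in $\log c_e$ (linear interpolation of the
50 % crossing is available as a cross-check). Because plasmolyzed cells
have shrunk, the internal osmolarity under normal growth is
$c_i = x\, c_{pl}$ with $x$ the plasmolyzed-to-normal volume ratio, and
turgor is $P = (c_i - c_{sea})/410$ MPa with $c_{sea} = 1100$ mOsm L⁻¹.
At the study conditions ($c_{pl} = 1980$ mOsm L⁻¹, $x = 0.658$) this gives
$P = 0.495$ MPa.

# Mechanics and Lockhart inference

For a pressurized axisymmetric membrane of thickness $\delta$:

$$\sigma_s = \frac{P}{2\delta\kappa_\theta}, \qquad
  \sigma_\theta = \frac{P\,(2\kappa_\theta-\kappa_s)}
                       {2\delta\kappa_\theta^2},$$

so $\sigma_\theta = \sigma_s$ at the tip and
$\sigma_\theta = 2\sigma_s$ on the cylinder. The scalar effective stress
uses the plane-stress von Mises form generalized by the flow coupling
$\nu$, $\sigma_e = \sqrt{\sigma_s^2 + \sigma_\theta^2 -
2\nu\sigma_s\sigma_\theta}$; $\nu = 0.5$ throughout, justified by the
transverse isotropy of the apical wall (cellulose microfibrils show no
preferred in-plane direction).

Self-similar growth — translation of the tip at speed $v$ without shape
change — fixes the normal surface velocity kinematically:
$V_n = v\cos\varphi$. Combining the circumferential kinematic identity
$\dot\varepsilon_\theta = V_n \kappa_\theta$ with the transversely
isotropic flow rule
$\dot\varepsilon_\theta = \dot\varepsilon\,(\sigma_\theta -
\nu\sigma_s)/\sigma_e$ yields the *expected* strain rate

$$\dot\varepsilon^*(s) = K\,\kappa_\theta\,
   \frac{\sigma_e}{\sigma_\theta - \nu\sigma_s}\,V_n,$$

computable from geometry, thickness and turgor alone, with $K = 1$ in the
µm/MPa/min unit system. If the wall is viscoplastic with *uniform*
properties, the parametric plot of $\dot\varepsilon^*$ against $\sigma_e$
must collapse onto a single Lockhart line
$\dot\varepsilon = \Phi(\sigma_e - \sigma_y)$. `lockhart_fit()` regresses
the increasing branch (points above 1 % of the maximal strain rate by
default; the threshold is configurable because an absolute cut-off would
be unit-dependent) and returns $\Phi$ (slope), $\sigma_y$
(−intercept/slope) and $r^2$. For a uniform-thickness wall at pollen-tube
conditions the same construction produces a *decreasing*, visibly
non-linear relation — the package flags the non-positive slope — which is
the mechanical signature distinguishing the two tip-growth strategies.

Two scaling laws are useful for interpreting condition changes: at fixed
geometry and gradient, every stress scales with $P$, so
$\sigma_y \propto P$; and $\dot\varepsilon^* \propto v$, so
$\Phi \propto v/P$. A hormone treatment that lowers turgor to 0.186 MPa
and doubles the growth rate therefore multiplies the inferred $\Phi$ by
$2\times0.495/0.186 \approx 5.3$ and divides $\sigma_y$ by
$0.495/0.186 \approx 2.7$, exactly the direction expected from a
wall-loosening response.

# The growth simulator

The meridian is discretized at constant spacing (50 nm by default). Each
step computes the discrete geometry (tangent angle by central differences
with the tip mirrored across the axis; $\kappa_s = \mathrm d\varphi/
\mathrm d s$), evaluates the thickness gradient *as a function of distance
from the current tip* — the thickness field travels with the tip, which is
what makes steady self-similar growth possible — computes the stresses and
displaces every point along its outward normal at

$$V_n = \Phi\,(\sigma_e-\sigma_y)\,
        \frac{\sigma_\theta-\nu\sigma_s}{\sigma_e \kappa_\theta},
        \qquad \sigma_e > \sigma_y,$$

zero below yield. After a prescribed tip advance (1–150 nm depending on
use) the contour is re-interpolated with a cubic spline (no smoothing) and
resampled at constant spacing; a few points are mirrored across the axis
first so the apex is interior to the spline and suffers no end-condition
artefact.

Two numerical safeguards deserve explanation, because the naive explicit
scheme is unstable:

* **Parabolic substepping.** The normal velocity responds to curvature
  (a locally sharper apex is more stressed *less*, hence slower), which
  acts as a diffusion of the front with coefficient
  $c \approx |\partial V_n/\partial\kappa_s|$. An explicit scheme is only
  stable for $\Delta t \lesssim h^2/2c$; at 50 nm spacing this is *smaller*
  than the time needed for 1 nm of tip advance, and ignoring it makes the
  contour blow up within a fraction of a micrometre of growth. Each
  displacement is therefore broken into substeps observing
  $\Delta t \le 0.4\,h^2/\hat c$ with $\hat c$ measured from the current
  fields.
* **Grid-scale filtering.** Discrete curvature amplifies sub-nanometre
  interpolation error by $1/h^2$, and the yield cut-off turns that noise
  into velocity noise. A 1-2-1 binomial filter (two passes on the
  curvatures, one on the velocity field, mirror-symmetric at the tip)
  removes the grid-scale component while leaving smooth features
  second-order accurate. Runs whose simulated duration exceeds six times
  the self-similar expectation are reported as stalled rather than
  integrated indefinitely.

**Self-similarity score.** After the tip has advanced by the target
distance (25 µm by default, about five dome lengths), the final contour is
compared with the initial one translated by $v\,t_{\mathrm{elapsed}}$ —
the *expected-speed* translation, so that both shape distortion and
growth-rate error are penalized; comparing against a fixed 25 µm
translation instead would make the score blind to the extensibility, which
only sets the pace. Points are paired by equal arc distance from their
respective tips, and distances are averaged with the dome-focused weight
$w(s) = e^{-(s/h_w)^2\ln 2}$ ($h_w = 1$ µm, half-weight at 1 µm; the
sensitivity to $h_w$ is mild because a uniform offset is reproduced
exactly regardless of weights). The score is $\log rD$, natural log.

**Optimisation.** $(\Phi, \sigma_y)$ are fitted by steepest descent on
$\log rD$ in log-parameter space (fixed probe step, deterministic order
$\Phi$ then $\sigma_y$, backtracking halving, convergence at $10^{-3}$
relative), started from the Lockhart regression estimates. Because full
simulations are expensive, the descent runs on a coarsened grid
(120–150 nm). Grid coarsening biases the realized growth *rate* by a few
per cent (the attractor shape is resolution-dependent at second order)
while leaving the shape valley in $\sigma_y$ unchanged; since $\Phi$
rescales the rate exactly without touching the trajectory, the coarse
optimum is finished with a single rate calibration at the reporting
resolution: one fine run measures the realized speed and $\Phi$ is scaled
by $v_{\mathrm{target}}/v_{\mathrm{realized}}$. At the study conditions
the calibrated optimum sustains 25 µm (≈10 h of biological time) of
growth with $\log rD < -3$ (residuals below 50 nm) at exactly the
observed 2.5 µm h⁻¹.

# Wall deposition flux

In the frame moving with the tip, wall material streams backwards along
the meridian at $v_m = v\sin\varphi$ while the surface stretches locally.
Keeping the thickness profile steady requires deposition (wall volume per
wall area per time)

$$D(s) = v_m \frac{\mathrm d\delta}{\mathrm d s}
       + \delta\,(\dot\varepsilon_s + \dot\varepsilon_\theta),$$

with $\dot\varepsilon_\theta = V_n\kappa_\theta$. For the meridional
strain rate the package defaults to the kinematic self-similar value
$\dot\varepsilon_s = V_n\kappa_s$, under which the identity
$2\pi\!\int\! D\,r\,\mathrm d s = 2\pi R\,\delta_{\max} v$ (deposition
balances the wall volume advected out at the back) holds exactly; the
flow-rule alternative
$\dot\varepsilon_s = \dot\varepsilon^{*}(\sigma_s-\nu\sigma_\theta)/
\sigma_e$ is available via `strain = "flow"` and agrees within a few per
cent wherever the profile is close to self-similar. The gradient slope is
evaluated analytically from the fitted family, never by differencing
noisy data. Per-area ($D$) and per-meridional-length ($2\pi r D$)
columns are both returned; the latter is the natural axis for comparing
with vesicle-trafficking images, and is the one whose maximum sits at the
base of the dome (s ≈ 4–5 µm at the study conditions) with substantial
deposition persisting far into the shanks. With a uniform wall
(pollen-tube configuration) the advection term vanishes and deposition
collapses into the dome, vanishing in the shanks — reproducing the
classic apical vesicle focus of pollen tubes.

# Bootstrap robustness

Whole cells are the resampling unit: each of the replicates draws, with
replacement, contours from the contour set and cells from the TEM
thickness set (independently — nothing links a particular contour to a
particular sectioned cell), recomputes the average contour from
precomputed per-cell window statistics, refits the Pearson gradient,
rebuilds the stress/strain-rate relation and refits the Lockhart line.
Summaries include the mean and 5th-percentile $r^2$, the mean thickness
contrast $\delta_{\max}-\delta_{\min}$, and the
$(\delta_{\min},\delta_{\max})$ and $(\Phi,\sigma_y)$ correlations (both
positive: every resample still exhibits a gradient, and flatter
stress/strain lines shift both plasticity parameters together). Each
replicate's RNG stream is derived from (seed, replicate index), so results
are order-independent and a prefix of replicates is reproducible
regardless of the total count.

# Microscopy statistics

**Bead trajectories.** Surface beads followed through time-lapse frames
define trajectories; the angle between each trajectory and the cell
outline at the same time point tests whether growth is orthogonal to the
surface. Trajectory splines are parametrized by path length rather than
time — beads decelerate sharply as they leave the dome, and a
time-parametrized cubic distorts tangents near the slowdown — and the
contour tangent is taken at the bead's projection on a finely resampled
outline. Angles are reported unfolded in $(0, \pi)$, oriented by contour
direction away from the tip and trajectory direction forward in time,
together with the meridional position of the intersection and the
Pearson correlation between the two (no correlation = orthogonality is
position-independent).

**FRAP.** Bleached-zone traces are corrected for background and
acquisition photobleaching with the standard double normalization
$A_c(t) = \left[A(t)-Z(t)-(A(0)-Z(0))\right]\,
\frac{U(0)-Z(0)}{U(t)-Z(t)}$ and fitted with
$Y(t)=Y_0+\alpha(1-e^{-t/\tau})$. The normalized initial slope $1/\tau$
serves as the membrane-turnover (exocytosis) proxy compared across zones
along the cell. Flat or zero-recovery traces are flagged as degenerate
(amplitude within twice the residual noise, or no significant trend)
instead of producing spurious rate estimates.

# Synthetic data: what it emulates, and what not

All generators are deterministic given a seed and return their ground
truth. Defaults reproduce the study conditions: shank radius 3.27 µm,
Pearson gradient (36.2 nm, 591 nm, 16.81 µm), turgor 0.495 MPa via
$c_{pl} = 1980$ mOsm L⁻¹ and shrink 0.658, tip speed 2.5 µm h⁻¹,
$\nu = 0.5$.

* **Contours.** The reference shape is an analytic dome blended into a
  cylinder: $\kappa_s(s) = \kappa_{\mathrm{tip}}
  e^{-(s/s_d)^p}$, with $s_d$ fixed by the quarter-turn condition and $p$
  solved so the asymptotic radius is 3.27 µm. The tip curvature default,
  0.40 µm⁻¹ (radius of curvature 2.5 µm), makes the tip sharper than a
  hemisphere, as observed. Per-cell shape variation is a log-normal
  factor (sd 3 %) on the tip curvature; tracing jitter is Gaussian
  (sd 30 nm) normal to the outline, sampled every 0.25 µm. Real traced
  contours have correlated, heavier-tailed errors and real cells vary in
  more than tip sharpness; recovery results on this generator bound only
  the idealized-noise behaviour.
* **Thickness.** Each synthetic cell is sectioned at one offset
  (half-normal, sd 0.4 µm) and apparent $(a, w)$ follow the exact
  circle-chord geometry, so the correction inverts the construction
  exactly at zero noise; multiplicative log-normal noise (5 %) keeps
  thickness positive. The cylinder assumption is applied at all $s$, as
  in the real correction.
* **Plasmolysis.** Binomial counts with a logistic response in
  $\log c_e$ (width 0.08, ten osmolarities between 1300 and 2900, 200
  cells per point, three experiments).
* **Beads.** Beads ride a self-similarly translating profile along local
  normals (many substeps per frame); measurement noise rotates each
  recorded displacement. True angles are exactly $\pi/2$ — the generator
  does not emulate the systematic few-degree deviation real bead data
  show.
* **FRAP.** Exponential recovery per zone (maximum turnover in the
  dome-base zone) behind a drifting background and a decaying unbleached
  reference, constructed so the double normalization is exact in the
  noise-free limit.

Because the paper's own data files are not redistributable here, the
acceptance script runs this generator at its defaults; quantities whose
value is pinned by the generator truth (turgor, gradient parameters,
Lockhart linearity, conservation) reproduce the study numbers, while
purely geometry-dependent magnitudes (peak stress, the absolute
$\Phi, \sigma_y$ optimum) are reported for the synthetic reference shape
and differ from values measured on real cells.

# Problem sizes and limitations

Unit tests run simulations at 120–150 nm spacing over 1–10 µm; the
acceptance script optimizes at 120 nm over 25 µm and scores a final 50 nm
run over 25 µm, with 3000 bootstrap replicates — a few minutes in total.
Known limitations: the simulator is strictly axisymmetric (no branching or
bending); elasticity is neglected (appropriate for very slow growth, not
for turgor steps or osmotic cycling); the optimizer is local (start from
the Lockhart estimates, as intended); and the thickness correction treats
the cell as a cylinder even within the dome, consistent with how the
measurements are corrected in practice.
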