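---
title: "The force shadow method: model, assumptions and numerical choices"
author: "forceshadow package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The force shadow method: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forceshadow)
```

## The problem

During double support — any stance phase in which both feet touch the
ground — the human body forms a closed kinetic chain, and the vertical
ground reaction force (vGRF) measured as a whole cannot be uniquely
assigned to the individual feet from kinematics alone. Force plates
resolve the ambiguity by measuring each contact separately, but they pin
the analysis to a laboratory. This package implements a constructive,
online method that distributes the total vGRF over an arbitrary set of
foot-contact regions using only kinematic data (segment centres of mass,
segment headings, foot landmarks) plus an anthropometric mass table.

## The model

**Total GRF.** With segment mass fractions $d_s$ and total mass
$m$, the whole-body CoM is $x_{CoM} = \sum_s d_s\, x_{CoM_s}$ and the
ground reaction force is taken as the Newtonian mirror of gravity plus
CoM acceleration,
$$F_{GRF} = m\,(\ddot x_{CoM} + [0,0,g]^T).$$
A configuration switch (`grf_sign = "as_printed"`) negates the inertial
term instead, giving $F_z = m(g - \ddot x_z)$; we default to the
Newtonian form because an upward CoM acceleration must *increase* the
vertical load, and both forms coincide in the static case. Flight phases
are detected by a 1 N floor on $|F_z|$ and produce zero loads.

**Force shadow.** Each segment CoM is projected along $F_{GRF}$ onto the
ground plane $z = 0$ (a vertical force drops the height; shear
components displace the projection, like a shadow cast along the force
direction). At each projected centre $\mu_s$ an elliptical bivariate
Gaussian is placed with covariance
$\Sigma_s = R_s\,\mathrm{diag}(a_s^2, b_s^2)\,R_s^T$, oriented by the
segment's planar heading, and scaled so its peak value equals the
segment's mass fraction: $f_s(\mu_s) = d_s$. The shadow function
$f(x) = \sum_s f_s(x)$ is a smooth, strictly positive surrogate for "how
much body mass is stacked above this point of the floor". Two
typographically ambiguous constructions in the source material are
resolved as follows, with switches for the alternatives: the covariance
is the plain product $C^TC$ (any global rescaling of $\Sigma$ cancels in
the normalised distribution factors; `sigma_norm = "spectral"` applies a
$\|C\|_2$ division), and the component scale divides by the peak density
(`peak_scale = "multiply"` keeps the literal product, which has no mass
interpretation).

**Foot regions and registration.** A triangulated 2D foot model with six
anatomical subregions (heel, arch, medial/lateral metatarsum,
medial/lateral toes) is registered to each frame by the affine transform
minimising the squared distance over the three landmark correspondences
(first and fifth metatarsal heads, calcaneus), solved in closed form
via the pseudo-inverse; with three non-collinear landmarks the fit is
exact. The transform is deliberately affine — exactly what the
least-squares formulation yields — even though it admits shear; a
warning is raised if $|\det M|$ leaves $[0.5, 2]$ (implausible foot
scaling).

A region is *in contact* iff its registered centre is below
$h_{min} = 0.03$ m and slower than $v_{min} = 0.8$ m/s; regions failing
either test carry zero load. The thresholds make the method independent
of stance times or gait-event detection.

**Load distribution.** The load on region $\Omega_k$ is
$$L_{\Omega_k} = F_{GRF,z}\,
  \frac{\int_{\Omega_k} \hat w f}
       {\int_{\Omega_L} \hat w_L f + \int_{\Omega_R} \hat w_R f},$$
with all integrals taken over in-contact regions only. Integrals use a
per-triangle midpoint rule: area times the mean of the integrand at the
three vertices (exact for affine integrands, second-order convergent
under refinement; a centroid-evaluation variant is available through
`integrate_region`). Conservation — region loads summing exactly to
$F_{GRF,z}$ whenever any contact exists — holds by construction,
whatever the weights.

**Arch weighting.** Unweighted shadow integration loads the arch like
the heel, which is true only of pathologically flat feet. A quadratic
surface $w(x,y)$ is fitted in the model frame with $w = 1$ at the three
bony support points and $w = h_a / \mathrm{dist}_{CP}$ at the midpoints
between front and rear contact points, where $\mathrm{dist}_{CP}$ is the
calcaneus–fifth-metatarsal distance and $h_a$ (metres, default 0.035)
models the height of the cuboid bone above the ground. Five constraints
determine six coefficients; the remaining freedom is resolved by
shrinking towards the flat surface $w \equiv 1$ (ridge $10^{-12}$), so
all-ones targets reproduce $w \equiv 1$ exactly and the fitted surface
stays positive over the mesh. The raw weights are rescaled per foot and
frame by $n_t = \int f / \int w f$ so that per-foot totals are untouched
— the arch model only redistributes load *within* a foot. The surface is
fitted once in the model frame and transported through the registration
transform, so it deforms with the foot.

**Hip-flexion balance.** Sustained balancing over one foot gradually
unloads the other leg even when the feet barely move — a muscle effect
invisible to kinematics. It is emulated by two scalars
$s_L, s_R \in [0,1]$ (initially 1): the planar CoM path is predicted
$\bar t$ frames ahead along its velocity, and if any predicted point
falls in the convex hull of exactly one foot, that side's scalar ramps
up and the other down by $m\,\Delta t$ per frame (slope $m$ in 1/s, so
behaviour is sampling-rate invariant); if the path stays in neither
hull — or reaches both, the conservative neutral case for overlapping
feet — both recover towards 1. The weight surfaces are multiplied by
$s_L + (1 - s_R)$ and $s_R + (1 - s_L)$. Saturation ($s_R = 0$,
$s_L = 1$) drives the unloaded foot's share to zero while the
normalisation preserves the total.

## Hyper-parameters and calibration

The tunable parameters are the per-segment dispersions $(a_s, b_s)$, the
prediction horizon $\bar t$ (frames) and the ramp slope $m$. They are
calibration outputs: `fit_hyperparameters()` minimises the summed squared
deviation between the method's six-region load vectors and reference
loads over all frames, using a bound-constrained quasi-Newton optimiser
(dispersions in $[10^{-3}, 1]$ m) inside an outer loop that enforces the
step-tolerance rule $\|P_{k+1} - P_k\| < 10^{-8}(1 + \|P_k\|)$. The
integer horizon $\bar t$ cannot be handled smoothly and is fitted by an
outer grid (default $0, 10, \dots, 60$ frames). Segments whose shadow
mass over the feet is negligible (share below 5 %) are unidentifiable
from load data and are ridge-regularised towards their initial values.
Calibration against a single representative sway recording is the
intended use; transfer to other motions is deliberately left untuned.

The shipped default dispersions were produced by exactly this procedure,
run once against the package's own quasi-static sway-all-around
condition (12 s at 10 Hz, 0.12 m amplitude, 0.4 m stance width, static
lever-rule reference loads split into regions by standard plantar load
shares) with the hip model disabled and the dispersions bounded to the
anatomically plausible range $[0.05, 0.35]$ m — an unconstrained fit
tracks marginally better but wanders into metre-scale, uninterpretable
dispersions. The fit starts from anatomically sized initial values
chosen by a small-signal gain argument: for torso-borne
segments, a dispersion near 0.2 m makes the logistic gain of the
two-foot shadow split match the linear gain of static lever balance at
ordinary stance width. Distal segments keep smaller, anatomically sized
dispersions. Hip defaults are $\bar t = 30$ frames (0.5 s at 60 Hz) and
$m = 2$ s$^{-1}$ (full transfer in half a second), conventional choices
in the absence of a printed reference value.

## The synthetic-data generator

`generate_motion()` is the package's software twin of a pressure-plate
study: a reduced nine-segment body (pelvis, trunk, lumped head+arms,
thighs, shanks, feet) performs quasi-static sway (all-around,
side-to-side, back-and-forth), squatting, or gait, with closed-form
twice-differentiable CoM trajectories so accelerations are exact.
Ground-truth per-foot loads follow the static lever rule along the
inter-foot axis, scaled by $m(g + \ddot x_{CoM,z})$ and, for gait, gated
by the stance schedule. Sway frequencies default to 0.25 Hz so peak CoM
accelerations stay below 0.5 m/s² and the quasi-static truth is valid to
a few percent — the generator's stated validity envelope. Measurement
error is emulated by additive Gaussian noise on segment CoMs (5 mm) and
landmarks (3 mm) plus an optional constant CoM offset reproducing
sensor-to-segment calibration bias; the deterministic part of a motion
consumes no randomness, so a spec and seed give bit-identical output.

`emulate_pressure_plate()` rasterises the posed feet onto a 176 × 64
grid (0.8469 cm² cells, 100 Hz) and distributes each foot's ground-truth
load over its regions with fixed anatomical shares (heel-dominant,
arch-discounted); within a region the profile is flat over interior
cells and tapers to zero on seam-straddling cells, since real plantar
pressure has no step discontinuities at anatomical boundaries. It requires stationary
feet (the weight-shifting protocols); per-frame plate totals equal the
interpolated ground truth by construction. What the emulator does *not*
model: soft-tissue pressure profiles, centre-of-pressure migration
within regions, sensor noise and hysteresis. Passing round-trip tests
therefore validates bookkeeping and registration, not biomechanical
realism of pressure distributions.

Gait ground truth is intentionally modest: contact timing and per-foot
totals are exact, but the classic double-hump vGRF shape is not claimed
— the generator's CoM template is too smooth for that.

## Evaluation tools

Footprints are extracted from a plate recording by summing frames over a
static-placement window, thresholding to a binary mask and labelling
4-connected components. Mapping model regions onto a footprint uses
centroid plus principal-axis alignment restricted to proper rotations
(the side of the print is known), with the 180° ambiguity resolved by
mesh-membership scoring and a sub-pixel translation lock-in that centres
the exact-raster-match plateau. This deliberately rigid, moment-based
alignment is an evaluation-harness device, not a general nonrigid
point-set registration.

Metrics follow the standard suite: RMSE; RMSE relative to the mean
peak-to-peak amplitude of the two series (percent); MAE; the standard
deviation of the signed error about its mean (an absolute-error variant
is available via `sd_absolute = TRUE`); and Pearson's r, flagged
undefined for constant series.

## Numerical choices and degenerate inputs

* Collinear landmark triples (model or pose) abort registration; the
  area tolerance is $10^{-8}$ m².
* Boundary points count as inside a convex hull — ties favour contact
  and loading continuity.
* Segments with undefined heading (near-vertical longitudinal axis) fall
  back to an isotropic component with dispersion $\min(a_s, b_s)$.
* If no region of either foot is in contact, all loads are zero and the
  frame is flagged; if contacts exist but the shadow mass over them is
  below $10^{-12}$, the frame errors out rather than dividing by noise.
* The online pipeline uses causal second-order backward differences when
  CoM derivatives are not supplied, so truncating the input reproduces
  the leading output rows exactly; the offline utility
  `com_derivatives()` uses central differences, which are one order more
  accurate but non-causal.

## Problem sizes used in the shipped tests

The test-suite and acceptance conditions run five synthetic motions of
at least 600 frames each on the default 1.5 cm foot meshes, a
dynamic-sway calibration recovery of ~90 frames at 15 Hz on 4 cm
meshes (dynamic rather than quasi-static, because the horizontal GRF
components shear the stacked torso projections apart by segment height
and make their dispersions separately identifiable), and 176 × 64 plate
emulations of a few seconds at 20–50 Hz — sizes chosen so the whole
pipeline, including a full hyper-parameter recovery, exercises every
code path at interactive runtimes.

## Known limitations

* Per-region pressure splits under a foot are ambiguous whenever muscle
  contraction changes the pressure distribution without changing the
  kinematics; per-foot totals are invariant to this, region splits are
  not.
* A constant CoM tracking bias (sensor-to-segment calibration error)
  translates directly into a lateral load bias; the generator's
  `com_offset` reproduces this failure mode for study.
* Only healthy foot geometry is modelled; the arch surface assumes a
  normal medial arch.
* The ground is a single flat plane at $z = 0$; multiple or non-planar
  interaction surfaces are out of scope.
* 3D shear components of the GRF and centres of pressure are not
  estimated.
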