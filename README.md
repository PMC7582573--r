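# forceshadow

Estimate the total **vertical ground reaction force (vGRF)** from body
kinematics alone and distribute it over both feet — including during
double support, where force-plate-free methods are otherwise
indeterminate.

## The problem and who this is for

In gait and posture analysis, the ground reaction force is the boundary
condition for all inverse dynamics. With a single contact it follows
from Newton's laws: \(F_{GRF} = m(\ddot x_{CoM} + [0,0,g]^T)\). But the
moment both feet touch the ground the body is a closed kinetic chain,
and kinematics no longer determine how the total force splits between
the feet. This package implements the *force shadow method*: a
constructive, online (frame-by-frame, no lookahead) solution aimed at
mobile motion-capture users — inertial suits, markerless systems — who
want per-foot and per-region vertical loads without a force plate.

The method:

1. projects every body-segment centre of mass along the GRF vector onto
   the ground, placing there an elliptical Gaussian whose peak equals
   the segment's mass fraction \(d_s\) and whose covariance
   \(\Sigma_s = R_s\,\mathrm{diag}(a_s^2,b_s^2)\,R_s^T\) follows the
   segment's heading — their sum is the **shadow function** \(f(x)\), a
   smooth picture of how body mass is stacked over the floor;
2. registers a triangulated 2D foot model (six anatomical subregions)
   to each frame by closed-form affine landmark least squares, and
   decides per-region ground contact by height/speed thresholds
   (0.03 m, 0.8 m/s);
3. integrates \(f\) over the in-contact regions by a vertex-average
   midpoint rule and normalises, so the region loads
   \(L_{\Omega_k} = F_{GRF,z}\,\int_{\Omega_k}\hat w f \big/
   \sum \int \hat w f\) sum *exactly* to the vertical GRF;
4. refines the within-foot distribution with a quadratic **arch weight
   surface** (the arch of a healthy foot carries less load than heel
   and forefoot) and the between-foot split with a ramped
   **hip-flexion balance model** that gradually unloads the leg the
   body is not standing over.

The per-segment dispersions and the hip-model horizon/slope are
calibration parameters; `fit_hyperparameters()` fits them to reference
load trajectories (e.g. from a pressure plate) by bound-constrained
least squares over the full forward model.

A synthetic-data module generates sway, squat and gait kinematics with
static-equilibrium ground-truth loads and an emulated 176 × 64 pressure
plate, so the entire pipeline is testable end to end without any
recorded data.

## Worked example

```r
library(forceshadow)

body <- default_body_model(m_total = 80)          # nine segments
spec <- motion_spec("sway_S2S", duration = 10, rate = 60,
                    noise_pos = 0, noise_lm = 0)   # side-to-side sway
m    <- generate_motion(spec, body)                # + ground truth

res  <- run_fsm(m$trajectory, body, m$feet,
                config = fsm_config(hip = FALSE))  # quasi-static mode
tot  <- foot_totals(res)

# compare per-foot totals (N/kg) against the lever-rule ground truth
fsm_metrics(c(tot$total_L, tot$total_R) / body$m_total,
            c(m$truth$load_L, m$truth$load_R) / body$m_total)
```

```
RMSE 0.01655 | rRMSE 0.3184% | MAE 0.0147 | SD 0.01656 | r 1.0000 (n=1202)
```

The body weighs 80 kg, so the total vertical load is 9.81 N/kg; while
the subject sways side to side the left-foot share moves between 23 %
and 77 % of body weight (the static lever rule), and the estimated
per-foot series tracks that reference with r = 1.000 and a mean
absolute error of 0.015 N/kg — about 0.15 % of body weight.
Conservation is exact by construction:

```r
max(abs(tot$total_L + tot$total_R - res$F_z))   # ~1e-13 N
```

Per-region columns (`L_L_Heel`, …, `I_R_ToesLat`) give the within-foot
distribution; with the arch model on, the arch region's share drops
relative to the heel and forefoot while each foot's total is unchanged.

A thin command-line wrapper is installed with the package
(`inst/scripts/fsm`) with subcommands `run`, `synth`, `calibrate` and
`eval` over CSV/YAML/JSON files.

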