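#' Synthetic motion specification
#'
#' Describes a synthetic study condition for the generator: quasi-static
#' weight-shifting sway (all-around `sway_AR`, side-to-side `sway_S2S`,
#' back-and-forth `sway_BF`), squatting, or gait. Sway and squat keep both
#' feet planted; gait alternates stance and swing with heel height and
#' speed crossing the contact thresholds.
#'
#' @param kind motion kind.
#' @param duration seconds.
#' @param rate sampling rate (Hz).
#' @param foot_sep lateral distance between foot centres (m).
#' @param amplitude CoM excursion amplitude (m); for squat, the vertical
#'   excursion.
#' @param freq sway/squat frequency (Hz); defaults keep peak CoM
#'   acceleration below ~0.5 m/s^2 so the static-equilibrium ground truth
#'   is valid.
#' @param seed integer RNG seed (noise only; the deterministic part does
#'   not consume randomness).
#' @param noise_pos,noise_lm additive Gaussian noise SD on segment CoMs and
#'   foot landmarks (m), emulating inertial-capture error.
#' @param com_offset constant 3-vector added to all segment CoMs and the
#'   CoM (m), emulating a sensor-to-segment calibration bias.
#' @param step_length,cycle_time,swing_time,swing_height gait parameters
#'   (m, s, s, m).
#' @return list of class `fsm_motion_spec`.
#' @export
motion_spec <- function(kind = c("sway_AR", "sway_S2S", "sway_BF",
                                 "squat", "gait"),
                        duration = 10, rate = 60, foot_sep = 0.4,
                        amplitude = 0.12, freq = 0.25, seed = 1,
                        noise_pos = 0.005, noise_lm = 0.003,
                        com_offset = c(0, 0, 0),
                        step_length = 0.35, cycle_time = 1.2,
                        swing_time = 0.45, swing_height = 0.08) {
  kind <- match.arg(kind)
  stopifnot(duration > 0, rate > 0, foot_sep > 0, amplitude >= 0, freq > 0)
  structure(as.list(environment()), class = "fsm_motion_spec")
}

# piecewise C^2 swing trajectory of one foot along +x.
# Returns x, z, speed at times t for swings starting at t0 + (j-1)*cycle.
.gait_foot <- function(t, t0, cycle, t_sw, stride, h_sw, x0) {
  x <- rep(x0, length(t)); z <- numeric(length(t)); sp <- numeric(length(t))
  rel <- t - t0
  j <- ifelse(rel < 0, 0, floor(rel / cycle) + 1)   # swings completed/underway
  u <- (rel - (j - 1) * cycle) / t_sw
  done <- j >= 1 & u >= 1
  x[done] <- x0 + j[done] * stride
  inswing <- j >= 1 & u >= 0 & u < 1
  us <- u[inswing]
  x[inswing] <- x0 + (j[inswing] - 1) * stride + stride * .smoothstep5(us)
  z[inswing] <- h_sw * sin(pi * us)^2
  dx <- stride * 30 * us^2 * (1 - us)^2 / t_sw     # d smoothstep5 / dt
  dz <- h_sw * pi * sin(2 * pi * us) / t_sw
  sp[inswing] <- sqrt(dx^2 + dz^2)
  list(x = x, z = z, speed = sp, stance = !inswing)
}

#' Generate a synthetic motion with ground-truth loads
#'
#' Builds a reduced nine-segment trajectory (pelvis, trunk, lumped
#' head+arms, thighs, shanks, feet) with closed-form, twice continuously
#' differentiable CoM motion, posed foot landmarks, per-foot heel/toe
#' height and speed channels, and static-equilibrium ground-truth per-foot
#' loads from the lever rule along the inter-foot axis: the left fraction
#' is \eqn{\mathrm{clamp}((p_R - x_{CoM})\cdot(p_R - p_L)/\|p_R - p_L\|^2,
#' 0, 1)}, scaled by \eqn{m_{total}(g + \ddot x_{CoM,z})}. For gait, loads
#' are additionally gated by the stance schedule (a swinging foot carries
#' zero load). Deterministic given the spec's seed.
#'
#' @param spec an `fsm_motion_spec`.
#' @param body an `fsm_body` (default [default_body_model()]).
#' @param feet list of `fsm_foot` models `L`, `R` (defaults built to match
#'   `spec$foot_sep`).
#' @return list of class `fsm_motion`: `trajectory` (an
#'   `fsm_trajectory`), `truth` (data frame with `time`, `total`,
#'   `frac_L`, `load_L`, `load_R`, `stance_L`, `stance_R`), `feet`,
#'   `foot_center` (list of `n x 2` matrices), `poses` (frame-1 transforms
#'   per side), and `spec`.
#' @export
generate_motion <- function(spec, body = default_body_model(), feet = NULL) {
  if (is.null(feet))
    feet <- list(L = foot_model("left"), R = foot_model("right"))
  if (spec$foot_sep < feet$L$foot_width)
    .stopf("overlapping stance geometry: foot_sep %.3g < foot width %.3g",
           spec$foot_sep, feet$L$foot_width)
  n <- round(spec$duration * spec$rate) + 1L
  t <- seq(0, by = 1 / spec$rate, length.out = n)
  sep <- spec$foot_sep
  segs <- c("pelvis", "trunk", "head_arms", "thigh_L", "thigh_R",
            "shank_L", "shank_R", "foot_L", "foot_R")
  if (!setequal(segs, body$segments))
    .stopf("generate_motion expects the default nine-segment body model")
  base <- rbind(pelvis = c(0, 0, 1.00), trunk = c(0, 0, 1.30),
                head_arms = c(0, 0, 1.55),
                thigh_L = c(0, 0.10, 0.72), thigh_R = c(0, -0.10, 0.72),
                shank_L = c(0, sep / 2, 0.35), shank_R = c(0, -sep / 2, 0.35),
                foot_L = c(0.03, sep / 2, 0.03), foot_R = c(0.03, -sep / 2, 0.03))
  torso <- c("pelvis", "trunk", "head_arms", "thigh_L", "thigh_R")
  sc <- array(rep(base, each = n), c(n, length(segs), 3),
              dimnames = list(NULL, segs, c("x", "y", "z")))
  om <- 2 * pi * spec$freq
  A <- spec$amplitude
  zero <- numeric(n)
  dxy <- cbind(zero, zero); ddxy <- cbind(zero, zero)
  dz <- zero; ddz <- zero
  foot_x <- list(L = rep(0, n), R = rep(0, n))
  foot_z <- list(L = zero, R = zero)
  foot_sp <- list(L = zero, R = zero)
  stance <- list(L = rep(TRUE, n), R = rep(TRUE, n))
  if (spec$kind %in% c("sway_AR", "sway_S2S", "sway_BF")) {
    share <- sum(body$d[torso])
    if (share * A > sep / 2)
      .stopf("sway amplitude drives the CoM outside the support polygon")
    if (A * om^2 > 0.5)
      warning("peak sway acceleration exceeds 0.5 m/s^2; ",
              "static-equilibrium ground truth degrades", call. = FALSE)
    dxy <- switch(spec$kind,
      sway_AR  = cbind(0.6 * A * cos(om * t), A * sin(om * t)),
      sway_S2S = cbind(zero, A * sin(om * t)),
      sway_BF  = cbind(A * sin(om * t), zero))
    ddxy <- switch(spec$kind,
      sway_AR  = cbind(-0.6 * A * om^2 * cos(om * t), -A * om^2 * sin(om * t)),
      sway_S2S = cbind(zero, -A * om^2 * sin(om * t)),
      sway_BF  = cbind(-A * om^2 * sin(om * t), zero))
  } else if (spec$kind == "squat") {
    dz <- -A * (1 - cos(om * t)) / 2
    ddz <- -A * om^2 * cos(om * t) / 2
  } else { # gait
    stride <- 2 * spec$step_length
    gl <- .gait_foot(t, t0 = 0.75 * spec$cycle_time / 1.2, spec$cycle_time,
                     spec$swing_time, stride, spec$swing_height, 0)
    gr <- .gait_foot(t, t0 = 0.15 * spec$cycle_time / 1.2, spec$cycle_time,
                     spec$swing_time, stride, spec$swing_height,
                     spec$step_length)
    foot_x <- list(L = gl$x, R = gr$x)
    foot_z <- list(L = gl$z, R = gr$z)
    foot_sp <- list(L = gl$speed, R = gr$speed)
    stance <- list(L = gl$stance, R = gr$stance)
    x_com <- (gl$x + gr$x) / 2
    a_lat <- 0.4 * sep / 2
    y_com <- a_lat * sin(2 * pi * (t - 0.075 * spec$cycle_time / 1.2) /
                           spec$cycle_time)
    dxy <- cbind(x_com, y_com)
    ddxy <- NULL   # derived numerically below (C^2 template)
  }
  # apply offsets: torso-borne segments carry the sway template; legs
  # follow the feet for gait
  for (s in torso) {
    sc[, s, 1] <- sc[, s, 1] + dxy[, 1]
    sc[, s, 2] <- sc[, s, 2] + dxy[, 2]
    sc[, s, 3] <- sc[, s, 3] + dz
  }
  for (side in c("L", "R")) {
    fs <- paste0("foot_", side); sh <- paste0("shank_", side)
    th <- paste0("thigh_", side)
    sc[, fs, 1] <- sc[, fs, 1] + foot_x[[side]]
    sc[, fs, 3] <- sc[, fs, 3] + foot_z[[side]]
    if (spec$kind == "gait") {
      sc[, sh, 1] <- sc[, sh, 1] + 0.75 * foot_x[[side]] + 0.25 * dxy[, 1]
      sc[, sh, 3] <- sc[, sh, 3] + 0.5 * foot_z[[side]]
      sc[, th, 1] <- base[th, 1] + 0.5 * (foot_x[[side]] + dxy[, 1])
    }
  }
  heading <- matrix(0, n, length(segs), dimnames = list(NULL, segs))
  # exact (noise-free) CoM and analytic derivatives
  com <- matrix(0, n, 3)
  for (k in 1:3) com[, k] <- sc[, , k] %*% body$d[segs]
  if (spec$kind == "gait") {
    der <- com_derivatives(t, com)
    com_vel <- der$vel; com_acc <- der$acc
  } else {
    share <- sum(body$d[torso])
    dsh <- share
    com_vel <- switch(spec$kind,
      sway_AR  = cbind(-0.6 * A * om * sin(om * t) * dsh,
                       A * om * cos(om * t) * dsh, zero),
      sway_S2S = cbind(zero, A * om * cos(om * t) * dsh, zero),
      sway_BF  = cbind(A * om * cos(om * t) * dsh, zero, zero),
      squat    = cbind(zero, zero, -share * A * om * sin(om * t) / 2))
    com_acc <- switch(spec$kind,
      sway_AR  = cbind(ddxy[, 1] * dsh, ddxy[, 2] * dsh, zero),
      sway_S2S = cbind(zero, ddxy[, 2] * dsh, zero),
      sway_BF  = cbind(ddxy[, 1] * dsh, zero, zero),
      squat    = cbind(zero, zero, share * ddz))
  }
  # ground-truth loads: lever rule along the inter-foot axis, gated by
  # the stance schedule
  ctrL <- cbind(foot_x$L, rep(sep / 2, n))
  ctrR <- cbind(foot_x$R, rep(-sep / 2, n))
  dvec <- ctrR - ctrL
  dd <- rowSums(dvec^2)
  fracL <- .clamp(rowSums((ctrR - com[, 1:2]) * dvec) / dd, 0, 1)
  fracL[stance$L & !stance$R] <- 1
  fracL[!stance$L & stance$R] <- 0
  total <- body$m_total * (body$g + com_acc[, 3])
  truth <- data.frame(time = t, total = total, frac_L = fracL,
                      load_L = total * fracL, load_R = total * (1 - fracL),
                      stance_L = stance$L, stance_R = stance$R)
  # posed landmarks (translation-only pose; world foot centre at mid-mesh)
  lmarr <- function(side) {
    ft <- feet[[side]]
    cmod <- c(ft$foot_length / 2, 0)
    ty <- if (side == "L") sep / 2 else -sep / 2
    a <- array(NA_real_, c(n, 3, 2),
               dimnames = list(NULL, c("FM", "VM", "CA"), c("x", "y")))
    for (lm in c("FM", "VM", "CA")) {
      a[, lm, 1] <- ft$landmarks[[lm]][1] - cmod[1] + foot_x[[side]]
      a[, lm, 2] <- ft$landmarks[[lm]][2] + ty
    }
    a
  }
  landmarks <- list(L = lmarr("L"), R = lmarr("R"))
  foot_kin <- lapply(c(L = "L", R = "R"), function(side) {
    m <- cbind(heel_z = foot_z[[side]], toe_z = foot_z[[side]],
               heel_speed = foot_sp[[side]], toe_speed = foot_sp[[side]])
    m
  })
  # measurement noise + calibration bias (deterministic part consumes no RNG)
  set.seed(spec$seed %% .Machine$integer.max)
  off <- spec$com_offset
  sc_noisy <- sc
  if (spec$noise_pos > 0)
    sc_noisy <- sc_noisy + array(stats::rnorm(length(sc), 0, spec$noise_pos),
                                 dim = dim(sc))
  for (k in 1:3) sc_noisy[, , k] <- sc_noisy[, , k] + off[k]
  if (spec$noise_lm > 0)
    for (side in c("L", "R"))
      landmarks[[side]] <- landmarks[[side]] +
        array(stats::rnorm(length(landmarks[[side]]), 0, spec$noise_lm),
              dim = dim(landmarks[[side]]))
  com_obs <- sweep(com, 2, off, "+")
  traj <- fsm_trajectory(time = t, seg_com = sc_noisy, heading = heading,
                         landmarks = landmarks, com = com_obs,
                         com_vel = com_vel, com_acc = com_acc,
                         foot_kin = foot_kin)
  poses <- lapply(c(L = "L", R = "R"), function(side) {
    lm <- landmarks[[side]][1, , ]
    register_foot(feet[[side]], lm["FM", ], lm["VM", ], lm["CA", ])
  })
  structure(list(trajectory = traj, truth = truth, feet = feet,
                 foot_center = list(L = ctrL, R = ctrR), poses = poses,
                 spec = spec),
            class = "fsm_motion")
}
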