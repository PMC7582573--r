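#' Pipeline configuration
#'
#' Collects the model switches and thresholds of the load-distribution
#' pipeline. `arch`/`hip` toggle the anatomical refinements; with both off
#' the pipeline reduces to plain shadow integration and normalisation.
#' `grf_sign`, `sigma_norm` and `peak_scale` select the documented variant
#' readings of the GRF sign convention, covariance normalisation and
#' component peak scaling.
#'
#' @param arch logical, apply the foot-arch weight surface.
#' @param hip logical, apply the hip-flexion balance model.
#' @param h_a cuboid height for the arch surface (m), see
#'   [fit_arch_surface()].
#' @param h_min,v_min contact thresholds (m, m/s), see [contact_state()].
#' @param eps_f vertical-GRF floor (N); frames below it (flight) produce
#'   zero loads everywhere.
#' @param grf_sign `"newton"` or `"as_printed"`, see
#'   [ground_reaction_force()].
#' @param sigma_norm `"ctc"` or `"spectral"`, see [segment_covariance()].
#' @param peak_scale `"divide"` or `"multiply"`, see [build_shadow()].
#' @return a list of class `fsm_config`.
#' @export
fsm_config <- function(arch = TRUE, hip = TRUE, h_a = 0.035,
                       h_min = 0.03, v_min = 0.8, eps_f = 1,
                       grf_sign = c("newton", "as_printed"),
                       sigma_norm = c("ctc", "spectral"),
                       peak_scale = c("divide", "multiply")) {
  structure(list(arch = arch, hip = hip, h_a = h_a, h_min = h_min,
                 v_min = v_min, eps_f = eps_f,
                 grf_sign = match.arg(grf_sign),
                 sigma_norm = match.arg(sigma_norm),
                 peak_scale = match.arg(peak_scale)),
            class = "fsm_config")
}

#' Hyper-parameter set
#'
#' The tunable parameters of the method: per-segment Gaussian dispersions
#' `(a_s, b_s)` (m), the hip-model prediction horizon `tbar` (frames) and
#' ramp slope `m` (1/s). These are calibration outputs in principle
#' ([fit_hyperparameters()]); the defaults are chosen by a small-signal
#' gain-matching argument (dispersion ~0.2 m for torso-borne segments so
#' that the two-foot shadow split tracks static lever balance at typical
#' stance width, smaller anatomically sized dispersions distally).
#'
#' @param body an `fsm_body`.
#' @param dispersion optional `S x 2` matrix (rownames = segments)
#'   overriding the defaults.
#' @param tbar prediction horizon (frames).
#' @param m ramp slope (1/s).
#' @return list of class `fsm_params` with `dispersion`, `tbar`, `m`.
#' @export
default_fsm_params <- function(body, dispersion = NULL, tbar = 30, m = 2) {
  if (is.null(dispersion)) {
    # factory calibration output: energy fit against the static-lever
    # reference on the canonical sway-all-around condition, dispersions
    # bounded to the anatomically plausible range [0.05, 0.35] m
    pick <- function(seg) {
      if (grepl("pelvis", seg)) c(0.164, 0.223)
      else if (grepl("trunk|torso", seg)) c(0.221, 0.050)
      else if (grepl("head|arm", seg)) c(0.350, 0.350)
      else if (grepl("thigh", seg)) c(0.050, 0.050)
      else if (grepl("shank|leg", seg)) c(0.050, 0.350)
      else if (grepl("foot", seg)) c(0.350, 0.050)
      else c(0.15, 0.10)
    }
    dispersion <- t(vapply(body$segments, pick, numeric(2)))
  }
  dispersion <- as.matrix(dispersion)
  colnames(dispersion) <- c("a", "b")
  if (is.null(rownames(dispersion))) rownames(dispersion) <- body$segments
  structure(list(dispersion = dispersion, tbar = as.integer(tbar), m = m),
            class = "fsm_params")
}

# Full forward pass. Returns per-frame load/factor matrices per foot plus
# diagnostics; run_fsm() flattens this into the user-facing table.
.fsm_forward <- function(traj, body, feet, params, config) {
  n <- n_frames(traj)
  regs <- foot_regions()
  segs <- body$segments
  if (!all(segs %in% dimnames(traj$seg_com)[[2]]))
    .stopf("trajectory lacks segment(s): %s",
           paste(setdiff(segs, dimnames(traj$seg_com)[[2]]), collapse = ", "))
  dt <- traj$dt
  com <- .traj_com(traj, body)
  if (!is.null(traj$com_vel) && !is.null(traj$com_acc)) {
    com_vel <- traj$com_vel; com_acc <- traj$com_acc
  } else {
    der <- .causal_derivatives(com, dt)
    com_vel <- if (is.null(traj$com_vel)) der$vel else traj$com_vel
    com_acc <- if (is.null(traj$com_acc)) der$acc else traj$com_acc
  }
  arch_w <- NULL
  if (config$arch) {
    arch_w <- lapply(feet, function(ft)
      eval_arch(fit_arch_surface(ft, config$h_a), ft$nodes))
    for (side in names(arch_w))
      if (any(arch_w[[side]] <= 0))
        warning("arch weight surface non-positive on part of the mesh",
                call. = FALSE)
  }
  hip <- hip_state(m = params$m, tbar = params$tbar, dt = dt)
  L_out <- list(L = matrix(0, n, length(regs), dimnames = list(NULL, regs)),
                R = matrix(0, n, length(regs), dimnames = list(NULL, regs)))
  I_out <- list(L = L_out$L, R = L_out$R)
  F_z <- numeric(n)
  flight <- logical(n)
  contact_any <- logical(n)
  s_log <- matrix(1, n, 2, dimnames = list(NULL, c("s_L", "s_R")))
  reg_frac <- lapply(feet, function(ft) ft$region_length_fraction)
  for (i in seq_len(n)) {
    f_grf <- ground_reaction_force(body, com_acc[i, ], sign = config$grf_sign)
    F_z[i] <- f_grf[3]
    if (abs(f_grf[3]) < config$eps_f) {   # flight: no ground interaction
      flight[i] <- TRUE
      s_log[i, ] <- c(hip$s_L, hip$s_R)
      next
    }
    shadow <- build_shadow(traj$seg_com[i, segs, ], traj$heading[i, segs],
                           body, f_grf, params$dispersion,
                           peak_scale = config$peak_scale,
                           sigma_norm = config$sigma_norm,
                           eps_f = config$eps_f)
    posed <- list(); contacts <- list()
    for (side in c("L", "R")) {
      lm <- traj$landmarks[[side]][i, , ]
      tf <- register_foot(feet[[side]], lm["FM", ], lm["VM", ], lm["CA", ])
      posed[[side]] <- pose_foot(feet[[side]], tf)
      if (is.null(traj$foot_kin)) {
        h <- rep(0, length(regs)); v <- rep(0, length(regs))
      } else {
        fk <- traj$foot_kin[[side]][i, ]
        fr <- reg_frac[[side]]
        h <- (1 - fr) * fk["heel_z"] + fr * fk["toe_z"]
        v <- (1 - fr) * fk["heel_speed"] + fr * fk["toe_speed"]
      }
      contacts[[side]] <- contact_state(h, v, config$h_min, config$v_min)
    }
    hip_mod <- list(L = 1, R = 1)
    if (config$hip) {
      com_xy <- project_to_ground(com[i, ], f_grf, eps_f = config$eps_f)
      hip <- hip_flexion_update(hip, com_xy, com_vel[i, 1:2],
                                posed$L$hull, posed$R$hull)
      hip_mod <- list(L = hip$mod_L, R = hip$mod_R)
    }
    s_log[i, ] <- c(hip$s_L, hip$s_R)
    core <- .frame_loads(f_grf[3], shadow, posed, contacts,
                         arch_w = arch_w, hip_mod = hip_mod)
    contact_any[i] <- core$any_contact
    for (side in c("L", "R")) {
      L_out[[side]][i, ] <- core$L[side, ]
      I_out[[side]][i, ] <- core$I[side, ]
    }
  }
  list(time = traj$time, F_z = F_z, L = L_out, I = I_out,
       flight = flight, contact_any = contact_any, s = s_log)
}

#' Run the full load-distribution pipeline
#'
#' Executes, frame by frame and strictly online (each output row depends
#' only on the current and earlier frames), the method's stages: total GRF
#' from CoM acceleration; projection of segment CoMs along the GRF and
#' construction of the elliptical-Gaussian shadow field; landmark
#' registration of both foot models; contact detection; arch weighting
#' with conservation rescaling; hip-flexion prediction and ramp update;
#' and midpoint-rule integration of the weighted shadow over the
#' in-contact regions, normalised so that the region loads sum to the
#' vertical GRF.
#'
#' @param traj an `fsm_trajectory`.
#' @param body an `fsm_body`.
#' @param feet list with `fsm_foot` elements `L` and `R` (model frame);
#'   defaults to [foot_model()] for both sides.
#' @param params an `fsm_params` (default [default_fsm_params()]).
#' @param config an `fsm_config`.
#' @return data frame with one row per frame: `time`, `F_z` (N), `flight`
#'   and `contact_any` flags, hip scalars `s_L`, `s_R`, and per-foot
#'   per-region loads `L_<side>_<region>` (N) and distribution factors
#'   `I_<side>_<region>`. The configuration and parameters used are
#'   attached as attributes `config` and `params`.
#' @export
run_fsm <- function(traj, body, feet = NULL, params = NULL,
                    config = fsm_config()) {
  if (is.null(feet))
    feet <- list(L = foot_model("left"), R = foot_model("right"))
  if (is.null(params)) params <- default_fsm_params(body)
  fw <- .fsm_forward(traj, body, feet, params, config)
  out <- data.frame(time = fw$time, F_z = fw$F_z, flight = fw$flight,
                    contact_any = fw$contact_any,
                    s_L = fw$s[, 1], s_R = fw$s[, 2])
  for (side in c("L", "R")) {
    colnames(fw$L[[side]]) <- paste("L", side, foot_regions(), sep = "_")
    colnames(fw$I[[side]]) <- paste("I", side, foot_regions(), sep = "_")
  }
  out <- cbind(out, fw$L$L, fw$L$R, fw$I$L, fw$I$R)
  attr(out, "config") <- config
  attr(out, "params") <- params
  out
}

#' Per-foot total loads from a pipeline output table
#'
#' @param result data frame from [run_fsm()].
#' @return data frame with `time`, `total_L`, `total_R` (N).
#' @export
foot_totals <- function(result) {
  lcols <- paste("L", "L", foot_regions(), sep = "_")
  rcols <- paste("L", "R", foot_regions(), sep = "_")
  data.frame(time = result$time,
             total_L = rowSums(result[lcols]),
             total_R = rowSums(result[rcols]))
}
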