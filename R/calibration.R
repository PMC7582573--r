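#' Calibration energy
#'
#' Sum of squared deviations between the method's per-region load vectors
#' and reference loads over all frames,
#' \eqn{E(P) = \sum_t \|L_L(P) - P_L\|^2 + \|L_R(P) - P_R\|^2},
#' where the six-dimensional load vectors come from the full forward pass
#' with hyper-parameter set P.
#'
#' @param params an `fsm_params`.
#' @param traj an `fsm_trajectory`.
#' @param body an `fsm_body`.
#' @param feet list of `fsm_foot` models.
#' @param reference list with `L` and `R`, `n x 6` matrices of reference
#'   per-region loads (N), columns ordered as [foot_regions()],
#'   frame-aligned with the trajectory.
#' @param config an `fsm_config`.
#' @return nonnegative scalar energy (N^2).
#' @export
fsm_energy <- function(params, traj, body, feet, reference,
                       config = fsm_config()) {
  n <- n_frames(traj)
  for (side in c("L", "R"))
    if (is.null(reference[[side]]) || nrow(reference[[side]]) != n)
      .stopf("reference$%s must have one row per trajectory frame", side)
  fw <- tryCatch(.fsm_forward(traj, body, feet, params, config),
                 error = function(e) .stopf("forward pass failed: %s",
                                            conditionMessage(e)))
  sum((fw$L$L - reference$L)^2) + sum((fw$L$R - reference$R)^2)
}

# Precomputed per-frame geometry for dispersion-only energy evaluations
# (hip model off): registration, posing, contacts and arch weights do not
# depend on the dispersions, so they are computed once per trajectory.
.calib_cache <- function(traj, body, feet, config) {
  n <- n_frames(traj)
  segs <- body$segments
  com <- .traj_com(traj, body)
  if (!is.null(traj$com_acc)) com_acc <- traj$com_acc
  else com_acc <- .causal_derivatives(com, traj$dt)$acc
  arch_w <- NULL
  if (config$arch)
    arch_w <- lapply(feet, function(ft)
      eval_arch(fit_arch_surface(ft, config$h_a), ft$nodes))
  regs <- foot_regions()
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    f_grf <- ground_reaction_force(body, com_acc[i, ], sign = config$grf_sign)
    if (abs(f_grf[3]) < config$eps_f) {
      frames[[i]] <- list(flight = TRUE, f_z = f_grf[3])
      next
    }
    fr <- list(flight = FALSE, f_z = f_grf[3], f_grf = f_grf,
               seg_pos = traj$seg_com[i, segs, ],
               heading = traj$heading[i, segs], side = list())
    for (side in c("L", "R")) {
      ft <- feet[[side]]
      lm <- traj$landmarks[[side]][i, , ]
      tf <- register_foot(ft, lm["FM", ], lm["VM", ], lm["CA", ])
      if (is.null(traj$foot_kin)) {
        ct <- rep(TRUE, length(regs))
      } else {
        fk <- traj$foot_kin[[side]][i, ]
        frk <- ft$region_length_fraction
        ct <- contact_state((1 - frk) * fk["heel_z"] + frk * fk["toe_z"],
                            (1 - frk) * fk["heel_speed"] +
                              frk * fk["toe_speed"],
                            config$h_min, config$v_min)
      }
      fr$side[[side]] <- list(
        nodes = apply_transform(tf, ft$nodes),
        areas = ft$areas * abs(det(tf$M)),
        tri = ft$tri, region = ft$region,
        active = unname(ct)[as.integer(ft$region)],
        any_ct = any(ct),
        w = if (is.null(arch_w)) NULL else arch_w[[side]])
    }
    frames[[i]] <- fr
  }
  list(frames = frames, body = body, config = config)
}

# Residual vector (frame x region x side) from the full forward pass
.residuals_full <- function(params, traj, body, feet, reference, config) {
  fw <- .fsm_forward(traj, body, feet, params, config)
  c(fw$L$L - reference$L, fw$L$R - reference$R)
}

# Residual vector from a cache (hip model off)
.residuals_cached <- function(params, cache, reference) {
  pred <- .predict_cached(params, cache)
  c(pred$L - reference$L, pred$R - reference$R)
}

# Per-frame load matrices from a cache; numerically identical to the
# full forward pass with the hip model disabled.
.predict_cached <- function(params, cache) {
  body <- cache$body
  config <- cache$config
  regs <- foot_regions()
  n <- length(cache$frames)
  out <- list(L = matrix(0, n, length(regs)),
              R = matrix(0, n, length(regs)))
  for (i in seq_len(n)) {
    fr <- cache$frames[[i]]
    if (fr$flight) next
    shadow <- build_shadow(fr$seg_pos, fr$heading, body, fr$f_grf,
                           params$dispersion,
                           peak_scale = config$peak_scale,
                           sigma_norm = config$sigma_norm,
                           eps_f = config$eps_f)
    num <- matrix(0, 2, length(regs), dimnames = list(c("L", "R"), regs))
    for (side in c("L", "R")) {
      sd_ <- fr$side[[side]]
      if (!sd_$any_ct || !any(sd_$active)) next
      fvals <- evaluate_shadow(shadow, sd_$nodes)
      wf0 <- if (is.null(sd_$w)) fvals else sd_$w * fvals
      tri <- sd_$tri
      fbar <- (fvals[tri[, 1]] + fvals[tri[, 2]] + fvals[tri[, 3]]) / 3
      wbar <- (wf0[tri[, 1]] + wf0[tri[, 2]] + wf0[tri[, 3]]) / 3
      int_f <- sum(fbar[sd_$active] * sd_$areas[sd_$active])
      int_wf <- sum(wbar[sd_$active] * sd_$areas[sd_$active])
      if (!is.finite(int_wf) || int_wf <= 0) next
      tri_int <- wbar * sd_$areas * sd_$active * (int_f / int_wf)
      sums <- rowsum(tri_int, sd_$region)
      num[side, rownames(sums)] <- sums[, 1]
    }
    denom <- sum(num)
    if (denom >= 1e-12) {
      out$L[i, ] <- fr$f_z * num["L", ] / denom
      out$R[i, ] <- fr$f_z * num["R", ] / denom
    } else if (any(vapply(fr$side, function(s) s$any_ct, logical(1)))) {
      .stopf("degenerate shadow mass at frame %d", i)
    }
  }
  out
}

# Energy from a cache; numerically identical to fsm_energy() with the
# hip model disabled.
.energy_cached <- function(params, cache, reference) {
  pred <- .predict_cached(params, cache)
  sum((pred$L - reference$L)^2) + sum((pred$R - reference$R)^2)
}

# pack/unpack the continuous parameter vector: per-segment (a, b) plus,
# when the hip model is active, the ramp slope m
.pack_params <- function(params, with_m) {
  th <- as.numeric(t(params$dispersion))
  names(th) <- paste0(rep(rownames(params$dispersion), each = 2), c("_a", "_b"))
  if (with_m) th <- c(th, m = params$m)
  th
}

.unpack_params <- function(theta, template, with_m) {
  S <- nrow(template$dispersion)
  disp <- matrix(theta[seq_len(2 * S)], S, 2, byrow = TRUE,
                 dimnames = dimnames(template$dispersion))
  template$dispersion <- disp
  if (with_m) template$m <- theta[2 * S + 1]
  template
}

# mean relative contribution of each segment's component mass to the
# shadow over both foot regions (identifiability screen)
.shadow_mass_share <- function(traj, body, feet, params, config,
                               frames = NULL) {
  n <- n_frames(traj)
  if (is.null(frames)) frames <- unique(round(seq(1, n, length.out = 5)))
  segs <- body$segments
  acc <- if (!is.null(traj$com_acc)) traj$com_acc else
    matrix(0, n, 3)
  share <- numeric(length(segs)); names(share) <- segs
  for (i in frames) {
    f_grf <- ground_reaction_force(body, acc[i, ], sign = config$grf_sign)
    if (abs(f_grf[3]) < config$eps_f) next
    shadow <- build_shadow(traj$seg_com[i, segs, ], traj$heading[i, segs],
                           body, f_grf, params$dispersion,
                           peak_scale = config$peak_scale,
                           sigma_norm = config$sigma_norm)
    for (side in c("L", "R")) {
      lm <- traj$landmarks[[side]][i, , ]
      posed <- pose_foot(feet[[side]],
                         register_foot(feet[[side]], lm["FM", ], lm["VM", ],
                                       lm["CA", ]))
      for (s in seq_along(segs)) {
        comp <- shadow
        keep <- seq_along(segs) == s
        comp$mu <- shadow$mu[keep, , drop = FALSE]
        comp$c <- shadow$c[keep]; comp$det <- shadow$det[keep]
        comp$inv11 <- shadow$inv11[keep]; comp$inv12 <- shadow$inv12[keep]
        comp$inv22 <- shadow$inv22[keep]; comp$segments <- segs[keep]
        share[s] <- share[s] +
          integrate_region(evaluate_shadow(comp, posed$nodes), posed)
      }
    }
  }
  share / max(sum(share), 1e-300)
}

#' Fit the hyper-parameters to reference loads
#'
#' Bound-constrained minimisation of [fsm_energy()] over the per-segment
#' dispersions (and the hip ramp slope when the hip model is enabled),
#' with the integer prediction horizon handled by an outer grid search.
#' The energy is a sum of squared load residuals, so the continuous fit
#' uses bound-constrained Levenberg-Marquardt least squares
#' (`minpack.lm::nls.lm`) inside an outer loop enforcing the
#' step-tolerance stopping rule
#' \eqn{\|P_{k+1} - P_k\| < 10^{-8} (1 + \|P_k\|)}; the result is defined
#' by the energy, not by the solver brand. The fit is staged: first the
#' well-identified segments (high shadow-mass share) alone, with the
#' remainder frozen at their initial values, then a joint refinement —
#' a warm start that avoids the flat valleys a joint fit from a distant
#' initial point tends to stall in. Segments whose
#' shadow mass over the feet is negligible (share below
#' `identify_threshold`) are ridge-regularised towards their initial
#' values, since their dispersions are unidentifiable from the loads.
#'
#' @inheritParams fsm_energy
#' @param init initial `fsm_params` (within bounds).
#' @param lower,upper dispersion bounds (m).
#' @param tbar_grid integer grid for the prediction horizon (frames); only
#'   used when `config$hip` is `TRUE`.
#' @param m_bounds bounds for the ramp slope (1/s).
#' @param identify_threshold shadow-mass share below which a segment's
#'   dispersions are regularised towards `init` (ridge 1e-6).
#' @param step_tol step-tolerance of the stopping rule.
#' @param max_outer maximum outer iterations per grid point.
#' @param maxit_inner L-BFGS-B iteration cap per outer iteration.
#' @return list of class `fsm_fit`: `params` (best `fsm_params`),
#'   `energy`, `energy_init`, `log` (data frame of accepted energies),
#'   `stopping` (reason), `tbar_grid_energies`.
#' @export
fit_hyperparameters <- function(traj, body, feet, reference, init,
                                config = fsm_config(),
                                lower = 1e-3, upper = 1,
                                tbar_grid = seq(0L, 60L, by = 10L),
                                m_bounds = c(0, 20),
                                identify_threshold = 0.05,
                                step_tol = 1e-8, max_outer = 25,
                                maxit_inner = 40) {
  with_m <- isTRUE(config$hip)
  if (any(init$dispersion < lower) || any(init$dispersion > upper))
    .stopf("init dispersions outside bounds")
  e_init <- fsm_energy(init, traj, body, feet, reference, config)
  if (!is.finite(e_init)) .stopf("non-finite energy at init")
  share <- .shadow_mass_share(traj, body, feet, init, config)
  reg_seg <- share < identify_threshold
  th_init <- .pack_params(init, with_m)
  reg_w <- rep(rep(1e-6 * as.numeric(reg_seg), each = 2), 1)
  if (with_m) reg_w <- c(reg_w, 0)
  lo <- rep(lower, 2 * nrow(init$dispersion))
  hi <- rep(upper, 2 * nrow(init$dispersion))
  if (with_m) { lo <- c(lo, m_bounds[1]); hi <- c(hi, m_bounds[2]) }
  if (!with_m) tbar_grid <- init$tbar
  grid_energies <- stats::setNames(numeric(0), character(0))
  best <- NULL
  logs <- list()
  cache <- if (!with_m) .calib_cache(traj, body, feet, config) else NULL
  for (tb in tbar_grid) {
    template <- init; template$tbar <- as.integer(tb)
    resid_fn <- function(theta) {
      p <- .unpack_params(theta, template, with_m)
      r <- if (is.null(cache))
        .residuals_full(p, traj, body, feet, reference, config)
      else .residuals_cached(p, cache, reference)
      c(r, sqrt(reg_w) * (theta - th_init))
    }
    obj <- function(theta) sum(resid_fn(theta)^2)
    theta <- th_init
    e_prev <- obj(theta)
    accepted <- data.frame(outer = 0L, tbar = tb, energy = e_prev)
    stopping <- "max_outer"
    # stage 1: fit the identifiable (high shadow-mass) segments with the
    # weakly identified ones frozen at init; a joint fit from a distant
    # start tends to stall in flat valleys that this warm start avoids
    free <- rep(!reg_seg, each = 2)
    if (with_m) free <- c(free, TRUE)
    if (any(free) && any(!free)) {
      sub_fn <- function(sub) {
        th <- theta; th[free] <- sub
        resid_fn(th)
      }
      r0 <- minpack.lm::nls.lm(
        par = theta[free], lower = lo[free], upper = hi[free], fn = sub_fn,
        control = minpack.lm::nls.lm.control(maxiter = maxit_inner,
                                             ftol = 1e-15, ptol = 1e-15))
      if (r0$deviance <= e_prev) {
        theta[free] <- r0$par
        e_prev <- r0$deviance
        accepted <- rbind(accepted,
                          data.frame(outer = 0L, tbar = tb, energy = e_prev))
      }
    }
    # stage 2: full refinement under the step-tolerance rule
    for (it in seq_len(max_outer)) {
      res <- minpack.lm::nls.lm(
        par = theta, lower = lo, upper = hi, fn = resid_fn,
        control = minpack.lm::nls.lm.control(maxiter = maxit_inner,
                                             ftol = 1e-15, ptol = 1e-15))
      step <- sqrt(sum((res$par - theta)^2))
      improved <- res$deviance <= e_prev + 1e-15
      if (improved) {
        theta <- res$par
        e_prev <- res$deviance
        accepted <- rbind(accepted,
                          data.frame(outer = it, tbar = tb, energy = e_prev))
      }
      if (step < step_tol * (1 + sqrt(sum(theta^2)))) {
        stopping <- "step_tolerance"
        break
      }
      if (!improved) { stopping <- "no_improvement"; break }
    }
    grid_energies[as.character(tb)] <- e_prev
    logs[[as.character(tb)]] <- accepted
    if (is.null(best) || e_prev < best$energy)
      best <- list(theta = theta, energy = e_prev, tbar = tb,
                   stopping = stopping)
  }
  params <- .unpack_params(best$theta, init, with_m)
  params$tbar <- as.integer(best$tbar)
  structure(list(params = params, energy = best$energy,
                 energy_init = e_init,
                 log = do.call(rbind, logs), stopping = best$stopping,
                 tbar_grid_energies = grid_energies,
                 regularised_segments = names(share)[reg_seg],
                 shadow_mass_share = share),
            class = "fsm_fit")
}

#' @export
print.fsm_fit <- function(x, ...) {
  cat(sprintf("Hyper-parameter fit: E %.4g -> %.4g (%s), tbar = %d\n",
              x$energy_init, x$energy, x$stopping, x$params$tbar))
  invisible(x)
}
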