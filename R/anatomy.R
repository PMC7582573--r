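#' Fit the foot-arch weight surface
#'
#' Fits the quadratic surface
#' \eqn{w(x, y) = a_0 + a_1 x + a_2 y + a_3 x y + a_4 x^2 + a_5 y^2}
#' in the foot-model frame so that \eqn{w = 1} at the three support
#' landmarks (both metatarsal heads and the calcaneus) and
#' \eqn{w = h_a / dist_{CP}} at the two midpoints between the front and
#' rear contact points (midpoint(FM, CA) and midpoint(VM, CA)), where
#' \eqn{dist_{CP} = \|p_{CA} - p_{VM}\|}. The parameter \eqn{h_a} models
#' the height of the cuboid bone above the ground (m); relative to the
#' support-point distance it sets how strongly the arch is unloaded
#' (\eqn{h_a/dist_{CP} < 1} down-weights the arch).
#'
#' Five interpolation constraints determine six coefficients; the
#' remaining freedom is resolved by shrinking towards the flat surface
#' \eqn{w \equiv 1} (ridge 1e-12), so that all-ones targets recover the
#' constant surface exactly.
#'
#' @param foot an `fsm_foot` (model frame).
#' @param h_a cuboid height above ground (m), in (0, `distCP`] for a
#'   down-weighting arch.
#' @return An object of class `fsm_arch`: coefficients `coef` (a0..a5),
#'   `h_a`, `distCP`, `w_mid` (the midpoint target), and the constraint
#'   matrix/targets used.
#' @export
fit_arch_surface <- function(foot, h_a = 0.035) {
  if (!is.finite(h_a) || h_a <= 0) .stopf("h_a must be positive")
  lm <- foot$landmarks
  distCP <- sqrt(sum((lm$CA - lm$VM)^2))
  w_mid <- h_a / distCP
  pts <- rbind(FM = lm$FM, VM = lm$VM, CA = lm$CA,
               midFM = (lm$FM + lm$CA) / 2, midVM = (lm$VM + lm$CA) / 2)
  b <- c(1, 1, 1, w_mid, w_mid)
  A <- cbind(1, pts[, 1], pts[, 2], pts[, 1] * pts[, 2],
             pts[, 1]^2, pts[, 2]^2)
  a_ref <- c(1, 0, 0, 0, 0, 0)
  s <- svd(A)
  if (min(s$d) < 1e-12 * max(s$d))
    .stopf("rank-deficient arch constraint system (constraints: %s)",
           paste(rownames(pts), collapse = ", "))
  cf <- a_ref + as.numeric(.pinv(A) %*% (b - A %*% a_ref))
  resid <- max(abs(A %*% cf - b))
  if (resid > 1e-9)
    .stopf("arch constraints not interpolated (max residual %.3g); %s",
           resid, paste(rownames(pts), collapse = ", "))
  structure(list(coef = cf, h_a = h_a, distCP = distCP, w_mid = w_mid,
                 constraints = list(A = A, b = b)),
            class = "fsm_arch")
}

#' Evaluate an arch weight surface
#'
#' @param arch an `fsm_arch`.
#' @param pts length-2 vector or `m x 2` matrix of model-frame points (m).
#'   The surface is fitted once in the model frame and transported to a
#'   posed foot through the registration transform (evaluate at
#'   \eqn{T^{-1} x}, i.e. simply at the model-frame nodes), so it deforms
#'   with the foot.
#' @return numeric vector of weights.
#' @export
eval_arch <- function(arch, pts) {
  one <- is.null(dim(pts))
  pts <- if (one) matrix(pts, 1, 2) else as.matrix(pts)
  cf <- arch$coef
  v <- cf[1] + cf[2] * pts[, 1] + cf[3] * pts[, 2] +
    cf[4] * pts[, 1] * pts[, 2] + cf[5] * pts[, 1]^2 + cf[6] * pts[, 2]^2
  if (one) v[1] else v
}

#' Conservation rescaling of a weight function
#'
#' Rescales raw weights w by the time-dependent scalar
#' \eqn{n_t = \int_\Omega f \, dx / \int_\Omega w f \, dx} over a foot's
#' active region so that the weighted integral of the shadow equals the
#' unweighted one (per-foot totals are untouched by the arch model). The
#' scalars differ between the left and right foot.
#'
#' @param fvals shadow values at the foot's mesh nodes.
#' @param wvals raw weight values at the same nodes.
#' @param foot an `fsm_foot` (posed).
#' @param triangles optional triangle selection (active regions).
#' @return list with `n` (the scalar) and `w_scaled` (`n * wvals`);
#'   `n = NA` and a `degenerate` flag if the weighted integral vanishes
#'   (no active area).
#' @export
conserve_rescale <- function(fvals, wvals, foot, triangles = NULL) {
  int_f <- integrate_region(fvals, foot, triangles)
  int_wf <- integrate_region(wvals * fvals, foot, triangles)
  if (!is.finite(int_wf) || int_wf <= 0)
    return(list(n = NA_real_, w_scaled = NULL, degenerate = TRUE))
  n <- int_f / int_wf
  list(n = n, w_scaled = n * wvals, degenerate = FALSE)
}

#' Initialise the hip-flexion balance state
#'
#' The hip-flexion model emulates gradual unloading of one leg while the
#' centre of mass is balanced over the other foot: two scalars
#' \eqn{s_L, s_R \in [0,1]} (initialised at 1) are ramped up/down with
#' slope `m` (1/s, i.e. per-frame step `m * dt`) depending on where the
#' predicted CoM path lands.
#'
#' @param m ramp slope (1/s).
#' @param tbar prediction horizon in frames (integer >= 0).
#' @param dt frame interval (s).
#' @return An object of class `fsm_hip` with `s_L`, `s_R`, `m`, `tbar`,
#'   `dt`.
#' @export
hip_state <- function(m = 2, tbar = 30, dt = 1 / 60) {
  stopifnot(m >= 0, tbar >= 0, dt > 0)
  structure(list(s_L = 1, s_R = 1, m = m, tbar = as.integer(tbar), dt = dt),
            class = "fsm_hip")
}

#' One hip-flexion update step
#'
#' Predicts the planar CoM path \eqn{\tilde x_{t+k} = x + k \Delta t \dot x}
#' for \eqn{k = 0..\bar t} and applies the three-case ramp rule: if any
#' predicted point lies in the convex hull of the left foot (only),
#' \eqn{s_L} rises and \eqn{s_R} falls; mirrored for the right hull; if
#' the path stays in neither hull — or reaches both, treated as the
#' neutral case — both rise. Steps are `m * dt`, clamped to `[0, 1]`.
#' The returned modifiers \eqn{s_L + (1 - s_R)} and \eqn{s_R + (1 - s_L)}
#' multiply the left/right weight surfaces.
#'
#' @param state an `fsm_hip`.
#' @param com_xy planar CoM position (m).
#' @param comvel_xy planar CoM velocity (m/s).
#' @param hull_L,hull_R convex hulls of the posed feet (`k x 2` matrices).
#' @return updated `fsm_hip`, with elements `mod_L`, `mod_R` (the weight
#'   modifiers) and `case` (`"left"`, `"right"` or `"neutral"`).
#' @export
hip_flexion_update <- function(state, com_xy, comvel_xy, hull_L, hull_R) {
  k <- 0:state$tbar
  pred <- cbind(com_xy[1] + k * state$dt * comvel_xy[1],
                com_xy[2] + k * state$dt * comvel_xy[2])
  in_l <- any(hull_contains(hull_L, pred))
  in_r <- any(hull_contains(hull_R, pred))
  step <- state$m * state$dt
  if (in_l && !in_r) {
    state$s_L <- min(1, state$s_L + step)
    state$s_R <- max(0, state$s_R - step)
    state$case <- "left"
  } else if (in_r && !in_l) {
    state$s_R <- min(1, state$s_R + step)
    state$s_L <- max(0, state$s_L - step)
    state$case <- "right"
  } else {
    state$s_L <- min(1, state$s_L + step)
    state$s_R <- min(1, state$s_R + step)
    state$case <- "neutral"
  }
  state$mod_L <- state$s_L + (1 - state$s_R)
  state$mod_R <- state$s_R + (1 - state$s_L)
  state
}

#' Distribute the vertical GRF over foot regions
#'
#' The load on region \eqn{\Omega_k} is
#' \deqn{L_{\Omega_k} = F_{GRF,z}
#'   \frac{\int_{\Omega_k} \hat w f \, dx}
#'        {\int_{\Omega_L} \hat w_L f \, dx +
#'         \int_{\Omega_R} \hat w_R f \, dx},}
#' where f is the shadow field and \eqn{\hat w} the (conservation-rescaled,
#' hip-modified) weight surface; integrals run over in-contact regions
#' only, and regions without contact carry zero load. With the arch
#' disabled (\eqn{w \equiv 1}) and the hip model disabled
#' (\eqn{s_L = s_R = 1}) this reduces to plain integration and
#' normalisation of the shadow itself.
#'
#' @param f_z vertical GRF (N).
#' @param shadow an `fsm_shadow`.
#' @param feet list with posed `fsm_foot` elements `L` and `R`.
#' @param contacts list `L`/`R` of logical vectors over [foot_regions()].
#' @param arch_w optional list `L`/`R` of raw arch weights at the feet's
#'   mesh nodes (`NULL` disables the arch model).
#' @param hip_mod optional list `L`/`R` of hip modifiers (default both 1).
#' @return An object of class `fsm_loads`: data frame with columns `side`,
#'   `region`, `L` (N), `I` (distribution factor), plus attributes
#'   `F_z`, `any_contact`, `n_t` (the per-foot conservation scalars).
#' @export
distribute_load <- function(f_z, shadow, feet, contacts, arch_w = NULL,
                            hip_mod = NULL) {
  core <- .frame_loads(f_z, shadow, feet, contacts, arch_w, hip_mod)
  regs <- foot_regions()
  out <- data.frame(side = rep(c("L", "R"), each = length(regs)),
                    region = rep(regs, 2),
                    I = c(core$I["L", ], core$I["R", ]))
  out$L <- f_z * out$I
  structure(out, class = c("fsm_loads", "data.frame"),
            F_z = f_z, any_contact = core$any_contact, n_t = core$n_t)
}

# matrix-level frame distribution (hot path, no data.frame overhead)
.frame_loads <- function(f_z, shadow, feet, contacts, arch_w = NULL,
                         hip_mod = NULL) {
  if (is.null(hip_mod)) hip_mod <- list(L = 1, R = 1)
  regs <- foot_regions()
  num <- matrix(0, 2, length(regs), dimnames = list(c("L", "R"), regs))
  n_t <- c(L = NA_real_, R = NA_real_)
  for (side in c("L", "R")) {
    foot <- feet[[side]]
    ct <- contacts[[side]]
    if (!any(ct)) next
    active_tri <- ct[as.integer(foot$region)]
    if (!any(active_tri)) next
    fvals <- evaluate_shadow(shadow, foot$nodes)
    wf0 <- if (is.null(arch_w)) fvals else arch_w[[side]] * fvals
    tri <- foot$tri
    fbar <- (fvals[tri[, 1]] + fvals[tri[, 2]] + fvals[tri[, 3]]) / 3
    wbar <- (wf0[tri[, 1]] + wf0[tri[, 2]] + wf0[tri[, 3]]) / 3
    int_f <- sum(fbar[active_tri] * foot$areas[active_tri])
    int_wf <- sum(wbar[active_tri] * foot$areas[active_tri])
    if (!is.finite(int_wf) || int_wf <= 0) next
    n_t[side] <- int_f / int_wf
    scale <- n_t[side] * hip_mod[[side]]
    tri_int <- wbar * foot$areas * active_tri * scale
    sums <- rowsum(tri_int, foot$region)
    num[side, rownames(sums)] <- sums[, 1]
  }
  denom <- sum(num)
  any_contact <- any(unlist(contacts))
  if (!any_contact) {
    I <- num * 0
  } else {
    if (denom < 1e-12)
      .stopf("degenerate shadow mass: denominator %.3g with contacts present",
             denom)
    I <- num / denom
  }
  list(I = I, L = f_z * I, n_t = n_t, any_contact = any_contact)
}
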