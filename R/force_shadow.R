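#' Project a point onto the ground along the GRF vector
#'
#' A segment CoM at height z is carried along the (reversed) ground
#' reaction force direction until it meets the ground plane z = 0:
#' \eqn{\mu = x - k F} with \eqn{k = (x^T n)/(F^T n)}, \eqn{n = [0,0,1]^T},
#' so the projected point has zero vertical component. With a purely
#' vertical GRF this simply drops the z coordinate; horizontal force
#' components shear the projection sideways.
#'
#' @param x length-3 vector or `n x 3` matrix of points (m).
#' @param f_grf length-3 GRF vector (N).
#' @param eps_f floor on the vertical force component (N); below it the
#'   projection direction is near-horizontal and undefined.
#' @return length-2 vector or `n x 2` matrix of ground-plane coordinates.
#' @examples
#' project_to_ground(c(0, 0, 1), c(80, 0, 800))  # (-0.1, 0)
#' @export
project_to_ground <- function(x, f_grf, eps_f = 1) {
  if (abs(f_grf[3]) < eps_f)
    .stopf("near-horizontal GRF (|F_z| = %.3g N < %.3g N), projection undefined",
           abs(f_grf[3]), eps_f)
  one <- is.null(dim(x))
  x <- if (one) matrix(x, 1, 3) else as.matrix(x)
  k <- x[, 3] / f_grf[3]
  mu <- cbind(x[, 1] - k * f_grf[1], x[, 2] - k * f_grf[2])
  if (one) as.numeric(mu) else mu
}

#' Elliptical covariance for a shadow component
#'
#' Builds the 2x2 covariance whose principal axes follow the segment's
#' planar heading: \eqn{\Sigma = C^T C} with
#' \eqn{C = \mathrm{diag}(a, b) R^T}, i.e.
#' \eqn{\Sigma = R\,\mathrm{diag}(a^2, b^2)\,R^T} — symmetric positive
#' definite by construction with \eqn{\det\Sigma = a^2 b^2}. The
#' `"spectral"` variant additionally divides by the spectral norm
#' \eqn{\|C\|_2 = \max(a, b)}; any such global rescaling cancels in the
#' normalised load-distribution factors, so the default keeps the plain
#' product.
#'
#' @param a,b dispersion along the major/minor segment axis (m), positive.
#' @param heading planar heading angle (rad).
#' @param norm `"ctc"` (default) or `"spectral"`.
#' @return 2x2 covariance matrix (m^2).
#' @export
segment_covariance <- function(a, b, heading, norm = c("ctc", "spectral")) {
  norm <- match.arg(norm)
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    .stopf("dispersion parameters must be positive (got a=%.3g, b=%.3g)", a, b)
  R <- .rot2(heading)
  sig <- R %*% diag(c(a^2, b^2)) %*% t(R)
  sig <- (sig + t(sig)) / 2
  if (norm == "spectral") sig <- sig / max(a, b)
  sig
}

#' Build the force-shadow field for one frame
#'
#' Each segment contributes one bivariate Gaussian centred at its CoM
#' projected along the GRF onto the ground, with covariance oriented by the
#' segment heading and peak value equal to the segment's mass fraction
#' \eqn{d_s} (scale \eqn{c_s = d_s / N(\mu;\mu,\Sigma)}, the default
#' `peak_scale = "divide"`). The shadow function is the superposition of
#' all components. The `"multiply"` variant uses the literal product
#' \eqn{c_s = d_s N(\mu;\mu,\Sigma)} instead.
#'
#' Segments whose heading is `NA` (degenerate, near-vertical longitudinal
#' axis) fall back to an isotropic component with dispersion
#' \eqn{\min(a_s, b_s)}.
#'
#' @param seg_pos `S x 3` matrix of segment CoM positions (m), rownames the
#'   segment names.
#' @param heading length-S vector of heading angles (rad; `NA` allowed).
#' @param body an `fsm_body`.
#' @param f_grf length-3 GRF vector (N).
#' @param dispersion `S x 2` matrix of `(a_s, b_s)` (m), rownames matching
#'   segments.
#' @param peak_scale `"divide"` (default) or `"multiply"`.
#' @param sigma_norm passed to [segment_covariance()].
#' @param eps_f vertical-force floor (N) for the projection.
#' @return An object of class `fsm_shadow`: list with `mu` (`S x 2`),
#'   `sigma` (`S x 2 x 2`), `c` (length S), `d`, `segments`, plus cached
#'   inverse-covariance terms for fast evaluation.
#' @export
build_shadow <- function(seg_pos, heading, body, f_grf, dispersion,
                         peak_scale = c("divide", "multiply"),
                         sigma_norm = c("ctc", "spectral"), eps_f = 1) {
  peak_scale <- match.arg(peak_scale)
  sigma_norm <- match.arg(sigma_norm)
  segs <- body$segments
  seg_pos <- as.matrix(seg_pos)
  if (!is.null(rownames(seg_pos))) seg_pos <- seg_pos[segs, , drop = FALSE]
  if (!is.null(rownames(dispersion))) dispersion <- dispersion[segs, , drop = FALSE]
  S <- length(segs)
  mu <- project_to_ground(seg_pos, f_grf, eps_f = eps_f)
  a <- dispersion[, 1]; b <- dispersion[, 2]
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0))
    .stopf("dispersion parameters must be positive")
  # vectorised R diag(a^2,b^2) R^T; NA heading -> isotropic fallback
  iso <- is.na(heading)
  ch <- cos(ifelse(iso, 0, heading)); sh <- sin(ifelse(iso, 0, heading))
  a2 <- ifelse(iso, pmin(a, b)^2, a^2)
  b2 <- ifelse(iso, pmin(a, b)^2, b^2)
  s11 <- a2 * ch^2 + b2 * sh^2
  s22 <- a2 * sh^2 + b2 * ch^2
  s12 <- (a2 - b2) * ch * sh
  if (sigma_norm == "spectral") {
    nrm <- pmax(a, b)
    s11 <- s11 / nrm; s22 <- s22 / nrm; s12 <- s12 / nrm
  }
  sigma <- array(c(s11, s12, s12, s22), c(S, 2, 2))
  det_s <- sigma[, 1, 1] * sigma[, 2, 2] - sigma[, 1, 2]^2
  peak <- 1 / (2 * pi * sqrt(det_s))           # N(mu; mu, Sigma)
  cc <- if (peak_scale == "divide") body$d / peak else body$d * peak
  # cached inverse covariance entries
  inv11 <- sigma[, 2, 2] / det_s
  inv22 <- sigma[, 1, 1] / det_s
  inv12 <- -sigma[, 1, 2] / det_s
  structure(list(mu = mu, sigma = sigma, c = cc, d = body$d, segments = segs,
                 det = det_s, inv11 = inv11, inv12 = inv12, inv22 = inv22),
            class = "fsm_shadow")
}

#' Evaluate a shadow field at planar points
#'
#' Sum of all Gaussian components at each query point; strictly positive
#' everywhere (Gaussians have full support).
#'
#' @param field an `fsm_shadow` from [build_shadow()].
#' @param pts length-2 vector or `m x 2` matrix of ground-plane points (m).
#' @return numeric vector of field values.
#' @export
evaluate_shadow <- function(field, pts) {
  one <- is.null(dim(pts))
  pts <- if (one) matrix(pts, 1, 2) else as.matrix(pts)
  val <- numeric(nrow(pts))
  norm_c <- unname(field$c) / (2 * pi * sqrt(field$det))
  mu <- unname(field$mu)
  for (s in seq_along(field$segments)) {
    dx <- pts[, 1] - mu[s, 1]
    dy <- pts[, 2] - mu[s, 2]
    q <- field$inv11[s] * dx^2 + 2 * field$inv12[s] * dx * dy +
      field$inv22[s] * dy^2
    val <- val + norm_c[s] * exp(-0.5 * q)
  }
  val
}

#' @export
print.fsm_shadow <- function(x, ...) {
  cat(sprintf("Force shadow: %d components, peak sum %.4g\n",
              length(x$segments), sum(evaluate_shadow(x, x$mu))))
  invisible(x)
}
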