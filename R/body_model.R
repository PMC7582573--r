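#' Multi-segment body model
#'
#' A body model holds the segment set of a reduced rigid multi-body
#' representation of a person: segment names, their mass fractions
#' \eqn{d_s} (each segment's share of total body mass, from an
#' anthropometric proportion table), the subject's total mass and gravity.
#' Segment masses are \eqn{m_s = d_s m_{total}}.
#'
#' Mass fractions are renormalised to sum to one on construction, so tables
#' given in percent can be passed as-is.
#'
#' @param segments character vector of segment identifiers.
#' @param fractions numeric vector of mass fractions (same length/order as
#'   `segments`, or named); any positive scale, renormalised to sum to 1.
#' @param m_total total body mass in kg.
#' @param g gravitational acceleration in m/s^2.
#' @return An object of class `fsm_body` with elements `segments`, `d`
#'   (named, normalised fractions), `m` (named segment masses, kg),
#'   `m_total`, `g`.
#' @examples
#' body <- body_model(c("trunk", "legs"), c(60, 40), m_total = 80)
#' body$d
#' @export
body_model <- function(segments, fractions, m_total, g = 9.81) {
  segments <- as.character(segments)
  if (!is.null(names(fractions))) fractions <- fractions[segments]
  fractions <- as.numeric(fractions)
  if (length(fractions) != length(segments))
    .stopf("need one mass fraction per segment (%d segments, %d fractions)",
           length(segments), length(fractions))
  if (any(!is.finite(fractions)) || any(fractions <= 0))
    .stopf("all mass fractions must be positive and finite")
  if (!is.finite(m_total) || m_total <= 0) .stopf("m_total must be positive")
  d <- fractions / sum(fractions)
  names(d) <- segments
  structure(list(segments = segments, d = d, m = d * m_total,
                 m_total = m_total, g = g),
            class = "fsm_body")
}

#' Default reduced body model
#'
#' Nine-segment reduction (pelvis, trunk, lumped head+arms, left/right
#' thigh, shank and foot) with mass proportions aggregated from the de
#' Leva-style anthropometric table commonly used in inertial motion
#' capture: pelvis 11.17%, thorax+abdomen 32.29%, head plus both arms
#' 16.82%, each thigh 14.16%, each shank 4.33%, each foot 1.37%.
#'
#' @param m_total total body mass in kg.
#' @param g gravitational acceleration in m/s^2.
#' @return An `fsm_body`.
#' @export
default_body_model <- function(m_total = 80, g = 9.81) {
  fr <- c(pelvis = 0.1117, trunk = 0.3229, head_arms = 0.1682,
          thigh_L = 0.1416, thigh_R = 0.1416,
          shank_L = 0.0433, shank_R = 0.0433,
          foot_L = 0.0137, foot_R = 0.0137)
  body_model(names(fr), fr, m_total = m_total, g = g)
}

#' Read a body model from YAML
#'
#' Expected keys: `total_mass` (kg), optional `gravity` (m/s^2, default
#' 9.81), and `segments`, a mapping from segment name to mass fraction
#' (any positive scale; renormalised).
#'
#' @param path path to a YAML file.
#' @return An `fsm_body`.
#' @export
read_body_model <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$segments) || is.null(y$total_mass))
    .stopf("body model YAML needs 'segments' and 'total_mass'")
  fr <- unlist(y$segments)
  body_model(names(fr), fr, m_total = y$total_mass,
             g = if (is.null(y$gravity)) 9.81 else y$gravity)
}

#' @export
print.fsm_body <- function(x, ...) {
  cat(sprintf("Body model: %d segments, m_total = %.2f kg, g = %.3f m/s^2\n",
              length(x$segments), x$m_total, x$g))
  print(round(x$d, 4))
  invisible(x)
}

#' Whole-body centre of mass
#'
#' The body CoM is the mass-fraction-weighted sum of the segment CoMs,
#' \eqn{x_{CoM} = \sum_s m_s x_{CoM_s} / m_{total} = \sum_s d_s x_{CoM_s}}.
#'
#' @param body an `fsm_body`.
#' @param seg_pos numeric matrix of segment CoM positions, one row per
#'   segment (rownames are matched against `body$segments`), columns x, y, z
#'   in metres.
#' @return length-3 numeric vector, the whole-body CoM in metres.
#' @export
total_com <- function(body, seg_pos) {
  seg_pos <- as.matrix(seg_pos)
  if (!is.null(rownames(seg_pos))) {
    missing <- setdiff(body$segments, rownames(seg_pos))
    if (length(missing))
      .stopf("missing segment position(s): %s", paste(missing, collapse = ", "))
    seg_pos <- seg_pos[body$segments, , drop = FALSE]
  } else if (nrow(seg_pos) != length(body$segments)) {
    .stopf("seg_pos has %d rows but the body has %d segments",
           nrow(seg_pos), length(body$segments))
  }
  if (any(!is.finite(seg_pos))) .stopf("non-finite segment position")
  as.numeric(crossprod(seg_pos, body$d))
}

#' Numerical CoM derivatives along a trajectory
#'
#' Fills velocity and acceleration of the whole-body CoM by finite
#' differences on a uniformly sampled position series: second-order central
#' differences at interior samples, one-sided differences at the two ends.
#' This is an offline utility; the streaming pipeline ([run_fsm()]) uses
#' causal (backward) differences when derivatives are not supplied, so that
#' no future frame is ever read.
#'
#' @param time numeric vector of sample times (s), strictly increasing,
#'   uniform spacing within `tol`.
#' @param pos numeric matrix, one row per frame (any number of columns).
#' @param tol tolerance on sampling-interval uniformity (s).
#' @return list with `vel` and `acc`, matrices shaped like `pos`.
#' @export
com_derivatives <- function(time, pos, tol = 1e-6) {
  pos <- as.matrix(pos)
  n <- length(time)
  if (n < 3) .stopf("need at least 3 frames for derivatives, got %d", n)
  if (nrow(pos) != n) .stopf("time and pos disagree on frame count")
  dt <- diff(time)
  if (any(dt <= 0)) .stopf("time must be strictly increasing")
  if (max(dt) - min(dt) > tol)
    .stopf("non-uniform sampling: dt varies by %.3g s (tol %.3g)",
           max(dt) - min(dt), tol)
  h <- mean(dt)
  vel <- pos; acc <- pos
  i <- 2:(n - 1)
  vel[i, ] <- (pos[i + 1, , drop = FALSE] - pos[i - 1, , drop = FALSE]) / (2 * h)
  acc[i, ] <- (pos[i + 1, , drop = FALSE] - 2 * pos[i, , drop = FALSE] +
                 pos[i - 1, , drop = FALSE]) / h^2
  vel[1, ] <- (pos[2, ] - pos[1, ]) / h
  vel[n, ] <- (pos[n, ] - pos[n - 1, ]) / h
  acc[1, ] <- (pos[3, ] - 2 * pos[2, ] + pos[1, ]) / h^2
  acc[n, ] <- (pos[n, ] - 2 * pos[n - 1, ] + pos[n - 2, ]) / h^2
  list(vel = vel, acc = acc)
}

# Causal second-order backward differences (online pipeline).  Row k uses
# rows <= k only; the first rows fall back to lower order / zero.
.causal_derivatives <- function(pos, h) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  vel <- matrix(0, n, ncol(pos))
  acc <- matrix(0, n, ncol(pos))
  if (n >= 2) {
    vel[2, ] <- (pos[2, ] - pos[1, ]) / h
  }
  if (n >= 3) {
    i <- 3:n
    vel[i, ] <- (3 * pos[i, , drop = FALSE] - 4 * pos[i - 1, , drop = FALSE] +
                   pos[i - 2, , drop = FALSE]) / (2 * h)
    acc[i, ] <- (pos[i, , drop = FALSE] - 2 * pos[i - 1, , drop = FALSE] +
                   pos[i - 2, , drop = FALSE]) / h^2
  }
  list(vel = vel, acc = acc)
}

#' Ground reaction force from CoM acceleration
#'
#' Newton's laws give the total ground reaction force acting on the body as
#' \eqn{F_{GRF} = m_{total}(\ddot x_{CoM} + [0,0,g]^T)} under the
#' assumption that the feet are the only contact with the environment. The
#' alternative sign convention `"as_printed"` flips the inertial term,
#' \eqn{F = m_{total}([0,0,g]^T - \ddot x_{CoM})}; both coincide in the
#' static case \eqn{F_z = m_{total} g}.
#'
#' @param body an `fsm_body`.
#' @param acc CoM acceleration, length-3 vector or n x 3 matrix (m/s^2).
#' @param sign `"newton"` (default) or `"as_printed"`.
#' @return force in newtons, shaped like `acc`; the vertical component is
#'   the third column.
#' @examples
#' b <- default_body_model(m_total = 80)
#' ground_reaction_force(b, c(0, 0, 0))  # static: (0, 0, 784.8)
#' @export
ground_reaction_force <- function(body, acc, sign = c("newton", "as_printed")) {
  sign <- match.arg(sign)
  one <- is.null(dim(acc))
  acc <- if (one) matrix(acc, 1, 3) else as.matrix(acc)
  if (ncol(acc) != 3) .stopf("acceleration must have 3 components")
  if (any(!is.finite(acc))) .stopf("non-finite CoM acceleration")
  gvec <- matrix(rep(c(0, 0, body$g), each = nrow(acc)), ncol = 3)
  f <- if (sign == "newton") body$m_total * (acc + gvec)
       else body$m_total * (gvec - acc)
  if (one) as.numeric(f) else f
}
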