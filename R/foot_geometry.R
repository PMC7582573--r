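#' Triangulated 2D foot model
#'
#' Builds a parametric planar foot outline (heel at x = 0, toes at
#' x = `length`), triangulated by a structured station/cross-line mesh and
#' partitioned into six anatomical subregions by fraction of foot length:
#' Heel, Arch, Metatarsum and Toes, with the latter two split into medial
#' and lateral halves (`MetaMed`, `MetaLat`, `ToesMed`, `ToesLat`). The
#' three registration landmarks are the first metatarsal head (`FM`,
#' medial forefoot), fifth metatarsal head (`VM`, lateral forefoot) and
#' calcaneus (`CA`, heel centre). For the left foot the medial side is
#' y < 0 in the model frame (feet are placed with the left foot at
#' positive world y); the right model is its mirror image.
#'
#' @param side `"left"` or `"right"`.
#' @param foot_length foot length (m).
#' @param foot_width maximal foot width (m).
#' @param max_edge target mesh edge length (m).
#' @param region_fractions length-4 numeric, fractions of foot length for
#'   heel/arch/metatarsum/toes; must sum to 1.
#' @return An object of class `fsm_foot`: node table (`N x 2`), triangle
#'   index matrix (`M x 3`), per-triangle region factor, landmark list,
#'   per-triangle model-frame areas, convex hull (ccw vertex matrix), and
#'   per-region length fractions used for contact interpolation.
#' @export
foot_model <- function(side = c("left", "right"), foot_length = 0.26,
                       foot_width = 0.10, max_edge = 0.015,
                       region_fractions = c(heel = 0.30, arch = 0.25,
                                            meta = 0.25, toes = 0.20)) {
  side <- match.arg(side)
  stopifnot(foot_length > 0, foot_width > 0, max_edge > 0)
  if (abs(sum(region_fractions) - 1) > 1e-9)
    .stopf("region_fractions must sum to 1")
  L <- foot_length; W <- foot_width
  # half-width profile of the outline (fractions of W/2) along u in [0,1]
  u_ctrl <- c(0.00, 0.10, 0.30, 0.45, 0.62, 0.75, 0.88, 1.00)
  w_ctrl <- c(0.55, 0.72, 0.68, 0.60, 0.90, 1.00, 0.92, 0.62)
  half_w <- function(u) (W / 2) * stats::spline(u_ctrl, w_ctrl, xout = u)$y
  nL <- max(8L, ceiling(L / max_edge)) + 1L
  nW <- max(4L, ceiling(W / max_edge)) + 1L
  u <- seq(0, 1, length.out = nL)
  hw <- pmax(half_w(u), 0.12 * W / 2)
  nodes <- matrix(NA_real_, nL * nW, 2)
  for (i in seq_len(nL)) {
    ys <- seq(-hw[i], hw[i], length.out = nW)
    nodes[(i - 1L) * nW + seq_len(nW), ] <- cbind(u[i] * L, ys)
  }
  idx <- function(i, j) (i - 1L) * nW + j
  tri <- matrix(0L, 2L * (nL - 1L) * (nW - 1L), 3)
  r <- 0L
  for (i in seq_len(nL - 1L)) for (j in seq_len(nW - 1L)) {
    tri[r + 1L, ] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
    tri[r + 2L, ] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    r <- r + 2L
  }
  medial_sign <- if (side == "left") -1 else 1
  if (side == "right") nodes[, 2] <- -nodes[, 2]
  areas <- .tri_areas(nodes, tri)
  if (any(areas <= 1e-10)) .stopf("degenerate triangle in foot mesh")
  # region partition by triangle centroid
  cx <- (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3
  cy <- (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3
  uf <- cx / L
  cuts <- cumsum(region_fractions)
  band <- findInterval(uf, c(cuts[1], cuts[2], cuts[3]), left.open = FALSE) + 1L
  med <- (cy * medial_sign) > 0
  region <- character(length(uf))
  region[band == 1L] <- "Heel"
  region[band == 2L] <- "Arch"
  region[band == 3L] <- ifelse(med[band == 3L], "MetaMed", "MetaLat")
  region[band == 4L] <- ifelse(med[band == 4L], "ToesMed", "ToesLat")
  region <- factor(region, levels = foot_regions())
  landmarks <- list(
    FM = c(0.72 * L, medial_sign * 0.62 * W / 2),
    VM = c(0.68 * L, -medial_sign * 0.70 * W / 2),
    CA = c(0.06 * L, 0))
  hull_idx <- grDevices::chull(nodes)
  hull <- nodes[hull_idx, , drop = FALSE]
  # per-region centroid length fraction (for heel/toe contact interpolation)
  reg_frac <- vapply(foot_regions(), function(rg) {
    sel <- region == rg
    sum(cx[sel] * areas[sel]) / sum(areas[sel]) / L
  }, numeric(1))
  structure(list(side = side, nodes = nodes, tri = tri, region = region,
                 landmarks = landmarks, areas = areas, hull = hull,
                 foot_length = L, foot_width = W,
                 region_length_fraction = reg_frac),
            class = "fsm_foot")
}

#' Names of the six foot subregions
#' @return character vector of region names, heel to toes.
#' @export
foot_regions <- function() c("Heel", "Arch", "MetaMed", "MetaLat",
                             "ToesMed", "ToesLat")

#' @export
print.fsm_foot <- function(x, ...) {
  cat(sprintf("%s foot model: %d nodes, %d triangles, area %.4g m^2\n",
              x$side, nrow(x$nodes), nrow(x$tri), sum(x$areas)))
  print(table(x$region))
  invisible(x)
}

#' Write / read a foot model as JSON
#' @param foot an `fsm_foot`.
#' @param path file path.
#' @return `write_foot_model` returns `path` invisibly; `read_foot_model`
#'   an `fsm_foot`.
#' @export
write_foot_model <- function(foot, path) {
  obj <- list(side = foot$side, nodes = foot$nodes, tri = foot$tri,
              region = as.character(foot$region), landmarks = foot$landmarks,
              foot_length = foot$foot_length, foot_width = foot$foot_width)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_foot_model
#' @export
read_foot_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- matrix(as.numeric(o$nodes), ncol = 2)
  tri <- matrix(as.integer(o$tri), ncol = 3)
  areas <- .tri_areas(nodes, tri)
  region <- factor(o$region, levels = foot_regions())
  L <- o$foot_length
  cx <- (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3
  reg_frac <- vapply(foot_regions(), function(rg) {
    sel <- region == rg
    sum(cx[sel] * areas[sel]) / sum(areas[sel]) / L
  }, numeric(1))
  structure(list(side = o$side, nodes = nodes, tri = tri, region = region,
                 landmarks = lapply(o$landmarks, as.numeric), areas = areas,
                 hull = nodes[grDevices::chull(nodes), , drop = FALSE],
                 foot_length = L, foot_width = o$foot_width,
                 region_length_fraction = reg_frac),
            class = "fsm_foot")
}

# landmark triple as 2x3 matrix (columns FM, VM, CA)
.lm_matrix <- function(lm) cbind(FM = lm$FM, VM = lm$VM, CA = lm$CA)

.collinear <- function(p, tol = 1e-8) {
  abs(.tri_signed_area(p[, 1], p[, 2], p[, 3])) < tol
}

#' Register the foot model to a kinematic pose
#'
#' Finds the affine transform T (2x2 matrix M plus translation t, in
#' homogeneous form) minimising \eqn{E(T) = \|T P - X\|^2} over the three
#' landmark correspondences model -> pose, solved in closed form via the
#' pseudo-inverse. With three non-collinear correspondences the fit is
#' exact.
#'
#' @param foot an `fsm_foot` (or a list with `landmarks`).
#' @param x_fm,x_vm,x_ca length-2 pose landmark coordinates (m).
#' @return An object of class `fsm_transform`: `M` (2x2), `t` (length 2),
#'   `T` (3x3 homogeneous), and residual `E` (m^2).
#' @export
register_foot <- function(foot, x_fm, x_vm, x_ca) {
  P2 <- .lm_matrix(foot$landmarks)
  X2 <- cbind(x_fm, x_vm, x_ca)
  if (.collinear(P2) || .collinear(X2))
    .stopf("degenerate landmark configuration (collinear landmark triple)")
  P <- rbind(P2, 1)
  X <- rbind(X2, 1)
  Tm <- tryCatch(X %*% solve(P), error = function(e) X %*% .pinv(P))
  Tm[3, ] <- c(0, 0, 1)
  E <- sum((Tm %*% P - X)^2)
  M <- Tm[1:2, 1:2, drop = FALSE]
  dM <- det(M)
  if (abs(dM) < 1e-3) .stopf("degenerate registration (det M = %.3g)", dM)
  if (abs(dM) < 0.5 || abs(dM) > 2)
    warning(sprintf("implausible foot scaling in registration (|det M| = %.3g)",
                    abs(dM)), call. = FALSE)
  structure(list(M = M, t = Tm[1:2, 3], T = Tm, E = E),
            class = "fsm_transform")
}

#' Apply an affine transform to planar points
#' @param tf an `fsm_transform`.
#' @param pts length-2 vector or `m x 2` matrix.
#' @return transformed points, same shape.
#' @export
apply_transform <- function(tf, pts) {
  one <- is.null(dim(pts))
  pts <- if (one) matrix(pts, 1, 2) else as.matrix(pts)
  out <- pts %*% t(tf$M)
  out[, 1] <- out[, 1] + tf$t[1]
  out[, 2] <- out[, 2] + tf$t[2]
  if (one) as.numeric(out) else out
}

#' Pose a foot model with a registered transform
#'
#' Transforms all mesh nodes, landmarks and the convex hull; triangle
#' areas scale uniformly by `|det M|` under an affine map.
#'
#' @param foot an `fsm_foot`.
#' @param tf an `fsm_transform` from [register_foot()].
#' @return An `fsm_foot` with posed coordinates (and the transform attached
#'   as `$transform`).
#' @export
pose_foot <- function(foot, tf) {
  posed <- foot
  posed$nodes <- apply_transform(tf, foot$nodes)
  posed$landmarks <- lapply(foot$landmarks, function(p) apply_transform(tf, p))
  posed$areas <- foot$areas * abs(det(tf$M))
  posed$hull <- apply_transform(tf, foot$hull)
  posed$transform <- tf
  posed
}

#' Contact decision from height and speed thresholds
#'
#' A (sub-)region is in ground contact iff its registered centre is below
#' `h_min` above the ground AND slower than `v_min`; failing either
#' condition the region is assumed airborne and its load is set to zero
#' downstream. Defaults follow the usual kinematic contact heuristics
#' (h_min ~ 0.03 m, v_min ~ 0.8 m/s).
#'
#' @param height numeric vector of region centre heights (m).
#' @param speed numeric vector of region centre speeds (m/s).
#' @param h_min height threshold (m).
#' @param v_min speed threshold (m/s).
#' @return logical vector, `TRUE` where in contact.
#' @export
contact_state <- function(height, speed, h_min = 0.03, v_min = 0.8) {
  if (any(!is.finite(height)) || any(!is.finite(speed)))
    .stopf("non-finite height/speed in contact test")
  height < h_min & speed < v_min
}

# Per-triangle integrals of a nodal field by the chosen midpoint rule.
# fvals: values at nodes (vertex rule) -- or at triangle centroids
# (centroid rule, length M).
.tri_integrals <- function(fvals, tri, areas, rule = "vertex") {
  if (rule == "vertex") {
    fbar <- (fvals[tri[, 1]] + fvals[tri[, 2]] + fvals[tri[, 3]]) / 3
    fbar * areas
  } else {
    fvals * areas
  }
}

#' Integrate a field over (part of) a triangulated region
#'
#' Midpoint-rule quadrature: each triangle contributes its area times the
#' mean of the field at its three vertices (`rule = "vertex"`, the
#' default), or the field at its centroid (`rule = "centroid"`). The
#' vertex-average rule integrates affine functions exactly and is additive
#' over disjoint triangle sets.
#'
#' @param field function mapping an `m x 2` matrix to `m` values, or a
#'   precomputed numeric vector of node values (vertex rule only).
#' @param foot an `fsm_foot` (model or posed).
#' @param triangles optional integer/logical index of triangles to use
#'   (default: all). An empty selection integrates to 0.
#' @param rule `"vertex"` or `"centroid"`.
#' @return the quadrature value (scalar).
#' @export
integrate_region <- function(field, foot, triangles = NULL,
                             rule = c("vertex", "centroid")) {
  rule <- match.arg(rule)
  tri <- foot$tri; areas <- foot$areas
  if (!is.null(triangles)) {
    tri <- tri[triangles, , drop = FALSE]
    areas <- areas[triangles]
  }
  if (nrow(tri) == 0L) return(0)
  if (rule == "vertex") {
    fvals <- if (is.function(field)) field(foot$nodes) else field
    if (any(!is.finite(fvals[unique(as.vector(tri))])))
      .stopf("non-finite field value on region nodes")
    sum(.tri_integrals(fvals, tri, areas, "vertex"))
  } else {
    if (!is.function(field)) .stopf("centroid rule needs a callable field")
    cen <- (foot$nodes[tri[, 1], , drop = FALSE] +
              foot$nodes[tri[, 2], , drop = FALSE] +
              foot$nodes[tri[, 3], , drop = FALSE]) / 3
    sum(field(cen) * areas)
  }
}

#' Convex-hull point containment
#'
#' Tests whether points lie inside or on the boundary of a convex polygon
#' (boundary counts as inside, favouring contact/loading continuity).
#'
#' @param hull `k x 2` matrix of convex polygon vertices (any consistent
#'   winding; k >= 3).
#' @param pts length-2 vector or `m x 2` matrix.
#' @param tol boundary tolerance (m).
#' @return logical vector.
#' @export
hull_contains <- function(hull, pts, tol = 1e-12) {
  hull <- as.matrix(hull)
  if (nrow(hull) < 3) .stopf("hull needs at least 3 vertices")
  one <- is.null(dim(pts))
  pts <- if (one) matrix(pts, 1, 2) else as.matrix(pts)
  k <- nrow(hull)
  nxt <- c(2:k, 1)
  # winding sign from polygon signed area
  area2 <- sum(hull[, 1] * hull[nxt, 2] - hull[nxt, 1] * hull[, 2])
  sgn <- if (area2 >= 0) 1 else -1
  inside <- rep(TRUE, nrow(pts))
  for (e in seq_len(k)) {
    ex <- hull[nxt[e], 1] - hull[e, 1]
    ey <- hull[nxt[e], 2] - hull[e, 2]
    cr <- sgn * (ex * (pts[, 2] - hull[e, 2]) - ey * (pts[, 1] - hull[e, 1]))
    inside <- inside & (cr >= -tol)
  }
  inside
}

# assign planar points to the subregion whose triangle contains them
# (NA where no triangle does)
.assign_regions <- function(pts, foot, tol = 1e-12) {
  nodes <- foot$nodes; tri <- foot$tri
  reg <- rep(NA_character_, nrow(pts))
  for (k in seq_len(nrow(tri))) {
    p1 <- nodes[tri[k, 1], ]; p2 <- nodes[tri[k, 2], ]; p3 <- nodes[tri[k, 3], ]
    det <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2])
    if (abs(det) < 1e-14) next
    l1 <- ((p2[2] - p3[2]) * (pts[, 1] - p3[1]) +
             (p3[1] - p2[1]) * (pts[, 2] - p3[2])) / det
    l2 <- ((p3[2] - p1[2]) * (pts[, 1] - p3[1]) +
             (p1[1] - p3[1]) * (pts[, 2] - p3[2])) / det
    inside <- l1 >= -tol & l2 >= -tol & (1 - l1 - l2) >= -tol
    reg[inside & is.na(reg)] <- as.character(foot$region[k])
  }
  reg
}

# area-weighted centroids of each subregion (model or posed frame)
.region_centroids <- function(foot) {
  cx <- (foot$nodes[foot$tri[, 1], 1] + foot$nodes[foot$tri[, 2], 1] +
           foot$nodes[foot$tri[, 3], 1]) / 3
  cy <- (foot$nodes[foot$tri[, 1], 2] + foot$nodes[foot$tri[, 2], 2] +
           foot$nodes[foot$tri[, 3], 2]) / 3
  t(vapply(foot_regions(), function(rg) {
    sel <- foot$region == rg
    a <- foot$areas[sel]
    c(sum(cx[sel] * a), sum(cy[sel] * a)) / sum(a)
  }, numeric(2)))
}
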