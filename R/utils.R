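# Internal geometry and numeric helpers.

# Signed area of triangle (p1, p2, p3), each a length-2 vector.
.tri_signed_area <- function(p1, p2, p3) {
  0.5 * ((p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2]))
}

# Vectorised triangle areas from a node table and index matrix (M x 3).
.tri_areas <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  abs((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

# Quintic smoothstep: C^2 ramp from 0 at u=0 to 1 at u=1.
.smoothstep5 <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Moore-Penrose pseudo-inverse via SVD (small dense systems only).
.pinv <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# 2D rotation matrix.
.rot2 <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, -s, c), 2, 2)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
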