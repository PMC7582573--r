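# Shared fixtures, all built in code.

fix_body <- function(m_total = 80) default_body_model(m_total)

fix_feet <- function(max_edge = 0.02)
  list(L = foot_model("left", max_edge = max_edge),
       R = foot_model("right", max_edge = max_edge))

# quick noise-free motion
fix_motion <- function(kind = "sway_S2S", duration = 4, rate = 30,
                       noise_pos = 0, noise_lm = 0, ...,
                       body = fix_body(), feet = fix_feet()) {
  generate_motion(motion_spec(kind, duration = duration, rate = rate,
                              noise_pos = noise_pos, noise_lm = noise_lm,
                              ...),
                  body, feet)
}

# structured polar triangulation of a disk (for quadrature oracles);
# vectorised so fine meshes stay cheap to build
disk_mesh <- function(radius, max_edge, center = c(0, 0)) {
  nr <- max(3L, ceiling(radius / max_edge))
  ns <- max(8L, ceiling(2 * pi * radius / max_edge))
  rr <- rep(radius * seq_len(nr) / nr, each = ns)
  th <- rep(2 * pi * (seq_len(ns) - 1) / ns, nr)
  nodes <- rbind(center,
                 cbind(center[1] + rr * cos(th), center[2] + rr * sin(th)))
  idx <- function(i, j) 1L + (i - 1L) * ns + (j - 1L) %% ns + 1L
  j <- rep(seq_len(ns), nr - 1L)
  i <- rep(seq_len(nr - 1L), each = ns)
  tri <- rbind(
    cbind(1L, idx(1L, seq_len(ns)), idx(1L, seq_len(ns) + 1L)),
    cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
    cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  list(nodes = nodes, tri = tri, areas = forceshadow:::.tri_areas(nodes, tri))
}

# wrap a raw mesh as a minimal fsm_foot-like object for integrate_region
as_region <- function(mesh) {
  structure(list(nodes = mesh$nodes, tri = mesh$tri, areas = mesh$areas),
            class = "fsm_foot")
}

# Independent minimal reference implementation of plain shadow
# integration + normalisation (no arch, no hip, all regions in contact):
# per-component Gaussians and vertex-average quadrature written as
# explicit loops, sharing no code with the package internals.
oracle_loads_frame <- function(traj, i, body, feet, params) {
  f_grf <- body$m_total * (traj$com_acc[i, ] + c(0, 0, body$g))
  ints <- list()
  for (side in c("L", "R")) {
    ft <- feet[[side]]
    lm <- traj$landmarks[[side]][i, , ]
    P <- rbind(cbind(ft$landmarks$FM, ft$landmarks$VM, ft$landmarks$CA), 1)
    X <- rbind(t(lm), 1)
    Tm <- X %*% solve(P)
    nodes <- cbind(ft$nodes, 1) %*% t(Tm)
    fvals <- numeric(nrow(nodes))
    for (s in seq_along(body$segments)) {
      z <- traj$seg_com[i, s, 3]
      mu <- traj$seg_com[i, s, 1:2] - z / f_grf[3] * f_grf[1:2]
      th <- traj$heading[i, s]
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      sig <- R %*% diag(params$dispersion[s, ]^2) %*% t(R)
      si <- solve(sig)
      dx <- nodes[, 1] - mu[1]; dy <- nodes[, 2] - mu[2]
      q <- si[1, 1] * dx^2 + 2 * si[1, 2] * dx * dy + si[2, 2] * dy^2
      fvals <- fvals + body$d[s] * exp(-q / 2)
    }
    reg_int <- stats::setNames(numeric(6), foot_regions())
    detM <- det(Tm[1:2, 1:2])
    for (k in seq_len(nrow(ft$tri))) {
      v <- ft$tri[k, ]
      ar <- ft$areas[k] * abs(detM)
      rg <- as.character(ft$region[k])
      reg_int[rg] <- reg_int[rg] + mean(fvals[v]) * ar
    }
    ints[[side]] <- reg_int
  }
  denom <- sum(ints$L) + sum(ints$R)
  lapply(ints, function(v) f_grf[3] * v / denom)
}

# a random trajectory of independent frames with prescribed CoM acceleration
random_frames <- function(n, body, feet, seed = 1) {
  set.seed(seed)
  segs <- body$segments
  sc <- array(0, c(n, length(segs), 3), dimnames = list(NULL, segs, NULL))
  sc[, , 1] <- matrix(stats::runif(n * length(segs), -0.3, 0.3), n)
  sc[, , 2] <- matrix(stats::runif(n * length(segs), -0.3, 0.3), n)
  sc[, , 3] <- matrix(stats::runif(n * length(segs), 0.1, 1.6), n)
  heading <- matrix(stats::runif(n * length(segs), -pi, pi), n,
                    dimnames = list(NULL, segs))
  lmarr <- function(side) {
    ft <- feet[[side]]
    ty <- if (side == "L") 0.2 else -0.2
    a <- array(NA_real_, c(n, 3, 2),
               dimnames = list(NULL, c("FM", "VM", "CA"), c("x", "y")))
    for (i in seq_len(n)) {
      th <- stats::runif(1, -0.3, 0.3)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      tr <- c(stats::runif(1, -0.05, 0.05) - ft$foot_length / 2,
              ty + stats::runif(1, -0.03, 0.03))
      for (lm in c("FM", "VM", "CA"))
        a[i, lm, ] <- as.numeric(R %*% ft$landmarks[[lm]]) + tr
    }
    a
  }
  com <- cbind(stats::runif(n, -0.05, 0.05), stats::runif(n, -0.05, 0.05),
               stats::runif(n, 0.9, 1.1))
  acc <- cbind(stats::runif(n, -0.3, 0.3), stats::runif(n, -0.3, 0.3),
               stats::runif(n, -0.5, 0.5))
  fsm_trajectory(time = seq(0, by = 1 / 60, length.out = n),
                 seg_com = sc, heading = heading,
                 landmarks = list(L = lmarr("L"), R = lmarr("R")),
                 com = com, com_vel = matrix(0, n, 3), com_acc = acc)
}
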