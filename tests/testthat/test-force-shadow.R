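test_that("projection along the GRF lands on the ground plane", {
  expect_equal(project_to_ground(c(1, 2, 0.5), c(0, 0, 800)), c(1, 2))
  expect_equal(project_to_ground(c(0, 0, 0), c(50, -20, 700)), c(0, 0))
  # line-plane intersection: k = 1/800, mu = x - k F
  expect_equal(project_to_ground(c(0, 0, 1), c(80, 0, 800)), c(-0.1, 0))
  expect_error(project_to_ground(c(0, 0, 1), c(100, 0, 0.5)),
               "near-horizontal")
})

test_that("segment covariance has the prescribed spectrum and orientation", {
  expect_equal(segment_covariance(0.3, 0.3, 1.234), diag(2) * 0.09)
  expect_equal(segment_covariance(2, 1, 0), diag(c(4, 1)))
  # explicit matrix product: R(pi/2) diag(4,1) R(pi/2)^T = diag(1,4)
  expect_equal(segment_covariance(2, 1, pi / 2), diag(c(1, 4)),
               tolerance = 1e-12)
  set.seed(3)
  for (rep in 1:20) {
    a <- stats::runif(1, 0.01, 0.5); b <- stats::runif(1, 0.01, 0.5)
    th <- stats::runif(1, -pi, pi)
    sig <- segment_covariance(a, b, th)
    expect_equal(sig, t(sig))
    expect_gt(min(eigen(sig)$values), 0)
    expect_equal(det(sig), a^2 * b^2, tolerance = 1e-12)
  }
  expect_error(segment_covariance(-1, 1, 0), "positive")
})

test_that("shadow peaks equal mass fractions and superpose", {
  b1 <- body_model("a", 1, m_total = 80)
  sh <- build_shadow(matrix(c(0.1, 0.2, 0.9), 1, dimnames = list("a", NULL)),
                     0.3, b1, c(0, 0, 784.8),
                     matrix(c(0.2, 0.1), 1, dimnames = list("a", NULL)))
  expect_equal(evaluate_shadow(sh, sh$mu[1, ]), 1, tolerance = 1e-12)
  # two co-located components of d = 0.1 each plus filler mass elsewhere
  b2 <- body_model(c("a", "b", "c"), c(0.1, 0.1, 0.8), m_total = 80)
  pos <- rbind(a = c(0, 0, 1), b = c(0, 0, 1), c = c(50, 50, 1))
  disp <- rbind(a = c(0.2, 0.1), b = c(0.2, 0.1), c = c(0.2, 0.1))
  sh2 <- build_shadow(pos, c(0, 0, 0), b2, c(0, 0, 784.8), disp)
  expect_equal(evaluate_shadow(sh2, c(0, 0)), 0.2, tolerance = 1e-9)
})

test_that("one component integrates to d * 2*pi*sqrt(det Sigma)", {
  b <- body_model("a", 1, m_total = 80)
  a_s <- 0.05; b_s <- 0.03; th <- 0.7; d_s <- 1
  sh <- build_shadow(matrix(c(0, 0, 1), 1, dimnames = list("a", NULL)),
                     th, b, c(0, 0, 784.8),
                     matrix(c(a_s, b_s), 1, dimnames = list("a", NULL)))
  closed <- d_s * 2 * pi * sqrt(a_s^2 * b_s^2)
  # fine-grid quadrature cross-check of the Gaussian integral identity
  h <- 0.002
  gx <- seq(-0.4, 0.4, by = h)
  grid <- as.matrix(expand.grid(gx, gx))
  expect_equal(sum(evaluate_shadow(sh, grid)) * h^2, closed,
               tolerance = 1e-6 * closed)
})

test_that("evaluation matches a naive per-point double loop", {
  body <- fix_body()
  set.seed(11)
  pos <- cbind(stats::rnorm(9, 0, 0.2), stats::rnorm(9, 0, 0.2),
               stats::runif(9, 0.2, 1.5))
  rownames(pos) <- body$segments
  disp <- cbind(stats::runif(9, 0.05, 0.3), stats::runif(9, 0.03, 0.2))
  rownames(disp) <- body$segments
  heading <- stats::runif(9, -pi, pi)
  f_grf <- c(30, -10, 780)
  sh <- build_shadow(pos, heading, body, f_grf, disp)
  pts <- cbind(stats::rnorm(100, 0, 0.3), stats::rnorm(100, 0, 0.3))
  naive <- numeric(100)
  for (i in 1:100) for (s in 1:9) {
    k <- pos[s, 3] / f_grf[3]
    mu <- pos[s, 1:2] - k * f_grf[1:2]
    R <- matrix(c(cos(heading[s]), sin(heading[s]),
                  -sin(heading[s]), cos(heading[s])), 2)
    sig <- R %*% diag(c(disp[s, 1]^2, disp[s, 2]^2)) %*% t(R)
    dn <- exp(-0.5 * t(pts[i, ] - mu) %*% solve(sig) %*% (pts[i, ] - mu)) /
      (2 * pi * sqrt(det(sig)))
    peak <- 1 / (2 * pi * sqrt(det(sig)))
    naive[i] <- naive[i] + body$d[s] / peak * dn
  }
  expect_equal(evaluate_shadow(sh, pts), naive, tolerance = 1e-12)
  # far field decay and component-order invariance
  expect_lt(evaluate_shadow(sh, c(50, 50)), 1e-10)
  perm <- sample(9)
  sh_perm <- build_shadow(pos[perm, ], heading[perm],
                          body_model(body$segments[perm], body$d[perm],
                                     body$m_total),
                          f_grf, disp[perm, ])
  expect_equal(evaluate_shadow(sh_perm, pts), evaluate_shadow(sh, pts),
               tolerance = 1e-12)
})

test_that("shadow is equivariant under rigid in-plane motion", {
  body <- fix_body()
  set.seed(5)
  pos <- cbind(stats::rnorm(9, 0, 0.2), stats::rnorm(9, 0, 0.2),
               stats::runif(9, 0.2, 1.5))
  rownames(pos) <- body$segments
  disp <- default_fsm_params(body)$dispersion
  heading <- stats::runif(9, -pi, pi)
  f <- c(0, 0, 784.8)   # vertical GRF
  sh <- build_shadow(pos, heading, body, f, disp)
  th <- 0.83; tr <- c(0.4, -0.7)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  pos2 <- pos
  pos2[, 1:2] <- pos[, 1:2] %*% t(R) + rep(tr, each = 9)
  sh2 <- build_shadow(pos2, heading + th, body, f, disp)
  expect_equal(sh2$mu, sh$mu %*% t(R) + rep(tr, each = 9), tolerance = 1e-9)
  pts <- cbind(stats::rnorm(50, 0, 0.4), stats::rnorm(50, 0, 0.4))
  pts2 <- pts %*% t(R) + rep(tr, each = 50)
  expect_equal(evaluate_shadow(sh2, pts2), evaluate_shadow(sh, pts),
               tolerance = 1e-9)
})

test_that("vanishing dispersion concentrates mass in the containing region", {
  # two-region toy: unit-square halves, each triangulated as a fan around
  # an interior node where one near-delta component is centred; the load
  # split must tend to the projected mass split d_a : d_b
  fan <- function(cx) {
    corners <- rbind(c(cx - 0.5, -1), c(cx + 0.5, -1),
                     c(cx + 0.5, 1), c(cx - 0.5, 1))
    nodes <- rbind(corners, c(cx, 0))
    tri <- rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5))
    list(nodes = nodes, tri = tri)
  }
  fl <- fan(-0.5); fr <- fan(0.5)
  nodes <- rbind(fl$nodes, fr$nodes)
  tri <- rbind(fl$tri, fr$tri + nrow(fl$nodes))
  region <- as_region(list(nodes = nodes, tri = tri,
                           areas = forceshadow:::.tri_areas(nodes, tri)))
  b <- body_model(c("a", "b"), c(0.7, 0.3), m_total = 80)
  pos <- rbind(a = c(-0.5, 0, 1), b = c(0.5, 0, 1))
  disp <- rbind(a = c(1e-3, 1e-3), b = c(1e-3, 1e-3))
  sh <- build_shadow(pos, c(0, 0), b, c(0, 0, 784.8), disp)
  fvals <- evaluate_shadow(sh, nodes)
  left <- integrate_region(fvals, region, triangles = 1:4)
  right <- integrate_region(fvals, region, triangles = 5:8)
  expect_equal(left / (left + right), 0.7, tolerance = 1e-9)
})
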