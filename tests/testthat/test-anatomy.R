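test_that("arch surface interpolates its constraints", {
  ft <- foot_model("left")
  arch <- fit_arch_surface(ft, h_a = 0.035)
  lm <- ft$landmarks
  expect_equal(eval_arch(arch, lm$CA), 1, tolerance = 1e-9)
  expect_equal(eval_arch(arch, lm$FM), 1, tolerance = 1e-9)
  expect_equal(eval_arch(arch, lm$VM), 1, tolerance = 1e-9)
  expect_equal(eval_arch(arch, (lm$VM + lm$CA) / 2), arch$h_a / arch$distCP,
               tolerance = 1e-9)
  expect_equal(eval_arch(arch, (lm$FM + lm$CA) / 2), arch$h_a / arch$distCP,
               tolerance = 1e-9)
  # arch is down-weighted and the surface stays positive on the mesh
  expect_lt(arch$w_mid, 1)
  expect_gt(min(eval_arch(arch, ft$nodes)), 0)
})

test_that("all-ones targets recover the constant surface", {
  ft <- foot_model("right")
  # h_a = distCP makes every constraint target exactly 1
  arch <- fit_arch_surface(ft, h_a = sqrt(sum((ft$landmarks$CA -
                                                 ft$landmarks$VM)^2)))
  expect_equal(eval_arch(arch, ft$nodes), rep(1, nrow(ft$nodes)),
               tolerance = 1e-9)
})

test_that("conservation rescaling preserves the shadow integral", {
  ft <- foot_model("left", max_edge = 0.03)
  fvals <- exp(-rowSums(sweep(ft$nodes, 2, c(0.1, 0))^2) / 0.01)
  cr1 <- conserve_rescale(fvals, rep(1, nrow(ft$nodes)), ft)
  expect_equal(cr1$n, 1, tolerance = 1e-12)
  cr2 <- conserve_rescale(fvals, rep(2, nrow(ft$nodes)), ft)
  expect_equal(cr2$n, 0.5, tolerance = 1e-12)
  arch <- fit_arch_surface(ft)
  w <- eval_arch(arch, ft$nodes)
  cr3 <- conserve_rescale(fvals, w, ft)
  expect_equal(integrate_region(cr3$w_scaled * fvals, ft),
               integrate_region(fvals, ft), tolerance = 1e-9)
  # degenerate: zero weights flag the foot inactive
  cr4 <- conserve_rescale(fvals, rep(0, nrow(ft$nodes)), ft)
  expect_true(cr4$degenerate)
})

test_that("hip ramp follows the three-case rule with clamping", {
  hull_L <- rbind(c(0.1, 0.15), c(0.3, 0.15), c(0.3, 0.25), c(0.1, 0.25))
  hull_R <- hull_L; hull_R[, 2] <- -hull_R[, 2]
  st <- hip_state(m = 2, tbar = 0, dt = 0.025)   # step = 0.05
  # prediction in neither hull, both already at maximum: unchanged
  st1 <- hip_flexion_update(st, c(0, 0), c(0, 0), hull_L, hull_R)
  expect_equal(c(st1$s_L, st1$s_R), c(1, 1))
  expect_equal(st1$case, "neutral")
  expect_equal(c(st1$mod_L, st1$mod_R), c(1, 1))
  # ramp arithmetic: s_L=1, s_R=0.8, prediction inside the left hull
  st$s_L <- 1; st$s_R <- 0.8
  st2 <- hip_flexion_update(st, c(0.2, 0.2), c(0, 0), hull_L, hull_R)
  expect_equal(st2$case, "left")
  expect_equal(st2$s_R, 0.75)
  expect_equal(st2$mod_L, 1.25)
  expect_equal(st2$mod_R, 0.75)
  # saturation after enough one-sided frames: exactly clamped at 0
  st3 <- hip_state(m = 2, tbar = 0, dt = 0.025)
  for (i in 1:25) st3 <- hip_flexion_update(st3, c(0.2, 0.2), c(0, 0),
                                            hull_L, hull_R)
  expect_equal(st3$s_R, 0)
  expect_equal(st3$mod_L, 2)
  expect_equal(st3$mod_R, 0)
  # right-hull case mirrors
  st4 <- hip_flexion_update(hip_state(m = 2, tbar = 0, dt = 0.025),
                            c(0.2, -0.2), c(0, 0), hull_L, hull_R)
  expect_equal(st4$case, "right")
  # the prediction horizon looks ahead along the velocity
  st5 <- hip_flexion_update(hip_state(m = 2, tbar = 20, dt = 0.025),
                            c(0.2, 0), c(0, 0.5), hull_L, hull_R)
  expect_equal(st5$case, "left")
})

test_that("load distribution conserves the vertical GRF", {
  body <- fix_body()
  feet <- fix_feet()
  set.seed(13)
  traj <- random_frames(1, body, feet)
  f_grf <- c(0, 0, 780)
  sh <- build_shadow(traj$seg_com[1, , ], traj$heading[1, ], body, f_grf,
                     default_fsm_params(body)$dispersion)
  posed <- lapply(c(L = "L", R = "R"), function(side) {
    lm <- traj$landmarks[[side]][1, , ]
    pose_foot(feet[[side]],
              register_foot(feet[[side]], lm["FM", ], lm["VM", ], lm["CA", ]))
  })
  all6 <- rep(TRUE, 6)
  loads <- distribute_load(f_grf[3], sh, posed,
                           list(L = all6, R = all6))
  expect_equal(sum(loads$L), f_grf[3], tolerance = 1e-9 * f_grf[3])
  expect_equal(sum(loads$I), 1, tolerance = 1e-12)
  expect_true(all(loads$I >= 0 & loads$I <= 1))
  # left foot only in contact: left sums to F_z, right all zero
  loads_l <- distribute_load(f_grf[3], sh, posed,
                             list(L = all6, R = rep(FALSE, 6)))
  expect_equal(sum(loads_l$L[loads_l$side == "L"]), f_grf[3],
               tolerance = 1e-9 * f_grf[3])
  expect_true(all(loads_l$L[loads_l$side == "R"] == 0))
  # no contact anywhere: all-zero with flag
  loads_0 <- distribute_load(f_grf[3], sh, posed,
                             list(L = rep(FALSE, 6), R = rep(FALSE, 6)))
  expect_true(all(loads_0$L == 0))
  expect_false(attr(loads_0, "any_contact"))
})

test_that("mirror-symmetric bodies split the load exactly in half", {
  body <- fix_body()
  feet <- fix_feet()
  segs <- body$segments
  pos <- rbind(pelvis = c(0, 0, 1), trunk = c(0, 0, 1.3),
               head_arms = c(0, 0, 1.55),
               thigh_L = c(0, 0.1, 0.72), thigh_R = c(0, -0.1, 0.72),
               shank_L = c(0, 0.2, 0.35), shank_R = c(0, -0.2, 0.35),
               foot_L = c(0.03, 0.2, 0.03), foot_R = c(0.03, -0.2, 0.03))
  f_grf <- c(0, 0, body$m_total * body$g)
  sh <- build_shadow(pos[segs, ], rep(0, 9), body, f_grf,
                     default_fsm_params(body)$dispersion)
  posed <- lapply(c(L = "L", R = "R"), function(side) {
    ft <- feet[[side]]
    ty <- if (side == "L") 0.2 else -0.2
    lmx <- lapply(ft$landmarks, function(p)
      p + c(-ft$foot_length / 2, ty))
    pose_foot(ft, register_foot(ft, lmx$FM, lmx$VM, lmx$CA))
  })
  arch_w <- lapply(feet, function(ft)
    eval_arch(fit_arch_surface(ft), ft$nodes))
  loads <- distribute_load(f_grf[3], sh, posed,
                           list(L = rep(TRUE, 6), R = rep(TRUE, 6)),
                           arch_w = arch_w)
  IL <- sum(loads$I[loads$side == "L"])
  IR <- sum(loads$I[loads$side == "R"])
  expect_equal(IL, 0.5, tolerance = 1e-9)
  expect_equal(IR, 0.5, tolerance = 1e-9)
})

test_that("the arch weighting strictly unloads the arch region", {
  body <- fix_body()
  feet <- fix_feet()
  m <- fix_motion("sway_S2S", duration = 0.5, rate = 30, amplitude = 0)
  res_flat <- run_fsm(m$trajectory, body, m$feet,
                      config = fsm_config(arch = FALSE, hip = FALSE))
  res_arch <- run_fsm(m$trajectory, body, m$feet,
                      config = fsm_config(arch = TRUE, hip = FALSE))
  expect_lt(res_arch$I_L_Arch[5], res_flat$I_L_Arch[5])
  expect_lt(res_arch$I_R_Arch[5], res_flat$I_R_Arch[5])
  # per-foot totals are untouched by the arch model (conservation rescale)
  tf <- foot_totals(res_flat); ta <- foot_totals(res_arch)
  expect_equal(ta$total_L, tf$total_L, tolerance = 1e-9)
})
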