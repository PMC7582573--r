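make_pp <- function(mats, dt = 0.01, ...) {
  arr <- array(unlist(mats), c(dim(mats[[1]]), length(mats)))
  pressure_frames(arr, seq(0, by = dt, length.out = length(mats)), ...)
}

test_that("footprint extraction labels 4-connected components", {
  m <- matrix(0, 20, 15)
  m[2:6, 2:3] <- 1          # 10-cell blob
  m[12:16, 10:11] <- 2      # 10-cell blob
  fp <- extract_footprints(make_pp(list(m)))
  expect_length(fp$components, 2)
  expect_equal(vapply(fp$components, nrow, integer(1)), c(10L, 10L))
  # single cell active in a single frame only: temporal sum picks it up
  m0 <- matrix(0, 5, 5); m1 <- m0; m1[3, 3] <- 0.5
  fp1 <- extract_footprints(make_pp(list(m0, m1, m0)))
  expect_length(fp1$components, 1)
  expect_equal(nrow(fp1$components[[1]]), 1L)
  expect_error(extract_footprints(make_pp(list(m0))), "empty plate")
})

test_that("component labelling matches a recursive flood fill", {
  set.seed(31)
  mask <- matrix(stats::runif(30 * 20) < 0.35, 30, 20)
  labels <- forceshadow:::.label_components(mask)
  # independent oracle: depth-first flood fill with an explicit stack,
  # written against (row, col) pairs rather than linear indices
  oracle <- matrix(0L, 30, 20); lab <- 0L
  for (r0 in 1:30) for (c0 in 1:20) {
    if (!mask[r0, c0] || oracle[r0, c0] != 0L) next
    lab <- lab + 1L
    stack <- list(c(r0, c0))
    while (length(stack)) {
      rc <- stack[[1]]; stack <- stack[-1]
      if (rc[1] < 1 || rc[1] > 30 || rc[2] < 1 || rc[2] > 20) next
      if (!mask[rc[1], rc[2]] || oracle[rc[1], rc[2]] != 0L) next
      oracle[rc[1], rc[2]] <- lab
      stack <- c(stack, list(rc + c(1, 0), rc - c(1, 0),
                             rc + c(0, 1), rc - c(0, 1)))
    }
  }
  # same partition (label ids may permute)
  expect_equal(oracle > 0, labels > 0)
  for (id in seq_len(max(labels)))
    expect_length(unique(oracle[labels == id]), 1L)
  expect_equal(max(labels), lab)
})

test_that("region force is pressure times area, additively", {
  m <- matrix(0, 176, 64)
  m[10:19, 5:14] <- 10                      # 100 cells at 10 N/cm^2
  cells <- expand.grid(row = 10:19, col = 5:14)
  expect_equal(region_force(m, cells, cell_area = 0.8469), 846.9)
  expect_equal(region_force(m, cells[0, ]), 0)
  split1 <- cells[1:40, ]; split2 <- cells[41:100, ]
  expect_equal(region_force(m, split1) + region_force(m, split2),
               region_force(m, cells))
  expect_error(region_force(m, data.frame(row = 200, col = 1)), "bounds")
})

test_that("plate emulation conserves force and maps back to regions", {
  body <- fix_body()
  m <- fix_motion("sway_S2S", duration = 2, rate = 30, amplitude = 0.08)
  pp <- emulate_pressure_plate(m, plate_rate = 50)
  # per-frame plate sum equals interpolated ground-truth total
  plate_tot <- vapply(seq_along(pp$time), function(i)
    sum(pp$frames[, , i]) * pp$cell_area, numeric(1))
  truth_tot <- rowSums(pp$planted$L) + rowSums(pp$planted$R)
  expect_equal(plate_tot, truth_tot, tolerance = 1e-6)
  # footprints: two feet
  fp <- extract_footprints(pp)
  expect_length(fp$components, 2)
  # full-footprint force equals plate total per frame
  allcells <- do.call(rbind, fp$components)
  i_mid <- length(pp$time) %/% 2
  expect_equal(region_force(pp$frames[, , i_mid], allcells, pp$cell_area),
               plate_tot[i_mid], tolerance = 1e-9 * plate_tot[i_mid])
})

test_that("region mapping round-trips a rasterised footprint", {
  body <- fix_body()
  m <- fix_motion("sway_S2S", duration = 1, rate = 30, amplitude = 0)
  pp <- emulate_pressure_plate(m, plate_rate = 20)
  fp <- extract_footprints(pp)
  # match components to sides via centroid y
  cy <- vapply(fp$components, function(cp) mean(cp$y), numeric(1))
  comp <- list(L = fp$components[[which.max(cy)]],
               R = fp$components[[which.min(cy)]])
  for (side in c("L", "R")) {
    mapped <- map_regions_to_plate(m$feet[[side]], comp[[side]],
                                   pitch = pp$pitch[1])
    truth_cells <- pp$cells[[side]]
    truth_hard <- truth_cells$region[match(
      paste(comp[[side]]$row, comp[[side]]$col),
      paste(truth_cells$row, truth_cells$col))]
    expect_gte(mean(!is.na(mapped$region)), 0.99)   # assigned
    agree <- mean(mapped$region == truth_hard, na.rm = TRUE)
    expect_gte(agree, 0.99)                         # to the right region
  }
})

test_that("region mapping is equivariant under whole-cell translation", {
  body <- fix_body()
  m <- fix_motion("sway_S2S", duration = 1, rate = 30, amplitude = 0)
  pp <- emulate_pressure_plate(m, plate_rate = 20)
  fp <- extract_footprints(pp)
  comp <- fp$components[[1]]
  mapped <- map_regions_to_plate(m$feet$L, comp, pitch = pp$pitch[1])
  shifted <- comp
  shifted$row <- shifted$row + 3
  shifted$x <- shifted$x + 3 * pp$pitch[1]
  mapped2 <- map_regions_to_plate(m$feet$L, shifted, pitch = pp$pitch[1])
  for (rg in foot_regions()) {
    a <- mapped$cells[[rg]]; b <- mapped2$cells[[rg]]
    expect_equal(nrow(a), nrow(b))
    expect_setequal(paste(a$row + 3, a$col), paste(b$row, b$col))
  }
  expect_equal(mapped2$dropped, mapped$dropped)
})

test_that("error metrics reproduce hand-computed values", {
  m0 <- fsm_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m0$RMSE, 0)
  expect_equal(m0$MAE, 0)
  expect_equal(m0$SD, 0)
  expect_equal(m0$r, 1)
  # y=(0,2), y_ref=(1,1): e=(-1,1)
  m1 <- fsm_metrics(c(0, 2), c(1, 1))
  expect_equal(m1$RMSE, 1)
  expect_equal(m1$MAE, 1)
  expect_equal(m1$SD, sqrt(2))
  expect_equal(m1$rRMSE, 100)
  m2 <- fsm_metrics(c(1, 2, 3), c(3, 2, 1))
  expect_equal(m2$r, -1)
  # constant series: r undefined
  m3 <- fsm_metrics(c(1, 1, 1), c(1, 2, 3))
  expect_false(m3$r_defined)
  expect_true(is.na(m3$r))
  expect_error(fsm_metrics(1:3, 1:4), "mismatch")
})

test_that("metric symmetry and the SD definition hold on random series", {
  set.seed(17)
  for (rep in 1:10) {
    y <- stats::rnorm(50); z <- stats::rnorm(50)
    a <- fsm_metrics(y, z); b <- fsm_metrics(z, y)
    expect_equal(a$RMSE, b$RMSE)
    expect_equal(a$rRMSE, b$rRMSE)
    expect_equal(a$MAE, b$MAE)
    expect_equal(abs(a$r), abs(b$r))
    # SD of the signed error, two-pass textbook variance
    e <- y - z
    expect_equal(a$SD, sqrt(sum((e - mean(e))^2) / (length(e) - 1)))
    expect_gte(a$RMSE, a$MAE)
    # absolute-error variant option
    expect_equal(fsm_metrics(y, z, sd_absolute = TRUE)$SD,
                 stats::sd(abs(e)))
  }
})
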