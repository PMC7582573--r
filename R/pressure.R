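#' Pressure-plate frame sequence
#'
#' Container for dense pressure-plate recordings: one `rows x cols`
#' nonnegative matrix of pressures (N/cm^2) per time step, with plate
#' geometry metadata. Default geometry follows a 176 x 64 plate of
#' 149 cm x 54.2 cm sensing area sampled at 100 Hz with a per-cell area
#' of 0.8469 cm^2.
#'
#' @param frames 3D array `rows x cols x n` of pressures (N/cm^2).
#' @param time numeric vector of frame times (s), length n.
#' @param cell_area sensor cell area (cm^2).
#' @param pitch length-2 cell pitch (m) along rows (x) and columns (y).
#' @param origin length-2 world coordinate (m) of the centre of cell
#'   `[1, 1]`.
#' @return list of class `fsm_pressure`.
#' @export
pressure_frames <- function(frames, time, cell_area = 0.8469,
                            pitch = c(1.49 / 176, 0.542 / 64),
                            origin = c(0, 0)) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == length(time))
  if (any(frames < 0)) .stopf("pressure values must be nonnegative")
  structure(list(frames = frames, time = time, cell_area = cell_area,
                 pitch = pitch, origin = origin),
            class = "fsm_pressure")
}

#' @export
print.fsm_pressure <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Pressure recording: %d x %d cells, %d frames, cell %.4f cm^2\n",
              d[1], d[2], d[3], x$cell_area))
  invisible(x)
}

# world coordinates of cell centres for (row, col) vectors
.cell_coords <- function(pp, row, col) {
  cbind(pp$origin[1] + (row - 1) * pp$pitch[1],
        pp$origin[2] + (col - 1) * pp$pitch[2])
}

# rasterise a posed foot onto the plate grid.  Cells straddling region
# boundaries are handled by area weighting (ss x ss supersampling of the
# cell): returns the covered cells with their per-region area fractions
# and a hard (majority) region label.
.rasterize_foot <- function(foot, pp, dims, ss = 4L) {
  nodes <- foot$nodes
  rng_r <- .clamp(floor((range(nodes[, 1]) - pp$origin[1]) / pp$pitch[1]) +
                    c(0, 2), 1, dims[1])
  rng_c <- .clamp(floor((range(nodes[, 2]) - pp$origin[2]) / pp$pitch[2]) +
                    c(0, 2), 1, dims[2])
  rows <- rng_r[1]:rng_r[2]; cols <- rng_c[1]:rng_c[2]
  grid <- expand.grid(row = rows, col = cols)
  xy <- .cell_coords(pp, grid$row, grid$col)
  regs <- foot_regions()
  # a cell belongs to the plate foot print iff its centre lies in the
  # mesh (the resolution-limited coverage a real plate would report);
  # its region is the majority of an ss x ss supersample of the cell
  keep <- !is.na(.assign_regions(xy, foot))
  grid <- grid[keep, , drop = FALSE]
  xy <- xy[keep, , drop = FALSE]
  off <- ((seq_len(ss) - 0.5) / ss - 0.5)
  frac <- matrix(0, nrow(grid), length(regs), dimnames = list(NULL, regs))
  for (ox in off) for (oy in off) {
    sub <- cbind(xy[, 1] + ox * pp$pitch[1], xy[, 2] + oy * pp$pitch[2])
    r <- .assign_regions(sub, foot)
    hit <- !is.na(r)
    if (any(hit))
      frac[cbind(which(hit), match(r[hit], regs))] <-
        frac[cbind(which(hit), match(r[hit], regs))] + 1
  }
  frac <- frac / ss^2
  data.frame(row = grid$row, col = grid$col,
             region = regs[max.col(frac, ties.method = "first")],
             frac, check.names = FALSE)
}

#' Emulate a pressure plate under a synthetic motion
#'
#' Distributes each foot's ground-truth load over the rasterised posed
#' foot regions using fixed anatomical region fractions (heel-dominant,
#' arch-discounted); within a region the profile is flat over interior
#' cells and tapers to zero on cells straddling a region seam, since real
#' plantar pressure has no step discontinuities at anatomical boundaries.
#' Pressures are the cell loads divided by cell area, and the load series
#' is resampled from the kinematic rate to the plate rate by linear
#' interpolation. The per-frame plate sum equals
#' the interpolated ground-truth total exactly (up to float rounding).
#' Requires stationary feet (sway/squat protocols).
#'
#' @param motion an `fsm_motion` from [generate_motion()].
#' @param plate_rate plate sampling rate (Hz).
#' @param dims plate grid dimensions (rows, cols).
#' @param cell_area cell area (cm^2).
#' @param region_fractions named share of a foot's load per subregion
#'   (summing to 1).
#' @return an `fsm_pressure` with extra elements `planted` (list `L`/`R`
#'   of `n_plate x 6` matrices of the planted per-region loads, N),
#'   `cells` (the per-foot rasterisation), and `plate_time`.
#' @export
emulate_pressure_plate <- function(motion, plate_rate = 100,
                                   dims = c(176, 64), cell_area = 0.8469,
                                   region_fractions = c(Heel = 0.40,
                                                        Arch = 0.10,
                                                        MetaMed = 0.17,
                                                        MetaLat = 0.13,
                                                        ToesMed = 0.12,
                                                        ToesLat = 0.08)) {
  if (abs(sum(region_fractions) - 1) > 1e-9)
    .stopf("region_fractions must sum to 1")
  ctr <- motion$foot_center
  if (max(apply(ctr$L, 2, function(v) diff(range(v)))) > 1e-9 ||
      max(apply(ctr$R, 2, function(v) diff(range(v)))) > 1e-9)
    .stopf("pressure-plate emulation requires stationary feet")
  pitch <- c(1.49, 0.542) / dims
  posed <- list(L = pose_foot(motion$feet$L, motion$poses$L),
                R = pose_foot(motion$feet$R, motion$poses$R))
  allx <- rbind(posed$L$nodes, posed$R$nodes)
  extent <- pitch * (dims - 1)
  origin <- colMeans(allx) - extent / 2
  pp_meta <- list(origin = origin, pitch = pitch)
  for (side in c("L", "R")) {
    lo <- apply(posed[[side]]$nodes, 2, min); hi <- apply(posed[[side]]$nodes, 2, max)
    if (any(lo < origin - pitch / 2) || any(hi > origin + extent + pitch / 2))
      .stopf("foot off-plate (side %s)", side)
  }
  cells <- lapply(posed, .rasterize_foot, pp = pp_meta, dims = dims)
  t_plate <- seq(min(motion$truth$time), max(motion$truth$time),
                 by = 1 / plate_rate)
  regs <- foot_regions()
  planted <- list()
  for (side in c("L", "R")) {
    tot <- stats::approx(motion$truth$time,
                         motion$truth[[paste0("load_", side)]],
                         xout = t_plate)$y
    planted[[side]] <- outer(tot, region_fractions[regs])
    colnames(planted[[side]]) <- regs
  }
  frames <- array(0, c(dims, length(t_plate)))
  for (side in c("L", "R")) {
    cs <- cells[[side]]
    for (rg in regs) {
      # boundary-tapered profile: interior cells carry full weight,
      # cells straddling a region seam taper towards zero (plantar
      # pressure has no step discontinuities at anatomical boundaries)
      w <- pmax(2 * cs[[rg]] - 1, 0)
      if (sum(w) <= 0) w <- cs[[rg]]
      sel <- w > 0
      if (!any(sel)) next
      idx <- cbind(cs$row[sel], cs$col[sel])
      wsel <- w[sel]
      p_series <- planted[[side]][, rg] / (sum(wsel) * cell_area)
      for (i in seq_along(t_plate))
        frames[, , i][idx] <- frames[, , i][idx] + p_series[i] * wsel
    }
  }
  pp <- pressure_frames(frames, t_plate, cell_area = cell_area,
                        pitch = pitch, origin = origin)
  pp$planted <- planted
  pp$cells <- cells
  pp$posed_feet <- posed
  pp
}
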