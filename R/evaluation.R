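#' Extract foot prints from a pressure recording
#'
#' Sums the pressure matrices over time (assuming a static foot placement
#' over the summed range), thresholds non-vanishing cells to one, and
#' labels 4-connected components of the resulting binary mask; each
#' component is one foot print.
#'
#' @param pp an `fsm_pressure`.
#' @param threshold pressures at or below this value count as vanishing.
#' @return list with `mask` (binary matrix), `labels` (integer matrix,
#'   0 = background) and `components`, a list of data frames with `row`,
#'   `col` and metric cell-centre coordinates `x`, `y`, ordered by
#'   decreasing size.
#' @export
extract_footprints <- function(pp, threshold = 0) {
  total <- apply(pp$frames, c(1, 2), sum)
  mask <- total > threshold
  if (!any(mask)) .stopf("empty plate: no non-vanishing cells")
  labels <- .label_components(mask)
  ids <- sort(unique(labels[labels > 0]))
  comps <- lapply(ids, function(id) {
    w <- which(labels == id, arr.ind = TRUE)
    xy <- .cell_coords(pp, w[, 1], w[, 2])
    data.frame(row = w[, 1], col = w[, 2], x = xy[, 1], y = xy[, 2])
  })
  comps <- comps[order(-vapply(comps, nrow, integer(1)))]
  list(mask = mask, labels = labels, components = comps)
}

# 4-connected component labelling by iterative queue-based flood fill
.label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  lab <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      cc <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + d[1]; c2 <- cc + d[2]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        i2 <- (c2 - 1L) * nr + r2
        if (mask[i2] && labels[i2] == 0L) {
          labels[i2] <- lab
          queue <- c(queue, i2)
        }
      }
    }
  }
  labels
}

#' Force on a set of plate cells
#'
#' Pointwise product of pressure (N/cm^2) and cell area (cm^2), summed
#' over the given cells: the vertical force carried by those cells (N).
#' If the cell table carries a weight column `w` (area fraction of the
#' cell attributed to the region, as produced by
#' [map_regions_to_plate()]), each cell contributes proportionally.
#'
#' @param frame one pressure matrix.
#' @param cells data frame with integer `row`, `col` and optional
#'   numeric `w`.
#' @param cell_area cell area (cm^2).
#' @return force in newtons.
#' @export
region_force <- function(frame, cells, cell_area = 0.8469) {
  if (nrow(cells) == 0) return(0)
  if (any(cells$row < 1 | cells$row > nrow(frame) |
            cells$col < 1 | cells$col > ncol(frame)))
    .stopf("cell index out of plate bounds")
  w <- if (is.null(cells$w)) 1 else cells$w
  sum(frame[cbind(cells$row, cells$col)] * w) * cell_area
}

#' Map foot-model regions onto a plate foot print
#'
#' Rigidly aligns the foot model to an extracted foot-print component by
#' centroid + principal-axis matching restricted to proper rotations (the
#' model side matches the print side); the remaining 180-degree ambiguity
#' is resolved by mesh-membership scoring, and the translation is locked
#' in at sub-pixel precision by centring the exact raster-match plateau.
#' Each cell is then assigned to the subregions overlapping it with
#' area-fraction weights from supersampling (boundary-straddling cells
#' split between regions instead of flipping wholesale); cells covered by
#' no region are given wholly to the nearest region within two cell
#' pitches, else dropped.
#'
#' @param foot an `fsm_foot` (model frame).
#' @param component a foot-print data frame from [extract_footprints()]
#'   (columns `x`, `y` in metres).
#' @param pitch cell pitch (m).
#' @return list with `cells` (named list per region of `row`/`col`/`w`
#'   data frames, `w` the cell's area fraction in that region), `region`
#'   (hard majority label per component cell), `frac` (full fraction
#'   matrix), `dropped` (count), `score` (alignment score in `[0, 1]`).
#' @export
map_regions_to_plate <- function(foot, component, pitch = 1.49 / 176) {
  X <- cbind(component$x, component$y)
  if (nrow(X) < 3) .stopf("foot print needs at least 3 cells")
  cf <- colMeans(X)
  Cf <- stats::cov(X)
  ef <- eigen(Cf, symmetric = TRUE)
  if (ef$values[1] / max(ef$values[2], 1e-18) < 1.1)
    .stopf("degenerate principal axes: foot print is near-isotropic")
  # model moments from a pitch-spaced rasterisation of the model itself,
  # so the discretisation bias matches the plate foot print's
  gx <- seq(min(foot$nodes[, 1]), max(foot$nodes[, 1]) + pitch / 2,
            by = pitch)
  gy <- seq(min(foot$nodes[, 2]), max(foot$nodes[, 2]) + pitch / 2,
            by = pitch)
  gpts <- as.matrix(expand.grid(gx, gy))
  gin <- gpts[!is.na(.assign_regions(gpts, foot)), , drop = FALSE]
  cm <- colMeans(gin)
  Cm <- stats::cov(gin)
  em <- eigen(Cm, symmetric = TRUE)
  # candidate rotations: the model side matches the print side, so only
  # proper rotations are admissible; the remaining 180-degree ambiguity is
  # resolved by mesh-membership scoring (the outline is length-asymmetric)
  best <- NULL
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    R <- ef$vectors %*% diag(c(s1, s2)) %*% t(em$vectors)
    if (det(R) < 0) next
    P <- sweep(sweep(X, 2, cf) %*% R, 2, cm, "+")
    score <- mean(!is.na(.assign_regions(P, foot, tol = 1e-9)))
    if (is.null(best) || score > best$score)
      best <- list(score = score, R = R)
  }
  # plate -> model map: p = R^T (x - anchor) + cm, anchor initially the
  # foot-print centroid.  Translation refinement: re-rasterise the model
  # in the plate grid under the current map and match raster centroids,
  # removing the sub-pixel phase bias between the plate and model-frame
  # rasterisations.
  R <- best$R
  anchor <- cf
  rows <- (min(component$row) - 2):(max(component$row) + 2)
  cols <- (min(component$col) - 2):(max(component$col) + 2)
  grid <- as.matrix(expand.grid(rows, cols))
  gxy <- cbind(component$x[1] + (grid[, 1] - component$row[1]) * pitch,
               component$y[1] + (grid[, 2] - component$col[1]) * pitch)
  for (it in 1:3) {
    Pg <- sweep(sweep(gxy, 2, anchor) %*% R, 2, cm, "+")
    pred <- !is.na(.assign_regions(Pg, foot, tol = 1e-9))
    if (sum(pred) < 3) break
    anchor <- anchor + (cf - colMeans(gxy[pred, , drop = FALSE]))
  }
  # sub-pixel lock-in: the raster match is exact on a small plateau of
  # translations; centre it by minimising the symmetric difference
  # between the predicted and observed cell sets over sub-pixel shifts
  fp_mask <- paste(grid[, 1], grid[, 2]) %in%
    paste(component$row, component$col)
  shifts <- as.matrix(expand.grid(seq(-0.45, 0.45, by = 0.09) * pitch,
                                  seq(-0.45, 0.45, by = 0.09) * pitch))
  mis <- vapply(seq_len(nrow(shifts)), function(k) {
    Pg <- sweep(sweep(gxy, 2, anchor + shifts[k, ]) %*% R, 2, cm, "+")
    sum(!is.na(.assign_regions(Pg, foot, tol = 1e-9)) != fp_mask)
  }, numeric(1))
  opt <- mis == min(mis)
  anchor <- anchor + colMeans(shifts[opt, , drop = FALSE])
  P <- sweep(sweep(X, 2, anchor) %*% R, 2, cm, "+")
  # area-weighted assignment: supersample each cell so boundary cells
  # split between adjacent regions instead of flipping wholesale
  regs <- foot_regions()
  ss <- 4L
  off <- ((seq_len(ss) - 0.5) / ss - 0.5) * pitch
  frac <- matrix(0, nrow(X), length(regs), dimnames = list(NULL, regs))
  for (ox in off) for (oy in off) {
    sub <- sweep(sweep(cbind(X[, 1] + ox, X[, 2] + oy), 2, anchor) %*% R,
                 2, cm, "+")
    r <- .assign_regions(sub, foot, tol = 1e-9)
    hit <- !is.na(r)
    if (any(hit))
      frac[cbind(which(hit), match(r[hit], regs))] <-
        frac[cbind(which(hit), match(r[hit], regs))] + 1
  }
  frac <- frac / ss^2
  covered <- rowSums(frac) > 0
  frac[covered, ] <- frac[covered, , drop = FALSE] /
    rowSums(frac)[covered]
  reg <- ifelse(covered, regs[max.col(frac, ties.method = "first")],
                NA_character_)
  # nearest-region rescue within 2 pitches for uncovered cells
  nodes <- foot$nodes; tri <- foot$tri
  un <- which(!covered)
  if (length(un)) {
    cx <- (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3
    cy <- (nodes[tri[, 1], 2] + nodes[tri[, 2], 2] + nodes[tri[, 3], 2]) / 3
    for (i in un) {
      d2 <- (cx - P[i, 1])^2 + (cy - P[i, 2])^2
      j <- which.min(d2)
      if (sqrt(d2[j]) <= 2 * pitch) {
        rg <- as.character(foot$region[j])
        reg[i] <- rg
        frac[i, rg] <- 1
      }
    }
  }
  dropped <- sum(is.na(reg))
  cells <- lapply(regs, function(rg) {
    sel <- !is.na(reg) & reg == rg     # majority assignment
    data.frame(row = component$row[sel], col = component$col[sel])
  })
  names(cells) <- regs
  list(cells = cells, dropped = dropped, score = best$score,
       model_coords = P, region = reg, frac = frac)
}

#' Trajectory comparison metrics
#'
#' Error metrics between an estimated series y and a reference series
#' \eqn{\tilde y} (conventionally both in N/kg, normalised by body
#' weight): RMSE; relative RMSE in percent of the mean peak-to-peak
#' amplitude of the two series; MAE; the standard deviation of the error
#' around its mean (the printed formula uses the signed error
#' \eqn{e(k) = y(k) - \tilde y(k)}; `sd_absolute = TRUE` uses
#' \eqn{|e(k)|} instead); and the Pearson correlation coefficient, flagged
#' undefined (`NA`) when either series is constant.
#'
#' @param y,y_ref numeric series of equal length >= 2.
#' @param sd_absolute compute the SD of `|e|` rather than of `e`.
#' @return list of class `fsm_metrics`: `RMSE`, `rRMSE` (percent), `MAE`,
#'   `SD`, `r`, `r_defined`, `n`.
#' @export
fsm_metrics <- function(y, y_ref, sd_absolute = FALSE) {
  if (length(y) != length(y_ref))
    .stopf("series length mismatch (%d vs %d)", length(y), length(y_ref))
  n <- length(y)
  if (n < 2) .stopf("need at least 2 samples")
  e <- y - y_ref
  if (sd_absolute) e_sd <- abs(e) else e_sd <- e
  rmse <- sqrt(mean(e^2))
  ptp <- (diff(range(y)) + diff(range(y_ref))) / 2
  rrmse <- if (ptp > 0) 100 * rmse / ptp else NA_real_
  r_def <- stats::sd(y) > 0 && stats::sd(y_ref) > 0
  structure(list(RMSE = rmse, rRMSE = rrmse, MAE = mean(abs(e)),
                 SD = stats::sd(e_sd),
                 r = if (r_def) stats::cor(y, y_ref) else NA_real_,
                 r_defined = r_def, n = n),
            class = "fsm_metrics")
}

#' @export
print.fsm_metrics <- function(x, ...) {
  cat(sprintf("RMSE %.4g | rRMSE %.4g%% | MAE %.4g | SD %.4g | r %s (n=%d)\n",
              x$RMSE, x$rRMSE, x$MAE, x$SD,
              if (x$r_defined) sprintf("%.4f", x$r) else "undefined", x$n))
  invisible(x)
}
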