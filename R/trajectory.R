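#' Kinematic trajectory container
#'
#' Bundles the per-frame kinematic state the pipeline consumes: segment
#' CoM positions and planar heading angles, 2D foot landmarks (first
#' metatarsal head FM, fifth metatarsal head VM, calcaneus CA per side),
#' and optionally the whole-body CoM with its derivatives and per-foot
#' heel/toe height & speed channels used for contact detection.
#'
#' @param time numeric vector of frame times (s), strictly increasing.
#' @param seg_com numeric array `n x S x 3` of segment CoM positions (m);
#'   second dimension named by segment.
#' @param heading numeric matrix `n x S` of planar segment heading angles
#'   (rad); `NA` headings fall back to an isotropic shadow component.
#' @param landmarks list with elements `L` and `R`, each an `n x 3 x 2`
#'   array of ground-plane landmark coordinates (m), second dimension named
#'   `FM`, `VM`, `CA`, third `x`, `y`.
#' @param com optional `n x 3` matrix of whole-body CoM (m); computed from
#'   `seg_com` on demand when absent.
#' @param com_vel,com_acc optional `n x 3` matrices (m/s, m/s^2).
#' @param foot_kin optional list `L`/`R` of `n x 4` matrices with columns
#'   `heel_z`, `toe_z`, `heel_speed`, `toe_speed` (m, m/s) driving the
#'   contact thresholds; absent channels mean feet flat and still on the
#'   ground (always eligible for contact).
#' @return An object of class `fsm_trajectory`.
#' @export
fsm_trajectory <- function(time, seg_com, heading, landmarks,
                           com = NULL, com_vel = NULL, com_acc = NULL,
                           foot_kin = NULL) {
  n <- length(time)
  if (n >= 2 && any(diff(time) <= 0)) .stopf("time must be strictly increasing")
  if (length(dim(seg_com)) != 3 || dim(seg_com)[1] != n || dim(seg_com)[3] != 3)
    .stopf("seg_com must be an n x S x 3 array")
  for (side in c("L", "R")) {
    lm <- landmarks[[side]]
    if (is.null(lm) || any(dim(lm) != c(n, 3, 2)))
      .stopf("landmarks$%s must be an n x 3 x 2 array", side)
  }
  strip <- function(m) { if (!is.null(m)) dimnames(m) <- NULL; m }
  structure(list(time = time, dt = if (n >= 2) mean(diff(time)) else NA_real_,
                 seg_com = seg_com, heading = heading, landmarks = landmarks,
                 com = strip(com), com_vel = strip(com_vel),
                 com_acc = strip(com_acc), foot_kin = foot_kin),
            class = "fsm_trajectory")
}

#' @export
print.fsm_trajectory <- function(x, ...) {
  cat(sprintf("Kinematic trajectory: %d frames, %d segments, %.4g s @ %.4g Hz\n",
              length(x$time), dim(x$seg_com)[2],
              diff(range(x$time)), 1 / x$dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `fsm_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$time)

#' Truncate a trajectory to its first n frames
#'
#' Used to verify the online property of the pipeline: no stage may look
#' ahead, so the first `n` output rows of a truncated input must equal
#' those of the full input.
#'
#' @param traj an `fsm_trajectory`.
#' @param n number of leading frames to keep.
#' @return an `fsm_trajectory` with `n` frames.
#' @export
truncate_trajectory <- function(traj, n) {
  stopifnot(n >= 1, n <= n_frames(traj))
  idx <- seq_len(n)
  sub3 <- function(a) if (is.null(a)) NULL else a[idx, , , drop = FALSE]
  sub2 <- function(m) if (is.null(m)) NULL else m[idx, , drop = FALSE]
  fsm_trajectory(
    time = traj$time[idx], seg_com = sub3(traj$seg_com),
    heading = sub2(traj$heading),
    landmarks = list(L = sub3(traj$landmarks$L), R = sub3(traj$landmarks$R)),
    com = sub2(traj$com), com_vel = sub2(traj$com_vel),
    com_acc = sub2(traj$com_acc),
    foot_kin = if (is.null(traj$foot_kin)) NULL else
      list(L = sub2(traj$foot_kin$L), R = sub2(traj$foot_kin$R)))
}

# Whole-body CoM series (n x 3), computing it from segments if absent.
.traj_com <- function(traj, body) {
  if (!is.null(traj$com)) return(traj$com)
  segs <- dimnames(traj$seg_com)[[2]]
  d <- body$d[segs]
  if (any(is.na(d))) .stopf("trajectory segments do not match the body model")
  com <- matrix(0, n_frames(traj), 3)
  for (k in 1:3) com[, k] <- traj$seg_com[, , k] %*% d
  com
}

#' Write / read a kinematic trajectory as wide CSV
#'
#' One row per frame. Columns: `time`; `<segment>_com_x/y/z` and
#' `<segment>_heading` per segment; `<L|R>_<FM|VM|CA>_x/y` landmark
#' coordinates; optional `com_x/y/z`, `com_vel_*`, `com_acc_*`, and
#' `<L|R>_heel_z/toe_z/heel_speed/toe_speed`. Units m, s, rad.
#'
#' @param traj an `fsm_trajectory`.
#' @param path output / input CSV path.
#' @return `write_kinematics` returns `path` invisibly; `read_kinematics`
#'   returns an `fsm_trajectory`.
#' @export
write_kinematics <- function(traj, path) {
  segs <- dimnames(traj$seg_com)[[2]]
  df <- data.frame(time = traj$time)
  for (s in seq_along(segs)) {
    for (k in 1:3)
      df[[paste0(segs[s], "_com_", c("x", "y", "z")[k])]] <- traj$seg_com[, s, k]
    df[[paste0(segs[s], "_heading")]] <- traj$heading[, s]
  }
  for (side in c("L", "R")) for (lm in c("FM", "VM", "CA")) for (k in 1:2)
    df[[paste(side, lm, c("x", "y")[k], sep = "_")]] <-
      traj$landmarks[[side]][, lm, k]
  addm <- function(m, base) {
    if (!is.null(m)) for (k in 1:3)
      df[[paste0(base, "_", c("x", "y", "z")[k])]] <<- m[, k]
  }
  addm(traj$com, "com"); addm(traj$com_vel, "com_vel"); addm(traj$com_acc, "com_acc")
  if (!is.null(traj$foot_kin))
    for (side in c("L", "R")) for (ch in colnames(traj$foot_kin[[side]]))
      df[[paste(side, ch, sep = "_")]] <- traj$foot_kin[[side]][, ch]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kinematics
#' @export
read_kinematics <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  segs <- unique(sub("_com_x$", "", grep("_com_x$", nm, value = TRUE)))
  segs <- setdiff(segs, "")
  segs <- segs[segs != "com" & !startsWith(segs, "com_")]
  n <- nrow(df)
  seg_com <- array(NA_real_, c(n, length(segs), 3),
                   dimnames = list(NULL, segs, c("x", "y", "z")))
  heading <- matrix(NA_real_, n, length(segs), dimnames = list(NULL, segs))
  for (s in segs) {
    for (k in 1:3) seg_com[, s, k] <- df[[paste0(s, "_com_", c("x", "y", "z")[k])]]
    h <- df[[paste0(s, "_heading")]]
    heading[, s] <- if (is.null(h)) NA_real_ else h
  }
  lmarr <- function(side) {
    a <- array(NA_real_, c(n, 3, 2),
               dimnames = list(NULL, c("FM", "VM", "CA"), c("x", "y")))
    for (lm in c("FM", "VM", "CA")) for (k in 1:2)
      a[, lm, k] <- df[[paste(side, lm, c("x", "y")[k], sep = "_")]]
    a
  }
  getm <- function(base) {
    cols <- paste0(base, "_", c("x", "y", "z"))
    if (all(cols %in% nm)) as.matrix(df[cols]) else NULL
  }
  fk <- NULL
  chans <- c("heel_z", "toe_z", "heel_speed", "toe_speed")
  if (all(paste("L", chans, sep = "_") %in% nm)) {
    fk <- lapply(c(L = "L", R = "R"), function(side) {
      m <- as.matrix(df[paste(side, chans, sep = "_")])
      colnames(m) <- chans
      m
    })
  }
  fsm_trajectory(time = df$time, seg_com = seg_com, heading = heading,
                 landmarks = list(L = lmarr("L"), R = lmarr("R")),
                 com = getm("com"), com_vel = getm("com_vel"),
                 com_acc = getm("com_acc"), foot_kin = fk)
}
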