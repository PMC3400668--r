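# Fast-start escape kinematics from frame-indexed centre-of-mass
# trajectories: response latency, maximum linear velocity, and stage-1
# turning radius. All three metrics are invariant to global translation
# and rotation of the coordinate frame.

frame_displacements <- function(traj) {
  n <- length(traj$x)
  sqrt(diff(traj$x)^2 + diff(traj$y)^2)  # displacement leaving frame i
}

#' Response latency of a fast-start escape
#'
#' Time from stimulus onset to the beginning of the first inter-frame
#' interval whose centre-of-mass displacement exceeds a motion threshold.
#' By construction the result is quantised to multiples of `1000/fps` ms.
#' The default threshold adapts to digitising noise: three times the
#' standard deviation of pre-stimulus frame-to-frame displacements, with
#' a floor of 0.2 mm.
#'
#' @param traj A `fast_start_traj`.
#' @param speed_threshold Displacement threshold, mm per frame; `NULL`
#'   selects the noise-adaptive default.
#' @param threshold_floor Minimum threshold, mm (default 0.2).
#' @return Latency in ms, or `NA_real_` if no post-stimulus displacement
#'   ever exceeds the threshold (no-response flag).
#' @export
detect_response_latency <- function(traj, speed_threshold = NULL,
                                    threshold_floor = 0.2) {
  stopifnot(inherits(traj, "fast_start_traj"))
  n <- length(traj$x)
  stim <- traj$stim_frame
  if (stim < 2L || stim > n - 5L) {
    stop("`stim_frame` must leave at least 5 post-stimulus frames",
         call. = FALSE)
  }
  disp <- frame_displacements(traj)
  if (is.null(speed_threshold)) {
    pre <- disp[seq_len(stim - 1L)]
    speed_threshold <- max(3 * stats::sd(pre), threshold_floor)
    if (is.na(speed_threshold)) speed_threshold <- threshold_floor
  }
  post <- which(disp > speed_threshold)
  post <- post[post >= stim]
  if (length(post) == 0L) return(NA_real_)
  (post[1L] - stim) * 1000 / traj$fps
}

#' Maximum linear velocity of the centre of mass
#'
#' Speed is measured on a moving-average-smoothed path by a five-frame
#' central difference, so a frame's velocity is the mean displacement
#' rate over the surrounding two frames of smoothed positions. The
#' maximum is taken over frames at or after response onset (the whole
#' recording if no onset is detectable).
#'
#' @param traj A `fast_start_traj` with coordinates in mm.
#' @param smooth_window Moving-average window in frames (odd, default 3).
#' @return Maximum speed in m s^-1 (0 for a stationary fish).
#' @export
max_linear_velocity <- function(traj, smooth_window = 3) {
  stopifnot(inherits(traj, "fast_start_traj"))
  w <- check_count(smooth_window, "smooth_window")
  if (w %% 2L == 0L) stop("`smooth_window` must be odd", call. = FALSE)
  n <- length(traj$x)
  if (n < w + 4L) {
    stop("trajectory shorter than the smoothing + differencing stencil",
         call. = FALSE)
  }
  xs <- stats::filter(traj$x, rep(1 / w, w), sides = 2)
  ys <- stats::filter(traj$y, rep(1 / w, w), sides = 2)
  # five-frame central difference on interior frames with full windows
  half <- (w - 1L) %/% 2L
  lo <- half + 3L; hi <- n - half - 2L
  if (hi < lo) stop("trajectory too short for velocity estimation",
                    call. = FALSE)
  idx <- lo:hi
  dx <- xs[idx + 2L] - xs[idx - 2L]
  dy <- ys[idx + 2L] - ys[idx - 2L]
  speed_mm_frame <- sqrt(dx^2 + dy^2) / 4
  onset <- suppressWarnings(detect_response_latency(traj))
  if (!is.na(onset)) {
    onset_frame <- traj$stim_frame + round(onset * traj$fps / 1000)
    keep <- idx >= onset_frame
    if (any(keep)) speed_mm_frame <- speed_mm_frame[keep]
  }
  max(speed_mm_frame) * traj$fps / 1000  # mm/frame -> m/s
}

# Algebraic (Kasa) circle fit: minimises sum((x^2+y^2+Dx+Ey+F)^2);
# linear normal equations, exact on points lying on a true circle.
kasa_circle_fit <- function(x, y) {
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  fit <- qr(A)
  if (fit$rank < 3L) return(NULL)
  coef <- unname(qr.coef(fit, b))
  cx <- -coef[1] / 2; cy <- -coef[2] / 2
  r2 <- cx^2 + cy^2 - coef[3]
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(centre = c(cx, cy), radius = sqrt(r2))
}

#' Stage-1 turning radius
#'
#' Radius of the least-squares circle fitted to the centre-of-mass path
#' during the first `turn_window_ms` after response onset. An escape
#' along a straight line has no finite turning radius and returns the
#' undefined flag.
#'
#' @param traj A `fast_start_traj`.
#' @param turn_window_ms Post-onset window used for the fit, ms
#'   (default 20, i.e. 10 frames at 500 fps).
#' @param collinear_tol Relative tolerance below which the points are
#'   treated as collinear.
#' @return Radius in mm, or `NA_real_` when the path is straight
#'   (undefined-radius flag) or no response was detected.
#' @export
turning_radius <- function(traj, turn_window_ms = 20,
                           collinear_tol = 1e-8) {
  stopifnot(inherits(traj, "fast_start_traj"))
  check_positive(turn_window_ms, "turn_window_ms")
  lat <- detect_response_latency(traj)
  if (is.na(lat)) return(NA_real_)
  onset <- traj$stim_frame + round(lat * traj$fps / 1000)
  nw <- max(3L, round(turn_window_ms * traj$fps / 1000))
  idx <- onset:min(onset + nw, length(traj$x))
  if (length(idx) < 3L) {
    stop("fewer than 3 frames inside the turn window", call. = FALSE)
  }
  x <- traj$x[idx]; y <- traj$y[idx]
  # collinearity: perpendicular spread relative to path extent
  v <- cbind(x - mean(x), y - mean(y))
  sv <- svd(v, nu = 0, nv = 0)$d
  if (sv[1] <= 0 || sv[2] / sv[1] < collinear_tol) return(NA_real_)
  fit <- kasa_circle_fit(x, y)
  if (is.null(fit)) return(NA_real_)
  fit$radius
}

#' Summarise fast-start metrics for one trajectory
#'
#' @param traj A `fast_start_traj`.
#' @param ... Passed on to the individual metric functions.
#' @return Data frame with `latency_ms`, `vmax_m_s`, `turn_radius_mm`.
#' @export
fast_start_metrics <- function(traj, ...) {
  data.frame(latency_ms = detect_response_latency(traj),
             vmax_m_s = max_linear_velocity(traj),
             turn_radius_mm = turning_radius(traj))
}
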