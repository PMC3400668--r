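# Synthetic fast-start escape trajectories. The profile is
# phenomenological, not hydrodynamic: a stationary pre-stimulus phase,
# a stage-1 turn along a circular arc at moderate speed, then a stage-2
# straight-line burst that ramps up to the target maximum velocity,
# holds it briefly and decays. This mimics the C-start structure that a
# 500 frames/s centre-of-mass recording resolves, while keeping every
# kinematic quantity (latency, vmax, turn radius) analytically known.

#' Simulate a fast-start escape trajectory
#'
#' Centre-of-mass coordinates (mm) of an escape response filmed at `fps`
#' frames per second. The fish is stationary until
#' `stim_frame + latency`; the requested latency is snapped to the frame
#' grid (multiples of `1000/fps` ms) because a camera cannot resolve
#' sub-frame onsets. Stage 1 is a turn of radius `turn_radius` lasting
#' `turn_duration_ms`, swum at `0.3 * vmax`; stage 2 accelerates along
#' the exit tangent to `vmax`, holds it for several frames, then decays.
#'
#' @param stim_frame Frame index at which the stimulus fires.
#' @param latency_ms True response latency, ms.
#' @param vmax True maximum linear velocity, m s^-1.
#' @param turn_radius True stage-1 turning radius, mm.
#' @param fps Recording rate, frames s^-1 (default 500).
#' @param n_frames Total number of recorded frames.
#' @param turn_duration_ms Stage-1 duration, ms (default 20).
#' @param noise_sd Digitising noise SD added to both coordinates, mm.
#' @param seed Optional integer seed.
#' @return A `fast_start_traj`: list with `frames`, `x`, `y` (mm), `fps`,
#'   `stim_frame` and the snapped ground truth in `truth`.
#' @examples
#' tr <- gen_fast_start_traj(latency_ms = 12, vmax = 1.42, turn_radius = 10,
#'                           noise_sd = 0, seed = 1)
#' detect_response_latency(tr)  # 12
#' @export
gen_fast_start_traj <- function(stim_frame = 50, latency_ms = 12,
                                vmax = 1.3, turn_radius = 12, fps = 500,
                                n_frames = 150, turn_duration_ms = 20,
                                noise_sd = 0, seed = NULL) {
  check_positive(fps, "fps")
  check_positive(vmax, "vmax")
  check_positive(turn_radius, "turn_radius")
  check_nonneg(latency_ms, "latency_ms")
  check_nonneg(noise_sd, "noise_sd")
  check_count(stim_frame, "stim_frame", min = 2L)
  check_count(n_frames, "n_frames", min = 10L)
  maybe_seed(seed)

  dt_ms <- 1000 / fps
  lat_frames <- round(latency_ms / dt_ms)      # snap to frame grid
  onset <- stim_frame + lat_frames             # last stationary frame
  n_turn <- max(3L, round(turn_duration_ms / dt_ms))
  n_ramp <- 10L; n_hold <- 9L; n_decay <- 10L
  n_burst <- n_turn + n_ramp + n_hold + n_decay
  if (onset + n_burst + 1L > n_frames) {
    stop("`n_frames` too small to contain the stimulus, latency and burst",
         call. = FALSE)
  }

  # per-frame speeds, mm per frame (vmax m/s = vmax mm/ms)
  v1 <- 0.3 * vmax * dt_ms
  vmax_step <- vmax * dt_ms
  speed <- c(rep(v1, n_turn),
             seq(v1, vmax_step, length.out = n_ramp + 1L)[-1L],
             rep(vmax_step, n_hold),
             seq(vmax_step, 0, length.out = n_decay + 1L)[-1L])

  x <- numeric(n_frames); y <- numeric(n_frames)
  # stage 1: arc on a circle of the requested radius, starting at origin
  theta0 <- stats::runif(1, 0, 2 * pi)
  centre <- turn_radius * c(cos(theta0), sin(theta0))
  dth <- speed[seq_len(n_turn)] / turn_radius
  th <- theta0 + pi - cumsum(c(0, dth))        # angle of each arc point
  px <- centre[1] + turn_radius * cos(th)
  py <- centre[2] + turn_radius * sin(th)
  # stage 2: straight along the exit tangent
  tangent <- c(sin(th[length(th)]), -cos(th[length(th)]))
  pos <- cbind(px, py)
  p <- pos[nrow(pos), ]
  for (s in speed[(n_turn + 1L):length(speed)]) {
    p <- p + s * tangent
    pos <- rbind(pos, p)
  }

  x[] <- pos[1, 1]; y[] <- pos[1, 2]           # stationary pre-onset
  idx <- onset + seq_len(nrow(pos) - 1L)
  x[idx] <- pos[-1L, 1]; y[idx] <- pos[-1L, 2]
  if (max(idx) < n_frames) {                   # glide ends, fish rests
    x[(max(idx) + 1L):n_frames] <- pos[nrow(pos), 1]
    y[(max(idx) + 1L):n_frames] <- pos[nrow(pos), 2]
  }
  if (noise_sd > 0) {
    x <- x + stats::rnorm(n_frames, 0, noise_sd)
    y <- y + stats::rnorm(n_frames, 0, noise_sd)
  }
  structure(
    list(frames = seq_len(n_frames), x = x, y = y, fps = fps,
         stim_frame = as.integer(stim_frame),
         truth = list(latency_ms = lat_frames * dt_ms, vmax = vmax,
                      turn_radius = turn_radius, n_turn = n_turn)),
    class = "fast_start_traj"
  )
}

#' Write a fast-start trajectory to CSV
#'
#' Columns `frame`, `x_mm`, `y_mm`; `fps` and `stim_frame` go in
#' `# key: value` header lines.
#'
#' @param traj A `fast_start_traj`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fast_start_traj <- function(traj, path) {
  stopifnot(inherits(traj, "fast_start_traj"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fps: %.6g", traj$fps), con)
  writeLines(sprintf("# stim_frame: %d", traj$stim_frame), con)
  utils::write.csv(data.frame(frame = traj$frames, x_mm = traj$x,
                              y_mm = traj$y),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_fast_start_traj()]
#'
#' @param path CSV path.
#' @return A `fast_start_traj` (without ground truth).
#' @export
read_fast_start_traj <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), ":\\s*")[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  body <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  structure(
    list(frames = body$frame, x = body$x_mm, y = body$y_mm,
         fps = meta$fps, stim_frame = as.integer(meta$stim_frame),
         truth = NULL),
    class = "fast_start_traj"
  )
}
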