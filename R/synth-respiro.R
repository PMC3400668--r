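# Synthetic generators for the respirometry / swim-performance side of the
# pipeline. Every generator is deterministic under a fixed seed and stores
# the ground truth needed by parameter-recovery tests.

#' Simulate a closed-phase oxygen depletion trace
#'
#' Generates the dissolved-oxygen time series recorded while a swim-tunnel
#' respirometer is sealed. A fish consuming oxygen at a mass-specific rate
#' `mo2_true` (mg O2 kg^-1 h^-1) inside an effective water volume
#' `resp_volume - fish_volume` depletes oxygen linearly at
#' `mo2_true * mass / (resp_volume - fish_volume)` mg L^-1 h^-1; Gaussian
#' probe noise is added on top.
#'
#' @param mo2_true True mass-specific oxygen consumption, mg O2 kg^-1 h^-1.
#' @param resp_volume Total respirometer volume, L.
#' @param fish_volume Fish volume, L; defaults to `mass` at neutral
#'   buoyancy (1 kg L^-1).
#' @param mass Fish body mass, kg.
#' @param duration Length of the closed phase, min.
#' @param interval Sampling interval of the oxygen probe, min (2 min is
#'   the usual probe logging rate).
#' @param o2_start Dissolved oxygen at the start of the phase, mg L^-1.
#' @param noise_sd Probe noise standard deviation, mg L^-1.
#' @param speed Swimming speed during the phase, cm s^-1 (metadata).
#' @param seed Optional integer seed; identical seeds reproduce the trace.
#' @return An object of class `o2_trace`: a list with `times` (min),
#'   `o2` (mg L^-1), `resp_volume`, `fish_volume`, `mass`, `speed`, and
#'   the ground-truth `mo2_true`.
#' @examples
#' tr <- gen_o2_trace(mo2_true = 69.8, resp_volume = 3.5, fish_volume = 0.01,
#'                    mass = 0.05, duration = 20, noise_sd = 0, seed = 1)
#' estimate_slope(tr)
#' @export
gen_o2_trace <- function(mo2_true, resp_volume = 3.5, fish_volume = NULL,
                         mass = 0.05, duration = 20, interval = 2,
                         o2_start = 8, noise_sd = 0.02, speed = NA_real_,
                         seed = NULL) {
  check_positive(mo2_true, "mo2_true")
  check_positive(resp_volume, "resp_volume")
  check_positive(mass, "mass")
  check_positive(duration, "duration")
  check_positive(interval, "interval")
  check_nonneg(noise_sd, "noise_sd")
  if (is.null(fish_volume)) fish_volume <- mass  # neutral buoyancy, 1 kg/L
  check_positive(fish_volume, "fish_volume")
  if (resp_volume <= fish_volume) {
    stop("`resp_volume` must exceed `fish_volume`", call. = FALSE)
  }
  if (duration < 2 * interval) {
    stop("`duration` must cover at least two sampling intervals",
         call. = FALSE)
  }
  maybe_seed(seed)
  times <- seq(0, duration, by = interval)
  slope_per_h <- mo2_true * mass / (resp_volume - fish_volume)  # mg/L/h
  o2 <- o2_start - slope_per_h * times / 60
  if (noise_sd > 0) o2 <- o2 + stats::rnorm(length(times), 0, noise_sd)
  structure(
    list(times = times, o2 = o2, resp_volume = resp_volume,
         fish_volume = fish_volume, mass = mass, speed = speed,
         mo2_true = mo2_true),
    class = "o2_trace"
  )
}

#' Simulate an incremental-velocity (Ucrit) swim trial
#'
#' Produces the step protocol record of a critical-swimming-speed test in
#' which water velocity rises by `delta_v` every `period` minutes until the
#' fish fatigues. The fish is given a true critical speed `true_ucrit`;
#' fatigue occurs in the step whose speed is the largest completed speed
#' not exceeding `true_ucrit`, after a partial time
#' `t = (true_ucrit - V) / delta_v * period`. A `true_ucrit` exactly on a
#' step speed fatigues at `t = 0` of that step, so Brett's equation applied
#' to the output recovers `true_ucrit` exactly for any target on or off
#' the step grid.
#'
#' @param true_ucrit Ground-truth critical swimming speed, cm s^-1.
#' @param delta_v Velocity increment per step, cm s^-1 (default 6).
#' @param period Prescribed swimming period per step, min (default 30).
#' @param start_v Speed of the first step, cm s^-1.
#' @return An object of class `step_protocol`: list with `completed_speed`
#'   (V, cm s^-1), `time_at_final` (t, min), `delta_v`, `period`,
#'   `step_history` (data frame of speed and duration for every step
#'   swum), and `true_ucrit`.
#' @examples
#' compute_ucrit(gen_ucrit_trial(63))  # 63
#' @export
gen_ucrit_trial <- function(true_ucrit, delta_v = 6, period = 30,
                            start_v = 6) {
  check_positive(true_ucrit, "true_ucrit")
  check_positive(delta_v, "delta_v")
  check_positive(period, "period")
  check_positive(start_v, "start_v")
  if (true_ucrit <= start_v) {
    stop("`true_ucrit` must exceed `start_v`", call. = FALSE)
  }
  n_full <- floor((true_ucrit - start_v) / delta_v)
  v_final <- start_v + n_full * delta_v          # largest step speed <= truth
  t_final <- (true_ucrit - v_final) / delta_v * period
  speeds <- seq(start_v, v_final, by = delta_v)
  hist <- data.frame(speed = speeds,
                     duration = c(rep(period, length(speeds) - 1L), t_final))
  structure(
    list(completed_speed = v_final, time_at_final = t_final,
         delta_v = delta_v, period = period, step_history = hist,
         true_ucrit = true_ucrit),
    class = "step_protocol"
  )
}

#' Simulate metabolic rate across swimming speeds
#'
#' Draws mass-standardised oxygen consumption values from the exponential
#' swim-cost model `MO2 = alpha * exp(beta * U)` with multiplicative
#' Gaussian noise of coefficient of variation `cv`.
#'
#' @param alpha Metabolic rate at zero speed (routine metabolic rate),
#'   mg O2 kg^-1 h^-1.
#' @param beta Steepness of the power curve, (cm s^-1)^-1.
#' @param speeds Vector of swimming speeds, cm s^-1.
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param seed Optional integer seed.
#' @return Data frame with columns `speed` and `mo2`.
#' @examples
#' gen_mo2_speed_series(150, 0.02, speeds = c(0, 25, 50), cv = 0)
#' @export
gen_mo2_speed_series <- function(alpha, beta, speeds, cv = 0.05,
                                 seed = NULL) {
  check_positive(alpha, "alpha")
  check_positive(beta, "beta")
  check_nonneg(cv, "cv")
  if (length(speeds) == 0L || !is.numeric(speeds) || anyNA(speeds)) {
    stop("`speeds` must be a non-empty numeric vector", call. = FALSE)
  }
  maybe_seed(seed)
  mo2 <- alpha * exp(beta * speeds)
  if (cv > 0) mo2 <- mo2 * stats::rnorm(length(speeds), 1, cv)
  data.frame(speed = speeds, mo2 = mo2)
}

#' Write an oxygen trace to CSV
#'
#' Columns `time_min`, `o2_mg_per_l`; trace metadata (volumes, mass,
#' speed) is stored in `# key: value` header lines so a trace file is
#' self-contained.
#'
#' @param trace An `o2_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_o2_trace <- function(trace, path) {
  stopifnot(inherits(trace, "o2_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# resp_volume: %.6g", trace$resp_volume), con)
  writeLines(sprintf("# fish_volume: %.6g", trace$fish_volume), con)
  writeLines(sprintf("# mass: %.6g", trace$mass), con)
  writeLines(sprintf("# speed: %.6g", trace$speed), con)
  utils::write.csv(data.frame(time_min = trace$times,
                              o2_mg_per_l = trace$o2),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read an oxygen trace written by [write_o2_trace()]
#'
#' @param path CSV path with `# key: value` metadata header.
#' @return An `o2_trace` (without ground truth).
#' @export
read_o2_trace <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), ":\\s*")[[1]]
    meta[[kv[1]]] <- as.numeric(kv[2])
  }
  body <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  structure(
    list(times = body$time_min, o2 = body$o2_mg_per_l,
         resp_volume = meta$resp_volume, fish_volume = meta$fish_volume,
         mass = meta$mass, speed = meta$speed, mo2_true = NA_real_),
    class = "o2_trace"
  )
}
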