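# Generators: printed site values, seeded determinism, ground-truth
# round trips at zero noise, and parameter validation.

test_that("built-in site table carries the published site ecology", {
  sites <- builtin_site_table()
  expect_equal(nrow(sites), 5L)
  expect_setequal(sites$site_id, c("YJ", "HK", "SN", "SD", "DG"))
  dg <- sites[sites$site_id == "DG", ]
  expect_equal(dg$river_slope_permille, 3.65)
  expect_equal(dg$water_velocity_m_s, 2.32)
  expect_equal(sites$dissolved_oxygen_pct_sat[sites$site_id == "YJ"], 102.0)
  expect_true(all(sites$predator_abundance_pct >= 0 &
                    sites$predator_abundance_pct <= 100))
  expect_true(all(sites$dissolved_oxygen_pct_sat > 0))
  # tributary pairs exist in lower and middle reaches only
  expect_equal(sum(sites$stream == "tributary"), 2L)
})

test_that("oxygen traces deplete at the theoretical slope and are seeded", {
  tr <- gen_o2_trace(mo2_true = 69.8, resp_volume = 3.5,
                     fish_volume = 0.01, mass = 0.05, duration = 20,
                     interval = 2, noise_sd = 0)
  # 69.8 * 0.05 / 3.49 = 1.0 mg/L/h
  expect_equal(estimate_slope(tr)$slope, 1.0, tolerance = 1e-12)
  t1 <- gen_o2_trace(200, noise_sd = 0.05, seed = 7)
  t2 <- gen_o2_trace(200, noise_sd = 0.05, seed = 7)
  expect_identical(t1$o2, t2$o2)
  expect_error(gen_o2_trace(100, resp_volume = 0.01, fish_volume = 0.05),
               "exceed")
  expect_error(gen_o2_trace(-5), "positive")
})

test_that("noisy traces still recover the slope within a few percent", {
  tr <- gen_o2_trace(200, mass = 0.05, duration = 20, interval = 2,
                     noise_sd = 0.02, seed = 7)
  truth <- 200 * tr$mass / (tr$resp_volume - tr$fish_volume)
  est <- estimate_slope(tr)
  expect_lt(abs(est$slope - truth) / truth, 0.05)
  expect_equal(est$slope, -oracle_slope(tr$times, tr$o2) * 60,
               tolerance = 1e-10)
})

test_that("ucrit trials place fatigue so Brett's equation inverts exactly", {
  tr <- gen_ucrit_trial(63, delta_v = 6, period = 30, start_v = 6)
  expect_equal(tr$completed_speed, 60)
  expect_equal(tr$time_at_final, 15)
  # a target on the step grid fatigues at t = 0 of that step
  tr0 <- gen_ucrit_trial(60, 6, 30, 6)
  expect_equal(tr0$completed_speed, 60)
  expect_equal(tr0$time_at_final, 0)
  # non-final steps all last the full period
  expect_true(all(tr$step_history$duration[-nrow(tr$step_history)] == 30))
  expect_error(gen_ucrit_trial(5, start_v = 6), "exceed")
})

test_that("mo2-speed series follow alpha*exp(beta*U) exactly at cv 0", {
  s <- gen_mo2_speed_series(150, 0.02, speeds = c(0, 50), cv = 0)
  expect_equal(s$mo2[1], 150)
  expect_equal(s$mo2[2], 150 * exp(1))
  expect_error(gen_mo2_speed_series(150, 0.02, speeds = numeric(0)),
               "non-empty")
  a <- gen_mo2_speed_series(150, 0.02, 1:10, cv = 0.1, seed = 3)
  b <- gen_mo2_speed_series(150, 0.02, 1:10, cv = 0.1, seed = 3)
  expect_identical(a$mo2, b$mo2)
})

test_that("fast-start trajectories respect the frame grid and burst size", {
  tj <- gen_fast_start_traj(stim_frame = 50, latency_ms = 12, fps = 500,
                            noise_sd = 0, seed = 1)
  d <- sqrt(diff(tj$x)^2 + diff(tj$y)^2)
  expect_equal(which(d > 1e-9)[1], 50L + 6L)  # 12 ms = 6 frames
  # latency between frames snaps to the grid
  tj2 <- gen_fast_start_traj(latency_ms = 11, fps = 500, noise_sd = 0,
                             seed = 1)
  expect_true(tj2$truth$latency_ms %in% c(10, 12))
  expect_error(gen_fast_start_traj(n_frames = 60, stim_frame = 50),
               "too small")
})

test_that("landmark sets have the requested geometry and ground truth", {
  lm0 <- gen_landmarks(6, 17, deformation_magnitude = 0, noise_sd = 0,
                       seed = 2)
  expect_equal(dim(lm0), c(17L, 2L, 6L))
  for (i in 2:6) {
    expect_lt(procrustes_distance(lm0[, , 1], lm0[, , i]), 1e-10)
  }
  expect_length(attr(lm0, "covariate"), 6L)
  expect_error(gen_landmarks(5, k = 3), ">= 4")
  expect_error(gen_landmarks(1), ">= 2")
})

test_that("sequence sets hit their divergence targets", {
  s0 <- gen_sequences(2, 3, 500, within_d = 0, between_d = 0.01, seed = 4)
  within_pairs <- combn(1:3, 2)
  for (j in seq_len(ncol(within_pairs))) {
    expect_equal(
      k2p_distance(s0$sequences[within_pairs[1, j]],
                   s0$sequences[within_pairs[2, j]])$d, 0)
  }
  a <- gen_sequences(3, 2, 300, seed = 9)
  b <- gen_sequences(3, 2, 300, seed = 9)
  expect_identical(a$sequences, b$sequences)
  # long alignment: between-group mean converges on the target
  sl <- gen_sequences(2, 4, 10000, within_d = 0.002, between_d = 0.02,
                      seed = 11)
  gm <- group_mean_distances(pairwise_matrix(sl), sl$groups)
  expect_gt(gm$between_mean, 0.018)
  expect_lt(gm$between_mean, 0.022)
})

test_that("trace, trajectory, TPS and FASTA writers round-trip", {
  td <- withr::local_tempdir()
  tr <- gen_o2_trace(150, noise_sd = 0.01, seed = 5, speed = 24)
  f <- write_o2_trace(tr, file.path(td, "trace.csv"))
  tr2 <- read_o2_trace(f)
  expect_equal(tr2$o2, tr$o2, tolerance = 1e-6)
  expect_equal(tr2$speed, 24)
  expect_equal(compute_mo2(estimate_slope(tr2)$slope, tr2),
               compute_mo2(estimate_slope(tr)$slope, tr), tolerance = 1e-5)

  tj <- gen_fast_start_traj(noise_sd = 0.02, seed = 5)
  f2 <- write_fast_start_traj(tj, file.path(td, "traj.csv"))
  tj2 <- read_fast_start_traj(f2)
  expect_equal(tj2$fps, 500)
  expect_equal(detect_response_latency(tj2), detect_response_latency(tj))

  lms <- gen_landmarks(4, 17, seed = 6)
  f3 <- write_tps(lms, file.path(td, "shapes.tps"))
  arr <- read_tps(f3)
  expect_equal(dim(arr), c(17L, 2L, 4L))
  expect_equal(unname(arr[, , 2]), unname(lms[, , 2]), tolerance = 1e-9)

  sq <- gen_sequences(2, 2, 100, seed = 7)
  f4 <- write_fasta(sq, file.path(td, "aln.fa"))
  aln <- read_fasta_alignment(f4)
  expect_identical(unname(aln), unname(sq$sequences))
})
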