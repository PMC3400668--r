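# Slope estimation, QC filtering, MO2 arithmetic, mass standardisation
# and MMR extraction.

make_trace <- function(times, o2, resp_volume = 3.5, fish_volume = 0.01,
                       mass = 0.05, speed = NA_real_) {
  structure(list(times = times, o2 = o2, resp_volume = resp_volume,
                 fish_volume = fish_volume, mass = mass, speed = speed,
                 mo2_true = NA_real_), class = "o2_trace")
}

test_that("estimate_slope recovers exact lines and flags degenerate input", {
  t_min <- seq(0, 60, by = 2)
  tr <- make_trace(t_min, 8 - 0.5 * t_min / 60)   # 0.5 mg/L per hour
  est <- estimate_slope(tr)
  expect_equal(est$slope, 0.5, tolerance = 1e-12)
  expect_equal(est$r2, 1, tolerance = 1e-12)

  flat <- make_trace(t_min, rep(8, length(t_min)))
  est_flat <- estimate_slope(flat)
  expect_equal(est_flat$slope, 0)
  expect_true(is.nan(est_flat$r2))
  rec <- metabolic_record(flat)
  expect_false(rec$passed_qc)

  expect_error(estimate_slope(make_trace(c(0, 2), c(8, 7))), "3 samples")
})

test_that("estimate_slope matches the normal-equations oracle on noise", {
  set.seed(42)
  for (i in 1:10) {
    t_min <- seq(0, 20, by = 2)
    o2 <- 8 - 0.01 * t_min + rnorm(length(t_min), 0, 0.05)
    est <- estimate_slope(make_trace(t_min, o2))
    expect_equal(est$slope, -oracle_slope(t_min, o2) * 60,
                 tolerance = 1e-10)
  }
})

test_that("qc_filter applies the strict r2 threshold and is idempotent", {
  recs <- data.frame(speed = c(6, 12, 18, 24),
                     slope = c(1, 1, 1, -0.2),
                     r2 = c(0.96, 0.95, 0.99, 0.99),
                     mo2 = 1:4, mo2_std = 1:4,
                     passed_qc = NA)
  out <- qc_filter(recs)
  expect_equal(out$speed, c(6, 18))       # 0.95 exactly is dropped
  expect_true(all(out$passed_qc))
  expect_identical(qc_filter(out), out)   # idempotent
  empty <- recs[0, ]
  expect_equal(nrow(qc_filter(empty)), 0L)
  # an oxygen-increasing phase (negative consumption) is non-physical
  expect_false(24 %in% out$speed)
})

test_that("compute_mo2 is the effective-volume arithmetic", {
  tr <- make_trace(0:10, rep(8, 11), resp_volume = 3.5,
                   fish_volume = 0.01, mass = 0.05)
  expect_equal(compute_mo2(1.0, tr), 1.0 * 3.49 / 0.05)
  expect_equal(compute_mo2(0, tr), 0)
  set.seed(1)
  for (i in 1:20) {
    vol <- runif(1, 1, 5); fv <- runif(1, 0.005, 0.5)
    m <- runif(1, 0.01, 0.2); sl <- runif(1, 0.1, 3)
    tri <- make_trace(0:5, rep(8, 6), vol + fv, fv, m)
    expect_equal(compute_mo2(sl, tri), sl * vol / m, tolerance = 1e-12)
  }
  bad <- make_trace(0:5, rep(8, 6), resp_volume = 0.01, fish_volume = 0.05)
  expect_error(compute_mo2(1, bad), "positive")
})

test_that("mass standardisation follows the 0.75 allometric exponent", {
  expect_equal(standardize_mass(100, 1), 100)
  expect_equal(standardize_mass(100, 0.0625), 50)  # 0.0625^0.25 = 0.5
  masses <- seq(0.01, 1, length.out = 20)
  vals <- standardize_mass(100, masses)
  expect_true(all(diff(vals) > 0))                 # monotone in mass
  expect_error(standardize_mass(100, 0), "positive")
})

test_that("MMR is the QC-filtered maximum of standardised rates", {
  recs <- data.frame(speed = c(6, 12, 18),
                     slope = c(1, 1, 1),
                     r2 = c(0.99, 0.99, 0.99),
                     mo2 = c(120, 300, 280),
                     mo2_std = c(120, 300, 280), passed_qc = NA)
  expect_equal(extract_mmr(recs), 300)
  expect_equal(extract_mmr(recs[1, ]), 120)
  # the largest value fails QC: next largest wins
  recs$r2[2] <- 0.90
  expect_equal(extract_mmr(recs), 280)
  recs$r2 <- 0.5
  expect_error(extract_mmr(recs), "QC-passing")
})

test_that("the trace -> MO2 pipeline is linear and exact when noiseless", {
  for (mo2_true in c(80, 160, 320)) {
    tr <- gen_o2_trace(mo2_true, mass = 0.05, duration = 20,
                       noise_sd = 0)
    got <- compute_mo2(estimate_slope(tr)$slope, tr)
    expect_lt(abs(got - mo2_true) / mo2_true, 1e-9)
  }
  # scaling depletion by c scales MO2 by exactly c
  tr1 <- gen_o2_trace(100, noise_sd = 0)
  tr3 <- tr1; tr3$o2 <- tr3$o2[1] + 3 * (tr3$o2 - tr3$o2[1])
  expect_equal(compute_mo2(estimate_slope(tr3)$slope, tr3),
               3 * compute_mo2(estimate_slope(tr1)$slope, tr1),
               tolerance = 1e-12)
})
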