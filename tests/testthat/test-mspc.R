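test_that("perfect coupling gives 1 regardless of constant offsets", {
  set.seed(51)
  for (case in 1:20) {
    K <- sample(3:40, 1)
    R <- sample(1:3, 1)
    w <- sample(c(-3:-1, 1:3), R, replace = TRUE)
    inp <- matrix(runif(K * R, -pi, pi), K, R)
    out <- as.vector(inp %*% w) + runif(1, -10, 10)   # arbitrary constant
    expect_equal(mspc(inp, out, w), 1, tolerance = 1e-12)
  }
})

test_that("a single epoch is degenerate and flagged", {
  expect_equal(mspc(cbind(0.3, 1.1), 2.2, c(1, 1)), 1)
  sched <- exp1_sched()
  p <- cascade_params(tau_jitter_sd = 0, noise_level = 0,
                      fs = 250, epoch_len = 5)
  tr <- simulate_trial(sched, p, rng_seed = 1)
  # a trial barely longer than one epoch yields K = 1, marked degenerate
  short <- tr$recording
  short$data <- short$data[, 1:round(6 * 250)]
  sched_short <- sched; sched_short$duration <- 6
  r <- mspc_trial(short, sched_short, enumerate_ims(1.2, 15, 2),
                  "stim", 5)
  expect_true(all(r$degenerate))
  expect_equal(r$value, rep(1, nrow(r)), tolerance = 1e-12)
})

test_that("vectorised statistic matches a naive complex sum", {
  set.seed(52)
  for (case in 1:1000) {
    K <- sample(2:30, 1)
    R <- sample(1:3, 1)
    w <- sample(c(-4:-1, 1:4), R, replace = TRUE)
    inp <- matrix(runif(K * R, -pi, pi), K, R)
    out <- runif(K, -pi, pi)
    v <- mspc(inp, out, w)
    expect_equal(v, mspc_naive(inp, out, w), tolerance = 1e-12)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("input validation rejects malformed phase sets", {
  expect_error(mspc(matrix(0, 0, 2), numeric(0), c(1, 1)), "epochs")
  expect_error(mspc(matrix(0, 5, 2), numeric(4), c(1, 1)), "counts differ")
  expect_error(mspc(matrix(0, 5, 2), numeric(5), 1), "match")
  expect_error(mspc(matrix(c(NA, runif(9)), 5, 2), runif(5), c(1, 1)),
               "missing")
  expect_error(mspc_spec(c(1.2, 15), c(1, 0)), "non-zero")
  expect_error(mspc_spec(c(1.2, 15), c(1, 1), output_freq = 10), "equal")
})

test_that("phase-locking value handles constant and random differences", {
  expect_equal(plv(rep(0.7, 20)), 1)
  expect_equal(plv(rep(pi, 20)), 1)   # consistency, not agreement
  set.seed(53)
  vals <- vapply(1:2000, function(i) plv(runif(100, -pi, pi)), numeric(1))
  expect_equal(mean(vals), sqrt(pi) / 2 / sqrt(100), tolerance = 0.02)
})

test_that("offset invariance holds for weighted multi-input sets", {
  set.seed(54)
  K <- 25
  w <- c(2, -1)
  inp <- matrix(runif(K * 2, -pi, pi), K, 2)
  out <- runif(K, -pi, pi)
  base <- mspc(inp, out, w)
  offs <- c(0.4, -1.3)
  shifted <- mspc(sweep(inp, 2, offs, `+`), out + sum(w * offs), w)
  expect_equal(shifted, base, tolerance = 1e-12)
})

test_that("null calibration approaches the Rayleigh expectation", {
  nc <- null_calibrate(K = 100, n_perm = 3000, rng_seed = 5)
  expect_equal(nc$null_mean, nc$rayleigh, tolerance = 0.05)
  expect_gt(nc$threshold_95, nc$null_mean)
  again <- null_calibrate(K = 100, n_perm = 3000, rng_seed = 5)
  expect_identical(nc, again)
  expect_true(null_calibrate(K = 10, n_perm = 50, rng_seed = 1)$warn_small)
  # shuffling observed phases: coupled inputs decohere under permutation
  set.seed(55)
  inp <- matrix(runif(40, -pi, pi), 20, 2)
  out <- as.vector(inp %*% c(1, 1))
  perm <- null_calibrate(K = 20, n_perm = 500, rng_seed = 2,
                         input_phases = inp, output_phases = out,
                         weights = c(1, 1))
  expect_lt(perm$null_mean, 0.5)
  expect_lt(perm$threshold_95, 1)
})

test_that("constant delays leave the two reference variants identical", {
  sched <- exp1_sched()
  ims <- enumerate_ims(1.2, 15, 2)
  p <- cascade_params(g_low = 0.4, g_high = 0.4, tau_jitter_sd = 0,
                      noise_level = 0, fs = 250, epoch_len = 5)
  tr <- simulate_trial(sched, p, rng_seed = 7)
  r <- mspc_trial(tr$recording, sched, ims, "both", 5)
  wide <- reshape(r[, c("channel", "freq", "variant", "value")],
                  idvar = c("channel", "freq"), timevar = "variant",
                  direction = "wide")
  expect_lt(max(abs(wide$value.stim - wide$value.res)), 1e-6)
})

test_that("stimulus-referenced variant validates requested frequencies", {
  sched <- exp1_sched()
  p <- cascade_params(fs = 250, epoch_len = 5)
  tr <- simulate_trial(sched, p, rng_seed = 3)
  bad <- mspc_spec(c(2.0, 15), c(1, 1))
  expect_error(mspc_stim(tr$recording, sched, list(bad), 5), "not tagged")
})

test_that("generalized input sets express higher-order couplings", {
  sched <- exp1_sched()
  ims <- enumerate_ims(1.2, 15, 2)
  p <- cascade_params(g_low = 0.5, g_high = 0, tau_jitter_sd = 0,
                      noise_level = 0, fs = 250, epoch_len = 5)
  tr <- simulate_trial(sched, p, rng_seed = 11)
  # fourth-order component 2f1 + 2f2 referenced to the second harmonics
  spec_h <- mspc_spec(c(2 * 1.2, 2 * 15), c(1, 1))
  expect_equal(spec_h$output_freq, 32.4)
  r <- mspc_res(tr$recording, sched, list(spec_h), 5)
  expect_true(all(r$value >= 0 & r$value <= 1))
  # same spec via weights 2,2 on the fundamentals reaches the same bin
  spec_w <- mspc_spec(c(1.2, 15), c(2, 2))
  expect_equal(spec_w$output_freq, spec_h$output_freq)
})
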