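test_that("summary currents reproduce hand-computable cases", {
  zero <- manual_sweep_set(matrix(0, 100, 1), n_hold = 20)
  expect_equal(unname(summary_current(zero, "peak")), 0)
  expect_equal(unname(summary_current(zero, "end_of_step")), 0)
  plateau <- manual_sweep_set(matrix(c(rep(5, 20), rep(105, 80))), n_hold = 20)
  expect_equal(unname(summary_current(plateau, "peak")), 100)
  expect_equal(unname(summary_current(plateau, "end_of_step")), 100)
  expect_error(summary_current(plateau, window_ms = c(200, 300)),
               "empty measurement window")
})

test_that("A-type sweeps give peak >> end-of-step with late mean near leak", {
  s0 <- simulate_sweeps(noiseless_cell(channel_preset("a_type")),
                        protocol_preset("sustained_1000ms"),
                        bath_preset("ames"))
  pk0 <- summary_current(s0, "peak")[["40"]]
  eos0 <- summary_current(s0, "end_of_step")[["40"]]
  expect_gt(pk0, 10 * abs(eos0))   # complete inactivation
  # with an ohmic leak the late baseline-subtracted mean is the leak step
  cell <- cell_spec(channels = list(channel_preset("a_type")),
                    leak_conductance_nS = 0.5, noise_sd_pA = 0)
  s <- simulate_sweeps(cell, protocol_preset("sustained_1000ms"),
                       bath_preset("ames"))
  eos <- summary_current(s, "end_of_step")[["40"]]
  leak_step <- 0.5 * (40 - (-70))
  expect_equal(eos, leak_step, tolerance = 0.02)
})

test_that("peak extraction equals the brute-force extremum oracle", {
  set.seed(21)
  for (rep in 1:10) {
    n_hold <- sample(20:60, 1)
    n_step <- sample(50:300, 1)
    traces <- sapply(1:6, function(j)
      cumsum(rnorm(n_hold + n_step, 0, 3)))   # random-walk traces
    s <- manual_sweep_set(traces, n_hold = n_hold)
    expect_equal(unname(summary_current(s, "peak")), peak_oracle(s))
    win <- sort(runif(2, 0, n_step - 1))
    if (diff(win) > 2)
      expect_equal(unname(summary_current(s, "peak", window_ms = win)),
                   peak_oracle(s, window_ms = win))
  }
})

test_that("an ohmic cell yields a straight IV through the leak reversal", {
  cell <- cell_spec(channels = list(), leak_conductance_nS = 1.25,
                    leak_erev_mV = -20, noise_sd_pA = 0)
  s <- simulate_sweeps(cell, protocol_preset("kir_iv"), bath_preset("ames"))
  iv <- build_iv(s, "peak")
  fit <- stats::lm(iv$currents_pA ~ iv$voltages_mV)
  slope <- unname(coef(fit)[2])
  expect_equal(slope, 1.25, tolerance = 0.005)
  # baseline subtraction pins the line to zero at the holding potential;
  # the raw IV passes through (leak_erev, 0)
  raw <- summary_current(s, "peak", baseline = FALSE)
  x0 <- -unname(coef(lm(raw ~ iv$voltages_mV))[1]) / slope
  expect_equal(x0, -20, tolerance = 0.1)
})

test_that("delayed-rectifier IV activates near -30 mV and grows above", {
  s <- simulate_sweeps(noiseless_cell(channel_preset("delayed_rectifier")),
                       protocol_preset("outward_50ms"), bath_preset("ames"))
  iv <- build_iv(s, "peak")
  expect_true(all(abs(iv$currents_pA[iv$voltages_mV < -30]) < 10))
  up <- iv$currents_pA[iv$voltages_mV >= -25]
  expect_true(all(diff(up) > 0))
  expect_gt(max(up), 80)
})

test_that("kir IV in the Na+ bath turns inward below about -70 mV", {
  s <- simulate_sweeps(noiseless_cell(channel_preset("kir")),
                       protocol_preset("kir_iv"), bath_preset("na_based"))
  raw <- summary_current(s, "peak", baseline = FALSE)
  v <- sweep_potentials(s)
  expect_true(all(raw[v <= -95] < 0))
  expect_true(all(diff(raw[v <= -75]) > 0))  # more inward as V drops
})

test_that("normalization pins the reference, is idempotent and scale-free", {
  s <- simulate_sweeps(noiseless_cell(channel_preset("delayed_rectifier")),
                       protocol_preset("outward_50ms"), bath_preset("ames"))
  iv <- build_iv(s, "peak")
  nv <- normalize_iv(iv, 45)
  expect_equal(nv$currents_pA[nv$voltages_mV == 45], 1)
  expect_equal(normalize_iv(nv, 45)$currents_pA, nv$currents_pA)
  # commutes with a positive rescaling of every trace
  s2 <- s; s2$sweeps <- s$sweeps * 3.7
  nv2 <- normalize_iv(build_iv(s2, "peak"), 45)
  expect_equal(nv2$currents_pA, nv$currents_pA, tolerance = 1e-12)
  expect_error(normalize_iv(iv, 44), "not present")
  flat <- iv_curve(c(-10, 0), c(0, 5))
  expect_error(normalize_iv(flat, -10), "zero current")
})

test_that("averaging IV curves gives pointwise mean and SEM", {
  a <- iv_curve(c(-10, 0, 10), c(0, 0, 0))
  b <- iv_curve(c(-10, 0, 10), c(2, 2, 2))
  av <- average_ivs(list(a, b))
  expect_equal(av$currents_pA, c(1, 1, 1))
  expect_equal(av$sem_pA, c(1, 1, 1))   # sd = sqrt(2), sem = 1
  expect_equal(av$n, 2L)
  same <- average_ivs(list(a, a, a))
  expect_equal(same$currents_pA, a$currents_pA)
  expect_equal(same$sem_pA, c(0, 0, 0))
  expect_warning(one <- average_ivs(list(a)), "SEM reported as 0")
  expect_equal(one$sem_pA, c(0, 0, 0))
  expect_error(average_ivs(list(a, iv_curve(c(-10, 0), c(1, 1)))),
               "mismatched")
})

test_that("per-cell normalization pins the reference point of the average", {
  cells <- lapply(1:5, function(i)
    cell_spec(channels = list(channel_preset("delayed_rectifier",
                                             gmax_nS = 0.3 + 0.2 * i)),
              leak_conductance_nS = 0, noise_sd_pA = 0))
  ivs <- lapply(cells, function(cl)
    normalize_iv(build_iv(simulate_sweeps(cl, protocol_preset("outward_50ms"),
                                          bath_preset("ames")), "peak"), 45))
  av <- average_ivs(ivs)
  expect_equal(av$currents_pA[av$voltages_mV == 45], 1)
  expect_equal(av$sem_pA[av$voltages_mV == 45], 0)
})

test_that("percent change follows the amplitude convention", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(100, 21), -79)
  expect_equal(percent_change(-10, -41.9), 319)
  expect_error(percent_change(0, 10), "zero control")
  expect_warning(percent_change(-10, 10), "differ in sign")
})

test_that("a pure conductance block reads as exactly that percent block", {
  cell <- noiseless_cell(channel_preset("delayed_rectifier"))
  blocked <- cell
  blocked$channels[[1]]$gmax_nS <- cell$channels[[1]]$gmax_nS * 0.37
  p <- protocol_preset("outward_50ms")
  i0 <- summary_current(simulate_sweeps(cell, p, bath_preset("ames")),
                        "peak")[["45"]]
  i1 <- summary_current(simulate_sweeps(blocked, p, bath_preset("ames")),
                        "peak")[["45"]]
  expect_equal(percent_change(i0, i1), -63, tolerance = 0.01)
})
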