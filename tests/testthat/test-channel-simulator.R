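test_that("steady-state activation hits its midpoint, limits and symmetry", {
  expect_equal(steady_state_open(-37.2, -37.2, 25.7), 0.5)
  expect_equal(steady_state_open(1e4, -37.2, 25.7), 1)
  expect_equal(steady_state_open(-1e4, -37.2, 25.7), 0)
  expect_equal(steady_state_open(-10, -37.2, 25.7), 0.742, tolerance = 1e-3)
  expect_error(steady_state_open(0, 0, 0), "positive")
  expect_error(steady_state_open(0, 0, -5), "positive")
  v <- seq(-150, 50, 1)
  expect_true(all(diff(steady_state_open(v, -37.2, 25.7)) > 0))
  for (x in seq(0, 80, 5))
    expect_equal(steady_state_open(-37.2 + x, -37.2, 25.7) +
                 steady_state_open(-37.2 - x, -37.2, 25.7), 1)
})

test_that("channel model invariants are enforced per family", {
  expect_error(channel_model("m_current", gmax_nS = -1, act_vhalf_mV = -37,
                             act_slope_mV = 25, act_tau_ms = 150),
               "non-negative")
  expect_error(channel_model("m_current", 1, act_vhalf_mV = -37,
                             act_slope_mV = -1, act_tau_ms = 150), "positive")
  expect_error(channel_preset("delayed_rectifier", inact_vhalf_mV = -60,
                              inact_slope_mV = 8, inact_tau_ms = 50),
               "a_type")
  expect_error(channel_preset("m_current", rect_vhalf_mV = -60,
                              rect_slope_mV = 20), "kir-only")
  expect_error(channel_model("kir", 1), "rect_")
  expect_silent(channel_preset("a_type"))
})

test_that("current is exactly zero at the reversal potential", {
  for (fam in c("delayed_rectifier", "m_current", "a_type", "kir")) {
    ch <- channel_preset(fam, erev_mV = -86)
    cell <- noiseless_cell(ch)
    prot <- voltage_protocol(-86, -86, -86, 10, 50)
    s <- simulate_sweeps(cell, prot, bath_preset("ames"))
    expect_lt(max(abs(s$sweeps)), 1e-12)
  }
})

test_that("halving the sample interval leaves shared samples unchanged", {
  cell <- noiseless_cell(channel_preset("m_current"),
                         channel_preset("a_type"))
  s1 <- simulate_sweeps(cell, protocol_preset("sustained_1000ms", 0.2),
                        bath_preset("ames"))
  s2 <- simulate_sweeps(cell, protocol_preset("sustained_1000ms", 0.1),
                        bath_preset("ames"))
  shared <- match(s1$time_ms, s2$time_ms)
  expect_false(any(is.na(shared)))
  rel <- abs(s2$sweeps[shared, ] - s1$sweeps) /
    pmax(abs(s1$sweeps), 1e-6)
  expect_lt(max(rel), 1e-3)   # exponential gate updates are exact in dt
})

test_that("M-current late amplitude at +40 mV is of order hundreds of pA", {
  s <- simulate_sweeps(m_cell(), protocol_preset("sustained_1000ms"),
                       bath_preset("ames"))
  i40 <- summary_current(s, "end_of_step")[["40"]]
  expect_gt(i40, 100)
  expect_lt(i40, 1000)
})

test_that("A-type current inactivates essentially completely within 1 s", {
  s <- simulate_sweeps(noiseless_cell(channel_preset("a_type")),
                       protocol_preset("sustained_1000ms"),
                       bath_preset("ames"))
  pk <- summary_current(s, "peak")[["40"]]
  eos <- summary_current(s, "end_of_step")[["40"]]
  expect_gt(pk, 50)
  expect_lt(eos / pk, 0.05)
})

test_that("M-current end-of-step current is non-decreasing in duration", {
  prev <- -Inf
  for (dur in c(100, 250, 500, 1000, 2000)) {
    p <- voltage_protocol(-70, 40, 40, 10, dur)
    s <- simulate_sweeps(m_cell(), p, bath_preset("ames"))
    eos <- summary_current(s, "end_of_step")[[1]]
    expect_gte(eos, prev)
    prev <- eos
  }
})

test_that("kir rectifies inward: |I(-145)| exceeds |I(+45)|", {
  s <- simulate_sweeps(noiseless_cell(channel_preset("kir")),
                       protocol_preset("kir_iv"), bath_preset("na_based"))
  i <- summary_current(s, "peak", baseline = FALSE)
  expect_lt(i[["-145"]], 0)
  expect_gt(abs(i[["-145"]]), abs(i[["45"]]))
})

test_that("simulation is deterministic given the cell seed", {
  cell <- cell_spec(channels = list(channel_preset("delayed_rectifier")),
                    noise_sd_pA = 3, seed = 99)
  s1 <- simulate_sweeps(cell, protocol_preset("outward_50ms"),
                        bath_preset("ames"))
  s2 <- simulate_sweeps(cell, protocol_preset("outward_50ms"),
                        bath_preset("ames"))
  expect_identical(s1$sweeps, s2$sweeps)
  cell2 <- cell_spec(channels = cell$channels, noise_sd_pA = 3, seed = 100)
  s3 <- simulate_sweeps(cell2, protocol_preset("outward_50ms"),
                        bath_preset("ames"))
  expect_false(identical(s1$sweeps, s3$sweeps))
})

test_that("modifiers scale conductances as configured", {
  cell <- cell_spec(channels = list(channel_preset("delayed_rectifier"),
                                    channel_preset("kir")))
  same <- apply_modifier(cell, "no_such_drug")
  expect_equal(same$channels[[1]]$gmax_nS, cell$channels[[1]]$gmax_nS)
  expect_error(apply_modifier(cell, "no_such_drug", strict = TRUE),
               "unknown modifier")
  rb <- apply_modifier(cell, "rb")
  expect_equal(rb$channels[[2]]$gmax_nS, 0.809 * 1.523)
  expect_equal(rb$channels[[1]]$gmax_nS, cell$channels[[1]]$gmax_nS)
  ba <- apply_modifier(cell, "ba2")
  expect_equal(ba$channels[[1]]$gmax_nS, 0.72 * 0.21)
})

test_that("a command-potential simulation shifts the membrane by the LJP", {
  cell <- noiseless_cell(channel_preset("kir"))
  na <- bath_preset("na_based")
  p_cmd <- voltage_protocol(-45, -100, -100, 10, 50)
  s_cmd <- simulate_sweeps(cell, p_cmd, na, potentials = "command")
  # same membrane potentials driven directly
  p_mem <- voltage_protocol(-56, -111, -111, 10, 50)
  s_mem <- simulate_sweeps(cell, p_mem, na, potentials = "membrane")
  expect_equal(s_cmd$sweeps, s_mem$sweeps, ignore_attr = TRUE)
  expect_false(s_cmd$ljp_applied)
  expect_equal(sweep_potentials(s_cmd), -111)
})

test_that("non-finite channel parameters abort the simulation", {
  ch <- channel_preset("m_current")
  ch$act_tau_ms <- NaN
  cell <- cell_spec(channels = list(ch))
  expect_error(simulate_sweeps(cell, protocol_preset("outward_50ms"),
                               bath_preset("ames")), "non-finite")
})
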