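# Shared fixture: the three survey protocols at a 0.5 ms sample interval
# (classification windows are insensitive to the grid).
.cls_protocols <- list(protocol_preset("outward_50ms", 0.5),
                       protocol_preset("sustained_1000ms", 0.5),
                       protocol_preset("kir_iv", 0.5))
.cls_baths <- list(bath_preset("ames"), bath_preset("ames"),
                   bath_preset("na_based"))

.record <- function(cell)
  lapply(seq_along(.cls_protocols), function(k)
    simulate_sweeps(cell, .cls_protocols[[k]], .cls_baths[[k]]))

test_that("a leak-only cell gets an empty label set", {
  cell <- cell_spec(channels = list(), noise_sd_pA = 3, seed = 5)
  res <- classify_cell(.record(cell))
  expect_length(res$labels, 0)
  expect_length(res$amplitude_at_reference_pA, 0)
})

test_that("a strong A-type cell is labelled a_type and nothing else", {
  cell <- cell_spec(channels = list(channel_preset("a_type")),
                    noise_sd_pA = 3, seed = 6)
  res <- classify_cell(.record(cell))
  expect_identical(res$labels, "a_type")
})

test_that("co-expressed current types are all recovered", {
  cell <- cell_spec(channels = list(channel_preset("delayed_rectifier"),
                                    channel_preset("m_current"),
                                    channel_preset("a_type"),
                                    channel_preset("kir")),
                    noise_sd_pA = 3, seed = 7)
  res <- classify_cell(.record(cell))
  expect_setequal(res$labels, c("delayed_rectifier", "m_current", "a_type",
                                "kir"))
  # template regression recovers the underlying conductances closely
  expect_equal(unname(res$gmax_nS[c("delayed_rectifier", "m_current",
                                    "a_type", "kir")]),
               c(0.72, 1.8, 1.39, 0.809), tolerance = 0.02)
})

test_that("blocking one family below threshold removes exactly its label", {
  cell <- cell_spec(channels = list(channel_preset("delayed_rectifier"),
                                    channel_preset("m_current",
                                                   modifier_sensitivity =
                                                     list(blocker = 0.02))),
                    noise_sd_pA = 3, seed = 8)
  before <- classify_cell(.record(cell))
  expect_setequal(before$labels, c("delayed_rectifier", "m_current"))
  after <- classify_cell(.record(apply_modifier(cell, "blocker")))
  expect_identical(after$labels, "delayed_rectifier")
})

test_that("reference amplitudes are reported for assigned labels only", {
  cell <- cell_spec(channels = list(channel_preset("kir")),
                    noise_sd_pA = 0, seed = 9)
  res <- classify_cell(.record(cell))
  expect_identical(res$labels, "kir")
  expect_named(res$amplitude_at_reference_pA, "kir")
  amp <- res$amplitude_at_reference_pA$kir
  expect_equal(as.numeric(names(amp)), -145)
  expect_lt(amp, 0)
})

test_that("the interpretable threshold rules work on single-type cells", {
  # The amplitude-threshold rules do no leak subtraction, so they presume
  # recordings whose leak is small against the detection threshold.
  crit <- classification_criteria(method = "threshold")
  one <- function(ch, seed) cell_spec(channels = list(ch),
                                      leak_conductance_nS = 0.1,
                                      noise_sd_pA = 3, seed = seed)
  dr <- one(channel_preset("delayed_rectifier"), 10)
  expect_true("delayed_rectifier" %in% classify_cell(.record(dr), crit)$labels)
  at <- one(channel_preset("a_type"), 11)
  expect_true("a_type" %in% classify_cell(.record(at), crit)$labels)
  mc <- one(channel_preset("m_current"), 12)
  expect_true("m_current" %in% classify_cell(.record(mc), crit)$labels)
  kir <- one(channel_preset("kir"), 13)
  expect_true("kir" %in% classify_cell(.record(kir), crit)$labels)
  lk <- cell_spec(channels = list(), leak_conductance_nS = 0.1,
                  noise_sd_pA = 3, seed = 14)
  expect_length(classify_cell(.record(lk), crit)$labels, 0)
  # missing protocols degrade gracefully
  expect_warning(classify_cell(.record(dr)[2], crit), "partial")
})

test_that("population generation honours incidences, determinism and labels", {
  spec <- population_spec(400, seed = 31)
  pop <- generate_population(spec, protocol_preset("outward_50ms", 1),
                             bath_preset("ames"), keep_traces = FALSE)
  expect_length(pop$cells, 400)
  for (f in c("delayed_rectifier", "m_current", "a_type", "kir")) {
    k <- sum(pop$truth[[f]])
    ci <- stats::binom.test(k, 400)$conf.int
    expect_gte(spec$incidence[[f]], ci[1])
    expect_lte(spec$incidence[[f]], ci[2])
  }
  # zero incidence -> leak-only cells
  none <- population_spec(20, incidence = c(delayed_rectifier = 0,
                                            m_current = 0, a_type = 0,
                                            kir = 0), seed = 1)
  pop0 <- generate_population(none, protocol_preset("outward_50ms", 1),
                              bath_preset("ames"), keep_traces = FALSE)
  expect_true(all(vapply(pop0$cells, function(cl)
    length(cl$channels) == 0, TRUE)))
  # same master seed -> identical cohort, sweep for sweep
  small <- population_spec(5, seed = 77)
  p1 <- generate_population(small, protocol_preset("outward_50ms", 1),
                            bath_preset("ames"))
  p2 <- generate_population(small, protocol_preset("outward_50ms", 1),
                            bath_preset("ames"))
  expect_identical(p1$truth, p2$truth)
  for (i in 1:5)
    expect_identical(p1$sweeps[[i]][[1]]$sweeps, p2$sweeps[[i]][[1]]$sweeps)
})
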