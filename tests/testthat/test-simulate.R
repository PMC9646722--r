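# Numerical integration of the baseline model: spontaneous rhythm,
# sampling-grid contract, gate boundedness, quasi-stability and the
# homeostasis endpoints.

test_that("baseline model beats with hiPSC-like AP metrics", {
  tr <- fx_baseline_trace()
  expect_false(attr(tr, "quiescent"))
  expect_true(attr(tr, "quasi_stable"))
  m <- ap_metrics(tr)
  # plausibility bands spanned by spontaneously beating hiPSC-CM recordings
  expect_gt(m$CL_ms, 239.5); expect_lt(m$CL_ms, 1326.0)
  expect_gt(m$MDP_mV, -87.4); expect_lt(m$MDP_mV, -61.5)
  expect_gt(m$OS_mV, 13.8); expect_lt(m$OS_mV, 33.0)
  expect_gt(m$APD20_ms, 40); expect_lt(m$APD20_ms, m$CL_ms)
})

test_that("output is on an exact uniform grid", {
  tr <- fx_baseline_trace()
  dt <- diff(tr$time_ms)
  expect_equal(max(abs(dt - 0.1)), 0, tolerance = 1e-9)
  expect_true(all(is.finite(tr$vm_mV)))
})

test_that("gate open probabilities stay inside [0, 1] along a trajectory", {
  tr <- simulate_cell(fx_params(), n_cycles = 2, output_dt = 0.5,
                      keep_states = TRUE)
  st <- attr(tr, "states")
  gates <- st[, 1 + which(pacefit:::.state_order %in% pacefit:::.gate_names),
              drop = FALSE]
  expect_true(all(gates >= 0 & gates <= 1))
})

test_that("restarting from the final state preserves the rhythm", {
  p <- fx_params()
  tr1 <- simulate_cell(p, n_cycles = 3, output_dt = 0.5)
  tr2 <- simulate_cell(p, init = attr(tr1, "final_state"), n_cycles = 3,
                       output_dt = 0.5)
  cl1 <- utils::tail(attr(tr1, "cycle_lengths"), 1)
  cl2 <- utils::tail(attr(tr2, "cycle_lengths"), 1)
  expect_lt(abs(cl1 - cl2) / cl1, 0.005)
})

test_that("simulation is reproducible", {
  p <- fx_params()
  tr1 <- simulate_cell(p, n_cycles = 2, output_dt = 0.5)
  tr2 <- simulate_cell(p, n_cycles = 2, output_dt = 0.5)
  expect_identical(tr1$vm_mV, tr2$vm_mV)
})

test_that("homeostasis restores Na_i and Ca_tot from a 10% Na perturbation", {
  p <- fx_params()
  s <- baseline_state()
  s[["Na_i"]] <- s[["Na_i"]] * 1.1
  tr <- simulate_cell(p, init = pacefit:::as_cell_state(s), n_cycles = 100,
                      output_dt = 1, max_cycles = 110)
  ups <- attr(tr, "cycles")
  ix <- which.min(abs(tr$time_ms - ups[length(ups)]))
  expect_lt(abs(tr$Na_i[ix] - p$std_Nai) / p$std_Nai, 0.005)
  expect_lt(abs(tr$Ca_tot[ix] - p$std_Catot) / p$std_Catot, 0.005)
})

test_that("a quiescent parameter set is signalled, not an error", {
  # removing the depolarization drive silences the model
  tr <- simulate_cell(fx_params(),
                      sf = scaling_factors(bNSC = 0.05, ha = 0.05, Na = 0.2),
                      n_cycles = 5, output_dt = 1, quiescence_window = 1500)
  expect_true(attr(tr, "quiescent"))
})

test_that("current breakdown along a trace covers the roster", {
  tr <- simulate_cell(fx_params(), n_cycles = 1, output_dt = 1,
                      keep_states = TRUE)
  br <- current_breakdown(tr, fx_params())
  expect_setequal(unique(br$current), current_roster)
  expect_true(all(is.finite(br$pA)))
})
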