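# The MSE objective: identity, constant offsets, brute-force oracle,
# window additivity and quiescent-penalty handling.

test_that("identical traces give zero MSE and exact superposition", {
  tgt <- fx_target()
  al <- align_traces(tgt, tgt)
  expect_equal(al$vm_adaptive, al$vm_target, tolerance = 1e-9)
  expect_equal(trace_mse(tgt, tgt), 0)
})

test_that("a constant 2 mV offset gives exactly 4 mV^2", {
  tgt <- fx_target()
  shifted <- tgt
  shifted$vm_mV <- shifted$vm_mV + 2
  # registration must use the same crossing shift; the offset moves the
  # -20 mV crossing, so compare on a synthetic plateau-free square wave
  sq <- square_trace(n_cycles = 3)
  sq2 <- sq
  sq2$vm_mV <- sq2$vm_mV + 2
  expect_equal(trace_mse(sq2, sq), 4, tolerance = 0.05)
})

test_that("MSE matches an independent flat re-summation", {
  tgt <- fx_target()
  tr <- simulate_cell(fx_params(), sf = scaling_factors(Kr = 1.02),
                      n_cycles = 12, output_dt = 0.1)
  al <- align_traces(tr, tgt)
  oracle <- sum(al$weight * (al$vm_adaptive - al$vm_target)^2) /
    sum(al$weight)
  expect_equal(trace_mse(tr, tgt), oracle)
  expect_gt(oracle, 0)
})

test_that("aligning a trace against a whole-cycle shifted copy superposes", {
  # smooth periodic pulse (Gaussian AP surrogate) on the 0.1 ms grid
  pulse <- function(n_cycles, t0 = 0) {
    t <- seq(t0, t0 + n_cycles * 400 - 0.1, by = 0.1)
    v <- -80 + 100 * exp(-((t %% 400) - 100)^2 / (2 * 30^2))
    structure(tibble::tibble(time_ms = t - t0, vm_mV = v),
              class = c("ap_trace", "tbl_df", "tbl", "data.frame"),
              output_dt = 0.1)
  }
  p1 <- pulse(6)
  p2 <- pulse(6, t0 = 2 * 400)
  expect_lt(trace_mse(p2, p1), 1e-10)
})

test_that("full-cycle MSE is the weight-share mean of phase MSEs", {
  tgt <- fx_target()
  tr <- simulate_cell(fx_params(), sf = scaling_factors(CaL = 1.03),
                      n_cycles = 12, output_dt = 0.1)
  full <- trace_mse(tr, tgt, objective_spec("cycle"))
  phases <- c("plateau", "repolarization", "sdd")
  parts <- vapply(phases, function(ph) {
    al <- align_traces(tr, tgt, objective_spec(ph))
    c(sum(al$weight * (al$vm_adaptive - al$vm_target)^2), sum(al$weight))
  }, numeric(2))
  expect_equal(full, sum(parts[1, ]) / sum(parts[2, ]), tolerance = 1e-10)
})

test_that("quiescent adaptive traces receive the penalty MSE", {
  tgt <- fx_target()
  spec <- objective_spec(penalty_mse = 1e4)
  quiet <- structure(tibble::tibble(time_ms = 0, vm_mV = -70),
                     quiescent = TRUE)
  expect_equal(trace_mse(quiet, tgt, spec), 1e4)
})

test_that("cost closure is deterministic, cached, and floored at truth", {
  tgt <- fx_target()
  cost <- make_cost(tgt, fx_params())
  f1 <- cost(c(Kr = 1))
  f2 <- cost(c(Kr = 1))
  expect_identical(f1, f2)
  expect_lt(f1, 1e-4)            # near-zero floor at the generating factors
  expect_gt(cost(c(Kr = 1.05)), 100 * f1)
  expect_identical(cost(c(Kr = -0.2)), Inf)
  info <- cost_info(cost)
  expect_gte(info$n_evals, 2)
})

test_that("monotone degradation: fluctuation power raises MSE accordingly", {
  tgt <- fx_target()
  pows <- c(1, 4)
  mses <- vapply(pows, function(pw) {
    mean(vapply(1:6, function(s) {
      noisy <- add_fluctuations(tgt, pw, correlation_time = 20, seed = s)
      trace_mse(noisy, tgt)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(mses[1], 1, tolerance = 0.5)
  expect_equal(mses[2], 4, tolerance = 1.5)
  expect_gt(mses[2], mses[1])
})
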