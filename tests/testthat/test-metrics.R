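# AP metrics, target construction, randomization and fluctuations.

test_that("metrics of a synthetic square wave are exact by construction", {
  tr <- square_trace(n_cycles = 4, period_ms = 400, high_ms = 100)
  m <- ap_metrics(tr)
  expect_equal(m$CL_ms, 400, tolerance = 1e-6)
  expect_equal(m$OS_mV, 20)
  expect_equal(m$MDP_mV, -80)
  expect_equal(m$APD20_ms, 100, tolerance = 0.11)  # one-sample jump width
})

test_that("metrics are invariant to time translation by whole cycles", {
  m1 <- ap_metrics(square_trace(n_cycles = 5))
  m2 <- ap_metrics(square_trace(n_cycles = 5, t0 = 800))
  expect_equal(m1[, 1:4], m2[, 1:4])
  # appending extra cycles leaves the trailing-cycle metrics unchanged
  m3 <- ap_metrics(square_trace(n_cycles = 8))
  expect_equal(m1[, 1:4], m3[, 1:4])
})

test_that("metrics require at least two upstrokes", {
  tr <- square_trace(n_cycles = 1)
  expect_error(ap_metrics(tr), "fewer than 2")
})

test_that("cell-specific targets are single cycles tagged with sf_true", {
  tgt <- fx_target()
  expect_s3_class(tgt, "ap_trace")
  expect_equal(tgt$time_ms[1], 0)
  expect_equal(diff(tgt$time_ms)[1], 0.1)
  expect_identical(unclass(attr(tgt, "sf_true")),
                   unclass(scaling_factors()))
  expect_equal(trace_mse(tgt, tgt), 0)
})

test_that("raising Kr shortens the AP duration of the target", {
  p <- fx_params()
  base <- ap_metrics(fx_baseline_trace())
  tr_kr <- simulate_cell(p, sf = scaling_factors(Kr = 1.2), n_cycles = 25,
                         output_dt = 0.1, stop_when_stable = TRUE)
  m_kr <- ap_metrics(tr_kr)
  expect_lt(m_kr$APD20_ms, base$APD20_ms)
})

test_that("randomize_sf is exact at range 0 and seed-reproducible", {
  ctr <- scaling_factors(Kr = 1.1)
  expect_identical(unclass(randomize_sf(ctr, c("Kr", "CaL"), 0, seed = 1)),
                   unclass(ctr))
  d1 <- randomize_sf(ctr, c("Kr", "CaL"), 0.15, seed = 99)
  d2 <- randomize_sf(ctr, c("Kr", "CaL"), 0.15, seed = 99)
  expect_identical(d1, d2)
  d3 <- randomize_sf(ctr, c("Kr", "CaL"), 0.15, seed = 100)
  expect_false(identical(d1, d3))
})

test_that("randomize_sf draws fill the stated uniform band", {
  draws <- vapply(seq_len(2000), function(i) {
    randomize_sf(scaling_factors(), "Kr", 0.15, seed = i)[["Kr"]]
  }, numeric(1))
  expect_gte(min(draws), 0.85)
  expect_lte(max(draws), 1.15)
  expect_lt(min(draws), 0.86)   # approaches the bounds
  expect_gt(max(draws), 1.14)
  # unselected currents untouched
  d <- randomize_sf(scaling_factors(), "Kr", 0.15, seed = 1)
  expect_equal(unname(d[setdiff(channel_roster, "Kr")]),
               rep(1, 8))
})

test_that("randomize_sf draws are independent across currents", {
  draws <- t(vapply(seq_len(500), function(i) {
    d <- randomize_sf(scaling_factors(), c("Kr", "CaL"), 0.15, seed = i)
    c(d[["Kr"]], d[["CaL"]])
  }, numeric(2)))
  expect_lt(abs(stats::cor(draws[, 1], draws[, 2])), 0.1)
})

test_that("fluctuations have the requested power and seed behaviour", {
  tgt <- square_trace(n_cycles = 10)
  expect_identical(add_fluctuations(tgt, 0, seed = 1), tgt)
  pow <- 4
  mses <- vapply(1:12, function(s) {
    noisy <- add_fluctuations(tgt, pow, correlation_time = 20, seed = s)
    mean((noisy$vm_mV - tgt$vm_mV)^2)
  }, numeric(1))
  expect_equal(mean(mses), pow, tolerance = 0.25)
  n1 <- add_fluctuations(tgt, pow, seed = 1)
  n2 <- add_fluctuations(tgt, pow, seed = 2)
  expect_false(identical(n1$vm_mV, n2$vm_mV))
  expect_identical(add_fluctuations(tgt, pow, seed = 1)$vm_mV, n1$vm_mV)
})
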