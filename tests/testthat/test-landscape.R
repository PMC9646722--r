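# Landscape sampling, envelopes and local-minimum detection on analytic
# surrogate costs (model-based scans run in the acceptance suite).

paraboloid_cost <- function(x) {
  # log-scale paraboloid with minimum at sf = 1 (log sf = 0)
  1e-4 + sum(log(x)^2)
}

test_that("sampling is deterministic, in range, and injects the centre", {
  ls1 <- sample_landscape(cost = paraboloid_cost, free = c("Kr", "bNSC"),
                          n_samples = 200, seed = 5)
  ls2 <- sample_landscape(cost = paraboloid_cost, free = c("Kr", "bNSC"),
                          n_samples = 200, seed = 5)
  expect_identical(ls1$mse, ls2$mse)
  expect_true(all(ls1$Kr[-1] >= 0.1 & ls1$Kr[-1] <= 10))
  expect_equal(ls1$Kr[1], 1)    # injected centre
  expect_equal(ls1$bNSC[1], 1)
  expect_equal(ls1$mse[1], 1e-4)
  expect_true(all(ls1$mse >= 0))
  ls3 <- sample_landscape(cost = paraboloid_cost, free = c("Kr", "bNSC"),
                          n_samples = 200, seed = 6)
  expect_false(identical(ls1$Kr[-1], ls3$Kr[-1]))
})

test_that("envelope takes per-bin minima and respects min-monotonicity", {
  ls <- sample_landscape(cost = paraboloid_cost, free = c("Kr", "bNSC"),
                         n_samples = 400, seed = 1)
  env <- mse_envelope(ls, "Kr", n_bins = 20)
  expect_equal(nrow(env), 20)
  nonempty <- env[env$n > 0, ]
  # each bin minimum bounds its members
  for (b in nonempty$bin) {
    inbin <- ls$Kr >= env$sf_lo[env$bin == b] &
      ls$Kr <= env$sf_hi[env$bin == b] & !ls$quiescent
    expect_lte(env$min_mse[env$bin == b], min(ls$mse[inbin]) + 1e-12)
  }
  # adding samples can only lower the envelope (superset built explicitly)
  extra <- sample_landscape(cost = paraboloid_cost, free = c("Kr", "bNSC"),
                            n_samples = 800, seed = 2,
                            include_center = FALSE)
  ls_more <- structure(dplyr::bind_rows(ls, extra), class = class(ls),
                       free = attr(ls, "free"), range = attr(ls, "range"))
  env_more <- mse_envelope(ls_more, "Kr", n_bins = 20)
  both <- env$n > 0 & env_more$n > 0
  expect_true(all(env_more$min_mse[both] <= env$min_mse[both] + 1e-12))
})

test_that("envelope of a paraboloid matches the conditional minimum", {
  ls <- sample_landscape(cost = paraboloid_cost, free = c("Kr", "bNSC"),
                         n_samples = 4000, seed = 2)
  env <- mse_envelope(ls, "Kr", n_bins = 15)
  nonempty <- env[env$n > 20, ]
  # conditional minimum over bNSC at fixed Kr: 1e-4 + log(Kr)^2
  expected <- 1e-4 + log(nonempty$sf_mid)^2
  expect_equal(log10(nonempty$min_mse), log10(expected), tolerance = 0.35)
})

test_that("local-minimum detection finds the single vertex and no more", {
  # V-shaped synthetic envelope
  env_v <- tibble::tibble(bin = 1:11, sf_lo = 1:11, sf_hi = 2:12,
                          sf_mid = 1.5 + 0:10,
                          min_mse = 10^(abs(-5:5) - 3), n = 10)
  mins <- detect_local_minima(env_v, prominence = 0.2)
  expect_equal(nrow(mins), 1)
  expect_equal(mins$bin, 6)
  # monotone envelope: no interior minimum
  env_mono <- tibble::tibble(bin = 1:8, sf_lo = 1:8, sf_hi = 2:9,
                             sf_mid = 1.5 + 0:7,
                             min_mse = 10^seq(-3, 1, length.out = 8), n = 5)
  expect_equal(nrow(detect_local_minima(env_mono, prominence = 0.2)), 0)
  # shallow ripple below the prominence threshold is ignored
  rip <- env_mono
  rip$min_mse[4] <- rip$min_mse[4] * 0.9
  expect_equal(nrow(detect_local_minima(rip, prominence = 0.2)), 0)
})

test_that("quiescent samples are flagged and excluded from envelopes", {
  cost_q <- function(x) if (x[["Kr"]] > 3) 1e4 else paraboloid_cost(x)
  ls <- sample_landscape(cost = cost_q, free = "Kr", n_samples = 300,
                         seed = 3, spec = objective_spec(penalty_mse = 1e4))
  expect_true(any(ls$quiescent))
  env <- mse_envelope(ls, "Kr", n_bins = 12)
  hi <- env$sf_lo > 3 & env$n > 0
  expect_true(all(is.na(env$min_mse[env$n == 0])))
  expect_false(any(hi))   # all samples above 3 were quiescent-flagged
})

test_that("landscape scans serialize and deserialize losslessly", {
  ls <- sample_landscape(cost = paraboloid_cost, free = c("Kr", "bNSC"),
                         n_samples = 50, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landscape(ls, path)
  back <- read_landscape(path)
  expect_equal(back$mse, ls$mse)
  expect_equal(back$Kr, ls$Kr)
  expect_identical(attr(back, "free"), attr(ls, "free"))
  expect_equal(attr(back, "range"), attr(ls, "range"))
})
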