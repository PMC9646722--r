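# Pattern Search on analytic surrogates: contraction bound, grid-oracle
# equivalence, base-point monotonicity, termination, tie-breaking, and the
# multi-run driver's bookkeeping on cheap cost functions.

quad_cost <- function(center) {
  force(center)
  function(x) sum((x[names(center)] - center)^2)
}

test_that("1-D convex contraction lands within the step-resolution bound", {
  cost <- quad_cost(c(a = 1))
  run <- ps_optimize(cost, c(a = 1.1),
                     ps_config(stp0 = 0.04, crtstp = 5e-5))
  expect_true(run$converged)
  expect_lt(abs(run$final_sf[["a"]] - 1), 5e-5 / (1 - 1 / 4))
})

test_that("2-D separable bowl matches an exhaustive fine-grid minimizer", {
  center <- c(a = 0.97, b = 1.06)
  cost <- quad_cost(center)
  run <- ps_optimize(cost, c(a = 1.1, b = 0.9), ps_config())
  # brute-force oracle on a fine grid around the start box
  grid <- expand.grid(a = seq(0.9, 1.1, by = 1e-3),
                      b = seq(0.9, 1.1, by = 1e-3))
  vals <- (grid$a - center["a"])^2 + (grid$b - center["b"])^2
  best <- grid[which.min(vals), ]
  expect_lt(abs(run$final_sf[["a"]] - best$a), 1e-3)
  expect_lt(abs(run$final_sf[["b"]] - best$b), 1e-3)
  expect_lt(run$final_mse, min(vals) + 1e-6)
})

test_that("base-point MSE sequence never increases", {
  set.seed(4)
  amat <- matrix(rnorm(9), 3)
  cost <- function(x) {
    v <- x[c("a", "b", "c")] - c(1, 1, 1)
    sum((amat %*% v)^2) + 0.5 * sum(v^2)
  }
  run <- ps_optimize(cost, c(a = 1.2, b = 0.85, c = 1.1), ps_config())
  expect_true(all(diff(run$bp_history$mse) <= 0))
  expect_equal(run$final_mse, min(run$bp_history$mse))
})

test_that("step reductions are bounded and the run always terminates", {
  cfg <- ps_config(stp0 = 0.04, redFct = 1 / 4, crtstp = 5e-5)
  bound <- ceiling(log(cfg$crtstp / cfg$stp0) / log(cfg$redFct))
  run <- ps_optimize(quad_cost(c(a = 1)), c(a = 1.05), cfg)
  expect_true(run$converged)
  stps <- unique(run$eval_log$stp)
  expect_lte(length(stps), bound + 1)
  expect_true(all(stps >= cfg$crtstp))
})

test_that("equal-cost probes break ties toward the + step", {
  # cost flat in a band around the start: both probes equal, no move
  cost <- function(x) max(abs(x[["a"]] - 1) - 0.2, 0)^2
  run <- ps_optimize(cost, c(a = 1), ps_config(stp0 = 0.04, crtstp = 1e-2,
                                               short_circuit = FALSE))
  expect_equal(run$final_sf[["a"]], 1)  # stays: no strict improvement
  # a strict tie between better +/- probes prefers + (documented contract)
  seen <- new.env(); seen$args <- list()
  vcost <- function(x) {
    seen$args[[length(seen$args) + 1]] <- x[["a"]]
    (abs(x[["a"]] - 1) - 0.04)^2  # minima symmetric at 1 +/- stp0
  }
  run2 <- ps_optimize(vcost, c(a = 1),
                      ps_config(stp0 = 0.04, crtstp = 0.02,
                                short_circuit = FALSE))
  expect_gt(run2$final_sf[["a"]], 1)
})

test_that("non-positive candidates are rejected as non-improvements", {
  cost <- function(x) (x[["a"]] - 0.5)^2
  run <- ps_optimize(cost, c(a = 0.03),
                     ps_config(stp0 = 0.04, crtstp = 1e-3))
  expect_true(all(run$bp_history$a > 0))
  expect_equal(run$final_sf[["a"]], 0.5, tolerance = 2e-3)
})

test_that("evaluation budget exhaustion returns best-so-far unconverged", {
  cost <- quad_cost(c(a = 1, b = 1))
  run <- ps_optimize(cost, c(a = 1.4, b = 0.6),
                     ps_config(max_evals = 7))
  expect_false(run$converged)
  expect_lte(run$n_evals, 7)
})

test_that("top_k_stats reproduces flat spreadsheet arithmetic", {
  toy <- structure(list(
    selected = c("Kr", "CaL"),
    finals = tibble::tibble(
      run = 1:3, seed = 1:3,
      final_mse = c(1e-3, 1e-5, 1e-4),
      converged = TRUE, n_evals = 10,
      Na_i = c(6.1, 6.2, 6.0), Ca_tot = c(79, 80, 78),
      sf_Kr = c(1.01, 0.99, 1.00), sf_CaL = c(0.98, 1.02, 1.00))
  ), class = "orp_result")
  ts <- top_k_stats(toy, k = 3)
  expect_equal(ts$per_sf$mean, c(1.00, 1.00), tolerance = 1e-12)
  expect_equal(ts$per_sf$se,
               c(stats::sd(c(1.01, 0.99, 1.00)) / sqrt(3),
                 stats::sd(c(0.98, 1.02, 1.00)) / sqrt(3)))
  expect_equal(ts$mean_log10_mse, mean(log10(c(1e-3, 1e-5, 1e-4))))
  expect_equal(ts$mean_Na_i, 6.1)
  # zero variance -> zero SE
  toy$finals$sf_Kr <- 1
  expect_equal(top_k_stats(toy, k = 3)$per_sf$se[1], 0)
  expect_error(top_k_stats(toy, k = 5), "usable")
})

test_that("frozen and selected current sets must not overlap", {
  tgt <- square_trace(n_cycles = 3)
  attr(tgt, "sf_true") <- scaling_factors()
  expect_error(
    orp_test(tgt, fx_params(), selected = c("Kr", "K1"), n_runs = 1,
             frozen = c(K1 = 1)),
    "frozen and selected")
})

test_that("constrained orp optimizes the reduced parameter set", {
  tgt <- fx_target()
  res <- constrained_orp(tgt, fx_params(), frozen = c(ha = 1, bNSC = 1),
                         selected = c("Kr", "K1"), n_runs = 1,
                         range_pct = 0.05, seed = 3,
                         config = ps_config(max_evals = 25))
  expect_setequal(setdiff(names(res$finals)[grepl("^sf_", names(res$finals))],
                          character()), c("sf_Kr", "sf_K1"))
  expect_true(is.finite(res$finals$final_mse))
  expect_equal(res$selected, c("Kr", "K1"))
})
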