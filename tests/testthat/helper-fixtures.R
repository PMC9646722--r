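# Shared fixtures, built once per test session.

# baseline parameters and a settled one-cycle target (memoized)
.fx <- new.env()

fx_params <- function() {
  if (is.null(.fx$params)) .fx$params <- cell_params()
  .fx$params
}

fx_target <- function() {
  if (is.null(.fx$target)) .fx$target <- make_target(fx_params())
  .fx$target
}

fx_baseline_trace <- function() {
  if (is.null(.fx$trace)) {
    .fx$trace <- simulate_cell(fx_params(), n_cycles = 4, output_dt = 0.1)
  }
  .fx$trace
}

# synthetic square-wave trace: -80 <-> +20 mV, high for `high_ms`,
# period `period_ms`, on a 0.1 ms grid
square_trace <- function(n_cycles = 4, period_ms = 400, high_ms = 100,
                         dt = 0.1, t0 = 0) {
  t <- seq(t0, t0 + n_cycles * period_ms - dt, by = dt)
  phase <- (t - t0) %% period_ms
  v <- ifelse(phase < high_ms, 20, -80)
  structure(tibble::tibble(time_ms = t, vm_mV = v),
            class = c("ap_trace", "tbl_df", "tbl", "data.frame"),
            output_dt = dt)
}

# random valid cell states for property checks
random_state <- function(seed) {
  set.seed(seed)
  cell_state(
    vm = stats::runif(1, -90, 30),
    Na_i = stats::runif(1, 4, 10),
    K_i = stats::runif(1, 120, 150),
    Catot = c(jnc = stats::runif(1, 0.05, 0.4),
              iz = stats::runif(1, 0.005, 0.08),
              blk = stats::runif(1, 0.005, 0.05),
              SRup = stats::runif(1, 0.02, 0.3),
              SRrl = stats::runif(1, 0.05, 0.5)),
    crf_NaK = stats::runif(1, 0.5, 1.5),
    crf_NCX = stats::runif(1, 0.5, 1.5)
  )
}
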