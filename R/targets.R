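# Cell-specific target traces: noise-free model output for a chosen
# ground-truth set of scaling factors, plus the randomized initial
# parameter sets and optional slow fluctuations used in robustness tests.

# run expr with a temporary RNG state seeded by `seed` (restores on exit)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(expr)
}

#' Generate a noise-free cell-specific target trace
#'
#' Integrates the model with the ground-truth scaling factors `sf_true`
#' until the rhythm is quasi-stable and extracts one complete cycle aligned
#' at the upstroke, on the exact output grid.  The returned trace carries
#' `sf_true` so that recovery experiments are self-describing.
#'
#' @param params A [cell_params()].
#' @param sf_true Ground-truth [scaling_factors()] (default all ones).
#' @param init Starting [cell_state()] (default the settled baseline).
#' @param output_dt Grid interval, ms.
#' @param max_cycles Cap on settling cycles.
#' @return An `ap_trace` of exactly one cycle starting at the upstroke,
#'   with attributes `sf_true` and `final_state`.
#' @examples
#' \donttest{
#' tgt <- make_target(cell_params(), scaling_factors(Kr = 1.1))
#' }
#' @export
make_target <- function(params = cell_params(), sf_true = scaling_factors(),
                        init = NULL, output_dt = 0.1, max_cycles = 100) {
  sf_true <- complete_sf(sf_true)
  settled <- simulate_cell(params, sf_true, init = init, n_cycles = max_cycles,
                           output_dt = 1, stop_when_stable = TRUE,
                           stability_tol = 0.001, max_cycles = max_cycles)
  if (attr(settled, "quiescent")) {
    stop("sf_true yields a quiescent model: targets must beat", call. = FALSE)
  }
  fine <- simulate_cell(params, sf_true, init = attr(settled, "final_state"),
                        n_cycles = 3, output_dt = output_dt)
  if (attr(fine, "quiescent") || length(attr(fine, "cycles")) < 3) {
    stop("could not capture a stable target cycle", call. = FALSE)
  }
  cyc <- extract_last_cycle(fine)
  attr(cyc, "sf_true") <- sf_true
  attr(cyc, "final_state") <- attr(fine, "final_state")
  attr(cyc, "quasi_stable") <- attr(fine, "quasi_stable")
  cyc
}

# last complete upstroke-to-upstroke cycle, re-timed to start at 0; the
# cut is at the grid sample at or just before the -20 mV upward crossing,
# so the crossing itself stays inside the cycle for sub-sample registration
extract_last_cycle <- function(trace) {
  t <- trace$time_ms
  v <- trace$vm_mV
  dt <- attr(trace, "output_dt") %||% (t[2] - t[1])
  ups <- spline_upcrossings(t, v)
  if (length(ups) < 2) {
    stop("trace holds fewer than 2 upstrokes", call. = FALSE)
  }
  u0 <- ups[length(ups) - 1]
  u1 <- ups[length(ups)]
  i0 <- findInterval(u0, t)
  i1 <- findInterval(u1, t)
  out <- trace[i0:(i1 - 1), , drop = FALSE]
  out$time_ms <- (seq_len(nrow(out)) - 1) * dt
  attrs <- attributes(trace)
  for (a in c("sf", "output_dt", "quiescent", "failed")) {
    attr(out, a) <- attrs[[a]]
  }
  attr(out, "cycles") <- 0
  attr(out, "cycle_lengths") <- (i1 - i0) * dt
  attr(out, "cl_exact") <- u1 - u0
  class(out) <- class(trace)
  out
}

#' Randomize scaling factors around a centre
#'
#' Draws each selected factor independently from the uniform distribution
#' `centre * (1 - range_pct, 1 + range_pct)`; unselected factors are
#' unchanged.  Fully reproducible from `seed`.
#'
#' @param center Centre [scaling_factors()].
#' @param selected Current names to randomize.
#' @param range_pct Half-width of the relative range (e.g. 0.1 for ±10%).
#' @param seed Integer seed (optional; uses the current RNG state if NULL).
#' @return A [scaling_factors()] draw.
#' @examples
#' randomize_sf(scaling_factors(), c("Kr", "CaL"), 0.1, seed = 1)
#' @export
randomize_sf <- function(center = scaling_factors(), selected = channel_roster,
                         range_pct = 0.1, seed = NULL) {
  stopifnot(range_pct >= 0, range_pct <= 0.5)
  center <- complete_sf(center)
  bad <- setdiff(selected, channel_roster)
  if (length(bad)) {
    stop("unknown current(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- with_seed(seed, {
    draw <- center
    for (nm in selected) {
      draw[[nm]] <- center[[nm]] * stats::runif(1, 1 - range_pct, 1 + range_pct)
    }
    draw
  })
  if (any(out <= 0)) {
    stop("randomization produced non-positive sf", call. = FALSE)
  }
  structure(out, class = c("scaling_factors", "numeric"))
}

#' Add slow membrane-potential fluctuations to a trace
#'
#' Superimposes a smoothed (first-order low-pass, correlation time
#' `correlation_time`) zero-mean noise process whose stationary mean-square
#' amplitude equals `target_power`.  Emulates the slow drift of unknown
#' origin seen in experimental recordings; used for robustness experiments
#' only.
#'
#' @param trace An `ap_trace`.
#' @param target_power Mean-square fluctuation amplitude, mV^2.
#' @param correlation_time Noise correlation time, ms.
#' @param seed Integer seed.
#' @return The trace with fluctuating `vm_mV`.
#' @export
add_fluctuations <- function(trace, target_power, correlation_time = 50,
                             seed = NULL) {
  stopifnot(target_power >= 0)
  if (target_power == 0) return(trace)
  dt <- attr(trace, "output_dt") %||% (trace$time_ms[2] - trace$time_ms[1])
  n <- nrow(trace)
  phi <- exp(-dt / correlation_time)
  innov_sd <- sqrt(target_power * (1 - phi^2))
  noise <- with_seed(seed, {
    e <- stats::rnorm(n, 0, innov_sd)
    x <- numeric(n)
    # start from the stationary distribution so the power is exact in law
    x[1] <- stats::rnorm(1, 0, sqrt(target_power))
    for (i in 2:n) x[i] <- phi * x[i - 1] + e[i]
    x
  })
  trace$vm_mV <- trace$vm_mV + noise
  trace
}
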