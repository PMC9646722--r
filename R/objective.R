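# The mean-squared-error objective between an adaptive model trace and a
# target trace:  MSE = sum((Vm_a - Vm_t)^2) / N  over a configurable
# AP-phase window on the 0.1 ms grid, after registering the two traces at
# their upstrokes.  Quiescent candidates receive a large finite penalty so
# the optimizer always has a comparable scalar.

#' Objective specification
#'
#' @param window Phase window: `"cycle"` (full cycle, default), `"sdd"`
#'   (slow diastolic depolarization: MDP to the next upstroke), `"plateau"`
#'   (upstroke to the -20 mV downward crossing) or `"repolarization"`
#'   (-20 mV downward crossing to MDP).  Phase landmarks are taken from the
#'   target cycle.
#' @param weights Optional named weights over the three phases
#'   (`plateau`, `repolarization`, `sdd`) for a weighted full-cycle MSE.
#' @param penalty_mse Penalty (mV^2) assigned to quiescent candidates;
#'   must exceed any physiological MSE.
#' @return An `objective_spec` object.
#' @export
objective_spec <- function(window = c("cycle", "sdd", "plateau",
                                      "repolarization"),
                           weights = NULL, penalty_mse = 1e4) {
  window <- match.arg(window)
  if (!is.null(weights)) {
    stopifnot(all(names(weights) %in% c("plateau", "repolarization", "sdd")),
              all(weights >= 0), any(weights > 0))
  }
  stopifnot(penalty_mse >= 1e3)
  structure(list(window = window, weights = weights,
                 penalty_mse = penalty_mse),
            class = "objective_spec")
}

# indices partitioning one target cycle (starting at its upstroke) into
# plateau / repolarization / sdd
phase_partition <- function(vm) {
  n <- length(vm)
  i_os <- which.max(vm)
  after <- which(vm < -20)
  i_dn <- after[after > i_os][1]
  if (is.na(i_dn)) i_dn <- i_os + 1
  i_mdp <- (i_dn - 1) + which.min(vm[i_dn:n])
  list(plateau = seq_len(i_dn - 1),
       repolarization = seq(i_dn, max(i_dn, i_mdp - 1)),
       sdd = seq(i_mdp, n))
}

#' Register an adaptive trace against a target cycle
#'
#' Extracts the last complete cycle of the adaptive trace and registers it
#' to the target cycle at the upstroke, using the sub-sample (linearly
#' interpolated) time of the -20 mV upward crossing as the registration
#' landmark.  The adaptive trace is interpolated onto the target's phase
#' grid, pairing samples over the shorter of the two cycles.
#'
#' @param adaptive An `ap_trace` (at least one full cycle) or a trace that
#'   is already a single cycle starting at its upstroke.
#' @param target A single-cycle target trace from [make_target()].
#' @param spec An [objective_spec()].
#' @return A tibble with columns `time_ms`, `vm_adaptive`, `vm_target`,
#'   `weight`, or a `quiescent` marker object when the adaptive trace is
#'   quiescent.
#' @export
align_traces <- function(adaptive, target, spec = objective_spec()) {
  if (isTRUE(attr(adaptive, "quiescent")) || isTRUE(attr(adaptive, "failed"))) {
    return(structure(list(), class = "quiescent_alignment"))
  }
  b <- as_single_cycle(target)
  dt <- b$time_ms[2] - b$time_ms[1]
  tc_b <- first_upcrossing(b)
  cl_b <- attr(b, "cl_exact") %||% (nrow(b) * dt)
  # registration landmark on the (uncut) adaptive trace: the -20 mV upward
  # crossing opening its last complete cycle
  ups_a <- spline_upcrossings(adaptive$time_ms, adaptive$vm_mV)
  if (length(ups_a) >= 2) {
    u0a <- ups_a[length(ups_a) - 1]
    cl_a <- ups_a[length(ups_a)] - u0a
    src <- adaptive
  } else {
    src <- as_single_cycle(adaptive)
    u0a <- first_upcrossing(src)
    cl_a <- attr(src, "cl_exact") %||% (nrow(src) * dt)
  }
  # pair target sample k (phase b$time_ms[k] - tc_b past the crossing)
  # with the adaptive potential interpolated at the matching phase
  want <- u0a + (b$time_ms - tc_b)
  ok <- want >= src$time_ms[1] & want <= src$time_ms[nrow(src)]
  n <- min(sum(ok), nrow(b))
  if (n < 2) stop("window selects no samples", call. = FALSE)
  idx <- which(ok)[seq_len(n)]
  vm_a <- stats::spline(src$time_ms, src$vm_mV, xout = want[idx],
                        method = "fmm")$y
  ph <- phase_partition(b$vm_mV)
  # continuous comparison window: clip at the shorter of the two cycle
  # lengths with a fractional weight on the boundary sample, so the MSE
  # varies continuously as the candidate cycle length slides across the
  # sampling grid (the cycle-length mismatch is still felt as an
  # end-of-window residual)
  t_end <- min(cl_a, cl_b)
  edge <- pmin(pmax((t_end - b$time_ms[idx]) / dt, 0), 1)
  w <- rep(1, n)
  if (spec$window != "cycle") {
    sel <- ph[[spec$window]]
    w <- as.numeric(idx %in% sel)
    if (!any(w > 0)) stop("window selects no samples", call. = FALSE)
  } else if (!is.null(spec$weights)) {
    w <- numeric(n)
    for (nm in names(ph)) {
      wv <- spec$weights[[nm]] %||% 0
      w[which(idx %in% ph[[nm]])] <- wv
    }
    if (!any(w > 0)) stop("window selects no samples", call. = FALSE)
  }
  tibble::tibble(time_ms = b$time_ms[idx],
                 vm_adaptive = vm_a,
                 vm_target = b$vm_mV[idx],
                 weight = w * edge)
}

# interpolated time of the first -20 mV upward crossing; falls back to the
# first sample for cycles cut exactly at the crossing
first_upcrossing <- function(trace, threshold = -20) {
  tc <- spline_upcrossings(trace$time_ms, trace$vm_mV, threshold)
  if (length(tc)) tc[1] else trace$time_ms[1]
}

# upward threshold crossings refined by local spline interpolation, so the
# registration landmark is free of the periodic bias linear interpolation
# picks up on the steep upstroke
spline_upcrossings <- function(t, v, threshold = -20) {
  rough <- detect_upstrokes(t, v, threshold, refine = FALSE)
  if (!length(rough)) return(rough)
  dt <- t[2] - t[1]
  vapply(rough, function(tc) {
    i <- findInterval(tc, t)
    lo <- max(1, i - 6)
    hi <- min(length(t), i + 6)
    if (hi - lo < 3) return(tc)
    dense <- stats::spline(t[lo:hi], v[lo:hi], n = 40 * (hi - lo))
    j <- which(dense$y[-length(dense$y)] < threshold &
                 dense$y[-1] >= threshold)
    if (!length(j)) return(tc)
    # sub-step linear correction on the dense grid
    k <- j[which.min(abs(dense$x[j] - tc))]
    f <- (threshold - dense$y[k]) / (dense$y[k + 1] - dense$y[k])
    dense$x[k] + f * (dense$x[k + 1] - dense$x[k])
  }, numeric(1))
}

# a trace reduced to one cycle starting at the upstroke; traces that are
# already single cycles (first sample at the upstroke) pass through
as_single_cycle <- function(trace) {
  ups <- detect_upstrokes(trace$time_ms, trace$vm_mV)
  dt <- attr(trace, "output_dt") %||% (trace$time_ms[2] - trace$time_ms[1])
  if (length(ups) < 2) {
    cl <- attr(trace, "cycle_lengths")
    if (!is.null(cl) && length(cl) >= 1 && nrow(trace) * dt <= max(cl) * 1.05) {
      return(trace)  # already a single extracted cycle
    }
    if (length(ups) == 1 && abs(ups[1] - trace$time_ms[1]) <= 2 * dt) {
      return(trace)  # starts at its only upstroke
    }
    stop("trace holds fewer than 2 upstrokes", call. = FALSE)
  }
  extract_last_cycle(trace)
}

#' Mean squared error between traces
#'
#' `MSE = sum(w * (Vm_a - Vm_t)^2) / sum(w)` over the aligned window; a
#' quiescent adaptive trace receives `spec$penalty_mse`.
#'
#' @inheritParams align_traces
#' @return MSE in mV^2.
#' @examples
#' \donttest{
#' tgt <- make_target(cell_params())
#' trace_mse(tgt, tgt)  # 0
#' }
#' @export
trace_mse <- function(adaptive, target, spec = objective_spec()) {
  al <- align_traces(adaptive, target, spec)
  if (inherits(al, "quiescent_alignment")) return(spec$penalty_mse)
  sum(al$weight * (al$vm_adaptive - al$vm_target)^2) / sum(al$weight)
}

#' Build an MSE cost function over scaling factors
#'
#' Returns a function mapping a (possibly partial, named) scaling-factor
#' vector to the MSE of the simulated quasi-stable cycle against the
#' target.  Every evaluation integrates a fixed number of settling cycles
#' from one fixed initial state (the target's settled state), so the cost
#' is a deterministic, smooth function of the factors whose global
#' minimum sits exactly at the target's generating factors.  MSE values
#' are cached on a quantized sf grid; quiescent candidates receive
#' `penalty_mse`.
#'
#' @param target Single-cycle target from [make_target()].
#' @param params A [cell_params()].
#' @param spec An [objective_spec()].
#' @param frozen Named values for currents held fixed (implicitly 1).
#' @param settle_cycles Settling time per evaluation, in units of the
#'   target cycle length (a fixed time horizon, so the cost varies
#'   smoothly with the factors).
#' @param settle_rtol Relative solver tolerance of the settling phase (the
#'   measured cycle always uses the stricter default tolerances).
#' @param cache_quantum sf quantum for exact-revisit caching.
#' @return Function `f(sf) -> mse` with attributes accessible through
#'   [cost_info()].
#' @export
make_cost <- function(target, params = cell_params(), spec = objective_spec(),
                      frozen = NULL, settle_cycles = 3,
                      settle_rtol = 1e-5, cache_quantum = 5e-6) {
  base_sf <- complete_sf(frozen)
  env <- new.env(parent = emptyenv())
  env$mse_cache <- new.env(parent = emptyenv())
  env$n_evals <- 0L
  env$log <- list()

  init0 <- attr(target, "final_state") %||% baseline_state()
  env$best <- list(mse = Inf, sf = NULL, state = init0)
  cl_ref <- max(attr(target, "cycle_lengths") %||% 800)
  p_settle <- params
  p_settle$rtol <- settle_rtol
  p_settle$atol <- settle_rtol * 1e-2

  fn <- function(sf) {
    full <- base_sf
    if (length(sf)) {
      stopifnot(!is.null(names(sf)))
      full[names(sf)] <- sf
    }
    if (any(full <= 0)) return(Inf)
    key <- paste(round(as.numeric(full) / cache_quantum), collapse = ",")
    hit <- get0(key, env$mse_cache)
    if (!is.null(hit)) return(hit)

    settled <- simulate_cell(p_settle, full, init = init0, output_dt = 2,
                             horizon = settle_cycles * cl_ref,
                             chunk_ms = settle_cycles * cl_ref)
    mse <- spec$penalty_mse
    if (!attr(settled, "quiescent")) {
      # cheap coarse bridge to just before the next upstroke, so the fine
      # 0.1 ms phase only has to cover a single cycle plus margin
      at_foot <- bridge_upstroke(p_settle, full,
                                 attr(settled, "final_state"), cl_ref)
      if (!is.null(at_foot)) {
        fine <- simulate_cell(params, full, init = at_foot,
                              output_dt = 0.1, horizon = 1.45 * cl_ref,
                              chunk_ms = 1.45 * cl_ref,
                              quiescence_window = 1.45 * cl_ref + 1)
        if (!attr(fine, "quiescent") &&
            length(detect_upstrokes(fine$time_ms, fine$vm_mV,
                                    refine = FALSE)) >= 2) {
          mse <- trace_mse(fine, target, spec)
          if (mse < env$best$mse) {
            env$best <- list(mse = mse, sf = full,
                             state = attr(fine, "final_state"))
          }
        }
      }
    }
    assign(key, mse, env$mse_cache)
    env$n_evals <- env$n_evals + 1L
    env$log[[length(env$log) + 1]] <- c(as.numeric(full), mse)
    mse
  }
  attr(fn, "env") <- env
  attr(fn, "params") <- params
  attr(fn, "target") <- target
  fn
}

#' Diagnostics of a cost closure
#'
#' @param cost A function from [make_cost()].
#' @return List with `n_evals` and the evaluation log tibble.
#' @export
cost_info <- function(cost) {
  env <- attr(cost, "env")
  lg <- do.call(rbind, env$log)
  tb <- NULL
  if (!is.null(lg)) {
    colnames(lg) <- c(channel_roster, "mse")
    tb <- tibble::as_tibble(as.data.frame(lg))
  }
  list(n_evals = env$n_evals, log = tb)
}

# integrate coarsely until the membrane crosses -30 mV upward (the foot of
# the next upstroke); returns the state there, or NULL when the model is
# quiescent within max_time
bridge_upstroke <- function(params, sf, init, cl_ref,
                            max_time = 3 * cl_ref) {
  p2 <- params
  p2$root_mv <- -30
  pv <- unname(parm_vector(p2, sf, homeostasis = FALSE))
  y <- as.numeric(init[.state_order])
  t_used <- 0
  while (t_used < max_time) {
    span <- min(1.5 * cl_ref, max_time - t_used)
    times <- seq(0, span, by = 2)
    out <- tryCatch(
      deSolve::lsodar(y, times, func = "pf_derivs", parms = pv,
                      dllname = "pacefit", initfunc = "pf_init",
                      rootfunc = "pf_root", nroot = 1,
                      rtol = params$rtol, atol = params$atol,
                      maxsteps = 50000),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(out) || nrow(out) < 2 ||
        any(!is.finite(out[nrow(out), ]))) {
      return(NULL)
    }
    n <- nrow(out)
    hit <- n < length(times) ||
      abs(out[n, 2] - p2$root_mv) < 1e-6
    v_prev <- out[n - 1, 2]
    y <- as.numeric(out[n, 1 + seq_along(.state_order)])
    t_used <- t_used + out[n, 1]
    if (hit && v_prev < p2$root_mv && y[1] >= p2$root_mv - 1e-6) {
      return(as_cell_state(stats::setNames(y, .state_order)))
    }
  }
  NULL
}

# final simulated state at the best (lowest-MSE) evaluated sf vector;
# re-simulates if a different sf is requested
cost_state_for <- function(cost, sf) {
  env <- attr(cost, "env")
  full <- complete_sf(sf)
  if (!is.null(env$best$sf) &&
      max(abs(as.numeric(env$best$sf) - as.numeric(full))) < 1e-12) {
    return(env$best$state)
  }
  tr <- simulate_cell(attr(cost, "params"), full, init = env$best$state,
                      n_cycles = 3, output_dt = 1)
  attr(tr, "final_state")
}
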