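# Numerical integration of the cell model.  The stiff solver (lsodar) runs
# the compiled right-hand side; a compiled root function flags every
# crossing of -20 mV and a compiled event function applies the per-cycle
# homeostasis increment at upward crossings.  Integration proceeds in
# chunks until the requested number of spontaneous cycles has been
# observed, the rhythm is quasi-stable, or quiescence is detected.

#' Simulate spontaneous action potentials
#'
#' Integrates the cell model from an initial state and returns the membrane
#' potential sampled on an exact uniform grid (0.1 ms by default), together
#' with detected cycle boundaries (upstrokes), a quasi-stability flag and
#' the final state for warm restarts.
#'
#' @param params A [cell_params()].
#' @param sf Channel conductance scaling factors; see [scaling_factors()].
#' @param init Initial [cell_state()]; default [baseline_state()].
#' @param n_cycles Number of spontaneous cycles to simulate (upstrokes).
#' @param output_dt Output sampling interval, ms.
#' @param homeostasis Apply the per-cycle Na/Ca homeostasis feedback.
#' @param stop_when_stable Stop early once the rhythm is quasi-stable.
#' @param stability_tol Relative cycle-length tolerance for quasi-stability.
#' @param stable_run Number of consecutive cycle lengths that must agree.
#' @param max_cycles Hard cap on simulated cycles.
#' @param quiescence_window Simulated time (ms) without an upstroke after
#'   which the model is declared quiescent.
#' @param keep_states Keep the full state matrix (for current breakdowns).
#' @param horizon Fixed total simulated time (ms).  When given, the
#'   integration runs for exactly this horizon instead of counting cycles
#'   (quiescence detection still applies); used where the output must vary
#'   smoothly with the parameters.
#' @param chunk_ms Integration chunk length override, ms.
#' @return An `ap_trace`: a tibble with columns `time_ms`, `vm_mV` and
#'   bookkeeping columns `Na_i`, `Ca_tot`, `crf_NaK`, `crf_NCX`, with
#'   attributes `cycles` (upstroke times, ms), `cycle_lengths`,
#'   `quasi_stable`, `quiescent`, `final_state`, `sf`, `output_dt`.
#' @examples
#' \donttest{
#' tr <- simulate_cell(cell_params(), n_cycles = 3)
#' attr(tr, "cycle_lengths")
#' }
#' @export
simulate_cell <- function(params = cell_params(), sf = NULL, init = NULL,
                          n_cycles = 30, output_dt = 0.1,
                          homeostasis = TRUE, stop_when_stable = FALSE,
                          stability_tol = 0.005, stable_run = 3,
                          max_cycles = 100, quiescence_window = 3000,
                          keep_states = FALSE, horizon = NULL,
                          chunk_ms = NULL) {
  stopifnot(n_cycles >= 1)
  n_cycles <- min(n_cycles, max_cycles)
  init <- init %||% baseline_state()
  y0 <- as.numeric(init[.state_order])
  pv <- unname(parm_vector(params, sf, homeostasis))

  t0 <- 0
  cl_est <- 500
  upstrokes <- numeric(0)
  rows <- list()
  state_rows <- list()
  quiescent <- FALSE
  failed <- FALSE
  last_up_t <- 0
  repeat {
    chunk <- max(2.5 * cl_est, 1000)
    chunk <- min(chunk, 6 * cl_est + 500)
    if (!is.null(chunk_ms)) chunk <- chunk_ms
    if (!is.null(horizon)) chunk <- min(chunk, max(horizon - t0, 10))
    nstep <- ceiling(chunk / output_dt)
    times <- t0 + output_dt * (0:nstep)
    out <- tryCatch(
      deSolve::lsodar(y0, times, func = "pf_derivs", parms = pv,
                      dllname = "pacefit", initfunc = "pf_init",
                      rootfunc = "pf_root", nroot = 1,
                      events = list(func = "pf_event", root = TRUE),
                      rtol = params$rtol, atol = params$atol,
                      maxsteps = 50000),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(out) || nrow(out) < length(times) ||
        any(!is.finite(out[, 2])) || max(abs(out[, 2])) > 250) {
      failed <- TRUE
      quiescent <- TRUE   # callers assign the penalty
      break
    }
    troot <- attr(out, "troot")
    v <- out[, 2]
    tt <- out[, 1]
    # upward crossings among the root times (grid-neighbour slope test)
    ups <- numeric(0)
    if (length(troot)) {
      for (tr in troot) {
        i <- findInterval(tr, tt)
        i0 <- max(1, i - 1); i1 <- min(length(v), i + 1)
        if (v[i1] > v[i0]) ups <- c(ups, tr)
      }
    }
    # t, vm, Na_i, K_i, the five Catot compartments, crf_NaK, crf_NCX
    rows[[length(rows) + 1]] <- out[-1, c(1, 2, 14, 15, 16:20, 21, 22),
                                    drop = FALSE]
    if (keep_states) state_rows[[length(state_rows) + 1]] <- out[-1, , drop = FALSE]
    if (length(ups)) {
      upstrokes <- c(upstrokes, ups)
      last_up_t <- max(ups)
      if (length(upstrokes) >= 2) {
        cl_est <- stats::median(diff(utils::tail(upstrokes, 4)))
      }
    }
    y0 <- as.numeric(out[nrow(out), 1 + seq_len(length(.state_order))])
    t0 <- tt[length(tt)]
    if (t0 - last_up_t > quiescence_window) {
      quiescent <- TRUE
      break
    }
    cls <- diff(upstrokes)
    stable <- is_quasi_stable(cls, stability_tol, stable_run)
    if (!is.null(horizon)) {
      if (t0 >= horizon) break
      next
    }
    if (length(upstrokes) >= n_cycles + 1) break
    if (stop_when_stable && stable && length(upstrokes) >= stable_run + 1) break
    if (length(upstrokes) >= max_cycles + 1) break
    if (t0 > (max_cycles + 2) * max(cl_est, 200) + quiescence_window) {
      quiescent <- TRUE
      break
    }
  }

  mat <- do.call(rbind, rows)
  if (is.null(mat)) {
    mat <- matrix(numeric(0), ncol = 11)
  }
  ca_vols <- 1000 * c(params$vol_jnc, params$vol_iz, params$vol_blk,
                      params$vol_SRup, params$vol_SRrl)
  # mat cols: t, vm, Na_i, K_i, Catot_jnc..SRrl (5), crf_NaK, crf_NCX
  tr <- tibble::new_tibble(list(
    time_ms = mat[, 1],
    vm_mV = mat[, 2],
    Na_i = mat[, 3],
    Ca_tot = if (nrow(mat)) {
      as.numeric(mat[, 4 + seq_len(5), drop = FALSE] %*% ca_vols)
    } else numeric(0),
    crf_NaK = mat[, 10],
    crf_NCX = mat[, 11]
  ), nrow = nrow(mat))

  cls <- diff(upstrokes)
  final_state <- if (!failed) {
    as_cell_state(stats::setNames(y0, .state_order), t = t0)
  } else init
  structure(tr,
            class = c("ap_trace", class(tr)),
            cycles = upstrokes,
            cycle_lengths = cls,
            quasi_stable = is_quasi_stable(cls, stability_tol, stable_run),
            quiescent = quiescent,
            failed = failed,
            final_state = final_state,
            sf = complete_sf(sf),
            output_dt = output_dt,
            states = if (keep_states) do.call(rbind, state_rows) else NULL)
}

is_quasi_stable <- function(cls, tol = 0.005, run = 3) {
  if (length(cls) < run) return(FALSE)
  last <- utils::tail(cls, run)
  all(abs(diff(last)) / last[-1] < tol)
}

#' Baseline quasi-stable starting state
#'
#' A diastolic state on the baseline model's quasi-stable rhythm, used as
#' the default warm starting point of [simulate_cell()].
#'
#' @return A [cell_state()].
#' @export
baseline_state <- function() {
  .baseline_state_cache
}

#' Extract the current breakdown along a trace
#'
#' Per-current time courses (the eleven roster terms, pA) for a trace
#' simulated with `keep_states = TRUE`.
#'
#' @param trace An `ap_trace` from [simulate_cell()].
#' @param params The [cell_params()] used for the simulation.
#' @param sf Scaling factors used for the simulation.
#' @return Tibble in long format: `time_ms`, `current`, `pA`.
#' @export
current_breakdown <- function(trace, params = cell_params(), sf = NULL) {
  states <- attr(trace, "states")
  if (is.null(states)) {
    stop("trace was not simulated with keep_states = TRUE", call. = FALSE)
  }
  pv <- unname(parm_vector(params, sf, homeostasis = FALSE))
  cur <- t(apply(states[, 1 + seq_len(length(.state_order)), drop = FALSE], 1,
                 function(y) .Call(pf_rhs_call, as.numeric(y), pv)$currents))
  colnames(cur) <- current_roster
  out <- tibble::as_tibble(cur)
  out$time_ms <- states[, 1]
  tidyr::pivot_longer(out, -"time_ms",
                      names_to = "current", values_to = "pA")
}
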