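# Action-potential metrics: cycle length (CL), overshoot (OS), maximum
# diastolic potential (MDP) and AP duration at -20 mV, averaged over the
# last quasi-stable cycles.

# upstroke times of a sampled trace: -20 mV upward crossings refined to the
# maximal dV/dt within a +/-10 ms neighbourhood; returns times in ms
detect_upstrokes <- function(time_ms, vm, threshold = -20, refine = TRUE) {
  n <- length(vm)
  if (n < 3) return(numeric(0))
  up <- which(vm[-n] < threshold & vm[-1] >= threshold)
  if (!length(up)) return(numeric(0))
  dt <- time_ms[2] - time_ms[1]
  vapply(up, function(i) {
    if (!refine) {
      # sub-sample crossing by linear interpolation
      f <- (threshold - vm[i]) / (vm[i + 1] - vm[i])
      return(time_ms[i] + f * dt)
    }
    lo <- max(2, i - round(10 / dt))
    hi <- min(n, i + round(10 / dt))
    dv <- diff(vm[lo:hi])
    time_ms[lo + which.max(dv) - 1]
  }, numeric(1))
}

# -20 mV downward crossing times (sub-sample, linear interpolation)
detect_downcrossings <- function(time_ms, vm, threshold = -20) {
  n <- length(vm)
  dn <- which(vm[-n] >= threshold & vm[-1] < threshold)
  dt <- time_ms[2] - time_ms[1]
  vapply(dn, function(i) {
    f <- (vm[i] - threshold) / (vm[i] - vm[i + 1])
    time_ms[i] + f * dt
  }, numeric(1))
}

#' Action-potential metrics
#'
#' Computes cycle length (CL, interval between successive upstrokes),
#' overshoot (OS, cycle maximum), maximum diastolic potential (MDP, cycle
#' minimum) and AP duration at -20 mV (time between the upward and
#' downward -20 mV crossings, sub-sample interpolated), averaged over the
#' last `n_avg` complete cycles.
#'
#' @param trace An `ap_trace` or any tibble/data.frame with `time_ms` and
#'   `vm_mV` columns on a uniform grid.
#' @param n_avg Number of trailing complete cycles to average (default 3).
#' @return One-row tibble: `CL_ms`, `OS_mV`, `MDP_mV`, `APD20_ms`,
#'   `n_cycles_used`.
#' @examples
#' \donttest{
#' tr <- simulate_cell(n_cycles = 4)
#' ap_metrics(tr)
#' }
#' @export
ap_metrics <- function(trace, n_avg = 3) {
  t <- trace$time_ms
  v <- trace$vm_mV
  ups <- detect_upstrokes(t, v, refine = FALSE)
  if (length(ups) < 2) {
    stop("fewer than 2 upstrokes: cannot compute AP metrics", call. = FALSE)
  }
  ncyc <- min(n_avg, length(ups) - 1)
  ups <- utils::tail(ups, ncyc + 1)
  dns <- detect_downcrossings(t, v)
  per_cycle <- lapply(seq_len(ncyc), function(k) {
    i <- t >= ups[k] & t < ups[k + 1]
    dn_in <- dns[dns > ups[k] & dns <= ups[k + 1]]
    apd <- if (length(dn_in)) dn_in[1] - ups[k] else NA_real_
    c(cl = ups[k + 1] - ups[k], os = max(v[i]), mdp = min(v[i]), apd = apd)
  })
  m <- colMeans(do.call(rbind, per_cycle))
  tibble::tibble(CL_ms = m[["cl"]], OS_mV = m[["os"]], MDP_mV = m[["mdp"]],
                 APD20_ms = m[["apd"]], n_cycles_used = ncyc)
}
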