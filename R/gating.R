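# Hodgkin-Huxley gating: every gated channel follows
#   dpO/dt = alpha(Vm) * (1 - pO) - beta(Vm) * pO
# with rates parameterized through the steady state x_inf(Vm) and time
# constant tau(Vm): alpha = x_inf/tau, beta = (1 - x_inf)/tau.

# scheme ids shared with the compiled code
.gate_schemes <- c(m = 0L, h = 1L, d = 2L, f = 3L, y = 4L, pa = 5L, n = 6L,
                   r_ur = 7L, s_ur = 8L, r_to = 9L, q_to = 10L)

# guarded exponential, identical to the compiled sexp()
sexp <- function(x) exp(pmin(50, pmax(-50, x)))

#' Voltage-dependent gate opening/closing rates
#'
#' Returns the opening rate `alpha` and closing rate `beta` (per ms) of one
#' gating scheme at the given membrane potential(s).  Schemes: `m`, `h`
#' (fast Na activation/inactivation), `d`, `f` (L-type Ca), `y` (funny
#' current activation), `pa` (rapid delayed rectifier activation), `n`
#' (slow delayed rectifier), `r_ur`/`s_ur` (ultrarapid K), `r_to`/`q_to`
#' (transient outward K).
#'
#' @param scheme Gating scheme name (see above).
#' @param vm Membrane potential, mV (vectorized).
#' @return Tibble with columns `vm`, `alpha`, `beta`.
#' @examples
#' gate_rates("m", c(-80, -40, 0))
#' @export
gate_rates <- function(scheme, vm) {
  scheme <- match.arg(scheme, names(.gate_schemes))
  x <- gate_inf_tau(scheme, vm)
  out <- tibble::tibble(vm = vm, alpha = x$inf / x$tau,
                        beta = (1 - x$inf) / x$tau)
  if (any(out$alpha < 0 | out$beta < 0)) {
    stop("gating scheme '", scheme, "' produced a negative rate", call. = FALSE)
  }
  out
}

# steady state and time constant per scheme (R mirror of the compiled table)
gate_inf_tau <- function(scheme, vm) {
  switch(scheme,
    m = list(inf = 1 / (1 + sexp(-(vm + 40) / 6)),
             tau = 0.12 + 0.4 / (1 + sexp((vm + 40) / 8))),
    h = list(inf = 1 / (1 + sexp((vm + 64) / 4.5)),
             tau = 1 + 30 / (1 + sexp((vm + 40) / 6))),
    d = list(inf = 1 / (1 + sexp(-(vm + 18) / 6)),
             tau = 0.6 + 1.8 / (1 + sexp((vm + 30) / 8))),
    f = list(inf = 1 / (1 + sexp((vm + 35) / 4.5)),
             tau = 100 + 200 / (1 + sexp((vm + 25) / 6))),
    y = list(inf = 1 / (1 + sexp((vm + 78) / 9)),
             tau = rep(250, length(vm))),
    pa = list(inf = 1 / (1 + sexp(-(vm + 10) / 7)),
              tau = 80 + 250 / (1 + sexp((vm + 35) / 8))),
    n = list(inf = 1 / (1 + sexp(-(vm - 2) / 13)),
             tau = rep(400, length(vm))),
    r_ur = list(inf = 1 / (1 + sexp(-(vm + 6) / 9)),
                tau = rep(8, length(vm))),
    s_ur = list(inf = 1 / (1 + sexp((vm + 30) / 10)),
                tau = rep(800, length(vm))),
    r_to = list(inf = 1 / (1 + sexp(-(vm + 14) / 9)),
                tau = rep(4, length(vm))),
    q_to = list(inf = 1 / (1 + sexp((vm + 42) / 6)),
                tau = rep(35, length(vm)))
  )
}

#' Time derivative of a gate open probability
#'
#' `dpO/dt = alpha * (1 - pO) - beta * pO` with voltage-dependent rates.
#' The fixed point at `alpha / (alpha + beta)` is the steady-state open
#' probability; the derivative is non-negative at `pO = 0` and
#' non-positive at `pO = 1`, so trajectories cannot leave `[0, 1]`.
#'
#' @param pO Open probability in `[0, 1]`.
#' @param vm Membrane potential, mV.
#' @param scheme Gating scheme name, see [gate_rates()].
#' @return Derivative in 1/ms.
#' @examples
#' gate_derivative(0.5, -60, "m")
#' @export
gate_derivative <- function(pO, vm, scheme) {
  if (any(pO < 0 | pO > 1)) {
    stop("open probability outside [0, 1]", call. = FALSE)
  }
  r <- gate_rates(scheme, vm)
  r$alpha * (1 - pO) - r$beta * pO
}
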