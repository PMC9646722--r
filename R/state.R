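# Full dynamical state of the cell: membrane potential, gate open
# probabilities, intracellular Na+/K+, total Ca of the five compartments
# (rapid-buffer approximation: free Ca is recovered algebraically), and the
# two homeostasis correction factors.

.state_order <- c("vm", "m", "h", "d", "f", "y", "pa", "n",
                  "r_ur", "s_ur", "r_to", "q_to",
                  "Na_i", "K_i",
                  "Catot_jnc", "Catot_iz", "Catot_blk",
                  "Catot_SRup", "Catot_SRrl",
                  "crf_NaK", "crf_NCX")

.gate_names <- .state_order[2:12]
.ca_compartments <- c("jnc", "iz", "blk", "SRup", "SRrl")

#' Construct a cell state
#'
#' A named numeric vector holding the full dynamical state.  With no
#' arguments, returns a diastolic starting state near the baseline model's
#' quasi-stable rhythm (gates at their steady state for the given `vm`).
#'
#' @param vm Membrane potential, mV.
#' @param Na_i,K_i Intracellular Na+/K+ concentrations, mM.
#' @param Catot Named vector of per-compartment total Ca (mM) over
#'   `jnc, iz, blk, SRup, SRrl`.
#' @param crf_NaK,crf_NCX Homeostasis correction factors (dimensionless).
#' @param t Time stamp attached as an attribute, ms.
#' @return Object of class `cell_state`.
#' @examples
#' s <- cell_state()
#' s[["vm"]]
#' @export
cell_state <- function(vm = -75, Na_i = 6.1, K_i = 140,
                       Catot = c(jnc = 0.01, iz = 0.01, blk = 0.015,
                                 SRup = 0.3, SRrl = 0.35),
                       crf_NaK = 1, crf_NCX = 1, t = 0) {
  stopifnot(all(.ca_compartments %in% names(Catot)))
  gates <- vapply(.gate_names, function(g) {
    x <- gate_inf_tau(g, vm)
    x$inf
  }, numeric(1))
  s <- c(vm = vm, gates,
         Na_i = Na_i, K_i = K_i,
         stats::setNames(as.numeric(Catot[.ca_compartments]),
                         paste0("Catot_", .ca_compartments)),
         crf_NaK = crf_NaK, crf_NCX = crf_NCX)
  s <- s[.state_order]
  validate_state(s)
  structure(s, t = t, class = c("cell_state", "numeric"))
}

as_cell_state <- function(x, t = 0) {
  stopifnot(is.numeric(x), all(.state_order %in% names(x)))
  structure(x[.state_order], t = t, class = c("cell_state", "numeric"))
}

validate_state <- function(s) {
  g <- s[.gate_names]
  if (any(!is.finite(s))) stop("non-finite cell state", call. = FALSE)
  if (any(g < 0 | g > 1)) {
    stop("gate open probability outside [0, 1]: ",
         paste(.gate_names[g < 0 | g > 1], collapse = ", "), call. = FALSE)
  }
  if (s[["Na_i"]] <= 0 || s[["K_i"]] <= 0) {
    stop("ion concentrations must be positive", call. = FALSE)
  }
  if (any(s[paste0("Catot_", .ca_compartments)] < 0)) {
    stop("negative compartment Ca", call. = FALSE)
  }
  if (s[["crf_NaK"]] <= 0 || s[["crf_NCX"]] <= 0) {
    stop("correction factors must be positive", call. = FALSE)
  }
  invisible(s)
}

# free Ca from total Ca under the rapid single-buffer approximation
free_ca <- function(catot, B, Kd) {
  b <- B + Kd - catot
  pmax(0, 0.5 * (-b + sqrt(b * b + 4 * Kd * catot)))
}

#' Total cellular calcium
#'
#' Volume-weighted sum of total (free plus buffered) Ca over the five
#' compartments (junctional cleft, intermediate zone, bulk cytosol, network
#' SR and junctional SR), in attomole.
#'
#' @param state A [cell_state()].
#' @param params A [cell_params()] (supplies the compartment volumes).
#' @return Total Ca, amol.
#' @examples
#' ca_total(cell_state(), cell_params())
#' @export
ca_total <- function(state, params = cell_params()) {
  nm <- paste0("Catot_", .ca_compartments)
  if (!all(nm %in% names(state))) {
    stop("state is missing Ca compartments: ",
         paste(setdiff(nm, names(state)), collapse = ", "), call. = FALSE)
  }
  vols <- unlist(params[paste0("vol_", .ca_compartments)])
  # mM * pL = fmol; report amol
  1000 * sum(as.numeric(state[nm]) * as.numeric(vols))
}

#' Per-cycle homeostasis update of the transporter correction factors
#'
#' Applies the slow negative feedback that clamps intracellular Na+ and
#' total cell Ca to their reference levels:
#' `crf_NaK <- crf_NaK - (std_Nai - Na_i) * 0.3` and
#' `crf_NCX <- crf_NCX - (std_Catot - Ca_tot) * 0.008`.
#' The updated factors scale `maxI_NaK` and `maxI_NCX` in all subsequent
#' transporter-current evaluations.  Factors driven to zero or below are
#' clipped at `params$crf_floor` with a warning (degenerate regime).
#'
#' @inheritParams ca_total
#' @return The state with updated `crf_NaK`, `crf_NCX`.
#' @examples
#' s <- cell_state(Na_i = 6.0)
#' homeostasis_update(s, cell_params())[["crf_NaK"]]
#' @export
homeostasis_update <- function(state, params = cell_params()) {
  catot <- ca_total(state, params)
  d_nak <- -(params$std_Nai - state[["Na_i"]]) * params$g_NaK
  d_ncx <- -(params$std_Catot - catot) * params$g_NCX
  state[["crf_NaK"]] <- state[["crf_NaK"]] + d_nak
  state[["crf_NCX"]] <- state[["crf_NCX"]] + d_ncx
  low <- c(state[["crf_NaK"]], state[["crf_NCX"]]) < params$crf_floor
  if (any(low)) {
    warning("correction factor driven to the floor (",
            paste(c("crf_NaK", "crf_NCX")[low], collapse = ", "),
            "); clipping", call. = FALSE)
    state[["crf_NaK"]] <- max(state[["crf_NaK"]], params$crf_floor)
    state[["crf_NCX"]] <- max(state[["crf_NCX"]], params$crf_floor)
  }
  state
}

#' @export
print.cell_state <- function(x, ...) {
  cat("<cell_state> t =", attr(x, "t") %||% 0, "ms\n")
  print(unclass(x))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
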