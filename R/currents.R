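# Membrane currents.  Every channel current has the form
#   I_x = sf_x * Gbar_x * pO * (Vm - E_x)          (outward positive)
# with pO resolved from the state (pO = 1 for the time-independent
# background non-selective cation current).  Transporter currents (NaK,
# NCX) follow saturating turnover expressions scaled by the homeostasis
# correction factors.

RTF_MV <- 26.7139   # RT/F at 310 K, mV
FARADAY <- 96485.332

# open probability of one channel from the state (+ params for rectifiers)
open_probability <- function(current, state, params) {
  vm <- state[["vm"]]
  switch(current,
    Na  = state[["m"]]^3 * state[["h"]],
    CaL = {
      caJ <- free_ca(state[["Catot_jnc"]], params$B_jnc, params$Kd_jnc)
      state[["d"]] * state[["f"]] * params$KL_CaL / (params$KL_CaL + caJ)
    },
    ha  = state[["y"]],
    K1  = {
      ek <- RTF_MV * log(params$K_o / state[["K_i"]])
      1 / (1 + sexp((vm - ek - 8) / 10))
    },
    Kr  = state[["pa"]] / (1 + sexp((vm + 10) / 12)),
    Ks  = state[["n"]]^2,
    Kur = state[["r_ur"]] * state[["s_ur"]],
    Kto = state[["r_to"]] * state[["q_to"]],
    bNSC = 1,
    stop("'", current, "' is not a channel current", call. = FALSE)
  )
}

# reversal potential of one channel, mV
reversal_potential <- function(current, state, params) {
  switch(current,
    Na = RTF_MV * log(params$Na_o / state[["Na_i"]]),
    CaL = params$E_CaL,
    ha = params$E_ha,
    bNSC = params$E_bNSC,
    K1 = , Kr = , Ks = , Kur = , Kto =
      RTF_MV * log(params$K_o / state[["K_i"]]),
    stop("'", current, "' is not a channel current", call. = FALSE)
  )
}

#' Single channel current
#'
#' Evaluates `I_x = sf_x * Gbar_x * pO * (Vm - E_x)` in pA (outward
#' positive) for one of the nine channel currents, with the open
#' probability resolved from the state.
#'
#' @param current Channel name, one of [channel_roster].
#' @param state A [cell_state()].
#' @param params A [cell_params()].
#' @param sf Scaling factors ([scaling_factors()] or named vector);
#'   currents not named are at sf = 1.
#' @return Current in pA.
#' @examples
#' channel_current("K1", cell_state(), cell_params())
#' @export
channel_current <- function(current, state, params = cell_params(), sf = NULL) {
  if (!current %in% channel_roster) {
    stop("'", current, "' is not in the channel roster", call. = FALSE)
  }
  sf <- complete_sf(sf)
  pO <- open_probability(current, state, params)
  if (pO < 0 || pO > 1) {
    stop("open probability outside [0, 1] for ", current, call. = FALSE)
  }
  g <- params[[paste0("G_", current)]] * unname(sf[[current]])
  e <- reversal_potential(current, state, params)
  g * pO * (state[["vm"]] - e)
}

# Na/K pump current, pA (outward positive)
nak_current <- function(state, params) {
  vm <- state[["vm"]]
  nai <- state[["Na_i"]]
  fv <- 1 / (1 + 0.1245 * sexp(-0.1 * vm / RTF_MV) + 0.0353 * sexp(-vm / RTF_MV))
  state[["crf_NaK"]] * params$maxI_NaK *
    (nai / (nai + params$Km_Na_NaK))^3 *
    (params$K_o / (params$K_o + params$Km_K_NaK)) * fv
}

# Na-Ca exchanger current, pA (outward positive; forward mode is inward)
ncx_current <- function(state, params) {
  vm <- state[["vm"]]
  nai <- state[["Na_i"]]
  caB <- free_ca(state[["Catot_blk"]], params$B_blk, params$Kd_blk)
  g <- params$gamma_NCX
  e1 <- sexp(g * vm / RTF_MV)
  e2 <- sexp((g - 1) * vm / RTF_MV)
  state[["crf_NCX"]] * params$maxI_NCX *
    (e1 * nai^3 * params$Ca_o - e2 * params$Na_o^3 * caB) /
    ((params$Km_Na_NCX^3 + params$Na_o^3) *
       (params$Km_Ca_NCX + params$Ca_o) * (1 + params$ksat_NCX * e2))
}

#' Total membrane current with per-current breakdown
#'
#' The net membrane current is the sum of the eleven roster terms:
#' nine channel currents plus the Na/K pump and Na-Ca exchanger.
#'
#' @inheritParams channel_current
#' @return A list with `total` (pA) and `breakdown`, a tibble with one row
#'   per roster current.
#' @examples
#' total_current(cell_state(), cell_params())$total
#' @export
total_current <- function(state, params = cell_params(), sf = NULL) {
  sf <- complete_sf(sf)
  ch <- vapply(channel_roster, channel_current, numeric(1),
               state = state, params = params, sf = sf)
  tr <- c(NaK = nak_current(state, params), NCX = ncx_current(state, params))
  br <- tibble::tibble(current = current_roster,
                       pA = as.numeric(c(ch, tr)[current_roster]))
  list(total = sum(br$pA), breakdown = br)
}

#' Time derivative of the full cell state
#'
#' `dVm/dt = -I_tot_cell / Cm`; each gate follows its Hodgkin-Huxley rate
#' equation; intracellular Na+/K+ and the five-compartment total-Ca pools
#' follow the membrane and SR fluxes with current-to-flux conversion
#' `J [fmol/ms] = I [pA] / (z F)`.  This is the reference R implementation;
#' [simulate_cell()] integrates the identical compiled right-hand side.
#'
#' @inheritParams channel_current
#' @return Named numeric vector of derivatives (per ms) in state order.
#' @examples
#' state_derivative(cell_state(), cell_params())[["vm"]]
#' @export
state_derivative <- function(state, params = cell_params(), sf = NULL) {
  validate_state(state)
  tc <- total_current(state, params, sf)
  br <- stats::setNames(tc$breakdown$pA, tc$breakdown$current)
  d <- stats::setNames(numeric(length(.state_order)), .state_order)
  d[["vm"]] <- -tc$total / params$Cm
  if (!is.finite(d[["vm"]])) {
    bad <- tc$breakdown$current[!is.finite(tc$breakdown$pA)]
    stop("non-finite membrane current from: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  vm <- state[["vm"]]
  for (g in .gate_names) {
    d[[g]] <- gate_derivative(state[[g]], vm, g)
  }

  vol_cyt <- params$vol_jnc + params$vol_iz + params$vol_blk
  j_na <- br[["Na"]] + params$f_ha_Na * br[["ha"]] +
    params$f_bNSC_Na * br[["bNSC"]]
  j_k <- br[["K1"]] + br[["Kr"]] + br[["Ks"]] + br[["Kur"]] + br[["Kto"]] +
    (1 - params$f_ha_Na) * br[["ha"]] +
    (1 - params$f_bNSC_Na) * br[["bNSC"]]
  d[["Na_i"]] <- -(j_na + 3 * br[["NaK"]] + 3 * br[["NCX"]]) /
    (FARADAY * vol_cyt)
  d[["K_i"]] <- -(j_k - 2 * br[["NaK"]]) / (FARADAY * vol_cyt)

  caJ <- free_ca(state[["Catot_jnc"]], params$B_jnc, params$Kd_jnc)
  caI <- free_ca(state[["Catot_iz"]], params$B_iz, params$Kd_iz)
  caB <- free_ca(state[["Catot_blk"]], params$B_blk, params$Kd_blk)
  caU <- state[["Catot_SRup"]]
  caR <- free_ca(state[["Catot_SRrl"]], params$B_SRrl, params$Kd_SRrl)

  po_ryr <- caJ^2 / (caJ^2 + params$Km_RyR^2)
  j_rel <- params$P_rel * po_ryr * (caR - caJ)
  j_up <- params$P_up * caB^2 / (caB^2 + params$K_up^2)
  j_tr <- params$g_tr * (caU - caR)
  j_ji <- params$g_d_jnc_iz * (caJ - caI)
  j_ib <- params$g_d_iz_blk * (caI - caB)

  d[["Catot_jnc"]] <- (-br[["CaL"]] / (2 * FARADAY) + j_rel - j_ji) /
    params$vol_jnc
  d[["Catot_iz"]] <- (j_ji - j_ib) / params$vol_iz
  d[["Catot_blk"]] <- (j_ib - j_up + br[["NCX"]] / FARADAY) / params$vol_blk
  d[["Catot_SRup"]] <- (j_up - j_tr) / params$vol_SRup
  d[["Catot_SRrl"]] <- (j_tr - j_rel) / params$vol_SRrl
  d[["crf_NaK"]] <- 0
  d[["crf_NCX"]] <- 0
  d
}

# compiled-equivalent RHS via .Call, used by consistency tests
rhs_compiled <- function(state, params = cell_params(), sf = NULL,
                         homeostasis = TRUE) {
  pv <- parm_vector(params, sf, homeostasis)
  out <- .Call(pf_rhs_call, as.numeric(state[.state_order]), unname(pv))
  list(deriv = stats::setNames(out$deriv, .state_order),
       currents = stats::setNames(out$currents, current_roster))
}
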