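#' Ionic current roster
#'
#' The eleven membrane current systems of the model: nine channel currents
#' and the two transporters (Na/K pump and Na-Ca exchanger).  Conductance
#' scaling factors are defined for the nine channel currents; transporter
#' capacity is governed by the homeostasis correction factors instead.
#'
#' @format Character vector of current names in roster order.
#' @export
current_roster <- c("Na", "CaL", "ha", "K1", "Kr", "Ks", "Kur", "Kto",
                    "bNSC", "NaK", "NCX")

#' @rdname current_roster
#' @export
channel_roster <- current_roster[1:9]

# canonical order of the compiled parameter vector (lock step with src/cellmodel.c)
.parm_order <- c(
  "Cm",
  "G_Na", "G_CaL", "G_ha", "G_K1", "G_Kr", "G_Ks", "G_Kur", "G_Kto", "G_bNSC",
  "maxI_NaK", "maxI_NCX",
  "E_CaL", "E_ha", "E_bNSC",
  "Na_o", "K_o", "Ca_o",
  "vol_jnc", "vol_iz", "vol_blk", "vol_SRup", "vol_SRrl",
  "B_jnc", "Kd_jnc", "B_iz", "Kd_iz", "B_blk", "Kd_blk", "B_SRrl", "Kd_SRrl",
  "KL_CaL",
  "P_up", "K_up", "P_rel", "Km_RyR", "g_tr", "g_d_jnc_iz", "g_d_iz_blk",
  "Km_Na_NaK", "Km_K_NaK",
  "Km_Na_NCX", "Km_Ca_NCX", "ksat_NCX", "gamma_NCX",
  "std_Nai", "std_Catot", "g_NaK", "g_NCX", "crf_floor",
  "f_ha_Na", "f_bNSC_Na",
  "homeostasis_on", "root_mv"
)

#' Model parameters
#'
#' Construct the full parameter set of the spontaneous-AP cell model:
#' membrane capacitance, the limiting conductances of the nine channel
#' currents (nS), transporter capacities (pA), reversal-potential rules,
#' calcium compartment volumes (pL) and buffers, SR flux parameters, and the
#' intracellular-ion homeostasis feedback (reference levels `std_Nai` = 6.1
#' mM and `std_Catot` = 79 amol with per-cycle gains 0.3 per mM and 0.008
#' per amol).  Defaults define the baseline cell; any field can be
#' overridden by name.
#'
#' @param ... Named overrides of individual parameters, e.g. `G_Kr = 5`.
#' @param rtol,atol Relative/absolute solver tolerances for [simulate_cell()].
#' @return An object of class `cell_params` (a named list).
#' @examples
#' p <- cell_params()
#' p$G_Kr
#' @export
cell_params <- function(..., rtol = 1e-6, atol = 1e-8) {
  p <- list(
    Cm = 50,                       # pF
    G_Na = 300, G_CaL = 12, G_ha = 1.2, G_K1 = 3.5, G_Kr = 6, G_Ks = 1,
    G_Kur = 0.15, G_Kto = 1, G_bNSC = 0.75,        # nS
    maxI_NaK = 12000, maxI_NCX = 60000,             # pA
    E_CaL = 45, E_ha = -30, E_bNSC = -10,          # mV (fixed reversals)
    Na_o = 140, K_o = 5.4, Ca_o = 1.8,             # mM
    vol_jnc = 0.03, vol_iz = 0.3, vol_blk = 3.4,
    vol_SRup = 0.06, vol_SRrl = 0.015,             # pL
    B_jnc = 0.3, Kd_jnc = 0.01,
    B_iz = 0.04, Kd_iz = 0.0006,
    B_blk = 0.05, Kd_blk = 0.0006,
    B_SRrl = 1, Kd_SRrl = 0.6,                     # mM
    KL_CaL = 0.03,                                # mM, Ca-dependent inactivation
    P_up = 0.01,                                   # fmol/ms
    K_up = 0.0006,                                 # mM
    P_rel = 0.3,                                   # pL/ms
    Km_RyR = 0.025,                                 # mM
    g_tr = 0.1, g_d_jnc_iz = 0.1, g_d_iz_blk = 0.15,  # pL/ms
    Km_Na_NaK = 32, Km_K_NaK = 1.5,                # mM
    Km_Na_NCX = 87.5, Km_Ca_NCX = 1.38, ksat_NCX = 0.1, gamma_NCX = 0.35,
    std_Nai = 6.1,                                 # mM
    std_Catot = 79,                                # amol
    g_NaK = 0.3,                                   # per mM, per cycle
    g_NCX = 0.008,                                 # per amol, per cycle
    crf_floor = 0.01,
    f_ha_Na = 0.8, f_bNSC_Na = 0.9,                # Na fraction of mixed currents
    homeostasis_on = 1,
    root_mv = -20                                  # cycle-detection threshold
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown cell parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  p$rtol <- rtol
  p$atol <- atol
  p$formulation_id <- "pacefit-hh-1"
  structure(p, class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params> formulation", x$formulation_id, "\n")
  cat("  Cm:", x$Cm, "pF   C channel conductances (nS):\n")
  g <- unlist(x[paste0("G_", channel_roster)])
  names(g) <- channel_roster
  print(g)
  cat("  maxI_NaK:", x$maxI_NaK, "pA  maxI_NCX:", x$maxI_NCX, "pA\n")
  cat("  homeostasis: std_Nai", x$std_Nai, "mM, std_Catot", x$std_Catot,
      "amol (gains", x$g_NaK, "/", x$g_NCX, ")\n")
  invisible(x)
}

#' Scaling factors for channel conductances
#'
#' A set of dimensionless multipliers `sf_x` on the limiting conductances of
#' the nine channel currents.  Currents not named are implicitly held at
#' their baseline value (sf = 1).
#'
#' @param ... Named values, e.g. `Kr = 1.1, CaL = 0.9`, or a single named
#'   numeric vector.
#' @return Named numeric vector over [channel_roster], class `scaling_factors`.
#' @examples
#' scaling_factors(Kr = 1.2)
#' @export
scaling_factors <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && is.null(names(dots)) && is.numeric(dots[[1]])) {
    dots <- as.list(dots[[1]])
  }
  sf <- stats::setNames(rep(1, length(channel_roster)), channel_roster)
  if (length(dots)) {
    vals <- unlist(dots)
    bad <- setdiff(names(vals), channel_roster)
    if (length(bad)) {
      stop("unknown current name(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (any(vals <= 0)) stop("every sf must be > 0", call. = FALSE)
    sf[names(vals)] <- vals
  }
  structure(sf, class = c("scaling_factors", "numeric"))
}

# complete an arbitrary named vector to the full 9-channel sf set
complete_sf <- function(sf = NULL) {
  if (is.null(sf)) return(scaling_factors())
  if (inherits(sf, "scaling_factors") && length(sf) == length(channel_roster)) {
    return(sf)
  }
  do.call(scaling_factors, as.list(sf))
}

# numeric vector in the canonical compiled order, with sf folded into the
# channel conductances (G_x = Gbar_x * sf_x)
parm_vector <- function(params, sf = NULL, homeostasis = TRUE) {
  stopifnot(inherits(params, "cell_params"))
  sf <- complete_sf(sf)
  p <- params
  for (cur in channel_roster) {
    p[[paste0("G_", cur)]] <- p[[paste0("G_", cur)]] * unname(sf[[cur]])
  }
  p$homeostasis_on <- as.numeric(homeostasis)
  v <- vapply(.parm_order, function(nm) as.numeric(p[[nm]]), numeric(1))
  stats::setNames(v, .parm_order)
}
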