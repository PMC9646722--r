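# pacefit-hh-1: the cell-model formulation

The package's spontaneous-AP model is an original compact formulation,
assembled from standard published building blocks and tuned so that the
baseline parameter set produces a spontaneously beating, hiPSC-CM-like
action potential.  It is *not* a re-implementation of any specific
published cell model; the recovery method the package implements is
formulation-agnostic, and the formulation is fixed by the contract below.

## Contract

1. The net membrane current is the sum of exactly eleven terms:
   `I_tot = I_Na + I_CaL + I_ha + I_K1 + I_Kr + I_Ks + I_Kur + I_Kto +
   I_bNSC + I_NaK + I_NCX`.
2. `dVm/dt = -I_tot / Cm`; every channel current has the form
   `I_x = sf_x * Gbar_x * pO * (Vm - E_x)` (outward positive), with every
   time-dependent gate obeying `dpO/dt = alpha(Vm) * (1 - pO) -
   beta(Vm) * pO`.
3. Whole-cell conductances enter only as `G_x = Gbar_x * sf_x`.
4. Intracellular Na+ and total cell Ca are clamped by per-cycle integral
   feedback on the transporter capacities:
   `crf_NaK += (Na_i - 6.1 mM) * 0.3` and
   `crf_NCX += (Ca_tot - 79 amol) * 0.008`, with
   `Ca_tot = sum over {jnc, iz, blk, SRup, SRrl} of [Ca_tot]_c * vol_c`.
5. At `sf = 1` the model beats spontaneously with CL, OS, MDP and APD(-20)
   inside the range spanned by spontaneously beating hiPSC-CM recordings
   (CL 240-1326 ms, OS 14-33 mV, MDP -87..-62 mV), with a long slow
   diastolic depolarization.

Baseline metrics of this formulation (computed by
`ap_metrics(simulate_cell())`): CL 756 ms, OS 16 mV, MDP -74 mV,
APD(-20) 69 ms.

## Current equations

All gates are parameterized by Boltzmann steady states `x_inf(Vm)` and
time constants `tau_x(Vm)` with `alpha = x_inf/tau`, `beta = (1-x_inf)/tau`;
the exact midpoints/slopes live in `src/cellmodel.c` (`gate_rates`) and the
identical R mirror `R/gating.R`.

| Current | pO | Reversal | Notes |
|---|---|---|---|
| I_Na | m^3 h | Nernst (Na) | fast activation m, inactivation h |
| I_CaL | d f fCa | fixed +45 mV | fCa = KL/(KL + [Ca]_jnc), rapid Ca inactivation |
| I_ha | y | fixed -30 mV | hyperpolarization-activated, mixed Na/K |
| I_K1 | inst. rectification | Nernst (K) | open fraction 1/(1+exp((V-E_K-8)/10)) |
| I_Kr | pa * inst. rect. | Nernst (K) | slow deactivation drives early SDD |
| I_Ks | n^2 | Nernst (K) | slow delayed rectifier |
| I_Kur | r_ur s_ur | Nernst (K) | small sustained outward |
| I_Kto | r_to q_to | Nernst (K) | transient outward |
| I_bNSC | 1 | fixed -10 mV | time-independent background cation |

Transporters (functional forms patterned on Luo & Rudy 1994, Circ Res
74:1071, as used across the human-ventricular-model literature):

- `I_NaK = crf_NaK * maxI_NaK * (Na_i/(Na_i+Km_Na))^3 * K_o/(K_o+Km_K) *
  fV(Vm)` with the standard voltage factor
  `fV = 1/(1 + 0.1245 exp(-0.1 VF/RT) + 0.0353 exp(-VF/RT))`.
- `I_NCX = crf_NCX * maxI_NCX * (e^{g VF/RT} Na_i^3 Ca_o -
  e^{(g-1)VF/RT} Na_o^3 [Ca]_blk) / ((Km_Na^3+Na_o^3)(Km_Ca+Ca_o)
  (1 + ksat e^{(g-1)VF/RT}))`, gamma = 0.35.

## Calcium subsystem

Five compartments (junctional cleft, intermediate zone, bulk cytosol,
network SR, junctional SR) carry total-Ca states; free Ca is recovered
algebraically by a rapid single-buffer equilibrium per compartment
(`free_ca()`).  Fluxes: L-type influx into jnc; RyR release
(Ca-activated, Hill-2 in junctional free Ca) SRrl -> jnc; passive
diffusion jnc -> iz -> blk; SERCA uptake (Hill-2 in bulk free Ca)
blk -> SRup; transfer SRup -> SRrl; NCX extrusion from blk.

## Ion bookkeeping

`d[ion]/dt = -I_ion / (z F vol_cyt)` with the pump/exchanger
stoichiometries 3Na+/2K+ and 3Na+/1Ca2+.  The mixed-cation currents
(I_ha, I_bNSC) are split into Na and K components by fixed fractions
(`f_ha_Na`, `f_bNSC_Na`); the split is electrically neutral and only
affects the ion bookkeeping (it was chosen to give the Na turnover that
damps the Na homeostasis loop within ~40 cycles).

## Units

mV, ms, pA, nS, pF, mM, pL; membrane fluxes `J [fmol/ms] = I [pA]/(zF)`;
total cell Ca reported in amol (`mM * pL * 1000`).
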