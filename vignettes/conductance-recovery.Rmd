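---
title: "Recovering ionic conductances from spontaneous action potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering ionic conductances from spontaneous action potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pacefit)
```

## The problem

Immature cardiomyocytes derived from human induced pluripotent stem cells
(hiPSC-CMs) beat spontaneously, with action-potential (AP) shapes too
heterogeneous to classify as nodal, atrial or ventricular.  A natural
hypothesis is that this heterogeneity reflects different functional
expression levels of a common set of membrane ionic currents.  If so, the
expression pattern of a cell should be recoverable from its spontaneous AP
waveform alone, by adjusting the whole-cell conductances `G_x` of a
mechanistic membrane model until its output superimposes on the recording.

This is an inverse problem, and its central difficulty is identifiability:
different conductance combinations can produce nearly identical waveforms.
`pacefit` implements the machinery for studying exactly that question at
desk scale: a compact spontaneously active cell model, a waveform MSE
objective, a base-point/new-point Pattern Search (PS) optimizer with a
multi-run randomized-restart protocol, global MSE-landscape mapping, and
post-hoc ensemble analytics (PCA, complementary-plane fits).

## The cell model

The model (formulation id `pacefit-hh-1`, fully documented in the
repository file `FORMULATION.md`) tracks the membrane potential, eleven
membrane current systems, intracellular Na+ and K+, and total Ca in five
compartments (junctional cleft, intermediate zone, bulk cytosol, network
and junctional SR; free Ca is recovered by a rapid-buffer approximation):

- `dVm/dt = -I_tot / Cm`, `I_tot = I_Na + I_CaL + I_ha + I_K1 + I_Kr +
  I_Ks + I_Kur + I_Kto + I_bNSC + I_NaK + I_NCX`;
- every channel current is `I_x = sf_x * Gbar_x * pO * (Vm - E_x)`
  (outward positive), each time-dependent gate obeying the two-state rate
  equation `dpO/dt = alpha(Vm)(1 - pO) - beta(Vm) pO`;
- the dimensionless scaling factors `sf_x` on the nine channel
  conductances are the optimization variables; currents left out of an
  experiment stay at `sf = 1`.

The baseline (`sf = 1`) rhythm has CL ≈ 756 ms, OS ≈ +16 mV, MDP ≈ -74 mV
and APD(-20) ≈ 69 ms — inside the range spanned by spontaneously beating
hiPSC-CM recordings — with a long slow diastolic depolarization (SDD)
carried by the background cation current, the hyperpolarization-activated
current and deactivating `I_Kr`, opposed by `I_K1`.

### Ionic homeostasis

Whenever conductances change, intracellular ion levels drift.  The model
imitates long-term physiological homeostasis by slow integral feedback on
the two transporter capacities, applied once per detected cycle (at the
upstroke, which is also the feedback's sampling instant):

```
crf_NaK <- crf_NaK - (std_Nai  - Na_i ) * 0.3     std_Nai  = 6.1 mM
crf_NCX <- crf_NCX - (std_Catot - Ca_tot) * 0.008  std_Catot = 79 amol
```

`Ca_tot` is the volume-weighted total Ca over the five compartments.  The
per-cycle cadence is a design choice: the stated gains are slow, and a
cycle is the natural sampling interval of a spontaneously beating cell.
Because `Ca_tot` turns over substantially within each beat (L-type influx
during the AP, exchanger efflux in diastole), the controller regulates its
value *at the cycle boundary*; steady-state reports therefore quote Na_i
and Ca_tot at the final upstroke.  From a ±10% Na_i perturbation both
quantities return to their reference levels within 100 cycles.

The Na fractions of the two mixed-cation currents (`f_ha_Na`,
`f_bNSC_Na`) are electrically neutral bookkeeping parameters; they were
set to give a per-cycle Na turnover that damps the integral loop in a few
tens of cycles rather than letting it ring.

## The objective

`MSE = sum(w * (Vm_a - Vm_t)^2) / sum(w)` on the 0.1 ms grid, between one
quasi-stable cycle of the candidate ("adaptive") model and one cycle of
the target, after registering the two at their upstrokes.  Details that
matter numerically:

- **Registration** uses the sub-sample time of the -20 mV upward crossing,
  refined by local spline interpolation.  Grid-snapped registration leaves
  a periodic bias of order `(dV/dt * dt)^2` that is large enough to create
  artificial micro-minima for the optimizer.
- **Interpolation** of the adaptive trace onto the target's phase grid is
  cubic; linear interpolation carries an error of order `V'' dt^2 / 8`
  that again shows up as a periodic ripple as the candidate's cycle length
  slides across the grid.
- **Window**: one full cycle by default, clipped at the shorter of the two
  cycle lengths with a fractional weight on the boundary sample (so the
  MSE is continuous in the parameters).  A cycle-length mismatch is felt
  as an end-of-window residual, which is what makes the objective
  sensitive to chronotropic errors.  Opt-in phase windows (SDD, plateau,
  repolarization) and per-phase weights are available via
  `objective_spec()`; phase landmarks are taken from the target cycle.
- **Quiescence**: parameter sets that stop beating receive a large finite
  penalty (`1e4` mV^2 by default), so the optimizer always has a
  comparable scalar.
- **Determinism**: every cost evaluation integrates a fixed settling
  horizon from one fixed initial state (the target's settled state) before
  the measured cycle.  This makes the cost a deterministic function whose
  global minimum sits exactly at the generating factors, at the price of a
  slight distortion of the landscape far from the optimum.  History
  dependence (warm starts from whichever state was evaluated last) would
  make identical factor sets score different MSEs, which Pattern Search
  tolerates poorly near convergence.

## Pattern Search and the multi-run protocol

`ps_optimize()` keeps a base point (BP) and probes each selected factor at
±`stp` in a fixed sweep order, accumulating improvements into a new point
(NP); an improved sweep renews BP at the same step, otherwise `stp` is
multiplied by `redFct` (default 1/4) until it falls below the critical
step `crtstp`.  Defaults: `stp0 = 0.04`, comparable to the ±5-15%
randomization scale of the restart protocol; `crtstp = 5e-5` within the
protocol's 2e-5 to 1e-4 range (the recovery experiments below use the
fine end, 2e-5, because the MSE valley around the optimum is strongly
anisotropic and coordinate descent advances along it in steps of order
`stp`).  Probes at non-positive factors are automatic non-improvements.
Two documented stand-ins where the protocol leaves the details open: the
`-stp` probe is skipped when `+stp` already improves, and ties between
equal `+`/`-` probes go to `+stp`.

`orp_test()` repeats the optimization from independent uniform
randomizations of the ground-truth factors (±10% by default), pools all
base points into a common sf-MSE scatter, and reports top-K statistics
(`top_k_stats()`): per-factor means and standard errors over the K
lowest-MSE runs, the mean final log10(MSE), and the homeostasis endpoints.
Single runs frequently stall at intermediate MSE levels — coordinate
search cannot follow a strongly anisotropic valley once the step outgrows
the valley width — which is precisely why the multi-run protocol with
top-K selection is the unit of inference, not the single run.

## Landscape mapping and ensemble analytics

`sample_landscape()` draws factor vectors log-uniformly over 1/10 to 10
times baseline (log-uniform is a documented choice: it covers the two
decades symmetrically), scores each against a fixed target, and
`mse_envelope()` takes per-bin minima along one factor axis, marginalizing
the others.  `detect_local_minima()` flags interior envelope minima with
prominence above 0.2 log10 units; for a baseline-generated target the
expectation is a single depression in the bin containing `sf = 1`.

`sf_pca()` computes principal components of a converged ensemble by
explicit variance maximization with deflation (asserted in tests to agree
with the eigendecomposition), centring but not scaling (the factors share
units), loadings unit-norm with deterministic sign.  `fit_plane()` fits
`a . sf = c` hyperplanes either orthogonally (total least squares, the
default: the printed plane treats all factors symmetrically) or by OLS
with a designated response; both report the OLS R^2 of the response on the
remaining factors, because a symmetric plane equation has no canonical
R^2.  `complementarity_report()` applies this to the SDD trio
(`ha`, `K1`, `bNSC`) and adds the 2-D composite replot (inward-weighted
sum against the outward term).

## What the synthetic targets do and do not show

Targets are the model's own output at chosen ground-truth factors —
noise-free by construction, exactly representable by the model.  This is
deliberate: it isolates the identifiability of the *method* (can the
optimizer find the generating parameters at all?) from model error.
Passing recovery tests therefore says nothing about fitting real
recordings, where slow Vm fluctuations of 1-6 mV^2 remain even after a
good fit and the model class is wrong by construction.
`add_fluctuations()` generates that nuisance component (low-pass noise of
stated power) for robustness experiments; it is never used in the
acceptance experiments.

## Problem sizes and numerics

The package's own experiments run at desk scale: the bundled recovery
test uses 30 restarts over the two strongly identified factors (`Kr`,
`CaL`) with ±10% randomization — the protocol's fast "smoke" scale; the
4-6 factor experiments run in minutes-to-hours and are provided as the
same call with a longer `selected` vector; landscape scans use
1000-2000 log-uniform samples over 2-3 free factors (the full 9-parameter,
multi-million-sample scan is configuration-reachable, not a default).
Integration uses a stiff solver (lsodar) with rtol 1e-6 / atol 1e-8 on the
measured cycle and a relaxed 1e-5 settling phase; cost evaluations settle
5 cycle-lengths from the target's state before measuring.  Cycle
boundaries are found by root-finding on the -20 mV crossing with the
upstroke refined to the maximal dV/dt.  Homeostasis updates clip at a
floor of 0.01 with a warning rather than letting a correction factor cross
zero.

## Known limitations

- The formulation is compact: no T-type Ca current, no sustained inward
  current, no ATP/pH modulation, no stochastic Ca release units, no
  contraction coupling; background currents beyond the non-selective
  cation current are absorbed into it.
- Fixed gating kinetics: only conductance scale factors are estimated, on
  the assumption that channel kinetics are shared across cells.
- The optimizer searches the raw factor axes; strongly interacting factor
  combinations (the SDD trio) converge slowly and individual runs stall,
  so conclusions should always rest on multi-run top-K statistics.
- Reported steady-state Na_i/Ca_tot refer to the cycle-boundary sampling
  instant of the homeostasis feedback.
```
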