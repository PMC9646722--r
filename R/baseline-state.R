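# Stored diastolic state on the baseline model's quasi-stable rhythm,
# captured at an upstroke (the homeostasis sampling instant) after 500
# settled cycles.  Regenerated with tools/settle-baseline.R after any
# change to the formulation or default parameters.
.baseline_state_cache <- local({
  s <- c(
    vm = -19.38244334,
    m = 0.9361436922,
    h = 0.04543185103,
    d = 0.1180533446,
    f = 0.9324059653,
    y = 0.1324518413,
    pa = 0.05835258592,
    n = 0.02831345397,
    r_ur = 0.02065907434,
    s_ur = 0.8977909189,
    r_to = 0.06819466769,
    q_to = 0.7818995135,
    Na_i = 6.100080993,
    K_i = 140.0068656,
    Catot_jnc = 0.2477933101,
    Catot_iz = 0.04896461293,
    Catot_blk = 0.01537995726,
    Catot_SRup = 0.05272440856,
    Catot_SRrl = 0.09513629235,
    crf_NaK = 0.744868606,
    crf_NCX = 0.3435643198
  )
  structure(s, t = 0, class = c("cell_state", "numeric"))
})
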