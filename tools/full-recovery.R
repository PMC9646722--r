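# Full-scale recovery experiment: 30 randomized restarts over the four
# major currents (Kr, CaL, Na, K1).  Expect one to three hours on one CPU;
# the bundled test suite runs the two-current smoke scale instead.
suppressPackageStartupMessages(library(pacefit))
p <- cell_params()
tgt <- make_target(p)
orp <- orp_test(tgt, p, selected = c("Kr", "CaL", "Na", "K1"),
                n_runs = 30, range_pct = 0.1,
                config = ps_config(crtstp = 2e-5), seed = 1, progress = TRUE)
ts <- top_k_stats(orp, k = 20)
print(ts$per_sf)
cat("mean top-20 log10(MSE):", ts$mean_log10_mse, "\n")
cat("mean Na_i:", ts$mean_Na_i, " mean Ca_tot:", ts$mean_Ca_tot, "\n")
write_orp(orp, "results/full_recovery_orp.json")
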