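#!/usr/bin/env Rscript
# Relative contribution of the NEFA signal to postprandial glucose
# regulation: decomposes the OGTT-time-course regulation of
# insulin-dependent glucose uptake and of EGP suppression into NEFA and
# non-NEFA terms, for the default parameters and for every member of a
# calibrated ensemble (reusing the archive written by 03_calibrate.R if
# present, otherwise refitting a small one).

library(glunefa)
dir.create("results", showWarnings = FALSE)

seed <- 101
truth <- default_parameters()

co <- contribution_ogtt(truth)
write.csv(co$terms, "results/contribution_terms.csv", row.names = FALSE)
cat(sprintf("default set: NEFA mediates %.0f%% of U_id regulation at %.0f min\n",
            100 * co$R_N_Uid_max, co$t_max_uid))
cat(sprintf("             and %.0f%% of EGP suppression at %.0f min\n",
            100 * co$R_N_EGP_max, co$t_max_egp))

study <- synthetic_study(truth, seed = seed)
fit <- multistart_optimize(study$data, list(
  base_params = truth,
  free = c("pA", "pB", "kegp5", "kuid3", "kra3", "kn1"),
  n_starts = 10L, maxit = 10L, seed = seed))
ens <- select_ensemble(fit)

tab <- contribution_ensemble(ens, truth, which_members = "S_sel")
write.csv(tab, "results/contribution_ensemble.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 3)
cat(sprintf("\nensemble range of R_N,Uid: [%.2f, %.2f] (shade members by V_EGP)\n",
            min(tab$R_N_Uid_max), max(tab$R_N_Uid_max)))
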