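#!/usr/bin/env Rscript
# Step 3 — TAC post-processing and ensemble statistics.
#
# Runs the measurement campaign at normal perfusion, processes every
# replicate (background subtraction, normalisation to 500 MBq, AIF peak
# alignment) and writes the ensemble mean/SD curves with the AUCs over the
# retention-model windows ([0, 60] s for the AIF, [60, 120] s for TRFs).

library(mpiphantom)
dir.create("results", showWarnings = FALSE)

cat("== TAC ensemble over 20 replicates at normal perfusion ==\n\n")

cfg <- experiment_config(n_replicates = 20, master_seed = 2022)
res <- run_experiment(cfg)
ens <- res$ensemble

cat(sprintf("AIF alignment shifts: %.2f to %.2f s (SD %.2f s)\n",
            min(ens$shifts), max(ens$shifts), sd(ens$shifts)))
cat(sprintf("mean AIF AUC over [0, 60] s   : %.3f +/- %.3f MBq.s/mL\n",
            ens$aif$auc_mean, ens$aif$auc_sd))
for (roi in names(ens$trf)) {
  cat(sprintf("mean %s AUC over [60, 120] s: %.3f +/- %.3f MBq.s/mL\n",
              roi, ens$trf[[roi]]$auc_mean, ens$trf[[roi]]$auc_sd))
}

curve_df <- function(e, label) {
  data.frame(curve = label,
             time_s = e$mean_tac$times,
             mean_MBq_per_mL = e$mean_tac$values,
             sd_MBq_per_mL = e$sd_tac$values)
}
curves <- rbind(curve_df(ens$aif, "AIF"),
                curve_df(ens$trf$MYO1, "TRF_MYO1"),
                curve_df(ens$trf$MYO2, "TRF_MYO2"),
                curve_df(ens$trf$MYO3, "TRF_MYO3"))
write.csv(curves, "results/ensemble_curves.csv", row.names = FALSE)

aucs <- data.frame(
  curve = c("AIF", names(ens$trf)),
  window_lo_s = c(0, rep(60, 3)), window_hi_s = c(60, rep(120, 3)),
  auc_mean = c(ens$aif$auc_mean,
               sapply(ens$trf, function(e) e$auc_mean)),
  auc_sd = c(ens$aif$auc_sd, sapply(ens$trf, function(e) e$auc_sd)))
write.csv(aucs, "results/ensemble_aucs.csv", row.names = FALSE)

cat("\nwrote results/ensemble_curves.csv and results/ensemble_aucs.csv\n")
cat("Note the rising tail of the mean TRFs: the leaky recirculation\n")
cat("filters leave a small re-entering tracer fraction, visible as a\n")
cat("strictly positive late slope (absent with ideal filters).\n")
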