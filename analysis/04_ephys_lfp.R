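#!/usr/bin/env Rscript
# Field-potential arm: baseline-zeroed 1-15 Hz wavelet power ratios during
# constant-light activation for three strains (activated, knockdown-like with
# no band gain, control), and pulse-locked ERP peaks including a paired
# gap-junction-blocker (CBX-like) comparison.

suppressPackageStartupMessages(library(sleeparousal))
out <- "results/ephys_lfp"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

band_ratio <- function(gain, seed) {
  tr <- simulate_lfp_trace(lfp_sim_config(fs = 250, duration = 300,
                                          stim_band_power_gain = gain,
                                          seed = seed))
  nb <- normalize_to_baseline(morlet_spectrogram(tr, analysis_fs = 250),
                              c(30, 60))
  as.numeric(band_power_ratio(nb, stim_window = c(65, 175)))
}

strains <- list(activated = list(gain = 2, n = 7),
                knockdown = list(gain = 1, n = 6),
                control = list(gain = 1, n = 4))
ratio_rows <- list()
for (nm in names(strains)) {
  st <- strains[[nm]]
  r <- vapply(seq_len(st$n),
              function(i) band_ratio(st$gain, 4000 + 100 * match(nm, names(strains)) + i),
              numeric(1))
  cmp <- compare_conditions(r, list(test = "wilcoxon_signed_rank_vs_zero"))
  cat(sprintf("%s (n = %d): median ratio %+.2f, Wilcoxon vs 0 p = %.3g\n",
              nm, st$n, median(r), cmp$p))
  ratio_rows[[nm]] <- data.frame(strain = nm, fly = seq_len(st$n), ratio = r)
}
ratios <- do.call(rbind, ratio_rows)
write.csv(ratios, file.path(out, "band_ratios.csv"), row.names = FALSE)

erp_peak <- function(amp, seed) {
  tr <- simulate_lfp_trace(lfp_sim_config(fs = 1000, duration = 300,
                                          light_mode = "pulsed_1hz_5ms",
                                          noise_amplitude = 5,
                                          noise_exponent = 0,
                                          erp_amplitude = amp,
                                          seed = seed))
  erp_peak_amplitude(tr)$mean_peak
}

wt_erp <- vapply(1:7, function(i) erp_peak(50, 5000 + i), numeric(1))
kd_erp <- vapply(1:6, function(i) erp_peak(15, 5100 + i), numeric(1))
mw <- compare_conditions(list(wt_erp, kd_erp), list(test = "mann_whitney"))
cat(sprintf("\nERP peak: intact %.1f vs knockdown %.1f, Mann-Whitney p = %.3g\n",
            mean(wt_erp), mean(kd_erp), mw$p))

# paired blocker comparison: same flies before and under CBX (reduced ERP)
base <- vapply(1:6, function(i) erp_peak(50, 5200 + i), numeric(1))
cbx <- vapply(1:6, function(i) erp_peak(20, 5300 + i), numeric(1))
pt <- compare_conditions(cbind(baseline = base, cbx = cbx),
                         list(test = "paired_t"))
cat(sprintf("CBX: baseline %.1f vs blocker %.1f, %s p = %.3g\n",
            mean(base), mean(cbx), pt$test_used, pt$p))
write.csv(data.frame(fly = 1:6, baseline = base, cbx = cbx),
          file.path(out, "erp_cbx.csv"), row.names = FALSE)
write.csv(data.frame(strain = rep(c("intact", "knockdown"), c(7, 6)),
                     erp_peak = c(wt_erp, kd_erp)),
          file.path(out, "erp_strains.csv"), row.names = FALSE)
cat("\nOnly the activated strain gains 1-15 Hz power; blocking or knocking\n")
cat("down the electrical synapse lowers the pulse-locked ERP. Tables under ",
    out, "\n", sep = "")
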