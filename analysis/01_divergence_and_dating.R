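#!/usr/bin/env Rscript
# Stage 1: molecular-clock dating from published divergences.
#
# Inputs are the printed per-locus Ks values for the Medicago splits and the
# Pisum-split calibration anchors; outputs are the per-locus age matrix, the
# per-pair average ages, and the two GS2 duplication ages (paralog Ks 0.1668;
# the two very similar GS2b sequences, Ks 0.0142).
#
# Usage: Rscript analysis/01_divergence_and_dating.R [outdir]

suppressPackageStartupMessages(library(divclock))

args <- commandArgs(trailingOnly = TRUE)
outdir <- if (length(args) >= 1L) args[[1L]] else "results/01_dating"
seed <- 1L

divergence_table <- data.frame(
  pair = rep(c("Medicago-Melilotus", "Medicago-Trifolium",
               "Medicago-Vicia", "Medicago-Pisum"), each = 3),
  locus = rep(c("rbcL", "matK", "trnL"), 4),
  ks = c(0.0590, 0.0511, 0.0126,
         0.0882, 0.0661, 0.0127,
         0.1149, 0.0782, 0.0297,
         0.1194, 0.1149, 0.0211))

anchors <- list(
  rbcL = calibration_anchor("Medicago-Pisum", "rbcL", 0.1194, 18.5),
  matK = calibration_anchor("Medicago-Pisum", "matK", 0.1149, 15.2),
  trnL = calibration_anchor("Medicago-Pisum", "trnL", 0.0211, 11.0),
  GS2  = calibration_anchor("Medicago-Pisum", "GS2", 0.2475, 14.9))

res <- run_dating(list(outdir = outdir, seed = seed,
                       divergence_table = divergence_table,
                       anchors = anchors,
                       duplication = list(ks = 0.1668, locus = "GS2",
                                          pair_label = "MtGS2a-MtGS2b",
                                          digits = 0)))

res2 <- run_dating(list(outdir = file.path(outdir, "recent_duplication"),
                        seed = seed,
                        divergence_table = divergence_table,
                        anchors = anchors,
                        duplication = list(ks = 0.0142, locus = "GS2",
                                           pair_label = "GS2b_2-1-GS2b_2-2",
                                           digits = 0)))

cat("Per-locus ages (My):\n")
print(res$ages[, c("pair", "locus", "ks", "age_my")])
cat("\nAverage ages (My):\n")
print(res$averages)
cat("\nDuplication ages (My):\n")
print(rbind(res$duplication, res2$duplication))

quit(status = max(res$status, res2$status))
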