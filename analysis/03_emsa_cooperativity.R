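#!/usr/bin/env Rscript
# Cooperativity-factor estimation across spacer variants: simulate noisy
# EMSA titrations under the two-site model at the cooperativity levels
# characteristic of a DIM-domain-containing SOXE protein on differently
# spaced palindromes (very strong on the enriched 3-5 bp spacers, ~100 on
# compressed/expanded spacers, weaker at 10 bp), then re-estimate omega
# per lane and by global least squares, and classify the binding mode.

suppressPackageStartupMessages(library(dimerscreen))

seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

scenarios <- data.frame(
  label = c("spacer_4bp_DIM", "spacer_0bp_DIM", "spacer_10bp_DIM",
            "spacer_4bp_HMG_only"),
  omega = c(1e4, 100, 10, 1),
  stringsAsFactors = FALSE)
K_true <- 1e7  # 1/M

rows <- list()
for (i in seq_len(nrow(scenarios))) {
  sc <- scenarios[i, ]
  m <- two_site_model(K_true, omega = sc$omega)
  conc <- titration_design(m, dna_total = 50, n_lanes = 8)
  tit <- simulate_titration(m, conc, dna_total = 50, noise_sd = 0.02,
                            seed = seed + i)
  write_lane_table(tit, file.path(out, paste0("lanes_", sc$label, ".tsv")),
                   seed = seed + i,
                   params = list(K = K_true, omega = sc$omega))
  fit <- fit_titration(tit)
  lane_med <- stats::median(fit$lane_omegas[is.finite(fit$lane_omegas)])
  omega_rep <- if (fit$reliability == "ok") fit$omega else Inf
  rows[[i]] <- data.frame(
    scenario = sc$label, omega_true = sc$omega,
    omega_fit = fit$omega, omega_lane_median = lane_med,
    K_fit = fit$K, reliability = fit$reliability,
    mode = classify_binding(if (is.finite(omega_rep)) omega_rep
                            else list(omega = Inf, reliable = FALSE)),
    stringsAsFactors = FALSE)
  cat(sprintf(
    "%-20s true omega %-7g fitted %-10.3g lane-median %-10.3g %s (%s)\n",
    sc$label, sc$omega, fit$omega, lane_med, rows[[i]]$mode,
    fit$reliability))
}

fits <- do.call(rbind, rows)
write_results_tsv(fits, file.path(out, "emsa_fits.tsv"), seed = seed,
                  params = list(K_true = K_true, noise_sd = 0.02,
                                dna_nM = 50, n_lanes = 8))
cat("wrote", file.path(out, "emsa_fits.tsv"), "\n")
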