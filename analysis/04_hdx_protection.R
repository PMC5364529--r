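#!/usr/bin/env Rscript
# NMR hydrogen-deuterium exchange: per-residue intensity-decay fitting,
# intrinsic rates from the Bai-Englander additive log-factor model, and
# protection factors. Three synthetic proteins with offset protection
# landscapes emulate the cross-paralog comparison (the least protected
# backbone exchanges fastest despite the highest global stability).

library(uchfold)
dir.create("results", showWarnings = FALSE)
seed <- 2

seq_aa <- "MTGNAGEWCLMESDPGVFTELIKGFGCRGAQVEEIWSLEPENFEKLKPVHGLIFLFKW"
segments <- data.frame(segment = c("beta1", "helix1", "beta2"),
                       start = c(2, 18, 40), end = c(12, 32, 55))

# one structured log-PF field, offset per protein: most protected first
set.seed(seed)
base_field <- 5.5 + 1.5 * sin(seq(0, 3 * pi, length.out = 40))
offsets <- c(uchl1 = 1.0, uchl3 = 0.0, uchl5 = -1.5)

profiles <- lapply(seq_along(offsets), function(i) {
  lp <- pmax(base_field + offsets[i], 1)
  sim <- simulate_hdx_series(seq_aa, lp, noise_cv = 0.05, seed = seed + i)
  hdx_protection_factors(sim$series_list, seq_aa, pd = 8.0, temperature = 298)
})
names(profiles) <- names(offsets)

for (nm in names(profiles)) {
  cat(sprintf("%-6s median log10 PF = %.2f over %d residues\n",
              nm, median(profiles[[nm]]$log10_pf), nrow(profiles[[nm]])))
}

cmp <- compare_pf_profiles(profiles, segments)
cat("\nper-segment median log10 PF:\n")
print(round(cmp$segment_medians, 2))
cat("protection ordering (most to least):",
    paste(cmp$ordering, collapse = " > "), "\n")
cat("-> the construct with the lowest protection factors exchanges fastest\n")
cat("   throughout its backbone: high conformational plasticity\n")

all_pf <- do.call(rbind, lapply(names(profiles), function(nm) {
  cbind(protein = nm, profiles[[nm]])
}))
write.csv(all_pf, "results/hdx_protection_factors.csv", row.names = FALSE)
write.csv(data.frame(segment = rownames(cmp$segment_medians),
                     cmp$segment_medians),
          "results/hdx_segment_medians.csv", row.names = FALSE)
cat("wrote results/hdx_protection_factors.csv and results/hdx_segment_medians.csv\n")
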