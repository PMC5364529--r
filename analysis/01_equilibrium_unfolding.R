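#!/usr/bin/env Rscript
# Urea-induced equilibrium unfolding of the UCH-L5 catalytic domain:
# SVD component counting on the titration spectra, then the global
# two-state (linear extrapolation) fit shared across fluorescence and
# far-UV CD probes. Instrument data are emulated by the package generator
# at the published parameter preset.

library(uchfold)
dir.create("results", showWarnings = FALSE)
seed <- 1

preset <- uchfold_presets()$equilibrium$uchl5_global
fluo <- simulate_equilibrium_titration(preset$dg_h2o, preset$m_value,
                                       noise_cv = 0.01, seed = seed)$series
cd <- simulate_equilibrium_titration(preset$dg_h2o, preset$m_value,
                                     wavelengths = seq(210, 250, by = 1),
                                     centers = c(222, 235), widths = c(12, 18),
                                     heights = c(-1, -0.35),
                                     noise_cv = 0.01, seed = seed + 1)$series
cd$probe <- "far-UV CD"

cat("SVD analysis of the titration spectra (threshold 0.8):\n")
sv_f <- svd_decompose(fluo); print(sv_f)
sv_c <- svd_decompose(cd)
cat(sprintf("fluorescence: %d significant components; far-UV CD: %d\n",
            sv_f$n_significant, sv_c$n_significant))
cat("-> two significant components: the unfolding is two-state, no\n")
cat("   spectroscopically distinct intermediate accumulates at equilibrium\n\n")

fits <- list(
  fluorescence = fit_two_state_equilibrium(fluo),
  cd = fit_two_state_equilibrium(cd),
  global = fit_two_state_equilibrium(list(fluo, cd))
)
for (nm in names(fits)) { cat(nm, ":\n"); print(fits[[nm]]) }

tab <- do.call(rbind, lapply(names(fits), function(nm) {
  f <- fits[[nm]]
  data.frame(fit = nm, dg_h2o = f$dg_h2o, se_dg = f$se[["dg_h2o"]],
             m_value = f$m_value, se_m = f$se[["m_value"]],
             d50 = f$d50, se_d50 = f$se[["d50"]])
}))
write.csv(tab, "results/equilibrium_fit.csv", row.names = FALSE)
write.csv(data.frame(component = seq_along(sv_f$d),
                     singular_value = sv_f$d,
                     acf_u = sv_f$autocorrelations_u,
                     acf_v = sv_f$autocorrelations_v),
          "results/svd_components_fluorescence.csv", row.names = FALSE)
cat("\nwrote results/equilibrium_fit.csv and results/svd_components_fluorescence.csv\n")
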