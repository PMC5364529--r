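#!/usr/bin/env Rscript
# Ubiquitin-binding thermodynamics by variable-temperature ITC: per-
# temperature one-site fits (20-37 C) followed by the global constant-dCp
# analysis yielding dH, dS, dCp, and the derived dG and K_D at 25 C, for
# the UCH-L1- and UCH-L3-like parameter sets.

library(uchfold)
dir.create("results", showWarnings = FALSE)
seed <- 8

presets <- uchfold_presets()$binding
rows <- lapply(names(presets), function(nm) {
  p <- presets[[nm]]
  sim <- simulate_itc_temperature_series(dh0 = p$dh0, ds0 = p$ds0, dcp = p$dcp,
                                         noise_frac = 0.03, seed = seed)
  per <- do.call(rbind, lapply(sim$isotherms, function(it) {
    f <- fit_one_site(it)
    data.frame(temperature = it$temperature, ka = f$ka, dh = f$dh,
               kd_um = f$kd_um, c_value = f$c_value)
  }))
  cat(sprintf("\n%s per-temperature one-site fits:\n", nm))
  print(round(per, 3))
  g <- global_fit_temperature_series(per)
  print(g)
  data.frame(protein = nm, dh0 = g$dh0, ds0 = g$ds0, dcp = g$dcp,
             se_dcp = g$se[["dcp"]], dg = g$dg, tds = g$tds, kd_um = g$kd_um)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/binding_thermo.csv", row.names = FALSE)
cat("\nThe more exothermic binder pays a larger entropic penalty and shows\n")
cat("the larger negative dCp, consistent with more surface buried (and more\n")
cat("structure ordered) on complex formation.\n")
cat("wrote results/binding_thermo.csv\n")
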