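#!/usr/bin/env Rscript
# Double-jump (interrupted refolding) analysis: mixing arithmetic of the
# two-step protocol, shared-rate global fitting across aging times,
# amplitude build-up kinetics, and inference of a linear three-state
# refolding scheme A (denatured) <-> B (intermediate) <-> C (native).

library(uchfold)
dir.create("results", showWarnings = FALSE)
seed <- 11

cat("Mixing protocol bookkeeping:\n")
mix <- final_concentration(
  list(list(added_denaturant = 0, ratio_added = 5, ratio_carried = 1),
       list(added_denaturant = 8, ratio_added = 1, ratio_carried = 1)),
  protein_start = 20, start_denaturant = 7.7)
print(round(mix, 3))
cat("-> refolding proceeds at", round(mix$denaturant[1], 2),
    "M urea; the second jump interrogates the aged population at",
    round(mix$denaturant[2], 2), "M\n\n")

sim <- simulate_interrupted_refolding(noise_cv = 0.02, seed = seed,
                                      final_denaturant = mix$denaturant[2])
g <- global_fit_shared_rates(sim$series, 2)
cat(sprintf("shared unfolding rates across %d aging times: %.3g and %.3g /s\n",
            length(sim$series$aging_times), g$rates[1], g$rates[2]))

bu <- fit_amplitude_buildup(g$amplitudes, g$aging_times)
print(as.data.frame(bu))
cat("-> the intermediate-phase amplitude rises first; the native-phase\n")
cat("   amplitude builds with a statistically detectable lag\n\n")

ts <- fit_linear_three_state(g$amplitudes, g$aging_times)
print(ts)
truth <- sim$truth$rates
tab <- data.frame(parameter = names(ts$rates), fitted = unname(ts$rates),
                  generator = unname(truth))
tab <- rbind(tab, data.frame(parameter = c("relax_fast", "relax_slow"),
                             fitted = rev(ts$relaxation_rates),
                             generator = rev(sim$truth$relaxation_rates)))
write.csv(tab, "results/double_jump_fit.csv", row.names = FALSE)
cat("wrote results/double_jump_fit.csv\n")
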