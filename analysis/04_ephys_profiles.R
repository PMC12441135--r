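#!/usr/bin/env Rscript
# Membrane-property extraction from the simulated voltage-step cohort:
# IV curves, membrane resistance (holding -20 mV), capacitance (-20 mV),
# reversal potential (-70 mV), specific outward (0/-20 mV at 40 ms) and
# inward (-120/-100 mV at 10 ms) conductances, four-group current-type
# classification, and activation/inactivation kinetics.

library(clonemap)

# regenerate the cohort simulated in 01 (same seed; traces are bulky)
seed <- 20260919L
cells <- simulate_ephys_cohort(n_per_class = 10, noise_sd = 2, seed = seed)
dir.create("results/ephys", showWarnings = FALSE, recursive = TRUE)

props <- cohort_properties(cells)
truth <- read.csv("results/inputs/true_classes.csv")
props$true_class <- truth$true_class[match(props$cell_id, truth$cell_id)]
write.csv(props, "results/ephys/membrane_properties.csv", row.names = FALSE)

acc <- mean(props$current_class == props$true_class)
message(sprintf("classified %d cells; agreement with generator classes %.0f%%",
                nrow(props), 100 * acc))
message(sprintf("median R_m %.0f MOhm, C_m %.1f pF, V_rev %.1f mV",
                median(props$R_m), median(props$C_m),
                median(props$V_rev, na.rm = TRUE)))
print(table(generator = props$true_class, classified = props$current_class))

# class differences in specific inward conductance, both reporting styles
cmp <- group_compare(props$G_in_spec, props$true_class)
write.csv(cmp$summary, "results/ephys/gin_by_class.csv", row.names = FALSE)
message(sprintf("%s test across classes for G_in: p = %.3g",
                cmp$test, cmp$p_value))

# kinetics on one inward+outward cell
cell <- cells[[grep("inward_and_outward", names(cells))[1]]]
act <- do.call(rbind, lapply(seq(-30, 60, 10), function(V) {
  f <- fit_activation_tau(cell$rec70, V)
  data.frame(V = V, tau_ms = f$tau, flagged = f$flagged)
}))
inact <- do.call(rbind, lapply(seq(-170, -110, 10), function(V) {
  f <- fit_inactivation_tau(cell$rec20, V)
  data.frame(V = V, tau_ms = f$tau, flagged = f$flagged)
}))
write.csv(rbind(cbind(kind = "activation", act),
                cbind(kind = "inactivation", inact)),
          "results/ephys/kinetics.csv", row.names = FALSE)
message(sprintf(
  "activation tau falls from %.1f ms (-30 mV) to %.1f ms (+60 mV); inactivation tau falls from %.1f ms (-110 mV) to %.1f ms (-170 mV)",
  act$tau_ms[1], act$tau_ms[nrow(act)],
  inact$tau_ms[nrow(inact)], inact$tau_ms[1]))
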