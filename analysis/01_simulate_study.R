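#!/usr/bin/env Rscript
# Build the synthetic study: a contralateral-like CSR group (stable ~1653
# labeled cells per mm^3, random colors) and a peak-phase stroke-like
# clustered group (Thomas process, ~2272 clones per mm^3 of mean size 5,
# sigma = 15 um), 3 mice x 3 stacks each, with Ki-67 flags whose
# probability falls with clone size. Writes the cell table consumed by the
# downstream scripts plus a voltage-step trace table and a set of cell
# masks.

library(clonemap)

seed <- 20260919L
dir.create("results/inputs", recursive = TRUE, showWarnings = FALSE)

ctr <- simulate_null_group(n_mice = 3, stacks_per_mouse = 3, seed = seed,
                           timepoint = "2w", condition = "contralateral",
                           prefix = "ctr")
cg <- simulate_clonal_group(n_mice = 3, stacks_per_mouse = 3,
                            seed = seed + 1, timepoint = "2w",
                            condition = "stroke", prefix = "str")
stroke <- lapply(names(study_stacks(cg$study)), function(id) {
  assign_ki67(get_stack(cg$study, id), cg$truth[[id]],
              function(s) min(0.9, 1.8 / s), seed = seed + 2)
})
study <- study_table(c(study_stacks(ctr), stroke))
write_cell_table(study, "results/inputs/cells.csv")
message(sprintf("cell table: %d cells in %d stacks (%d stroke, %d contralateral)",
                nrow(study$cells), nrow(study$stacks),
                sum(study$stacks$condition == "stroke"),
                sum(study$stacks$condition == "contralateral")))

# ground-truth clone sizes, for the recovery comparison in 03
truth_sizes <- unlist(lapply(cg$truth, function(t) t$clone_sizes))
write.csv(data.frame(clone = names(truth_sizes), size = truth_sizes,
                     row.names = NULL),
          "results/inputs/true_clone_sizes.csv", row.names = FALSE)

# the 40-cell patch-clamp cohort (10 per current-type class) is
# regenerated from this same seed in 04_ephys_profiles.R; full-resolution
# traces (0.05 ms sampling) are too bulky to park on disk, so only the
# class key is written here
coh <- simulate_ephys_cohort(n_per_class = 10, noise_sd = 2, seed = seed)
write.csv(data.frame(cell_id = names(coh),
                     true_class = vapply(coh, `[[`, "", "true_class")),
          "results/inputs/true_classes.csv", row.names = FALSE)
message(sprintf("ephys cohort: %d cells x 2 holding potentials (key written)",
                length(coh)))

# four analytic shapes spanning the morphology spectrum
shapes <- list(ball = shape_ball(15), ellipsoid = shape_ellipsoid(30, 20, 10),
               rod = shape_rod(60, 4), tree = shape_tree())
for (nm in names(shapes)) {
  sim <- simulate_cell_mask(shapes[[nm]], seed = seed)
  write_cell_mask(sim$mask, sprintf("results/inputs/mask_%s.tif", nm))
}
message("masks: ", paste(names(shapes), collapse = ", "))
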