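#!/usr/bin/env Rscript
# Stage 5: the uncertainty budget — repeated 80/20 subsampling of the field
# campaigns for the allometric term, the crown-area mapping term from the
# evaluation fixture, and their quadrature combination.

library(drylandtrees)

samples <- split(read.csv("results/inputs/field_samples.csv"), ~component)
unc <- allometric_uncertainty(samples, n_reps = 10, seed = 20260926L)
cat(sprintf("allometric uncertainty per repetition: %s\n",
            paste(sprintf("%.1f%%", 100 * unc$delta_allometric_rel_per_rep),
                  collapse = " ")))
cat(sprintf("mean allometric uncertainty: %.1f%%\n",
            100 * unc$delta_allometric_rel_mean))

fx <- gen_eval_fixture(1000, commission_rate = 0.049, omission_rate = 0.027,
                       seed = 20260924L)
lab <- sum(vapply(fx, function(p) sum(p$labelled$crown_area_m2), 1))
pred <- sum(vapply(fx, function(p) sum(p$predicted$crown_area_m2), 1))
d_area <- crown_area_relative_error(lab, pred)
d_area_plot <- crown_area_relative_error_per_plot(
  vapply(fx, function(p) sum(p$labelled$crown_area_m2), 1),
  vapply(fx, function(p) sum(p$predicted$crown_area_m2), 1))
cat(sprintf("crown-area error: %.2f%% (pooled totals), %.2f%% (per-plot mean)\n",
            100 * d_area, 100 * d_area_plot))

d_total <- total_uncertainty(d_area, unc$delta_allometric_rel_mean)
cat(sprintf("total carbon uncertainty: +/- %.1f%%\n", 100 * d_total))

jsonlite::write_json(list(
  delta_allometric_rel_per_rep = unc$delta_allometric_rel_per_rep,
  delta_allometric_rel_mean = unc$delta_allometric_rel_mean,
  delta_area_pooled = d_area,
  delta_area_per_plot = d_area_plot,
  delta_total = d_total),
  "results/uncertainty_budget.json", auto_unbox = TRUE, digits = NA)
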