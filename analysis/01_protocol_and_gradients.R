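#!/usr/bin/env Rscript
# Stage 1: stimulus protocol facts and tonotopic-gradient recovery.
#
# Generates synthetic focal planes and single-neuron populations under the
# TR and CT presets and fits the caudal->rostral gradient of best frequency,
# summarizing slope, Pearson R and significance over 50 seeded replicates.
# Writes results/gradients.csv.

suppressMessages(library(tonotopr))
dir.create("results", showWarnings = FALSE)

p <- make_protocol()
print(p)
cat(sprintf("unique frequency-level combinations: %d\n\n",
            length(p$frequencies_khz) * length(p$levels_db)))

seeds <- 1:50
rows <- list()
for (nm in c("TR", "CT")) {
  pr <- synth_preset(nm)
  plane_fits <- lapply(seeds, function(s) {
    sp <- sample_planes(pr, seed = s)
    fit_gradient(sp$planes$axis_mm, sp$planes$median_bf_khz)
  })
  neuron_fits <- lapply(seeds, function(s) {
    pop <- sample_population(pr, pr$gradient$neuron[["n"]], p, seed = s,
                             tuned_only = TRUE)
    fit_gradient(pop$axis_mm, pop$bf_khz)
  })
  for (lvl in c("plane", "neuron")) {
    fits <- if (lvl == "plane") plane_fits else neuron_fits
    sl <- vapply(fits, `[[`, numeric(1), "slope_oct_per_mm")
    r <- vapply(fits, `[[`, numeric(1), "pearson_r")
    ps <- vapply(fits, `[[`, numeric(1), "p_value")
    rows[[paste(nm, lvl)]] <- data.frame(
      preset = nm, level = lvl,
      target_slope = pr$gradient[[lvl]]$slope_oct_per_mm,
      mean_slope = mean(sl), se_slope = sd(sl) / sqrt(length(sl)),
      mean_r = mean(r), frac_significant = mean(ps < 0.05))
    cat(sprintf("%s %-6s slope %.2f oct/mm (target %.2f), R %.2f, significant in %d%% of seeds\n",
                nm, lvl, mean(sl), pr$gradient[[lvl]]$slope_oct_per_mm,
                mean(r), round(100 * mean(ps < 0.05))))
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/gradients.csv", row.names = FALSE)
cat("\nThe TR gradient is steep and reliably significant; the CT gradient is",
    "\nflat and mostly non-significant - tonotopy is present in the input",
    "\npopulation and absent in the corticothalamic one.\n")
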