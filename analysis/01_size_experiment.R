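#!/usr/bin/env Rscript
# Electrode-size experiment on synthetic iEEG (fast-ripple band).
#
# For each of 50 source realizations, the same HFO train, tissue coverage and
# background are re-measured through the lumped electrode model at the three
# contact areas of the high-density grid study (1.08, 2.16, 4.32 mm^2 =
# small / pair / quad). HFOs are detected per record and the per-area
# distributions of global rate per area, amplitude, duration and peak
# frequency are compared between adjacent sizes with rank-sum tests.
#
# Findings with the default configuration (seed 1): the rate of detected
# fast ripples per unit electrode area and their amplitude fall steeply and
# significantly as contact area grows; duration and peak frequency remain
# essentially unchanged (a small residual duration truncation at the largest
# size is discussed in the vignette).

suppressPackageStartupMessages(library(hfoarea))

seed <- 1L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- simulation_config(duration = 120, seed = seed)
message("simulating and detecting 50 records x 3 areas ...")
ex <- run_size_experiment(cfg, areas = c(1.08, 2.16, 4.32),
                          n_per_area = 50, seed = seed)
print(ex)

utils::write.csv(ex$records, file.path(out_dir, "size_records.csv"),
                 row.names = FALSE)
write_events(ex$events, file.path(out_dir, "size_events.csv"))
utils::write.csv(ex$tests, file.path(out_dir, "size_tests.csv"),
                 row.names = FALSE)
write_run_manifest(file.path(out_dir, "size_experiment_manifest.json"),
                   "size_experiment",
                   params = list(n_per_area = 50, duration_s = 120,
                                 areas = c(1.08, 2.16, 4.32),
                                 band = cfg$band),
                   seed = seed)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  ex$records$area_f <- factor(ex$records$area)
  p1 <- ggplot(ex$records, aes(area_f, rate_per_area)) +
    geom_boxplot() +
    labs(x = "electrode area (mm^2)", y = "HFO rate per area (1/min/mm^2)",
         title = "Fast-ripple rate per electrode area vs contact size")
  ex$events$area_f <- factor(ex$events$area)
  p2 <- ggplot(ex$events, aes(area_f, amplitude)) +
    geom_boxplot() +
    labs(x = "electrode area (mm^2)", y = "amplitude (uV)")
  p3 <- ggplot(ex$events, aes(area_f, duration_s * 1000)) +
    geom_boxplot() +
    labs(x = "electrode area (mm^2)", y = "duration (ms)")
  pdf(file.path(out_dir, "fig_size_trends.pdf"), width = 9, height = 3.2)
  print(p1); print(p2); print(p3)
  dev.off()
  message("wrote ", file.path(out_dir, "fig_size_trends.pdf"))
}
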