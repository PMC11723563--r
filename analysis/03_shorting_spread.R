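#!/usr/bin/env Rscript
# Virtual electrode shorting and the spatial spread of detected HFOs.
#
# One 8x8 grid recording is simulated (independent HFO sources per contact)
# and then re-referenced virtually: contacts are shorted into pairs and
# 2x2 quads, mimicking larger electrodes over the same tissue. Detection in
# the fast-ripple band runs on each configuration of the same underlying
# data; events are grouped by temporal overlap, the spread S (number of
# simultaneously active channels) is summarized, and the global rate per
# summed contact area (constant 69.12 mm^2 across configurations) is
# reported.
#
# Findings (seed 1): most events are seen on a single channel at every size;
# the global rate per area falls as contacts are shorted into larger
# effective electrodes, since averaging dilutes localized sources below the
# detection thresholds.

suppressPackageStartupMessages(library(hfoarea))

seed <- 1L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

lay <- grid_layout()
cfg <- simulation_config(duration = 120, seed = seed)
message("simulating the 8x8 grid ...")
rec <- simulate_grid_recording(cfg, lay, seed = seed)

schemes <- list(
  small = make_shorting_scheme(lay, "small"),
  pair = make_shorting_scheme(lay, "pair"),
  quad = make_shorting_scheme(lay, "quad")
)

dur_min <- recording_duration_min(rec)
groups_by_scheme <- list()
rates <- data.frame()
for (lbl in names(schemes)) {
  message("detecting on the '", lbl, "' configuration ...")
  r <- apply_shorting(rec, schemes[[lbl]])
  car <- common_average_reference(r)
  ev <- detect_hfos(car$recording, "fast_ripple", car = car$car)
  g <- group_events(ev, r$fs)
  groups_by_scheme[[lbl]] <- g$groups
  rates <- rbind(rates, data.frame(
    scheme = lbl,
    n_channels = nrow(r$data),
    n_events = nrow(ev),
    n_unique = nrow(g$groups),
    global_rate_per_area = global_rate_per_area(
      g$groups, dur_min, scheme_total_area(schemes[[lbl]])
    )
  ))
}

spread <- summarize_spread(groups_by_scheme)
print(rates, row.names = FALSE)
print(spread, row.names = FALSE)

utils::write.csv(rates, file.path(out_dir, "shorting_rates.csv"),
                 row.names = FALSE)
utils::write.csv(spread, file.path(out_dir, "spread_summary.csv"),
                 row.names = FALSE)
write_run_manifest(file.path(out_dir, "shorting_spread_manifest.json"),
                   "shorting_spread",
                   params = list(duration_s = 120, band = "fast_ripple"),
                   seed = seed)
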