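#!/usr/bin/env Rscript
# Stage 1: build the synthetic site — eight years of daily drivers with a
# pronounced Aug-Nov dry season, a truth forward run from the reference
# posterior medians, and all nine observation streams (plus the half-hourly
# NEE rendering and the daily soil-respiration series).
#
# Writes: results/synthetic/{driver,trajectory,streams/*,halfhourly_nee,
# soil_respiration_daily}.csv and a manifest.

suppressMessages(library(carbonfuse))

seed <- 1
out <- file.path("results", "synthetic")
dir.create(file.path(out, "streams"), recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = seed)
truth <- truth_run(cfg)
obs <- generate_observations(truth, cfg)

write_driver_csv(truth$driver, file.path(out, "driver.csv"))
write_trajectory_csv(truth$trajectory, file.path(out, "trajectory.csv"))
for (id in names(obs$streams)) {
  utils::write.csv(obs$streams[[id]], file.path(out, "streams", paste0(id, ".csv")),
                   row.names = FALSE)
}
utils::write.csv(obs$halfhourly, file.path(out, "halfhourly_nee.csv"),
                 row.names = FALSE)
utils::write.csv(obs$soil_daily, file.path(out, "soil_respiration_daily.csv"),
                 row.names = FALSE)

mask <- truth$mask
cat(sprintf("synthetic site: %d days, %d dry (%.1f%%); SWC mean %.3f sd %.3f, lower quartile %.3f\n",
            nrow(truth$driver), sum(mask), 100 * mean(mask),
            mean(truth$driver$swc_m3_m3), sd(truth$driver$swc_m3_m3),
            quantile(truth$driver$swc_m3_m3, 0.25)))
cat(sprintf("truth run: mean GPP %.2f, mean NEE %.2f g C m-2 d-1\n",
            mean(truth$trajectory$fluxes$gpp), mean(truth$trajectory$fluxes$nee)))
cat("streams:", paste(names(obs$streams), vapply(obs$streams, nrow, 1L),
                      collapse = ", "), "\n")

manifest <- list(stage = "synthesize", seed = seed,
                 n_days = nrow(truth$driver), n_dry = sum(mask),
                 timestamp = format(Sys.time(), tz = "UTC"))
writeLines(paste(names(manifest), unlist(manifest), sep = ": "),
           file.path(out, "manifest.txt"))
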