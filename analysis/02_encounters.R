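#!/usr/bin/env Rscript
# Step 2: predator-prey encounter rates. Calm-water (Gerritsen-Strickler)
# and turbulence-augmented (Rothschild-Osborn) rates per station, plus
# vertical profiles per stratum. The surface turbulent velocity w0 is
# calibrated per season from the observed neritic surface enhancement
# ratios of the reference field study (turbulent/calm = 115.1/75.4 in
# summer, 39.4/25.2 in fall, 100.3/55.7 in winter); the decay depth is set
# so w falls to 10% of w0 at the depth where calm and turbulent profiles
# were observed to converge (~28 m in summer/fall, ~40 m in winter).

suppressPackageStartupMessages(library(chaetofeed))

stations <- read_station_table("results/stations.csv")
params <- encounter_params(R = 0.003, x = 0.150, y = 0)

season_w0 <- c(
  summer = calibrate_surface_w(115.1 / 75.4, x = 0.150),
  fall   = calibrate_surface_w(39.4 / 25.2, x = 0.150),
  winter = calibrate_surface_w(100.3 / 55.7, x = 0.150))
season_decay <- c(summer = 28 / log(10), fall = 28 / log(10),
                  winter = 40 / log(10))

stations$c_gs <- gs_rate(params, stations$copepod_density_ind_m3)
stations$w0 <- season_w0[stations$season]
stations$c_ro_surface <- ro_rate(params, stations$copepod_density_ind_m3,
                                 stations$w0)
write_table(stations[, c("station_id", "season", "zone",
                         "copepod_density_ind_m3", "w0", "c_gs",
                         "c_ro_surface")],
            "results/encounters.csv")

depths <- seq(0, 100, by = 2)
profiles <- do.call(rbind, lapply(unique(stations$season), function(s) {
  for_zone <- function(z) {
    N <- mean(stations$copepod_density_ind_m3[stations$season == s &
                                              stations$zone == z])
    spec <- turbulence_spec(w0 = season_w0[[s]],
                            decay_depth = season_decay[[s]])
    cbind(season = s, zone = z, encounter_profile(params, N, spec, depths))
  }
  rbind(for_zone("neritic"), for_zone("oceanic"))
}))
write_table(profiles, "results/encounter_profiles.csv")

cat("surface encounter rates (copepods/chaetognath/day), stratum means:\n")
print(aggregate(cbind(c_gs, c_ro_surface) ~ season + zone, stations, mean),
      row.names = FALSE)
cat(sprintf("\ncalibrated w0: summer %.3f, fall %.3f, winter %.3f m/s\n",
            season_w0[["summer"]], season_w0[["fall"]],
            season_w0[["winter"]]))
cat("surface enhancement factors:",
    sprintf("%.2f", enhancement_factor(0.150, season_w0)), "\n")
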