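#!/usr/bin/env Rscript
# Step 3: gut-content feeding rates. For every station: mean gut fullness
# (NPC) from the examined predators, digestion time from the upper-50-m
# integrated CTD temperature, and the daily feeding rate FR = (NPC/DT)*24.
# Stratum summaries are mean-of-ratios: FR is computed per station, then
# averaged.

suppressPackageStartupMessages(library(chaetofeed))

stations <- read_station_table("results/stations.csv")
ctd <- read_ctd_table("results/ctd.csv")
guts <- read_gut_table("results/guts.csv")
model <- digestion_model()   # a = 10.48 h, b = 0.086 / degC

rows <- lapply(seq_len(nrow(stations)), function(i) {
  id <- stations$station_id[i]
  prof <- ctd[ctd$station_id == id, ]
  T50 <- integrate_upper_layer(prof$depth_m, prof$temp_c, z_max = 50)
  sv <- gut_survey(guts$n_prey_in_gut[guts$station_id == id])
  st <- station_record(stations$season[i], stations$zone[i], T_c = T50,
                       station_id = id)
  fr <- station_feeding_rate(st, sv, model)
  data.frame(station_id = id, season = st$season, zone = st$zone,
             T50_c = T50, NPC = fr$NPC, DT_h = fr$DT_h,
             FR_per_day = fr$FR_per_day, n_predators = fr$n_predators)
})
feeding <- do.call(rbind, rows)
write_table(feeding, "results/feeding_rates.csv")

summarise <- function(v) c(min = min(v), max = max(v), mean = mean(v),
                           sd = stats::sd(v))
summary_tab <- do.call(rbind, lapply(split(feeding, feeding$season), function(d)
  data.frame(season = d$season[1],
             t(c(T = summarise(d$T50_c), NPC = summarise(d$NPC),
                 DT = summarise(d$DT_h), FR = summarise(d$FR_per_day))))))
write_table(summary_tab, "results/feeding_summary.csv")

cat("per-season feeding parameters (min / max / mean):\n")
for (s in unique(feeding$season)) {
  d <- feeding[feeding$season == s, ]
  cat(sprintf(
    "  %-6s  T %.2f-%.2f  NPC %.3f-%.3f  DT %.2f-%.2f h  FR %.2f-%.2f (mean %.2f)\n",
    s, min(d$T50_c), max(d$T50_c), min(d$NPC), max(d$NPC),
    min(d$DT_h), max(d$DT_h), min(d$FR_per_day), max(d$FR_per_day),
    mean(d$FR_per_day)))
}
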