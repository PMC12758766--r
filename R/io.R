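SEASONS <- c("summer", "fall", "winter")
ZONES <- c("neritic", "oceanic")

read_csv_checked <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty input file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("input file has a header but no rows: ", path)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s', row %d of %s",
                   df[[col]][bad[1L]], col, bad[1L], basename(path)))
    df[[col]] <- v
  }
  df
}

check_enum <- function(values, allowed, what, hints = c(autumn = "fall")) {
  bad <- which(!(values %in% allowed))
  if (length(bad)) {
    v <- values[bad[1L]]
    hint <- if (v %in% names(hints))
      sprintf(" (did you mean \"%s\"?)", hints[[v]]) else ""
    stop(sprintf("unknown %s \"%s\" in row %d; expected one of: %s%s",
                 what, v, bad[1L], paste(allowed, collapse = ", "), hint))
  }
  invisible(values)
}

#' Read a station table
#'
#' Reads and validates a per-station CSV with columns `station_id`,
#' `season`, `zone`, and any of the numeric covariates produced by
#' [generate_station_grid()] (`temp_c`, `sal_psu`, `chl_mg_m3`,
#' `bottom_depth_m`, `dist_coast_km`, `copepod_density_ind_m3`,
#' `chaetognath_density_ind_m3`, `wind_speed_m_s`). Unknown season or zone
#' labels are rejected with the offending row number.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_station_table <- function(path) {
  num <- c("temp_c", "sal_psu", "chl_mg_m3", "bottom_depth_m",
           "dist_coast_km", "copepod_density_ind_m3",
           "chaetognath_density_ind_m3", "wind_speed_m_s")
  df <- read_csv_checked(path, required = c("station_id", "season", "zone"),
                         numeric_cols = num)
  check_enum(df$season, SEASONS, "season")
  check_enum(df$zone, ZONES, "zone")
  dens <- intersect(c("copepod_density_ind_m3", "chaetognath_density_ind_m3",
                      "wind_speed_m_s"), names(df))
  for (col in dens)
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop("negative values in column ", col)
  df
}

#' Read a gut-content table
#'
#' Columns: `predator_id`, `station_id`, `n_prey_in_gut` (non-negative
#' integer) and optionally `near_mouth_excluded` (0/1 upstream cleaning
#' flag; rows are kept, the flag is informational).
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_gut_table <- function(path) {
  df <- read_csv_checked(path,
                         required = c("predator_id", "station_id",
                                      "n_prey_in_gut"),
                         numeric_cols = c("n_prey_in_gut",
                                          "near_mouth_excluded"))
  if (any(df$n_prey_in_gut < 0) || any(df$n_prey_in_gut != round(df$n_prey_in_gut)))
    stop("n_prey_in_gut must be non-negative integers")
  df
}

#' Read a CTD profile table
#'
#' Columns: `station_id`, `depth_m`, `temp_c`, and optionally `sal_psu`,
#' `chl_mg_m3`. Depths must be non-negative and strictly increasing within
#' each station.
#'
#' @param path Path to the CSV file.
#' @return A validated data frame.
#' @export
read_ctd_table <- function(path) {
  df <- read_csv_checked(path, required = c("station_id", "depth_m", "temp_c"),
                         numeric_cols = c("depth_m", "temp_c", "sal_psu",
                                          "chl_mg_m3"))
  if (any(df$depth_m < 0)) stop("negative depths in CTD table")
  for (id in unique(df$station_id)) {
    z <- df$depth_m[df$station_id == id]
    if (is.unsorted(z, strictly = TRUE))
      stop("CTD depths not strictly increasing for station ", id)
  }
  df
}

#' Read a gut/habitat composition table
#'
#' Either integer counts (`taxon`, `gut_count`, `habitat_count`) or printed
#' percentages with known totals (`taxon`, `gut_pct`, `habitat_pct`, plus
#' `gut_total` and `habitat_total` arguments), in which case counts are
#' reconstructed with [counts_from_percent()].
#'
#' @param path Path to the CSV file.
#' @param gut_total,habitat_total Totals, required in percentage mode.
#' @return A list of two [composition_table()]s, `gut` and `habitat`.
#' @export
read_composition_pair <- function(path, gut_total = NULL, habitat_total = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("gut_count", "habitat_count") %in% names(df))) {
    g <- ifelse(is.na(df$gut_count), 0L, df$gut_count)
    a <- ifelse(is.na(df$habitat_count), 0L, df$habitat_count)
  } else if (all(c("gut_pct", "habitat_pct") %in% names(df))) {
    if (is.null(gut_total) || is.null(habitat_total))
      stop("percentage-mode composition tables need gut_total and habitat_total")
    g <- counts_from_percent(ifelse(is.na(df$gut_pct), 0, df$gut_pct), gut_total)
    a <- counts_from_percent(ifelse(is.na(df$habitat_pct), 0, df$habitat_pct),
                             habitat_total)
  } else {
    stop("composition table needs gut_count/habitat_count or gut_pct/habitat_pct")
  }
  list(gut = composition_table(df$taxon, g),
       habitat = composition_table(df$taxon, a))
}

#' Write a table to CSV
#'
#' RFC-4180 CSV (UTF-8, "." decimal, no row names): the single tabular
#' interchange format of the pipeline; readers and writers round-trip all
#' fields.
#'
#' @param df Data frame to write.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

fmt_section <- function(title, body) {
  c(paste0("## ", title), "", body, "")
}

#' Render a human-readable pipeline report
#'
#' Assembles a markdown report from whichever analysis outputs are
#' available: per-stratum encounter rates, feeding-rate summaries, the
#' electivity table, the PERMANOVA table and the BIOENV result. Missing
#' sections are marked `SKIPPED`, so partial runs render partial reports.
#' Rendering is deterministic: regenerating the report from the same saved
#' tables yields byte-identical text.
#'
#' @param encounters Data frame of per-stratum encounter rates, or `NULL`.
#' @param feeding Data frame of per-stratum feeding summaries, or `NULL`.
#' @param electivity An [electivity_table()] data frame, or `NULL`.
#' @param permanova A [permanova_two_way()] table, or `NULL`.
#' @param bioenv A [bioenv_best()] result, or `NULL`.
#' @param params Named list of run parameters and seeds to echo, or `NULL`.
#' @return Character vector of report lines.
#' @export
pipeline_report <- function(encounters = NULL, feeding = NULL,
                            electivity = NULL, permanova = NULL,
                            bioenv = NULL, params = NULL) {
  df_lines <- function(df, digits = 4) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], function(v) formatC(v, digits = digits,
                                                   format = "g"))
    utils::capture.output(print(df, row.names = FALSE))
  }
  lines <- c("# Chaetognath-copepod trophic analysis report", "")
  if (!is.null(params)) {
    kv <- vapply(names(params),
                 function(k) sprintf("- %s: %s", k,
                                     paste(format(params[[k]]), collapse = " ")),
                 character(1L))
    lines <- c(lines, fmt_section("Run parameters", kv))
  }
  lines <- c(lines,
    fmt_section("Encounter rates",
                if (is.null(encounters)) "SKIPPED" else df_lines(encounters)),
    fmt_section("Feeding rates",
                if (is.null(feeding)) "SKIPPED" else df_lines(feeding)),
    fmt_section("Prey electivity",
                if (is.null(electivity)) "SKIPPED" else df_lines(electivity)),
    fmt_section("PERMANOVA",
                if (is.null(permanova)) "SKIPPED"
                else df_lines(as.data.frame(permanova))),
    fmt_section("BIOENV",
                if (is.null(bioenv)) "SKIPPED"
                else sprintf("Best subset: %s (rho = %.4f)",
                             paste(bioenv$best_vars, collapse = " + "),
                             bioenv$rho)))
  lines
}
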