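# Shared fixtures, built in code at load time.

# Hand-written three-storm HURDAT2 text exercising sign conventions,
# missing-value sentinels and multi-point tracks.
hurdat2_fixture_text <- function() {
  c(
    "AL011999,          ALPHA,      3,",
    "19990801, 0000,  , TS, 18.0N,  65.7W,  40, 1005,",
    "19990801, 0600,  , TS, 18.4N,  66.1W,  45, 1002,",
    "19990801, 1200, L, HU, 18.8N,  66.5W,  70,  987,",
    "AL022000,           BETA,      2,",
    "20000910, 1200,  , TD, 12.0N,  60.0W, -99, -999,",
    "20000910, 1800,  , TS, 12.5S,  59.5E,  35,  999,",
    "AL032001,        UNNAMED,      1,",
    "20010701, 0000,  , HU, 25.0N,  80.0W, 100,  950,"
  )
}

empty_track_tbl_for_test <- function() parse_hurdat2(character())

# Minimal manual track-point tibble (one storm unless n > 1).
make_track <- function(storm_id = "AL011999", year = 1999L,
                       lat, lon, wind = rep(50, length(lat)),
                       status = "HU") {
  tibble::tibble(
    storm_id = storm_id, name = "FIX", year = year,
    timestamp = as.POSIXct("1999-08-01 00:00:00", tz = "UTC") +
      (seq_along(lat) - 1) * 6 * 3600,
    lat = lat, lon = lon, max_wind = wind,
    min_pressure = 1010 - 0.5 * wind, status = status, record_id = ""
  )
}

make_sites <- function(lat, lon, ids = sprintf("s%02d", seq_along(lat))) {
  tibble::tibble(site_id = ids, lat = lat, lon = lon)
}

# Site-year cover series shorthand
make_series <- function(site_id, years, covers) {
  tibble::tibble(site_id = site_id, year = as.integer(years),
                 total_cover = covers)
}

# A minimal catalog row for event matching
make_catalog_row <- function(site_id, storm_id, year, dist = 10,
                             month = 9L) {
  tibble::tibble(
    site_id = site_id, storm_id = storm_id, year = as.integer(year),
    min_distance_km = dist, closest_point = 1L,
    closest_time = as.POSIXct(sprintf("%d-%02d-15 00:00:00", year, month),
                              tz = "UTC"),
    wind_at_closest = 80, category_used = "1", band = "<=35"
  )
}

# Small synthetic world reused across tests (built once per test run).
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- synth_bundle(synth_params(
        seed = 42, n_sites = 25, years = c(1990, 2010),
        initial_cover = c(50, 80)
      ))
    }
    cache
  }
})

# Independent brute-force catalog oracle: plain per-pair scan with
# geosphere distances and the retention rules restated directly.
oracle_catalog <- function(tracks, reefs) {
  peaks_all <- tapply(tracks$max_wind, tracks$storm_id,
                      function(w) if (all(is.na(w))) NA else max(w, na.rm = TRUE))
  rows <- list()
  for (sid in unique(tracks$storm_id)) {
    pts <- tracks[tracks$storm_id == sid, ]
    for (r in seq_len(nrow(reefs))) {
      d <- geosphere::distHaversine(
        cbind(reefs$lon[r], reefs$lat[r]), cbind(pts$lon, pts$lat),
        r = 6371000) / 1000
      dmin <- min(d)
      if (dmin > 100) next
      w_near <- pts$max_wind[d <= 100]
      if (all(is.na(w_near))) next
      w <- max(w_near, na.rm = TRUE)
      cat_num <- if (w >= 137) 5 else if (w >= 113) 4 else if (w >= 96) 3 else
        if (w >= 83) 2 else if (w >= 64) 1 else if (w >= 34) 0 else -1
      keep <- (dmin <= 35 && cat_num >= 0) ||
        (dmin > 35 && dmin <= 65 && cat_num >= 3) ||
        (dmin > 65 && dmin <= 100 && cat_num >= 4)
      if (!keep) next
      band <- if (dmin <= 35) "<=35" else if (dmin <= 65) "35-65" else "65-100"
      rows[[length(rows) + 1]] <- data.frame(
        site_id = reefs$site_id[r], storm_id = sid,
        min_distance_km = dmin, band = band,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(site_id = character(), storm_id = character(),
                      min_distance_km = numeric(), band = character())
  }
  out[order(out$site_id, out$storm_id), , drop = FALSE]
}
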