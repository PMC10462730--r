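#' Default parameters for the synthetic study system
#'
#' Returns the parameter list the generator functions consume. Defaults
#' describe a Caribbean-like study system: reef sites scattered uniformly in
#' a Caribbean bounding box, Poisson storm arrivals, correlated-random-walk
#' storm tracks recorded every 6 h with a rise-and-fall wind profile, a
#' linear background decline in coral cover, and immediate storm impacts that
#' differ by life-history group (large loss for competitive corals, moderate
#' for stress-tolerant, none for weedy), followed by a brief stasis and
#' resumed decline. Immediate impacts total -8.5 percentage points, the
#' median 1980s per-event loss, and the background decline is 0.25 %/yr, the
#' median regional loss rate.
#'
#' @param ... Named overrides of any default.
#' @return Named list of generator parameters.
#' @export
synth_params <- function(...) {
  p <- list(
    n_sites = 60,
    bbox = c(lat_min = 10, lat_max = 27, lon_min = -88, lon_max = -60),
    years = c(1970, 2017),
    lambda = 6,                 # basin storms per year (Poisson)
    step_hours = 6,
    speed_kmh = c(10, 30),      # translation speed range
    peak_wind_kt = c(35, 150),  # lifetime peak wind drawn uniformly
    duration_days = c(3, 9),
    baseline_decline = 0.25,    # percent cover lost per year
    initial_cover = c(20, 45),  # percent, uniform
    delta_competitive = -5.5,   # immediate impact, percentage points
    delta_stress = -3.0,
    delta_weedy = 0.0,
    stasis_years = 3,
    sigma = 2.0,                # observation noise sd, percent cover
    lhg_share = c(competitive = 0.35, stress_tolerant = 0.45, weedy = 0.20),
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  p[names(over)] <- over
  stopifnot(p$lambda > 0, p$sigma >= 0, p$n_sites >= 0,
            p$stasis_years >= 0)
  p
}

#' Generate reef survey sites
#'
#' Uniformly placed sites inside the bounding box, with unique coordinate
#' pairs and subregion labels from a 2x2 split of the box. Reproducible for
#' a given seed.
#'
#' @param params Parameter list from [synth_params()].
#' @return Tibble `site_id`, `lat`, `lon`, `subregion`.
#' @export
gen_reef_sites <- function(params = synth_params()) {
  n <- params$n_sites
  if (n == 0) {
    return(tibble::tibble(site_id = character(), lat = numeric(),
                          lon = numeric(), subregion = character()))
  }
  bb <- params$bbox
  withr::with_seed(as.integer(params$seed), {
    lat <- stats::runif(n, bb["lat_min"], bb["lat_max"])
    lon <- stats::runif(n, bb["lon_min"], bb["lon_max"])
    while (anyDuplicated(cbind(lat, lon)) > 0) { # measure-zero event
      dup <- duplicated(cbind(lat, lon))
      lat[dup] <- stats::runif(sum(dup), bb["lat_min"], bb["lat_max"])
      lon[dup] <- stats::runif(sum(dup), bb["lon_min"], bb["lon_max"])
    }
    mid_lat <- mean(bb[c("lat_min", "lat_max")])
    mid_lon <- mean(bb[c("lon_min", "lon_max")])
    tibble::tibble(
      site_id = sprintf("site_%03d", seq_len(n)),
      lat = lat, lon = lon,
      subregion = paste0(ifelse(lat >= mid_lat, "N", "S"),
                         ifelse(lon >= mid_lon, "E", "W"))
    )
  })
}

#' Generate synthetic storm tracks
#'
#' Annual storm counts are Poisson(lambda); each storm is a correlated random
#' walk with 6-hourly positions, generally westward-to-northwestward motion,
#' and a rise-and-fall sustained-wind profile reaching a uniformly drawn
#' lifetime peak. Coordinates are generated at the 0.1-degree, whole-knot
#' precision carried by HURDAT2 text, so tracks round-trip exactly through
#' [write_hurdat2()] / [parse_hurdat2()].
#'
#' @param params Parameter list from [synth_params()].
#' @return Track-point tibble in the [parse_hurdat2()] layout.
#' @export
gen_storm_tracks <- function(params = synth_params()) {
  bb <- params$bbox
  withr::with_seed(as.integer(params$seed) + 1L, {
    years <- seq(params$years[1], params$years[2])
    counts <- stats::rpois(length(years), params$lambda)
    storms <- list()
    for (yi in seq_along(years)) {
      if (counts[yi] == 0) next
      for (s in seq_len(counts[yi])) {
        storms[[length(storms) + 1L]] <-
          gen_one_track(years[yi], s, params)
      }
    }
    if (length(storms) == 0) return(empty_track_tbl())
    tracks <- dplyr::bind_rows(storms)
    validate_tracks(tracks)
    tracks
  })
}

gen_one_track <- function(year, number, params) {
  bb <- params$bbox
  n_steps <- round(stats::runif(1, params$duration_days[1],
                                params$duration_days[2]) * 24 / params$step_hours)
  n_steps <- max(n_steps, 4)
  # genesis biased to the east/south of the box so tracks cross it
  lat0 <- stats::runif(1, bb["lat_min"], bb["lat_max"] - 3)
  lon0 <- stats::runif(1, bb["lon_min"] + 5, bb["lon_max"] + 8)
  heading <- stats::runif(1, 200, 330) * pi / 180 # mostly W to NW (from N, cw)
  speed <- stats::runif(1, params$speed_kmh[1], params$speed_kmh[2])

  lat <- numeric(n_steps); lon <- numeric(n_steps)
  lat[1] <- lat0; lon[1] <- lon0
  for (i in 2:n_steps) {
    heading <- heading + stats::rnorm(1, 0.02, 0.08) # slow recurvature + jitter
    step_km <- speed * params$step_hours
    dlat <- step_km * cos(heading) / 111.195
    dlon <- step_km * sin(heading) / (111.195 * cos(lat[i - 1] * pi / 180))
    lat[i] <- min(max(lat[i - 1] + dlat, -89), 89)
    lon[i] <- lon[i - 1] + dlon
  }

  peak <- stats::runif(1, params$peak_wind_kt[1], params$peak_wind_kt[2])
  peak_at <- stats::runif(1, 0.3, 0.7) * n_steps
  wind <- peak * exp(-((seq_len(n_steps) - peak_at) / (0.35 * n_steps))^2)
  wind <- pmax(round(wind), 15)

  start <- as.POSIXct(sprintf("%d-%02d-%02d 00:00:00", year,
                              sample(6:10, 1), sample(1:28, 1)),
                      tz = "UTC")
  tibble::tibble(
    storm_id = sprintf("AL%02d%04d", number, year),
    name = sprintf("SYN%02d%04d", number, year),
    year = as.integer(year),
    timestamp = start + (seq_len(n_steps) - 1) * params$step_hours * 3600,
    lat = round(lat, 1),
    lon = round(normalize_lon(lon), 1),
    max_wind = as.numeric(wind),
    min_pressure = round(1013 - 0.75 * wind),
    status = ifelse(wind >= 64, "HU", ifelse(wind >= 34, "TS", "TD")),
    record_id = ""
  )
}

#' Generate coral-cover survey records with known ground truth
#'
#' Builds one annual survey per site and year: each life-history-group
#' component starts from its share of the site's initial cover and declines
#' linearly at the background rate; at every retained storm intersection the
#' component drops to (its level one year before the storm + its group's
#' immediate impact delta), holds that level for the stasis period, then
#' resumes the linear decline. Gaussian observation noise is added and the
#' result clamped to [0, 100]. With zero noise the pre/post (one year either
#' side) difference at an impact equals the injected delta exactly.
#'
#' @param sites Reef-site tibble from [gen_reef_sites()].
#' @param catalog Retained intersections from [build_intersection_catalog()]
#'   (the generator and the engine deliberately share the retention rules so
#'   parameter-recovery tests are meaningful).
#' @param params Parameter list from [synth_params()].
#' @return Survey-record tibble in the [read_surveys()] layout (long: one
#'   `TOTAL` row plus one row per life-history-group proxy species per
#'   site-year), with attribute `"ground_truth"` carrying the injected
#'   parameters.
#' @export
gen_cover_trajectories <- function(sites, catalog, params = synth_params()) {
  years <- seq(params$years[1], params$years[2])
  deltas <- c(competitive = params$delta_competitive,
              stress_tolerant = params$delta_stress,
              weedy = params$delta_weedy)
  proxy_species <- c(competitive = "Acropora palmata",
                     stress_tolerant = "Orbicella annularis",
                     weedy = "Porites astreoides")

  withr::with_seed(as.integer(params$seed) + 2L, {
    per_site <- lapply(seq_len(nrow(sites)), function(i) {
      sid <- sites$site_id[i]
      init_total <- stats::runif(1, params$initial_cover[1], params$initial_cover[2])
      storm_yrs <- sort(catalog$year[catalog$site_id == sid])
      comp <- lapply(names(deltas), function(g) {
        traj <- trajectory_with_impacts(
          years, init_total * params$lhg_share[[g]],
          params$baseline_decline * params$lhg_share[[g]],
          storm_yrs, deltas[[g]], params$stasis_years
        )
        tibble::tibble(site_id = sid, year = years, species = proxy_species[[g]],
                       true_cover = traj)
      })
      dplyr::bind_rows(comp)
    })
    truth <- dplyr::bind_rows(per_site)
    totals <- truth |>
      dplyr::group_by(.data$site_id, .data$year) |>
      dplyr::summarise(true_cover = sum(.data$true_cover), .groups = "drop") |>
      dplyr::mutate(species = "TOTAL")
    long <- dplyr::bind_rows(truth, totals)
    long$cover_pct <- pmin(pmax(
      long$true_cover + stats::rnorm(nrow(long), 0, params$sigma), 0), 100)

    out <- tibble::tibble(
      site_id = long$site_id,
      date = as.Date(sprintf("%d-07-01", long$year)),
      year = as.integer(long$year),
      year_only = TRUE,
      species = long$species,
      cover_pct = long$cover_pct,
      source = "synthetic"
    ) |>
      dplyr::arrange(.data$site_id, .data$year, .data$species)
    attr(out, "ground_truth") <- list(
      baseline_decline = params$baseline_decline,
      deltas = deltas,
      delta_total = sum(deltas * 1), # per-event total immediate impact
      sigma = params$sigma,
      stasis_years = params$stasis_years,
      lhg_share = params$lhg_share,
      proxy_species = proxy_species
    )
    out
  })
}

# deterministic trajectory: linear decline, impact drops measured from the
# pre-storm-year level, stasis, resumed decline; never below 0
trajectory_with_impacts <- function(years, init, slope, storm_years, delta,
                                    stasis) {
  n <- length(years)
  level <- numeric(n)
  level[1] <- init
  hold <- 0L
  for (i in 2:n) {
    if (years[i] %in% storm_years) {
      level[i] <- level[i - 1] + delta
      hold <- as.integer(stasis)
    } else if (hold > 0L) {
      level[i] <- level[i - 1]
      hold <- hold - 1L
    } else {
      level[i] <- level[i - 1] - slope
    }
    level[i] <- max(level[i], 0)
  }
  level
}

#' Generate the full synthetic bundle
#'
#' Runs the three generators and the intersection engine in order, optionally
#' writing the artifacts (HURDAT2 text, reefs CSV, surveys CSV, life-history
#' lookup CSV, ground-truth JSON) to a directory.
#'
#' @param params Parameter list from [synth_params()].
#' @param dir Optional output directory (created if needed).
#' @return List with `sites`, `tracks`, `catalog`, `surveys`, `lhg_table`,
#'   `ground_truth` (and `paths` when `dir` is given).
#' @export
synth_bundle <- function(params = synth_params(), dir = NULL) {
  sites <- gen_reef_sites(params)
  tracks <- gen_storm_tracks(params)
  tracks <- filter_tropical_storms(tracks)
  catalog <- build_intersection_catalog(tracks, sites)
  surveys <- gen_cover_trajectories(sites, catalog, params)
  truth <- attr(surveys, "ground_truth")
  lhg_table <- tibble::tibble(
    species = unname(truth$proxy_species),
    group = names(truth$proxy_species)
  )
  out <- list(sites = sites, tracks = tracks, catalog = catalog,
              surveys = surveys, lhg_table = lhg_table, ground_truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      tracks = file.path(dir, "tracks.hurdat2"),
      reefs = file.path(dir, "reefs.csv"),
      surveys = file.path(dir, "surveys.csv"),
      lhg = file.path(dir, "lhg_lookup.csv"),
      truth = file.path(dir, "ground_truth.json")
    )
    write_hurdat2(tracks, paths$tracks)
    readr::write_csv(sites, paths$reefs)
    readr::write_csv(
      dplyr::mutate(surveys[c("site_id", "date", "species", "cover_pct", "source")],
                    cover_pct = sprintf("%.6f", .data$cover_pct)),
      paths$surveys)
    readr::write_csv(lhg_table, paths$lhg)
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}
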