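#' Run the full reef-storm analysis pipeline
#'
#' Orchestrates ingest -> intersection -> cover aggregation -> resilience ->
#' inference, writing tidy CSV outputs plus a JSON manifest (input checksums,
#' seed, parameter echo, stage record counts, output checksums). The run is
#' deterministic: the same configuration and inputs produce byte-identical
#' outputs.
#'
#' The configuration is a named list (or a YAML file path) with any of:
#' \describe{
#'   \item{tracks, reefs, surveys, lhg}{Input file paths (HURDAT2 text, reef
#'     CSV, survey CSV, life-history lookup CSV). When omitted, a synthetic
#'     bundle is generated from `synth` instead.}
#'   \item{synth}{Named list of [synth_params()] overrides.}
#'   \item{band_mode}{`"contiguous"` (default) or `"strict"`.}
#'   \item{tolerance}{Pre/post matching tolerance in years (default 0).}
#'   \item{bootstrap_B, seed}{Bootstrap replicates (default 1000) and seed
#'     (default 1).}
#'   \item{control_gap}{Control-reef exclusion gap in years (default 10).}
#'   \item{climatology}{Window for regime metrics, `c(first, last)`; defaults
#'     to the span of the track data.}
#'   \item{out_dir}{Output directory (required).}
#' }
#'
#' @param config Named list or YAML file path.
#' @return Invisibly, a list with every stage's tables and the manifest.
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(tracks = NULL, reefs = NULL, surveys = NULL, lhg = NULL,
         synth = list(), band_mode = "contiguous", tolerance = 0,
         bootstrap_B = 1000, seed = 1L, control_gap = 10,
         climatology = NULL, out_dir = NULL),
    config
  )
  if (is.null(cfg$out_dir)) stop("config must name an out_dir", call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- ingest ---------------------------------------------------------------
  input_paths <- Filter(Negate(is.null),
                        cfg[c("tracks", "reefs", "surveys", "lhg")])
  dat <- stage("ingest", {
    if (length(input_paths) == 0) {
      b <- synth_bundle(do.call(synth_params,
                                c(cfg$synth, list(seed = as.integer(cfg$seed)))))
      list(tracks = b$tracks, sites = b$sites, surveys = b$surveys,
           lhg_table = b$lhg_table, truth = b$ground_truth)
    } else {
      missing <- names(input_paths)[!vapply(input_paths, file.exists, logical(1))]
      if (length(missing)) stop("missing input file(s): ",
                                paste(unlist(input_paths[missing]), collapse = ", "))
      list(
        tracks = filter_tropical_storms(parse_hurdat2(cfg$tracks)),
        sites = readr::read_csv(cfg$reefs, show_col_types = FALSE),
        surveys = read_surveys(cfg$surveys),
        lhg_table = if (!is.null(cfg$lhg)) read_lhg_table(cfg$lhg) else NULL,
        truth = NULL
      )
    }
  })
  message("ingest: ", dplyr::n_distinct(dat$tracks$storm_id), " storms, ",
          nrow(dat$sites), " reef sites, ", nrow(dat$surveys), " survey rows")

  # -- intersect ------------------------------------------------------------
  inter <- stage("intersect", {
    catalog <- build_intersection_catalog(dat$tracks, dat$sites,
                                          band_mode = cfg$band_mode)
    peaks <- storm_peak_wind(dat$tracks)
    window <- cfg$climatology %||%
      c(min(dat$tracks$year), max(dat$tracks$year))
    regime <- disturbance_regime(catalog, peaks, sites = dat$sites,
                                 window = window)
    list(catalog = catalog, peaks = peaks, regime = regime)
  })
  message("intersect: ", nrow(inter$catalog), " retained reef-storm intersections")

  # -- cover ----------------------------------------------------------------
  cover <- stage("cover", {
    totals <- annual_series(dat$surveys)
    lhg <- if (!is.null(dat$lhg_table)) annual_series(dat$surveys, dat$lhg_table)
           else NULL
    list(totals = totals, lhg = lhg,
         regional = regional_means(totals))
  })
  message("cover: ", nrow(cover$totals), " site-year cover values")

  # -- resilience -----------------------------------------------------------
  resil <- stage("resilience", {
    events <- match_pre_post(cover$totals, inter$catalog,
                             tolerance = cfg$tolerance) |>
      add_resistance()
    events_lhg <- if (!is.null(cover$lhg)) {
      abs_ev <- match_pre_post(cover$lhg, inter$catalog, value = "abs_cover",
                               tolerance = cfg$tolerance) |> add_resistance()
      rel_ev <- match_pre_post(cover$lhg, inter$catalog, value = "rel_cover",
                               tolerance = cfg$tolerance) |> add_resistance()
      list(abs = abs_ev, rel = rel_ev)
    } else NULL
    cr_events <- select_event_for_cr(events, inter$peaks)
    cr_records <- cr_events |>
      dplyr::rowwise() |>
      dplyr::mutate(cr_rate(cover$totals[cover$totals$site_id == .data$site_id, ],
                            .data$impact_year)) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.na(.data$cr))
    controls <- select_controls(cover$totals, inter$catalog,
                                min_gap = cfg$control_gap) |>
      dplyr::filter(!is.na(.data$cr))
    list(events = events, events_lhg = events_lhg, cr_records = cr_records,
         controls = controls)
  })
  message("resilience: ", nrow(resil$events), " matched events, ",
          nrow(resil$cr_records), " CR series, ",
          nrow(resil$controls), " control windows")

  # -- inference ------------------------------------------------------------
  infer <- stage("inference", {
    wil <- list(
      tibble::tibble(group = "total", measure = "absolute",
                     paired_wilcoxon(resil$events$pre_cover,
                                     resil$events$post_cover))
    )
    if (!is.null(resil$events_lhg)) {
      for (meas in c("abs", "rel")) {
        ev <- resil$events_lhg[[meas]]
        wil <- c(wil, lapply(split(ev, ev$group), function(g) {
          tibble::tibble(group = g$group[1],
                         measure = if (meas == "abs") "absolute" else "relative",
                         paired_wilcoxon(g$pre_cover, g$post_cover))
        }))
      }
    }
    wilcoxon <- dplyr::bind_rows(wil)
    ev <- dplyr::mutate(resil$events,
                        decade = floor(.data$impact_year / 10) * 10)
    kw <- if (dplyr::n_distinct(ev$decade) >= 2) {
      dplyr::bind_rows(
        dplyr::mutate(kruskal_wallis(ev$resistance_abs, ev$decade),
                      measure = "absolute", .before = 1),
        dplyr::mutate(kruskal_wallis(ev$resistance_rel, ev$decade),
                      measure = "relative", .before = 1)
      )
    } else NULL
    dec <- dplyr::bind_rows(
      dplyr::mutate(resil$cr_records, category = "impacted",
                    year = .data$impact_year),
      dplyr::mutate(resil$controls, category = "control",
                    year = floor((.data$window_start + .data$window_end) / 2))
    ) |>
      decadal_summary("cr", by = "category", B = cfg$bootstrap_B,
                      seed = cfg$seed)
    list(wilcoxon = wilcoxon, kruskal = kw, decadal_cr = dec)
  })

  # -- outputs --------------------------------------------------------------
  manifest <- stage("write", {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- list(
      catalog = inter$catalog, regime = inter$regime,
      cover_annual = cover$totals, cover_regional = cover$regional,
      events_total = resil$events, cr_records = resil$cr_records,
      controls = resil$controls, wilcoxon = infer$wilcoxon,
      decadal_cr = infer$decadal_cr
    )
    if (!is.null(cover$lhg)) tables$cover_lhg <- cover$lhg
    if (!is.null(resil$events_lhg)) {
      tables$events_lhg_abs <- resil$events_lhg$abs
      tables$events_lhg_rel <- resil$events_lhg$rel
    }
    if (!is.null(infer$kruskal)) tables$kruskal <- infer$kruskal
    paths <- vapply(names(tables), function(nm) {
      p <- file.path(cfg$out_dir, paste0(nm, ".csv"))
      readr::write_csv(tables[[nm]], p)
      p
    }, character(1))
    manifest <- list(
      seed = as.integer(cfg$seed),
      band_mode = cfg$band_mode,
      tolerance = cfg$tolerance,
      control_gap = cfg$control_gap,
      inputs = if (length(input_paths))
        as.list(tools::md5sum(unlist(input_paths))) else list(synthetic = TRUE),
      synth = cfg$synth,
      counts = list(
        storms = dplyr::n_distinct(dat$tracks$storm_id),
        reefs = nrow(dat$sites),
        intersections = nrow(inter$catalog),
        events = nrow(resil$events),
        cr_series = nrow(resil$cr_records),
        control_windows = nrow(resil$controls)
      ),
      outputs = as.list(tools::md5sum(unname(paths)))
    )
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  })

  invisible(list(data = dat, intersect = inter, cover = cover,
                 resilience = resil, inference = infer, manifest = manifest))
}
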