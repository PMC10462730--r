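#' Match pre- and post-storm surveys to intersections
#'
#' Builds one storm event per intersection for which the cover series
#' brackets the impact: the pre value is the survey one calendar year before
#' the impact year and the post value one year after. With `tolerance > 0`
#' the nearest survey within `tolerance` extra years on the far side of each
#' anchor is used instead (pre searched in `[year - 1 - tolerance, year - 1]`,
#' post in `[year + 1, year + 1 + tolerance]`) and the event is flagged as
#' inexact. Events missing either side are dropped (absence is a value, not
#' an error).
#'
#' @param series Site-year cover tibble (`site_id`, `year`, value column);
#'   may carry a `group` column (life-history group), in which case events
#'   are matched within each group.
#' @param catalog Intersection catalog from [build_intersection_catalog()].
#' @param value Name of the cover column to match (default `"total_cover"`).
#' @param tolerance Non-negative integer, extra years allowed (default 0 =
#'   exact +/- 1 year).
#' @return Event tibble: `site_id`, (`group`,) `storm_id`, `impact_year`,
#'   `closest_time`, `wind_at_closest`, `pre_year`, `post_year`, `pre_cover`,
#'   `post_cover`, `matched_exact`.
#' @export
match_pre_post <- function(series, catalog, value = "total_cover",
                           tolerance = 0) {
  stopifnot(tolerance >= 0, value %in% names(series))
  grouped <- "group" %in% names(series)

  nearest <- function(site_years, site_values, anchor, lo, hi) {
    in_win <- which(site_years >= lo & site_years <= hi)
    if (length(in_win) == 0) return(list(year = NA_integer_, value = NA_real_))
    i <- in_win[which.min(abs(site_years[in_win] - anchor))]
    list(year = site_years[i], value = site_values[i])
  }

  one_group <- function(sdat) {
    cat_site <- dplyr::semi_join(catalog, sdat, by = "site_id")
    if (nrow(cat_site) == 0) return(NULL)
    purrr::pmap_dfr(
      cat_site[c("site_id", "storm_id", "year", "closest_time", "wind_at_closest")],
      function(site_id, storm_id, year, closest_time, wind_at_closest) {
        s <- sdat[sdat$site_id == site_id, ]
        pre <- nearest(s$year, s[[value]], year - 1, year - 1 - tolerance, year - 1)
        post <- nearest(s$year, s[[value]], year + 1, year + 1, year + 1 + tolerance)
        tibble::tibble(
          site_id = site_id, storm_id = storm_id, impact_year = year,
          closest_time = closest_time, wind_at_closest = wind_at_closest,
          pre_year = pre$year, post_year = post$year,
          pre_cover = pre$value, post_cover = post$value,
          matched_exact = identical(pre$year, year - 1L) &&
            identical(post$year, year + 1L)
        )
      })
  }

  events <- if (grouped) {
    series |>
      dplyr::group_by(.data$group) |>
      dplyr::group_map(~ {
        ev <- one_group(.x)
        if (!is.null(ev)) dplyr::mutate(ev, group = .y$group, .after = "site_id")
        else NULL
      }) |>
      dplyr::bind_rows()
  } else {
    one_group(series)
  }
  if (is.null(events) || nrow(events) == 0) return(empty_event_tbl(grouped))
  events |>
    dplyr::filter(!is.na(.data$pre_cover), !is.na(.data$post_cover)) |>
    dplyr::mutate(matched_exact = .data$pre_year == .data$impact_year - 1 &
                    .data$post_year == .data$impact_year + 1) |>
    dplyr::arrange(.data$site_id, .data$impact_year, .data$storm_id)
}

empty_event_tbl <- function(grouped = FALSE) {
  out <- tibble::tibble(
    site_id = character(), storm_id = character(), impact_year = integer(),
    closest_time = as.POSIXct(character(), tz = "UTC"),
    wind_at_closest = numeric(),
    pre_year = integer(), post_year = integer(),
    pre_cover = numeric(), post_cover = numeric(), matched_exact = logical()
  )
  if (grouped) dplyr::mutate(out, group = character(), .after = "site_id") else out
}

#' Resistance to a storm event
#'
#' Absolute resistance is the change in cover from one year pre- to one year
#' post-storm (percentage points); relative resistance expresses it as a
#' percentage of the pre-storm cover,
#' (post - pre) / pre x 100. Relative resistance is undefined (`NA`) when
#' pre-storm cover is zero; the absolute change is still returned.
#'
#' @param pre,post Percent cover one year before and after the storm.
#' @return Tibble with `resistance_abs` and `resistance_rel`.
#' @examples
#' resistance(20, 15) # -5 points, -25 %
#' @export
resistance <- function(pre, post) {
  # covers are percentages but relative-abundance inputs may exceed 100
  stopifnot(all(pre >= 0, na.rm = TRUE), all(post >= 0, na.rm = TRUE))
  tibble::tibble(
    resistance_abs = post - pre,
    resistance_rel = ifelse(pre > 0, (post - pre) / pre * 100, NA_real_)
  )
}

#' Attach resistance columns to an event table
#'
#' @param events Event tibble from [match_pre_post()].
#' @return `events` with `resistance_abs` and `resistance_rel` appended.
#' @export
add_resistance <- function(events) {
  dplyr::bind_cols(events, resistance(events$pre_cover, events$post_cover))
}

#' Recovery trajectory relative to initial conditions
#'
#' For one site's cover series around a storm, expresses every surveyed year
#' as an offset from the impact year and its cover as the difference from the
#' initial conditions (cover one year before the storm). The offset -1 value
#' is exactly zero by construction.
#'
#' @param series One site's cover tibble (`year`, value column).
#' @param impact_year Calendar year of the storm.
#' @param value Cover column name.
#' @return Tibble `offset` (year - impact_year), `delta` (cover minus initial
#'   cover).
#' @export
relative_recovery <- function(series, impact_year, value = "total_cover") {
  init <- series[[value]][series$year == impact_year - 1]
  if (length(init) != 1 || is.na(init)) {
    stop("initial conditions (cover at impact_year - 1) are missing",
         call. = FALSE)
  }
  tibble::tibble(offset = series$year - impact_year,
                 delta = series[[value]] - init) |>
    dplyr::arrange(.data$offset)
}

#' Annual post-storm rate of cover change (CR)
#'
#' CR = (pca - pcb) / d, where pcb is the cover immediately after the storm
#' (one year post), pca the cover at the end of the site's series, and d the
#' number of years between them. Depends only on the two endpoints.
#'
#' @param series One site's cover tibble (`year`, value column).
#' @param impact_year Calendar year of the storm.
#' @param value Cover column name.
#' @return One-row tibble `cr`, `pcb`, `pca`, `pcb_year`, `pca_year`, `d`;
#'   `cr = NA` when there is no post-storm series (missing `impact_year + 1`
#'   survey or nothing after it).
#' @examples
#' s <- tibble::tibble(year = c(1999, 2001, 2005), total_cover = c(20, 10, 8))
#' cr_rate(s, 2000) # (8 - 10) / 4 = -0.5
#' @export
cr_rate <- function(series, impact_year, value = "total_cover") {
  undefined <- tibble::tibble(cr = NA_real_, pcb = NA_real_, pca = NA_real_,
                              pcb_year = NA_integer_, pca_year = NA_integer_,
                              d = NA_real_)
  pcb_year <- impact_year + 1
  i <- which(series$year == pcb_year)
  if (length(i) != 1) return(undefined)
  later <- series[series$year > pcb_year, ]
  if (nrow(later) == 0) return(undefined)
  j <- which.max(later$year)
  pcb <- series[[value]][i]
  pca <- later[[value]][j]
  d <- later$year[j] - pcb_year
  tibble::tibble(cr = (pca - pcb) / d, pcb = pcb, pca = pca,
                 pcb_year = as.integer(pcb_year),
                 pca_year = as.integer(later$year[j]), d = d)
}

#' Resolve same-site, same-year storm events for CR series
#'
#' When two or more storms strike a site in the same calendar year, only one
#' recovery series is kept: the stronger storm (higher peak sustained wind),
#' with ties broken by the later impact date.
#'
#' @param events Event tibble carrying `site_id`, `impact_year` and
#'   `closest_time`.
#' @param storm_peaks Tibble `storm_id`, `peak_wind` from [storm_peak_wind()].
#' @return `events` with at most one row per site and impact year.
#' @export
select_event_for_cr <- function(events, storm_peaks) {
  grp <- intersect(c("site_id", "group", "impact_year"), names(events))
  events |>
    dplyr::left_join(storm_peaks[c("storm_id", "peak_wind")], by = "storm_id") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::arrange(dplyr::desc(.data$peak_wind), dplyr::desc(.data$closest_time),
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$site_id, .data$impact_year)
}

#' Select control-reef windows
#'
#' Controls are survey series unconfounded by storm recovery: sites never hit
#' by a retained storm contribute their full series, and previously-hit sites
#' contribute survey years that are more than `min_gap` years (strictly)
#' after the most recent prior storm, with no storm in between. Each
#' qualifying run of years forms a window whose annual rate of change
#' (CR) is computed from its first and last surveys, mirroring the
#' storm-event CR formula.
#'
#' @param series Site-year cover tibble (`site_id`, `year`, value column,
#'   optional `subregion`).
#' @param catalog Intersection catalog (full climatology).
#' @param value Cover column name.
#' @param min_gap Years that must elapse after a storm before a survey counts
#'   as control (default 10, exclusive).
#' @return Tibble `site_id`, (`subregion`,) `window_start`, `window_end`,
#'   `n_years`, `cr`, `never_hit`; windows with a single survey year have
#'   `cr = NA`.
#' @export
select_controls <- function(series, catalog, value = "total_cover",
                            min_gap = 10) {
  storm_years <- catalog |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(years = list(sort(unique(.data$year))), .groups = "drop")

  series |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_map(function(s, key) {
      sy <- storm_years$years[match(key$site_id, storm_years$site_id)]
      sy <- if (is.na(match(key$site_id, storm_years$site_id))) integer() else sy[[1]]
      s <- dplyr::arrange(s, .data$year)
      last_prior <- vapply(s$year, function(y) {
        prior <- sy[sy <= y] # a survey in the impact year is post-storm
        if (length(prior) == 0) -Inf else max(prior)
      }, numeric(1))
      qualifies <- (s$year - last_prior) > min_gap
      if (!any(qualifies)) return(NULL)
      q <- s[qualifies, , drop = FALSE]
      win <- last_prior[qualifies] # one window per preceding storm (or -Inf)
      q |>
        dplyr::mutate(.window = win) |>
        dplyr::group_by(.data$.window) |>
        dplyr::summarise(
          window_start = min(.data$year),
          window_end = max(.data$year),
          n_years = dplyr::n(),
          cr = if (dplyr::n() > 1)
            (.data[[value]][which.max(.data$year)] -
               .data[[value]][which.min(.data$year)]) /
            (max(.data$year) - min(.data$year))
          else NA_real_,
          .groups = "drop"
        ) |>
        dplyr::mutate(
          site_id = key$site_id,
          subregion = if ("subregion" %in% names(s)) s$subregion[1] else NA_character_,
          never_hit = length(sy) == 0,
          .before = 1
        ) |>
        dplyr::select(-".window")
    }) |>
    dplyr::bind_rows()
}

#' Decadal summaries with bootstrap confidence limits
#'
#' Per-decade (and per-category) means of a value with non-parametric
#' percentile-bootstrap confidence limits and sample sizes. Decades are
#' calendar decades of the supplied year (1980s = 1980-1989). Cells with a
#' single observation report the mean with `NA` limits and are flagged
#' degenerate.
#'
#' @param df Tibble with a year column, a value column and optional grouping
#'   columns.
#' @param value Value column name.
#' @param by Extra grouping column names (e.g. `"category"` or `"group"`).
#' @param year_col Year column name (default `"year"`).
#' @param B,level,seed Bootstrap replicates, confidence level and seed
#'   (passed to [bootstrap_ci()]).
#' @return Tibble `decade`, grouping columns, `mean`, `ci_lo`, `ci_hi`, `n`,
#'   `degenerate`.
#' @export
decadal_summary <- function(df, value, by = character(), year_col = "year",
                            B = 1000, level = 0.95, seed = 1L) {
  df |>
    dplyr::filter(!is.na(.data[[value]])) |>
    dplyr::mutate(decade = floor(.data[[year_col]] / 10) * 10) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("decade", by)))) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      ci_lo = if (dplyr::n() > 1)
        bootstrap_ci(.data[[value]], B = B, level = level, seed = seed)$lo
      else NA_real_,
      ci_hi = if (dplyr::n() > 1)
        bootstrap_ci(.data[[value]], B = B, level = level, seed = seed)$hi
      else NA_real_,
      n = dplyr::n(),
      degenerate = dplyr::n() < 2,
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c("decade", by))))
}
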