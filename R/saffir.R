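#' Saffir-Simpson classification of sustained wind
#'
#' Classifies maximum sustained wind (knots) on the standard National
#' Hurricane Center scale. Thresholds, inclusive on the lower edge:
#' tropical storm at 34 kt, category 1 at 64, 2 at 83, 3 at 96, 4 at 113
#' and 5 at 137 kt.
#'
#' @param max_wind Numeric vector of sustained winds in knots; `NA` yields
#'   `NA` (missing wind has no category).
#' @return An ordered factor with levels
#'   `below_TS < TS < 1 < 2 < 3 < 4 < 5`.
#' @examples
#' classify_category(c(33, 34, 96, 140))
#' @export
classify_category <- function(max_wind) {
  max_wind <- as.numeric(max_wind)
  if (any(!is.na(max_wind) & max_wind < 0)) {
    stop("negative wind speed has no Saffir-Simpson category", call. = FALSE)
  }
  cut(max_wind,
      breaks = c(-Inf, ss_thresholds(), Inf),
      labels = ss_levels(),
      right = FALSE, ordered_result = TRUE)
}

ss_thresholds <- function() c(TS = 34, `1` = 64, `2` = 83, `3` = 96, `4` = 113, `5` = 137)

ss_levels <- function() c("below_TS", "TS", "1", "2", "3", "4", "5")

#' Per-storm lifetime peak wind
#'
#' @param tracks Track-point tibble ([parse_hurdat2()] layout).
#' @return Tibble with one row per storm: `storm_id`, `name`, `year`,
#'   `n_points`, `peak_wind` (knots, max over points with non-missing wind;
#'   `NA` when every point's wind is missing).
#' @export
storm_peak_wind <- function(tracks) {
  tracks |>
    dplyr::group_by(.data$storm_id, .data$name, .data$year) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      peak_wind = if (all(is.na(.data$max_wind))) NA_real_
                  else max(.data$max_wind, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$year, .data$storm_id)
}

#' Tropical-storm-strength filter
#'
#' Flags (or keeps) storms whose lifetime peak sustained wind reaches
#' tropical-storm strength (>= 34 kt). Downstream intersection work assumes
#' tracks have been filtered this way, matching the analysis convention of
#' considering storms of tropical-storm strength or stronger.
#'
#' @param tracks Track-point tibble.
#' @return `is_tropical_storm_or_stronger()`: tibble `storm_id`, `peak_wind`,
#'   `is_ts` (`NA` peak gives `NA`). `filter_tropical_storms()`: the track
#'   tibble restricted to qualifying storms.
#' @export
is_tropical_storm_or_stronger <- function(tracks) {
  storm_peak_wind(tracks) |>
    dplyr::transmute(.data$storm_id, .data$peak_wind,
                     is_ts = .data$peak_wind >= 34)
}

#' @rdname is_tropical_storm_or_stronger
#' @export
filter_tropical_storms <- function(tracks) {
  keep <- is_tropical_storm_or_stronger(tracks)
  keep <- keep$storm_id[!is.na(keep$is_ts) & keep$is_ts]
  dplyr::filter(tracks, .data$storm_id %in% keep)
}
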