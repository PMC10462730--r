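#' Read benthic survey records (long CSV)
#'
#' Reads survey data in long format with columns `site_id`, `date`
#' (ISO date or bare year), `species` (species name or the literal `TOTAL`
#' for absolute total scleractinian cover) and `cover_pct`; an optional
#' `source` column is carried through. Year-only records are assigned a
#' mid-year pseudo-date (1 July) and flagged `year_only` so they skip
#' within-year daily aggregation semantics downstream.
#'
#' @param path CSV path.
#' @return Survey-record tibble: `site_id`, `date` (`Date`), `year`,
#'   `year_only`, `species`, `cover_pct`, `source`.
#' @export
read_surveys <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  req <- c("site_id", "date", "species", "cover_pct")
  missing <- setdiff(req, names(raw))
  if (length(missing)) {
    stop("survey CSV lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  year_only <- grepl("^[0-9]{4}$", raw$date)
  date <- as.Date(ifelse(year_only, paste0(raw$date, "-07-01"), raw$date),
                  format = "%Y-%m-%d")
  if (any(is.na(date))) {
    stop("unparseable survey date: ", raw$date[which(is.na(date))[1]],
         call. = FALSE)
  }
  cover <- as.numeric(raw$cover_pct)
  if (any(is.na(cover) | cover < 0)) {
    stop("cover_pct must be numeric and non-negative", call. = FALSE)
  }
  tibble::tibble(
    site_id = raw$site_id,
    date = date,
    year = as.integer(format(date, "%Y")),
    year_only = year_only,
    species = trimws(raw$species),
    cover_pct = cover,
    source = if ("source" %in% names(raw)) raw$source else NA_character_
  )
}

#' Average replicate surveys to one value per site, day and taxon
#'
#' When more than one survey was made at the same reef on the same day, the
#' covers are arithmetically averaged to a single value per day/location (and
#' taxon). Idempotent: aggregating aggregated data changes nothing.
#'
#' @param records Survey-record tibble (see [read_surveys()]).
#' @return Same layout, one row per `site_id` x `date` x `species`.
#' @export
aggregate_daily <- function(records) {
  records |>
    dplyr::group_by(.data$site_id, .data$date, .data$species) |>
    dplyr::summarise(
      year = .data$year[1],
      year_only = any(.data$year_only),
      cover_pct = mean(.data$cover_pct),
      source = .data$source[1],
      .groups = "drop"
    ) |>
    dplyr::select("site_id", "date", "year", "year_only", "species",
                  "cover_pct", "source")
}

#' Relative cover of a life-history group
#'
#' Relative percent cover = absolute LHG cover / total coral cover x 100.
#' Scale-invariant in the absolute covers; undefined (`NA`) when total cover
#' is zero.
#'
#' @param lhg_abs Absolute percent cover of the group.
#' @param total Total coral percent cover (> 0 for a defined result).
#' @return Relative cover in percent.
#' @examples
#' relative_lhg_cover(4, 10) # 40
#' @export
relative_lhg_cover <- function(lhg_abs, total) {
  out <- lhg_abs / total * 100 # recycles the shorter argument
  out[rep_len(is.na(total) | total <= 0, length(out))] <- NA_real_
  out
}

#' Read a species-to-life-history-group lookup table
#'
#' CSV with columns `species` and `group` (values `competitive`,
#' `stress_tolerant`, `weedy`; anything absent from the table maps to
#' `unclassified`). Matching is case-insensitive after whitespace trimming,
#' so genus-level entries like `"Porites spp."` are honoured as written.
#'
#' @param path CSV path.
#' @return Tibble `species`, `group`.
#' @export
read_lhg_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  stopifnot(all(c("species", "group") %in% names(tbl)))
  bad <- setdiff(unique(tbl$group), lhg_levels())
  if (length(bad)) {
    stop("unknown life-history group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(species = trimws(tbl$species), group = tbl$group)
}

lhg_levels <- function() c("competitive", "stress_tolerant", "weedy", "unclassified")

# total function: unknown species -> "unclassified"
assign_lhg <- function(species, lhg_table) {
  key <- tolower(trimws(species))
  idx <- match(key, tolower(lhg_table$species))
  grp <- lhg_table$group[idx]
  grp[is.na(grp)] <- "unclassified"
  grp
}

#' Site-by-year cover series
#'
#' Collapses daily-aggregated records to one value per site and year (mean of
#' the daily values), for total cover and, when a lookup table is supplied,
#' for each life-history group (absolute and relative cover).
#'
#' Total cover is taken from `TOTAL` rows; for site/dates that carry only
#' per-species covers the total is derived as their sum and flagged
#' (`derived_total`).
#'
#' @param records Survey-record tibble; daily aggregation is applied first
#'   (idempotent).
#' @param lhg_table Optional lookup from [read_lhg_table()].
#' @return With `lhg_table = NULL`: tibble `site_id`, `year`, `total_cover`,
#'   `derived_total`. Otherwise additionally one row per group in long form:
#'   `site_id`, `year`, `group`, `abs_cover`, `rel_cover`, `total_cover`.
#' @export
annual_series <- function(records, lhg_table = NULL) {
  daily <- aggregate_daily(records)

  daily_total <- daily |>
    dplyr::group_by(.data$site_id, .data$date, .data$year) |>
    dplyr::summarise(
      total_cover = if (any(.data$species == "TOTAL"))
        .data$cover_pct[.data$species == "TOTAL"][1]
      else sum(.data$cover_pct),
      derived_total = !any(.data$species == "TOTAL"),
      .groups = "drop"
    )

  totals <- daily_total |>
    dplyr::group_by(.data$site_id, .data$year) |>
    dplyr::summarise(total_cover = mean(.data$total_cover),
                     derived_total = any(.data$derived_total),
                     .groups = "drop") |>
    dplyr::arrange(.data$site_id, .data$year)

  if (is.null(lhg_table)) {
    return(totals)
  }

  by_group <- daily |>
    dplyr::filter(.data$species != "TOTAL") |>
    dplyr::mutate(group = assign_lhg(.data$species, lhg_table)) |>
    dplyr::group_by(.data$site_id, .data$date, .data$year, .data$group) |>
    dplyr::summarise(abs_cover = sum(.data$cover_pct), .groups = "drop") |>
    dplyr::group_by(.data$site_id, .data$year, .data$group) |>
    dplyr::summarise(abs_cover = mean(.data$abs_cover), .groups = "drop") |>
    tidyr::complete(tidyr::nesting(!!rlang::sym("site_id"), !!rlang::sym("year")),
                    group = lhg_levels(), fill = list(abs_cover = 0)) |>
    dplyr::left_join(totals[c("site_id", "year", "total_cover")],
                     by = c("site_id", "year")) |>
    dplyr::mutate(rel_cover = relative_lhg_cover(.data$abs_cover, .data$total_cover)) |>
    dplyr::arrange(.data$site_id, .data$year, .data$group)

  by_group[c("site_id", "year", "group", "abs_cover", "rel_cover", "total_cover")]
}

#' Regional (grouped) annual means with standard errors
#'
#' Basin- or subregion-wide annual average cover across sites, with the
#' standard error of the mean (sd across sites / sqrt(n); `NA` for a single
#' site).
#'
#' @param series Site-year tibble with a `total_cover` column (from
#'   [annual_series()]); any extra grouping columns (e.g. `subregion`) may be
#'   named in `grouping`.
#' @param grouping Character vector of column names to group by, in addition
#'   to `year`.
#' @return Tibble with the grouping columns, `year`, `mean_cover`, `se`, `n`.
#' @export
regional_means <- function(series, grouping = character()) {
  series |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grouping, "year")))) |>
    dplyr::summarise(
      mean_cover = mean(.data$total_cover),
      se = if (dplyr::n() > 1) stats::sd(.data$total_cover) / sqrt(dplyr::n())
           else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}
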