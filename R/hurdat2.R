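#' Parse HURDAT2 best-track text
#'
#' Reads cyclone best-track records in the NOAA HURDAT2 fixed text layout:
#' a header line (`ID, NAME, n_rows,`) followed by `n_rows` six-hourly data
#' lines. Hemisphere suffixes are converted to signed decimal degrees
#' (`W`/`S` negative) and the sentinel values `-99` (wind) and `-999`
#' (pressure) are mapped to `NA`.
#'
#' @param x Path to a HURDAT2 file, or a character vector of lines (a single
#'   string containing newlines is split).
#' @return A tibble with one row per track point and columns `storm_id`,
#'   `name`, `year`, `timestamp` (UTC `POSIXct`), `lat`, `lon` (decimal
#'   degrees, west/south negative), `max_wind` (knots, `NA` if missing),
#'   `min_pressure` (mb, `NA` if missing), `status` (two-letter code) and
#'   `record_id` (single-character landfall/peak flag, `""` if absent).
#' @details Structural problems (malformed header, row-count mismatch,
#'   unparseable coordinates, non-increasing timestamps) abort with the
#'   offending line number. Longitudes are normalised to (-180, 180].
#' @examples
#' txt <- c(
#'   "AL011999,           TEST,      2,",
#'   "19990801, 0000,  , TS, 18.0N,  65.7W,  40, 1000,",
#'   "19990801, 0600,  , TS, 18.5N,  66.2W,  45,  998,"
#' )
#' parse_hurdat2(txt)
#' @export
parse_hurdat2 <- function(x) {
  lines <- if (length(x) == 1 && (file.exists(x) || grepl("\n", x, fixed = TRUE))) {
    if (file.exists(x)) readLines(x, warn = FALSE) else strsplit(x, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(x)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(empty_track_tbl())
  }

  out <- vector("list", 64L)
  n_storms <- 0L
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(lines[[i]], ",", fixed = TRUE)[[1]]
    hdr <- trimws(hdr)
    if (length(hdr) < 3 || !grepl("^[A-Z]{2}[0-9]{6}$", hdr[1])) {
      stop("malformed HURDAT2 header at line ", i, ": ", lines[[i]], call. = FALSE)
    }
    storm_id <- hdr[1]
    name <- hdr[2]
    n_rows <- suppressWarnings(as.integer(hdr[3]))
    if (is.na(n_rows) || n_rows < 1) {
      stop("malformed row count in header at line ", i, call. = FALSE)
    }
    if (i + n_rows > length(lines)) {
      stop("header at line ", i, " declares ", n_rows,
           " rows but the file ends early", call. = FALSE)
    }
    rows <- lines[(i + 1L):(i + n_rows)]
    pts <- parse_hurdat2_rows(rows, first_line = i + 1L)
    if (any(grepl("^[A-Z]{2}[0-9]{6}$", substr(rows, 1, 8)) &
            !grepl("^[0-9]{8}", rows))) {
      stop("row-count mismatch: header at line ", i,
           " overlaps the next storm header", call. = FALSE)
    }
    year <- as.integer(substr(storm_id, 5, 8))
    if (any(diff(as.numeric(pts$timestamp)) <= 0)) {
      bad <- which(diff(as.numeric(pts$timestamp)) <= 0)[1]
      stop("timestamps not strictly increasing for ", storm_id,
           " at line ", i + bad + 1L, call. = FALSE)
    }
    n_storms <- n_storms + 1L
    if (n_storms > length(out)) out <- c(out, vector("list", length(out)))
    out[[n_storms]] <- dplyr::mutate(pts, storm_id = storm_id, name = name,
                                     year = year, .before = 1L)
    i <- i + 1L + n_rows
  }
  tracks <- dplyr::bind_rows(out[seq_len(n_storms)])
  validate_tracks(tracks)
  tracks
}

parse_hurdat2_rows <- function(rows, first_line) {
  fields <- strsplit(rows, ",", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 8)) {
    bad <- which(n_fields < 8)[1]
    stop("data line ", first_line + bad - 1L, " has fewer than 8 fields", call. = FALSE)
  }
  f <- function(k) trimws(vapply(fields, `[[`, "", k))
  date <- f(1); time <- f(2); record_id <- f(3); status <- f(4)
  lat_raw <- f(5); lon_raw <- f(6)
  wind <- suppressWarnings(as.numeric(f(7)))
  pres <- suppressWarnings(as.numeric(f(8)))

  if (any(!grepl("^[0-9]{8}$", date))) {
    bad <- which(!grepl("^[0-9]{8}$", date))[1]
    stop("unparseable date on line ", first_line + bad - 1L, call. = FALSE)
  }
  ts <- as.POSIXct(paste0(date, formatC(time, width = 4, flag = "0")),
                   format = "%Y%m%d%H%M", tz = "UTC")
  lat <- parse_hemisphere(lat_raw, c("N", "S"), first_line)
  lon <- parse_hemisphere(lon_raw, c("E", "W"), first_line)
  lon <- normalize_lon(lon)
  if (any(is.na(ts))) {
    stop("unparseable date/time on line ",
         first_line + which(is.na(ts))[1] - 1L, call. = FALSE)
  }

  tibble::tibble(
    timestamp = ts, lat = lat, lon = lon,
    max_wind = ifelse(!is.na(wind) & wind < 0, NA_real_, wind),
    min_pressure = ifelse(!is.na(pres) & pres < 0, NA_real_, pres),
    status = status, record_id = record_id
  )
}

parse_hemisphere <- function(x, hemis, first_line) {
  suf <- toupper(substr(x, nchar(x), nchar(x)))
  num <- suppressWarnings(as.numeric(substr(x, 1, nchar(x) - 1L)))
  ok <- suf %in% hemis & !is.na(num)
  if (any(!ok)) {
    stop("unparseable coordinate '", x[which(!ok)[1]], "' on line ",
         first_line + which(!ok)[1] - 1L, call. = FALSE)
  }
  num * ifelse(suf %in% c("S", "W"), -1, 1)
}

normalize_lon <- function(lon) {
  lon <- ((lon + 180) %% 360) - 180
  ifelse(lon == -180, 180, lon)
}

validate_tracks <- function(tracks) {
  stopifnot(all(tracks$lat >= -90 & tracks$lat <= 90),
            all(tracks$lon > -180 & tracks$lon <= 180),
            all(is.na(tracks$max_wind) | tracks$max_wind >= 0))
  yr <- as.integer(substr(tracks$storm_id, 5, 8))
  if (!all(yr == tracks$year)) {
    stop("storm_id year does not match the year field", call. = FALSE)
  }
  invisible(tracks)
}

empty_track_tbl <- function() {
  tibble::tibble(
    storm_id = character(), name = character(), year = integer(),
    timestamp = as.POSIXct(character(), tz = "UTC"),
    lat = numeric(), lon = numeric(),
    max_wind = numeric(), min_pressure = numeric(),
    status = character(), record_id = character()
  )
}

#' Write tracks back to HURDAT2 text
#'
#' Serialises a track-point tibble (as returned by [parse_hurdat2()] or
#' [gen_storm_tracks()]) to HURDAT2 fixed text. The round trip
#' `parse_hurdat2(write_hurdat2(x))` reproduces `x` field for field provided
#' coordinates are at the format's 0.1-degree precision and winds/pressures
#' are whole numbers (the precision the format carries).
#'
#' @param tracks Track-point tibble (columns as in [parse_hurdat2()]).
#' @param path Optional file path; when `NULL` the text is returned invisibly
#'   as a character vector of lines.
#' @return The lines, invisibly; written to `path` when given.
#' @export
write_hurdat2 <- function(tracks, path = NULL) {
  if (nrow(tracks) == 0) {
    lines <- character()
  } else {
    lines <- tracks |>
      dplyr::group_by(storm_ord = factor(.data$storm_id,
                                         levels = unique(.data$storm_id))) |>
      dplyr::group_map(function(pts, key) {
        header <- sprintf("%s,%19s,%7d,", pts$storm_id[1], pts$name[1], nrow(pts))
        body <- sprintf(
          "%s, %s, %1s, %2s, %5.1f%s, %6.1f%s, %3d, %4d,",
          format(pts$timestamp, "%Y%m%d", tz = "UTC"),
          format(pts$timestamp, "%H%M", tz = "UTC"),
          pts$record_id, pts$status,
          abs(pts$lat), ifelse(pts$lat >= 0, "N", "S"),
          abs(pts$lon), ifelse(pts$lon >= 0 | pts$lon == -180, "E", "W"),
          as.integer(ifelse(is.na(pts$max_wind), -99, round(pts$max_wind))),
          as.integer(ifelse(is.na(pts$min_pressure), -999, round(pts$min_pressure)))
        )
        c(header, body)
      }, .keep = TRUE) |>
      unlist()
    if (is.null(lines)) lines <- character()
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Validate a HURDAT2 file and summarise its storms
#'
#' Convenience wrapper used to vet a best-track file before analysis: parses
#' it (aborting on structural errors with line numbers) and returns one row
#' per storm with its point count, span and peak intensity.
#'
#' @param path HURDAT2 file path or text.
#' @return Tibble with `storm_id`, `name`, `year`, `n_points`, `peak_wind`,
#'   `category` (Saffir-Simpson class at peak).
#' @export
validate_hurdat2 <- function(path) {
  tracks <- parse_hurdat2(path)
  storm_peak_wind(tracks) |>
    dplyr::mutate(category = classify_category(pmax(.data$peak_wind, 0)))
}
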