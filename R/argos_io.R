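#' Read an Argos location table
#'
#' Parses a delimited text file (or literal text) of Argos fixes into a
#' validated `argos_fixes` data.frame with columns `ptt` (character),
#' `time` (POSIXct, UTC), `lon`, `lat` (decimal degrees WGS84) and `lc`
#' (Argos location class, one of 3, 2, 1, 0, A, B). Row order is
#' preserved.
#'
#' @param source Path to a delimited file, or a character vector of
#'   lines, or a connection.
#' @param col_map Named character vector mapping the canonical names
#'   `ptt`, `date`, `lon`, `lat`, `lc` to the column names used in the
#'   file.
#' @param sep Field separator (default comma).
#' @param date_format `strptime` pattern for the date column; the
#'   default accepts ISO-8601 `"%Y-%m-%dT%H:%M:%S"` and falls back to
#'   `"%Y-%m-%d %H:%M:%S"`.
#' @param allowed_lc Location classes accepted; fixes with any other
#'   class (e.g. "Z") are a row error.
#' @return An `argos_fixes` data.frame.
#' @export
read_argos_table <- function(source,
                             col_map = c(ptt = "ptt", date = "date",
                                         lon = "lon", lat = "lat", lc = "lc"),
                             sep = ",",
                             date_format = "%Y-%m-%dT%H:%M:%S",
                             allowed_lc = LC_LEVELS) {
  need <- c("ptt", "date", "lon", "lat", "lc")
  if (!all(need %in% names(col_map)))
    stop("col_map must name columns for: ", paste(need, collapse = ", "))
  if (is.character(source) && length(source) > 1) {
    tf <- tempfile(fileext = ".csv")
    on.exit(unlink(tf), add = TRUE)
    writeLines(source, tf)
    source <- tf
  }
  raw <- utils::read.table(source, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"")
  missing_cols <- setdiff(unname(col_map[need]), names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0L) return(new_argos_fixes(character(), as_utc(character()),
                                              numeric(), numeric(), character()))
  ptt <- raw[[col_map[["ptt"]]]]
  tm <- as_utc(raw[[col_map[["date"]]]], date_format)
  lon <- suppressWarnings(as.numeric(raw[[col_map[["lon"]]]]))
  lat <- suppressWarnings(as.numeric(raw[[col_map[["lat"]]]]))
  lc <- toupper(trimws(raw[[col_map[["lc"]]]]))
  line_no <- seq_len(nrow(raw)) + 1L   # +1 for the header line
  bad_time <- is.na(tm)
  bad_coord <- is.na(lon) | is.na(lat) | lon < -180 | lon > 180 |
    lat < -90 | lat > 90
  bad_lc <- !(lc %in% allowed_lc)
  if (any(bad_time))
    stop("unparseable timestamp at line(s): ",
         paste(line_no[bad_time], collapse = ", "))
  if (any(bad_coord))
    stop("invalid coordinate at line(s): ",
         paste(line_no[bad_coord], collapse = ", "))
  if (any(bad_lc))
    stop("location class outside {", paste(allowed_lc, collapse = ","),
         "} at line(s): ", paste(line_no[bad_lc], collapse = ", "))
  new_argos_fixes(ptt, tm, lon, lat, lc)
}

as_utc <- function(x, fmt = "%Y-%m-%dT%H:%M:%S") {
  out <- as.POSIXct(x, format = fmt, tz = "UTC")
  alt <- is.na(out) & !is.na(x) & nzchar(x)
  if (any(alt))
    out[alt] <- as.POSIXct(x[alt], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  out
}

new_argos_fixes <- function(ptt, time, lon, lat, lc) {
  df <- data.frame(ptt = as.character(ptt), time = time,
                   lon = lon, lat = lat, lc = as.character(lc),
                   stringsAsFactors = FALSE)
  class(df) <- c("argos_fixes", "data.frame")
  df
}

#' Write Argos fixes as CSV in the dialect `read_argos_table` reads
#'
#' @param fixes An `argos_fixes` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_argos_csv <- function(fixes, path) {
  out <- data.frame(ptt = fixes$ptt,
                    date = format(fixes$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                    lon = sprintf("%.17g", fixes$lon),
                    lat = sprintf("%.17g", fixes$lat),
                    lc = fixes$lc)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble per-platform, time-ordered tracks
#'
#' Splits fixes by PTT and sorts each track by time. Fixes sharing an
#' identical timestamp within a platform are reduced to the one with the
#' best location class (3 > 2 > 1 > 0 > A > B); dropped duplicates are
#' recorded in the `"dropped"` attribute.
#'
#' @param fixes An `argos_fixes` data.frame.
#' @return Named list of `argos_fixes`, one per PTT, each time-sorted.
#' @export
assemble_tracks <- function(fixes) {
  if (nrow(fixes) == 0L) return(setNames(list(), character()))
  dropped_all <- list()
  tracks <- lapply(split(seq_len(nrow(fixes)), fixes$ptt), function(idx) {
    tr <- fixes[idx, , drop = FALSE]
    # order by time, then by lc quality so the best fix comes first per tie
    qual <- match(tr$lc, LC_LEVELS)
    tr <- tr[order(tr$time, qual), , drop = FALSE]
    dup <- duplicated(tr$time)
    dropped <- tr[dup, , drop = FALSE]
    tr <- tr[!dup, , drop = FALSE]
    rownames(tr) <- NULL
    attr(tr, "dropped") <- dropped
    class(tr) <- c("argos_fixes", "data.frame")
    tr
  })
  tracks[order(names(tracks))]
}

#' Split a track into segments at long temporal gaps
#'
#' Inserts a segment boundary between consecutive fixes whose gap
#' strictly exceeds `gap_threshold_days` (the analysis convention for
#' gaps longer than four days). Segments are labelled "a", "b", ... in
#' temporal order.
#'
#' @param track A time-ordered `argos_fixes` data.frame for one PTT.
#' @param gap_threshold_days Gap threshold in days; a boundary is placed
#'   only when the gap is strictly greater.
#' @return List of `track_segment` objects: each a list with `ptt`,
#'   `segment_label`, `fixes` and `duration_days`.
#' @export
split_on_gaps <- function(track, gap_threshold_days = 4) {
  if (nrow(track) == 0L) stop("cannot split an empty track")
  if (is.unsorted(as.numeric(track$time)))
    stop("track must be time-ordered; run assemble_tracks() first")
  gaps_days <- diff(as.numeric(track$time)) / 86400
  seg_id <- cumsum(c(0, gaps_days > gap_threshold_days)) + 1L
  labels <- make_segment_labels(max(seg_id))
  lapply(seq_len(max(seg_id)), function(k) {
    fx <- track[seg_id == k, , drop = FALSE]
    rownames(fx) <- NULL
    class(fx) <- c("argos_fixes", "data.frame")
    new_track_segment(track$ptt[1], labels[k], fx)
  })
}

make_segment_labels <- function(n) {
  stopifnot(n >= 1)
  if (n <= 26) letters[seq_len(n)] else
    paste0(letters[((seq_len(n) - 1) %/% 26)], letters[((seq_len(n) - 1) %% 26) + 1])
}

new_track_segment <- function(ptt, segment_label, fixes) {
  dur <- if (nrow(fixes) > 1)
    as.numeric(difftime(fixes$time[nrow(fixes)], fixes$time[1], units = "days"))
  else 0
  structure(list(ptt = ptt, segment_label = segment_label,
                 fixes = fixes, duration_days = dur),
            class = "track_segment")
}

#' @export
print.track_segment <- function(x, ...) {
  cat(sprintf("<track_segment %s%s: %d fixes, %.1f days>\n",
              x$ptt, x$segment_label, nrow(x$fixes), x$duration_days))
  invisible(x)
}

#' Apply platform exclusion rules
#'
#' Platforms that returned no location fixes at all are excluded with
#' reason `no_locations`; platforms whose total tracked duration is
#' below `min_duration_days` or with fewer than `min_fixes` fixes in
#' total are excluded with reason `too_short`. All segments of every
#' other platform are kept.
#'
#' @param segments List of `track_segment` objects.
#' @param min_duration_days Minimum total tracked duration to keep.
#' @param min_fixes Minimum total number of location fixes to keep.
#' @param all_ptts Optional character vector of every deployed platform,
#'   including those that produced transmissions but no locations
#'   (absent from `segments`); such platforms are reported as
#'   `no_locations`.
#' @return List with `kept` (list of segments) and `excluded`
#'   (data.frame of `ptt`, `reason`).
#' @export
apply_exclusions <- function(segments, min_duration_days = 3,
                             min_fixes = 10, all_ptts = NULL) {
  seg_ptt <- vapply(segments, function(s) s$ptt, character(1))
  have <- unique(seg_ptt)
  no_loc <- setdiff(as.character(all_ptts %||% character()), have)
  tot_dur <- tapply(vapply(segments, function(s) s$duration_days, numeric(1)),
                    seg_ptt, sum)
  tot_fix <- tapply(vapply(segments, function(s) nrow(s$fixes), numeric(1)),
                    seg_ptt, sum)
  too_short <- names(tot_dur)[tot_dur < min_duration_days |
                                tot_fix < min_fixes]
  excluded <- rbind(
    if (length(no_loc)) data.frame(ptt = no_loc, reason = "no_locations"),
    if (length(too_short)) data.frame(ptt = too_short, reason = "too_short")
  )
  if (is.null(excluded))
    excluded <- data.frame(ptt = character(), reason = character())
  kept <- segments[!(seg_ptt %in% excluded$ptt)]
  list(kept = kept, excluded = excluded[order(excluded$ptt), , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export segments as one CSV (one row per fix, with segment label)
#'
#' @param segments List of `track_segment` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments_csv <- function(segments, path) {
  rows <- do.call(rbind, lapply(segments, function(s) {
    data.frame(ptt = s$fixes$ptt,
               segment_label = s$segment_label,
               date = format(s$fixes$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
               lon = s$fixes$lon, lat = s$fixes$lat, lc = s$fixes$lc)
  }))
  utils::write.table(rows, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export segments as GeoJSON LineStrings
#'
#' One LineString feature per segment, with `ptt` and `segment_label`
#' properties.
#'
#' @param segments List of `track_segment` objects.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_segments_geojson <- function(segments, path) {
  feats <- lapply(segments, function(s) {
    list(type = "Feature",
         properties = list(ptt = s$ptt, segment_label = s$segment_label),
         geometry = list(type = "LineString",
                         coordinates = unname(
                           lapply(seq_len(nrow(s$fixes)),
                                  function(i) c(s$fixes$lon[i], s$fixes$lat[i])))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
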