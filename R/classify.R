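#' Classify posterior mean behavioural states
#'
#' Converts posterior mean states `bhat` in \[1, 2\] into labels under
#' conservative cut-offs: `bhat < cutoffs[1]` is transit, `bhat >
#' cutoffs[2]` is ARS, anything in the closed interval (including the
#' boundaries) is uncertain.
#'
#' @param bhat Numeric vector in \[1, 2\].
#' @param cutoffs Length-2 numeric `(lo, hi)` with `1 < lo < hi < 2`.
#' @return Character vector with values `"transit"`, `"ARS"`,
#'   `"uncertain"`.
#' @export
classify_state <- function(bhat, cutoffs = c(1.25, 1.75)) {
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2],
            cutoffs[1] > 1, cutoffs[2] < 2)
  if (any(bhat < 1 | bhat > 2, na.rm = TRUE))
    stop("bhat values must lie in [1, 2]")
  ifelse(bhat < cutoffs[1], "transit",
         ifelse(bhat > cutoffs[2], "ARS", "uncertain"))
}

#' Build per-segment behaviour series from a fitted model
#'
#' @param fit A `posterior_fit`.
#' @param cutoffs Classification cut-offs passed to `classify_state`.
#' @return List of `behaviour_series` data.frames (ptt, segment_label,
#'   state_time, bhat, label).
#' @export
behaviour_series <- function(fit, cutoffs = c(1.25, 1.75)) {
  bh <- behaviour_means(fit)
  lapply(seq_along(fit$segments), function(i) {
    rs <- fit$segments[[i]]
    df <- data.frame(ptt = rs$ptt, segment_label = rs$segment_label,
                     state_time = rs$state_times, bhat = bh[[i]],
                     label = classify_state(bh[[i]], cutoffs),
                     stringsAsFactors = FALSE)
    class(df) <- c("behaviour_series", "data.frame")
    df
  })
}

# Largest-remainder rounding of label counts to integer percentages
# summing exactly to 100; ties in remainder broken by label order.
largest_remainder_pct <- function(counts) {
  total <- sum(counts)
  stopifnot(total > 0)
  shares <- counts / total * 100
  base <- floor(shares)
  need <- 100 - sum(base)
  rem <- shares - base
  ord <- order(-rem, seq_along(counts))
  add <- integer(length(counts))
  if (need > 0) add[ord[seq_len(need)]] <- 1L
  as.integer(base + add)
}

#' Summarise a behaviour series into a Table-style track report
#'
#' Percentages of transit, ARS and uncertain locations, rounded by the
#' largest-remainder rule so the integers sum exactly to 100 (remainder
#' ties broken in the order transit, ARS, uncertain).
#'
#' @param series A `behaviour_series` data.frame (needs `label`; uses
#'   `ptt`, `segment_label`, `state_time` when present).
#' @param days_of_transmission Optional; defaults to the series' time
#'   span in days.
#' @return One-row data.frame: ptt, segment_label, days_of_transmission,
#'   pct_transit, pct_ars, pct_uncertain.
#' @export
summarise_track <- function(series, days_of_transmission = NULL) {
  if (nrow(series) == 0) stop("empty behaviour series")
  counts <- c(transit = sum(series$label == "transit"),
              ARS = sum(series$label == "ARS"),
              uncertain = sum(series$label == "uncertain"))
  pct <- largest_remainder_pct(counts)
  if (is.null(days_of_transmission)) {
    days_of_transmission <- if (!is.null(series$state_time))
      as.numeric(difftime(max(series$state_time), min(series$state_time),
                          units = "days"))
    else NA_real_
  }
  data.frame(ptt = series$ptt[1] %||% NA_character_,
             segment_label = series$segment_label[1] %||% NA_character_,
             days_of_transmission = days_of_transmission,
             pct_transit = pct[1], pct_ars = pct[2], pct_uncertain = pct[3],
             stringsAsFactors = FALSE)
}

#' Pooled behavioural percentages across segments
#'
#' Label counts are pooled over all locations of all listed series and
#' then converted to percentages (pooling, not averaging of per-segment
#' percentages).
#'
#' @param series_list List of `behaviour_series` data.frames.
#' @return List with `pct_transit`, `pct_ars`, `pct_uncertain`
#'   (unrounded percentages) and `n_locations`.
#' @export
pooled_ars_fraction <- function(series_list) {
  if (length(series_list) == 0) stop("at least one series is required")
  if (is.data.frame(series_list)) series_list <- list(series_list)
  labels <- unlist(lapply(series_list, `[[`, "label"))
  n <- length(labels)
  list(pct_transit = 100 * sum(labels == "transit") / n,
       pct_ars = 100 * sum(labels == "ARS") / n,
       pct_uncertain = 100 * sum(labels == "uncertain") / n,
       n_locations = n)
}

#' Write Table-style track reports as CSV
#'
#' @param reports Data frame of rows from `summarise_track`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_track_reports_csv <- function(reports, path) {
  utils::write.table(reports, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
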