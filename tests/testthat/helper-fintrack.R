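# Shared fixtures, built in code.

fix_df <- function(ptt, times, lon, lat, lc) {
  fintrack:::new_argos_fixes(rep_len(ptt, length(times)),
                             as.POSIXct(times, tz = "UTC"),
                             lon, lat, rep_len(lc, length(times)))
}

# Regular daily fixes for one platform starting at a date.
daily_fixes <- function(ptt, start, n_days, lon0 = 8, lat0 = 43, lc = "1") {
  t0 <- as.POSIXct(start, tz = "UTC")
  fix_df(ptt, t0 + (0:(n_days)) * 86400,
         lon0 + 0.05 * (0:n_days), lat0 + 0.02 * (0:n_days), lc)
}

# The eight Pelagos-deployment platforms: durations (days of
# transmission) as decoded from the published tag-performance table;
# one platform produced transmissions but no locations, one lasted
# only two days.
pelagos_deployments <- function() {
  specs <- list(
    list(ptt = "112697", days = 142, gap_after = 60),  # split a/b
    list(ptt = "112716", days = 83,  gap_after = 70),
    list(ptt = "112708", days = 81,  gap_after = 40),
    list(ptt = "112709", days = 2,   gap_after = NA),
    list(ptt = "102223", days = 18,  gap_after = NA),
    list(ptt = "102221", days = 35,  gap_after = NA),
    list(ptt = "102224", days = 22,  gap_after = NA)
  )
  fixes <- do.call(rbind, lapply(specs, function(s) {
    t0 <- as.POSIXct("2012-09-10 00:00:00", tz = "UTC")
    days <- 0:s$days
    if (!is.na(s$gap_after))  # open a >4-day hole to force an a/b split
      days <- setdiff(days, (s$gap_after + 1):(s$gap_after + 5))
    fix_df(s$ptt, t0 + days * 86400, 8 + 0.03 * days, 43 + 0.01 * days, "0")
  }))
  list(fixes = fixes,
       all_ptts = c("112707", vapply(specs, `[[`, "", "ptt")))
}

# Simulate -> observe -> assemble -> regularise, grid-aligned to truth.
sim_regularised <- function(params, n_steps, seed, ptt = "SIM01",
                            origin = c(7.5, 43), rate = 3) {
  tru <- simulate_dcrws(params, n_steps, 12, origin = origin, seed = seed)
  fx <- observe_argos(tru, rate, seed = seed + 1L, ptt = ptt)
  seg <- split_on_gaps(assemble_tracks(fx)[[1]])[[1]]
  list(truth = tru, reg = regularise(seg, 12, origin = tru$times[1]))
}

# True behavioural label at each grid node of an aligned segment.
truth_labels_at_nodes <- function(truth, reg) {
  ni <- round(as.numeric(difftime(reg$state_times, truth$times[1],
                                  units = "hours")) / 12) + 1
  ifelse(ni >= 1 & ni <= length(truth$b),
         ifelse(truth$b[pmin(pmax(ni, 1), length(truth$b))] == 1,
                "transit", "ARS"),
         NA_character_)
}

# Independent gift-wrapping convex hull (oracle for chull-based MBG).
wrap_hull <- function(xy) {
  xy <- unique(xy)
  n <- nrow(xy)
  start <- which.min(xy[, 2] + 1e-9 * xy[, 1])
  h <- start
  repeat {
    p <- h[length(h)]
    cand <- 1
    for (q in 2:n) {
      if (q == p) next
      cr <- (xy[cand, 1] - xy[p, 1]) * (xy[q, 2] - xy[p, 2]) -
        (xy[cand, 2] - xy[p, 2]) * (xy[q, 1] - xy[p, 1])
      if (cand == p || cr < 0) cand <- q
    }
    if (cand == start) break
    h <- c(h, cand)
    if (length(h) > n + 1) stop("hull oracle failed")
  }
  xy[h, , drop = FALSE]
}

shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]; n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# Direct haversine (independent of geosphere), R = 6371 km.
hav_km <- function(lon1, lat1, lon2, lat2) {
  to <- pi / 180
  dlat <- (lat2 - lat1) * to; dlon <- (lon2 - lon1) * to
  a <- sin(dlat / 2)^2 + cos(lat1 * to) * cos(lat2 * to) * sin(dlon / 2)^2
  2 * 6371 * asin(sqrt(pmin(1, a)))
}

# Fabricated posterior_fit with known state samples (for averaging
# tests without running MCMC).
fake_fit_from_b <- function(b_chain_list, n) {
  segs <- list(structure(list(ptt = "X", segment_label = "a",
                              state_times = as.POSIXct("2012-01-01", tz = "UTC") +
                                (seq_len(n) - 1) * 43200,
                              n = n), class = "regularised_segment"))
  structure(list(chains = lapply(b_chain_list,
                                 function(m) list(b = list(m))),
                 segments = segs), class = "posterior_fit")
}
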