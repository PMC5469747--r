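# End-to-end orchestration: a single config drives simulate -> ingest
# -> fit -> classify -> homerange -> habitat -> overlap -> report, with
# a manifest recording the config hash, seed and per-file checksums.

#' Default pipeline configuration
#'
#' @param outdir Output directory for the run.
#' @param seed Global seed (required when any stochastic stage runs).
#' @return A nested config list; override entries before passing to
#'   [run_pipeline()].
#' @export
default_pipeline_config <- function(outdir, seed = 1) {
  list(
    outdir = outdir,
    seed = seed,
    stages = c("simulate", "ingest", "fit", "classify", "homerange",
               "habitat", "overlap", "report"),
    simulate = list(
      n_platforms = 2,
      n_steps = 120,
      step_hours = 12,
      # long ARS bouts and ~2/3 ARS occupancy, emulating the
      # ARS-dominated movement of Mediterranean feeding grounds
      params = dcrws_params(alpha = c(0.9, 0.05)),
      obs_rate_per_day = 3,
      origin = c(7.5, 43.0),
      tag_types = c("transdermal", "LIMPET"),
      scene = list(lon_range = c(4, 11), lat_range = c(40, 45),
                   cell_deg = 0.1, n_days = 90,
                   front = list(lon = 7.0, width_deg = 0.4,
                                chl_low = 0.08, chl_high = 0.45,
                                drift_deg_per_day = 0.01),
                   lanes = list(list(from = c(4.5, 42.2), to = c(10.5, 43.8),
                                     width_cells = 2, value = 380)))),
    ingest = list(gap_threshold_days = 4, min_duration_days = 3,
                  min_fixes = 10),
    fit = list(step_hours = 12,
               mcmc = list(chains = 2, iter = 4000, burn = 3000, thin = 10)),
    classify = list(cutoffs = c(1.25, 1.75)),
    homerange = list(grid_n = 96),
    habitat = list(threshold_km = 7),
    overlap = list(rule = list(type = "quantile", q = 0.9))
  )
}

validate_config <- function(config) {
  if (is.null(config$outdir)) stop("config key missing: outdir")
  stochastic <- intersect(config$stages, c("simulate", "fit"))
  if (length(stochastic) && is.null(config$seed))
    stop("config key missing: seed (required for stages: ",
         paste(stochastic, collapse = ", "), ")")
  if ("habitat" %in% config$stages && !("simulate" %in% config$stages)) {
    if (is.null(config$habitat$scene_dir))
      stop("config key missing: habitat.scene_dir")
    if (!dir.exists(config$habitat$scene_dir))
      stop("config path does not exist: habitat.scene_dir = ",
           config$habitat$scene_dir)
  }
  if ("ingest" %in% config$stages && !("simulate" %in% config$stages)) {
    if (is.null(config$ingest$argos_csv))
      stop("config key missing: ingest.argos_csv")
    if (!file.exists(config$ingest$argos_csv))
      stop("config path does not exist: ingest.argos_csv = ",
           config$ingest$argos_csv)
  }
  invisible(TRUE)
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order on one output directory and
#' writes a manifest (config hash, seed, stage list, per-file md5
#' digests). Identical config and seed reproduce identical digests for
#' the deterministic stages. A stage failure aborts with the failing
#' stage named; outputs of completed stages are retained.
#'
#' @param config Config list as from [default_pipeline_config()].
#' @return The output directory, invisibly; the manifest is
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ran <- character()
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e)
                     stop(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)), call. = FALSE))
    if (ok) ran <<- c(ran, name)
  }

  run_stage("simulate", function() {
    sc <- config$simulate
    fixes_all <- list(); truths <- list()
    for (k in seq_len(sc$n_platforms)) {
      tru <- simulate_dcrws(sc$params, sc$n_steps, sc$step_hours,
                            origin = sc$origin + c(0.3, 0.2) * (k - 1),
                            seed = config$seed + 1000L * k)
      fixes_all[[k]] <- observe_argos(tru, sc$obs_rate_per_day,
                                      seed = config$seed + 1000L * k + 1L,
                                      ptt = sprintf("SIM%02d", k))
      truths[[k]] <- tru
      write_truth(tru, file.path(out, sprintf("truth_SIM%02d.csv", k)))
    }
    write_argos_csv(do.call(rbind, fixes_all), file.path(out, "argos.csv"))
    g <- scene_grid(sc$scene$lon_range, sc$scene$lat_range,
                    sc$scene$cell_deg)
    scene <- simulate_scene(g, front_spec = sc$scene$front,
                            lane_spec = sc$scene$lanes,
                            n_days = sc$scene$n_days,
                            seed = config$seed + 77L)
    write_scene(scene, file.path(out, "scene"))
    state$scene <- scene
    state$tag_types <- rep_len(sc$tag_types, sc$n_platforms)
  })

  run_stage("ingest", function() {
    csv <- config$ingest$argos_csv %||% file.path(out, "argos.csv")
    fixes <- read_argos_table(csv)
    tracks <- assemble_tracks(fixes)
    segs <- unlist(lapply(tracks, split_on_gaps,
                          gap_threshold_days = config$ingest$gap_threshold_days),
                   recursive = FALSE)
    excl <- apply_exclusions(segs, config$ingest$min_duration_days,
                             config$ingest$min_fixes,
                             all_ptts = names(tracks))
    write_segments_csv(excl$kept, file.path(out, "segments.csv"))
    jsonlite::write_json(excl$excluded, file.path(out, "excluded.json"),
                         auto_unbox = TRUE, digits = NA)
    state$kept <- excl$kept
  })

  run_stage("fit", function() {
    regs <- lapply(state$kept, regularise,
                   step_hours = config$fit$step_hours)
    mc <- utils::modifyList(config$fit$mcmc, list(seed = config$seed))
    fit <- fit_hssm(regs, mcmc = mc)
    write_fit_csv(fit, file.path(out, "posterior_locations.csv"))
    write_fit_json(fit, file.path(out, "posterior_parameters.json"))
    state$fit <- fit
  })

  run_stage("classify", function() {
    series <- behaviour_series(state$fit, config$classify$cutoffs)
    reports <- do.call(rbind, lapply(series, summarise_track))
    write_track_reports_csv(reports, file.path(out, "track_reports.csv"))
    pooled <- pooled_ars_fraction(series)
    jsonlite::write_json(pooled, file.path(out, "pooled_behaviour.json"),
                         auto_unbox = TRUE, digits = NA)
    state$series <- series
    state$reports <- reports
  })

  run_stage("homerange", function() {
    locs <- do.call(rbind, posterior_locations(state$fit))
    mbg <- minimum_bounding_geometry(locs[, c("lon", "lat")])
    ud <- kde_ud(locs[, c("lon", "lat")],
                 grid_n = config$homerange$grid_n)
    home <- home_ranges(ud)
    write_ud_grid(ud, file.path(out, "ud.tsv"))
    write_home_ranges_geojson(home, file.path(out, "home_ranges.geojson"))
    jsonlite::write_json(
      list(mbg_area_km2 = mbg$area_km2,
           chr_area_km2 = home$chr$area_km2,
           thr_area_km2 = home$thr$area_km2),
      file.path(out, "homerange.json"), auto_unbox = TRUE, digits = NA)
    state$home <- home
    state$mbg <- mbg
    state$locs <- locs
  })

  run_stage("habitat", function() {
    scene <- state$scene %||% read_scene(config$habitat$scene_dir)
    stack <- habitat_stack(scene)
    pos <- daily_positions(state$locs)
    day0 <- min(pos$day)
    pos$day <- as.integer(pos$day - day0) + 1L
    pos <- pos[pos$day %in% stack$days, , drop = FALSE]
    prox <- distance_to_habitat(pos, stack,
                                threshold_km = config$habitat$threshold_km)
    jsonlite::write_json(
      list(fraction_within = prox$fraction_within,
           threshold_km = prox$threshold_km, n = prox$n,
           n_missing = prox$n_missing),
      file.path(out, "proximity.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(prox$positions, file.path(out, "proximity.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    state$prox <- prox
  })

  run_stage("overlap", function() {
    scene <- state$scene %||% read_scene(config$habitat$scene_dir)
    ht <- extract_high_traffic(scene, state$mbg, config$overlap$rule)
    rep <- overlap_percentages(state$home, ht, state$mbg)
    write_overlap_json(rep, file.path(out, "overlap.json"))
    state$overlap <- rep
  })

  # manifest: config hash + checksums of every output file
  cfgfile <- file.path(out, "config.json")
  jsonlite::write_json(config_echo(config), cfgfile, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  files <- setdiff(list.files(out, recursive = TRUE), "manifest.json")
  digests <- tools::md5sum(file.path(out, files))
  names(digests) <- files
  jsonlite::write_json(
    list(config_md5 = unname(tools::md5sum(cfgfile)),
         seed = config$seed, stages = ran,
         package_version = as.character(utils::packageVersion("fintrack")),
         files = as.list(digests)),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)

  run_stage("report", function() {
    rep <- pipeline_report(out, tag_types = state$tag_types)
    writeLines(rep$text, file.path(out, "report.txt"))
  })
  invisible(out)
}

# JSON-serialisable view of the config (dcrws_params flattened; the
# output directory is not part of the scientific configuration, so it
# is excluded and identical runs in different directories hash alike).
config_echo <- function(config) {
  config$outdir <- NULL
  if (!is.null(config$simulate$params)) {
    p <- config$simulate$params
    config$simulate$params <- list(gamma = p$gamma, theta = p$theta,
                                   alpha = p$alpha, Sigma = p$Sigma)
  }
  config
}

#' Mean and sample SD of tag durations
#'
#' Sample (n - 1 denominator) standard deviation; SD is NA for a
#' single duration.
#'
#' @param durations Numeric vector of days.
#' @return List with `mean`, `sd`, `n`.
#' @export
duration_summary <- function(durations) {
  list(mean = mean(durations),
       sd = if (length(durations) > 1) stats::sd(durations) else NA_real_,
       n = length(durations))
}

#' Human-readable run summary
#'
#' Re-reads the outputs of a run directory and assembles the per-tag
#' behavioural table, the pooled ARS fraction, mean/SD of transmission
#' durations by tag type and, when present, proximity and overlap
#' summaries. Missing stage outputs are listed as absent, not fatal.
#' Re-running on the same directory is idempotent.
#'
#' @param run_dir A directory produced by [run_pipeline()].
#' @param tag_types Optional character vector (or named by PTT) of tag
#'   types for the duration summaries.
#' @return List with `tracks` (data.frame or NULL), `pooled`,
#'   `durations_by_type`, `proximity`, `overlap`, `absent` and `text`
#'   (printable lines).
#' @export
pipeline_report <- function(run_dir, tag_types = NULL) {
  absent <- character()
  grab <- function(file, reader) {
    p <- file.path(run_dir, file)
    if (!file.exists(p)) { absent <<- c(absent, file); return(NULL) }
    reader(p)
  }
  tracks <- grab("track_reports.csv",
                 function(p) utils::read.table(p, header = TRUE, sep = ","))
  pooled <- grab("pooled_behaviour.json",
                 function(p) jsonlite::read_json(p, simplifyVector = TRUE))
  prox <- grab("proximity.json",
               function(p) jsonlite::read_json(p, simplifyVector = TRUE))
  ovl <- grab("overlap.json",
              function(p) jsonlite::read_json(p, simplifyVector = TRUE))

  lines <- c("== fintrack run summary ==")
  durations_by_type <- NULL
  if (!is.null(tracks)) {
    tracks$ptt <- as.character(tracks$ptt)
    per_tag <- stats::aggregate(days_of_transmission ~ ptt, tracks, sum)
    if (!is.null(tag_types)) {
      tt <- if (!is.null(names(tag_types)))
        tag_types[per_tag$ptt] else rep_len(tag_types, nrow(per_tag))
      durations_by_type <- lapply(split(per_tag$days_of_transmission, tt),
                                  duration_summary)
      for (ty in names(durations_by_type)) {
        d <- durations_by_type[[ty]]
        lines <- c(lines, sprintf(
          "%s tags: mean duration %.1f days, SD %s (n=%d)", ty, d$mean,
          if (is.na(d$sd)) "not applicable" else sprintf("%.1f", d$sd), d$n))
      }
    }
    lines <- c(lines, "per-segment behaviour (%):",
               sprintf("  %s%s: %d days, transit %d / ARS %d / uncertain %d",
                       tracks$ptt, tracks$segment_label,
                       round(tracks$days_of_transmission),
                       tracks$pct_transit, tracks$pct_ars,
                       tracks$pct_uncertain))
  }
  if (!is.null(pooled))
    lines <- c(lines, sprintf("pooled: ARS %.1f%%, transit %.1f%%, uncertain %.1f%% (n=%d)",
                              pooled$pct_ars, pooled$pct_transit,
                              pooled$pct_uncertain, pooled$n_locations))
  if (!is.null(prox))
    lines <- c(lines, sprintf("habitat proximity: %.1f%% of %d positions within %g km",
                              100 * prox$fraction_within, prox$n,
                              prox$threshold_km))
  if (!is.null(ovl))
    lines <- c(lines, sprintf("traffic overlap: THR %.1f%%, CHR %.1f%%",
                              ovl$pct_thr, ovl$pct_chr))
  if (length(absent))
    lines <- c(lines, paste("absent outputs:", paste(absent, collapse = ", ")))
  list(tracks = tracks, pooled = pooled,
       durations_by_type = durations_by_type,
       proximity = prox, overlap = ovl, absent = absent, text = lines)
}
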