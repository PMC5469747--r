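#' Construct and validate switching-CRW model parameters
#'
#' Parameters of the two-state switching first-difference correlated
#' random walk: per-state move persistence `gamma` (state 1 = transit
#' must exceed state 2 = ARS), mean turning angles `theta` (radians),
#' switching probabilities `alpha` (`alpha[k]` = P(b_t = 1 | b_(t-1) =
#' k)), process covariance `Sigma` (degrees^2) and a per-location-class
#' Student-t observation error table.
#'
#' @param gamma Numeric pair in (0,1), `gamma[1] > gamma[2]`.
#' @param theta Numeric pair in (-pi, pi].
#' @param alpha Numeric pair in (0,1] (1 = an absorbing state, useful
#'   for degenerate single-state simulations).
#' @param Sigma 2x2 symmetric positive-definite matrix (degrees^2).
#' @param error_table Data frame with columns `lc`, `tau`, `nu`.
#' @return A `dcrws_params` object.
#' @export
dcrws_params <- function(gamma = c(0.85, 0.15),
                         theta = c(0, pi),
                         alpha = c(0.9, 0.3),
                         Sigma = diag(c(0.1, 0.1)^2),
                         error_table = default_error_table()) {
  Sigma <- unname(as.matrix(Sigma))
  stopifnot(length(gamma) == 2, all(gamma > 0), all(gamma < 1),
            length(theta) == 2, all(theta > -pi), all(theta <= pi),
            length(alpha) == 2, all(alpha > 0), all(alpha <= 1),
            all(dim(Sigma) == 2), isTRUE(all.equal(Sigma[1, 2], Sigma[2, 1])))
  if (gamma[1] <= gamma[2])
    stop("identifiability requires gamma[1] (transit) > gamma[2] (ARS)")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("Sigma must be positive-definite")
  if (any(error_table$tau <= 0)) stop("all tau must be positive")
  if (any(error_table$nu <= 1)) stop("all nu must exceed 1")
  structure(list(gamma = gamma, theta = theta, alpha = alpha,
                 Sigma = Sigma, error_table = error_table),
            class = "dcrws_params")
}

#' 2x2 rotation matrix for a turning angle
#'
#' @param theta Angle in radians (counter-clockwise).
#' @return Orthonormal 2x2 matrix with determinant 1.
#' @export
rotation <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Expected next location under the first-difference CRW
#'
#' `E[x_(t+1)] = x_t + gamma_k T(theta_k) (x_t - x_prev)` for
#' behavioural state `k`.
#'
#' @param x_t,x_prev Length-2 numeric locations (degrees).
#' @param state Behavioural state, 1 (transit) or 2 (ARS).
#' @param params A `dcrws_params` object.
#' @return Length-2 numeric expected location.
#' @export
process_mean <- function(x_t, x_prev, state, params) {
  stopifnot(state %in% c(1, 2))
  as.numeric(x_t + params$gamma[state] *
               rotation(params$theta[state]) %*% (x_t - x_prev))
}

#' Observation log-likelihood of an Argos fix
#'
#' The fix position is modelled as the within-interval linear
#' interpolation of the bracketing latent locations plus independent
#' per-coordinate Student-t noise with class-specific scale `tau` and
#' degrees of freedom `nu`.
#'
#' @param fix One-row `argos_fixes` data.frame (or list with `lon`,
#'   `lat`, `lc`).
#' @param interp_loc Length-2 interpolated latent location (degrees).
#' @param params A `dcrws_params` object (supplies the error table).
#' @return Log-density (finite real).
#' @export
obs_loglik <- function(fix, interp_loc, params) {
  et <- params$error_table
  row <- match(as.character(fix$lc), et$lc)
  if (is.na(row)) stop("unknown location class: ", fix$lc)
  tau <- et$tau[row]; nu <- et$nu[row]
  r <- c(fix$lon - interp_loc[1], fix$lat - interp_loc[2]) / tau
  sum(stats::dt(r, df = nu, log = TRUE) - log(tau))
}

#' Regularise a track segment onto an even time grid
#'
#' Builds the discrete state grid of the state-space model: equally
#' spaced node times spanning the segment, and for every fix the node
#' interval it falls in together with its fractional position
#' `j = (time - node_time) / step` in `[0, 1)`.
#'
#' @param segment A `track_segment`.
#' @param step_hours Regular state interval in hours (default 12).
#' @param origin Grid anchor time (POSIXct, not after the first fix).
#'   The default anchors at the last UTC step boundary at or before the
#'   first fix (00:00, 12:00, ... for the 12-h step), so state
#'   intervals are canonical rather than tied to the arbitrary arrival
#'   time of the first fix.
#' @return A `regularised_segment` object.
#' @export
regularise <- function(segment, step_hours = 12, origin = NULL) {
  fx <- segment$fixes
  t0 <- origin %||% as.POSIXct(
    floor(as.numeric(fx$time[1]) / (step_hours * 3600)) *
      step_hours * 3600,
    tz = "UTC", origin = "1970-01-01")
  if (t0 > fx$time[1]) stop("origin must not be after the first fix")
  span_h <- as.numeric(difftime(fx$time[nrow(fx)], t0, units = "hours"))
  if (span_h < 2 * step_hours)
    stop(sprintf("segment %s%s too short to regularise (%.1f h < 2 steps)",
                 segment$ptt, segment$segment_label, span_h))
  n <- ceiling(span_h / step_hours - 1e-9) + 1L
  state_times <- t0 + (seq_len(n) - 1) * step_hours * 3600
  u <- as.numeric(difftime(fx$time, t0, units = "hours")) / step_hours
  t_idx <- pmin(floor(u) + 1L, n)
  j <- u - (t_idx - 1L)
  j[t_idx == n] <- 0
  structure(list(ptt = segment$ptt, segment_label = segment$segment_label,
                 step_hours = step_hours, state_times = state_times,
                 n = n, fixes = fx, t_idx = as.integer(t_idx), j = j),
            class = "regularised_segment")
}

#' @export
print.regularised_segment <- function(x, ...) {
  cat(sprintf("<regularised_segment %s%s: %d nodes at %g h, %d fixes>\n",
              x$ptt, x$segment_label, x$n, x$step_hours, nrow(x$fixes)))
  invisible(x)
}

#' Fit the hierarchical switching state-space model
#'
#' Fits the two-state switching first-difference correlated random walk
#' to one or more regularised segments by Metropolis-within-Gibbs MCMC.
#' Movement parameters (gamma, theta, alpha, Sigma) are pooled across
#' all segments (the hierarchical sharing that lets short tracks borrow
#' strength from long ones); latent locations and behavioural states
#' are sampled per segment. Identical seed and configuration give
#' bit-identical output.
#'
#' @param segments List of `regularised_segment` objects.
#' @param priors List with `sigma0` (half-normal scale for the process
#'   noise SDs, degrees), `theta1_max` (half-width of the uniform prior
#'   on the transit turning angle) and `gamma1_shape` / `gamma2_shape`
#'   (Beta shape pairs for the persistence priors, truncated to the
#'   gamma1 > gamma2 ordering). The weakly-informative defaults --
#'   transit persistent, ARS not -- keep the two states identified even
#'   when a track contains a single regime; set both to `c(1, 1)` for
#'   flat priors.
#' @param mcmc List with `chains` (>= 2), `iter` (post-burn-in
#'   iterations per chain), `burn`, `thin`, `seed`.
#' @param error_table Per-class Student-t observation error table; the
#'   default equals the synthetic generator's table.
#' @return A `posterior_fit` object: per-chain parameter samples,
#'   per-segment latent location and state samples, diagnostics
#'   (split-Rhat, effective sample size) and a config echo.
#' @export
fit_hssm <- function(segments,
                     priors = list(sigma0 = 1, theta1_max = pi / 4,
                                   gamma1_shape = c(5, 2),
                                   gamma2_shape = c(2, 5)),
                     mcmc = list(chains = 2, iter = 10000, burn = 5000,
                                 thin = 10, seed = 1),
                     error_table = default_error_table()) {
  if (length(segments) == 0) stop("at least one segment is required")
  stopifnot(all(vapply(segments, inherits, logical(1), "regularised_segment")))
  mcmc <- utils::modifyList(list(chains = 2, iter = 10000, burn = 5000,
                                 thin = 10, seed = 1), mcmc)
  priors <- utils::modifyList(list(sigma0 = 1, theta1_max = pi / 4,
                                   gamma1_shape = c(5, 2),
                                   gamma2_shape = c(2, 5)), priors)
  if (mcmc$chains < 2) stop("mcmc$chains must be >= 2")

  seg_data <- lapply(segments, function(rs) {
    fx <- rs$fixes
    row <- match(fx$lc, error_table$lc)
    if (anyNA(row))
      stop("location class missing from error table: ",
           paste(unique(fx$lc[is.na(row)]), collapse = ", "))
    # initial latent path: linear interpolation of fixes onto the grid
    tt <- as.numeric(fx$time)
    gt <- as.numeric(rs$state_times)
    x0 <- cbind(stats::approx(tt, fx$lon, xout = gt, rule = 2)$y,
                stats::approx(tt, fx$lat, xout = gt, rule = 2)$y)
    if (!all(is.finite(x0))) stop("non-finite initial latent path")
    list(n = rs$n, y = cbind(fx$lon, fx$lat),
         oidx = rs$t_idx - 1L, oj = rs$j,
         otau = error_table$tau[row], onu = error_table$nu[row],
         x0 = x0)
  })

  set.seed(mcmc$seed)
  chains <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    init <- c(gamma1 = min(0.98, 0.7 + runif(1, -0.1, 0.15)),
              gamma2 = max(0.02, 0.3 + runif(1, -0.15, 0.1)),
              theta1 = runif(1, -0.2, 0.2),
              theta2 = runif(1, -3, 3),
              alpha1 = runif(1, 0.6, 0.95),
              alpha2 = runif(1, 0.05, 0.4),
              sigma_lon = exp(runif(1, log(0.03), log(0.3))),
              sigma_lat = exp(runif(1, log(0.03), log(0.3))),
              rho = 0)
    chains[[ch]] <- dcrws_mcmc_chain(seg_data, unname(init), priors,
                                     as.integer(mcmc$burn),
                                     as.integer(mcmc$iter),
                                     as.integer(mcmc$thin))
  }

  par_mats <- lapply(chains, `[[`, "params")
  diag <- mcmc_diagnostics(par_mats)
  structure(list(
    chains = chains,
    segments = segments,
    par_samples = do.call(rbind, par_mats),
    par_chains = par_mats,
    diagnostics = diag,
    config = list(priors = priors, mcmc = mcmc, error_table = error_table)
  ), class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("<posterior_fit: %d segments, %d chains x %d retained draws>\n",
              length(x$segments), length(x$par_chains),
              nrow(x$par_chains[[1]])))
  print(round(posterior_parameters(x), 4))
  invisible(x)
}

#' Posterior parameter summary
#'
#' @param fit A `posterior_fit`.
#' @param probs Quantiles to report.
#' @return Matrix: one row per pooled parameter with posterior mean,
#'   quantiles, split-Rhat and effective sample size.
#' @export
posterior_parameters <- function(fit, probs = c(0.05, 0.5, 0.95)) {
  sm <- fit$par_samples
  out <- cbind(mean = colMeans(sm),
               t(apply(sm, 2, stats::quantile, probs = probs)),
               rhat = fit$diagnostics$rhat,
               ess = fit$diagnostics$ess)
  out
}

#' Posterior mean behavioural state per state-time
#'
#' `bhat_t` is the average of the sampled states (1 = transit, 2 = ARS)
#' across all retained iterations and chains, so lies in \[1, 2\].
#'
#' @param fit A `posterior_fit`.
#' @return List (one element per segment) of numeric vectors.
#' @export
behaviour_means <- function(fit) {
  lapply(seq_along(fit$segments), function(i) {
    bs <- do.call(rbind, lapply(fit$chains, function(ch) ch$b[[i]]))
    colMeans(bs)
  })
}

#' Posterior location summary per segment
#'
#' @param fit A `posterior_fit`.
#' @param probs Credible-bound quantiles.
#' @return List of data.frames: per state-time posterior mean lon/lat,
#'   credible bounds and mean behavioural state.
#' @export
posterior_locations <- function(fit, probs = c(0.05, 0.95)) {
  bh <- behaviour_means(fit)
  lapply(seq_along(fit$segments), function(i) {
    rs <- fit$segments[[i]]
    xs <- do.call(rbind, lapply(fit$chains, function(ch) ch$x[[i]]))
    n <- rs$n
    lon <- xs[, seq_len(n), drop = FALSE]
    lat <- xs[, n + seq_len(n), drop = FALSE]
    data.frame(
      ptt = rs$ptt, segment_label = rs$segment_label,
      state_time = rs$state_times,
      lon = colMeans(lon), lat = colMeans(lat),
      lon_lo = apply(lon, 2, stats::quantile, probs[1]),
      lon_hi = apply(lon, 2, stats::quantile, probs[2]),
      lat_lo = apply(lat, 2, stats::quantile, probs[1]),
      lat_hi = apply(lat, 2, stats::quantile, probs[2]),
      bhat = bh[[i]])
  })
}

#' Export posterior location summaries as CSV
#'
#' @param fit A `posterior_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fit_csv <- function(fit, path) {
  tab <- do.call(rbind, posterior_locations(fit))
  tab$state_time <- format(tab$state_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export fitted parameters and diagnostics as JSON
#'
#' @param fit A `posterior_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  ps <- posterior_parameters(fit)
  jsonlite::write_json(list(
    parameters = as.data.frame(cbind(parameter = rownames(ps),
                                     as.data.frame(ps))),
    mcmc = fit$config$mcmc,
    priors = fit$config$priors
  ), path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' Export per-iteration location clouds as GeoJSON MultiPoint
#'
#' One MultiPoint feature per state-time of the chosen segment,
#' containing the retained posterior draws of that location.
#'
#' @param fit A `posterior_fit`.
#' @param segment Segment index.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_location_cloud_geojson <- function(fit, segment, path) {
  rs <- fit$segments[[segment]]
  xs <- do.call(rbind, lapply(fit$chains, function(ch) ch$x[[segment]]))
  n <- rs$n
  feats <- lapply(seq_len(n), function(t) {
    pts <- lapply(seq_len(nrow(xs)),
                  function(k) c(xs[k, t], xs[k, n + t]))
    list(type = "Feature",
         properties = list(ptt = rs$ptt, node = t),
         geometry = list(type = "MultiPoint", coordinates = unname(pts)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
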