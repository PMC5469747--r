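test_that("regularise builds the grid and interval mapping of the examples", {
  t0 <- as.POSIXct("2012-09-10 00:00:00", tz = "UTC")
  seg <- fintrack:::new_track_segment(
    "P", "a", fix_df("P", t0 + c(0, 5, 24) * 3600, 1:3, 1:3, "1"))
  rs <- regularise(seg, 12)
  expect_equal(rs$n, 3)
  expect_equal(rs$t_idx[3], 3)       # final fix sits on the last node
  expect_equal(rs$j[3], 0)
  expect_equal(rs$t_idx[2], 1)       # fix at 5 h: first interval
  expect_equal(rs$j[2], 5 / 12)

  short <- fintrack:::new_track_segment(
    "P", "a", fix_df("P", t0 + c(0, 10) * 3600, 1:2, 1:2, "1"))
  expect_error(regularise(short, 12), "Pa too short")
})

test_that("regularise interval mapping matches a linear scan oracle", {
  tru <- simulate_dcrws(dcrws_params(), 50, 12, seed = 21)
  fx <- observe_argos(tru, 4, seed = 22, ptt = "S")
  seg <- split_on_gaps(assemble_tracks(fx)[[1]])[[1]]
  rs <- regularise(seg, 12)
  gt <- as.numeric(rs$state_times)
  for (i in seq_len(nrow(rs$fixes))) {
    ti <- as.numeric(rs$fixes$time[i])
    # brute-force: last node not after the fix
    k <- max(which(gt <= ti + 1e-6))
    expect_equal(rs$t_idx[i], k)
    expect_equal(rs$j[i], (ti - gt[k]) / (12 * 3600), tolerance = 1e-9)
    expect_true(rs$j[i] >= 0 && rs$j[i] < 1 || (rs$t_idx[i] == rs$n && rs$j[i] == 0))
  }
})

test_that("rotation matrices are orthonormal and compose additively", {
  expect_equal(rotation(0), diag(2))
  expect_equal(rotation(pi / 2), matrix(c(0, 1, -1, 0), 2, 2))
  set.seed(3)
  for (i in 1:100) {
    a <- runif(1, -pi, pi); b <- runif(1, -pi, pi)
    expect_equal(rotation(a) %*% rotation(b), rotation(a + b),
                 tolerance = 1e-12)
    expect_equal(det(rotation(a)), 1, tolerance = 1e-12)
  }
})

test_that("process_mean reproduces the first-difference CRW expectation", {
  p0 <- dcrws_params(gamma = c(0.9, 1e-9), theta = c(0, 0))
  expect_equal(process_mean(c(3, 4), c(1, 1), 2, p0), c(3, 4),
               tolerance = 1e-6)                     # gamma ~ 0: random walk
  p1 <- dcrws_params(gamma = c(1 - 1e-12, 0.5), theta = c(0, 0))
  expect_equal(process_mean(c(1, 1), c(0, 0), 1, p1), c(2, 2),
               tolerance = 1e-9)                     # straight continuation
  set.seed(8)
  for (i in 1:20) {
    g <- sort(runif(2))[2:1]; th <- runif(2, -pi, pi)
    p <- dcrws_params(gamma = g, theta = th)
    xt <- rnorm(2); xp <- rnorm(2); k <- sample(1:2, 1)
    d <- xt - xp
    manual <- xt + g[k] * c(cos(th[k]) * d[1] - sin(th[k]) * d[2],
                            sin(th[k]) * d[1] + cos(th[k]) * d[2])
    expect_equal(process_mean(xt, xp, k, p), manual, tolerance = 1e-12)
  }
})

test_that("obs_loglik matches an independently coded t density and is symmetric", {
  p <- dcrws_params()
  et <- p$error_table
  # hand-coded scaled-t log density via lgamma
  ldt <- function(r, tau, nu)
    lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi) - log(tau) -
    (nu + 1) / 2 * log(1 + (r / tau)^2 / nu)
  fx0 <- list(lon = 5, lat = 43, lc = "B")
  i <- match("B", et$lc)
  expect_equal(obs_loglik(fx0, c(5, 43), p),
               2 * ldt(0, et$tau[i], et$nu[i]), tolerance = 1e-12)
  set.seed(12)
  for (k in 1:50) {
    lc <- sample(et$lc, 1); i <- match(lc, et$lc)
    r <- rnorm(2, 0, 0.3); loc <- c(runif(1, 0, 10), runif(1, 35, 45))
    fx <- list(lon = loc[1] + r[1], lat = loc[2] + r[2], lc = lc)
    expect_equal(obs_loglik(fx, loc, p),
                 ldt(r[1], et$tau[i], et$nu[i]) + ldt(r[2], et$tau[i], et$nu[i]),
                 tolerance = 1e-10)
    fx_neg <- list(lon = loc[1] - r[1], lat = loc[2] - r[2], lc = lc)
    expect_equal(obs_loglik(fx, loc, p), obs_loglik(fx_neg, loc, p))
  }
  expect_error(obs_loglik(list(lon = 1, lat = 1, lc = "Z"), c(1, 1), p),
               "unknown location class")
})

test_that("behaviour_means averages sampled states across chains and iterations", {
  all1 <- matrix(1L, 10, 6)
  expect_equal(behaviour_means(fake_fit_from_b(list(all1, all1), 6))[[1]],
               rep(1, 6))
  half <- rbind(matrix(1L, 5, 6), matrix(2L, 5, 6))
  expect_equal(behaviour_means(fake_fit_from_b(list(half, half), 6))[[1]],
               rep(1.5, 6))
  set.seed(4)
  b1 <- matrix(sample(1:2, 80, TRUE), 20, 4)
  b2 <- matrix(sample(1:2, 80, TRUE), 20, 4)
  expect_equal(behaviour_means(fake_fit_from_b(list(b1, b2), 4))[[1]],
               colMeans(rbind(b1, b2)))
})

test_that("fit_hssm is deterministic under a fixed seed and config", {
  sr <- sim_regularised(dcrws_params(), 40, seed = 31)
  mc <- list(chains = 2, iter = 300, burn = 300, thin = 10, seed = 9)
  f1 <- fit_hssm(list(sr$reg), mcmc = mc)
  f2 <- fit_hssm(list(sr$reg), mcmc = mc)
  expect_identical(f1$par_samples, f2$par_samples)
  expect_identical(behaviour_means(f1), behaviour_means(f2))
  expect_error(fit_hssm(list()), "at least one segment")
})

test_that("a single-state (absorbing transit) simulation is decoded as transit", {
  p <- dcrws_params(alpha = c(1, 0.999))   # never leaves state 1
  srs <- lapply(1:3, function(k)
    sim_regularised(p, 150, seed = 400 + k, ptt = sprintf("S%d", k),
                    origin = c(6 + k, 42)))
  fit <- fit_hssm(lapply(srs, `[[`, "reg"),
                  mcmc = list(chains = 2, iter = 3000, burn = 3000,
                              thin = 10, seed = 2))
  for (bh in behaviour_means(fit)) {
    interior <- bh[2:(length(bh) - 1)]
    expect_gte(mean(interior < 1.25), 0.95)
  }
})

test_that("sampled state sequences are consistent with sampled alpha", {
  # chain validity: empirical transition frequencies from the posterior
  # b draws should track the sampled switching probabilities
  sr <- sim_regularised(dcrws_params(), 120, seed = 51)
  fit <- fit_hssm(list(sr$reg),
                  mcmc = list(chains = 2, iter = 2000, burn = 2000,
                              thin = 10, seed = 3))
  bs <- do.call(rbind, lapply(fit$chains, function(ch) ch$b[[1]]))
  n <- ncol(bs)
  from1 <- bs[, 2:(n - 2)] == 1
  to1 <- bs[, 3:(n - 1)] == 1
  emp_a1 <- sum(to1 & from1) / sum(from1)
  post_a1 <- mean(fit$par_samples[, "alpha1"])
  se <- sqrt(post_a1 * (1 - post_a1) / sum(from1)) + 0.05
  expect_lt(abs(emp_a1 - post_a1), 4 * se + 0.05)
})

test_that("pooled posteriors are unchanged by segment order up to Monte Carlo noise", {
  p <- dcrws_params()
  srs <- lapply(c(61, 62), function(s) sim_regularised(p, 60, seed = s))
  regs <- lapply(srs, `[[`, "reg")
  mc <- list(chains = 2, iter = 1500, burn = 1500, thin = 10, seed = 5)
  fa <- fit_hssm(regs, mcmc = mc)
  fb <- fit_hssm(rev(regs), mcmc = mc)
  ma <- colMeans(fa$par_samples); mb <- colMeans(fb$par_samples)
  for (nm in c("gamma1", "alpha1", "sigma_lon", "sigma_lat"))
    expect_lt(abs(ma[nm] - mb[nm]), 0.1)
})
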