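test_that("minimum bounding geometry is the convex hull of the positions", {
  sq <- cbind(lon = c(5, 5.5, 5.5, 5), lat = c(43, 43, 43.4, 43.4))
  mbg <- minimum_bounding_geometry(sq)
  expect_equal(nrow(mbg$lonlat), 4)
  expect_setequal(paste(mbg$lonlat[, 1], mbg$lonlat[, 2]),
                  paste(sq[, 1], sq[, 2]))

  with_interior <- rbind(sq, cbind(lon = runif(20, 5.05, 5.45),
                                   lat = runif(20, 43.05, 43.35)))
  mbg2 <- minimum_bounding_geometry(with_interior, center = mbg$center)
  expect_equal(sort(mbg2$lonlat[, 1]), sort(mbg$lonlat[, 1]))
  expect_equal(mbg2$area_km2, mbg$area_km2, tolerance = 1e-9)

  expect_error(minimum_bounding_geometry(sq[1:2, ]), "at least 3")
  line <- cbind(lon = c(5, 5.1, 5.2), lat = c(43, 43.1, 43.2))
  expect_error(minimum_bounding_geometry(line), "collinear")
})

test_that("hull area agrees with an independent gift-wrapping oracle", {
  set.seed(17)
  pts <- cbind(lon = runif(200, 4, 6), lat = runif(200, 42, 44))
  mbg <- minimum_bounding_geometry(pts)
  xy <- project_laea(pts, mbg$center)
  oracle <- wrap_hull(xy)
  expect_equal(mbg$area_km2, shoelace(oracle), tolerance = 1e-8)
  # all positions inside or on the hull
  expect_true(all(mgcv::in.out(rbind(oracle, oracle[1, ]),
                               xy[!duplicated(xy), ] * (1 - 1e-9))))
})

test_that("projection round-trips and preserves small-scale areas", {
  ctr <- c(6, 42)
  pts <- cbind(runif(50, 4, 8), runif(50, 40, 44))
  back <- unproject_laea(project_laea(pts, ctr), ctr)
  expect_equal(back[, 1], pts[, 1], tolerance = 1e-9)
  expect_equal(back[, 2], pts[, 2], tolerance = 1e-9)
})

test_that("kde_ud integrates to one, peaks at the data mode, respects barriers", {
  set.seed(23)
  pts <- cbind(lon = 6 + rnorm(400, 0, 0.1), lat = 42 + rnorm(400, 0, 0.1))
  ud <- kde_ud(pts, grid_n = 96)
  expect_equal(sum(ud$density) * ud$cell_area_km2, 1, tolerance = 1e-6)
  pk <- which(ud$density == max(ud$density), arr.ind = TRUE)
  ctr_xy <- project_laea(matrix(colMeans(pts), 1), ud$center)
  expect_lt(abs(ud$x[pk[1, 2]] - ctr_xy[1]), ud$bandwidth_km[1])
  expect_lt(abs(ud$y[pk[1, 1]] - ctr_xy[2]), ud$bandwidth_km[2])

  # half-plane barrier through the centroid: mass renormalised on sea
  udb <- kde_ud(pts, grid_n = 96, barrier = function(x, y) x > ctr_xy[1])
  expect_equal(sum(udb$density) * udb$cell_area_km2, 1, tolerance = 1e-6)
  expect_true(all(udb$density[, udb$x > ctr_xy[1]] == 0))

  expect_error(kde_ud(pts, grid_n = 32, barrier = function(x, y) x > -Inf),
               "barrier")
})

test_that("UD mass inside the analytic 50% circle of a bivariate normal is ~0.5", {
  set.seed(29)
  n <- 2000
  sd_deg <- 0.3
  lat <- 42 + rnorm(n, 0, sd_deg)
  lon <- 6 + rnorm(n, 0, sd_deg / cos(42 * pi / 180))
  ud <- kde_ud(cbind(lon, lat), grid_n = 128)
  sigma_km <- sd_deg * 111.19
  r50 <- sigma_km * sqrt(2 * log(2))
  ctr <- project_laea(matrix(c(6, 42), 1), ud$center)
  dist2 <- outer(ud$y - ctr[2], ud$x - ctr[1],
                 function(y, x) x^2 + y^2)
  mass <- sum(ud$density[dist2 <= r50^2]) * ud$cell_area_km2
  # the UD mass should match the sample's own in-circle fraction (the
  # smoothing bias is small) and sit near the analytic 50%
  xy <- project_laea(cbind(lon, lat), ud$center)
  emp <- mean((xy[, 1] - ctr[1])^2 + (xy[, 2] - ctr[2])^2 <= r50^2)
  expect_equal(mass, emp, tolerance = 0.05)
  expect_equal(mass, 0.5, tolerance = 0.1)
})

test_that("isopleth is the smallest superlevel set reaching the mass", {
  fake_ud <- function(dens, cell = 1) {
    dens <- dens / (sum(dens) * cell^2)
    structure(list(x = seq_len(ncol(dens)), y = seq_len(nrow(dens)),
                   dx = cell, dy = cell, density = dens,
                   cell_area_km2 = cell^2,
                   bandwidth_km = c(1, 1), center = c(0, 45),
                   barrier = NULL, n_positions = NA), class = "ud_grid")
  }
  # level 1 returns every positive cell
  set.seed(5)
  d <- matrix(runif(100), 10, 10); d[1:3] <- 0
  ud <- fake_ud(d)
  expect_equal(isopleth(ud, 1)$n_cells, sum(d > 0))
  expect_error(isopleth(ud, 0), "level")
  expect_error(isopleth(ud, 1.2), "level")

  # greedy oracle
  for (i in 1:10) {
    d <- matrix(rexp(144), 12, 12)
    ud <- fake_ud(d)
    lev <- runif(1, 0.2, 0.95)
    iso <- isopleth(ud, lev)
    v <- sort(as.vector(ud$density), decreasing = TRUE)
    k <- which(cumsum(v) * ud$cell_area_km2 >= lev - 1e-12)[1]
    expect_equal(iso$n_cells, k)
    expect_gte(iso$mass, lev - 1e-9)
    # nesting
    iso2 <- isopleth(ud, min(1, lev + 0.04))
    expect_true(all(iso2$mask[iso$mask]))
  }

  # two equal symmetric modes split the 50% region equally
  half <- matrix(0, 9, 9)
  half[c(4, 6), 2] <- half[c(4, 6), 8] <- 2
  half[5, 2] <- half[5, 8] <- 4
  ud2 <- fake_ud(half)
  iso <- isopleth(ud2, 0.5)
  expect_equal(sum(iso$mask[, 1:4]), sum(iso$mask[, 6:9]))
})

test_that("home ranges nest and match the uniform-density example", {
  dens <- matrix(0, 10, 12)
  dens[1:10, 1:10] <- 1
  dens <- dens / sum(dens)
  ud <- structure(list(x = seq_len(12), y = seq_len(10), dx = 1, dy = 1,
                       density = dens, cell_area_km2 = 1,
                       bandwidth_km = c(1, 1), center = c(0, 45),
                       barrier = NULL, n_positions = NA),
                  class = "ud_grid")
  hr <- home_ranges(ud)
  expect_equal(hr$chr$n_cells, 50)
  expect_equal(hr$thr$n_cells, 90)
  expect_gte(hr$thr$area_km2, hr$chr$area_km2)
  expect_true(all(hr$thr$mask[hr$chr$mask]))
})

test_that("halving the cell size changes smooth home-range areas by < 5%", {
  set.seed(37)
  pts <- cbind(lon = 6 + rnorm(500, 0, 0.2), lat = 42 + rnorm(500, 0, 0.15))
  a <- home_ranges(kde_ud(pts, grid_n = 64))
  b <- home_ranges(kde_ud(pts, grid_n = 128))
  expect_lt(abs(a$chr$area_km2 - b$chr$area_km2) / b$chr$area_km2, 0.05)
  expect_lt(abs(a$thr$area_km2 - b$thr$area_km2) / b$thr$area_km2, 0.05)
})

test_that("kernel density agrees with an independent KDE implementation", {
  set.seed(41)
  pts <- cbind(lon = 6 + rnorm(300, 0, 0.1), lat = 42 + rnorm(300, 0, 0.1))
  ud <- kde_ud(pts, bandwidth_km = c(5, 5), grid_n = 64)
  xy <- project_laea(pts, ud$center)
  # MASS::kde2d uses bandwidth h with kernel sd h/4
  k2 <- MASS::kde2d(xy[, 1], xy[, 2], h = c(20, 20), n = 64,
                    lims = c(range(ud$x), range(ud$y)))
  # identical up to the discrete renormalisation to exact unit mass
  expect_equal(ud$density, t(k2$z), tolerance = 1e-4, ignore_attr = TRUE)
})
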