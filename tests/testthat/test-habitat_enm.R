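# grid whose cell centres fall on round 0.1-degree coordinates
habitat_grid <- function() scene_grid(c(-0.05, 10.05), c(39.95, 42.05), 0.1)

test_that("front detection flags steep log-gradients and ignores flat fields", {
  g <- habitat_grid()
  flat <- matrix(0.3, length(g$lat), length(g$lon))
  expect_false(any(detect_fronts(flat, g)))

  sc <- simulate_scene(g, front_spec = list(lon = 5, width_deg = 0.2,
                                            chl_low = 0.1, chl_high = 0.8))
  fr <- detect_fronts(sc$chl[[1]], g)
  # the band must contain the analytic maximum-gradient line (lon = 5)
  centre_col <- which.min(abs(g$lon - 5))
  expect_true(all(fr[, centre_col]))
  # log-gradient invariance under uniform scaling
  expect_identical(detect_fronts(2 * sc$chl[[1]], g), fr)
  expect_error(detect_fronts(matrix(1, 2, 2), scene_grid(c(0, 1), c(0, 1), 0.5)),
               "3 x 3")
})

test_that("habitat mask is the conjunction of front, chlorophyll window and depth", {
  g <- habitat_grid()
  sc <- simulate_scene(g, front_spec = list(lon = 5, width_deg = 0.2,
                                            chl_low = 0.1, chl_high = 0.45))
  fr <- detect_fronts(sc$chl[[1]], g)

  shallow <- matrix(100, length(g$lat), length(g$lon))
  expect_false(any(habitat_mask(sc$chl[[1]], fr, shallow)))

  cfg <- list(chl_min = 0.05, chl_max = 0.5, depth_min = 200,
              dilate_cells = 2)
  msk <- habitat_mask(sc$chl[[1]], fr, sc$depth, sc$land, cfg)
  manual <- fintrack:::dilate_mask(fr, 2) & sc$chl[[1]] >= 0.05 &
    sc$chl[[1]] <= 0.5 & sc$depth >= 200 & !sc$land
  manual[is.na(manual)] <- FALSE
  expect_identical(msk, manual)

  # chlorophyll above the 0.5 mg m^-3 ceiling is unsuitable even on fronts
  rich <- sc$chl[[1]] * 0 + 0.6
  expect_false(any(habitat_mask(rich, fr, sc$depth, sc$land, cfg)))

  expect_error(habitat_mask(sc$chl[[1]][1:5, ], fr, sc$depth), "share the grid")
})

test_that("widening the chlorophyll window never shrinks the suitable set", {
  g <- habitat_grid()
  sc <- simulate_scene(g, front_spec = list(lon = 5, width_deg = 0.3,
                                            chl_low = 0.08, chl_high = 0.6))
  fr <- detect_fronts(sc$chl[[1]], g)
  narrow <- habitat_mask(sc$chl[[1]], fr, sc$depth, sc$land,
                         list(chl_min = 0.1, chl_max = 0.4))
  wide <- habitat_mask(sc$chl[[1]], fr, sc$depth, sc$land,
                       list(chl_min = 0.05, chl_max = 0.55))
  expect_true(all(wide[narrow]))
  # lowering the gradient threshold never shrinks the front set
  fr_lo <- detect_fronts(sc$chl[[1]], g, threshold_per_100km = 0.1)
  expect_true(all(fr_lo[fr]))
})

test_that("habitat frequency is the per-cell fraction of suitable days", {
  g <- scene_grid(c(0, 2), c(40, 41), 0.25)
  m1 <- matrix(c(TRUE, FALSE), length(g$lat), length(g$lon))
  st <- structure(list(grid = g, days = 1:30,
                       masks = c(rep(list(m1), 15), rep(list(!m1), 15)),
                       config = list()), class = "habitat_stack")
  f <- habitat_frequency(st)
  expect_true(all(abs(f - 0.5) < 1e-12))
  f15 <- habitat_frequency(st, window = 1:15)
  expect_true(all(f15 %in% c(0, 1)))
  expect_error(habitat_frequency(st, window = c(5, 99)), "99")

  set.seed(11)
  masks <- lapply(1:7, function(i) matrix(runif(8 * 4) < 0.4, 4, 8))
  st2 <- structure(list(grid = scene_grid(c(0, 2), c(40, 41), 0.25),
                        days = 1:7, masks = masks, config = list()),
                   class = "habitat_stack")
  expect_equal(habitat_frequency(st2),
               Reduce(`+`, lapply(masks, `*`, 1)) / 7)
})

test_that("habitat area fraction matches direct cell accounting", {
  g <- habitat_grid()
  region <- cbind(c(1.02, 8.98, 8.98, 1.02), c(40.22, 40.22, 41.78, 41.78))
  full <- matrix(TRUE, length(g$lat), length(g$lon))
  expect_equal(habitat_area_fraction(full, g, region), 100)

  # half the region's columns suitable
  half <- matrix(FALSE, length(g$lat), length(g$lon))
  half[, g$lon < 5] <- TRUE
  got <- habitat_area_fraction(half, g, region)
  areas <- matrix(cell_area_km2(g), length(g$lat), length(g$lon))
  inside <- outer(g$lat > 40.22 & g$lat < 41.78,
                  g$lon > 1.02 & g$lon < 8.98, `&`)
  expect_equal(got, 100 * sum(areas[inside & half]) / sum(areas[inside]),
               tolerance = 1e-9)
  expect_error(habitat_area_fraction(full, g, region + 100), "intersect")
})

test_that("distance to habitat matches haversine and an exhaustive scan", {
  g <- habitat_grid()
  empty <- matrix(FALSE, length(g$lat), length(g$lon))
  m <- empty
  m[which(abs(g$lat - 41) < 1e-9), which(abs(g$lon - 5) < 1e-9)] <- TRUE
  st <- structure(list(grid = g, days = 1L, masks = list(m),
                       config = list()), class = "habitat_stack")

  on_cell <- data.frame(ptt = "P", day = 1L, lon = 5.0, lat = 41.0)
  expect_equal(distance_to_habitat(on_cell, st)$positions$distance_km, 0)

  one_deg <- data.frame(ptt = "P", day = 1L, lon = 5.0, lat = 40.0)
  d <- distance_to_habitat(one_deg, st)$positions$distance_km
  expect_equal(d, 111.19, tolerance = 0.01)

  set.seed(19)
  msk <- matrix(runif(length(g$lat) * length(g$lon)) < 0.01,
                length(g$lat), length(g$lon))
  st2 <- structure(list(grid = g, days = 1L, masks = list(msk),
                        config = list()), class = "habitat_stack")
  pos <- data.frame(ptt = "P", day = 1L,
                    lon = runif(200, 0, 10), lat = runif(200, 40, 42))
  got <- distance_to_habitat(pos, st2)$positions$distance_km
  idx <- which(msk, arr.ind = TRUE)
  for (i in seq_len(nrow(pos))) {
    dd <- hav_km(pos$lon[i], pos$lat[i], g$lon[idx[, 2]], g$lat[idx[, 1]])
    own <- fintrack:::grid_cell_of(g, pos$lon[i], pos$lat[i])
    expected <- if (msk[own[1, 1], own[1, 2]]) 0 else min(dd)
    expect_equal(got[i], expected, tolerance = 1e-6)
  }
})

test_that("days with empty habitat masks are excluded from the summary fraction", {
  g <- scene_grid(c(0, 2), c(40, 41), 0.25)
  m <- matrix(TRUE, length(g$lat), length(g$lon))
  st <- structure(list(grid = g, days = 1:2,
                       masks = list(m, m & FALSE), config = list()),
                  class = "habitat_stack")
  pos <- data.frame(ptt = "P", day = c(1L, 2L), lon = 1, lat = 40.5)
  res <- distance_to_habitat(pos, st)
  expect_equal(res$n, 1)
  expect_equal(res$n_missing, 1)
  expect_equal(res$fraction_within, 1)
  expect_error(distance_to_habitat(data.frame(ptt = "P", day = 9L,
                                              lon = 1, lat = 40.5), st),
               "day")
})

test_that("perturbing a position by x km changes its distance by at most x", {
  g <- habitat_grid()
  msk <- matrix(FALSE, length(g$lat), length(g$lon))
  msk[10, 30] <- msk[15, 70] <- TRUE
  st <- structure(list(grid = g, days = 1L, masks = list(msk),
                       config = list()), class = "habitat_stack")
  set.seed(23)
  for (i in 1:20) {
    p0 <- data.frame(ptt = "P", day = 1L, lon = runif(1, 1, 9),
                     lat = runif(1, 40.2, 41.8))
    eps <- 0.05
    p1 <- p0; p1$lat <- p1$lat + eps
    d0 <- distance_to_habitat(p0, st)$positions$distance_km
    d1 <- distance_to_habitat(p1, st)$positions$distance_km
    moved <- hav_km(p0$lon, p0$lat, p1$lon, p1$lat)
    expect_lte(abs(d1 - d0), moved + 1e-6)
  }
})
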