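test_that("NDVI follows (nir - red)/(nir + red) with domain checks", {
  expect_equal(compute_ndvi(0.1, 0.3), 0.5)
  expect_equal(compute_ndvi(0.25, 0.25), 0)
  expect_equal(compute_ndvi(0.2, 0.0), -1)
  expect_equal(compute_ndvi(c(0.1, 0.2), c(0.3, 0.2)), c(0.5, 0))
  expect_error(compute_ndvi(0, 0), "positive")
  expect_error(compute_ndvi(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(compute_ndvi(0.5, 1.2), "\\[0, 1\\]")
})

test_that("Savitzky-Golay reproduces low-order polynomials and cuts noise", {
  x <- seq_len(46)
  quad <- 0.3 + 0.01 * x - 2e-4 * x^2
  expect_lt(max(abs(sg_smooth(quad, 5, 2) - quad)), 1e-10)
  expect_lt(max(abs(sg_smooth(rep(0.4, 46), 5, 2) - 0.4)), 1e-12)
  cubic <- 0.1 + 1e-4 * x^3
  expect_lt(max(abs(sg_smooth(cubic, 7, 3) - cubic)), 1e-10)
  # noisy logistic: smoothing must reduce RMSE to the clean curve
  clean <- logistic_branch_values(x, a = 4.6, b = -0.2, c = 0.6, d = 0.2)
  noisy <- withr::with_seed(1, clean + rnorm(46, 0, 0.05))
  sm <- sg_smooth(noisy, 5, 2)
  expect_lt(sqrt(mean((sm - clean)^2)), sqrt(mean((noisy - clean)^2)))
  expect_error(sg_smooth(clean, 4, 2), "odd")
  expect_error(sg_smooth(clean, 5, 5), "smaller")
  expect_error(sg_smooth(clean[1:3], 5, 2), "exceed")
})

test_that("daily spline interpolates knots exactly and reproduces cubics", {
  doy <- seq(1, 81, by = 8)
  cubic <- function(t) 0.2 + 0.003 * t - 5e-5 * t^2 + 3e-7 * t^3
  d <- interpolate_daily(doy, cubic(doy))
  expect_identical(d$day, 1:81)
  expect_lt(max(abs(d$ndvi - cubic(d$day))), 1e-8)
  expect_equal(d$ndvi[match(doy, d$day)], cubic(doy))
  lin <- interpolate_daily(doy, 0.1 + 0.002 * doy)
  expect_lt(max(abs(lin$ndvi - (0.1 + 0.002 * lin$day))), 1e-10)
  expect_error(interpolate_daily(c(1, 9, 17), c(0.1, 0.2, 0.3)),
               "at least 4")
})

test_that("season detection finds the valley bottoms flanking the peak", {
  # symmetric triangle: SD and ED at its support ends
  tri <- ramp_series(150, 200, 250)
  s <- detect_growing_season(tri$adj_day, tri$ndvi)
  expect_identical(s$sd, 150L)
  expect_identical(s$ed, 250L)
  # monotone series: no interior peak
  expect_error(detect_growing_season(1:100, seq(0.1, 0.8, length.out = 100)),
               "monotone|peak")
  expect_error(detect_growing_season(1:100, rep(0.3, 100)), "flat")
})

test_that("noise-free SD/ED recovery is within 3 days of the 1% onset truth", {
  for (k in c(0.08, 0.10, 0.12, 0.14)) {
    p <- example_params(rise_steep = k, fall_steep = k, amplitude = 0.55)
    daily <- data.frame(day = 1:365,
                        ndvi = simulate_pixel_curve(p, 1:365))
    td <- true_stage_dates(p)
    s <- detect_growing_season(daily$day, daily$ndvi)
    expect_lt(abs(s$sd - td$sd), 3)
    expect_lt(abs(s$ed - td$ed), 3)
  }
})

test_that("multi-peak series fail loudly unless overridden", {
  day <- 1:200
  two <- 0.2 + 0.5 * exp(-(day - 60)^2 / 200) + 0.45 * exp(-(day - 150)^2 / 200)
  expect_error(detect_growing_season(day, two), "multiple")
  # with the override, the season brackets the highest peak (the valley
  # between the two humps becomes ED)
  s <- detect_growing_season(day, two, allow_multiple = TRUE)
  expect_true(s$sd < 60 && s$ed > 60)
})

test_that("phenological adjustment truncates, re-indexes and is idempotent", {
  daily <- data.frame(day = 100:300, ndvi = runif(201))
  adj <- phenologically_adjust(daily, list(sd = 150, ed = 280))
  expect_identical(nrow(adj), 131L)
  expect_equal(adj$adj_day, 0:130)
  expect_equal(attr(adj, "sd_day"), 150)
  expect_equal(adj$ndvi[1], daily$ndvi[daily$day == 150])
  # adjusted index of DOY d is d - SD
  expect_equal(adj$ndvi[adj$adj_day == 40], daily$ndvi[daily$day == 190])
  # applying the full-span adjustment again changes nothing
  again <- phenologically_adjust(adj, list(sd = 0, ed = 130))
  expect_equal(again$adj_day, adj$adj_day)
  expect_equal(again$ndvi, adj$ndvi)
  expect_error(phenologically_adjust(daily, list(sd = 50, ed = 280)),
               "inside")
})

test_that("pixel prep chain keeps values finite and in NDVI range", {
  p <- example_params()
  truth <- simulate_pixel_curve(p, 1:365)
  comp <- simulate_composites(truth, noise_sd = 0.015, dropout_prob = 0.15,
                              seed = 4)
  adj <- prep_pixel(comp)
  expect_true(all(is.finite(adj$ndvi)))
  expect_true(all(adj$ndvi >= -1.05 & adj$ndvi <= 1.05))
  expect_equal(adj$adj_day[1], 0)
  expect_true(attr(adj, "sd_day") < attr(adj, "ed_day"))
})
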