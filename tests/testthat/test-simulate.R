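test_that("double-logistic curve has the expected peak, tails and inflection", {
  p <- example_params()
  day <- 1:365
  v <- simulate_pixel_curve(p, day)
  expect_lt(abs(max(v) - 0.8), 0.01)
  expect_lt(abs(day[which.max(v)] - 205), 6)
  expect_lt(abs(v[40] - 0.2), 0.005)   # far before the season: base
  expect_lt(abs(v[360] - 0.2), 0.01)   # far after the season: base
  # flat line at base when amplitude is zero
  expect_equal(simulate_pixel_curve(example_params(amplitude = 0), day),
               rep(0.2, 365))
  # out-of-order midpoints rejected
  expect_error(simulate_pixel_curve(example_params(rise_mid = 250,
                                                   fall_mid = 160), day),
               "midpoint")
})

test_that("true V6/R6 equal the logistic midpoints (numeric derivative check)", {
  for (s in 1:5) {
    p <- withr::with_seed(s, example_params(
      rise_mid = runif(1, 150, 170), fall_mid = runif(1, 245, 265),
      rise_steep = runif(1, 0.08, 0.14), fall_steep = runif(1, 0.08, 0.12),
      amplitude = runif(1, 0.45, 0.65)))
    td <- true_stage_dates(p)
    expect_identical(td$v6, p$rise_mid)
    expect_identical(td$r6, p$fall_mid)
    grid <- seq(1, 365, by = 0.5)
    dv <- diff(simulate_pixel_curve(p, grid))
    expect_lt(abs(grid[which.max(dv)] - p$rise_mid), 1)
    expect_lt(abs(grid[which.min(dv)] - p$fall_mid), 1)
    ord <- unlist(td[c("sd", "v1", "v6", "vt", "r4", "r6", "ed")])
    expect_false(is.unsorted(ord))
  }
})

test_that("8-day MVC produces 46 composites per 365-day year, each the window max", {
  p <- example_params()
  truth <- simulate_pixel_curve(p, 1:365)
  comp <- simulate_composites(truth)
  expect_identical(nrow(comp), 46L)
  expect_identical(comp$doy, seq(1L, 361L, by = 8L))
  # brute-force window maxima oracle
  win <- findInterval(1:365, comp$doy)
  expect_equal(comp$ndvi, as.numeric(tapply(truth, win, max)))
  expect_equal(truth[match(comp$doy_obs, 1:365)], comp$ndvi)
})

test_that("full dropout depresses every composite by the cloud bias", {
  p <- example_params()
  truth <- simulate_pixel_curve(p, 1:365)
  comp <- simulate_composites(truth, noise_sd = 0, dropout_prob = 1,
                              dropout_bias = 0.3, seed = 2)
  win <- findInterval(1:365, comp$doy)
  wmax <- as.numeric(tapply(truth, win, max))
  expect_true(all(comp$ndvi <= wmax - 0.3 + 1e-12))
  expect_equal(comp$ndvi, wmax - 0.3)
})

test_that("MVC suppresses negatively biased dropouts better than symmetric ones", {
  p <- example_params()
  truth <- simulate_pixel_curve(p, 1:365)
  ref <- simulate_composites(truth)$ndvi
  mad_of <- function(sym) {
    devs <- vapply(1:20, function(s) {
      got <- simulate_composites(truth, noise_sd = 0, dropout_prob = 0.3,
                                 dropout_bias = 0.3, dropout_symmetric = sym,
                                 seed = s)$ndvi
      mean(abs(got - ref))
    }, numeric(1))
    mean(devs)
  }
  expect_lt(mad_of(FALSE), mad_of(TRUE))
})

test_that("yields are the stated linear function of true metrics", {
  panel <- simulate_panel(noise_free_config(n_counties = 8,
                                            years = 2014:2016))
  tr <- panel$truth$counties
  betas <- c(intercept = 100, gp2d = 50, gp3d = -20)
  y0 <- simulate_yields(tr, betas, noise_sd = 0, seed = 1)
  expect_equal(y0$yield_kg_ha, 100 + 50 * tr$gp2d - 20 * tr$gp3d)
  expect_equal(summary(lm(yield_kg_ha ~ gp2d + gp3d, y0))$r.squared, 1)
  expect_equal(attr(y0, "gen_r2"), 1)
  # zero betas: constant plus noise
  yc <- simulate_yields(tr, c(intercept = 10000), noise_sd = 5, seed = 1)
  expect_lt(max(abs(yc$yield_kg_ha - 10000)), 25)
  expect_error(simulate_yields(tr, c(intercept = NA, gp2d = 1), 0),
               "finite")
  expect_error(simulate_yields(tr, c(intercept = 0, nope = 1), 0),
               "missing")
})

test_that("panels are byte-identical under the same config", {
  cfg <- tiny_config()
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)
  # and change with the seed
  p3 <- simulate_panel(sim_config(n_counties = 4, pixels_per_county = 3,
                                  years = 2014:2016, seed = 43))
  expect_false(identical(p1$composites$ndvi, p3$composites$ndvi))
})

test_that("panel dimensions and cross-references are consistent", {
  cfg <- sim_config(n_counties = 5, pixels_per_county = 2,
                    years = 2014:2016, seed = 9)
  panel <- simulate_panel(cfg)
  expect_identical(nrow(panel$yields), 15L)
  expect_identical(nrow(panel$truth$counties), 15L)
  expect_identical(nrow(panel$composites), 5L * 2L * 3L * 46L)
  expect_true(all(panel$composites$county_id %in% panel$yields$county_id))
  expect_setequal(unique(panel$yields$region_group),
                  c("semi_arid", "non_semi_arid"))
})

test_that("generating R^2 calibration hits its target", {
  panel <- simulate_panel(sim_config(n_counties = 10, pixels_per_county = 2,
                                     years = 2010:2018, seed = 3,
                                     target_gen_r2 = 0.65))
  expect_equal(attr(panel$truth$counties, "gen_r2_expected"), 0.65,
               tolerance = 1e-6)
  # realized sample R^2 of the generating model stays near the target
  expect_lt(abs(panel$truth$gen_r2 - 0.65), 0.08)
})

test_that("aligned county truth shifts dates by the selected pixels' mean shift", {
  panel <- simulate_panel(tiny_config())
  tr <- county_truth_aligned(panel, threshold = 0.7)
  sel <- select_corn_pixels(panel$fractions, 0.7)
  px <- merge(panel$truth$pixels, sel, by = c("county_id", "pixel_id"))
  one <- tr[1, ]
  pxi <- px[px$county_id == one$county_id & px$year == one$year, ]
  ms <- sum(pxi$corn_fraction * pxi$shift) / sum(pxi$corn_fraction)
  raw <- panel$truth$counties
  raw1 <- raw[raw$county_id == one$county_id & raw$year == one$year, ]
  expect_equal(one$v6_true, raw1$v6_true + ms)
  expect_equal(one$gp2d, raw1$gp2d)  # metrics are shift-invariant
})
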