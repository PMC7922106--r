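test_that("best univariate family tracks the generating shape", {
  x <- seq(-3, 3, length.out = 60)
  lin <- fit_univariate_best(x, 2 * x + 1)
  expect_identical(lin$family, "linear")
  expect_equal(lin$r2, 1)
  expect_true(lin$significant)
  # pure quadratic on symmetric x: linear R^2 is 0 by odd-even orthogonality
  quad <- fit_univariate_best(x, x^2)
  expect_identical(quad$family, "quadratic")
  expect_equal(quad$r2, 1)
  expect_lt(quad$all_r2[["linear"]], 1e-20)
  lg <- withr::with_seed(11, {
    xl <- runif(80, 1, 10)
    fit_univariate_best(xl, log(xl) + rnorm(80, 0, 0.01))
  })
  expect_identical(lg$family, "logarithmic")
  expect_error(fit_univariate_best(rep(1, 10), 1:10), "zero variance")
})

test_that("VIF equals 1/(1 - R_i^2) with the documented special cases", {
  # orthogonal centered columns -> all VIF = 1
  X <- poly(1:50, 3)
  expect_equal(as.numeric(vif(X)), rep(1, 3), tolerance = 1e-10)
  # construct x1 regressed on x2 with R^2 exactly 0.75 -> VIF = 4
  z <- withr::with_seed(2, rnorm(200))
  w <- withr::with_seed(3, rnorm(200))
  w <- residuals(lm(w ~ z))  # exactly orthogonal to z
  x1 <- sqrt(0.75) * scale(z)[, 1] + sqrt(0.25) * scale(w)[, 1]
  v <- vif(cbind(x1 = x1, x2 = scale(z)[, 1]))
  expect_equal(unname(v[1]), 4, tolerance = 1e-8)
  # random design against the per-column regression oracle (and car::vif)
  X5 <- withr::with_seed(4, matrix(rnorm(500), 100, 5,
                                   dimnames = list(NULL, paste0("x", 1:5))))
  got <- vif(X5)
  brute <- vapply(1:5, function(i)
    1 / (1 - summary(lm(X5[, i] ~ X5[, -i]))$r.squared), numeric(1))
  expect_equal(as.numeric(got), brute, tolerance = 1e-8)
  df5 <- as.data.frame(X5)
  df5$y <- withr::with_seed(5, rnorm(100))
  expect_equal(as.numeric(got),
               as.numeric(car::vif(lm(y ~ ., df5))), tolerance = 1e-6)
  # perfect collinearity flagged as infinite
  vdup <- vif(cbind(a = X5[, 1], b = X5[, 1], c = X5[, 2]))
  expect_true(is.infinite(vdup[["a"]]) && is.infinite(vdup[["b"]]))
  expect_true(any(attr(vdup, "collinear")))
  expect_error(vif(X5[, 1, drop = FALSE]), "at least 2")
})

test_that("stepwise selects the generating variable and only it", {
  d <- withr::with_seed(7, {
    d <- as.data.frame(matrix(rnorm(200 * 5), 200, 5,
                              dimnames = list(NULL, paste0("x", 1:5))))
    d$yield_kg_ha <- d$x1 + rnorm(200, 0, 0.1)
    d
  })
  m <- stepwise_regression(d, paste0("x", 1:5))
  expect_identical(m$variables, "x1")
  # exhaustive best-subset by BIC agrees
  subsets <- unlist(lapply(1:5, function(k)
    combn(paste0("x", 1:5), k, simplify = FALSE)), recursive = FALSE)
  bics <- vapply(subsets, function(v)
    BIC(lm(reformulate(v, "yield_kg_ha"), d)), numeric(1))
  expect_identical(sort(subsets[[which.min(bics)]]), sort(m$variables))
})

test_that("stepwise on an exact linear model reaches R^2 = 1 with scaled betas", {
  d <- withr::with_seed(8, data.frame(x1 = rnorm(50), x2 = rnorm(50)))
  d$yield_kg_ha <- 2 * d$x1 - 3 * d$x2 + 10
  m <- stepwise_regression(d, c("x1", "x2"))
  expect_equal(m$r2, 1)
  expect_setequal(m$variables, c("x1", "x2"))
  expect_equal(unname(m$standardized[c("x1", "x2")]),
               c(2 * sd(d$x1), -3 * sd(d$x2)) / sd(d$yield_kg_ha),
               tolerance = 1e-10)
  # a duplicated candidate column never joins its twin
  d$x1copy <- d$x1
  m2 <- stepwise_regression(d, c("x1", "x1copy", "x2"))
  expect_false(all(c("x1", "x1copy") %in% m2$variables))
  expect_true(all(m2$vif < 4))
  # nothing predictive: intercept-only with a warning
  d3 <- withr::with_seed(9, data.frame(x1 = rnorm(40),
                                       yield_kg_ha = rnorm(40)))
  expect_warning(m3 <- stepwise_regression(d3, "x1"), "intercept")
  expect_length(m3$variables, 0)
})

test_that("standardized coefficients behave under rescaling and equal Pearson r", {
  d <- withr::with_seed(10, data.frame(x = rnorm(60, 50, 9)))
  d$y <- 3 * d$x + withr::with_seed(12, rnorm(60, 0, 5))
  f <- lm(y ~ x, d)
  b <- standardize_coefficients(coef(f), d, d$y)
  expect_equal(unname(b["x"]), cor(d$x, d$y), tolerance = 1e-10)
  # doubling the predictor's units halves the raw, keeps the standardized
  d2 <- transform(d, x = x / 2)
  f2 <- lm(y ~ x, d2)
  expect_equal(unname(coef(f2)["x"]), 2 * unname(coef(f)["x"]))
  expect_equal(standardize_coefficients(coef(f2), d2, d2$y), b,
               tolerance = 1e-12)
  # z-scored inputs: standardized equal raw
  dz <- data.frame(x = scale(d$x)[, 1])
  dz$y <- scale(d$y)[, 1]
  fz <- lm(y ~ x, dz)
  bz <- standardize_coefficients(coef(fz), dz, dz$y)
  expect_equal(unname(bz["x"]), unname(coef(fz)["x"]), tolerance = 1e-12)
  expect_error(standardize_coefficients(coef(f), d, rep(1, 60)),
               "zero-variance")
})

make_cv_table <- function(n_per_year = 30, years = 2010:2018, noise = 0,
                          seed = 20) {
  withr::with_seed(seed, {
    d <- expand.grid(county = seq_len(n_per_year), year = years)
    d$x1 <- rnorm(nrow(d), 20, 4)
    d$x2 <- rnorm(nrow(d), 0.01, 0.002)
    d$yield_kg_ha <- 1000 + 300 * d$x1 + 1e5 * d$x2 +
      rnorm(nrow(d), 0, noise)
    d
  })
}

test_that("leave-one-year-out CV is exact on a noise-free linear panel", {
  d <- make_cv_table()
  cv <- loyo_cv(d, c("x1", "x2"))
  expect_identical(nrow(cv$folds), length(2010:2018))
  expect_true(all(cv$folds$r2 > 1 - 1e-10))
  expect_lt(max(cv$folds$rmse), 1e-6)
})

test_that("permuted yields leave no cross-validated predictability", {
  d <- make_cv_table(noise = 300)
  d$yield_kg_ha <- withr::with_seed(21, sample(d$yield_kg_ha))
  cv <- loyo_cv(d, c("x1", "x2"))
  expect_lt(median(cv$folds$r2), 0.1)
  expect_error(loyo_cv(d[d$year < 2012, ], "x1"), "3 distinct years")
})

test_that("date agreement yields textbook values on shifted series", {
  ref <- c(150, 155, 148, 160, 152, 158)
  same <- date_agreement(ref, ref)
  expect_equal(same$r2, 1)
  expect_equal(same$rmse_days, 0)
  off <- date_agreement(ref + 3, ref)
  expect_equal(off$r2, 1)
  expect_equal(off$rmse_days, 3)
  expect_equal(off$bias_days, 3)
  expect_error(date_agreement(ref, ref[-1]), "length")
  # regional mean aggregation matches a hand-computed mean
  d <- data.frame(region_group = rep(c("a", "b"), each = 4),
                  year = rep(c(2010, 2011), 4),
                  v1 = c(10, 12, 14, 16, 20, 22, 24, 26))
  agg <- regional_mean_dates(d, "v1")
  a2010 <- mean(d$v1[d$region_group == "a" & d$year == 2010])
  expect_equal(agg$v1[agg$group == "a" & agg$year == 2010], a2010)
})
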