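#' Best univariate yield model among linear, quadratic and logarithmic fits
#'
#' Fits `y ~ x`, `y ~ x + x^2` and `y ~ log(x)` (the last only when all
#' `x > 0`) and reports the family with the largest R^2, together with the
#' overall-F p-value and its significance at p < 0.05.
#'
#' @param x predictor vector.
#' @param y yield vector.
#' @return list of class `univariate_fit`: `family`, `coefficients`, `r2`,
#'   `p_value`, `significant`.
#' @export
fit_univariate_best <- function(x, y) {
  if (length(x) < 5) stop("need at least 5 observations")
  if (stats::sd(x) < 1e-12) stop("degenerate predictor: zero variance")
  fits <- list(linear = stats::lm(y ~ x),
               quadratic = stats::lm(y ~ x + I(x^2)))
  if (all(x > 0)) fits$logarithmic <- stats::lm(y ~ log(x))
  r2 <- vapply(fits, function(f) summary(f)$r.squared, numeric(1))
  best <- names(which.max(r2))
  f <- fits[[best]]
  sm <- summary(f)
  p <- if (is.null(sm$fstatistic)) NA_real_ else
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE)
  structure(list(family = best, coefficients = stats::coef(f),
                 r2 = unname(r2[best]), p_value = unname(p),
                 significant = is.finite(p) && p < 0.05,
                 all_r2 = r2),
            class = "univariate_fit")
}

#' Variance inflation factors
#'
#' `VIF_i = 1 / (1 - R_i^2)` where `R_i^2` is the coefficient of
#' determination of predictor `i` regressed on all other predictors. Values
#' below 4 are read as non-collinear. Perfectly collinear columns are
#' reported as `Inf` and flagged.
#'
#' @param design numeric matrix or data.frame of predictors (>= 2 columns,
#'   more rows than columns + 1).
#' @return named numeric vector of VIFs; attribute `collinear` flags
#'   infinite entries.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  k <- ncol(X)
  if (k < 2) stop("VIF needs at least 2 predictors")
  if (nrow(X) <= k + 1) stop("VIF needs n > number of predictors + 1")
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(k))
  out <- vapply(seq_len(k), function(i) {
    r2 <- summary(stats::lm(X[, i] ~ X[, -i, drop = FALSE]))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- colnames(X)
  attr(out, "collinear") <- !is.finite(out)
  out
}

#' Standardized regression coefficients
#'
#' `beta*_i = beta_i * sd(X_i) / sd(Y)` for every non-intercept coefficient;
#' the intercept has no standardized counterpart. For a single-predictor
#' linear model the standardized coefficient equals the Pearson correlation.
#'
#' @param coefficients named coefficient vector (may include
#'   `(Intercept)`).
#' @param data data.frame containing the predictor columns.
#' @param y response vector.
#' @return named vector of standardized coefficients.
#' @export
standardize_coefficients <- function(coefficients, data, y) {
  sy <- stats::sd(y)
  if (!is.finite(sy) || sy < 1e-12) stop("zero-variance response")
  vars <- setdiff(names(coefficients), "(Intercept)")
  vapply(vars, function(v)
    coefficients[[v]] * stats::sd(data[[v]]) / sy, numeric(1))
}

#' Stepwise multiple linear regression by partial-F p-values
#'
#' Forward-backward selection: at each step the candidate with the smallest
#' partial-F p-value enters if `p < p_enter`; then any included variable
#' with `p > p_remove` is dropped (largest first). A VIF guard keeps the
#' selection non-collinear: a candidate whose entry would push any
#' variance inflation factor above `vif_limit` never enters (a duplicated
#' column therefore can never join its twin). Returns raw and standardized
#' coefficients, training R^2 and per-variable VIFs.
#'
#' @param data data.frame of complete cases with the response and candidate
#'   columns.
#' @param candidates character vector of candidate predictor names.
#' @param response response column name (default `"yield_kg_ha"`).
#' @param p_enter,p_remove entry/removal p-value thresholds (defaults 0.05
#'   and 0.10).
#' @param vif_limit collinearity guard on entry (default 4, the conventional
#'   non-collinearity bound); `Inf` disables it.
#' @return list of class `stepwise_model`: `variables`, `coefficients`
#'   (incl. intercept), `standardized`, `r2`, `vif`, `n`, `fit` (the `lm`).
#' @export
stepwise_regression <- function(data, candidates,
                                response = "yield_kg_ha",
                                p_enter = 0.05, p_remove = 0.10,
                                vif_limit = 4) {
  stopifnot(all(candidates %in% names(data)), response %in% names(data))
  data <- data[stats::complete.cases(data[, c(response, candidates)]), ,
               drop = FALSE]
  y <- data[[response]]
  selected <- character(0)
  fit_with <- function(vars) {
    fml <- if (length(vars))
      stats::reformulate(vars, response = response)
    else stats::as.formula(paste(response, "~ 1"))
    stats::lm(fml, data = data)
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 100L) break  # guard against enter/remove oscillation
    changed <- FALSE
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      pvals <- vapply(pool, function(v) {
        f <- fit_with(c(selected, v))
        cf <- summary(f)$coefficients
        if (!(v %in% rownames(cf)) || anyNA(stats::coef(f)))
          return(NA_real_)  # aliased/collinear with current model
        if (length(selected) >= 1 && is.finite(vif_limit)) {
          v_new <- vif(data[, c(selected, v), drop = FALSE])
          if (any(!is.finite(v_new)) || max(v_new) > vif_limit)
            return(NA_real_)  # VIF guard: entry would create collinearity
        }
        cf[v, 4]
      }, numeric(1))
      if (any(is.finite(pvals)) && min(pvals, na.rm = TRUE) < p_enter) {
        selected <- c(selected, pool[which.min(pvals)])
        changed <- TRUE
      }
    }
    if (length(selected) > 1) {
      f <- fit_with(selected)
      cf <- summary(f)$coefficients
      pv <- cf[selected, 4]
      if (max(pv) > p_remove) {
        selected <- setdiff(selected, selected[which.max(pv)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!length(selected))
    warning("no candidate met the entry criterion; returning an ",
            "intercept-only model")
  fit <- fit_with(selected)
  vifs <- if (length(selected) >= 2)
    vif(data[, selected, drop = FALSE])
  else NULL
  structure(list(
    variables = selected,
    coefficients = stats::coef(fit),
    standardized = if (length(selected))
      standardize_coefficients(stats::coef(fit), data, y)
    else numeric(0),
    r2 = summary(fit)$r.squared,
    vif = vifs,
    n = nrow(data),
    fit = fit), class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat("Stepwise linear model (n = ", x$n, ")\n", sep = "")
  cat("  variables:", if (length(x$variables))
    paste(x$variables, collapse = ", ") else "(intercept only)", "\n")
  cat("  R^2 =", formatC(x$r2, digits = 3, format = "f"), "\n")
  if (length(x$standardized)) {
    cat("  standardized coefficients:\n")
    print(round(x$standardized, 3))
  }
  if (!is.null(x$vif)) {
    cat("  VIF:\n")
    v <- round(x$vif, 2)
    attr(v, "collinear") <- NULL
    print(v)
  }
  invisible(x)
}

#' Leave-one-year-out cross-validation of a yield model
#'
#' For each calendar year the model is trained on all other years and used
#' to predict the held-out year. Per-fold predictive R^2 is the squared
#' Pearson correlation between predicted and actual yields (option
#' `"rsq"` uses 1 - SSE/SST instead) and RMSE the root mean squared
#' prediction error. Folds with fewer than 3 observations are skipped with
#' a warning.
#'
#' @param data data.frame with the response, predictors and a year column.
#' @param variables predictor names of the (fixed) model, e.g. the stepwise
#'   selection from the full panel.
#' @param response response column name.
#' @param year_col year column name.
#' @param r2_method `"cor"` (squared correlation, default) or `"rsq"`
#'   (1 - SSE/SST).
#' @param refit_stepwise if `TRUE`, stepwise selection is re-run inside each
#'   training fold using `variables` as the candidate set.
#' @return list of class `loyo_cv`: `folds` (data.frame year, n, r2, rmse)
#'   and `summary` (medians and quartiles).
#' @export
loyo_cv <- function(data, variables, response = "yield_kg_ha",
                    year_col = "year", r2_method = c("cor", "rsq"),
                    refit_stepwise = FALSE) {
  r2_method <- match.arg(r2_method)
  data <- data[stats::complete.cases(data[, c(response, variables, year_col)]), ,
               drop = FALSE]
  years <- sort(unique(data[[year_col]]))
  if (length(years) < 3) stop("need at least 3 distinct years")
  rows <- lapply(years, function(yy) {
    test <- data[data[[year_col]] == yy, , drop = FALSE]
    train <- data[data[[year_col]] != yy, , drop = FALSE]
    if (nrow(test) < 3) {
      warning("year ", yy, " has fewer than 3 observations; fold skipped")
      return(NULL)
    }
    vars <- if (refit_stepwise)
      stepwise_regression(train, variables, response)$variables
    else variables
    fml <- if (length(vars)) stats::reformulate(vars, response = response)
           else stats::as.formula(paste(response, "~ 1"))
    fit <- stats::lm(fml, data = train)
    pred <- stats::predict(fit, newdata = test)
    obs <- test[[response]]
    r2 <- if (r2_method == "cor") {
      if (stats::sd(pred) < 1e-12 || stats::sd(obs) < 1e-12) {
        if (max(abs(pred - obs)) < 1e-8) 1 else NA_real_
      } else stats::cor(pred, obs)^2
    } else 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    data.frame(year = yy, n = nrow(test), r2 = r2,
               rmse = sqrt(mean((obs - pred)^2)))
  })
  folds <- do.call(rbind, rows)
  if (is.null(folds) || !nrow(folds)) stop("no usable folds")
  qs <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE)
  structure(list(folds = folds,
                 summary = list(r2 = qs(folds$r2), rmse = qs(folds$rmse))),
            class = "loyo_cv")
}

#' @export
print.loyo_cv <- function(x, ...) {
  cat("Leave-one-year-out cross-validation (", nrow(x$folds), " folds)\n",
      sep = "")
  cat("  median R^2 =", formatC(x$summary$r2[[2]], digits = 3, format = "f"),
      " median RMSE =", formatC(x$summary$rmse[[2]], digits = 1,
                                format = "f"), "\n")
  invisible(x)
}

#' Agreement between two stage-date series
#'
#' R^2 of the linear regression of predicted on reference dates, RMSE in
#' days, and the mean bias for 1:1-line diagnostics.
#'
#' @param predicted,reference paired DOY vectors (length >= 3).
#' @return list `r2`, `rmse_days`, `bias_days`, `n`.
#' @export
date_agreement <- function(predicted, reference) {
  if (length(predicted) != length(reference)) stop("length mismatch")
  if (length(predicted) < 3) stop("need at least 3 paired dates")
  r2 <- if (stats::sd(reference) < 1e-12 || stats::sd(predicted) < 1e-12) {
    if (max(abs(predicted - reference - mean(predicted - reference))) < 1e-8)
      1 else NA_real_
  } else summary(stats::lm(predicted ~ reference))$r.squared
  list(r2 = r2,
       rmse_days = sqrt(mean((predicted - reference)^2)),
       bias_days = mean(predicted - reference),
       n = length(predicted))
}

#' Unweighted aggregation of county stage dates to a regional mean
#'
#' Maps county-level dates to a coarser unit (e.g. state or region) as the
#' plain mean per unit-year, the convention used when comparing satellite
#' dates against survey dates reported at that coarser level.
#'
#' @param dates data.frame with a grouping column, a year column and a date
#'   column.
#' @param date_col,group_col,year_col column names.
#' @return data.frame with one mean date per group-year.
#' @export
regional_mean_dates <- function(dates, date_col, group_col = "region_group",
                                year_col = "year") {
  agg <- stats::aggregate(dates[[date_col]],
                          by = list(group = dates[[group_col]],
                                    year = dates[[year_col]]),
                          FUN = mean)
  names(agg)[3] <- date_col
  agg
}
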