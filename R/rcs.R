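#' Default adjustment covariates for the dose-response models
#'
#' Age (continuous and squared), sex, race/ethnicity, marital status,
#' education, smoking, drinking, hypertension, hyperlipidemia, diabetes,
#' eGFR, and the folate-related nutrient intakes (total folate, dietary
#' folic acid, food folate, DFE), all as printed in the model description.
#'
#' @return Character vector of cohort column names (`age` implies the
#'   squared term).
#' @export
fc_covariates <- function() {
  c("age", "sex", "race_ethnicity", "marital", "education", "smoking",
    "drinking", "hypertension", "hyperlipidemia", "diabetes", "egfr",
    "diet_total_folate", "diet_folic_acid", "food_folate", "dfe")
}

#' Knot placement for a 3-knot restricted cubic spline
#'
#' Knots are empirical percentiles of the exposure (default 10th, 50th and
#' 90th), computed by linear interpolation of order statistics
#' ([stats::quantile()] type 7).
#'
#' @param x Numeric exposure values (missing values dropped).
#' @param percentiles Percentiles in (0, 100), strictly increasing.
#' @return List of class `"spline_spec"` with `knots` (named numeric) and
#'   `percentiles`.
#' @export
compute_knots <- function(x, percentiles = c(10, 50, 90)) {
  x <- x[!is.na(x)]
  if (any(percentiles <= 0 | percentiles >= 100) || is.unsorted(percentiles, strictly = TRUE)) {
    stop_fc("`percentiles` must be strictly increasing within (0, 100).",
            "fc_config_error")
  }
  if (length(unique(x)) < 3) {
    stop_fc("need at least 3 distinct exposure values to place knots.",
            "fc_degenerate_knots")
  }
  knots <- unname(quantile(x, percentiles / 100, type = 7))
  if (is.unsorted(knots, strictly = TRUE)) {
    stop_fc("tied exposure percentiles give non-distinct knots.",
            "fc_degenerate_knots")
  }
  structure(list(knots = knots, percentiles = percentiles),
            class = "spline_spec")
}

#' Restricted cubic spline basis (3 knots)
#'
#' Returns the two exposure columns of the 3-knot restricted (natural) cubic
#' spline in the truncated-power form: the linear term `x` and
#' `R(x) = [(x - t1)+^3 - (x - t2)+^3 (t3 - t1)/(t3 - t2)
#'          + (x - t3)+^3 (t2 - t1)/(t3 - t2)] / (t3 - t1)^2`.
#' The implied fit is linear beyond the boundary knots.
#'
#' @param x Numeric vector.
#' @param spec A `"spline_spec"` from [compute_knots()], or a length-3
#'   numeric vector of knots.
#' @return Matrix with columns `x` and `rcs1`.
#' @export
rcs_basis <- function(x, spec) {
  t <- if (inherits(spec, "spline_spec")) spec$knots else spec
  stopifnot(length(t) == 3, !is.unsorted(t, strictly = TRUE))
  cube <- function(u) pmax(u, 0)^3
  r <- (cube(x - t[1]) -
          cube(x - t[2]) * (t[3] - t[1]) / (t[3] - t[2]) +
          cube(x - t[3]) * (t[2] - t[1]) / (t[3] - t[2])) / (t[3] - t[1])^2
  cbind(x = x, rcs1 = r)
}

# dummy-code one categorical column against its first observed (or known)
# level; returns a named matrix possibly with zero columns
fc_known_levels <- function(col) {
  switch(col,
         sex = c("male", "female"),
         race_ethnicity = fc_race_levels,
         marital = fc_marital_levels,
         education = fc_education_levels,
         NULL)
}

make_dummies <- function(v, col) {
  lev <- fc_known_levels(col)
  f <- if (is.null(lev)) factor(v) else factor(v, levels = lev)
  f <- droplevels(f)
  if (nlevels(f) < 2) {
    return(matrix(numeric(0), nrow = length(v), ncol = 0))
  }
  m <- vapply(levels(f)[-1], function(l) as.numeric(f == l),
              numeric(length(v)))
  colnames(m) <- paste(col, levels(f)[-1], sep = "_")
  m
}

# drop exactly collinear (aliased) columns, keeping the leftmost ones;
# e.g. DFE is by definition food folate + folic acid / 0.6
drop_aliased <- function(X) {
  qrx <- qr(X)
  if (qrx$rank == ncol(X)) return(list(X = X, aliased = character()))
  aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
  list(X = X[, setdiff(colnames(X), aliased), drop = FALSE], aliased = aliased)
}

# assemble the raw design matrix in a deterministic column order
build_X <- function(data, exposure, spline, covariates) {
  n <- nrow(data)
  cols <- list("(Intercept)" = rep(1, n))
  xb <- if (is.null(spline)) {
    matrix(data[[exposure]], ncol = 1, dimnames = list(NULL, exposure))
  } else {
    b <- rcs_basis(data[[exposure]], spline)
    colnames(b) <- c(exposure, paste0(exposure, "_rcs1"))
    b
  }
  for (j in seq_len(ncol(xb))) cols[[colnames(xb)[j]]] <- xb[, j]
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.character(v) || is.factor(v)) {
      dm <- make_dummies(v, cv)
      for (j in seq_len(ncol(dm))) cols[[colnames(dm)[j]]] <- dm[, j]
    } else if (is.logical(v)) {
      cols[[cv]] <- as.numeric(v)
    } else {
      cols[[cv]] <- as.numeric(v)
      if (cv == "age") cols[["age_sq"]] <- as.numeric(v)^2
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Build an adjusted regression design matrix
#'
#' Assembles intercept + exposure (optionally with its restricted cubic
#' spline column) + dummy-coded categorical and continuous covariates from
#' complete-case rows, in a deterministic column order. Age contributes both
#' a linear and a squared column. Columns with zero variance (for instance a
#' single-sex stratum) are dropped with a warning naming them.
#'
#' @param data Cohort tibble (derived columns present if `egfr` is among the
#'   covariates; see [derive_cohort()]).
#' @param outcome Name of the response column.
#' @param exposure Name of the exposure column.
#' @param spline Optional `"spline_spec"`; when supplied the spline column is
#'   included.
#' @param covariates Character vector of covariate columns
#'   (default [fc_covariates()]); use `NULL` for an unadjusted design.
#' @param drop Columns to force-drop (used internally to keep counterfactual
#'   designs aligned with the fitted one).
#' @return List of class `"fc_design"`: `X`, `y`, `data` (complete-case
#'   rows), `outcome`, `exposure`, `spline`, `covariates`, `dropped`.
#' @export
build_design <- function(data, outcome, exposure, spline = NULL,
                         covariates = fc_covariates(), drop = NULL) {
  if (exposure %in% covariates) {
    stop_fc("`exposure` must not be duplicated among the covariates.",
            "fc_config_error")
  }
  used <- unique(c(outcome, exposure, covariates))
  absent <- setdiff(used, names(data))
  if (length(absent) > 0) {
    stop_fc(sprintf("column(s) not found in `data`: %s (run derive_cohort()?)",
                    paste(absent, collapse = ", ")), "fc_schema_error")
  }
  cc <- !Reduce(`|`, lapply(data[used], is.na))
  dat <- data[cc, , drop = FALSE]
  if (nrow(dat) == 0) {
    stop_fc("no complete-case rows for the requested design.", "fc_design_error")
  }
  # categorical covariates with a single observed level contribute no columns
  degenerate_cat <- covariates[vapply(covariates, function(cv) {
    v <- dat[[cv]]
    (is.character(v) || is.factor(v)) && length(unique(v)) < 2
  }, logical(1))]
  X <- build_X(dat, exposure, spline, covariates)
  keep_var <- apply(X, 2, function(col) stats::sd(col) > 0)
  keep_var["(Intercept)"] <- TRUE
  zero_var <- colnames(X)[!keep_var]
  if ((length(zero_var) > 0 || length(degenerate_cat) > 0) && is.null(drop)) {
    warn(sprintf("dropping zero-variance column(s): %s",
                 paste(c(degenerate_cat, zero_var), collapse = ", ")),
         class = "fc_singular_warning")
  }
  dropped <- union(zero_var, drop %||% character())
  X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  if (is.null(drop)) {
    # aliased covariates (exact linear combinations, e.g. DFE given food
    # folate and folic acid) are dropped silently but recorded
    al <- drop_aliased(X)
    X <- al$X
    dropped <- union(dropped, al$aliased)
  }
  structure(list(X = X, y = dat[[outcome]], data = dat, outcome = outcome,
                 exposure = exposure, spline = spline,
                 covariates = covariates, dropped = dropped),
            class = "fc_design")
}

#' Ordinary least squares with Gaussian log-likelihood
#'
#' Fits `y ~ X` by QR-based least squares and returns the coefficient
#' vector, its covariance `sigma^2 (X'X)^-1`, the residual sum of squares,
#' and the Gaussian profile log-likelihood
#' `-(n/2) (log(2 pi RSS / n) + 1)`. A residual sum of squares of exactly
#' zero (a perfect fit) is floored at `.Machine$double.eps * (n - 1) * var(y)`
#' before the logarithm, so the log-likelihood stays finite.
#'
#' @param X Numeric design matrix (including any intercept column).
#' @param y Numeric response.
#' @return List of class `"ols_fit"`: `coefficients`, `vcov`, `rss`,
#'   `loglik`, `sigma2`, `n`, `p`, `fitted`, `residuals`.
#' @export
fit_ols <- function(X, y) {
  n <- length(y)
  p <- ncol(X)
  if (n <= p) {
    stop_fc("need more observations than parameters.", "fc_estimation_error")
  }
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop_fc(sprintf("design is rank deficient; collinear column(s): %s",
                    paste(bad, collapse = ", ")),
            "fc_estimation_error")
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  sigma2 <- rss / (n - p)
  XtX_inv <- chol2inv(qr.R(qrx))[order(qrx$pivot), order(qrx$pivot), drop = FALSE]
  vc <- sigma2 * XtX_inv
  dimnames(vc) <- list(colnames(X), colnames(X))
  rss_floor <- max(rss, .Machine$double.eps * max(var(y) * (n - 1), 1))
  ll <- -(n / 2) * (log(2 * pi * rss_floor / n) + 1)
  structure(list(coefficients = beta, vcov = vc, rss = rss, loglik = ll,
                 sigma2 = sigma2, n = n, p = p, fitted = fitted,
                 residuals = res),
            class = "ols_fit")
}

#' Likelihood-ratio test for non-linearity
#'
#' Compares the spline model against the nested linear model on the same
#' rows: `LR = 2 (loglik_full - loglik_reduced) = n log(RSS_reduced /
#' RSS_full)`, referred to a chi-square with `df = p_full - p_reduced`
#' degrees of freedom (1 for the 3-knot restricted cubic spline basis).
#'
#' @param fit_linear Reduced-model `"ols_fit"` (spline column removed).
#' @param fit_spline Full-model `"ols_fit"`.
#' @return Tibble with `statistic`, `df`, `p.value`.
#' @export
lr_nonlinearity <- function(fit_linear, fit_spline) {
  if (fit_linear$n != fit_spline$n) {
    stop_fc("models were fitted on different numbers of rows.",
            "fc_contract_error")
  }
  df <- fit_spline$p - fit_linear$p
  if (df <= 0) {
    stop_fc("the reduced model must be nested in the full model.",
            "fc_contract_error")
  }
  lr <- max(0, 2 * (fit_spline$loglik - fit_linear$loglik))
  tibble(statistic = lr, df = df,
         p.value = pchisq(lr, df, lower.tail = FALSE))
}

#' Fit an adjusted restricted-cubic-spline dose-response model
#'
#' End-to-end convenience wrapper: places knots at the 10th/50th/90th
#' percentiles of the complete-case exposure, fits the covariate-adjusted
#' spline model and its nested linear model by OLS, and runs the
#' likelihood-ratio test for non-linearity.
#'
#' @inheritParams build_design
#' @param knot_percentiles Percentiles for [compute_knots()].
#' @return Object of class `"rcs_model"`: `outcome`, `exposure`, `spline`,
#'   `design`, `fit`, `fit_linear`, `nonlinearity`.
#' @examples
#' sim <- generate_cohort(synth_config(n = 400, seed = 7))
#' dat <- apply_eligibility(sim$cohort)$cohort
#' m <- rcs_fit(dat, "cerad_wl", "rbc_folate")
#' glance(m)
#' @export
rcs_fit <- function(data, outcome, exposure, covariates = fc_covariates(),
                    knot_percentiles = c(10, 50, 90)) {
  used <- unique(c(outcome, exposure, covariates))
  cc <- !Reduce(`|`, lapply(data[used], is.na))
  spline <- compute_knots(data[[exposure]][cc], knot_percentiles)
  design <- build_design(data, outcome, exposure, spline, covariates)
  design_lin <- build_design(data, outcome, exposure, NULL, covariates,
                             drop = design$dropped)
  fit <- fit_ols(design$X, design$y)
  fit_linear <- fit_ols(design_lin$X, design_lin$y)
  structure(list(outcome = outcome, exposure = exposure, spline = spline,
                 design = design, fit = fit, fit_linear = fit_linear,
                 nonlinearity = lr_nonlinearity(fit_linear, fit)),
            class = "rcs_model")
}

#' Adjusted dose-response curve with 95% confidence band
#'
#' Predicts the adjusted score over a grid of exposure values. The default
#' (`at = "average"`) is the population-average (g-computation) curve: for
#' each grid value the fitted design rows are re-evaluated with the exposure
#' set to that value and the predictions averaged over the observed
#' covariate distribution. `at = "means"` instead evaluates a single row
#' with every covariate fixed at its sample mean. The confidence band is
#' `estimate +/- z * SE` with the delta-method standard error
#' `sqrt(xbar' V xbar)`.
#'
#' @param model An `"rcs_model"`.
#' @param grid Numeric grid of exposure values; defaults to 100 points
#'   spanning the observed range. Values outside the observed exposure range
#'   raise an extrapolation error.
#' @param at `"average"` (population-average, default) or `"means"`.
#' @param level Confidence level (default 0.95).
#' @return Tibble with columns `exposure`, `estimate`, `se`, `conf.low`,
#'   `conf.high`.
#' @export
predict_curve <- function(model, grid = NULL, at = c("average", "means"),
                          level = 0.95) {
  at <- match.arg(at)
  design <- model$design
  xobs <- design$data[[design$exposure]]
  if (is.null(grid)) {
    grid <- seq(min(xobs), max(xobs), length.out = 100)
  }
  if (any(grid < min(xobs) | grid > max(xobs))) {
    stop_fc("grid extends beyond the observed exposure range.",
            "fc_extrapolation_error")
  }
  beta <- model$fit$coefficients
  V <- model$fit$vcov
  z <- qnorm((1 + level) / 2)
  base <- design$data
  rows <- purrr::map(grid, function(g) {
    cf <- base
    cf[[design$exposure]] <- g
    Xg <- build_X(cf, design$exposure, design$spline, design$covariates)
    Xg <- Xg[, setdiff(colnames(Xg), design$dropped), drop = FALSE]
    xbar <- if (at == "average") colMeans(Xg) else {
      cm <- colMeans(build_X(base, design$exposure, design$spline,
                             design$covariates))
      cm <- cm[setdiff(names(cm), design$dropped)]
      # covariates at means, exposure terms at the grid value
      expo_cols <- c(design$exposure, paste0(design$exposure, "_rcs1"))
      cm[intersect(expo_cols, colnames(Xg))] <-
        colMeans(Xg[, intersect(expo_cols, colnames(Xg)), drop = FALSE])
      cm
    }
    est <- sum(xbar * beta[names(xbar)])
    se <- sqrt(drop(t(xbar) %*% V[names(xbar), names(xbar)] %*% xbar))
    tibble(exposure = g, estimate = est, se = se,
           conf.low = est - z * se, conf.high = est + z * se)
  })
  dplyr::bind_rows(rows)
}

#' Stratified spline fits by vitamin B12 status
#'
#' Repeats the full spline pipeline independently within each stratum of a
#' grouping variable (by default the derived low/normal vitamin B12 status).
#' Strata with too few complete-case rows for the requested design are
#' skipped with a warning.
#'
#' @inheritParams rcs_fit
#' @param group Name of the stratifying column; rows with a missing value
#'   are excluded.
#' @return Tibble with one row per fitted stratum: `stratum`, `n`, the
#'   non-linearity `statistic`, `df` and `p.value`, and the `"rcs_model"`
#'   in the list-column `model`.
#' @export
subgroup_fits <- function(data, outcome, exposure, group = "b12_status",
                          covariates = fc_covariates(),
                          knot_percentiles = c(10, 50, 90)) {
  strata <- sort(unique(data[[group]][!is.na(data[[group]])]))
  out <- purrr::map(strata, function(s) {
    dat <- data[!is.na(data[[group]]) & data[[group]] == s, , drop = FALSE]
    m <- tryCatch(
      rcs_fit(dat, outcome, exposure, covariates, knot_percentiles),
      error = function(e) {
        warn(sprintf("stratum '%s' skipped: %s", s, conditionMessage(e)),
             class = "fc_small_stratum")
        NULL
      })
    if (is.null(m)) return(NULL)
    tibble(stratum = s, n = m$fit$n,
           statistic = m$nonlinearity$statistic,
           df = m$nonlinearity$df, p.value = m$nonlinearity$p.value,
           model = list(m))
  })
  dplyr::bind_rows(out)
}

#' Likelihood-ratio test for exposure-by-modifier interaction
#'
#' Tests whether a binary modifier (by default the low/normal vitamin B12
#' status) changes the exposure dose-response: the model with products of
#' the spline basis and the modifier is compared against the model with main
#' effects only. With the 3-knot basis the test has 2 degrees of freedom
#' (one per product column).
#'
#' @inheritParams rcs_fit
#' @param modifier Name of a binary column (two observed levels required).
#' @return Tibble with `statistic`, `df`, `p.value`.
#' @export
interaction_lr <- function(data, outcome, exposure, modifier = "b12_status",
                           covariates = fc_covariates(),
                           knot_percentiles = c(10, 50, 90)) {
  used <- unique(c(outcome, exposure, modifier, covariates))
  cc <- !Reduce(`|`, lapply(data[used], is.na))
  dat <- data[cc, , drop = FALSE]
  mod_levels <- sort(unique(dat[[modifier]]))
  if (length(mod_levels) != 2) {
    stop_fc("`modifier` must take exactly two observed values.",
            "fc_contract_error")
  }
  spline <- compute_knots(dat[[exposure]], knot_percentiles)
  design <- build_design(dat, outcome, exposure, spline, covariates)
  mvec <- as.numeric(design$data[[modifier]] == mod_levels[2])
  basis <- rcs_basis(design$data[[exposure]], spline)
  X_main <- cbind(design$X, modifier = mvec)
  X_full <- cbind(X_main,
                  mod_x = mvec * basis[, 1],
                  mod_rcs1 = mvec * basis[, 2])
  fit_main <- fit_ols(X_main, design$y)
  fit_full <- fit_ols(X_full, design$y)
  lr_nonlinearity(fit_main, fit_full)
}

#' @export
tidy.ols_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(se),
         statistic = unname(x$coefficients / se),
         p.value = 2 * stats::pt(abs(x$coefficients / se),
                                 df = x$n - x$p, lower.tail = FALSE))
}

#' @export
glance.ols_fit <- function(x, ...) {
  tibble(n = x$n, p = x$p, rss = x$rss, sigma = sqrt(x$sigma2),
         logLik = x$loglik)
}

#' @export
tidy.rcs_model <- function(x, ...) tidy(x$fit)

#' @export
glance.rcs_model <- function(x, ...) {
  dplyr::bind_cols(glance(x$fit),
                   tibble(lr_nonlinearity = x$nonlinearity$statistic,
                          df_nonlinearity = x$nonlinearity$df,
                          p_nonlinearity = x$nonlinearity$p.value))
}

#' @export
print.rcs_model <- function(x, ...) {
  cat(sprintf("Restricted cubic spline model: %s ~ %s (knots %s)\n",
              x$outcome, x$exposure,
              paste(signif(x$spline$knots, 4), collapse = ", ")))
  cat(sprintf("n = %d, RSS = %.4g, LR non-linearity = %.3f (df %d), p = %.4g\n",
              x$fit$n, x$fit$rss, x$nonlinearity$statistic,
              x$nonlinearity$df, x$nonlinearity$p.value))
  invisible(x)
}

#' Plot an adjusted dose-response curve
#'
#' @param object An `"rcs_model"`.
#' @param ... Passed to [predict_curve()].
#' @return A ggplot: adjusted score with its confidence ribbon.
#' @export
autoplot.rcs_model <- function(object, ...) {
  curve <- predict_curve(object, ...)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$exposure, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = object$exposure,
                  y = sprintf("adjusted %s", object$outcome))
}
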