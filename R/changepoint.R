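#' Candidate change-point grid
#'
#' "All possible values" of the change point, operationalized as the unique
#' observed exposure values inside a percentile window (default 5th-95th)
#' with at least `min_per_side` observations on each side (at or below vs
#' strictly above the candidate). Untrimmed extremes would yield degenerate
#' one-sided fits.
#'
#' @param x Numeric exposure values (missing dropped).
#' @param trim_lo,trim_hi Percentile bounds for candidates (defaults 5, 95).
#' @param min_per_side Minimum observations required on each side of a
#'   candidate (default 10).
#' @return Sorted numeric vector of candidate change points.
#' @export
candidate_grid <- function(x, trim_lo = 5, trim_hi = 95, min_per_side = 10) {
  x <- x[!is.na(x)]
  ux <- sort(unique(x))
  if (length(ux) < 2) {
    stop_fc("not enough distinct exposure values for a candidate grid.",
            "fc_grid_error")
  }
  bounds <- quantile(x, c(trim_lo, trim_hi) / 100, type = 7)
  cand <- ux[ux >= bounds[1] & ux <= bounds[2]]
  n_below <- vapply(cand, function(c) sum(x <= c), numeric(1))
  n_above <- vapply(cand, function(c) sum(x > c), numeric(1))
  cand <- cand[n_below >= min_per_side & n_above >= min_per_side]
  if (length(cand) == 0) {
    stop_fc("candidate change-point grid is empty after trimming.",
            "fc_grid_error")
  }
  cand
}

#' Fit a two-line piecewise linear model by exhaustive profile likelihood
#'
#' For every candidate change point `c`, fits the continuous hinge model
#' `y ~ 1 + x + (x - c)+ [+ covariates]` by OLS and keeps the candidate
#' minimizing the residual sum of squares (equivalently maximizing the
#' Gaussian likelihood). Ties in RSS are broken by the smaller candidate.
#' The full profile of candidates and their log-likelihoods is retained.
#'
#' @param x Exposure vector.
#' @param y Response vector.
#' @param covariates Optional numeric matrix (or data frame) of adjustment
#'   columns; rows aligned with `x`/`y`.
#' @param grid Candidate change points (default [candidate_grid()] of `x`).
#' @return Object of class `"changepoint_fit"`: `breakpoint`,
#'   `coefficients` (named: intercept, slope_below, slope_change, then any
#'   covariates), `slope_above`, `se` (same order), `rss`, `loglik`, `n`,
#'   `profile` (tibble `candidate`, `rss`, `loglik`), `skipped` (candidates
#'   whose design was singular).
#' @examples
#' x <- runif(300, 0, 10)
#' y <- two_line(x, c = 6, b0 = 1, b1 = 2, b2 = -3)
#' fit_changepoint(x, y)$breakpoint
#' @export
fit_changepoint <- function(x, y, covariates = NULL, grid = NULL) {
  cc <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    cc <- cc & stats::complete.cases(covariates)
    covariates <- covariates[cc, , drop = FALSE]
  }
  x <- x[cc]; y <- y[cc]
  if (is.null(grid)) grid <- candidate_grid(x)
  if (length(grid) == 0) {
    stop_fc("empty candidate grid.", "fc_grid_error")
  }
  n <- length(y)
  best <- NULL
  skipped <- numeric(0)
  prof_rss <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    c0 <- grid[i]
    X <- cbind(intercept = 1, slope_below = x,
               slope_change = pmax(x - c0, 0), covariates)
    fit <- stats::.lm.fit(X, y)
    if (fit$rank < ncol(X)) {
      skipped <- c(skipped, c0)
      next
    }
    rss <- sum(fit$residuals^2)
    prof_rss[i] <- rss
    # strict improvement over an ascending grid: ties go to the smaller c
    if (is.null(best) || rss < best$rss) best <- list(c = c0, rss = rss)
  }
  if (is.null(best)) {
    stop_fc("every candidate change point gave a singular design.",
            "fc_grid_error")
  }
  # refit at the optimum with full inference
  Xb <- cbind(intercept = 1, slope_below = x,
              slope_change = pmax(x - best$c, 0), covariates)
  ols <- fit_ols(Xb, y)
  loglik <- function(rss) {
    rssf <- pmax(rss, .Machine$double.eps * max(var(y) * (n - 1), 1))
    -(n / 2) * (log(2 * pi * rssf / n) + 1)
  }
  profile <- tibble(candidate = grid, rss = prof_rss,
                    loglik = loglik(prof_rss))
  structure(
    list(breakpoint = best$c,
         coefficients = ols$coefficients,
         slope_above = unname(ols$coefficients["slope_below"] +
                                ols$coefficients["slope_change"]),
         se = sqrt(diag(ols$vcov)),
         rss = best$rss, loglik = ols$loglik, n = n,
         profile = profile, skipped = skipped),
    class = "changepoint_fit")
}

#' Scan change points for every marker-by-test pair
#'
#' Runs [fit_changepoint()] for each combination of exposures and outcomes
#' on complete-case rows, optionally adjusted for the standard covariates.
#'
#' @param data Cohort tibble (derived columns present when adjusting).
#' @param exposures,outcomes Character vectors (default the four markers and
#'   the four cognitive tests).
#' @param adjust Include the standard covariates ([fc_covariates()]) in the
#'   change-point model (default `TRUE`).
#' @param ... Passed to [candidate_grid()].
#' @return Tibble with columns `marker`, `test`, and the `"changepoint_fit"`
#'   in the list-column `fit`.
#' @export
breakpoint_scan <- function(data, exposures = fc_markers(),
                            outcomes = fc_tests(), adjust = TRUE, ...) {
  combos <- tidyr::expand_grid(marker = exposures, test = outcomes)
  fits <- purrr::pmap(combos, function(marker, test) {
    used <- c(marker, test, if (adjust) fc_covariates())
    cc <- !Reduce(`|`, lapply(data[used], is.na))
    dat <- data[cc, , drop = FALSE]
    covm <- NULL
    if (adjust) {
      covm <- build_X(dat, marker, NULL, fc_covariates())
      covm <- covm[, setdiff(colnames(covm), c("(Intercept)", marker)),
                   drop = FALSE]
      covm <- covm[, apply(covm, 2, function(v) stats::sd(v) > 0), drop = FALSE]
      covm <- drop_aliased(covm)$X
    }
    grid <- candidate_grid(dat[[marker]], ...)
    fit_changepoint(dat[[marker]], dat[[test]], covariates = covm, grid = grid)
  })
  combos$fit <- fits
  combos
}

#' Tidy change-point report table
#'
#' Flattens a [breakpoint_scan()] result into one row per marker-by-test
#' pair with the estimated breakpoint and both slopes.
#'
#' @param fits Tibble from [breakpoint_scan()], or an empty tibble.
#' @return Tibble with columns `marker`, `test`, `breakpoint`,
#'   `slope_below`, `slope_above`, `rss`, `n`.
#' @export
breakpoint_report <- function(fits) {
  if (is.null(fits) || nrow(fits) == 0) {
    return(tibble(marker = character(), test = character(),
                  breakpoint = numeric(), slope_below = numeric(),
                  slope_above = numeric(), rss = numeric(), n = integer()))
  }
  purrr::pmap_dfr(fits, function(marker, test, fit) {
    tibble(marker = marker, test = test, breakpoint = fit$breakpoint,
           slope_below = unname(fit$coefficients["slope_below"]),
           slope_above = fit$slope_above, rss = fit$rss, n = fit$n)
  })
}

#' @export
tidy.changepoint_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se[names(x$coefficients)]))
}

#' @export
glance.changepoint_fit <- function(x, ...) {
  tibble(breakpoint = x$breakpoint,
         slope_below = unname(x$coefficients["slope_below"]),
         slope_above = x$slope_above,
         rss = x$rss, logLik = x$loglik, n = x$n,
         n_candidates = nrow(x$profile))
}

#' @export
print.changepoint_fit <- function(x, ...) {
  cat(sprintf(
    "Two-line change-point fit: breakpoint %.4g (slopes %.4g / %.4g), n = %d\n",
    x$breakpoint, x$coefficients["slope_below"], x$slope_above, x$n))
  invisible(x)
}

#' Plot the profile log-likelihood of a change-point fit
#'
#' @param object A `"changepoint_fit"`.
#' @param ... Ignored.
#' @return A ggplot of profile log-likelihood against the candidate change
#'   point, with the chosen breakpoint marked.
#' @export
autoplot.changepoint_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$candidate, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$breakpoint, linetype = 2) +
    ggplot2::labs(x = "candidate change point", y = "profile log-likelihood")
}
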