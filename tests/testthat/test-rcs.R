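test_that("knots are the empirical percentiles under the declared quantile rule", {
  x <- 1:100
  sp <- compute_knots(x, c(10, 50, 90))
  # order-statistic oracle: type-7 linear interpolation, h = (n-1)p + 1
  oracle_q <- function(x, p) {
    xs <- sort(x); h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(x))] - xs[lo])
  }
  expect_equal(sp$knots, sapply(c(0.1, 0.5, 0.9), oracle_q, x = x))

  expect_error(compute_knots(rep(5, 50)), class = "fc_degenerate_knots")
  expect_error(compute_knots(1:10, c(50, 10, 90)), class = "fc_config_error")

  set.seed(1)
  x10 <- runif(10)
  k10 <- compute_knots(x10)$knots
  expect_true(all(diff(k10) > 0))
  expect_true(all(k10 >= min(x10) & k10 <= max(x10)))
})

test_that("restricted cubic spline basis matches the closed form and is linear in the tails", {
  set.seed(2)
  for (r in 1:10) {
    t <- sort(runif(3, 0, 10))
    x <- runif(100, -5, 15)
    b <- rcs_basis(x, t)
    expect_equal(b[, "x"], x)
    expect_equal(b[, "rcs1"], oracle_rcs(x, t[1], t[2], t[3]))
  }
  t <- c(2, 5, 9)
  expect_equal(rcs_basis(c(-3, 0, 2), t)[, "rcs1"], rep(0, 3))
  # second finite difference far beyond t3 vanishes (tail linearity)
  xx <- 50 + (0:2)
  r <- rcs_basis(xx, t)[, "rcs1"]
  expect_equal(r[3] - 2 * r[2] + r[1], 0, tolerance = 1e-8)
})

test_that("design matrix encodes covariates deterministically", {
  sim <- generate_cohort(synth_config(n = 300, seed = 44, missing_rate = 0))
  dat <- derive_cohort(sim$cohort)
  d <- build_design(dat, "cerad_wl", "rbc_folate",
                    spline = compute_knots(dat$rbc_folate))
  expect_equal(unname(d$X[, "age_sq"]), unname(d$X[, "age"])^2)
  # 6 observed marital categories -> 5 indicator columns
  expect_equal(sum(grepl("^marital_", colnames(d$X))), 5)
  # DFE is aliased with food folate + folic acid and silently recorded
  expect_true("dfe" %in% d$dropped)
  expect_equal(qr(d$X)$rank, ncol(d$X))

  dat_onesex <- dplyr::mutate(dat, sex = "female")
  expect_warning(build_design(dat_onesex, "cerad_wl", "rbc_folate"),
                 "sex", class = "fc_singular_warning")
  expect_error(build_design(dat, "cerad_wl", "rbc_folate",
                            covariates = c("age", "rbc_folate")),
               class = "fc_config_error")
})

test_that("OLS matches the normal-equations oracle and flags rank problems", {
  set.seed(3)
  for (r in 1:10) {
    n <- 20; p <- 4
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
    colnames(X) <- paste0("c", 1:p)
    y <- rnorm(n)
    fit <- fit_ols(X, y)
    expect_equal(unname(fit$coefficients), unname(drop(oracle_ols(X, y))),
                 tolerance = 1e-8)
    expect_equal(fit$rss, oracle_rss(X, y), tolerance = 1e-8)
    # covariance against explicit sigma^2 (X'X)^-1
    expect_equal(unname(fit$vcov),
                 unname(fit$rss / (n - p) * solve(crossprod(X))),
                 tolerance = 1e-8)
    # Gaussian profile log-likelihood identity
    expect_equal(fit$loglik, -(n / 2) * (log(2 * pi * fit$rss / n) + 1))
  }
  X <- cbind(1, rnorm(20)); X <- cbind(X, X[, 2])
  colnames(X) <- c("a", "b", "b_dup")
  expect_error(fit_ols(X, rnorm(20)), "b_dup", class = "fc_estimation_error")

  # perfect fit: RSS floored, log-likelihood finite
  x <- rnorm(30); Xp <- cbind(1, x); colnames(Xp) <- c("i", "x")
  fitp <- fit_ols(Xp, 2 + 3 * x)
  expect_equal(fitp$rss, 0, tolerance = 1e-20)
  expect_true(is.finite(fitp$loglik))
})

test_that("likelihood-ratio test for non-linearity behaves as an LR test", {
  set.seed(4)
  n <- 120
  x <- runif(n, 0, 10)
  y <- 1 + 0.5 * x + rnorm(n)
  sp <- compute_knots(x)
  Xl <- cbind(1, x); colnames(Xl) <- c("i", "x")
  Xs <- cbind(1, rcs_basis(x, sp)); colnames(Xs) <- c("i", "x", "rcs1")
  fl <- fit_ols(Xl, y); fs <- fit_ols(Xs, y)
  lr <- lr_nonlinearity(fl, fs)
  expect_equal(lr$df, 1)
  expect_equal(lr$statistic, 2 * (fs$loglik - fl$loglik))
  expect_equal(lr$statistic, n * log(fl$rss / fs$rss), tolerance = 1e-8)
  expect_equal(lr$p.value, pchisq(lr$statistic, 1, lower.tail = FALSE))

  # identical RSS (no improvement from the extra parameter): LR = 0, p = 1
  same_ll <- structure(list(n = fs$n, p = fl$p + 1, loglik = fl$loglik),
                       class = "ols_fit")
  lr0 <- lr_nonlinearity(fl, same_ll)
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p.value, 1)
  fl2 <- fit_ols(Xl[1:100, ], y[1:100])
  expect_error(lr_nonlinearity(fl2, fs), class = "fc_contract_error")
})

test_that("the LR statistic is invariant to affine rescaling of the exposure", {
  sim <- generate_cohort(synth_config(n = 400, seed = 8, missing_rate = 0))
  dat <- derive_cohort(sim$cohort)
  m1 <- rcs_fit(dat, "cerad_wl", "rbc_folate")
  dat2 <- dplyr::mutate(dat, rbc_folate = 3.7 * rbc_folate + 11)
  m2 <- rcs_fit(dat2, "cerad_wl", "rbc_folate")
  expect_equal(m1$nonlinearity$statistic, m2$nonlinearity$statistic,
               tolerance = 1e-8)
})

test_that("adjusted curves match the delta-method oracle and stay linear past the last knot", {
  sim <- generate_cohort(synth_config(n = 500, seed = 9, missing_rate = 0))
  dat <- derive_cohort(sim$cohort)
  m <- rcs_fit(dat, "dsst", "vitamin_b12")
  grid <- as.numeric(quantile(m$design$data$vitamin_b12, c(0.2, 0.5, 0.8)))
  curve <- predict_curve(m, grid = grid)
  expect_true(all(curve$conf.low <= curve$estimate &
                    curve$estimate <= curve$conf.high))

  # delta-method oracle at one grid point by explicit matrix arithmetic
  g <- grid[2]
  cf <- m$design$data
  cf$vitamin_b12 <- g
  Xg <- folatecog:::build_X(cf, "vitamin_b12", m$spline, m$design$covariates)
  Xg <- Xg[, setdiff(colnames(Xg), m$design$dropped), drop = FALSE]
  xbar <- colMeans(Xg)
  est <- sum(xbar * m$fit$coefficients[names(xbar)])
  se <- sqrt(drop(t(xbar) %*% m$fit$vcov[names(xbar), names(xbar)] %*% xbar))
  expect_equal(curve$estimate[2], est)
  expect_equal(curve$se[2], se)

  # tail linearity of the fitted exposure effect beyond the last knot
  t3 <- m$spline$knots[3]
  xmax <- max(m$design$data$vitamin_b12)
  if (xmax > t3 * 1.05) {
    gg <- seq(t3 * 1.01, xmax, length.out = 4)
    cc <- predict_curve(m, grid = gg)
    slopes <- diff(cc$estimate) / diff(cc$exposure)
    expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-6)
  }

  expect_error(predict_curve(m, grid = xmax * 2),
               class = "fc_extrapolation_error")

  # at-the-means curve differs from population-average only through age^2
  cm <- predict_curve(m, grid = grid, at = "means")
  expect_equal(nrow(cm), 3)
})

test_that("confidence bands widen where exposure data are sparse", {
  set.seed(10)
  n <- 800
  x <- rexp(n, 1)           # right-skewed design
  y <- 1 + x + rnorm(n)
  dat <- tibble::tibble(y = y, x = x)
  sp <- compute_knots(x)
  d <- build_design(dat, "y", "x", spline = sp, covariates = NULL)
  fit <- fit_ols(d$X, d$y)
  m <- structure(list(outcome = "y", exposure = "x", spline = sp,
                      design = d, fit = fit), class = "rcs_model")
  q <- as.numeric(quantile(x, c(0.10, 0.99)))
  cc <- predict_curve(m, grid = q)
  expect_gt(cc$se[2], cc$se[1])
})

test_that("stratified fits run the pipeline per stratum and skip tiny strata", {
  sim <- generate_cohort(synth_config(n = 700, seed = 15, missing_rate = 0))
  dat <- derive_cohort(sim$cohort)
  sg <- subgroup_fits(dat, "cerad_wl", "rbc_folate")
  expect_equal(sort(sg$stratum), c("low", "normal"))
  expect_true(all(sg$p.value >= 0 & sg$p.value <= 1))

  dat_all_normal <- dplyr::mutate(dat, b12_status = "normal")
  sg1 <- subgroup_fits(dat_all_normal, "cerad_wl", "rbc_folate")
  expect_equal(nrow(sg1), 1)

  dat_tiny <- dat
  dat_tiny$b12_status <- c(rep("normal", nrow(dat) - 5), rep("low", 5))
  classes <- character()
  withCallingHandlers(
    sg2 <- subgroup_fits(dat_tiny, "cerad_wl", "rbc_folate"),
    warning = function(w) {
      classes <<- c(classes, class(w)[1])
      invokeRestart("muffleWarning")
    })
  expect_true("fc_small_stratum" %in% classes)
  expect_equal(nrow(sg2), 1)
})

test_that("interaction test is calibrated under the null and errors on a constant modifier", {
  # a modifier independent of the response given the design: null holds
  set.seed(16)
  reps <- 400
  n <- 150
  pvals <- replicate(reps, {
    x <- runif(n, 0, 10)
    y <- 1 + 0.8 * x + rnorm(n)
    mod <- sample(c("a", "b"), n, replace = TRUE)
    dat <- tibble::tibble(y = y, x = x, mod = mod)
    interaction_lr(dat, "y", "x", modifier = "mod", covariates = NULL)$p.value
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)

  dat <- tibble::tibble(y = rnorm(50), x = runif(50), mod = "a")
  expect_error(interaction_lr(dat, "y", "x", modifier = "mod",
                              covariates = NULL),
               class = "fc_contract_error")
})

test_that("interaction test detects a modifier that changes the slope", {
  set.seed(17)
  hits <- replicate(40, {
    n <- 2000
    x <- runif(n, 0, 10)
    mod <- sample(c("a", "b"), n, replace = TRUE)
    slope <- ifelse(mod == "b", 1.0, 0.5)  # modifier doubles the slope
    y <- 1 + slope * x + rnorm(n)
    dat <- tibble::tibble(y = y, x = x, mod = mod)
    interaction_lr(dat, "y", "x", modifier = "mod",
                   covariates = NULL)$p.value < 0.05
  })
  expect_gt(mean(hits), 0.5)
})
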