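test_that("min-max scaling maps the range onto [0, 1] and keeps its parameters", {
  dat <- tibble::tibble(a = c(0, 5, 10), b = c(2, 3, 4))
  res <- minmax_fit_transform(dat, c("a", "b"))
  expect_equal(res$scaled[, "a"], c(0, 0.5, 1))
  expect_equal(res$scaled[, "b"], c(0, 0.5, 1))
  expect_equal(res$params$value_min, c(0, 2))
  expect_equal(res$params$value_max, c(10, 4))

  set.seed(31)
  dat2 <- tibble::tibble(a = rlnorm(100), b = rnorm(100))
  sc <- minmax_fit_transform(dat2, c("a", "b"))$scaled
  expect_true(all(sc >= 0 & sc <= 1))

  expect_error(minmax_fit_transform(tibble::tibble(a = rep(1, 5)), "a"),
               class = "fc_scaling_error")
  # reapplying fitted parameters reproduces the transform
  expect_equal(minmax_apply(dat, res$params), res$scaled)
})

test_that("normalization then clustering is invariant to per-marker affine rescaling", {
  set.seed(32)
  X <- tibble::tibble(a = rlnorm(120, 0, 1), b = rlnorm(120, 1, 0.5))
  s1 <- minmax_fit_transform(X, c("a", "b"))$scaled
  X2 <- dplyr::mutate(X, a = 100 * a + 7, b = 0.01 * b - 3)
  s2 <- minmax_fit_transform(X2, c("a", "b"))$scaled
  expect_equal(s1, s2, tolerance = 1e-12)
  m1 <- kmeans_fit(s1, 3, restarts = 10, seed = 5)
  m2 <- kmeans_fit(s2, 3, restarts = 10, seed = 5)
  expect_equal(m1$cluster, m2$cluster)
})

test_that("k-means recovers a perfectly separable partition with zero WCSS", {
  X <- blob_matrix(k = 3, m = 12, d = 50)
  m <- kmeans_fit(X, 3, restarts = 5, seed = 1)
  expect_equal(m$wcss, 0)
  expect_equal(m$cluster, rep(1:3, each = 12))  # relabelled by appearance
  expect_equal(tabulate(m$cluster, 3), rep(12L, 3))
})

test_that("k-means is deterministic given a seed and never worse than random partitions", {
  set.seed(33)
  X <- matrix(rnorm(200), 100, 2)
  m1 <- kmeans_fit(X, 4, restarts = 20, seed = 9)
  m2 <- kmeans_fit(X, 4, restarts = 20, seed = 9)
  expect_identical(m1$cluster, m2$cluster)
  expect_identical(m1$wcss, m2$wcss)

  wcss_random <- replicate(1000, {
    cl <- sample(1:4, 100, replace = TRUE)
    sum(vapply(1:4, function(k) {
      Xi <- X[cl == k, , drop = FALSE]
      if (nrow(Xi) == 0) return(0)
      sum(sweep(Xi, 2, colMeans(Xi))^2)
    }, numeric(1)))
  })
  expect_lte(m1$wcss, min(wcss_random))

  # independent route: never beaten by stats::kmeans on the same data
  km <- stats::kmeans(X, 4, nstart = 50, iter.max = 100)
  expect_lte(m1$wcss, km$tot.withinss * 1.02)
})

test_that("Calinski-Harabasz equals the brute-force sum-of-squares oracle", {
  set.seed(34)
  X <- matrix(rnorm(300), 100, 3)
  cl <- sample(1:4, 100, replace = TRUE)
  expect_equal(calinski_harabasz(X, cl), oracle_ch(X, cl))

  # separation monotonicity: true blobs beat a random relabelling
  Xb <- blob_matrix(3, 15, 40) + matrix(rnorm(90, 0, 0.1), 45, 2)
  truth <- rep(1:3, each = 15)
  expect_gt(calinski_harabasz(Xb, truth),
            calinski_harabasz(Xb, sample(truth)))

  # degenerate: zero within-cluster scatter
  Xd <- blob_matrix(2, 5, 10)
  expect_equal(calinski_harabasz(Xd, rep(1:2, each = 5)), Inf)
  expect_error(calinski_harabasz(X, rep(1, 100)), class = "fc_domain_error")
})

test_that("K selection returns the CH argmax with a full score table", {
  set.seed(35)
  X <- blob_matrix(3, 30, 30) + matrix(rnorm(180, 0, 0.5), 90, 2)
  sel <- select_k(X, 2:6, restarts = 10, seed = 3)
  expect_equal(sel$k, 3)
  expect_equal(nrow(sel$scores), 5)
  expect_equal(sel$scores$k[which.max(sel$scores$ch)], 3)

  sel2 <- select_k(X, k_range = 2, restarts = 5, seed = 3)
  expect_equal(sel2$k, 2)
  expect_error(select_k(X, 1:3, restarts = 5, seed = 1),
               class = "fc_domain_error")

  # a single Gaussian blob still returns a K without error
  Xg <- matrix(rnorm(200), 100, 2)
  selg <- select_k(Xg, 2:4, restarts = 5, seed = 4)
  expect_true(selg$k %in% 2:4)
})

test_that("Jaccard similarity follows the set formula", {
  expect_equal(jaccard(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(jaccard(1:5, 1:5), 1)
  expect_equal(jaccard(1:3, 4:6), 0)
  expect_error(jaccard(integer(0), integer(0)), class = "fc_domain_error")
})

test_that("bootstrap stability is high for separable clusters and reproducible", {
  X <- blob_matrix(3, 25, 30) + matrix(rnorm(150, 0, 0.3), 75, 2)
  m <- kmeans_fit(X, 3, restarts = 10, seed = 2)
  s1 <- bootstrap_stability(X, m, B = 50, seed = 7, restarts = 5)
  expect_equal(nrow(s1), 3)
  expect_true(all(s1$mean_jaccard > 0.95))
  expect_true(all(s1$dissolved == 0))
  s2 <- bootstrap_stability(X, m, B = 50, seed = 7, restarts = 5)
  expect_equal(s1$mean_jaccard, s2$mean_jaccard, tolerance = 1e-12)
  expect_error(bootstrap_stability(X, m, B = 0, seed = 1),
               class = "fc_domain_error")
})

test_that("heavily overlapping mixtures are less stable than separated ones", {
  set.seed(36)
  Xo <- matrix(rnorm(800, 0, 1), 400, 2)  # one blob forced into 4 clusters
  mo <- kmeans_fit(Xo, 4, restarts = 10, seed = 2)
  so <- bootstrap_stability(Xo, mo, B = 60, seed = 3, restarts = 10)
  expect_true(any(so$mean_jaccard < 0.8))
})

test_that("cluster phenotype tables follow the ANOVA / chi-square arithmetic", {
  set.seed(37)
  sim <- generate_cohort(synth_config(n = 300, seed = 37, missing_rate = 0))
  dat <- sim$cohort
  cl <- sim$truth$cluster
  ph <- cluster_phenotype(dat, cl, vars = c(fc_markers(), "mma", "umfa"))
  expect_equal(nrow(ph), 6)  # six marker rows
  expect_true(all(c("cluster_1", "cluster_2", "cluster_3") %in% names(ph)))

  # one-way ANOVA F against an explicit sum-of-squares decomposition
  v <- dat$rbc_folate
  k <- length(unique(cl)); n <- length(v)
  gm <- mean(v)
  ssb <- sum(tapply(v, cl, function(g) length(g) * (mean(g) - gm)^2))
  ssw <- sum(tapply(v, cl, function(g) sum((g - mean(g))^2)))
  f_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(ph$statistic[ph$variable == "rbc_folate"][1], f_oracle,
               tolerance = 1e-8)

  # identical group means give F = 0, p = 1
  datc <- tibble::tibble(v = rep(c(1, 2, 3), times = 3))
  clc <- rep(1:3, each = 3)
  phc <- cluster_phenotype(datc, clc, vars = "v")
  expect_equal(phc$statistic, 0)
  expect_equal(phc$p.value, 1)

  # categorical variables get count (%) rows per level and a chi-square p
  phs <- cluster_phenotype(dat, cl, vars = "sex")
  expect_equal(nrow(phs), 2)
  expect_equal(phs$test, rep("chisq", 2))
})

test_that("recovered cluster ordering matches the generator's low/medium/high pattern", {
  sim <- generate_cohort(synth_config(n = 1200, seed = 38, missing_rate = 0))
  dat <- sim$cohort
  norm <- minmax_fit_transform(dat)
  m <- kmeans_fit(norm$scaled, 3, restarts = 20, seed = 6)
  tab <- table(m$cluster, sim$truth$cluster)
  acc <- sum(apply(tab, 2, max)) / nrow(dat)
  expect_gt(acc, 0.9)
  # each recovered cluster inherits the serum-folate rank of its matched
  # truth component (low < medium < high)
  rec_means <- tapply(dat$serum_total_folate, m$cluster, mean)
  true_means <- tapply(dat$serum_total_folate, sim$truth$cluster, mean)
  matched <- apply(tab, 1, which.max)
  expect_equal(rank(rec_means), rank(true_means[matched]),
               ignore_attr = TRUE)
  expect_gt(max(rec_means) / min(rec_means), 2)
})
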