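#' Min-max normalization of clustering features
#'
#' Rescales each marker to `[0, 1]` via
#' `(value - value_min) / (value_max - value_min)` and retains the per-marker
#' minima and maxima so the same scaling can be reapplied (or refitted) on
#' resamples.
#'
#' @param data Tibble or data frame holding the marker columns.
#' @param cols Columns to scale (default the four markers, [fc_markers()]).
#' @return List with `params` (tibble `marker`, `value_min`, `value_max`)
#'   and `scaled` (numeric matrix, one column per marker, values in
#'   `[0, 1]`).
#' @export
minmax_fit_transform <- function(data, cols = fc_markers()) {
  vals <- lapply(cols, function(cn) data[[cn]])
  rng <- lapply(vals, range, na.rm = TRUE)
  bad <- cols[vapply(rng, function(r) !is.finite(r[1]) || r[2] <= r[1],
                     logical(1))]
  if (length(bad) > 0) {
    stop_fc(sprintf("constant (or empty) marker(s) cannot be min-max scaled: %s",
                    paste(bad, collapse = ", ")), "fc_scaling_error")
  }
  scaled <- vapply(seq_along(cols), function(j) {
    (vals[[j]] - rng[[j]][1]) / (rng[[j]][2] - rng[[j]][1])
  }, numeric(nrow(data)))
  colnames(scaled) <- cols
  params <- tibble(marker = cols,
                   value_min = vapply(rng, `[`, numeric(1), 1),
                   value_max = vapply(rng, `[`, numeric(1), 2))
  list(params = params, scaled = scaled)
}

#' Apply previously fitted min-max scaling parameters
#'
#' @param data Tibble with the marker columns.
#' @param params Params tibble from [minmax_fit_transform()].
#' @return Numeric matrix (values may fall outside `[0, 1]` if the new data
#'   exceed the fitted range).
#' @export
minmax_apply <- function(data, params) {
  scaled <- vapply(seq_len(nrow(params)), function(j) {
    (data[[params$marker[j]]] - params$value_min[j]) /
      (params$value_max[j] - params$value_min[j])
  }, numeric(nrow(data)))
  colnames(scaled) <- params$marker
  scaled
}

# squared Euclidean distances from every row of X to every center (n x K)
dist2_to_centers <- function(X, centers) {
  n2x <- rowSums(X^2)
  n2c <- rowSums(centers^2)
  outer(n2x, n2c, `+`) - 2 * X %*% t(centers)
}

# k-means++ seeding: first center uniform, later ones with probability
# proportional to the squared distance to the nearest chosen center
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in seq_len(k)[-1]) {
    p <- pmax(d2, 0)
    if (sum(p) == 0) p <- rep(1, n)
    centers[j, ] <- X[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

# one Lloyd run; empty clusters are re-seeded from the farthest point
lloyd <- function(X, centers, max_iter = 300, tol = 1e-6) {
  k <- nrow(centers)
  wcss_prev <- Inf
  assign <- rep(1L, nrow(X))
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centers(X, centers)
    assign <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      members <- assign == j
      if (!any(members)) {
        far <- which.max(d2[cbind(seq_len(nrow(X)), assign)])
        centers[j, ] <- X[far, ]
        assign[far] <- j
        members <- assign == j
      }
      centers[j, ] <- colMeans(X[members, , drop = FALSE])
    }
    wcss <- sum((X - centers[assign, , drop = FALSE])^2)
    # Lloyd's objective never increases; guard against numerical slip
    if (wcss > wcss_prev + 1e-8 * (1 + wcss_prev)) {
      stop_fc("within-cluster sum of squares increased during Lloyd iteration.",
              "fc_internal_error")
    }
    if (wcss_prev - wcss <= tol * (1 + wcss)) {
      return(list(centers = centers, cluster = assign, wcss = wcss, iter = it))
    }
    wcss_prev <- wcss
  }
  list(centers = centers, cluster = assign, wcss = wcss_prev, iter = max_iter)
}

#' K-means with k-means++ restarts
#'
#' Lloyd's algorithm from `restarts` independent k-means++ initializations;
#' the solution with the lowest within-cluster sum of squares is kept. A
#' cluster emptied during iteration is re-seeded from the point farthest
#' from its center. Deterministic given `seed`. Clusters are relabelled in
#' order of appearance (first record belongs to cluster 1).
#'
#' @param X Numeric matrix of (normalized) features, one row per record.
#' @param k Number of clusters (`>= 2`, `<= nrow(X)`).
#' @param restarts Independent initializations (default 10,000, the
#'   field-scale setting; a few dozen are adequate for well-separated data).
#' @param seed Integer seed.
#' @param max_iter,tol Lloyd iteration cap and relative convergence
#'   tolerance.
#' @return Object of class `"kmeans_model"`: `k`, `centers`, `cluster`,
#'   `wcss`, `ch` (Calinski-Harabasz score), `restarts`, `seed`, `iter`.
#' @export
kmeans_fit <- function(X, k, restarts = 10000, seed = 1L,
                       max_iter = 300, tol = 1e-6) {
  X <- as.matrix(X)
  if (k < 2 || k > nrow(X)) {
    stop_fc("`k` must be between 2 and the number of records.",
            "fc_domain_error")
  }
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(restarts)) {
      run <- lloyd(X, kmeanspp_init(X, k), max_iter, tol)
      if (is.null(best) || run$wcss < best$wcss) best <- run
    }
  })
  relabelled <- match(best$cluster, unique(best$cluster))
  centers <- best$centers[unique(best$cluster), , drop = FALSE]
  structure(list(k = k, centers = centers, cluster = relabelled,
                 wcss = best$wcss,
                 ch = calinski_harabasz(X, relabelled),
                 restarts = restarts, seed = seed, iter = best$iter),
            class = "kmeans_model")
}

#' Calinski-Harabasz score
#'
#' Ratio of between- to within-cluster dispersion, each scaled by its
#' degrees of freedom: `CH = [B / (K - 1)] / [W / (n - K)]` where `B` is the
#' between-cluster and `W` the within-cluster sum of squares. A perfectly
#' tight clustering (`W = 0`) returns `Inf`.
#'
#' @param X Numeric feature matrix.
#' @param cluster Integer assignments, one per row of `X`.
#' @return The score (larger = better separated).
#' @export
calinski_harabasz <- function(X, cluster) {
  X <- as.matrix(X)
  k <- length(unique(cluster))
  if (k < 2) {
    stop_fc("Calinski-Harabasz needs at least 2 clusters.", "fc_domain_error")
  }
  n <- nrow(X)
  grand <- colMeans(X)
  W <- 0; B <- 0
  for (j in unique(cluster)) {
    Xi <- X[cluster == j, , drop = FALSE]
    ck <- colMeans(Xi)
    W <- W + sum(sweep(Xi, 2, ck)^2)
    B <- B + nrow(Xi) * sum((ck - grand)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of clusters by the Calinski-Harabasz score
#'
#' Fits K-means for each candidate K and returns the K with the highest
#' score (ties broken by the smaller K), together with the full per-K table
#' for reporting.
#'
#' @param X Numeric feature matrix.
#' @param k_range Candidate numbers of clusters (default 2..8).
#' @param restarts,seed Passed to [kmeans_fit()]; each K uses a sub-seed
#'   derived from `seed`.
#' @return List of class `"k_selection"`: `k` (the selected K), `scores`
#'   (tibble `k`, `wcss`, `ch`), `model` (the fitted model at the selected
#'   K).
#' @export
select_k <- function(X, k_range = 2:8, restarts = 100, seed = 1L) {
  X <- as.matrix(X)
  if (any(k_range < 2 | k_range > nrow(X) - 1)) {
    stop_fc("`k_range` must lie within [2, n - 1].", "fc_domain_error")
  }
  models <- lapply(seq_along(k_range), function(i) {
    kmeans_fit(X, k_range[i], restarts = restarts,
               seed = seed + i - 1L)
  })
  scores <- tibble(
    k = k_range,
    wcss = vapply(models, `[[`, numeric(1), "wcss"),
    ch = vapply(models, `[[`, numeric(1), "ch"))
  best <- which.max(scores$ch)  # which.max takes the first (smallest K) tie
  structure(list(k = k_range[best], scores = scores, model = models[[best]]),
            class = "k_selection")
}

#' Jaccard similarity of two record sets
#'
#' `|A intersect B| / |A union B|`. Undefined (error) when both sets are
#' empty.
#'
#' @param a,b Vectors of record identifiers.
#' @return Similarity in `[0, 1]`.
#' @examples
#' jaccard(1:3, 2:4)  # 0.5
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) {
    stop_fc("Jaccard similarity of two empty sets is undefined.",
            "fc_domain_error")
  }
  length(intersect(a, b)) / u
}

#' Bootstrap Jaccard stability of a clustering
#'
#' Case-resampling cluster stability in the style of bootstrap cluster
#' validation: for each of `B` bootstrap resamples (with replacement, full
#' n), K-means is re-run at the same K; each original cluster is matched to
#' the resample cluster with the maximum Jaccard similarity, computed on the
#' records present in the resample; the per-original-cluster mean Jaccard
#' over resamples and the number of dissolutions (Jaccard < 0.5) are
#' reported. By default each resample is re-scaled with its own min-max
#' parameters (min-max scaling of a resample is unaffected by any prior
#' per-marker affine scaling, so passing already-normalized features is
#' equivalent to re-scaling the raw ones).
#'
#' @param X Feature matrix the model was fitted on (normalized space).
#' @param model A `"kmeans_model"` fitted on `X`.
#' @param B Number of bootstrap resamples (field-scale 2000).
#' @param seed Integer seed.
#' @param restarts Restarts for each bootstrap refit (default 20).
#' @param rescale Re-apply min-max scaling within each resample (default
#'   `TRUE`).
#' @return Object of class `"stability_report"`: tibble `cluster`, `n`,
#'   `mean_jaccard`, `dissolved` (count of resamples with Jaccard < 0.5),
#'   plus attributes `B` and `seed`.
#' @export
bootstrap_stability <- function(X, model, B = 2000, seed = 1L,
                                restarts = 20, rescale = TRUE) {
  X <- as.matrix(X)
  if (B < 1) {
    stop_fc("`B` must be at least 1.", "fc_domain_error")
  }
  n <- nrow(X)
  k <- model$k
  orig <- split(seq_len(n), model$cluster)
  jac <- matrix(NA_real_, B, k)
  withr::with_seed(seed, {
    sub_seeds <- sample.int(2^30, B)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      if (rescale) {
        rng_lo <- apply(Xb, 2, min)
        rng_hi <- apply(Xb, 2, max)
        if (any(rng_hi <= rng_lo)) next  # degenerate resample, skip
        Xb <- sweep(sweep(Xb, 2, rng_lo), 2, rng_hi - rng_lo, `/`)
      }
      mb <- kmeans_fit(Xb, k, restarts = restarts, seed = sub_seeds[b])
      present <- unique(idx)
      resample_sets <- split(idx, mb$cluster)
      resample_sets <- lapply(resample_sets, unique)
      for (j in seq_len(k)) {
        oj <- intersect(orig[[j]], present)
        if (length(oj) == 0) next
        jac[b, j] <- max(vapply(resample_sets, jaccard, numeric(1), a = oj))
      }
    }
  })
  out <- tibble(
    cluster = seq_len(k),
    n = lengths(orig),
    mean_jaccard = colMeans(jac, na.rm = TRUE),
    dissolved = colSums(jac < 0.5, na.rm = TRUE))
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  class(out) <- c("stability_report", class(out))
  out
}

#' Per-cluster phenotype tables (ANOVA / chi-square)
#'
#' Summarizes variables across clusters: continuous variables get per-cluster
#' mean (SD) and a one-way ANOVA p-value; categorical variables get count
#' (%) per level and a Pearson chi-square p-value. One row per continuous
#' variable, one row per level of each categorical variable.
#'
#' @param data Cohort tibble.
#' @param cluster Integer assignments aligned with `data` rows.
#' @param vars Variables to summarize (default: the four markers plus MMA
#'   and UMFA, followed by the four cognitive tests).
#' @return Tibble with columns `variable`, `level`, per-cluster formatted
#'   summaries (`cluster_1`, ...), `statistic`, `p.value`, `test`.
#' @export
cluster_phenotype <- function(data, cluster,
                              vars = c(fc_markers(), "mma", "umfa", fc_tests())) {
  stopifnot(nrow(data) == length(cluster))
  ks <- sort(unique(cluster))
  rows <- purrr::map(vars, function(vn) {
    v <- data[[vn]]
    if (is.numeric(v)) {
      by_k <- vapply(ks, function(k) {
        vi <- v[cluster == k & !is.na(v)]
        if (length(vi) < 2) return(NA_character_)
        sprintf("%.2f (%.2f)", mean(vi), sd(vi))
      }, character(1))
      ok <- !is.na(v)
      an <- stats::anova(stats::lm(v[ok] ~ factor(cluster[ok])))
      out <- tibble(variable = vn, level = NA_character_,
                    statistic = an$`F value`[1], p.value = an$`Pr(>F)`[1],
                    test = "anova")
      for (i in seq_along(ks)) out[[paste0("cluster_", ks[i])]] <- by_k[i]
      out
    } else {
      tabv <- table(factor(v), factor(cluster, levels = ks))
      stat <- tryCatch(chisq_groups(unclass(tabv)),
                       error = function(e) tibble(statistic = NA_real_,
                                                  p.value = NA_real_))
      lev_rows <- purrr::map(rownames(tabv), function(l) {
        out <- tibble(variable = vn, level = l,
                      statistic = stat$statistic[1], p.value = stat$p.value[1],
                      test = "chisq")
        for (i in seq_along(ks)) {
          cnt <- tabv[l, i]
          out[[paste0("cluster_", ks[i])]] <-
            sprintf("%d (%.1f)", cnt, 100 * cnt / sum(tabv[, i]))
        }
        out
      })
      dplyr::bind_rows(lev_rows)
    }
  })
  dplyr::bind_rows(rows) |>
    dplyr::relocate(dplyr::starts_with("cluster_"),
                    .after = "level")
}

#' @export
tidy.kmeans_model <- function(x, ...) {
  centers <- as_tibble(x$centers)
  centers$cluster <- seq_len(x$k)
  centers$size <- tabulate(x$cluster, x$k)
  dplyr::relocate(centers, "cluster", "size")
}

#' @export
glance.kmeans_model <- function(x, ...) {
  tibble(k = x$k, wcss = x$wcss, ch = x$ch, restarts = x$restarts,
         seed = x$seed)
}

#' @export
augment.kmeans_model <- function(x, data, ...) {
  data$.cluster <- x$cluster
  data
}

#' @export
tidy.k_selection <- function(x, ...) x$scores

#' @export
print.kmeans_model <- function(x, ...) {
  cat(sprintf("K-means model: k = %d, WCSS = %.4g, CH = %.4g (sizes: %s)\n",
              x$k, x$wcss, x$ch,
              paste(tabulate(x$cluster, x$k), collapse = ", ")))
  invisible(x)
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("Calinski-Harabasz K selection: K = %d\n", x$k))
  print(x$scores)
  invisible(x)
}

#' Plot the Calinski-Harabasz score against K
#'
#' @param object A `"k_selection"`.
#' @param ... Ignored.
#' @return A ggplot with the selected K marked.
#' @export
autoplot.k_selection <- function(object, ...) {
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$k, y = .data$ch)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = 2) +
    ggplot2::labs(x = "number of clusters K", y = "Calinski-Harabasz score")
}

#' Plot per-cluster bootstrap Jaccard stability
#'
#' @param object A `"stability_report"`.
#' @param ... Ignored.
#' @return A ggplot bar chart with the conventional 0.5 dissolution and 0.8
#'   stability reference lines.
#' @export
autoplot.stability_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$cluster),
                                       y = .data$mean_jaccard)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(0.5, 0.8), linetype = c(3, 2)) +
    ggplot2::labs(x = "cluster", y = "mean bootstrap Jaccard")
}
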