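#' Two-sample t-test for continuous baseline variables
#'
#' Pooled-variance Student's t-test by default (the convention for baseline
#' tables); Welch's unequal-variance variant available.
#'
#' @param values_a,values_b Numeric vectors (each with at least 2 non-missing
#'   values).
#' @param variant `"student"` (pooled variance, default) or `"welch"`.
#' @return Tibble with `statistic`, `df`, `p.value`, `estimate` (mean
#'   difference a - b).
#' @export
ttest_groups <- function(values_a, values_b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2 || length(b) < 2) {
    stop_fc("each group needs at least 2 observations.", "fc_domain_error")
  }
  if (variant == "student") {
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    if (sp2 == 0) {
      stop_fc("zero pooled variance: t-test is degenerate.", "fc_domain_error")
    }
  }
  tt <- stats::t.test(a, b, var.equal = variant == "student")
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p.value = tt$p.value, estimate = mean(a) - mean(b))
}

#' Pooled-variance t-test from group summaries
#'
#' Same test as [ttest_groups()] when only `(mean, SD, n)` per group are
#' available (for instance from a published table).
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @return Tibble with `statistic`, `df`, `p.value`, `estimate`.
#' @export
ttest_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2 || n_b < 2) {
    stop_fc("each group needs at least 2 observations.", "fc_domain_error")
  }
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
  if (sp2 == 0) {
    stop_fc("zero pooled variance: t-test is degenerate.", "fc_domain_error")
  }
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  stat <- (mean_a - mean_b) / se
  df <- n_a + n_b - 2
  tibble(statistic = stat, df = df,
         p.value = 2 * stats::pt(abs(stat), df, lower.tail = FALSE),
         estimate = mean_a - mean_b)
}

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson chi-square, `df = (r - 1)(c - 1)`. All row and column
#' marginals must be positive.
#'
#' @param counts Numeric matrix of counts (rows = variable levels, columns =
#'   groups).
#' @return Tibble with `statistic`, `df`, `p.value`.
#' @export
chisq_groups <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop_fc("contingency table has a zero marginal.", "fc_domain_error")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p.value = ct$p.value)
}

#' Group percentage as printed in baseline tables
#'
#' `100 * count / total`, rounded to the requested number of decimals (one
#' by convention).
#'
#' @param count,total Counts.
#' @param digits Decimals to round to (default 1).
#' @return Numeric percentage.
#' @examples
#' group_percent(635, 2204)       # 28.8
#' group_percent(654, 2204, 2)    # 29.67
#' @export
group_percent <- function(count, total, digits = 1) {
  round(100 * count / total, digits)
}

#' Baseline comparison table
#'
#' Builds a baseline-characteristics comparison across the levels of a
#' grouping variable: continuous variables get mean, SD and n per group with
#' a pooled-variance t-test (two groups) or one-way ANOVA (three or more);
#' categorical variables get count and percentage per level with a Pearson
#' chi-square test. With a single group, summaries are returned without
#' tests. Percentages are `100 * count / group n`, rounded to one decimal;
#' means and SDs are carried at full precision.
#'
#' @param data Cohort tibble.
#' @param group Name of the grouping column (must be non-missing; missing
#'   rows are dropped).
#' @param vars Variables to compare; defaults to the standard baseline set
#'   present in `data`.
#' @return Tidy tibble with one row per group-by-variable(-by-level) cell:
#'   `variable`, `level`, `group`, `n`, `mean`, `sd`, `count`, `pct`,
#'   `statistic`, `p.value`, `test` (test columns repeated within variable).
#' @export
baseline_table <- function(data, group, vars = NULL) {
  if (is.null(vars)) {
    vars <- intersect(
      c("age", "sex", "race_ethnicity", "marital", "education", "bmi",
        "drinking", "smoking", "hypertension", "hyperlipidemia", "diabetes",
        "diet_total_folate", "diet_folic_acid", "food_folate", "dfe",
        "diet_b12", "impaired_cerad", "impaired_af", "impaired_dsst"),
      names(data))
  }
  keep <- !is.na(data[[group]])
  data <- data[keep, , drop = FALSE]
  gl <- sort(unique(data[[group]]))
  rows <- purrr::map(vars, function(vn) {
    v <- data[[vn]]
    if (is.numeric(v)) {
      per <- purrr::map(gl, function(g) {
        vi <- v[data[[group]] == g & !is.na(v)]
        tibble(variable = vn, level = NA_character_, group = as.character(g),
               n = length(vi), mean = mean(vi), sd = sd(vi),
               count = NA_integer_, pct = NA_real_)
      }) |> dplyr::bind_rows()
      tst <- NULL
      if (length(gl) == 2) {
        tst <- tryCatch(
          ttest_groups(v[data[[group]] == gl[1]], v[data[[group]] == gl[2]]),
          error = function(e) NULL)
        if (!is.null(tst)) tst$test <- "t"
      } else if (length(gl) > 2) {
        ok <- !is.na(v)
        an <- stats::anova(stats::lm(v[ok] ~ factor(data[[group]][ok])))
        tst <- tibble(statistic = an$`F value`[1], p.value = an$`Pr(>F)`[1],
                      test = "anova")
      }
      if (is.null(tst)) {
        tst <- tibble(statistic = NA_real_, p.value = NA_real_,
                      test = NA_character_)
      }
      dplyr::bind_cols(per, tst[rep(1, nrow(per)), c("statistic", "p.value", "test")])
    } else {
      vf <- factor(v)
      tab <- table(vf, factor(data[[group]], levels = gl))
      tst <- if (length(gl) >= 2 && nrow(tab) >= 2) {
        tryCatch(dplyr::bind_cols(chisq_groups(unclass(tab)),
                                  tibble(test = "chisq")),
                 error = function(e) tibble(statistic = NA_real_,
                                            p.value = NA_real_,
                                            test = NA_character_))
      } else {
        tibble(statistic = NA_real_, p.value = NA_real_, test = NA_character_)
      }
      per <- purrr::map(levels(vf), function(l) {
        purrr::map(seq_along(gl), function(gi) {
          gn <- sum(tab[, gi])
          tibble(variable = vn, level = l, group = as.character(gl[gi]),
                 n = gn, mean = NA_real_, sd = NA_real_,
                 count = as.integer(tab[l, gi]),
                 pct = group_percent(tab[l, gi], gn))
        }) |> dplyr::bind_rows()
      }) |> dplyr::bind_rows()
      dplyr::bind_cols(per, tst[rep(1, nrow(per)), c("statistic", "p.value", "test")])
    }
  })
  dplyr::bind_rows(rows)
}
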