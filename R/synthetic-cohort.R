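#' Marker and cognitive test names used throughout the package
#'
#' The four folate/B12 status markers used as exposures (and as clustering
#' features) and the four cognitive outcomes.
#'
#' @format Character vectors.
#' @name fc_names
NULL

#' @rdname fc_names
#' @export
fc_markers <- function() {
  c("rbc_folate", "serum_total_folate", "five_methyl_thf", "vitamin_b12")
}

#' @rdname fc_names
#' @export
fc_tests <- function() {
  c("cerad_wl", "cerad_dr", "af", "dsst")
}

# fixed category sets matching common survey codings
fc_race_levels <- c("MA", "Hispanic", "NHW", "NHB", "Other")
fc_marital_levels <- c("married", "widowed", "divorced", "separated",
                       "never_married", "living_with_partner")
fc_education_levels <- c("less_than_9th", "grade_9_11", "hs_grad_ged",
                         "some_college_aa", "college_grad_plus")

#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. The defaults
#' describe an elderly (60+) cohort of about 2200 participants whose four
#' folate/B12 markers arise from a well-separated three-component log-normal
#' mixture (a low, an intermediate, and a high folate/B12-status subgroup),
#' and whose cognitive scores follow an inverted-U (two-line piecewise
#' linear) dose-response in a designated driver marker plus additive
#' covariate effects and Gaussian noise.
#'
#' @param n Number of participants.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   `(config, seed)`.
#' @param cluster_weights Length-3 positive mixing proportions summing to 1,
#'   ordered low / medium / high folate-B12 status.
#' @param cluster_means 3 x 4 matrix of log-scale means (rows = clusters in
#'   the order of `cluster_weights`, columns = [fc_markers()]).
#' @param cluster_sds 3 x 4 matrix of log-scale standard deviations.
#' @param breakpoints Tibble with columns `marker`, `test`, `breakpoint`,
#'   `slope_below`, `slope_above`: the true piecewise linear effects. Each
#'   test's score receives the sum of the two-line contributions of the rows
#'   naming that test (default: one driver marker per test).
#' @param covariate_effects Tibble with columns `test`, `age`, `female`,
#'   `education`: additive effects of age (per year), female sex, and
#'   education level (ordinal 1-5) on each score.
#' @param intercepts Named numeric, intercept per cognitive test.
#' @param noise_sd Named numeric, residual standard deviation per test
#'   (score units); all `>= 0`.
#' @param missing_rate Fraction of records in which one field (chosen
#'   uniformly among the missable fields) is set missing, completely at
#'   random.
#' @param b12_deficient_frac Target fraction of records meeting the low
#'   vitamin B12 rule (serum B12 < 148 pmol/L or MMA > 210 nmol/L). With 0,
#'   no record is flagged low.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n = 2204,
                         seed = 1L,
                         cluster_weights = c(low = 0.65, medium = 0.30, high = 0.05),
                         cluster_means = NULL,
                         cluster_sds = NULL,
                         breakpoints = default_breakpoints(),
                         covariate_effects = default_covariate_effects(),
                         intercepts = c(cerad_wl = 16, cerad_dr = 5, af = 16.8, dsst = 51),
                         noise_sd = c(cerad_wl = 3, cerad_dr = 1.5, af = 2.5, dsst = 6),
                         missing_rate = 0.05,
                         b12_deficient_frac = 0.288) {
  if (is.null(cluster_means)) {
    cluster_means <- log(rbind(
      low    = c(rbc_folate = 1000, serum_total_folate = 42,  five_methyl_thf = 39,  vitamin_b12 = 403),
      medium = c(rbc_folate = 2100, serum_total_folate = 80,  five_methyl_thf = 72,  vitamin_b12 = 565),
      high   = c(rbc_folate = 1900, serum_total_folate = 190, five_methyl_thf = 165, vitamin_b12 = 2700)
    ))
  }
  if (is.null(cluster_sds)) {
    cluster_sds <- matrix(0.15, 3, 4,
                          dimnames = dimnames(cluster_means))
  }
  check_scalar(n, "n", function(v) is.numeric(v) && v > 0 && v == round(v),
               "a positive integer")
  check_scalar(seed, "seed", is.numeric, "an integer")
  if (length(cluster_weights) != 3 || any(cluster_weights <= 0) ||
      abs(sum(cluster_weights) - 1) > 1e-8) {
    stop_fc("`cluster_weights` must be 3 positive proportions summing to 1.",
            "fc_config_error")
  }
  stopifnot(is.matrix(cluster_means), dim(cluster_means) == c(3, 4),
            is.matrix(cluster_sds), dim(cluster_sds) == c(3, 4))
  if (is.null(colnames(cluster_means))) {
    colnames(cluster_means) <- fc_markers()
  }
  if (is.null(rownames(cluster_means))) {
    rownames(cluster_means) <- c("low", "medium", "high")
  }
  dimnames(cluster_sds) <- dimnames(cluster_means)
  if (any(cluster_sds < 0)) {
    stop_fc("`cluster_sds` must be non-negative.", "fc_config_error")
  }
  # 5MeTHF is a component of serum total folate
  if (any(cluster_means[, "five_methyl_thf"] > cluster_means[, "serum_total_folate"])) {
    stop_fc("log-scale 5MeTHF mean exceeds serum total folate mean in some cluster.",
            "fc_config_error")
  }
  stopifnot(is.data.frame(breakpoints),
            all(c("marker", "test", "breakpoint", "slope_below", "slope_above")
                %in% names(breakpoints)))
  if (any(noise_sd < 0)) {
    stop_fc("`noise_sd` must be non-negative.", "fc_config_error")
  }
  check_scalar(missing_rate, "missing_rate",
               function(v) is.numeric(v) && v >= 0 && v < 1, "in [0, 1)")
  check_scalar(b12_deficient_frac, "b12_deficient_frac",
               function(v) is.numeric(v) && v >= 0 && v <= 1, "in [0, 1]")
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         cluster_weights = cluster_weights,
         cluster_means = cluster_means, cluster_sds = cluster_sds,
         breakpoints = as_tibble(breakpoints),
         covariate_effects = as_tibble(covariate_effects),
         intercepts = intercepts, noise_sd = noise_sd,
         missing_rate = missing_rate,
         b12_deficient_frac = b12_deficient_frac),
    class = "synth_config")
}

#' Default true change-point effects for the synthetic cohort
#'
#' One driver marker per cognitive test, each with an inverted-U two-line
#' effect (positive slope below the breakpoint, negative above). Slopes are
#' sized so that the hinge effect spans roughly twice the default residual
#' noise over the bulk of the marker distribution.
#'
#' @return Tibble with columns `marker`, `test`, `breakpoint`, `slope_below`,
#'   `slope_above`.
#' @export
default_breakpoints <- function() {
  tibble(
    marker = fc_markers(),
    test = fc_tests(),
    breakpoint = c(1700, 75, 70, 600),
    slope_below = c(0.0065, 0.073, 0.128, 0.044),
    slope_above = c(-0.0065, -0.073, -0.128, -0.012)
  )
}

#' Default covariate effects on the cognitive scores
#'
#' @return Tibble with columns `test`, `age`, `female`, `education`.
#' @export
default_covariate_effects <- function() {
  tibble(
    test = fc_tests(),
    age = c(-0.10, -0.05, -0.12, -0.45),
    female = c(1.2, 0.4, 0, 2.0),
    education = c(0.6, 0.2, 0.8, 3.0)
  )
}

# truncated draws via inverse-CDF so a single uniform stream drives everything
rlnorm_trunc <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  p_lo <- stats::plnorm(lower, meanlog, sdlog)
  p_hi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(p_lo + runif(n) * (p_hi - p_lo), meanlog, sdlog)
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(p_lo + runif(n) * (p_hi - p_lo), mean, sd)
}

#' Generate a synthetic elderly cohort with known ground truth
#'
#' Draws `config$n` participants aged 60+ with demographics, comorbidity
#' flags, serum creatinine, a three-component log-normal mixture of the four
#' folate/B12 markers (plus passively generated MMA and UMFA), dietary folate
#' variables, and four cognitive scores built as
#' `intercept + two-line(driver marker) + covariate effects + Gaussian noise`.
#' The latent cluster label, the low-B12 indicator, and the parameters
#' actually used are returned as the ground truth. Identical `(config, seed)`
#' yield identical cohorts.
#'
#' @param config A [synth_config()].
#' @return A list with elements `cohort` (tibble, one row per participant)
#'   and `truth` (list of class `"synth_truth"`: `cluster`, `low_b12`,
#'   `config`, `seed`).
#' @examples
#' cfg <- synth_config(n = 200, seed = 42)
#' sim <- generate_cohort(cfg)
#' dplyr::count(sim$cohort, cut(vitamin_b12, c(0, 148, Inf)))
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synth_config")) {
    stop_fc("`config` must be created by `synth_config()`.", "fc_config_error")
  }
  n <- config$n
  withr::with_seed(config$seed, {
    cluster <- sample.int(3L, n, replace = TRUE, prob = config$cluster_weights)

    # demographics, NHANES-like marginals for a 60+ population
    age <- round(rnorm_trunc(n, 69, 6.7, lower = 60, upper = 80), 1)
    sex <- ifelse(runif(n) < 0.503, "female", "male")
    race_ethnicity <- sample(fc_race_levels, n, replace = TRUE,
                             prob = c(0.092, 0.105, 0.500, 0.218, 0.086))
    marital <- sample(fc_marital_levels, n, replace = TRUE,
                      prob = c(0.571, 0.176, 0.143, 0.024, 0.055, 0.030))
    education <- sample(fc_education_levels, n, replace = TRUE,
                        prob = c(0.104, 0.132, 0.231, 0.289, 0.244))
    bmi <- round(rnorm_trunc(n, 29.0, 6.2, lower = 15, upper = 60), 1)
    smoking <- runif(n) < 0.496
    drinking <- runif(n) < 0.700
    hypertension <- runif(n) < 0.594
    hyperlipidemia <- runif(n) < 0.552
    diabetes <- runif(n) < 0.211
    stroke_history <- runif(n) < 0.03
    # creatinine such that eGFR is mostly, but not always, >= 60
    creat_med <- ifelse(sex == "female", 0.78, 0.95)
    serum_creatinine <- round(rlnorm_trunc(n, log(creat_med), 0.18), 2)

    # markers: per-cluster log-normal draws
    mk <- matrix(NA_real_, n, 4, dimnames = list(NULL, fc_markers()))
    for (k in 1:3) {
      idx <- which(cluster == k)
      for (j in seq_along(fc_markers())) {
        mk[idx, j] <- rlnorm(length(idx),
                             config$cluster_means[k, j], config$cluster_sds[k, j])
      }
    }

    # low-B12 ground truth: Bernoulli flag, then draw B12/MMA consistent
    # with the flag (low = B12 < 148 pmol/L or MMA > 210 nmol/L)
    low_b12 <- runif(n) < config$b12_deficient_frac
    mma <- numeric(n)
    mma_med <- c(160, 155, 120)[cluster]  # passive marker, lowest in the high cluster
    mechanism <- runif(n)
    for (i in seq_len(n)) {
      if (low_b12[i]) {
        if (mechanism[i] < 0.4) {        # low serum B12 only
          mk[i, "vitamin_b12"] <- rlnorm_trunc(1, log(115), 0.2, upper = 148 - 1e-9)
          mma[i] <- rlnorm_trunc(1, log(mma_med[i]), 0.35, upper = 210)
        } else if (mechanism[i] < 0.8) { # elevated MMA only
          mk[i, "vitamin_b12"] <- max(mk[i, "vitamin_b12"], 148)
          mma[i] <- rlnorm_trunc(1, log(300), 0.45, lower = 210 + 1e-9)
        } else {                         # both
          mk[i, "vitamin_b12"] <- rlnorm_trunc(1, log(115), 0.2, upper = 148 - 1e-9)
          mma[i] <- rlnorm_trunc(1, log(300), 0.45, lower = 210 + 1e-9)
        }
      } else {
        mk[i, "vitamin_b12"] <- max(mk[i, "vitamin_b12"], 148)
        mma[i] <- rlnorm_trunc(1, log(mma_med[i]), 0.35, upper = 210)
      }
    }
    umfa <- rlnorm(n, log(c(1.0, 2.5, 6.0)[cluster]), 1.0)

    # diet
    diet_folic_acid <- round(rlnorm(n, log(110), 0.8), 1)
    food_folate <- round(rlnorm(n, log(180), 0.55), 1)
    diet_total_folate <- diet_folic_acid + food_folate
    dfe <- food_folate + diet_folic_acid / 0.6
    diet_b12 <- round(rlnorm(n, log(0.35), 1.2), 2)

    # cognitive scores
    female <- as.numeric(sex == "female")
    edu_level <- match(education, fc_education_levels)
    scores <- matrix(0, n, 4, dimnames = list(NULL, fc_tests()))
    for (tn in fc_tests()) {
      y <- rep(config$intercepts[[tn]], n)
      rows <- config$breakpoints[config$breakpoints$test == tn, , drop = FALSE]
      for (r in seq_len(nrow(rows))) {
        y <- y + two_line(mk[, rows$marker[r]], rows$breakpoint[r],
                          b0 = 0, b1 = rows$slope_below[r],
                          b2 = rows$slope_above[r] - rows$slope_below[r])
      }
      ce <- config$covariate_effects[config$covariate_effects$test == tn, , drop = FALSE]
      if (nrow(ce) == 1) {
        y <- y + ce$age * age + ce$female * female + ce$education * edu_level
      }
      y <- y + rnorm(n, 0, config$noise_sd[[tn]])
      scores[, tn] <- y
    }

    cohort <- tibble(
      id = seq_len(n),
      age = age, sex = sex, race_ethnicity = race_ethnicity,
      marital = marital, education = education, bmi = bmi,
      smoking = smoking, drinking = drinking, hypertension = hypertension,
      hyperlipidemia = hyperlipidemia, diabetes = diabetes,
      stroke_history = stroke_history,
      serum_creatinine = serum_creatinine,
      rbc_folate = mk[, "rbc_folate"],
      serum_total_folate = mk[, "serum_total_folate"],
      five_methyl_thf = mk[, "five_methyl_thf"],
      vitamin_b12 = mk[, "vitamin_b12"],
      mma = mma, umfa = umfa,
      diet_total_folate = diet_total_folate,
      diet_folic_acid = diet_folic_acid,
      food_folate = food_folate, dfe = dfe, diet_b12 = diet_b12,
      cerad_wl = scores[, "cerad_wl"], cerad_dr = scores[, "cerad_dr"],
      af = scores[, "af"], dsst = scores[, "dsst"]
    )

    # completely-at-random missingness: one missable field per hit record
    if (config$missing_rate > 0) {
      missable <- c("bmi", "serum_creatinine", fc_markers(), "mma", "umfa",
                    "diet_total_folate", "diet_folic_acid", "food_folate",
                    "dfe", "diet_b12", fc_tests())
      hit <- which(runif(n) < config$missing_rate)
      field <- sample(missable, length(hit), replace = TRUE)
      for (j in seq_along(hit)) {
        cohort[[field[j]]][hit[j]] <- NA
      }
    }

    truth <- structure(
      list(cluster = cluster, low_b12 = low_b12,
           config = config, seed = config$seed),
      class = "synth_truth")
    list(cohort = cohort, truth = truth)
  })
}

#' Write a synthetic cohort and its ground truth to disk
#'
#' The cohort is written as CSV; the truth (latent cluster labels, low-B12
#' flags, and the generating parameters) as a JSON sidecar next to it.
#'
#' @param sim Result of [generate_cohort()].
#' @param path Output CSV path; the sidecar gets the extension `.truth.json`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(sim, path) {
  readr::write_csv(sim$cohort, path)
  truth <- sim$truth
  side <- list(
    seed = truth$seed,
    cluster = truth$cluster,
    low_b12 = truth$low_b12,
    cluster_weights = truth$config$cluster_weights,
    cluster_means = truth$config$cluster_means,
    cluster_sds = truth$config$cluster_sds,
    breakpoints = truth$config$breakpoints,
    covariate_effects = truth$config$covariate_effects,
    intercepts = truth$config$intercepts,
    noise_sd = truth$config$noise_sd
  )
  jsonlite::write_json(side, paste0(tools::file_path_sans_ext(path), ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
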