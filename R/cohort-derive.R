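#' Columns expected in a participant-level cohort table
#'
#' The full column dictionary for a cohort file: demographics, comorbidity
#' flags, serum creatinine, folate/B12 biomarkers, dietary folate variables,
#' and the four cognitive scores.
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c("id", "age", "sex", "race_ethnicity", "marital", "education", "bmi",
    "smoking", "drinking", "hypertension", "hyperlipidemia", "diabetes",
    "stroke_history", "serum_creatinine",
    fc_markers(), "mma", "umfa",
    "diet_total_folate", "diet_folic_acid", "food_folate", "dfe", "diet_b12",
    fc_tests())
}

# fields that must be non-missing for a record to count as complete
required_fields <- function() {
  setdiff(cohort_columns(), c("umfa", "diet_b12"))
}

#' Read a cohort table from delimited text
#'
#' Reads a CSV/TSV cohort file, optionally renaming file columns to the
#' package's column dictionary via `column_map`, coerces each column to its
#' expected type, and records provenance (source path, rows read, cells that
#' failed to parse and became missing).
#'
#' @param path Path to a delimited text file (delimiter inferred from the
#'   extension: `.tsv`/`.txt` tab, otherwise comma).
#' @param column_map Optional named character vector mapping package column
#'   names to file column names, e.g. `c(rbc_folate = "LBDRFO")`.
#' @param required Columns that must be present after mapping; a missing one
#'   raises a schema error naming it. Defaults to [cohort_columns()] minus
#'   the optional `umfa` and `diet_b12`.
#' @return A tibble with attribute `provenance` (list: `source`, `n`,
#'   `unparseable_cells`).
#' @export
read_cohort <- function(path, column_map = NULL,
                        required = setdiff(cohort_columns(), c("umfa", "diet_b12"))) {
  if (!file.exists(path)) {
    stop_fc(sprintf("cohort file not found: %s", path), "fc_schema_error")
  }
  delim <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           na = c("", "NA"), progress = FALSE,
                           show_col_types = FALSE)
  if (!is.null(column_map)) {
    for (internal in names(column_map)) {
      if (column_map[[internal]] %in% names(raw)) {
        names(raw)[names(raw) == column_map[[internal]]] <- internal
      }
    }
  }
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop_fc(sprintf("required column(s) missing from %s: %s",
                    path, paste(missing_cols, collapse = ", ")),
            "fc_schema_error")
  }

  chr_cols <- c("sex", "race_ethnicity", "marital", "education")
  lgl_cols <- c("smoking", "drinking", "hypertension", "hyperlipidemia",
                "diabetes", "stroke_history")
  num_cols <- setdiff(intersect(cohort_columns(), names(raw)),
                      c(chr_cols, lgl_cols))
  unparseable <- 0L
  out <- raw
  for (cn in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cn]]))
    unparseable <- unparseable + sum(is.na(v) & !is.na(raw[[cn]]))
    out[[cn]] <- v
  }
  for (cn in intersect(lgl_cols, names(raw))) {
    v <- tolower(raw[[cn]])
    parsed <- dplyr::case_when(
      v %in% c("true", "t", "1", "yes") ~ TRUE,
      v %in% c("false", "f", "0", "no") ~ FALSE,
      .default = NA
    )
    unparseable <- unparseable + sum(is.na(parsed) & !is.na(raw[[cn]]))
    out[[cn]] <- parsed
  }
  out <- as_tibble(out)
  attr(out, "provenance") <- list(source = path, n = nrow(out),
                                  unparseable_cells = unparseable)
  out
}

#' Estimated glomerular filtration rate (CKD-EPI 2009 creatinine equation)
#'
#' Computes eGFR in mL/min/1.73 m^2 from serum creatinine, age, sex and
#' Black race, using the 2009 CKD-EPI creatinine equation:
#' `141 * min(Scr/k, 1)^a * max(Scr/k, 1)^(-1.209) * 0.993^age * 1.018[female] * 1.159[Black]`
#' with `k = 0.7` (female) / `0.9` (male) and `a = -0.329` (female) /
#' `-0.411` (male).
#'
#' @param creatinine Serum creatinine, mg/dL (must be positive).
#' @param age Age in years (positive).
#' @param sex `"female"` or `"male"` (vectorized).
#' @param race_black Logical, Black race indicator.
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' compute_egfr(0.7, 60, "female", FALSE)
#' @export
compute_egfr <- function(creatinine, age, sex, race_black) {
  ok <- !is.na(creatinine)
  if (any(creatinine[ok] <= 0)) {
    stop_fc("`creatinine` must be positive.", "fc_domain_error")
  }
  if (any(age[!is.na(age)] <= 0)) {
    stop_fc("`age` must be positive.", "fc_domain_error")
  }
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  ratio <- creatinine / kappa
  141 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^(-1.209) * 0.993^age *
    ifelse(female, 1.018, 1) * ifelse(race_black, 1.159, 1)
}

#' Classify vitamin B12 status
#'
#' A participant has low vitamin B12 status when serum B12 is below
#' 148 pmol/L, or methylmalonic acid (MMA) is above 210 nmol/L, or both.
#' Both thresholds are strict.
#'
#' @param b12 Serum vitamin B12, pmol/L.
#' @param mma Methylmalonic acid, nmol/L.
#' @return Character vector, `"low"` / `"normal"`, `NA` when either input is
#'   missing (such records are excluded from status-stratified analyses).
#' @examples
#' classify_b12_status(c(147, 300, 148), c(100, 211, 210))
#' @export
classify_b12_status <- function(b12, mma) {
  ifelse(is.na(b12) | is.na(mma), NA_character_,
         ifelse(b12 < 148 | mma > 210, "low", "normal"))
}

#' Flag potential cognitive impairment from test scores
#'
#' Applies the conventional strict cutoffs: CERAD impairment requires both
#' word-learning < 17 and delayed recall < 5; Animal Fluency < 14; Digit
#' Symbol Substitution < 34.
#'
#' @param cerad_wl,cerad_dr,af,dsst Numeric score vectors.
#' @return Tibble with logical columns `impaired_cerad`, `impaired_af`,
#'   `impaired_dsst` (`NA` where inputs are missing).
#' @export
flag_cognitive_impairment <- function(cerad_wl, cerad_dr, af, dsst) {
  tibble(
    impaired_cerad = cerad_wl < 17 & cerad_dr < 5,
    impaired_af = af < 14,
    impaired_dsst = dsst < 34
  )
}

#' Dietary folate equivalents
#'
#' `DFE = food folate + folic acid / 0.6` (in micrograms): 1 DFE equals 1 ug
#' food folate and 0.6 ug synthetic folic acid from supplements or fortified
#' food.
#'
#' @param food_folate Food folate intake, ug.
#' @param folic_acid Synthetic folic acid intake, ug.
#' @return DFE, ug.
#' @examples
#' compute_dfe(100, 0)  # 100
#' compute_dfe(0, 60)   # 100
#' @export
compute_dfe <- function(food_folate, folic_acid) {
  if (any(food_folate < 0, na.rm = TRUE) || any(folic_acid < 0, na.rm = TRUE)) {
    stop_fc("folate intakes must be non-negative.", "fc_domain_error")
  }
  food_folate + folic_acid / 0.6
}

#' Attach derived flags to a cohort
#'
#' Adds `egfr`, `b12_status`, and the cognitive impairment flags as columns.
#'
#' @param cohort Cohort tibble with the columns of [cohort_columns()].
#' @return The cohort with derived columns appended.
#' @export
derive_cohort <- function(cohort) {
  flags <- flag_cognitive_impairment(cohort$cerad_wl, cohort$cerad_dr,
                                     cohort$af, cohort$dsst)
  cohort |>
    mutate(
      egfr = compute_egfr(.data$serum_creatinine, .data$age, .data$sex,
                          .data$race_ethnicity == "NHB"),
      b12_status = classify_b12_status(.data$vitamin_b12, .data$mma)
    ) |>
    dplyr::bind_cols(flags)
}

#' Apply eligibility filters with an exclusion audit log
#'
#' Keeps participants aged 60 or older, with complete required fields, an
#' eGFR of at least 60 mL/min/1.73 m^2, and no stroke history. Each excluded
#' record receives exactly one reason, assigned in the fixed order
#' age, incomplete, egfr, stroke, so audit counts are reproducible.
#' Derived columns are (re)computed if absent.
#'
#' @param cohort Cohort tibble.
#' @return List with `cohort` (eligible records, derived columns attached;
#'   attribute `provenance` holds counts in/out) and `log` (tibble `id`,
#'   `reason`).
#' @export
apply_eligibility <- function(cohort) {
  if (!all(c("egfr", "b12_status") %in% names(cohort))) {
    cohort <- derive_cohort(cohort)
  }
  req <- intersect(required_fields(), names(cohort))
  complete <- !Reduce(`|`, lapply(cohort[req], is.na))
  reason <- rep(NA_character_, nrow(cohort))
  reason[is.na(reason) & !is.na(cohort$age) & cohort$age < 60] <- "age"
  reason[is.na(reason) & !complete] <- "incomplete"
  reason[is.na(reason) & cohort$egfr < 60] <- "egfr"
  reason[is.na(reason) & cohort$stroke_history] <- "stroke"
  keep <- is.na(reason)
  out <- cohort[keep, , drop = FALSE]
  attr(out, "provenance") <- list(n_in = nrow(cohort), n_out = sum(keep),
                                  n_excluded = sum(!keep))
  list(cohort = out,
       log = tibble(id = cohort$id[!keep], reason = reason[!keep]))
}
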