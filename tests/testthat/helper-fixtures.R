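# shared fixtures and independent oracles, built in code at test time

# a tiny fully-populated cohort tibble (n rows cycled from a 3-row template)
tiny_cohort <- function(n = 3) {
  template <- tibble::tibble(
    id = 1:3,
    age = c(65, 72, 61),
    sex = c("female", "male", "female"),
    race_ethnicity = c("NHW", "NHB", "MA"),
    marital = c("married", "widowed", "divorced"),
    education = c("hs_grad_ged", "some_college_aa", "college_grad_plus"),
    bmi = c(27.1, 31.4, 24.9),
    smoking = c(TRUE, FALSE, FALSE),
    drinking = c(TRUE, TRUE, FALSE),
    hypertension = c(FALSE, TRUE, FALSE),
    hyperlipidemia = c(TRUE, FALSE, TRUE),
    diabetes = c(FALSE, FALSE, TRUE),
    stroke_history = c(FALSE, FALSE, FALSE),
    serum_creatinine = c(0.8, 1.1, 0.7),
    rbc_folate = c(1100, 2000, 900),
    serum_total_folate = c(45, 80, 38),
    five_methyl_thf = c(41, 74, 35),
    vitamin_b12 = c(420, 600, 390),
    mma = c(150, 180, 120),
    umfa = c(1.2, 3.5, 0.8),
    diet_total_folate = c(350, 420, 300),
    diet_folic_acid = c(150, 200, 120),
    food_folate = c(200, 220, 180),
    dfe = c(200 + 150 / 0.6, 220 + 200 / 0.6, 180 + 120 / 0.6),
    diet_b12 = c(0.8, 1.5, 0.3),
    cerad_wl = c(20, 17, 23),
    cerad_dr = c(6, 5, 8),
    af = c(18, 14, 21),
    dsst = c(52, 40, 60)
  )
  out <- template[rep(1:3, length.out = n), ]
  out$id <- seq_len(n)
  out
}

# independent hinge-formula oracle (written against the printed closed form,
# not the package implementation)
oracle_two_line <- function(x, c, b0, b1, b2) {
  ifelse(x > c, b0 + b1 * x + b2 * (x - c), b0 + b1 * x)
}

# independent restricted-cubic-spline closed form
oracle_rcs <- function(x, t1, t2, t3) {
  plus3 <- function(u) ifelse(u > 0, u^3, 0)
  (plus3(x - t1) - plus3(x - t2) * (t3 - t1) / (t3 - t2) +
      plus3(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
}

# normal-equations least squares oracle
oracle_ols <- function(X, y) {
  solve(crossprod(X), crossprod(X, y))
}

oracle_rss <- function(X, y) {
  beta <- oracle_ols(X, y)
  sum((y - X %*% beta)^2)
}

# brute-force between/within sum-of-squares Calinski-Harabasz
oracle_ch <- function(X, cl) {
  n <- nrow(X); K <- length(unique(cl)); gm <- colMeans(X)
  W <- 0; B <- 0
  for (k in unique(cl)) {
    Xi <- X[cl == k, , drop = FALSE]
    ck <- colMeans(Xi)
    W <- W + sum(sweep(Xi, 2, ck)^2)
    B <- B + nrow(Xi) * sum((ck - gm)^2)
  }
  (B / (K - 1)) / (W / (n - K))
}

# separable blob data: k groups of m duplicated points, far apart
blob_matrix <- function(k = 3, m = 10, d = 100) {
  do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(rep(c(j * d, -j * d), each = m), m, 2)
  }))
}
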