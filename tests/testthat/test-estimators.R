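completed_tables <- function(x) {
  attr(x, "ispec") <- NULL
  x
}

test_that("complete-records fit equals full OLS when nothing is missing", {
  set.seed(1)
  n <- 200L
  df <- data.frame(x = rbinom(n, 1, 0.4), c_ = rnorm(n))
  df$y <- 1 + 0.5 * df$x + 2 * df$c_ + rnorm(n)
  spec <- estimand_regression("y", "x", "c_")
  f <- fit_cra(df, spec)
  ref <- lm(y ~ x + c_, data = df)
  expect_equal(f$estimate, unname(coef(ref)["x"]), tolerance = 1e-10)
  expect_equal(f$se, unname(sqrt(diag(vcov(ref)))["x"]), tolerance = 1e-10)
  expect_identical(f$n_complete, n)
})

test_that("complete-records fit drops incomplete rows and matches hand arithmetic", {
  # complete records (x, y) = (0,1), (1,3), (2,5): slope 2, intercept 1
  df <- data.frame(x = c(0, 1, 2, NA), y = c(1, 3, 5, 7))
  f <- fit_cra(df, estimand_regression("y", "x"))
  expect_equal(f$estimate, 2, tolerance = 1e-12)
  expect_equal(unname(f$coefficients["(Intercept)"]), 1, tolerance = 1e-12)
  expect_identical(f$n_complete, 3L)
})

test_that("too few complete records is an explicit error", {
  df <- data.frame(x = c(1, NA, NA, NA), y = c(1, 2, 3, 4), c_ = 1:4)
  expect_error(fit_cra(df, estimand_regression("y", "x", "c_")),
               "insufficient complete records")
})

test_that("imputing a dataset with no missing cells returns identical copies", {
  df <- data.frame(a = rnorm(10), b = rbinom(10, 1, 0.5))
  out <- fcs_impute(df, imputation_spec(n_imputations = 3, seed = 1))
  expect_length(out, 3)
  for (d in out) expect_identical(d, df)
})

test_that("explicit zero deltas are an exact no-op", {
  df <- toy_single_missing()
  i0 <- imputation_spec(n_imputations = 4, n_cycles = 3, seed = 9)
  iz <- imputation_spec(n_imputations = 4, n_cycles = 3, seed = 9,
                        deltas = c(y = 0))
  expect_identical(completed_tables(fcs_impute(df, i0)),
                   completed_tables(fcs_impute(df, iz)))
})

test_that("a delta shifts the imputed cells by exactly its value", {
  df <- toy_single_missing()
  mis <- is.na(df$y)
  d <- 1.75
  base <- fcs_impute(df, imputation_spec(4, 3, seed = 9))
  shifted <- fcs_impute(df, imputation_spec(4, 3, seed = 9,
                                            deltas = c(y = d)))
  for (k in seq_along(base)) {
    expect_identical(shifted[[k]]$y[!mis], base[[k]]$y[!mis])
    expect_equal(shifted[[k]]$y[mis], base[[k]]$y[mis] + d,
                 tolerance = 1e-12)
  }
})

test_that("observed cells are never altered by imputation", {
  m <- cached_case_study_model("a")
  md <- simulate_masked(m, n = 600, seed = 15)
  out <- fcs_impute(md, imputation_spec(3, 4, seed = 2))
  for (d in out) {
    expect_false(anyNA(d))
    for (v in names(md$data)) {
      obs <- !is.na(md$data[[v]])
      expect_identical(d[[v]][obs], md$data[[v]][obs])
    }
  }
  # and a fixed seed reproduces the completed tables exactly
  out2 <- fcs_impute(md, imputation_spec(3, 4, seed = 2))
  expect_identical(completed_tables(out), completed_tables(out2))
})

test_that("binary variables are imputed as 0/1 and reject deltas", {
  m <- cached_case_study_model("a")
  md <- simulate_masked(m, n = 600, seed = 16)
  out <- fcs_impute(md, imputation_spec(2, 3, seed = 3))
  for (d in out) expect_true(all(d$X %in% 0:1))
  expect_error(fcs_impute(md, imputation_spec(2, 3, seed = 3,
                                              deltas = c(X = 1))),
               "binary")
})

test_that("Rubin pooling reproduces hand arithmetic and degenerate cases", {
  p <- pool_rubin(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$between_variance, 1)
  expect_equal(p$within_variance, 1)
  expect_equal(p$total_variance, 1 + (1 + 1 / 3) * 1)  # 7/3
  expect_equal(p$total_variance, 7 / 3)
  # single imputation
  p1 <- pool_rubin(5, 2)
  expect_equal(p1$estimate, 5)
  expect_equal(p1$between_variance, 0)
  expect_equal(p1$total_variance, 2)
  # zero spread across imputations
  p0 <- pool_rubin(rep(1.3, 4), rep(0.5, 4))
  expect_equal(p0$between_variance, 0)
  expect_equal(p0$total_variance, p0$within_variance)
  expect_error(pool_rubin(numeric(0), numeric(0)), "no estimates")
})

test_that("pooling is invariant to the order of imputations", {
  set.seed(4)
  est <- rnorm(8); v <- runif(8, 0.5, 1.5)
  p1 <- pool_rubin(est, v, df_com = 100)
  perm <- sample(8)
  p2 <- pool_rubin(est[perm], v[perm], df_com = 100)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("total variance always satisfies the decomposition identity", {
  set.seed(5)
  for (i in 1:10) {
    m <- sample(2:10, 1)
    est <- rnorm(m); v <- runif(m, 0.2, 2)
    p <- pool_rubin(est, v)
    expect_equal(p$total_variance,
                 p$within_variance + (1 + 1 / m) * p$between_variance,
                 tolerance = 1e-12)
    expect_lt(p$ci_low, p$ci_high)
    expect_gte(p$between_variance, 0)
  }
})

test_that("a zero delta grid reproduces the standard MI estimate", {
  df <- toy_single_missing()
  spec <- estimand_regression("y", "x", "c_")
  isp <- imputation_spec(5, 3, seed = 6)
  res <- delta_adjusted_analysis(df, spec, isp, delta_grid = 0)
  std <- mi_analysis(df, spec, isp)
  expect_equal(res[[1]], std, tolerance = 1e-12)
  expect_error(delta_adjusted_analysis(df, spec, isp, numeric(0)),
               "nonempty")
})

test_that("the mean imputed outcome moves one-for-one with the delta grid", {
  gen <- case_study_generator(
    seed = 41, n = 2000,
    model = cached_case_study_model("pm", seed = 41))
  md <- gen$data
  mis <- md$indicators$M_Y == 1L
  isp <- imputation_spec(3, 2, seed = 7)
  spec <- case_study_estimand()
  d1 <- 0.5; d2 <- 3.25
  c1 <- fcs_impute(md, imputation_spec(3, 2, seed = 7,
                                       deltas = c(Y = d1)))
  c2 <- fcs_impute(md, imputation_spec(3, 2, seed = 7,
                                       deltas = c(Y = d2)))
  m1 <- mean(vapply(c1, function(d) mean(d$Y[mis]), numeric(1)))
  m2 <- mean(vapply(c2, function(d) mean(d$Y[mis]), numeric(1)))
  expect_equal(m2 - m1, d2 - d1, tolerance = 1e-10)
})
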