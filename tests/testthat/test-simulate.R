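gaussian_root_model <- function(intercept = 5, sd = 1, n = 10000L) {
  g <- mdag(list(node("a")), list())
  generative_model(g, list(a = list(family = "gaussian",
                                    intercept = intercept, sd = sd)),
                   n = n, seed = 1L)
}

test_that("model construction rejects inconsistent specifications", {
  g <- mdag(list(node("a"), node("b")), list(c("a", "b")))
  expect_error(generative_model(g, list(
    a = list(family = "gaussian", sd = 1),
    b = list(family = "gaussian", coefs = c(a = 1), sd = 0))), "sd > 0")
  expect_error(generative_model(g, list(
    a = list(family = "gaussian", sd = 1),
    b = list(family = "gaussian", sd = 1))), "every parent")
  expect_error(generative_model(g, list(
    a = list(family = "gaussian", coefs = c(b = 1), sd = 1),
    b = list(family = "gaussian", coefs = c(a = 1), sd = 1))),
    "non-parent")
})

test_that("a root gaussian node recovers its location parameter", {
  m <- gaussian_root_model(intercept = 5, sd = 1, n = 10000L)
  d <- simulate_complete(m)
  expect_lt(abs(mean(d$a) - 5), 4 / sqrt(nrow(d)))
})

test_that("a linear child reproduces the closed-form covariance", {
  g <- mdag(list(node("a"), node("b")), list(c("a", "b")))
  m <- generative_model(g, list(
    a = list(family = "gaussian", intercept = 0, sd = 1),
    b = list(family = "gaussian", intercept = 0, coefs = c(a = 2), sd = 1)),
    n = 50000L, seed = 2L)
  d <- simulate_complete(m)
  # cov(a, b) = coef * var(a) = 2 * 1
  expect_lt(abs(cov(d$a, d$b) - 2), 0.05)
})

test_that("identical seeds give identical tables", {
  m <- cached_case_study_model("a")
  expect_identical(simulate_complete(m, n = 500, seed = 3),
                   simulate_complete(m, n = 500, seed = 3))
  expect_identical(simulate_masked(m, n = 500, seed = 3),
                   simulate_masked(m, n = 500, seed = 3))
})

test_that("missingness mechanisms hit their marginal probabilities", {
  g <- mdag(list(node("a"),
                 node("M_a", kind = "missingness", indicator_of = "a")),
            list(c("a", "M_a")))
  mk <- function(intercept, coef) generative_model(g, list(
    a = list(family = "gaussian", intercept = 0, sd = 1)),
    list(M_a = list(intercept = intercept, coefs = c(a = coef))),
    n = 50000L, seed = 4L)
  n <- 50000L
  # flat mechanism: expit(0) = 1/2
  m0 <- mk(0, 0)
  d <- simulate_complete(m0)
  ind <- simulate_missingness(m0, d, seed = 5)
  expect_lt(abs(mean(ind$M_a) - 0.5), 4 * sqrt(0.25 / n))
  # degenerate intercept: no missingness at all
  ind2 <- simulate_missingness(mk(-30, 0), d, seed = 5)
  expect_identical(sum(ind2$M_a), 0L)
  # unit coefficient on a standard-gaussian parent: marginal proportion
  # E[expit(intercept + W)], computed by quadrature
  for (a0 in c(0, 1)) {
    m1 <- mk(a0, 1)
    ind3 <- simulate_missingness(m1, d, seed = 6)
    target <- integrate(function(w) plogis(a0 + w) * dnorm(w),
                        -10, 10)$value
    expect_lt(abs(mean(ind3$M_a) - target), 4 * sqrt(0.25 / n))
  }
})

test_that("mechanisms may not reference non-parents", {
  g <- mdag(list(node("a"), node("b"),
                 node("M_a", kind = "missingness", indicator_of = "a")),
            list(c("a", "b"), c("a", "M_a")))
  expect_error(generative_model(g, list(
    a = list(family = "gaussian", sd = 1),
    b = list(family = "gaussian", coefs = c(a = 1), sd = 1)),
    list(M_a = list(intercept = 0, coefs = c(a = 0, b = 1)))),
    "non-parent")
})

test_that("intercept calibration reaches its targets", {
  g <- mdag(list(node("a"),
                 node("M_a", kind = "missingness", indicator_of = "a")),
            list(c("a", "M_a")))
  m <- generative_model(g, list(
    a = list(family = "gaussian", intercept = 0, sd = 1)),
    list(M_a = list(intercept = 2, coefs = c(a = 0))), seed = 8L)
  # zero covariate effect, target 1/2: closed form intercept 0
  m05 <- calibrate_intercepts(m, c(M_a = 0.5))
  expect_lt(abs(m05$mechanisms$M_a$intercept), 0.02)
  # nonzero covariate effect, target 0.15
  m$mechanisms$M_a$coefs <- c(a = 0.8)
  m15 <- calibrate_intercepts(m, c(M_a = 0.15))
  d <- simulate_complete(m15, n = 200000L, seed = 9L)
  ind <- simulate_missingness(m15, d, seed = 10L)
  expect_lt(abs(mean(ind$M_a) - 0.15), 0.005)
  # boundary targets rejected
  expect_error(calibrate_intercepts(m, c(M_a = 0)), "\\(0, 1\\)")
  # recalibration is (nearly) idempotent
  m15b <- calibrate_intercepts(m15, c(M_a = 0.15), seed = 77L)
  expect_lt(abs(m15b$mechanisms$M_a$intercept -
                  m15$mechanisms$M_a$intercept), 0.05)
})

test_that("masking conserves observed cells and flags missing ones", {
  m <- cached_case_study_model("a")
  md <- simulate_masked(m, n = 2000, seed = 12)
  for (v in names(md$indicators)) {
    target <- m$graph$nodes[[v]]$indicator_of
    expect_identical(is.na(md$data[[target]]), md$indicators[[v]] == 1L)
    obs <- md$indicators[[v]] == 0L
    expect_identical(md$data[[target]][obs], md$shadow[[target]][obs])
  }
  expect_true(all(unlist(md$indicators) %in% 0:1))
})

test_that("the case-study generator emulates the study structure", {
  gen <- case_study_generator(seed = 21, n = 4882,
                              model = cached_case_study_model("a", seed = 21))
  md <- gen$data
  expect_identical(nrow(md$data), 4882L)
  props <- c(mean(md$indicators$M_X), mean(md$indicators$M_Y),
             mean(md$indicators$M_Z))
  expect_lt(abs(props[1] - 0.15), 0.02)
  expect_lt(abs(props[2] - 0.23), 0.02)
  expect_lt(abs(props[3] - 0.19), 0.02)
  expect_true(all(md$shadow$Y >= 0 & md$shadow$Y <= 40))
  expect_identical(sort(names(md$data)), sort(c("C", "Z", "X", "Y")))
  expect_true(is.numeric(gen$truth))
  # determinism
  gen2 <- case_study_generator(seed = 21, n = 4882,
                               model = cached_case_study_model("a", seed = 21))
  expect_identical(gen$data, gen2$data)
})

test_that("outcome is uncorrelated with indicators given regressors under variant a", {
  m <- cached_case_study_model("a")
  n <- 50000L
  set.seed(31)
  d <- simulate_complete(m, n = n, seed = NA)
  ind <- simulate_missingness(m, d, seed = NA)
  Xr <- cbind(1, d$X, d$C, d$Z)
  ry <- lm.fit(Xr, d$Y)$residuals
  for (v in names(ind)) {
    rm_ <- lm.fit(Xr, ind[[v]])$residuals
    expect_lt(abs(cor(ry, rm_)), 4 / sqrt(n))
  }
})

test_that("masked CSV round-trips observed data and indicators", {
  m <- cached_case_study_model("a")
  md <- simulate_masked(m, n = 300, seed = 14)
  path <- withr::local_tempfile(fileext = ".csv")
  write_masked_csv(md, path)
  back <- read_masked_csv(path, m$graph)
  expect_equal(back$data, md$data, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(as.integer(unlist(back$indicators)),
                   as.integer(unlist(md$indicators)))
})
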