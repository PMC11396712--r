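test_that("asinh transform matches its closed form and is monotone", {
  expect_equal(asinh_transform(0, 5), 0)
  expect_equal(asinh_transform(5, 1), log(5 + sqrt(26)))
  x <- sort(stats::runif(100, 0, 50))
  y <- asinh_transform(x, 2.5)
  expect_true(all(diff(y) > 0))
  expect_warning(asinh_transform(-1, 1), "negative")
  expect_error(asinh_transform(1, -2), "positive")
})

test_that("EM recovers a well-separated normal mixture", {
  x <- withr::with_seed(7, c(stats::rnorm(1800, 1, 1), stats::rnorm(1200, 6, 1)))
  f <- fit_mixture(x, "normal", seed = 7)
  expect_equal(f$status, "ok")
  expect_true(f$converged)
  expect_lt(abs(f$weights[["negative"]] - 0.6), 0.03)
  expect_lt(abs(f$weights[["positive"]] - 0.4), 0.03)
  expect_lt(abs(f$params["negative", "mean"] - 1), 0.1)
  expect_lt(abs(f$params["positive", "mean"] - 6), 0.1)
})

test_that("a two-spike sample is fit by direct grouping", {
  x <- withr::with_seed(2, c(
    stats::runif(30, -0.01, 0.01), 10 + stats::runif(30, -0.01, 0.01)
  ))
  f <- fit_mixture(x, "normal", seed = 1)
  expect_lt(abs(f$params["negative", "mean"] - 0), 0.02)
  expect_lt(abs(f$params["positive", "mean"] - 10), 0.02)
  expect_equal(unname(f$weights), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("EM log-likelihood never decreases within a run", {
  for (s in 1:4) {
    x <- withr::with_seed(s, c(
      stats::rlnorm(300, 0, 0.5), stats::rlnorm(200, 2.5, 0.3)
    ))
    for (fam in c("normal", "lognormal", "weibull")) {
      f <- fit_mixture(x, fam, seed = s)
      expect_true(all(diff(f$loglik_trace) > -1e-6 * abs(f$loglik)),
        label = paste("monotone loglik:", fam, "seed", s)
      )
    }
  }
})

test_that("mixture fit agrees with the mclust oracle on normal data", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust") # Mclust needs its namespace attached
  x <- withr::with_seed(13, c(stats::rnorm(900, 0, 1), stats::rnorm(600, 5, 1.4)))
  f <- fit_mixture(x, "normal", seed = 3)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(f$loglik - mc$loglik), 0.05)
  expect_equal(sort(unname(f$params[, "mean"])),
    sort(unname(mc$parameters$mean)),
    tolerance = 0.02
  )
})

test_that("single-component data is flagged low-separation", {
  x <- withr::with_seed(5, stats::rlnorm(800, 0, 0.5))
  f <- fit_mixture(x, "lognormal", seed = 5)
  expect_true(f$status == "ok")
  expect_true(f$low_separation)
})

test_that("mixture preconditions are enforced", {
  expect_error(fit_mixture(stats::rnorm(20), "normal"), "at least 50")
  x <- c(stats::rlnorm(100), -1)
  expect_error(fit_mixture(x, "lognormal"), "strictly positive")
  expect_error(fit_mixture(x, "weibull"), "strictly positive")
})

test_that("BIC model selection prefers the generating family", {
  x_norm <- withr::with_seed(21, c(
    stats::rnorm(1500, 10, 1), stats::rnorm(1000, 20, 1.5)
  ))
  expect_equal(select_model(x_norm, seed = 2)$family, "normal")

  x_skew <- withr::with_seed(22, c(
    stats::rlnorm(1500, 0, 0.6), stats::rlnorm(1000, 2.7, 0.25)
  ))
  f_all <- lapply(
    c("normal", "lognormal", "weibull"),
    function(fam) fit_mixture(x_skew, fam, seed = 2)
  )
  bics <- vapply(f_all, `[[`, numeric(1), "bic")
  sel <- select_model(x_skew, seed = 2)
  expect_true(sel$family %in% c("lognormal", "weibull"))
  # never normal when the skewed families are clearly better
  expect_gt(bics[1] - min(bics[2:3]), 10)
})

test_that("a single requested family is returned unconditionally", {
  x <- withr::with_seed(23, c(stats::rnorm(300, 0, 1), stats::rnorm(300, 6, 1)))
  f <- select_model(x, families = "normal", seed = 1)
  expect_equal(f$family, "normal")
})

test_that("posterior probabilities match closed forms", {
  x <- withr::with_seed(1, c(stats::rnorm(500, 0, 1), stats::rnorm(500, 4, 1)))
  f <- fit_mixture(x, "normal", seed = 1)
  # overwrite with exact parameters to test the posterior formula alone
  f$weights[] <- c(0.5, 0.5)
  f$params[, "mean"] <- c(0, 4)
  f$params[, "sd"] <- c(1, 1)
  f$means[] <- c(0, 4)
  expect_equal(posterior_positive(f, 2), 0.5) # midpoint symmetry
  expect_equal(posterior_positive(f, 3), 1 / (1 + exp(-4))) # log-odds 2x - 4
  expect_equal(posterior_positive(f, 1e4), 1)
  expect_equal(posterior_positive(f, -1e4), 0)
})

test_that("positivity calls use a strict posterior threshold", {
  x <- withr::with_seed(3, c(stats::rlnorm(400, 0, 0.5), stats::rlnorm(300, 2.7, 0.3)))
  f <- fit_mixture(x, "lognormal", seed = 3)
  p0 <- posterior_positive(f, 4)
  expect_false(call_positive(f, 4, threshold = p0)) # equality is negative
  expect_true(call_positive(f, 4, threshold = p0 - 1e-9))
  expect_false(call_positive(f, 4, threshold = 1 - 1e-12))
  expect_error(call_positive(f, 4, threshold = 1.2), "0, 1")
  # below-support intensities can never be positive
  expect_equal(posterior_positive(f, -3), 0)
})

test_that("lognormal gating is invariant to intensity rescaling", {
  b <- make_bimodal(2000, 0.25, seed = 17)
  f1 <- fit_mixture(b$values, "lognormal", seed = 4)
  f2 <- fit_mixture(b$values * 7.3, "lognormal", seed = 4)
  expect_identical(
    call_positive(f1, b$values),
    call_positive(f2, b$values * 7.3)
  )
})
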