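test_that("k = 1 fit is the closed-form normal MLE", {
  f <- fit_mixture(c(-1, -1, -2, -2), k = 1)
  expect_equal(f$components$mean, -1.5)
  expect_equal(f$components$sd, 0.5)  # population SD (MLE)
  expect_equal(f$loglik, sum(dnorm(c(-1, -1, -2, -2), -1.5, 0.5,
                                   log = TRUE)))
})

test_that("EM log-likelihood is non-decreasing and labels are canonical", {
  for (s in 1:8) {
    v <- draw_two_state(400, seed = s)
    f <- fit_mixture(v, 2, seed = s, keep_data = FALSE)
    expect_true(all(diff(f$loglik_trace) >= -1e-9))
    expect_lt(f$components$mean[1], f$components$mean[2])
    expect_identical(f$components$state, c("S", "L"))
    expect_equal(sum(f$components$weight), 1, tolerance = 1e-9)
  }
})

test_that("the two-state parameters are recovered at n = 2000", {
  v <- draw_two_state(2000, seed = 7)
  f <- fit_mixture(v, 2, seed = 1, keep_data = FALSE)
  comp <- all_synapse_components()
  expect_lt(max(abs(f$components$mean - comp$mean)), 0.05)
  expect_lt(max(abs(f$components$sd - comp$sd)), 0.04)
  expect_lt(abs(f$components$weight[1] - 0.77), 0.05)
})

test_that("the EM agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  v <- draw_two_state(2000, seed = 7)
  f <- fit_mixture(v, 2, seed = 1, keep_data = FALSE)
  mc <- mclust::Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
  expect_gte(f$loglik, mc$loglik - 0.5)
  expect_lt(max(abs(sort(f$components$mean) -
                      sort(as.numeric(mc$parameters$mean)))), 0.02)
  expect_lt(max(abs(sort(f$components$sd) -
                      sort(sqrt(as.numeric(mc$parameters$variance$sigmasq))))),
            0.02)
})

test_that("truncated fitting removes the bias of ignoring the cutoff", {
  v <- withr::with_seed(6, rnorm(4000, -1, 0.3))
  v <- v[v >= -1.2]
  f_tr <- fit_mixture(v, 1, truncation_lower = -1.2)
  f_un <- fit_mixture(v, 1)
  expect_lt(abs(f_tr$components$mean - (-1)), 0.05)
  expect_gt(f_un$components$mean, -1 + 0.05)
})

test_that("truncated two-component density integrates to 1 above the bound", {
  v <- c(withr::with_seed(8, rnorm(600, -1, 0.25)),
         withr::with_seed(9, rnorm(300, -0.3, 0.2)))
  b <- -1.3
  v <- v[v >= b]
  f <- fit_mixture(v, 2, truncation_lower = b, seed = 2, keep_data = FALSE)
  expect_true(all(diff(f$loglik_trace) >= -1e-9))
  itg <- integrate(function(x) dmix(x, f), b, Inf)
  expect_equal(itg$value, 1, tolerance = 1e-6)
  expect_equal(dmix(b - 0.01, f), 0)
})

test_that("degenerate inputs raise degeneracy errors", {
  expect_error(fit_mixture(rep(-1, 50), 2),
               class = "spinestates_degeneracy_error")
  expect_error(fit_mixture(-1, 1), class = "spinestates_data_error")
  expect_error(fit_mixture(rnorm(100), 3),
               class = "spinestates_config_error")
})

test_that("weight refits move only the weights", {
  fixed <- fit_mixture(draw_two_state(2000, seed = 7), 2, seed = 1,
                       keep_data = FALSE)
  pure_s <- withr::with_seed(5, rnorm(1000, -1.42, 0.24))
  rf <- refit_weights(pure_s, fixed)
  expect_gt(rf$weights[["S"]], 0.95)
  expect_equal(sum(rf$weights), 1, tolerance = 1e-9)
  # symmetric components, values at the equal-likelihood point
  sym <- tibble::tibble(state = c("S", "L"), mean = c(-1, 1),
                        sd = c(0.5, 0.5), weight = c(0.5, 0.5))
  rf0 <- refit_weights(rep(0, 20), sym)
  expect_equal(rf0$weights[["S"]], 0.5, tolerance = 1e-6)
  # nested optimization: refit loglik cannot beat the full fit
  v2 <- draw_two_state(500, seed = 3)
  full <- fit_mixture(v2, 2, seed = 3, keep_data = FALSE)
  expect_lte(refit_weights(v2, full)$loglik, full$loglik + 1e-6)
})

test_that("bootstrap weight SDs are deterministic and shrink with n", {
  v <- draw_two_state(2000, seed = 10)
  b1 <- bootstrap_weight_sd(v[1:500], B = 120, seed = 4)
  b2 <- bootstrap_weight_sd(v, B = 120, seed = 4)
  expect_lt(b2$weight_sd[["S"]], b1$weight_sd[["S"]])
  b3 <- bootstrap_weight_sd(v, B = 120, seed = 4)
  expect_identical(b2$weight_sd, b3$weight_sd)
  expect_error(bootstrap_weight_sd(v, B = 50, seed = 1),
               class = "spinestates_config_error")
})

test_that("the LR against a single normal is non-negative and powerful", {
  for (s in 1:5) {
    v <- withr::with_seed(s, rnorm(300, 0, 1))
    expect_gte(lrt_vs_single(v, seed = s)$lr, 0)
  }
  ps <- vapply(1:20, function(s) {
    v <- draw_two_state(1960, seed = s)
    lrt_vs_single(v, seed = s)$p_value
  }, double(1))
  expect_true(all(ps < 1e-6))
})

test_that("the parametric-bootstrap LRT p is roughly calibrated under the null", {
  # scaled-down calibration: 40 single-normal replicates, B = 99
  rej <- vapply(1:40, function(s) {
    v <- withr::with_seed(900 + s, rnorm(300, -1, 0.3))
    lrt_vs_single(v, bootstrap = TRUE, B = 99, seed = s)$p_boot <= 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.15)
})

test_that("tidy and glance expose the fit in broom style", {
  f <- fit_mixture(draw_two_state(300, seed = 2), 2, seed = 2)
  td <- generics::tidy(f)
  expect_identical(names(td), c("state", "mean", "sd", "weight"))
  gl <- generics::glance(f)
  expect_identical(gl$k, 2L)
  expect_true(is.finite(gl$AIC))
})
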