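test_that("symmetrization doubles pairs and preserves the pooled distribution", {
  p <- tibble::tibble(v1 = c(-1.2), v2 = c(-0.8))
  s <- symmetrize_pairs(p)
  expect_equal(nrow(s), 2)
  expect_equal(s$v1, c(-1.2, -0.8))
  expect_equal(s$v2, c(-0.8, -1.2))
  pp <- simulate_pairs(50, seed = 1)
  ss <- symmetrize_pairs(pp)
  # first positions of the symmetrized set = pooled values, exactly
  expect_equal(sort(ss$v1), sort(c(pp$v1, pp$v2)))
  p0 <- tibble::tibble(v1 = -1, v2 = -1)
  s0 <- symmetrize_pairs(p0)
  expect_equal(s0$v1, s0$v2)
})

test_that("phi matches the published joints and the analytic special cases", {
  expect_equal(round(phi_from_joint(
    pair_state_joint(0.490, 0.0885, 0.0885, 0.333)), 3), 0.637)
  expect_equal(round(phi_from_joint(
    pair_state_joint(0.427, 0.116, 0.116, 0.342)), 2), 0.53)
  expect_equal(round(phi_from_joint(
    pair_state_joint(0.529, 0.0615, 0.0615, 0.348)), 2), 0.75)
  expect_equal(phi_from_joint(pair_state_joint(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(phi_from_joint(pair_state_joint(0.5, 0, 0, 0.5)), 1)
  expect_error(phi_from_joint(pair_state_joint(1, 0, 0, 0)),
               class = "spinestates_undefined_error")
})

test_that("the pair model recovers joint and emissions at n = 2000", {
  p <- simulate_pairs(2000, components = dual_emission_components(), seed = 99)
  m <- fit_pair_model(p, seed = 99)
  expect_lt(max(abs(as.numeric(m$joint) -
                      as.numeric(dual_state_joint()))), 0.03)
  expect_lt(max(abs(m$emissions$mean - dual_emission_components()$mean)), 0.03)
  expect_lt(abs(m$joint[["sl"]] - m$joint[["ls"]]), 1e-6)
  expect_true(all(diff(m$loglik_trace) >= -1e-9))
})

test_that("independent latent states give phi near zero", {
  marg <- c(S = 0.5785, L = 0.4215)
  jind <- c(ss = marg[["S"]]^2, sl = prod(marg), ls = prod(marg),
            ll = marg[["L"]]^2)
  jind <- jind / sum(jind)
  for (s in 1:3) {
    p <- simulate_pairs(2000, joint = jind,
                        components = dual_emission_components(), seed = s)
    m <- fit_pair_model(p, seed = s)
    expect_lt(abs(m$phi), 0.1)
  }
})

test_that("the pair model's marginal mixture is consistent with a direct fit", {
  p <- simulate_pairs(2000, components = dual_emission_components(), seed = 5)
  m <- fit_pair_model(p, seed = 5)
  pooled <- c(p$v1, p$v2)
  direct <- fit_mixture(pooled, 2, seed = 5, keep_data = FALSE)
  marg_w <- m$joint[["ss"]] + m$joint[["sl"]]
  expect_lt(abs(marg_w - direct$components$weight[1]), 0.05)
  marg_comp <- tibble::tibble(mean = m$emissions$mean,
                              sd = m$emissions$sd,
                              weight = c(marg_w, 1 - marg_w))
  ll_marg <- sum(dmix(pooled, marg_comp, log = TRUE))
  expect_lt(abs(ll_marg - direct$loglik), 5)
})

test_that("pair posteriors follow Bayes' rule and its symmetries", {
  m <- fit_pair_model(simulate_pairs(500, components = dual_emission_components(),
                                     seed = 4), seed = 4)
  em <- m$emissions
  lowv <- em$mean[1] - 5 * em$sd[1]
  po <- posterior_states(tibble::tibble(v1 = lowv, v2 = lowv), m)
  expect_gt(po$p_ss, 0.99)
  # independent oracle: direct Bayes computation
  num <- as.numeric(m$joint) * c(
    dnorm(lowv, em$mean[1], em$sd[1])^2,
    dnorm(lowv, em$mean[1], em$sd[1]) * dnorm(lowv, em$mean[2], em$sd[2]),
    dnorm(lowv, em$mean[2], em$sd[2]) * dnorm(lowv, em$mean[1], em$sd[1]),
    dnorm(lowv, em$mean[2], em$sd[2])^2)
  expect_equal(po$p_ss, (num / sum(num))[1], tolerance = 1e-9)
  # symmetric pair: mixed-state posteriors equal
  pa <- posterior_states(tibble::tibble(v1 = -1.1, v2 = -1.1), m)
  expect_equal(pa$p_sl, pa$p_ls)
  # (a, b) and (b, a) posteriors are transposes
  pab <- posterior_states(tibble::tibble(v1 = -1.5, v2 = -0.8), m)
  pba <- posterior_states(tibble::tibble(v1 = -0.8, v2 = -1.5), m)
  expect_equal(pab$p_sl, pba$p_ls, tolerance = 1e-12)
  expect_equal(pab$p_ss, pba$p_ss, tolerance = 1e-12)
  expect_equal(rowSums(cbind(pab$p_ss, pab$p_sl, pab$p_ls, pab$p_ll)), 1)
})

test_that("phi recovery at the study's dual-connection sample size", {
  phis <- vapply(1:20, function(s) {
    p <- simulate_pairs(160, components = dual_emission_components(), seed = s)
    fit_pair_model(p, seed = s)$phi
  }, double(1))
  # unbiased around the generating phi, spread set by information at n=160
  expect_lt(abs(mean(phis) - 0.637), 0.05)
  expect_lt(stats::sd(phis), 0.15)
})

test_that("projections are proper densities with the root-2 separation gain", {
  m <- fit_pair_model(simulate_pairs(800, components = dual_emission_components(),
                                     seed = 6), seed = 6)
  for (ax in c("marginal", "mean", "ratio")) {
    pr <- project_joint(m, ax)
    expect_equal(integrate(function(x) dmix(x, pr), -Inf, Inf)$value, 1,
                 tolerance = 1e-6)
  }
  # SS/LL-only joint: mean-projection separation/sd gains a factor sqrt(2)
  m2 <- m
  m2$joint <- structure(c(ss = 0.5, sl = 0, ls = 0, ll = 0.5),
                        class = "pair_state_joint")
  m2$emissions$sd <- c(0.2, 0.2)
  marg <- project_joint(m2, "marginal")
  mean_pr <- project_joint(m2, "mean")
  sep_ratio <- (diff(mean_pr$mean) / mean_pr$sd[1]) /
    (diff(marg$mean) / marg$sd[1])
  expect_equal(sep_ratio, sqrt(2), tolerance = 1e-9)
  # ratio projection of a symmetric joint is symmetric about 0
  rat <- project_joint(m, "ratio")
  expect_equal(sum(rat$mean * rat$weight), 0, tolerance = 1e-9)
  x <- seq(-1, 1, length.out = 101)
  expect_equal(dmix(x, rat), rev(dmix(-x, rat)), tolerance = 1e-9)
})
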