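test_that("generation is deterministic in (config, seed)", {
  cfg <- connectome_config(n_connections = 200)
  a <- generate_connectome(cfg, seed = 5)
  b <- generate_connectome(cfg, seed = 5)
  expect_identical(a, b)
  c <- generate_connectome(cfg, seed = 6)
  expect_false(identical(a, c))
})

test_that("monosynaptic fraction matches the configured 0.891 at n = 10,000", {
  tbl <- generate_connectome(connectome_config(n_connections = 10000),
                             seed = 2)
  mf <- multiplicity_fractions(group_connections(tbl))
  p <- default_multiplicity_probs()[["1"]]
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mf$fraction[mf$multiplicity == 1] - p), 3 * se)
})

test_that("latent-state marginal converges to the configured marginal", {
  tbl <- generate_connectome(connectome_config(n_connections = 5000),
                             seed = 8)
  j <- default_joint_state_probs()
  p_L <- j[["ls"]] + j[["ll"]]
  n <- nrow(tbl)
  expect_gt(n, 5000)
  se <- sqrt(p_L * (1 - p_L) / n)
  expect_lt(abs(mean(tbl$.state == "L") - p_L), 3 * se)
})

test_that("an independence joint yields uncorrelated latent states in duals", {
  marg <- c(S = 0.5785, L = 0.4215)
  jind <- c(ss = marg[["S"]]^2, sl = prod(marg), ls = prod(marg),
            ll = marg[["L"]]^2)
  jind <- jind / sum(jind)
  cfg <- connectome_config(n_connections = 10000,
                           multiplicity_probs = c(`2` = 1),
                           joint_state_probs = jind)
  tbl <- generate_connectome(cfg, seed = 3)
  st <- matrix(tbl$.state, ncol = 2, byrow = TRUE)
  phi_hat <- cor(st[, 1] == "L", st[, 2] == "L")
  expect_lt(abs(phi_hat), 3 / sqrt(10000))
})

test_that("sizes are conditionally independent given the true states", {
  cfg <- connectome_config(n_connections = 8000,
                           multiplicity_probs = c(`2` = 1))
  tbl <- generate_connectome(cfg, seed = 4)
  v <- matrix(log10(tbl$spine_volume), ncol = 2, byrow = TRUE)
  h <- matrix(tbl$.state, ncol = 2, byrow = TRUE)
  for (st in list(c("S", "S"), c("L", "L"))) {
    sel <- h[, 1] == st[1] & h[, 2] == st[2]
    r <- cor(v[sel, 1], v[sel, 2])
    expect_lt(abs(r), 3 / sqrt(sum(sel)))
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(connectome_config(multiplicity_probs = c(`1` = 0.5)),
               class = "spinestates_config_error")
  expect_error(connectome_config(
    joint_state_probs = c(ss = 0.5, sl = 0.2, ls = 0.1, ll = 0.2)),
    class = "spinestates_config_error")
  expect_error(connectome_config(
    populations = tibble::tibble(weight = c(0.5, 0.2), mean = 0, sd = 1)),
    class = "spinestates_config_error")
  expect_error(generate_mixed_population(connectome_config(), seed = 1),
               class = "spinestates_config_error")
})

test_that("a single mixed population gives plain log-normal sizes", {
  cfg <- connectome_config(
    n_connections = 4500,
    populations = tibble::tibble(weight = 1, mean = -1.1, sd = 0.25))
  tbl <- generate_mixed_population(cfg, seed = 6)
  lv <- utils::head(log10(tbl$spine_volume), 5000)
  expect_gte(length(lv), 4000)
  expect_gt(stats::shapiro.test(lv)$p.value, 0.01)
  expect_true(all(tbl$.population == 1))
})

test_that("pooled multi-population data show bimodality less than two-state data", {
  pops <- tibble::tibble(weight = c(1, 1, 1) / 3,
                         mean = c(-1.6, -1.15, -0.7), sd = 0.22)
  cfg_mix <- connectome_config(n_connections = 300, populations = pops)
  cfg_two <- connectome_config(n_connections = 300)
  p_mix <- vapply(1:6, function(s) {
    v <- log10(generate_mixed_population(cfg_mix, seed = s)$spine_volume)
    bimodality_test(v, seed = s)$p_value
  }, double(1))
  p_two <- vapply(1:6, function(s) {
    v <- log10(generate_connectome(cfg_two, seed = s)$spine_volume)
    bimodality_test(v, seed = s)$p_value
  }, double(1))
  expect_lte(sum(p_mix <= 0.05), sum(p_two <= 0.05))
  expect_lt(stats::median(p_two), stats::median(p_mix) + 1e-12)
})

test_that("population labels are recorded for every synapse", {
  cfg <- connectome_config(
    n_connections = 100,
    populations = tibble::tibble(weight = c(0.5, 0.5),
                                 mean = c(-1.5, -0.8), sd = 0.2))
  tbl <- generate_mixed_population(cfg, seed = 9)
  expect_true(all(tbl$.population %in% 1:2))
  expect_equal(length(tbl$.population), nrow(tbl))
  # all synapses of a connection share the population
  per_conn <- tapply(tbl$.population, tbl$.connection_id,
                     function(x) length(unique(x)))
  expect_true(all(per_conn == 1))
})

test_that("simulate_pairs reproduces the requested joint at large n", {
  p <- simulate_pairs(20000, seed = 13)
  j <- default_joint_state_probs()
  emp <- c(mean(p$.h1 == "S" & p$.h2 == "S"),
           mean(p$.h1 == "S" & p$.h2 == "L"),
           mean(p$.h1 == "L" & p$.h2 == "S"),
           mean(p$.h1 == "L" & p$.h2 == "L"))
  expect_lt(max(abs(emp - as.numeric(j))), 3 * sqrt(0.25 / 20000) * 2)
  expect_identical(p, simulate_pairs(20000, seed = 13))
})
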