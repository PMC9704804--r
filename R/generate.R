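#' Default multiplicity distribution of PyC-PyC connections
#'
#' Fractions of connections with 1..5 synapses among 1735 connections
#' (counts 1546, 160, 24, 3, 2): a connection usually (89.1%) has a single
#' synapse.
#' @return Named numeric vector of fractions summing to 1.
#' @export
default_multiplicity_probs <- function() {
  counts <- c(`1` = 1546, `2` = 160, `3` = 24, `4` = 3, `5` = 2)
  counts / sum(counts)
}

#' Default joint latent-state probabilities at dual connections
#'
#' Joint distribution of the two latent states (SS, SL, LS, LL) of a dual
#' connection: same states (SS, LL) dominate, mixed states are rare, giving
#' a phi coefficient of 0.637.
#' @return Named numeric vector `c(ss, sl, ls, ll)`.
#' @export
default_joint_state_probs <- function() {
  c(ss = 0.490, sl = 0.0885, ls = 0.0885, ll = 0.333)
}

#' Default S/L emission components
#'
#' Log10 spine-volume components of the two latent states fitted over all
#' recurrent PyC-PyC synapses: S(-1.42, 0.24), L(-0.77, 0.22) (log10 um^3).
#' @return A tibble with `state`, `mean`, `sd`.
#' @export
default_state_components <- function() {
  tibble::tibble(state = c("S", "L"),
                 mean = c(-1.42, -0.77),
                 sd = c(0.24, 0.22))
}

#' Configuration of the synthetic connectome generator
#'
#' Defines the generative model the analysis assumes: per-connection synapse
#' counts, a binary latent state per synapse whose consecutive within-
#' connection pairs follow a (symmetric) joint distribution, per-state
#' log-normal sizes, and uniform synapse centroids in a bounded tissue
#' volume.  Defaults reproduce the study conditions: the empirical
#' multiplicity fractions, the dual-connection joint state distribution, the
#' all-synapse S/L components, and a 250 x 140 x 90 um^3 volume.
#'
#' @param n_connections Number of directed connections to generate.
#' @param multiplicity_probs Named vector: probability of each synapse count.
#' @param joint_state_probs Named vector `c(ss, sl, ls, ll)`, symmetric
#'   (`sl == ls`), for consecutive synapse pairs within a connection.
#' @param components Tibble with `state` ("S" under "L"-ordering by mean),
#'   `mean`, `sd` in log10 um^3.
#' @param box Named vector of box edge lengths in micrometres.
#' @param n_pre_cells,n_post_cells Sizes of the presynaptic/postsynaptic cell
#'   pools.  Directed cell pairs are always sampled without replacement, so
#'   the multiplicity per pair is exactly the configured one; the default
#'   pool size of about one cell per five connections mirrors the study's
#'   cell-to-connection ratio (334 cells, 1735 connections), which leaves
#'   individual cells participating in several connections — needed for the
#'   same-axon/same-dendrite control pairings.
#' @param populations Optional tibble with `weight`, `mean`, `sd` for the
#'   mixed-population ("orphan axon") mode; see
#'   [generate_mixed_population()].
#' @return A list of class `connectome_config`.
#' @export
connectome_config <- function(n_connections = 1735,
                              multiplicity_probs = default_multiplicity_probs(),
                              joint_state_probs = default_joint_state_probs(),
                              components = default_state_components(),
                              box = c(x = 250, y = 140, z = 90),
                              n_pre_cells = NULL,
                              n_post_cells = NULL,
                              populations = NULL) {
  check_number(n_connections, "n_connections", min = 1)
  if (abs(sum(multiplicity_probs) - 1) > 1e-8 || any(multiplicity_probs < 0))
    abort_fmt("`multiplicity_probs` must be non-negative and sum to 1",
              "config_error")
  j <- joint_state_probs
  if (length(j) != 4 || abs(sum(j) - 1) > 1e-6 || any(j < 0))
    abort_fmt("`joint_state_probs` must be 4 non-negative values summing to 1",
              "config_error")
  if (abs(j[["sl"]] - j[["ls"]]) > 1e-9)
    abort_fmt("`joint_state_probs` must be symmetric (sl == ls)",
              "config_error")
  if (any(components$sd <= 0))
    abort_fmt("component `sd` must be positive", "config_error")
  if (!is.null(populations)) {
    populations <- tibble::as_tibble(populations)
    if (nrow(populations) == 0)
      abort_fmt("`populations` must be nonempty when given", "config_error")
    if (abs(sum(populations$weight) - 1) > 1e-8)
      abort_fmt("population weights must sum to 1", "config_error")
  }
  structure(list(
    n_connections = as.integer(n_connections),
    multiplicity_probs = multiplicity_probs,
    joint_state_probs = j,
    components = tibble::as_tibble(components),
    box = box,
    n_pre_cells = as.integer(n_pre_cells %||%
                               max(10, ceiling(n_connections / 5))),
    n_post_cells = as.integer(n_post_cells %||%
                                max(10, ceiling(n_connections / 5))),
    populations = populations
  ), class = "connectome_config")
}

# distinct directed (pre, post) cell pairs with pre != post
sample_cell_pairs <- function(n, n_pre, n_post) {
  pairs <- matrix(integer(0), ncol = 2)
  guard <- 0
  while (nrow(pairs) < n) {
    m <- 2 * (n - nrow(pairs)) + 10
    cand <- cbind(sample.int(n_pre, m, replace = TRUE),
                  sample.int(n_post, m, replace = TRUE))
    cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
    pairs <- unique(rbind(pairs, cand))
    if ((guard <- guard + 1) > 1000)
      abort_fmt("cell pools too small for the requested connection count",
                "config_error")
  }
  pairs[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic connectome synapse table
#'
#' For each connection the synapse count is drawn from the multiplicity
#' distribution; the first synapse's latent state from the marginal of the
#' joint state distribution and each subsequent state from its conditional
#' given the previous state (a first-order chain — for pairs this is exactly
#' the configured joint, for triples and beyond an extrapolation);
#' conditioned on its state, each log10 size is drawn independently from
#' that state's normal component; centroids are uniform in the box.  Ground
#' truth (latent state, connection index) is emitted in dot-prefixed columns
#' that the analysis pipeline never reads.
#'
#' @param config A [connectome_config()].
#' @param seed Integer seed; identical `(config, seed)` give identical
#'   tables.
#' @return A `synapse_tbl` with extra `.connection_id` and `.state` columns.
#' @export
generate_connectome <- function(config = connectome_config(), seed = 1L) {
  stopifnot(inherits(config, "connectome_config"))
  withr::with_seed(seed, {
    n <- config$n_connections
    mult_k <- as.integer(names(config$multiplicity_probs))
    mult <- mult_k[sample.int(length(mult_k), n, replace = TRUE,
                              prob = config$multiplicity_probs)]
    cells <- sample_cell_pairs(n, config$n_pre_cells, config$n_post_cells)
    j <- config$joint_state_probs
    marg <- c(S = j[["ss"]] + j[["sl"]], L = j[["ls"]] + j[["ll"]])
    cond <- rbind(S = c(j[["ss"]], j[["sl"]]) / marg[["S"]],
                  L = c(j[["ls"]], j[["ll"]]) / marg[["L"]])
    comp <- config$components[order(config$components$mean), ]
    states <- purrr::map(mult, function(k) {
      h <- character(k)
      h[1] <- sample(c("S", "L"), 1, prob = marg)
      for (i in seq_len(k - 1))
        h[i + 1] <- sample(c("S", "L"), 1, prob = cond[h[i], ])
      h
    })
    m <- sum(mult)
    h_all <- unlist(states)
    idx <- match(h_all, comp$state)
    logv <- rnorm(m, mean = comp$mean[idx], sd = comp$sd[idx])
    tbl <- tibble::tibble(
      synapse_id = sprintf("syn%06d", seq_len(m)),
      pre_id = sprintf("pre%05d", rep(cells[, 1], mult)),
      post_id = sprintf("post%05d", rep(cells[, 2], mult)),
      x = runif(m, 0, config$box[["x"]]),
      y = runif(m, 0, config$box[["y"]]),
      z = runif(m, 0, config$box[["z"]]),
      spine_volume = 10^logv,
      .connection_id = rep(seq_len(n), mult),
      .state = h_all
    )
    as_synapse_table(tbl, metadata = list(generator = "two_state",
                                          seed = seed))
  })
}

#' Generate a mixed-population ("orphan axon") synapse table
#'
#' Emulates synapse tables pooled over axons of mixed, unknown cell types:
#' each connection is assigned one population by weight, and all its synapse
#' sizes are drawn from that population's single log-normal component.
#' There is no S/L latent structure; pooling several populations with
#' distinct means smears the size distribution, which is why bimodality is
#' not expected for such data.
#'
#' @inheritParams generate_connectome
#' @return A `synapse_tbl` with a `.population` ground-truth column.
#' @export
generate_mixed_population <- function(config, seed = 1L) {
  stopifnot(inherits(config, "connectome_config"))
  if (is.null(config$populations))
    abort_fmt("`config$populations` must be set for mixed-population mode",
              "config_error")
  withr::with_seed(seed, {
    n <- config$n_connections
    pops <- config$populations
    mult_k <- as.integer(names(config$multiplicity_probs))
    mult <- mult_k[sample.int(length(mult_k), n, replace = TRUE,
                              prob = config$multiplicity_probs)]
    cells <- sample_cell_pairs(n, config$n_pre_cells, config$n_post_cells)
    pop_of_conn <- sample.int(nrow(pops), n, replace = TRUE,
                              prob = pops$weight)
    m <- sum(mult)
    pop_all <- rep(pop_of_conn, mult)
    logv <- rnorm(m, mean = pops$mean[pop_all], sd = pops$sd[pop_all])
    tbl <- tibble::tibble(
      synapse_id = sprintf("syn%06d", seq_len(m)),
      pre_id = sprintf("pre%05d", rep(cells[, 1], mult)),
      post_id = sprintf("post%05d", rep(cells[, 2], mult)),
      x = runif(m, 0, config$box[["x"]]),
      y = runif(m, 0, config$box[["y"]]),
      z = runif(m, 0, config$box[["z"]]),
      spine_volume = 10^logv,
      .connection_id = rep(seq_len(n), mult),
      .population = pop_all
    )
    as_synapse_table(tbl, metadata = list(generator = "mixed_population",
                                          seed = seed))
  })
}

#' Simulate dual-connection pairs directly from a pair-state model
#'
#' Convenience sampler for the dual-connection analysis: draws `n` latent
#' state pairs from the joint, then conditionally independent log10 sizes
#' from the shared emissions; distances come from pairs of uniform points in
#' `box`.
#'
#' @param n Number of dual connections.
#' @param joint Named vector `c(ss, sl, ls, ll)`.
#' @param components Tibble with `state`, `mean`, `sd` (log10 units).
#' @param box Box edge lengths (um) used to draw synapse positions.
#' @param seed Integer seed.
#' @param analog_correlation Pearson correlation injected between the two
#'   analog (within-state) deviations; 0 reproduces the model's conditional
#'   independence, positive values are a deliberate model violation for
#'   power checks.
#' @return A tibble with `connection_id`, `v1`, `v2`, `distance` and
#'   ground-truth `.h1`, `.h2`.
#' @export
simulate_pairs <- function(n, joint = default_joint_state_probs(),
                           components = default_state_components(),
                           box = c(x = 250, y = 140, z = 90),
                           seed = 1L, analog_correlation = 0) {
  withr::with_seed(seed, {
    comp <- components[order(components$mean), ]
    labels <- c("ss", "sl", "ls", "ll")
    st <- sample(labels, n, replace = TRUE, prob = joint[labels])
    h1 <- ifelse(substr(st, 1, 1) == "s", "S", "L")
    h2 <- ifelse(substr(st, 2, 2) == "s", "S", "L")
    i1 <- match(h1, comp$state); i2 <- match(h2, comp$state)
    z1 <- rnorm(n)
    z2 <- analog_correlation * z1 +
      sqrt(1 - analog_correlation^2) * rnorm(n)
    p1 <- cbind(runif(n, 0, box[["x"]]), runif(n, 0, box[["y"]]),
                runif(n, 0, box[["z"]]))
    p2 <- cbind(runif(n, 0, box[["x"]]), runif(n, 0, box[["y"]]),
                runif(n, 0, box[["z"]]))
    tibble::tibble(
      connection_id = sprintf("conn%05d", seq_len(n)),
      v1 = comp$mean[i1] + comp$sd[i1] * z1,
      v2 = comp$mean[i2] + comp$sd[i2] * z2,
      distance = sqrt(rowSums((p1 - p2)^2)),
      .h1 = h1, .h2 = h2
    )
  })
}
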