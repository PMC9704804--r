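#' Pearson correlation of paired log10 sizes
#'
#' Thin validated wrapper around [stats::cor()]: at least three pairs and
#' nonzero variance on both sides are required, otherwise the correlation is
#' undefined.
#'
#' @param xs,ys Numeric vectors of equal length (log10 sizes).
#' @return Pearson's r in `[-1, 1]`.
#' @export
pearson_r <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 3)
    abort_fmt("need at least 3 complete pairs", "data_error")
  if (stats::sd(xs) < 1e-14 || stats::sd(ys) < 1e-14)
    abort_fmt("zero variance: correlation undefined", "undefined_error")
  cor(xs, ys)
}

#' State-conditioned resampling test of conditional independence
#'
#' If sizes are conditionally independent given the latent states, then
#' within the SS (or LL) state the two sizes of a pair should be
#' uncorrelated.  Each iteration assigns every pair to the target state by
#' an independent biased coin flip weighted by the pair's posterior
#' probability of that state, and computes Pearson's r over the included
#' pairs; iterations with fewer than three included pairs are redrawn so the
#' iteration count stays fixed.
#'
#' @param pairs Tibble with `v1`, `v2`.
#' @param model A fitted [fit_pair_model()].
#' @param state `"SS"` or `"LL"`.
#' @param n_iter Number of sampling iterations.
#' @param seed Integer seed (bit-for-bit reproducible r samples).
#' @param kde_bandwidth Gaussian KDE bandwidth used for the density summary
#'   of the r samples (the same 0.15 log10-space bandwidth convention used
#'   for size histograms).
#' @return An object of class `resample_result`: `r_samples`, `state`,
#'   `summary` (mean, sd, and the one-sided exceedance fraction
#'   `P(r <= 0)`), and a `kde` tibble.
#' @export
state_conditioned_resample <- function(pairs, model, state = c("SS", "LL"),
                                       n_iter = 10000, seed = 1L,
                                       kde_bandwidth = 0.15) {
  state <- match.arg(state)
  if (nrow(pairs) < 10) abort_fmt("need at least 10 pairs", "data_error")
  post <- posterior_states(pairs, model)
  p <- if (state == "SS") post$p_ss else post$p_ll
  if (all(p < 1e-12))
    abort_fmt(sprintf("no posterior mass on state %s", state),
              "undefined_error")
  n <- length(p)
  rs <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      repeat {
        inc <- rbinom(n, 1, p) == 1
        if (sum(inc) >= 3 && stats::sd(pairs$v1[inc]) > 1e-14 &&
            stats::sd(pairs$v2[inc]) > 1e-14)
          return(cor(pairs$v1[inc], pairs$v2[inc]))
      }
    }, double(1))
  })
  kd <- density(rs, bw = kde_bandwidth, from = -1 - 4 * kde_bandwidth,
                to = 1 + 4 * kde_bandwidth, n = 512)
  out <- list(r_samples = rs, state = state, n_iterations = n_iter,
              kde_bandwidth = kde_bandwidth,
              summary = tibble::tibble(state = state, mean_r = mean(rs),
                                       sd_r = stats::sd(rs),
                                       exceedance = mean(rs <= 0)),
              kde = tibble::tibble(r = kd$x, density = kd$y))
  class(out) <- "resample_result"
  out
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf("State-conditioned resampling (%s, %d iterations): r = %.3f +/- %.3f, P(r <= 0) = %.3f\n",
              x$state, x$n_iterations, x$summary$mean_r, x$summary$sd_r,
              x$summary$exceedance))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.resample_result <- function(x, ...) x$summary

#' Residual correlation after removing the binary component
#'
#' Subtracts each synapse's latent-state emission mean (the binary
#' component) from its log10 size and correlates the residuals of the pair:
#' under the model the residuals are the analog components, which should be
#' uncorrelated.  By default each synapse's state is the
#' maximum-a-posteriori state under the marginal mixture given *its own*
#' size only.  This partner-blindness matters: assigning states from the
#' pair posterior makes the subtracted component for one synapse depend on
#' the other synapse's size through the correlated joint, which by itself
#' induces spurious negative correlation between the residuals.  The
#' partner-dependent conventions are available for comparison:
#' `"pair_map"` (MAP marginal state from the pair posterior) and
#' `"posterior"` (posterior-weighted emission mean from the pair
#' posterior).
#'
#' @inheritParams state_conditioned_resample
#' @param weighting `"map"` (default, partner-blind), `"pair_map"` or
#'   `"posterior"`.
#' @return A list with `r` and a `residuals` tibble (`r1`, `r2` per pair).
#' @export
residual_correlation <- function(pairs, model,
                                 weighting = c("map", "pair_map",
                                               "posterior")) {
  weighting <- match.arg(weighting)
  em <- model$emissions
  if (weighting == "map") {
    m1 <- em$mean[map_state(pairs$v1, model) + 1L]
    m2 <- em$mean[map_state(pairs$v2, model) + 1L]
  } else {
    post <- posterior_states(pairs, model)
    p1L <- post$p_ls + post$p_ll  # P(h1 = L | v1, v2)
    p2L <- post$p_sl + post$p_ll
    if (weighting == "pair_map") {
      m1 <- ifelse(p1L > 0.5, em$mean[2], em$mean[1])
      m2 <- ifelse(p2L > 0.5, em$mean[2], em$mean[1])
    } else {
      m1 <- (1 - p1L) * em$mean[1] + p1L * em$mean[2]
      m2 <- (1 - p2L) * em$mean[1] + p2L * em$mean[2]
    }
  }
  r1 <- pairs$v1 - m1
  r2 <- pairs$v2 - m2
  list(r = pearson_r(r1, r2),
       residuals = tibble::tibble(connection_id = pairs$connection_id,
                                  r1 = r1, r2 = r2))
}

# MAP S/L state of individual synapses under the marginal mixture implied
# by a pair model (weights = state marginals, shared emissions).
map_state <- function(v, model) {
  em <- model$emissions
  marg <- c(model$joint[["ss"]] + model$joint[["sl"]],
            model$joint[["ls"]] + model$joint[["ll"]])
  lS <- log(marg[1]) + dnorm(v, em$mean[1], em$sd[1], log = TRUE)
  lL <- log(marg[2]) + dnorm(v, em$mean[2], em$sd[2], log = TRUE)
  ifelse(lL > lS, 1L, 0L)  # 1 = L
}

#' Same-axon / same-dendrite control pairings
#'
#' Synapse pairs sharing only one endpoint — the same presynaptic cell but
#' different postsynaptic cells (`same_axon`) or the same postsynaptic cell
#' but different presynaptic cells (`same_dendrite`) — drawn from the
#' synapses that belong to dual connections.  Per draw, each eligible cell
#' contributes one such pair (two synapses onto/from two distinct partner
#' cells, sampled without replacement within the draw); the latent-state phi
#' (via MAP states) and Pearson's r of sizes are computed per draw and
#' summarized as mean and SD over draws.
#'
#' @param tbl A `synapse_tbl`.
#' @param model A fitted `pair_state_model` used for MAP state assignment.
#' @param mode `"same_axon"` or `"same_dendrite"`.
#' @param n_draws Number of random draws.
#' @param seed Integer seed.
#' @param measure Size column.
#' @return A list of class `control_pair_result`: `mode`, `phi_mean`,
#'   `phi_sd`, `r_mean`, `r_sd`, `n_draws`, `n_cells`, and the per-draw
#'   tibble `draws`.
#' @export
control_pair_analysis <- function(tbl, model,
                                  mode = c("same_axon", "same_dendrite"),
                                  n_draws = 1000, seed = 1L,
                                  measure = "spine_volume") {
  mode <- match.arg(mode)
  groups <- group_connections(tbl)
  duals <- dplyr::filter(groups, .data$multiplicity == 2L)
  syn <- duals |>
    dplyr::select("pre_id", "post_id", "synapses") |>
    tidyr::unnest("synapses")
  key <- if (mode == "same_axon") "pre_id" else "post_id"
  other <- if (mode == "same_axon") "post_id" else "pre_id"
  syn$v <- log10(syn[[measure]])
  syn$h <- map_state(syn$v, model)
  eligible <- syn |>
    dplyr::group_by(.data[[key]]) |>
    dplyr::filter(dplyr::n_distinct(.data[[other]]) >= 2) |>
    dplyr::group_split()
  if (length(eligible) < 10)
    abort_fmt("fewer than 10 eligible cells with qualifying synapse pairs",
              "data_error")
  draws <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_draws), function(d) {
      pairs <- purrr::map_dfr(eligible, function(g) {
        partners <- sample(unique(g[[other]]), 2)
        s1 <- dplyr::slice_sample(g[g[[other]] == partners[1], ], n = 1)
        s2 <- dplyr::slice_sample(g[g[[other]] == partners[2], ], n = 1)
        tibble::tibble(v1 = s1$v, v2 = s2$v, h1 = s1$h, h2 = s2$h,
                       shared_both = s1$pre_id == s2$pre_id &
                         s1$post_id == s2$post_id)
      })
      phi <- if (stats::sd(pairs$h1) > 0 && stats::sd(pairs$h2) > 0)
        cor(pairs$h1, pairs$h2) else NA_real_
      tibble::tibble(draw = d, phi = phi, r = cor(pairs$v1, pairs$v2),
                     any_shared_both = any(pairs$shared_both))
    })
  })
  if (any(draws$any_shared_both))
    abort_fmt("internal audit failed: a control pair shared both endpoints",
              "audit_error")
  out <- list(mode = mode,
              phi_mean = mean(draws$phi, na.rm = TRUE),
              phi_sd = stats::sd(draws$phi, na.rm = TRUE),
              r_mean = mean(draws$r), r_sd = stats::sd(draws$r),
              n_draws = n_draws, n_cells = length(eligible), draws = draws)
  class(out) <- "control_pair_result"
  out
}

#' @export
print.control_pair_result <- function(x, ...) {
  cat(sprintf("%s controls (%d cells, %d draws): phi = %.3f +/- %.3f, r = %.3f +/- %.3f\n",
              x$mode, x$n_cells, x$n_draws, x$phi_mean, x$phi_sd, x$r_mean,
              x$r_sd))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.control_pair_result <- function(x, ...) {
  tibble::tibble(mode = x$mode, phi_mean = x$phi_mean, phi_sd = x$phi_sd,
                 r_mean = x$r_mean, r_sd = x$r_sd, n_draws = x$n_draws)
}

#' Distance-split pair-model analysis
#'
#' Splits dual connections at a distance threshold (default: the median
#' Euclidean distance between the two synapses), fits the pair model
#' independently to the near (`<=` threshold) and far groups, and reports
#' both models with their phi coefficients — probing whether latent-state
#' correlations are confined to nearby synapse pairs.
#'
#' @param pairs Tibble with `v1`, `v2`, `distance`.
#' @param threshold `"median"` or a numeric distance in micrometres.
#' @param seed Seed passed to the two fits.
#' @return A list of class `distance_split_result` with `near`, `far`
#'   (fitted models), `phi_near`, `phi_far`, `threshold`.
#' @export
distance_split_analysis <- function(pairs, threshold = "median",
                                    seed = NULL) {
  if (anyNA(pairs$distance))
    abort_fmt("all pairs need a distance", "data_error")
  thr <- if (identical(threshold, "median")) stats::median(pairs$distance)
         else check_number(threshold, "threshold", min = 0)
  near <- dplyr::filter(pairs, .data$distance <= thr)
  far <- dplyr::filter(pairs, .data$distance > thr)
  if (nrow(near) < 20 || nrow(far) < 20)
    abort_fmt("need at least 20 pairs in each distance group", "data_error")
  m_near <- fit_pair_model(near, seed = if (is.null(seed)) NULL
                           else derive_seed(seed, 1L))
  m_far <- fit_pair_model(far, seed = if (is.null(seed)) NULL
                          else derive_seed(seed, 2L))
  structure(list(near = m_near, far = m_far, phi_near = m_near$phi,
                 phi_far = m_far$phi, threshold = thr,
                 n_near = nrow(near), n_far = nrow(far)),
            class = "distance_split_result")
}

#' @export
print.distance_split_result <- function(x, ...) {
  cat(sprintf("Distance split at %.1f um: near phi = %.3f (n = %d), far phi = %.3f (n = %d)\n",
              x$threshold, x$phi_near, x$n_near, x$phi_far, x$n_far))
  invisible(x)
}
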