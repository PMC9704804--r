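#' Construct a joint latent-state distribution for synapse pairs
#'
#' The joint distribution of the two binary latent states `(H1, H2)` of a
#' dual connection over `{S, L}^2`.  Joints whose printed probabilities sum
#' to within 1% of one (rounding in reported tables) are renormalized; the
#' phi coefficient is invariant to that renormalization.
#'
#' @param p_ss,p_sl,p_ls,p_ll Probabilities of the four state pairs.
#' @return A named numeric vector of class `pair_state_joint`.
#' @export
pair_state_joint <- function(p_ss, p_sl, p_ls, p_ll) {
  j <- c(ss = p_ss, sl = p_sl, ls = p_ls, ll = p_ll)
  if (any(j < 0) || abs(sum(j) - 1) > 0.01)
    abort_fmt("joint probabilities must be non-negative and sum to 1",
              "config_error")
  structure(j / sum(j), class = "pair_state_joint")
}

#' Phi coefficient of a joint state distribution
#'
#' Pearson's correlation specialized to two binary variables:
#' `phi = (p_ss * p_ll - p_sl * p_ls) / sqrt(p1_S * p1_L * p2_S * p2_L)`
#' with the row/column marginals `p1_S = p_ss + p_sl` etc.
#'
#' @param joint A [pair_state_joint()], a named `c(ss, sl, ls, ll)` vector,
#'   or a fitted [fit_pair_model()] object.
#' @return Phi in `[-1, 1]`.
#' @export
phi_from_joint <- function(joint) {
  if (inherits(joint, "pair_state_model")) joint <- joint$joint
  if (!inherits(joint, "pair_state_joint"))
    joint <- pair_state_joint(joint[["ss"]], joint[["sl"]], joint[["ls"]],
                              joint[["ll"]])
  p1s <- joint[["ss"]] + joint[["sl"]]
  p2s <- joint[["ss"]] + joint[["ls"]]
  den <- p1s * (1 - p1s) * p2s * (1 - p2s)
  if (den <= 0)
    abort_fmt("degenerate marginal: phi undefined", "undefined_error")
  unname((joint[["ss"]] * joint[["ll"]] - joint[["sl"]] * joint[["ls"]]) /
           sqrt(den))
}

#' Symmetrize dual-connection pairs
#'
#' A dual connection's two synapses have no inherent order, but a chain
#' model is trained on ordered pairs; every pair is therefore included
#' twice, once in each order.
#'
#' @param pairs A tibble with `v1`, `v2` columns (log10 sizes), as from
#'   [dual_pairs()] or [simulate_pairs()].
#' @return A tibble of `2 * nrow(pairs)` ordered rows.
#' @export
symmetrize_pairs <- function(pairs) {
  if (nrow(pairs) == 0) abort_fmt("no pairs to symmetrize", "data_error")
  flipped <- pairs
  flipped$v1 <- pairs$v2
  flipped$v2 <- pairs$v1
  dplyr::bind_rows(pairs, flipped)
}

#' Fit the correlated-latent-state model to dual connections
#'
#' Fits a two-state chain of length two — a hidden Markov model with initial
#' distribution `pi`, transition matrix `A` and normal emissions shared by
#' both positions — to the symmetrized pairs by EM.  The public result is
#' the joint `joint(h1, h2) = pi(h1) * A(h1 -> h2)`; symmetrization makes
#' `SL` and `LS` equal in expectation and any residual numerical asymmetry
#' is removed by averaging.  Emission components are labelled so that
#' `mean(S) < mean(L)`.
#'
#' @param pairs Tibble with `v1`, `v2` (log10 sizes), one row per dual
#'   connection (unsymmetrized; symmetrization happens internally).
#' @inheritParams fit_mixture
#' @return An object of class `pair_state_model`: `joint`
#'   (a [pair_state_joint()]), `emissions` (tibble `state`, `mean`, `sd`),
#'   `phi`, `loglik`, `n_pairs`, `converged`, `n_iter`, `loglik_trace`.
#' @export
fit_pair_model <- function(pairs, tol = 1e-8, max_iter = 2000,
                           sd_floor = 1e-3, n_restarts = 5, seed = NULL) {
  if (nrow(pairs) < 20)
    abort_fmt("need at least 20 pairs", "data_error")
  sym <- symmetrize_pairs(pairs)
  V <- cbind(sym$v1, sym$v2)
  pooled <- as.numeric(V)
  if (stats::sd(pooled) < 1e-12)
    abort_fmt("degenerate data: all values equal", "degeneracy_error")
  with_seed_if(seed, {
    fit <- NULL
    for (attempt in 0:n_restarts) {
      init <- init_pair(pooled, V, attempt, sd_floor)
      fit <- em_pair(V, init, tol, max_iter, sd_floor)
      if (!fit$collapsed) break
    }
    if (fit$collapsed)
      abort_fmt("emission collapse persisted across restarts",
                "degeneracy_error")
  })
  # order states by emission mean, then joint from (pi, A), symmetrized
  ord <- order(fit$mu)
  mu <- fit$mu[ord]; s <- fit$s[ord]
  pi0 <- fit$pi[ord]; A <- fit$A[ord, ord, drop = FALSE]
  joint <- outer(pi0, rep(1, 2)) * A   # joint[h1, h2] = pi[h1] A[h1, h2]
  off <- (joint[1, 2] + joint[2, 1]) / 2
  j <- c(ss = joint[1, 1], sl = off, ls = off, ll = joint[2, 2])
  j <- j / sum(j)
  joint <- structure(j, class = "pair_state_joint")
  out <- list(joint = joint,
              emissions = tibble::tibble(state = c("S", "L"), mean = mu,
                                         sd = s),
              phi = phi_from_joint(joint),
              loglik = fit$loglik, n_pairs = nrow(pairs),
              converged = fit$converged, n_iter = fit$n_iter,
              loglik_trace = fit$trace)
  class(out) <- "pair_state_model"
  out
}

init_pair <- function(pooled, V, attempt, sd_floor) {
  if (attempt == 0) {
    km <- kmeans(pooled, centers = 2, nstart = 5)
    mu <- as.numeric(km$centers)
    ord <- order(mu)
    lab <- matrix(match(km$cluster, ord), ncol = 2)  # 1 = S, 2 = L
    s <- vapply(1:2, function(j) {
      v <- pooled[km$cluster == ord[j]]
      if (length(v) > 1) stats::sd(v) else stats::sd(pooled) / 2
    }, double(1))
    counts <- table(factor(lab[, 1], 1:2), factor(lab[, 2], 1:2)) + 1
    A <- sweep(counts, 1, rowSums(counts), "/")
    list(mu = sort(mu), s = pmax(s, 10 * sd_floor),
         pi = as.numeric(table(factor(lab[, 1], 1:2)) + 1) /
           (nrow(lab) + 2),
         A = matrix(as.numeric(A), 2, 2))
  } else {
    s0 <- stats::sd(pooled)
    list(mu = sort(sample(pooled, 2) + rnorm(2, 0, s0 / 4)),
         s = pmax(s0 * runif(2, 0.3, 1.2), 10 * sd_floor),
         pi = c(0.5, 0.5),
         A = matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2))
  }
}

# EM for a length-2 two-state chain with tied normal emissions on
# symmetrized ordered pairs.
em_pair <- function(V, init, tol, max_iter, sd_floor) {
  mu <- init$mu; s <- init$s; pi0 <- init$pi; A <- init$A
  m <- nrow(V)
  ll_old <- -Inf; trace <- numeric(0)
  converged <- FALSE; collapsed <- FALSE
  for (it in seq_len(max_iter)) {
    # log joint over the 4 state combos, per pair
    lg <- matrix(0, m, 4)  # columns: SS, SL, LS, LL
    e1 <- cbind(dnorm(V[, 1], mu[1], s[1], log = TRUE),
                dnorm(V[, 1], mu[2], s[2], log = TRUE))
    e2 <- cbind(dnorm(V[, 2], mu[1], s[1], log = TRUE),
                dnorm(V[, 2], mu[2], s[2], log = TRUE))
    combo <- cbind(c(1, 1, 2, 2), c(1, 2, 1, 2))
    for (c4 in 1:4) {
      h1 <- combo[c4, 1]; h2 <- combo[c4, 2]
      lg[, c4] <- log(pi0[h1]) + log(A[h1, h2]) + e1[, h1] + e2[, h2]
    }
    mx <- apply(lg, 1, max)
    li <- mx + log(rowSums(exp(lg - mx)))
    ll <- sum(li)
    trace <- c(trace, ll)
    if (it > 1 && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-300)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    g <- exp(lg - li)  # m x 4 posterior
    # marginal responsibilities per position
    r1 <- cbind(g[, 1] + g[, 2], g[, 3] + g[, 4])  # h1 = S, L
    r2 <- cbind(g[, 1] + g[, 3], g[, 2] + g[, 4])  # h2 = S, L
    pi0 <- colSums(r1) / m
    Anew <- matrix(c(sum(g[, 1]), sum(g[, 2]), sum(g[, 3]), sum(g[, 4])),
                   2, 2, byrow = TRUE)
    A <- sweep(Anew, 1, rowSums(Anew), "/")
    # tied emissions pool both positions
    for (h in 1:2) {
      r <- c(r1[, h], r2[, h])
      v <- c(V[, 1], V[, 2])
      sw <- sum(r)
      mu[h] <- sum(r * v) / sw
      s[h] <- sqrt(max(sum(r * (v - mu[h])^2) / sw, 0))
    }
    if (any(s < sd_floor) || any(pi0 < 1e-8)) { collapsed <- TRUE; break }
  }
  list(mu = mu, s = s, pi = pi0, A = A, loglik = ll,
       n_iter = length(trace), converged = converged, collapsed = collapsed,
       trace = trace)
}

#' Posterior state probabilities for dual pairs
#'
#' Posterior of the four latent-state combinations given a pair's two log10
#' sizes: `p(h1, h2 | v1, v2)` proportional to
#' `joint(h1, h2) * f_h1(v1) * f_h2(v2)`.
#'
#' @param pairs Tibble with `v1`, `v2`.
#' @param model A fitted `pair_state_model`.
#' @return `pairs` with columns `p_ss`, `p_sl`, `p_ls`, `p_ll` added
#'   (each row sums to 1).
#' @export
posterior_states <- function(pairs, model) {
  stopifnot(inherits(model, "pair_state_model"))
  em <- model$emissions
  j <- model$joint
  e1 <- cbind(dnorm(pairs$v1, em$mean[1], em$sd[1], log = TRUE),
              dnorm(pairs$v1, em$mean[2], em$sd[2], log = TRUE))
  e2 <- cbind(dnorm(pairs$v2, em$mean[1], em$sd[1], log = TRUE),
              dnorm(pairs$v2, em$mean[2], em$sd[2], log = TRUE))
  lg <- cbind(log(j[["ss"]]) + e1[, 1] + e2[, 1],
              log(j[["sl"]]) + e1[, 1] + e2[, 2],
              log(j[["ls"]]) + e1[, 2] + e2[, 1],
              log(j[["ll"]]) + e1[, 2] + e2[, 2])
  mx <- apply(lg, 1, max)
  g <- exp(lg - mx)
  g <- g / rowSums(g)
  pairs$p_ss <- g[, 1]; pairs$p_sl <- g[, 2]
  pairs$p_ls <- g[, 3]; pairs$p_ll <- g[, 4]
  pairs
}

#' Project the joint pair model onto a one-dimensional axis
#'
#' The fitted joint distribution over `(V1, V2)` can be projected onto the
#' vertical axis (the marginal size distribution), the `x = y` diagonal
#' (the geometric mean of the pair, components separated by sqrt(2) more
#' standard deviations than the marginal), or the `x = -y` diagonal (the
#' log ratio of the pair).  Each projection is again a normal mixture.
#'
#' @param model A fitted `pair_state_model`.
#' @param axis `"marginal"`, `"mean"` or `"ratio"`.
#' @return A tibble of mixture components (`mean`, `sd`, `weight`) usable
#'   with [dmix()] and [count_modes()].
#' @export
project_joint <- function(model, axis = c("marginal", "mean", "ratio")) {
  axis <- match.arg(axis)
  stopifnot(inherits(model, "pair_state_model"))
  em <- model$emissions
  j <- model$joint
  if (axis == "marginal") {
    w <- c(j[["ss"]] + j[["sl"]], j[["ls"]] + j[["ll"]])
    out <- tibble::tibble(mean = em$mean, sd = em$sd, weight = w)
  } else {
    sgn <- if (axis == "mean") 1 else -1
    combo <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
    out <- purrr::map_dfr(seq_along(combo), function(c4) {
      h <- combo[[c4]]
      tibble::tibble(
        mean = (em$mean[h[1]] + sgn * em$mean[h[2]]) / 2,
        sd = sqrt(em$sd[h[1]]^2 + em$sd[h[2]]^2) / 2,
        weight = unname(j[c4]))
    })
    # merge coincident components (SL and LS project identically)
    out <- out |>
      dplyr::group_by(mean = round(.data$mean, 12),
                      sd = round(.data$sd, 12)) |>
      dplyr::summarise(weight = sum(.data$weight), .groups = "drop") |>
      dplyr::filter(.data$weight > 1e-12)
  }
  dplyr::arrange(out, .data$mean)
}

#' @export
print.pair_state_model <- function(x, ...) {
  cat(sprintf("Pair latent-state model (%d dual connections)\n", x$n_pairs))
  cat(sprintf("joint: SS %.3f  SL %.3f  LS %.3f  LL %.3f   phi = %.3f\n",
              x$joint[["ss"]], x$joint[["sl"]], x$joint[["ls"]],
              x$joint[["ll"]], x$phi))
  print(x$emissions)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pair_state_model <- function(x, ...) {
  tibble::tibble(state_pair = c("SS", "SL", "LS", "LL"),
                 probability = as.numeric(x$joint))
}

#' @exportS3Method generics::glance
glance.pair_state_model <- function(x, ...) {
  tibble::tibble(phi = x$phi, loglik = x$loglik, n_pairs = x$n_pairs,
                 converged = x$converged, n_iter = x$n_iter)
}
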