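#' Fit a one- or two-component normal mixture to log10 sizes
#'
#' Maximum-likelihood fit by expectation-maximization, initialized with
#' k-means (number of clusters equal to the number of components).  For
#' cleft-size data the component densities can be truncated at a lower bound
#' — `log10(50)` voxels, the detection cutoff — in which case each component
#' is renormalized over `[truncation_lower, Inf)` and the M-step maximizes
#' the weighted truncated-normal likelihood numerically.  Components are
#' always returned sorted by ascending mean and labelled `S` then `L`.
#'
#' @param values Numeric vector of log10-transformed sizes.
#' @param k Number of components, 1 or 2.
#' @param truncation_lower Optional lower truncation bound (log10 units),
#'   e.g. `log10(50)` for cleft sizes; `NULL` for spine volumes.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param sd_floor Lower bound on component standard deviations; a fit whose
#'   component collapses below it is restarted (up to `n_restarts` times)
#'   from perturbed initial values before a degeneracy error is raised.
#' @param n_restarts Random restarts after a collapsed fit.
#' @param seed Optional seed controlling k-means initialization and
#'   restarts.
#' @param keep_data Store the data in the result (needed by [autoplot()]).
#' @return An object of class `mixture_fit`: a list with `components`
#'   (tibble `state`, `mean`, `sd`, `weight`), `truncation_lower`, `loglik`,
#'   `n`, `k`, `converged`, `n_iter` and `loglik_trace`.
#' @export
fit_mixture <- function(values, k = 2, truncation_lower = NULL, tol = 1e-8,
                        max_iter = 2000, sd_floor = 1e-3, n_restarts = 5,
                        seed = NULL, keep_data = TRUE) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    abort_fmt("`values` must be finite", "data_error")
  if (!k %in% c(1L, 2L))
    abort_fmt("`k` must be 1 or 2", "config_error")
  n <- length(values)
  n_min <- if (k == 1L) 2L else 10L
  if (n < n_min)
    abort_fmt(sprintf("need at least %d values for k = %d", n_min, k),
              "data_error")
  if (stats::sd(values) < 1e-12)
    abort_fmt("degenerate data: all values equal", "degeneracy_error")
  if (k == 1L) return(fit_single(values, truncation_lower, keep_data))
  with_seed_if(seed, {
    fit <- NULL
    for (attempt in 0:n_restarts) {
      init <- init_two(values, attempt, sd_floor)
      fit <- if (is.null(truncation_lower)) {
        r <- cpp_em2(values, init$mu[1], init$mu[2], init$s[1], init$s[2],
                     init$w, tol, max_iter, sd_floor)
        list(mu = c(r$mu1, r$mu2), s = c(r$s1, r$s2), w = c(r$w1, 1 - r$w1),
             loglik = r$loglik, n_iter = r$n_iter, converged = r$converged,
             collapsed = r$collapsed, trace = r$trace)
      } else {
        em_trunc2(values, truncation_lower, init$mu, init$s,
                  c(init$w, 1 - init$w), tol, max_iter, sd_floor)
      }
      if (!fit$collapsed) break
    }
    if (fit$collapsed)
      abort_fmt("component collapse persisted across restarts",
                "degeneracy_error")
    ord <- order(fit$mu)
    new_mixture_fit(
      components = tibble::tibble(state = c("S", "L"),
                                  mean = fit$mu[ord], sd = fit$s[ord],
                                  weight = fit$w[ord]),
      truncation_lower = truncation_lower, loglik = fit$loglik, n = n,
      k = 2L, converged = fit$converged, n_iter = fit$n_iter,
      loglik_trace = fit$trace,
      data = if (keep_data) values else NULL)
  })
}

new_mixture_fit <- function(components, truncation_lower, loglik, n, k,
                            converged, n_iter, loglik_trace, data = NULL) {
  structure(list(components = components,
                 truncation_lower = truncation_lower, loglik = loglik,
                 n = n, k = k, converged = converged, n_iter = n_iter,
                 loglik_trace = loglik_trace, data = data),
            class = "mixture_fit")
}

init_two <- function(values, attempt, sd_floor) {
  if (attempt == 0) {
    km <- kmeans(values, centers = 2, nstart = 5)
    mu <- as.numeric(km$centers)
    s <- vapply(1:2, function(j) {
      v <- values[km$cluster == j]
      if (length(v) > 1) stats::sd(v) else stats::sd(values) / 2
    }, double(1))
    w <- mean(km$cluster == which.min(mu))
    ord <- order(mu)
    list(mu = mu[ord], s = pmax(s[ord], 10 * sd_floor),
         w = min(max(w, 0.05), 0.95))
  } else {
    q <- sort(sample(values, 2))
    s0 <- stats::sd(values)
    list(mu = q + rnorm(2, 0, s0 / 4),
         s = pmax(s0 * runif(2, 0.3, 1.2), 10 * sd_floor),
         w = runif(1, 0.2, 0.8))
  }
}

fit_single <- function(values, truncation_lower, keep_data) {
  n <- length(values)
  if (is.null(truncation_lower)) {
    mu <- mean(values)
    s <- sqrt(mean((values - mu)^2))
    ll <- sum(dnorm(values, mu, s, log = TRUE))
    it <- 1L; conv <- TRUE
  } else {
    nll <- function(p)
      -sum(dnorm(values, p[1], exp(p[2]), log = TRUE) -
             pnorm(truncation_lower, p[1], exp(p[2]), lower.tail = FALSE,
                   log.p = TRUE))
    o <- optim(c(mean(values), log(stats::sd(values))), nll,
               method = "BFGS", control = list(maxit = 500))
    mu <- o$par[1]; s <- exp(o$par[2]); ll <- -o$value
    it <- as.integer(o$counts[1]); conv <- o$convergence == 0
  }
  new_mixture_fit(
    components = tibble::tibble(state = "S", mean = mu, sd = s, weight = 1),
    truncation_lower = truncation_lower, loglik = ll, n = n, k = 1L,
    converged = conv, n_iter = it, loglik_trace = ll,
    data = if (keep_data) values else NULL)
}

# EM for a two-component truncated-normal mixture (ECM: the weighted
# truncated-normal M-step has no closed form and is solved with BFGS).
em_trunc2 <- function(x, b, mu, s, w, tol, max_iter, sd_floor) {
  if (any(x < b))
    abort_fmt("values below the truncation bound", "data_error")
  ldens <- function(x, m, sg)
    dnorm(x, m, sg, log = TRUE) -
      pnorm(b, m, sg, lower.tail = FALSE, log.p = TRUE)
  ll_old <- -Inf; trace <- numeric(0)
  converged <- FALSE; collapsed <- FALSE
  for (it in seq_len(max_iter)) {
    l1 <- log(w[1]) + ldens(x, mu[1], s[1])
    l2 <- log(w[2]) + ldens(x, mu[2], s[2])
    m12 <- pmax(l1, l2)
    li <- m12 + log(exp(l1 - m12) + exp(l2 - m12))
    ll <- sum(li)
    trace <- c(trace, ll)
    if (it > 1 && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-300)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    r1 <- exp(l1 - li)
    w <- c(mean(r1), 1 - mean(r1))
    for (j in 1:2) {
      r <- if (j == 1) r1 else 1 - r1
      nll <- function(p) -sum(r * (dnorm(x, p[1], exp(p[2]), log = TRUE) -
                                     pnorm(b, p[1], exp(p[2]),
                                           lower.tail = FALSE, log.p = TRUE)))
      o <- optim(c(mu[j], log(s[j])), nll, method = "BFGS",
                 control = list(maxit = 50))
      mu[j] <- o$par[1]
      s[j] <- exp(o$par[2])
    }
    if (any(s < sd_floor) || any(w < 1e-8)) { collapsed <- TRUE; break }
  }
  list(mu = mu, s = s, w = w, loglik = ll, n_iter = length(trace),
       converged = converged, collapsed = collapsed, trace = trace)
}

#' Mixture density
#'
#' Density of a fitted (possibly truncated) normal mixture at `x`.
#'
#' @param x Numeric vector (log10 units).
#' @param model A `mixture_fit`, or a tibble/data frame with `mean`, `sd`,
#'   `weight` columns.
#' @param truncation_lower Lower truncation bound; taken from the fit when
#'   `model` is a `mixture_fit`.
#' @param log Return the log density.
#' @return Numeric vector of densities.
#' @export
dmix <- function(x, model, truncation_lower = NULL, log = FALSE) {
  comp <- mixture_components(model)
  if (inherits(model, "mixture_fit") && is.null(truncation_lower))
    truncation_lower <- model$truncation_lower
  d <- rep(0, length(x))
  for (j in seq_len(nrow(comp))) {
    dj <- dnorm(x, comp$mean[j], comp$sd[j])
    if (!is.null(truncation_lower)) {
      dj <- dj / pnorm(truncation_lower, comp$mean[j], comp$sd[j],
                       lower.tail = FALSE)
      dj[x < truncation_lower] <- 0
    }
    d <- d + comp$weight[j] * dj
  }
  if (log) base::log(d) else d
}

#' Draw from a fitted mixture
#' @param n Number of draws.
#' @inheritParams dmix
#' @return Numeric vector of log10 values.
#' @export
rmix <- function(n, model, truncation_lower = NULL) {
  comp <- mixture_components(model)
  if (inherits(model, "mixture_fit") && is.null(truncation_lower))
    truncation_lower <- model$truncation_lower
  j <- sample.int(nrow(comp), n, replace = TRUE, prob = comp$weight)
  v <- rnorm(n, comp$mean[j], comp$sd[j])
  if (!is.null(truncation_lower)) {
    while (any(bad <- v < truncation_lower)) {
      jb <- j[bad]
      v[bad] <- rnorm(length(jb), comp$mean[jb], comp$sd[jb])
    }
  }
  v
}

#' @export
mixture_components <- function(model) UseMethod("mixture_components")

#' Component table of a mixture
#' @param model A `mixture_fit` or a data frame with `mean`, `sd`, `weight`.
#' @return Tibble sorted by ascending mean.
#' @export
mixture_components.mixture_fit <- function(model) model$components

#' @export
mixture_components.data.frame <- function(model) {
  stopifnot(all(c("mean", "sd", "weight") %in% names(model)))
  tibble::as_tibble(model[order(model$mean), ])
}

#' Refit mixture weights with frozen components
#'
#' Re-estimates only the component weights of an already-fitted
#' two-component mixture on a new subset of synapses (single, dual, triple
#' connections), keeping means and standard deviations fixed — the two-state
#' model predicts the components themselves are subset-invariant while the
#' S/L occupancies shift with connection multiplicity.
#'
#' @param values Log10 sizes of the subset.
#' @param fixed A fitted `mixture_fit` with 2 components (or a component
#'   tibble).
#' @param tol,max_iter EM controls.
#' @return A list with `weights` (named `S`, `L`), `loglik`, `n_iter`,
#'   `converged`.
#' @export
refit_weights <- function(values, fixed, tol = 1e-10, max_iter = 5000) {
  comp <- mixture_components(fixed)
  if (nrow(comp) != 2)
    abort_fmt("`fixed` must have exactly 2 components", "config_error")
  if (length(values) < 10)
    abort_fmt("need at least 10 values to refit weights", "data_error")
  b <- if (inherits(fixed, "mixture_fit")) fixed$truncation_lower else NULL
  ld <- vapply(1:2, function(j) {
    d <- dnorm(values, comp$mean[j], comp$sd[j], log = TRUE)
    if (!is.null(b))
      d <- d - pnorm(b, comp$mean[j], comp$sd[j], lower.tail = FALSE,
                     log.p = TRUE)
    d
  }, double(length(values)))
  w <- 0.5; ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    l1 <- log(w) + ld[, 1]
    l2 <- log(1 - w) + ld[, 2]
    m <- pmax(l1, l2)
    li <- m + log(exp(l1 - m) + exp(l2 - m))
    ll <- sum(li)
    if (it > 1 && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-300)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    w <- mean(exp(l1 - li))
  }
  list(weights = c(S = w, L = 1 - w), loglik = ll, n_iter = it,
       converged = converged)
}

#' Bootstrap standard deviation of mixture weights
#'
#' Nonparametric bootstrap: resample the synapse population with
#' replacement, refit the full mixture, and report the standard deviation of
#' the small-component weight across resamples (the `L` weight SD is
#' identical since the weights sum to one).
#'
#' @inheritParams fit_mixture
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer seed; resamples and refits are deterministic given
#'   it.
#' @return A list with `weight_sd` (named `S`, `L`), the bootstrap `weights`
#'   vector and `n_failed`.
#' @export
bootstrap_weight_sd <- function(values, k = 2, B = 200, seed = 1L,
                                truncation_lower = NULL, ...) {
  if (B < 100) abort_fmt("`B` must be at least 100", "config_error")
  n <- length(values)
  ws <- rep(NA_real_, B)
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      f <- tryCatch(
        fit_mixture(values[idx], k = k, truncation_lower = truncation_lower,
                    seed = derive_seed(seed, b), keep_data = FALSE, ...),
        spinestates_error = function(e) NULL)
      if (!is.null(f)) ws[b] <- f$components$weight[1]
    }
  })
  n_failed <- sum(is.na(ws))
  if (n_failed > 0.1 * B)
    abort_fmt(sprintf("%d of %d bootstrap fits failed", n_failed, B),
              "bootstrap_error")
  s <- stats::sd(ws, na.rm = TRUE)
  list(weight_sd = c(S = s, L = s), weights = ws, n_failed = n_failed,
       B = B)
}

#' Likelihood-ratio test: two components versus one
#'
#' Tests whether a two-component normal mixture fits the log10 sizes better
#' than a single normal, accounting for the 3 extra free parameters.  The
#' default reference is chi-squared with 3 degrees of freedom; because the
#' null lies on the boundary of the mixture parameter space this reference
#' is approximate, so a parametric bootstrap (simulate from the fitted
#' single normal, refit both models per replicate) is available as the
#' robust alternative.
#'
#' @inheritParams fit_mixture
#' @param bootstrap Also compute a parametric-bootstrap p-value.
#' @param B Bootstrap replicates.
#' @return A list of class `lrt_result`: `lr`, `df`, `p_value`, optional
#'   `p_boot`, and the two fits.
#' @export
lrt_vs_single <- function(values, truncation_lower = NULL, bootstrap = FALSE,
                          B = 500, seed = 1L) {
  if (length(values) < 20)
    abort_fmt("need at least 20 values", "data_error")
  f1 <- fit_mixture(values, k = 1, truncation_lower = truncation_lower,
                    keep_data = FALSE)
  f2 <- fit_mixture(values, k = 2, truncation_lower = truncation_lower,
                    seed = derive_seed(seed, 1L), keep_data = FALSE)
  lr <- max(0, 2 * (f2$loglik - f1$loglik))
  out <- list(lr = lr, df = 3L, p_value = pchisq(lr, df = 3, lower.tail = FALSE),
              fit1 = f1, fit2 = f2)
  if (bootstrap) {
    lr_b <- withr::with_seed(seed, {
      vapply(seq_len(B), function(b) {
        v <- rmix(length(values), f1)
        g1 <- fit_single(v, truncation_lower, keep_data = FALSE)
        g2 <- tryCatch(
          fit_mixture(v, k = 2, truncation_lower = truncation_lower,
                      seed = derive_seed(seed, 1000L + b),
                      keep_data = FALSE),
          spinestates_error = function(e) NULL)
        if (is.null(g2)) 0 else max(0, 2 * (g2$loglik - g1$loglik))
      }, double(1))
    })
    out$p_boot <- (1 + sum(lr_b >= lr)) / (B + 1)
    out$lr_boot <- lr_b
  }
  class(out) <- "lrt_result"
  out
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Normal mixture fit (k = %d, n = %d)%s\n", x$k, x$n,
              if (!is.null(x$truncation_lower))
                sprintf(", truncated below %.3f", x$truncation_lower)
              else ""))
  print(x$components)
  cat(sprintf("log-likelihood %.3f after %d EM iteration(s)%s\n", x$loglik,
              x$n_iter, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mixture_fit <- function(x, ...) x$components

#' @exportS3Method generics::glance
glance.mixture_fit <- function(x, ...) {
  npar <- if (x$k == 2) 5 else 2
  tibble::tibble(k = x$k, loglik = x$loglik, n = x$n,
                 AIC = 2 * npar - 2 * x$loglik, converged = x$converged,
                 n_iter = x$n_iter)
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LR = %.3f on %d df, p = %.3g (chi-squared)\n", x$lr, x$df,
              x$p_value))
  if (!is.null(x$p_boot))
    cat(sprintf("parametric bootstrap p = %.3g\n", x$p_boot))
  invisible(x)
}
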