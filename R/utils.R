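#' @useDynLib spinestates, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn %||% .data
#' @importFrom stats dnorm pnorm qnorm rnorm runif rbinom sd var cor kmeans
#'   optim pchisq density setNames integrate
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @keywords internal
"_PACKAGE"

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# Deterministic fan-out of one top-level seed into stage-specific seeds, so a
# stage can be rerun in isolation.  Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6) * 2039 + 7919 * offset) %% 2147483629L
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

abort_fmt <- function(msg, class) {
  abort(msg, class = c(paste0("spinestates_", class), "spinestates_error"))
}

check_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min)
    abort_fmt(sprintf("`%s` must be a single finite number >= %g", name, min),
              "config_error")
  invisible(x)
}
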