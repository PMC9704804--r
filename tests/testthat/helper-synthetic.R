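# Shared study-condition parameters and tiny fixture builders.

# All-synapse S/L components of the two-state size model (log10 um^3)
all_synapse_components <- function() {
  tibble::tibble(state = c("S", "L"), mean = c(-1.42, -0.77),
                 sd = c(0.24, 0.22))
}

# Dual-connection S/L emission components (log10 um^3)
dual_emission_components <- function() {
  tibble::tibble(state = c("S", "L"), mean = c(-1.470, -0.833),
                 sd = c(0.216, 0.244))
}

dual_state_joint <- function() c(ss = 0.490, sl = 0.0885, ls = 0.0885, ll = 0.333)

# Draw from the all-synapse two-state marginal mixture
draw_two_state <- function(n, seed, comp = all_synapse_components(),
                           w_S = 0.77) {
  withr::with_seed(seed, {
    st <- sample(c("S", "L"), n, replace = TRUE, prob = c(w_S, 1 - w_S))
    i <- match(st, comp$state)
    rnorm(n, comp$mean[i], comp$sd[i])
  })
}

# Minimal in-memory synapse table
make_table <- function(pre, post, vol, coords = NULL) {
  n <- length(vol)
  coords <- coords %||% matrix(runif(3 * n, 0, 100), ncol = 3)
  as_synapse_table(tibble::tibble(
    synapse_id = sprintf("s%03d", seq_len(n)),
    pre_id = pre, post_id = post,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    spine_volume = vol))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
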