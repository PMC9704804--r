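#' Run the full latent-state analysis
#'
#' Orchestrates the complete pipeline on a synapse table: connection
#' grouping and multiplicity statistics; full mixture fits on all synapses
#' and on the single/dual/triple subsets; weight-only refits of the subsets
#' against the frozen all-synapse components, with bootstrap weight errors;
#' geometric- and arithmetic-mean summaries of dual connections with their
#' mixture fits; bimodality tests; the correlated pair-state model with phi
#' and its three 1-D projections; state-conditioned resampling and residual
#' correlations; same-axon/same-dendrite controls; and the distance-split
#' analysis.  One top-level seed fans out deterministically to
#' stage-specific seeds, so two runs with the same inputs produce identical
#' reports.
#'
#' A stage that fails aborts the run with a stage-tagged error; if
#' `out_dir` is given, the report of the completed stages is written first.
#'
#' @param tbl A `synapse_tbl` (e.g. from [read_synapse_table()] or
#'   [generate_connectome()]).
#' @param measure Size column to analyze.
#' @param truncation_lower Lower truncation bound in log10 units, used for
#'   cleft-size fits (`log10(50)`); `NULL` for spine volumes.
#' @param seed Top-level integer seed.
#' @param n_bootstrap Bootstrap resamples for weight SDs.
#' @param n_resample_iter Iterations of the state-conditioned resampling.
#' @param n_control_draws Draws for the control pairings.
#' @param bimodality_method,bimodality_B Method and replicate count for the
#'   bimodality tests.
#' @param out_dir Optional directory for `report.json`, per-table CSVs and
#'   a line-delimited JSON log with per-stage timings and record counts.
#' @return A list of class `analysis_report`.
#' @export
run_full_analysis <- function(tbl, measure = "spine_volume",
                              truncation_lower = NULL, seed = 1L,
                              n_bootstrap = 200, n_resample_iter = 2000,
                              n_control_draws = 200,
                              bimodality_method = "asymptotic",
                              bimodality_B = 199, out_dir = NULL) {
  report <- list(config = list(measure = measure,
                               truncation_lower = truncation_lower,
                               seed = seed, n_bootstrap = n_bootstrap,
                               n_resample_iter = n_resample_iter,
                               n_control_draws = n_control_draws,
                               bimodality_method = bimodality_method))
  log <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) write_report(report, out_dir, log)
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
            class = "spinestates_stage_error")
    })
    log[[length(log) + 1]] <<- list(stage = name,
                                    seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  groups <- stage("load", {
    if (nrow(tbl) == 0) abort_fmt("empty synapse table", "data_error")
    group_connections(tbl)
  })

  report$multiplicity <- stage("multiplicity", multiplicity_fractions(groups))

  vals_all <- stage("log_transform", log_sizes(tbl, measure))
  subset_vals <- purrr::map(c(single = 1L, dual = 2L, triple = 3L),
                            function(k) {
      g <- dplyr::filter(groups, .data$multiplicity == k)
      if (nrow(g) == 0) return(numeric(0))
      log10(unlist(purrr::map(g$synapses, ~ .x[[measure]])))
  })

  fits <- stage("mixture_fits", {
    full <- list(all = fit_mixture(vals_all, 2,
                                   truncation_lower = truncation_lower,
                                   seed = derive_seed(seed, 1L)))
    for (nm in names(subset_vals))
      if (length(subset_vals[[nm]]) >= 10)
        full[[nm]] <- fit_mixture(subset_vals[[nm]], 2,
                                  truncation_lower = truncation_lower,
                                  seed = derive_seed(seed, 2L))
    full
  })

  refits <- stage("weight_refits", {
    purrr::map(subset_vals[purrr::map_int(subset_vals, length) >= 10],
               ~ refit_weights(.x, fits$all))
  })

  boot <- stage("bootstrap_weights", {
    bootstrap_weight_sd(vals_all, B = n_bootstrap,
                        seed = derive_seed(seed, 3L),
                        truncation_lower = truncation_lower)
  })

  report$lrt_all <- stage("lrt", {
    l <- lrt_vs_single(vals_all, truncation_lower = truncation_lower,
                       seed = derive_seed(seed, 4L))
    tibble::tibble(lr = l$lr, df = l$df, p_value = l$p_value)
  })

  duals <- stage("dual_pairs", dual_pairs(tbl, measure))

  summaries <- stage("connection_summaries", {
    dual_groups <- dplyr::filter(groups, .data$multiplicity == 2L)
    list(geometric = log10(connection_summary(dual_groups, "geometric",
                                              measure)$summary),
         arithmetic = log10(connection_summary(dual_groups, "arithmetic",
                                               measure)$summary))
  })

  mixture_rows <- function(nm, fit, n) {
    tibble::tibble(subset = nm, n = n,
                   mean_S = fit$components$mean[1],
                   sd_S = fit$components$sd[1],
                   weight_S = fit$components$weight[1],
                   mean_L = fit$components$mean[2],
                   sd_L = fit$components$sd[2],
                   weight_L = fit$components$weight[2],
                   loglik = fit$loglik)
  }
  report$mixture <- stage("mixture_table", {
    rows <- purrr::imap_dfr(fits, ~ mixture_rows(.y, .x, .x$n))
    refit_rows <- purrr::imap_dfr(refits, function(rf, nm) {
      tibble::tibble(subset = paste0("all_weights_refit_", nm),
                     n = length(subset_vals[[nm]]),
                     mean_S = fits$all$components$mean[1],
                     sd_S = fits$all$components$sd[1],
                     weight_S = rf$weights[["S"]],
                     mean_L = fits$all$components$mean[2],
                     sd_L = fits$all$components$sd[2],
                     weight_L = rf$weights[["L"]], loglik = rf$loglik)
    })
    mean_fits <- purrr::imap_dfr(summaries, function(v, nm) {
      if (length(v) < 10) return(tibble::tibble())
      f <- fit_mixture(v, 2, seed = derive_seed(seed, 5L))
      mixture_rows(paste0(nm, "_mean_dual"), f, length(v))
    })
    dplyr::bind_rows(rows, refit_rows, mean_fits) |>
      dplyr::mutate(weight_sd = dplyr::if_else(.data$subset == "all",
                                               boot$weight_sd[["S"]],
                                               NA_real_))
  })

  report$bimodality <- stage("bimodality", {
    targets <- list(dual_synapses = subset_vals$dual,
                    geometric_mean_dual = summaries$geometric)
    purrr::imap_dfr(targets, function(v, nm) {
      if (length(v) < 50) return(tibble::tibble())
      b <- bimodality_test(v, method = bimodality_method, B = bimodality_B,
                           seed = derive_seed(seed, 6L))
      dplyr::bind_cols(tibble::tibble(subset = nm, n = length(v)),
                       glance(b))
    })
  })

  pair_model <- stage("pair_model", {
    if (nrow(duals) < 20) abort_fmt("fewer than 20 dual connections",
                                    "data_error")
    fit_pair_model(duals, seed = derive_seed(seed, 7L))
  })
  report$pair_model <- dplyr::bind_cols(
    tibble::tibble(subset = "all_duals"), glance(pair_model),
    tibble::as_tibble(as.list(pair_model$joint)))

  report$projections <- stage("projections", {
    purrr::map_dfr(c("marginal", "mean", "ratio"), function(ax) {
      dplyr::mutate(project_joint(pair_model, ax), axis = ax,
                    .before = 1)
    })
  })

  report$resampling <- stage("resampling", {
    purrr::map_dfr(c("SS", "LL"), function(st) {
      state_conditioned_resample(duals, pair_model, st,
                                 n_iter = n_resample_iter,
                                 seed = derive_seed(seed, 8L))$summary
    })
  })

  report$residuals <- stage("residuals", {
    res <- residual_correlation(duals, pair_model)
    tibble::tibble(r = res$r, n_pairs = nrow(duals))
  })

  report$controls <- stage("controls", {
    purrr::map_dfr(c("same_axon", "same_dendrite"), function(md) {
      tidy(control_pair_analysis(tbl, pair_model, md,
                                 n_draws = n_control_draws,
                                 seed = derive_seed(seed, 9L),
                                 measure = measure))
    })
  })

  report$distance_split <- stage("distance_split", {
    ds <- distance_split_analysis(duals, seed = derive_seed(seed, 10L))
    tibble::tibble(group = c("near", "far"),
                   phi = c(ds$phi_near, ds$phi_far),
                   n = c(ds$n_near, ds$n_far),
                   threshold = ds$threshold)
  })

  report$fits <- fits
  report$pair_fit <- pair_model
  class(report) <- "analysis_report"
  if (!is.null(out_dir)) write_report(report, out_dir, log)
  report
}

write_report <- function(report, out_dir, log = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  serializable <- report[intersect(names(report),
                                   c("config", "multiplicity", "mixture",
                                     "lrt_all", "bimodality", "pair_model",
                                     "projections", "resampling",
                                     "residuals", "controls",
                                     "distance_split"))]
  jsonlite::write_json(serializable, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in c("multiplicity", "mixture", "bimodality", "controls",
               "distance_split"))
    if (!is.null(report[[nm]]) && is.data.frame(report[[nm]]))
      readr::write_csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       progress = FALSE)
  if (length(log) > 0)
    writeLines(vapply(log, function(l) jsonlite::toJSON(l, auto_unbox = TRUE),
                      character(1)),
               file.path(out_dir, "log.jsonl"))
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Latent-state synapse-size analysis\n")
  cat(sprintf("connections: %d, measure: %s\n",
              sum(x$multiplicity$n), x$config$measure))
  cat("\nMultiplicity fractions:\n"); print(x$multiplicity)
  cat("\nMixture fits:\n"); print(x$mixture)
  cat("\nPair model:\n"); print(x$pair_model)
  cat("\nResampling:\n"); print(x$resampling)
  if (!is.null(x$controls)) { cat("\nControls:\n"); print(x$controls) }
  if (!is.null(x$distance_split)) {
    cat("\nDistance split:\n"); print(x$distance_split)
  }
  invisible(x)
}
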