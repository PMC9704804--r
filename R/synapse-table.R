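#' Coerce a data frame to a synapse table
#'
#' A synapse table holds one row per synapse between reconstructed cells:
#' identifiers of the presynaptic and postsynaptic cell, the 3-D centroid of
#' the synapse in micrometres, and at least one size measurement — the
#' spine-head volume in cubic micrometres and/or the synaptic-cleft voxel
#' count.  Cleft counts below 50 voxels never pass the detector, so the cleft
#' column must be `>= 50` where present.
#'
#' @param x A data frame with columns `synapse_id`, `pre_id`, `post_id`,
#'   `x`, `y`, `z` and at least one of `spine_volume`, `cleft_size`.
#' @param metadata Optional named list of provenance (source file, units,
#'   seed) stored as an attribute.
#' @return A tibble of class `synapse_tbl`.
#' @export
as_synapse_table <- function(x, metadata = list()) {
  x <- tibble::as_tibble(x)
  required <- c("synapse_id", "pre_id", "post_id", "x", "y", "z")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0)
    abort_fmt(paste0("missing required column(s): ",
                     paste(missing, collapse = ", ")), "format_error")
  if (!any(c("spine_volume", "cleft_size") %in% names(x)))
    abort_fmt("need at least one of `spine_volume`, `cleft_size`",
              "format_error")
  if (anyDuplicated(x$synapse_id))
    abort_fmt("`synapse_id` must be unique", "format_error")
  if ("spine_volume" %in% names(x) &&
      any(x$spine_volume <= 0, na.rm = TRUE))
    abort_fmt("`spine_volume` must be positive", "format_error")
  if ("cleft_size" %in% names(x) && any(x$cleft_size < 50, na.rm = TRUE))
    abort_fmt("`cleft_size` below the 50-voxel detection cutoff",
              "format_error")
  structure(x,
            class = c("synapse_tbl", class(tibble::tibble()))) -> out
  attr(out, "metadata") <- metadata
  out
}

default_mapping <- function() {
  list(
    delim = ",",
    columns = list(synapse_id = "synapse_id", pre_id = "pre_id",
                   post_id = "post_id", x = "x", y = "y", z = "z",
                   spine_volume = "spine_volume", cleft_size = "cleft_size"),
    coord_scale = c(x = 1, y = 1, z = 1)
  )
}

#' Read a delimited synapse table
#'
#' Reads a delimited text file with a header row into a [as_synapse_table()]
#' tibble.  Column names, the delimiter, and per-axis coordinate scales
#' (voxel index to micrometre) are configurable through `mapping`, either a
#' named list or the path to a JSON sidecar with the same shape, so deposited
#' and synthetic tables share one reader.  Rows whose selected size
#' measurement is missing or non-positive are dropped and counted in the
#' `drop_report` attribute rather than raising.
#'
#' @param path Path to a CSV/TSV file with header.
#' @param mapping Named list (or path to a JSON file) with elements `delim`,
#'   `columns` (map from canonical names to file column names) and
#'   `coord_scale` (named x/y/z multipliers applied to the coordinates).
#'   Missing elements fall back to defaults: comma delimiter, identity
#'   column names, unit scales.
#' @param measure Which size column the downstream analysis will use;
#'   filtering applies to this column.
#' @return A `synapse_tbl` with attributes `drop_report` (list with
#'   `n_dropped` and the 1-based data row indices dropped) and `metadata`.
#' @export
read_synapse_table <- function(path, mapping = NULL,
                               measure = c("spine_volume", "cleft_size")) {
  measure <- match.arg(measure)
  if (is.character(mapping) && length(mapping) == 1)
    mapping <- jsonlite::read_json(mapping, simplifyVector = TRUE)
  map <- utils::modifyList(default_mapping(), as.list(mapping %||% list()))
  raw <- readr::read_delim(path, delim = map$delim,
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  cols <- map$columns
  present <- intersect(names(cols), c("synapse_id", "pre_id", "post_id",
                                      "x", "y", "z", "spine_volume",
                                      "cleft_size"))
  need <- c("synapse_id", "pre_id", "post_id", "x", "y", "z", measure)
  file_cols <- unlist(cols[present])
  have <- present[file_cols %in% names(raw)]
  if (!all(need %in% have))
    abort_fmt(paste0("input file lacks mapped column(s): ",
                     paste(unlist(cols[setdiff(need, have)]),
                           collapse = ", ")), "format_error")
  out <- tibble::tibble(.rows = nrow(raw))
  for (nm in have) out[[nm]] <- raw[[cols[[nm]]]]
  numeric_cols <- intersect(names(out),
                            c("x", "y", "z", "spine_volume", "cleft_size"))
  for (nm in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(out[[nm]]))
    bad <- which(!is.na(out[[nm]]) & out[[nm]] != "" & is.na(parsed))
    if (length(bad) > 0)
      abort_fmt(sprintf("column `%s` (file column `%s`): unparseable value at data row(s) %s",
                        nm, cols[[nm]],
                        paste(utils::head(bad, 5), collapse = ", ")),
                "row_error")
    out[[nm]] <- parsed
  }
  scale <- map$coord_scale
  for (ax in c("x", "y", "z"))
    out[[ax]] <- out[[ax]] * (scale[[ax]] %||% 1)
  keep <- !is.na(out[[measure]]) & out[[measure]] > 0
  dropped <- which(!keep)
  out <- out[keep, , drop = FALSE]
  tbl <- as_synapse_table(out, metadata = list(source = path,
                                               measure = measure,
                                               coord_units = "um"))
  attr(tbl, "drop_report") <- list(n_dropped = length(dropped),
                                   rows = dropped, measure = measure)
  tbl
}

#' Write a synapse table to CSV
#'
#' Values are written with `readr`'s shortest round-trippable representation,
#' so `read_synapse_table()` on the output reproduces every field exactly.
#'
#' @param tbl A `synapse_tbl`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synapse_table <- function(tbl, path) {
  readr::write_csv(tibble::as_tibble(tbl), path, progress = FALSE)
  invisible(path)
}

#' Report of rows dropped while reading
#' @param tbl A table returned by [read_synapse_table()].
#' @return A list with `n_dropped` and `rows`.
#' @export
drop_report <- function(tbl) attr(tbl, "drop_report")

#' Group synapses into directed connections
#'
#' A connection is an ordered (directed) presynaptic/postsynaptic cell pair;
#' reciprocal pairs are distinct connections.  Every synapse lands in exactly
#' one group.
#'
#' @param tbl A `synapse_tbl` (or plain data frame with the same columns).
#' @return A tibble with one row per connection: `connection_id`, `pre_id`,
#'   `post_id`, `multiplicity`, and a `synapses` list-column of per-synapse
#'   tibbles.
#' @export
group_connections <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  if (nrow(tbl) == 0)
    return(tibble::tibble(connection_id = character(), pre_id = character(),
                          post_id = character(), multiplicity = integer(),
                          synapses = list()))
  tbl |>
    dplyr::mutate(pre_id = as.character(.data$pre_id),
                  post_id = as.character(.data$post_id)) |>
    tidyr::nest(synapses = -c("pre_id", "post_id")) |>
    dplyr::mutate(
      connection_id = paste0(.data$pre_id, "->", .data$post_id),
      multiplicity = vapply(.data$synapses, nrow, integer(1))) |>
    dplyr::select("connection_id", "pre_id", "post_id", "multiplicity",
                  "synapses")
}

#' Fractions of connections by synapse count
#'
#' @param groups Output of [group_connections()].
#' @return A tibble with `multiplicity`, `n` and `fraction` (summing to 1).
#' @export
multiplicity_fractions <- function(groups) {
  if (nrow(groups) == 0)
    abort_fmt("no connections: cannot compute multiplicity fractions",
              "empty_error")
  groups |>
    dplyr::count(.data$multiplicity, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::arrange(.data$multiplicity)
}

#' Euclidean distance between two synapse centroids
#'
#' @param a,b Either numeric `c(x, y, z)` vectors or one-row data frames with
#'   `x`, `y`, `z` columns, in micrometres.
#' @return Distance in micrometres.
#' @export
pair_distance <- function(a, b) {
  xyz <- function(p) {
    if (is.data.frame(p)) p <- unlist(p[1, c("x", "y", "z")])
    p <- as.numeric(p)
    if (length(p) != 3 || anyNA(p))
      abort_fmt("coordinates must be 3 finite numbers", "coord_error")
    p
  }
  sqrt(sum((xyz(a) - xyz(b))^2))
}

#' Per-connection summary size
#'
#' Summarizes each connection's synapse sizes by the geometric mean
#' (`10^mean(log10 v)`, i.e. the mean in log space) or the arithmetic mean.
#'
#' @param groups Output of [group_connections()].
#' @param mode `"geometric"` or `"arithmetic"`.
#' @param measure Size column to summarize.
#' @return `groups` with an added `summary` column (same units as `measure`).
#' @export
connection_summary <- function(groups, mode = c("geometric", "arithmetic"),
                               measure = "spine_volume") {
  mode <- match.arg(mode)
  vals <- purrr::map_dbl(groups$synapses, function(s) {
    v <- s[[measure]]
    if (is.null(v) || anyNA(v) || any(v <= 0))
      abort_fmt(sprintf("measure `%s` missing or non-positive in a connection",
                        measure), "measure_error")
    if (mode == "geometric") 10^mean(log10(v)) else mean(v)
  })
  dplyr::mutate(groups, summary = vals)
}

#' Log10-transformed sizes
#'
#' Sizes are log10-transformed before any statistical modelling: log10 um^3
#' for spine volumes, log10 voxels for cleft sizes.
#'
#' @param tbl A `synapse_tbl`.
#' @param measure Size column.
#' @return Numeric vector of finite log10 values, one per row of `tbl`.
#' @export
log_sizes <- function(tbl, measure = "spine_volume") {
  v <- tbl[[measure]]
  if (is.null(v))
    abort_fmt(sprintf("no `%s` column", measure), "measure_error")
  if (anyNA(v) || any(v <= 0))
    abort_fmt(sprintf("`%s` must be present and positive for all rows",
                      measure), "measure_error")
  log10(v)
}

#' Extract dual-connection pairs
#'
#' Selects connections with exactly two synapses and returns one row per
#' dual connection with the log10 sizes of its two synapses and the
#' Euclidean distance between them.  Order within a pair is lexicographic by
#' `synapse_id`, which carries no information: downstream fitting symmetrizes
#' over order.
#'
#' @inheritParams log_sizes
#' @return A tibble with `connection_id`, `pre_id`, `post_id`, `v1`, `v2`
#'   (log10 sizes) and `distance` (micrometres).
#' @export
dual_pairs <- function(tbl, measure = "spine_volume") {
  groups <- group_connections(tbl)
  duals <- dplyr::filter(groups, .data$multiplicity == 2L)
  if (nrow(duals) == 0)
    return(tibble::tibble(connection_id = character(), pre_id = character(),
                          post_id = character(), v1 = double(),
                          v2 = double(), distance = double()))
  info <- purrr::map(duals$synapses, function(s) {
    s <- s[order(as.character(s$synapse_id)), ]
    v <- s[[measure]]
    if (is.null(v) || anyNA(v) || any(v <= 0))
      abort_fmt(sprintf("measure `%s` missing in a dual connection", measure),
                "measure_error")
    d <- if (all(c("x", "y", "z") %in% names(s)) && !anyNA(s[, c("x", "y", "z")]))
      pair_distance(s[1, ], s[2, ]) else NA_real_
    c(log10(v[1]), log10(v[2]), d)
  })
  duals |>
    dplyr::mutate(v1 = purrr::map_dbl(info, 1),
                  v2 = purrr::map_dbl(info, 2),
                  distance = purrr::map_dbl(info, 3)) |>
    dplyr::select("connection_id", "pre_id", "post_id", "v1", "v2",
                  "distance")
}
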