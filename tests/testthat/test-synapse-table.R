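test_that("reading a well-formed file yields one record per row", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    synapse_id = c("a", "b", "c"), pre_id = "p1", post_id = "q1",
    x = 1:3, y = 4:6, z = 7:9, spine_volume = c(0.01, 0.1, 0.5)), path)
  tbl <- read_synapse_table(path)
  expect_s3_class(tbl, "synapse_tbl")
  expect_equal(nrow(tbl), 3)
  expect_equal(drop_report(tbl)$n_dropped, 0)
})

test_that("rows with non-positive selected size are dropped and reported", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    synapse_id = c("a", "b", "c"), pre_id = "p1", post_id = "q1",
    x = 1:3, y = 1:3, z = 1:3, spine_volume = c(0.01, 0, 0.5)), path)
  tbl <- read_synapse_table(path)
  expect_equal(nrow(tbl), 2)
  expect_equal(drop_report(tbl)$n_dropped, 1)
  expect_equal(drop_report(tbl)$rows, 2L)
})

test_that("column mapping and coordinate scaling work via a JSON sidecar", {
  path <- withr::local_tempfile(fileext = ".csv")
  side <- withr::local_tempfile(fileext = ".json")
  readr::write_csv(tibble::tibble(
    id = "a", pre = "p", post = "q", cx = 100, cy = 200, cz = 10,
    vol = 0.02), path)
  jsonlite::write_json(list(
    columns = list(synapse_id = "id", pre_id = "pre", post_id = "post",
                   x = "cx", y = "cy", z = "cz", spine_volume = "vol"),
    coord_scale = list(x = 0.00358, y = 0.00358, z = 0.04)),
    side, auto_unbox = TRUE, digits = NA)
  tbl <- read_synapse_table(path, mapping = side)
  expect_equal(tbl$x, 0.358)
  expect_equal(tbl$z, 0.4)
})

test_that("write/read round-trip reproduces every field exactly", {
  tbl <- generate_connectome(connectome_config(n_connections = 40), seed = 3)
  tbl <- dplyr::select(tibble::as_tibble(tbl), -dplyr::starts_with("."))
  path <- withr::local_tempfile(fileext = ".csv")
  write_synapse_table(as_synapse_table(tbl), path)
  back <- read_synapse_table(path)
  for (nm in names(tbl)) expect_identical(back[[nm]], tbl[[nm]])
})

test_that("reader errors name the missing column and the bad row", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(synapse_id = "a", pre_id = "p",
                                  post_id = "q", x = 1, y = 1, z = 1), path)
  expect_error(read_synapse_table(path), class = "spinestates_format_error")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("synapse_id,pre_id,post_id,x,y,z,spine_volume",
               "a,p,q,1,1,oops,0.1"), path2)
  expect_error(read_synapse_table(path2), regexp = "row",
               class = "spinestates_row_error")
})

test_that("grouping respects direction and partitions every synapse", {
  tbl <- make_table(pre = c("A", "A", "B"), post = c("B", "B", "A"),
                    vol = c(0.1, 0.2, 0.3))
  g <- group_connections(tbl)
  expect_equal(nrow(g), 2)
  expect_setequal(g$multiplicity, c(2L, 1L))
  expect_equal(sum(g$multiplicity), nrow(tbl))
  expect_equal(nrow(group_connections(tibble::tibble())), 0)
})

test_that("group count on synthetic tables equals the generated connection count", {
  cfg <- connectome_config(n_connections = 300)
  tbl <- generate_connectome(cfg, seed = 11)
  g <- group_connections(tbl)
  expect_equal(nrow(g), 300)
  expect_equal(sum(g$multiplicity), nrow(tbl))
})

test_that("multiplicity fractions match the published connection counts", {
  counts <- c(1546, 160, 24, 3, 2)
  tbl <- make_table(pre = sprintf("p%04d", rep(seq_len(sum(counts)),
                                               rep(1:5, counts))),
                    post = "q",
                    vol = rep(0.1, sum(rep(1:5, counts))))
  # distinct directed pairs per connection
  tbl$post_id <- tbl$pre_id
  tbl$pre_id <- "hub"
  g <- group_connections(tbl)
  mf <- multiplicity_fractions(g)
  expect_equal(sum(mf$fraction), 1, tolerance = 1e-12)
  expect_equal(round(mf$fraction[mf$multiplicity == 1], 3), 0.891)
  expect_equal(round(mf$fraction[mf$multiplicity == 2], 4), 0.0922)
  expect_equal(round(mf$fraction[mf$multiplicity == 3], 4), 0.0138)
})

test_that("multiplicity fractions handle simple cases and reject empty input", {
  g1 <- group_connections(make_table(c("a", "b"), c("x", "y"), c(0.1, 0.2)))
  expect_equal(multiplicity_fractions(g1)$fraction, 1)
  g2 <- group_connections(make_table(c("a", "a", "b", "c"),
                                     c("x", "x", "y", "z"),
                                     rep(0.1, 4)))
  mf <- multiplicity_fractions(g2)
  expect_equal(mf$fraction[mf$multiplicity == 1], 2 / 3)
  expect_equal(mf$fraction[mf$multiplicity == 2], 1 / 3)
  expect_error(multiplicity_fractions(g2[0, ]),
               class = "spinestates_empty_error")
})

test_that("pair_distance is a metric", {
  expect_equal(pair_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(pair_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(pair_distance(c(1, 2), c(1, 2, 3)),
               class = "spinestates_coord_error")
  withr::with_seed(42, {
    for (i in 1:1000) {
      p <- matrix(runif(9, -50, 50), 3)
      dab <- pair_distance(p[1, ], p[2, ])
      dbc <- pair_distance(p[2, ], p[3, ])
      dac <- pair_distance(p[1, ], p[3, ])
      expect_true(dac <= dab + dbc + 1e-12)
      expect_equal(dab, pair_distance(p[2, ], p[1, ]))
      expect_gte(dab, 0)
    }
  })
})

test_that("connection summaries: geometric mean is the mean in log space", {
  g <- group_connections(make_table(c("a", "a"), c("x", "x"),
                                    c(0.01, 0.1)))
  expect_equal(connection_summary(g, "geometric")$summary, 10^(-1.5),
               tolerance = 1e-12)
  expect_equal(connection_summary(g, "arithmetic")$summary, 0.055)
  ge <- group_connections(make_table(c("a", "a"), c("x", "x"),
                                     c(0.2, 0.2)))
  expect_equal(connection_summary(ge, "geometric")$summary, 0.2)
  expect_equal(connection_summary(ge, "arithmetic")$summary, 0.2)
  withr::with_seed(1, {
    for (i in 1:50) {
      v <- 10^runif(2, -2, 0)
      gg <- group_connections(make_table(c("a", "a"), c("x", "x"), v))
      gm <- connection_summary(gg, "geometric")$summary
      am <- connection_summary(gg, "arithmetic")$summary
      expect_lte(gm, am + 1e-12)
      expect_equal(log10(gm), mean(log10(v)), tolerance = 1e-12)
    }
  })
})

test_that("dual_pairs extracts log sizes and distances for 2-synapse connections", {
  tbl <- make_table(pre = c("A", "A", "B"), post = c("B", "B", "C"),
                    vol = c(0.01, 0.1, 0.5),
                    coords = rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1)))
  d <- dual_pairs(tbl)
  expect_equal(nrow(d), 1)
  expect_equal(sort(c(d$v1, d$v2)), c(-2, -1))
  expect_equal(d$distance, 5)
})
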