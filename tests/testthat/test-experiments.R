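test_that("scatter tables carry one row per protocol order with flags", {
  m <- abstract_model("negFB")
  tab <- scatter_experiment(m, spacing = 4, interval = 2)
  expect_equal(nrow(tab), 12)
  expect_equal(sum(tab$is_sequential), 1)
  expect_equal(tab$order[tab$is_sequential], "0-1-2-3-4")
  expect_equal(tab$Q[tab$is_sequential], 1)
  expect_true(all(abs(tab$Q) <= 1))
  expect_equal(attr(tab, "interval"), 2)
})

test_that("selectivity matrices validate their axes and bound their cells", {
  m <- abstract_model("negFB")
  M <- selectivity_matrix(m, intervals = c(1, 2), spacings = c(3, 6))
  expect_s3_class(M, "selectivity_matrix")
  expect_equal(dim(M), c(2, 2))
  expect_true(all(M[is.finite(M)] <= 1))
  expect_equal(attr(M, "zone_length"), 4 * c(3, 6) + 1)
  expect_error(selectivity_matrix(m, intervals = c(2, 1), spacings = c(3)),
               "increasing")
  expect_error(selectivity_matrix(m, intervals = numeric(0), spacings = 3),
               "increasing")
})

test_that("the preferred cell breaks ties toward small interval then spacing", {
  M <- structure(matrix(c(0.5, 0.9, 0.9, 0.1), 2, 2),
                 class = c("selectivity_matrix", "matrix"),
                 intervals = c(1, 2), spacings = c(3, 6))
  pc <- preferred_cell(M)
  # both (2 s, 3 um) and (1 s, 6 um) hold the max; smaller interval wins
  expect_equal(unname(pc[c("interval", "spacing")]), c(1, 6))
})

test_that("model selectivity at the tuned points is ordered switch > FHN > negFF > negFB ~ 0", {
  sel <- sapply(c("negFB", "negFF", "FHN", "switch"), function(fam) {
    m <- abstract_model(fam)
    selectivity(atot_subsample(m, m$tuned[["spacing"]],
                               m$tuned[["interval"]]))$selectivity
  })
  expect_lt(abs(sel[["negFB"]]), 0.05)
  expect_gt(sel[["negFF"]], sel[["negFB"]])
  expect_gt(sel[["FHN"]], sel[["negFF"]])
  expect_gt(sel[["switch"]], sel[["FHN"]])
  expect_gt(sel[["switch"]], 0.5)
})

test_that("parameter sensitivity reproduces the reference at factor 1 and validates names", {
  m <- abstract_model("switch")
  tab <- parameter_sensitivity(m, "k1a", factors = c(0.9, 1, 1.1))
  expect_equal(nrow(tab), 3)
  ref <- selectivity(atot_subsample(m, m$tuned[["spacing"]],
                                    m$tuned[["interval"]]))$selectivity
  expect_equal(tab$selectivity[tab$factor == 1], ref, tolerance = 1e-8)
  expect_error(parameter_sensitivity(m, "nope"), "valid: k1a")
  # stimulus-side parameters are accepted
  tab2 <- parameter_sensitivity(m, "amplitude", factors = 1)
  expect_equal(tab2$selectivity, ref, tolerance = 1e-8)
})

test_that("sweep outputs are reproducible bit-for-bit", {
  m <- abstract_model("negFF")
  M1 <- selectivity_matrix(m, intervals = c(1.5, 2.5), spacings = c(3, 5))
  M2 <- selectivity_matrix(m, intervals = c(1.5, 2.5), spacings = c(3, 5))
  expect_identical(unclass(M1), unclass(M2))
})

test_that("matrices serialise to CSV with labelled axes and a JSON sidecar", {
  m <- abstract_model("negFB")
  M <- selectivity_matrix(m, intervals = c(1, 2), spacings = c(3, 6))
  path <- file.path(tempdir(), "mat.csv")
  write_selectivity_matrix(M, path)
  df <- read.csv(path)
  expect_equal(df$interval, c(1, 2))
  expect_equal(names(df)[-1], c("spacing_3", "spacing_6"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$model, "negFB")
  expect_equal(side$spacings_um, c(3, 6))
  unlink(c(path, paste0(path, ".json")))
})
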