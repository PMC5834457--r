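# Feature catalogue, extraction, and paired-core reduction.

test_that("the catalogue has the fixed factorial structure", {
  cat <- build_catalogue()
  expect_identical(nrow(cat), 1536L)
  expect_identical(as.integer(table(cat$compartment)), c(768L, 768L))
  expect_identical(as.integer(table(cat$object_class)), c(768L, 768L))
  expect_identical(length(unique(cat$base)), 96L)
  expect_false(anyDuplicated(cat$name) > 0)
  # stable across calls, and the name ordering is versioned via a checksum:
  # any change to names or their order must be a deliberate version bump
  expect_identical(cat, build_catalogue())
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(cat$name, collapse = "|"), tf)
  expect_identical(unname(tools::md5sum(tf)), "a713c4714d6eea153cbc37929ee68eff")
})

test_that("a single square object yields its analytic measurements", {
  h <- 32L
  lab <- matrix(0L, h, h)
  lab[11:20, 11:20] <- 1L            # 10x10 square, area 100
  comp <- matrix(1L, h, h)           # all epithelial
  img <- array(0.5, dim = c(h, h, 3))
  seg <- manual_seg(lab, comp, list(`1` = "epithelial_nucleus"))
  fv <- extract_features(img, seg)
  expect_identical(fv[["epithelial.nuclear.area.mean"]], 100)
  expect_identical(fv[["epithelial.nuclear.area.max"]], 100)
  expect_identical(fv[["epithelial.nuclear.area.min"]], 100)
  expect_identical(fv[["epithelial.nuclear.area.sd"]], 0)
  expect_equal(fv[["epithelial.nuclear.equiv_diameter.mean"]], 2 * sqrt(100 / pi))
  expect_equal(fv[["epithelial.nuclear.extent.mean"]], 1)
  expect_equal(fv[["epithelial.nuclear.solidity.mean"]], 1)
  expect_equal(fv[["epithelial.nuclear.mean_R.mean"]], 0.5)
  expect_equal(fv[["epithelial.nuclear.sd_R.mean"]], 0)
  # no stromal objects: all 768 stromal features NA
  expect_true(all(is.na(fv[startsWith(names(fv), "stromal.")])))
  expect_identical(sum(startsWith(names(fv), "stromal.")), 768L)
})

test_that("mean features are invariant to duplicating every object", {
  h <- 40L
  lab1 <- matrix(0L, h, h); lab1[5:10, 5:12] <- 1L
  lab2 <- lab1; lab2[25:30, 25:32] <- 2L  # identical disjoint copy
  comp <- matrix(1L, h, h)
  img <- array(0.4, dim = c(h, h, 3))
  f1 <- extract_features(img, manual_seg(lab1, comp, list(`1` = "epithelial_nucleus")))
  f2 <- extract_features(img, manual_seg(lab2, comp, list(`1` = "epithelial_nucleus",
                                                          `2` = "epithelial_nucleus")))
  means <- grepl("\\.mean$", names(f1)) & startsWith(names(f1), "epithelial.nuclear")
  expect_equal(f2[means], f1[means])
})

test_that("size and shape features are translation invariant", {
  h <- 48L
  lab <- matrix(0L, h, h); lab[5:11, 6:14] <- 1L
  lab_shift <- matrix(0L, h, h); lab_shift[25:31, 20:28] <- 1L
  comp <- matrix(2L, h, h)
  img <- array(0.6, dim = c(h, h, 3))
  f1 <- extract_features(img, manual_seg(lab, comp, list(`1` = "inflammatory_cell")))
  f2 <- extract_features(img, manual_seg(lab_shift, comp, list(`1` = "inflammatory_cell")))
  morpho <- c("area", "perimeter", "equiv_diameter", "major_axis", "minor_axis",
              "eccentricity", "solidity", "extent", "circularity", "aspect_ratio",
              "convex_area", "border_length", "radius_mean", "radius_sd",
              "roundness", "compactness")
  sel <- names(f1)[vapply(strsplit(names(f1), ".", fixed = TRUE),
                          function(p) p[1] == "stromal" && p[2] == "nuclear" &&
                            p[3] %in% morpho, logical(1))]
  expect_equal(f1[sel], f2[sel])
})

test_that("case averaging follows the single-core fallback rules", {
  v1 <- c(a = 0.2, b = NA, c = NA, d = 1)
  v2 <- c(a = 0.4, b = 5.0, c = NA, d = 1)
  out <- case_average(v1, v2)
  expect_equal(out[["a"]], 0.3)
  expect_identical(out[["b"]], 5.0)
  expect_identical(out[["c"]], NA_real_)
  expect_identical(out[["d"]], 1)
  # commutative
  expect_identical(case_average(v2, v1), out)
  # identical cores pass through
  expect_identical(case_average(v2, v2), v2)
  expect_error(case_average(v1, v2[1:3]), "catalogue")
})

test_that("paired-core correlation matches its closed forms", {
  m <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  expect_equal(unname(paired_core_correlation(m, m)), rep(1, 3))
  expect_equal(unname(paired_core_correlation(m, -m)), rep(-1, 3))
  mc <- m; mc[, 2] <- 7  # constant feature
  expect_warning(rho <- paired_core_correlation(mc, m), "constant")
  expect_true(is.na(rho[["f2"]]))
  expect_error(paired_core_correlation(m, m[, c(2, 1, 3)]), "catalogue")
  # fewer than 3 complete pairs -> NA
  m2 <- m; m2[3:10, 1] <- NA
  rho2 <- suppressWarnings(paired_core_correlation(m2, m))
  expect_true(is.na(rho2[["f1"]]))
})

test_that("paired-core correlation falls in the band implied by heterogeneity", {
  set.seed(31)
  truth <- rbeta(1000, 1, 3)
  core1 <- pmin(pmax(truth + rnorm(1000, 0, 0.2), 0), 1)
  core2 <- pmin(pmax(truth + rnorm(1000, 0, 0.2), 0), 1)
  rho <- paired_core_correlation(matrix(core1, dimnames = list(NULL, "si")),
                                 matrix(core2, dimnames = list(NULL, "si")))
  # attenuation: var(truth)/(var(truth)+0.04) with clipping, near 0.4-0.6
  expect_gt(rho[["si"]], 0.30)
  expect_lt(rho[["si"]], 0.65)
})

test_that("features extracted from a segmented synthetic core are complete", {
  fx <- test_seg_fixture()
  fv <- extract_features(fx$sim$image, fx$seg)
  expect_identical(length(fv), 1536L)
  expect_identical(names(fv), build_catalogue()$name)
  expect_lt(mean(is.na(fv)), 0.05)
  # epithelial nuclei are larger than stromal (inflammatory) cells by design
  expect_gt(fv[["epithelial.nuclear.area.mean"]], fv[["stromal.nuclear.area.mean"]])
})
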