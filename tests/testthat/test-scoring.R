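# SI scoring rules: raw fraction, quantization, case averaging, delta,
# PD-L1, concordance.

test_that("quantization follows the 0.05 grid with round-half-up midpoints", {
  expect_identical(quantize_si(0.34), 0.35)
  expect_identical(quantize_si(0.30), 0.30)
  expect_identical(quantize_si(0), 0)
  expect_identical(quantize_si(1), 1)
  expect_identical(quantize_si(0.025), 0.05)  # exact midpoint rounds up
  expect_identical(quantize_si(0.024), 0.00)
  grid <- seq(0, 1, by = 0.05)
  expect_equal(quantize_si(grid), grid)                   # grid fixed points
  x <- seq(0, 1, by = 0.01)
  expect_identical(quantize_si(quantize_si(x)), quantize_si(x))  # idempotent
  expect_true(all(abs(quantize_si(x) - x) <= 0.025 + 1e-9))
  expect_error(quantize_si(1.2), "\\[0, 1\\]")
  expect_error(quantize_si(-0.1), "\\[0, 1\\]")
  expect_identical(quantize_si(c(0.1, NA)), c(0.1, NA))
})

test_that("case SI follows the mean / single-core / NA rules", {
  expect_equal(case_si(0.30, 0.40), 0.35)
  expect_identical(case_si(NA, 0.50), 0.50)
  expect_identical(case_si(0.50, NA), 0.50)
  expect_identical(case_si(NA_real_, NA_real_), NA_real_)
  expect_equal(case_si(0.2, 0.6), case_si(0.6, 0.2))  # symmetric
})

test_that("delta-value and its median split behave as specified", {
  expect_equal(delta_value(0.2, 0.7), 0.5)
  expect_equal(delta_value(0.7, 0.2), 0.5)
  expect_identical(delta_value(0.4, 0.4), 0)
  expect_true(is.na(delta_value(NA, 0.4)))
  d <- c(0.0, 0.1, 0.2, 0.3)
  s <- split_by_median(d)
  expect_identical(as.character(s), c("low", "low", "high", "high"))
  expect_identical(levels(s), c("low", "high"))
  # ties at the median go low; degenerate split warns
  expect_identical(as.character(split_by_median(c(0.1, 0.1, 0.5)))[1:2],
                   c("low", "low"))
  expect_warning(split_by_median(rep(0, 5)), "degenerate")
  expect_error(split_by_median(NA_real_), "2 non-NA")
})

test_that("PD-L1 scoring enforces the viable-cell minimum", {
  expect_identical(pdl1_core_score(rep(TRUE, 100), rep(FALSE, 100)), 0)
  expect_true(is.na(pdl1_core_score(rep(TRUE, 99), rep(TRUE, 99))))
  expect_equal(pdl1_core_score(rep(TRUE, 150), rep(c(TRUE, FALSE), c(30, 120))), 0.2)
  # non-viable stained cells do not count in either direction
  v <- c(rep(TRUE, 100), rep(FALSE, 50))
  s <- c(rep(FALSE, 100), rep(TRUE, 50))
  expect_identical(pdl1_core_score(v, s), 0)
  expect_equal(pdl1_case_score(0.1, 0.3), 0.2)
  expect_identical(pdl1_case_score(NA, 0.3), 0.3)
  expect_true(is.na(pdl1_case_score(NA_real_, NA_real_)))
  # stratum boundary: exactly the zero scores are "low"
  st <- pdl1_stratum(c(0, 0.001, 0.5, 0))
  expect_identical(as.character(st), c("low", "high", "high", "low"))
})

test_that("concordance matches closed forms and guards degeneracy", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(concordance(x, x * 3 + 1), 1)
  expect_equal(concordance(x, rev(x)), -1)
  expect_warning(r <- concordance(x, rep(2, 5)), "constant")
  expect_true(is.na(r))
  expect_warning(r2 <- concordance(c(1, 2, NA, NA, NA), c(1, 2, NA, NA, NA)),
                 "pairs")
  expect_true(is.na(r2))
})

test_that("two quantized noisy readings of one truth land in the expected band", {
  set.seed(21)
  truth <- rbeta(300, 1.2, 3)
  read1 <- quantize_si(pmin(pmax(truth + rnorm(300, 0, 0.05), 0), 1))
  read2 <- quantize_si(pmin(pmax(truth + rnorm(300, 0, 0.05), 0), 1))
  rho <- concordance(read1, read2)
  # observer noise of 0.05 on scores with SD ~0.16 implies rho near 0.85-0.95
  expect_gt(rho, 0.78)
  expect_lt(rho, 0.98)
})

test_that("raw SI counts only stromal inflammatory area", {
  h <- 40L
  comp <- matrix(2L, h, h)          # all stroma
  comp[, 1:10] <- 1L                # an epithelial band
  lab <- matrix(0L, h, h)
  lab[5:6, 15:16] <- 1L             # inflammatory cell in stroma
  lab[15:16, 20:21] <- 2L           # another
  seg <- manual_seg(lab, comp, list(`1` = "inflammatory_cell",
                                    `2` = "inflammatory_cell"))
  expect_identical(compute_si_raw(seg), 8 / sum(comp == 2L))
  # moving one cell into the epithelial band strictly decreases raw SI
  lab2 <- matrix(0L, h, h)
  lab2[5:6, 3:4] <- 1L              # now intraepithelial
  lab2[15:16, 20:21] <- 2L
  seg2 <- manual_seg(lab2, comp, list(`1` = "inflammatory_cell",
                                      `2` = "inflammatory_cell"))
  expect_lt(compute_si_raw(seg2), compute_si_raw(seg))
  # relabeling object ids leaves the score unchanged
  lab3 <- lab; lab3[lab == 1L] <- 2L; lab3[lab == 2L] <- 1L
  seg3 <- manual_seg(lab3, comp, list(`1` = "inflammatory_cell",
                                      `2` = "inflammatory_cell"))
  expect_identical(compute_si_raw(seg3), compute_si_raw(seg))
  # zero stromal area -> NA with a warning
  comp_epi <- matrix(1L, h, h)
  seg4 <- manual_seg(lab, comp_epi, list(`1` = "inflammatory_cell",
                                         `2` = "inflammatory_cell"))
  expect_warning(r <- compute_si_raw(seg4), "stromal")
  expect_true(is.na(r))
})

test_that("raw SI is zero on an uninflamed core", {
  sim <- generate_tma_image(image_sim_params(seed = 5, stromal_inflammation_density = 0))
  seg <- segment_tma(sim$image, test_model())
  expect_identical(compute_si_raw(seg), 0)
})
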