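# Superpixels, compartment classification, cell segmentation, midline audit.

test_that("superpixel partition covers tissue at the requested granularity", {
  img <- array(0.5, dim = c(96, 96, 3))  # uniform mid-gray: all tissue
  s <- 8
  spx <- compute_superpixels(img, target_size = s)
  expect_true(all(spx$labels > 0L))
  expect_identical(sort(unique(as.vector(spx$labels))), seq_len(spx$n))
  expected_k <- 96 * 96 / s^2
  expect_gt(spx$n, expected_k / 2)
  expect_lt(spx$n, expected_k * 2)
  # deterministic rerun
  expect_identical(spx$labels, compute_superpixels(img, target_size = s)$labels)
})

test_that("an all-background image yields an empty map with a warning", {
  img <- array(1, dim = c(32, 32, 3))
  expect_warning(spx <- compute_superpixels(img), "no tissue")
  expect_identical(spx$n, 0L)
  expect_true(all(spx$labels == 0L))
})

test_that("classifier training validates its inputs and is symmetric", {
  set.seed(1)
  d <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  d[1:50, 1] <- d[1:50, 1] + 4  # separable
  y <- rep(c("epithelial", "stromal"), each = 50)
  expect_error(train_compartment_classifier(d[1:50, ], y[1:50]), "stromal")
  m <- train_compartment_classifier(d, y)
  expect_gte(m$resubstitution_accuracy, 0.95)
  # swapped labels give the complementary prediction
  m_swap <- train_compartment_classifier(d, ifelse(y == "epithelial", "stromal", "epithelial"))
  spx_like <- list(n = 100L, labels = matrix(1L, 1, 1), descriptors = d)
  class(spx_like) <- "superpixel_map"
  p1 <- classify_compartments(spx_like, m)
  p2 <- classify_compartments(spx_like, m_swap)
  expect_true(all(p1 != p2))
  # duplicated examples leave the fitted rule unchanged
  m_dup <- train_compartment_classifier(rbind(d, d[1:30, ]), c(y, y[1:30]))
  expect_identical(classify_compartments(spx_like, m_dup), p1)
})

test_that("held-out compartment accuracy is high on separable descriptors", {
  set.seed(2)
  mk <- function(n) {
    d <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rep(c("epithelial", "stromal"), length.out = n)
    d[y == "epithelial", 1] <- d[y == "epithelial", 1] + 5
    list(d = d, y = y)
  }
  tr <- mk(200); te <- mk(400)
  m <- train_compartment_classifier(tr$d, tr$y)
  spx_like <- structure(list(n = 400L, labels = matrix(1L, 1, 1),
                             descriptors = te$d), class = "superpixel_map")
  expect_gte(mean(classify_compartments(spx_like, m) == te$y), 0.95)
})

test_that("trained pipeline recovers compartments on synthetic tissue", {
  fx <- test_seg_fixture()
  seg <- fx$seg; truth <- fx$sim$truth
  # superpixel-majority accuracy against the ground-truth compartments
  truth_code <- vapply(seq_len(seg$spx$n), function(k) {
    v <- truth$compartment_mask[seg$spx$labels == k]
    which.max(tabulate(v + 1L, nbins = 3L)[2:3])
  }, integer(1))
  pred_code <- c(epithelial = 1L, stromal = 2L)[seg$compartment_labels]
  expect_gte(mean(pred_code == truth_code), 0.90)
  # rerun with the same model gives identical labels
  seg2 <- segment_tma(fx$sim$image, test_model())
  expect_identical(seg$compartment_labels, seg2$compartment_labels)
})

test_that("a stroma-only image is classified all-stromal", {
  sim <- generate_tma_image(image_sim_params(seed = 3, epithelial_fraction = 0,
                                             stromal_inflammation_density = 0.2))
  spx <- compute_superpixels(sim$image)
  labs <- classify_compartments(spx, test_model())
  expect_gte(mean(labs == "stromal"), 0.97)
})

test_that("classification is invariant to superpixel order and checks dims", {
  fx <- test_seg_fixture()
  spx <- fx$seg$spx
  perm <- rev(seq_len(spx$n))
  spx_perm <- spx
  spx_perm$descriptors <- spx$descriptors[perm, , drop = FALSE]
  relab <- spx$labels; sel <- relab > 0L
  relab[sel] <- match(relab[sel], perm)
  spx_perm$labels <- relab
  p <- classify_compartments(spx, test_model())
  p_perm <- classify_compartments(spx_perm, test_model())
  expect_identical(p_perm, p[perm])
  bad <- spx
  bad$descriptors <- spx$descriptors[, 1:3, drop = FALSE]
  expect_error(classify_compartments(bad, test_model()), "descriptor")
})

test_that("cell detection counts track ground truth on synthetic cores", {
  fx <- test_seg_fixture()
  n_truth <- length(fx$sim$truth$cell_classes)
  n_det <- nrow(fx$seg$cells$objects)
  expect_gte(n_det, 0.9 * n_truth)
  expect_lte(n_det, 1.1 * n_truth)
  # structural invariants: disjoint pixel sets inside the image
  lab <- fx$seg$cells$labels
  expect_true(all(lab >= 0L))
  expect_lte(sum(lab > 0L), sum(fx$seg$compartments > 0L))
  areas <- tabulate(lab[lab > 0L])
  expect_identical(sort(unique(lab[lab > 0L])), seq_along(areas))
  expect_true(all(areas[areas > 0] >= 5L))
  # no cytoplasm pixel overlaps a nucleus pixel
  expect_false(any(fx$seg$cells$cyto_labels > 0L & lab > 0L))
})

test_that("blank stroma yields zero inflammatory objects", {
  sim <- generate_tma_image(image_sim_params(seed = 5, stromal_inflammation_density = 0))
  seg <- segment_tma(sim$image, test_model())
  expect_identical(sum(seg$cells$objects$class == "inflammatory_cell"), 0L)
})

test_that("the midline audit matches its protocol", {
  fx <- test_seg_fixture()
  truth <- fx$sim$truth
  h <- nrow(truth$compartment_mask)
  mid <- h %/% 2 + 1L
  # a segmentation built from the truth itself audits perfectly
  spx <- fx$seg$spx
  truth_labels <- vapply(seq_len(spx$n), function(k) {
    v <- truth$compartment_mask[spx$labels == k]
    c("epithelial", "stromal")[which.max(tabulate(v + 1L, nbins = 3L)[2:3])]
  }, character(1))
  seg_perfect <- fx$seg
  seg_perfect$compartment_labels <- truth_labels
  seg_perfect$cells$labels <- truth$cell_mask
  a <- audit_accuracy(seg_perfect, truth)
  expect_identical(a$superpixel_accuracy, 1)
  expect_identical(a$nucleus_accuracy, 1)
  expect_gt(a$n_superpixels_audited, 0L)
  # inverting every compartment label complements the superpixel accuracy
  seg_inv <- seg_perfect
  seg_inv$compartment_labels <- ifelse(truth_labels == "epithelial", "stromal", "epithelial")
  expect_identical(audit_accuracy(seg_inv, truth)$superpixel_accuracy,
                   1 - a$superpixel_accuracy)
  # changes away from the midline leave the audit untouched
  off_mid <- setdiff(unique(spx$labels[c(1L, h), ]), unique(spx$labels[mid, ]))
  off_mid <- setdiff(off_mid, 0L)
  seg_off <- seg_perfect
  seg_off$compartment_labels[off_mid] <-
    ifelse(truth_labels[off_mid] == "epithelial", "stromal", "epithelial")
  expect_identical(audit_accuracy(seg_off, truth)$superpixel_accuracy,
                   a$superpixel_accuracy)
})
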