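# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# A compartment classifier trained on ground-truth-labeled superpixels of
# two default synthetic cores.
test_model <- function() {
  memo("model", {
    sims <- lapply(1:2, function(s) generate_tma_image(image_sim_params(seed = s)))
    ex <- lapply(sims, training_examples_from_truth)
    train_compartment_classifier(
      do.call(rbind, lapply(ex, `[[`, "descriptors")),
      unlist(lapply(ex, `[[`, "labels")))
  })
}

# One default synthetic core plus its segmentation, reused across files.
test_seg_fixture <- function() {
  memo("seg_fixture", {
    sim <- generate_tma_image(image_sim_params(seed = 42,
                                               stromal_inflammation_density = 0.3))
    list(sim = sim, seg = segment_tma(sim$image, test_model()))
  })
}

# Exponential proportional-hazards survival times for screen tests.
sim_survival <- function(n, lp = rep(0, n), base_rate = 0.02, cens_rate = 0.01) {
  t_ev <- stats::rexp(n, base_rate * exp(lp))
  t_ce <- stats::rexp(n, cens_rate)
  list(time = pmin(t_ev, t_ce), event = as.integer(t_ev <= t_ce))
}

# Build a minimal segmentation_result by hand from label matrices, for
# analytic fixtures (no image pipeline involved).
manual_seg <- function(cell_labels, compartments, classes, cyto_labels = NULL) {
  ids <- sort(unique(cell_labels[cell_labels > 0L]))
  h <- nrow(cell_labels)
  obj <- do.call(rbind, lapply(ids, function(id) {
    idx <- which(cell_labels == id)
    comp_px <- compartments[idx]
    data.frame(id = id, class = classes[[as.character(id)]],
               compartment = c("epithelial", "stromal")[
                 which.max(tabulate(comp_px, nbins = 2L))],
               area = length(idx),
               centroid_row = mean(((idx - 1L) %% h) + 1L),
               centroid_col = mean(((idx - 1L) %/% h) + 1L),
               perimeter = NA_real_, stringsAsFactors = FALSE)
  }))
  if (is.null(cyto_labels)) cyto_labels <- matrix(0L, h, ncol(cell_labels))
  structure(list(
    spx = structure(list(labels = (compartments > 0L) * 1L, n = 1L,
                         descriptors = NULL), class = "superpixel_map"),
    compartment_labels = "stromal",
    compartments = compartments,
    cells = structure(list(labels = cell_labels, cyto_labels = cyto_labels,
                           objects = obj), class = "cell_objects")),
    class = "segmentation_result")
}
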