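#' Superpixel partition of a TMA image
#'
#' Partitions the tissue pixels of an RGB raster into compact superpixels by
#' k-means clustering in joint color + position space (an SLIC-style
#' partition). Near-white background pixels are masked out first; superpixel
#' labels are the contiguous integers `1..K` over tissue, 0 elsewhere.
#'
#' @param image RGB array `height x width x 3`, values in `[0, 1]`.
#' @param target_size Approximate superpixel side length in pixels (>= 5).
#' @param compactness Weight of the spatial coordinates relative to color;
#'   larger values give more regular superpixels.
#' @return Object of class `superpixel_map`: list with `labels` (integer
#'   matrix), `n` (superpixel count), and `descriptors` (matrix `n x d` of
#'   per-superpixel color/texture descriptors, see
#'   [superpixel_descriptors()]).
#' @export
compute_superpixels <- function(image, target_size = 8, compactness = 0.5) {
  if (length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop("'image' must be an RGB array", call. = FALSE)
  if (target_size < 5) stop("'target_size' must be >= 5 pixels", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  tis <- tissue_mask(image)
  labels <- matrix(0L, h, w)
  if (!any(tis)) {
    warning("image contains no tissue pixels; returning an empty superpixel map")
    return(structure(list(labels = labels, n = 0L,
                          descriptors = matrix(numeric(0), 0, 0)),
                     class = "superpixel_map"))
  }
  idx <- which(tis)
  pr <- ((idx - 1L) %% h) + 1L
  pc <- ((idx - 1L) %/% h) + 1L

  # seed centers on a regular grid restricted to tissue
  step <- target_size
  gr <- seq(ceiling(step / 2), h, by = step)
  gc <- seq(ceiling(step / 2), w, by = step)
  seeds <- as.matrix(expand.grid(r = gr, c = gc))
  seeds <- seeds[tis[seeds], , drop = FALSE]
  if (nrow(seeds) < 1L) seeds <- cbind(r = pr[1L], c = pc[1L])

  sw <- compactness / target_size
  feat <- cbind(
    image[, , 1][idx], image[, , 2][idx], image[, , 3][idx],
    pr * sw, pc * sw
  )
  seed_idx <- (seeds[, 2] - 1L) * h + seeds[, 1]
  centers <- cbind(
    image[, , 1][seed_idx], image[, , 2][seed_idx], image[, , 3][seed_idx],
    seeds[, 1] * sw, seeds[, 2] * sw
  )
  centers <- unique(centers)
  km <- suppressWarnings(stats::kmeans(feat, centers = centers,
                                       iter.max = 10L, algorithm = "Lloyd"))
  lab <- km$cluster
  # relabel to contiguous 1..K (some clusters may be empty after Lloyd)
  lab <- match(lab, sort(unique(lab)))
  labels[idx] <- lab
  desc <- superpixel_descriptors(image, labels)
  structure(list(labels = labels, n = max(lab), descriptors = desc),
            class = "superpixel_map")
}

#' Per-superpixel color and texture descriptors
#'
#' For each superpixel: mean and SD of the R, G, B, luminance and blue-ratio
#' channels, the dark-pixel fraction (luminance < 0.5, a nuclear-density
#' proxy), mean and SD of a local-contrast channel (absolute horizontal +
#' vertical gradient of luminance), and the log area.
#'
#' @param image RGB array.
#' @param labels Integer superpixel label matrix (0 = background).
#' @return Numeric matrix `K x 14` with named columns.
#' @export
superpixel_descriptors <- function(image, labels) {
  idx <- which(labels > 0L)
  if (length(idx) == 0L) return(matrix(numeric(0), 0, 0))
  lab <- labels[idx]
  lum <- luminance(image)
  grad <- abs(lum - lum[c(2:nrow(lum), nrow(lum)), ]) +
    abs(lum - lum[, c(2:ncol(lum), ncol(lum))])
  chans <- list(R = image[, , 1], G = image[, , 2], B = image[, , 3],
                lum = lum, br = blue_ratio(image))
  K <- max(lab)
  f <- factor(lab, levels = seq_len(K))
  cols <- list()
  for (nm in names(chans)) {
    v <- chans[[nm]][idx]
    cols[[paste0(nm, "_mean")]] <- tapply(v, f, mean)
    cols[[paste0(nm, "_sd")]] <- tapply(v, f, function(x) if (length(x) > 1) stats::sd(x) else 0)
  }
  cols[["dark_frac"]] <- tapply(lum[idx], f, function(x) mean(x < 0.5))
  cols[["grad_mean"]] <- tapply(grad[idx], f, mean)
  cols[["grad_sd"]] <- tapply(grad[idx], f, function(x) if (length(x) > 1) stats::sd(x) else 0)
  cols[["log_area"]] <- log(as.numeric(table(f)))
  out <- do.call(cbind, cols)
  rownames(out) <- NULL
  out
}

#' Train the epithelium-versus-stroma superpixel classifier
#'
#' Fits a linear discriminant rule on labeled superpixel descriptors,
#' mirroring a workflow in which an expert paints example regions of tumor
#' epithelium and stroma. Training rows are deduplicated first, class priors
#' are equal, and the fit is fully deterministic.
#'
#' @param descriptors Numeric matrix of superpixel descriptors (rows =
#'   examples), as produced by [superpixel_descriptors()].
#' @param labels Character/factor vector with values `"epithelial"` or
#'   `"stromal"`, one per row.
#' @return Object of class `compartment_model` with the fitted rule, the
#'   descriptor columns used, and the resubstitution accuracy.
#' @export
train_compartment_classifier <- function(descriptors, labels) {
  descriptors <- as.matrix(descriptors)
  labels <- as.character(labels)
  stopifnot(nrow(descriptors) == length(labels))
  classes <- c("epithelial", "stromal")
  missing_class <- setdiff(classes, unique(labels))
  if (length(missing_class) > 0L)
    stop("training set is missing class: ", paste(missing_class, collapse = ", "),
         call. = FALSE)
  dat <- unique(data.frame(descriptors, .label = labels, check.names = FALSE))
  X <- as.matrix(dat[, setdiff(names(dat), ".label"), drop = FALSE])
  y <- factor(dat$.label, levels = classes)
  keep <- apply(X, 2, function(col) stats::sd(col) > 1e-10)
  if (!any(keep)) stop("all descriptor columns are constant", call. = FALSE)
  X <- X[, keep, drop = FALSE]
  fit <- suppressWarnings(MASS::lda(X, grouping = y, prior = c(0.5, 0.5), tol = 1e-8))
  pred <- stats::predict(fit, X)$class
  structure(list(
    fit = fit,
    columns = colnames(X),
    levels = classes,
    resubstitution_accuracy = mean(pred == y),
    n_train = nrow(X)
  ), class = "compartment_model")
}

#' @export
print.compartment_model <- function(x, ...) {
  cat("Epithelium/stroma superpixel classifier (linear discriminant)\n")
  cat(sprintf("  training examples (deduplicated): %d\n", x$n_train))
  cat(sprintf("  descriptors used: %d\n", length(x$columns)))
  cat(sprintf("  resubstitution accuracy: %.3f\n", x$resubstitution_accuracy))
  invisible(x)
}

#' Classify superpixels as epithelial or stromal
#'
#' @param spx A `superpixel_map`.
#' @param model A `compartment_model`.
#' @return Character vector of length `spx$n` with values `"epithelial"` or
#'   `"stromal"`.
#' @export
classify_compartments <- function(spx, model) {
  stopifnot(inherits(spx, "superpixel_map"), inherits(model, "compartment_model"))
  if (spx$n == 0L) return(character(0))
  d <- spx$descriptors
  if (!all(model$columns %in% colnames(d)))
    stop("descriptor columns do not match the trained model", call. = FALSE)
  as.character(stats::predict(model$fit, d[, model$columns, drop = FALSE])$class)
}

#' Rasterize superpixel compartment labels
#'
#' @param spx A `superpixel_map`.
#' @param compartments Character vector from [classify_compartments()].
#' @return Integer matrix: 0 background, 1 epithelial, 2 stromal.
#' @export
compartment_raster <- function(spx, compartments) {
  stopifnot(length(compartments) == spx$n)
  code <- c(epithelial = 1L, stromal = 2L)[compartments]
  out <- matrix(0L, nrow(spx$labels), ncol(spx$labels))
  sel <- spx$labels > 0L
  out[sel] <- code[spx$labels[sel]]
  out
}

#' Segment nuclei and cells
#'
#' Detects dark (hematoxylin-dense) nuclear blobs by Otsu thresholding of the
#' tissue luminance, splits touching nuclei by distance-transform watershed,
#' removes objects below a minimum size, and assigns each object a
#' compartment (majority vote over its pixels) and a class: nuclei in the
#' epithelial compartment are `"epithelial_nucleus"`; small, round stromal
#' objects are `"inflammatory_cell"`; other stromal objects are
#' `"stromal_other"`. A disjoint cytoplasmic zone is associated to every cell
#' (nearest-nucleus basins within the object's compartment, limited to a halo
#' around the nucleus).
#'
#' @param image RGB array.
#' @param compartments Integer compartment raster (1 epithelial, 2 stromal).
#' @param min_size Minimum object area in pixels.
#' @param inflammatory_max_area Stromal objects at or below this area (px^2)
#'   qualify as inflammatory cells.
#' @param inflammatory_min_circularity Minimum circularity `4*pi*A/P^2` of an
#'   inflammatory cell.
#' @param cyto_halo Cytoplasmic halo radius in pixels.
#' @return Object of class `cell_objects`: list with `labels` (integer object
#'   mask), `cyto_labels` (integer cytoplasm mask, same ids), and `objects`
#'   (data.frame: id, class, compartment, area, centroid_row, centroid_col).
#' @export
segment_cells <- function(image, compartments, min_size = 5L,
                          inflammatory_max_area = 40L,
                          inflammatory_min_circularity = 0.4,
                          cyto_halo = 4L) {
  h <- dim(image)[1]; w <- dim(image)[2]
  stopifnot(all(dim(compartments) == c(h, w)))
  lum <- luminance(image)
  tis <- compartments > 0L
  empty <- structure(list(labels = matrix(0L, h, w),
                          cyto_labels = matrix(0L, h, w),
                          objects = data.frame(id = integer(0), class = character(0),
                                               compartment = character(0), area = integer(0),
                                               centroid_row = numeric(0), centroid_col = numeric(0))),
                     class = "cell_objects")
  if (!any(tis)) return(empty)
  thr <- otsu_threshold(lum[tis])
  nmask <- tis & lum < thr
  if (!any(nmask)) return(empty)
  # speckle suppression is handled by the minimum object size; a morphological
  # opening here would erode small round inflammatory cells below it
  dm <- EBImage::distmap(nmask * 1)
  wt <- EBImage::watershed(dm, tolerance = 0.5, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(wt)), h, w)

  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  if (length(keep) == 0L) return(empty)
  remap <- integer(length(sizes)); remap[keep] <- seq_along(keep)
  sel <- lab > 0L
  lab[sel] <- remap[lab[sel]]

  n_obj <- length(keep)
  idx <- which(lab > 0L)
  f <- factor(lab[idx], levels = seq_len(n_obj))
  area <- as.integer(table(f))
  rowi <- ((idx - 1L) %% h) + 1L
  coli <- ((idx - 1L) %/% h) + 1L
  centroid_row <- as.numeric(tapply(rowi, f, mean))
  centroid_col <- as.numeric(tapply(coli, f, mean))
  # majority compartment per object
  comp_code <- vapply(split(compartments[idx], f), function(v) {
    tb <- tabulate(v + 1L, nbins = 3L)  # counts of 0,1,2
    which.max(tb[2:3])
  }, integer(1))
  comp <- c("epithelial", "stromal")[comp_code]
  # circularity from border-pixel perimeter
  perim <- object_border_lengths(lab, n_obj)
  circ <- 4 * pi * area / pmax(perim, 1)^2
  class <- ifelse(comp == "epithelial", "epithelial_nucleus",
                  ifelse(area <= inflammatory_max_area &
                           circ >= inflammatory_min_circularity,
                         "inflammatory_cell", "stromal_other"))

  # cytoplasmic zones: nearest-nucleus basins within the compartment, within
  # a halo of the nuclear mask, excluding nuclei themselves
  halo <- EBImage::dilate((lab > 0L) * 1,
                          EBImage::makeBrush(2L * as.integer(cyto_halo) + 1L, "disc"))
  obj_comp_raster <- matrix(0L, h, w)
  obj_comp_raster[idx] <- comp_code[lab[idx]]
  zone_mask <- halo > 0 & compartments > 0L & lab == 0L
  cyto <- matrix(0L, h, w)
  if (any(zone_mask)) {
    basins <- EBImage::propagate(lum, seeds = lab, mask = zone_mask | lab > 0L)
    basins <- matrix(as.integer(EBImage::imageData(basins)), h, w)
    sel2 <- zone_mask & basins > 0L
    # keep only cytoplasm pixels in the same compartment as their nucleus
    same <- sel2 & compartments == ifelse(basins > 0L, comp_code[pmax(basins, 1L)], 0L)
    cyto[same] <- basins[same]
  }

  structure(list(
    labels = lab, cyto_labels = cyto,
    objects = data.frame(id = seq_len(n_obj), class = class, compartment = comp,
                         area = area, centroid_row = centroid_row,
                         centroid_col = centroid_col, perimeter = perim,
                         stringsAsFactors = FALSE)
  ), class = "cell_objects")
}

# Otsu threshold of a numeric vector in [0, 1].
otsu_threshold <- function(v, n_breaks = 256L) {
  hst <- tabulate(pmin(pmax(floor(v * n_breaks) + 1L, 1L), n_breaks), n_breaks)
  p <- hst / sum(hst)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n_breaks))
  mu_t <- mu[n_breaks]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  which.max(sigma_b) / n_breaks
}

# Border length per object: count of object pixels with at least one
# 4-neighbour outside the object.
object_border_lengths <- function(lab, n_obj) {
  h <- nrow(lab); w <- ncol(lab)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- lab
  ctr <- pad[2:(h + 1L), 2:(w + 1L)]
  border <- ctr > 0L & (
    pad[1:h, 2:(w + 1L)] != ctr | pad[3:(h + 2L), 2:(w + 1L)] != ctr |
      pad[2:(h + 1L), 1:w] != ctr | pad[2:(h + 1L), 3:(w + 2L)] != ctr)
  counts <- tabulate(ctr[border], nbins = n_obj)
  as.numeric(counts)
}

#' Segment a TMA image end to end
#'
#' Convenience wrapper: superpixels, compartment classification, compartment
#' raster, and cell segmentation in one call.
#'
#' @param image RGB array.
#' @param model A trained `compartment_model`.
#' @param target_size Superpixel size, see [compute_superpixels()].
#' @param ... Passed to [segment_cells()].
#' @return Object of class `segmentation_result`: list with `spx`,
#'   `compartment_labels` (per superpixel), `compartments` (raster), `cells`.
#' @export
segment_tma <- function(image, model, target_size = 8, ...) {
  spx <- compute_superpixels(image, target_size = target_size)
  labels <- classify_compartments(spx, model)
  comp <- compartment_raster(spx, labels)
  cells <- segment_cells(image, comp, ...)
  structure(list(spx = spx, compartment_labels = labels,
                 compartments = comp, cells = cells),
            class = "segmentation_result")
}

#' Audit segmentation accuracy along the horizontal diameter
#'
#' Replicates a manual audit protocol in which an observer assesses all
#' superpixels and all nuclei in contact with the horizontal diameter (the
#' middle row) of the image: superpixel accuracy is the fraction of
#' midline-touching superpixels whose predicted compartment matches the
#' ground-truth majority compartment of their pixels; nucleus accuracy is the
#' fraction of midline-touching ground-truth cells at least half covered by a
#' detected object.
#'
#' @param seg A `segmentation_result`.
#' @param truth A `ground_truth` object on the same raster.
#' @return List: `superpixel_accuracy`, `nucleus_accuracy` (each in `[0, 1]`
#'   or NA), `n_superpixels_audited`, `n_nuclei_audited`.
#' @export
audit_accuracy <- function(seg, truth) {
  stopifnot(inherits(seg, "segmentation_result"), inherits(truth, "ground_truth"))
  labels <- seg$spx$labels
  stopifnot(all(dim(labels) == dim(truth$compartment_mask)))
  mid <- midline_row(nrow(labels))

  spx_mid <- setdiff(unique(labels[mid, ]), 0L)
  spx_acc <- NA_real_
  if (length(spx_mid) > 0L) {
    truth_code <- vapply(spx_mid, function(k) {
      v <- truth$compartment_mask[labels == k]
      tb <- tabulate(v + 1L, nbins = 3L)
      which.max(tb[2:3])
    }, integer(1))
    pred <- c(epithelial = 1L, stromal = 2L)[seg$compartment_labels[spx_mid]]
    spx_acc <- mean(pred == truth_code)
  } else {
    warning("no superpixels touch the midline")
  }

  nuc_mid <- setdiff(unique(truth$cell_mask[mid, ]), 0L)
  nuc_acc <- NA_real_
  if (length(nuc_mid) > 0L) {
    det <- seg$cells$labels
    covered <- vapply(nuc_mid, function(id) {
      px <- truth$cell_mask == id
      mean(det[px] > 0L) >= 0.5
    }, logical(1))
    nuc_acc <- mean(covered)
  } else {
    warning("no ground-truth cells touch the midline")
  }

  list(superpixel_accuracy = spx_acc, nucleus_accuracy = nuc_acc,
       n_superpixels_audited = length(spx_mid),
       n_nuclei_audited = length(nuc_mid))
}

#' Build classifier training examples from ground truth
#'
#' Labels each superpixel of an image by the majority ground-truth
#' compartment of its pixels, producing (descriptor, label) training pairs —
#' the synthetic analog of expert-painted example regions.
#'
#' @param sim A `tma_image_sim` object.
#' @param target_size Superpixel size.
#' @return List with `descriptors` (matrix) and `labels` (character vector).
#' @export
training_examples_from_truth <- function(sim, target_size = 8) {
  stopifnot(inherits(sim, "tma_image_sim"))
  spx <- compute_superpixels(sim$image, target_size = target_size)
  if (spx$n == 0L) return(list(descriptors = spx$descriptors, labels = character(0)))
  truth_code <- vapply(seq_len(spx$n), function(k) {
    v <- sim$truth$compartment_mask[spx$labels == k]
    tb <- tabulate(v + 1L, nbins = 3L)
    which.max(tb[2:3])
  }, integer(1))
  list(descriptors = spx$descriptors,
       labels = c("epithelial", "stromal")[truth_code])
}
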