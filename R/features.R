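# Fixed per-image feature catalogue and its extraction.
#
# The catalogue is the full factorial: 2 compartments (epithelial, stromal)
# x 2 object classes (nuclear, cytoplasmic) x 96 base measurements x 4
# cross-object summaries (mean, sd, max, min) = 1,536 features, 768 per
# compartment. The 96 base measurements per object are 16 morphometrics plus
# 16 intensity statistics on each of 5 channels (R, G, B, luminance,
# blue-ratio).

catalogue_morpho <- c(
  "area", "perimeter", "equiv_diameter", "major_axis", "minor_axis",
  "eccentricity", "solidity", "extent", "circularity", "aspect_ratio",
  "convex_area", "border_length", "radius_mean", "radius_sd",
  "roundness", "compactness")

catalogue_stats <- c(
  "mean", "sd", "min", "max", "median", "mad", "q10", "q25", "q75", "q90",
  "skewness", "kurtosis", "energy", "entropy", "range", "cv")

catalogue_channels <- c("R", "G", "B", "lum", "blueratio")

catalogue_summaries <- c("mean", "sd", "max", "min")

#' Build the fixed feature catalogue
#'
#' Deterministic, versioned catalogue of the 1,536 per-image features:
#' 2 compartments x 2 object classes x 96 base measurements x 4 summary
#' statistics across objects. Feature names are
#' `<compartment>.<class>.<base>.<summary>`.
#'
#' @return A data.frame of class `feature_catalogue` with columns `name`,
#'   `compartment`, `object_class`, `base`, `summary`, `units`.
#' @examples
#' cat <- build_catalogue()
#' nrow(cat)           # 1536
#' table(cat$compartment)
#' @export
build_catalogue <- function() {
  base <- c(catalogue_morpho,
            as.vector(t(outer(catalogue_stats, catalogue_channels, paste, sep = "_"))))
  units <- c(
    stats::setNames(c("px2", "px", "px", "px", "px", "ratio", "ratio", "ratio",
                      "ratio", "ratio", "px2", "px", "px", "px", "ratio", "ratio"),
                    catalogue_morpho),
    stats::setNames(rep("intensity", 80L),
                    as.vector(t(outer(catalogue_stats, catalogue_channels, paste, sep = "_")))))
  grid <- expand.grid(summary = catalogue_summaries, base = base,
                      object_class = c("nuclear", "cytoplasmic"),
                      compartment = c("epithelial", "stromal"),
                      stringsAsFactors = FALSE)
  grid <- grid[, c("compartment", "object_class", "base", "summary")]
  grid$name <- with(grid, paste(compartment, object_class, base, summary, sep = "."))
  grid$units <- units[grid$base]
  stopifnot(nrow(grid) == 1536L, !anyDuplicated(grid$name))
  structure(grid[, c("name", "compartment", "object_class", "base", "summary", "units")],
            class = c("feature_catalogue", "data.frame"))
}

# Third/fourth standardized moments; NA for n < 2 or zero variance.
sample_skewness <- function(v) {
  n <- length(v); if (n < 2L) return(NA_real_)
  s <- stats::sd(v); if (s < 1e-12) return(0)
  mean((v - mean(v))^3) / s^3
}
sample_kurtosis <- function(v) {
  n <- length(v); if (n < 2L) return(NA_real_)
  s <- stats::sd(v); if (s < 1e-12) return(0)
  mean((v - mean(v))^4) / s^4 - 3
}
histogram_entropy <- function(v, bins = 16L) {
  p <- tabulate(pmin(pmax(floor(v * bins) + 1L, 1L), bins), bins)
  p <- p / sum(p); p <- p[p > 0]
  -sum(p * log2(p))
}

# 16 intensity statistics of a pixel-value vector (values in [0, 1]).
intensity_stats <- function(v) {
  qs <- stats::quantile(v, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  m <- mean(v)
  c(mean = m, sd = if (length(v) > 1L) stats::sd(v) else 0,
    min = min(v), max = max(v), median = stats::median(v),
    mad = stats::mad(v), q10 = qs[1], q25 = qs[2], q75 = qs[3], q90 = qs[4],
    skewness = sample_skewness(v), kurtosis = sample_kurtosis(v),
    energy = mean(v^2), entropy = histogram_entropy(v),
    range = max(v) - min(v), cv = if (abs(m) > 1e-12) stats::sd(v) / m else NA_real_)
}

# Convex-hull area of an integer pixel set (shoelace on the hull of pixel
# corners); falls back to the pixel count for degenerate sets.
convex_hull_area <- function(rows, cols) {
  if (length(rows) < 3L) return(as.numeric(length(rows)))
  # use pixel corners so a filled square of side s has hull area s^2
  pr <- c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5)
  pc <- c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  hull <- grDevices::chull(pc, pr)
  x <- pc[hull]; y <- pr[hull]
  n <- length(hull)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# 16 morphometrics for one object given its pixel coordinates.
object_morphometrics <- function(rows, cols, border_len) {
  a <- length(rows)
  ctr_r <- mean(rows); ctr_c <- mean(cols)
  d <- sqrt((rows - ctr_r)^2 + (cols - ctr_c)^2)
  # second central moments -> ellipse axes (EBImage moment convention)
  mrr <- mean((rows - ctr_r)^2); mcc <- mean((cols - ctr_c)^2)
  mrc <- mean((rows - ctr_r) * (cols - ctr_c))
  common <- sqrt((mrr - mcc)^2 + 4 * mrc^2)
  l1 <- (mrr + mcc + common) / 2; l2 <- pmax((mrr + mcc - common) / 2, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- if (l1 > 1e-12) sqrt(pmax(1 - l2 / l1, 0)) else 0
  perim <- border_len
  hull_a <- max(convex_hull_area(rows, cols), a)
  bbox_a <- (diff(range(rows)) + 1) * (diff(range(cols)) + 1)
  c(area = a,
    perimeter = perim,
    equiv_diameter = 2 * sqrt(a / pi),
    major_axis = major,
    minor_axis = minor,
    eccentricity = ecc,
    solidity = a / hull_a,
    extent = a / bbox_a,
    circularity = 4 * pi * a / max(perim, 1)^2,
    aspect_ratio = if (minor > 1e-12) major / minor else NA_real_,
    convex_area = hull_a,
    border_length = perim,
    radius_mean = mean(d),
    radius_sd = if (a > 1L) stats::sd(d) else 0,
    roundness = if (major > 1e-12) 4 * a / (pi * major^2) else NA_real_,
    compactness = max(perim, 1)^2 / a)
}

# Per-object base-measurement matrix (objects x 96) for one label raster.
object_base_measurements <- function(image, labels, ids) {
  if (length(ids) == 0L) return(NULL)
  h <- nrow(labels)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  keep <- lab %in% ids
  idx <- idx[keep]; lab <- lab[keep]
  f <- factor(lab, levels = ids)
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  border <- object_border_lengths(labels, max(labels))
  chans <- list(R = image[, , 1], G = image[, , 2], B = image[, , 3],
                lum = luminance(image), blueratio = blue_ratio(image))
  split_rows <- split(rows, f)
  split_cols <- split(cols, f)
  split_idx <- split(idx, f)
  out <- matrix(NA_real_, length(ids), 96L)
  for (i in seq_along(ids)) {
    r <- split_rows[[i]]; cl <- split_cols[[i]]
    if (length(r) == 0L) next
    morph <- object_morphometrics(r, cl, border[ids[i]])
    ints <- unlist(lapply(chans, function(ch) intensity_stats(ch[split_idx[[i]]])),
                   use.names = FALSE)
    # lay out as stats x channels flattened channel-major to match catalogue
    ints_mat <- matrix(ints, nrow = 16L)                 # stats x channels
    out[i, ] <- c(morph, as.vector(ints_mat))            # channel-major
  }
  # name intensity block channel-major: stat_channel for channel 1 first
  colnames(out) <- c(catalogue_morpho,
                     as.vector(outer(catalogue_stats, catalogue_channels, paste, sep = "_")))
  out
}

#' Extract the 1,536 catalogue features from one segmented image
#'
#' For each compartment (epithelial, stromal) and object class (nuclear,
#' cytoplasmic), computes the 96 base measurements per object and summarizes
#' each across objects by mean, SD, max and min. A compartment/class with no
#' objects yields NA for all of its features; an SD over a single object is 0.
#'
#' @param image RGB array.
#' @param seg A `segmentation_result` (from [segment_tma()]).
#' @param catalogue A `feature_catalogue`; defaults to [build_catalogue()].
#' @return Named numeric vector of length 1,536 in catalogue order.
#' @export
extract_features <- function(image, seg, catalogue = build_catalogue()) {
  stopifnot(inherits(seg, "segmentation_result"))
  obj <- seg$cells$objects
  out <- stats::setNames(rep(NA_real_, nrow(catalogue)), catalogue$name)
  for (comp in c("epithelial", "stromal")) {
    ids <- obj$id[obj$compartment == comp]
    for (cls in c("nuclear", "cytoplasmic")) {
      labels <- if (cls == "nuclear") seg$cells$labels else seg$cells$cyto_labels
      present <- ids[ids %in% labels]
      block <- catalogue$compartment == comp & catalogue$object_class == cls
      if (length(present) == 0L) next
      bm <- object_base_measurements(image, labels, present)
      summ <- rbind(
        mean = colMeans(bm, na.rm = TRUE),
        sd = apply(bm, 2, function(v) if (sum(!is.na(v)) > 1L) stats::sd(v, na.rm = TRUE) else 0),
        max = suppressWarnings(apply(bm, 2, max, na.rm = TRUE)),
        min = suppressWarnings(apply(bm, 2, min, na.rm = TRUE)))
      summ[!is.finite(summ)] <- NA_real_
      idxb <- which(block)
      for (j in seq_along(idxb)) {
        b <- catalogue$base[idxb[j]]; s <- catalogue$summary[idxb[j]]
        out[idxb[j]] <- summ[s, b]
      }
    }
  }
  out
}

#' Average two per-core feature vectors to the case level
#'
#' Elementwise mean of the two cores; if exactly one core is NA for a
#' feature, the available core's value is used; if both are NA the case
#' value is NA.
#'
#' @param core1,core2 Named numeric vectors sharing the catalogue.
#' @return Named numeric case-level vector.
#' @export
case_average <- function(core1, core2) {
  if (length(core1) != length(core2) ||
      !identical(names(core1), names(core2)))
    stop("core feature vectors do not share the same catalogue", call. = FALSE)
  pairwise_mean(core1, core2)
}

#' Per-feature Spearman correlation between paired cores
#'
#' A per-feature measure of intratumoral heterogeneity: the rank correlation
#' between the first and second core of each case.
#'
#' @param core1,core2 Matrices or data.frames, cases x features, sharing
#'   column names.
#' @param min_pairs Minimum complete pairs per feature (default 3).
#' @return Named numeric vector of Spearman rho (NA where undefined).
#' @export
paired_core_correlation <- function(core1, core2, min_pairs = 3L) {
  core1 <- as.matrix(core1); core2 <- as.matrix(core2)
  if (!identical(colnames(core1), colnames(core2)))
    stop("core tables do not share the same catalogue", call. = FALSE)
  out <- vapply(seq_len(ncol(core1)), function(j)
    spearman_or_na(core1[, j], core2[, j], min_pairs = min_pairs, warn = FALSE),
    numeric(1))
  constant <- vapply(seq_len(ncol(core1)), function(j) {
    ok <- !is.na(core1[, j]) & !is.na(core2[, j])
    sum(ok) >= min_pairs &&
      (length(unique(core1[ok, j])) < 2L || length(unique(core2[ok, j])) < 2L)
  }, logical(1))
  if (any(constant))
    warning(sprintf("%d constant feature(s); their correlation is NA", sum(constant)))
  stats::setNames(out, colnames(core1))
}

#' Write a feature table with its catalogue sidecar
#'
#' @param table Matrix/data.frame of cases x features.
#' @param path TSV output path; a JSON catalogue sidecar is written next to
#'   it as `<path>.catalogue.json`.
#' @param catalogue The `feature_catalogue` describing the columns.
#' @return Invisibly, the TSV path.
#' @export
write_feature_table <- function(table, path, catalogue = build_catalogue()) {
  df <- data.frame(id = rownames(table), as.data.frame(table, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(catalogue, paste0(path, ".catalogue.json"), dataframe = "rows")
  invisible(path)
}
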