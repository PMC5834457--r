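#' Parameters for a synthetic TMA core image
#'
#' Bundles the knobs of the synthetic H&E-like tissue microarray (TMA) core
#' renderer. The renderer emulates a single 0.6 mm core: a roughly circular
#' tissue disc on a white background, containing contiguous epithelial nests
#' (tightly packed large nuclei with cytoplasm) embedded in a textured
#' stromal matrix sprinkled with small, dark, near-circular inflammatory
#' cells at a controlled areal density.
#'
#' @param width,height Image size in pixels.
#' @param epithelial_fraction Target fraction of tissue area occupied by
#'   epithelial nests, in `[0, 1]`.
#' @param nest_scale Characteristic epithelial-nest radius in pixels; must be
#'   smaller than `min(width, height)`.
#' @param stromal_inflammation_density Target fraction of stromal area covered
#'   by inflammatory cells, in `[0, 1]`. This is the ground-truth stromal
#'   inflammation (SI) of the rendered core.
#' @param nuclear_radius_mean,nuclear_radius_sd Mean and SD of the epithelial
#'   nuclear radius in pixels. Inflammatory cells are rendered at one third of
#'   the epithelial radius, mirroring small-lymphocyte morphology.
#' @param stain_palette Named list of RGB triples (values in `[0, 1]`) for
#'   `epithelial_nucleus`, `epithelial_cytoplasm`, `stromal_matrix` and
#'   `inflammatory_nucleus`.
#' @param noise_sd SD of the additive Gaussian intensity noise.
#' @param seed Integer seed; the renderer is fully deterministic given it.
#'
#' @return An object of class `image_sim_params`.
#' @seealso [generate_tma_image()]
#' @export
image_sim_params <- function(width = 128L, height = 128L,
                             epithelial_fraction = 0.5,
                             nest_scale = 20,
                             stromal_inflammation_density = 0.15,
                             nuclear_radius_mean = 6,
                             nuclear_radius_sd = 0.8,
                             stain_palette = default_stain_palette(),
                             noise_sd = 0.02,
                             seed = 1L) {
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0)
    stop("'width' and 'height' must be positive", call. = FALSE)
  stopifnot_scalar01(epithelial_fraction, "epithelial_fraction")
  stopifnot_scalar01(stromal_inflammation_density, "stromal_inflammation_density")
  if (!is.numeric(nuclear_radius_mean) || nuclear_radius_mean <= 0)
    stop("'nuclear_radius_mean' must be > 0", call. = FALSE)
  if (nest_scale >= min(width, height))
    stop(sprintf(
      "degenerate geometry: nest_scale (%s) must be smaller than min(width, height) = %s",
      format(nest_scale), min(width, height)), call. = FALSE)
  needed <- c("epithelial_nucleus", "epithelial_cytoplasm",
              "stromal_matrix", "inflammatory_nucleus")
  if (!all(needed %in% names(stain_palette)))
    stop("'stain_palette' must name: ", paste(needed, collapse = ", "), call. = FALSE)
  structure(list(
    width = as.integer(width), height = as.integer(height),
    epithelial_fraction = epithelial_fraction,
    nest_scale = nest_scale,
    stromal_inflammation_density = stromal_inflammation_density,
    nuclear_radius_mean = nuclear_radius_mean,
    nuclear_radius_sd = nuclear_radius_sd,
    stain_palette = stain_palette,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "image_sim_params")
}

#' Default H&E-like stain palette
#'
#' Approximate hematoxylin/eosin colors: dark blue-purple epithelial nuclei,
#' pink-purple cytoplasm, pale pink stromal matrix, and darker blue
#' inflammatory nuclei.
#'
#' @return Named list of RGB triples in `[0, 1]`.
#' @export
default_stain_palette <- function() {
  list(
    epithelial_nucleus   = c(0.36, 0.22, 0.55),
    epithelial_cytoplasm = c(0.82, 0.58, 0.78),
    stromal_matrix       = c(0.93, 0.72, 0.80),
    inflammatory_nucleus = c(0.20, 0.16, 0.45)
  )
}

# Disc pixel offsets (integer row/col matrix) for a given radius.
disc_offsets <- function(r) {
  d <- -ceiling(r):ceiling(r)
  sel <- outer(d^2, d^2, "+") <= r^2 + 1e-9
  cbind(dr = d[row(sel)[sel]], dc = d[col(sel)[sel]])
}

# Place non-overlapping discs inside `mask` until the covered fraction of
# `mask` reaches `target_fraction` (or attempts are exhausted). Returns an
# integer matrix of object ids (0 = empty), ids starting at `first_id`.
place_discs <- function(mask, radius_mean, radius_sd, target_fraction,
                        first_id = 1L, max_attempts_factor = 40L,
                        min_gap = 1L) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  avail <- which(mask)
  if (length(avail) == 0L || target_fraction <= 0) return(out)
  denom <- sum(mask)
  mean_area <- pi * radius_mean^2
  n_target <- ceiling(target_fraction * denom / mean_area)
  max_attempts <- max_attempts_factor * max(n_target, 1L)
  # forbidden zone: already-claimed pixels plus a gap ring so objects do not touch
  claimed <- matrix(FALSE, h, w)
  covered <- 0L
  id <- first_id
  attempts <- 0L
  while (covered / denom < target_fraction && attempts < max_attempts) {
    attempts <- attempts + 1L
    ctr <- avail[sample.int(length(avail), 1L)]
    cr <- ((ctr - 1L) %% h) + 1L
    cc <- ((ctr - 1L) %/% h) + 1L
    r <- max(1.2, stats::rnorm(1L, radius_mean, radius_sd))
    off <- disc_offsets(r)
    rows <- cr + off[, 1L]; cols <- cc + off[, 2L]
    keep <- rows >= 1L & rows <= h & cols >= 1L & cols <= w
    rows <- rows[keep]; cols <- cols[keep]
    px <- cbind(rows, cols)
    inside <- mask[px]
    # reject sliver placements: a cell must keep most of its disc after
    # clipping to the compartment mask
    if (sum(inside) < 0.6 * nrow(px)) next
    px <- px[inside, , drop = FALSE]
    # reject if any pixel (or its gap ring) already claimed
    off_g <- disc_offsets(r + min_gap)
    rows_g <- cr + off_g[, 1L]; cols_g <- cc + off_g[, 2L]
    keep_g <- rows_g >= 1L & rows_g <= h & cols_g >= 1L & cols_g <= w
    ring <- cbind(rows_g[keep_g], cols_g[keep_g])
    if (any(claimed[ring])) next
    out[px] <- id
    claimed[px] <- TRUE
    covered <- covered + nrow(px)
    id <- id + 1L
  }
  out
}

#' Generate a synthetic TMA core image with ground truth
#'
#' Renders one H&E-like TMA core and returns both the RGB raster and the
#' pixel-level ground truth. Epithelial nests are contiguous blobs obtained by
#' thresholding low-frequency Gaussian noise at the quantile matching the
#' requested epithelial fraction; the remaining tissue is stroma. Epithelial
#' nuclei are tightly packed discs with a cytoplasmic background; inflammatory
#' cells are small dark discs placed in the stroma until the requested areal
#' density is reached. The stored `true_si` is recomputed exactly from the
#' final masks (inflammatory pixels inside stroma / stromal pixels).
#'
#' @param params An [image_sim_params()] object.
#' @return A list of class `tma_image_sim` with elements:
#'   \describe{
#'     \item{image}{numeric array `height x width x 3`, values in `[0, 1]`.}
#'     \item{truth}{list of class `ground_truth`: `compartment_mask` (integer
#'       matrix; 0 background, 1 epithelial, 2 stromal), `cell_mask` (integer
#'       object-id matrix, 0 background), `cell_classes` (named character
#'       vector, `"epithelial_nucleus"` or `"inflammatory_cell"`), and
#'       `true_si`.}
#'     \item{params}{the input parameters.}
#'   }
#' @examples
#' sim <- generate_tma_image(image_sim_params(width = 64, height = 64, seed = 7))
#' sim$truth$true_si
#' @export
generate_tma_image <- function(params) {
  if (!inherits(params, "image_sim_params"))
    params <- do.call(image_sim_params, params)
  with_seed(params$seed, {
    h <- params$height; w <- params$width
    pal <- params$stain_palette

    # circular tissue core on white background
    rr <- matrix(seq_len(h), h, w)
    cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    core_r <- 0.47 * min(h, w)
    tissue <- (rr - cy)^2 + (cc - cx)^2 <= core_r^2

    # epithelial nests: thresholded low-frequency Gaussian field
    ef <- params$epithelial_fraction
    if (ef <= 0) {
      epi <- matrix(FALSE, h, w)
    } else if (ef >= 1) {
      epi <- tissue
    } else {
      field <- matrix(stats::rnorm(h * w), h, w)
      field <- EBImage::gblur(field, sigma = max(2, params$nest_scale / 2))
      cut <- stats::quantile(field[tissue], probs = 1 - ef, names = FALSE)
      epi <- tissue & field > cut
    }
    stroma <- tissue & !epi

    compartment <- matrix(0L, h, w)
    compartment[epi] <- 1L
    compartment[stroma] <- 2L

    # epithelial nuclei: tightly packed large discs inside the nests
    epi_nuc <- place_discs(epi, params$nuclear_radius_mean,
                           params$nuclear_radius_sd,
                           target_fraction = 0.40, first_id = 1L)
    n_epi <- max(epi_nuc, 0L)

    # inflammatory cells: small dark discs in the stroma at the target density
    inf_r <- max(1.1, params$nuclear_radius_mean / 3)
    inf_cells <- place_discs(stroma, inf_r, inf_r * 0.12,
                             target_fraction = params$stromal_inflammation_density,
                             first_id = n_epi + 1L)

    cell_mask <- epi_nuc
    cell_mask[inf_cells > 0L] <- inf_cells[inf_cells > 0L]
    ids <- sort(unique(cell_mask[cell_mask > 0L]))
    cell_classes <- stats::setNames(
      ifelse(ids <= n_epi, "epithelial_nucleus", "inflammatory_cell"),
      as.character(ids))

    stromal_px <- sum(stroma)
    true_si <- if (stromal_px == 0L) NA_real_ else
      sum(inf_cells > 0L & stroma) / stromal_px

    # ---- rendering ----
    img <- array(0.97, dim = c(h, w, 3))
    # stromal matrix: pale pink with coarse + fine texture
    coarse <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w), sigma = 3)
    coarse <- coarse / max(stats::sd(coarse), 1e-8) * 0.05
    fine <- matrix(stats::rnorm(h * w, sd = 0.03), h, w)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[stroma] <- pal$stromal_matrix[ch] + coarse[stroma] + fine[stroma]
      plane[epi] <- pal$epithelial_cytoplasm[ch] + fine[epi]
      plane[epi_nuc > 0L] <- pal$epithelial_nucleus[ch]
      plane[inf_cells > 0L] <- pal$inflammatory_nucleus[ch]
      img[, , ch] <- plane
    }
    if (params$noise_sd > 0)
      img <- img + array(stats::rnorm(length(img), sd = params$noise_sd), dim = dim(img))
    img <- pmin(pmax(img, 0), 1)

    truth <- structure(list(
      compartment_mask = compartment,
      cell_mask = cell_mask,
      cell_classes = cell_classes,
      true_si = true_si
    ), class = "ground_truth")

    structure(list(image = img, truth = truth, params = params),
              class = "tma_image_sim")
  })
}

#' Write a simulated core to disk
#'
#' Writes the RGB raster as PNG and the compartment and cell masks as
#' single-channel 16-bit TIFF (0 = background).
#'
#' @param sim A `tma_image_sim` object.
#' @param prefix Path prefix; files `<prefix>.png`, `<prefix>_compartments.tif`
#'   and `<prefix>_cells.tif` are created.
#' @return Invisibly, the named vector of written paths.
#' @export
write_tma_image <- function(sim, prefix) {
  stopifnot(inherits(sim, "tma_image_sim"))
  paths <- c(image = paste0(prefix, ".png"),
             compartments = paste0(prefix, "_compartments.tif"),
             cells = paste0(prefix, "_cells.tif"))
  png::writePNG(sim$image, paths[["image"]])
  tiff::writeTIFF(sim$truth$compartment_mask / 65535, paths[["compartments"]],
                  bits.per.sample = 16L)
  tiff::writeTIFF(sim$truth$cell_mask / 65535, paths[["cells"]],
                  bits.per.sample = 16L)
  invisible(paths)
}

#' Read a TMA core image from disk
#'
#' @param path PNG or TIFF path.
#' @return Numeric RGB array `height x width x 3` in `[0, 1]`.
#' @export
read_tma_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  img[, , 1:3, drop = FALSE]
}
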