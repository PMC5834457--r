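# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-stage substream of a master seed; always < 2^31 - 1.
sub_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (abs(seed) %% 1000003) * 2011 + (abs(stage) %% 7919) * 104729 + 17
}

#' @noRd
stopifnot_scalar01 <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# Luminance (Rec. 601) of an RGB array [rows, cols, 3] with values in [0, 1].
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Blue-ratio channel: emphasizes hematoxylin-dense (nuclear) pixels.
blue_ratio <- function(img) {
  img[, , 3] / (img[, , 1] + img[, , 2] + 0.1)
}

# Pixel mask of tissue (non-background): background is rendered near-white.
tissue_mask <- function(img, white_cutoff = 0.92) {
  lum <- luminance(img)
  chroma <- pmax(img[, , 1], img[, , 2], img[, , 3]) -
    pmin(img[, , 1], img[, , 2], img[, , 3])
  lum < white_cutoff | chroma > 0.10
}

# Row index (1-based) of the horizontal diameter of an image with `h` rows,
# matching a 0-based row-major convention where the midline is row h %/% 2.
midline_row <- function(h) h %/% 2L + 1L

# Elementwise mean of two vectors where a single NA falls back to the other
# value and a double NA stays NA.  Shared by case-level feature averaging,
# case SI, and case PD-L1.
pairwise_mean <- function(a, b) {
  out <- (a + b) / 2
  out[is.na(a) & !is.na(b)] <- b[is.na(a) & !is.na(b)]
  out[!is.na(a) & is.na(b)] <- a[!is.na(a) & is.na(b)]
  out[is.na(a) & is.na(b)] <- NA_real_
  out
}

# Spearman rank correlation returning NA (with a warning) on constant input
# or when fewer than `min_pairs` complete pairs are available.
spearman_or_na <- function(a, b, min_pairs = 3L, warn = TRUE) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_pairs) {
    if (warn) warning(sprintf("fewer than %d complete pairs; returning NA", min_pairs))
    return(NA_real_)
  }
  if (length(unique(a[ok])) < 2L || length(unique(b[ok])) < 2L) {
    if (warn) warning("constant vector; Spearman correlation undefined, returning NA")
    return(NA_real_)
  }
  stats::cor(a[ok], b[ok], method = "spearman")
}
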