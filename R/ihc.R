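# DAB optical densitometry: H-DAB colour deconvolution, optical density of
# image regions, and triplicate random-region sampling.

#' Stain absorbance vectors for H-DAB deconvolution
#'
#' Unit RGB absorbance vectors for haematoxylin and DAB (defaults are the
#' standard published H-DAB pair). A residual third vector (the unit cross
#' product, orthogonal to both) completes the basis so the stain matrix is
#' invertible.
#'
#' @param hematoxylin,dab Length-3 non-negative RGB absorbance vectors; they
#'   are normalized to unit length.
#' @return A `stain_vectors` object: a 3x3 matrix whose columns are the unit
#'   absorbance vectors (hematoxylin, dab, residual).
#' @export
stain_vectors <- function(hematoxylin = c(0.650, 0.704, 0.286),
                          dab = c(0.269, 0.568, 0.778)) {
  for (v in list(hematoxylin, dab)) {
    if (length(v) != 3 || any(v < 0) || sum(v) == 0) {
      stop_tpsad("Stain vectors must be length-3, non-negative and non-zero.",
                 "tpsad_validation_error")
    }
  }
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  r <- c(h[2] * d[3] - h[3] * d[2], h[3] * d[1] - h[1] * d[3], h[1] * d[2] - h[2] * d[1])
  if (sqrt(sum(r^2)) < 1e-8) {
    stop_tpsad("Haematoxylin and DAB vectors are collinear; stain matrix is singular.",
               "tpsad_validation_error")
  }
  r <- r / sqrt(sum(r^2))
  m <- cbind(hematoxylin = h, dab = d, residual = r)
  structure(m, class = c("stain_vectors", class(m)))
}

#' Optical density of a region
#'
#' `OD = log10(max_intensity / mean_intensity)`; for 8-bit images the maximum
#' intensity is 255. A blank region (mean 255) has OD 0; mean 25.5 gives OD 1.
#'
#' @param mean_intensity Mean pixel intensity of the region, in
#'   `(0, max_intensity]`. Vectorized.
#' @param max_intensity Intensity of an unstained pixel (default 255).
#' @return Optical density (log10 units).
#' @export
optical_density <- function(mean_intensity, max_intensity = 255) {
  check_numeric(mean_intensity, "mean_intensity")
  if (any(mean_intensity <= 0)) {
    stop_tpsad("`mean_intensity` must be positive (saturated/black regions have no finite OD).",
               "tpsad_validation_error")
  }
  if (any(mean_intensity > max_intensity)) {
    stop_tpsad("`mean_intensity` cannot exceed `max_intensity`.", "tpsad_validation_error")
  }
  log10(max_intensity / mean_intensity)
}

# per-channel absorbance of 8-bit intensities; eps avoids log(0) on saturated
# pixels and is matched by the forward synthesis in simulate_ihc_rgb()
intensity_to_absorbance <- function(i, eps = 1) -log10((i + eps) / 255)
absorbance_to_intensity <- function(a, eps = 1) {
  pmin(pmax(round(255 * 10^(-a) - eps), 0), 255)
}

#' H-DAB colour deconvolution
#'
#' Separates an 8-bit RGB micrograph into haematoxylin and DAB channels:
#' per-channel absorbance `-log10((I + eps) / 255)` is projected onto the
#' stain basis by the inverse of the stain matrix, and each stain amount is
#' re-expressed as an 8-bit intensity image (255 = no stain).
#'
#' @param rgb Numeric array `height x width x 3` of 8-bit intensities
#'   (0-255).
#' @param vectors A [stain_vectors()] basis.
#' @param eps Absorbance regularizer added to intensities before the log
#'   (default 1).
#' @return A list of 8-bit intensity matrices: `hematoxylin`, `dab`,
#'   `residual`, plus `amounts`, an array of raw stain absorbances.
#' @export
hdab_deconvolve <- function(rgb, vectors = stain_vectors(), eps = 1) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) {
    stop_tpsad("`rgb` must be a height x width x 3 array.", "tpsad_validation_error")
  }
  if (min(rgb) < 0 || max(rgb) > 255) {
    stop_tpsad("`rgb` intensities must lie in [0, 255].", "tpsad_validation_error")
  }
  m <- unclass(vectors)
  if (abs(det(m)) < 1e-10) stop_tpsad("Stain matrix is singular.", "tpsad_validation_error")
  dm <- dim(rgb)[1:2]
  A <- matrix(intensity_to_absorbance(rgb, eps), ncol = 3)  # pixels x channels
  C <- A %*% t(solve(m))                                    # pixels x stains
  # stain channels re-express as plain 8-bit transmittance (255 = no stain),
  # so optical_density() on a channel recovers the stain absorbance directly
  out <- lapply(1:3, function(s) {
    matrix(pmin(pmax(round(255 * 10^(-C[, s])), 0), 255), dm[1], dm[2])
  })
  names(out) <- colnames(m)
  out$amounts <- array(C, dim = c(dm, 3), dimnames = list(NULL, NULL, colnames(m)))
  out
}

#' Optical densities of random regions
#'
#' Selects `n_regions` equal-size axis-aligned square regions at seeded
#' uniform-random positions (triplicate by default), measures each region's
#' mean intensity, converts it to optical density, and summarises by the
#' arithmetic mean.
#'
#' @param image Numeric matrix of 8-bit intensities (a single-channel image).
#' @param n_regions Number of regions (default 3).
#' @param region_size Side length of the square regions in pixels
#'   (default 128). Must fit inside the image.
#' @param seed Optional integer seed making region placement reproducible.
#' @param allow_overlap If `FALSE`, regions are resampled on overlap (up to
#'   1000 attempts). Default `TRUE`.
#' @return A list: `regions`, a tibble (`region`, `row0`, `col0`,
#'   `mean_intensity`, `od`), and `mean_od`.
#' @export
sample_region_ods <- function(image, n_regions = 3, region_size = 128, seed = NULL,
                              allow_overlap = TRUE) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_tpsad("`image` must be a numeric matrix.", "tpsad_validation_error")
  }
  nr <- nrow(image); nc <- ncol(image)
  if (region_size > nr || region_size > nc) {
    stop_tpsad("`region_size` exceeds the image dimensions.", "tpsad_validation_error")
  }
  draw <- function() {
    picked <- list()
    attempts <- 0
    while (length(picked) < n_regions) {
      r0 <- sample.int(nr - region_size + 1, 1)
      c0 <- sample.int(nc - region_size + 1, 1)
      if (!allow_overlap) {
        clash <- any(vapply(picked, function(p) {
          abs(p[1] - r0) < region_size && abs(p[2] - c0) < region_size
        }, logical(1)))
        attempts <- attempts + 1
        if (clash) {
          if (attempts > 1000) stop_tpsad("Could not place non-overlapping regions.", "tpsad_error")
          next
        }
      }
      picked[[length(picked) + 1]] <- c(r0, c0)
    }
    picked
  }
  picked <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  regions <- purrr::map2_dfr(picked, seq_along(picked), function(p, i) {
    sub <- image[p[1]:(p[1] + region_size - 1), p[2]:(p[2] + region_size - 1)]
    mi <- mean(sub)
    tibble::tibble(region = i, row0 = p[1], col0 = p[2],
                   mean_intensity = mi, od = optical_density(mi))
  })
  list(regions = regions, mean_od = mean(regions$od))
}

#' Read an image as 8-bit intensities
#'
#' Reads a PNG or TIFF image. Grayscale images return a matrix; RGB images
#' return a `height x width x 3` array. Values are rescaled from `[0, 1]` to
#' 8-bit `[0, 255]`.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix or array of intensities in `[0, 255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_tpsad(sprintf("Unsupported image format: '%s'.", ext), "tpsad_validation_error")
  )
  if (length(dim(img)) == 3 && dim(img)[3] >= 3) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (length(dim(img)) == 3) {
    img <- img[, , 1]
  }
  round(img * 255)
}
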