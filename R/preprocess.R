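#' Min-max intensity normalization
#'
#' Affine map of the observed intensity range `[min(I), max(I)]` onto
#' `[out_min, out_max]`. A constant image has no range to stretch; it is
#' returned as all-`out_min` with a warning (documented convention).
#'
#' @param image Numeric `H x W` matrix (grayscale).
#' @param out_min,out_max Target range, `out_min < out_max`.
#' @return Matrix of the same shape with values in `[out_min, out_max]`.
#' @examples
#' minmax_normalize(matrix(0:255, 16, 16))[16, 16]
#' @export
minmax_normalize <- function(image, out_min = 0, out_max = 1) {
  image <- check_image(image)
  if (out_min >= out_max) abort("`out_min` must be < `out_max`.")
  lo <- min(image)
  hi <- max(image)
  if (hi == lo) {
    warn("Constant image: returning all `out_min`.")
    return(matrix(out_min, nrow(image), ncol(image)))
  }
  (image - lo) * (out_max - out_min) / (hi - lo) + out_min
}

check_image <- function(image) {
  image <- as.matrix(image)
  if (!is.numeric(image) || !all(is.finite(image))) {
    abort("`image` must be a finite numeric matrix.")
  }
  if (nrow(image) < 1L || ncol(image) < 1L) abort("Empty image.")
  image
}

#' Grayscale augmentation transforms
#'
#' The four training-time transforms used for CT-style grayscale images:
#' rotation by `theta` degrees in `[-10, 10]` about the image center,
#' translation by up to 10% of each dimension, horizontal flip, and a
#' 5 x 5 Gaussian blur whose standard deviation follows the kernel-size
#' rule `sigma = 0.3 * ((ksize - 1) * 0.5 - 1) + 0.8` (1.1 for a 5 x 5
#' kernel). Geometric transforms use bilinear interpolation with zero fill
#' and keep the input shape. Parameters outside the stated ranges are
#' rejected. Omitted parameters are drawn uniformly from their admissible
#' range.
#'
#' @param image Numeric `H x W` matrix.
#' @param op One of `"rotate"`, `"translate"`, `"hflip"`,
#'   `"gaussian_blur"`.
#' @param theta Rotation angle in degrees, `|theta| <= 10`.
#' @param dx,dy Row/column shifts in pixels, each `|.| <= 0.1 * dim`.
#' @return Matrix of the same shape.
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' all.equal(augment_image(augment_image(img, "hflip"), "hflip"), img)
#' @export
augment_image <- function(image, op = c("rotate", "translate", "hflip",
                                        "gaussian_blur"),
                          theta = NULL, dx = NULL, dy = NULL) {
  op <- match.arg(op)
  image <- check_image(image)
  switch(op,
    rotate = {
      if (is.null(theta)) theta <- runif(1, -10, 10)
      if (abs(theta) > 10) abort("`theta` must lie in [-10, 10] degrees.")
      img <- EBImage::rotate(EBImage::Image(image), theta,
                             filter = "bilinear",
                             output.dim = dim(image), bg.col = 0)
      EBImage::imageData(img)
    },
    translate = {
      max_dx <- 0.1 * nrow(image)
      max_dy <- 0.1 * ncol(image)
      if (is.null(dx)) dx <- runif(1, -max_dx, max_dx)
      if (is.null(dy)) dy <- runif(1, -max_dy, max_dy)
      if (abs(dx) > max_dx || abs(dy) > max_dy) {
        abort("Translation exceeds 10% of the image dimensions.")
      }
      img <- EBImage::translate(EBImage::Image(image), c(dx, dy),
                                filter = "bilinear", bg.col = 0)
      EBImage::imageData(img)
    },
    hflip = image[, ncol(image):1, drop = FALSE],
    gaussian_blur = {
      kern <- gaussian_kernel_5x5()
      img <- EBImage::filter2(EBImage::Image(image), kern, boundary = 0)
      EBImage::imageData(img)
    }
  )
}

# normalized 5x5 Gaussian, sigma from the kernel-size rule
gaussian_kernel_5x5 <- function() {
  sigma <- 0.3 * ((5 - 1) * 0.5 - 1) + 0.8
  g <- dnorm(-2:2, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

#' Summarize a dataset manifest
#'
#' Per-class sample totals and the grand total from a manifest of
#' per-class (optionally per-image-size) counts.
#'
#' @param manifest Data frame with a `class` column, a nonnegative integer
#'   `n` column, and any other stratifying columns (e.g. `image_size`).
#' @return A tibble with one row per class (`class`, `n`) plus a final
#'   `"total"` row holding the grand total.
#' @examples
#' summarize_manifest(tibble::tibble(
#'   class = c("a", "b", "b"), image_size = c("512x512", "512x512", "512x623"),
#'   n = c(10, 20, 5)))
#' @export
summarize_manifest <- function(manifest) {
  manifest <- tibble::as_tibble(manifest)
  if (nrow(manifest) == 0L) {
    return(tibble::tibble(class = "total", n = 0))
  }
  if (!all(c("class", "n") %in% names(manifest))) {
    abort("`manifest` needs `class` and `n` columns.")
  }
  if (any(manifest$n < 0) || any(manifest$n != floor(manifest$n))) {
    abort("Counts `n` must be nonnegative integers.")
  }
  per_class <- manifest |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = sum(.data$n), .groups = "drop")
  dplyr::bind_rows(per_class,
                   tibble::tibble(class = "total", n = sum(per_class$n)))
}

#' Class/image-size manifest of the IQ-OTH/NCCD lung CT dataset
#'
#' The published per-class, per-image-size sample counts of the public
#' IQ-OTH/NCCD lung cancer CT dataset (benign/malignant/normal), used here
#' purely as a worked accounting example; no images are consumed.
#'
#' @return A tibble with columns `class`, `image_size`, `n`.
#' @export
lung_ct_manifest <- function() {
  tibble::tribble(
    ~class,      ~image_size, ~n,
    "benign",    "512x512",   120,
    "malignant", "512x512",   501,
    "malignant", "512x623",   31,
    "malignant", "512x801",   28,
    "malignant", "404x511",   1,
    "normal",    "512x512",   415,
    "normal",    "331x506",   1
  )
}
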