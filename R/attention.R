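#' Squeeze: global average pooling over spatial positions
#'
#' Collapses an `H x W x C` feature map to a length-`C` channel descriptor,
#' `z_c = mean over (i, j) of U[i, j, c]`.
#'
#' @param feature_map Numeric `H x W x C` array with finite entries.
#' @return Numeric vector of length `C`.
#' @export
se_squeeze <- function(feature_map) {
  U <- check_feature_map(feature_map)
  apply(U, 3, mean)
}

check_feature_map <- function(x, name = "feature_map") {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L) {
    abort(paste0("`", name, "` must be an H x W x C array."))
  }
  if (!all(is.finite(x))) abort(paste0("`", name, "` must be finite."))
  x
}

#' Excitation weights for a squeeze-and-excitation gate
#'
#' Holds the two weight matrices of the gating MLP. The hidden size is
#' `max(1, floor(C / reduction))`; the customary reduction ratio is 16.
#' No bias terms by default (the canonical gate has none); optional biases
#' can be supplied.
#'
#' @param W1 `(C/r) x C` matrix, or `NULL` to draw a random Gaussian
#'   initialization.
#' @param W2 `C x (C/r)` matrix, or `NULL` as above.
#' @param channels Number of channels `C` (needed when drawing randomly).
#' @param reduction Reduction ratio `r` (default 16).
#' @param b1,b2 Optional bias vectors for the hidden/output layers.
#' @param sd Standard deviation of the random initialization.
#' @return An object of class `se_weights`.
#' @export
se_weights <- function(W1 = NULL, W2 = NULL, channels = NULL,
                       reduction = 16, b1 = NULL, b2 = NULL, sd = 0.5) {
  if (is.null(W1) || is.null(W2)) {
    if (is.null(channels)) {
      abort("Provide `channels` to draw random excitation weights.")
    }
    hidden <- max(1L, floor(channels / reduction))
    if (is.null(W1)) W1 <- matrix(rnorm(hidden * channels, sd = sd),
                                  hidden, channels)
    if (is.null(W2)) W2 <- matrix(rnorm(channels * hidden, sd = sd),
                                  channels, hidden)
  }
  W1 <- as.matrix(W1)
  W2 <- as.matrix(W2)
  if (ncol(W2) != nrow(W1)) {
    abort("`W2` columns must match `W1` rows (the hidden size).")
  }
  if (nrow(W2) != ncol(W1)) {
    abort("`W2` rows must match `W1` columns (the channel count).")
  }
  structure(list(W1 = W1, W2 = W2, b1 = b1, b2 = b2,
                 reduction = reduction),
            class = "se_weights")
}

#' Excitation: channel gates from the squeezed descriptor
#'
#' `s = sigmoid(W2 %*% relu(W1 %*% z))` (plus biases when present). Gates
#' lie strictly inside `(0, 1)`.
#'
#' @param z Channel descriptor from [se_squeeze()].
#' @param weights An [se_weights()] object.
#' @return Gate vector of length `C` in `(0, 1)`.
#' @export
se_excite <- function(z, weights) {
  if (!inherits(weights, "se_weights")) abort("`weights` must be se_weights.")
  if (length(z) != ncol(weights$W1)) {
    abort("`z` length must equal the channel count.")
  }
  h <- drop(weights$W1 %*% z)
  if (!is.null(weights$b1)) h <- h + weights$b1
  h <- pmax(h, 0)
  o <- drop(weights$W2 %*% h)
  if (!is.null(weights$b2)) o <- o + weights$b2
  1 / (1 + exp(-o))
}

#' Recalibrate a feature map channel-wise
#'
#' Multiplies channel `c` of the map by its gate `s_c`, the squeeze ->
#' excite -> rescale pipeline in one call.
#'
#' @param feature_map Numeric `H x W x C` array.
#' @param weights An [se_weights()] object.
#' @return List with the rescaled `map` (same shape), the `gates`, and the
#'   squeezed descriptor `z`.
#' @export
se_recalibrate <- function(feature_map, weights) {
  U <- check_feature_map(feature_map)
  z <- apply(U, 3, mean)
  s <- se_excite(z, weights)
  out <- U
  for (c in seq_along(s)) out[, , c] <- U[, , c] * s[c]
  list(map = out, gates = s, z = z)
}

#' Channel importance from supplied gradients
#'
#' Spatial mean of the class-score gradient per channel,
#' `gamma_m = mean over (p, q) of dy/dF[p, q, m]`. Gradients are inputs
#' (e.g. analytic gradients of a toy scorer); no network is differentiated
#' here.
#'
#' @param gradients Numeric `H x W x C` array of class-score gradients.
#' @return Numeric vector `gamma` of length `C`.
#' @export
gradcam_weights <- function(gradients) {
  G <- check_feature_map(gradients, "gradients")
  apply(G, 3, mean)
}

#' Class-activation heatmap from channel weights
#'
#' `M = relu(sum_m gamma_m * F^m)`: a nonnegative `H x W` map. Min-max
#' scaling to `[0, 1]` is presentation-only and off by default; a constant
#' map scales to all zeros.
#'
#' @param feature_map Numeric `H x W x C` array.
#' @param gamma Channel weights from [gradcam_weights()].
#' @param normalize Min-max scale the map to `[0, 1]` for display.
#' @return Numeric `H x W` matrix, elementwise nonnegative.
#' @export
gradcam_map <- function(feature_map, gamma, normalize = FALSE) {
  U <- check_feature_map(feature_map)
  if (length(gamma) != dim(U)[3]) {
    abort("`gamma` must have one weight per channel.")
  }
  M <- matrix(0, dim(U)[1], dim(U)[2])
  for (m in seq_along(gamma)) M <- M + gamma[m] * U[, , m]
  M <- pmax(M, 0)
  if (normalize) {
    rng <- range(M)
    M <- if (rng[2] > rng[1]) (M - rng[1]) / (rng[2] - rng[1]) else M * 0
  }
  M
}
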