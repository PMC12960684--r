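#' SMOTE class balancing
#'
#' Brings every class up to the majority-class count by synthesizing
#' minority examples: each synthetic point is
#' `x_new = x_i + lambda * (x_nn - x_i)` with `lambda ~ U(0, 1)` and
#' `x_nn` one of `x_i`'s `k` nearest same-class neighbors (Euclidean).
#' Original rows are preserved verbatim; `k` shrinks to `class size - 1`
#' when a class is smaller than `k + 1`. A minority class with a single
#' sample is an error (interpolation is undefined).
#'
#' @param data Data frame with numeric feature columns and one label
#'   column.
#' @param label Name of the label column (default `"label"`).
#' @param k Number of nearest neighbors considered (default 5).
#' @param seed Optional integer seed.
#' @return A tibble with the original rows first, then synthetic rows, and
#'   an added logical column `synthetic`. All classes have the majority
#'   count.
#' @examples
#' df <- simulate_imbalanced_clusters(counts = c(20, 8, 5), dim = 3, seed = 1)
#' dplyr::count(smote_balance(df, seed = 1), label)
#' @export
smote_balance <- function(data, label = "label", k = 5, seed = NULL) {
  data <- tibble::as_tibble(data)
  if (!label %in% names(data)) {
    abort(paste0("Label column `", label, "` not found."))
  }
  feats <- data[setdiff(names(data), label)]
  if (!all(vapply(feats, is.numeric, logical(1)))) {
    abort("All feature columns must be numeric.")
  }
  if (nrow(data) < 1L) abort("`data` must have >= 1 row.")
  labs <- data[[label]]
  counts <- table(labs)
  target <- max(counts)
  minority <- names(counts)[counts < target]
  if (any(counts[minority] < 2L)) {
    abort("Every minority class needs >= 2 samples to interpolate.")
  }
  X <- as.matrix(feats)
  synth <- with_optional_seed(seed, {
    purrr::map(minority, function(cl) {
      idx <- which(labs == cl)
      Xc <- X[idx, , drop = FALSE]
      n_c <- nrow(Xc)
      k_eff <- min(k, n_c - 1L)
      D <- as.matrix(dist(Xc))
      diag(D) <- Inf
      nn <- apply(D, 1, function(row) order(row)[seq_len(k_eff)])
      nn <- matrix(nn, nrow = k_eff) # k_eff x n_c
      need <- target - n_c
      parent <- sample.int(n_c, need, replace = TRUE)
      buddy <- vapply(parent, function(p) {
        nn[sample.int(k_eff, 1L), p]
      }, integer(1))
      lambda <- runif(need)
      Xs <- Xc[parent, , drop = FALSE] +
        lambda * (Xc[buddy, , drop = FALSE] - Xc[parent, , drop = FALSE])
      out <- tibble::as_tibble(as.data.frame(Xs))
      names(out) <- names(feats)
      out[[label]] <- rep(labs[idx[1]], need)
      out
    })
  })
  orig <- data
  orig$synthetic <- FALSE
  if (length(synth) > 0) {
    synth_df <- dplyr::bind_rows(synth)
    if (nrow(synth_df) > 0) {
      synth_df$synthetic <- TRUE
      return(dplyr::bind_rows(orig, synth_df))
    }
  }
  orig
}

#' @importFrom stats dist
NULL
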