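#' Simulate per-model class-probability matrices with planted structure
#'
#' Stand-in for the softmax outputs of an ensemble's base classifiers.
#' True labels are uniform over classes. For each model and sample the
#' predicted class equals the true class with probability equal to the
#' model's accuracy target, otherwise a uniformly random wrong class. The
#' probability row is a convex blend of a flat Dirichlet draw and the
#' one-hot of the predicted class: `row = (1 - sharpness) * dirichlet +
#' sharpness * onehot`, so with `sharpness > 0.5` the row's argmax is
#' guaranteed to be the predicted class (mimicking a confident softmax).
#'
#' Error correlation between models is induced by sharing a per-sample
#' difficulty draw: with probability `correlation` a model reuses the
#' sample's shared uniform when deciding correctness, otherwise it draws
#' its own, leaving each model's marginal accuracy unchanged.
#'
#' @param n_samples,n_classes,n_models Scenario dimensions.
#' @param accuracy Per-model accuracy targets in `[1/C, 1]`; recycled to
#'   `n_models`.
#' @param correlation Error-correlation knob in `[0, 1]`.
#' @param sharpness Row concentration in `(0.5, 1]`.
#' @param seed Optional integer seed.
#' @return A list with `matrices` (list of `S x C` row-stochastic
#'   matrices), `labels` (1-based integers) and the scenario settings.
#' @export
simulate_prediction_matrices <- function(n_samples = 300, n_classes = 3,
                                         n_models = 3,
                                         accuracy = c(0.9, 0.8, 0.7),
                                         correlation = 0, sharpness = 0.8,
                                         seed = NULL) {
  if (n_samples < 1 || n_classes < 2 || n_models < 1) {
    abort("Need n_samples >= 1, n_classes >= 2, n_models >= 1.")
  }
  accuracy <- rep_len(accuracy, n_models)
  if (any(accuracy < 1 / n_classes) || any(accuracy > 1)) {
    abort("Accuracy targets must lie in [1/C, 1].")
  }
  check_prob(correlation, "correlation")
  if (sharpness <= 0.5 || sharpness > 1) {
    abort("`sharpness` must lie in (0.5, 1] so the argmax is planted.")
  }
  with_optional_seed(seed, {
    labels <- sample.int(n_classes, n_samples, replace = TRUE)
    shared_u <- runif(n_samples)
    matrices <- lapply(seq_len(n_models), function(k) {
      use_shared <- runif(n_samples) < correlation
      u <- ifelse(use_shared, shared_u, runif(n_samples))
      correct <- u < accuracy[k]
      predicted <- ifelse(correct, labels, wrong_class(labels, n_classes))
      base <- matrix(stats::rexp(n_samples * n_classes), n_samples)
      base <- base / rowSums(base)
      onehot <- matrix(0, n_samples, n_classes)
      onehot[cbind(seq_len(n_samples), predicted)] <- 1
      (1 - sharpness) * base + sharpness * onehot
    })
    list(matrices = matrices, labels = labels,
         accuracy = accuracy, correlation = correlation,
         sharpness = sharpness)
  })
}

wrong_class <- function(labels, n_classes) {
  shift <- sample.int(n_classes - 1L, length(labels), replace = TRUE)
  (labels - 1L + shift) %% n_classes + 1L
}

#' Standard benchmark objectives
#'
#' Sphere, Rastrigin, Rosenbrock and Ackley test functions with their
#' analytic minima (all 0, at the origin except Rosenbrock's all-ones) and
#' conventional search boxes.
#'
#' @param name Objective name.
#' @param dim Problem dimension (used for the reported optimum and
#'   bounds).
#' @return A list with `fn`, `bounds` (an [oat_bounds()]), `optimum`
#'   (argmin) and `minimum` (0).
#' @examples
#' b <- benchmark_objective("sphere", dim = 2)
#' b$fn(b$optimum)
#' @export
benchmark_objective <- function(name = c("sphere", "rastrigin",
                                         "rosenbrock", "ackley"),
                                dim = 2) {
  name <- match.arg(name)
  spec <- switch(name,
    sphere = list(
      fn = function(x) sum(x^2),
      box = c(-5, 5), opt = rep(0, dim)
    ),
    rastrigin = list(
      fn = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
      box = c(-5.12, 5.12), opt = rep(0, dim)
    ),
    rosenbrock = list(
      fn = function(x) {
        n <- length(x)
        sum(100 * (x[-1] - x[-n]^2)^2 + (1 - x[-n])^2)
      },
      box = c(-2.048, 2.048), opt = rep(1, dim)
    ),
    ackley = list(
      fn = function(x) {
        n <- length(x)
        -20 * exp(-0.2 * sqrt(sum(x^2) / n)) -
          exp(sum(cos(2 * pi * x)) / n) + 20 + exp(1)
      },
      box = c(-32.768, 32.768), opt = rep(0, dim)
    )
  )
  list(name = name, fn = spec$fn,
       bounds = oat_bounds(spec$box[1], spec$box[2], dim = dim),
       optimum = spec$opt, minimum = 0)
}

#' Simulate a feature map with a companion linear scorer
#'
#' Reproducible `H x W x C` activation tensors: channel `m` is
#' `signal[m] + noise`, with `noise ~ N(0, noise_sd)`. The companion
#' scorer is linear in the channel means, `y = sum_m a_m * mean(F^m)`, so
#' its gradient is analytic: `dy/dF[p, q, m] = a_m / (H * W)`, supplied as
#' the `gradients` array for the class-activation math.
#'
#' @param h,w,channels Tensor dimensions.
#' @param signal Per-channel mean levels; recycled to `channels`.
#' @param score_weights Linear scorer coefficients `a`; recycled.
#' @param noise_sd Gaussian noise level (0 gives exact planted means).
#' @param seed Optional integer seed.
#' @return A list with `map`, `gradients`, `score_weights` and `signal`.
#' @export
simulate_feature_maps <- function(h = 8, w = 8, channels = 4,
                                  signal = 1, score_weights = 1,
                                  noise_sd = 0.1, seed = NULL) {
  signal <- rep_len(signal, channels)
  score_weights <- rep_len(score_weights, channels)
  with_optional_seed(seed, {
    U <- array(rnorm(h * w * channels, sd = noise_sd), c(h, w, channels))
    for (m in seq_len(channels)) U[, , m] <- U[, , m] + signal[m]
    grads <- array(rep(score_weights / (h * w), each = h * w),
                   c(h, w, channels))
    list(map = U, gradients = grads, score_weights = score_weights,
         signal = signal)
  })
}

#' Simulate imbalanced Gaussian feature clusters
#'
#' Labeled Gaussian blobs with the requested per-class counts, the input
#' fixture for SMOTE balancing. Class means sit at `separation * e_k`
#' (scaled unit directions), unit isotropic spread. The default counts
#' reproduce the imbalanced three-class shape typical of the lung CT
#' corpus this workflow emulates (420 / 312 / 90).
#'
#' @param counts Per-class sample counts.
#' @param dim Feature dimension.
#' @param separation Distance scale between class means.
#' @param sd Within-class standard deviation.
#' @param seed Optional integer seed.
#' @return A tibble with `dim` numeric feature columns `f1..fD` and a
#'   character `label` column `class_1..class_K`.
#' @export
simulate_imbalanced_clusters <- function(counts = c(420, 312, 90), dim = 4,
                                         separation = 5, sd = 1,
                                         seed = NULL) {
  if (any(counts < 1)) abort("All class counts must be >= 1.")
  k <- length(counts)
  with_optional_seed(seed, {
    rows <- purrr::map(seq_len(k), function(cl) {
      mu <- numeric(dim)
      mu[(cl - 1L) %% dim + 1L] <- separation * cl
      X <- matrix(rnorm(counts[cl] * dim, sd = sd), counts[cl], dim)
      X <- sweep(X, 2, mu, "+")
      out <- tibble::as_tibble(as.data.frame(X))
      names(out) <- paste0("f", seq_len(dim))
      out$label <- paste0("class_", cl)
      out
    })
    dplyr::bind_rows(rows)
  })
}
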