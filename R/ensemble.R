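#' Project a raw vector onto the probability simplex
#'
#' Negative entries are clipped to zero, then the vector is divided by its
#' sum. An all-zero (or all-negative) input maps to the uniform vector, the
#' documented degenerate rule.
#'
#' @param raw Finite numeric vector.
#' @return A nonnegative vector summing to 1.
#' @examples
#' normalize_to_simplex(c(2, 1, 1))
#' normalize_to_simplex(c(0, 0, 0))
#' @export
normalize_to_simplex <- function(raw) {
  if (!all(is.finite(raw))) abort("`raw` must be finite.")
  w <- pmax(raw, 0)
  s <- sum(w)
  if (s == 0) rep(1 / length(w), length(w)) else w / s
}

check_prediction_matrices <- function(matrices, labels = NULL,
                                      tol = 1e-6, renormalize = TRUE) {
  if (!is.list(matrices) || length(matrices) < 1L) {
    abort("`matrices` must be a non-empty list of probability matrices.")
  }
  matrices <- lapply(matrices, as.matrix)
  dims <- vapply(matrices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("All prediction matrices must share the same dimensions.")
  }
  if (dims[2, 1] < 2L) abort("Prediction matrices need >= 2 classes.")
  matrices <- lapply(seq_along(matrices), function(k) {
    m <- matrices[[k]]
    if (any(m < -tol)) {
      abort(paste0("Matrix ", k, " has negative probabilities."))
    }
    rs <- rowSums(m)
    off <- which(abs(rs - 1) > tol)
    if (length(off) > 0 && !renormalize) {
      abort(paste0("Matrix ", k, " rows not summing to 1 (tolerance ", tol,
                   "): rows ", paste(head(off, 10), collapse = ", ")))
    }
    pmax(m, 0) / rowSums(pmax(m, 0))
  })
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) == 0L) abort("`labels` must be non-empty.")
    if (length(labels) != dims[1, 1]) {
      abort("`labels` must align with the prediction-matrix rows.")
    }
    if (any(labels < 1L) || any(labels > dims[2, 1])) {
      abort("`labels` must be class indices in 1..C.")
    }
  }
  list(matrices = matrices, labels = labels,
       n_samples = dims[1, 1], n_classes = dims[2, 1])
}

#' Weighted soft-vote aggregation
#'
#' `P_final = sum_k w_k * P_k`. With simplex weights the result stays
#' row-stochastic.
#'
#' @param matrices List of `S x C` row-stochastic probability matrices, one
#'   per model.
#' @param weights Simplex weight vector, one entry per model.
#' @return The `S x C` aggregate probability matrix.
#' @export
weighted_aggregate <- function(matrices, weights) {
  chk <- check_prediction_matrices(matrices)
  if (length(weights) != length(matrices)) {
    abort("`weights` must have one entry per model.")
  }
  Reduce(`+`, Map(function(w, m) w * m, weights, chk$matrices))
}

#' Row-argmax decision rule
#'
#' Predicted class per row; ties resolve to the lowest class index.
#'
#' @param p_final An `S x C` probability matrix.
#' @return Integer vector of class indices in 1..C.
#' @export
predict_labels <- function(p_final) {
  apply(as.matrix(p_final), 1, which.max)
}

#' Ensemble-accuracy fitness
#'
#' Fraction of samples whose aggregated argmax equals the true label. This
#' is the quantity the weight search maximizes (exposed to the minimizers
#' via negation inside [optimize_weights()]).
#'
#' @param weights Simplex weight vector.
#' @param matrices List of per-model probability matrices.
#' @param labels Integer true labels in 1..C.
#' @return Accuracy in `[0, 1]`.
#' @export
fitness_accuracy <- function(weights, matrices, labels) {
  chk <- check_prediction_matrices(matrices, labels)
  P <- Reduce(`+`, Map(function(w, m) w * m, weights, chk$matrices))
  mean(max.col(P, ties.method = "first") == chk$labels)
}

#' Ensemble cross-entropy fitness
#'
#' Mean negative log-probability of the true class under the weighted
#' aggregate, with probabilities floored at 1e-12 before the log. Lower is
#' better; a perfectly confident, correct ensemble scores 0 and uniform
#' predictions over `C` classes score `log(C)`.
#'
#' @inheritParams fitness_accuracy
#' @return Nonnegative scalar.
#' @export
fitness_cross_entropy <- function(weights, matrices, labels) {
  chk <- check_prediction_matrices(matrices, labels)
  P <- Reduce(`+`, Map(function(w, m) w * m, weights, chk$matrices))
  p_true <- P[cbind(seq_along(chk$labels), chk$labels)]
  -mean(log(pmax(p_true, 1e-12)))
}

# validation-free fitness kernels used inside optimizer loops
fast_accuracy <- function(w, mats, labels) {
  P <- Reduce(`+`, Map(function(wk, m) wk * m, w, mats))
  mean(max.col(P, ties.method = "first") == labels)
}

fast_cross_entropy <- function(w, mats, labels) {
  P <- Reduce(`+`, Map(function(wk, m) wk * m, w, mats))
  p_true <- P[cbind(seq_along(labels), labels)]
  -mean(log(pmax(p_true, 1e-12)))
}

ensemble_objectives <- function() {
  list(
    accuracy = list(fn = fast_accuracy, maximize = TRUE),
    cross_entropy = list(fn = fast_cross_entropy, maximize = FALSE)
  )
}

#' Optimize soft-voting ensemble weights
#'
#' Searches the box `[0, 1]^M` with the chosen optimizer; every candidate
#' is pushed through [normalize_to_simplex()] before evaluation, so the
#' search is effectively over the weight simplex. The initial population is
#' warm-started with the uniform weight vector and every one-hot vector,
#' which guarantees the optimized ensemble is never worse than the
#' unweighted mean or any single model under the chosen objective.
#'
#' @param matrices List of `S x C` row-stochastic matrices (>= 2 models).
#' @param labels Integer true labels in 1..C.
#' @param objective `"accuracy"` (maximized; the default) or
#'   `"cross_entropy"` (minimized).
#' @param optimizer One of [optimizer_registry()]'s names.
#' @param config Optional optimizer config (defaults to the registry's);
#'   its `seed` governs reproducibility.
#' @param seed Convenience override of `config$seed`.
#' @param warm_start Seed uniform + one-hot weight vectors into the initial
#'   population.
#' @return An object of class `ensemble_result` with elements `weights`,
#'   `p_final`, `predicted`, `objective`, `objective_value`, `accuracy`,
#'   `optimizer` (the underlying `oat_result`) and `rule = "optimized"`.
#' @export
optimize_weights <- function(matrices, labels,
                             objective = c("accuracy", "cross_entropy"),
                             optimizer = "eaoo", config = NULL, seed = NULL,
                             warm_start = TRUE) {
  objective <- match.arg(objective)
  chk <- check_prediction_matrices(matrices, labels)
  M <- length(matrices)
  if (M < 2L) abort("Weight optimization needs >= 2 models.")
  obj <- ensemble_objectives()[[objective]]
  entry <- get_optimizer(optimizer)
  if (is.null(config)) config <- entry$config
  if (!is.null(seed)) config$seed <- seed
  bounds <- oat_bounds(0, 1, dim = M)
  fn <- function(v) obj$fn(normalize_to_simplex(v), chk$matrices,
                           chk$labels)
  init <- if (warm_start) rbind(rep(1 / M, M), diag(M)) else NULL
  res <- entry$fn(fn, bounds, config, init = init, maximize = obj$maximize)
  w <- normalize_to_simplex(res$best_position)
  p_final <- weighted_aggregate(chk$matrices, w)
  new_ensemble_result(
    weights = w, p_final = p_final,
    predicted = predict_labels(p_final),
    labels = chk$labels, objective = objective,
    objective_value = res$best_fitness,
    rule = "optimized", optimizer = res
  )
}

#' Conventional fusion rules
#'
#' Static aggregation baselines: `"mean"` (unweighted average), `"product"`
#' (elementwise product, renormalized per row), `"hard_vote"` (majority of
#' per-model argmax decisions, ties to the lowest class index; the reported
#' probabilities are the vote fractions), `"max_rule"` (per-cell maximum,
#' renormalized per row), `"best_single"` (the single model with the
#' highest individual accuracy on `labels`), and `"fixed_weighted"`
#' (weights proportional to the models' individual accuracies).
#'
#' @param matrices List of `S x C` row-stochastic matrices.
#' @param labels Integer true labels; required by every rule for the
#'   reported accuracy and by `"best_single"`/`"fixed_weighted"` to score
#'   the individual models.
#' @param rule Fusion rule name.
#' @return An `ensemble_result` (see [optimize_weights()]); `weights` is
#'   `NA` for rules that do not reduce to a weighted average.
#' @export
fuse_conventional <- function(matrices, labels,
                              rule = c("mean", "product", "hard_vote",
                                       "max_rule", "best_single",
                                       "fixed_weighted")) {
  rule <- match.arg(rule)
  chk <- check_prediction_matrices(matrices, labels)
  mats <- chk$matrices
  M <- length(mats)
  weights <- rep(NA_real_, M)
  p_final <- switch(rule,
    mean = {
      weights <- rep(1 / M, M)
      Reduce(`+`, mats) / M
    },
    product = {
      P <- Reduce(`*`, mats)
      rs <- rowSums(P)
      # an all-zero row (every class vetoed somewhere) falls back to uniform
      P[rs == 0, ] <- 1 / chk$n_classes
      P / rowSums(P)
    },
    hard_vote = {
      votes <- vapply(mats, function(m) max.col(m, ties.method = "first"),
                      integer(chk$n_samples))
      votes <- matrix(votes, nrow = chk$n_samples)
      P <- t(apply(votes, 1, function(v) {
        tabulate(v, nbins = chk$n_classes)
      }))
      P / rowSums(P)
    },
    max_rule = {
      P <- Reduce(pmax, mats)
      P / rowSums(P)
    },
    best_single = {
      acc <- vapply(mats, function(m) {
        mean(max.col(m, ties.method = "first") == chk$labels)
      }, numeric(1))
      weights <- as.numeric(seq_len(M) == which.max(acc))
      mats[[which.max(acc)]]
    },
    fixed_weighted = {
      acc <- vapply(mats, function(m) {
        mean(max.col(m, ties.method = "first") == chk$labels)
      }, numeric(1))
      weights <- normalize_to_simplex(acc)
      Reduce(`+`, Map(function(w, m) w * m, weights, mats))
    }
  )
  new_ensemble_result(
    weights = weights, p_final = p_final,
    predicted = predict_labels(p_final),
    labels = chk$labels, objective = "accuracy",
    objective_value = mean(predict_labels(p_final) == chk$labels),
    rule = rule, optimizer = NULL
  )
}

new_ensemble_result <- function(weights, p_final, predicted, labels,
                                objective, objective_value, rule,
                                optimizer) {
  structure(
    list(weights = weights, p_final = p_final, predicted = predicted,
         labels = labels, objective = objective,
         objective_value = objective_value,
         accuracy = mean(predicted == labels), rule = rule,
         optimizer = optimizer),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat("<ensemble_result> rule:", x$rule, "\n")
  if (!anyNA(x$weights)) {
    cat("  weights:", paste(signif(x$weights, 4), collapse = " "), "\n")
  }
  cat("  objective (", x$objective, "): ", format(x$objective_value),
      "\n", sep = "")
  cat("  accuracy:", format(x$accuracy), "on", length(x$labels),
      "samples\n")
  invisible(x)
}

#' Tidy per-sample ensemble decisions
#'
#' @param x An `ensemble_result`.
#' @param ... Unused.
#' @return A tibble with one row per sample: `sample`, `label`,
#'   `predicted`, `correct`, and one `p_<class>` column per class.
#' @method tidy ensemble_result
#' @export
tidy.ensemble_result <- function(x, ...) {
  P <- as.matrix(x$p_final)
  colnames(P) <- paste0("p_", seq_len(ncol(P)))
  dplyr::bind_cols(
    tibble::tibble(
      sample = seq_along(x$predicted),
      label = x$labels,
      predicted = x$predicted,
      correct = x$predicted == x$labels
    ),
    tibble::as_tibble(P)
  )
}

#' One-row summary of an ensemble fit
#'
#' @param x An `ensemble_result`.
#' @param ... Unused.
#' @return A tibble with the rule, objective, achieved objective value,
#'   accuracy, and the model weights as a list column.
#' @method glance ensemble_result
#' @export
glance.ensemble_result <- function(x, ...) {
  tibble::tibble(
    rule = x$rule,
    objective = x$objective,
    objective_value = x$objective_value,
    accuracy = x$accuracy,
    n_samples = length(x$labels),
    n_models = length(x$weights),
    weights = list(x$weights)
  )
}

#' Weight profile plot for an ensemble fit
#'
#' @param object An `ensemble_result` with defined weights.
#' @param ... Unused.
#' @return A ggplot bar chart of the model weights.
#' @method autoplot ensemble_result
#' @export
autoplot.ensemble_result <- function(object, ...) {
  if (anyNA(object$weights)) {
    abort("This fusion rule has no weight representation to plot.")
  }
  df <- tibble::tibble(
    model = factor(paste0("model_", seq_along(object$weights)),
                   levels = paste0("model_", seq_along(object$weights))),
    weight = object$weights
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$weight)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::labs(x = NULL, y = "Ensemble weight",
                  title = paste("Fusion weights:", object$rule)) +
    ggplot2::theme_minimal()
}
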