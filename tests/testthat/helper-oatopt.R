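# shared toy fixtures built in code

toy_bounds_2d <- function() oat_bounds(c(-2, -2), c(3, 4))

# two-model / two-class matrices with hand-checkable rows
toy_matrices <- function() {
  list(
    rbind(c(0.8, 0.2), c(0.3, 0.7), c(0.6, 0.4), c(0.1, 0.9)),
    rbind(c(0.4, 0.6), c(0.9, 0.1), c(0.55, 0.45), c(0.2, 0.8))
  )
}

toy_labels <- function() c(1L, 2L, 1L, 2L)

quick_eaoo <- function(seed = NULL, ...) {
  eaoo_config(pop_size = 12, max_iter = 15, seed = seed, ...)
}

# exhaustive two-model simplex-grid search, the brute-force oracle
grid_search_2m <- function(matrices, labels, objective = "accuracy",
                           n_grid = 1001) {
  grid <- seq(0, 1, length.out = n_grid)
  f <- if (objective == "accuracy") fitness_accuracy else
    fitness_cross_entropy
  vals <- vapply(grid, function(w) f(c(w, 1 - w), matrices, labels),
                 numeric(1))
  if (objective == "accuracy") max(vals) else min(vals)
}
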