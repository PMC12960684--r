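new_oat_result <- function(best_position, best_fitness, history, evaluations,
                           method, config, maximize = FALSE) {
  structure(
    list(best_position = best_position, best_fitness = best_fitness,
         history = history, evaluations = evaluations, method = method,
         config = config, maximize = maximize),
    class = "oat_result"
  )
}

#' @export
print.oat_result <- function(x, ...) {
  cat("<oat_result> method:", x$method,
      if (x$maximize) "(maximization)" else "(minimization)", "\n")
  cat("  best fitness:", format(x$best_fitness), "after",
      x$evaluations, "evaluations,", length(x$history), "iterations\n")
  cat("  best position:",
      paste(signif(head(x$best_position, 6), 5), collapse = " "),
      if (length(x$best_position) > 6) "...\n" else "\n")
  invisible(x)
}

#' Tidy the convergence history of an optimizer run
#'
#' @param x An `oat_result`.
#' @param ... Unused.
#' @return A tibble with columns `method`, `iteration`, `best_fitness`.
#' @method tidy oat_result
#' @export
tidy.oat_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    iteration = seq_along(x$history),
    best_fitness = x$history
  )
}

#' One-row summary of an optimizer run
#'
#' @param x An `oat_result`.
#' @param ... Unused.
#' @return A tibble with the method, final fitness, iteration and
#'   evaluation counts, and the seed used (NA when unseeded).
#' @method glance oat_result
#' @export
glance.oat_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    best_fitness = x$best_fitness,
    iterations = length(x$history),
    evaluations = x$evaluations,
    dim = length(x$best_position),
    seed = if (is.null(x$config$seed)) NA_integer_ else
      as.integer(x$config$seed)
  )
}

#' Convergence plot for an optimizer run
#'
#' @param object An `oat_result`.
#' @param log_y Plot the fitness axis on a log10 scale (minimization runs
#'   with positive fitness only).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot oat_result
#' @export
autoplot.oat_result <- function(object, log_y = FALSE, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                        y = .data$best_fitness)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "Iteration", y = "Best fitness",
                  title = paste("Convergence:", object$method)) +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}
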