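#' Box constraints for an optimization problem
#'
#' Bundles the per-coordinate lower and upper bounds of the search box.
#' Scalar bounds are recycled to `dim` coordinates.
#'
#' @param lower,upper Numeric vectors of lower/upper bounds. Must be finite
#'   and satisfy `lower <= upper` elementwise.
#' @param dim Optional problem dimension used to recycle scalar bounds.
#'
#' @return An object of class `oat_bounds`: a list with elements `lower`,
#'   `upper` and `dim`.
#' @examples
#' oat_bounds(-5, 5, dim = 3)
#' oat_bounds(c(0, 0), c(1, 2))
#' @export
oat_bounds <- function(lower, upper, dim = NULL) {
  if (!is.numeric(lower) || !is.numeric(upper)) {
    abort("`lower` and `upper` must be numeric.")
  }
  if (!is.null(dim)) {
    if (length(lower) == 1L) lower <- rep(lower, dim)
    if (length(upper) == 1L) upper <- rep(upper, dim)
  }
  if (length(lower) != length(upper)) {
    abort("`lower` and `upper` must have the same length.")
  }
  if (length(lower) < 1L) abort("Bounds must have dimension >= 1.")
  if (!all(is.finite(lower)) || !all(is.finite(upper))) {
    abort("Bounds must be finite.")
  }
  if (any(lower > upper)) abort("Each `lower` must be <= its `upper`.")
  structure(
    list(lower = as.numeric(lower), upper = as.numeric(upper),
         dim = length(lower)),
    class = "oat_bounds"
  )
}

as_oat_bounds <- function(bounds, lower = NULL, upper = NULL, dim = NULL) {
  if (inherits(bounds, "oat_bounds")) return(bounds)
  oat_bounds(lower, upper, dim)
}

#' @export
print.oat_bounds <- function(x, ...) {
  cat("<oat_bounds> dim =", x$dim, "\n")
  cat("  lower:", paste(signif(head(x$lower, 6), 4), collapse = " "),
      if (x$dim > 6) "...\n" else "\n")
  cat("  upper:", paste(signif(head(x$upper, 6), 4), collapse = " "),
      if (x$dim > 6) "...\n" else "\n")
  invisible(x)
}

# every move is clipped back into the box; the box is the only constraint
clip_to_bounds <- function(x, bounds) {
  pmin(pmax(x, bounds$lower), bounds$upper)
}
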