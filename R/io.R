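#' Read and write prediction matrices, labels and weights
#'
#' Prediction matrices travel as headered CSV (one column per class, one
#' row per sample); labels as a single-column CSV (`label`, 1-based class
#' indices); weights as JSON. On read, rows further than `tol` from
#' stochastic raise an error listing the offending rows; rows within `tol`
#' are renormalized.
#'
#' @param matrix,path,weights Objects/paths as appropriate.
#' @param tol Row-sum tolerance on read.
#' @name ensemble_io
NULL

#' @rdname ensemble_io
#' @export
write_prediction_matrix <- function(matrix, path) {
  m <- as.matrix(matrix)
  if (is.null(colnames(m))) colnames(m) <- paste0("class_", seq_len(ncol(m)))
  readr::write_csv(tibble::as_tibble(m), path)
  invisible(path)
}

#' @rdname ensemble_io
#' @export
read_prediction_matrix <- function(path, tol = 1e-6) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df)
  check_prediction_matrices(list(m), tol = tol,
                            renormalize = FALSE)$matrices[[1]]
}

#' @rdname ensemble_io
#' @export
write_labels <- function(labels, path) {
  readr::write_csv(tibble::tibble(label = as.integer(labels)), path)
  invisible(path)
}

#' @rdname ensemble_io
#' @export
read_labels <- function(path) {
  as.integer(readr::read_csv(path, show_col_types = FALSE)$label)
}

#' @rdname ensemble_io
#' @export
write_weights <- function(weights, path) {
  jsonlite::write_json(list(weights = weights), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname ensemble_io
#' @export
read_weights <- function(path) {
  as.numeric(jsonlite::read_json(path, simplifyVector = TRUE)$weights)
}

#' Read a flat YAML run configuration
#'
#' Flat key-value file carrying optimizer settings and scenario knobs,
#' merged over the given defaults.
#'
#' @param path YAML file path.
#' @param defaults Named list of defaults.
#' @return Named list.
#' @export
read_run_config <- function(path, defaults = list()) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort("Config file must be a YAML mapping.")
  utils::modifyList(defaults, cfg)
}
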