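#' Configuration for the animated oat optimizer
#'
#' All tuning knobs of the oat-dispersal metaheuristic and its genetic
#' enhancement. Defaults follow the settings used throughout the comparative
#' literature on population metaheuristics: a population of 50 evolved for
#' 100 iterations, differential scale factor `F = 0.5`, crossover rate
#' `CR = 0.9`, mutation probability `Pm = 0.1` and Levy stability
#' exponent `beta = 1.5`.
#'
#' @param pop_size Population size `N` (>= 4; differential crossover needs
#'   three distinct partners besides the target).
#' @param max_iter Number of iterations `T` (>= 1).
#' @param scale_factor Differential scale factor `F` (> 0).
#' @param crossover_rate Binomial crossover rate `CR` in `[0, 1]`.
#' @param mutation_prob Per-coordinate non-uniform mutation probability
#'   `Pm` in `[0, 1]`.
#' @param nonuniformity Non-uniformity degree `b` (> 0) of the mutation
#'   step-size decay; 5 is the conventional choice.
#' @param levy_beta Levy stability exponent `beta` in `(0, 2]`.
#' @param levy_variant `"literal"` uses the algorithm's printed scale
#'   formula (pi in the denominator, uniform step mean); `"mantegna"` the
#'   standard Mantegna scheme. See [levy_step()].
#' @param gravity Gravitational constant `g` (> 0) in the jumping update.
#' @param p_explore Per-individual probability of taking the wind-dispersal
#'   exploration move rather than an exploitation move.
#' @param p_roll Within exploitation, probability of the hygroscopic rolling
#'   move; otherwise the elastic jumping move (both outcomes equiprobable by
#'   default).
#' @param use_ga_operators If `TRUE` (the enhanced variant), differential
#'   crossover and non-uniform mutation with greedy replacement are applied
#'   population-wide after the oat moves; `FALSE` gives the plain algorithm.
#' @param seed Optional integer seed; when set, runs are bitwise
#'   reproducible.
#'
#' @return An object of class `eaoo_config` (a named list).
#' @seealso [optimize_eaoo()]
#' @export
eaoo_config <- function(pop_size = 50, max_iter = 100,
                        scale_factor = 0.5, crossover_rate = 0.9,
                        mutation_prob = 0.1, nonuniformity = 5,
                        levy_beta = 1.5, levy_variant = c("literal", "mantegna"),
                        gravity = 9.81, p_explore = 0.5, p_roll = 0.5,
                        use_ga_operators = TRUE, seed = NULL) {
  levy_variant <- match.arg(levy_variant)
  cfg <- structure(
    list(pop_size = as.integer(pop_size), max_iter = as.integer(max_iter),
         scale_factor = scale_factor, crossover_rate = crossover_rate,
         mutation_prob = mutation_prob, nonuniformity = nonuniformity,
         levy_beta = levy_beta, levy_variant = levy_variant,
         gravity = gravity, p_explore = p_explore, p_roll = p_roll,
         use_ga_operators = isTRUE(use_ga_operators), seed = seed),
    class = c("eaoo_config", "oat_config")
  )
  validate_eaoo_config(cfg)
}

validate_eaoo_config <- function(cfg) {
  if (cfg$pop_size < 4L) abort("`pop_size` must be >= 4.")
  if (cfg$max_iter < 1L) abort("`max_iter` must be >= 1.")
  if (!is.numeric(cfg$scale_factor) || cfg$scale_factor <= 0) {
    abort("`scale_factor` must be > 0.")
  }
  check_prob(cfg$crossover_rate, "crossover_rate")
  check_prob(cfg$mutation_prob, "mutation_prob")
  check_prob(cfg$p_explore, "p_explore")
  check_prob(cfg$p_roll, "p_roll")
  if (cfg$nonuniformity <= 0) abort("`nonuniformity` must be > 0.")
  if (cfg$levy_beta <= 0 || cfg$levy_beta > 2) {
    abort("`levy_beta` must lie in (0, 2].")
  }
  if (cfg$gravity <= 0) abort("`gravity` must be > 0.")
  check_seed(cfg$seed)
  cfg
}

#' Configurations for the reference optimizers
#'
#' Defaults mirror the settings conventionally used when benchmarking
#' population optimizers under a shared budget: population 50, 100
#' iterations; differential evolution (rand/1/bin) with `F = 0.5`,
#' `CR = 0.7`; a real-coded genetic algorithm with crossover probability
#' 0.8, per-gene mutation probability 0.1 and tournament selection of
#' size 3.
#'
#' @param pop_size Population size (candidates per iteration for random
#'   search).
#' @param max_iter Number of iterations/generations.
#' @param scale_factor,crossover_rate DE control parameters.
#' @param crossover_prob,mutation_prob,tournament_size GA control
#'   parameters; crossover is arithmetic (blend) with a fresh mixing
#'   coefficient per mating, mutation is per-gene uniform reset, and one
#'   elite is carried over unchanged.
#' @param seed Optional integer seed.
#'
#' @return A config object (named list) for the matching `optimize_*()`
#'   function.
#' @name baseline_config
NULL

#' @rdname baseline_config
#' @export
de_config <- function(pop_size = 50, max_iter = 100, scale_factor = 0.5,
                      crossover_rate = 0.7, seed = NULL) {
  if (pop_size < 4L) abort("`pop_size` must be >= 4.")
  if (max_iter < 1L) abort("`max_iter` must be >= 1.")
  if (scale_factor <= 0) abort("`scale_factor` must be > 0.")
  check_prob(crossover_rate, "crossover_rate")
  check_seed(seed)
  structure(
    list(pop_size = as.integer(pop_size), max_iter = as.integer(max_iter),
         scale_factor = scale_factor, crossover_rate = crossover_rate,
         seed = seed),
    class = c("de_config", "oat_config")
  )
}

#' @rdname baseline_config
#' @export
ga_config <- function(pop_size = 50, max_iter = 100, crossover_prob = 0.8,
                      mutation_prob = 0.1, tournament_size = 3, seed = NULL) {
  if (pop_size < 2L) abort("`pop_size` must be >= 2.")
  if (max_iter < 1L) abort("`max_iter` must be >= 1.")
  check_prob(crossover_prob, "crossover_prob")
  check_prob(mutation_prob, "mutation_prob")
  if (tournament_size < 1L) abort("`tournament_size` must be >= 1.")
  check_seed(seed)
  structure(
    list(pop_size = as.integer(pop_size), max_iter = as.integer(max_iter),
         crossover_prob = crossover_prob, mutation_prob = mutation_prob,
         tournament_size = as.integer(tournament_size), seed = seed),
    class = c("ga_config", "oat_config")
  )
}

#' @rdname baseline_config
#' @export
random_search_config <- function(pop_size = 50, max_iter = 100, seed = NULL) {
  if (pop_size < 1L) abort("`pop_size` must be >= 1.")
  if (max_iter < 1L) abort("`max_iter` must be >= 1.")
  check_seed(seed)
  structure(
    list(pop_size = as.integer(pop_size), max_iter = as.integer(max_iter),
         seed = seed),
    class = c("random_search_config", "oat_config")
  )
}

#' @export
print.oat_config <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat("  ", nm, ": ", if (is.null(val)) "NULL" else format(val), "\n",
        sep = "")
  }
  invisible(x)
}

check_prob <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    abort(paste0("`", name, "` must be a probability in [0, 1]."))
  }
  invisible(p)
}

check_seed <- function(seed) {
  if (!is.null(seed) &&
      (!is.numeric(seed) || length(seed) != 1L || is.na(seed))) {
    abort("`seed` must be NULL or a single integer.")
  }
  invisible(seed)
}

# Evaluate `expr` under `seed` when given, leaving the caller's RNG state
# untouched; without a seed, use (and advance) the ambient RNG stream.
with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
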