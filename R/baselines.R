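#' Differential evolution (rand/1/bin)
#'
#' Classic DE with the rand/1 mutant, binomial crossover with a forced
#' coordinate, greedy one-to-one replacement and clipping to the box.
#'
#' @inheritParams optimize_eaoo
#' @param config A [de_config()].
#' @return An `oat_result`.
#' @export
optimize_de <- function(objective, bounds, config = de_config(),
                        init = NULL, maximize = FALSE) {
  bounds <- as_oat_bounds(bounds)
  f <- wrap_objective(objective, maximize)
  with_optional_seed(config$seed, {
    n <- config$pop_size
    d <- bounds$dim
    X <- init_population(bounds, n, init)
    fit <- apply(X, 1, f)
    evals <- n
    best_i <- which.min(fit)
    best_x <- X[best_i, ]
    best_f <- fit[best_i]
    history <- numeric(config$max_iter)
    for (t in seq_len(config$max_iter)) {
      for (i in seq_len(n)) {
        U <- de_crossover(X, i, config$scale_factor, config$crossover_rate,
                          bounds)
        fu <- f(U)
        evals <- evals + 1L
        if (greedy_keep(fit[i], fu)) {
          X[i, ] <- U
          fit[i] <- fu
          if (fu < best_f) {
            best_f <- fu
            best_x <- U
          }
        }
      }
      history[t] <- best_f
    }
    list(best_position = best_x, best_fitness = best_f, history = history,
         evaluations = evals)
  }) |> finalize_result(maximize, "de", config)
}

#' Real-coded genetic algorithm
#'
#' Tournament selection, arithmetic (blend) crossover with a fresh mixing
#' coefficient per mating, per-gene uniform-reset mutation, and elitism of
#' one. The best-so-far solution is tracked across generations.
#'
#' @inheritParams optimize_eaoo
#' @param config A [ga_config()].
#' @return An `oat_result`.
#' @export
optimize_ga <- function(objective, bounds, config = ga_config(),
                        init = NULL, maximize = FALSE) {
  bounds <- as_oat_bounds(bounds)
  f <- wrap_objective(objective, maximize)
  with_optional_seed(config$seed, {
    n <- config$pop_size
    d <- bounds$dim
    X <- init_population(bounds, n, init)
    fit <- apply(X, 1, f)
    evals <- n
    best_i <- which.min(fit)
    best_x <- X[best_i, ]
    best_f <- fit[best_i]
    history <- numeric(config$max_iter)
    tournament <- function() {
      idx <- sample.int(n, min(config$tournament_size, n))
      idx[which.min(fit[idx])]
    }
    for (t in seq_len(config$max_iter)) {
      newX <- matrix(0, n, d)
      newX[1, ] <- X[which.min(fit), ] # elite
      i <- 2L
      while (i <= n) {
        p1 <- X[tournament(), ]
        p2 <- X[tournament(), ]
        if (runif(1) < config$crossover_prob) {
          a <- runif(1)
          c1 <- a * p1 + (1 - a) * p2
          c2 <- (1 - a) * p1 + a * p2
        } else {
          c1 <- p1
          c2 <- p2
        }
        for (child in list(c1, c2)) {
          if (i > n) break
          reset <- runif(d) < config$mutation_prob
          child[reset] <- runif(sum(reset), bounds$lower[reset],
                                bounds$upper[reset])
          newX[i, ] <- clip_to_bounds(child, bounds)
          i <- i + 1L
        }
      }
      X <- newX
      fit <- apply(X, 1, f)
      evals <- evals + n
      gen_i <- which.min(fit)
      if (fit[gen_i] < best_f) {
        best_f <- fit[gen_i]
        best_x <- X[gen_i, ]
      }
      history[t] <- best_f
    }
    list(best_position = best_x, best_fitness = best_f, history = history,
         evaluations = evals)
  }) |> finalize_result(maximize, "ga", config)
}

#' Uniform random search
#'
#' `pop_size * max_iter` independent uniform draws over the box; the best
#' draw so far is tracked after each batch of `pop_size` candidates. Warm
#' starts replace the first candidates of the first batch.
#'
#' @inheritParams optimize_eaoo
#' @param config A [random_search_config()].
#' @return An `oat_result`.
#' @export
optimize_random_search <- function(objective, bounds,
                                   config = random_search_config(),
                                   init = NULL, maximize = FALSE) {
  bounds <- as_oat_bounds(bounds)
  f <- wrap_objective(objective, maximize)
  with_optional_seed(config$seed, {
    n <- config$pop_size
    best_f <- Inf
    best_x <- NULL
    evals <- 0L
    history <- numeric(config$max_iter)
    for (t in seq_len(config$max_iter)) {
      X <- init_population(bounds, n, if (t == 1L) init else NULL)
      for (i in seq_len(n)) {
        fc <- f(X[i, ])
        evals <- evals + 1L
        if (fc < best_f) {
          best_f <- fc
          best_x <- X[i, ]
        }
      }
      history[t] <- best_f
    }
    list(best_position = best_x, best_fitness = best_f, history = history,
         evaluations = evals)
  }) |> finalize_result(maximize, "random_search", config)
}

#' Registry of available optimizers
#'
#' Maps optimizer names to their driver function and default config.
#' `"eaoo"` is the GA-enhanced oat optimizer, `"aoo"` the plain variant.
#'
#' @return A named list; each entry has elements `fn` and `config`.
#' @export
optimizer_registry <- function() {
  list(
    eaoo = list(fn = optimize_eaoo, config = eaoo_config()),
    aoo = list(fn = optimize_eaoo,
               config = eaoo_config(use_ga_operators = FALSE)),
    de = list(fn = optimize_de, config = de_config()),
    ga = list(fn = optimize_ga, config = ga_config()),
    random_search = list(fn = optimize_random_search,
                         config = random_search_config())
  )
}

get_optimizer <- function(name) {
  reg <- optimizer_registry()
  if (!name %in% names(reg)) {
    abort(paste0("Unknown optimizer `", name, "`. Available: ",
                 paste(names(reg), collapse = ", "), "."))
  }
  reg[[name]]
}
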