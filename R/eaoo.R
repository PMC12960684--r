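#' Initialize a uniform random population inside the box
#'
#' Each entry is `r * (UB_j - LB_j) + LB_j` with an independent
#' `r ~ U(0, 1)`.
#'
#' @param bounds An [oat_bounds()] object.
#' @param pop_size Number of individuals.
#' @param init Optional numeric matrix whose rows replace the first rows of
#'   the random population (warm starts). Rows are clipped to the box.
#' @return A `pop_size` x `dim` numeric matrix.
#' @export
init_population <- function(bounds, pop_size, init = NULL) {
  d <- bounds$dim
  span <- bounds$upper - bounds$lower
  X <- matrix(runif(pop_size * d), pop_size, d)
  X <- sweep(sweep(X, 2, span, "*"), 2, bounds$lower, "+")
  if (!is.null(init)) {
    init <- as.matrix(init)
    if (ncol(init) != d) abort("`init` must have `dim` columns.")
    k <- min(nrow(init), pop_size)
    for (i in seq_len(k)) X[i, ] <- clip_to_bounds(init[i, ], bounds)
  }
  X
}

#' Per-iteration dynamic parameters of the oat dispersal model
#'
#' Seed mass `m = 0.5 * r / Dim`, awn length `L = N * r / Dim` and
#' eccentricity `e = 0.5 * r / Dim` each use a fresh `r ~ U(0, 1)`; the
#' decay factor `c = 1 - (t / T)^3` is deterministic, falling from 1 at
#' `t = 0` to 0 at `t = T`.
#'
#' @param t Current iteration (0 <= t <= T).
#' @param max_iter Total iterations `T` (>= 1).
#' @param pop_size Population size `N`.
#' @param dim Problem dimension.
#' @param r Optional injected vector of the three uniforms `(r_m, r_L, r_e)`.
#' @return A list with elements `m`, `L`, `e`, `decay`, `t`, `max_iter`.
#' @export
dynamic_params <- function(t, max_iter, pop_size, dim, r = NULL) {
  if (max_iter < 1) abort("`max_iter` must be >= 1.")
  if (t < 0 || t > max_iter) abort("`t` must lie in [0, max_iter].")
  if (is.null(r)) r <- runif(3)
  list(
    m = 0.5 * r[1] / dim,
    L = pop_size * r[2] / dim,
    e = 0.5 * r[3] / dim,
    decay = 1 - (t / max_iter)^3,
    t = t, max_iter = max_iter
  )
}

# step size s of the modular branch split: ~10% of individuals take each
# special branch
branch_step <- function(pop_size) max(1L, as.integer(floor(pop_size / 10)))

#' Wind-dispersal exploration move
#'
#' Perturbation `W = (c / pi) * (2 * r_Dim - 1) (x) UB` with a fresh uniform
#' vector per individual. The anchor depends on the individual's index `i`
#' and the branch step `s = max(1, floor(N / 10))`: the population mean when
#' `i mod s == 0`, the incumbent best when `i mod s == 1`, the individual's
#' own position otherwise. The result is clipped to the box.
#'
#' @param i 1-based individual index (drives the branch split).
#' @param X Current population matrix.
#' @param best Incumbent best position.
#' @param bounds An [oat_bounds()] object.
#' @param decay Decay factor `c` of [dynamic_params()].
#' @param r_dim Optional injected uniform vector (length `dim`).
#' @return Proposed position (length `dim`).
#' @export
exploration_move <- function(i, X, best, bounds, decay, r_dim = NULL) {
  d <- bounds$dim
  if (is.null(r_dim)) r_dim <- runif(d)
  W <- (decay / pi) * (2 * r_dim - 1) * bounds$upper
  s <- branch_step(nrow(X))
  anchor <- switch(as.character(i %% s),
    "0" = colMeans(X),
    "1" = best,
    X[i, ]
  )
  clip_to_bounds(anchor + W, bounds)
}

#' Hygroscopic rolling exploitation move
#'
#' Amplitude `A = UB - |UB * t * sin(2 * pi * r) / T|` with a fresh scalar
#' `r`; displacement `R = (m * e + L^2) * U(-A, A) / Dim` per coordinate;
#' proposal `X_best + R + c * Levy (x) X_best`, clipped to the box.
#'
#' @inheritParams exploration_move
#' @param params Output of [dynamic_params()].
#' @param config An [eaoo_config()].
#' @param r,r_dim,levy Optional injected randoms: scalar uniform `r`,
#'   uniform vector on `(-A, A)` expressed as `U(0,1)` draws `r_dim`, and a
#'   Levy step vector.
#' @return Proposed position (length `dim`).
#' @export
rolling_move <- function(best, bounds, params, config,
                         r = NULL, r_dim = NULL, levy = NULL) {
  d <- bounds$dim
  if (is.null(r)) r <- runif(1)
  A <- abs_amplitude(bounds$upper, params$t, params$max_iter, sin(2 * pi * r))
  if (is.null(r_dim)) r_dim <- runif(d)
  draw <- (2 * r_dim - 1) * A # uniform in (-A_j, A_j)
  R <- (params$m * params$e + params$L^2) * draw / d
  if (is.null(levy)) {
    levy <- levy_step(d, config$levy_beta, config$levy_variant)
  }
  clip_to_bounds(best + R + params$decay * levy * best, bounds)
}

#' Elastic jumping exploitation move
#'
#' Amplitude `B = UB - |UB * t * cos(2 * pi * r) / T|`; awn elasticity
#' `k = 0.5 + 0.5 * r2`, length change `x = 3 * r2 / Dim`, launch angle
#' `theta = pi * r2` (one fresh scalar `r2` drives all three), drag
#' `alpha = exp(r' / T) / pi` with `r' ~ U(0, T)` (so `alpha <= e / pi < 1`);
#' displacement
#' `J = 2 * k * x^2 * sin(2 * theta) / (m * g) * U(-B, B) / Dim * (1 - alpha)`;
#' proposal `X_best + J + c * Levy (x) X_best`, clipped. The seed mass `m`
#' is floored at 1e-12 in the denominator.
#'
#' @inheritParams rolling_move
#' @param r2,r_prime Optional injected scalar randoms (see Details).
#' @return Proposed position (length `dim`).
#' @export
jumping_move <- function(best, bounds, params, config,
                         r = NULL, r2 = NULL, r_prime = NULL,
                         r_dim = NULL, levy = NULL) {
  d <- bounds$dim
  if (is.null(r)) r <- runif(1)
  B <- abs_amplitude(bounds$upper, params$t, params$max_iter, cos(2 * pi * r))
  if (is.null(r2)) r2 <- runif(1)
  k <- 0.5 + 0.5 * r2
  x <- 3 * r2 / d
  theta <- pi * r2
  if (is.null(r_prime)) r_prime <- runif(1, 0, params$max_iter)
  alpha <- exp(r_prime / params$max_iter) / pi
  if (is.null(r_dim)) r_dim <- runif(d)
  draw <- (2 * r_dim - 1) * B
  m <- max(params$m, 1e-12)
  J <- 2 * k * x^2 * sin(2 * theta) / (m * config$gravity) *
    draw / d * (1 - alpha)
  if (is.null(levy)) {
    levy <- levy_step(d, config$levy_beta, config$levy_variant)
  }
  clip_to_bounds(best + J + params$decay * levy * best, bounds)
}

abs_amplitude <- function(upper, t, max_iter, trig) {
  upper - abs(upper * t * trig / max_iter)
}

#' Differential crossover trial vector
#'
#' rand/1 mutant `V = X_r1 + F * (X_r2 - X_r3)` from three distinct
#' partners (none equal to the target), followed by binomial crossover at
#' rate `CR` with a forced coordinate `j_rand`, then clipping.
#'
#' @param X Population matrix (>= 4 rows).
#' @param i Target row index.
#' @param scale_factor Differential weight `F`.
#' @param crossover_rate Crossover rate `CR`.
#' @param bounds An [oat_bounds()] object.
#' @param partners,j_rand,r_cross Optional injected randoms: the three
#'   partner indices, the forced coordinate, and the per-coordinate
#'   uniforms compared against `CR`.
#' @return Trial vector of length `dim`.
#' @export
de_crossover <- function(X, i, scale_factor, crossover_rate, bounds,
                         partners = NULL, j_rand = NULL, r_cross = NULL) {
  n <- nrow(X)
  if (n < 4L) abort("Differential crossover needs a population of >= 4.")
  d <- ncol(X)
  if (is.null(partners)) partners <- sample(seq_len(n)[-i], 3L)
  V <- X[partners[1], ] + scale_factor * (X[partners[2], ] - X[partners[3], ])
  if (is.null(j_rand)) j_rand <- sample.int(d, 1L)
  if (is.null(r_cross)) r_cross <- runif(d)
  take <- r_cross <= crossover_rate
  take[j_rand] <- TRUE
  U <- ifelse(take, V, X[i, ])
  clip_to_bounds(U, bounds)
}

#' Non-uniform mutation
#'
#' Each coordinate mutates with probability `Pm`; the displacement is
#' `Delta(t, y) = y * (1 - r^((1 - t/T)^b))`, shrinking to exactly zero at
#' `t = T`, applied toward the upper or lower bound on a fair coin flip.
#' Because `Delta(t, y) <= y`, a mutated point never leaves the box.
#'
#' @param x Position vector inside the box.
#' @param bounds An [oat_bounds()] object.
#' @param t,max_iter Current/total iteration.
#' @param mutation_prob Per-coordinate mutation probability `Pm`.
#' @param nonuniformity Decay degree `b`.
#' @param r_gate,r_dir,r_mag Optional injected uniform vectors (length
#'   `dim`): mutation gate, direction coin, and magnitude draw.
#' @return Mutated position vector.
#' @export
nonuniform_mutate <- function(x, bounds, t, max_iter, mutation_prob,
                              nonuniformity, r_gate = NULL, r_dir = NULL,
                              r_mag = NULL) {
  d <- length(x)
  if (is.null(r_gate)) r_gate <- runif(d)
  if (is.null(r_dir)) r_dir <- runif(d)
  if (is.null(r_mag)) r_mag <- runif(d)
  expo <- (1 - t / max_iter)^nonuniformity
  shrink <- 1 - r_mag^expo
  up <- r_dir < 0.5
  y <- ifelse(up, bounds$upper - x, x - bounds$lower)
  delta <- y * shrink
  out <- ifelse(r_gate < mutation_prob, ifelse(up, x + delta, x - delta), x)
  clip_to_bounds(out, bounds)
}

#' Greedy replacement rule
#'
#' Keep the trial iff its fitness is no worse (minimization; ties go to the
#' trial). Non-finite trial fitness is rejected.
#'
#' @param current_fitness,trial_fitness Scalar objective values.
#' @return `TRUE` to keep the trial.
#' @export
greedy_keep <- function(current_fitness, trial_fitness) {
  is.finite(trial_fitness) && trial_fitness <= current_fitness
}

#' Optimize with the animated oat metaheuristic (plain or GA-enhanced)
#'
#' Minimizes `objective` over the box. Each iteration recomputes the
#' dynamic parameters, then moves every individual: with probability
#' `p_explore` the wind-dispersal exploration move, otherwise one of the
#' two exploitation moves (hygroscopic rolling with probability `p_roll`,
#' elastic jumping otherwise). Moves are accepted greedily. With
#' `use_ga_operators = TRUE`, differential crossover and non-uniform
#' mutation (each followed by greedy replacement) then sweep the whole
#' population. The best solution is tracked continuously and only replaced
#' on strict improvement, so ties keep the first optimum found.
#'
#' Non-finite objective values are treated as `+Inf`; supply `maximize =
#' TRUE` to maximize (the objective is negated internally and the reported
#' fitness is on the original scale).
#'
#' @param objective Function mapping a length-`dim` numeric vector to a
#'   scalar.
#' @param bounds An [oat_bounds()] object (or `lower`/`upper` vectors via
#'   [oat_bounds()]).
#' @param config An [eaoo_config()].
#' @param init Optional warm-start matrix; rows seed the initial
#'   population.
#' @param maximize Maximize instead of minimize.
#' @return An object of class `oat_result`: `best_position`,
#'   `best_fitness`, `history` (best fitness after each iteration,
#'   non-increasing under minimization), `evaluations`, `method`, `config`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- optimize_eaoo(sphere, oat_bounds(-5, 5, dim = 3),
#'                      eaoo_config(pop_size = 20, max_iter = 30, seed = 1))
#' res$best_fitness
#' @export
optimize_eaoo <- function(objective, bounds, config = eaoo_config(),
                          init = NULL, maximize = FALSE) {
  validate_eaoo_config(config)
  bounds <- as_oat_bounds(bounds)
  f <- wrap_objective(objective, maximize)
  with_optional_seed(config$seed, {
    run_eaoo(f, bounds, config, init)
  }) |> finalize_result(maximize, method_name(config), config)
}

method_name <- function(config) {
  if (config$use_ga_operators) "eaoo_ga" else "aoo"
}

run_eaoo <- function(f, bounds, config, init) {
  n <- config$pop_size
  d <- bounds$dim
  T_ <- config$max_iter
  X <- init_population(bounds, n, init)
  fit <- apply(X, 1, f)
  evals <- n
  b_idx <- which.min(fit)
  best_x <- X[b_idx, ]
  best_f <- fit[b_idx]
  history <- numeric(T_)

  for (t in seq_len(T_)) {
    params <- dynamic_params(t, T_, n, d)
    for (i in seq_len(n)) {
      cand <- if (runif(1) < config$p_explore) {
        exploration_move(i, X, best_x, bounds, params$decay)
      } else if (runif(1) < config$p_roll) {
        rolling_move(best_x, bounds, params, config)
      } else {
        jumping_move(best_x, bounds, params, config)
      }
      fc <- f(cand)
      evals <- evals + 1L
      if (greedy_keep(fit[i], fc)) {
        X[i, ] <- cand
        fit[i] <- fc
        if (fc < best_f) {
          best_f <- fc
          best_x <- cand
        }
      }
    }
    if (config$use_ga_operators) {
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
      for (i in seq_len(n)) {
        M <- nonuniform_mutate(X[i, ], bounds, t, T_, config$mutation_prob,
                               config$nonuniformity)
        fm <- f(M)
        evals <- evals + 1L
        if (greedy_keep(fit[i], fm)) {
          X[i, ] <- M
          fit[i] <- fm
          if (fm < best_f) {
            best_f <- fm
            best_x <- M
          }
        }
      }
    }
    history[t] <- best_f
  }
  list(best_position = best_x, best_fitness = best_f, history = history,
       evaluations = evals)
}

wrap_objective <- function(objective, maximize) {
  sign <- if (maximize) -1 else 1
  function(x) {
    v <- sign * objective(x)
    if (!is.finite(v)) Inf else v
  }
}

finalize_result <- function(raw, maximize, method, config) {
  sign <- if (maximize) -1 else 1
  new_oat_result(
    best_position = raw$best_position,
    best_fitness = sign * raw$best_fitness,
    history = sign * raw$history,
    evaluations = raw$evaluations,
    method = method, config = config, maximize = maximize
  )
}
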