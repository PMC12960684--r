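test_that("population initialization respects bounds, degeneracy and seed", {
  b <- oat_bounds(0, 1, dim = 3)
  X <- withr::with_seed(1, init_population(b, 4))
  expect_equal(dim(X), c(4L, 3L))
  expect_true(all(X >= 0 & X <= 1))

  deg <- oat_bounds(rep(5, 2), rep(5, 2))
  expect_true(all(init_population(deg, 6) == 5))

  X2 <- withr::with_seed(1, init_population(b, 4))
  expect_identical(X, X2)

  expect_error(oat_bounds(c(0, Inf), c(1, 2)), "finite")
  expect_error(oat_bounds(1, 0), "<=")
})

test_that("decay factor has its closed-form endpoints and midpoint", {
  p0 <- dynamic_params(0, 10, 20, 4)
  pT <- dynamic_params(10, 10, 20, 4)
  ph <- dynamic_params(5, 10, 20, 4)
  expect_equal(p0$decay, 1)
  expect_equal(pT$decay, 0)
  expect_equal(ph$decay, 0.875)
  expect_error(dynamic_params(1, 0, 20, 4), ">= 1")
})

test_that("dynamic parameters stay in their stated ranges", {
  for (s in 1:20) {
    p <- withr::with_seed(s, dynamic_params(3, 10, pop_size = 30, dim = 6))
    expect_true(p$m >= 0 && p$m <= 0.5 / 6)
    expect_true(p$e >= 0 && p$e <= 0.5 / 6)
    expect_true(p$L >= 0 && p$L <= 30 / 6)
  }
})

test_that("exploration with zero decay leaves own-branch positions fixed", {
  b <- oat_bounds(-5, 5, dim = 2)
  X <- matrix(c(1, 2, -1, 0, 3, 1, 0.5, -2, 2, 2, -3, 1), 6, 2,
              byrow = TRUE)
  params <- list(decay = 0)
  # pop of 6 -> branch step 1, every index is in the mean branch; with
  # decay 0 the perturbation W vanishes so the move lands on the mean
  got <- exploration_move(3, X, X[1, ], b, decay = 0)
  expect_equal(got, colMeans(X))
})

test_that("exploration branches follow the modular split, hand-checked", {
  b <- oat_bounds(c(-10, -10), c(10, 10))
  X <- matrix(seq(-2, 2, length.out = 60), 30, 2) # pop 30 -> step 3
  best <- c(9, -9)
  r_dim <- c(0.75, 0.25)
  decay <- 0.5
  W <- (decay / pi) * (2 * r_dim - 1) * c(10, 10)
  # i = 3 -> mod 0 -> population mean anchor
  expect_equal(exploration_move(3, X, best, b, decay, r_dim = r_dim),
               colMeans(X) + W)
  # i = 4 -> mod 1 -> best anchor
  expect_equal(exploration_move(4, X, best, b, decay, r_dim = r_dim),
               best + W)
  # i = 5 -> otherwise -> own position
  expect_equal(exploration_move(5, X, best, b, decay, r_dim = r_dim),
               X[5, ] + W)
})

test_that("rolling amplitude at t = 0 equals the upper bound", {
  b <- oat_bounds(c(-1, -2), c(2, 6))
  params <- list(m = 0.1, L = 1, e = 0.1, decay = 1, t = 0, max_iter = 10)
  # A = UB - |UB * 0 * sin(...) / T| = UB regardless of r
  got <- rolling_move(c(0, 0), b, params, eaoo_config(),
                      r = 0.3, r_dim = c(1, 1), levy = c(0, 0))
  # with r_dim = 1 the uniform draw on (-A, A) hits +A = UB exactly
  want <- (0.1 * 0.1 + 1) * c(2, 6) / 2
  expect_equal(got, pmin(pmax(want, b$lower), b$upper))
})

test_that("rolling with zero mass, awn, eccentricity is a pure Levy move", {
  b <- oat_bounds(-5, 5, dim = 2)
  params <- list(m = 0, L = 0, e = 0, decay = 0.8, t = 2, max_iter = 10)
  best <- c(1, -2)
  lv <- c(0.01, 0.02)
  got <- rolling_move(best, b, params, eaoo_config(), r = 0.3,
                      r_dim = c(0.9, 0.1), levy = lv)
  expect_equal(got, best + 0.8 * lv * best)
})

test_that("rolling matches independent arithmetic of the update chain", {
  b <- oat_bounds(c(-50, -50), c(4, 7))
  cfg <- eaoo_config()
  params <- list(m = 0.05, L = 2, e = 0.03, decay = 0.875, t = 5,
                 max_iter = 10)
  r <- 0.37
  r_dim <- c(0.8, 0.3)
  lv <- c(0.004, -0.002)
  best <- c(1.5, -0.5)
  got <- rolling_move(best, b, params, cfg, r = r, r_dim = r_dim,
                      levy = lv)
  ub <- c(4, 7)
  A <- ub - abs(ub * 5 * sin(2 * pi * 0.37) / 10)
  draw <- (2 * r_dim - 1) * A
  R <- (0.05 * 0.03 + 2^2) * draw / 2
  want <- best + R + 0.875 * lv * best
  expect_equal(got, pmin(pmax(want, b$lower), b$upper))
})

test_that("jumping with a launch angle of pi/2 has zero displacement", {
  b <- oat_bounds(-5, 5, dim = 2)
  params <- list(m = 0.1, L = 1, e = 0.1, decay = 0.5, t = 2, max_iter = 10)
  best <- c(1, 1)
  lv <- c(0, 0)
  # r2 = 0.5 -> theta = pi/2 -> sin(2 theta) = 0 -> J = 0
  got <- jumping_move(best, b, params, eaoo_config(), r = 0.1, r2 = 0.5,
                      r_prime = 3, r_dim = c(0.9, 0.2), levy = lv)
  expect_equal(got, best)
})

test_that("air drag stays below one for any admissible draw", {
  # alpha = exp(r'/T)/pi with r' in [0, T] peaks at e/pi < 1
  expect_lt(exp(1) / pi, 1)
  for (rp in seq(0, 10, length.out = 25)) {
    expect_lt(exp(rp / 10) / pi, 1)
  }
})

test_that("jumping matches independent arithmetic of the update chain", {
  b <- oat_bounds(c(-100, -100), c(5, 8))
  cfg <- eaoo_config(gravity = 9.81)
  params <- list(m = 0.04, L = 1, e = 0.02, decay = 0.6, t = 4,
                 max_iter = 20)
  r <- 0.21
  r2 <- 0.8
  rp <- 12
  r_dim <- c(0.65, 0.15)
  lv <- c(0.003, 0.001)
  best <- c(2, -1)
  got <- jumping_move(best, b, params, cfg, r = r, r2 = r2, r_prime = rp,
                      r_dim = r_dim, levy = lv)
  ub <- c(5, 8)
  B <- ub - abs(ub * 4 * cos(2 * pi * 0.21) / 20)
  k <- 0.5 + 0.5 * 0.8
  x <- 3 * 0.8 / 2
  theta <- pi * 0.8
  alpha <- exp(12 / 20) / pi
  J <- 2 * k * x^2 * sin(2 * theta) / (0.04 * 9.81) *
    ((2 * r_dim - 1) * B) / 2 * (1 - alpha)
  want <- best + J + 0.6 * lv * best
  expect_equal(got, pmin(pmax(want, b$lower), b$upper))
})

test_that("differential crossover honors CR extremes and zero scale", {
  b <- oat_bounds(-10, 10, dim = 4)
  X <- withr::with_seed(3, init_population(b, 6))
  V <- X[2, ] + 0.5 * (X[3, ] - X[4, ])
  # CR = 1: the trial is the mutant everywhere
  U1 <- de_crossover(X, 1, 0.5, 1, b, partners = c(2, 3, 4), j_rand = 2,
                     r_cross = rep(0.5, 4))
  expect_equal(U1, pmin(pmax(V, -10), 10))
  # CR = 0: only the forced coordinate comes from the mutant
  U0 <- de_crossover(X, 1, 0.5, 0, b, partners = c(2, 3, 4), j_rand = 3,
                     r_cross = rep(0.5, 4))
  expect_equal(U0[-3], X[1, -3])
  expect_equal(U0[3], min(max(V[3], -10), 10))
  # F = 0: the mutant is the first partner
  Uf <- de_crossover(X, 1, 0, 1, b, partners = c(5, 3, 4), j_rand = 1,
                     r_cross = rep(0, 4))
  expect_equal(Uf, pmin(pmax(X[5, ], -10), 10))
  expect_error(de_crossover(X[1:3, ], 1, 0.5, 0.9, b), ">= 4")
})

test_that("crossover never copies the target row as its mutant base", {
  b <- oat_bounds(0, 1, dim = 2)
  # rows are distinct, so with F = 0 and CR = 1 the trial must equal one
  # of the partner rows, never the target itself
  X <- matrix(seq_len(10) / 10, 5, 2)
  for (s in 1:50) {
    U <- withr::with_seed(s, de_crossover(X, 2, 0, 1, b))
    matches <- which(apply(X, 1, function(row) all(row == U)))
    expect_length(matches, 1L)
    expect_false(matches == 2L)
  }
})

test_that("non-uniform mutation vanishes at the final iteration", {
  b <- oat_bounds(-1, 1, dim = 3)
  x <- c(-0.5, 0, 0.9)
  got <- nonuniform_mutate(x, b, t = 10, max_iter = 10, mutation_prob = 1,
                           nonuniformity = 5, r_gate = rep(0, 3),
                           r_dir = c(0.1, 0.9, 0.1), r_mag = runif(3))
  expect_equal(got, x) # exponent 0 => r^0 = 1 => delta = 0
})

test_that("mutation endpoints: r = 1 keeps, r = 0 jumps to a bound", {
  b <- oat_bounds(-1, 2, dim = 2)
  x <- c(0.5, 0.5)
  keep <- nonuniform_mutate(x, b, 2, 10, 1, 5, r_gate = c(0, 0),
                            r_dir = c(0.1, 0.9), r_mag = c(1, 1))
  expect_equal(keep, x)
  jump <- nonuniform_mutate(x, b, 2, 10, 1, 5, r_gate = c(0, 0),
                            r_dir = c(0.1, 0.9), r_mag = c(0, 0))
  expect_equal(jump, c(2, -1)) # toward upper then lower bound
})

test_that("mutated points never leave the box (property over seeds)", {
  b <- oat_bounds(c(-3, 0, 1), c(2, 5, 1.5))
  for (s in 1:25) {
    x <- withr::with_seed(s, runif(3, b$lower, b$upper))
    got <- withr::with_seed(s + 100,
                            nonuniform_mutate(x, b, 3, 10, 0.8, 5))
    expect_true(all(got >= b$lower & got <= b$upper))
  }
})

test_that("greedy selection keeps ties and rejects non-finite trials", {
  expect_true(greedy_keep(0.7, 0.5))
  expect_true(greedy_keep(0.5, 0.5))
  expect_false(greedy_keep(0.1, 0.9))
  expect_false(greedy_keep(0.1, NaN))
  expect_false(greedy_keep(0.1, Inf))
})
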