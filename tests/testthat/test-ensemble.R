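test_that("simplex projection handles proportions, zeros and negatives", {
  expect_equal(normalize_to_simplex(c(2, 1, 1)), c(0.5, 0.25, 0.25))
  expect_equal(normalize_to_simplex(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(normalize_to_simplex(c(-1, 1, 0)), c(0, 1, 0))
  expect_error(normalize_to_simplex(c(1, NA)), "finite")
})

test_that("weighted aggregation is convex and exact on hand arithmetic", {
  mats <- toy_matrices()
  expect_equal(weighted_aggregate(mats, c(1, 0)), mats[[1]])
  expect_equal(weighted_aggregate(list(mats[[1]], mats[[1]]), c(0.3, 0.7)),
               mats[[1]])
  agg <- weighted_aggregate(mats, c(0.5, 0.5))
  expect_equal(agg[1, ], c(0.6, 0.4)) # (0.8,0.2)/2 + (0.4,0.6)/2
  expect_equal(rowSums(agg), rep(1, 4))
})

test_that("aggregation preserves row-stochasticity for random weights", {
  scen <- simulate_prediction_matrices(n_samples = 40, seed = 2)
  for (s in 1:10) {
    w <- withr::with_seed(s, normalize_to_simplex(runif(3)))
    agg <- weighted_aggregate(scen$matrices, w)
    expect_equal(rowSums(agg), rep(1, 40))
    expect_true(all(agg >= 0))
  }
})

test_that("accuracy fitness agrees with direct counting", {
  mats <- toy_matrices()
  labs <- toy_labels()
  expect_equal(fitness_accuracy(c(1, 0), mats, labs), 1) # model 1 perfect
  # identical matrices make the value weight-independent
  twin <- list(mats[[1]], mats[[1]])
  vals <- sapply(seq(0, 1, 0.25), function(w) {
    fitness_accuracy(c(w, 1 - w), twin, labs)
  })
  expect_true(all(vals == vals[1]))
  expect_error(fitness_accuracy(c(1, 0), mats, integer(0)), "non-empty")
})

test_that("cross-entropy fitness matches closed forms and hand arithmetic", {
  onehot <- rbind(c(1, 0), c(0, 1), c(1, 0))
  labs <- c(1L, 2L, 1L)
  expect_equal(fitness_cross_entropy(c(1, 0), list(onehot, onehot), labs),
               0, tolerance = 1e-9)
  unif <- matrix(1 / 4, 3, 4)
  expect_equal(fitness_cross_entropy(c(0.5, 0.5), list(unif, unif),
                                     c(1L, 2L, 3L)),
               log(4))
  m1 <- rbind(c(0.7, 0.3), c(0.2, 0.8), c(0.5, 0.5))
  m2 <- rbind(c(0.9, 0.1), c(0.4, 0.6), c(0.1, 0.9))
  w <- c(0.25, 0.75)
  p_true <- c(0.25 * 0.7 + 0.75 * 0.9,
              0.25 * 0.8 + 0.75 * 0.6,
              0.25 * 0.5 + 0.75 * 0.1)
  expect_equal(fitness_cross_entropy(w, list(m1, m2), labs),
               -mean(log(p_true)))
})

test_that("weight search matches the exhaustive simplex grid (2 models)", {
  scen <- simulate_prediction_matrices(n_samples = 60, n_models = 2,
                                       accuracy = c(0.8, 0.7), seed = 42)
  gopt <- grid_search_2m(scen$matrices, scen$labels)
  fit <- optimize_weights(scen$matrices, scen$labels,
                          config = quick_eaoo(), seed = 1)
  expect_equal(fit$objective_value, gopt, tolerance = 1e-6)
})

test_that("warm start bounds the search from below", {
  scen <- simulate_prediction_matrices(n_samples = 80, seed = 4)
  base <- max(
    fitness_accuracy(rep(1 / 3, 3), scen$matrices, scen$labels),
    sapply(1:3, function(k) {
      fitness_accuracy(as.numeric(1:3 == k), scen$matrices, scen$labels)
    })
  )
  for (opt in c("eaoo", "de", "ga", "random_search")) {
    entry_cfg <- switch(opt,
      eaoo = quick_eaoo(), de = de_config(12, 10),
      ga = ga_config(12, 10), random_search = random_search_config(12, 10))
    fit <- optimize_weights(scen$matrices, scen$labels, optimizer = opt,
                            config = entry_cfg, seed = 5)
    expect_gte(fit$objective_value, base)
  }
})

test_that("a perfect base model pins the optimum at accuracy one", {
  scen <- simulate_prediction_matrices(n_samples = 50,
                                       accuracy = c(1, 0.5, 0.4),
                                       seed = 11)
  fit <- optimize_weights(scen$matrices, scen$labels,
                          config = quick_eaoo(), seed = 1)
  expect_equal(fit$accuracy, 1)
})

test_that("weights are reproducible under a fixed seed", {
  scen <- simulate_prediction_matrices(n_samples = 50, seed = 8)
  f1 <- optimize_weights(scen$matrices, scen$labels, config = quick_eaoo(),
                         seed = 2)
  f2 <- optimize_weights(scen$matrices, scen$labels, config = quick_eaoo(),
                         seed = 2)
  expect_identical(f1$weights, f2$weights)
})

test_that("cross-entropy objective is also searchable", {
  scen <- simulate_prediction_matrices(n_samples = 60, n_models = 2,
                                       accuracy = c(0.9, 0.6), seed = 13)
  gopt <- grid_search_2m(scen$matrices, scen$labels, "cross_entropy")
  fit <- optimize_weights(scen$matrices, scen$labels,
                          objective = "cross_entropy",
                          config = quick_eaoo(), seed = 1)
  expect_lte(fit$objective_value, gopt + 1e-6)
})

test_that("conventional fusion rules behave as defined", {
  mats <- toy_matrices()
  labs <- toy_labels()
  # identical matrices: every rule reproduces that matrix's decisions
  twin <- list(mats[[1]], mats[[1]], mats[[1]])
  own <- predict_labels(mats[[1]])
  for (rule in c("mean", "product", "hard_vote", "max_rule",
                 "best_single", "fixed_weighted")) {
    expect_equal(fuse_conventional(twin, labs, rule)$predicted, own,
                 info = rule)
  }
  # product rule: a zero entry vetoes the class
  z1 <- rbind(c(0, 1), c(0.5, 0.5))
  z2 <- rbind(c(0.6, 0.4), c(0.5, 0.5))
  pr <- fuse_conventional(list(z1, z2), c(2L, 1L), "product")
  expect_equal(pr$p_final[1, 1], 0)
  # three-model hard vote, argmaxes (1, 1, 2) -> class 1
  h1 <- rbind(c(0.9, 0.1))
  h2 <- rbind(c(0.6, 0.4))
  h3 <- rbind(c(0.2, 0.8))
  hv <- fuse_conventional(list(h1, h2, h3), 1L, "hard_vote")
  expect_equal(hv$predicted, 1L)
  expect_equal(hv$p_final[1, ], c(2 / 3, 1 / 3))
  expect_error(fuse_conventional(mats, labs, "median"))
})

test_that("best-single and fixed-weighted score models by accuracy", {
  mats <- toy_matrices()
  labs <- toy_labels()
  acc <- sapply(mats, function(m) mean(predict_labels(m) == labs))
  bs <- fuse_conventional(mats, labs, "best_single")
  expect_equal(bs$p_final, mats[[which.max(acc)]])
  fw <- fuse_conventional(mats, labs, "fixed_weighted")
  expect_equal(fw$weights, acc / sum(acc))
})

test_that("argmax decisions break ties toward the lowest class", {
  P <- rbind(c(0.6, 0.4), c(0.5, 0.5), c(0, 1))
  expect_equal(predict_labels(P), c(1L, 1L, 2L))
})

test_that("ensemble results tidy, glance and plot", {
  scen <- simulate_prediction_matrices(n_samples = 30, seed = 3)
  fit <- optimize_weights(scen$matrices, scen$labels, config = quick_eaoo(),
                          seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 30)
  expect_true(all(c("sample", "label", "predicted", "correct",
                    "p_1") %in% names(td)))
  expect_equal(mean(td$correct), fit$accuracy)
  gl <- glance(fit)
  expect_equal(gl$rule, "optimized")
  expect_s3_class(autoplot(fit), "ggplot")
  hv <- fuse_conventional(scen$matrices, scen$labels, "hard_vote")
  expect_error(autoplot(hv), "no weight representation")
})

test_that("malformed prediction inputs are rejected", {
  mats <- toy_matrices()
  expect_error(weighted_aggregate(list(mats[[1]], mats[[2]][1:3, ]),
                                  c(0.5, 0.5)),
               "same dimensions")
  expect_error(fitness_accuracy(c(1, 0), mats, c(1L, 2L)), "align")
  expect_error(fitness_accuracy(c(1, 0), mats, c(1L, 2L, 3L, 0L)), "1..C")
  expect_error(optimize_weights(mats[1], toy_labels()), ">= 2 models")
})
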