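test_that("position binarization applies the threshold and repair rules", {
  expect_identical(binarize_position(c(0.7, 0.3)), c(1L, 0L))
  expect_identical(binarize_position(c(0.5, 0.5)), c(1L, 1L))  # >= rule
  rep_mask <- binarize_position(c(0.1, 0.4, 0.2))
  expect_identical(rep_mask, c(0L, 1L, 0L))   # argmax repair, exactly one 1
  none <- binarize_position(c(0.1, 0.4), repair = "none")
  expect_identical(none, c(0L, 0L))
})

test_that("fitness composes accuracy with the removed-channel bonus", {
  m8 <- c(rep(1L, 8), rep(0L, 44))
  f <- fitness_value(86.5, m8)
  expect_equal(f$fitness, 86.94)              # 86.50 + 0.01 * 44
  expect_equal(f$n_zeros + f$n_selected, 52L)

  m16 <- c(rep(1L, 16), rep(0L, 36))
  expect_equal(fitness_value(87, m16)$fitness, 87.36)
  expect_equal(fitness_value(77.7, rep(1L, 52))$fitness, 77.7)

  # equal accuracy, 8 vs 12 selected of 20: difference exactly 0.04
  fa <- fitness_value(80, c(rep(1L, 8), rep(0L, 12)))
  fb <- fitness_value(80, c(rep(1L, 12), rep(0L, 8)))
  expect_equal(fa$fitness - fb$fitness, 0.04)

  expect_error(fitness_value(101, m8), "\\[0, 100\\]")
})

test_that("fitness closures memoize per mask", {
  calls <- 0L
  fn <- surrogate_fitness_function(function(mask) {
    calls <<- calls + 1L
    70
  })
  r1 <- fn(c(1L, 0L, 1L))
  r2 <- fn(c(1L, 0L, 1L))
  expect_identical(r1, r2)
  expect_equal(calls, 1L)               # second call was a cache hit
  fn(c(1L, 1L, 1L))
  expect_equal(calls, 2L)
})

test_that("GA generation implements crossover, mutation, elitism", {
  cfg <- optimizer_config(N = 4L, max_iter = 1L, crossover_rate = 1,
                          mutation_rate = 0)
  pop <- rbind(rep(1L, 4), rep(0L, 4), rep(1L, 4), rep(0L, 4))
  withr::with_seed(1, nxt <- ga_generation(pop, c(4, 1, 4, 1), cfg))
  expect_identical(nxt[1, ], rep(1L, 4))      # elite survives unchanged
  for (i in 2:4) {                            # children are prefix/suffix mixes
    runs <- rle(nxt[i, ])$lengths
    expect_lte(length(runs), 2L)
  }

  # with both rates zero the population is a re-sampling of existing rows
  cfg0 <- optimizer_config(N = 4L, max_iter = 1L, crossover_rate = 0,
                           mutation_rate = 0)
  pop2 <- rbind(c(1L, 0L, 1L), c(0L, 1L, 0L), c(1L, 1L, 0L), c(0L, 0L, 1L))
  withr::with_seed(2, nxt2 <- ga_generation(pop2, c(3, 2, 1, 1), cfg0))
  keys <- apply(pop2, 1, paste, collapse = "")
  expect_true(all(apply(nxt2, 1, paste, collapse = "") %in% keys))

  # elitism: chained generations never lose the best surrogate fitness
  fn <- surrogate_fitness_function(surrogate_accuracy(c(1, 0, 1, 0)))
  withr::with_seed(3, {
    pop3 <- fnirsopt:::random_population(8L, 4L)
    cfg3 <- optimizer_config(N = 8L, max_iter = 1L)
    best <- -Inf
    for (g in 1:10) {
      fits <- sapply(seq_len(8), function(i) fn(pop3[i, ])$fitness)
      expect_gte(max(fits), best)
      best <- max(best, max(fits))
      pop3 <- ga_generation(pop3, fits, cfg3)
    }
  })
})

test_that("PSO updates obey the velocity and position bounds", {
  cfg <- optimizer_config(N = 4L, max_iter = 1L)
  fn <- surrogate_fitness_function(surrogate_accuracy(c(1, 0, 1, 0, 1)))
  withr::with_seed(4, sw <- fnirsopt:::init_swarm(4L, 5L, cfg, fn))

  # x = pbest = gbest: attraction terms vanish, v = inertia * v
  sw0 <- sw
  sw0$x[1, ] <- sw0$pbest_x[1, ] <- sw0$gbest_x
  v_before <- sw0$v[1, ]
  withr::with_seed(5, sw1 <- pso_generation(sw0, cfg, fn))
  # attraction terms vanish, and 0.9 * v stays inside the clamp
  expect_equal(unname(sw1$v[1, ]), unname(cfg$inertia * v_before),
               tolerance = 1e-12)

  # bounds hold over repeated generations
  for (i in 1:10) {
    sw <- pso_generation(sw, cfg, fn)
    expect_true(all(sw$v >= -0.5 & sw$v <= 0.5))
    expect_true(all(sw$x >= 0 & sw$x <= 1))
    expect_true(all(rowSums(sw$masks) >= 1))
  }
})

test_that("velocity clamp caps raw updates at the bound", {
  cfg <- optimizer_config(N = 4L, max_iter = 1L)
  fn <- surrogate_fitness_function(surrogate_accuracy(c(1, 0, 1)))
  withr::with_seed(6, sw <- fnirsopt:::init_swarm(4L, 3L, cfg, fn))
  # force a large attraction: x at 0, pbest and gbest at 1, zero inertia term
  sw$v[] <- 0
  sw$x[2, ] <- 0
  sw$pbest_x[2, ] <- 1
  sw$gbest_x <- rep(1, 3)
  sw2 <- pso_generation(sw, cfg, fn)
  expect_true(all(sw2$v <= 0.5 & sw2$v >= -0.5))
  expect_true(all(sw2$x[2, ] <= 1))
})

test_that("exhaustive search is an exact oracle with the stated tie-breaks", {
  # only channel 1 informative
  fn <- surrogate_fitness_function(function(mask) 50 + 30 * mask[1])
  bf <- brute_force_best(fitness_fn = fn, n_channels = 2L)
  expect_identical(bf$mask, c(1L, 0L))

  # single channel: only candidate
  fn1 <- surrogate_fitness_function(function(mask) 50)
  expect_identical(brute_force_best(fitness_fn = fn1, n_channels = 1L)$mask, 1L)

  # accuracy tie between {1} and {1,2}: penalty favors fewer channels
  fn2 <- surrogate_fitness_function(function(mask)
    if (mask[1] == 1L) 80 else 10)
  expect_identical(brute_force_best(fitness_fn = fn2, n_channels = 2L)$mask,
                   c(1L, 0L))

  expect_error(brute_force_best(fitness_fn = fn, n_channels = 17L),
               "infeasible")
})

test_that("all runners produce valid, monotone, seed-reproducible results", {
  target <- c(1, 0, 1, 0, 1)
  for (m in all_methods) {
    r1 <- run_optimizer(m, fitness_fn =
                          surrogate_fitness_function(surrogate_accuracy(target)),
                        n_channels = 5L,
                        config = optimizer_config(N = 10L, max_iter = 12L,
                                                  seed = 31L))
    r2 <- run_optimizer(m, fitness_fn =
                          surrogate_fitness_function(surrogate_accuracy(target)),
                        n_channels = 5L,
                        config = optimizer_config(N = 10L, max_iter = 12L,
                                                  seed = 31L))
    expect_identical(r1$best_mask, r2$best_mask)
    expect_identical(r1$trace, r2$trace)
    expect_length(r1$trace, 12L)
    expect_false(is.unsorted(r1$trace))
    expect_gte(sum(r1$best_mask), 1L)
    expect_identical(r1$selected_channels, which(r1$best_mask == 1L))
    # recorded accuracy and zeros recompose to the fitness exactly
    expect_equal(r1$best_fitness,
                 r1$best_accuracy + 0.01 * (5 - r1$n_selected))
  }
})

test_that("parallel hybrids partition the ranked population as specified", {
  # variant I: ceil(N/2) to GA; variant II: ceil(N/5) to PSO
  expect_equal(ceiling(50 / 2), 25)
  counts <- local({
    cfg <- optimizer_config(N = 10L, max_iter = 3L, seed = 2L)
    fn <- surrogate_fitness_function(surrogate_accuracy(c(1, 0, 1, 0)))
    r <- run_pgapso("I", fitness_fn = fn, n_channels = 4L, config = cfg)
    r
  })
  expect_s3_class(counts, "run_result")

  # the partition arithmetic itself
  N <- 50L
  expect_equal(length(seq_len(ceiling(N / 2))), 25L)        # variant I to GA
  expect_equal(length(seq_len(ceiling(N / 5))), 10L)        # variant II to PSO
  expect_equal(N - ceiling(N / 5), 40L)
})

test_that("the SVM-backed fitness drives a GA toward informative channels", {
  sep <- separable_features(n_per_class = 10L, d = 4L, seed = 7L)
  cv <- cv_config(k = 5L, fold_seed = 1L, C = 1)
  fit <- evaluate_mask(rep(1L, 4), sep$features, sep$labels, cv)
  expect_equal(fit$accuracy, 100)
  expect_equal(fit$fitness, 100)        # zero removed channels

  r <- run_ga(sep$features, sep$labels, cv,
              optimizer_config(N = 8L, max_iter = 5L, seed = 1L))
  expect_equal(r$best_accuracy, 100)
  expect_false(is.unsorted(r$trace))
})
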