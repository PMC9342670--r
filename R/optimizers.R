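# The seven binary channel-selection metaheuristics. All of them optimize
# the same penalized objective (accuracy + 0.01 * removed channels) over
# non-empty binary masks of length D, share one memoized fitness closure
# per run, and are bit-reproducible from optimizer_config()$seed.

resolve_fitness <- function(features, labels, cv, config, fitness_fn,
                            n_channels) {
  if (is.null(fitness_fn)) {
    if (is.null(features)) {
      stop_("supply either features + labels or a fitness_fn")
    }
    fitness_fn <- mask_fitness_function(features, labels, cv, config)
    n_channels <- length(features$channel_ids)
    ids <- features$channel_ids
  } else {
    if (is.null(n_channels)) stop_("n_channels is required with fitness_fn")
    ids <- seq_len(n_channels)
  }
  list(fn = fitness_fn, D = as.integer(n_channels), ids = as.integer(ids))
}

rank_order <- function(fitvals, n_selected) {
  order(-fitvals, n_selected, seq_along(fitvals))
}

fit_values <- function(fitlist) {
  vapply(fitlist, function(f) f$fitness, numeric(1))
}

sel_counts <- function(fitlist) {
  vapply(fitlist, function(f) f$n_selected, numeric(1))
}

update_best <- function(best, masks, fitlist) {
  for (i in seq_along(fitlist)) {
    if (is.null(best$fit) ||
        mask_better(fitlist[[i]], masks[i, ], best$fit, best$mask)) {
      best$fit <- fitlist[[i]]
      best$mask <- masks[i, ]
    }
  }
  best
}

new_run_result <- function(method, best, trace, config, rf) {
  cache <- attr(rf$fn, "cache")
  structure(list(
    method = method,
    best_mask = as.integer(best$mask),
    best_fitness = best$fit$fitness,
    best_accuracy = best$fit$accuracy,
    selected_channels = rf$ids[best$mask == 1L],
    n_selected = best$fit$n_selected,
    trace = trace,
    n_evaluations = if (!is.null(cache)) get(".n_evals", cache) else NA_integer_,
    seed = config$seed,
    config = config), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("run_result [%s]: fitness %.4f, accuracy %.2f%%, %d channels\n",
              x$method, x$best_fitness, x$best_accuracy, x$n_selected))
  cat("  selected:", paste(x$selected_channels, collapse = " "), "\n")
  invisible(x)
}

random_population <- function(N, D) {
  pop <- matrix(as.integer(stats::runif(N * D) < 0.5), N, D)
  for (i in seq_len(N)) {
    if (!any(pop[i, ] == 1L)) pop[i, sample.int(D, 1L)] <- 1L
  }
  pop
}

binarize_rows <- function(x, config, repair = "argmax") {
  out <- matrix(0L, nrow(x), ncol(x))
  for (i in seq_len(nrow(x))) {
    out[i, ] <- binarize_position(x[i, ], config$threshold, repair)
  }
  out
}

eval_rows <- function(masks, fitness_fn) {
  lapply(seq_len(nrow(masks)), function(i) fitness_fn(masks[i, ]))
}

#' One genetic-algorithm generation
#'
#' Fitness-proportionate (roulette) parent selection, single-point
#' crossover with probability `crossover_rate`, per-bit mutation with
#' probability `mutation_rate`, and elitism of one: the best chromosome
#' survives unchanged in the first row of the output. Offspring repaired
#' to keep at least one selected channel (one random bit set). Falls back
#' to uniform parent selection when all fitnesses are zero or equal.
#'
#' @param population Integer 0/1 matrix, N x D, one chromosome per row.
#' @param fitnesses Numeric fitness per row (non-negative).
#' @param config An [optimizer_config()].
#' @return An N x D chromosome matrix.
#' @export
ga_generation <- function(population, fitnesses, config = optimizer_config()) {
  N <- nrow(population)
  D <- ncol(population)
  ord <- rank_order(fitnesses, rowSums(population))
  elite <- population[ord[1L], ]
  w <- fitnesses
  if (sum(w) <= 0 || all(w == w[1L])) w <- rep(1, N)
  children <- matrix(0L, N - 1L, D)
  i <- 1L
  while (i <= N - 1L) {
    pa <- population[sample.int(N, 1L, prob = w), ]
    pb <- population[sample.int(N, 1L, prob = w), ]
    if (D >= 2L && stats::runif(1) < config$crossover_rate) {
      cut <- sample.int(D - 1L, 1L)
      off <- list(c(pa[seq_len(cut)], pb[(cut + 1L):D]),
                  c(pb[seq_len(cut)], pa[(cut + 1L):D]))
    } else {
      off <- list(pa, pb)
    }
    for (ch in off) {
      if (i > N - 1L) break
      flip <- stats::runif(D) < config$mutation_rate
      ch[flip] <- 1L - ch[flip]
      if (!any(ch == 1L)) ch[sample.int(D, 1L)] <- 1L
      children[i, ] <- ch
      i <- i + 1L
    }
  }
  rbind(matrix(elite, nrow = 1L), children)
}

# --- PSO swarm state -------------------------------------------------------

init_swarm <- function(N, D, config, fitness_fn) {
  x <- matrix(stats::runif(N * D), N, D)
  v <- matrix(stats::runif(N * D, -config$v_max, config$v_max), N, D)
  masks <- binarize_rows(x, config)
  fits <- eval_rows(masks, fitness_fn)
  sw <- list(x = x, v = v, masks = masks, fits = fits,
             pbest_x = x, pbest_mask = masks, pbest_fit = fits,
             gbest_x = NULL, gbest_mask = NULL, gbest_fit = NULL)
  refresh_gbest(sw)
}

refresh_gbest <- function(sw) {
  for (i in seq_along(sw$pbest_fit)) {
    if (is.null(sw$gbest_fit) ||
        mask_better(sw$pbest_fit[[i]], sw$pbest_mask[i, ],
                    sw$gbest_fit, sw$gbest_mask)) {
      sw$gbest_fit <- sw$pbest_fit[[i]]
      sw$gbest_mask <- sw$pbest_mask[i, ]
      sw$gbest_x <- sw$pbest_x[i, ]
    }
  }
  sw
}

update_pbest <- function(sw, rows = seq_along(sw$fits)) {
  for (i in rows) {
    if (mask_better(sw$fits[[i]], sw$masks[i, ],
                    sw$pbest_fit[[i]], sw$pbest_mask[i, ])) {
      sw$pbest_fit[[i]] <- sw$fits[[i]]
      sw$pbest_mask[i, ] <- sw$masks[i, ]
      sw$pbest_x[i, ] <- sw$x[i, ]
    }
  }
  refresh_gbest(sw)
}

# Velocity/position update on the given rows against the swarm's gbest:
# v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x), v clamped to +-v_max,
# x <- x + v clamped to [0, 1]; positions re-binarized and re-evaluated.
pso_step_rows <- function(sw, rows, config, fitness_fn) {
  m <- length(rows)
  D <- ncol(sw$x)
  r1 <- matrix(stats::runif(m * D), m, D)
  r2 <- matrix(stats::runif(m * D), m, D)
  g <- matrix(sw$gbest_x, m, D, byrow = TRUE)
  v <- config$inertia * sw$v[rows, , drop = FALSE] +
    config$c1 * r1 * (sw$pbest_x[rows, , drop = FALSE] -
                        sw$x[rows, , drop = FALSE]) +
    config$c2 * r2 * (g - sw$x[rows, , drop = FALSE])
  v <- pmin(pmax(v, -config$v_max), config$v_max)
  x <- pmin(pmax(sw$x[rows, , drop = FALSE] + v, 0), 1)
  sw$v[rows, ] <- v
  sw$x[rows, ] <- x
  sw$masks[rows, ] <- binarize_rows(x, config)
  sw$fits[rows] <- eval_rows(sw$masks[rows, , drop = FALSE], fitness_fn)
  update_pbest(sw, rows)
}

#' One particle-swarm generation
#'
#' Applies the inertia-weighted velocity update with fresh uniform random
#' coefficients per dimension, clamps velocities to `[-v_max, v_max]` and
#' positions to `[0, 1]`, re-binarizes, re-evaluates, and updates
#' pbest/gbest.
#'
#' @param swarm Swarm state as built by the runners (list with `x`, `v`,
#'   `masks`, `fits`, `pbest_*`, `gbest_*`).
#' @param config An [optimizer_config()].
#' @param fitness_fn A `mask -> fitness_result` function.
#' @return The updated swarm state.
#' @export
pso_generation <- function(swarm, config, fitness_fn) {
  pso_step_rows(swarm, seq_len(nrow(swarm$x)), config, fitness_fn)
}

# --- Runners ---------------------------------------------------------------

#' Run a channel-selection optimizer
#'
#' `run_optimizer()` dispatches on `method`; the `run_*` functions run one
#' algorithm each. Every runner seeds its own RNG stream from
#' `config$seed` (restoring the caller's RNG state), iterates for
#' `config$max_iter` generations, and returns a `run_result` with the best
#' mask found, its fitness and accuracy, the 1-based selected channel ids,
#' and the per-generation best-so-far fitness trace (non-decreasing,
#' length `max_iter`).
#'
#' @param method One of `"ga"`, `"pso"`, `"pgapso1"`, `"pgapso2"`,
#'   `"pgapso3"`, `"spsoga"`, `"sgapso"`.
#' @param features A [feature_matrix()] (or NULL when `fitness_fn` is
#'   given).
#' @param labels 0/1 group labels.
#' @param cv A [cv_config()].
#' @param config An [optimizer_config()].
#' @param fitness_fn Optional `mask -> fitness_result` function replacing
#'   the SVM fitness (see [surrogate_fitness_function()]); requires
#'   `n_channels`.
#' @param n_channels Mask length D when `fitness_fn` is given.
#' @return An object of class `run_result`.
#' @export
run_optimizer <- function(method = c("ga", "pso", "pgapso1", "pgapso2",
                                     "pgapso3", "spsoga", "sgapso"),
                          features = NULL, labels = NULL, cv = cv_config(),
                          config = optimizer_config(), fitness_fn = NULL,
                          n_channels = NULL) {
  method <- match.arg(method)
  runner <- switch(method,
    ga = run_ga, pso = run_pso,
    pgapso1 = function(...) run_pgapso("I", ...),
    pgapso2 = function(...) run_pgapso("II", ...),
    pgapso3 = function(...) run_pgapso("III", ...),
    spsoga = run_spsoga, sgapso = run_sgapso)
  runner(features = features, labels = labels, cv = cv, config = config,
         fitness_fn = fitness_fn, n_channels = n_channels)
}

#' @rdname run_optimizer
#' @export
run_ga <- function(features = NULL, labels = NULL, cv = cv_config(),
                   config = optimizer_config(), fitness_fn = NULL,
                   n_channels = NULL) {
  rf <- resolve_fitness(features, labels, cv, config, fitness_fn, n_channels)
  local_seed(config$seed, {
    pop <- random_population(config$N, rf$D)
    fits <- eval_rows(pop, rf$fn)
    best <- update_best(list(fit = NULL, mask = NULL), pop, fits)
    trace <- numeric(config$max_iter)
    for (g in seq_len(config$max_iter)) {
      pop <- ga_generation(pop, fit_values(fits), config)
      fits <- eval_rows(pop, rf$fn)
      best <- update_best(best, pop, fits)
      trace[g] <- best$fit$fitness
    }
    new_run_result("ga", best, trace, config, rf)
  })
}

#' @rdname run_optimizer
#' @export
run_pso <- function(features = NULL, labels = NULL, cv = cv_config(),
                    config = optimizer_config(), fitness_fn = NULL,
                    n_channels = NULL) {
  rf <- resolve_fitness(features, labels, cv, config, fitness_fn, n_channels)
  local_seed(config$seed, {
    sw <- init_swarm(config$N, rf$D, config, rf$fn)
    trace <- numeric(config$max_iter)
    for (g in seq_len(config$max_iter)) {
      sw <- pso_generation(sw, config, rf$fn)
      trace[g] <- sw$gbest_fit$fitness
    }
    new_run_result("pso", list(fit = sw$gbest_fit, mask = sw$gbest_mask),
                   trace, config, rf)
  })
}

# GA sub-step on a subset of the hybrid population: evolve their masks one
# GA generation, then reset those slots' continuous state to the new
# chromosomes (position = bits, velocity 0) so a later PSO assignment has
# valid state.
hybrid_ga_rows <- function(sw, rows, config, fitness_fn) {
  if (length(rows) < 2L) return(sw)
  sub <- sw$masks[rows, , drop = FALSE]
  newmasks <- ga_generation(sub, fit_values(sw$fits[rows]), config)
  sw$masks[rows, ] <- newmasks
  sw$x[rows, ] <- newmasks
  sw$v[rows, ] <- 0
  sw$fits[rows] <- eval_rows(newmasks, fitness_fn)
  update_pbest(sw, rows)
}

#' @rdname run_optimizer
#' @param variant Parallel-hybrid variant: `"I"` (best 50\% of the ranked
#'   population to GA, rest to PSO), `"II"` (best 20\% to PSO, rest to GA)
#'   or `"III"` (each individual assigned to GA or PSO by a fair coin).
#' @export
run_pgapso <- function(variant = c("I", "II", "III"), features = NULL,
                       labels = NULL, cv = cv_config(),
                       config = optimizer_config(), fitness_fn = NULL,
                       n_channels = NULL) {
  variant <- match.arg(variant)
  rf <- resolve_fitness(features, labels, cv, config, fitness_fn, n_channels)
  local_seed(config$seed, {
    sw <- init_swarm(config$N, rf$D, config, rf$fn)
    trace <- numeric(config$max_iter)
    N <- config$N
    for (g in seq_len(config$max_iter)) {
      ranked <- rank_order(fit_values(sw$fits), sel_counts(sw$fits))
      if (variant == "I") {
        ga_rows <- ranked[seq_len(ceiling(N / 2))]
        pso_rows <- setdiff(ranked, ga_rows)
      } else if (variant == "II") {
        pso_rows <- ranked[seq_len(ceiling(N / 5))]
        ga_rows <- setdiff(ranked, pso_rows)
      } else {
        coin <- stats::runif(N) < 0.5
        ga_rows <- which(coin)
        pso_rows <- which(!coin)
      }
      sw <- hybrid_ga_rows(sw, ga_rows, config, rf$fn)
      if (length(pso_rows)) sw <- pso_step_rows(sw, pso_rows, config, rf$fn)
      trace[g] <- sw$gbest_fit$fitness
    }
    new_run_result(paste0("pgapso", match(variant, c("I", "II", "III"))),
                   list(fit = sw$gbest_fit, mask = sw$gbest_mask),
                   trace, config, rf)
  })
}

#' @rdname run_optimizer
#' @export
run_spsoga <- function(features = NULL, labels = NULL, cv = cv_config(),
                       config = optimizer_config(), fitness_fn = NULL,
                       n_channels = NULL) {
  rf <- resolve_fitness(features, labels, cv, config, fitness_fn, n_channels)
  local_seed(config$seed, {
    sw <- init_swarm(config$N, rf$D, config, rf$fn)
    trace <- numeric(config$max_iter)
    N <- config$N
    half <- N %/% 2L
    for (g in seq_len(config$max_iter)) {
      # keep the best half, discard the rest
      ranked <- rank_order(fit_values(sw$fits), sel_counts(sw$fits))
      keep <- ranked[seq_len(half)]
      sw <- pso_step_rows(sw, keep, config, rf$fn)
      # GA on the binarized pbest chromosomes of the kept half
      pb_masks <- binarize_rows(sw$pbest_x[keep, , drop = FALSE], config)
      pb_fits <- fit_values(eval_rows(pb_masks, rf$fn))
      offspring <- ga_generation(pb_masks, pb_fits, config)
      off_fits <- eval_rows(offspring, rf$fn)
      # next population = kept particles + offspring as fresh individuals
      drop_rows <- setdiff(seq_len(N), keep)
      sw$masks[drop_rows, ] <- offspring
      sw$x[drop_rows, ] <- offspring
      sw$v[drop_rows, ] <- 0
      sw$fits[drop_rows] <- off_fits
      sw$pbest_x[drop_rows, ] <- offspring
      sw$pbest_mask[drop_rows, ] <- offspring
      sw$pbest_fit[drop_rows] <- off_fits
      sw <- refresh_gbest(sw)
      trace[g] <- sw$gbest_fit$fitness
    }
    new_run_result("spsoga", list(fit = sw$gbest_fit, mask = sw$gbest_mask),
                   trace, config, rf)
  })
}

#' Build a genetic-learning exemplar for one particle
#'
#' Per-dimension uniform crossover of the particle's pbest with the swarm
#' gbest (fair coin per dimension), then per-dimension mutation with
#' probability `mutation_rate` (the mutated dimension is redrawn uniformly
#' in [0, 1]).
#'
#' @param pbest,gbest Numeric position vectors.
#' @param config An [optimizer_config()].
#' @return Numeric exemplar position vector.
#' @export
ga_exemplar <- function(pbest, gbest, config = optimizer_config()) {
  take_g <- stats::runif(length(pbest)) < 0.5
  e <- ifelse(take_g, gbest, pbest)
  mut <- stats::runif(length(e)) < config$mutation_rate
  if (any(mut)) e[mut] <- stats::runif(sum(mut))
  e
}

#' @rdname run_optimizer
#' @details `run_sgapso()` follows the genetic-learning scheme: GA
#'   operators act on pbest/gbest to construct a per-particle exemplar,
#'   accepted only if its binarization out-scores the old exemplar's
#'   (tournament), and the PSO velocity update uses the single attraction
#'   term `c1 r (exemplar - x)` in place of the separate cognitive and
#'   social terms.
#' @export
run_sgapso <- function(features = NULL, labels = NULL, cv = cv_config(),
                       config = optimizer_config(), fitness_fn = NULL,
                       n_channels = NULL) {
  rf <- resolve_fitness(features, labels, cv, config, fitness_fn, n_channels)
  local_seed(config$seed, {
    sw <- init_swarm(config$N, rf$D, config, rf$fn)
    N <- config$N
    D <- rf$D
    ex_x <- sw$pbest_x
    ex_fit <- sw$pbest_fit
    trace <- numeric(config$max_iter)
    for (g in seq_len(config$max_iter)) {
      for (i in seq_len(N)) {
        trial <- ga_exemplar(sw$pbest_x[i, ], sw$gbest_x, config)
        tmask <- binarize_position(trial, config$threshold, "argmax")
        tfit <- rf$fn(tmask)
        emask <- binarize_position(ex_x[i, ], config$threshold, "argmax")
        if (mask_better(tfit, tmask, ex_fit[[i]], emask)) {
          ex_x[i, ] <- trial
          ex_fit[[i]] <- tfit
        }
        r <- stats::runif(D)
        v <- config$inertia * sw$v[i, ] + config$c1 * r * (ex_x[i, ] - sw$x[i, ])
        v <- pmin(pmax(v, -config$v_max), config$v_max)
        x <- pmin(pmax(sw$x[i, ] + v, 0), 1)
        sw$v[i, ] <- v
        sw$x[i, ] <- x
        sw$masks[i, ] <- binarize_position(x, config$threshold, "argmax")
        sw$fits[[i]] <- rf$fn(sw$masks[i, ])
      }
      sw <- update_pbest(sw)
      trace[g] <- sw$gbest_fit$fitness
    }
    new_run_result("sgapso", list(fit = sw$gbest_fit, mask = sw$gbest_mask),
                   trace, config, rf)
  })
}
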