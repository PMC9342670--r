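#' Optimizer configuration
#'
#' Shared settings for all seven channel-selection metaheuristics.
#'
#' @param N Population / swarm size (even, >= 4; default 50).
#' @param max_iter Number of generations (default 200).
#' @param crossover_rate GA single-point crossover probability (default
#'   0.8).
#' @param mutation_rate GA per-bit mutation probability (default 0.01).
#' @param inertia PSO inertia weight, fixed over all iterations (default
#'   0.9).
#' @param c1,c2 PSO cognitive and social acceleration coefficients
#'   (default 2, 2).
#' @param v_max Velocity bound; velocities are clamped to `[-v_max, v_max]`
#'   (default 0.5).
#' @param threshold Binarization threshold on positions (default 0.5; a
#'   position >= threshold selects the channel).
#' @param channel_penalty Weight of the removed-channel bonus in the
#'   fitness (default 0.01): fitness = accuracy(%) + penalty * n_zeros,
#'   a tie-breaker favoring fewer channels at equal accuracy.
#' @param seed Integer RNG seed; every run is bit-reproducible from it.
#' @return An object of class `optimizer_config`.
#' @export
optimizer_config <- function(N = 50L, max_iter = 200L, crossover_rate = 0.8,
                             mutation_rate = 0.01, inertia = 0.9,
                             c1 = 2, c2 = 2, v_max = 0.5, threshold = 0.5,
                             channel_penalty = 0.01, seed = 1L) {
  if (!is_count(N) || N < 4L || N %% 2L != 0L) {
    stop_("N must be an even integer >= 4")
  }
  if (!is_count(max_iter) || max_iter < 1L) stop_("max_iter must be >= 1")
  for (r in c(crossover_rate, mutation_rate)) {
    if (r < 0 || r > 1) stop_("rates must lie in [0, 1]")
  }
  if (v_max <= 0) stop_("v_max must be positive")
  structure(list(N = as.integer(N), max_iter = as.integer(max_iter),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate, inertia = inertia,
                 c1 = c1, c2 = c2, v_max = v_max, threshold = threshold,
                 channel_penalty = channel_penalty, seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Binarize a continuous position vector into a channel mask
#'
#' A bit is 1 (channel selected) iff the position component is at or above
#' the threshold. An all-zero result is repaired so that every mask keeps
#' at least one channel.
#'
#' @param x Numeric position vector with entries in [0, 1].
#' @param threshold Binarization threshold (default 0.5).
#' @param repair Repair rule for an all-zero mask: `"argmax"` sets the bit
#'   of the largest position component (PSO rule), `"random"` sets one
#'   uniformly random bit (GA rule), `"none"` returns the all-zero mask.
#' @return Integer 0/1 vector of the same length.
#' @export
binarize_position <- function(x, threshold = 0.5,
                              repair = c("argmax", "random", "none")) {
  repair <- match.arg(repair)
  bits <- as.integer(x >= threshold)
  if (!any(bits == 1L)) {
    if (repair == "argmax") {
      bits[which.max(x)] <- 1L
    } else if (repair == "random") {
      bits[sample.int(length(bits), 1L)] <- 1L
    }
  }
  bits
}

#' Fitness of a channel mask at a given accuracy
#'
#' fitness = accuracy (percent) + weight * (number of removed channels).
#' The removed-channel term acts as a tie-breaker: at the default weight
#' 0.01 it favors the smaller channel set among masks with equal
#' cross-validated accuracy.
#'
#' @param accuracy Classification accuracy on the 0-100 scale.
#' @param mask Binary channel mask.
#' @param weight Penalty weight (default 0.01).
#' @return List of class `fitness_result`: `fitness`, `accuracy`,
#'   `n_zeros`, `n_selected`.
#' @export
fitness_value <- function(accuracy, mask, weight = 0.01) {
  if (!is.numeric(accuracy) || accuracy < 0 || accuracy > 100) {
    stop_("accuracy must lie in [0, 100] (got %s)", format(accuracy))
  }
  mask <- as.integer(mask)
  n_sel <- sum(mask == 1L)
  n_zero <- length(mask) - n_sel
  structure(list(fitness = accuracy + weight * n_zero, accuracy = accuracy,
                 n_zeros = n_zero, n_selected = n_sel),
            class = "fitness_result")
}

# Memoizing fitness closure over an accuracy function. The cache
# environment (key = bit string) is attached as attribute "cache" and holds
# counters n_calls (total) and n_evals (actual accuracy evaluations).
make_fitness_closure <- function(accuracy_fn, weight) {
  cache <- new.env(parent = emptyenv())
  assign(".n_calls", 0L, cache)
  assign(".n_evals", 0L, cache)
  fn <- function(mask) {
    mask <- as.integer(mask)
    assign(".n_calls", get(".n_calls", cache) + 1L, cache)
    key <- paste0("m", paste(mask, collapse = ""))
    if (!is.null(cache[[key]])) return(cache[[key]])
    assign(".n_evals", get(".n_evals", cache) + 1L, cache)
    res <- fitness_value(accuracy_fn(mask), mask, weight)
    cache[[key]] <- res
    res
  }
  attr(fn, "cache") <- cache
  fn
}

#' Build the cross-validated SVM fitness function for an optimization run
#'
#' Fixes one fold partition from `cv$fold_seed`, shared by every fitness
#' evaluation of the run, so that fitness differences between masks are not
#' confounded with fold noise. Results are memoized per mask.
#'
#' @param features A [feature_matrix()].
#' @param labels 0/1 group labels.
#' @param cv A [cv_config()] (its `C`/`gamma` are used as-is; tune them
#'   once on the all-channel matrix with [tune_hyperparameters()] first).
#' @param config An [optimizer_config()] (supplies the penalty weight).
#' @return A function `mask -> fitness_result`.
#' @export
mask_fitness_function <- function(features, labels, cv = cv_config(),
                                  config = optimizer_config()) {
  labels <- as.integer(labels)
  folds <- stratified_folds(labels, cv$k, cv$fold_seed, cv$stratified)
  make_fitness_closure(function(mask) {
    cv_accuracy(features, labels, mask, cv, folds = folds)$accuracy
  }, config$channel_penalty)
}

#' @rdname mask_fitness_function
#' @param accuracy_fn A deterministic function `mask -> accuracy` on the
#'   0-100 scale (a surrogate objective, e.g. for optimizer testing).
#' @param weight Penalty weight.
#' @export
surrogate_fitness_function <- function(accuracy_fn, weight = 0.01) {
  make_fitness_closure(accuracy_fn, weight)
}

#' Evaluate one channel mask
#'
#' Composes [cv_accuracy()] and [fitness_value()] for a single mask.
#'
#' @inheritParams mask_fitness_function
#' @param mask Binary channel mask (repaired, at least one 1).
#' @return A `fitness_result`.
#' @export
evaluate_mask <- function(mask, features, labels, cv = cv_config(),
                          config = optimizer_config()) {
  acc <- cv_accuracy(features, labels, mask, cv)$accuracy
  fitness_value(acc, mask, config$channel_penalty)
}

# mask_a strictly preferred over mask_b under the ranking used everywhere:
# higher fitness, then fewer selected channels, then lexicographically
# smaller bit vector.
mask_better <- function(fit_a, mask_a, fit_b, mask_b) {
  if (fit_a$fitness != fit_b$fitness) return(fit_a$fitness > fit_b$fitness)
  if (fit_a$n_selected != fit_b$n_selected) {
    return(fit_a$n_selected < fit_b$n_selected)
  }
  diff <- which(mask_a != mask_b)
  length(diff) > 0L && mask_a[diff[1L]] < mask_b[diff[1L]]
}

#' Exhaustive search over all non-empty channel masks
#'
#' Exact maximizer of the penalized fitness over all 2^D - 1 non-empty
#' masks; the test oracle for the metaheuristics. Ties are broken by fewer
#' selected channels, then lexicographically. Cost is exponential, so D is
#' capped at 16.
#'
#' @inheritParams mask_fitness_function
#' @param fitness_fn Optional `mask -> fitness_result` function (e.g. from
#'   [surrogate_fitness_function()]); when given, `features`/`labels`/`cv`
#'   are ignored and `n_channels` is required.
#' @param n_channels Mask length D when `fitness_fn` is supplied.
#' @return List with `mask` and `fitness` (a `fitness_result`).
#' @export
brute_force_best <- function(features = NULL, labels = NULL,
                             cv = cv_config(), config = optimizer_config(),
                             fitness_fn = NULL, n_channels = NULL) {
  if (is.null(fitness_fn)) {
    fitness_fn <- mask_fitness_function(features, labels, cv, config)
    n_channels <- length(features$channel_ids)
  }
  if (is.null(n_channels)) stop_("n_channels is required with fitness_fn")
  if (n_channels > 16L) {
    stop_("exhaustive search over D = %d channels is infeasible (max 16)",
          n_channels)
  }
  best_mask <- NULL
  best_fit <- NULL
  for (m in seq_len(2L^n_channels - 1L)) {
    mask <- as.integer(bitwAnd(bitwShiftR(m, seq_len(n_channels) - 1L), 1L))
    fit <- fitness_fn(mask)
    if (is.null(best_fit) || mask_better(fit, mask, best_fit, best_mask)) {
      best_fit <- fit
      best_mask <- mask
    }
  }
  list(mask = best_mask, fitness = best_fit)
}
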