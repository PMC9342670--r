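#' Results table of repeated optimization runs
#'
#' Long-format table with one row per (feature, optimizer, run): the
#' cross-validated accuracy (percent) and the selected channel count.
#' Balanced designs (equal runs per cell) are required by the ANOVA
#' routines.
#'
#' @param feature Character vector of feature kinds (`time`, `fc`,
#'   `wavelet`).
#' @param optimizer Character vector of optimizer names.
#' @param run Integer run index within each cell.
#' @param accuracy Accuracy in percent, in [0, 100].
#' @param n_channels Selected channel counts.
#' @return A data.frame of class `results_table`.
#' @export
results_table <- function(feature, optimizer, run, accuracy, n_channels) {
  df <- data.frame(feature = as.character(feature),
                   optimizer = as.character(optimizer),
                   run = as.integer(run), accuracy = as.numeric(accuracy),
                   n_channels = as.numeric(n_channels),
                   stringsAsFactors = FALSE)
  if (any(df$accuracy < 0 | df$accuracy > 100)) {
    stop_("accuracies must lie in [0, 100]")
  }
  class(df) <- c("results_table", "data.frame")
  df
}

cell_stats <- function(table, response) {
  agg <- stats::aggregate(table[[response]],
                          by = list(feature = table$feature,
                                    optimizer = table$optimizer),
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  data.frame(feature = agg$feature, optimizer = agg$optimizer,
             mean = agg$x[, "mean"], sd = agg$x[, "sd"], n = agg$x[, "n"],
             stringsAsFactors = FALSE)
}

#' Per-cell mean/SD summary of a results table
#'
#' @param table A [results_table()].
#' @param response `"accuracy"` or `"n_channels"`.
#' @return A `summary_table` data.frame with columns feature, optimizer,
#'   mean, sd, n.
#' @export
summarize_results <- function(table, response = c("accuracy", "n_channels")) {
  response <- match.arg(response)
  s <- cell_stats(table, response)
  if (any(s$n < 2)) stop_("each (feature, optimizer) cell needs >= 2 runs")
  class(s) <- c("summary_table", "data.frame")
  s
}

as_summary <- function(x, response) {
  if (inherits(x, "summary_table")) return(x)
  if (inherits(x, "results_table") || all(c("feature", "optimizer",
                                            response) %in% names(x))) {
    return(summarize_results(x, response))
  }
  if (all(c("feature", "optimizer", "mean", "sd", "n") %in% names(x))) {
    class(x) <- c("summary_table", "data.frame")
    return(x)
  }
  stop_("cannot interpret input as a results or summary table")
}

check_balanced <- function(s) {
  if (length(unique(s$n)) != 1L) {
    stop_("unbalanced design: the two-way ANOVA requires equal runs per cell")
  }
  tab <- table(s$feature, s$optimizer)
  if (any(tab != 1L)) stop_("missing or duplicated (feature, optimizer) cell")
  invisible(s)
}

cells_matrix <- function(s, value = "mean") {
  stats::xtabs(stats::as.formula(paste(value, "~ feature + optimizer")),
               data = s)
}

#' Marginal mean difference between two factor levels
#'
#' In a balanced two-way design the marginal (population) mean of a factor
#' level is the unweighted average of its cell means across the other
#' factor's levels. Returns `level_a - level_b`.
#'
#' @param x A [results_table()], [summarize_results()] output, or any
#'   data.frame with feature/optimizer/mean columns.
#' @param factor `"feature"` or `"optimizer"`.
#' @param level_a,level_b Factor levels to contrast.
#' @param response Response variable when `x` is a results table.
#' @return The marginal mean difference (numeric scalar).
#' @export
marginal_mean_difference <- function(x, factor = c("feature", "optimizer"),
                                     level_a, level_b,
                                     response = c("accuracy", "n_channels")) {
  factor <- match.arg(factor)
  s <- as_summary(x, match.arg(response))
  check_balanced(s)
  marg <- tapply(s$mean, s[[factor]], mean)
  for (lev in c(level_a, level_b)) {
    if (!lev %in% names(marg)) stop_("unknown %s level '%s'", factor, lev)
  }
  unname(marg[level_a] - marg[level_b])
}

eta_partial <- function(ss_effect, ss_resid) ss_effect / (ss_effect + ss_resid)

anova_result <- function(effects, model) {
  out <- data.frame(effect = names(effects),
                    df = vapply(effects, `[[`, numeric(1), "df"),
                    SS = vapply(effects, `[[`, numeric(1), "SS"),
                    F = vapply(effects, `[[`, numeric(1), "F"),
                    p = vapply(effects, `[[`, numeric(1), "p"),
                    partial_eta2 = vapply(effects, `[[`, numeric(1), "eta"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "model") <- model
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Balanced two-way fixed-effects ANOVA
#'
#' Standard decomposition for the feature x optimizer design. The additive
#' model pools the interaction sum of squares into the residual; the
#' interaction model reports it as an effect. Partial eta squared is
#' `SS_effect / (SS_effect + SS_residual)`.
#'
#' @param table A [results_table()].
#' @param response `"accuracy"` or `"n_channels"`.
#' @param model `"additive"` or `"interaction"`.
#' @return An `anova_result` data.frame with one row per effect plus the
#'   residual row (df, SS, F, p, partial eta squared).
#' @export
two_way_anova <- function(table, response = c("accuracy", "n_channels"),
                          model = c("additive", "interaction")) {
  response <- match.arg(response)
  model <- match.arg(model)
  check_balanced(summarize_results(table, response))
  df <- data.frame(y = table[[response]],
                   feature = factor(table$feature),
                   optimizer = factor(table$optimizer))
  form <- if (model == "interaction") y ~ feature * optimizer else
    y ~ feature + optimizer
  fit <- stats::aov(form, data = df)
  at <- summary(fit)[[1L]]
  rn <- trimws(rownames(at))
  ss <- at[["Sum Sq"]]
  dfs <- at[["Df"]]
  resid_i <- which(rn == "Residuals")
  ss_res <- ss[resid_i]
  df_res <- dfs[resid_i]
  ms_res <- ss_res / df_res
  effects <- list()
  for (i in seq_along(rn)[-resid_i]) {
    Fv <- if (ss[i] == 0) 0 else (ss[i] / dfs[i]) / ms_res
    effects[[sub(":", "x", rn[i])]] <- list(
      df = dfs[i], SS = ss[i], F = Fv,
      p = stats::pf(Fv, dfs[i], df_res, lower.tail = FALSE),
      eta = eta_partial(ss[i], ss_res))
  }
  effects[["residual"]] <- list(df = df_res, SS = ss_res, F = NA_real_,
                                p = NA_real_, eta = NA_real_)
  anova_result(effects, model)
}

#' Two-way ANOVA from per-cell summary statistics
#'
#' Reconstructs the balanced two-way decomposition from cell means, SDs
#' and per-cell n alone: within-cell SS from the SDs, factor SS from the
#' marginal means, interaction SS from the cell means. Under the additive
#' model the residual is the within-cell SS plus the interaction SS.
#' Algebraically identical to [two_way_anova()] on the raw data.
#'
#' @param summary A summary table (feature, optimizer, mean, sd, n).
#' @param model `"additive"` or `"interaction"`.
#' @return An `anova_result` data.frame.
#' @export
anova_from_summary <- function(summary, model = c("additive", "interaction")) {
  model <- match.arg(model)
  s <- as_summary(summary, "accuracy")
  check_balanced(s)
  n <- s$n[1L]
  if (n < 2) stop_("per-cell n must be >= 2")
  m <- cells_matrix(s, "mean")
  sdm <- cells_matrix(s, "sd")
  a <- nrow(m)
  b <- ncol(m)
  N <- a * b * n
  grand <- mean(m)
  ss_within <- sum((n - 1) * sdm^2)
  ss_a <- b * n * sum((rowMeans(m) - grand)^2)
  ss_b <- a * n * sum((colMeans(m) - grand)^2)
  ss_ab <- n * sum((sweep(sweep(m, 1L, rowMeans(m)), 2L, colMeans(m)) +
                      grand)^2)
  if (model == "additive") {
    ss_res <- ss_within + ss_ab
    df_res <- N - 1L - (a - 1L) - (b - 1L)
  } else {
    ss_res <- ss_within
    df_res <- N - a * b
  }
  ms_res <- ss_res / df_res
  eff <- function(ss, df) {
    Fv <- if (ss == 0) 0 else (ss / df) / ms_res
    list(df = df, SS = ss, F = Fv,
         p = stats::pf(Fv, df, df_res, lower.tail = FALSE),
         eta = eta_partial(ss, ss_res))
  }
  effects <- list(feature = eff(ss_a, a - 1L), optimizer = eff(ss_b, b - 1L))
  if (model == "interaction") {
    effects[["featurexoptimizer"]] <- eff(ss_ab, (a - 1L) * (b - 1L))
  }
  effects[["residual"]] <- list(df = df_res, SS = ss_res, F = NA_real_,
                                p = NA_real_, eta = NA_real_)
  anova_result(effects, model)
}

#' Bonferroni-adjusted pairwise marginal comparisons
#'
#' For every pair of levels of one factor: the marginal mean difference,
#' the t statistic on the residual mean square of the chosen model, the
#' unadjusted p, and the Bonferroni-adjusted p (`min(1, p * n_pairs)`).
#'
#' @param x A results table or summary table.
#' @param factor `"feature"` or `"optimizer"`.
#' @param response Response variable.
#' @param model ANOVA model supplying the residual mean square.
#' @return data.frame with level_a, level_b, MD, t, p, p_adjusted.
#' @export
pairwise_bonferroni <- function(x, factor = c("feature", "optimizer"),
                                response = c("accuracy", "n_channels"),
                                model = c("additive", "interaction")) {
  factor <- match.arg(factor)
  response <- match.arg(response)
  model <- match.arg(model)
  s <- as_summary(x, response)
  check_balanced(s)
  an <- anova_from_summary(s, model)
  resid <- an[an$effect == "residual", ]
  ms_res <- resid$SS / resid$df
  levs <- sort(unique(s[[factor]]))
  other <- setdiff(c("feature", "optimizer"), factor)
  m_other <- length(unique(s[[other]])) * s$n[1L]  # obs per marginal mean
  marg <- tapply(s$mean, s[[factor]], mean)
  pairs <- utils::combn(levs, 2L)
  n_pairs <- ncol(pairs)
  out <- data.frame(level_a = pairs[1L, ], level_b = pairs[2L, ],
                    stringsAsFactors = FALSE)
  out$MD <- unname(marg[out$level_a] - marg[out$level_b])
  se <- sqrt(ms_res * 2 / m_other)
  out$t <- out$MD / se
  out$p <- 2 * stats::pt(-abs(out$t), resid$df)
  out$p_adjusted <- pmin(1, out$p * n_pairs)
  out
}

#' Channel occurrence counts across best-mask sets
#'
#' Counts, for every channel, in how many of the given channel sets it
#' appears (the overlay-heatmap summary of repeated selections).
#'
#' @param mask_sets List of integer vectors of 1-based channel ids.
#' @param n_channels Total channel count (default 52).
#' @return Named integer vector of length `n_channels` (names `c1`...).
#' @export
channel_occurrence <- function(mask_sets, n_channels = 52L) {
  if (!length(mask_sets)) stop_("mask_sets must be a non-empty list")
  counts <- integer(n_channels)
  for (set in mask_sets) {
    set <- as.integer(set)
    if (any(set < 1L | set > n_channels)) {
      stop_("channel id out of range 1..%d", n_channels)
    }
    counts[unique(set)] <- counts[unique(set)] + 1L
  }
  names(counts) <- sprintf("c%d", seq_len(n_channels))
  counts
}

#' Bundled reference benchmark tables
#'
#' Summary statistics (per-cell accuracy and channel-count mean, SD, best
#' run, n = 10) and best-run channel sets from a published 52-channel
#' verbal-fluency-task benchmark of the seven optimizers on the three
#' feature kinds. These drive the reporting examples and the statistical
#' reproduction checks.
#'
#' @return `reference_results()`: data.frame with feature, optimizer,
#'   acc_mean, acc_sd, acc_best, nch_mean, nch_sd, nch_best, n_runs.
#' @export
reference_results <- function() {
  utils::read.csv(system.file("extdata", "reference_results.csv",
                              package = "fnirsopt", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_results
#' @param response `"accuracy"` or `"n_channels"`.
#' @return `reference_summary()`: a `summary_table` for the chosen
#'   response.
#' @export
reference_summary <- function(response = c("accuracy", "n_channels")) {
  response <- match.arg(response)
  r <- reference_results()
  s <- data.frame(feature = r$feature, optimizer = r$optimizer,
                  mean = if (response == "accuracy") r$acc_mean else r$nch_mean,
                  sd = if (response == "accuracy") r$acc_sd else r$nch_sd,
                  n = r$n_runs, stringsAsFactors = FALSE)
  class(s) <- c("summary_table", "data.frame")
  s
}

#' @rdname reference_results
#' @return `reference_best_channels()`: named list (names
#'   `<feature>.<optimizer>`) of integer channel-id vectors of each cell's
#'   best run.
#' @export
reference_best_channels <- function() {
  b <- utils::read.csv(system.file("extdata", "reference_best_channels.csv",
                                   package = "fnirsopt", mustWork = TRUE),
                       stringsAsFactors = FALSE)
  sets <- lapply(strsplit(b$channels, " +"), as.integer)
  names(sets) <- paste(b$feature, b$optimizer, sep = ".")
  sets
}

#' Build a full analysis report from run results
#'
#' Aggregates a results table (and optionally the per-cell best channel
#' sets) into the summary matrix, both ANOVA tables, pairwise comparisons
#' and channel-occurrence counts, ready for JSON serialization.
#'
#' @param table A [results_table()].
#' @param best_masks Optional named list of channel-id vectors.
#' @param n_channels Channel count for occurrence counting.
#' @return A list of report components.
#' @export
build_report <- function(table, best_masks = NULL, n_channels = 52L) {
  rep <- list(
    summary_accuracy = summarize_results(table, "accuracy"),
    summary_channels = summarize_results(table, "n_channels"),
    anova_accuracy = two_way_anova(table, "accuracy", "additive"),
    anova_channels = two_way_anova(table, "n_channels", "interaction"),
    pairwise_feature = pairwise_bonferroni(table, "feature", "accuracy"),
    pairwise_optimizer = pairwise_bonferroni(table, "optimizer", "accuracy"))
  if (!is.null(best_masks)) {
    rep$occurrence <- channel_occurrence(best_masks, n_channels)
  }
  rep
}
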