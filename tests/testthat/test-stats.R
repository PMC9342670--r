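# Rebuild raw per-run data whose cell means/SDs equal a given summary
# exactly (any such reconstruction has identical ANOVA sums of squares).
reconstruct_runs <- function(s, seed = 1L) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(nrow(s)), function(i) {
      v <- rnorm(s$n[i])
      v <- (v - mean(v)) / sd(v) * s$sd[i] + s$mean[i]
      data.frame(feature = s$feature[i], optimizer = s$optimizer[i],
                 run = seq_len(s$n[i]), accuracy = v, n_channels = 1)
    })
    do.call(rbind, rows)
  })
}

test_that("marginal mean differences are unweighted cell-mean contrasts", {
  s <- reference_summary("accuracy")
  expect_equal(marginal_mean_difference(s, "optimizer", "GA", "PSO"),
               2.1333, tolerance = 1e-4)
  # antisymmetry and identical levels
  expect_equal(marginal_mean_difference(s, "optimizer", "PSO", "GA"),
               -marginal_mean_difference(s, "optimizer", "GA", "PSO"))
  expect_equal(marginal_mean_difference(s, "feature", "time", "time"), 0)
  expect_error(marginal_mean_difference(s, "feature", "time", "bogus"),
               "unknown feature level")
})

test_that("summary-based and raw-data ANOVA agree algebraically", {
  s <- reference_summary("accuracy")
  df <- reconstruct_runs(s)
  rt <- results_table(df$feature, df$optimizer, df$run, df$accuracy,
                      df$n_channels)
  for (model in c("additive", "interaction")) {
    a_raw <- two_way_anova(rt, "accuracy", model)
    a_sum <- anova_from_summary(summarize_results(rt, "accuracy"), model)
    expect_equal(a_raw$SS, a_sum$SS, tolerance = 1e-9)
    expect_equal(a_raw$F, a_sum$F, tolerance = 1e-9)
    expect_equal(a_raw$partial_eta2, a_sum$partial_eta2, tolerance = 1e-9)
  }
  # df bookkeeping: all rows sum to N - 1
  a <- two_way_anova(rt, "accuracy", "additive")
  expect_equal(sum(a$df), nrow(rt) - 1L)
  eta <- a$partial_eta2[!is.na(a$partial_eta2)]
  expect_true(all(eta >= 0 & eta <= 1))
})

test_that("a constant response yields zero effect sums of squares", {
  s <- expand.grid(feature = c("time", "fc"), optimizer = c("GA", "PSO"),
                   stringsAsFactors = FALSE)
  s$mean <- 5; s$sd <- 0; s$n <- 3
  a <- anova_from_summary(s, "interaction")
  eff <- a[a$effect != "residual", ]
  expect_true(all(eff$SS == 0))
  expect_true(all(eff$F == 0))
})

test_that("an injected additive feature effect is detected", {
  s <- reference_summary("accuracy")
  hits <- 0L
  for (seed in 1:5) {
    df <- reconstruct_runs(s, seed = seed)
    # wipe real structure, then inject a 3-SD feature effect
    df$accuracy <- withr::with_seed(seed + 100L, {
      base <- rnorm(nrow(df), 80, 1)
      base + 3 * (df$feature == "time")
    })
    rt <- results_table(df$feature, df$optimizer, df$run, df$accuracy, 1)
    a <- two_way_anova(rt, "accuracy", "additive")
    if (a$p[a$effect == "feature"] < 0.01) hits <- hits + 1L
  }
  expect_equal(hits, 5L)
})

test_that("pairwise Bonferroni comparisons cover all level pairs", {
  s <- reference_summary("accuracy")
  pw <- pairwise_bonferroni(s, "optimizer", "accuracy")
  expect_equal(nrow(pw), 21L)           # C(7,2)
  expect_true(all(pw$p_adjusted >= pw$p))
  expect_true(all(pw$p_adjusted <= 1))
  ga_pso <- pw[pw$level_a == "GA" & pw$level_b == "PSO", ]
  expect_equal(ga_pso$MD, 2.1333, tolerance = 1e-4)
  expect_lt(ga_pso$p_adjusted, 0.001)
})

test_that("channel occurrence counts recurrent selections", {
  sets <- reference_best_channels()
  time_sets <- sets[startsWith(names(sets), "time.")]
  expect_length(time_sets, 7L)
  occ <- channel_occurrence(time_sets, 52L)
  expect_equal(unname(occ["c19"]), 7L)  # selected by every optimizer
  expect_equal(unname(occ["c39"]), 7L)

  empty <- channel_occurrence(list(integer(0), integer(0)), 5L)
  expect_true(all(empty == 0L))
  expect_error(channel_occurrence(list(c(1L, 99L)), 52L), "out of range")
})

test_that("report assembly aggregates runs end to end", {
  s <- reference_summary("accuracy")
  df <- reconstruct_runs(s, seed = 3L)
  rt <- results_table(df$feature, df$optimizer, df$run, df$accuracy,
                      pmax(1, round(df$accuracy / 10)))
  rep <- build_report(rt, best_masks = list(c(1L, 5L), c(5L, 9L)),
                      n_channels = 10L)
  expect_named(rep, c("summary_accuracy", "summary_channels",
                      "anova_accuracy", "anova_channels",
                      "pairwise_feature", "pairwise_optimizer",
                      "occurrence"))
  expect_equal(unname(rep$occurrence["c5"]), 2L)
  # unbalanced designs are rejected with direction to the requirement
  expect_error(two_way_anova(rt[-1, ], "accuracy"), "balanced|equal runs")
})
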