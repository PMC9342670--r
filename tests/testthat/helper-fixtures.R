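# Fixtures built in code; no data files.

# Small random dataset with reproducible content.
tiny_dataset <- function(p = 4L, channels = 3L, s = 10L, fs = 10, seed = 1L) {
  withr::with_seed(seed, {
    sig <- array(rnorm(p * channels * s), dim = c(p, channels, s))
    fnirs_dataset(sig, fs, rep_len(c(1L, 0L), p))
  })
}

# Two Gaussian clusters separated by `gap` SDs on every dimension: any
# sensible classifier reaches 100% CV accuracy.
separable_features <- function(n_per_class = 20L, d = 4L, gap = 10,
                               seed = 1L) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * d, mean = 0), ncol = d),
               matrix(rnorm(n_per_class * d, mean = gap), ncol = d))
    list(features = feature_matrix(x, "time", seq_len(d)),
         labels = c(rep(0L, n_per_class), rep(1L, n_per_class)))
  })
}

# Deterministic multimodal surrogate objective over masks: rewards
# matching `target`, plus small pairwise synergy terms. Optimum (checked
# by exhaustive enumeration in the tests) is at `target`.
surrogate_accuracy <- function(target) {
  force(target)
  function(mask) {
    base <- 60 + 5 * sum(mask == target)
    syn <- 3 * (mask[1L] == 1L && mask[3L] == 1L)
    if (length(mask) >= 4L) {
      syn <- syn - 2 * (mask[2L] == 1L && mask[4L] == 1L)
    }
    min(100, base + syn)
  }
}

all_methods <- c("ga", "pso", "pgapso1", "pgapso2", "pgapso3", "spsoga",
                 "sgapso")

# Amplitude of a sinusoid of known frequency in a series, by least squares
# on sine/cosine regressors (robust to the phase shifts at the edges).
sine_amplitude <- function(x, freq, fs) {
  tt <- (seq_along(x) - 1L) / fs
  fit <- lm(x ~ sin(2 * pi * freq * tt) + cos(2 * pi * freq * tt))
  sqrt(sum(coef(fit)[2:3]^2))
}
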