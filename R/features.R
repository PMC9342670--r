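#' Feature matrix container
#'
#' Participants x features table produced by one of the three extractors.
#' `kind` records the extractor: `"time"` and `"wavelet"` matrices have one
#' column per channel; `"fc"` matrices have one column per unordered channel
#' pair `"c<i>-c<j>"` (i < j) in lexicographic order.
#'
#' @param values Numeric matrix, participants x features.
#' @param kind One of `"time"`, `"fc"`, `"wavelet"`.
#' @param channel_ids Integer vector of the channel ids the columns derive
#'   from.
#' @param normalized Logical; whether columns were z-normalized across
#'   participants.
#' @param pairs For `kind = "fc"`, an integer matrix with columns `i`, `j`
#'   giving each feature's channel pair (indices into `channel_ids`).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, kind = c("time", "fc", "wavelet"),
                           channel_ids, normalized = FALSE, pairs = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop_("feature matrix contains NA or non-finite values")
  }
  nc <- length(channel_ids)
  expected <- if (kind == "fc") nc * (nc - 1L) / 2L else nc
  if (ncol(values) != expected) {
    stop_("%s features: expected %d columns for %d channels, got %d",
          kind, expected, nc, ncol(values))
  }
  if (kind == "fc") {
    if (is.null(pairs)) pairs <- t(utils::combn(nc, 2L))
    colnames(values) <- sprintf("c%d-c%d", channel_ids[pairs[, 1L]],
                                channel_ids[pairs[, 2L]])
  } else {
    colnames(values) <- sprintf("c%d", channel_ids)
  }
  if (anyDuplicated(colnames(values))) stop_("duplicate feature names")
  structure(list(values = values, kind = kind,
                 channel_ids = as.integer(channel_ids),
                 normalized = isTRUE(normalized), pairs = pairs),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix (%s): %d participants x %d features%s\n",
              x$kind, nrow(x$values), ncol(x$values),
              if (x$normalized) ", z-normalized" else ""))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

# Forward-backward IIR filtering with odd-reflection end padding, so that
# startup transients live in the discarded pad rather than in the signal.
zero_phase_filter <- function(bf, x) {
  n <- length(x)
  p <- min(n - 1L, 100L)
  ext <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- signal::filtfilt(bf, ext)
  y[(p + 1L):(p + n)]
}

# z-normalize each column across participants; population SD by default.
znorm_columns <- function(m, sd_type = c("population", "sample"),
                          what = "channel") {
  sd_type <- match.arg(sd_type)
  n <- nrow(m)
  mu <- colMeans(m)
  ctr <- sweep(m, 2L, mu)
  ss <- colSums(ctr^2)
  denom <- if (sd_type == "population") n else n - 1L
  s <- sqrt(ss / denom)
  zero <- which(s == 0)
  if (length(zero)) {
    stop_("zero across-participant variance in %s %s", what,
          paste(colnames(m)[zero], collapse = ", "))
  }
  sweep(ctr, 2L, s, "/")
}

#' Zero-phase low-pass filter
#'
#' Applies a 4th-order Butterworth low-pass filter forward and backward
#' (zero phase shift, squared magnitude response) to every channel of every
#' participant. The default 0.6 Hz cutoff removes cardiac and
#' high-frequency noise while leaving the task-evoked hemodynamic response
#' intact.
#'
#' @param dataset An [fnirs_dataset()].
#' @param cutoff Cutoff frequency in Hz; must be below the Nyquist
#'   frequency.
#' @param order Filter order (default 4).
#' @return A filtered [fnirs_dataset()] of the same shape.
#' @export
lowpass_filter <- function(dataset, cutoff = 0.6, order = 4L) {
  stopifnot(inherits(dataset, "fnirs_dataset"))
  nyq <- dataset$sampling_rate / 2
  if (cutoff >= nyq) {
    stop_("cutoff %g Hz is not below the Nyquist frequency %g Hz", cutoff, nyq)
  }
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  sig <- dataset$signals
  d <- dim(sig)
  for (p in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      sig[p, ch, ] <- zero_phase_filter(bf, sig[p, ch, ])
    }
  }
  out <- dataset
  out$signals <- sig
  out
}

#' Time-domain mean features
#'
#' Per participant and channel, the temporal mean over the provided task
#' window, z-normalized per channel across participants.
#'
#' @param dataset An [fnirs_dataset()] (normally low-pass filtered first).
#' @param normalize Whether to z-normalize across participants (default
#'   TRUE).
#' @param sd_type `"population"` (divide by n, default) or `"sample"`
#'   (n - 1) standard deviation for the normalization.
#' @return A `"time"` [feature_matrix()], participants x channels.
#' @export
extract_time_mean <- function(dataset, normalize = TRUE,
                              sd_type = c("population", "sample")) {
  stopifnot(inherits(dataset, "fnirs_dataset"))
  m <- apply(dataset$signals, c(1L, 2L), mean)
  colnames(m) <- sprintf("c%d", dataset$channel_ids)
  if (normalize) m <- znorm_columns(m, match.arg(sd_type))
  feature_matrix(m, "time", dataset$channel_ids, normalized = normalize)
}

#' Functional-connectivity features
#'
#' Per participant, the Pearson correlation between every unordered pair of
#' channel time series; features are the upper triangle vectorized in
#' lexicographic (i < j) order and stay on their natural [-1, 1] scale.
#'
#' @param dataset An [fnirs_dataset()] with at least 2 samples.
#' @return An `"fc"` [feature_matrix()], participants x C(channels, 2).
#' @export
extract_fc <- function(dataset) {
  stopifnot(inherits(dataset, "fnirs_dataset"))
  d <- dim(dataset$signals)
  if (d[3L] < 2L) stop_("need at least 2 samples per channel for correlation")
  pairs <- t(utils::combn(d[2L], 2L))
  vals <- matrix(NA_real_, d[1L], nrow(pairs))
  for (p in seq_len(d[1L])) {
    x <- t(dataset$signals[p, , , drop = TRUE])  # samples x channels
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
      stop_("zero temporal variance for participant %d, channel %d",
            p, dataset$channel_ids[which(sds == 0)[1L]])
    }
    cm <- stats::cor(x)
    vals[p, ] <- cm[cbind(pairs[, 1L], pairs[, 2L])]
  }
  feature_matrix(vals, "fc", dataset$channel_ids, normalized = FALSE,
                 pairs = pairs)
}

#' @rdname extract_fc
#' @param fc_row One row of an `"fc"` feature matrix.
#' @param n_channels Number of channels.
#' @return `fc_to_matrix()`: the symmetric correlation matrix with unit
#'   diagonal corresponding to one participant's FC feature vector.
#' @export
fc_to_matrix <- function(fc_row, n_channels) {
  m <- diag(1, n_channels)
  pairs <- t(utils::combn(n_channels, 2L))
  m[pairs] <- fc_row
  m[pairs[, c(2L, 1L)]] <- fc_row
  m
}

#' Wavelet-energy features
#'
#' Per participant and channel, the energy (sum of squared coefficients) of
#' the final approximation band of a 3-level periodized Daubechies-5
#' decomposition, computed on the raw (unfiltered) signals. At 10 Hz
#' sampling the band spans 0-0.625 Hz, the range of the task-evoked
#' hemodynamic response. Energies are z-normalized across participants
#' like the time-domain features so that SVM feature scales stay
#' comparable.
#'
#' @param dataset An [fnirs_dataset()]; use raw signals, not the low-pass
#'   filtered ones.
#' @param levels Decomposition depth (default 3).
#' @param relative If TRUE, divide each channel's approximation energy by
#'   its total signal energy before normalization.
#' @param normalize,sd_type As in [extract_time_mean()].
#' @return A `"wavelet"` [feature_matrix()], participants x channels.
#' @export
extract_wavelet_energy <- function(dataset, levels = 3L, relative = FALSE,
                                   normalize = TRUE,
                                   sd_type = c("population", "sample")) {
  stopifnot(inherits(dataset, "fnirs_dataset"))
  d <- dim(dataset$signals)
  if (d[3L] < 2L^levels) {
    stop_("signals of length %d are too short for a %d-level decomposition",
          d[3L], levels)
  }
  m <- matrix(NA_real_, d[1L], d[2L])
  for (p in seq_len(d[1L])) {
    for (ch in seq_len(d[2L])) {
      dec <- wavelet_decompose(dataset$signals[p, ch, ], levels)
      e <- sum(dec$a^2)
      if (relative) {
        tot <- e + sum(vapply(dec$d, function(v) sum(v^2), numeric(1)))
        e <- if (tot > 0) e / tot else 0
      }
      m[p, ch] <- e
    }
  }
  colnames(m) <- sprintf("c%d", dataset$channel_ids)
  if (normalize) m <- znorm_columns(m, match.arg(sd_type))
  feature_matrix(m, "wavelet", dataset$channel_ids, normalized = normalize)
}

#' Write or read a feature matrix as delimited text
#'
#' One row per participant, a header row of feature names, and `#` comment
#' lines recording the kind, channel ids and normalization flag.
#'
#' @param fm A [feature_matrix()].
#' @param path Output path (TSV/CSV by extension).
#' @return `read_feature_matrix()` returns the [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  sep <- delim_for(path)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(sprintf("#kind %s", fm$kind),
               sprintf("#channels %s", paste(fm$channel_ids, collapse = " ")),
               sprintf("#normalized %d", as.integer(fm$normalized)),
               paste(colnames(fm$values), collapse = sep)), con)
  utils::write.table(format(fm$values, digits = 17, trim = TRUE),
                     con, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(fm)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get_hdr <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key))]
    if (!length(ln)) stop_("feature file %s lacks '#%s' header", path, key)
    trimws(sub(paste0("^#", key), "", ln[1L]))
  }
  kind <- get_hdr("kind")
  channels <- as.integer(strsplit(get_hdr("channels"), " +")[[1L]])
  normalized <- as.integer(get_hdr("normalized")) == 1L
  body <- lines[!startsWith(lines, "#")]
  sep <- delim_for(path)
  vals <- utils::read.table(text = body[-1L], sep = sep)
  vals <- as.matrix(vals)
  feature_matrix(vals, kind, channels, normalized = normalized)
}
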