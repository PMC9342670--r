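# Periodized orthogonal discrete wavelet transform.
#
# No wavelet decomposition is needed beyond a fixed-depth Daubechies
# analysis bank, so the transform is implemented directly: circular
# convolution with the decomposition pair followed by dyadic decimation.
# With periodization the decimated analysis matrix is orthogonal for any
# even signal length, which makes the energy partition across subbands
# exact (Parseval) rather than approximate as under zero or symmetric
# padding.

# Daubechies-5 decomposition low-pass filter (standard published values).
DB5_DEC_LO <- c(
   0.0033357252854737712, -0.012580751999081999, -0.006241490212798274,
   0.07757149384004572,   -0.032244869584638375, -0.24229488706638203,
   0.13842814590132074,    0.7243085284377729,    0.6038292697971896,
   0.16010239797419293)

# Quadrature mirror high-pass: g[n] = (-1)^n h[N + 1 - n] (1-based n).
db5_dec_hi <- function() {
  h <- DB5_DEC_LO
  n <- length(h)
  rev(h) * (-1)^(seq_len(n))
}

# One analysis step: returns approximation and detail coefficients of
# length ceiling(L / 2). Odd-length inputs are extended by repeating the
# final sample before the circular convolution.
dwt_step <- function(x) {
  if (length(x) %% 2L == 1L) x <- c(x, x[length(x)])
  L <- length(x)
  h <- DB5_DEC_LO
  g <- db5_dec_hi()
  nf <- length(h)
  if (L < nf) {
    # tile the signal periodically up to the filter support
    x <- rep_len(x, nf + (nf %% 2L))
    L <- length(x)
  }
  half <- L %/% 2L
  idx <- outer(2L * (seq_len(half) - 1L), seq_len(nf) - 1L, "+") %% L + 1L
  xm <- matrix(x[idx], nrow = half, ncol = nf)
  list(a = drop(xm %*% h), d = drop(xm %*% g))
}

#' Multi-level Daubechies-5 wavelet decomposition
#'
#' Periodized (circular) discrete wavelet transform with the Daubechies-5
#' mother wavelet. Under periodization the transform is orthogonal, so the
#' summed squared coefficients of the approximation and all detail bands
#' equal the squared norm of the (possibly end-padded) input exactly.
#'
#' @param x Numeric signal vector.
#' @param levels Decomposition depth (default 3). At a 10 Hz sampling rate
#'   and 3 levels the final approximation band spans 0-0.625 Hz.
#' @return List with `a` (approximation coefficients at the final level)
#'   and `d` (list of detail coefficient vectors, level 1 first).
#' @export
wavelet_decompose <- function(x, levels = 3L) {
  x <- as.numeric(x)
  if (!is_count(levels) || levels < 1L) stop_("levels must be a positive integer")
  if (length(x) < 2L^levels) {
    stop_("signal of length %d is too short for a %d-level decomposition",
          length(x), levels)
  }
  d <- vector("list", levels)
  a <- x
  for (lev in seq_len(levels)) {
    st <- dwt_step(a)
    a <- st$a
    d[[lev]] <- st$d
  }
  list(a = a, d = d)
}

#' @rdname wavelet_decompose
#' @param decomposition Result of `wavelet_decompose()`.
#' @return `wavelet_band_energies()`: named numeric vector of summed squared
#'   coefficients per band (`a<levels>`, then `d<levels>`..`d1`).
#' @export
wavelet_band_energies <- function(decomposition) {
  levels <- length(decomposition$d)
  e <- c(sum(decomposition$a^2),
         rev(vapply(decomposition$d, function(v) sum(v^2), numeric(1))))
  names(e) <- c(sprintf("a%d", levels), sprintf("d%d", levels:1))
  e
}

#' @rdname wavelet_decompose
#' @param sampling_rate Sampling rate in Hz.
#' @return `approximation_band()`: numeric length-2 vector, the frequency
#'   range (Hz) covered by the final approximation band.
#' @export
approximation_band <- function(sampling_rate, levels = 3L) {
  c(0, sampling_rate / 2 / 2^levels)
}
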