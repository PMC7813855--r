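# Welch spectral estimation: averaged modified periodograms with Hann
# windows. One-sided conventions throughout: integrating the PSD over
# (0, Nyquist] recovers the signal variance.

hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / n))
}

welch_segments <- function(n, segment_length, overlap) {
  step <- max(1L, as.integer(round(segment_length * (1 - overlap))))
  starts <- seq.int(1L, n - segment_length + 1L, by = step)
  starts
}

# Averaged one-sided auto/cross spectral densities of one or two demeaned
# traces. Returns frequency grid (excluding DC), Sxx, Syy, Sxy (complex),
# the number of averaged segments and the resolution bandwidth fs/L.
welch_spectra <- function(x, y = NULL, fs, segment_length, overlap = 0.5) {
  n <- length(x)
  l <- as.integer(segment_length)
  if (l < 8L) stop("`segment_length` must be at least 8", call. = FALSE)
  if (n < 2L * l) {
    stop("trace must be at least twice `segment_length`", call. = FALSE)
  }
  if (overlap < 0 || overlap >= 1) {
    stop("`overlap` must be in [0, 1)", call. = FALSE)
  }
  w <- hann_window(l)
  scale <- 1 / (fs * sum(w^2))
  starts <- welch_segments(n, l, overlap)
  half <- l %/% 2L
  kidx <- seq_len(half)  # bins 1 .. L/2 (DC dropped, Nyquist kept)
  sxx <- numeric(half)
  syy <- if (!is.null(y)) numeric(half) else NULL
  sxy <- if (!is.null(y)) complex(half) else NULL
  for (s in starts) {
    seg <- x[s:(s + l - 1L)]
    fx <- stats::fft(w * (seg - mean(seg)))[kidx + 1L]
    sxx <- sxx + Mod(fx)^2
    if (!is.null(y)) {
      segy <- y[s:(s + l - 1L)]
      fy <- stats::fft(w * (segy - mean(segy)))[kidx + 1L]
      syy <- syy + Mod(fy)^2
      sxy <- sxy + Conj(fx) * fy
    }
  }
  m <- length(starts)
  one_sided <- c(rep(2, half - 1L), if (l %% 2L == 0L) 1 else 2)
  sxx <- sxx / m * scale * one_sided
  if (!is.null(y)) {
    syy <- syy / m * scale * one_sided
    sxy <- sxy / m * scale * one_sided
  }
  list(frequency = kidx * fs / l, sxx = sxx, syy = syy, sxy = sxy,
       n_segments = m, rbw = fs / l)
}
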