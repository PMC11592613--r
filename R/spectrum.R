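# smallest 5-smooth integer >= n (sizes R's mixed-radix FFT handles fast)
next_fast_n <- function(n) {
  if (n <= 2) return(2L)
  best <- nextn(n, 2)
  p5 <- 1
  while (p5 < best) {
    p35 <- p5
    while (p35 < best) {
      k <- p35 * 2^max(0, ceiling(log2(n / p35)))
      if (k >= n && k < best) best <- k
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  as.integer(best)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hamming-windowed segments with 50%
#' overlap, one-sided density in signal-units^2/Hz. Scaling satisfies
#' Parseval: `sum(psd) * df` approximates the signal variance.
#'
#' @param x numeric vector.
#' @param rate sampling rate, Hz.
#' @param seg_s segment length in seconds (default 2; shortened to the
#'   signal length if necessary).
#' @param overlap fractional segment overlap.
#' @return list with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, rate, seg_s = 2, overlap = 0.5) {
  n <- length(x)
  nseg <- min(n, round(seg_s * rate))
  if (nseg < 8) stop("signal too short for spectral estimation")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  u <- sum(w^2)
  nf <- nseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- abs(fft(seg))^2
    acc <- acc + P[seq_len(nf)]
  }
  psd <- acc / (length(starts) * u * rate)
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[nf] <- 1
  psd <- psd * dbl
  list(freq = (seq_len(nf) - 1) * rate / nseg, psd = psd)
}

band_power <- function(freq, psd, lo, hi) {
  sel <- freq >= lo & freq <= hi
  if (!any(sel)) return(0)
  df <- if (length(freq) > 1) freq[2] - freq[1] else 1
  sum(psd[sel]) * df
}
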