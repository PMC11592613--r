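# Filtering, resampling, channel exclusion, re-referencing, baseline removal.
#
# The filter is a zero-phase windowed-sinc FIR (Hamming window), applied by
# FFT convolution with reflect padding of one filter length and the group
# delay removed exactly - the EEGLAB-style default that preserves ERP
# latencies. Cutoffs sit at the stated band edges with half the transition
# band on each side, so a 0.5 Hz high-pass reaches its ~53 dB Hamming
# stopband by 0.25 Hz.

#' Band-pass filter specification
#'
#' @param highpass_hz lower passband edge, Hz.
#' @param lowpass_hz upper passband edge, Hz.
#' @param transition_width_hz length-2 transition widths (low edge, high
#'   edge); default `max(0.5, 0.25 * cutoff)` per edge.
#' @param design filter family; only `"fir_zero_phase"` is provided.
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(highpass_hz = 0.5, lowpass_hz = 70,
                        transition_width_hz = NULL,
                        design = "fir_zero_phase") {
  design <- match.arg(design, "fir_zero_phase")
  if (!(highpass_hz > 0 && lowpass_hz > highpass_hz))
    stop("need 0 < highpass_hz < lowpass_hz")
  if (is.null(transition_width_hz))
    transition_width_hz <- pmax(0.5, 0.25 * c(highpass_hz, lowpass_hz))
  if (length(transition_width_hz) == 1L)
    transition_width_hz <- rep(transition_width_hz, 2)
  structure(list(highpass_hz = highpass_hz, lowpass_hz = lowpass_hz,
                 transition_width_hz = transition_width_hz, design = design),
            class = "filter_spec")
}

# Hamming-windowed sinc low-pass kernel, odd length
fir_lowpass_kernel <- function(fc_norm, ntaps) {
  m <- ntaps - 1L
  k <- seq(0, m) - m / 2
  h <- 2 * fc_norm * ifelse(k == 0, 1, sin(2 * pi * fc_norm * k) /
                              (2 * pi * fc_norm * k))
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, m) / m)
  h <- h * w
  h / sum(h)
}

fir_bandpass_kernel <- function(rate, spec) {
  tw <- min(spec$transition_width_hz)
  ntaps <- ceiling(3.3 * rate / tw)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1L
  lo <- spec$highpass_hz / rate
  hi <- spec$lowpass_hz / rate
  fir_lowpass_kernel(hi, ntaps) - fir_lowpass_kernel(lo, ntaps)
}

# zero-phase FIR via batched FFT convolution; x is a row-wise channel matrix
apply_fir <- function(x, h) {
  single <- is.null(dim(x))
  if (single) x <- matrix(x, 1)
  n <- ncol(x)
  L <- length(h)
  half <- (L - 1L) / 2L
  pad <- min(L, n - 1L)
  nfft <- next_fast_n(n + 2 * pad + L - 1L)
  H <- fft(c(h, numeric(nfft - L)))
  # reflect-pad every channel about both ends, columns = channels
  XE <- matrix(0, nfft, nrow(x))
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    XE[seq_len(n + 2 * pad), i] <- c(2 * xi[1] - xi[(pad + 1):2],
                                     xi,
                                     2 * xi[n] - xi[n - seq_len(pad)])
  }
  Y <- Re(mvfft(mvfft(XE) * H, inverse = TRUE)) / nfft
  out <- t(Y[pad + half + seq_len(n), , drop = FALSE])
  dimnames(out) <- dimnames(x)
  if (single) out[1, ] else out
}

#' Zero-phase band-pass filtering
#'
#' Applies the windowed-sinc FIR described by `spec` with no group delay: a
#' pulse's peak stays at the same sample index.
#'
#' @param recording an [eeg_recording()].
#' @param spec a [filter_spec()]; default 0.5-70 Hz.
#' @return the filtered recording.
#' @export
bandpass <- function(recording, spec = filter_spec()) {
  if (spec$lowpass_hz >= recording$rate / 2)
    stop("lowpass_hz must be below the Nyquist frequency ",
         recording$rate / 2, " Hz")
  h <- fir_bandpass_kernel(recording$rate, spec)
  recording$data <- apply_fir(recording$data, h)
  recording
}

#' Resample a recording
#'
#' Anti-alias low-pass filtering (when downsampling) followed by cubic
#' spline interpolation onto the new sampling grid. Annotations are in
#' seconds and are unchanged.
#'
#' @param recording an [eeg_recording()].
#' @param target_rate new sampling rate, Hz.
#' @return resampled recording with `round(samples * target_rate / rate)`
#'   samples.
#' @export
resample_recording <- function(recording, target_rate) {
  if (!is.numeric(target_rate) || target_rate <= 0)
    stop("target_rate must be > 0")
  rate <- recording$rate
  if (target_rate == rate) return(recording)
  n <- ncol(recording$data)
  m <- round(n * target_rate / rate)
  x <- recording$data
  if (target_rate < rate) {
    fc <- 0.45 * target_rate
    h <- fir_lowpass_kernel(fc / rate, local({
      nt <- ceiling(3.3 * rate / (0.1 * target_rate))
      if (nt %% 2 == 0) nt + 1L else nt
    }))
    x <- apply_fir(x, h)
  }
  t_old <- (seq_len(n) - 1) / rate
  t_new <- (seq_len(m) - 1) / target_rate
  out <- matrix(0, nrow(x), m)
  for (i in seq_len(nrow(x)))
    out[i, ] <- spline(t_old, x[i, ], xout = pmin(t_new, t_old[n]))$y
  eeg_recording(out, rate = target_rate, labels = recording$labels,
                annotations = recording$annotations,
                reference = recording$reference)
}

#' Exclude channels
#'
#' @param recording an [eeg_recording()].
#' @param labels channels to drop; must all be present.
#' @return recording without those rows, remaining order preserved.
#' @export
exclude_channels <- function(recording, labels) {
  if (!length(labels)) return(recording)
  unknown <- setdiff(labels, recording$labels)
  if (length(unknown))
    stop("cannot exclude unknown channels: ", paste(unknown, collapse = ", "))
  keep <- !recording$labels %in% labels
  eeg_recording(recording$data[keep, , drop = FALSE], rate = recording$rate,
                labels = recording$labels[keep],
                annotations = recording$annotations,
                reference = recording$reference)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, the
#' standard CAR re-referencing. Idempotent; the output's column means are
#' zero to numerical precision and the reference tag is set to `"CAR"`.
#'
#' @param recording an [eeg_recording()] with at least 2 channels.
#' @return the re-referenced recording.
#' @export
common_average_reference <- function(recording) {
  if (nrow(recording$data) < 2)
    stop("CAR needs at least 2 channels")
  if (recording$reference == "CAR")
    message("recording is already CAR-referenced; re-applying is a no-op")
  recording$data <- sweep(recording$data, 2, colMeans(recording$data))
  recording$reference <- "CAR"
  recording
}

#' Baseline removal on epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' (default: the whole pre-event interval).
#'
#' @param epochs an `eeg_epochs` object from [extract_epochs()].
#' @param baseline_window length-2 numeric `(t0, t1)` in epoch time,
#'   seconds; must intersect the epoch time axis.
#' @return the baseline-corrected epochs.
#' @export
remove_baseline <- function(epochs, baseline_window = NULL) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (is.null(baseline_window))
    baseline_window <- c(epochs$times[1], 0)
  sel <- epochs$times >= baseline_window[1] & epochs$times <= baseline_window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  bl <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- sweep(epochs$data, c(1, 2), bl)
  epochs$baseline <- baseline_window
  epochs
}
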