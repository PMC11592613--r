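# Peak-to-Peak Amplitude Fluctuation (PPAF).
#
# PPAF is the mean of successive peak-minus-following-trough amplitude
# differences,
#     PPAF = (1/N) * sum_i (Peak_i - Trough_i),
# over N peak/trough pairs. Large, regular pairs are the signature of ictal
# spike-and-wave activity. The companion stability percentage,
# 100 * (1 - sd/mean) of the pair amplitudes clipped to [0, 100], expresses
# how consistent the pair amplitudes are: 100 means perfectly repeating
# peak-to-trough swings.
#
# Pairing rule: peaks are strict local maxima with topographic prominence
# at least `prominence_uV`, thinned so accepted peaks are at least
# `min_separation_s` apart (larger peaks win; ties go to the earlier one);
# each accepted peak is paired with the lowest local minimum strictly
# before the next accepted peak (or the end of the signal), and peaks with
# no following minimum are dropped.

#' Detect peak/trough pairs
#'
#' @param signal numeric vector, microvolts.
#' @param rate sampling rate, Hz.
#' @param prominence_uV minimum topographic prominence for a peak; `NULL`
#'   requests the adaptive default, twice the raw median absolute deviation
#'   of the signal.
#' @param min_separation_s minimum spacing between accepted peaks, s.
#' @return data frame with columns `peak_index`, `peak_amp`, `trough_index`,
#'   `trough_amp` (indices 1-based), ordered by `peak_index`; zero rows for
#'   signals without qualifying pairs (e.g. constants).
#' @export
detect_pairs <- function(signal, rate, prominence_uV = NULL,
                         min_separation_s = 0.05) {
  signal <- as.numeric(signal)
  if (length(signal) < 3) stop("signal must have at least 3 samples")
  if (is.null(prominence_uV))
    prominence_uV <- 2 * median(abs(signal - median(signal)))
  if (prominence_uV < 0) stop("prominence_uV must be >= 0")
  min_sep <- max(1L, round(min_separation_s * rate))
  m <- ppaf_pairs_cpp(signal, prominence_uV, min_sep)
  as.data.frame(m)
}

#' Compute the PPAF statistic from pairs
#'
#' @param pairs data frame from [detect_pairs()] (or any frame with
#'   `peak_index`, `peak_amp`, `trough_index`, `trough_amp`).
#' @return a `ppaf_result`: `ppaf` (uV, mean pair difference), `n_pairs`,
#'   `amplitudes` (per-pair differences), `stability_percent` and
#'   `stability_defined` (FALSE when there were no pairs). A single pair
#'   has no observable variability and reports stability 100.
#' @export
compute_ppaf <- function(pairs) {
  pairs <- as.data.frame(pairs)
  n <- nrow(pairs)
  if (n > 0 && any(pairs$trough_index <= pairs$peak_index))
    stop("integrity error: every trough must follow its peak")
  amps <- if (n) pairs$peak_amp - pairs$trough_amp else numeric(0)
  ppaf <- if (n) mean(amps) else 0
  if (n == 0) {
    stab <- 0; defined <- FALSE
  } else if (n == 1) {
    stab <- 100; defined <- TRUE
  } else {
    cv <- if (ppaf != 0) sd(amps) / ppaf else 0
    stab <- min(100, max(0, 100 * (1 - cv)))
    defined <- TRUE
  }
  structure(list(ppaf = ppaf, n_pairs = n, amplitudes = amps,
                 stability_percent = stab, stability_defined = defined),
            class = "ppaf_result")
}

#' @export
print.ppaf_result <- function(x, ...) {
  cat(sprintf("<ppaf_result> PPAF = %.2f uV over %d pairs, stability %.2f%%%s\n",
              x$ppaf, x$n_pairs, x$stability_percent,
              if (!x$stability_defined) " (no pairs)" else ""))
  invisible(x)
}

#' Sliding-window PPAF over a recording
#'
#' Computes PPAF in every window of `window_s` seconds advanced by
#' `step_s`, for every channel. Windows are tagged ictal when at least half
#' the window overlaps a `seizure` annotation. Windows with no qualifying
#' pairs report PPAF 0 (keeping the feature matrix dense).
#'
#' @param recording an [eeg_recording()].
#' @param window_s window length, s.
#' @param step_s hop, s.
#' @param prominence_uV fixed prominence, or `NULL` for an adaptive
#'   prominence of `prominence_mult` x the raw median absolute deviation,
#'   computed over each window (`prominence_scope = "window"`) or once per
#'   channel over the whole recording (`"channel"` - the detector's choice,
#'   since a seizure inside a window inflates that window's own MAD and
#'   would suppress its pairs).
#' @param min_separation_s minimum peak spacing, s.
#' @param prominence_scope scope of the adaptive prominence, see above.
#' @param prominence_mult multiplier on the MAD for the adaptive prominence.
#' @return data frame: `channel`, `window_start_s`, `ppaf_uV`, `n_pairs`,
#'   `stability_pct`, `ictal`.
#' @export
sliding_ppaf <- function(recording, window_s = 2, step_s = 1,
                         prominence_uV = NULL, min_separation_s = 0.05,
                         prominence_scope = c("window", "channel"),
                         prominence_mult = 2) {
  prominence_scope <- match.arg(prominence_scope)
  rate <- recording$rate
  n <- ncol(recording$data)
  win <- round(window_s * rate)
  step <- round(step_s * rate)
  if (win > n) stop("window is longer than the recording")
  if (step > win) stop("step_s must not exceed window_s")
  nw <- (n - win) %/% step + 1L
  starts_s <- (seq_len(nw) - 1L) * step / rate

  sz <- annotations_with_label(recording, "seizure")
  ov <- numeric(nw)
  for (i in seq_len(nrow(sz))) {
    a <- sz$onset[i]; b <- a + sz$duration[i]
    ov <- ov + pmax(0, pmin(starts_s + window_s, b) - pmax(starts_s, a))
  }
  ictal <- ov >= window_s / 2

  min_sep <- max(1L, round(min_separation_s * rate))
  nch <- length(recording$labels)
  P <- N <- S <- matrix(0, nw, nch)
  for (ci in seq_len(nch)) {
    prom <- if (!is.null(prominence_uV)) prominence_uV
            else if (prominence_scope == "channel") {
      x <- recording$data[ci, ]
      prominence_mult * median(abs(x - median(x)))
    } else NA_real_
    m <- sliding_ppaf_cpp(recording$data[ci, ], win, step, prom, min_sep,
                          prominence_mult)
    P[, ci] <- m[, 1]; N[, ci] <- m[, 2]; S[, ci] <- m[, 3]
  }
  data.frame(channel = rep(recording$labels, each = nw),
             window_start_s = rep(starts_s, nch),
             ppaf_uV = as.vector(P), n_pairs = as.integer(N),
             stability_pct = as.vector(S), ictal = rep(ictal, nch),
             stringsAsFactors = FALSE)
}

#' PPAF of an ERP trace
#'
#' Composition of [detect_pairs()] and [compute_ppaf()] on one channel of
#' an ERP - the form in which PPAF summarises waveform stability across
#' averaged seizures.
#'
#' @param erp an `eeg_erp` from [compute_erp()].
#' @param channel channel label.
#' @param prominence_uV as in [detect_pairs()].
#' @param min_separation_s as in [detect_pairs()].
#' @return a `ppaf_result`.
#' @export
erp_ppaf <- function(erp, channel, prominence_uV = NULL,
                     min_separation_s = 0.05) {
  ci <- match(channel, erp$labels)
  if (is.na(ci)) stop("unknown channel: ", channel)
  compute_ppaf(detect_pairs(erp$erp[ci, ], erp$rate, prominence_uV,
                            min_separation_s))
}
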