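# Time-locked epoch extraction, ERPs, ERP images, component contribution
# envelopes, spectra and scalp interpolation grids.

#' Extract time-locked epochs
#'
#' One epoch per annotation with `event_label`, on the window
#' `(t_min, t_max)` around its onset (t = 0 at onset). Events whose window
#' does not fit inside the recording are dropped with a warning.
#'
#' @param recording an [eeg_recording()].
#' @param event_label annotation label marking the events (default
#'   `"seizure"`).
#' @param window length-2 numeric `(t_min, t_max)`, seconds, with
#'   `t_min < 0 < t_max`. Default `(-1, 2)`.
#' @return an `eeg_epochs` object: `data` (epochs x channels x samples),
#'   `times`, `rate`, `labels`, `event_ids`.
#' @export
extract_epochs <- function(recording, event_label = "seizure",
                           window = c(-1, 2)) {
  if (!(window[1] < 0 && window[2] > 0))
    stop("window must straddle the event: t_min < 0 < t_max")
  ev <- annotations_with_label(recording, event_label)
  if (!nrow(ev)) stop("no events with label '", event_label, "'")
  rate <- recording$rate
  n <- ncol(recording$data)
  nsamp <- round((window[2] - window[1]) * rate)
  rel <- round(window[1] * rate) + seq_len(nsamp) - 1L
  times <- rel / rate
  keep <- integer(0)
  slices <- list()
  for (i in seq_len(nrow(ev))) {
    i0 <- round(ev$onset[i] * rate) + 1L
    idx <- i0 + rel
    if (idx[1] < 1L || idx[length(idx)] > n) next
    keep <- c(keep, i)
    slices[[length(slices) + 1L]] <- recording$data[, idx, drop = FALSE]
  }
  if (length(keep) < nrow(ev))
    warning(nrow(ev) - length(keep),
            " event(s) too close to the recording edge were dropped")
  if (!length(keep)) stop("no events fit inside the recording")
  data <- array(0, c(length(keep), nrow(recording$data), nsamp))
  for (k in seq_along(slices)) data[k, , ] <- slices[[k]]
  structure(list(data = data, times = times, rate = rate,
                 labels = recording$labels, event_ids = keep,
                 baseline = NULL),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs x %d channels x %d samples (%g..%g s)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times)))
  invisible(x)
}

#' Event-related potential
#'
#' Arithmetic mean across epochs per channel and sample.
#'
#' @param epochs an `eeg_epochs`.
#' @return an `eeg_erp`: `erp` (channels x samples), `times`, `rate`,
#'   `labels`, `n_epochs`.
#' @export
compute_erp <- function(epochs) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  erp <- apply(epochs$data, c(2, 3), mean)
  rownames(erp) <- epochs$labels
  structure(list(erp = erp, times = epochs$times, rate = epochs$rate,
                 labels = epochs$labels, n_epochs = dim(epochs$data)[1]),
            class = "eeg_erp")
}

#' @export
print.eeg_erp <- function(x, ...) {
  cat(sprintf("<eeg_erp> %d channels x %d samples, mean of %d epochs\n",
              nrow(x$erp), ncol(x$erp), x$n_epochs))
  invisible(x)
}

#' ERP image
#'
#' The trials x time matrix of single-epoch potentials for one channel,
#' optionally trial-sorted and vertically boxcar-smoothed - the standard
#' single-trial visualisation. Column means of the unsmoothed image equal
#' that channel's ERP.
#'
#' @param epochs an `eeg_epochs`.
#' @param channel channel label.
#' @param sort_key optional numeric, one value per trial; rows are ordered
#'   by it (default: event order).
#' @param smooth_trials odd integer >= 1, boxcar width across trials.
#' @return trials x samples matrix.
#' @export
erp_image <- function(epochs, channel, sort_key = NULL, smooth_trials = 1L) {
  ci <- match(channel, epochs$labels)
  if (is.na(ci)) stop("unknown channel: ", channel)
  ntr <- dim(epochs$data)[1]
  if (smooth_trials %% 2 == 0 || smooth_trials < 1)
    stop("smooth_trials must be odd and >= 1")
  if (smooth_trials > ntr)
    stop("smooth_trials exceeds the number of trials")
  img <- epochs$data[, ci, , drop = TRUE]
  if (ntr == 1) img <- matrix(img, 1)
  if (!is.null(sort_key)) {
    if (length(sort_key) != ntr) stop("sort_key must have one value per trial")
    img <- img[order(sort_key), , drop = FALSE]
  }
  if (smooth_trials > 1) {
    half <- (smooth_trials - 1L) / 2L
    sm <- img
    for (r in seq_len(ntr)) {
      lo <- max(1L, r - half)
      hi <- min(ntr, r + half)
      sm[r, ] <- colMeans(img[lo:hi, , drop = FALSE])
    }
    img <- sm
  }
  img
}

#' Channel power spectrum
#'
#' Welch spectrum of one channel of a recording, or the across-epoch
#' average Welch spectrum for epoched data, restricted to `band`.
#'
#' @param x an [eeg_recording()] or `eeg_epochs`.
#' @param channel channel label.
#' @param band length-2 numeric frequency band, Hz.
#' @param seg_s Welch segment length, s.
#' @return list with `freq` and `power` (uV^2/Hz).
#' @export
channel_spectrum <- function(x, channel, band = NULL, seg_s = 2) {
  if (inherits(x, "eeg_recording")) {
    ci <- match(channel, x$labels)
    if (is.na(ci)) stop("unknown channel: ", channel)
    sp <- welch_psd(x$data[ci, ], x$rate, seg_s = seg_s)
  } else if (inherits(x, "eeg_epochs")) {
    ci <- match(channel, x$labels)
    if (is.na(ci)) stop("unknown channel: ", channel)
    ntr <- dim(x$data)[1]
    sps <- lapply(seq_len(ntr), function(k)
      welch_psd(x$data[k, ci, ], x$rate,
                seg_s = min(seg_s, length(x$times) / x$rate)))
    sp <- list(freq = sps[[1]]$freq,
               psd = Reduce(`+`, lapply(sps, `[[`, "psd")) / ntr)
  } else stop("x must be an eeg_recording or eeg_epochs")
  if (is.null(band)) band <- c(0, x$rate / 2)
  if (band[1] >= band[2]) stop("band must be an increasing pair")
  sel <- sp$freq >= band[1] & sp$freq <= band[2]
  if (!any(sel)) stop("band contains no frequency bins")
  list(freq = sp$freq[sel], power = sp$psd[sel])
}

#' Per-component contributions to an ERP
#'
#' The back-projection of each independent component through the ERP:
#' `contribution_k = mixing[, k] %*% (unmixing[k, ] %*% erp)`. Within the
#' subspace the decomposition spans, the contributions sum to the ERP.
#' Components are ranked by percent variance accounted for,
#' `pvaf_k = 100 (1 - var(erp - contribution_k) / var(erp))` (EEGLAB
#' convention; variance pooled over channels and samples).
#'
#' @param erp an `eeg_erp`.
#' @param decomp an `eeg_ica` fit on data with the same channels.
#' @return list with `contributions` (list of channels x samples matrices)
#'   and `pvaf` (percent, one per component).
#' @export
component_contributions <- function(erp, decomp) {
  if (!identical(erp$labels, decomp$labels))
    stop("ERP and decomposition channel labels differ")
  E <- erp$erp
  k <- nrow(decomp$unmixing)
  contribs <- vector("list", k)
  pvaf <- numeric(k)
  tot <- var(as.vector(E))
  for (i in seq_len(k)) {
    ci <- decomp$mixing[, i, drop = FALSE] %*%
      (decomp$unmixing[i, , drop = FALSE] %*% E)
    rownames(ci) <- erp$labels
    contribs[[i]] <- ci
    pvaf[i] <- if (tot > 0) 100 * (1 - var(as.vector(E - ci)) / tot) else 0
  }
  list(contributions = contribs, pvaf = pvaf)
}

#' ERP envelopes with top component contributions
#'
#' The data envelope is the pointwise min and max of the ERP over channels;
#' the `k_top` components with the largest pvaf contribute their own
#' envelopes, the standard way of showing which sources dominate an ERP.
#'
#' @param erp an `eeg_erp`.
#' @param contributions result of [component_contributions()].
#' @param k_top how many components to keep (default 5).
#' @return list with `times`, `env_min`, `env_max`, `selected_components`,
#'   `pvaf` (of the selected), and `component_envelopes` (list of
#'   `min`/`max` pairs).
#' @export
erp_envelope <- function(erp, contributions, k_top = 5) {
  k_top <- min(k_top, length(contributions$contributions))
  sel <- order(contributions$pvaf, decreasing = TRUE)[seq_len(k_top)]
  comp_env <- lapply(sel, function(i) {
    ci <- contributions$contributions[[i]]
    list(min = apply(ci, 2, min), max = apply(ci, 2, max))
  })
  list(times = erp$times,
       env_min = apply(erp$erp, 2, min),
       env_max = apply(erp$erp, 2, max),
       selected_components = sel,
       pvaf = contributions$pvaf[sel],
       component_envelopes = comp_env)
}

#' Scalp interpolation grid
#'
#' Thin-plate-spline interpolation of per-channel values onto a square grid
#' over the unit disc (the 2D montage projection), with pixels outside the
#' disc set to NA. TPS interpolates exactly at the electrodes and
#' reproduces affine fields exactly.
#'
#' @param values named numeric vector, one value per channel.
#' @param montage an `eeg_montage` covering those channels.
#' @param resolution grid side length in pixels.
#' @return resolution x resolution matrix; rows index y from +1 (front) to
#'   -1, columns x from -1 to +1.
#' @export
topographic_grid <- function(values, montage, resolution = 64) {
  if (!all(is.finite(values))) stop("values must be finite")
  labs <- names(values)
  if (is.null(labs)) {
    if (length(values) != length(montage$labels))
      stop("unnamed values must match the montage length")
    labs <- montage$labels
  }
  P <- montage$pos2d[match(labs, montage$labels), , drop = FALSE]
  if (anyNA(P)) stop("montage lacks positions for some channels")
  if (nrow(P) < 4) stop("need at least 4 channels to interpolate")
  if (anyDuplicated(round(P, 10))) stop("duplicate electrode positions")
  n <- nrow(P)
  D <- as.matrix(dist(P))
  Km <- ifelse(D > 0, D^2 * log(D), 0)
  A <- rbind(cbind(Km, 1, P),
             cbind(t(cbind(1, P)), matrix(0, 3, 3)))
  rhs <- c(values, 0, 0, 0)
  coefs <- solve(A + diag(1e-10, n + 3), rhs)
  g <- seq(-1, 1, length.out = resolution)
  grid <- matrix(NA_real_, resolution, resolution)
  for (r in seq_len(resolution)) {
    y <- g[resolution - r + 1]
    for (c in seq_len(resolution)) {
      x <- g[c]
      if (x^2 + y^2 > 1) next
      d <- sqrt((P[, 1] - x)^2 + (P[, 2] - y)^2)
      k <- ifelse(d > 0, d^2 * log(d), 0)
      grid[r, c] <- sum(coefs[seq_len(n)] * k) + coefs[n + 1] +
        coefs[n + 2] * x + coefs[n + 3] * y
    }
  }
  grid
}
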