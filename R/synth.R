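# Synthetic annotated scalp EEG.
#
# The generator emulates the statistical structure the downstream analysis
# assumes of long-term clinical monitoring data: spatially correlated
# pink-noise background with a posterior alpha rhythm, focal 3 Hz
# spike-and-wave seizures concentrated on a configurable electrode set,
# frontally weighted ocular blinks, temporally weighted EMG bursts and
# mains interference. Each nuisance source is rank-1 in space (one fixed
# scalp pattern times a time course), which is what makes it a recoverable
# independent component rather than a head-model simulation.

#' Synthetic EEG configuration
#'
#' Collects every knob of the generator with clinically plausible defaults:
#' 29 channels at 256 Hz, 20 uV RMS pink background, 30 uV alpha on the
#' occiput, 3 Hz spike-and-wave seizures of 150 uV peak-to-trough focused on
#' Cz/Pz/Fp2 with 30% propagation elsewhere, seizures of mean 30 s (sd 5 s)
#' separated by at least 15 s, 4 blinks/min of 120 uV on the frontopolar
#' row, 1 EMG burst/min of 30 uV RMS on the temporal rows, and 5 uV of
#' 50 Hz mains.
#'
#' @param n_channels number of channels (labels taken from
#'   [clinical_channels()] when 29, else a subset/superset must be supplied
#'   via `labels`).
#' @param labels channel labels; default the 29-channel clinical set.
#' @param rate sampling rate, Hz (integer).
#' @param duration recording length, seconds.
#' @param seizure_count number of seizures to plant (0 allowed for control
#'   runs).
#' @param seizure_duration_s mean ictal segment length, s.
#' @param seizure_duration_jitter_s sd of segment length, s.
#' @param min_gap_s minimum interictal gap between planted segments, s.
#' @param sw_freq spike-wave repetition rate, Hz.
#' @param sw_amplitude peak-to-trough amplitude of the planted complexes on
#'   focus channels, uV.
#' @param focus_channels labels carrying the full seizure amplitude.
#' @param propagation_factor amplitude fraction on non-focus channels, 0-1.
#' @param background_rms per-channel RMS of the pink background, uV.
#' @param alpha_amplitude peak amplitude of the 10 Hz posterior rhythm, uV.
#' @param blink_rate ocular blinks per minute.
#' @param blink_amplitude blink peak amplitude at Fp1/Fp2, uV.
#' @param emg_burst_rate EMG bursts per minute.
#' @param emg_amplitude EMG burst RMS at the strongest temporal channel, uV.
#' @param line_freq mains frequency, Hz (50 by default; set 60 where
#'   applicable).
#' @param line_amplitude mains sinusoid amplitude, uV.
#' @param seed integer seed; every stochastic choice in the generator is a
#'   pure function of it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_channels = 29, labels = NULL, rate = 256,
                         duration = 600, seizure_count = 3,
                         seizure_duration_s = 30,
                         seizure_duration_jitter_s = 5,
                         min_gap_s = 15,
                         sw_freq = 3, sw_amplitude = 150,
                         focus_channels = c("Cz", "Pz", "Fp2"),
                         propagation_factor = 0.3,
                         background_rms = 20, alpha_amplitude = 30,
                         blink_rate = 4, blink_amplitude = 120,
                         emg_burst_rate = 1, emg_amplitude = 30,
                         line_freq = 50, line_amplitude = 5,
                         seed = 1L) {
  if (is.null(labels)) {
    if (n_channels == 29) labels <- clinical_channels()
    else labels <- clinical_channels()[seq_len(n_channels)]
  }
  cfg <- list(n_channels = length(labels), labels = labels, rate = rate,
              duration = duration, seizure_count = seizure_count,
              seizure_duration_s = seizure_duration_s,
              seizure_duration_jitter_s = seizure_duration_jitter_s,
              min_gap_s = min_gap_s, sw_freq = sw_freq,
              sw_amplitude = sw_amplitude, focus_channels = focus_channels,
              propagation_factor = propagation_factor,
              background_rms = background_rms,
              alpha_amplitude = alpha_amplitude,
              blink_rate = blink_rate, blink_amplitude = blink_amplitude,
              emg_burst_rate = emg_burst_rate, emg_amplitude = emg_amplitude,
              line_freq = line_freq, line_amplitude = line_amplitude,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$duration <= 0) stop("duration must be > 0")
  if (cfg$rate <= 0 || cfg$rate %% 1 != 0)
    stop("rate must be a positive integer (Hz)")
  amps <- c(cfg$sw_amplitude, cfg$background_rms, cfg$alpha_amplitude,
            cfg$blink_amplitude, cfg$emg_amplitude, cfg$line_amplitude)
  if (any(amps < 0)) stop("all amplitudes must be >= 0")
  if (cfg$propagation_factor < 0 || cfg$propagation_factor > 1)
    stop("propagation_factor must lie in [0, 1]")
  if (cfg$seizure_count < 0) stop("seizure_count must be >= 0")
  if (cfg$seizure_count > 0 &&
      cfg$seizure_count * (cfg$seizure_duration_s + cfg$min_gap_s) >=
      cfg$duration)
    stop("seizures do not fit: seizure_count * (duration + gap) must be ",
         "less than the recording duration")
  invisible(cfg)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  force(expr)
}

# pink noise by spectral shaping: white spectrum scaled by f^(-1/2), giving
# a 1/f power spectrum (log-log slope -1); unit variance per column.
# Generates k independent traces in one batched FFT.
pink_noise <- function(n, k = 1L) {
  m <- next_fast_n(n)
  W <- mvfft(matrix(rnorm(m * k), m, k))
  shape <- c(1, seq_len(m - 1))^(-0.5)
  shape[1] <- shape[2]             # guard DC
  X <- Re(mvfft(W * shape, inverse = TRUE)) / m
  X <- X[seq_len(n), , drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  X <- sweep(X, 2, apply(X, 2, sd), `/`)
  if (k == 1L) X[, 1] else X
}

#' Generate interictal background EEG
#'
#' Spatially correlated pink noise scaled to `background_rms` per channel,
#' plus a posterior-dominant 10 Hz alpha rhythm with a slow waxing-waning
#' envelope. Channels mix a small set of latent pink sources through
#' distance-based weights, so common-average referencing and ICA operate on
#' genuinely correlated data.
#'
#' @param config a [synth_config()].
#' @return an [eeg_recording()] with no annotations.
#' @export
generate_background <- function(config) {
  validate_synth_config(config)
  n <- round(config$duration * config$rate)
  if (n < 2) stop("duration too short")
  nch <- config$n_channels
  mont <- standard_montage(config$labels)
  with_seed(config$seed, {
    # latent pink sources anchored at spread scalp sites
    anchors <- c("Fz", "Cz", "Pz", "Oz", "T3", "T4", "F7", "F8")
    apos <- standard_montage(anchors)$pos2d
    S <- pink_noise(n, length(anchors))
    D <- as.matrix(dist(rbind(mont$pos2d, apos)))[seq_len(nch),
                                                  nch + seq_along(anchors)]
    Wmix <- exp(-(D / 0.6)^2)
    X <- Wmix %*% t(S)
    X <- X + 0.5 * t(pink_noise(n, nch))
    if (config$background_rms > 0) {
      rms <- sqrt(rowMeans(X^2))
      X <- X * (config$background_rms / rms)
    } else X[] <- 0
    if (config$alpha_amplitude > 0) {
      t_s <- (seq_len(n) - 1) / config$rate
      env <- 0.5 * (1 + sin(2 * pi * 0.1 * t_s + runif(1, 0, 2 * pi)))
      alpha <- sin(2 * pi * 10 * t_s + runif(1, 0, 2 * pi)) * env
      occ <- exp(-(rowSums(sweep(mont$pos2d, 2, c(0, -0.8))^2)) / 0.4^2)
      X <- X + config$alpha_amplitude * (occ %o% alpha)
    }
    eeg_recording(X, rate = config$rate, labels = config$labels)
  })
}

# one spike-wave cycle: biphasic Gaussian-derivative spike (~70 ms wide)
# followed by a half-sine slow wave of opposite polarity filling the rest of
# the cycle; normalized to unit peak-to-trough
sw_cycle <- function(rate, sw_freq) {
  nT <- round(rate / sw_freq)
  t <- (seq_len(nT) - 1) / rate
  cyc <- numeric(nT)
  # spike occupies the first ~70 ms
  sp_w <- 0.070
  sig <- sp_w / 6
  tc <- sp_w / 2
  g <- -(t - tc) / sig * exp(-((t - tc)^2) / (2 * sig^2))
  g[t > sp_w] <- 0
  cyc <- cyc + g / max(abs(g))
  # slow wave over the remainder, opposite polarity, 60% of spike height
  wave_idx <- t > sp_w
  tw <- t[wave_idx] - sp_w
  wdur <- max(tw) + 1 / rate
  cyc[wave_idx] <- cyc[wave_idx] - 0.9 * sin(pi * tw / wdur)
  cyc / (max(cyc) - min(cyc))
}

# Exact uniform placement: the free time left after segments, inter-segment
# gaps and 1 s edge margins is split by uniform order statistics, so every
# admissible configuration is equally likely and no rejection loop is
# needed. The gap constrains spacing between segments only.
place_segments <- function(count, seg_len, total, gap) {
  margin <- 1
  free <- total - 2 * margin - sum(seg_len) - (count - 1) * gap
  if (free <= 0)
    stop("could not place ", count, " non-overlapping seizures with gap ",
         gap, " s in ", total, " s; reduce count or duration")
  slack <- sort(runif(count, 0, free))
  margin + slack + c(0, cumsum(seg_len[-count] + gap))
}

#' Plant spike-and-wave seizures
#'
#' Adds `seizure_count` non-overlapping ictal segments at uniform random
#' onsets (respecting `min_gap_s`). Each segment is a train of
#' spike-and-wave complexes at `sw_freq` - a narrow biphasic spike followed
#' by a half-sine slow wave - with `sw_amplitude` peak-to-trough on the
#' focus channels and `propagation_factor` of that elsewhere, tapered with
#' raised-cosine ramps. One `seizure` annotation per segment.
#'
#' @param recording background from [generate_background()].
#' @param config the same [synth_config()].
#' @return the recording with ictal activity and annotations added.
#' @export
inject_seizures <- function(recording, config) {
  if (config$seizure_count == 0) return(recording)
  rate <- recording$rate
  n <- ncol(recording$data)
  total <- n / rate
  with_seed(config$seed + 1L, {
    durs <- rnorm(config$seizure_count, config$seizure_duration_s,
                  config$seizure_duration_jitter_s)
    durs <- pmax(durs, 5)
    onsets <- place_segments(config$seizure_count, durs, total,
                             config$min_gap_s)
    cyc <- sw_cycle(rate, config$sw_freq)
    gains <- ifelse(recording$labels %in% config$focus_channels, 1,
                    config$propagation_factor)
    ann <- recording$annotations
    for (k in seq_len(config$seizure_count)) {
      nseg <- round(durs[k] * rate)
      ncyc <- ceiling(nseg / length(cyc))
      # small per-cycle amplitude jitter for realism
      amp <- rep(1 + 0.05 * rnorm(ncyc), each = length(cyc))[seq_len(nseg)]
      train <- rep(cyc, ncyc)[seq_len(nseg)] * amp
      ramp_n <- round(0.5 * rate)
      taper <- rep(1, nseg)
      up <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
      taper[seq_len(ramp_n)] <- up
      taper[nseg + 1 - seq_len(ramp_n)] <- up
      train <- train * taper * config$sw_amplitude
      i0 <- round(onsets[k] * rate)
      idx <- i0 + seq_len(nseg)
      recording$data[, idx] <- recording$data[, idx] + gains %o% train
      ann <- rbind(ann, data.frame(onset = onsets[k], duration = durs[k],
                                   label = "seizure",
                                   seizure_type = "IAS",
                                   stringsAsFactors = FALSE))
    }
    recording$annotations <- validate_annotations(ann, n, rate)
    recording
  })
}

#' Add ocular, muscle and mains artifacts
#'
#' Blinks are ~300 ms half-cosine transients with a fixed frontally peaked
#' scalp pattern (maximal at Fp1/Fp2, decaying with scalp distance), at
#' Poisson rate `blink_rate` per minute. EMG bursts are 20-70 Hz bandpassed
#' noise of 0.5-2 s with a temporally weighted pattern (left or right
#' hemisphere per burst), at `emg_burst_rate` per minute. A `line_freq`
#' sinusoid is added to all channels with slightly varying per-channel gain.
#' Blinks and EMG bursts get `artifact` annotations. Zero rates/amplitudes
#' are exact no-ops.
#'
#' @param recording an [eeg_recording()].
#' @param config the [synth_config()].
#' @return the recording with artifacts added.
#' @export
inject_artifacts <- function(recording, config) {
  rate <- recording$rate
  n <- ncol(recording$data)
  total <- n / rate
  mont <- standard_montage(recording$labels)
  with_seed(config$seed + 2L, {
    ann <- recording$annotations
    if (config$blink_rate > 0 && config$blink_amplitude > 0) {
      w <- exp(-rowSums(sweep(mont$pos2d, 2, c(0, 0.95))^2) / 0.35^2)
      w <- w / max(w)
      nb <- rpois(1, config$blink_rate * total / 60)
      times <- sort(runif(nb, 0.5, total - 0.5))
      blen <- round(0.3 * rate)
      pulse <- 0.5 * (1 - cos(2 * pi * seq_len(blen) / blen))
      for (tb in times) {
        idx <- round(tb * rate) + seq_len(blen)
        amp <- config$blink_amplitude * runif(1, 0.8, 1.2)
        recording$data[, idx] <- recording$data[, idx] + (w * amp) %o% pulse
        ann <- rbind(ann, data.frame(onset = tb, duration = 0.3,
                                     label = "artifact",
                                     seizure_type = NA_character_,
                                     stringsAsFactors = FALSE))
      }
    }
    if (config$emg_burst_rate > 0 && config$emg_amplitude > 0) {
      sides <- list(
        left  = exp(-rowSums(sweep(mont$pos2d, 2, c(-0.85, -0.1))^2) / 0.35^2),
        right = exp(-rowSums(sweep(mont$pos2d, 2, c(0.85, -0.1))^2) / 0.35^2))
      sides <- lapply(sides, function(w) w / max(w))
      ne <- rpois(1, config$emg_burst_rate * total / 60)
      times <- sort(runif(ne, 1, total - 3))
      for (tb in times) {
        dur <- runif(1, 0.5, 2)
        blen <- round(dur * rate)
        burst <- bandpass_fft(rnorm(blen), rate, 20, min(70, rate / 2 - 1))
        burst <- burst / sqrt(mean(burst^2)) * config$emg_amplitude
        ramp <- round(0.05 * rate)
        tap <- rep(1, blen)
        tap[seq_len(ramp)] <- seq_len(ramp) / ramp
        tap[blen + 1 - seq_len(ramp)] <- rev(seq_len(ramp) / ramp)
        w <- sides[[sample(1:2, 1)]]
        idx <- round(tb * rate) + seq_len(blen)
        recording$data[, idx] <- recording$data[, idx] + w %o% (burst * tap)
        ann <- rbind(ann, data.frame(onset = tb, duration = dur,
                                     label = "artifact",
                                     seizure_type = NA_character_,
                                     stringsAsFactors = FALSE))
      }
    }
    if (config$line_amplitude > 0) {
      t_s <- (seq_len(n) - 1) / rate
      gains <- runif(config$n_channels, 0.8, 1.2)
      line <- sin(2 * pi * config$line_freq * t_s + runif(1, 0, 2 * pi))
      recording$data <- recording$data +
        (config$line_amplitude * gains) %o% line
    }
    recording$annotations <- validate_annotations(ann, n, rate)
    recording
  })
}

# ideal FFT brick-wall bandpass; used only inside the generator where
# transition sharpness is irrelevant
bandpass_fft <- function(x, rate, lo, hi) {
  n <- length(x)
  f <- (seq_len(n) - 1) / n * rate
  f <- pmin(f, rate - f)
  keep <- f >= lo & f <= hi
  Re(fft(fft(x) * keep, inverse = TRUE)) / n
}

#' Generate one fully annotated synthetic recording
#'
#' Convenience composition of [generate_background()], [inject_seizures()]
#' and [inject_artifacts()].
#'
#' @param config a [synth_config()].
#' @return an [eeg_recording()].
#' @export
synth_recording <- function(config) {
  inject_artifacts(inject_seizures(generate_background(config), config),
                   config)
}

#' Generate a synthetic patient cohort
#'
#' Emulates a clinical cohort in which patients are grouped by seizure
#' count. Per-patient seeds are derived deterministically from the master
#' seed, so the same seed always reproduces the same cohort bitwise.
#'
#' @param group_sizes named integer vector mapping seizure count to number
#'   of patients, e.g. `c("3" = 3, "4" = 2, "5" = 2)`.
#' @param config_overrides list of [synth_config()] arguments applied to
#'   every patient (e.g. `list(sw_amplitude = 100)`), or a list of such
#'   lists named by seizure count for per-group settings.
#' @param seed master integer seed.
#' @return list of patients, each `list(patient_id, seizure_count, config,
#'   recording)`.
#' @export
generate_cohort <- function(group_sizes, config_overrides = list(),
                            seed = 1L) {
  if (!length(group_sizes)) stop("group_sizes must be non-empty")
  counts <- as.integer(names(group_sizes))
  if (anyNA(counts)) stop("group_sizes must be named by seizure count")
  per_group <- !is.null(names(config_overrides)) &&
    all(names(config_overrides) %in% names(group_sizes))
  out <- list()
  pid <- 0L
  for (g in seq_along(group_sizes)) {
    ov <- if (per_group) config_overrides[[names(group_sizes)[g]]]
          else config_overrides
    if (is.null(ov)) ov <- list()
    for (p in seq_len(group_sizes[[g]])) {
      pid <- pid + 1L
      pseed <- as.integer((as.numeric(seed) * 131 + 100 + pid) %% 2147483647)
      args <- ov
      args$seizure_count <- counts[g]
      args$seed <- pseed
      cfg <- do.call(synth_config, args)
      out[[pid]] <- list(patient_id = sprintf("P%02d", pid),
                         seizure_count = counts[g], config = cfg,
                         recording = synth_recording(cfg))
    }
  }
  out
}
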