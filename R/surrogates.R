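# Synthetic benchmark surrogates.
#
# The package's quantitative claims are evaluated on fully synthetic
# cohorts under fixed, stated generator conditions: three seizure-count
# groups of increasing difficulty (amplitude falling, background and EMG
# rising), and ERP stability fixtures with controlled per-epoch amplitude
# variability. These functions define those conditions in one place so the
# test suite and the acceptance script cannot drift apart.

#' Benchmark group conditions
#'
#' Three-patient groups at 10 min / 256 Hz / 29 channels:
#' 3 seizures at 150 uV spike-wave on 20 uV RMS background,
#' 4 seizures at 100 uV on 25 uV, and
#' 5 seizures at 60 uV on 30 uV with 3 EMG bursts/min - the last being the
#' hardest condition. Blinks 4/min, EMG 1/min (except group 5), 5 uV mains
#' throughout.
#'
#' @return named list of group definitions consumable by
#'   [pipeline_config()]'s `groups` entries.
#' @export
benchmark_groups <- function() {
  list(
    "3" = list(seizure_count = 3, n_patients = 3,
               synth = list(duration = 600, sw_amplitude = 150,
                            background_rms = 20)),
    "4" = list(seizure_count = 4, n_patients = 3,
               synth = list(duration = 600, sw_amplitude = 100,
                            background_rms = 25)),
    "5" = list(seizure_count = 5, n_patients = 3,
               synth = list(duration = 600, sw_amplitude = 60,
                            background_rms = 30, emg_burst_rate = 3)))
}

#' Mean detector accuracy for one benchmark group
#'
#' Runs the full pipeline (filter, CAR, ICA clean, bad-segment mask,
#' sliding PPAF, leave-one-patient-out threshold) on freshly generated
#' cohorts for each master seed and averages the group window accuracy.
#'
#' @param group one entry of [benchmark_groups()].
#' @param master_seeds integer vector of pipeline seeds.
#' @return mean accuracy in percent.
#' @export
benchmark_accuracy <- function(group, master_seeds) {
  accs <- vapply(master_seeds, function(s) {
    cfg <- pipeline_config(seed = s, groups = list(group))
    run_pipeline(cfg)$groups[[as.character(group$seizure_count)]]$accuracy
  }, numeric(1))
  mean(accs)
}

#' ERP stability surrogate
#'
#' Builds an ERP from `n_epochs` repetitions of a 3 Hz spike-wave template
#' (peak-to-trough `base_p2p` uV) with per-epoch multiplicative amplitude
#' jitter and additive white noise, then reports the PPAF stability
#' percentage of the averaged waveform - the surrogate for waveform
#' stability across recorded seizures.
#'
#' @param n_epochs number of epochs averaged.
#' @param amplitude_jitter sd of the per-epoch multiplicative amplitude
#'   factor (e.g. 0.02 for a 2% coefficient of variation).
#' @param noise_sd additive white-noise sd per sample, uV.
#' @param base_p2p template peak-to-trough amplitude, uV.
#' @param rate sampling rate, Hz.
#' @param sw_freq spike-wave repetition rate, Hz.
#' @param duration_s epoch length, s.
#' @param seed integer seed.
#' @return a `ppaf_result` for the ERP trace (see [compute_ppaf()]).
#' @export
erp_stability_surrogate <- function(n_epochs = 50, amplitude_jitter = 0.02,
                                    noise_sd = 1, base_p2p = 100,
                                    rate = 256, sw_freq = 3,
                                    duration_s = 2, seed = 42) {
  cyc <- sw_cycle(rate, sw_freq)
  n <- round(duration_s * rate)
  template <- rep(cyc, ceiling(n / length(cyc)))[seq_len(n)] * base_p2p
  with_seed(seed, {
    epochs <- vapply(seq_len(n_epochs), function(i)
      template * (1 + rnorm(1, 0, amplitude_jitter)) + rnorm(n, 0, noise_sd),
      numeric(n))
    erp <- rowMeans(epochs)
    compute_ppaf(detect_pairs(erp, rate))
  })
}
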