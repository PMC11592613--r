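# planted-source fixtures --------------------------------------------------

# mixes k sources into m channels with a random well-conditioned matrix
mix_sources <- function(S, m, seed = 1) {
  k <- nrow(S)
  set.seed(seed)
  A <- matrix(rnorm(m * k), m, k)
  eeg_recording(A %*% S, rate = 256,
                labels = clinical_channels()[seq_len(m)])
}

# activations matched greedily to sources by absolute correlation
matched_cors <- function(decomp, S) {
  k <- nrow(S)
  C <- abs(cor(t(decomp$activations), t(S)))
  out <- numeric(k)
  for (i in seq_len(k)) {
    j <- which(C == max(C), arr.ind = TRUE)[1, ]
    out[i] <- C[j[1], j[2]]
    C[j[1], ] <- -1; C[, j[2]] <- -1
  }
  out
}

test_that("ICA recovers two planted sources from a 3-channel mixture", {
  n <- 256 * 30
  t <- (0:(n - 1)) / 256
  saw <- 2 * ((t * 4) %% 1) - 1                       # sawtooth, sub-Gaussian
  set.seed(3)
  spiky <- rnorm(n) * (runif(n) < 0.05)               # sparse, super-Gaussian
  S <- rbind(saw, spiky)
  rec <- mix_sources(S, 3)
  d <- fit_ica(rec, n_components = 2, seed = 1)
  expect_true(all(matched_cors(d, S) >= 0.95))
})

test_that("solutions from different seeds agree up to permutation and sign", {
  n <- 256 * 30
  set.seed(4)
  S <- rbind(rnorm(n)^3, 2 * ((seq_len(n) / 97) %% 1) - 1,
             rnorm(n) * (runif(n) < 0.1))
  rec <- mix_sources(S, 5, seed = 2)
  d1 <- fit_ica(rec, n_components = 3, seed = 10)
  d2 <- fit_ica(rec, n_components = 3, seed = 77)
  C <- abs(cor(t(d1$activations), t(d2$activations)))
  # greedy matching between the two solutions
  best <- apply(C, 1, max)
  expect_true(all(best >= 0.95))
})

test_that("ICA recovers four super-Gaussian sources in ten channels", {
  n <- 256 * 40
  set.seed(6)
  S <- rbind(rnorm(n)^3,
             rnorm(n) * (runif(n) < 0.05),
             sign(rnorm(n)) * rexp(n)^1.5,
             rnorm(n) * rbinom(n, 1, 0.2))
  rec <- mix_sources(S, 10, seed = 3)
  d <- fit_ica(rec, n_components = 4, seed = 1)
  expect_gte(mean(matched_cors(d, S)), 0.95)
})

test_that("white isotropic Gaussian data does not crash and yields flat components", {
  set.seed(8)
  rec <- eeg_recording(matrix(rnorm(5 * 256 * 20), 5), rate = 256,
                       labels = clinical_channels()[1:5])
  d <- fit_ica(rec, seed = 1)
  kurt <- apply(d$activations, 1, ppafseiz:::excess_kurtosis)
  expect_true(all(abs(kurt) < 1))
  sc <- score_components(d)
  expect_true(all(!sc$is_artifact[sc$reason == "ocular"]))
})

test_that("back-projection with all components reconstructs the input", {
  cfg <- quick_config(duration = 30, seizure_count = 0, seed = 12)
  rec <- common_average_reference(bandpass(generate_background(cfg)))
  d <- fit_ica(rec, seed = 1)
  recon <- d$mixing %*% d$activations + d$means
  expect_lt(max(abs(recon - rec$data)), 1e-6)
  # unmixing/mixing are mutual inverses on the retained subspace
  expect_lt(max(abs(d$unmixing %*% d$mixing - diag(nrow(d$unmixing)))), 1e-6)
  # components come ordered by explained variance
  expect_true(all(diff(d$explained_var) <= 1e-12))
})

test_that("component scoring flags planted ocular, line and neural sources correctly", {
  cfg <- quick_config(duration = 60, seizure_count = 0, blink_rate = 6,
                      emg_burst_rate = 0, line_amplitude = 0, seed = 14)
  rec <- common_average_reference(bandpass(synth_recording(cfg)))
  d <- fit_ica(rec, seed = 1)
  sc <- score_components(d)
  expect_true(any(sc$reason == "ocular"))
  # the ocular component is frontal and heavy-tailed by construction
  oc <- sc[sc$reason == "ocular", ][1, ]
  expect_gt(oc$frontal_weight, 0.6)
  expect_gt(oc$kurtosis, 5)
  # a hand-built pure 50 Hz component scores as line
  n <- 256 * 20
  line <- sin(2 * pi * 50 * (0:(n - 1)) / 256)
  set.seed(15)
  S <- rbind(line, rnorm(n) * (runif(n) < 0.1))
  d2 <- fit_ica(mix_sources(S, 4, seed = 5), n_components = 2, seed = 2)
  sc2 <- score_components(d2)
  li <- which.max(sc2$line_power_ratio)
  expect_equal(sc2$reason[li], "line")
  # a planted posterior alpha source is not flagged
  alpha_cfg <- quick_config(duration = 60, seizure_count = 0, blink_rate = 0,
                            emg_burst_rate = 0, line_amplitude = 0,
                            alpha_amplitude = 40, seed = 16)
  reca <- common_average_reference(bandpass(generate_background(alpha_cfg)))
  da <- fit_ica(reca, seed = 1)
  sca <- score_components(da)
  # find the alpha component: largest 8-12 Hz power fraction
  afrac <- vapply(seq_len(nrow(sca)), function(i) {
    sp <- welch_psd(da$activations[i, ], 256)
    band_power(sp$freq, sp$psd, 8, 12) / band_power(sp$freq, sp$psd, 0.5, 125)
  }, numeric(1))
  expect_false(sca$is_artifact[which.max(afrac)])
})

test_that("rejecting the blink component removes blinks but spares alpha", {
  cfg <- quick_config(duration = 120, seizure_count = 0, blink_rate = 8,
                      emg_burst_rate = 0, line_amplitude = 0,
                      alpha_amplitude = 30, seed = 17)
  rec <- synth_recording(cfg)
  cr <- common_average_reference(bandpass(rec))
  d <- fit_ica(cr, seed = 1)
  sc <- score_components(d)
  clean <- reject_components(cr, d, sc)
  # no flags -> identity
  sc0 <- sc; sc0$is_artifact <- FALSE
  expect_lt(max(abs(reject_components(cr, d, sc0)$data - cr$data)), 1e-6)
  # blink-window RMS on Fp2 drops by at least 70%
  bl <- rec$annotations[rec$annotations$label == "artifact", ]
  idx <- unlist(lapply(bl$onset, function(o) round(o * 256) + seq_len(77)))
  fp2 <- match("Fp2", cr$labels)
  expect_lt(sqrt(mean(clean$data[fp2, idx]^2)),
            0.3 * sqrt(mean(cr$data[fp2, idx]^2)))
  # alpha-band power at O1 changes by under 10%
  a0 <- sum(channel_spectrum(cr, "O1", band = c(8, 12))$power)
  a1 <- sum(channel_spectrum(clean, "O1", band = c(8, 12))$power)
  expect_lt(abs(a1 / a0 - 1), 0.10)
  # energy never increases
  expect_lte(sum(clean$data^2), sum(cr$data^2) * (1 + 1e-9))
  # refusing to reject everything
  scall <- sc; scall$is_artifact <- TRUE
  expect_error(reject_components(cr, d, scall), "refusing")
})

test_that("bad-segment mask flags amplitude glitches and flatlines only", {
  cfg <- quick_config(duration = 30, seizure_count = 0, seed = 18)
  rec <- generate_background(cfg)
  expect_true(all(!detect_bad_segments(rec)))
  # planted 2000 uV glitch at t = 5 s
  rec$data[3, round(5 * 256)] <- 2000
  mask <- detect_bad_segments(rec, amplitude_uV = 500, window_s = 1)
  expect_true(mask[round(5 * 256)])
  expect_true(mask[round(4.6 * 256)])
  expect_true(mask[round(5.4 * 256)])
  expect_false(mask[round(8 * 256)])
  # flatline detection
  rec2 <- generate_background(cfg)
  rec2$data[1, 1000:(1000 + 6 * 256)] <- 1.0
  m2 <- detect_bad_segments(rec2, flatline_s = 5)
  expect_true(m2[1000 + 3 * 256])
  # masked fraction on a default synthetic patient stays small
  full <- synth_recording(quick_config(duration = 60, seed = 19))
  expect_lt(mean(detect_bad_segments(full)), 0.2)
  expect_error(detect_bad_segments(rec, amplitude_uV = -1), "thresholds")
})
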