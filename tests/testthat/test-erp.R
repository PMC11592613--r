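fixture_rec <- function(seed = 4) {
  synth_recording(quick_config(duration = 120, seizure_count = 3,
                               seizure_duration_s = 10, min_gap_s = 10,
                               seed = seed))
}

test_that("epoch extraction is shaped and aligned correctly", {
  rec <- fixture_rec()
  ep <- extract_epochs(rec, "seizure", c(-1, 2))
  expect_equal(dim(ep$data), c(3L, 29L, 768L))
  expect_equal(diff(ep$times)[1], 1 / 256)
  # the t=0 sample equals the recording sample at the annotation onset
  sz <- rec$annotations[rec$annotations$label == "seizure", ]
  i0 <- which.min(abs(ep$times))
  for (k in seq_len(3)) {
    samp <- round(sz$onset[k] * 256) + 1
    expect_equal(ep$data[k, , i0], unname(rec$data[, samp]), tolerance = 1e-12)
  }
  expect_error(extract_epochs(rec, "other"), "no events")
})

test_that("events too close to the recording edge are dropped with a warning", {
  rec <- eeg_recording(matrix(rnorm(2 * 256 * 20), 2), rate = 256,
                       labels = c("Cz", "Pz"),
                       annotations = data.frame(
                         onset = c(0.2, 10), duration = c(1, 1),
                         label = "seizure"))
  expect_warning(ep <- extract_epochs(rec, "seizure", c(-1, 2)), "dropped")
  expect_equal(dim(ep$data)[1], 1L)
})

test_that("the ERP is the epoch mean and concentrates against noise", {
  rec <- fixture_rec()
  ep <- extract_epochs(rec, "seizure", c(-1, 2))
  erp <- compute_erp(ep)
  expect_equal(erp$erp, apply(ep$data, c(2, 3), mean), tolerance = 1e-12,
               ignore_attr = TRUE)
  # single epoch: ERP equals the epoch
  ep1 <- ep; ep1$data <- ep$data[1, , , drop = FALSE]
  expect_equal(compute_erp(ep1)$erp[1, ], ep$data[1, 1, ], tolerance = 1e-12)
  # law of large numbers: signal + noise, n = 200 epochs
  n <- 256
  sig <- sin(2 * pi * 3 * (0:(n - 1)) / 256) * 10
  set.seed(31)
  noise_sd <- 5
  data <- array(rep(sig, each = 200 * 1), c(200, 1, n)) +
    array(rnorm(200 * n, 0, noise_sd), c(200, 1, n))
  ep2 <- structure(list(data = data, times = (0:(n - 1)) / 256, rate = 256,
                        labels = "Cz", event_ids = 1:200, baseline = NULL),
                   class = "eeg_epochs")
  err <- compute_erp(ep2)$erp[1, ] - sig
  expect_lt(sqrt(mean(err^2)), 2 * noise_sd / sqrt(200))
})

test_that("ERP images stack, sort and smooth trials correctly", {
  rec <- fixture_rec()
  ep <- extract_epochs(rec, "seizure", c(-1, 2))
  img <- erp_image(ep, "Cz")
  expect_equal(img, ep$data[, match("Cz", ep$labels), ])
  # column means of the unsmoothed image equal the ERP
  erp <- compute_erp(ep)
  expect_lt(max(abs(colMeans(img) - erp$erp["Cz", ])), 1e-9)
  # sorting permutes rows accordingly
  key <- c(2, 0, 1)
  expect_equal(erp_image(ep, "Cz", sort_key = key), img[order(key), ])
  expect_error(erp_image(ep, "Cz", smooth_trials = 5), "trials")
  expect_error(erp_image(ep, "Cz", smooth_trials = 2), "odd")
})

test_that("Welch spectra satisfy closed forms and Parseval", {
  rate <- 256
  t <- (0:(rate * 64 - 1)) / rate
  A <- 7
  x <- A * sin(2 * pi * 10 * t)
  rec <- eeg_recording(matrix(x, 1), rate = rate, labels = "Cz")
  sp <- channel_spectrum(rec, "Cz", band = c(1, 100))
  expect_equal(sp$freq[which.max(sp$power)], 10, tolerance = 0.5)
  df <- sp$freq[2] - sp$freq[1]
  expect_lt(abs(sum(sp$power) * df - A^2 / 2) / (A^2 / 2), 0.1)
  # white noise: approximately flat with enough averaged segments
  set.seed(41)
  w <- rnorm(rate * 128)
  spw <- welch_psd(w, rate, seg_s = 2)
  sel <- spw$freq > 1 & spw$freq < 120
  expect_lt(max(spw$psd[sel]) / min(spw$psd[sel]), 10)
  # Parseval for the noise
  expect_lt(abs(sum(spw$psd) * (spw$freq[2] - spw$freq[1]) - var(w)) / var(w),
            0.05)
  expect_error(channel_spectrum(rec, "Cz", band = c(50, 10)), "band")
})

test_that("synthetic ictal epochs carry dominant power inside 3-30 Hz", {
  rec <- fixture_rec(seed = 6)
  ep <- extract_epochs(rec, "seizure", c(-0.5, 5))
  sp <- channel_spectrum(ep, "Cz", band = c(0.5, 128), seg_s = 2)
  inband <- sum(sp$power[sp$freq >= 3 & sp$freq <= 30])
  expect_gt(inband / sum(sp$power), 0.5)
})

test_that("component contributions partition the ERP and rank by pvaf", {
  rec <- fixture_rec()
  cr <- common_average_reference(bandpass(rec))
  d <- fit_ica(cr, seed = 1)
  ep <- extract_epochs(cr, "seizure", c(-1, 2))
  erp <- compute_erp(ep)
  cc <- component_contributions(erp, d)
  total <- Reduce(`+`, cc$contributions)
  expect_lt(max(abs(total - erp$erp)), 1e-6)
  env <- erp_envelope(erp, cc, k_top = 5)
  expect_identical(env$selected_components,
                   order(cc$pvaf, decreasing = TRUE)[1:5])
  # data envelope bounds every channel trace pointwise
  for (i in seq_len(nrow(erp$erp))) {
    expect_true(all(erp$erp[i, ] >= env$env_min - 1e-12))
    expect_true(all(erp$erp[i, ] <= env$env_max + 1e-12))
  }
})

test_that("pvaf identifies a planted dominant source and nulls zero components", {
  # hand-built decomposition: 2 channels, 2 components
  n <- 512
  a1 <- sin(2 * pi * 5 * (0:(n - 1)) / 256)
  M <- cbind(c(1, 0.8), c(0, 0))    # second component contributes nothing
  U <- rbind(c(1, 0), c(0, 1))
  d <- structure(list(unmixing = U, mixing = M,
                      activations = rbind(a1, 0), means = c(0, 0),
                      rate = 256, labels = c("Cz", "Pz"), n_iter = 1,
                      explained_var = c(1, 0)), class = "eeg_ica")
  erp <- structure(list(erp = M %*% rbind(a1, 0) |> `rownames<-`(c("Cz", "Pz")),
                        times = (0:(n - 1)) / 256, rate = 256,
                        labels = c("Cz", "Pz"), n_epochs = 1),
                   class = "eeg_erp")
  cc <- component_contributions(erp, d)
  expect_gte(cc$pvaf[1], 95)
  expect_equal(cc$pvaf[2], 0)
  # single-channel envelope degenerates to the trace itself
  erp1 <- structure(list(erp = matrix(a1, 1, dimnames = list("Cz")),
                         times = (0:(n - 1)) / 256, rate = 256,
                         labels = "Cz", n_epochs = 1), class = "eeg_erp")
  d1 <- structure(list(unmixing = matrix(1), mixing = matrix(1),
                       activations = matrix(a1, 1), means = 0, rate = 256,
                       labels = "Cz", n_iter = 1, explained_var = 1),
                  class = "eeg_ica")
  env1 <- erp_envelope(erp1, component_contributions(erp1, d1), k_top = 1)
  expect_equal(env1$env_min, env1$env_max)
  expect_equal(unname(env1$env_min), a1)
})

test_that("topographic interpolation honours electrodes, constants and gradients", {
  m <- standard_montage(clinical_channels())
  ones <- setNames(rep(1, 29), clinical_channels())
  g <- topographic_grid(ones, m, resolution = 41)
  expect_lt(max(abs(g[!is.na(g)] - 1)), 1e-6)
  expect_true(all(is.na(g[1, 1])))                  # corners outside the disc
  # single hot channel at Cz peaks at the central pixel
  hot <- setNames(rep(0, 29), clinical_channels()); hot["Cz"] <- 1
  gh <- topographic_grid(hot, m, resolution = 41)
  expect_equal(unname(which(gh == max(gh, na.rm = TRUE), arr.ind = TRUE)[1, ]),
               c(21, 21))
  # affine field reproduced exactly -> monotone along x
  lin <- setNames(m$pos2d[, "x"], clinical_channels())
  gl <- topographic_grid(lin, m, resolution = 41)
  mid <- gl[21, ]
  expect_true(all(diff(mid[!is.na(mid)]) > 0))
  # grid value at an electrode pixel is within 5% of the electrode value
  set.seed(5)
  v <- setNames(rnorm(29, 10, 2), clinical_channels())
  gv <- topographic_grid(v, m, resolution = 201)
  px <- round((m$pos2d[, "x"] + 1) / 2 * 200) + 1
  py <- 201 - round((m$pos2d[, "y"] + 1) / 2 * 200)
  for (i in seq_len(29)) {
    got <- gv[py[i], px[i]]
    if (!is.na(got)) expect_lt(abs(got - v[i]) / abs(v[i]), 0.05)
  }
  dup <- m; dup$pos2d[2, ] <- dup$pos2d[1, ]
  expect_error(topographic_grid(ones, dup, 21), "duplicate")
})
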