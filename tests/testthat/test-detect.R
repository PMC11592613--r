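test_that("threshold fitting separates separable classes and matches brute force", {
  f <- c(1, 2, 10, 11)
  tr <- c(FALSE, FALSE, TRUE, TRUE)
  th <- fit_threshold(f, tr)
  expect_gt(th, 2); expect_lt(th, 10)
  expect_true(all(classify_windows(f, th) == tr))
  # brute-force oracle over all midpoints
  brute <- function(features, truth) {
    u <- sort(unique(features))
    cand <- (u[-1] + u[-length(u)]) / 2
    ba <- vapply(cand, function(t) {
      p <- features >= t
      (sum(p & truth) / sum(truth) + sum(!p & !truth) / sum(!truth)) / 2
    }, numeric(1))
    cand[which.max(ba)]
  }
  set.seed(51)
  for (i in 1:25) {
    features <- round(c(rnorm(40, 5), rnorm(40, 6.5)), 2)
    truth <- rep(c(FALSE, TRUE), each = 40)
    expect_equal(fit_threshold(features, truth), brute(features, truth))
  }
  expect_error(fit_threshold(c(1, 2), c(TRUE, TRUE)), "both classes")
  expect_error(fit_threshold(1:3, c(TRUE, FALSE)), "length")
})

test_that("indistinguishable classes stay near chance on held-out data", {
  set.seed(52)
  train_f <- rnorm(2000); train_t <- rep(c(TRUE, FALSE), 1000)
  th <- fit_threshold(train_f, train_t)
  test_f <- rnorm(2000); test_t <- rep(c(TRUE, FALSE), 1000)
  acc <- mean(classify_windows(test_f, th) == test_t)
  expect_gt(acc, 0.45); expect_lt(acc, 0.55)
})

test_that("classification tie rule and idempotence", {
  expect_true(classify_windows(5, 5))              # tie -> positive
  expect_true(all(!classify_windows(c(1, 2, 3), 10)))
  p <- classify_windows(c(1, 7, 3), 5)
  expect_identical(classify_windows(as.numeric(p) * 10, 5), p)
  expect_error(classify_windows(1, Inf), "finite")
})

test_that("evaluation computes the confusion matrix and percentages", {
  tr <- c(TRUE, TRUE, FALSE, FALSE)
  r <- evaluate_detection(tr, tr)
  expect_equal(r$accuracy, 100)
  r2 <- evaluate_detection(c(rep(TRUE, 100), rep(FALSE, 100)),
                           c(rep(TRUE, 99), FALSE, TRUE, rep(FALSE, 99)))
  expect_equal(unname(r2$confusion), c(99, 1, 99, 1))   # TP FP TN FN
  expect_equal(r2$accuracy, 99)
  expect_equal(r2$sensitivity, 99)
  expect_equal(r2$specificity, 99)
  expect_equal(sum(r2$confusion), r2$n_windows)
  # random predictions against balanced truth: ~50% over 10000 windows
  set.seed(53)
  acc <- evaluate_detection(runif(10000) > 0.5,
                            rep(c(TRUE, FALSE), 5000))$accuracy
  expect_gt(acc, 47); expect_lt(acc, 53)
  # invariant to window ordering
  set.seed(54)
  p <- runif(200) > 0.3; t2 <- runif(200) > 0.7
  o <- sample(200)
  expect_equal(evaluate_detection(p, t2)$accuracy,
               evaluate_detection(p[o], t2[o])$accuracy)
  expect_error(evaluate_detection(c(TRUE), c(TRUE, FALSE)), "length")
})

test_that("channel ranking orders by separability with alphabetical ties", {
  tab <- data.frame(
    channel = rep(c("Cz", "Ax", "Bx"), each = 4),
    ppaf_uV = c(10, 10, 2, 2,  3, 3, 2, 2,  3, 3, 2, 2),
    ictal = rep(c(TRUE, TRUE, FALSE, FALSE), 3))
  r <- rank_channels(tab)
  expect_identical(r$channel, c("Cz", "Ax", "Bx"))  # tie Ax/Bx alphabetical
  expect_equal(r$separability_uV, c(8, 1, 1))
  same <- tab; same$ppaf_uV <- rep(c(5, 5, 5, 5), 3)
  rs <- rank_channels(same)
  expect_identical(rs$channel, c("Ax", "Bx", "Cz"))
  noict <- tab; noict$ictal <- FALSE
  expect_error(rank_channels(noict), "ictal")
})

test_that("short positive runs are cleaned from predictions", {
  p <- c(rep(FALSE, 5), rep(TRUE, 2), rep(FALSE, 5), rep(TRUE, 8), FALSE)
  out <- clean_predictions(p, 6)
  expect_true(all(!out[6:7]))
  expect_true(all(out[13:20]))
  expect_identical(clean_predictions(p, 1), p)
})

test_that("detection features standardise channels and honour smoothing", {
  set.seed(55)
  nw <- 60
  tab <- data.frame(
    channel = rep(c("A", "B"), each = nw),
    window_start_s = rep(0:(nw - 1), 2),
    ppaf_uV = c(rnorm(nw, 100, 5), rnorm(nw, 10, 1)),
    n_pairs = 5L, stability_pct = 80,
    ictal = rep(rep(c(FALSE, TRUE), c(40, 20)), 2))
  f <- detection_features(tab, smooth_windows = 1)
  expect_equal(nrow(f), nw)
  expect_identical(f$truth, rep(c(FALSE, TRUE), c(40, 20)))
  # channel scale is irrelevant after robust standardisation
  tab2 <- tab; tab2$ppaf_uV[tab2$channel == "A"] <-
    tab2$ppaf_uV[tab2$channel == "A"] / 100
  f2 <- detection_features(tab2, smooth_windows = 1)
  expect_equal(f$feature, f2$feature, tolerance = 1e-6)
  # smoothing suppresses an isolated spike
  tab3 <- tab; tab3$ppaf_uV[10] <- 1e4
  raw <- detection_features(tab3, smooth_windows = 1)$feature[10]
  sm <- detection_features(tab3, smooth_windows = 9)$feature[10]
  expect_lt(sm, raw / 10)
})

test_that("the pipeline runs reproducibly end to end on a small cohort", {
  cfg <- pipeline_config(
    seed = 3,
    groups = list(list(seizure_count = 2, n_patients = 2,
                       synth = list(duration = 180, seizure_duration_s = 12,
                                    min_gap_s = 12, sw_amplitude = 150,
                                    background_rms = 20))),
    detect = list(smooth_windows = 5L, min_event_windows = 4L))
  rep1 <- run_pipeline(cfg)
  expect_true(rep1$groups[["2"]]$accuracy > 80)
  expect_equal(sum(rep1$groups[["2"]]$confusion), rep1$groups[["2"]]$n_windows)
  rep2 <- run_pipeline(cfg)
  expect_identical(rep1$groups[["2"]]$confusion, rep2$groups[["2"]]$confusion)
  expect_identical(rep1$ranking, rep2$ranking)
  # report files are written
  out <- withr::local_tempdir()
  run_pipeline(cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "report.json")))
  expect_true(file.exists(file.path(out, "channel_ranking.tsv")))
  js <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(js$groups[["2"]]$accuracy, rep1$groups[["2"]]$accuracy)
})

test_that("a seizure-free control cohort is refused for evaluation", {
  cfg <- pipeline_config(
    seed = 4,
    groups = list(list(seizure_count = 0, n_patients = 2,
                       synth = list(duration = 120))))
  expect_error(run_pipeline(cfg), "class")
})

test_that("config validation and YAML parsing", {
  expect_error(pipeline_config(bogus = 1), "unknown config")
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 12", "filter:", "  highpass_hz: 1.0"), f)
  cfg <- read_pipeline_config(f)
  expect_equal(cfg$seed, 12)
  expect_equal(cfg$filter$highpass_hz, 1.0)
  expect_equal(cfg$filter$lowpass_hz, 70)          # defaults survive merging
})
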