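# PPAF-based seizure detection and end-to-end orchestration.
#
# The detector is deliberately minimal so that the PPAF feature carries the
# whole classification burden. Per window and channel, PPAF is computed on
# the 3-30 Hz analysis band (the band ictal spike-and-wave energy occupies)
# with a per-channel prominence floor; each channel's window series is then
# standardised robustly (median/MAD), median-smoothed over neighbouring
# windows (seizures are sustained events, noise excursions are not), and
# the across-channel maximum is the window feature. A single global
# threshold is fit by maximising balanced accuracy on training windows,
# short positive runs (below the plausible minimum seizure duration) are
# discarded, and evaluation is leave-one-patient-out within each
# seizure-count group.

#' Fit the detection threshold
#'
#' Scans the midpoints of consecutive sorted unique feature values and
#' returns the threshold maximising balanced accuracy
#' (`(sensitivity + specificity) / 2`) on the training windows, with the
#' classification rule `feature >= threshold`. Ties go to the smallest
#' candidate.
#'
#' @param features numeric vector, one value per training window (in the
#'   pipeline: the across-channel maximum of the standardised, smoothed
#'   PPAF series from [detection_features()]).
#' @param truth logical vector, TRUE = ictal.
#' @return the threshold, in the units of `features`.
#' @export
fit_threshold <- function(features, truth) {
  if (length(features) != length(truth)) stop("length mismatch")
  truth <- as.logical(truth)
  if (!any(truth) || all(truth))
    stop("training windows must contain both classes")
  u <- sort(unique(features))
  if (length(u) == 1) return(u)
  cand <- (u[-1] + u[-length(u)]) / 2
  npos <- sum(truth); nneg <- sum(!truth)
  # one pass over the sorted features: at threshold cand[j] everything above
  # the j-th unique value is predicted positive
  ord <- order(features)
  fs <- features[ord]; ts <- truth[ord]
  last_at <- cumsum(tabulate(match(fs, u), length(u)))
  pos_below <- cumsum(ts)[last_at][-length(u)]
  neg_below <- cumsum(!ts)[last_at][-length(u)]
  ba <- ((npos - pos_below) / npos + neg_below / nneg) / 2
  cand[which.max(ba)]
}

#' Classify windows by threshold
#'
#' `feature >= threshold` is positive; the tie goes to positive, favouring
#' sensitivity in a screening context.
#'
#' @param features numeric vector.
#' @param threshold finite numeric threshold.
#' @return logical predictions.
#' @export
classify_windows <- function(features, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  features >= threshold
}

#' Evaluate window predictions
#'
#' @param predictions,truth logical vectors of equal length.
#' @param group optional seizure-count tag carried into the result.
#' @param threshold optional threshold carried into the result.
#' @return a `detection_result`: confusion counts (TP/FP/TN/FN) and
#'   accuracy, sensitivity, specificity in percent.
#' @export
evaluate_detection <- function(predictions, truth, group = NA,
                               threshold = NA_real_) {
  if (length(predictions) != length(truth)) stop("length mismatch")
  predictions <- as.logical(predictions); truth <- as.logical(truth)
  tp <- sum(predictions & truth)
  fp <- sum(predictions & !truth)
  tn <- sum(!predictions & !truth)
  fn <- sum(!predictions & truth)
  total <- tp + fp + tn + fn
  structure(list(threshold_uV = threshold, group = group,
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 n_windows = total,
                 accuracy = 100 * (tp + tn) / total,
                 sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "<detection_result>%s acc %.2f%% sens %.2f%% spec %.2f%% (TP %d FP %d TN %d FN %d)\n",
    if (!is.na(x$group)) sprintf(" group %s:", x$group) else "",
    x$accuracy, x$sensitivity, x$specificity,
    x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
    x$confusion["FN"]))
  invisible(x)
}

#' Rank channels by ictal/interictal PPAF separability
#'
#' Separability of a channel is its mean ictal PPAF minus its mean
#' interictal PPAF (uV) over the supplied window table. Ties break
#' alphabetically.
#'
#' @param ppaf_table data frame from [sliding_ppaf()] (possibly pooled over
#'   patients) with columns `channel`, `ppaf_uV`, `ictal`.
#' @return data frame `channel`, `separability_uV`, sorted descending.
#' @export
rank_channels <- function(ppaf_table) {
  if (!any(ppaf_table$ictal)) stop("no ictal windows in the table")
  ag <- function(sel) tapply(ppaf_table$ppaf_uV[sel],
                             ppaf_table$channel[sel], mean)
  mi <- ag(ppaf_table$ictal)
  mn <- ag(!ppaf_table$ictal)
  chans <- sort(unique(ppaf_table$channel))
  score <- mi[chans] - ifelse(is.na(mn[chans]), 0, mn[chans])
  out <- data.frame(channel = chans, separability_uV = as.numeric(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$separability_uV, out$channel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()], mirroring the processing
#' stages: `groups` (per seizure-count cohorts and their generator
#' settings), `filter`, `exclude`, `ica`, `reject`, `bad` (bad-segment
#' mask), `analysis_band` (band-limit applied before the PPAF windowing;
#' NULL disables it), `ppaf` (windowing and prominence), `detect` (feature
#' smoothing and the minimum event length) and the master `seed`. Any
#' subset may be supplied; the rest take the defaults below. Can also be
#' read from a YAML file with [read_pipeline_config()].
#'
#' @param ... named sections overriding the defaults.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 7L,
    groups = list(
      list(seizure_count = 3, n_patients = 3, synth = list()),
      list(seizure_count = 4, n_patients = 3, synth = list()),
      list(seizure_count = 5, n_patients = 3, synth = list())),
    filter = list(highpass_hz = 0.5, lowpass_hz = 70),
    exclude = character(0),
    ica = list(seed = 1L, max_fit_samples = 30000L),
    reject = list(frontal = 0.6, kurtosis = 5, muscle = 0.6, line = 0.5),
    bad = list(amplitude_uV = 500, flatline_s = 5, window_s = 1),
    analysis_band = c(3, 30),
    ppaf = list(window_s = 2, step_s = 1, prominence_uV = NULL,
                min_separation_s = 0.15, prominence_scope = "channel",
                prominence_mult = 3),
    detect = list(smooth_windows = 9L, min_event_windows = 6L))
  ov <- list(...)
  bad_names <- setdiff(names(ov), names(defaults))
  if (length(bad_names))
    stop("unknown config sections: ", paste(bad_names, collapse = ", "))
  cfg <- defaults
  for (nm in names(ov)) {
    cfg[[nm]] <- if (is.list(defaults[[nm]]) && is.list(ov[[nm]]) &&
                     nm != "groups")
      modifyList(defaults[[nm]], ov[[nm]]) else ov[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with the same sections.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Process one recording through the cleaning chain
#'
#' Filter, optional channel exclusion, CAR, ICA fit/score/reject,
#' bad-segment masking, sliding PPAF. Returns the per-window PPAF table
#' with windows overlapping the bad-segment mask removed, plus stage
#' metadata.
#'
#' @param recording an [eeg_recording()].
#' @param config a [pipeline_config()].
#' @return list with `ppaf_table`, `scores`, `n_rejected`, `mask_fraction`.
#' @export
process_recording <- function(recording, config) {
  rec <- bandpass(recording, filter_spec(config$filter$highpass_hz,
                                         config$filter$lowpass_hz))
  if (length(config$exclude)) rec <- exclude_channels(rec, config$exclude)
  rec <- common_average_reference(rec)
  decomp <- fit_ica(rec, seed = config$ica$seed,
                    max_fit_samples = config$ica$max_fit_samples)
  scores <- score_components(decomp, line_freq = 50,
                             thresholds = config$reject)
  rec <- reject_components(rec, decomp, scores)
  mask <- detect_bad_segments(rec, config$bad$amplitude_uV,
                              config$bad$flatline_s, config$bad$window_s)
  if (!is.null(config$analysis_band))
    # band selection only; relaxed transitions keep the kernel short
    rec <- bandpass(rec, filter_spec(config$analysis_band[1],
                                     config$analysis_band[2],
                                     transition_width_hz =
                                       0.5 * config$analysis_band))
  tab <- sliding_ppaf(rec, config$ppaf$window_s, config$ppaf$step_s,
                      config$ppaf$prominence_uV,
                      config$ppaf$min_separation_s,
                      prominence_scope = config$ppaf$prominence_scope,
                      prominence_mult = config$ppaf$prominence_mult)
  # drop windows that touch masked samples
  if (any(mask)) {
    win <- round(config$ppaf$window_s * rec$rate)
    bad_idx <- which(mask)
    starts <- unique(tab$window_start_s)
    s0 <- round(starts * rec$rate) + 1L
    bad_win <- vapply(seq_along(starts), function(i)
      any(bad_idx >= s0[i] & bad_idx < s0[i] + win), logical(1))
    drop <- tab$window_start_s %in% starts[bad_win]
    tab <- tab[!drop, , drop = FALSE]
  }
  list(ppaf_table = tab, scores = scores,
       n_rejected = sum(scores$is_artifact),
       mask_fraction = mean(mask))
}

#' Window detection features from a PPAF table
#'
#' Turns the per-channel PPAF window series into one feature per window:
#' each channel is standardised robustly (median centred, MAD scaled, over
#' that recording's windows), median-smoothed over `smooth_windows`
#' neighbouring windows, and the across-channel maximum is taken. The
#' robust standardisation makes channels comparable despite different
#' background levels; the median smoothing exploits that seizures span many
#' consecutive windows while noise excursions do not, without blurring
#' onset/offset edges the way a moving average would.
#'
#' @param ppaf_table data frame from [sliding_ppaf()] for one recording.
#' @param smooth_windows odd integer, running-median width in windows
#'   (1 = no smoothing).
#' @return data frame: `window_start_s`, `feature`, `truth`.
#' @export
detection_features <- function(ppaf_table, smooth_windows = 9L) {
  starts <- sort(unique(ppaf_table$window_start_s))
  chans <- unique(ppaf_table$channel)
  ord <- order(match(ppaf_table$channel, chans), ppaf_table$window_start_s)
  P <- matrix(ppaf_table$ppaf_uV[ord], length(starts), length(chans))
  ict <- matrix(ppaf_table$ictal[ord], length(starts), length(chans))
  feat <- rep(-Inf, length(starts))
  for (j in seq_along(chans)) {
    p <- P[, j]
    z <- (p - median(p)) / (median(abs(p - median(p))) + 1e-9)
    if (smooth_windows > 1L && length(z) > smooth_windows)
      z <- as.numeric(stats::runmed(z, smooth_windows, endrule = "keep"))
    feat <- pmax(feat, z)
  }
  data.frame(window_start_s = starts, feature = feat,
             truth = rowSums(ict) > 0)
}

#' Remove implausibly short detections
#'
#' Seizures last several seconds, so positive runs shorter than
#' `min_event_windows` consecutive windows are reclassified as negative.
#'
#' @param predictions logical window predictions in temporal order.
#' @param min_event_windows minimum run length kept.
#' @return cleaned logical vector.
#' @export
clean_predictions <- function(predictions, min_event_windows = 6L) {
  if (min_event_windows <= 1L) return(predictions)
  r <- rle(as.logical(predictions))
  r$values[r$values & r$lengths < min_event_windows] <- FALSE
  inverse.rle(r)
}

#' Run the full detection pipeline on a synthetic cohort
#'
#' Generates (or accepts) a cohort, runs every recording through
#' [process_recording()], fits the PPAF threshold leave-one-patient-out
#' within each seizure-count group, and aggregates per-group detection
#' metrics, the pooled channel ranking and PPAF summaries. Fully
#' reproducible from the config seed.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-generated cohort (as from
#'   [generate_cohort()]); when NULL the config's `groups` are generated.
#' @param out_dir optional directory; when given, `report.json` and TSV
#'   tables are written there.
#' @return report list: `groups` (named list of `detection_result`),
#'   `ranking`, `ppaf_summary`, `patients`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL) {
  if (is.null(cohort)) {
    cohort <- list()
    pid <- 0L
    for (g in config$groups) {
      sizes <- setNames(g$n_patients, as.character(g$seizure_count))
      part <- generate_cohort(sizes, g$synth,
                              seed = config$seed * 1000 + g$seizure_count)
      for (p in part) {
        pid <- pid + 1L
        p$patient_id <- sprintf("P%02d", pid)
        cohort[[pid]] <- p
      }
    }
  }
  processed <- lapply(cohort, function(p) {
    pr <- process_recording(p$recording, config)
    pr$patient_id <- p$patient_id
    pr$seizure_count <- p$seizure_count
    pr
  })

  groups <- split(processed, vapply(processed, `[[`, 0, "seizure_count"))
  results <- list()
  for (gname in names(groups)) {
    gp <- groups[[gname]]
    feats <- lapply(gp, function(p)
      detection_features(p$ppaf_table, config$detect$smooth_windows))
    pred_all <- logical(0); truth_all <- logical(0); ths <- numeric(0)
    for (i in seq_along(gp)) {
      train <- do.call(rbind, feats[-i])
      if (length(gp) == 1) train <- feats[[i]]  # degenerate: fit on self
      th <- fit_threshold(train$feature, train$truth)
      ths <- c(ths, th)
      pred <- clean_predictions(classify_windows(feats[[i]]$feature, th),
                                config$detect$min_event_windows)
      pred_all <- c(pred_all, pred)
      truth_all <- c(truth_all, feats[[i]]$truth)
    }
    results[[gname]] <- evaluate_detection(pred_all, truth_all,
                                           group = gname,
                                           threshold = mean(ths))
  }

  pooled <- do.call(rbind, lapply(processed, function(p) p$ppaf_table))
  ranking <- rank_channels(pooled)
  summ <- data.frame(
    state = c("ictal", "interictal"),
    mean_ppaf_uV = c(mean(pooled$ppaf_uV[pooled$ictal]),
                     mean(pooled$ppaf_uV[!pooled$ictal])),
    mean_stability_pct = c(mean(pooled$stability_pct[pooled$ictal]),
                           mean(pooled$stability_pct[!pooled$ictal])))
  patients <- data.frame(
    patient_id = vapply(processed, `[[`, "", "patient_id"),
    seizure_count = vapply(processed, `[[`, 0, "seizure_count"),
    components_rejected = vapply(processed, `[[`, 0, "n_rejected"),
    mask_fraction = vapply(processed, `[[`, 0, "mask_fraction"))

  report <- list(groups = results, ranking = ranking, ppaf_summary = summ,
                 patients = patients, config = unclass(config))
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(
    groups = lapply(report$groups, function(g)
      list(group = g$group, threshold_uV = g$threshold_uV,
           confusion = as.list(g$confusion), accuracy = g$accuracy,
           sensitivity = g$sensitivity, specificity = g$specificity)),
    ppaf_summary = report$ppaf_summary,
    patients = report$patients,
    config = report$config)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  write.table(report$ranking, file.path(out_dir, "channel_ranking.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(report$patients, file.path(out_dir, "patients.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
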