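#' Multichannel EEG recording
#'
#' The unit every stage of the pipeline consumes and produces: a channels x
#' samples matrix of scalp potentials in microvolts, its sampling rate,
#' ordered 10-20 channel labels, a table of time annotations and a reference
#' tag. Plays the role EEGLAB's EEG structure plays in that ecosystem.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param rate sampling frequency in Hz (> 0).
#' @param labels character vector of unique channel names, one per row of
#'   `data`, in 10-20/10-10 nomenclature (e.g. "Fp2", "Cz").
#' @param annotations data frame with columns `onset` (s from start),
#'   `duration` (s, >= 0), `label` (one of "seizure", "artifact", "other")
#'   and optionally `seizure_type` ("IAS"/"WIAS"/NA). Intervals are half-open
#'   `[onset, onset + duration)` and must lie inside the recording.
#' @param reference reference tag, "original" or "CAR".
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, labels,
                          annotations = empty_annotations(),
                          reference = "original") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number")
  labels <- as.character(labels)
  if (length(labels) != nrow(data))
    stop("length(labels) must equal nrow(data): ", length(labels), " vs ",
         nrow(data))
  if (anyDuplicated(labels))
    stop("channel labels must be unique")
  annotations <- validate_annotations(annotations, nsamp = ncol(data),
                                      rate = rate)
  reference <- match.arg(reference, c("original", "CAR"))
  rownames(data) <- labels
  structure(list(data = data, rate = rate, labels = labels,
                 annotations = annotations, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref=%s\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
              x$reference))
  if (nrow(x$annotations))
    cat(sprintf("  annotations: %s\n",
                paste(sprintf("%d %s", table(x$annotations$label),
                              names(table(x$annotations$label))),
                      collapse = ", ")))
  invisible(x)
}

#' Empty annotation table
#'
#' @return zero-row data frame with the annotation columns.
#' @export
empty_annotations <- function() {
  data.frame(onset = numeric(0), duration = numeric(0),
             label = character(0), seizure_type = character(0),
             stringsAsFactors = FALSE)
}

validate_annotations <- function(ann, nsamp, rate) {
  if (is.null(ann)) return(empty_annotations())
  ann <- as.data.frame(ann, stringsAsFactors = FALSE)
  if (!nrow(ann)) return(empty_annotations())
  need <- c("onset", "duration", "label")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotations missing columns: ", paste(miss, collapse = ", "))
  if (!"seizure_type" %in% names(ann)) ann$seizure_type <- NA_character_
  ann <- ann[, c("onset", "duration", "label", "seizure_type")]
  ann$onset <- as.numeric(ann$onset)
  ann$duration <- as.numeric(ann$duration)
  ann$label <- as.character(ann$label)
  ann$seizure_type <- as.character(ann$seizure_type)
  if (any(ann$onset < 0)) stop("annotation onsets must be >= 0")
  if (any(ann$duration < 0)) stop("annotation durations must be >= 0")
  bad <- !ann$label %in% c("seizure", "artifact", "other")
  if (any(bad))
    stop("annotation labels must be seizure/artifact/other; got: ",
         paste(unique(ann$label[bad]), collapse = ", "))
  total <- nsamp / rate
  if (any(ann$onset + ann$duration > total + 1 / rate))
    stop("annotation intervals must lie within [0, ", signif(total, 6), "] s")
  ann <- ann[order(ann$onset), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Duration of a recording in seconds
#' @param recording an `eeg_recording`.
#' @return length in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$data) / recording$rate
}

annotations_with_label <- function(recording, label) {
  ann <- recording$annotations
  ann[ann$label == label, , drop = FALSE]
}
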