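# Independent oracles used across the suite. These deliberately re-derive
# results with naive loop-based code (or raw byte inspection) so that they
# share no implementation with the package functions they check.

# Brute-force peak/trough enumerator implementing the documented pairing
# rules with plain loops.
oracle_pairs <- function(x, prominence, min_sep) {
  n <- length(x)
  maxima <- integer(0); minima <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) maxima <- c(maxima, i)
    if (x[i] < x[i - 1] && x[i] < x[i + 1]) minima <- c(minima, i)
  }
  prom_of <- function(i) {
    h <- x[i]
    ml <- h; j <- i - 1
    while (j >= 1 && x[j] <= h) { ml <- min(ml, x[j]); j <- j - 1 }
    mr <- h; j <- i + 1
    while (j <= n && x[j] <= h) { mr <- min(mr, x[j]); j <- j + 1 }
    h - max(ml, mr)
  }
  cand <- maxima[vapply(maxima, prom_of, 0) >= prominence]
  acc <- integer(0)
  for (i in cand[order(-x[cand], cand)])
    if (!length(acc) || all(abs(i - acc) >= min_sep)) acc <- c(acc, i)
  acc <- sort(acc)
  rows <- NULL
  for (k in seq_along(acc)) {
    lo <- acc[k]
    hi <- if (k < length(acc)) acc[k + 1] else n + 1L
    mm <- minima[minima > lo & minima < hi]
    if (!length(mm)) next
    tr <- mm[which.min(x[mm])]
    rows <- rbind(rows, c(lo, x[lo], tr, x[tr]))
  }
  if (is.null(rows)) rows <- matrix(0, 0, 4)
  colnames(rows) <- c("peak_index", "peak_amp", "trough_index", "trough_amp")
  rows
}

# random smooth test signal: moving-average filtered white noise
random_smooth_signal <- function(n, smooth = 7) {
  x <- as.numeric(stats::filter(rnorm(n + 2 * smooth), rep(1 / smooth, smooth),
                                sides = 2))
  x <- x[!is.na(x)]
  x[seq_len(n)]
}

# Minimal independent EDF inspector: reads header fields and annotation
# bytes straight off the file, no shared code with read_edf().
inspect_edf_raw <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  fld <- function(off, w) trimws(rawToChar(raw[(off + 1):(off + w)]))
  ns <- as.integer(fld(252, 4))
  nrec <- as.integer(fld(236, 8))
  labels <- vapply(seq_len(ns) - 1L, function(i)
    trimws(rawToChar(raw[(256 + i * 16 + 1):(256 + i * 16 + 16)])), "")
  sprs <- vapply(seq_len(ns) - 1L, function(i)
    as.integer(trimws(rawToChar(raw[(256 + ns * 216 + i * 8 + 1):
                                      (256 + ns * 216 + i * 8 + 8)]))), 0L)
  body <- raw[(256 * (ns + 1) + 1):length(raw)]
  txt <- rawToChar(body[body != as.raw(0) & body < as.raw(128)])
  n_seiz <- lengths(regmatches(txt, gregexpr("\x15[0-9.]+\x14seizure", txt)))
  list(ns = ns, nrec = nrec, labels = labels, sprs = sprs,
       n_seizure_annotations = n_seiz)
}

# short synthetic config used by many tests: 2 min, quick seizures
quick_config <- function(...) {
  args <- list(duration = 120, seizure_count = 2, seizure_duration_s = 10,
               seizure_duration_jitter_s = 1, min_gap_s = 10, seed = 11)
  args <- utils::modifyList(args, list(...))
  do.call(synth_config, args)
}
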