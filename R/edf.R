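# EDF+C reading and writing.
#
# The on-disk dialect is classic EDF with the EDF+ continuous extension: a
# 256-byte fixed header, 256 bytes of per-signal header fields, then data
# records of little-endian 16-bit integers. Annotations travel in the
# standard "EDF Annotations" signal as time-stamped annotation lists (TALs):
#   +onset<0x15>duration<0x14>label<0x14><0x00>
# with every record opening with a bare "+t<0x14><0x14>" timestamp TAL.
# Record duration is fixed at 1 s, so sampling rates must be integer Hz
# (true of the 200-512 Hz clinical range this targets). Recordings whose
# duration is not a whole number of seconds are zero-padded to the next
# record boundary on write, with a warning.

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) stop("EDF header field too wide: ", s)
  formatC(s, width = -width)
}

edf_num <- function(x, width = 8) {
  s <- format(x, trim = TRUE, scientific = FALSE)
  if (nchar(s) > width) s <- substr(format(x, digits = width - 2,
                                           scientific = FALSE), 1, width)
  pad_field(s, width)
}

#' Write a recording to an EDF+C file
#'
#' Samples are quantized to 16 bits over `physical_range`; the default
#' range of -3276.8 to +3276.7 microvolts gives exactly 0.1 microvolt
#' resolution with 0 uV on a digital code, and enough headroom for ictal
#' amplitudes without precision loss. Samples outside the
#' range are clipped and counted in a warning. Annotations are stored in an
#' "EDF Annotations" signal; `seizure_type`, when present, is appended to
#' the label as `"seizure|IAS"`.
#'
#' @param recording an [eeg_recording()]; finite data, integer Hz rate.
#' @param path output file path.
#' @param physical_range length-2 numeric, microvolt range mapped onto the
#'   16-bit digital range.
#' @return `path`, invisibly.
#' @seealso [read_edf()], [write_annotations_csv()]
#' @export
write_edf <- function(recording, path,
                      physical_range = c(-3276.8, 3276.7)) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!all(is.finite(recording$data)))
    stop("recording data must be finite")
  if (recording$rate %% 1 != 0)
    stop("EDF writer requires an integer sampling rate (1 s records)")
  rate <- as.integer(recording$rate)
  phys_lo <- physical_range[1]; phys_hi <- physical_range[2]
  if (!(phys_hi > phys_lo)) stop("physical_range must be increasing")
  nchan <- nrow(recording$data)
  nsamp <- ncol(recording$data)
  nrec <- ceiling(nsamp / rate)
  if (nrec * rate != nsamp) {
    warning(sprintf("padding %d samples to fill the last 1 s record",
                    nrec * rate - nsamp))
  }

  dmin <- -32768L; dmax <- 32767L
  gain <- (phys_hi - phys_lo) / (dmax - dmin)
  x <- recording$data
  nclip <- sum(x < phys_lo | x > phys_hi)
  if (nclip > 0)
    warning(sprintf("%d samples outside physical_range [%g, %g] were clipped",
                    nclip, phys_lo, phys_hi))
  dig <- round((pmin(pmax(x, phys_lo), phys_hi) - phys_lo) / gain) + dmin
  storage.mode(dig) <- "integer"
  if (nrec * rate != nsamp) {
    zero_dig <- as.integer(round((0 - phys_lo) / gain) + dmin)
    pad <- matrix(zero_dig, nchan, nrec * rate - nsamp)
    dig <- cbind(dig, pad)
  }

  # annotation TALs per record
  ann <- recording$annotations
  tal_label <- ifelse(is.na(ann$seizure_type) | ann$seizure_type == "",
                      ann$label, paste0(ann$label, "|", ann$seizure_type))
  rec_of <- if (nrow(ann)) pmin(floor(ann$onset), nrec - 1) else integer(0)
  tals <- character(nrec)
  for (r in seq_len(nrec) - 1L) {
    s <- sprintf("+%d\x14\x14", r)
    idx <- which(rec_of == r)
    for (i in idx)
      s <- paste0(s, sprintf("+%.4f\x15%.4f\x14%s\x14",
                             ann$onset[i], ann$duration[i], tal_label[i]))
    tals[r + 1L] <- s
  }
  ann_bytes <- max(60L, max(nchar(tals, type = "bytes")) + 2L)
  ann_spr <- as.integer(ceiling(ann_bytes / 2))
  ns <- nchan + 1L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(pad_field("0", 8))
  wr(pad_field("X X X X", 80))
  wr(pad_field("Startdate X X X X", 80))
  wr("01.01.00"); wr("00.00.00")
  wr(edf_num(256L * (ns + 1L)))
  wr(pad_field("EDF+C", 44))
  wr(edf_num(nrec))
  wr(edf_num(1L))
  wr(pad_field(ns, 4))
  lab16 <- c(vapply(recording$labels, pad_field, "", width = 16),
             pad_field("EDF Annotations", 16))
  wr(paste(lab16, collapse = ""))
  wr(strrep(" ", 80 * ns))                      # transducer
  wr(paste(c(rep(pad_field("uV", 8), nchan), pad_field("", 8)),
           collapse = ""))                      # physical dimension
  wr(paste(c(rep(edf_num(phys_lo), nchan), edf_num(-1)), collapse = ""))
  wr(paste(c(rep(edf_num(phys_hi), nchan), edf_num(1)), collapse = ""))
  wr(paste(rep(edf_num(dmin), ns), collapse = ""))
  wr(paste(rep(edf_num(dmax), ns), collapse = ""))
  wr(strrep(" ", 80 * ns))                      # prefiltering
  wr(paste(c(rep(edf_num(rate), nchan), edf_num(ann_spr)), collapse = ""))
  wr(strrep(" ", 32 * ns))

  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * rate + 1L):(r * rate)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2L,
             endian = "little")
    raw_tal <- charToRaw(tals[r])
    writeBin(c(raw_tal, raw(2L * ann_spr - length(raw_tal))), con)
  }
  invisible(path)
}

read_header_field <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1):(offset + width)]))
}

#' Read an EDF/EDF+ file
#'
#' Parses the header, converts 16-bit digital samples to physical units via
#' each signal's gain/offset, and extracts annotations from the
#' "EDF Annotations" signal when present. All data signals must share one
#' sampling rate.
#'
#' @param path an EDF or EDF+ file.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 256L)
  if (length(hdr) < 256L) stop("malformed EDF header: file shorter than 256 bytes")
  version <- read_header_field(hdr, 0, 8)
  if (version != "0") stop("malformed EDF header: version field is '",
                           version, "', expected '0'")
  nrec <- suppressWarnings(as.integer(read_header_field(hdr, 236, 8)))
  if (is.na(nrec)) stop("malformed EDF header: number-of-records field")
  rec_dur <- suppressWarnings(as.numeric(read_header_field(hdr, 244, 8)))
  if (is.na(rec_dur) || rec_dur <= 0)
    stop("malformed EDF header: record-duration field")
  ns <- suppressWarnings(as.integer(read_header_field(hdr, 252, 4)))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: number-of-signals field")

  sig <- readBin(con, "raw", 256L * ns)
  fld <- function(off, width) {
    vapply(seq_len(ns) - 1L, function(i)
      read_header_field(sig, off * ns + i * width, width), "")
  }
  labels <- fld(0, 16)
  pmins <- as.numeric(fld(16 + 80 + 8, 8))
  pmaxs <- as.numeric(fld(16 + 80 + 8 + 8, 8))
  dmins <- as.numeric(fld(16 + 80 + 8 + 16, 8))
  dmaxs <- as.numeric(fld(16 + 80 + 8 + 24, 8))
  sprs <- as.integer(fld(16 + 80 + 8 + 32 + 80, 8))
  if (anyNA(pmins) || anyNA(pmaxs))
    stop("malformed EDF header: physical min/max fields")
  if (anyNA(dmins) || anyNA(dmaxs))
    stop("malformed EDF header: digital min/max fields")
  if (anyNA(sprs)) stop("malformed EDF header: samples-per-record fields")

  is_ann <- labels == "EDF Annotations"
  data_idx <- which(!is_ann)
  if (!length(data_idx)) stop("EDF file contains no data signals")
  if (length(unique(sprs[data_idx])) != 1L)
    stop("unsupported EDF: data signals have mixed sampling rates (",
         paste(unique(sprs[data_idx]), collapse = ", "), " samples/record)")
  spr <- sprs[data_idx[1]]
  rate <- spr / rec_dur
  rec_words <- sum(sprs)
  expect_sz <- 256L + 256L * ns + 2 * as.numeric(rec_words) * nrec
  if (!is.na(sz) && sz < expect_sz)
    stop("malformed EDF: file truncated (expected ", expect_sz, " bytes)")

  nchan <- length(data_idx)
  data <- matrix(0, nchan, spr * nrec)
  ann_raw <- list()
  offs <- c(0L, cumsum(sprs))
  for (r in seq_len(nrec)) {
    words <- readBin(con, "integer", rec_words, size = 2L, signed = TRUE,
                     endian = "little")
    for (j in seq_along(data_idx)) {
      s <- data_idx[j]
      data[j, ((r - 1L) * spr + 1L):(r * spr)] <-
        words[(offs[s] + 1L):(offs[s] + spr)]
    }
    for (s in which(is_ann)) {
      w <- words[(offs[s] + 1L):(offs[s] + sprs[s])]
      lo <- bitwAnd(w, 255L)
      hi <- bitwAnd(bitwShiftR(bitwAnd(w, 65535L), 8L), 255L)
      ann_raw[[length(ann_raw) + 1L]] <- as.raw(rbind(lo, hi))
    }
  }
  gain <- (pmaxs[data_idx] - pmins[data_idx]) / (dmaxs[data_idx] - dmins[data_idx])
  off <- pmins[data_idx] - gain * dmins[data_idx]
  data <- data * gain + off

  ann <- parse_tals(ann_raw)
  eeg_recording(data, rate = rate, labels = labels[data_idx],
                annotations = ann)
}

parse_tals <- function(ann_raw) {
  out <- empty_annotations()
  if (!length(ann_raw)) return(out)
  bytes <- do.call(c, ann_raw)
  # each TAL is "+onset[\x15dur]\x14label\x14"; timestamp TALs have no label
  txt <- rawToChar(bytes[bytes != as.raw(0)])
  tal_strings <- regmatches(txt, gregexpr("\\+[0-9.]+(\x15[0-9.]+)?\x14[^+\x14]*\x14?",
                                          txt))[[1]]
  for (tal in tal_strings) {
    parts <- strsplit(tal, "\x14")[[1]]
    if (length(parts) < 2L || !nzchar(parts[2])) next  # timestamp TAL
    time <- strsplit(parts[1], "\x15")[[1]]
    onset <- as.numeric(sub("^\\+", "", time[1]))
    dur <- if (length(time) > 1L) as.numeric(time[2]) else 0
    lab <- parts[2]
    type <- NA_character_
    if (grepl("|", lab, fixed = TRUE)) {
      bits <- strsplit(lab, "|", fixed = TRUE)[[1]]
      lab <- bits[1]; type <- bits[2]
    }
    if (!lab %in% c("seizure", "artifact", "other")) lab <- "other"
    out <- rbind(out, data.frame(onset = onset, duration = dur, label = lab,
                                 seizure_type = type,
                                 stringsAsFactors = FALSE))
  }
  out[order(out$onset), , drop = FALSE]
}

#' Annotation CSV sidecar
#'
#' Plain-text companion to the EDF annotations for tools without EDF+
#' support. Columns: `onset_s,duration_s,label,seizure_type`.
#'
#' @param recording an [eeg_recording()] (or a bare annotation data frame).
#' @param path CSV path.
#' @return `path` invisibly / an annotation data frame.
#' @export
write_annotations_csv <- function(recording, path) {
  ann <- if (inherits(recording, "eeg_recording")) recording$annotations
         else validate_annotations(recording, nsamp = Inf, rate = 1)
  out <- data.frame(onset_s = ann$onset, duration_s = ann$duration,
                    label = ann$label, seizure_type = ann$seizure_type)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("onset_s", "duration_s", "label")
  if (!all(need %in% names(d)))
    stop("annotation CSV must have columns onset_s,duration_s,label")
  if (!"seizure_type" %in% names(d)) d$seizure_type <- NA_character_
  d$seizure_type[d$seizure_type == ""] <- NA_character_
  data.frame(onset = d$onset_s, duration = d$duration_s, label = d$label,
             seizure_type = d$seizure_type, stringsAsFactors = FALSE)
}
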