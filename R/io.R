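# Reading and writing the formats the pipeline touches: EDF and raw-binary
# EEG/EMG recordings, hypnogram CSVs, and event tables (CSV/JSON).  The EDF
# layer is a minimal, self-contained implementation of the continuous
# 16-bit EDF layout (no installed R package reads EDF).

#' Construct an EEG/EMG recording
#'
#' @param eeg,emg numeric signals in µV, equal length.
#' @param fs sampling rate (Hz).
#' @param start_time recording start offset in seconds.
#' @param subject_id opaque subject identifier.
#' @return object of class `sleep_recording`.
#' @export
new_recording <- function(eeg, emg, fs, start_time = 0, subject_id = "") {
  stopifnot(length(eeg) == length(emg), fs > 0)
  if (length(eeg) < 5 * fs) stop("recording shorter than one staging window (5 s)")
  structure(list(eeg = as.numeric(eeg), emg = as.numeric(emg), fs = fs,
                 start_time = start_time, subject_id = subject_id),
            class = "sleep_recording")
}

#' @export
print.sleep_recording <- function(x, ...) {
  cat("<sleep_recording> ", length(x$eeg) / x$fs, " s at ", x$fs,
      " Hz (EEG+EMG)", if (nzchar(x$subject_id))
        paste0(", subject ", x$subject_id), "\n", sep = "")
  invisible(x)
}

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to EDF
#'
#' Continuous 16-bit EDF with two signals labelled `EEG` and `EMG`, physical
#' dimension µV (signal amplitudes are preserved through the digital
#' scaling).  The recording is truncated to whole 1 s data records.
#'
#' @param recording a `sleep_recording`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  fs <- recording$fs
  stopifnot(fs == round(fs))
  spr <- as.integer(fs)                       # 1 s data records
  n_rec <- length(recording$eeg) %/% spr
  if (n_rec < 1) stop("recording shorter than one EDF data record")
  sig <- list(EEG = recording$eeg[seq_len(n_rec * spr)],
              EMG = recording$emg[seq_len(n_rec * spr)])
  pmin_ <- vapply(sig, function(s) min(s, -1), numeric(1))
  pmax_ <- vapply(sig, function(s) max(s, 1), numeric(1))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(.edf_pad("0", 8),
                .edf_pad(recording$subject_id, 80),
                .edf_pad("sleeprhythms export", 80),
                .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
                .edf_pad(256 * (1 + length(sig)), 8),
                .edf_pad("", 44),
                .edf_pad(n_rec, 8), .edf_pad("1", 8),
                .edf_pad(length(sig), 4))
  field <- function(vals, width) paste0(vapply(vals, .edf_pad, "", width),
                                        collapse = "")
  hdr <- paste0(hdr,
                field(names(sig), 16), field(rep("", 2), 80),
                field(rep("uV", 2), 8),
                field(format(pmin_, digits = 6), 8),
                field(format(pmax_, digits = 6), 8),
                field(rep("-32768", 2), 8), field(rep("32767", 2), 8),
                field(rep("", 2), 80), field(rep(spr, 2), 8),
                field(rep("", 2), 32))
  writeChar(hdr, con, eos = NULL)
  dig <- lapply(seq_along(sig), function(i) {
    as.integer(round((sig[[i]] - pmin_[i]) / (pmax_[i] - pmin_[i]) * 65535 -
                       32768))
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (i in seq_along(sig)) {
      writeBin(dig[[i]][idx], con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

.read_edf <- function(path, eeg_pattern = "EEG", emg_pattern = "EMG") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (!identical(version, "0")) stop("unreadable EDF header (version field '",
                                     version, "')")
  subject <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(n_rec) || is.na(ns) || ns < 1) stop("unreadable EDF header")
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)              # transducer
  for (i in seq_len(ns)) rd(8)               # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)              # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  data <- lapply(spr, function(k) numeric(n_rec * k))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2, endian = "little",
                   signed = TRUE)
      data[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (d - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i]) +
        pmin_[i]
    }
  }
  pick <- function(pattern, what) {
    hit <- grep(pattern, labels, ignore.case = TRUE)
    if (!length(hit)) {
      stop("no ", what, " channel matching '", pattern,
           "'; available channels: ", paste(labels, collapse = ", "))
    }
    hit[1]
  }
  i_eeg <- pick(eeg_pattern, "EEG")
  i_emg <- pick(emg_pattern, "EMG")
  new_recording(data[[i_eeg]], data[[i_emg]], fs = spr[i_eeg] / rec_dur,
                subject_id = subject)
}

#' Read an EEG/EMG recording
#'
#' `format = "edf"` parses a continuous 16-bit EDF and selects the EEG and
#' EMG channels by label pattern (signals in µV are not rescaled beyond the
#' EDF digital-to-physical mapping).  `format = "raw"` reads a headerless
#' binary file accompanied by a JSON sidecar `<path>.meta.json` declaring
#' `fs`, `channels` (in file order, channel blocks stored sequentially),
#' `dtype` (`"float64"` or `"int16"`), `n` (samples per channel) and
#' `units`.
#'
#' @param path file path.
#' @param format `"edf"` or `"raw"`.
#' @param eeg_pattern,emg_pattern channel-label regexes (case-insensitive).
#' @return a `sleep_recording`.
#' @export
read_recording <- function(path, format = c("edf", "raw"),
                           eeg_pattern = "EEG", emg_pattern = "EMG") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edf") return(.read_edf(path, eeg_pattern, emg_pattern))
  meta_path <- paste0(path, ".meta.json")
  if (!file.exists(meta_path)) stop("missing sidecar metadata: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  stopifnot(!is.null(meta$fs), !is.null(meta$channels), !is.null(meta$n))
  dtype <- meta$dtype %||% "float64"
  con <- file(path, "rb")
  on.exit(close(con))
  readers <- list(float64 = function(n) readBin(con, "double", n, size = 8,
                                                endian = "little"),
                  int16 = function(n) readBin(con, "integer", n, size = 2,
                                              endian = "little",
                                              signed = TRUE))
  if (is.null(readers[[dtype]])) stop("unsupported dtype: ", dtype)
  chans <- lapply(meta$channels, function(ch) readers[[dtype]](meta$n))
  names(chans) <- meta$channels
  pick <- function(pattern, what) {
    hit <- grep(pattern, meta$channels, ignore.case = TRUE)
    if (!length(hit)) stop("no ", what, " channel matching '", pattern,
                           "'; available channels: ",
                           paste(meta$channels, collapse = ", "))
    hit[1]
  }
  new_recording(chans[[pick(eeg_pattern, "EEG")]],
                chans[[pick(emg_pattern, "EMG")]],
                fs = meta$fs, subject_id = meta$subject_id %||% "")
}

#' Write / read a hypnogram CSV
#'
#' CSV with a leading comment line declaring the epoch length
#' (`# epoch_s=2.5 start_s=0`) and columns `epoch_index`, `start_s`,
#' `state` over `{W, N, R, U}`.  `read_hypnogram(write_hypnogram(h)) == h`.
#'
#' @param hypnogram a `hypnogram` (nonempty).
#' @param path file path.
#' @return `path` invisibly; `read_hypnogram` returns a `hypnogram`.
#' @export
write_hypnogram <- function(hypnogram, path) {
  if (!length(hypnogram)) stop("refusing to write an empty hypnogram")
  ep <- attr(hypnogram, "epoch_s") %||% 2.5
  start_s <- attr(hypnogram, "start_s") %||% 0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# epoch_s=%g start_s=%g", ep, start_s), con)
  writeLines("epoch_index,start_s,state", con)
  idx <- seq_along(hypnogram)
  writeLines(sprintf("%d,%g,%s", idx, start_s + (idx - 1) * ep,
                     as.character(hypnogram)), con)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || !startsWith(lines[1], "#")) {
    stop("not a hypnogram CSV (missing '# epoch_s=' header): ", path)
  }
  kv <- regmatches(lines[1], gregexpr("[a-z_]+=[-0-9.eE]+", lines[1]))[[1]]
  meta <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  body <- utils::read.csv(text = lines[-1], stringsAsFactors = FALSE,
                          colClasses = c("integer", "numeric", "character"))
  bad <- which(!body$state %in% c("W", "N", "R", "U"))
  if (length(bad)) {
    stop("unknown state token '", body$state[bad[1]], "' at line ",
         bad[1] + 2L, " of ", path)
  }
  new_hypnogram(body$state, epoch_s = meta[["epoch_s"]],
                start_s = if ("start_s" %in% names(meta))
                  meta[["start_s"]] else 0)
}

#' Write / read an event table
#'
#' Events are rows of `(time_s, kind, duration_s, ...)`; times must be
#' non-negative and sorted ascending, durations non-negative.  The format
#' follows the file extension: `.json` via jsonlite, anything else CSV with
#' stable column order (`time_s`, `kind`, `duration_s`, then extras).
#'
#' @param events data.frame with at least `time_s`, `kind`, `duration_s`.
#' @param path file path.
#' @return `path` invisibly; `read_events` returns the data.frame.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("time_s", "kind", "duration_s") %in% names(events)))
  if (any(events$time_s < 0)) stop("event times must be non-negative")
  if (is.unsorted(events$time_s)) {
    stop("event times must be sorted ascending; sort before writing")
  }
  if (any(events$duration_s < 0)) stop("event durations must be non-negative")
  first <- c("time_s", "kind", "duration_s")
  events <- events[, c(first, setdiff(names(events), first)), drop = FALSE]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(events, path, digits = NA, dataframe = "rows")
  } else {
    utils::write.csv(events, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  out <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("time_s", "kind", "duration_s") %in% names(out)))
  out
}
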