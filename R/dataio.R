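# Beat/rhythm annotation I/O (WFDB MIT annotation format) and window tables.

# WFDB annotation type codes used here.  Beat codes follow the standard
# WFDB table; 28 is the rhythm-change pseudo-annotation whose aux string
# carries labels such as "(AFIB" or "(N".
.WFDB_RHYTHM <- 28L
.WFDB_SKIP <- 59L
.WFDB_NUM <- 60L
.WFDB_SUB <- 61L
.WFDB_CHN <- 62L
.WFDB_AUX <- 63L
.WFDB_BEAT_CODES <- c(1:13, 25L, 34L, 35L, 38L)

#' Construct a beat series
#'
#' A beat series couples the beat (R-peak or pulse-peak) times of one
#' recording with its rhythm annotation segments.  Beat times are stored in
#' seconds; the raw sample indices are kept alongside so no precision is
#' lost when writing annotations back out.
#'
#' @param record_id Character scalar naming the recording.
#' @param sampling_rate Sampling frequency in Hz (positive).
#' @param beat_samples Strictly increasing integer sample indices of beats.
#' @param rhythm_segments Data frame with columns `start`, `end` (seconds)
#'   and `label` (verbatim rhythm strings such as `"(AFIB"`), or `NULL`
#'   for none.  Segments must be non-overlapping with `start < end`.
#' @return An object of class `beat_series` with elements `record_id`,
#'   `sampling_rate`, `beat_samples`, `beat_times` and `rhythm_segments`.
#' @export
beat_series <- function(record_id, sampling_rate, beat_samples = integer(),
                        rhythm_segments = NULL) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0)
    stop("`sampling_rate` must be a positive scalar (Hz)")
  beat_samples <- as.numeric(beat_samples)
  if (length(beat_samples) > 1 && any(diff(beat_samples) <= 0))
    stop("`beat_samples` must be strictly increasing")
  if (is.null(rhythm_segments)) {
    rhythm_segments <- data.frame(start = numeric(), end = numeric(),
                                  label = character(),
                                  stringsAsFactors = FALSE)
  } else {
    rhythm_segments <- as.data.frame(rhythm_segments,
                                     stringsAsFactors = FALSE)
    stopifnot(all(c("start", "end", "label") %in% names(rhythm_segments)))
    if (nrow(rhythm_segments)) {
      if (any(rhythm_segments$start >= rhythm_segments$end))
        stop("rhythm segments must satisfy start < end")
      o <- order(rhythm_segments$start)
      rhythm_segments <- rhythm_segments[o, , drop = FALSE]
      if (nrow(rhythm_segments) > 1 &&
          any(rhythm_segments$start[-1] <
              rhythm_segments$end[-nrow(rhythm_segments)] - 1e-12))
        stop("rhythm segments must not overlap")
    }
  }
  structure(list(record_id = as.character(record_id),
                 sampling_rate = sampling_rate,
                 beat_samples = beat_samples,
                 beat_times = beat_samples / sampling_rate,
                 rhythm_segments = rhythm_segments),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> record %s: %d beats @ %g Hz, %d rhythm segment(s)\n",
              x$record_id, length(x$beat_samples), x$sampling_rate,
              nrow(x$rhythm_segments)))
  invisible(x)
}

# Low-level parse of an MIT-format annotation byte stream into a table of
# (sample, code, aux).  Times are delta-encoded 10-bit fields; SKIP carries
# a 4-byte jump (high word first, each word little-endian); AUX attaches a
# string to the preceding annotation.
.parse_mit_bytes <- function(bytes) {
  n <- length(bytes)
  samples <- integer(0); codes <- integer(0); auxs <- character(0)
  t <- 0; i <- 1; pending_skip <- 0
  while (i + 1 <= n) {
    lo <- as.integer(bytes[i]); hi <- as.integer(bytes[i + 1]); i <- i + 2
    word <- lo + 256L * hi
    code <- word %/% 1024L
    field <- word %% 1024L
    if (word == 0L) break                      # end of annotation stream
    if (code == .WFDB_SKIP) {
      if (i + 3 > n) stop("truncated SKIP annotation")
      w1 <- as.integer(bytes[i]) + 256L * as.integer(bytes[i + 1])
      w2 <- as.integer(bytes[i + 2]) + 256L * as.integer(bytes[i + 3])
      i <- i + 4
      pending_skip <- pending_skip + w1 * 65536 + w2
    } else if (code == .WFDB_AUX) {
      if (i + field - 1 > n) stop("truncated AUX annotation")
      raw_aux <- bytes[seq_len(field) + i - 1L]
      i <- i + field + (field %% 2L)           # pad byte keeps words aligned
      s <- rawToChar(raw_aux[raw_aux != as.raw(0)])
      if (length(auxs)) auxs[length(auxs)] <- s
    } else if (code %in% c(.WFDB_NUM, .WFDB_SUB, .WFDB_CHN)) {
      # subtype/channel/num modifiers: no time advance, ignored here
    } else {
      t <- t + pending_skip + field
      pending_skip <- 0
      samples <- c(samples, t)
      codes <- c(codes, code)
      auxs <- c(auxs, NA_character_)
    }
  }
  data.frame(sample = samples, code = codes, aux = auxs,
             stringsAsFactors = FALSE)
}

.encode_mit_bytes <- function(samples, codes, auxs) {
  out <- raw(0)
  word_bytes <- function(w) as.raw(c(w %% 256L, w %/% 256L))
  prev <- 0
  for (k in seq_along(samples)) {
    delta <- samples[k] - prev
    prev <- samples[k]
    if (delta < 0) stop("annotation samples must be non-decreasing")
    if (delta > 1023) {
      out <- c(out, word_bytes(.WFDB_SKIP * 1024L),
               word_bytes(delta %/% 65536), word_bytes(delta %% 65536))
      delta <- 0
    }
    out <- c(out, word_bytes(codes[k] * 1024L + delta))
    if (!is.na(auxs[k]) && nzchar(auxs[k])) {
      ab <- charToRaw(auxs[k])
      out <- c(out, word_bytes(.WFDB_AUX * 1024L + length(ab)), ab)
      if (length(ab) %% 2L) out <- c(out, as.raw(0))
    }
  }
  c(out, as.raw(c(0, 0)))
}

#' Read beat and rhythm annotations from a WFDB-style annotation file
#'
#' Parses an MIT-format annotation file (the binary format of PhysioNet
#' `.atr` files): beat annotations become beat times, and rhythm-change
#' pseudo-annotations (aux strings such as `"(AFIB"`, `"(N"`) are
#' reconstructed into rhythm segments.  A rhythm label holds from its mark
#' until the next rhythm mark, or until the end of the record (the time of
#' the last annotation).
#'
#' @param path Path to the annotation file.
#' @param sampling_rate Sampling frequency in Hz used to convert sample
#'   indices to seconds.
#' @param record_id Record name; defaults to the file name without
#'   extension.
#' @return A [beat_series()].
#' @export
read_beat_annotations <- function(path, sampling_rate,
                                  record_id = sub("\\.[^.]*$", "", basename(path))) {
  bytes <- readBin(path, "raw", n = file.size(path))
  ann <- tryCatch(.parse_mit_bytes(bytes),
                  error = function(e) stop("unreadable annotation stream: ",
                                           conditionMessage(e)))
  beats <- ann$sample[ann$code %in% .WFDB_BEAT_CODES]
  if (length(beats) > 1 && any(diff(beats) <= 0))
    stop("beat annotations are not strictly increasing in time")
  rhy <- ann[ann$code == .WFDB_RHYTHM & !is.na(ann$aux), , drop = FALSE]
  segs <- NULL
  if (nrow(rhy)) {
    end_sample <- max(ann$sample)
    starts <- rhy$sample / sampling_rate
    ends <- c(rhy$sample[-1], end_sample) / sampling_rate
    keep <- starts < ends
    segs <- data.frame(start = starts[keep], end = ends[keep],
                       label = rhy$aux[keep], stringsAsFactors = FALSE)
  }
  beat_series(record_id, sampling_rate, beats, segs)
}

#' Write a beat series as a WFDB-style annotation file
#'
#' The inverse of [read_beat_annotations()]: beats are written as normal
#' beat annotations and each rhythm segment start as a rhythm-change
#' pseudo-annotation carrying its verbatim label.
#'
#' @param series A [beat_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_beat_annotations <- function(series, path) {
  stopifnot(inherits(series, "beat_series"))
  fs <- series$sampling_rate
  samples <- round(series$beat_samples)
  codes <- rep(1L, length(samples))
  auxs <- rep(NA_character_, length(samples))
  segs <- series$rhythm_segments
  if (nrow(segs)) {
    samples <- c(samples, round(segs$start * fs))
    codes <- c(codes, rep(.WFDB_RHYTHM, nrow(segs)))
    auxs <- c(auxs, segs$label)
    # close the record so segment ends survive the round trip
    end_sample <- round(max(segs$end) * fs)
    if (end_sample > max(samples)) {
      samples <- c(samples, end_sample)
      codes <- c(codes, .WFDB_SUB + 0L)  # placeholder below
      auxs <- c(auxs, NA_character_)
      codes[length(codes)] <- 14L        # NOISE marker: time-keeping only
    }
  }
  # rhythm marks sort before beats at the same sample
  o <- order(samples, codes != .WFDB_RHYTHM)
  writeBin(.encode_mit_bytes(samples[o], codes[o], auxs[o]), path)
  invisible(path)
}

#' Read or write a window table
#'
#' A window table is the tabular dataset format of the pipeline: one row
#' per labeled window of `W` consecutive interbeat intervals, stored as
#' plain comma-separated text with a one-line header
#' (`record_id, window_index, label, i1 ... iW`).  Values round-trip to
#' within 1e-9 s.
#'
#' @param table Data frame with columns `record_id`, `window_index`,
#'   `label` (0 = non-AF, 1 = AF) and interval columns `i1..iW`.
#' @param path File path.
#' @return `read_window_table` returns the data frame;
#'   `write_window_table` returns `path` invisibly.
#' @export
write_window_table <- function(table, path) {
  .validate_window_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_window_table
#' @export
read_window_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  .validate_window_table(tab)
  tab
}

.interval_cols <- function(table) grep("^i[0-9]+$", names(table), value = TRUE)

.validate_window_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("record_id", "window_index", "label")
  if (!all(need %in% names(table)))
    stop("window table must have columns record_id, window_index, label")
  ic <- .interval_cols(table)
  if (nrow(table)) {
    if (!length(ic)) stop("window table has no interval columns")
    vals <- as.matrix(table[, ic, drop = FALSE])
    bad <- which(apply(vals, 1, function(v) any(!is.finite(v))))
    if (length(bad))
      stop("row ", bad[1], " has a missing or non-finite interval value")
    bad <- which(apply(vals, 1, function(v) any(v <= 0)))
    if (length(bad))
      stop("row ", bad[1], " has a non-positive interval value")
    if (!all(table$label %in% c(0, 1)))
      stop("labels must be 0 (non-AF) or 1 (AF)")
  }
  invisible(table)
}

#' Convert a window table to a model input matrix and label vector
#'
#' @param table A window table (see [write_window_table()]).
#' @return List with `x` (numeric matrix, one row per window) and `y`
#'   (0/1 label vector).
#' @export
windows_to_xy <- function(table) {
  .validate_window_table(table)
  ic <- .interval_cols(table)
  list(x = unname(as.matrix(table[, ic, drop = FALSE])),
       y = as.integer(table$label))
}

# Assemble a window table data.frame from a matrix of interval rows.
.window_table <- function(x, label, record_id, window_index = seq_len(nrow(x))) {
  x <- as.matrix(x)
  df <- data.frame(record_id = record_id, window_index = window_index,
                   label = as.integer(label), stringsAsFactors = FALSE)
  colnames(x) <- paste0("i", seq_len(ncol(x)))
  cbind(df, as.data.frame(x))
}
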