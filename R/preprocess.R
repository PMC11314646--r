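# Episode extraction, window segmentation, class balancing and splitting.

#' RR intervals from beat times
#'
#' @param beat_times Strictly increasing beat times in seconds.
#' @return Numeric vector of successive differences (length
#'   `length(beat_times) - 1`; empty for 0 or 1 beats).
#' @export
rr_from_beats <- function(beat_times) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) > 1 && any(diff(beat_times) <= 0))
    stop("`beat_times` must be strictly increasing")
  if (length(beat_times) <= 1) return(numeric(0))
  diff(beat_times)
}

#' Default rhythm-label class maps
#'
#' Maps verbatim rhythm labels to the binary classes used downstream.
#' For AFDB-style annotations, `"(AFIB"` is AF and `"(N"` (which in that
#' database stands for all other rhythms) is non-AF, while atrial flutter
#' and junctional rhythm are excluded.  For ADB-style annotations only
#' sinus rhythm and AF episodes are kept.  `"generic"` maps `"(AFIB"` to
#' AF and `"(N"` to non-AF.
#'
#' @param db One of `"afdb"`, `"adb"`, `"generic"`.
#' @return Named character vector: label -> `"AF"`, `"non-AF"` or
#'   `"exclude"`.
#' @export
default_class_map <- function(db = c("afdb", "adb", "generic")) {
  db <- match.arg(db)
  switch(db,
    afdb = c("(AFIB" = "AF", "(N" = "non-AF",
             "(AFL" = "exclude", "(J" = "exclude"),
    adb = c("(AFIB" = "AF", "(N" = "non-AF", "(AFL" = "exclude",
            "(B" = "exclude", "(BII" = "exclude", "(IVR" = "exclude",
            "(NOD" = "exclude", "(P" = "exclude", "(PREX" = "exclude",
            "(SBR" = "exclude", "(SVTA" = "exclude", "(T" = "exclude",
            "(VFL" = "exclude", "(VT" = "exclude", "(AB" = "exclude"),
    generic = c("(AFIB" = "AF", "(N" = "non-AF"))
}

#' Split a beat series into single-rhythm interval episodes
#'
#' An RR interval belongs to an episode only if both of its beats fall
#' inside one rhythm segment; intervals spanning a segment boundary are
#' dropped, so no mixed-rhythm interval ever enters the dataset.  Segments
#' whose label maps to `"exclude"` (or is absent from the map, with a
#' warning) contribute nothing.
#'
#' @param series A [beat_series()].
#' @param class_map Named character vector mapping rhythm labels to
#'   `"AF"`, `"non-AF"` or `"exclude"`; see [default_class_map()].
#' @return List of episodes, each a list with `record_id`, `class`
#'   (`"AF"` or `"non-AF"`) and `intervals` (seconds).
#' @export
episodes_from_segments <- function(series, class_map = default_class_map("afdb")) {
  stopifnot(inherits(series, "beat_series"))
  segs <- series$rhythm_segments
  times <- series$beat_times
  episodes <- list()
  if (!nrow(segs) || length(times) < 2) return(episodes)
  unmapped <- setdiff(unique(segs$label), names(class_map))
  if (length(unmapped)) {
    warning("excluding segments with unmapped rhythm label(s): ",
            paste(unmapped, collapse = ", "))
    class_map <- c(class_map,
                   stats::setNames(rep("exclude", length(unmapped)), unmapped))
  }
  starts <- segs$start
  for (k in seq_len(nrow(segs))) {
    cls <- class_map[[segs$label[k]]]
    if (cls == "exclude") next
    # a beat exactly on a shared boundary belongs to the later segment
    upper_open <- any(abs(starts - segs$end[k]) < 1e-12)
    inside <- times >= segs$start[k] - 1e-12 &
      (if (upper_open) times < segs$end[k] - 1e-12
       else times <= segs$end[k] + 1e-12)
    tt <- times[inside]
    if (length(tt) < 2) next
    episodes[[length(episodes) + 1]] <-
      list(record_id = series$record_id, class = cls, intervals = diff(tt))
  }
  episodes
}

#' Cut an episode into fixed-length windows
#'
#' Consecutive, non-overlapping blocks of `W` intervals are taken from the
#' episode start; a trailing remainder shorter than `W` is discarded, and
#' an episode with fewer than `W` intervals yields no windows at all.
#'
#' @param episode An episode from [episodes_from_segments()], or a bare
#'   numeric vector of intervals (then `record_id`/`label` must be given).
#' @param W Window length in intervals (default 30).
#' @param stride Step between window starts (default `W`,
#'   i.e. non-overlapping).
#' @param record_id,label Used when `episode` is a bare vector.
#' @return A window table data frame (possibly with zero rows).
#' @export
windowize <- function(episode, W = 30L, stride = W,
                      record_id = "episode", label = 0L) {
  stopifnot(W >= 2, stride >= 1)
  if (is.list(episode)) {
    intervals <- episode$intervals
    record_id <- episode$record_id %||% record_id
    label <- if (!is.null(episode$class)) as.integer(episode$class == "AF")
             else label
  } else intervals <- as.numeric(episode)
  n <- length(intervals)
  starts <- seq.int(1L, by = stride, length.out = max(0L, (n - W) %/% stride + 1L))
  if (n < W || !length(starts))
    return(.window_table(matrix(numeric(0), 0, W), integer(0), character(0),
                         integer(0)))
  x <- t(vapply(starts, function(s) intervals[s:(s + W - 1L)], numeric(W)))
  .window_table(x, rep(label, length(starts)), record_id,
                window_index = seq_along(starts))
}

#' Episodes of several beat series to one window table
#'
#' Convenience wrapper: extracts episodes from each series, windows them,
#' and binds the result with per-record running window indices.
#'
#' @param series_list List of [beat_series()] objects.
#' @param class_map See [episodes_from_segments()].
#' @param W,stride See [windowize()].
#' @return A window table data frame.
#' @export
windows_from_series <- function(series_list, class_map = default_class_map("afdb"),
                                W = 30L, stride = W) {
  if (inherits(series_list, "beat_series")) series_list <- list(series_list)
  parts <- list()
  for (s in series_list) {
    eps <- episodes_from_segments(s, class_map)
    for (e in eps) parts[[length(parts) + 1]] <- windowize(e, W, stride)
  }
  if (!length(parts)) return(windowize(numeric(0), W))
  out <- do.call(rbind, parts)
  # running window index per record
  out$window_index <- stats::ave(seq_len(nrow(out)), out$record_id,
                                 FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Balance a window set 50/50 by down-sampling the larger class
#'
#' Windows removed to reach balance are drawn uniformly at random from the
#' larger class; the relative order of the survivors is preserved.
#'
#' @param windows A window table.
#' @param seed Integer seed for the removal draw.
#' @return The balanced window table.
#' @export
balance_classes <- function(windows, seed = 1L) {
  .validate_window_table(windows)
  n1 <- sum(windows$label == 1); n0 <- sum(windows$label == 0)
  if (n1 == 0 || n0 == 0)
    stop("cannot balance: class ", if (n1 == 0) "AF" else "non-AF",
         " is absent")
  if (n1 == n0) return(windows)
  m <- min(n0, n1)
  larger <- as.integer(n1 > n0)
  idx <- which(windows$label == larger)
  drop <- with_seed(seed, sample(idx, length(idx) - m))
  out <- windows[-drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split windows into training and test sets
#'
#' With `by_record = TRUE` (the default) whole records are assigned to one
#' side, preventing within-patient leakage: records are shuffled with
#' `seed` and the prefix whose window share is closest to `fraction` forms
#' the training side.  Otherwise individual windows are shuffled and split
#' at `round(fraction * n)`.  Each side is then 50/50 class-balanced
#' (down-sampling, see [balance_classes()]) unless `balance = FALSE`.
#'
#' @param windows A window table.
#' @param fraction Training fraction in (0, 1); default 0.76.
#' @param seed Integer seed for shuffling and balancing.
#' @param by_record Assign whole records to a side (default `TRUE`).
#' @param balance Balance classes per side after splitting (default
#'   `TRUE`).
#' @return List with elements `train`, `test` (window tables),
#'   `fraction` and `seed`.
#' @export
split_dataset <- function(windows, fraction = 0.76, seed = 1L,
                          by_record = TRUE, balance = TRUE) {
  .validate_window_table(windows)
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(windows)
  if (by_record) {
    recs <- unique(windows$record_id)
    if (length(recs) < 2)
      stop("record-level split needs at least 2 records")
    recs <- with_seed(seed, sample(recs))
    counts <- vapply(recs, function(r) sum(windows$record_id == r), 0L)
    cum <- cumsum(counts)
    k <- which.min(abs(cum[-length(recs)] / n - fraction))
    train_ids <- recs[seq_len(k)]
    train <- windows[windows$record_id %in% train_ids, , drop = FALSE]
    test <- windows[!windows$record_id %in% train_ids, , drop = FALSE]
  } else {
    ord <- with_seed(seed, sample(n))
    cut <- round(fraction * n)
    if (cut < 1 || cut >= n) stop("split leaves an empty side")
    train <- windows[sort(ord[seq_len(cut)]), , drop = FALSE]
    test <- windows[sort(ord[-seq_len(cut)]), , drop = FALSE]
  }
  if (balance) {
    train <- balance_classes(train, seed = seed + 1L)
    test <- balance_classes(test, seed = seed + 2L)
  }
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test, fraction = fraction, seed = seed)
}
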