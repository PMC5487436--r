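#' Address-event representation (AER) event streams
#'
#' An `event_stream` is a tibble of spikes, one row per event, ordered by
#' timestamp, together with the geometry of the sensor / layer that produced
#' it. Columns:
#'
#' * `t`: integer microseconds since the stream origin (`t >= 0`),
#' * `x`: column index, 0-based, `0 <= x < width`,
#' * `y`: row index, 0-based, origin top-left, `0 <= y < height`,
#' * `sign`: `+1` (ON / positive spike) or `-1` (OFF / negative spike),
#' * `fm` (optional): feature-map index for events emitted inside a network.
#'
#' Time windows are half-open `[t_start, t_end)`. Events with equal
#' timestamps keep their input order (stable sort).
#'
#' @param events data frame with columns `t`, `x`, `y`, `sign` (and
#'   optionally `fm`), or `NULL` for an empty stream.
#' @param width,height sensor geometry in pixels.
#' @param duration_us stream duration in microseconds; defaults to
#'   `max(t) ` (or 0 for an empty stream). Events must lie in
#'   `[0, duration_us]`.
#' @param samples optional tibble of sample-window annotations with columns
#'   `label`, `t_start`, `t_end` (non-overlapping, ordered).
#' @return an `event_stream` (a tibble subclass carrying geometry metadata).
#' @examples
#' ev <- event_stream(data.frame(t = c(5, 0), x = 0:1, y = c(2, 0),
#'                               sign = c(-1, 1)), width = 32, height = 32)
#' ev_duration(ev)
#' @export
event_stream <- function(events = NULL, width, height,
                         duration_us = NULL, samples = NULL) {
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    events <- tibble(t = integer(), x = integer(), y = integer(),
                     sign = integer())
  }
  events <- as_tibble(events)
  need <- c("t", "x", "y", "sign")
  if (!all(need %in% names(events))) {
    abort(paste0("event data must have columns ", paste(need, collapse = ", ")),
          class = "spikehist_validation_error")
  }
  keep <- intersect(c("t", "x", "y", "sign", "fm"), names(events))
  events <- events[keep]
  for (cl in keep) events[[cl]] <- as.double(events[[cl]])
  validate_events(events, width, height)
  # stable sort by timestamp (radix keeps ties in input order)
  ord <- order(events$t, method = "radix")
  events <- events[ord, , drop = FALSE]
  if (is.null(duration_us)) {
    duration_us <- if (nrow(events)) max(events$t) else 0
  }
  if (nrow(events) && max(events$t) > duration_us) {
    abort("events extend beyond the declared duration",
          class = "spikehist_validation_error")
  }
  if (!is.null(samples)) {
    samples <- as_tibble(samples)
    stopifnot(all(c("label", "t_start", "t_end") %in% names(samples)))
    if (nrow(samples) > 1L &&
        any(samples$t_start[-1L] < samples$t_end[-nrow(samples)])) {
      abort("sample windows must be ordered and non-overlapping",
            class = "spikehist_validation_error")
    }
  }
  structure(events,
            class = c("event_stream", class(tibble())),
            width = as.integer(width), height = as.integer(height),
            duration_us = as.double(duration_us), samples = samples)
}

validate_events <- function(events, width, height) {
  if (!nrow(events)) return(invisible(TRUE))
  bad <- which(events$t < 0 | events$x < 0 | events$x >= width |
                 events$y < 0 | events$y >= height |
                 !(events$sign %in% c(-1, 1)))
  if (length(bad)) {
    abort(sprintf("invalid event at row %d: t=%g x=%g y=%g sign=%g (geometry %dx%d)",
                  bad[1L], events$t[bad[1L]], events$x[bad[1L]],
                  events$y[bad[1L]], events$sign[bad[1L]],
                  as.integer(width), as.integer(height)),
          class = "spikehist_validation_error")
  }
  invisible(TRUE)
}

#' @rdname event_stream
#' @param stream an `event_stream`.
#' @export
ev_geometry <- function(stream) {
  c(width = attr(stream, "width"), height = attr(stream, "height"))
}

#' @rdname event_stream
#' @export
ev_duration <- function(stream) attr(stream, "duration_us")

#' @rdname event_stream
#' @export
ev_samples <- function(stream) attr(stream, "samples")

#' @export
print.event_stream <- function(x, ...) {
  g <- ev_geometry(x)
  cat(sprintf("<event_stream> %d events, %dx%d, %.0f us\n",
              nrow(x), g[["width"]], g[["height"]], ev_duration(x)))
  s <- ev_samples(x)
  if (!is.null(s)) cat(sprintf("  %d annotated sample windows\n", nrow(s)))
  print(as_tibble(unclass_stream(x)), ...)
  invisible(x)
}

unclass_stream <- function(x) {
  attr(x, "width") <- NULL; attr(x, "height") <- NULL
  attr(x, "duration_us") <- NULL; attr(x, "samples") <- NULL
  class(x) <- class(tibble())
  x
}

#' Sample sets
#'
#' A `sample_set` is a tibble with one row per labeled sample: a `label`
#' column and a `stream` list-column of [event_stream()]s sharing one
#' geometry. This is the sample-by-sample (SBS) form; the one-pass (OP) form
#' is a single [event_stream()] with sample-window annotations, produced by
#' [concat_streams()].
#'
#' @param streams list of `event_stream`s with identical geometry.
#' @param labels integer class labels in `[0, class_count)`.
#' @param class_count number of classes `K`; defaults to `max(labels) + 1`.
#' @return a `sample_set` tibble.
#' @export
sample_set <- function(streams, labels, class_count = NULL) {
  stopifnot(length(streams) == length(labels))
  labels <- as.integer(labels)
  if (is.null(class_count)) class_count <- max(labels) + 1L
  if (any(labels < 0L | labels >= class_count)) {
    abort("labels must lie in [0, class_count)",
          class = "spikehist_validation_error")
  }
  if (length(streams) > 1L) {
    g0 <- ev_geometry(streams[[1L]])
    for (s in streams[-1L]) {
      if (!identical(ev_geometry(s), g0)) {
        abort("all streams in a sample set must share geometry",
              class = "spikehist_validation_error")
      }
    }
  }
  structure(tibble(label = labels, stream = streams),
            class = c("sample_set", class(tibble())),
            class_count = as.integer(class_count))
}

#' @rdname sample_set
#' @param x a `sample_set`.
#' @export
class_count <- function(x) attr(x, "class_count")

#' Read and write AER event files
#'
#' The canonical interchange format is `ev-csv`: a UTF-8, LF-terminated text
#' file with a geometry header, optional sample-window header lines, a column
#' header, and one `t_us,x,y,sign` row per event (plus a 5th `fm` column when
#' feature-map indices are present):
#'
#' ```
#' # width=32 height=32 duration_us=1000
#' # sample=0,0,255
#' t_us,x,y,sign
#' 0,1,2,1
#' 5,0,0,-1
#' ```
#'
#' Two binary dialects are read (not written): `nmnist-bin`, 5 bytes per
#' event (byte 1 = x, byte 2 = y, byte 3 bit 7 = polarity and bits 6..0 =
#' timestamp bits 22..16, bytes 4-5 = timestamp bits 15..0, microseconds);
#' and `aedat`, 8 bytes per event, big-endian 32-bit address then 32-bit
#' timestamp, DVS128 address layout (bit 0 polarity, bits 1..7 = x,
#' bits 8..14 = y), `#`-prefixed header lines skipped. In both dialects an
#' OFF polarity bit maps to `sign = -1` unless `rectify = TRUE`.
#'
#' @param path file path.
#' @param format one of `"ev-csv"`, `"nmnist-bin"`, `"aedat"`.
#' @param width,height geometry for binary dialects (ev-csv carries its own).
#' @param rectify map all polarities to `sign = +1`. Default `FALSE`: OFF
#'   events enter the (signed) network as `-1`.
#' @return [read_events()] returns an [event_stream()]; [write_events()]
#'   returns `path` invisibly. `read_events(write_events(s))` reproduces `s`
#'   exactly for ev-csv.
#' @export
read_events <- function(path, format = c("ev-csv", "nmnist-bin", "aedat"),
                        width = NULL, height = NULL, rectify = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "spikehist_io_error")
  }
  switch(format,
         "ev-csv" = read_ev_csv(path),
         "nmnist-bin" = read_nmnist_bin(path, width %||% 34L, height %||% 34L,
                                        rectify),
         "aedat" = read_aedat(path, width %||% 128L, height %||% 128L, rectify))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_ev_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || !grepl("^# width=", lines[1L])) {
    abort(paste0("line 1: missing '# width=... height=... duration_us=...' header in ", path),
          class = "spikehist_parse_error")
  }
  hdr <- lines[1L]
  num <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "=(-?[0-9.]+)"), hdr))[[1L]]
    if (length(m) < 2L) {
      abort(paste0("line 1: header lacks ", key), class = "spikehist_parse_error")
    }
    as.double(m[2L])
  }
  width <- num("width"); height <- num("height"); dur <- num("duration_us")
  i <- 2L
  samples <- NULL
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    if (grepl("^# sample=", lines[i])) {
      f <- strsplit(sub("^# sample=", "", lines[i]), ",", fixed = TRUE)[[1L]]
      if (length(f) != 3L || anyNA(suppressWarnings(as.double(f)))) {
        abort(sprintf("line %d: malformed sample annotation", i),
              class = "spikehist_parse_error")
      }
      samples <- bind_rows(samples,
                           tibble(label = as.integer(f[1L]),
                                  t_start = as.double(f[2L]),
                                  t_end = as.double(f[3L])))
    }
    i <- i + 1L
  }
  if (i > length(lines) || !grepl("^t_us,x,y,sign", lines[i])) {
    abort(sprintf("line %d: missing 't_us,x,y,sign' column header", i),
          class = "spikehist_parse_error")
  }
  has_fm <- grepl("fm", lines[i], fixed = TRUE)
  body <- lines[-seq_len(i)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    return(event_stream(NULL, width, height, dur, samples))
  }
  ncol <- if (has_fm) 5L else 4L
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != ncol)) {
    bad <- which(nf != ncol)[1L]
    abort(sprintf("line %d: expected %d fields, found %d",
                  i + bad, ncol, nf[bad]),
          class = "spikehist_parse_error")
  }
  m <- suppressWarnings(matrix(as.double(unlist(parts)), ncol = ncol,
                               byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1L]
    abort(sprintf("line %d: non-numeric field", i + bad),
          class = "spikehist_parse_error")
  }
  ev <- tibble(t = m[, 1L], x = m[, 2L], y = m[, 3L], sign = m[, 4L])
  if (has_fm) ev$fm <- m[, 5L]
  event_stream(ev, width, height, dur, samples)
}

read_nmnist_bin <- function(path, width, height, rectify) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) %% 5L != 0L) {
    abort(sprintf("byte %d: truncated 5-byte event record", length(raw)),
          class = "spikehist_parse_error")
  }
  n <- length(raw) %/% 5L
  if (n == 0L) return(event_stream(NULL, width, height))
  b <- matrix(as.integer(raw), nrow = 5L)
  x <- b[1L, ]; y <- b[2L, ]
  pol <- bitwShiftR(b[3L, ], 7L)
  t <- bitwShiftL(bitwAnd(b[3L, ], 127L), 16L) + bitwShiftL(b[4L, ], 8L) + b[5L, ]
  sign <- if (rectify) rep(1L, n) else ifelse(pol == 1L, 1L, -1L)
  event_stream(tibble(t = t, x = x, y = y, sign = sign), width, height)
}

read_aedat <- function(path, width, height, rectify) {
  raw <- readBin(path, "raw", n = file.size(path))
  # skip '#'-prefixed ASCII header lines, if any
  off <- 0L
  while (off < length(raw) && raw[off + 1L] == as.raw(35L)) {
    nl <- which(raw[(off + 1L):length(raw)] == as.raw(10L))[1L]
    if (is.na(nl)) break
    off <- off + nl
  }
  body <- raw[(off + 1L):length(raw)]
  if (length(body) %% 8L != 0L) {
    abort(sprintf("byte %d: truncated 8-byte event record", off + length(body)),
          class = "spikehist_parse_error")
  }
  n <- length(body) %/% 8L
  if (n == 0L) return(event_stream(NULL, width, height))
  b <- matrix(as.integer(body), nrow = 8L)
  addr <- bitwShiftL(b[1L, ], 24L) + bitwShiftL(b[2L, ], 16L) +
    bitwShiftL(b[3L, ], 8L) + b[4L, ]
  t <- bitwShiftL(b[5L, ], 24L) + bitwShiftL(b[6L, ], 16L) +
    bitwShiftL(b[7L, ], 8L) + b[8L, ]
  pol <- bitwAnd(addr, 1L)
  x <- bitwAnd(bitwShiftR(addr, 1L), 127L)
  y <- bitwAnd(bitwShiftR(addr, 8L), 127L)
  sign <- if (rectify) rep(1L, n) else ifelse(pol == 1L, 1L, -1L)
  event_stream(tibble(t = t, x = x, y = y, sign = sign), width, height)
}

#' @rdname read_events
#' @param stream an [event_stream()] to serialize (ev-csv only).
#' @export
write_events <- function(stream, path, format = "ev-csv") {
  if (format != "ev-csv") {
    abort("only ev-csv is written", class = "spikehist_io_error")
  }
  g <- ev_geometry(stream)
  lines <- sprintf("# width=%d height=%d duration_us=%s",
                   g[["width"]], g[["height"]],
                   format(ev_duration(stream), scientific = FALSE))
  s <- ev_samples(stream)
  if (!is.null(s) && nrow(s)) {
    lines <- c(lines, sprintf("# sample=%d,%s,%s", as.integer(s$label),
                              format(s$t_start, scientific = FALSE),
                              format(s$t_end, scientific = FALSE)))
  }
  has_fm <- "fm" %in% names(stream)
  lines <- c(lines, if (has_fm) "t_us,x,y,sign,fm" else "t_us,x,y,sign")
  if (nrow(stream)) {
    fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
    rows <- paste(fmt(stream$t), fmt(stream$x), fmt(stream$y),
                  fmt(stream$sign), sep = ",")
    if (has_fm) rows <- paste(rows, fmt(stream$fm), sep = ",")
    lines <- c(lines, rows)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Slice a stream into fixed-length sample windows
#'
#' Cuts a stream into consecutive, non-overlapping windows of
#' `slice_len_us` microseconds (half-open `[i*L, (i+1)*L)`), re-timing each
#' slice to start at 0. A trailing partial slice is kept and flagged with
#' attribute `partial = TRUE`. This is how continuous DVS recordings are
#' turned into training samples (e.g. 100 ms time slots).
#'
#' @param stream an [event_stream()].
#' @param slice_len_us window length, > 0.
#' @param label class label assigned to every slice (integer, default 0).
#' @return a [sample_set()] whose streams all carry `label`.
#' @export
slice_stream <- function(stream, slice_len_us, label = 0L) {
  stopifnot(slice_len_us > 0)
  g <- ev_geometry(stream)
  dur <- ev_duration(stream)
  n_slices <- max(1L, ceiling(dur / slice_len_us))
  if (dur > 0 && dur %% slice_len_us == 0) n_slices <- dur %/% slice_len_us
  streams <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    t0 <- (i - 1) * slice_len_us
    t1 <- min(i * slice_len_us, dur)
    sel <- stream$t >= t0 & stream$t < t1
    # final slice: include events exactly at dur (window closed at stream end)
    if (i == n_slices) sel <- stream$t >= t0 & stream$t <= dur
    ev <- unclass_stream(stream)[sel, , drop = FALSE]
    ev$t <- ev$t - t0
    sl <- event_stream(ev, g[["width"]], g[["height"]],
                       duration_us = t1 - t0)
    attr(sl, "partial") <- (t1 - t0) < slice_len_us
    streams[[i]] <- sl
  }
  sample_set(streams, rep(as.integer(label), n_slices),
             class_count = as.integer(label) + 1L)
}

#' Concatenate samples into a one-pass (OP) stream
#'
#' Joins the samples of a [sample_set()] into one continuous stream, the
#' one-pass presentation mode in which non-zero leakage (rather than an
#' explicit reset) separates samples. Sample `i` is offset by the cumulative
#' durations of its predecessors plus `i * gap_us`; boundary annotations
#' `(label, t_start, t_end)` are recorded so that histograms and readouts can
#' be windowed per sample.
#'
#' @param samples a [sample_set()].
#' @param gap_us inter-sample silent gap in microseconds (>= 0), during which
#'   leaky membranes decay toward rest.
#' @return an [event_stream()] with a `samples` annotation table.
#' @export
concat_streams <- function(samples, gap_us = 0) {
  stopifnot(inherits(samples, "sample_set"), gap_us >= 0)
  g <- ev_geometry(samples$stream[[1L]])
  offs <- 0
  evs <- vector("list", nrow(samples))
  ann <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    s <- samples$stream[[i]]
    ev <- unclass_stream(s)
    ev$t <- ev$t + offs
    evs[[i]] <- ev
    ann[[i]] <- tibble(label = samples$label[i], t_start = offs,
                       t_end = offs + ev_duration(s))
    offs <- offs + ev_duration(s) + gap_us
  }
  total <- offs - if (nrow(samples)) gap_us else 0
  event_stream(bind_rows(evs), g[["width"]], g[["height"]],
               duration_us = total, samples = bind_rows(ann))
}

#' @rdname concat_streams
#' @param stream an annotated OP stream, as produced by [concat_streams()].
#' @return [split_op_stream()] recovers the [sample_set()]: events of each
#'   annotated window, re-timed to start at 0.
#' @export
split_op_stream <- function(stream) {
  ann <- ev_samples(stream)
  if (is.null(ann)) {
    abort("stream has no sample annotations", class = "spikehist_validation_error")
  }
  g <- ev_geometry(stream)
  streams <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    # windows are half-open; the top end is included only when no later
    # window starts exactly there (events at t == duration are legal)
    closed_top <- i == nrow(ann) || ann$t_start[i + 1L] > ann$t_end[i]
    sel <- stream$t >= ann$t_start[i] &
      (stream$t < ann$t_end[i] | (closed_top & stream$t == ann$t_end[i]))
    ev <- unclass_stream(stream)[sel, , drop = FALSE]
    ev$t <- ev$t - ann$t_start[i]
    streams[[i]] <- event_stream(ev, g[["width"]], g[["height"]],
                                 duration_us = ann$t_end[i] - ann$t_start[i])
  }
  sample_set(streams, ann$label)
}
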