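# PlateTrace: long-format per-second displacement records, one larva per well.

.trace_cols <- c("plate", "batch", "well", "genotype", "treatment",
                 "dose_uM", "t_sec", "displacement_cm")

#' Construct and validate a plate trace
#'
#' A trace holds one row per (well, second): per-second displacement (cm) of a
#' single larva, annotated with plate, batch (biological replicate), genotype,
#' treatment and dose. Time is a 1-based second index from recording start; the
#' bin covering (0, 1] s is `t_sec = 1`. All wells must share the same complete
#' time grid and every second must fall inside the protocol duration.
#'
#' @param records data.frame with columns plate, batch, well, genotype,
#'   treatment, dose_uM, t_sec, displacement_cm.
#' @param protocol the [vmr_protocol()] the recording followed.
#' @return an object of class `vmr_trace` (a data.frame carrying the protocol
#'   as an attribute).
#' @export
vmr_trace <- function(records, protocol = vmr_protocol()) {
  if (!is.data.frame(records)) .stop_fmt("`records` must be a data.frame")
  missing_cols <- setdiff(.trace_cols, names(records))
  if (length(missing_cols))
    .stop_fmt("trace is missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (!inherits(protocol, "vmr_protocol")) .stop_fmt("`protocol` must be a vmr_protocol")
  rec <- records[.trace_cols]
  rec$t_sec <- as.integer(rec$t_sec)
  rec$displacement_cm <- as.numeric(rec$displacement_cm)
  rec$dose_uM <- as.numeric(rec$dose_uM)
  for (col in c("plate", "batch", "well", "genotype", "treatment"))
    rec[[col]] <- as.character(rec[[col]])

  if (nrow(rec)) {
    bad <- which(!is.finite(rec$displacement_cm) | rec$displacement_cm < 0)
    if (length(bad))
      .stop_fmt("negative or non-finite displacement at row %d (well %s, t=%d)",
                bad[1], rec$well[bad[1]], rec$t_sec[bad[1]])
    bad <- which(rec$t_sec < 1L | rec$t_sec > protocol$duration_s)
    if (length(bad))
      .stop_fmt("t_sec outside protocol duration at row %d (well %s, t=%d)",
                bad[1], rec$well[bad[1]], rec$t_sec[bad[1]])
    key <- paste(rec$plate, rec$well, rec$t_sec, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup))
      .stop_fmt("duplicated (well, time) at row %d (plate %s, well %s, t=%d)",
                dup[1], rec$plate[dup[1]], rec$well[dup[1]], rec$t_sec[dup[1]])
    # rectangularity: with no duplicate (well, t), equal per-well counts plus
    # a matching number of distinct seconds forces a shared time grid
    larva <- paste(rec$plate, rec$well, sep = ":")
    ids <- unique(larva)
    cnt <- tabulate(match(larva, ids), nbins = length(ids))
    n_t <- length(unique(rec$t_sec))
    if (any(cnt != n_t))
      .stop_fmt("wells do not share a common time grid (first offender: %s)",
                ids[which(cnt != n_t)[1]])
  }
  structure(rec, protocol = protocol, class = c("vmr_trace", "data.frame"))
}

#' @export
print.vmr_trace <- function(x, ...) {
  larvae <- unique(paste(x$plate, x$well, sep = ":"))
  cat(sprintf("VMR trace: %d larvae, %d s grid, %d rows\n",
              length(larvae),
              if (length(larvae)) length(unique(x$t_sec)) else 0L, nrow(x)))
  cat(sprintf("  batches: %s\n", paste(unique(x$batch), collapse = ", ")))
  tr <- table(x$treatment[!duplicated(paste(x$plate, x$well))])
  cat("  larvae per treatment: ",
      paste(sprintf("%s=%d", names(tr), tr), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Protocol attached to a trace
#' @param trace a `vmr_trace`.
#' @export
trace_protocol <- function(trace) {
  p <- attr(trace, "protocol")
  if (is.null(p)) .stop_fmt("trace carries no protocol attribute")
  p
}

#' Read a plate trace from CSV
#'
#' The dialect is plain comma-separated UTF-8 with a header row and columns
#' plate, batch, well, genotype, treatment, dose_uM, t_sec, displacement_cm.
#' Validation errors name the offending row; wells with an incomplete time grid
#' are rejected rather than imputed.
#'
#' @param path CSV file path.
#' @param protocol the [vmr_protocol()] the recording followed.
#' @return a `vmr_trace`.
#' @export
read_trace_csv <- function(path, protocol = vmr_protocol()) {
  if (!file.exists(path)) .stop_fmt("no such file: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  vmr_trace(raw, protocol)
}

#' Write a plate trace to CSV
#'
#' Rows are sorted by (plate, well, t_sec) before writing, so the same trace
#' always produces byte-identical output.
#'
#' @param trace a `vmr_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  if (!inherits(trace, "vmr_trace")) .stop_fmt("`trace` must be a vmr_trace")
  df <- as.data.frame(trace)[.trace_cols]
  if (nrow(df))
    df <- df[order(df$plate, df$well, df$t_sec), , drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) .stop_fmt("cannot write trace to %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Extract an event-aligned window matrix
#'
#' Selects the larvae matching `filter` and returns their displacement over the
#' seconds `event + start_offset` ... `event + end_offset` (inclusive, 1-based:
#' offset 1 is the first full second after the event) as a larvae x seconds
#' matrix -- the unit every multivariate test consumes. The 1-to-30-s window
#' therefore has dimension p = 30.
#'
#' @param trace a `vmr_trace`.
#' @param filter named list restricting larvae, e.g.
#'   `list(treatment = "DMSO", batch = "B1")`; values may be vectors. NULL
#'   keeps every larva.
#' @param event event name, currently `"light_off"`.
#' @param start_offset,end_offset post-event second offsets (inclusive).
#' @param group optional group label stored on the result.
#' @return a `window_matrix`: numeric matrix with one row per larva
#'   (rownames `plate:well`), one column per second, and attributes
#'   `window` (event time, offsets) and `group`.
#' @export
extract_window <- function(trace, filter = NULL, event = "light_off",
                           start_offset = 1L, end_offset = 30L, group = NULL) {
  if (!inherits(trace, "vmr_trace")) .stop_fmt("`trace` must be a vmr_trace")
  if (!identical(event, "light_off"))
    .stop_fmt("only the light_off event is supported")
  if (!.is_count(start_offset) || !.is_count(end_offset) ||
      start_offset < 1 || end_offset < start_offset)
    .stop_fmt("offsets must satisfy 1 <= start_offset <= end_offset")
  protocol <- trace_protocol(trace)
  t_event <- .light_off_event(protocol)
  t_lo <- t_event + as.integer(start_offset)
  t_hi <- t_event + as.integer(end_offset)
  if (t_hi > protocol$duration_s)
    .stop_fmt("window end (t=%d) exceeds recording duration (%d s)",
              t_hi, protocol$duration_s)
  df <- as.data.frame(trace)
  keep <- rep(TRUE, nrow(df))
  if (!is.null(filter)) {
    if (is.null(names(filter)) || any(!nzchar(names(filter))))
      .stop_fmt("`filter` must be a named list")
    for (col in names(filter)) {
      if (!col %in% names(df)) .stop_fmt("unknown filter column: %s", col)
      keep <- keep & df[[col]] %in% filter[[col]]
    }
  }
  df <- df[keep & df$t_sec >= t_lo & df$t_sec <= t_hi, , drop = FALSE]
  if (max(df$t_sec, t_lo - 1L) < t_hi && nrow(df) > 0L)
    .stop_fmt("window end (t=%d) exceeds the recorded grid", t_hi)
  larva <- paste(df$plate, df$well, sep = ":")
  ids <- sort(unique(larva))
  if (length(ids) < 2L)
    .stop_fmt("need at least 2 larvae in the window (found %d)", length(ids))
  p <- as.integer(end_offset - start_offset + 1L)
  m <- matrix(NA_real_, nrow = length(ids), ncol = p,
              dimnames = list(ids, paste0("t", seq.int(start_offset, end_offset))))
  m[cbind(match(larva, ids), df$t_sec - t_lo + 1L)] <- df$displacement_cm
  if (anyNA(m)) .stop_fmt("window has missing seconds for some larvae")
  structure(m,
            window = list(event = "light_off", event_t = t_event,
                          start_offset = as.integer(start_offset),
                          end_offset = as.integer(end_offset)),
            group = group,
            class = c("window_matrix", "matrix", "array"))
}

#' @export
print.window_matrix <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("window matrix: n = %d larvae, p = %d s (%s offset %d..%d)%s\n",
              nrow(x), ncol(x), w$event, w$start_offset, w$end_offset,
              if (is.null(attr(x, "group"))) "" else
                paste0(", group = ", attr(x, "group"))))
  invisible(x)
}

# Wrap a bare matrix as a window matrix (used by simulations and tests).
as_window_matrix <- function(m, start_offset = 1L, end_offset = start_offset + ncol(m) - 1L,
                             group = NULL) {
  m <- as.matrix(m)
  if (nrow(m) < 2L) .stop_fmt("need at least 2 rows")
  structure(m,
            window = list(event = "light_off", event_t = NA_integer_,
                          start_offset = as.integer(start_offset),
                          end_offset = as.integer(end_offset)),
            group = group,
            class = c("window_matrix", "matrix", "array"))
}
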