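#' Stimulus protocol for a visual motor response recording
#'
#' A protocol is an ordered sequence of dark/light segments with durations in
#' seconds and illuminance in lux. The analysis aligns everything to the single
#' light-off event: the transition from a light segment to a dark segment.
#' Displacement is binned per second; the bin covering (event, event + 1]
#' is post-event offset 1.
#'
#' @param segments data.frame with columns `label` ("dark" or "light"),
#'   `duration_s` (positive integer seconds) and `lux` (illuminance, >= 0;
#'   must be 0 for dark segments... any non-negative value is accepted for
#'   light segments, scotopic assays use 0.01 lx).
#' @return an object of class `vmr_protocol` with derived event times
#'   `light_on` and `light_off` (seconds from recording start) and total
#'   `duration_s`.
#' @examples
#' vmr_protocol()            # the scotopic assay: 30 min dark, 60 min 0.01 lx, 5 min off
#' @export
vmr_protocol <- function(segments = data.frame(
                           label = c("dark", "light", "dark"),
                           duration_s = c(1800L, 3600L, 300L),
                           lux = c(0, 0.01, 0))) {
  req <- c("label", "duration_s", "lux")
  if (!is.data.frame(segments) || !all(req %in% names(segments)))
    .stop_fmt("`segments` must be a data.frame with columns %s",
              paste(req, collapse = ", "))
  if (nrow(segments) == 0L) .stop_fmt("protocol needs at least one segment")
  if (!all(segments$label %in% c("dark", "light")))
    .stop_fmt("segment labels must be 'dark' or 'light'")
  if (!all(segments$duration_s > 0) || any(segments$duration_s != round(segments$duration_s)))
    .stop_fmt("segment durations must be positive whole seconds")
  if (!all(is.finite(segments$lux)) || any(segments$lux < 0))
    .stop_fmt("illuminance must be >= 0 lux")
  ends <- cumsum(as.integer(segments$duration_s))
  starts <- c(0L, ends[-length(ends)])
  lab <- segments$label
  on_idx  <- which(lab == "light" & c("dark", lab[-length(lab)]) == "dark")
  off_idx <- which(lab == "dark" & c("", lab[-length(lab)]) == "light")
  structure(list(
    segments  = data.frame(label = lab,
                           duration_s = as.integer(segments$duration_s),
                           lux = as.numeric(segments$lux)),
    light_on  = if (length(on_idx)) as.integer(starts[on_idx]) else integer(0),
    light_off = if (length(off_idx)) as.integer(starts[off_idx]) else integer(0),
    duration_s = as.integer(ends[length(ends)])
  ), class = "vmr_protocol")
}

#' @export
print.vmr_protocol <- function(x, ...) {
  cat("VMR stimulus protocol (", x$duration_s, " s total)\n", sep = "")
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("  %-5s %6d s  %g lx\n", x$segments$label[i],
                x$segments$duration_s[i], x$segments$lux[i]))
  if (length(x$light_off))
    cat("light-off event(s) at t = ", paste(x$light_off, collapse = ", "), " s\n", sep = "")
  invisible(x)
}

# The single analyzed light-off event, with a clear error otherwise.
.light_off_event <- function(protocol) {
  if (!inherits(protocol, "vmr_protocol")) .stop_fmt("`protocol` must be a vmr_protocol")
  if (length(protocol$light_off) != 1L)
    .stop_fmt("protocol must contain exactly one light-off event (found %d)",
              length(protocol$light_off))
  protocol$light_off
}

#' Stimulus intensity after stacked neutral-density filters
#'
#' Each neutral-density filter attenuates the source multiplicatively by its
#' transmittance, so `n_filters` identical filters give
#' `base * transmittance^n_filters`. This is how the scotopic stimulus is
#' derived from the tracking box's lowest output (e.g. 3.2 uW/cm^2 through
#' seven ~40% filters is about 0.005 uW/cm^2).
#'
#' @param base source intensity (any non-negative photometric/radiometric unit).
#' @param transmittance per-filter transmittance in (0, 1].
#' @param n_filters number of stacked filters (non-negative integer).
#' @return attenuated intensity in the units of `base`.
#' @examples
#' attenuated_intensity(3.2, 0.40, 7)
#' @export
attenuated_intensity <- function(base, transmittance, n_filters) {
  if (!is.numeric(base) || length(base) != 1L || !is.finite(base) || base < 0)
    .stop_fmt("`base` must be a single non-negative number")
  if (!is.numeric(transmittance) || length(transmittance) != 1L ||
      !is.finite(transmittance) || transmittance <= 0 || transmittance > 1)
    .stop_fmt("`transmittance` must lie in (0, 1]")
  if (!.is_count(n_filters)) .stop_fmt("`n_filters` must be a non-negative integer")
  base * transmittance^n_filters
}
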