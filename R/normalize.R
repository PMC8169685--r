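# Linear-model normalization of VMR traces: remove per-larva baseline
# activity, per-well light-intensity variation and batch effect, then add a
# single global offset so no normalized displacement is negative.
#
# The nuisance model is an additive OLS of baseline-window displacement on
# batch and well-position factors; the per-larva baseline is the larva's mean
# residual. Because both factors are constant within a larva and every larva
# shares the same balanced time grid, fitting on per-larva baseline means is
# algebraically identical to fitting on the raw per-second rows (and far
# cheaper); the equivalence is asserted against a normal-equations oracle in
# the test suite.

#' Fit the trace normalization model
#'
#' @param trace a `vmr_trace` containing every batch and well level that will
#'   later be normalized (controls and treated larvae together).
#' @param baseline_window integer vector `c(first, last)` of seconds used as
#'   baseline; default is the full dark-acclimation segment (recording start
#'   up to light onset), which excludes every post-stimulus second.
#' @return an object of class `vmr_norm` holding the intercept, per-level
#'   batch and well coefficients, per-larva baseline residuals, the
#'   non-negativity offset and the window used.
#' @seealso [apply_normalization()]
#' @export
fit_normalization <- function(trace, baseline_window = NULL) {
  if (!inherits(trace, "vmr_trace")) .stop_fmt("`trace` must be a vmr_trace")
  protocol <- trace_protocol(trace)
  if (is.null(baseline_window)) {
    if (!length(protocol$light_on))
      .stop_fmt("protocol has no light onset; give `baseline_window` explicitly")
    baseline_window <- c(1L, protocol$light_on[1])
  }
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) != 2L || baseline_window[1] < 1L ||
      baseline_window[2] < baseline_window[1])
    .stop_fmt("`baseline_window` must be c(first, last) with 1 <= first <= last")
  if (length(protocol$light_on) &&
      baseline_window[2] > protocol$light_on[1])
    .stop_fmt("baseline window must end at or before light onset (t=%d)",
              protocol$light_on[1])

  df <- as.data.frame(trace)
  in_base <- df$t_sec >= baseline_window[1] & df$t_sec <= baseline_window[2]
  if (!any(in_base)) .stop_fmt("no trace rows fall inside the baseline window")
  base <- df[in_base, , drop = FALSE]
  larva <- paste(base$plate, base$well, sep = ":")
  n_sec <- rowsum(rep(1, nrow(base)), larva)
  base_mean <- rowsum(base$displacement_cm, larva) / n_sec
  idx <- match(rownames(base_mean), larva)
  per <- data.frame(larva = rownames(base_mean),
                    base_mean = as.vector(base_mean),
                    batch = base$batch[idx],
                    well = base$well[idx],
                    stringsAsFactors = FALSE)
  per$batch <- factor(per$batch)
  per$well <- factor(per$well)

  terms <- character(0)
  if (nlevels(per$batch) > 1L) terms <- c(terms, "batch") else
    warning("single batch level: batch effect is not estimable and is dropped",
            call. = FALSE)
  if (nlevels(per$well) > 1L) terms <- c(terms, "well") else
    warning("single well level: well effect is not estimable and is dropped",
            call. = FALSE)
  if (length(terms)) {
    fit <- stats::lm(stats::reformulate(terms, response = "base_mean"), data = per)
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      warning("rank-deficient normalization design: aliased level(s) set to zero",
              call. = FALSE)
      cf[is.na(cf)] <- 0
    }
  } else {
    cf <- c(`(Intercept)` = mean(per$base_mean))
  }
  pull_levels <- function(prefix, levels) {
    out <- stats::setNames(numeric(length(levels)), levels)
    hit <- paste0(prefix, levels)
    found <- hit %in% names(cf)
    out[found] <- cf[hit[found]]
    out
  }
  intercept <- unname(cf["(Intercept)"])
  batch_coefs <- pull_levels("batch", levels(per$batch))
  well_coefs <- pull_levels("well", levels(per$well))
  fitted_nuis <- intercept + batch_coefs[as.character(per$batch)] +
    well_coefs[as.character(per$well)]
  larva_baseline <- stats::setNames(per$base_mean - unname(fitted_nuis), per$larva)

  # offset: smallest adjusted activity over the training trace, clamped at 0
  all_larva <- paste(df$plate, df$well, sep = ":")
  adj <- df$displacement_cm -
    (intercept + batch_coefs[df$batch] + well_coefs[df$well] +
       larva_baseline[all_larva])
  offset <- max(0, -min(adj))

  structure(list(intercept = intercept,
                 batch_coefs = batch_coefs,
                 well_coefs = well_coefs,
                 larva_baseline = larva_baseline,
                 offset = offset,
                 baseline_window = baseline_window,
                 dropped = setdiff(c("batch", "well"), terms)),
            class = "vmr_norm")
}

#' @export
print.vmr_norm <- function(x, ...) {
  cat(sprintf(paste0("VMR normalization model: %d batch, %d well levels, ",
                     "%d larvae; baseline t=%d..%d; offset %.4f cm\n"),
              length(x$batch_coefs), length(x$well_coefs),
              length(x$larva_baseline),
              x$baseline_window[1], x$baseline_window[2], x$offset))
  if (length(x$dropped))
    cat("  dropped (not estimable):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.vmr_norm <- function(object, ...) {
  list(intercept = object$intercept,
       batch = object$batch_coefs,
       well = object$well_coefs,
       larva_baseline = object$larva_baseline,
       offset = object$offset)
}

#' Apply a fitted normalization model to a trace
#'
#' Subtracts the fitted batch effect, well effect and per-larva baseline from
#' every displacement and adds the model's non-negativity offset. Every batch,
#' well and larva in `trace` must have been seen when the model was fitted.
#'
#' @param trace a `vmr_trace`.
#' @param model a [fit_normalization()] result.
#' @return a normalized `vmr_trace` (all displacements >= 0 on the data the
#'   model was fitted to).
#' @export
apply_normalization <- function(trace, model) {
  if (!inherits(trace, "vmr_trace")) .stop_fmt("`trace` must be a vmr_trace")
  if (!inherits(model, "vmr_norm")) .stop_fmt("`model` must be a vmr_norm")
  df <- as.data.frame(trace)
  unseen <- setdiff(unique(df$batch), names(model$batch_coefs))
  if (length(unseen) && !"batch" %in% model$dropped)
    .stop_fmt("batch level not seen by the normalization model: %s", unseen[1])
  unseen <- setdiff(unique(df$well), names(model$well_coefs))
  if (length(unseen) && !"well" %in% model$dropped)
    .stop_fmt("well level not seen by the normalization model: %s", unseen[1])
  larva <- paste(df$plate, df$well, sep = ":")
  unseen <- setdiff(unique(larva), names(model$larva_baseline))
  if (length(unseen))
    .stop_fmt("larva not seen by the normalization model: %s", unseen[1])
  b <- if (length(model$batch_coefs)) model$batch_coefs[df$batch] else 0
  w <- if (length(model$well_coefs)) model$well_coefs[df$well] else 0
  b[is.na(b)] <- 0; w[is.na(w)] <- 0
  df$displacement_cm <- df$displacement_cm -
    (model$intercept + unname(b) + unname(w) +
       unname(model$larva_baseline[larva])) + model$offset
  # numerical guard: the offset makes training data non-negative by
  # construction; clip only sub-nanometre negatives from float round-off
  df$displacement_cm[df$displacement_cm < 0 & df$displacement_cm > -1e-12] <- 0
  vmr_trace(df, trace_protocol(trace))
}

#' Serialize a normalization model to a plain-text file
#' @param model a `vmr_norm`.
#' @param path output path (YAML key/value text).
#' @export
write_norm_model <- function(model, path) {
  if (!inherits(model, "vmr_norm")) .stop_fmt("`model` must be a vmr_norm")
  yaml::write_yaml(list(intercept = model$intercept,
                        batch_coefs = as.list(model$batch_coefs),
                        well_coefs = as.list(model$well_coefs),
                        larva_baseline = as.list(model$larva_baseline),
                        offset = model$offset,
                        baseline_window = as.integer(model$baseline_window),
                        dropped = model$dropped), path,
                   precision = 15L)
  invisible(path)
}

#' Read a serialized normalization model
#' @param path file written by [write_norm_model()].
#' @export
read_norm_model <- function(path) {
  x <- yaml::read_yaml(path)
  structure(list(intercept = as.numeric(x$intercept),
                 batch_coefs = unlist(x$batch_coefs),
                 well_coefs = unlist(x$well_coefs),
                 larva_baseline = unlist(x$larva_baseline),
                 offset = as.numeric(x$offset),
                 baseline_window = as.integer(x$baseline_window),
                 dropped = as.character(unlist(x$dropped))),
            class = "vmr_norm")
}
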