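# The screening funnel: toxicity filter, replicate-consistency criterion
# (high-dimensional test, p > 0.9 read as similarity), and significance vs
# vehicle (Hotelling's T-squared, p < 0.05), per drug over the 1-s and
# 1-to-30-s post-offset windows.

#' Flag a drug as toxic from its raw traces
#'
#' A larva is classified dead/immobile when its total recording displacement
#' falls below `dead_rel_threshold` times the median total displacement of the
#' vehicle-control larvae. A drug is flagged toxic when the dead fraction
#' exceeds `toxic_frac` in any single replicate (batch) -- a drug that kills
#' most larvae in one replicate is unusable regardless of the other.
#'
#' @param trace the raw (un-normalized) `vmr_trace` of the screen.
#' @param treatment drug label to assess.
#' @param vehicle vehicle-control label (default `"DMSO"`).
#' @param dead_rel_threshold fraction of the vehicle median total displacement
#'   below which a larva counts as dead (default 0.05).
#' @param toxic_frac dead fraction above which a replicate is toxic
#'   (strict inequality; default 0.5).
#' @return list with `toxic` (logical), `diagnostics` (per-replicate
#'   data.frame: batch, n, n_dead, frac_dead) and `dead_larvae` ids.
#' @export
flag_toxic <- function(trace, treatment, vehicle = "DMSO",
                       dead_rel_threshold = 0.05, toxic_frac = 0.5) {
  if (!inherits(trace, "vmr_trace")) .stop_fmt("`trace` must be a vmr_trace")
  df <- as.data.frame(trace)
  if (!any(df$treatment == treatment))
    .stop_fmt("no wells with treatment '%s'", treatment)
  if (!any(df$treatment == vehicle))
    .stop_fmt("no vehicle ('%s') wells to calibrate the movement threshold", vehicle)
  larva <- paste(df$plate, df$well, sep = ":")
  totals <- rowsum(df$displacement_cm, larva)
  info_idx <- !duplicated(larva)
  meta <- data.frame(larva = larva[info_idx],
                     treatment = df$treatment[info_idx],
                     batch = df$batch[info_idx], stringsAsFactors = FALSE)
  meta$total <- totals[meta$larva, 1]
  thr <- dead_rel_threshold * stats::median(meta$total[meta$treatment == vehicle])
  drug_meta <- meta[meta$treatment == treatment, , drop = FALSE]
  drug_meta$dead <- drug_meta$total < thr
  diag <- do.call(rbind, lapply(split(drug_meta, drug_meta$batch), function(d)
    data.frame(batch = d$batch[1], n = nrow(d), n_dead = sum(d$dead),
               frac_dead = mean(d$dead), stringsAsFactors = FALSE)))
  rownames(diag) <- NULL
  list(toxic = any(diag$frac_dead > toxic_frac),
       diagnostics = diag,
       dead_larvae = drug_meta$larva[drug_meta$dead],
       movement_threshold = thr)
}

#' Replicate-consistency criterion
#'
#' Tests whether the two biological replicates of a drug produced the same
#' mean response vector using [hd_two_sample_test()]; the pair passes when the
#' p-value strictly exceeds `p_cutoff` (default 0.9), i.e. when the replicates
#' are statistically indistinguishable well beyond the usual bar.
#'
#' @param rep1,rep2 window matrices for the two replicates (same window spec).
#' @param n_boot,seed,calibration passed to [hd_two_sample_test()].
#' @param p_cutoff consistency cutoff; strict `p > p_cutoff` passes.
#' @return list with `p_value`, `pass` and the underlying `test`.
#' @export
replicate_consistency <- function(rep1, rep2, n_boot = 1000L, seed,
                                  p_cutoff = 0.9,
                                  calibration = c("permutation", "multiplier")) {
  if (!.is_prob(p_cutoff)) .stop_fmt("`p_cutoff` must lie in [0, 1]")
  ht <- hd_two_sample_test(rep1, rep2, n_boot = n_boot, seed = seed,
                           calibration = match.arg(calibration))
  list(p_value = ht$p.value, pass = ht$p.value > p_cutoff, test = ht)
}

#' Significance-vs-vehicle criterion
#'
#' Hotelling's T-squared test of the drug-treated response against the
#' vehicle-control response. With per-replicate input (lists of window
#' matrices) every replicate must individually reject at `alpha`; with single
#' pooled matrices one test decides.
#'
#' @param drug a window matrix, or a list of per-replicate window matrices.
#' @param vehicle a window matrix, or a list parallel to `drug` (each
#'   replicate tested against its own, typically same-batch, controls).
#' @param alpha significance level; strict `p < alpha` passes.
#' @param ridge passed to [hotelling_t2()].
#' @return list with `p_values`, `pass` and the `tests`.
#' @export
drug_vs_control <- function(drug, vehicle, alpha = 0.05, ridge = 0) {
  if (!.is_prob(alpha)) .stop_fmt("`alpha` must lie in [0, 1]")
  if (!is.list(drug)) drug <- list(drug)
  if (!is.list(vehicle)) vehicle <- rep(list(vehicle), length(drug))
  if (length(vehicle) != length(drug))
    .stop_fmt("`vehicle` must match the number of drug replicates")
  tests <- mapply(function(d, v) hotelling_t2(d, v, ridge = ridge),
                  drug, vehicle, SIMPLIFY = FALSE)
  p <- vapply(tests, function(t) t$p.value, numeric(1))
  list(p_values = p, pass = all(p < alpha), tests = tests)
}

# Toxicity for many drugs at once: per-larva totals are computed a single
# time over the trace (flag_toxic() gives the same answer drug by drug).
.toxicity_flags <- function(df, drugs, vehicle, dead_rel_threshold, toxic_frac) {
  larva <- paste(df$plate, df$well, sep = ":")
  totals <- rowsum(df$displacement_cm, larva)
  first <- !duplicated(larva)
  meta <- data.frame(larva = larva[first], treatment = df$treatment[first],
                     batch = df$batch[first], stringsAsFactors = FALSE)
  meta$total <- totals[meta$larva, 1]
  thr <- dead_rel_threshold * stats::median(meta$total[meta$treatment == vehicle])
  meta$dead <- meta$total < thr
  vapply(stats::setNames(drugs, drugs), function(d) {
    m <- meta[meta$treatment == d, , drop = FALSE]
    any(tapply(m$dead, m$batch, mean) > toxic_frac)
  }, logical(1))
}

# Build one wide larvae x seconds matrix for the union of window offsets,
# plus per-larva metadata, from a (normalized) trace.
.screen_windows <- function(trace, max_offset) {
  protocol <- trace_protocol(trace)
  t_off <- .light_off_event(protocol)
  if (t_off + max_offset > protocol$duration_s)
    .stop_fmt("recording ends before offset+%d s", max_offset)
  df <- as.data.frame(trace)
  df <- df[df$t_sec > t_off & df$t_sec <= t_off + max_offset, , drop = FALSE]
  larva <- paste(df$plate, df$well, sep = ":")
  ids <- sort(unique(larva))
  M <- matrix(NA_real_, length(ids), max_offset,
              dimnames = list(ids, paste0("t", seq_len(max_offset))))
  M[cbind(match(larva, ids), df$t_sec - t_off)] <- df$displacement_cm
  first <- !duplicated(larva)
  meta <- data.frame(larva = larva[first], treatment = df$treatment[first],
                     batch = df$batch[first], stringsAsFactors = FALSE)
  meta <- meta[match(ids, meta$larva), , drop = FALSE]
  list(M = M, meta = meta)
}

#' Run the full screening funnel
#'
#' Per drug: toxicity filter on the raw traces, then -- on
#' normalization-adjusted data -- the replicate-consistency criterion and the
#' significance-vs-vehicle criterion over each requested post-offset window. A
#' drug is a hit in a window when it is non-toxic, its replicates are
#' consistent (p > `consistency_cutoff`) and it differs from vehicle
#' (p < `alpha`).
#'
#' @param trace the raw screen `vmr_trace` (vehicle wells present in every
#'   batch that contains treated wells).
#' @param windows list of `c(start, end)` post-offset windows (seconds);
#'   default the 1-s and 1-to-30-s windows.
#' @param vehicle vehicle treatment label.
#' @param consistency_cutoff,alpha the two decision thresholds.
#' @param n_boot resamples for the consistency test.
#' @param seed mandatory master seed (consistency tests draw resamples).
#' @param normalize fit and apply [fit_normalization()] before testing.
#' @param significance `"per_replicate"` (each replicate must reject against
#'   its same-batch controls; default) or `"pooled"`.
#' @param calibration calibration scheme for the consistency test.
#' @param dead_rel_threshold,toxic_frac toxicity rule, see [flag_toxic()].
#' @return an object of class `vmr_screen` with elements `records` (one row
#'   per drug x window), `summary` (a `screen_summary`), and the settings.
#' @export
run_screen <- function(trace, windows = list(c(1L, 1L), c(1L, 30L)),
                       vehicle = "DMSO", consistency_cutoff = 0.9,
                       alpha = 0.05, n_boot = 1000L, seed,
                       normalize = TRUE,
                       significance = c("per_replicate", "pooled"),
                       calibration = c("permutation", "multiplier"),
                       dead_rel_threshold = 0.05, toxic_frac = 0.5) {
  significance <- match.arg(significance)
  calibration <- match.arg(calibration)
  if (missing(seed)) .stop_fmt("`seed` is mandatory")
  if (!inherits(trace, "vmr_trace")) .stop_fmt("`trace` must be a vmr_trace")
  if (!length(windows)) .stop_fmt("need at least one analysis window")
  df <- as.data.frame(trace)
  if (!any(df$treatment == vehicle))
    .stop_fmt("design error: no vehicle ('%s') wells in the screen", vehicle)
  drugs <- setdiff(unique(df$treatment), vehicle)
  drug_batches <- unique(df[df$treatment != vehicle, c("treatment", "batch")])
  veh_batches <- unique(df$batch[df$treatment == vehicle])
  missing_veh <- setdiff(unique(drug_batches$batch), veh_batches)
  if (length(missing_veh))
    .stop_fmt("design error: batch %s has treated wells but no vehicle controls",
              missing_veh[1])

  win_label <- vapply(windows, function(w) sprintf("%d-%d s", w[1], w[2]), character(1))
  if (length(drugs) == 0L) {
    records <- data.frame(drug = character(0), window = character(0),
                          toxic = logical(0), consistency_p = numeric(0),
                          consistent = logical(0), significance_p = numeric(0),
                          significant = logical(0), hit = logical(0))
    return(structure(list(records = records,
                          summary = summarize_screen(records),
                          windows = windows, seed = seed),
                     class = "vmr_screen"))
  }

  is_toxic <- .toxicity_flags(df, drugs, vehicle, dead_rel_threshold, toxic_frac)

  norm_trace <- if (normalize) {
    model <- fit_normalization(trace)
    apply_normalization(trace, model)
  } else trace
  max_off <- max(vapply(windows, `[`, integer(1), 2))
  sw <- .screen_windows(norm_trace, max_off)

  grab <- function(treatment, batch = NULL, w) {
    rows <- sw$meta$treatment == treatment
    if (!is.null(batch)) rows <- rows & sw$meta$batch == batch
    as_window_matrix(sw$M[rows, seq.int(w[1], w[2]), drop = FALSE],
                     start_offset = w[1], group = treatment)
  }

  rec <- vector("list", length(drugs) * length(windows))
  k <- 0L
  for (d in drugs) {
    d_batches <- sort(drug_batches$batch[drug_batches$treatment == d])
    for (wi in seq_along(windows)) {
      w <- as.integer(windows[[wi]])
      k <- k + 1L
      row <- data.frame(drug = d, window = win_label[wi], toxic = is_toxic[[d]],
                        consistency_p = NA_real_, consistent = FALSE,
                        significance_p = NA_real_, significant = FALSE,
                        hit = FALSE, stringsAsFactors = FALSE)
      if (!is_toxic[[d]]) {
        if (length(d_batches) >= 2L) {
          cons <- replicate_consistency(
            grab(d, d_batches[1], w), grab(d, d_batches[2], w),
            n_boot = n_boot,
            seed = derive_seed(seed, match(d, drugs) * 100L + wi),
            p_cutoff = consistency_cutoff, calibration = calibration)
          row$consistency_p <- cons$p_value
          row$consistent <- cons$pass
        }
        sig <- if (significance == "per_replicate")
          drug_vs_control(lapply(d_batches, function(b) grab(d, b, w)),
                          lapply(d_batches, function(b) grab(vehicle, b, w)),
                          alpha = alpha)
        else
          drug_vs_control(grab(d, NULL, w),
                          as_window_matrix(
                            sw$M[sw$meta$treatment == vehicle &
                                   sw$meta$batch %in% d_batches,
                                 seq.int(w[1], w[2]), drop = FALSE],
                            start_offset = w[1], group = vehicle),
                          alpha = alpha)
        row$significance_p <- max(sig$p_values)
        row$significant <- sig$pass
        row$hit <- row$consistent && row$significant
      }
      rec[[k]] <- row
    }
  }
  records <- do.call(rbind, rec)
  structure(list(records = records, summary = summarize_screen(records),
                 windows = windows, seed = seed,
                 consistency_cutoff = consistency_cutoff, alpha = alpha,
                 significance = significance, calibration = calibration),
            class = "vmr_screen")
}

#' @export
print.vmr_screen <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Funnel summary of screening records
#'
#' Collapses per-drug, per-window hit records into the screening funnel:
#' starting drugs, non-toxic drugs, replicate-consistent drugs per window,
#' and consistent-and-significant (hit) drugs per window. The funnel is
#' monotone by construction.
#'
#' @param records the `records` data.frame of a [run_screen()] result (or any
#'   data.frame with columns drug, window, toxic, consistent, hit).
#' @return an object of class `screen_summary`.
#' @export
summarize_screen <- function(records) {
  if (inherits(records, "vmr_screen")) records <- records$records
  req <- c("drug", "window", "toxic", "consistent", "hit")
  if (!all(req %in% names(records)))
    .stop_fmt("records must have columns %s", paste(req, collapse = ", "))
  drugs <- unique(records$drug)
  toxic_drugs <- unique(records$drug[records$toxic])
  wins <- unique(records$window)
  per_win <- do.call(rbind, lapply(wins, function(w) {
    r <- records[records$window == w, , drop = FALSE]
    data.frame(window = w,
               consistent = sum(r$consistent & !r$toxic),
               hits = sum(r$hit & !r$toxic),
               stringsAsFactors = FALSE)
  }))
  structure(list(starting = length(drugs),
                 non_toxic = length(drugs) - length(toxic_drugs),
                 per_window = per_win,
                 hit_drugs = lapply(stats::setNames(wins, wins), function(w)
                   sort(records$drug[records$window == w & records$hit]))),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("Drug-screening funnel\n")
  cat(sprintf("  starting drugs:   %d\n", x$starting))
  cat(sprintf("  non-toxic drugs:  %d\n", x$non_toxic))
  if (!is.null(x$per_window) && nrow(x$per_window))
    for (i in seq_len(nrow(x$per_window)))
      cat(sprintf("  window %-9s consistent: %d, hits: %d%s\n",
                  x$per_window$window[i], x$per_window$consistent[i],
                  x$per_window$hits[i],
                  if (x$per_window$hits[i] > 0)
                    paste0(" (", paste(x$hit_drugs[[x$per_window$window[i]]],
                                       collapse = ", "), ")") else ""))
  invisible(x)
}
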