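# Generative model for scotopic VMR plate traces, whole screens and
# dose-response readouts. The model behind every per-second displacement:
#
#   d(w, t) = max(0, b_w + batch_b + intensity_w
#                    + A_w * exp(-(t - t_off - 1)/tau_w) * 1[t > t_off] + eps)
#
# with per-larva baseline b_w, additive batch and well-column effects, a
# light-off startle burst of per-larva amplitude A_w decaying exponentially,
# and Gaussian measurement noise, all clipped at zero. Dead larvae emit ~0
# displacement throughout.

# E[max(0, N(mu, sigma))], the mean of a zero-clipped Gaussian.
.clipped_mean <- function(mu, sigma) {
  z <- mu / sigma
  mu * stats::pnorm(z) + sigma * stats::dnorm(z)
}

# Solve for mu so that the zero-clipped mean equals `target`.
.solve_clipped_mu <- function(target, sigma) {
  stats::uniroot(function(mu) .clipped_mean(mu, sigma) - target,
                 lower = -5 * sigma, upper = target + 5 * sigma,
                 tol = 1e-12)$root
}

#' Genotype-level parameters of the VMR generative model
#'
#' Presets `"WT"` and `"Q344X"` are calibrated so that the expected
#' (zero-clipped) displacement in the first second after light offset equals
#' the published group means, 0.281 cm and 0.127 cm, with per-larva startle
#' heterogeneity sized so an 18-larva sample has s.e.m. near the published
#' 0.036 / 0.031 cm. The calibration solves the truncated-Gaussian mean
#' identity for the startle amplitude, so clipping at zero introduces no bias.
#'
#' @param genotype `"WT"`, `"Q344X"`, or NULL for fully manual parameters.
#' @param baseline_rate mean dark locomotor displacement, cm per second.
#' @param baseline_dispersion sd of the per-larva baseline offset, cm.
#' @param startle_amplitude mean added displacement in the first post-offset
#'   second, cm. For a named genotype this is solved from
#'   `target_startle_mean`; pass a value to override.
#' @param startle_sd per-larva sd of the startle amplitude, cm.
#' @param startle_tau exponential decay constant of the burst, seconds.
#' @param response_prob probability a larva responds to the stimulus at all.
#' @param noise_sd per-second measurement noise sd, cm.
#' @param target_startle_mean expected clipped displacement at offset+1 s the
#'   amplitude is calibrated to (only when `startle_amplitude` is NULL).
#' @return an object of class `genotype_params`.
#' @examples
#' genotype_params("WT")
#' genotype_params("Q344X")
#' @export
genotype_params <- function(genotype = NULL,
                            baseline_rate = 0.05,
                            baseline_dispersion = 0.02,
                            startle_amplitude = NULL,
                            startle_sd = 0.15,
                            startle_tau = 1.5,
                            response_prob = 1,
                            noise_sd = 0.02,
                            target_startle_mean = NULL) {
  label <- if (is.null(genotype)) "custom" else match.arg(genotype, c("WT", "Q344X"))
  if (identical(label, "WT")) {
    if (missing(startle_sd)) startle_sd <- 0.150
    if (is.null(target_startle_mean)) target_startle_mean <- 0.281
  } else if (identical(label, "Q344X")) {
    if (missing(startle_sd)) startle_sd <- 0.128
    if (is.null(target_startle_mean)) target_startle_mean <- 0.127
  }
  for (v in c(baseline_rate, baseline_dispersion, startle_sd, startle_tau, noise_sd))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      .stop_fmt("genotype parameters must be single non-negative numbers")
  if (!.is_prob(response_prob)) .stop_fmt("`response_prob` must lie in [0, 1]")
  if (is.null(startle_amplitude)) {
    if (is.null(target_startle_mean))
      .stop_fmt("give either `startle_amplitude` or `target_startle_mean`")
    sigma <- sqrt(startle_sd^2 + baseline_dispersion^2 + noise_sd^2)
    startle_amplitude <- .solve_clipped_mu(target_startle_mean, sigma) - baseline_rate
  }
  if (!is.numeric(startle_amplitude) || length(startle_amplitude) != 1L ||
      !is.finite(startle_amplitude) || startle_amplitude < -baseline_rate)
    .stop_fmt("`startle_amplitude` must be a finite number >= -baseline_rate")
  structure(list(genotype = label,
                 baseline_rate = baseline_rate,
                 baseline_dispersion = baseline_dispersion,
                 startle_amplitude = startle_amplitude,
                 startle_sd = startle_sd,
                 startle_tau = startle_tau,
                 response_prob = response_prob,
                 noise_sd = noise_sd),
            class = "genotype_params")
}

#' @export
print.genotype_params <- function(x, ...) {
  cat(sprintf(paste0("genotype_params [%s]: baseline %.3f cm/s (disp %.3f), ",
                     "startle %.4f cm (sd %.3f, tau %.1f s), ",
                     "response prob %.2f, noise %.3f\n"),
              x$genotype, x$baseline_rate, x$baseline_dispersion,
              x$startle_amplitude, x$startle_sd, x$startle_tau,
              x$response_prob, x$noise_sd))
  invisible(x)
}

#' Drug effect applied on top of a genotype
#'
#' @param amplitude_mult multiplier on the mean startle amplitude (>= 0).
#' @param tau_mult multiplier on the decay constant; values well above 1 give
#'   the sustained light-off response a restorative drug produces.
#' @param toxic logical flag carried into the ground-truth table.
#' @param lethality per-larva probability of death (immobile well).
#' @return an object of class `drug_effect`.
#' @export
drug_effect <- function(amplitude_mult = 1, tau_mult = 1,
                        toxic = FALSE, lethality = 0) {
  if (!is.numeric(amplitude_mult) || amplitude_mult < 0 ||
      !is.numeric(tau_mult) || tau_mult < 0)
    .stop_fmt("effect multipliers must be >= 0")
  if (!.is_prob(lethality)) .stop_fmt("`lethality` must lie in [0, 1]")
  structure(list(amplitude_mult = amplitude_mult, tau_mult = tau_mult,
                 toxic = isTRUE(toxic), lethality = lethality),
            class = "drug_effect")
}

# Additive well-position intensity effect: linear in plate column (lamp
# inhomogeneity proxy), centred so it averages to zero across a full plate.
.well_effect <- function(wells, well_sd) {
  col_idx <- as.integer(sub("^[A-H]", "", wells))
  well_sd * (col_idx - 6.5) / 5.5
}

.plate_wells <- function(n) {
  if (n > 96L) .stop_fmt("a plate holds at most 96 wells (asked for %d)", n)
  paste0(rep(LETTERS[1:8], each = 12L), rep(1:12, 8L))[seq_len(n)]
}

# Simulate displacement for n larvae of one batch. Returns an n x T matrix.
.simulate_wells <- function(n, params, drug, protocol, batch_eff, well_eff) {
  T_total <- protocol$duration_s
  t_off <- .light_off_event(protocol)
  dead <- stats::rbinom(n, 1L, drug$lethality) == 1L
  responder <- stats::rbinom(n, 1L, params$response_prob) == 1L
  b <- stats::rnorm(n, params$baseline_rate, params$baseline_dispersion)
  # the multiplier scales the mean response; larva-to-larva heterogeneity
  # stays a property of the genotype
  A <- stats::rnorm(n, drug$amplitude_mult * params$startle_amplitude,
                    params$startle_sd)
  tau <- max(params$startle_tau * drug$tau_mult, 1e-6)
  tt <- seq_len(T_total)
  decay <- ifelse(tt > t_off, exp(-(tt - t_off - 1) / tau), 0)
  M <- matrix(stats::rnorm(n * T_total, 0, params$noise_sd), n, T_total)
  M <- M + (b + batch_eff + well_eff) + (A * responder) %o% decay
  if (any(dead))
    M[dead, ] <- matrix(stats::rnorm(sum(dead) * T_total, 0, 0.002),
                        sum(dead), T_total)
  M[M < 0] <- 0
  M
}

.wells_to_records <- function(M, plate, batch, wells, genotype, treatment, dose_uM) {
  n <- nrow(M); T_total <- ncol(M)
  data.frame(plate = rep(plate, n * T_total),
             batch = rep(batch, n * T_total),
             well = rep(wells, each = T_total),
             genotype = rep(genotype, n * T_total),
             treatment = rep(treatment, n * T_total),
             dose_uM = rep(dose_uM, n * T_total),
             t_sec = rep.int(seq_len(T_total), n),
             displacement_cm = as.vector(t(M)),
             stringsAsFactors = FALSE)
}

#' Simulate a control arm or drug-treated plate trace
#'
#' Generates one plate of `n_larvae` wells per batch under the generative
#' model above. Identical seeds give identical traces; each batch draws its
#' own additive batch effect and its own larvae.
#'
#' @param genotype a [genotype_params()] object.
#' @param n_larvae larvae (wells) per batch, at most 96.
#' @param n_batches number of biological replicates (one plate each).
#' @param drug optional [drug_effect()]; NULL means vehicle.
#' @param protocol the stimulus [vmr_protocol()]; must contain exactly one
#'   light-off event.
#' @param treatment,dose_uM annotation labels for the wells.
#' @param batch_sd sd of the additive per-batch effect, cm.
#' @param well_sd scale of the additive well-column intensity effect, cm.
#' @param seed mandatory RNG seed.
#' @param batch_labels optional character vector of batch ids (length
#'   `n_batches`); plates are named after their batch.
#' @return a `vmr_trace`.
#' @examples
#' tr <- simulate_plate(genotype_params("WT"), n_larvae = 6, n_batches = 2,
#'                      protocol = vmr_protocol(data.frame(
#'                        label = c("dark", "light", "dark"),
#'                        duration_s = c(30, 30, 30), lux = c(0, 0.01, 0))),
#'                      seed = 1)
#' @export
simulate_plate <- function(genotype, n_larvae = 48L, n_batches = 1L,
                           drug = NULL, protocol = vmr_protocol(),
                           treatment = if (is.null(drug)) "DMSO" else "drug",
                           dose_uM = if (is.null(drug)) 0 else 10,
                           batch_sd = 0.01, well_sd = 0.02,
                           seed, batch_labels = NULL) {
  if (!inherits(genotype, "genotype_params"))
    .stop_fmt("`genotype` must be a genotype_params object")
  force(treatment); force(dose_uM)  # defaults depend on `drug` being NULL
  if (is.null(drug)) drug <- drug_effect()
  if (!inherits(drug, "drug_effect")) .stop_fmt("`drug` must be a drug_effect")
  if (!.is_count(n_larvae) || n_larvae < 1 || !.is_count(n_batches) || n_batches < 1)
    .stop_fmt("`n_larvae` and `n_batches` must be positive integers")
  if (missing(seed)) .stop_fmt("`seed` is mandatory")
  .light_off_event(protocol)
  if (is.null(batch_labels))
    batch_labels <- sprintf("B%02d", seq_len(n_batches))
  if (length(batch_labels) != n_batches) .stop_fmt("need one batch label per batch")
  wells <- .plate_wells(n_larvae)
  well_eff <- .well_effect(wells, well_sd)
  out <- vector("list", n_batches)
  for (bi in seq_len(n_batches)) {
    out[[bi]] <- .with_seed(derive_seed(seed, bi), {
      batch_eff <- stats::rnorm(1, 0, batch_sd)
      M <- .simulate_wells(n_larvae, genotype, drug, protocol, batch_eff, well_eff)
      .wells_to_records(M, plate = sprintf("P_%s", batch_labels[bi]),
                        batch = batch_labels[bi], wells = wells,
                        genotype = genotype$genotype,
                        treatment = treatment, dose_uM = dose_uM)
    })
  }
  vmr_trace(do.call(rbind, out), protocol)
}

#' Design of a whole drug screen
#'
#' Defaults follow the screening layout: each drug applied at 10 uM to 24
#' Q344X larvae in two independent replicates, with 9 vehicle-control
#' replicates of 48 larvae.
#'
#' @param n_drugs number of library compounds.
#' @param replicates biological replicates per drug.
#' @param larvae_per_drug larvae per drug per replicate.
#' @param control_replicates vehicle (DMSO) batches.
#' @param control_larvae vehicle larvae per batch.
#' @param batch_sd,well_sd nuisance-effect scales (cm), as in [simulate_plate()].
#' @param seed mandatory master seed.
#' @return an object of class `screen_design`.
#' @export
screen_design <- function(n_drugs = 84L, replicates = 2L, larvae_per_drug = 24L,
                          control_replicates = 9L, control_larvae = 48L,
                          batch_sd = 0.01, well_sd = 0.02, seed) {
  if (missing(seed)) .stop_fmt("`seed` is mandatory")
  for (v in list(replicates, larvae_per_drug, control_replicates, control_larvae))
    if (!.is_count(v) || v < 1) .stop_fmt("screen design counts must be positive")
  if (!.is_count(n_drugs)) .stop_fmt("`n_drugs` must be a non-negative integer")
  if (replicates > control_replicates)
    .stop_fmt("drug replicates must fit inside the control batches")
  structure(list(n_drugs = as.integer(n_drugs), replicates = as.integer(replicates),
                 larvae_per_drug = as.integer(larvae_per_drug),
                 control_replicates = as.integer(control_replicates),
                 control_larvae = as.integer(control_larvae),
                 batch_sd = batch_sd, well_sd = well_sd,
                 seed = as.integer(seed)),
            class = "screen_design")
}

#' Compound library specification with planted toxics and hits
#'
#' @param n_drugs library size.
#' @param n_toxic how many compounds are lethally toxic at screening dose.
#' @param hit_drugs integer indices (among the non-toxic drugs) of planted
#'   active compounds.
#' @param hit_effect the [drug_effect()] planted actives carry; the default is
#'   a carvedilol-like sustained response (amplitude x1.5, tau x4).
#' @param toxic_lethality per-larva death probability for toxic compounds.
#' @return data.frame with one row per drug: drug, amplitude_mult, tau_mult,
#'   lethality, is_toxic, is_hit.
#' @export
screen_library <- function(n_drugs = 84L, n_toxic = 16L, hit_drugs = integer(0),
                           hit_effect = drug_effect(amplitude_mult = 1.5, tau_mult = 4),
                           toxic_lethality = 0.9) {
  if (!.is_count(n_drugs) || !.is_count(n_toxic))
    .stop_fmt("`n_drugs` and `n_toxic` must be non-negative integers")
  if (n_toxic > n_drugs)
    .stop_fmt("more toxic compounds (%d) than drugs (%d)", n_toxic, n_drugs)
  if (n_drugs == 0L)
    return(data.frame(drug = character(0), amplitude_mult = numeric(0),
                      tau_mult = numeric(0), lethality = numeric(0),
                      is_toxic = logical(0), is_hit = logical(0)))
  drug <- sprintf("drug_%03d", seq_len(n_drugs))
  lib <- data.frame(drug = drug, amplitude_mult = 1, tau_mult = 1,
                    lethality = 0, is_toxic = FALSE, is_hit = FALSE,
                    stringsAsFactors = FALSE)
  if (n_toxic > 0L) {
    tox <- seq_len(n_toxic)  # deterministic placement: first block is toxic
    lib$is_toxic[tox] <- TRUE
    lib$lethality[tox] <- toxic_lethality
  }
  if (length(hit_drugs)) {
    hit_drugs <- as.integer(hit_drugs)
    if (any(hit_drugs < 1 | hit_drugs > n_drugs))
      .stop_fmt("`hit_drugs` indices out of range")
    if (any(lib$is_toxic[hit_drugs]))
      .stop_fmt("planted hits must be non-toxic drugs")
    lib$is_hit[hit_drugs] <- TRUE
    lib$amplitude_mult[hit_drugs] <- hit_effect$amplitude_mult
    lib$tau_mult[hit_drugs] <- hit_effect$tau_mult
  }
  lib
}

#' Simulate a whole drug screen
#'
#' Generates vehicle-control batches and, for every library compound,
#' `replicates` treated groups placed in the first batches, all sharing each
#' batch's additive effect. Returns the combined trace plus the ground-truth
#' table for downstream validation.
#'
#' @param design a [screen_design()].
#' @param library a [screen_library()]-style data.frame.
#' @param genotype the screened genotype, default calibrated Q344X.
#' @param protocol the stimulus [vmr_protocol()].
#' @param seed RNG seed; defaults to the design's master seed.
#' @return list with elements `trace` (a `vmr_trace`) and `truth` (the library
#'   table).
#' @export
simulate_screen <- function(design, library = screen_library(design$n_drugs),
                            genotype = genotype_params("Q344X"),
                            protocol = vmr_protocol(), seed = design$seed) {
  if (!inherits(design, "screen_design")) .stop_fmt("`design` must be a screen_design")
  if (nrow(library) != design$n_drugs)
    .stop_fmt("library has %d drugs but the design expects %d",
              nrow(library), design$n_drugs)
  t_off <- .light_off_event(protocol)
  if (t_off + 30L > protocol$duration_s)
    .stop_fmt("protocol too short: need 30 s of recording after light offset")
  batches <- sprintf("B%02d", seq_len(design$control_replicates))
  pieces <- list()
  # one shared batch effect per batch
  batch_eff <- .with_seed(derive_seed(seed, 0L),
                          stats::rnorm(design$control_replicates, 0, design$batch_sd))
  for (bi in seq_along(batches)) {
    wells <- .plate_wells(design$control_larvae)
    M <- .with_seed(derive_seed(seed, bi), {
      .simulate_wells(design$control_larvae, genotype, drug_effect(), protocol,
                      batch_eff[bi], .well_effect(wells, design$well_sd))
    })
    pieces[[length(pieces) + 1L]] <-
      .wells_to_records(M, plate = sprintf("P_%s_veh", batches[bi]),
                        batch = batches[bi], wells = wells,
                        genotype = genotype$genotype,
                        treatment = "DMSO", dose_uM = 0)
  }
  if (design$n_drugs > 0L) {
    # treated wells: chunk drugs into plates of <= 96 wells within each batch
    per_plate <- max(1L, 96L %/% design$larvae_per_drug)
    for (di in seq_len(design$n_drugs)) {
      eff <- drug_effect(amplitude_mult = library$amplitude_mult[di],
                         tau_mult = library$tau_mult[di],
                         toxic = library$is_toxic[di],
                         lethality = library$lethality[di])
      for (ri in seq_len(design$replicates)) {
        plate_no <- (di - 1L) %/% per_plate + 1L
        slot <- (di - 1L) %% per_plate
        wells <- paste0(rep(LETTERS[1:8], each = 12L),
                        rep(1:12, 8L))[slot * design$larvae_per_drug +
                                         seq_len(design$larvae_per_drug)]
        M <- .with_seed(derive_seed(seed, 1000L + di * 10L + ri), {
          .simulate_wells(design$larvae_per_drug, genotype, eff, protocol,
                          batch_eff[ri], .well_effect(wells, design$well_sd))
        })
        pieces[[length(pieces) + 1L]] <-
          .wells_to_records(M, plate = sprintf("P_%s_%02d", batches[ri], plate_no),
                            batch = batches[ri], wells = wells,
                            genotype = genotype$genotype,
                            treatment = library$drug[di], dose_uM = 10)
      }
    }
  }
  list(trace = vmr_trace(do.call(rbind, pieces), protocol), truth = library)
}

#' Simulate a GloSensor-style luminescence dose-response table
#'
#' Responses follow the logistic model used by [fit_logistic()]:
#' `bottom + (top - bottom) / (1 + 10^((pXC50 + log10(dose)) * hill * s))`
#' with `s = -1` for agonist (response rises with dose) and `s = +1` for
#' antagonist curves, plus Gaussian noise.
#'
#' @param curve list with `bottom`, `top`, `pXC50` (-log10 molar) and `hill`.
#' @param doses molar concentrations (> 0).
#' @param orientation `"agonist"` or `"antagonist"`.
#' @param n_wells replicate wells per dose.
#' @param noise_sd Gaussian noise sd on the response scale.
#' @param seed mandatory RNG seed.
#' @param experiment experiment label.
#' @return data.frame with columns experiment, dose_M, well, luminescence.
#' @export
simulate_dose_response <- function(curve = list(bottom = 0, top = 1, pXC50 = 7.49, hill = 1),
                                   doses = 10^seq(-9, -5, by = 0.5),
                                   orientation = c("agonist", "antagonist"),
                                   n_wells = 4L, noise_sd = 0.05, seed,
                                   experiment = "E1") {
  orientation <- match.arg(orientation)
  if (missing(seed)) .stop_fmt("`seed` is mandatory")
  if (any(!is.finite(doses)) || any(doses <= 0))
    .stop_fmt("doses must be positive molar concentrations")
  if (is.null(curve$hill)) curve$hill <- 1
  if (curve$top < curve$bottom) .stop_fmt("`top` must be >= `bottom`")
  s <- if (orientation == "agonist") -1 else 1
  mu <- curve$bottom + (curve$top - curve$bottom) /
    (1 + 10^((curve$pXC50 + log10(doses)) * curve$hill * s))
  .with_seed(seed, {
    df <- data.frame(
      experiment = experiment,
      dose_M = rep(doses, each = n_wells),
      well = rep(seq_len(n_wells), times = length(doses)),
      luminescence = rep(mu, each = n_wells) +
        stats::rnorm(length(doses) * n_wells, 0, noise_sd),
      stringsAsFactors = FALSE)
    df
  })
}
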