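sim_screen_trace <- function(n_drugs = 6, n_toxic = 1, hit = integer(0),
                             seed = 42, protocol = short_protocol(),
                             control_replicates = 3, control_larvae = 24,
                             larvae_per_drug = 12) {
  des <- screen_design(n_drugs = n_drugs, control_replicates = control_replicates,
                       control_larvae = control_larvae,
                       larvae_per_drug = larvae_per_drug, seed = seed)
  simulate_screen(des, screen_library(n_drugs, n_toxic, hit_drugs = hit),
                  protocol = protocol)
}

test_that("fully lethal plates are toxic and healthy plates are not", {
  sim <- sim_screen_trace(n_drugs = 2, n_toxic = 1, seed = 11,
                          protocol = tiny_protocol())
  tox <- flag_toxic(sim$trace, "drug_001")  # planted toxic, lethality 0.9
  expect_true(tox$toxic)
  ok <- flag_toxic(sim$trace, "drug_002")
  expect_false(ok$toxic)
  expect_equal(sum(ok$diagnostics$n), 2 * 12)
  expect_error(flag_toxic(sim$trace, "drug_099"), "no wells")
})

test_that("60% lethality is flagged toxic in nearly every realization", {
  proto <- tiny_protocol()
  q <- genotype_params("Q344X")
  flagged <- vapply(1:100, function(i) {
    s <- derive_seed(6000, i)
    veh <- simulate_plate(q, n_larvae = 24, protocol = proto, seed = s,
                          batch_labels = "B09")
    drg <- simulate_plate(q, n_larvae = 24, n_batches = 2,
                          drug = drug_effect(lethality = 0.6),
                          treatment = "drug_X", protocol = proto,
                          seed = derive_seed(s, 3))
    both <- vmr_trace(rbind(as.data.frame(veh), as.data.frame(drg)), proto)
    flag_toxic(both, "drug_X")$toxic
  }, logical(1))
  expect_gte(mean(flagged), 0.95)
})

test_that("replicate consistency passes near-copies and fails planted shifts", {
  set.seed(21)
  rep1 <- gauss_window(24, 30)
  rep2 <- rep1 + matrix(rnorm(24 * 30, 0, 0.01), 24, 30)
  res <- replicate_consistency(rep1, rep2, seed = 5)
  expect_true(res$pass)
  expect_gt(res$p_value, 0.9)

  fails <- vapply(1:200, function(i) {
    set.seed(7000 + i)
    a <- matrix(rnorm(24 * 30), 24, 30)
    b <- matrix(rnorm(24 * 30), 24, 30)
    b[, 1:10] <- b[, 1:10] + 3
    !replicate_consistency(a, b, n_boot = 400, seed = i)$pass
  }, logical(1))
  expect_gte(mean(fails), 0.95)
})

test_that("a consistency p-value exactly at the cutoff fails (strict rule)", {
  local_mocked_bindings(
    hd_two_sample_test = function(...) list(p.value = 0.9),
    .package = "vmrscreen")
  res <- replicate_consistency(gauss_window(4, 3, seed = 1),
                               gauss_window(4, 3, seed = 2), seed = 1)
  expect_equal(res$p_value, 0.9)
  expect_false(res$pass)
})

test_that("identical drug and vehicle groups are never significant", {
  x <- gauss_window(24, 30, seed = 31)
  res <- drug_vs_control(x, x)
  expect_false(res$pass)
  expect_equal(res$p_values, 1)
})

test_that("the sustained planted effect is detected on pooled replicates", {
  proto <- tiny_protocol()
  q <- genotype_params("Q344X")
  hit <- drug_effect(amplitude_mult = 1.5, tau_mult = 4)
  pass <- vapply(1:200, function(i) {
    s <- derive_seed(8000, i)
    veh <- simulate_plate(q, n_larvae = 96, protocol = proto, seed = s)
    drg <- simulate_plate(q, n_larvae = 48, drug = hit, treatment = "drug",
                          protocol = proto, seed = derive_seed(s, 1))
    wv <- extract_window(veh, start_offset = 1, end_offset = 30)
    wd <- extract_window(drg, start_offset = 1, end_offset = 30)
    drug_vs_control(wd, wv)$pass
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("a first-second-only effect is easiest to see in the 1-s window", {
  proto <- tiny_protocol()
  q <- genotype_params("Q344X")
  # burst with near-instant decay: effectively confined to offset+1
  brief <- genotype_params(startle_amplitude = 3 * q$startle_amplitude,
                           startle_sd = q$startle_sd, startle_tau = 0.2,
                           baseline_rate = q$baseline_rate,
                           baseline_dispersion = q$baseline_dispersion,
                           noise_sd = q$noise_sd)
  base <- genotype_params(startle_amplitude = q$startle_amplitude,
                          startle_sd = q$startle_sd, startle_tau = 0.2,
                          baseline_rate = q$baseline_rate,
                          baseline_dispersion = q$baseline_dispersion,
                          noise_sd = q$noise_sd)
  res <- vapply(1:100, function(i) {
    s <- derive_seed(8500, i)
    veh <- simulate_plate(base, n_larvae = 96, protocol = proto, seed = s)
    drg <- simulate_plate(brief, n_larvae = 48, treatment = "drug",
                          protocol = proto, seed = derive_seed(s, 1))
    c(p1 = drug_vs_control(extract_window(drg, start_offset = 1, end_offset = 1),
                           extract_window(veh, start_offset = 1, end_offset = 1))$pass,
      p30 = drug_vs_control(extract_window(drg, start_offset = 1, end_offset = 30),
                            extract_window(veh, start_offset = 1, end_offset = 30))$pass)
  }, logical(2))
  power_1s <- mean(res["p1", ])
  power_30s <- mean(res["p30", ])
  expect_gte(power_1s, 0.9)
  expect_gte(power_1s, power_30s)
})

test_that("run_screen produces a monotone funnel matching planted toxicity", {
  sim <- sim_screen_trace(n_drugs = 6, n_toxic = 2, hit = 5, seed = 101)
  res <- run_screen(sim$trace, seed = 9, n_boot = 400)
  expect_s3_class(res, "vmr_screen")
  s <- res$summary
  expect_equal(s$starting, 6L)
  expect_equal(s$non_toxic, 4L)
  flagged <- unique(res$records$drug[res$records$toxic])
  expect_setequal(flagged, sim$truth$drug[sim$truth$is_toxic])
  for (i in seq_len(nrow(s$per_window))) {
    expect_lte(s$per_window$hits[i], s$per_window$consistent[i])
    expect_lte(s$per_window$consistent[i], s$non_toxic)
  }
  expect_lte(s$non_toxic, s$starting)
  # toxic drugs never reach the later criteria
  expect_true(all(!res$records$hit[res$records$toxic]))
  expect_true(all(is.na(res$records$consistency_p[res$records$toxic])))
})

test_that("run_screen is deterministic given a seed", {
  sim <- sim_screen_trace(n_drugs = 3, n_toxic = 0, seed = 55,
                          protocol = short_protocol(120L, 60L, 40L),
                          control_replicates = 2, control_larvae = 12,
                          larvae_per_drug = 8)
  wins <- list(c(1L, 1L), c(1L, 10L))  # sized to the small control groups
  r1 <- run_screen(sim$trace, windows = wins, seed = 3, n_boot = 300)
  r2 <- run_screen(sim$trace, windows = wins, seed = 3, n_boot = 300)
  expect_identical(r1$records, r2$records)
})

test_that("run_screen enforces design preconditions", {
  sim <- sim_screen_trace(n_drugs = 2, n_toxic = 0, seed = 77,
                          protocol = tiny_protocol())
  df <- as.data.frame(sim$trace)
  no_veh <- vmr_trace(df[df$treatment != "DMSO", ], trace_protocol(sim$trace))
  expect_error(run_screen(no_veh, seed = 1), "design error")
  drop_b1 <- vmr_trace(df[!(df$treatment == "DMSO" & df$batch == "B01"), ],
                       trace_protocol(sim$trace))
  expect_error(run_screen(drop_b1, seed = 1), "design error")
  expect_error(run_screen(sim$trace), "seed")
})

test_that("a vehicle-only screen yields an empty summary without error", {
  des <- screen_design(n_drugs = 0, control_replicates = 2, control_larvae = 8,
                       seed = 5)
  sim <- simulate_screen(des, screen_library(0, 0), protocol = tiny_protocol())
  res <- run_screen(sim$trace, seed = 2)
  expect_equal(nrow(res$records), 0L)
  expect_equal(res$summary$starting, 0L)
})

test_that("summarize_screen reproduces the published funnel shape", {
  # counting fixture in the shape of the published table: 84 drugs, 16 toxic,
  # 4 consistent in the 30-s window of which 1 is the hit
  drugs <- sprintf("d%02d", 1:84)
  toxic <- drugs[1:16]
  consistent30 <- drugs[17:20]
  hit30 <- drugs[17]
  rec <- rbind(
    data.frame(drug = drugs, window = "1-1 s", toxic = drugs %in% toxic,
               consistent = drugs %in% drugs[21:25], hit = FALSE),
    data.frame(drug = drugs, window = "1-30 s", toxic = drugs %in% toxic,
               consistent = drugs %in% consistent30, hit = drugs %in% hit30))
  s <- summarize_screen(rec)
  expect_equal(s$starting, 84L)
  expect_equal(s$non_toxic, 68L)
  expect_equal(s$per_window$consistent[s$per_window$window == "1-30 s"], 4L)
  expect_equal(s$per_window$hits[s$per_window$window == "1-30 s"], 1L)
  expect_equal(s$per_window$consistent[s$per_window$window == "1-1 s"], 5L)
  expect_equal(s$per_window$hits[s$per_window$window == "1-1 s"], 0L)
  expect_equal(s$hit_drugs[["1-30 s"]], "d17")

  # order invariance and the all-toxic degenerate case
  s2 <- summarize_screen(rec[sample.int(nrow(rec)), ])
  expect_equal(s2$per_window[order(s2$per_window$window), ],
               s$per_window[order(s$per_window$window), ],
               ignore_attr = TRUE)
  all_tox <- rec; all_tox$toxic <- TRUE; all_tox$consistent <- FALSE; all_tox$hit <- FALSE
  s3 <- summarize_screen(all_tox)
  expect_equal(s3$non_toxic, 0L)
  expect_true(all(s3$per_window$consistent == 0))
})
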