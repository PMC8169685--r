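# Shared fixtures: all synthetic, built in code.

# Short protocols keep simulation cheap; window structure (one light-off
# event, >= 30 s of post-offset recording) matches the full assay.
short_protocol <- function(dark = 300L, light = 120L, off = 60L)
  vmr_protocol(data.frame(label = c("dark", "light", "dark"),
                          duration_s = c(dark, light, off),
                          lux = c(0, 0.01, 0)))

tiny_protocol <- function() short_protocol(60L, 60L, 40L)

# A hand-sized trace: n wells, deterministic displacement values.
toy_trace <- function(n_wells = 3L, n_sec = 9L, protocol = NULL) {
  if (is.null(protocol))
    protocol <- vmr_protocol(data.frame(label = c("dark", "light", "dark"),
                                        duration_s = c(3L, 3L, n_sec - 6L),
                                        lux = c(0, 0.01, 0)))
  wells <- paste0("A", seq_len(n_wells))
  df <- expand.grid(t_sec = seq_len(n_sec), well = wells,
                    stringsAsFactors = FALSE)
  df$plate <- "P1"; df$batch <- "B1"; df$genotype <- "Q344X"
  df$treatment <- "DMSO"; df$dose_uM <- 0
  df$displacement_cm <- round(abs(sin(seq_len(nrow(df)))) / 10, 4)
  vmr_trace(df, protocol)
}

# Gaussian window matrices for the multivariate tests.
gauss_window <- function(n, p, shift = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(n * p), n, p)
  if (length(shift) == 1L) shift <- rep(shift, p)
  sweep(m, 2, shift, `+`)
}

expect_p_value <- function(p) {
  expect_true(is.finite(p))
  expect_gte(p, 0)
  expect_lte(p, 1)
}
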