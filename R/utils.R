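# Internal helpers shared across modules.

#' @keywords internal
.stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

#' Derive a reproducible child seed from a master seed
#'
#' A single master seed drives every stochastic stage; per-plate, per-drug and
#' per-bootstrap streams get their own derived seeds so stages can be re-run in
#' isolation. The derivation is a fixed affine step modulo the Mersenne prime
#' 2^31 - 1, so results stay inside R's 32-bit integer range.
#'
#' @param seed master seed (single finite number).
#' @param index non-negative stream index.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, index = 0L) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    .stop_fmt("`seed` must be a single finite number")
  m <- 2147483647
  s <- (abs(as.double(seed)) %% m)
  for (k in seq_len(as.integer(index) + 1L))
    s <- (s * 48271 + 11 + k) %% m
  as.integer(max(1, s))
}

# Evaluate expr with a locally-set RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  force(seed)  # before the state snapshot: `seed` may itself consume RNG draws
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

.is_prob <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x <= 1

# Polynomial rolling hash of a raw vector modulo the Mersenne prime 2^31 - 1,
# returned as 8 hex characters. Used only for run manifests (no cryptographic
# intent); plain double arithmetic keeps every intermediate exactly
# representable.
.fnv1a <- function(bytes) {
  m <- 2147483647
  h <- 17
  for (b in as.integer(bytes))
    h <- (h * 31 + b + 1) %% m
  sprintf("%08x", as.integer(h))
}
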