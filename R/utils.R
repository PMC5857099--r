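## Shared internal helpers: seed substreams, CPM, NB sampling, validation.

#' @importFrom stats rnbinom rnorm
NULL

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("rbpscreen_invalid_input", "error")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper)
    stop_invalid(name, " must be in ", if (strict_lower) "(" else "[",
                 lower, ", ", upper, "]")
  invisible(x)
}

#' Derive a reproducible per-generator substream seed
#'
#' One global seed expands to independent substreams, one per generator, so
#' adding a generator never perturbs the draws of another. The substream seed
#' is a deterministic 31-bit hash of the global seed and the stream name.
#'
#' @param seed integer global seed.
#' @param name character stream name, e.g. `"rip"`.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
#' @noRd
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  ## 31-bit mix, kept well inside R's integer range
  as.integer((as.numeric(seed) * 48271 + h * 69621) %% 2147483647)
}

with_substream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

## counts per million for a count vector/matrix given library sizes
cpm_of <- function(counts, lib_sizes) {
  if (any(lib_sizes <= 0)) stop_invalid("library sizes must be > 0")
  if (is.matrix(counts)) {
    sweep(counts, 2L, lib_sizes, "/") * 1e6
  } else {
    counts / lib_sizes * 1e6
  }
}

## NB sampler parameterized by mean and dispersion (var = mu + disp * mu^2);
## dispersion ~ 0 degenerates to Poisson.
rnb <- function(n, mu, dispersion) {
  if (dispersion <= 1e-12) return(stats::rpois(n, lambda = mu))
  rnbinom(n, mu = mu, size = 1 / dispersion)
}

gene_ids <- function(n, prefix = "G") sprintf("%s%04d", prefix, seq_len(n))
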