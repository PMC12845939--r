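#' @keywords internal
#' @import stats
#' @importFrom utils head tail combn read.csv write.csv
"_PACKAGE"

# All randomness in the package flows from one root seed through named
# substreams so that e.g. the iris renderer and the cohort sampler can be
# re-run independently without disturbing each other.
substream_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 65521
  s <- (as.numeric(seed) %% 2147483647) * 7919 + h * 104729
  as.integer(s %% 2147483646) + 1L
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# state is restored afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Equicorrelated multivariate normal draw via the one-factor construction:
# u_j = sqrt(rho) g + sqrt(1 - rho) e_j, exact for an equicorrelation matrix.
rmvn_equicorr <- function(n, p, rho) {
  if (rho < 0 || rho >= 1)
    stop("equicorrelation must lie in [0, 1) for a positive-definite matrix")
  g <- rnorm(n)
  e <- matrix(rnorm(n * p), n, p)
  sqrt(rho) * g + sqrt(1 - rho) * e
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
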