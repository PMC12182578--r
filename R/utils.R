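# seed hygiene: run code under a seed, restore the caller's RNG state after
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# balanced partition of n items into k contiguous runs (sizes differ by <= 1)
split_sizes <- function(n, k) {
  cuts <- round(seq(0, n, length.out = k + 1))
  diff(cuts)
}

# spatially autocorrelated standard field: white noise convolved with a
# Gaussian kernel by FFT (circular), then standardized to mean 0 / sd 1
smooth_field <- function(nr, nc, corr_len) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (corr_len <= 0) return(z)
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- exp(-outer(di^2, dj^2, `+`) / (2 * corr_len^2))
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k / sum(k)), inverse = TRUE)) /
    (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

# min-max squash to [0, 1]; constant input maps to 0
unit_scale <- function(x) {
  r <- range(x)
  if (r[2] == r[1]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}
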