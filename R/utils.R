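# Internal numerical helpers shared by the phantom generator and the
# layering/vessel analysis.

# Row-normalised 1D Gaussian convolution matrix (truncated at 3 sigma,
# renormalised at the edges so constants are preserved).
.gauss_convmat <- function(n, sigma_px) {
  if (sigma_px <= 0.05) return(NULL)
  h <- max(1L, as.integer(ceiling(3 * sigma_px)))
  off <- -h:h
  w <- stats::dnorm(off, sd = sigma_px)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    ok <- j >= 1L & j <= n
    K[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  K
}

# Separable Gaussian blur of a [nx, ny, nz] array, FWHM given per axis in um.
.blur_volume <- function(a, spacing, fwhm_lateral, fwhm_axial) {
  d <- dim(a)
  sig <- c(fwhm_lateral / 2.35482 / spacing[1L],
           fwhm_lateral / 2.35482 / spacing[2L],
           fwhm_axial / 2.35482 / spacing[3L])
  Kx <- .gauss_convmat(d[1L], sig[1L])
  if (!is.null(Kx)) {
    dim(a) <- c(d[1L], d[2L] * d[3L]); a <- Kx %*% a; dim(a) <- d
  }
  Ky <- .gauss_convmat(d[2L], sig[2L])
  if (!is.null(Ky)) {
    a <- aperm(a, c(2L, 1L, 3L))
    dim(a) <- c(d[2L], d[1L] * d[3L]); a <- Ky %*% a
    dim(a) <- c(d[2L], d[1L], d[3L]); a <- aperm(a, c(2L, 1L, 3L))
  }
  Kz <- .gauss_convmat(d[3L], sig[3L])
  if (!is.null(Kz)) {
    dim(a) <- c(d[1L] * d[2L], d[3L]); a <- a %*% t(Kz); dim(a) <- d
  }
  a
}

# Running suffix maximum along the columns of a [n, nz] matrix:
# out[, k] = max(m[, k], ..., m[, nz]). Lets a maximum amplitude projection
# below any depth be read off as a single slice.
.suffix_max <- function(m) suffix_max_z(m)

# Evaluate an RNG-dependent expression under a local seed without disturbing
# the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Quantile helper returning 0 for empty input.
.q <- function(x, p) if (length(x) == 0L) 0 else
  as.numeric(stats::quantile(x, p, names = FALSE, type = 7))
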