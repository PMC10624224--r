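#' Background-noise model
#'
#' The imaging system's background noise is summarised by a single amplitude
#' `floor`: voxels at or below it are treated as signal-free. The floor is
#' either fixed by the user or estimated as a percentile of the pre-surface
#' (air/coupling-medium) region, see [estimate_noise_floor()].
#'
#' @param floor non-negative amplitude threshold, same units as the volume.
#' @param method `"fixed"` or `"percentile"`.
#' @param percentile the percentile used when `method = "percentile"`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(floor, method = c("fixed", "percentile"), percentile = NA_real_) {
  method <- match.arg(method)
  if (!is.numeric(floor) || length(floor) != 1L || is.na(floor) || floor < 0)
    stop("`floor` must be a single non-negative number")
  if (method == "percentile" && !(is.numeric(percentile) && percentile > 0 && percentile < 100))
    stop("`percentile` must lie in (0, 100)")
  structure(list(floor = as.numeric(floor), method = method,
                 percentile = as.numeric(percentile)),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> floor = %g (%s%s)\n", x$floor, x$method,
              if (x$method == "percentile") sprintf(" %g", x$percentile) else ""))
  invisible(x)
}

# Vectorised running median along the z axis of a [ncol, nz] matrix.
# Small windows (1, 3, 5) use min/max selection networks; larger odd windows
# fall back to per-window sorting. Edges are reflected (edge sample included).
.alines_runmed <- function(m, window) {
  nz <- ncol(m)
  if (window == 1L) return(m)
  h <- (window - 1L) %/% 2L
  if (window == 3L) return(median3_z(m))
  # reflect-pad columns: [h, ..., 1] | 1..nz | [nz, ..., nz-h+1]
  pad <- cbind(m[, h:1, drop = FALSE], m, m[, nz:(nz - h + 1L), drop = FALSE])
  if (window == 5L) {
    s <- lapply(0:4, function(k) pad[, (1L + k):(nz + k), drop = FALSE])
    # partial sorting network selecting the median of 5
    lo <- function(x, y) pmin(x, y); hi <- function(x, y) pmax(x, y)
    a <- s[[1]]; b <- s[[2]]; cc <- s[[3]]; d <- s[[4]]; e <- s[[5]]
    t1 <- lo(a, b); a <- hi(a, b); b <- t1
    t1 <- lo(d, e); d <- hi(d, e); e <- t1
    t1 <- lo(a, d); a <- hi(a, d); d <- t1   # a is overall max candidate out
    t1 <- lo(b, e); b <- hi(b, e); e <- t1   # e is overall min candidate out
    # median of remaining {b, cc, d}
    return(pmax(pmin(b, cc), pmin(pmax(b, cc), d)))
  }
  out <- m
  for (k in seq_len(nz)) {
    block <- pad[, k:(k + window - 1L), drop = FALSE]
    out[, k] <- apply(block, 1L, stats::median)
  }
  out
}

#' Median-filter every A-line of a volume
#'
#' Applies a 1D median filter of odd width independently along the depth (z)
#' axis of every lateral position, removing one-sample impulse noise while
#' preserving the broad axial point-spread peak. Edges are handled by
#' reflection; `window = 1` is the identity.
#'
#' @param volume a [pa_volume()].
#' @param window odd positive integer, `<=` number of axial samples.
#' @return A filtered [pa_volume()] of identical shape and spacing.
#' @export
median_filter_alines <- function(volume, window = 3L) {
  stopifnot(inherits(volume, "pa_volume"))
  window <- as.integer(window)
  nz <- dim(volume$amplitude)[3L]
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("`window` must be a positive odd integer")
  if (window > nz)
    stop("`window` exceeds the number of axial samples (", nz, ")")
  a <- volume$amplitude
  d <- dim(a)
  dim(a) <- c(d[1L] * d[2L], d[3L])
  a <- .alines_runmed(a, window)
  dim(a) <- d
  volume$amplitude <- a
  volume
}

#' Estimate the background-noise floor from the pre-surface region
#'
#' The shallowest three axial samples of every A-line precede the skin
#' surface (air or coupling medium) and carry only system noise. The floor
#' is a percentile of the amplitudes in that region; the default percentile
#' used by the pipeline is 99.
#'
#' @param volume a [pa_volume()] with at least 4 axial samples.
#' @param percentile percentile in (0, 100).
#' @return A [noise_model()] with `method = "percentile"`.
#' @export
estimate_noise_floor <- function(volume, percentile = 99) {
  stopifnot(inherits(volume, "pa_volume"))
  if (dim(volume$amplitude)[3L] < 4L)
    stop("volume needs at least 4 axial samples to expose a pre-surface region")
  if (!(is.numeric(percentile) && percentile > 0 && percentile < 100))
    stop("`percentile` must lie in (0, 100)")
  top <- volume$amplitude[, , 1:3]
  floor <- as.numeric(stats::quantile(top, percentile / 100, names = FALSE, type = 7))
  noise_model(floor, method = "percentile", percentile = percentile)
}

#' Suppress background noise by hard thresholding
#'
#' Voxels with amplitude at or below the noise floor are set to 0; voxels
#' above it are unchanged (no rescaling). The operation is idempotent.
#'
#' @param volume a [pa_volume()].
#' @param noise a [noise_model()].
#' @return The thresholded [pa_volume()].
#' @export
apply_threshold <- function(volume, noise) {
  stopifnot(inherits(volume, "pa_volume"), inherits(noise, "noise_model"))
  a <- volume$amplitude
  a[a <= noise$floor] <- 0
  volume$amplitude <- a
  volume
}
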