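#' Segment vessels on a dermal MAP image
#'
#' Pixels above the background floor are first binarised at Otsu's
#' threshold (computed on the above-floor amplitude histogram) after light
#' Gaussian smoothing. The threshold is then refined to a fraction of the
#' segmented structures' robust peak amplitude (`peak_frac`, default 0.4):
#' on a maximum amplitude projection a thin tube loses apparent amplitude
#' towards its lateral edge (short chords against the axial point spread),
#' so a cut slightly below half-maximum recovers the true width where a
#' plain Otsu cut erodes it. Components smaller than `min_component_px`
#' are removed as speckle, and compact components are removed as punctate
#' pigment: a component is kept only when its area divided by the square of
#' its maximum inscribed radius reaches `min_shape_ratio` (a disc scores
#' about pi, a tube of length L and width w about 4L/w). An entirely
#' sub-floor MAP yields an empty mask, not an error.
#'
#' @param map a [map_image][max_amplitude_projection()] of the dermis
#'   (XY plane).
#' @param noise a [noise_model()].
#' @param smooth_sigma Gaussian smoothing scale in pixels (0 disables).
#' @param min_component_px minimum connected-component size kept.
#' @param min_shape_ratio minimum area / (max inscribed radius)^2 kept;
#'   set 0 to disable the shape filter.
#' @param peak_frac refined threshold as a fraction of the 99th-percentile
#'   amplitude of the Otsu-segmented pixels; `NULL` keeps the plain Otsu cut.
#' @param threshold optional fixed threshold overriding both.
#' @return An object of class `vessel_mask`: list with `mask` (logical
#'   matrix) and pixel spacings `d1`, `d2` (micrometres).
#' @export
segment_vessels <- function(map, noise, smooth_sigma = 1,
                            min_component_px = 10L, min_shape_ratio = 5,
                            peak_frac = 0.4, threshold = NULL) {
  stopifnot(inherits(map, "map_image"), inherits(noise, "noise_model"))
  px <- map$pixels
  sm <- if (smooth_sigma > 0) as.matrix(EBImage::gblur(px, sigma = smooth_sigma)) else px
  above <- sm > noise$floor
  out <- structure(list(mask = matrix(FALSE, nrow(px), ncol(px)),
                        d1 = map$d1, d2 = map$d2), class = "vessel_mask")
  if (!any(above)) return(out)
  if (is.null(threshold)) {
    thr <- .otsu_threshold(sm[above])
    if (!is.null(peak_frac) && any(above & sm > thr))
      thr <- max(noise$floor, peak_frac * .q(sm[above & sm > thr], 0.99))
  } else {
    thr <- threshold
  }
  mask <- above & sm > thr
  if (any(mask) && (min_component_px > 1L || min_shape_ratio > 0)) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- sizes >= min_component_px
    if (min_shape_ratio > 0)
      keep <- keep & .component_shape_ratio(mask, lab, length(sizes)) >=
        min_shape_ratio
    mask <- matrix(as.vector(lab) %in% which(keep), nrow(px), ncol(px))
  }
  out$mask <- mask
  out
}

# Area / (maximum inscribed radius)^2 per labelled component: ~pi for a
# disc, ~4 * length / width for a tube. Scale-free blob-vs-tube measure.
.component_shape_ratio <- function(mask, lab, n_comp) {
  dist <- as.matrix(EBImage::distmap(mask * 1))
  sel <- lab > 0
  g <- as.vector(lab)[sel]
  area <- tabulate(g, n_comp)
  rmax <- rep(1e-9, n_comp)
  mx <- tapply(dist[sel], g, max)
  rmax[as.integer(names(mx))] <- mx
  area / rmax^2
}

# Otsu's threshold on a numeric vector: the cut maximising between-class
# variance of a 256-bin histogram. A flat maximum (an empty gap between the
# modes) resolves to its middle; a constant input thresholds just below it.
.otsu_threshold <- function(v, levels = 256L) {
  r <- range(v)
  if (r[1L] == r[2L]) return(r[1L] - 1e-9 * max(1, abs(r[1L])))
  h <- graphics::hist(v, breaks = seq(r[1L], r[2L], length.out = levels + 1L),
                      plot = FALSE)
  cnt <- h$counts; mids <- h$mids
  w1 <- cumsum(cnt); w2 <- sum(cnt) - w1
  mu <- cumsum(cnt * mids)
  mu1 <- mu / pmax(w1, 1); mu2 <- (mu[length(mu)] - mu) / pmax(w2, 1)
  between <- (w1 * w2 * (mu1 - mu2)^2)[-length(cnt)]
  ks <- which(between >= max(between) * (1 - 1e-12))
  h$breaks[ks[ceiling(length(ks) / 2)] + 1L]
}

#' Construct a vessel mask from a logical matrix
#'
#' Mostly useful for validating the morphometric estimators on masks of
#' known geometry; [segment_vessels()] produces masks from image data.
#'
#' @param mask logical matrix (vessel = `TRUE`).
#' @param d1,d2 pixel spacing, micrometres.
#' @return A `vessel_mask`.
#' @export
vessel_mask <- function(mask, d1 = 1, d2 = d1) {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(list(mask = mask, d1 = d1, d2 = d2), class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d px, %d vessel pixels (%.1f%%)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Vessel area density
#'
#' The ratio of vessel pixels to total pixels within the analysed region:
#' exact integer arithmetic, a fraction in `[0, 1]`.
#'
#' @param mask a [vessel_mask][segment_vessels()].
#' @param roi optional logical matrix restricting the analysed area
#'   (default: all pixels).
#' @return Density as a fraction.
#' @export
vessel_density <- function(mask, roi = NULL) {
  stopifnot(inherits(mask, "vessel_mask"))
  m <- mask$mask
  if (is.null(roi)) roi <- matrix(TRUE, nrow(m), ncol(m))
  stopifnot(identical(dim(roi), dim(m)))
  n_roi <- sum(roi)
  if (n_roi == 0L) stop("empty ROI")
  sum(m & roi) / n_roi
}

# Zhang-Suen morphological thinning of a logical matrix down to a 1-pixel
# skeleton. Vectorised over the image; iterates until stable.
.skeletonize <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  if (!any(m)) return(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  get_nb <- function(p) {
    i <- 2:(nr + 1L); j <- 2:(nc + 1L)
    list(p2 = p[i - 1L, j], p3 = p[i - 1L, j + 1L], p4 = p[i, j + 1L],
         p5 = p[i + 1L, j + 1L], p6 = p[i + 1L, j], p7 = p[i + 1L, j - 1L],
         p8 = p[i, j - 1L], p9 = p[i - 1L, j - 1L])
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      pad[2:(nr + 1L), 2:(nc + 1L)] <- m
      nb <- get_nb(pad)
      bsum <- Reduce(`+`, nb)
      seqn <- with(nb, list(p2, p3, p4, p5, p6, p7, p8, p9, p2))
      a <- Reduce(`+`, lapply(1:8, function(k) !seqn[[k]] & seqn[[k + 1L]]))
      if (phase == 1L) {
        c1 <- !(nb$p2 & nb$p4 & nb$p6)
        c2 <- !(nb$p4 & nb$p6 & nb$p8)
      } else {
        c1 <- !(nb$p2 & nb$p4 & nb$p8)
        c2 <- !(nb$p2 & nb$p6 & nb$p8)
      }
      del <- m & bsum >= 2 & bsum <= 6 & a == 1 & c1 & c2
      if (any(del)) {
        m[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Mean vessel diameter from skeleton and distance transform
#'
#' The mask is thinned to its centerline skeleton; at each skeleton pixel
#' the local diameter is twice the Euclidean distance to the nearest
#' background pixel (minus half a pixel for the pixel-center offset), scaled
#' by the lateral spacing. The mean over skeleton pixels is the standard
#' morphometric diameter estimate, accurate to about one pixel on straight
#' bands.
#'
#' @param mask a [vessel_mask][segment_vessels()] with isotropic pixels.
#' @return Mean diameter in micrometres; 0 for an empty mask.
#' @export
mean_vessel_diameter <- function(mask) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (!isTRUE(all.equal(mask$d1, mask$d2)))
    stop("diameter estimation requires isotropic pixels (dx = dy = ",
         mask$d1, "/", mask$d2, " um); resample the MAP first")
  if (!any(mask$mask)) return(0)
  g <- .vessel_geometry(mask)
  mean(2 * (g$dist[g$skel] - 0.5)) * mask$d1
}

# Skeleton and Euclidean distance transform of a mask, computed once and
# cached on the object environment-free way: recomputed per call unless the
# caller passes it around (the pipeline does).
.vessel_geometry <- function(mask) {
  list(skel = .skeletonize(mask$mask),
       dist = as.matrix(EBImage::distmap(mask$mask * 1)))
}

#' Correlation between local vessel diameter and local density
#'
#' Partitions the mask into a grid of square tiles; every tile containing at
#' least one vessel pixel contributes a (local diameter, local density)
#' pair, where the local diameter is sampled at the skeleton pixels of the
#' tile (or, lacking any, at the tile's thickest point). Returns the Pearson
#' correlation with its two-sided p-value from the t distribution on
#' `n_tiles - 2` degrees of freedom. Zero variance in either variable makes
#' the correlation undefined: `r` and `p` are `NA` with a warning, never a
#' silent 0.
#'
#' @param mask a [vessel_mask][segment_vessels()].
#' @param tile_px tile side length in pixels.
#' @param geometry optional precomputed skeleton/distance-transform pair
#'   (internal reuse by the pipeline).
#' @return A list with `r`, `p`, `n_tiles` and `tiles` (data.frame with
#'   per-tile `phi_um` and `rho`).
#' @export
diameter_density_correlation <- function(mask, tile_px = 32L, geometry = NULL) {
  stopifnot(inherits(mask, "vessel_mask"))
  tiles <- .vessel_tiles(mask, tile_px, geometry)
  if (nrow(tiles) < 3L)
    stop("insufficient data: fewer than 3 tiles contain vessels")
  if (stats::sd(tiles$phi_um) == 0 || stats::sd(tiles$rho) == 0) {
    warning("diameter or density is constant across tiles; correlation undefined",
            call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, n_tiles = nrow(tiles), tiles = tiles))
  }
  ct <- stats::cor.test(tiles$phi_um, tiles$rho, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_tiles = nrow(tiles),
       tiles = tiles)
}

# Per-tile local diameter and density. Shared by the correlation statistic
# and the lesional-vs-control replicate comparison.
.vessel_tiles <- function(mask, tile_px = 32L, geometry = NULL) {
  m <- mask$mask
  empty <- data.frame(tile = integer(), phi_um = numeric(), rho = numeric())
  if (!any(m)) return(empty)
  if (is.null(geometry)) geometry <- .vessel_geometry(mask)
  skel <- geometry$skel; dist <- geometry$dist
  nr <- nrow(m); nc <- ncol(m)
  nti <- ceiling(nr / tile_px)
  tid <- matrix(ceiling(row(m) / tile_px) +
                  (ceiling(col(m) / tile_px) - 1L) * nti, nr, nc)
  n_tiles_all <- max(tid)
  npix <- tabulate(tid, n_tiles_all)
  nves <- tabulate(tid[m], n_tiles_all)
  # local diameter: mean over skeleton pixels; tiles with vessels but no
  # skeleton pixel fall back to their thickest point
  diam_sum <- rep(0, n_tiles_all); diam_n <- rep(0L, n_tiles_all)
  if (any(skel)) {
    diam_sum <- diam_sum + .tabulate_weighted(tid[skel], 2 * (dist[skel] - 0.5),
                                             n_tiles_all)
    diam_n <- diam_n + tabulate(tid[skel], n_tiles_all)
  }
  thick <- rep(-Inf, n_tiles_all)
  if (any(m)) {
    mx <- tapply(dist[m], tid[m], max)
    thick[as.integer(names(mx))] <- mx
  }
  q <- which(nves > 0L)
  if (length(q) == 0L) return(empty)
  phi <- ifelse(diam_n[q] > 0, diam_sum[q] / pmax(diam_n[q], 1L),
                2 * (thick[q] - 0.5)) * mask$d1
  data.frame(tile = q, phi_um = phi, rho = nves[q] / npix[q])
}

# sum of weights per integer bin
.tabulate_weighted <- function(bin, w, nbins) {
  out <- rep(0, nbins)
  s <- rowsum(w, bin)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}
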