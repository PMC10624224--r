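#' Extract the skin-surface profile from A-lines
#'
#' For every lateral position the surface depth is the depth of the first
#' local maximum along z whose amplitude exceeds the noise floor — the first
#' extreme point of the A-line. Plateau ties resolve to the shallowest
#' sample. A-lines with no qualifying sample are marked invalid; isolated
#' invalid pixels (at least 5 valid 8-neighbours) are filled with the median
#' of their valid neighbours.
#'
#' A noise floor set at a percentile of the background leaves, by
#' construction, a corresponding fraction of A-lines in which an isolated
#' noise extremum precedes the true surface. Because the skin surface is
#' laterally continuous, such depth outliers are isolated; with
#' `smooth_outliers = TRUE` (default) pixels deviating by more than
#' `outlier_tol` samples from their local (separable 3x3) median depth are
#' replaced by it.
#'
#' @param volume a [pa_volume()], raw or thresholded.
#' @param noise a [noise_model()].
#' @param smooth_outliers replace isolated depth outliers by the local
#'   median depth.
#' @param outlier_tol deviation (axial samples) beyond which a pixel counts
#'   as an outlier.
#' @return An object of class `surface_profile`: list with `z_um` (depth
#'   map, micrometres, `NA` where invalid), `index` (1-based axial sample of
#'   the surface), `valid` (logical matrix), `dz`, `filled` (count of
#'   neighbour-filled pixels) and `smoothed` (count of outlier-replaced
#'   pixels).
#' @export
extract_surface <- function(volume, noise, smooth_outliers = TRUE,
                            outlier_tol = 2L) {
  stopifnot(inherits(volume, "pa_volume"), inherits(noise, "noise_model"))
  a <- volume$amplitude
  d <- dim(a)
  nxy <- d[1L] * d[2L]; nz <- d[3L]
  m <- a; dim(m) <- c(nxy, nz)
  # first local maximum above the floor: strictly rising into the sample,
  # not rising out of it (plateau ties resolve shallow)
  idx <- first_local_max(m, noise$floor)
  valid <- idx > 0L
  idx[!valid] <- NA_integer_
  idx_m <- matrix(idx, d[1L], d[2L])
  valid_m <- matrix(valid, d[1L], d[2L])

  filled <- 0L
  if (any(!valid_m) && any(valid_m)) {
    nb <- .neighbour_stack(idx_m)
    n_valid_nb <- rowSums(!is.na(nb))
    fill_ok <- !valid & n_valid_nb >= 5L
    if (any(fill_ok)) {
      med <- apply(nb[fill_ok, , drop = FALSE], 1L,
                   function(r) stats::median(r, na.rm = TRUE))
      idx_m[fill_ok] <- as.integer(round(med))
      valid_m[fill_ok] <- TRUE
      filled <- sum(fill_ok)
    }
  }
  if (mean(valid_m) < 0.5)
    stop("surface extraction failed: more than 50% of A-lines have no ",
         "extremum above the noise floor (empty volume or floor too high)")
  smoothed <- 0L
  if (smooth_outliers && any(valid_m)) {
    tmp <- idx_m
    tmp[!valid_m] <- as.integer(stats::median(idx_m[valid_m]))
    ref <- t(.alines_runmed(t(.alines_runmed(tmp + 0, 3L)), 3L))
    out <- valid_m & abs(idx_m - ref) > outlier_tol
    if (any(out)) {
      idx_m[out] <- as.integer(round(ref[out]))
      smoothed <- sum(out)
    }
  }
  structure(list(z_um = (idx_m - 1L) * volume$dz, index = idx_m,
                 valid = valid_m, dz = volume$dz, filled = filled,
                 smoothed = smoothed),
            class = "surface_profile")
}

# 8-neighbour values of a matrix as an [n, 8] matrix (NA outside the image).
.neighbour_stack <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(di, dj) {
    out <- matrix(NA, nr, nc)
    ri <- seq_len(nr) + di; cj <- seq_len(nc) + dj
    ok_i <- ri >= 1L & ri <= nr; ok_j <- cj >= 1L & cj <= nc
    out[ok_i, ok_j] <- m[ri[ok_i], cj[ok_j]]
    out
  }
  offs <- expand.grid(di = -1:1, dj = -1:1)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  do.call(cbind, Map(function(di, dj) as.vector(shift(di, dj)),
                     offs$di, offs$dj))
}

#' @export
print.surface_profile <- function(x, ...) {
  cat(sprintf("<surface_profile> %d x %d, depth %g-%g um, %d invalid, %d filled\n",
              nrow(x$z_um), ncol(x$z_um),
              min(x$z_um, na.rm = TRUE), max(x$z_um, na.rm = TRUE),
              sum(!x$valid), x$filled))
  invisible(x)
}

#' Re-index a volume to surface-relative depth
#'
#' Shifts every valid A-line so that its surface sample lands at relative
#' depth 0; deeper samples follow at `dz` steps, zero-padded at the bottom.
#' Invalid columns are zero-filled.
#'
#' @param volume a [pa_volume()].
#' @param surface a [surface_profile][extract_surface()] from the same volume.
#' @return A list with `flat` (array `[x, y, depth]`, depth-relative), and
#'   `valid` (logical matrix of usable columns).
#' @export
flatten_to_surface <- function(volume, surface) {
  stopifnot(inherits(volume, "pa_volume"), inherits(surface, "surface_profile"))
  a <- volume$amplitude
  d <- dim(a)
  nxy <- d[1L] * d[2L]; nz <- d[3L]
  m <- a; dim(m) <- c(nxy, nz)
  idx <- as.vector(surface$index)
  valid <- as.vector(surface$valid)
  flat <- matrix(0, nxy, nz)
  # columns group into few distinct surface depths: shift block-wise
  for (s in unique(idx[valid])) {
    cols <- which(valid & idx == s)
    flat[cols, 1:(nz - s + 1L)] <- m[cols, s:nz]
  }
  dim(flat) <- d
  list(flat = flat, valid = matrix(valid, d[1L], d[2L]))
}

#' Determine the epidermis/dermis boundary depth Z
#'
#' Scans candidate boundary depths (ascending, surface-relative) and returns
#' the smallest candidate whose dermal maximum amplitude projection shows
#' tubular structure — the operational version of lowering the sampling
#' depth until vascular morphology appears on the MAP image. The tubularity
#' score of a MAP is the fraction of its strong pixels (above half the
#' robust maximum) whose local structure tensor is anisotropic (coherence
#' above `coherence_threshold`); a MAP whose strong pixels blanket most of
#' the image (superficial melanin) scores 0, since tubes are sparse. Before
#' the scan, candidates still inside the epidermal melanin layer are
#' discarded: the layer is located first as the depths where
#' above-half-height melanin coverage spans at least half the columns, and
#' the vessel search starts below it. If no candidate reaches
#' `tubularity_threshold`, the best-scoring candidate is returned with a
#' low-confidence flag.
#'
#' @param volume a [pa_volume()] (thresholded recommended).
#' @param surface a [surface_profile][extract_surface()].
#' @param candidates ascending candidate depths, micrometres, multiples of `dz`.
#' @param noise a [noise_model()].
#' @param tubularity_threshold minimum score to accept a candidate.
#' @param coherence_threshold structure-tensor coherence above which a pixel
#'   counts as anisotropic.
#' @param tensor_sigma_px Gaussian integration scale of the structure
#'   tensor, pixels.
#' @param flat optional precomputed [flatten_to_surface()] result for the
#'   same volume/surface, to avoid re-flattening in a pipeline.
#' @return An object of class `boundary_z`: list with `Z_um`, `low_confidence`,
#'   `score` (of the chosen candidate), and `profile` (data.frame of
#'   candidate depths and scores; scores after an accepted candidate are `NA`).
#' @export
determine_boundary_z <- function(volume, surface, candidates, noise,
                                 tubularity_threshold = 0.15,
                                 coherence_threshold = 0.5,
                                 tensor_sigma_px = 3,
                                 flat = NULL) {
  stopifnot(inherits(volume, "pa_volume"), inherits(surface, "surface_profile"))
  if (length(candidates) == 0L) stop("empty candidate list for boundary depth")
  if (is.unsorted(candidates)) stop("`candidates` must be sorted ascending")
  dz <- volume$dz
  if (any(abs(candidates / dz - round(candidates / dz)) > 1e-6))
    stop("candidates must be multiples of the axial spacing dz = ", dz)
  fv <- if (is.null(flat)) flatten_to_surface(volume, surface) else flat
  d <- dim(fv$flat)
  m <- fv$flat; dim(m) <- c(d[1L] * d[2L], d[3L])
  m[!as.vector(fv$valid), ] <- 0
  smax <- .suffix_max(m)
  ks <- as.integer(round(candidates / dz)) + 1L
  usable <- ks <= d[3L]
  # locate the epidermal melanin blanket first: candidates inside it would
  # project superficial melanin into the "dermal" MAP. The melanin plateau
  # is estimated from flattened depths 60-110 um: beyond the axial tail of
  # the bright surface peak, yet inside a typical epidermis
  depth <- (seq_len(d[3L]) - 1L) * dz
  win <- which(depth >= 60 & depth <= 110)
  vals <- if (length(win) > 0L) {
    sh <- m[, win, drop = FALSE]
    sh[sh > noise$floor]
  } else numeric(0)
  if (length(vals) == 0L) vals <- m[m > noise$floor]
  if (length(vals) > 0L) {
    mfl <- max(noise$floor, 0.5 * stats::median(vals))
    coverage <- colSums(m > mfl) / max(1L, sum(fv$valid))
    past_blanket <- which(coverage < 0.5)
    if (length(past_blanket) > 0L && past_blanket[1L] > 1L)
      usable <- usable & ks >= past_blanket[1L]
    if (!any(usable)) usable <- ks <= d[3L]  # degenerate: keep depth-valid set
  }
  if (!any(usable)) stop("all candidates exceed the available depth")
  scores <- rep(NA_real_, length(candidates))
  for (i in which(usable)) {
    map <- matrix(smax[, ks[i]], d[1L], d[2L])
    scores[i] <- .tubularity_score(map, noise$floor, coherence_threshold,
                                   tensor_sigma_px)
    if (scores[i] >= tubularity_threshold) {
      return(structure(list(Z_um = candidates[i], low_confidence = FALSE,
                            score = scores[i],
                            profile = data.frame(depth_um = candidates,
                                                 score = scores)),
                       class = "boundary_z"))
    }
  }
  best <- which.max(replace(scores, is.na(scores), -Inf))
  structure(list(Z_um = candidates[best], low_confidence = TRUE,
                 score = scores[best],
                 profile = data.frame(depth_um = candidates, score = scores)),
            class = "boundary_z")
}

#' @export
print.boundary_z <- function(x, ...) {
  cat(sprintf("<boundary_z> Z = %g um (tubularity %.3f%s)\n", x$Z_um, x$score,
              if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  invisible(x)
}

# Tubularity of a 2D MAP image: fraction of strong pixels with anisotropic
# local structure. Strong = above half the robust (99th percentile) maximum
# of above-floor pixels. A strong set covering most of the image is a
# melanin blanket, not vasculature, and scores 0.
.tubularity_score <- function(map, floor, coherence_threshold = 0.5,
                              sigma = 3) {
  above <- map > floor
  if (!any(above)) return(0)
  thr <- max(floor, 0.5 * .q(map[above], 0.99))
  strong <- map > thr
  nr <- nrow(map); nc <- ncol(map)
  interior <- matrix(FALSE, nr, nc)
  interior[3:(nr - 2L), 3:(nc - 2L)] <- TRUE
  sel <- strong & interior
  if (!any(sel)) return(0)
  # a strong set blanketing nearly the whole image is superficial melanin,
  # not vasculature; skip the tensor for these obvious cases
  if (mean(strong[interior]) > 0.85) return(0)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[2:(nr - 1L), ] <- (map[3:nr, ] - map[1:(nr - 2L), ]) / 2
  gy[, 2:(nc - 1L)] <- (map[, 3:nc] - map[, 1:(nc - 2L)]) / 2
  sm <- function(z) as.matrix(EBImage::gblur(z, sigma = sigma))
  jxx <- sm(gx * gx); jyy <- sm(gy * gy); jxy <- sm(gx * gy)
  tr <- jxx + jyy
  coh <- ((jxx - jyy)^2 + 4 * jxy^2) / (tr + 1e-12)^2
  mean(coh[sel] > coherence_threshold)
}

#' Split a volume into surface-flattened epidermis and dermis
#'
#' Samples are re-indexed to surface-relative depth; the epidermis holds
#' depths in `[0, Z)` and the dermis depths in `[Z, max]` (half-open, so no
#' sample belongs to both layers). Invalid surface columns are zero-filled
#' and flagged for exclusion from downstream statistics.
#'
#' @param volume a [pa_volume()].
#' @param surface a [surface_profile][extract_surface()].
#' @param Z boundary depth below the surface, micrometres, a positive
#'   multiple of `dz`.
#' @param flat optional precomputed [flatten_to_surface()] result.
#' @return An object of class `layer_stack`: list with `Z_um`, `epidermis`
#'   and `dermis` (class `pa_layer`: flattened sub-volume plus spacing and
#'   the depth of its first slice), `flat` (full flattened array), `valid`,
#'   `surface`, and spacing fields.
#' @export
split_layers <- function(volume, surface, Z, flat = NULL) {
  stopifnot(inherits(volume, "pa_volume"))
  dz <- volume$dz
  if (length(Z) != 1L || !is.finite(Z) || Z <= 0)
    stop("Z must be a single positive depth in um")
  if (abs(Z / dz - round(Z / dz)) > 1e-6)
    stop("Z must be a multiple of the axial spacing dz = ", dz)
  nz <- dim(volume$amplitude)[3L]
  deepest <- max(surface$index[surface$valid])
  if (round(Z / dz) >= nz - deepest + 1L)
    stop(sprintf("Z = %g um leaves no dermal samples below the deepest surface point", Z))
  fv <- if (is.null(flat)) flatten_to_surface(volume, surface) else flat
  kZ <- as.integer(round(Z / dz))  # slices 1..kZ have depth < Z
  layer <- function(slices, name, d0) {
    structure(list(amplitude = fv$flat[, , slices, drop = FALSE],
                   dx = volume$dx, dy = volume$dy, dz = dz,
                   layer = name, d0_um = d0, valid = fv$valid),
              class = "pa_layer")
  }
  structure(list(
    Z_um = Z,
    epidermis = layer(seq_len(kZ), "epidermis", 0),
    dermis = layer((kZ + 1L):nz, "dermis", Z),
    flat = fv$flat, valid = fv$valid, surface = surface,
    dx = volume$dx, dy = volume$dy, dz = dz, label = volume$label
  ), class = "layer_stack")
}

#' Maximum amplitude projection of a layer
#'
#' Collapses one axis of a flattened layer by taking the per-pixel maximum:
#' `"XY"` collapses depth (en-face image), `"XZ"` collapses the y axis
#' (cross-sectional image).
#'
#' @param layer a `pa_layer` from [split_layers()], or a plain 3D array
#'   `[x, y, depth]` (then spacing defaults to 1 um).
#' @param plane `"XY"` or `"XZ"`.
#' @return An object of class `map_image`: list with `pixels` (matrix),
#'   `plane`, `layer`, and the pixel spacings `d1`, `d2` (micrometres).
#' @export
max_amplitude_projection <- function(layer, plane = c("XY", "XZ")) {
  plane <- match.arg(plane)
  if (is.array(layer) && !inherits(layer, "pa_layer"))
    layer <- structure(list(amplitude = layer, dx = 1, dy = 1, dz = 1,
                            layer = "full", d0_um = 0, valid = NULL),
                       class = "pa_layer")
  a <- layer$amplitude
  d <- dim(a)
  if (any(d == 0L)) stop("empty layer")
  if (plane == "XY") {
    px <- a[, , 1L]
    if (d[3L] > 1L) for (k in 2:d[3L]) px <- pmax(px, a[, , k])
    sp <- c(layer$dx, layer$dy)
  } else {
    px <- a[, 1L, ]
    if (d[2L] > 1L) for (j in 2:d[2L]) px <- pmax(px, a[, j, ])
    if (is.null(dim(px))) px <- matrix(px, d[1L], d[3L])
    sp <- c(layer$dx, layer$dz)
  }
  structure(list(pixels = px, plane = plane, layer = layer$layer,
                 d1 = sp[1L], d2 = sp[2L]),
            class = "map_image")
}

#' @export
print.map_image <- function(x, ...) {
  cat(sprintf("<map_image> %s MAP of %s: %d x %d px, spacing (%g, %g) um\n",
              x$plane, x$layer, nrow(x$pixels), ncol(x$pixels), x$d1, x$d2))
  invisible(x)
}
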