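#' Melanin area as a function of surface-relative depth
#'
#' Counts, for every surface-relative depth slice, the pixels whose
#' amplitude exceeds the melanin floor — the area-versus-depth curve whose
#' zero crossing defines the maximum pigmentation depth. Invalid surface
#' columns are excluded; an optional lateral vessel mask excludes vessel
#' columns so dermal vascular signal is not counted as melanin (geometric
#' disambiguation: single-wavelength amplitudes cannot separate the two
#' absorbers spectrally).
#'
#' @param stack a [layer_stack][split_layers()] (its full flattened volume
#'   is analysed).
#' @param noise a [noise_model()] giving the melanin floor.
#' @param vessel_mask optional [vessel_mask][segment_vessels()] or logical
#'   matrix of lateral positions to exclude.
#' @param min_neighbors count a pixel only if at least this many of its
#'   in-slice 8-neighbours are also above the floor (default 0: plain
#'   count). Genuine pigment is spatially clustered and keeps its area;
#'   scattered noise pixels are isolated and drop out.
#' @return A data.frame with `depth_um` and `area_px`.
#' @export
melanin_area_profile <- function(stack, noise, vessel_mask = NULL,
                                 min_neighbors = 0L) {
  stopifnot(inherits(stack, "layer_stack"), inherits(noise, "noise_model"))
  d <- dim(stack$flat)
  keep <- as.vector(stack$valid)
  if (!is.null(vessel_mask)) {
    vm <- if (inherits(vessel_mask, "vessel_mask")) vessel_mask$mask else vessel_mask
    stopifnot(identical(dim(vm), d[1:2]))
    keep <- keep & !as.vector(vm)
  }
  above <- stack$flat > noise$floor
  if (min_neighbors > 0L) {
    nb <- array(0L, d)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      src_i <- max(1L, 1L + di):min(d[1L], d[1L] + di)
      src_j <- max(1L, 1L + dj):min(d[2L], d[2L] + dj)
      dst_i <- src_i - di; dst_j <- src_j - dj
      nb[dst_i, dst_j, ] <- nb[dst_i, dst_j, , drop = FALSE] +
        above[src_i, src_j, , drop = FALSE]
    }
    above <- above & nb >= min_neighbors
  }
  dim(above) <- c(d[1L] * d[2L], d[3L])
  area <- as.integer(colSums(above[keep, , drop = FALSE]))
  data.frame(depth_um = (seq_len(d[3L]) - 1L) * stack$dz, area_px = area)
}

#' Maximum pigmentation depth D
#'
#' The largest surface-relative depth whose melanin area exceeds `min_area`
#' pixels — the depth at which the area of melanin reaches zero. Gaps in
#' the profile are allowed: only the deepest qualifying slice counts. With
#' no qualifying slice, `D = 0`.
#'
#' @param profile area profile from [melanin_area_profile()].
#' @param min_area pixel count a slice must exceed to qualify (default 0,
#'   i.e. any strictly positive area; raise to suppress speckle).
#' @return D in micrometres.
#' @export
pigmentation_depth <- function(profile, min_area = 0) {
  stopifnot(is.data.frame(profile), all(c("depth_um", "area_px") %in% names(profile)))
  q <- which(profile$area_px > min_area)
  if (length(q) == 0L) return(0)
  profile$depth_um[max(q)]
}

#' Amplitude statistics of a melanin MAP
#'
#' Mean amplitude over above-floor pixels of a (grayscale) melanin MAP and
#' the above-floor pixel fraction; both 0 when nothing exceeds the floor.
#'
#' @param map a [map_image][max_amplitude_projection()], typically the
#'   epidermal XY MAP.
#' @param noise a [noise_model()].
#' @return A list with `mean_amplitude` and `fraction`.
#' @export
amplitude_stats <- function(map, noise) {
  stopifnot(inherits(map, "map_image"), inherits(noise, "noise_model"))
  px <- map$pixels
  above <- px > noise$floor
  if (!any(above)) return(list(mean_amplitude = 0, fraction = 0))
  list(mean_amplitude = mean(px[above]), fraction = mean(above))
}
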