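#' Define a dermal vessel tube for a phantom
#'
#' Vessels are cylinders of constant radius around a centerline polyline
#' given in micrometres. Coordinates are `(x, y, depth)` where `depth` is
#' measured below the local skin surface, so tubes follow the curved
#' surface. The default is a straight tube running the full x extent at
#' constant `y` and depth.
#'
#' @param y_um,depth_um centerline position for a straight x-parallel tube:
#'   lateral y and depth below the surface (to the tube axis), micrometres.
#' @param radius_um tube radius, micrometres (> 0).
#' @param amplitude absorption amplitude of blood inside the tube.
#' @param centerline optional explicit polyline, an `n x 3` matrix of
#'   `(x_um, y_um, depth_um)` rows overriding `y_um`/`depth_um`; `NA` x
#'   values are stretched to the full lateral extent at generation time.
#' @return A list describing one tube.
#' @export
vessel_tube <- function(y_um, depth_um, radius_um, amplitude = 1, centerline = NULL) {
  if (radius_um <= 0) stop("vessel radius must be > 0")
  if (is.null(centerline))
    centerline <- matrix(c(NA, y_um, depth_um, NA, y_um, depth_um),
                         nrow = 2L, byrow = TRUE)
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 3L || nrow(centerline) < 2L)
    stop("`centerline` must be an n x 3 matrix (x, y, depth in um), n >= 2")
  list(centerline = centerline, radius_um = as.numeric(radius_um),
       amplitude = as.numeric(amplitude))
}

#' Specify a synthetic layered-skin phantom
#'
#' The phantom emulates the structures the analysis pipeline quantifies: a
#' gently curved skin surface, an epidermal melanin layer of known thickness
#' with a bright superficial peak (the strong entrance signal of the
#' melanin-rich superficial epidermis), optional punctate dermal melanin
#' deposits reaching a known maximum depth, and dermal vessel tubes of known
#' radius and lateral coverage. The absorption map is blurred by a separable
#' Gaussian point spread (about 7 um lateral and 50 um axial FWHM by
#' default, the system resolution regime this pipeline targets) and
#' perturbed by additive half-normal noise, so the volume is a non-negative
#' envelope-amplitude volume throughout.
#'
#' `melanin_max_depth_um` at or below `epidermal_thickness_um` yields a
#' purely epidermal pigment distribution; a larger value adds
#' `dermal_dot_count` punctate deposits spanning the epidermis/dermis
#' boundary down to exactly `melanin_max_depth_um`, placed away from vessels
#' (interstitially) using `geometry_seed`.
#'
#' @param nx,ny,nz grid size (x, y, z).
#' @param dx,dy,dz voxel spacing, micrometres.
#' @param surface_depth_um mean depth of the skin surface below z = 0.
#' @param bump_amplitude_um,bump_period_um low-frequency surface curvature:
#'   sinusoidal bumps of this amplitude and lateral period.
#' @param epidermal_thickness_um true epidermis/dermis boundary depth below
#'   the surface (ground-truth Z).
#' @param melanin_max_depth_um true maximum pigmentation depth below the
#'   surface (ground-truth D).
#' @param melanin_amplitude absorption amplitude of the epidermal melanin
#'   layer (arbitrary units).
#' @param melanin_surface_boost,melanin_surface_decay_um superficial
#'   enhancement: the melanin profile is
#'   `amplitude * (1 + boost * exp(-depth/decay))`, giving every A-line its
#'   first and strongest peak at the surface.
#' @param dermal_dot_count,dermal_dot_radius_um,dermal_dot_amplitude_factor
#'   punctate dermal melanin deposits (only used when D > Z).
#' @param vessels list of [vessel_tube()]s.
#' @param noise_sigma scale of the additive half-normal noise.
#' @param lateral_psf_fwhm_um,axial_psf_fwhm_um point-spread FWHM.
#' @param seed integer seed for the noise realisation.
#' @param geometry_seed integer seed for randomised geometry (dot
#'   placement); kept separate from `seed` so noise replicates share
#'   identical anatomy.
#' @param label volume label, e.g. `"lesional"`.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [phantom_preset()]
#' @export
phantom_spec <- function(nx = 128L, ny = 128L, nz = 96L,
                         dx = 5, dy = 5, dz = 7.5,
                         surface_depth_um = 90,
                         bump_amplitude_um = 7.5,
                         bump_period_um = 320,
                         epidermal_thickness_um = 112.5,
                         melanin_max_depth_um = 112.5,
                         melanin_amplitude = 1,
                         melanin_surface_boost = 100,
                         melanin_surface_decay_um = 3,
                         dermal_dot_count = 6L,
                         dermal_dot_radius_um = 15,
                         dermal_dot_amplitude_factor = 1.75,
                         vessels = list(),
                         noise_sigma = 0.05,
                         lateral_psf_fwhm_um = 7,
                         axial_psf_fwhm_um = 50,
                         seed = 1L,
                         geometry_seed = 1L,
                         label = "lesional") {
  spec <- list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
               dx = dx, dy = dy, dz = dz,
               surface_depth_um = surface_depth_um,
               bump_amplitude_um = bump_amplitude_um,
               bump_period_um = bump_period_um,
               epidermal_thickness_um = epidermal_thickness_um,
               melanin_max_depth_um = melanin_max_depth_um,
               melanin_amplitude = melanin_amplitude,
               melanin_surface_boost = melanin_surface_boost,
               melanin_surface_decay_um = melanin_surface_decay_um,
               dermal_dot_count = as.integer(dermal_dot_count),
               dermal_dot_radius_um = dermal_dot_radius_um,
               dermal_dot_amplitude_factor = dermal_dot_amplitude_factor,
               vessels = vessels,
               noise_sigma = noise_sigma,
               lateral_psf_fwhm_um = lateral_psf_fwhm_um,
               axial_psf_fwhm_um = axial_psf_fwhm_um,
               seed = as.integer(seed),
               geometry_seed = as.integer(geometry_seed),
               label = label)
  class(spec) <- "phantom_spec"
  .validate_phantom_spec(spec)
  spec
}

.validate_phantom_spec <- function(spec) {
  with(spec, {
    if (any(c(dx, dy, dz) <= 0)) stop("voxel spacings must be positive")
    if (melanin_max_depth_um < 0) stop("melanin_max_depth_um must be >= 0")
    if (epidermal_thickness_um <= 0) stop("epidermal_thickness_um must be > 0")
    if (noise_sigma < 0) stop("noise_sigma must be >= 0")
    depth_extent <- (nz - 1L) * dz
    max_surface <- surface_depth_um + bump_amplitude_um
    if (max_surface + melanin_max_depth_um > depth_extent)
      stop(sprintf(
        "melanin depth %g um below a surface reaching %g um exceeds the grid depth %g um",
        melanin_max_depth_um, max_surface, depth_extent))
    for (i in seq_along(vessels)) {
      v <- vessels[[i]]
      if (min(v$centerline[, 3L]) - v$radius_um < epidermal_thickness_um)
        stop(sprintf(
          "vessel %d (top at %g um) reaches above the epidermal boundary %g um: vessels must be dermal",
          i, min(v$centerline[, 3L]) - v$radius_um, epidermal_thickness_um))
      if (max_surface + max(v$centerline[, 3L]) + v$radius_um > depth_extent)
        stop(sprintf("vessel %d (bottom at %g um below surface) exceeds the grid depth %g um",
                     i, max(v$centerline[, 3L]) + v$radius_um, depth_extent))
    }
  })
  invisible(spec)
}

# Surface depth map in um, [nx, ny].
.phantom_surface <- function(spec) {
  x <- (seq_len(spec$nx) - 1L) * spec$dx
  y <- (seq_len(spec$ny) - 1L) * spec$dy
  spec$surface_depth_um + spec$bump_amplitude_um *
    outer(sin(2 * pi * x / spec$bump_period_um),
          cos(2 * pi * y / spec$bump_period_um))
}

# Rasterise one tube into a logical [nx, ny, nz] mask. Coordinates are
# surface-relative in depth so tubes follow the surface curvature.
.rasterize_tube <- function(tube, surf, spec) {
  nx <- spec$nx; ny <- spec$ny; nz <- spec$nz
  cl <- tube$centerline
  cl[is.na(cl[, 1L]), 1L] <- c(0, (nx - 1L) * spec$dx)[seq_len(sum(is.na(cl[, 1L])))]
  r <- tube$radius_um
  xs <- (seq_len(nx) - 1L) * spec$dx
  ys <- (seq_len(ny) - 1L) * spec$dy
  # bounding box (lateral; depth handled per-column because of the surface)
  xi <- which(xs >= min(cl[, 1L]) - r & xs <= max(cl[, 1L]) + r)
  yi <- which(ys >= min(cl[, 2L]) - r & ys <= max(cl[, 2L]) + r)
  mask <- array(FALSE, c(nx, ny, nz))
  if (length(xi) == 0L || length(yi) == 0L) return(mask)
  # voxel coordinates inside the box
  nb <- length(xi) * length(yi) * nz
  px <- rep(xs[xi], times = length(yi) * nz)
  py <- rep(rep(ys[yi], each = length(xi)), times = nz)
  sb <- surf[xi, yi, drop = FALSE]
  pz <- rep((seq_len(nz) - 1L) * spec$dz, each = length(xi) * length(yi)) -
    rep(as.vector(sb), times = nz)
  d2 <- rep(Inf, nb)
  for (s in seq_len(nrow(cl) - 1L)) {
    a <- cl[s, ]; b <- cl[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2s <- (px - a[1L])^2 + (py - a[2L])^2 + (pz - a[3L])^2
    } else {
      t <- ((px - a[1L]) * ab[1L] + (py - a[2L]) * ab[2L] + (pz - a[3L]) * ab[3L]) / len2
      t <- pmin(pmax(t, 0), 1)
      d2s <- (px - (a[1L] + t * ab[1L]))^2 + (py - (a[2L] + t * ab[2L]))^2 +
        (pz - (a[3L] + t * ab[3L]))^2
    }
    d2 <- pmin(d2, d2s)
  }
  inside <- array(d2 <= r^2, c(length(xi), length(yi), nz))
  mask[xi, yi, ] <- inside
  mask
}

# Deterministically place punctate dermal melanin deposits away from vessels.
.place_dots <- function(spec, vessel_proj) {
  n <- spec$dermal_dot_count
  if (n <= 0L) return(NULL)
  margin_um <- spec$dermal_dot_radius_um + 10
  lim_x <- c(margin_um, (spec$nx - 1L) * spec$dx - margin_um)
  lim_y <- c(margin_um, (spec$ny - 1L) * spec$dy - margin_um)
  clear_px <- margin_um / spec$dx
  dist_to_vessel <- NULL
  if (any(vessel_proj)) {
    dist_to_vessel <- as.matrix(EBImage::distmap(1 - (vessel_proj > 0)))
  }
  .with_seed(spec$geometry_seed, {
    centers <- matrix(NA_real_, n, 2L)
    placed <- 0L
    for (try in seq_len(1000L)) {
      if (placed == n) break
      cx <- stats::runif(1, lim_x[1L], lim_x[2L])
      cy <- stats::runif(1, lim_y[1L], lim_y[2L])
      if (!is.null(dist_to_vessel)) {
        i <- pmin(pmax(round(cx / spec$dx) + 1L, 1L), spec$nx)
        j <- pmin(pmax(round(cy / spec$dy) + 1L, 1L), spec$ny)
        if (dist_to_vessel[i, j] < clear_px) next
      }
      if (placed > 0L &&
          any((centers[seq_len(placed), 1L] - cx)^2 +
              (centers[seq_len(placed), 2L] - cy)^2 < (3 * spec$dermal_dot_radius_um)^2))
        next
      placed <- placed + 1L
      centers[placed, ] <- c(cx, cy)
    }
    if (placed < n)
      stop("could not place ", n, " dermal melanin deposits clear of vessels; ",
           "reduce dermal_dot_count or vessel coverage")
    centers
  })
}

#' Generate the noise-free phantom volume and its ground truth
#'
#' The deterministic part of [generate_phantom()]: absorption map times
#' Gaussian point spread, no noise. Exposed so that replicate studies can
#' reuse one anatomy across many noise realisations via
#' [add_phantom_noise()].
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` (a [pa_volume()]) and `truth` (see
#'   [generate_phantom()]).
#' @export
phantom_base <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .validate_phantom_spec(spec)
  nx <- spec$nx; ny <- spec$ny; nz <- spec$nz
  surf <- .phantom_surface(spec)
  # depth below surface of every voxel
  drel <- rep((seq_len(nz) - 1L) * spec$dz, each = nx * ny) - rep(as.vector(surf), nz)
  dim(drel) <- c(nx, ny, nz)

  absorb <- array(0, c(nx, ny, nz))
  melanin_mask <- array(FALSE, c(nx, ny, nz))
  slab_bottom <- min(spec$melanin_max_depth_um, spec$epidermal_thickness_um)
  if (spec$melanin_amplitude > 0 && spec$melanin_max_depth_um > 0) {
    in_slab <- drel >= 0 & drel <= slab_bottom
    # superficial boost integrated over each voxel's depth extent, so its
    # total mass (hence the post-blur surface peak) is independent of the
    # sub-voxel phase of the surface
    dd <- drel[in_slab]
    lo <- pmax(dd - spec$dz / 2, 0)
    hi <- dd + spec$dz / 2
    boost <- spec$melanin_surface_boost *
      (spec$melanin_surface_decay_um / spec$dz) *
      (exp(-lo / spec$melanin_surface_decay_um) -
         exp(-hi / spec$melanin_surface_decay_um))
    absorb[in_slab] <- spec$melanin_amplitude * (1 + boost)
    melanin_mask <- melanin_mask | in_slab
  }

  vessel_mask <- array(FALSE, c(nx, ny, nz))
  for (tube in spec$vessels) {
    m <- .rasterize_tube(tube, surf, spec)
    absorb[m] <- pmax(absorb[m], tube$amplitude)
    vessel_mask <- vessel_mask | m
  }

  if (spec$melanin_max_depth_um > spec$epidermal_thickness_um &&
      spec$melanin_amplitude > 0) {
    vm <- vessel_mask; dim(vm) <- c(nx * ny, nz)
    proj <- matrix(rowSums(vm) > 0, nx, ny)
    centers <- .place_dots(spec, proj)
    xs <- (seq_len(nx) - 1L) * spec$dx
    ys <- (seq_len(ny) - 1L) * spec$dy
    dot_amp <- spec$melanin_amplitude * spec$dermal_dot_amplitude_factor
    in_band <- drel >= spec$epidermal_thickness_um & drel <= spec$melanin_max_depth_um
    for (q in seq_len(nrow(centers))) {
      disc <- outer((xs - centers[q, 1L])^2, (ys - centers[q, 2L])^2, `+`) <=
        spec$dermal_dot_radius_um^2
      dot <- array(disc, c(nx, ny, nz)) & in_band
      absorb[dot] <- pmax(absorb[dot], dot_amp)
      melanin_mask <- melanin_mask | dot
    }
  }

  blurred <- .blur_volume(absorb, c(spec$dx, spec$dy, spec$dz),
                          spec$lateral_psf_fwhm_um, spec$axial_psf_fwhm_um)
  blurred[blurred < 0] <- 0

  vm2 <- vessel_mask; dim(vm2) <- c(nx * ny, nz)
  proj_mask <- matrix(rowSums(vm2) > 0, nx, ny)
  amps <- vapply(spec$vessels, `[[`, numeric(1L), "amplitude")
  radii <- vapply(spec$vessels, `[[`, numeric(1L), "radius_um")
  truth <- list(
    # recoverable surface: depth of the first absorber voxel per column
    # (the analytic surface rasterised onto the axial grid)
    surface_um = ceiling(surf / spec$dz - 1e-9) * spec$dz,
    surface_analytic_um = surf,
    Z_true = spec$epidermal_thickness_um,
    D_true = if (spec$melanin_amplitude > 0) spec$melanin_max_depth_um else 0,
    vessel_mask = vessel_mask,
    melanin_mask = melanin_mask,
    mean_diameter_true = if (length(amps)) sum(amps * 2 * radii) / sum(amps) else 0,
    density_true = mean(proj_mask)
  )
  list(volume = pa_volume(blurred, spec$dx, spec$dy, spec$dz, spec$label),
       truth = truth)
}

#' Add half-normal background noise to a volume
#'
#' Noise is additive `|N(0, sigma)|`, keeping the volume non-negative
#' without clipping bias at the floor.
#'
#' @param volume a [pa_volume()].
#' @param sigma noise scale (same units as the amplitudes).
#' @param seed integer seed; the same seed reproduces the realisation.
#' @return The noisy [pa_volume()].
#' @export
add_phantom_noise <- function(volume, sigma, seed) {
  stopifnot(inherits(volume, "pa_volume"))
  if (sigma <= 0) return(volume)
  a <- volume$amplitude
  a <- a + .with_seed(as.integer(seed),
                      abs(stats::rnorm(length(a), 0, sigma)))
  volume$amplitude <- a
  volume
}

#' Generate a synthetic PAM skin volume with known ground truth
#'
#' Builds the absorption map described by `spec` (melanin layer, punctate
#' dermal deposits, vessel tubes), blurs it with the separable Gaussian
#' point spread, and adds seeded half-normal noise. Generation is a pure
#' function of the spec: the same spec yields a bit-identical volume.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements:
#' \describe{
#'   \item{volume}{a [pa_volume()].}
#'   \item{truth}{a list with `surface_um` (recoverable depth map: the
#'     first absorber voxel per column, um), `surface_analytic_um` (the
#'     continuous surface before rasterisation), `Z_true` and
#'     `D_true` (um below the surface), `vessel_mask` and `melanin_mask`
#'     (3D logical, pre-blur rasterisation), `mean_diameter_true`
#'     (amplitude-weighted mean of tube diameters, um) and `density_true`
#'     (lateral projected vessel-pixel fraction).}
#' }
#' @export
generate_phantom <- function(spec) {
  base <- phantom_base(spec)
  base$volume <- add_phantom_noise(base$volume, spec$noise_sigma, spec$seed)
  base
}

# Preset geometry shared by all four classes.
.preset_table <- function() {
  tube <- function(y, r, amp = 1) vessel_tube(y_um = y, depth_um = 240,
                                              radius_um = r, amplitude = amp)
  list(
    epidermal_m = list(
      Z = 112.5, D = 112.5,
      les = list(amp = 1.0, vessels = list(tube(120, 30), tube(320, 30), tube(520, 30))),
      ctl = list(amp = 0.5, vessels = list(tube(200, 40), tube(440, 40)))),
    mixed_m = list(
      Z = 135, D = 165,
      les = list(amp = 1.0, vessels = list(tube(180, 35), tube(460, 35))),
      ctl = list(amp = 0.5, vessels = list(tube(200, 40), tube(440, 40)))),
    epidermal_mv = list(
      Z = 165, D = 165,
      les = list(amp = 1.0, vessels = list(tube(200, 50), tube(440, 50))),
      ctl = list(amp = 0.5, vessels = list(tube(320, 25)))),
    mixed_mv = list(
      Z = 135, D = 165,
      les = list(amp = 1.0, vessels = list(tube(200, 50), tube(440, 50))),
      ctl = list(amp = 0.5, vessels = list(tube(320, 25))))
  )
}

#' Phantom presets mimicking the four melasma classes
#'
#' Each preset encodes one of the four target classes by construction:
#' `epidermal_m` (pigment confined to the epidermis, lesional vessels not
#' enlarged), `mixed_m` (pigment reaching the dermis, vessels not enlarged),
#' `epidermal_mv` (epidermal pigment with lesional vessels about twice the
#' control diameter and about four times the control density) and
#' `mixed_mv` (dermal pigment plus the enlarged-vessel pattern). The
#' lesional site carries twice the control melanin amplitude. Grid, spacing
#' and noise defaults are those of [phantom_spec()].
#'
#' @param name one of `"epidermal_m"`, `"mixed_m"`, `"epidermal_mv"`,
#'   `"mixed_mv"`.
#' @param seed integer seed for the noise realisation.
#' @param site `"lesional"` or `"control"`.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name, seed = 1L, site = c("lesional", "control")) {
  site <- match.arg(site)
  tab <- .preset_table()
  if (!name %in% names(tab))
    stop("unknown preset `", name, "`; available: ",
         paste(names(tab), collapse = ", "))
  p <- tab[[name]]
  s <- if (site == "lesional") p$les else p$ctl
  phantom_spec(
    epidermal_thickness_um = p$Z,
    melanin_max_depth_um = if (site == "lesional") p$D else p$Z,
    melanin_amplitude = s$amp,
    vessels = s$vessels,
    seed = if (site == "lesional") seed else seed + 1L,
    geometry_seed = 1L,
    label = if (site == "lesional") "lesional" else "non_lesional")
}

#' Generate a lesional/control phantom pair for a preset
#'
#' @inheritParams phantom_preset
#' @return A list with `lesional` and `control`, each as returned by
#'   [generate_phantom()], plus `name`.
#' @export
phantom_case_preset <- function(name, seed = 1L) {
  list(name = name,
       lesional = generate_phantom(phantom_preset(name, seed, "lesional")),
       control = generate_phantom(phantom_preset(name, seed, "control")))
}
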