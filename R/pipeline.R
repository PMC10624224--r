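#' Analysis configuration
#'
#' Bundles every tunable of the volume-to-classification pipeline with its
#' default. Values of note: the background floor is the 99th percentile of
#' the pre-surface region unless fixed; the melanin floor for the
#' area-depth curve sits at half the typical epidermal melanin amplitude
#' (half-height edge criterion, which locates the blurred boundary of a
#' uniform layer at its true position); boundary candidates default to
#' every axial sample between `z_min_um` and `z_max_um`.
#'
#' @param median_window A-line median filter width (odd), samples.
#' @param noise_percentile percentile for [estimate_noise_floor()].
#' @param noise_floor_fixed fixed floor overriding the percentile estimate.
#' @param boundary_z manual epidermis/dermis boundary override, micrometres
#'   (skips the tubularity search; logged in the result).
#' @param z_min_um,z_max_um candidate boundary depth range, micrometres.
#' @param tubularity_threshold,coherence_threshold,tensor_sigma_px see
#'   [determine_boundary_z()].
#' @param melanin_rel_floor melanin floor as a fraction of the median
#'   above-floor epidermal amplitude.
#' @param min_area_frac slice area (as a fraction of valid columns) that
#'   must be exceeded to extend the pigmentation depth; suppresses speckle.
#' @param melanin_min_neighbors in-slice 8-neighbour support required for a
#'   pixel to count as melanin area (see [melanin_area_profile()]).
#' @param vessel_smooth_sigma,min_component_px,min_shape_ratio,vessel_peak_frac
#'   see [segment_vessels()].
#' @param vessel_offset_um extra depth below Z at which the vessel-analysis
#'   MAP starts; keeps the blurred epidermal boundary out of the vessel
#'   image (a maximum projection over the remaining depth still sees every
#'   deeper vessel at full amplitude).
#' @param tile_px tile size for [diameter_density_correlation()].
#' @param exclude_vessel_columns exclude the segmented vessel footprint from
#'   the melanin area-depth curve.
#' @param melanin_exclude_dilate_px dilation radius (pixels) applied to the
#'   vessel footprint before exclusion, covering the point-spread tails
#'   around vessels.
#' @param require_significance,alpha,group_test see [classify_case()] and
#'   [compare_groups()].
#' @return A list of class `pam_config`.
#' @export
pam_config <- function(median_window = 3L,
                       noise_percentile = 99,
                       noise_floor_fixed = NULL,
                       boundary_z = NULL,
                       z_min_um = 30,
                       z_max_um = 330,
                       tubularity_threshold = 0.15,
                       coherence_threshold = 0.5,
                       tensor_sigma_px = 3,
                       melanin_rel_floor = 0.5,
                       min_area_frac = 0.005,
                       melanin_min_neighbors = 2L,
                       vessel_smooth_sigma = 1,
                       min_component_px = 10L,
                       min_shape_ratio = 5,
                       vessel_peak_frac = 0.4,
                       vessel_offset_um = 22.5,
                       tile_px = 32L,
                       exclude_vessel_columns = TRUE,
                       melanin_exclude_dilate_px = 4L,
                       require_significance = FALSE,
                       alpha = 0.05,
                       group_test = "welch") {
  structure(as.list(environment()), class = "pam_config")
}

#' Quantify one PAM skin volume
#'
#' Runs the single-volume pipeline: A-line median filtering, noise-floor
#' estimation, thresholding, surface extraction, boundary-depth
#' determination (or manual override), layer splitting, dermal vessel
#' quantification on the XY MAP, and melanin quantification (epidermal MAP
#' amplitude statistics and the area-depth curve with its maximum
#' pigmentation depth).
#'
#' @param volume a [pa_volume()].
#' @param config a [pam_config()].
#' @return A list of class `volume_analysis` with elements `noise`,
#'   `surface`, `boundary` (a `boundary_z`), `Z_um`, `layers`, `melanin`
#'   (list: `mean_amplitude`, `fraction`, `area_profile`, `D_um`,
#'   `floor`), `vessels` (list: `mask`, `Phi_um`, `rho`, `r`, `p_corr`,
#'   `n_tiles`, `tiles`) and `flags`.
#' @export
analyze_volume <- function(volume, config = pam_config()) {
  stopifnot(inherits(volume, "pa_volume"))
  flags <- character()
  dz <- volume$dz
  filtered <- median_filter_alines(volume, config$median_window)
  noise <- if (!is.null(config$noise_floor_fixed))
    noise_model(config$noise_floor_fixed, "fixed")
  else estimate_noise_floor(filtered, config$noise_percentile)
  thr <- apply_threshold(filtered, noise)
  surface <- extract_surface(thr, noise)
  flat <- flatten_to_surface(thr, surface)

  nz <- dim(volume$amplitude)[3L]
  avail <- (nz - max(surface$index[surface$valid]) - 2L) * dz
  if (!is.null(config$boundary_z)) {
    Z <- config$boundary_z
    boundary <- structure(list(Z_um = Z, low_confidence = FALSE, score = NA_real_,
                               profile = NULL, manual = TRUE),
                          class = "boundary_z")
    flags <- c(flags, sprintf("boundary Z = %g um set manually", Z))
  } else {
    cand <- seq(max(dz, ceiling(config$z_min_um / dz) * dz),
                min(config$z_max_um, avail), by = dz)
    boundary <- determine_boundary_z(
      thr, surface, cand, noise,
      tubularity_threshold = config$tubularity_threshold,
      coherence_threshold = config$coherence_threshold,
      tensor_sigma_px = config$tensor_sigma_px,
      flat = flat)
    Z <- boundary$Z_um
    if (boundary$low_confidence)
      flags <- c(flags, "no depth showed clear vascular morphology (low-confidence Z)")
  }

  layers <- split_layers(thr, surface, Z, flat = flat)
  # vessel-analysis MAP starts vessel_offset_um below the boundary
  off <- min(as.integer(round(config$vessel_offset_um / dz)),
             dim(layers$dermis$amplitude)[3L] - 1L)
  kv <- as.integer(round(Z / dz)) + 1L + max(off, 0L)
  dermal_map <- max_amplitude_projection(
    layers$flat[, , kv:nz, drop = FALSE], "XY")
  dermal_map$d1 <- volume$dx; dermal_map$d2 <- volume$dy
  dermal_map$layer <- "dermis"
  dermal_map$pixels[!layers$valid] <- 0
  vmask <- segment_vessels(dermal_map, noise,
                           smooth_sigma = config$vessel_smooth_sigma,
                           min_component_px = config$min_component_px,
                           min_shape_ratio = config$min_shape_ratio,
                           peak_frac = config$vessel_peak_frac)
  rho <- vessel_density(vmask, roi = layers$valid)
  phi <- 0
  corr <- list(r = NA_real_, p = NA_real_, n_tiles = 0L,
               tiles = data.frame(phi_um = numeric(), rho = numeric()))
  if (any(vmask$mask)) {
    geom <- .vessel_geometry(vmask)
    phi <- mean(2 * (geom$dist[geom$skel] - 0.5)) * vmask$d1
    corr <- withCallingHandlers(
      tryCatch(
        diameter_density_correlation(vmask, config$tile_px, geometry = geom),
        error = function(e) {
          flags <<- c(flags, conditionMessage(e))
          list(r = NA_real_, p = NA_real_, n_tiles = 0L,
               tiles = .vessel_tiles(vmask, config$tile_px, geom))
        }),
      warning = function(w) {
        flags <<- c(flags, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  epi_map <- max_amplitude_projection(layers$epidermis, "XY")
  epi_map$pixels[!layers$valid] <- 0
  mel_stats <- amplitude_stats(epi_map, noise)
  # half-height melanin floor, estimated from the deeper half of the
  # epidermis so the bright superficial peak does not inflate it
  epi <- layers$epidermis$amplitude
  kZe <- dim(epi)[3L]
  deep <- epi[, , max(1L, ceiling(kZe / 2)):kZe, drop = FALSE]
  vals <- deep[deep > noise$floor]
  if (length(vals) == 0L) vals <- epi[epi > noise$floor]
  mel_floor <- if (length(vals) == 0L) noise$floor else
    max(noise$floor, config$melanin_rel_floor * stats::median(vals))
  mel_noise <- noise_model(mel_floor, "fixed")
  excl <- NULL
  if (config$exclude_vessel_columns && any(vmask$mask)) {
    excl <- vmask$mask
    if (config$melanin_exclude_dilate_px > 0) {
      brush <- EBImage::makeBrush(2L * config$melanin_exclude_dilate_px + 1L,
                                  shape = "disc")
      excl <- as.matrix(EBImage::dilate(excl * 1, brush)) > 0
    }
  }
  profile <- melanin_area_profile(layers, mel_noise, vessel_mask = excl,
                                  min_neighbors = config$melanin_min_neighbors)
  min_area <- config$min_area_frac * sum(layers$valid)
  D <- pigmentation_depth(profile, min_area = min_area)

  structure(list(
    label = volume$label, noise = noise, surface = surface,
    boundary = boundary, Z_um = Z, layers = layers,
    melanin = list(mean_amplitude = mel_stats$mean_amplitude,
                   fraction = mel_stats$fraction,
                   area_profile = profile, D_um = D, floor = mel_floor),
    vessels = list(mask = vmask, Phi_um = phi, rho = rho,
                   r = corr$r, p_corr = corr$p, n_tiles = corr$n_tiles,
                   tiles = corr$tiles),
    flags = flags
  ), class = "volume_analysis")
}

#' Analyse and classify a lesional/control case
#'
#' Quantifies both volumes with [analyze_volume()], assembles the
#' [case_metrics()] (boundary depth and pigmentation depth from the
#' lesional volume; vessel metrics from both) and applies
#' [classify_case()].
#'
#' @param lesional,control [pa_volume()]s of the lesional and matched
#'   non-lesional site, or a `pa_case` from [read_case()] as the first
#'   argument.
#' @param config a [pam_config()].
#' @param case_id identifier used in reports.
#' @return A list of class `case_analysis` with `metrics`,
#'   `classification`, `lesional` and `control` (the two
#'   `volume_analysis` objects) and `config`.
#' @export
analyze_case <- function(lesional, control = NULL, config = pam_config(),
                         case_id = "case") {
  if (inherits(lesional, "pa_case")) {
    case_id <- lesional$case_id
    control <- lesional$control
    lesional <- lesional$lesional
  }
  stopifnot(inherits(lesional, "pa_volume"), inherits(control, "pa_volume"))
  ls <- analyze_volume(lesional, config)
  ns <- analyze_volume(control, config)
  metrics <- case_metrics(
    Z = ls$Z_um, D = ls$melanin$D_um,
    Phi_ls = ls$vessels$Phi_um, Phi_ns = ns$vessels$Phi_um,
    rho_ls = ls$vessels$rho, rho_ns = ns$vessels$rho,
    r_ls = ls$vessels$r, p_corr_ls = ls$vessels$p_corr,
    diam_reps_ls = ls$vessels$tiles$phi_um,
    diam_reps_ns = ns$vessels$tiles$phi_um,
    dens_reps_ls = ls$vessels$tiles$rho,
    dens_reps_ns = ns$vessels$tiles$rho,
    case_id = case_id)
  cls <- classify_case(metrics,
                       require_significance = config$require_significance,
                       alpha = config$alpha,
                       method = config$group_test,
                       flags = c(ls$flags, ns$flags))
  structure(list(metrics = metrics, classification = cls,
                 lesional = ls, control = ns, config = config),
            class = "case_analysis")
}

#' @export
print.case_analysis <- function(x, ...) {
  print(x$classification)
  invisible(x)
}

#' Write a case report as JSON
#'
#' Emits the classification, the supporting metrics and the full
#' configuration (provenance) for one analysed case.
#'
#' @param analysis a `case_analysis` from [analyze_case()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_case_report <- function(analysis, path) {
  stopifnot(inherits(analysis, "case_analysis"))
  m <- analysis$metrics
  rep <- list(
    case_id = m$case_id,
    classification = list(
      label = analysis$classification$label,
      layer_call = analysis$classification$layer_call,
      vascular_call = analysis$classification$vascular_call,
      flags = analysis$classification$flags),
    Z_um = m$Z,
    melanin = list(D_um = m$D,
                   mean_amplitude = analysis$lesional$melanin$mean_amplitude,
                   area_by_depth = analysis$lesional$melanin$area_profile),
    vessels = list(Phi_um = m$Phi_ls, Phi_ns_um = m$Phi_ns,
                   rho_percent = 100 * m$rho_ls,
                   rho_ns_percent = 100 * m$rho_ns,
                   r = m$r_ls, p_corr = m$p_corr_ls,
                   n_tiles = length(m$diam_reps_ls),
                   p_diameter = analysis$classification$p_diameter,
                   p_density = analysis$classification$p_density),
    config = analysis$config[!vapply(analysis$config, is.null, logical(1L))])
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Summarise several analysed cases as a table
#'
#' One row per case in the style of a per-patient results table: case id,
#' optional clinical label, the classification, and the supporting numbers
#' (depths in micrometres, densities in percent).
#'
#' @param analyses list of `case_analysis` objects.
#' @param clinical optional character vector of clinical labels.
#' @return A data.frame.
#' @export
summarize_cases <- function(analyses, clinical = NULL) {
  rows <- lapply(seq_along(analyses), function(i) {
    a <- analyses[[i]]
    m <- a$metrics
    data.frame(case = m$case_id,
               clinical = if (is.null(clinical)) NA_character_ else clinical[i],
               pa_class = a$classification$label,
               Z_um = m$Z, D_um = m$D,
               Phi_ls_um = m$Phi_ls, Phi_ns_um = m$Phi_ns,
               rho_ls_percent = 100 * m$rho_ls,
               rho_ns_percent = 100 * m$rho_ns,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
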