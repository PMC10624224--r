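#' Construct a photoacoustic amplitude volume
#'
#' A `pa_volume` holds a 3D array of non-negative envelope amplitudes indexed
#' `[x, y, z]` together with its voxel spacing in micrometres. The z index
#' increases with tissue depth; `z = 1` is the shallowest sample. Voxel
#' spacing is mandatory: every downstream quantity (surface depth, boundary
#' depth, vessel diameter) is reported in micrometres and no default spacing
#' exists.
#'
#' @param amplitude numeric 3D array of non-negative envelope amplitudes,
#'   indexed `[x, y, z]` (arbitrary units).
#' @param dx,dy lateral voxel spacing, micrometres.
#' @param dz axial voxel spacing, micrometres.
#' @param label free-text label, conventionally `"lesional"` or
#'   `"non_lesional"`.
#' @return An object of class `pa_volume`: a list with elements `amplitude`,
#'   `dx`, `dy`, `dz`, `label`.
#' @examples
#' v <- pa_volume(array(0, c(4, 4, 8)), dx = 5, dy = 5, dz = 7.5)
#' dim(v$amplitude)
#' @export
pa_volume <- function(amplitude, dx, dy, dz, label = "unlabelled") {
  if (!is.array(amplitude) || length(dim(amplitude)) != 3L)
    stop("`amplitude` must be a rank-3 array")
  if (!is.numeric(amplitude))
    stop("`amplitude` must be numeric")
  if (anyNA(amplitude))
    stop("`amplitude` contains missing values")
  if (min(amplitude) < 0)
    stop("`amplitude` must be non-negative (envelope amplitudes); ",
         "clip or use read_volume() which clips with a warning")
  for (s in c(dx, dy, dz))
    if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
      stop("voxel spacings dx, dy, dz must be positive finite scalars (µm)")
  structure(
    list(amplitude = amplitude, dx = as.numeric(dx), dy = as.numeric(dy),
         dz = as.numeric(dz), label = as.character(label)[1L]),
    class = "pa_volume"
  )
}

#' @export
print.pa_volume <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf(
    "<pa_volume> %s: %d x %d x %d voxels, spacing (%g, %g, %g) um, extent (%g, %g, %g) um\n",
    x$label, d[1], d[2], d[3], x$dx, x$dy, x$dz,
    d[1] * x$dx, d[2] * x$dy, d[3] * x$dz))
  cat(sprintf("  amplitude range [%g, %g]\n", min(x$amplitude), max(x$amplitude)))
  invisible(x)
}

#' @export
dim.pa_volume <- function(x) dim(x$amplitude)

clip_negative <- function(a, path = NULL) {
  n_neg <- sum(a < 0)
  if (n_neg > 0) {
    warning(sprintf("%d negative voxel%s clipped to 0%s", n_neg,
                    if (n_neg == 1L) "" else "s",
                    if (is.null(path)) "" else paste0(" in ", path)),
            call. = FALSE)
    a[a < 0] <- 0
  }
  a
}

#' Read a 3D photoacoustic volume from disk
#'
#' Supported containers are multi-page grayscale TIFF (`.tif`/`.tiff`; pages
#' are z-slices, within a page row = y and column = x, matching a stack of
#' B-scans) and NIfTI-1 (`.nii`/`.nii.gz`) with voxel spacing in the header
#' `pixdim`. Negative stored values are clipped to 0 and counted in a
#' warning. For TIFF, `spacing` is mandatory (the format has no trustworthy
#' physical z spacing); for NIfTI an explicit `spacing` argument overrides
#' the embedded `pixdim`.
#'
#' @param path file path.
#' @param spacing numeric length-3 vector `(dx, dy, dz)` in micrometres, or
#'   `NULL` to use embedded metadata (NIfTI only).
#' @param label passed to [pa_volume()].
#' @return A [pa_volume()].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, spacing = NULL, label = "unlabelled") {
  if (!file.exists(path))
    stop("volume file not found: ", path)
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
      stop("`spacing` must be three positive numbers (dx, dy, dz) in µm")
  }
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tif", "tiff")) {
    if (is.null(spacing))
      stop("reading TIFF requires an explicit `spacing` (dx, dy, dz in µm): ", path)
    pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE,
                                     info = TRUE),
                      error = function(e)
                        stop("not a readable TIFF volume: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE))
    if (!is.list(pages)) pages <- list(pages)
    bps <- attr(pages[[1L]], "bits.per.sample")
    if (is.null(bps) || bps >= 32L) {
      # 32-bit samples are float here: re-read without the integer
      # passthrough so the stored float32 values come back verbatim
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
    }
    d2 <- dim(pages[[1L]])
    if (length(d2) != 2L)
      stop("TIFF pages must be single-channel grayscale: ", path)
    a <- array(0, c(d2[2L], d2[1L], length(pages)))  # [x, y, z]
    for (k in seq_along(pages)) {
      pk <- pages[[k]]
      if (!identical(dim(pk), d2))
        stop("TIFF pages disagree in shape: ", path)
      a[, , k] <- t(pk)
    }
    a <- clip_negative(a, path)
    return(pa_volume(a, spacing[1L], spacing[2L], spacing[3L], label))
  }
  if (ext == "nii") {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    attributes(a) <- list(dim = dim(a))  # plain array, no NIfTI baggage
    if (length(dim(a)) != 3L)
      stop("NIfTI dataset must be rank 3, got rank ", length(dim(a)), ": ", path)
    if (!is.numeric(a))
      stop("NIfTI dataset is non-numeric: ", path)
    if (is.null(spacing)) {
      spacing <- RNifti::pixdim(img)[1:3]
      if (anyNA(spacing) || any(spacing <= 0))
        stop("NIfTI header has no usable pixdim; pass `spacing` explicitly: ", path)
    }
    a <- clip_negative(a, path)
    return(pa_volume(a, spacing[1L], spacing[2L], spacing[3L], label))
  }
  stop("unrecognised volume format (expected .tif/.tiff or .nii/.nii.gz): ", path)
}

#' Write a 3D photoacoustic volume to disk
#'
#' The format is selected by extension. NIfTI stores float64 and round-trips
#' any volume bit-exactly. TIFF uses uint16 when all amplitudes are integers
#' in `[0, 65535]` (exact round-trip) and 32-bit float when amplitudes lie in
#' `[0, 1]`; other ranges are rejected with a pointer to NIfTI, because TIFF
#' float storage is only defined on `[0, 1]` here.
#'
#' @param volume a [pa_volume()].
#' @param path destination path (`.tif`/`.tiff` or `.nii`/`.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pa_volume"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  a <- volume$amplitude
  if (ext %in% c("tif", "tiff")) {
    nz <- dim(a)[3L]
    integral <- max(a) <= 65535 && all(a == round(a))
    if (!integral && max(a) > 1)
      stop("TIFF export supports integer amplitudes in [0, 65535] (uint16) or ",
           "real amplitudes in [0, 1] (float32); rescale or write NIfTI instead")
    pages <- vector("list", nz)
    for (k in seq_len(nz))
      pages[[k]] <- t(if (integral) a[, , k] / 65535 else a[, , k])
    if (integral) {
      tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    } else {
      tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    }
    return(invisible(path))
  }
  if (ext == "nii") {
    img <- RNifti::asNifti(
      a, reference = list(pixdim = c(-1, volume$dx, volume$dy, volume$dz, rep(0, 4))),
      datatype = "double")
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  stop("unrecognised volume format (expected .tif/.tiff or .nii/.nii.gz): ", path)
}

#' Read a case manifest pairing lesional and control volumes
#'
#' A case manifest is a JSON file with fields `case_id`, `lesional`,
#' `control` (paths, relative to the manifest's directory unless absolute),
#' `spacing` (`[dx, dy, dz]` in micrometres, applied to both volumes) and
#' optional `notes`. Lesional and control volumes of one case share the same
#' voxel spacing by construction.
#'
#' @param path manifest JSON path.
#' @return A list of class `pa_case` with elements `case_id`, `lesional` and
#'   `control` ([pa_volume()]s), and `notes`.
#' @export
read_case <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("case_id", "lesional", "control", "spacing"))
    if (is.null(m[[f]])) stop("case manifest is missing field `", f, "`: ", path)
  base <- dirname(path)
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  structure(list(
    case_id = as.character(m$case_id),
    lesional = read_volume(resolve(m$lesional), m$spacing, label = "lesional"),
    control = read_volume(resolve(m$control), m$spacing, label = "non_lesional"),
    notes = if (is.null(m$notes)) "" else as.character(m$notes)
  ), class = "pa_case")
}

#' Write a case manifest and its two volumes
#'
#' @param lesional,control [pa_volume()]s with identical spacing.
#' @param dir output directory (created if needed).
#' @param case_id case identifier used in file names.
#' @param format `"nii"` (lossless) or `"tif"`.
#' @param notes free-text acquisition notes.
#' @return Path of the written manifest, invisibly.
#' @export
write_case <- function(lesional, control, dir, case_id = "case",
                       format = c("nii", "tif"), notes = "") {
  format <- match.arg(format)
  stopifnot(inherits(lesional, "pa_volume"), inherits(control, "pa_volume"))
  sp <- c(lesional$dx, lesional$dy, lesional$dz)
  if (!isTRUE(all.equal(sp, c(control$dx, control$dy, control$dz))))
    stop("lesional and control volumes must share identical voxel spacing")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fl <- paste0(case_id, "_lesional.", format)
  fn <- paste0(case_id, "_control.", format)
  write_volume(lesional, file.path(dir, fl))
  write_volume(control, file.path(dir, fn))
  manifest <- file.path(dir, paste0(case_id, "_manifest.json"))
  jsonlite::write_json(
    list(case_id = case_id, lesional = fl, control = fn,
         spacing = sp, notes = notes),
    manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
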