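#' Write / read a velocity field on disk
#'
#' The on-disk layout is three per-direction 4-D NIfTI files
#' (\code{<prefix>_Vx.nii.gz}, \code{_Vy}, \code{_Vz}; float32 cm/s, voxel
#' spacing and frame interval in the header pixdim) plus a JSON metadata
#' sidecar \code{<prefix>.json} carrying \code{venc_cms},
#' \code{spacing_mm}, and \code{frame_interval_ms}. The sidecar is
#' authoritative: a field cannot be read without its venc, because
#' unwrapping is undefined without it.
#'
#' @param field a [velocity_field()].
#' @param prefix path prefix (no extension).
#' @return \code{write_field} returns the prefix invisibly;
#'   \code{read_field} returns a [velocity_field()].
#' @export
write_field <- function(field, prefix) {
  stopifnot(is_velocity_field(field))
  dirs <- c("Vx", "Vy", "Vz")
  for (d in 1:3) {
    img <- RNifti::asNifti(field$values[, , , , d, drop = TRUE])
    RNifti::pixdim(img) <- c(field$voxel_spacing, field$frame_interval / 1000)
    RNifti::writeNifti(img, paste0(prefix, "_", dirs[d], ".nii.gz"),
                       datatype = "float")
  }
  jsonlite::write_json(
    list(format_version = 1L, venc_cms = field$venc,
         spacing_mm = field$voxel_spacing,
         frame_interval_ms = field$frame_interval,
         n_frames = dim(field$values)[4]),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_field
#' @export
read_field <- function(prefix) {
  sidecar <- paste0(prefix, ".json")
  if (!file.exists(sidecar)) stop("metadata sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$venc_cms))
    stop("metadata attribute `venc_cms` is missing in ", sidecar,
         "; unwrapping is undefined without the venc")
  for (key in c("spacing_mm", "frame_interval_ms"))
    if (is.null(meta[[key]]))
      stop("metadata attribute `", key, "` is missing in ", sidecar)
  dirs <- c("Vx", "Vy", "Vz")
  vols <- lapply(dirs, function(d) {
    f <- paste0(prefix, "_", d, ".nii.gz")
    if (!file.exists(f)) stop("velocity component file not found: ", f)
    v <- as.array(RNifti::readNifti(f))
    if (length(dim(v)) == 3L) dim(v) <- c(dim(v), 1L)
    v
  })
  d1 <- dim(vols[[1]])
  for (i in 2:3)
    if (!identical(dim(vols[[i]]), d1))
      stop("shape inconsistency across direction files: ", dirs[i],
           " has dims [", paste(dim(vols[[i]]), collapse = ","),
           "], Vx has [", paste(d1, collapse = ","), "]")
  vals <- array(0, c(d1, 3L))
  for (i in 1:3) vals[, , , , i] <- vols[[i]]
  velocity_field(vals, meta$venc_cms, meta$spacing_mm, meta$frame_interval_ms)
}

#' Write / read a binary mask
#'
#' Masks (vessel segmentations, wrap masks) are stored as uint8 NIfTI, 3-D
#' or 5-D congruent with their field.
#'
#' @param mask logical/binary array.
#' @param path output path (.nii or .nii.gz).
#' @export
write_mask <- function(mask, path) {
  arr <- array(as.integer(as.logical(mask)), dim(as.array(mask)))
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "uint8"), path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  arr <- as.array(RNifti::readNifti(path))
  array(arr != 0, dim(arr))
}

#' Import scanner-style phase integers
#'
#' Converts phase-integer data in \code{[-4096, 4096)} to velocities in
#' \code{[-venc, venc)} cm/s.
#'
#' @param phase integer array.
#' @param venc venc in cm/s.
#' @return Numeric array of velocities.
#' @export
phase_to_velocity <- function(phase, venc) {
  if (any(phase < -4096 | phase >= 4096))
    stop("phase integers must lie in [-4096, 4096)")
  phase / 4096 * venc
}
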