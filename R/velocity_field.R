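#' Construct a velocity field
#'
#' The central container of the package: a 5-axis array of velocities in
#' cm/s indexed \code{[x, y, z, frame, direction]} with direction 1..3 being
#' Vx, Vy, Vz, together with the acquisition metadata every stage needs
#' (venc, voxel spacing, frame interval).
#'
#' @param values numeric 5-D array \code{[x, y, z, frame, direction]}, cm/s.
#' @param venc velocity-encoding sensitivity in cm/s (positive scalar).
#' @param voxel_spacing numeric length-3, voxel edge lengths in mm.
#' @param frame_interval temporal resolution in ms (positive scalar).
#' @return An object of class \code{velocity_field}.
#' @examples
#' v <- velocity_field(array(0, c(4, 4, 2, 3, 3)), venc = 150,
#'                     voxel_spacing = c(2.4, 2.4, 2.6), frame_interval = 40)
#' dim(v$values)
#' @export
velocity_field <- function(values, venc, voxel_spacing, frame_interval) {
  if (!is.array(values) || length(dim(values)) != 5L)
    stop("`values` must be a 5-D array [x, y, z, frame, direction]")
  if (dim(values)[5] != 3L)
    stop("fifth axis must have length 3 (Vx, Vy, Vz)")
  if (!is.numeric(venc) || length(venc) != 1L || !is.finite(venc) || venc <= 0)
    stop("`venc` must be a positive finite scalar (cm/s)")
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop("`voxel_spacing` must be 3 positive lengths (mm)")
  if (length(frame_interval) != 1L || frame_interval <= 0)
    stop("`frame_interval` must be a positive duration (ms)")
  structure(
    list(values = values, venc = as.numeric(venc),
         voxel_spacing = as.numeric(voxel_spacing),
         frame_interval = as.numeric(frame_interval)),
    class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$values)
  cat("<velocity_field> ", paste(d[1:3], collapse = " x "),
      " voxels, ", d[4], " frames, 3 directions\n", sep = "")
  cat("  venc: ", x$venc, " cm/s | spacing: ",
      paste(x$voxel_spacing, collapse = " x "), " mm | frame interval: ",
      x$frame_interval, " ms\n", sep = "")
  cat("  velocity range: [", round(min(x$values), 2), ", ",
      round(max(x$values), 2), "] cm/s\n", sep = "")
  invisible(x)
}

is_velocity_field <- function(x) inherits(x, "velocity_field")

field_dim <- function(field) dim(field$values)

n_frames <- function(field) dim(field$values)[4]

#' @noRd
check_congruent <- function(a, b, what = "mask") {
  da <- if (is_velocity_field(a)) dim(a$values) else dim(a)
  db <- if (is_velocity_field(b)) dim(b$values) else dim(b)
  if (!identical(da, db))
    stop(sprintf("shape mismatch: %s has dims [%s], field has dims [%s]",
                 what, paste(db, collapse = ","), paste(da, collapse = ",")))
  invisible(TRUE)
}

# Expand a static 3-D vessel mask to the 5-D field geometry (logical).
broadcast_vessel <- function(vessel, dims5) {
  stopifnot(identical(dim(vessel), dims5[1:3]))
  array(rep(as.logical(vessel), times = prod(dims5[4:5])), dim = dims5)
}
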