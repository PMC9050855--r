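#' Vessel geometry descriptors
#'
#' Two centerline geometries are supported: a straight tube along one grid
#' axis, and a "candy-cane" U-bend (ascending limb, 180-degree arch,
#' descending limb) lying in a plane that can be tilted about the z axis so
#' that all three velocity components are exercised.
#'
#' @param radius_mm tube (lumen) radius in mm.
#' @param axis for the straight tube, the grid axis the tube runs along
#'   (\code{"x"}, \code{"y"} or \code{"z"}).
#' @param bend_radius_mm centerline radius of the arch, mm.
#' @param tilt_deg rotation of the bend plane about the z axis, degrees.
#'   A non-zero tilt gives the arch a Vy component.
#' @return A geometry descriptor list used in [phantom_spec()].
#' @export
vessel_straight <- function(radius_mm = 12, axis = "z") {
  axis <- match.arg(axis, c("x", "y", "z"))
  list(type = "straight", radius_mm = radius_mm, axis = axis)
}

#' @rdname vessel_straight
#' @export
vessel_ubend <- function(radius_mm = 8, bend_radius_mm = 20, tilt_deg = 20) {
  list(type = "ubend", radius_mm = radius_mm,
       bend_radius_mm = bend_radius_mm, tilt_deg = tilt_deg)
}

#' Parameterize a synthetic 4D-flow phantom
#'
#' The defaults emulate a thoracic aortic acquisition: ~2.4-2.6 mm voxels,
#' 40 ms temporal resolution, venc 150 cm/s with peak velocity at the venc
#' (so any reduced venc wraps), and a magnitude SNR of 15 driving
#' venc-proportional velocity noise.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing numeric length-3, mm.
#' @param n_frames number of cardiac frames (>= 2).
#' @param frame_interval temporal resolution, ms.
#' @param vessel geometry from [vessel_straight()] or [vessel_ubend()].
#' @param peak_velocity centerline peak velocity at the systolic peak, cm/s.
#' @param venc velocity-encoding sensitivity of the simulated scan, cm/s.
#' @param snr magnitude signal-to-noise ratio; velocity noise has standard
#'   deviation \code{sqrt(2) * venc / (pi * snr)} cm/s. Use \code{Inf} for a
#'   noise-free phantom.
#' @param systole_fraction fraction of the cycle occupied by the systolic
#'   pulse, passed to [generate_waveform()].
#' @param seed integer seed; identical specs regenerate identical phantoms.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(64, 48, 24),
                         voxel_spacing = c(2.4, 2.4, 2.6),
                         n_frames = 20,
                         frame_interval = 40,
                         vessel = vessel_ubend(),
                         peak_velocity = 150,
                         venc = 150,
                         snr = 15,
                         systole_fraction = 0.35,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop("`grid_shape` must be 3 integers >= 4")
  if (length(voxel_spacing) != 3L || any(voxel_spacing <= 0))
    stop("`voxel_spacing` must be 3 positive lengths (mm)")
  if (n_frames < 2L) stop("`n_frames` must be >= 2")
  if (peak_velocity <= 0) stop("`peak_velocity` must be > 0")
  if (venc <= 0) stop("`venc` must be > 0")
  if (!(snr > 0)) stop("`snr` must be positive (may be Inf)")
  # lumen must span at least 2 voxels in every in-plane direction
  if (any(vessel$radius_mm / voxel_spacing[1:2] < 2))
    stop("vessel radius must be >= 2 voxels in every in-plane direction")
  structure(
    list(grid_shape = grid_shape, voxel_spacing = as.numeric(voxel_spacing),
         n_frames = as.integer(n_frames),
         frame_interval = as.numeric(frame_interval), vessel = vessel,
         peak_velocity = as.numeric(peak_velocity), venc = as.numeric(venc),
         snr = as.numeric(snr), systole_fraction = systole_fraction,
         seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Cardiac waveform scale factors
#'
#' A deterministic raised-cosine systolic pulse on top of a low diastolic
#' plateau, sampled at frame centers and normalized so the maximum factor is
#' exactly 1. The plateau keeps diastolic factors below 0.15, matching the
#' near-absence of aliasing in diastolic frames of aortic scans.
#'
#' @param n_frames number of frames (>= 2).
#' @param frame_interval frame duration in ms (carried for integration; the
#'   waveform shape depends only on the frame phase).
#' @param systole_fraction fraction of the cycle covered by the pulse,
#'   in (0, 1).
#' @return Numeric vector of length \code{n_frames} in \code{[0, 1]} with
#'   maximum 1.
#' @examples
#' w <- generate_waveform(20, 40)
#' which.max(w)  # early-systolic peak
#' @export
generate_waveform <- function(n_frames, frame_interval = 40,
                              systole_fraction = 0.35) {
  if (length(n_frames) != 1L || !is.finite(n_frames) || n_frames < 2)
    stop("`n_frames` must be an integer >= 2")
  if (!(systole_fraction > 0 && systole_fraction < 1))
    stop("`systole_fraction` must lie in (0, 1)")
  n_frames <- as.integer(n_frames)
  plateau <- 0.05
  p <- (seq_len(n_frames) - 0.5) / n_frames     # frame-center phase in [0,1)
  w <- ifelse(p < systole_fraction,
              plateau + (1 - plateau) * 0.5 *
                (1 - cos(2 * pi * p / systole_fraction)),
              plateau)
  w / max(w)
}

#' Generate a synthetic 4D-flow phantom
#'
#' Inside the vessel the through-axis velocity follows a parabolic
#' (Poiseuille) profile scaled per frame by the cardiac waveform and
#' decomposed into Vx/Vy/Vz along the local centerline tangent; outside the
#' vessel the true velocity is zero (static tissue). Zero-mean Gaussian
#' noise with standard deviation \code{sqrt(2) * venc / (pi * snr)} is added
#' independently per voxel, frame, and direction — the standard
#' phase-contrast relation in which velocity noise is proportional to the
#' selected venc.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class \code{flow_phantom} with elements
#'   \code{field} (a [velocity_field()]), \code{vessel} (logical 3-D mask),
#'   \code{waveform}, \code{truth} (the noise-free field, for reference),
#'   and \code{spec}.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(32, 24, 12),
#'                                     n_frames = 5, snr = Inf))
#' max(abs(ph$field$values))
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_shape; sp <- spec$voxel_spacing
  nt <- spec$n_frames
  geom <- phantom_geometry(spec)
  w <- generate_waveform(nt, spec$frame_interval, spec$systole_fraction)

  nvox <- prod(g)
  vals <- array(0, c(g, nt, 3L))
  base <- geom$speed  # centerline-profile speed at waveform peak, [x,y,z]
  for (d in 1:3) {
    comp <- base * geom$tangent[[d]]
    for (t in seq_len(nt)) vals[, , , t, d] <- comp * w[t]
  }
  truth <- velocity_field(vals, spec$venc, sp, spec$frame_interval)

  if (is.finite(spec$snr)) {
    sigma <- sqrt(2) * spec$venc / (pi * spec$snr)
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old_seed), add = TRUE)
    set.seed(spec$seed)
    vals <- vals + array(rnorm(length(vals), sd = sigma), dim = dim(vals))
  }
  field <- velocity_field(vals, spec$venc, sp, spec$frame_interval)
  structure(list(field = field, vessel = geom$inside, waveform = w,
                 truth = truth, spec = spec),
            class = "flow_phantom")
}

#' @export
print.flow_phantom <- function(x, ...) {
  cat("<flow_phantom> vessel:", x$spec$vessel$type,
      "| voxels in vessel:", sum(x$vessel), "\n")
  print(x$field)
  invisible(x)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

# Geometry kernel: returns, per voxel, the inside-lumen mask, the peak-frame
# speed (parabolic in centerline distance), and the unit tangent components.
phantom_geometry <- function(spec) {
  g <- spec$grid_shape; sp <- spec$voxel_spacing
  R <- spec$vessel$radius_mm
  # voxel-center coordinates, mm
  cx <- (seq_len(g[1]) - 0.5) * sp[1]
  cy <- (seq_len(g[2]) - 0.5) * sp[2]
  cz <- (seq_len(g[3]) - 0.5) * sp[3]
  X <- array(rep(cx, times = g[2] * g[3]), g)
  Y <- array(rep(rep(cy, each = g[1]), times = g[3]), g)
  Z <- array(rep(cz, each = g[1] * g[2]), g)
  extent <- g * sp

  if (spec$vessel$type == "straight") {
    ax <- spec$vessel$axis
    ctr <- extent / 2
    if (ax == "z") { d2 <- (X - ctr[1])^2 + (Y - ctr[2])^2; tvec <- c(0, 0, 1) }
    else if (ax == "x") { d2 <- (Y - ctr[2])^2 + (Z - ctr[3])^2; tvec <- c(1, 0, 0) }
    else { d2 <- (X - ctr[1])^2 + (Z - ctr[3])^2; tvec <- c(0, 1, 0) }
    if (2 * R > min(extent[setdiff(1:3, match(ax, c("x", "y", "z")))]))
      stop("vessel geometry exceeds the grid")
    inside <- d2 <= R^2
    speed <- spec$peak_velocity * pmax(0, 1 - d2 / R^2) * inside
    tangent <- lapply(tvec, function(v) array(v, g))
    return(list(inside = inside, speed = speed, tangent = tangent))
  }

  # U-bend: limbs along z for z <= z0, arch of radius Rb for z > z0, in a
  # plane through the grid center rotated by tilt about the z axis.
  Rb <- spec$vessel$bend_radius_mm
  tilt <- spec$vessel$tilt_deg * pi / 180
  ct <- cos(tilt); st <- sin(tilt)
  ctr <- extent / 2
  z0 <- extent[3] - (Rb + R) - min(sp)   # arch apex kept inside the grid
  if (z0 <= R || Rb - R <= 0 ||
      Rb + R > min(abs(c(ctr[1] / ct, if (abs(st) > 1e-8) ctr[2] / abs(st) else Inf))))
    stop("vessel geometry exceeds the grid")
  # rotated in-plane coordinate u (bend plane) and out-of-plane coordinate v
  U <- (X - ctr[1]) * ct + (Y - ctr[2]) * st
  V <- -(X - ctr[1]) * st + (Y - ctr[2]) * ct
  W <- Z - z0

  inside <- array(FALSE, g); d2 <- array(Inf, g)
  tx <- array(0, g); ty <- array(0, g); tz <- array(0, g)

  limb <- W <= 0
  # ascending limb at u = -Rb (flow +z); descending at u = +Rb (flow -z)
  d2a <- (U + Rb)^2 + V^2
  d2d <- (U - Rb)^2 + V^2
  sel <- limb & d2a <= d2d
  d2[sel] <- d2a[sel]; tz[sel] <- 1
  sel <- limb & d2a > d2d
  d2[sel] <- d2d[sel]; tz[sel] <- -1

  arch <- W > 0
  rho <- sqrt(U^2 + W^2)
  phi <- atan2(W, -U)                    # 0 at ascending top, pi at descending
  d2arc <- (rho - Rb)^2 + V^2
  # arch tangent in bend-plane coords: (sin(phi), 0, cos(phi)); rotate back
  tx[arch] <- (sin(phi) * ct)[arch]
  ty[arch] <- (sin(phi) * st)[arch]
  tz[arch] <- cos(phi)[arch]
  d2[arch] <- d2arc[arch]

  inside <- d2 <= R^2
  speed <- spec$peak_velocity * pmax(0, 1 - d2 / R^2) * inside
  tx[!inside] <- 0; ty[!inside] <- 0; tz[!inside] <- 0
  list(inside = inside, speed = speed, tangent = list(tx, ty, tz))
}
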