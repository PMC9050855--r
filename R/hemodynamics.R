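#' Define a 2D analysis plane
#'
#' A plane through \code{origin} (mm) with unit \code{normal}. Flow is
#' integrated over the in-plane region where the vessel mask is set.
#'
#' @param origin numeric length-3 point on the plane, mm.
#' @param normal numeric length-3 plane normal (normalized internally).
#' @return An \code{analysis_plane}.
#' @export
analysis_plane <- function(origin, normal) {
  stopifnot(length(origin) == 3L, length(normal) == 3L)
  nn <- sqrt(sum(normal^2))
  if (nn == 0) stop("`normal` must be non-zero")
  structure(list(origin = as.numeric(origin), normal = as.numeric(normal) / nn),
            class = "analysis_plane")
}

#' Quantify flow through an analysis plane
#'
#' Per frame, the volumetric flow rate is
#' \code{Q = sum_ROI (v . n) * pixel_area} in ml/s; net flow is the
#' temporal integral of Q over the cardiac cycle (ml); peak flow is the
#' maximum of the series; peak velocity is the maximum voxelwise speed
#' (vector magnitude) over the ROI and all frames, reported in m/s.
#'
#' Planes whose normal is grid-axis aligned are evaluated directly on the
#' matching voxel slice. Oblique planes are resampled on a regular in-plane
#' grid at the finest voxel spacing with nearest-neighbor velocity sampling.
#' In both cases the ROI is the connected vessel cross-section containing
#' the plane origin — a slice through a curved vessel can intersect the
#' lumen more than once, and opposing limbs would cancel in the flux sum.
#'
#' @param field a [velocity_field()].
#' @param plane an [analysis_plane()].
#' @param vessel static 3-D vessel mask defining the in-plane ROI.
#' @return A \code{flow_report}: \code{net_flow_ml}, \code{peak_flow_mls},
#'   \code{peak_velocity_ms}, \code{series_mls}, \code{time_ms}.
#' @export
plane_flow <- function(field, plane, vessel) {
  stopifnot(is_velocity_field(field), inherits(plane, "analysis_plane"))
  dims <- dim(field$values); sp <- field$voxel_spacing
  stopifnot(identical(dim(as.array(vessel)), dims[1:3]))
  nt <- dims[4]
  axis <- which(abs(abs(plane$normal) - 1) < 1e-6)

  if (length(axis) == 1L) {
    k <- round(plane$origin[axis] / sp[axis] + 0.5)
    if (k < 1 || k > dims[axis]) stop("plane does not intersect the field")
    idx <- switch(axis,
                  `1` = list(k, TRUE, TRUE), `2` = list(TRUE, k, TRUE),
                  `3` = list(TRUE, TRUE, k))
    roi <- do.call(`[`, c(list(array(as.logical(vessel), dims[1:3])), idx))
    if (!any(roi)) stop("degenerate ROI: the plane misses the vessel")
    # keep only the vessel cross-section at the plane origin: a slice can
    # intersect the vessel more than once (both limbs of a U-bend), and
    # opposing limbs would cancel in the flux sum
    roi <- connected_roi(roi, (plane$origin / sp)[-axis] + 0.5)
    area_mm2 <- prod(sp[-axis])
    sgn <- sign(plane$normal[axis])
    series <- vapply(seq_len(nt), function(t) {
      vn <- do.call(`[`, c(list(field$values), idx, list(t, axis)))
      sum(vn[roi]) * sgn * 10 * area_mm2 / 1000   # cm/s -> mm/s; mm^3/s -> ml/s
    }, numeric(1))
    speed2max <- 0
    for (t in seq_len(nt)) {
      v1 <- do.call(`[`, c(list(field$values), idx, list(t, 1)))
      v2 <- do.call(`[`, c(list(field$values), idx, list(t, 2)))
      v3 <- do.call(`[`, c(list(field$values), idx, list(t, 3)))
      s2 <- v1^2 + v2^2 + v3^2
      speed2max <- max(speed2max, s2[roi])
    }
  } else {
    samp <- oblique_samples(plane, dims, sp)
    keep <- samp$inside & as.vector(vessel != 0)[samp$vox]
    if (!any(keep)) stop("degenerate ROI: the plane misses the vessel")
    keep_m <- matrix(keep, samp$n_grid, samp$n_grid)
    ctr <- (samp$n_grid + 1) / 2
    keep <- as.vector(connected_roi(keep_m, c(ctr, ctr)))
    vox <- samp$vox[keep]
    nvol <- prod(dims[1:3])
    n <- plane$normal
    series <- vapply(seq_len(nt), function(t) {
      off <- (t - 1) * nvol
      vn <- field$values[vox + off] * n[1] +
        field$values[vox + off + nvol * nt] * n[2] +
        field$values[vox + off + 2 * nvol * nt] * n[3]
      sum(vn) * 10 * samp$area_mm2 / 1000
    }, numeric(1))
    speed2max <- 0
    for (t in seq_len(nt)) {
      off <- (t - 1) * nvol
      s2 <- field$values[vox + off]^2 +
        field$values[vox + off + nvol * nt]^2 +
        field$values[vox + off + 2 * nvol * nt]^2
      speed2max <- max(speed2max, s2)
    }
  }
  dt_s <- field$frame_interval / 1000
  structure(list(net_flow_ml = sum(series) * dt_s,
                 peak_flow_mls = max(series),
                 peak_velocity_ms = sqrt(speed2max) / 100,
                 series_mls = series,
                 time_ms = (seq_len(nt) - 1) * field$frame_interval),
            class = "flow_report")
}

#' @export
print.flow_report <- function(x, ...) {
  cat(sprintf("<flow_report> net %.1f ml | peak %.1f ml/s | peak velocity %.2f m/s\n",
              x$net_flow_ml, x$peak_flow_mls, x$peak_velocity_ms))
  invisible(x)
}

# Regular in-plane sample grid for an oblique plane; nearest-neighbor voxel
# lookup, pixel area h^2 with h the finest voxel spacing.
oblique_samples <- function(plane, dims, sp) {
  n <- plane$normal
  ref <- diag(3)[, which.min(abs(n))]
  e1 <- ref - sum(ref * n) * n; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  h <- min(sp)
  half_diag <- sqrt(sum((dims[1:3] * sp)^2)) / 2
  s <- seq(-half_diag, half_diag, by = h)
  G <- expand.grid(a = s, b = s)
  pts <- cbind(plane$origin[1] + G$a * e1[1] + G$b * e2[1],
               plane$origin[2] + G$a * e1[2] + G$b * e2[2],
               plane$origin[3] + G$a * e1[3] + G$b * e2[3])
  ijk <- sweep(pts, 2, sp, "/") + 0.5
  ijk <- round(ijk)
  inside <- ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
  ijk[!inside, ] <- 1
  vox <- ijk[, 1] + dims[1] * (ijk[, 2] - 1) + dims[1] * dims[2] * (ijk[, 3] - 1)
  list(vox = as.integer(vox), inside = inside, area_mm2 = h^2,
       n_grid = length(s))
}

# 4-connected component of a 2-D logical mask containing (or nearest to)
# the seed point, by breadth-first flood fill.
connected_roi <- function(mask, seed_xy) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  dist2 <- (idx[, 1] - seed_xy[1])^2 + (idx[, 2] - seed_xy[2])^2
  start <- idx[which.min(dist2), ]
  comp <- matrix(FALSE, d[1], d[2])
  queue <- matrix(start, ncol = 2)
  comp[start[1], start[2]] <- TRUE
  while (nrow(queue) > 0) {
    p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
    for (step in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      q <- p + step
      if (q[1] >= 1 && q[1] <= d[1] && q[2] >= 1 && q[2] <= d[2] &&
          mask[q[1], q[2]] && !comp[q[1], q[2]]) {
        comp[q[1], q[2]] <- TRUE
        queue <- rbind(queue, q)
      }
    }
  }
  comp
}

#' Dual-venc ground truth for paired scans
#'
#' For a pair of co-registered scans of the same flow, a low-venc (aliased)
#' and a high-venc (non-aliased) acquisition, a voxel is truly aliased in
#' the low-venc scan where the per-direction velocity difference exceeds
#' the low venc. On noise-free simulated pairs this reproduces the wrap
#' simulator's ground-truth mask exactly: any wrapped value differs from
#' the truth by a multiple of \code{2 * venc_low}.
#'
#' @param low the low-venc (aliased) [velocity_field()].
#' @param high the high-venc (reference) [velocity_field()].
#' @return Logical ground-truth mask congruent with the fields.
#' @export
dual_venc_truth <- function(low, high) {
  stopifnot(is_velocity_field(low), is_velocity_field(high))
  check_congruent(high, low$values, "low-venc field")
  if (low$venc >= high$venc)
    stop("`low` must have the smaller venc")
  abs(high$values - low$values) > low$venc
}

#' Bland-Altman agreement
#'
#' Bias is \code{mean(test - reference)}; the limits of agreement (LOA) are
#' \code{1.96 * SD} of the differences (sample SD, n-1); the percent LOA is
#' the LOA as a percentage of the reference mean.
#'
#' @param reference,test numeric vectors of paired measurements
#'   (length >= 2).
#' @return An \code{agreement_report}: \code{bias}, \code{loa},
#'   \code{loa_percent} (NA with a warning when the reference mean is 0).
#' @examples
#' bland_altman(c(10, 10, 10, 10), c(11, 11, 11, 11))
#' @export
bland_altman <- function(reference, test) {
  if (length(reference) != length(test) || length(reference) < 2L)
    stop("`reference` and `test` must be equal-length vectors (length >= 2)")
  d <- test - reference
  bias <- mean(d)
  loa <- 1.96 * sd(d)
  mref <- mean(reference)
  if (mref == 0) {
    warning("reference mean is 0; percent LOA undefined")
    pct <- NA_real_
  } else pct <- 100 * loa / mref
  structure(list(bias = bias, loa = loa, loa_percent = pct,
                 n = length(reference)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement> bias %.3g | LOA %.3g | LOA %% of reference %.3g%% (n=%d)\n",
              x$bias, x$loa, x$loa_percent, x$n))
  invisible(x)
}

#' Standard analysis planes for a phantom
#'
#' Places planes emulating the ascending aorta, arch, and descending aorta
#' locations: for the U-bend, transverse planes through each limb midpoint
#' and a tangent-normal plane at the arch apex; for the straight tube, a
#' single mid-tube transverse plane.
#'
#' @param phantom a \code{flow_phantom} from [generate_phantom()].
#' @return Named list of [analysis_plane()] objects.
#' @export
phantom_planes <- function(phantom) {
  spec <- phantom$spec
  extent <- spec$grid_shape * spec$voxel_spacing
  ctr <- extent / 2
  if (spec$vessel$type == "straight") {
    ax <- match(spec$vessel$axis, c("x", "y", "z"))
    origin <- ctr; origin[ax] <- extent[ax] / 2
    nrm <- c(0, 0, 0); nrm[ax] <- 1
    return(list(mid = analysis_plane(origin, nrm)))
  }
  Rb <- spec$vessel$bend_radius_mm
  tilt <- spec$vessel$tilt_deg * pi / 180
  z0 <- extent[3] - (Rb + spec$vessel$radius_mm) - min(spec$voxel_spacing)
  u_asc <- c(-Rb * cos(tilt), -Rb * sin(tilt), 0)
  u_dsc <- -u_asc
  list(
    aao = analysis_plane(c(ctr[1] + u_asc[1], ctr[2] + u_asc[2], z0 / 2),
                         c(0, 0, 1)),
    arch = analysis_plane(c(ctr[1], ctr[2], z0 + Rb), c(cos(tilt), sin(tilt), 0)),
    dao = analysis_plane(c(ctr[1] + u_dsc[1], ctr[2] + u_dsc[2], z0 / 2),
                         c(0, 0, -1)))
}
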