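#' Dice overlap between detection and ground truth
#'
#' \code{(2|X intersect Y| + 1e-5) / (|X| + |Y| + 1e-5)}. The small constant
#' in numerator and denominator makes the score of two empty masks 1, so
#' frames with no aliasing are well defined. When a vessel mask is given,
#' only voxels inside the vessel are considered.
#'
#' @param detected,truth congruent binary/logical arrays (any shape; for 5-D
#'   masks the score pools all frames and directions).
#' @param restrict optional static 3-D vessel mask; metrics are computed
#'   only inside it.
#' @return Dice score in \code{[0, 1]}.
#' @examples
#' a <- array(c(1, 1, 1, 0), c(2, 2, 1))
#' b <- array(c(1, 1, 0, 1), c(2, 2, 1))
#' dice_score(a, b)
#' @export
dice_score <- function(detected, truth, restrict = NULL) {
  check_congruent(detected, truth, "truth")
  X <- as.logical(detected); Y <- as.logical(truth)
  if (!is.null(restrict)) {
    keep <- restrict_index(dim(as.array(detected)), restrict)
    X <- X[keep]; Y <- Y[keep]
  }
  eps <- 1e-5
  (2 * sum(X & Y) + eps) / (sum(X) + sum(Y) + eps)
}

restrict_index <- function(dims, restrict) {
  restrict <- as.logical(restrict)
  if (length(dims) == 3L) return(as.vector(restrict))
  stopifnot(length(dims) == 5L)
  rep(as.vector(restrict), times = prod(dims[4:5]))
}

#' Hausdorff distance between two masks, in mm
#'
#' The symmetric max-of-directed-min Euclidean distance between the voxel
#' center point sets of two binary masks, with coordinates scaled by the
#' voxel spacing. For 5-D masks the distance is computed per
#' (frame, direction) volume and the dataset value is the maximum over
#' volumes; the per-volume values are returned alongside. Volumes where both
#' masks are empty carry no distance and are skipped; a volume where exactly
#' one mask is empty has an undefined distance (\code{NA}, reported with a
#' warning for 5-D input, an error for a single volume).
#'
#' @inheritParams dice_score
#' @param voxel_spacing numeric length-3, mm.
#' @param method \code{"fast"} (early-exit scan, default) or
#'   \code{"brute"} (dense distance matrix); both give identical results.
#' @return For 3-D masks, the distance in mm. For 5-D masks, a list with
#'   \code{max_mm} and a data frame \code{per_volume}.
#' @export
hausdorff_mm <- function(detected, truth, voxel_spacing, restrict = NULL,
                         method = c("fast", "brute")) {
  method <- match.arg(method)
  check_congruent(detected, truth, "truth")
  dims <- dim(as.array(detected))
  stopifnot(length(voxel_spacing) == 3L, all(voxel_spacing > 0))
  if (length(dims) == 3L) {
    d <- hausdorff_volume(as.logical(detected), as.logical(truth), dims,
                          voxel_spacing, restrict, method)
    if (is.na(d))
      stop("Hausdorff distance is undefined: a mask is empty ",
           "(after vessel restriction)")
    return(d)
  }
  stopifnot(length(dims) == 5L)
  X <- array(as.logical(detected), dims); Y <- array(as.logical(truth), dims)
  rows <- expand.grid(frame = seq_len(dims[4]), direction = seq_len(dims[5]))
  rows$hausdorff_mm <- NA_real_
  n_undef <- 0L
  for (i in seq_len(nrow(rows))) {
    xm <- X[, , , rows$frame[i], rows$direction[i]]
    ym <- Y[, , , rows$frame[i], rows$direction[i]]
    if (!is.null(restrict)) { xm <- xm & restrict; ym <- ym & restrict }
    if (!any(xm) && !any(ym)) next
    if (!any(xm) || !any(ym)) { n_undef <- n_undef + 1L; next }
    rows$hausdorff_mm[i] <- hausdorff_volume(xm, ym, dims[1:3],
                                             voxel_spacing, NULL, method)
  }
  if (n_undef > 0L)
    warning(n_undef, " volume(s) have an undefined Hausdorff distance ",
            "(one mask empty); reported as NA")
  vals <- rows$hausdorff_mm[!is.na(rows$hausdorff_mm)]
  if (length(vals) == 0L)
    stop("Hausdorff distance is undefined for every volume")
  list(max_mm = max(vals), per_volume = rows)
}

hausdorff_volume <- function(xm, ym, dims3, spacing, restrict, method) {
  if (!is.null(restrict)) { xm <- xm & as.logical(restrict); ym <- ym & as.logical(restrict) }
  xi <- which(array(xm, dims3)); yi <- which(array(ym, dims3))
  if (length(xi) == 0L || length(yi) == 0L) return(NA_real_)
  P <- mask_coords(xi, dims3, spacing)
  Q <- mask_coords(yi, dims3, spacing)
  if (method == "fast") return(.hausdorff_points_cpp(P, Q))
  DM <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
  DM[DM < 0] <- 0
  max(max(apply(DM, 1, min)), max(apply(DM, 2, min)))^0.5
}

# voxel-center coordinates (mm) of linear indices in a 3-D grid
mask_coords <- function(idx, dims3, spacing) {
  idx0 <- idx - 1L
  x <- idx0 %% dims3[1]
  y <- (idx0 %/% dims3[1]) %% dims3[2]
  z <- idx0 %/% (dims3[1] * dims3[2])
  cbind(x * spacing[1], y * spacing[2], z * spacing[3])
}

#' Count detected aliased voxels inside the vessel
#'
#' @param mask binary/logical mask, 3-D or 5-D; for 5-D masks the count is
#'   summed over frames and directions.
#' @param restrict static 3-D vessel mask.
#' @return Integer count.
#' @export
count_aliased <- function(mask, restrict) {
  dims <- dim(as.array(mask))
  stopifnot(identical(dims[1:3], dim(as.array(restrict))[1:3]))
  keep <- restrict_index(dims, restrict)
  sum(as.logical(mask) & keep)
}
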