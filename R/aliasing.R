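#' Specify a simulated venc reduction
#'
#' Velocity aliasing is simulated retrospectively by reducing the venc of a
#' non-aliased scan: every true velocity outside the reduced representable
#' range \code{[-venc_sim, venc_sim)} wraps back in, shifted by multiples of
#' \code{2 * venc_sim}. Training draws reduce the venc to a uniformly random
#' fraction of the original in \code{[0.40, 0.70]}.
#'
#' @param venc_sim the reduced (simulated) venc, cm/s. Give either this or
#'   \code{venc_fraction}.
#' @param venc the original venc, cm/s.
#' @param venc_fraction fraction of the original venc (e.g. 0.5).
#' @return A \code{wrap_spec} with \code{venc_sim}, \code{venc}, and the
#'   implied \code{fraction}.
#' @examples
#' # venc 1.5 m/s reduced to 0.62 m/s is a 41% fraction
#' round(100 * wrap_spec(venc_sim = 62, venc = 150)$fraction)
#' @export
wrap_spec <- function(venc_sim = NULL, venc, venc_fraction = NULL) {
  if (is.null(venc_sim)) {
    if (is.null(venc_fraction)) stop("give `venc_sim` or `venc_fraction`")
    venc_sim <- venc * venc_fraction
  }
  if (!(venc_sim > 0) || !(venc > 0))
    stop("vencs must be positive")
  if (venc_sim >= venc)
    stop("`venc_sim` must be smaller than the original venc (nothing can wrap)")
  structure(list(venc_sim = as.numeric(venc_sim), venc = as.numeric(venc),
                 fraction = as.numeric(venc_sim / venc)),
            class = "wrap_spec")
}

#' Draw random training venc fractions
#'
#' Uniform on \code{[0.40, 0.70]} (the training augmentation range) using
#' the session RNG; seed with \code{set.seed()} upstream for reproducible
#' draws.
#'
#' @param n number of draws.
#' @param range lower and upper fraction bounds.
#' @return Numeric vector of fractions.
#' @export
sample_venc_fraction <- function(n, range = c(0.40, 0.70)) {
  stopifnot(length(range) == 2L, range[1] > 0, range[2] < 1,
            range[1] <= range[2])
  runif(n, range[1], range[2])
}

# Symmetric modular wrap of a numeric array into [-v, v). Returns the
# wrapped values and the integer wrap counts. Single shifts (|count| == 1)
# are exact in floating point (Sterbenz: v <= |V| <= 4v implies fl(V -+ 2v)
# is exact), which is what makes the mask-driven round trip bit-exact in the
# single-wrap regime.
wrap_mod <- function(x, v) {
  two_v <- 2 * v
  k <- floor((x + v) / two_v)
  out <- x - two_v * k
  # guard against boundary rounding in the division
  bad <- out < -v
  while (any(bad)) { out[bad] <- out[bad] + two_v; k[bad] <- k[bad] - 1; bad <- out < -v }
  bad <- out >= v
  while (any(bad)) { out[bad] <- out[bad] - two_v; k[bad] <- k[bad] + 1; bad <- out >= v }
  list(values = out, count = k)
}

#' Simulate venc-induced velocity wrapping
#'
#' Applies the symmetric modular wrap
#' \code{V_A = ((V_T + v) mod 2v) - v} with \code{v = venc_sim} to the whole
#' field, across all frames and velocity directions. For
#' \code{venc_sim < V_T < 3 venc_sim} this reduces to the single-wrap rule
#' \code{V_A = V_T - 2 venc_sim} (and its mirror for negative velocities).
#' The representable interval is half-open: a velocity exactly at
#' \code{+venc_sim} wraps to \code{-venc_sim}.
#'
#' @param field a [velocity_field()] with the true (non-aliased) velocities.
#' @param spec a [wrap_spec()]; its original venc must match the field's.
#' @return A list with \code{aliased} (a [velocity_field()] carrying
#'   \code{venc = venc_sim}) and \code{truth}, the logical ground-truth mask
#'   of voxels whose wrapped value differs from the true value.
#' @examples
#' f <- velocity_field(array(100, c(1, 1, 1, 2, 3)), venc = 150,
#'                     voxel_spacing = c(1, 1, 1), frame_interval = 40)
#' w <- wrap_velocity(f, wrap_spec(venc_sim = 60, venc = 150))
#' w$aliased$values[1]   # 100 - 120 = -20 cm/s
#' @export
wrap_velocity <- function(field, spec) {
  stopifnot(is_velocity_field(field), inherits(spec, "wrap_spec"))
  if (spec$venc_sim >= field$venc)
    stop("`venc_sim` must be smaller than the field's venc (nothing can wrap)")
  m <- wrap_mod(field$values, spec$venc_sim)
  aliased <- velocity_field(m$values, spec$venc_sim, field$voxel_spacing,
                            field$frame_interval)
  truth <- m$values != field$values
  dim(truth) <- dim(field$values)
  list(aliased = aliased, truth = truth)
}

#' Correct aliased voxels given a detection mask
#'
#' Single-wrap correction: each masked voxel is shifted by
#' \code{-sign(V_A) * 2 * venc} (an aliased value that is negative is shifted
#' up, and vice versa). A masked voxel with value exactly 0 is corrected
#' upward and counted in the returned attribute
#' \code{"n_zero_corrected_up"}. Unmasked voxels pass through unchanged.
#'
#' @param aliased a [velocity_field()] (typically from [wrap_velocity()] or a
#'   low-venc scan).
#' @param mask logical/binary array congruent with the field, marking the
#'   voxels to correct.
#' @param venc the wrap venc, cm/s; defaults to the aliased field's venc.
#' @return The corrected [velocity_field()] (venc metadata unchanged).
#' @export
unwrap_with_mask <- function(aliased, mask, venc = aliased$venc) {
  stopifnot(is_velocity_field(aliased))
  check_congruent(aliased, mask, "mask")
  vals <- aliased$values
  m <- as.logical(mask); dim(m) <- dim(vals)
  shift <- ifelse(vals > 0, -2 * venc, 2 * venc)
  n_zero <- sum(m & vals == 0)
  vals[m] <- vals[m] + shift[m]
  out <- velocity_field(vals, aliased$venc, aliased$voxel_spacing,
                        aliased$frame_interval)
  attr(out, "n_zero_corrected_up") <- n_zero
  out
}
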