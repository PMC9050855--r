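#' Parameters for the conventional phase-jump algorithm
#'
#' @param jump_threshold_factor jumps larger than
#'   \code{factor * venc} between nearest neighbors are flagged; the
#'   standard criterion is jumps greater than the venc itself (factor 1).
#' @param max_iterations maximum number of temporal+spatial sweeps per
#'   slice/direction sub-array.
#' @return A \code{jump_params} list.
#' @export
jump_params <- function(jump_threshold_factor = 1.0, max_iterations = 10L) {
  if (!(jump_threshold_factor > 0 && jump_threshold_factor <= 2))
    stop("`jump_threshold_factor` must lie in (0, 2]")
  if (max_iterations < 1) stop("`max_iterations` must be >= 1")
  structure(list(jump_threshold_factor = jump_threshold_factor,
                 max_iterations = as.integer(max_iterations)),
            class = "jump_params")
}

#' Conventional spatio-temporal velocity anti-aliasing
#'
#' The automatic baseline: for every slice z and velocity direction
#' independently, the \code{[X, Y, time]} sub-array is scanned with
#' nearest-neighbor difference arrays along time, x, and y. Voxel pairs
#' whose difference exceeds the threshold localize a velocity jump; the
#' later voxel of the pair (relative to the trusted reference: the first
#' cardiac frame for the temporal pass, the field border for the spatial
#' passes) is corrected by \code{-sign(V) * 2 * venc}, but only when the
#' jump sign is consistent with that correction — inconsistent (tied)
#' voxels are left unchanged. Passes are repeated, temporal first, until
#' the sweep reaches a fixed point (individual passes may shift a
#' wall-gradient voxel back and forth within a sweep; the sweep-end state
#' is what must be stationary) or \code{max_iterations} is reached.
#'
#' Corrections are applied as integer multiples of \code{2 * venc} on top
#' of the original aliased values, so a single net shift is exact in
#' floating point and a do/undo cycle leaves a voxel bit-identical.
#'
#' Because the correction direction is read off the sign of the aliased
#' value, the method is exact only where \code{|V_T| < 2 * venc}; voxels
#' wrapped beyond that (aliased values that land back on the true sign)
#' present no sign-consistent jump and are missed — and each miss leaves a
#' stale temporal reference that degrades later frames. This is the
#' characteristic severe-aliasing failure of this algorithm family.
#'
#' @param aliased a [velocity_field()] with at least 2 frames.
#' @param params a [jump_params()].
#' @return A list with \code{corrected} (a [velocity_field()]),
#'   \code{detected} (logical mask of voxels the algorithm shifted),
#'   \code{converged} (logical), and \code{iterations} (per slice/direction
#'   maximum sweep count).
#' @export
conventional_unwrap <- function(aliased, params = jump_params()) {
  stopifnot(is_velocity_field(aliased))
  dims <- dim(aliased$values)
  if (dims[4] < 2L)
    stop("temporal differences are undefined for a single-frame field")
  v <- aliased$venc
  thr <- params$jump_threshold_factor * v
  vals <- aliased$values
  shifts <- array(0L, dims)
  converged <- TRUE
  max_sweeps <- 0L

  for (d in 1:3) for (z in seq_len(dims[3])) {
    A0 <- vals[, , z, , d, drop = FALSE]
    dim(A0) <- dims[c(1, 2, 4)]
    res <- unwrap_xy_t(A0, v, thr, params$max_iterations)
    vals[, , z, , d] <- res$A
    shifts[, , z, , d] <- res$S
    converged <- converged && res$converged
    max_sweeps <- max(max_sweeps, res$sweeps)
  }
  if (!converged)
    warning("conventional unwrap did not converge within max_iterations; ",
            "returning the last iterate")
  corrected <- velocity_field(vals, aliased$venc, aliased$voxel_spacing,
                              aliased$frame_interval)
  list(corrected = corrected, detected = shifts != 0L,
       converged = converged, iterations = max_sweeps)
}

# One [X, Y, time] sub-array. `A0` holds the original values; the working
# state is A = A0 + S * 2v with S the integer net shift count, recomputed
# (not accumulated) so single net shifts stay exact. Sequential passes:
# each comparison trusts the already-processed side (earlier frame /
# smaller index toward the border).
unwrap_xy_t <- function(A0, v, thr, max_iterations) {
  dims <- dim(A0); nx <- dims[1]; ny <- dims[2]; nt <- dims[3]
  two_v <- 2 * v
  A <- A0
  S <- array(0L, dims)
  sweeps <- 0L; converged <- FALSE
  S_prev <- NULL
  for (iter in seq_len(max_iterations)) {
    sweeps <- iter
    changed <- FALSE
    # temporal pass, frame 1 trusted
    for (t in 2:nt) {
      for (rep in 1:4) {
        D <- A[, , t] - A[, , t - 1]
        up <- D < -thr & A[, , t] < 0    # wrapped down; shift up
        dn <- D > thr & A[, , t] > 0     # wrapped up; shift down
        if (!any(up) && !any(dn)) break
        sc <- S[, , t]
        sc[up] <- sc[up] + 1L; sc[dn] <- sc[dn] - 1L
        S[, , t] <- sc
        A[, , t] <- A0[, , t] + sc * two_v
        changed <- TRUE
      }
    }
    # spatial passes, borders trusted
    for (x in 2:nx) {
      for (rep in 1:4) {
        sl <- A[x, , , drop = TRUE]
        D <- sl - A[x - 1, , , drop = TRUE]
        up <- D < -thr & sl < 0
        dn <- D > thr & sl > 0
        if (!any(up) && !any(dn)) break
        sc <- S[x, , ]
        sc[up] <- sc[up] + 1L; sc[dn] <- sc[dn] - 1L
        S[x, , ] <- sc
        A[x, , ] <- A0[x, , ] + sc * two_v
        changed <- TRUE
      }
    }
    for (y in 2:ny) {
      for (rep in 1:4) {
        sl <- A[, y, , drop = TRUE]
        D <- sl - A[, y - 1, , drop = TRUE]
        up <- D < -thr & sl < 0
        dn <- D > thr & sl > 0
        if (!any(up) && !any(dn)) break
        sc <- S[, y, ]
        sc[up] <- sc[up] + 1L; sc[dn] <- sc[dn] - 1L
        S[, y, ] <- sc
        A[, y, ] <- A0[, y, ] + sc * two_v
        changed <- TRUE
      }
    }
    if (!changed) { converged <- TRUE; break }
    # a sweep may shift a wall-gradient voxel back and forth yet return to
    # the same state; a stationary sweep map is convergence
    if (!is.null(S_prev) && identical(S, S_prev)) { converged <- TRUE; break }
    S_prev <- S
  }
  list(A = A, S = S, converged = converged, sweeps = sweeps)
}
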