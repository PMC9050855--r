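# Shared fixture builders: every test input is generated in code.

# Standard desk-scale phantom: U-bend vessel, venc 150 cm/s with peak
# velocity at the venc, SNR 15 unless noise-free is requested.
desk_phantom <- function(seed = 1L, snr = 15, n_frames = 10,
                         grid = c(64, 48, 16), vessel = vessel_ubend(),
                         peak = 150, venc = 150) {
  generate_phantom(phantom_spec(
    grid_shape = grid, voxel_spacing = c(2.4, 2.4, 2.6),
    n_frames = n_frames, frame_interval = 80, vessel = vessel,
    peak_velocity = peak, venc = venc, snr = snr, seed = seed))
}

# Small straight-tube phantom with a voxel center exactly on the tube axis
# (odd in-plane grid), for analytic checks.
tube_phantom <- function(seed = 1L, snr = Inf, grid = c(33, 33, 10),
                         spacing = c(1.5, 1.5, 2), radius = 15,
                         n_frames = 6, peak = 150, venc = 150) {
  generate_phantom(phantom_spec(
    grid_shape = grid, voxel_spacing = spacing, n_frames = n_frames,
    frame_interval = 100, vessel = vessel_straight(radius_mm = radius),
    peak_velocity = peak, venc = venc, snr = snr, seed = seed))
}

# Tiny field wrapper for toy value arrays.
toy_field <- function(values, venc = 150, spacing = c(1, 1, 1),
                      frame_interval = 40) {
  velocity_field(values, venc, spacing, frame_interval)
}

# Random sparse toy masks on a small grid (for metric oracles).
random_mask <- function(dims, p = 0.1) {
  array(runif(prod(dims)) < p, dims)
}

# Expand a static 3-D mask along the frame/direction axes.
broadcast_5d <- function(vessel, dims5) {
  array(rep(as.logical(vessel), times = prod(dims5[4:5])), dims5)
}

# R-side brute-force Hausdorff oracle via the dense distance matrix.
brute_hausdorff <- function(xm, ym, spacing) {
  xi <- which(xm); yi <- which(ym)
  d3 <- dim(xm)
  coords <- function(idx) {
    idx0 <- idx - 1L
    cbind((idx0 %% d3[1]) * spacing[1],
          ((idx0 %/% d3[1]) %% d3[2]) * spacing[2],
          (idx0 %/% (d3[1] * d3[2])) * spacing[3])
  }
  P <- coords(xi); Q <- coords(yi)
  D2 <- outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q)
  D <- sqrt(pmax(D2, 0))
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}
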