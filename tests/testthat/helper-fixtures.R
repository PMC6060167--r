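# Shared fixtures, all built in code.

# A fast small phantom for unit tests (16 x 16 x 24 voxels at 2 mm).
small_phantom <- function(...) {
  build_phantom(phantom_config(grid_shape = c(16L, 16L, 24L),
                               tract_radius = 4, tract_curve_amp = 1.5,
                               brainstem_halfwidth = 9,
                               brainstem_z_extent = 16, ...))
}

# Assemble a symmetric 3x3 matrix from 6 components (Dxx Dxy Dxz Dyy Dyz Dzz).
tensor_matrix <- function(cmp) {
  matrix(c(cmp[1], cmp[2], cmp[3],
           cmp[2], cmp[4], cmp[5],
           cmp[3], cmp[5], cmp[6]), 3, 3)
}

# Noiseless monoexponential signals for one tensor over a gradient table.
model_signal <- function(D, gt, s0 = 1000) {
  s0 * exp(-gt$bvals * colSums(gt$bvecs * (D %*% gt$bvecs)))
}

# 4D array holding the same signal vector in every voxel of a small grid.
uniform_data4d <- function(signal, dims = c(4L, 4L, 4L)) {
  array(rep(signal, each = prod(dims)), dim = c(dims, length(signal)))
}

# Independent closed-form FA used as the oracle against package output.
fa_reference <- function(l) {
  md <- mean(l)
  sqrt(3 / 2) * sqrt(sum((l - md)^2)) / sqrt(sum(l^2))
}

# Random SPD tensors in a physiological diffusivity range, n x 6.
random_spd_tensors <- function(n) {
  t(vapply(seq_len(n), function(i) {
    A <- matrix(stats::rnorm(9), 3, 3)
    D <- crossprod(A)
    D <- D / max(diag(D)) * stats::runif(1, 0.5e-3, 3e-3)
    c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
  }, numeric(6)))
}
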