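test_that("phantom ground truth matches closed-form FA and partitions the grid", {
  ph <- small_phantom()
  # FA of the default tract eigenvalues, evaluated independently
  expect_equal(unique(ph$fa_truth[ph$masks$tract]),
               fa_reference(c(1.7e-3, 0.3e-3, 0.2e-3)), tolerance = 1e-12)
  expect_true(fa_reference(c(1.7e-3, 0.3e-3, 0.2e-3)) >= 0.4)
  # isotropic background: equal eigenvalues, FA exactly 0
  expect_equal(unique(ph$fa_truth[ph$masks$background]), 0)
  # labels partition the grid
  counts <- vapply(ph$label_levels, function(l) sum(ph$labels == l), numeric(1))
  expect_equal(sum(counts), prod(ph$dims))
  # all tensors symmetric positive-definite in brain (check a sample)
  idx <- which(ph$masks$brain)[seq(1, sum(ph$masks$brain), length.out = 50)]
  tn <- matrix(ph$tensors, ncol = 6)
  for (i in idx)
    expect_true(min(eigen(tensor_matrix(tn[i, ]), symmetric = TRUE,
                          only.values = TRUE)$values) > 0)
})

test_that("tract is a connected tube from the pulsatile brainstem to the top face", {
  ph <- small_phantom()
  expect_true(any(ph$masks$tract & ph$pulsatile_zones$brainstem))
  # present on every axial slice, including the superior face
  per_slice <- apply(ph$masks$tract, 3, sum)
  expect_true(all(per_slice > 0))
  # inferior part lies inside the brainstem zone
  expect_true(all((ph$masks$tract & ph$pulsatile_zones$brainstem)[, , 1] ==
                    ph$masks$tract[, , 1]))
})

test_that("invalid phantom configurations are rejected", {
  expect_error(build_phantom(phantom_config(tract_radius = 0)), "radius")
  expect_error(build_phantom(phantom_config(tract_radius = -2)), "radius")
  expect_error(build_phantom(phantom_config(grid_shape = c(10, 10, 20),
                                            tract_radius = 12)),
               "does not fit")
})

test_that("gated noiseless signals equal the tensor model exactly", {
  ph <- small_phantom()
  gt <- default_gradient_table()
  st <- simulate_acquisition(ph, pulsatile_model(),
                             acquisition_protocol(gt, 2, "cardiac_gated", 0, 3))
  # b=0 volume equals s0 exactly
  expect_identical(st$repetitions[[1]][, , , 1], ph$s0)
  # spot-check the monoexponential model at a few voxels
  tn <- matrix(ph$tensors, ncol = 6)
  for (i in c(which(ph$masks$tract)[1], which(ph$masks$CSF)[1],
              which(ph$masks$background)[1])) {
    D <- tensor_matrix(tn[i, ])
    expected <- ph$s0[i] * exp(-gt$bvals * colSums(gt$bvecs * (D %*% gt$bvecs)))
    got <- vapply(seq_len(gt$n_volumes), function(v)
      st$repetitions[[1]][, , , v][i], numeric(1))
    expect_equal(got, expected, tolerance = 1e-14)
  }
  # both repetitions identical (no artefact, no noise)
  expect_identical(st$repetitions[[1]], st$repetitions[[2]])
})

test_that("zero-strength artefact reproduces the gated data bit for bit", {
  ph <- small_phantom()
  gt <- default_gradient_table()
  pm0 <- pulsatile_model(kappa = 0)
  ng <- simulate_acquisition(ph, pm0, acquisition_protocol(gt, 3, "non_gated",
                                                           20, 11))
  g <- simulate_acquisition(ph, pm0, acquisition_protocol(gt, 3, "cardiac_gated",
                                                          20, 11))
  expect_identical(ng$repetitions, g$repetitions)
})

test_that("attenuation is direction-dependent and only reduces signal", {
  ph <- small_phantom()
  m <- c(0, 0, 1)
  # one direction parallel to the motion, one orthogonal
  gt <- gradient_table(c(0, 1000, 1000),
                       cbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0)))
  pm <- pulsatile_model(motion_direction = m, systole_fraction = 0.999)
  ng <- simulate_acquisition(ph, pm, acquisition_protocol(gt, 2, "non_gated", 0, 5))
  g <- simulate_acquisition(ph, pm, acquisition_protocol(gt, 2, "cardiac_gated", 0, 5))
  pz <- ph$pulsatile_zones$brainstem
  # parallel volume attenuated, orthogonal volume untouched (|g.m| = 0)
  expect_true(mean(ng$repetitions[[1]][, , , 2][pz]) <
                mean(g$repetitions[[1]][, , , 2][pz]))
  expect_equal(ng$repetitions[[1]][, , , 3], g$repetitions[[1]][, , , 3])
  # attenuation never increases any voxel's signal
  expect_true(all(ng$repetitions[[1]] <= g$repetitions[[1]] + 1e-12))
  # the factor itself: exp(-kappa * v * |g.m|) on brainstem voxels
  fac <- mean(ng$repetitions[[1]][, , , 2][pz] / g$repetitions[[1]][, , , 2][pz])
  expect_equal(fac, exp(-0.3 * 1.5 * 1), tolerance = 1e-12)
})

test_that("non-unit gradient tables are rejected at simulation", {
  ph <- small_phantom()
  gt <- gradient_table(c(0, 1000), cbind(c(0, 0, 0), c(0, 0, 1)))
  gt$bvecs[, 2] <- c(0, 0, 2)       # corrupt after construction
  expect_error(simulate_acquisition(ph, pulsatile_model(),
                                    acquisition_protocol(gt, 2, "non_gated", 0, 1)),
               "unit-norm")
})

test_that("simulation is reproducible and signals stay non-negative", {
  ph <- small_phantom()
  gt <- default_gradient_table()
  pm <- pulsatile_model()
  a <- simulate_acquisition(ph, pm, acquisition_protocol(gt, 2, "non_gated", 30, 9))
  b <- simulate_acquisition(ph, pm, acquisition_protocol(gt, 2, "non_gated", 30, 9))
  expect_identical(a$repetitions, b$repetitions)
  expect_true(all(a$repetitions[[1]] >= 0))
})

test_that("Rician noise has the Rayleigh mean at zero signal", {
  expect_identical(add_rician_noise(array(5, c(2, 2)), 0),
                   array(5, c(2, 2)))
  expect_error(add_rician_noise(1, -1), "non-negative")
  set.seed(42)
  draws <- add_rician_noise(numeric(1e6), 10)
  expect_true(all(draws >= 0))
  # E|N(0,sigma) + i N(0,sigma)| = sigma sqrt(pi/2)
  expect_equal(mean(draws), 10 * sqrt(pi / 2), tolerance = 0.01)
})

test_that("model and protocol constructors validate their invariants", {
  expect_error(pulsatile_model(systole_fraction = 0), "between 0 and 1")
  expect_error(pulsatile_model(motion_direction = c(0, 0, 0)), "nonzero")
  expect_error(pulsatile_model(kappa = -1), "non-negative")
  expect_error(acquisition_protocol(n_repetitions = 0), ">= 1")
  expect_error(acquisition_protocol(noise_sigma = -5), "non-negative")
  pm <- pulsatile_model(motion_direction = c(0, -0.45, -0.89))
  expect_equal(sum(pm$motion_direction^2), 1)
})
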