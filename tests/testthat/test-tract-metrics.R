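test_that("Jaccard distance matches set enumeration", {
  dims <- c(4, 4, 4)
  m <- array(FALSE, dims); m[1:10] <- TRUE
  expect_equal(jaccard_distance(replicate(5, m, simplify = FALSE)), 0)
  m2 <- array(FALSE, dims); m2[11:20] <- TRUE
  expect_equal(jaccard_distance(list(m, m2)), 1)
  # A = {a, b}, B = {b, c} -> 1 - 1/3
  a <- array(FALSE, dims); a[c(1, 2)] <- TRUE
  b <- array(FALSE, dims); b[c(2, 3)] <- TRUE
  expect_equal(jaccard_distance(list(a, b)), 1 - 1 / 3)
  expect_error(jaccard_distance(list(array(FALSE, dims), array(FALSE, dims))),
               "empty")
  expect_error(jaccard_distance(list(a, array(TRUE, c(2, 2, 2)))), "mismatch")
  expect_error(jaccard_distance(list(a)), "at least 2")
})

test_that("Jaccard distance is bounded, order-invariant and monotone", {
  set.seed(11)
  for (case in 1:30) {
    n <- sample(2:6, 1)
    masks <- replicate(n, array(stats::runif(64) < 0.4, c(4, 4, 4)),
                       simplify = FALSE)
    if (!any(Reduce(`|`, masks))) next
    jd <- jaccard_distance(masks)
    expect_gte(jd, 0); expect_lte(jd, 1)
    expect_equal(jaccard_distance(sample(masks)), jd)
    if (n > 2) {
      # dropping a mask can only decrease (or keep) the distance
      expect_gte(jd, jaccard_distance(masks[-1]))
    }
  }
})

test_that("tract subdivision intersects and accounts for every voxel", {
  dims <- c(4, 4, 12)
  zmask <- function(zs) { m <- array(FALSE, dims); m[, , zs] <- TRUE; m }
  regions <- list(BS = zmask(1:4), PLIC = zmask(5:8), SC = zmask(10:12))
  tmask <- array(FALSE, dims)
  tmask[2, 2, ] <- TRUE                 # 12 voxels, one per slice
  tr <- tract_object(tmask, 2)
  parts <- subdivide_tract(tr, regions)
  expect_equal(sum(parts$BS$mask), 4L)
  expect_equal(sum(parts$PLIC$mask), 4L)
  expect_equal(sum(parts$SC$mask), 3L)
  expect_equal(attr(parts, "n_outside"), 1L)   # slice 9 in no region
  expect_lte(sum(vapply(parts, function(p) p$volume_cm3, numeric(1))),
             tr$volume_cm3)

  inside <- tract_object(zmask(2) & tmask, 2)
  p2 <- subdivide_tract(inside, regions)
  expect_equal(p2$BS$mask, inside$mask)
  expect_equal(sum(p2$PLIC$mask) + sum(p2$SC$mask), 0L)

  overlapping <- list(A = zmask(1:5), B = zmask(5:8))
  expect_error(subdivide_tract(tr, overlapping), "overlap")
})

test_that("slab profiles tile 105 mm and average within slabs", {
  dims <- c(6L, 6L, 60L)
  h <- 2
  tmask <- array(FALSE, dims); tmask[3:4, 3:4, ] <- TRUE
  const <- array(0.5, dims)
  prof <- slab_profile(list(FA = const), tmask, h)
  expect_equal(nrow(prof), 21L)
  expect_equal(prof$z_max_mm - prof$z_min_mm, rep(5, 21))
  expect_equal(prof$z_max_mm[21] - prof$z_min_mm[1], 105)
  expect_equal(prof$section[c(1, 5, 6, 10, 11, 13, 14, 18, 19, 21)],
               c("BS", "BS", "PLIC", "PLIC", "CC", "CC",
                 "cingulum", "cingulum", "motor_cortex", "motor_cortex"))
  nz <- prof$n_voxels > 0
  expect_true(all(prof$mean_FA[nz] == 0.5))

  # a linear-in-z ramp gives strictly increasing slab means
  ramp <- array(rep(seq_len(dims[3]), each = 36), dim = dims)
  pr <- slab_profile(list(FA = ramp), tmask, h)
  expect_true(all(diff(pr$mean_FA[pr$n_voxels > 0]) > 0))

  # empty slabs report n_voxels = 0 and undefined means
  short <- array(FALSE, dims); short[3, 3, 1:5] <- TRUE
  ps <- slab_profile(list(FA = const), short, h)
  expect_true(all(ps$n_voxels[ps$slab_index > 2] == 0))
  expect_true(all(is.na(ps$mean_FA[ps$n_voxels == 0])))

  expect_error(slab_profile(list(FA = const), tmask, h,
                            slab_thickness_mm = 0), "positive")
  expect_error(slab_profile(list(FA = const), array(FALSE, dims), h), "empty")
})

test_that("eigenvector z-angle map folds antipodally to [0, 90]", {
  v1 <- array(0, c(2, 2, 1, 3))
  v1[1, 1, 1, ] <- c(0, 0, 1)
  v1[2, 1, 1, ] <- c(0, 0, -1)
  v1[1, 2, 1, ] <- c(1, 0, 0)
  v1[2, 2, 1, ] <- c(0.6, 0, 0.8)
  ang <- v1_z_angle_map(v1)
  expect_equal(ang[1, 1, 1], 0)
  expect_equal(ang[2, 1, 1], 0)              # antipodal symmetry
  expect_equal(ang[1, 2, 1], 90)
  expect_equal(ang[2, 2, 1], acos(0.8) * 180 / pi, tolerance = 1e-10)

  v1[1, 1, 1, ] <- 0                          # zero vector: masked, counted
  ang2 <- v1_z_angle_map(v1)
  expect_true(is.na(ang2[1, 1, 1]))
  expect_equal(attr(ang2, "n_zero"), 1L)
})

test_that("paired comparison matches the closed-form t-test", {
  x <- c(2, 4, 6); y <- c(1, 2, 3)       # differences 1, 2, 3
  res <- paired_compare(x, y)
  d <- x - y
  t_ref <- mean(d) / (stats::sd(d) / sqrt(3))        # = sqrt(12) = 3.464
  p_ref <- 2 * stats::pt(-abs(t_ref), df = 2)
  expect_equal(res$t, t_ref, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$p, p_ref, tolerance = 1e-12)
  expect_equal(round(res$p, 4), 0.0742)
  expect_false(res$significant)

  swap <- paired_compare(y, x)
  expect_equal(swap$t, -res$t)
  expect_equal(swap$p, res$p)

  same <- paired_compare(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_true(is.na(same$p))
  expect_error(paired_compare(1:3, 1:2), "equal length")
  expect_error(paired_compare(1, 1), "at least 2")
})
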