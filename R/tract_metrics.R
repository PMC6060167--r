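#' Generalized Jaccard distance of repeated segmentations
#'
#' The Jaccard coefficient of a collection of masks is the size of their
#' common intersection divided by the size of their union; the Jaccard
#' distance JD = 1 - JC measures the dissimilarity (here: run-to-run
#' variability) of repeated tract reconstructions. With five repetitions
#' this is the five-sample generalization of the usual pairwise measure.
#'
#' @param masks list of >= 2 logical arrays on identical grids (or
#'   `tract_object`s, whose masks are used).
#' @return JD in \[0, 1\]. An empty union is undefined and rejected.
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE), 3)
#' b <- array(c(FALSE, TRUE, TRUE), 3)
#' jaccard_distance(list(a, b)) # 1 - 1/3
#' @export
jaccard_distance <- function(masks) {
  if (!is.list(masks) || length(masks) < 2L) stop("need at least 2 masks")
  masks <- lapply(masks, function(m) if (inherits(m, "tract_object")) m$mask else m)
  d <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), d)) stop("mask grid mismatch")
  uni <- Reduce(`|`, masks)
  if (!any(uni)) stop("union of masks is empty; Jaccard distance undefined")
  int <- Reduce(`&`, masks)
  1 - sum(int) / sum(uni)
}

#' Subdivide a tract into anatomical regions
#'
#' Intersects the tract mask with each (mutually disjoint) region mask,
#' e.g. brainstem / posterior limb of the internal capsule / subcortex.
#' Tract voxels falling outside every region are counted, not dropped
#' silently.
#'
#' @param tract a [tract_object()].
#' @param region_masks named list of disjoint logical masks.
#' @return Named list of `tract_object`s (one per region) with an attribute
#'   `n_outside`, the tract voxels not covered by any region.
#' @export
subdivide_tract <- function(tract, region_masks) {
  stopifnot(inherits(tract, "tract_object"))
  nm <- names(region_masks)
  if (is.null(nm) || any(!nzchar(nm))) stop("region masks must be named")
  for (m in region_masks)
    if (!identical(dim(m), dim(tract$mask))) stop("region grid mismatch")
  if (length(region_masks) > 1L) {
    cover <- Reduce(`+`, lapply(region_masks, function(m) m * 1L))
    if (any(cover > 1L)) stop("region masks overlap")
  }
  parts <- lapply(nm, function(r)
    tract_object(tract$mask & region_masks[[r]], tract$voxel_size,
                 gating = tract$gating, repetition = tract$repetition))
  names(parts) <- nm
  any_region <- Reduce(`|`, region_masks)
  attr(parts, "n_outside") <- sum(tract$mask & !any_region)
  parts
}

slab_sections <- function(n_slabs) {
  sec <- rep(NA_character_, n_slabs)
  assign_rng <- function(lo, hi, lab) {
    i <- intersect(lo:hi, seq_len(n_slabs))
    sec[i] <<- lab
  }
  assign_rng(1, 5, "BS")
  assign_rng(6, 10, "PLIC")
  assign_rng(11, 13, "CC")
  assign_rng(14, 18, "cingulum")
  assign_rng(19, 21, "motor_cortex")
  sec
}

#' Along-tract slab profile
#'
#' Cuts the tract into `n_slabs` consecutive slabs of `slab_thickness_mm`
#' along z, starting at the inferior-most tract voxel, and averages each
#' scalar map over the tract voxels of each slab. With the default 21 slabs
#' of 5 mm the profile spans 105 mm and the slabs carry the conventional
#' section labels: brainstem (1-5), posterior limb of the internal capsule
#' (6-10), corpus callosum level (11-13), cingulum level (14-18), motor
#' cortex (19-21).
#'
#' @param scalar_maps named list of 3D arrays (e.g. FA, MD, angle) on the
#'   tract grid.
#' @param tract_mask logical 3D array, non-empty.
#' @param voxel_size voxel edge, mm.
#' @param slab_thickness_mm slab thickness (default 5).
#' @param n_slabs number of slabs (default 21).
#' @return data.frame with `slab_index`, `z_min_mm`, `z_max_mm`, `section`,
#'   one `mean_<name>` column per map (NA for empty slabs) and `n_voxels`.
#' @export
slab_profile <- function(scalar_maps, tract_mask, voxel_size,
                         slab_thickness_mm = 5, n_slabs = 21) {
  if (slab_thickness_mm <= 0) stop("slab thickness must be positive")
  if (!any(tract_mask)) stop("empty tract mask")
  if (is.null(names(scalar_maps))) stop("scalar_maps must be named")
  dims <- dim(tract_mask)
  for (m in scalar_maps)
    if (!identical(dim(m)[1:3], dims)) stop("map grid mismatch")

  kz <- which(apply(tract_mask, 3, any))
  z0 <- (min(kz) - 1) * voxel_size            # inferior face of lowest slab
  idx <- which(tract_mask, arr.ind = TRUE)
  zc <- (idx[, 3] - 0.5) * voxel_size
  slab <- floor((zc - z0) / slab_thickness_mm) + 1
  lin <- idx[, 1] + (idx[, 2] - 1) * dims[1] + (idx[, 3] - 1) * dims[1] * dims[2]

  out <- data.frame(slab_index = seq_len(n_slabs),
                    z_min_mm = z0 + (seq_len(n_slabs) - 1) * slab_thickness_mm,
                    z_max_mm = z0 + seq_len(n_slabs) * slab_thickness_mm,
                    section = slab_sections(n_slabs),
                    stringsAsFactors = FALSE)
  for (nm in names(scalar_maps)) out[[paste0("mean_", nm)]] <- NA_real_
  out$n_voxels <- 0L
  for (s in seq_len(n_slabs)) {
    sel <- lin[slab == s]
    out$n_voxels[s] <- length(sel)
    if (length(sel))
      for (nm in names(scalar_maps))
        out[[paste0("mean_", nm)]][s] <- mean(scalar_maps[[nm]][sel], na.rm = TRUE)
  }
  out
}

#' Angle of the principal eigenvector to the z-axis
#'
#' The axial angle arccos(|V1 . z|) in degrees, folded to \[0, 90\] because
#' eigenvectors are sign-ambiguous: (0,0,1) and (0,0,-1) both map to 0.
#' Zero vectors are masked out (NA) and counted in the `n_zero` attribute.
#'
#' @param v1 4D array (x, y, z, 3) of per-voxel eigenvectors, or a
#'   [dti_eigen()] object.
#' @return 3D array of angles in degrees.
#' @export
v1_z_angle_map <- function(v1) {
  if (inherits(v1, "dti_eigen")) v1 <- v1_map(v1)
  d4 <- dim(v1)
  if (length(d4) != 4L || d4[4] != 3L) stop("v1 must be an (x,y,z,3) array")
  nvox <- prod(d4[1:3])
  vz <- v1[seq_len(nvox) + 2L * nvox]
  nrm <- sqrt(v1[seq_len(nvox)]^2 + v1[seq_len(nvox) + nvox]^2 + vz^2)
  ang <- acos(pmin(1, abs(vz) / ifelse(nrm > 0, nrm, NA_real_))) * 180 / pi
  n_zero <- sum(nrm == 0, na.rm = TRUE)
  out <- array(ang, dim = d4[1:3])
  attr(out, "n_zero") <- n_zero
  out
}

#' Paired comparison of two matched samples
#'
#' Two-sided paired t-test at significance level `alpha`. A zero-variance
#' difference vector is degenerate (no p-value is produced).
#'
#' @param values_nongated,values_gated equal-length paired numeric vectors
#'   (n >= 2). Pairs with a missing value in either member are dropped.
#' @param alpha significance level (default 0.05).
#' @return List with `t`, `df`, `p`, `mean_diff`, `n`, `significant`,
#'   `degenerate`.
#' @export
paired_compare <- function(values_nongated, values_gated, alpha = 0.05) {
  if (length(values_nongated) != length(values_gated))
    stop("paired samples must have equal length")
  ok <- is.finite(values_nongated) & is.finite(values_gated)
  x <- values_nongated[ok]; y <- values_gated[ok]
  if (length(x) < 2L) stop("need at least 2 complete pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                mean_diff = mean(d), n = length(d), significant = FALSE,
                degenerate = TRUE))
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), n = length(d),
       significant = tt$p.value < alpha, degenerate = FALSE)
}
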