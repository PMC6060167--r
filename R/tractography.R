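#' Tracking parameters
#'
#' @param step_size Euler integration step, mm (default 1).
#' @param fa_threshold stop tracking when interpolated FA falls below this.
#' @param max_turn_angle stop when the direction turns by more than this per
#'   step, degrees.
#' @param seed_fa minimum FA for a voxel to seed a streamline.
#' @param max_steps cap on steps per direction (safety; generous default).
#' @return Named list of parameters.
#' @export
track_params <- function(step_size = 1, fa_threshold = 0.15,
                         max_turn_angle = 35, seed_fa = 0.25,
                         max_steps = 600L) {
  if (step_size <= 0) stop("step_size must be positive")
  if (max_turn_angle <= 0 || max_turn_angle > 180)
    stop("max_turn_angle must be in (0, 180]")
  list(step_size = step_size, fa_threshold = fa_threshold,
       max_turn_angle = max_turn_angle, seed_fa = seed_fa,
       max_steps = as.integer(max_steps))
}

# Full-grid tensor component array (x,y,z,6) from a dti_fit; zeros outside
# the fitted mask so interpolation decays smoothly to isotropic-zero there.
tensor_component_array <- function(fit) {
  arr <- array(0, dim = c(fit$dims, 6L))
  nvox <- prod(fit$dims)
  midx <- which(fit$mask)
  for (k in 1:6) arr[midx + (k - 1L) * nvox] <- fit$tensors[, k]
  arr
}

# Trilinear interpolation of the 6 tensor components at world points (n x 3,
# mm). Points outside the region spanned by voxel centres get NA.
interp_tensor <- function(tarr, points, voxel_size) {
  dims <- dim(tarr)[1:3]
  nvox <- prod(dims)
  cc <- points / voxel_size + 0.5               # continuous 1-based index
  i0 <- floor(cc)
  fr <- cc - i0
  ok <- i0[, 1] >= 1 & i0[, 1] < dims[1] &
        i0[, 2] >= 1 & i0[, 2] < dims[2] &
        i0[, 3] >= 1 & i0[, 3] < dims[3]
  out <- matrix(NA_real_, nrow(points), 6)
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]; fr <- fr[ok, , drop = FALSE]
  base <- i0[, 1] + (i0[, 2] - 1) * dims[1] + (i0[, 3] - 1) * dims[1] * dims[2]
  acc <- matrix(0, sum(ok), 6)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
         (if (dy) fr[, 2] else 1 - fr[, 2]) *
         (if (dz) fr[, 3] else 1 - fr[, 3])
    idx <- base + dx + dy * dims[1] + dz * dims[1] * dims[2]
    for (k in 1:6) acc[, k] <- acc[, k] + w * tarr[idx + (k - 1) * nvox]
  }
  out[ok, ] <- acc
  out
}

# Dominant eigenvector of interpolated tensors by power iteration, warm-
# started from the incoming direction and sign-aligned with it. Vectorised
# over points; tensors here are SPD or near-SPD, so a handful of iterations
# from a well-aligned start converges far past the needs of 1 mm stepping.
principal_direction <- function(tn, v0, iterations = 12L) {
  v <- v0
  for (it in seq_len(iterations)) {
    w1 <- tn[, 1] * v[, 1] + tn[, 2] * v[, 2] + tn[, 3] * v[, 3]
    w2 <- tn[, 2] * v[, 1] + tn[, 4] * v[, 2] + tn[, 5] * v[, 3]
    w3 <- tn[, 3] * v[, 1] + tn[, 5] * v[, 2] + tn[, 6] * v[, 3]
    nw <- sqrt(w1^2 + w2^2 + w3^2)
    bad <- nw <= 0 | !is.finite(nw)
    nw[bad] <- 1
    v <- cbind(w1 / nw, w2 / nw, w3 / nw)
    v[bad, ] <- NA_real_
  }
  # sign continuity with the incoming direction
  s <- sign(rowSums(v * v0))
  s[s == 0] <- 1
  v * s
}

#' Deterministic streamline tractography
#'
#' FACT-style tracking: bidirectional fixed-step Euler integration along the
#' principal eigenvector field, with trilinear interpolation of the tensor
#' and local extraction of its dominant eigenvector at every step. The
#' eigenvector sign is chosen to match the incoming direction. A streamline
#' terminates when interpolated FA drops below `fa_threshold`, the direction
#' turns by more than `max_turn_angle` in one step, or it leaves the grid.
#'
#' Seeds are placed at the centre of every voxel of `seed_mask` whose fitted
#' FA is at least `params$seed_fa`. Identical inputs always produce identical
#' streamlines.
#'
#' @param fit a [dti_fit()] of one repetition.
#' @param seed_mask logical 3D array of candidate seed voxels.
#' @param params a [track_params()] list.
#' @return Object of class `streamline_set`: `streamlines` (list of n x 3
#'   matrices of mm coordinates, ordered along the line), `params`, `dims`,
#'   `voxel_size`.
#' @export
seed_and_track <- function(fit, seed_mask, params = track_params()) {
  stopifnot(inherits(fit, "dti_fit"))
  if (!any(seed_mask)) stop("empty seed mask")
  dims <- fit$dims; h <- fit$voxel_size
  tarr <- tensor_component_array(fit)

  fa_vox <- fa_from_tensor_components(fit$tensors[, 1], fit$tensors[, 2],
                                      fit$tensors[, 3], fit$tensors[, 4],
                                      fit$tensors[, 5], fit$tensors[, 6])
  fa_grid <- array(0, dim = dims)
  fa_grid[fit$mask] <- fa_vox
  seeds <- which(seed_mask & fa_grid >= params$seed_fa, arr.ind = TRUE)
  n <- nrow(seeds)
  if (n == 0L)
    return(structure(list(streamlines = list(), params = params,
                          dims = dims, voxel_size = h),
                     class = "streamline_set"))
  p0 <- (seeds - 0.5) * h

  # seed directions: exact eigenvector at the seed-voxel tensor
  lin <- seeds[, 1] + (seeds[, 2] - 1) * dims[1] +
    (seeds[, 3] - 1) * dims[1] * dims[2]
  row_of <- match(lin, which(fit$mask))
  v0 <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    tv <- fit$tensors[row_of[i], ]
    M <- matrix(c(tv[1], tv[2], tv[3], tv[2], tv[4], tv[5],
                  tv[3], tv[5], tv[6]), 3, 3)
    v0[i, ] <- eigen(M, symmetric = TRUE)$vectors[, 1]
  }

  march <- function(dir0) {
    pts <- vector("list", params$max_steps)
    pos <- p0
    dir <- dir0
    active <- rep(TRUE, n)
    ct <- cos(params$max_turn_angle * pi / 180)
    for (s in seq_len(params$max_steps)) {
      if (!any(active)) break
      ia <- which(active)
      tn <- interp_tensor(tarr, pos[ia, , drop = FALSE], h)
      alive <- rowSums(is.na(tn)) == 0L
      fa <- rep(0, length(ia))
      fa[alive] <- fa_from_tensor_components(tn[alive, 1], tn[alive, 2],
                                             tn[alive, 3], tn[alive, 4],
                                             tn[alive, 5], tn[alive, 6])
      alive <- alive & fa >= params$fa_threshold
      nd <- matrix(NA_real_, length(ia), 3)
      if (any(alive))
        nd[alive, ] <- principal_direction(tn[alive, , drop = FALSE],
                                           dir[ia[alive], , drop = FALSE])
      turn_ok <- rowSums(nd * dir[ia, , drop = FALSE]) >= ct
      alive <- alive & !is.na(turn_ok) & turn_ok
      stop_now <- ia[!alive]
      active[stop_now] <- FALSE
      keep <- ia[alive]
      if (length(keep)) {
        pos[keep, ] <- pos[keep, , drop = FALSE] +
          params$step_size * nd[alive, , drop = FALSE]
        dir[keep, ] <- nd[alive, , drop = FALSE]
        rec <- matrix(NA_real_, n, 3)
        rec[keep, ] <- pos[keep, , drop = FALSE]
        pts[[s]] <- rec
      } else break
    }
    pts[!vapply(pts, is.null, logical(1))]
  }
  fwd <- march(v0)
  bwd <- march(-v0)

  streamlines <- vector("list", n)
  for (i in seq_len(n)) {
    f <- do.call(rbind, lapply(fwd, function(m) m[i, ]))
    bk <- do.call(rbind, lapply(bwd, function(m) m[i, ]))
    f <- f[stats::complete.cases(f), , drop = FALSE]
    bk <- bk[stats::complete.cases(bk), , drop = FALSE]
    sl <- rbind(bk[rev(seq_len(nrow(bk))), , drop = FALSE],
                p0[i, , drop = FALSE], f)
    streamlines[[i]] <- sl
  }
  structure(list(streamlines = streamlines, params = params,
                 dims = dims, voxel_size = h), class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  npts <- vapply(x$streamlines, nrow, integer(1))
  cat(sprintf("Streamline set: %d streamlines, median length %.0f mm\n",
              length(x$streamlines),
              if (length(npts)) stats::median(npts - 1) * x$params$step_size else 0))
  invisible(x)
}

#' Include/exclude region set for streamline filtering
#'
#' @param include list of exactly two non-empty, mutually disjoint logical
#'   masks (inferior and superior include regions).
#' @param exclude list of zero or more logical masks.
#' @return Object of class `roi_set`.
#' @export
roi_set <- function(include, exclude = list()) {
  if (length(include) != 2L) stop("exactly two include ROIs are required")
  if (!all(vapply(include, any, logical(1)))) stop("include ROIs must be non-empty")
  if (any(include[[1]] & include[[2]])) stop("include ROIs must be disjoint")
  d <- dim(include[[1]])
  for (m in c(include, exclude))
    if (!identical(dim(m), d)) stop("ROI grids differ")
  structure(list(include = include, exclude = exclude), class = "roi_set")
}

streamline_voxels <- function(sl, dims, voxel_size) {
  v <- floor(sl / voxel_size) + 1
  inside <- v[, 1] >= 1 & v[, 1] <= dims[1] &
            v[, 2] >= 1 & v[, 2] <= dims[2] &
            v[, 3] >= 1 & v[, 3] <= dims[3]
  v <- v[inside, , drop = FALSE]
  list(lin = unique(v[, 1] + (v[, 2] - 1) * dims[1] +
                      (v[, 3] - 1) * dims[1] * dims[2]),
       n_outside = sum(!inside))
}

#' Filter streamlines by include/exclude regions
#'
#' Keeps exactly the streamlines that intersect both include ROIs and no
#' exclude ROI (a point intersects a ROI when it falls inside a ROI voxel).
#'
#' @param streamlines a [seed_and_track()] result.
#' @param rois a [roi_set()].
#' @return A filtered `streamline_set`.
#' @export
apply_roi_filters <- function(streamlines, rois) {
  stopifnot(inherits(streamlines, "streamline_set"), inherits(rois, "roi_set"))
  dims <- streamlines$dims; h <- streamlines$voxel_size
  if (!identical(dim(rois$include[[1]]), as.integer(dims)) &&
      !identical(dim(rois$include[[1]]), dims))
    stop("ROI grid does not match the tracking grid")
  keep <- vapply(streamlines$streamlines, function(sl) {
    lin <- streamline_voxels(sl, dims, h)$lin
    if (!all(vapply(rois$include, function(m) any(m[lin]), logical(1))))
      return(FALSE)
    for (m in rois$exclude) if (any(m[lin])) return(FALSE)
    TRUE
  }, logical(1))
  out <- streamlines
  out$streamlines <- streamlines$streamlines[keep]
  out
}

#' Rasterize streamlines into a binary tract object
#'
#' A voxel belongs to the tract mask iff at least one streamline point falls
#' inside it. Points outside the grid are ignored and counted.
#'
#' @param streamlines a `streamline_set`.
#' @param dims,voxel_size grid geometry (defaults taken from the set).
#' @param gating,repetition optional provenance labels.
#' @return Object of class `tract_object`: `mask` (logical array),
#'   `volume_cm3` (= voxel count x voxel volume / 1000), `n_streamlines`,
#'   `n_points_outside`, `gating`, `repetition`.
#' @export
rasterize_tract <- function(streamlines, dims = streamlines$dims,
                            voxel_size = streamlines$voxel_size,
                            gating = NA_character_, repetition = NA_integer_) {
  if (prod(dims) == 0) stop("empty grid")
  mask <- array(FALSE, dim = dims)
  n_out <- 0L
  for (sl in streamlines$streamlines) {
    sv <- streamline_voxels(sl, dims, voxel_size)
    mask[sv$lin] <- TRUE
    n_out <- n_out + sv$n_outside
  }
  tract_object(mask, voxel_size, gating = gating, repetition = repetition,
               n_streamlines = length(streamlines$streamlines),
               n_points_outside = n_out)
}

#' Construct a tract object from a binary mask
#'
#' @param mask logical 3D array.
#' @param voxel_size voxel edge, mm.
#' @param gating,repetition,n_streamlines,n_points_outside metadata.
#' @return Object of class `tract_object`.
#' @export
tract_object <- function(mask, voxel_size, gating = NA_character_,
                         repetition = NA_integer_, n_streamlines = NA_integer_,
                         n_points_outside = 0L) {
  structure(list(mask = mask,
                 volume_cm3 = sum(mask) * voxel_size^3 / 1000,
                 voxel_size = voxel_size, gating = gating,
                 repetition = repetition, n_streamlines = n_streamlines,
                 n_points_outside = n_points_outside),
            class = "tract_object")
}

#' @export
print.tract_object <- function(x, ...) {
  cat(sprintf("Tract object: %d voxels, %.2f cm^3%s\n", sum(x$mask),
              x$volume_cm3,
              if (!is.na(x$gating)) paste0(" (", x$gating, ")") else ""))
  invisible(x)
}

#' Dice overlap of two binary masks
#'
#' @param a,b logical arrays on the same grid.
#' @return 2|a & b| / (|a| + |b|).
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("grid mismatch")
  denom <- sum(a) + sum(b)
  if (denom == 0) stop("both masks are empty")
  2 * sum(a & b) / denom
}
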