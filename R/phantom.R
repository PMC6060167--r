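#' Digital phantom for pulsatile-motion DWI studies
#'
#' Builds a rectangular phantom containing a z-oriented corticospinal-tract
#' analogue (an anisotropic tube bowed in the x-z plane), an isotropic tissue
#' background, a CSF compartment, and two pulsatile regions: a brainstem
#' analogue around the inferior tract and a cerebellar analogue posterior to
#' it. Every voxel carries a ground-truth diffusion tensor and b=0 signal.
#'
#' Region labels partition the grid (`tract` takes precedence where
#' structures overlap); the pulsatile influence zones are stored separately
#' as masks and deliberately include the tract voxels they engulf, because
#' pulsatile motion displaces the tract tissue running through the brainstem
#' just as much as the surrounding parenchyma.
#'
#' @param config list of phantom parameters, see [phantom_config()].
#' @return An object of class `dwi_phantom` with elements:
#'   `dims` (voxels per axis), `voxel_size` (mm), `labels` (integer array,
#'   see `label_levels`), `tensors` (4D array, 6 components per voxel in the
#'   order Dxx Dxy Dxz Dyy Dyz Dzz, mm^2/s), `s0` (3D array), `masks`
#'   (per-region logical arrays plus `brain`), `pulsatile_zones` (logical
#'   arrays, may overlap anatomy), `rois` (two include masks and one exclude
#'   mask for tractography), `fa_truth`, `md_truth`, `v1_truth`, and the
#'   `config` used.
#' @examples
#' ph <- build_phantom(phantom_config(grid_shape = c(20, 20, 30)))
#' range(ph$fa_truth[ph$masks$tract])
#' @export
build_phantom <- function(config = phantom_config()) {
  cf <- utils::modifyList(phantom_config(), config)
  dims <- as.integer(cf$grid_shape)
  h <- cf$voxel_size
  if (length(dims) != 3L || any(dims < 4L)) stop("grid_shape must be 3 axes of >= 4 voxels")
  if (h <= 0) stop("voxel_size must be positive")
  if (cf$tract_radius <= 0) stop("tract_radius must be positive")

  ext <- dims * h                      # field of view, mm
  # voxel-centre world coordinates
  xc <- (seq_len(dims[1]) - 0.5) * h
  yc <- (seq_len(dims[2]) - 0.5) * h
  zc <- (seq_len(dims[3]) - 0.5) * h

  # tract centreline: gentle bow in the x-z plane
  cx0 <- if (is.null(cf$tract_center_x)) ext[1] / 2 else cf$tract_center_x
  cy0 <- if (is.null(cf$tract_center_y)) ext[2] / 2 else cf$tract_center_y
  cline_x <- function(z) cx0 + cf$tract_curve_amp * sin(pi * z / ext[3])
  if (any(cline_x(zc) - cf$tract_radius < 0) ||
      any(cline_x(zc) + cf$tract_radius > ext[1]) ||
      cy0 - cf$tract_radius < 0 || cy0 + cf$tract_radius > ext[2])
    stop("tract does not fit inside the grid; reduce radius/curve amplitude or recenter")

  X <- array(rep(xc, times = dims[2] * dims[3]), dim = dims)
  Y <- array(rep(rep(yc, each = dims[1]), times = dims[3]), dim = dims)
  Z <- array(rep(zc, each = dims[1] * dims[2]), dim = dims)
  CX <- array(rep(cline_x(zc), each = dims[1] * dims[2]), dim = dims)

  tract <- (X - CX)^2 + (Y - cy0)^2 <= cf$tract_radius^2

  # CSF compartment: a ventricle-like slab lateral to the tract, mid-grid
  csf <- (X >= cx0 - 0.45 * ext[1]) & (X <= cx0 - 0.28 * ext[1]) &
         (abs(Y - cy0) <= 0.10 * ext[2]) &
         (Z >= 0.42 * ext[3]) & (Z <= 0.66 * ext[3])

  # pulsatile influence zones (may overlap the tract)
  bs_zone <- (abs(X - CX) <= cf$brainstem_halfwidth) &
             (abs(Y - cy0) <= cf$brainstem_halfwidth) &
             (Z < cf$brainstem_z_extent)
  cb_zone <- (abs(X - cx0) <= 0.18 * ext[1]) &
             (Y > cy0 + 0.15 * ext[2]) & (Y <= cy0 + 0.42 * ext[2]) &
             (Z < 0.25 * ext[3])
  cb_zone <- cb_zone & !bs_zone

  labels <- array(1L, dim = dims)                 # 1 = background
  labels[bs_zone] <- 4L
  labels[cb_zone] <- 5L
  labels[csf] <- 2L
  labels[tract] <- 3L
  label_levels <- c(background = 1L, CSF = 2L, tract = 3L,
                    pulsatile_brainstem = 4L, pulsatile_cerebellum = 5L)

  # ground-truth tensors, component order Dxx Dxy Dxz Dyy Dyz Dzz
  nvox <- prod(dims)
  tensors <- array(0, dim = c(dims, 6L))
  iso <- function(mask, d) {
    for (k in c(1L, 4L, 6L)) {
      comp <- tensors[, , , k]; comp[mask] <- d; tensors[, , , k] <<- comp
    }
  }
  iso(labels == 1L, cf$background_adc)
  iso(labels == 4L | labels == 5L, cf$background_adc)
  iso(labels == 2L, cf$csf_adc)

  # tract tensor: eigenvalues cf$tract_evals along the local tangent
  tan_x <- cf$tract_curve_amp * (pi / ext[3]) * cos(pi * zc / ext[3])
  ev <- cf$tract_evals
  idx <- which(tract, arr.ind = TRUE)
  tz <- idx[, 3]
  tx <- tan_x[tz]
  tn <- sqrt(tx^2 + 1)
  e1 <- cbind(tx / tn, 0, 1 / tn)                # unit tangent
  e2 <- cbind(0, rep(1, nrow(idx)), 0)           # y stays transverse
  e3 <- cbind(-e1[, 3], 0, e1[, 1])              # completes the frame
  Dxx <- ev[1] * e1[, 1]^2 + ev[2] * e2[, 1]^2 + ev[3] * e3[, 1]^2
  Dyy <- ev[1] * e1[, 2]^2 + ev[2] * e2[, 2]^2 + ev[3] * e3[, 2]^2
  Dzz <- ev[1] * e1[, 3]^2 + ev[2] * e2[, 3]^2 + ev[3] * e3[, 3]^2
  Dxy <- ev[1] * e1[, 1] * e1[, 2] + ev[2] * e2[, 1] * e2[, 2] + ev[3] * e3[, 1] * e3[, 2]
  Dxz <- ev[1] * e1[, 1] * e1[, 3] + ev[2] * e2[, 1] * e2[, 3] + ev[3] * e3[, 1] * e3[, 3]
  Dyz <- ev[1] * e1[, 2] * e1[, 3] + ev[2] * e2[, 2] * e2[, 3] + ev[3] * e3[, 2] * e3[, 3]
  lin <- idx[, 1] + (idx[, 2] - 1L) * dims[1] + (idx[, 3] - 1L) * dims[1] * dims[2]
  comps <- list(Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)
  for (k in 1:6) tensors[lin + (k - 1L) * nvox] <- comps[[k]]

  s0 <- array(0, dim = dims)
  s0[labels != 1L] <- cf$s0_brain
  s0[labels == 2L] <- cf$s0_csf

  # truth maps
  fa_truth <- array(0, dim = dims)
  fa_truth[labels == 1L | labels == 4L | labels == 5L] <- 0
  fa_truth[tract] <- fa_from_eigenvalues(ev[1], ev[2], ev[3])
  md_truth <- array(cf$background_adc, dim = dims)
  md_truth[labels == 2L] <- cf$csf_adc
  md_truth[tract] <- mean(ev)
  v1_truth <- array(0, dim = c(dims, 3L))
  v1_truth[lin] <- e1[, 1]
  v1_truth[lin + nvox] <- e1[, 2]
  v1_truth[lin + 2L * nvox] <- e1[, 3]

  # tractography ROIs: inferior "cerebral peduncle" and superior "motor
  # cortex" analogues on the tract; a default exclude box in the cerebellum
  roi_inf <- tract & (Z >= 0.01 * ext[3]) & (Z <= 0.09 * ext[3])
  roi_sup <- tract & (Z >= 0.80 * ext[3]) & (Z <= 0.90 * ext[3])
  roi_exc <- cb_zone & (Z < 0.10 * ext[3])

  structure(list(
    dims = dims, voxel_size = h, labels = labels, label_levels = label_levels,
    tensors = tensors, s0 = s0,
    masks = list(background = labels == 1L, CSF = labels == 2L,
                 tract = labels == 3L,
                 pulsatile_brainstem = labels == 4L,
                 pulsatile_cerebellum = labels == 5L,
                 brain = labels != 1L),
    pulsatile_zones = list(brainstem = bs_zone, cerebellum = cb_zone),
    rois = list(include_inferior = roi_inf, include_superior = roi_sup,
                exclude = roi_exc),
    fa_truth = fa_truth, md_truth = md_truth, v1_truth = v1_truth,
    config = cf), class = "dwi_phantom")
}

#' Default phantom parameters
#'
#' @param grid_shape voxels per axis.
#' @param voxel_size isotropic voxel edge, mm.
#' @param tract_radius tract tube radius, mm.
#' @param tract_curve_amp amplitude of the x-direction bow of the tract
#'   centreline, mm.
#' @param tract_center_x,tract_center_y centreline anchor, mm (NULL = grid
#'   centre).
#' @param tract_evals ground-truth tract eigenvalues, mm^2/s (descending).
#' @param background_adc,csf_adc isotropic diffusivities, mm^2/s.
#' @param s0_brain,s0_csf non-diffusion-weighted signal levels.
#' @param brainstem_halfwidth half-width of the brainstem pulsatile zone, mm.
#' @param brainstem_z_extent superior limit of the brainstem pulsatile zone,
#'   mm from the inferior grid face.
#' @return Named list of parameters.
#' @export
phantom_config <- function(grid_shape = c(40L, 40L, 60L),
                           voxel_size = 2,
                           tract_radius = 5,
                           tract_curve_amp = 4,
                           tract_center_x = NULL,
                           tract_center_y = NULL,
                           tract_evals = c(1.7e-3, 0.3e-3, 0.2e-3),
                           background_adc = 0.8e-3,
                           csf_adc = 3.0e-3,
                           s0_brain = 1000,
                           s0_csf = 1500,
                           brainstem_halfwidth = 13,
                           brainstem_z_extent = 40) {
  list(grid_shape = grid_shape, voxel_size = voxel_size,
       tract_radius = tract_radius, tract_curve_amp = tract_curve_amp,
       tract_center_x = tract_center_x, tract_center_y = tract_center_y,
       tract_evals = tract_evals, background_adc = background_adc,
       csf_adc = csf_adc, s0_brain = s0_brain, s0_csf = s0_csf,
       brainstem_halfwidth = brainstem_halfwidth,
       brainstem_z_extent = brainstem_z_extent)
}

#' @export
print.dwi_phantom <- function(x, ...) {
  cat(sprintf("DWI phantom: %s voxels at %.1f mm\n",
              paste(x$dims, collapse = " x "), x$voxel_size))
  for (nm in names(x$label_levels))
    cat(sprintf("  %-22s %6d voxels\n", nm,
                sum(x$labels == x$label_levels[[nm]])))
  invisible(x)
}

#' Pulsatile motion model
#'
#' Cardiac systole displaces brainstem and cerebellar tissue with a peak
#' velocity of about 1.5 mm/s in the anterio-caudal direction; during a
#' diffusion-weighted acquisition this bulk motion dephases the signal in
#' proportion to the alignment of the encoding gradient with the motion.
#' The model attenuates the signal of pulsatile-zone voxels in systolic
#' volumes by exp(-kappa * v * |g . m|), with v the zone's velocity
#' amplitude (mm/s), m the unit motion direction and kappa a dimensionless
#' artefact-strength calibration.
#'
#' @param motion_direction 3-vector, normalised internally (default
#'   anterio-caudal).
#' @param velocity named amplitudes in mm/s for the `brainstem` and
#'   `cerebellum` zones.
#' @param systole_fraction fraction of the cardiac cycle treated as
#'   systolic, in (0, 1).
#' @param kappa attenuation scale; the default makes systolic brainstem
#'   signal drop by roughly 20-40% for near-axial encoding directions.
#' @return Object of class `pulsatile_model`.
#' @export
pulsatile_model <- function(motion_direction = c(0, -0.45, -0.89),
                            velocity = c(brainstem = 1.5, cerebellum = 1.0),
                            systole_fraction = 0.3,
                            kappa = 0.3) {
  nd <- sqrt(sum(motion_direction^2))
  if (nd == 0) stop("motion_direction must be nonzero")
  if (systole_fraction <= 0 || systole_fraction >= 1)
    stop("systole_fraction must lie strictly between 0 and 1")
  if (kappa < 0) stop("kappa must be non-negative")
  if (!all(c("brainstem", "cerebellum") %in% names(velocity)))
    stop("velocity needs 'brainstem' and 'cerebellum' entries")
  if (any(velocity < 0)) stop("velocities must be non-negative")
  structure(list(motion_direction = motion_direction / nd,
                 velocity = velocity,
                 systole_fraction = systole_fraction,
                 kappa = kappa), class = "pulsatile_model")
}

#' Acquisition protocol
#'
#' @param gradients a [gradient_table()].
#' @param n_repetitions number of repeated acquisitions (default 5).
#' @param gating `"cardiac_gated"` (acquisition triggered into diastole; no
#'   pulsatile attenuation) or `"non_gated"`.
#' @param noise_sigma Rician noise level in signal units; 0 = noiseless.
#'   The default corresponds to SNR 30 on a b=0 brain signal of 1000.
#' @param rng_seed integer seed controlling cardiac phases and noise.
#' @return Object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(gradients = default_gradient_table(),
                                 n_repetitions = 5,
                                 gating = c("cardiac_gated", "non_gated"),
                                 noise_sigma = 1000 / 30,
                                 rng_seed = 1L) {
  gating <- match.arg(gating)
  stopifnot(inherits(gradients, "gradient_table"))
  if (n_repetitions < 1) stop("n_repetitions must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  structure(list(gradients = gradients, n_repetitions = as.integer(n_repetitions),
                 gating = gating, noise_sigma = noise_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "acquisition_protocol")
}

#' Simulate a gated or non-gated DWI acquisition
#'
#' The clean signal follows the monoexponential tensor model
#' S(g, b) = S0 exp(-b g' D g) per voxel. For a non-gated protocol each
#' (volume, repetition) draws an independent cardiac phase uniform on
#' \[0, 1); if the phase falls in the systolic window, voxels inside each
#' pulsatile zone are attenuated by exp(-kappa * v * |g . m|). Gated
#' acquisitions draw the same phases (so RNG streams align across gating
#' modes) but apply no attenuation. Rician noise is applied last.
#'
#' @param phantom a [build_phantom()] result.
#' @param pulsatile a [pulsatile_model()].
#' @param protocol an [acquisition_protocol()].
#' @return Object of class `dwi_study`: `repetitions` (list of 4D arrays,
#'   x-y-z-volume), `gating`, `protocol`, `phases` (volumes x repetitions
#'   matrix), `systolic` (logical, same shape) and `phantom` (the ground
#'   truth, by reference).
#' @export
simulate_acquisition <- function(phantom, pulsatile, protocol) {
  stopifnot(inherits(phantom, "dwi_phantom"),
            inherits(pulsatile, "pulsatile_model"),
            inherits(protocol, "acquisition_protocol"))
  gt <- protocol$gradients
  dw <- gt$bvals > 0
  nrm <- sqrt(colSums(gt$bvecs^2))
  if (any(abs(nrm[dw] - 1) > 1e-6))
    stop("gradient table directions are not unit-norm")

  dims <- phantom$dims
  nvox <- prod(dims)
  nvol <- gt$n_volumes
  # clean signal, shared by all repetitions
  tens <- matrix(phantom$tensors, nrow = nvox)   # nvox x 6
  clean <- array(0, dim = c(dims, nvol))
  for (v in seq_len(nvol)) {
    g <- gt$bvecs[, v]; b <- gt$bvals[v]
    quad <- tens[, 1] * g[1]^2 + tens[, 4] * g[2]^2 + tens[, 6] * g[3]^2 +
      2 * (tens[, 2] * g[1] * g[2] + tens[, 3] * g[1] * g[3] +
             tens[, 5] * g[2] * g[3])
    clean[(v - 1L) * nvox + seq_len(nvox)] <- phantom$s0 * exp(-b * quad)
  }

  zones <- phantom$pulsatile_zones
  vel <- c(brainstem = unname(pulsatile$velocity["brainstem"]),
           cerebellum = unname(pulsatile$velocity["cerebellum"]))
  set.seed(protocol$rng_seed)
  phases <- matrix(stats::runif(nvol * protocol$n_repetitions),
                   nrow = nvol, ncol = protocol$n_repetitions)
  systolic <- phases < pulsatile$systole_fraction
  reps <- vector("list", protocol$n_repetitions)
  for (r in seq_len(protocol$n_repetitions)) {
    sig <- clean
    if (protocol$gating == "non_gated") {
      for (v in which(systolic[, r] & dw)) {
        g <- gt$bvecs[, v]
        align <- abs(sum(g * pulsatile$motion_direction))
        for (zn in names(zones)) {
          fac <- exp(-pulsatile$kappa * vel[[zn]] * align)
          vol <- sig[, , , v]
          vol[zones[[zn]]] <- vol[zones[[zn]]] * fac
          sig[, , , v] <- vol
        }
      }
    }
    reps[[r]] <- add_rician_noise(sig, protocol$noise_sigma)
  }
  structure(list(repetitions = reps, gating = protocol$gating,
                 protocol = protocol, phases = phases, systolic = systolic,
                 phantom = phantom), class = "dwi_study")
}

#' @export
print.dwi_study <- function(x, ...) {
  cat(sprintf("DWI study: %d repetitions, %s, %d volumes, noise sigma %.2f\n",
              length(x$repetitions), x$gating,
              x$protocol$gradients$n_volumes, x$protocol$noise_sigma))
  invisible(x)
}

#' Add Rician noise to a magnitude image
#'
#' Magnitude MR noise: the output is sqrt((S + n1)^2 + n2^2) with n1, n2
#' independent zero-mean Gaussians of standard deviation `sigma`. With
#' sigma = 0 the input is returned unchanged.
#'
#' @param signal numeric array of non-negative signal values.
#' @param sigma noise standard deviation (>= 0).
#' @return Array of the same shape, everywhere non-negative.
#' @export
add_rician_noise <- function(signal, sigma) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(signal)
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 +
                stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}
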