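#' Diffusion gradient tables
#'
#' A gradient table pairs one b-value (s/mm^2) with one encoding direction
#' per acquired volume. Volumes with b = 0 carry no diffusion weighting and
#' their direction is undefined (stored as the zero vector).
#'
#' @param bvals numeric vector of b-values, one per volume (s/mm^2).
#' @param bvecs 3 x n matrix of encoding directions (columns are volumes).
#'   Diffusion-weighted columns must be unit-norm to within 1e-6.
#' @return An object of class `gradient_table` with elements `bvals`,
#'   `bvecs` and `n_volumes`.
#' @examples
#' gt <- gradient_table(c(0, 1000, 1000),
#'                      cbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)))
#' subspace_angle(gt$bvecs[, 3], c(0, 0, 1))
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L)
    stop("bvecs must have 3 rows (one direction per column)")
  if (length(bvals) != ncol(bvecs))
    stop(sprintf("bvals has %d entries but bvecs has %d columns",
                 length(bvals), ncol(bvecs)))
  if (any(!is.finite(bvals)) || any(!is.finite(bvecs)))
    stop("non-finite values in gradient table")
  if (any(bvals < 0)) stop("negative b-values")
  dw <- bvals > 0
  if (!any(!dw)) stop("gradient table needs at least one b=0 volume")
  if (any(dw)) {
    nrm <- sqrt(colSums(bvecs[, dw, drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("diffusion-weighted directions must be unit-norm (tolerance 1e-6)")
  }
  structure(list(bvals = bvals, bvecs = bvecs, n_volumes = length(bvals)),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  nb0 <- sum(x$bvals == 0)
  cat(sprintf("Gradient table: %d volumes (%d b=0, %d diffusion-weighted)\n",
              x$n_volumes, nb0, x$n_volumes - nb0))
  cat(sprintf("b-values: %s s/mm^2\n",
              paste(unique(x$bvals), collapse = ", ")))
  invisible(x)
}

#' Read a bvals/bvecs file pair
#'
#' Reads the plain-text dialect used throughout diffusion MRI tooling:
#' the bvals file holds one row of n numbers, the bvecs file three rows of
#' n numbers (x, y, z components), whitespace-separated.
#'
#' @param bval_path,bvec_path paths to the two files.
#' @return A [gradient_table()].
#' @export
read_bvals_bvecs <- function(bval_path, bvec_path) {
  for (p in c(bval_path, bvec_path))
    if (!file.exists(p)) stop("file not found: ", p)
  parse_rows <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
      toks <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
      vals <- suppressWarnings(as.numeric(toks))
      if (any(is.na(vals)))
        stop(sprintf("non-numeric token '%s' in %s line %d",
                     toks[which(is.na(vals))[1]], path, i))
      vals
    })
    rows
  }
  bv <- parse_rows(bval_path)
  if (length(bv) != 1L)
    stop("bvals file must contain exactly one row: ", bval_path)
  gv <- parse_rows(bvec_path)
  if (length(gv) != 3L)
    stop(sprintf("bvecs file must contain exactly 3 rows, found %d: %s",
                 length(gv), bvec_path))
  n <- length(bv[[1]])
  lens <- vapply(gv, length, integer(1))
  if (any(lens != n))
    stop(sprintf("column count mismatch: bvals has %d, bvecs rows have %s (%s)",
                 n, paste(lens, collapse = "/"), bvec_path))
  gradient_table(bv[[1]], do.call(rbind, gv))
}

#' Write a gradient table as a bvals/bvecs file pair
#'
#' @param table a [gradient_table()].
#' @param bval_path,bvec_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_bvals_bvecs <- function(table, bval_path, bvec_path) {
  stopifnot(inherits(table, "gradient_table"))
  writeLines(paste(format(table$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(table$bvecs, 1, function(r)
    paste(format(r, digits = 10, trim = TRUE), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Built-in 30-direction encoding scheme
#'
#' A fixed electrostatic-repulsion scheme with one b=0 volume followed by 30
#' unit directions at b = 1000 s/mm^2, shipped with the package. Direction
#' signs are canonicalised to non-negative z.
#'
#' @return A [gradient_table()] with 31 volumes.
#' @export
default_gradient_table <- function() {
  read_bvals_bvecs(
    system.file("extdata", "encoding30.bval", package = "pulsedti",
                mustWork = TRUE),
    system.file("extdata", "encoding30.bvec", package = "pulsedti",
                mustWork = TRUE))
}

#' Subspace angle between two directions
#'
#' The literal angle arccos(g . a / (|g| |a|)) in degrees, in [0, 180].
#' Encoding directions have a physical sign (the stored polarity of the
#' gradient), so no antipodal folding is applied here; use
#' [axial_angle()] for sign-ambiguous vectors such as eigenvectors.
#'
#' @param g,axis nonzero 3-vectors (need not be unit-norm).
#' @return Angle in degrees.
#' @examples
#' subspace_angle(c(0.6, 0, 0.8), c(0, 0, 1)) # 36.87
#' @export
subspace_angle <- function(g, axis) {
  ng <- sqrt(sum(g^2)); na <- sqrt(sum(axis^2))
  if (ng == 0 || na == 0) stop("zero vector has no direction")
  ct <- sum(g * axis) / (ng * na)
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Axial (sign-invariant) angle between two directions
#'
#' arccos(|g . a| / (|g| |a|)) in degrees, folded to [0, 90]. Appropriate for
#' eigenvectors, which are only defined up to sign.
#'
#' @inheritParams subspace_angle
#' @return Angle in degrees in [0, 90].
#' @export
axial_angle <- function(g, axis) {
  a <- subspace_angle(g, axis)
  if (a > 90) 180 - a else a
}

#' Select the encoding directions closest to and farthest from an axis
#'
#' Scans the diffusion-weighted volumes of a gradient table and returns the
#' indices (volume positions, b=0 volumes excluded from candidates) of the
#' directions with the smallest and largest subspace angle to `axis`.
#' Ties are broken by the lowest volume index.
#'
#' @param table a [gradient_table()].
#' @param axis reference axis (default the scanner z-axis).
#' @return List with `min_index`, `max_index`, `min_angle`, `max_angle`
#'   (degrees) and `angles`, the per-volume angle (NA for b=0 volumes).
#' @export
select_extreme_volumes <- function(table, axis = c(0, 0, 1)) {
  stopifnot(inherits(table, "gradient_table"))
  dw <- which(table$bvals > 0)
  if (length(dw) == 0L)
    stop("gradient table has no diffusion-weighted volumes")
  ang <- rep(NA_real_, table$n_volumes)
  for (i in dw) ang[i] <- subspace_angle(table$bvecs[, i], axis)
  imin <- dw[which.min(ang[dw])]
  imax <- dw[which.max(ang[dw])]
  list(min_index = imin, max_index = imax,
       min_angle = ang[imin], max_angle = ang[imax], angles = ang)
}
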