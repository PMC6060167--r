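#' Log-linear least-squares diffusion tensor fit
#'
#' Fits the monoexponential tensor model ln S = ln S0 - b g' D g per voxel by
#' unweighted linear least squares on the log-signal, the standard first-pass
#' estimator used by common DTI toolchains. The fit is exact on noiseless
#' monoexponential data. Signals are floored at 1e-6 times the voxel's mean
#' b=0 signal before taking logs, so artefact-induced near-zero values cannot
#' produce infinities.
#'
#' @param data4d 4D numeric array (x, y, z, volume).
#' @param table [gradient_table()] matching the 4th dimension.
#' @param mask logical 3D array of voxels to fit; NULL fits every voxel.
#' @param voxel_size voxel edge in mm, carried along for downstream geometry.
#' @return Object of class `dti_fit`: `tensors` (n_mask x 6 matrix, columns
#'   Dxx Dxy Dxz Dyy Dyz Dzz, mm^2/s), `s0_hat`, `mask`, `dims`,
#'   `voxel_size`, `table`.
#' @examples
#' gt <- default_gradient_table()
#' D <- diag(c(1.7, 0.3, 0.2)) * 1e-3
#' s <- 1000 * exp(-gt$bvals * colSums(gt$bvecs * (D %*% gt$bvecs)))
#' arr <- array(rep(s, each = 8), dim = c(2, 2, 2, 31))
#' fit <- dti_fit(arr, gt)
#' max(abs(coef(fit)[1, ] - c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])))
#' @export
dti_fit <- function(data4d, table, mask = NULL, voxel_size = 1) {
  stopifnot(inherits(table, "gradient_table"))
  dims4 <- dim(data4d)
  if (length(dims4) != 4L || dims4[4] != table$n_volumes)
    stop("data must be 4D with one volume per gradient-table entry")
  dims <- dims4[1:3]
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  if (!identical(dim(mask), as.integer(dims)) &&
      !identical(dim(mask), dims)) stop("mask geometry mismatch")
  if (!any(mask)) stop("empty mask")

  # design: ln S = B %*% (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
  g <- table$bvecs; b <- table$bvals
  B <- cbind(1, -b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
             -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
             -2 * b * g[2, ] * g[3, ])
  qrB <- qr(B)
  if (qrB$rank < 7L)
    stop("degenerate encoding scheme: need >= 6 non-collinear directions plus b=0")

  nvox <- prod(dims)
  midx <- which(mask)
  S <- matrix(data4d, nrow = nvox)[midx, , drop = FALSE]   # n_mask x n_vol
  s0_ref <- rowMeans(S[, b == 0, drop = FALSE])
  floor_at <- pmax(1e-6 * s0_ref, .Machine$double.xmin)
  S <- pmax(S, floor_at)                                    # recycles by row
  beta <- qr.coef(qrB, t(log(S)))                           # 7 x n_mask
  tensors <- t(beta[c(2, 5, 6, 3, 7, 4), , drop = FALSE])   # -> Dxx Dxy Dxz Dyy Dyz Dzz
  colnames(tensors) <- c("Dxx", "Dxy", "Dxz", "Dyy", "Dyz", "Dzz")
  structure(list(tensors = tensors, s0_hat = exp(beta[1, ]),
                 mask = mask, dims = dims, voxel_size = voxel_size,
                 table = table), class = "dti_fit")
}

#' @export
print.dti_fit <- function(x, ...) {
  cat(sprintf("Diffusion tensor fit: %d voxels on a %s grid (%.1f mm)\n",
              nrow(x$tensors), paste(x$dims, collapse = " x "), x$voxel_size))
  invisible(x)
}

#' @export
coef.dti_fit <- function(object, ...) object$tensors

#' @export
summary.dti_fit <- function(object, ...) {
  eig <- dti_eigen(object)
  md <- (eig$L1 + eig$L2 + eig$L3) / 3
  fa <- fa_from_eigenvalues(eig$L1, eig$L2, eig$L3)
  res <- list(n_voxels = nrow(object$tensors),
              fa = stats::quantile(fa, c(0.05, 0.5, 0.95), na.rm = TRUE),
              md = stats::quantile(md, c(0.05, 0.5, 0.95), na.rm = TRUE),
              n_negative_eigenvalues = sum(eig$L3 < 0))
  class(res) <- "summary.dti_fit"
  res
}

#' @export
print.summary.dti_fit <- function(x, ...) {
  cat(sprintf("dti_fit over %d voxels\n", x$n_voxels))
  cat("FA  (5/50/95%):", paste(signif(x$fa, 3), collapse = " / "), "\n")
  cat("MD  (5/50/95%):", paste(signif(x$md, 3), collapse = " / "), "mm^2/s\n")
  cat(sprintf("voxels with a negative eigenvalue: %d\n",
              x$n_negative_eigenvalues))
  invisible(x)
}

#' Eigendecomposition of a fitted tensor field
#'
#' Per-voxel symmetric eigendecomposition with eigenvalues sorted
#' descending. Raw (possibly negative) eigenvalues are kept; scalar-map
#' helpers clamp at zero. Voxels with non-finite tensor entries are dropped
#' from the mask and counted.
#'
#' @param fit a [dti_fit()].
#' @return Object of class `dti_eigen`: vectors `L1`, `L2`, `L3` (mm^2/s),
#'   matrix `V1` (n x 3 unit principal eigenvectors), `mask`, `dims`,
#'   `voxel_size`, and counts `n_excluded` (non-finite voxels) and
#'   `n_negative` (voxels with any eigenvalue < 0).
#' @export
dti_eigen <- function(fit) {
  stopifnot(inherits(fit, "dti_fit"))
  tn <- fit$tensors
  ok <- rowSums(!is.finite(tn)) == 0L
  mask <- fit$mask
  if (any(!ok)) mask[which(mask)[!ok]] <- FALSE
  tn <- tn[ok, , drop = FALSE]
  n <- nrow(tn)
  L <- matrix(0, n, 3)
  V1 <- matrix(0, n, 3)
  M <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    M[1, 1] <- tn[i, 1]; M[1, 2] <- M[2, 1] <- tn[i, 2]
    M[1, 3] <- M[3, 1] <- tn[i, 3]; M[2, 2] <- tn[i, 4]
    M[2, 3] <- M[3, 2] <- tn[i, 5]; M[3, 3] <- tn[i, 6]
    e <- eigen(M, symmetric = TRUE)
    L[i, ] <- e$values
    V1[i, ] <- e$vectors[, 1]
  }
  structure(list(L1 = L[, 1], L2 = L[, 2], L3 = L[, 3], V1 = V1,
                 mask = mask, dims = fit$dims, voxel_size = fit$voxel_size,
                 n_excluded = sum(!ok), n_negative = sum(L[, 3] < 0)),
            class = "dti_eigen")
}

#' Fractional anisotropy from eigenvalues
#'
#' FA = sqrt(3/2) * ||L - MD||  / ||L||, with negative eigenvalues clamped
#' at zero first and FA defined as 0 when all eigenvalues are zero.
#'
#' @param l1,l2,l3 eigenvalue vectors (any order).
#' @return FA values in \[0, 1\].
#' @export
fa_from_eigenvalues <- function(l1, l2, l3) {
  l1 <- pmax(l1, 0); l2 <- pmax(l2, 0); l3 <- pmax(l3, 0)
  md <- (l1 + l2 + l3) / 3
  num <- (l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- sqrt(1.5 * num / pmax(den, .Machine$double.xmin))
  fa[den == 0] <- 0
  pmin(fa, 1)
}

map_from_values <- function(values, mask, dims) {
  out <- array(NA_real_, dim = dims)
  out[mask] <- values
  out
}

#' Scalar and vector maps from an eigendecomposition
#'
#' `fa_map` and `md_map` return 3D arrays (NA outside the mask) of
#' fractional anisotropy and mean diffusivity; eigenvalues are clamped at
#' zero, so FA lies in \[0, 1\] and MD >= 0. `eigenvalue_map` returns L1, L2
#' or L3 unclamped; `v1_map` returns the principal eigenvector as a 4D array
#' with 3 components.
#'
#' @param eig a [dti_eigen()].
#' @param which for `eigenvalue_map`, 1, 2 or 3.
#' @return 3D array (4D for `v1_map`).
#' @export
fa_map <- function(eig) {
  stopifnot(inherits(eig, "dti_eigen"))
  map_from_values(fa_from_eigenvalues(eig$L1, eig$L2, eig$L3),
                  eig$mask, eig$dims)
}

#' @rdname fa_map
#' @export
md_map <- function(eig) {
  stopifnot(inherits(eig, "dti_eigen"))
  map_from_values((pmax(eig$L1, 0) + pmax(eig$L2, 0) + pmax(eig$L3, 0)) / 3,
                  eig$mask, eig$dims)
}

#' @rdname fa_map
#' @export
eigenvalue_map <- function(eig, which = 1) {
  stopifnot(inherits(eig, "dti_eigen"), which %in% 1:3)
  map_from_values(eig[[c("L1", "L2", "L3")[which]]], eig$mask, eig$dims)
}

#' @rdname fa_map
#' @export
v1_map <- function(eig) {
  stopifnot(inherits(eig, "dti_eigen"))
  out <- array(NA_real_, dim = c(eig$dims, 3L))
  nvox <- prod(eig$dims)
  midx <- which(eig$mask)
  for (k in 1:3) out[midx + (k - 1L) * nvox] <- eig$V1[, k]
  out
}

# FA directly from tensor components (no eigendecomposition), used by the
# tracker on interpolated tensors: FA^2 = 3/2 * (||D||^2 - 3 MD^2) / ||D||^2.
fa_from_tensor_components <- function(xx, xy, xz, yy, yz, zz) {
  tr <- xx + yy + zz
  n2 <- xx^2 + yy^2 + zz^2 + 2 * (xy^2 + xz^2 + yz^2)
  dev2 <- pmax(n2 - tr^2 / 3, 0)
  fa <- sqrt(1.5 * dev2 / pmax(n2, .Machine$double.xmin))
  fa[n2 == 0] <- 0
  fa
}
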