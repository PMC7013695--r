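# selection helpers used by the PCA battery -------------------------------

#' C-alpha selections for PCA
#'
#' `receptor_ca_selection` returns every C-alpha of the receptor chain (the
#' fit set); `tm_ca_selection` the C-alphas of one helix, either its whole
#' mapped span or a sub-span of BW positions (e.g. `50 + (-8:8)` around a
#' conserved tyrosine).
#'
#' @param traj an `md_trajectory`.
#' @param map a [bw_map()].
#' @return integer atom indices in residue order.
#' @export
receptor_ca_selection <- function(traj, map) {
  sel <- atom_select(traj, chain = map$chain, elety = "CA", water = FALSE)
  sel[order(traj$atoms$resno[sel])]
}

#' @rdname receptor_ca_selection
#' @param helix helix number 1-7.
#' @param positions optional BW positions (e.g. `42:58`); default whole span.
#' @export
tm_ca_selection <- function(traj, map, helix, positions = NULL) {
  if (is.null(positions)) {
    resnos <- map$spans[helix, 1]:map$spans[helix, 2]
  } else {
    resnos <- map$anchors[[helix]] + (positions - 50L)
  }
  resnos <- resnos[resnos >= map$spans[helix, 1] & resnos <= map$spans[helix, 2]]
  sel <- atom_select(traj, chain = map$chain, resno = resnos, elety = "CA")
  sel[order(traj$atoms$resno[sel])]
}

#' Coordinate covariance matrix of a C-alpha subset
#'
#' Frames are superposed on `fit_sel` in two passes (fit to the first frame,
#' compute the average structure, re-fit to the average), then the
#' non-mass-weighted covariance of the `analysis_sel` C-alpha coordinates
#' about their mean is accumulated.
#'
#' @param traj an `md_trajectory` with >= 2 frames.
#' @param fit_sel atom indices for superposition (typically all receptor
#'   C-alphas).
#' @param analysis_sel atom indices whose motion is analysed.
#' @return list of class `ca_covariance`: `cov` (3N x 3N, A^2), `mean`
#'   (3N vector), `coords` (frames x 3N superposed analysis coordinates),
#'   `times`.
#' @export
build_covariance <- function(traj, fit_sel, analysis_sel) {
  if (n_frames(traj) < 2L) smd_stop("covariance needs >= 2 frames", "switchmd_structure_error")
  ref <- frame_coords(traj, 1L)
  pass1 <- lapply(seq_len(n_frames(traj)), function(i)
    superpose_frames(frame_coords(traj, i), ref, fit_sel)$coords)
  avg <- Reduce(`+`, pass1) / length(pass1)
  fitted <- lapply(seq_len(n_frames(traj)), function(i)
    superpose_frames(frame_coords(traj, i), avg, fit_sel)$coords[analysis_sel, , drop = FALSE])
  X <- t(vapply(fitted, function(m) as.vector(t(m)), numeric(3L * length(analysis_sel))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  covm <- crossprod(Xc) / nrow(Xc)
  structure(list(cov = covm, mean = mu, coords = X, times = traj$times),
            class = "ca_covariance")
}

#' Principal component analysis of a coordinate covariance
#'
#' Symmetric eigendecomposition of the covariance (eigenvalues clipped at
#' zero), with projections of the superposed frames onto the leading
#' components and identification of the extreme-projection frames along PC1.
#'
#' @param cov_obj a [build_covariance()] result.
#' @param traj unused placeholder for future external-window projection;
#'   projections use the coordinates stored in `cov_obj`.
#' @param window optional integer frame indices to project (default all).
#' @param n_components number of components to report projections for.
#' @return list of class `traj_pca`: `eigenvalues` (A^2, descending),
#'   `eigenvectors` (orthonormal columns), `projections` (frames x
#'   components, A), `variance_fraction`, `extreme_frames` (PC1 min/max),
#'   `mean`.
#' @export
pca_project <- function(cov_obj, traj = NULL, window = NULL, n_components = 2L) {
  e <- eigen(cov_obj$cov, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  if (is.null(window)) window <- seq_len(nrow(cov_obj$coords))
  if (any(window < 1L | window > nrow(cov_obj$coords)))
    smd_stop("projection window outside trajectory", "switchmd_range_error")
  k <- min(n_components, length(vals))
  Xc <- sweep(cov_obj$coords[window, , drop = FALSE], 2L, cov_obj$mean)
  proj <- Xc %*% e$vectors[, seq_len(k), drop = FALSE]
  colnames(proj) <- paste0("PC", seq_len(k))
  structure(list(eigenvalues = vals, eigenvectors = e$vectors,
                 projections = proj,
                 variance_fraction = if (sum(vals) > 0) vals / sum(vals) else vals,
                 extreme_frames = c(min = window[which.min(proj[, 1])],
                                    max = window[which.max(proj[, 1])]),
                 times = cov_obj$times[window],
                 mean = cov_obj$mean),
            class = "traj_pca")
}

#' @export
print.traj_pca <- function(x, ...) {
  vf <- x$variance_fraction
  cat(sprintf("traj_pca: %d modes; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(x$eigenvalues), 100 * vf[1], 100 * ifelse(length(vf) > 1, vf[2], 0)))
  cat(sprintf("  extreme PC1 frames: %d (min), %d (max)\n",
              x$extreme_frames["min"], x$extreme_frames["max"]))
  invisible(x)
}

# symmetric PSD square root with negative-eigenvalue clipping
psd_sqrt <- function(A) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

#' Normalized overlap of two covariance matrices
#'
#' The trace metric used to compare sampled subspaces of two simulations:
#' \deqn{\Omega = 1 - \sqrt{ tr((A^{1/2} - B^{1/2})^2) / (tr A + tr B) }}
#' It equals 1 when the matrices are identical and 0 when the sampled
#' subspaces are totally orthogonal. Matrix square roots are taken via
#' symmetric eigendecomposition with negative eigenvalues clipped to zero.
#'
#' @param A,B symmetric positive semi-definite matrices of equal dimension
#'   (or `ca_covariance` objects).
#' @return overlap value in [0, 1].
#' @export
covariance_overlap <- function(A, B) {
  if (inherits(A, "ca_covariance")) A <- A$cov
  if (inherits(B, "ca_covariance")) B <- B$cov
  if (!all(dim(A) == dim(B)))
    smd_stop("covariance matrices differ in dimension", "switchmd_structure_error")
  trA <- sum(diag(A)); trB <- sum(diag(B))
  if (trA + trB <= 0)
    smd_stop("both covariance matrices have zero trace", "switchmd_degenerate_input")
  D <- psd_sqrt(A) - psd_sqrt(B)
  num <- max(sum(D * D), 0)
  min(1, max(0, 1 - sqrt(num / (trA + trB))))
}

#' Pairwise covariance-overlap matrix
#' @param covs named list of covariance matrices or `ca_covariance` objects.
#' @return symmetric matrix with unit diagonal, labelled like the input.
#' @export
overlap_matrix <- function(covs) {
  n <- length(covs)
  out <- diag(1, n)
  labs <- names(covs) %||% paste0("traj", seq_len(n))
  dimnames(out) <- list(labs, labs)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    out[i, j] <- out[j, i] <- covariance_overlap(covs[[i]], covs[[j]])
  }
  out
}
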