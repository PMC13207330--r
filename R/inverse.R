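#' Forward model: scalp potentials from a current density
#'
#' `V = L J + eps` with i.i.d. Gaussian sensor noise, then re-referenced to
#' the average (the reference convention used throughout the inverse
#' pipeline).
#'
#' @param leadfield A `leadfield`.
#' @param J Numeric vector of per-voxel current, length = number of voxels.
#' @param noise_sd Sensor noise standard deviation (0 = noiseless).
#' @param seed Seed for the noise draw (required when `noise_sd > 0`).
#' @param average_reference Re-reference to zero mean (default TRUE).
#' @return Numeric vector of sensor potentials (class `scalp_vector` with
#'   sensor labels as names).
#' @export
forward_model <- function(leadfield, J, noise_sd = 0, seed = NULL,
                          average_reference = TRUE) {
  stopifnot(inherits(leadfield, "leadfield"))
  if (length(J) != ncol(leadfield$matrix)) {
    stop("J has length ", length(J), " but lead field has ",
         ncol(leadfield$matrix), " voxels")
  }
  V <- drop(leadfield$matrix %*% J)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required when noise_sd > 0")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    V <- V + rnorm(length(V), sd = noise_sd)
  }
  if (average_reference) V <- V - mean(V)
  names(V) <- leadfield$sensor_labels
  V
}

#' Laplacian-regularized minimum-norm inverse
#'
#' Closed-form solution of
#' `argmin_J ||V - L J||^2 + alpha ||B J||^2`
#' via the normal equations `(L'L + alpha B'B) J = L'V`. With `alpha = 0`
#' the Moore-Penrose pseudoinverse is used (tolerance 1e-10 relative to the
#' largest singular value); a singular system at `alpha = 0` raises an
#' error advising `alpha > 0`.
#'
#' @param V Scalp potential vector (will be average-referenced).
#' @param leadfield A `leadfield`.
#' @param B Voxel smoothness operator (default the head model's graph
#'   Laplacian).
#' @param alpha Regularization weight `>= 0`, or `"lcurve"` to select it by
#'   the L-curve corner on a log grid.
#' @return An object of class `current_density`: `values`, `alpha`,
#'   `residual` (`||V - LJ||`), `V` (the referenced data), `B_used`.
#' @export
inverse_minimum_norm <- function(V, leadfield, B = leadfield$laplacian,
                                 alpha = "lcurve") {
  stopifnot(inherits(leadfield, "leadfield"))
  L <- leadfield$matrix
  if (length(V) != nrow(L)) stop("V length does not match sensor count")
  V <- V - mean(V)
  L <- L - matrix(colMeans(L), nrow(L), ncol(L), byrow = TRUE)

  if (identical(alpha, "lcurve")) {
    alpha <- lcurve_alpha(V, L, B)
  }
  stopifnot(is.numeric(alpha), alpha >= 0)

  if (alpha == 0) {
    sv <- svd(L)
    tol <- 1e-10 * sv$d[1]
    pos <- sv$d > tol
    if (!any(pos)) stop("singular system at alpha = 0; use alpha > 0")
    J <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], V)) / sv$d[pos])
    J <- drop(J)
  } else {
    A <- crossprod(L) + alpha * crossprod(B)
    J <- tryCatch(drop(solve(A, crossprod(L, V))),
                  error = function(e) {
                    stop("normal equations singular; increase alpha (",
                         conditionMessage(e), ")")
                  })
  }

  structure(
    list(values = J, alpha = alpha, residual = sqrt(sum((V - L %*% J)^2)),
         V = V, B_used = !is.null(B) && alpha > 0),
    class = "current_density"
  )
}

# L-curve corner: maximum distance from the line joining the extreme
# points of the (log residual, log penalty) curve.
lcurve_alpha <- function(V, L, B, grid = 10^seq(-6, 2, length.out = 25)) {
  K <- crossprod(L)
  P <- crossprod(B)
  LtV <- crossprod(L, V)
  rho <- eta <- numeric(length(grid))
  for (i in seq_along(grid)) {
    J <- tryCatch(solve(K + grid[i] * P, LtV), error = function(e) NULL)
    if (is.null(J)) { rho[i] <- NA; eta[i] <- NA; next }
    rho[i] <- sqrt(sum((V - L %*% J)^2))
    eta[i] <- sqrt(sum((B %*% J)^2))
  }
  ok <- is.finite(rho) & is.finite(eta) & rho > 0 & eta > 0
  g <- grid[ok]; x <- log10(rho[ok]); y <- log10(eta[ok])
  if (length(g) < 3) return(grid[1])
  x1 <- x[1]; y1 <- y[1]; x2 <- x[length(x)]; y2 <- y[length(y)]
  d <- abs((x2 - x1) * (y1 - y) - (x1 - x) * (y2 - y1)) /
    sqrt((x2 - x1)^2 + (y2 - y1)^2)
  g[which.max(d)]
}

#' sLORETA standardization of a source estimate
#'
#' Classic standardized low-resolution map: with the minimum-norm transfer
#' operator `T = L'(LL' + alpha I)^-1`, each voxel estimate is divided by
#' the square root of the corresponding diagonal entry of the resolution
#' matrix `R = T L`, and scores are the squared standardized estimates.
#' Because `R` is symmetric positive semidefinite, a noiseless single
#' source is always localized exactly (zero localization error). Ties at
#' the maximum resolve to the lowest voxel index; all tied indices are
#' reported.
#'
#' @param J A `current_density` from [inverse_minimum_norm()] (supplies the
#'   referenced data vector) or a raw scalp vector.
#' @param leadfield A `leadfield`.
#' @param alpha Regularization used for the standardizing operator; default
#'   the one stored in `J`.
#' @return An object of class `source_map`: `scores` (per voxel, >= 0),
#'   `peak_voxel`, `tied_peaks`, `roi_labels`, `alpha`.
#' @export
sloreta_standardize <- function(J, leadfield, alpha = NULL) {
  stopifnot(inherits(leadfield, "leadfield"))
  if (inherits(J, "current_density")) {
    V <- J$V
    if (is.null(alpha)) alpha <- J$alpha
  } else {
    V <- J - mean(J)
    if (is.null(alpha)) alpha <- 1e-6
  }
  if (alpha <= 0) alpha <- 1e-10
  L <- leadfield$matrix
  L <- L - matrix(colMeans(L), nrow(L), ncol(L), byrow = TRUE)
  M <- tcrossprod(L) + alpha * diag(nrow(L))
  W <- solve(M)
  Tm <- crossprod(L, W)                     # voxels x sensors
  Jstd <- drop(Tm %*% V)
  Rdiag <- rowSums(Tm * t(L))               # diag(T L)
  if (any(Rdiag <= 0)) {
    stop("non-positive resolution variance at voxel(s) ",
         paste(utils::head(which(Rdiag <= 0)), collapse = ", "),
         "; lead field may contain a null column")
  }
  scores <- Jstd^2 / Rdiag
  mx <- max(scores)
  tied <- which(scores >= mx * (1 - 1e-9))
  structure(
    list(scores = scores, peak_voxel = tied[1], tied_peaks = tied,
         roi_labels = leadfield$roi_labels, alpha = alpha),
    class = "source_map"
  )
}

#' @export
print.source_map <- function(x, ...) {
  cat(sprintf("<source_map> %d voxels, peak at voxel %d (%s), alpha=%.3g\n",
              length(x$scores), x$peak_voxel, x$roi_labels[x$peak_voxel],
              x$alpha))
  invisible(x)
}

#' Mean standardized power over a region of interest
#'
#' @param map A `source_map`.
#' @param roi ROI label present in the map (e.g. `"Precuneus"`, `"PCC"`).
#' @return Scalar mean score over the ROI's voxels.
#' @export
roi_power <- function(map, roi) {
  stopifnot(inherits(map, "source_map"))
  sel <- map$roi_labels == roi
  if (!any(sel)) stop("ROI '", roi, "' has no voxels in this map")
  mean(map$scores[sel])
}
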