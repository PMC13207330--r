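#' Build a toy head model (lead field + voxel Laplacian)
#'
#' Spherical geometry: 19 sensors at idealized 10-20 positions on the unit
#' sphere and voxels on an inner shell (radius 0.7, quasi-uniform Fibonacci
#' directions). The gain of a radial unit dipole at eccentricity `b` seen
#' at surface angle `gamma` follows the analytic homogeneous-sphere
#' solution
#' \deqn{V(\gamma) \propto \sum_{n \ge 1} (2n+1)\, b^{\,n-1} P_n(\cos\gamma)}
#' (Legendre series, truncated at n = 60). Random geometry substitutes a
#' seeded well-conditioned Gaussian matrix for property tests. Voxels carry
#' ROI labels: a posterior-midline superior block is `Precuneus`, the block
#' beneath it `PCC`, the rest `other`.
#'
#' @param n_sensors Number of sensors (19 = the standard montage;
#'   spherical geometry requires 19).
#' @param n_voxels Number of voxels, at least `n_sensors` (default 60).
#' @param geometry `"spherical"` or `"random"`.
#' @param seed Seed for the random geometry (ignored for spherical, which
#'   is deterministic).
#' @param cond_warn Condition-number threshold above which a warning is
#'   recorded (default 1e8).
#' @return An object of class `leadfield`: `matrix` (sensors x voxels),
#'   `sensor_labels`, `voxel_positions`, `roi_labels`, `laplacian`
#'   (voxel x voxel, symmetric, zero row sums), `condition_number`,
#'   `geometry`.
#' @export
build_toy_headmodel <- function(n_sensors = 19L, n_voxels = 60L,
                                geometry = c("spherical", "random"),
                                seed = 1L, cond_warn = 1e8) {
  geometry <- match.arg(geometry)
  if (n_voxels < n_sensors) stop("n_voxels must be >= n_sensors")

  if (geometry == "spherical") {
    if (n_sensors != 19L) stop("spherical geometry uses the 19-channel 10-20 montage")
    sensors <- standard_1020_positions()
    # brain voxels live under the sensor cap: upper hemisphere only
    vox_dir <- fibonacci_hemisphere(n_voxels)
    vox <- vox_dir * 0.7
    L <- sphere_gain_matrix(sensors, vox)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    sensors <- NULL
    vox <- matrix(runif(n_voxels * 3, -0.7, 0.7), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z")))
    L <- matrix(rnorm(n_sensors * n_voxels), n_sensors, n_voxels)
    rownames(L) <- sprintf("S%02d", seq_len(n_sensors))
  }

  roi <- voxel_roi_labels(vox)
  sv <- svd(L)$d
  cond <- sv[1] / sv[length(sv)]
  if (!is.finite(cond) || cond > cond_warn) {
    warning("lead field condition number ", format(cond, digits = 3),
            " exceeds threshold")
  }

  lap <- voxel_laplacian(vox, k = 6L)

  structure(
    list(matrix = L, sensor_labels = rownames(L), voxel_positions = vox,
         roi_labels = roi, laplacian = lap, condition_number = cond,
         geometry = geometry,
         full_column_rank = sum(sv > max(dim(L)) * .Machine$double.eps * sv[1]) == min(dim(L))),
    class = "leadfield"
  )
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d sensors x %d voxels (%s), cond %.3g\n",
              nrow(x$matrix), ncol(x$matrix), x$geometry, x$condition_number))
  cat("  ROI voxels:", sum(x$roi_labels == "Precuneus"), "Precuneus,",
      sum(x$roi_labels == "PCC"), "PCC\n")
  invisible(x)
}

# Quasi-uniform directions on the unit sphere (deterministic).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta), z = cos(phi))
}

# Quasi-uniform directions on the upper hemisphere (z > 0).
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - i / n)            # inclination in (0, pi/2)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta), z = cos(phi))
}

# Analytic homogeneous-sphere radial-dipole surface gain.
# sensors: m x 3 on the unit sphere; voxels: v x 3 inside it.
sphere_gain_matrix <- function(sensors, voxels, n_terms = 60L) {
  b <- sqrt(rowSums(voxels^2))
  vox_dir <- voxels / b
  cosg <- tcrossprod(sensors, vox_dir)          # m x v, cos(gamma)
  cosg <- pmin(pmax(cosg, -1), 1)
  G <- matrix(0, nrow(sensors), nrow(voxels),
              dimnames = list(rownames(sensors), NULL))
  # Legendre polynomials by recurrence, accumulated term by term.
  Pnm1 <- matrix(1, nrow(sensors), nrow(voxels))   # P_0
  Pn <- cosg                                       # P_1
  bpow <- matrix(1, nrow(sensors), nrow(voxels))   # b^(n-1) for n = 1
  brow <- matrix(b, nrow(sensors), nrow(voxels), byrow = TRUE)
  for (n in seq_len(n_terms)) {
    G <- G + (2 * n + 1) * bpow * Pn
    Pnp1 <- ((2 * n + 1) * cosg * Pn - n * Pnm1) / (n + 1)
    Pnm1 <- Pn
    Pn <- Pnp1
    bpow <- bpow * brow
  }
  G / (4 * pi)
}

# Posterior-midline ROI blocks in the unit head frame
# (y anterior, so posterior = y < 0; Precuneus superior, PCC beneath).
voxel_roi_labels <- function(vox) {
  roi <- rep("other", nrow(vox))
  post_mid <- vox[, "y"] < -0.2 & abs(vox[, "x"]) < 0.35
  roi[post_mid & vox[, "z"] > 0.25] <- "Precuneus"
  roi[post_mid & vox[, "z"] <= 0.25] <- "PCC"
  roi
}

# Symmetric graph Laplacian (D - A) on the k-nearest-neighbour voxel graph.
voxel_laplacian <- function(vox, k = 6L) {
  n <- nrow(vox)
  d2 <- as.matrix(stats::dist(vox))^2
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[2:(k + 1L)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A))               # symmetrize
  diag(A) <- 0
  diag(rowSums(A)) - A
}
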