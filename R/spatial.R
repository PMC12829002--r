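#' Matern correlation function
#'
#' Correlation between two points a distance `d` apart under the Matern
#' family with smoothness `nu` and spatial range `rho`, using the range
#' convention `kappa = sqrt(8 * nu) / rho` so that the correlation at
#' `d = rho` is approximately 0.1 (0.139 for `nu = 1`). The range is the
#' distance at which between-herd environmental correlation has essentially
#' died out.
#'
#' @param d Non-negative distance(s), km.
#' @param rho Spatial range, km (> 0).
#' @param nu Smoothness; fixed at 1 throughout the package (the 2-D
#'   Whittle/SPDE default), but exposed for completeness.
#' @return Correlation value(s) in `[0, 1]`; exactly 1 at `d = 0`.
#' @examples
#' matern_correlation(0, 30)            # 1
#' matern_correlation(30, 30)           # ~0.139, "near 0.1"
#' @export
matern_correlation <- function(d, rho, nu = 1) {
  if (any(!is.finite(d)) || any(d < 0)) {
    stop_sg("`d` must be finite and non-negative.", "invalid_distance")
  }
  if (!is.finite(rho) || rho <= 0) {
    stop_sg("`rho` must be a positive finite range (km).", "invalid_range")
  }
  if (!is.finite(nu) || nu <= 0) {
    stop_sg("`nu` must be positive.", "invalid_range")
  }
  kappa <- sqrt(8 * nu) / rho
  x <- kappa * d
  out <- numeric(length(x))
  pos <- x > 0
  out[!pos] <- 1
  xp <- x[pos]
  # besselK underflows for large x; correlation is 0 there anyway
  out[pos] <- (2^(1 - nu) / gamma(nu)) * xp^nu * besselK(xp, nu)
  out[!is.finite(out)] <- 0
  pmin(pmax(out, 0), 1)
}

#' Spatial kernel over herd locations
#'
#' Bundles herd ids, projected coordinates (km), the Euclidean distance
#' matrix and the Matern hyper-parameters into a kernel object used by the
#' simulator and the model fitter.
#'
#' @param herds Data frame with columns `herd_id`, `x_km`, `y_km`.
#' @param rho Spatial range, km.
#' @param sigma2_s Spatial variance (phenotypic-variance units).
#' @param nu Matern smoothness (default 1).
#' @return An object of class `spatial_kernel`.
#' @export
spatial_kernel <- function(herds, rho, sigma2_s = 1, nu = 1) {
  herds <- as_tibble(herds)
  need <- c("herd_id", "x_km", "y_km")
  miss <- setdiff(need, names(herds))
  if (length(miss)) {
    stop_sg(paste0("herd table lacks column(s): ", paste(miss, collapse = ", ")),
            "schema")
  }
  if (anyDuplicated(herds$herd_id)) {
    stop_sg("duplicate herd ids in herd table.", "schema")
  }
  xy <- cbind(herds$x_km, herds$y_km)
  if (any(!is.finite(xy))) {
    stop_sg("non-finite herd coordinates.", "invalid_coordinates")
  }
  if (!is.finite(sigma2_s) || sigma2_s < 0) {
    stop_sg("`sigma2_s` must be non-negative.", "invalid_variance")
  }
  D <- as.matrix(stats::dist(xy))
  dimnames(D) <- list(herds$herd_id, herds$herd_id)
  structure(
    list(herd_id = as.character(herds$herd_id), coords = xy, dist = D,
         rho = rho, sigma2_s = sigma2_s, nu = nu),
    class = "spatial_kernel"
  )
}

#' @export
print.spatial_kernel <- function(x, ...) {
  cat("<spatial_kernel> ", length(x$herd_id), " herds, rho = ", x$rho,
      " km, sigma2_s = ", x$sigma2_s, ", nu = ", x$nu, "\n", sep = "")
  invisible(x)
}

#' Matern covariance matrix over herd locations
#'
#' Entry (i, j) is `sigma2_s * matern_correlation(S_ij, rho, nu)` where `S`
#' is the Euclidean distance matrix between herd locations. Duplicated
#' locations get correlation exactly 1. A floating-point PSD repair adds
#' diagonal jitter `1e-8 * sigma2_s` when the minimum eigenvalue falls below
#' `-1e-8` times the maximum (logged via a message).
#'
#' @param kernel A [spatial_kernel()].
#' @return Symmetric positive semi-definite covariance matrix.
#' @export
spatial_covariance <- function(kernel) {
  stopifnot(inherits(kernel, "spatial_kernel"))
  C <- kernel$sigma2_s * matern_cor_matrix(kernel$dist, kernel$rho, kernel$nu)
  if (kernel$sigma2_s > 0) {
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(ev)) {
      inform("spatial covariance: adding 1e-8*sigma2_s diagonal jitter (PSD repair)")
      C <- C + diag(1e-8 * kernel$sigma2_s, nrow(C))
    }
  }
  C
}

# correlation matrix from a distance matrix; keeps exact 1 on zero distances.
# Hot path for the sampler: skips besselK where the correlation underflows
# (kappa*d > 38 gives correlation < 1e-14) and bypasses argument checks.
matern_cor_matrix <- function(D, rho, nu = 1) {
  q <- nrow(D)
  ut <- upper.tri(D)
  x <- sqrt(8 * nu) / rho * D[ut]
  out <- numeric(length(x))
  out[x == 0] <- 1
  mid <- x > 0 & x < 38
  xm <- x[mid]
  out[mid] <- (2^(1 - nu) / gamma(nu)) * xm^nu * besselK(xm, nu)
  R <- matrix(0, q, q)
  R[ut] <- out
  R <- R + t(R)
  diag(R) <- 1
  dimnames(R) <- dimnames(D)
  R
}

#' Approximate lon/lat to km projection (toy use only)
#'
#' Equirectangular approximation around the centroid latitude. This is an
#' intentionally rough utility for toy coordinates; real analyses should
#' supply properly projected km coordinates from a local equal-area
#' projection.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @return Tibble with `x_km`, `y_km`.
#' @export
lonlat_to_km <- function(lon, lat) {
  lat0 <- mean(lat) * pi / 180
  tibble(x_km = 111.32 * cos(lat0) * (lon - mean(lon)),
         y_km = 110.57 * (lat - mean(lat)))
}
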