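#' Map the posterior-mean spatial field
#'
#' Kriges the posterior-mean spatial effect from the fitted herd locations
#' onto a regular grid using the Matern conditional mean at the
#' posterior-mean range, and draws it with the herd locations overlaid.
#'
#' @param fit A `gblup_fit` from a spatial model.
#' @param grid_res Grid resolution per axis (default 60).
#' @param expand_km Margin around the herd bounding box (default 30 km).
#' @return A ggplot object.
#' @export
plot_spatial_field <- function(fit, grid_res = 60, expand_km = 30) {
  if (is.null(fit$draws$s)) {
    stop_sg("model has no spatial term.", "unsupported_model")
  }
  xy <- fit$kernel_coords
  s_hat <- rowMeans(fit$draws$s)
  rho <- mean(fit$draws$vc[, "rho"])
  gx <- seq(min(xy[, 1]) - expand_km, max(xy[, 1]) + expand_km,
            length.out = grid_res)
  gy <- seq(min(xy[, 2]) - expand_km, max(xy[, 2]) + expand_km,
            length.out = grid_res)
  grid <- as.matrix(expand.grid(x_km = gx, y_km = gy))
  D_oo <- as.matrix(stats::dist(xy))
  R_oo <- matern_cor_matrix(D_oo, rho) + diag(1e-8, nrow(xy))
  cross_d <- sqrt(outer(grid[, 1], xy[, 1], "-")^2 +
                    outer(grid[, 2], xy[, 2], "-")^2)
  R_go <- matrix(matern_correlation(as.vector(cross_d), rho),
                 nrow(grid), nrow(xy))
  s_grid <- drop(R_go %*% solve(R_oo, s_hat))
  df <- tibble(x_km = grid[, 1], y_km = grid[, 2], spatial = s_grid)
  pts <- tibble(x_km = xy[, 1], y_km = xy[, 2])
  ggplot2::ggplot(df, ggplot2::aes(.data$x_km, .data$y_km)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$spatial)) +
    ggplot2::geom_point(data = pts, size = 0.3, alpha = 0.5) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Easting (km)", y = "Northing (km)",
                  fill = "Spatial effect\n(phenotypic sd)",
                  title = paste0("Posterior-mean spatial field (", fit$model, ")"))
}

#' @export
autoplot.ebv_shift <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$spatial, .data$delta)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#b2182b") +
    ggplot2::labs(x = "Estimated spatial effect at the animal's herd",
                  y = "EBV difference (non-spatial - spatial model)",
                  subtitle = sprintf("slope = %.3f, R² = %.2f",
                                     object$slope, object$r_squared))
}

#' @export
autoplot.gblup_validation <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(as_tibble(object), .data$group != "overall"),
                  ggplot2::aes(.data$group, .data$accuracy, fill = .data$model)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~grouping, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Prediction accuracy (Pearson r)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
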