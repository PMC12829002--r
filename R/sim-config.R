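#' Simulation configuration
#'
#' Holds every knob of the synthetic smallholder-dairy generator. The
#' defaults emulate the structure of East African smallholder test-day
#' recording at desk scale: ~500 admixed cows spread over ~340 herds in four
#' spatially clustered regions, >71% single-cow herds, ~10 repeated test-day
#' records per cow, and a phenotype whose variance decomposes into genomic,
#' herd, spatial, permanent-environment and residual parts expressed in
#' phenotypic-variance units (so they sum to roughly 1 for standardised
#' yield).
#'
#' @param n_animals Number of cows.
#' @param n_snps Number of SNP markers.
#' @param n_regions Number of geographic clusters (default 4).
#' @param region_centres Matrix/list of region centre coordinates (km); one
#'   row per region. Defaults to four well-separated centres a few hundred
#'   km apart.
#' @param region_spread_km Isotropic Gaussian scatter (sd, km) of ward
#'   centres around their region centre (default 50, matching regional
#'   cluster extents of one to two hundred km).
#' @param wards_per_region Number of wards (village-scale clusters of
#'   herds) per region; the motivating data sit in 72 wards across 4
#'   regions, so the default is 18.
#' @param herd_spread_km Scatter (sd, km) of herds around their ward
#'   centre; wards are a few km across (default 3).
#' @param herd_size_pmf Probability vector over herd sizes 1..9; must sum
#'   to 1. Default reproduces >71% singleton herds and >93% herds with
#'   fewer than 3 cows.
#' @param ancestral_freqs Optional list with vectors `exotic` and
#'   `indigenous` of per-SNP allele frequencies in (0,1); drawn
#'   Uniform(0.05, 0.95) per pool if NULL.
#' @param admixture_alpha Beta shape pair for each cow's exotic genome
#'   proportion when no regional structure is used. The default (2.6, 0.8)
#'   matches the observed four-class admixture composition of the motivating
#'   population.
#' @param region_exotic_means Mean exotic-genome proportion per region
#'   (recycled to `n_regions`), with per-cow draws
#'   `Beta(mu_r * nu, (1 - mu_r) * nu)` where `nu = sum(admixture_alpha)`.
#'   Smallholder regions differ systematically in admixture (some clusters
#'   import far more exotic germplasm), and this genetics-by-geography
#'   correlation is what lets environmental gradients leak into breeding
#'   values; `NULL` draws admixture independently of region.
#' @param var_g,var_h,var_s,var_p,var_e Genomic, herd, spatial,
#'   permanent-environment and residual variances (phenotypic-variance
#'   units).
#' @param spatial_range_km Matern range `rho` of the simulated spatial
#'   field, km.
#' @param records_per_cow Mean of the Poisson number of test-day records per
#'   cow (minimum 1 enforced).
#' @param dim_range Closed days-in-milk range, default `c(4, 500)`.
#' @param birth_years Possible birth years.
#' @param mean_yield_l,sd_yield_l Affine map from the standardised latent
#'   phenotype to litres for the written `milk_yield` column (defaults 8.3
#'   and 4.3 L, the field-typical test-day mean and sd).
#' @param fixed_effect_sd sd of the non-intercept true fixed-effect
#'   coefficients (standardised scale).
#' @param seed Integer seed; the whole generator is deterministic given the
#'   config.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_animals = 500,
                       n_snps = 2000,
                       n_regions = 4,
                       region_centres = NULL,
                       region_spread_km = 50,
                       wards_per_region = 18,
                       herd_spread_km = 3,
                       herd_size_pmf = c(0.71, 0.22, 0.05, 0.008, 0.005,
                                         0.003, 0.002, 0.001, 0.001),
                       ancestral_freqs = NULL,
                       admixture_alpha = c(2.6, 0.8),
                       region_exotic_means = c(0.82, 0.65, 0.72, 0.85),
                       var_g = 0.15, var_h = 0.15, var_s = 0.3,
                       var_p = 0, var_e = 0.3,
                       spatial_range_km = 30,
                       records_per_cow = 10,
                       dim_range = c(4, 500),
                       birth_years = 2012:2017,
                       mean_yield_l = 8.3, sd_yield_l = 4.3,
                       fixed_effect_sd = 0.1,
                       seed = 1L) {
  if (is.null(region_centres)) {
    region_centres <- matrix(c(500, 950,   # North-Central-like cluster
                               900, 700,   # North-East-like cluster
                               600, 300,   # South-Central-like cluster
                               200, 150),  # South-West-like cluster
                             ncol = 2, byrow = TRUE)[seq_len(min(n_regions, 4)), ,
                                                     drop = FALSE]
    if (n_regions > 4) {
      extra <- n_regions - 4
      region_centres <- rbind(region_centres,
                              cbind(runif(extra, 0, 1000), runif(extra, 0, 1000)))
    }
  }
  region_centres <- matrix(unlist(region_centres), ncol = 2)
  cfg <- list(n_animals = as.integer(n_animals), n_snps = as.integer(n_snps),
              n_regions = as.integer(n_regions),
              region_centres = region_centres,
              region_spread_km = region_spread_km,
              wards_per_region = as.integer(wards_per_region),
              herd_spread_km = herd_spread_km,
              herd_size_pmf = herd_size_pmf,
              ancestral_freqs = ancestral_freqs,
              admixture_alpha = admixture_alpha,
              region_exotic_means =
                if (!is.null(region_exotic_means))
                  rep_len(region_exotic_means, n_regions),
              var_g = var_g, var_h = var_h, var_s = var_s,
              var_p = var_p, var_e = var_e,
              spatial_range_km = spatial_range_km,
              records_per_cow = records_per_cow,
              dim_range = dim_range, birth_years = birth_years,
              mean_yield_l = mean_yield_l, sd_yield_l = sd_yield_l,
              fixed_effect_sd = fixed_effect_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_animals < 1 || cfg$n_snps < 1) {
    stop_sg("n_animals and n_snps must be at least 1.", "invalid_config")
  }
  if (length(cfg$herd_size_pmf) == 0 || any(cfg$herd_size_pmf < 0) ||
      abs(sum(cfg$herd_size_pmf) - 1) > 1e-8) {
    stop_sg("herd_size_pmf must be a non-negative vector summing to 1.",
            "invalid_config")
  }
  vs <- c(cfg$var_g, cfg$var_h, cfg$var_s, cfg$var_p, cfg$var_e)
  if (any(!is.finite(vs)) || any(vs < 0)) {
    stop_sg("all variance components must be finite and >= 0.", "invalid_config")
  }
  if (nrow(cfg$region_centres) != cfg$n_regions) {
    stop_sg("region_centres must have one row per region.", "invalid_config")
  }
  if (cfg$spatial_range_km <= 0 || cfg$region_spread_km <= 0 ||
      cfg$herd_spread_km <= 0 || cfg$wards_per_region < 1) {
    stop_sg("spatial_range_km, region_spread_km, herd_spread_km must be positive and wards_per_region >= 1.",
            "invalid_config")
  }
  if (!is.null(cfg$ancestral_freqs)) {
    fr <- unlist(cfg$ancestral_freqs)
    if (any(fr <= 0) || any(fr >= 1)) {
      stop_sg("ancestral frequencies must lie strictly inside (0, 1).",
              "invalid_config")
    }
  }
  if (length(cfg$admixture_alpha) != 2 || any(cfg$admixture_alpha <= 0)) {
    stop_sg("admixture_alpha must be two positive Beta shapes.", "invalid_config")
  }
  if (!is.null(cfg$region_exotic_means) &&
      (any(cfg$region_exotic_means <= 0) || any(cfg$region_exotic_means >= 1))) {
    stop_sg("region_exotic_means must lie strictly inside (0, 1).",
            "invalid_config")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_animals, " cows, ", x$n_snps, " SNPs, ",
      x$n_regions, " regions; var (g,h,s,p,e) = (",
      paste(c(x$var_g, x$var_h, x$var_s, x$var_p, x$var_e), collapse = ", "),
      "); rho = ", x$spatial_range_km, " km; seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Exotic-genome class from percentage
#'
#' Maps the percentage of exotic genome to the four admixture classes used
#' as a fixed effect: C1 for at least 87.5%, C2 for [60, 87.5), C3 for
#' [36, 60), C4 below 36. Intervals are closed at their lower bound, so the
#' printed boundary values 87.5, 60 and 36 fall in the upper class.
#'
#' @param exotic_pct Percentage in `[0, 100]` (vectorised).
#' @return Factor with levels C1..C4.
#' @export
assign_exotic_class <- function(exotic_pct) {
  if (any(!is.finite(exotic_pct)) || any(exotic_pct < 0) || any(exotic_pct > 100)) {
    stop_sg("exotic_pct must lie in [0, 100].", "invalid_config")
  }
  cls <- cut(exotic_pct, breaks = c(-Inf, 36, 60, 87.5, Inf),
             labels = c("C4", "C3", "C2", "C1"), right = FALSE)
  factor(as.character(cls), levels = c("C1", "C2", "C3", "C4"))
}
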