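#' Simulate admixed SNP genotypes
#'
#' Each cow's exotic genome proportion is drawn from
#' `Beta(admixture_alpha)`; each SNP dosage is Binomial(2, p) with p the
#' admixture-weighted mixture of the exotic-pool and indigenous-pool allele
#' frequencies. This produces a one-dimensional admixture gradient in the
#' genotypes, the dominant genetic structure of the target population.
#'
#' @param config A [sim_config()].
#' @param region Optional integer/character region per animal; when given
#'   (and `region_exotic_means` is set) each cow's exotic proportion is
#'   drawn from the Beta distribution of its region, reproducing the
#'   regional admixture imbalance of smallholder populations.
#' @return List with `geno` (a [genotype_matrix()]) and `admixture` (tibble
#'   of `animal_id`, `exotic_pct`, `exotic_class`).
#' @export
simulate_admixed_genotypes <- function(config, region = NULL) {
  validate_sim_config(config)
  set.seed(config$seed)
  sim_genotypes_impl(config, region)$out
}

# internal: also returns pool frequencies for reuse inside simulate_dataset
sim_genotypes_impl <- function(config, region = NULL) {
  n <- config$n_animals; m <- config$n_snps
  fr <- config$ancestral_freqs
  if (is.null(fr)) {
    fr <- list(exotic = runif(m, 0.05, 0.95), indigenous = runif(m, 0.05, 0.95))
  }
  if (length(fr$exotic) != m || length(fr$indigenous) != m) {
    stop_sg("ancestral frequency vectors must have length n_snps.",
            "invalid_config")
  }
  if (!is.null(region) && !is.null(config$region_exotic_means)) {
    if (length(region) != n) {
      stop_sg("`region` must give one region per animal.", "dimension_mismatch")
    }
    ri <- as.integer(factor(region, levels = sort(unique(region))))
    nu <- sum(config$admixture_alpha)
    mu <- config$region_exotic_means[ri]
    prop <- rbeta(n, mu * nu, (1 - mu) * nu)
  } else {
    prop <- rbeta(n, config$admixture_alpha[1], config$admixture_alpha[2])
  }
  P <- outer(prop, fr$exotic) + outer(1 - prop, fr$indigenous)  # n x m
  M <- matrix(rbinom(n * m, 2L, as.vector(P)), n, m)
  ids <- sprintf("A%04d", seq_len(n))
  geno <- genotype_matrix(M, animal_id = ids,
                          snp_id = sprintf("snp%05d", seq_len(m)))
  adm <- tibble(animal_id = ids, exotic_pct = 100 * prop,
                exotic_class = assign_exotic_class(100 * prop))
  list(out = list(geno = geno, admixture = adm), freqs = fr)
}

#' Simulate herds, locations and animal assignment
#'
#' Herd sizes are drawn from `herd_size_pmf` until the configured number of
#' animals is tiled (the last herd truncated if needed); each herd gets a
#' region (uniform over regions) and a location scattered isotropically
#' (sd `region_spread_km`) around the region centre.
#'
#' @param config A [sim_config()].
#' @return List with `herds` (tibble `herd_id`, `region`, `x_km`, `y_km`)
#'   and `animals` (tibble `animal_id`, `herd_id`).
#' @export
simulate_herds <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  sim_herds_impl(config)
}

sim_herds_impl <- function(config) {
  n <- config$n_animals
  pmf <- config$herd_size_pmf
  sizes_draw <- sample(seq_along(pmf), size = n, replace = TRUE, prob = pmf)
  cum <- cumsum(sizes_draw)
  k <- which(cum >= n)[1]
  sizes <- sizes_draw[seq_len(k)]
  sizes[k] <- sizes[k] - (cum[k] - n)  # truncate last herd to tile exactly
  nh <- length(sizes)
  # ward-level clustering: herds sit a few km around ward centres, which in
  # turn scatter tens of km around the region centre
  nw <- config$n_regions * config$wards_per_region
  ward_region <- rep(seq_len(config$n_regions), each = config$wards_per_region)
  wc <- config$region_centres[ward_region, , drop = FALSE] +
    matrix(rnorm(2 * nw, 0, config$region_spread_km), nw, 2)
  wi <- sample.int(nw, nh, replace = TRUE)
  herds <- tibble(
    herd_id = sprintf("H%04d", seq_len(nh)),
    region = paste0("R", ward_region[wi]),
    ward = sprintf("W%03d", wi),
    x_km = wc[wi, 1] + rnorm(nh, 0, config$herd_spread_km),
    y_km = wc[wi, 2] + rnorm(nh, 0, config$herd_spread_km)
  )
  animals <- tibble(
    animal_id = sprintf("A%04d", seq_len(n)),
    herd_id = rep(herds$herd_id, times = sizes)
  )
  list(herds = herds, animals = animals)
}

#' Simulate a Matern spatial field over herds
#'
#' One draw from a zero-mean Gaussian with covariance
#' `sigma2_s * Matern(distance; rho, nu = 1)`. Duplicated coordinates are
#' collapsed before sampling so they receive exactly identical values.
#'
#' @param herds Tibble with `herd_id`, `x_km`, `y_km`.
#' @param rho Matern range, km.
#' @param var_s Spatial variance; 0 gives an exactly zero field.
#' @param seed Integer seed.
#' @return Tibble `herd_id`, `spatial` in the input herd order.
#' @export
simulate_spatial_field <- function(herds, rho, var_s, seed = 1L) {
  if (any(!is.finite(herds$x_km)) || any(!is.finite(herds$y_km))) {
    stop_sg("non-finite herd coordinates.", "invalid_coordinates")
  }
  if (var_s < 0) stop_sg("var_s must be >= 0.", "invalid_variance")
  set.seed(seed)
  tibble(herd_id = as.character(herds$herd_id),
         spatial = sim_field_impl(herds, rho, var_s))
}

sim_field_impl <- function(herds, rho, var_s) {
  nh <- nrow(herds)
  if (var_s == 0) return(rep(0, nh))
  key <- paste(herds$x_km, herds$y_km)
  uni <- !duplicated(key)
  hu <- herds[uni, , drop = FALSE]
  K <- spatial_kernel(hu[, c("herd_id", "x_km", "y_km")], rho = rho,
                      sigma2_s = var_s)
  C <- spatial_covariance(K) + diag(1e-10 * var_s, sum(uni))
  L <- chol(C)
  su <- drop(crossprod(L, rnorm(sum(uni))))
  su[match(key, key[uni])]
}

#' Simulate test-day phenotypes with known truth
#'
#' Builds the full record table and the latent phenotype
#' `y = X b + a + h + s + p + e` on the standardised scale:
#' breeding values come from per-marker effects
#' `alpha ~ N(0, var_g / (2 sum p(1-p)))` applied to centred dosages (so
#' `var(a)` matches `var_g` under the VanRaden scaling and the simulated
#' architecture is exactly the GBLUP model); herd, permanent-environment
#' and residual effects are iid normal; the spatial effect is the supplied
#' field at each record's herd. Fixed-effect contributions use the same
#' design construction as the fitter ([build_design()]), with true
#' coefficients drawn `N(0, fixed_effect_sd^2)` (intercept 0). The written
#' `milk_yield` is the affine map of the latent standardised phenotype to
#' litres.
#'
#' @param config A [sim_config()].
#' @param geno Output of [simulate_admixed_genotypes()].
#' @param herds Output of [simulate_herds()].
#' @param field Output of [simulate_spatial_field()].
#' @return List with `phenotypes` (tibble, one row per test-day record) and
#'   `truth` (a `sim_truth` list of all simulated components).
#' @export
simulate_phenotypes <- function(config, geno, herds, field) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  sim_phenotypes_impl(config, geno, herds, field)
}

sim_phenotypes_impl <- function(config, geno, herds, field) {
  animals <- herds$animals
  n <- nrow(animals)
  if (n != config$n_animals || nrow(geno$geno) != n) {
    stop_sg("animal counts disagree between genotype and herd inputs.",
            "dimension_mismatch")
  }
  if (!identical(sort(field$herd_id), sort(herds$herds$herd_id))) {
    stop_sg("spatial field herds do not match the herd table.",
            "dimension_mismatch")
  }

  # --- animal-level structure ---------------------------------------------
  birth_year <- sample(config$birth_years, n, replace = TRUE)
  n_par <- pmin(sample.int(5, n, replace = TRUE, prob = c(.35, .3, .2, .1, .05)), 9L)
  age_first <- round(rnorm(n, 30, 4))            # months at first calving
  age_first <- pmax(age_first, 16)               # a few below the 18-mo filter

  # --- breeding values from marker effects --------------------------------
  M <- unclass(geno$geno)
  p <- colMeans(M) / 2
  sc <- 2 * sum(p * (1 - p))
  alpha <- rnorm(ncol(M), 0, sqrt(config$var_g / sc))
  a <- drop(sweep(M, 2, 2 * p) %*% alpha)

  nh <- nrow(herds$herds)
  h <- rnorm(nh, 0, sqrt(config$var_h))
  pe <- rnorm(n, 0, sqrt(config$var_p))
  s <- field$spatial[match(herds$herds$herd_id, field$herd_id)]

  # --- records: one current lactation per cow, ~monthly tests -------------
  nrec <- pmax(1L, rpois(n, config$records_per_cow))
  rec <- tibble(
    animal_id = rep(animals$animal_id, nrec),
    herd_id = rep(animals$herd_id, nrec),
    birth_year = rep(birth_year, nrec),
    parity_raw = rep(n_par, nrec)
  )
  nr <- nrow(rec)
  # age at the current calving: first-calving age plus ~13.5 months per parity
  age_calv <- rep(age_first, nrec) + (rec$parity_raw - 1) * round(rnorm(nr, 13.5, 1.5))
  calv_month <- sample.int(12, nr, replace = TRUE)
  # all records of a cow share one calving (repeatability structure)
  first_of <- !duplicated(rec$animal_id)
  age_calv <- age_calv[rep(which(first_of), nrec)]
  calv_month <- calv_month[rep(which(first_of), nrec)]
  calving_year <- rec$birth_year + age_calv %/% 12
  dim <- integer(nr)
  for (i in seq_len(n)) {
    idx <- which(rec$animal_id == animals$animal_id[i])
    k <- length(idx)
    start <- sample(config$dim_range[1]:60, 1)
    d <- start + round(cumsum(c(0, rnorm(k - 1, 30, 5))))
    dim[idx] <- pmin(pmax(d, config$dim_range[1]), config$dim_range[2])
  }
  test_month <- 1 + (calv_month - 1 + dim %/% 30) %% 12
  test_year <- calving_year + (calv_month - 1 + dim %/% 30) %/% 12

  adm <- geno$admixture
  rec <- rec |>
    dplyr::mutate(
      region = herds$herds$region[match(.data$herd_id, herds$herds$herd_id)],
      parity = recode_parity(.data$parity_raw),
      dim = dim,
      age_at_calving = age_calv,
      age_first_calving = rep(age_first, nrec),
      calving_year = calving_year,
      calving_season = calving_season_of(calv_month),
      test_year = test_year,
      test_month = test_month,
      exotic_pct = adm$exotic_pct[match(.data$animal_id, adm$animal_id)]
    ) |>
    dplyr::select(-"parity_raw")

  # --- fixed effects through the shared design definition -----------------
  ds <- build_design(rec, model_spec())
  b <- c(0, rnorm(ncol(ds$X) - 1, 0, config$fixed_effect_sd))
  xb <- drop(ds$X %*% b)

  ia <- match(rec$animal_id, animals$animal_id)
  ih <- match(rec$herd_id, herds$herds$herd_id)
  e <- rnorm(nr, 0, sqrt(config$var_e))
  y <- unname(xb + a[ia] + h[ih] + s[ih] + pe[ia] + e)

  rec$milk_yield <- config$mean_yield_l + config$sd_yield_l * y

  truth <- structure(list(
    breeding_values = tibble(animal_id = animals$animal_id, a = a),
    herd_effects = tibble(herd_id = herds$herds$herd_id, h = h),
    spatial_field = tibble(herd_id = herds$herds$herd_id, s = s),
    pe_effects = tibble(animal_id = animals$animal_id, p = pe),
    fixed_effects = tibble(term = colnames(ds$X), b = b),
    admixture = adm,
    latent_y = y,
    config = config
  ), class = "sim_truth")

  list(phenotypes = rec, truth = truth)
}

recode_parity <- function(parity_raw) {
  factor(ifelse(parity_raw >= 3, "3+", as.character(parity_raw)),
         levels = c("1", "2", "3+"))
}

calving_season_of <- function(month) {
  # January-June is the dry season in the study system
  ifelse(month <= 6, "dry", "wet")
}

#' Simulate a complete dataset
#'
#' Convenience wrapper chaining genotypes, herds, spatial field and
#' phenotypes under one seed. Deterministic: identical configs give
#' identical outputs.
#'
#' @param config A [sim_config()].
#' @return List with `phenotypes`, `geno`, `herds` (herd table), `animals`
#'   (animal-to-herd map), `truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  hd <- sim_herds_impl(config)
  region <- hd$herds$region[match(hd$animals$herd_id, hd$herds$herd_id)]
  set.seed(config$seed)
  g <- sim_genotypes_impl(config, region)
  fld <- simulate_spatial_field(hd$herds, rho = config$spatial_range_km,
                                var_s = config$var_s,
                                seed = config$seed + 7L)
  ph <- simulate_phenotypes(config, g$out, hd, fld)
  list(phenotypes = ph$phenotypes, geno = g$out$geno,
       admixture = g$out$admixture, herds = hd$herds, animals = hd$animals,
       truth = ph$truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$breeding_values), " animals, ",
      nrow(x$herd_effects), " herds; component sds: a=",
      round(sd(x$breeding_values$a), 3), " h=", round(sd(x$herd_effects$h), 3),
      " s=", round(sd(x$spatial_field$s), 3), "\n", sep = "")
  invisible(x)
}
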