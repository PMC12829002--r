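# --- genotypes -------------------------------------------------------------

test_that("simulated dosages are valid and deterministic", {
  cfg <- sim_config(n_animals = 50, n_snps = 60, seed = 12)
  g1 <- simulate_admixed_genotypes(cfg)
  g2 <- simulate_admixed_genotypes(cfg)
  expect_identical(g1, g2)
  expect_true(all(unclass(g1$geno) %in% c(0, 1, 2)))
  expect_true(all(g1$admixture$exotic_pct >= 0 & g1$admixture$exotic_pct <= 100))
})

test_that("pure exotic animals hit the exotic pool frequencies", {
  m <- 80
  fr <- list(exotic = runif(m, 0.1, 0.9), indigenous = runif(m, 0.1, 0.9))
  cfg <- sim_config(n_animals = 2000, n_snps = m, ancestral_freqs = fr,
                    admixture_alpha = c(1e6, 1e-2), seed = 3)
  # Beta(1e6, 1e-2) is numerically 1: every animal is fully exotic
  g <- simulate_admixed_genotypes(cfg)
  emp <- colMeans(unclass(g$geno)) / 2
  se <- sqrt(fr$exotic * (1 - fr$exotic) / (2 * 2000))
  expect_true(all(abs(emp - fr$exotic) < 3.5 * se))
})

test_that("per-SNP frequencies match the analytic admixture mixture", {
  m <- 100
  fr <- list(exotic = runif(m, 0.1, 0.9), indigenous = runif(m, 0.1, 0.9))
  cfg <- sim_config(n_animals = 2000, n_snps = m, ancestral_freqs = fr,
                    seed = 1)
  g <- simulate_admixed_genotypes(cfg)
  pi_i <- g$admixture$exotic_pct / 100
  # law-of-large-numbers oracle: expected frequency per SNP given the drawn
  # admixture proportions
  expected <- colMeans(outer(pi_i, fr$exotic) + outer(1 - pi_i, fr$indigenous))
  emp <- colMeans(unclass(g$geno)) / 2
  se <- sqrt(expected * (1 - expected) / (2 * 2000))
  expect_lt(max(abs(emp - expected) / se), 3.5)
})

test_that("exotic-genome classes follow the printed boundaries, upper-closed", {
  expect_equal(as.character(assign_exotic_class(c(100, 0, 87.5, 60, 36))),
               c("C1", "C4", "C1", "C2", "C3"))
  expect_equal(as.character(assign_exotic_class(c(87.49, 59.9, 35.9))),
               c("C2", "C3", "C4"))
  expect_error(assign_exotic_class(101), class = "spatialgblup_invalid_config")
  expect_error(assign_exotic_class(-1), class = "spatialgblup_invalid_config")
})

# --- herds -----------------------------------------------------------------

test_that("herd sizes tile the animals exactly and emulate the census profile", {
  cfg <- sim_config(n_animals = 2000, n_snps = 10, seed = 31)
  hd <- simulate_herds(cfg)
  sizes <- table(hd$animals$herd_id)
  expect_equal(sum(sizes), 2000)
  expect_equal(sort(unique(hd$animals$herd_id)), sort(hd$herds$herd_id))
  # ~1400 herds: singleton fraction near 0.71, <3 cows above 0.93
  expect_lt(abs(mean(sizes == 1) - 0.71), 0.03)
  expect_gt(mean(sizes <= 2), 0.90)
})

test_that("herd-size distribution is consistent with the configured pmf", {
  cfg <- sim_config(n_animals = 14000, n_snps = 10, seed = 52)
  hd <- simulate_herds(cfg)
  sizes <- as.integer(table(hd$animals$herd_id))
  # drop the single truncated herd from the goodness-of-fit comparison
  obs <- tabulate(sizes, 9)
  exp_p <- cfg$herd_size_pmf
  keep <- exp_p > 0
  chi <- suppressWarnings(chisq.test(obs[keep], p = exp_p[keep] / sum(exp_p[keep])))
  expect_gt(chi$p.value, 0.01)
})

test_that("region assignment is multinomial with equal weights", {
  cfg <- sim_config(n_animals = 14000, n_snps = 10, seed = 7)
  hd <- simulate_herds(cfg)
  nh <- nrow(hd$herds)
  counts <- table(hd$herds$region)
  expect_equal(length(counts), 4)
  se <- sqrt(nh * 0.25 * 0.75)
  expect_true(all(abs(counts - nh / 4) < 3 * se))
})

# --- spatial field ---------------------------------------------------------

test_that("zero spatial variance gives an exactly zero field", {
  hs <- data.frame(herd_id = paste0("H", 1:5),
                   x_km = runif(5), y_km = runif(5))
  f <- simulate_spatial_field(hs, rho = 30, var_s = 0, seed = 1)
  expect_identical(f$spatial, rep(0, 5))
})

test_that("duplicated coordinates receive identical field values", {
  hs <- data.frame(herd_id = c("A", "B", "C", "D"),
                   x_km = c(1, 1, 9, 1), y_km = c(2, 2, 5, 2))
  f <- simulate_spatial_field(hs, rho = 20, var_s = 1, seed = 2)
  expect_identical(f$spatial[1], f$spatial[2])
  expect_identical(f$spatial[1], f$spatial[4])
})

test_that("empirical field covariance matches the Matern covariance", {
  hs <- data.frame(herd_id = c("A", "B", "C"),
                   x_km = c(0, 12, 40), y_km = c(0, 5, 18))
  target <- spatial_covariance(spatial_kernel(hs, rho = 25, sigma2_s = 0.6))
  nrep <- 20000
  draws <- vapply(seq_len(nrep), function(r) {
    simulate_spatial_field(hs, rho = 25, var_s = 0.6, seed = r)$spatial
  }, numeric(3))
  emp <- tcrossprod(draws - rowMeans(draws)) / (nrep - 1)
  # Monte-Carlo SE of a covariance entry ~ sqrt((c_ii c_jj + c_ij^2)/n)
  se <- sqrt((outer(diag(target), diag(target)) + target^2) / nrep)
  expect_true(all(abs(emp - unname(target)) < 3.5 * se))
})

test_that("non-finite coordinates are rejected", {
  hs <- data.frame(herd_id = "A", x_km = Inf, y_km = 0)
  expect_error(simulate_spatial_field(hs, 30, 1, 1),
               class = "spatialgblup_invalid_coordinates")
})

# --- phenotypes ------------------------------------------------------------

test_that("with all variances and effects zeroed, phenotypes are constant", {
  cfg <- sim_config(n_animals = 30, n_snps = 50, var_g = 0, var_h = 0,
                    var_s = 0, var_p = 0, var_e = 0, fixed_effect_sd = 0,
                    seed = 5)
  ds <- simulate_dataset(cfg)
  expect_equal(ds$phenotypes$milk_yield,
               rep(cfg$mean_yield_l, nrow(ds$phenotypes)))
})

test_that("record structure respects DIM range and parity pooling", {
  ds <- simulate_dataset(sim_config(n_animals = 150, n_snps = 50, seed = 6))
  ph <- ds$phenotypes
  expect_true(all(ph$dim >= 4 & ph$dim <= 500))
  expect_true(all(as.character(ph$parity) %in% c("1", "2", "3+")))
  expect_true(all(ph$calving_season %in% c("dry", "wet")))
  expect_true(all(ph$test_month %in% 1:12))
  # every record's animal has a genotype row
  expect_true(all(ph$animal_id %in% rownames(ds$geno)))
})

test_that("simulated component variances track their configured values", {
  nrep <- 30
  va <- vh <- vs <- ve <- numeric(nrep)
  for (r in seq_len(nrep)) {
    ds <- simulate_dataset(sim_config(n_animals = 500, n_snps = 300,
                                      seed = 400 + r))
    va[r] <- var(ds$truth$breeding_values$a)
    vh[r] <- var(ds$truth$herd_effects$h)
    vs[r] <- var(ds$truth$spatial_field$s)
  }
  expect_lt(abs(mean(va) - 0.15), 3 * sd(va) / sqrt(nrep))
  expect_lt(abs(mean(vh) - 0.15), 3 * sd(vh) / sqrt(nrep))
  expect_lt(abs(mean(vs) - 0.30), 3 * sd(vs) / sqrt(nrep))
})

test_that("the full generator is deterministic given the config", {
  cfg <- sim_config(n_animals = 40, n_snps = 30, seed = 99)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(d1$truth$spatial_field, d2$truth$spatial_field)
  expect_identical(unclass(d1$geno), unclass(d2$geno))
})

test_that("phenotypic variance decomposes into the configured components", {
  # latent-scale variance across replicates approaches the sum of component
  # variances plus the (small) fixed-effect contribution
  tot <- vapply(1:12, function(r) {
    ds <- simulate_dataset(sim_config(n_animals = 400, n_snps = 200,
                                      seed = 500 + r))
    var(ds$truth$latent_y)
  }, 0)
  expect_lt(abs(mean(tot) - 0.9), 0.12)  # 0.9 + fixed-effect variance ~ 0.05
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(herd_size_pmf = c(0.5, 0.4)),
               class = "spatialgblup_invalid_config")
  expect_error(sim_config(var_g = -1), class = "spatialgblup_invalid_config")
  expect_error(sim_config(ancestral_freqs = list(exotic = 1.2,
                                                 indigenous = 0.5)),
               class = "spatialgblup_invalid_config")
  expect_error(sim_config(n_regions = 3,
                          region_centres = matrix(0, 2, 2)),
               class = "spatialgblup_invalid_config")
})
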