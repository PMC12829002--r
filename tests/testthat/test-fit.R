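test_that("a pure-noise dataset yields residual-dominated posteriors", {
  cfg <- sim_config(n_animals = 150, n_snps = 300, var_g = 0, var_h = 0,
                    var_s = 0, var_p = 0, var_e = 0.5, fixed_effect_sd = 0,
                    seed = 61)
  ds <- simulate_dataset(cfg)
  d <- ds$phenotypes
  d$y <- (d$milk_yield - cfg$mean_yield_l) / cfg$sd_yield_l
  G <- vanraden_grm(ds$geno)
  spec <- model_spec("GHS", fixed = "intercept", n_iter = 700, burnin = 300,
                     thin = 2, seed = 3)
  f <- suppressWarnings(fit_model(d, G, ds$herds, spec, response = "y",
                                  store_loglik = FALSE))
  vc <- colMeans(f$draws$vc)
  expect_lt(abs(vc["sigma2_e"] - 0.5) / 0.5, 0.1)
  expect_lt(vc["sigma2_g"], 0.1 * vc["sigma2_e"])
  expect_lt(vc["sigma2_h"], 0.1 * vc["sigma2_e"])
  expect_lt(vc["sigma2_s"], 0.1 * vc["sigma2_e"])
})

test_that("a spatial model fitted to non-spatial data shrinks the field", {
  # herd variance must also be absent: a Matern field with a free range
  # degenerates towards iid herd effects as rho -> 0, so GS legitimately
  # absorbs herd-level variance when it exists
  cfg <- sim_config(n_animals = 500, n_snps = 300, var_s = 0, var_h = 0,
                    seed = 62)
  ds <- simulate_dataset(cfg)
  d <- ds$phenotypes
  d$y <- (d$milk_yield - cfg$mean_yield_l) / cfg$sd_yield_l
  G <- vanraden_grm(ds$geno)
  spec <- model_spec("GS", n_iter = 700, burnin = 300, thin = 2, seed = 4)
  f <- suppressWarnings(fit_model(d, G, ds$herds, spec, response = "y",
                                  store_loglik = FALSE))
  expect_lt(mean(f$draws$vc[, "sigma2_s"]), 0.05)
  expect_lt(sd(rowMeans(f$draws$s)), 0.05)
})

test_that("clamping the herd variance to zero reproduces the GS posterior", {
  ds <- tiny_dataset()
  d <- ds$phenotypes
  G <- ds$grm
  sp_gs <- quick_spec("GS", n_iter = 900, burnin = 300, seed = 5)
  sp_ghs0 <- quick_spec("GHS", n_iter = 900, burnin = 300, seed = 5)
  sp_ghs0$fix <- list(sigma2_h = 1e-10)
  f_gs <- suppressWarnings(fit_model(d, G, ds$herds, sp_gs, response = "y",
                                     store_loglik = FALSE))
  f_0 <- suppressWarnings(fit_model(d, G, ds$herds, sp_ghs0, response = "y",
                                    store_loglik = FALSE))
  # shared parameters agree within Monte-Carlo error
  for (term in c("sigma2_g", "sigma2_s", "sigma2_e")) {
    m1 <- mean(f_gs$draws$vc[, term]); m2 <- mean(f_0$draws$vc[, term])
    se <- sqrt(var(f_gs$draws$vc[, term]) / 50 + var(f_0$draws$vc[, term]) / 50)
    expect_lt(abs(m1 - m2), 4 * se)
  }
  expect_gt(cor(rowMeans(f_gs$draws$s), rowMeans(f_0$draws$s)), 0.95)
})

test_that("fits expose tidy, glance, ebv and prediction interfaces", {
  ds <- tiny_dataset()
  f <- suppressWarnings(fit_model(ds$phenotypes, ds$grm, ds$herds,
                                  quick_spec("GH", seed = 6), response = "y"))
  td <- tidy(f)
  expect_setequal(td$term, c("sigma2_g", "sigma2_h", "sigma2_e", "h2"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  expect_equal(nrow(tidy(f, "ebv")), 120)
  gl <- glance(f)
  expect_equal(gl$model, "GH")
  expect_true(is.finite(gl$waic))
  expect_equal(gl$h2,
               mean(f$draws$vc[, "sigma2_g"] /
                      rowSums(f$draws$vc[, c("sigma2_g", "sigma2_h",
                                             "sigma2_e")])),
               tolerance = 0.05)
  pr <- predict(f)
  expect_equal(length(pr), nrow(ds$phenotypes))
  expect_gt(cor(pr, ds$phenotypes$y), 0.5)
  expect_error(tidy(f, "spatial"), class = "spatialgblup_unsupported_model")
})

test_that("heritability uses every variance component in the fitted model", {
  ds <- tiny_dataset()
  f <- suppressWarnings(fit_model(ds$phenotypes, ds$grm, ds$herds,
                                  quick_spec("GPH", seed = 8), response = "y",
                                  store_loglik = FALSE))
  vc <- f$draws$vc
  expect_equal(vc[, "h2"],
               vc[, "sigma2_g"] / (vc[, "sigma2_g"] + vc[, "sigma2_h"] +
                                     vc[, "sigma2_p"] + vc[, "sigma2_e"]))
})

test_that("spatial fits demand coordinates and a complete GRM", {
  ds <- tiny_dataset()
  expect_error(fit_model(ds$phenotypes, ds$grm, herds = NULL,
                         quick_spec("GS"), response = "y"),
               class = "spatialgblup_missing_coordinates")
  expect_error(fit_model(ds$phenotypes, ds$grm[1:50, 1:50], ds$herds,
                         quick_spec("G"), response = "y"),
               class = "spatialgblup_missing_genotype")
  expect_error(fit_model(ds$phenotypes, ds$grm, ds$herds, quick_spec("G"),
                         response = "nope"),
               class = "spatialgblup_schema")
})
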