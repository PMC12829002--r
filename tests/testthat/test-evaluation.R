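toy_recs <- function(n = 8) {
  tibble::tibble(animal_id = paste0("a", seq_len(n)),
                 herd_id = paste0("h", rep(seq_len(n / 2), each = 2)))
}

test_that("contribution correlations reproduce textbook formulas", {
  rec <- toy_recs(6)
  x <- c(2.0, -1.0, 0.5, 1.5, -0.5, 0.2)
  yv <- c(1.0, -0.8, 0.3, 2.0, -1.2, 0.0)
  fits <- list(A = fake_fit(setNames(x, rec$animal_id), rec),
               B = fake_fit(setNames(yv, rec$animal_id), rec))
  cc <- contribution_correlations(fits)
  # textbook Pearson
  px <- sum((x - mean(x)) * (yv - mean(yv))) /
    sqrt(sum((x - mean(x))^2) * sum((yv - mean(yv))^2))
  expect_equal(cc$pearson["BV_A", "BV_B"], px, tolerance = 1e-12)
  # textbook Spearman via midranks
  rx <- rank(x); ry <- rank(yv)
  sx <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(cc$spearman["BV_A", "BV_B"], sx, tolerance = 1e-12)
  expect_equal(diag(cc$pearson), c(BV_A = 1, BV_B = 1))
  # combined table carries Pearson above and Spearman below the diagonal
  expect_equal(cc$table$BV_B[1], px)
  expect_equal(cc$table$BV_A[2], sx)
})

test_that("Spearman is invariant under monotone transforms; Pearson is not", {
  rec <- toy_recs(6)
  set.seed(9)
  x <- rnorm(6); yv <- rnorm(6)
  f1 <- list(A = fake_fit(setNames(x, rec$animal_id), rec),
             B = fake_fit(setNames(yv, rec$animal_id), rec))
  f2 <- list(A = fake_fit(setNames(exp(2 * x), rec$animal_id), rec),
             B = fake_fit(setNames(yv, rec$animal_id), rec))
  c1 <- contribution_correlations(f1)
  c2 <- contribution_correlations(f2)
  expect_equal(c1$spearman["BV_A", "BV_B"], c2$spearman["BV_A", "BV_B"])
})

test_that("zero-variance contributions are reported as NA with a warning", {
  rec <- toy_recs(6)
  fits <- list(A = fake_fit(setNames(rep(1, 6), rec$animal_id), rec),
               B = fake_fit(setNames(rnorm(6), rec$animal_id), rec))
  expect_warning(cc <- contribution_correlations(fits), "zero-variance")
  expect_true(is.na(cc$pearson["BV_A", "BV_B"]))
  expect_equal(cc$pearson["BV_A", "BV_A"], 1)
})

test_that("EBV shift regression matches closed-form least squares", {
  rec <- toy_recs(8)
  s_by_herd <- setNames(c(0.5, -0.3, 0.1, 0.8), paste0("h", 1:4))
  e2 <- setNames(rnorm(8, sd = 0.1), rec$animal_id)
  # exact linear construction: delta = 0.5 * s*
  sstar <- s_by_herd[rec$herd_id[match(names(e2), rec$animal_id)]]
  f_ns <- fake_fit(e2 + 0.5 * sstar, rec)
  f_sp <- fake_fit(e2, rec, s_by_herd = s_by_herd)
  sh <- ebv_shift_vs_spatial(f_ns, f_sp)
  expect_equal(sh$slope, 0.5, tolerance = 1e-10)
  expect_equal(sh$r_squared, 1, tolerance = 1e-10)

  # closed-form OLS oracle on a 10-animal table
  rec10 <- tibble::tibble(animal_id = paste0("a", 1:10),
                          herd_id = paste0("h", 1:10))
  set.seed(3)
  sb <- setNames(rnorm(10), rec10$herd_id)
  d1 <- setNames(rnorm(10), rec10$animal_id)
  f_a <- fake_fit(d1, rec10)
  f_b <- fake_fit(setNames(rep(0, 10), rec10$animal_id), rec10,
                  s_by_herd = sb)
  sh2 <- ebv_shift_vs_spatial(f_a, f_b)
  delta <- d1; sstar2 <- sb
  beta <- cov(delta, sstar2) / var(sstar2)
  alpha <- mean(delta) - beta * mean(sstar2)
  r2 <- cor(delta, sstar2)^2
  expect_equal(sh2$slope, unname(beta), tolerance = 1e-10)
  expect_equal(sh2$intercept, unname(alpha), tolerance = 1e-10)
  expect_equal(sh2$r_squared, unname(r2), tolerance = 1e-10)
})

test_that("identical EBVs give the zero-shift convention", {
  rec <- toy_recs(6)
  e <- setNames(rnorm(6), rec$animal_id)
  sb <- setNames(rnorm(3), paste0("h", 1:3))
  f1 <- fake_fit(e, rec)
  f2 <- fake_fit(e, rec, s_by_herd = sb)
  expect_message(sh <- ebv_shift_vs_spatial(f1, f2), "zero")
  expect_equal(sh$slope, 0)
  expect_equal(sh$r_squared, 0)
  # constant spatial effect is degenerate
  f3 <- fake_fit(e + 1, rec, s_by_herd = setNames(rep(2, 3), paste0("h", 1:3)))
  expect_error(ebv_shift_vs_spatial(f1, f3),
               class = "spatialgblup_degenerate_regression")
})

test_that("top-k overlap counts set intersections with id tie-breaks", {
  rec <- toy_recs(8)
  e1 <- setNames(c(8, 7, 6, 5, 4, 3, 2, 1), rec$animal_id)
  e2 <- setNames(c(1, 2, 8, 7, 3, 4, 6, 5), rec$animal_id)
  f1 <- fake_fit(e1, rec); f2 <- fake_fit(e2, rec)
  expect_equal(top_k_overlap(f1, f1, 5), 5)
  expect_equal(top_k_overlap(f1, f2, 8), 8)
  # top-3 of e1: a1 a2 a3; of e2: a3 a4 a7 -> overlap {a3}
  expect_equal(top_k_overlap(f1, f2, 3), 1)
  expect_error(top_k_overlap(f1, f2, 0), class = "spatialgblup_invalid_k")
  expect_error(top_k_overlap(f1, f2, 9), class = "spatialgblup_invalid_k")
})

test_that("cross-validation bookkeeping: one fold per class, exact masking", {
  ds <- tiny_dataset()
  d <- ds$phenotypes
  vc1 <- list(sigma2_g = 0.15, sigma2_h = 0.15, sigma2_e = 0.3)
  cv <- suppressWarnings(cross_validate(
    d, ds$grm, ds$herds, models = "GH", grouping = "exotic_class",
    response = "y", spec = quick_spec("GH"), method = "mme",
    vc = list(GH = vc1)))
  d$exotic_class <- assign_exotic_class(d$exotic_pct)
  counts <- table(d$exotic_class)
  counts <- counts[counts > 0]
  expect_equal(nrow(cv), length(counts))
  expect_equal(setNames(cv$n_records, cv$group),
               setNames(as.integer(counts), names(counts)))
  expect_true(all(is.na(cv$accuracy) | abs(cv$accuracy) <= 1))
  expect_s3_class(attr(cv, "summary"), "tbl_df")
})

test_that("training-set accuracy exceeds masked accuracy", {
  ds <- tiny_dataset()
  d <- ds$phenotypes
  spec <- quick_spec("GH", seed = 10)
  f <- suppressWarnings(fit_model(d, ds$grm, ds$herds, spec, response = "y",
                                  store_loglik = FALSE))
  cv <- suppressWarnings(cross_validate(
    d, ds$grm, ds$herds, models = "GH", grouping = "region",
    response = "y", spec = spec, method = "mme",
    vc = list(GH = spatialgblup:::vc_of(f))))
  train_acc <- cor(predict(f), d$y)
  expect_gt(train_acc, max(cv$accuracy, na.rm = TRUE))
})

test_that("forward validation masks by birth year and validates inputs", {
  ds <- tiny_dataset()
  d <- ds$phenotypes
  vc1 <- list(sigma2_g = 0.15, sigma2_h = 0.15, sigma2_e = 0.3)
  cut <- 2016
  fw <- suppressWarnings(forward_validate(
    d, ds$grm, ds$herds, models = "GH", birth_year_cutoff = cut,
    response = "y", spec = quick_spec("GH"), method = "mme",
    vc = list(GH = vc1)))
  ov <- fw[fw$group == "overall", ]
  expect_equal(ov$n_animals,
               length(unique(d$animal_id[d$birth_year >= cut])))
  expect_equal(ov$n_records, sum(d$birth_year >= cut))
  expect_error(forward_validate(d, ds$grm, ds$herds, models = "GH",
                                birth_year_cutoff = 1900, response = "y",
                                spec = quick_spec("GH"), method = "mme",
                                vc = list(GH = vc1)),
               class = "spatialgblup_empty_split")
  expect_error(forward_validate(d, ds$grm, ds$herds, models = "GH",
                                birth_year_cutoff = 3000, response = "y",
                                spec = quick_spec("GH"), method = "mme",
                                vc = list(GH = vc1)),
               class = "spatialgblup_empty_split")
})
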