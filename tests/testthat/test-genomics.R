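test_that("QC leaves a clean matrix untouched and reports zero removals", {
  set.seed(1)
  M <- matrix(rbinom(20 * 10, 2, 0.5), 20, 10)
  M[1, ] <- c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0)  # guard against monomorphism
  g <- genotype_matrix(M)
  out <- qc_genotypes(g)
  expect_equal(unclass(out$geno), unclass(g))
  expect_equal(out$report$removed[1:3], c(0, 0, 0))
})

test_that("a rare SNP is removed at the MAF step", {
  set.seed(2)
  M <- matrix(rbinom(200 * 5, 2, 0.5), 200, 5)
  M[, 3] <- 0
  M[1, 3] <- 1  # MAF = 1/400 = 0.0025 < 0.01
  out <- qc_genotypes(genotype_matrix(M))
  expect_equal(ncol(out$geno), 4)
  expect_equal(out$report$removed[out$report$step == "maf"], 1)
})

test_that("QC matches a brute-force reapplication of the three filters", {
  # 6 animals x 5 SNPs with a prescribed missingness pattern
  M <- rbind(c(0,  1,  2, NA,  1),
             c(1, NA, NA, NA,  2),
             c(2,  1,  0, NA,  0),
             c(NA, 0,  1, NA,  1),
             c(1,  2,  2, NA,  2),
             c(0, NA,  1,  2,  1))
  g <- genotype_matrix(M)
  out <- qc_genotypes(g, snp_call_rate = 0.8, maf_min = 0.1,
                      animal_call_rate = 0.8)
  # independent oracle: reapply the rules step by step
  keep_snp <- colMeans(!is.na(M)) >= 0.8
  M1 <- M[, keep_snp, drop = FALSE]
  p <- colMeans(M1, na.rm = TRUE) / 2
  M2 <- M1[, pmin(p, 1 - p) >= 0.1, drop = FALSE]
  keep_an <- rowMeans(!is.na(M2)) >= 0.8
  M3 <- M2[keep_an, , drop = FALSE]
  expect_equal(dim(out$geno), dim(M3))
  # residual NAs are imputed to the observed column mean dosage
  expect_false(anyNA(out$geno))
  na_pos <- which(is.na(M3), arr.ind = TRUE)
  for (k in seq_len(nrow(na_pos))) {
    expect_equal(out$geno[na_pos[k, 1], na_pos[k, 2]],
                 mean(M3[, na_pos[k, 2]], na.rm = TRUE))
  }
})

test_that("QC errors when nothing survives", {
  M <- matrix(NA_real_, 4, 3)
  M[1, 1] <- 1
  expect_error(qc_genotypes(genotype_matrix(M)),
               class = "spatialgblup_empty_after_qc")
})

bare <- function(M) {
  M <- unclass(M)
  array(as.numeric(M), dim = dim(M))
}

test_that("VanRaden G matches the hand-computed toy example", {
  M <- rbind(c(0, 2), c(1, 1), c(2, 0))
  G <- vanraden_grm(genotype_matrix(M))
  # p = (0.5, 0.5); Z = M - 1; scale = 2 * (0.25 + 0.25) = 1
  expect_equal(bare(G), rbind(c(2, 0, -2), c(0, 0, 0), c(-2, 0, 2)))
  expect_equal(attr(G, "scale"), 1)
})

test_that("identical genotype rows give identical G rows and diagonals", {
  set.seed(3)
  M <- matrix(rbinom(6 * 50, 2, runif(50, 0.2, 0.8)), 6, 50, byrow = TRUE)
  M[2, ] <- M[5, ]
  G <- suppressWarnings(unclass(vanraden_grm(genotype_matrix(M))))
  expect_equal(G[2, ], G[5, ])
  expect_equal(G[2, 2], G[5, 5])
})

test_that("G is a Gram matrix: symmetric, PSD, permutation-consistent", {
  g <- simulate_admixed_genotypes(sim_config(n_animals = 40, n_snps = 300,
                                             seed = 8))$geno
  G <- unclass(vanraden_grm(g))
  expect_equal(bare(G), bare(t(G)))
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # SNP column order is irrelevant
  set.seed(1)
  g2 <- genotype_matrix(unclass(g)[, sample(ncol(g))],
                        animal_id = rownames(g))
  expect_equal(bare(vanraden_grm(g2)), bare(G), tolerance = 1e-12)
  # animal permutation acts as the symmetric permutation of G
  pr <- sample(nrow(g))
  g3 <- genotype_matrix(unclass(g)[pr, ], animal_id = rownames(g)[pr])
  expect_equal(bare(vanraden_grm(g3)), bare(G[pr, pr]), tolerance = 1e-12)
})

test_that("mean diagonal of G approaches 1 under the mixture model", {
  g <- simulate_admixed_genotypes(sim_config(n_animals = 150, n_snps = 2000,
                                             seed = 21))$geno
  G <- vanraden_grm(g)
  expect_lt(abs(mean(diag(unclass(G))) - 1), 0.1)
})

test_that("monomorphic-only input errors", {
  M <- matrix(2, 5, 4)
  expect_error(vanraden_grm(genotype_matrix(M)),
               class = "spatialgblup_monomorphic")
})

test_that("genotype TSV and PLINK .raw layouts round-trip", {
  g <- simulate_admixed_genotypes(sim_config(n_animals = 12, n_snps = 20,
                                             seed = 5))$geno
  tmp <- tempfile(fileext = ".tsv")
  write_genotypes(g, tmp)
  g2 <- read_genotypes(tmp)
  expect_equal(unclass(g2), unclass(g))
  # PLINK .raw-style table
  raw <- tempfile(fileext = ".raw")
  tb <- data.frame(FID = rownames(g), IID = rownames(g), PAT = 0, MAT = 0,
                   SEX = 2, PHENOTYPE = -9, unclass(g), check.names = FALSE)
  readr::write_tsv(tb, raw)
  g3 <- read_genotypes(raw)
  expect_equal(unname(unclass(g3)), unname(unclass(g)))
  expect_equal(rownames(g3), rownames(g))
})
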