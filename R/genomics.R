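#' Genotype matrix container
#'
#' Thin wrapper around an animals x SNPs allele-dosage matrix (entries 0, 1,
#' 2 or NA) with unique animal and SNP ids as dimnames.
#'
#' @param dosage Numeric matrix, animals in rows.
#' @param animal_id,snp_id Optional ids; taken from dimnames if absent.
#' @return Object of class `genotype_matrix` (the matrix itself, classed).
#' @export
genotype_matrix <- function(dosage, animal_id = rownames(dosage),
                            snp_id = colnames(dosage)) {
  dosage <- as.matrix(dosage)
  if (is.null(animal_id)) animal_id <- paste0("A", seq_len(nrow(dosage)))
  if (is.null(snp_id)) snp_id <- paste0("snp", seq_len(ncol(dosage)))
  if (anyDuplicated(animal_id) || anyDuplicated(snp_id)) {
    stop_sg("duplicate animal or SNP ids.", "schema")
  }
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) {
    stop_sg("dosages must be 0, 1, 2 or NA.", "invalid_genotype")
  }
  dimnames(dosage) <- list(as.character(animal_id), as.character(snp_id))
  class(dosage) <- c("genotype_matrix", "matrix", "array")
  dosage
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x), " animals x ", ncol(x), " SNPs, ",
      round(100 * mean(is.na(x)), 2), "% missing\n", sep = "")
  invisible(x)
}

#' Genotype quality control
#'
#' Applies the standard three-step filter in order: (1) drop SNPs with call
#' rate below `snp_call_rate`; (2) drop SNPs with minor allele frequency
#' below `maf_min`; (3) drop animals with call rate (over the surviving
#' SNPs) below `animal_call_rate`. Any dosages still missing afterwards are
#' mean-imputed to `2p` with `p` the observed allele frequency.
#'
#' @param geno A [genotype_matrix()] (or plain dosage matrix).
#' @param snp_call_rate Keep SNPs genotyped in at least this fraction of
#'   animals (default 0.95).
#' @param maf_min Exclude SNPs with minor allele frequency below this
#'   (default 0.01).
#' @param animal_call_rate Keep animals genotyped for at least this fraction
#'   of surviving SNPs (default 0.90).
#' @return List with `geno` (filtered, imputed [genotype_matrix()]) and
#'   `report` (tibble of counts removed per step, plus imputed-cell count).
#' @export
qc_genotypes <- function(geno, snp_call_rate = 0.95, maf_min = 0.01,
                         animal_call_rate = 0.90) {
  thr <- c(snp_call_rate, maf_min, animal_call_rate)
  if (any(!is.finite(thr)) || any(thr < 0) || any(thr > 1)) {
    stop_sg("QC thresholds must lie in [0, 1].", "invalid_config")
  }
  M <- unclass(geno)
  n0_snp <- ncol(M); n0_animal <- nrow(M)

  snp_cr <- colMeans(!is.na(M))
  keep1 <- snp_cr >= snp_call_rate
  M <- M[, keep1, drop = FALSE]

  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep2 <- maf >= maf_min
  M <- M[, keep2, drop = FALSE]

  if (ncol(M) == 0) stop_sg("no SNPs left after QC.", "empty_after_qc")

  an_cr <- rowMeans(!is.na(M))
  keep3 <- an_cr >= animal_call_rate
  M <- M[keep3, , drop = FALSE]
  if (nrow(M) == 0) stop_sg("no animals left after QC.", "empty_after_qc")

  n_imputed <- sum(is.na(M))
  if (n_imputed > 0) {
    p2 <- colMeans(M, na.rm = TRUE)  # = 2 * observed allele frequency
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- p2[idx[, 2]]
  }

  report <- tibble(
    step = c("snp_call_rate", "maf", "animal_call_rate", "imputed_cells"),
    removed = c(sum(!keep1), sum(!keep2), sum(!keep3), n_imputed),
    remaining_snps = c(sum(keep1), sum(keep1) - sum(!keep2), ncol(M), ncol(M)),
    remaining_animals = c(n0_animal, n0_animal, nrow(M), nrow(M))
  )
  class(M) <- c("genotype_matrix", "matrix", "array")
  list(geno = M, report = report)
}

#' VanRaden type-1 genomic relationship matrix
#'
#' `G = Z Z' / (2 * sum(p * (1 - p)))` where `Z` is the dosage matrix with
#' each column centred at twice the observed allele frequency `p`. Allele
#' frequencies come from the observed sample. Input should already have
#' passed [qc_genotypes()]; residual NAs are not accepted.
#'
#' @param geno A [genotype_matrix()] without missing values.
#' @return Object of class `grm`: the symmetric matrix with attributes
#'   `scale` (the `2*sum(p(1-p))` constant) and `p` (allele frequencies).
#' @export
vanraden_grm <- function(geno) {
  M <- unclass(geno)
  if (anyNA(M)) {
    stop_sg("missing dosages; run qc_genotypes() first.", "invalid_genotype")
  }
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) {
    stop_sg("all SNPs monomorphic: VanRaden scaling constant is zero.",
            "monomorphic")
  }
  sc <- 2 * sum(p * (1 - p))
  Z <- sweep(M, 2, 2 * p)
  G <- tcrossprod(Z) / sc
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(M), rownames(M))
  md <- mean(diag(G))
  if (abs(md - 1) > 0.3) {
    warn(sprintf("mean diagonal of G is %.2f (expected near 1).", md))
  }
  structure(G, scale = sc, p = p, class = c("grm", "matrix", "array"))
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm> ", nrow(x), " animals, mean diag = ",
      round(mean(diag(unclass(x))), 3), "\n", sep = "")
  invisible(x)
}

#' Read / write genotype dosage TSV
#'
#' The on-disk format is tab-separated with a header row of SNP ids and a
#' first column `animal_id`. `read_genotypes()` also accepts a PLINK
#' .raw-style additive table (header starting FID/IID, SNP columns after the
#' standard six), mapped to the same internal matrix with IID as animal id.
#'
#' @param path File path.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  nm <- names(tb)
  if (identical(toupper(nm[1:2]), c("FID", "IID"))) {
    lead <- intersect(toupper(nm), c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))
    ids <- as.character(tb$IID)
    M <- as.matrix(tb[, setdiff(nm, nm[toupper(nm) %in% lead]), drop = FALSE])
  } else {
    ids <- as.character(tb[[1]])
    M <- as.matrix(tb[, -1, drop = FALSE])
  }
  rownames(M) <- ids
  genotype_matrix(M)
}

#' @rdname read_genotypes
#' @param geno A [genotype_matrix()].
#' @export
write_genotypes <- function(geno, path) {
  tb <- as_tibble(unclass(geno))
  tb <- dplyr::bind_cols(tibble(animal_id = rownames(geno)), tb)
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}
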