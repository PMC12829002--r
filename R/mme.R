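#' Solve Henderson's mixed-model equations at fixed variance components
#'
#' Deterministic BLUP/BLUE solver for the GBLUP models: with all variance
#' components fixed, solves
#' `(W'W / sigma2_e + P) theta = W'y / sigma2_e` where `W` stacks the fixed
#' design and the incidence matrices of the random terms and `P` is the
#' block-diagonal prior precision (`I / sigma2_beta` on fixed effects,
#' `Ginv / sigma2_g`, `I / sigma2_h`, `Rinv(rho) / sigma2_s`,
#' `I / sigma2_p`). The proper Gaussian prior on the fixed effects makes
#' the system uniquely solvable. This is both a fast refitting engine for
#' validation folds and the exact-posterior-mean oracle for the MCMC
#' sampler run at clamped variances.
#'
#' @param design Output of [build_design()] on the full record table.
#' @param y Response vector (one per record of `design`).
#' @param spec A [model_spec()] (selects the random terms).
#' @param grm A [vanraden_grm()] covering `design$animal_id`.
#' @param kernel A [spatial_kernel()] over `design$herd_id` (needed for
#'   spatial models; its `rho` is overridden by `vc$rho` when given).
#' @param vc Named list of variance components: `sigma2_g`, `sigma2_e`,
#'   plus `sigma2_h`, `sigma2_s`, `rho`, `sigma2_p` as required by the
#'   model.
#' @param sigma2_beta Fixed-effect prior variance (default 1000).
#' @param subset Optional integer/logical row subset (training rows);
#'   effects are still returned for every animal/herd level, held-out
#'   levels getting their conditional (kriging) mean.
#' @return List with `b`, `a`, `h`, `s`, `p` (NULL when absent), `fitted`
#'   (length = all records of `design`), and the condition number of the
#'   coefficient matrix.
#' @export
mme_solve <- function(design, y, spec, grm = NULL, kernel = NULL, vc,
                      sigma2_beta = 1000, subset = NULL) {
  if (is.null(vc$sigma2_e) || vc$sigma2_e <= 0) {
    stop_sg("vc$sigma2_e must be positive.", "invalid_variance")
  }
  n_all <- nrow(design$X)
  rows <- if (is.null(subset)) seq_len(n_all) else seq_len(n_all)[subset]
  X <- design$X[rows, , drop = FALSE]
  ia <- design$ia[rows]; ih <- design$ih[rows]
  yv <- y[rows]
  qa <- length(design$animal_id); qh <- length(design$herd_id)
  p <- ncol(X)

  Za <- Matrix::sparseMatrix(i = seq_along(rows), j = ia, x = 1,
                             dims = c(length(rows), qa))
  Zh <- Matrix::sparseMatrix(i = seq_along(rows), j = ih, x = 1,
                             dims = c(length(rows), qh))

  Wl <- list(Matrix::Matrix(X, sparse = TRUE), Za)
  Pl <- list(diag(1 / sigma2_beta, p),
             ginv_stab(grm, design$animal_id) / vc$sigma2_g)
  if (spec$include_herd) {
    Wl <- c(Wl, Zh); Pl <- c(Pl, list(diag(1 / vc$sigma2_h, qh)))
  }
  if (spec$include_spatial) {
    if (is.null(kernel)) stop_sg("spatial model needs a kernel.", "missing_kernel")
    rho <- vc$rho %||% kernel$rho
    R <- matern_cor_matrix(kernel$dist, rho) + diag(1e-8, qh)
    Wl <- c(Wl, Zh)
    Pl <- c(Pl, list(chol2inv(chol(R)) / vc$sigma2_s))
  }
  if (spec$include_pe) {
    Wl <- c(Wl, Za); Pl <- c(Pl, list(diag(1 / vc$sigma2_p, qa)))
  }

  W <- do.call(cbind, Wl)
  C <- as.matrix(Matrix::crossprod(W)) / vc$sigma2_e
  off <- 0
  for (B in Pl) {
    k <- nrow(B)
    C[off + seq_len(k), off + seq_len(k)] <-
      C[off + seq_len(k), off + seq_len(k)] + B
    off <- off + k
  }
  rhs <- as.vector(Matrix::crossprod(W, yv)) / vc$sigma2_e
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    stop_sg(sprintf("mixed-model equations singular (rcond = %.2e).",
                    rcond(C)), "singular_system")
  }
  theta <- backsolve(ch, forwardsolve(t(ch), rhs))

  out <- list(b = setNames(theta[seq_len(p)], colnames(X)))
  off <- p
  take <- function(k, nm) {
    v <- setNames(theta[off + seq_len(k)], nm)
    off <<- off + k
    v
  }
  out$a <- take(qa, design$animal_id)
  out$h <- if (spec$include_herd) take(qh, design$herd_id) else NULL
  out$s <- if (spec$include_spatial) take(qh, design$herd_id) else NULL
  out$p <- if (spec$include_pe) take(qa, design$animal_id) else NULL

  out$fitted <- drop(design$X %*% out$b) + out$a[design$ia] +
    (if (!is.null(out$h)) out$h[design$ih] else 0) +
    (if (!is.null(out$s)) out$s[design$ih] else 0)
  names(out$fitted) <- NULL
  out$condition <- 1 / rcond(C)
  out
}

# stabilised inverse of the GRM, subset and ordered to the design's animals:
# +1e-6 diagonal at solve time only
ginv_stab <- function(grm, animal_id) {
  if (is.null(grm)) stop_sg("a genomic relationship matrix is required.",
                            "missing_grm")
  miss <- setdiff(animal_id, rownames(grm))
  if (length(miss)) {
    stop_sg(paste0(length(miss), " animals lack GRM rows."), "missing_genotype")
  }
  G <- unclass(grm)[animal_id, animal_id]
  chol2inv(chol(G + diag(1e-6, length(animal_id))))
}
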