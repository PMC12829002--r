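#' Legendre polynomial basis for days in milk
#'
#' Maps DIM onto `x = 2 (dim - dim_min) / (dim_max - dim_min) - 1` and
#' returns the unnormalised Legendre polynomials of order 0..2:
#' `(1, x, (3 x^2 - 1) / 2)`. Normalisation constants are omitted; they are
#' absorbed by the regression coefficients.
#'
#' @param dim Days in milk (vectorised), within `[dim_min, dim_max]`.
#' @param dim_min,dim_max Range of valid DIM (defaults 4 and 500).
#' @return Matrix with columns `P0`, `P1`, `P2`.
#' @examples
#' legendre_basis(252)   # midpoint: (1, 0, -0.5)
#' @export
legendre_basis <- function(dim, dim_min = 4, dim_max = 500) {
  if (any(dim < dim_min | dim > dim_max)) {
    stop_sg("DIM outside the allowed range; filter records first.",
            "invalid_dim")
  }
  x <- 2 * (dim - dim_min) / (dim_max - dim_min) - 1
  cbind(P0 = rep(1, length(x)), P1 = x, P2 = (3 * x^2 - 1) / 2)
}

#' Model specification
#'
#' Fixed-effect recipe, prior settings and sampler settings for the GBLUP
#' mixed models. The model string selects random terms: `"G"` (breeding
#' values + residual only), `"GH"` (+ iid herd), `"GS"` (+ Matern spatial),
#' `"GHS"` (both); a `"P"` anywhere adds an iid permanent-environment
#' effect (e.g. `"GPHS"`).
#'
#' @param model Model label, e.g. `"GHS"`.
#' @param fixed Character vector of fixed-effect blocks, any of
#'   `"intercept"`, `"exotic_class"`, `"parity"`, `"calving_ys"`,
#'   `"test_ym"`, `"age_parity"` (standardised age-at-calving slope nested
#'   in parity), `"legendre_parity"` (Legendre P1, P2 of DIM nested in
#'   parity; P0 is absorbed by the parity intercepts).
#' @param sigma2_beta Prior variance of fixed-effect coefficients
#'   (default 1000).
#' @param prec_shape,prec_rate Gamma prior on the precisions of the
#'   genomic, herd, permanent-environment and residual variances
#'   (defaults 1 and 5e-5).
#' @param pc_rho0 Reference range of the penalised-complexity prior on the
#'   spatial range, `P(rho < pc_rho0) = pc_alpha_rho`; `NULL` uses the 5th
#'   percentile of the nonzero pairwise herd distances, i.e. the prior
#'   penalises ranges below the smallest scale the herd layout resolves.
#' @param pc_alpha_rho Lower-tail probability for the range prior
#'   (default 0.05).
#' @param pc_sigma0,pc_alpha_sigma PC prior on the spatial sd:
#'   `P(sigma_s > pc_sigma0) = pc_alpha_sigma` (defaults 1 and 0.1; the
#'   phenotype is standardised).
#' @param n_iter,burnin,thin,chains Sampler settings (defaults 4000, 1000,
#'   3, 1).
#' @param seed Sampler seed.
#' @param fix Optional named list clamping parameters instead of sampling
#'   them: any of `sigma2_g`, `sigma2_h`, `sigma2_s`, `sigma2_p`,
#'   `sigma2_e`, `rho`. Used for conditional runs against the deterministic
#'   solver.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(model = "GHS",
                       fixed = c("intercept", "exotic_class", "parity",
                                 "calving_ys", "test_ym", "age_parity",
                                 "legendre_parity"),
                       sigma2_beta = 1000,
                       prec_shape = 1, prec_rate = 5e-5,
                       pc_rho0 = NULL, pc_alpha_rho = 0.05,
                       pc_sigma0 = 1, pc_alpha_sigma = 0.1,
                       n_iter = 4000, burnin = 1000, thin = 3, chains = 1,
                       seed = 1L, fix = list()) {
  model <- toupper(model)
  if (!grepl("^G", model) || grepl("[^GHSP]", model)) {
    stop_sg("model label must be built from letters G, H, S, P and start with G.",
            "invalid_model")
  }
  if (!"intercept" %in% fixed) {
    stop_sg("the fixed-effect recipe must include the intercept.", "invalid_model")
  }
  if (n_iter <= burnin) {
    stop_sg("n_iter must exceed burnin.", "invalid_model")
  }
  structure(list(
    model = model,
    include_herd = grepl("H", model),
    include_spatial = grepl("S", model),
    include_pe = grepl("P", model),
    fixed = fixed, sigma2_beta = sigma2_beta,
    prec_shape = prec_shape, prec_rate = prec_rate,
    pc_rho0 = pc_rho0, pc_alpha_rho = pc_alpha_rho,
    pc_sigma0 = pc_sigma0, pc_alpha_sigma = pc_alpha_sigma,
    n_iter = as.integer(n_iter), burnin = as.integer(burnin),
    thin = as.integer(thin), chains = as.integer(chains),
    seed = as.integer(seed), fix = fix
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$model, "; fixed: ", paste(x$fixed, collapse = ", "),
      "; ", x$n_iter, " iterations (", x$burnin, " burn-in, thin ", x$thin,
      ")\n", sep = "")
  invisible(x)
}

#' Build the fixed-effect design and incidence maps
#'
#' Constructs the fixed-effect design matrix from the test-day record table
#' following the standard test-day-model recipe: intercept; exotic-genome
#' class; parity (1, 2, 3+); calving year-season; test year-month;
#' standardised age-at-calving slope nested within parity; and Legendre
#' order-2 lactation-curve terms (P1, P2) nested within parity. Categorical
#' blocks are reference-coded against their first sorted level. Also
#' returns integer incidence maps for the animal, herd and
#' permanent-environment random effects.
#'
#' @param records Phenotype tibble (see [simulate_phenotypes()] for the
#'   column layout). `exotic_class` is derived from `exotic_pct` when
#'   absent; `calving_ys`/`test_ym` are pasted from their year and
#'   season/month columns.
#' @param spec A [model_spec()].
#' @param age_stats Optional `list(mean, sd)` reused to standardise age at
#'   calving (stored in the output for reuse on held-out data).
#' @return List with `X` (dense design matrix with named columns), `terms`
#'   (tibble mapping columns to blocks), `animal_id`, `herd_id` (level
#'   vectors), `ia`, `ih` (record-level indices), `age_stats`.
#' @export
build_design <- function(records, spec = model_spec(), age_stats = NULL) {
  records <- as_tibble(records)
  n <- nrow(records)
  if (n == 0) stop_sg("no records.", "schema")
  if (!"exotic_class" %in% names(records)) {
    if (!"exotic_pct" %in% names(records)) {
      stop_sg("records need `exotic_class` or `exotic_pct`.", "schema")
    }
    records$exotic_class <- assign_exotic_class(records$exotic_pct)
  }
  if (!"parity" %in% names(records)) stop_sg("records need `parity`.", "schema")
  records$parity <- droplevels(factor(as.character(records$parity),
                                      levels = c("1", "2", "3+")))

  blocks <- list(intercept = matrix(1, n, 1,
                                    dimnames = list(NULL, "(Intercept)")))
  fx <- spec$fixed

  ref_code <- function(f, prefix) {
    f <- factor(as.character(f))
    lv <- sort(levels(f))
    f <- factor(f, levels = lv)
    if (length(lv) < 2) {
      return(matrix(0, n, 0))
    }
    X <- matrix(0, n, length(lv) - 1,
                dimnames = list(NULL, paste0(prefix, lv[-1])))
    for (j in seq_along(lv)[-1]) X[f == lv[j], j - 1] <- 1
    X
  }

  if ("exotic_class" %in% fx) {
    blocks$exotic_class <- ref_code(records$exotic_class, "exotic_class")
  }
  if ("parity" %in% fx || "legendre_parity" %in% fx) {
    blocks$parity <- ref_code(records$parity, "parity")
  }
  if ("calving_ys" %in% fx) {
    if (!all(c("calving_year", "calving_season") %in% names(records))) {
      stop_sg("records need `calving_year` and `calving_season`.", "schema")
    }
    blocks$calving_ys <- ref_code(
      paste(records$calving_year, records$calving_season, sep = "-"),
      "calving_ys")
  }
  if ("test_ym" %in% fx) {
    if (!all(c("test_year", "test_month") %in% names(records))) {
      stop_sg("records need `test_year` and `test_month`.", "schema")
    }
    blocks$test_ym <- ref_code(
      sprintf("%s-%02d", records$test_year, as.integer(records$test_month)),
      "test_ym")
  }
  if ("age_parity" %in% fx) {
    if (!"age_at_calving" %in% names(records)) {
      stop_sg("records need `age_at_calving`.", "schema")
    }
    if (is.null(age_stats)) {
      age_stats <- list(mean = mean(records$age_at_calving),
                        sd = stats::sd(records$age_at_calving))
      if (!is.finite(age_stats$sd) || age_stats$sd == 0) age_stats$sd <- 1
    }
    z <- (records$age_at_calving - age_stats$mean) / age_stats$sd
    A <- sapply(levels(records$parity),
                function(l) z * (records$parity == l))
    colnames(A) <- paste0("age_parity", levels(records$parity))
    blocks$age_parity <- A
  }
  if ("legendre_parity" %in% fx) {
    if (!"dim" %in% names(records)) stop_sg("records need `dim`.", "schema")
    P <- legendre_basis(records$dim)
    L <- do.call(cbind, lapply(levels(records$parity), function(l) {
      ind <- as.numeric(records$parity == l)
      out <- cbind(P[, "P1"] * ind, P[, "P2"] * ind)
      colnames(out) <- paste0(c("dimP1_parity", "dimP2_parity"), l)
      out
    }))
    blocks$legendre_parity <- L
  }

  X <- do.call(cbind, blocks)
  terms <- tibble(
    column = colnames(X),
    block = rep(names(blocks), vapply(blocks, ncol, 1L))
  )

  animal_id <- sort(unique(as.character(records$animal_id)))
  herd_id <- sort(unique(as.character(records$herd_id)))
  list(X = X, terms = terms,
       animal_id = animal_id, herd_id = herd_id,
       ia = match(as.character(records$animal_id), animal_id),
       ih = match(as.character(records$herd_id), herd_id),
       age_stats = age_stats)
}
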