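#' Correlations between estimated contributions to phenotype
#'
#' For each fitted model, the per-record contribution of breeding values
#' (posterior-mean EBV of the record's animal), herd effects and spatial
#' effects (posterior-mean effect of the record's herd) are merged into one
#' table; columns a model lacks are simply absent. Pairwise Pearson and
#' Spearman (midrank ties) correlation matrices over these columns are
#' returned, plus a combined square table with Pearson above and Spearman
#' below the diagonal.
#'
#' @param fits Named list of `gblup_fit` objects fitted to the same records.
#' @return List with `pearson`, `spearman` (matrices) and `table` (tibble,
#'   Pearson above / Spearman below the diagonal).
#' @export
contribution_correlations <- function(fits) {
  stopifnot(length(fits) >= 1)
  labs <- names(fits) %||% vapply(fits, `[[`, "", "model")
  if (is.null(names(fits))) names(fits) <- labs
  rec0 <- fits[[1]]$records
  cols <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (!identical(nrow(f$records), nrow(rec0)) ||
        !identical(f$records$animal_id, rec0$animal_id)) {
      stop_sg("all fits must be computed on the same records.", "mismatch")
    }
    d <- f$design
    ia <- d$ia[f$rows]; ih <- d$ih[f$rows]
    cols[[paste0("BV_", nm)]] <- rowMeans(f$draws$a)[ia]
    if (!is.null(f$draws$h)) {
      cols[[paste0("Herd_", nm)]] <- rowMeans(f$draws$h)[ih]
    }
    if (!is.null(f$draws$s)) {
      cols[[paste0("Spatial_", nm)]] <- rowMeans(f$draws$s)[ih]
    }
  }
  M <- do.call(cbind, cols)
  zv <- apply(M, 2, sd) == 0
  if (any(zv)) {
    warn(paste0("zero-variance contribution column(s): ",
                paste(colnames(M)[zv], collapse = ", "),
                "; correlations reported as NA."))
  }
  pear <- suppressWarnings(cor(M, method = "pearson"))
  spear <- suppressWarnings(cor(M, method = "spearman"))
  pear[zv, ] <- NA; pear[, zv] <- NA; diag(pear) <- 1
  spear[zv, ] <- NA; spear[, zv] <- NA; diag(spear) <- 1
  comb <- pear
  comb[lower.tri(comb)] <- spear[lower.tri(spear)]
  tab <- as_tibble(comb, rownames = "contribution")
  list(pearson = pear, spearman = spear, table = tab)
}

# posterior-mean variance components of a fit, as the list mme_solve wants
vc_of <- function(fit) {
  m <- colMeans(fit$draws$vc)
  out <- as.list(m)
  out$h2 <- NULL
  out
}

#' Leave-group-out cross-validation of phenotype prediction
#'
#' For each level of the grouping variable, all records of that level are
#' masked, every requested model is refitted on the remaining records, and
#' the masked phenotypes are predicted as `X b + a + h + s` (terms present
#' in the model). Animals and herds unseen in training keep their prior
#' mean of zero, except the spatial effect at held-out herd locations which
#' takes its Matern conditional (kriging) mean automatically through the
#' joint Gaussian model. Accuracy is the Pearson correlation between
#' predicted and observed phenotypes within the masked group.
#'
#' @param data Record tibble; must carry the grouping column (or
#'   `exotic_pct` when grouping by `exotic_class`).
#' @param grm A [vanraden_grm()] for all animals.
#' @param herds Herd coordinate table (spatial models).
#' @param models Character vector of model labels (default all four).
#' @param grouping `"exotic_class"` or `"region"` (any column name works).
#' @param response Response column (standardised yield).
#' @param spec Base [model_spec()]; its sampler settings apply to every
#'   refit.
#' @param method `"mcmc"` refits the full sampler per fold; `"mme"`
#'   (default) refits the deterministic mixed-model equations per fold at
#'   variance components estimated once per model on the complete data (a
#'   standard fast BLUP cross-validation).
#' @param vc Optional named list (per model label) of variance-component
#'   lists for `method = "mme"`, e.g. from fits already in hand; estimated
#'   by MCMC on the full data when NULL.
#' @return A `gblup_validation` tibble: one row per model x group with
#'   `n_records`, `n_animals`, `accuracy`; per-model plain and size-weighted
#'   average accuracies in `attr(, "summary")`.
#' @export
cross_validate <- function(data, grm, herds = NULL,
                           models = c("G", "GH", "GS", "GHS"),
                           grouping = "exotic_class",
                           response = "milk_yield_std",
                           spec = model_spec(), method = c("mme", "mcmc"),
                           vc = NULL) {
  method <- match.arg(method)
  data <- as_tibble(data)
  data <- add_grouping(data, grouping)
  g <- as.character(data[[grouping]])
  design <- build_design(data, spec)
  y <- data[[response]]
  fold_refit_validate(data, y, g, design, grm, herds, models, spec, method,
                      vc, scheme = "cross", grouping = grouping,
                      response = response)
}

#' Forward validation: predict the youngest animals
#'
#' Masks every record of animals born in or after `birth_year_cutoff`,
#' refits on the remaining (older) animals, and scores predictions of the
#' masked phenotypes overall and within each exotic-genome class and
#' region.
#'
#' @inheritParams cross_validate
#' @param birth_year_cutoff Animals with `birth_year >= cutoff` form the
#'   validation set.
#' @return A `gblup_validation` tibble (scheme `"forward"`); rows for the
#'   overall split and per exotic class / region.
#' @export
forward_validate <- function(data, grm, herds = NULL,
                             models = c("G", "GH", "GS", "GHS"),
                             birth_year_cutoff,
                             response = "milk_yield_std",
                             spec = model_spec(), method = c("mme", "mcmc"),
                             vc = NULL) {
  method <- match.arg(method)
  data <- as_tibble(data)
  data <- add_grouping(data, "exotic_class")
  test <- data$birth_year >= birth_year_cutoff
  if (!any(test)) stop_sg("no animals at or above the cutoff year.", "empty_split")
  if (all(test)) stop_sg("cutoff leaves an empty training set.", "empty_split")
  design <- build_design(data, spec)
  y <- data[[response]]
  kernel <- make_kernel(design, herds, models)
  train <- !test

  out <- list()
  summ <- list()
  for (m in models) {
    spec_m <- respec(spec, m)
    pred <- refit_predict(data, y, design, grm, herds, kernel, spec_m,
                          method, vc[[m]], train, response)
    grp_tbl <- dplyr::bind_rows(
      tibble(grouping = "overall", group = "overall", idx = list(which(test))),
      group_rows(test, data$exotic_class, "exotic_class"),
      group_rows(test, data$region, "region")
    )
    for (i in seq_len(nrow(grp_tbl))) {
      idx <- grp_tbl$idx[[i]]
      out[[length(out) + 1]] <- tibble(
        scheme = "forward", grouping = grp_tbl$grouping[i],
        group = grp_tbl$group[i], model = m,
        n_records = length(idx),
        n_animals = dplyr::n_distinct(data$animal_id[idx]),
        accuracy = safe_cor(pred[idx], y[idx])
      )
    }
  }
  res <- dplyr::bind_rows(out)
  finalize_validation(res)
}

# ---- internal helpers -----------------------------------------------------

add_grouping <- function(data, grouping) {
  if (grouping == "exotic_class" && !"exotic_class" %in% names(data)) {
    if (!"exotic_pct" %in% names(data)) {
      stop_sg("grouping by exotic_class needs `exotic_class` or `exotic_pct`.",
              "schema")
    }
    data$exotic_class <- assign_exotic_class(data$exotic_pct)
  }
  if (!grouping %in% names(data)) {
    stop_sg(paste0("grouping column `", grouping, "` not found."), "schema")
  }
  data
}

make_kernel <- function(design, herds, models) {
  if (!any(grepl("S", models))) return(NULL)
  if (is.null(herds)) {
    stop_sg("spatial models need herd coordinates.", "missing_coordinates")
  }
  herds <- as_tibble(herds)
  hsub <- herds[match(design$herd_id, as.character(herds$herd_id)), ]
  if (anyNA(hsub$x_km)) stop_sg("herds lack coordinates.", "missing_coordinates")
  spatial_kernel(hsub[, c("herd_id", "x_km", "y_km")], rho = 1)
}

respec <- function(spec, model) {
  s <- spec
  s$model <- model
  s$include_herd <- grepl("H", model)
  s$include_spatial <- grepl("S", model)
  s$include_pe <- grepl("P", model)
  s
}

safe_cor <- function(pred, obs) {
  if (length(obs) < 3) {
    warn("fewer than 3 masked records in a group; accuracy NA.")
    return(NA_real_)
  }
  if (sd(pred) == 0 || sd(obs) == 0) {
    warn("zero-variance predictions or observations in a group; accuracy NA.")
    return(NA_real_)
  }
  cor(pred, obs)
}

group_rows <- function(test, fac, grouping) {
  lv <- sort(unique(as.character(fac[test])))
  tibble(grouping = grouping, group = lv,
         idx = lapply(lv, function(l) which(test & as.character(fac) == l)))
}

# refit one model on `train` rows and return predictions for all records
refit_predict <- function(data, y, design, grm, herds, kernel, spec_m,
                          method, vc_m, train, response) {
  if (method == "mme") {
    if (is.null(vc_m)) {
      full_fit <- fit_model(data, grm, herds, spec_m, response = response,
                            design = design, store_loglik = FALSE)
      vc_m <- vc_of(full_fit)
    }
    sol <- mme_solve(design, y, spec_m, grm, kernel, vc_m,
                     sigma2_beta = spec_m$sigma2_beta, subset = train)
    sol$fitted
  } else {
    fit <- fit_model(data, grm, herds, spec_m, response = response,
                     design = design, subset = train, store_loglik = FALSE)
    predict(fit)
  }
}

fold_refit_validate <- function(data, y, g, design, grm, herds, models, spec,
                                method, vc, scheme, grouping, response) {
  kernel <- make_kernel(design, herds, models)
  lv <- sort(unique(g))
  if (length(lv) < 2) stop_sg("grouping needs at least 2 levels.", "empty_split")
  out <- list()
  for (m in models) {
    spec_m <- respec(spec, m)
    vc_m <- vc[[m]]
    if (method == "mme" && is.null(vc_m)) {
      full_fit <- fit_model(data, grm, herds, spec_m, response = response,
                            design = design, store_loglik = FALSE)
      vc_m <- vc_of(full_fit)
    }
    for (l in lv) {
      mask <- g == l
      if (all(mask)) stop_sg("a fold leaves an empty training set.", "empty_split")
      pred <- refit_predict(data, y, design, grm, herds, kernel, spec_m,
                            method, vc_m, train = !mask, response = response)
      out[[length(out) + 1]] <- tibble(
        scheme = scheme, grouping = grouping, group = l, model = m,
        n_records = sum(mask),
        n_animals = dplyr::n_distinct(data$animal_id[mask]),
        accuracy = safe_cor(pred[mask], y[mask])
      )
    }
  }
  finalize_validation(dplyr::bind_rows(out))
}

finalize_validation <- function(res) {
  summ <- res |>
    dplyr::filter(.data$group != "overall") |>
    dplyr::group_by(.data$model, .data$grouping) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy, na.rm = TRUE),
      weighted_accuracy = stats::weighted.mean(.data$accuracy, .data$n_records,
                                               na.rm = TRUE),
      .groups = "drop")
  structure(res, summary = summ,
            class = c("gblup_validation", class(res)))
}

#' @export
print.gblup_validation <- function(x, ...) {
  NextMethod()
  cat("\nAverage accuracy by model (plain / record-weighted):\n")
  print(attr(x, "summary"))
  invisible(x)
}

#' EBV shift between models against the spatial field
#'
#' Per animal, the difference in posterior-mean EBV between a non-spatial
#' and a spatial model is regressed (ordinary least squares) on the
#' spatial-model posterior-mean spatial effect at the animal's herd. A
#' positive slope with substantial R-squared is the signature of spatial
#' confounding: the non-spatial model inflates EBVs of animals in good
#' environments and deflates them in poor ones.
#'
#' @param fit_a Fit without the spatial term (e.g. GH).
#' @param fit_b Fit with the spatial term (e.g. GHS); the spatial effect is
#'   taken from this fit.
#' @return Object of class `ebv_shift`: list with `slope`, `intercept`,
#'   `r_squared`, and `data` (tibble `animal_id`, `delta`, `spatial`).
#' @export
ebv_shift_vs_spatial <- function(fit_a, fit_b) {
  if (!identical(fit_a$design$animal_id, fit_b$design$animal_id)) {
    stop_sg("fits cover different animals.", "mismatch")
  }
  if (is.null(fit_b$draws$s)) {
    stop_sg("second fit has no spatial term.", "unsupported_model")
  }
  delta <- rowMeans(fit_a$draws$a) - rowMeans(fit_b$draws$a)
  amap <- fit_b$records |> dplyr::distinct(.data$animal_id, .data$herd_id)
  s_hat <- rowMeans(fit_b$draws$s)
  sstar <- s_hat[match(amap$herd_id[match(fit_b$design$animal_id,
                                          amap$animal_id)],
                       fit_b$design$herd_id)]
  if (sd(sstar) == 0) {
    stop_sg("zero variance in the spatial effect; regression undefined.",
            "degenerate_regression")
  }
  tab <- tibble(animal_id = fit_b$design$animal_id, delta = delta,
                spatial = sstar)
  if (all(delta == 0)) {
    inform("all EBV differences are zero; slope 0 and R^2 0 by convention.")
    out <- list(slope = 0, intercept = 0, r_squared = 0, data = tab)
  } else {
    m <- lm(delta ~ spatial, data = tab)
    out <- list(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
                r_squared = summary(m)$r.squared, data = tab)
  }
  structure(out, class = "ebv_shift")
}

#' @export
print.ebv_shift <- function(x, ...) {
  cat("<ebv_shift> slope = ", round(x$slope, 4), ", R^2 = ",
      round(x$r_squared, 4), " over ", nrow(x$data), " animals\n", sep = "")
  invisible(x)
}

#' Overlap of top-ranked animals between two fits
#'
#' Size of the intersection of the top-`k` animal sets ranked by
#' posterior-mean EBV in each fit. Ties are broken by animal id (ascending).
#'
#' @param fit_a,fit_b `gblup_fit` objects over the same animals.
#' @param k Number of top animals.
#' @return Integer overlap count.
#' @export
top_k_overlap <- function(fit_a, fit_b, k) {
  if (k <= 0) stop_sg("k must be positive.", "invalid_k")
  ids <- fit_a$design$animal_id
  if (k > length(ids)) stop_sg("k exceeds the number of animals.", "invalid_k")
  if (!identical(sort(ids), sort(fit_b$design$animal_id))) {
    stop_sg("fits cover different animals.", "mismatch")
  }
  top <- function(f) {
    e <- rowMeans(f$draws$a)
    f$design$animal_id[order(-e, f$design$animal_id)][seq_len(k)]
  }
  length(intersect(top(fit_a), top(fit_b)))
}
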