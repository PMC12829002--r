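#' Watanabe-Akaike information criterion
#'
#' Computed from the stored per-record, per-draw log-likelihood matrix:
#' `lppd = sum_i log(mean_d exp(ll[i, d]))`, `p_waic = sum_i var_d(ll[i, d])`
#' and `WAIC = -2 (lppd - p_waic)`. Lower is better.
#'
#' @param x A `gblup_fit`, or a records x draws log-likelihood matrix.
#' @return Tibble with `waic`, `lppd`, `p_waic`, `n_records`, `n_draws`.
#' @export
waic <- function(x) {
  ll <- if (inherits(x, "gblup_fit")) x$loglik else as.matrix(x)
  if (is.null(ll)) {
    stop_sg("fit was run with store_loglik = FALSE; no WAIC available.",
            "missing_loglik")
  }
  if (ncol(ll) < 2) stop_sg("WAIC needs at least 2 retained draws.", "waic")
  if (any(!is.finite(ll))) {
    bad <- which(rowSums(!is.finite(ll)) > 0)
    stop_sg(paste0("non-finite log-likelihoods for record(s) ",
                   paste(head(bad, 5), collapse = ", "),
                   if (length(bad) > 5) " ..."), "waic")
  }
  # log-mean-exp per record, guarded against underflow
  mx <- apply(ll, 1, max)
  lppd_i <- mx + log(rowMeans(exp(ll - mx)))
  p_i <- apply(ll, 1, var)
  lppd <- sum(lppd_i); p_waic <- sum(p_i)
  tibble(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic,
         n_records = nrow(ll), n_draws = ncol(ll))
}

#' Realised spatial variance at the herd locations
#'
#' The spatial variance parameter describes the field over all space; the
#' realised spatial variance is the variance of the field values at the
#' observed herd locations, summarised over posterior draws: for each
#' retained draw the variance across herds of the spatial-effect vector is
#' computed, and the posterior mean and sd of those per-draw variances are
#' reported. When more draws are available than `n_samples`, a deterministic
#' thinning to `n_samples` draws is used.
#'
#' @param fit A `gblup_fit` from a spatial model.
#' @param n_samples Number of posterior realisations to use (default 1000).
#' @return Tibble with `mean`, `sd`, `n_samples`.
#' @export
realized_spatial_variance <- function(fit, n_samples = 1000) {
  if (is.null(fit$draws$s)) {
    stop_sg("model has no spatial term; realised spatial variance undefined.",
            "unsupported_model")
  }
  S <- fit$draws$s
  nd <- ncol(S)
  if (nd > n_samples) {
    S <- S[, round(seq(1, nd, length.out = n_samples)), drop = FALSE]
  }
  v <- apply(S, 2, var)
  tibble(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
         n_samples = ncol(S))
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("<gblup_fit> model ", x$model, ": ", x$n_records, " records, ",
      length(x$design$animal_id), " animals, ", length(x$design$herd_id),
      " herds, ", ncol(x$draws$a), " retained draws",
      if (!is.na(x$mh_acceptance))
        sprintf(", MH acceptance %.2f", x$mh_acceptance),
      "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Tidy posterior summaries of a GBLUP fit
#'
#' @param x A `gblup_fit`.
#' @param effects Which block to summarise: `"variance"` (variance
#'   components, range and heritability; default), `"fixed"`, `"ebv"`,
#'   `"herd"`, `"spatial"`, `"pe"`.
#' @param conf_level Credible-interval mass (default 0.95, equal-tailed).
#' @param ... Unused.
#' @return Tibble with `term`/id, `estimate` (posterior mean), `std.error`
#'   (posterior sd), `conf.low`, `conf.high`.
#' @export
tidy.gblup_fit <- function(x, effects = c("variance", "fixed", "ebv", "herd",
                                          "spatial", "pe"),
                           conf_level = 0.95, ...) {
  effects <- match.arg(effects)
  al <- (1 - conf_level) / 2
  summ <- function(M, id_name, ids) {
    tibble(!!id_name := ids,
           estimate = rowMeans(M),
           std.error = apply(M, 1, sd),
           conf.low = apply(M, 1, quantile, probs = al),
           conf.high = apply(M, 1, quantile, probs = 1 - al))
  }
  switch(effects,
    variance = summ(t(x$draws$vc), "term", colnames(x$draws$vc)),
    fixed = summ(x$draws$b, "term", rownames(x$draws$b)),
    ebv = summ(x$draws$a, "animal_id", x$design$animal_id),
    herd = {
      if (is.null(x$draws$h)) stop_sg("model has no herd term.", "unsupported_model")
      summ(x$draws$h, "herd_id", x$design$herd_id)
    },
    spatial = {
      if (is.null(x$draws$s)) stop_sg("model has no spatial term.", "unsupported_model")
      summ(x$draws$s, "herd_id", x$design$herd_id)
    },
    pe = {
      if (is.null(x$draws$p)) stop_sg("model has no permanent-environment term.",
                                      "unsupported_model")
      summ(x$draws$p, "animal_id", x$design$animal_id)
    })
}

#' One-row model summary
#'
#' @param x A `gblup_fit`.
#' @param ... Unused.
#' @return Tibble with model label, WAIC pieces, posterior-mean heritability,
#'   sizes and MH acceptance.
#' @export
glance.gblup_fit <- function(x, ...) {
  w <- if (!is.null(x$loglik)) waic(x) else
    tibble(waic = NA_real_, lppd = NA_real_, p_waic = NA_real_)
  vc <- colMeans(x$draws$vc)
  tibble(model = x$model, waic = w$waic, lppd = w$lppd, p_waic = w$p_waic,
         h2 = unname(vc["h2"]),
         sigma2_g = unname(vc["sigma2_g"]),
         sigma2_e = unname(vc["sigma2_e"]),
         n_records = x$n_records,
         n_animals = length(x$design$animal_id),
         n_draws = ncol(x$draws$a),
         mh_acceptance = x$mh_acceptance,
         runtime_s = x$runtime_s)
}

#' Posterior-mean estimated breeding values
#'
#' @param fit A `gblup_fit`.
#' @return Tibble `animal_id`, `ebv`.
#' @export
ebv <- function(fit) {
  tibble(animal_id = fit$design$animal_id, ebv = rowMeans(fit$draws$a))
}

#' Predict record-level phenotypes from posterior means
#'
#' Linear predictor `X b + a + h + s` (terms present in the model;
#' permanent-environment effects are animal-history effects and are not
#' used for phenotype prediction). With `rows = NULL` predictions are for
#' every record of the design the model was built on, including records the
#' fit never saw (their herd/animal effects take prior/kriging means).
#'
#' @param object A `gblup_fit`.
#' @param rows Optional record rows (indices into the full design).
#' @param ... Unused.
#' @return Numeric vector of predicted (standardised) phenotypes.
#' @export
predict.gblup_fit <- function(object, rows = NULL, ...) {
  d <- object$design
  rows <- rows %||% seq_len(nrow(d$X))
  bh <- rowMeans(object$draws$b)
  ah <- rowMeans(object$draws$a)
  out <- drop(d$X[rows, , drop = FALSE] %*% bh) + ah[d$ia[rows]]
  if (!is.null(object$draws$h)) out <- out + rowMeans(object$draws$h)[d$ih[rows]]
  if (!is.null(object$draws$s)) out <- out + rowMeans(object$draws$s)[d$ih[rows]]
  unname(out)
}
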