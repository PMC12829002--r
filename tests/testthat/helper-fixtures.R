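# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

# a small complete dataset with GRM and generative-scale response
tiny_dataset <- function() {
  if (is.null(.fixture_env$tiny)) {
    ds <- simulate_dataset(sim_config(n_animals = 120, n_snps = 400, seed = 77))
    cfg <- ds$truth$config
    ds$phenotypes$y <- (ds$phenotypes$milk_yield - cfg$mean_yield_l) /
      cfg$sd_yield_l
    ds$phenotypes$milk_yield_std <- as.numeric(standardise(ds$phenotypes$milk_yield))
    ds$grm <- vanraden_grm(ds$geno)
    .fixture_env$tiny <- ds
  }
  .fixture_env$tiny
}

quick_spec <- function(model, n_iter = 600, burnin = 200, thin = 2, seed = 1,
                       ...) {
  model_spec(model, n_iter = n_iter, burnin = burnin, thin = thin,
             seed = seed, ...)
}

# minimal stand-in fit objects for evaluation-layer unit tests
fake_fit <- function(ebv, records, model = "X", s_by_herd = NULL,
                     h_by_herd = NULL) {
  animal_id <- names(ebv)
  herd_id <- sort(unique(records$herd_id))
  draws <- list(a = matrix(ebv, ncol = 1, dimnames = list(animal_id, NULL)),
                b = matrix(0, 1, 1), vc = matrix(0, 1, 1))
  if (!is.null(s_by_herd)) {
    draws$s <- matrix(s_by_herd[herd_id], ncol = 1,
                      dimnames = list(herd_id, NULL))
  }
  if (!is.null(h_by_herd)) {
    draws$h <- matrix(h_by_herd[herd_id], ncol = 1,
                      dimnames = list(herd_id, NULL))
  }
  structure(list(
    model = model, draws = draws,
    design = list(animal_id = animal_id, herd_id = herd_id,
                  ia = match(records$animal_id, animal_id),
                  ih = match(records$herd_id, herd_id)),
    records = tibble::tibble(animal_id = records$animal_id,
                             herd_id = records$herd_id),
    rows = seq_len(nrow(records))
  ), class = "gblup_fit")
}
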