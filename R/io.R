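#' Filter raw test-day records
#'
#' Applies the standard edits: daily milk yield within 1-45 L, age at first
#' calving at least 18 months, and days in milk within 4-500 days. All
#' bounds are inclusive. Rules are evaluated independently on the raw table
#' and a record is dropped once if it violates any of them; the report
#' counts violations per rule. Parity is recoded to the three levels 1, 2
#' and 3+.
#'
#' @param raw Tibble with at least `milk_yield`, `dim`,
#'   `age_first_calving`, `parity`.
#' @return List with `phenotypes` (filtered tibble, parity recoded) and
#'   `report` (tibble: rule, violations; plus kept/dropped totals as
#'   attributes printed by the report).
#' @export
filter_phenotypes <- function(raw) {
  raw <- as_tibble(raw)
  need <- c("milk_yield", "dim", "age_first_calving", "parity")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop_sg(paste0("missing required column(s): ", paste(miss, collapse = ", ")),
            "schema")
  }
  ok_yield <- raw$milk_yield >= 1 & raw$milk_yield <= 45
  ok_dim <- raw$dim >= 4 & raw$dim <= 500
  ok_age <- raw$age_first_calving >= 18
  keep <- ok_yield & ok_dim & ok_age
  out <- raw[keep, , drop = FALSE]
  out$parity <- recode_parity(suppressWarnings(
    as.integer(gsub("\\+", "", as.character(out$parity)))))
  report <- tibble(
    rule = c("milk_yield_1_45_l", "dim_4_500_d", "age_first_calving_ge_18_mo",
             "total_dropped", "kept"),
    records = c(sum(!ok_yield), sum(!ok_dim), sum(!ok_age),
                sum(!keep), sum(keep))
  )
  list(phenotypes = out, report = report)
}

#' Standardise a numeric vector
#'
#' Centres and scales to zero mean and unit variance using the population
#' standard deviation (divide by n). When `stats` is supplied (a list with
#' `mean` and `sd`, e.g. from the training set), those statistics are
#' reused so held-out data are standardised without information leakage.
#'
#' @param values Numeric vector.
#' @param stats Optional `list(mean =, sd =)` reference statistics.
#' @return Standardised vector with attributes `mean` and `sd`.
#' @export
standardise <- function(values, stats = NULL) {
  if (is.null(stats)) {
    if (length(unique(values)) < 2) {
      stop_sg("need at least 2 distinct values to standardise.", "degenerate")
    }
    m <- mean(values)
    s <- sqrt(mean((values - m)^2))  # population sd
    stats <- list(mean = m, sd = s)
  }
  if (!is.finite(stats$sd) || stats$sd == 0) {
    stop_sg("zero or non-finite sd; cannot standardise.", "degenerate")
  }
  out <- (values - stats$mean) / stats$sd
  attr(out, "mean") <- stats$mean
  attr(out, "sd") <- stats$sd
  out
}

#' Write / read a simulated dataset as plain-text files
#'
#' Phenotypes and herd locations go to CSV, genotypes to the dosage TSV of
#' [write_genotypes()], and (when present) each ground-truth component to
#' its own CSV. [read_dataset()] reproduces the tables exactly (numeric
#' round-trip via full-precision formatting).
#'
#' @param dataset Output of [simulate_dataset()] (truth optional).
#' @param dir Directory to create/use.
#' @return `dir`, invisibly (write) or the dataset list (read).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset$phenotypes, file.path(dir, "phenotypes.csv"),
                   progress = FALSE)
  readr::write_csv(dataset$herds, file.path(dir, "herds.csv"), progress = FALSE)
  if (!is.null(dataset$geno)) {
    write_genotypes(dataset$geno, file.path(dir, "genotypes.tsv"))
  }
  if (!is.null(dataset$truth)) {
    tr <- dataset$truth
    readr::write_csv(tr$breeding_values, file.path(dir, "truth_breeding_values.csv"), progress = FALSE)
    readr::write_csv(tr$herd_effects, file.path(dir, "truth_herd_effects.csv"), progress = FALSE)
    readr::write_csv(tr$spatial_field, file.path(dir, "truth_spatial_field.csv"), progress = FALSE)
    readr::write_csv(tr$pe_effects, file.path(dir, "truth_pe_effects.csv"), progress = FALSE)
    readr::write_csv(tr$fixed_effects, file.path(dir, "truth_fixed_effects.csv"), progress = FALSE)
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  ph <- readr::read_csv(file.path(dir, "phenotypes.csv"),
                        show_col_types = FALSE, progress = FALSE)
  if ("parity" %in% names(ph)) {
    ph$parity <- factor(as.character(ph$parity), levels = c("1", "2", "3+"))
  }
  herds <- readr::read_csv(file.path(dir, "herds.csv"),
                           show_col_types = FALSE, progress = FALSE)
  geno <- NULL
  if (file.exists(file.path(dir, "genotypes.tsv"))) {
    geno <- read_genotypes(file.path(dir, "genotypes.tsv"))
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth_breeding_values.csv"))) {
    truth <- list(
      breeding_values = readr::read_csv(file.path(dir, "truth_breeding_values.csv"), show_col_types = FALSE, progress = FALSE),
      herd_effects = readr::read_csv(file.path(dir, "truth_herd_effects.csv"), show_col_types = FALSE, progress = FALSE),
      spatial_field = readr::read_csv(file.path(dir, "truth_spatial_field.csv"), show_col_types = FALSE, progress = FALSE),
      pe_effects = readr::read_csv(file.path(dir, "truth_pe_effects.csv"), show_col_types = FALSE, progress = FALSE),
      fixed_effects = readr::read_csv(file.path(dir, "truth_fixed_effects.csv"), show_col_types = FALSE, progress = FALSE)
    )
  }
  list(phenotypes = ph, herds = herds, geno = geno, truth = truth)
}
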