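#' Simulation configuration
#'
#' Parameters of the synthetic spectral-count generator, which emulates the
#' study design the pipeline targets: two groups measured in 3 runs each
#' (pooled samples run on gel), overdispersed counts, a strongly right-skewed
#' abundance distribution with most proteins in the very-low tier, and a
#' minority of proteins differentially expressed or present in only one
#' group.
#'
#' Per protein i a baseline expected count `mu_i` is drawn log-normal
#' (`meanlog`, `sdlog`); counts are negative binomial with mean
#' `mu_i * f_{i,g}` and dispersion `theta` (smaller theta = more
#' overdispersion). The fold factor f is `effect_size` for overexpressed
#' proteins in the test group, `1/effect_size` for underexpressed ones, and 0
#' in the group where a unique protein is absent.
#'
#' @param n_proteins number of proteins.
#' @param n_runs_per_group runs per group (>= 2; default 3).
#' @param length_range integer range of protein lengths (residues).
#' @param meanlog,sdlog log-normal parameters of the baseline expected SpC;
#'   the defaults put the bulk of proteins in the very-low abundance tier.
#' @param theta negative-binomial dispersion (size) parameter.
#' @param frac_over,frac_under,frac_unique_test,frac_unique_ref fractions of
#'   proteins in each perturbed class; must sum to <= 1.
#' @param effect_size multiplicative fold change (> 1) for over/under
#'   proteins.
#' @param test_group,ref_group group labels.
#' @param seed integer seed; a single seed drives all randomness.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_proteins = 500, n_runs_per_group = 3,
                       length_range = c(100L, 2000L),
                       meanlog = log(4), sdlog = 1.1, theta = 5,
                       frac_over = 0.05, frac_under = 0.05,
                       frac_unique_test = 0.02, frac_unique_ref = 0.02,
                       effect_size = 4,
                       test_group = "cancer", ref_group = "fertile",
                       seed = 42L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              n_runs_per_group = as.integer(n_runs_per_group),
              length_range = as.integer(length_range),
              meanlog = meanlog, sdlog = sdlog, theta = theta,
              frac_over = frac_over, frac_under = frac_under,
              frac_unique_test = frac_unique_test,
              frac_unique_ref = frac_unique_ref,
              effect_size = effect_size,
              test_group = test_group, ref_group = ref_group,
              seed = as.integer(seed))
  fr <- c(cfg$frac_over, cfg$frac_under, cfg$frac_unique_test,
          cfg$frac_unique_ref)
  if (cfg$n_proteins < 1) config_error("n_proteins must be positive")
  if (cfg$n_runs_per_group < 2) config_error("n_runs_per_group must be >= 2")
  if (any(fr < 0) || sum(fr) > 1)
    config_error("category fractions must be >= 0 and sum to <= 1")
  if (cfg$effect_size <= 1) config_error("effect_size must exceed 1")
  if (cfg$theta <= 0) config_error("theta must be positive")
  if (length(cfg$length_range) != 2 || cfg$length_range[1] < 1 ||
      diff(cfg$length_range) < 0)
    config_error("length_range must be an increasing positive pair")
  if (identical(cfg$test_group, cfg$ref_group))
    config_error("group labels must differ")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a spectral-count dataset with known ground truth
#'
#' @param config a [sim_config()].
#' @return List with `matrix` (an [spc_matrix()]) and `truth` (data.frame:
#'   `accession`, `true_category` in unchanged/overexpressed/underexpressed/
#'   unique_test/unique_reference, `true_fold_change`, `mu` baseline mean),
#'   plus the generating `config`. Reproducible for a fixed seed.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  np <- config$n_proteins
  nr <- config$n_runs_per_group

  n_over <- round(config$frac_over * np)
  n_under <- round(config$frac_under * np)
  n_ut <- round(config$frac_unique_test * np)
  n_ur <- round(config$frac_unique_ref * np)
  truth_cat <- rep("unchanged", np)
  idx <- seq_len(n_over + n_under + n_ut + n_ur)
  truth_cat[idx] <- rep(c("overexpressed", "underexpressed", "unique_test",
                          "unique_reference"),
                        times = c(n_over, n_under, n_ut, n_ur))
  # shuffle so perturbed proteins are not clustered at the top of the matrix
  truth_cat <- sample(truth_cat)

  lengths <- sample(config$length_range[1]:config$length_range[2], np,
                    replace = TRUE)
  mu <- stats::rlnorm(np, meanlog = config$meanlog, sdlog = config$sdlog)

  fold <- rep(1, np)
  fold[truth_cat == "overexpressed"] <- config$effect_size
  fold[truth_cat == "underexpressed"] <- 1 / config$effect_size
  f_test <- fold
  f_ref <- rep(1, np)
  f_test[truth_cat == "unique_reference"] <- 0
  f_ref[truth_cat == "unique_test"] <- 0

  draw <- function(f) {
    m <- matrix(0, np, nr)
    for (r in seq_len(nr))
      m[, r] <- stats::rnbinom(np, size = config$theta, mu = mu * f)
    m
  }
  counts <- cbind(draw(f_test), draw(f_ref))
  run_ids <- c(paste0(config$test_group, "_r", seq_len(nr)),
               paste0(config$ref_group, "_r", seq_len(nr)))
  groups <- stats::setNames(rep(c(config$test_group, config$ref_group),
                                each = nr), run_ids)
  accessions <- sprintf("SYN%04d", seq_len(np))
  mat <- spc_matrix(counts, accessions, lengths, run_ids, groups)
  truth <- data.frame(accession = accessions, true_category = truth_cat,
                      true_fold_change = fold, mu = mu,
                      stringsAsFactors = FALSE)
  list(matrix = mat, truth = truth, config = config)
}

#' Compare pipeline calls against simulation ground truth
#'
#' Builds the truth x called confusion matrix and, for the pooled
#' differentially-expressed class (over + under + unique), sensitivity
#' (called-and-true / true) and false discovery rate (called-and-false /
#' called). Unique-protein sensitivity is reported among unique-truth
#' proteins whose mean SpC in the present group reaches the detection floor
#' (others are undetectable by construction).
#'
#' @param records DEP records data.frame from [run_dep_analysis()].
#' @param truth truth data.frame from [simulate_dataset()].
#' @param detection_threshold detection floor used for the unique-sensitivity
#'   denominator.
#' @return List with `confusion` (table), `sensitivity`, `fdr`,
#'   `unique_sensitivity`, and the underlying counts.
#' @export
evaluate_recovery <- function(records, truth, detection_threshold = 1.7) {
  if (!setequal(records$accession, truth$accession))
    contract_error("records and truth cover different protein universes")
  truth <- truth[match(records$accession, truth$accession), , drop = FALSE]
  dep_cats <- c("overexpressed", "underexpressed", "unique_test",
                "unique_reference")
  confusion <- table(truth = truth$true_category, called = records$category)
  true_de <- truth$true_category %in% dep_cats
  called_de <- records$category %in% dep_cats
  sens <- if (any(true_de)) sum(true_de & called_de) / sum(true_de) else NA_real_
  fdr <- if (any(called_de)) sum(called_de & !true_de) / sum(called_de) else 0
  uniq_true <- truth$true_category %in% c("unique_test", "unique_reference")
  detectable <- ifelse(truth$true_category == "unique_test",
                       records$meanSpC_test, records$meanSpC_ref) >=
    detection_threshold
  denom <- uniq_true & detectable
  uniq_sens <- if (any(denom))
    sum(denom & records$category == truth$true_category) / sum(denom)
  else NA_real_
  list(confusion = confusion, sensitivity = sens, fdr = fdr,
       unique_sensitivity = uniq_sens,
       n_true_de = sum(true_de), n_called_de = sum(called_de),
       n_true_unique_detectable = sum(denom))
}
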