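#' Abundance-tier rule set
#'
#' The differential caller judges each protein at thresholds that depend on
#' its spectral-count abundance tier. The defaults are the study thresholds:
#'
#' | tier      | mean SpC      | p max | over ratio | under ratio |
#' |-----------|---------------|-------|------------|-------------|
#' | very_low  | \[1.7, 8)     | 0.001 | >= 2.5     | <= 0.4      |
#' | low       | \[8, 20)      | 0.01  | >= 2.5     | <= 0.4      |
#' | medium    | \[20, 80)     | 0.05  | >= 2.0     | <= 0.5      |
#' | high      | \[80, Inf)    | 0.05  | >= 1.5     | <= 0.67     |
#'
#' Tiers are contiguous half-open intervals `[spc_lo, spc_hi)`: the printed
#' integer bins ("1.7-7", "8-19", "20-79", ">80") leave gaps for fractional
#' mean SpC values, and the half-open convention closes them while agreeing
#' with every printed integer. A mean SpC below 1.7 is below detection.
#'
#' @param tiers a data.frame with columns `name`, `spc_lo`, `spc_hi`, `p_max`,
#'   `over_ratio_min`, `under_ratio_max`; defaults to the table above.
#' @return A validated `tier_rules` data.frame.
#' @export
tier_rules <- function(tiers = NULL) {
  if (is.null(tiers)) {
    tiers <- data.frame(
      name = c("very_low", "low", "medium", "high"),
      spc_lo = c(1.7, 8, 20, 80),
      spc_hi = c(8, 20, 80, Inf),
      p_max = c(0.001, 0.01, 0.05, 0.05),
      over_ratio_min = c(2.5, 2.5, 2.0, 1.5),
      under_ratio_max = c(0.4, 0.4, 0.5, 0.67),
      stringsAsFactors = FALSE
    )
  }
  tiers <- as.data.frame(tiers, stringsAsFactors = FALSE)
  need <- c("name", "spc_lo", "spc_hi", "p_max", "over_ratio_min", "under_ratio_max")
  if (!all(need %in% colnames(tiers)))
    config_error(paste("tier rules need columns:", paste(need, collapse = ", ")))
  tiers <- tiers[order(tiers$spc_lo), , drop = FALSE]
  if (anyDuplicated(tiers$name)) config_error("tier names must be unique")
  if (any(tiers$spc_hi <= tiers$spc_lo)) config_error("tier intervals must be non-empty")
  if (nrow(tiers) > 1 &&
      any(abs(tiers$spc_hi[-nrow(tiers)] - tiers$spc_lo[-1]) > 1e-12))
    config_error("tiers must be contiguous and non-overlapping")
  if (any(tiers$p_max <= 0 | tiers$p_max > 1))
    config_error("tier p_max must lie in (0, 1]")
  if (any(tiers$over_ratio_min <= 1) || any(tiers$under_ratio_max >= 1) ||
      any(tiers$under_ratio_max <= 0))
    config_error("need over_ratio_min > 1 > under_ratio_max > 0 in every tier")
  rownames(tiers) <- NULL
  class(tiers) <- c("tier_rules", "data.frame")
  tiers
}

#' Assign an abundance tier from mean spectral count
#'
#' @param mean_spc non-negative mean spectral count (vectorized).
#' @param rules a [tier_rules()] rule set.
#' @return Character vector of tier names, `"below_detection"` for values
#'   under the lowest tier's lower edge.
#' @examples
#' assign_tier(c(1, 5, 8, 100), tier_rules())
#' @export
assign_tier <- function(mean_spc, rules = tier_rules()) {
  rules <- tier_rules(rules)
  vapply(mean_spc, function(x) {
    if (is.na(x)) return(NA_character_)
    hit <- which(x >= rules$spc_lo & x < rules$spc_hi)
    if (length(hit) == 0) "below_detection" else rules$name[hit[1L]]
  }, character(1))
}

#' Classify presence of a protein in the two compared groups
#'
#' A group "has" a protein when its mean SpC reaches the detection floor
#' (default 1.7, the lower edge of the lowest abundance tier). A protein is
#' uniquely expressed in a group when it is detected there and literally
#' absent (mean SpC exactly zero) in the other group.
#'
#' @param mean_spc_test,mean_spc_ref non-negative mean SpC in the test and
#'   reference groups (vectorized).
#' @param detection_threshold detection floor on mean SpC.
#' @return Character vector in `{"both", "test_only", "reference_only",
#'   "neither"}`.
#' @export
classify_presence <- function(mean_spc_test, mean_spc_ref,
                              detection_threshold = 1.7) {
  stopifnot(length(mean_spc_test) == length(mean_spc_ref))
  out <- character(length(mean_spc_test))
  for (i in seq_along(out)) {
    t <- mean_spc_test[i]; r <- mean_spc_ref[i]
    if (t < 0 || r < 0) contract_error("mean SpC must be non-negative")
    out[i] <-
      if (t < detection_threshold && r < detection_threshold) "neither"
      else if (t >= detection_threshold && r == 0) "test_only"
      else if (r >= detection_threshold && t == 0) "reference_only"
      else "both"
  }
  out
}

#' Two-sample differential test on NSAF replicate values
#'
#' Default method is Welch's unequal-variance t-test on `log(NSAF + p0)`,
#' where the pseudocount `p0` stabilizes zeros (recommended: half the smallest
#' nonzero NSAF in the experiment). The test is symmetric in the two groups.
#' When both groups are exactly constant the t statistic is undefined; the
#' function returns 1 when the constants agree (no evidence of change) and 0
#' when they differ.
#'
#' @param nsaf_test,nsaf_ref numeric vectors of per-run NSAF values
#'   (>= 2 replicates each).
#' @param pseudocount added before taking logs.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
test_differential <- function(nsaf_test, nsaf_ref, pseudocount = 1e-6) {
  if (length(nsaf_test) < 2 || length(nsaf_ref) < 2)
    nsafde_error("need at least 2 replicates per group",
                 "nsafde_insufficient_replicates_error")
  x <- log(nsaf_test + pseudocount)
  y <- log(nsaf_ref + pseudocount)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

# Fisher's exact alternative: 2x2 of (protein counts, all-other counts) summed
# per group. Offered for very low counts where a t-test is underpowered.
test_fisher_pooled <- function(spc_test, spc_ref, total_test, total_ref) {
  a <- round(sum(spc_test)); b <- round(sum(spc_ref))
  tab <- matrix(c(a, total_test - a, b, total_ref - b), nrow = 2)
  stats::fisher.test(tab)$p.value
}

#' Categorize one protein from tier, presence, NSAF ratio and p-value
#'
#' Uniquely expressed proteins short-circuit to `unique_test` /
#' `unique_reference`. Proteins below detection in both groups are
#' `below_detection`. Otherwise a protein is `overexpressed` when
#' `p <= p_max(tier)` and `ratio >= over_ratio_min(tier)`, `underexpressed`
#' when `p <= p_max(tier)` and `ratio <= under_ratio_max(tier)`, else
#' `unchanged`. All thresholds are inclusive.
#'
#' @param tier tier name from [assign_tier()], or `"below_detection"`.
#' @param presence presence state from [classify_presence()].
#' @param nsaf_ratio mean NSAF test / mean NSAF reference (required when
#'   presence is `"both"`).
#' @param p_value two-sided p-value (required when presence is `"both"`).
#' @param rules a [tier_rules()] rule set.
#' @return One of `"unchanged"`, `"overexpressed"`, `"underexpressed"`,
#'   `"unique_test"`, `"unique_reference"`, `"below_detection"`.
#' @export
call_dep <- function(tier, presence, nsaf_ratio = NA_real_,
                     p_value = NA_real_, rules = tier_rules()) {
  rules <- tier_rules(rules)
  if (presence == "test_only") return("unique_test")
  if (presence == "reference_only") return("unique_reference")
  if (presence == "neither" || tier == "below_detection")
    return("below_detection")
  if (is.na(nsaf_ratio) || is.na(p_value))
    contract_error("presence 'both' requires nsaf_ratio and p_value")
  row <- rules[rules$name == tier, , drop = FALSE]
  if (nrow(row) != 1) contract_error(sprintf("unknown tier: %s", tier))
  if (p_value <= row$p_max && nsaf_ratio >= row$over_ratio_min) return("overexpressed")
  if (p_value <= row$p_max && nsaf_ratio <= row$under_ratio_max) return("underexpressed")
  "unchanged"
}

#' Run the full differential-expression analysis
#'
#' End-to-end tiered caller: computes NSAF, per-group mean SpC and NSAF,
#' assigns each protein an abundance tier from the larger of its two group
#' mean SpCs (a protein well-measured in either group is judged at that
#' evidence level), partitions presence, tests common proteins, and
#' categorizes every protein. Deterministic for a fixed input.
#'
#' @param matrix an [spc_matrix()].
#' @param test_group,ref_group the two group labels to compare; the NSAF
#'   ratio is test over reference.
#' @param rules a [tier_rules()] rule set.
#' @param test `"welch_log_nsaf"` (default) or `"fisher_pooled"`.
#' @param detection_threshold detection floor on mean SpC.
#' @return A `dep_analysis` object: list with `records` (one row per protein:
#'   accession, tier, mean SpC and NSAF per group, nsaf_ratio, p_value,
#'   category), `summary` (a [partition_summary()]), and the call parameters.
#' @export
run_dep_analysis <- function(matrix, test_group, ref_group,
                             rules = tier_rules(),
                             test = c("welch_log_nsaf", "fisher_pooled"),
                             detection_threshold = 1.7) {
  stopifnot(inherits(matrix, "spc_matrix"))
  test <- match.arg(test)
  rules <- tier_rules(rules)
  if (identical(test_group, ref_group))
    design_error("test and reference groups must differ")
  test_runs <- group_runs(matrix, test_group)
  ref_runs <- group_runs(matrix, ref_group)
  if (length(test_runs) < 2 || length(ref_runs) < 2)
    design_error("each compared group needs at least 2 runs")

  nsaf <- compute_nsaf(matrix)
  keep_t <- setdiff(test_runs, nsaf$excluded_runs)
  keep_r <- setdiff(ref_runs, nsaf$excluded_runs)
  ms_t <- nsaf$group_mean_spc[, test_group]
  ms_r <- nsaf$group_mean_spc[, ref_group]
  mn_t <- nsaf$group_mean_nsaf[, test_group]
  mn_r <- nsaf$group_mean_nsaf[, ref_group]

  tier <- assign_tier(pmax(ms_t, ms_r), rules)
  presence <- classify_presence(ms_t, ms_r, detection_threshold)

  pseudo <- {
    nz <- nsaf$nsaf[nsaf$nsaf > 0 & !is.na(nsaf$nsaf)]
    if (length(nz)) min(nz) / 2 else 1e-6
  }
  n <- nrow(matrix$counts)
  ratio <- rep(NA_real_, n)
  pval <- rep(NA_real_, n)
  category <- character(n)
  tot_t <- sum(matrix$counts[, keep_t])
  tot_r <- sum(matrix$counts[, keep_r])
  for (i in seq_len(n)) {
    if (presence[i] == "both") {
      ratio[i] <- if (mn_r[i] == 0) {
        if (mn_t[i] == 0) NA_real_ else Inf
      } else mn_t[i] / mn_r[i]
      pval[i] <- if (test == "welch_log_nsaf") {
        test_differential(nsaf$nsaf[i, keep_t], nsaf$nsaf[i, keep_r], pseudo)
      } else {
        test_fisher_pooled(matrix$counts[i, keep_t], matrix$counts[i, keep_r],
                           tot_t, tot_r)
      }
    }
    category[i] <- call_dep(tier[i], presence[i], ratio[i], pval[i], rules)
  }

  records <- data.frame(
    accession = matrix$accessions,
    tier = tier,
    meanSpC_test = ms_t, meanSpC_ref = ms_r,
    meanNSAF_test = mn_t, meanNSAF_ref = mn_r,
    nsaf_ratio = ratio, p_value = pval,
    category = category,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(records = records, summary = partition_summary(records),
         test_group = test_group, ref_group = ref_group,
         test = test, rules = rules, pseudocount = pseudo),
    class = "dep_analysis"
  )
}

#' @export
print.dep_analysis <- function(x, ...) {
  cat(sprintf("dep_analysis: %s vs %s (%s)\n",
              x$test_group, x$ref_group, x$test))
  print(x$summary)
  invisible(x)
}

#' Partition accounting for a set of differential-expression records
#'
#' Counts proteins per category and checks the accounting identities:
#' `n_dep = n_over + n_under + n_unique_test + n_unique_reference` and
#' `n_common = n_over + n_under + n_unchanged` (proteins present in both
#' groups).
#'
#' @param records data.frame with a `category` column (as produced by
#'   [run_dep_analysis()]).
#' @return A `partition_summary` list of counts: `n_common`, `n_dep`,
#'   `n_over`, `n_under`, `n_unique_test`, `n_unique_reference`,
#'   `n_unchanged`, `n_below_detection`.
#' @export
partition_summary <- function(records) {
  cat_ <- records$category
  counts <- list(
    n_over = sum(cat_ == "overexpressed"),
    n_under = sum(cat_ == "underexpressed"),
    n_unchanged = sum(cat_ == "unchanged"),
    n_unique_test = sum(cat_ == "unique_test"),
    n_unique_reference = sum(cat_ == "unique_reference"),
    n_below_detection = sum(cat_ == "below_detection")
  )
  counts$n_common <- counts$n_over + counts$n_under + counts$n_unchanged
  counts$n_dep <- counts$n_over + counts$n_under +
    counts$n_unique_test + counts$n_unique_reference
  structure(counts[c("n_common", "n_dep", "n_over", "n_under",
                     "n_unique_test", "n_unique_reference",
                     "n_unchanged", "n_below_detection")],
            class = "partition_summary")
}

#' @export
print.partition_summary <- function(x, ...) {
  cat(sprintf(
    "common: %d | DEPs: %d (over %d, under %d, unique-test %d, unique-ref %d) | below detection: %d\n",
    x$n_common, x$n_dep, x$n_over, x$n_under,
    x$n_unique_test, x$n_unique_reference, x$n_below_detection))
  invisible(x)
}
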