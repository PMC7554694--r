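#' Normalized spectral abundance factors
#'
#' For protein i with spectral count SpC_i and length L_i in a run, the
#' spectral abundance factor is SAF_i = SpC_i / L_i and
#' NSAF_i = SAF_i / sum_j SAF_j, computed independently per run, so each run's
#' NSAF values sum to one. Group means are arithmetic means over that group's
#' runs. NSAF is computed per run and then averaged (not on pooled summed
#' counts) so run-to-run variability is preserved for the statistical test.
#'
#' Runs with zero total counts have no defined normalization; they are flagged,
#' given NA NSAF, and excluded from group means with a warning.
#'
#' @param matrix an [spc_matrix()].
#' @return An object of class `nsaf_table`: list with `nsaf` (proteins x runs
#'   matrix), `group_mean_nsaf` and `group_mean_spc` (proteins x groups
#'   matrices), and `excluded_runs` (character vector of zero-total runs).
#' @examples
#' m <- spc_matrix(matrix(c(10, 20), 2, 1), c("P1", "P2"), c(100L, 400L),
#'                 "r1", c(r1 = "a", r2 = "b"))
#' @export
compute_nsaf <- function(matrix) {
  stopifnot(inherits(matrix, "spc_matrix"))
  if (nrow(matrix$counts) < 1) contract_error("matrix has no proteins")
  saf <- matrix$counts / matrix$lengths
  totals <- colSums(saf)
  excluded <- matrix$run_ids[totals == 0]
  if (length(excluded))
    warning(sprintf("run(s) with zero total counts excluded from group means: %s",
                    paste(excluded, collapse = ", ")), call. = FALSE)
  nsaf <- sweep(saf, 2, totals, "/")
  nsaf[, totals == 0] <- NA_real_
  glabels <- sort(unique(unname(matrix$groups)))
  keep <- !(matrix$run_ids %in% excluded)
  nprot <- nrow(nsaf)
  group_mean_nsaf <- vapply(glabels, function(g) {
    runs <- matrix$run_ids[matrix$groups == g & keep]
    if (!length(runs)) return(rep(NA_real_, nprot))
    rowMeans(nsaf[, runs, drop = FALSE])
  }, numeric(nprot))
  group_mean_spc <- vapply(glabels, function(g) {
    runs <- matrix$run_ids[matrix$groups == g & keep]
    if (!length(runs)) return(rep(NA_real_, nprot))
    rowMeans(matrix$counts[, runs, drop = FALSE])
  }, numeric(nprot))
  group_mean_nsaf <- matrix(group_mean_nsaf, nrow = nprot)
  group_mean_spc <- matrix(group_mean_spc, nrow = nprot)
  dimnames(group_mean_nsaf) <- list(matrix$accessions, glabels)
  dimnames(group_mean_spc) <- list(matrix$accessions, glabels)
  structure(
    list(nsaf = nsaf, group_mean_nsaf = group_mean_nsaf,
         group_mean_spc = group_mean_spc, excluded_runs = excluded),
    class = "nsaf_table"
  )
}

#' Per-protein mean spectral count in a group
#'
#' Arithmetic mean of spectral counts over the group's runs, per protein.
#' Means can be fractional; the abundance tiers of the differential caller are
#' defined on this scale (the lowest tier starts at 1.7).
#'
#' @param matrix an [spc_matrix()].
#' @param group a group label present in the design.
#' @return Named numeric vector, one mean SpC per protein.
#' @export
mean_spc <- function(matrix, group) {
  stopifnot(inherits(matrix, "spc_matrix"))
  runs <- group_runs(matrix, group)
  rowMeans(matrix$counts[, runs, drop = FALSE])
}

#' Export an NSAF table as TSV
#'
#' Writes proteins x runs NSAF values followed by per-group mean NSAF and
#' mean SpC columns.
#'
#' @param nsaf an `nsaf_table` from [compute_nsaf()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_nsaf_table <- function(nsaf, path) {
  stopifnot(inherits(nsaf, "nsaf_table"))
  groups <- colnames(nsaf$group_mean_nsaf)
  tab <- data.frame(accession = rownames(nsaf$nsaf), nsaf$nsaf,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (g in groups) {
    tab[[paste0("meanNSAF_", g)]] <- nsaf$group_mean_nsaf[, g]
    tab[[paste0("meanSpC_", g)]] <- nsaf$group_mean_spc[, g]
  }
  write_tsv(tab, path, digits = 10)
}
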