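#' Spectral-count matrix container
#'
#' Bundles a proteins x runs matrix of MS/MS spectral counts (SpC) with the
#' protein sequence lengths needed for NSAF normalization and the run-to-group
#' design. This is the sole real-data input of the pipeline: everything
#' downstream (NSAF tables, tiered differential-expression calls, pathway
#' scores) is derived from it.
#'
#' @param counts integer matrix, proteins x runs, all values >= 0. Row names
#'   (if present) are ignored in favour of `accessions`.
#' @param accessions character vector of unique protein identifiers (e.g.
#'   UniProt accessions), one per row of `counts`.
#' @param lengths positive integer vector of protein lengths in amino-acid
#'   residues, one per row of `counts`.
#' @param run_ids character vector of unique run identifiers, one per column.
#' @param groups named character vector mapping every run id to a group label;
#'   at least two distinct labels are required for a comparison.
#' @return An object of class `spc_matrix` (a validated list with elements
#'   `counts`, `accessions`, `lengths`, `run_ids`, `groups`).
#' @examples
#' m <- spc_matrix(matrix(c(10L, 20L, 5L, 8L), 2, 2),
#'                 accessions = c("P1", "P2"), lengths = c(100L, 400L),
#'                 run_ids = c("r1", "r2"),
#'                 groups = c(r1 = "cancer", r2 = "fertile"))
#' dim(m$counts)
#' @export
spc_matrix <- function(counts, accessions, lengths, run_ids, groups) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) != length(accessions) || nrow(counts) != length(lengths))
    format_error("counts rows must match accessions and lengths")
  if (ncol(counts) != length(run_ids))
    format_error("counts columns must match run_ids")
  if (anyDuplicated(accessions)) {
    dup <- accessions[duplicated(accessions)][1L]
    format_error(sprintf("duplicate accession: %s", dup))
  }
  if (anyDuplicated(run_ids))
    format_error(sprintf("duplicate run id: %s", run_ids[duplicated(run_ids)][1L]))
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != floor(counts)))
    format_error("counts must be non-negative integers")
  if (any(!is.finite(lengths)) || any(lengths < 1) || any(lengths != floor(lengths)))
    format_error("protein lengths must be positive integers")
  missing_runs <- setdiff(run_ids, names(groups))
  if (length(missing_runs))
    design_error(sprintf("run(s) missing from design: %s",
                         paste(missing_runs, collapse = ", ")))
  groups <- groups[run_ids]
  if (length(unique(groups)) < 2)
    design_error("design must contain at least two distinct groups")
  dimnames(counts) <- list(accessions, run_ids)
  structure(
    list(counts = counts,
         accessions = as.character(accessions),
         lengths = as.numeric(lengths),
         run_ids = as.character(run_ids),
         groups = stats::setNames(as.character(groups), run_ids)),
    class = "spc_matrix"
  )
}

#' @export
print.spc_matrix <- function(x, ...) {
  cat(sprintf("spc_matrix: %d proteins x %d runs\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s (%d runs)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# run ids belonging to a group, with existence check
group_runs <- function(matrix, group) {
  if (!group %in% matrix$groups)
    design_error(sprintf("unknown group label: %s", group))
  matrix$run_ids[matrix$groups == group]
}
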