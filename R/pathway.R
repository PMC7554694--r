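#' Over-representation p-value (hypergeometric upper tail)
#'
#' Probability that a gene set of size `K` in a universe of `N` detected
#' proteins overlaps a DEP list of size `n` in at least `k` members, i.e.
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`. Returns 1 when `k = 0`.
#'
#' @param k observed overlap count.
#' @param K set size within the universe.
#' @param n DEP-list size.
#' @param N universe size.
#' @return p-value in `(0, 1]`.
#' @examples
#' overrepresentation_p(3, 4, 3, 10)  # 4/120
#' @export
overrepresentation_p <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N || k > min(K, n))
    contract_error("inconsistent hypergeometric counts")
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Additive activation z-score for a directional gene set
#'
#' For the set members that carry both an expected direction (the sign of
#' their expression change when the pathway or upstream regulator is active)
#' and an observed direction from the differential analysis, the score is
#' `z = (n_consistent - n_inconsistent) / sqrt(n_consistent + n_inconsistent)`,
#' a member being consistent when its observed sign equals its expected sign.
#' Antisymmetric: flipping every observed sign negates z.
#'
#' @param expected named numeric vector of expected signs (+1/-1) per member
#'   accession.
#' @param observed named numeric vector of observed signs (+1/-1) per
#'   accession; members absent from `observed` are not scored.
#' @return Finite z-score, or `NA` when no member is scoreable.
#' @export
activation_zscore <- function(expected, observed) {
  if (any(!expected %in% c(-1, 1)) || any(!observed %in% c(-1, 1)))
    contract_error("signs must be +1 or -1")
  common <- intersect(names(expected), names(observed))
  if (!length(common)) return(NA_real_)
  agree <- expected[common] == observed[common]
  (sum(agree) - sum(!agree)) / sqrt(length(common))
}

#' Activation state from a z-score
#'
#' `z > 2` predicts activation, `z < -2` deactivation; anything else —
#' including an undefined z and the boundary values of exactly +/-2 — yields
#' no prediction (the inequalities are strict).
#'
#' @param z z-score, possibly `NA`.
#' @return `"activated"`, `"deactivated"`, or `"no_prediction"` (vectorized).
#' @export
call_activation_state <- function(z) {
  out <- rep("no_prediction", length(z))
  out[!is.na(z) & z > 2] <- "activated"
  out[!is.na(z) & z < -2] <- "deactivated"
  out
}

# Observed expression signs from DEP categories: overexpressed and
# unique-in-test go up (+1), underexpressed and unique-in-reference go down
# (-1). Unique proteins participate because the study's pathway calls rest on
# both sets of DEPs; disable with include_unique = FALSE.
observed_signs <- function(records, include_unique = TRUE) {
  sign_of <- c(overexpressed = 1, underexpressed = -1)
  if (include_unique)
    sign_of <- c(sign_of, unique_test = 1, unique_reference = -1)
  keep <- records$category %in% names(sign_of)
  stats::setNames(unname(sign_of[records$category[keep]]),
                  records$accession[keep])
}

#' Enrichment and activation analysis over a gene-set collection
#'
#' For each set: hypergeometric over-representation of the DEP list within
#' the detected-protein universe, and (when directional annotations exist)
#' the activation z-score with its activated / deactivated / no-prediction
#' call. The DEP list is every protein categorized overexpressed,
#' underexpressed or uniquely expressed.
#'
#' @param records DEP records data.frame (from [run_dep_analysis()]).
#' @param sets a [gene_sets()] collection.
#' @param universe character vector of detected-protein accessions; must
#'   contain every DEP accession. Defaults to all accessions in `records`.
#' @param include_unique include uniquely expressed proteins as observed
#'   signs in z-scores.
#' @return data.frame of class `enrichment_table`, one row per set, sorted by
#'   p-value ascending with ties broken by set name: columns `set`, `k`, `K`,
#'   `n`, `N`, `p_value`, `neg_log10_p`, `z_score`, `activation_state`.
#' @export
enrich_all <- function(records, sets, universe = records$accession,
                       include_unique = TRUE) {
  stopifnot(inherits(sets, "gene_sets"))
  dep_cats <- c("overexpressed", "underexpressed", "unique_test",
                "unique_reference")
  deps <- records$accession[records$category %in% dep_cats]
  if (length(setdiff(deps, universe)))
    contract_error("DEP accession(s) outside the universe")
  universe <- unique(universe)
  N <- length(universe)
  n <- length(deps)
  obs <- observed_signs(records, include_unique)
  rows <- lapply(names(sets$sets), function(nm) {
    members <- intersect(sets$sets[[nm]], universe)
    K <- length(members)
    k <- length(intersect(members, deps))
    p <- overrepresentation_p(k, K, n, N)
    z <- NA_real_
    if (!is.null(sets$directions)) {
      d <- sets$directions[sets$directions$set == nm, , drop = FALSE]
      if (nrow(d)) {
        expected <- stats::setNames(d$sign, d$member)
        z <- activation_zscore(expected, obs)
      }
    }
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               p_value = p, neg_log10_p = -log10(p),
               z_score = z, activation_state = call_activation_state(z),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(), k = integer(), K = integer(),
               n = integer(), N = integer(), p_value = numeric(),
               neg_log10_p = numeric(), z_score = numeric(),
               activation_state = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Export a heat-map matrix for one gene set
#'
#' Builds the set-member proteins x groups table of mean NSAF values (plus
#' the log2 ratio) that any plotting tool can render as a heat map of, e.g.,
#' oxidative-phosphorylation proteins. Row order follows the set definition.
#'
#' @param records DEP records data.frame.
#' @param members character vector of set-member accessions.
#' @param path optional output TSV path; when given the table is also written.
#' @return data.frame with columns `accession`, `meanNSAF_test`,
#'   `meanNSAF_ref`, `log2_ratio`, `category`.
#' @export
export_heatmap_matrix <- function(records, members, path = NULL) {
  keep <- members[members %in% records$accession]
  if (!length(keep))
    warning("gene set has no overlap with the analysis; empty matrix",
            call. = FALSE)
  idx <- match(keep, records$accession)
  out <- data.frame(
    accession = records$accession[idx],
    meanNSAF_test = records$meanNSAF_test[idx],
    meanNSAF_ref = records$meanNSAF_ref[idx],
    log2_ratio = log2(records$meanNSAF_test[idx] / records$meanNSAF_ref[idx]),
    category = records$category[idx],
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) write_tsv(out, path, digits = 10)
  out
}
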