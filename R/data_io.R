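#' Read a spectral-count matrix and its design
#'
#' The count file is a tab-delimited table with a header row: the first column
#' holds protein accessions, the second protein lengths (residues), and each
#' remaining column one run of spectral counts. The design file is a two-column
#' tab-delimited table (`run_id`, `group`) mapping every run to a group label.
#'
#' @param path path to the tab-delimited count matrix.
#' @param design_path path to the tab-delimited run-to-group design table.
#' @return A validated [spc_matrix()].
#' @export
read_count_matrix <- function(path, design_path) {
  if (!file.exists(path)) io_error(sprintf("count file not found: %s", path))
  if (!file.exists(design_path))
    io_error(sprintf("design file not found: %s", design_path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 3)
    format_error("count file needs accession, length and at least one run column")
  accessions <- tab[[1L]]
  lengths <- suppressWarnings(as.numeric(tab[[2L]]))
  if (any(is.na(lengths)))
    format_error("non-numeric protein length in count file")
  run_ids <- colnames(tab)[-(1:2)]
  counts <- suppressWarnings(
    vapply(tab[-(1:2)], as.numeric, numeric(nrow(tab)))
  )
  counts <- matrix(counts, nrow = nrow(tab), ncol = length(run_ids))
  if (any(is.na(counts)))
    format_error("non-numeric spectral count in count file")
  design <- utils::read.delim(design_path, header = TRUE, sep = "\t",
                              colClasses = "character")
  if (ncol(design) < 2) design_error("design file needs run_id and group columns")
  groups <- stats::setNames(design[[2L]], design[[1L]])
  spc_matrix(counts, accessions, lengths, run_ids, groups)
}

#' Write a spectral-count matrix and design to TSV
#'
#' @param matrix an [spc_matrix()].
#' @param path output path for the count matrix TSV.
#' @param design_path output path for the design TSV.
#' @return invisibly, the two paths.
#' @export
write_count_matrix <- function(matrix, path, design_path) {
  tab <- data.frame(accession = matrix$accessions,
                    length = as.integer(matrix$lengths),
                    matrix$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(tab) <- c("accession", "length", matrix$run_ids)
  write_tsv(tab, path)
  write_tsv(data.frame(run_id = matrix$run_ids,
                       group = unname(matrix$groups),
                       stringsAsFactors = FALSE),
            design_path)
  invisible(c(path, design_path))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Blank lines are skipped;
#' duplicate members within a line are removed with a warning. An optional
#' sidecar table ([read_directions()]) supplies signed expected directions for
#' activation scoring.
#'
#' @param path path to the GMT file.
#' @return A `gene_sets` object: list with `sets` (named list of character
#'   member vectors) and `directions` (initially `NULL`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) io_error(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3)
      format_error(sprintf("GMT line %d has fewer than 3 fields", i))
    name <- fields[1L]
    if (name %in% names(sets))
      format_error(sprintf("duplicate gene-set name at line %d: %s", i, name))
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT line %d (%s): duplicate members removed", i, name),
              call. = FALSE)
      members <- unique(members)
    }
    sets[[name]] <- members
  }
  gene_sets(sets)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (set name -> member accessions).
#' @param directions optional data.frame with columns `set`, `member`, `sign`
#'   (+1 when the member goes up under activation of the set, -1 when it goes
#'   down); every row must reference an existing member.
#' @return A `gene_sets` object.
#' @export
gene_sets <- function(sets, directions = NULL) {
  if (anyDuplicated(names(sets)))
    format_error("gene-set names must be unique")
  sets <- lapply(sets, function(m) unique(as.character(m)))
  obj <- structure(list(sets = sets, directions = NULL), class = "gene_sets")
  if (!is.null(directions)) obj <- attach_directions(obj, directions)
  obj
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("gene_sets: %d sets, %s directional annotations\n",
              length(x$sets),
              if (is.null(x$directions)) "no" else nrow(x$directions)))
  invisible(x)
}

#' Read a signed-direction sidecar table
#'
#' Tab-delimited with header `set<TAB>member<TAB>sign`; `sign` is +1 or -1 and
#' states the member's expected expression direction when the set (pathway or
#' upstream regulator) is active.
#'
#' @param path path to the sidecar TSV.
#' @param sets a `gene_sets` object the directions refer to.
#' @return `sets` with the `directions` field populated.
#' @export
read_directions <- function(path, sets) {
  if (!file.exists(path)) io_error(sprintf("directions file not found: %s", path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "numeric"))
  colnames(tab) <- c("set", "member", "sign")
  attach_directions(sets, tab)
}

attach_directions <- function(sets, directions) {
  directions <- as.data.frame(directions, stringsAsFactors = FALSE)
  if (!all(c("set", "member", "sign") %in% colnames(directions)))
    format_error("directions table needs set, member and sign columns")
  directions$sign <- as.numeric(directions$sign)
  if (any(!directions$sign %in% c(-1, 1)))
    format_error("direction signs must be +1 or -1")
  for (i in seq_len(nrow(directions))) {
    s <- directions$set[i]
    if (is.null(sets$sets[[s]]))
      format_error(sprintf("direction references unknown set: %s", s))
    if (!directions$member[i] %in% sets$sets[[s]])
      format_error(sprintf("direction references non-member %s of set %s",
                           directions$member[i], s))
  }
  sets$directions <- directions
  sets
}

# Shared TSV writer: fixed column order, explicit float formatting so output
# files are byte-stable for a fixed input.
write_tsv <- function(tab, path, digits = 6) {
  ok <- tryCatch({
    con <- file(path, open = "wt")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) io_error(sprintf("cannot open for writing: %s", path))
  on.exit(close(con))
  out <- tab
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- out[[j]]
      s <- ifelse(is.na(v), "NA",
                  ifelse(is.infinite(v), ifelse(v > 0, "Inf", "-Inf"),
                         formatC(v, digits = digits, format = "g")))
      out[[j]] <- s
    }
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a results table to TSV
#'
#' Writes any of the pipeline's result tables (differential-expression
#' records, enrichment records, partition summaries) as tab-delimited text
#' with a header and explicit float precision, so files are byte-stable and
#' round-trip losslessly through [read_results()].
#'
#' @param table a data.frame of results.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_results <- function(table, path) {
  write_tsv(as.data.frame(table), path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path path to a TSV written by [write_results()].
#' @return data.frame with types restored (numeric columns re-parsed).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) io_error(sprintf("results file not found: %s", path))
  utils::read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
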