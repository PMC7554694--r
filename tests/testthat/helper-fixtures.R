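# Small in-code builders used across test files.

# counts: proteins x (2*nrep) matrix, first nrep columns = test group
make_matrix <- function(counts, lengths = rep(100L, nrow(counts)),
                        nrep = ncol(counts) / 2,
                        test_group = "cancer", ref_group = "fertile") {
  counts <- as.matrix(counts)
  np <- nrow(counts)
  run_ids <- c(paste0("t", seq_len(nrep)),
               paste0("r", seq_len(ncol(counts) - nrep)))
  groups <- stats::setNames(
    rep(c(test_group, ref_group), c(nrep, ncol(counts) - nrep)), run_ids)
  spc_matrix(counts, paste0("P", seq_len(np)), lengths, run_ids, groups)
}

write_counts_files <- function(mat, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  counts <- file.path(dir, "counts.tsv")
  design <- file.path(dir, "design.tsv")
  write_count_matrix(mat, counts, design)
  list(counts = counts, design = design, dir = dir)
}

extdata <- function(f) system.file("extdata", f, package = "nsafDE")
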