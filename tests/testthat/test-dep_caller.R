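# Independent restatement of the tiered calling rules, written directly from
# the threshold table as nested literals. Used as the oracle for call_dep.
oracle_call <- function(mean_spc_max, presence, ratio, p) {
  if (presence == "test_only") return("unique_test")
  if (presence == "reference_only") return("unique_reference")
  if (presence == "neither" || mean_spc_max < 1.7) return("below_detection")
  if (mean_spc_max < 8) { pmax_ <- 0.001; over <- 2.5; under <- 0.4 }
  else if (mean_spc_max < 20) { pmax_ <- 0.01; over <- 2.5; under <- 0.4 }
  else if (mean_spc_max < 80) { pmax_ <- 0.05; over <- 2.0; under <- 0.5 }
  else { pmax_ <- 0.05; over <- 1.5; under <- 0.67 }
  if (p <= pmax_ && ratio >= over) return("overexpressed")
  if (p <= pmax_ && ratio <= under) return("underexpressed")
  "unchanged"
}

test_that("tier assignment is total and exact on the boundary grid", {
  grid <- c(0, 1, 1.69, 1.7, 5, 7.99, 8, 15, 19.99, 20, 79.99, 80, 100, 1e6)
  want <- c("below_detection", "below_detection", "below_detection",
            "very_low", "very_low", "very_low",
            "low", "low", "low",
            "medium", "medium",
            "high", "high", "high")
  expect_identical(assign_tier(grid), want)
  # totality: every non-negative value lands in exactly one category
  set.seed(3)
  x <- c(runif(500, 0, 200), runif(100, 0, 2))
  expect_true(all(assign_tier(x) %in%
                    c("below_detection", "very_low", "low", "medium", "high")))
})

test_that("custom tier rules are validated", {
  expect_error(tier_rules(data.frame(name = "a", spc_lo = 1, spc_hi = 1,
                                     p_max = 0.05, over_ratio_min = 2,
                                     under_ratio_max = 0.5)),
               class = "nsafde_config_error")
  bad <- tier_rules()
  bad$spc_lo[2] <- 9  # gap between tiers
  expect_error(tier_rules(bad), class = "nsafde_config_error")
  bad2 <- tier_rules()
  bad2$over_ratio_min[1] <- 0.9
  expect_error(tier_rules(bad2), class = "nsafde_config_error")
})

test_that("presence classification follows the detection floor and absence rule", {
  expect_identical(classify_presence(5, 0), "test_only")
  expect_identical(classify_presence(0, 5), "reference_only")
  expect_identical(classify_presence(5, 5), "both")
  expect_identical(classify_presence(1, 0), "neither")
  expect_identical(classify_presence(0, 0), "neither")
  # detected in one group, trace (nonzero) in the other: compared, not unique
  expect_identical(classify_presence(5, 1), "both")
  expect_identical(classify_presence(1.7, 0), "test_only")  # floor inclusive
  # threshold sweep: unique requires floor in one group AND exact zero in other
  for (thr in c(1, 1.7, 3)) {
    expect_identical(classify_presence(thr, 0, thr), "test_only")
    expect_identical(classify_presence(thr - 1e-9, 0, thr), "neither")
  }
})

test_that("differential test matches an independent Welch computation", {
  # manual Welch t on the log scale, written from the textbook formula
  welch_p <- function(x, y) {
    vx <- var(x) / length(x); vy <- var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    2 * pt(-abs(t), df)
  }
  set.seed(5)
  for (i in 1:25) {
    a <- rlnorm(3, -6, 0.4); b <- rlnorm(3, -6, 0.4)
    p0 <- 1e-6
    expect_equal(test_differential(a, b, p0),
                 welch_p(log(a + p0), log(b + p0)), tolerance = 1e-12)
    # symmetry under group swap
    expect_equal(test_differential(a, b, p0), test_differential(b, a, p0))
  }
  # clear separation with tiny jitter is highly significant
  a <- 0.001 * c(1, 1.0001, 0.9999); b <- 0.01 * c(1, 1.0001, 0.9999)
  expect_lt(test_differential(a, b), 0.001)
  # identical constant vectors: no evidence of change
  expect_gte(test_differential(c(0.1, 0.1, 0.1), c(0.1, 0.1, 0.1)), 0.99)
  expect_error(test_differential(0.1, c(0.1, 0.2)),
               class = "nsafde_insufficient_replicates_error")
})

test_that("call_dep agrees with the brute-force rule restatement on a full grid", {
  tiers <- data.frame(name = c("very_low", "low", "medium", "high"),
                      spc = c(5, 15, 50, 100))
  ratios <- c(0.3, 0.4, 0.5, 0.67, 1, 1.5, 2, 2.5, 3)
  ps <- c(1e-4, 1e-3, 5e-3, 1e-2, 0.04, 0.05, 0.1)
  n_cells <- 0
  for (i in seq_len(nrow(tiers))) for (r in ratios) for (p in ps) {
    got <- call_dep(tiers$name[i], "both", r, p)
    want <- oracle_call(tiers$spc[i], "both", r, p)
    expect_identical(got, want,
                     label = sprintf("tier=%s ratio=%g p=%g: %s",
                                     tiers$name[i], r, p, got))
    n_cells <- n_cells + 1
  }
  expect_gte(n_cells, 250)
  # unique presence short-circuits regardless of ratio/p
  expect_identical(call_dep("low", "test_only"), "unique_test")
  expect_identical(call_dep("high", "reference_only"), "unique_reference")
  expect_identical(call_dep("below_detection", "neither"), "below_detection")
  expect_error(call_dep("low", "both"), class = "nsafde_contract_error")
})

test_that("threshold monotonicity: larger ratios never undo an over call", {
  for (tier in c("very_low", "low", "medium", "high")) {
    rules <- tier_rules()
    row <- rules[rules$name == tier, ]
    p <- row$p_max
    cats <- vapply(seq(row$over_ratio_min, row$over_ratio_min + 3, by = 0.25),
                   function(r) call_dep(tier, "both", r, p), character(1))
    expect_true(all(cats == "overexpressed"))
    cats <- vapply(seq(0.01, row$under_ratio_max, by = 0.03),
                   function(r) call_dep(tier, "both", r, p), character(1))
    expect_true(all(cats == "underexpressed"))
  }
})

test_that("identical groups yield zero differential calls", {
  set.seed(21)
  counts <- matrix(rpois(60, 20), 10, 6)
  counts[, 4:6] <- counts[, 1:3]
  m <- make_matrix(counts, nrep = 3)
  ana <- run_dep_analysis(m, "cancer", "fertile")
  expect_equal(ana$summary$n_dep, 0)
  expect_true(all(ana$records$nsaf_ratio[ana$records$category != "below_detection"] == 1))
})

test_that("a protein present only in the test group is called unique", {
  counts <- rbind(c(6, 7, 5, 0, 0, 0),
                  c(10, 12, 9, 11, 10, 12))
  m <- make_matrix(counts, nrep = 3)
  ana <- run_dep_analysis(m, "cancer", "fertile")
  expect_identical(ana$records$category[1], "unique_test")
  expect_equal(ana$summary$n_unique_test, 1)
  expect_equal(ana$summary$n_dep, 1)
  expect_true(is.na(ana$records$p_value[1]))  # no test across presence gap
})

test_that("analysis is deterministic: identical input gives identical output files", {
  set.seed(9)
  counts <- matrix(rnbinom(300, size = 5, mu = 10), 50, 6)
  m <- make_matrix(counts, nrep = 3)
  d <- withr::local_tempdir()
  for (run in 1:2) {
    ana <- run_dep_analysis(m, "cancer", "fertile")
    write_results(ana$records, file.path(d, sprintf("rec%d.tsv", run)))
  }
  expect_identical(readLines(file.path(d, "rec1.tsv")),
                   readLines(file.path(d, "rec2.tsv")))
})

test_that("fisher_pooled alternative runs and respects group symmetry of counts", {
  counts <- rbind(c(30, 28, 32, 5, 6, 4),
                  c(10, 12, 9, 11, 10, 12))
  m <- make_matrix(counts, nrep = 3)
  ana <- run_dep_analysis(m, "cancer", "fertile", test = "fisher_pooled")
  expect_true(all(ana$records$p_value >= 0 & ana$records$p_value <= 1,
                  na.rm = TRUE))
  expect_lt(ana$records$p_value[1], 0.05)
})

test_that("partition accounting identities hold, including on random records", {
  # the published category counts: 208 under, 62 over, 182 unique in the
  # reference (fertile) group, 8 unique in the test (cancer) group
  records <- data.frame(category = rep(
    c("underexpressed", "overexpressed", "unique_reference", "unique_test",
      "unchanged"),
    times = c(208, 62, 182, 8, 868)))
  s <- partition_summary(records)
  expect_equal(s$n_dep, 460)
  expect_equal(s$n_common, 208 + 62 + 868)

  expect_equal(partition_summary(data.frame(category = character()))$n_dep, 0)

  set.seed(13)
  cats <- c("unchanged", "overexpressed", "underexpressed", "unique_test",
            "unique_reference", "below_detection")
  for (i in 1:25) {
    recs <- data.frame(category = sample(cats, sample(1:200, 1), replace = TRUE))
    s <- partition_summary(recs)
    expect_equal(s$n_dep,
                 s$n_over + s$n_under + s$n_unique_test + s$n_unique_reference)
    expect_equal(s$n_common, s$n_over + s$n_under + s$n_unchanged)
    expect_equal(s$n_common + s$n_unique_test + s$n_unique_reference +
                   s$n_below_detection, nrow(recs))
  }
})
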