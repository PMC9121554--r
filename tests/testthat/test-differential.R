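make_cm <- function(counts, cond = c("A", "A", "B", "B")) {
  n <- nrow(counts)
  peaks <- interval_set("chr1", seq_len(n) * 1000, seq_len(n) * 1000 + 500,
                        name = paste0("pk", seq_len(n)))
  samples <- data.frame(sample_id = paste0(cond, "_", seq_along(cond)),
                        condition = cond,
                        replicate = stats::ave(seq_along(cond), cond,
                                               FUN = seq_along),
                        stringsAsFactors = FALSE)
  # interval_set sorts by coordinates; counts rows are already in that order
  count_matrix(peaks, samples, counts)
}

test_that("consensus keeps merged intervals with enough supporting samples", {
  r1 <- interval_set("chr1", c(100, 5000), c(300, 5200), name = c("x", "y"))
  r2 <- interval_set("chr1", 150, 350)
  cons <- build_consensus(list(r1 = r1, r2 = r2), min_samples = 2)
  expect_equal(nrow(cons), 1)
  expect_equal(c(cons$start, cons$end), c(100, 350))
  cons1 <- build_consensus(list(r1 = r1, r2 = r2), min_samples = 1)
  expect_equal(nrow(cons1), 2)
  expect_error(build_consensus(list(r1 = r1, r2 = r2), min_samples = 3),
               "exceeds")

  # random fixture vs direct per-interval oracle
  sets <- lapply(41:44, function(s) random_interval_set(80, seed = s))
  names(sets) <- paste0("s", 1:4)
  cons2 <- build_consensus(sets, min_samples = 3)
  pooled <- do.call(rbind, lapply(sets, function(s)
    as.data.frame(s)[c("chrom", "start", "end")]))
  uni <- merge_set(interval_set(pooled$chrom, pooled$start, pooled$end))
  support <- vapply(seq_len(nrow(uni)), function(i) {
    one <- interval_set(uni$chrom[i], uni$start[i], uni$end[i])
    sum(vapply(sets, function(s) nrow(intersect_sets(one, s)) > 0, logical(1)))
  }, numeric(1))
  keep <- uni[support >= 3, , drop = FALSE]
  expect_equal(as.data.frame(cons2)[c("chrom", "start", "end")],
               as.data.frame(keep)[c("chrom", "start", "end")],
               ignore_attr = TRUE)
})

test_that("median-of-ratios size factors behave on closed-form cases", {
  set.seed(1)
  base <- matrix(rnbinom(200, mu = 50, size = 10), ncol = 2)
  same <- normalize_counts(make_cm(cbind(base[, 1], base[, 1]), c("A", "B")))
  expect_equal(unname(same$size_factors), c(1, 1))

  doubled <- normalize_counts(make_cm(cbind(base[, 1], base[, 1] * 2),
                                      c("A", "B")))
  expect_equal(unname(doubled$size_factors[2] / doubled$size_factors[1]), 2)

  no_common <- matrix(c(0, 5, 5, 0), ncol = 2)  # no all-nonzero peak
  expect_message(normalize_counts(make_cm(no_common, c("A", "B"))),
                 "total-count")
})

test_that("differential test is invariant to count scaling and label swap", {
  set.seed(2)
  cnt <- matrix(rnbinom(400, mu = 80, size = 10), ncol = 4)
  cm <- make_cm(cnt)
  res <- test_differential(cm)
  res10 <- test_differential(make_cm(cnt * 10L))
  expect_equal(res$log2fc, res10$log2fc, tolerance = 0.02)

  # same data, condition labels exchanged
  swapped <- test_differential(make_cm(cnt, cond = c("B", "B", "A", "A")))
  expect_equal(swapped$log2fc, -res$log2fc, tolerance = 1e-6)
  expect_equal(swapped$pvalue, res$pvalue, tolerance = 1e-6)
})

test_that("identical counts in both conditions give null results", {
  cnt <- matrix(c(50L, 70L, 50L, 70L), nrow = 1)  # A = B exactly
  res <- test_differential(make_cm(cnt))
  expect_equal(res$log2fc, 0)
  expect_gt(res$pvalue, 0.99)
})

test_that("BH q-values are monotone in p-value rank", {
  set.seed(3)
  cnt <- matrix(rnbinom(2000, mu = 60, size = 8), ncol = 4)
  res <- test_differential(make_cm(cnt))
  o <- order(res$pvalue)
  expect_true(all(diff(res$qvalue[o]) >= -1e-12))
  expect_true(all(res$pvalue >= 0 & res$pvalue <= 1))
  expect_true(all(res$qvalue >= 0 & res$qvalue <= 1))
})

test_that("unique-peak calls partition the union in occupancy mode", {
  a1 <- interval_set("chr1", c(100, 1000, 5000), c(300, 1200, 5200))
  a2 <- interval_set("chr1", c(120, 1020, 5050), c(310, 1210, 5250))
  b1 <- interval_set("chr1", c(1000, 9000), c(1200, 9200))
  b2 <- interval_set("chr1", c(1010, 9050), c(1190, 9300))
  calls <- call_unique_peaks(list(a1, a2, b1, b2), c("A", "A", "B", "B"))
  # peaks at 100 and 5000 in both A reps only; 9000 in both B reps only
  expect_equal(nrow(calls$unique_a), 2)
  expect_equal(nrow(calls$unique_b), 1)
  expect_equal(nrow(calls$shared), 1)
  total <- nrow(calls$unique_a) + nrow(calls$unique_b) + nrow(calls$shared)
  expect_equal(total, nrow(merge_set(interval_set(
    rep("chr1", 8), c(100, 120, 1000, 1020, 5000, 5050, 9000, 9050),
    c(300, 310, 1200, 1210, 5200, 5250, 9200, 9300)))))

  expect_warning(call_unique_peaks(list(a1, b1), c("A", "B")),
                 "fewer than 2 replicates")
  expect_error(call_unique_peaks(list(a1, a2), c("A", "A")),
               "two conditions")
  expect_error(call_unique_peaks(list(a1, b1), c("A", "B"), mode = "affinity"),
               "results")
})

test_that("affinity mode recovers truth-unique peaks on synthetic counts", {
  ds <- simulate_dataset(test_config(seed = 5,
                                     n_unique_peaks_per_condition = 50,
                                     n_shared_peaks = 100,
                                     chrom_length = 2.5e6, n_genes = 60))
  cm <- normalize_counts(ds$counts)
  res <- test_differential(cm)
  calls <- call_unique_peaks(ds$peaksets, ds$samples$condition,
                             mode = "affinity", results = res,
                             alpha_fdr = 0.05, lfc_threshold = 1)
  truth_a <- ds$truth$peak_id[ds$truth$unique_to == "A"]
  truth_b <- ds$truth$peak_id[ds$truth$unique_to == "B"]
  recall_a <- mean(truth_a %in% calls$unique_a$name)
  recall_b <- mean(truth_b %in% calls$unique_b$name)
  expect_gte(recall_a, 0.9)
  expect_gte(recall_b, 0.9)
})

test_that("dispersion estimate recovers the generating value", {
  set.seed(6)
  cnt <- matrix(rnbinom(4000 * 4, mu = 100, size = 10), ncol = 4)
  cm <- normalize_counts(make_cm(cnt))
  expect_equal(estimate_dispersion(cm), 0.1, tolerance = 0.25)
})
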