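# Fixtures and independent brute-force oracles used across the suite.

random_interval_set <- function(n, seed, chroms = c("chr1", "chr2"),
                                max_start = 10000, max_width = 200,
                                label = "rand") {
  set.seed(seed)
  start <- sample.int(max_start, n, replace = TRUE) - 1
  width <- sample.int(max_width, n, replace = TRUE)
  interval_set(sample(chroms, n, replace = TRUE), start, start + width,
               name = paste0(label, "_", seq_len(n)), label = label)
}

# all-pairs O(n*m) intersection oracle, independent of GenomicRanges
brute_intersect <- function(a, b, min_overlap = 1) {
  rows <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= min_overlap)
      rows[[length(rows) + 1]] <- data.frame(
        a_name = a$name[i], b_name = b$name[j], overlap = ov,
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(a_name = character(), b_name = character(),
                      overlap = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$a_name, out$b_name), , drop = FALSE]
}

# base-resolution coverage oracle over a bounded coordinate space
coverage_vector <- function(x, chrom, limit) {
  v <- logical(limit)
  sub <- x[x$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sub))) {
    lo <- max(sub$start[i], 0); hi <- min(sub$end[i], limit)
    if (hi > lo) v[(lo + 1):hi] <- TRUE
  }
  v
}

# small deterministic gene fixture: two genes on chr1 (one per strand),
# one gene on chr2
tiny_genes <- function() {
  gene_models(
    data.frame(gene_id = c("gA", "gB", "gC"),
               chrom = c("chr1", "chr1", "chr2"),
               start = c(10000, 50000, 5000),
               end = c(20000, 60000, 9000),
               strand = c("+", "-", "+"), stringsAsFactors = FALSE),
    exons = data.frame(gene_id = c("gA", "gA", "gB", "gB", "gC"),
                       start = c(10000, 18000, 50000, 58000, 5000),
                       end = c(11000, 20000, 51000, 60000, 9000),
                       stringsAsFactors = FALSE))
}

# exhaustive PWM p-value oracle: enumerate all 4^w k-mers with true scores
enumerate_pvalue <- function(p, score) {
  w <- p$width
  grid <- expand.grid(rep(list(1:4), w))
  sc <- as.matrix(grid)
  tot <- numeric(nrow(sc))
  prob <- rep(1, nrow(sc))
  for (j in seq_len(w)) {
    tot <- tot + p$lodds[cbind(sc[, j], j)]
    prob <- prob * p$background[sc[, j]]
  }
  sum(prob[tot >= score - 1e-12])
}

# closed-form Poisson two-group LRT p-value with offsets
poisson_lrt_pvalue <- function(y, s, ia, ib) {
  mle_ll <- function(yy, ss) {
    m <- sum(yy) / sum(ss)
    if (m == 0) return(0)
    sum(stats::dpois(yy, ss * m, log = TRUE))
  }
  lr <- 2 * (mle_ll(y[ia], s[ia]) + mle_ll(y[ib], s[ib]) - mle_ll(y, s))
  stats::pchisq(max(lr, 0), 1, lower.tail = FALSE)
}

# a small fast simulation config for tests that do not need default scale
test_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_chromosomes = 1, chrom_length = 1.2e6, n_genes = 30,
         n_shared_peaks = 30, n_unique_peaks_per_condition = 10,
         n_super_enhancers = 2, seed = seed),
    list(...))
  do.call(sim_config, args)
}
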