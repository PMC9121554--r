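#' Count matrix over consensus peaks
#'
#' @param peaks an `interval_set` of consensus peaks (one row per peak).
#' @param samples data frame with columns `sample_id`, `condition`,
#'   `replicate`.
#' @param counts non-negative integer matrix, `nrow(peaks)` x
#'   `nrow(samples)`; rows named by peak, columns by sample.
#' @return object of class `count_matrix` with elements `peaks`, `samples`,
#'   `counts`, `size_factors` (NULL until [normalize_counts()]).
#' @export
count_matrix <- function(peaks, samples, counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(peaks), ncol(counts) == nrow(samples),
            all(counts >= 0),
            all(c("sample_id", "condition", "replicate") %in% names(samples)))
  rownames(counts) <- peaks$name
  colnames(counts) <- samples$sample_id
  structure(list(peaks = peaks, samples = as.data.frame(samples),
                 counts = counts, size_factors = NULL),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "peaks x", ncol(x$counts),
      "samples (conditions:",
      paste(unique(x$samples$condition), collapse = ", "), ")\n")
  invisible(x)
}

#' Build consensus peaks across samples
#'
#' Merges the union of all per-sample peak sets (>= 1 bp overlap joins) and
#' keeps the merged intervals supported by at least `min_samples` of the
#' input sets.
#'
#' @param peaksets named list of per-sample `interval_set` objects (>= 2).
#' @param min_samples minimum number of supporting sets.
#' @return `interval_set` of consensus peaks.
#' @export
build_consensus <- function(peaksets, min_samples = 2) {
  stopifnot(length(peaksets) >= 2)
  if (min_samples > length(peaksets))
    stop("min_samples (", min_samples, ") exceeds number of peak sets (",
         length(peaksets), ")")
  oc <- overlap_counts(peaksets)
  memb <- oc$membership
  support <- rowSums(as.matrix(memb[, -(1:4), drop = FALSE]))
  keep <- support >= min_samples
  interval_set(memb$chrom[keep], memb$start[keep], memb$end[keep],
               name = paste0("consensus_", seq_len(sum(keep))),
               label = "consensus")
}

#' Median-of-ratios size factors
#'
#' For each sample, the median across all-nonzero peaks of the ratio of its
#' count to the per-peak geometric mean; when no peak has all-nonzero counts
#' the function falls back to total-count scaling (factors proportional to
#' library size, geometric mean 1) with a message.
#'
#' @param x a `count_matrix`.
#' @return `x` with `size_factors` filled.
#' @export
normalize_counts <- function(x) {
  cnt <- x$counts
  if (any(colSums(cnt) == 0)) stop("every sample needs at least one nonzero count")
  ok <- rowSums(cnt == 0) == 0
  if (!any(ok)) {
    message("no peak with all-nonzero counts; falling back to total-count scaling")
    libs <- colSums(cnt)
    sf <- libs / exp(mean(log(libs)))
  } else {
    lg <- log(cnt[ok, , drop = FALSE])
    ref <- rowMeans(lg)
    sf <- exp(apply(lg - ref, 2, stats::median))
  }
  x$size_factors <- sf
  x
}

## normalized counts (computing size factors on demand)
norm_counts <- function(x) {
  if (is.null(x$size_factors)) x <- normalize_counts(x)
  sweep(x$counts, 2, x$size_factors, "/")
}

#' Common NB dispersion by method of moments
#'
#' Pools per-peak, per-condition moments of the normalized counts into a
#' single dispersion `alpha` under the parameterisation
#' `variance = mu + alpha * mu^2`.  The naive pooled estimator
#' `sum(v - m) / sum(m^2)` is biased downward because `E[m^2]` exceeds
#' `mu^2` by `var/n`; the denominator therefore uses the unbiased second
#' moment `m^2 - v/n`.  Conditions with a single replicate contribute
#' nothing (no within-group variance).
#'
#' @param x a `count_matrix`.
#' @return dispersion estimate (floored at 1e-8).
#' @export
estimate_dispersion <- function(x) {
  nc <- norm_counts(x)
  cond <- x$samples$condition
  num <- 0; den <- 0
  for (cc in unique(cond)) {
    sub <- nc[, cond == cc, drop = FALSE]
    n <- ncol(sub)
    if (n < 2) next
    m <- rowMeans(sub)
    v <- apply(sub, 1, stats::var)
    num <- num + sum(v - m)
    den <- den + sum(pmax(m^2 - v / n, 0))
  }
  if (den <= 0) return(1e-8)
  max(num / den, 1e-8)
}

## MLE of the NB mean with sample-specific multiplicative offsets s and
## fixed size (= 1/dispersion).  Closed form (mean(y)/s) when offsets are
## equal; 1-D likelihood optimisation otherwise.
nb_mle_mean <- function(y, s, size) {
  if (all(y == 0)) return(0)
  naive <- sum(y) / sum(s)
  if (length(unique(s)) == 1) return(mean(y) / s[1])
  f <- function(lm) -sum(stats::dnbinom(y, size = size, mu = s * exp(lm),
                                        log = TRUE))
  exp(stats::optimize(f, c(log(naive) - 6, log(naive) + 6))$minimum)
}

nb_loglik <- function(y, s, m, size) {
  sum(stats::dnbinom(y, size = size, mu = s * m, log = TRUE))
}

#' Differential accessibility test
#'
#' Two-group negative-binomial likelihood-ratio test per peak with a common
#' dispersion (see [estimate_dispersion()]) and size factors as
#' multiplicative offsets.  P-values are chi-squared with 1 df on the
#' likelihood ratio; q-values are Benjamini-Hochberg.  The fold change is
#' `log2((mean_a + 0.5)/(mean_b + 0.5))` on normalized means ("a" = first
#' condition level in sorted order), with a 0.5 pseudocount so it is always
#' finite.
#'
#' @param x a `count_matrix` with exactly two conditions.
#' @param alpha_fdr FDR threshold used downstream (stored in the result).
#' @param dispersion optional fixed dispersion overriding the common
#'   estimate (e.g. a near-zero value reproduces a Poisson test).
#' @return data frame, one row per peak: `peak, chrom, start, end, mean_a,
#'   mean_b, log2fc, pvalue, qvalue, unique_to` (the last is `"none"` here;
#'   see [call_unique_peaks()]).
#' @export
test_differential <- function(x, alpha_fdr = 0.05, dispersion = NULL) {
  conds <- sort(unique(x$samples$condition))
  if (length(conds) != 2) stop("two conditions required")
  if (is.null(x$size_factors)) x <- normalize_counts(x)
  disp <- if (is.null(dispersion)) estimate_dispersion(x) else dispersion
  size <- 1 / disp
  ia <- which(x$samples$condition == conds[1])
  ib <- which(x$samples$condition == conds[2])
  sf <- x$size_factors
  nc <- norm_counts(x)
  mean_a <- rowMeans(nc[, ia, drop = FALSE])
  mean_b <- rowMeans(nc[, ib, drop = FALSE])
  pv <- vapply(seq_len(nrow(x$counts)), function(i) {
    y <- x$counts[i, ]
    m0 <- nb_mle_mean(y, sf, size)
    ma <- nb_mle_mean(y[ia], sf[ia], size)
    mb <- nb_mle_mean(y[ib], sf[ib], size)
    lr <- 2 * (nb_loglik(y[ia], sf[ia], ma, size) +
               nb_loglik(y[ib], sf[ib], mb, size) -
               nb_loglik(y, sf, m0, size))
    stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  }, numeric(1))
  res <- data.frame(peak = x$peaks$name, chrom = x$peaks$chrom,
                    start = x$peaks$start, end = x$peaks$end,
                    mean_a = mean_a, mean_b = mean_b,
                    log2fc = log2((mean_a + 0.5) / (mean_b + 0.5)),
                    pvalue = pv, qvalue = bh_adjust(pv),
                    unique_to = "none", stringsAsFactors = FALSE)
  attr(res, "conditions") <- conds
  attr(res, "dispersion") <- disp
  attr(res, "alpha_fdr") <- alpha_fdr
  res
}

#' Call condition-unique and shared peaks
#'
#' Occupancy mode (the default, mirroring presence/absence reasoning over
#' duplicates): a merged union interval is unique to condition A when it is
#' supported by every A replicate and overlaps (>= 1 bp) no B replicate
#' peak; symmetrically for B; everything else in the union is shared.
#' Affinity mode instead thresholds the differential test:
#' `qvalue < alpha_fdr` and `|log2fc| >= lfc_threshold`, sign giving the
#' direction.
#'
#' @param peaksets named list of per-sample `interval_set` objects.
#' @param conditions character vector, one condition label per element of
#'   `peaksets` (exactly two distinct labels).
#' @param mode `"occupancy"` or `"affinity"`.
#' @param results differential-test result from [test_differential()]
#'   (required in affinity mode).
#' @param alpha_fdr,lfc_threshold affinity-mode thresholds.
#' @return list with `interval_set`s `unique_a`, `unique_b`, `shared` and
#'   the two condition labels in `conditions` ("a" = first sorted label).
#' @export
call_unique_peaks <- function(peaksets, conditions,
                              mode = c("occupancy", "affinity"),
                              results = NULL, alpha_fdr = 0.05,
                              lfc_threshold = 1) {
  mode <- match.arg(mode)
  conds <- sort(unique(conditions))
  if (length(conds) != 2) stop("two conditions required")
  if (mode == "occupancy") {
    if (any(table(conditions) < 2))
      warning("fewer than 2 replicates in a condition; ",
              "occupancy calls rest on a single sample")
    oc <- overlap_counts(peaksets)
    memb <- oc$membership
    pres <- as.matrix(memb[, -(1:4), drop = FALSE])
    in_a <- pres[, conditions == conds[1], drop = FALSE]
    in_b <- pres[, conditions == conds[2], drop = FALSE]
    ua <- rowSums(in_a) == ncol(in_a) & rowSums(in_b) == 0
    ub <- rowSums(in_b) == ncol(in_b) & rowSums(in_a) == 0
    mk <- function(keep, lab) {
      interval_set(memb$chrom[keep], memb$start[keep], memb$end[keep],
                   name = memb$name[keep], label = lab)
    }
    list(unique_a = mk(ua, paste0("unique_", conds[1])),
         unique_b = mk(ub, paste0("unique_", conds[2])),
         shared = mk(!ua & !ub, "shared"),
         conditions = conds)
  } else {
    if (is.null(results)) stop("affinity mode needs `results` from test_differential()")
    sig <- results$qvalue < alpha_fdr & abs(results$log2fc) >= lfc_threshold
    ua <- sig & results$log2fc > 0
    ub <- sig & results$log2fc < 0
    mk <- function(keep, lab) {
      interval_set(results$chrom[keep], results$start[keep],
                   results$end[keep], name = results$peak[keep], label = lab)
    }
    list(unique_a = mk(ua, paste0("unique_", conds[1])),
         unique_b = mk(ub, paste0("unique_", conds[2])),
         shared = mk(!ua & !ub, "shared"),
         conditions = conds)
  }
}
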