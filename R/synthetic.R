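#' Simulation configuration
#'
#' Parameters of the synthetic two-condition ATAC-seq experiment the
#' generator emulates: two isogenic conditions ("A" and "B") assayed in
#' replicate, with shared open-chromatin peaks, condition-unique peaks,
#' negative-binomial fragment counts (`variance = mu + dispersion * mu^2`),
#' motif instances implanted into condition-A-unique peaks, and an
#' expression table whose upregulated genes host a configurable fraction of
#' the condition-unique peaks.
#'
#' All randomness flows from `seed` through fixed per-stage child seeds, so
#' every stage is independently reproducible and the same seed yields
#' byte-identical outputs.
#'
#' @param n_chromosomes,chrom_length genome shape (bp).
#' @param n_genes number of non-overlapping gene models.
#' @param gene_length_range,n_exons_range gene geometry (bp, count).
#' @param n_shared_peaks peaks open in every sample.
#' @param n_unique_peaks_per_condition condition-specific peaks per side.
#' @param peak_width_range peak width range (bp).
#' @param replicates_per_condition biological replicates per condition.
#' @param nb_mean,nb_dispersion NB count model for open peaks.
#' @param closed_count_mean expected count where a peak is closed.
#' @param implant_rate fraction of condition-A-unique peaks receiving a
#'   motif consensus instance.
#' @param coupled_fraction fraction of condition-unique peaks placed inside
#'   bodies of genes that will be called upregulated in that condition.
#' @param lfc_mean,lfc_sd log2 fold-change distribution of upregulated
#'   genes (truncated positive).
#' @param h3k27ac_fraction fraction of condition-A-unique peaks covered by
#'   an H3K27ac interval (padded +/- `h3k27ac_pad` bp).
#' @param n_super_enhancers number of super-enhancer clusters (>= 3 nearby
#'   H3K27ac intervals each) built around coupled condition-A peaks.
#' @param se_gap merge gap (bp) when stitching H3K27ac intervals into
#'   super-enhancers.
#' @param h3k27ac_pad padding around peaks for H3K27ac intervals (bp).
#' @param seed master integer seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 2, chrom_length = 3e6,
                       n_genes = 150, gene_length_range = c(3000, 8000),
                       n_exons_range = c(2, 4),
                       n_shared_peaks = 200,
                       n_unique_peaks_per_condition = 50,
                       peak_width_range = c(300, 700),
                       replicates_per_condition = 2,
                       nb_mean = 100, nb_dispersion = 0.1,
                       closed_count_mean = 5,
                       implant_rate = 0.5, coupled_fraction = 0.6,
                       lfc_mean = 2, lfc_sd = 0.5,
                       h3k27ac_fraction = 1, n_super_enhancers = 5,
                       se_gap = 1000, h3k27ac_pad = 500, seed = 1) {
  cfg <- list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              n_genes = n_genes, gene_length_range = gene_length_range,
              n_exons_range = n_exons_range,
              n_shared_peaks = n_shared_peaks,
              n_unique_peaks_per_condition = n_unique_peaks_per_condition,
              peak_width_range = peak_width_range,
              replicates_per_condition = replicates_per_condition,
              nb_mean = nb_mean, nb_dispersion = nb_dispersion,
              closed_count_mean = closed_count_mean,
              implant_rate = implant_rate,
              coupled_fraction = coupled_fraction,
              lfc_mean = lfc_mean, lfc_sd = lfc_sd,
              h3k27ac_fraction = h3k27ac_fraction,
              n_super_enhancers = n_super_enhancers, se_gap = se_gap,
              h3k27ac_pad = h3k27ac_pad, seed = seed)
  with(cfg, {
    stopifnot(n_chromosomes >= 1, chrom_length > 0, n_genes >= 0,
              n_shared_peaks >= 0, n_unique_peaks_per_condition >= 0,
              replicates_per_condition >= 1,
              nb_mean >= 0, nb_dispersion >= 0, closed_count_mean >= 0,
              implant_rate >= 0, implant_rate <= 1,
              coupled_fraction >= 0, coupled_fraction <= 1,
              h3k27ac_fraction >= 0, h3k27ac_fraction <= 1,
              length(peak_width_range) == 2, peak_width_range[1] > 0,
              diff(peak_width_range) >= 0,
              length(gene_length_range) == 2, gene_length_range[1] > 0,
              n_exons_range[1] >= 2,
              lfc_sd > 0, se_gap >= 0, h3k27ac_pad >= 0)
  })
  # capacity check: all features must be placeable without overlap
  need <- cfg$n_genes * (max(cfg$gene_length_range) + 2 * GENE_MARGIN) +
    (cfg$n_shared_peaks + 2 * cfg$n_unique_peaks_per_condition) *
      (max(cfg$peak_width_range) + 2 * PEAK_MARGIN)
  avail <- cfg$n_chromosomes * cfg$chrom_length
  if (need > avail)
    stop("placement capacity exceeded: features need ~", need,
         " bp but genome has ", avail, " bp")
  n_coupled <- ceiling(cfg$coupled_fraction * cfg$n_unique_peaks_per_condition)
  if (2 * n_coupled > cfg$n_genes)
    stop("placement capacity exceeded: ", 2 * n_coupled,
         " coupled genes needed but only ", cfg$n_genes, " genes")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_chromosomes, " x ", x$chrom_length, " bp, ",
      x$n_genes, " genes, ", x$n_shared_peaks, " shared + 2 x ",
      x$n_unique_peaks_per_condition, " unique peaks, ",
      x$replicates_per_condition, " reps/condition, seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

## spacing constants (bp): genes are kept far enough apart that promoter
## windows and GREAT basal domains of neighbours cannot reach into a gene
## body; peaks far enough apart that +/-500 bp H3K27ac padding never
## stitches unrelated peaks into one super-enhancer.
GENE_MARGIN <- 7000
PEAK_MARGIN <- 1500

## deterministic per-stage child seed from the master seed
child_seed <- function(seed, stage) {
  off <- c(genome = 101, genes = 211, peaks = 307, counts = 401,
           implant = 503, expression = 607, h3k27ac = 701)
  if (!stage %in% names(off)) stop("unknown stage: ", stage)
  (as.numeric(seed) * 31 + off[[stage]]) %% (2^31 - 1)
}

## sequentially place `widths` non-overlapping intervals with `margin` bp
## clearance into the free segments `segs` (data.frame chrom/start/end).
## Returns list(placed = data.frame(chrom,start,end), segs = remaining).
place_intervals <- function(segs, widths, margin) {
  placed <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), stringsAsFactors = FALSE)
  for (w in widths) {
    cap <- (segs$end - segs$start) - w - 2 * margin + 1
    ok <- which(cap >= 1)
    if (!length(ok))
      stop("placement error: no free segment can hold a feature of width ",
           w, " with margin ", margin)
    i <- if (length(ok) == 1) ok else sample(ok, 1, prob = cap[ok])
    s <- segs$start[i] + margin + floor(stats::runif(1) * cap[i])
    placed <- rbind(placed, data.frame(chrom = segs$chrom[i], start = s,
                                       end = s + w, stringsAsFactors = FALSE))
    segs <- rbind(segs[-i, , drop = FALSE],
                  data.frame(chrom = segs$chrom[i],
                             start = c(segs$start[i], s + w + margin),
                             end = c(s - margin, segs$end[i]),
                             stringsAsFactors = FALSE))
    segs <- segs[segs$end - segs$start > 0, , drop = FALSE]
  }
  list(placed = placed, segs = segs)
}

#' Generate a genome and gene models
#'
#' I.i.d. uniform A/C/G/T sequence per chromosome (uniform composition
#' keeps the scramble-based motif background unbiased) and non-overlapping
#' gene models with random strand and >= 2 exons; the first exon starts at
#' the body start and the last ends at the body end, so BED12 round-trips.
#' Deterministic given `config$seed`.
#'
#' @param config a `sim_config`.
#' @return list: `genome` ([Biostrings::DNAStringSet]), `genes`
#'   (`gene_models`), `free_segments` (intergenic space left for peak
#'   placement, used by [generate_peaks_and_counts()]).
#' @export
generate_genome <- function(config) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  genome <- with_seed(child_seed(config$seed, "genome"), {
    seqs <- vapply(chroms, function(ch)
      paste(sample(BASES, config$chrom_length, replace = TRUE),
            collapse = ""), character(1))
    Biostrings::DNAStringSet(seqs)
  })
  names(genome) <- chroms
  segs <- data.frame(chrom = chroms, start = 0, end = config$chrom_length,
                     stringsAsFactors = FALSE)
  if (config$n_genes == 0) {
    genes <- gene_models(data.frame(gene_id = character(),
                                    chrom = character(), start = numeric(),
                                    end = numeric(), strand = character(),
                                    stringsAsFactors = FALSE))
    return(list(genome = genome, genes = genes, free_segments = segs))
  }
  res <- with_seed(child_seed(config$seed, "genes"), {
    widths <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                     config$n_genes, replace = TRUE)
    pl <- place_intervals(segs, widths, GENE_MARGIN)
    g <- pl$placed
    g$gene_id <- sprintf("gene_%03d", seq_len(nrow(g)))
    g$strand <- sample(c("+", "-"), nrow(g), replace = TRUE)
    exons <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      L <- g$end[i] - g$start[i]
      k <- sample(config$n_exons_range[1]:config$n_exons_range[2], 1)
      block <- L / k
      ws <- pmax(50, floor(block * stats::runif(k, 0.2, 0.5)))
      ss <- g$start[i] + floor((seq_len(k) - 1) * block)
      ss[1] <- g$start[i]
      ee <- ss + ws
      ee[k] <- g$end[i]
      ss[k] <- max(ss[k], ee[k - 1] + 1, g$start[i] + floor((k - 1) * block))
      data.frame(gene_id = g$gene_id[i], start = ss, end = ee,
                 stringsAsFactors = FALSE)
    }))
    list(genes = g, exons = exons, segs = pl$segs)
  })
  genes <- gene_models(res$genes[c("gene_id", "chrom", "start", "end",
                                   "strand")], res$exons)
  list(genome = genome, genes = genes, free_segments = res$segs)
}

#' Generate peak sets, counts and ground truth
#'
#' Places shared and condition-unique peaks (never overlapping each other):
#' `coupled_fraction` of each condition's unique peaks go inside the bodies
#' of genes flagged for upregulation in that condition (one peak per gene),
#' the rest into intergenic space.  Every replicate of a condition carries
#' the shared peaks plus that condition's unique peaks; counts are NB with
#' `nb_mean` where the sample's condition is open at the peak and
#' `closed_count_mean` otherwise.
#'
#' @param gen output of [generate_genome()].
#' @param config a `sim_config`.
#' @return list: `peaksets` (named list of per-sample `interval_set`s),
#'   `samples` (data frame), `counts` (`count_matrix` over all true peaks),
#'   `truth` (data frame: peak_id, chrom, start, end, unique_to,
#'   linked_gene, implanted_motif, implant_offset, implant_strand).
#' @export
generate_peaks_and_counts <- function(gen, config) {
  if (config$replicates_per_condition < 2)
    warning("fewer than 2 replicates per condition; ",
            "occupancy-based unique-peak logic assumes duplicates")
  nun <- config$n_unique_peaks_per_condition
  n_coupled <- ceiling(config$coupled_fraction * nun)
  res <- with_seed(child_seed(config$seed, "peaks"), {
    g <- gen$genes$genes
    widths <- function(n) if (n == 0) integer() else
      sample(config$peak_width_range[1]:config$peak_width_range[2], n,
             replace = TRUE)
    coupled_genes <- if (2 * n_coupled > 0)
      sample(g$gene_id, 2 * n_coupled) else character()
    cg_a <- utils::head(coupled_genes, n_coupled)
    cg_b <- utils::tail(coupled_genes, n_coupled)
    place_in_gene <- function(gid, w) {
      row <- g[g$gene_id == gid, ]
      L <- row$end - row$start
      s <- row$start + floor(stats::runif(1) * (L - w + 1))
      data.frame(chrom = row$chrom, start = s, end = s + w,
                 linked_gene = gid, stringsAsFactors = FALSE)
    }
    coupled <- function(gids) {
      if (!length(gids)) return(NULL)
      do.call(rbind, lapply(gids, function(gid)
        place_in_gene(gid, widths(1))))
    }
    pa <- coupled(cg_a); pb <- coupled(cg_b)
    n_free <- config$n_shared_peaks + 2 * (nun - n_coupled)
    pl <- place_intervals(gen$free_segments, widths(n_free), PEAK_MARGIN)
    free <- pl$placed
    free$linked_gene <- NA_character_
    iA <- seq_len(nun - n_coupled)
    iB <- (nun - n_coupled) + seq_len(nun - n_coupled)
    iS <- setdiff(seq_len(nrow(free)), c(iA, iB))
    truth <- rbind(
      if (!is.null(pa)) cbind(pa, unique_to = "A") else NULL,
      if (length(iA)) cbind(free[iA, , drop = FALSE], unique_to = "A") else NULL,
      if (!is.null(pb)) cbind(pb, unique_to = "B") else NULL,
      if (length(iB)) cbind(free[iB, , drop = FALSE], unique_to = "B") else NULL,
      if (length(iS))
        cbind(free[iS, , drop = FALSE], unique_to = "none") else NULL)
    truth <- truth[order(truth$chrom, truth$start), ]
    truth$peak_id <- sprintf("peak_%04d", seq_len(nrow(truth)))
    rownames(truth) <- NULL
    truth
  })
  truth <- res
  truth$implanted_motif <- NA_character_
  truth$implant_offset <- NA_real_
  truth$implant_strand <- NA_character_
  truth <- truth[c("peak_id", "chrom", "start", "end", "unique_to",
                   "linked_gene", "implanted_motif", "implant_offset",
                   "implant_strand")]
  reps <- config$replicates_per_condition
  samples <- data.frame(
    sample_id = c(paste0("A_rep", seq_len(reps)), paste0("B_rep", seq_len(reps))),
    condition = rep(c("A", "B"), each = reps),
    replicate = rep(seq_len(reps), 2), stringsAsFactors = FALSE)
  peaksets <- lapply(seq_len(nrow(samples)), function(i) {
    open <- truth$unique_to %in% c("none", samples$condition[i])
    interval_set(truth$chrom[open], truth$start[open], truth$end[open],
                 name = truth$peak_id[open], label = samples$sample_id[i])
  })
  names(peaksets) <- samples$sample_id
  counts <- with_seed(child_seed(config$seed, "counts"), {
    open <- outer(truth$unique_to, samples$condition,
                  function(u, s) u == "none" | u == s)
    mu <- ifelse(open, config$nb_mean, config$closed_count_mean)
    m <- matrix(0L, nrow(truth), nrow(samples))
    pos <- mu > 0
    if (config$nb_dispersion > 0) {
      m[pos] <- stats::rnbinom(sum(pos), mu = mu[pos],
                               size = 1 / config$nb_dispersion)
    } else m[pos] <- stats::rpois(sum(pos), mu[pos])
    m
  })
  peaks <- interval_set(truth$chrom, truth$start, truth$end,
                        name = truth$peak_id, label = "true_peaks")
  cm <- count_matrix(peaks, samples,
                     counts[match(peaks$name, truth$peak_id), , drop = FALSE])
  list(peaksets = peaksets, samples = samples, counts = cm, truth = truth)
}

#' Implant motif consensus instances
#'
#' Writes the consensus (argmax base per column) of a PWM into
#' `implant_rate` of the condition-A-unique peaks, at a uniformly chosen
#' offset and random strand (reverse strand implants the reverse
#' complement).  Truth records motif id, peak-relative offset and strand.
#' A PWM wider than the peak is skipped with a warning.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param truth truth table from [generate_peaks_and_counts()].
#' @param pwm_set a `pwm` or list of `pwm`s (cycled over implant peaks).
#' @param config a `sim_config`.
#' @return list: modified `genome`, updated `truth`.
#' @export
implant_motifs <- function(genome, truth, pwm_set, config) {
  if (inherits(pwm_set, "pwm")) pwm_set <- list(pwm_set)
  ua <- which(truth$unique_to == "A")
  n_impl <- round(config$implant_rate * length(ua))
  if (n_impl == 0) return(list(genome = genome, truth = truth))
  chrs <- lapply(genome, as.character)
  with_seed(child_seed(config$seed, "implant"), {
    sel <- if (length(ua) == 1) ua else sort(sample(ua, n_impl))
    for (j in seq_along(sel)) {
      i <- sel[j]
      p <- pwm_set[[(j - 1) %% length(pwm_set) + 1]]
      w <- p$width
      peak_w <- truth$end[i] - truth$start[i]
      if (w > peak_w) {
        warning("PWM ", p$motif_id, " wider than peak ", truth$peak_id[i],
                "; skipped")
        next
      }
      off <- floor(stats::runif(1) * (peak_w - w + 1))
      strand <- sample(c("+", "-"), 1)
      cons <- consensus(p)
      ins <- if (strand == "+") cons else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
      a <- truth$start[i] + off + 1
      substr(chrs[[truth$chrom[i]]], a, a + w - 1) <- ins
      truth$implanted_motif[i] <- p$motif_id
      truth$implant_offset[i] <- off
      truth$implant_strand[i] <- strand
    }
  })
  new_genome <- Biostrings::DNAStringSet(unlist(chrs))
  names(new_genome) <- names(genome)
  list(genome = new_genome, truth = truth)
}

## mean of a Normal(mean, sd) truncated to (0, Inf)
truncnorm_mean <- function(mean, sd) {
  a <- (0 - mean) / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

rtruncnorm_pos <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

#' Generate the expression table
#'
#' Genes coupled to condition-A-unique peaks get a positive log2 fold
#' change (truncated `Normal(lfc_mean, lfc_sd)`) and `padj < 0.05`; genes
#' coupled to condition-B peaks the mirror image (negative log2FC,
#' `padj < 0.05`); all other genes `Normal(0, lfc_sd)` log2FC with
#' `padj >= 0.05`.  One row per gene; log2FC is condition A vs B.
#'
#' @param genes a `gene_models` object.
#' @param truth truth table with `linked_gene`/`unique_to`.
#' @param config a `sim_config`.
#' @return data frame `gene_id, log2fc, padj`.
#' @export
generate_expression <- function(genes, truth, config) {
  g <- genes$genes
  up_a <- unique(stats::na.omit(truth$linked_gene[truth$unique_to == "A"]))
  up_b <- unique(stats::na.omit(truth$linked_gene[truth$unique_to == "B"]))
  with_seed(child_seed(config$seed, "expression"), {
    lfc <- stats::rnorm(nrow(g), 0, config$lfc_sd)
    padj <- stats::runif(nrow(g), 0.05, 1)
    ia <- g$gene_id %in% up_a
    ib <- g$gene_id %in% up_b
    lfc[ia] <- rtruncnorm_pos(sum(ia), config$lfc_mean, config$lfc_sd)
    lfc[ib] <- -rtruncnorm_pos(sum(ib), config$lfc_mean, config$lfc_sd)
    padj[ia | ib] <- stats::runif(sum(ia | ib), 1e-8, 0.05 - 1e-8)
    data.frame(gene_id = g$gene_id, log2fc = lfc, padj = padj,
               stringsAsFactors = FALSE)
  })
}

#' Generate H3K27ac intervals and super-enhancers
#'
#' H3K27ac intervals cover `h3k27ac_fraction` of the condition-A-unique
#' peaks (each padded +/- `h3k27ac_pad` bp); around the first
#' `n_super_enhancers` coupled condition-A peaks, two flanking intervals
#' are added so the stitched (gap <= `se_gap`) run has >= 3 constituents
#' and qualifies as a super-enhancer.  Super-enhancers are recorded with
#' the coupled gene they were built around.
#'
#' @param truth truth table from [generate_peaks_and_counts()].
#' @param config a `sim_config`.
#' @return list: `h3k27ac` (`interval_set`), `super_enhancers`
#'   (`interval_set`), `se_genes` (data frame `se`, `gene_id`).
#' @export
generate_h3k27ac_and_se <- function(truth, config) {
  ua <- truth[truth$unique_to == "A", , drop = FALSE]
  pad <- config$h3k27ac_pad
  base <- with_seed(child_seed(config$seed, "h3k27ac"), {
    n_cov <- round(config$h3k27ac_fraction * nrow(ua))
    if (n_cov == 0) ua[0, , drop = FALSE]
    else ua[sort(sample(seq_len(nrow(ua)), n_cov)), , drop = FALSE]
  })
  ivs <- data.frame(chrom = base$chrom, start = pmax(base$start - pad, 0),
                    end = base$end + pad, stringsAsFactors = FALSE)
  coup <- ua[!is.na(ua$linked_gene), , drop = FALSE]
  coup <- utils::head(coup[order(coup$chrom, coup$start), , drop = FALSE],
                      config$n_super_enhancers)
  flank_w <- 800; flank_gap <- min(200, config$se_gap)
  se_meta <- NULL
  if (nrow(coup)) {
    ctr <- data.frame(chrom = coup$chrom, start = pmax(coup$start - pad, 0),
                      end = coup$end + pad, stringsAsFactors = FALSE)
    left <- data.frame(chrom = coup$chrom,
                       start = pmax(ctr$start - flank_gap - flank_w, 0),
                       end = pmax(ctr$start - flank_gap, 0),
                       stringsAsFactors = FALSE)
    right <- data.frame(chrom = coup$chrom, start = ctr$end + flank_gap,
                        end = ctr$end + flank_gap + flank_w,
                        stringsAsFactors = FALSE)
    ivs <- rbind(ivs, ctr, left, right)
    se_meta <- data.frame(chrom = coup$chrom, start = left$start,
                          end = right$end, gene_id = coup$linked_gene,
                          stringsAsFactors = FALSE)
  }
  ivs <- ivs[ivs$end > ivs$start, , drop = FALSE]
  ivs <- unique(ivs)
  h3k27ac <- interval_set(ivs$chrom, ivs$start, ivs$end,
                          name = sprintf("k27ac_%04d", seq_len(nrow(ivs))),
                          label = "H3K27ac")
  merged <- merge_set(h3k27ac, max_gap = config$se_gap)
  if (nrow(merged)) {
    support <- intersect_sets(merged, h3k27ac, min_overlap = 1)
    nconst <- table(factor(support$a_name, levels = merged$name))
    keep <- merged$name %in% names(nconst)[nconst >= 3]
    ses <- merged[keep, , drop = FALSE]
    class(ses) <- class(merged)
  } else ses <- merged
  ses <- interval_set(ses$chrom, ses$start, ses$end,
                      name = if (nrow(ses)) sprintf("SE_%02d", seq_len(nrow(ses)))
                             else character(),
                      label = "super_enhancers")
  se_genes <- data.frame(se = character(), gene_id = character(),
                         stringsAsFactors = FALSE)
  if (!is.null(se_meta) && nrow(ses)) {
    ov <- intersect_sets(ses, interval_set(se_meta$chrom, se_meta$start,
                                           se_meta$end,
                                           name = se_meta$gene_id))
    se_genes <- data.frame(se = ov$a_name, gene_id = ov$b_name,
                           stringsAsFactors = FALSE)
  }
  list(h3k27ac = h3k27ac, super_enhancers = ses, se_genes = se_genes)
}

#' Simulate a complete synthetic dataset
#'
#' Runs the full generator: genome + gene models, peaks + counts, motif
#' implantation, expression table, H3K27ac/super-enhancer tracks.  All
#' stages are driven by `config$seed`.
#'
#' @param config a `sim_config`.
#' @param pwm_set PWM(s) to implant into condition-A-unique peaks (default
#'   the width-8 AP-1-like fixture motif, detectable at the default scan
#'   threshold).
#' @return object of class `synthetic_dataset`: list with `config`,
#'   `genome`, `genes`, `peaksets`, `samples`, `counts`, `expression`,
#'   `h3k27ac`, `super_enhancers`, `truth` (peak-level truth),
#'   `se_genes`, `pwms`.
#' @export
simulate_dataset <- function(config = sim_config(),
                             pwm_set = fixture_pwms()$AP1) {
  gen <- generate_genome(config)
  pk <- generate_peaks_and_counts(gen, config)
  imp <- implant_motifs(gen$genome, pk$truth, pwm_set, config)
  expr <- generate_expression(gen$genes, imp$truth, config)
  se <- generate_h3k27ac_and_se(imp$truth, config)
  structure(list(config = config, genome = imp$genome, genes = gen$genes,
                 peaksets = pk$peaksets, samples = pk$samples,
                 counts = pk$counts, expression = expr,
                 h3k27ac = se$h3k27ac, super_enhancers = se$super_enhancers,
                 truth = imp$truth, se_genes = se$se_genes,
                 pwms = if (inherits(pwm_set, "pwm")) list(pwm_set) else pwm_set),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset: ", sum(Biostrings::width(x$genome)), " bp genome, ",
      nrow(x$genes$genes), " genes, ", nrow(x$truth), " true peaks (",
      sum(x$truth$unique_to == "A"), " A-unique, ",
      sum(x$truth$unique_to == "B"), " B-unique), ",
      nrow(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' FASTA genome, BED6 per-sample peaks, BED12 gene models, count-matrix
#' TSV (`peak_id, chrom, start, end`, one column per sample), expression
#' TSV, H3K27ac and super-enhancer BED6, and the truth TSV.  All intervals
#' 0-based half-open.  Byte-identical across runs with the same seed.
#'
#' @param ds a `synthetic_dataset`.
#' @param outdir output directory (created).
#' @return named vector of written paths, invisibly.
#' @export
write_synthetic_dataset <- function(ds, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(outdir, "genome.fa"))
  Biostrings::writeXStringSet(ds$genome, paths["genome"])
  write_bed12(ds$genes, file.path(outdir, "genes.bed12"))
  paths["genes"] <- file.path(outdir, "genes.bed12")
  for (nm in names(ds$peaksets)) {
    p <- file.path(outdir, paste0("peaks_", nm, ".bed"))
    write_bed(ds$peaksets[[nm]], p)
    paths[paste0("peaks_", nm)] <- p
  }
  cm <- ds$counts
  cnt_df <- data.frame(peak_id = cm$peaks$name, chrom = cm$peaks$chrom,
                       start = format_coord(cm$peaks$start),
                       end = format_coord(cm$peaks$end),
                       stringsAsFactors = FALSE)
  cnt_df <- cbind(cnt_df, as.data.frame(cm$counts))
  paths["counts"] <- file.path(outdir, "counts.tsv")
  utils::write.table(cnt_df, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["expression"] <- file.path(outdir, "expression.tsv")
  utils::write.table(ds$expression, paths["expression"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["h3k27ac"] <- file.path(outdir, "h3k27ac.bed")
  write_bed(ds$h3k27ac, paths["h3k27ac"])
  paths["super_enhancers"] <- file.path(outdir, "super_enhancers.bed")
  write_bed(ds$super_enhancers, paths["super_enhancers"])
  paths["truth"] <- file.path(outdir, "truth.tsv")
  utils::write.table(ds$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
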