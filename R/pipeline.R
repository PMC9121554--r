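#' Run the full accessibility-integration pipeline
#'
#' End-to-end analysis of a (synthetic or assembled) two-condition dataset:
#' occupancy-based condition-unique peaks, NB differential test, genomic
#' category proportions, concordant upregulated genes, enhancer and
#' super-enhancer overlap, scrambled-background motif enrichment per
#' condition, and the condition-A TF-to-gene regulatory network.  When the
#' input carries a truth table (a `synthetic_dataset`), truth-recovery
#' metrics are attached.
#'
#' @param ds a `synthetic_dataset` (see [simulate_dataset()]).
#' @param scan_p PWM scan p-value threshold (default 1e-4).
#' @param n_shuffles scrambles per sequence for the motif background.
#' @param fold_threshold motif enrichment call threshold (default 2).
#' @param alpha adjusted-p threshold for upregulated genes and FDR for the
#'   differential test.
#' @return list of class `pipeline_result` with elements `unique_peaks`,
#'   `differential`, `annotation`, `links_a`, `concordant`, `enhancers`,
#'   `se_hits`, `motif_enrichment` (per condition), `network`, `tf_overlap`,
#'   and `metrics` (named numeric vector; `NULL` without truth).
#' @export
run_pipeline <- function(ds, scan_p = 1e-4, n_shuffles = 10,
                         fold_threshold = 2, alpha = 0.05) {
  uniq <- call_unique_peaks(ds$peaksets, ds$samples$condition,
                            mode = "occupancy")
  cm <- normalize_counts(ds$counts)
  diff <- test_differential(cm, alpha_fdr = alpha)
  all_peaks <- ds$counts$peaks
  annot <- category_proportions(all_peaks, ds$genes)
  links_a <- link_peaks_to_gene_bodies(uniq$unique_a, ds$genes)
  concordant <- select_concordant_genes(links_a, ds$expression,
                                        direction = "up", alpha = alpha)
  enhancers <- define_enhancers(ds$h3k27ac, promoter_windows(ds$genes))
  se_hits <- overlap_super_enhancers(uniq$unique_a, ds$super_enhancers,
                                     ds$genes, ds$expression, alpha = alpha)
  seq_a <- peak_sequences(uniq$unique_a, ds$genome)
  seq_b <- peak_sequences(uniq$unique_b, ds$genome)
  enr <- function(seqs, cond_off) {
    do.call(rbind, lapply(seq_along(ds$pwms), function(i)
      fold_enrichment(ds$pwms[[i]], seqs, n_shuffles = n_shuffles,
                      p_threshold = scan_p, fold_threshold = fold_threshold,
                      seed = child_seed(ds$config$seed, "h3k27ac") +
                        cond_off + 131 * i)))
  }
  enrich_a <- enr(seq_a, 11); enrich_b <- enr(seq_b, 23)
  enriched_tfs <- enrich_a$motif_id[enrich_a$enriched]
  hits_a <- do.call(rbind, lapply(ds$pwms, function(p)
    scan_pwm(p, seq_a, p_threshold = scan_p)))
  tf_sets <- motif_target_genes(hits_a, links_a, concordant$genes)
  network <- suppressWarnings(
    build_network(tf_sets, enriched_tfs, condition_label = "A"))
  metrics <- NULL
  if (!is.null(ds$truth)) {
    tr <- ds$truth
    truth_a <- tr[tr$unique_to == "A", , drop = FALSE]
    truth_b <- tr[tr$unique_to == "B", , drop = FALSE]
    overlap_frac <- function(truth_df, called) {
      if (nrow(truth_df) == 0) return(NA_real_)
      ts <- interval_set(truth_df$chrom, truth_df$start, truth_df$end,
                         name = truth_df$peak_id)
      hit <- intersect_sets(ts, called, min_overlap = 1)
      length(unique(hit$a_name)) / nrow(truth_df)
    }
    truth_genes_a <- unique(stats::na.omit(truth_a$linked_gene))
    called_genes <- concordant$genes
    imp <- truth_a[!is.na(truth_a$implanted_motif) &
                     !is.na(truth_a$linked_gene), , drop = FALSE]
    imp <- imp[imp$linked_gene %in% truth_genes_a, , drop = FALSE]
    truth_edges <- unique(paste(imp$implanted_motif, imp$linked_gene))
    called_edges <- unique(paste(network$edges$tf, network$edges$gene))
    imp_id <- unique(stats::na.omit(tr$implanted_motif))
    fold_of <- function(tab, id) {
      if (!length(id)) return(NA_real_)
      f <- tab$fold[tab$motif_id %in% id]
      if (length(f)) max(f) else NA_real_
    }
    metrics <- c(
      unique_peak_recall_a = overlap_frac(truth_a, uniq$unique_a),
      unique_peak_recall_b = overlap_frac(truth_b, uniq$unique_b),
      concordant_gene_precision =
        if (length(called_genes))
          mean(called_genes %in% truth_genes_a) else NA_real_,
      concordant_gene_recall =
        if (length(truth_genes_a))
          mean(truth_genes_a %in% called_genes) else NA_real_,
      implanted_motif_fold_a = fold_of(enrich_a, imp_id),
      implanted_motif_fold_b = fold_of(enrich_b, imp_id),
      edge_precision = if (length(called_edges))
        mean(called_edges %in% truth_edges) else NA_real_,
      edge_recall = if (length(truth_edges))
        mean(truth_edges %in% called_edges) else NA_real_,
      se_gene_recovery = se_recovery(se_hits, ds$se_genes))
  }
  structure(list(unique_peaks = uniq, differential = diff,
                 annotation = annot, links_a = links_a,
                 concordant = concordant, enhancers = enhancers,
                 se_hits = se_hits, motif_enrichment =
                   list(A = enrich_a, B = enrich_b),
                 network = network, tf_overlap = tf_overlap(network),
                 metrics = metrics),
            class = "pipeline_result")
}

## fraction of truth (SE, gene) couplings recovered as upregulated SE hits
se_recovery <- function(se_hits, se_genes) {
  if (is.null(se_genes) || nrow(se_genes) == 0) return(NA_real_)
  got <- vapply(seq_len(nrow(se_genes)), function(i) {
    any(se_hits$se == se_genes$se[i] &
          se_hits$gene_id == se_genes$gene_id[i] &
          se_hits$upregulated, na.rm = TRUE)
  }, logical(1))
  mean(got)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:\n")
  cat("  unique peaks: A =", nrow(x$unique_peaks$unique_a),
      ", B =", nrow(x$unique_peaks$unique_b),
      ", shared =", nrow(x$unique_peaks$shared), "\n")
  cat("  concordant upregulated genes:", length(x$concordant$genes), "\n")
  cat("  SE hits:", length(unique(x$se_hits$se)), "\n")
  cat("  enriched motifs (A):",
      paste(x$motif_enrichment$A$motif_id[x$motif_enrichment$A$enriched],
            collapse = ", "), "\n")
  cat("  network:", length(x$network$tf_nodes), "TFs ->",
      length(x$network$gene_nodes), "genes,", nrow(x$network$edges),
      "edges\n")
  if (!is.null(x$metrics)) {
    cat("  truth-recovery metrics:\n")
    for (nm in names(x$metrics))
      cat(sprintf("    %-28s %.3f\n", nm, x$metrics[[nm]]))
  }
  invisible(x)
}
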