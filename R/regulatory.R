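#' GREAT-style association rule
#'
#' Basal-plus-extension regulatory domains: every gene gets a strand-aware
#' basal domain around its TSS (`basal_upstream`/`basal_downstream`,
#' defaults 5 kb / 1 kb) extended in both directions by up to `extension`
#' bp (default 1 Mb) but never into a neighbouring gene's basal domain.
#' These are the named tool's documented defaults; all three are
#' configurable.
#'
#' @param basal_upstream,basal_downstream,extension sizes in bp.
#' @return list of class `association_rule`.
#' @export
association_rule <- function(basal_upstream = 5000, basal_downstream = 1000,
                             extension = 1e6) {
  stopifnot(basal_upstream >= 0, basal_downstream >= 0, extension >= 0)
  structure(list(basal_upstream = basal_upstream,
                 basal_downstream = basal_downstream,
                 extension = extension),
            class = "association_rule")
}

#' Define enhancers from H3K27ac peaks
#'
#' Enhancers are H3K27ac-enriched regions minus promoter windows
#' (zero-length remnants dropped).
#'
#' @param h3k27ac an `interval_set` of H3K27ac peaks.
#' @param promoters an `interval_set` of promoter windows (see
#'   [promoter_windows()]).
#' @return an `interval_set` of enhancer regions.
#' @export
define_enhancers <- function(h3k27ac, promoters) {
  out <- subtract_sets(h3k27ac, promoters)
  attr(out, "label") <- "enhancers"
  out
}

#' Per-gene regulatory domains
#'
#' The basal domain is `[tss - basal_upstream, tss + basal_downstream)` on
#' `+` (mirrored on `-`), clipped at 0.  Each side is then extended by up
#' to `extension` bp but stops at the nearest other gene's basal domain;
#' a neighbouring basal domain overlapping the gene's own blocks extension
#' on that side entirely (the basal domain itself is always kept).
#'
#' @param genes a `gene_models` object.
#' @param rule an `association_rule`.
#' @return an `interval_set` of extended domains named by gene id.
#' @export
regulatory_domains <- function(genes, rule = association_rule()) {
  g <- genes$genes
  bup <- rule$basal_upstream; bdn <- rule$basal_downstream
  bs <- pmax(ifelse(g$strand == "+", g$tss - bup, g$tss - bdn), 0)
  be <- ifelse(g$strand == "+", g$tss + bdn, g$tss + bup)
  ext_s <- pmax(bs - rule$extension, 0)
  ext_e <- be + rule$extension
  for (chr in unique(g$chrom)) {
    idx <- which(g$chrom == chr)
    for (j in idx) {
      others <- setdiff(idx, j)
      left <- others[bs[others] < bs[j]]
      if (length(left))
        ext_s[j] <- max(ext_s[j], min(max(be[left]), bs[j]))
      right <- others[be[others] > be[j]]
      if (length(right))
        ext_e[j] <- min(ext_e[j], max(min(bs[right]), be[j]))
    }
  }
  interval_set(g$chrom, ext_s, ext_e, name = g$gene_id, strand = g$strand,
               label = "regulatory_domains")
}

#' Associate regions with genes (basal plus extension)
#'
#' A region is associated with every gene whose regulatory domain it
#' overlaps by >= 1 bp.
#'
#' @param regions an `interval_set` (e.g. enhancers or super-enhancers).
#' @param genes a `gene_models` object.
#' @param rule an `association_rule`.
#' @return data frame: `region` (name in `regions`), `gene_id`, `overlap`.
#' @export
associate_regions_to_genes <- function(regions, genes,
                                       rule = association_rule()) {
  dom <- regulatory_domains(genes, rule)
  hits <- intersect_sets(regions, dom, min_overlap = 1)
  data.frame(region = hits$a_name, gene_id = hits$b_name,
             overlap = hits$overlap, stringsAsFactors = FALSE)
}

#' Overlap condition-unique peaks with super-enhancers
#'
#' Reports every super-enhancer containing at least one condition-unique
#' ATAC peak, together with the genes its regulatory domain associates to
#' and each gene's upregulation status (`padj < alpha` and `log2fc > 0`).
#' An optional `se_gene_override` table (columns `se`, `gene_id`, e.g. a
#' catalog's own assignments) replaces the association rule for the listed
#' super-enhancers.
#'
#' @param atac_unique `interval_set` of condition-unique peaks.
#' @param ses `interval_set` of super-enhancers.
#' @param genes a `gene_models` object.
#' @param expression expression table (`gene_id`, `log2fc`, `padj`).
#' @param rule an `association_rule`.
#' @param alpha adjusted-p threshold for the upregulated flag.
#' @param se_gene_override optional data frame `se`, `gene_id`.
#' @return data frame, one row per (super-enhancer, gene): `se, chrom,
#'   start, end, n_peaks, peaks, gene_id, log2fc, padj, upregulated`
#'   (gene columns `NA` for hits with no associated gene).
#' @export
overlap_super_enhancers <- function(atac_unique, ses, genes, expression,
                                    rule = association_rule(), alpha = 0.05,
                                    se_gene_override = NULL) {
  pk <- intersect_sets(ses, atac_unique, min_overlap = 1)
  if (nrow(pk) == 0)
    return(data.frame(se = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_peaks = integer(), peaks = character(),
                      gene_id = character(), log2fc = numeric(),
                      padj = numeric(), upregulated = logical(),
                      stringsAsFactors = FALSE))
  hit_ids <- unique(pk$a_name)
  se_hit <- ses[ses$name %in% hit_ids, , drop = FALSE]
  class(se_hit) <- class(ses); attr(se_hit, "label") <- set_label(ses)
  assoc <- associate_regions_to_genes(se_hit, genes, rule)
  if (!is.null(se_gene_override)) {
    keep <- !(assoc$region %in% se_gene_override$se)
    assoc <- rbind(assoc[keep, , drop = FALSE],
                   data.frame(region = se_gene_override$se,
                              gene_id = se_gene_override$gene_id,
                              overlap = NA_real_, stringsAsFactors = FALSE))
    assoc <- assoc[assoc$region %in% hit_ids, , drop = FALSE]
  }
  rows <- lapply(hit_ids, function(id) {
    se_row <- se_hit[se_hit$name == id, , drop = FALSE]
    pks <- sort(unique(pk$b_name[pk$a_name == id]))
    gs <- unique(assoc$gene_id[assoc$region == id])
    base <- data.frame(se = id, chrom = se_row$chrom, start = se_row$start,
                       end = se_row$end, n_peaks = length(pks),
                       peaks = paste(pks, collapse = ","),
                       stringsAsFactors = FALSE)
    if (!length(gs))
      return(cbind(base, gene_id = NA_character_, log2fc = NA_real_,
                   padj = NA_real_, upregulated = NA))
    m <- match(gs, expression$gene_id)
    cbind(base[rep(1, length(gs)), , drop = FALSE],
          data.frame(gene_id = gs, log2fc = expression$log2fc[m],
                     padj = expression$padj[m],
                     upregulated = !is.na(m) & expression$padj[m] < alpha &
                       expression$log2fc[m] > 0,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
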