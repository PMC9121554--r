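#' Link peaks to gene bodies
#'
#' One link per (peak, gene) pair whose intervals share >= 1 bp of the
#' transcript span; a peak spanning two genes yields two links.
#'
#' @param peaks an `interval_set`.
#' @param genes a `gene_models` object.
#' @return data frame: `peak, gene_id, overlap, link_type` (`"body"`).
#' @export
link_peaks_to_gene_bodies <- function(peaks, genes) {
  g <- genes$genes
  bodies <- interval_set(g$chrom, g$start, g$end, name = g$gene_id,
                         label = "gene_bodies")
  hits <- intersect_sets(peaks, bodies, min_overlap = 1)
  data.frame(peak = hits$a_name, gene_id = hits$b_name,
             overlap = hits$overlap, link_type = "body",
             stringsAsFactors = FALSE)
}

#' Read a differential-expression table
#'
#' TSV with a header and columns `gene_id`, `log2fc`, `padj` (extra columns
#' kept).  Emulates the per-gene output of a 3'-end counting assay.
#'
#' @param path file path.
#' @return data frame with validated `padj` in `[0, 1]`.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(df)))
    stop("expression table needs columns: ", paste(need, collapse = ", "))
  if (any(df$padj < 0 | df$padj > 1, na.rm = TRUE))
    stop("padj outside [0, 1]")
  df
}

#' Select genes with concordant accessibility and expression
#'
#' Genes called differentially expressed in the requested direction
#' (`up`: `log2fc > 0`; `down`: `log2fc < 0`) at `padj < alpha` that have
#' at least one link to the supplied condition-specific peak set.  Genes
#' linked to peaks but missing from the expression table are dropped with a
#' message.
#'
#' @param links peak-to-gene links (see [link_peaks_to_gene_bodies()]),
#'   computed against the condition-specific peaks.
#' @param expression data frame with `gene_id`, `log2fc`, `padj`.
#' @param direction `"up"` or `"down"`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return list with `genes` (character vector) and `report` (data frame:
#'   gene_id, log2fc, padj, n_peaks, peaks — comma-separated supporting
#'   peak ids).
#' @export
select_concordant_genes <- function(links, expression,
                                    direction = c("up", "down"),
                                    alpha = 0.05) {
  direction <- match.arg(direction)
  if (is.null(expression) || nrow(expression) == 0)
    stop("empty expression table")
  linked <- unique(links$gene_id)
  missing <- setdiff(linked, expression$gene_id)
  if (length(missing))
    message(length(missing), " linked gene(s) missing from expression table; excluded")
  expr <- expression[expression$gene_id %in% linked, , drop = FALSE]
  keep <- expr$padj < alpha &
    (if (direction == "up") expr$log2fc > 0 else expr$log2fc < 0)
  expr <- expr[keep, , drop = FALSE]
  support <- vapply(expr$gene_id, function(g) {
    paste(sort(unique(links$peak[links$gene_id == g])), collapse = ",")
  }, character(1))
  report <- data.frame(gene_id = expr$gene_id, log2fc = expr$log2fc,
                       padj = expr$padj,
                       n_peaks = vapply(strsplit(support, ","), length,
                                        integer(1)),
                       peaks = support, stringsAsFactors = FALSE)
  report <- report[order(report$padj, -abs(report$log2fc)), ]
  rownames(report) <- NULL
  list(genes = sort(unique(report$gene_id)), report = report)
}
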