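#' Gene models
#'
#' A `gene_models` object holds one transcript model per `gene_id`: the
#' transcript span (gene body), strand, TSS and exon blocks.  The TSS is the
#' body start on `+` and the last base of the body (`end - 1`) on `-`.
#'
#' @param genes data frame with columns `gene_id, chrom, start, end, strand`
#'   (0-based half-open body span; strand `+` or `-`).
#' @param exons data frame with columns `gene_id, start, end`; exons must
#'   lie within the gene body and not overlap each other.  If `NULL`, each
#'   gene gets a single exon equal to its body.
#' @param collapse_duplicates if `TRUE`, duplicate `gene_id`s are collapsed
#'   to the longest body (with a message); otherwise duplicates are an error.
#' @return object of class `gene_models`: list with elements `genes`
#'   (including a computed `tss` column) and `exons`.
#' @export
gene_models <- function(genes, exons = NULL, collapse_duplicates = FALSE) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  stopifnot(all(need %in% names(genes)))
  genes <- as.data.frame(genes)[need]
  if (anyDuplicated(genes$gene_id)) {
    if (!collapse_duplicates)
      stop("duplicate gene_id(s); one model per gene_id is required ",
           "(set collapse_duplicates = TRUE to keep the longest body)")
    message("collapsing duplicate gene_id(s) to the longest body")
    genes <- genes[order(-(genes$end - genes$start)), ]
    genes <- genes[!duplicated(genes$gene_id), ]
  }
  stopifnot(all(genes$strand %in% c("+", "-")), all(genes$start < genes$end))
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes <- genes[order(genes$chrom, genes$start, method = "radix"), ]
  rownames(genes) <- NULL
  if (is.null(exons)) {
    exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                        end = genes$end, stringsAsFactors = FALSE)
  } else {
    exons <- as.data.frame(exons)[c("gene_id", "start", "end")]
    m <- match(exons$gene_id, genes$gene_id)
    if (anyNA(m)) stop("exon refers to unknown gene_id")
    if (any(exons$start < genes$start[m] | exons$end > genes$end[m]))
      stop("exon outside gene body")
  }
  exons$chrom <- genes$chrom[match(exons$gene_id, genes$gene_id)]
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Annotation configuration
#'
#' Promoters are defined as the window from `promoter_upstream` bp upstream
#' of the TSS to `promoter_downstream` bp downstream (defaults 2000/1000,
#' the definition used for the genomic-category breakdown this module
#' reproduces).  `precedence` resolves peaks overlapping several feature
#' classes; the default promoter > exon > intron > intergenic.
#'
#' @param promoter_upstream,promoter_downstream window sizes in bp.
#' @param precedence permutation of
#'   `c("promoter", "exon", "intron", "intergenic")`.
#' @return a list of class `annotation_config`.
#' @export
annotation_config <- function(promoter_upstream = 2000,
                              promoter_downstream = 1000,
                              precedence = c("promoter", "exon", "intron",
                                             "intergenic")) {
  stopifnot(promoter_upstream >= 0, promoter_downstream >= 0,
            setequal(precedence, c("promoter", "exon", "intron", "intergenic")),
            length(precedence) == 4)
  structure(list(promoter_upstream = promoter_upstream,
                 promoter_downstream = promoter_downstream,
                 precedence = precedence),
            class = "annotation_config")
}

#' Promoter windows
#'
#' Strand-aware promoter window around each TSS: on `+`,
#' `[tss - upstream, tss + downstream)`; on `-` the mirror image
#' `[tss - downstream, tss + upstream)` so that "upstream" always points
#' away from the gene body.  Windows are clipped at coordinate 0.
#'
#' @param genes a `gene_models` object.
#' @param cfg an `annotation_config`.
#' @return an `interval_set` of promoter windows (named by gene, stranded).
#' @export
promoter_windows <- function(genes, cfg = annotation_config()) {
  g <- genes$genes
  up <- cfg$promoter_upstream; dn <- cfg$promoter_downstream
  start <- ifelse(g$strand == "+", g$tss - up, g$tss - dn)
  end <- ifelse(g$strand == "+", g$tss + dn, g$tss + up)
  start <- pmax(start, 0)
  keep <- end > start
  interval_set(g$chrom[keep], start[keep], end[keep],
               name = g$gene_id[keep], strand = g$strand[keep],
               label = "promoters")
}

## logical: which peaks overlap the given feature set by >= 1 bp
overlaps_any <- function(peaks, features) {
  if (nrow(features) == 0 || nrow(peaks) == 0)
    return(rep(FALSE, nrow(peaks)))
  hits <- intersect_sets(peaks, features, min_overlap = 1)
  peaks$name %in% hits$a_name
}

#' Classify peaks into genomic categories
#'
#' Assigns each peak the first category in the configured precedence whose
#' feature space it overlaps by >= 1 bp: promoter windows, exons, introns
#' (gene body minus exons minus promoters), else intergenic.  Peak-level
#' classification: each peak gets exactly one label.
#'
#' @param peaks an `interval_set`.
#' @param genes a `gene_models` object.
#' @param cfg an `annotation_config`.
#' @return character vector of categories, one per peak (in `peaks` order).
#' @export
classify_peaks <- function(peaks, genes, cfg = annotation_config()) {
  g <- genes$genes
  prom <- promoter_windows(genes, cfg)
  exon <- interval_set(genes$exons$chrom, genes$exons$start, genes$exons$end,
                       label = "exons")
  body <- interval_set(g$chrom, g$start, g$end, name = g$gene_id,
                       label = "bodies")
  intron <- subtract_sets(subtract_sets(body, exon), prom)
  feats <- list(promoter = prom, exon = exon, intron = intron)
  cat_of <- rep("intergenic", nrow(peaks))
  assigned <- rep(FALSE, nrow(peaks))
  for (cl in cfg$precedence) {
    if (cl == "intergenic") next
    hit <- overlaps_any(peaks, feats[[cl]])
    cat_of[hit & !assigned] <- cl
    assigned <- assigned | hit
  }
  cat_of
}

#' Genomic-category proportions of a peak set
#'
#' The proportion of peaks falling in promoters, exons, introns and
#' intergenic space (peak counts, not covered bases); fractions sum to 1.
#'
#' @inheritParams classify_peaks
#' @return data frame with columns `category`, `count`, `fraction`, ordered
#'   by the configured precedence.
#' @export
category_proportions <- function(peaks, genes, cfg = annotation_config()) {
  if (nrow(peaks) == 0) stop("no peaks to annotate")
  cl <- classify_peaks(peaks, genes, cfg)
  counts <- vapply(cfg$precedence, function(k) sum(cl == k), numeric(1))
  data.frame(category = cfg$precedence, count = as.integer(counts),
             fraction = counts / sum(counts), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read gene models from BED12
#'
#' Standard 12-column BED: the thick/blocks fields supply exon structure.
#' Malformed lines raise an error with their line number.
#'
#' @param path BED12 file path.
#' @inheritParams gene_models
#' @return a `gene_models` object.
#' @export
read_bed12 <- function(path, collapse_duplicates = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty BED12 file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12)
  if (length(bad))
    stop("malformed BED12 line ", lineno[bad[1]], " in ", path,
         ": fewer than 12 fields")
  f <- function(i) vapply(fields, `[[`, character(1), i)
  start <- as.numeric(f(2)); end <- as.numeric(f(3))
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinates in ", path)
  genes <- data.frame(gene_id = f(4), chrom = f(1), start = start, end = end,
                      strand = f(6), stringsAsFactors = FALSE)
  nblock <- as.integer(f(10))
  sizes <- strsplit(f(11), ",", fixed = TRUE)
  starts <- strsplit(f(12), ",", fixed = TRUE)
  exons <- do.call(rbind, lapply(seq_along(fields), function(i) {
    bs <- as.numeric(starts[[i]][seq_len(nblock[i])])
    bw <- as.numeric(sizes[[i]][seq_len(nblock[i])])
    data.frame(gene_id = genes$gene_id[i], start = genes$start[i] + bs,
               end = genes$start[i] + bs + bw, stringsAsFactors = FALSE)
  }))
  gene_models(genes, exons, collapse_duplicates = collapse_duplicates)
}

#' Write gene models to BED12
#'
#' @param genes a `gene_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed12 <- function(genes, path) {
  g <- genes$genes
  rows <- vapply(seq_len(nrow(g)), function(i) {
    ex <- genes$exons[genes$exons$gene_id == g$gene_id[i], , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    paste(g$chrom[i], format_coord(g$start[i]), format_coord(g$end[i]),
          g$gene_id[i], 0, g$strand[i],
          format_coord(g$start[i]), format_coord(g$end[i]), "0",
          nrow(ex),
          paste0(paste(format_coord(ex$end - ex$start), collapse = ","), ","),
          paste0(paste(format_coord(ex$start - g$start[i]), collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
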