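#' Bipartite TF-to-gene regulatory network
#'
#' Builds the condition-specific regulatory network: one edge per
#' (enriched TF motif, target gene), with pooled peak-level evidence
#' (which peaks carry the motif hit, at which offsets).  Heterodimer motif
#' ids (e.g. "FOSL1::JUN") are single TF nodes.  Isolated nodes are
#' dropped.
#'
#' @param tf_gene_sets output of [motif_target_genes()]: motif id ->
#'   `list(genes, evidence)`.
#' @param enriched_tfs motif ids flagged enriched (fold >= threshold);
#'   motifs not in this list are excluded entirely.
#' @param condition_label label stored on the network.
#' @return object of class `regulatory_network`: list with `tf_nodes`,
#'   `gene_nodes`, `edges` (data frame `tf, gene, n_peaks`), `evidence`
#'   (data frame `tf, gene, peak, offset, strand`), `condition_label`.
#' @export
build_network <- function(tf_gene_sets, enriched_tfs,
                          condition_label = "condition") {
  keep <- intersect(names(tf_gene_sets), enriched_tfs)
  ev <- do.call(rbind, lapply(keep, function(m) {
    e <- tf_gene_sets[[m]]$evidence
    if (is.null(e) || nrow(e) == 0) return(NULL)
    data.frame(tf = m, gene = e$gene_id, peak = e$peak, offset = e$offset,
               strand = e$strand, stringsAsFactors = FALSE)
  }))
  if (is.null(ev) || nrow(ev) == 0) {
    warning("empty network")
    ev <- data.frame(tf = character(), gene = character(),
                     peak = character(), offset = numeric(),
                     strand = character(), stringsAsFactors = FALSE)
  }
  key <- paste(ev$tf, ev$gene, sep = "\r")
  edges <- if (nrow(ev)) {
    agg <- tapply(ev$peak, key, function(p) length(unique(p)))
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    data.frame(tf = vapply(parts, `[[`, character(1), 1),
               gene = vapply(parts, `[[`, character(1), 2),
               n_peaks = as.integer(agg), stringsAsFactors = FALSE)
  } else data.frame(tf = character(), gene = character(),
                    n_peaks = integer(), stringsAsFactors = FALSE)
  edges <- edges[order(edges$tf, edges$gene), ]
  rownames(edges) <- NULL
  structure(list(tf_nodes = sort(unique(edges$tf)),
                 gene_nodes = sort(unique(edges$gene)),
                 edges = edges, evidence = ev,
                 condition_label = condition_label),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network [", x$condition_label, "]: ",
      length(x$tf_nodes), " TFs, ", length(x$gene_nodes), " genes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' TF hub ranking by out-degree
#'
#' Descriptive ranking of TF nodes by number of target genes (no
#' statistical test is applied).
#'
#' @param network a `regulatory_network`.
#' @return data frame `tf, out_degree` sorted decreasing.
#' @export
tf_hubs <- function(network) {
  deg <- table(network$edges$tf)
  out <- data.frame(tf = names(deg), out_degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$out_degree, out$tf), ]
  rownames(out) <- NULL
  out
}

#' Pairwise TF target overlap
#'
#' Shared-target counts and Jaccard indices for every unordered TF pair,
#' sorted by descending Jaccard.
#'
#' @param network a `regulatory_network`.
#' @return data frame `tf1, tf2, shared, jaccard` (empty if < 2 TFs).
#' @export
tf_overlap <- function(network) {
  tfs <- network$tf_nodes
  empty <- data.frame(tf1 = character(), tf2 = character(),
                      shared = integer(), jaccard = numeric(),
                      stringsAsFactors = FALSE)
  if (length(tfs) < 2) return(empty)
  targets <- lapply(tfs, function(t)
    unique(network$edges$gene[network$edges$tf == t]))
  names(targets) <- tfs
  pairs <- utils::combn(tfs, 2)
  rows <- apply(pairs, 2, function(p) {
    a <- targets[[p[1]]]; b <- targets[[p[2]]]
    sh <- length(intersect(a, b))
    un <- length(union(a, b))
    data.frame(tf1 = p[1], tf2 = p[2], shared = sh,
               jaccard = if (un) sh / un else 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$jaccard, out$tf1, out$tf2), ]
  rownames(out) <- NULL
  out
}

#' Export a regulatory network
#'
#' Writes any of: GraphML (via igraph, with a `type` node attribute
#' distinguishing TF and gene nodes and an `n_peaks` edge attribute), SIF
#' (`tf  regulates  gene` lines), and node/edge TSVs.
#'
#' @param network a `regulatory_network`.
#' @param dir output directory (created if needed).
#' @param formats subset of `c("graphml", "sif", "tsv")`.
#' @param basename_ file stem.
#' @return named character vector of written paths, invisibly.
#' @export
export_network <- function(network, dir,
                           formats = c("graphml", "sif", "tsv"),
                           basename_ = "network") {
  unknown <- setdiff(formats, c("graphml", "sif", "tsv"))
  if (length(unknown)) stop("unknown format(s): ", paste(unknown, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- character()
  if ("graphml" %in% formats) {
    g <- as_igraph(network)
    p <- file.path(dir, paste0(basename_, ".graphml"))
    igraph::write_graph(g, p, format = "graphml")
    out["graphml"] <- p
  }
  if ("sif" %in% formats) {
    p <- file.path(dir, paste0(basename_, ".sif"))
    writeLines(paste(network$edges$tf, "regulates", network$edges$gene,
                     sep = "\t"), p)
    out["sif"] <- p
  }
  if ("tsv" %in% formats) {
    pn <- file.path(dir, paste0(basename_, "_nodes.tsv"))
    deg_tf <- table(network$edges$tf)
    deg_gene <- table(network$edges$gene)
    nodes <- rbind(
      data.frame(id = network$tf_nodes, type = "tf",
                 degree = as.integer(deg_tf[network$tf_nodes]),
                 stringsAsFactors = FALSE),
      data.frame(id = network$gene_nodes, type = "gene",
                 degree = as.integer(deg_gene[network$gene_nodes]),
                 stringsAsFactors = FALSE))
    utils::write.table(nodes, pn, sep = "\t", quote = FALSE, row.names = FALSE)
    pe <- file.path(dir, paste0(basename_, "_edges.tsv"))
    utils::write.table(network$edges, pe, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out["nodes_tsv"] <- pn; out["edges_tsv"] <- pe
  }
  invisible(out)
}

#' Convert to an igraph bipartite graph
#'
#' @param network a `regulatory_network`.
#' @return an igraph object with vertex attribute `type` ("tf"/"gene").
#' @export
as_igraph <- function(network) {
  verts <- data.frame(
    name = c(network$tf_nodes, network$gene_nodes),
    type = c(rep("tf", length(network$tf_nodes)),
             rep("gene", length(network$gene_nodes))),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = verts)
}
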