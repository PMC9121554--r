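#' Upper-tail hypergeometric over-representation p-value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing a query of size
#' `n` from a universe of `N` genes of which `K` belong to the term, the
#' probability of at least the observed `k` term genes.  Computed by exact
#' summation (`stats::phyper`).
#'
#' @param k query-term intersection size.
#' @param K term size in the universe.
#' @param n query size.
#' @param N universe size.
#' @return p-value.
#' @export
hypergeometric_test <- function(k, K, n, N) {
  if (k < 0 || K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need 0 <= k <= min(K, n) and K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper over `stats::p.adjust(method = "BH")`; input
#' order is preserved in the output.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric())
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Read a gene-set collection (GMT)
#'
#' Tab-separated GMT: term id, description, then member genes.  Gene ids
#' are uppercased on load.  The description field is parsed for a category
#' tag (`BP`, `CC`, `MF`, `KEGG`) used for per-category correction; terms
#' without one are tagged `other`.
#'
#' @param path GMT file path.
#' @return object of class `gene_set_collection`: named list of sets, each
#'   `list(name, category, genes)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop("malformed GMT line ", bad[1], " in ", path, ": fewer than 3 fields")
  sets <- lapply(fields, function(f) {
    desc <- f[2]
    tag <- regmatches(desc, regexpr("\\b(BP|CC|MF|KEGG)\\b", desc))
    list(name = desc,
         category = if (length(tag)) tag else "other",
         genes = unique(toupper(f[-(1:2)])))
  })
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  structure(sets, class = "gene_set_collection")
}

#' Build a gene-set collection in code
#'
#' @param sets named list: term id -> character vector of gene ids.
#' @param categories optional named character vector of category tags
#'   (`BP`, `CC`, `MF`, `KEGG`, `other`) per term; default `other`.
#' @param names_ optional named character vector of term names.
#' @return a `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, categories = NULL, names_ = NULL) {
  stopifnot(length(sets) > 0, !is.null(names(sets)))
  out <- lapply(names(sets), function(id) {
    list(name = if (!is.null(names_)) unname(names_[id]) else id,
         category = if (!is.null(categories)) unname(categories[id]) else "other",
         genes = unique(toupper(sets[[id]])))
  })
  names(out) <- names(sets)
  structure(out, class = "gene_set_collection")
}

#' Gene-set over-representation analysis
#'
#' Hypergeometric upper-tail test of each term against a query gene list,
#' with Benjamini-Hochberg correction applied separately within each
#' category (`BP`, `CC`, `MF`, `KEGG`, `other`), matching per-category
#' reporting; a pooled correction is available via `per_category = FALSE`.
#' Query genes absent from the universe are dropped with a message; terms
#' with no universe genes are skipped.
#'
#' @param query character vector of query gene ids.
#' @param universe character vector of background gene ids (the choice of
#'   background materially affects results and is reported in the output
#'   attributes).
#' @param collection a `gene_set_collection`.
#' @param q_threshold significance threshold recorded per term.
#' @param per_category correct within categories (default) or pooled.
#' @return data frame sorted by (qvalue, pvalue): `term, name, category, k,
#'   K, n, N, pvalue, qvalue, significant`.
#' @export
enrich <- function(query, universe, collection, q_threshold = 0.05,
                   per_category = TRUE) {
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe")
  query <- unique(toupper(query))
  drop <- setdiff(query, universe)
  if (length(drop)) {
    message(length(drop), " query gene(s) absent from universe; dropped")
    query <- intersect(query, universe)
  }
  if (!length(query))
    return(data.frame(term = character(), name = character(),
                      category = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), pvalue = numeric(),
                      qvalue = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(id) {
    gs <- intersect(collection[[id]]$genes, universe)
    K <- length(gs)
    if (K == 0) return(NULL)
    k <- length(intersect(gs, query))
    data.frame(term = id, name = collection[[id]]$name,
               category = collection[[id]]$category,
               k = k, K = K, n = n, N = N,
               pvalue = hypergeometric_test(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no term has genes in the universe")
  res$qvalue <- NA_real_
  if (per_category) {
    for (cc in unique(res$category)) {
      i <- res$category == cc
      res$qvalue[i] <- bh_adjust(res$pvalue[i])
    }
  } else res$qvalue <- bh_adjust(res$pvalue)
  res$significant <- res$qvalue < q_threshold
  res <- res[order(res$qvalue, res$pvalue), ]
  rownames(res) <- NULL
  attr(res, "universe_size") <- N
  res
}
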