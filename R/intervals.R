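#' Genomic interval sets
#'
#' An `interval_set` is a plain data frame of genomic intervals in the BED
#' dialect: coordinates are 0-based, half-open (`start` inclusive, `end`
#' exclusive) on named sequences.  This is the unit of all overlap logic in
#' the package; 1-based coordinates appear only when converting to
#' `GRanges` internally.
#'
#' @param chrom character vector of sequence names.
#' @param start,end numeric vectors, 0-based half-open; `0 <= start < end`.
#' @param name optional interval identifiers (default `peak_1`, ...).
#' @param score optional numeric scores (default 0).
#' @param strand one of `"+"`, `"-"`, `"."` per interval (default `"."`).
#'   Strand is carried but ignored by all overlap operations: ATAC peaks are
#'   unstranded; strand matters only for promoter windows and motif scans.
#' @param label a track/sample label attached to the set.
#' @return A data frame of class `interval_set` with columns
#'   `chrom, start, end, name, score, strand`, sorted by
#'   (lexicographic chrom, start, end).
#' @export
interval_set <- function(chrom, start, end, name = NULL, score = NULL,
                         strand = NULL, label = "intervals") {
  n <- length(start)
  stopifnot(length(end) == n)
  if (length(chrom) == 1 && n > 1) chrom <- rep(chrom, n)
  stopifnot(length(chrom) == n)
  if (is.null(name))   name   <- if (n) paste0("peak_", seq_len(n)) else character()
  if (is.null(score))  score  <- rep(0, n)
  if (is.null(strand)) strand <- rep(".", n)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   name = as.character(name), score = as.numeric(score),
                   strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df <- df[order(df$chrom, df$start, df$end, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("interval_set", "data.frame"), label = label)
}

validate_intervals <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  if (any(!nzchar(df$chrom)))
    stop("empty chromosome name")
  if (any(!df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

#' @export
print.interval_set <- function(x, ...) {
  cat("interval_set '", attr(x, "label"), "': ", nrow(x), " intervals on ",
      length(unique(x$chrom)), " sequence(s)\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

set_label <- function(x) attr(x, "label") %||% "intervals"
`%||%` <- function(a, b) if (is.null(a)) b else a

## interval_set (0-based half-open) -> GRanges (1-based closed); a shared
## seqlevels universe avoids cross-set level mismatches in overlap calls
as_granges <- function(x, seqlvls = NULL) {
  if (is.null(seqlvls)) seqlvls <- sort(unique(x$chrom))
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = seqlvls),
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = ifelse(x$strand == ".", "*", x$strand))
}

granges_to_set <- function(gr, label = "intervals", names = NULL) {
  n <- length(gr)
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1,
               GenomicRanges::end(gr),
               name = names,
               strand = {
                 s <- as.character(GenomicRanges::strand(gr))
                 ifelse(s == "*", ".", s)
               },
               label = label)
}

#' Intersect two interval sets
#'
#' Returns every pair of intervals (one from `a`, one from `b`) on the same
#' chromosome sharing at least `min_overlap` bases, the bedtools-style
#' primitive used to overlap peak sets with genes, enhancers and
#' super-enhancers.
#'
#' @param a,b `interval_set` objects.
#' @param min_overlap minimum shared bases (default 1, the bedtools default;
#'   the source analyses state no fraction threshold).
#' @return data frame with one row per overlapping pair, ordered by
#'   (chrom, a start, b start): columns `chrom`, `a_name`, `a_start`,
#'   `a_end`, `b_name`, `b_start`, `b_end`, `overlap` (shared bases).
#' @export
intersect_sets <- function(a, b, min_overlap = 1) {
  stopifnot(min_overlap >= 1)
  empty <- data.frame(chrom = character(), a_name = character(),
                      a_start = numeric(), a_end = numeric(),
                      b_name = character(), b_start = numeric(),
                      b_end = numeric(), overlap = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  lv <- sort(unique(c(a$chrom, b$chrom)))
  gra <- as_granges(a, lv); grb <- as_granges(b, lv)
  hits <- GenomicRanges::findOverlaps(gra, grb, minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  out <- data.frame(chrom = a$chrom[qi],
                    a_name = a$name[qi], a_start = a$start[qi], a_end = a$end[qi],
                    b_name = b$name[si], b_start = b$start[si], b_end = b$end[si],
                    overlap = ov, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$a_start, out$b_start, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge intervals within a gap
#'
#' Collapses an interval set to the minimal set of non-overlapping intervals
#' covering the same bases; intervals separated by at most `max_gap`
#' uncovered bases are joined.  Idempotent.
#'
#' @param a an `interval_set`.
#' @param max_gap maximum half-open gap (in bp) across which intervals are
#'   still joined; 0 joins touching/overlapping intervals only.
#' @return merged `interval_set` (strand-blind; merged intervals get strand
#'   `"."` and fresh names).
#' @export
merge_set <- function(a, max_gap = 0) {
  stopifnot(max_gap >= 0)
  if (nrow(a) == 0) return(a)
  gr <- GenomicRanges::reduce(as_granges(a), min.gapwidth = max_gap + 1,
                              ignore.strand = TRUE)
  granges_to_set(gr, label = set_label(a),
                 names = paste0("merged_", seq_along(gr), recycle0 = TRUE))
}

#' Subtract covered bases
#'
#' Removes from the coverage of `a` every base covered by `b`; intervals may
#' split.  Used e.g. to define enhancers as H3K27ac regions minus promoter
#' windows.  The result is reported on the merged coverage of `a`
#' (overlapping input intervals are first collapsed); zero-length remnants
#' are dropped.
#'
#' @param a,b `interval_set` objects.
#' @return `interval_set` covering `bases(a) \ bases(b)`.
#' @export
subtract_sets <- function(a, b) {
  if (nrow(a) == 0) return(a)
  if (nrow(b) == 0) return(merge_set(a))
  lv <- sort(unique(c(a$chrom, b$chrom)))
  gr <- GenomicRanges::setdiff(as_granges(a, lv), as_granges(b, lv),
                               ignore.strand = TRUE)
  granges_to_set(gr, label = set_label(a),
                 names = paste0("sub_", seq_along(gr), recycle0 = TRUE))
}

#' Total covered bases
#'
#' @param a an `interval_set`.
#' @return number of distinct bases covered (overlaps counted once).
#' @export
covered_bases <- function(a) {
  if (nrow(a) == 0) return(0)
  m <- merge_set(a)
  sum(m$end - m$start)
}

#' Replicate/condition membership of merged peaks
#'
#' Builds the merged union of several interval sets and records, for each
#' union interval, which input sets contribute at least one overlapping
#' (>= 1 bp) interval — the Venn-partition summary used to compare
#' duplicate peak sets.
#'
#' @param sets a named list of >= 2 `interval_set` objects.
#' @return list with `membership` (data frame: union interval coordinates +
#'   one logical column per set) and `partition` (data frame: presence
#'   `pattern` such as `"101"` in the order of `sets`, and interval `count`;
#'   counts sum to the number of union intervals).
#' @export
overlap_counts <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- paste0("set", seq_along(sets))
  pooled <- do.call(rbind, lapply(sets, function(s) as.data.frame(s)[c("chrom", "start", "end")]))
  uni <- merge_set(interval_set(pooled$chrom, pooled$start, pooled$end,
                                label = "union"))
  memb <- as.data.frame(uni)[c("chrom", "start", "end", "name")]
  for (nm in names(sets)) {
    hit <- intersect_sets(uni, sets[[nm]], min_overlap = 1)
    memb[[nm]] <- memb$name %in% hit$a_name
  }
  pat <- apply(as.matrix(memb[names(sets)]), 1, function(z)
    paste(as.integer(z), collapse = ""))
  tab <- table(pat)
  partition <- data.frame(pattern = names(tab), count = as.integer(tab),
                          stringsAsFactors = FALSE)
  list(membership = memb, partition = partition)
}

#' Read a BED3/BED6 file
#'
#' Tab-separated, no header; `track`/`browser` lines are tolerated and
#' skipped.  Coordinates pass through unchanged (BED is 0-based half-open).
#' A malformed line raises an error naming its line number.  Duplicate
#' intervals are permitted but flagged with a warning.
#'
#' @param path file path.
#' @param label track label (default: file name).
#' @return an `interval_set`.
#' @export
read_bed <- function(path, label = basename(path)) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(interval_set(character(), numeric(), numeric(), label = label))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 3)
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], " in ", path,
         ": fewer than 3 fields")
  get <- function(i, default) vapply(seq_along(fields), function(j) {
    if (nf[j] >= i) fields[[j]][i] else default
  }, character(1))
  start <- suppressWarnings(as.numeric(get(2, NA)))
  end <- suppressWarnings(as.numeric(get(3, NA)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1]], " in ", path,
         ": non-numeric coordinates")
  score <- suppressWarnings(as.numeric(get(5, "0")))
  score[is.na(score)] <- 0
  x <- interval_set(get(1, "."), start, end,
                    name = get(4, "."), score = score,
                    strand = get(6, "."), label = label)
  key <- paste(x$chrom, x$start, x$end)
  if (anyDuplicated(key))
    warning("duplicate intervals in ", path)
  x
}

#' Write a BED6 file
#'
#' @param x an `interval_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- as.data.frame(x)[c("chrom", "start", "end", "name", "score", "strand")]
  df$start <- format_coord(df$start); df$end <- format_coord(df$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## integer-style formatting for coordinates stored as doubles
format_coord <- function(x) formatC(x, format = "d")
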