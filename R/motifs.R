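#' Position weight matrices
#'
#' A `pwm` stores per-position base probabilities (rows A, C, G, T; one
#' column per motif position) together with a background model.  A
#' pseudocount is added and columns renormalised on construction, so
#' log-odds scores are always finite.
#'
#' @param mat 4 x W numeric matrix of base probabilities (or counts), rows
#'   in A, C, G, T order; W >= 4.
#' @param motif_id motif identifier (e.g. a database accession).
#' @param tf_name transcription-factor name.
#' @param background base probabilities (A, C, G, T), default uniform.
#' @param pseudocount added to every cell before renormalisation.
#' @return object of class `pwm` with elements `motif_id`, `tf_name`,
#'   `mat` (probabilities), `lodds` (log2 odds vs background), `background`,
#'   `width`.
#' @export
pwm <- function(mat, motif_id = "motif", tf_name = motif_id,
                background = rep(0.25, 4), pseudocount = 1e-3) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4, ncol(mat) >= 4, all(mat >= 0),
            length(background) == 4, all(background > 0))
  background <- background / sum(background)
  mat <- sweep(mat, 2, colSums(mat), "/")
  mat <- mat + pseudocount
  mat <- sweep(mat, 2, colSums(mat), "/")
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, tf_name = tf_name, mat = mat,
                 lodds = log2(mat / background), background = background,
                 width = ncol(mat)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm ", x$motif_id, " (", x$tf_name, "), width ", x$width,
      ", consensus ", consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a PWM (argmax base per column)
#' @param x a `pwm`.
#' @return character string of length `width`.
#' @export
consensus <- function(x) {
  paste(rownames(x$mat)[apply(x$mat, 2, which.max)], collapse = "")
}

BASES <- c("A", "C", "G", "T")

base_index <- function(seq) {
  idx <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], BASES)
  idx
}

#' Log-odds score of a k-mer
#'
#' `sum_i log2(p_i(base_i) / bg(base_i))` in bits.  The k-mer must have the
#' motif's width and contain only A/C/G/T.
#'
#' @param x a `pwm`.
#' @param kmer character string over A, C, G, T of length `x$width`.
#' @return score in bits.
#' @export
log_odds_score <- function(x, kmer) {
  idx <- base_index(kmer)
  if (length(idx) != x$width)
    stop("k-mer length ", length(idx), " != motif width ", x$width)
  if (anyNA(idx)) stop("k-mer contains non-ACGT characters")
  sum(x$lodds[cbind(idx, seq_len(x$width))])
}

## Lattice distribution of the score under the background model.
## Scores are discretised to integer multiples of `delta` bits; returns the
## integer offsets per (base, column), the minimum achievable lattice sum
## and the tail probability vector tail[i] = P(lattice sum >= lo + i - 1).
pwm_score_lattice <- function(x, delta = 1e-3) {
  off <- round(x$lodds / delta)
  lo <- sum(apply(off, 2, min)); hi <- sum(apply(off, 2, max))
  n <- hi - lo + 1
  dist <- numeric(n)
  dist[1] <- 1  # before any column: sum = 0 at index of current lo
  cur_lo <- 0
  for (j in seq_len(x$width)) {
    col_lo <- min(off[, j])
    new <- numeric(n)
    for (b in 1:4) {
      sh <- off[b, j] - col_lo
      if (sh == 0) new[seq_len(n)] <- new[seq_len(n)] + dist * x$background[b]
      else new[(sh + 1):n] <- new[(sh + 1):n] +
          dist[seq_len(n - sh)] * x$background[b]
    }
    dist <- new
    cur_lo <- cur_lo + col_lo
  }
  tail <- rev(cumsum(rev(dist)))
  list(offsets = off, lo = lo, tail = tail, delta = delta)
}

#' Exact tail p-value of a PWM score
#'
#' Probability that a k-mer drawn from the background model scores at least
#' `score`, computed by dynamic programming over a discretised score lattice
#' (bin width `delta` bits, default 1e-3).  The lattice threshold uses a
#' half-window boundary rule (`ceil(score/delta - width/2)`) so that every
#' k-mer whose true score reaches `score` is counted; p-values are exact
#' whenever distinct achievable scores are separated by more than
#' `width * delta` bits, and monotone non-increasing in `score` always.
#'
#' @param x a `pwm`.
#' @param score score in bits.
#' @param lattice optional precomputed lattice from repeated calls.
#' @return tail probability in `[0, 1]`.
#' @export
score_pvalue <- function(x, score, lattice = NULL) {
  if (is.null(lattice)) lattice <- pwm_score_lattice(x)
  thr <- ceiling(score / lattice$delta - x$width / 2 - 1e-9)
  i <- thr - lattice$lo + 1
  if (i <= 1) return(1)
  if (i > length(lattice$tail)) return(0)
  lattice$tail[i]
}

#' Scan sequences with a PWM
#'
#' Slides the motif over both strands of every sequence and reports every
#' position whose score p-value is below `p_threshold` (FIMO-style: the
#' p-value is the background probability of an equal-or-better score).
#' Reverse-strand hits are scored on the reverse complement; the reported
#' offset is the 0-based position of the match start on the forward strand.
#' Windows containing non-ACGT characters are skipped.
#'
#' @param x a `pwm`.
#' @param sequences named character vector (or list) of sequences, names are
#'   peak/sequence ids.
#' @param p_threshold report positions with p-value < this (default 1e-4;
#'   note short motifs may have a best achievable p-value above a strict
#'   threshold: the minimum is `P(consensus)` under the background).
#' @return data frame of hits sorted by (peak, offset, strand): columns
#'   `motif_id, peak, offset, strand, score, pvalue`.
#' @export
scan_pwm <- function(x, sequences, p_threshold = 1e-4) {
  lattice <- pwm_score_lattice(x)
  w <- x$width
  out <- list()
  seq_names <- names(sequences)
  if (is.null(seq_names)) seq_names <- paste0("seq_", seq_along(sequences))
  for (si in seq_along(sequences)) {
    s <- as.character(sequences[[si]])
    idx <- base_index(s)
    L <- length(idx)
    if (L < w) next
    npos <- L - w + 1
    for (strand in c("+", "-")) {
      ii <- if (strand == "+") idx else rev(5 - idx)  # reverse complement
      sc <- numeric(npos)
      ok <- rep(TRUE, npos)
      for (j in seq_len(w)) {
        b <- ii[j:(j + npos - 1)]
        nab <- is.na(b)
        ok <- ok & !nab
        b[nab] <- 1
        sc <- sc + x$lodds[cbind(b, j)]
      }
      # vectorized lattice lookup (same rule as score_pvalue)
      thr <- ceiling(sc / lattice$delta - w / 2 - 1e-9)
      li <- thr - lattice$lo + 1
      pv <- rep(1, npos)
      pv[li > length(lattice$tail)] <- 0
      inb <- li > 1 & li <= length(lattice$tail)
      pv[inb] <- lattice$tail[li[inb]]
      hit <- which(ok & pv < p_threshold)
      if (length(hit)) {
        off <- if (strand == "+") hit - 1 else (npos - hit)  # forward coords
        out[[length(out) + 1]] <- data.frame(
          motif_id = x$motif_id, peak = seq_names[si], offset = off,
          strand = strand, score = sc[hit], pvalue = pv[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(motif_id = character(), peak = character(),
                      offset = numeric(), strand = character(),
                      score = numeric(), pvalue = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$peak, res$offset, res$strand, method = "radix"), ]
  rownames(res) <- NULL
  res
}

#' Scramble a sequence
#'
#' Uniform random permutation of the characters (mononucleotide shuffle):
#' base composition is exactly preserved.  Deterministic given `seed`.
#'
#' @param sequence character string.
#' @param seed integer seed.
#' @return scrambled string.
#' @export
scramble <- function(sequence, seed) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  ord <- with_seed(seed, sample.int(length(chars)))
  paste(chars[ord], collapse = "")
}

## evaluate expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% (.Machine$integer.max - 1)))
  expr
}

#' Fold enrichment over scrambled background
#'
#' Counts motif occurrences (scan hits below `p_threshold`, both strands,
#' overlaps all counted) in the supplied sequences and in `n_shuffles`
#' independent composition-preserving scrambles of every sequence.
#' `fold = observed / max(background_mean, 0.5 / n_shuffles)`; the epsilon
#' floor prevents an infinite fold when no background hit occurs.  A motif
#' is flagged enriched when `fold >= fold_threshold` (default 2, the
#' significance rule this module reproduces).
#'
#' @param x a `pwm`.
#' @param sequences named character vector of peak sequences.
#' @param n_shuffles number of scrambles per sequence (default 10).
#' @param p_threshold scan p-value threshold.
#' @param fold_threshold enrichment call threshold (default 2).
#' @param seed integer seed for the scrambles.
#' @return data frame (one row) with `motif_id, tf_name, observed,
#'   background_mean, fold, n_shuffles, enriched`.
#' @export
fold_enrichment <- function(x, sequences, n_shuffles = 10,
                            p_threshold = 1e-4, fold_threshold = 2,
                            seed = 1) {
  stopifnot(n_shuffles >= 1)
  observed <- nrow(scan_pwm(x, sequences, p_threshold))
  bg <- numeric(n_shuffles)
  for (k in seq_len(n_shuffles)) {
    shuf <- vapply(seq_along(sequences), function(i)
      scramble(as.character(sequences[[i]]),
               seed = (seed + 7919 * k + i) %% .Machine$integer.max),
      character(1))
    names(shuf) <- names(sequences)
    bg[k] <- nrow(scan_pwm(x, shuf, p_threshold))
  }
  bgm <- mean(bg)
  fold <- observed / max(bgm, 0.5 / n_shuffles)
  data.frame(motif_id = x$motif_id, tf_name = x$tf_name,
             observed = observed, background_mean = bgm, fold = fold,
             n_shuffles = n_shuffles, enriched = fold >= fold_threshold,
             stringsAsFactors = FALSE)
}

#' Map motif hits to selected target genes
#'
#' For each motif, the set of selected (e.g. concordantly upregulated)
#' genes having at least one linked peak that carries at least one hit —
#' the input layer of the TF-to-gene regulatory network.
#'
#' @param hits data frame from [scan_pwm()] (possibly several motifs bound
#'   together).
#' @param links data frame of peak-to-gene links with columns `peak` and
#'   `gene_id` (see [link_peaks_to_gene_bodies()]).
#' @param selected_genes character vector of selected gene ids.
#' @return named list: motif_id -> list with `genes` (character vector) and
#'   `evidence` (data frame peak/gene/offset/strand).
#' @export
motif_target_genes <- function(hits, links, selected_genes) {
  out <- list()
  for (m in unique(hits$motif_id)) {
    h <- hits[hits$motif_id == m, , drop = FALSE]
    ev <- merge(h, links[, c("peak", "gene_id")], by = "peak")
    ev <- ev[ev$gene_id %in% selected_genes, , drop = FALSE]
    out[[m]] <- list(genes = sort(unique(ev$gene_id)),
                     evidence = ev[, c("peak", "gene_id", "offset", "strand")])
  }
  out
}

#' Extract peak sequences from a genome
#'
#' @param peaks an `interval_set`.
#' @param genome a [Biostrings::DNAStringSet] keyed by chromosome name.
#' @return named character vector of peak sequences (names = peak names).
#' @export
peak_sequences <- function(peaks, genome) {
  out <- vapply(seq_len(nrow(peaks)), function(i) {
    as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                    start = peaks$start[i] + 1,
                                    end = peaks$end[i]))
  }, character(1))
  names(out) <- peaks$name
  out
}

#' Built-in fixture motifs
#'
#' Two synthetic test matrices shipped for examples and tests (not curated
#' database motifs): an E-box-like CAGCTG (width 6) and an extended
#' AP-1-like TGACTCAG (width 8).  Both put probability `p_major` on the
#' consensus base so achievable scores are well separated.
#'
#' @param p_major probability of the consensus base per column.
#' @return a named list of `pwm` objects.
#' @export
fixture_pwms <- function(p_major = 0.85) {
  mk <- function(cons, id, tf) {
    idx <- match(strsplit(cons, "")[[1]], BASES)
    m <- matrix((1 - p_major) / 3, 4, length(idx))
    m[cbind(idx, seq_along(idx))] <- p_major
    pwm(m, motif_id = id, tf_name = tf)
  }
  list(EBOX = mk("CAGCTG", "EBOX_syn", "EboxTF"),
       AP1 = mk("TGACTCAG", "AP1_syn", "Ap1TF"))
}

#' Read PWMs in JASPAR text format
#'
#' Accepts the JASPAR 2020 flat format: a `>ID NAME` header followed by four
#' lines `A [ 1 2 3 ]` (brackets optional).  Count matrices are converted to
#' probabilities with a pseudocount.
#'
#' @param path file path.
#' @inheritParams pwm
#' @return named list of `pwm` objects (by motif id).
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 1e-3) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no '>' header in JASPAR file ", path)
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    stopifnot(i + 4 <= length(lines))
    hd <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]]
    id <- hd[1]; tf <- if (length(hd) > 1) hd[2] else hd[1]
    rows <- lapply(lines[(i + 1):(i + 4)], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1)
      stop("ragged matrix for motif ", id, " in ", path)
    out[[id]] <- pwm(do.call(rbind, rows), motif_id = id, tf_name = tf,
                     background = background, pseudocount = pseudocount)
  }
  out
}

#' Read PWMs in MEME minimal format
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections
#' (alphabet ACGT).
#'
#' @inheritParams read_jaspar
#' @return named list of `pwm` objects.
#' @export
read_meme <- function(path, background = rep(0.25, 4), pseudocount = 1e-3) {
  lines <- readLines(path)
  starts <- grep("^MOTIF", lines)
  if (!length(starts)) stop("no MOTIF block in MEME file ", path)
  out <- list()
  for (s in starts) {
    hd <- strsplit(trimws(lines[s]), "\\s+")[[1]]
    id <- hd[2]; tf <- if (length(hd) > 2) hd[3] else hd[2]
    lp <- s + grep("^letter-probability", lines[(s + 1):length(lines)])[1]
    w <- sub(".*w\\s*=\\s*(\\d+).*", "\\1", lines[lp])
    w <- as.integer(w)
    if (is.na(w)) stop("missing w= in letter-probability line for ", id)
    rows <- lapply(lines[(lp + 1):(lp + w)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    mat <- t(do.call(rbind, rows))  # file rows = positions; pwm wants 4 x W
    out[[id]] <- pwm(mat, motif_id = id, tf_name = tf,
                     background = background, pseudocount = pseudocount)
  }
  out
}
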