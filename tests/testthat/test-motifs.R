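test_that("log-odds scores sum per-column contributions", {
  m <- matrix(0.25, 4, 4)
  m[1, 1] <- 0.5; m[2:4, 1] <- 0.5 / 3  # column 1 favours A
  p <- pwm(m, pseudocount = 0)
  expect_equal(log_odds_score(p, "AAAA"), log2(0.5 / 0.25) + 3 * 0)
  expect_equal(log_odds_score(p, "CCCC"), log2((0.5 / 3) / 0.25))

  e <- fixture_pwms()$EBOX
  hand <- sum(log2(apply(e$mat, 2, max) / 0.25))
  expect_equal(log_odds_score(e, consensus(e)), hand)

  expect_error(log_odds_score(e, "CAG"), "width")
  expect_error(log_odds_score(e, "CAGCTN"), "non-ACGT")
})

test_that("lattice DP tail probabilities equal exhaustive enumeration", {
  for (p in fixture_pwms()) {
    if (p$width > 6) next
    # thresholds spanning the score range plus the exact consensus score
    probes <- c(seq(min(p$lodds) * p$width, max(p$lodds) * p$width,
                    length.out = 15),
                log_odds_score(p, consensus(p)))
    for (s in probes)
      expect_equal(score_pvalue(p, s), enumerate_pvalue(p, s),
                   tolerance = 1e-9)
  }
  # width-5 matrix with unequal column weights
  set.seed(20)
  m <- matrix(0.05, 4, 5)
  m[cbind(sample(1:4, 5, TRUE), 1:5)] <- 0.85
  p5 <- pwm(m)
  for (s in seq(-20, 12, by = 2.7))
    expect_equal(score_pvalue(p5, s), enumerate_pvalue(p5, s),
                 tolerance = 1e-9)
})

test_that("score p-values are bounded and monotone", {
  p <- fixture_pwms()$EBOX
  expect_equal(score_pvalue(p, -1e6), 1)
  expect_equal(score_pvalue(p, 1e6), 0)
  ss <- seq(-15, 15, length.out = 60)
  pv <- vapply(ss, function(s) score_pvalue(p, s), numeric(1))
  expect_true(all(diff(pv) <= 1e-12))
  # best achievable p-value of a width-6 motif is 4^-6 under uniform bg
  expect_equal(score_pvalue(p, log_odds_score(p, consensus(p))), 0.25^6,
               tolerance = 1e-9)
})

test_that("scanning finds a palindromic E-box on both strands", {
  p <- fixture_pwms()$EBOX  # consensus CAGCTG, its own reverse complement
  hits <- scan_pwm(p, c(pk = "AACAGCTGAA"), p_threshold = 1e-3)
  expect_equal(nrow(hits), 2)
  expect_equal(hits$offset, c(2, 2))
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(nrow(scan_pwm(p, character(), p_threshold = 1e-3)), 0)
})

test_that("hit counts are reverse-complement symmetric", {
  revcomp <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  set.seed(21)
  for (p in fixture_pwms()) {
    seqs <- vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""),
      character(1))
    seqs[2] <- paste0(substr(seqs[2], 1, 100), consensus(p),
                      substr(seqs[2], 107 + p$width - 6, 400))
    for (s in seqs)
      expect_equal(nrow(scan_pwm(p, c(fwd = s), p_threshold = 1e-3)),
                   nrow(scan_pwm(p, c(rev = revcomp(s)), p_threshold = 1e-3)))
  }
})

test_that("windows containing ambiguous bases are skipped", {
  p <- fixture_pwms()$EBOX
  hits <- scan_pwm(p, c(pk = "AACAGNTGAACAGCTGAA"), p_threshold = 1e-3)
  expect_equal(hits$offset, c(10, 10))  # only the intact site
})

test_that("scrambling permutes composition-preservingly and reproducibly", {
  expect_equal(scramble("AAAA", 1), "AAAA")
  s <- paste(rep(c("A", "C", "G", "T"), 250), collapse = "")
  t1 <- scramble(s, 42); t2 <- scramble(s, 42); t3 <- scramble(s, 43)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
  count <- function(x) table(strsplit(x, "")[[1]])
  expect_equal(count(t1), count(s))
})

test_that("fold enrichment flags implanted motifs and not empty signals", {
  p <- fixture_pwms()$EBOX
  empty <- fold_enrichment(p, c(a = "TTTTTTTTTTTTTTTT"), n_shuffles = 2,
                           p_threshold = 1e-3, seed = 1)
  expect_equal(empty$observed, 0)
  expect_equal(empty$fold, 0)
  expect_false(empty$enriched)

  set.seed(22)
  seqs <- vapply(1:20, function(i) {
    flank <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
    paste0(substr(flank, 1, 40), "CAGCTG", substr(flank, 47, 100))
  }, character(1))
  names(seqs) <- paste0("pk", 1:20)
  fe <- fold_enrichment(p, seqs, n_shuffles = 10, p_threshold = 1e-3,
                        seed = 7)
  expect_gte(fe$fold, 2)
  expect_true(fe$enriched)
})

test_that("motif hits map to selected genes through peak links", {
  hits <- data.frame(motif_id = "m1", peak = c("p1", "p2", "p3"),
                     offset = 0, strand = "+", score = 1, pvalue = 1e-5,
                     stringsAsFactors = FALSE)
  links <- data.frame(peak = c("p1", "p2", "p3"),
                      gene_id = c("g1", "g2", "g9"),
                      stringsAsFactors = FALSE)
  tg <- motif_target_genes(hits, links, c("g1", "g2"))
  expect_equal(tg$m1$genes, c("g1", "g2"))
  tg2 <- motif_target_genes(hits, links, "g5")
  expect_equal(length(tg2$m1$genes), 0)
})

test_that("JASPAR and MEME minimal parsers agree on the same motif", {
  fj <- tempfile(fileext = ".jaspar")
  writeLines(c(">MA0000.1 TESTTF",
               "A [ 10  0  0  5 ]",
               "C [  0 10  0  5 ]",
               "G [  0  0 10  0 ]",
               "T [  0  0  0  0 ]"), fj)
  pj <- read_jaspar(fj)[["MA0000.1"]]
  expect_equal(pj$tf_name, "TESTTF")
  expect_equal(pj$width, 4)
  expect_equal(consensus(pj), "ACGA")
  expect_equal(colSums(pj$mat), rep(1, 4), tolerance = 1e-6)

  fm <- tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF MA0000.1 TESTTF",
               "letter-probability matrix: alength= 4 w= 4 nsites= 20",
               " 1.0 0.0 0.0 0.0",
               " 0.0 1.0 0.0 0.0",
               " 0.0 0.0 1.0 0.0",
               " 0.5 0.5 0.0 0.0"), fm)
  pm <- read_meme(fm)[["MA0000.1"]]
  expect_equal(pm$width, 4)
  expect_equal(consensus(pm), "ACGA")
  expect_equal(pm$mat, pj$mat, tolerance = 0.05)

  expect_error(suppressWarnings(read_jaspar(tempfile())))
  f0 <- tempfile(); writeLines("no motifs here", f0)
  expect_error(read_meme(f0), "MOTIF")
})
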