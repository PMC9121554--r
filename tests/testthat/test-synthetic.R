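test_that("genome generation is deterministic and composition-balanced", {
  cfg <- test_config(seed = 1)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$genes$genes, g2$genes$genes)

  # binomial oracle: each base frequency within 3 SD of 0.25 on 1 Mb
  seq1 <- as.character(g1$genome[[1]])
  n <- nchar(seq1)
  tab <- table(strsplit(seq1, "")[[1]])
  sd3 <- 3 * sqrt(0.25 * 0.75 / n)
  for (b in c("A", "C", "G", "T"))
    expect_lt(abs(tab[[b]] / n - 0.25), sd3)
})

test_that("gene-free genomes are allowed", {
  cfg <- test_config(seed = 2, n_genes = 0, n_shared_peaks = 5,
                     n_unique_peaks_per_condition = 0,
                     n_super_enhancers = 0)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$genes$genes), 0)
  expect_equal(length(g$genome), 1)
})

test_that("gene models are valid: strands, exon bounds, TSS convention", {
  g <- generate_genome(test_config(seed = 3))$genes
  expect_true(all(g$genes$strand %in% c("+", "-")))
  expect_true(all(table(g$exons$gene_id) >= 2))
  m <- match(g$exons$gene_id, g$genes$gene_id)
  expect_true(all(g$exons$start >= g$genes$start[m]))
  expect_true(all(g$exons$end <= g$genes$end[m]))
  plus <- g$genes$strand == "+"
  expect_equal(g$genes$tss[plus], g$genes$start[plus])
  expect_equal(g$genes$tss[!plus], g$genes$end[!plus] - 1)
  # genes never overlap
  bodies <- interval_set(g$genes$chrom, g$genes$start, g$genes$end)
  expect_equal(nrow(merge_set(bodies)), nrow(g$genes))
})

test_that("replicate peak sets realise the designed occupancy structure", {
  cfg <- test_config(seed = 4, n_shared_peaks = 10,
                     n_unique_peaks_per_condition = 5)
  gen <- generate_genome(cfg)
  pk <- generate_peaks_and_counts(gen, cfg)
  for (ps in pk$peaksets) expect_equal(nrow(ps), 15)

  truth_a <- pk$truth[pk$truth$unique_to == "A", ]
  b_sets <- pk$peaksets[pk$samples$condition == "B"]
  for (bs in b_sets)
    expect_equal(nrow(intersect_sets(
      interval_set(truth_a$chrom, truth_a$start, truth_a$end), bs)), 0)

  # truth is consistent: unique ids, flags mutually exclusive
  expect_false(anyDuplicated(pk$truth$peak_id) > 0)
  expect_true(all(pk$truth$unique_to %in% c("A", "B", "none")))
  # peaks never overlap each other
  all_pk <- interval_set(pk$truth$chrom, pk$truth$start, pk$truth$end)
  expect_equal(nrow(merge_set(all_pk)), nrow(pk$truth))
})

test_that("open-peak counts match the NB moments", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 6e6, n_genes = 0,
                    n_shared_peaks = 1000, n_unique_peaks_per_condition = 0,
                    coupled_fraction = 0, n_super_enhancers = 0,
                    nb_mean = 100, nb_dispersion = 0.1,
                    closed_count_mean = 5, seed = 5)
  gen <- generate_genome(cfg)
  pk <- generate_peaks_and_counts(gen, cfg)
  cnts <- pk$counts$counts[, 1]
  se3 <- 3 * sqrt((100 + 0.1 * 100^2) / 1000)
  expect_lt(abs(mean(cnts) - 100), se3)
})

test_that("motif implantation writes retrievable consensus instances", {
  cfg <- test_config(seed = 6, implant_rate = 1)
  gen <- generate_genome(cfg)
  pk <- generate_peaks_and_counts(gen, cfg)
  p <- fixture_pwms()$EBOX
  imp <- implant_motifs(gen$genome, pk$truth, p, cfg)
  tr <- imp$truth
  ua <- tr[tr$unique_to == "A", ]
  expect_true(all(!is.na(ua$implanted_motif)))
  cons <- consensus(p)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  for (i in seq_len(nrow(ua))) {
    a <- ua$start[i] + ua$implant_offset[i] + 1
    got <- as.character(Biostrings::subseq(imp$genome[[ua$chrom[i]]],
                                           a, a + p$width - 1))
    expect_true(got == cons || got == rc)
    expect_equal(got, if (ua$implant_strand[i] == "+") cons else rc)
  }

  cfg0 <- test_config(seed = 6, implant_rate = 0)
  imp0 <- implant_motifs(gen$genome, pk$truth, p, cfg0)
  expect_identical(as.character(imp0$genome), as.character(gen$genome))
  expect_true(all(is.na(imp0$truth$implanted_motif)))
})

test_that("expression flags coupled genes and only coupled genes", {
  cfg <- test_config(seed = 7)
  gen <- generate_genome(cfg)
  pk <- generate_peaks_and_counts(gen, cfg)
  expr <- generate_expression(gen$genes, pk$truth, cfg)
  expect_equal(nrow(expr), nrow(gen$genes$genes))
  coupled_a <- unique(na.omit(pk$truth$linked_gene[pk$truth$unique_to == "A"]))
  coupled_b <- unique(na.omit(pk$truth$linked_gene[pk$truth$unique_to == "B"]))
  sig_up <- expr$gene_id[expr$padj < 0.05 & expr$log2fc > 0]
  sig_dn <- expr$gene_id[expr$padj < 0.05 & expr$log2fc < 0]
  expect_setequal(sig_up, coupled_a)
  expect_setequal(sig_dn, coupled_b)

  cfg0 <- test_config(seed = 7, coupled_fraction = 0)
  gen0 <- generate_genome(cfg0)
  pk0 <- generate_peaks_and_counts(gen0, cfg0)
  expr0 <- generate_expression(gen0$genes, pk0$truth, cfg0)
  expect_equal(sum(expr0$padj < 0.05), 0)
})

test_that("flagged log2FCs follow the positive-truncated normal", {
  # 500 flagged genes against the closed-form truncated-normal mean
  genes <- gene_models(data.frame(
    gene_id = paste0("g", 1:500), chrom = "chr1",
    start = seq(0, by = 10000, length.out = 500),
    end = seq(0, by = 10000, length.out = 500) + 5000,
    strand = "+", stringsAsFactors = FALSE))
  truth <- data.frame(peak_id = paste0("pk", 1:500), chrom = "chr1",
                      start = 0, end = 1, unique_to = "A",
                      linked_gene = paste0("g", 1:500),
                      stringsAsFactors = FALSE)
  cfg <- test_config(seed = 8, lfc_mean = 2, lfc_sd = 0.5)
  expr <- generate_expression(genes, truth, cfg)
  a <- (0 - 2) / 0.5
  mu_trunc <- 2 + 0.5 * dnorm(a) / (1 - pnorm(a))
  expect_lt(abs(mean(expr$log2fc) - mu_trunc), 3 * 0.5 / sqrt(500))
})

test_that("H3K27ac covers unique peaks and super-enhancers have >= 3 parts", {
  cfg <- test_config(seed = 9, h3k27ac_fraction = 1)
  gen <- generate_genome(cfg)
  pk <- generate_peaks_and_counts(gen, cfg)
  se <- generate_h3k27ac_and_se(pk$truth, cfg)
  ua <- pk$truth[pk$truth$unique_to == "A", ]
  ua_set <- interval_set(ua$chrom, ua$start, ua$end, name = ua$peak_id)
  hit <- intersect_sets(ua_set, se$h3k27ac)
  expect_setequal(unique(hit$a_name), ua$peak_id)

  expect_equal(nrow(se$super_enhancers), cfg$n_super_enhancers)
  support <- intersect_sets(se$super_enhancers, se$h3k27ac)
  expect_true(all(table(support$a_name) >= 3))
  # each SE is tied to the gene its seed peak is coupled to
  expect_equal(nrow(se$se_genes), cfg$n_super_enhancers)
  expect_true(all(se$se_genes$gene_id %in% ua$linked_gene))

  empty <- generate_h3k27ac_and_se(pk$truth[pk$truth$unique_to == "B", ],
                                   test_config(seed = 9, h3k27ac_fraction = 0,
                                               n_super_enhancers = 0))
  expect_equal(nrow(empty$super_enhancers), 0)
})

test_that("identical seeds give byte-identical written datasets", {
  cfg <- test_config(seed = 10)
  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic_dataset(simulate_dataset(cfg), d1)
  write_synthetic_dataset(simulate_dataset(cfg), d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("impossible placement densities are rejected", {
  expect_error(sim_config(n_chromosomes = 1, chrom_length = 1e5,
                          n_genes = 50), "capacity")
  expect_error(sim_config(n_genes = 10, n_unique_peaks_per_condition = 50,
                          coupled_fraction = 1), "coupled")
})
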