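test_that("enhancers are H3K27ac minus promoters", {
  k27 <- interval_set("chr1", 0, 5000, name = "k1")
  prom <- interval_set("chr1", 2000, 3000)
  enh <- define_enhancers(k27, prom)
  expect_equal(enh$start, c(0, 3000))
  expect_equal(enh$end, c(2000, 5000))

  inside <- define_enhancers(interval_set("chr1", 2100, 2900), prom)
  expect_equal(nrow(inside), 0)

  none <- define_enhancers(k27, interval_set(character(), numeric(), numeric()))
  expect_equal(as.data.frame(none)[c("start", "end")],
               data.frame(start = 0, end = 5000))
  # no enhancer base remains inside a promoter
  expect_equal(nrow(intersect_sets(enh, prom)), 0)
})

test_that("basal-plus-extension domains follow the rule arithmetic", {
  one <- gene_models(data.frame(gene_id = "g", chrom = "chr1",
                                start = 100000, end = 110000, strand = "+",
                                stringsAsFactors = FALSE))
  # region inside the basal domain [95000, 101000)
  a <- associate_regions_to_genes(interval_set("chr1", 96000, 96100,
                                               name = "r1"), one)
  expect_equal(a$gene_id, "g")
  # region 2 Mb away exceeds the 1 Mb extension
  far <- associate_regions_to_genes(interval_set("chr1", 2.2e6, 2.2e6 + 100,
                                                 name = "r2"), one)
  expect_equal(nrow(far), 0)
  # region just inside the downstream extension limit
  near <- associate_regions_to_genes(interval_set("chr1", 1.08e6, 1.08e6 + 100,
                                                  name = "r3"), one)
  expect_equal(near$gene_id, "g")
})

test_that("extension stops at a neighbouring basal domain", {
  two <- gene_models(data.frame(
    gene_id = c("left", "right"), chrom = "chr1",
    start = c(100000, 110000), end = c(105000, 115000), strand = "+",
    stringsAsFactors = FALSE))
  # basal domains: left [95000,101000), right [105000,111000)
  doms <- regulatory_domains(two)
  left <- doms[doms$name == "left", ]
  right <- doms[doms$name == "right", ]
  # left gene may not extend into right's basal domain
  expect_equal(left$end, 105000)
  expect_equal(right$start, 101000)
  # a region in the inter-basal gap [101000,105000) belongs to both
  both <- associate_regions_to_genes(interval_set("chr1", 102000, 102200,
                                                  name = "mid"), two)
  expect_setequal(both$gene_id, c("left", "right"))
  # a region inside left's basal domain belongs to left only
  onlyl <- associate_regions_to_genes(interval_set("chr1", 96000, 96100,
                                                   name = "in_left"), two)
  expect_equal(onlyl$gene_id, "left")
})

test_that("associations are invariant under genome-wide translation", {
  g <- tiny_genes()
  regions <- random_interval_set(60, seed = 33, max_start = 60000)
  base <- associate_regions_to_genes(regions, g)
  shift <- 12345
  g2 <- gene_models(transform(g$genes[c("gene_id", "chrom", "start", "end",
                                        "strand")],
                              start = start + shift, end = end + shift),
                    transform(g$exons[c("gene_id", "start", "end")],
                              start = start + shift, end = end + shift))
  r2 <- interval_set(regions$chrom, regions$start + shift,
                     regions$end + shift, name = regions$name)
  moved <- associate_regions_to_genes(r2, g2)
  o <- function(d) d[order(d$region, d$gene_id), c("region", "gene_id")]
  expect_equal(o(moved), o(base), ignore_attr = TRUE)
})

test_that("super-enhancer hits carry peaks, genes and upregulation flags", {
  g <- gene_models(data.frame(gene_id = "tgt", chrom = "chr1",
                              start = 50000, end = 56000, strand = "+",
                              stringsAsFactors = FALSE))
  ses <- interval_set("chr1", c(48000, 200000), c(60000, 210000),
                      name = c("SE_hit", "SE_empty"))
  peaks <- interval_set("chr1", 52000, 52400, name = "upk")
  expr <- data.frame(gene_id = "tgt", log2fc = 2.5, padj = 0.001,
                     stringsAsFactors = FALSE)
  hits <- overlap_super_enhancers(peaks, ses, g, expr)
  expect_equal(unique(hits$se), "SE_hit")
  expect_equal(hits$peaks, "upk")
  expect_true(hits$upregulated[hits$gene_id == "tgt"])

  # not upregulated when padj fails
  hits2 <- overlap_super_enhancers(peaks, ses, g,
                                   transform(expr, padj = 0.5))
  expect_false(hits2$upregulated[1])

  # catalog override replaces rule-based assignment
  hits3 <- overlap_super_enhancers(peaks, ses, g, expr,
                                   se_gene_override = data.frame(
                                     se = "SE_hit", gene_id = "tgt",
                                     stringsAsFactors = FALSE))
  expect_equal(hits3$gene_id, "tgt")

  none <- overlap_super_enhancers(interval_set("chr2", 0, 100), ses, g, expr)
  expect_equal(nrow(none), 0)
})
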