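# Robust SNPs, LD profiles, genotype-class comparisons, gene annotation.

test_that("robust SNPs are Confirmed AND inside a QTL, inclusive bounds", {
  snps <- toy_snps(10, start = 100L, step = 100L)   # pos 100..1000
  dec <- data.frame(snp_id = snps$snp_id,
                    decision = c("Confirmed", "Confirmed", "Rejected",
                                 "Confirmed", "Tentative", "Confirmed",
                                 "Rejected", "Confirmed", "Confirmed",
                                 "Rejected"),
                    stringsAsFactors = FALSE)
  qtls <- data.frame(qtl_id = "QTL1", chrom = "1",
                     start = 200L, end = 600L, stringsAsFactors = FALSE)
  rb <- robust_snps(dec, qtls, snps)
  # s002 (200, boundary), s004 (400), s006 (600, boundary) qualify;
  # s005 is Tentative, s003 Rejected, s001/s008/s009 outside
  expect_equal(rb$snp_id, c("s002", "s004", "s006"))
  expect_true(all(rb$decision == "Confirmed"))
  expect_true(all(rb$pos >= 200 & rb$pos <= 600))
  # no QTLs -> empty
  expect_equal(nrow(robust_snps(dec, qtls[0, ], snps)), 0L)
  # wald carried over from the association table
  assoc <- data.frame(snp_id = snps$snp_id, wald = seq(0.1, 1, by = 0.1))
  rb2 <- robust_snps(dec, qtls, snps, assoc = assoc)
  expect_equal(rb2$wald, c(0.2, 0.4, 0.6))
})

test_that("LD profile is 1 for duplicates/self and small for independents", {
  set.seed(61)
  G <- toy_genotypes(300, 10, seed = 61)
  G$dosage[, 2] <- G$dosage[, 1]          # duplicate of the anchor
  p <- ld_profile(G, "s001", window_bp = 1e6)
  expect_equal(p$r2[p$snp_id == "s001"], 1, tolerance = 1e-12)
  expect_equal(p$r2[p$snp_id == "s002"], 1, tolerance = 1e-12)
  # independent SNPs rarely exceed r2 = 0.05 at n = 300
  others <- p$r2[!p$snp_id %in% c("s001", "s002")]
  expect_gte(mean(others < 0.05), 0.75)
  # monomorphic companion -> NA
  G$dosage[, 3] <- 2
  p2 <- ld_profile(G, "s001")
  expect_true(is.na(p2$r2[p2$snp_id == "s003"]))
  expect_error(ld_profile(G, "nope"), "not found")
})

test_that("genotype-class comparison calibrates and detects", {
  # same distribution in all classes: mostly ns
  ns_count <- 0L
  for (s in 1:10) {
    set.seed(700 + s)
    d <- rbinom(120, 2, 0.5)
    y <- rnorm(120)
    gt <- genotype_class_test(d, y)
    ns_count <- ns_count + all(gt$pairs$stars[gt$pairs$note == ""] == "ns" |
                                 gt$pairs$p[gt$pairs$note == ""] > 0.05 / 3)
  }
  expect_gte(ns_count, 7L)
  # strong separation: *** for the 0-vs-2 contrast
  set.seed(71)
  d <- rep(c(0, 2), each = 30)
  y <- c(rnorm(30, 0, 1), rnorm(30, 5, 1))
  gt <- genotype_class_test(d, y)
  i <- which(gt$pairs$class_a == 0 & gt$pairs$class_b == 2)
  expect_equal(gt$pairs$stars[i], "***")
  expect_lt(gt$pairs$p[i], 1e-3)
  # identical constants in both classes: undefined test, flagged ns
  d <- rep(c(0, 1), each = 10)
  y <- rep(3, 20)
  gt <- genotype_class_test(d, y)
  expect_true(all(gt$pairs$stars == "ns"))
  expect_match(gt$pairs$note[1], "zero variance")
  # class below minimum size is skipped with a note
  d <- c(rep(0, 15), rep(1, 15), 2)
  y <- rnorm(31)
  gt <- genotype_class_test(d, y)
  small <- gt$pairs$class_b == 2
  expect_true(all(nzchar(gt$pairs$note[small])))
  expect_true(all(is.na(gt$pairs$p[small])))
  # Tukey mode returns adjusted p-values
  set.seed(72)
  d <- rbinom(90, 2, 0.5)
  y <- rnorm(90) + d
  gt <- genotype_class_test(d, y, method = "tukey")
  expect_true(all(is.finite(gt$pairs$p[gt$pairs$note == ""])))
})

test_that("gene annotation requires a contained robust SNP", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "1",
                      start = c(100L, 300L), end = c(200L, 400L),
                      stringsAsFactors = FALSE)
  robust <- data.frame(snp_id = c("r1", "r2", "r3"), chrom = "1",
                       pos = c(150L, 99L, 160L), qtl_id = "QTL1",
                       stringsAsFactors = FALSE)
  ann <- annotate_genes(robust, genes)
  expect_equal(ann$gene_id, "gA")          # gB contains no SNP; 99 < 100
  expect_equal(ann$n_robust_snps, 2L)      # r1 and r3 inside gA
  expect_equal(ann$snp_ids, "r1,r3")
  # boundary inclusive
  robust2 <- data.frame(snp_id = "rb", chrom = "1", pos = 200L,
                        qtl_id = "QTL1", stringsAsFactors = FALSE)
  expect_equal(annotate_genes(robust2, genes)$gene_id, "gA")
  expect_equal(nrow(annotate_genes(robust[0, ], genes)), 0L)
})
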