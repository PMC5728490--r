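toy_records <- function(chrom, pos, strand, umi, unique_flag = TRUE,
                        gene_hits = "gA") {
  data.frame(chrom = chrom, pos = pos, strand = strand, umi = umi,
             unique_flag = unique_flag, gene_hits = gene_hits)
}

test_that("downsampling keeps exact sizes and unbiased proportions", {
  recs <- data.frame(chrom = "chrI", pos = 1:300, strand = "+",
                     umi = "AAAA", unique_flag = TRUE, gene_hits = "gA")
  expect_identical(nrow(downsample_reads(recs, 400)), 300L)
  big <- recs[rep(1:300, 40), ]
  expect_identical(nrow(downsample_reads(big, 4000, seed = 1)), 4000L)
  # a gene holding 30% of reads keeps ~30% after down-sampling
  n <- 100000
  gene <- c(rep("gA", 0.3 * n), rep("gB", 0.7 * n))
  recs2 <- data.frame(chrom = "chrI", pos = seq_len(n), strand = "+",
                      umi = "AAAA", unique_flag = TRUE, gene_hits = gene)
  kept <- downsample_reads(recs2, 40000, seed = 2)
  p_hat <- mean(kept$gene_hits == "gA")
  ci99 <- 2.58 * sqrt(0.3 * 0.7 / 40000)
  expect_lt(abs(p_hat - 0.3), ci99 * 1.5)
})

test_that("UMI position scores count distinct UMIs, bounded by 256", {
  r <- toy_records("chrI", c(10, 10, 10), "+", c("AAAA", "AAAA", "AAAC"))
  sc <- umi_position_score(r)
  expect_identical(sc$score, 2L)
  expect_identical(nrow(umi_position_score(r[0, ])), 0L)
  expect_warning(sc2 <- umi_position_score(
    toy_records("chrI", c(1, 2), "+", c("AAAA", "AAXA"))), "malformed")
  expect_identical(sum(sc2$score), 1L)
  # collector's curve: 1000 uniform UMIs at one position
  set.seed(5)
  umis <- apply(matrix(sample(c("A", "C", "G", "T"), 4000, TRUE), ncol = 4),
                1, paste0, collapse = "")
  sc3 <- umi_position_score(toy_records("chrI", 50, "+", umis))
  expect_lte(sc3$score, 256L)
  expected <- 256 * (1 - (1 - 1 / 256)^1000)   # ~250.6
  expect_equal(sc3$score, expected, tolerance = 10 / expected)
})

test_that("3' windows are strand-oriented and half-open", {
  ann <- data.frame(gene_id = "gA", chrom = "chrI", strand = "+",
                    three_prime_pos = 1000L)
  sc <- data.frame(chrom = "chrI", pos = c(999L, 1250L), strand = "+",
                   score = c(5L, 7L))
  expect_identical(unname(gene_window_counts(sc, ann)), 5)
  # window edges: [600, 1200) on the + strand
  edge <- data.frame(chrom = "chrI", pos = c(599L, 600L, 1199L, 1200L),
                     strand = "+", score = rep(1L, 4))
  expect_identical(unname(gene_window_counts(edge, ann)), 2)
  # empty scores give zero for annotated genes
  expect_identical(unname(gene_window_counts(sc[0, ], ann)), 0)
  # mirror-image - strand gene counts identically to its + strand twin
  ann2 <- data.frame(gene_id = c("plus", "minus"), chrom = "chrI",
                     strand = c("+", "-"),
                     three_prime_pos = c(1000L, 5000L))
  off <- c(-400L, -1L, 0L, 199L)      # 5'->3' offsets inside the + window
  sc_pm <- data.frame(chrom = "chrI",
                      pos = c(1000L + off, 5000L - off),
                      strand = rep(c("+", "-"), each = 4),
                      score = rep(c(2L, 3L, 4L, 5L), 2))
  cts <- gene_window_counts(sc_pm, ann2)
  expect_identical(cts[["plus"]], cts[["minus"]])
  expect_identical(cts[["plus"]], 14)
  # off-strand positions never count
  sc_wrong <- data.frame(chrom = "chrI", pos = 1000L, strand = "-",
                         score = 9L)
  expect_identical(unname(gene_window_counts(sc_wrong, ann)), 0)
})

test_that("ambiguous mass splits by unique counts and is conserved", {
  wc <- c(gA = 30, gB = 10)
  amb <- toy_records("chrI", rep(1:20, 1), "+",
                     replicate(20, paste0(sample(c("A", "C", "G", "T"), 4,
                                                 TRUE), collapse = "")),
                     unique_flag = FALSE, gene_hits = "gA;gB")
  out <- allocate_ambiguous(wc, amb)
  expect_equal(unname(out["gA"]), 45)
  expect_equal(unname(out["gB"]), 15)
  expect_equal(sum(out), sum(wc) + 20)
  # no shared reads: unchanged
  expect_identical(allocate_ambiguous(wc, amb[0, ]), wc)
  # both unique counts zero: equal split
  out0 <- allocate_ambiguous(c(gA = 0, gB = 0), amb[1:10, ])
  expect_equal(unname(out0["gA"]), 5)
  expect_equal(unname(out0["gB"]), 5)
  # three-way sharing is rejected loudly
  bad <- toy_records("chrI", 1, "+", "AAAA", FALSE, "gA;gB;gC")
  expect_error(allocate_ambiguous(wc, bad), "more than two")
})

test_that("mass conservation holds across random ambiguous configurations", {
  set.seed(8)
  for (i in 1:10) {
    wc <- setNames(rpois(4, 50), c("gA", "gB", "gC", "gD"))
    n_amb <- rpois(1, 30) + 1
    pair <- sample(c("gA;gB", "gC;gD", "gB;gC"), n_amb, TRUE)
    amb <- toy_records("chrI", sample(1000, n_amb, TRUE), "+",
                       replicate(n_amb,
                                 paste0(sample(c("A", "C", "G", "T"), 4,
                                               TRUE), collapse = "")),
                       unique_flag = FALSE, gene_hits = pair)
    out <- allocate_ambiguous(wc, amb)
    mass <- nrow(unique(amb[c("chrom", "pos", "strand", "umi",
                              "gene_hits")]))
    expect_equal(sum(out), sum(wc) + mass)
  }
})

test_that("normalization scales to 1e6 and thresholds detection", {
  tb <- normalize_and_threshold(c(gA = 1, gB = 3))
  expect_equal(tb$normalized, c(250000, 750000))
  expect_equal(sum(tb$normalized), 1e6, tolerance = 1e-6)
  one <- normalize_and_threshold(c(gA = 17))
  expect_equal(one$normalized, 1e6)
  low <- normalize_and_threshold(setNames(c(8, 1e6 - 8), c("lo", "hi")))
  expect_false(low$detected[low$gene_id == "lo"])
  expect_true(low$detected[low$gene_id == "hi"])
  expect_error(normalize_and_threshold(c(gA = 0, gB = 0)), "all-zero")
})

test_that("synthetic alignments respect truth proportions and windows", {
  ann <- toy_annotation(2)
  truth <- data.frame(gene_id = ann$gene_id, count = c(3, 1))
  recs <- simulate_alignments(truth, ann, depth = 40000, seed = 1)
  w1 <- table(recs$gene_hits)
  p_hat <- w1[[ann$gene_id[1]]] / 40000
  ci99 <- 2.58 * sqrt(0.75 * 0.25 / 40000)
  expect_lt(abs(p_hat - 0.75), ci99)
  # every read lies inside its gene's strand-oriented window
  cts <- gene_window_counts(umi_position_score(recs), ann)
  expect_identical(sum(recs$unique_flag), nrow(recs))
  expect_gt(min(cts), 0)
  # zero-truth gene receives no reads
  truth0 <- data.frame(gene_id = ann$gene_id, count = c(5, 0))
  recs0 <- simulate_alignments(truth0, ann, depth = 5000, seed = 2)
  expect_false(ann$gene_id[2] %in% recs0$gene_hits)
  # unannotated truth gene is rejected
  expect_error(simulate_alignments(
    data.frame(gene_id = "ghost", count = 1), ann, depth = 10),
    "without 3' annotation")
})

test_that("end-to-end: normalized counts recover truth proportions", {
  n_genes <- 60
  ann <- toy_annotation(n_genes)
  set.seed(3)
  truth <- data.frame(gene_id = ann$gene_id,
                      count = rgamma(n_genes, shape = 0.8, rate = 1e-3))
  recs <- simulate_alignments(truth, ann, depth = 400000,
                              shared_frac = 0.05, seed = 4)
  tb <- count_pipeline(recs, ann, depth = 400000, seed = 5)
  rho <- cor(tb$normalized[match(truth$gene_id, tb$gene_id)], truth$count,
             method = "spearman")
  expect_gte(rho, 0.95)
  expect_equal(sum(tb$normalized), 1e6, tolerance = 1e-6)
})
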