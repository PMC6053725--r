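reads_dt <- function(starts, ends, chrom = "chr1")
  data.table::data.table(chrom = chrom, start = starts, end = ends)

test_that("count_reads uses >= 1 bp overlap on half-open intervals", {
  seg <- iv(50, 100)
  expect_equal(count_reads(reads_dt(10, 60), seg, "chr1"), 1)   # 10 bp in
  expect_equal(count_reads(reads_dt(10, 50), seg, "chr1"), 0)   # abutting
  expect_equal(count_reads(reads_dt(100, 150), seg, "chr1"), 0) # abutting
  r <- reads_dt(c(55, 60, 70, 40), c(65, 70, 80, 55))
  expect_equal(count_reads(r, seg, "chr1"), 4)  # 3 inside + 1 spanning edge
  expect_equal(count_reads(r, seg, "chrX"), 0)  # absent chromosome
  u <- rbind(iv(0, 10), iv(20, 30))
  expect_equal(count_reads(reads_dt(5, 25), u, "chr1"), 1)  # union: once
})

test_that("count_reads and count_segment_matrix match a brute-force scan", {
  set.seed(99)
  for (rep in 1:8) {
    starts <- sample(0:2000, 400, replace = TRUE)
    reads <- reads_dt(starts, starts + sample(20:80, 400, replace = TRUE),
                      chrom = sample(c("chr1", "chr2"), 400, replace = TRUE))
    genes <- list()
    for (k in 1:4) {
      s <- sample(0:1800, 1)
      genes[[paste0("g", k)]] <- make_gene(
        list(iv(s, s + 150), iv(s + 250, s + 400)),
        gene_id = paste0("g", k),
        chrom = sample(c("chr1", "chr2"), 1))
    }
    segs <- extract_all_segments(genes, c(chr1 = 5000, chr2 = 5000))
    got <- epideg:::count_segment_matrix(reads, segs)
    for (i in seq_len(nrow(got))) {
      ss <- segs[[got$gene_id[i]]]
      want <- oracle_count(reads, ss[[got$kind[i]]], attr(ss, "chrom"))
      expect_equal(got$n[i], want,
                   label = paste("seg", got$gene_id[i], got$kind[i]))
      expect_equal(
        count_reads(reads, ss[[got$kind[i]]], attr(ss, "chrom")), want)
    }
  }
})

test_that("normalize_density is RPKM-style and scale-invariant", {
  expect_equal(normalize_density(100, 1000, 1e6), 100)
  expect_equal(normalize_density(0, 500, 1e6), 0)
  expect_equal(normalize_density(40, 2000, 2e7),
               normalize_density(80, 2000, 4e7))
  expect_true(is.na(normalize_density(5, 0, 1e6)))
  expect_error(normalize_density(5, 100, 0), "positive")
})

test_that("diff_metric follows the scaled-difference formula and bounds", {
  expect_equal(diff_metric(1, 3), 1.0)
  expect_equal(diff_metric(5, 5), 0.0)
  expect_equal(diff_metric(0, 5), 2.0)
  expect_equal(diff_metric(5, 0), -2.0)
  expect_equal(diff_metric(0, 0), 0.0)
  expect_error(diff_metric(-1, 2), "nonnegative")
  set.seed(7)
  a <- rexp(500); b <- rexp(500)
  d <- diff_metric(a, b)
  expect_true(all(d >= -2 & d <= 2))
  expect_equal(sign(d), sign(log2fc(a, b)))  # both inputs positive
})

test_that("log2fc handles pseudocount and zeros", {
  expect_equal(log2fc(2, 8, pseudocount = 1e-12), 2, tolerance = 1e-9)
  expect_equal(log2fc(3, 3), 0)
  expect_equal(log2fc(0, 0), 0)
  expect_error(log2fc(1, 2, pseudocount = 0), "pseudocount")
})

test_that("feature names concatenate genotype, mark, quantity, segment", {
  expect_equal(build_feature_name("C", "K9", "A", "UTR5"), "CK9A_UTR5")
  expect_equal(build_feature_name("C", "K9", "log2FC", "UTR5"),
               "CK9log2FC_UTR5")
  expect_equal(build_feature_name("e", "K23", "C", "full_gene"),
               "eK23C_full_gene")
  expect_error(build_feature_name("Z", "K9", "A", "UTR5"), "vocabulary")
})

test_that("segment feature matrix has the full combinatorial schema", {
  genes <- list(g1 = make_gene(list(iv(5000, 5600)), gene_id = "g1"))
  segs <- extract_all_segments(genes, c(chr1 = 20000))
  empty <- data.table::data.table(chrom = character(0), start = numeric(0),
                                  end = numeric(0))
  vocab <- default_vocabulary()
  tracks <- list()
  for (g in vocab$genotypes) for (mk in vocab$marks)
    for (cond in vocab$conditions)
      tracks[[paste(g, mk, cond, sep = ".")]] <-
        list(reads = empty, total_reads = 1e6)
  mat <- build_segment_feature_matrix(tracks, segs, vocab)
  expect_equal(ncol(mat), 2 * 3 * 4 * 16)   # 384 columns
  expect_false(anyDuplicated(colnames(mat)) > 0)

  vocab1 <- default_vocabulary(genotypes = "C", marks = "K9",
                               segments = "full_gene")
  tracks1 <- list(C.K9.A = list(reads = empty, total_reads = 1e6),
                  C.K9.C = list(reads = empty, total_reads = 1e6))
  expect_equal(ncol(build_segment_feature_matrix(tracks1, segs, vocab1)), 4)
})

test_that("densities, diff and log2FC land in the right columns", {
  genes <- list(g1 = make_gene(list(iv(5000, 6000)), gene_id = "g1"))
  segs <- extract_all_segments(genes, c(chr1 = 20000))
  vocab <- default_vocabulary(genotypes = "C", marks = "K9",
                              segments = c("full_gene", "single_intron"))
  air <- list(reads = reads_dt(rep(5100, 10), rep(5150, 10)),
              total_reads = 1e6)
  eth <- list(reads = reads_dt(rep(5100, 30), rep(5150, 30)),
              total_reads = 1e6)
  mat <- build_segment_feature_matrix(list(C.K9.A = air, C.K9.C = eth),
                                      segs, vocab)
  expect_equal(mat["g1", "CK9A_full_gene"], 10 / 1)      # 10 reads / 1 kb
  expect_equal(mat["g1", "CK9C_full_gene"], 30 / 1)
  expect_equal(mat["g1", "CK9diff_full_gene"], 1.0)      # (30-10)/20
  expect_equal(mat["g1", "CK9log2FC_full_gene"],
               log2(30.001 / 10.001))
  # single-exon gene has no intron: missing, not zero
  expect_true(is.na(mat["g1", "CK9A_single_intron"]))
  imp <- impute_missing(mat)
  expect_equal(imp["g1", "CK9A_single_intron"], 0)
  expect_equal(attr(imp, "missingness")[["CK9A_single_intron"]], 1)
})

test_that("row order of the matrix is independent of input gene order", {
  genes <- list(g2 = make_gene(list(iv(9000, 9400)), gene_id = "g2"),
                g1 = make_gene(list(iv(5000, 5600)), gene_id = "g1"))
  segs_a <- extract_all_segments(genes, c(chr1 = 20000))
  segs_b <- extract_all_segments(rev(genes), c(chr1 = 20000))
  vocab <- default_vocabulary(genotypes = "C", marks = "K9",
                              segments = "full_gene")
  tr <- list(C.K9.A = list(reads = reads_dt(5100, 5200), total_reads = 1e6),
             C.K9.C = list(reads = reads_dt(9100, 9200), total_reads = 1e6))
  ma <- build_segment_feature_matrix(tr, segs_a, vocab)
  mb <- build_segment_feature_matrix(tr, segs_b, vocab)
  expect_identical(ma, mb)
})
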