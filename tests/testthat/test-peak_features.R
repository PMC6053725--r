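peak_dt <- function(starts, ends, chrom = "chr1", fe = 5)
  data.table::data.table(chrom = chrom, start = starts, end = ends,
                         fold_enrichment = fe)

two_genes <- function() list(
  gA = make_gene(list(iv(10000, 12000)), gene_id = "gA"),
  gB = make_gene(list(iv(20000, 21000)), gene_id = "gB"))

test_that("peaks assign to the nearest gene within 5 kb", {
  genes <- two_genes()
  a <- assign_peaks_to_genes(peak_dt(10500, 11000), genes)
  expect_equal(a$gene_id, "gA")
  expect_equal(a$distance, 0)          # overlapping
  # 6 kb away from the only gene in range: unassigned
  a2 <- assign_peaks_to_genes(peak_dt(3000, 4000), genes["gA"])
  expect_equal(nrow(a2), 0)
  expect_equal(attr(a2, "n_unassigned"), 1)
  # two genes at 1 kb and 3 kb: nearest wins
  a3 <- assign_peaks_to_genes(peak_dt(13000, 17000), genes)
  expect_equal(a3$gene_id, "gA")       # gap 1000 vs 3000
  expect_equal(a3$distance, 1000)
  # equidistant tie: lexicographically smallest id
  a4 <- assign_peaks_to_genes(peak_dt(15900, 16100), genes)
  expect_equal(a4$distance, 3900)
  expect_equal(a4$gene_id, "gA")
})

test_that("nearest-gene assignment matches a brute-force scan", {
  set.seed(31)
  for (rep in 1:6) {
    genes <- list()
    for (k in 1:6) {
      s <- sample(seq(0, 80000, by = 9000), 1) + sample(0:500, 1)
      id <- paste0("g", k)
      genes[[id]] <- make_gene(list(iv(s, s + sample(500:2000, 1))),
                               gene_id = id,
                               chrom = sample(c("chr1", "chr2"), 1))
    }
    starts <- sample(0:90000, 30)
    peaks <- peak_dt(starts, starts + sample(150:800, 30, replace = TRUE),
                     chrom = sample(c("chr1", "chr2"), 30, replace = TRUE))
    got <- assign_peaks_to_genes(peaks, genes)
    gene_tab <- data.table::data.table(
      chrom = vapply(genes, `[[`, character(1), "chrom"),
      start = vapply(genes, function(g) g$exons[1, 1], numeric(1)),
      end = vapply(genes, function(g) g$exons[nrow(g$exons), 2], numeric(1)),
      gene_id = names(genes))
    for (i in seq_len(nrow(peaks))) {
      want <- oracle_nearest(peaks[i], gene_tab, 5000)
      hit <- got[got$start == peaks$start[i] & got$chrom == peaks$chrom[i], ]
      if (is.null(want)) {
        expect_equal(nrow(hit), 0, label = paste("peak", i, "unassigned"))
      } else {
        expect_equal(hit$gene_id, want$gene_id, label = paste("peak", i))
        expect_equal(hit$distance, want$distance)
      }
    }
  }
})

test_that("peak aggregates are arithmetic means with the track suffix", {
  genes <- two_genes()
  pk <- peak_dt(c(10500, 14000), c(10700, 14600), fe = c(4, 8))
  asg <- assign_peaks_to_genes(pk, genes)
  feats <- peak_gene_features(asg, "CK9A", c("gA", "gB"))
  expect_equal(colnames(feats), c("numberpeaks_CK9A", "avg_peaksize_CK9A",
                                  "avg_FE_CK9A", "avg_distance_CK9A"))
  expect_equal(unname(feats["gA", ]), c(2, 400, 6, 1000))  # means
  expect_true(all(is.na(feats["gB", ])))                   # no peaks
  one <- peak_gene_features(
    assign_peaks_to_genes(peak_dt(10500, 10900, fe = 5), genes),
    "CK9A", c("gA"))
  expect_equal(unname(one["gA", ]), c(1, 400, 5, 0))
})

test_that("m_value is the log2 treated/control ratio", {
  expect_equal(m_value(4, 1), 2)
  expect_equal(m_value(7, 7), 0)
  expect_equal(m_value(1, 2), -1)
  expect_error(m_value(0, 1), "positive")
})

test_that("median-M normalization is exact and invertible", {
  balanced <- data.table::data.table(
    chrom = "chr1", start = (1:5) * 1000, end = (1:5) * 1000 + 300,
    count_air = c(100, 50, 80, 120, 60),
    count_eth = c(100, 50, 80, 120, 60))
  n1 <- normalize_densities(balanced)
  expect_equal(n1$factor, 1)
  expect_equal(n1$median_M, 0)

  doubled <- data.table::copy(balanced)
  doubled$count_eth <- doubled$count_eth * 2
  n2 <- normalize_densities(doubled)
  expect_equal(n2$factor, 0.5, tolerance = 5e-3)  # pseudocount-perturbed
  expect_equal(n2$median_M, 0)

  set.seed(5)
  mixed <- data.table::copy(balanced)
  mixed$count_eth <- round(mixed$count_eth * 2^runif(5, -1, 2))
  pc <- 0.5
  m_raw <- log2((mixed$count_eth + pc) / (mixed$count_air + pc))
  n3 <- normalize_densities(mixed)
  expect_equal(n3$factor, 2^(-median(m_raw)))     # closed form
  expect_equal(n3$median_M, 0)                    # exact
  expect_warning(normalize_densities(balanced[0]), "no common peaks")
})

test_that("differential peaks respect the M and p thresholds", {
  common <- data.table::data.table(
    chrom = "chr1", start = (1:5) * 1000, end = (1:5) * 1000 + 300,
    count_air = c(100, 100, 50, 80, 4),
    count_eth = c(100, 200, 50, 80, 5))
  norm <- normalize_densities(common)
  dp <- call_differential_peaks(norm)
  # (100,100): M = 0 -> rejected; (200,100): M ~ 1, binomial p << 0.05 ->
  # retained; (5,4): M ~ 0.29 < 0.4 -> rejected regardless of p
  expect_equal(dp$count_eth, 200)
  expect_true(abs(dp$M) >= 0.4 && dp$p_value <= 0.05)
  expect_equal(dp$fold_enrichment, 2^dp$M)
  # monotone: raising the M threshold never adds peaks
  for (thr in c(0.2, 0.4, 0.8, 1.2)) {
    lo <- nrow(call_differential_peaks(norm, m_threshold = thr))
    hi <- nrow(call_differential_peaks(norm, m_threshold = thr + 0.2))
    expect_gte(lo, hi)
  }
})

test_that("pair_common_peaks pairs overlapping intervals across conditions", {
  air <- peak_dt(c(1000, 5000), c(1400, 5400))
  air$count <- c(10, 20)
  eth <- peak_dt(c(1200, 9000), c(1600, 9400))
  eth$count <- c(30, 40)
  common <- pair_common_peaks(air, eth)
  expect_equal(nrow(common), 1)                 # only the overlapping pair
  expect_equal(common$start, 1000)              # union interval
  expect_equal(common$end, 1600)
  expect_equal(common$count_air, 10)
  expect_equal(common$count_eth, 30)
})

test_that("differential peak features average the M-derived enrichment", {
  genes <- two_genes()
  dp <- data.table::data.table(
    chrom = "chr1", start = c(10100, 11000), end = c(10500, 11400),
    M = c(1, 2), fold_enrichment = 2^c(1, 2))
  feats <- differential_peak_gene_features(dp, genes, "CK9diff",
                                           c("gA", "gB"))
  expect_equal(feats["gA", "avg_FE_CK9diff"], 3)   # mean of 2^M = (2+4)/2
  expect_equal(feats["gA", "numberpeaks_CK9diff"], 2)
  expect_true(all(is.na(feats["gB", ])))           # no differential peaks
})
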