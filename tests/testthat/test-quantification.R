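test_that("in-peak counting uses fragment overlap and normalizes per 10M", {
  peaks <- GRanges("c", IRanges(101, 300))           # [100, 300) 0-based
  # + strand tag at 0-based position 100 extends over the whole peak
  tg <- TagSet(GRanges("c", IRanges(101, width = 1), strand = "+"), "s")
  ct <- count_in_peaks(tg, peaks, extend_to = 200)
  expect_equal(ct$raw_count, 1L)
  expect_equal(ct$normalized_count, 1e7)
  # a tag whose fragment ends before the peak does not count
  tg2 <- TagSet(GRanges("c", IRanges(5000, width = 1), strand = "-"), "s")
  expect_equal(count_in_peaks(tg2, peaks)$raw_count, 0L)
  # empty tag set -> zero counts
  e <- TagSet(GRanges(), "e")
  expect_equal(count_in_peaks(e, peaks)$raw_count, 0L)
})

test_that("counts match the all-pairs brute-force oracle", {
  set.seed(30)
  for (k in 1:5) {
    peaks <- random_intervals(15, max_pos = 3000)
    gr <- GRanges("chrA", IRanges(sample.int(3000, 80, TRUE), width = 1),
                  strand = sample(c("+", "-"), 80, TRUE))
    tg <- TagSet(gr, "s")
    expect_identical(count_in_peaks(tg, peaks, 150)$raw_count,
                     oracle_count_in_peaks(tg, peaks, 150))
  }
})

test_that("normalization is invariant to library duplication", {
  w <- small_world()
  ip <- simulate_tags(w, "ip")
  dup <- TagSet(sort(c(ip$tags, ip$tags)), "dup")
  peaks <- granges(w$sites)
  expect_equal(count_in_peaks(ip, peaks)$normalized_count,
               count_in_peaks(dup, peaks)$normalized_count)
  p1 <- composite_profile(ip, peaks, flank = 1000, bin = 50)
  p2 <- composite_profile(dup, peaks, flank = 1000, bin = 50)
  expect_equal(p1$composite, p2$composite)
})

test_that("knockdown fold changes apply the combined-count filter", {
  peaks <- GRanges("c", IRanges(c(101, 1001), width = 200))
  mk <- function(n1, n2, id) {
    pos <- c(rep(150, n1), rep(1050, n2))
    TagSet(GRanges("c", IRanges(pos, width = 1), strand = "+"), id)
  }
  ctrl <- mk(40, 10, "ctrl")
  kd <- mk(30, 10, "kd")
  tab <- knockdown_foldchange(ctrl, kd, peaks, min_tags = 50)
  # peak 2 has 10 + 10 = 20 < 50 combined tags -> excluded
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$start, 100L)
  # identical samples give fold change exactly 1
  same <- knockdown_foldchange(ctrl, ctrl, peaks, min_tags = 10)
  expect_true(all(same$fold_change == 1))
  # raising min_tags never adds a peak
  t70 <- knockdown_foldchange(ctrl, kd, peaks, min_tags = 70)
  expect_true(all(t70$start %in% tab$start))
  expect_warning(knockdown_foldchange(ctrl, kd, peaks, min_tags = 1e6),
                 "excluded")
})

test_that("rank-sum test reproduces exact enumeration and handles edges", {
  expect_equal(ranksum_test(c(1, 2), c(3, 4))$p.value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(ranksum_test(c(1, 2), c(3, 4))$p.value,
               oracle_ranksum_exact(c(1, 2), c(3, 4)), tolerance = 1e-12)
  # identical multisets -> p = 1
  expect_equal(ranksum_test(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_error(ranksum_test(numeric(0), 1), "non-empty")
  # approximation close to exact at n = 10 + 10
  set.seed(31)
  dd <- replicate(50, {
    a <- rnorm(10); b <- rnorm(10, 0.5)
    abs(stats::wilcox.test(a, b, exact = TRUE)$p.value -
          stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  })
  expect_lt(mean(dd), 0.01)
  expect_lt(max(dd), 0.03)
})

test_that("signed-rank test drops zeros and matches enumeration", {
  expect_equal(signedrank_test(c(1, -1))$p.value, 1)
  expect_equal(signedrank_test(c(1, 2, 3))$p.value, 1 / 4,
               tolerance = 1e-12)
  expect_equal(signedrank_test(c(1, 2, 3))$p.value,
               oracle_signedrank_exact(c(1, 2, 3)), tolerance = 1e-12)
  expect_equal(signedrank_test(c(0, 0, 1, 2, 3))$p.value, 1 / 4,
               tolerance = 1e-12)
  expect_error(signedrank_test(c(0, 0)), "zero")
  set.seed(32)
  dd <- replicate(50, {
    d <- rnorm(15, 0.3)
    abs(stats::wilcox.test(d, exact = TRUE)$p.value -
          stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value)
  })
  expect_lt(mean(dd), 0.01)
  expect_lt(max(dd), 0.03)
})

test_that("composite profiles place mass where fragments lie", {
  anchors <- GRanges("c", IRanges(10001, 10200))   # center0 = 10100
  tg <- TagSet(GRanges("c", IRanges(10101, width = 1), strand = "+"), "s")
  pm <- composite_profile(tg, anchors, flank = 1000, bin = 10,
                          extend_to = 200)
  nonzero <- pm$positions[pm$composite > 0]
  expect_true(all(nonzero >= 0 & nonzero < 200))
  expect_error(composite_profile(tg, anchors, flank = 1001, bin = 10),
               "divisible")
  # symmetric simulated enrichment gives a symmetric composite
  w <- small_world()
  ip <- simulate_tags(w, "ip")
  pms <- composite_profile(ip, w$sites, flank = 1000, bin = 20)
  y <- pms$composite
  asym <- sum(abs(y - rev(y))) / sum(y)
  expect_lt(asym, 0.1)
  # heatmap order sorts decreasing row intensity
  o <- profile_order(pms)
  expect_true(all(diff(rowSums(pms$matrix)[o]) <= 1e-9))
})

test_that("peak density histograms conserve counts and see clustering", {
  w <- small_world()
  g <- w$genome
  one <- GRanges("chrA", IRanges(101, 300))
  h1 <- peak_density_histogram(one, g, bin = 50000)
  expect_equal(sum(h1$count), 1)
  set.seed(33)
  pk <- GRanges("chrA", IRanges(sample.int(290000, 200), width = 100))
  h <- peak_density_histogram(pk, g, bin = 50000)
  expect_equal(sum(h$count), 200)
  # per-class histograms partition the total
  cls <- sample(c("class1", "class2"), 200, TRUE)
  hc <- peak_density_histogram(pk, g, bin = 50000, classes = cls)
  expect_equal(sum(hc$count), 200)
  expect_equal(sort(unique(hc$class)), c("class1", "class2"))
  # sites concentrated on chrA leave chrB bins near-empty
  hA <- h[h$chrom == "chrA", ]; hB <- h[h$chrom == "chrB", ]
  expect_gt(mean(hA$count), mean(hB$count))
})

test_that("gene-body metaprofiles rescale bodies to fixed bins", {
  w <- small_world()
  ip <- simulate_tags(w, "ip")
  gb <- gene_body_profile(ip, w$genes[1:20], flank = 500, flank_bins = 10,
                          body_bins = 30)
  expect_equal(dim(gb$matrix), c(20, 50))
  expect_false(any(is.na(gb$matrix)))
  expect_equal(table(gb$bin_type)[["body"]], 30)
})
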