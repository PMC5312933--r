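test_that("cofactor combinations follow the overlap definition", {
  # peak [100,300) overlapping all three core references -> gypsy-like
  pk <- GRanges("c", IRanges(101, 300))
  ref1 <- GRanges("c", IRanges(251, 400))
  refs <- list("Su(Hw)" = ref1, "Mod(mdg4)" = ref1, "CP190" = ref1)
  cc <- cofactor_combinations(pk, refs, min_group_size = 1)
  expect_equal(cc$labels$combination, "Su(Hw);Mod(mdg4);CP190")
  expect_true(cc$labels$gypsy_like)
  # no overlap -> empty combination, not gypsy-like
  far <- GRanges("c", IRanges(10000, 10100))
  cc2 <- cofactor_combinations(far, refs)
  expect_equal(cc2$labels$combination, "none")
  expect_false(cc2$labels$gypsy_like)
  expect_error(cofactor_combinations(pk, list(GRanges())), "named")
})

test_that("combination labels match the all-pairs oracle and conserve counts", {
  set.seed(20)
  for (k in 1:5) {
    peaks <- random_intervals(40, max_pos = 5000)
    refs <- lapply(setNames(1:5, c("Su(Hw)", "Mod(mdg4)", "CP190", "CTCF",
                                   "BEAF-32")), function(i)
      random_intervals(sample(3:15, 1), max_pos = 5000))
    cc <- cofactor_combinations(peaks, refs)
    expect_identical(cc$labels$combination, oracle_combination(peaks, refs))
    # Venn conservation: group cardinalities sum to the peak count
    expect_equal(sum(cc$table$n), length(peaks))
    # gypsy-like implies the core subset
    has_core <- grepl("Su\\(Hw\\)", cc$labels$combination) &
      grepl("Mod\\(mdg4\\)", cc$labels$combination) &
      grepl("CP190", cc$labels$combination)
    expect_identical(cc$labels$gypsy_like, unname(has_core))
  }
})

test_that("group-size display filter flags but retains small groups", {
  pk <- GRanges("c", IRanges(seq(1, 2000, by = 100), width = 50))
  refs <- list("Su(Hw)" = GRanges("c", IRanges(1, 550)))
  cc <- cofactor_combinations(pk, refs, min_group_size = 11)
  expect_equal(sum(cc$table$n), length(pk))
  small <- cc$table[cc$table$combination == "Su(Hw)", ]
  expect_false(small$displayed)   # 6 members < 11
  expect_true(cc$table$displayed[cc$table$combination == "none"])
})

test_that("HP1a adjacency classification follows the window rule", {
  dom <- GRanges("c", IRanges(10001, 20000))
  # center 200 bp outside the edge -> class1
  p1 <- GRanges("c", IRanges(20101, 20300))
  # center far away -> class2
  p2 <- GRanges("c", IRanges(70001, 70200))
  # overlapping the domain -> class1
  p3 <- GRanges("c", IRanges(9950, 10149))
  cls <- classify_hp1a_adjacency(c(p1, p2, p3), dom, 1000)
  expect_equal(as.character(cls), c("class1", "class2", "class1"))
  # partition property
  expect_true(all(!is.na(cls)))
  # monotonicity: widening the window never moves class1 -> class2
  for (win in c(200, 500, 2000, 5000)) {
    cls_w <- classify_hp1a_adjacency(c(p1, p2, p3), dom, win)
    expect_true(all(!(cls == "class1" & cls_w == "class2") | win < 1000))
  }
  expect_error(classify_hp1a_adjacency(
    p1, GRanges("c", IRanges(c(1, 50), c(100, 150)))), "overlap")
})

test_that("border offsets are signed distances to the nearest edge", {
  # domain [2000, 9000) in 0-based half-open coordinates
  dom <- GRanges("c", IRanges(2001, 9000))
  pk_out <- GRanges("c", IRanges(1401, 1600))   # center 1500 -> +500
  pk_in <- GRanges("c", IRanges(2401, 2600))    # center 2500 -> -500
  expect_equal(border_offset(c(pk_out, pk_in), dom), c(500, -500))
  expect_true(is.na(border_offset(GRanges("other", IRanges(1, 10)), dom)))
  # random configurations match a brute-force minimum over all edges
  set.seed(21)
  doms <- reduce(random_intervals(5, max_pos = 20000,
                                  width_range = c(500, 3000)))
  pks <- random_intervals(30, max_pos = 20000)
  off <- border_offset(pks, doms)
  for (i in seq_along(pks)) {
    ctr <- (start(pks)[i] + end(pks)[i] - 1) / 2
    edges <- c(start(doms) - 1, end(doms))
    d <- min(abs(ctr - edges))
    inside <- any(start(doms) - 1 < ctr & ctr < end(doms))
    expect_equal(off[i], if (inside) -d else d)
  }
})

test_that("motif scanning finds planted instances and matches the oracle", {
  w <- small_world()
  spec <- w$spec
  ins <- w$sites[w$sites$site_class != "border"]
  sm <- scan_motif(ins, w$sequence, spec$motif)
  expect_equal(sm$fraction, 1)    # consensus planted at every center
  # strand symmetry: the reverse complement of a planted peak still hits
  rc <- Biostrings::reverseComplement(
    subseq(w$sequence[[as.character(seqnames(ins))[1]]],
           start(ins)[1], end(ins)[1]))
  one <- DNAStringSet(setNames(list(rc), "rcpeak"))
  hit_rc <- scan_motif(GRanges("rcpeak", IRanges(1, width(ins)[1])),
                       one, spec$motif)
  expect_true(hit_rc$hit)
  # random sequences agree with the per-offset brute-force oracle
  set.seed(22)
  seqs <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""), "")
  pwm_small <- consensus_pwm("ACGTAC")
  dss <- DNAStringSet(setNames(seqs, paste0("s", 1:30)))
  got <- scan_motif(GRanges(names(dss), IRanges(1, 60)), dss, pwm_small,
                    score_fraction = 0.75)$hit
  want <- vapply(seqs, oracle_pwm_hit, logical(1), pw = pwm_small,
                 score_fraction = 0.75)
  expect_identical(unname(got), unname(want))
  expect_error(scan_motif(GRanges("s1", IRanges(1, 100)), dss, pwm_small),
               "bounds")
})

test_that("classify_peaks assembles a coherent per-peak table", {
  w <- small_world()
  cls <- classify_peaks(granges(w$sites), w$cofactor_refs, w$domains,
                        w$sequence, w$spec$motif)
  df <- cls$peaks
  expect_equal(nrow(df), length(w$sites))
  expect_true(all(df$hp1a_class %in% c("class1", "class2")))
  # planted truth recovered from truth domains
  truth_border <- w$sites$site_class == "border"
  expect_true(all(df$hp1a_class[truth_border] == "class1"))
  expect_true(all(df$hp1a_class[!truth_border] == "class2"))
  expect_identical(unname(df$gypsy_like),
                   unname(w$sites$site_class == "gypsy_like"))
})
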