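test_that("world generation is deterministic and truth-consistent", {
  spec <- small_spec()
  w1 <- build_world(spec)
  w2 <- build_world(spec)
  expect_identical(as.character(w1$sites), as.character(w2$sites))
  expect_identical(w1$sites$cofactors, w2$sites$cofactors)
  expect_identical(as.character(w1$sequence), as.character(w2$sequence))
  expect_identical(as.character(w1$genes), as.character(w2$genes))

  w <- small_world()
  # every feature lies within the genome
  lens <- GenomeInfoDb::seqlengths(w$genome)
  for (gr in list(w$sites, w$domains, w$genes)) {
    expect_true(all(start(gr) >= 1))
    expect_true(all(end(gr) <= lens[as.character(seqnames(gr))]))
  }
  # planted-truth consistency: every gypsy-like site in all three core
  # references, no border site in any of them
  core <- c("Su(Hw)", "Mod(mdg4)", "CP190")
  gl <- w$sites[w$sites$site_class == "gypsy_like"]
  bd <- w$sites[w$sites$site_class == "border"]
  for (nm in core) {
    expect_true(all(oracle_overlaps_any(gl, w$cofactor_refs[[nm]])))
    expect_false(any(oracle_overlaps_any(bd, w$cofactor_refs[[nm]])))
  }
  # border sites lie within 500 bp of a domain edge and near a TSS
  off <- border_offset(bd, w$domains)
  expect_true(all(off > 0 & off <= 500))
  dtss <- vapply(seq_along(bd), function(i) {
    g <- w$genes[!is.na(w$genes$bound_site) &
                   w$genes$bound_site == bd$site_id[i]]
    abs((start(bd)[i] + end(bd)[i] - 1) / 2 - g$tss)
  }, numeric(1))
  expect_true(all(dtss <= 500))
})

test_that("cofactor-subset counts follow largest-remainder rounding", {
  expect_identical(largest_remainder(c(a = 0.6, b = 0.4), 50),
                   c(a = 30L, b = 20L))
  expect_identical(largest_remainder(c(a = 1 / 3, b = 1 / 3, c = 1 / 3), 10),
                   c(a = 4L, b = 3L, c = 3L))
  spec <- small_spec(cofactor_fractions = c(
    "Su(Hw);Mod(mdg4);CP190" = 0.6, "BEAF-32" = 0.4))
  w <- build_world(spec, sequence = FALSE)
  ins <- w$sites[w$sites$site_class != "border"]
  expect_equal(sum(ins$cofactors == "Su(Hw);Mod(mdg4);CP190"),
               round(0.6 * spec$n_insulator_sites))
  # recount through the reference BED cardinalities
  expect_equal(length(w$cofactor_refs[["Mod(mdg4)"]]),
               round(0.6 * spec$n_insulator_sites))
})

test_that("tag simulation conserves totals, is deterministic per child seed", {
  w <- small_world()
  for (smp in c("ip", "input", "h3", "hp1a")) {
    ts <- simulate_tags(w, smp)
    expect_equal(ts$library_size, w$spec$n_tags)
  }
  a <- simulate_tags(w, "ip", sample_id = "ip_rep1")
  b <- simulate_tags(w, "ip", sample_id = "ip_rep1")
  c <- simulate_tags(w, "ip", sample_id = "ip_rep2")
  expect_identical(as.character(a$tags), as.character(b$tags))
  expect_false(identical(as.character(a$tags), as.character(c$tags)))
  # zero tags is a valid (empty) sample
  expect_equal(simulate_tags(w, "ip", n_tags = 0)$library_size, 0L)
})

test_that("unenriched IP is distributionally identical to input", {
  spec <- small_spec(enrichment_fold = c(gypsy_like = 1, border = 1,
                                         other = 1), n_tags = 10000)
  w <- build_world(spec, sequence = FALSE)
  ip <- simulate_tags(w, "ip")
  input <- simulate_tags(w, "input")
  ks <- suppressWarnings(stats::ks.test(start(ip$tags), start(input$tags)))
  expect_gt(ks$p.value, 0.01)
})

test_that("knockdown with scaling 1 equals the untreated IP law", {
  w <- small_world()
  a <- simulate_tags(w, "ip", sample_id = "same")
  b <- simulate_tags(w, "ip_knockdown", sample_id = "same",
                     overrides = list(knockdown_scaling = 1))
  expect_identical(as.character(a$tags), as.character(b$tags))
})

test_that("with background off, all site tags stay within one fragment", {
  spec <- simulation_spec(
    genome = bc_genome("chrA", 100000L),
    n_hp1a_domains = 0, n_border_sites = 0, n_insulator_sites = 1,
    cofactor_fractions = c("Su(Hw);Mod(mdg4);CP190" = 1),
    enrichment_fold = c(gypsy_like = 20, border = 20, other = 20),
    background_rate = 0, n_tags = 2000, n_genes = 5, seed = 3)
  w <- build_world(spec, sequence = FALSE)
  ip <- simulate_tags(w, "ip")
  ctr <- (start(w$sites) + end(w$sites) - 1) / 2
  expect_true(all(abs(start(ip$tags) - ctr) <= spec$fragment_length))
})

test_that("repeat count simulation recovers true folds and respects zeros", {
  lib <- data.frame(
    repeat_id = sprintf("R%02d", 1:52),
    length = 4000L, copies = c(rep(10L, 50), 10L, 0L),
    fold = c(rep(1, 50), 4, 2),
    five_prime_enriched = FALSE, stringsAsFactors = FALSE)
  spec <- small_spec(repeat_library = lib, repeat_read_rate = 0.05)
  w <- build_world(spec, sequence = FALSE)
  rc <- simulate_repeat_counts(w)
  # zero copy number -> zero counts
  expect_equal(rc$counts$ip_count[52], 0L)
  expect_equal(rc$counts$input_count[52], 0L)
  # fold-1 repeats: mean log2 ratio ~ 0 within 3 SE over the 50 repeats
  null <- rc$counts[1:50, ]
  lr <- log2(null$ip_count / null$input_count)
  expect_lt(abs(mean(lr)), 3 * stats::sd(lr) / sqrt(50))
  # deep fold-4 repeat recovered near log2fc 2
  expect_equal(log2(rc$counts$ip_count[51] / rc$counts$input_count[51]),
               2, tolerance = 0.15)
  # coverage conserves counts
  expect_equal(sum(rc$coverage$R01$ip), rc$counts$ip_count[1])
})

test_that("expression simulation shifts border-bound genes by -effect", {
  w <- small_world()
  e1 <- simulate_expression(w, effect = 1)
  e2 <- simulate_expression(w, effect = 1)
  expect_identical(e1, e2)
  expect_equal(median(e1$mut_log2fc[e1$border_bound]), -1, tolerance = 0.25)
  expect_equal(median(e1$mut_log2fc[!e1$border_bound]), 0, tolerance = 0.25)
  e0 <- simulate_expression(w, effect = 0)
  expect_equal(median(e0$mut_log2fc[e0$border_bound]), 0, tolerance = 0.25)
  # active genes have higher wild-type levels
  expect_gt(median(e1$wt_level[e1$expression_class == "active"]),
            median(e1$wt_level[e1$expression_class == "inactive"]))
})
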