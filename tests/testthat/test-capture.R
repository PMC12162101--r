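test_that("expand_merge grows, clips and merges intervals", {
  gi <- genomic_intervals(c("chr1", "chr1"), c(1000, 1200), c(1120, 1320))
  m <- expand_merge(gi, 200)
  expect_equal(m$start, 800L)
  expect_equal(m$end, 1520L)

  near0 <- expand_merge(genomic_intervals("chr1", 50, 170), 200)
  expect_equal(near0$start, 0L)
  expect_equal(near0$end, 370L)

  disjoint <- genomic_intervals(c("chr1", "chr2"), c(10, 10), c(20, 20))
  expect_equal(as.data.frame(expand_merge(disjoint, 0))[, c("chrom", "start", "end")],
               as.data.frame(disjoint)[, c("chrom", "start", "end")])

  clipped <- expand_merge(genomic_intervals("chr1", 100, 200), 50,
                          chrom_lengths = c(chr1 = 220L))
  expect_equal(clipped$end, 220L)
})

test_that("expand_merge covers exactly the union of expanded inputs", {
  set.seed(101)
  for (rep in 1:25) {
    extent <- 5000L
    gi <- random_intervals(sample(1:12, 1), extent)
    flank <- sample(c(0L, 10L, 200L), 1)
    m <- expand_merge(gi, flank, chrom_lengths = c(chr1 = extent))
    covered <- rep(FALSE, extent)
    for (i in seq_len(nrow(m))) covered[(m$start[i] + 1):m$end[i]] <- TRUE
    expect_equal(covered, oracle_expand_merge_bases(gi, flank, extent))
    # sorted and disjoint
    if (nrow(m) > 1) expect_true(all(m$start[-1] > m$end[-nrow(m)]))
  }
})

test_that("proximity classification uses the gap-to-nearest rule", {
  probe <- genomic_intervals("chr1", 300, 420)
  expect_true(proximity_mask(data.frame(chrom = "chr1", pos0 = 250),
                             probe, 200)$mask)
  expect_false(proximity_mask(data.frame(chrom = "chr1", pos0 = 49),
                              probe, 200)$mask)  # gap 250
  expect_true(proximity_mask(data.frame(chrom = "chr1", pos0 = 99),
                             probe, 200)$mask)   # gap exactly 200
  expect_false(proximity_mask(genomic_intervals("chr1", 0, 100),
                              genomic_intervals("chr1", 200, 300), 0)$mask)
  # different chromosome never matches
  expect_false(proximity_mask(data.frame(chrom = "chr2", pos0 = 350),
                              probe, 200)$mask)
  expect_error(proximity_mask(probe, probe, tol = -1), "tol")
})

test_that("proximity mask matches a brute-force gap oracle", {
  set.seed(202)
  for (rep in 1:25) {
    extent <- 3000L
    q <- random_intervals(sample(1:15, 1), extent, max_len = 100)
    r <- random_intervals(sample(1:6, 1), extent, max_len = 200)
    tol <- sample(c(0L, 50L, 200L), 1)
    got <- proximity_mask(q, r, tol)$mask
    want <- vapply(seq_len(nrow(q)), function(i)
      oracle_on_target(q$start[i], q$end[i], r, tol), logical(1))
    expect_equal(got, want)
  }
})

test_that("proximity fraction is invariant to query order and reference splits", {
  set.seed(7)
  q <- random_intervals(40, 5000, max_len = 50)
  r <- genomic_intervals("chr1", c(1000, 3000), c(1600, 3800))
  f0 <- proximity_mask(q, r, 100)$summary$fraction_on_target
  perm <- sample(nrow(q))
  qp <- q[perm, , drop = FALSE]
  expect_equal(proximity_mask(qp, r, 100)$summary$fraction_on_target, f0)
  # split a reference interval at an interior point
  r2 <- genomic_intervals("chr1", c(1000, 1300, 3000), c(1300, 1600, 3800))
  expect_equal(proximity_mask(q, r2, 100)$summary$fraction_on_target, f0)
})

test_that("expected CpG counting merges regions before counting", {
  genome <- c(s = "ACGCGT")
  expect_equal(expected_cpg_count(genomic_intervals("s", 0, 6), genome,
                                  flank = 0), 2L)
  # two probes whose expansions cover the same CG count it once
  genome2 <- c(chr1 = paste0(strrep("A", 100), "CG", strrep("T", 100)))
  two <- genomic_intervals(c("chr1", "chr1"), c(90, 104), c(95, 110))
  expect_equal(expected_cpg_count(two, genome2, flank = 20), 1L)
  # empty region set
  expect_equal(expected_cpg_count(empty_intervals(), genome), 0L)
  expect_error(expected_cpg_count(genomic_intervals("chrX", 0, 5), genome),
               "absent")
  # a CG with only its G inside the region is not counted (C-position rule)
  genome3 <- c(c1 = "AACGAA")
  expect_equal(expected_cpg_count(genomic_intervals("c1", 3, 6), genome3,
                                  flank = 0), 0L)
  expect_equal(expected_cpg_count(genomic_intervals("c1", 2, 4), genome3,
                                  flank = 0), 1L)
})

test_that("expected CpG count is bounded by the genome total", {
  ref <- gen_reference(n_chroms = 1, chrom_length = 20000, cpg_rate = 0.02,
                       probes_per_chrom = 15, seed = 5)
  total <- nrow(ref$cpg_sites)
  n <- expected_cpg_count(ref$probes, ref$sequences, flank = 200)
  expect_lte(n, total)
  whole <- genomic_intervals("chr1", 0, ref$chrom_lengths[["chr1"]])
  expect_equal(expected_cpg_count(whole, ref$sequences, flank = 0), total)
})

test_that("base coverage equals the per-base oracle", {
  target <- genomic_intervals("chr1", 0, 1000)
  one <- genomic_intervals("chr1", 0, 100)
  bc <- base_coverage(one, target)
  expect_equal(bc$mean, 0.1)
  expect_equal(base_coverage(empty_intervals(), target)$mean, 0)
  expect_equal(base_coverage(empty_intervals(), target)$median, 0)
  expect_error(base_coverage(one, empty_intervals()), "empty target")

  set.seed(303)
  for (rep in 1:20) {
    extent <- 2000L
    frags <- random_intervals(sample(1:25, 1), extent, max_len = 300)
    target <- expand_merge(random_intervals(sample(1:4, 1), extent), 0)
    got <- base_coverage(frags, target)
    depth <- oracle_base_depth(frags, target, extent)
    expect_equal(got$mean, mean(depth))
    expect_equal(got$median, median(depth))
  }
})

test_that("shores and shelves follow the 2kb/4kb arithmetic with precedence", {
  lab <- derive_shores_shelves(genomic_intervals("chr1", 10000, 10500))
  shores <- lab[lab$label == "shore", ]
  shelves <- lab[lab$label == "shelf", ]
  expect_equal(shores$start, c(8000L, 10500L))
  expect_equal(shores$end, c(10000L, 12500L))
  expect_equal(shelves$start, c(6000L, 12500L))
  expect_equal(shelves$end, c(8000L, 14500L))

  near0 <- derive_shores_shelves(genomic_intervals("chr1", 1000, 1500))
  expect_equal(near0[near0$label == "shore", ]$start[1], 0L)

  set.seed(404)
  for (rep in 1:15) {
    extent <- 30000L
    isl <- expand_merge(random_intervals(sample(1:4, 1), extent,
                                         max_len = 2000), 0)
    lab <- derive_shores_shelves(isl, chrom_lengths = c(chr1 = extent))
    per_base <- rep("none", extent)
    for (i in seq_len(nrow(lab)))
      per_base[(lab$start[i] + 1):lab$end[i]] <- lab$label[i]
    expect_equal(per_base, oracle_shore_shelf_labels(isl, extent))
    # labels partition: no base assigned twice
    expect_equal(sum(lab$end - lab$start),
                 sum(oracle_shore_shelf_labels(isl, extent) != "none"))
  }
})

test_that("promoter derivation is strand-aware", {
  tss <- genomic_intervals(c("chr1", "chr1"), c(5000, 8000), c(5001, 8001),
                           strand = c("+", "-"))
  pr <- promoters_from_tss(tss, upstream = 2000)
  expect_equal(pr$start, c(3000L, 8001L))
  expect_equal(pr$end, c(5000L, 10001L))
})
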