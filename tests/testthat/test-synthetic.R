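test_that("reference generation is deterministic and CpG-exact", {
  a <- gen_reference(n_chroms = 2, chrom_length = 20000, cpg_rate = 0.02,
                     probes_per_chrom = 10, seed = 42)
  b <- gen_reference(n_chroms = 2, chrom_length = 20000, cpg_rate = 0.02,
                     probes_per_chrom = 10, seed = 42)
  expect_identical(as.character(a$sequences), as.character(b$sequences))
  expect_identical(a$cpg_sites, b$cpg_sites)
  expect_identical(a$probes, b$probes)

  # the CpG list is exactly the set of CG occurrences
  for (ch in names(a$chrom_lengths)) {
    s <- as.character(a$sequences[[ch]])
    hits <- gregexpr("CG", s, fixed = TRUE)[[1]]
    found <- if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
    expect_equal(a$cpg_sites$pos0[a$cpg_sites$chrom == ch], found)
  }

  # every probe overlaps at least one CpG
  pm <- proximity_mask(a$probes, sites_gi <- genomic_intervals(
    a$cpg_sites$chrom, a$cpg_sites$pos0, a$cpg_sites$pos0 + 2L), tol = 0)
  expect_true(all(pm$mask))
})

test_that("a zero CpG rate yields a CG-free genome", {
  r <- gen_reference(n_chroms = 1, chrom_length = 5000, cpg_rate = 0,
                     probes_per_chrom = 0, seed = 7)
  expect_equal(nrow(r$cpg_sites), 0L)
  expect_false(grepl("CG", as.character(r$sequences[[1]]), fixed = TRUE))
  expect_error(gen_reference(cpg_rate = 0.5), "cpg_rate")
})

test_that("methylome simulation matches its stated moments", {
  ref <- gen_reference(n_chroms = 1, chrom_length = 2e5, cpg_rate = 0.03,
                       probes_per_chrom = 10, seed = 1)
  sim <- gen_methylome(ref, n_per_group = c(3, 3), mu_cov = 20, n_chh = 0,
                       conv_error = 0, seed = 2)
  cov <- sim$M + sim$U
  expect_true(nrow(sim$M) * ncol(sim$M) > 1e4)
  expect_lt(abs(mean(cov) - 20) / 20, 0.05)
  expect_true(all(sim$M >= 0 & sim$U >= 0))

  # delta = 0: the two group truths are identical
  expect_equal(sim$truth$pi_group0, sim$truth$pi_group1)

  # effect sites carry exactly delta
  sim2 <- gen_methylome(ref, n_per_group = c(2, 2), delta = 0.2,
                        n_effect = 50, n_chh = 0, seed = 3)
  eff <- sim2$truth$effect
  expect_equal(sum(eff), 50L)
  expect_equal(sim2$truth$pi_group1[eff] - sim2$truth$pi_group0[eff],
               rep(0.2, 50))
  expect_error(gen_methylome(ref, delta = 0.5, effect_sites = which.max(
    gen_methylome(ref, n_per_group = c(1, 1), n_chh = 0,
                  seed = 3)$truth$pi_group0), seed = 3), "pi \\+ delta")
})

test_that("conversion error surfaces in CHH records at the planted rate", {
  ref <- gen_reference(n_chroms = 1, chrom_length = 1e5, cpg_rate = 0.02,
                       probes_per_chrom = 5, seed = 1)
  sim <- gen_methylome(ref, n_per_group = c(4, 4), conv_error = 0.005,
                       n_chh = 4000, mu_cov = 20, seed = 8)
  est <- chh_conversion(do.call(rbind, sim$reports))
  expect_equal(est$status, "pass")
  expect_lt(abs(est$percent_chh - 0.5), 0.1)
})

test_that("observed methylation is bimodal with hypo and hyper modes", {
  ref <- gen_reference(n_chroms = 1, chrom_length = 3e5, cpg_rate = 0.02,
                       probes_per_chrom = 10, seed = 1)
  sim <- gen_methylome(ref, n_per_group = c(6, 6), mu_cov = 30, n_chh = 0,
                       seed = 5)
  cm <- count_matrix(sim$sites, sim$M, sim$U, sim$meta)
  mu <- rowMeans(methylation_levels(cm), na.rm = TRUE)
  d <- density(mu[!is.na(mu)], bw = 0.05, from = 0, to = 1)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1
  modes <- d$x[peaks][order(d$y[peaks], decreasing = TRUE)][1:2]
  expect_true(min(modes) < 0.2)
  expect_true(max(modes) > 0.8)
})

test_that("array betas follow the offset formula and its ceiling", {
  m <- seq(0, 1, by = 0.1)
  expect_equal(gen_array_betas(m, alpha_off = 0, noise_sd = 0), m)
  b <- gen_array_betas(m, alpha_off = 100, noise_sd = 0)
  expect_true(all(b < 1))
  expect_equal(b[11], 1000 / 1100)  # fully methylated, compressed by the offset
  expect_identical(gen_array_betas(m, 100, 25, seed = 3),
                   gen_array_betas(m, 100, 25, seed = 3))
  expect_error(gen_array_betas(m, alpha_off = -1), "alpha_off")
})

test_that("fragment mixture respects the on-target probability", {
  # sparse probes on a long genome keep the accidental on-target rate negligible
  ref <- gen_reference(n_chroms = 2, chrom_length = 1e6, cpg_rate = 0.01,
                       probes_per_chrom = 4, seed = 2)
  fr <- gen_fragments(ref$probes, 10000, ref$chrom_lengths,
                      on_target_prob = 0.785, seed = 6)
  frac <- proximity_mask(fr, ref$probes, tol = 200)$summary$fraction_on_target
  ci <- qbinom(c(0.005, 0.995), 10000, 0.785) / 10000
  expect_gte(frac, ci[1])
  # allow the small uniform-placement excess on the upper side
  expect_lte(frac, ci[2] + 0.01)

  all_on <- gen_fragments(ref$probes, 500, ref$chrom_lengths,
                          on_target_prob = 1, seed = 6)
  expect_true(all(proximity_mask(all_on, ref$probes, tol = 200)$mask))
  expect_equal(nrow(gen_fragments(ref$probes, 0, ref$chrom_lengths)), 0L)
  expect_error(gen_fragments(ref$probes[0, ], 10, ref$chrom_lengths), "empty")
})

test_that("in-silico MspI digest cuts, partitions and size-selects", {
  d <- msp1_digest("TTCCGGAACCGGTT", digest_config(size_min = 1, size_max = 99))
  expect_equal(d$fragments$start, c(0L, 3L, 9L))
  expect_equal(d$fragments$end, c(3L, 9L, 14L))
  expect_equal(nrow(d$retained), 3L)

  # default 180-2000 bounds retain nothing from the toy
  dd <- msp1_digest("TTCCGGAACCGGTT")
  expect_equal(nrow(dd$retained), 0L)
  expect_equal(nrow(dd$covered_cpgs), 0L)

  # no motif: a single fragment spanning the sequence
  d1 <- msp1_digest("AAATTTAAA", digest_config(size_min = 1, size_max = 99))
  expect_equal(nrow(d1$fragments), 1L)
  expect_equal(d1$fragments$end, 9L)

  # fragments partition [0, len) for random sequences
  set.seed(21)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
    f <- msp1_digest(s, digest_config(size_min = 1, size_max = 1e6))$fragments
    expect_equal(f$start[1], 0L)
    expect_equal(f$end[nrow(f)], 500L)
    if (nrow(f) > 1) expect_equal(f$start[-1], f$end[-nrow(f)])
  }
})

test_that("digest-covered CpGs are exactly those on retained fragments", {
  set.seed(33)
  s <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  cfg <- digest_config(size_min = 20, size_max = 200)
  d <- msp1_digest(s, cfg)
  hits <- gregexpr("CG", s, fixed = TRUE)[[1]]
  cg <- if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
  manual <- cg[vapply(cg, function(p)
    any(p >= d$retained$start & p < d$retained$end), logical(1))]
  expect_equal(d$covered_cpgs$pos0, manual)
})

test_that("digest config validates its invariants", {
  expect_error(digest_config(motif = ""), "non-empty")
  expect_error(digest_config(cut_offset = 9), "within the motif")
  expect_error(digest_config(size_min = 0), "size_min")
  expect_error(digest_config(size_min = 300, size_max = 200), "size_min")
})
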