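mk_reports <- function() {
  list(
    a = data.frame(chrom = "chr1", pos0 = c(10L, 20L, 30L),
                   M = c(5L, 0L, 2L), U = c(1L, 4L, 2L)),
    b = data.frame(chrom = "chr1", pos0 = c(10L, 30L),
                   M = c(3L, 1L), U = c(3L, 0L)))
}

mk_sheet <- function() data.frame(sample = c("a", "b"),
                                  group = c(0L, 1L),
                                  stringsAsFactors = FALSE)

test_that("matrix assembly takes the site union with zero fill", {
  cm <- assemble_matrix(mk_reports(), mk_sheet())
  expect_equal(dim(cm), c(3L, 2L))
  expect_equal(cm$sites$pos0, c(10L, 20L, 30L))
  expect_equal(unname(cm$M[, "b"]), c(3L, 0L, 1L))
  expect_equal(unname(cm$U[, "b"]), c(3L, 0L, 0L))

  single <- assemble_matrix(mk_reports()["a"], mk_sheet())
  expect_equal(unname(single$M[, 1]), c(5L, 0L, 2L))

  dup <- mk_reports(); names(dup) <- c("a", "a")
  expect_error(assemble_matrix(dup, mk_sheet()), "uniquely named")
  expect_error(assemble_matrix(mk_reports(), data.frame(sample = "a")),
               "cover")
})

test_that("the worked coverage/missingness filter examples hold", {
  sites <- data.frame(chrom = "chr1", pos0 = c(1L, 2L))
  M <- matrix(c(3L, 3L, 3L, 3L, 3L, 0L), 2, 3, byrow = TRUE)
  U <- matrix(c(3L, 3L, 3L, 3L, 3L, 0L), 2, 3, byrow = TRUE)
  meta <- data.frame(sample = c("s1", "s2", "s3"))
  cm <- count_matrix(sites, M, U, meta)  # coverages (6,6,6) and (6,6,0)

  strictish <- filter_matrix(cm, filter_spec(min_cov = 5, min_frac = 0.75))
  expect_equal(strictish$matrix$sites$pos0, 1L)
  expect_equal(strictish$report$n_dropped_coverage, 1L)

  relaxed <- filter_matrix(cm, filter_spec(min_cov = 1, min_frac = 2 / 3))
  expect_equal(relaxed$matrix$sites$pos0, c(1L, 2L))

  empty <- count_matrix(sites[0, ], M[0, , drop = FALSE],
                        U[0, , drop = FALSE], meta)
  expect_equal(filter_matrix(empty)$report$n_kept, 0L)
})

test_that("filtering matches the double-loop oracle over all comparators", {
  set.seed(55)
  for (rep in 1:30) {
    ns <- sample(5:80, 1); nn <- sample(3:12, 1)
    M <- matrix(rpois(ns * nn, 3), ns, nn)
    U <- matrix(rpois(ns * nn, 3), ns, nn)
    cm <- count_matrix(data.frame(chrom = "chr1", pos0 = seq_len(ns)),
                       M, U, data.frame(sample = paste0("s", seq_len(nn))))
    for (cc in c("ge", "gt")) for (fc in c("ge", "gt")) {
      spec <- filter_spec(min_cov = sample(0:8, 1),
                          min_frac = sample(c(0, 0.5, 0.75, 1), 1),
                          cov_cmp = cc, frac_cmp = fc)
      got <- filter_matrix(cm, spec)$matrix
      want <- oracle_filter_keep(M, U, spec$min_cov, spec$min_frac, cc, fc)
      expect_equal(got$sites$pos0, cm$sites$pos0[want])
    }
  }
})

test_that("filtering is idempotent and respects a region target", {
  set.seed(56)
  ns <- 200
  M <- matrix(rpois(ns * 4, 4), ns, 4)
  U <- matrix(rpois(ns * 4, 4), ns, 4)
  cm <- count_matrix(data.frame(chrom = "chr1",
                                pos0 = sort(sample(1:100000, ns))),
                     M, U, data.frame(sample = paste0("s", 1:4)))
  target <- genomic_intervals("chr1", 20000, 60000)
  spec <- filter_spec(min_cov = 5, min_frac = 0.5, target = target, tol = 0)
  once <- filter_matrix(cm, spec)
  twice <- filter_matrix(once$matrix, spec)
  expect_equal(twice$matrix$sites, once$matrix$sites)
  expect_equal(twice$matrix$M, once$matrix$M)
  expect_true(all(once$matrix$sites$pos0 >= 20000 &
                  once$matrix$sites$pos0 < 60000))
  expect_equal(once$report$n_input - once$report$n_dropped_region -
                 once$report$n_dropped_coverage, once$report$n_kept)
})

test_that("methylation levels are M/(M+U) with explicit missingness", {
  cm <- count_matrix(data.frame(chrom = "chr1", pos0 = 1:3),
                     matrix(c(5L, 0L, 4L), 3, 1),
                     matrix(c(3L, 0L, 0L), 3, 1),
                     data.frame(sample = "s1"))
  m <- methylation_levels(cm)
  expect_equal(unname(m[, 1]), c(0.625, NA, 1.0))
})

test_that("levels converge to truth at deep coverage", {
  ref <- gen_reference(n_chroms = 1, chrom_length = 50000, cpg_rate = 0.02,
                       probes_per_chrom = 5, seed = 2)
  sim <- gen_methylome(ref, n_per_group = c(1, 1), mu_cov = 500, disp = 20,
                       conv_error = 0, n_chh = 0, seed = 3)
  cm <- count_matrix(sim$sites, sim$M, sim$U, sim$meta)
  lev <- methylation_levels(cm)
  err <- abs(rowMeans(lev, na.rm = TRUE) - sim$truth$pi_group0)
  expect_lt(mean(err, na.rm = TRUE), 0.02)
})

test_that("site summaries apply strict variable bounds", {
  lev <- rbind(c(0.2, 0.4, NA),
               c(NA, NA, NA),
               c(0.9, 0.9, 0.9),
               c(0.95, 0.95, 0.95))
  ss <- site_summary(lev)
  expect_equal(ss$mean[1], 0.3)
  expect_equal(ss$median[1], 0.3)
  expect_equal(ss$n_observed[1], 2L)
  expect_true(ss$variable[1])
  expect_true(is.na(ss$mean[2]))
  expect_false(ss$variable[2])
  expect_false(ss$variable[3])  # mean exactly 0.9 is not variable
  expect_true(ss$hyper[4])
  expect_false(ss$hypo[4])
  expect_error(site_summary(lev, lo = 0.9, hi = 0.1), "lo < hi")
})

test_that("annotation summaries count multi-label sites in every label", {
  med <- data.frame(chrom = "chr1", pos0 = c(100L, 200L, 5000L, 9000L),
                    median = c(0.1, 0.3, 0.9, 0.5))
  ann <- genomic_intervals(c("chr1", "chr1"), c(50, 4500), c(250, 5500),
                           name = NA)
  ann$label <- c("A", "B")
  s <- annotation_summary(med, ann)
  s <- s[order(s$label), ]
  expect_equal(s$label, c("A", "B", "unannotated"))
  expect_equal(s$n_sites, c(2L, 1L, 1L))
  expect_equal(s$median_meth, c(0.2, 0.9, 0.5))

  # overlapping labels double-count the shared site
  ann2 <- ann; ann2$start <- c(50L, 150L); ann2$end <- c(250L, 260L)
  s2 <- annotation_summary(med, ann2)
  expect_equal(s2$n_sites[s2$label == "B"], 1L)
  expect_equal(s2$n_sites[s2$label == "A"], 2L)

  none <- annotation_summary(med, NULL)
  expect_equal(none$label, "unannotated")
  expect_equal(none$n_sites, 4L)
})

test_that("planted hypo/hyper structure is recovered by annotation summaries", {
  # quiescent-like regions planted hypermethylated, promoter-like hypomethylated
  set.seed(77)
  pos <- sort(sample(1:100000, 400))
  in_prom <- pos < 50000
  pi <- ifelse(in_prom, rbeta(400, 1, 10), rbeta(400, 10, 1))
  cov <- matrix(rpois(400 * 6, 30), 400, 6)
  M <- matrix(rbinom(400 * 6, cov, pi), 400, 6)
  cm <- count_matrix(data.frame(chrom = "chr1", pos0 = pos), M, cov - M,
                     data.frame(sample = paste0("s", 1:6)))
  med <- data.frame(chrom = "chr1", pos0 = pos,
                    median = apply(methylation_levels(cm), 1, median,
                                   na.rm = TRUE))
  ann <- genomic_intervals(c("chr1", "chr1"), c(0, 50000), c(50000, 100000))
  ann$label <- c("promoter_like", "quiescent_like")
  s <- annotation_summary(med, ann)
  expect_lt(s$median_meth[s$label == "promoter_like"], 0.3)
  expect_gt(s$median_meth[s$label == "quiescent_like"], 0.7)
})

test_that("count matrices round-trip through TSV", {
  cm <- assemble_matrix(mk_reports(), mk_sheet())
  prefix <- file.path(withr::local_tempdir(), "cm")
  write_count_matrix(cm, prefix)
  back <- read_count_matrix(prefix)
  expect_equal(back$sites, cm$sites)
  expect_equal(unname(back$M), unname(cm$M))
  expect_equal(unname(back$U), unname(cm$U))
  expect_equal(back$meta$sample, cm$meta$sample)
})
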