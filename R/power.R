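#' Configuration for the coverage-conditioned power simulation
#'
#' Defaults mirror the study grid: 1,000 simulated CpG sites per cell, sample
#' sizes 100/200/400, effect sizes 0-20% methylation difference, coverage
#' multipliers 1/2/4 (the observed ~20x distribution and its 40x/80x
#' scalings), and a nominal per-site significance threshold of 0.001.
#'
#' @param n_sites simulated sites per grid cell.
#' @param sample_sizes total samples per simulation (split into two balanced
#'   groups).
#' @param deltas group methylation differences.
#' @param multipliers integer coverage multipliers.
#' @param a_sig per-site significance threshold.
#' @param baseline `"symmetric"` (p0 = 0.5 - delta/2, so the two groups sit
#'   symmetrically around 50%) or `"fixed"` (p0 = `p0`).
#' @param p0 baseline methylation proportion when `baseline = "fixed"`.
#' @param test per-site test: `"binomial-glm-lrt"` (likelihood-ratio of the
#'   logistic-binomial group model) or `"pooled-fisher"` (two-sided exact
#'   test on group-pooled counts).
#' @export
power_config <- function(n_sites = 1000L,
                         sample_sizes = c(100L, 200L, 400L),
                         deltas = seq(0, 0.20, by = 0.05),
                         multipliers = c(1L, 2L, 4L),
                         a_sig = 0.001,
                         baseline = c("symmetric", "fixed"),
                         p0 = 0.5,
                         test = c("binomial-glm-lrt", "pooled-fisher")) {
  baseline <- match.arg(baseline)
  test <- match.arg(test)
  if (a_sig <= 0 || a_sig >= 1) stop("a_sig must be in (0, 1)")
  if (any(deltas < 0)) stop("deltas must be >= 0")
  if (any(multipliers < 1) || any(multipliers != round(multipliers)))
    stop("multipliers must be positive integers")
  if (baseline == "fixed" && any(p0 + deltas > 1))
    stop("p0 + delta > 1")
  structure(list(n_sites = as.integer(n_sites),
                 sample_sizes = as.integer(sample_sizes),
                 deltas = deltas, multipliers = as.integer(multipliers),
                 a_sig = a_sig, baseline = baseline, p0 = p0, test = test),
            class = "power_config")
}

baseline_p0 <- function(config, delta) {
  if (config$baseline == "symmetric") 0.5 - delta / 2 else config$p0
}

#' Draw per-sample coverages from an empirical pool
#'
#' i.i.d. draws with replacement from the observed coverage distribution,
#' each multiplied by the coverage multiplier `k` — the study's device for
#' simulating 40x and 80x regimes from ~20x data.
#'
#' @param pool non-empty vector of observed non-negative coverages.
#' @param n number of samples (>= 2).
#' @param k coverage multiplier.
#' @param seed RNG seed.
#' @return integer coverage vector of length `n`.
#' @export
draw_coverage <- function(pool, n, k = 1L, seed = 1) {
  if (length(pool) == 0 || any(pool < 0)) stop("invalid coverage pool")
  if (n < 2) stop("n must be >= 2")
  set.seed(seed)
  pool <- as.integer(pool)
  pool[sample.int(length(pool), n, replace = TRUE)] * as.integer(k)
}

#' Simulate methylated counts under a binary group effect
#'
#' Each sample's methylated count is binomial with its coverage as size and
#' success probability `p0` (group 0) or `p0 + delta` (group 1).
#'
#' @param coverages per-sample total counts.
#' @param groups 0/1 labels, same length.
#' @param p0 baseline methylation probability.
#' @param delta group-1 shift; `p0 + delta` must not exceed 1.
#' @param seed RNG seed.
#' @return integer methylated-count vector.
#' @export
simulate_counts <- function(coverages, groups, p0, delta, seed = 1) {
  if (p0 < 0 || p0 + delta > 1) stop("need 0 <= p0 and p0 + delta <= 1")
  if (length(groups) != length(coverages)) stop("length mismatch")
  set.seed(seed)
  stats::rbinom(length(coverages), coverages, p0 + delta * groups)
}

xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

# Closed-form logistic-binomial LRT for a binary predictor: group MLEs are
# the pooled group proportions, so the deviance needs no iterative fit and
# complete separation is handled exactly.
lrt_from_sums <- function(M0, C0, M1, C1) {
  p0h <- ifelse(C0 > 0, M0 / C0, 0)
  p1h <- ifelse(C1 > 0, M1 / C1, 0)
  ph <- (M0 + M1) / (C0 + C1)
  dev <- 2 * (xlogy(M0, p0h) + xlogy(C0 - M0, 1 - p0h) +
              xlogy(M1, p1h) + xlogy(C1 - M1, 1 - p1h) -
              xlogy(M0 + M1, ph) - xlogy(C0 + C1 - M0 - M1, 1 - ph))
  dev <- pmax(dev, 0)
  p <- stats::pchisq(dev, df = 1, lower.tail = FALSE)
  p[C0 == 0 | C1 == 0] <- NA_real_
  list(stat = dev, p = p)
}

#' Per-site test of a group effect on methylation
#'
#' Default is the likelihood-ratio test comparing logistic-binomial models
#' with and without the group term (chi-square, 1 df); because the only
#' predictor is binary the deviance has a closed form in the group-pooled
#' counts. The alternative collapses counts per group into a 2x2 table and
#' applies Fisher's exact test.
#'
#' @param M methylated counts per sample.
#' @param c total counts per sample.
#' @param groups 0/1 labels.
#' @param test `"binomial-glm-lrt"` or `"pooled-fisher"`.
#' @return list with `stat` (LRT deviance, or `NA` for the exact test) and
#'   `p`; `p` is `NA` when a group has no coverage.
#' @export
site_pvalue <- function(M, c, groups,
                        test = c("binomial-glm-lrt", "pooled-fisher")) {
  test <- match.arg(test)
  if (any(M > c)) stop("M must not exceed c")
  M0 <- sum(M[groups == 0]); C0 <- sum(c[groups == 0])
  M1 <- sum(M[groups == 1]); C1 <- sum(c[groups == 1])
  if (C0 == 0 || C1 == 0) return(list(stat = NA_real_, p = NA_real_))
  if (test == "binomial-glm-lrt") {
    r <- lrt_from_sums(M0, C0, M1, C1)
    list(stat = r$stat, p = r$p)
  } else {
    tab <- matrix(c(M0, C0 - M0, M1, C1 - M1), nrow = 2)
    list(stat = NA_real_,
         p = stats::fisher.test(tab, alternative = "two.sided")$p.value)
  }
}

#' Estimate power across the sample-size / effect-size / coverage grid
#'
#' For each grid cell, simulates `n_sites` independent CpG sites: coverages
#' are drawn with replacement from the empirical pool (multiplied by the
#' coverage multiplier), methylated counts are binomial under the balanced
#' two-group design, each site is tested, and power is the fraction of
#' testable sites significant at `a_sig`. Coverage draws are shared across
#' effect sizes and multipliers within a sample size, so power comparisons
#' along those axes are positively coupled. Fully seed-deterministic.
#'
#' @param config a [power_config()].
#' @param pool empirical coverage pool (non-negative integers).
#' @param seed master RNG seed.
#' @return data.frame with one row per (n, delta, k): achieved mean
#'   coverage, power, numbers of simulated and testable sites, `a_sig` and
#'   the seed.
#' @export
estimate_power <- function(config = power_config(), pool, seed = 1) {
  if (length(pool) == 0) stop("empty coverage pool")
  pool <- as.integer(pool)
  rows <- list()
  for (ni in seq_along(config$sample_sizes)) {
    n <- config$sample_sizes[ni]
    groups <- rep(c(0L, 1L), c(floor(n / 2), ceiling(n / 2)))
    set.seed((seed + 7919L * ni) %% .Machine$integer.max)
    cov_base <- matrix(pool[sample.int(length(pool), config$n_sites * n,
                                       replace = TRUE)],
                       config$n_sites, n)
    for (ki in seq_along(config$multipliers)) {
      k <- config$multipliers[ki]
      cov <- cov_base * k
      C0 <- rowSums(cov[, groups == 0L, drop = FALSE])
      C1 <- rowSums(cov[, groups == 1L, drop = FALSE])
      for (di in seq_along(config$deltas)) {
        delta <- config$deltas[di]
        p0 <- baseline_p0(config, delta)
        set.seed((seed + 7919L * ni + 131L * ki + 17L * di) %%
                   .Machine$integer.max)
        pvec <- p0 + delta * groups
        Mm <- matrix(stats::rbinom(length(cov), as.vector(cov),
                                   rep(pvec, each = config$n_sites)),
                     config$n_sites, n)
        M0 <- rowSums(Mm[, groups == 0L, drop = FALSE])
        M1 <- rowSums(Mm[, groups == 1L, drop = FALSE])
        p <- if (config$test == "binomial-glm-lrt") {
          lrt_from_sums(M0, C0, M1, C1)$p
        } else {
          vapply(seq_len(config$n_sites), function(i) {
            if (C0[i] == 0 || C1[i] == 0) return(NA_real_)
            stats::fisher.test(matrix(c(M0[i], C0[i] - M0[i],
                                        M1[i], C1[i] - M1[i]), 2))$p.value
          }, numeric(1))
        }
        tested <- !is.na(p)
        rows[[length(rows) + 1L]] <- data.frame(
          n = n, delta = delta, k = k,
          mean_coverage = mean(cov),
          power = if (any(tested)) mean(p[tested] < config$a_sig) else NA_real_,
          n_sites = config$n_sites, n_tested = sum(tested),
          a_sig = config$a_sig, seed = seed)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
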