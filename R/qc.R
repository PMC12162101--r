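#' Conversion-efficiency estimate from CHH methylation
#'
#' Mammalian CHH cytosines are essentially unmethylated, so the observed CHH
#' methylation percentage estimates the rate at which unmethylated cytosines
#' fail to convert. Status thresholds follow common practice: below 1%
#' passes, 5% is the conventional failure cutoff.
#'
#' @param chh_M total methylated CHH count.
#' @param chh_total total CHH count (> 0).
#' @param warn_pct,fail_pct status thresholds in percent.
#' @return list with `percent_chh` and `status` in `{pass, warn, fail}`.
#' @export
conversion_estimate <- function(chh_M, chh_total, warn_pct = 1, fail_pct = 5) {
  if (chh_total <= 0) stop("chh_total must be > 0")
  if (chh_M < 0 || chh_M > chh_total)
    stop("need 0 <= chh_M <= chh_total")
  pct <- 100 * chh_M / chh_total
  status <- if (pct < warn_pct) "pass" else if (pct < fail_pct) "warn" else "fail"
  list(percent_chh = pct, status = status)
}

#' Summarize CHH methylation from a cytosine report
#'
#' @param records cytosine-report data.frame.
#' @return a [conversion_estimate()] result computed over all CHH records.
#' @export
chh_conversion <- function(records) {
  chh <- records[records$context == "CHH", , drop = FALSE]
  conversion_estimate(sum(chh$M), sum(chh$M) + sum(chh$U))
}

#' Assembly Nx statistic
#'
#' Sorts lengths descending and returns the first length at which the
#' cumulative sum reaches at least `x` of the total — N50 for `x = 0.5`,
#' N90 for `x = 0.9`. The returned value is always an element of the input.
#'
#' @param lengths positive integer lengths (non-empty).
#' @param x fraction in (0, 1).
#' @return list with `x` and `value`.
#' @export
nx_stat <- function(lengths, x = 0.5) {
  if (length(lengths) == 0) stop("empty length set")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (x <= 0 || x >= 1) stop("x must be in (0, 1)")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  i <- which(cumsum(s) >= x * sum(s))[1]
  list(x = x, value = s[i])
}

#' Randomly thin reads
#'
#' For fragment sets each fragment is kept independently with probability
#' `f`. For count matrices each cell's coverage is thinned binomially and the
#' retained methylated count drawn hypergeometrically from the original
#' reads, so the result remains a valid integer count matrix with expected
#' coverage `f * c`.
#'
#' @param x a [count_matrix()] or fragment intervals.
#' @param f retention fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return object of the same type, thinned.
#' @export
thin_counts <- function(x, f, seed = 1) {
  if (f < 0 || f > 1) stop("f must be in [0, 1]")
  set.seed(seed)
  if (inherits(x, "count_matrix")) {
    if (f == 1) return(x)
    cov <- x$M + x$U
    n <- length(cov)
    new_cov <- stats::rbinom(n, as.vector(cov), f)
    new_m <- rhyper_safe(as.vector(x$M), as.vector(x$U), new_cov)
    M <- matrix(new_m, nrow(cov), ncol(cov))
    U <- matrix(new_cov - new_m, nrow(cov), ncol(cov))
    return(count_matrix(x$sites, M, U, x$meta))
  }
  gi <- as_intervals(x)
  if (f == 1) return(gi)
  keep <- stats::runif(nrow(gi)) < f
  out <- gi[keep, , drop = FALSE]
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Coverage as a function of read subsampling
#'
#' Thins the fragment set to each fraction, recomputes mean and median
#' per-base depth over the target, and fits the line of mean depth against
#' fraction — sequencing effort converts to coverage linearly, so the fitted
#' intercept should sit at 0.
#'
#' @param fragments fragment intervals.
#' @param target merged target intervals (non-empty).
#' @param fractions subsampling fractions.
#' @param seed RNG seed.
#' @return list: `table` (fraction, mean_depth, median_depth) and `fit`
#'   (slope, intercept of mean depth ~ fraction).
#' @export
coverage_curve <- function(fragments, target,
                           fractions = c(0.25, 0.5, 0.75, 1.0), seed = 1) {
  target <- as_intervals(target)
  if (nrow(target) == 0) stop("empty target")
  rows <- lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    thinned <- thin_counts(fragments, f, seed = seed + i)
    bc <- base_coverage(thinned, target)
    data.frame(fraction = f, mean_depth = bc$mean, median_depth = bc$median)
  })
  tab <- do.call(rbind, rows)
  fit <- stats::lm(mean_depth ~ fraction, data = tab)
  list(table = tab,
       fit = list(slope = unname(stats::coef(fit)[2]),
                  intercept = unname(stats::coef(fit)[1])))
}
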