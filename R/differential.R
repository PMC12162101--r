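#' Beta-binomial log-likelihood on the mean/overdispersion scale
#'
#' Beta-binomial with mean `mu` and intra-class correlation `rho`
#' (shape parameters a = mu(1-rho)/rho, b = (1-mu)(1-rho)/rho); at `rho = 0`
#' the model reduces to the binomial.
#'
#' @param m methylated counts.
#' @param size total counts.
#' @param mu mean methylation proportion in (0, 1).
#' @param rho overdispersion in `[0, 1)`.
#' @return total log-likelihood over all observations.
#' @export
betabinom_loglik <- function(m, size, mu, rho) {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (rho < 1e-12) {
    return(sum(stats::dbinom(m, size, mu, log = TRUE)))
  }
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  sum(lchoose(size, m) + lbeta(m + a, size - m + b) - lbeta(a, b))
}

# Negative log-likelihood of the two-arm beta-binomial model with logit-scale
# means and a shared dispersion; theta = (b0[, b1], logit(rho)).
bb_nll <- function(theta, m, size, focal, with_effect) {
  b0 <- theta[1]
  b1 <- if (with_effect) theta[2] else 0
  rho <- stats::plogis(theta[length(theta)])
  mu <- stats::plogis(b0 + b1 * focal)
  mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  -sum(lchoose(size, m) + lbeta(m + a, size - m + b) - lbeta(a, b))
}

# Binomial (rho = 0) maximum log-likelihood in closed form: arm proportions
# for the full model, the pooled proportion for the null.
binom_profile_ll <- function(m, size, focal, with_effect) {
  ll_arm <- function(mm, cc) {
    p <- if (sum(cc) > 0) sum(mm) / sum(cc) else 0
    sum(lchoose(cc, mm)) + xlogy(sum(mm), p) + xlogy(sum(cc) - sum(mm), 1 - p)
  }
  if (with_effect)
    ll_arm(m[focal == 1], size[focal == 1]) + ll_arm(m[focal == 0], size[focal == 0])
  else ll_arm(m, size)
}

fit_bb_model <- function(m, size, focal, with_effect) {
  pool_p <- min(max(sum(m) / sum(size), 1e-4), 1 - 1e-4)
  b0_start <- stats::qlogis(pool_p)
  b1_start <- 0
  if (with_effect) {
    p1 <- min(max(sum(m[focal == 1]) / max(sum(size[focal == 1]), 1), 1e-4),
              1 - 1e-4)
    b1_start <- stats::qlogis(p1) - b0_start
  }
  start <- if (with_effect) c(b0_start, b1_start, stats::qlogis(0.05))
           else c(b0_start, stats::qlogis(0.05))
  k <- length(start)
  opt <- try(stats::optim(start, bb_nll, m = m, size = size, focal = focal,
                          with_effect = with_effect, method = "L-BFGS-B",
                          lower = c(rep(-25, k - 1), -25),
                          upper = c(rep(25, k - 1), 8)),
             silent = TRUE)
  if (inherits(opt, "try-error") || opt$convergence > 1) {
    # the dispersion boundary can defeat the line search; fall back to a
    # derivative-free restart
    opt <- try(stats::optim(start, bb_nll, m = m, size = size, focal = focal,
                            with_effect = with_effect,
                            control = list(maxit = 2000)),
               silent = TRUE)
    if (inherits(opt, "try-error") || opt$convergence > 0) return(NULL)
    opt$par[k] <- min(opt$par[k], 8)
  }
  ll <- -opt$value
  # boundary: profile down to the binomial when the dispersion pins at 0
  ll_bin <- binom_profile_ll(m, size, focal, with_effect)
  if (ll_bin > ll) {
    par <- opt$par
    par[k] <- -Inf
    return(list(par = par, ll = ll_bin, at_boundary = TRUE, opt = opt))
  }
  list(par = opt$par, ll = ll, at_boundary = FALSE, opt = opt)
}

#' Fit the per-site beta-binomial tissue model
#'
#' Maximum-likelihood beta-binomial with logit mean `b0 + b1 * focal` and a
#' single shared overdispersion `rho`; the p-value is the likelihood-ratio
#' test of `b1 = 0` (chi-square, 1 df) and the standardized effect is
#' `z = b1 / se(b1)` from the observed information.
#'
#' @param M methylated counts per sample.
#' @param c total counts per sample.
#' @param focal 0/1 indicator of the focal arm; each arm needs >= 2 samples
#'   with positive coverage.
#' @return list: `b0`, `b1`, `rho`, `z`, `se`, `stat`, `p`, `converged`.
#' @export
fit_betabinom_site <- function(M, c, focal) {
  focal <- as.integer(focal)
  keep <- c > 0
  M <- M[keep]; c <- c[keep]; focal <- focal[keep]
  bad <- list(b0 = NA_real_, b1 = NA_real_, rho = NA_real_, z = NA_real_,
              se = NA_real_, stat = NA_real_, p = NA_real_, converged = FALSE)
  if (sum(focal == 1) < 2 || sum(focal == 0) < 2) return(bad)
  full <- fit_bb_model(M, c, focal, with_effect = TRUE)
  null <- fit_bb_model(M, c, focal, with_effect = FALSE)
  if (is.null(full) || is.null(null)) return(bad)
  stat <- max(0, 2 * (full$ll - null$ll))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  se <- NA_real_
  if (!full$at_boundary) {
    H <- try(stats::optimHess(full$opt$par, bb_nll, m = M, size = c,
                              focal = focal, with_effect = TRUE),
             silent = TRUE)
    if (!inherits(H, "try-error")) {
      V <- try(solve(H), silent = TRUE)
      if (!inherits(V, "try-error") && V[2, 2] > 0) se <- sqrt(V[2, 2])
    }
  } else {
    # binomial-limit SE of the logit effect from arm counts
    s1 <- sum(M[focal == 1]); n1 <- sum(c[focal == 1])
    s0 <- sum(M[focal == 0]); n0 <- sum(c[focal == 0])
    if (s1 > 0 && s1 < n1 && s0 > 0 && s0 < n0)
      se <- sqrt(1 / s1 + 1 / (n1 - s1) + 1 / s0 + 1 / (n0 - s0))
  }
  b1 <- full$par[2]
  list(b0 = full$par[1], b1 = b1,
       rho = stats::plogis(full$par[3]),
       z = if (is.finite(se) && se > 0) b1 / se else NA_real_,
       se = se, stat = stat, p = p, converged = TRUE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Missing p-values are propagated and excluded from the effective number of
#' tests.
#'
#' @param p vector of p-values in `[0, 1]`, `NA` allowed.
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Scan all sites for focal-tissue-specific methylation
#'
#' Restricts to variably methylated sites (per-site median level strictly
#' between `lo` and `hi`), fits the beta-binomial focal-vs-rest model at
#' each, and applies BH FDR over the tested sites.
#'
#' @param cm a [count_matrix()] whose `meta` has a `tissue` column.
#' @param focal focal tissue name (must be present).
#' @param lo,hi variable-site bounds on the per-site median (default 0.1,
#'   0.9).
#' @param fdr significance threshold on q (default 0.05).
#' @return data.frame: one row per tested site with `chrom`, `pos0`, `b0`,
#'   `b1`, `rho`, `z`, `p`, `q`, `significant`, `converged`; attribute
#'   `n_excluded` counts non-converged fits.
#' @export
tissue_scan <- function(cm, focal, lo = 0.1, hi = 0.9, fdr = 0.05) {
  if (!"tissue" %in% names(cm$meta)) stop("meta must have a 'tissue' column")
  tissues <- cm$meta$tissue
  if (!focal %in% tissues) stop(sprintf("focal tissue '%s' absent", focal))
  ind <- as.integer(tissues == focal)
  lev <- methylation_levels(cm)
  med <- apply(lev, 1, stats::median, na.rm = TRUE)
  variable <- !is.na(med) & med > lo & med < hi
  idx <- which(variable)
  fits <- lapply(idx, function(i)
    fit_betabinom_site(cm$M[i, ], cm$M[i, ] + cm$U[i, ], ind))
  out <- data.frame(
    chrom = cm$sites$chrom[idx], pos0 = cm$sites$pos0[idx],
    b0 = vapply(fits, `[[`, numeric(1), "b0"),
    b1 = vapply(fits, `[[`, numeric(1), "b1"),
    rho = vapply(fits, `[[`, numeric(1), "rho"),
    z = vapply(fits, `[[`, numeric(1), "z"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  out$q <- bh_fdr(out$p)
  out$significant <- !is.na(out$q) & out$q < fdr
  attr(out, "n_excluded") <- sum(!out$converged)
  out
}

#' Overlap enrichment between two significant site sets
#'
#' Builds the 2x2 table (in both, A only, B only, neither) over a universe
#' of tested sites. The odds ratio is ad/bc with a Haldane +0.5 correction
#' applied only when a cell is zero; the 95% CI is Wald on the log scale
#' (reported in log2 units) and the two-sided p is Fisher's exact test on
#' the uncorrected table.
#'
#' @param sigA,sigB character vectors of site keys, subsets of `universe`.
#' @param universe character vector of all tested site keys.
#' @return list: `table` (a, b, c, d), `odds_ratio`, `log2_or`, `ci95`
#'   (log2 scale), `p`.
#' @export
overlap_enrichment <- function(sigA, sigB, universe) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(sigA %in% universe) || !all(sigB %in% universe))
    stop("significant sets must be subsets of the universe")
  inA <- universe %in% sigA
  inB <- universe %in% sigB
  a <- sum(inA & inB); b <- sum(inA & !inB)
  cc <- sum(!inA & inB); d <- sum(!inA & !inB)
  corr <- if (any(c(a, b, cc, d) == 0)) 0.5 else 0
  a2 <- a + corr; b2 <- b + corr; c2 <- cc + corr; d2 <- d + corr
  or <- (a2 * d2) / (b2 * c2)
  se_log <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  ci <- (log(or) + c(-1, 1) * 1.96 * se_log) / log(2)
  p <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2))$p.value
  list(table = c(a = a, b = b, c = cc, d = d),
       odds_ratio = or, log2_or = log2(or), ci95 = ci, p = p)
}
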