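# Brute-force oracles used across the interval and filtering tests. All are
# deliberately naive per-base / double-loop computations, independent of the
# package's interval machinery.

# every base covered by any input interval grown by `flank`
oracle_expand_merge_bases <- function(gi, flank, extent) {
  covered <- rep(FALSE, extent)
  for (i in seq_len(nrow(gi))) {
    lo <- max(gi$start[i] - flank, 0L)
    hi <- min(gi$end[i] + flank, extent)
    if (lo < hi) covered[(lo + 1):hi] <- TRUE
  }
  covered
}

# gap-based on-target call for one query interval against reference intervals
oracle_on_target <- function(qs, qe, ref, tol) {
  for (i in seq_len(nrow(ref))) {
    gap <- max(ref$start[i] - qe, qs - ref$end[i], 0L)
    if (gap <= tol) return(TRUE)
  }
  FALSE
}

oracle_base_depth <- function(frags, target, extent) {
  depth <- integer(extent)
  for (i in seq_len(nrow(frags))) {
    s <- frags$start[i]; e <- min(frags$end[i], extent)
    if (s < e) depth[(s + 1):e] <- depth[(s + 1):e] + 1L
  }
  tmask <- rep(FALSE, extent)
  for (i in seq_len(nrow(target))) tmask[(target$start[i] + 1):target$end[i]] <- TRUE
  depth[tmask]
}

# island > shore > shelf per-base labels
oracle_shore_shelf_labels <- function(islands, extent, shore_bp = 2000, shelf_bp = 4000) {
  lab <- rep("none", extent)
  for (i in seq_len(nrow(islands))) {
    lo <- max(islands$start[i] - shelf_bp, 0L); hi <- min(islands$end[i] + shelf_bp, extent)
    if (lo < hi) lab[(lo + 1):hi] <- "shelf"
  }
  for (i in seq_len(nrow(islands))) {
    lo <- max(islands$start[i] - shore_bp, 0L); hi <- min(islands$end[i] + shore_bp, extent)
    if (lo < hi) lab[(lo + 1):hi] <- "shore"
  }
  for (i in seq_len(nrow(islands))) {
    lab[(islands$start[i] + 1):islands$end[i]] <- "island"
  }
  lab
}

# double-loop reference for the coverage/missingness filter
oracle_filter_keep <- function(M, U, min_cov, min_frac, cov_cmp, frac_cmp) {
  cfun <- if (cov_cmp == "ge") `>=` else `>`
  ffun <- if (frac_cmp == "ge") `>=` else `>`
  keep <- logical(nrow(M))
  for (i in seq_len(nrow(M))) {
    nok <- 0L
    for (j in seq_len(ncol(M))) if (cfun(M[i, j] + U[i, j], min_cov)) nok <- nok + 1L
    keep[i] <- ffun(nok / ncol(M), min_frac)
  }
  keep
}

# enumerate suffix sums of the descending sort
oracle_nx <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(as.numeric(s))
  for (i in seq_along(s)) if (sum(as.numeric(s[1:i])) >= x * tot) return(s[i])
  s[length(s)]
}

# beta-binomial likelihood by direct rising-factorial products over the
# counts (independent of the lbeta-based closed form): for c trials,
# P(m) = C(c,m) * prod_{i<m}(a+i) * prod_{j<c-m}(b+j) / prod_{k<c}(a+b+k)
oracle_bb_loglik <- function(m, size, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  rising <- function(x, n) if (n == 0) 1 else prod(x + seq_len(n) - 1)
  sum(vapply(seq_along(m), function(i) {
    log(choose(size[i], m[i])) + log(rising(a, m[i])) +
      log(rising(b, size[i] - m[i])) - log(rising(a + b, size[i]))
  }, numeric(1)))
}

# step-up BH by direct definition: q_i = min over p_(j) >= p_(i) of p_(j)*m/j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) min(1, min(ps[i:m] * m / seq(i, m))), numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

random_intervals <- function(n, extent, chrom = "chr1", max_len = NULL) {
  if (is.null(max_len)) max_len <- max(2L, extent %/% 5L)
  start <- sample.int(extent - 2L, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  end <- pmin(start + len, extent)
  ok <- start < end
  genomic_intervals(chrom, start[ok], end[ok])
}
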