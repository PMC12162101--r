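#' Ordinary least-squares concordance fit
#'
#' Simple regression of `y` on `x` over pairwise-complete observations;
#' `r2 = 1 - SS_res/SS_tot` (equal to the squared Pearson correlation for a
#' simple linear fit). A fit over fewer than 3 points, or with zero variance
#' on either axis, is reported as undefined rather than raising.
#'
#' @param x,y numeric vectors of equal length.
#' @return list: `slope`, `intercept`, `r2`, `pearson_r`, `n_points`.
#' @export
ols_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  und <- list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
              pearson_r = NA_real_, n_points = n)
  if (n < 3) return(und)
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  if (sxx == 0 || syy == 0) return(und)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  ss_res <- syy - slope * sxy
  list(slope = slope, intercept = intercept,
       r2 = 1 - ss_res / syy,
       pearson_r = sxy / sqrt(sxx * syy),
       n_points = n)
}

#' Microarray-style beta values from count pairs
#'
#' beta = M / (M + U + offset). With a positive offset a beta of exactly 1
#' is impossible — the systematic compression that biases array values
#' downward at highly methylated sites.
#'
#' @param M,U non-negative counts (or intensities).
#' @param alpha_off offset (>= 0), default 100.
#' @return numeric beta vector; `NA` where `M = U = 0` with zero offset.
#' @export
beta_values <- function(M, U, alpha_off = 100) {
  if (alpha_off < 0) stop("alpha_off must be >= 0")
  if (any(M < 0) || any(U < 0)) stop("counts must be >= 0")
  denom <- M + U + alpha_off
  ifelse(denom > 0, M / denom, NA_real_)
}

#' Per-sample cross-technology agreement, matched or permuted
#'
#' For each sample pair, fits per-site methylation levels of technology B on
#' technology A over mutually observed sites and records the r2. With
#' `permute = TRUE` the pairing is replaced by a seeded random derangement
#' (no sample paired with itself), giving the null distribution against
#' which matched agreement is compared.
#'
#' @param levA,levB methylation-level matrices over a shared, row-aligned
#'   site set; columns are samples.
#' @param pairing named character vector mapping colnames of `levA` to
#'   colnames of `levB`; default pairs identical names.
#' @param permute replace the pairing with a derangement.
#' @param seed RNG seed for the derangement.
#' @return data.frame with `sample_a`, `sample_b`, `r2`, `n_sites`.
#' @export
paired_sample_r2 <- function(levA, levB, pairing = NULL, permute = FALSE,
                             seed = 1) {
  if (nrow(levA) != nrow(levB)) stop("site sets must be row-aligned")
  if (is.null(pairing)) {
    shared <- intersect(colnames(levA), colnames(levB))
    if (length(shared) == 0) stop("no shared sample names and no pairing given")
    pairing <- stats::setNames(shared, shared)
  }
  a_ids <- names(pairing)
  b_ids <- unname(pairing)
  if (anyDuplicated(a_ids) || anyDuplicated(b_ids))
    stop("pairing must be bijective")
  if (permute) {
    set.seed(seed)
    b_ids <- b_ids[derangement(length(b_ids))]
  }
  res <- lapply(seq_along(a_ids), function(i) {
    x <- levA[, a_ids[i]]
    y <- levB[, b_ids[i]]
    fit <- ols_fit(x, y)
    data.frame(sample_a = a_ids[i], sample_b = b_ids[i],
               r2 = fit$r2, n_sites = fit$n_points,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# Random derangement by rejection; for n = 1 there is none, so pairing a
# single sample with itself under permutation is an error.
derangement <- function(n) {
  if (n == 1) stop("no derangement of a single element exists")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Welch's two-sample t test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom. The
#' degenerate zero-variance cases are defined rather than raised: identical
#' constant vectors give t = 0, p = 1; constant vectors with unequal means
#' give p = 0 with a `degenerate` flag.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list: `t`, `df`, `p`, `degenerate`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each vector needs n >= 2")
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    return(list(t = NA_real_, df = NA_real_, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Concordance fits over named site subsets
#'
#' Applies [ols_fit()] within each named boolean mask — variably methylated
#' sites, islands/shores/shelves, hypo/hypermethylated sites, array probe
#' types: any subset rule reduces to a mask.
#'
#' @param meanA,meanB per-site mean levels over a shared site vector.
#' @param masks named list of logical masks aligned to the site vector.
#' @return named list of [ols_fit()] results (undefined fits for masks with
#'   fewer than 3 sites).
#' @export
subset_compare <- function(meanA, meanB, masks) {
  if (length(meanA) != length(meanB)) stop("length mismatch")
  lapply(masks, function(m) {
    m <- m & !is.na(m)
    ols_fit(meanA[m], meanB[m])
  })
}
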