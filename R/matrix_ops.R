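#' Construct a multi-sample methylation count matrix
#'
#' The central container: per-site, per-sample methylated (`M`) and
#' unmethylated (`U`) read counts with sample metadata, analogous to a BSseq
#' object. Sites are keyed by chromosome and 0-based plus-strand C position.
#'
#' @param sites data.frame with `chrom`, `pos0` (unique rows).
#' @param M,U integer matrices, sites x samples.
#' @param meta data.frame with a `sample` column (and optionally `group`,
#'   `tissue`, `technology`), one row per sample, ordered as the columns.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(sites, M, U, meta) {
  M <- as.matrix(M); U <- as.matrix(U)
  if (!all(dim(M) == dim(U))) stop("M and U must have identical dimensions")
  if (nrow(M) != nrow(sites)) stop("site rows must match matrix rows")
  if (nrow(meta) != ncol(M)) stop("meta rows must match matrix columns")
  if (any(M < 0) || any(U < 0)) stop("counts must be non-negative")
  if (anyDuplicated(paste(sites$chrom, sites$pos0))) stop("duplicate site keys")
  if (anyDuplicated(meta$sample)) stop("duplicate sample IDs")
  colnames(M) <- colnames(U) <- meta$sample
  structure(list(sites = as.data.frame(sites), M = M, U = U,
                 meta = as.data.frame(meta)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d sites x %d samples\n",
              nrow(x$M), ncol(x$M)))
  cat("samples:", paste(utils::head(x$meta$sample, 8), collapse = ", "),
      if (ncol(x$M) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$M)

#' Assemble a count matrix from per-sample collapsed reports
#'
#' The site set is the union across samples; cells absent from a sample get
#' (0, 0), so missingness filtering downstream is meaningful.
#'
#' @param reports named list: sample ID -> data.frame with `chrom`, `pos0`,
#'   `M`, `U` (the output of [collapse_strands()]).
#' @param sheet sample sheet data.frame with a `sample` column covering all
#'   report names.
#' @return a [count_matrix()].
#' @export
assemble_matrix <- function(reports, sheet) {
  ids <- names(reports)
  if (is.null(ids) || anyDuplicated(ids))
    stop("reports must be a uniquely named list")
  if (!all(ids %in% sheet$sample))
    stop("sample sheet does not cover all report samples")
  sheet <- sheet[match(ids, sheet$sample), , drop = FALSE]
  keys <- unique(do.call(rbind, lapply(reports, function(r)
    data.frame(chrom = r$chrom, pos0 = r$pos0, stringsAsFactors = FALSE))))
  keys <- keys[order(keys$chrom, keys$pos0), , drop = FALSE]
  rownames(keys) <- NULL
  kid <- paste(keys$chrom, keys$pos0)
  M <- matrix(0L, nrow(keys), length(ids))
  U <- matrix(0L, nrow(keys), length(ids))
  for (j in seq_along(ids)) {
    r <- reports[[j]]
    i <- match(paste(r$chrom, r$pos0), kid)
    M[i, j] <- r$M
    U[i, j] <- r$U
  }
  count_matrix(keys, M, U, sheet)
}

#' Filtering rule for count matrices
#'
#' The study default keeps sites covered at >= 5x in >= 75% of samples within
#' the expanded probe target; a relaxed variant for tiny groups keeps sites
#' with at least one read in at least two-thirds of samples. Both the
#' coverage and the fraction comparators are explicit because ">5X" and
#' ">75%" may be read inclusively or strictly.
#'
#' @param min_cov coverage threshold (default 5).
#' @param min_frac required fraction of samples (default 0.75).
#' @param cov_cmp,frac_cmp `"ge"` (inclusive, default) or `"gt"` (strict).
#' @param target optional merged target intervals; when given, only on-target
#'   sites survive.
#' @param tol proximity tolerance against `target` in bp (default 0; pass
#'   the probe BED itself with `tol = 200` for the equivalent rule).
#' @export
filter_spec <- function(min_cov = 5L, min_frac = 0.75,
                        cov_cmp = c("ge", "gt"), frac_cmp = c("ge", "gt"),
                        target = NULL, tol = 0L) {
  cov_cmp <- match.arg(cov_cmp); frac_cmp <- match.arg(frac_cmp)
  if (min_cov < 0) stop("min_cov must be >= 0")
  if (min_frac < 0 || min_frac > 1) stop("min_frac must be in [0, 1]")
  structure(list(min_cov = min_cov, min_frac = min_frac,
                 cov_cmp = cov_cmp, frac_cmp = frac_cmp,
                 target = target, tol = tol),
            class = "filter_spec")
}

cmp_fun <- function(which) if (which == "ge") `>=` else `>`

#' Filter a count matrix by region and coverage/missingness
#'
#' A site survives iff (no target is configured, or the site is on-target per
#' [proximity_mask()]) and the fraction of samples whose coverage satisfies
#' the coverage comparison satisfies the fraction comparison. Site order is
#' preserved.
#'
#' @param cm a [count_matrix()].
#' @param spec a [filter_spec()].
#' @return list: `matrix` (filtered [count_matrix()]) and `report`
#'   (`n_input`, `n_kept`, `n_dropped_region`, `n_dropped_coverage`).
#' @export
filter_matrix <- function(cm, spec = filter_spec()) {
  ns <- nrow(cm$M)
  if (ns == 0)
    return(list(matrix = cm,
                report = list(n_input = 0L, n_kept = 0L,
                              n_dropped_region = 0L, n_dropped_coverage = 0L)))
  on_target <- rep(TRUE, ns)
  if (!is.null(spec$target))
    on_target <- proximity_mask(cm$sites, spec$target, tol = spec$tol)$mask
  cov <- cm$M + cm$U
  frac <- rowMeans(cmp_fun(spec$cov_cmp)(cov, spec$min_cov))
  cov_ok <- cmp_fun(spec$frac_cmp)(frac, spec$min_frac)
  keep <- on_target & cov_ok
  out <- count_matrix(cm$sites[keep, , drop = FALSE],
                      cm$M[keep, , drop = FALSE],
                      cm$U[keep, , drop = FALSE], cm$meta)
  list(matrix = out,
       report = list(n_input = ns, n_kept = sum(keep),
                     n_dropped_region = sum(!on_target),
                     n_dropped_coverage = sum(on_target & !cov_ok)))
}

#' Per-cell methylation levels
#'
#' m = M / (M + U) where coverage is positive, `NA` where a cell has no
#' reads.
#'
#' @param cm a [count_matrix()].
#' @return numeric matrix of methylation proportions with explicit `NA`s.
#' @export
methylation_levels <- function(cm) {
  cov <- cm$M + cm$U
  m <- ifelse(cov > 0, cm$M / cov, NA_real_)
  dimnames(m) <- dimnames(cm$M)
  m
}

#' Per-site summaries of methylation levels
#'
#' Mean and median across observed cells, plus the study's classification
#' flags: a site is "variable" iff its mean lies strictly between `lo` and
#' `hi` (default 10-90%), hypomethylated below 0.5 and hypermethylated above.
#'
#' @param levels methylation-level matrix (see [methylation_levels()]).
#' @param lo,hi strict variability bounds.
#' @return data.frame with `mean`, `median`, `n_observed`, `variable`,
#'   `hypo`, `hyper` per site.
#' @export
site_summary <- function(levels, lo = 0.1, hi = 0.9) {
  if (lo >= hi) stop("need lo < hi")
  n_obs <- rowSums(!is.na(levels))
  mu <- rowMeans(levels, na.rm = TRUE)
  mu[n_obs == 0] <- NA_real_
  med <- apply(levels, 1, stats::median, na.rm = TRUE)
  med[n_obs == 0] <- NA_real_
  data.frame(mean = mu, median = med, n_observed = n_obs,
             variable = !is.na(mu) & mu > lo & mu < hi,
             hypo = !is.na(mu) & mu < 0.5,
             hyper = !is.na(mu) & mu > 0.5)
}

#' Summarize site methylation by annotation label
#'
#' Counts sites falling in each labeled region class and takes the median of
#' per-site medians within each class. A site overlapping k labels
#' contributes to all k; sites under no annotation are reported as
#' `"unannotated"`.
#'
#' @param site_medians data.frame with `chrom`, `pos0`, `median`.
#' @param annotations intervals with a `label` column.
#' @return data.frame with `label`, `n_sites`, `median_meth`.
#' @export
annotation_summary <- function(site_medians, annotations) {
  n <- nrow(site_medians)
  labs <- character(0); idx <- integer(0)
  if (!is.null(annotations) && nrow(annotations) > 0) {
    qt <- gi_to_gr(sites_to_gi(site_medians))
    rt <- gi_to_gr(as_intervals(annotations))
    hits <- GenomicRanges::findOverlaps(qt, rt, ignore.strand = TRUE)
    idx <- S4Vectors::queryHits(hits)
    labs <- annotations$label[S4Vectors::subjectHits(hits)]
    # one contribution per (site, label) even if a label's regions tile
    dd <- !duplicated(paste(idx, labs))
    idx <- idx[dd]; labs <- labs[dd]
  }
  unann <- setdiff(seq_len(n), unique(idx))
  all_lab <- c(labs, rep("unannotated", length(unann)))
  all_idx <- c(idx, unann)
  if (length(all_idx) == 0)
    return(data.frame(label = character(), n_sites = integer(),
                      median_meth = numeric(), stringsAsFactors = FALSE))
  sp <- split(site_medians$median[all_idx], all_lab)
  data.frame(label = names(sp),
             n_sites = lengths(sp),
             median_meth = vapply(sp, stats::median, numeric(1), na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a count matrix as TSV files
#'
#' @param cm a [count_matrix()].
#' @param prefix path prefix; writes `<prefix>_M.tsv`, `<prefix>_U.tsv` and
#'   `<prefix>_samples.tsv`.
#' @export
write_count_matrix <- function(cm, prefix) {
  mm <- cbind(cm$sites, as.data.frame(cm$M))
  uu <- cbind(cm$sites, as.data.frame(cm$U))
  utils::write.table(mm, paste0(prefix, "_M.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(uu, paste0(prefix, "_U.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cm$meta, paste0(prefix, "_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param prefix path prefix used when writing.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(prefix) {
  mm <- utils::read.delim(paste0(prefix, "_M.tsv"), check.names = FALSE)
  uu <- utils::read.delim(paste0(prefix, "_U.tsv"), check.names = FALSE)
  meta <- utils::read.delim(paste0(prefix, "_samples.tsv"))
  sites <- mm[, c("chrom", "pos0")]
  count_matrix(sites,
               as.matrix(mm[, -(1:2), drop = FALSE]),
               as.matrix(uu[, -(1:2), drop = FALSE]), meta)
}
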