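#' Expand intervals by a flank and merge
#'
#' Grows every interval by `flank` bp on each side (clipped at 0 and, when
#' chromosome lengths are supplied, at the chromosome end), then merges
#' overlapping or book-ended results. This is the canonical definition of the
#' capture target: the probe footprint plus a +/- 200 bp buffer.
#'
#' @param gi intervals.
#' @param flank bp added to each side (>= 0).
#' @param chrom_lengths optional named integer vector for right clipping.
#' @return sorted, disjoint merged intervals.
#' @export
expand_merge <- function(gi, flank = 200L, chrom_lengths = NULL) {
  if (flank < 0) stop("flank must be >= 0")
  gi <- as_intervals(gi)
  if (nrow(gi) == 0) return(empty_intervals())
  start <- pmax(gi$start - as.integer(flank), 0L)
  end <- gi$end + as.integer(flank)
  if (!is.null(chrom_lengths)) {
    cl <- chrom_lengths[gi$chrom]
    if (any(is.na(cl))) stop("chromosome missing from chrom_lengths")
    end <- pmin(end, as.integer(cl))
    if (any(start >= end))
      stop("clipping produced an empty interval")
  }
  gr <- GenomicRanges::reduce(gi_to_gr(genomic_intervals(gi$chrom, start, end)))
  gr <- GenomicRanges::sort(gr)
  gr_to_gi(gr)
}

#' Classify query elements as on- or off-target by proximity
#'
#' A query element (an interval, or a point site treated as a length-1
#' interval) is on-target iff the gap between it and the nearest reference
#' interval on the same chromosome is at most `tol` bp; any overlap counts as
#' gap 0. With `tol = 200` this is the "within 200 bp of at least one probe"
#' rule for sites and fragments; with `tol = 0` and fragments as the
#' reference it gives the probes-covered-by-at-least-one-read fraction.
#'
#' @param query intervals, or a data.frame of sites (`chrom`, `pos0`).
#' @param reference intervals.
#' @param tol maximum gap in bp (>= 0).
#' @return list: `mask` (logical per query element, in query order) and
#'   `summary` (`n_query`, `n_on_target`, `fraction_on_target`; the fraction
#'   is 0 with `empty_query = TRUE` flagged when there is no query).
#' @export
proximity_mask <- function(query, reference, tol = 200L) {
  if (tol < 0) stop("tol must be >= 0")
  qgi <- if (is.data.frame(query) && "pos0" %in% names(query) &&
             !"end" %in% names(query)) sites_to_gi(query) else as_intervals(query)
  rgi <- as_intervals(reference)
  nq <- nrow(qgi)
  if (nq == 0 || nrow(rgi) == 0) {
    mask <- rep(FALSE, nq)
  } else {
    qgr <- gi_to_gr(qgi)
    rgr <- gi_to_gr(rgi)
    # queries on chromosomes absent from the reference are simply off-target
    hits <- suppressWarnings(
      GenomicRanges::distanceToNearest(qgr, rgr, ignore.strand = TRUE))
    mask <- rep(FALSE, nq)
    qh <- S4Vectors::queryHits(hits)
    mask[qh] <- S4Vectors::mcols(hits)$distance <= tol
  }
  n_on <- sum(mask)
  list(mask = mask,
       summary = list(n_query = nq, n_on_target = n_on,
                      fraction_on_target = if (nq > 0) n_on / nq else 0,
                      empty_query = nq == 0))
}

#' Count CG dinucleotides expected within an expanded probe target
#'
#' Expands and merges the mapped probe intervals first, so a CpG under two
#' nearby probes is counted once; a CG straddling a region boundary counts
#' iff its C lies inside the region. This is the expected-CpG estimate used
#' to judge capture completeness on a new genome.
#'
#' @param probes mapped probe intervals.
#' @param genome a named [Biostrings::DNAStringSet] (or named character
#'   vector of sequences).
#' @param flank buffer added to each probe before merging (default 200).
#' @return integer count of distinct CG dinucleotides in the merged target.
#' @export
expected_cpg_count <- function(probes, genome, flank = 200L) {
  probes <- as_intervals(probes)
  if (nrow(probes) == 0) return(0L)
  seqs <- if (is.character(genome)) Biostrings::DNAStringSet(genome) else genome
  lens <- stats::setNames(Biostrings::width(seqs), names(seqs))
  missing <- setdiff(unique(probes$chrom), names(lens))
  if (length(missing) > 0)
    stop(sprintf("chromosome '%s' absent from FASTA", missing[1]))
  merged <- expand_merge(probes, flank, chrom_lengths = lens)
  total <- 0L
  for (ch in unique(merged$chrom)) {
    cg <- Biostrings::start(Biostrings::matchPattern("CG", seqs[[ch]])) - 1L
    reg <- merged[merged$chrom == ch, , drop = FALSE]
    if (length(cg) == 0 || nrow(reg) == 0) next
    hit <- IRanges::findOverlaps(
      IRanges::IRanges(start = cg + 1L, width = 1L),
      IRanges::IRanges(start = reg$start + 1L, end = reg$end))
    total <- total + length(unique(S4Vectors::queryHits(hit)))
  }
  total
}

#' Per-base depth of fragments over a target
#'
#' Depth at each target base is the number of fragments covering it; the mean
#' is total overlap bases divided by target length, and the median is over
#' per-base depths across the whole target.
#'
#' @param fragments fragment intervals.
#' @param target merged, disjoint target intervals (non-empty).
#' @return list with `mean`, `median` and `target_bases`.
#' @export
base_coverage <- function(fragments, target) {
  target <- as_intervals(target)
  if (nrow(target) == 0) stop("empty target")
  fragments <- as_intervals(fragments)
  tlen <- sum(target$end - target$start)
  if (nrow(fragments) == 0)
    return(list(mean = 0, median = 0, target_bases = tlen))
  depths <- integer(0)
  for (ch in unique(target$chrom)) {
    reg <- target[target$chrom == ch, , drop = FALSE]
    fr <- fragments[fragments$chrom == ch, , drop = FALSE]
    tir <- IRanges::IRanges(start = reg$start + 1L, end = reg$end)
    if (nrow(fr) == 0) {
      depths <- c(depths, rep(0L, sum(IRanges::width(tir))))
      next
    }
    cov <- IRanges::coverage(IRanges::IRanges(start = fr$start + 1L, end = fr$end),
                             width = max(reg$end, fr$end))
    v <- IRanges::Views(cov, tir)
    depths <- c(depths, unlist(lapply(seq_along(v), function(i)
      as.integer(v[[i]])), use.names = FALSE))
  }
  list(mean = sum(as.numeric(depths)) / tlen,
       median = stats::median(depths),
       target_bases = tlen)
}

#' Derive CpG island shores and shelves
#'
#' Shores are the bases within 2 kb of an island boundary that are not in any
#' island; shelves are the bases between 2 kb and 4 kb out, in neither island
#' nor shore. Precedence when regions from neighboring islands collide is
#' island > shore > shelf; coordinates are clipped at 0 (and at chromosome
#' ends when lengths are given).
#'
#' @param islands CpG island intervals.
#' @param shore_bp,shelf_bp outer extents (defaults 2000 and 4000 bp).
#' @param chrom_lengths optional right-clipping lengths.
#' @return intervals with a `label` column in `{island, shore, shelf}`,
#'   sorted and disjoint.
#' @export
derive_shores_shelves <- function(islands, shore_bp = 2000L, shelf_bp = 4000L,
                                  chrom_lengths = NULL) {
  islands <- as_intervals(islands)
  if (nrow(islands) == 0) return(cbind(empty_intervals(), label = character(0)))
  isl <- gi_to_gr(expand_merge(islands, 0L, chrom_lengths))
  ext2 <- gi_to_gr(expand_merge(islands, shore_bp, chrom_lengths))
  ext4 <- gi_to_gr(expand_merge(islands, shelf_bp, chrom_lengths))
  shore <- GenomicRanges::setdiff(ext2, isl, ignore.strand = TRUE)
  shelf <- GenomicRanges::setdiff(ext4, GenomicRanges::union(ext2, isl, ignore.strand = TRUE),
                                  ignore.strand = TRUE)
  out <- rbind(
    cbind(gr_to_gi(isl), label = rep("island", length(isl))),
    cbind(gr_to_gi(shore), label = rep("shore", length(shore))),
    cbind(gr_to_gi(shelf), label = rep("shelf", length(shelf))))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Promoter intervals from transcription start sites
#'
#' Applies the "2000 bp upstream of the TSS" convention to a TSS BED with
#' strand: upstream is left of the start for `+` and right of the end for
#' `-` features.
#'
#' @param tss intervals carrying strand.
#' @param upstream bp upstream of the TSS (default 2000).
#' @param chrom_lengths optional right-clipping lengths.
#' @return merged promoter intervals.
#' @export
promoters_from_tss <- function(tss, upstream = 2000L, chrom_lengths = NULL) {
  tss <- as_intervals(tss)
  if (nrow(tss) == 0) return(empty_intervals())
  minus <- tss$strand == "-"
  start <- ifelse(minus, tss$end, pmax(tss$start - upstream, 0L))
  end <- ifelse(minus, tss$end + upstream, tss$start)
  ok <- start < end
  expand_merge(genomic_intervals(tss$chrom[ok], start[ok], end[ok]),
               0L, chrom_lengths)
}
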