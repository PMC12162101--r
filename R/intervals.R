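#' Construct a set of genomic intervals
#'
#' Intervals use the BED convention throughout: 0-based, half-open
#' `[start, end)`. This is the substrate of all capture-efficiency
#' analytics and of region filtering.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive start.
#' @param end integer vector, 0-based exclusive end.
#' @param name optional character labels (recycled `NA` if absent).
#' @param strand optional strand, one of `"+"`, `"-"`, `"."`.
#'
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `strand`, one row per interval, of class `genomic_intervals`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              strand = ".") {
  start <- as.integer(start)
  end <- as.integer(end)
  n <- max(length(chrom), length(start))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("chrom, start, end must have equal length")
  if (any(is.na(start)) || any(is.na(end)))
    stop("start/end must be non-missing integers")
  if (any(start < 0L)) stop("negative coordinate")
  if (any(start >= end)) stop("start must be < end (0-based half-open)")
  name <- rep_len(as.character(name), n)
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    name = name, strand = strand,
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' An empty interval set
#'
#' @return a zero-row `genomic_intervals` data.frame.
#' @export
empty_intervals <- function() {
  out <- data.frame(chrom = character(), start = integer(), end = integer(),
                    name = character(), strand = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

as_intervals <- function(x) {
  if (inherits(x, "genomic_intervals")) return(x)
  if (is.data.frame(x)) {
    if (!all(c("chrom", "start", "end") %in% names(x)))
      stop("interval data.frame needs chrom, start, end columns")
    if (nrow(x) == 0) return(empty_intervals())
    return(genomic_intervals(x$chrom, x$start, x$end,
                             if ("name" %in% names(x)) x$name else NA,
                             if ("strand" %in% names(x)) x$strand else "."))
  }
  stop("cannot interpret object as genomic intervals")
}

# Internal bridge to the Bioconductor ranges machinery. GRanges is 1-based
# closed, so [start, end) maps to [start + 1, end].
gi_to_gr <- function(gi, seqlengths = NULL) {
  gi <- as_intervals(gi)
  gr <- GenomicRanges::GRanges(
    seqnames = gi$chrom,
    ranges = IRanges::IRanges(start = gi$start + 1L, end = gi$end)
  )
  if (!is.null(seqlengths)) {
    sl <- seqlengths[GenomeInfoDb_seqlevels(gr)]
    suppressWarnings(GenomicRanges::seqinfo(gr) <-
      GenomicRanges::seqinfo(GenomicRanges::GRanges(
        seqnames = names(sl),
        ranges = IRanges::IRanges(start = 1, width = pmax(sl, 1)))))
  }
  gr
}

GenomeInfoDb_seqlevels <- function(gr) as.character(unique(GenomicRanges::seqnames(gr)))

gr_to_gi <- function(gr, name = NA_character_, strand = ".") {
  if (length(gr) == 0) return(empty_intervals())
  genomic_intervals(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = name, strand = strand
  )
}

# Point sites (0-based positions of the plus-strand C) as length-1 intervals.
sites_to_gi <- function(sites) {
  if (nrow(sites) == 0) return(empty_intervals())
  genomic_intervals(sites$chrom, sites$pos0, sites$pos0 + 1L)
}
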