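#' Parse a cytosine report
#'
#' Reads the Bismark-style CpG/cytosine report dialect: tab-separated lines
#' with at least six columns — chromosome, 1-based position, strand (`+`/`-`),
#' methylated count, unmethylated count, context (`CG`/`CpG`, `CHG`, `CHH`).
#' A seventh trinucleotide column, if present, is ignored.
#'
#' @param source path to a file, or a character vector of lines.
#' @return A `data.frame` with columns `chrom`, `pos1` (1-based), `strand`,
#'   `M`, `U`, `context` (normalized to `CpG`/`CHG`/`CHH`), in input order.
#' @export
parse_cytosine_report <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source))
    readLines(source) else as.character(source)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), pos1 = integer(),
                      strand = character(), M = integer(), U = integer(),
                      context = character(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 6))
    stop(sprintf("cytosine report parse error at line %d: expected >= 6 columns, got %d",
                 which(nf < 6)[1], nf[which(nf < 6)[1]]))
  mat <- t(vapply(fields, function(f) f[1:6], character(6)))
  pos1 <- suppressWarnings(as.integer(mat[, 2]))
  M <- suppressWarnings(as.integer(mat[, 4]))
  U <- suppressWarnings(as.integer(mat[, 5]))
  bad <- which(is.na(pos1) | is.na(M) | is.na(U) | M < 0 | U < 0 | pos1 < 1)
  if (length(bad) > 0)
    stop(sprintf("cytosine report parse error at line %d: non-integer or negative position/count",
                 bad[1]))
  strand <- mat[, 3]
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad) > 0)
    stop(sprintf("cytosine report parse error at line %d: unknown strand '%s'",
                 bad[1], strand[bad[1]]))
  context <- mat[, 6]
  context[context == "CG"] <- "CpG"
  bad <- which(!context %in% c("CpG", "CHG", "CHH"))
  if (length(bad) > 0)
    stop(sprintf("cytosine report parse error at line %d: unknown context '%s'",
                 bad[1], mat[bad[1], 6]))
  data.frame(chrom = mat[, 1], pos1 = pos1, strand = strand,
             M = M, U = U, context = context, stringsAsFactors = FALSE)
}

#' Write a cytosine report
#'
#' @param records data.frame as returned by [parse_cytosine_report()].
#' @param path output path.
#' @export
write_cytosine_report <- function(records, path) {
  ctx <- records$context
  ctx[ctx == "CpG"] <- "CG"
  writeLines(paste(records$chrom, records$pos1, records$strand,
                   records$M, records$U, ctx, sep = "\t"), path)
  invisible(path)
}

#' Parse a BED file
#'
#' BED3/BED6, 0-based half-open. Lines starting with `track`, `browser` or
#' `#` are skipped; columns beyond the sixth are ignored.
#'
#' @param source path to a file, or a character vector of lines.
#' @return A `genomic_intervals` data.frame in input order.
#' @export
parse_bed <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source))
    readLines(source) else as.character(source)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_intervals())
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 lineno[which(nf < 3)[1]]))
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0)
  if (length(bad) > 0)
    stop(sprintf("BED parse error at line %d: negative or non-integer coordinate",
                 lineno[bad[1]]))
  bad <- which(start >= end)
  if (length(bad) > 0)
    stop(sprintf("BED parse error at line %d: start >= end (zero/negative length)",
                 lineno[bad[1]]))
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))],
                                 character(1)), NA_character_)
  strand <- ifelse(nf >= 6, vapply(fields, function(f) f[min(6, length(f))],
                                   character(1)), ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  genomic_intervals(chrom, start, end, name, strand)
}

#' Write intervals as BED
#'
#' BED6 when names or strands are informative, BED3 otherwise.
#'
#' @param gi intervals (`genomic_intervals` or coercible data.frame).
#' @param path output path.
#' @export
write_bed <- function(gi, path) {
  gi <- as_intervals(gi)
  if (nrow(gi) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  use6 <- any(!is.na(gi$name)) || any(gi$strand != ".")
  lines <- if (use6) {
    nm <- ifelse(is.na(gi$name), ".", gi$name)
    paste(gi$chrom, gi$start, gi$end, nm, 0L, gi$strand, sep = "\t")
  } else {
    paste(gi$chrom, gi$start, gi$end, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Collapse CpG records across strands
#'
#' CpG methylation is palindromic: the cytosines of the two strands of one CG
#' dinucleotide report the same epigenetic state. A minus-strand record at
#' 1-based position p belongs to the plus-strand C at p - 1; counts from the
#' two strands are summed and keyed by the 0-based plus-strand C position.
#'
#' @param records cytosine-report data.frame (see [parse_cytosine_report()]).
#' @param context context class to collapse, default `"CpG"`.
#' @return A `data.frame` with columns `chrom`, `pos0`, `M`, `U`, sorted by
#'   chromosome then position, one row per CpG dinucleotide.
#' @export
collapse_strands <- function(records, context = "CpG") {
  rec <- records[records$context == context, , drop = FALSE]
  if (nrow(rec) == 0)
    return(data.frame(chrom = character(), pos0 = integer(),
                      M = integer(), U = integer(), stringsAsFactors = FALSE))
  minus_at_1 <- rec$strand == "-" & rec$pos1 == 1L
  if (any(minus_at_1))
    stop("minus-strand record at position 1 has no plus-strand partner position")
  # plus C at 1-based p -> pos0 = p - 1; minus G-strand C at p -> pos0 = p - 2
  pos0 <- ifelse(rec$strand == "+", rec$pos1 - 1L, rec$pos1 - 2L)
  key <- paste(rec$chrom, pos0, sep = "\r")
  M <- as.integer(rowsum(rec$M, key))
  U <- as.integer(rowsum(rec$U, key))
  keys <- rownames(rowsum(rec$M, key))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, character(1), 1),
                    pos0 = as.integer(vapply(parts, `[`, character(1), 2)),
                    M = M, U = U, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a sample sheet
#'
#' Tab-separated with a header; must contain a `sample` column, and may carry
#' `file`, `group`, `tissue`, `technology`.
#'
#' @param path sample sheet path.
#' @return data.frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(sheet))
    stop("sample sheet must have a 'sample' column")
  if (anyDuplicated(sheet$sample))
    stop("duplicate sample IDs in sample sheet")
  sheet
}

#' Normalize chromosome names
#'
#' Chromosome matching is exact string equality everywhere in the package; this
#' optional helper strips or adds the UCSC-style `chr` prefix when two inputs
#' disagree on it. It is never applied implicitly.
#'
#' @param x character vector of chromosome names.
#' @param style `"strip"` to remove a leading `chr`, `"add"` to ensure one.
#' @export
normalize_chrom <- function(x, style = c("strip", "add")) {
  style <- match.arg(style)
  if (style == "strip") sub("^chr", "", x)
  else ifelse(grepl("^chr", x), x, paste0("chr", x))
}
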