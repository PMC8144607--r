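#' Construct peak ranges from BED-style coordinates
#'
#' Peaks are handled throughout the package as [GenomicRanges::GRanges]
#' objects. On disk and in all user-facing identifiers the package uses BED
#' convention: 0-based, half-open `[start, end)`. This constructor takes BED
#' coordinates and returns the corresponding 1-based closed `GRanges`.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive starts.
#' @param end integer vector, 0-based exclusive ends; must satisfy
#'   `end > start`.
#' @param ... further vectors stored as metadata columns.
#' @return A `GRanges` with one range per input interval.
#' @examples
#' bed_ranges("chrS", c(100, 300), c(200, 450))
#' @export
bed_ranges <- function(chrom, start, end, ...) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be non-missing numbers")
  if (any(start < 0)) stop("BED starts must be >= 0")
  if (any(end <= start)) stop("intervals must satisfy end > start")
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    ...
  )
}

#' Stable peak identifiers
#'
#' Identifiers have the form `"chrom:start-end"` in BED (0-based half-open)
#' coordinates, so they round-trip exactly through BED files.
#'
#' @param gr a `GRanges`.
#' @return Character vector of ids, one per range.
#' @export
peak_id <- function(gr) {
  paste0(
    as.character(GenomicRanges::seqnames(gr)), ":",
    GenomicRanges::start(gr) - 1L, "-",
    GenomicRanges::end(gr)
  )
}

#' Parse peak identifiers back into ranges
#'
#' @param ids character vector of `"chrom:start-end"` ids as produced by
#'   [peak_id()].
#' @return A `GRanges`.
#' @export
parse_peak_id <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("malformed peak ids: ", paste(ids[bad], collapse = ", "))
  bed_ranges(
    chrom = vapply(m, `[`, character(1), 2L),
    start = as.numeric(vapply(m, `[`, character(1), 3L)),
    end = as.numeric(vapply(m, `[`, character(1), 4L))
  )
}

#' Read and write peak BED files
#'
#' Thin wrappers around [rtracklayer::import()]/[rtracklayer::export()].
#' narrowPeak summit columns, if present, are ignored: only the interval is
#' used downstream.
#'
#' @param path file path.
#' @param gr a `GRanges` to write.
#' @return `read_peaks_bed` returns a sorted `GRanges`.
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  S4Vectors::mcols(gr) <- NULL
  GenomicRanges::sort(gr)
}

#' @rdname read_peaks_bed
#' @export
write_peaks_bed <- function(gr, path) {
  out <- gr
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(name = peak_id(gr))
  rtracklayer::export(out, path, format = "BED")
  invisible(path)
}

## internal: canonicalize a peak set (sorted, overlapping runs collapsed;
## abutting intervals are NOT merged — only true overlaps)
canonical_peaks <- function(gr) {
  GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 0L)
}

## internal: GRanges -> per-chromosome list of 0-based half-open
## (start, end) matrices, preserving order within chromosome
as_bed0 <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  split(df[c("start", "end")], df$chrom)
}

## internal: inverse of as_bed0
from_bed0 <- function(lst) {
  if (length(lst) == 0L) return(GenomicRanges::GRanges())
  chrom <- rep(names(lst), vapply(lst, nrow, integer(1)))
  start <- unlist(lapply(lst, `[[`, "start"), use.names = FALSE)
  end <- unlist(lapply(lst, `[[`, "end"), use.names = FALSE)
  GenomicRanges::sort(bed_ranges(chrom, start, end))
}
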