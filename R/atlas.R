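## Cross-patient peak atlas construction.
##
## The atlas is built by an iterative overlap heuristic operating on disjoint
## per-sample peak sets: peaks from the first sample seed the atlas; every
## subsequent peak is resolved against the current atlas peak by peak. For an
## overlapping pair with overlap fraction f = |a intersect b| / min(|a|, |b|):
##   f >  threshold -> the non-overlapping portions of both peaks are removed,
##                     leaving a single unified peak (the intersection);
##   f <= threshold -> the overlapping portion is removed from both peaks,
##                     leaving two separate flanking peaks.
## Products are re-checked against the atlas until no overlap remains, so the
## atlas is disjoint at every step.

## internal merge rule on 0-based half-open scalars; returns a 2-column
## matrix of (start, end) pieces. `a` is the atlas peak, `b` the incoming.
merge_pair0 <- function(as, ae, bs, be, threshold) {
  is <- max(as, bs)
  ie <- min(ae, be)
  ov <- ie - is
  stopifnot(ov > 0)
  f <- ov / min(ae - as, be - bs)
  if (f > threshold) {
    return(matrix(c(is, ie), ncol = 2L))
  }
  pieces <- matrix(numeric(0), ncol = 2L)
  if (is > as) pieces <- rbind(pieces, c(as, is))   # a left of overlap
  if (ae > ie) pieces <- rbind(pieces, c(ie, ae))   # a right of overlap
  if (is > bs) pieces <- rbind(pieces, c(bs, is))   # b left of overlap
  if (be > ie) pieces <- rbind(pieces, c(ie, be))   # b right of overlap
  pieces
}

#' Resolve one overlapping peak pair
#'
#' Applies the atlas overlap heuristic to a single pair of overlapping
#' peaks. With overlap fraction `f = |a intersect b| / min(|a|, |b|)`
#' strictly above `threshold`, the two peaks are unified into their
#' intersection (non-overlapping portions removed); otherwise the
#' overlapping portion is removed from both, producing two separate peaks.
#' `f` exactly at the threshold is treated as *not* merged (the rule is
#' strict).
#'
#' @param a,b single-range `GRanges` on the same chromosome with a
#'   non-empty intersection.
#' @param threshold overlap fraction above which peaks are unified;
#'   default 0.75.
#' @return A `GRanges` of one (unified) or two (separated) peaks.
#' @examples
#' a <- bed_ranges("chrS", 100, 200)
#' b <- bed_ranges("chrS", 110, 205)
#' merge_pair(a, b)          # f = 90/95 > 0.75: unified [110,200)
#' @export
merge_pair <- function(a, b, threshold = 0.75) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (as.character(GenomicRanges::seqnames(a)) !=
      as.character(GenomicRanges::seqnames(b)))
    stop("merge_pair requires peaks on the same chromosome")
  as <- GenomicRanges::start(a) - 1L; ae <- GenomicRanges::end(a)
  bs <- GenomicRanges::start(b) - 1L; be <- GenomicRanges::end(b)
  if (min(ae, be) - max(as, bs) <= 0)
    stop("merge_pair requires overlapping peaks")
  p <- merge_pair0(as, ae, bs, be, threshold)
  p <- p[order(p[, 1L]), , drop = FALSE]
  bed_ranges(as.character(GenomicRanges::seqnames(a)), p[, 1L], p[, 2L])
}

## internal: insert one incoming 0-based peak into sorted disjoint
## (starts, ends) vectors, resolving overlaps until stable
atlas_insert0 <- function(starts, ends, s, e, threshold) {
  work_s <- s
  work_e <- e
  while (length(work_s) > 0L) {
    ps <- work_s[1L]; pe <- work_e[1L]
    work_s <- work_s[-1L]; work_e <- work_e[-1L]
    hit <- which(starts < pe & ends > ps)
    if (length(hit) == 0L) {
      at <- sum(starts < ps)
      starts <- append(starts, ps, after = at)
      ends <- append(ends, pe, after = at)
    } else {
      i <- hit[1L]  # leftmost overlapping atlas peak
      qs <- starts[i]; qe <- ends[i]
      starts <- starts[-i]; ends <- ends[-i]
      pieces <- merge_pair0(qs, qe, ps, pe, threshold)
      work_s <- c(pieces[, 1L], work_s)
      work_e <- c(pieces[, 2L], work_e)
    }
  }
  list(starts = starts, ends = ends)
}

## internal incremental builder state: named list (chrom) of starts/ends
atlas_state_new <- function() list()

atlas_state_add <- function(state, gr, threshold) {
  by_chrom <- as_bed0(canonical_peaks(gr))
  for (chrom in names(by_chrom)) {
    cur <- state[[chrom]]
    if (is.null(cur)) cur <- list(starts = numeric(0), ends = numeric(0))
    df <- by_chrom[[chrom]]
    for (j in seq_len(nrow(df))) {
      cur <- atlas_insert0(cur$starts, cur$ends, df$start[j], df$end[j],
                           threshold)
    }
    state[[chrom]] <- cur
  }
  state
}

atlas_state_size <- function(state) {
  sum(vapply(state, function(x) length(x$starts), integer(1)))
}

atlas_state_granges <- function(state) {
  from_bed0(lapply(state, function(x)
    data.frame(start = x$starts, end = x$ends)))
}

#' Build a cross-patient peak atlas
#'
#' Iterates over samples in the given order; each sample's peaks are
#' resolved against the current atlas with [merge_pair()] until no overlap
#' remains, then inserted. The result is globally disjoint and sorted, and
#' rebuilding the atlas from itself returns it unchanged.
#'
#' @param peak_sets a list of `GRanges` (one per sample), ideally named by
#'   sample id. Each set is canonicalized (sorted, internally merged)
#'   before use.
#' @param threshold overlap fraction for [merge_pair()]; default 0.75.
#' @param min_patients optional integer: if given, atlas peaks overlapped by
#'   the peak sets of fewer than `min_patients` samples are dropped in a
#'   final pass. Default `NULL` (off).
#' @return A sorted, disjoint `GRanges`; `names()` carry [peak_id()]s and
#'   `metadata()$samples` records the contributing sample names.
#' @export
build_atlas <- function(peak_sets, threshold = 0.75, min_patients = NULL) {
  if (methods::is(peak_sets, "GRanges")) peak_sets <- list(peak_sets)
  if (length(peak_sets) == 0L) return(GenomicRanges::GRanges())
  ok <- vapply(peak_sets, methods::is, logical(1), class2 = "GRanges")
  if (!all(ok)) stop("peak_sets must be a list of GRanges")
  state <- atlas_state_new()
  for (gr in peak_sets) state <- atlas_state_add(state, gr, threshold)
  atlas <- atlas_state_granges(state)
  if (!is.null(min_patients) && min_patients > 1L && length(atlas) > 0L) {
    support <- Reduce(`+`, lapply(peak_sets, function(gr) {
      as.integer(GenomicRanges::countOverlaps(
        atlas, canonical_peaks(gr)) > 0L)
    }))
    atlas <- atlas[support >= min_patients]
  }
  names(atlas) <- peak_id(atlas)
  S4Vectors::metadata(atlas)$samples <-
    if (is.null(names(peak_sets))) sprintf("S%02d", seq_along(peak_sets))
    else names(peak_sets)
  atlas
}

#' Reproducible peaks between replicate libraries
#'
#' A simplified reproducibility filter standing in for a full IDR analysis:
#' a peak of `rep1` is retained when its best overlap with any `rep2` peak
#' reaches `intersection / min(lengths) >= min_frac`. Retained peaks keep
#' their `rep1` coordinates. The overlap fraction itself is symmetric in the
#' pair; only the output coordinates are not. With `symmetric = TRUE` the
#' filter is applied in both directions and the union of retained peaks is
#' returned (canonicalized).
#'
#' @param rep1,rep2 `GRanges` replicate peak sets (canonicalized
#'   internally).
#' @param min_frac minimum overlap fraction (non-strict); default 0.5.
#' @param symmetric return the canonical union of both directions.
#' @return A sorted `GRanges`; empty input yields an empty result.
#' @export
reproducible_peaks <- function(rep1, rep2, min_frac = 0.5,
                               symmetric = FALSE) {
  rep1 <- canonical_peaks(rep1)
  rep2 <- canonical_peaks(rep2)
  keep_dir <- function(x, y) {
    if (length(x) == 0L || length(y) == 0L) return(x[0])
    ov <- GenomicRanges::findOverlaps(x, y)
    if (length(ov) == 0L) return(x[0])
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(GenomicRanges::pintersect(x[qi], y[si]))
    f <- w / pmin(GenomicRanges::width(x)[qi], GenomicRanges::width(y)[si])
    keep <- unique(qi[f >= min_frac])
    x[sort(keep)]
  }
  out <- keep_dir(rep1, rep2)
  if (symmetric) out <- canonical_peaks(c(out, keep_dir(rep2, rep1)))
  out
}

#' Drop bottom-quartile samples by reproducible-peak count
#'
#' Samples whose reproducible-peak count falls strictly below the 25th
#' percentile of the cohort's counts are excluded. The percentile is
#' computed with linear interpolation ([stats::quantile()] type 7).
#'
#' @param peak_sets named list of `GRanges`, one per sample.
#' @return The retained subset of `peak_sets`, with attributes
#'   `"dropped"` (names of excluded samples) and `"counts"` (all counts).
#' @export
qc_filter_patients <- function(peak_sets) {
  if (length(peak_sets) < 4L)
    stop("quartile QC requires at least 4 samples")
  counts <- vapply(peak_sets, length, integer(1))
  q25 <- stats::quantile(counts, 0.25, names = FALSE, type = 7)
  keep <- counts >= q25
  out <- peak_sets[keep]
  attr(out, "dropped") <- names(peak_sets)[!keep]
  attr(out, "counts") <- counts
  out
}

#' Saturation analysis of atlas peak discovery
#'
#' Samples are randomly permuted `n_resamples` times; for each permutation
#' the atlas is grown one sample at a time and its size recorded at every
#' prefix. Within a single permutation the curve is non-decreasing by
#' construction of the merge heuristic.
#'
#' @param peak_sets list of `GRanges`, one per sample.
#' @param n_resamples number of random orderings; default 500.
#' @param seed RNG seed for the permutations.
#' @param threshold overlap fraction passed to the atlas builder.
#' @return A data.frame with columns `n_patients`, `mean_peaks`,
#'   `sd_peaks`; the full resample-by-prefix size matrix is attached as
#'   attribute `"sizes"`.
#' @export
saturation_curve <- function(peak_sets, n_resamples = 500, seed = 1,
                             threshold = 0.75) {
  if (n_resamples < 1L) stop("n_resamples must be >= 1")
  n <- length(peak_sets)
  if (n < 1L) stop("need at least one sample")
  set.seed(seed)
  sizes <- matrix(NA_real_, nrow = n_resamples, ncol = n)
  for (r in seq_len(n_resamples)) {
    perm <- sample.int(n)
    state <- atlas_state_new()
    for (k in seq_len(n)) {
      state <- atlas_state_add(state, peak_sets[[perm[k]]], threshold)
      sizes[r, k] <- atlas_state_size(state)
    }
  }
  out <- data.frame(
    n_patients = seq_len(n),
    mean_peaks = colMeans(sizes),
    sd_peaks = apply(sizes, 2L, stats::sd)
  )
  if (n_resamples == 1L) out$sd_peaks <- 0
  attr(out, "sizes") <- sizes
  out
}
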