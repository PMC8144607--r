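## Differential chromatin accessibility over the atlas: fragment counting,
## median-of-ratios normalization, per-peak negative-binomial GLM with
## clinical covariates, signature calling at an |log2FC| / FDR threshold,
## and expression concordance of signature-linked genes.

#' Shift fragment coordinates for the Tn5 insertion offset
#'
#' Tn5 inserts its adapters 9 bp apart, so plus-strand fragments are shifted
#' by +4 bp and minus-strand fragments by -5 bp. The whole interval is
#' shifted; fragment lengths are preserved.
#'
#' @param fragments a `GRanges` with strand set to `+` or `-` on every
#'   range.
#' @return The shifted `GRanges`.
#' @examples
#' fr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(101, 150),
#'                              strand = "+")
#' tn5_shift(fr)  # [104,154) in BED coordinates
#' @export
tn5_shift <- function(fragments) {
  if (length(fragments) == 0L) return(fragments)
  str <- as.character(GenomicRanges::strand(fragments))
  if (any(str == "*"))
    stop("tn5_shift requires stranded fragments (no '*' strand)")
  GenomicRanges::shift(fragments, ifelse(str == "+", 4L, -5L))
}

#' Count fragments over a disjoint peak atlas
#'
#' Each fragment is assigned by its midpoint to at most one atlas peak;
#' because the atlas is disjoint the assignment is unambiguous. The
#' midpoint of a BED interval `[s, e)` is `floor((s + e) / 2)`.
#'
#' @param fragments a named list of `GRanges` (one element per sample), or
#'   a single `GRanges` for a one-sample matrix.
#' @param atlas a disjoint `GRanges`; if unsorted it is sorted with a
#'   warning.
#' @return An integer matrix, atlas peaks (rows, named by [peak_id()]) by
#'   samples (columns).
#' @export
count_fragments <- function(fragments, atlas) {
  if (methods::is(fragments, "GRanges"))
    fragments <- list(sample1 = fragments)
  if (is.null(names(fragments)))
    names(fragments) <- sprintf("S%02d", seq_along(fragments))
  if (GenomicRanges::isDisjoint(atlas) == FALSE)
    stop("atlas must be disjoint")
  srt <- GenomicRanges::sort(atlas)
  if (!all(GenomicRanges::start(atlas) == GenomicRanges::start(srt)) ||
      !all(as.character(GenomicRanges::seqnames(atlas)) ==
           as.character(GenomicRanges::seqnames(srt)))) {
    warning("atlas was unsorted; sorting")
    atlas <- srt
  }
  counts <- vapply(fragments, function(fr) {
    if (length(fr) == 0L) return(integer(length(atlas)))
    s0 <- GenomicRanges::start(fr) - 1L
    e0 <- GenomicRanges::end(fr)
    mid0 <- (s0 + e0) %/% 2L
    mids <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(fr),
      IRanges::IRanges(mid0 + 1L, width = 1L)
    )
    GenomicRanges::countOverlaps(atlas, mids)
  }, integer(length(atlas)))
  counts <- matrix(counts, nrow = length(atlas),
                   dimnames = list(peak_id(atlas), names(fragments)))
  counts
}

#' Median-of-ratios size factors
#'
#' The per-sample factor is the median over peaks of the ratio between the
#' sample's count and the peak's geometric mean across samples; peaks with
#' a zero count in any sample are excluded from the median. If no peak has
#' all-nonzero counts the function falls back to total-count scaling
#' (factors proportional to column sums, geometric mean 1) with a warning.
#'
#' @param counts nonnegative integer matrix, peaks by samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (ncol(counts) == 1L)
    return(stats::setNames(1, colnames(counts)))
  all_pos <- rowSums(counts == 0) == 0L
  if (!any(all_pos)) {
    warning("no peak with nonzero counts in all samples; ",
            "falling back to total-count scaling")
    cs <- colSums(counts)
    if (any(cs == 0)) stop("sample with zero total counts")
    return(stats::setNames(cs / exp(mean(log(cs))), colnames(counts)))
  }
  lc <- log(counts[all_pos, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(exp(lc - geo), 2L, stats::median)
  stats::setNames(sf, colnames(counts))
}

## internal: pooled within-group method-of-moments NB dispersion for one
## peak, on size-factor-normalized counts
mom_dispersion <- function(z, group, floor = 1e-8) {
  est <- vapply(split(z, group), function(x) {
    if (length(x) < 2L) return(NA_real_)
    m <- mean(x)
    if (m <= 0) return(NA_real_)
    (stats::var(x) - m) / m^2
  }, numeric(1))
  est <- est[!is.na(est)]
  if (length(est) == 0L) return(floor)
  max(mean(est), floor)
}

#' Fit a per-peak negative-binomial GLM for differential accessibility
#'
#' For every atlas peak a negative-binomial log-link GLM is fitted with
#' `log(size factor)` offsets and design
#' `~ group + log(nuclear_read_depth) + margin_status`. Dispersion is
#' estimated per peak by a pooled within-group method of moments with a
#' floor of 1e-8 and held fixed during the fit. The group coefficient
#' (recurrent vs non-recurrent) is Wald-tested; `log2fc` is the
#' coefficient divided by `log(2)`.
#'
#' @param counts integer matrix, peaks by samples.
#' @param metadata data.frame with one row per count column: `sample`,
#'   `group` (factor or character with levels non_recurrent / recurrent;
#'   non_recurrent is the reference), `nuclear_read_depth` (positive),
#'   `margin_status` (0/1). Extra columns are ignored.
#' @param sf optional precomputed size factors; default [size_factors()].
#' @param adjust_covariates set `FALSE` to fit the group-only design
#'   (used to quantify confounding).
#' @return A data.frame of class `"diff_result"` with columns `peak_id`,
#'   `base_mean`, `log2fc`, `se`, `stat`, `pvalue`, `padj` (BH over all
#'   tested peaks), `direction`. Peaks where the fit fails carry `NA`
#'   statistics.
#' @export
fit_nb_glm <- function(counts, metadata, sf = NULL,
                       adjust_covariates = TRUE) {
  counts <- as.matrix(counts)
  if (nrow(metadata) != ncol(counts))
    stop("metadata must have one row per count column")
  if (!is.null(metadata$sample) && !is.null(colnames(counts)) &&
      !all(metadata$sample == colnames(counts)))
    stop("metadata sample order does not match count columns")
  group <- factor(metadata$group, levels = c("non_recurrent", "recurrent"))
  if (any(is.na(group))) stop("group labels must be non_recurrent/recurrent")
  if (min(table(group)) < 2L) stop("need >= 2 samples per group")
  if (is.null(sf)) sf <- size_factors(counts)
  off <- log(sf)
  dat <- data.frame(
    group = group,
    log_depth = log(metadata$nuclear_read_depth),
    margin = metadata$margin_status
  )
  form <- if (adjust_covariates) y ~ group + log_depth + margin
          else y ~ group
  n_peaks <- nrow(counts)
  log2fc <- se <- stat <- pvalue <- base_mean <- rep(NA_real_, n_peaks)
  for (i in seq_len(n_peaks)) {
    y <- counts[i, ]
    z <- y / sf
    base_mean[i] <- mean(z)
    if (all(y == 0)) next
    alpha <- mom_dispersion(z, group)
    fit <- tryCatch({
      theta <- min(1 / alpha, 1e8)
      dat$y <- y
      suppressWarnings(stats::glm(
        form, data = dat, offset = off,
        family = MASS::negative.binomial(theta = theta, link = "log")
      ))
    }, error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    sm <- suppressWarnings(summary(fit, dispersion = 1))
    co <- sm$coefficients
    if (!"grouprecurrent" %in% rownames(co)) next
    b <- co["grouprecurrent", "Estimate"]
    s <- co["grouprecurrent", "Std. Error"]
    log2fc[i] <- b / log(2)
    se[i] <- s / log(2)
    stat[i] <- b / s
    pvalue[i] <- 2 * stats::pnorm(-abs(stat[i]))
  }
  padj <- rep(NA_real_, n_peaks)
  tested <- !is.na(pvalue)
  padj[tested] <- stats::p.adjust(pvalue[tested], method = "BH")
  res <- data.frame(
    peak_id = rownames(counts) %||% sprintf("peak%05d", seq_len(n_peaks)),
    base_mean = base_mean,
    log2fc = log2fc, se = se, stat = stat,
    pvalue = pvalue, padj = padj,
    direction = ifelse(is.na(log2fc), NA_character_,
                       ifelse(log2fc > 0, "open_in_recurrent",
                              "open_in_nonrecurrent")),
    stringsAsFactors = FALSE
  )
  class(res) <- c("diff_result", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Call the differential accessibility signature
#'
#' Benjamini-Hochberg adjustment is (re)applied across all tested peaks;
#' a peak enters the signature when `|log2fc| > lfc_threshold` (strict)
#' and `padj < fdr` (strict), then the signature is split by sign.
#'
#' @param results a [fit_nb_glm()] result.
#' @param lfc_threshold absolute log2 fold-change cutoff; default 1.
#' @param fdr adjusted-p cutoff; default 0.001.
#' @return A list of class `"signature"`: `open_in_recurrent` and
#'   `open_in_nonrecurrent` (character vectors of peak ids), and `table`
#'   (the results restricted to signature peaks, with refreshed `padj`).
#' @export
call_differential <- function(results, lfc_threshold = 1, fdr = 0.001) {
  if (nrow(results) == 0L)
    return(structure(list(open_in_recurrent = character(0),
                          open_in_nonrecurrent = character(0),
                          table = results), class = "signature"))
  tested <- !is.na(results$pvalue)
  results$padj <- NA_real_
  results$padj[tested] <- stats::p.adjust(results$pvalue[tested],
                                          method = "BH")
  hit <- tested & abs(results$log2fc) > lfc_threshold &
    results$padj < fdr
  structure(list(
    open_in_recurrent = results$peak_id[hit & results$log2fc > 0],
    open_in_nonrecurrent = results$peak_id[hit & results$log2fc < 0],
    table = results[hit, , drop = FALSE]
  ), class = "signature")
}

#' Map peaks to their nearest gene TSS
#'
#' Distance is measured from the peak midpoint to the transcription start
#' site; ties are broken toward the gene with the smaller TSS coordinate.
#'
#' @param peaks a `GRanges` or character vector of [peak_id()]s.
#' @param genes data.frame with columns `gene`, `chrom`, `tss` (0-based
#'   coordinate of the TSS).
#' @return Character vector of gene names (NA where the peak's chromosome
#'   has no annotated gene), one per peak.
#' @export
nearest_gene <- function(peaks, genes) {
  if (is.character(peaks)) peaks <- parse_peak_id(peaks)
  stopifnot(all(c("gene", "chrom", "tss") %in% names(genes)))
  s0 <- GenomicRanges::start(peaks) - 1L
  e0 <- GenomicRanges::end(peaks)
  mid <- (s0 + e0) %/% 2L
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  out <- rep(NA_character_, length(peaks))
  for (ch in unique(chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0L) next
    g <- g[order(g$tss, g$gene), , drop = FALSE]
    idx <- which(chrom == ch)
    pos <- mid[idx]
    right <- findInterval(pos, g$tss) + 1L    # first TSS >= pos (approx)
    left <- right - 1L
    pick <- vapply(seq_along(pos), function(j) {
      cand <- c(left[j], right[j])
      cand <- cand[cand >= 1L & cand <= nrow(g)]
      d <- abs(g$tss[cand] - pos[j])
      best <- cand[d == min(d)]
      # equidistant TSSs: smaller coordinate wins (g sorted by tss)
      best[1L]
    }, integer(1))
    out[idx] <- g$gene[pick]
  }
  out
}

#' Expression concordance of signature-linked genes
#'
#' Genes nearest to differentially closed peaks (open in non-recurrent,
#' i.e. closed in recurrent tumors) and genes nearest to differentially
#' open peaks are each compared with genes nearest to unchanged peaks by
#' a two-sided two-sample Kolmogorov-Smirnov test on expression log2 fold
#' changes.
#'
#' @param signature a [call_differential()] result.
#' @param expression_lfc data.frame with columns `gene`, `log2fc`
#'   (expression, recurrent vs non-recurrent).
#' @param genes gene annotation as for [nearest_gene()].
#' @param atlas the atlas `GRanges` (source of the unchanged background
#'   peaks).
#' @return A list with elements `closed` and `open`, each a list
#'   `(D, p, n_signature, n_background)`.
#' @export
expression_concordance <- function(signature, expression_lfc, genes,
                                   atlas) {
  ids <- peak_id(atlas)
  sig_ids <- c(signature$open_in_recurrent, signature$open_in_nonrecurrent)
  unchanged <- setdiff(ids, sig_ids)
  lfc_of <- function(peak_ids) {
    if (length(peak_ids) == 0L) return(numeric(0))
    gs <- nearest_gene(peak_ids, genes)
    gs <- unique(gs[!is.na(gs)])
    expression_lfc$log2fc[match(gs, expression_lfc$gene)] |>
      stats::na.omit() |> as.numeric()
  }
  bg <- lfc_of(unchanged)
  if (length(bg) == 0L) stop("no mappable background genes")
  one <- function(peak_ids) {
    x <- lfc_of(peak_ids)
    if (length(x) == 0L) stop("no mappable signature genes")
    kt <- suppressWarnings(stats::ks.test(x, bg))
    list(D = unname(kt$statistic), p = kt$p.value,
         n_signature = length(x), n_background = length(bg))
  }
  list(closed = one(signature$open_in_nonrecurrent),
       open = one(signature$open_in_recurrent))
}
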