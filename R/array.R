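## ATAC-array: two-channel normalization, probe-class medians, the
## Prognosis Score and its variants, the RED/BLUE t-test sample call, and
## correlation with ATAC-seq.
##
## Probe classes: RED = regions open in recurrent tumors, BLUE = open in
## non-recurrent tumors, GREEN = positive controls open in all tumors,
## BLACK = aCGH backbone negative controls. The Prognosis Score of a
## sample is BLUE / (CTRL - CGH): the BLUE class median normalized by the
## difference between positive (GREEN) and negative (BLACK) control
## medians. Above-median scores mark good prognosis.

PROBE_CLASSES <- c("RED", "BLUE", "GREEN", "BLACK")

#' Validate a probe table
#'
#' @param probes data.frame with columns `probe_id`, `class` and
#'   optionally `chrom`, `start`, `end`, `region_id`. Classes must be
#'   among RED, BLUE, GREEN, BLACK; RED/BLUE probes must carry a
#'   `region_id` while BLACK probes must not.
#' @return The validated data.frame, with a class-count attribute
#'   `"class_counts"`.
#' @export
probe_set <- function(probes) {
  stopifnot(all(c("probe_id", "class") %in% names(probes)))
  if (anyDuplicated(probes$probe_id)) stop("duplicate probe ids")
  bad <- setdiff(unique(probes$class), PROBE_CLASSES)
  if (length(bad) > 0L)
    stop("unknown probe classes: ", paste(bad, collapse = ", "))
  if ("region_id" %in% names(probes)) {
    sig <- probes$class %in% c("RED", "BLUE")
    if (any(sig & is.na(probes$region_id)))
      stop("RED/BLUE probes must map to a signature region")
    if (any(probes$class == "BLACK" & !is.na(probes$region_id)))
      stop("BLACK backbone probes must not map to a signature region")
  }
  attr(probes, "class_counts") <- table(factor(probes$class,
                                               levels = PROBE_CLASSES))
  probes
}

#' Design probes tiling signature regions
#'
#' Plumbing for building a probe table from class-labeled regions: each
#' region is tiled with fixed-length probes at a fixed step, clipped to
#' the region.
#'
#' @param regions data.frame with columns `region_id`, `chrom`, `start`,
#'   `end` (BED convention) and `class`.
#' @param probe_length probe length in bp; default 60.
#' @param step distance between probe starts; default `probe_length`.
#' @return A probe table as accepted by [probe_set()].
#' @export
design_probes <- function(regions, probe_length = 60, step = probe_length) {
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    starts <- seq(r$start, max(r$start, r$end - probe_length), by = step)
    data.frame(
      probe_id = sprintf("%s_p%d", r$region_id, seq_along(starts)),
      chrom = r$chrom,
      start = starts,
      end = pmin(starts + probe_length, r$end),
      class = r$class,
      region_id = r$region_id,
      stringsAsFactors = FALSE
    )
  })
  probe_set(do.call(rbind, rows))
}

#' Normalize a two-channel array scan
#'
#' Hybridization efficiency is controlled by the reference gDNA channel:
#' the normalized per-probe intensity is the linear ratio `cy5 / cy3`
#' (`log2 = TRUE` returns log2 ratios instead). Probes with `cy3 <= 0`
#' are dropped with a warning and their count reported.
#'
#' @param scan data.frame with columns `probe_id`, `cy5`, `cy3`.
#' @param log2 return log2 ratios; default `FALSE` (linear).
#' @return data.frame (probe_id, value) with attribute `"n_dropped"`.
#' @export
normalize_scan <- function(scan, log2 = FALSE) {
  stopifnot(all(c("probe_id", "cy5", "cy3") %in% names(scan)))
  bad <- !is.finite(scan$cy3) | scan$cy3 <= 0
  if (any(bad))
    warning(sum(bad), " probe(s) with nonpositive Cy3 dropped")
  scan <- scan[!bad, , drop = FALSE]
  value <- scan$cy5 / scan$cy3
  if (log2) value <- base::log2(value)
  out <- data.frame(probe_id = scan$probe_id, value = value,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Probe-class median intensities
#'
#' @param normalized a [normalize_scan()] result.
#' @param probes a [probe_set()] table.
#' @return A list of class `"class_medians"` with elements `CTRL` (GREEN
#'   median), `CGH` (BLACK median), `BLUE` and `RED`. The median of an
#'   even number of probes is the mean of the central pair
#'   ([stats::median()]). An empty class is an error naming the class.
#' @export
class_medians <- function(normalized, probes) {
  cls <- probes$class[match(normalized$probe_id, probes$probe_id)]
  if (anyNA(cls)) stop("scan contains probes absent from the probe table")
  med <- function(class_name) {
    v <- normalized$value[cls == class_name]
    if (length(v) == 0L) stop("no probes in class ", class_name)
    stats::median(v)
  }
  structure(list(CTRL = med("GREEN"), CGH = med("BLACK"),
                 BLUE = med("BLUE"), RED = med("RED")),
            class = "class_medians")
}

#' ATAC-array Prognosis Score
#'
#' `blue_score = BLUE / (CTRL - CGH)` (the Prognosis Score), with the
#' variants `red_score = RED / (CTRL - CGH)` and
#' `diff_score = (BLUE - RED) / (CTRL - CGH)`.
#'
#' @param m a [class_medians()] result.
#' @return A list of class `"prognosis_score"` with `blue_score`,
#'   `red_score`, `diff_score`.
#' @export
prognosis_score <- function(m) {
  stopifnot(inherits(m, "class_medians"))
  denom <- m$CTRL - m$CGH
  if (denom <= 0)
    stop("positive-control failure: CTRL median must exceed CGH median")
  structure(list(
    blue_score = m$BLUE / denom,
    red_score = m$RED / denom,
    diff_score = (m$BLUE - m$RED) / denom
  ), class = "prognosis_score")
}

#' Convenience: score one scan end to end
#'
#' @param scan,probes as in [normalize_scan()] / [class_medians()].
#' @return A [prognosis_score()] result.
#' @export
score_scan <- function(scan, probes) {
  prognosis_score(class_medians(normalize_scan(scan), probes))
}

#' Median-split patient classification
#'
#' Patients with a Prognosis Score above the cohort median (or an
#' externally supplied median) are called good prognosis, below it poor.
#' A score exactly at the median is assigned to the good group and
#' flagged as a tie; if all scores are identical every call is flagged
#' indeterminate.
#'
#' @param scores named numeric vector of blue scores (names = patients).
#' @param cohort_median optional externally supplied split value; default
#'   `median(scores)`.
#' @return data.frame (patient, score, call, tie).
#' @export
classify_patients <- function(scores, cohort_median = NULL) {
  if (is.null(cohort_median) && length(scores) < 2L)
    stop("need >= 2 patients or an externally supplied median")
  m <- cohort_median %||% stats::median(scores)
  if (length(unique(scores)) == 1L && is.null(cohort_median)) {
    return(data.frame(patient = names(scores), score = unname(scores),
                      call = "indeterminate", tie = TRUE,
                      stringsAsFactors = FALSE))
  }
  call <- ifelse(scores > m, "good", ifelse(scores < m, "poor", "good"))
  data.frame(patient = names(scores) %||% seq_along(scores),
             score = unname(scores), call = unname(call),
             tie = unname(scores == m), stringsAsFactors = FALSE)
}

#' RED/BLUE t-test sample call
#'
#' Welch's two-sample t-test between the RED and BLUE probe log2-ratio
#' distributions. The sample is called `"blue"` (good prognosis) when the
#' BLUE median exceeds the RED median with p < `alpha`, `"red"` (poor)
#' in the opposite case, and `"indeterminate"` otherwise. If both classes
#' are degenerate (zero variance), medians are compared directly.
#'
#' @param normalized a [normalize_scan()] result on the *linear* scale
#'   (log2 is taken internally).
#' @param probes a [probe_set()] table.
#' @param alpha significance level; default 0.05.
#' @return A list (call, p, median_blue, median_red) on the log2 scale.
#' @export
red_blue_ttest_call <- function(normalized, probes, alpha = 0.05) {
  cls <- probes$class[match(normalized$probe_id, probes$probe_id)]
  lv <- base::log2(normalized$value)
  blue <- lv[cls == "BLUE" & is.finite(lv)]
  red <- lv[cls == "RED" & is.finite(lv)]
  if (length(blue) < 2L || length(red) < 2L)
    stop("need >= 2 probes in each of RED and BLUE")
  mb <- stats::median(blue)
  mr <- stats::median(red)
  if (stats::sd(blue) == 0 && stats::sd(red) == 0) {
    p <- if (mb == mr) 1 else 0   # zero-variance shortcut
  } else {
    p <- stats::t.test(blue, red)$p.value
  }
  call <- if (p < alpha && mb > mr) "blue"
          else if (p < alpha && mr > mb) "red"
          else "indeterminate"
  list(call = call, p = p, median_blue = mb, median_red = mr)
}

#' Spearman correlation of region-level array and ATAC-seq signal
#'
#' Mid-rank Spearman correlation with a Fisher-z confidence interval and
#' a two-sided p-value (normal approximation through [stats::cor.test()]
#' when ties are present).
#'
#' @param array_values,seq_values paired numeric vectors, one value per
#'   region (the array value per region is conventionally the median over
#'   its probes).
#' @param conf confidence level; default 0.95.
#' @return A list (rho, ci, p, n).
#' @export
correlate_with_atacseq <- function(array_values, seq_values,
                                   conf = 0.95) {
  ok <- is.finite(array_values) & is.finite(seq_values)
  x <- array_values[ok]
  y <- seq_values[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 paired regions")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  rho <- unname(ct$estimate)
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  list(rho = rho, ci = tanh(c(z - q * se, z + q * se)),
       p = ct$p.value, n = n)
}

#' Aggregate probe values to region level
#'
#' @param normalized a [normalize_scan()] result.
#' @param probes a [probe_set()] table with `region_id`.
#' @return Named numeric vector of per-region medians (signature regions
#'   only).
#' @export
region_medians <- function(normalized, probes) {
  idx <- match(normalized$probe_id, probes$probe_id)
  reg <- probes$region_id[idx]
  keep <- !is.na(reg)
  vapply(split(normalized$value[keep], reg[keep]), stats::median,
         numeric(1))
}

#' Read and write probe/scan/clinical TSV tables
#'
#' Plain-TSV readers matching the writers in the synthetic-data module
#' and the tabular output of array feature extraction.
#'
#' @param path file path.
#' @return A data.frame.
#' @export
read_probes_tsv <- function(path) {
  probe_set(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_probes_tsv
#' @export
read_scan_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_probes_tsv
#' @export
read_clinical_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
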