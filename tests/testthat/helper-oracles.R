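# Independent oracles used across the suite. These deliberately re-derive
# results from first principles with different code paths and data
# structures than the package implementation.

# --- atlas: naive sequential re-application of the published merge rule ---
# peaks as plain data.frames of 0-based half-open (start, end); single
# chromosome. The atlas is a data.frame kept sorted by start; every incoming
# peak is resolved by literal application of the rule, re-checking products
# until nothing overlaps.
oracle_atlas <- function(peak_dfs, threshold = 0.75) {
  atlas <- data.frame(start = numeric(0), end = numeric(0))
  for (df in peak_dfs) {
    df <- df[order(df$start), , drop = FALSE]
    for (r in seq_len(nrow(df))) {
      queue <- list(c(df$start[r], df$end[r]))
      while (length(queue) > 0L) {
        p <- queue[[1L]]
        queue <- queue[-1L]
        ov <- which(atlas$start < p[2] & atlas$end > p[1])
        if (length(ov) == 0L) {
          atlas <- rbind(atlas, data.frame(start = p[1], end = p[2]))
          atlas <- atlas[order(atlas$start), , drop = FALSE]
          next
        }
        i <- ov[which.min(atlas$start[ov])]
        a <- c(atlas$start[i], atlas$end[i])
        atlas <- atlas[-i, , drop = FALSE]
        ints <- c(max(a[1], p[1]), min(a[2], p[2]))
        f <- (ints[2] - ints[1]) / min(a[2] - a[1], p[2] - p[1])
        pieces <- if (f > threshold) {
          list(ints)
        } else {
          out <- list()
          if (ints[1] > a[1]) out <- c(out, list(c(a[1], ints[1])))
          if (a[2] > ints[2]) out <- c(out, list(c(ints[2], a[2])))
          if (ints[1] > p[1]) out <- c(out, list(c(p[1], ints[1])))
          if (p[2] > ints[2]) out <- c(out, list(c(ints[2], p[2])))
          out
        }
        queue <- c(pieces, queue)
      }
    }
  }
  rownames(atlas) <- NULL
  atlas[order(atlas$start), , drop = FALSE]
}

# random small peak configurations for oracle equivalence checks
random_peak_config <- function(max_peaks = 6, max_sets = 3, span = 40) {
  n_sets <- sample.int(max_sets, 1L)
  total <- sample.int(max_peaks, 1L)
  alloc <- tabulate(sample.int(n_sets, total, replace = TRUE), n_sets)
  lapply(alloc, function(k) {
    if (k == 0L) return(data.frame(start = numeric(0), end = numeric(0)))
    s <- sample.int(span, k, replace = TRUE) - 1L
    w <- sample.int(12, k, replace = TRUE)
    df <- data.frame(start = s, end = s + w)
    # peak sets are canonical: merge overlapping peaks within a set
    df <- df[order(df$start), , drop = FALSE]
    keep <- data.frame(start = numeric(0), end = numeric(0))
    for (i in seq_len(nrow(df))) {
      if (nrow(keep) > 0L && df$start[i] <= keep$end[nrow(keep)]) {
        keep$end[nrow(keep)] <- max(keep$end[nrow(keep)], df$end[i])
      } else {
        keep <- rbind(keep, df[i, ])
      }
    }
    rownames(keep) <- NULL
    keep
  })
}

grl_from_dfs <- function(dfs, chrom = "chrS") {
  lapply(dfs, function(df) {
    if (nrow(df) == 0L) return(GenomicRanges::GRanges())
    bed_ranges(chrom, df$start, df$end)
  })
}

atlas_as_df <- function(gr) {
  data.frame(start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr))
}

# --- survival: first-principles O/E log-rank oracle ---------------------
# walks individual event times, computing observed, expected and
# hypergeometric variance with scalar arithmetic only (two groups).
oracle_logrank <- function(time, event, group) {
  g1 <- levels(factor(group))[1L]
  O1 <- 0; E1 <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(chisq = (O1 - E1)^2 / V, O1 = O1, E1 = E1, V = V)
}

# --- ridge: numerical minimizer of the penalized objective --------------
# minimizes ||y - X b||^2 + lambda ||b||^2 over b by BFGS with exact
# gradient, on whatever scale X is supplied.
oracle_ridge <- function(X, y, lambda) {
  obj <- function(b) sum((y - X %*% b)^2) + lambda * sum(b^2)
  grad <- function(b) drop(-2 * crossprod(X, y - X %*% b) + 2 * lambda * b)
  stats::optim(rep(0, ncol(X)), obj, grad, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}

# empirical survival function (no censoring): fraction of subjects with
# time > t
empirical_survival <- function(times, t) mean(times > t)
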