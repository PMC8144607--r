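make_fragments <- function(chrom, starts, ends, strands) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts + 1L, ends),
                         strand = strands)
}

test_that("tn5_shift moves +4 / -5 by strand and preserves lengths", {
  fr <- make_fragments("chrS", c(100, 100), c(150, 150), c("+", "-"))
  sh <- tn5_shift(fr)
  expect_equal(GenomicRanges::start(sh) - 1L, c(104, 95))
  expect_equal(GenomicRanges::end(sh), c(154, 145))
  expect_equal(GenomicRanges::width(sh), GenomicRanges::width(fr))
  expect_equal(length(tn5_shift(fr[0])), 0L)
  expect_error(tn5_shift(GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(1, 10))), "strand")
})

test_that("count_fragments assigns by midpoint to the unique covering peak", {
  atlas <- bed_ranges("chrS", c(100, 300), c(200, 400))
  # midpoints: (100+150)/2 = 125 -> peak 1; (180+260)/2 = 220 -> none;
  # (290+320)/2 = 305 -> peak 2
  fr <- make_fragments("chrS", c(100, 180, 290), c(150, 260, 320),
                       rep("+", 3))
  m <- count_fragments(list(s1 = fr), atlas)
  expect_equal(unname(m[, "s1"]), c(1L, 1L))
  # 10 fragments tiling one peak, 5 fully outside: column sum is 10
  inside <- make_fragments("chrS", 100 + (0:9) * 10, 110 + (0:9) * 10,
                           rep("+", 10))
  outside <- make_fragments("chrS", 500 + (0:4) * 10, 540 + (0:4) * 10,
                            rep("+", 5))
  m2 <- count_fragments(list(s1 = c(inside, outside)),
                        bed_ranges("chrS", 100, 220))
  expect_equal(sum(m2), 10L)
  expect_warning(count_fragments(list(s1 = fr), rev(atlas)), "unsorted")
})

test_that("size factors follow median-of-ratios with documented fallback", {
  counts <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
                   dimnames = list(NULL, c("a", "b")))
  sf <- size_factors(counts)
  # column 2 = 2 x column 1: factors (1/sqrt(2), sqrt(2))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # identical columns: all factors 1
  expect_equal(unname(size_factors(cbind(counts[, 1], counts[, 1]))),
               c(1, 1))
  # single sample: factor 1
  expect_equal(unname(size_factors(counts[, 1, drop = FALSE])), 1)
  # no all-nonzero peak: total-count fallback with warning
  z <- matrix(c(0, 5, 5, 0), ncol = 2)
  expect_warning(sfz <- size_factors(z), "total-count")
  expect_equal(prod(sfz), 1, tolerance = 1e-12)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(8)
  counts <- matrix(rnbinom(600, mu = 50, size = 10), ncol = 6)
  counts[1, 1] <- 0  # exercise the all-nonzero filter
  expect_equal(unname(size_factors(counts)),
               unname(DESeq2::estimateSizeFactorsForMatrix(counts)),
               tolerance = 1e-10)
})

test_that("NB GLM recovers planted fold changes in the Poisson limit", {
  cfg <- simulation_config(n_patients = 40, frac_recurrent = 0.5,
                           n_atlas_peaks = 200, n_diff_open_recurrent = 40,
                           n_diff_open_nonrecurrent = 40, dispersion = 0,
                           base_mean = 200, planted_lfc = 2, seed = 11)
  co <- simulate_cohort(cfg)
  atlas <- bed_ranges("chrS", (0:199) * 1000, (0:199) * 1000 + 500)
  sim <- simulate_counts_and_motifs(co, atlas, cfg)
  res <- fit_nb_glm(sim$counts, sim$metadata)
  tr <- sim$truth$diff_peaks
  est <- res$log2fc[match(tr$peak_id, res$peak_id)]
  expect_lt(mean(abs(est - tr$lfc)), 0.1)
  expect_equal(mean(est[tr$lfc > 0]), 2, tolerance = 0.1)
  expect_equal(mean(est[tr$lfc < 0]), -2, tolerance = 0.1)
  # direction labels consistent with sign
  expect_true(all(res$direction[!is.na(res$log2fc) & res$log2fc > 0] ==
                    "open_in_recurrent"))
})

test_that("NB GLM is null on equal group means and adjusts for confounding", {
  cfg <- simulation_config(n_patients = 20, frac_recurrent = 0.5,
                           n_atlas_peaks = 150, n_diff_open_recurrent = 1,
                           n_diff_open_nonrecurrent = 1, planted_lfc = 0,
                           base_mean = 200, seed = 17)
  co <- simulate_cohort(cfg)
  atlas <- bed_ranges("chrS", (0:149) * 1000, (0:149) * 1000 + 500)
  sim <- simulate_counts_and_motifs(co, atlas, cfg)
  res <- fit_nb_glm(sim$counts, sim$metadata)
  expect_lt(abs(mean(res$log2fc, na.rm = TRUE)), 0.1)
  expect_gt(stats::ks.test(stats::na.omit(res$pvalue), "punif")$p.value,
            0.001)

  # confounded design: a depth gradient aligned with group fully explains
  # a marginal difference; adjustment should remove it
  set.seed(23)
  n <- 20
  grp <- rep(c("non_recurrent", "recurrent"), each = n / 2)
  # depth varies within group (so the slope is identifiable) but is
  # shifted between groups (so it confounds the marginal contrast)
  depth <- rlnorm(n, meanlog = log(ifelse(grp == "recurrent", 4e7, 1e7)),
                  sdlog = 0.5)
  mu <- 100 * (depth / 2e7)  # counts driven by depth only
  counts <- matrix(rpois(100 * n, rep(mu, each = 100)), nrow = 100)
  rownames(counts) <- sprintf("p%03d", 1:100)
  md <- data.frame(sample = sprintf("s%02d", 1:n), group = grp,
                   nuclear_read_depth = depth, margin_status = 0L)
  sf1 <- rep(1, n)
  adj <- fit_nb_glm(counts, md, sf = sf1)
  unadj <- fit_nb_glm(counts, md, sf = sf1, adjust_covariates = FALSE)
  expect_gt(abs(mean(unadj$log2fc, na.rm = TRUE)), 1)
  expect_lt(abs(mean(adj$log2fc, na.rm = TRUE)), 0.2)
})

test_that("label swap negates every log2 fold change", {
  cfg <- simulation_config(n_patients = 12, frac_recurrent = 0.5,
                           n_atlas_peaks = 60, n_diff_open_recurrent = 10,
                           n_diff_open_nonrecurrent = 10, seed = 29)
  co <- simulate_cohort(cfg)
  atlas <- bed_ranges("chrS", (0:59) * 1000, (0:59) * 1000 + 500)
  sim <- simulate_counts_and_motifs(co, atlas, cfg)
  res <- fit_nb_glm(sim$counts, sim$metadata)
  md2 <- sim$metadata
  md2$group <- factor(ifelse(md2$group == "recurrent", "non_recurrent",
                             "recurrent"),
                      levels = c("non_recurrent", "recurrent"))
  res2 <- fit_nb_glm(sim$counts, md2)
  expect_equal(res2$log2fc, -res$log2fc, tolerance = 1e-6)
})

test_that("signature calling applies BH and strict thresholds", {
  res <- data.frame(
    peak_id = c("a", "b", "c"),
    base_mean = 10, log2fc = c(2, -3, 0.2), se = 0.1, stat = 1,
    pvalue = c(0.0001, 0.0006, 0.9), padj = NA_real_,
    direction = c("open_in_recurrent", "open_in_nonrecurrent",
                  "open_in_recurrent"),
    stringsAsFactors = FALSE
  )
  sig <- call_differential(res, lfc_threshold = 1, fdr = 0.001)
  # hand BH on (0.0001, 0.0006, 0.9), m = 3: (0.0003, 0.0009, 0.9)
  expect_equal(sig$table$padj, c(0.0003, 0.0009), tolerance = 1e-12)
  expect_equal(sig$open_in_recurrent, "a")
  expect_equal(sig$open_in_nonrecurrent, "b")
  # log2fc exactly 1 is excluded (strict > 1)
  res$log2fc <- c(1, -3, 0.2)
  sig2 <- call_differential(res)
  expect_equal(length(sig2$open_in_recurrent), 0L)
  # all raw p = 1: empty signature
  res$pvalue <- rep(1, 3)
  expect_equal(nrow(call_differential(res)$table), 0L)
  # BH monotonicity and padj >= p on random p-vectors
  set.seed(31)
  p <- runif(50)
  res3 <- data.frame(peak_id = sprintf("x%02d", 1:50), base_mean = 1,
                     log2fc = 2, se = 1, stat = 1, pvalue = p,
                     padj = NA_real_, direction = "open_in_recurrent",
                     stringsAsFactors = FALSE)
  out <- call_differential(res3, lfc_threshold = 0, fdr = 1.01)
  expect_true(all(out$table$padj >= out$table$pvalue))
  o <- order(out$table$pvalue)
  expect_true(all(diff(out$table$padj[o]) >= -1e-12))
})

test_that("nearest_gene measures TSS distance and breaks ties low", {
  genes <- data.frame(gene = c("gL", "gR"), chrom = "chrS",
                      tss = c(100, 300))
  # peak [140,260) has midpoint 200, equidistant from both: lower wins
  expect_equal(nearest_gene("chrS:140-260", genes), "gL")
  expect_equal(nearest_gene("chrS:150-260", genes), "gR")  # mid 205
  expect_equal(nearest_gene("chrS:0-100", genes), "gL")
  expect_true(is.na(nearest_gene("chrX:0-100", genes)))
})

test_that("expression concordance detects a planted downshift", {
  # geometry: one gene per peak, signature genes shifted down by 1 sd
  set.seed(37)
  n_sig <- 200; n_bg <- 400
  atlas <- bed_ranges("chrS", (0:(n_sig + n_bg - 1)) * 1000,
                      (0:(n_sig + n_bg - 1)) * 1000 + 500)
  ids <- peak_id(atlas)
  genes <- data.frame(gene = sprintf("g%04d", seq_along(ids)),
                      chrom = "chrS",
                      tss = (seq_along(ids) - 1) * 1000 + 250)
  sig <- structure(list(open_in_recurrent = character(0),
                        open_in_nonrecurrent = ids[1:n_sig],
                        table = NULL), class = "signature")
  lfc <- data.frame(gene = genes$gene,
                    log2fc = c(rnorm(n_sig, -1), rnorm(n_bg, 0)))
  cc <- expression_concordance(
    structure(list(open_in_recurrent = ids[n_sig + 1:5],
                   open_in_nonrecurrent = ids[1:n_sig]),
              class = "signature"),
    lfc, genes, atlas)
  expect_gt(cc$closed$D, 0.3)
  expect_lt(cc$closed$p, 1e-3)
  # identical distributions: D ~ 0, p large
  lfc0 <- data.frame(gene = genes$gene, log2fc = rnorm(nrow(genes)))
  cc0 <- expression_concordance(
    structure(list(open_in_recurrent = ids[1:100],
                   open_in_nonrecurrent = ids[101:200]),
              class = "signature"),
    lfc0, genes, atlas)
  expect_gt(cc0$open$p, 0.01)
})

test_that("KS p-value for a singleton set matches exact enumeration", {
  # one signature gene against a small background: enumerate all
  # placements of the singleton among the pooled values
  x <- 0.31
  bg <- c(-1.2, -0.4, 0.8, 1.5)
  kt <- suppressWarnings(stats::ks.test(x, bg))
  # enumeration oracle: under the null each insertion position of the
  # singleton is equally likely; D for position k is max(k/m, 1 - (k-1)/m)?
  # compute D directly for every possible rank of x among bg
  m <- length(bg)
  # D given k background values below the singleton: the singleton ECDF
  # jumps 0 -> 1 at x, so sup|F1 - F2| = max(k/m, 1 - k/m); the rank k is
  # uniform on 0..m under the null
  d_rank <- vapply(0:m, function(k) max(1 - k / m, k / m), numeric(1))
  d_obs <- max(1 - sum(bg < x) / m, sum(bg < x) / m)
  expect_equal(unname(kt$statistic), d_obs)
  p_exact <- mean(d_rank >= d_obs)
  expect_equal(kt$p.value, p_exact, tolerance = 1e-12)
})

test_that("differential recovery survives the full pipeline from fragments", {
  # place fragments so that counting + GLM recover a 4-fold planted peak
  atlas <- bed_ranges("chrS", c(0, 1000), c(500, 1500))
  set.seed(41)
  n <- 12
  grp <- rep(c("non_recurrent", "recurrent"), each = n / 2)
  frs <- lapply(seq_len(n), function(i) {
    mu1 <- if (grp[i] == "recurrent") 400 else 100
    mids1 <- sample(0:499, rpois(1, mu1), replace = TRUE)
    mids2 <- sample(1000:1499, rpois(1, 100), replace = TRUE)
    mids <- c(mids1, mids2)
    make_fragments("chrS", pmax(mids - 50, 0), mids + 50,
                   rep("+", length(mids)))
  })
  names(frs) <- sprintf("s%02d", seq_len(n))
  counts <- count_fragments(frs, atlas)
  md <- data.frame(sample = colnames(counts), group = grp,
                   nuclear_read_depth = 2e7, margin_status = 0L)
  res <- fit_nb_glm(counts, md, sf = rep(1, n))
  expect_equal(res$log2fc[1], 2, tolerance = 0.25)
  expect_lt(res$padj[1], 0.001)
  expect_gt(res$pvalue[2], 0.01)
})
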