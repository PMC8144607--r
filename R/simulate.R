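## Synthetic cohorts with planted ground truth.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: per-patient duplicate peak calls with patient-level
## reproducibility, negative-binomially distributed fragment counts over a
## disjoint atlas with planted recurrent-vs-non-recurrent differential
## peaks and technical covariates, binary motif plantings with known
## directional effects, two-channel array scans whose class medians shift
## with prognosis group, and exponential disease-free survival linked to
## group with independent censoring.

#' Configuration for a synthetic cohort
#'
#' Defaults mirror the study design the pipeline targets: a discovery set
#' of 16 patients of whom 6 (37.5%) recur within a year; a peak atlas
#' scaled to desk size (2,000 peaks rather than the ~120k of a full
#' cohort); a differential signature with roughly 1 open-in-recurrent
#' region per 3 open-in-non-recurrent, matching the skew of the array's
#' RED/BLUE classes; negative-binomial counts with dispersion 0.05; a
#' group hazard ratio of 3 around a baseline median DFS of 845 days.
#'
#' @param n_patients cohort size.
#' @param frac_recurrent fraction of patients in the recurrent (DFS < 1
#'   year) group.
#' @param n_atlas_peaks number of template atlas peaks.
#' @param n_diff_open_recurrent,n_diff_open_nonrecurrent numbers of planted
#'   differential peaks by direction; their sum must stay below
#'   `n_atlas_peaks`.
#' @param base_mean expected fragments per peak before scaling.
#' @param dispersion negative-binomial dispersion alpha in
#'   `Var = mu + alpha * mu^2`; 0 gives Poisson counts.
#' @param planted_lfc absolute log2 fold change planted on differential
#'   peaks (sign follows direction, recurrent vs non-recurrent).
#' @param n_tfs number of transcription-factor motif columns.
#' @param motif_density background probability of a motif hit.
#' @param planted_tf_effects named numeric vector of TF effects; positive
#'   effects enrich the TF in open-in-recurrent peaks, negative in
#'   open-in-non-recurrent peaks.
#' @param array_noise_sd standard deviation of per-probe log2 Cy5/Cy3
#'   ratios around their class mean; must be positive.
#' @param hazard_ratio_groups hazard ratio of recurrent vs non-recurrent
#'   DFS (exponential model).
#' @param censor_rate probability a patient's DFS time is censored.
#' @param seed integer RNG seed; a fixed seed reproduces the whole cohort
#'   byte for byte.
#' @param chrom synthetic chromosome name.
#' @param peak_width,peak_gap template peak geometry in bp.
#' @param peak_presence probability a patient carries each template peak.
#' @param boundary_jitter max uniform jitter (bp) applied independently to
#'   each replicate peak boundary.
#' @param noise_peak_frac replicate-private noise peaks as a fraction of a
#'   patient's true peaks.
#' @param baseline_median_dfs median DFS (days) of the non-recurrent group.
#' @param depth_lfc,margin_lfc log2-scale coefficients with which nuclear
#'   read depth and margin status perturb the count means, so covariate
#'   adjustment is exercised.
#' @return A validated list of class `"sim_config"`.
#' @export
simulation_config <- function(n_patients = 16,
                              frac_recurrent = 0.375,
                              n_atlas_peaks = 2000,
                              n_diff_open_recurrent = 60,
                              n_diff_open_nonrecurrent = 170,
                              base_mean = 100,
                              dispersion = 0.05,
                              planted_lfc = 2,
                              n_tfs = 50,
                              motif_density = 0.1,
                              planted_tf_effects = c(ZKSCAN1 = 1,
                                                     HNF1B = -1),
                              array_noise_sd = 0.25,
                              hazard_ratio_groups = 3,
                              censor_rate = 0.2,
                              seed = 1,
                              chrom = "chrS",
                              peak_width = 500,
                              peak_gap = 500,
                              peak_presence = 0.9,
                              boundary_jitter = 25,
                              noise_peak_frac = 0.05,
                              baseline_median_dfs = 845,
                              depth_lfc = 0.3,
                              margin_lfc = 0.2) {
  cfg <- as.list(environment())
  frac_fields <- c("frac_recurrent", "motif_density", "censor_rate",
                   "peak_presence", "noise_peak_frac")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("config error: ", f, " must be a fraction in [0, 1]")
  }
  if (cfg$frac_recurrent <= 0 || cfg$frac_recurrent >= 1)
    stop("config error: frac_recurrent must lie strictly in (0, 1)")
  if (cfg$n_diff_open_recurrent + cfg$n_diff_open_nonrecurrent >=
      cfg$n_atlas_peaks)
    stop("config error: planted differential peaks must number fewer ",
         "than atlas peaks")
  if (cfg$array_noise_sd <= 0)
    stop("config error: array_noise_sd must be positive")
  if (cfg$dispersion < 0) stop("config error: dispersion must be >= 0")
  if (cfg$base_mean <= 0) stop("config error: base_mean must be positive")
  if (cfg$hazard_ratio_groups <= 0)
    stop("config error: hazard_ratio_groups must be positive")
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

## internal: sub-seeds per generator stage so each simulate_* call is
## individually reproducible from config$seed
sim_seed <- function(config, offset) {
  (config$seed %% 1000000L) * 1000L + offset
}

#' Simulate a patient cohort with clinical outcomes
#'
#' Group sizes are `round(n_patients * frac_recurrent)` recurrent patients
#' and the complement non-recurrent. DFS times are exponential with
#' group-specific rates whose ratio is `hazard_ratio_groups`; censoring
#' comes from an independent exponential clock calibrated so a
#' non-recurrent patient is censored with probability `censor_rate`.
#' Covariates `nuclear_read_depth` (log-normal) and
#' `margin_status` (Bernoulli) are attached for downstream GLM adjustment.
#'
#' @param config a [simulation_config()].
#' @return A list of class `"sim_cohort"` with elements `clinical` (a
#'   data.frame: patient, group, dfs_days, event, nuclear_read_depth,
#'   margin_status) and `truth` (group labels and survival parameters).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(sim_seed(config, 1L))
  n <- config$n_patients
  n_rec <- round(n * config$frac_recurrent)
  if (n_rec < 1L || n_rec >= n)
    stop("config error: group sizes degenerate for n_patients = ", n)
  group <- c(rep("recurrent", n_rec), rep("non_recurrent", n - n_rec))
  patient <- sprintf("PT%02d", seq_len(n))
  rate_non <- log(2) / config$baseline_median_dfs
  rate <- ifelse(group == "recurrent",
                 rate_non * config$hazard_ratio_groups, rate_non)
  latent <- stats::rexp(n, rate = rate)
  # independent exponential censoring clock, calibrated so the
  # non-recurrent group is censored with probability censor_rate
  cens_rate <- rate_non * config$censor_rate / (1 - config$censor_rate)
  cens_time <- if (cens_rate > 0) stats::rexp(n, rate = cens_rate)
               else rep(Inf, n)
  censored <- cens_time < latent
  time <- pmin(latent, cens_time)
  time <- pmax(time, 0.5)  # DFS measured in days; keep times positive
  clinical <- data.frame(
    patient = patient,
    group = group,
    dfs_days = round(time, 1),
    event = as.integer(!censored),
    nuclear_read_depth = round(stats::rlnorm(n, log(2e7), 0.4)),
    margin_status = stats::rbinom(n, 1L, 0.3),
    stringsAsFactors = FALSE
  )
  structure(list(
    clinical = clinical,
    truth = list(group = stats::setNames(group, patient),
                 rate_non_recurrent = rate_non,
                 hazard_ratio = config$hazard_ratio_groups)
  ), class = "sim_cohort")
}

## internal: the disjoint template atlas the generator draws peaks from
template_atlas <- function(config) {
  i <- seq_len(config$n_atlas_peaks) - 1L
  start <- i * (config$peak_width + config$peak_gap)
  bed_ranges(config$chrom, start, start + config$peak_width)
}

#' Simulate duplicate peak calls per patient
#'
#' Each patient carries a Bernoulli(`peak_presence`) subset of a shared
#' disjoint template atlas. Both replicates contain the patient's true
#' peaks with independently jittered boundaries, plus replicate-private
#' noise peaks, so the reproducibility filter and atlas builder are
#' exercised with known truth.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param config the same [simulation_config()].
#' @return A named list (per patient) of lists with elements `rep1` and
#'   `rep2` (`GRanges`); the template atlas is attached as attribute
#'   `"template"`.
#' @export
simulate_peak_sets <- function(cohort, config) {
  stopifnot(inherits(cohort, "sim_cohort"))
  set.seed(sim_seed(config, 2L))
  template <- template_atlas(config)
  t0 <- GenomicRanges::start(template) - 1L
  t1 <- GenomicRanges::end(template)
  genome_end <- max(t1) + config$peak_gap
  jit <- config$boundary_jitter
  patients <- cohort$clinical$patient
  out <- lapply(patients, function(p) {
    present <- stats::rbinom(length(template), 1L, config$peak_presence) == 1L
    make_rep <- function() {
      s <- t0[present]
      e <- t1[present]
      if (jit > 0) {
        s <- pmax(0, s + sample(seq(-jit, jit), length(s), replace = TRUE))
        e <- e + sample(seq(-jit, jit), length(e), replace = TRUE)
        e <- pmax(e, s + 50L)
      }
      n_noise <- round(config$noise_peak_frac * length(s))
      if (n_noise > 0) {
        ns <- sample.int(genome_end - 200L, n_noise)
        ne <- ns + sample(100:300, n_noise, replace = TRUE)
        s <- c(s, ns); e <- c(e, ne)
      }
      canonical_peaks(bed_ranges(config$chrom, s, e))
    }
    list(rep1 = make_rep(), rep2 = make_rep())
  })
  names(out) <- patients
  attr(out, "template") <- template
  out
}

#' Simulate fragment counts and motif hits over an atlas
#'
#' Counts are negative-binomial with mean
#' `base_mean * size_factor_s * 2^(lfc_p * group_s + covariate effects)`
#' and dispersion `config$dispersion` (`dispersion = 0` gives Poisson).
#' Planted differential peaks receive `lfc = +/- planted_lfc` by
#' direction. The motif matrix is Bernoulli(`motif_density`) background
#' with each planted TF enriched in the differential peaks matching the
#' sign of its effect, so the true ridge coefficient carries that sign.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param atlas a disjoint `GRanges` (e.g. from [build_atlas()]).
#' @param config the same [simulation_config()].
#' @return A list with `counts` (integer matrix, peaks x samples),
#'   `metadata` (a data.frame mirroring the clinical covariates),
#'   `motif_hits` (binary matrix, peaks x TFs) and `truth` (planted peak
#'   ids with direction and lfc, planted TF effects, size factors).
#' @export
simulate_counts_and_motifs <- function(cohort, atlas, config) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!methods::is(atlas, "GRanges")) stop("atlas must be a GRanges")
  n_peaks <- length(atlas)
  n_dr <- config$n_diff_open_recurrent
  n_dn <- config$n_diff_open_nonrecurrent
  if (n_dr + n_dn >= n_peaks)
    stop("dimension error: atlas smaller than the planted signature")
  set.seed(sim_seed(config, 3L))
  ids <- peak_id(atlas)
  planted <- sample.int(n_peaks, n_dr + n_dn)
  idx_rec <- planted[seq_len(n_dr)]
  idx_non <- planted[n_dr + seq_len(n_dn)]
  lfc <- numeric(n_peaks)
  lfc[idx_rec] <- config$planted_lfc
  lfc[idx_non] <- -config$planted_lfc

  cl <- cohort$clinical
  n_s <- nrow(cl)
  sf <- exp(stats::rnorm(n_s, 0, 0.15))
  sf <- sf / exp(mean(log(sf)))
  grp <- as.numeric(cl$group == "recurrent")
  depth_dev <- log2(cl$nuclear_read_depth) -
    mean(log2(cl$nuclear_read_depth))
  log2_mu <- outer(lfc, grp) +
    matrix(rep(config$depth_lfc * depth_dev +
                 config$margin_lfc * cl$margin_status,
               each = n_peaks), nrow = n_peaks)
  mu <- config$base_mean * matrix(rep(sf, each = n_peaks),
                                  nrow = n_peaks) * 2^log2_mu
  counts <- if (config$dispersion == 0) {
    matrix(stats::rpois(n_peaks * n_s, lambda = mu), nrow = n_peaks)
  } else {
    matrix(stats::rnbinom(n_peaks * n_s, mu = mu,
                          size = 1 / config$dispersion), nrow = n_peaks)
  }
  dimnames(counts) <- list(ids, cl$patient)

  tf_names <- unique(c(names(config$planted_tf_effects),
                       sprintf("TF%03d", seq_len(config$n_tfs))))
  tf_names <- tf_names[seq_len(max(config$n_tfs,
                                   length(config$planted_tf_effects)))]
  hits <- matrix(stats::rbinom(n_peaks * length(tf_names), 1L,
                               config$motif_density),
                 nrow = n_peaks,
                 dimnames = list(ids, tf_names))
  for (tf in names(config$planted_tf_effects)) {
    e <- config$planted_tf_effects[[tf]]
    target <- if (e > 0) idx_rec else idx_non
    p_hit <- min(0.95, config$motif_density + 0.6 * min(1, abs(e)))
    hits[target, tf] <- stats::rbinom(length(target), 1L, p_hit)
  }

  diff_truth <- data.frame(
    peak_id = ids[c(idx_rec, idx_non)],
    direction = rep(c("open_in_recurrent", "open_in_nonrecurrent"),
                    c(n_dr, n_dn)),
    lfc = lfc[c(idx_rec, idx_non)],
    stringsAsFactors = FALSE
  )
  metadata <- data.frame(
    sample = cl$patient,
    group = factor(cl$group, levels = c("non_recurrent", "recurrent")),
    nuclear_read_depth = cl$nuclear_read_depth,
    margin_status = cl$margin_status,
    stringsAsFactors = FALSE
  )
  list(counts = counts, metadata = metadata, motif_hits = hits,
       truth = list(diff_peaks = diff_truth,
                    tf_effects = config$planted_tf_effects,
                    size_factors = stats::setNames(sf, cl$patient)))
}

#' Default synthetic probe set for ATAC-array simulations
#'
#' Builds a probe table with the four array classes: RED and BLUE probes
#' tile signature regions (open in recurrent / non-recurrent tumors
#' respectively), GREEN probes tile positive-control regions open in all
#' tumors, and BLACK probes form an aCGH-style backbone mapping to no
#' signature region.
#'
#' @param n_red,n_blue,n_green numbers of signature/control regions;
#'   defaults follow the array design the pipeline targets (244 RED + 688
#'   BLUE signature regions, 312 GREEN controls).
#' @param n_black number of backbone probes (default 7000).
#' @param probes_per_region probes tiled across each region (default 5).
#' @param chrom chromosome name for synthetic probe coordinates.
#' @return A data.frame (probe_id, chrom, start, end, class, region_id).
#' @export
simulate_probe_set <- function(n_red = 244, n_blue = 688, n_green = 312,
                               n_black = 7000, probes_per_region = 5,
                               chrom = "chrS") {
  n_reg <- n_red + n_blue + n_green
  cls <- rep(c("RED", "BLUE", "GREEN"), c(n_red, n_blue, n_green))
  region_id <- sprintf("R%04d", seq_len(n_reg))
  reg_start <- (seq_len(n_reg) - 1L) * 1000L
  probe_rows <- do.call(rbind, lapply(seq_len(n_reg), function(i) {
    ps <- reg_start[i] + (seq_len(probes_per_region) - 1L) * 80L
    data.frame(
      probe_id = sprintf("%s_p%d", region_id[i], seq_len(probes_per_region)),
      chrom = chrom, start = ps, end = ps + 60L,
      class = cls[i], region_id = region_id[i],
      stringsAsFactors = FALSE
    )
  }))
  bb_start <- max(probe_rows$end) + 10000L +
    (seq_len(n_black) - 1L) * 500L
  black <- data.frame(
    probe_id = sprintf("BB%05d", seq_len(n_black)),
    chrom = chrom, start = bb_start, end = bb_start + 60L,
    class = "BLACK", region_id = NA_character_,
    stringsAsFactors = FALSE
  )
  rbind(probe_rows, black)
}

## internal: class mean log2(Cy5/Cy3) ratios by prognosis group. The
## non-recurrent (good prognosis) group has brighter BLUE regions and
## dimmer RED regions; GREEN controls are open in everyone and the BLACK
## backbone is dark in any ATAC library. On the linear scale these means
## give cohort Prognosis Scores spanning roughly 0.4-0.9, with the good
## and poor groups falling on either side of the cohort median.
array_class_means <- function(group) {
  if (group == "non_recurrent") {
    c(RED = log2(0.35), BLUE = log2(0.68), GREEN = 0, BLACK = log2(0.2))
  } else {
    c(RED = log2(0.70), BLUE = log2(0.40), GREEN = 0, BLACK = log2(0.2))
  }
}

#' Simulate two-channel ATAC-array scans
#'
#' Per-probe log2 Cy5/Cy3 ratios are Normal(class mean, `array_noise_sd`)
#' where the class means depend on the patient's prognosis group: the good
#' prognosis (non-recurrent) group has higher BLUE and lower RED medians.
#' Cy3 reference intensities are log-normal and strictly positive.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param probes a probe table as from [simulate_probe_set()].
#' @param config the same [simulation_config()].
#' @param class_means optional function `(group) -> named numeric` of log2
#'   ratio class means, replacing the built-in defaults.
#' @return A named list (per patient) of data.frames
#'   (probe_id, cy5, cy3).
#' @export
simulate_array_scans <- function(cohort, probes, config,
                                 class_means = array_class_means) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (config$array_noise_sd <= 0)
    stop("config error: array_noise_sd must be positive")
  if (!all(probes$class %in% c("RED", "BLUE", "GREEN", "BLACK")))
    stop("unknown probe classes present")
  set.seed(sim_seed(config, 4L))
  n_p <- nrow(probes)
  out <- lapply(seq_len(nrow(cohort$clinical)), function(i) {
    grp <- cohort$clinical$group[i]
    mu <- class_means(grp)[probes$class]
    lr <- stats::rnorm(n_p, mean = mu, sd = config$array_noise_sd)
    cy3 <- stats::rlnorm(n_p, log(1000), 0.3)
    data.frame(probe_id = probes$probe_id,
               cy5 = cy3 * 2^lr,
               cy3 = cy3,
               stringsAsFactors = FALSE)
  })
  names(out) <- cohort$clinical$patient
  out
}

#' Write a simulated cohort to plain-text files
#'
#' Emits the generator's outputs in the formats the analysis reads back:
#' per-replicate peak BEDs, a peak-by-sample count TSV, a clinical TSV and
#' per-patient array scan TSVs.
#'
#' @param dir output directory (created if needed).
#' @param cohort,peak_sets,sim,scans outputs of the `simulate_*`
#'   generators; any may be `NULL` to skip.
#' @return Invisibly, the output directory.
#' @export
write_cohort_files <- function(dir, cohort = NULL, peak_sets = NULL,
                               sim = NULL, scans = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cohort)) {
    utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(peak_sets)) {
    for (p in names(peak_sets)) {
      write_peaks_bed(peak_sets[[p]]$rep1,
                      file.path(dir, paste0(p, "_rep1.bed")))
      write_peaks_bed(peak_sets[[p]]$rep2,
                      file.path(dir, paste0(p, "_rep2.bed")))
    }
  }
  if (!is.null(sim)) {
    counts <- data.frame(peak_id = rownames(sim$counts), sim$counts,
                         check.names = FALSE)
    utils::write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(scans)) {
    for (p in names(scans)) {
      utils::write.table(scans[[p]], file.path(dir, paste0(p, "_scan.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}
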