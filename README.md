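# atacarray

Chromatin accessibility prognostics for resected tumors: peak-atlas
construction, differential-accessibility signature calling, motif ridge
regression, ATAC-array Prognosis Scores, and survival stratification —
with a synthetic-cohort generator so every stage is testable without
controlled-access patient data.

## Who this is for

Computational biologists analyzing ATAC-seq of tumor cohorts with
clinical follow-up: the package turns per-patient replicate peak calls
and fragment counts into a cross-patient signature of recurrence, reads
that signature out on a low-cost two-channel microarray ("ATAC-array"),
and quantifies how well the resulting score separates disease-free
survival.

## The methods at the core

**Atlas merge heuristic.** Per-patient reproducible peaks (overlap
fraction ≥ 0.5 between duplicate libraries) are combined across patients:
for an overlapping pair with f = |a∩b| / min(|a|, |b|), f > 0.75 unifies
the pair into its intersection, f ≤ 0.75 removes the overlap from both
and keeps the flanks. The atlas is disjoint at every step and idempotent.

**Differential signature.** Per atlas peak, a negative-binomial GLM
(log link, size-factor offsets, method-of-moments dispersion) with
design `~ group + log(nuclear_read_depth) + margin_status`; Wald test on
the group coefficient; signature = peaks with |log2FC| > 1 and BH-adjusted
p < 0.001, split by direction.

**Motif ridge regression.** Binary motif-hit matrix X (log-odds PWM
scanning, both strands) against per-peak log2 fold changes y:

    beta_hat = argmin_beta ||y − X beta||² + lambda ||beta||²

solved in closed form on standardized columns, lambda by seeded 5-fold
CV. Positive coefficients = motifs of recurrent-direction opening.

**Prognosis Score.** Per scan, probe-class medians of cy5/cy3 ratios:
BLUE (open in non-recurrent), RED (open in recurrent), CTRL (GREEN
positive controls), CGH (BLACK backbone). Score = BLUE / (CTRL − CGH);
above the cohort median = good prognosis.

**Survival.** Kaplan-Meier product-limit curves, Mantel-Cox /
Gehan-Breslow-Wilcoxon / trend log-rank tests, O/E and Newton-Raphson
Cox hazard ratios, median-split and score-by-marker four-group
stratification.

## Worked example

```r
library(atacarray)

cfg    <- simulation_config(seed = 42)        # 16 patients, 6 recurrent
cohort <- simulate_cohort(cfg)
peaks  <- simulate_peak_sets(cohort, cfg)
repro  <- lapply(peaks, function(x) reproducible_peaks(x$rep1, x$rep2))
atlas  <- build_atlas(repro)
length(atlas)
#> [1] 2003

sim <- simulate_counts_and_motifs(cohort, atlas, cfg)
res <- fit_nb_glm(sim$counts, sim$metadata)
sig <- call_differential(res, lfc_threshold = 1, fdr = 0.001)
lengths(sig[c("open_in_recurrent", "open_in_nonrecurrent")])
#>    open_in_recurrent open_in_nonrecurrent
#>                   60                  170

fit <- ridge_fit(sim$motif_hits, ifelse(is.na(res$log2fc), 0, res$log2fc),
                 k = 5, seed = 42)
head(rank_tfs(fit), 3)
#>              tf coefficient            direction
#> HNF1B     HNF1B -0.62021934 open_in_nonrecurrent
#> ZKSCAN1 ZKSCAN1  0.39404425    open_in_recurrent
#> TF005     TF005  0.08541761    open_in_recurrent
```

The atlas recovers the generator's 2,000-peak template (up to boundary
jitter), the signature call finds exactly the 60 + 170 planted
differential peaks, and the two planted transcription factors head the
two direction lists with the planted signs — HNF1B marking
non-recurrent-direction (good prognosis) chromatin, ZKSCAN1 the
recurrent direction.

Scoring a 40-patient cohort on a simulated array (244 RED + 688 BLUE
signature regions, 312 GREEN controls, 7,000-probe backbone) and
stratifying survival:

```r
cfg40  <- simulation_config(n_patients = 40, frac_recurrent = 0.5, seed = 42)
co40   <- simulate_cohort(cfg40)
probes <- probe_set(simulate_probe_set())
scans  <- simulate_array_scans(co40, probes, cfg40)
scores <- vapply(scans, function(s) score_scan(s, probes)$blue_score,
                 numeric(1))
round(range(scores), 2); round(median(scores), 2)
#> [1] 0.49 0.86
#> [1] 0.67

st <- median_split_stratify(scores, co40$clinical)
st$groups
#>   group  n events median_dfs
#> 1  poor 20     20      145.5
#> 2  good 20     10     2283.4
sprintf("log-rank p = %.3g, HR (poor/good) = %.2f [%.2f, %.2f]",
        st$logrank$p, st$hr$hr, st$hr$ci[1], st$hr$ci[2])
#> [1] "log-rank p = 6.62e-07, HR (poor/good) = 4.85 [2.21, 10.65]"
```

Patients below the median score (poor prognosis) recur with a median DFS
of 146 days against 2,283 days above it; the split is highly significant
under the simulated hazard ratio of 3.

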