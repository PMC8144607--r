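## Kaplan-Meier estimation, the weighted log-rank family (Mantel-Cox,
## Gehan-Breslow-Wilcoxon, trend), O/E (Pike) hazard ratios, and the
## median-split and score-by-marker stratifications.
##
## Conventions: ties among events at one time are handled in a single
## hypergeometric draw; a censoring at exactly an event time leaves the
## subject in the risk set for that event (events before censorings).

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive event/censoring times (days).
#' @param event 1 = event observed, 0 = censored.
#' @return A list of class `"km_fit"`: `table` (data.frame time, n_risk,
#'   n_event, n_censor, survival at each distinct time), `median` (the
#'   earliest time with `S(t) <= 0.5`, `NA` if the curve never reaches
#'   0.5) and `n`.
#' @export
km_estimate <- function(time, event) {
  if (is.data.frame(time)) {
    event <- time$event
    time <- time$dfs_days %||% time$time
  }
  if (length(time) < 1L) stop("need at least one record")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  o <- order(time)
  time <- time[o]; event <- event[o]
  ut <- unique(time)
  n <- length(time)
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  tab <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, survival = surv)
  med <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1L]] else NA_real_
  structure(list(table = tab, median = med, n = n), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier fit: n =", x$n, ", median =",
      if (is.na(x$median)) "not reached" else x$median, "\n")
  invisible(x)
}

## internal: pooled event table across groups. Returns per-event-time
## at-risk and event counts per group plus totals.
logrank_table <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (any(table(group) == 0L)) stop("group with zero subjects")
  et <- sort(unique(time[event == 1]))
  d_g <- matrix(0, length(et), k,
                dimnames = list(NULL, levels(group)))
  n_g <- matrix(0, length(et), k,
                dimnames = list(NULL, levels(group)))
  for (g in seq_len(k)) {
    in_g <- group == levels(group)[g]
    n_g[, g] <- vapply(et, function(t) sum(time[in_g] >= t), numeric(1))
    d_g[, g] <- vapply(et, function(t)
      sum(time[in_g] == t & event[in_g] == 1), numeric(1))
  }
  list(event_times = et, d_g = d_g, n_g = n_g,
       d = rowSums(d_g), n = rowSums(n_g), levels = levels(group))
}

## internal: weighted O-E vector and covariance matrix.
## weights: per-event-time weight vector w_t. Cov contribution at t:
##   w_t^2 * d (n - d) / (n - 1) * (n_g/n) (delta_gh - n_h/n)
logrank_oe <- function(tab, w) {
  k <- ncol(tab$d_g)
  E <- tab$n_g * (tab$d / tab$n)
  U <- colSums(w * (tab$d_g - E))
  V <- matrix(0, k, k)
  for (t in seq_along(tab$event_times)) {
    n <- tab$n[t]; d <- tab$d[t]
    if (n <= 1) next
    pg <- tab$n_g[t, ] / n
    Vt <- d * (n - d) / (n - 1) * (diag(pg) - tcrossprod(pg))
    V <- V + w[t]^2 * Vt
  }
  O <- colSums(tab$d_g)
  Etot <- colSums(E)
  list(U = U, V = V, O = O, E = Etot)
}

#' Log-rank family of survival tests
#'
#' The Mantel-Cox log-rank statistic sums observed-minus-expected events
#' over event times with hypergeometric variance; the
#' Gehan-Breslow-Wilcoxon variant weights each event time by the number
#' at risk; the trend test scores ordered groups `1..k` and tests the
#' score-weighted O-E sum on 1 degree of freedom.
#'
#' @param time,event,group vectors of equal length; `group` a factor (its
#'   level order defines the trend scores).
#' @param weights one of `"logrank"`, `"gehan_breslow_wilcoxon"`,
#'   `"trend"`.
#' @param scores trend scores, default `1:k` in level order.
#' @return A list (chisq, df, p, observed, expected, weights).
#' @export
logrank_family <- function(time, event, group,
                           weights = c("logrank",
                                       "gehan_breslow_wilcoxon",
                                       "trend"),
                           scores = NULL) {
  weights <- match.arg(weights)
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (k < 2L) stop("need >= 2 groups")
  tab <- logrank_table(time, event, group)
  w <- switch(weights,
              logrank = rep(1, length(tab$event_times)),
              gehan_breslow_wilcoxon = tab$n,
              trend = rep(1, length(tab$event_times)))
  oe <- logrank_oe(tab, w)
  # O-E sums to zero across groups by construction
  stopifnot(abs(sum(oe$U)) < 1e-8 * max(1, sum(tab$d)))
  if (weights == "trend") {
    s <- scores %||% seq_len(k)
    if (length(s) != k) stop("scores must have one value per group")
    T0 <- sum(s * oe$U)
    vT <- drop(t(s) %*% oe$V %*% s)
    if (vT <= 0) stop("degenerate trend variance")
    chisq <- T0^2 / vT
    df <- 1L
  } else {
    idx <- seq_len(k - 1L)
    V1 <- oe$V[idx, idx, drop = FALSE]
    chisq <- drop(t(oe$U[idx]) %*% solve(V1) %*% oe$U[idx])
    df <- k - 1L
  }
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE),
       observed = oe$O, expected = oe$E, weights = weights)
}

#' Two-group hazard ratio with log-scale confidence interval
#'
#' The default `"pike"` estimator is `HR = (O1/E1) / (O2/E2)` from the
#' log-rank event table with `SE(log HR) = sqrt(1/E1 + 1/E2)`, matching
#' the reporting style usually printed alongside Mantel-Cox tests. Note
#' that the O/E estimator is biased toward 1 for hazard ratios far from
#' unity; `method = "cox"` fits the Cox partial likelihood for the group
#' indicator by Newton-Raphson (Breslow tie handling) and is the
#' estimator to prefer when the magnitude itself matters. The first
#' factor level of `group` is the numerator. A group without events
#' yields a flagged undefined ratio rather than an error.
#'
#' @param time,event,group as in [logrank_family()]; exactly two groups.
#' @param conf confidence level; default 0.95.
#' @param method `"pike"` (O/E, default) or `"cox"`.
#' @return A list (hr, ci, log_hr_se, observed, expected, numerator,
#'   method, defined).
#' @export
hazard_ratio <- function(time, event, group, conf = 0.95,
                         method = c("pike", "cox")) {
  method <- match.arg(method)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("hazard_ratio requires exactly 2 groups")
  tab <- logrank_table(time, event, group)
  oe <- logrank_oe(tab, rep(1, length(tab$event_times)))
  if (any(oe$O == 0)) {
    return(list(hr = NA_real_, ci = c(NA_real_, NA_real_),
                log_hr_se = NA_real_, observed = oe$O, expected = oe$E,
                numerator = levels(group)[1L], method = method,
                defined = FALSE))
  }
  if (method == "pike") {
    log_hr <- log((oe$O[1L] / oe$E[1L]) / (oe$O[2L] / oe$E[2L]))
    se <- sqrt(1 / oe$E[1L] + 1 / oe$E[2L])
  } else {
    # Newton-Raphson on the Cox partial likelihood for x = 1{group 1},
    # Breslow tie handling; the event table already carries per-time
    # at-risk and event counts per group
    d1 <- tab$d_g[, 1L]; d <- tab$d
    n1 <- tab$n_g[, 1L]; n0 <- tab$n_g[, 2L]
    beta <- 0
    for (it in 1:50) {
      eb <- exp(beta)
      p1 <- n1 * eb / (n0 + n1 * eb)
      U <- sum(d1 - d * p1)
      I <- sum(d * p1 * (1 - p1))
      if (I <= 0) break
      step <- U / I
      beta <- beta + step
      if (abs(step) < 1e-10) break
    }
    eb <- exp(beta)
    p1 <- n1 * eb / (n0 + n1 * eb)
    info <- sum(d * p1 * (1 - p1))
    log_hr <- beta
    se <- 1 / sqrt(info)
  }
  log_hr <- unname(log_hr)
  q <- stats::qnorm(1 - (1 - conf) / 2)
  list(hr = exp(log_hr), ci = unname(exp(log_hr + c(-q, q) * se)),
       log_hr_se = unname(se), observed = oe$O, expected = oe$E,
       numerator = levels(group)[1L], method = method, defined = TRUE)
}

## internal: join score calls onto survival records by patient id
join_records <- function(calls, records) {
  missing_ids <- setdiff(calls$patient, records$patient)
  if (length(missing_ids) > 0L)
    stop("patients without survival records: ",
         paste(missing_ids, collapse = ", "))
  idx <- match(calls$patient, records$patient)
  cbind(calls, records[idx, c("dfs_days", "event"), drop = FALSE])
}

#' Median-split survival stratification
#'
#' Classifies patients by Prognosis Score ([classify_patients()]),
#' attaches survival, and runs the log-rank and Gehan-Breslow-Wilcoxon
#' tests plus the O/E hazard ratio (poor vs good, so a detrimental poor
#' group gives HR > 1). Per-group median DFS comes from [km_estimate()].
#'
#' @param scores named numeric vector of blue scores.
#' @param records data.frame (patient, dfs_days, event).
#' @param cohort_median optional external split value.
#' @return A list of class `"stratification"`: `calls`, `groups`
#'   (per-group n, events, median DFS), `logrank`, `gbw`, `hr`. With
#'   fewer than 2 patients per group the tests are skipped with a
#'   warning and returned as `NULL`.
#' @export
median_split_stratify <- function(scores, records, cohort_median = NULL) {
  calls <- classify_patients(scores, cohort_median)
  dat <- join_records(calls, records)
  dat <- dat[dat$call %in% c("good", "poor"), , drop = FALSE]
  grp <- factor(dat$call, levels = c("poor", "good"))
  groups <- do.call(rbind, lapply(levels(grp), function(g) {
    d <- dat[grp == g, ]
    data.frame(group = g, n = nrow(d), events = sum(d$event),
               median_dfs = if (nrow(d) > 0)
                 km_estimate(d$dfs_days, d$event)$median else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tests <- list(logrank = NULL, gbw = NULL, hr = NULL)
  if (all(table(grp) >= 2L) && nlevels(droplevels(grp)) == 2L) {
    tests$logrank <- logrank_family(dat$dfs_days, dat$event, grp,
                                    weights = "logrank")
    tests$gbw <- logrank_family(dat$dfs_days, dat$event, grp,
                                weights = "gehan_breslow_wilcoxon")
    tests$hr <- hazard_ratio(dat$dfs_days, dat$event, grp)
  } else {
    warning("group too small for survival tests; tests skipped")
  }
  structure(c(list(calls = calls, groups = groups), tests),
            class = "stratification")
}

#' Four-group stratification by Prognosis Score and nuclear marker
#'
#' Combines the median-split array call with a binary nuclear
#' localization marker (e.g. HNF1b) into four ordered groups, best to
#' worst prognosis: good+marker, good-marker, poor+marker, poor-marker.
#' Reports group fractions, per-group median DFS, the k-group log-rank
#' test and the log-rank trend test across the ordering.
#'
#' @param scores named numeric vector of blue scores.
#' @param marker named binary vector (1 = nuclear localization present).
#'   Patients missing the marker are excluded and reported.
#' @param records data.frame (patient, dfs_days, event).
#' @param cohort_median optional external split value.
#' @return A list of class `"stratification4"`: `groups` (group, n,
#'   fraction, events, median_dfs in prognosis order), `logrank`,
#'   `trend`, `excluded`. Tests are `NULL` with a warning when any group
#'   is empty.
#' @export
combined_stratify <- function(scores, marker, records,
                              cohort_median = NULL) {
  calls <- classify_patients(scores, cohort_median)
  have_marker <- calls$patient %in% names(marker)[!is.na(marker)]
  excluded <- calls$patient[!have_marker]
  calls <- calls[have_marker, , drop = FALSE]
  m <- marker[calls$patient]
  lvl <- c("good_marker_pos", "good_marker_neg",
           "poor_marker_pos", "poor_marker_neg")
  g4 <- factor(paste0(calls$call, ifelse(m == 1, "_marker_pos",
                                         "_marker_neg")),
               levels = lvl)
  dat <- join_records(calls, records)
  n_tot <- nrow(dat)
  groups <- do.call(rbind, lapply(lvl, function(g) {
    d <- dat[g4 == g, , drop = FALSE]
    data.frame(group = g, n = nrow(d),
               fraction = nrow(d) / n_tot,
               events = sum(d$event),
               median_dfs = if (nrow(d) > 0)
                 km_estimate(d$dfs_days, d$event)$median else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tests <- list(logrank = NULL, trend = NULL)
  if (all(groups$n >= 1L) && length(unique(g4)) == 4L) {
    tests$logrank <- logrank_family(dat$dfs_days, dat$event, g4,
                                    weights = "logrank")
    tests$trend <- logrank_family(dat$dfs_days, dat$event, g4,
                                  weights = "trend")
  } else {
    warning("empty stratum; k-group tests skipped")
  }
  structure(c(list(groups = groups, excluded = excluded), tests),
            class = "stratification4")
}

#' Cox proportional-hazards adjustment (secondary)
#'
#' A thin wrapper around [survival::coxph()] for covariate-adjusted
#' hazard ratios; the primary reporting route of the package is the O/E
#' estimator of [hazard_ratio()].
#'
#' @param records data.frame with `dfs_days`, `event` and the model
#'   covariates.
#' @param formula right-hand side of the Cox model, e.g. `~ group + age`.
#' @return The fitted `coxph` object.
#' @export
cox_adjusted <- function(records, formula) {
  if (!requireNamespace("survival", quietly = TRUE))
    stop("the survival package is required for cox_adjusted()")
  f <- stats::as.formula(paste(
    "survival::Surv(dfs_days, event)", paste(deparse(formula), collapse = "")
  ))
  survival::coxph(f, data = records)
}
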