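## TF motif scanning and ridge regression of differential accessibility on
## motif presence. Scanning is a log-odds sweep against background base
## frequencies on both strands (a lightweight stand-in for a full
## p-value-calibrated scanner); the hit threshold is expressed as a
## fraction of the motif's maximal attainable score. The ridge fit solves
##   beta_hat = argmin_beta ||y - X beta||^2 + lambda ||beta||^2
## in closed form on standardized columns, with lambda chosen by seeded
## k-fold cross-validation.

#' Construct a position weight matrix
#'
#' @param name TF name.
#' @param mat numeric matrix of per-position base probabilities; 4 rows
#'   (A, C, G, T) and one column per motif position; every column must sum
#'   to 1 within 1e-6.
#' @param bg background base frequencies (named, A/C/G/T); default uniform.
#' @return An object of class `"pwm"`.
#' @export
pwm <- function(name, mat, bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  dimnames(mat) <- list(c("A", "C", "G", "T"), NULL)
  if (any(abs(colSums(mat) - 1) > 1e-6))
    stop("PWM columns must each sum to 1")
  if (any(mat < 0)) stop("PWM probabilities must be nonnegative")
  bg <- bg[c("A", "C", "G", "T")]
  if (any(is.na(bg)) || abs(sum(bg) - 1) > 1e-6)
    stop("background must be named A/C/G/T frequencies summing to 1")
  structure(list(name = name, mat = mat, bg = bg), class = "pwm")
}

## internal: log2-odds matrix with a pseudocount, plus an all-zero row for
## ambiguous bases (N scores as background)
pwm_logodds <- function(p, pseudo = 1e-3) {
  lo <- log2((p$mat + pseudo) / (p$bg + pseudo))
  rbind(lo, N = 0)
}

#' Maximal attainable log-odds score of a PWM
#' @param p a [pwm()].
#' @param pseudo pseudocount used in the log-odds; default 1e-3.
#' @return A single number.
#' @export
pwm_max_score <- function(p, pseudo = 1e-3) {
  sum(apply(pwm_logodds(p, pseudo)[1:4, , drop = FALSE], 2L, max))
}

#' Consensus sequence of a PWM
#' @param p a [pwm()].
#' @return Character scalar of the most probable base per position.
#' @export
pwm_consensus <- function(p) {
  paste(rownames(p$mat)[apply(p$mat, 2L, which.max)], collapse = "")
}

## internal: reverse-complement a PWM (scanning the RC motif on the
## forward sequence is equivalent to scanning the motif on the reverse
## strand)
pwm_revcomp <- function(p) {
  m <- p$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(p$mat))), drop = FALSE]
  rownames(m) <- c("A", "C", "G", "T")
  bg_rc <- stats::setNames(p$bg[c("T", "G", "C", "A")],
                           c("A", "C", "G", "T"))
  pwm(p$name, m, bg_rc)
}

## internal: best window log-odds score of one PWM on one sequence
## (forward strand only); -Inf when the sequence is shorter than the motif
scan_one <- function(idx, lo) {
  w <- ncol(lo)
  n <- length(idx)
  if (n < w) return(-Inf)
  s <- numeric(n - w + 1L)
  for (k in seq_len(w)) s <- s + lo[idx[k:(n - w + k)], k]
  max(s)
}

#' Scan peak sequences for motif matches
#'
#' Every position of every sequence is scored on both strands as the sum
#' of per-base log2 odds versus background (`N` contributes 0); a peak is
#' marked as hit by a TF when any window reaches
#' `threshold_frac * pwm_max_score(pwm)`. The reverse strand is scanned
#' via the reverse-complemented motif.
#'
#' @param sequences named character vector of uppercase DNA sequences (or
#'   a `Biostrings::DNAStringSet`), one per atlas peak.
#' @param pwms list of [pwm()] objects.
#' @param threshold_frac hit threshold as a fraction of each motif's
#'   maximal score; default 0.8.
#' @return A list with `hit_matrix` (binary, peaks by TFs) and `scores`
#'   (numeric matrix of best per-peak window scores). Sequences shorter
#'   than a motif simply score no hit.
#' @export
scan_motifs <- function(sequences, pwms, threshold_frac = 0.8) {
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("peak%05d", seq_along(sequences))
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  alphabet <- c("A", "C", "G", "T", "N")
  idx_list <- lapply(sequences, function(s) {
    v <- match(strsplit(s, "", fixed = TRUE)[[1L]], alphabet)
    if (anyNA(v)) stop("invalid base in sequence (allowed: A, C, G, T, N)")
    v
  })
  tf_names <- vapply(pwms, `[[`, character(1), "name")
  scores <- matrix(-Inf, nrow = length(sequences), ncol = length(pwms),
                   dimnames = list(names(sequences), tf_names))
  for (j in seq_along(pwms)) {
    lo_f <- pwm_logodds(pwms[[j]])
    lo_r <- pwm_logodds(pwm_revcomp(pwms[[j]]))
    for (i in seq_along(idx_list)) {
      scores[i, j] <- max(scan_one(idx_list[[i]], lo_f),
                          scan_one(idx_list[[i]], lo_r))
    }
  }
  thr <- threshold_frac * vapply(pwms, pwm_max_score, numeric(1))
  hit <- sweep(scores, 2L, thr, `>=`) * 1L
  hit[!is.finite(scores)] <- 0L
  list(hit_matrix = hit, scores = scores)
}

#' Read and write a simplified MEME motif file
#'
#' Supports the minimal MEME subset used here: an optional
#' `Background letter frequencies` block, and per motif a `MOTIF name`
#' line, a `letter-probability matrix:` header and one row of four
#' probabilities per position.
#'
#' @param path file path.
#' @param pwms list of [pwm()] objects to write.
#' @return `read_meme_lite` returns a named list of `pwm` objects.
#' @export
read_meme_lite <- function(path) {
  lines <- trimws(readLines(path))
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bgl <- grep("^Background letter frequencies", lines)
  if (length(bgl) == 1L && bgl < length(lines)) {
    tok <- strsplit(lines[bgl + 1L], "\\s+")[[1L]]
    vals <- as.numeric(tok[c(FALSE, TRUE)])
    names(vals) <- tok[c(TRUE, FALSE)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) stop("no MOTIF records in ", path)
  bounds <- c(starts, length(lines) + 1L)
  out <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:(bounds[k + 1L] - 1L)]
    name <- strsplit(block[1L], "\\s+")[[1L]][2L]
    hdr <- grep("^letter-probability matrix", block)
    if (length(hdr) != 1L)
      stop("motif ", name, ": missing letter-probability matrix header")
    rows <- block[-seq_len(hdr)]
    rows <- rows[grepl("^[-0-9.eE+ \t]+$", rows) & nzchar(rows)]
    mat <- t(vapply(strsplit(rows, "\\s+"),
                    function(x) as.numeric(x[1:4]), numeric(4)))
    out[[name]] <- pwm(name, t(mat), bg = bg)
  }
  out
}

#' @rdname read_meme_lite
#' @export
write_meme_lite <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("MEME version 4\n", con)
  bg <- pwms[[1L]]$bg
  writeLines(c("Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       bg["A"], bg["C"], bg["G"], bg["T"]), ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$name), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       ncol(p$mat)), con)
    writeLines(apply(p$mat, 2L, function(col)
      sprintf("%.6f %.6f %.6f %.6f", col[1], col[2], col[3], col[4])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Ridge regression of differential accessibility on motif presence
#'
#' Solves `beta_hat = argmin ||y - X beta||^2 + lambda ||beta||^2` in
#' closed form, `beta_hat = (X'X + lambda I)^-1 X'y`, on centered
#' `y` and standardized columns of `X` (the intercept is unpenalized and
#' recovered afterwards). `lambda` is chosen from a log-spaced grid by
#' minimizing the k-fold cross-validated mean squared error with a seeded
#' fold assignment; coefficients are reported on the original (binary)
#' column scale.
#'
#' @param X numeric matrix, peaks by TFs (typically a binary hit matrix).
#' @param y numeric vector of per-peak log2 fold changes, aligned with the
#'   rows of `X`.
#' @param lambdas penalty grid; default 50 values log-spaced over
#'   `[1e-4, 1e4] * ||X'y|| / n` (computed on the standardized system).
#' @param k number of cross-validation folds; default 5.
#' @param seed RNG seed for fold assignment.
#' @return An object of class `"ridge_fit"`: `coefficients` (named,
#'   original scale), `intercept`, `lambda`, `lambdas`, `cv_mse`, plus the
#'   standardized system (`beta_std`, `xtx_std`, `xty_std`) retained so
#'   the normal equations can be verified.
#' @export
ridge_fit <- function(X, y, lambdas = NULL, k = 5, seed = 1) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("rows of X must align with y")
  if (k > n) stop("k-fold CV requires k <= n")
  if (k < 2L) stop("k must be >= 2")
  if (is.null(colnames(X))) colnames(X) <- sprintf("TF%03d", seq_len(p))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  zero_var <- scl == 0 | is.na(scl)
  if (any(zero_var)) {
    warning("zero-variance columns retained with unit scale: ",
            paste(colnames(X)[zero_var], collapse = ", "))
    scl[zero_var] <- 1
  }
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  ym <- mean(y)
  yc <- y - ym
  xty_full <- crossprod(Xs, yc)
  if (is.null(lambdas)) {
    lref <- sqrt(sum(xty_full^2)) / n
    if (lref <= 0) lref <- 1
    lambdas <- lref * 10^seq(-4, 4, length.out = 50)
  }
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  solve_ridge <- function(xtx, xty, lam) {
    solve(xtx + diag(lam, nrow(xtx)), xty)
  }
  cv_mse <- vapply(lambdas, function(lam) {
    errs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      xtx <- crossprod(Xs[tr, , drop = FALSE])
      xty <- crossprod(Xs[tr, , drop = FALSE], yc[tr])
      b <- solve_ridge(xtx, xty, lam)
      pred <- Xs[!tr, , drop = FALSE] %*% b
      mean((yc[!tr] - pred)^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  lambda <- lambdas[which.min(cv_mse)]
  xtx_std <- crossprod(Xs)
  beta_std <- drop(solve_ridge(xtx_std, xty_full, lambda))
  beta <- beta_std / scl
  intercept <- ym - sum(beta * ctr)
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    intercept = intercept,
    lambda = lambda,
    lambdas = lambdas,
    cv_mse = cv_mse,
    beta_std = stats::setNames(beta_std, colnames(X)),
    xtx_std = xtx_std,
    xty_std = drop(xty_full),
    n = n
  ), class = "ridge_fit")
}

#' @export
print.ridge_fit <- function(x, ...) {
  cat("Ridge fit:", x$n, "peaks,", length(x$coefficients), "TFs;",
      "lambda =", signif(x$lambda, 4),
      "(CV MSE", signif(min(x$cv_mse), 4), ")\n")
  invisible(x)
}

#' Rank transcription factors by ridge coefficient
#'
#' Positive coefficients mark motifs enriched in peaks opening in
#' recurrent tumors (the response is log2FC recurrent vs non-recurrent);
#' negative coefficients mark motifs of the non-recurrent direction.
#'
#' @param fit a [ridge_fit()].
#' @param min_abs magnitude cutoff (strict); default 0, which still
#'   excludes exactly-zero coefficients.
#' @return A data.frame (tf, coefficient, direction) sorted by decreasing
#'   `|coefficient|`.
#' @export
rank_tfs <- function(fit, min_abs = 0) {
  co <- fit$coefficients
  keep <- abs(co) > min_abs
  co <- co[keep]
  out <- data.frame(
    tf = names(co),
    coefficient = unname(co),
    direction = ifelse(co > 0, "open_in_recurrent", "open_in_nonrecurrent"),
    stringsAsFactors = FALSE
  )
  out[order(-abs(out$coefficient)), , drop = FALSE]
}

#' Count motif hits for one TF and list nearest genes
#'
#' @param hit_matrix binary peaks-by-TFs matrix with peak-id rownames.
#' @param tf TF (column) name; unknown names are an error.
#' @param genes gene annotation as for [nearest_gene()].
#' @return A list with `count` (column sum) and `genes` (data.frame of
#'   hit peak ids and their nearest gene).
#' @export
count_tf_hits <- function(hit_matrix, tf, genes) {
  if (!tf %in% colnames(hit_matrix)) stop("unknown TF: ", tf)
  hit_ids <- rownames(hit_matrix)[hit_matrix[, tf] == 1L]
  gene_df <- if (length(hit_ids) == 0L) {
    data.frame(peak_id = character(0), gene = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(peak_id = hit_ids,
               gene = nearest_gene(hit_ids, genes),
               stringsAsFactors = FALSE)
  }
  list(count = sum(hit_matrix[, tf] == 1L), genes = gene_df)
}
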