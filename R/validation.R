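#' Confusion-matrix validation battery
#'
#' All derived rates of a 2x2 confusion matrix:
#' sensitivity TP/(TP+FN), specificity TN/(TN+FP), TSS = sensitivity +
#' specificity - 1, accuracy (TP+TN)/N, balanced accuracy
#' (sensitivity+specificity)/2, precision TP/(TP+FP), F1, predicted
#' prevalence (TP+FP)/N and observed prevalence (TP+FN)/N. A metric with a
#' zero denominator is returned as `NA` with the reason recorded in the
#' `undefined` element. Deviations of predicted from observed prevalence
#' beyond 10 percentage points raise the `prevalence_mismatch` flag.
#'
#' @param tp,fp,tn,fn nonnegative integer counts.
#' @return list of class `"validation_report"` with the metrics above, the
#'   counts, `undefined` (named character), and `prevalence_mismatch`
#'   (logical).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    abort("counts must be nonnegative integers")
  n <- sum(counts)
  if (n == 0) abort("empty confusion matrix (N = 0)")
  undefined <- character(0)
  safe <- function(num, den, what) {
    if (den == 0) {
      undefined[[what]] <<- paste0(what, ": zero denominator")
      NA_real_
    } else num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) {
    undefined[["f1"]] <- "f1: undefined precision/recall"
    NA_real_
  } else 2 * prec * sens / (prec + sens)
  rep <- list(
    sensitivity = sens, specificity = spec,
    tss = sens + spec - 1,
    accuracy = (tp + tn) / n,
    balanced_accuracy = (sens + spec) / 2,
    precision = prec, f1 = f1,
    predicted_prevalence = (tp + fp) / n,
    observed_prevalence = (tp + fn) / n,
    counts = counts, n = n, undefined = undefined)
  # integer arithmetic: |fp - fn|/N > 1/10 without float rounding at the edge
  rep$prevalence_mismatch <- 10 * abs(fp - fn) > n
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, digits = 3, ...) {
  cat("Confusion-matrix validation (N =", x$n, ")\n")
  m <- unlist(x[c("sensitivity", "specificity", "tss", "accuracy",
                  "balanced_accuracy", "precision", "f1",
                  "predicted_prevalence", "observed_prevalence")])
  print(round(m, digits))
  if (x$prevalence_mismatch)
    cat("NOTE: predicted prevalence deviates > 10 percentage points",
        "from observed\n")
  invisible(x)
}

#' Rank-based AUC
#'
#' Area under the ROC curve as the Mann-Whitney statistic: the probability
#' that a random presence scores above a random background point, ties
#' counted half (average ranks).
#'
#' @param presence,background numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(presence, background) {
  n1 <- length(presence); n0 <- length(background)
  if (n1 < 1L || n0 < 1L) abort("empty score set")
  r <- rank(c(presence, background))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Select a classification threshold
#'
#' `"default"` returns 0.5 regardless of the data. `"MaxSS"` maximizes
#' sensitivity + specificity and `"MinROCdist"` minimizes the Euclidean
#' distance to the perfect-classification corner (0, 1) of ROC space, both
#' scanning candidate thresholds at the midpoints of sorted unique scores
#' plus 0 and 1; ties break toward the lower threshold. A site counts as
#' predicted present when its score is >= the threshold.
#'
#' @param presence,background numeric score vectors in \[0, 1\].
#' @param method `"default"`, `"MaxSS"` or `"MinROCdist"`.
#' @return list with `method`, `threshold` and `objective` (sum of
#'   sensitivity and specificity for MaxSS, ROC distance for MinROCdist,
#'   `NA` for default).
#' @export
select_threshold <- function(presence, background,
                             method = c("default", "MaxSS", "MinROCdist")) {
  method <- match.arg(method)
  if (method == "default")
    return(list(method = method, threshold = 0.5, objective = NA_real_))
  s <- sort(unique(c(presence, background)))
  cand <- sort(unique(c(0, if (length(s) > 1)
    (s[-1] + s[-length(s)]) / 2, 1)))
  sens <- vapply(cand, function(t) mean(presence >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(background < t), numeric(1))
  obj <- switch(method,
                MaxSS = sens + spec,
                MinROCdist = sqrt((1 - sens)^2 + (1 - spec)^2))
  best <- if (method == "MaxSS") which(obj == max(obj)) else
    which(obj == min(obj))
  best <- min(best)  # tie toward the lower threshold
  list(method = method, threshold = cand[best], objective = obj[best])
}

#' Normalized calibration ratio
#'
#' A presence-only calibration statistic: with q = mean presence score /
#' mean background score, the ratio (q - 1)/(q + 1) lies in (-1, 1);
#' positive values mean presences sit on higher predicted suitability than
#' the landscape at large.
#'
#' @param presence,background numeric score vectors; mean background must
#'   be positive.
#' @return numeric in (-1, 1\].
#' @export
calibration_ratio <- function(presence, background) {
  mb <- mean(background)
  if (mb <= 0) abort("mean background score must be positive")
  q <- mean(presence) / mb
  (q - 1) / (q + 1)
}

#' Continuous Boyce index
#'
#' Threshold-independent, presence-only calibration: moving windows slide
#' across the suitability range; in each window the predicted-to-expected
#' ratio P/E compares the fraction of presences with the fraction of
#' background points falling in the window, and the Boyce index is the
#' Spearman rank correlation (average ranks) between window midpoints and
#' P/E. Windows with zero expected (background) frequency are dropped.
#'
#' @param presence,background numeric score vectors.
#' @param n_windows number of moving windows (default 10).
#' @param window_width window width as a fraction of the score range
#'   (default 0.2).
#' @return list with `boyce` (Spearman rho in \[-1, 1\]), `midpoints`,
#'   `pe_ratio` (per retained window).
#' @export
boyce_index <- function(presence, background, n_windows = 10,
                        window_width = 0.2) {
  if (length(presence) < 1L || length(background) < 1L)
    abort("empty score set")
  rng <- range(c(presence, background))
  w <- window_width * diff(rng)
  if (w <= 0) abort("degenerate score range")
  mids <- seq(rng[1] + w / 2, rng[2] - w / 2, length.out = n_windows)
  pe <- vapply(mids, function(m) {
    p <- mean(presence >= m - w / 2 & presence <= m + w / 2)
    e <- mean(background >= m - w / 2 & background <= m + w / 2)
    if (e == 0) NA_real_ else p / e
  }, numeric(1))
  keep <- !is.na(pe)
  if (sum(keep) < 2L) abort("fewer than two windows with nonzero expected frequency")
  list(boyce = cor(mids[keep], pe[keep], method = "spearman"),
       midpoints = mids[keep], pe_ratio = pe[keep])
}

#' Leave-one-out cross-validation of the HSI model
#'
#' For each site the whole curve-fitting pipeline is re-fitted on the
#' remaining sites and the held-out site's composite HSI is predicted. The
#' "observed" value is the full-data HSI, so LOOCV here measures the
#' self-consistency of the unsupervised index under site removal (the only
#' reading under which cross-validating an index is defined). Reported:
#' per-site predicted/observed/residual (observed - predicted), R-squared
#' = 1 - SS_res/SS_tot, RMSE, MAE and the mean residual. A fold whose
#' re-fit degenerates (e.g. zero weighted variance) is flagged in `failed`
#' rather than silently skipped.
#'
#' @param data site table as for [hsi_fit()].
#' @param ... further arguments passed to [hsi_fit()].
#' @return list of class `"loocv_report"` with `table` (site, observed,
#'   predicted, residual), `r_squared`, `rmse`, `mae`, `mean_residual`,
#'   `failed` (character vector of flagged sites).
#' @export
loocv_hsi <- function(data, ...) {
  n <- nrow(data)
  if (n < 3L) abort("LOOCV needs at least 3 sites")
  full <- hsi_fit(data, ...)
  obs <- full$hsi
  pred <- rep(NA_real_, n)
  failed <- character(0)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(hsi_fit(data[-i, , drop = FALSE], ...),
                      error = function(e) e)
    if (inherits(fit_i, "error")) {
      failed <- c(failed, paste0(full$site[i], ": ", conditionMessage(fit_i)))
      next
    }
    pred[i] <- predict(fit_i, newdata = data[i, , drop = FALSE])
  }
  ok <- !is.na(pred)
  res <- obs - pred
  ss_res <- sum(res[ok]^2)
  ss_tot <- sum((obs[ok] - mean(obs[ok]))^2)
  structure(list(
    table = data.frame(site = full$site, observed = obs, predicted = pred,
                       residual = res, row.names = NULL),
    r_squared = 1 - ss_res / ss_tot,
    rmse = sqrt(mean(res[ok]^2)),
    mae = mean(abs(res[ok])),
    mean_residual = mean(res[ok]),
    failed = failed), class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, digits = 3, ...) {
  cat(sprintf("LOOCV transfer of the HSI model: R^2 = %.*f, RMSE = %.*f, MAE = %.*f\n",
              digits, x$r_squared, digits, x$rmse, digits, x$mae))
  if (length(x$failed))
    cat("Flagged folds:\n ", paste(x$failed, collapse = "\n  "), "\n")
  invisible(x)
}
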