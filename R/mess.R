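#' Multivariate environmental similarity (MESS)
#'
#' For each projection point and each variable, with f the percentage of
#' reference values strictly below the point value p and min/max the
#' reference extremes:
#' \itemize{
#'   \item f = 0:   100 (p - min) / (max - min)
#'   \item 0 < f <= 50:  2 f
#'   \item 50 < f < 100: 2 (100 - f)
#'   \item f = 100: 100 (max - p) / (max - min)
#' }
#' The MESS value of the point is the minimum similarity across variables
#' and the most-dissimilar variable is the argmin. Negative values flag
#' extrapolation (conditions outside the reference environmental space).
#' A degenerate reference variable (max = min) scores 100 when the point
#' equals the constant and the sentinel -1000 otherwise. `NA` points
#' propagate `NA`.
#'
#' @param ref reference matrix/data.frame (points x variables) describing
#'   the calibration environmental space; >= 2 rows.
#' @param points matrix/data.frame of projection points with the same
#'   variables (matched by column name when both are named).
#' @return data.frame with one row per point: `mess` (minimum similarity),
#'   `mess_variable` (most dissimilar variable), and one similarity column
#'   per variable.
#' @export
mess <- function(ref, points) {
  ref <- as.matrix(ref)
  points <- as.matrix(points)
  if (nrow(ref) < 2L) abort("reference set needs >= 2 points")
  if (!is.null(colnames(ref)) && !is.null(colnames(points))) {
    if (!setequal(colnames(ref), colnames(points)))
      abort("reference and projection variable sets differ")
    points <- points[, colnames(ref), drop = FALSE]
  } else if (ncol(ref) != ncol(points)) {
    abort("reference and projection have different numbers of variables")
  }
  vars <- colnames(ref) %||% paste0("V", seq_len(ncol(ref)))
  sim <- matrix(NA_real_, nrow(points), ncol(ref),
                dimnames = list(NULL, vars))
  for (j in seq_len(ncol(ref))) {
    rv <- ref[, j]
    if (anyNA(rv)) abort("missing values in reference variable ", vars[j])
    lo <- min(rv); hi <- max(rv)
    for (i in seq_len(nrow(points))) {
      p <- points[i, j]
      if (is.na(p)) next
      sim[i, j] <- if (hi == lo) {
        if (p == lo) 100 else -1000
      } else {
        f <- 100 * sum(rv < p) / length(rv)
        if (f == 0) 100 * (p - lo) / (hi - lo)
        else if (f <= 50) 2 * f
        else if (f < 100) 2 * (100 - f)
        else 100 * (hi - p) / (hi - lo)
      }
    }
  }
  m <- apply(sim, 1L, function(s) if (anyNA(s)) NA_real_ else min(s))
  which_v <- apply(sim, 1L, function(s)
    if (anyNA(s)) NA_character_ else vars[which.min(s)])
  data.frame(mess = m, mess_variable = which_v, sim,
             row.names = NULL, check.names = FALSE)
}

#' Classify MESS values into extrapolation-risk categories
#'
#' Strong extrapolation (MESS < -10), moderate extrapolation
#' (-10 <= MESS < 0), analog conditions (MESS >= 0); the -10 boundary is
#' moderate. `NA` values are excluded from the fractions.
#'
#' @param values numeric MESS values.
#' @return list with `labels` (factor per value) and `fractions` (named
#'   percentages per class, summing to 100 over non-missing values).
#' @export
classify_mess <- function(values) {
  lev <- c("strong", "moderate", "analog")
  lab <- ifelse(is.na(values), NA_character_,
                ifelse(values < -10, "strong",
                       ifelse(values < 0, "moderate", "analog")))
  lab <- factor(lab, levels = lev)
  tab <- table(lab)
  frac <- setNames(100 * as.numeric(tab) / sum(tab), lev)
  list(labels = lab, fractions = frac, class_counts = tab)
}

#' Per-cell coefficient of variation across model replicates
#'
#' CV = sample SD / mean for each cell of a stack of replicate prediction
#' grids; cells with zero mean are undefined (`NA`) and excluded from the
#' high-uncertainty fraction's denominator.
#'
#' @param stack a list of numeric matrices (same dimensions), or a 3-d
#'   array with replicates along the third margin.
#' @param threshold CV above which a cell counts as high-uncertainty
#'   (default 0.5).
#' @return list with `cv` (matrix), `fraction_high` (share of defined cells
#'   with CV > threshold).
#' @export
replicate_cv <- function(stack, threshold = 0.5) {
  if (is.list(stack)) {
    dims <- dim(stack[[1]])
    stack <- array(unlist(stack), dim = c(dims, length(stack)))
  }
  if (length(dim(stack)) != 3L || dim(stack)[3] < 2L)
    abort("need >= 2 replicate grids of identical dimensions")
  if (any(stack < 0, na.rm = TRUE)) abort("negative replicate values")
  mu <- apply(stack, c(1, 2), mean)
  sdv <- apply(stack, c(1, 2), sd)
  cv <- ifelse(is.na(mu) | mu == 0, NA_real_, sdv / mu)
  list(cv = cv, fraction_high = mean(cv > threshold, na.rm = TRUE))
}

#' Equal-interval suitability classes
#'
#' Classifies suitability values in \[0, 1\] into absent \[0, 0.25), low
#' \[0.25, 0.5), medium \[0.5, 0.75) and high \[0.75, 1\] (left-closed
#' boundaries, top class closed).
#'
#' @param x numeric vector/matrix of suitabilities (NA allowed).
#' @param cell_area area of one cell (same units squared) used for
#'   per-class areas; default 1 (areas are then cell counts).
#' @return list with `labels` (factor, same shape as `x` flattened),
#'   `counts` and `area` per class.
#' @export
equal_interval_classes <- function(x, cell_area = 1) {
  lev <- c("absent", "low", "medium", "high")
  v <- as.numeric(x)
  if (any(v < 0 | v > 1, na.rm = TRUE)) abort("suitability outside [0, 1]")
  idx <- findInterval(v, c(0.25, 0.5, 0.75)) + 1L
  lab <- factor(lev[idx], levels = lev)
  counts <- table(lab)
  list(labels = lab, counts = counts,
       area = setNames(as.numeric(counts) * cell_area, lev))
}
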