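#' Geometric-mean habitat suitability index
#'
#' Combines per-parameter suitability scores into a composite HSI as the
#' geometric mean \eqn{(\prod s_i)^{1/n}}, computed in log space. The
#' geometric mean is deliberately conservative: a single unsuitable
#' parameter drags the composite toward zero, so a score of exactly zero is
#' an error here -- zeros must be floored upstream (see [texture_score()]),
#' never silently absorbed.
#'
#' @param scores numeric vector of per-parameter suitabilities in (0, 1].
#' @return the composite HSI (single numeric).
#' @export
geometric_mean_hsi <- function(scores) {
  if (length(scores) == 0L) abort("empty score vector")
  if (anyNA(scores) || any(!is.finite(scores))) abort("non-finite scores")
  if (any(scores <= 0))
    abort("score <= 0: a zero annihilates the geometric mean; ",
          "handle unsuitable parameters upstream with an explicit floor")
  exp(mean(log(scores)))
}

#' Classify HSI values into suitability zones
#'
#' Five-zone classification of composite HSI values. By default the four
#' thresholds are the 20/40/60/80th empirical percentiles of the supplied
#' values (quantile classification; linear interpolation between order
#' statistics, `stats::quantile()` type 7). Intervals are closed on the
#' left and open on the right, except the top class which is closed on both
#' sides, so a value equal to a threshold falls in the class above it.
#' Explicit thresholds may be supplied instead, and the thresholds published
#' for the 12 Hajar Mountain wadi sites (0.47, 0.51, 0.59, 0.75) ship as
#' preset `"hajar"`.
#'
#' @param hsi numeric vector of HSI values.
#' @param thresholds either `"quantile"` (default), the preset name
#'   `"hajar"`, or a numeric vector of 4 ascending thresholds.
#' @param type quantile interpolation type (see [stats::quantile()]).
#' @return a list with `thresholds` (ascending numeric, length 4), `labels`
#'   (ordered factor, one per site) and `levels` (the five class names).
#' @export
classify_suitability <- function(hsi, thresholds = "quantile", type = 7) {
  if (length(hsi) == 0L) abort("empty HSI vector")
  lev <- c("Unsuitable", "Less Suitable", "Moderately Suitable",
           "Suitable", "Highly Suitable")
  if (is.character(thresholds)) {
    thr <- switch(match.arg(thresholds, c("quantile", "hajar")),
                  quantile = unname(quantile(hsi, c(.2, .4, .6, .8),
                                             type = type, names = FALSE)),
                  hajar = c(0.47, 0.51, 0.59, 0.75))
  } else {
    thr <- as.numeric(thresholds)
    if (length(thr) != 4L || is.unsorted(thr))
      abort("explicit thresholds must be 4 ascending numbers")
  }
  # left-closed: value == threshold goes up; findInterval counts x >= thr
  idx <- findInterval(hsi, thr, left.open = FALSE) + 1L
  list(thresholds = thr,
       labels = factor(lev[idx], levels = lev, ordered = TRUE),
       levels = lev)
}

#' Substrate-texture impact on the HSI
#'
#' Per-site percent change of the composite HSI when the substrate-texture
#' sub-score is included, `100 * (with - without) / without`, with counts of
#' improved, degraded and unchanged sites.
#'
#' @param hsi_with,hsi_without composite HSI values for the same sites with
#'   and without the texture score.
#' @return a list with `percent_change` (numeric, per site), and counts
#'   `improved`, `degraded`, `unchanged`.
#' @export
substrate_impact <- function(hsi_with, hsi_without) {
  if (length(hsi_with) != length(hsi_without))
    abort("site sets differ in length")
  if (any(hsi_without == 0)) abort("zero baseline HSI")
  pc <- 100 * (hsi_with - hsi_without) / hsi_without
  list(percent_change = pc,
       improved = sum(pc > 0), degraded = sum(pc < 0),
       unchanged = sum(pc == 0))
}
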