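#' Cosby pedotransfer function
#'
#' Saturated hydraulic conductivity predicted from sand and clay fractions by
#' the Cosby et al. (1984) regression,
#' \eqn{\log_{10} K_s = b_0 + b_1 \cdot sand\% + b_2 \cdot clay\%}
#' (default coefficients -0.6, 0.0126, -0.0064; Ks in inches/hour).
#' The coefficients are an explicit argument so the regression is auditable
#' and swappable.
#'
#' @param sand,clay fractions in \[0, 1\].
#' @param coefs named numeric vector `c(intercept, sand, clay)` applied to
#'   percentages.
#' @return predicted saturated hydraulic conductivity (positive numeric).
#' @export
cosby_ks <- function(sand, clay,
                     coefs = c(intercept = -0.6, sand = 0.0126, clay = -0.0064)) {
  if (any(sand < 0 | sand > 1 | clay < 0 | clay > 1, na.rm = TRUE))
    abort("sand and clay must be fractions in [0, 1]")
  10^(coefs[["intercept"]] + coefs[["sand"]] * 100 * sand +
        coefs[["clay"]] * 100 * clay)
}

#' Substrate-texture suitability score
#'
#' Converts site substrate compositions into a (0, 1] sub-score that can
#' enter the geometric-mean HSI alongside the Gaussian parameter scores.
#' Sand/silt/clay fractions (gravel excluded, fines renormalized to sum to 1)
#' are passed through the Cosby pedotransfer regression ([cosby_ks()]) and
#' the predicted conductivities are log-normalized over the site set:
#' \deqn{score_i = \frac{\log v_i - \log v_{min}}{\log v_{max} - \log v_{min}},}
#' floored at `floor` so the minimum-value site cannot annihilate the
#' geometric mean. The score is relative to the supplied site set, hence
#' deterministic given that set; a single site has no normalization span and
#' is an error.
#'
#' @param sand,silt,clay numeric vectors of fractions in \[0, 1\], one value
#'   per site; each site's fractions must sum to 1 within `tol`
#'   (after renormalizing over the fines if gravel was reported separately,
#'   pass already-renormalized fractions).
#' @param floor minimum score (default 1e-3).
#' @param tol allowed deviation of sand+silt+clay from 1 (default 0.02).
#' @param coefs passed to [cosby_ks()].
#' @return numeric vector of texture scores in `[floor, 1]`.
#' @export
texture_score <- function(sand, silt, clay, floor = 1e-3, tol = 0.02,
                          coefs = c(intercept = -0.6, sand = 0.0126,
                                    clay = -0.0064)) {
  n <- length(sand)
  if (length(silt) != n || length(clay) != n)
    abort("sand, silt and clay must have equal length")
  if (n < 2L)
    abort("texture_score needs at least two sites: ",
          "log-normalization has no span on a single site")
  if (any(c(sand, silt, clay) < 0 | c(sand, silt, clay) > 1, na.rm = TRUE))
    abort("substrate fractions must lie in [0, 1]")
  tot <- sand + silt + clay
  bad <- which(abs(tot - 1) > tol)
  if (length(bad))
    abort("sand+silt+clay deviates from 1 beyond tolerance at site(s) ",
          paste(bad, collapse = ", "),
          " (renormalize the fines if gravel is reported separately)")
  # renormalize residual rounding so compositions are exact
  sand <- sand / tot; clay <- clay / tot
  v <- log(cosby_ks(sand, clay, coefs = coefs))
  span <- max(v) - min(v)
  if (span == 0) return(rep(1, n))  # identical compositions: no discrimination
  pmax((v - min(v)) / span, floor)
}
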