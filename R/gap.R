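#' High-suitability habitat mask
#'
#' Thresholds a suitability grid at an upper percentile of its valid cells
#' (default the 90th); cells at or above the threshold form the
#' high-suitability habitat. `NA` (NODATA) cells are excluded from both the
#' percentile computation and the mask.
#'
#' @param suitability numeric matrix (or vector) of suitability values.
#' @param percentile percentile threshold in (0, 100) (default 90).
#' @param type quantile interpolation type (default 7, linear).
#' @return list with `mask` (logical, same shape, `NA` where input is
#'   `NA`), `threshold`, `n_habitat` (cells in the mask).
#' @export
high_suitability_mask <- function(suitability, percentile = 90, type = 7) {
  v <- as.numeric(suitability)
  if (all(is.na(v))) abort("no valid cells")
  thr <- quantile(v, percentile / 100, na.rm = TRUE, type = type,
                  names = FALSE)
  mask <- suitability >= thr
  list(mask = mask, threshold = thr, n_habitat = sum(mask, na.rm = TRUE))
}

#' Protection rate of high-suitability habitat
#'
#' Overlays a protected-area mask on a habitat mask: the protection rate is
#' the percentage of habitat cells that fall inside protected areas, and
#' areas are cell counts times a constant cell area (equal-area grid
#' assumed).
#'
#' @param habitat logical habitat mask (e.g. from
#'   [high_suitability_mask()]).
#' @param protected logical protected-area mask, same shape.
#' @param cell_area_km2 area of one cell in square km (default 1).
#' @return list with `habitat_km2`, `protected_km2`, `rate` (percent),
#'   and the underlying cell counts.
#' @export
protection_rate <- function(habitat, protected, cell_area_km2 = 1) {
  if (!identical(dim(habitat), dim(protected)) &&
      length(habitat) != length(protected))
    abort("habitat and protected masks differ in shape")
  hab <- sum(habitat, na.rm = TRUE)
  if (hab == 0) abort("empty habitat mask")
  both <- sum(habitat & protected, na.rm = TRUE)
  list(habitat_cells = hab, protected_cells = both,
       habitat_km2 = hab * cell_area_km2,
       protected_km2 = both * cell_area_km2,
       rate = 100 * both / hab)
}

#' Progress and fold increase against protection targets
#'
#' For each named percentage target: progress = 100 * rate / target and the
#' required fold increase = target / rate (reported raw and rounded to the
#' nearest integer; infinite when the current rate is zero).
#'
#' @param rate current protection rate in percent.
#' @param targets named numeric vector of percentage targets, e.g.
#'   `c(national_2040 = 7.5, cbd_30x30 = 30)` (the default).
#' @return data.frame with columns `target_name`, `target`, `progress`,
#'   `fold_increase`, `fold_rounded`.
#' @export
target_progress <- function(rate,
                            targets = c(national_2040 = 7.5, cbd_30x30 = 30)) {
  if (rate < 0) abort("negative protection rate")
  if (any(targets <= 0)) abort("targets must be positive")
  fold <- if (rate == 0) rep(Inf, length(targets)) else targets / rate
  data.frame(target_name = names(targets) %||% seq_along(targets),
             target = unname(targets),
             progress = if (rate == 0) rep(0, length(targets)) else
               unname(100 * rate / targets),
             fold_increase = unname(fold),
             fold_rounded = round(unname(fold)),
             row.names = NULL)
}

#' Classify wadi (stream) density
#'
#' Three-way classification of stream density (km of stream per square km):
#' high above 0.0008, medium in the closed interval \[0.0004, 0.0008\], low
#' below 0.0004. Both boundary values fall in the medium class.
#'
#' @param density numeric vector of densities (km/km^2).
#' @return factor with levels low/medium/high.
#' @export
wadi_density_classify <- function(density) {
  if (any(density < 0, na.rm = TRUE)) abort("negative stream density")
  lab <- ifelse(is.na(density), NA_character_,
                ifelse(density > 0.0008, "high",
                       ifelse(density >= 0.0004, "medium", "low")))
  factor(lab, levels = c("low", "medium", "high"))
}

#' Wadi-density protection summary
#'
#' Accounts for stream protection by density class in two explicitly
#' labelled readings: (i) the within-class protection rate, i.e. the
#' percentage of each class's streams that are protected, with the gap to
#' that class's target; and (ii) the composition of the protected stream
#' set, i.e. each class's share of all protected streams (these shares sum
#' to 100).
#'
#' @param class factor/character of density classes per stream
#'   (low/medium/high, e.g. from [wadi_density_classify()]).
#' @param protected logical per stream.
#' @param targets named percentage targets per class (default high 50,
#'   medium 30, low 10).
#' @return data.frame with one row per class: `total`, `protected_n`,
#'   `within_class_rate`, `target`, `gap`, `share_of_protected`.
#' @export
density_protection_summary <- function(class, protected,
                                       targets = c(high = 50, medium = 30,
                                                   low = 10)) {
  if (length(class) != length(protected))
    abort("class and protected differ in length")
  class <- factor(as.character(class), levels = c("high", "medium", "low"))
  if (anyNA(class)) abort("unknown density class")
  tot <- tapply(rep(1L, length(class)), class, sum, default = 0L)
  prot <- tapply(as.integer(protected), class, sum, default = 0L)
  rate <- ifelse(tot > 0, 100 * prot / tot, NA_real_)
  share <- if (sum(prot) > 0) 100 * prot / sum(prot) else rep(NA_real_, 3)
  data.frame(class = names(tot), total = as.integer(tot),
             protected_n = as.integer(prot),
             within_class_rate = as.numeric(rate),
             target = unname(targets[names(tot)]),
             gap = unname(targets[names(tot)]) - as.numeric(rate),
             share_of_protected = as.numeric(share),
             row.names = NULL)
}
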