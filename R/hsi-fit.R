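#' Fit a Habitat Suitability Index model
#'
#' The central fitting function. For each environmental parameter an
#' abundance-weighted Gaussian suitability curve is fitted
#' ([weighted_gaussian_fit()]), each site is scored on each curve
#' ([gaussian_suitability()], clamped to observed ranges by default), an
#' optional substrate-texture sub-score is added ([texture_score()]), and
#' the per-site scores are combined into the composite HSI as their
#' geometric mean ([geometric_mean_hsi()]).
#'
#' @param data data.frame of sites: one row per site with numeric
#'   environmental parameter columns, an abundance column, and (optionally)
#'   `sand`, `silt`, `clay` fraction columns for the texture sub-score. A
#'   `site` column, if present, supplies site IDs; otherwise row names are
#'   used.
#' @param abundance name of the abundance (weight) column.
#' @param params character vector of parameter columns to fit. Default: all
#'   numeric columns except the abundance, site and substrate columns.
#' @param texture include the substrate-texture sub-score (requires the
#'   fraction columns)?
#' @param weights_type passed to [weighted_gaussian_fit()].
#' @param clamp clamp parameter values to observed ranges when scoring?
#' @param texture_floor floor for the texture log-normalization.
#' @return an object of class `"hsi_fit"` with components `curves` (named
#'   list of suitability curves), `scores` (sites x parameters matrix of
#'   suitabilities, including a `texture` column when fitted), `hsi`
#'   (composite per site), `site` (IDs), `abundance`, `texture` (the stored
#'   normalization, or `NULL`), `data` and `call`. Methods: `print`,
#'   `summary`, `coef`, `predict`, `fitted`, `plot`.
#' @examples
#' set.seed(1)
#' d <- simulate_sites(n_sites = 12, model = true_model(seed = 1))$sites
#' fit <- hsi_fit(d)
#' fit
#' head(fitted(fit))
#' @export
hsi_fit <- function(data, abundance = "abundance", params = NULL,
                    texture = TRUE,
                    weights_type = c("frequency", "reliability"),
                    clamp = TRUE, texture_floor = 1e-3) {
  weights_type <- match.arg(weights_type)
  if (!is.data.frame(data)) abort("'data' must be a data.frame of sites")
  if (!abundance %in% names(data))
    abort("abundance column '", abundance, "' not found")
  w <- data[[abundance]]
  if (any(w < 0)) abort("negative abundance")
  site <- if ("site" %in% names(data)) as.character(data$site)
          else rownames(data)
  frac_cols <- c("sand", "silt", "clay", "gravel")
  if (is.null(params)) {
    num <- vapply(data, is.numeric, logical(1))
    params <- setdiff(names(data)[num],
                      c(abundance, "site", "season", "true_suitability",
                        frac_cols))
  }
  if (length(params) == 0L) abort("no parameter columns to fit")
  missing_p <- setdiff(params, names(data))
  if (length(missing_p))
    abort("parameter column(s) not found: ", paste(missing_p, collapse = ", "))

  curves <- lapply(params, function(p)
    weighted_gaussian_fit(data[[p]], w, parameter = p, type = weights_type))
  names(curves) <- params
  scores <- vapply(params, function(p)
    gaussian_suitability(data[[p]], curves[[p]], clamp = clamp),
    numeric(nrow(data)))
  scores <- matrix(scores, nrow = nrow(data),
                   dimnames = list(site, params))

  tex <- NULL
  if (texture) {
    have <- all(c("sand", "silt", "clay") %in% names(data))
    if (!have && !missing(texture))
      abort("texture = TRUE but sand/silt/clay columns are missing")
    if (have) {
      ts <- texture_score(data$sand, data$silt, data$clay,
                          floor = texture_floor)
      v <- log(cosby_ks(sand = data$sand / (data$sand + data$silt + data$clay),
                        clay = data$clay / (data$sand + data$silt + data$clay)))
      tex <- list(log_min = min(v), log_max = max(v), floor = texture_floor)
      scores <- cbind(scores, texture = ts)
    }
  }

  hsi <- apply(scores, 1L, geometric_mean_hsi)
  structure(
    list(curves = curves, scores = scores, hsi = hsi, site = site,
         abundance = w, texture = tex, clamp = clamp, data = data,
         call = match.call()),
    class = "hsi_fit")
}

#' @export
print.hsi_fit <- function(x, digits = 3, ...) {
  cat("Habitat Suitability Index model (abundance-weighted Gaussian curves)\n")
  cat(sprintf("  %d sites, %d parameters%s\n", length(x$hsi),
              length(x$curves),
              if (is.null(x$texture)) "" else " + substrate texture"))
  cat(sprintf("  composite HSI: %.*f - %.*f (mean %.*f)\n",
              digits, min(x$hsi), digits, max(x$hsi), digits, mean(x$hsi)))
  invisible(x)
}

#' @export
coef.hsi_fit <- function(object, ...) {
  t(vapply(object$curves,
           function(cv) c(mu = cv$mu, sigma = cv$sigma,
                          low = cv$low, high = cv$high),
           numeric(4)))
}

#' @export
fitted.hsi_fit <- function(object, ...) object$hsi

#' Summarize a fitted HSI model
#'
#' Reports per-site composite HSI with suitability classes, the fitted
#' curve parameters with their optimal ranges, and parameter importance
#' (mean and SD of each parameter's suitability across sites, ranked).
#'
#' @param object an [hsi_fit()] object.
#' @param thresholds passed to [classify_suitability()].
#' @param ... ignored.
#' @export
summary.hsi_fit <- function(object, thresholds = "quantile", ...) {
  cls <- classify_suitability(object$hsi, thresholds = thresholds)
  sites <- data.frame(site = object$site, hsi = object$hsi,
                      class = cls$labels, row.names = NULL)
  opt <- t(vapply(object$curves, optimal_range, numeric(2)))
  curves <- data.frame(coef(object), optimal_low = opt[, "low"],
                       optimal_high = opt[, "high"])
  imp <- data.frame(mean_suitability = colMeans(object$scores),
                    sd_suitability = apply(object$scores, 2L, sd))
  imp <- imp[order(-imp$mean_suitability), ]
  structure(list(sites = sites, curves = curves, importance = imp,
                 thresholds = cls$thresholds),
            class = "summary.hsi_fit")
}

#' @export
print.summary.hsi_fit <- function(x, digits = 3, ...) {
  cat("Per-site composite HSI:\n")
  print(x$sites, digits = digits)
  cat(sprintf("\nClass thresholds: %s\n",
              paste(format(x$thresholds, digits = digits), collapse = ", ")))
  cat("\nFitted curves (mu, sigma, observed and optimal ranges):\n")
  print(round(x$curves, digits))
  cat("\nParameter importance (mean suitability across sites):\n")
  print(round(x$importance, digits))
  invisible(x)
}

#' Predict composite HSI for new sites
#'
#' Scores new sites on the stored curves. The texture sub-score of a new
#' site is log-normalized against the training span (and clipped into it),
#' keeping prediction consistent with the constrained-range philosophy of
#' the fit.
#'
#' @param object an [hsi_fit()] object.
#' @param newdata data.frame with the same parameter (and, if the model was
#'   fitted with texture, substrate fraction) columns. Default: the
#'   training data.
#' @param type `"hsi"` (composite, default) or `"scores"` (matrix).
#' @param ... ignored.
#' @export
predict.hsi_fit <- function(object, newdata = object$data,
                            type = c("hsi", "scores"), ...) {
  type <- match.arg(type)
  params <- names(object$curves)
  missing_p <- setdiff(params, names(newdata))
  if (length(missing_p))
    abort("newdata lacks column(s): ", paste(missing_p, collapse = ", "))
  scores <- vapply(params, function(p)
    gaussian_suitability(newdata[[p]], object$curves[[p]],
                         clamp = object$clamp),
    numeric(nrow(newdata)))
  scores <- matrix(scores, nrow = nrow(newdata),
                   dimnames = list(NULL, params))
  if (!is.null(object$texture)) {
    if (!all(c("sand", "silt", "clay") %in% names(newdata)))
      abort("model includes texture but newdata lacks sand/silt/clay")
    tot <- newdata$sand + newdata$silt + newdata$clay
    v <- log(cosby_ks(newdata$sand / tot, newdata$clay / tot))
    tx <- object$texture
    sc <- (pmin(pmax(v, tx$log_min), tx$log_max) - tx$log_min) /
      (tx$log_max - tx$log_min)
    scores <- cbind(scores, texture = pmax(sc, tx$floor))
  }
  if (type == "scores") return(scores)
  apply(scores, 1L, geometric_mean_hsi)
}

#' Plot fitted suitability curves
#'
#' One panel per environmental parameter: the Gaussian suitability curve
#' over the observed range, the observed site values (abundance-weighted
#' point sizes), and the optimal range (shaded).
#'
#' @param x an [hsi_fit()] object.
#' @param params which curves to draw (default all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.hsi_fit <- function(x, params = names(x$curves), ...) {
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(params)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (p in params) {
    cv <- x$curves[[p]]
    xx <- seq(cv$low, cv$high, length.out = 200)
    opt <- optimal_range(cv)
    plot(xx, gaussian_suitability(xx, cv), type = "l", ylim = c(0, 1),
         xlab = p, ylab = "suitability", main = p, ...)
    graphics::rect(opt["low"], 0, opt["high"], 1,
                   col = grDevices::adjustcolor("steelblue", 0.15),
                   border = NA)
    w <- x$abundance / max(x$abundance)
    graphics::points(x$data[[p]], gaussian_suitability(x$data[[p]], cv),
                     cex = 0.5 + 1.5 * w, pch = 19,
                     col = grDevices::adjustcolor("darkred", 0.6))
  }
  invisible(x)
}
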