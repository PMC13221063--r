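#' Define the generating model for synthetic wadi data
#'
#' Encodes the Gaussian response structure the HSI framework assumes: each
#' environmental parameter has a true niche optimum and width, sites draw
#' parameter values uniformly within field-observed bounds, and expected
#' abundance is an abundance scale times the product of per-parameter
#' Gaussian responses. Defaults emulate the 12-site Hajar Mountain survey:
#' the parameter bounds are the published field ranges (depth 25-84 cm,
#' width 2.5-11.5 m, velocity 0.01-0.4 m/s, temperature 28-31.6 deg C, pH
#' 7.9-8.6, EC 696.2-2609.5 uS/cm, TDS 351.7-1331.2 mg/L, salinity
#' 0.33-1.33 ppt, DO 5.8-10.4 mg/L, BOD 2.84-4.36 mg/L, turbidity 1.1-22
#' NTU), true optima sit at range midpoints with widths of a third of the
#' range, and the abundance scale is calibrated so the noiseless median
#' abundance is near the geometric midpoint of the observed 979-17,708
#' envelope.
#'
#' @param parameters data.frame with columns `parameter`, `low`, `high`,
#'   and optionally `mu_true`, `sigma_true` (defaults: midpoint, range/3).
#' @param gamma specialist-dominance exponent (> 0): how steeply the
#'   specialist's share of the community grows with habitat suitability.
#' @param n_species species pool size S (>= 2).
#' @param abundance_scale expected abundance at a site sitting exactly on
#'   every niche optimum.
#' @param dispersion lognormal noise dispersion (sdlog) on abundance; 0 for
#'   noiseless.
#' @param specialist_cap upper cap (< 1) on the specialist's expected share
#'   so diversity stays defined at suitability 1.
#' @param seed integer seed; all generator randomness flows from it.
#' @return object of class `"true_model"`.
#' @export
true_model <- function(parameters = NULL, gamma = 2, n_species = 4,
                       abundance_scale = 2.6e5, dispersion = 0.3,
                       specialist_cap = 0.995, seed = 1) {
  if (is.null(parameters)) {
    parameters <- data.frame(
      parameter = c("depth", "width", "velocity", "temperature", "pH",
                    "ec", "tds", "salinity", "do", "bod", "turbidity"),
      low  = c(25, 2.5, 0.01, 28, 7.9, 696.2, 351.7, 0.33, 5.8, 2.84, 1.1),
      high = c(84, 11.5, 0.4, 31.6, 8.6, 2609.5, 1331.2, 1.33, 10.4, 4.36, 22))
  }
  if (!all(c("parameter", "low", "high") %in% names(parameters)))
    abort("'parameters' needs columns parameter, low, high")
  if (is.null(parameters$mu_true))
    parameters$mu_true <- (parameters$low + parameters$high) / 2
  if (is.null(parameters$sigma_true))
    parameters$sigma_true <- (parameters$high - parameters$low) / 3
  bad <- parameters$parameter[parameters$low >= parameters$high]
  if (length(bad))
    abort("degenerate bounds (low >= high) for parameter(s): ",
          paste(bad, collapse = ", "))
  if (any(parameters$sigma_true <= 0)) abort("sigma_true must be positive")
  if (gamma <= 0) abort("gamma must be positive")
  if (n_species < 2) abort("need a species pool of at least 2")
  if (abundance_scale <= 0 || dispersion < 0) abort("invalid abundance model")
  if (specialist_cap <= 0 || specialist_cap >= 1)
    abort("specialist_cap must lie in (0, 1)")
  structure(list(parameters = parameters, gamma = gamma,
                 n_species = n_species, abundance_scale = abundance_scale,
                 dispersion = dispersion, specialist_cap = specialist_cap,
                 seed = as.integer(seed)),
            class = "true_model")
}

#' Generate synthetic wadi sites
#'
#' Draws `n_sites` sites: parameter values uniform within the model bounds,
#' substrate fractions (sand-dominated fines plus a separately reported
#' gravel fraction, as in the surveyed wadis), and realized abundance =
#' expected Gaussian-response abundance times multiplicative lognormal
#' noise (mean-preserving, dispersion `model$dispersion`), rounded and
#' floored at 1. With `seasons > 1` each site is emitted once per seasonal
#' visit with independently drawn measurements (pooled, single-season
#' output is the default). Identical model + seed gives identical output.
#'
#' @param model a [true_model()].
#' @param n_sites number of sites (>= 2).
#' @param seasons number of seasonal visits per site (default 1).
#' @param seed optional override of `model$seed`.
#' @return list with `sites` (data.frame: site, season if > 1, parameter
#'   columns, sand/silt/clay/gravel, true_suitability, abundance) and
#'   `model`.
#' @export
simulate_sites <- function(model = true_model(), n_sites = 12, seasons = 1,
                           seed = model$seed) {
  if (!inherits(model, "true_model")) abort("'model' must be a true_model")
  if (n_sites < 2) abort("n_sites must be >= 2")
  pars <- model$parameters
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(seasons), function(s) {
      x <- vapply(seq_len(nrow(pars)), function(j)
        runif(n_sites, pars$low[j], pars$high[j]), numeric(n_sites))
      colnames(x) <- pars$parameter
      suit <- vapply(seq_len(nrow(pars)), function(j)
        exp(-(x[, j] - pars$mu_true[j])^2 / (2 * pars$sigma_true[j]^2)),
        numeric(n_sites))
      true_s <- apply(suit, 1L, prod)
      mu_ab <- model$abundance_scale * true_s
      noise <- if (model$dispersion > 0)
        rlnorm(n_sites, -model$dispersion^2 / 2, model$dispersion)
      else rep(1, n_sites)
      # substrate: sand-dominated fines, gravel reported separately
      sand_f <- runif(n_sites, 0.3, 0.9)
      silt_f <- runif(n_sites, 0, 1 - sand_f)
      clay_f <- 1 - sand_f - silt_f
      gravel <- runif(n_sites, 0, 0.9)
      data.frame(site = sprintf("W%02d", seq_len(n_sites)),
                 season = s, x, sand = sand_f, silt = silt_f, clay = clay_f,
                 gravel = gravel, true_suitability = true_s,
                 abundance = pmax(1, round(mu_ab * noise)))
    }))
    if (seasons == 1) out$season <- NULL
    list(sites = out, model = model)
  })
}

#' Generate a synthetic community matrix from HSI scores
#'
#' Emulates the specialization-dominance structure: at each site the
#' specialist's expected relative abundance is `h^gamma` rescaled from the
#' uniform share 1/S (at h = 0) up to the cap (at h = 1); the remaining
#' mass is split equally among the S - 1 generalists. With `noise = TRUE`
#' counts are a multinomial draw (symmetric noise around the expected
#' shares); otherwise expected shares are scaled by `n_individuals` and
#' rounded. The Shannon diversity of the expected composition is
#' non-increasing in h, which is what drives the negative HSI-diversity
#' correlation downstream.
#'
#' @param hsi numeric vector of per-site HSI scores in \[0, 1\].
#' @param model a [true_model()] (supplies gamma, S, cap, seed).
#' @param n_individuals community size per site (default 1000).
#' @param noise multinomial sampling noise (default TRUE)?
#' @param seed optional override of `model$seed`.
#' @return sites x species integer matrix; first column is the specialist.
#' @export
simulate_community <- function(hsi, model = true_model(),
                               n_individuals = 1000, noise = TRUE,
                               seed = model$seed) {
  if (length(hsi) == 0L) abort("empty HSI score vector")
  if (any(hsi < 0 | hsi > 1)) abort("HSI scores must lie in [0, 1]")
  S <- model$n_species
  shares <- community_shares(hsi, model)
  counts <- with_seed(seed, {
    t(vapply(seq_along(hsi), function(i) {
      if (noise) as.integer(rmultinom(1, n_individuals, shares[i, ]))
      else as.integer(round(shares[i, ] * n_individuals))
    }, integer(S)))
  })
  colnames(counts) <- c("specialist", paste0("generalist_", seq_len(S - 1)))
  rownames(counts) <- names(hsi) %||% sprintf("W%02d", seq_along(hsi))
  counts
}

# internal: expected relative abundances under the dominance model
community_shares <- function(hsi, model) {
  S <- model$n_species
  p1 <- 1 / S + (model$specialist_cap - 1 / S) * hsi^model$gamma
  cbind(p1, matrix((1 - p1) / (S - 1), length(hsi), S - 1))
}

#' Generate synthetic grids for gap analysis
#'
#' A suitability grid (uniform values in \[0, 1\]), a binary protected-area
#' mask with an exact protected fraction (cells chosen by seeded sampling),
#' and a nonnegative stream-density grid (exponential, mean 0.0006
#' km/km^2, spanning the low/medium/high wadi-density classes).
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param pa_fraction protected fraction in (0, 1).
#' @param seed integer seed.
#' @return list of three `"ascii_grid"` objects: `suitability`,
#'   `protected`, `density`.
#' @export
simulate_grids <- function(n_rows, n_cols, pa_fraction = 0.056, seed = 1) {
  if (n_rows < 1 || n_cols < 1) abort("grid dimensions must be >= 1")
  if (pa_fraction <= 0 || pa_fraction >= 1)
    abort("pa_fraction must lie strictly between 0 and 1")
  n <- n_rows * n_cols
  with_seed(seed, {
    suit <- matrix(runif(n), n_rows, n_cols)
    prot <- matrix(0, n_rows, n_cols)
    prot[sample.int(n, round(pa_fraction * n))] <- 1
    dens <- matrix(rexp(n, rate = 1 / 0.0006), n_rows, n_cols)
    as_g <- function(m) structure(
      list(data = m, xllcorner = 0, yllcorner = 0, cellsize = 1,
           nodata_value = -9999), class = "ascii_grid")
    list(suitability = as_g(suit), protected = as_g(prot),
         density = as_g(dens))
  })
}

#' Generate presence/background suitability score sets
#'
#' Background scores are uniform on \[0, 1/(1+s)\] and presence scores
#' uniform on \[s/(1+s), 1\] with s = `separation`: s = 0 gives
#' exchangeable sets (AUC 0.5 in expectation), AUC grows monotonically with
#' s, and s > 1 makes the supports disjoint (AUC = 1).
#'
#' @param n_presence,n_background set sizes (>= 1).
#' @param separation nonnegative real.
#' @param seed integer seed.
#' @return list with numeric vectors `presence` and `background` in
#'   \[0, 1\].
#' @export
simulate_prediction_sets <- function(n_presence, n_background,
                                     separation = 1, seed = 1) {
  if (n_presence < 1 || n_background < 1) abort("set sizes must be >= 1")
  if (separation < 0) abort("separation must be nonnegative")
  with_seed(seed, {
    s <- separation
    list(presence = (s + runif(n_presence)) / (1 + s),
         background = runif(n_background) / (1 + s))
  })
}
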