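#' Alpha diversity metrics
#'
#' Shannon diversity \eqn{H = -\sum p_i \ln p_i} (natural log),
#' Gini-Simpson diversity \eqn{1 - \sum p_i^2}, and Pielou evenness
#' \eqn{J = H / \ln S_{obs}}. Shannon and Simpson are computed through
#' \pkg{vegan}; evenness uses the observed species richness and is
#' undefined (`NA`) for a single-species community rather than 0.
#'
#' @param counts nonnegative numeric vector of species counts (one
#'   community), or a sites x species matrix/data.frame (one value per row).
#' @return numeric vector of index values.
#' @name alpha_diversity
NULL

count_matrix <- function(counts) {
  m <- if (is.null(dim(counts))) matrix(counts, nrow = 1L)
       else as.matrix(counts)
  if (any(m < 0)) abort("negative counts")
  if (any(rowSums(m) <= 0)) abort("community with zero total count")
  m
}

#' @rdname alpha_diversity
#' @export
shannon <- function(counts) {
  unname(vegan::diversity(count_matrix(counts), index = "shannon"))
}

#' @rdname alpha_diversity
#' @export
simpson <- function(counts) {
  unname(vegan::diversity(count_matrix(counts), index = "simpson"))
}

#' @rdname alpha_diversity
#' @export
evenness <- function(counts) {
  m <- count_matrix(counts)
  s_obs <- rowSums(m > 0)
  ifelse(s_obs > 1, shannon(m) / log(s_obs), NA_real_)
}

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarity
#' \eqn{d(x, y) = 1 - 2\sum\min(x_i, y_i) / (\sum x + \sum y)} between site
#' rows of a community matrix (through [vegan::vegdist()]).
#'
#' @param comm sites x species matrix of nonnegative counts.
#' @return symmetric numeric matrix in \[0, 1\] with zero diagonal.
#' @export
bray_curtis_matrix <- function(comm) {
  m <- count_matrix(comm)
  as.matrix(vegan::vegdist(m, method = "bray"))
}

#' Pearson correlation with bootstrap confidence interval
#'
#' Pearson's r with a seeded nonparametric bootstrap CI: whole site pairs
#' (x_i, y_i) are resampled with replacement `n_boot` times and the CI is
#' the percentile interval of the bootstrap r distribution. The p-value is
#' the usual two-sided t-transform of r (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors, equal length >= 4.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed for the resampling.
#' @param conf confidence level (default 0.95).
#' @return list with `r`, `ci` (length-2 numeric), `p_value`, `n_boot`,
#'   `seed`, `boot_r` (the bootstrap distribution).
#' @export
correlate_with_bootstrap <- function(x, y, n_boot = 1000, seed = 1,
                                     conf = 0.95) {
  if (length(x) != length(y)) abort("x and y differ in length")
  n <- length(x)
  if (n < 4L) abort("need at least 4 pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y")
  ct <- cor.test(x, y)
  boot_r <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(x[idx]) == 0 || sd(y[idx]) == 0) NA_real_
      else cor(x[idx], y[idx])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot_r, c(alpha, 1 - alpha), na.rm = TRUE))
  list(r = unname(ct$estimate), ci = ci, p_value = ct$p.value,
       n_boot = n_boot, seed = seed, boot_r = boot_r)
}

#' Diversity summary of a community matrix
#'
#' Per-site Shannon, Gini-Simpson and Pielou metrics in one tidy table.
#'
#' @param comm sites x species count matrix (rownames = site IDs).
#' @return data.frame with columns `site`, `shannon`, `simpson`, `evenness`.
#' @export
diversity_table <- function(comm) {
  m <- count_matrix(comm)
  data.frame(site = rownames(m) %||% seq_len(nrow(m)),
             shannon = shannon(m), simpson = simpson(m),
             evenness = evenness(m), row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
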