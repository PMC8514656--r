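# Validation statistics: overlap-over-union "mutual information" between two
# discretized posterior distributions, highest-density-interval trueness,
# and weighted posterior correlation matrices.

#' Weighted quantiles (left-continuous inverse CDF)
#'
#' @param x Sample values.
#' @param w Non-negative weights (need not be normalised).
#' @param probs Probabilities in \[0, 1\].
#' @return Quantile values: the smallest `x` whose cumulative weight reaches
#'   each probability.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) {
    if (p <= 0) return(x[1])
    x[which(cw >= p - 1e-12)[1]]
  }, numeric(1))
}

weighted_histogram <- function(x, w, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = FALSE)
  n_bins <- length(edges) - 1L
  inside <- idx >= 1L & idx <= n_bins
  h <- numeric(n_bins)
  if (any(inside)) {
    tab <- tapply(w[inside], idx[inside], sum)
    h[as.integer(names(tab))] <- tab
  }
  h
}

#' Overlap-over-union mutual information between two weighted distributions
#'
#' Both sample sets are discretized on a shared 100-bin equal-width grid
#' spanning the union of their ranges; each weighted histogram is
#' normalised to unit mass, and
#' `MI = 100 * sum(min(hA, hB)) / sum(max(hA, hB))` percent.  Identical
#' distributions give 100%, disjoint supports give 0%.  This is the
#' reproducibility overlap statistic, not Shannon mutual information.
#'
#' @param a,b Numeric sample vectors.
#' @param wa,wb Optional weights (default equal).
#' @param n_bins Number of bins (default 100).
#' @param resample If `TRUE`, each weighted set is first resampled (with
#'   replacement, seeded by the caller) to an unweighted set of the same
#'   size before binning.
#' @return MI percentage in \[0, 100\]; symmetric in its arguments.
#' @export
mutual_information <- function(a, b, wa = NULL, wb = NULL, n_bins = 100,
                               resample = FALSE) {
  stopifnot(length(a) > 0, length(b) > 0)
  if (is.null(wa)) wa <- rep(1, length(a))
  if (is.null(wb)) wb <- rep(1, length(b))
  # non-finite samples and samples of negligible relative weight (failed
  # or posterior-irrelevant simulations) carry no visible mass at any bin
  # resolution and are excluded from the discretization
  ok_a <- is.finite(a) & wa > 1e-12 * max(wa); a <- a[ok_a]; wa <- wa[ok_a]
  ok_b <- is.finite(b) & wb > 1e-12 * max(wb); b <- b[ok_b]; wb <- wb[ok_b]
  if (!length(a) || !length(b)) stop("no finite samples")
  if (sum(wa) <= 0 || sum(wb) <= 0) stop("zero total weight")
  if (resample) {
    a <- sample(a, length(a), replace = TRUE, prob = wa)
    b <- sample(b, length(b), replace = TRUE, prob = wb)
    wa <- rep(1, length(a)); wb <- rep(1, length(b))
  }
  lo <- min(a, b); hi <- max(a, b)
  if (hi <= lo) { # all mass at one point: widen by an epsilon
    eps <- max(1e-12, abs(lo) * 1e-9)
    lo <- lo - eps; hi <- hi + eps
  }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  ha <- weighted_histogram(a, wa, edges); ha <- ha / sum(ha)
  hb <- weighted_histogram(b, wb, edges); hb <- hb / sum(hb)
  100 * sum(pmin(ha, hb)) / sum(pmax(ha, hb))
}

#' Freedman-Diaconis bin width for a weighted sample
#'
#' `2 * IQR * n^(-1/3)` with the interquartile range taken from the
#' weighted quantiles and `n` the number of samples.
#'
#' @param x Sample values (n >= 2).
#' @param w Optional weights.
#' @return Bin width (0 when the weighted IQR is 0).
#' @export
freedman_diaconis_bin_width <- function(x, w = NULL) {
  stopifnot(length(x) >= 2)
  if (is.null(w)) w <- rep(1, length(x))
  iqr <- diff(weighted_quantile(x, w, c(0.25, 0.75)))
  2 * iqr * length(x)^(-1 / 3)
}

#' Posterior mass denser than the bin holding the true value
#'
#' Trueness statistic for virtual-patient validation: the posterior is
#' approximated by a weighted histogram with Freedman-Diaconis bin width,
#' and the statistic is the total mass of bins whose density strictly
#' exceeds the density of the bin containing `true_value` (that density is
#' 0 if the true value falls outside the sample range).  0% means the true
#' value sits in the modal bin (at the maximum a posteriori); 100% means it
#' is outside the distribution entirely.
#'
#' @param x Posterior samples.
#' @param w Optional weights.
#' @param true_value The known true parameter value.
#' @return Percentage in \[0, 100\].
#' @export
hdi_containing_true <- function(x, w = NULL, true_value) {
  stopifnot(length(x) >= 1)
  if (is.null(w)) w <- rep(1, length(x))
  ok <- is.finite(x) & w > 1e-12 * max(w)
  x <- x[ok]; w <- w[ok]
  if (!length(x) || sum(w) <= 0) stop("no finite samples with weight")
  h_width <- if (length(x) >= 2) freedman_diaconis_bin_width(x, w) else 0
  rng <- range(x)
  if (h_width <= 0 || diff(rng) == 0) {
    # degenerate spread: single bin holding all mass
    inside <- true_value >= rng[1] && true_value <= rng[2]
    return(if (inside) 0 else 100)
  }
  n_bins <- min(1e6, max(1L, ceiling(diff(rng) / h_width)))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  masses <- weighted_histogram(x, w, edges)
  masses <- masses / sum(masses)
  i_true <- findInterval(true_value, edges, rightmost.closed = TRUE)
  d_true <- if (i_true >= 1 && i_true <= n_bins) masses[i_true] else 0
  100 * sum(masses[masses > d_true])
}

#' Weighted posterior correlation matrix
#'
#' Weighted Pearson correlations between all parameter columns of a
#' posterior sample set, optionally augmented with the derived RV tissue
#' properties.  Columns with zero weighted variance get correlation 0 (with
#' a warning); the diagonal is 1.
#'
#' @param result An `amis_result` (or any list with `theta` data frame and
#'   `weight`).
#' @param tissue Optional `tissue_posterior` whose per-segment properties
#'   are appended as extra columns (wide format, matched by sample index).
#' @return Symmetric correlation matrix with entries in \[-1, 1\].
#' @export
weighted_correlation_matrix <- function(result, tissue = NULL) {
  X <- as.matrix(result$theta)
  w <- result$weight
  if (!is.null(tissue)) {
    props <- c("contractility", "compliance", "work_density")
    for (seg in tissue$segments) {
      sub <- tissue$properties[tissue$properties$segment == seg, ]
      add <- matrix(NA_real_, nrow(X), length(props),
                    dimnames = list(NULL, paste(props, seg, sep = "_")))
      add[sub$sample, ] <- as.matrix(sub[, props])
      X <- cbind(X, add)
    }
  }
  keep <- rowSums(!is.finite(X)) == 0 & is.finite(w)
  X <- X[keep, , drop = FALSE]
  w <- w[keep]
  if (sum(w > 0) < 2) stop("need at least 2 positively weighted samples")
  w <- w / sum(w)
  mu <- colSums(X * w)
  C <- sweep(X, 2, mu)
  cov_w <- crossprod(C * w, C)
  sd_w <- sqrt(pmax(diag(cov_w), 0))
  zero_var <- sd_w == 0
  if (any(zero_var)) {
    warning(sprintf("zero-variance column(s): %s; correlations set to 0",
                    paste(colnames(X)[zero_var], collapse = ", ")))
    sd_w[zero_var] <- 1
  }
  R <- cov_w / tcrossprod(sd_w)
  R[zero_var, ] <- 0
  R[, zero_var] <- 0
  diag(R) <- 1
  R <- pmin(pmax(R, -1), 1)
  R
}
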