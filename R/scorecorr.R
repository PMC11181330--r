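#' @include utils.R
NULL

#' Correlation panel between a score and a dynamics metric
#'
#' Computes the four association measures used to relate AlphaFold
#' confidence scores to fluctuation metrics: Pearson's R (linear),
#' Spearman's rho (monotone), Kendall's tau (ordinal) and mutual
#' information (general dependency). MI is estimated from an
#' equal-width 2D histogram with `miBins` bins per axis, in nats; the
#' fixed-bin estimator is deterministic and slightly positively biased
#' on independent data (compare against a permutation null for
#' calibrated use).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param miBins histogram bins per axis for MI (default 16).
#' @return list with `pearson_r`, `spearman_rho`, `kendall_tau`,
#'   `mutual_information` (nats) and `n_points`. Pearson R is NA
#'   (with a warning suppressed) when either variable is constant;
#'   rank statistics are still reported.
#' @export
correlateScores <- function(x, y, miBins = 16) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 points")
  constX <- stats::sd(x) == 0
  constY <- stats::sd(y) == 0
  pear <- if (constX || constY) NA_real_ else stats::cor(x, y)
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  tau <- suppressWarnings(stats::cor(x, y, method = "kendall"))
  list(pearson_r = pear, spearman_rho = rho, kendall_tau = tau,
       mutual_information = mutualInformation(x, y, bins = miBins),
       n_points = length(x))
}

#' Mutual information via equal-width 2D binning
#'
#' @param x,y numeric vectors of equal length.
#' @param bins bins per axis (default 16).
#' @return MI estimate in nats (>= 0).
#' @export
mutualInformation <- function(x, y, bins = 16) {
  stopifnot(length(x) == length(y), bins >= 2)
  cut1 <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) rep(1L, length(v))
    else pmin(pmax(findInterval(v, seq(r[1], r[2], length.out = bins + 1L),
                                rightmost.closed = TRUE), 1L), bins)
  }
  tab <- table(cut1(x), cut1(y))
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
}

#' Ordinary least-squares fit of a score on a fluctuation metric
#'
#' The regression used to summarize score-dynamics relationships,
#' e.g. pLDDT ~ sigma_d,20 (published pooled fit: slope about -9 per
#' Angstrom, intercepts with median 101.3) and PAE ~ sigma_d (slope
#' about 0.7, median intercept 2.4 Angstrom).
#'
#' @param x metric values (Angstrom), non-constant, length >= 2.
#' @param y score values.
#' @return list with `slope`, `intercept`, `pearson_r`,
#'   `slope_se`, `intercept_se`, `n_points`.
#' @export
fitLinearScore <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("need at least 2 points")
  if (stats::sd(x) == 0) stop("metric values are constant")
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  list(slope = unname(cf["x", "Estimate"]),
       intercept = unname(cf["(Intercept)", "Estimate"]),
       pearson_r = if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y),
       slope_se = unname(cf["x", "Std. Error"]),
       intercept_se = unname(cf["(Intercept)", "Std. Error"]),
       n_points = length(x))
}

#' Sensitivity/specificity sweep of a score threshold
#'
#' Sweeps a confidence-score threshold and reports how well it
#' separates rigid from flexible according to a fluctuation metric
#' cutoff. For pLDDT-like scores (high score = rigid):
#' sensitivity(t) = P(metric < cutoff | score > t) and
#' specificity(t) = P(metric > cutoff | score < t). For PAE-like
#' scores (low score = rigid): sensitivity(t) =
#' P(metric < cutoff | score < t) and specificity(t) =
#' P(metric > cutoff | score > t). Thresholds whose conditioning set
#' is empty are flagged undefined (NA) rather than reported as 0 —
#' the curves simply end there.
#'
#' @param score numeric score values.
#' @param metric numeric metric values in Angstrom.
#' @param thresholds sorted score thresholds to sweep.
#' @param metricCutoff metric cutoff in Angstrom (e.g. 2 for
#'   sigma_d,20, 2.5 for sigma_d).
#' @param orientation "high_score_means_rigid" (pLDDT) or
#'   "low_score_means_rigid" (PAE).
#' @return data.frame with columns threshold, sensitivity,
#'   specificity, n_sens, n_spec (conditioning-set sizes).
#' @export
sweepSensSpec <- function(score, metric, thresholds, metricCutoff,
                          orientation = c("high_score_means_rigid",
                                          "low_score_means_rigid")) {
  stopifnot(length(score) == length(metric))
  orientation <- match.arg(orientation)
  if (is.unsorted(thresholds)) stop("thresholds must be sorted")
  res <- lapply(thresholds, function(t) {
    if (orientation == "high_score_means_rigid") {
      condS <- score > t; condP <- score < t
    } else {
      condS <- score < t; condP <- score > t
    }
    ns <- sum(condS); np <- sum(condP)
    data.frame(
      threshold = t,
      sensitivity = if (ns) mean(metric[condS] < metricCutoff) else NA_real_,
      specificity = if (np) mean(metric[condP] > metricCutoff) else NA_real_,
      n_sens = ns, n_spec = np)
  })
  do.call(rbind, res)
}

#' Probability of large distance deviation
#'
#' Fraction of (masked) residue pairs whose reference-structure
#' distance deviates from the ensemble-mean distance by more than
#' `relTol` (relative): |ref - mean| / mean > relTol. Used to judge
#' how representative a predicted structure's distances are of the
#' ensemble under different bond-selection criteria.
#'
#' @param refDists reference distances (Angstrom).
#' @param meanDists ensemble-mean distances (Angstrom), > 0.
#' @param mask optional logical selection of pairs (default all).
#' @param relTol relative tolerance (default 0.20).
#' @return fraction in [0, 1] (NA if the mask selects nothing).
#' @export
deviationProbability <- function(refDists, meanDists, mask = NULL,
                                 relTol = 0.20) {
  stopifnot(length(refDists) == length(meanDists), relTol > 0)
  if (is.null(mask)) mask <- rep(TRUE, length(refDists))
  r <- refDists[mask]; m <- meanDists[mask]
  if (!length(r)) return(NA_real_)
  if (any(m <= 0)) stop("mean distances must be positive")
  mean(abs(r - m) / m > relTol)
}
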