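# Fixed-effect meta-analysis across outcome GWAS, sex-difference testing,
# Bonferroni classification, and MR power calculation.

#' Fixed-effect inverse-variance meta-analysis of MR estimates
#'
#' Pools k estimates of the same exposure-outcome effect (typically from
#' two outcome GWAS) with weights \eqn{w_i = 1/se_i^2}. Heterogeneity is
#' summarized by Cochran's Q with k - 1 df and
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100} (0 when Q = 0).
#'
#' @param estimates list of \code{MrEstimate}s (or a data.frame with
#'   columns \code{beta} and \code{se}); at least two.
#' @return a \code{\linkS4class{MetaResult}}.
#' @export
metaFixed <- function(estimates) {
  if (is.data.frame(estimates)) {
    betas <- estimates$beta; ses <- estimates$se
  } else {
    stopifnot(all(vapply(estimates, is, TRUE, "MrEstimate")))
    betas <- vapply(estimates, function(e) e@beta, numeric(1))
    ses <- vapply(estimates, function(e) e@se, numeric(1))
  }
  k <- length(betas)
  if (k < 2) stop("meta-analysis needs at least 2 estimates", call. = FALSE)
  if (any(ses <= 0)) stop("all SEs must be positive", call. = FALSE)
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (betas - beta)^2)
  df <- k - 1
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  new("MetaResult", beta = beta, se = se, pval = zPvalue(beta, se),
      q = q, df = df, pHet = pchisq(q, df, lower.tail = FALSE), i2 = i2,
      nStudies = k)
}

#' Two-sided test for a sex difference between MR estimates
#'
#' \eqn{z = (b_m - b_w)/\sqrt{se_m^2 + se_w^2}}, two-sided normal p.
#' Algebraically identical to the heterogeneity p of a two-group Cochran Q
#' test on the same pair.
#'
#' @param estMen,estWomen \code{MrEstimate}s from the sex-specific
#'   analyses.
#' @return numeric(1) two-sided p-value.
#' @export
sexDifferenceTest <- function(estMen, estWomen) {
  if (missing(estMen) || missing(estWomen) || is.null(estMen) || is.null(estWomen))
    stop("both sex-specific estimates are required", call. = FALSE)
  stopifnot(is(estMen, "MrEstimate"), is(estWomen, "MrEstimate"))
  if (estMen@se <= 0 || estWomen@se <= 0)
    stop("estimates must have positive SEs", call. = FALSE)
  z <- (estMen@beta - estWomen@beta) / sqrt(estMen@se^2 + estWomen@se^2)
  2 * pnorm(-abs(z))
}

#' Classify outcome p-values under a Bonferroni-corrected cut-off
#'
#' The family-wise threshold is \code{alpha/nTests}; p below it is
#' \code{significant}, p in [threshold, alpha) is \code{suggestive}, and
#' anything else is \code{null}.
#'
#' @param pvals named numeric vector of per-outcome p-values.
#' @param nTests number of tests in the family (e.g. 15 for 7 primary + 8
#'   secondary outcomes, giving a threshold of 0.05/15, printed 0.003).
#' @param alpha base significance level (default 0.05).
#' @return named character vector of classes, with the numeric threshold in
#'   the \code{"threshold"} attribute.
#' @examples
#' classifySignificance(c(ihd = 0.04, bc = 0.001), nTests = 15)
#' @export
classifySignificance <- function(pvals, nTests, alpha = 0.05) {
  if (!is.numeric(nTests) || nTests < 1) stop("nTests must be >= 1", call. = FALSE)
  threshold <- alpha / nTests
  cls <- ifelse(pvals < threshold, "significant",
                ifelse(pvals < alpha, "suggestive", "null"))
  cls <- setNames(as.character(cls), names(pvals))
  attr(cls, "threshold") <- threshold
  cls
}

#' Minimum detectable effect of an MR analysis (normal approximation)
#'
#' The effective sample size of a two-sample MR analysis is the outcome
#' sample size scaled by the instrument variance explained, so the standard
#' error of the causal log OR is approximately
#' \eqn{1/\sqrt{n \, r^2 \, cf (1 - cf)}} for a binary outcome with case
#' fraction cf (the \eqn{cf(1-cf)} term is the Bernoulli outcome variance;
#' it is omitted for quantitative outcomes). The minimum detectable effect
#' at two-sided level alpha and target power is
#' \eqn{(z_{1-\alpha/2} + z_{power}) \times se}.
#'
#' @param n outcome sample size (combined across GWAS when meta-analyzed).
#' @param caseFraction case fraction in (0,1) for binary outcomes; NA for
#'   quantitative outcomes.
#' @param r2 instrument variance explained in the exposure, in (0,1).
#' @param alpha two-sided significance level (default 0.05).
#' @param powerTarget target power (default 0.8).
#' @return a \code{\linkS4class{PowerResult}}.
#' @export
minDetectableEffect <- function(n, caseFraction = NA_real_, r2, alpha = 0.05,
                                powerTarget = 0.8) {
  stopifnotScalarPos(n, "n")
  if (!is.numeric(r2) || r2 <= 0 || r2 >= 1)
    stop("'r2' must lie in (0,1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0,1)", call. = FALSE)
  if (powerTarget <= 0 || powerTarget >= 1)
    stop("'powerTarget' must lie in (0,1)", call. = FALSE)
  v <- 1
  if (!is.na(caseFraction)) {
    if (caseFraction <= 0 || caseFraction >= 1)
      stop("'caseFraction' must lie in (0,1)", call. = FALSE)
    v <- caseFraction * (1 - caseFraction)
  }
  se <- 1 / sqrt(n * r2 * v)
  mde <- (qnorm(1 - alpha / 2) + qnorm(powerTarget)) * se
  new("PowerResult", alpha = alpha, powerTarget = powerTarget, r2 = r2,
      n = n, caseFraction = caseFraction, minDetectableBeta = mde,
      minDetectableOr = exp(mde))
}
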