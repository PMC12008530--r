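# Empirical-Bayes variance moderation and Storey q-values.
#
# The hierarchical model treats each feature's residual variance s2 (d df)
# as scaled chi-square around a feature-specific variance, with a scaled
# inverse-chi-square prior (d0, s02) shared across features. Hyperparameters
# are estimated by method of moments on log s2: for s2 ~ s02 * chisq(d)/d *
# (prior), e = log(s2) - digamma(d/2) + log(d/2) has mean log(s02) +
# digamma(d0/2) - log(d0/2) and excess variance trigamma(d0/2) beyond the
# sampling term trigamma(d/2).

# Newton inversion of trigamma on (0, Inf)
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

# Moment estimation of (d0, s02) from residual variances s2 with d df each.
# Returns d0 = Inf (flagged) when the observed spread of log s2 does not
# exceed its sampling variance, i.e. the data carry no evidence of
# variance heterogeneity.
.fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) {
    return(list(d0 = NA_real_, s0_2 = NA_real_, estimable = FALSE))
  }
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (!is.finite(evar) || evar <= 0) {
    # d0 -> Inf corner: prior mean still identified
    return(list(d0 = Inf, s0_2 = exp(mean(e)), estimable = FALSE))
  }
  d0 <- 2 * .trigamma_inverse(evar)
  s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2, estimable = is.finite(d0))
}

#' Shrink residual variances toward a pooled prior
#'
#' Squeezes per-feature residual variances toward an empirically estimated
#' scaled inverse-chi-square prior:
#' `s2_post = (d0 * s0^2 + d * s2) / (d0 + d)`, with `(d0, s0^2)` fitted by
#' method of moments on `log(s2)`.
#'
#' @param s2 vector of residual variances.
#' @param d residual degrees of freedom (scalar, shared).
#' @param prior_df optional fixed prior df `d0` overriding the moment
#'   estimate; `0` leaves the variances untouched (ordinary t), `Inf`
#'   replaces them all by the prior variance.
#' @return list with `s2_post`, `d0`, `s0_2` and `estimable` (FALSE when
#'   the moment estimate of `d0` was non-finite).
#' @export
squeeze_variances <- function(s2, d, prior_df = NULL) {
  stopifnot(d > 0)
  fit <- .fit_variance_prior(s2, d)
  if (!is.null(prior_df)) {
    fit$d0 <- prior_df
    fit$estimable <- TRUE
    if (is.infinite(prior_df)) {
      return(list(s2_post = rep(fit$s0_2, length(s2)), d0 = Inf,
                  s0_2 = fit$s0_2, estimable = TRUE))
    }
    if (prior_df == 0) {
      return(list(s2_post = s2, d0 = 0, s0_2 = fit$s0_2, estimable = TRUE))
    }
  }
  if (!fit$estimable) {
    return(list(s2_post = s2, d0 = NA_real_, s0_2 = fit$s0_2,
                estimable = FALSE))
  }
  list(s2_post = (fit$d0 * fit$s0_2 + d * s2) / (fit$d0 + d),
       d0 = fit$d0, s0_2 = fit$s0_2, estimable = TRUE)
}

#' Storey q-values
#'
#' Computes q-values from p-values with the proportion of true nulls
#' estimated at a single lambda: `pi0 = min(1, mean(p > lambda) /
#' (1 - lambda))`. q-values are `pi0 * m * p / rank(p)` made monotone by a
#' cumulative minimum from the largest p downwards and clipped to \[0, 1\].
#' Forcing `pi0 = 1` reproduces Benjamini-Hochberg adjusted p-values
#' exactly.
#'
#' @param pvals vector of p-values in \[0, 1\].
#' @param lambda tuning parameter for the pi0 estimate (default 0.5).
#' @param pi0 optional fixed pi0 overriding the estimate.
#' @return vector of q-values, same order as `pvals`; the pi0 used is
#'   attached as attribute `pi0`.
#' @export
estimate_qvalues <- function(pvals, lambda = 0.5, pi0 = NULL) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1] and be non-missing")
  }
  m <- length(pvals)
  if (is.null(pi0)) {
    pi0 <- min(1, mean(pvals > lambda) / (1 - lambda))
    pi0 <- max(pi0, 1 / m)   # guard against a degenerate zero estimate
  }
  o <- order(pvals, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(pi0 * m * pvals[o] / (m:1)))[ro]
  attr(q, "pi0") <- pi0
  q
}
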