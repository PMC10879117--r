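# Shared statistical utilities: correlation with confidence interval and the
# dependent-correlation Z test used for paired model comparison.

#' Pearson correlation with a Fisher-z confidence interval
#'
#' @param x,y Numeric vectors (n >= 3 after pairwise NA removal).
#' @param conf_level Confidence level (default 0.95).
#' @return List: `r`, `conf_low`, `conf_high`, `n`.
#' @export
pearson_ci <- function(x, y, conf_level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  r <- stats::cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(r = r, conf_low = tanh(z - q * se), conf_high = tanh(z + q * se), n = n)
}

#' Steiger's Z test for two dependent correlations sharing one variable
#'
#' Tests whether cor(observed, model1 predictions) differs from
#' cor(observed, model2 predictions) when both correlations are computed on
#' the same sample, using the Fisher-z based statistic for dependent
#' correlations with one variable in common (Steiger's method in the
#' Meng-Rosenthal-Rubin formulation).
#'
#' @param r_jk Correlation of the shared variable with the first variable.
#' @param r_jh Correlation of the shared variable with the second variable.
#' @param r_kh Correlation between the two non-shared variables.
#' @param n Sample size.
#' @return List: `z` statistic and two-sided `p_value`.
#' @export
steiger_z <- function(r_jk, r_jh, r_kh, n) {
  if (n < 4) stop("need n >= 4")
  rm2 <- (r_jk^2 + r_jh^2) / 2
  f <- (1 - r_kh) / (2 * (1 - rm2))
  f <- min(f, 1)
  h <- (1 - f * rm2) / (1 - rm2)
  z <- (atanh(r_jk) - atanh(r_jh)) * sqrt((n - 3) / (2 * (1 - r_kh) * h))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Steiger's Z from raw vectors
#'
#' Convenience wrapper computing the three correlations from an observed
#' vector and two prediction vectors.
#'
#' @param observed Shared observed variable.
#' @param pred1,pred2 Competing predictions, same length.
#' @return As [steiger_z()], plus the three correlations.
#' @export
steiger_z_vectors <- function(observed, pred1, pred2) {
  r_jk <- stats::cor(observed, pred1)
  r_jh <- stats::cor(observed, pred2)
  r_kh <- stats::cor(pred1, pred2)
  c(steiger_z(r_jk, r_jh, r_kh, length(observed)),
    list(r1 = r_jk, r2 = r_jh, r12 = r_kh))
}

#' Geometric mean
#'
#' exp of the mean natural log; all values must be strictly positive.
#'
#' @param x Positive numeric vector.
#' @return The geometric mean.
#' @export
geometric_mean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}
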