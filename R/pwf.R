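#' Fit the probability weighting function (PWF)
#'
#' The PWF gives each gene's probability of being called DE as a monotone
#' function of a bias covariate — transcript length, or the gene's total
#' read count across both conditions. It is estimated by least squares:
#' a cubic regression spline in log10(covariate) is fitted to the binary
#' DE indicators with a monotonicity constraint on the spline coefficients
#' (constrained penalised least squares via [mgcv::pcls()]; knots at
#' equally spaced quantiles of the distinct log-covariate values).
#'
#' Monotonicity is justified because the power of any statistical DE test
#' increases with read count; the direction is not assumed but chosen by
#' fitting both the increasing and the decreasing constraint and keeping
#' the lower residual sum of squares — non-statistical DE criteria such as
#' fold-change cutoffs produce decreasing trends.
#'
#' Fitted values are clamped to `[floor_eps, 1]`: a weight of exactly zero
#' would make a gene unsampleable under the resampling null.
#'
#' @param covariate strictly positive numeric vector, one value per gene.
#' @param de_flags logical or 0/1 vector of DE calls, same length.
#' @param n_knots number of spline knots (basis dimension); default 6.
#' @param covariate_kind label recorded on the fit: `"length"` or
#'   `"total_count"` (any other positive covariate is accepted).
#' @param floor_eps lower clamp for fitted probabilities.
#' @return a `pwf` object; evaluate it with [evaluate_pwf()] or `predict()`.
#' @export
fit_pwf <- function(covariate, de_flags, n_knots = 6,
                    covariate_kind = "length", floor_eps = 1e-8) {
  de_flags <- as.logical(de_flags)
  if (length(covariate) != length(de_flags)) {
    stop_validation("covariate and de_flags must have equal length")
  }
  if (any(!is.finite(covariate)) || any(covariate <= 0)) {
    stop_validation("covariate must be strictly positive")
  }
  if (anyNA(de_flags)) stop_validation("de_flags must not contain NA")
  if (all(de_flags) || !any(de_flags)) {
    stop_validation(paste("all DE flags are identical; no trend can be fitted.",
                          "Use a constant PWF equal to the DE fraction instead."))
  }
  x <- log10(covariate)
  y <- as.numeric(de_flags)
  n_distinct <- length(unique(x))
  if (n_distinct < n_knots) {
    n_knots <- max(3L, n_distinct)
    warning(sprintf("fewer distinct covariate values than knots; reduced to %d knots",
                    n_knots))
  }

  dat <- data.frame(x = x, y = y)
  sm <- mgcv::smoothCon(mgcv::s(x, k = n_knots, bs = "cr"), dat,
                        knots = NULL, absorb.cons = FALSE)[[1]]
  sp <- mgcv::gam(y ~ s(x, k = n_knots, bs = "cr"), data = dat)$sp

  fit_dir <- function(up) {
    con <- mgcv::mono.con(sm$xp, up = up)
    G <- list(X = sm$X, C = matrix(0, 0, 0), sp = sp,
              p = if (up) sm$xp else rev(sm$xp),
              y = y, w = rep(1, length(y)),
              Ain = con$A, bin = con$b, S = sm$S, off = 0)
    coef <- mgcv::pcls(G)
    rss <- sum((y - drop(sm$X %*% coef))^2)
    list(coef = coef, rss = rss)
  }
  inc <- fit_dir(TRUE)
  dec <- fit_dir(FALSE)
  up <- inc$rss <= dec$rss
  fit <- if (up) inc else dec

  obj <- structure(list(
    smooth = sm,
    coefficients = fit$coef,
    direction = if (up) "increasing" else "decreasing",
    covariate_kind = covariate_kind,
    n_knots = n_knots,
    floor = floor_eps,
    range = range(x),
    n_de = sum(de_flags),
    n_genes = length(de_flags)
  ), class = "pwf")
  obj
}

#' Evaluate a fitted PWF
#'
#' Covariates outside the fitted range are evaluated at the nearest boundary
#' (constant extrapolation); outputs are clamped to `[floor, 1]`.
#'
#' @param pwf a `pwf` object from [fit_pwf()].
#' @param covariate strictly positive numeric vector.
#' @return probability vector, same length as `covariate`.
#' @export
evaluate_pwf <- function(pwf, covariate) {
  if (!inherits(pwf, "pwf")) stop_validation("pwf must be a fitted pwf object")
  if (any(!is.finite(covariate)) || any(covariate <= 0)) {
    stop_validation("covariate must be strictly positive")
  }
  x <- pmin(pmax(log10(covariate), pwf$range[1]), pwf$range[2])
  X <- mgcv::PredictMat(pwf$smooth, data.frame(x = x))
  p <- drop(X %*% pwf$coefficients)
  pmin(pmax(p, pwf$floor), 1)
}

#' @export
predict.pwf <- function(object, covariate, ...) evaluate_pwf(object, covariate)

#' @export
print.pwf <- function(x, ...) {
  cat(sprintf("pwf: monotone %s cubic spline in log10(%s), %d knots\n",
              x$direction, x$covariate_kind, x$n_knots))
  cat(sprintf("  fitted on %d genes (%d DE), log10-covariate range [%.3g, %.3g]\n",
              x$n_genes, x$n_de, x$range[1], x$range[2]))
  invisible(x)
}

#' Binned DE proportions along a covariate
#'
#' The standard diagnostic for selection bias: genes are sorted by the
#' covariate and partitioned into consecutive bins of `bin_size` genes (the
#' last bin may be smaller); each bin contributes its median covariate and
#' the fraction of its genes flagged DE. Plotted against a fitted PWF it
#' shows whether the spline tracks the empirical trend.
#'
#' @param covariate numeric vector.
#' @param de_flags logical or 0/1 vector, same length.
#' @param bin_size genes per bin (default 300).
#' @return data.frame with columns `median_covariate`, `de_proportion`,
#'   `n_genes`.
#' @export
bin_de_proportions <- function(covariate, de_flags, bin_size = 300) {
  if (length(covariate) != length(de_flags)) {
    stop_validation("covariate and de_flags must have equal length")
  }
  if (!is.finite(bin_size) || bin_size < 2) {
    stop_validation("bin_size must be at least 2")
  }
  bin_size <- as.integer(bin_size)
  ord <- order(covariate)
  cov_s <- covariate[ord]
  de_s <- as.logical(de_flags)[ord]
  n <- length(cov_s)
  bin <- rep(seq_len(ceiling(n / bin_size)), each = bin_size)[seq_len(n)]
  data.frame(
    median_covariate = as.numeric(tapply(cov_s, bin, median)),
    de_proportion = as.numeric(tapply(de_s, bin, mean)),
    n_genes = as.integer(tapply(de_s, bin, length)),
    row.names = NULL
  )
}
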