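#' Fit the normal-exponential convolution model by maximum likelihood
#'
#' Models observed intensities as X = B + S with background noise
#' B ~ N(mu, sigma^2) and true signal S ~ Exp(mean alpha). The closed-form
#' convolution density is maximized in log space (Nelder-Mead over
#' (mu, log sigma, log alpha)) from a method-of-moments start.
#'
#' @param intensities Non-negative numeric vector; at least 50 finite values
#'   are recommended (a warning is emitted below that).
#' @param max_iter Maximum Nelder-Mead iterations.
#' @return A list of class `"NormexpParams"` with `mu`, `sigma`, `alpha` and
#'   the achieved `loglik`.
#' @export
normexp_fit <- function(intensities, max_iter = 1000) {
  x <- intensities[is.finite(intensities)]
  if (length(x) < 4) stop("need at least 4 finite intensities")
  if (length(x) < 50)
    warning("fewer than 50 finite intensities; estimates may be unstable")
  if (stats::sd(x) == 0)
    stop("constant intensities: sigma and alpha are not identifiable")
  scale_x <- stats::sd(x)   # standardize so the optimizer is scale-invariant
  xs <- x / scale_x
  m1 <- mean(xs)
  v <- stats::var(xs)
  m3 <- mean((xs - m1)^3)
  alpha0 <- max((max(m3, 1e-8) / 2)^(1 / 3), 1e-3)
  mu0 <- m1 - alpha0
  sigma0 <- sqrt(max(v - alpha0^2, 0.01 * v))
  neg_ll <- function(theta) {
    ll <- normexp_loglik(xs, theta[1], exp(theta[2]), exp(theta[3]))
    if (!is.finite(ll)) 1e300 else -ll
  }
  opt <- stats::optim(c(mu0, log(sigma0), log(alpha0)), neg_ll,
                      method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("normexp maximum likelihood did not converge; last iterate: mu=",
         format(opt$par[1] * scale_x), " sigma=",
         format(exp(opt$par[2]) * scale_x), " alpha=",
         format(exp(opt$par[3]) * scale_x))
  structure(list(mu = opt$par[1] * scale_x, sigma = exp(opt$par[2]) * scale_x,
                 alpha = exp(opt$par[3]) * scale_x,
                 loglik = -opt$value - length(x) * log(scale_x)),
            class = "NormexpParams")
}

# Log-likelihood of the normal + exponential convolution, evaluated in log
# space: log f(x) = -log(a) + (mu - x)/a + s^2/(2 a^2) + log Phi((x - mu - s^2/a)/s)
normexp_loglik <- function(x, mu, sigma, alpha) {
  if (sigma <= 0 || alpha <= 0) return(-Inf)
  z <- (x - mu - sigma^2 / alpha) / sigma
  sum(-log(alpha) + (mu - x) / alpha + sigma^2 / (2 * alpha^2) +
        stats::pnorm(z, log.p = TRUE))
}

#' Background-correct intensities under the normexp model
#'
#' Returns the posterior expected signal E\[S | X = x\], which is strictly
#' positive and monotone non-decreasing in x, so the corrected intensities can
#' be log-transformed without producing missing values.
#'
#' @param x Numeric vector of observed intensities.
#' @param params A `"NormexpParams"` object from [normexp_fit()].
#' @return Positive numeric vector of corrected intensities.
#' @export
normexp_correct <- function(x, params) {
  if (!inherits(params, "NormexpParams")) stop("params must be NormexpParams")
  if (params$sigma <= 0 || params$alpha <= 0) stop("invalid normexp params")
  mu_sf <- x - params$mu - params$sigma^2 / params$alpha
  z <- mu_sf / params$sigma
  # Mills ratio phi/Phi computed in log space for deep-left-tail stability
  mills <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
  out <- mu_sf + params$sigma * mills
  pmax(out, .Machine$double.xmin)
}

#' Quantile normalization
#'
#' Every column is forced to the identical empirical distribution: the value
#' at rank r is replaced by the mean across columns of the rank-r order
#' statistics. Tied values receive the mean of their tied target values, which
#' makes the transform deterministic and idempotent.
#'
#' @param m ExpressionMatrix without missing values.
#' @return ExpressionMatrix with quantile-normalized columns.
#' @export
quantile_normalize <- function(m) {
  x <- m$values
  if (anyNA(x))
    stop("quantile normalization requires complete data; use cyclic loess for matrices with missing values")
  if (ncol(x) < 2) return(m)
  target <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    xs <- x[o, j]
    assigned <- stats::ave(target, match(xs, unique(xs)))
    out[o, j] <- assigned
  }
  m$values <- out
  m
}

#' Cyclic loess normalization
#'
#' For each pair of columns (cyclically) a degree-1 loess curve of
#' M = x_i - x_j on A = (x_i + x_j)/2 is fitted and half of it subtracted from
#' each column. Observation weights, when present, act as loess weights:
#' weight-0-like probes do not influence the curve but are still adjusted.
#'
#' @param m ExpressionMatrix on the log scale.
#' @param span Loess span.
#' @param iterations Number of cycles over all column pairs.
#' @return Normalized ExpressionMatrix.
#' @export
cyclic_loess_normalize <- function(m, span = 0.7, iterations = 3) {
  x <- m$values
  n <- ncol(x)
  if (n < 2) return(m)
  w <- m$obs_weights
  for (it in seq_len(iterations)) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        a_vals <- (x[, i] + x[, j]) / 2
        m_vals <- x[, i] - x[, j]
        pw <- if (!is.null(w)) w[, i] * w[, j] else NULL
        ok <- is.finite(a_vals) & is.finite(m_vals)
        if (!is.null(pw)) okw <- ok & pw > 0 else okw <- ok
        if (stats::sd(m_vals[okw]) < 1e-10 * (1 + abs(mean(m_vals[okw])))) {
          offset <- mean(m_vals[okw])
          x[ok, i] <- x[ok, i] - offset / 2
          x[ok, j] <- x[ok, j] + offset / 2
          next
        }
        fit <- stats::loess(y ~ a,
                            data = data.frame(a = a_vals[okw],
                                              y = m_vals[okw]),
                            weights = if (!is.null(pw)) pw[okw],
                            span = span, degree = 1, family = "symmetric")
        pred <- stats::predict(fit, newdata = data.frame(a = a_vals[ok]))
        # flat extrapolation outside the fitted A-range
        rng <- range(a_vals[okw])
        pred[is.na(pred) & a_vals[ok] < rng[1]] <-
          stats::predict(fit, newdata = data.frame(a = rng[1]))
        pred[is.na(pred) & a_vals[ok] > rng[2]] <-
          stats::predict(fit, newdata = data.frame(a = rng[2]))
        x[ok, i] <- x[ok, i] - pred / 2
        x[ok, j] <- x[ok, j] + pred / 2
      }
    }
  }
  m$values <- x
  m
}

#' Log2-transform raw intensities with a positive offset
#'
#' Computes log2(x + offset). The offset keeps low intensities away from zero
#' so the transform never produces -Inf or missing values; moderate offsets
#' trade a small bias for a large variance reduction at the low end.
#'
#' @param m ExpressionMatrix of raw (non-negative) intensities; a matrix that
#'   is already on the log scale is returned unchanged.
#' @param offset Offset added before the log (default 16).
#' @return ExpressionMatrix with `kind = "log_intensity"`.
#' @export
log_with_offset <- function(m, offset = 16) {
  if (m$kind == "log_intensity") return(m)
  x <- m$values
  if (any(x < 0, na.rm = TRUE))
    stop("negative intensities cannot be log-transformed; background correction guarantees positivity")
  if (offset <= 0 && any(x == 0, na.rm = TRUE))
    stop("offset must be positive when zero intensities are present")
  m$values <- log2(x + offset)
  m$kind <- "log_intensity"
  m
}
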