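#' Log2 counts per million
#'
#' Computes `log2((count + prior_count) / (lib_size + 1) * 1e6)`. The small
#' prior count keeps zero counts finite; the +1 in the denominator guarantees
#' the argument stays below 1e6 * (count + prior)/lib.
#'
#' @param counts ExpressionMatrix of kind `"counts"` (or a bare matrix).
#' @param lib_sizes Library sizes; default column sums (optionally times
#'   normalization factors).
#' @param prior_count Prior count added to every observation.
#' @param norm_factors Optional scale normalization factors (e.g. from
#'   [tmm_factors()]) multiplied into the default library sizes.
#' @return ExpressionMatrix of kind `"logcpm"`.
#' @export
logcpm <- function(counts, lib_sizes = NULL, prior_count = 0.5,
                   norm_factors = NULL) {
  if (!inherits(counts, "ExpressionMatrix"))
    counts <- expression_matrix(counts, kind = "counts")
  x <- counts$values
  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(x)
    if (!is.null(norm_factors)) lib_sizes <- lib_sizes * norm_factors
  }
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  y <- t(log2(t(x + prior_count) / (lib_sizes + 1) * 1e6))
  out <- expression_matrix(y, gene_ids = counts$gene_ids,
                           sample_ids = counts$sample_ids, kind = "logcpm")
  attr(out, "lib_sizes") <- lib_sizes
  out
}

#' Trimmed mean of M-values scale normalization factors
#'
#' For each sample, gene-wise log2 ratios (M) of library-size-normalized
#' abundances against a reference column are trimmed (by M and by average
#' abundance A) and combined by a precision-weighted mean, with weights from
#' the asymptotic (delta-method) variance of each M-value. The reference is
#' the column whose 75th percentile of relative abundance is closest to the
#' mean such percentile. Factors are rescaled to geometric mean 1.
#'
#' @param counts ExpressionMatrix of counts (or matrix).
#' @param logratio_trim Two-sided trim fraction on M-values.
#' @param sum_trim Two-sided trim fraction on A-values.
#' @return Positive numeric vector of factors, one per sample.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  if (!inherits(counts, "ExpressionMatrix"))
    counts <- expression_matrix(counts, kind = "counts")
  x <- counts$values
  if (ncol(x) < 2) stop("TMM needs at least two samples")
  lib <- colSums(x)
  if (any(lib == 0)) stop("a sample with all-zero counts cannot be normalized")
  f75 <- vapply(seq_len(ncol(x)), function(j)
    stats::quantile(x[, j] / lib[j], 0.75, names = FALSE), 0)
  ref <- which.min(abs(f75 - mean(f75)))
  factors <- vapply(seq_len(ncol(x)), function(j) {
    if (j == ref) return(1)
    2^tmm_pair(x[, j], x[, ref], lib[j], lib[ref], logratio_trim, sum_trim)
  }, 0)
  factors / exp(mean(log(factors)))
}

tmm_pair <- function(obs, ref, nobs, nref, logratio_trim, sum_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  m_val <- log2((obs / nobs) / (ref / nref))
  a_val <- 0.5 * log2((obs / nobs) * (ref / nref))
  v <- (nobs - obs) / (nobs * obs) + (nref - ref) / (nref * ref)
  fin <- is.finite(m_val) & is.finite(a_val)
  m_val <- m_val[fin]; a_val <- a_val[fin]; v <- v[fin]
  if (!length(m_val) || max(abs(m_val)) < 1e-6) return(0)
  n <- length(m_val)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(m_val); ra <- rank(a_val)
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep2)) return(0)
  f <- sum(m_val[keep2] / v[keep2]) / sum(1 / v[keep2])
  if (!is.finite(f) || abs(f) < 1e-6) 0 else f
}

#' Transform counts to logCPM with observation precision weights
#'
#' The mean-variance relationship of log-counts is estimated empirically:
#' gene-wise linear models on the logCPM values give residual standard
#' deviations, a lowess curve of sqrt(sd) on average log2 count captures the
#' trend, and each observation's fitted log2 count is mapped through the
#' curve (piecewise-linear interpolation, flat beyond the observed range) to
#' a predicted sqrt-sd whose inverse fourth power is the precision weight.
#'
#' @param counts ExpressionMatrix of counts.
#' @param design Design matrix or [design_spec()].
#' @param lib_sizes Optional library sizes (default: column sums times
#'   `norm_factors`).
#' @param span Lowess span for the trend.
#' @param norm_factors Optional scale normalization factors.
#' @return A list of class `"VoomResult"`: `elist` (logCPM ExpressionMatrix
#'   carrying `obs_weights`), `trend_x`, `trend_y`, `trend` (the lowess
#'   curve), and `lib_sizes`.
#' @export
voom <- function(counts, design, lib_sizes = NULL, span = 0.5,
                 norm_factors = NULL) {
  if (!inherits(counts, "ExpressionMatrix"))
    counts <- expression_matrix(counts, kind = "counts")
  design <- as_design_spec(design)
  x <- counts$values
  if (nrow(x) < 10) stop("too few genes to estimate the mean-variance trend")
  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(x)
    if (!is.null(norm_factors)) lib_sizes <- lib_sizes * norm_factors
  }
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  n <- ncol(x); p <- ncol(design$design)
  if (n - p < 2) stop("need at least 2 residual degrees of freedom overall")
  if (any(rowSums(x) == 0))
    warning("all-zero count rows present; filter genes before voom")
  y <- t(log2(t(x + 0.5) / (lib_sizes + 1) * 1e6))
  qr_x <- qr(design$design)
  coefs <- t(qr.coef(qr_x, t(y)))
  fitted <- coefs %*% t(design$design)
  res <- y - fitted
  sigma <- sqrt(colSums(t(res)^2) / (n - p))
  amean <- rowMeans(y)
  sx <- amean + mean(log2(lib_sizes + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  ok <- is.finite(sx) & is.finite(sy) & sigma > 0
  lo <- stats::lowess(sx[ok], sy[ok], f = span)
  trend_fun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  fitted_cpm <- 2^fitted
  fitted_count <- 1e-6 * t(t(fitted_cpm) * (lib_sizes + 1))
  fitted_logcount <- log2(fitted_count)
  w <- 1 / trend_fun(fitted_logcount)^4
  w <- matrix(w, nrow = nrow(y))
  if (!all(is.finite(w)) || any(w <= 0))
    stop("non-finite voom weights; check for degenerate genes")
  elist <- expression_matrix(y, gene_ids = counts$gene_ids,
                             sample_ids = counts$sample_ids, kind = "logcpm",
                             obs_weights = w)
  structure(list(elist = elist, trend_x = sx, trend_y = sy, trend = lo,
                 lib_sizes = lib_sizes), class = "VoomResult")
}

#' @export
print.VoomResult <- function(x, ...) {
  cat(sprintf("VoomResult: %d genes x %d samples, weights in [%.3g, %.3g]\n",
              nrow(x$elist$values), ncol(x$elist$values),
              min(x$elist$obs_weights), max(x$elist$obs_weights)))
  invisible(x)
}

#' voom with sample quality weights
#'
#' Iterates voom and sample-weight estimation: precision weights from the
#' mean-variance trend are combined with relative sample variance weights
#' from [array_weights()], over two rounds. The final observation weights are
#' the elementwise product of the voom weights and the sample weights.
#'
#' @inheritParams voom
#' @return A `"VoomResult"` with an extra `sample_weights` component;
#'   `elist$obs_weights` holds the combined weights and
#'   `elist$sample_weights` the sample layer.
#' @export
voom_with_quality_weights <- function(counts, design, lib_sizes = NULL,
                                      span = 0.5, norm_factors = NULL) {
  v <- voom(counts, design, lib_sizes = lib_sizes, span = span,
            norm_factors = norm_factors)
  sw <- array_weights(v$elist, design)
  m2 <- v$elist
  m2$sample_weights <- sw        # round 2: refine on top of round-1 weights
  sw <- sw * array_weights(m2, design)
  sw <- sw / exp(mean(log(sw)))
  v$sample_weights <- sw
  voom_w <- v$elist$obs_weights
  v$elist$obs_weights <- sweep(voom_w, 2, sw, `*`)
  v$elist$sample_weights <- sw
  v$voom_weights <- voom_w
  v
}

#' Filter genes by CPM abundance
#'
#' Keeps genes with counts-per-million above `cpm_cutoff` in at least
#' `min_samples` samples (default: the smallest design group size when a
#' treatment-means design is supplied, else 1).
#'
#' @param counts ExpressionMatrix of counts.
#' @param cpm_cutoff CPM threshold.
#' @param min_samples Minimum number of samples exceeding the threshold.
#' @return Filtered ExpressionMatrix.
#' @export
filter_by_cpm <- function(counts, cpm_cutoff = 1, min_samples = 1) {
  lib <- colSums(counts$values)
  cpm <- t(t(counts$values) / lib * 1e6)
  keep <- rowSums(cpm > cpm_cutoff) >= min_samples
  counts[keep, ]
}
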