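#' Fit a scaled F prior to gene-wise sample variances
#'
#' Under the hierarchical model s2_g | sigma2_g ~ sigma2_g chi2_df/df and
#' 1/sigma2_g ~ chi2_d0/(d0 s0^2), the log sample variances satisfy
#' E\[log s2\] = log s0^2 + psi(d0/2) - log(d0/2) - (psi(df/2) - log(df/2))
#' and Var\[log s2\] = psi'(df/2) + psi'(d0/2). Both hyperparameters are
#' estimated by moments: the prior df d0 solves the trigamma equation by
#' Newton inversion. With a covariate, log s0^2 follows a robustified lowess
#' of log s2 on the covariate (a trended prior) and the moments use the
#' residuals from that curve.
#'
#' @param s2 Gene-wise sample variances (positive; genes with `df == 0` or
#'   non-finite variances are excluded and do not affect the estimates).
#' @param df Residual degrees of freedom per gene (scalar recycled).
#' @param covariate Optional trend covariate (e.g. average log-expression).
#' @param span Lowess span for the trend.
#' @return A list of class `"FDistPrior"`: `df_prior` (d0, possibly `Inf`),
#'   `s2_prior` (scalar, or per-gene vector for a trended prior, aligned with
#'   the full input ordering), and `trend_curve` (lowess points or `NULL`).
#' @export
fit_fdist <- function(s2, df, covariate = NULL, span = 0.5) {
  n_all <- length(s2)
  df <- rep_len(df, n_all)
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2) stop("need at least two genes with positive variance and df")
  z <- log(s2[ok])
  dfo <- df[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  trend_curve <- NULL
  if (!is.null(covariate)) {
    if (length(covariate) != n_all)
      stop("covariate must have one value per gene")
    cov_ok <- covariate[ok]
    lo <- stats::lowess(cov_ok, e, f = span, iter = 3)
    trend_fun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
    emean_ok <- trend_fun(cov_ok)
    resid <- e - emean_ok
    evar <- stats::var(resid)
    emean <- trend_fun(covariate)  # full-length, flat outside the range
    trend_curve <- lo
  } else {
    emean <- mean(e)
    evar <- stats::var(e)
  }
  evar <- evar - mean(trigamma(dfo / 2))
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s2_prior <- exp(emean)
  }
  structure(list(df_prior = df_prior, s2_prior = s2_prior,
                 trend_curve = trend_curve, robust_df = NULL),
            class = "FDistPrior")
}

# Newton inversion of the trigamma function: solve trigamma(x) = y, y > 0.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Robust (winsorized) variant of [fit_fdist()]
#'
#' Global hyperparameters are estimated from 5%/95%-winsorized log-variances,
#' so hypervariable outlier genes do not inflate the prior. Genes whose
#' adjusted log-variance exceeds the upper winsorization limit receive an
#' individual prior df that decays smoothly to zero with outlyingness, so
#' their variances are not squeezed down and they cannot ride the shrinkage
#' into false significance.
#'
#' @inheritParams fit_fdist
#' @param winsor_tail Lower/upper winsorization probabilities.
#' @return An `"FDistPrior"` with a per-gene `robust_df` vector (aligned with
#'   the input; `NA` for excluded genes).
#' @export
fit_fdist_robust <- function(s2, df, covariate = NULL, span = 0.5,
                             winsor_tail = c(0.05, 0.95)) {
  n_all <- length(s2)
  df <- rep_len(df, n_all)
  ok <- is.finite(s2) & s2 > 0 & df > 0
  z <- log(s2[ok])
  dfo <- df[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  if (!is.null(covariate)) {
    lo <- stats::lowess(covariate[ok], e, f = span, iter = 3)
    trend_fun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
    e_centered <- e - trend_fun(covariate[ok])
  } else {
    e_centered <- e
    lo <- NULL
  }
  q <- stats::quantile(e_centered, winsor_tail, names = FALSE)
  e_win <- pmin(pmax(e_centered, q[1]), q[2])
  ewvar <- stats::var(e_win) - mean(trigamma(dfo / 2))
  if (is.finite(ewvar) && ewvar > 0) d0 <- 2 * trigamma_inverse(ewvar)
  else d0 <- Inf
  center <- mean(e_win)
  adj <- if (is.finite(d0)) digamma(d0 / 2) - log(d0 / 2) else 0
  if (is.null(covariate)) s2_prior <- exp(center + adj)
  else s2_prior <- exp(trend_fun(covariate) + center + adj)
  total_sd <- sqrt(max(stats::var(e_centered), 1e-12))
  excess <- pmax(e_centered - q[2], 0)
  d0_gene <- rep(NA_real_, n_all)
  shrinkf <- 2 * stats::pnorm(-excess / total_sd)  # 1 inside limits, -> 0 out
  d0_gene[ok] <- if (is.finite(d0)) d0 * shrinkf else ifelse(excess > 0,
                                                             1e6 * shrinkf, Inf)
  structure(list(df_prior = d0, s2_prior = s2_prior, trend_curve = lo,
                 robust_df = d0_gene), class = "FDistPrior")
}

#' Squeeze gene-wise variances towards the prior
#'
#' Posterior variance `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)`; with
#' `d0 = Inf` every gene gets `s0^2`, with `d0 = 0` variances are unchanged.
#' Genes with `df = 0` receive the prior variance so they remain testable.
#'
#' @param s2 Sample variances.
#' @param df Residual df per gene.
#' @param prior `"FDistPrior"` from [fit_fdist()] (or a robust variant).
#' @return Vector of posterior variances.
#' @export
squeeze_var <- function(s2, df, prior) {
  df <- rep_len(df, length(s2))
  d0 <- if (!is.null(prior$robust_df))
    ifelse(is.na(prior$robust_df), prior$df_prior, prior$robust_df)
  else rep_len(prior$df_prior, length(s2))
  s0 <- rep_len(prior$s2_prior, length(s2))
  s2_use <- ifelse(is.finite(s2), s2, 0)
  df_use <- ifelse(is.finite(s2), df, 0)
  out <- ifelse(is.infinite(d0), s0,
                (d0 * s0 + df_use * s2_use) / (d0 + df_use))
  ifelse(d0 + df_use == 0, s2, out)
}

#' Empirical Bayes moderated t, F and B statistics
#'
#' Squeezes the gene-wise residual variances towards the fitted prior and
#' forms moderated t-statistics `t = beta / (u * s_post)` on `d0 + df`
#' degrees of freedom, a moderated F over all columns (contrasts
#' orthogonalized through the coefficient correlation), and B (log-odds of
#' differential expression) under a two-component normal mixture with DE
#' proportion `proportion` and a coefficient-variance prior matched to the
#' 90th percentile of |t|.
#'
#' @param fit LinearFit from [lm_fit()] (optionally after [contrasts_fit()]).
#' @param trend Use an abundance-dependent (trended) prior variance.
#' @param robust Use the winsorized robust prior with per-gene prior df.
#' @param proportion Assumed proportion of differentially expressed genes
#'   (used only by the B statistic).
#' @param prior Optional pre-fitted `"FDistPrior"` overriding the internal
#'   fit; `list(df_prior = 0)`-style priors give classical (unmoderated)
#'   statistics.
#' @return The fit, extended with `df_prior`, `s2_prior`, `s2_post`,
#'   `df_total`, `t`, `p_value`, `lods`, `F`, `F_p`.
#' @export
moderated_stats <- function(fit, trend = FALSE, robust = FALSE,
                            proportion = 0.01, prior = NULL) {
  s2 <- fit$sigma^2
  df <- fit$df_residual
  if (all(df == 0)) stop("all genes have zero residual df; cannot moderate")
  if (is.null(prior)) {
    covariate <- if (trend) fit$amean else NULL
    prior <- if (robust) fit_fdist_robust(s2, df, covariate = covariate)
             else fit_fdist(s2, df, covariate = covariate)
  }
  d0 <- if (!is.null(prior$robust_df))
    ifelse(is.na(prior$robust_df), prior$df_prior, prior$robust_df)
  else rep_len(prior$df_prior, length(s2))
  s2_post <- squeeze_var(s2, df, prior)
  df_total <- pmin(df + d0, sum(df, na.rm = TRUE))
  se <- fit$stdev_unscaled * sqrt(s2_post)
  tstat <- fit$coefficients / se
  p_value <- 2 * stats::pt(-abs(tstat), df = df_total)
  n_col <- ncol(tstat)
  corr <- stats::cov2cor(fit$coef_cov)
  if (n_col == 1) {
    f_rank <- 1L
    f_stat <- as.vector(tstat^2)
  } else {
    # orthogonalize through the contrast correlation; redundant contrasts
    # (rank-deficient correlation) only contribute their effective rank
    ee <- eigen(corr, symmetric = TRUE)
    keep <- ee$values > 1e-8 * max(ee$values)
    f_rank <- sum(keep)
    a_mat <- ee$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(ee$values[keep]), f_rank)
    f_stat <- rowSums((tstat %*% a_mat)^2) / f_rank
  }
  f_p <- stats::pf(f_stat, f_rank, df_total, lower.tail = FALSE)
  lods <- b_statistic(tstat, fit$stdev_unscaled, df_total, proportion)
  fit$df_prior <- prior$df_prior
  fit$robust_df <- prior$robust_df
  fit$s2_prior <- prior$s2_prior
  fit$trend_curve <- prior$trend_curve
  fit$s2_post <- s2_post
  fit$df_total <- df_total
  fit$t <- tstat
  fit$p_value <- p_value
  fit$lods <- lods
  fit$F <- f_stat
  fit$F_p <- f_p
  fit
}

# Log-odds of differential expression. The unscaled coefficient-variance
# prior v0 is estimated per column by matching the 90th percentile of |t|
# against its null counterpart; excess spread is attributed to true effects.
b_statistic <- function(tstat, stdev_unscaled, df_total, proportion) {
  lods <- tstat
  for (j in seq_len(ncol(tstat))) {
    tj <- tstat[, j]
    okt <- is.finite(tj)
    dfj <- df_total
    df_med <- stats::median(dfj[okt])
    q_obs <- stats::quantile(abs(tj[okt]), 0.9, names = FALSE)
    q_null <- stats::qt(0.95, df_med)
    u2 <- stdev_unscaled[, j]^2
    u2_med <- stats::median(u2[okt])
    v0 <- u2_med * max((q_obs / q_null)^2 - 1, 0)
    r <- (u2 + v0) / u2
    t2 <- tj^2
    kernel <- (1 + dfj) / 2 * log((t2 + dfj) / (t2 / r + dfj))
    lods[, j] <- log(proportion / (1 - proportion)) - 0.5 * log(r) + kernel
  }
  lods
}

#' Test whether |log-fold-change| exceeds a threshold (TREAT)
#'
#' Replaces the point null beta = 0 with the interval null |beta| <= lfc:
#' p = P(T > (|b| - lfc)/se) + P(T > (|b| + lfc)/se) on the moderated
#' degrees of freedom. With `lfc = 0` this is the ordinary moderated test.
#'
#' @param fit Moderated LinearFit (after [moderated_stats()]).
#' @param lfc Non-negative log2-fold-change threshold.
#' @return The fit with `t` and `p_value` replaced by the threshold test
#'   (the reported t is the sign of the coefficient times the smaller tail
#'   statistic) and `treat_lfc` recorded.
#' @export
treat <- function(fit, lfc) {
  if (is.null(fit$s2_post)) stop("run moderated_stats() before treat()")
  if (lfc < 0) stop("lfc must be non-negative")
  se <- fit$stdev_unscaled * sqrt(fit$s2_post)
  acoef <- abs(fit$coefficients)
  t_right <- (acoef - lfc) / se
  t_left <- (acoef + lfc) / se
  p <- stats::pt(t_right, df = fit$df_total, lower.tail = FALSE) +
    stats::pt(t_left, df = fit$df_total, lower.tail = FALSE)
  fit$t <- sign(fit$coefficients) * t_right
  fit$p_value <- pmin(p, 1)
  fit$treat_lfc <- lfc
  fit
}

#' Adjust p-values for multiple testing
#'
#' Supported methods: Benjamini-Hochberg (`"BH"`), Benjamini-Yekutieli
#' (`"BY"`), Holm (`"holm"`) and Bonferroni (`"bonferroni"`). Adjusted values
#' are clipped at 1 and monotone in the order statistics.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @param method Adjustment method.
#' @return Adjusted p-values in the original order.
#' @export
p_adjust <- function(p, method = c("BH", "BY", "holm", "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Top differentially expressed genes for one contrast
#'
#' @param fit Moderated LinearFit.
#' @param coef Coefficient/contrast name or column index.
#' @param number Maximum rows returned (default all).
#' @param adjust Multiple-testing adjustment (see [p_adjust()]).
#' @param sort_by `"p"` (ascending), `"logFC"` (by |logFC|, descending) or
#'   `"B"` (descending).
#' @return data.frame with columns gene_id, logFC, AveExpr, t, p, adj_p, B.
#' @export
top_table <- function(fit, coef = 1, number = Inf,
                      adjust = c("BH", "BY", "holm", "bonferroni"),
                      sort_by = c("p", "logFC", "B")) {
  adjust <- match.arg(adjust)
  sort_by <- match.arg(sort_by)
  if (is.null(fit$t)) stop("run moderated_stats() before top_table()")
  j <- coef_index(fit, coef)
  tab <- data.frame(gene_id = fit$gene_ids,
                    logFC = fit$coefficients[, j],
                    AveExpr = fit$amean,
                    t = fit$t[, j],
                    p = fit$p_value[, j],
                    adj_p = p_adjust(fit$p_value[, j], adjust),
                    B = fit$lods[, j],
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- switch(sort_by,
                p = order(tab$p, -abs(tab$t)),
                logFC = order(-abs(tab$logFC)),
                B = order(-tab$B))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  utils::head(tab, n = min(number, nrow(tab)))
}

coef_index <- function(fit, coef) {
  if (is.character(coef)) {
    j <- match(coef, colnames(fit$coefficients))
    if (is.na(j)) stop("unknown coefficient: ", coef)
    j
  } else {
    if (coef < 1 || coef > ncol(fit$coefficients))
      stop("coefficient index out of range")
    as.integer(coef)
  }
}

#' Classify genes as up/down/not-significant across contrasts
#'
#' `method = "separate"` adjusts each contrast's p-values independently;
#' `method = "global"` adjusts the pooled vector of all genes x contrasts
#' p-values, giving error rate control across contrasts and genes
#' simultaneously.
#'
#' @param fit Moderated LinearFit.
#' @param method `"separate"` or `"global"`.
#' @param adjust Multiple-testing adjustment.
#' @param p_threshold Significance threshold on adjusted p-values (in (0,1]).
#' @param lfc Minimum |logFC| additionally required.
#' @return A [test_results()] object.
#' @export
decide_tests <- function(fit, method = c("separate", "global"),
                         adjust = c("BH", "BY", "holm", "bonferroni"),
                         p_threshold = 0.05, lfc = 0) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (is.null(fit$t)) stop("run moderated_stats() before decide_tests()")
  if (p_threshold <= 0 || p_threshold > 1)
    stop("p_threshold must lie in (0, 1]")
  p <- fit$p_value
  adj <- if (method == "separate") apply(p, 2, p_adjust, method = adjust)
         else matrix(p_adjust(as.vector(p), adjust), nrow(p), ncol(p))
  adj <- matrix(adj, nrow(p), ncol(p), dimnames = dimnames(p))
  sig <- adj <= p_threshold & abs(fit$coefficients) >= lfc
  codes <- sign(fit$t) * sig
  test_results(codes, method = method, adjust_method = adjust,
               p_threshold = p_threshold, lfc_threshold = lfc)
}

#' Estimate the proportion of true null hypotheses
#'
#' Methods: `"mean"` = min(1, 2 * mean(p)); `"hist"` = histogram-based
#' iteration (tail bins whose average height the current bin does not
#' exceed); `"convest"` = maximum likelihood over the convex decreasing
#' densities on \[0,1\] (mixtures of triangular densities plus a uniform
#' component, fitted by EM; pi0 is the uniform weight); `"lfdr"` = average of
#' local false discovery rates from a boundary-corrected kernel density
#' estimate of the p-values.
#'
#' @param p Vector of p-values (length >= 20 recommended).
#' @param method Estimation method.
#' @return Estimated pi0 in \[0, 1\].
#' @export
prop_true_null <- function(p, method = c("lfdr", "mean", "hist", "convest")) {
  method <- match.arg(method)
  p <- p[!is.na(p)]
  if (!length(p)) stop("no p-values supplied")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  switch(method,
    mean = min(1, 2 * mean(p)),
    hist = {
      n_bins <- 20
      counts <- tabulate(pmin(floor(p * n_bins) + 1, n_bins), n_bins)
      pi0 <- counts[n_bins] * n_bins / n
      for (i in seq_len(n_bins)) {
        avg <- mean(counts[i:n_bins])
        if (counts[i] <= avg) { pi0 <- avg * n_bins / n; break }
      }
      min(1, max(0, pi0))
    },
    convest = {
      theta <- seq(0.02, 1, by = 0.02)
      dens <- vapply(theta, function(th) 2 * pmax(th - p, 0) / th^2,
                     numeric(n))
      dens <- cbind(dens, 1)  # uniform component
      k <- ncol(dens)
      wts <- rep(1 / k, k)
      for (it in 1:300) {
        mix <- as.vector(dens %*% wts)
        resp <- t(dens) * wts
        new_wts <- rowSums(t(t(resp) / mix)) / n
        if (max(abs(new_wts - wts)) < 1e-8) { wts <- new_wts; break }
        wts <- new_wts
      }
      min(1, max(0, wts[k]))
    },
    lfdr = {
      refl <- c(-p, p, 2 - p)
      d <- stats::density(refl, from = 0, to = 1, n = 512,
                          bw = max(stats::bw.nrd0(p), 0.02))
      f <- stats::approxfun(d$x, 3 * d$y, rule = 2)
      f1 <- f(1)
      lfdr <- pmin(1, f1 / pmax(f(p), 1e-10))
      min(1, max(0, mean(lfdr)))
    })
}
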