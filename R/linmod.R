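#' Block structure for correlated observations
#'
#' Describes samples sharing a block (duplicate probes, repeated measures)
#' with a common intrablock correlation, as estimated by
#' [duplicate_correlation()].
#'
#' @param block Categorical vector, one entry per sample.
#' @param correlation Consensus intrablock correlation, |rho| < 1.
#' @return An object of class `"BlockStructure"`.
#' @export
block_structure <- function(block, correlation) {
  block <- as.factor(block)
  if (!is.finite(correlation) || abs(correlation) >= 1)
    stop("correlation must lie strictly inside (-1, 1)")
  if (!any(table(block) >= 2))
    stop("at least one block must contain two or more samples")
  structure(list(block = block, correlation = correlation),
            class = "BlockStructure")
}

# Orthogonal transform diagonalizing the equicorrelation matrix of every
# block simultaneously: within a block of size m the first transformed
# coordinate (the scaled block mean) has variance 1+(m-1)rho and the m-1
# orthogonal contrasts have variance 1-rho, for every rho at once.
block_transform <- function(block) {
  block <- as.factor(block)
  n <- length(block)
  q_mat <- matrix(0, n, n)
  sizes <- integer(n)
  is_common <- logical(n)
  nxt <- 1
  for (lev in levels(block)) {
    idx <- which(block == lev)
    m <- length(idx)
    coords <- seq(nxt, nxt + m - 1)
    nxt <- nxt + m
    if (m == 1) qb <- matrix(1, 1, 1)
    else qb <- qr.Q(qr(cbind(rep(1 / sqrt(m), m),
                             diag(m)[, seq_len(m - 1)])))
    q_mat[idx, coords] <- qb
    sizes[coords] <- m
    is_common[coords] <- c(TRUE, rep(FALSE, m - 1))
  }
  list(q = q_mat, sizes = sizes, is_common = is_common)
}

block_variances <- function(bt, rho) {
  ifelse(bt$is_common, 1 + (bt$sizes - 1) * rho, 1 - rho)
}

#' Fit gene-wise linear models
#'
#' Fits one weighted least squares model per gene (row). Weights are the
#' product of observation weights and sample weights stored on `m`. Missing
#' values (permitted for log-intensity data) are dropped per gene with the
#' residual degrees of freedom reduced accordingly. With a
#' [block_structure()], generalized least squares under an equicorrelated
#' within-block covariance at the supplied correlation is used (the data are
#' whitened by an orthogonal within-block transform; with `correlation = 0`
#' the code path is ordinary least squares, identical bit for bit). With
#' `robust = TRUE` coefficients are re-estimated by iteratively reweighted
#' least squares with Huber weights (k = 1.345); `df_residual` is unchanged.
#'
#' @param m ExpressionMatrix.
#' @param design Design matrix or [design_spec()]; must have full column rank.
#' @param block Optional [block_structure()].
#' @param robust Use Huber IRLS per gene.
#' @return An object of class `"LinearFit"` with `coefficients`,
#'   `stdev_unscaled`, `sigma`, `df_residual`, `amean`, `coef_cov` (p x p
#'   unscaled covariance of the coefficients for the common design),
#'   `gene_ids`, `coef_names` and the `design` used.
#' @export
lm_fit <- function(m, design, block = NULL, robust = FALSE) {
  if (!inherits(m, "ExpressionMatrix"))
    m <- expression_matrix(m, kind = "log_intensity")
  design <- as_design_spec(design)
  x_mat <- design$design
  y <- m$values
  n <- ncol(y); p <- ncol(x_mat); n_genes <- nrow(y)
  if (nrow(x_mat) != n) stop("design rows must match samples")
  amean <- rowMeans(y, na.rm = TRUE)
  sw <- m$sample_weights
  obsw <- m$obs_weights
  if (!is.null(block) && block$correlation != 0) {
    if (anyNA(y)) stop("missing values are not supported with a block structure")
    bt <- block_transform(block$block)
    d <- block_variances(bt, block$correlation)
    if (any(d <= 0)) stop("correlation outside the positive-definite range for these block sizes")
    scl <- 1 / sqrt(d)
    # heteroscedastic weights act on the standardized errors, so scale first
    if (!is.null(sw)) {
      y <- sweep(y, 2, sqrt(sw), `*`)
      x_mat_w <- x_mat * sqrt(sw)
      sw <- NULL
    } else x_mat_w <- x_mat
    if (!is.null(obsw))
      warning("observation weights combined with a block correlation are experimental")
    y <- (y %*% bt$q) * rep(scl, each = nrow(y))
    x_mat <- (t(bt$q) %*% x_mat_w) * scl
  } else if (!is.null(sw)) {
    y <- sweep(y, 2, sqrt(sw), `*`)
    x_mat <- x_mat * sqrt(sw)
    sw <- NULL
  }
  coef_cov <- chol2inv(chol(crossprod(x_mat)))
  dimnames(coef_cov) <- list(design$coef_names, design$coef_names)
  coefs <- matrix(NA_real_, n_genes, p,
                  dimnames = list(m$gene_ids, design$coef_names))
  stdev <- coefs
  sigma <- rep(NA_real_, n_genes)
  df_res <- rep(0, n_genes)
  simple <- is.null(obsw) && !anyNA(y) && !robust
  if (simple) {
    qr_x <- qr(x_mat)
    coefs[] <- t(qr.coef(qr_x, t(y)))
    res <- qr.resid(qr_x, t(y))
    df_res[] <- n - p
    if (n > p) sigma <- sqrt(colSums(res^2) / (n - p))
    stdev[] <- rep(sqrt(diag(coef_cov)), each = n_genes)
  } else {
    for (g in seq_len(n_genes)) {
      yg <- y[g, ]
      wg <- if (!is.null(obsw)) obsw[g, ] else rep(1, n)
      ok <- !is.na(yg) & wg > 0
      if (sum(ok) < p) next
      fit <- stats::lm.wfit(x_mat[ok, , drop = FALSE], yg[ok], wg[ok])
      if (fit$rank < p) next
      dfg <- sum(ok) - p
      if (robust && dfg > 0) {
        fit <- huber_irls(x_mat[ok, , drop = FALSE], yg[ok], wg[ok])
      }
      r_mat <- qr.R(fit$qr)
      piv <- fit$qr$pivot
      v <- chol2inv(r_mat)[order(piv), order(piv), drop = FALSE]
      coefs[g, ] <- fit$coefficients
      stdev[g, ] <- sqrt(diag(v))
      df_res[g] <- dfg
      if (dfg > 0) {
        wr2 <- sum(fit$weights * fit$residuals^2)
        sigma[g] <- sqrt(wr2 / dfg)
      }
    }
  }
  structure(list(coefficients = coefs, stdev_unscaled = stdev, sigma = sigma,
                 df_residual = df_res, amean = amean, coef_cov = coef_cov,
                 gene_ids = m$gene_ids, coef_names = design$coef_names,
                 design = design$design), class = "LinearFit")
}

# Huber IRLS refit; returns an lm.wfit-like list with final working weights.
huber_irls <- function(x_mat, y, w, k = 1.345, iterations = 20) {
  fit <- stats::lm.wfit(x_mat, y, w)
  for (it in seq_len(iterations)) {
    r <- y - x_mat %*% fit$coefficients
    s <- stats::median(abs(r - stats::median(r))) / 0.6745
    if (s <= 0) break
    u <- pmin(1, k / pmax(abs(r) / s, 1e-12))
    new_fit <- stats::lm.wfit(x_mat, y, w * as.vector(u))
    if (max(abs(new_fit$coefficients - fit$coefficients), na.rm = TRUE) <
        1e-8 * max(1, max(abs(fit$coefficients), na.rm = TRUE))) {
      fit <- new_fit; break
    }
    fit <- new_fit
  }
  fit
}

#' Re-express a fit in terms of contrasts of the coefficients
#'
#' Coefficients become `coefficients %*% contrasts`; the unscaled standard
#' deviations are propagated through the unscaled coefficient covariance
#' (per gene, using the gene's stdev_unscaled and the common correlation
#' structure). An identity contrast is a no-op.
#'
#' @param fit LinearFit.
#' @param contrasts Numeric p x c matrix (p = number of coefficients).
#' @return LinearFit with one column per contrast.
#' @export
contrasts_fit <- function(fit, contrasts) {
  contrasts <- as.matrix(contrasts)
  p <- ncol(fit$coefficients)
  if (nrow(contrasts) != p)
    stop("contrast matrix must have one row per coefficient")
  if (is.null(colnames(contrasts)))
    colnames(contrasts) <- paste0("c", seq_len(ncol(contrasts)))
  corr <- stats::cov2cor(fit$coef_cov)
  new_coef <- fit$coefficients %*% contrasts
  n_genes <- nrow(new_coef)
  new_stdev <- matrix(NA_real_, n_genes, ncol(contrasts),
                      dimnames = dimnames(new_coef))
  for (j in seq_len(ncol(contrasts))) {
    uc <- fit$stdev_unscaled * rep(contrasts[, j], each = n_genes)
    new_stdev[, j] <- sqrt(rowSums((uc %*% corr) * uc))
  }
  fit$coefficients <- new_coef
  fit$stdev_unscaled <- new_stdev
  fit$coef_cov <- t(contrasts) %*% fit$coef_cov %*% contrasts
  fit$coef_names <- colnames(new_coef)
  fit
}

#' Consensus intrablock correlation
#'
#' Estimates, for every gene, the intrablock correlation of a random-
#' intercept model by restricted maximum likelihood (an exact profiled REML
#' criterion evaluated over a fine correlation grid after an orthogonal
#' within-block transform, refined by parabolic interpolation), then combines
#' the per-gene estimates on the atanh scale by a trimmed mean.
#'
#' @param m ExpressionMatrix (>= 50 genes recommended).
#' @param design Design matrix or [design_spec()].
#' @param block Categorical vector assigning samples to blocks; at least one
#'   block must have two or more members.
#' @param trim Trim fraction for the consensus mean.
#' @param grid_step Correlation grid resolution.
#' @return Consensus correlation (scalar) with the per-gene estimates in
#'   attribute `"all_rho"`.
#' @export
duplicate_correlation <- function(m, design, block, trim = 0.15,
                                  grid_step = 0.005) {
  if (!inherits(m, "ExpressionMatrix"))
    m <- expression_matrix(m, kind = "log_intensity")
  design <- as_design_spec(design)
  block <- as.factor(block)
  sizes <- table(block)
  if (!any(sizes >= 2)) stop("all blocks are singletons; correlation is not estimable")
  if (nrow(m$values) < 50)
    warning("fewer than 50 genes; the consensus correlation may be unstable")
  y <- m$values
  if (anyNA(y)) stop("missing values are not supported in duplicate_correlation")
  x_mat <- design$design
  n <- ncol(y); p <- ncol(x_mat)
  if (n - p < 1) stop("no residual degrees of freedom")
  bt <- block_transform(block)
  y2 <- y %*% bt$q
  x2 <- t(bt$q) %*% x_mat
  max_m <- max(sizes)
  rho_lo <- max(-0.9, -1 / (max_m - 1) + 2 * grid_step)
  grid <- seq(rho_lo, 0.99, by = grid_step)
  ll <- matrix(-Inf, length(grid), nrow(y))
  yt <- t(y2)
  for (k in seq_along(grid)) {
    d <- block_variances(bt, grid[k])
    scl <- 1 / sqrt(d)
    xw <- x2 * scl
    qr_x <- qr(xw)
    if (qr_x$rank < p) next
    res <- qr.resid(qr_x, yt * scl)
    rss <- colSums(res^2)
    ldet_x <- 2 * sum(log(abs(diag(qr.R(qr_x)))))
    ll[k, ] <- -0.5 * ((n - p) * log(rss) + sum(log(d)) + ldet_x)
  }
  best <- apply(ll, 2, which.max)
  rho_g <- grid[best]
  # parabolic refinement inside the grid
  interior <- best > 1 & best < length(grid)
  idx <- which(interior)
  if (length(idx)) {
    l1 <- ll[cbind(best[idx] - 1, idx)]
    l2 <- ll[cbind(best[idx], idx)]
    l3 <- ll[cbind(best[idx] + 1, idx)]
    denom <- l1 - 2 * l2 + l3
    delta <- ifelse(abs(denom) > 0, 0.5 * (l1 - l3) / denom, 0)
    rho_g[idx] <- rho_g[idx] + pmin(pmax(delta, -1), 1) * grid_step
  }
  keep <- is.finite(rho_g)
  rho_g <- pmin(pmax(rho_g[keep], -0.99), 0.99)
  consensus <- tanh(mean(atanh(rho_g), trim = trim))
  attr(consensus, "all_rho") <- rho_g
  consensus
}

#' Estimate relative sample (array) quality weights
#'
#' Fits the heteroscedastic model var(e_gj) = sigma_g^2 / w_j by an iterative
#' moment/scoring update: given current weights, gene-wise weighted fits give
#' standardized squared residuals whose per-sample mean (relative to its
#' leverage-based expectation) multiplies the inverse weight. Weights are
#' normalized to geometric mean 1.
#'
#' @param m ExpressionMatrix (observation weights and prior sample weights,
#'   when present, are treated as fixed and multiplied in).
#' @param design Design matrix or [design_spec()].
#' @param max_iter,tol Iteration control; non-convergence warns and returns
#'   the last iterate.
#' @return Positive vector of sample weights with geometric mean 1.
#' @export
array_weights <- function(m, design, max_iter = 50, tol = 1e-4) {
  if (!inherits(m, "ExpressionMatrix"))
    m <- expression_matrix(m, kind = "log_intensity")
  design <- as_design_spec(design)
  x_mat <- design$design
  y <- m$values
  n <- ncol(y); p <- ncol(x_mat); n_genes <- nrow(y)
  if (n <= p + 1) stop("need more samples than coefficients + 1")
  if (anyNA(y)) stop("missing values are not supported in array_weights")
  obsw <- m$obs_weights
  base_sw <- if (!is.null(m$sample_weights)) m$sample_weights else rep(1, n)
  sw <- rep(1, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (is.null(obsw)) {
      wfull <- base_sw * sw
      sq <- sqrt(wfull)
      qr_x <- qr(x_mat * sq)
      h <- rowSums(qr.Q(qr_x)[, seq_len(p), drop = FALSE]^2)
      res <- qr.resid(qr_x, t(y) * sq)
      s2 <- colSums(res^2) / (n - p)
      ok <- s2 > 0
      std <- res[, ok, drop = FALSE]^2 /
        matrix(s2[ok], n, sum(ok), byrow = TRUE)
      v <- rowMeans(std) / (1 - h)
    } else {
      num <- rep(0, n); den <- rep(0, n)
      for (g in seq_len(n_genes)) {
        wg <- obsw[g, ] * base_sw * sw
        fit <- stats::lm.wfit(x_mat, y[g, ], wg)
        if (fit$rank < p) next
        r2w <- fit$weights * fit$residuals^2
        s2g <- sum(r2w) / (n - p)
        if (s2g <= 0) next
        h <- rowSums(qr.Q(fit$qr)[, seq_len(p), drop = FALSE]^2)
        num <- num + r2w / s2g
        den <- den + (1 - h)
      }
      v <- num / den
    }
    v <- pmin(pmax(v, 1e-4), 1e4)
    sw <- sw / v
    sw <- sw / exp(mean(log(sw)))
    if (max(abs(log(v))) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("array_weights did not converge in ", max_iter,
            " iterations; returning last iterate")
  names(sw) <- m$sample_ids
  sw
}

#' Remove additive batch effects from an expression matrix
#'
#' Fits a gene-wise model containing the supplied design plus sum-to-zero
#' batch indicators and subtracts only the fitted batch terms, so corrected
#' values stay centred on the grand mean and the design effects are retained.
#'
#' @param m ExpressionMatrix.
#' @param batch Categorical vector, one entry per sample.
#' @param design Optional design whose effects must be protected (default:
#'   intercept only).
#' @return Corrected ExpressionMatrix.
#' @export
remove_batch_effect <- function(m, batch, design = NULL) {
  if (!inherits(m, "ExpressionMatrix"))
    m <- expression_matrix(m, kind = "log_intensity")
  batch <- as.factor(batch)
  if (nlevels(batch) < 2) return(m)
  b_mat <- stats::model.matrix(~batch,
                               contrasts.arg = list(batch = "contr.sum"))
  b_mat <- b_mat[, -1, drop = FALSE]
  x_mat <- if (is.null(design)) matrix(1, ncol(m$values), 1)
           else as_design_spec(design)$design
  full <- cbind(x_mat, b_mat)
  qr_f <- qr(full)
  if (qr_f$rank < ncol(full))
    stop("batch is aliased with the design (confounded columns: ",
         paste(colnames(full)[qr_f$pivot[-seq_len(qr_f$rank)]],
               collapse = ", "), ")")
  y <- m$values
  bcols <- seq(ncol(x_mat) + 1, ncol(full))
  if (!anyNA(y)) {
    beta <- qr.coef(qr_f, t(y))
    y <- y - t(b_mat %*% beta[bcols, , drop = FALSE])
  } else {
    for (g in seq_len(nrow(y))) {
      ok <- !is.na(y[g, ])
      beta <- qr.coef(qr(full[ok, , drop = FALSE]), y[g, ok])
      beta[is.na(beta)] <- 0
      y[g, ok] <- y[g, ok] - as.vector(b_mat[ok, , drop = FALSE] %*%
                                         beta[bcols])
    }
  }
  m$values <- y
  m
}
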