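#' Differential splicing from an exon-level fit
#'
#' For each gene with at least two exons, each exon's coefficient for the
#' chosen contrast is compared with the precision-weighted average coefficient
#' of all exons in the gene (precisions 1 / (u^2 * s2_post) from the
#' empirical Bayes moderated variances). Exon-level moderated t statistics
#' test each exon's deviation; gene-level results combine the deviations into
#' an F statistic and aggregate the exon p-values by the Simes rule.
#' Single-exon genes are dropped (their count is reported in an attribute).
#'
#' @param exon_fit LinearFit on the exon-level matrix (after [voom()] for
#'   RNA-seq counts).
#' @param gene_ids Per-exon gene labels, one per fit row.
#' @param coef Coefficient/contrast name or index to test.
#' @return List with `exon` (gene_id, exon_id, logFC_diff, precision, t, p,
#'   adj_p) and
#'   `gene` (gene_id, n_exons, F, F_p, simes_p, and BH-adjusted columns)
#'   tables; attribute `"n_dropped"` counts single-exon genes removed.
#' @export
diff_splice <- function(exon_fit, gene_ids, coef = 1) {
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(exon_fit$coefficients))
    stop("gene_ids must label every exon row")
  j <- coef_index(exon_fit, coef)
  prior <- fit_fdist(exon_fit$sigma^2, exon_fit$df_residual)
  s2_post <- squeeze_var(exon_fit$sigma^2, exon_fit$df_residual, prior)
  d0 <- prior$df_prior
  beta <- exon_fit$coefficients[, j]
  u2 <- exon_fit$stdev_unscaled[, j]^2
  w <- 1 / (u2 * s2_post)
  df_total <- pmin(exon_fit$df_residual + d0,
                   sum(exon_fit$df_residual, na.rm = TRUE))
  groups <- split(seq_along(gene_ids), gene_ids)
  sizes <- lengths(groups)
  dropped <- sum(sizes < 2)
  groups <- groups[sizes >= 2]
  if (!length(groups)) stop("all genes have a single exon; nothing to test")
  exon_rows <- vector("list", length(groups))
  gene_rows <- vector("list", length(groups))
  exon_names <- exon_fit$gene_ids
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    wg <- w[idx]
    bg <- beta[idx]
    sw <- sum(wg)
    bbar <- sum(wg * bg) / sw
    dev <- bg - bbar
    var_dev <- 1 / wg - 1 / sw
    t_ex <- dev / sqrt(var_dev)
    df_ex <- df_total[idx]
    p_ex <- 2 * stats::pt(-abs(t_ex), df = df_ex)
    k <- length(idx)
    f_gene <- sum(wg * dev^2) / (k - 1)
    df2 <- mean(df_ex)
    f_p <- stats::pf(f_gene, k - 1, df2, lower.tail = FALSE)
    ps <- sort(p_ex)
    simes <- min(pmin(length(ps) * ps / seq_along(ps), 1))
    exon_rows[[g]] <- data.frame(gene_id = names(groups)[g],
                                 exon_id = exon_names[idx],
                                 logFC_diff = dev, precision = wg,
                                 t = t_ex, p = p_ex,
                                 stringsAsFactors = FALSE)
    gene_rows[[g]] <- data.frame(gene_id = names(groups)[g], n_exons = k,
                                 F = f_gene, F_p = f_p, simes_p = simes,
                                 stringsAsFactors = FALSE)
  }
  exon_tab <- do.call(rbind, exon_rows)
  gene_tab <- do.call(rbind, gene_rows)
  exon_tab$adj_p <- p_adjust(exon_tab$p, "BH")
  gene_tab$adj_F_p <- p_adjust(gene_tab$F_p, "BH")
  gene_tab$adj_simes_p <- p_adjust(gene_tab$simes_p, "BH")
  rownames(exon_tab) <- rownames(gene_tab) <- NULL
  out <- list(exon = exon_tab, gene = gene_tab)
  attr(out, "n_dropped") <- dropped
  out
}

#' Multidimensional scaling on leading log-fold-changes
#'
#' The distance between two samples is the root-mean-square of the `top`
#' largest absolute log-fold-changes between them — the "leading fold
#' change". With `selection = "pairwise"` the top genes are chosen separately
#' for every pair; with `"common"` one set of most variable genes (largest
#' mean squared deviation from the gene's average) is used for all pairs.
#' Classical (Torgerson) multidimensional scaling of the squared distances
#' gives the plotting coordinates; each dimension's sign is fixed so its
#' first nonzero loading is positive.
#'
#' @param m ExpressionMatrix (log scale), at least 3 samples.
#' @param top Number of top genes per (pair of) samples.
#' @param selection `"pairwise"` or `"common"`.
#' @param dims Number of dimensions returned.
#' @return List with `coords` (samples x dims), `distance` (symmetric
#'   matrix), `eig` (eigenvalues).
#' @export
mds_leading_lfc <- function(m, top = 500, selection = c("pairwise", "common"),
                            dims = 2) {
  selection <- match.arg(selection)
  if (top < 2) stop("top must be at least 2")
  x <- m$values
  n <- ncol(x)
  if (n < 3) stop("MDS needs at least 3 samples")
  top_use <- min(top, nrow(x))
  dd <- matrix(0, n, n, dimnames = list(m$sample_ids, m$sample_ids))
  if (selection == "common") {
    s <- rowMeans((x - rowMeans(x))^2)
    keep <- order(s, decreasing = TRUE)[seq_len(top_use)]
    xs <- x[keep, , drop = FALSE]
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      dd[i, j] <- dd[j, i] <- sqrt(mean((xs[, i] - xs[, j])^2))
    }
  } else {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      d2 <- sort((x[, i] - x[, j])^2, decreasing = TRUE)[seq_len(top_use)]
      dd[i, j] <- dd[j, i] <- sqrt(mean(d2))
    }
  }
  dims_use <- min(dims, n - 1)
  mds <- stats::cmdscale(stats::as.dist(dd), k = dims_use, eig = TRUE)
  coords <- mds$points
  for (k in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, k]) > 1e-12)
    if (length(nz) && coords[nz[1], k] < 0) coords[, k] <- -coords[, k]
  }
  rownames(coords) <- m$sample_ids
  list(coords = coords, distance = dd, eig = mds$eig)
}

#' Mean-difference values of one sample against a virtual reference
#'
#' A virtual array is built as the gene-wise mean of all samples other than
#' the chosen one; A = (sample + virtual)/2 and M = sample - virtual.
#'
#' @param m ExpressionMatrix (log scale), at least 2 samples.
#' @param column Sample index or id.
#' @return List with vectors `A` and `M`.
#' @export
mean_difference <- function(m, column) {
  x <- m$values
  if (ncol(x) < 2) stop("mean-difference values need at least 2 samples")
  if (is.character(column)) column <- match(column, m$sample_ids)
  if (is.na(column) || column < 1 || column > ncol(x))
    stop("unknown sample column")
  virtual <- rowMeans(x[, -column, drop = FALSE], na.rm = TRUE)
  list(A = (x[, column] + virtual) / 2, M = x[, column] - virtual)
}

#' Mean-difference values from a fitted model
#'
#' Pairs the fit's average log-expression with the log-fold-changes of a
#' chosen contrast, exactly as stored on the fit (no transformation).
#'
#' @param fit LinearFit.
#' @param coef Coefficient/contrast name or index.
#' @return List with vectors `A` (average log-expression) and `logFC`.
#' @export
md_fit <- function(fit, coef = 1) {
  j <- coef_index(fit, coef)
  list(A = fit$amean, logFC = fit$coefficients[, j])
}

#' Residual standard deviation versus abundance profile
#'
#' Returns the (average log-expression, sqrt residual sd) pairs of a fit and
#' the robust lowess trend through them — the curve a trended empirical
#' Bayes prior would use. Genes with missing sigma are dropped and counted.
#'
#' @param fit LinearFit.
#' @param span Lowess span.
#' @return List with `A`, `sqrt_sigma`, `trend` (lowess points) and
#'   `n_dropped`.
#' @export
sa_profile <- function(fit, span = 0.5) {
  ok <- is.finite(fit$sigma) & fit$sigma >= 0
  a_vals <- fit$amean[ok]
  s_vals <- sqrt(fit$sigma[ok])
  lo <- stats::lowess(a_vals, s_vals, f = span, iter = 3)
  list(A = a_vals, sqrt_sigma = s_vals, trend = lo, n_dropped = sum(!ok))
}
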