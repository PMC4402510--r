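#' Simulate a log-intensity matrix under the hierarchical variance model
#'
#' Gene variances are drawn from the scaled inverse chi-square prior
#' sigma2_g ~ d0 * s0^2 / chi2_d0 (optionally modulated by an
#' abundance-dependent trend), baseline abundances are uniform on
#' `amean_range`, and a `de_fraction` of genes receive a true effect
#' ~ N(0, logfc_sd^2) on the chosen design coefficient. Errors are normal.
#' All generators are pure functions of their seed and parameters (R RNG
#' pinned to Mersenne-Twister / Inversion / Rejection).
#'
#' @param n_genes,design Number of genes and the design (matrix or
#'   [design_spec()]) defining the samples.
#' @param de_fraction Fraction of genes with a true effect, in \[0, 1\].
#' @param logfc_sd Standard deviation of true log2-fold-changes.
#' @param d0,s0_sq Prior df and prior variance of the variance distribution.
#' @param trend If `TRUE`, low-abundance genes get inflated variances
#'   (factor 1 + 3 exp(-(A - min A)/2)).
#' @param coef Design coefficient carrying the effect (default: last).
#' @param amean_range Range of baseline average log2-expression.
#' @param seed RNG seed.
#' @return List: `m` (ExpressionMatrix, kind log_intensity) and `truth`
#'   (data.frame gene_id, is_de, true_lfc, sigma2, amean).
#' @export
sim_log_matrix <- function(n_genes = 10000, design, de_fraction = 0.1,
                           logfc_sd = 1, d0 = 4, s0_sq = 0.05, trend = FALSE,
                           coef = NULL, amean_range = c(4, 14), seed = 0) {
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must lie in [0, 1]")
  design <- as_design_spec(design)
  x_mat <- design$design
  n <- nrow(x_mat)
  if (is.null(coef)) coef <- ncol(x_mat)
  with_seed(seed, {
    amean <- stats::runif(n_genes, amean_range[1], amean_range[2])
    sigma2 <- d0 * s0_sq / stats::rchisq(n_genes, df = d0)
    if (trend)
      sigma2 <- sigma2 * (1 + 3 * exp(-(amean - amean_range[1]) / 2))
    n_de <- round(de_fraction * n_genes)
    de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
    lfc <- numeric(n_genes)
    lfc[de_idx] <- stats::rnorm(n_de, 0, logfc_sd)
    beta <- matrix(0, n_genes, ncol(x_mat))
    beta[, coef] <- lfc
    eff <- beta %*% t(x_mat)
    eff <- eff - rowMeans(eff)  # effects centred so amean stays the baseline
    y <- amean + eff +
      matrix(stats::rnorm(n_genes * n), n_genes, n) * sqrt(sigma2)
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    rownames(y) <- gene_ids
    colnames(y) <- paste0("s", seq_len(n))
    list(m = expression_matrix(y, kind = "log_intensity"),
         truth = data.frame(gene_id = gene_ids,
                            is_de = seq_len(n_genes) %in% de_idx,
                            true_lfc = lfc, sigma2 = sigma2, amean = amean,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate negative-binomial RNA-seq counts with a dispersion trend
#'
#' Gene expected counts are log-uniform over `mean_range`, library sizes
#' vary uniformly within +/-30% of their mean, and dispersions follow a
#' positive decreasing function of the expected count (default
#' 0.05 + 2/mu: technical variability shrinks with count size towards a
#' biological floor). A `de_fraction` of genes carry a log2-fold-change of
#' magnitude `de_lfc` (random sign) on the chosen design coefficient.
#'
#' @param n_genes,design Genes and design.
#' @param mean_range Range of expected base counts (at the average library
#'   size).
#' @param dispersion_trend Function mu -> dispersion (positive decreasing).
#' @param de_fraction Fraction of DE genes.
#' @param de_lfc Absolute log2-fold-change of DE genes.
#' @param coef Design coefficient carrying the effect (default: last).
#' @param seed RNG seed.
#' @return List: `counts` (ExpressionMatrix of counts), `truth` (data.frame),
#'   `lib_sizes`.
#' @export
sim_counts_nb <- function(n_genes = 5000, design, mean_range = c(5, 5000),
                          dispersion_trend = function(mu) 0.05 + 2 / mu,
                          de_fraction = 0, de_lfc = 2, coef = NULL,
                          seed = 0) {
  design <- as_design_spec(design)
  x_mat <- design$design
  n <- nrow(x_mat)
  if (is.null(coef)) coef <- ncol(x_mat)
  with_seed(seed, {
    base_mu <- 2^stats::runif(n_genes, log2(mean_range[1]),
                              log2(mean_range[2]))
    phi <- dispersion_trend(base_mu)
    if (any(phi <= 0)) stop("dispersion_trend must be positive")
    n_de <- round(de_fraction * n_genes)
    de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
    lfc <- numeric(n_genes)
    lfc[de_idx] <- de_lfc * sample(c(-1, 1), n_de, replace = TRUE)
    lib_factor <- stats::runif(n, 0.7, 1.3)
    xc <- x_mat[, coef]
    mu <- outer(base_mu, lib_factor) * 2^outer(lfc, xc)
    counts <- matrix(stats::rnbinom(n_genes * n, mu = mu,
                                    size = rep(1 / phi, n)),
                     n_genes, n)
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    rownames(counts) <- gene_ids
    colnames(counts) <- paste0("s", seq_len(n))
    list(counts = expression_matrix(counts, kind = "counts"),
         truth = data.frame(gene_id = gene_ids,
                            is_de = seq_len(n_genes) %in% de_idx,
                            true_lfc = lfc, base_mean = base_mu,
                            dispersion = phi, stringsAsFactors = FALSE),
         lib_sizes = colSums(counts))
  })
}

#' Simulate equicorrelated within-block expression data
#'
#' Errors within each block share a common correlation `rho` (any rho in the
#' positive-definite range, including negative values); blocks are
#' independent. Variances come from a scaled inverse chi-square prior.
#'
#' @param n_genes Number of genes.
#' @param n_blocks,block_size Blocking layout; samples = n_blocks x
#'   block_size.
#' @param rho Intrablock correlation.
#' @param d0,s0_sq Variance prior hyperparameters.
#' @param amean_range Baseline abundance range.
#' @param seed RNG seed.
#' @return List: `m` (ExpressionMatrix), `block` (factor of length N) and
#'   `truth` (per-gene baseline and variance).
#' @export
sim_blocks <- function(n_genes = 5000, n_blocks = 4, block_size = 2,
                       rho = 0.5, d0 = 8, s0_sq = 0.1,
                       amean_range = c(4, 14), seed = 0) {
  if (rho <= -1 / (block_size - 1) || rho >= 1)
    stop("rho outside the positive-definite range for this block size")
  n <- n_blocks * block_size
  block <- factor(rep(seq_len(n_blocks), each = block_size))
  r_mat <- matrix(rho, block_size, block_size)
  diag(r_mat) <- 1
  ch <- chol(r_mat)
  with_seed(seed, {
    amean <- stats::runif(n_genes, amean_range[1], amean_range[2])
    sigma <- sqrt(d0 * s0_sq / stats::rchisq(n_genes, df = d0))
    y <- matrix(0, n_genes, n)
    for (b in seq_len(n_blocks)) {
      z <- matrix(stats::rnorm(n_genes * block_size), n_genes, block_size)
      y[, which(block == b)] <- z %*% ch
    }
    y <- amean + y * sigma
    rownames(y) <- sprintf("g%05d", seq_len(n_genes))
    colnames(y) <- paste0("s", seq_len(n))
    list(m = expression_matrix(y, kind = "log_intensity"), block = block,
         truth = data.frame(gene_id = rownames(y), amean = amean,
                            sigma2 = sigma^2, stringsAsFactors = FALSE))
  })
}

#' Simulate null data with internally correlated gene sets
#'
#' The first `n_sets * set_size` genes form disjoint sets whose members share
#' a latent factor inducing pairwise correlation `rho_within`; the remaining
#' genes are independent. No gene is differentially expressed, so the data
#' calibrate competitive set tests under inter-gene correlation.
#'
#' @param n_genes Total genes (must be >= n_sets * set_size).
#' @param set_size Genes per correlated set.
#' @param n_sets Number of correlated sets.
#' @param rho_within Target within-set correlation in \[0, 1).
#' @param n_samples Number of samples.
#' @param amean_range Baseline abundance range.
#' @param seed RNG seed.
#' @return List: `m` (ExpressionMatrix), `sets` ([gene_set_collection()]).
#' @export
sim_correlated_sets <- function(n_genes = 2000, set_size = 20, n_sets = 20,
                                rho_within = 0.1, n_samples = 20,
                                amean_range = c(4, 14), seed = 0) {
  if (rho_within < 0 || rho_within >= 1) stop("rho_within must be in [0, 1)")
  if (n_sets * set_size > n_genes)
    stop("n_genes too small for the requested sets")
  with_seed(seed, {
    amean <- stats::runif(n_genes, amean_range[1], amean_range[2])
    e <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
    y <- sqrt(1 - rho_within) * e
    set_list <- list()
    for (s in seq_len(n_sets)) {
      idx <- seq((s - 1) * set_size + 1, s * set_size)
      latent <- stats::rnorm(n_samples)
      y[idx, ] <- y[idx, ] + sqrt(rho_within) *
        matrix(latent, set_size, n_samples, byrow = TRUE)
      set_list[[sprintf("SET%03d", s)]] <- sprintf("g%05d", idx)
    }
    bg <- seq(n_sets * set_size + 1, n_genes)
    if (length(bg)) y[bg, ] <- e[bg, ]
    y <- y + amean
    rownames(y) <- sprintf("g%05d", seq_len(n_genes))
    colnames(y) <- paste0("s", seq_len(n_samples))
    list(m = expression_matrix(y, kind = "log_intensity"),
         sets = gene_set_collection(set_list))
  })
}
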