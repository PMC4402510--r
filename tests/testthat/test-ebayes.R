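test_that("fit_fdist recovers hyperparameters and handles degenerate input", {
  set.seed(1)
  n_genes <- 20000; d0 <- 4; s0 <- 0.05; df <- 6
  sigma2 <- d0 * s0 / stats::rchisq(n_genes, d0)
  s2 <- sigma2 * stats::rchisq(n_genes, df) / df
  prior <- fit_fdist(s2, df)
  expect_lt(abs(prior$df_prior / d0 - 1), 0.15)
  expect_lt(abs(prior$s2_prior / s0 - 1), 0.05)
  # identical variances: no excess spread, infinite prior df
  flat <- fit_fdist(rep(2, 100), 6)
  expect_identical(flat$df_prior, Inf)
  expect_equal(flat$s2_prior,
               exp(log(2) - digamma(3) + log(3)))
  # genes with zero df are excluded without affecting the estimates
  with_junk <- fit_fdist(c(s2, rep(1e6, 50)), c(rep(df, n_genes), rep(0, 50)))
  expect_equal(with_junk$df_prior, prior$df_prior)
  expect_equal(with_junk$s2_prior, prior$s2_prior)
})

test_that("fit_fdist matches the reference moment estimator", {
  set.seed(2)
  s2 <- 0.05 * 6 / stats::rchisq(3000, 6) * stats::rchisq(3000, 4) / 4
  mine <- fit_fdist(s2, 4)
  ref <- limma::fitFDist(s2, df1 = 4)
  expect_equal(mine$df_prior, ref$df2, tolerance = 1e-6)
  expect_equal(mine$s2_prior, ref$scale, tolerance = 1e-6)
})

test_that("squeeze_var interpolates between sample and prior variances", {
  pr <- function(d0, s0) structure(list(df_prior = d0, s2_prior = s0),
                                   class = "FDistPrior")
  expect_equal(squeeze_var(2, 4, pr(4, 1)), 1.5)  # (4*1 + 4*2) / 8
  s2 <- c(0.3, 1.7, 4)
  expect_equal(squeeze_var(s2, 6, pr(0, 1)), s2)
  expect_equal(squeeze_var(s2, 6, pr(Inf, 1)), rep(1, 3))
  out <- squeeze_var(s2, 6, pr(3, 1))
  expect_true(all(out >= pmin(s2, 1) & out <= pmax(s2, 1)))
})

test_that("moderated statistics reproduce the hand-computed example", {
  # gene of interest: beta = 1, u = 0.5, sigma = 1, df = 4 with prior
  # d0 = 4, s0^2 = 1 -> s2_post = 1, t = 2 on 8 df
  fit <- structure(list(
    coefficients = matrix(c(1, 0.5, -0.2), 3, 1,
                          dimnames = list(paste0("g", 1:3), "c1")),
    stdev_unscaled = matrix(0.5, 3, 1),
    sigma = c(1, 1.2, 0.9), df_residual = rep(4, 3),
    amean = rep(5, 3), coef_cov = matrix(0.25),
    gene_ids = paste0("g", 1:3), coef_names = "c1"), class = "LinearFit")
  mod <- moderated_stats(fit, prior = structure(
    list(df_prior = 4, s2_prior = 1), class = "FDistPrior"))
  expect_equal(unname(mod$s2_post[1]), 1)
  expect_equal(unname(mod$t[1, 1]), 2)
  expect_equal(unname(mod$df_total[1]), 8)
  expect_equal(unname(mod$p_value[1, 1]), 2 * stats::pt(-2, 8))
  # single contrast: F = t^2 with identical p-value
  expect_equal(mod$F, unname(mod$t[, 1]^2), tolerance = 1e-12)
  expect_equal(mod$F_p, unname(mod$p_value[, 1]), tolerance = 1e-12)
})

test_that("a zero prior df reduces moderated t to the classical t exactly", {
  sim <- sim_log_matrix(200, two_group_design(), de_fraction = 0.2, seed = 3)
  fit <- contrasts_fit(lm_fit(sim$m, two_group_design()), bva_contrast)
  mod <- moderated_stats(fit, prior = structure(
    list(df_prior = 0, s2_prior = 1), class = "FDistPrior"))
  t_classic <- fit$coefficients[, 1] / (fit$stdev_unscaled[, 1] * fit$sigma)
  p_classic <- 2 * stats::pt(-abs(t_classic), fit$df_residual)
  expect_equal(mod$t[, 1], t_classic, tolerance = 1e-12)
  expect_equal(mod$p_value[, 1], p_classic, tolerance = 1e-12)
})

test_that("moderation shrinks |t| exactly when the gene variance exceeds the prior", {
  sim <- sim_log_matrix(500, two_group_design(), de_fraction = 0.1, seed = 4)
  fit <- contrasts_fit(lm_fit(sim$m, two_group_design()), bva_contrast)
  mod <- moderated_stats(fit)
  t_classic <- fit$coefficients[, 1] / (fit$stdev_unscaled[, 1] * fit$sigma)
  up <- fit$sigma^2 > mod$s2_prior
  expect_true(all(abs(mod$t[up, 1]) >= abs(t_classic[up])))
  expect_true(all(abs(mod$t[!up, 1]) <= abs(t_classic[!up])))
})

test_that("moderated results agree with the reference eBayes pipeline", {
  sim <- sim_log_matrix(1000, two_group_design(), de_fraction = 0.1, seed = 5)
  mine <- moderated_two_group(sim, two_group_design())
  ref <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(sim$m$values, two_group_design()$design),
    bva_contrast))
  expect_equal(mine$df_prior, ref$df.prior, tolerance = 1e-8)
  expect_equal(mine$s2_prior, ref$s2.prior, tolerance = 1e-8)
  expect_equal(unname(mine$t[, 1]), unname(ref$t[, 1]), tolerance = 1e-8)
  expect_equal(unname(mine$p_value[, 1]), unname(ref$p.value[, 1]),
               tolerance = 1e-8)
  # trended prior: per-gene prior variances follow the reference closely
  simt <- sim_log_matrix(2000, two_group_design(), de_fraction = 0,
                         trend = TRUE, seed = 6)
  mt <- moderated_stats(contrasts_fit(lm_fit(simt$m, two_group_design()),
                                      bva_contrast), trend = TRUE)
  rt <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(simt$m$values, two_group_design()$design), bva_contrast),
    trend = TRUE)
  expect_gt(stats::cor(mt$s2_prior, rt$s2.prior), 0.99)
})

test_that("robust moderation leaves hypervariable genes unsqueezed", {
  sim <- sim_log_matrix(2000, two_group_design(), de_fraction = 0, seed = 7)
  y <- sim$m$values
  y[1:20, ] <- y[1:20, ] * 8  # inflate a block of outlier variances
  m <- expression_matrix(y, kind = "log_intensity")
  fit <- contrasts_fit(lm_fit(m, two_group_design()), bva_contrast)
  rob <- moderated_stats(fit, robust = TRUE)
  plain <- moderated_stats(fit)
  expect_true(is.numeric(rob$robust_df))
  shrink_rob <- abs(rob$s2_post[1:20] - fit$sigma[1:20]^2)
  shrink_plain <- abs(plain$s2_post[1:20] - fit$sigma[1:20]^2)
  expect_lt(mean(shrink_rob), mean(shrink_plain))
  expect_lt(mean(rob$robust_df[1:20], na.rm = TRUE), rob$df_prior)
})

test_that("treat tests a fold-change threshold with monotone p-values", {
  fit <- structure(list(
    coefficients = matrix(c(2, 1, 0.3), 3, 1,
                          dimnames = list(paste0("g", 1:3), "c1")),
    stdev_unscaled = matrix(0.5, 3, 1),
    sigma = rep(1, 3), df_residual = rep(4, 3), amean = rep(5, 3),
    coef_cov = matrix(0.25), gene_ids = paste0("g", 1:3),
    coef_names = "c1"), class = "LinearFit")
  mod <- moderated_stats(fit, prior = structure(
    list(df_prior = 4, s2_prior = 1), class = "FDistPrior"))
  tr0 <- treat(mod, 0)
  expect_equal(tr0$p_value, mod$p_value, tolerance = 1e-12)
  tr1 <- treat(mod, 1)
  # beta = 2, se = 0.5, df = 8, lfc = 1: p = P(T8 > 2) + P(T8 > 6)
  expect_equal(unname(tr1$p_value[1, 1]),
               stats::pt(2, 8, lower.tail = FALSE) +
                 stats::pt(6, 8, lower.tail = FALSE), tolerance = 1e-12)
  lfcs <- c(0, 0.5, 1, 2, 5, 20)
  pseq <- vapply(lfcs, function(l) treat(mod, l)$p_value[1, 1], 0)
  expect_true(all(diff(pseq) > 0))
  expect_gt(utils::tail(pseq, 1), 0.999)
  expect_true(all(treat(mod, 0.5)$p_value >= mod$p_value))
  expect_error(treat(mod, -1), "non-negative")
})

test_that("p-value adjustment matches step-up/step-down arithmetic", {
  expect_equal(p_adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_equal(p_adjust(c(0.01, 0.4), "bonferroni"), c(0.02, 0.8))
  for (meth in c("BH", "BY", "holm", "bonferroni")) {
    expect_equal(p_adjust(0.037, meth), 0.037)
  }
  # brute-force BH step-up oracle on a random vector
  set.seed(8)
  p <- stats::runif(37)^2
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  oracle <- pmin(1, cummin(n / (n:1) * p[o]))[order(o)]
  expect_equal(p_adjust(p, "BH"), oracle)
  expect_error(p_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("top tables sort, truncate and agree with decide_tests", {
  sim <- sim_log_matrix(300, two_group_design(), de_fraction = 0.3,
                        logfc_sd = 2, seed = 9)
  fit <- moderated_two_group(sim, two_group_design())
  tab <- top_table(fit, "BvA")
  expect_true(!is.unsorted(tab$p))
  expect_equal(nrow(top_table(fit, "BvA", number = 1e6)), 300)
  expect_equal(nrow(top_table(fit, "BvA", number = 7)), 7)
  tab_fc <- top_table(fit, "BvA", sort_by = "logFC")
  expect_true(!is.unsorted(-abs(tab_fc$logFC)))
  dt <- decide_tests(fit, p_threshold = 0.05)
  expect_equal(sum(tab$adj_p <= 0.05), sum(dt$codes != 0))
  expect_error(top_table(fit, "nope"), "unknown coefficient")
})

test_that("decide_tests classifies by sign and supports global adjustment", {
  sim <- sim_log_matrix(50, two_group_design(), de_fraction = 0.4,
                        logfc_sd = 2, seed = 10)
  d <- two_group_design()
  contr <- cbind(BvA = c(-1, 1), AvB = c(1, -1), Aonly = c(1, 0))
  fit <- moderated_stats(contrasts_fit(lm_fit(sim$m, d), contr))
  all_in <- decide_tests(fit, p_threshold = 1)
  expect_equal(all_in$codes, sign(fit$t), ignore_attr = TRUE)
  none <- decide_tests(fit, p_threshold = 1e-300)
  expect_true(all(none$codes[, "Aonly"] == 0 | fit$p_value[, "Aonly"] < 1e-300))
  # global adjustment equals a brute-force pooled step-up reshaped
  glob <- decide_tests(fit, method = "global", p_threshold = 0.05)
  pv <- as.vector(fit$p_value)
  n <- length(pv)
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n:1) * pv[o]))[order(o)]
  oracle <- matrix(adj <= 0.05, nrow(fit$p_value)) * sign(fit$t)
  expect_equal(unname(glob$codes), unname(oracle))
  expect_error(decide_tests(fit, p_threshold = 0), "p_threshold")
})

test_that("pi0 estimates behave on null, saturated and toy inputs", {
  set.seed(11)
  p_null <- stats::runif(10000)
  for (meth in c("lfdr", "mean", "hist", "convest")) {
    est <- prop_true_null(p_null, meth)
    expect_gte(est, 0.93)
    expect_lte(est, 1)
  }
  p_alt <- stats::runif(200, 0, 1e-6)
  for (meth in c("lfdr", "mean", "hist", "convest")) {
    expect_lt(prop_true_null(p_alt, meth), 0.05)
  }
  expect_equal(prop_true_null(c(0.1, 0.2, 0.3), "mean"), 0.4)
  expect_error(prop_true_null(numeric(0)), "no p-values")
  # mixture: estimates fall between the null fraction and 1
  p_mix <- c(stats::runif(1600), stats::rbeta(400, 0.2, 8))
  est_mix <- prop_true_null(p_mix, "convest")
  expect_gt(est_mix, 0.6)
  expect_lt(est_mix, 0.98)
})
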