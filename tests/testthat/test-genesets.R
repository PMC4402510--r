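test_that("rank-sum set test matches exhaustive enumeration of placements", {
  stats <- setNames(as.numeric(1:10), paste0("g", 1:10))
  # enumeration oracle: all C(10,2) placements of a 2-gene set
  combos <- utils::combn(10, 2)
  u_all <- apply(combos, 2, function(idx) sum(rank(stats)[idx]) - 3)
  u_obs <- sum(rank(stats)[9:10]) - 3
  p_oracle <- mean(u_all >= u_obs)
  expect_equal(p_oracle, 1 / 45)
  expect_equal(gene_set_test(stats, c("g9", "g10"), "up"), p_oracle)
  # one-gene set holding the largest statistic: p = 1/G
  expect_equal(gene_set_test(stats, "g10", "up"), 0.1)
  expect_equal(gene_set_test(stats, "g1", "down"), 0.1)
  expect_error(gene_set_test(stats, paste0("g", 1:10)), "strict subset")
})

test_that("rank-sum p-values are uniform for random sets of exchangeable stats", {
  set.seed(1)
  ps <- replicate(2000, {
    s <- stats::rnorm(100)
    gene_set_test(s, sample.int(100, 20), "up")
  })
  # a few p-values repeat across draws; the tie warning is immaterial here
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("exact and normal-approximation branches agree near the boundary", {
  set.seed(2)
  s <- stats::rnorm(60)
  idx <- sample.int(60, 10)           # exact branch (min group = 10)
  r <- rank(s)
  u <- sum(r[idx]) - 10 * 11 / 2
  mu <- 10 * 50 / 2
  v <- 10 * 50 * 61 / 12
  normal_p <- stats::pnorm((u - 0.5 - mu) / sqrt(v), lower.tail = FALSE)
  exact_p <- gene_set_test(s, idx, "up")
  expect_lt(abs(exact_p - normal_p), 0.01)
})

test_that("camera reports the variance inflation factor and BH adjustment", {
  d <- two_group_design(5)
  sim <- sim_log_matrix(200, d, de_fraction = 0, seed = 1)
  sets <- gene_set_collection(list(S10 = sim$truth$gene_id[1:10],
                                   S5 = sim$truth$gene_id[21:25]))
  cam <- camera(sim$m, sets, d, contrast = c(-1, 1), fixed_cor = 0.1)
  expect_equal(cam$vif[cam$set_name == "S10"], 1.9)  # 1 + 9 * 0.1
  expect_equal(cam$vif[cam$set_name == "S5"], 1.4)
  expect_true(all(cam$adj_p >= cam$p_value))
  expect_true(all(cam$p_value > 0 & cam$p_value <= 1))
})

test_that("camera with zero fixed correlation is the plain two-sample z test", {
  d <- two_group_design(5)
  sim <- sim_log_matrix(300, d, de_fraction = 0.1, seed = 2)
  sets <- gene_set_collection(list(S = sim$truth$gene_id[1:30]))
  cam <- camera(sim$m, sets, d, contrast = c(-1, 1), fixed_cor = 0)
  fit <- moderated_two_group(sim, d)
  z <- modlm:::zscore_t(fit$t[, 1], fit$df_total)
  idx <- 1:30
  delta <- mean(z[idx]) - mean(z[-idx])
  tt <- delta / sqrt(stats::var(z) * (1 / 30 + 1 / 270))
  expect_equal(cam$statistic, tt, tolerance = 1e-10)
  expect_equal(cam$p_value, 2 * stats::pt(-abs(tt), 298), tolerance = 1e-10)
})

test_that("camera's correlation estimate tracks the generating correlation", {
  cs <- sim_correlated_sets(n_genes = 1000, set_size = 50, n_sets = 5,
                            rho_within = 0.25, n_samples = 30, seed = 3)
  d <- design_spec(cbind(A = rep(c(1, 0), each = 15),
                         B = rep(c(0, 1), each = 15)))
  cam <- camera(cs$m, cs$sets, d, contrast = c(-1, 1))
  rho_hat <- (cam$vif - 1) / (cam$n_genes - 1)
  expect_lt(max(abs(rho_hat - 0.25)), 0.08)
})

test_that("roast p-values are granular, reproducible and bounded below", {
  d <- two_group_design()
  sim <- sim_log_matrix(400, d, de_fraction = 0, seed = 4)
  y <- sim$m$values
  y[1:20, 4:6] <- y[1:20, 4:6] + 5  # strongly DE set
  m <- expression_matrix(y, kind = "log_intensity")
  sets <- gene_set_collection(list(S = sim$truth$gene_id[1:20]))
  out <- roast(m, sets, d, contrast = c(-1, 1), nrot = 99, seed = 1,
               alternative = "up")
  expect_equal(out$p_value, 1 / 100)  # the plus-one lower bound
  out2 <- roast(m, sets, d, contrast = c(-1, 1), nrot = 99, seed = 1,
                alternative = "up")
  expect_identical(out, out2)
  out3 <- roast(m, sets, d, contrast = c(-1, 1), nrot = 99, seed = 2,
                alternative = "up")
  expect_equal(out3$p_value, out$p_value, tolerance = 0.05)
  expect_error(roast(m, sets, d, contrast = c(-1, 1), nrot = 0), "nrot")
})

test_that("roast respects direction and weight annotations", {
  d <- two_group_design()
  sim <- sim_log_matrix(300, d, de_fraction = 0, seed = 5)
  y <- sim$m$values
  up_genes <- sim$truth$gene_id[1:10]
  dn_genes <- sim$truth$gene_id[11:20]
  y[1:10, 4:6] <- y[1:10, 4:6] + 0.5
  y[11:20, 4:6] <- y[11:20, 4:6] - 0.5
  m <- expression_matrix(y, kind = "log_intensity")
  members <- c(up_genes, dn_genes)
  plain <- gene_set_collection(list(S = members))
  signed <- gene_set_collection(list(S = members),
                                directions = list(S = setNames(
                                  rep(c(1, -1), each = 10), members)))
  p_plain <- roast(m, plain, d, contrast = c(-1, 1), nrot = 199, seed = 1,
                   alternative = "up")$p_value
  p_signed <- roast(m, signed, d, contrast = c(-1, 1), nrot = 199, seed = 1,
                    alternative = "up")$p_value
  expect_gt(p_plain, 0.05)       # opposing halves cancel without annotation
  expect_equal(p_signed, 1 / 200)  # signs align the signature: floor p
})

test_that("set tests are invariant to gene order permutations", {
  d <- two_group_design()
  sim <- sim_log_matrix(200, d, de_fraction = 0.2, seed = 6)
  sets <- gene_set_collection(list(S = sim$truth$gene_id[5:40]))
  perm <- sample(200)
  m2 <- sim$m[perm, ]
  r1 <- roast(sim$m, sets, d, contrast = c(-1, 1), nrot = 99, seed = 3)
  r2 <- roast(m2, sets, d, contrast = c(-1, 1), nrot = 99, seed = 3)
  expect_equal(r1$p_value, r2$p_value)
  c1 <- camera(sim$m, sets, d, contrast = c(-1, 1))
  c2 <- camera(m2, sets, d, contrast = c(-1, 1))
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-10)
})

test_that("mroast shares the rotation stream and adjusts across sets", {
  d <- two_group_design()
  sim <- sim_log_matrix(300, d, de_fraction = 0, seed = 7)
  ids <- sim$truth$gene_id
  sets <- gene_set_collection(list(S1 = ids[1:20], S2 = ids[21:40],
                                   S3 = ids[41:60]))
  one <- roast(sim$m, gene_set_collection(list(S1 = ids[1:20])), d,
               contrast = c(-1, 1), nrot = 99, seed = 9)
  many <- mroast(sim$m, sets, d, contrast = c(-1, 1), nrot = 99, seed = 9)
  expect_equal(many$p_value[1], one$p_value)
  expect_true(all(many$adj_p >= many$p_value))
})

test_that("romer is deterministic and guards degenerate inputs", {
  d <- two_group_design()
  sim <- sim_log_matrix(300, d, de_fraction = 0, seed = 8)
  ids <- sim$truth$gene_id
  sets <- gene_set_collection(list(S1 = ids[1:25], S2 = ids[26:50]))
  r1 <- romer(sim$m, sets, d, contrast = c(-1, 1), nrot = 199, seed = 4)
  r2 <- romer(sim$m, sets, d, contrast = c(-1, 1), nrot = 199, seed = 4)
  expect_identical(r1, r2)
  expect_true(all(r1$p_up > 0 & r1$p_up <= 1))
  all_genes <- gene_set_collection(list(ALL = ids))
  expect_error(romer(sim$m, all_genes, d, contrast = c(-1, 1), nrot = 9),
               "every gene")
  # saturated design: no residual space to rotate in
  sat <- design_spec(diag(6))
  expect_error(romer(sim$m, sets, sat, contrast = 6, nrot = 9),
               "residual df")
})

test_that("hypergeometric enrichment matches the combinatorial oracle", {
  universe <- paste0("u", 1:100)
  de <- paste0("u", c(1:5, 21:35))  # 20 DE genes, 5 in the set
  sets <- gene_set_collection(list(S = paste0("u", 1:10),
                                   MISS = paste0("u", 91:95),
                                   ALL = universe))
  tab <- enrich_overlap(de, universe, sets)
  oracle <- sum(vapply(5:10, function(k)
    choose(20, k) * choose(80, 10 - k), 0)) / choose(100, 10)
  expect_equal(tab$p_value[tab$set_name == "S"], oracle)
  expect_equal(tab$overlap[tab$set_name == "S"], 5)
  # zero overlap: the upper tail includes k = 0, so p = 1
  expect_equal(tab$p_value[tab$set_name == "MISS"], 1)
  # set = universe: overlap = |DE| and p = 1
  expect_equal(tab$overlap[tab$set_name == "ALL"], 20)
  expect_equal(tab$p_value[tab$set_name == "ALL"], 1)
  expect_error(enrich_overlap(de, character(0), sets), "empty universe")
  expect_error(enrich_overlap("zz", universe, sets), "subset")
})

test_that("barcode profiles locate a top-ranked set and stay near 1 for noise", {
  set.seed(9)
  stats <- setNames(sort(stats::rnorm(2000), decreasing = TRUE),
                    paste0("g", 1:2000))
  top <- barcode_profile(stats, paste0("g", 1:50))
  expect_equal(top$positions, 1:50)
  expect_gt(max(top$enrichment[1:100]), 1)
  expect_equal(which.max(top$enrichment), 1)
  rnd_idx <- sample(2000, 100)
  rnd <- barcode_profile(stats, rnd_idx)
  expect_equal(rnd$positions, sort(rank(-stats)[rnd_idx]),
               ignore_attr = TRUE)
  expect_gt(mean(rnd$enrichment > 0.5 & rnd$enrichment < 2), 0.95)
  # directional split
  dirs <- setNames(rep(c(1, -1), each = 25), paste0("g", c(1:25, 1976:2000)))
  split <- barcode_profile(stats, paste0("g", c(1:25, 1976:2000)),
                           directions = dirs)
  expect_equal(split$positions_up, 1:25)
  expect_equal(split$positions_down, 1976:2000)
})
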