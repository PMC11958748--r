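test_that("t_statistic evaluates the pooled formula", {
  # (1,2,3) vs (4,5,6): pooled variance 1, t = 3 / sqrt(2/3)
  expect_equal(t_statistic(c(1, 2, 3), c(4, 5, 6)), 3 / sqrt(2 / 3))
  expect_identical(t_statistic(c(2, 4, 6), c(2, 4, 6)), 0)
  # floor contract: constant, different groups stay finite
  expect_equal(t_statistic(c(0, 0, 0), c(5, 5, 5), variance_floor = 1e-8),
               5 / sqrt(1e-8 * 2 / 3))
  expect_error(t_statistic(1, c(1, 2)), "at least 2")
})

test_that("t_statistic agrees with stats::t.test on random data", {
  set.seed(1)
  for (i in 1:25) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1), mean = 1)
    expect_equal(t_statistic(a, b),
                 unname(t.test(b, a, var.equal = TRUE)$statistic))
    expect_equal(t_statistic(a, b, welch = TRUE),
                 unname(t.test(b, a)$statistic))
  }
})

test_that("exhaustive null enumerates every distinct assignment", {
  s <- sim_norm(n_genes = 40, seed = 10, frac_de = 0, frac_silent = 0)
  null <- build_null(s$norm, de_config(permutation_scheme = "exhaustive"))
  expect_identical(null$n_permutations, 20L)   # choose(6, 3) for 3 vs 3
  expect_length(null$pooled_abs_t, 40L * 20L)
  expect_false(is.unsorted(null$pooled_abs_t))
  expect_true(all(null$pooled_abs_t >= 0))
  # the identity assignment is enumerated, so every observed |t| is in the pool
  tt <- permDE:::.row_t(s$norm$values, which(s$norm$groups == "control"),
                        which(s$norm$groups == "treated"))
  expect_true(all(abs(tt) %in% null$pooled_abs_t))
})

test_that("sampled null is reproducible for a fixed seed", {
  s <- sim_norm(n_genes = 50, seed = 4, frac_silent = 0)
  cfg <- de_config(n_permutations = 50, seed = 99)
  expect_identical(build_null(s$norm, cfg)$pooled_abs_t,
                   build_null(s$norm, cfg)$pooled_abs_t)
  expect_error(build_null(s$norm, de_config(n_permutations = 0)),
               "n_permutations")
})

test_that("signed permutation t pooled over a global-null matrix is centred", {
  # Monte Carlo symmetry check: mean of signed pooled t within 3 SEs of 0
  s <- sim_norm(n_genes = 5000, seed = 21, frac_de = 0, frac_silent = 0)
  set.seed(33)
  vals <- s$norm$values
  signed <- replicate(100, {
    p <- sample(6)
    permDE:::.row_t(vals, p[1:3], p[4:6])
  })
  expect_lt(abs(mean(signed)), 3 * sd(signed) / sqrt(length(signed)))
})

test_that("empirical p-values follow the add-one exceedance rule", {
  null9 <- structure(list(pooled_abs_t = sort(c(0.1, 0.4, 0.6, 1.1, 1.5,
                                                2.0, 2.5, 3.0, 3.2)),
                          n_permutations = 1L, permutation_scheme = "sampled",
                          seed = 1L), class = "null_distribution")
  # 3 of 9 null values >= 2.1 -> p = (1+3)/(1+9)
  expect_equal(empirical_pvalue(2.1, null9), 4 / 10)
  expect_equal(empirical_pvalue(0, null9), 1)                 # all values >= 0
  expect_equal(empirical_pvalue(10, null9), 1 / 10)           # beyond the max
  expect_equal(empirical_pvalue(-2.1, null9), 4 / 10)         # two-sided in |t|
  expect_equal(empirical_pvalue(2.0, null9), 5 / 10)          # ties count as >=

  # brute-force counting on random nulls, including exact ties
  set.seed(8)
  for (i in 1:10) {
    v <- sort(round(abs(rnorm(200)), 2))
    nd <- structure(list(pooled_abs_t = v, n_permutations = 1L,
                         permutation_scheme = "sampled", seed = 1L),
                    class = "null_distribution")
    t0 <- c(sample(v, 3), abs(rnorm(3)))
    expect_equal(empirical_pvalue(t0, nd),
                 sapply(t0, function(t1) (1 + sum(v >= abs(t1))) / (1 + length(v))))
  }
})

test_that("empirical p is monotone non-increasing in |t|", {
  s <- sim_norm(n_genes = 100, seed = 14, frac_silent = 0)
  null <- build_null(s$norm, de_config(n_permutations = 100, seed = 2))
  ts <- seq(0, 6, by = 0.25)
  p <- empirical_pvalue(ts, null)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p > 0 & p <= 1))
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(0.2, 5)), rep(0.2, 5))  # BH fixed point
  expect_equal(adjust_pvalues(0.7), 0.7)                  # m = 1
  set.seed(5)
  for (i in 1:10) {
    p <- runif(sample(1:50, 1))
    adj <- adjust_pvalues(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
  }
  expect_error(adjust_pvalues(c(0.5, 0)), "0, 1")
  expect_error(adjust_pvalues(numeric()), "empty")
})

test_that("fc_cutoff honours both modes", {
  cfg_fixed <- de_config(fc_cutoff_mode = "fixed")
  expect_identical(fc_cutoff(rnorm(100), cfg_fixed), 0.336)
  cfg_pct <- de_config(fc_cutoff_mode = "percentile", fc_percentile = 0.95)
  expect_equal(fc_cutoff(rep(0.7, 50), cfg_pct), 0.7)  # constant distribution
  expect_equal(fc_cutoff(1:100, cfg_pct), quantile7_oracle(1:100, 0.95))
  set.seed(31)
  x <- rnorm(137)
  expect_equal(fc_cutoff(x, cfg_pct), quantile7_oracle(abs(x), 0.95))
})

test_that("call_degs output satisfies the DEG-table contract", {
  s <- sim_norm(n_genes = 400, seed = 16, frac_de = 0.1,
                effect_size_log2 = 2, frac_silent = 0.1)
  cfg <- de_config(n_permutations = 300, seed = 7)
  degs <- call_degs(s$norm, cfg)
  cut <- attr(degs, "fc_cutoff")
  expect_identical(nrow(degs), nrow(s$norm$values))
  expect_identical(degs$is_deg,
                   degs$p_adj < cfg$alpha_adj & abs(degs$log2fc) > cut)
  expect_identical(degs$direction == "up", degs$is_deg & degs$log2fc > 0)
  expect_identical(degs$direction == "down", degs$is_deg & degs$log2fc < 0)
  expect_true(all(degs$p_emp > 0 & degs$p_emp <= 1))
  expect_true(all(degs$p_adj >= degs$p_emp))
  expect_false(is.unsorted(degs$p_adj))
  expect_equal(degs$log2fc, degs$mean_treated - degs$mean_control)
  expect_identical(attr(degs, "n_up") + attr(degs, "n_down"),
                   sum(degs$is_deg))
  # unnormalized input is refused
  raw <- log_transform(filter_expressed(s$fpkm))
  expect_error(call_degs(raw, cfg), "quantile-normalized")
})

test_that("duplicated gene rows receive identical statistics", {
  s <- sim_norm(n_genes = 60, seed = 23, frac_silent = 0)
  v <- s$norm$values
  v <- rbind(v, dup = v[1, ])
  rownames(v) <- c(rownames(s$norm$values), "gene_dup")
  m <- as_norm(v, as.character(s$norm$groups))
  degs <- call_degs(m, de_config(n_permutations = 100, seed = 3))
  a <- degs[degs$gene_id == rownames(v)[1], -1]
  b <- degs[degs$gene_id == "gene_dup", -1]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("sample column order does not change the result", {
  s <- sim_norm(n_genes = 80, seed = 27, frac_silent = 0)
  cfg <- de_config(n_permutations = 200, seed = 12)
  ref <- call_degs(s$norm, cfg)
  perm <- sample(ncol(s$norm$values))
  shuffled <- as_norm(s$norm$values[, perm],
                      as.character(s$norm$groups)[perm])
  expect_identical(call_degs(shuffled, cfg), ref)
})

test_that("called DEGs match their planted sign and power grows with effect", {
  sens <- sapply(c(0.5, 1, 2), function(es) {
    s <- sim_norm(n_genes = 600, seed = 31, frac_de = 0.1,
                  effect_size_log2 = es, frac_silent = 0)
    degs <- call_degs(s$norm, de_config(n_permutations = 300, seed = 9,
                                        fc_cutoff_mode = "fixed"))
    called <- degs$gene_id[degs$is_deg]
    truth <- s$truth[match(called, s$truth$gene_id), ]
    lfc <- degs$log2fc[degs$is_deg]
    true_pos <- truth$is_de
    # every true-positive call has the planted direction
    expect_true(all(sign(lfc[true_pos]) ==
                      sign(truth$planted_effect_log2[true_pos])))
    mean(s$truth$gene_id[s$truth$is_de] %in% called)
  })
  expect_true(all(diff(sens) >= 0))
})

test_that("sampled and exhaustive nulls give matching p-values", {
  s <- sim_norm(n_genes = 100, seed = 35, frac_silent = 0)
  tt <- permDE:::.row_t(s$norm$values, which(s$norm$groups == "control"),
                        which(s$norm$groups == "treated"))
  p_ex <- empirical_pvalue(tt, build_null(s$norm,
    de_config(permutation_scheme = "exhaustive")))
  p_sa <- empirical_pvalue(tt, build_null(s$norm,
    de_config(n_permutations = 1000, seed = 17)))
  expect_lt(max(abs(p_ex - p_sa)), 0.02)
})

test_that("the permutation-FDR adjustment is a valid alternative", {
  s <- sim_norm(n_genes = 300, seed = 39, frac_de = 0.1, frac_silent = 0)
  degs <- call_degs(s$norm, de_config(n_permutations = 200, seed = 5,
                                      adjust_method = "perm_fdr"))
  expect_true(all(degs$p_adj > 0 & degs$p_adj <= 1))
  # monotone: more extreme statistics never get a larger estimate
  o <- order(abs(degs$t_stat), decreasing = TRUE)
  expect_true(all(diff(degs$p_adj[o]) >= 0))
})
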