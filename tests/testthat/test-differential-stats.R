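test_that("weighted t-type test honors its null identities", {
  # identical proportions in both groups
  r <- weighted_t_test(c(10, 10, 10), rep(1000, 3), c(10, 10, 10), rep(1000, 3))
  expect_equal(r[["statistic"]], 0)
  expect_equal(r[["p_value"]], 1)
  # proportion invariance: scaling counts and totals together changes nothing
  r2 <- weighted_t_test(rep(100, 3), rep(1e4, 3), rep(200, 3), rep(2e4, 3))
  expect_equal(r2[["statistic"]], 0)
  expect_equal(r2[["p_value"]], 1)
  # all-zero counts
  r3 <- weighted_t_test(c(0, 0), c(10, 10), c(0, 0, 0), c(5, 5, 5))
  expect_equal(r3[["statistic"]], 0)
  expect_equal(r3[["p_value"]], 1)
  expect_error(weighted_t_test(1, 10, c(1, 2), c(10, 10)), "2 replicates")
  expect_error(weighted_t_test(c(11, 1), c(10, 10), c(1, 2), c(10, 10)),
               "count <= total")
  # a clear difference is detected
  r4 <- weighted_t_test(c(100, 110, 90), rep(1e4, 3), c(11, 9, 10), rep(1e4, 3))
  expect_lt(r4[["p_value"]], 0.01)
})

test_that("weighted test reduces to Welch when replicate scatter dominates", {
  set.seed(11)
  for (i in 1:5) {
    mu <- runif(1, 5e3, 2e4)
    x_a <- round(mu * rlnorm(3, 0, 0.3)); n_a <- rep(1e5, 3)
    x_b <- round(mu * rlnorm(3, 0.2, 0.3)); n_b <- rep(1e5, 3)
    r <- weighted_t_test(x_a, n_a, x_b, n_b)
    w <- t.test(x_a / n_a, x_b / n_b)
    expect_equal(r[["statistic"]], unname(w$statistic), tolerance = 0.05)
  }
})

test_that("weighted test p-values rank like a permutation oracle", {
  set.seed(12)
  n_inst <- 20
  p_wtt <- p_perm <- numeric(n_inst)
  for (i in seq_len(n_inst)) {
    tot <- round(runif(6, 8e3, 1.2e4))
    shift <- sample(c(1, 1.3, 1.7, 2.5), 1)
    mu <- runif(1, 100, 500)
    x <- rpois(6, mu * c(1, 1, 1, shift, shift, shift) * (tot / 1e4))
    p_wtt[i] <- weighted_t_test(x[1:3], tot[1:3], x[4:6], tot[4:6])[["p_value"]]
    # permutation oracle: all 20 group relabelings, difference of mean
    # proportions as the statistic
    pr <- x / tot
    obs <- abs(mean(pr[1:3]) - mean(pr[4:6]))
    splits <- combn(6, 3)
    stat_perm <- apply(splits, 2, function(ix) {
      abs(mean(pr[ix]) - mean(pr[-ix]))
    })
    p_perm[i] <- mean(stat_perm >= obs - 1e-15)
  }
  expect_gt(cor(rank(p_wtt), rank(p_perm), method = "spearman"), 0.7)
})

test_that("TE Student test matches its closed form and is symmetric", {
  expect_equal(te_student_test(c(2, 2, 2), c(2, 2, 2)), 1)
  set.seed(3)
  a <- c(1, 1, 1) * exp(rnorm(3, 0, 0.01))
  b <- c(4, 4, 4) * exp(rnorm(3, 0, 0.01))
  p <- te_student_test(a, b)
  expect_lt(p, 0.01)
  expect_equal(te_student_test(b, a), p)
  # closed-form pooled-variance t on log2 values
  la <- log2(a); lb <- log2(b)
  sp2 <- (2 * var(la) + 2 * var(lb)) / 4
  tstat <- (mean(la) - mean(lb)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(p, 2 * pt(-abs(tstat), 4), tolerance = 1e-12)
  expect_error(te_student_test(1, c(1, 2)), "2 replicates")
  expect_error(te_student_test(c(0, 1, 2), c(1, 1, 1)), "log scale")
})

test_that("the two-criteria regulation caller needs fold, TE p, and ribo p", {
  expect_false(call_translational_regulation(3.0, 0.01, 0.2))
  expect_true(call_translational_regulation(3.0, 0.01, 0.01))
  expect_false(call_translational_regulation(1.9, 0.001, 0.001))
  # direction of the footprint change matters when supplied
  expect_false(call_translational_regulation(3.0, 0.01, 0.01, ribo_fc = 0.4))
  expect_true(call_translational_regulation(3.0, 0.01, 0.01, ribo_fc = 2.5))
})

test_that("threshold differential calls mirror under reciprocal fold change", {
  expect_equal(call_differential(4, 0.01), "up")
  expect_equal(call_differential(4, 0.2), "none")
  expect_equal(call_differential(0.2, 0.01), "down")
  expect_error(call_differential(-1, 0.01), "> 0")
  set.seed(4)
  fc <- exp(runif(50, -3, 3)); p <- runif(50)
  a <- call_differential(fc, p)
  b <- call_differential(1 / fc, p)
  expect_equal(a == "up", b == "down")
  expect_equal(a == "down", b == "up")
  # configurable cutoffs
  expect_equal(call_differential(1.6, 0.01, fold_min = 1.5), "up")
  expect_equal(call_differential(1.6, 0.01, fold_min = 2), "none")
})

test_that("global shift is null on identical inputs and detects a shift", {
  set.seed(5)
  expr <- setNames(rlnorm(200, 3, 1), sprintf("g%03d", 1:200))
  idn <- global_shift(expr, expr, expr, expr)
  expect_equal(idn$mean_fc, 1)
  expect_equal(idn$ks_D, 0)
  noisy <- expr * rlnorm(200, 0, 0.1)
  up <- expr * 2 * rlnorm(200, 0, 0.1)
  det <- global_shift(up, expr, noisy, expr)
  expect_gt(det$mean_fc, 1.8)
  expect_lt(det$ks_p, 1e-6)
  expect_error(global_shift(expr, setNames(1, "zzz"), expr, expr), "shared")
  expect_warning(global_shift(expr[1:10], expr[1:10], expr, expr), "unstable")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # from-scratch step-up evaluation as independent oracle
  set.seed(6)
  for (i in 1:5) {
    p <- runif(25)
    m <- length(p)
    ord <- order(p)
    stepup <- numeric(m)
    running <- 1
    for (k in m:1) {
      running <- min(running, m / k * p[ord[k]])
      stepup[ord[k]] <- running
    }
    adj <- bh_adjust(p)
    expect_equal(adj, stepup, tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(!is.unsorted(adj[ord]))
  }
})

test_that("the ddCt utility converts cycle differences to fold changes", {
  expect_equal(ddct_fold_change(20, 15, 22, 17), 1)
  expect_equal(ddct_fold_change(21, 15, 20, 15), 0.5)
  expect_equal(ddct_fold_change(19, 15, 20, 15), 2)
})

test_that("differential_table tests detected genes and flags strong changes", {
  cfg <- small_config(seed = 41, n_genes = 40, library_size = 4e4)
  tr <- generate_transcriptome(cfg)
  ann <- annotation_of(tr)
  boost <- genotype_spec("boost", boosted_te_genes = tr$gene_id[1:4],
                         boosted_te_factor = 6)
  tab_wt <- count_reads(simulate_reads(tr, cfg, "footprint", "WT"), ann)
  tab_b <- count_reads(simulate_reads(tr, cfg, "footprint", boost), ann)
  dt <- differential_table(tab_b, tab_wt, "footprint", fold_min = 3)
  expect_true(all(dt$p_value >= 0 & dt$p_value <= 1))
  hits <- dt$gene_id[dt$call == "up"]
  expect_true(all(hits %in% tr$gene_id[1:4]))
  expect_gte(length(hits), 2)
  expect_true(all(dt$call[dt$gene_id %in% setdiff(dt$gene_id, tr$gene_id[1:4])]
                  %in% c("none", "down")))
})
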