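test_that("fold change follows the linear-scale group-mean definition", {
  expect_equal(fold_change(c(2, 2, 2), c(2, 2, 2))$direction, "none")
  fc <- fold_change(c(2, 2, 2), c(4, 4, 4))
  expect_equal(fc$fc, 2)
  expect_equal(fc$log2fc, 1)
  expect_equal(fc$direction, "up")
  down <- fold_change(c(4, 4), c(1, 1))
  expect_equal(down$fc, 0.25)
  expect_equal(down$n_fold, 4)        # reported as 4-fold down
  expect_equal(down$direction, "down")
  expect_error(fold_change(numeric(), 1:3), "empty")
})

test_that("Welch test matches the t-distribution oracle and handles degeneracy", {
  res <- two_group_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, 3.674, tolerance = 1e-3)
  expect_equal(res$df, 4, tolerance = 1e-6)
  expect_equal(res$p, 2 * pt(-abs(res$t), res$df))
  # agrees with stats::t.test when variances are healthy
  withr::with_seed(8, {
    for (i in 1:20) {
      a <- rnorm(4); b <- rnorm(5, 1)
      ours <- two_group_test(a, b)
      ref <- t.test(b, a, var.equal = FALSE)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-6)
    }
  })
  ident <- two_group_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(ident$t, 0)
  expect_equal(ident$p, 1)
  expect_error(two_group_test(1, c(1, 2)), "at least 2")
})

test_that("BH adjustment equals the direct step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(1, {
    for (i in 1:50) {
      p <- runif(sample(1:10, 1))
      expect_equal(bh_fdr(p), bh_stepup_oracle(p))
    }
  })
})

test_that("call_differential flags exactly the planted genes on a clean fixture", {
  de <- tibble::tibble(class = "mrna", gene_id = c("mrna_0002", "mrna_0007"),
                       contrast = "B", direction = c("up", "down"), log2fc = 3)
  cfg <- sim_config(n_per_group = 4, n_mirna = 4, n_lncrna = 4, n_mrna = 10,
                    noise_sd = 0.1, de_spec = de, seed = 31)
  sim <- simulate_expression(cfg)
  tab <- call_differential(sim$mrna, ref = "A", test = "B",
                           thresholds = de_thresholds("mrna"))
  expect_equal(sort(tab$gene_id[tab$significant]),
               c("mrna_0002", "mrna_0007"))
  expect_equal(tab$direction[tab$gene_id == "mrna_0002"], "up")
  expect_equal(tab$direction[tab$gene_id == "mrna_0007"], "down")
  g <- glance(tab)
  expect_equal(g$n_up + g$n_down, g$n_significant)
  expect_equal(g$n_significant, 2L)
})

test_that("significant set shrinks as thresholds tighten", {
  cfg <- demo_config(seed = 3)
  sim <- simulate_expression(cfg)
  base <- call_differential(sim$lncrna, thresholds = de_thresholds("lncrna"))
  for (fc_min in c(2.5, 3, 4)) {
    tighter <- call_differential(sim$lncrna,
                                 thresholds = de_thresholds("lncrna", fc_min = fc_min))
    expect_true(all(tighter$significant <= base$significant))
  }
  low_p <- call_differential(sim$lncrna,
                             thresholds = de_thresholds("lncrna", p_max = 0.01))
  expect_true(all(low_p$significant <= base$significant))
})

test_that("class default thresholds are fc 1.5 for miRNA and 2.0 otherwise", {
  expect_equal(de_thresholds("mirna")$fc_min, 1.5)
  expect_equal(de_thresholds("lncrna")$fc_min, 2.0)
  expect_equal(de_thresholds("mrna")$fc_min, 2.0)
  expect_equal(de_thresholds("mirna")$p_max, 0.05)
  expect_error(de_thresholds("mrna", fc_min = 0.9), "exceed 1")
})

test_that("empty gene list yields an empty DE table", {
  x <- expr_fixture(matrix(numeric(), nrow = 0, ncol = 4,
                           dimnames = list(NULL, paste0("s", 1:4))),
                    groups = c("A", "A", "B", "B"))
  tab <- call_differential(x)
  expect_equal(nrow(tab), 0)
})

test_that("hierarchical clustering merges identical profiles first at height 0", {
  m <- 2^rbind(g1 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1), g3 = c(1, 2, 3, 4) + 1)
  hc <- hierarchical_cluster(expr_fixture(m))
  # g1 and g3 are perfectly correlated (distance 0) and merge first
  expect_equal(sort(hc$merge[1, ]), c(-3, -1))
  expect_equal(hc$height[1], 0)
  # 3-leaf brute force: second height is the average of the remaining distances
  d <- as.matrix(1 - cor(t(log2(m))))
  expect_equal(hc$height[2], mean(c(d["g1", "g2"], d["g3", "g2"])))
  expect_error(hierarchical_cluster(expr_fixture(rbind(c(1, 1, 1), c(1, 2, 3)))),
               "zero-variance")
})

test_that("ddCt relative expression matches hand arithmetic and inverts on swap", {
  treated <- list(ct_target = 20, ct_reference = 15)
  control <- list(ct_target = 22, ct_reference = 15)
  expect_equal(ddct_fold_change(treated, control), 4)
  expect_equal(ddct_fold_change(control, treated), 1 / 4)
  expect_equal(ddct_fold_change(control, control), 1)
  expect_error(ddct_fold_change(list(ct_target = NA, ct_reference = 15), control),
               "finite")
})
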