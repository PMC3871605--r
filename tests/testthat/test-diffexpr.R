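toy_design <- function(m) {
  data.frame(sample = colnames(m),
             condition = ifelse(startsWith(colnames(m), "a"), "A", "B"),
             stringsAsFactors = FALSE)
}

test_that("log2 fold change is the difference of condition means", {
  m <- matrix(c(8, 8, 10, 10,
                5, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("a1", "a2", "b1", "b2")))
  d <- toy_design(m)
  lfc <- log2_fold_change(m, d)
  expect_equal(unname(lfc), c(2, 0))
  expect_equal(unname(2^abs(lfc)), c(4, 1))
  expect_error(log2_fold_change(m, d[d$condition == "A", ]), "two condition")
})

test_that("planted effects are recovered exactly when noiseless", {
  cfg <- simulation_config(seed = 2, n_genes = 80, de_fraction = 0.1,
                           de_log2fc = 2, noise_sd = 0)
  sim <- generate_dataset(cfg)
  lfc <- log2_fold_change(sim$matrix, sim$design)
  expect_equal(unname(lfc[sim$truth$de_genes$gene]),
               sim$truth$de_genes$log2fc, tolerance = 1e-12)
  expect_equal(unname(lfc[setdiff(names(lfc), sim$truth$de_genes$gene)]),
               rep(0, 72), tolerance = 1e-12)
})

test_that("the per-gene test behaves at its boundary cases and is label-symmetric", {
  m <- matrix(c(3, 3, 3, 3, 3, 3, 3,
                1, 1, 1, 2, 2, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("flat", "sep"),
                              c("a1", "a2", "a3", "b1", "b2", "b3", "b4")))
  d <- toy_design(m)
  p <- test_differential(m, d)
  expect_equal(unname(p["flat"]), 1)  # identical groups, no variance
  expect_equal(unname(p["sep"]), 0)   # exact noiseless separation

  set.seed(9)
  mr <- matrix(rnorm(10 * 7), 10, 7,
               dimnames = list(paste0("g", 1:10), colnames(m)))
  d2 <- d
  d2$condition <- ifelse(d$condition == "A", "B", "A")
  expect_equal(test_differential(mr, d), test_differential(mr, d2))

  # agrees with t.test's Welch p-value on ordinary data
  pref <- apply(mr, 1, function(x) {
    t.test(x[d$condition == "B"], x[d$condition == "A"])$p.value
  })
  expect_equal(unname(test_differential(mr, d)), unname(pref),
               tolerance = 1e-12)
  expect_error(test_differential(mr[, c(1, 4:7)],
                                 toy_design(mr[, c(1, 4:7)])), ">= 2 samples")
})

test_that("planted signal gives tiny p-values against quiet noise", {
  cfg <- simulation_config(seed = 21, n_genes = 200, de_fraction = 0.1,
                           de_log2fc = 2, noise_sd = 0.01)
  sim <- generate_dataset(cfg)
  p <- test_differential(sim$matrix, sim$design)
  expect_true(all(p[sim$truth$de_genes$gene] < 1e-3))
})

test_that("BH adjustment matches a step-up oracle and honours its contract", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(4)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    adj <- adjust_fdr(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("selection applies the fold-change and FDR gates jointly", {
  rec <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                    log2fc = c(2, 0.9, -2, 1.5),
                    fold_change = c(4, 1.9, 4, 2.8),
                    p_raw = c(0.001, 0.0001, 0.2, 0.004),
                    fdr = c(0.01, 0.001, 0.3, 0.04),
                    direction = c("up", "down", "down", "up"))
  out <- select_degs(rec)
  expect_equal(out$selected, c(TRUE, FALSE, FALSE, TRUE))
  out2 <- select_degs(rec, p_threshold = 0.002)
  expect_equal(out2$selected, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("a full synthetic run recovers the planted up/down split", {
  cfg <- simulation_config(seed = 13, n_genes = 2000, de_fraction = 0.075,
                           de_log2fc = 2, noise_sd = 0.05)
  sim <- generate_dataset(cfg)
  deg <- differential_expression(sim$matrix, sim$design)
  sel <- deg[deg$selected, ]
  expect_setequal(sel$gene, sim$truth$de_genes$gene)
  truth_dir <- ifelse(sim$truth$de_genes$log2fc > 0, "up", "down")
  expect_equal(sel$direction[match(sim$truth$de_genes$gene, sel$gene)],
               truth_dir)
})

test_that("2^-ddCt relative quantification follows the formula", {
  expect_equal(ddct_fold_change(20, 15, 20, 15), 1)
  expect_equal(ddct_fold_change(19, 15, 20, 15), 2)
  expect_equal(ddct_fold_change(20, 15, 22, 15), 4)
  expect_error(ddct_fold_change(Inf, 15, 20, 15), "finite")
})

test_that("cluster ordering is a deterministic permutation grouping correlated genes", {
  set.seed(6)
  base <- rnorm(7)
  noise <- function() rnorm(7, sd = 0.05)
  # two modules, internally correlated, anti-correlated with each other
  m <- rbind(m1a = base + noise(), m2a = -base + noise(),
             m1b = base + noise(), m2b = -base + noise(),
             m1c = base + noise(), m2c = -base + noise())
  colnames(m) <- paste0("s", 1:7)
  ord <- cluster_order(m)
  expect_setequal(ord$genes, rownames(m))
  expect_setequal(ord$samples, colnames(m))
  pos1 <- match(c("m1a", "m1b", "m1c"), ord$genes)
  pos2 <- match(c("m2a", "m2b", "m2c"), ord$genes)
  expect_equal(max(pos1) - min(pos1), 2L)
  expect_equal(max(pos2) - min(pos2), 2L)
  expect_identical(ord, cluster_order(m))
  expect_equal(cluster_order(m[1, , drop = FALSE])$genes, "m1a")
})
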