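test_that("pearson_matrix matches the covariance formula and guards degeneracy", {
  set.seed(15)
  m <- matrix(rnorm(6 * 4), 6, 4,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  r <- pearson_matrix(m)
  expect_equal(diag(r), setNames(rep(1, 6), rownames(m)))
  expect_equal(r, t(r))
  # direct covariance-formula oracle
  for (i in 1:5) for (j in (i + 1):6) {
    x <- m[i, ]; y <- m[j, ]
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(r[i, j], oracle, tolerance = 1e-12)
  }
  m2 <- rbind(m, dup = m[1, ], neg = -m[1, ], flat = rep(2, 4))
  expect_warning(r2 <- pearson_matrix(m2), "zero-variance")
  expect_false("flat" %in% rownames(r2))
  expect_equal(r2["g1", "dup"], 1, tolerance = 1e-12)
  expect_equal(r2["g1", "neg"], -1, tolerance = 1e-12)
  expect_error(pearson_matrix(m[, 1:2]), ">= 3 samples")
})

test_that("edges obey the strict absolute-correlation threshold with signs", {
  corr <- diag(4)
  dimnames(corr) <- list(letters[1:4], letters[1:4])
  corr["a", "b"] <- corr["b", "a"] <- 0.9995
  corr["a", "c"] <- corr["c", "a"] <- 0.998
  corr["b", "c"] <- corr["c", "b"] <- -0.9992
  corr["a", "d"] <- corr["d", "a"] <- 0.999  # tie: excluded, strict >
  net <- build_network(corr, threshold = 0.999, condition = "HC")
  key <- paste(net$edges$gene1, net$edges$gene2)
  expect_setequal(key, c("a b", "b c"))
  expect_equal(net$edges$sign[key == "a b"], "positive")
  expect_equal(net$edges$sign[key == "b c"], "negative")
  expect_error(build_network(corr, threshold = 1), "threshold")

  # raising the threshold never adds edges
  n_low <- nrow(build_network(corr, 0.99)$edges)
  n_high <- nrow(build_network(corr, 0.9993)$edges)
  expect_lte(n_high, n_low)
})

test_that("degree centrality counts raw links and sums to twice the edges", {
  adj <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  adj["a", "b"] <- adj["b", "a"] <- 1
  adj["b", "c"] <- adj["c", "b"] <- 1
  net <- network_from_adjacency(adj)
  expect_equal(degree_centrality(net), c(a = 1L, b = 2L, c = 1L))

  k5 <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  net5 <- network_from_adjacency(k5)
  expect_equal(unname(degree_centrality(net5)), rep(4L, 5))
  expect_equal(sum(degree_centrality(net5)), 2L * nrow(net5$edges))
})

test_that("k-core decomposition handles canonical small graphs", {
  # triangle plus a pendant node
  adj <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  adj["a", "b"] <- adj["a", "c"] <- adj["b", "c"] <- 1
  adj["c", "d"] <- 1
  adj <- adj + t(adj)
  kc <- kcore_decompose(network_from_adjacency(adj))
  expect_equal(kc$core, c(a = 2L, b = 2L, c = 2L, d = 1L))
  expect_equal(kc$max_k, 2L)
  expect_setequal(kc$max_core_members, c("a", "b", "c"))

  k4 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(unname(kcore_decompose(network_from_adjacency(k4))$core),
               rep(3L, 4))

  empty <- network_from_adjacency(matrix(0, 3, 3,
                                         dimnames = list(letters[1:3],
                                                         letters[1:3])))
  expect_equal(unname(kcore_decompose(empty)$core), rep(0L, 3))
})

test_that("k-core agrees with brute-force deletion and igraph on random graphs", {
  set.seed(23)
  for (i in 1:200) {
    net <- random_network(sample(2:12, 1), runif(1, 0.1, 0.8))
    kc <- kcore_decompose(net)
    expect_identical(kc$core, kcore_oracle(net$nodes, net$edges))
    g <- as_igraph(net)
    expect_identical(unname(kc$core[igraph::V(g)$name]),
                     unname(as.integer(igraph::coreness(g))))
    deg <- degree_centrality(net)
    expect_true(all(kc$core <= deg[names(kc$core)]))
  }
})

test_that("relabelling genes permutes network results identically", {
  set.seed(31)
  m <- matrix(rnorm(8 * 4), 8, 4,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:4)))
  net <- build_network(pearson_matrix(m), 0.7)
  perm <- sample(8)
  m2 <- m[perm, ]
  net2 <- build_network(pearson_matrix(m2), 0.7)
  expect_equal(sort(unname(degree_centrality(net))),
               sort(unname(degree_centrality(net2))))
  expect_identical(degree_centrality(net)[rownames(m2)],
                   degree_centrality(net2))
  expect_identical(kcore_decompose(net)$core[rownames(m2)],
                   kcore_decompose(net2)$core)
})

test_that("core regulators rank by absolute degree difference with stated ties", {
  adjA <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  adjB <- adjA
  adjB["x", "y"] <- adjB["y", "x"] <- 1
  adjB["x", "z"] <- adjB["z", "x"] <- 1
  netA <- network_from_adjacency(adjA, "A")
  netB <- network_from_adjacency(adjB, "B")
  regs <- core_regulators(netA, netB)
  expect_equal(regs$gene[1], "x")
  expect_equal(regs$degree_diff[regs$gene == "x"], 2L)
  # tie between y and z broken by gene ID
  expect_equal(regs$gene[2:3], c("y", "z"))
  # identical networks: all differences zero
  regs0 <- core_regulators(netB, netB)
  expect_true(all(regs0$degree_diff == 0L))
})

test_that("a condition-specific planted module dominates the regulator ranking", {
  cfg <- simulation_config(
    seed = 41, n_genes = 400, de_fraction = 0, noise_sd = 0.3,
    modules = list(module_spec(6, residual_sd = 0,
                               condition_specific = "B_only"),
                   module_spec(5, residual_sd = 0)))
  sim <- generate_dataset(cfg)
  members <- sim$truth$modules[[1]]
  shared <- sim$truth$modules[[2]]
  genes <- c(members, shared)
  nets <- lapply(c(A = "A", B = "B"), function(cc) {
    cols <- sim$design$sample[sim$design$condition == cc]
    build_network(pearson_matrix(sim$matrix[genes, cols]), 0.999, cc)
  })
  # B_only module forms a clique in B only; shared module in both
  degB <- degree_centrality(nets$B)
  expect_true(all(degB[members] >= 5L))
  kcB <- kcore_decompose(nets$B)
  expect_true(all(kcB$core[members] >= 5L))
  regs <- core_regulators(nets$A, nets$B)
  expect_setequal(regs$gene[1:6], members)
  member_min <- min(abs(regs$degree_diff[regs$gene %in% members]))
  other_max <- max(abs(regs$degree_diff[!regs$gene %in% members]))
  expect_gt(member_min, other_max)
})
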