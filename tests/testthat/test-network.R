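# SparCC inference, permutation significance, FDR thresholding and topology.

test_that("sparcc output is a valid correlation matrix", {
  cfg <- count_config(seed = 61, n_taxa = 10, n_samples = 10)
  cm <- generate_count_matrix(cfg)
  est <- sparcc(cm)
  expect_equal(unname(diag(est$rho)), rep(1, 10))
  expect_equal(est$rho, t(est$rho))
  expect_true(all(abs(est$rho) <= 1))
  expect_error(sparcc(matrix(1:9, 3, 3)), "at least 4 taxa")
  expect_error(sparcc(matrix(1:16, 4, 4)), "at least 5 samples")
  same <- matrix(rep(c(5, 3, 2, 1), 6), 4, 6)
  expect_error(sparcc(same), "identical")
})

test_that("a planted basis correlation is recovered as the top pair", {
  S <- diag(12); S[1, 2] <- S[2, 1] <- 0.9
  cfg <- count_config(seed = 62, n_taxa = 12, n_samples = 50, log_cov = S)
  cm <- generate_count_matrix(cfg)
  est <- sparcc(cm)
  r <- abs(est$rho); diag(r) <- 0
  top <- which(r == max(r), arr.ind = TRUE)[1, ]
  expect_setequal(unname(top), c(1L, 2L))
  expect_gt(est$rho[1, 2], 0.6)
})

test_that("row-shuffled counts yield near-zero correlations", {
  cfg <- count_config(seed = 63, n_taxa = 20, n_samples = 50)
  cm <- generate_count_matrix(cfg)
  set.seed(1)
  shuffled <- t(apply(cm$counts, 1, sample))
  est <- sparcc(shuffled)
  q95 <- quantile(abs(est$rho[upper.tri(est$rho)]), 0.95)
  expect_lt(q95, 0.4)
})

test_that("the dirichlet variant is seeded and deterministic", {
  cfg <- count_config(seed = 64, n_taxa = 8, n_samples = 12)
  cm <- generate_count_matrix(cfg)
  e1 <- sparcc(cm, method = "dirichlet", n_inner_iterations = 5, seed = 3)
  e2 <- sparcc(cm, method = "dirichlet", n_inner_iterations = 5, seed = 3)
  expect_identical(e1$rho, e2$rho)
  expect_equal(e1$iterations, 5L)
})

test_that("permutation p-values follow the add-one rule and are seeded", {
  S <- diag(8); S[1, 2] <- S[2, 1] <- 0.95
  cfg <- count_config(seed = 65, n_taxa = 8, n_samples = 40, log_cov = S)
  cm <- generate_count_matrix(cfg)
  est <- sparcc(cm)
  est <- sparcc_pvalues(est, cm, n_permutations = 99, seed = 5)
  # the planted pair should beat every permuted value: p = (1+0)/(99+1)
  expect_equal(est$p[1, 2], 0.01)
  expect_true(all(est$q >= est$p - 1e-12, na.rm = TRUE))
  est2 <- sparcc_pvalues(sparcc(cm), cm, n_permutations = 99, seed = 5)
  expect_identical(est$p, est2$p)
  expect_error(sparcc_pvalues(est, cm, n_permutations = 10), "at least 19")
})

test_that("null-data permutation p-values are approximately uniform", {
  cfg <- count_config(seed = 66, n_taxa = 12, n_samples = 40)
  cm <- generate_count_matrix(cfg)
  est <- sparcc_pvalues(sparcc(cm), cm, n_permutations = 99, seed = 6)
  pv <- est$p[upper.tri(est$p)]
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment matches step-up arithmetic", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # matrix form mirrors the triangle and preserves monotonicity q >= p
  set.seed(67)
  p <- matrix(runif(25), 5, 5); p <- (p + t(p)) / 2; diag(p) <- NA
  q <- bh_fdr(p)
  expect_equal(q, t(q))
  expect_true(all(q[upper.tri(q)] >= p[upper.tri(p)]))
  expect_equal(q[upper.tri(q)], p.adjust(p[upper.tri(p)], "BH"))
})

test_that("network thresholding keeps exactly the qualifying pairs", {
  est <- fake_estimate(pairs_spec(c(0.7), list(c(1, 2))), c(0.001), d = 5)
  net <- build_network(est)
  expect_equal(nrow(net$edges), 1L)
  expect_identical(net$edges$sign, "positive")

  est2 <- fake_estimate(pairs_spec(c(0.7), list(c(1, 2))), c(0.05), d = 5)
  expect_equal(nrow(build_network(est2)$edges), 0L)

  est3 <- fake_estimate(pairs_spec(c(-0.65), list(c(2, 4))), c(0.001), d = 5)
  net3 <- build_network(est3)
  expect_equal(nrow(net3$edges), 1L)
  expect_identical(net3$edges$sign, "negative")
  expect_equal(net3$edges$rho, -0.65)

  # isolates excluded by default, kept on request
  expect_equal(length(net$nodes), 2L)
  expect_equal(length(build_network(est, keep_isolates = TRUE)$nodes), 5L)
  expect_error(build_network(est, rho_min = 1.2), "rho_min")
  expect_error(build_network(est, q_max = 0), "q_max")
})

test_that("edge retention is monotone in both thresholds", {
  S <- diag(15)
  S[1, 2] <- S[2, 1] <- 0.9; S[3, 4] <- S[4, 3] <- 0.7
  cfg <- count_config(seed = 68, n_taxa = 15, n_samples = 40, log_cov = S)
  cm <- generate_count_matrix(cfg)
  est <- sparcc_pvalues(sparcc(cm), cm, n_permutations = 49, seed = 8)
  grid_rho <- c(0.2, 0.4, 0.6, 0.8)
  grid_q <- c(0.5, 0.1, 0.02)
  for (qm in grid_q) {
    sizes <- vapply(grid_rho, function(rm)
      nrow(build_network(est, rho_min = rm, q_max = qm)$edges), numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
  for (rm in grid_rho) {
    sizes <- vapply(grid_q, function(qm)
      nrow(build_network(est, rho_min = rm, q_max = qm)$edges), numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("topology metrics match closed-form values on canonical graphs", {
  tri <- edges_to_net(rbind(c(1, 2), c(2, 3), c(1, 3)), 1:3)
  tt <- network_topology(tri)
  expect_equal(tt$n_nodes, 3L); expect_equal(tt$n_edges, 3L)
  expect_equal(tt$average_degree, 2)
  expect_equal(tt$transitivity, 1)
  expect_equal(tt$density, 1)

  path <- edges_to_net(rbind(c(1, 2), c(2, 3)), 1:3)
  expect_equal(network_topology(path)$transitivity, 0)

  empty <- edges_to_net(matrix(numeric(0), 0, 2), integer(0))
  et <- network_topology(empty)
  expect_true(et$empty)
  expect_equal(et$average_degree, 0)
})

test_that("two disjoint triangles have modularity 1/2 (exhaustive oracle)", {
  net <- edges_to_net(rbind(c(1, 2), c(2, 3), c(1, 3),
                            c(4, 5), c(5, 6), c(4, 6)), 1:6)
  topo <- network_topology(net)
  # brute-force maximum modularity over all partitions of 6 nodes
  adj <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    adj[e[1], e[2]] <- adj[e[2], e[1]] <- 1
  }
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  part_q <- function(memb) {
    q <- 0
    for (i in 1:6) for (j in 1:6) {
      if (memb[i] == memb[j])
        q <- q + adj[i, j] - deg[i] * deg[j] / (2 * m)
    }
    q / (2 * m)
  }
  # enumerate all set partitions via restricted growth strings
  best <- -Inf
  memb <- integer(6)
  recurse <- function(i, maxl) {
    if (i > 6) { best <<- max(best, part_q(memb)); return() }
    for (l in 1:(maxl + 1)) {
      memb[i] <<- l
      recurse(i + 1, max(maxl, l))
    }
  }
  recurse(1, 0)
  expect_equal(best, 0.5, tolerance = 1e-12)
  expect_equal(topo$modularity, 0.5, tolerance = 1e-12)
})

test_that("transitivity and degree agree with brute force on random graphs", {
  set.seed(69)
  for (i in 1:12) {
    n <- sample(4:12, 1)
    adj <- matrix(0, n, n)
    for (a in 1:(n - 1)) for (b in (a + 1):n) {
      if (runif(1) < 0.35) adj[a, b] <- adj[b, a] <- 1
    }
    eidx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    net <- edges_to_net(eidx, 1:n)
    topo <- network_topology(net)
    if (topo$empty) next
    expect_equal(topo$average_degree, sum(adj) / n, tolerance = 1e-12)
    expect_equal(topo$transitivity, brute_transitivity(adj), tolerance = 1e-12)
    expect_equal(topo$density, sum(adj) / (n * (n - 1)), tolerance = 1e-12)
  }
})

test_that("taxon aggregation sums counts by lineage", {
  cfg <- count_config(seed = 70, n_taxa = 6, n_samples = 3)
  cm <- generate_count_matrix(cfg)
  lin <- c("p1", "p1", "p2", "p2", "p2", "p3")
  agg <- aggregate_taxa(cm, lin)
  expect_equal(nrow(agg$counts), 3L)
  expect_equal(unname(agg$counts["p1", ]),
               unname(cm$counts[1, ] + cm$counts[2, ]))
  expect_equal(colSums(agg$counts), colSums(cm$counts))
  top2 <- aggregate_taxa(cm$counts, lin, top = 2)
  expect_equal(nrow(top2), 2L)
})
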