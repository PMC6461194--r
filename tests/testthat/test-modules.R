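test_that("modularity Q matches its closed forms and the enumeration oracle", {
  set.seed(31)
  ## any network under the single-module partition has Q = 0 exactly
  a <- rand_graph(12, 0.4)
  expect_identical(modularity_q(a, rep(1L, 12)), 0)

  ## two disconnected K5 cliques split by clique: Q = 1 - 2 (1/2)^2 = 0.5
  a2 <- two_cliques_bridge(5); a2[5, 6] <- a2[6, 5] <- 0
  expect_equal(modularity_q(a2, rep(1:2, each = 5)), 0.5)

  ## random graphs and partitions agree with the naive oracle (and igraph)
  for (rep in 1:20) {
    a <- rand_graph(10, 0.5)
    if (sum(a) == 0) next
    memb <- rand_partition(10)
    q <- modularity_q(a, memb)
    expect_equal(q, naive_modularity(a, memb), tolerance = 1e-12)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    expect_equal(q, igraph::modularity(g, memb), tolerance = 1e-12)
  }

  ## label-permutation invariance
  a <- rand_graph(10, 0.5)
  memb <- rand_partition(10, 4)
  perm <- sample(max(memb))
  expect_equal(modularity_q(a, perm[memb]), modularity_q(a, memb), tolerance = 1e-12)

  expect_error(modularity_q(matrix(0, 4, 4), rep(1, 4)), "edgeless")
})

test_that("spectral detection recovers planted community structures", {
  ## two K5 cliques joined by a bridge: the cliques, at the exhaustive optimum
  a <- two_cliques_bridge(5)
  p <- detect_modules(a)
  expect_equal(p$n_modules, 2)
  expect_equal(unname(comembership(p$assignment)),
               unname(comembership(rep(1:2, each = 5))))
  best <- exhaustive_best_q(a)
  expect_equal(p$q, best$q, tolerance = 1e-12)

  ## complete graph: no split increases Q
  k6 <- matrix(1, 6, 6); diag(k6) <- 0
  expect_equal(detect_modules(k6)$n_modules, 1)

  ## ring of four 8-cliques: the four cliques
  ar <- clique_ring(4, 8)
  pr <- detect_modules(ar)
  expect_equal(pr$n_modules, 4)
  planted <- rep(1:4, each = 8)
  expect_equal(unname(comembership(pr$assignment)),
               unname(comembership(planted)))
  expect_gte(pr$q, modularity_q(ar, planted) - 1e-12)

  ## disconnected components are partitioned independently
  a2 <- two_cliques_bridge(5); a2[5, 6] <- a2[6, 5] <- 0
  expect_equal(detect_modules(a2)$n_modules, 2)

  expect_error(detect_modules(matrix(0, 3, 3)), "edgeless")
})

test_that("detected Q is non-negative and labels are canonical", {
  set.seed(32)
  for (rep in 1:15) {
    a <- rand_graph(sample(6:12, 1), 0.4)
    if (sum(a) == 0) next
    p <- detect_modules(a)
    expect_gte(p$q, 0)                        # at least the trivial partition
    labs <- unique(p$assignment)
    expect_identical(sort(as.integer(labs)), seq_along(labs))  # contiguous
    sizes <- as.integer(table(p$assignment))
    expect_true(all(diff(sizes) <= 0))        # decreasing size order
  }
})

test_that("reference matching relabels by maximum overlap without regrouping", {
  a <- clique_ring(4, 8)
  dimnames(a) <- rep(list(paste0("n", seq_len(32))), 2)
  ref <- detect_modules(a)

  ## identity
  expect_equal(match_to_reference(ref, ref, a)$assignment, ref$assignment)

  ## permuted labels are restored exactly
  perm <- c(3L, 1L, 4L, 2L)
  permuted <- perm[ref$assignment]
  m <- match_to_reference(permuted, ref, a)
  expect_equal(unname(m$assignment), unname(ref$assignment))

  ## splitting one reference module: larger half keeps the label,
  ## smaller half gets a fresh label above the reference maximum
  split <- ref$assignment
  mod1 <- which(split == 1)
  split[mod1[1:3]] <- 99L  # smaller half of module 1
  split <- as.integer(factor(split, levels = unique(split)))
  ms <- match_to_reference(split, ref, a)
  bigger <- setdiff(mod1, mod1[1:3])
  expect_true(all(ms$assignment[bigger] == 1))
  expect_true(all(ms$assignment[mod1[1:3]] == 5))

  ## co-membership is never altered by relabeling
  expect_equal(unname(comembership(ms$assignment)), unname(comembership(split)))

  ## node-set mismatch
  ref2 <- ref; names(ref2$assignment) <- paste0("x", seq_along(ref2$assignment))
  expect_error(match_to_reference(ref2, ref, a), "node set")
})

test_that("sparsity sweep records one (sparsity, Q) point per threshold", {
  set.seed(33)
  cfg <- synth_config(n_nodes = 64, planted_partition = rep(1:4, each = 16))
  z <- planted_weight_matrix(cfg, "HC-low")

  curve <- sparsity_sweep(z)
  expect_equal(nrow(curve), 21)
  expect_equal(curve$sparsity, seq(0.10, 0.30, by = 0.01))

  ## analytic oracle for the expected curve: with within-pair weights
  ## uniform on (wl, wh) and between-pair weights uniform on (bl, bh), the
  ## sparsity-S cutoff t solves W P(w > t) + B P(b > t) = K(S), the expected
  ## within-edge fraction is W P(w > t) / K, and for four equal modules
  ## with evenly spread between edges Q ~ f_within - 1/4
  n <- 64; W <- 4 * choose(16, 2); B <- choose(n, 2) - W
  surv <- function(t, lo, hi) pmin(1, pmax(0, (hi - t) / (hi - lo)))
  q_expected <- vapply(curve$sparsity, function(s) {
    K <- round(s * choose(n, 2))
    t <- uniroot(function(t) W * surv(t, 0.15, 0.45) + B * surv(t, 0.05, 0.30) - K,
                 c(0.05, 0.45))$root
    W * surv(t, 0.15, 0.45) / K - 0.25
  }, 0)
  expect_true(all(abs(curve$q - q_expected) < 0.05))
  ## modular structure is strong throughout the conventional range
  expect_true(all(curve$n_modules == 4))
  expect_true(all(curve$q >= 0.25))
  ## and sits inside the canonical 0.3-0.7 band at the 20% working threshold
  expect_gte(curve$q[curve$sparsity == 0.2], 0.3)
  expect_lte(curve$q[curve$sparsity == 0.2], 0.7)

  one <- sparsity_sweep(z, 0.2)
  expect_equal(nrow(one), 1)
  expect_equal(one$q, detect_modules(threshold_sparsity(z, 0.2))$q)

  expect_error(sparsity_sweep(z, c(0.2, 0.1)))
})

test_that("undersized modules merge into their best-connected neighbor", {
  ## two K6 cliques plus a 2-node appendage hanging off clique 1
  a <- matrix(0, 14, 14)
  a[1:6, 1:6] <- 1; a[7:12, 7:12] <- 1; diag(a) <- 0
  a[13, 14] <- a[14, 13] <- 1
  a[1, 13] <- a[13, 1] <- 1; a[2, 14] <- a[14, 2] <- 1
  part <- c(rep(1L, 6), rep(2L, 6), 3L, 3L)
  merged <- merge_small_modules(a, part, min_size = 5)
  expect_equal(merged$n_modules, 2)
  ## the appendage joins clique 1, where its two edges go
  expect_equal(unname(merged$assignment[13]), unname(merged$assignment[1]))
  ## partitions already above the floor are untouched
  expect_equal(unname(merge_small_modules(a, part, min_size = 2)$assignment),
               canonical <- unname(merge_small_modules(a, part, min_size = 1)$assignment))
})
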