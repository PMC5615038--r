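test_that("make_tree_like produces valid functional graphs (property, brute-force oracle)", {
  set.seed(42)
  for (rep in 1:150) {
    S <- sample(2:25, 1)
    L <- if (S == 2) 2L else sample(2:S, 1)
    topo <- make_tree_like(S, L, seed = sample.int(1e6, 1))
    expect_length(topo$successor, S)
    expect_false(any(topo$successor == seq_len(S)))
    cyc <- oracle_cycles(topo$successor)
    expect_equal(cyc$n_cycles, 1L)
    expect_equal(cyc$lengths, L)
    expect_equal(oracle_n_components(topo$successor), 1L)
    expect_equal(connectivity(adjacency_mask(topo)), 2 / S)
  }
})

test_that("forced and minimal topologies match their unique shapes", {
  t2 <- make_tree_like(2, 2)
  expect_equal(t2$successor, c(2L, 1L))
  t3 <- make_tree_like(3, 3, seed = 9)
  expect_setequal(oracle_cycles(t3$successor)$cycle_nodes, 1:3)
  # S=6, L=3: cycle of 3 with 3 attached tree nodes
  t6 <- make_tree_like(6, 3, seed = 5)
  cyc <- oracle_cycles(t6$successor)
  expect_equal(cyc$lengths, 3L)
  expect_length(setdiff(1:6, cyc$cycle_nodes), 3)
})

test_that("make_tree_like rejects invalid loop lengths and sizes", {
  expect_error(make_tree_like(5, 6), "loop_length")
  expect_error(make_tree_like(5, 1), "loop_length")
  expect_error(make_tree_like(1, 2), "at least 2")
  expect_error(tree_topology(4, c(2L, 3L, 4L, 4L), 2),  # self-link at node 4
               "self-link")
})

test_that("add_random_links hits the target connectivity exactly by count", {
  topo <- make_tree_like(20, 3, seed = 1)
  ex <- add_random_links(topo, 0.5, 0.1, seed = 2)
  expect_equal(nrow(ex$positions), 160L)  # 0.5*400 - 40
  expect_equal(connectivity(adjacency_mask(topo, ex)), 0.5)

  t10 <- make_tree_like(10, 3, seed = 1)
  e10 <- add_random_links(t10, 0.5, 0.1, seed = 2)
  expect_equal(nrow(e10$positions), 30L)
  expect_equal(connectivity(adjacency_mask(t10, e10)), 0.5)

  expect_equal(nrow(add_random_links(topo, 2 / 20, 0.1, seed = 3)$positions), 0L)
  expect_error(add_random_links(topo, 0.05, 0.1), "floor")
})

test_that("extra links avoid the diagonal, duplicates, and base links (property)", {
  set.seed(7)
  for (rep in 1:50) {
    S <- sample(5:25, 1)
    topo <- make_tree_like(S, sample(2:min(S, 6), 1), seed = sample.int(1e6, 1))
    C <- runif(1, 2 / S, 1)
    ex <- add_random_links(topo, C, 0.2, seed = sample.int(1e6, 1))
    if (!nrow(ex$positions)) next
    expect_false(any(ex$positions[, 1] == ex$positions[, 2]))
    expect_equal(anyDuplicated(ex$positions), 0L)
    base <- cbind(seq_len(S), topo$successor)
    overlap <- merge(as.data.frame(ex$positions), as.data.frame(base))
    expect_equal(nrow(overlap), 0L)
    expect_lte(abs(connectivity(adjacency_mask(topo, ex)) - C), 1 / S^2)
  }
})

test_that("join_tree_like is closed over the tree-like class (property)", {
  set.seed(11)
  for (rep in 1:1000) {
    Sa <- sample(2:12, 1); La <- if (Sa == 2) 2L else sample(2:Sa, 1)
    Sb <- sample(2:12, 1); Lb <- if (Sb == 2) 2L else sample(2:Sb, 1)
    a <- make_tree_like(Sa, La, seed = sample.int(1e6, 1))
    b <- make_tree_like(Sb, Lb, seed = sample.int(1e6, 1))
    j <- join_tree_like(a, b, seed = sample.int(1e6, 1))
    expect_equal(j$n_nodes, Sa + Sb)
    expect_equal(j$loop_length, Lb)       # b's cycle survives
    cyc <- oracle_cycles(j$successor)
    expect_equal(cyc$n_cycles, 1L)
    expect_equal(cyc$lengths, Lb)
    expect_equal(oracle_n_components(j$successor), 1L)
    expect_equal(connectivity(adjacency_mask(j)), 2 / (Sa + Sb))
  }
})

test_that("merge_sparse_counts implements the self-similar link arithmetic", {
  expect_equal(merge_sparse_counts(4, 5, 2, 1), 17)
  expect_equal(merge_sparse_counts(6, 6, 1, 0), 12)
  set.seed(3)
  for (rep in 1:100) {
    a <- sample(1:4, 1); b <- sample(0:3, 1)
    S <- sample((b + 1):20, 1) + b; Sp <- sample((b + 1):20, 1) + b
    expect_equal(merge_sparse_counts(S, Sp, a, b), a * (S + Sp) - b)
  }
  expect_error(merge_sparse_counts(2, 5, 1, 3), "positive")
  expect_error(merge_sparse_counts(4, 5, 0, 0), "a >= 1")
})

test_that("edge-list TSV round-trips topologies and weight matrices", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  topo <- make_tree_like(8, 3, seed = 4)
  write_edge_list(topo, tmp)
  m <- read_edge_list(tmp)
  expect_equal(rowSums(m != 0), rep(1, 8), ignore_attr = TRUE)
  expect_equal(m[cbind(seq_len(8), topo$successor)], rep(1, 8))

  w <- inverse_weights(topo, NULL, runif(8, 0.5, 1.5), 1)
  write_edge_list(unclass(w), tmp)
  expect_equal(read_edge_list(tmp, 8), unclass(w), tolerance = 1e-12)
})
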