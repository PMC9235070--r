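test_that("consensus k-means recovers planted gene blocks", {
  expect_equal(unique(consensus_kmeans(matrix(rnorm(40), 4), 1)$assignment),
               1L)
  set.seed(6)
  block1 <- outer(runif(10, 0.8, 1.2), rnorm(50))
  block2 <- outer(runif(10, 0.8, 1.2), rnorm(50))
  v <- rbind(block1 + matrix(rnorm(500, sd = .3), 10),
             block2 + matrix(rnorm(500, sd = .3), 10))
  rownames(v) <- paste0("g", 1:20)
  ck <- consensus_kmeans(v, 2, n_runs = 30, subsample_frac = 0.8, seed = 3)
  expect_equal(length(unique(ck$assignment[1:10])), 1)
  expect_equal(length(unique(ck$assignment[11:20])), 1)
  expect_false(ck$assignment[1] == ck$assignment[11])
  expect_true(all(ck$consensus >= 0 & ck$consensus <= 1))
  expect_equal(ck$consensus, t(ck$consensus))
  # duplicated gene rows always co-cluster
  vd <- rbind(v, g21 = v[1, ])
  ckd <- consensus_kmeans(vd, 2, n_runs = 30, seed = 4)
  expect_equal(unname(ckd$consensus["g1", "g21"]), 1)
  expect_error(consensus_kmeans(v, 21), "exceeds")
})

test_that("full hierarchy edges follow the 15% inheritance rule", {
  set.seed(8)
  suite <- simulate_hierarchy_suite(n_datasets = 1, shared_blocks = 2,
                                    private_blocks = 0, block_size = 16,
                                    n_background = 6, n_cells = 60, seed = 10)
  h <- build_full_hierarchy(suite$datasets[[1]], k_max = 5, n_runs = 20,
                            inherit_threshold = 0.15, seed = 12)
  expect_s3_class(h, "ClusterHierarchy")
  expect_equal(min(h$nodes$level), 1)
  # brute-force recomputation of every possible edge
  for (k in 1:4) {
    up <- h$nodes$id[h$nodes$level == k]
    down <- h$nodes$id[h$nodes$level == k + 1]
    for (ci in up) for (cj in down) {
      gi <- h$members[[as.character(ci)]]
      gj <- h$members[[as.character(cj)]]
      expected <- length(intersect(gi, gj)) >= 0.15 * length(gj)
      present <- any(h$edges$from == ci & h$edges$to == cj)
      expect_equal(present, expected)
      if (present) {
        w <- h$edges$weight[h$edges$from == ci & h$edges$to == cj]
        expect_equal(w, length(intersect(gi, gj)) / length(gj))
      }
    }
  }
  # levels are consecutive and the graph is acyclic by construction
  lv <- setNames(h$nodes$level, h$nodes$id)
  expect_true(all(lv[as.character(h$edges$to)] -
                  lv[as.character(h$edges$from)] == 1))
})

test_that("a cluster joined from two coarser clusters gets two parents", {
  members <- list("1" = paste0("g", 1:8), "2" = paste0("g", 1:4),
                  "3" = paste0("g", 5:8), "4" = paste0("g", c(1, 2, 5, 6)))
  nodes <- data.frame(id = 1:4, level = c(1, 2, 2, 3), size = lengths(members))
  # 50/50 join: overlap with each parent = 2 = 0.5 * |c_j| >= 0.15 * 4
  edges <- data.frame(from = c(1, 1, 2, 3), to = c(2, 3, 4, 4),
                      weight = c(1, 1, 0.5, 0.5))
  h <- cluster_hierarchy(nodes, members, edges)
  expect_equal(sum(h$edges$to == 4), 2)
})

test_that("stump collapsing matches the worked example and simple shapes", {
  h <- reduction_toy_hierarchy()
  r <- reduce_hierarchy(h)
  nm <- r$node_map
  expect_equal(nm[["4"]], nm[["5"]])
  expect_equal(nm[["8"]], nm[["9"]])
  others <- setdiff(as.character(1:11), c("4", "5", "8", "9"))
  expect_false(anyDuplicated(nm[others]) > 0)
  expect_false(any(nm[others] %in% c(nm[["4"]], nm[["8"]])))
  # collapsed node keeps the bottom (deepest) cluster's gene set by default
  expect_equal(r$graph$members[[as.character(nm[["4"]])]], h$members[["5"]])
  ru <- reduce_hierarchy(h, representative = "union")
  expect_setequal(ru$graph$members[[as.character(nm[["4"]])]],
                  c(h$members[["4"]], h$members[["5"]]))
  # a pure path collapses to a single node
  path5 <- dag_hierarchy(5, cbind(1:4, 2:5))
  expect_equal(nrow(reduce_hierarchy(path5)$graph$nodes), 1)
  # a complete binary tree has no multi-node stumps below the root
  tree <- dag_hierarchy(7, cbind(c(1, 1, 2, 2, 3, 3), c(2, 3, 4, 5, 6, 7)),
                        levels = c(1, 2, 2, 3, 3, 3, 3))
  rt <- reduce_hierarchy(tree)
  expect_equal(nrow(rt$graph$nodes), 7)
  expect_equal(nrow(rt$graph$edges), 6)
  # reduction is idempotent: re-reducing maps every node to itself
  r2 <- reduce_hierarchy(r$graph)
  expect_equal(nrow(r2$graph$nodes), nrow(r$graph$nodes))
  expect_equal(nrow(r2$graph$edges), nrow(r$graph$edges))
  expect_false(anyDuplicated(r2$node_map) > 0)
})

test_that("reduction agrees with a brute-force stump finder on random DAGs", {
  for (seed in 1:60) {
    h <- random_dag(seed)
    r <- reduce_hierarchy(h)
    expect_equal(canon_partition(map_partition(r$node_map)),
                 canon_partition(oracle_reduce_partition(h)),
                 info = paste("seed", seed))
    # reduced edge set equals the partition-quotient edges
    got <- sort(unique(paste(
      vapply(split(names(r$node_map), r$node_map)[as.character(r$graph$edges$from)],
             function(p) paste(sort(p), collapse = ","), character(1)),
      vapply(split(names(r$node_map), r$node_map)[as.character(r$graph$edges$to)],
             function(p) paste(sort(p), collapse = ","), character(1)),
      sep = "|")))
    expect_equal(got, oracle_reduced_edges(h, oracle_reduce_partition(h)),
                 info = paste("seed", seed))
    expect_lte(nrow(r$graph$nodes), nrow(h$nodes))
  }
})

test_that("annotation computes density and separates planted heterogeneity", {
  set.seed(20)
  n_cells <- 60
  tumor <- rep(paste0("t", 1:3), each = n_cells / 3)
  profiles <- matrix(rnorm(8 * 3, sd = 2), 8)  # one gene profile per tumor
  homo <- profiles[, as.integer(factor(tumor))] +
    matrix(rnorm(8 * n_cells, sd = .5), 8)
  hetero <- matrix(rnorm(8 * n_cells), 8)
  v <- rbind(homo, hetero)
  rownames(v) <- paste0("g", 1:16)
  mask <- matrix(TRUE, 16, n_cells)
  mask[9:16, seq(1, n_cells, 2)] <- FALSE  # half the hetero block missing
  vm <- v; vm[!mask] <- NA
  raw <- expression_matrix(vm, tumor = tumor)
  imp <- impute(raw, "mean")
  members <- list("1" = paste0("g", 1:16), "2" = paste0("g", 1:8),
                  "3" = paste0("g", 9:16))
  h <- cluster_hierarchy(
    data.frame(id = 1:3, level = c(1, 2, 2), size = c(16, 8, 8)),
    members, data.frame(from = c(1, 1), to = c(2, 3), weight = 1))
  ann <- annotate_clusters(h, imp, mask_m = raw, n_samples = 1e4, seed = 2)
  expect_equal(ann$nodes$density, c(0.75, 1, 0.5))
  expect_gt(ann$nodes$p_diff[2], ann$nodes$p_diff[3])  # homogeneous block
  expect_lt(ann$nodes$avg_nsv[2], ann$nodes$avg_nsv[3])
})

test_that("p_diff ranks are descending with average ties", {
  h <- dag_hierarchy(3, cbind(c(1, 1), c(2, 3)))
  h$nodes$p_diff <- c(0.9, 0.5, 0.1)
  expect_equal(unname(rank_pdiff(h)), c(1, 2, 3))
  h$nodes$p_diff <- c(0.9, 0.9, 0.1)
  expect_equal(unname(rank_pdiff(h)), c(1.5, 1.5, 3))
  set.seed(30)
  h$nodes$p_diff <- runif(3)
  expect_equal(unname(rank_pdiff(h)),
               unname(rank(-h$nodes$p_diff, ties.method = "average")))
  h$nodes$p_diff[2] <- NA
  expect_error(rank_pdiff(h), "annotation")
})

test_that("hierarchies survive a JSON round-trip", {
  h <- reduction_toy_hierarchy()
  h$nodes$p_diff <- runif(11)
  f <- tempfile(fileext = ".json")
  write_hierarchy(h, f)
  back <- read_hierarchy(f)
  expect_equal(back$nodes$id, h$nodes$id)
  expect_equal(back$nodes$p_diff, h$nodes$p_diff)
  expect_equal(back$members, h$members)
  r <- reduce_hierarchy(h)
  write_hierarchy(r, f)
  rback <- read_hierarchy(f)
  expect_s3_class(rback, "ReducedHierarchy")
  expect_equal(rback$node_map, r$node_map)
})
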