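test_that("two-tier cluster overlap applies the Jaccard and mutual-rank rules", {
  a <- list("1" = paste0("g", 1:10))
  b <- list("1" = paste0("g", 1:10), "2" = paste0("g", 11:20))
  ov <- cluster_overlap_matrix(a, b)
  expect_true(ov["1", "1"])    # identical sets
  expect_false(ov["1", "2"])   # disjoint sets
  # |A| = |B| = 10, overlap 3: Jaccard 3/17 ~ 0.176 sits in the fallback band,
  # so the verdict follows the mutual top-ten ranks; with few clusters the
  # ranks are trivially within ten
  a2 <- list(A = paste0("g", 1:10))
  b2 <- list(B = paste0("g", c(1:3, 21:27)))
  expect_true(cluster_overlap_matrix(a2, b2)["A", "B"])
  # same Jaccard but pushed out of the top-ten by 10 better partners
  b3 <- c(b2, setNames(lapply(1:10, function(i) paste0("g", 1:10)),
                       paste0("C", 1:10)))
  ov3 <- cluster_overlap_matrix(a2, b3)
  expect_false(ov3["A", "B"])
  expect_true(all(ov3["A", paste0("C", 1:10)]))
  # brute-force check of the full rule on a constructed 12-cluster pair
  set.seed(33)
  pool <- paste0("g", 1:60)
  ca <- setNames(lapply(1:12, function(i) sample(pool, sample(5:15, 1))),
                 paste0("a", 1:12))
  cb <- setNames(lapply(1:12, function(i) sample(pool, sample(5:15, 1))),
                 paste0("b", 1:12))
  ov <- cluster_overlap_matrix(ca, cb)
  J <- sapply(cb, function(y) sapply(ca, function(x)
    length(intersect(x, y)) / length(union(x, y))))
  for (i in 1:12) for (j in 1:12) {
    expected <- J[i, j] > 0.2 ||
      (J[i, j] >= 0.1 && J[i, j] <= 0.2 &&
       sum(J[i, ] > J[i, j]) + 1 <= 10 && sum(J[, j] > J[i, j]) + 1 <= 10)
    expect_equal(unname(ov[i, j]), expected, info = paste(i, j))
  }
})

test_that("path matching finds maximal matched subpath pairs", {
  # identical hierarchies: every root-leaf path matches itself maximally
  h <- dag_hierarchy(5, cbind(c(1, 1, 2, 2), c(2, 3, 4, 5)),
                     levels = c(1, 2, 2, 3, 3),
                     members = list("1" = paste0("g", 1:8),
                                    "2" = paste0("g", 1:4),
                                    "3" = paste0("g", 5:8),
                                    "4" = paste0("g", 1:2),
                                    "5" = paste0("g", 3:4)))
  ms <- match_paths(h, h)
  keys <- vapply(ms, function(m) paste(paste(m$path_a, collapse = ","),
                                       paste(m$path_b, collapse = ","),
                                       sep = "|"), character(1))
  expect_true(all(c("1,2,4|1,2,4", "1,2,5|1,2,5", "1,3|1,3") %in% keys))
  # matched pairs agree with exhaustive enumeration on random instances
  for (seed in 1:40) {
    pair <- random_hierarchy_pair(seed)
    ov <- cluster_overlap_matrix(pair$a$members, pair$b$members)
    got <- sort(vapply(match_paths(pair$a, pair$b, ov = ov), function(m)
      paste(paste(m$path_a, collapse = ","), paste(m$path_b, collapse = ","),
            sep = "|"), character(1)))
    expect_equal(got, oracle_match_paths(pair$a, pair$b, ov),
                 info = paste("seed", seed))
  }
})

test_that("an uninformative shared root is trimmed from matched paths", {
  # two datasets, each: root containing everything, one branch per block;
  # blocks A and B are shared, the branches below the root are disjoint
  mk <- function(bg) {
    members <- list("1" = c(paste0("A", 1:10), paste0("B", 1:10), bg),
                    "2" = paste0("A", 1:10), "3" = paste0("B", 1:10))
    dag_hierarchy(3, cbind(c(1, 1), c(2, 3)), levels = c(1, 2, 2),
                  members = members)
  }
  ha <- mk(paste0("x", 1:5)); hb <- mk(paste0("y", 1:5))
  ov <- cluster_overlap_matrix(ha$members, hb$members)
  ms <- match_paths(ha, hb, ov = ov)
  tr <- trim_path_tops(ms, ha, hb, ov)
  for (m in tr) {
    expect_false("1" %in% m$path_a)
    expect_false("1" %in% m$path_b)
  }
  # with no shared top nodes the matches pass through unchanged
  single <- list(list(path_a = c("2"), path_b = c("2")))
  expect_equal(trim_path_tops(single, ha, hb, ov), single)
})

test_that("mergeable path groups are the maximal cliques of the relation", {
  # dataset 1 paths p1, p2, p3 share the top node; p1/p2 have overlapping
  # matches in dataset 2, p3's match is elsewhere
  matches <- list(
    list(path_a = c("1", "2"), path_b = c("10", "11")),
    list(path_a = c("1", "3"), path_b = c("10", "12")),
    list(path_a = c("1", "4"), path_b = c("20", "21")))
  ov22 <- matrix(FALSE, 5, 5,
                 dimnames = list(c("10", "11", "12", "20", "21"),
                                 c("10", "11", "12", "20", "21")))
  diag(ov22) <- TRUE
  ov22[c("10", "11", "12"), c("10", "11", "12")] <- TRUE  # p1/p2 partners overlap
  ov11 <- diag(4) > 0
  dimnames(ov11) <- list(as.character(1:4), as.character(1:4))
  subs <- group_mergeable_paths(list("1|2" = matches),
                                list("1|1" = ov11, "2|2" = ov22),
                                n_datasets = 2)
  d1 <- subs[[1]]
  key <- vapply(d1, function(s) paste(sort(s$nodes), collapse = ","),
                character(1))
  expect_setequal(key, c("1,2,3", "1,4"))
  expect_setequal(d1[[which(key == "1,2,3")]]$edges, c("1->2", "1->3"))
  # clique grouping matches brute-force maximal cliques on random relations
  set.seed(44)
  for (trial in 1:20) {
    n <- sample(4:8, 1)
    adj <- matrix(FALSE, n, n)
    adj[upper.tri(adj)] <- runif(n * (n - 1) / 2) < 0.4
    adj <- adj | t(adj)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    got <- sort(vapply(igraph::max_cliques(g), function(cl)
      paste(sort(as.integer(cl)), collapse = ","), character(1)))
    expect_equal(got, oracle_max_cliques(adj), info = paste("trial", trial))
  }
})

test_that("NMF decomposition recovers the two planted components", {
  toy <- nmf_subgraph_toy()
  A <- subgraph_matrix(toy$subgraphs, toy$hier)
  expect_equal(dim(A), c(4, 8))
  expect_equal(unname(rowSums(A)), c(3, 3, 4, 2))
  hits <- 0
  for (s in 1:10) {
    comps <- nmf_components(A, k_range = 2, seed = s)
    keys <- lapply(comps, sort)
    if (length(keys) == 2 &&
        any(vapply(keys, identical, logical(1), toy$target[[1]])) &&
        any(vapply(keys, identical, logical(1), toy$target[[2]])))
      hits <- hits + 1
  }
  expect_gte(hits, 5)  # recovered in at least half the seeded restarts
  # a one-row matrix yields at most its own edge set
  comps1 <- nmf_components(A[1, , drop = FALSE], k_range = 2, seed = 1)
  for (cc in comps1) expect_true(all(cc %in% colnames(A)[A[1, ] == 1]))
  # rank-1 matrix (identical rows): a single unique component
  A1 <- A[c(3, 3, 3), ]
  comps_r1 <- nmf_components(A1, k_range = 2, seed = 2)
  expect_equal(length(comps_r1), 1)
  expect_equal(sort(comps_r1[[1]]), sort(colnames(A)[A[3, ] == 1]))
  # disconnected edge sets are discarded
  A2 <- rbind(c(1, 1, 0, 0, 1, 1, 0, 0))
  colnames(A2) <- colnames(A)
  expect_length(nmf_components(A2, k_range = 2, seed = 3), 0)
})

test_that("component merging follows the 75% incident-cluster rule", {
  toy <- nmf_subgraph_toy()
  ids <- as.character(1:9)
  ov <- matrix(FALSE, 9, 9, dimnames = list(ids, ids))
  diag(ov) <- TRUE
  comps <- list(list(dataset = 1, edges = toy$target[[1]]),
                list(dataset = 1, edges = toy$target[[2]]))
  # components {e1,e2,e4} and {e1,e2,e3} touch clusters {1,2,3,5} and
  # {1,2,3,4}: 3 of 4 matched on both sides = 75% -> merged
  metas <- merge_components(comps, list("1|1" = ov), merge_frac = 0.75)
  expect_length(metas, 1)
  expect_setequal(metas[[1]]$edges_by_dataset[["1"]],
                  union(toy$target[[1]], toy$target[[2]]))
  # identical components always merge; raising the bar above 75% separates
  # the toy pair
  expect_length(merge_components(comps[c(1, 1)], list("1|1" = ov)), 1)
  expect_length(merge_components(comps, list("1|1" = ov), merge_frac = 0.8), 2)
  # disjoint components stay separate meta clusters
  far <- list(list(dataset = 1, edges = c("1->2", "2->3")),
              list(dataset = 1, edges = c("5->8", "5->9")))
  expect_length(merge_components(far, list("1|1" = ov)), 2)
})

test_that("consensus picks the trial with smallest total Hamming distance", {
  toy <- consensus_trials_toy()
  cons <- consensus_meta(toy$trials, toy$universe)
  expect_equal(cons$trial_id, 5L)
  expect_equal(which.min(cons$distances), 5L)
  # all-identical trials have zero total distance
  same <- consensus_meta(toy$trials[c(5, 5, 5)], toy$universe)
  expect_equal(unname(same$distances), c(0, 0, 0))
  # medoid equals a brute-force computation on random trials
  set.seed(55)
  for (trial in 1:10) {
    u <- paste(1, 1:6, sep = ":")
    trs <- lapply(1:3, function(i) {
      grp <- split(1:6, sample(1:2, 6, replace = TRUE))
      grp <- Filter(function(g) length(g) > 1, grp)
      lapply(grp, function(g)
        list(edges_by_dataset = list(`1` = paste(g[-length(g)], g[-1],
                                                 sep = "->"))))
    })
    got <- consensus_meta(trs, u)$trial_id
    members <- lapply(trs, function(tr)
      lapply(tr, function(m) {
        ends <- unique(unlist(strsplit(m$edges_by_dataset[["1"]], "->")))
        paste(1, ends, sep = ":")
      }))
    expect_equal(got, oracle_medoid(members, u), info = paste("trial", trial))
  }
})

test_that("meta characterization aggregates scores and ranks", {
  # assignment with one meta over a 4-node chain in one dataset
  h <- dag_hierarchy(4, cbind(1:3, 2:4))
  asg <- structure(list(
    assignments = setNames(list(1L, 1L, 1L, integer(0)),
                           paste(1, 1:4, sep = ":")),
    metas = list(list(edges_by_dataset = list(`1` = c("1->2", "2->3")))),
    orphans = "1:4"), class = "MetaClusterAssignment")
  scores <- setNames(c(6, 6, 6, 1), as.character(1:4))
  expect_equal(meta_enrichment_score(asg, 1, 1, h, scores), 6)
  # no >= 3-node path clears the cutoff -> absent
  expect_true(is.na(meta_enrichment_score(asg, 1, 1, h,
                                          setNames(c(6, 1, 6, 1), 1:4))))
  # hand-computed geometric mean over the path nodes
  s2 <- setNames(c(4, 9, 16, 1), as.character(1:4))
  expect_equal(meta_enrichment_score(asg, 1, 1, h, s2, p_cut = 1e-3),
               exp(mean(log(c(4, 9, 16)))))
  # rank averaging: members ranked 1 and 3 average to 2
  ranks <- list(setNames(c(1, 3, 2, 4), as.character(1:4)))
  asg2 <- asg
  asg2$assignments <- setNames(list(1L, 1L, integer(0), integer(0)),
                               paste(1, 1:4, sep = ":"))
  expect_equal(unname(meta_pdiff_ranks(asg2, ranks)[1]), 2)
  # all clusters in one meta: the rank-sum identity (n + 1) / 2
  asg3 <- asg
  asg3$assignments <- setNames(as.list(rep(1L, 4)), paste(1, 1:4, sep = ":"))
  expect_equal(unname(meta_pdiff_ranks(asg3, ranks)[1]), 2.5)
})

test_that("shared gene-set selection needs two supporting datasets", {
  sc <- array(NA_real_, dim = c(2, 3, 3),
              dimnames = list(NULL, NULL, c("S1", "S2", "S3")))
  sc[1, , "S1"] <- c(5, 4, NA)   # meta 1: enriched in 2 datasets
  sc[1, , "S2"] <- c(5, 1, NA)   # only 1 dataset
  sc[2, , "S3"] <- c(4, 4, 4)    # meta 2: 3 datasets
  sel <- select_shared_gensets(sc, min_datasets = 2, p_cut = 1e-3)
  expect_setequal(sel$set, c("S1", "S3"))
  sel2 <- select_shared_gensets(sc, focal = c(1, 2))
  expect_equal(sel2$group[sel2$set == "S1"], 1L)
  expect_equal(sel2$group[sel2$set == "S3"], 2L)
})

test_that("alignment recovers planted shared blocks and orphans private ones", {
  suite <- simulate_hierarchy_suite(seed = 11)
  hiers <- lapply(seq_along(suite$datasets), function(d) {
    reduce_hierarchy(build_full_hierarchy(suite$datasets[[d]], k_max = 10,
                                          n_runs = 25, seed = 100 + d))
  })
  asg <- align_hierarchies(hiers, n_trials = 15, seed = 99)
  expect_gte(length(asg$metas), 2)
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  shared <- Filter(function(b) b$shared, suite$blocks)
  for (b in shared)
    expect_gte(max(vapply(asg$genes, jac, numeric(1), b = b$genes)), 0.5)
  # private blocks end up in the orphan set
  graphs <- lapply(hiers, `[[`, "graph")
  for (b in Filter(function(b) !b$shared, suite$blocks)) {
    d <- b$datasets[1]
    ids <- names(graphs[[d]]$members)[vapply(graphs[[d]]$members, function(g)
      jac(g, b$genes) > 0.5, logical(1))]
    keys <- paste(d, ids, sep = ":")
    expect_true(all(keys %in% asg$orphans))
  }
  # assignments plus orphans cover every reduced cluster exactly
  expect_setequal(c(asg$orphans,
                    names(asg$assignments)[lengths(asg$assignments) > 0]),
                  names(asg$assignments))
})
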