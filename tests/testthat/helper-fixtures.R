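# Shared fixture builders. Everything is generated in code; no data files.

# small expression matrix with optional missing entries
toy_matrix <- function(values, tumor, genes = NULL, cells = NULL) {
  values <- as.matrix(values)
  rownames(values) <- genes %||% paste0("g", seq_len(nrow(values)))
  colnames(values) <- cells %||% paste0("c", seq_len(ncol(values)))
  expression_matrix(values, tumor = tumor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random masked matrix: `frac` of entries missing, no all-missing gene
random_masked_matrix <- function(n_genes, n_cells, frac = 0.3, n_tumors = 2,
                                 seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * n_cells), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("c", seq_len(n_cells))))
  mask <- matrix(runif(n_genes * n_cells) < frac, n_genes)
  mask[, 1] <- FALSE  # keep every gene observed somewhere
  v[mask] <- NA
  expression_matrix(v, tumor = rep(paste0("t", seq_len(n_tumors)),
                                   length.out = n_cells))
}

# hierarchy from an edge list over nodes 1..n with single-gene members
dag_hierarchy <- function(n, edges, levels = NULL, members = NULL) {
  nodes <- data.frame(id = seq_len(n),
                      level = levels %||% seq_len(n),
                      size = 1)
  if (is.null(members))
    members <- setNames(lapply(seq_len(n), function(i) paste0("g", i)),
                        seq_len(n))
  nodes$size <- lengths(members[as.character(nodes$id)])
  e <- if (length(edges)) data.frame(from = edges[, 1], to = edges[, 2],
                                     weight = 1)
       else data.frame(from = integer(), to = integer(), weight = numeric())
  cluster_hierarchy(nodes, members, e)
}

# the 11-node two-subgraph reduction toy: v4 and v8 are the only multi-node
# chain seeds; v5 and v9 are appended at the chain bottoms
reduction_toy_hierarchy <- function() {
  edges <- cbind(c(1, 1, 2, 2, 3, 3, 4, 5, 5, 8, 9, 9),
                 c(2, 3, 6, 7, 4, 7, 5, 6, 7, 9, 10, 11))
  dag_hierarchy(11, edges, levels = c(1, 2, 2, 3, 4, 5, 5, 1, 2, 3, 3))
}

# NMF toy: a small hierarchy whose first four edges e1..e4 carry four
# subgraphs p1..p4 that decompose into components {e1,e2,e4} and {e1,e2,e3}
nmf_subgraph_toy <- function() {
  hedges <- cbind(c(1, 2, 3, 3, 4, 4, 5, 5), c(2, 3, 4, 5, 6, 7, 8, 9))
  h <- dag_hierarchy(9, hedges, levels = c(1, 2, 3, 4, 4, 5, 5, 5, 5))
  ekeys <- paste(hedges[, 1], hedges[, 2], sep = "->")
  subgraphs <- list(
    list(dataset = 1, nodes = NULL, edges = ekeys[c(1, 2, 4)]),
    list(dataset = 1, nodes = NULL, edges = ekeys[c(1, 2, 3)]),
    list(dataset = 1, nodes = NULL, edges = ekeys[c(1, 2, 3, 4)]),
    list(dataset = 1, nodes = NULL, edges = ekeys[c(1, 2)]))
  list(hier = h, subgraphs = subgraphs, edge_keys = ekeys,
       target = list(sort(ekeys[c(1, 2, 4)]), sort(ekeys[c(1, 2, 3)])))
}

# five meta-clustering trials over ten clusters where trial 5 is the medoid:
# trials 1-4 perturb the consensus grouping in different directions
consensus_trials_toy <- function() {
  u <- paste(1, 1:10, sep = ":")
  mk_trial <- function(groups) {
    lapply(groups, function(g)
      list(edges_by_dataset = list(`1` = paste(g[-length(g)], g[-1],
                                               sep = "->"))))
  }
  trials <- list(
    mk_trial(list(1:4, 6:10)),        # cluster 5 dropped
    mk_trial(list(1:6, 7:10)),        # cluster 6 moved
    mk_trial(list(1:5, 5:10)),        # cluster 5 shared
    mk_trial(list(2:5, 6:10)),        # cluster 1 dropped
    mk_trial(list(1:5, 6:10)))        # the consensus grouping
  list(trials = trials, universe = u)
}

# random layered DAG (for oracle-equivalence tests); returns a hierarchy
random_dag <- function(seed, max_nodes = 30) {
  set.seed(seed)
  n_levels <- sample(3:5, 1)
  per <- sample(1:4, n_levels, replace = TRUE)
  while (sum(per) > max_nodes) per <- pmax(1, per - 1)
  ids <- split(seq_len(sum(per)), rep(seq_len(n_levels), per))
  edges <- NULL
  for (l in seq_len(n_levels - 1)) {
    for (child in ids[[l + 1]]) {
      parents <- sample(ids[[l]], sample(1:min(2, length(ids[[l]])), 1))
      edges <- rbind(edges, cbind(parents, child))
    }
  }
  dag_hierarchy(sum(per), edges,
                levels = rep(seq_len(n_levels), per))
}

# random pair of tiny hierarchies over a shared gene pool, for path matching
random_hierarchy_pair <- function(seed, n_pool = 40) {
  set.seed(seed)
  pool <- paste0("G", seq_len(n_pool))
  mk <- function() {
    n_levels <- 3
    per <- c(1, 2, sample(2:3, 1))
    n <- sum(per)
    lv <- rep(seq_len(n_levels), per)
    members <- list()
    members[["1"]] <- pool
    halves <- split(sample(pool), rep(1:2, length.out = n_pool))
    members[["2"]] <- halves[[1]]; members[["3"]] <- halves[[2]]
    for (i in 4:n) {
      parent <- sample(2:3, 1)
      members[[as.character(i)]] <- sample(members[[as.character(parent)]],
                                           ceiling(length(members[[as.character(parent)]]) / 2))
    }
    edges <- NULL
    for (i in 4:n)  # attach each leaf to the half it came from
      edges <- rbind(edges,
                     c(ifelse(length(intersect(members[[as.character(i)]],
                                               members[["2"]])) >
                              length(members[[as.character(i)]]) / 2, 2, 3), i))
    edges <- rbind(c(1, 2), c(1, 3), edges)
    dag_hierarchy(n, edges, levels = lv, members = members)
  }
  list(a = mk(), b = mk())
}
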