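# ---- cluster overlap (two-tier rule) ---------------------------------------

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Pairwise cluster-overlap relation between two datasets
#'
#' Two clusters overlap when their Jaccard index exceeds `jaccard_hi`, or when
#' it lies in `[jaccard_lo, jaccard_hi]` and each cluster is within the other
#' dataset's top `top_n` clusters ranked by that overlap ratio (mutual
#' top-ten fallback).
#'
#' @param members_a,members_b named lists of cluster gene sets (node id ->
#'   genes), one per dataset; pass the same list twice for a within-dataset
#'   relation.
#' @param jaccard_hi,jaccard_lo the two Jaccard tiers (defaults 0.2, 0.1).
#' @param top_n mutual-rank window (default 10).
#' @return logical matrix, rows = clusters of a, columns = clusters of b.
#' @export
cluster_overlap_matrix <- function(members_a, members_b, jaccard_hi = 0.2,
                                   jaccard_lo = 0.1, top_n = 10) {
  J <- matrix(0, length(members_a), length(members_b),
              dimnames = list(names(members_a), names(members_b)))
  for (i in seq_along(members_a))
    for (j in seq_along(members_b))
      J[i, j] <- jaccard(members_a[[i]], members_b[[j]])
  rank_rows <- t(apply(-J, 1, rank, ties.method = "min"))  # rank of b among a's partners
  rank_cols <- apply(-J, 2, rank, ties.method = "min")     # rank of a among b's partners
  ov <- J > jaccard_hi |
    (J >= jaccard_lo & J <= jaccard_hi &
       rank_rows <= top_n & rank_cols <= top_n)
  dimnames(ov) <- dimnames(J)
  ov
}

#' Do two clusters overlap under the two-tier rule?
#'
#' Convenience wrapper over [cluster_overlap_matrix()]; the top-ten fallback is
#' evaluated against all clusters of the two datasets.
#'
#' @param id_a,id_b node ids (coercible to character) of the two clusters.
#' @param members_a,members_b the datasets' full cluster gene-set lists.
#' @param ... passed to [cluster_overlap_matrix()].
#' @return logical.
#' @export
clusters_overlap <- function(id_a, id_b, members_a, members_b, ...) {
  ov <- cluster_overlap_matrix(members_a, members_b, ...)
  ov[as.character(id_a), as.character(id_b)]
}

# ---- path enumeration and matching -----------------------------------------

# all contiguous subpaths (length >= min_len) of all root-leaf paths
all_subpaths <- function(h, min_len = 1) {
  paths <- root_leaf_paths(h)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (p in paths) {
    n <- length(p)
    if (n < min_len) next
    for (i in seq_len(n - min_len + 1L)) for (j in (i + min_len - 1L):n) {
      sp <- p[i:j]
      key <- paste(sp, collapse = "\r")
      if (!exists(key, envir = seen)) {
        assign(key, TRUE, envir = seen)
        out[[length(out) + 1L]] <- sp
      }
    }
  }
  out
}

# is `a` a contiguous subsequence of `b`?
is_subpath <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na > nb) return(FALSE)
  for (s in seq_len(nb - na + 1L))
    if (identical(b[s:(s + na - 1L)], a)) return(TRUE)
  FALSE
}

path_pair_overlap_frac <- function(pa, pb, ov) {
  mean(ov[pa, pb, drop = FALSE])
}

#' Maximally matched path pairs between two hierarchies
#'
#' Two (sub)paths are matched when more than `match_frac` of their member
#' cluster pairs overlap under the two-tier rule; a matched pair is maximal
#' when no matched pair of longer containing paths exists. Only subpaths with
#' at least `min_len` nodes take part: a path match is evidence of shared
#' lineage structure, and a single cluster carries no lineage (edge)
#' information - it can pair with almost any coarse foreign path through the
#' overlap fallback while the trimming rule has no downstream portion to test.
#'
#' @param hier_a,hier_b `ReducedHierarchy` (or `ClusterHierarchy`) objects.
#' @param ov logical overlap matrix between the two datasets' clusters
#'   (defaults to [cluster_overlap_matrix()] on their members).
#' @param match_frac matched-pair threshold (default 0.9).
#' @param min_len minimum nodes per side (default 2).
#' @param ... passed to [cluster_overlap_matrix()] when `ov` is NULL.
#' @return list of matches, each `list(path_a, path_b)` of node-id character
#'   vectors.
#' @export
match_paths <- function(hier_a, hier_b, ov = NULL, match_frac = 0.9,
                        min_len = 2, ...) {
  ga <- if (inherits(hier_a, "ReducedHierarchy")) hier_a$graph else hier_a
  gb <- if (inherits(hier_b, "ReducedHierarchy")) hier_b$graph else hier_b
  if (is.null(ov))
    ov <- cluster_overlap_matrix(ga$members, gb$members, ...)
  pa_all <- all_subpaths(ga, min_len = min_len)
  pb_all <- all_subpaths(gb, min_len = min_len)
  # a cluster overlapping nothing in the other dataset fails a full row/column
  # of pairs, so a path with dead/length >= 1 - match_frac can never match
  dead_a <- rownames(ov)[rowSums(ov) == 0]
  dead_b <- colnames(ov)[colSums(ov) == 0]
  pa_all <- Filter(function(p)
    mean(p %in% dead_a) < 1 - match_frac, pa_all)
  pb_all <- Filter(function(p)
    mean(p %in% dead_b) < 1 - match_frac, pb_all)
  matched <- list()
  for (i in seq_along(pa_all)) for (j in seq_along(pb_all)) {
    if (path_pair_overlap_frac(pa_all[[i]], pb_all[[j]], ov) > match_frac)
      matched[[length(matched) + 1L]] <- list(path_a = pa_all[[i]],
                                              path_b = pb_all[[j]])
  }
  if (!length(matched)) return(list())
  keep <- rep(TRUE, length(matched))
  for (i in seq_along(matched)) {
    for (j in seq_along(matched)) {
      if (i == j) next
      larger <- (length(matched[[j]]$path_a) > length(matched[[i]]$path_a) ||
                 length(matched[[j]]$path_b) > length(matched[[i]]$path_b))
      if (larger &&
          is_subpath(matched[[i]]$path_a, matched[[j]]$path_a) &&
          is_subpath(matched[[i]]$path_b, matched[[j]]$path_b)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  matched[keep]
}

#' Trim poorly supported top nodes from matched paths
#'
#' For each matched path, the top node is removed when the complementary paths
#' (root-leaf paths of the same hierarchy passing through the top node whose
#' below-top portions are disjoint from the path's) and the path's matched
#' partners in the other dataset are poorly overlapped below the top nodes -
#' i.e. more than half of those cluster pairs do not overlap. The typical case
#' is a shared root (the all-genes cluster) joining branches that have nothing
#' to do with each other.
#'
#' The rule is applied to both sides of every match and iterated to a fixed
#' point, since trimming one side's top can expose the other side's. Trimmed
#' pairs must still be matched paths: pairs whose overlap fraction falls to
#' `match_frac` or below after trimming are dropped.
#'
#' @param matches output of [match_paths()] for one dataset pair.
#' @param hier_a,hier_b the two hierarchies the matches came from.
#' @param ov the overlap matrix used to produce `matches`.
#' @param match_frac the matched-pair threshold used in [match_paths()]
#'   (default 0.9).
#' @param max_iter iteration cap (default 10).
#' @return the trimmed match list (empty paths dropped, duplicates removed).
#' @export
trim_path_tops <- function(matches, hier_a, hier_b, ov, match_frac = 0.9,
                           max_iter = 10) {
  if (!length(matches)) return(matches)
  ga <- if (inherits(hier_a, "ReducedHierarchy")) hier_a$graph else hier_a
  gb <- if (inherits(hier_b, "ReducedHierarchy")) hier_b$graph else hier_b
  rl <- list(path_a = root_leaf_paths(ga), path_b = root_leaf_paths(gb))
  trim_side <- function(matches, side) {
    other <- if (side == "path_a") "path_b" else "path_a"
    flags <- rep(FALSE, length(matches))
    for (i in seq_along(matches)) {
      p1 <- matches[[i]][[side]]
      if (length(p1) < 2) next
      top <- p1[1]
      rest <- p1[-1]
      comp <- list()
      for (q in rl[[side]]) {
        pos <- match(top, q)
        if (is.na(pos) || pos == length(q)) next
        below <- q[(pos + 1L):length(q)]
        if (!length(intersect(below, rest)))
          comp[[length(comp) + 1L]] <- below
      }
      if (!length(comp)) next
      partners <- lapply(matches[vapply(matches, function(mm)
        identical(mm[[side]], p1), logical(1))], function(mm) mm[[other]])
      partners <- lapply(partners, function(q) if (length(q) >= 2) q[-1] else q)
      comp_nodes <- unique(unlist(comp))
      part_nodes <- unique(unlist(partners))
      if (!length(comp_nodes) || !length(part_nodes)) next
      sub <- if (side == "path_a") ov[comp_nodes, part_nodes, drop = FALSE]
             else t(ov)[comp_nodes, part_nodes, drop = FALSE]
      if (mean(!sub) > 0.5) flags[i] <- TRUE
    }
    flags
  }
  cur <- matches
  for (it in seq_len(max_iter)) {
    fa <- trim_side(cur, "path_a")
    fb <- trim_side(cur, "path_b")
    if (!any(fa) && !any(fb)) break
    out <- list()
    seen <- character(0)
    for (i in seq_along(cur)) {
      pa <- cur[[i]]$path_a
      pb <- cur[[i]]$path_b
      if (fa[i]) pa <- pa[-1]
      if (fb[i]) pb <- pb[-1]
      if (!length(pa) || !length(pb)) next
      key <- paste(paste(pa, collapse = ","), paste(pb, collapse = ","),
                   sep = "|")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(path_a = pa, path_b = pb)
    }
    cur <- out
    if (!length(cur)) break
  }
  Filter(function(m)
    path_pair_overlap_frac(m$path_a, m$path_b, ov) > match_frac, cur)
}

#' Group mergeable maximal paths into subgraphs
#'
#' Two maximal paths of one dataset are mergeable when their top nodes
#' coincide and, in at least one partner dataset, a matched path of the first
#' and a matched path of the second overlap in more than `match_frac` of their
#' member cluster pairs. Maximal cliques of the mergeable relation become the
#' path groups; each group spans a subgraph (the union of the paths' nodes and
#' consecutive edges).
#'
#' @param matches_by_pair named list of match lists as produced by
#'   [match_paths()] (after [trim_path_tops()]); names of the form `"i|j"`
#'   giving the two dataset indices.
#' @param ov_list named list of the corresponding overlap matrices (same
#'   names); within-dataset overlap matrices under names `"i|i"` are required
#'   for comparing matched paths of a common partner.
#' @param n_datasets number of datasets.
#' @param match_frac threshold for "considerably overlapped" (default 0.9).
#' @return list (one element per dataset) of subgraph lists; each subgraph is
#'   `list(dataset, nodes, edges)` with edges as `"from->to"` keys.
#' @export
group_mergeable_paths <- function(matches_by_pair, ov_list, n_datasets,
                                  match_frac = 0.9) {
  path_key <- function(p) paste(p, collapse = ",")
  out <- vector("list", n_datasets)
  for (d in seq_len(n_datasets)) {
    # collect this dataset's maximal paths and their partners per other dataset
    paths <- list()
    partner_of <- list()  # path key -> list(partner dataset -> list of paths)
    for (nm in names(matches_by_pair)) {
      idx <- as.integer(strsplit(nm, "|", fixed = TRUE)[[1]])
      ms <- matches_by_pair[[nm]]
      if (!length(ms)) next
      for (mm in ms) {
        if (idx[1] == d) {
          p <- mm$path_a; q <- mm$path_b; pd <- idx[2]
        } else if (idx[2] == d) {
          p <- mm$path_b; q <- mm$path_a; pd <- idx[1]
        } else next
        k <- path_key(p)
        if (is.null(partner_of[[k]])) {
          partner_of[[k]] <- list()
          paths[[k]] <- p
        }
        pdk <- as.character(pd)
        partner_of[[k]][[pdk]] <- c(partner_of[[k]][[pdk]], list(q))
      }
    }
    if (!length(paths)) { out[[d]] <- list(); next }
    keys <- names(paths)
    n <- length(keys)
    mergeable <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (j <= i) next
      p <- paths[[keys[i]]]; q <- paths[[keys[j]]]
      if (p[1] != q[1]) next                      # top nodes must coincide
      common <- intersect(names(partner_of[[keys[i]]]),
                          names(partner_of[[keys[j]]]))
      hit <- FALSE
      for (pd in common) {
        ovd <- ov_list[[paste(pd, pd, sep = "|")]]
        for (mp in partner_of[[keys[i]]][[pd]]) {
          for (mq in partner_of[[keys[j]]][[pd]]) {
            if (path_pair_overlap_frac(mp, mq, ovd) > match_frac) {
              hit <- TRUE; break
            }
          }
          if (hit) break
        }
        if (hit) break
      }
      mergeable[i, j] <- mergeable[j, i] <- hit
    }
    g <- igraph::graph_from_adjacency_matrix(mergeable, mode = "undirected")
    cliques <- igraph::max_cliques(g)
    subs <- list()
    seen <- character(0)
    for (cl in cliques) {
      grp <- keys[as.integer(cl)]
      nodes <- unique(unlist(paths[grp]))
      edges <- unique(unlist(lapply(paths[grp], function(p) {
        if (length(p) < 2) character(0)
        else paste(p[-length(p)], p[-1], sep = "->")
      })))
      key <- paste(sort(c(nodes, edges)), collapse = ";")
      if (key %in% seen) next
      seen <- c(seen, key)
      subs[[length(subs) + 1L]] <- list(dataset = d, nodes = nodes,
                                        edges = edges)
    }
    out[[d]] <- subs
  }
  out
}

# ---- NMF over subgraph-edge membership matrices ----------------------------

#' Binary subgraph x edge membership matrix of one dataset
#'
#' @param subgraphs the dataset's subgraph list from
#'   [group_mergeable_paths()].
#' @param hier the dataset's hierarchy (column order = its edge list).
#' @return binary matrix, rows = subgraphs, columns = `"from->to"` edge keys.
#' @export
subgraph_matrix <- function(subgraphs, hier) {
  g <- if (inherits(hier, "ReducedHierarchy")) hier$graph else hier
  edge_keys <- paste(g$edges$from, g$edges$to, sep = "->")
  A <- matrix(0, length(subgraphs), length(edge_keys),
              dimnames = list(NULL, edge_keys))
  for (i in seq_along(subgraphs))
    A[i, intersect(subgraphs[[i]]$edges, edge_keys)] <- 1
  A
}

# multiplicative-update NMF with Frobenius objective
nmf_mu <- function(A, k, n_iter = 500, eps = 1e-9) {
  n <- nrow(A); m <- ncol(A)
  W <- matrix(stats::runif(n * k), n, k)
  H <- matrix(stats::runif(k * m), k, m)
  for (it in seq_len(n_iter)) {
    H <- H * (t(W) %*% A) / (t(W) %*% W %*% H + eps)
    W <- W * (A %*% t(H)) / (W %*% H %*% t(H) + eps)
  }
  list(W = W, H = H)
}

# are these edge keys one connected (undirected) subgraph?
edges_connected <- function(edge_keys) {
  if (!length(edge_keys)) return(FALSE)
  ends <- do.call(rbind, strsplit(edge_keys, "->", fixed = TRUE))
  g <- igraph::graph_from_edgelist(ends, directed = FALSE)
  igraph::count_components(g) == 1
}

#' Candidate meta-cluster components from NMF of a subgraph matrix
#'
#' For each `K` in `k_range`, factorizes `A ~ W H` by multiplicative-update
#' NMF, quantizes each component (row of `H`) by keeping entries at least
#' `quantize_frac` of the row maximum, and pools over `K` the unique quantized
#' components that have more than one edge and form a single connected
#' subgraph.
#'
#' @param A binary subgraph x edge matrix from [subgraph_matrix()].
#' @param k_range candidate component counts (default `2:10`).
#' @param quantize_frac quantization threshold (default 0.1).
#' @param n_iter NMF iterations per factorization (default 500).
#' @param seed optional integer seed for the random initializations.
#' @return list of components, each a character vector of edge keys.
#' @export
nmf_components <- function(A, k_range = 2:10, quantize_frac = 0.1,
                           n_iter = 500, seed = NULL) {
  if (!nrow(A) || !ncol(A)) return(list())
  if (!is.null(seed)) set.seed(seed)
  comps <- list()
  seen <- character(0)
  for (k in k_range) {
    fit <- nmf_mu(A, k, n_iter = n_iter)
    for (r in seq_len(k)) {
      h <- fit$H[r, ]
      mx <- max(h)
      if (mx <= 0) next
      edges <- colnames(A)[h >= quantize_frac * mx]
      if (length(edges) < 2) next
      if (!edges_connected(edges)) next
      key <- paste(sort(edges), collapse = ";")
      if (key %in% seen) next
      seen <- c(seen, key)
      comps[[length(comps) + 1L]] <- edges
    }
  }
  comps
}

# ---- merging components into meta clusters ---------------------------------

# split an edge key into its endpoints
edge_ends <- function(edge_keys) {
  if (!length(edge_keys))
    return(matrix(character(0), 0, 2))
  do.call(rbind, strsplit(edge_keys, "->", fixed = TRUE))
}

# clusters incident to a component's edges
component_nodes <- function(edge_keys) unique(as.vector(edge_ends(edge_keys)))

# number of clusters of component a overlapping >= 1 cluster of component b
matched_node_count <- function(nodes_a, nodes_b, ov) {
  if (!length(nodes_a) || !length(nodes_b)) return(0L)
  sum(vapply(nodes_a, function(u) any(ov[u, nodes_b]), logical(1)))
}

#' Merge NMF components (within and across datasets) into meta clusters
#'
#' Components are collections of hierarchy edges. Two components are mergeable
#' when, in both directions, at least `merge_frac` of the clusters incident to
#' one component's edges overlap a cluster incident to the other's, under the
#' two-tier rule (within one dataset a cluster always overlaps itself, so
#' same-dataset matching subsumes shared edges). Maximal cliques of the
#' mergeable relation are combined into meta clusters.
#'
#' @param components list of `list(dataset, edges)` pooled over datasets.
#' @param ov_list named list of overlap matrices (`"i|j"` for every ordered
#'   dataset pair including `i == i`).
#' @param merge_frac the overlap fraction (default 0.75).
#' @return list of meta clusters, each `list(edges_by_dataset = named list of
#'   edge-key vectors)`.
#' @export
merge_components <- function(components, ov_list, merge_frac = 0.75) {
  n <- length(components)
  if (!n) return(list())
  mergeable <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    ci <- components[[i]]; cj <- components[[j]]
    ni <- component_nodes(ci$edges); nj <- component_nodes(cj$edges)
    mij <- matched_node_count(ni, nj,
                              ov_list[[paste(ci$dataset, cj$dataset,
                                             sep = "|")]])
    mji <- matched_node_count(nj, ni,
                              ov_list[[paste(cj$dataset, ci$dataset,
                                             sep = "|")]])
    mergeable[i, j] <- mergeable[j, i] <-
      (mij >= merge_frac * length(ni)) && (mji >= merge_frac * length(nj))
  }
  g <- igraph::graph_from_adjacency_matrix(mergeable, mode = "undirected")
  cliques <- igraph::max_cliques(g)
  metas <- list()
  seen <- character(0)
  for (cl in cliques) {
    idx <- as.integer(cl)
    by_ds <- list()
    for (i in idx) {
      dk <- as.character(components[[i]]$dataset)
      by_ds[[dk]] <- unique(c(by_ds[[dk]], components[[i]]$edges))
    }
    key <- paste(vapply(sort(names(by_ds)), function(d)
      paste(d, paste(sort(by_ds[[d]]), collapse = ","), sep = ":"),
      character(1)), collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    metas[[length(metas) + 1L]] <- list(edges_by_dataset = by_ds)
  }
  metas
}

# cluster membership of a trial's meta clusters: (dataset, node) pairs that
# are endpoints of the meta's edges
meta_members <- function(metas) {
  lapply(metas, function(m) {
    unlist(lapply(names(m$edges_by_dataset), function(d) {
      ends <- edge_ends(m$edges_by_dataset[[d]])
      paste(d, unique(as.vector(ends)), sep = ":")
    }), use.names = FALSE)
  })
}

#' Consensus meta clustering over multiple trials
#'
#' Builds, per trial, the binary co-occurrence matrix of clusters (do two
#' clusters share a meta cluster), computes Hamming distances between the
#' trials' matrices, and returns the medoid trial (smallest total distance to
#' all others; ties broken by trial order).
#'
#' @param trials list of trials, each a meta-cluster list as returned by
#'   [merge_components()].
#' @param cluster_universe character vector of all `"dataset:node"` keys.
#' @return list with `trial_id`, `metas` (the medoid trial's meta clusters)
#'   and `distances` (the total Hamming distance of each trial).
#' @export
consensus_meta <- function(trials, cluster_universe) {
  if (!length(trials)) stop("need >= 1 trial")
  n_u <- length(cluster_universe)
  cooc <- lapply(trials, function(tr) {
    M <- matrix(0L, n_u, n_u, dimnames = list(cluster_universe,
                                              cluster_universe))
    for (mem in meta_members(tr)) {
      mem <- intersect(mem, cluster_universe)
      M[mem, mem] <- 1L
    }
    M
  })
  n_t <- length(trials)
  D <- matrix(0, n_t, n_t)
  for (i in seq_len(n_t)) for (j in seq_len(n_t)) {
    if (j <= i) next
    D[i, j] <- D[j, i] <- sum(cooc[[i]] != cooc[[j]])
  }
  totals <- rowSums(D)
  best <- which.min(totals)
  list(trial_id = best, metas = trials[[best]], distances = totals)
}

# ---- top-level alignment ----------------------------------------------------

#' Align reduced hierarchies from multiple datasets into meta gene clusters
#'
#' Runs the full alignment: pairwise path matching, top trimming, mergeable
#' path grouping into subgraphs (all deterministic), then `n_trials`
#' randomized NMF decompositions of the subgraph-edge matrices followed by
#' component merging, and finally the Hamming-distance consensus over trials.
#' An optional user-supplied merge map combines meta clusters afterwards (the
#' combination of meta clusters is a curation step, never automated).
#'
#' @param hiers list of `ReducedHierarchy` objects, one per dataset.
#' @param n_trials number of randomized trials (default 100).
#' @param k_range NMF component counts (default `2:10`).
#' @param jaccard_hi,jaccard_lo,top_n overlap-rule parameters.
#' @param match_frac path-match threshold (default 0.9).
#' @param merge_frac component-merge threshold (default 0.75).
#' @param quantize_frac NMF quantization threshold (default 0.1).
#' @param merge_map optional named vector mapping meta-cluster id ->
#'   combined id (applied after consensus).
#' @param seed optional integer seed.
#' @return an object of class `MetaClusterAssignment`: list with
#'   `assignments` (named list, `"dataset:node"` -> integer vector of meta
#'   ids; empty = orphan), `metas` (edge sets per meta), `orphans`,
#'   `trial_id`, `subgraphs`, `genes` (per meta: union of member-cluster
#'   genes).
#' @export
align_hierarchies <- function(hiers, n_trials = 100, k_range = 2:10,
                              jaccard_hi = 0.2, jaccard_lo = 0.1, top_n = 10,
                              match_frac = 0.9, merge_frac = 0.75,
                              quantize_frac = 0.1, merge_map = NULL,
                              seed = NULL) {
  n_ds <- length(hiers)
  if (n_ds < 2) stop("alignment needs >= 2 datasets")
  if (!is.null(seed)) set.seed(seed)
  graphs <- lapply(hiers, function(h)
    if (inherits(h, "ReducedHierarchy")) h$graph else h)
  ov_list <- list()
  for (i in seq_len(n_ds)) for (j in seq_len(n_ds)) {
    ov_list[[paste(i, j, sep = "|")]] <-
      cluster_overlap_matrix(graphs[[i]]$members, graphs[[j]]$members,
                             jaccard_hi = jaccard_hi, jaccard_lo = jaccard_lo,
                             top_n = top_n)
  }
  matches_by_pair <- list()
  for (i in seq_len(n_ds - 1)) for (j in (i + 1):n_ds) {
    nm <- paste(i, j, sep = "|")
    ms <- match_paths(graphs[[i]], graphs[[j]], ov = ov_list[[nm]],
                      match_frac = match_frac)
    matches_by_pair[[nm]] <- trim_path_tops(ms, graphs[[i]], graphs[[j]],
                                            ov_list[[nm]],
                                            match_frac = match_frac)
  }
  subgraphs <- group_mergeable_paths(matches_by_pair, ov_list, n_ds,
                                     match_frac = match_frac)
  A_list <- lapply(seq_len(n_ds), function(d)
    subgraph_matrix(subgraphs[[d]], graphs[[d]]))
  trials <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    comps <- list()
    for (d in seq_len(n_ds)) {
      cs <- nmf_components(A_list[[d]], k_range = k_range,
                           quantize_frac = quantize_frac)
      for (cc in cs)
        comps[[length(comps) + 1L]] <- list(dataset = d, edges = cc)
    }
    trials[[t]] <- merge_components(comps, ov_list, merge_frac = merge_frac)
  }
  universe <- unlist(lapply(seq_len(n_ds), function(d)
    paste(d, as.character(graphs[[d]]$nodes$id), sep = ":")))
  cons <- consensus_meta(trials, universe)
  metas <- cons$metas
  members <- meta_members(metas)
  if (!is.null(merge_map)) {
    grp <- merge_map[as.character(seq_along(metas))]
    grp[is.na(grp)] <- as.character(seq_along(metas))[is.na(grp)]
    merged <- list(); merged_members <- list()
    for (gid in unique(grp)) {
      idx <- which(grp == gid)
      by_ds <- list()
      for (i in idx)
        for (d in names(metas[[i]]$edges_by_dataset))
          by_ds[[d]] <- unique(c(by_ds[[d]], metas[[i]]$edges_by_dataset[[d]]))
      merged[[length(merged) + 1L]] <- list(edges_by_dataset = by_ds)
      merged_members[[length(merged_members) + 1L]] <-
        unique(unlist(members[idx]))
    }
    metas <- merged
    members <- merged_members
  }
  assignments <- stats::setNames(vector("list", length(universe)), universe)
  for (k in seq_along(members))
    for (cl in members[[k]])
      assignments[[cl]] <- c(assignments[[cl]], k)
  orphans <- universe[!lengths(assignments)]
  genes <- lapply(members, function(mem) {
    unique(unlist(lapply(mem, function(key) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      graphs[[as.integer(parts[1])]]$members[[parts[2]]]
    })))
  })
  structure(list(assignments = assignments, metas = metas, orphans = orphans,
                 trial_id = cons$trial_id, subgraphs = subgraphs,
                 genes = genes),
            class = "MetaClusterAssignment")
}

#' @exportS3Method base::print
print.MetaClusterAssignment <- function(x, ...) {
  cat(sprintf("MetaClusterAssignment: %d meta clusters, %d/%d clusters assigned\n",
              length(x$metas), sum(lengths(x$assignments) > 0),
              length(x$assignments)))
  invisible(x)
}

# ---- meta-cluster characterization ------------------------------------------

#' Enrichment score of a meta cluster in one dataset
#'
#' Builds the subgraph of the dataset's reduced hierarchy spanned by the meta
#' cluster's member nodes (adding minimal connecting edges when disconnected
#' and dropping connector nodes claimed by other meta clusters), finds the
#' maximal paths of at least `min_path_len` nodes whose members all satisfy
#' the adjusted p-value cutoff, and returns the geometric mean of the
#' `-log10` adjusted p-values over the union of their nodes. `NA` when no
#' qualifying path exists.
#'
#' @param assignment a `MetaClusterAssignment`.
#' @param meta_id meta cluster index.
#' @param dataset dataset index.
#' @param hier the dataset's `ReducedHierarchy`.
#' @param scores named numeric vector of `-log10` FDR-adjusted p-values per
#'   node id for one gene set.
#' @param min_path_len minimum qualifying path length (default 3).
#' @param p_cut adjusted p-value cutoff along paths (default 1e-3).
#' @return geometric-mean score, or `NA_real_`.
#' @export
meta_enrichment_score <- function(assignment, meta_id, dataset, hier, scores,
                                  min_path_len = 3, p_cut = 1e-3) {
  g <- if (inherits(hier, "ReducedHierarchy")) hier$graph else hier
  pref <- paste0(dataset, ":")
  in_meta <- function(k) {
    ids <- names(assignment$assignments)[vapply(assignment$assignments,
                                                function(v) k %in% v,
                                                logical(1))]
    ids <- ids[startsWith(ids, pref)]
    sub("^[0-9]+:", "", ids)
  }
  nodes <- in_meta(meta_id)
  if (!length(nodes)) return(NA_real_)
  ug <- hierarchy_graph(g)
  und <- igraph::as_undirected(ug)
  node_set <- nodes
  comp <- igraph::components(igraph::induced_subgraph(und, nodes))
  if (comp$no > 1) {
    # connect components through shortest paths in the full hierarchy
    parts <- split(nodes, comp$membership[nodes])
    base <- parts[[1]]
    for (k in seq_along(parts)[-1]) {
      sp <- igraph::shortest_paths(und, from = parts[[k]][1],
                                   to = base[1])$vpath[[1]]
      node_set <- union(node_set, igraph::as_ids(sp))
      base <- union(base, parts[[k]])
    }
    others <- setdiff(unlist(lapply(setdiff(seq_along(assignment$metas),
                                            meta_id), in_meta)), nodes)
    node_set <- setdiff(node_set, setdiff(others, nodes))
    node_set <- union(node_set, nodes)
  }
  sub <- igraph::induced_subgraph(ug, intersect(igraph::V(ug)$name, node_set))
  thr <- -log10(p_cut)
  qual <- igraph::V(sub)$name[scores[igraph::V(sub)$name] >= thr]
  if (length(qual) < min_path_len) return(NA_real_)
  qg <- igraph::induced_subgraph(sub, qual)
  # all maximal directed paths within the qualifying subgraph
  adj <- igraph::as_adj_list(qg, mode = "out")
  nm <- igraph::V(qg)$name
  paths <- list()
  walk <- function(path) {
    nxt <- adj[[path[length(path)]]]
    if (!length(nxt)) {
      paths[[length(paths) + 1L]] <<- nm[path]
    } else for (v in as.integer(nxt)) walk(c(path, v))
  }
  indeg <- igraph::degree(qg, mode = "in")
  for (r in which(indeg == 0)) walk(r)
  ok <- Filter(function(p) length(p) >= min_path_len, paths)
  if (!length(ok)) return(NA_real_)
  sel <- unique(unlist(ok))
  exp(mean(log(scores[sel])))
}

#' Average p_diff rank of each meta cluster
#'
#' @param assignment a `MetaClusterAssignment`.
#' @param ranks_by_dataset list (per dataset index) of named rank vectors from
#'   [rank_pdiff()].
#' @return named numeric vector, meta id -> mean member rank (NA for empty).
#' @export
meta_pdiff_ranks <- function(assignment, ranks_by_dataset) {
  n_meta <- length(assignment$metas)
  out <- rep(NA_real_, n_meta)
  for (k in seq_len(n_meta)) {
    keys <- names(assignment$assignments)[vapply(assignment$assignments,
                                                 function(v) k %in% v,
                                                 logical(1))]
    if (!length(keys)) next
    rk <- vapply(keys, function(key) {
      parts <- strsplit(key, ":", fixed = TRUE)[[1]]
      ranks_by_dataset[[as.integer(parts[1])]][[parts[2]]]
    }, numeric(1))
    out[k] <- mean(rk)
  }
  stats::setNames(out, seq_len(n_meta))
}

#' Gene sets enriched in at least `min_datasets` datasets of some meta cluster
#'
#' @param score_array 3-d array (meta x dataset x set) of geometric-mean
#'   `-log10` scores from [meta_enrichment_score()] (NA = absent).
#' @param min_datasets minimum supporting datasets (default 2).
#' @param p_cut adjusted p-value cutoff (default 1e-3).
#' @param focal optional pair of meta ids; when given, each selected set is
#'   assigned to group 1 (enriched in more datasets of `focal[1]`), group 2
#'   (more datasets of `focal[2]`) or group 3 (ties/other).
#' @return data.frame with columns `set`, per-meta dataset counts, and
#'   (with `focal`) `group`.
#' @export
select_shared_gensets <- function(score_array, min_datasets = 2,
                                  p_cut = 1e-3, focal = NULL) {
  thr <- -log10(p_cut)
  sets <- dimnames(score_array)[[3]]
  counts <- apply(score_array >= thr, c(1, 3), sum, na.rm = TRUE)
  keep <- apply(counts >= min_datasets, 2, any)
  res <- data.frame(set = sets[keep], stringsAsFactors = FALSE)
  for (k in seq_len(nrow(counts)))
    res[[paste0("meta", k, "_datasets")]] <- counts[k, keep]
  if (!is.null(focal)) {
    a <- counts[focal[1], keep]; b <- counts[focal[2], keep]
    res$group <- ifelse(a > b, 1L, ifelse(b > a, 2L, 3L))
  }
  res
}
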