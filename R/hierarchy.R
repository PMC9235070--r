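# k-means++ initial centers: first uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  if (k > 1) {
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    for (j in 2:k) {
      probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = probs)
      centers[j, ] <- x[idx, ]
      d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

#' Consensus k-means clustering of genes
#'
#' Subsamples the genes `n_runs` times, runs k-means (k-means++ initialization,
#' Euclidean distance over cells after per-gene z-scoring) on each subsample,
#' and computes the pairwise consensus value of two genes as the fraction of
#' runs, among those where both were subsampled, in which they landed in the
#' same cluster. Agglomerative hierarchical clustering (average linkage) on
#' `1 - consensus` distances is then pruned to `k` groups.
#'
#' @param m an `ExpressionMatrix` (imputed) or a plain gene x cell matrix.
#' @param k number of clusters (1 <= k <= n_genes).
#' @param n_runs number of subsampled k-means runs (default 100).
#' @param subsample_frac fraction of genes per subsample (default 0.8).
#' @param seed optional integer seed.
#' @return list with `assignment` (named integer vector of cluster ids 1..k)
#'   and `consensus` (symmetric gene x gene matrix in `[0, 1]`).
#' @export
consensus_kmeans <- function(m, k, n_runs = 100, subsample_frac = 0.8,
                             seed = NULL) {
  v <- if (inherits(m, "ExpressionMatrix")) m$values else as.matrix(m)
  n_genes <- nrow(v)
  if (k < 1) stop("`k` must be >= 1")
  if (k > n_genes) stop("`k` exceeds the number of genes")
  if (!is.null(seed)) set.seed(seed)
  genes <- rownames(v)
  if (k == 1) {
    return(list(assignment = stats::setNames(rep(1L, n_genes), genes),
                consensus = matrix(1, n_genes, n_genes,
                                   dimnames = list(genes, genes))))
  }
  # per-gene z-score so magnitude does not dominate the distance
  sds <- apply(v, 1, stats::sd)
  sds[sds == 0] <- 1
  x <- sweep(sweep(v, 1, rowMeans(v)), 1, sds, "/")
  together <- matrix(0, n_genes, n_genes)
  sampled <- matrix(0, n_genes, n_genes)
  n_sub <- max(k, ceiling(subsample_frac * n_genes))
  for (run in seq_len(n_runs)) {
    idx <- sort(sample.int(n_genes, n_sub))
    xs <- x[idx, , drop = FALSE]
    fit <- suppressWarnings(
      stats::kmeans(xs, centers = kmeanspp_centers(xs, k), iter.max = 30))
    sampled[idx, idx] <- sampled[idx, idx] + 1
    for (cl in seq_len(k)) {
      members <- idx[fit$cluster == cl]
      together[members, members] <- together[members, members] + 1
    }
  }
  consensus <- ifelse(sampled > 0, together / sampled, 0)
  diag(consensus) <- 1
  dimnames(consensus) <- list(genes, genes)
  tree <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  assignment <- stats::cutree(tree, k = k)
  list(assignment = stats::setNames(as.integer(assignment), genes),
       consensus = consensus)
}

#' Construct a gene-cluster hierarchy object
#'
#' Low-level constructor: use [build_full_hierarchy()] to build one from data.
#' Edges run from the coarser cluster (smaller `k`) to the finer cluster
#' (larger `k`); roots sit at the top (smallest `k`) and leaves at the bottom.
#'
#' @param nodes data.frame with columns `id`, `level`, `size` (and optional
#'   annotation columns `p_diff`, `avg_nsv`, `density`).
#' @param members named list mapping node id (as character) to its gene set.
#' @param edges data.frame with columns `from`, `to`, `weight`; `from` is the
#'   coarser (upstream) node, `weight` the overlap fraction
#'   `|intersection| / |finer cluster|`.
#' @return an object of class `ClusterHierarchy`.
#' @export
cluster_hierarchy <- function(nodes, members, edges) {
  stopifnot(all(c("id", "level", "size") %in% names(nodes)))
  if (nrow(edges) && !all(c("from", "to", "weight") %in% names(edges)))
    stop("edges need columns from, to, weight")
  if (!all(as.character(nodes$id) %in% names(members)))
    stop("every node needs a member gene set")
  if (any(!lengths(members[as.character(nodes$id)])))
    stop("every node's gene set must be nonempty")
  h <- structure(list(nodes = nodes, members = members, edges = edges),
                 class = "ClusterHierarchy")
  g <- hierarchy_graph(h)
  if (!igraph::is_acyclic(g)) stop("hierarchy must be acyclic")
  h
}

# igraph view of a hierarchy (directed, coarse -> fine)
hierarchy_graph <- function(h) {
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(as.character(h$nodes$id))
  if (nrow(h$edges))
    g <- igraph::add_edges(g, rbind(as.character(h$edges$from),
                                    as.character(h$edges$to)))
  g
}

#' @exportS3Method base::print
print.ClusterHierarchy <- function(x, ...) {
  cat(sprintf("ClusterHierarchy: %d nodes over levels %s, %d edges\n",
              nrow(x$nodes), paste(range(x$nodes$level), collapse = ".."),
              nrow(x$edges)))
  invisible(x)
}

#' Build the full gene-cluster hierarchy over k = 1..k_max
#'
#' Runs [consensus_kmeans()] for every `k`, creates one node per (level,
#' cluster) and adds an inheritance edge between a cluster `c_i` at level `k`
#' and a cluster `c_j` at level `k + 1` whenever their overlap is at least
#' `inherit_threshold` of `|c_j|`. A cluster may have multiple parents (it is
#' joined from several coarser clusters) and multiple children.
#'
#' @param m an `ExpressionMatrix` (imputed) or gene x cell matrix.
#' @param k_max deepest level (default 12).
#' @param inherit_threshold overlap fraction defining inheritance
#'   (default 0.15).
#' @param n_runs,subsample_frac passed to [consensus_kmeans()].
#' @param include_root include the k = 1 all-genes root (default TRUE).
#' @param seed optional integer seed.
#' @return a `ClusterHierarchy`.
#' @export
build_full_hierarchy <- function(m, k_max = 12, inherit_threshold = 0.15,
                                 n_runs = 100, subsample_frac = 0.8,
                                 include_root = TRUE, seed = NULL) {
  if (k_max < 2) stop("`k_max` must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  k_min <- if (include_root) 1L else 2L
  levels <- k_min:k_max
  partitions <- lapply(levels, function(k)
    consensus_kmeans(m, k, n_runs = n_runs,
                     subsample_frac = subsample_frac)$assignment)
  names(partitions) <- levels
  nodes <- list(); members <- list(); edges <- list()
  next_id <- 1L
  level_ids <- list()
  for (li in seq_along(levels)) {
    k <- levels[li]
    part <- partitions[[li]]
    ids <- integer(max(part))
    for (cl in seq_len(max(part))) {
      genes <- names(part)[part == cl]
      ids[cl] <- next_id
      nodes[[length(nodes) + 1L]] <- data.frame(id = next_id, level = k,
                                                size = length(genes))
      members[[as.character(next_id)]] <- genes
      next_id <- next_id + 1L
    }
    level_ids[[li]] <- ids
    if (li > 1) {
      prev <- partitions[[li - 1L]]
      for (cl in seq_len(max(part))) {
        cj <- names(part)[part == cl]
        for (pcl in seq_len(max(prev))) {
          ci <- names(prev)[prev == pcl]
          ov <- length(intersect(ci, cj))
          if (ov >= inherit_threshold * length(cj))
            edges[[length(edges) + 1L]] <- data.frame(
              from = level_ids[[li - 1L]][pcl], to = ids[cl],
              weight = ov / length(cj))
        }
      }
    }
  }
  cluster_hierarchy(do.call(rbind, nodes), members,
                    if (length(edges)) do.call(rbind, edges)
                    else data.frame(from = integer(), to = integer(),
                                    weight = numeric()))
}

#' Reduce a cluster hierarchy by collapsing stumps
#'
#' Identifies the linear nodes (at most one parent and at most one child),
#' groups them into maximal chains, appends to the bottom of each chain its
#' unique child when that child has exactly one parent and multiple or no
#' children (the appended chains are the stumps), maps every stump to a single
#' reduced node and every other node to its own reduced node, and rebuilds the
#' edges through the mapping. Reduction is idempotent.
#'
#' @param h a `ClusterHierarchy`.
#' @param representative which full node's gene set labels a collapsed stump:
#'   `"bottom"` (deepest node, default) or `"union"` of the stump's genes.
#' @return an object of class `ReducedHierarchy`: list with `graph` (a
#'   `ClusterHierarchy` of reduced nodes) and `node_map` (named vector, full
#'   node id -> reduced node id).
#' @export
reduce_hierarchy <- function(h, representative = c("bottom", "union")) {
  stopifnot(inherits(h, "ClusterHierarchy"))
  representative <- match.arg(representative)
  ids <- as.character(h$nodes$id)
  parents <- split(as.character(h$edges$from), as.character(h$edges$to))
  children <- split(as.character(h$edges$to), as.character(h$edges$from))
  indeg <- stats::setNames(integer(length(ids)), ids)
  outdeg <- stats::setNames(integer(length(ids)), ids)
  indeg[names(parents)] <- lengths(parents)
  outdeg[names(children)] <- lengths(children)
  linear <- ids[indeg <= 1 & outdeg <= 1]
  # maximal chains of linear nodes along edges
  in_chain <- character(0)
  chains <- list()
  for (v in linear) {
    if (v %in% in_chain) next
    chain <- v
    repeat {  # extend upward through linear parents
      p <- parents[[chain[1]]]
      if (length(p) == 1 && p %in% linear && !(p %in% in_chain) &&
          length(children[[p]]) == 1) chain <- c(p, chain) else break
    }
    repeat {  # extend downward through linear children
      ch <- children[[chain[length(chain)]]]
      if (length(ch) == 1 && ch %in% linear && !(ch %in% in_chain) &&
          length(parents[[ch]]) == 1) chain <- c(chain, ch) else break
    }
    in_chain <- c(in_chain, chain)
    chains[[length(chains) + 1L]] <- chain
  }
  # append the bottom: the unique child, if it has one parent and is not linear
  for (i in seq_along(chains)) {
    bottom <- chains[[i]][length(chains[[i]])]
    ch <- children[[bottom]]
    if (length(ch) == 1 && !(ch %in% linear) &&
        length(parents[[ch]]) == 1)
      chains[[i]] <- c(chains[[i]], ch)
  }
  stump_of <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (i in seq_along(chains)) stump_of[chains[[i]]] <- i
  # reduced nodes: one per stump, one per remaining node; keep id order stable
  node_map <- stats::setNames(integer(length(ids)), ids)
  red_nodes <- list(); red_members <- list()
  next_id <- 1L
  done_stumps <- integer(0)
  for (v in ids) {
    si <- stump_of[[v]]
    if (is.na(si)) {
      node_map[[v]] <- next_id
      red_nodes[[next_id]] <- data.frame(
        id = next_id, level = h$nodes$level[h$nodes$id == as.integer(v)],
        size = length(h$members[[v]]))
      red_members[[as.character(next_id)]] <- h$members[[v]]
      next_id <- next_id + 1L
    } else if (!(si %in% done_stumps)) {
      chain <- chains[[si]]
      node_map[chain] <- next_id
      lv <- h$nodes$level[match(as.integer(chain), h$nodes$id)]
      genes <- if (representative == "bottom")
        h$members[[chain[which.max(lv)]]]
      else unique(unlist(h$members[chain]))
      red_nodes[[next_id]] <- data.frame(id = next_id, level = min(lv),
                                         size = length(genes))
      red_members[[as.character(next_id)]] <- genes
      done_stumps <- c(done_stumps, si)
      next_id <- next_id + 1L
    }
  }
  red_edges <- list()
  if (nrow(h$edges)) {
    u1 <- node_map[as.character(h$edges$from)]
    u2 <- node_map[as.character(h$edges$to)]
    keep <- u1 != u2
    if (any(keep)) {
      e <- unique(data.frame(from = u1[keep], to = u2[keep]))
      e$weight <- NA_real_
      for (r in seq_len(nrow(e))) {  # recompute overlap on representative sets
        a <- red_members[[as.character(e$from[r])]]
        b <- red_members[[as.character(e$to[r])]]
        e$weight[r] <- length(intersect(a, b)) / length(b)
      }
      red_edges[[1]] <- e
    }
  }
  graph <- cluster_hierarchy(do.call(rbind, red_nodes), red_members,
                             if (length(red_edges)) red_edges[[1]]
                             else data.frame(from = integer(), to = integer(),
                                             weight = numeric()))
  structure(list(graph = graph, node_map = node_map),
            class = "ReducedHierarchy")
}

#' @exportS3Method base::print
print.ReducedHierarchy <- function(x, ...) {
  cat(sprintf("ReducedHierarchy: %d -> %d nodes\n",
              length(x$node_map), nrow(x$graph$nodes)))
  invisible(x)
}

#' Annotate hierarchy nodes with heterogeneity and density
#'
#' Adds per-node `p_diff` (over the cluster's gene subset), `avg_nsv` and
#' `density` (fraction of observed entries in the cluster's submatrix of the
#' pre-imputation mask) columns to the node table.
#'
#' @param h a `ClusterHierarchy` or `ReducedHierarchy`.
#' @param m the imputed `ExpressionMatrix` the clusters came from.
#' @param mask_m optional `ExpressionMatrix` carrying the original dropout
#'   mask (defaults to `m`).
#' @param epsilon,n_samples,seed passed to [p_diff()].
#' @param include_self silhouette convention.
#' @return the annotated object (same class as `h`).
#' @export
annotate_clusters <- function(h, m, mask_m = m, epsilon = 0.05,
                              n_samples = 1e5, seed = NULL,
                              include_self = TRUE) {
  if (inherits(h, "ReducedHierarchy")) {
    h$graph <- annotate_clusters(h$graph, m, mask_m, epsilon, n_samples,
                                 seed, include_self)
    return(h)
  }
  stopifnot(inherits(h, "ClusterHierarchy"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(h$nodes)
  pd <- nsv <- dens <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    genes <- intersect(h$members[[as.character(h$nodes$id[i])]],
                       rownames(m$values))
    if (!length(genes)) stop("cluster ", h$nodes$id[i], " has no genes in the matrix")
    dens[i] <- mean(mask_m$observed[intersect(genes, rownames(mask_m$values)), ,
                                    drop = FALSE])
    if (length(genes) < 2) next  # correlations over a single gene are undefined
    cc <- intra_inter_correlations(m, genes = genes)
    pd[i] <- p_diff(cc$intra, cc$inter, epsilon = epsilon,
                    n_samples = n_samples)
    z <- zscore_cells(m, genes = genes)
    sil <- silhouette_values(z, m$tumor_of, include_self = include_self)
    nsv[i] <- nsv_fractions(sil, m$tumor_of)$avg_nsv
  }
  h$nodes$p_diff <- pd
  h$nodes$avg_nsv <- nsv
  h$nodes$density <- dens
  h
}

#' Rank hierarchy nodes by p_diff
#'
#' Descending ranks (rank 1 = most homogeneous / largest p_diff), ties
#' receiving their average rank.
#'
#' @param h an annotated `ClusterHierarchy` or `ReducedHierarchy`.
#' @return named numeric vector of ranks by node id.
#' @export
rank_pdiff <- function(h) {
  g <- if (inherits(h, "ReducedHierarchy")) h$graph else h
  if (is.null(g$nodes$p_diff) || anyNA(g$nodes$p_diff))
    stop("all nodes must carry a p_diff annotation")
  r <- rank(-g$nodes$p_diff, ties.method = "average")
  stats::setNames(r, as.character(g$nodes$id))
}

#' Serialize a hierarchy to JSON
#'
#' @param h a `ClusterHierarchy` or `ReducedHierarchy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path) {
  if (inherits(h, "ReducedHierarchy")) {
    obj <- list(reduced = TRUE, nodes = h$graph$nodes,
                members = h$graph$members, edges = h$graph$edges,
                node_map = as.list(h$node_map))
  } else {
    obj <- list(reduced = FALSE, nodes = h$nodes, members = h$members,
                edges = h$edges)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a hierarchy serialized by [write_hierarchy()]
#'
#' @param path path to the JSON file.
#' @return a `ClusterHierarchy` or `ReducedHierarchy`.
#' @export
read_hierarchy <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  members <- lapply(obj$members, as.character)
  edges <- if (length(obj$edges)) as.data.frame(obj$edges)
           else data.frame(from = integer(), to = integer(), weight = numeric())
  g <- cluster_hierarchy(as.data.frame(obj$nodes), members, edges)
  if (isTRUE(obj$reduced)) {
    structure(list(graph = g, node_map = unlist(obj$node_map)),
              class = "ReducedHierarchy")
  } else g
}
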