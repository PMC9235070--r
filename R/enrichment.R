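#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least the actual overlap between a gene cluster
#' and a gene set when the cluster is drawn uniformly from the universe.
#'
#' @param cluster,geneset character vectors of gene identifiers, both subsets
#'   of `universe`.
#' @param universe character vector of all genes considered.
#' @return the raw p-value `P(overlap >= observed)`.
#' @export
hypergeom_enrich <- function(cluster, geneset, universe) {
  if (!length(universe)) stop("empty universe")
  cluster <- unique(cluster); geneset <- unique(geneset)
  universe <- unique(universe)
  if (length(setdiff(cluster, universe)) || length(setdiff(geneset, universe)))
    stop("cluster and geneset must be subsets of the universe")
  q <- length(intersect(cluster, geneset))
  stats::phyper(q - 1, length(geneset), length(universe) - length(geneset),
                length(cluster), lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment of an enrichment p-value matrix
#'
#' @param raw_p numeric matrix (clusters x gene sets) of p-values in `[0, 1]`.
#' @param scope `"per_cluster"` adjusts each row as its own family (one family
#'   per cluster, the default); `"global"` adjusts over the whole matrix.
#' @return the adjusted matrix.
#' @export
fdr_adjust <- function(raw_p, scope = c("per_cluster", "global")) {
  scope <- match.arg(scope)
  raw_p <- as.matrix(raw_p)
  if (any(raw_p < 0 | raw_p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- if (scope == "global") {
    matrix(stats::p.adjust(raw_p, method = "BH"), nrow(raw_p),
           dimnames = dimnames(raw_p))
  } else {
    t(apply(raw_p, 1, stats::p.adjust, method = "BH"))
  }
  if (is.null(dimnames(adj))) dimnames(adj) <- dimnames(raw_p)
  adj
}

#' Cluster x gene-set enrichment table
#'
#' Hypergeometric enrichment of every hierarchy cluster against every gene
#' set, with FDR adjustment and `-log10` scores.
#'
#' @param h a `ClusterHierarchy` or `ReducedHierarchy`.
#' @param collection a `GeneSetCollection`.
#' @param universe enrichment universe; defaults to the genes of the
#'   hierarchy's root level (all clustered genes).
#' @param fdr_scope see [fdr_adjust()].
#' @return an object of class `EnrichmentTable`: list with matrices `raw_p`,
#'   `adjusted` and `score` (`-log10` adjusted), rows = cluster ids,
#'   columns = set names.
#' @export
enrichment_table <- function(h, collection, universe = NULL,
                             fdr_scope = c("per_cluster", "global")) {
  g <- if (inherits(h, "ReducedHierarchy")) h$graph else h
  stopifnot(inherits(collection, "GeneSetCollection"))
  if (is.null(universe))
    universe <- unique(unlist(g$members, use.names = FALSE))
  ids <- as.character(g$nodes$id)
  sets <- lapply(collection$sets, intersect, universe)
  raw <- matrix(NA_real_, length(ids), length(sets),
                dimnames = list(ids, names(sets)))
  for (i in seq_along(ids)) {
    cl <- intersect(g$members[[ids[i]]], universe)
    for (j in seq_along(sets))
      raw[i, j] <- if (length(sets[[j]]))
        hypergeom_enrich(cl, sets[[j]], universe) else 1
  }
  adjusted <- fdr_adjust(raw, scope = fdr_scope)
  structure(list(raw_p = raw, adjusted = adjusted,
                 score = -log10(pmax(adjusted, .Machine$double.xmin))),
            class = "EnrichmentTable")
}

# all root-to-leaf paths of a hierarchy, as lists of node-id characters
root_leaf_paths <- function(h) {
  g <- if (inherits(h, "ReducedHierarchy")) h$graph else h
  ids <- as.character(g$nodes$id)
  children <- split(as.character(g$edges$to), as.character(g$edges$from))
  indeg <- stats::setNames(rep(0L, length(ids)), ids)
  tb <- table(as.character(g$edges$to))
  indeg[names(tb)] <- as.integer(tb)
  roots <- ids[indeg == 0]
  paths <- list()
  walk <- function(path) {
    ch <- children[[path[length(path)]]]
    if (is.null(ch) || !length(ch)) {
      paths[[length(paths) + 1L]] <<- path
    } else {
      for (c_ in ch) walk(c(path, c_))
    }
  }
  for (r in roots) walk(r)
  # canonical (lexicographic) order makes tie-breaks deterministic
  keys <- vapply(paths, function(p)
    paste(sprintf("%08d", as.numeric(p)), collapse = ","), character(1))
  paths[order(keys)]
}

#' Uniquely enriched cluster of a gene set along the hierarchy
#'
#' Implements the maximal-path extraction: sort clusters by descending
#' `-log10` FDR-adjusted p-value, grow the top-ranking list `L` while trimming
#' the root-leaf paths that contain all of `L` (stopping when the next cluster
#' leaves all candidate paths, completes a root-leaf path, or scores below
#' both half the last member and `score_threshold`), extract the maximal
#' (sub)path spanned by `L`, optionally extend it through parents/children
#' whose sort rank is within `rank_window` of the path's max rank and whose
#' score passes the threshold, and report the most downstream cluster of the
#' path when its score is at least `score_threshold`.
#'
#' @param h a `ClusterHierarchy` or `ReducedHierarchy`.
#' @param scores named numeric vector of `-log10` FDR-adjusted p-values, one
#'   per node id (already transformed).
#' @param score_threshold minimum reportable transformed score (default 5).
#' @param rank_window rank slack for path extension (default 5).
#' @return list with `cluster` (node id as integer, or `NA` if none),
#'   `path` (character node ids of the maximal path) and `score` (the bottom
#'   node's transformed score).
#' @export
unique_enrichment <- function(h, scores, score_threshold = 5, rank_window = 5) {
  g <- if (inherits(h, "ReducedHierarchy")) h$graph else h
  ids <- as.character(g$nodes$id)
  if (!all(ids %in% names(scores)))
    stop("`scores` must cover every node")
  s <- scores[ids]
  # descending score, ties by smaller cluster id
  ord <- ids[order(-s, as.numeric(ids))]
  rank_of <- stats::setNames(seq_along(ord), ord)
  paths <- root_leaf_paths(g)
  if (!length(paths)) stop("hierarchy has no root-leaf paths")
  none <- list(cluster = NA_integer_, path = character(0), score = NA_real_)
  parents <- split(as.character(g$edges$from), as.character(g$edges$to))
  children <- split(as.character(g$edges$to), as.character(g$edges$from))

  L <- ord[1]
  P <- Filter(function(p) all(L %in% p), paths)
  if (!length(P)) return(none)
  completed <- NULL
  i <- 2L
  while (i <= length(ord)) {
    cand <- ord[i]
    in_some <- Filter(function(p) all(c(L, cand) %in% p), P)
    if (!length(in_some)) break                     # leaves all candidate paths
    last_score <- s[[L[length(L)]]]
    # a low scorer never joins L, even when it would complete a path
    if (s[[cand]] < last_score / 2 && s[[cand]] < score_threshold) break
    full <- Filter(function(p) all(p %in% c(L, cand)), in_some)
    if (length(full)) {                             # completes a root-leaf path
      L <- c(L, cand); P <- in_some; completed <- full[[1]]
      break
    }
    L <- c(L, cand); P <- in_some
    i <- i + 1L
  }

  # step 5: extract the maximal path
  maximal <- NULL
  if (!is.null(completed)) {
    maximal <- completed
  } else {
    nxt <- setdiff(ord, L)[1]
    if (!is.na(nxt) && length(L) > 1) {
      last <- L[length(L)]
      shares_parent <- length(intersect(parents[[nxt]], parents[[last]])) > 0
      if (shares_parent && s[[nxt]] > s[[last]] / 2 &&
          s[[nxt]] > score_threshold)
        L <- L[-length(L)]
    }
    if (!length(L)) return(none)
    min_L <- min(s[L])
    span_on <- function(p) {      # contiguous section of p from first to last L member
      pos <- which(p %in% L)
      if (!length(pos)) return(NULL)
      p[min(pos):max(pos)]
    }
    has_hole <- function(p) {
      sp <- span_on(p)
      any(!(sp %in% L) & s[sp] < min_L)
    }
    if (all(vapply(P, has_hole, logical(1)))) {
      # maximal contiguous run of L members over all candidate paths
      best <- character(0)
      for (p in P) {
        inL <- p %in% L
        r <- rle(inL)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        for (j in which(r$values)) {
          run <- p[starts[j]:ends[j]]
          if (length(run) > length(best)) best <- run
        }
      }
      maximal <- best
    } else {
      p <- Filter(Negate(has_hole), P)[[1]]
      maximal <- span_on(p)
    }
  }
  if (is.null(maximal) || !length(maximal)) return(none)

  # step 6: extension through unambiguous high-scoring parents/children
  qualifies <- function(v) {
    rank_of[[v]] < max(rank_of[maximal]) + rank_window &&
      s[[v]] >= score_threshold
  }
  repeat {
    ps <- parents[[maximal[1]]]
    if (is.null(ps)) break
    ok <- ps[vapply(ps, qualifies, logical(1))]
    if (length(ok) == 1 && !(ok %in% maximal)) maximal <- c(ok, maximal) else break
  }
  repeat {
    cs <- children[[maximal[length(maximal)]]]
    if (is.null(cs)) break
    ok <- cs[vapply(cs, qualifies, logical(1))]
    if (length(ok) == 1 && !(ok %in% maximal)) maximal <- c(maximal, ok) else break
  }

  bottom <- maximal[length(maximal)]
  if (s[[bottom]] >= score_threshold)
    list(cluster = as.integer(bottom), path = maximal, score = s[[bottom]])
  else none
}

#' Uniquely enriched clusters for every set of a collection
#'
#' @param h a `ClusterHierarchy` or `ReducedHierarchy`.
#' @param etab an `EnrichmentTable` for `h`.
#' @param score_threshold,rank_window passed to [unique_enrichment()].
#' @return data.frame with columns `set`, `cluster`, `score` (only sets with a
#'   reported cluster).
#' @export
unique_enrichment_table <- function(h, etab, score_threshold = 5,
                                    rank_window = 5) {
  stopifnot(inherits(etab, "EnrichmentTable"))
  rows <- list()
  for (set in colnames(etab$score)) {
    res <- unique_enrichment(h, etab$score[, set],
                             score_threshold = score_threshold,
                             rank_window = rank_window)
    if (!is.na(res$cluster))
      rows[[length(rows) + 1L]] <- data.frame(set = set,
                                              cluster = res$cluster,
                                              score = res$score)
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(set = character(), cluster = integer(), score = numeric())
}
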