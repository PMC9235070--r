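# Independent reference implementations used as oracles. They avoid the
# package's internal helpers and recompute everything from first principles.

# exact upper-tail hypergeometric probability by direct summation
oracle_hypergeom <- function(cluster, geneset, universe) {
  N <- length(universe); K <- length(geneset); n <- length(cluster)
  q <- length(intersect(cluster, geneset))
  ks <- q:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# silhouette by explicit pairwise loops on raw expression (Pearson identity)
oracle_silhouette <- function(values, tumor, include_self = TRUE) {
  n <- ncol(values)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    D[i, j] <- sqrt(max(0, 2 - 2 * cor(values[, i], values[, j])))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(tumor == tumor[i])
    a <- if (include_self) mean(D[i, own])
         else if (length(own) == 1) 0 else sum(D[i, setdiff(own, i)]) / (length(own) - 1)
    b <- Inf
    for (t in setdiff(unique(tumor), tumor[i]))
      b <- min(b, mean(D[i, which(tumor == t)]))
    s[i] <- (b - a) / max(a, b)
  }
  setNames(s, colnames(values))
}

# closed-form p_diff for X ~ N(mu1, s1^2), Y ~ N(mu2, s2^2)
gaussian_pdiff <- function(mu1, s1, mu2, s2, eps) {
  sd_ <- sqrt(s1^2 + s2^2)
  pnorm((mu1 - mu2 - eps) / sd_) - pnorm(-(mu1 - mu2) - eps, sd = sd_)
}

# --- brute-force stump reduction -------------------------------------------

# partition of nodes induced by a reduction mapping
map_partition <- function(node_map) {
  unname(lapply(split(names(node_map), node_map), sort))
}

oracle_reduce_partition <- function(h) {
  ids <- as.character(h$nodes$id)
  par <- split(as.character(h$edges$from), as.character(h$edges$to))
  chl <- split(as.character(h$edges$to), as.character(h$edges$from))
  indeg <- sapply(ids, function(v) length(par[[v]]))
  outdeg <- sapply(ids, function(v) length(chl[[v]]))
  linear <- ids[indeg <= 1 & outdeg <= 1]
  # enumerate every directed path consisting solely of linear nodes
  paths <- list()
  grow <- function(p) {
    paths[[length(paths) + 1L]] <<- p
    ch <- chl[[p[length(p)]]]
    if (length(ch) == 1 && ch %in% linear) grow(c(p, ch))
  }
  for (v in linear) grow(v)
  # maximal = not a contiguous subsequence of a longer all-linear path
  contains <- function(big, small) {
    nb <- length(big); ns <- length(small)
    if (ns > nb) return(FALSE)
    any(vapply(seq_len(nb - ns + 1), function(s)
      identical(big[s:(s + ns - 1)], small), logical(1)))
  }
  maximal <- Filter(function(p)
    !any(vapply(paths, function(q)
      length(q) > length(p) && contains(q, p), logical(1))), paths)
  # drop duplicates and non-maximal starts (paths enumerated from every node)
  keys <- sapply(maximal, paste, collapse = ",")
  maximal <- maximal[!duplicated(keys)]
  # append the unique non-linear child with a single parent
  stumps <- lapply(maximal, function(p) {
    ch <- chl[[p[length(p)]]]
    if (length(ch) == 1 && !(ch %in% linear) && length(par[[ch]]) == 1)
      c(p, ch) else p
  })
  in_stump <- unlist(stumps)
  parts <- c(stumps, as.list(setdiff(ids, in_stump)))
  unname(lapply(parts, sort))
}

# canonical form of a partition for comparison
canon_partition <- function(parts) {
  sort(vapply(parts, function(p) paste(sort(p), collapse = ","), character(1)))
}

# reduced edge set implied by a node partition (as sorted "A|B" keys over
# canonical class labels)
oracle_reduced_edges <- function(h, parts) {
  class_of <- new.env(parent = emptyenv())
  for (p in parts) {
    lab <- paste(sort(p), collapse = ",")
    for (v in p) assign(v, lab, envir = class_of)
  }
  keys <- character(0)
  for (r in seq_len(nrow(h$edges))) {
    u <- get(as.character(h$edges$from[r]), envir = class_of)
    v <- get(as.character(h$edges$to[r]), envir = class_of)
    if (u != v) keys <- c(keys, paste(u, v, sep = "|"))
  }
  sort(unique(keys))
}

# --- brute-force path matching ----------------------------------------------

# every directed path in a hierarchy, via DFS from every node
oracle_all_paths <- function(h) {
  chl <- split(as.character(h$edges$to), as.character(h$edges$from))
  paths <- list()
  grow <- function(p) {
    paths[[length(paths) + 1L]] <<- p
    for (ch in chl[[p[length(p)]]]) grow(c(p, ch))
  }
  for (v in as.character(h$nodes$id)) grow(v)
  paths
}

oracle_match_paths <- function(ha, hb, ov, match_frac = 0.9, min_len = 2) {
  keep_len <- function(ps) Filter(function(p) length(p) >= min_len, ps)
  pa <- keep_len(oracle_all_paths(ha)); pb <- keep_len(oracle_all_paths(hb))
  frac <- function(p, q) {
    hits <- 0
    for (u in p) for (v in q) if (ov[u, v]) hits <- hits + 1
    hits / (length(p) * length(q))
  }
  matched <- list()
  for (p in pa) for (q in pb)
    if (frac(p, q) > match_frac)
      matched[[length(matched) + 1L]] <- list(path_a = p, path_b = q)
  contains <- function(big, small) {
    nb <- length(big); ns <- length(small)
    if (ns > nb) return(FALSE)
    any(vapply(seq_len(nb - ns + 1), function(s)
      identical(big[s:(s + ns - 1)], small), logical(1)))
  }
  keep <- vapply(seq_along(matched), function(i) {
    !any(vapply(seq_along(matched), function(j) {
      if (i == j) return(FALSE)
      (length(matched[[j]]$path_a) > length(matched[[i]]$path_a) ||
       length(matched[[j]]$path_b) > length(matched[[i]]$path_b)) &&
        contains(matched[[j]]$path_a, matched[[i]]$path_a) &&
        contains(matched[[j]]$path_b, matched[[i]]$path_b)
    }, logical(1)))
  }, logical(1))
  matched <- matched[keep]
  sort(vapply(matched, function(m)
    paste(paste(m$path_a, collapse = ","), paste(m$path_b, collapse = ","),
          sep = "|"), character(1)))
}

# brute-force maximal cliques by subset enumeration (n <= ~15)
oracle_max_cliques <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  for (size in seq_len(n)) {
    for (sub in utils::combn(n, size, simplify = FALSE)) {
      ok <- TRUE
      if (size > 1)
        for (i in seq_len(size - 1)) for (j in (i + 1):size)
          if (!adj[sub[i], sub[j]]) { ok <- FALSE; break }
      if (ok) cliques[[length(cliques) + 1L]] <- sub
    }
  }
  maximal <- Filter(function(cl)
    !any(vapply(cliques, function(other)
      length(other) > length(cl) && all(cl %in% other), logical(1))), cliques)
  sort(vapply(maximal, function(cl) paste(sort(cl), collapse = ","),
              character(1)))
}

# medoid trial by direct Hamming computation
oracle_medoid <- function(trial_members, universe) {
  n_u <- length(universe)
  mats <- lapply(trial_members, function(mem_list) {
    M <- matrix(0L, n_u, n_u, dimnames = list(universe, universe))
    for (mem in mem_list) M[mem, mem] <- 1L
    M
  })
  n <- length(mats)
  tot <- numeric(n)
  for (i in seq_len(n))
    tot[i] <- sum(vapply(seq_len(n), function(j) sum(mats[[i]] != mats[[j]]),
                         numeric(1)))
  which.min(tot)
}

# --- independent unique-enrichment implementation ---------------------------

oracle_unique_enrichment <- function(h, scores, thr = 5, window = 5) {
  ids <- as.character(h$nodes$id)
  s <- scores[ids]
  ord <- ids[order(-s, as.numeric(ids))]
  rnk <- setNames(seq_along(ord), ord)
  par <- split(as.character(h$edges$from), as.character(h$edges$to))
  chl <- split(as.character(h$edges$to), as.character(h$edges$from))
  roots <- ids[!ids %in% as.character(h$edges$to)]
  # path enumeration as a membership matrix, lexicographic order
  all_paths <- list()
  dfs <- function(p) {
    ch <- chl[[p[length(p)]]]
    if (is.null(ch)) all_paths[[length(all_paths) + 1L]] <<- p
    else for (v in ch) dfs(c(p, v))
  }
  for (r in roots) dfs(r)
  path_keys <- vapply(all_paths, function(p)
    paste(sprintf("%08d", as.numeric(p)), collapse = ","), character(1))
  all_paths <- all_paths[order(path_keys)]
  if (!length(all_paths)) stop("no paths")
  none <- list(cluster = NA_integer_)

  L <- ord[1]
  P_idx <- which(vapply(all_paths, function(p) L %in% p, logical(1)))
  if (!length(P_idx)) return(none)
  completed <- NA_integer_
  pos <- 2L
  while (pos <= length(ord)) {
    cand <- ord[pos]
    ok <- P_idx[vapply(all_paths[P_idx], function(p) cand %in% p, logical(1))]
    if (!length(ok)) break
    if (s[cand] < s[L[length(L)]] / 2 && s[cand] < thr) break
    done <- ok[vapply(all_paths[ok], function(p)
      all(p %in% c(L, cand)), logical(1))]
    if (length(done)) { L <- c(L, cand); P_idx <- ok; completed <- done[1]; break }
    L <- c(L, cand); P_idx <- ok
    pos <- pos + 1L
  }

  if (!is.na(completed)) {
    maximal <- all_paths[[completed]]
  } else {
    nxt <- setdiff(ord, L)[1]
    if (!is.na(nxt) && length(L) > 1) {
      last <- L[length(L)]
      if (length(intersect(par[[nxt]], par[[last]])) > 0 &&
          s[nxt] > s[last] / 2 && s[nxt] > thr) L <- L[-length(L)]
    }
    if (!length(L)) return(none)
    min_L <- min(s[L])
    span <- function(p) {
      w <- which(p %in% L)
      if (!length(w)) return(NULL)
      p[min(w):max(w)]
    }
    holey <- vapply(all_paths[P_idx], function(p) {
      sp <- span(p)
      any(!(sp %in% L) & s[sp] < min_L)
    }, logical(1))
    if (all(holey)) {
      best <- character(0)
      for (p in all_paths[P_idx]) {
        run <- character(0)
        for (v in p) {
          if (v %in% L) {
            run <- c(run, v)
            if (length(run) > length(best)) best <- run
          } else run <- character(0)
        }
      }
      maximal <- best
    } else {
      maximal <- span(all_paths[P_idx][!holey][[1]])
    }
  }
  if (!length(maximal)) return(none)

  good <- function(v) rnk[v] < max(rnk[maximal]) + window && s[v] >= thr
  repeat {
    ps <- par[[maximal[1]]]
    if (is.null(ps)) break
    ok <- ps[vapply(ps, good, logical(1))]
    if (length(ok) == 1 && !(ok %in% maximal)) maximal <- c(ok, maximal)
    else break
  }
  repeat {
    cs <- chl[[maximal[length(maximal)]]]
    if (is.null(cs)) break
    ok <- cs[vapply(cs, good, logical(1))]
    if (length(ok) == 1 && !(ok %in% maximal)) maximal <- c(maximal, ok)
    else break
  }
  bottom <- maximal[length(maximal)]
  if (s[bottom] >= thr) list(cluster = as.integer(bottom)) else none
}
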