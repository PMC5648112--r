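# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the package's own traversal code and ape's
# distance/diversity functions: everything is computed from parent
# pointers and explicit path enumeration.

tree_parents <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  parent <- integer(n)
  blen <- numeric(n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  if (!is.null(tree$edge.length)) blen[tree$edge[, 2]] <- tree$edge.length
  list(parent = parent, blen = blen, ntip = ape::Ntip(tree))
}

path_to_root <- function(parent, v) {
  p <- v
  while (parent[v] != 0) {
    v <- parent[v]
    p <- c(p, v)
  }
  p
}

# patristic distances by explicit path enumeration over all tip pairs
oracle_cophenetic <- function(tree) {
  tp <- tree_parents(tree)
  nt <- tp$ntip
  D <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(nt), path_to_root, parent = tp$parent)
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      pi <- paths[[i]]
      pj <- paths[[j]]
      mrca <- pi[pi %in% pj][1]
      di <- sum(tp$blen[pi[seq_len(which(pi == mrca) - 1)]])
      dj <- sum(tp$blen[pj[seq_len(which(pj == mrca) - 1)]])
      D[i, j] <- D[j, i] <- di + dj
    }
  }
  D
}

# Faith's PD as the union of root-to-tip edge sets of the present taxa
oracle_pd <- function(tree, taxa, include_root = TRUE) {
  tp <- tree_parents(tree)
  tips <- match(taxa, tree$tip.label)
  paths <- lapply(tips, path_to_root, parent = tp$parent)
  edge_sets <- lapply(paths, function(p) p[-length(p)]) # drop root
  union_set <- unique(unlist(edge_sets))
  if (!include_root && length(edge_sets) >= 1) {
    shared <- Reduce(intersect, edge_sets)
    union_set <- setdiff(union_set, shared)
  }
  sum(tp$blen[union_set])
}

# exhaustive pair loops for the weighted/unweighted distance metrics
oracle_mpd <- function(d, n, weighted) {
  s <- length(n)
  num <- 0
  den <- 0
  for (i in seq_len(s)) {
    for (j in seq_len(s)) {
      if (i == j) next
      w <- if (weighted) n[i] * n[j] else 1
      num <- num + w * d[i, j]
      den <- den + w
    }
  }
  unname(num / den)
}

oracle_mntd <- function(d, n, weighted) {
  s <- length(n)
  nn <- numeric(s)
  for (i in seq_len(s)) {
    nn[i] <- min(d[i, setdiff(seq_len(s), i)])
  }
  if (weighted) sum(nn * n) / sum(n) else mean(nn)
}

# exact tip-shuffle null for unweighted metrics: enumeration of all
# richness-sized label subsets of the pool
oracle_subset_null <- function(dist, s, metric = c("mpd", "mntd")) {
  metric <- match.arg(metric)
  combos <- utils::combn(nrow(dist), s)
  apply(combos, 2, function(idx) {
    d <- dist[idx, idx]
    if (metric == "mpd") {
      mean(d[lower.tri(d)])
    } else {
      diag(d) <- Inf
      mean(apply(d, 1, min))
    }
  })
}

# slope of the plane through three corners of a square quadrat using the
# right-angle-vertex closed form (drop corner j of corners ordered
# (0,0),(s,0),(s,s),(0,s); right angle sits opposite the dropped corner)
oracle_quadslope <- function(corners, side) {
  angles <- vapply(1:4, function(drop) {
    r <- (drop + 1) %% 4 + 1
    nb <- setdiff(1:4, c(drop, r))
    atan(sqrt((corners[nb[1]] - corners[r])^2 + (corners[nb[2]] - corners[r])^2) / side) * 180 / pi
  }, numeric(1))
  mean(angles)
}

# naive bipartition (split) set of a tree, for topology comparison
tip_splits <- function(tree) {
  tp <- tree_parents(tree)
  nt <- tp$ntip
  below <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) below[[i]] <- tree$tip.label[i]
  ord <- rev(unique(tree$edge[, 1][order(tree$edge[, 1])]))
  # accumulate tips below each internal node by repeated passes (small trees)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(tree$edge))) {
      p <- tree$edge[k, 1]
      c <- tree$edge[k, 2]
      if (!is.null(below[[c]])) {
        add <- setdiff(below[[c]], below[[p]])
        if (length(add) > 0) {
          below[[p]] <- c(below[[p]], add)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(nt))
  splits <- vapply(
    internal,
    function(v) paste(sort(below[[v]]), collapse = "|"),
    ""
  )
  sort(unique(splits[vapply(internal, function(v) length(below[[v]]), 1L) >= 2]))
}

# random ultrametric chronogram via a coalescent-style agglomeration
random_chronogram <- function(n, max_age = 100) {
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * max_age
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}
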