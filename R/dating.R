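#' Build a calibration set
#'
#' A calibration names an internal node either by its internal label or as
#' the most recent common ancestor (MRCA) of a pair of tips, and attaches an
#' age in million years that is either `fixed` (held exactly) or `min` (a
#' lower bound).
#'
#' @param kind Character vector, `"fixed"` or `"min"`.
#' @param node Internal node label, or `NA` when `tip_a`/`tip_b` are used.
#' @param tip_a,tip_b Tip labels whose MRCA is the calibrated node, or `NA`.
#' @param age Ages in million years, positive.
#' @return A tibble of class `calibration_set`.
#' @export
calibration_set <- function(kind, age, node = NA_character_,
                            tip_a = NA_character_, tip_b = NA_character_) {
  cal <- tibble(
    kind = as.character(kind), node = node,
    tip_a = tip_a, tip_b = tip_b, age = as.numeric(age)
  )
  if (!all(cal$kind %in% c("fixed", "min"))) abort("kind must be 'fixed' or 'min'")
  if (any(!is.finite(cal$age)) || any(cal$age <= 0)) abort("ages must be positive")
  has_label <- !is.na(cal$node)
  has_pair <- !is.na(cal$tip_a) & !is.na(cal$tip_b)
  if (!all(has_label | has_pair)) {
    abort("each calibration needs a node label or a tip pair")
  }
  class(cal) <- c("calibration_set", class(cal))
  cal
}

#' Read calibrations from a whitespace-delimited file
#'
#' One entry per line: `fixed|min <tipA>,<tipB>|<node_label> <age>`, the
#' input style of common node-dating tools.
#'
#' @param file Path to the calibration file.
#' @return A [calibration_set()].
#' @export
read_calibrations <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort("no calibration entries found")
  parts <- strsplit(lines, "\\s+")
  bad <- lengths(parts) != 3
  if (any(bad)) abort(paste0("malformed calibration line(s): ", paste(which(bad), collapse = ", ")))
  kind <- vapply(parts, `[[`, "", 1)
  target <- vapply(parts, `[[`, "", 2)
  age <- as.numeric(vapply(parts, `[[`, "", 3))
  is_pair <- grepl(",", target, fixed = TRUE)
  tip_a <- ifelse(is_pair, sub(",.*$", "", target), NA_character_)
  tip_b <- ifelse(is_pair, sub("^.*,", "", target), NA_character_)
  node <- ifelse(is_pair, NA_character_, target)
  calibration_set(kind = kind, age = age, node = node, tip_a = tip_a, tip_b = tip_b)
}

# resolve each calibration to an internal node number of `tree`
resolve_calibrations <- function(tree, cal) {
  ntip <- ape::Ntip(tree)
  node_num <- integer(nrow(cal))
  for (i in seq_len(nrow(cal))) {
    if (!is.na(cal$node[i])) {
      if (identical(cal$node[i], "root")) {
        node_num[i] <- ntip + 1L
      } else {
        if (is.null(tree$node.label)) abort("tree has no internal node labels")
        j <- match(cal$node[i], tree$node.label)
        if (is.na(j)) abort(paste0("calibrated node not found: ", cal$node[i]))
        node_num[i] <- ntip + j
      }
    } else {
      miss <- setdiff(c(cal$tip_a[i], cal$tip_b[i]), tree$tip.label)
      if (length(miss) > 0) {
        abort(paste0("calibration tips not on tree: ", paste(miss, collapse = ", ")))
      }
      node_num[i] <- ape::getMRCA(tree, c(cal$tip_a[i], cal$tip_b[i]))
    }
  }
  dup <- node_num[duplicated(node_num)]
  if (length(dup) > 0) {
    conflicting <- vapply(
      unique(dup),
      function(n) length(unique(cal$age[node_num == n])) > 1 ||
        length(unique(cal$kind[node_num == n])) > 1,
      logical(1)
    )
    if (any(conflicting)) abort("a node carries conflicting calibration entries")
  }
  node_num
}

# children lists and a postorder (children-before-parents) node sequence
tree_traversal <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  n_all <- ntip + nnode
  children <- vector("list", n_all)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    children[[p]] <- c(children[[p]], tree$edge[k, 2])
  }
  parent <- integer(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ntip + 1L
  # iterative preorder, reversed for postorder
  pre <- integer(0)
  stack <- root
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pre <- c(pre, v)
    stack <- c(stack, children[[v]])
  }
  list(
    children = children, parent = parent, root = root,
    preorder = pre, postorder = rev(pre), ntip = ntip
  )
}

ages_to_edge_lengths <- function(tree, ages) {
  tree$edge.length <- ages[tree$edge[, 1]] - ages[tree$edge[, 2]]
  attr(tree, "node_ages") <- ages
  tree
}

#' Node ages of an ultrametric tree
#'
#' @param tree An ultrametric `phylo` (e.g. output of [bladj()] or
#'   [mpl_date()]).
#' @return Numeric vector of ages (time before present) indexed by node
#'   number (tips first, then internal nodes).
#' @export
node_ages <- function(tree) {
  a <- attr(tree, "node_ages")
  if (!is.null(a)) {
    return(a)
  }
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Pseudo-chronogram by even-spacing branch-length adjustment
#'
#' Assigns ages to a tree topology from node calibrations: every calibrated
#' node keeps its age exactly, tips sit at age 0, and each uncalibrated node
#' is placed by even spacing along the chain running from its closest aged
#' ancestor down to the oldest age constraint below it (a calibrated
#' descendant, or the tip level at age 0 via the longest uncalibrated
#' chain). For a chain of k uncalibrated nodes between anchors at ages
#' a_top > a_bottom, the i-th node from the top receives
#' a_top - i (a_top - a_bottom) / (k + 1). Branch lengths of the input are
#' ignored; only the topology is used.
#'
#' @param tree A `phylo`; internal labels address calibrations.
#' @param cal A [calibration_set()]. All entries are treated as exact node
#'   ages (the classic age-file convention of this method); the root must
#'   carry one.
#' @return An ultrametric `phylo` in million-year branch lengths, with node
#'   ages in attribute `"node_ages"`.
#' @export
bladj <- function(tree, cal) {
  tv <- tree_traversal(tree)
  node_num <- resolve_calibrations(tree, cal)
  n_all <- tv$ntip + tree$Nnode
  cal_age <- rep(NA_real_, n_all)
  cal_age[node_num] <- cal$age
  if (any(node_num <= tv$ntip)) abort("calibrations must address internal nodes")
  if (is.na(cal_age[tv$root])) abort("the root must carry a calibrated age")

  # oldest constraint below each node: (age, m = uncalibrated nodes strictly
  # between the node and the constraint), built tips-up
  best_age <- rep(NA_real_, n_all)
  best_m <- rep(NA_integer_, n_all)
  for (v in tv$postorder) {
    if (v <= tv$ntip) next
    b_age <- -Inf
    b_m <- -1L
    for (c in tv$children[[v]]) {
      if (c <= tv$ntip) {
        c_age <- 0
        c_m <- 0L
      } else if (!is.na(cal_age[c])) {
        c_age <- cal_age[c]
        c_m <- 0L
      } else {
        c_age <- best_age[c]
        c_m <- best_m[c] + 1L
      }
      if (c_age > b_age || (c_age == b_age && c_m > b_m)) {
        b_age <- c_age
        b_m <- c_m
      }
    }
    best_age[v] <- b_age
    best_m[v] <- b_m
  }

  ages <- rep(0, n_all)
  for (v in tv$preorder) {
    if (v <= tv$ntip) next
    if (v == tv$root) {
      ages[v] <- cal_age[v]
      next
    }
    p_age <- ages[tv$parent[v]]
    if (!is.na(cal_age[v])) {
      if (cal_age[v] > p_age + 1e-12) {
        abort(paste0(
          "calibration conflict: node aged ", cal_age[v],
          " lies below an ancestor aged ", signif(p_age, 10)
        ))
      }
      ages[v] <- cal_age[v]
    } else {
      k <- best_m[v] + 1L
      ages[v] <- p_age - (p_age - best_age[v]) / (k + 1)
    }
  }
  ages_to_edge_lengths(tree, ages)
}

#' Mean-path-length dating with age constraints
#'
#' Transforms a tree with substitution branch lengths into an ultrametric
#' chronogram: (1) the raw depth of each internal node is the mean path
#' length from the node to its descendant tips; (2) all depths are rescaled
#' so the node carrying the single fixed age matches it; (3) minimum-age
#' constraints raise any violating node to its bound; (4) a single root-ward
#' sweep restores monotonicity (a parent is at least as old as its oldest
#' child). This is a deliberate simplification of rate-smoothing dating: no
#' correction for rate heterogeneity is attempted.
#'
#' @param tree A `phylo` with branch lengths (substitutions).
#' @param cal A [calibration_set()] with exactly one `fixed` entry and any
#'   number of `min` entries.
#' @return An ultrametric `phylo` in million-year units, node ages in
#'   attribute `"node_ages"`.
#' @export
mpl_date <- function(tree, cal) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (all(tree$edge.length == 0)) abort("all branch lengths are zero; cannot date")
  fixed <- cal[cal$kind == "fixed", , drop = FALSE]
  if (nrow(fixed) != 1) abort("exactly one fixed age is required")
  mins <- cal[cal$kind == "min", , drop = FALSE]

  tv <- tree_traversal(tree)
  n_all <- tv$ntip + tree$Nnode
  blen <- rep(NA_real_, n_all)
  blen[tree$edge[, 2]] <- tree$edge.length

  ntips <- integer(n_all)
  sumpath <- numeric(n_all)
  for (v in tv$postorder) {
    if (v <= tv$ntip) {
      ntips[v] <- 1L
      next
    }
    for (c in tv$children[[v]]) {
      ntips[v] <- ntips[v] + ntips[c]
      sumpath[v] <- sumpath[v] + sumpath[c] + ntips[c] * blen[c]
    }
  }
  depth <- ifelse(seq_len(n_all) <= tv$ntip, 0, sumpath / pmax(ntips, 1L))

  fixed_node <- resolve_calibrations(tree, fixed)
  if (fixed_node <= tv$ntip) abort("the fixed age must sit on an internal node")
  if (depth[fixed_node] <= 0) abort("fixed-age node has zero mean path length")
  ages <- depth * (fixed$age / depth[fixed_node])

  if (nrow(mins) > 0) {
    min_nodes <- resolve_calibrations(tree, mins)
    if (any(mins$age > fixed$age & fixed_node == tv$root)) {
      abort("a minimum age exceeds the fixed root age")
    }
    ages[min_nodes] <- pmax(ages[min_nodes], mins$age)
  }
  # root-ward monotone sweep
  for (v in tv$postorder) {
    if (v == tv$root) next
    p <- tv$parent[v]
    if (ages[v] > ages[p]) ages[p] <- ages[v]
  }
  if (abs(ages[fixed_node] - fixed$age) > 1e-9 * fixed$age) {
    abort("minimum-age constraints conflict with the fixed age")
  }
  ages_to_edge_lengths(tree, ages)
}
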