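#' Faith's phylogenetic diversity of one community
#'
#' Sum of branch lengths of the minimal spanning subtree connecting the
#' taxa present in the community; on a chronogram the result is in million
#' years. With `include_root = TRUE` (default) the path from the subtree up
#' to the tree root is included, so a single-taxon community has PD equal to
#' its root-to-tip depth.
#'
#' @param tree A `phylo` with branch lengths.
#' @param taxa Character vector of present taxa, or a named numeric vector
#'   (abundances; presence is abundance > 0).
#' @param include_root Include the root path (default `TRUE`).
#' @return PD in branch-length units (million years on a chronogram).
#' @export
faith_pd <- function(tree, taxa, include_root = TRUE) {
  if (is.numeric(taxa)) taxa <- names(taxa)[taxa > 0]
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0) abort("at least one taxon must be present")
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("taxa not on tree: ", paste(missing, collapse = ", ")))
  }
  tv <- tree_traversal(tree)
  n_all <- tv$ntip + tree$Nnode
  present_below <- integer(n_all)
  present_below[match(taxa, tree$tip.label)] <- 1L
  for (v in tv$postorder) {
    if (v > tv$ntip) {
      for (c in tv$children[[v]]) present_below[v] <- present_below[v] + present_below[c]
    }
  }
  s <- length(taxa)
  child <- tree$edge[, 2]
  on_subtree <- present_below[child] >= 1L
  if (!include_root) on_subtree <- on_subtree & present_below[child] < s
  sum(tree$edge.length[on_subtree])
}

# set-up shared by mpd/mntd: named abundances -> (sub-matrix, counts)
metric_inputs <- function(dist, abundances) {
  if (is.null(names(abundances))) abort("abundances must be a named vector")
  abundances <- abundances[abundances > 0]
  missing <- setdiff(names(abundances), rownames(dist))
  if (length(missing) > 0) {
    abort(paste0("taxa not in distance matrix: ", paste(missing, collapse = ", ")))
  }
  idx <- match(names(abundances), rownames(dist))
  list(d = dist[idx, idx, drop = FALSE], n = as.numeric(abundances))
}

mpd_from <- function(d, n, weighted) {
  s <- length(n)
  if (s < 2) {
    return(NA_real_)
  }
  if (weighted) {
    # heterospecific pairs only; diag(d) = 0 removes self terms from the
    # numerator, the denominator drops them explicitly
    num <- as.numeric(t(n) %*% d %*% n)
    den <- sum(n)^2 - sum(n^2)
    num / den
  } else {
    sum(d[lower.tri(d)]) / (s * (s - 1) / 2)
  }
}

mntd_from <- function(d, n, weighted) {
  s <- length(n)
  if (s < 2) {
    return(NA_real_)
  }
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  if (weighted) sum(nn * n) / sum(n) else mean(nn)
}

#' Mean pairwise phylogenetic distance of one community
#'
#' Mean patristic distance over heterospecific pairs. When
#' `weighted = TRUE` the pairs are weighted by abundance products
#' (conspecific self-pairs excluded):
#' \eqn{\sum_{i \ne j} d_{ij} n_i n_j / \sum_{i \ne j} n_i n_j}.
#'
#' @param dist Symmetric patristic distance matrix with taxon dimnames.
#' @param abundances Named numeric vector of abundances (taxa with count 0
#'   are ignored).
#' @param weighted Weight by abundances (default `FALSE`).
#' @return The mean pairwise distance, or `NA` when fewer than two taxa are
#'   present.
#' @export
mpd <- function(dist, abundances, weighted = FALSE) {
  inp <- metric_inputs(dist, abundances)
  mpd_from(inp$d, inp$n, weighted)
}

#' Mean nearest taxon distance of one community
#'
#' For each present taxon the distance to its closest heterospecific
#' relative; the community value is the (abundance-weighted) mean of these
#' nearest-neighbour distances.
#'
#' @inheritParams mpd
#' @return The mean nearest taxon distance, or `NA` when fewer than two
#'   taxa are present.
#' @export
mntd <- function(dist, abundances, weighted = FALSE) {
  inp <- metric_inputs(dist, abundances)
  mntd_from(inp$d, inp$n, weighted)
}

#' Tip-shuffle null distribution for MPD or MNTD
#'
#' Randomises species identities by shuffling tip labels across the entire
#' distance matrix: each randomisation draws a uniformly random relabelling
#' of the pool, so the community keeps its richness and abundance vector
#' but sits on random tips. Equivalent to drawing a random subset of pool
#' taxa and carrying the observed abundances over.
#'
#' @inheritParams mpd
#' @param metric `"mpd"` or `"mntd"`.
#' @param n_rand Number of randomisations (study value 1000).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `null_ensemble`: list with `metric`, `obs`,
#'   `values` (length `n_rand`), `mean`, `sd`, `rank` (of obs among
#'   obs and randomisations, mean rank under ties) and `n_rand`.
#' @export
tip_shuffle_null <- function(dist, abundances, metric = c("mpd", "mntd"),
                             weighted = FALSE, n_rand = 1000, seed = NULL) {
  metric <- match.arg(metric)
  if (n_rand < 1) abort("n_rand must be >= 1")
  inp <- metric_inputs(dist, abundances)
  fun <- if (metric == "mpd") mpd_from else mntd_from
  obs <- fun(inp$d, inp$n, weighted)
  if (!is.null(seed)) set.seed(seed)
  pool <- nrow(dist)
  s <- length(inp$n)
  values <- vapply(seq_len(n_rand), function(r) {
    idx <- sample.int(pool, s)
    fun(dist[idx, idx, drop = FALSE], inp$n, weighted)
  }, numeric(1))
  rk <- rank(c(obs, values))[1]
  structure(
    list(
      metric = metric, weighted = weighted, obs = obs, values = values,
      mean = mean(values), sd = sd(values), rank = unname(rk), n_rand = n_rand
    ),
    class = "null_ensemble"
  )
}

#' Standardised effect size from a null ensemble
#'
#' SES = (obs - mean(rand)) / sd(rand); the rank-based quantile is
#' q = rank(obs) / (n_rand + 1). The net relatedness index (NRI, from MPD)
#' and nearest taxon index (NTI, from MNTD) are -1 times the respective
#' SES, so positive values indicate phylogenetic clustering.
#'
#' @param null A `null_ensemble` from [tip_shuffle_null()].
#' @return A tibble with one row: `metric`, `obs`, `null_mean`, `null_sd`,
#'   `ses`, `q` and `degenerate` (`TRUE` when the null has zero spread, in
#'   which case `ses` is `NA` and `q` is 1).
#' @export
ses <- function(null) {
  stopifnot(inherits(null, "null_ensemble"))
  degenerate <- !is.finite(null$sd) || null$sd == 0 || !is.finite(null$obs)
  tibble(
    metric = null$metric,
    obs = null$obs,
    null_mean = null$mean,
    null_sd = null$sd,
    ses = if (degenerate) NA_real_ else (null$obs - null$mean) / null$sd,
    q = if (degenerate) 1 else null$rank / (null$n_rand + 1),
    degenerate = degenerate
  )
}

#' Classify a community as clustered, overdispersed or random
#'
#' Uses the low-tail rank quantile of the observed metric under the null.
#' Two-tailed (default): clustered when q <= alpha/2, overdispersed when
#' q >= 1 - alpha/2. One-tailed-each-way: thresholds alpha and 1 - alpha.
#'
#' @param q Rank quantile(s) in (0, 1].
#' @param alpha Significance level (default 0.05).
#' @param tail `"two"` (default) or `"one"`.
#' @return Character vector: `"clustered"`, `"overdispersed"` or
#'   `"random"`.
#' @export
classify_significance <- function(q, alpha = 0.05, tail = c("two", "one")) {
  tail <- match.arg(tail)
  lo <- if (tail == "two") alpha / 2 else alpha
  hi <- 1 - lo
  dplyr::case_when(
    is.na(q) ~ "random",
    q <= lo ~ "clustered",
    q >= hi ~ "overdispersed",
    TRUE ~ "random"
  )
}
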