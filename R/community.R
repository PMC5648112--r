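#' Coerce to a community table
#'
#' A community table is a tibble whose first column, `subplot`, identifies
#' a quadrat and whose remaining numeric columns hold non-negative integer
#' stem counts per taxon (one column per phylogeny tip).
#'
#' @param x A data frame (first column subplot ids), or a numeric matrix
#'   with subplot rownames and taxon colnames.
#' @return A validated tibble with first column `subplot`.
#' @export
as_community <- function(x) {
  if (is.matrix(x)) {
    x <- tibble::as_tibble(x, rownames = "subplot")
  }
  stopifnot(is.data.frame(x))
  x <- as_tibble(x)
  if (names(x)[1] != "subplot") names(x)[1] <- "subplot"
  x$subplot <- as.character(x$subplot)
  vals <- x[, -1, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("taxon columns must be numeric counts")
  }
  if (any(as.matrix(vals) < 0, na.rm = TRUE)) abort("abundances must be >= 0")
  if (anyDuplicated(x$subplot)) abort("duplicate subplot ids")
  x
}

community_matrix <- function(comm) {
  comm <- as_community(comm)
  m <- as.matrix(comm[, -1, drop = FALSE])
  rownames(m) <- comm$subplot
  m
}

#' Read a community matrix from delimited text
#'
#' Subplots as rows, taxa as columns; the delimiter (tab, comma,
#' semicolon or whitespace) is sniffed from the header line.
#'
#' @param file Path to the table.
#' @return A community tibble (see [as_community()]).
#' @export
read_community <- function(file) {
  header <- readLines(file, n = 1)
  delim <- if (grepl("\t", header)) {
    "\t"
  } else if (grepl(",", header)) {
    ","
  } else if (grepl(";", header)) {
    ";"
  } else {
    " "
  }
  df <- if (delim == " ") {
    readr::read_table(file, show_col_types = FALSE)
  } else {
    readr::read_delim(file, delim = delim, show_col_types = FALSE)
  }
  as_community(df)
}

#' Write a community matrix as TSV
#'
#' @param comm A community tibble.
#' @param file Output path.
#' @export
write_community <- function(comm, file) {
  readr::write_tsv(as_community(comm), file)
}

#' Per-subplot phylogenetic community structure
#'
#' For every subplot of a community table computes species richness,
#' Faith's PD, abundance-weighted (or unweighted) MPD and MNTD, their
#' standardised effect sizes under the tip-shuffle null, the net
#' relatedness index (NRI = -SES of MPD) and nearest taxon index
#' (NTI = -SES of MNTD), rank p-quantiles, and a significance call per
#' metric. Subplots with fewer than two taxa get `NA` metrics and are
#' flagged (they are excluded from downstream means and tests).
#'
#' Reproducibility: each (subplot, metric) null stream uses its own seed
#' derived from `seed` by a fixed counter, so results do not depend on
#' subplot order.
#'
#' @param comm Community tibble (see [as_community()]); taxon columns must
#'   match tree tips.
#' @param tree Ultrametric `phylo` chronogram.
#' @param weighted Abundance-weight MPD/MNTD (default `TRUE`, the study
#'   setting).
#' @param n_rand Tip-shuffle randomisations per subplot (default 1000).
#' @param seed Integer seed.
#' @param alpha,tail Significance settings for [classify_significance()].
#' @param include_root Passed to [faith_pd()].
#' @return An object of class `phylo_structure`; use [tidy()] for the
#'   per-subplot tibble and [glance()] for the one-row summary.
#' @export
phylo_structure <- function(comm, tree, weighted = TRUE, n_rand = 1000,
                            seed = NULL, alpha = 0.05, tail = c("two", "one"),
                            include_root = TRUE) {
  tail <- match.arg(tail)
  if (n_rand < 1) abort("n_rand must be >= 1")
  m <- community_matrix(comm)
  unmatched <- setdiff(colnames(m), tree$tip.label)
  if (length(unmatched) > 0) {
    abort(paste0(
      "community taxa absent from tree: ",
      paste(unmatched, collapse = ", ")
    ))
  }
  dist <- cophenetic_dist(tree)
  # per-subplot seed substreams keyed by the subplot id's rank, so results
  # do not depend on row order
  id_rank <- match(rownames(m), sort(rownames(m)))

  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    x <- m[i, ]
    x <- x[x > 0]
    rich <- length(x)
    base <- tibble(
      subplot = rownames(m)[i], richness = rich, n_stems = sum(x)
    )
    if (rich == 0) {
      return(dplyr::mutate(base,
        pd = NA_real_, mpd = NA_real_, mntd = NA_real_,
        ses_mpd = NA_real_, ses_mntd = NA_real_,
        nri = NA_real_, nti = NA_real_,
        q_mpd = NA_real_, q_mntd = NA_real_,
        call_nri = NA_character_, call_nti = NA_character_,
        degenerate = NA
      ))
    }
    pd_i <- faith_pd(tree, x, include_root = include_root)
    if (rich < 2) {
      return(dplyr::mutate(base,
        pd = pd_i, mpd = NA_real_, mntd = NA_real_,
        ses_mpd = NA_real_, ses_mntd = NA_real_,
        nri = NA_real_, nti = NA_real_,
        q_mpd = NA_real_, q_mntd = NA_real_,
        call_nri = NA_character_, call_nti = NA_character_,
        degenerate = NA
      ))
    }
    seed_i <- if (is.null(seed)) NULL else (seed + 2L * id_rank[i]) %% .Machine$integer.max
    seed_j <- if (is.null(seed)) NULL else (seed + 2L * id_rank[i] + 1L) %% .Machine$integer.max
    s_mpd <- ses(tip_shuffle_null(dist, x, "mpd", weighted, n_rand, seed_i))
    s_mntd <- ses(tip_shuffle_null(dist, x, "mntd", weighted, n_rand, seed_j))
    dplyr::mutate(base,
      pd = pd_i, mpd = s_mpd$obs, mntd = s_mntd$obs,
      ses_mpd = s_mpd$ses, ses_mntd = s_mntd$ses,
      nri = -s_mpd$ses, nti = -s_mntd$ses,
      q_mpd = s_mpd$q, q_mntd = s_mntd$q,
      call_nri = classify_significance(s_mpd$q, alpha, tail),
      call_nti = classify_significance(s_mntd$q, alpha, tail),
      degenerate = s_mpd$degenerate | s_mntd$degenerate
    )
  })

  structure(
    list(
      metrics = dplyr::bind_rows(rows),
      params = list(
        weighted = weighted, n_rand = n_rand, seed = seed,
        alpha = alpha, tail = tail, include_root = include_root,
        pool_size = length(tree$tip.label)
      )
    ),
    class = "phylo_structure"
  )
}

#' @export
print.phylo_structure <- function(x, ...) {
  p <- x$params
  ok <- x$metrics$richness >= 2
  cat(
    "Phylogenetic community structure:", nrow(x$metrics), "subplots (",
    sum(!ok), "with < 2 taxa ),", p$pool_size, "pool taxa\n"
  )
  cat(
    "  null: tip shuffle,", p$n_rand, "randomisations;",
    if (p$weighted) "abundance-weighted;" else "unweighted;",
    paste0(p$tail, "-tailed alpha = ", p$alpha), "\n"
  )
  cat(
    "  mean NRI:", signif(mean(x$metrics$nri[ok], na.rm = TRUE), 4),
    " mean NTI:", signif(mean(x$metrics$nti[ok], na.rm = TRUE), 4), "\n"
  )
  cat(
    "  NRI calls:", sum(x$metrics$call_nri[ok] == "clustered", na.rm = TRUE),
    "clustered /", sum(x$metrics$call_nri[ok] == "overdispersed", na.rm = TRUE),
    "overdispersed\n"
  )
  invisible(x)
}

#' @describeIn phylo_structure Per-subplot metric tibble.
#' @param x A `phylo_structure` object.
#' @param ... Unused.
#' @export
tidy.phylo_structure <- function(x, ...) {
  x$metrics
}

#' @describeIn phylo_structure One-row summary: means, variances and
#'   significance counts over subplots with at least two taxa.
#' @export
glance.phylo_structure <- function(x, ...) {
  m <- x$metrics[!is.na(x$metrics$nri) | !is.na(x$metrics$nti), , drop = FALSE]
  tibble(
    n_subplots = nrow(x$metrics),
    n_used = nrow(m),
    mean_pd = mean(m$pd, na.rm = TRUE),
    mean_nri = mean(m$nri, na.rm = TRUE),
    mean_nti = mean(m$nti, na.rm = TRUE),
    var_nri = var(m$nri, na.rm = TRUE),
    var_nti = var(m$nti, na.rm = TRUE),
    n_nri_clustered = sum(m$call_nri == "clustered", na.rm = TRUE),
    n_nri_overdispersed = sum(m$call_nri == "overdispersed", na.rm = TRUE),
    n_nti_clustered = sum(m$call_nti == "clustered", na.rm = TRUE),
    n_nti_overdispersed = sum(m$call_nti == "overdispersed", na.rm = TRUE)
  )
}

#' @describeIn phylo_structure NRI/NTI dot plot across subplots, coloured
#'   by significance call.
#' @param object A `phylo_structure` object.
#' @export
autoplot.phylo_structure <- function(object, ...) {
  long <- tidy(object) |>
    dplyr::filter(.data$richness >= 2) |>
    dplyr::select("subplot", "nri", "nti", "call_nri", "call_nti") |>
    tidyr::pivot_longer(c("nri", "nti"),
      names_to = "index", values_to = "value"
    ) |>
    dplyr::mutate(
      call = ifelse(.data$index == "nri", .data$call_nri, .data$call_nti),
      index = toupper(.data$index)
    )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$index, y = .data$value, colour = .data$call
  )) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = NULL, y = "index value", colour = "call",
      title = "Net relatedness and nearest taxon indices"
    )
}
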