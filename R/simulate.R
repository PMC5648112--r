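#' Simulate an ultrametric species-pool phylogeny
#'
#' Pure-birth (Yule) tree in time units, the standard stand-in for a
#' regional species pool. Simulation is delegated to [ape::rphylo()]
#' conditioned on the number of extant tips.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth Speciation rate per lineage per time unit.
#' @param seed Optional integer seed.
#' @return An ultrametric `phylo` with tips `sp001`, `sp002`, ...
#' @export
simulate_pool_tree <- function(n_species, birth = 1, seed = NULL) {
  if (n_species < 2) abort("n_species must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth, death = 0)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

#' Evolve a continuous trait by Brownian motion
#'
#' Brownian motion along the branches (via [ape::rTraitCont()]), so the
#' covariance of two tips equals sigma^2 times their shared path length —
#' the trait-conservatism premise under which habitat filtering produces
#' phylogenetic clustering.
#'
#' @param tree A `phylo` with branch lengths.
#' @param sigma Brownian rate (per sqrt time unit).
#' @param seed Optional integer seed.
#' @param k Number of independent trait axes. One axis suffices for
#'   habitat filtering; limiting-similarity simulations are far more
#'   reliable on a multi-axis niche (see [assemble_community()]).
#' @return For `k = 1` a named numeric vector of tip trait values (root
#'   state 0); for `k > 1` a tips x axes matrix.
#' @export
simulate_traits <- function(tree, sigma = 1, seed = NULL, k = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (k == 1) {
    return(ape::rTraitCont(tree, model = "BM", sigma = sigma, root.value = 0))
  }
  m <- vapply(
    seq_len(k),
    function(i) ape::rTraitCont(tree, model = "BM", sigma = sigma, root.value = 0),
    numeric(ape::Ntip(tree))
  )
  rownames(m) <- tree$tip.label
  colnames(m) <- paste0("trait", seq_len(k))
  m
}

#' Sample from a Fisher log-series abundance distribution
#'
#' P(k) proportional to x^k / k, the classic fit to tropical stem counts.
#'
#' @param n Number of draws.
#' @param x Log-series parameter in (0, 1); larger values give heavier
#'   tails.
#' @return Integer vector of abundances >= 1.
#' @export
rlogseries <- function(n, x = 0.9) {
  if (x <= 0 || x >= 1) abort("x must be in (0, 1)")
  kmax <- 1
  repeat {
    k <- seq_len(kmax)
    p <- x^k / k
    if (p[kmax] / sum(p) < 1e-12) break
    kmax <- kmax * 2
  }
  sample.int(kmax, n, replace = TRUE, prob = p)
}

#' Assemble one community from a species pool
#'
#' Draws a community of the given richness from the pool under one of
#' three assembly regimes: `neutral` (uniform sampling of species),
#' `filter` (habitat filtering — sampling weights proportional to
#' exp(-(trait - optimum)^2 / (2 w^2)) on the first trait axis, which
#' clusters the community on the trait and, under trait conservatism, on
#' the phylogeny) or `repulsion` (limiting similarity — sequential
#' max-min spacing on Euclidean niche distance over all trait axes,
#' producing overdispersion). Abundances are drawn from a log-series or
#' geometric distribution.
#'
#' A note on the repulsion regime: with a single trait axis, even trait
#' spacing only weakly (and unreliably) translates into phylogenetic
#' overdispersion, because a one-dimensional spacing can still land
#' repeatedly inside trait-dense clades. A multi-axis Brownian niche
#' (`k >= 3` in [simulate_traits()]) makes niche distance track
#' phylogenetic distance closely enough for consistent overdispersion and
#' is the regime the package's recovery experiments use.
#'
#' @param traits Named trait vector, or a species x axes trait matrix
#'   with species rownames (from [simulate_traits()]).
#' @param richness Number of species to draw.
#' @param model `"neutral"`, `"filter"` or `"repulsion"`.
#' @param optimum Trait optimum for `filter` (default: pool mean).
#' @param filter_sd Filter width w (trait units); `Inf` reduces `filter`
#'   to `neutral`.
#' @param abundance `"logseries"` or `"geometric"`.
#' @param ab_param Log-series x, or geometric success probability.
#' @return Named integer vector of abundances for the selected species.
#' @export
assemble_community <- function(traits, richness,
                               model = c("neutral", "filter", "repulsion"),
                               optimum = NULL, filter_sd = 0.5,
                               abundance = c("logseries", "geometric"),
                               ab_param = 0.9) {
  model <- match.arg(model)
  abundance <- match.arg(abundance)
  tm <- if (is.matrix(traits)) traits else matrix(traits,
    dimnames = list(names(traits), "trait1")
  )
  pool <- rownames(tm)
  if (is.null(pool)) abort("traits must carry species names")
  if (richness < 1 || richness > length(pool)) {
    abort("richness must be between 1 and the pool size")
  }
  axis1 <- tm[, 1]
  chosen <- switch(model,
    neutral = sample(pool, richness),
    filter = {
      opt <- optimum %||% mean(axis1)
      w <- if (is.finite(filter_sd)) {
        exp(-(axis1 - opt)^2 / (2 * filter_sd^2))
      } else {
        rep(1, length(axis1))
      }
      if (sum(w) == 0) w <- rep(1, length(axis1))
      sample(pool, richness, prob = w)
    },
    repulsion = {
      sel <- sample(pool, 1)
      while (length(sel) < richness) {
        rest <- setdiff(pool, sel)
        dmin <- vapply(rest, function(s) {
          min(sqrt(colSums((t(tm[sel, , drop = FALSE]) - tm[s, ])^2)))
        }, numeric(1))
        best <- rest[dmin == max(dmin)]
        sel <- c(sel, if (length(best) > 1) sample(best, 1) else best)
      }
      sel
    }
  )
  ab <- switch(abundance,
    logseries = rlogseries(richness, ab_param),
    geometric = stats::rgeom(richness, ab_param) + 1L
  )
  setNames(as.integer(ab), chosen)
}

#' Assemble a community table of many subplots
#'
#' Repeated [assemble_community()] draws packed into a community tibble.
#' All randomness flows from `seed`, so the table is reproducible.
#'
#' @inheritParams assemble_community
#' @param n_plots Number of subplots.
#' @param richness Scalar richness, or length-2 vector giving an inclusive
#'   uniform integer range per subplot.
#' @param optima Optional vector of per-subplot trait optima (recycled),
#'   used by the `filter` model to tie composition to an environment.
#'   `filter_sd` may likewise be a per-subplot vector (recycled), letting
#'   filter strength vary along an environmental gradient.
#' @param seed Optional integer seed.
#' @return A community tibble with subplots `q001`, `q002`, ...
#' @export
simulate_communities <- function(traits, n_plots, richness,
                                 model = "neutral", optima = NULL,
                                 filter_sd = 0.5,
                                 abundance = "logseries", ab_param = 0.9,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(optima)) optima <- rep_len(optima, n_plots)
  filter_sd <- rep_len(filter_sd, n_plots)
  rich <- if (length(richness) == 2) {
    sample(seq(richness[1], richness[2]), n_plots, replace = TRUE)
  } else {
    rep(richness, n_plots)
  }
  rows <- purrr::map(seq_len(n_plots), function(i) {
    ab <- assemble_community(traits, rich[i],
      model = model,
      optimum = if (is.null(optima)) NULL else optima[i],
      filter_sd = filter_sd[i], abundance = abundance, ab_param = ab_param
    )
    tibble(subplot = sprintf("q%03d", i), taxon = names(ab), n = as.integer(ab))
  })
  dplyr::bind_rows(rows) |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "n", values_fill = 0L) |>
    as_community()
}

#' Simulate a smooth elevation grid
#'
#' Sum of a random linear trend and low-frequency cosine waves, rescaled
#' to a target elevation range — a smooth stand-in for the dissected
#' topography of a steep tropical plot. With `smoothness = Inf` the waves
#' vanish and the surface is exactly affine (all interior convexities 0).
#'
#' @param n_rows,n_cols Number of quadrats in each direction.
#' @param spacing Quadrat side in metres (default 10).
#' @param elev_range Target min/max elevation in metres (default
#'   `c(160, 320)`, a steep hill-and-valley plot).
#' @param smoothness Dominant wavelength in quadrat units (larger =
#'   smoother; `Inf` = affine).
#' @param n_waves Number of cosine components.
#' @param seed Optional integer seed.
#' @return A [topo_grid()] over an (R+1) x (C+1) corner lattice.
#' @export
simulate_topography <- function(n_rows = 50, n_cols = 50, spacing = 10,
                                elev_range = c(160, 320), smoothness = 8,
                                n_waves = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xs <- seq(0, n_cols) * spacing
  ys <- seq(0, n_rows) * spacing
  gx <- outer(rep(1, length(ys)), xs)
  gy <- outer(ys, rep(1, length(xs)))
  slope_dir <- runif(1, 0, 2 * pi)
  z <- cos(slope_dir) * gx + sin(slope_dir) * gy
  z <- z / max(abs(z))
  if (is.finite(smoothness)) {
    wavelength <- smoothness * spacing
    for (k in seq_len(n_waves)) {
      theta <- runif(1, 0, 2 * pi)
      freq <- runif(1, 0.5, 1.5) / wavelength
      phase <- runif(1, 0, 2 * pi)
      amp <- runif(1, 0.3, 1)
      z <- z + amp * cos(2 * pi * freq * (cos(theta) * gx + sin(theta) * gy) + phase)
    }
  }
  span <- max(z) - min(z)
  if (span == 0) span <- 1
  z <- elev_range[1] + (z - min(z)) / span * diff(elev_range)
  topo_grid(z, spacing = spacing)
}

#' Simulate a complete synthetic study
#'
#' Ground-truth bundle for the full pipeline: a dated species-pool tree, a
#' Brownian trait, a smooth elevation grid with per-quadrat topography and
#' habitat labels, a stratified sample of subplots, and communities
#' assembled on those subplots. Under the `filter` model the trait optimum
#' of each subplot follows its (standardised) elevation, so composition —
#' and with it phylogenetic structure — tracks topography.
#'
#' @param seed Integer seed driving every random step.
#' @param n_species Pool size.
#' @param n_plots Number of sampled subplots.
#' @param richness Per-subplot richness (scalar or range, see
#'   [simulate_communities()]).
#' @param model Assembly regime for the communities.
#' @param filter_sd Filter width in trait standard deviations.
#' @param n_rows,n_cols Quadrat grid dimensions.
#' @param smoothness Topography smoothness (see [simulate_topography()]).
#' @return A list: `tree`, `traits`, `grid`, `topo` (quadrat table with
#'   habitats), `sampled` (the subplot rows used), `comm` (community
#'   tibble keyed by the sampled subplot ids).
#' @export
simulate_study <- function(seed = 1, n_species = 120, n_plots = 70,
                           richness = c(10, 25), model = "filter",
                           filter_sd = 0.5, n_rows = 20, n_cols = 20,
                           smoothness = 8) {
  set.seed(seed)
  tree <- simulate_pool_tree(n_species)
  # repulsion needs a multi-axis niche to produce reliable overdispersion
  traits <- simulate_traits(tree, sigma = 1, k = if (model == "repulsion") 3 else 1)
  axis1 <- if (is.matrix(traits)) traits[, 1] else traits
  grid <- simulate_topography(n_rows = n_rows, n_cols = n_cols, smoothness = smoothness)
  topo <- classify_habitat(quadrat_topography(grid))
  sampled <- topo[sample.int(nrow(topo), n_plots), , drop = FALSE]
  opt <- NULL
  widths <- filter_sd * sd(axis1)
  if (model == "filter") {
    # the trait optimum follows elevation, and the filter narrows on
    # convex terrain (ridges/crests filter harder than gullies), so
    # phylogenetic clustering strengthens with convexity by construction
    e <- scale(sampled$elevation)[, 1]
    opt <- e * sd(axis1) + mean(axis1)
    conv <- scale(sampled$convexity)[, 1]
    widths <- widths * exp(-0.5 * conv)
  }
  comm <- simulate_communities(traits, n_plots, richness,
    model = model, optima = opt, filter_sd = widths
  )
  comm$subplot <- sampled$subplot
  list(
    tree = tree, traits = traits, grid = grid, topo = topo,
    sampled = as_tibble(sampled), comm = comm
  )
}
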