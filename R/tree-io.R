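#' Read a phylogeny from newick or NEXUS text
#'
#' Thin wrapper around [ape::read.tree()] / [ape::read.nexus()] that sniffs
#' the dialect, validates the result (unique, non-empty tip labels;
#' non-negative branch lengths) and optionally sanitises tip labels
#' (spaces to underscores), recording the mapping so labels can be joined
#' back to community-matrix columns.
#'
#' @param file Path to a newick (`.nwk`/`.tre`/free-form) or NEXUS file.
#'   NEXUS files may contain several trees; all are returned.
#' @param text Newick string, used instead of `file` when supplied.
#' @param sanitize_labels Replace spaces in tip labels with underscores.
#' @return A single `phylo` object, or a `multiPhylo` list when the source
#'   holds more than one tree. When labels were altered, the attribute
#'   `"label_map"` holds a tibble with columns `original`, `sanitized`.
#' @seealso [write_phylo()], [label_map()]
#' @export
read_phylo <- function(file = NULL, text = NULL, sanitize_labels = TRUE) {
  if (is.null(file) && is.null(text)) {
    abort("supply either `file` or `text`")
  }
  if (is.null(text)) {
    raw <- paste(readLines(file, warn = FALSE), collapse = "\n")
  } else {
    raw <- text
  }
  is_nexus <- grepl("^\\s*#NEXUS", raw, ignore.case = TRUE)
  tr <- if (is_nexus) {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf), add = TRUE)
    writeLines(raw, tf)
    ape::read.nexus(tf)
  } else {
    parsed <- tryCatch(ape::read.tree(text = raw),
      error = function(e) abort(paste0("newick parse error: ", conditionMessage(e)))
    )
    if (is.null(parsed)) abort("newick parse error: no tree could be read")
    parsed
  }
  if (inherits(tr, "multiPhylo")) {
    out <- lapply(tr, validate_phylo, sanitize_labels = sanitize_labels)
    class(out) <- "multiPhylo"
    return(out)
  }
  validate_phylo(tr, sanitize_labels = sanitize_labels)
}

validate_phylo <- function(tree, sanitize_labels = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (any(!nzchar(labs))) abort("empty tip labels are not allowed")
  if (anyDuplicated(labs)) {
    abort(paste0(
      "duplicate tip labels: ",
      paste(unique(labs[duplicated(labs)]), collapse = ", ")
    ))
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < -1e-12, na.rm = TRUE)) {
    abort("negative branch lengths are not allowed")
  }
  if (sanitize_labels) {
    orig <- gsub("^'|'$", "", labs) # ape keeps surrounding quotes
    clean <- gsub("[ ']", "_", orig)
    if (!identical(clean, labs)) {
      attr(tree, "label_map") <- tibble(original = orig, sanitized = clean)
      tree$tip.label <- clean
    }
  }
  tree
}

#' Tip-label sanitation map of a tree
#'
#' @param tree A `phylo` read with [read_phylo()].
#' @return A tibble with columns `original` and `sanitized` (identity map
#'   when no label needed cleaning).
#' @export
label_map <- function(tree) {
  m <- attr(tree, "label_map")
  if (is.null(m)) {
    m <- tibble(original = tree$tip.label, sanitized = tree$tip.label)
  }
  m
}

#' Write a phylogeny as newick
#'
#' Emits unquoted labels and branch lengths with 6 significant digits, and
#' can write the label sanitation map as a sidecar TSV next to the tree.
#'
#' @param tree A `phylo`.
#' @param file Output path; when `NULL` the newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @param label_map_file Optional path for the sidecar label-map TSV.
#' @return The newick string, invisibly when written to a file.
#' @export
write_phylo <- function(tree, file = NULL, digits = 6, label_map_file = NULL) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(label_map_file)) {
    readr::write_tsv(label_map(tree), label_map_file)
  }
  if (is.null(file)) {
    return(txt)
  }
  writeLines(txt, file)
  invisible(txt)
}

#' Patristic (cophenetic) distance matrix
#'
#' Pairwise tip-to-tip path-length distances on the tree; for a chronogram
#' the entries are in (twice the) million-year units of divergence.
#'
#' @param tree A `phylo` with branch lengths on every edge.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @export
cophenetic_dist <- function(tree) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- tree$edge[is.na(tree$edge.length), 2]
    abort(paste0("missing branch length above node(s): ", paste(bad, collapse = ", ")))
  }
  ape::cophenetic.phylo(tree)
}

#' Prune a tree to a set of tips
#'
#' Drops all other tips and suppresses the resulting unary nodes by summing
#' their branch lengths, so patristic distances among the kept tips are
#' unchanged.
#'
#' @param tree A `phylo`.
#' @param keep Character vector of tip labels to retain (must all be on the
#'   tree).
#' @return A `phylo` with `length(keep)` tips.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  if (length(keep) == 0) abort("`keep` must name at least one tip")
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("tips not on tree: ", paste(missing, collapse = ", ")))
  }
  if (length(keep) == length(tree$tip.label)) {
    return(tree)
  }
  ape::keep.tip(tree, keep)
}

#' Check whether a tree is ultrametric
#'
#' All root-to-tip path lengths must agree within a relative tolerance of
#' their mean.
#'
#' @param tree A `phylo` with branch lengths.
#' @param rel_tol Relative tolerance.
#' @return A list with `ultrametric` (logical) and `max_deviation` (largest
#'   relative departure of a tip depth from the mean depth).
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-8) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  m <- mean(depths)
  dev <- if (m == 0) 0 else max(abs(depths - m)) / m
  list(ultrametric = dev <= rel_tol, max_deviation = dev)
}

#' Build an ordinal constraint tree
#'
#' Grafts every taxon as a polytomy under its order on a fixed order-level
#' backbone, mirroring the standard constraint-tree construction used when
#' deep relationships are fixed to a reference classification while tips are
#' left to the sequence data. The output carries no branch lengths.
#'
#' @param taxonomy Data frame with columns `taxon` and `order` (optionally
#'   `genus`, `family`, ignored here); every community taxon must map to
#'   exactly one order.
#' @param backbone Either a `phylo` whose tips are order names, or a newick
#'   string for one.
#' @return A `phylo`: backbone topology above orders, species polytomies
#'   below.
#' @export
build_constraint_tree <- function(taxonomy, backbone) {
  stopifnot(is.data.frame(taxonomy), all(c("taxon", "order") %in% names(taxonomy)))
  if (is.character(backbone)) backbone <- read_phylo(text = backbone)
  dup <- taxonomy$taxon[duplicated(taxonomy$taxon)]
  if (length(dup) > 0) {
    abort(paste0("taxa mapped to more than one order: ", paste(unique(dup), collapse = ", ")))
  }
  orders_present <- unique(taxonomy$order)
  unknown <- setdiff(orders_present, backbone$tip.label)
  if (length(unknown) > 0) {
    bad_taxa <- taxonomy$taxon[taxonomy$order %in% unknown]
    abort(paste0(
      "taxa with order absent from backbone: ",
      paste(bad_taxa, collapse = ", ")
    ))
  }
  if (length(orders_present) == 1) {
    taxa <- taxonomy$taxon
    return(read_phylo(text = paste0("(", paste(taxa, collapse = ","), ");"),
      sanitize_labels = FALSE
    ))
  }
  bb <- prune_to_taxa(backbone, orders_present)
  bb$edge.length <- NULL
  # splice each order tip into a polytomy of its taxa via newick surgery
  nwk <- ape::write.tree(bb)
  for (ord in orders_present) {
    taxa <- taxonomy$taxon[taxonomy$order == ord]
    repl <- if (length(taxa) == 1) taxa else paste0("(", paste(taxa, collapse = ","), ")")
    nwk <- sub(paste0("(?<=[(,])", ord, "(?=[,):])"), repl, nwk, perl = TRUE)
  }
  read_phylo(text = nwk, sanitize_labels = FALSE)
}
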