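#' Read an aligned FASTA matrix
#'
#' Reads aligned sequences over the alphabet `A,C,G,T,-,N,?` (case is
#' folded to upper). All rows must have equal length.
#'
#' @param file Path to a FASTA file.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(file) {
  seqs <- seqinr::read.fasta(file, as.string = TRUE, forceDNAtolower = FALSE)
  aln <- toupper(vapply(seqs, as.character, ""))
  names(aln) <- names(seqs)
  validate_alignment(aln)
}

#' Write an aligned matrix as FASTA
#'
#' @param aln Named character vector of aligned sequences.
#' @param file Output path.
#' @export
write_alignment <- function(aln, file) {
  seqinr::write.fasta(as.list(aln), names = names(aln), file.out = file)
  invisible(file)
}

validate_alignment <- function(aln) {
  if (length(aln) == 0) abort("empty alignment")
  if (length(unique(nchar(aln))) != 1) abort("aligned rows differ in length")
  bad <- grepl("[^ACGTN?-]", aln)
  if (any(bad)) {
    abort(paste0(
      "unexpected characters in sequence(s): ",
      paste(names(aln)[bad], collapse = ", ")
    ))
  }
  aln
}

MISSING_CHARS <- c("-", "N", "?")

#' Collapse aligned sequences into haplotypes
#'
#' Groups rows by sequence identity; identical sequences share a haplotype.
#' In `strict` mode (default) every character, including gaps and
#' ambiguity/missing symbols, must match exactly — deterministic and
#' conservative. In `wildcard` mode the symbols `-`, `N` and `?` match any
#' state, and a sequence joins the first compatible haplotype in input
#' order. When a morphotaxon map is supplied, one representative per
#' (haplotype x morphotaxon) combination is recorded, so a morphotaxon
#' split across several haplotypes keeps a representative in each.
#'
#' @param aln Named character vector of aligned sequences (tag ids as
#'   names).
#' @param morphotaxa Optional named character vector: tag id -> morphotaxon
#'   id.
#' @param mode `"strict"` or `"wildcard"`.
#' @return A tibble with one row per haplotype: `haplotype` (id),
#'   `representative` (first member tag), `sequence`, `n_members`,
#'   `members` (list of tag ids), `morphotaxa` (list of morphotaxon ids
#'   observed).
#' @export
collapse_haplotypes <- function(aln, morphotaxa = NULL, mode = c("strict", "wildcard")) {
  mode <- match.arg(mode)
  validate_alignment(aln)
  tags <- names(aln)
  if (is.null(tags) || any(!nzchar(tags))) abort("sequences must be named by tag id")
  if (mode == "strict") {
    group <- match(aln, unique(aln))
  } else {
    group <- integer(length(aln))
    reps <- character(0)
    for (i in seq_along(aln)) {
      hit <- which(vapply(reps, wildcard_equal, logical(1), b = aln[[i]]))
      if (length(hit) > 0) {
        group[i] <- hit[1]
      } else {
        reps <- c(reps, aln[[i]])
        group[i] <- length(reps)
      }
    }
  }
  tibble(tag = tags, sequence = unname(aln), group = group) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      representative = .data$tag[1],
      sequence = .data$sequence[1],
      n_members = dplyr::n(),
      members = list(.data$tag),
      morphotaxa = list(if (is.null(morphotaxa)) {
        character(0)
      } else {
        unique(stats::na.omit(unname(morphotaxa[.data$tag])))
      }),
      .groups = "drop"
    ) |>
    dplyr::mutate(haplotype = paste0("H", sprintf("%03d", .data$group))) |>
    dplyr::select(
      "haplotype", "representative", "sequence",
      "n_members", "members", "morphotaxa"
    )
}

wildcard_equal <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ok <- ca == cb | ca %in% MISSING_CHARS | cb %in% MISSING_CHARS
  all(ok)
}

#' Alignment summary statistics
#'
#' Length, variable-site count (columns with at least two distinct
#' non-missing states) and the percentage of gap/undetermined cells
#' (`-`, `N`, `?`) over the whole matrix.
#'
#' @param aln Named character vector of aligned sequences.
#' @return A one-row tibble: `n_seq`, `length`, `variable_sites`,
#'   `missing_pct`.
#' @export
alignment_stats <- function(aln) {
  validate_alignment(aln)
  m <- do.call(rbind, strsplit(unname(aln), ""))
  is_missing <- matrix(m %in% MISSING_CHARS, nrow = nrow(m))
  variable <- vapply(seq_len(ncol(m)), function(j) {
    states <- unique(m[!is_missing[, j], j])
    length(states) >= 2
  }, logical(1))
  tibble(
    n_seq = nrow(m),
    length = ncol(m),
    variable_sites = sum(variable),
    missing_pct = 100 * mean(is_missing)
  )
}

#' Screen a coding sequence for internal stop codons
#'
#' Translates the sequence in the given reading frame with the standard
#' genetic code (whose stop set TAA/TAG/TGA is shared by the bacterial and
#' plastid table) and flags internal stop codons — the pseudogene signal
#' used for protein-coding barcodes. Codons containing gaps or missing
#' characters are skipped.
#'
#' @param seq A single unaligned or aligned nucleotide string.
#' @param frame Frame offset, 0, 1 or 2.
#' @return A list: `pseudogene` (flag: any internal stop), `stop_codons`
#'   (1-based codon positions of stops, in the frame), `n_codons`.
#' @export
stop_codon_screen <- function(seq, frame = 0) {
  if (!frame %in% 0:2) abort("frame must be 0, 1 or 2")
  s <- toupper(gsub("\\s", "", seq))
  s <- substring(s, frame + 1)
  n_codons <- nchar(s) %/% 3
  if (n_codons < 1) abort("sequence shorter than one codon in this frame")
  codons <- substring(s, 3 * (seq_len(n_codons) - 1) + 1, 3 * seq_len(n_codons))
  stops <- which(codons %in% c("TAA", "TAG", "TGA"))
  internal <- stops[stops < n_codons]
  list(
    pseudogene = length(internal) > 0,
    stop_codons = stops,
    n_codons = n_codons
  )
}

#' Build a community matrix from tagged-stem records
#'
#' Sequenced stems are counted under their haplotype tip. Unsequenced stems
#' with a morphological identification are assigned to the haplotype of
#' sequenced conspecifics; when the morphotaxon maps to more than one
#' haplotype the configured policy decides (`"most_frequent"`, the default,
#' assigns to the morphotaxon's commonest haplotype among sequenced stems
#' and logs the choice; `"exclude"` drops the stem). Stems with neither a
#' haplotype nor a usable morphotaxon are excluded and counted.
#'
#' @param stems Data frame with columns `tag`, `subplot`, `morphotaxon`
#'   (optional id or `NA`) and `haplotype` (id or `NA`).
#' @param ambiguous Assignment policy, `"most_frequent"` or `"exclude"`.
#' @return A list: `community` (community tibble, subplots x haplotypes),
#'   `exclusions` (tibble of excluded stems with a `reason`),
#'   `ambiguity_log` (tibble of morphotaxon -> haplotype choices),
#'   `excluded_fraction`.
#' @export
build_community_matrix <- function(stems, ambiguous = c("most_frequent", "exclude")) {
  ambiguous <- match.arg(ambiguous)
  stopifnot(all(c("tag", "subplot", "morphotaxon", "haplotype") %in% names(stems)))
  stems <- as_tibble(stems)

  seq_stems <- stems |> dplyr::filter(!is.na(.data$haplotype))
  # morphotaxon -> haplotype table from sequenced stems
  morpho_map <- seq_stems |>
    dplyr::filter(!is.na(.data$morphotaxon)) |>
    dplyr::count(.data$morphotaxon, .data$haplotype, name = "n_sequenced") |>
    dplyr::group_by(.data$morphotaxon) |>
    dplyr::arrange(dplyr::desc(.data$n_sequenced), .data$haplotype, .by_group = TRUE) |>
    dplyr::mutate(n_haplotypes = dplyr::n()) |>
    dplyr::slice(1) |>
    dplyr::ungroup()

  unseq <- stems |> dplyr::filter(is.na(.data$haplotype))
  assigned_unseq <- unseq |>
    dplyr::inner_join(
      dplyr::select(morpho_map, "morphotaxon",
        assigned_haplotype = "haplotype", "n_haplotypes"
      ),
      by = "morphotaxon"
    )
  if (ambiguous == "exclude") {
    ambiguous_dropped <- assigned_unseq |> dplyr::filter(.data$n_haplotypes > 1)
    assigned_unseq <- assigned_unseq |> dplyr::filter(.data$n_haplotypes == 1)
  } else {
    ambiguous_dropped <- assigned_unseq[0, , drop = FALSE]
  }

  assigned <- dplyr::bind_rows(
    dplyr::transmute(seq_stems, .data$tag, .data$subplot, tip = .data$haplotype),
    dplyr::transmute(assigned_unseq, .data$tag, .data$subplot, tip = .data$assigned_haplotype)
  )

  excluded <- dplyr::bind_rows(
    unseq |>
      dplyr::filter(is.na(.data$morphotaxon)) |>
      dplyr::mutate(reason = "no morphological or sequence information"),
    unseq |>
      dplyr::filter(
        !is.na(.data$morphotaxon),
        !.data$morphotaxon %in% morpho_map$morphotaxon
      ) |>
      dplyr::mutate(reason = "morphotaxon never sequenced"),
    ambiguous_dropped |>
      dplyr::select(-"assigned_haplotype", -"n_haplotypes") |>
      dplyr::mutate(reason = "morphotaxon maps to several haplotypes")
  )

  comm <- assigned |>
    dplyr::count(.data$subplot, .data$tip) |>
    tidyr::pivot_wider(
      names_from = "tip", values_from = "n", values_fill = 0
    ) |>
    dplyr::arrange(.data$subplot) |>
    as_community()

  ambiguity_log <- morpho_map |>
    dplyr::filter(.data$n_haplotypes > 1) |>
    dplyr::select("morphotaxon", chosen_haplotype = "haplotype", "n_haplotypes")

  stopifnot(nrow(assigned) + nrow(excluded) == nrow(stems))
  list(
    community = comm,
    exclusions = excluded,
    ambiguity_log = ambiguity_log,
    excluded_fraction = nrow(excluded) / nrow(stems)
  )
}
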