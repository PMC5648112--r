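#' Corner-elevation grid of a forest plot
#'
#' Elevations measured at the corner points of the quadrat grid: an
#' (R+1) x (C+1) lattice for R x C quadrats with a fixed spacing (10 m for
#' a 500 x 500 m plot of 10 x 10 m subplots). Row index runs along y,
#' column index along x.
#'
#' @param z Numeric matrix of corner elevations (m a.s.l.).
#' @param spacing Grid spacing in metres (default 10).
#' @param centers Optional R x C matrix of measured quadrat-centre
#'   elevations (used by the edge-quadrat convexity rule).
#' @return An object of class `topo_grid`.
#' @export
topo_grid <- function(z, spacing = 10, centers = NULL) {
  z <- as.matrix(z)
  if (!all(is.finite(z))) abort("corner elevations must be finite")
  if (nrow(z) < 2 || ncol(z) < 2) abort("grid needs at least one quadrat")
  if (!is.null(centers)) {
    centers <- as.matrix(centers)
    stopifnot(nrow(centers) == nrow(z) - 1, ncol(centers) == ncol(z) - 1)
  }
  structure(list(z = z, spacing = spacing, centers = centers),
    class = "topo_grid"
  )
}

#' Read a corner-elevation grid from a 3-column TSV
#'
#' Columns `x`, `y`, `elevation` with coordinates in metres on a regular
#' lattice.
#'
#' @param file Path to the TSV.
#' @return A [topo_grid()].
#' @export
read_topo_grid <- function(file) {
  df <- readr::read_tsv(file, show_col_types = FALSE)
  stopifnot(all(c("x", "y", "elevation") %in% names(df)))
  xs <- sort(unique(df$x))
  ys <- sort(unique(df$y))
  spacing <- if (length(xs) > 1) diff(xs)[1] else 10
  z <- matrix(NA_real_, nrow = length(ys), ncol = length(xs))
  z[cbind(match(df$y, ys), match(df$x, xs))] <- df$elevation
  if (anyNA(z)) abort("lattice is not complete/rectangular")
  topo_grid(z, spacing = spacing)
}

#' Write a corner-elevation grid as a 3-column TSV
#'
#' @param grid A [topo_grid()].
#' @param file Output path.
#' @export
write_topo_grid <- function(grid, file) {
  z <- grid$z
  df <- tidyr::expand_grid(
    y = (seq_len(nrow(z)) - 1) * grid$spacing,
    x = (seq_len(ncol(z)) - 1) * grid$spacing
  )
  df$elevation <- as.vector(t(z))[seq_len(nrow(df))]
  df <- df[, c("x", "y", "elevation")]
  readr::write_tsv(df, file)
}

check_quadrat <- function(grid, row, col) {
  R <- nrow(grid$z) - 1
  C <- ncol(grid$z) - 1
  if (row < 1 || row > R || col < 1 || col > C) {
    abort(paste0("quadrat (", row, ", ", col, ") outside the ", R, " x ", C, " grid"))
  }
}

quadrat_corners <- function(grid, row, col) {
  # counter-clockwise from the (0,0) corner of the quadrat
  z <- grid$z
  c(z[row, col], z[row, col + 1], z[row + 1, col + 1], z[row + 1, col])
}

#' Mean elevation of a quadrat
#'
#' Arithmetic mean of the four corner elevations.
#'
#' @param grid A [topo_grid()].
#' @param row,col Quadrat indices (1-based).
#' @return Elevation in metres.
#' @export
mean_elevation <- function(grid, row, col) {
  check_quadrat(grid, row, col)
  mean(quadrat_corners(grid, row, col))
}

slope_from_corners <- function(corners, side) {
  # mean angular slope of the four planes, each through three of the four
  # corners; plane orientation from the normal of the corner triangle
  xy <- rbind(c(0, 0), c(side, 0), c(side, side), c(0, side))
  angles <- vapply(1:4, function(drop) {
    idx <- setdiff(1:4, drop)
    p <- cbind(xy[idx, ], corners[idx])
    n <- pracma_cross(p[2, ] - p[1, ], p[3, ] - p[1, ])
    acos(abs(n[3]) / sqrt(sum(n^2))) * 180 / pi
  }, numeric(1))
  mean(angles)
}

pracma_cross <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Slope of a quadrat in degrees
#'
#' The mean of the angular slopes of the four planes fitted through each
#' subset of three of the four corner points (the convention of forest
#' dynamics plot surveys).
#'
#' @inheritParams mean_elevation
#' @return Slope in degrees, in `[0, 90)`.
#' @export
quadrat_slope <- function(grid, row, col) {
  check_quadrat(grid, row, col)
  slope_from_corners(quadrat_corners(grid, row, col), grid$spacing)
}

#' Convexity of a quadrat in metres
#'
#' Interior quadrats: mean elevation of the four focal corners minus the
#' mean of the 12 outer-boundary lattice points of the surrounding 3 x 3
#' block of quadrats. Edge quadrats: centre-point elevation minus the mean
#' of the four corners; when no measured centre exists, the centre is
#' bilinearly interpolated from the corners, which makes edge convexity 0
#' by construction. Positive values indicate convex terrain.
#'
#' @inheritParams mean_elevation
#' @return Convexity in metres.
#' @export
convexity <- function(grid, row, col) {
  check_quadrat(grid, row, col)
  z <- grid$z
  R <- nrow(z) - 1
  C <- ncol(z) - 1
  interior <- row >= 2 && row <= R - 1 && col >= 2 && col <= C - 1
  focal <- mean(quadrat_corners(grid, row, col))
  if (interior) {
    block <- z[(row - 1):(row + 2), (col - 1):(col + 2)]
    ring <- c(block[1, ], block[4, ], block[2:3, 1], block[2:3, 4])
    focal - mean(ring)
  } else {
    centre <- if (!is.null(grid$centers)) grid$centers[row, col] else focal
    centre - focal
  }
}

#' Topography table for every quadrat
#'
#' @param grid A [topo_grid()].
#' @return A tibble with columns `subplot` (\code{"r<row>c<col>"}), `row`,
#'   `col`, `elevation` (m), `slope` (degrees) and `convexity` (m).
#' @export
quadrat_topography <- function(grid) {
  R <- nrow(grid$z) - 1
  C <- ncol(grid$z) - 1
  g <- tidyr::expand_grid(row = seq_len(R), col = seq_len(C))
  g |>
    dplyr::mutate(
      subplot = paste0("r", .data$row, "c", .data$col),
      elevation = purrr::map2_dbl(.data$row, .data$col, ~ mean_elevation(grid, .x, .y)),
      slope = purrr::map2_dbl(.data$row, .data$col, ~ quadrat_slope(grid, .x, .y)),
      convexity = purrr::map2_dbl(.data$row, .data$col, ~ convexity(grid, .x, .y))
    ) |>
    dplyr::select("subplot", "row", "col", "elevation", "slope", "convexity")
}

#' Five-way habitat classification of quadrats
#'
#' Applies the slope/elevation/convexity rule table: valley
#' (S < S_mean, E < E_mean); low slope (S >= S_mean, E < E_mean); high
#' slope (S >= S_mean, E >= E_mean, C >= 0); high gully (S >= S_mean,
#' E >= E_mean, C < 0); ridge top (S < S_mean, E >= E_mean). Boundary
#' tie-breaks: S exactly at the threshold with E >= E_mean goes to the
#' high-slope/high-gully branch, and C = 0 to high slope, so every input
#' receives exactly one label.
#'
#' @param topo Data frame with columns `slope`, `elevation`, `convexity`
#'   (e.g. from [quadrat_topography()]).
#' @param s_mean,e_mean Classification thresholds in degrees / metres;
#'   default to the means of the supplied table (pass the plot-wide values
#'   explicitly to reproduce a published classification).
#' @return The input tibble with an added `habitat` column.
#' @export
classify_habitat <- function(topo, s_mean = NULL, e_mean = NULL) {
  stopifnot(all(c("slope", "elevation", "convexity") %in% names(topo)))
  s_mean <- s_mean %||% mean(topo$slope)
  e_mean <- e_mean %||% mean(topo$elevation)
  topo |>
    as_tibble() |>
    dplyr::mutate(habitat = dplyr::case_when(
      .data$elevation < e_mean & .data$slope < s_mean ~ "valley",
      .data$elevation < e_mean ~ "low slope",
      .data$slope < s_mean ~ "ridge top",
      .data$convexity < 0 ~ "high gully",
      TRUE ~ "high slope"
    ))
}

#' Habitat map of the quadrat grid
#'
#' @param topo Output of [classify_habitat()] carrying `row`, `col` and
#'   `habitat`.
#' @return A ggplot tile map.
#' @export
plot_habitat_map <- function(topo) {
  stopifnot(all(c("row", "col", "habitat") %in% names(topo)))
  ggplot2::ggplot(topo, ggplot2::aes(
    x = .data$col, y = .data$row, fill = .data$habitat
  )) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "quadrat column", y = "quadrat row", fill = "habitat")
}
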