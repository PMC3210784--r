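#' Proliferation curve: cells per frame
#'
#' @param masks List of per-frame label matrices (detected or truth).
#' @return Tibble `frame`, `n_cells`.
#' @export
proliferation_curve <- function(masks) {
  tibble(frame = seq_along(masks),
         n_cells = vapply(masks, function(m)
           length(unique(m[m > 0L])), integer(1)))
}

#' Per-window division probability
#'
#' The probability for a cell to divide within a time window:
#' 100 * (mitoses in the window) / (mean cell count in the window).
#'
#' @param counts Proliferation curve tibble (`frame`, `n_cells`).
#' @param mitosis_frames Integer vector of division frames (one entry
#'   per mitosis).
#' @param window Window length in minutes.
#' @param frame_interval Minutes per frame.
#' @return Tibble `window_start_min`, `window_end_min`, `n_mitoses`,
#'   `mean_cells`, `division_probability_pct`.
#' @export
division_probability <- function(counts, mitosis_frames, window = 120,
                                 frame_interval = 15) {
  stopifnot(window >= frame_interval)
  frames_per_window <- max(1L, round(window / frame_interval))
  win_id <- (counts$frame - 1L) %/% frames_per_window
  mito_win <- (mitosis_frames - 1L) %/% frames_per_window
  purrr::map_dfr(sort(unique(win_id)), function(wd) {
    n_mit <- sum(mito_win == wd)
    mc <- mean(counts$n_cells[win_id == wd])
    tibble(window_start_min = wd * frames_per_window * frame_interval,
           window_end_min = (wd + 1) * frames_per_window * frame_interval,
           n_mitoses = n_mit, mean_cells = mc,
           division_probability_pct =
             ifelse(mc > 0, 100 * n_mit / mc, NA_real_))
  })
}

#' Confluency and mean cell area per frame
#'
#' Confluency is the percentage of the observed area covered by cell
#' pixels; the mean and standard deviation of region areas are
#' reported in pixels and, when a pixel size is given, in square
#' micrometres.
#'
#' @param masks List of label matrices.
#' @param pixel_size Micrometres per pixel (`NA` to skip µm² columns).
#' @return Tibble `frame`, `confluency_pct`, `mean_area_px`,
#'   `sd_area_px`, `mean_area_um2`, `sd_area_um2`.
#' @export
confluency_and_mean_area <- function(masks, pixel_size = NA_real_) {
  purrr::map_dfr(seq_along(masks), function(t) {
    m <- masks[[t]]
    fg <- sum(m > 0L)
    areas <- if (fg) as.double(table(m[m > 0L])) else double(0)
    tibble(frame = t,
           confluency_pct = 100 * fg / length(m),
           mean_area_px = ifelse(length(areas), mean(areas), NA_real_),
           sd_area_px = ifelse(length(areas) > 1, sd(areas), NA_real_),
           mean_area_um2 = .data$mean_area_px * pixel_size^2,
           sd_area_um2 = .data$sd_area_px * pixel_size^2)
  })
}

#' Life-time distribution of accepted complete paths
#'
#' A life time is the span between two consecutive mitoses of one
#' cell: (death frame - birth frame) * frame interval. Each sample is
#' stamped with the time its path ends, so the distribution can be
#' inspected as a function of culture age (confluency effects).
#'
#' @param complete Tibble of complete paths (`path`, `birth_frame`,
#'   `death_frame`), e.g. `result$complete` or `result$accepted`.
#' @param frame_interval Minutes per frame.
#' @return Tibble `path`, `lifetime_min`, `end_time_min`.
#' @export
lifetime_distribution <- function(complete, frame_interval = 15) {
  tibble(path = complete$path,
         lifetime_min = (complete$death_frame - complete$birth_frame) *
           frame_interval,
         end_time_min = (complete$death_frame - 1) * frame_interval)
}

#' Sibling symmetry: life-time differences of daughter pairs
#'
#' For every mitosis whose both daughters are complete paths, the
#' signed difference of the daughters' life times (first daughter
#' minus second, daughters ordered by birth centroid y then x when
#' positions are available, otherwise by path id). Values near zero
#' mean symmetric divisions.
#'
#' @param forest Tibble of accepted mitosis edges (`parent`,
#'   `daughter`) as in `lineage_result$forest`, or any two-daughter
#'   edge list.
#' @param complete Tibble with `path` and `lifetime_min` (or
#'   birth/death frames plus `frame_interval`).
#' @param frame_interval Minutes per frame (used if `lifetime_min`
#'   absent).
#' @return Tibble `parent`, `daughter1`, `daughter2`,
#'   `symmetry_min` (signed), `abs_symmetry_min`.
#' @export
sibling_symmetry <- function(forest, complete, frame_interval = 15) {
  if (!"lifetime_min" %in% names(complete)) {
    complete <- mutate(complete, lifetime_min =
                         (.data$death_frame - .data$birth_frame) *
                         frame_interval)
  }
  sib <- forest %>%
    group_by(.data$parent) %>%
    filter(n() == 2L) %>%
    arrange(.data$daughter, .by_group = TRUE) %>%
    summarise(daughter1 = dplyr::first(.data$daughter),
              daughter2 = dplyr::last(.data$daughter), .groups = "drop")
  lt <- setNames(complete$lifetime_min, complete$path)
  sib <- sib %>%
    mutate(l1 = lt[as.character(.data$daughter1)],
           l2 = lt[as.character(.data$daughter2)]) %>%
    filter(!is.na(.data$l1), !is.na(.data$l2)) %>%
    transmute(.data$parent, .data$daughter1, .data$daughter2,
              symmetry_min = unname(.data$l1 - .data$l2),
              abs_symmetry_min = unname(abs(.data$l1 - .data$l2)))
  sib
}

#' Per-tree generation and path counts
#'
#' A tree's generation count is its longest root-to-leaf mitosis depth
#' plus one; its size is the number of connected paths (nodes).
#'
#' @param forest Tibble of accepted mitosis edges (`parent`,
#'   `daughter`).
#' @param paths Optional vector of all path ids (isolated paths form
#'   one-node trees).
#' @return Tibble `tree`, `n_paths`, `generations`.
#' @export
tree_summary <- function(forest, paths = NULL) {
  ids <- unique(c(forest$parent, forest$daughter, paths))
  if (!length(ids)) {
    return(tibble(tree = integer(), n_paths = integer(),
                  generations = integer()))
  }
  g <- igraph::make_graph(
    edges = as.character(rbind(forest$parent, forest$daughter)),
    isolates = setdiff(as.character(ids),
                       as.character(c(forest$parent, forest$daughter))),
    directed = TRUE)
  comp <- igraph::components(igraph::as_undirected(g))$membership
  purrr::map_dfr(sort(unique(comp)), function(k) {
    nodes <- names(comp)[comp == k]
    sub <- igraph::induced_subgraph(g, nodes)
    roots <- igraph::V(sub)[igraph::degree(sub, mode = "in") == 0]
    depth <- if (igraph::ecount(sub) == 0) 0 else
      max(igraph::distances(sub, v = roots, mode = "out")[
        is.finite(igraph::distances(sub, v = roots, mode = "out"))])
    tibble(tree = k, n_paths = length(nodes),
           generations = as.integer(depth) + 1L)
  })
}
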