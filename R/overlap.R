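#' Pairwise mask overlaps between consecutive frames
#'
#' For every pair of labels whose regions intersect, reports the
#' intersection pixel count and the forward overlap (intersection over
#' the area of the cell in frame t) and backward overlap (intersection
#' over the area of the candidate in frame t+1).
#'
#' @param mask_t,mask_t1 Integer label matrices of equal dimensions for
#'   frames t and t+1.
#' @return A tibble with columns `label_t`, `label_t1`, `intersection`,
#'   `o_fw`, `o_bw`. Pairs with zero intersection are not stored.
#' @export
pairwise_overlaps <- function(mask_t, mask_t1) {
  if (!all(dim(mask_t) == dim(mask_t1)))
    stop("masks must have identical dimensions")
  sel <- mask_t > 0L & mask_t1 > 0L
  if (!any(sel)) {
    return(tibble(label_t = integer(), label_t1 = integer(),
                  intersection = integer(), o_fw = double(), o_bw = double()))
  }
  a <- mask_t[sel]; b <- mask_t1[sel]
  key <- paste(a, b)
  tab <- table(key)
  parts <- strsplit(names(tab), " ", fixed = TRUE)
  lt <- as.integer(vapply(parts, `[`, "", 1))
  lt1 <- as.integer(vapply(parts, `[`, "", 2))
  area_t <- tabulate(mask_t[mask_t > 0L])
  area_t1 <- tabulate(mask_t1[mask_t1 > 0L])
  out <- tibble(label_t = lt, label_t1 = lt1,
                intersection = as.integer(tab),
                o_fw = as.integer(tab) / area_t[lt],
                o_bw = as.integer(tab) / area_t1[lt1])
  arrange(out, .data$label_t, .data$label_t1)
}

#' Threshold overlaps into unique links and ambiguous candidates
#'
#' An overlap entry is a candidate continuation when both its forward
#' and backward overlap exceed the thresholds. A link is unique -- the
#' condition for extending a path fragment -- when its source has
#' exactly one candidate successor and its target exactly one candidate
#' predecessor. Every other candidate is reported as ambiguous.
#'
#' @param overlaps Output of [pairwise_overlaps()].
#' @param t_fw,t_bw Forward/backward overlap thresholds in `[0, 1]`.
#' @param t_amb Ambiguity floor: overlaps with both ratios above this
#'   value count as concurrent continuations and veto uniqueness even
#'   when they fail the link thresholds (path construction aborts as
#'   soon as more than one relevant overlap occurs). Pixel-level
#'   incidental contacts below the floor are ignored.
#' @return List with `links` (unique links) and `ambiguous` (candidate
#'   entries that are not unique links), both in the format of
#'   `overlaps`.
#' @export
link_cells <- function(overlaps, t_fw = 0.3, t_bw = 0.3, t_amb = 0.1) {
  stopifnot(t_fw >= 0, t_fw <= 1, t_bw >= 0, t_bw <= 1,
            t_amb >= 0, t_amb <= 1)
  relevant <- filter(overlaps, .data$o_fw > t_amb, .data$o_bw > t_amb)
  cand <- filter(overlaps, .data$o_fw > t_fw, .data$o_bw > t_bw)
  if (!nrow(cand)) {
    return(list(links = cand, ambiguous = cand))
  }
  n_succ <- count(relevant, .data$label_t, name = "n_succ")
  n_pred <- count(relevant, .data$label_t1, name = "n_pred")
  cand <- cand %>%
    left_join(n_succ, by = "label_t") %>%
    left_join(n_pred, by = "label_t1")
  links <- cand %>% filter(.data$n_succ == 1L, .data$n_pred == 1L) %>%
    select(-"n_succ", -"n_pred")
  ambiguous <- cand %>% filter(.data$n_succ > 1L | .data$n_pred > 1L) %>%
    select(-"n_succ", -"n_pred")
  list(links = links, ambiguous = ambiguous)
}

#' Build path fragments and the fragment adjacency matrix
#'
#' Chains unique one-to-one overlap links into maximal path fragments:
#' a fragment follows one cell over consecutive frames and is aborted
#' as soon as the cell has anything other than exactly one candidate
#' successor with exactly one candidate predecessor. At every abort
#' point all concurrent overlap candidates between the terminating
#' fragment and the fragments starting in the next frame are recorded
#' in a symmetric adjacency relation -- the starting hypothesis later
#' refined by validation.
#'
#' @param masks List of per-frame label matrices.
#' @param frames Optional list of grey frames; when given, per-cell
#'   features are attached to the fragment table (needed for mitosis
#'   detection).
#' @param t_fw,t_bw Overlap thresholds for unique links.
#' @param t_amb Ambiguity floor passed to [link_cells()].
#' @param adjacency_floor Minimum intersection (pixels) for an
#'   ambiguous pair to enter the adjacency relation; the default keeps
#'   every nonzero overlap.
#' @return An object of class `track_result`: list with `fragments`
#'   (tibble: `fragment`, `frame`, `label` plus feature columns),
#'   `adjacency` (tibble: `fragment_a`, `fragment_b`, `boundary_frame`,
#'   `intersection`; `fragment_a` ends at `boundary_frame`,
#'   `fragment_b` starts at `boundary_frame + 1`), `masks`, `frames`
#'   and `params`.
#' @export
build_path_fragments <- function(masks, frames = NULL, t_fw = 0.3,
                                 t_bw = 0.3, t_amb = 0.1,
                                 adjacency_floor = 1) {
  n_frames <- length(masks)
  stopifnot(n_frames >= 1)
  n_cells <- vapply(masks, max, integer(1))
  # fragment id per (frame, label)
  frag_of <- lapply(n_cells, function(n) integer(n))
  next_frag <- 0L
  if (n_cells[1] > 0) {
    frag_of[[1]] <- seq_len(n_cells[1])
    next_frag <- n_cells[1]
  }
  adjacency <- vector("list", n_frames)
  overlaps_all <- vector("list", n_frames)
  for (t in seq_len(max(0, n_frames - 1))) {
    ov <- pairwise_overlaps(masks[[t]], masks[[t + 1]])
    overlaps_all[[t]] <- ov
    lc <- link_cells(ov, t_fw, t_bw, t_amb)
    nxt <- integer(n_cells[t + 1])
    if (nrow(lc$links)) nxt[lc$links$label_t1] <- frag_of[[t]][lc$links$label_t]
    starts <- which(nxt == 0L)
    if (length(starts)) {
      nxt[starts] <- next_frag + seq_along(starts)
      next_frag <- next_frag + length(starts)
    }
    frag_of[[t + 1]] <- nxt
    # adjacency: all non-link overlap pairs between a fragment that
    # terminates at t and one that starts at t+1
    if (nrow(ov)) {
      amb <- anti_join(filter(ov, .data$intersection >= adjacency_floor),
                       lc$links, by = c("label_t", "label_t1"))
      if (nrow(amb)) {
        ends_at_t <- if (nrow(lc$links)) !(seq_len(n_cells[t]) %in% lc$links$label_t)
          else rep(TRUE, n_cells[t])
        starts_at_t1 <- nxt %in% nxt[starts]
        keep <- ends_at_t[amb$label_t] & starts_at_t1[amb$label_t1]
        amb <- amb[keep, , drop = FALSE]
        if (nrow(amb)) {
          adjacency[[t]] <- tibble(
            fragment_a = frag_of[[t]][amb$label_t],
            fragment_b = nxt[amb$label_t1],
            boundary_frame = t,
            intersection = amb$intersection)
        }
      }
    }
  }
  frag_tbl <- purrr::map_dfr(seq_len(n_frames), function(t) {
    if (n_cells[t] == 0L) return(NULL)
    tibble(fragment = frag_of[[t]], frame = t, label = seq_len(n_cells[t]))
  })
  # renumber fragments consecutively in order of first appearance
  if (nrow(frag_tbl)) {
    frag_tbl <- arrange(frag_tbl, .data$frame, .data$label)
    remap <- integer(next_frag)
    firsts <- frag_tbl$fragment[!duplicated(frag_tbl$fragment)]
    remap[firsts] <- seq_along(firsts)
    frag_tbl$fragment <- remap[frag_tbl$fragment]
    frag_tbl <- arrange(frag_tbl, .data$fragment, .data$frame)
  }
  adj_tbl <- bind_rows(adjacency)
  if (nrow(adj_tbl)) {
    adj_tbl$fragment_a <- remap[adj_tbl$fragment_a]
    adj_tbl$fragment_b <- remap[adj_tbl$fragment_b]
  } else {
    adj_tbl <- tibble(fragment_a = integer(), fragment_b = integer(),
                      boundary_frame = integer(), intersection = integer())
  }
  feats <- feature_table(masks, frames)
  if (nrow(frag_tbl)) {
    frag_tbl <- left_join(frag_tbl, feats, by = c("frame", "label"))
  } else {
    frag_tbl <- bind_cols(tibble(fragment = integer()), feats[0, ])
  }
  structure(list(fragments = frag_tbl, adjacency = adj_tbl,
                 masks = masks, frames = frames,
                 params = list(t_fw = t_fw, t_bw = t_bw, t_amb = t_amb,
                               adjacency_floor = adjacency_floor)),
            class = "track_result")
}

#' @export
print.track_result <- function(x, ...) {
  cat("Overlap tracking result:", max(c(0L, x$fragments$fragment)),
      "path fragments over", length(x$masks), "frames\n")
  cat(nrow(x$adjacency), "adjacency candidates\n")
  invisible(x)
}

#' Tidy a tracking result
#'
#' One row per path fragment with its frame span and length.
#'
#' @param x A `track_result`.
#' @param ... Unused.
#' @method tidy track_result
#' @export
tidy.track_result <- function(x, ...) {
  x$fragments %>%
    group_by(.data$fragment) %>%
    summarise(start_frame = min(.data$frame), end_frame = max(.data$frame),
              length = n(), .groups = "drop")
}

#' Unvalidated backward greedy tracking baseline
#'
#' The comparison baseline: walking the movie last frame to first,
#' every cell is assigned the predecessor with the greatest mask
#' intersection -- no thresholds, no validation. Chains of such
#' assignments form paths; any predecessor chosen by two or more cells
#' forms a Y-junction, which this approach must take at face value as a
#' mitosis (junctions with exactly two branches). Optical merges that
#' later separate therefore surface as false mitoses.
#'
#' @param masks List of per-frame label matrices.
#' @param frames Optional list of grey frames for feature columns.
#' @return A `tracking_paths` object: list with `cells` (tibble `path`,
#'   `frame`, `label`), `mitoses` (tibble `parent`, `daughter1`,
#'   `daughter2`, `frame`, `label` of the parent cell at the division
#'   frame), `complete` (paths bounded by mitoses on both ends) and
#'   `lineage` (path-level parent/daughter edges).
#' @export
naive_track <- function(masks, frames = NULL) {
  n_frames <- length(masks)
  n_cells <- vapply(masks, max, integer(1))
  pred <- lapply(n_cells, function(n) integer(n))  # predecessor label, 0 = none
  for (t in rev(seq_len(n_frames))[seq_len(max(0L, n_frames - 1L))]) {
    ov <- pairwise_overlaps(masks[[t - 1]], masks[[t]])
    if (!nrow(ov)) next
    best <- ov %>%
      group_by(.data$label_t1) %>%
      arrange(dplyr::desc(.data$intersection), dplyr::desc(.data$o_fw),
              .data$label_t, .by_group = TRUE) %>%
      slice(1L) %>% ungroup()
    pred[[t]][best$label_t1] <- best$label_t
  }
  # successors per (frame, label)
  succ <- vector("list", n_frames)
  for (t in seq_len(n_frames - 1L)) {
    s <- split(seq_len(n_cells[t + 1])[pred[[t + 1]] > 0L],
               pred[[t + 1]][pred[[t + 1]] > 0L])
    succ[[t]] <- s
  }
  # build paths: a path continues t -> t+1 when the cell has exactly one
  # successor; junctions (>= 2 successors) end the parent path
  path_of <- lapply(n_cells, function(n) integer(n))
  next_path <- 0L
  edges <- list()
  mito <- list()
  for (t in seq_len(n_frames)) {
    new <- which(path_of[[t]] == 0L)
    if (length(new)) {
      path_of[[t]][new] <- next_path + seq_along(new)
      next_path <- next_path + length(new)
    }
    if (t == n_frames) break
    s <- succ[[t]]
    if (is.null(s)) next
    for (lab_chr in names(s)) {
      lab <- as.integer(lab_chr)
      kids <- s[[lab_chr]]
      if (length(kids) == 1L) {
        path_of[[t + 1]][kids] <- path_of[[t]][lab]
      } else {
        # junction: daughters start new paths
        path_of[[t + 1]][kids] <- next_path + seq_along(kids)
        next_path <- next_path + length(kids)
        if (length(kids) == 2L) {
          mito[[length(mito) + 1L]] <- tibble(
            parent = path_of[[t]][lab], frame = t, label = lab,
            daughter1 = path_of[[t + 1]][kids[1]],
            daughter2 = path_of[[t + 1]][kids[2]])
        }
        for (k in kids) {
          edges[[length(edges) + 1L]] <- tibble(
            parent = path_of[[t]][lab], daughter = path_of[[t + 1]][k],
            frame = t)
        }
      }
    }
  }
  cells <- purrr::map_dfr(seq_len(n_frames), function(t) {
    if (n_cells[t] == 0L) return(NULL)
    tibble(path = path_of[[t]], frame = t, label = seq_len(n_cells[t]))
  })
  mitoses <- if (length(mito)) bind_rows(mito) else
    tibble(parent = integer(), frame = integer(), label = integer(),
           daughter1 = integer(), daughter2 = integer())
  lineage <- if (length(edges)) bind_rows(edges) else
    tibble(parent = integer(), daughter = integer(), frame = integer())
  # complete paths: born at a two-daughter junction, end as parent of one
  meta <- cells %>% group_by(.data$path) %>%
    summarise(start_frame = min(.data$frame), end_frame = max(.data$frame),
              .groups = "drop")
  born <- unique(c(mitoses$daughter1, mitoses$daughter2))
  dies <- unique(mitoses$parent)
  complete <- meta %>%
    filter(.data$path %in% born, .data$path %in% dies) %>%
    rename(birth_frame = "start_frame", death_frame = "end_frame")
  structure(list(cells = cells, mitoses = mitoses, lineage = lineage,
                 complete = complete, n_frames = n_frames),
            class = "tracking_paths")
}

#' @export
print.tracking_paths <- function(x, ...) {
  cat("Naive tracking:", length(unique(x$cells$path)), "paths,",
      nrow(x$mitoses), "putative mitoses,",
      nrow(x$complete), "complete paths\n")
  invisible(x)
}
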