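#' Classify path-fragment termini with status flags
#'
#' Every fragment start is explained as exactly one of: `begin` (movie
#' starts there), `junction` (the adjacency relation offers candidate
#' predecessors -- resolved later as mitosis or merge), `border_begin`
#' (no predecessor and the terminal centroid lies within the border
#' margin) or `lost_begin` (no predecessor, mid-image: the cell seems
#' to appear out of nothing). Fragment ends are flagged analogously
#' (`end`, `junction`, `border_end`, `lost_end`).
#'
#' @param tracks A `track_result` from [build_path_fragments()].
#' @param border_margin Distance (px) from the image border below which
#'   an unexplained terminus is attributed to a border crossing.
#' @return A tibble with one row per fragment: frame span, terminal
#'   centroids and `start_flag` / `end_flag`.
#' @export
assign_path_flags <- function(tracks, border_margin = 30) {
  stopifnot(inherits(tracks, "track_result"))
  dims <- dim(tracks$masks[[1]])
  h <- dims[1]; w <- dims[2]
  n_frames <- length(tracks$masks)
  meta <- tracks$fragments %>%
    group_by(.data$fragment) %>%
    summarise(start_frame = min(.data$frame), end_frame = max(.data$frame),
              length = n(),
              start_x = .data$x[which.min(.data$frame)],
              start_y = .data$y[which.min(.data$frame)],
              end_x = .data$x[which.max(.data$frame)],
              end_y = .data$y[which.max(.data$frame)],
              .groups = "drop")
  near_border <- function(x, y) {
    pmin(x - 1, w - x, y - 1, h - y) < border_margin
  }
  has_pred <- meta$fragment %in% tracks$adjacency$fragment_b
  has_succ <- meta$fragment %in% tracks$adjacency$fragment_a
  meta$start_flag <- dplyr::case_when(
    meta$start_frame == 1L ~ "begin",
    has_pred ~ "junction",
    near_border(meta$start_x, meta$start_y) ~ "border_begin",
    TRUE ~ "lost_begin")
  meta$end_flag <- dplyr::case_when(
    meta$end_frame == n_frames ~ "end",
    has_succ ~ "junction",
    near_border(meta$end_x, meta$end_y) ~ "border_end",
    TRUE ~ "lost_end")
  meta
}

#' Detect merged-cell events (reversed Y junctions)
#'
#' Two or more cells that optically fuse appear as a reversed Y in the
#' path representation: several fragments ending into one common
#' successor fragment. The successor carries the merged flag; it is a
#' tracking error, not a biological event, and paths through it are
#' rejected by validation.
#'
#' @param tracks A `track_result`.
#' @return A tibble of merge events: `successor`, `frame` (last frame
#'   of the predecessors), `n_predecessors`, `predecessors`
#'   (";"-joined fragment ids).
#' @export
detect_merges <- function(tracks) {
  adj <- tracks$adjacency
  if (!nrow(adj)) {
    return(tibble(successor = integer(), frame = integer(),
                  n_predecessors = integer(), predecessors = character()))
  }
  adj %>%
    group_by(.data$fragment_b, .data$boundary_frame) %>%
    summarise(n_predecessors = dplyr::n_distinct(.data$fragment_a),
              predecessors = paste(sort(unique(.data$fragment_a)),
                                   collapse = ";"),
              .groups = "drop") %>%
    filter(.data$n_predecessors >= 2L) %>%
    rename(successor = "fragment_b", frame = "boundary_frame") %>%
    select("successor", "frame", "n_predecessors", "predecessors")
}

# per-fragment difference vectors (one row per step)
fragment_steps <- function(fragments) {
  fragments %>%
    arrange(.data$fragment, .data$frame) %>%
    group_by(.data$fragment) %>%
    mutate(ds = sqrt((.data$x - lag(.data$x))^2 + (.data$y - lag(.data$y))^2),
           d_area = .data$area - lag(.data$area),
           d_grey = .data$mean_grey - lag(.data$mean_grey),
           d_comp = .data$compactness - lag(.data$compactness)) %>%
    ungroup() %>%
    filter(!is.na(.data$ds))
}

# mean of the last k difference vectors of each fragment
terminal_window <- function(fragments, k = 2) {
  fragment_steps(fragments) %>%
    group_by(.data$fragment) %>%
    slice(utils::tail(seq_len(n()), k)) %>%
    summarise(ds = mean(.data$ds), d_area = mean(.data$d_area),
              d_grey = mean(.data$d_grey), d_comp = mean(.data$d_comp),
              .groups = "drop")
}

#' Fit the mitosis pattern model on a calibration movie
#'
#' A dividing cell contracts, rounds up and brightens over its last
#' frames. This calibration runs the full detection/tracking pipeline
#' on a simulated movie with known divisions, collects the terminal
#' difference-vector windows of every fragment whose end coincides
#' with a true division (matched by dual overlap against the true
#' masks), fits a multivariate-normal model to these mitotic windows,
#' and stores the detection threshold `t_mit` as the quantile of the
#' training densities giving the requested recall. Fitting on tracked
#' (not ground-truth) features keeps the model on the same scale as
#' the difference vectors it will later score.
#'
#' @param movie A `cell_movie` from [simulate_movie()].
#' @param cfg A [run_config()] matching the one used for tracking.
#' @param k Number of terminal steps averaged into the pattern window.
#' @param recall Training recall used to place `t_mit`.
#' @param frame_tolerance Allowed |fragment end - true division| in
#'   frames when matching.
#' @return A `similarity_model` with extra `t_mit` and `k` elements.
#' @export
fit_mitosis_model <- function(movie, cfg = run_config(), k = 2,
                              recall = 0.95, frame_tolerance = 1L) {
  stopifnot(inherits(movie, "cell_movie"))
  tracks <- track_movie(movie$frames, cfg)
  corr <- truth_correspondence(tracks$masks, movie$truth$masks,
                               cfg$overlap_floor)
  reg <- movie$truth$cells
  frag_end <- tracks$fragments %>%
    group_by(.data$fragment) %>%
    filter(.data$frame == max(.data$frame)) %>% ungroup() %>%
    left_join(corr, by = c("frame", "label"))
  t_death <- reg$death_frame[match(frag_end$true_id, reg$id)]
  t_fate <- reg$fate[match(frag_end$true_id, reg$id)]
  mitotic <- frag_end$fragment[!is.na(frag_end$true_id) &
                                 !is.na(t_fate) & t_fate == "division" &
                                 abs(t_death - frag_end$frame) <=
                                   frame_tolerance]
  wins <- terminal_window(tracks$fragments, k = k) %>%
    filter(.data$fragment %in% mitotic, complete.cases(.))
  if (nrow(wins) < 6)
    stop("calibration movie yields too few mitotic windows (",
         nrow(wins), ")")
  model <- fit_similarity_model(wins)
  dens <- similarity_probability(wins, model)
  model$t_mit <- unname(quantile(dens, 1 - recall))
  model$k <- k
  model
}

# features of true cells, linked by true id, from ground-truth masks
truth_features <- function(movie) {
  purrr::map_dfr(seq_along(movie$truth$masks), function(t) {
    m <- movie$truth$masks[[t]]
    ids <- sort(unique(m[m > 0L]))
    if (!length(ids)) return(NULL)
    relab <- matrix(0L, nrow(m), ncol(m))
    relab[m > 0L] <- match(m[m > 0L], ids)
    f <- extract_features(relab, movie$frames[[t]], frame = t)
    f$id <- ids[f$label]
    f
  })
}

#' Detect mitoses among fragment junctions
#'
#' A fragment end is mitotic when (a) the adjacency relation shows a
#' Y-shape -- exactly two successor fragments starting the next frame,
#' each having this fragment as its only candidate predecessor -- and
#' (b) the parent's terminal difference-vector window scores
#' `Prob(d) > t_mit` under the mitosis pattern model, i.e. the cell
#' shrank, rounded and brightened the way dividing cells do.
#'
#' @param tracks A `track_result` built with grey frames (features
#'   are needed for the pattern test).
#' @param model Mitosis pattern model from [fit_mitosis_model()] (or
#'   [read_similarity_model()]).
#' @param t_mit Detection threshold on the pattern density; defaults to
#'   the threshold stored in the model.
#' @return A tibble of mitosis events: `parent`, `frame` (division
#'   frame = parent's last frame), `label` (parent's detected label at
#'   that frame), `daughter1`, `daughter2`, `prob`.
#' @export
detect_mitoses <- function(tracks, model, t_mit = model$t_mit) {
  stopifnot(inherits(tracks, "track_result"), inherits(model, "similarity_model"))
  if (is.null(t_mit)) stop("no t_mit supplied and none stored in the model")
  adj <- tracks$adjacency
  empty <- tibble(parent = integer(), frame = integer(), label = integer(),
                  daughter1 = integer(), daughter2 = integer(), prob = double())
  if (!nrow(adj)) return(empty)
  n_succ <- adj %>% group_by(.data$fragment_a) %>%
    summarise(n = dplyr::n_distinct(.data$fragment_b), .groups = "drop")
  n_pred <- adj %>% group_by(.data$fragment_b) %>%
    summarise(n = dplyr::n_distinct(.data$fragment_a), .groups = "drop")
  two_succ <- n_succ$fragment_a[n_succ$n == 2L]
  single_pred <- n_pred$fragment_b[n_pred$n == 1L]
  cand <- adj %>%
    filter(.data$fragment_a %in% two_succ,
           .data$fragment_b %in% single_pred) %>%
    group_by(.data$fragment_a, .data$boundary_frame) %>%
    filter(n() == 2L) %>%
    ungroup()
  if (!nrow(cand)) return(empty)
  cand <- cand %>%
    group_by(.data$fragment_a, .data$boundary_frame) %>%
    summarise(daughter1 = min(.data$fragment_b),
              daughter2 = max(.data$fragment_b), .groups = "drop")
  win <- terminal_window(tracks$fragments, k = if (is.null(model$k)) 2 else model$k)
  win <- win[match(cand$fragment_a, win$fragment), , drop = FALSE]
  prob <- rep(0, nrow(cand))
  ok <- !is.na(win$fragment)
  if (any(ok)) prob[ok] <- similarity_probability(win[ok, ], model)
  lab <- tracks$fragments %>%
    group_by(.data$fragment) %>%
    summarise(label = .data$label[which.max(.data$frame)],
              frame = max(.data$frame), .groups = "drop")
  out <- tibble(parent = cand$fragment_a, frame = cand$boundary_frame,
                label = lab$label[match(cand$fragment_a, lab$fragment)],
                daughter1 = cand$daughter1, daughter2 = cand$daughter2,
                prob = prob)
  filter(out, .data$prob > t_mit)
}

#' Attempt local-threshold recovery of lost fragments
#'
#' Cells that fall below the global detection threshold make their path
#' fragment end in mid-image ("lost"). Starting from every
#' `lost_begin` fragment, this searches the preceding frame inside a
#' window centred on the terminal centroid using a locally computed
#' Otsu threshold. If a region satisfying the forward/backward overlap
#' criteria emerges, the fragment is extended backwards; if the
#' extension reaches the last cell of another fragment, the two
#' fragments are joined across the gap.
#'
#' @param tracks A `track_result` built with grey frames.
#' @param flags Flag table from [assign_path_flags()].
#' @param window Half-width (px) of the local search window.
#' @param max_gap Maximum number of frames bridged per lost terminus.
#' @param min_area Minimum area of a locally recovered region.
#' @return List with `joins` (tibble `from`, `to`: fragment `from`
#'   ends where fragment `to`'s recovered extension begins) and
#'   `recovered` (tibble of virtual cell records: `fragment`, `frame`,
#'   `x`, `y`, `area`).
#' @export
recover_undetected <- function(tracks, flags, window = 60, max_gap = 4,
                               min_area = 25) {
  stopifnot(inherits(tracks, "track_result"))
  t_fw <- tracks$params$t_fw; t_bw <- tracks$params$t_bw
  joins <- list(); recovered <- list()
  if (is.null(tracks$frames)) return(list(joins = empty_joins(),
                                          recovered = empty_recovered()))
  lost <- flags %>% filter(.data$start_flag == "lost_begin",
                           .data$start_frame > 1L)
  frag_last <- tracks$fragments %>%
    group_by(.data$fragment) %>%
    filter(.data$frame == max(.data$frame)) %>% ungroup()
  h <- nrow(tracks$masks[[1]]); w <- ncol(tracks$masks[[1]])
  for (i in seq_len(nrow(lost))) {
    f <- lost$fragment[i]
    s <- lost$start_frame[i]
    lab <- tracks$fragments$label[tracks$fragments$fragment == f &
                                    tracks$fragments$frame == s]
    ref_idx <- which(tracks$masks[[s]] == lab)
    cx <- lost$start_x[i]; cy <- lost$start_y[i]
    for (g in seq_len(max_gap)) {
      t <- s - g
      if (t < 1L) break
      # 1) does the reference region already overlap a detected cell in
      #    frame t strongly enough? Then the gap is closed: join if
      #    that cell is the end of another fragment.
      hit_labs <- tracks$masks[[t]][ref_idx]
      hit_labs <- hit_labs[hit_labs > 0L]
      if (length(hit_labs)) {
        hit <- as.integer(names(which.max(table(hit_labs))))
        int <- sum(hit_labs == hit)
        area_hit <- sum(tracks$masks[[t]] == hit)
        if (int / area_hit > t_fw && int / length(ref_idx) > t_bw) {
          g_row <- frag_last %>% filter(.data$frame == t,
                                        .data$label == hit)
          if (nrow(g_row) == 1L) {
            joins[[length(joins) + 1L]] <- tibble(from = g_row$fragment,
                                                  to = f)
          }
          break   # reached existing detections either way
        }
      }
      # 2) otherwise look for the invisible cell with a local threshold
      y0 <- max(1L, floor(cy - window)); y1 <- min(h, ceiling(cy + window))
      x0 <- max(1L, floor(cx - window)); x1 <- min(w, ceiling(cx + window))
      sub <- tracks$frames[[t]][y0:y1, x0:x1]
      known <- tracks$masks[[t]][y0:y1, x0:x1] > 0L
      # the local threshold separates the faint cell from the local
      # background; pixels of already detected (bright) cells would
      # pull it far too high and are excluded from the histogram
      th <- otsu_threshold(sub[!known])
      if (is.na(th)) break
      sublab <- label_components(sub > th & !known)
      if (max(sublab) == 0L) break
      # candidate regions as full-image pixel index sets
      full <- matrix(0L, h, w)
      full[y0:y1, x0:x1] <- sublab
      ov <- vapply(seq_len(max(sublab)), function(k) {
        idx <- which(full == k)
        int <- length(intersect(idx, ref_idx))
        c(int, length(idx))
      }, double(2))
      int <- ov[1, ]; areas <- ov[2, ]
      pass <- int / areas > t_fw & int / length(ref_idx) > t_bw &
        areas >= min_area
      if (!any(pass)) break
      k <- which(pass)[which.max(int[pass])]
      idx <- which(full == k)
      rows <- (idx - 1L) %% h + 1L; cols <- (idx - 1L) %/% h + 1L
      recovered[[length(recovered) + 1L]] <-
        tibble(fragment = f, frame = t, x = mean(cols), y = mean(rows),
               area = length(idx))
      ref_idx <- idx; cx <- mean(cols); cy <- mean(rows)
    }
  }
  joins <- if (length(joins)) distinct(bind_rows(joins)) else empty_joins()
  # a fragment may serve as join source only once; ambiguity is discarded
  if (nrow(joins)) {
    joins <- joins %>% group_by(.data$from) %>% filter(n() == 1L) %>%
      ungroup() %>% group_by(.data$to) %>% filter(n() == 1L) %>% ungroup()
  }
  recovered <- if (length(recovered)) bind_rows(recovered) else empty_recovered()
  list(joins = joins, recovered = recovered)
}

empty_joins <- function() tibble(from = integer(), to = integer())
empty_recovered <- function() tibble(fragment = integer(), frame = integer(),
                                     x = double(), y = double(),
                                     area = double())

#' Classify every unexplained terminus with the error decision tree
#'
#' Works through the error scenarios from the most conclusive to the
#' least: border crossing, merged cells, mitosis, vanished-recovered,
#' cell death, debris, unresolved. Debris shows as paths that appear
#' suddenly (lost begin), span at most a couple of frames and drift
#' fast; cell death as a sustained terminal shrinkage.
#'
#' @param flags Flag table from [assign_path_flags()].
#' @param merges Merge events from [detect_merges()].
#' @param mitoses Mitosis events from [detect_mitoses()].
#' @param recovery Result of [recover_undetected()].
#' @param tracks The `track_result`.
#' @param debris_max_span Maximum fragment length (frames) for the
#'   debris class.
#' @param debris_min_speed Mean step displacement (px/frame) above
#'   which a short lost path counts as debris; single-frame fragments
#'   have no displacement and qualify by span alone.
#' @param min_area Area (px) under which terminal shrinkage counts as
#'   cell death.
#' @return Tibble with `fragment`, `side` ("begin"/"end") and `class`.
#' @export
classify_tracking_errors <- function(flags, merges, mitoses, recovery,
                                     tracks, debris_max_span = 2,
                                     debris_min_speed = 10,
                                     min_area = 50) {
  steps <- fragment_steps(tracks$fragments)
  speed <- steps %>% group_by(.data$fragment) %>%
    summarise(speed = mean(.data$ds), .groups = "drop")
  end_area <- tracks$fragments %>%
    arrange(.data$fragment, .data$frame) %>%
    group_by(.data$fragment) %>%
    summarise(final_area = dplyr::last(.data$area),
              shrinking = n() >= 3 &&
                all(diff(utils::tail(.data$area, 3)) < 0),
              .groups = "drop")
  per_side <- function(side) {
    fl <- if (side == "begin") flags$start_flag else flags$end_flag
    f <- flags$fragment
    sp <- speed$speed[match(f, speed$fragment)]
    ea <- end_area[match(f, end_area$fragment), ]
    merged_succ <- f %in% merges$successor
    mito_parent <- f %in% mitoses$parent
    mito_child <- f %in% c(mitoses$daughter1, mitoses$daughter2)
    joined_to <- f %in% recovery$joins$to      # start explained by join
    joined_from <- f %in% recovery$joins$from  # end explained by join
    is_debris <- flags$length <= debris_max_span &
      (flags$length == 1L | (!is.na(sp) & sp > debris_min_speed))
    if (side == "begin") {
      dplyr::case_when(
        fl == "begin" ~ "movie_begin",
        fl == "border_begin" ~ "border",
        merged_succ ~ "merged",
        mito_child ~ "mitosis",
        joined_to ~ "vanished_recovered",
        fl == "lost_begin" & is_debris ~ "debris",
        fl == "junction" ~ "unresolved",
        fl == "lost_begin" ~ "unresolved",
        TRUE ~ "unresolved")
    } else {
      dplyr::case_when(
        fl == "end" ~ "movie_end",
        fl == "border_end" ~ "border",
        mito_parent ~ "mitosis",
        joined_from ~ "vanished_recovered",
        fl == "lost_end" & ea$shrinking & ea$final_area < 1.5 * min_area ~
          "cell_death",
        fl == "lost_end" & is_debris ~ "debris",
        TRUE ~ dplyr::if_else(fl %in% c("junction", "lost_end"),
                              "unresolved", "unresolved"))
    }
  }
  bind_rows(
    tibble(fragment = flags$fragment, side = "begin",
           class = per_side("begin")),
    tibble(fragment = flags$fragment, side = "end",
           class = per_side("end")))
}

#' Validate tracking output and assemble the accepted lineage forest
#'
#' The conservative validation pass: flags every fragment terminus,
#' finds merges (reversed Y) and mitoses (Y plus the morphological
#' division pattern), attempts local-threshold recovery of lost
#' fragments, classifies all remaining termini with the error decision
#' tree, and finally accepts only complete paths -- whole cell lives
#' from one mitosis to the next -- that touch no merge, border or
#' unresolved terminus. If in doubt, a path is excluded.
#'
#' @param tracks A `track_result` built with grey frames.
#' @param model Mitosis pattern model ([fit_mitosis_model()]).
#' @param t_mit Mitosis detection threshold (defaults to the model's).
#' @param border_margin Border vicinity in pixels.
#' @param frame_interval Minutes per frame, for life times.
#' @param recover Attempt dropout recovery (local threshold search).
#' @param rectify_merges Experimental: re-assign identities across
#'   merge-then-split scenarios by feature matching. Off by default
#'   because it may introduce additional errors; merged paths are then
#'   simply rejected.
#' @param debris_max_span,debris_min_speed Debris classification
#'   limits, see [classify_tracking_errors()].
#' @return An object of class `lineage_result`; see Details.
#' @details The returned list contains `accepted` (complete paths:
#'   `path`, `birth_frame`, `death_frame`, `lifetime_min`,
#'   `parent_path`, `fragments`), `forest` (mitosis edges between
#'   accepted paths), `cells` (every detected cell with its chain id),
#'   `mitoses`, `merges`, `complete` (= accepted, for evaluation),
#'   `lineage` (all chain-level mitosis edges), `rejected` (one reason
#'   per rejected fragment), `flags`, `termini`, `recovery`.
#' @export
validate_tracks <- function(tracks, model, t_mit = model$t_mit,
                            border_margin = 30, frame_interval = 15,
                            recover = TRUE, rectify_merges = FALSE,
                            debris_max_span = 2, debris_min_speed = 10) {
  stopifnot(inherits(tracks, "track_result"))
  flags <- assign_path_flags(tracks, border_margin)
  merges <- detect_merges(tracks)
  mitoses <- detect_mitoses(tracks, model, t_mit)
  # the decision tree ranks "merged" above "mitosis": a Y-split of a
  # fragment that itself arose from a reversed-Y merge is a separation
  # of merged cells, not a division
  mitoses <- filter(mitoses, !(.data$parent %in% merges$successor))
  recovery <- if (recover)
    recover_undetected(tracks, flags) else
      list(joins = empty_joins(), recovered = empty_recovered())
  if (rectify_merges) {
    extra <- rectify_merge_joins(tracks, merges, flags)
    recovery$joins <- bind_rows(recovery$joins, extra) %>%
      group_by(.data$from) %>% filter(n() == 1L) %>% ungroup() %>%
      group_by(.data$to) %>% filter(n() == 1L) %>% ungroup()
  }
  termini <- classify_tracking_errors(flags, merges, mitoses, recovery,
                                      tracks, debris_max_span,
                                      debris_min_speed)
  n_frag <- max(c(0L, tracks$fragments$fragment))

  # --- chains: fragments joined across recovered gaps
  g <- igraph::make_graph(edges = rbind(recovery$joins$from,
                                        recovery$joins$to),
                          n = n_frag, directed = FALSE)
  chain_of <- as.integer(igraph::components(g)$membership)
  # order fragments within chains by start frame
  frag_meta <- flags
  chain_tbl <- tibble(fragment = frag_meta$fragment,
                      chain = chain_of[frag_meta$fragment],
                      start_frame = frag_meta$start_frame,
                      end_frame = frag_meta$end_frame)
  chains <- chain_tbl %>%
    group_by(.data$chain) %>%
    arrange(.data$start_frame, .by_group = TRUE) %>%
    summarise(first_fragment = dplyr::first(.data$fragment),
              last_fragment = dplyr::last(.data$fragment),
              birth_frame = min(.data$start_frame),
              death_frame = max(.data$end_frame),
              fragments = paste(.data$fragment, collapse = ";"),
              n_fragments = n(), .groups = "drop")

  begin_cls <- termini %>% filter(.data$side == "begin")
  end_cls <- termini %>% filter(.data$side == "end")
  chains <- chains %>%
    mutate(start_class = begin_cls$class[match(.data$first_fragment,
                                               begin_cls$fragment)],
           end_class = end_cls$class[match(.data$last_fragment,
                                           end_cls$fragment)])
  # any merged fragment anywhere in the chain poisons it
  merged_chains <- unique(chain_of[merges$successor])
  chains$has_merged <- chains$chain %in% merged_chains

  # chain-level mitosis edges
  mito_chain <- mitoses %>%
    mutate(parent_chain = chain_of[.data$parent],
           d1 = chain_of[.data$daughter1],
           d2 = chain_of[.data$daughter2])

  born_by_mito <- chains$first_fragment %in%
    c(mitoses$daughter1, mitoses$daughter2)
  dies_by_mito <- chains$last_fragment %in% mitoses$parent
  chains$accepted <- born_by_mito & dies_by_mito & !chains$has_merged &
    chains$start_class == "mitosis" & chains$end_class == "mitosis"

  accepted <- chains %>% filter(.data$accepted) %>%
    arrange(.data$birth_frame, .data$chain) %>%
    mutate(path = .data$chain,
           lifetime_min = (.data$death_frame - .data$birth_frame) *
             frame_interval)
  # parent path: the accepted chain whose mitosis bore this chain
  birth_edge <- mito_chain %>%
    tidyr::pivot_longer(c("d1", "d2"), values_to = "daughter_chain") %>%
    select(parent_chain = "parent_chain", daughter_chain = "daughter_chain",
           frame = "frame")
  accepted_ids <- accepted$chain
  accepted <- accepted %>%
    left_join(birth_edge, by = c(chain = "daughter_chain")) %>%
    mutate(parent_path = if_else(.data$parent_chain %in% .env$accepted_ids,
                                 .data$parent_chain, NA_integer_)) %>%
    select("path", "birth_frame", "death_frame", "lifetime_min",
           "parent_path", fragments = "fragments")
  forest <- birth_edge %>%
    filter(.data$parent_chain %in% accepted$path,
           .data$daughter_chain %in% accepted$path) %>%
    select(parent = "parent_chain", daughter = "daughter_chain", "frame")

  # rejection report: one row per fragment not inside an accepted chain
  rejected <- chain_tbl %>%
    left_join(select(chains, "chain", "accepted", "has_merged",
                     "start_class", "end_class"), by = "chain") %>%
    filter(!.data$accepted)
  reason <- dplyr::case_when(
    rejected$has_merged ~ "merged",
    rejected$start_class == "border" | rejected$end_class == "border" ~
      "border",
    rejected$start_class == "debris" | rejected$end_class == "debris" ~
      "debris",
    rejected$end_class == "cell_death" ~ "cell_death",
    rejected$start_class %in% c("movie_begin") ~ "incomplete_no_birth",
    rejected$end_class %in% c("movie_end") ~ "incomplete_no_death",
    rejected$start_class == "unresolved" | rejected$end_class == "unresolved"
      ~ "unresolved",
    rejected$start_class != "mitosis" ~ "incomplete_no_birth",
    TRUE ~ "incomplete_no_death")
  rejected <- rejected %>%
    transmute(fragment = .data$fragment, chain = .data$chain,
              reason = reason, start_frame = .data$start_frame,
              end_frame = .data$end_frame)

  cells <- tracks$fragments %>%
    transmute(path = chain_of[.data$fragment], .data$frame, .data$label)
  mito_out <- mito_chain %>%
    transmute(parent = .data$parent_chain, .data$frame, .data$label,
              daughter1 = .data$d1, daughter2 = .data$d2,
              prob = .data$prob)
  lineage <- birth_edge %>%
    select(parent = "parent_chain", daughter = "daughter_chain", "frame")

  structure(list(accepted = accepted, forest = forest, cells = cells,
                 mitoses = mito_out, merges = merges,
                 complete = select(accepted, path = "path",
                                   "birth_frame", "death_frame",
                                   "lifetime_min"),
                 lineage = lineage, rejected = rejected, flags = flags,
                 termini = termini, recovery = recovery,
                 chains = chains, n_frames = length(tracks$masks),
                 frame_interval = frame_interval,
                 params = list(t_mit = t_mit, border_margin = border_margin,
                               rectify_merges = rectify_merges)),
            class = "lineage_result")
}

# experimental merge rectification: match the cells entering a merge to
# the cells leaving it by smallest feature distance
rectify_merge_joins <- function(tracks, merges, flags) {
  out <- list()
  feats <- tracks$fragments
  for (i in seq_len(nrow(merges))) {
    m <- merges[i, ]
    preds <- as.integer(strsplit(m$predecessors, ";")[[1]])
    # the merged fragment's end must split into as many successors
    succs <- tracks$adjacency %>%
      filter(.data$fragment_a == m$successor) %>%
      pull(.data$fragment_b) %>% unique()
    if (length(succs) != length(preds)) next
    fin <- feats %>% filter(.data$fragment %in% preds) %>%
      group_by(.data$fragment) %>% filter(.data$frame == max(.data$frame)) %>%
      ungroup()
    fout <- feats %>% filter(.data$fragment %in% succs) %>%
      group_by(.data$fragment) %>% filter(.data$frame == min(.data$frame)) %>%
      ungroup()
    sc <- function(v) (v - mean(v)) / max(sd(v), 1e-9)
    za <- sc(c(fin$area, fout$area))
    zg <- sc(c(fin$mean_grey, fout$mean_grey))
    na_in <- nrow(fin)
    cost <- outer(seq_len(na_in), seq_len(nrow(fout)), function(a, b) {
      (za[a] - za[na_in + b])^2 + (zg[a] - zg[na_in + b])^2
    })
    # greedy assignment
    for (k in seq_len(nrow(fin))) {
      idx <- which(cost == min(cost), arr.ind = TRUE)[1, ]
      out[[length(out) + 1L]] <- tibble(from = fin$fragment[idx[1]],
                                        to = fout$fragment[idx[2]])
      cost[idx[1], ] <- Inf; cost[, idx[2]] <- Inf
    }
  }
  if (length(out)) distinct(bind_rows(out)) else empty_joins()
}

#' @export
print.lineage_result <- function(x, ...) {
  cat("Validated tracking result\n")
  cat("  fragments:", nrow(x$flags), " chains:",
      dplyr::n_distinct(x$cells$path), "\n")
  cat("  detected mitoses:", nrow(x$mitoses),
      " merges:", nrow(x$merges), "\n")
  cat("  accepted complete paths:", nrow(x$accepted), "\n")
  invisible(x)
}

#' Tidy a validated tracking result
#'
#' One row per accepted complete path.
#'
#' @param x A `lineage_result`.
#' @param ... Unused.
#' @method tidy lineage_result
#' @export
tidy.lineage_result <- function(x, ...) as_tibble(x$accepted)

#' Glance at a validated tracking result
#'
#' @param x A `lineage_result`.
#' @param ... Unused.
#' @method glance lineage_result
#' @export
glance.lineage_result <- function(x, ...) {
  tibble(n_fragments = nrow(x$flags),
         n_chains = dplyr::n_distinct(x$cells$path),
         n_mitoses = nrow(x$mitoses),
         n_merges = nrow(x$merges),
         n_accepted = nrow(x$accepted),
         n_rejected_fragments = nrow(x$rejected),
         mean_lifetime_min = mean(x$accepted$lifetime_min))
}
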