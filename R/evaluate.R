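#' Match detected cells against a reference mask
#'
#' A detected cell counts as a true positive when it overlaps one and
#' only one reference cell with both directional overlap ratios above
#' the floor, and that reference cell likewise dual-overlaps only this
#' detection. Unmatched detections are false positives, unmatched
#' reference cells false negatives; a low-accuracy detection (an
#' overlap below the floor) therefore shows up as both a false
#' positive and a false negative, which is why the two error rates are
#' correlated in practice.
#'
#' @param detected,reference Integer label matrices of one frame.
#' @param overlap_floor Minimum dual-overlap ratio (default 30%).
#' @return List with `counts` (tibble `tp`, `fp`, `fn`) and `matches`
#'   (tibble `det_label`, `ref_label` of the accepted one-to-one
#'   pairs).
#' @export
match_detections <- function(detected, reference, overlap_floor = 0.3) {
  if (!all(dim(detected) == dim(reference)))
    stop("detected and reference masks must have identical dimensions")
  ov <- pairwise_overlaps(detected, reference)
  n_det <- max(detected); n_ref <- max(reference)
  cand <- filter(ov, .data$o_fw > overlap_floor, .data$o_bw > overlap_floor)
  if (nrow(cand)) {
    deg_det <- count(cand, .data$label_t, name = "n_d")
    deg_ref <- count(cand, .data$label_t1, name = "n_r")
    matches <- cand %>%
      left_join(deg_det, by = "label_t") %>%
      left_join(deg_ref, by = "label_t1") %>%
      filter(.data$n_d == 1L, .data$n_r == 1L) %>%
      select(det_label = "label_t", ref_label = "label_t1")
  } else {
    matches <- tibble(det_label = integer(), ref_label = integer())
  }
  tp <- nrow(matches)
  list(counts = tibble(tp = tp, fp = n_det - tp, fn = n_ref - tp),
       matches = matches)
}

#' Detection error rates
#'
#' The false acceptance rate FAR = FP / (TP + FP) is the fraction of
#' returned detections that are wrong; the false rejection rate
#' FRR = FN / (TP + FN) is the fraction of reference cells that were
#' missed. An empty denominator yields `NA`.
#'
#' @param counts A tibble (or one-row data frame) with `tp`, `fp`, `fn`.
#' @return Tibble with `far` and `frr`.
#' @export
detection_error_rates <- function(counts) {
  tibble(
    far = ifelse(counts$tp + counts$fp > 0,
                 counts$fp / (counts$tp + counts$fp), NA_real_),
    frr = ifelse(counts$tp + counts$fn > 0,
                 counts$fn / (counts$tp + counts$fn), NA_real_))
}

#' Per-frame detection evaluation of a whole stack
#'
#' @param detected,reference Lists of label matrices.
#' @param overlap_floor Dual-overlap matching floor.
#' @return Tibble with one row per frame: `frame`, `tp`, `fp`, `fn`,
#'   `far`, `frr`.
#' @export
evaluate_detection <- function(detected, reference, overlap_floor = 0.3) {
  stopifnot(length(detected) == length(reference))
  purrr::map_dfr(seq_along(detected), function(t) {
    m <- match_detections(detected[[t]], reference[[t]], overlap_floor)
    bind_cols(tibble(frame = t), m$counts,
              detection_error_rates(m$counts))
  })
}

#' Tracking / mitosis trustworthiness
#'
#' The quotient 100 * correct / total, the central quality measure for
#' validated tracking: of the items an algorithm returned, how many
#' are right.
#'
#' @param correct,total Non-negative counts, `correct <= total`.
#' @return Percentage in `[0, 100]`; `NA` when `total` is zero.
#' @export
trustworthiness <- function(correct, total) {
  stopifnot(correct >= 0, total >= 0)
  if (any(correct > total)) stop("correct count exceeds total count")
  ifelse(total > 0, 100 * correct / total, NA_real_)
}

#' Compounded error propagation over a path
#'
#' With a per-frame success probability p and independent errors, a
#' complete path of n frames survives with probability p^n -- the
#' reason even excellent detection rates produce few correct long
#' paths without validation.
#'
#' @param p Per-frame success probability.
#' @param n_frames Path length in frames.
#' @return Probability in `[0, 1]`.
#' @export
path_survival_probability <- function(p, n_frames) {
  stopifnot(p >= 0, p <= 1, n_frames >= 0)
  p^n_frames
}

# per-frame correspondence detected label -> true id
truth_correspondence <- function(masks, truth_masks, overlap_floor = 0.3) {
  purrr::map_dfr(seq_along(masks), function(t) {
    tm <- truth_masks[[t]]
    ids <- sort(unique(tm[tm > 0L]))
    if (!length(ids)) return(NULL)
    relab <- matrix(0L, nrow(tm), ncol(tm))
    relab[tm > 0L] <- match(tm[tm > 0L], ids)
    m <- match_detections(masks[[t]], relab, overlap_floor)
    if (!nrow(m$matches)) return(NULL)
    tibble(frame = t, label = m$matches$det_label,
           true_id = ids[m$matches$ref_label])
  })
}

#' Table-2-style path classification counts
#'
#' Scores a tracking result (naive or validated) against ground truth:
#' number of paths, detected and correct mitoses, complete
#' (mitosis-to-mitosis) paths and correct complete paths, plus the two
#' trustworthiness quotients. A detected mitosis is correct when the
#' matched true parent divides within one frame of the detected
#' division. A complete path is correct when its cells match one and
#' the same true cell over the whole span and both endpoint mitoses
#' are correct.
#'
#' @param result A `tracking_paths` or `lineage_result` object (fields
#'   `cells`, `mitoses`, `complete`).
#' @param truth A `ground_truth`.
#' @param masks The detected masks the result was computed from.
#' @param overlap_floor Dual-overlap matching floor.
#' @param frame_tolerance Allowed |detected - true| division frame
#'   difference.
#' @return A one-row tibble mirroring the classification count table:
#'   `paths`, `detected_mitoses`, `correct_mitoses`,
#'   `mitosis_trustworthiness`, `complete_paths`,
#'   `correct_complete_paths`, `tracking_trustworthiness`.
#' @export
classification_counts <- function(result, truth, masks,
                                  overlap_floor = 0.3,
                                  frame_tolerance = 1L) {
  corr <- truth_correspondence(masks, truth$masks, overlap_floor)
  reg <- truth$cells
  div_frames <- reg$death_frame[match(reg$id, reg$id)]
  # mitosis correctness: matched parent cell divides at frame +/- tol
  mito <- result$mitoses
  correct_mito <- logical(nrow(mito))
  if (nrow(mito)) {
    matched <- mito %>%
      left_join(corr, by = c("frame", "label"))
    t_death <- reg$death_frame[match(matched$true_id, reg$id)]
    t_fate <- reg$fate[match(matched$true_id, reg$id)]
    correct_mito <- !is.na(matched$true_id) & !is.na(t_fate) &
      t_fate == "division" &
      abs(t_death - matched$frame) <= frame_tolerance
  }
  # complete-path correctness
  comp <- result$complete
  correct_path <- logical(nrow(comp))
  if (nrow(comp)) {
    cell_corr <- result$cells %>% left_join(corr, by = c("frame", "label"))
    for (i in seq_len(nrow(comp))) {
      cc <- cell_corr %>% filter(.data$path == comp$path[i])
      ids <- cc$true_id
      if (any(is.na(ids)) || dplyr::n_distinct(ids) != 1L) next
      tid <- ids[1]
      birth_ok <- !is.na(reg$birth_frame[match(tid, reg$id)]) &&
        abs(reg$birth_frame[match(tid, reg$id)] - 1L - comp$birth_frame[i]) <=
          frame_tolerance
      death_ok <- identical(reg$fate[match(tid, reg$id)], "division") &&
        abs(reg$death_frame[match(tid, reg$id)] - comp$death_frame[i]) <=
          frame_tolerance
      correct_path[i] <- birth_ok && death_ok
    }
  }
  tibble(paths = dplyr::n_distinct(result$cells$path),
         detected_mitoses = nrow(mito),
         correct_mitoses = sum(correct_mito),
         mitosis_trustworthiness = trustworthiness(sum(correct_mito),
                                                   nrow(mito)),
         complete_paths = nrow(comp),
         correct_complete_paths = sum(correct_path),
         tracking_trustworthiness = trustworthiness(sum(correct_path),
                                                    nrow(comp)))
}

#' Represent ground truth in the tracking-result format
#'
#' Useful as the reference column of the classification count table
#' and for genealogy comparisons: every true cell becomes a path, true
#' divisions become mitoses, and true cells born and dying by division
#' inside the movie become complete paths.
#'
#' @param truth A `ground_truth`.
#' @return A `tracking_paths`-shaped list (`cells` uses true ids as
#'   both path and label; pair it with `truth$masks`).
#' @export
truth_as_tracking <- function(truth) {
  cells <- purrr::map_dfr(seq_along(truth$masks), function(t) {
    m <- truth$masks[[t]]
    ids <- sort(unique(m[m > 0L]))
    if (!length(ids)) return(NULL)
    tibble(path = ids, frame = t, label = match(ids, ids))
  })
  # labels must match the relabelled truth masks (1..n per frame)
  reg <- truth$cells
  lin <- truth$lineage
  mitoses <- if (nrow(lin)) {
    lin %>% group_by(.data$parent, .data$frame) %>%
      summarise(daughter1 = min(.data$daughter),
                daughter2 = max(.data$daughter), .groups = "drop") %>%
      mutate(label = NA_integer_) %>%
      select(parent = "parent", "frame", "label", "daughter1", "daughter2")
  } else {
    tibble(parent = integer(), frame = integer(), label = integer(),
           daughter1 = integer(), daughter2 = integer())
  }
  # fill parent labels from the per-frame mask id order
  if (nrow(mitoses)) {
    for (i in seq_len(nrow(mitoses))) {
      m <- truth$masks[[mitoses$frame[i]]]
      ids <- sort(unique(m[m > 0L]))
      mitoses$label[i] <- match(mitoses$parent[i], ids)
    }
  }
  complete <- reg %>%
    filter(!is.na(.data$parent), .data$fate == "division") %>%
    transmute(path = .data$id, birth_frame = .data$birth_frame,
              death_frame = .data$death_frame)
  structure(list(cells = cells, mitoses = mitoses, complete = complete,
                 lineage = select(lin, "parent", "daughter", "frame"),
                 masks = relabel_masks_consecutive(truth$masks)),
            class = "tracking_paths")
}

#' Degree of relation between two cells in a genealogic forest
#'
#' The number of mitoses connecting the two cells through their
#' genealogic tree: siblings and parent/child pairs have degree 1,
#' first cousins degree 3. Unrelated cells (different trees) have
#' degree 0, which is why the query cells must differ.
#'
#' @param lineage A tibble of parent -> daughter edges (`parent`,
#'   `daughter`), each edge one mitosis crossing.
#' @param a,b Two distinct cell/path ids.
#' @return Non-negative integer degree.
#' @export
degree_of_relation <- function(lineage, a, b) {
  if (a == b) stop("degree of relation is defined between distinct cells")
  up <- function(x) {
    depth <- 0L; chain <- setNames(0L, as.character(x))
    while (TRUE) {
      p <- lineage$parent[match(x, lineage$daughter)]
      if (is.na(p)) break
      depth <- depth + 1L
      chain[as.character(p)] <- depth
      x <- p
    }
    chain
  }
  ca <- up(a); cb <- up(b)
  common <- intersect(names(ca), names(cb))
  if (!length(common)) return(0L)
  lca <- common[which.min(ca[common] + cb[common])]
  da <- ca[[lca]]; db <- cb[[lca]]
  as.integer(da + db - (da > 0L && db > 0L))
}

#' Genealogy error rates in one frame
#'
#' Over all pairs of reference cells present in the frame that are
#' related (reference degree > 0): the false rejection rate is the
#' fraction of these relations the prediction misses (predicted degree
#' 0, including cells it did not track), and the false acceptance rate
#' the fraction assigned a wrong nonzero degree.
#'
#' @param predicted A result with `cells` (path, frame, label) and a
#'   lineage edge table (`forest` for validated results, `lineage`
#'   otherwise).
#' @param truth A `ground_truth`.
#' @param frame Frame index to evaluate.
#' @param masks Detected masks underlying `predicted`.
#' @param overlap_floor Dual-overlap matching floor.
#' @return Tibble `far`, `frr`, `n_relations`; rates are `NA` when the
#'   frame holds no reference relations.
#' @export
genealogy_error_rates <- function(predicted, truth, frame, masks,
                                  overlap_floor = 0.3) {
  lin_pred <- if (!is.null(predicted$forest)) predicted$forest else
    predicted$lineage
  corr <- truth_correspondence(masks[frame], truth$masks[frame],
                               overlap_floor)
  if (nrow(corr)) corr$frame <- frame
  # true cells present in the frame
  tm <- truth$masks[[frame]]
  tru_ids <- sort(unique(tm[tm > 0L]))
  pred_cells <- predicted$cells %>% filter(.data$frame == .env$frame)
  map <- corr %>%
    left_join(pred_cells, by = c("frame", "label")) %>%
    select("true_id", "path")
  pairs <- utils::combn(tru_ids, 2)
  ref_deg <- apply(pairs, 2, function(p)
    degree_of_relation(truth$lineage, p[1], p[2]))
  rel <- which(ref_deg > 0L)
  if (!length(rel)) {
    return(tibble(far = NA_real_, frr = NA_real_, n_relations = 0L))
  }
  miss <- 0L; wrong <- 0L
  for (j in rel) {
    pa <- map$path[match(pairs[1, j], map$true_id)]
    pb <- map$path[match(pairs[2, j], map$true_id)]
    pd <- if (is.na(pa) || is.na(pb) || pa == pb) 0L else
      degree_of_relation(lin_pred, pa, pb)
    if (pd == 0L) miss <- miss + 1L
    else if (pd != ref_deg[j]) wrong <- wrong + 1L
  }
  tibble(far = wrong / length(rel), frr = miss / length(rel),
         n_relations = length(rel))
}
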