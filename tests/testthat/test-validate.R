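disk_at <- function(x, y, r = 8, w = 200, h = 200) {
  m <- matrix(0L, h, w)
  xs <- rep(seq_len(w), each = h); ys <- rep(seq_len(h), times = w)
  sel <- (xs - x)^2 + (ys - y)^2 <= r^2
  m[cbind(ys, xs)[sel, ]] <- 1L
  m
}

relabel_all <- function(masks) {
  lapply(masks, function(m) label_components(m > 0))
}

test_that("terminus flags follow the status-flag taxonomy", {
  # cell A spans the whole movie mid-image; cell B appears at frame 3
  # near the left border; cell C appears at frame 4 mid-image
  masks <- lapply(1:8, function(t) {
    m <- disk_at(100, 100)
    if (t >= 3) m <- m + 2L * disk_at(12, 150)
    if (t >= 4) m <- m + 3L * disk_at(160, 40)
    m
  })
  masks <- relabel_all(masks)
  tr <- build_path_fragments(masks)
  flags <- assign_path_flags(tr, border_margin = 30)
  expect_equal(nrow(flags), 3)
  whole <- dplyr::filter(flags, start_frame == 1)
  expect_equal(whole$start_flag, "begin")
  expect_equal(whole$end_flag, "end")
  border <- dplyr::filter(flags, start_frame == 3)
  expect_equal(border$start_flag, "border_begin")
  lost <- dplyr::filter(flags, start_frame == 4)
  expect_equal(lost$start_flag, "lost_begin")
})

test_that("simulated divisions are detected at the true frame", {
  mv <- div_movie()
  res <- div_result()
  lin <- dplyr::distinct(mv$truth$lineage, parent, frame)
  # every detected mitosis sits within one frame of a true division
  corr <- frame_correspondence(div_tracks()$masks, mv$truth)
  matched <- dplyr::left_join(res$mitoses, corr, by = c("frame", "label"))
  reg <- mv$truth$cells
  t_death <- reg$death_frame[match(matched$true_id, reg$id)]
  t_fate <- reg$fate[match(matched$true_id, reg$id)]
  expect_gt(nrow(matched), 10)
  expect_true(all(!is.na(matched$true_id)))
  expect_true(all(t_fate == "division"))
  expect_true(all(abs(t_death - matched$frame) <= 1))
  # and the detector finds the majority of usable true divisions
  expect_gt(nrow(res$mitoses), 0.6 * nrow(lin))
})

test_that("reversed-Y junctions are merges, not mitoses", {
  tr <- merge_tracks()
  merges <- detect_merges(tr)
  expect_gte(nrow(merges), 1)
  expect_true(all(merges$n_predecessors >= 2))
  # division junctions (1 -> 2) are never merge events
  div_res <- div_result()
  expect_false(any(div_res$mitoses$parent %in% div_res$merges$successor))
})

test_that("dropout gaps are bridged by local-threshold recovery", {
  mv <- dropout_movie()
  tr <- track_movie(mv$frames, run_config())
  flags <- assign_path_flags(tr)
  expect_gte(sum(flags$start_flag == "lost_begin"), 1)
  rec <- recover_undetected(tr, flags)
  expect_gte(nrow(rec$joins), 1)
  # after recovery the joined fragments share one chain in the result
  res <- validate_tracks(tr, mitosis_model())
  expect_gte(nrow(res$recovery$joins), 1)
  j <- res$recovery$joins[1, ]
  frag_chain <- function(fr) {
    rows <- tr$fragments[tr$fragments$fragment == fr, ]
    unique(res$cells$path[match(paste(rows$frame, rows$label),
                                paste(res$cells$frame, res$cells$label))])
  }
  expect_equal(frag_chain(j$from), frag_chain(j$to))

  # a movie without dropouts yields no joins
  tr2 <- merge_tracks()
  rec2 <- recover_undetected(tr2, assign_path_flags(tr2))
  expect_equal(nrow(rec2$recovered), 0)
})

test_that("the decision tree classifies debris and leaves reasons everywhere", {
  res <- err_bundle()$result
  # debris particles appear suddenly and span almost no frames
  deb <- dplyr::filter(res$termini, class == "debris")
  expect_gte(nrow(deb), 1)
  deb_frag <- dplyr::filter(res$flags, fragment %in% deb$fragment)
  expect_true(all(deb_frag$length <= 2))
  # every fragment is either accepted or rejected with a reason
  acc_frags <- unlist(lapply(strsplit(res$accepted$fragments, ";"),
                             as.integer))
  expect_setequal(c(acc_frags, res$rejected$fragment),
                  res$flags$fragment)
  expect_true(all(nchar(res$rejected$reason) > 0))
  expect_true(all(res$termini$class %in%
                    c("movie_begin", "movie_end", "border", "merged",
                      "mitosis", "vanished_recovered", "cell_death",
                      "debris", "unresolved")))
})

test_that("only complete mitosis-to-mitosis paths are accepted", {
  mv <- div_movie()
  res <- div_result()
  reg <- mv$truth$cells
  corr <- frame_correspondence(div_tracks()$masks, mv$truth)
  cells <- dplyr::left_join(res$cells, corr, by = c("frame", "label"))
  for (i in seq_len(nrow(res$accepted))) {
    p <- res$accepted[i, ]
    ids <- dplyr::filter(cells, path == p$path)$true_id
    expect_equal(dplyr::n_distinct(stats::na.omit(ids)), 1)
    tid <- stats::na.omit(ids)[1]
    # born by division, dies by division, inside the movie
    expect_false(is.na(reg$parent[match(tid, reg$id)]))
    expect_equal(reg$fate[match(tid, reg$id)], "division")
  }
  # roots (alive at frame 1) are never accepted
  root_ids <- reg$id[reg$birth_frame == 1]
  acc_ids <- cells |> dplyr::filter(path %in% res$accepted$path) |>
    dplyr::pull(true_id)
  expect_false(any(stats::na.omit(acc_ids) %in% root_ids))

  # a movie without mitoses yields zero complete paths
  res0 <- validate_tracks(merge_tracks(), mitosis_model())
  expect_equal(nrow(res0$accepted), 0)
})

test_that("the accepted forest is an acyclic two-daughter lineage", {
  res <- err_bundle()$result
  forest <- res$forest
  if (nrow(forest)) {
    g <- igraph::make_graph(as.character(rbind(forest$parent,
                                               forest$daughter)),
                            directed = TRUE)
    expect_true(igraph::is_dag(g))
    expect_true(all(dplyr::count(forest, parent)$n <= 2))
  }
  expect_true(all(dplyr::count(res$lineage, parent)$n == 2))
})

test_that("life times of accepted paths are unbiased (no-selection check)", {
  nb <- nobias_bundle()
  truec <- dplyr::filter(nb$reg, !is.na(parent), fate == "division")
  lt_true <- (truec$death_frame - truec$birth_frame) * 15
  lt_acc <- nb$accepted$lifetime_min
  expect_gte(length(lt_acc), 300)
  ks <- suppressWarnings(stats::ks.test(lt_acc, lt_true))
  expect_gt(ks$p.value, 0.01)
})
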