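two_frame_rect <- function(shift) {
  # 10x10 cell in frame t; shifted copy in frame t+1
  a <- matrix(0L, 40, 40); a[11:20, 11:20] <- 1L
  b <- matrix(0L, 40, 40); b[11:20 + shift, 11:20] <- 1L
  list(a, b)
}

test_that("forward and backward overlaps follow their definitions", {
  m <- two_frame_rect(0)
  ov <- pairwise_overlaps(m[[1]], m[[2]])
  expect_equal(nrow(ov), 1)
  expect_equal(ov$o_fw, 1); expect_equal(ov$o_bw, 1)

  # areas 100 and 120 with intersection 60
  a <- matrix(0L, 40, 40); a[1:10, 1:10] <- 1L
  b <- matrix(0L, 40, 40); b[5:14, 1:12] <- 1L
  ov2 <- pairwise_overlaps(a, b)
  expect_equal(ov2$intersection, 60L)
  expect_equal(ov2$o_fw, 0.6)
  expect_equal(ov2$o_bw, 0.5)

  # disjoint masks
  d <- matrix(0L, 40, 40); d[30:35, 30:35] <- 1L
  expect_equal(nrow(pairwise_overlaps(m[[1]], d)), 0)
  expect_error(pairwise_overlaps(m[[1]], matrix(0L, 10, 10)),
               "dimensions")
})

test_that("linking requires both thresholds and uniqueness", {
  ov <- tibble::tibble(label_t = 1L, label_t1 = 1L, intersection = 60L,
                       o_fw = 0.6, o_bw = 0.6)
  lc <- link_cells(ov, 0.3, 0.3)
  expect_equal(nrow(lc$links), 1)

  # a split: one source, two candidate successors
  ov2 <- tibble::tibble(label_t = c(1L, 1L), label_t1 = c(1L, 2L),
                        intersection = c(60L, 50L),
                        o_fw = c(0.5, 0.4), o_bw = c(0.6, 0.5))
  lc2 <- link_cells(ov2, 0.3, 0.3)
  expect_equal(nrow(lc2$links), 0)
  expect_equal(nrow(lc2$ambiguous), 2)

  # threshold conjunction: o_bw below threshold is not a candidate
  ov3 <- tibble::tibble(label_t = 1L, label_t1 = 1L, intersection = 30L,
                        o_fw = 0.6, o_bw = 0.2)
  expect_equal(nrow(link_cells(ov3, 0.3, 0.3)$links), 0)

  # a sub-threshold concurrent overlap above the ambiguity floor
  # vetoes uniqueness
  ov4 <- tibble::tibble(label_t = c(1L, 1L), label_t1 = c(1L, 2L),
                        intersection = c(60L, 20L),
                        o_fw = c(0.5, 0.15), o_bw = c(0.6, 0.15))
  expect_equal(nrow(link_cells(ov4, 0.3, 0.3, t_amb = 0.1)$links), 0)
  expect_equal(nrow(link_cells(ov4, 0.3, 0.3, t_amb = 0.2)$links), 1)
})

test_that("a drifting cell yields one fragment and no adjacency", {
  masks <- lapply(0:9, function(s) {
    m <- matrix(0L, 60, 80)
    xs <- rep(1:80, each = 60); ys <- rep(1:60, times = 80)
    m[cbind(ys, xs)[(xs - 20 - 2 * s)^2 + (ys - 30)^2 <= 80, ]] <- 1L
    m
  })
  tr <- build_path_fragments(masks)
  expect_equal(max(tr$fragments$fragment), 1)
  expect_equal(nrow(tr$fragments), 10)
  expect_equal(nrow(tr$adjacency), 0)
})

test_that("a division ends the parent fragment and links both daughters", {
  mv <- div_movie()
  tr <- div_tracks()
  lin <- mv$truth$lineage
  f_div <- lin$frame[1]
  corr <- frame_correspondence(tr$masks, mv$truth)
  par_lab <- dplyr::filter(corr, frame == f_div,
                           true_id == lin$parent[1])$label
  par_frag <- dplyr::filter(tr$fragments, frame == f_div,
                            label == par_lab)$fragment
  expect_equal(max(dplyr::filter(tr$fragments,
                                 fragment == par_frag)$frame), f_div)
  kids <- dplyr::filter(tr$adjacency, fragment_a == par_frag)
  expect_equal(nrow(kids), 2)
  expect_true(all(kids$boundary_frame == f_div))
  kid_start <- dplyr::filter(tr$fragments,
                             fragment %in% kids$fragment_b) |>
    dplyr::group_by(fragment) |>
    dplyr::summarise(s = min(frame))
  expect_true(all(kid_start$s == f_div + 1))
})

test_that("fragments partition the detected cells", {
  tr <- div_tracks()
  cells <- dplyr::count(tr$fragments, frame, label)
  expect_true(all(cells$n == 1))
  n_detected <- sum(vapply(tr$masks, max, integer(1)))
  expect_equal(nrow(tr$fragments), n_detected)
  # fragment ids are consecutive
  expect_setequal(unique(tr$fragments$fragment),
                  seq_len(max(tr$fragments$fragment)))
  # frames within a fragment are strictly consecutive
  gaps <- tr$fragments |>
    dplyr::group_by(fragment) |>
    dplyr::summarise(ok = all(diff(sort(frame)) == 1))
  expect_true(all(gaps$ok))
})

test_that("raising the overlap thresholds only fragments further", {
  masks <- div_tracks()$masks[1:25]
  n_frag <- vapply(c(0.2, 0.4, 0.6, 0.8), function(tt) {
    max(build_path_fragments(masks, t_fw = tt, t_bw = tt,
                             t_amb = min(tt, 0.1))$fragments$fragment)
  }, integer(1))
  expect_true(all(diff(n_frag) >= 0))
})

test_that("adjacency entries are temporally compatible", {
  eb <- err_bundle()
  meta <- eb$fragments |>
    dplyr::group_by(fragment) |>
    dplyr::summarise(s = min(frame), e = max(frame))
  adj <- eb$adjacency
  expect_true(all(meta$e[match(adj$fragment_a, meta$fragment)] ==
                    adj$boundary_frame))
  expect_true(all(meta$s[match(adj$fragment_b, meta$fragment)] ==
                    adj$boundary_frame + 1))
  expect_true(all(adj$fragment_a != adj$fragment_b))
  expect_false(any(duplicated(adj[, c("fragment_a", "fragment_b",
                                      "boundary_frame")])))
})

test_that("naive backward tracking reproduces the clean single-cell case", {
  masks <- lapply(0:7, function(s) {
    m <- matrix(0L, 50, 70)
    xs <- rep(1:70, each = 50); ys <- rep(1:50, times = 70)
    m[cbind(ys, xs)[(xs - 15 - 2 * s)^2 + (ys - 25)^2 <= 60, ]] <- 1L
    m
  })
  nt <- naive_track(masks)
  expect_equal(length(unique(nt$cells$path)), 1)
  expect_equal(nrow(nt$mitoses), 0)
  # a frame with no overlap to the previous one starts a new path
  masks2 <- masks
  masks2[[5]][] <- 0L
  m2 <- matrix(0L, 50, 70); m2[40:46, 60:66] <- 1L
  masks2[[5]] <- m2
  nt2 <- naive_track(masks2)
  expect_gt(length(unique(nt2$cells$path)), 1)
})

test_that("an optical merge gives naive tracking a false Y but no validated mitosis", {
  mv <- merge_movie()
  tr <- merge_tracks()
  nt <- naive_track(tr$masks)
  expect_gte(nrow(nt$mitoses), 1)     # merge-then-separate fakes a division
  res <- validate_tracks(tr, mitosis_model())
  expect_equal(nrow(res$mitoses), 0)  # no true divisions in this movie
  expect_gte(nrow(res$merges), 1)
})
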