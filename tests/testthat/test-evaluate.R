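rect_mask <- function(y0, y1, x0, x1, w = 40, h = 40, lab = 1L) {
  m <- matrix(0L, h, w); m[y0:y1, x0:x1] <- lab; m
}

test_that("dual-overlap matching counts TP, FP and FN correctly", {
  ref <- rect_mask(11, 20, 11, 20)
  expect_equal(match_detections(ref, ref)$counts,
               tibble::tibble(tp = 1L, fp = 0L, fn = 0L))

  # one detected blob covering two reference cells at > 30% each
  det <- rect_mask(11, 20, 1, 30)
  ref2 <- rect_mask(11, 20, 3, 12) + 2L * rect_mask(11, 20, 19, 28)
  mm <- match_detections(det, ref2)
  expect_equal(mm$counts, tibble::tibble(tp = 0L, fp = 1L, fn = 2L))

  # low-accuracy detection (one overlap 25%) is both FP and FN
  det3 <- rect_mask(1, 10, 1, 10)
  ref3 <- rect_mask(1, 10, 9, 18)   # intersection 20 of 100: 20%... shift
  ref3 <- rect_mask(1, 10, 8, 17)   # intersection 30 -> 30%, still <= floor
  mm3 <- match_detections(det3, ref3)
  expect_equal(mm3$counts, tibble::tibble(tp = 0L, fp = 1L, fn = 1L))

  # symmetry: swapping detected and reference swaps FP and FN
  a <- rect_mask(5, 14, 5, 14) + 2L * rect_mask(25, 34, 25, 34)
  b <- rect_mask(5, 14, 7, 16)
  ab <- match_detections(a, b)$counts
  ba <- match_detections(b, a)$counts
  expect_equal(ab$tp, ba$tp)
  expect_equal(ab$fp, ba$fn)
  expect_equal(ab$fn, ba$fp)
})

test_that("FAR and FRR follow their definitions", {
  r <- detection_error_rates(tibble::tibble(tp = 95, fp = 5, fn = 5))
  expect_equal(r$far, 0.05)
  expect_equal(r$frr, 0.05)
  expect_equal(detection_error_rates(tibble::tibble(tp = 10, fp = 0, fn = 0)),
               tibble::tibble(far = 0, frr = 0))
  r2 <- detection_error_rates(tibble::tibble(tp = 0, fp = 3, fn = 0))
  expect_equal(r2$far, 1)
  expect_true(is.na(r2$frr))
})

test_that("trustworthiness is the percentage of correct results", {
  expect_equal(trustworthiness(7, 7), 100)
  expect_true(is.na(trustworthiness(0, 0)))
  expect_error(trustworthiness(5, 4), "exceeds")
  # adding a correct result never lowers it; adding a wrong one never
  # raises it
  for (k in 1:10) {
    c0 <- sample(0:20, 1); t0 <- c0 + sample(0:20, 1)
    if (t0 == 0) next
    expect_gte(trustworthiness(c0 + 1, t0 + 1), trustworthiness(c0, t0))
    expect_lte(trustworthiness(c0, t0 + 1), trustworthiness(c0, t0))
  }
})

test_that("classification counts give the reference pattern on truth itself", {
  truth <- div_movie()$truth
  ref <- truth_as_tracking(truth)
  cc <- classification_counts(ref, truth, ref$masks)
  expect_equal(cc$mitosis_trustworthiness, 100)
  expect_equal(cc$tracking_trustworthiness, 100)
  expect_equal(cc$detected_mitoses, nrow(truth$lineage) / 2)
  expect_equal(cc$complete_paths,
               sum(!is.na(truth$cells$parent) &
                     truth$cells$fate == "division"))
})

test_that("degree of relation counts mitoses on the tree path", {
  # enumerated 3-generation tree: 1 -> (2,3); 2 -> (4,5); 3 -> (6,7)
  lin <- tibble::tibble(parent = c(1, 1, 2, 2, 3, 3),
                        daughter = c(2, 3, 4, 5, 6, 7),
                        frame = c(5, 5, 10, 10, 12, 12))
  expect_equal(degree_of_relation(lin, 4, 5), 1)   # siblings
  expect_equal(degree_of_relation(lin, 2, 4), 1)   # parent-child
  expect_equal(degree_of_relation(lin, 4, 6), 3)   # first cousins
  expect_equal(degree_of_relation(lin, 1, 4), 2)   # grandparent
  expect_equal(degree_of_relation(lin, 4, 99), 0)  # different trees
  expect_error(degree_of_relation(lin, 4, 4), "distinct")
  # symmetry and brute-force oracle over every pair
  ids <- 1:7
  for (a in ids) for (b in ids) {
    if (a >= b) next
    expect_equal(degree_of_relation(lin, a, b),
                 degree_of_relation(lin, b, a))
    expect_equal(degree_of_relation(lin, a, b), brute_degree(lin, a, b))
  }
})

test_that("degree of relation matches brute force on a simulated forest", {
  lin <- div_movie()$truth$lineage
  ids <- unique(c(lin$parent, lin$daughter))
  set.seed(6)
  for (k in 1:40) {
    ab <- sample(ids, 2)
    expect_equal(degree_of_relation(lin, ab[1], ab[2]),
                 brute_degree(lin, ab[1], ab[2]))
  }
})

test_that("genealogy error rates compare predicted and true relations", {
  truth <- div_movie()$truth
  ref <- truth_as_tracking(truth)
  f <- max(truth$lineage$frame) + 1
  # prediction identical to the reference: no errors
  r0 <- genealogy_error_rates(ref, truth, f, ref$masks)
  expect_equal(r0$far, 0)
  expect_equal(r0$frr, 0)
  expect_gt(r0$n_relations, 0)
  # empty prediction: every relation missed
  none <- ref
  none$lineage <- none$lineage[0, ]
  r1 <- genealogy_error_rates(none, truth, f, ref$masks)
  expect_equal(r1$frr, 1)
  expect_equal(r1$far, 0)
  # one mitosis deleted: rates match exhaustive pair enumeration
  broken <- ref
  drop_parent <- broken$lineage$parent[1]
  broken$lineage <- dplyr::filter(broken$lineage, parent != drop_parent)
  r2 <- genealogy_error_rates(broken, truth, f, ref$masks)
  tm <- truth$masks[[f]]
  ids <- sort(unique(tm[tm > 0]))
  pairs <- utils::combn(ids, 2)
  refd <- apply(pairs, 2, function(p) brute_degree(truth$lineage, p[1], p[2]))
  predd <- apply(pairs, 2, function(p) brute_degree(broken$lineage, p[1], p[2]))
  rel <- refd > 0
  expect_equal(r2$frr, sum(rel & predd == 0) / sum(rel))
  expect_equal(r2$far, sum(rel & predd > 0 & predd != refd) / sum(rel))
})

test_that("validated tracking beats naive tracking on classification counts", {
  mv <- div_movie()
  tr <- div_tracks()
  cc_val <- classification_counts(div_result(), mv$truth, tr$masks)
  cc_naive <- classification_counts(naive_track(tr$masks), mv$truth,
                                    tr$masks)
  expect_gt(cc_val$tracking_trustworthiness,
            cc_naive$tracking_trustworthiness)
  expect_gt(cc_val$mitosis_trustworthiness,
            cc_naive$mitosis_trustworthiness)
})
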