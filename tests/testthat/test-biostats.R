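test_that("proliferation counts match the simulator's living-cell register", {
  mv <- div_movie()
  counts <- proliferation_curve(mv$truth$masks)
  reg <- mv$truth$cells
  living <- vapply(seq_along(mv$truth$masks), function(t)
    sum(reg$birth_frame <= t & reg$death_frame >= t), integer(1))
  expect_equal(counts$n_cells, living)
  expect_equal(proliferation_curve(list(matrix(0L, 5, 5)))$n_cells, 0L)
})

test_that("division probability is mitoses over mean cell count", {
  counts <- tibble::tibble(frame = 1:16, n_cells = rep(1000, 16))
  dp <- division_probability(counts, mitosis_frames = rep(4, 10),
                             window = 120, frame_interval = 15)
  expect_equal(dp$division_probability_pct[1], 1.0)
  expect_equal(dp$division_probability_pct[2], 0)
  dp0 <- division_probability(counts, integer(0), 120, 15)
  expect_true(all(dp0$division_probability_pct == 0))
  # integration: sum of prob * mean count recovers the mitosis total
  mv <- div_movie()
  cc <- proliferation_curve(mv$truth$masks)
  mf <- mv$truth$lineage$frame[!duplicated(paste(mv$truth$lineage$parent,
                                                 mv$truth$lineage$frame))]
  dp2 <- division_probability(cc, mf, window = 120, frame_interval = 15)
  expect_equal(sum(dp2$division_probability_pct * dp2$mean_cells / 100),
               length(mf), tolerance = 1e-8)
})

test_that("confluency and mean area follow their definitions", {
  m <- matrix(0L, 20, 20); m[1:10, 1:10] <- 1L   # exactly 25% foreground
  st <- confluency_and_mean_area(list(m))
  expect_equal(st$confluency_pct, 25)
  m2 <- matrix(0L, 20, 50); m2[1:10, 1:10] <- 1L  # 100 px in 1000 px
  st2 <- confluency_and_mean_area(list(m2), pixel_size = 2)
  expect_equal(st2$confluency_pct, 10)
  expect_equal(st2$mean_area_px, 100)
  expect_equal(st2$mean_area_um2, 400)
})

test_that("life times are path spans in minutes, stamped with end times", {
  comp <- tibble::tibble(path = 1L, birth_frame = 10L, death_frame = 58L)
  lt <- lifetime_distribution(comp, frame_interval = 15)
  expect_equal(lt$lifetime_min, 720)       # 12 hours
  expect_equal(lt$end_time_min, 57 * 15)
  expect_equal(nrow(lifetime_distribution(comp[0, ], 15)), 0)
  # recovery of the configured distribution from the simulator's truth
  reg <- dplyr::filter(div_movie()$truth$cells, fate == "division",
                       !is.na(parent))
  lt2 <- (reg$death_frame - reg$birth_frame) * 15
  se <- sd(lt2) / sqrt(length(lt2))
  expect_lt(abs(mean(lt2) - 240), 3 * se)
})

test_that("sibling symmetry is the signed life-time difference", {
  forest <- tibble::tibble(parent = c(1, 1), daughter = c(2, 3),
                           frame = c(4, 4))
  comp <- tibble::tibble(path = c(2, 3), lifetime_min = c(720, 780))
  sym <- sibling_symmetry(forest, comp)
  expect_equal(abs(sym$symmetry_min), 60)
  expect_equal(sym$abs_symmetry_min, 60)
  comp_eq <- tibble::tibble(path = c(2, 3), lifetime_min = c(700, 700))
  expect_equal(sibling_symmetry(forest, comp_eq)$symmetry_min, 0)
  # a mitosis with an incomplete daughter is skipped
  comp_half <- tibble::tibble(path = 2, lifetime_min = 700)
  expect_equal(nrow(sibling_symmetry(forest, comp_half)), 0)
})

test_that("sibling life times are symmetric on unbiased simulations", {
  nb <- nobias_bundle()
  sym <- sibling_symmetry(nb$forest, nb$accepted)
  expect_gt(nrow(sym), 20)
  se <- sd(sym$symmetry_min) / sqrt(nrow(sym))
  expect_lt(abs(mean(sym$symmetry_min)), 3 * se)
})

test_that("tree summaries count generations and connected paths", {
  expect_equal(tree_summary(tibble::tibble(parent = integer(),
                                           daughter = integer()),
                            paths = 5)$n_paths, 1L)
  full <- tibble::tibble(parent = c(1, 1, 2, 2, 3, 3),
                         daughter = 2:7)
  ts <- tree_summary(full)
  expect_equal(ts$n_paths, 7L)           # 1 + 2 + 4
  expect_equal(ts$generations, 3L)
  # simulator cross-check: one tree per initial cell that divided
  lin <- div_movie()$truth$lineage
  ts2 <- tree_summary(lin)
  roots <- setdiff(lin$parent, lin$daughter)
  expect_equal(nrow(ts2), length(unique(roots)))
  expect_equal(sum(ts2$n_paths), length(unique(c(lin$parent,
                                                 lin$daughter))))
})
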