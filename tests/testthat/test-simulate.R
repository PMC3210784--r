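test_that("a movie without divisions or injected errors is event-free", {
  cfg <- simulation_config(width = 300, height = 300, n_frames = 50,
                           n_initial = 10, life_mean = 1e7, life_sd = 10,
                           seed = 3)
  mv <- simulate_movie(cfg)
  expect_length(mv$frames, 50)
  expect_equal(nrow(mv$truth$cells), 10)
  expect_equal(nrow(mv$truth$lineage), 0)
  expect_equal(nrow(mv$truth$events), 0)
  # conservation: every frame shows exactly the living cells
  for (t in c(1, 25, 50)) {
    m <- mv$truth$masks[[t]]
    expect_equal(length(unique(m[m > 0])), 10)
  }
})

test_that("identical config and seed give bit-identical output", {
  cfg <- simulation_config(width = 128, height = 128, n_frames = 6,
                           n_initial = 4, life_mean = 1e7, life_sd = 10,
                           seed = 7)
  a <- simulate_movie(cfg)
  b <- simulate_movie(cfg)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth$masks, b$truth$masks)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("simulated life times follow the configured distribution", {
  cfg <- simulation_config(width = 700, height = 700, n_frames = 30,
                           n_initial = 25, life_mean = 120, life_sd = 30,
                           frame_interval = 15, seed = 11)
  mv <- simulate_movie(cfg)
  div <- dplyr::filter(mv$truth$cells, fate == "division")
  lt <- (div$death_frame - div$birth_frame) * 15
  expect_gt(length(lt), 100)
  se <- sd(lt) / sqrt(length(lt))
  expect_lt(abs(mean(lt) - 120), 3 * se)
})

test_that("lineage is a two-daughter forest with contiguous frames", {
  mv <- div_movie()
  lin <- mv$truth$lineage
  per_mito <- dplyr::count(lin, parent, frame)
  expect_true(all(per_mito$n == 2))
  # every non-root id is daughter of exactly one mitosis
  expect_false(any(duplicated(lin$daughter)))
  reg <- mv$truth$cells
  # daughters start the frame after the parent's last frame
  daughter_birth <- reg$birth_frame[match(lin$daughter, reg$id)]
  parent_death <- reg$death_frame[match(lin$parent, reg$id)]
  parent_birth <- reg$birth_frame[match(lin$parent, reg$id)]
  expect_equal(length(daughter_birth), nrow(lin))
  expect_true(all(daughter_birth == parent_death + 1))
  # acyclic by construction: daughters born strictly after parents
  expect_true(all(daughter_birth > parent_birth))
})

test_that("rendering honours background, cells, dropouts and noise", {
  cfg <- simulation_config(width = 80, height = 80, n_frames = 1,
                           n_initial = 1, noise_sd = 0,
                           gradient_amplitude = 0, seed = 1)
  mv <- simulate_movie(cfg)
  img <- mv$frames[[1]]
  m <- mv$truth$masks[[1]]
  expect_true(all(img[m == 0] == cfg$background))
  expect_true(all(img[m > 0] > cfg$background + 20))
  expect_equal(max(img), max(img[m > 0]))

  # dropout at zero contrast renders within 2 grey levels of background
  cfg2 <- simulation_config(width = 300, height = 300, n_frames = 25,
                            n_initial = 5, life_mean = 1e7, life_sd = 10,
                            dropout_events = 1, dropout_duration = 3,
                            dropout_contrast = 0, noise_sd = 0,
                            gradient_amplitude = 0, seed = 13)
  mv2 <- simulate_movie(cfg2)
  ev <- dplyr::filter(mv2$truth$events, type == "dropout")
  expect_equal(nrow(ev), 1)
  t <- ev$start_frame[1]
  id <- as.integer(ev$ids[1])
  px <- mv2$frames[[t]][mv2$truth$masks[[t]] == id]
  expect_true(all(abs(px - cfg2$background) <= 2))
})

test_that("injected events are logged with their frame spans", {
  ev <- err_bundle()$events
  expect_setequal(unique(ev$type),
                  c("merge", "dropout", "debris", "border_exit",
                    "border_entry"))
  expect_true(all(ev$start_frame >= 1 & ev$end_frame <= 150))
  expect_true(all(ev$end_frame >= ev$start_frame))
  expect_equal(sum(ev$type == "merge"), 6)
  expect_equal(sum(ev$type == "dropout"), 6)
})

test_that("ground truth round-trips through export and import", {
  mv <- simulate_movie(simulation_config(width = 150, height = 150,
                                         n_frames = 12, n_initial = 4,
                                         life_mean = 90, life_sd = 20,
                                         seed = 2))
  dir <- withr::local_tempdir()
  export_ground_truth(mv$truth, dir)
  back <- read_ground_truth(dir)
  expect_identical(back$masks, mv$truth$masks)
  expect_equal(as.data.frame(back$cells), as.data.frame(mv$truth$cells))
  expect_equal(as.data.frame(back$lineage),
               as.data.frame(mv$truth$lineage))
  # two lineage rows per mitosis
  expect_equal(nrow(back$lineage) %% 2, 0)
})

test_that("Otsu detection recovers nearly all true regions on a clean movie", {
  det <- clean_bundle()$det
  expect_gte(sum(det$tp) / (sum(det$tp) + sum(det$fn)), 0.99)
})

test_that("degenerate configurations are rejected", {
  expect_error(simulate_movie(simulation_config(n_frames = 0)),
               "configuration error")
  expect_error(simulate_movie(simulation_config(n_initial = 0)),
               "configuration error")
})
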