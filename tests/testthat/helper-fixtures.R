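# Shared fixtures, memoised so expensive simulations run once per suite.
# Large raster stacks are reduced to compact derived objects inside the
# builders, so peak memory stays bounded to one pipeline at a time.
fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, build) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, build(), envir = fixture_env)
    gc(verbose = FALSE)
  }
  get(name, envir = fixture_env)
}

# calibration movie: clean culture with plenty of divisions
cal_movie <- function() get_fixture("cal_movie", function() {
  simulate_movie(simulation_config(width = 400, height = 400,
                                   n_frames = 50, n_initial = 12,
                                   life_mean = 240, life_sd = 60,
                                   seed = 42))
})

mitosis_model <- function() get_fixture("mitosis_model", function() {
  fit_mitosis_model(cal_movie())
})

# clean moderate-density movie, reduced to the derived tables the tests
# need (per-frame detection scores, one preprocessed frame, a few truth
# frames for feature checks)
clean_bundle <- function() get_fixture("clean_bundle", function() {
  movie <- simulate_movie(simulation_config(width = 640, height = 640,
                                            n_frames = 40, n_initial = 40,
                                            life_mean = 360, life_sd = 90,
                                            seed = 5))
  tracks <- track_movie(movie$frames, run_config())
  det <- evaluate_detection(tracks$masks,
                            relabel_masks_consecutive(movie$truth$masks))
  list(det = det,
       pre10 = tracks$frames[[10]],
       truth5 = relabel_masks_consecutive(movie$truth$masks[1:5]),
       frames5 = movie$frames[1:5])
})

# small dividing culture used across tracking/validation tests
div_movie <- function() get_fixture("div_movie", function() {
  simulate_movie(simulation_config(width = 400, height = 400,
                                   n_frames = 50, n_initial = 12,
                                   life_mean = 240, life_sd = 60,
                                   seed = 9))
})

div_tracks <- function() get_fixture("div_tracks", function() {
  track_movie(div_movie()$frames, run_config())
})

div_result <- function() get_fixture("div_result", function() {
  validate_tracks(div_tracks(), mitosis_model())
})

# merge-only fixture: no divisions, one steered optical merge
merge_movie <- function() get_fixture("merge_movie", function() {
  simulate_movie(simulation_config(width = 300, height = 300,
                                   n_frames = 25, n_initial = 5,
                                   life_mean = 1e7, life_sd = 10,
                                   merge_events = 1, merge_duration = 4,
                                   seed = 21))
})

merge_tracks <- function() get_fixture("merge_tracks", function() {
  track_movie(merge_movie()$frames, run_config())
})

# dropout fixture: one cell fades below the global threshold for 3 frames
dropout_movie <- function() get_fixture("dropout_movie", function() {
  simulate_movie(simulation_config(width = 300, height = 300,
                                   n_frames = 25, n_initial = 5,
                                   life_mean = 1e7, life_sd = 10,
                                   dropout_events = 1,
                                   dropout_duration = 3,
                                   dropout_contrast = 0.35,
                                   seed = 13))
})

# error-injected benchmark (all four error scenarios), reduced to the
# validated result, naive comparison and truth correspondence tables
err_bundle <- function() get_fixture("err_bundle", function() {
  movie <- simulate_movie(simulation_config(width = 768, height = 614,
                                            n_frames = 150,
                                            n_initial = 50,
                                            life_mean = 720,
                                            life_sd = 180,
                                            merge_events = 6,
                                            dropout_events = 6,
                                            debris_count = 4,
                                            border_entry_rate = 0.03,
                                            seed = 17))
  tracks <- track_movie(movie$frames, run_config())
  result <- validate_tracks(tracks, mitosis_model())
  naive <- naive_track(tracks$masks)
  corr <- frame_correspondence(tracks$masks, movie$truth)
  list(events = movie$truth$events,
       reg = movie$truth$cells,
       result = result,
       fragments = tracks$fragments,
       adjacency = tracks$adjacency,
       corr = corr,
       cc_val = classification_counts(result, movie$truth, tracks$masks),
       cc_naive = classification_counts(naive, movie$truth,
                                        tracks$masks))
})

# unbiased high-yield movie for distribution-level checks, reduced to
# the registry and the accepted output
nobias_bundle <- function() get_fixture("nobias_bundle", function() {
  movie <- simulate_movie(simulation_config(width = 1280, height = 1280,
                                            n_frames = 90, n_initial = 36,
                                            radius_mean = 9,
                                            radius_sd = 1.8,
                                            life_mean = 240, life_sd = 60,
                                            seed = 33))
  tracks <- track_movie(movie$frames, run_config())
  result <- validate_tracks(tracks, mitosis_model())
  list(reg = movie$truth$cells,
       accepted = result$accepted,
       forest = result$forest)
})

# rasterize a filled disk, centred, on an otherwise empty frame
raster_disk <- function(radius, pad = 10, value = 1L) {
  n <- 2L * radius + 2L * pad + 1L
  ctr <- radius + pad + 1L
  xs <- rep(seq_len(n), each = n)
  ys <- rep(seq_len(n), times = n)
  m <- matrix(0L, n, n)
  m[cbind(ys, xs)[(xs - ctr)^2 + (ys - ctr)^2 <= radius^2, ]] <- value
  m
}

# exhaustive-search Otsu oracle: argmax of between-class variance over
# all 255 cut points
brute_otsu <- function(img) {
  g <- as.integer(img)
  best <- -Inf; bt <- NA_real_
  for (t in 0:254) {
    a <- g[g <= t]; b <- g[g > t]
    if (!length(a) || !length(b)) next
    w0 <- length(a) / length(g)
    v <- w0 * (1 - w0) * (mean(a) - mean(b))^2
    if (v > best) { best <- v; bt <- t }
  }
  bt
}

# brute-force degree of relation: count mitosis nodes on the shortest
# path in a bipartite cell/mitosis graph
brute_degree <- function(lineage, a, b) {
  if (!nrow(lineage)) return(0L)
  mito <- lineage |>
    dplyr::group_by(parent, frame) |>
    dplyr::mutate(mid = paste0("m", dplyr::cur_group_id())) |>
    dplyr::ungroup()
  edges <- c(rbind(paste0("c", mito$parent), mito$mid),
             rbind(mito$mid, paste0("c", mito$daughter)))
  g <- igraph::make_graph(edges, directed = FALSE)
  va <- paste0("c", a); vb <- paste0("c", b)
  if (!(va %in% igraph::V(g)$name) || !(vb %in% igraph::V(g)$name))
    return(0L)
  sp <- suppressWarnings(igraph::shortest_paths(g, va, vb)$vpath[[1]])
  if (!length(sp)) return(0L)
  sum(grepl("^m", names(sp)))
}

# per-frame correspondence between detected labels and true ids
frame_correspondence <- function(masks, truth) {
  trackvalidatr:::truth_correspondence(masks, truth$masks, 0.3)
}
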