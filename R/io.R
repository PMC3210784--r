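#' Read an ordered image stack
#'
#' Reads a directory of PNG/TIFF frames (natural filename order) or a
#' multi-page TIFF into a list of grey-value matrices. 16-bit input is
#' kept at its native scale; colour images are converted to grey by
#' averaging channels.
#'
#' @param path Directory containing frames, a glob pattern, or a
#'   multi-page TIFF file.
#' @param pattern Filename regex used when `path` is a directory.
#' @return List of numeric matrices (grey values), ordered by frame.
#' @export
read_image_stack <- function(path, pattern = "\\.(png|tif|tiff)$") {
  to_grey <- function(a) {
    if (length(dim(a)) == 3L) a <- apply(a[, , seq_len(min(3, dim(a)[3])),
                                           drop = FALSE], c(1, 2), mean)
    round(a * 255 * ifelse(max(a) <= 1, 1, 0))  # png/tiff read as [0,1]
  }
  read_one <- function(f) {
    if (grepl("\\.png$", f, ignore.case = TRUE)) {
      a <- png::readPNG(f)
      if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]),
                                             drop = FALSE], c(1, 2), mean)
      matrix(as.integer(round(a * 255)), nrow(a), ncol(a))
    } else {
      a <- tiff::readTIFF(f, all = TRUE)
      lapply(a, function(x) {
        if (length(dim(x)) == 3L) x <- apply(x[, , 1:min(3, dim(x)[3]),
                                               drop = FALSE], c(1, 2), mean)
        matrix(as.integer(round(x * 65535)), nrow(x), ncol(x))
      })
    }
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = pattern, full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("input error: no frames match in ", path)
    frames <- lapply(files, function(f) {
      r <- read_one(f)
      if (is.list(r)) r[[1]] else r
    })
  } else if (file.exists(path)) {
    r <- read_one(path)
    frames <- if (is.list(r)) r else list(r)
  } else stop("input error: ", path, " not found")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("format error: frames have mixed dimensions")
  frames
}

#' Write frames or label masks to disk
#'
#' Grey frames go out as 8-bit PNG; label masks as 16-bit single
#' channel TIFF (0 = background, k = label), allowing more than 255
#' cells per frame.
#'
#' @param frames List of matrices.
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @param labels Write 16-bit label TIFFs instead of 8-bit PNGs.
#' @return Vector of written paths, invisibly.
#' @export
write_frames <- function(frames, dir, prefix = "frame", labels = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(seq_along(frames), function(t) {
    if (labels) {
      f <- file.path(dir, sprintf("%s_%04d.tif", prefix, t))
      tiff::writeTIFF(frames[[t]] / 65535, f, bits.per.sample = 16L,
                      compression = "none")
    } else {
      f <- file.path(dir, sprintf("%s_%04d.png", prefix, t))
      png::writePNG(frames[[t]] / 255, f)
    }
    f
  }, character(1))
  invisible(paths)
}

#' Read label masks written by [write_frames()]
#'
#' @param dir Directory of 16-bit label TIFFs.
#' @param prefix Filename prefix used when writing.
#' @return List of integer label matrices.
#' @export
read_masks <- function(dir, prefix = "mask") {
  files <- sort(list.files(dir, pattern = paste0("^", prefix,
                                                 "_\\d+\\.tif$"),
                           full.names = TRUE))
  if (!length(files)) stop("input error: no masks in ", dir)
  lapply(files, function(f) {
    a <- tiff::readTIFF(f)
    matrix(as.integer(round(a * 65535)), nrow(a), ncol(a))
  })
}

#' Export ground truth to plain files
#'
#' True masks go out as 16-bit label TIFFs (one per frame, pixel value
#' = true cell id), the cell registry, lineage edges and event log as
#' CSV tables. The export round-trips losslessly through
#' [read_ground_truth()].
#'
#' @param truth A `ground_truth`.
#' @param dir Destination directory.
#' @return `dir`, invisibly.
#' @export
export_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_frames(truth$masks, dir, prefix = "truth", labels = TRUE)
  write.csv(truth$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(truth$lineage, file.path(dir, "lineage.csv"), row.names = FALSE)
  write.csv(truth$events, file.path(dir, "events.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname export_ground_truth
#' @export
read_ground_truth <- function(dir) {
  masks <- read_masks(dir, prefix = "truth")
  cells <- as_tibble(read.csv(file.path(dir, "cells.csv")))
  cells$fate <- as.character(cells$fate)
  lineage <- as_tibble(read.csv(file.path(dir, "lineage.csv")))
  events <- as_tibble(read.csv(file.path(dir, "events.csv"),
                               colClasses = c(ids = "character")))
  structure(list(masks = masks, cells = cells, lineage = lineage,
                 events = events), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", length(x$masks), "frames,", nrow(x$cells),
      "cells,", nrow(x$lineage) / 2, "mitoses,", nrow(x$events),
      "logged events\n")
  invisible(x)
}

#' @export
print.cell_movie <- function(x, ...) {
  cat("Synthetic movie:", length(x$frames), "frames of",
      x$config$width, "x", x$config$height, "px\n")
  print(x$truth)
  invisible(x)
}

#' Run configuration
#'
#' Bundles all stage parameters of the tracking pipeline. Unknown keys
#' are rejected so configuration typos fail loudly.
#'
#' @param ... Named parameters overriding the defaults (see
#'   [default_run_config()] for the full list).
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- default_run_config()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown configuration keys: ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  with(cfg, stopifnot(t_fw >= 0, t_fw <= 1, t_bw >= 0, t_bw <= 1,
                      overlap_floor >= 0, overlap_floor <= 1,
                      frame_interval > 0, pixel_size > 0))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @export
default_run_config <- function() {
  list(frame_interval = 15, pixel_size = 1.6, sigma = 25,
       erosion_radius = 1, dilation_radius = 1, min_area = 50,
       t_fw = 0.3, t_bw = 0.3, t_amb = 0.1, border_margin = 30, t_mit = NA_real_,
       overlap_floor = 0.3, debris_max_span = 2, debris_min_speed = 10,
       recover = TRUE, rectify_merges = FALSE, seed = 1L)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg A `run_config`.
#' @return `read_run_config` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Track a movie end to end
#'
#' Convenience wrapper chaining preprocessing, detection, and fragment
#' construction with one parameter set; the returned `track_result`
#' keeps the preprocessed frames so validation can run local recovery.
#'
#' @param frames List of raw grey frames.
#' @param cfg A [run_config()].
#' @return A `track_result`.
#' @export
track_movie <- function(frames, cfg = run_config()) {
  pre <- lapply(frames, preprocess_frame, sigma = cfg$sigma)
  masks <- detect_stack(pre, erosion_radius = cfg$erosion_radius,
                        dilation_radius = cfg$dilation_radius,
                        min_area = cfg$min_area, preprocess = FALSE)
  build_path_fragments(masks, pre, t_fw = cfg$t_fw, t_bw = cfg$t_bw,
                       t_amb = cfg$t_amb)
}

#' Write the artifacts of a full tracking run
#'
#' Emits fragments, adjacency, accepted paths, lineage, rejection
#' report and statistics as CSV plus a JSON manifest with config hash
#' and seed; masks as 16-bit label TIFFs.
#'
#' @param result A `lineage_result`.
#' @param tracks The underlying `track_result` (for fragments and
#'   masks).
#' @param dir Destination directory.
#' @param cfg The `run_config` used.
#' @param write_masks Also write per-frame mask TIFFs.
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, tracks, dir, cfg = run_config(),
                          write_masks = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(tracks$fragments, file.path(dir, "fragments.csv"),
            row.names = FALSE)
  write.csv(tracks$adjacency, file.path(dir, "adjacency.csv"),
            row.names = FALSE)
  write.csv(result$accepted, file.path(dir, "accepted_paths.csv"),
            row.names = FALSE)
  write.csv(result$rejected, file.path(dir, "rejected.csv"),
            row.names = FALSE)
  write.csv(result$mitoses, file.path(dir, "mitoses.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(forest = result$forest, accepted = result$accepted),
    file.path(dir, "lineage.json"))
  manifest <- list(package = "trackvalidatr",
                   version = as.character(utils::packageVersion("trackvalidatr")),
                   config = unclass(cfg),
                   config_hash = config_hash(cfg),
                   seed = cfg$seed,
                   n_frames = result$n_frames,
                   n_accepted = nrow(result$accepted))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (write_masks) write_frames(tracks$masks, dir, "mask", labels = TRUE)
  invisible(dir)
}

config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  # small stable polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
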