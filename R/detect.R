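#' High-pass illumination correction and 8-bit normalization
#'
#' Removes slowly varying illumination by subtracting a Gaussian-blurred
#' copy of the image from the raw image (a high-pass filter), then
#' linearly rescales the grey values to the full 8-bit range.
#'
#' @param img Numeric matrix of grey values, rows are image y, columns x.
#' @param sigma Standard deviation of the Gaussian blur in pixels. Should
#'   be large compared to the cell diameter so that cell bodies survive
#'   the high-pass while the illumination gradient is removed.
#' @return Integer matrix with values in `[0, 255]`. A constant input
#'   (no structure at all) maps to an all-zero frame.
#' @export
preprocess_frame <- function(img, sigma = 25) {
  stopifnot(is.matrix(img), sigma > 0)
  storage.mode(img) <- "double"
  # gblur's kernel must fit inside the image
  max_sigma <- floor((min(dim(img)) - 1) / 8)
  sigma <- min(sigma, max_sigma)
  if (sigma <= 0) {
    bg <- matrix(mean(img), nrow(img), ncol(img))
  } else {
    bg <- EBImage::gblur(img, sigma = sigma)
  }
  hp <- img - bg
  rng <- range(hp)
  if (diff(rng) == 0) {
    out <- matrix(0L, nrow(img), ncol(img))
  } else {
    out <- matrix(as.integer(round((hp - rng[1]) / diff(rng) * 255)),
                  nrow(img), ncol(img))
  }
  out
}

#' Otsu global threshold
#'
#' Finds the grey value that maximizes the between-class variance of the
#' image histogram. Pixels strictly brighter than the returned threshold
#' are foreground.
#'
#' @param img Integer matrix of grey values in `[0, 255]`.
#' @return The threshold grey value, or `NA` if the histogram has a
#'   single occupied bin (no threshold exists).
#' @export
otsu_threshold <- function(img) {
  g <- as.integer(img)
  stopifnot(all(g >= 0L), all(g <= 255L))
  h <- tabulate(g + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L) return(NA_real_)
  p <- h / sum(h)
  levels <- 0:255
  w0 <- cumsum(p)                      # P(class 0) for cut at t
  mu_t <- cumsum(p * levels)
  mu_total <- mu_t[256]
  w1 <- 1 - w0
  # between-class variance for every cut t in 0..254
  num <- (mu_total * w0 - mu_t)^2
  den <- w0 * w1
  sigma_b <- ifelse(den > 0, num / den, -Inf)[1:255]
  t_star <- which.max(sigma_b) - 1L    # first argmax: lowest threshold
  as.numeric(t_star)
}

#' Detect cells in a preprocessed frame
#'
#' Thresholds the frame (pixels strictly brighter than `threshold` are
#' foreground), separates tiny false connections by erosion, fills holes
#' by dilation, removes components smaller than `min_area`, and labels
#' the remaining 8-connected regions 1..n in raster-scan order of their
#' first pixel.
#'
#' @param img Integer matrix of 8-bit grey values.
#' @param threshold Foreground threshold; defaults to [otsu_threshold()].
#' @param erosion_radius,dilation_radius Radii (pixels) of the disc
#'   structuring elements; 0 skips the step.
#' @param min_area Minimum region area in pixels; smaller regions are
#'   removed.
#' @return Integer label matrix (a cell mask): 0 background, 1..n cells.
#' @export
detect_cells <- function(img, threshold = NULL, erosion_radius = 1,
                         dilation_radius = 1, min_area = 50) {
  stopifnot(is.matrix(img))
  if (is.null(threshold)) threshold <- otsu_threshold(img)
  if (is.na(threshold)) return(matrix(0L, nrow(img), ncol(img)))
  fg <- img > threshold
  if (erosion_radius > 0 && any(fg)) {
    fg <- EBImage::erode(fg * 1, EBImage::makeBrush(2L * erosion_radius + 1L,
                                                    "disc")) > 0
  }
  if (dilation_radius > 0 && any(fg)) {
    fg <- EBImage::dilate(fg * 1, EBImage::makeBrush(2L * dilation_radius + 1L,
                                                     "disc")) > 0
  }
  lab <- label_components(fg)
  if (max(lab) > 0L && min_area > 0) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_area)
    lab[!(lab %in% keep)] <- 0L
    lab <- relabel_raster_order(lab)
  }
  lab
}

#' Label 8-connected foreground components
#'
#' Row-run based connected-component labelling with 8-connectivity,
#' the project-wide convention for bright blobs. Labels are assigned
#' 1..n in raster-scan order (top row first, left to right) of each
#' component's first pixel.
#'
#' @param fg Logical matrix, `TRUE` = foreground.
#' @return Integer label matrix.
#' @export
label_components <- function(fg) {
  stopifnot(is.matrix(fg))
  nr <- nrow(fg); nc <- ncol(fg)
  if (!any(fg)) return(matrix(0L, nr, nc))
  # run-length encode each row (pad with FALSE so diff finds all edges)
  v <- as.vector(t(cbind(FALSE, fg, FALSE)))
  d <- diff(c(FALSE, v))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  width <- nc + 2L
  row_of <- (starts - 1L) %/% width + 1L
  c_start <- (starts - 1L) %% width      # 1-based column after removing pad
  c_end <- (ends - 1L) %% width
  n_runs <- length(starts)
  # connect runs in adjacent rows whose column spans overlap (8-conn: +/-1)
  edges <- integer(0)
  runs_by_row <- split(seq_len(n_runs), row_of)
  row_keys <- as.integer(names(runs_by_row))
  for (k in seq_along(row_keys)[-1]) {
    if (row_keys[k] - row_keys[k - 1] != 1L) next
    a <- runs_by_row[[k - 1]]; b <- runs_by_row[[k]]
    for (i in a) {
      hit <- b[c_start[b] <= c_end[i] + 1L & c_end[b] >= c_start[i] - 1L]
      if (length(hit)) edges <- c(edges, rbind(i, hit))
    }
  }
  g <- igraph::make_graph(edges = edges, n = n_runs, directed = FALSE)
  comp <- as.integer(igraph::components(g)$membership)
  lab <- matrix(0L, nr, nc)
  for (i in seq_len(n_runs)) {
    lab[row_of[i], c_start[i]:c_end[i]] <- comp[i]
  }
  relabel_raster_order(lab)
}

# Renumber labels 1..n by raster-scan order (row-major) of first pixel.
relabel_raster_order <- function(lab) {
  labs <- lab[lab > 0L]
  if (!length(labs)) return(lab)
  tl <- t(lab)                       # row-major order = column order of t()
  firsts <- tl[tl > 0L]
  order_first <- unique(firsts)
  map <- integer(max(lab))
  map[order_first] <- seq_along(order_first)
  lab[lab > 0L] <- map[labs]
  lab
}

#' Run detection on a whole frame stack
#'
#' Applies [preprocess_frame()] and [detect_cells()] to every frame with
#' a per-frame Otsu threshold.
#'
#' @param frames List of raw grey-value matrices.
#' @param sigma High-pass Gaussian sigma (pixels).
#' @inheritParams detect_cells
#' @param preprocess If `FALSE`, frames are assumed already 8-bit and
#'   illumination-corrected.
#' @return List of label matrices, one cell mask per frame.
#' @export
detect_stack <- function(frames, sigma = 25, erosion_radius = 1,
                         dilation_radius = 1, min_area = 50,
                         preprocess = TRUE) {
  lapply(frames, function(f) {
    if (preprocess) f <- preprocess_frame(f, sigma = sigma)
    detect_cells(f, erosion_radius = erosion_radius,
                 dilation_radius = dilation_radius, min_area = min_area)
  })
}
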