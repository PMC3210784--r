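#' Configuration for the synthetic time-lapse simulator
#'
#' Defaults emulate the reference culture the tracker was built for:
#' adherent bright-on-dark pancreatic stem cells imaged at 1376 x 1038
#' pixels (1.6 um/px) every 15 minutes, mean cell cycle around 12 hours.
#' Error phenomena (optical merging, detection dropouts, border
#' crossings, drifting debris) are off by default and switched on by
#' count, so that test movies contain a known number of each scenario.
#'
#' @param width,height Image size in pixels.
#' @param n_frames Number of frames.
#' @param frame_interval Minutes between frames.
#' @param pixel_size Micrometres per pixel.
#' @param n_initial Number of cells at frame 1.
#' @param radius_mean,radius_sd Cell effective radius distribution (px);
#'   cells are ellipses with area pi * r^2 and mild aspect ratio.
#' @param step_sd Brownian motion step standard deviation (px/frame).
#' @param drift Deterministic drift (px/frame), length-2 vector (x, y).
#' @param life_mean,life_sd Cell life time distribution in minutes
#'   (truncated normal, floor two frames).
#' @param division_prob Probability that a cell divides at the end of
#'   its life (otherwise it simply persists).
#' @param mitosis_frames Number of frames over which the pre-mitotic
#'   pattern (shrinking, rounding, brightening) develops.
#' @param mitosis_area_drop Fractional area decrease at the mitosis
#'   frame.
#' @param mitosis_brightness_rise Fractional brightness increase at the
#'   mitosis frame.
#' @param background,cell_intensity Background and cell-body grey
#'   levels (8-bit scale).
#' @param noise_sd Additive Gaussian pixel noise (grey levels).
#' @param gradient_amplitude Amplitude of a linear illumination ramp
#'   (grey levels); removed by preprocessing.
#' @param merge_events Number of optical-merge events to inject (two
#'   cells steered into contact, held, then separated).
#' @param merge_duration Frames a merge interval lasts.
#' @param dropout_events Number of dropout events (a cell's contrast
#'   drops below global detectability for some frames).
#' @param dropout_duration Frames a dropout lasts.
#' @param dropout_contrast Fraction of the cell-background contrast
#'   retained during dropout (0 renders the cell invisible; around 0.35
#'   keeps it recoverable by a local threshold).
#' @param debris_count Number of fast, linearly drifting debris
#'   particles.
#' @param debris_speed Debris speed (px/frame).
#' @param debris_radius Debris radius (px).
#' @param border_entry_rate Expected number of new cells entering
#'   through the image border per frame.
#' @param seed Integer random seed; identical config + seed gives
#'   bit-identical movies.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(width = 1376, height = 1038, n_frames = 209,
                              frame_interval = 15, pixel_size = 1.6,
                              n_initial = 282,
                              radius_mean = 12, radius_sd = 2.5,
                              step_sd = 1.5, drift = c(0, 0),
                              life_mean = 720, life_sd = 180,
                              division_prob = 1,
                              mitosis_frames = 2,
                              mitosis_area_drop = 0.25,
                              mitosis_brightness_rise = 0.3,
                              background = 40, cell_intensity = 120,
                              noise_sd = 5, gradient_amplitude = 10,
                              merge_events = 0, merge_duration = 4,
                              dropout_events = 0, dropout_duration = 3,
                              dropout_contrast = 0.35,
                              debris_count = 0, debris_speed = 30,
                              debris_radius = 5,
                              border_entry_rate = 0,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$width > 0, cfg$height > 0, cfg$frame_interval > 0,
            cfg$radius_mean > 0, cfg$radius_sd > 0, cfg$life_sd > 0,
            cfg$n_initial >= 0, cfg$n_frames >= 0,
            cfg$merge_events >= 0, cfg$dropout_events >= 0,
            cfg$debris_count >= 0, length(cfg$drift) == 2)
  structure(cfg, class = "simulation_config")
}

# life time in frames: truncated normal with a two-frame floor
draw_life_frames <- function(n, cfg) {
  lf <- round(rnorm(n, cfg$life_mean, cfg$life_sd) / cfg$frame_interval)
  pmax(2L, as.integer(lf))
}

new_cells <- function(n, ids, x, y, birth, cfg, parent = rep(NA_integer_, n),
                      area_factor = rep(1, n)) {
  r <- pmax(3, rnorm(n, cfg$radius_mean, cfg$radius_sd))
  aspect <- runif(n, 1.1, 1.6)
  divides <- runif(n) < cfg$division_prob
  data.frame(
    id = ids, x = x, y = y,
    r = r, aspect = aspect, angle = runif(n, 0, pi),
    intensity = pmin(240, pmax(cfg$background + 20,
                               rnorm(n, cfg$cell_intensity, 5))),
    birth = birth, life = ifelse(divides, draw_life_frames(n, cfg), .Machine$integer.max),
    parent = parent,
    area_factor = area_factor,     # < 1 right after birth, grows to 1
    dropout_until = 0L, merge_until = 0L, merge_partner = NA_integer_
  )
}

#' Simulate a synthetic time-lapse movie with ground truth
#'
#' Runs the cell-culture world model frame by frame and renders every
#' frame, returning the grey image stack together with pixel-exact
#' ground truth (per-frame label masks, cell registry, lineage edges
#' and an event log of injected error scenarios).
#'
#' @param config A [simulation_config()].
#' @return An object of class `cell_movie`: a list with `frames` (list
#'   of integer grey matrices), `truth` (class `ground_truth`: `masks`,
#'   `cells`, `lineage`, `events`) and `config`.
#' @export
simulate_movie <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  if (cfg$n_frames < 1) stop("configuration error: need at least one frame")
  if (cfg$n_initial < 1) stop("configuration error: need at least one cell")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  # --- initial placement: rejection-sampled, non-overlapping
  margin <- cfg$radius_mean * 2
  xs <- ys <- numeric(0)
  tries <- 0
  while (length(xs) < cfg$n_initial && tries < cfg$n_initial * 400) {
    tries <- tries + 1
    px <- runif(1, margin, cfg$width - margin)
    py <- runif(1, margin, cfg$height - margin)
    if (!length(xs) || min(sqrt((xs - px)^2 + (ys - py)^2)) >
        2.2 * cfg$radius_mean + 4) {
      xs <- c(xs, px); ys <- c(ys, py)
    }
  }
  n0 <- length(xs)
  cells <- new_cells(n0, seq_len(n0), xs, ys, 1L, cfg)
  next_id <- n0 + 1L

  registry <- data.frame(id = cells$id, parent = NA_integer_,
                         birth_frame = 1L, death_frame = NA_integer_,
                         fate = NA_character_)
  lineage <- data.frame(parent = integer(), daughter = integer(),
                        frame = integer())
  events <- data.frame(type = character(), start_frame = integer(),
                       end_frame = integer(), ids = character())

  # --- schedule injected error scenarios
  sched_merge <- if (cfg$merge_events > 0)
    sort(sample(seq(3, max(3, cfg$n_frames - cfg$merge_duration - 4)),
                cfg$merge_events, replace = TRUE)) else integer(0)
  sched_drop <- if (cfg$dropout_events > 0)
    sort(sample(seq(3, max(3, cfg$n_frames - cfg$dropout_duration - 2)),
                cfg$dropout_events, replace = TRUE)) else integer(0)
  debris <- if (cfg$debris_count > 0) {
    entry <- sample(seq_len(max(1, cfg$n_frames - 2)), cfg$debris_count,
                    replace = TRUE)
    side <- sample(1:4, cfg$debris_count, replace = TRUE)
    th <- runif(cfg$debris_count, -pi / 3, pi / 3)
    data.frame(entry = entry, side = side, theta = th,
               pos = runif(cfg$debris_count))
  } else NULL

  frames <- vector("list", cfg$n_frames)
  masks <- vector("list", cfg$n_frames)

  for (t in seq_len(cfg$n_frames)) {
    if (t > 1 && nrow(cells)) {
      age <- t - cells$birth
      # --- divisions happening at this frame boundary
      dividing <- which(age - 1L >= cells$life & cells$dropout_until < t &
                          is.na(cells$merge_partner))
      if (length(dividing)) {
        for (i in dividing) {
          p <- cells[i, ]
          registry$death_frame[registry$id == p$id] <- t - 1L
          registry$fate[registry$id == p$id] <- "division"
          u <- runif(1, 0, 2 * pi)
          rd <- pmax(3, p$r * rnorm(2, 1, 0.06))
          # daughters appear side by side inside the parent's former
          # footprint: round, small, separated by a narrow cleavage gap
          # (minor axis along the division axis) so each keeps a solid
          # overlap with the parent's last mask
          asp_d <- runif(2, 1.05, 1.15)
          off <- rd * sqrt(0.55) / sqrt(asp_d) + 1.8
          d <- new_cells(2, next_id + 0:1,
                         p$x + cos(u) * off * c(1, -1),
                         p$y + sin(u) * off * c(1, -1),
                         t, cfg, parent = rep(p$id, 2),
                         area_factor = c(0.55, 0.55))
          d$r <- rd
          d$aspect <- asp_d
          d$angle <- rep(u + pi / 2, 2)
          cells <- rbind(cells, d)
          lineage <- rbind(lineage,
                           data.frame(parent = p$id, daughter = d$id,
                                      frame = t - 1L))
          registry <- rbind(registry,
                            data.frame(id = d$id, parent = p$id,
                                       birth_frame = t, death_frame = NA_integer_,
                                       fate = NA_character_))
          next_id <- next_id + 2L
        }
        cells <- cells[-dividing, , drop = FALSE]
      }
      if (nrow(cells)) {
        # --- motion: Brownian + drift; merge dynamics override.
        # A scheduled merge has two phases: the pair first migrates
        # towards each other at a bounded speed (so mask overlap stays
        # contiguous), then holds in optical contact for the configured
        # duration; the event is logged when contact is reached.
        nn <- nrow(cells)
        steer <- !is.na(cells$merge_partner)
        newborn <- cells$birth == t      # keep the cleavage gap intact
        dx <- rnorm(nn, 0, cfg$step_sd) + cfg$drift[1]
        dy <- rnorm(nn, 0, cfg$step_sd) + cfg$drift[2]
        cells$x <- cells$x + ifelse(steer | newborn, 0, dx)
        cells$y <- cells$y + ifelse(steer | newborn, 0, dy)
        approaching <- which(steer & cells$merge_until < 0L)
        for (i in approaching) {
          jj <- match(cells$merge_partner[i], cells$id)
          if (is.na(jj)) {   # partner gone (divided or left)
            cells$merge_partner[i] <- NA_integer_
            cells$merge_until[i] <- 0L
            next
          }
          vx <- cells$x[jj] - cells$x[i]; vy <- cells$y[jj] - cells$y[i]
          dd <- sqrt(vx^2 + vy^2)
          target <- 0.45 * (cells$r[i] + cells$r[jj])
          if (dd > target) {
            # bounded by the cell's own size so its mask overlap chain
            # stays above the linking thresholds while it migrates
            stepv <- min(0.4 * cells$r[i] * sqrt(cells$area_factor[i]),
                         (dd - target) / 2)
            cells$x[i] <- cells$x[i] + vx / dd * stepv
            cells$y[i] <- cells$y[i] + vy / dd * stepv
          }
        }
        for (i in which(steer & cells$merge_until < 0L)) {
          jj <- match(cells$merge_partner[i], cells$id)
          if (is.na(jj) || jj < i) next
          dd <- sqrt((cells$x[jj] - cells$x[i])^2 +
                       (cells$y[jj] - cells$y[i])^2)
          if (dd <= 0.45 * (cells$r[i] + cells$r[jj]) + 0.5) {
            cells$merge_until[c(i, jj)] <- t + cfg$merge_duration - 1L
            events <- rbind(events,
                            data.frame(type = "merge", start_frame = t,
                                       end_frame = t + cfg$merge_duration - 1L,
                                       ids = paste(cells$id[c(i, jj)],
                                                   collapse = ";")))
          }
        }
        # --- shape jitter and regrowth (newborns keep their initial
        # geometry on the birth frame so the cleavage gap survives)
        jit_r <- exp(rnorm(nn, 0, 0.01)); jit_a <- rnorm(nn, 0, 0.05)
        cells$r <- cells$r * ifelse(newborn, 1, jit_r)
        cells$angle <- cells$angle + ifelse(newborn, 0, jit_a)
        cells$area_factor <- pmin(1, cells$area_factor +
                                    ifelse(newborn, 0, 0.09))
        # --- soft repulsion keeps non-merging cells separated
        # (adherent cells are contact inhibited; iterated sweeps resolve
        # chains of contacts created by Brownian motion and divisions)
        if (nn > 1) {
          pair_merge <- matrix(FALSE, nn, nn)
          mp <- match(cells$merge_partner, cells$id)
          act <- which(!is.na(mp))
          if (length(act)) pair_merge[cbind(act, mp[act])] <- TRUE
          # sibling pairs are exempt on their birth frame only: the
          # cleavage gap must survive rendering once, afterwards the
          # normal contact repulsion separates them
          young <- newborn & !is.na(cells$parent)
          sib <- outer(cells$parent, cells$parent, "==") &
            outer(young, young, "&")
          sib[is.na(sib)] <- FALSE
          pair_merge <- pair_merge | sib
          for (sweep in 1:6) {
            dmat <- as.matrix(stats::dist(cbind(cells$x, cells$y)))
            rsum <- outer(cells$r, cells$r, "+")
            too_close <- which(dmat < rsum * 1.15 + 2 & upper.tri(dmat) &
                                 !pair_merge, arr.ind = TRUE)
            if (!nrow(too_close)) break
            for (k in seq_len(nrow(too_close))) {
              i <- too_close[k, 1]; j <- too_close[k, 2]
              vx <- cells$x[j] - cells$x[i]; vy <- cells$y[j] - cells$y[i]
              dd <- sqrt(vx^2 + vy^2)
              if (dd < 1e-6) { vx <- 1; vy <- 0; dd <- 1 }
              need <- (cells$r[i] + cells$r[j]) * 1.15 + 2 - dd
              push <- min(need, 6)
              # newborns stay put (their cleavage geometry is fragile);
              # the other cell absorbs the whole displacement
              wi <- if (newborn[i] && !newborn[j]) 0 else
                if (!newborn[i] && newborn[j]) 1 else 0.5
              cells$x[i] <- cells$x[i] - vx / dd * push * wi
              cells$y[i] <- cells$y[i] - vy / dd * push * wi
              cells$x[j] <- cells$x[j] + vx / dd * push * (1 - wi)
              cells$y[j] <- cells$y[j] + vy / dd * push * (1 - wi)
            }
          }
        }
        # --- border exits: cell body fully outside -> removed
        gone <- which(cells$x < -cells$r | cells$x > cfg$width + cells$r |
                        cells$y < -cells$r | cells$y > cfg$height + cells$r)
        if (length(gone)) {
          for (i in gone) {
            registry$death_frame[registry$id == cells$id[i]] <- t - 1L
            registry$fate[registry$id == cells$id[i]] <- "border_exit"
            events <- rbind(events,
                            data.frame(type = "border_exit", start_frame = t - 1L,
                                       end_frame = t - 1L,
                                       ids = as.character(cells$id[i])))
          }
          cells <- cells[-gone, , drop = FALSE]
        }
      }
      # --- border entries
      if (cfg$border_entry_rate > 0) {
        k <- stats::rpois(1, cfg$border_entry_rate)
        if (k > 0) {
          side <- sample(1:4, k, replace = TRUE)
          pos <- runif(k)
          r0 <- cfg$radius_mean
          ex <- ifelse(side == 1, r0 * 0.7,
                       ifelse(side == 2, cfg$width - r0 * 0.7,
                              pos * cfg$width))
          ey <- ifelse(side <= 2, pos * cfg$height,
                       ifelse(side == 3, r0 * 0.7, cfg$height - r0 * 0.7))
          nc <- new_cells(k, next_id + seq_len(k) - 1L, ex, ey, t, cfg)
          cells <- rbind(cells, nc)
          registry <- rbind(registry,
                            data.frame(id = nc$id, parent = NA_integer_,
                                       birth_frame = t, death_frame = NA_integer_,
                                       fate = NA_character_))
          events <- rbind(events,
                          data.frame(type = "border_entry", start_frame = t,
                                     end_frame = t,
                                     ids = paste(nc$id, collapse = ";")))
          next_id <- next_id + k
        }
      }
    }

    # --- start scheduled merge events: pick the closest free pair
    # with enough remaining life to approach, merge and separate
    for (m in which(sched_merge == t)) {
      free <- which(is.na(cells$merge_partner) &
                      cells$dropout_until < t &
                      (t - cells$birth) + cfg$merge_duration + 18 <
                        cells$life &
                      cells$birth < t)
      if (length(free) < 2) next
      dmat <- as.matrix(stats::dist(cbind(cells$x[free], cells$y[free])))
      diag(dmat) <- Inf
      pick <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
      i <- free[pick[1]]; j <- free[pick[2]]
      cells$merge_partner[i] <- cells$id[j]
      cells$merge_partner[j] <- cells$id[i]
      cells$merge_until[c(i, j)] <- -1L    # approaching
    }
    if (nrow(cells)) {
      done <- which(!is.na(cells$merge_partner) &
                      cells$merge_until >= 0L & cells$merge_until < t)
      cells$merge_partner[done] <- NA_integer_
    }
    # --- start scheduled dropouts
    for (m in which(sched_drop == t)) {
      free <- which(cells$dropout_until < t & is.na(cells$merge_partner) &
                      (t - cells$birth) + cfg$dropout_duration + 2 < cells$life)
      if (!length(free)) next
      i <- sample(free, 1)
      cells$dropout_until[i] <- t + cfg$dropout_duration - 1L
      events <- rbind(events,
                      data.frame(type = "dropout", start_frame = t,
                                 end_frame = t + cfg$dropout_duration - 1L,
                                 ids = as.character(cells$id[i])))
    }

    # --- debris positions for this frame
    deb <- NULL
    if (!is.null(debris)) {
      active <- which(debris$entry <= t)
      if (length(active)) {
        dt <- t - debris$entry[active]
        sx <- ifelse(debris$side[active] == 1, 1,
                     ifelse(debris$side[active] == 2, cfg$width,
                            debris$pos[active] * cfg$width))
        sy <- ifelse(debris$side[active] <= 2, debris$pos[active] * cfg$height,
                     ifelse(debris$side[active] == 3, 1, cfg$height))
        base_dir <- ifelse(debris$side[active] == 1, 0,
                           ifelse(debris$side[active] == 2, pi,
                                  ifelse(debris$side[active] == 3, pi / 2, -pi / 2)))
        th <- base_dir + debris$theta[active]
        px <- sx + cos(th) * cfg$debris_speed * dt
        py <- sy + sin(th) * cfg$debris_speed * dt
        inside <- px > -cfg$debris_radius & px < cfg$width + cfg$debris_radius &
          py > -cfg$debris_radius & py < cfg$height + cfg$debris_radius
        if (any(inside)) deb <- data.frame(x = px[inside], y = py[inside])
        for (i in active[inside]) {
          key <- paste0("D", i)
          row <- which(events$type == "debris" & events$ids == key)
          if (length(row)) events$end_frame[row] <- t
          else events <- rbind(events,
                               data.frame(type = "debris", start_frame = t,
                                          end_frame = t, ids = key))
        }
      }
    }

    rendered <- render_frame(cells, cfg, t, debris = deb)
    frames[[t]] <- rendered$image
    masks[[t]] <- rendered$mask
  }

  registry$death_frame[is.na(registry$death_frame) &
                         registry$id %in% cells$id] <- cfg$n_frames
  registry$fate[is.na(registry$fate) & registry$id %in% cells$id] <- "alive_at_end"
  registry <- registry[!is.na(registry$death_frame), , drop = FALSE]

  truth <- structure(list(masks = masks,
                          cells = as_tibble(registry),
                          lineage = as_tibble(lineage),
                          events = as_tibble(events)),
                     class = "ground_truth")
  structure(list(frames = frames, truth = truth, config = cfg),
            class = "cell_movie")
}

#' Render one frame of the simulated world
#'
#' Draws every living cell as a bright ellipse over the background
#' (plus an optional illumination ramp), applies the pre-mitotic
#' pattern and dropout contrast reduction, adds debris and pixel noise,
#' and produces the matching ground-truth label mask (overlapping cell
#' pixels go to the nearest cell centre; debris is not a cell and never
#' enters the mask).
#'
#' @param cells Internal world-state data frame (one row per living
#'   cell).
#' @param cfg A [simulation_config()].
#' @param t Frame index (for the pre-mitotic phase and dropout state).
#' @param debris Optional data frame of debris positions (`x`, `y`).
#' @return List with `image` (integer grey matrix) and `mask` (integer
#'   label matrix of true cell ids).
#' @export
render_frame <- function(cells, cfg, t = 1L, debris = NULL) {
  w <- cfg$width; h <- cfg$height
  img <- matrix(cfg$background, h, w)
  if (cfg$gradient_amplitude != 0) {
    ramp <- outer(seq(0, 1, length.out = h), seq(0, 1, length.out = w), "+") / 2
    img <- img + cfg$gradient_amplitude * ramp
  }
  mask <- matrix(0L, h, w)
  best <- matrix(Inf, h, w)
  if (nrow(cells)) {
    if (any(cells$r <= 0 | cells$area_factor <= 0))
      stop("state error: cell with non-positive area")
    age <- t - cells$birth
    to_go <- cells$life - 1L - age    # frames until division frame
    phase <- pmax(0, pmin(1, 1 - to_go / cfg$mitosis_frames))
    for (i in seq_len(nrow(cells))) {
      af <- cells$area_factor[i] * (1 - cfg$mitosis_area_drop * phase[i])
      r_eff <- cells$r[i] * sqrt(af)
      asp <- cells$aspect[i] * (1 - phase[i]) + 1 * phase[i]
      ra <- r_eff * sqrt(asp); rb <- r_eff / sqrt(asp)
      inten <- cells$intensity[i] * (1 + cfg$mitosis_brightness_rise * phase[i])
      if (cells$dropout_until[i] >= t)
        inten <- cfg$background +
          cfg$dropout_contrast * (inten - cfg$background)
      px <- draw_ellipse(cells$x[i], cells$y[i], ra, rb, cells$angle[i], w, h)
      if (!length(px$idx)) next
      img[px$idx] <- pmax(img[px$idx], inten)
      upd <- px$nd < best[px$idx]
      mask[px$idx[upd]] <- cells$id[i]
      best[px$idx[upd]] <- px$nd[upd]
    }
  }
  if (!is.null(debris) && nrow(debris)) {
    for (i in seq_len(nrow(debris))) {
      px <- draw_ellipse(debris$x[i], debris$y[i], cfg$debris_radius,
                         cfg$debris_radius * 0.8, 0, w, h)
      if (length(px$idx)) img[px$idx] <- pmax(img[px$idx], cfg$cell_intensity)
    }
  }
  if (cfg$noise_sd > 0) img <- img + rnorm(length(img), 0, cfg$noise_sd)
  img <- matrix(as.integer(pmin(255, pmax(0, round(img)))), h, w)
  list(image = img, mask = mask)
}

# pixel indices (into an h x w matrix) inside an ellipse, plus the
# normalized squared ellipse distance of each pixel
draw_ellipse <- function(cx, cy, ra, rb, angle, w, h) {
  rmax <- max(ra, rb)
  x0 <- max(1L, floor(cx - rmax)); x1 <- min(w, ceiling(cx + rmax))
  y0 <- max(1L, floor(cy - rmax)); y1 <- min(h, ceiling(cy + rmax))
  if (x0 > x1 || y0 > y1) return(list(idx = integer(0), nd = numeric(0)))
  xs <- x0:x1; ys <- y0:y1
  dx <- rep(xs - cx, each = length(ys))
  dy <- rep(ys - cy, times = length(xs))
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  nd <- (u / ra)^2 + (v / rb)^2
  keep <- nd <= 1
  row <- rep(ys, times = length(xs))[keep]
  col <- rep(xs, each = length(ys))[keep]
  list(idx = (col - 1L) * h + row, nd = nd[keep])
}
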