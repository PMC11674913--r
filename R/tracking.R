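# Measurement pipeline: background estimation, detection, feature
# extraction, frame-to-frame linking and pre/post-electrode velocity
# fitting.
#
# Pixel conventions: origin top-left, 0-based sub-pixel centroids,
# x (columns) rightward = downstream.

#' Estimate the static background
#'
#' Pixelwise temporal median over a uniform subsample of at most 200
#' frames. Moving cells that cover a pixel less than half the time do
#' not contaminate the median.
#'
#' @param frames list of frame matrices.
#' @param max_frames maximum number of frames entering the median.
#' @return background matrix.
#' @export
estimate_background <- function(frames, max_frames = 200) {
  if (length(frames) < 20) stop("need at least 20 frames")
  idx <- unique(round(seq(1, length(frames),
                          length.out = min(max_frames, length(frames)))))
  stack <- vapply(frames[idx], identity,
                  matrix(0, nrow(frames[[1]]), ncol(frames[[1]])))
  apply(stack, c(1, 2), stats::median)
}

#' Default detection parameters
#'
#' @param sigma Gaussian smoothing sd (pixels).
#' @param k MAD multiplier for the detection threshold.
#' @param d_min,d_max accepted equivalent-diameter range (um).
#' @param ecc_max eccentricity cutoff; larger components are rejected
#'   as debris/aggregates.
#' @param um_per_pixel resolution (um/pixel).
#' @param noise_floor lower bound (grey levels) on the MAD noise scale
#'   entering the threshold, so noise-free stacks keep a finite
#'   threshold.
#' @param border_margin_px detections whose centroid lies within this
#'   distance plus one cell radius of the frame edge are rejected
#'   (truncated cells bias centroids and sizes).
#' @return named list of parameters.
#' @export
detect_params <- function(sigma = 1, k = 4, d_min = 5, d_max = 30,
                          ecc_max = 0.9, um_per_pixel = 0.62,
                          noise_floor = 2.5, border_margin_px = 2) {
  list(sigma = sigma, k = k, d_min = d_min, d_max = d_max,
       ecc_max = ecc_max, um_per_pixel = um_per_pixel,
       noise_floor = noise_floor, border_margin_px = border_margin_px)
}

#' Detect cells in one frame
#'
#' Pipeline: Gaussian smoothing of |frame - background|, threshold at
#' `k` times the MAD (about zero) of the smoothed difference,
#' 8-connected components, hole filling, then per-component features:
#' intensity-weighted sub-pixel centroid, area, equivalent-circle
#' diameter and eccentricity from central second moments. Components
#' outside the diameter window or above the eccentricity cutoff are
#' rejected.
#'
#' @param frame,background matrices of equal size (0-255 scale).
#' @param params list from [detect_params()].
#' @return data frame with `x_px`, `y_px`, `area_px2`, `diameter_um`,
#'   `eccentricity` (possibly 0 rows).
#' @export
detect <- function(frame, background, params = detect_params()) {
  if (!all(dim(frame) == dim(background)))
    stop("frame and background differ in shape")
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px2 = numeric(0), diameter_um = numeric(0),
                      eccentricity = numeric(0))
  if (mean(frame >= 255) > 0.5) {
    warning("saturated frame; returning no detections")
    return(empty)
  }
  diffim <- abs(frame - background)
  sm <- EBImage::gblur(diffim, sigma = params$sigma)
  noise <- stats::mad(sm, center = 0)
  bin <- sm > params$k * max(noise, params$noise_floor)
  lab <- EBImage::bwlabel(bin)
  lab <- EBImage::bwlabel(EBImage::fillHull(lab) > 0)
  nlab <- max(lab)
  if (nlab == 0) return(empty)
  pix <- which(lab > 0)
  lb <- lab[pix]
  wt <- sm[pix]
  rows <- (pix - 1) %% nrow(lab)          # 0-based y
  cols <- (pix - 1) %/% nrow(lab)         # 0-based x
  area <- tabulate(lb, nlab)
  wsum <- vapply(seq_len(nlab), function(l) sum(wt[lb == l]), numeric(1))
  cx <- vapply(seq_len(nlab), function(l) {
    s <- lb == l; sum(cols[s] * wt[s])
  }, numeric(1)) / wsum
  cy <- vapply(seq_len(nlab), function(l) {
    s <- lb == l; sum(rows[s] * wt[s])
  }, numeric(1)) / wsum
  ecc <- vapply(seq_len(nlab), function(l) {
    s <- lb == l
    mx <- mean(cols[s]); my <- mean(rows[s])
    mxx <- mean((cols[s] - mx)^2); myy <- mean((rows[s] - my)^2)
    mxy <- mean((cols[s] - mx) * (rows[s] - my))
    tr <- mxx + myy; det2 <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
    l1 <- tr / 2 + det2; l2 <- tr / 2 - det2
    if (l1 <= 0) return(0)
    sqrt(max(1 - l2 / l1, 0))
  }, numeric(1))
  d_um <- 2 * sqrt(area / pi) * params$um_per_pixel
  r_px <- d_um / 2 / params$um_per_pixel
  bm <- params$border_margin_px
  inside <- cx >= r_px + bm & cx <= ncol(frame) - 1 - r_px - bm &
    cy >= r_px + bm & cy <= nrow(frame) - 1 - r_px - bm
  keep <- d_um >= params$d_min & d_um <= params$d_max &
    ecc <= params$ecc_max & inside
  data.frame(x_px = cx, y_px = cy, area_px2 = area,
             diameter_um = d_um, eccentricity = ecc)[keep, , drop = FALSE]
}

#' Detect cells in every frame
#'
#' @param frames list of frames.
#' @param background from [estimate_background()].
#' @param params detection parameters.
#' @param frame_index integer frame indices (default 0-based sequence).
#' @return data frame of detections with a `frame` column.
#' @export
detect_all <- function(frames, background, params = detect_params(),
                       frame_index = seq_along(frames) - 1L) {
  out <- lapply(seq_along(frames), function(i) {
    d <- detect(frames[[i]], background, params)
    if (nrow(d)) d$frame <- frame_index[i]
    d
  })
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (!length(out))
    return(data.frame(frame = integer(0), x_px = numeric(0),
                      y_px = numeric(0), area_px2 = numeric(0),
                      diameter_um = numeric(0), eccentricity = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$frame), c("frame", "x_px", "y_px", "area_px2",
                        "diameter_um", "eccentricity")]
}

# Exact minimum-cost bipartite assignment with per-node opt-out.
# Candidate pairs are gated at max_cost; connected components of the
# gated graph are solved independently by exhaustive enumeration
# (components are tiny once gated). Rows/columns may remain unmatched
# at cost max_cost each. Returns assignment vector over rows (NA =
# unmatched).
assign_min_cost <- function(cost, max_cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  res <- rep(NA_integer_, nr)
  if (nr == 0 || nc == 0) return(res)
  feas <- cost <= max_cost
  # connected components over the bipartite feasibility graph
  row_comp <- rep(NA_integer_, nr); col_comp <- rep(NA_integer_, nc)
  comp <- 0L
  for (r0 in seq_len(nr)) {
    if (!is.na(row_comp[r0]) || !any(feas[r0, ])) next
    comp <- comp + 1L
    qr <- r0
    while (length(qr)) {
      r <- qr[1]; qr <- qr[-1]
      if (!is.na(row_comp[r])) next
      row_comp[r] <- comp
      for (cc in which(feas[r, ] & is.na(col_comp))) {
        col_comp[cc] <- comp
        qr <- c(qr, which(feas[, cc] & is.na(row_comp)))
      }
    }
  }
  solve_comp <- function(rs, cs) {
    # enumerate assignments of rows rs to columns cs (or NA)
    k <- length(rs)
    best <- NULL; best_cost <- Inf
    rec <- function(i, used, cur, curcost) {
      if (curcost >= best_cost) return()
      if (i > k) { best <<- cur; best_cost <<- curcost; return() }
      r <- rs[i]
      for (cc in cs[!used]) {
        if (feas[r, cc])
          rec(i + 1, used | cs == cc, c(cur, cc),
              curcost + cost[r, cc])
      }
      rec(i + 1, used, c(cur, NA_integer_), curcost + max_cost)
    }
    rec(1L, rep(FALSE, length(cs)), integer(0), 0)
    best
  }
  for (cp in seq_len(comp)) {
    rs <- which(row_comp == cp); cs <- which(col_comp == cp)
    if (length(rs) > 12) {
      # large ambiguous subnet: greedy by increasing cost
      ord <- order(cost[rs, cs])
      taken_r <- logical(length(rs)); taken_c <- logical(length(cs))
      for (o in ord) {
        ri <- (o - 1) %% length(rs) + 1; ci <- (o - 1) %/% length(rs) + 1
        if (taken_r[ri] || taken_c[ci] || !feas[rs[ri], cs[ci]]) next
        res[rs[ri]] <- cs[ci]; taken_r[ri] <- TRUE; taken_c[ci] <- TRUE
      }
      warning("linking subnet larger than 12; greedy fallback used")
    } else {
      res[rs] <- solve_comp(rs, cs)
    }
  }
  res
}

#' Link detections into tracks
#'
#' Frame-to-frame minimum-cost assignment on squared displacement
#' between each track's predicted position (last position plus last
#' velocity) and the new detections, gated at `max_disp` pixels.
#' Unmatched tracks persist for up to `memory` frames (bridged gaps);
#' tracks shorter than `min_length` detections are discarded.
#'
#' @param detections data frame from [detect_all()] (sorted by frame).
#' @param max_disp maximum per-frame displacement (pixels).
#' @param memory frames a lost track may survive unmatched.
#' @param min_length minimum detections per reported track.
#' @return the detections data frame with a `particle_id` column,
#'   restricted to retained tracks.
#' @export
link <- function(detections, max_disp, memory = 2, min_length = 5) {
  if (!nrow(detections)) {
    detections$particle_id <- integer(0)
    return(detections)
  }
  stopifnot(!is.unsorted(detections$frame))
  frames <- sort(unique(detections$frame))
  det_rows <- split(seq_len(nrow(detections)), detections$frame)
  # active track state
  act <- list()       # each: id, x, y, vx, vy, last_frame, rows
  next_id <- 1L
  done <- list()
  pid <- rep(NA_integer_, nrow(detections))
  for (f in frames) {
    rows <- det_rows[[as.character(f)]]
    dx <- detections$x_px[rows]; dy <- detections$y_px[rows]
    # drop expired tracks
    if (length(act)) {
      expired <- vapply(act, function(a) f - a$last_frame > memory + 1,
                        logical(1))
      done <- c(done, act[expired]); act <- act[!expired]
    }
    if (length(act)) {
      pred <- t(vapply(act, function(a) {
        dt <- f - a$last_frame
        c(a$x + a$vx * dt, a$y + a$vy * dt)
      }, numeric(2)))
      cost <- outer(pred[, 1], dx, "-")^2 + outer(pred[, 2], dy, "-")^2
      asg <- assign_min_cost(cost, max_disp^2)
    } else asg <- integer(0)
    used_det <- rep(FALSE, length(rows))
    for (i in seq_along(asg)) {
      j <- asg[i]
      if (is.na(j)) next
      a <- act[[i]]
      dt <- f - a$last_frame
      act[[i]]$vx <- (dx[j] - a$x) / dt
      act[[i]]$vy <- (dy[j] - a$y) / dt
      act[[i]]$x <- dx[j]; act[[i]]$y <- dy[j]
      act[[i]]$last_frame <- f
      act[[i]]$rows <- c(a$rows, rows[j])
      used_det[j] <- TRUE
      pid[rows[j]] <- a$id
    }
    for (j in which(!used_det)) {
      act[[length(act) + 1]] <- list(id = next_id, x = dx[j], y = dy[j],
                                     vx = 0, vy = 0, last_frame = f,
                                     rows = rows[j])
      pid[rows[j]] <- next_id
      next_id <- next_id + 1L
    }
  }
  done <- c(done, act)
  keep_ids <- vapply(done[vapply(done, function(a)
    length(a$rows) >= min_length, logical(1))],
    function(a) a$id, integer(1))
  out <- detections
  out$particle_id <- pid
  out <- out[out$particle_id %in% keep_ids, , drop = FALSE]
  out[order(out$particle_id, out$frame), ]
}

#' Pre/post-electrode velocities of one track
#'
#' Ordinary least-squares slopes of downstream position (um) against
#' time (s) over the points upstream of `x_e1 - margin` and downstream
#' of `x_e2 + margin`. Units: um/s.
#'
#' @param track data frame with `frame` and `x_px` for one particle.
#' @param optics an `optics_spec` (pixel size, frame rate).
#' @param electrode_window c(x_e1, x_e2) in um, image-x reference.
#' @param margin exclusion margin (um), default 50.
#' @return list with `vi`, `vo`, `vdiff` (um/s) and `flags`.
#' @export
track_velocities <- function(track, optics, electrode_window,
                             margin = 50) {
  x_um <- track$x_px * optics$um_per_pixel
  t_s <- track$frame / optics$frame_rate
  pre <- x_um < electrode_window[1] - margin
  post <- x_um > electrode_window[2] + margin
  if (!any(pre) && !any(post))
    stop("all points inside the electrode exclusion window")
  slope <- function(sel) {
    if (sum(sel) < 3) return(NA_real_)
    stats::coef(stats::lm(x_um[sel] ~ t_s[sel]))[[2]]
  }
  vi <- slope(pre); vo <- slope(post)
  flags <- if (is.na(vi) || is.na(vo)) "partial" else ""
  list(vi = vi, vo = vo, vdiff = vi - vo, flags = flags)
}

#' Velocities for all tracks
#'
#' @param tracks linked detections from [link()].
#' @param optics an `optics_spec`.
#' @param electrode_window c(x_e1, x_e2) in um.
#' @param margin exclusion margin (um).
#' @return data frame (particle_id, vi_um_s, vo_um_s, vdiff_um_s,
#'   diameter_um, flags); diameter is the per-track median.
#' @export
all_velocities <- function(tracks, optics, electrode_window,
                           margin = 50) {
  ids <- unique(tracks$particle_id)
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$particle_id == id, ]
    v <- tryCatch(track_velocities(tr, optics, electrode_window, margin),
                  error = function(e) list(vi = NA, vo = NA, vdiff = NA,
                                           flags = "unmeasurable"))
    data.frame(particle_id = id, vi_um_s = v$vi, vo_um_s = v$vo,
               vdiff_um_s = v$vdiff,
               diameter_um = stats::median(tr$diameter_um),
               flags = v$flags)
  })
  do.call(rbind, rows)
}
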