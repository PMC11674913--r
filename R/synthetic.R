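# Synthetic data generation: ground-truth population sampling and
# quasi-darkfield frame rendering. This is the fixture generator that
# makes the tracking and clustering stages testable without recorded
# video.

#' Imaging optics specification
#'
#' Defaults follow the reference device: 0.62 um/pixel, 226 fps, a
#' 670 x 894 um^2 field of view (1080 x 1442 pixels), 8-bit frames.
#' Image rows are the cross-flow (y) direction, columns the downstream
#' (x) direction.
#'
#' @param um_per_pixel resolution (um/pixel).
#' @param frame_rate frame rate (Hz).
#' @param frame_px frame size in pixels, c(rows, cols).
#' @param fov_um optional field of view c(y, x) in um; checked against
#'   `frame_px * um_per_pixel` within one pixel.
#' @param bit_depth bits per pixel (8).
#' @return an object of class `optics_spec`.
#' @export
optics_spec <- function(um_per_pixel = 0.62, frame_rate = 226,
                        frame_px = c(1080L, 1442L), fov_um = NULL,
                        bit_depth = 8L) {
  stopifnot(um_per_pixel > 0, frame_rate > 0, all(frame_px > 0))
  if (!is.null(fov_um) &&
      any(abs(fov_um - frame_px * um_per_pixel) > um_per_pixel))
    stop("field of view inconsistent with frame size and resolution")
  structure(list(um_per_pixel = um_per_pixel, frame_rate = frame_rate,
                 frame_px = as.integer(frame_px),
                 fov_um = frame_px * um_per_pixel,
                 bit_depth = as.integer(bit_depth)),
            class = "optics_spec")
}

#' Mixed-population specification
#'
#' Each component describes one sub-population: its mixing fraction, a
#' truncated-normal diameter distribution (um), a fixed Re{Kcm} at the
#' drive frequency (or a dielectric preset name resolved at the drive
#' frequency), and a particle mass density.
#'
#' @param components list of lists with fields `name`, `fraction`,
#'   `diam_mean_um`, `diam_sd_um`, `diam_bounds_um` (length 2),
#'   `re_kcm` (or `preset`), `rho_p`.
#' @param arrival_rate mean cell arrival rate (cells/s).
#' @param medium a `dep_medium`.
#' @param vbar mean flow velocity (m/s).
#' @param H channel height (m).
#' @param drive_frequency DEP frequency (Hz), used to resolve presets.
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(components, arrival_rate = 10,
                            medium = dep_medium(),
                            vbar = 1000e-6, H = 50e-6,
                            drive_frequency = 6e6) {
  fr <- vapply(components, function(cc) cc$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-8) stop("component fractions must sum to 1")
  for (cc in components) {
    if (!is.null(cc$diam_sd_um) && cc$diam_sd_um < 0)
      stop("negative diameter standard deviation")
    if (is.null(cc$re_kcm) && is.null(cc$preset))
      stop("component needs re_kcm or preset")
  }
  structure(list(components = components, arrival_rate = arrival_rate,
                 medium = medium, vbar = vbar, H = H,
                 drive_frequency = drive_frequency),
            class = "population_spec")
}

#' Reference CHO viable/non-viable mixture
#'
#' Convenience constructor for the two-component CHO mixture used in
#' the worked examples: viable (pDEP at 6 MHz) and non-viable (nDEP)
#' cells with truncated-normal diameters.
#'
#' @param viable_fraction mixing fraction of the viable component.
#' @param medium suspension medium.
#' @param vbar mean flow velocity (m/s).
#' @return a `population_spec`.
#' @export
cho_mixture_spec <- function(viable_fraction = 0.45,
                             medium = dep_medium(78, 0.17, density = 1017.5),
                             vbar = 1000e-6) {
  f <- 6e6
  kv <- re_kcm_at(dep_preset("cho_viable"), medium, f)
  kn <- re_kcm_at(dep_preset("cho_nonviable"), medium, f)
  population_spec(list(
    list(name = "viable", fraction = viable_fraction,
         diam_mean_um = 12.5, diam_sd_um = 1.25,
         diam_bounds_um = c(10, 15), re_kcm = kv, rho_p = 1050),
    list(name = "nonviable", fraction = 1 - viable_fraction,
         diam_mean_um = 11, diam_sd_um = 1.25,
         diam_bounds_um = c(9, 14), re_kcm = kn, rho_p = 1050)),
    arrival_rate = 10, medium = medium, vbar = vbar,
    drive_frequency = f)
}

# Truncated normal sampling by rejection (bounds are narrow here)
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2 * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Sample a ground-truth particle list
#'
#' Draws `n` particles from the mixture: component label, diameter,
#' Re{Kcm}, Poisson-process entry time, uniform lateral position, and
#' entry height. Entry heights are the particle's lift/weight
#' equilibrium plus an upward half-normal jitter (cells reaching the
#' field of view before settling completely sit above, not below,
#' their equilibrium), or the height matching a uniformly drawn target
#' incoming velocity when `entry = "vi_range"`.
#'
#' @param spec a `population_spec`.
#' @param n number of particles.
#' @param seed RNG seed (integer); same seed gives an identical list.
#' @param entry `"equilibrium"` (default) or `"vi_range"`.
#' @param jitter_sd sd of the upward entry-height jitter (m).
#' @param vi_range target incoming-velocity range (m/s) for
#'   `entry = "vi_range"`.
#' @param fov_y_um lateral extent for entry positions (um).
#' @return data frame with one row per particle: `id`, `label`,
#'   `diameter_um`, `re_kcm`, `rho_p`, `t_entry_s`, `y_um`,
#'   `h_entry_m`.
#' @export
sample_population <- function(spec, n, seed,
                              entry = c("equilibrium", "vi_range"),
                              jitter_sd = 2e-6,
                              vi_range = c(800e-6, 1200e-6),
                              fov_y_um = 670) {
  stopifnot(n >= 1)
  entry <- match.arg(entry)
  set.seed(seed)
  fr <- vapply(spec$components, function(cc) cc$fraction, numeric(1))
  comp <- sample.int(length(fr), n, replace = TRUE, prob = fr)
  out <- data.frame(id = seq_len(n),
                    label = vapply(spec$components,
                                   function(cc) cc$name, character(1))[comp],
                    diameter_um = NA_real_, re_kcm = NA_real_,
                    rho_p = NA_real_, t_entry_s = NA_real_,
                    y_um = stats::runif(n, 0, fov_y_um),
                    h_entry_m = NA_real_)
  out$t_entry_s <- cumsum(stats::rexp(n, rate = spec$arrival_rate))
  for (ic in seq_along(spec$components)) {
    cc <- spec$components[[ic]]
    sel <- comp == ic
    if (!any(sel)) next
    b <- if (is.null(cc$diam_bounds_um)) c(1e-6, Inf) else cc$diam_bounds_um
    out$diameter_um[sel] <- rtruncnorm1(sum(sel), cc$diam_mean_um,
                                        cc$diam_sd_um, b[1], b[2])
    k <- if (!is.null(cc$re_kcm)) cc$re_kcm
         else re_kcm_at(dep_preset(cc$preset), spec$medium,
                        spec$drive_frequency)
    out$re_kcm[sel] <- k
    out$rho_p[sel] <- cc$rho_p
  }
  H <- spec$H
  for (i in seq_len(n)) {
    r <- out$diameter_um[i] / 2 * 1e-6
    p <- transport_params(spec$medium, r = r, rho_p = out$rho_p[i],
                          re_kcm = 0, vbar = spec$vbar, H = H)
    if (entry == "equilibrium") {
      h <- equilibrium_height(p) + abs(stats::rnorm(1, 0, jitter_sd))
    } else {
      vi <- stats::runif(1, vi_range[1], vi_range[2])
      disc <- max(1 - 4 * vi / (6 * spec$vbar), 0)
      h <- H / 2 * (1 - sqrt(disc))
    }
    out$h_entry_m[i] <- min(max(h, r * 1.01), H / 2)
  }
  out
}

#' Ground-truth pixel tracks from simulated trajectories
#'
#' Runs the transport simulation for each particle and samples its
#' position at the camera's frame times, converting to pixel
#' coordinates (origin top-left, x rightward = downstream). The
#' electrode pair sits at the true layout position within the field of
#' view.
#'
#' @param particles data frame from [sample_population()].
#' @param spec the `population_spec` used to draw them.
#' @param field a `field_grid` covering the field of view.
#' @param optics an `optics_spec`.
#' @param x_offset_um downstream position of the left image edge in
#'   field-grid coordinates (um); default centres the field of view on
#'   the electrode gap.
#' @param max_frames recording length cap per particle (frames); a
#'   particle trapped at the electrodes simply sits in the remaining
#'   frames of a real recording, so its sampled track is truncated
#'   here rather than extended indefinitely.
#' @return list with `tracks` (frame, particle_id, x_px, y_px,
#'   diameter_um, label, h_m) and `duration_s`.
#' @export
truth_tracks <- function(particles, spec, field, optics,
                         x_offset_um = NULL, max_frames = 2000) {
  fov_x <- optics$fov_um[2]
  if (is.null(x_offset_um))
    x_offset_um <- field$x_center * 1e6 - fov_x / 2
  fps <- optics$frame_rate
  rows <- list()
  for (i in seq_len(nrow(particles))) {
    pt <- particles[i, ]
    r <- pt$diameter_um / 2 * 1e-6
    p <- transport_params(spec$medium, r = r, rho_p = pt$rho_p,
                          re_kcm = pt$re_kcm, vbar = spec$vbar,
                          H = spec$H)
    tr <- suppressWarnings(
      simulate_trajectory(p, field, entry_h = pt$h_entry_m, n_out = 250))
    # time grid of frames while the particle is inside the FOV
    tmax <- min(max(tr$path$t_s), (max_frames - 1) / fps)
    tt <- seq(0, tmax, by = 1 / fps)
    xx <- stats::approx(tr$path$t_s, tr$path$x_m, xout = tt)$y
    x_px <- (xx * 1e6 - x_offset_um) / optics$um_per_pixel
    keep <- !is.na(x_px) & x_px >= 0 & x_px < optics$frame_px[2]
    if (sum(keep) < 2) next
    frame0 <- round(pt$t_entry_s * fps)
    rows[[length(rows) + 1]] <- data.frame(
      frame = frame0 + seq_along(tt)[keep] - 1L,
      particle_id = pt$id,
      x_px = x_px[keep],
      y_px = pt$y_um / optics$um_per_pixel,
      diameter_um = pt$diameter_um,
      label = pt$label,
      h_m = stats::approx(tr$path$t_s, tr$path$h_m, xout = tt)$y[keep])
  }
  tracks <- do.call(rbind, rows)
  tracks <- tracks[order(tracks$frame, tracks$particle_id), ]
  list(tracks = tracks,
       duration_s = (max(tracks$frame) + 1) / fps,
       x_offset_um = x_offset_um)
}

#' Constant-velocity ground-truth tracks
#'
#' Simple track generator (no transport simulation): particles advect
#' at fixed velocity across the field of view. Used for estimator
#' calibration tests.
#'
#' @param particles data frame with `id`, `diameter_um`, `y_um` and a
#'   `vx_um_s` column (downstream speed, um/s).
#' @param optics an `optics_spec`.
#' @param n_frames number of frames.
#' @param x0_px starting x pixel positions (recycled).
#' @return tracks data frame as in [truth_tracks()].
#' @export
constant_velocity_tracks <- function(particles, optics, n_frames,
                                     x0_px = 0) {
  x0_px <- rep_len(x0_px, nrow(particles))
  rows <- lapply(seq_len(nrow(particles)), function(i) {
    pt <- particles[i, ]
    dx <- pt$vx_um_s / optics$um_per_pixel / optics$frame_rate
    x <- x0_px[i] + (seq_len(n_frames) - 1) * dx
    keep <- x >= 0 & x < optics$frame_px[2]
    data.frame(frame = which(keep) - 1L, particle_id = pt$id,
               x_px = x[keep], y_px = pt$y_um / optics$um_per_pixel,
               diameter_um = pt$diameter_um,
               label = if (is.null(pt$label)) "p" else pt$label,
               h_m = NA_real_)
  })
  do.call(rbind, rows)
}

#' Static synthetic background
#'
#' Smooth illumination gradient plus two darker electrode stripes at
#' the layout positions and a fixed-pattern texture. Values on the
#' 8-bit scale.
#'
#' @param optics an `optics_spec`.
#' @param layout an `electrode_layout` (stripe geometry), or NULL for
#'   no stripes.
#' @param x_offset_um downstream coordinate of the left image edge
#'   relative to the gap centre (um); electrodes are drawn where they
#'   truly sit. Default centres the gap.
#' @param base mean background level.
#' @param gradient peak-to-peak illumination gradient amplitude.
#' @param stripe_depth electrode stripe darkening.
#' @param texture_sd fixed-pattern texture standard deviation.
#' @param seed seed for the fixed-pattern texture.
#' @return matrix (rows x cols) of background intensities.
#' @export
synthetic_background <- function(optics, layout = electrode_layout(),
                                 x_offset_um = NULL, base = 30,
                                 gradient = 10, stripe_depth = 8,
                                 texture_sd = 1.5, seed = 1) {
  nr <- optics$frame_px[1]; nc <- optics$frame_px[2]
  if (is.null(x_offset_um)) x_offset_um <- -optics$fov_um[2] / 2
  xs <- (seq_len(nc) - 0.5) * optics$um_per_pixel + x_offset_um
  ys <- (seq_len(nr) - 0.5) / nr
  bg <- base + gradient * outer(ys - 0.5, (xs - mean(xs)) / diff(range(xs)),
                                function(a, b) a * 0.5 + b)
  if (!is.null(layout)) {
    g <- layout$gap * 1e6; w <- layout$electrode_width * 1e6
    stripe <- (xs >= -g / 2 - w & xs <= -g / 2) |
      (xs >= g / 2 & xs <= g / 2 + w)
    bg[, stripe] <- bg[, stripe] - stripe_depth
  }
  old <- .Random.seed_save()
  set.seed(seed)
  bg <- bg + matrix(stats::rnorm(nr * nc, 0, texture_sd), nr, nc)
  .Random.seed_restore(old)
  bg
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Quasi-darkfield photometric profile of one cell: bright annulus near
# the rim (Gaussian edge, width ~1 px) with a dimmer interior. The
# annulus is inset from the geometric radius so that the detectable
# footprint (Gaussian skirt down to typical detection thresholds)
# spans the cell's true diameter.
render_cell_patch <- function(radius_px, edge_sigma = 1,
                              rim = 120, interior = 25,
                              rim_inset = 2.8) {
  half <- ceiling(radius_px + 4 * edge_sigma)
  r_rim <- max(radius_px - rim_inset, 1)
  d <- sqrt(outer((-half:half)^2, (-half:half)^2, "+"))
  rimI <- rim * exp(-(d - r_rim)^2 / (2 * edge_sigma^2))
  inner <- interior * (d < r_rim - edge_sigma)
  pmax(rimI, inner)
}

#' Render synthetic quasi-darkfield frames
#'
#' Draws each tracked cell as a radially symmetric bright-rimmed disk
#' of its true diameter on the static background, then applies
#' signal-dependent shot noise, additive Gaussian read noise and 8-bit
#' quantisation.
#'
#' @param tracks data frame (frame, particle_id, x_px, y_px,
#'   diameter_um); frames are rendered for `0:max(frame)` unless
#'   `frames` is given.
#' @param optics an `optics_spec`.
#' @param background background matrix from [synthetic_background()]
#'   (or NULL for a flat background).
#' @param noise list with `read_sd` (additive, grey levels) and
#'   `shot_scale` (variance per unit signal); set both 0 for noise-free
#'   renders.
#' @param seed RNG seed for the noise.
#' @param frames optional integer vector of frame indices to render.
#' @param rim,interior,edge_sigma,rim_inset photometric parameters of
#'   the cell profile (grey levels, pixels); `rim_inset` pulls the
#'   bright annulus inside the geometric radius so the detectable
#'   footprint matches the true diameter.
#' @return list of integer matrices (one per frame, values 0-255), with
#'   attribute `frames` giving the frame indices.
#' @export
render_frames <- function(tracks, optics, background = NULL,
                          noise = list(read_sd = 2, shot_scale = 0.08),
                          seed = 1, frames = NULL,
                          rim = 120, interior = 25, edge_sigma = 1,
                          rim_inset = 2.8) {
  nr <- optics$frame_px[1]; nc <- optics$frame_px[2]
  if (is.null(background)) background <- matrix(30, nr, nc)
  if (is.null(frames)) frames <- 0:max(tracks$frame)
  set.seed(seed)
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    img <- background
    sel <- tracks$frame == f
    if (any(sel)) {
      sub <- tracks[sel, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        rpx <- sub$diameter_um[i] / 2 / optics$um_per_pixel
        r_rim <- max(rpx - rim_inset, 1)
        half <- ceiling(rpx + 4 * edge_sigma)
        cy <- round(sub$y_px[i]) + 1; cx <- round(sub$x_px[i]) + 1
        # sub-pixel offset via patch recentring
        oy <- sub$y_px[i] + 1 - cy; ox <- sub$x_px[i] + 1 - cx
        dy <- (-half:half) - oy; dx <- (-half:half) - ox
        d <- sqrt(outer(dy^2, dx^2, "+"))
        patch <- rim * exp(-(d - r_rim)^2 / (2 * edge_sigma^2))
        patch <- pmax(patch, interior * (d < r_rim - edge_sigma))
        ry <- (cy - half):(cy + half); rx <- (cx - half):(cx + half)
        ok_y <- ry >= 1 & ry <= nr; ok_x <- rx >= 1 & rx <= nc
        img[ry[ok_y], rx[ok_x]] <- img[ry[ok_y], rx[ok_x]] +
          patch[ok_y, ok_x]
      }
    }
    if (noise$shot_scale > 0)
      img <- img + stats::rnorm(nr * nc, 0,
                                sqrt(pmax(noise$shot_scale * img, 0)))
    if (noise$read_sd > 0)
      img <- img + stats::rnorm(nr * nc, 0, noise$read_sd)
    out[[fi]] <- matrix(as.integer(pmin(pmax(round(img), 0), 255)), nr, nc)
  }
  attr(out, "frames") <- frames
  out
}

#' Write frames to disk
#'
#' Either numbered 8-bit PNG files (`frame_%05d.png`) or one
#' multi-page TIFF.
#'
#' @param frames list of integer matrices from [render_frames()].
#' @param path output directory (PNG mode) or `.tif` file path.
#' @param format "png" or "tiff".
#' @return the path, invisibly.
#' @export
write_frames <- function(frames, path, format = c("png", "tiff")) {
  format <- match.arg(format)
  if (format == "png") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    idx <- attr(frames, "frames")
    if (is.null(idx)) idx <- seq_along(frames) - 1L
    for (i in seq_along(frames))
      png::writePNG(frames[[i]] / 255,
                    file.path(path, sprintf("frame_%05d.png", idx[i])))
  } else {
    tiff::writeTIFF(lapply(frames, function(m) m / 255), path,
                    bits.per.sample = 8L)
  }
  invisible(path)
}

#' Read frames from disk
#'
#' Accepts a directory of numbered PNGs or a (multi-page) TIFF file.
#' @param path directory or file.
#' @return list of numeric matrices on the 0-255 scale.
#' @export
read_frames <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG frames found in ", path)
    lapply(files, function(f) png::readPNG(f) * 255)
  } else {
    imgs <- tiff::readTIFF(path, all = TRUE)
    lapply(imgs, function(m) m * 255)
  }
}
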