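# Measurement pipeline: background, detection, linking, velocimetry.

make_stack <- function(n_frames = 40, noise = list(read_sd = 2,
                                                   shot_scale = 0.08),
                       frame_px = c(120, 500), seed = 7) {
  optics <- optics_spec(frame_px = frame_px)
  parts <- data.frame(id = 1:3, diameter_um = c(14.7, 12, 10),
                      y_um = c(20, 42, 58),
                      vx_um_s = c(1000, 900, 1100))
  tracks <- constant_velocity_tracks(parts, optics, n_frames,
                                     x0_px = c(5, 60, 120))
  bg <- synthetic_background(optics, layout = NULL, texture_sd = 1)
  frames <- render_frames(tracks, optics, background = bg,
                          noise = noise, seed = seed)
  list(optics = optics, truth = tracks, frames = frames, bg = bg)
}

test_that("temporal median recovers the static background under
           moving cells", {
  st <- make_stack()
  est <- estimate_background(st$frames)
  expect_lt(stats::median(abs(est - st$bg)), 2)
  # no pixel retains a cell imprint (cells cover any pixel < 50% of
  # the time)
  expect_lt(max(est - st$bg), 25)
  expect_error(estimate_background(st$frames[1:10]), "at least 20")
  # constant frames: background equals any frame
  const <- replicate(25, matrix(7, 4, 5), simplify = FALSE)
  expect_equal(estimate_background(const), matrix(7, 4, 5))
})

test_that("detection recovers position and size; empty and saturated
           frames degrade gracefully", {
  st <- make_stack()
  bg <- estimate_background(st$frames)
  det <- detect(st$frames[[10]], bg)
  truth10 <- st$truth[st$truth$frame == 9, ]  # frame index is 0-based
  expect_equal(nrow(det), nrow(truth10))
  det <- det[order(det$y_px), ]; truth10 <- truth10[order(truth10$y_px), ]
  expect_lt(max(abs(det$x_px - truth10$x_px)), 0.5)
  expect_equal(det$diameter_um, truth10$diameter_um, tolerance = 0.05)
  expect_true(all(det$eccentricity < 0.5))
  # empty frame
  expect_equal(nrow(detect(bg, bg)), 0)
  # saturated frame warns and returns nothing
  expect_warning(d <- detect(matrix(255, 120, 500), bg), "saturated")
  expect_equal(nrow(d), 0)
  expect_error(detect(matrix(0, 10, 10), bg), "shape")
})

test_that("merged overlapping cells carry high eccentricity and the
           anomaly cut rejects them", {
  optics <- optics_spec(frame_px = c(80, 140))
  two <- data.frame(frame = 0L, particle_id = 1:2,
                    x_px = c(50, 64), y_px = 40, diameter_um = 10)
  one <- data.frame(frame = 0L, particle_id = 1L,
                    x_px = 50, y_px = 40, diameter_um = 10)
  bg <- matrix(20, 80, 140)
  nz <- list(read_sd = 1, shot_scale = 0)
  fr2 <- render_frames(two, optics, background = bg, noise = nz, seed = 3)
  fr1 <- render_frames(one, optics, background = bg, noise = nz, seed = 3)
  loose <- detect_params(ecc_max = 1)
  d2 <- detect(fr2[[1]], bg, loose)
  d1 <- detect(fr1[[1]], bg, loose)
  # the touching pair merges into one elongated component, far more
  # eccentric than the single round cell
  expect_equal(nrow(d2), 1)
  expect_gt(d2$eccentricity, 0.7)
  expect_lt(d1$eccentricity, 0.3)
  # an eccentricity cut between the two rejects the aggregate
  strict <- detect_params(ecc_max = 0.6)
  expect_equal(nrow(detect(fr2[[1]], bg, strict)), 0)
  expect_equal(nrow(detect(fr1[[1]], bg, strict)), 1)
})

test_that("detection counts are invariant to a global illumination
           offset", {
  st <- make_stack()
  bg <- estimate_background(st$frames)
  d1 <- detect_all(st$frames[1:10], bg)
  shifted <- lapply(st$frames[1:10], function(m) m + 12)
  d2 <- detect_all(shifted, bg + 12)
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(d1$x_px, d2$x_px, tolerance = 1e-6)
})

test_that("assignment linking matches the brute-force optimum and
           beats greedy on a crossing", {
  set.seed(99)
  for (rep in 1:20) {
    nr <- sample(1:5, 1); nc <- sample(1:5, 1)
    cost <- matrix(runif(nr * nc, 0, 10)^2, nr, nc)
    a <- depcyto:::assign_min_cost(cost, 25)
    b <- brute_force_assignment(cost, 25)
    tc <- function(asg) sum(ifelse(is.na(asg), 25,
                                   cost[cbind(seq_len(nr), asg)]))
    expect_equal(tc(a), tc(b), tolerance = 1e-12)
  }
  # constructed crossing: optimal assignment preserves identity where
  # greedy nearest-neighbour would swap
  det <- data.frame(
    frame = c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5),
    x_px = c(0, 2, 10, 12, 20, 22, 30, 32, 40, 42, 50, 52),
    y_px = c(0, 30, 5, 25, 10, 20, 15, 15.5, 20, 10, 25, 5))
  lk <- link(det, max_disp = 40, min_length = 5)
  expect_equal(length(unique(lk$particle_id)), 2)
  # the track that started at y=0 ends at y=25 (crossed through)
  t1 <- lk[lk$particle_id == lk$particle_id[1], ]
  expect_equal(t1$y_px, c(0, 5, 10, 15, 20, 25))
})

test_that("single cell yields one track holding every detection; short
           tracks are discarded", {
  st <- make_stack()
  det <- detect_all(st$frames, estimate_background(st$frames))
  lk <- link(det, max_disp = 15)
  expect_equal(length(unique(lk$particle_id)), 3)
  # per-frame displacement bounded by the gate
  for (id in unique(lk$particle_id)) {
    tr <- lk[lk$particle_id == id, ]
    expect_true(all(diff(tr$frame) >= 1))
    expect_true(all(abs(diff(tr$x_px)) <= 15 * (diff(tr$frame))))
  }
  # a 3-detection track is dropped at min_length = 5
  d3 <- data.frame(frame = 0:2, x_px = c(0, 5, 10), y_px = 1)
  expect_equal(nrow(link(d3, max_disp = 10, min_length = 5)), 0)
})

test_that("package linking agrees with the independent optimal-oracle
           linker on a 50-cell stack", {
  set.seed(31)
  n <- 50
  # ground-truth detections with centroid jitter, staggered entries
  rows <- lapply(seq_len(n), function(i) {
    f0 <- sample(0:60, 1)
    nf <- sample(12:30, 1)
    v <- runif(1, 5, 9)       # px/frame
    data.frame(frame = f0 + 0:(nf - 1),
               x_px = runif(1, 0, 80) + v * 0:(nf - 1) +
                 rnorm(nf, 0, 0.3),
               y_px = runif(1, 5, 495) + rnorm(nf, 0, 0.3))
  })
  det <- do.call(rbind, rows)
  det <- det[det$x_px < 400, ]
  det <- det[order(det$frame), ]
  lk1 <- link(det, max_disp = 14, min_length = 5)
  lk2 <- oracle_link(det, max_disp = 14, min_length = 5)
  expect_gte(linking_agreement(lk1, lk2), 0.99)
})

test_that("velocity fits are exact on uniform motion and unbiased
           under centroid noise", {
  optics <- optics_spec()
  fr <- 0:200
  x_px <- 10 + (1000 / 0.62 / 226) * fr
  track <- data.frame(frame = fr, x_px = x_px)
  v <- track_velocities(track, optics, electrode_window = c(380, 475),
                        margin = 50)
  expect_equal(v$vi, 1000, tolerance = 1e-9)
  expect_equal(v$vo, 1000, tolerance = 1e-9)
  expect_equal(v$vdiff, 0, tolerance = 1e-9)
  # 4.42 um/frame at 226 fps
  expect_equal(v$vi / 226, 4.425, tolerance = 1e-3)
  # unbiased over 200 noisy replicates
  set.seed(5)
  errs <- replicate(200, {
    tr <- data.frame(frame = fr, x_px = x_px + rnorm(length(fr), 0, 1))
    track_velocities(tr, optics, c(380, 475), 50)$vi - 1000
  })
  expect_lt(abs(mean(errs)) / 1000, 0.005)
  # all points inside the exclusion window is unmeasurable
  inside <- data.frame(frame = 0:9, x_px = seq(620, 700, length.out = 10))
  expect_error(track_velocities(inside, optics, c(0, 1000), 50),
               "exclusion")
})

test_that("end-to-end closure: a rendered transport trajectory is
           re-measured within tolerance", {
  # an nDEP (non-viable) cell: it crosses the electrodes cleanly, so
  # the closure isolates the render -> track -> velocity chain from
  # the pDEP trapping regime (tested in the transport module)
  fg <- default_field()
  med <- cho_medium()
  optics <- optics_spec(frame_px = c(60, 1000))
  p <- transport_params(med, r = 5.5e-6, re_kcm = -0.199, vbar = 1000e-6)
  spec <- cho_mixture_spec()
  parts <- data.frame(id = 1L, label = "nonviable", diameter_um = 11,
                      re_kcm = -0.199, rho_p = 1050, t_entry_s = 0,
                      y_um = 18, h_entry_m = equilibrium_height(p))
  tt <- truth_tracks(parts, spec, fg, optics)
  lay <- fg$layout
  bg <- synthetic_background(optics, layout = lay,
                             x_offset_um = tt$x_offset_um -
                               fg$x_center * 1e6)
  frames <- render_frames(tt$tracks, optics, background = bg, seed = 21)
  det <- detect_all(frames, estimate_background(frames, max_frames = 80))
  rm(bg); gc()
  lk <- link(det, max_disp = 15)
  expect_equal(length(unique(lk$particle_id)), 1)
  # centroid accuracy against ground truth
  m <- merge(lk, tt$tracks, by = "frame", suffixes = c("", ".t"))
  expect_lt(sqrt(mean((m$x_px - m$x_px.t)^2)), 1)
  # electrode window in image coordinates
  win <- c(fg$x_e1, fg$x_e2) * 1e6 - tt$x_offset_um
  v <- all_velocities(lk, optics, electrode_window = win)
  # compare against the simulation's own velocities fitted over the
  # same (camera-limited) windows
  x0 <- tt$x_offset_um * 1e-6
  sim <- simulate_trajectory(p, fg, entry_h = parts$h_entry_m,
                             x_start = x0,
                             x_span = optics$fov_um[2] * 1e-6)
  expect_equal(v$vdiff_um_s, sim$vdiff * 1e6, tolerance = 0.10)
  expect_equal(v$vi_um_s, sim$vi * 1e6, tolerance = 0.02)
  rm(frames, det, lk); gc()
})
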