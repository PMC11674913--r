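# Forward lookup grid (radius, Re{Kcm}, incoming velocity) -> differential
# velocity, and inversion of tracked observations to Re{Kcm}.

#' Entry height reproducing a target incoming velocity
#'
#' Finds the entry height in the lower half-channel [r, H/2] at which a
#' simulated particle's fitted incoming velocity matches `vi` to the
#' given relative tolerance. The analytic inverse of the parabolic
#' profile seeds a secant iteration on the simulated slope (the fitted
#' vi differs slightly from the profile because the particle drifts
#' vertically before the electrodes).
#'
#' @param vi target incoming velocity (m/s).
#' @param params a `transport_params` (its `re_kcm` is used).
#' @param field a `field_grid`.
#' @param tol relative tolerance on vi (default 0.01).
#' @return entry height (m), or NA if unattainable in [r, H/2].
#' @export
entry_height_for_vi <- function(vi, params, field, tol = 0.01) {
  H <- params$H; r <- params$r
  disc <- 1 - 4 * vi / (6 * params$vbar)
  if (disc < 0) return(NA_real_)              # vi above profile maximum
  h0 <- H / 2 * (1 - sqrt(disc))              # lower-branch inverse
  lo <- r * (1 + 1e-3); hi <- H / 2
  h0 <- min(max(h0, lo), hi)
  sim_vi <- function(h) {
    simulate_trajectory(params, field, entry_h = h, n_out = 150)$vi
  }
  h <- h0
  v <- sim_vi(h)
  if (abs(v - vi) <= tol * vi) return(h)
  # secant on h using the local slope of the profile as the first step
  dvdh <- 6 * params$vbar / H * (1 - 2 * h / H)
  h2 <- min(max(h + (vi - v) / dvdh, lo), hi)
  for (i in 1:8) {
    v2 <- sim_vi(h2)
    if (abs(v2 - vi) <= tol * vi) return(h2)
    if (v2 == v) break
    h3 <- h2 + (vi - v2) * (h2 - h) / (v2 - v)
    h <- h2; v <- v2
    h2 <- min(max(h3, lo), hi)
  }
  NA_real_
}

#' Build the forward (r, Re{Kcm}, vi) -> vdiff mapping grid
#'
#' Each node is filled by a full trajectory simulation whose entry
#' height is chosen so the simulated incoming velocity matches the
#' `vi_axis` value within 1 %. Entry heights are restricted to the
#' lower half-channel (cells settle below the centreline; the
#' height-velocity relation is two-valued over the full channel).
#' Nodes whose target vi is unattainable are marked invalid (NA).
#'
#' @param params a `transport_params` template; radius and `re_kcm` are
#'   overridden per node.
#' @param field a `field_grid`.
#' @param r_axis particle radii (m), sorted, length >= 3.
#' @param kcm_axis Re{Kcm} values, sorted, length >= 3.
#' @param vi_axis incoming velocities (m/s), sorted, length >= 3.
#' @param vi_tol relative tolerance of the inner height root-find.
#' @return an object of class `kcm_map`: axes, the `vdiff` array
#'   (r x kcm x vi, m/s), an `entry_h` matrix (r x vi) and provenance.
#' @export
build_mapping <- function(params, field, r_axis, kcm_axis, vi_axis,
                          vi_tol = 0.01) {
  stopifnot(length(r_axis) >= 3, length(kcm_axis) >= 3,
            length(vi_axis) >= 3)
  stopifnot(!is.unsorted(r_axis), !is.unsorted(kcm_axis),
            !is.unsorted(vi_axis))
  nr <- length(r_axis); nk <- length(kcm_axis); nv <- length(vi_axis)
  vd <- array(NA_real_, c(nr, nk, nv))
  entry_h <- matrix(NA_real_, nr, nv)
  for (ir in seq_len(nr)) {
    for (iv in seq_len(nv)) {
      p0 <- params
      p0$r <- r_axis[ir]; p0$re_kcm <- 0
      h <- suppressWarnings(
        entry_height_for_vi(vi_axis[iv], p0, field, tol = vi_tol))
      entry_h[ir, iv] <- h
      if (is.na(h)) next
      for (ik in seq_len(nk)) {
        pk <- p0; pk$re_kcm <- kcm_axis[ik]
        tr <- simulate_trajectory(pk, field, entry_h = h, n_out = 150)
        vd[ir, ik, iv] <- tr$vdiff
      }
    }
  }
  frac_invalid <- mean(is.na(vd))
  if (frac_invalid > 0.2)
    stop(sprintf(
      "mapping build failed: %.0f%% of nodes invalid (vi unattainable)",
      100 * frac_invalid))
  structure(list(r_axis = r_axis, kcm_axis = kcm_axis,
                 vi_axis = vi_axis, vdiff = vd, entry_h = entry_h,
                 provenance = list(
                   vpp = field$layout$vpp,
                   frequency = field$layout$frequency,
                   grid_step = field$grid_step,
                   vbar = params$vbar, H = params$H, C = params$C,
                   medium = unclass(params$medium))),
            class = "kcm_map")
}

#' @export
print.kcm_map <- function(x, ...) {
  cat("Kcm mapping grid\n")
  cat(sprintf("  r: %d nodes %.2f-%.2f um | Kcm: %d nodes %.2f-%.2f | vi: %d nodes %.0f-%.0f um/s\n",
              length(x$r_axis), min(x$r_axis) * 1e6, max(x$r_axis) * 1e6,
              length(x$kcm_axis), min(x$kcm_axis), max(x$kcm_axis),
              length(x$vi_axis), min(x$vi_axis) * 1e6, max(x$vi_axis) * 1e6))
  cat(sprintf("  invalid nodes: %.1f%%\n", 100 * mean(is.na(x$vdiff))))
  invisible(x)
}

# 1-D linear interpolation coefficient
.interp_w <- function(axis, v) {
  i <- pmin(pmax(findInterval(v, axis), 1L), length(axis) - 1L)
  t <- (v - axis[i]) / (axis[i + 1] - axis[i])
  list(i = i, t = t)
}

#' vdiff(Kcm) profile at an off-grid (r, vi)
#'
#' Bilinear interpolation of the mapping in r and vi, returning the
#' vdiff value at each kcm-axis node.
#'
#' @param grid a `kcm_map`.
#' @param r particle radius (m).
#' @param vi incoming velocity (m/s).
#' @return numeric vector along `kcm_axis` (may contain NA).
#' @export
vdiff_profile <- function(grid, r, vi) {
  if (r < min(grid$r_axis) || r > max(grid$r_axis) ||
      vi < min(grid$vi_axis) || vi > max(grid$vi_axis))
    stop("(r, vi) outside the mapping grid hull")
  wr <- .interp_w(grid$r_axis, r)
  wv <- .interp_w(grid$vi_axis, vi)
  v00 <- grid$vdiff[wr$i, , wv$i]
  v10 <- grid$vdiff[wr$i + 1L, , wv$i]
  v01 <- grid$vdiff[wr$i, , wv$i + 1L]
  v11 <- grid$vdiff[wr$i + 1L, , wv$i + 1L]
  v00 * (1 - wr$t) * (1 - wv$t) + v10 * wr$t * (1 - wv$t) +
    v01 * (1 - wr$t) * wv$t + v11 * wr$t * wv$t
}

#' Invert an observation to Re{Kcm}
#'
#' Monotone 1-D interpolation of the vdiff(Kcm) profile at the
#' observation's (r, vi). The reported interval brackets the estimate
#' by inverting vdiff +/- one unit of measurement noise (default
#' 56 um/s, the no-DEP differential-velocity standard deviation).
#' Observations outside the attainable vdiff range are clamped to the
#' nearest axis endpoint and flagged `out_of_range`.
#'
#' @param vi incoming velocity (m/s).
#' @param vdiff differential velocity vi - vo (m/s).
#' @param r particle radius (m).
#' @param grid a `kcm_map`.
#' @param noise measurement noise unit for the interval (m/s).
#' @return list with `estimate`, `lower`, `upper`, `flag` ("" or
#'   "out_of_range").
#' @export
infer_kcm <- function(vi, vdiff, r, grid, noise = 56e-6) {
  prof <- vdiff_profile(grid, r, vi)
  ok <- !is.na(prof)
  k <- grid$kcm_axis[ok]; p <- prof[ok]
  if (length(p) < 2) stop("too few valid mapping nodes at (r, vi)")
  if (any(diff(p) <= 0))
    p <- cummax(p - seq_along(p) * 1e-15) + seq_along(p) * 1e-15
  inv <- function(v) {
    if (v <= p[1]) return(list(k = k[1], oob = v < p[1]))
    if (v >= p[length(p)]) return(list(k = k[length(k)],
                                       oob = v > p[length(p)]))
    list(k = stats::approx(p, k, xout = v)$y, oob = FALSE)
  }
  est <- inv(vdiff)
  lo <- inv(vdiff - noise)$k
  hi <- inv(vdiff + noise)$k
  list(estimate = est$k, lower = min(lo, hi), upper = max(lo, hi),
       flag = if (est$oob) "out_of_range" else "")
}

#' Persist a mapping grid as a self-describing JSON archive
#'
#' @param grid a `kcm_map`.
#' @param path output file.
#' @export
write_kcm_map <- function(grid, path) {
  obj <- list(r_axis = grid$r_axis, kcm_axis = grid$kcm_axis,
              vi_axis = grid$vi_axis,
              vdiff = as.vector(grid$vdiff),
              entry_h = as.vector(grid$entry_h),
              provenance = grid$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read a mapping grid written by [write_kcm_map()]
#' @param path file path.
#' @return a `kcm_map`.
#' @export
read_kcm_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nr <- length(obj$r_axis); nk <- length(obj$kcm_axis)
  nv <- length(obj$vi_axis)
  structure(list(r_axis = obj$r_axis, kcm_axis = obj$kcm_axis,
                 vi_axis = obj$vi_axis,
                 vdiff = array(obj$vdiff, c(nr, nk, nv)),
                 entry_h = matrix(obj$entry_h, nr, nv),
                 provenance = obj$provenance),
            class = "kcm_map")
}
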