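# Electrostatics above the coplanar electrode pair: 2-D Laplace solve in
# the (x, h) channel cross-section, E_rms and grad(E_rms^2), DEP force.
#
# Conventions: x is the flow direction, h the height above the channel
# floor. The two electrodes are zero-thickness equipotential segments on
# the floor, driven anti-phase at +/- V0/2 with amplitude V0 = Vpp/2;
# all other boundaries are insulating (zero normal derivative). For a
# sinusoidal drive E_rms = |E_peak| / sqrt(2).

#' Coplanar electrode layout
#'
#' @param electrode_width electrode width (m), default 35 um.
#' @param gap gap between the electrodes (m), default 25 um.
#' @param vpp applied peak-to-peak voltage (V).
#' @param frequency drive frequency (Hz).
#' @return An object of class `electrode_layout`.
#' @export
electrode_layout <- function(electrode_width = 35e-6, gap = 25e-6,
                             vpp = 8, frequency = 6e6) {
  stopifnot(electrode_width > 0, gap > 0, vpp >= 0, frequency > 0)
  structure(list(electrode_width = electrode_width, gap = gap,
                 vpp = vpp, frequency = frequency),
            class = "electrode_layout")
}

#' Channel geometry for the field solve
#'
#' The simulated x-extent must be at least ten electrode pitches
#' (2 * width + gap) so the insulating side boundaries do not perturb
#' the solution near the electrodes.
#'
#' @param height channel height (m), default 50 um.
#' @param width channel width (m), default 8 mm (not discretised; the
#'   field is assumed invariant across it).
#' @param x_extent simulated length in x (m).
#' @param layout the `electrode_layout` used to validate `x_extent`.
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(height = 50e-6, width = 8e-3,
                             x_extent = NULL,
                             layout = electrode_layout()) {
  pitch <- 2 * layout$electrode_width + layout$gap
  if (is.null(x_extent)) x_extent <- 10 * pitch
  stopifnot(height > 0, width > 0)
  if (x_extent < 10 * pitch)
    stop("x_extent must be at least 10 * (2*electrode_width + gap)")
  structure(list(height = height, width = width, x_extent = x_extent),
            class = "channel_geometry")
}

# Exact potential of two coplanar half-plane electrodes at +/- v0/2
# separated by a gap of half-width a (conformal map of the upper half
# plane), centred at xc, left electrode positive. Satisfies the
# electrode Dirichlet values and the insulating condition on the gap
# segment exactly, and carries the inner-edge field singularities.
# Returns the potential and its gradient.
.coplanar_base <- function(x, h, a, v0, xc) {
  # evaluated on |x - xc| and reflected, so the exact odd/even
  # symmetries about the gap centre hold to the last bit
  xm <- x - xc
  s <- ifelse(xm >= 0, 1, -1)
  z <- complex(real = abs(xm), imaginary = h)
  S <- -1i * sqrt(z - a) * sqrt(z + a)      # = sqrt(a^2 - z^2), branch
                                            # positive on the gap
  w <- (1i * z + S) / a
  f <- 1 / S                                # d arcsin(z/a) / dz
  list(phi = s * (-(v0 / pi) * Arg(w)),     # odd in x - xc
       dx = -(v0 / pi) * Re(f),             # even
       dh = s * ((v0 / pi) * Im(f)))        # odd
}

#' Solve the electrostatic potential above the electrode pair
#'
#' Five-point finite-difference Laplace solve on a uniform grid with a
#' direct sparse factorisation. Dirichlet values +/- V0/2 (V0 = Vpp/2)
#' are imposed on the floor nodes covered by the electrodes (centred in
#' x, left electrode positive); every other boundary node is insulating
#' (zero normal derivative). The solve subtracts the exact
#' conformal-map solution of the infinite coplanar pair, so the
#' electrode inner-edge field singularities are represented
#' analytically and the discretised correction is smooth there; this
#' restores clean grid convergence of the field gradients near the
#' gap. Derived fields: E_rms components, E_rms^2 and its gradient.
#'
#' @param layout an `electrode_layout`.
#' @param geometry a `channel_geometry`.
#' @param grid_step grid spacing (m); values <= 1e-6 recommended.
#' @return An object of class `field_grid` with node vectors `x`, `h`,
#'   matrices (length(x) by length(h)) `phi`, `ex`, `eh`, `e2rms`,
#'   `gx`, `gh`, and metadata. Units: V, V/m, V^2/m^2, V^2/m^3.
#' @export
solve_potential <- function(layout, geometry, grid_step = 0.5e-6) {
  w <- layout$electrode_width; g <- layout$gap
  v0 <- layout$vpp / 2                 # drive amplitude
  L <- geometry$x_extent; H <- geometry$height
  nx <- round(L / grid_step) + 1L
  nh <- round(H / grid_step) + 1L
  x <- seq(0, by = grid_step, length.out = nx)
  h <- seq(0, by = grid_step, length.out = nh)
  xc <- L / 2
  a_gap <- g / 2

  # Dirichlet mask on the floor row (h = 0); values are for the
  # correction u = phi - phi_c (zero up to round-off on the
  # electrodes, since phi_c matches them exactly)
  base_floor <- .coplanar_base(x, 0, a_gap, v0, xc)
  on_left  <- x >= xc - g / 2 - w & x <= xc - g / 2
  on_right <- x >= xc + g / 2 & x <= xc + g / 2 + w
  dir_val <- rep(NA_real_, nx)
  dir_val[on_left]  <- +v0 / 2 - base_floor$phi[on_left]
  dir_val[on_right] <- -v0 / 2 - base_floor$phi[on_right]

  idx <- matrix(seq_len(nx * nh), nx, nh)   # node numbering, x fastest
  is_dir <- matrix(FALSE, nx, nh)
  is_dir[, 1] <- !is.na(dir_val)
  phi_dir <- matrix(0, nx, nh)
  phi_dir[, 1][is_dir[, 1]] <- dir_val[!is.na(dir_val)]

  # boundary flux of the correction: du/dn = -dphi_c/dn on insulating
  # boundaries (zero in the gap by construction of phi_c)
  base_top <- .coplanar_base(x, H, a_gap, v0, xc)
  base_left <- .coplanar_base(rep(0, nh), h, a_gap, v0, xc)
  base_right <- .coplanar_base(rep(L, nh), h, a_gap, v0, xc)

  # Assemble the 5-point Laplacian with mirror (Neumann) closure:
  # a neighbour outside the domain is replaced by the opposite
  # interior neighbour, which doubles that coefficient.
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  rhs <- numeric(nx * nh)
  add <- function(from, to, val) {
    ii <<- c(ii, from); jj <<- c(jj, to); vv <<- c(vv, rep_len(val, length(from)))
  }
  # Build in vectorised blocks over all nodes.
  all_i <- rep(seq_len(nx), nh)
  all_j <- rep(seq_len(nh), each = nx)
  k <- idx[cbind(all_i, all_j)]
  dir_k <- is_dir[cbind(all_i, all_j)]

  # Diagonal -4 for unknowns; identity for Dirichlet nodes.
  add(k[dir_k], k[dir_k], 1)
  rhs[k[dir_k]] <- phi_dir[cbind(all_i, all_j)][dir_k]
  ku <- k[!dir_k]; iu <- all_i[!dir_k]; ju <- all_j[!dir_k]
  add(ku, ku, -4)
  neigh <- function(di, dj) {
    ni <- iu + di; nj <- ju + dj
    out <- ni < 1L | ni > nx | nj < 1L | nj > nh
    # mirror across the boundary, with the correction's flux entering
    # the RHS (sign follows the outward direction of the neighbour)
    if (any(out)) {
      flux <- numeric(sum(out))
      io <- iu[out]; jo <- ju[out]
      if (dj != 0L) {
        bb <- if (dj > 0L) base_top else base_floor
        flux <- dj * bb$dh[io]
      } else {
        bb <- if (di > 0L) base_right else base_left
        flux <- di * bb$dx[jo]
      }
      rhs[ku[out]] <<- rhs[ku[out]] + 2 * grid_step * flux
    }
    ni <- ifelse(ni < 1L, 2L, ifelse(ni > nx, nx - 1L, ni))
    nj <- ifelse(nj < 1L, 2L, ifelse(nj > nh, nh - 1L, nj))
    nk <- idx[cbind(ni, nj)]
    ndir <- is_dir[cbind(ni, nj)]
    # Dirichlet neighbours contribute to the RHS
    rhs[ku[ndir]] <<- rhs[ku[ndir]] - phi_dir[cbind(ni, nj)][ndir]
    add(ku[!ndir], nk[!ndir], 1)
  }
  neigh(-1L, 0L); neigh(1L, 0L); neigh(0L, -1L); neigh(0L, 1L)

  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                            dims = c(nx * nh, nx * nh))
  sol <- Matrix::solve(A, rhs)
  u <- matrix(as.numeric(sol), nx, nh)
  # the continuum solution is exactly odd about the gap centre
  # (electrodes centred, anti-phase drive); project out the solver's
  # round-off asymmetry
  u <- (u - u[nx:1, , drop = FALSE]) / 2

  res <- as.numeric(A %*% sol - rhs)
  resid <- max(abs(res))
  if (v0 > 0 && resid > 1e-8 * v0)
    stop(sprintf("field solve residual %.3g exceeds tolerance %.3g",
                 resid, 1e-8 * v0))

  # Analytic base on all nodes; at the two electrode-edge nodes the
  # base gradient is singular, so those entries are evaluated a
  # quarter-cell above the floor.
  base <- .coplanar_base(rep(x, nh), rep(h, each = nx), a_gap, v0, xc)
  phi_c <- matrix(base$phi, nx, nh)
  dxc <- matrix(base$dx, nx, nh)
  dhc <- matrix(base$dh, nx, nh)
  bad <- which(!is.finite(dxc) | !is.finite(dhc))
  if (length(bad)) {
    bi <- (bad - 1) %% nx + 1; bj <- (bad - 1) %/% nx + 1
    rb <- .coplanar_base(x[bi], h[bj] + grid_step / 4, a_gap, v0, xc)
    dxc[bad] <- rb$dx; dhc[bad] <- rb$dh
  }
  phi <- u + phi_c

  # Peak field components: analytic base gradient plus central
  # differences of the smooth correction (one-sided at edges)
  ddx <- function(m) {
    d <- m
    d[2:(nx - 1), ] <- (m[3:nx, ] - m[1:(nx - 2), ]) / (2 * grid_step)
    d[1, ] <- (m[2, ] - m[1, ]) / grid_step
    d[nx, ] <- (m[nx, ] - m[nx - 1, ]) / grid_step
    d
  }
  ddh <- function(m) {
    d <- m
    d[, 2:(nh - 1)] <- (m[, 3:nh] - m[, 1:(nh - 2)]) / (2 * grid_step)
    d[, 1] <- (m[, 2] - m[, 1]) / grid_step
    d[, nh] <- (m[, nh] - m[, nh - 1]) / grid_step
    d
  }
  ex <- -(ddx(u) + dxc); eh <- -(ddh(u) + dhc)
  e2rms <- (ex^2 + eh^2) / 2          # rms for sinusoidal drive
  gx <- ddx(e2rms); gh <- ddh(e2rms)

  structure(list(x = x, h = h, phi = phi, ex = ex, eh = eh,
                 e2rms = e2rms, gx = gx, gh = gh,
                 grid_step = grid_step, layout = layout,
                 geometry = geometry, residual = resid,
                 x_center = xc,
                 x_e1 = xc - g / 2 - w, x_e2 = xc + g / 2 + w),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat("Electrostatic field grid\n")
  cat(sprintf("  %d x %d nodes, step %.3g um\n", length(x$x), length(x$h),
              x$grid_step * 1e6))
  cat(sprintf("  Vpp = %g V, electrodes %g/%g um (width/gap)\n",
              x$layout$vpp, x$layout$electrode_width * 1e6,
              x$layout$gap * 1e6))
  cat(sprintf("  Laplace residual: %.3g V\n", x$residual))
  invisible(x)
}

#' @export
plot.field_grid <- function(x, what = c("phi", "e2rms"), ...) {
  what <- match.arg(what)
  graphics::image(x$x * 1e6, x$h * 1e6, x[[what]],
                  xlab = "x (um)", ylab = "h (um)", main = what, ...)
  invisible(x)
}

# Bilinear interpolation of one field component at (xq, hq)
interp_grid <- function(field, m, xq, hq) {
  x <- field$x; h <- field$h
  if (any(xq < x[1] | xq > x[length(x)] | hq < h[1] | hq > h[length(h)]))
    stop("query point outside the field grid")
  ix <- pmin(pmax(findInterval(xq, x), 1L), length(x) - 1L)
  ih <- pmin(pmax(findInterval(hq, h), 1L), length(h) - 1L)
  tx <- (xq - x[ix]) / (x[ix + 1] - x[ix])
  th <- (hq - h[ih]) / (h[ih + 1] - h[ih])
  m[cbind(ix, ih)] * (1 - tx) * (1 - th) +
    m[cbind(ix + 1L, ih)] * tx * (1 - th) +
    m[cbind(ix, ih + 1L)] * (1 - tx) * th +
    m[cbind(ix + 1L, ih + 1L)] * tx * th
}

#' Interpolate grad(E_rms^2) at query points
#'
#' @param field a `field_grid`.
#' @param xq,hq query coordinates (m), vectorised.
#' @return list with components `gx`, `gh` (V^2/m^3).
#' @export
grad_e2 <- function(field, xq, hq) {
  list(gx = interp_grid(field, field$gx, xq, hq),
       gh = interp_grid(field, field$gh, xq, hq))
}

#' Time-average DEP force on a spherical particle
#'
#' 2 pi eps0 eps_rm r^3 Re{Kcm} grad(E_rms^2).
#'
#' @param r particle radius (m).
#' @param re_kcm real part of the Clausius-Mossotti factor.
#' @param medium a `dep_medium`.
#' @param grad_e2 list with `gx`, `gh` (V^2/m^3), e.g. from
#'   [grad_e2()].
#' @return list with force components `fx`, `fh` in N.
#' @export
dep_force <- function(r, re_kcm, medium, grad_e2) {
  stopifnot(r > 0)
  pref <- 2 * pi * EPS0 * medium$rel_permittivity * r^3 * re_kcm
  list(fx = pref * grad_e2$gx, fh = pref * grad_e2$gh)
}

#' Export a field grid to CSV
#'
#' Writes a long-format table (x_m, h_m, phi_v, e2rms, gx, gh) preceded
#' by `#`-prefixed header lines recording the layout, geometry and grid
#' step, so the file is self-describing.
#'
#' @param field a `field_grid`.
#' @param path output file.
#' @export
write_field_grid <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(sprintf("# electrode_width=%.9g", field$layout$electrode_width),
           sprintf("# gap=%.9g", field$layout$gap),
           sprintf("# vpp=%.9g", field$layout$vpp),
           sprintf("# frequency=%.9g", field$layout$frequency),
           sprintf("# height=%.9g", field$geometry$height),
           sprintf("# width=%.9g", field$geometry$width),
           sprintf("# x_extent=%.9g", field$geometry$x_extent),
           sprintf("# grid_step=%.9g", field$grid_step))
  writeLines(hdr, con)
  df <- data.frame(x_m = rep(field$x, times = length(field$h)),
                   h_m = rep(field$h, each = length(field$x)),
                   phi_v = as.vector(field$phi),
                   e2rms = as.vector(field$e2rms),
                   gx = as.vector(field$gx),
                   gh = as.vector(field$gh))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a field grid written by [write_field_grid()]
#'
#' @param path file path.
#' @return a `field_grid` (phi/e2rms/gradient fields restored;
#'   `ex`/`eh` are not stored and are returned as NULL).
#' @export
read_field_grid <- function(path) {
  lines <- readLines(path, n = 20)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "="))
  meta <- stats::setNames(as.numeric(kv[, 2]), kv[, 1])
  meta_get <- function(k) unname(meta[[k]])
  df <- utils::read.csv(path, comment.char = "#")
  x <- sort(unique(df$x_m)); h <- sort(unique(df$h_m))
  shape <- function(v) matrix(v, length(x), length(h))
  layout <- electrode_layout(meta_get("electrode_width"), meta_get("gap"),
                             meta_get("vpp"), meta_get("frequency"))
  geometry <- channel_geometry(meta_get("height"), meta_get("width"),
                               meta_get("x_extent"), layout)
  xc <- meta_get("x_extent") / 2
  structure(list(x = x, h = h, phi = shape(df$phi_v), ex = NULL, eh = NULL,
                 e2rms = shape(df$e2rms), gx = shape(df$gx),
                 gh = shape(df$gh), grid_step = meta_get("grid_step"),
                 layout = layout, geometry = geometry, residual = NA_real_,
                 x_center = xc,
                 x_e1 = xc - meta_get("gap") / 2 - meta_get("electrode_width"),
                 x_e2 = xc + meta_get("gap") / 2 + meta_get("electrode_width")),
            class = "field_grid")
}
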