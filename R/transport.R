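# Overdamped particle transport through the channel: parabolic flow,
# gravity/buoyancy, near-wall hydrodynamic lift, wall-corrected Stokes
# drag, DEP force; trajectory integration and pre/post-electrode
# velocity extraction.
#
# Heights h are measured from the channel floor to the particle centre.
# Vertical forces are signed with +h upward.

G_ACCEL <- 9.81

#' Parabolic channel flow profile
#'
#' Laminar pressure-driven flow between parallel plates:
#' v(h) = 6 vbar (h/H)(1 - h/H). Its height-average equals `vbar`.
#'
#' @param h height above the floor (m), in [0, H]; vectorised.
#' @param vbar mean flow velocity (m/s).
#' @param H channel height (m).
#' @return fluid velocity (m/s).
#' @export
fluid_velocity <- function(h, vbar, H) {
  if (any(h < 0 | h > H)) stop("height outside the channel")
  6 * vbar * (h / H) * (1 - h / H)
}

#' Net gravity + buoyancy force
#'
#' Signed vertical force (4/3) pi g r^3 (rho_p - rho_m), negative
#' (downward) when the particle is denser than the medium.
#'
#' @param r particle radius (m).
#' @param rho_p,rho_m particle and medium mass densities (kg/m^3).
#' @return signed vertical force (N), + up.
#' @export
gravity_buoyancy <- function(r, rho_p, rho_m) {
  stopifnot(r > 0)
  -(4 / 3) * pi * G_ACCEL * r^3 * (rho_p - rho_m)
}

#' Near-wall hydrodynamic lift force
#'
#' Lift pushing the particle away from the nearest wall, diverging at
#' wall contact and vanishing at mid-channel. The default closure is
#'
#'   F = 6 C eta vbar r^3 (r/H)^2 / gap^2,
#'
#' where gap is the clearance between the particle surface and the
#' nearest wall. The (r/H)^2 confinement scaling makes the lift/weight
#' balance of 9-16 um cells settle at heights whose advection velocity
#' is in the device's 800-1200 um/s operating band, and keeps the lift
#' relaxation slow relative to electrode transit so DEP-induced height
#' changes persist downstream (the quantity the cytometer measures).
#' The closure is pluggable through `form`; [lift_clearance_sq()] gives
#' the unscaled 6 C eta vbar r^3 / gap^2 alternative.
#'
#' @param h particle centre height (m).
#' @param r particle radius (m).
#' @param vbar mean flow velocity (m/s).
#' @param eta medium viscosity (Pa s).
#' @param H channel height (m).
#' @param C dimensionless lift coefficient (default 0.31).
#' @param form optional function(gap, r, vbar, eta, H, C) returning the
#'   unsigned magnitude.
#' @return signed vertical force (N), + up (away from the floor).
#' @export
lift_force <- function(h, r, vbar, eta, H, C = 0.31, form = NULL) {
  stopifnot(r > 0, H > 0)
  s <- sign(H / 2 - h)                       # away from nearest wall
  gap <- pmin(h, H - h) - r
  if (any(gap <= 0)) {
    warning("particle in wall contact; clamping clearance to 10 nm")
    gap <- pmax(gap, 1e-8)
  }
  mag <- if (is.null(form)) 6 * C * eta * vbar * r^3 * (r / H)^2 / gap^2
         else form(gap, r, vbar, eta, H, C)
  s * mag
}

#' Unscaled inverse-square-clearance lift closure
#'
#' Alternative lift magnitude 6 C eta vbar r^3 / gap^2 without the
#' confinement scaling, usable as the `form`/`lift_form` argument.
#'
#' @param gap surface-to-wall clearance (m).
#' @param r,vbar,eta,H,C see [lift_force()].
#' @return unsigned force magnitude (N).
#' @export
lift_clearance_sq <- function(gap, r, vbar, eta, H, C) {
  6 * C * eta * vbar * r^3 / gap^2
}

# Single-wall perpendicular drag correction, Brenner-type reciprocal
# series truncated at third order in xi = r/h.
lambda_single_wall <- function(xi) {
  1 / (1 - 9 / 8 * xi + 0.5 * xi^3)
}

#' Two-wall perpendicular drag correction
#'
#' Ratio of the drag on a sphere translating perpendicular to two
#' confining parallel walls to the unbounded Stokes drag. Implemented
#' as the product of two single-wall corrections (truncated reciprocal
#' series at third order in r/distance); a user-supplied table or
#' function can replace it via `TransportParams`.
#'
#' @param h particle centre height (m).
#' @param r particle radius (m), must satisfy r < min(h, H - h).
#' @param H channel height (m).
#' @return lambda >= 1.
#' @export
wall_drag_lambda <- function(h, r, H) {
  if (any(r >= pmin(h, H - h))) stop("particle overlaps a wall")
  lambda_single_wall(r / h) * lambda_single_wall(r / (H - h))
}

#' Transport parameter set
#'
#' @param medium a `dep_medium`.
#' @param r particle radius (m).
#' @param rho_p particle density (kg/m^3), default 1050.
#' @param re_kcm Re{Kcm} at the drive frequency, in [-0.5, 1].
#' @param vbar mean flow velocity (m/s).
#' @param H channel height (m), default 50 um.
#' @param C lift coefficient, default 0.31.
#' @param lambda_fun wall-correction function(h, r, H); defaults to
#'   [wall_drag_lambda()].
#' @param lift_form optional alternative lift closure, see
#'   [lift_force()].
#' @return an object of class `transport_params`.
#' @export
transport_params <- function(medium, r, rho_p = 1050, re_kcm = 0,
                             vbar = 1000e-6, H = 50e-6, C = 0.31,
                             lambda_fun = wall_drag_lambda,
                             lift_form = NULL) {
  stopifnot(r > 0, vbar > 0, H > 0, C >= 0,
            re_kcm >= -0.5, re_kcm <= 1)
  structure(list(medium = medium, r = r, rho_p = rho_p,
                 re_kcm = re_kcm, vbar = vbar, H = H, C = C,
                 lambda_fun = lambda_fun, lift_form = lift_form),
            class = "transport_params")
}

#' Dimensionless-number check for the overdamped model
#'
#' Computes the particle Reynolds and Stokes numbers for the given
#' parameters and warns if either approaches unity, where the
#' quasi-static force balance would lose validity.
#'
#' @param params a `transport_params`.
#' @return invisibly, a named vector with `reynolds` and `stokes`.
#' @export
check_overdamped <- function(params) {
  v <- 1.5 * params$vbar
  rho_m <- params$medium$density
  eta <- params$medium$viscosity
  re <- rho_m * v * 2 * params$r / eta
  tau <- (2 / 9) * params$rho_p * params$r^2 / eta
  stk <- tau * v / params$H
  if (re > 0.1 || stk > 0.1)
    warning(sprintf(
      "overdamped assumption marginal: Re = %.3g, Stk = %.3g", re, stk))
  invisible(c(reynolds = re, stokes = stk))
}

#' Equilibrium height of a flowing particle
#'
#' Height in the lower half-channel where the near-wall lift balances
#' the net weight (no DEP). Found by bisection on (r, H/2).
#'
#' @param params a `transport_params`.
#' @return equilibrium height (m).
#' @export
equilibrium_height <- function(params) {
  H <- params$H; r <- params$r
  eta <- params$medium$viscosity
  fg <- gravity_buoyancy(r, params$rho_p, params$medium$density)
  net <- function(h) {
    lift_force(h, r, params$vbar, eta, H, params$C,
               form = params$lift_form) + fg
  }
  if (fg >= 0) return(H / 2)          # buoyant or neutral: mid-channel
  lo <- r * (1 + 1e-6); hi <- H / 2 * (1 - 1e-9)
  if (net(hi) > 0) return(H / 2)      # lift dominates everywhere below mid
  stats::uniroot(net, c(lo, hi), tol = 1e-12)$root
}

#' Simulate a particle trajectory over the electrode region
#'
#' Integrates the overdamped force balance: horizontal velocity equals
#' the local fluid velocity plus the DEP slip F_DEP,x / (6 pi eta r);
#' vertical velocity is (F_DEP,h + F_lift + F_grav+buoy) /
#' (6 pi eta r lambda(h)). Integration uses x as the independent
#' variable with an adaptive solver (relative tolerance 1e-6), from
#' `x_start` to `x_start + x_span`. The trajectory terminates early,
#' flagged `captured`, if the particle reaches wall contact (pDEP
#' capture at the floor or pinning at the ceiling).
#'
#' Incoming and outgoing velocities are least-squares slopes of x(t)
#' over the windows upstream of `x_e1 - margin` and downstream of
#' `x_e2 + margin`, where `x_e1`/`x_e2` are the outer electrode edges
#' stored in the field grid.
#'
#' @param entry_h entry height of the particle centre (m); defaults to
#'   the equilibrium height.
#' @param params a `transport_params`.
#' @param field a `field_grid` whose x-range covers the span.
#' @param x_start,x_span integration start and length (m); default the
#'   full field grid extent.
#' @param margin exclusion margin around the electrodes for the
#'   velocity fits (m), default 50 um.
#' @param n_out number of output samples along x.
#' @return an object of class `dep_trajectory`: data frame `path`
#'   (t_s, x_m, h_m, vx_m_per_s), logical `captured`, and the fitted
#'   `vi`, `vo`, `vdiff` (m/s).
#' @export
simulate_trajectory <- function(params, field, entry_h = NULL,
                                x_start = NULL, x_span = NULL,
                                margin = 50e-6, n_out = 400) {
  check_overdamped(params)
  r <- params$r; H <- params$H
  eta <- params$medium$viscosity
  if (is.null(entry_h)) entry_h <- equilibrium_height(params)
  if (is.null(x_start)) x_start <- field$x[1]
  if (is.null(x_span)) x_span <- field$x[length(field$x)] - x_start
  if (entry_h < r || entry_h > H - r) stop("entry height out of bounds")
  fg <- gravity_buoyancy(r, params$rho_p, params$medium$density)
  drag <- 6 * pi * eta * r
  pref <- 2 * pi * EPS0 * params$medium$rel_permittivity * r^3 *
    params$re_kcm

  xr <- range(field$x)
  rhs <- function(x, state, parms) {
    h <- min(max(state[1], r * (1 + 1e-9)), H - r * (1 + 1e-9))
    x <- min(max(x, xr[1]), xr[2])
    g2 <- grad_e2(field, x, h)
    fdep_x <- pref * g2$gx
    fdep_h <- pref * g2$gh
    fl <- lift_force(h, r, params$vbar, eta, H, params$C,
                     form = params$lift_form)
    vx <- fluid_velocity(h, params$vbar, H) + fdep_x / drag
    vx <- max(vx, 1e-9)                      # forward advection
    vh <- (fdep_h + fl + fg) / (drag * params$lambda_fun(h, r, H))
    list(c(vh / vx, 1 / vx))
  }
  root <- function(x, state, parms) {
    c(state[1] - r * (1 + 1e-6), (H - r * (1 + 1e-6)) - state[1])
  }
  xs <- seq(x_start, x_start + x_span, length.out = n_out)
  sol <- deSolve::ode(y = c(h = entry_h, t = 0), times = xs, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-6, atol = c(1e-12, 1e-9),
                      events = list(root = TRUE), rootfun = root)
  sol <- as.data.frame(sol)
  names(sol) <- c("x_m", "h_m", "t_s")
  # captured: wall contact terminated the integration, or the particle
  # stalled (advection velocity collapsed under an opposing DEP slip
  # at an electrode edge -- a pDEP trap)
  vx_seg <- diff(sol$x_m) / pmax(diff(sol$t_s), .Machine$double.eps)
  captured <- nrow(sol) < n_out ||
    sol$h_m[nrow(sol)] <= r * (1 + 2e-6) ||
    sol$h_m[nrow(sol)] >= H - r * (1 + 2e-6) ||
    any(vx_seg < 0.02 * params$vbar)
  vx <- c(diff(sol$x_m) / pmax(diff(sol$t_s), .Machine$double.eps),
          NA_real_)
  path <- data.frame(t_s = sol$t_s, x_m = sol$x_m, h_m = sol$h_m,
                     vx_m_per_s = vx)
  obs <- velocity_observation(path, c(field$x_e1, field$x_e2), margin)
  structure(list(path = path, captured = captured,
                 vi = obs$vi, vo = obs$vo, vdiff = obs$vdiff,
                 flags = obs$flags, params = params,
                 entry_h = entry_h),
            class = "dep_trajectory")
}

# Least-squares slopes of x(t) before/after the electrode window.
velocity_observation <- function(path, electrode_window, margin) {
  pre <- path$x_m < electrode_window[1] - margin
  post <- path$x_m > electrode_window[2] + margin
  slope <- function(sel) {
    if (sum(sel, na.rm = TRUE) < 3) return(NA_real_)
    stats::coef(stats::lm(x_m ~ t_s, data = path[sel, ]))[["t_s"]]
  }
  vi <- slope(pre); vo <- slope(post)
  flags <- character(0)
  if (is.na(vi) || is.na(vo)) flags <- "partial"
  list(vi = vi, vo = vo, vdiff = vi - vo, flags = flags)
}

#' @export
print.dep_trajectory <- function(x, ...) {
  cat("DEP trajectory\n")
  cat(sprintf("  entry h = %.2f um, r = %.2f um, Re{Kcm} = %.3f\n",
              x$entry_h * 1e6, x$params$r * 1e6, x$params$re_kcm))
  cat(sprintf("  vi = %.1f um/s, vo = %.1f um/s, vdiff = %.1f um/s\n",
              x$vi * 1e6, x$vo * 1e6, x$vdiff * 1e6))
  if (x$captured) cat("  flagged: captured (wall contact or electrode-edge stall)\n")
  invisible(x)
}

#' @export
plot.dep_trajectory <- function(x, ...) {
  graphics::plot(x$path$x_m * 1e6, x$path$h_m * 1e6, type = "l",
                 xlab = "x (um)", ylab = "h (um)", ...)
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Columns t_s, x_m, h_m, vx_m_per_s.
#' @param x a `dep_trajectory`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(x, path) {
  utils::write.csv(x$path, path, row.names = FALSE)
  invisible(path)
}
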