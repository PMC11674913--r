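# Shared fixtures (cached across test files) and independent oracles.

.fx <- new.env(parent = emptyenv())

cho_medium <- function() dep_medium(78, 0.17, density = 1017.5)

# Default-device field grid, solved once per test run
default_field <- function(grid_step = 0.5e-6) {
  key <- sprintf("field_%g", grid_step)
  if (is.null(.fx[[key]])) {
    lay <- electrode_layout(vpp = 8, frequency = 6e6)
    .fx[[key]] <- solve_potential(lay, channel_geometry(layout = lay),
                                  grid_step)
  }
  .fx[[key]]
}

# Standard mapping grid over the device's operating band
default_mapping <- function() {
  if (is.null(.fx$mapping)) {
    fg <- default_field()
    p <- transport_params(cho_medium(), r = 5e-6, re_kcm = 0,
                          vbar = 1000e-6)
    .fx$mapping <- build_mapping(
      p, fg,
      r_axis = c(4.5, 5.5, 6.5, 7.5) * 1e-6,
      kcm_axis = c(-0.3, -0.1, 0.1, 0.3, 0.5),
      vi_axis = c(780, 960, 1140, 1320, 1480) * 1e-6)
  }
  .fx$mapping
}

# --- independent oracles -------------------------------------------------

# Closed-form |E| for two coplanar half-plane electrodes at +/- V0/2
# separated by a gap of half-width a (conformal map of the upper half
# plane): |E|(x, h) = (V0 / pi) / |sqrt(a^2 - z^2)|, z = x + i h.
conformal_gap_field <- function(x, h, a, v0) {
  z <- complex(real = x, imaginary = h)
  (v0 / pi) / Mod(sqrt(a^2 - z^2))
}

# Fixed-step RK4 integration of the same overdamped force balance in x,
# independent of deSolve; used as the fine-step trajectory oracle.
rk4_trajectory <- function(params, field, entry_h, x_start, x_end, dx,
                           margin = 50e-6) {
  r <- params$r; H <- params$H
  eta <- params$medium$viscosity
  fgv <- gravity_buoyancy(r, params$rho_p, params$medium$density)
  drag <- 6 * pi * eta * r
  pref <- 2 * pi * EPS0 * params$medium$rel_permittivity * r^3 *
    params$re_kcm
  deriv <- function(x, h) {
    h <- min(max(h, r * (1 + 1e-9)), H - r * (1 + 1e-9))
    g2 <- grad_e2(field, x, h)
    fl <- lift_force(h, r, params$vbar, eta, H, params$C)
    vx <- fluid_velocity(h, params$vbar, H) + pref * g2$gx / drag
    vh <- (pref * g2$gh + fl + fgv) /
      (drag * params$lambda_fun(h, r, H))
    c(dhdx = vh / vx, dtdx = 1 / vx)
  }
  xs <- seq(x_start, x_end, by = dx)
  h <- entry_h; t <- 0
  out <- matrix(NA_real_, length(xs), 3)
  out[1, ] <- c(xs[1], h, t)
  for (i in seq_len(length(xs) - 1)) {
    x <- xs[i]
    k1 <- deriv(x, h)
    k2 <- deriv(x + dx / 2, h + dx / 2 * k1[1])
    k3 <- deriv(x + dx / 2, h + dx / 2 * k2[1])
    k4 <- deriv(x + dx, h + dx * k3[1])
    h <- h + dx / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    t <- t + dx / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    out[i + 1, ] <- c(xs[i + 1], h, t)
  }
  df <- data.frame(x_m = out[, 1], h_m = out[, 2], t_s = out[, 3])
  pre <- df$x_m < field$x_e1 - margin
  post <- df$x_m > field$x_e2 + margin
  vi <- stats::coef(stats::lm(x_m ~ t_s, df[pre, ]))[[2]]
  vo <- stats::coef(stats::lm(x_m ~ t_s, df[post, ]))[[2]]
  list(vi = vi, vo = vo, vdiff = vi - vo, path = df)
}

# Brute-force optimal assignment (full enumeration incl. opt-outs);
# independent of the package's subnet decomposition. Rows whose single
# feasible column is contested by no other row are assigned outright
# (taking a feasible column is never worse than the opt-out penalty),
# which keeps the residual enumeration tiny.
brute_force_assignment <- function(cost, max_cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- rep(NA_integer_, nr)
  if (nr == 0) return(best)
  cand <- lapply(seq_len(nr), function(i) which(cost[i, ] <= max_cost))
  free_rows <- seq_len(nr); free_cols <- rep(TRUE, nc)
  repeat {
    done <- FALSE
    for (i in free_rows) {
      cc <- cand[[i]][free_cols[cand[[i]]]]
      if (length(cc) == 1) {
        others <- setdiff(free_rows, i)
        contested <- any(vapply(others, function(k)
          cc %in% cand[[k]][free_cols[cand[[k]]]], logical(1)))
        if (!contested) {
          best[i] <- cc; free_cols[cc] <- FALSE
          free_rows <- setdiff(free_rows, i)
          done <- TRUE
          break
        }
      } else if (length(cc) == 0) {
        free_rows <- setdiff(free_rows, i)   # stays NA
        done <- TRUE
        break
      }
    }
    if (!done) break
  }
  if (!length(free_rows)) return(best)
  rs <- free_rows
  sub_best <- rep(NA_integer_, length(rs)); sub_cost <- Inf
  ord <- order(vapply(rs, function(i)
    length(cand[[i]][free_cols[cand[[i]]]]), integer(1)))
  rs <- rs[ord]
  rec <- function(i, used, cur, acc) {
    if (acc >= sub_cost) return()
    if (i > length(rs)) { sub_best <<- cur; sub_cost <<- acc; return() }
    r <- rs[i]
    cc <- cand[[r]][free_cols[cand[[r]]]]
    for (j in cc[order(cost[r, cc])]) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(i + 1, used, c(cur, j), acc + cost[r, j])
        used[j] <- FALSE
      }
    }
    rec(i + 1, used, c(cur, NA_integer_), acc + max_cost)
  }
  rec(1L, rep(FALSE, nc), integer(0), 0)
  best[rs] <- sub_best
  best
}

# Independent frame-by-frame linker built on the brute-force
# assignment (same linking model, separate implementation).
oracle_link <- function(detections, max_disp, memory = 2,
                        min_length = 5) {
  frames <- sort(unique(detections$frame))
  pid <- rep(NA_integer_, nrow(detections))
  act <- list(); next_id <- 1L
  for (f in frames) {
    rows <- which(detections$frame == f)
    dx <- detections$x_px[rows]; dy <- detections$y_px[rows]
    act <- Filter(function(a) f - a$last <= memory + 1, act)
    asg <- if (length(act)) {
      pred <- t(vapply(act, function(a)
        c(a$x + a$vx * (f - a$last), a$y + a$vy * (f - a$last)),
        numeric(2)))
      cost <- outer(pred[, 1], dx, "-")^2 + outer(pred[, 2], dy, "-")^2
      brute_force_assignment(cost, max_disp^2)
    } else integer(0)
    used <- rep(FALSE, length(rows))
    for (i in seq_along(asg)) {
      j <- asg[i]
      if (is.na(j)) next
      a <- act[[i]]; dt <- f - a$last
      act[[i]]$vx <- (dx[j] - a$x) / dt; act[[i]]$vy <- (dy[j] - a$y) / dt
      act[[i]]$x <- dx[j]; act[[i]]$y <- dy[j]; act[[i]]$last <- f
      act[[i]]$n <- a$n + 1L
      pid[rows[j]] <- a$id; used[j] <- TRUE
    }
    for (j in which(!used)) {
      act[[length(act) + 1]] <- list(id = next_id, x = dx[j], y = dy[j],
                                     vx = 0, vy = 0, last = f, n = 1L)
      pid[rows[j]] <- next_id; next_id <- next_id + 1L
    }
  }
  counts <- table(pid)
  keep <- as.integer(names(counts)[counts >= min_length])
  out <- detections
  out$particle_id <- pid
  out[out$particle_id %in% keep, ]
}

# Same-track co-membership agreement between two linkings of the same
# detection table (pairwise Rand-style agreement on consecutive-frame
# pairs).
linking_agreement <- function(a, b) {
  key <- function(d) paste(d$frame, round(d$x_px, 3), round(d$y_px, 3))
  ka <- key(a); kb <- key(b)
  common <- intersect(ka, kb)
  ia <- match(common, ka); ib <- match(common, kb)
  pa <- a$particle_id[ia]; pb <- b$particle_id[ib]
  fr <- a$frame[ia]
  agree <- 0L; total <- 0L
  for (f in sort(unique(fr))[-1]) {
    cur <- which(fr == f); prev <- which(fr == f - 1)
    if (!length(cur) || !length(prev)) next
    for (i in cur) {
      pa_prev <- prev[pa[prev] == pa[i]]
      pb_prev <- prev[pb[prev] == pb[i]]
      total <- total + 1L
      same <- (length(pa_prev) == length(pb_prev)) &&
        all(sort(pa_prev) == sort(pb_prev))
      agree <- agree + as.integer(same)
    }
  }
  agree / max(total, 1L)
}
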