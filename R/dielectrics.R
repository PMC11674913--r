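# Dielectric models: complex permittivities, confocal shelled-sphere
# reduction, Clausius-Mossotti spectra, crossover and sensitivity analysis.

#' Vacuum permittivity (F/m)
#'
#' Fixed physical constant used throughout the package.
#' @export
EPS0 <- 8.854187817e-12

#' Suspension medium
#'
#' Describes the aqueous suspension medium by its relative permittivity,
#' conductivity, mass density and dynamic viscosity.
#'
#' @param rel_permittivity dimensionless relative permittivity (>= 1).
#' @param conductivity electrical conductivity in S/m (>= 0).
#' @param density mass density in kg/m^3.
#' @param viscosity dynamic viscosity in Pa s.
#' @return An object of class `dep_medium`.
#' @examples
#' dep_medium(78, 0.17)
#' @export
dep_medium <- function(rel_permittivity = 78, conductivity = 0.17,
                       density = 1017.5, viscosity = 1e-3) {
  stopifnot(rel_permittivity >= 1, conductivity >= 0,
            density > 0, viscosity > 0)
  structure(list(rel_permittivity = rel_permittivity,
                 conductivity = conductivity,
                 density = density,
                 viscosity = viscosity),
            class = "dep_medium")
}

#' Double-shell dielectric model of a cell
#'
#' Concentric-sphere representation of a nucleated cell: nucleoplasm,
#' nuclear envelope, cytoplasm and plasma membrane. `r_n` is the outer
#' radius of the nucleus including its envelope; the nucleoplasm radius
#' is `r_n - d_n`. Permittivities are given as multiples of the vacuum
#' permittivity.
#'
#' @param r_cell cell radius (m).
#' @param r_n outer nucleus radius (m); default 0.55 * r_cell.
#' @param d_n nuclear envelope thickness (m).
#' @param d_mem plasma membrane thickness (m).
#' @param sigma_mem,sigma_ne,sigma_cyt,sigma_n conductivities (S/m) of
#'   membrane, nuclear envelope, cytoplasm and nucleoplasm.
#' @param eps_mem,eps_ne,eps_cyt,eps_n relative permittivities of the
#'   same compartments (multiples of EPS0, all >= 1).
#' @return An object of class `double_shell_cell`.
#' @export
double_shell_cell <- function(r_cell, r_n = 0.55 * r_cell,
                              d_n = 40e-9, d_mem = 5e-9,
                              sigma_mem = 1e-6, sigma_ne = 1e-3,
                              sigma_cyt = 0.53, sigma_n = 1.5,
                              eps_mem = 8.5, eps_ne = 11.5,
                              eps_cyt = 54.5, eps_n = 120) {
  if (!(0 < r_n - d_n && r_n - d_n < r_n && r_n < r_cell - d_mem &&
        r_cell - d_mem < r_cell))
    stop("inconsistent geometry: require 0 < r_n - d_n < r_n < r_cell - d_mem < r_cell")
  sig <- c(sigma_mem, sigma_ne, sigma_cyt, sigma_n)
  eps <- c(eps_mem, eps_ne, eps_cyt, eps_n)
  stopifnot(all(sig >= 0), all(eps >= 1))
  structure(list(r_cell = r_cell, r_n = r_n, d_n = d_n, d_mem = d_mem,
                 sigma_mem = sigma_mem, sigma_ne = sigma_ne,
                 sigma_cyt = sigma_cyt, sigma_n = sigma_n,
                 eps_mem = eps_mem, eps_ne = eps_ne,
                 eps_cyt = eps_cyt, eps_n = eps_n),
            class = "double_shell_cell")
}

#' Surface-conducting homogeneous sphere
#'
#' Model for polystyrene microspheres: a bulk relative permittivity plus
#' a surface conductance that contributes an effective conductivity
#' 2 * k_surf / r.
#'
#' @param radius sphere radius (m).
#' @param rel_permittivity bulk relative permittivity (dimensionless).
#' @param k_surf surface conductance (S).
#' @return An object of class `pss_sphere`.
#' @export
pss_sphere <- function(radius, rel_permittivity = 2.5, k_surf = 1e-9) {
  stopifnot(radius > 0, k_surf >= 0, rel_permittivity >= 1)
  structure(list(radius = radius, rel_permittivity = rel_permittivity,
                 k_surf = k_surf,
                 conductivity = 2 * k_surf / radius),
            class = "pss_sphere")
}

#' Bundled particle and medium presets
#'
#' Reads one of the parameter files shipped with the package
#' (`cho_viable`, `cho_nonviable`, `pss_10um`, `pss_15p7um`) and returns
#' the corresponding model object. Files are plain YAML with SI units.
#'
#' @param name preset name.
#' @return A `double_shell_cell` or `pss_sphere`.
#' @export
dep_preset <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "depcyto")
  if (path == "") stop("unknown preset: ", name)
  p <- yaml::read_yaml(path)
  if (identical(p$model, "double_shell")) {
    double_shell_cell(r_cell = p$r_cell, r_n = p$r_n_fraction * p$r_cell,
                      d_n = p$d_n, d_mem = p$d_mem,
                      sigma_mem = p$sigma_mem, sigma_ne = p$sigma_ne,
                      sigma_cyt = p$sigma_cyt, sigma_n = p$sigma_n,
                      eps_mem = p$eps_mem, eps_ne = p$eps_ne,
                      eps_cyt = p$eps_cyt, eps_n = p$eps_n)
  } else if (identical(p$model, "surface_conducting_sphere")) {
    pss_sphere(radius = p$radius, rel_permittivity = p$rel_permittivity,
               k_surf = p$k_surf)
  } else stop("unrecognised model type in preset file: ", p$model)
}

#' Complex permittivity of a lossy dielectric
#'
#' eps0 * eps_r - i * sigma / (2 pi f), vectorised over frequency.
#'
#' @param eps_r relative permittivity (>= 1).
#' @param sigma conductivity (S/m, >= 0).
#' @param f frequency (Hz, > 0); may be a vector.
#' @return complex permittivity in F/m.
#' @export
complex_permittivity <- function(eps_r, sigma, f) {
  if (any(f <= 0)) stop("frequency must be positive")
  stopifnot(eps_r >= 1, sigma >= 0)
  complex(real = EPS0 * eps_r, imaginary = -sigma / (2 * pi * f))
}

#' Clausius-Mossotti factor
#'
#' Contrast factor (ep - em) / (ep + 2 em) between particle and medium
#' complex permittivities. Governs the sign and magnitude of the DEP
#' force.
#'
#' @param eps_p,eps_m complex permittivities (F/m) of particle and medium.
#' @return complex Kcm (vectorised).
#' @export
clausius_mossotti <- function(eps_p, eps_m) {
  den <- eps_p + 2 * eps_m
  if (any(Mod(den) == 0)) stop("degenerate permittivity pair: eps_p + 2*eps_m = 0")
  (eps_p - eps_m) / den
}

#' Confocal shelled-sphere reduction
#'
#' Replaces a core of permittivity `eps_inner` (radius `r_inner`) coated
#' by a shell `eps_shell` (outer radius `r_outer`) with a single
#' homogeneous sphere of equivalent complex permittivity:
#' eps_shell * (g^3 + 2K) / (g^3 - K), with g = r_outer / r_inner and
#' K the core/shell Clausius-Mossotti factor. Exact identity for a
#' matched shell or zero shell thickness.
#'
#' @param eps_inner,eps_shell complex permittivities (F/m).
#' @param r_inner,r_outer radii (m), 0 < r_inner <= r_outer.
#' @return complex equivalent permittivity (F/m).
#' @export
shell_reduce <- function(eps_inner, eps_shell, r_inner, r_outer) {
  stopifnot(r_inner > 0, r_outer >= r_inner)
  g3 <- (r_outer / r_inner)^3
  K <- (eps_inner - eps_shell) / (eps_inner + 2 * eps_shell)
  if (any(Mod(g3 - K) < .Machine$double.eps * Mod(g3 + 2 * K)))
    stop("degenerate shell reduction: g^3 = K")
  eps_shell * (g3 + 2 * K) / (g3 - K)
}

#' Equivalent complex permittivity of a particle model
#'
#' For a `double_shell_cell`, performs the three nested confocal
#' reductions (nucleoplasm|envelope, then |cytoplasm, then |membrane).
#' For a `pss_sphere`, uses the bulk permittivity with the effective
#' surface conductivity 2 k_surf / r. Vectorised over frequency.
#'
#' @param model a `double_shell_cell` or `pss_sphere`.
#' @param f frequency (Hz).
#' @return complex permittivity (F/m), same length as `f`.
#' @export
particle_permittivity <- function(model, f) {
  UseMethod("particle_permittivity")
}

#' @export
particle_permittivity.double_shell_cell <- function(model, f) {
  m <- model
  e_np  <- complex_permittivity(m$eps_n,   m$sigma_n,   f)
  e_ne  <- complex_permittivity(m$eps_ne,  m$sigma_ne,  f)
  e_cyt <- complex_permittivity(m$eps_cyt, m$sigma_cyt, f)
  e_mem <- complex_permittivity(m$eps_mem, m$sigma_mem, f)
  e1 <- shell_reduce(e_np, e_ne, m$r_n - m$d_n, m$r_n)
  e2 <- shell_reduce(e1, e_cyt, m$r_n, m$r_cell - m$d_mem)
  shell_reduce(e2, e_mem, m$r_cell - m$d_mem, m$r_cell)
}

#' @export
particle_permittivity.pss_sphere <- function(model, f) {
  complex_permittivity(model$rel_permittivity, model$conductivity, f)
}

#' Particle radius accessor
#' @param model a particle model object.
#' @return radius in m.
#' @export
particle_radius <- function(model) {
  if (inherits(model, "double_shell_cell")) model$r_cell
  else if (inherits(model, "pss_sphere")) model$radius
  else stop("unknown particle model")
}

#' Default logarithmic frequency grid
#'
#' 400 points from 10 kHz to 1 GHz, covering the beta-dispersion window.
#' @param n number of points.
#' @param from,to frequency range (Hz).
#' @return numeric vector of frequencies.
#' @export
default_frequency_grid <- function(n = 400, from = 1e4, to = 1e9) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Clausius-Mossotti spectrum of a particle in a medium
#'
#' Evaluates Kcm(f) on a frequency grid and locates crossover
#' frequencies (sign changes of Re{Kcm}) by bisection to a relative
#' tolerance of 1e-6.
#'
#' @param model particle model (`double_shell_cell` or `pss_sphere`).
#' @param medium a `dep_medium`.
#' @param f frequency grid (Hz), strictly positive and sorted.
#' @return An object of class `cmf_spectrum` with components
#'   `frequency_hz`, `kcm` (complex), `crossovers_hz`, `model`, `medium`.
#' @export
cmf_spectrum <- function(model, medium, f = default_frequency_grid()) {
  if (length(f) == 0) stop("empty frequency grid")
  if (any(f <= 0)) stop("frequencies must be positive")
  if (is.unsorted(f)) stop("frequency grid must be sorted")
  em <- complex_permittivity(medium$rel_permittivity, medium$conductivity, f)
  ep <- particle_permittivity(model, f)
  k <- clausius_mossotti(ep, em)
  re_at <- function(fq) {
    Re(clausius_mossotti(
      particle_permittivity(model, fq),
      complex_permittivity(medium$rel_permittivity, medium$conductivity, fq)))
  }
  rk <- Re(k)
  cross <- numeric(0)
  sgn <- sign(rk)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    root <- stats::uniroot(re_at, lower = f[i], upper = f[i + 1],
                           tol = 1e-6 * f[i])
    cross <- c(cross, root$root)
  }
  structure(list(frequency_hz = f, kcm = k, crossovers_hz = cross,
                 model = model, medium = medium),
            class = "cmf_spectrum")
}

#' Evaluate Re{Kcm} at a single frequency
#'
#' Convenience wrapper around [particle_permittivity()] and
#' [clausius_mossotti()].
#'
#' @inheritParams cmf_spectrum
#' @param f frequency (Hz), scalar or vector.
#' @return numeric Re{Kcm}.
#' @export
re_kcm_at <- function(model, medium, f) {
  em <- complex_permittivity(medium$rel_permittivity, medium$conductivity, f)
  Re(clausius_mossotti(particle_permittivity(model, f), em))
}

#' @export
print.cmf_spectrum <- function(x, ...) {
  rk <- Re(x$kcm)
  cat("Clausius-Mossotti spectrum\n")
  cat(sprintf("  frequencies: %d points, %.3g - %.3g Hz\n",
              length(x$frequency_hz), min(x$frequency_hz), max(x$frequency_hz)))
  cat(sprintf("  Re{Kcm} range: [%.4f, %.4f]\n", min(rk), max(rk)))
  if (length(x$crossovers_hz))
    cat("  crossover frequencies (Hz):",
        paste(signif(x$crossovers_hz, 5), collapse = ", "), "\n")
  else cat("  no crossover in grid\n")
  invisible(x)
}

#' @export
plot.cmf_spectrum <- function(x, ...) {
  graphics::plot(x$frequency_hz, Re(x$kcm), type = "l", log = "x",
                 xlab = "frequency (Hz)", ylab = "Re{Kcm}",
                 ylim = c(-0.6, 1), ...)
  graphics::abline(h = 0, lty = 3)
  if (length(x$crossovers_hz))
    graphics::abline(v = x$crossovers_hz, lty = 2, col = "grey50")
  invisible(x)
}

#' Sensitivity band of the Re{Kcm} spectrum
#'
#' Recomputes the spectrum with a single model parameter varied by
#' +/- `fraction` and returns the pointwise lower/upper envelopes.
#' For `r_cell`, the nucleus radius is rescaled as 0.55 * r_cell so the
#' cell keeps its geometric proportions.
#'
#' @inheritParams cmf_spectrum
#' @param parameter name of the field to vary (e.g. `"r_cell"`,
#'   `"sigma_cyt"`).
#' @param fraction relative variation (default 0.2 for +/- 20 %).
#' @return list with `frequency_hz`, `nominal`, `lower`, `upper`
#'   (Re{Kcm} vectors) and the varied parameter values.
#' @export
sensitivity_band <- function(model, medium, f = default_frequency_grid(),
                             parameter, fraction = 0.2) {
  if (!parameter %in% names(model))
    stop("unknown parameter name: ", parameter)
  vary <- function(fac) {
    m <- model
    m[[parameter]] <- model[[parameter]] * fac
    if (identical(parameter, "r_cell") && inherits(model, "double_shell_cell"))
      m$r_n <- 0.55 * m$r_cell
    re_kcm_at(m, medium, f)
  }
  lo <- vary(1 - fraction)
  hi <- vary(1 + fraction)
  nom <- re_kcm_at(model, medium, f)
  list(frequency_hz = f,
       nominal = nom,
       lower = pmin(lo, hi, nom),
       upper = pmax(lo, hi, nom),
       parameter = parameter,
       values = model[[parameter]] * c(1 - fraction, 1 + fraction))
}

#' Write a Clausius-Mossotti spectrum to CSV
#'
#' Columns: frequency_hz, re_kcm, im_kcm.
#' @param x a `cmf_spectrum`.
#' @param path output file.
#' @export
write_spectrum_csv <- function(x, path) {
  df <- data.frame(frequency_hz = x$frequency_hz,
                   re_kcm = Re(x$kcm), im_kcm = Im(x$kcm))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
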