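# Two-population discrimination in (vi, vdiff) space: Gaussian mixture
# fitting by expectation-maximisation, probability ellipses, viability
# fraction and per-cluster size statistics.

# log density of a bivariate normal
.dmvnorm2_log <- function(x, mu, sigma) {
  ch <- chol(sigma)
  z <- backsolve(ch, t(x) - mu, transpose = TRUE)
  -log(2 * pi) - sum(log(diag(ch))) - colSums(z^2) / 2
}

# one EM run from given responsibilities
.em_run <- function(x, resp, tol, max_iter, reg = 1e-6) {
  n <- nrow(x)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    nk <- colSums(resp)
    w <- nk / n
    mu <- lapply(1:2, function(k) colSums(x * resp[, k]) / nk[k])
    sg <- lapply(1:2, function(k) {
      xc <- sweep(x, 2, mu[[k]])
      s <- crossprod(xc * resp[, k], xc) / nk[k]
      if (det(s) < 1e-300 || min(eigen(s, symmetric = TRUE,
                                       only.values = TRUE)$values) < 1e-12) {
        warning("near-singular covariance; diagonal regularisation added")
        s <- s + diag(reg * mean(diag(s)) + 1e-300, 2)
      }
      s
    })
    lg <- vapply(1:2, function(k)
      log(w[k]) + .dmvnorm2_log(x, mu[[k]], sg[[k]]), numeric(n))
    m <- pmax(lg[, 1], lg[, 2])
    ll <- sum(m + log(exp(lg[, 1] - m) + exp(lg[, 2] - m)))
    resp <- exp(lg - m)
    resp <- resp / rowSums(resp)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(weights = w, means = mu, covs = sg, resp = resp,
       loglik = ll, iters = it)
}

#' Fit a two-component Gaussian mixture
#'
#' Full-covariance EM with `n_init` seeded random restarts, keeping the
#' best log-likelihood. The component with the larger mean
#' differential velocity is labelled `pDEP` (viable at 6 MHz), the
#' other `nDEP`. A stability diagnostic reports the spread of the
#' recovered weights across restarts; a large spread signals an
#' effectively single-component sample.
#'
#' @param x two-column matrix or data frame (vi, vdiff); any units.
#' @param seed RNG seed for the restarts.
#' @param n_init number of random restarts (default 10).
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter EM iteration cap per restart.
#' @return an object of class `gmm2`: `weights`, `means` (2x2 matrix,
#'   rows = components), `covs` (list of 2x2), `posterior` (n x 2),
#'   `labels` (factor pDEP/nDEP), `loglik`, `stability` (sd of the
#'   first weight across restarts).
#' @export
fit_two_component_gmm <- function(x, seed = 1, n_init = 10,
                                  tol = 1e-8, max_iter = 500) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 20) stop("need at least 20 points")
  if (ncol(x) != 2) stop("x must have two columns (vi, vdiff)")
  set.seed(seed)
  best <- NULL
  wtrace <- numeric(0)
  for (i in seq_len(n_init)) {
    # responsibilities seeded from two random distinct points
    ctr <- x[sample.int(nrow(x), 2), , drop = FALSE]
    d1 <- rowSums(sweep(x, 2, ctr[1, ])^2)
    d2 <- rowSums(sweep(x, 2, ctr[2, ])^2)
    resp <- cbind(d2, d1) / pmax(d1 + d2, 1e-300)
    fit <- suppressWarnings(.em_run(x, resp, tol, max_iter))
    wtrace <- c(wtrace, fit$weights[1])
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  # order components: larger mean vdiff first -> pDEP
  ord <- order(vapply(best$means, `[`, numeric(1), 2),
               decreasing = TRUE)
  w <- stats::setNames(best$weights[ord], c("pDEP", "nDEP"))
  mu <- do.call(rbind, best$means[ord])
  rownames(mu) <- c("pDEP", "nDEP")
  covs <- best$covs[ord]
  names(covs) <- c("pDEP", "nDEP")
  post <- best$resp[, ord, drop = FALSE]
  colnames(post) <- c("pDEP", "nDEP")
  labels <- factor(ifelse(post[, 1] >= 0.5, "pDEP", "nDEP"),
                   levels = c("pDEP", "nDEP"))
  structure(list(weights = w, means = mu, covs = covs,
                 posterior = post, labels = labels,
                 loglik = best$loglik,
                 stability = stats::sd(pmin(wtrace, 1 - wtrace)),
                 data = x),
            class = "gmm2")
}

#' @export
print.gmm2 <- function(x, ...) {
  cat("Two-component Gaussian mixture (vi, vdiff)\n")
  cat(sprintf("  weights: pDEP %.3f / nDEP %.3f\n",
              x$weights[1], x$weights[2]))
  cat(sprintf("  mean (vi, vdiff): pDEP (%.3g, %.3g), nDEP (%.3g, %.3g)\n",
              x$means[1, 1], x$means[1, 2], x$means[2, 1], x$means[2, 2]))
  cat(sprintf("  log-likelihood %.2f, weight stability sd %.3f\n",
              x$loglik, x$stability))
  invisible(x)
}

#' @export
plot.gmm2 <- function(x, level = 0.75, ...) {
  cols <- c(pDEP = "#2166ac", nDEP = "#b2182b")
  graphics::plot(x$data[, 1], x$data[, 2], col = cols[x$labels],
                 pch = 16, cex = 0.6, xlab = "incoming velocity",
                 ylab = "differential velocity", ...)
  for (k in 1:2) {
    e <- probability_ellipse(list(mean = x$means[k, ],
                                  cov = x$covs[[k]]), level)
    graphics::lines(e$path[, 1], e$path[, 2], col = cols[k], lwd = 2)
  }
  invisible(x)
}

#' Probability ellipse of a bivariate Gaussian component
#'
#' Mahalanobis contour containing the stated probability mass: the
#' squared radius is the chi-squared (2 df) quantile of `level`.
#'
#' @param component list with `mean` (length 2) and `cov` (2x2).
#' @param level probability mass in (0, 1).
#' @param n_points points on the returned polygonal path.
#' @return list with `center`, `semi_axes` (decreasing), `angle`
#'   (radians, major axis vs x) and `path` (n_points x 2 matrix).
#' @export
probability_ellipse <- function(component, level = 0.75,
                                n_points = 181) {
  stopifnot(level > 0, level < 1)
  q <- stats::qchisq(level, df = 2)
  eg <- eigen(component$cov, symmetric = TRUE)
  axes <- sqrt(pmax(eg$values, 0) * q)
  ang <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  th <- seq(0, 2 * pi, length.out = n_points)
  circ <- rbind(axes[1] * cos(th), axes[2] * sin(th))
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  path <- t(rot %*% circ + component$mean)
  list(center = component$mean, semi_axes = axes, angle = ang,
       path = path)
}

#' Viability fraction and per-cluster size statistics
#'
#' The viable fraction is the share of cells labelled pDEP. Per
#' cluster, reports the sample mean and the maximum-likelihood normal
#' fit (mean, sd with denominator n) of the diameters.
#'
#' @param labels factor of cluster labels (levels pDEP/nDEP).
#' @param diameters numeric vector of cell diameters (um), aligned
#'   with `labels`.
#' @return list with `viable_fraction`, `n`, and per-cluster stats
#'   (`mean_um`, `sd_um`, `n`; NA-flagged when a cluster is empty).
#' @export
viability_and_size_stats <- function(labels, diameters) {
  stopifnot(length(labels) == length(diameters))
  n <- length(labels)
  stat1 <- function(d) {
    if (!length(d)) return(list(mean_um = NA_real_, sd_um = NA_real_,
                                n = 0L, empty = TRUE))
    list(mean_um = mean(d),
         sd_um = sqrt(mean((d - mean(d))^2)),   # ML estimate
         n = length(d), empty = FALSE)
  }
  list(viable_fraction = mean(labels == "pDEP"),
       n = n,
       pDEP = stat1(diameters[labels == "pDEP"]),
       nDEP = stat1(diameters[labels == "nDEP"]))
}
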