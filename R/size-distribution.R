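#' Particle size distribution
#'
#' Describes the diameter distribution of a polydisperse nanoparticle
#' ensemble. Two single-component families are supported, both strictly
#' positive: `"lognormal"` (the default; right-skewed, matching typical
#' laser-ablation nanoparticle histograms) and `"truncnorm"` (a normal
#' truncated at zero). Mixtures (e.g. bimodal ensembles) are built with
#' [size_mixture()].
#'
#' Parameters are the *target* mean and standard deviation of the particle
#' diameter in nm: for both families the underlying parameters are solved
#' numerically so that the distribution's actual mean and SD equal `mean`
#' and `sd` (for the truncated normal this means the parent-normal
#' parameters are shifted to compensate for the mass cut at zero).
#'
#' @param mean mean diameter, nm (> 0).
#' @param sd standard deviation of the diameter, nm (>= 0); `sd = 0` is the
#'   degenerate point mass at `mean`.
#' @param kind `"lognormal"` or `"truncnorm"`.
#' @return An object of class `size_distribution`.
#' @examples
#' d <- size_distribution(14, 10)          # mesoporous-Si-in-water ensemble
#' dist_moments(d)
#' @export
size_distribution <- function(mean, sd, kind = c("lognormal", "truncnorm")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(mean), mean > 0, is.numeric(sd), sd >= 0)
  comp <- list(kind = kind, mean = mean, sd = sd, weight = 1)
  if (kind == "truncnorm" && sd > 0) {
    par <- truncnorm_parent(mean, sd)
    comp$mu <- par$mu
    comp$sigma <- par$sigma
  }
  structure(list(components = list(comp)), class = "size_distribution")
}

# parent-normal parameters whose zero-truncated moments hit the targets
truncnorm_parent <- function(mean, sd) {
  obj <- function(p) {
    mu <- p[1]; sigma <- exp(p[2])
    a <- -mu / sigma
    Z <- 1 - stats::pnorm(a)
    lam <- stats::dnorm(a) / Z
    m <- mu + sigma * lam
    v <- sigma^2 * (1 + a * lam - lam^2)
    (m - mean)^2 + (sqrt(max(v, 0)) - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > (1e-6 * sd)^2)
    stop(sprintf("cannot moment-match a zero-truncated normal to mean %g, sd %g",
                 mean, sd))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Mixture of size distributions
#'
#' Combines single-component [size_distribution()] objects into a weighted
#' mixture, e.g. the pronounced bimodal ensembles seen for some
#' laser-ablation targets.
#'
#' @param ... `size_distribution` objects (single- or multi-component).
#' @param weights mixture weights, summing to 1 after normalisation.
#' @return A `size_distribution` with multiple components.
#' @export
size_mixture <- function(..., weights) {
  parts <- list(...)
  stopifnot(length(parts) >= 2L, length(weights) == length(parts),
            all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  comps <- list()
  for (i in seq_along(parts)) {
    stopifnot(inherits(parts[[i]], "size_distribution"))
    for (comp in parts[[i]]$components) {
      comp$weight <- comp$weight * weights[i]
      comps[[length(comps) + 1L]] <- comp
    }
  }
  structure(list(components = comps), class = "size_distribution")
}

# log-space parameters reproducing a lognormal's target mean/sd exactly
lognormal_pars <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

comp_pdf <- function(comp, d) {
  if (comp$sd == 0) stop("degenerate component has no density")
  switch(comp$kind,
    lognormal = {
      p <- lognormal_pars(comp$mean, comp$sd)
      stats::dlnorm(d, p$meanlog, p$sdlog)
    },
    truncnorm = {
      z0 <- stats::pnorm(0, comp$mu, comp$sigma)
      ifelse(d > 0, stats::dnorm(d, comp$mu, comp$sigma) / (1 - z0), 0)
    })
}

comp_quantile <- function(comp, p) {
  if (comp$sd == 0) return(rep(comp$mean, length(p)))
  switch(comp$kind,
    lognormal = {
      pr <- lognormal_pars(comp$mean, comp$sd)
      stats::qlnorm(p, pr$meanlog, pr$sdlog)
    },
    truncnorm = {
      z0 <- stats::pnorm(0, comp$mu, comp$sigma)
      stats::qnorm(z0 + p * (1 - z0), comp$mu, comp$sigma)
    })
}

comp_moments <- function(comp) {
  # both families are moment-matched at construction
  c(mean = comp$mean, sd = comp$sd)
}

#' Moments of a size distribution
#'
#' @param dist a [size_distribution()].
#' @return Named vector with the overall `mean` and `sd` of the particle
#'   diameter (nm), combining mixture components exactly.
#' @export
dist_moments <- function(dist) {
  stopifnot(inherits(dist, "size_distribution"))
  w <- vapply(dist$components, `[[`, numeric(1), "weight")
  mom <- vapply(dist$components, comp_moments, numeric(2))
  m <- sum(w * mom["mean", ])
  ex2 <- sum(w * (mom["sd", ]^2 + mom["mean", ]^2))
  c(mean = m, sd = sqrt(max(ex2 - m^2, 0)))
}

#' Quadrature rule over a size distribution
#'
#' Gauss-Legendre nodes and weights for averaging a smooth function of the
#' particle diameter over the distribution, used by [ensemble_properties()].
#' Each component is integrated on its central 99.994% probability interval
#' (log-space for lognormal components), so the captured probability mass is
#' reported and a warning is raised if more than 1% is missed.
#'
#' @param dist a [size_distribution()].
#' @param n_points nodes per component (>= 16; default 64).
#' @return Data frame with columns `d` (nm) and `w` (weights, summing to the
#'   captured probability mass, ~1).
#' @export
size_quadrature <- function(dist, n_points = 64) {
  stopifnot(inherits(dist, "size_distribution"), n_points >= 16)
  gl <- gauss_legendre(n_points)
  out <- list()
  for (comp in dist$components) {
    if (comp$sd == 0) {
      out[[length(out) + 1L]] <- data.frame(d = comp$mean, w = comp$weight)
      next
    }
    p_tail <- 3e-5
    if (comp$kind == "lognormal") {
      pr <- lognormal_pars(comp$mean, comp$sd)
      lo <- pr$meanlog + stats::qnorm(p_tail) * pr$sdlog
      hi <- pr$meanlog + stats::qnorm(1 - p_tail) * pr$sdlog
      u <- (lo + hi) / 2 + (hi - lo) / 2 * gl$x        # log-diameter nodes
      d <- exp(u)
      w <- (hi - lo) / 2 * gl$w * comp_pdf(comp, d) * d  # Jacobian d
    } else {
      lo <- max(comp_quantile(comp, p_tail), comp$sd * 1e-6)
      hi <- comp_quantile(comp, 1 - p_tail)
      d <- (lo + hi) / 2 + (hi - lo) / 2 * gl$x
      w <- (hi - lo) / 2 * gl$w * comp_pdf(comp, d)
    }
    out[[length(out) + 1L]] <- data.frame(d = d, w = comp$weight * w)
  }
  q <- do.call(rbind, out)
  mass <- sum(q$w)
  if (abs(1 - mass) > 0.01)
    warning(sprintf("quadrature captures only %.1f%% of distribution mass",
                    100 * mass))
  q
}

# Golub-Welsch Gauss-Legendre nodes/weights on [-1, 1]
gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(x = e$values[idx], w = 2 * e$vectors[1, idx]^2)
}

#' Draw particle diameters
#'
#' Samples i.i.d. diameters from a size distribution (or from the
#' distribution attached to a synthetic scenario, in which case the
#' scenario's seed is applied first).
#'
#' @param x a [size_distribution()] or [sinp_scenario()].
#' @param n number of draws.
#' @param ... unused.
#' @return Numeric vector of `n` diameters (nm), all positive.
#' @export
sample_sizes <- function(x, n, ...) UseMethod("sample_sizes")

#' @export
sample_sizes.size_distribution <- function(x, n, ...) {
  stopifnot(n >= 1)
  w <- vapply(x$components, `[[`, numeric(1), "weight")
  idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  u <- stats::runif(n)
  d <- numeric(n)
  for (j in seq_along(x$components)) {
    sel <- idx == j
    if (any(sel)) d[sel] <- comp_quantile(x$components[[j]], u[sel])
  }
  d
}

#' @export
print.size_distribution <- function(x, ...) {
  mom <- dist_moments(x)
  cat(sprintf("Size distribution: %d component(s), mean %.1f nm, SD %.1f nm\n",
              length(x$components), mom["mean"], mom["sd"]))
  for (comp in x$components)
    cat(sprintf("  %-10s mean %6.1f nm  sd %5.1f nm  weight %.3f\n",
                comp$kind, comp$mean, comp$sd, comp$weight))
  invisible(x)
}
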