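#' Lookup-table grid specification
#'
#' Axes of the (mu_a, mu_s, g) lookup table. The defaults bracket the
#' optical-property ranges typical of dilute nanoparticle suspensions
#' (mu_a of order 0.1 mm^-1, mu_s of order 0.02-0.5 mm^-1).
#'
#' @param mu_a ascending grid of absorption coefficients, mm^-1 (>= 0).
#' @param mu_s ascending grid of scattering coefficients, mm^-1 (>= 0).
#' @param g ascending grid of anisotropy factors in \[-1, 1\].
#' @return Object of class `lut_grid`.
#' @export
lut_grid <- function(mu_a = seq(0, 0.2, by = 0.01),
                     mu_s = seq(0, 0.6, by = 0.02),
                     g = seq(0, 0.95, by = 0.05)) {
  check_axis <- function(x, name, lo, hi) {
    if (length(x) < 1 || any(!is.finite(x)))
      stop(name, " axis must be finite")
    if (length(x) > 1 && any(diff(x) <= 0))
      stop(name, " axis must be strictly increasing")
    if (any(x < lo) || any(x > hi))
      stop(sprintf("%s axis outside [%g, %g]", name, lo, hi))
    as.numeric(x)
  }
  structure(list(mu_a = check_axis(mu_a, "mu_a", 0, Inf),
                 mu_s = check_axis(mu_s, "mu_s", 0, Inf),
                 g = check_axis(g, "g", -1, 1)),
            class = "lut_grid")
}

# deterministic per-node seed stream from the base seed
node_seed <- function(base_seed, node_index) {
  (base_seed * 1000003 + node_index * 97) %% 2147483629 + 1
}

#' Build a Monte-Carlo lookup table
#'
#' Runs one [mc_simulate()] per grid node of (mu_a, mu_s, g), with the
#' per-node seed derived deterministically from the base seed and the node
#' index so the table is bit-reproducible. Nodes are stored in ascending
#' lexicographic (mu_a, mu_s, g) order.
#'
#' @param geometry a [cuvette_geometry()].
#' @param grid a [lut_grid()].
#' @param config a [sim_config()]; its seed is the base seed.
#' @param progress print a progress line every 500 nodes.
#' @return Object of class `mc_lut`: node data frame plus axes and full
#'   provenance (geometry, simulation config, package version).
#' @export
lut_build <- function(geometry, grid = lut_grid(), config = sim_config(),
                      progress = FALSE) {
  stopifnot(inherits(geometry, "cuvette_geometry"), inherits(grid, "lut_grid"),
            inherits(config, "sim_config"))
  nodes <- expand.grid(g = grid$g, mu_s = grid$mu_s, mu_a = grid$mu_a,
                       KEEP.OUT.ATTRS = FALSE)
  nodes <- nodes[, c("mu_a", "mu_s", "g")]
  n <- nrow(nodes)
  cols <- c("T_C", "T_D", "R_D", "A_medium", "side_loss",
            "se_T_C", "se_T_D", "se_R_D", "seed")
  vals <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  for (i in seq_len(n)) {
    cfg <- config
    cfg$seed <- node_seed(config$seed, i)
    tr <- mc_simulate(geometry, nodes$mu_a[i], nodes$mu_s[i], nodes$g[i], cfg)
    if (any(!is.finite(unlist(tr[c("T_C", "T_D", "R_D")]))))
      stop(sprintf("non-finite simulation output at node %d (mu_a=%g, mu_s=%g, g=%g)",
                   i, nodes$mu_a[i], nodes$mu_s[i], nodes$g[i]))
    vals[i, ] <- c(tr$T_C, tr$T_D, tr$R_D, tr$A_medium, tr$side_loss,
                   tr$se_T_C, tr$se_T_D, tr$se_R_D, cfg$seed)
    if (progress && i %% 500 == 0)
      message(sprintf("lut_build: %d / %d nodes", i, n))
  }
  structure(list(nodes = cbind(nodes, as.data.frame(vals)),
                 axis_mu_a = grid$mu_a, axis_mu_s = grid$mu_s,
                 axis_g = grid$g,
                 geometry = geometry, config = config,
                 version = as.character(utils::packageVersion("imcspect"))),
            class = "mc_lut")
}

#' @export
print.mc_lut <- function(x, ...) {
  cat(sprintf("Monte-Carlo lookup table: %d nodes (%d x %d x %d), %g photons/node\n",
              nrow(x$nodes), length(x$axis_mu_a), length(x$axis_mu_s),
              length(x$axis_g), x$config$n_photons))
  cat(sprintf("  mu_a: %g-%g mm^-1  mu_s: %g-%g mm^-1  g: %g-%g\n",
              min(x$axis_mu_a), max(x$axis_mu_a),
              min(x$axis_mu_s), max(x$axis_mu_s),
              min(x$axis_g), max(x$axis_g)))
  invisible(x)
}

#' Relative least-squares inversion functional
#'
#' The discrepancy between a simulated and a measured channel triple:
#' the sum over the three channels of the squared deviation relative to the
#' measured value,
#' `F = (T_Ci - T_Cm)^2 / T_Cm^2 + (T_Di - T_Dm)^2 / T_Dm^2 +
#'  (R_Di - R_Dm)^2 / R_Dm^2`.
#' Zero iff the triples agree channel-by-channel.
#'
#' @param simulated a [measurement_triple()] or numeric `c(T_C, T_D, R_D)`.
#' @param measured a [measurement_triple()] or numeric `c(T_C, T_D, R_D)`;
#'   all channels must be positive (the relative form divides by them).
#' @return Non-negative scalar.
#' @export
functional_f <- function(simulated, measured) {
  as_ch <- function(x) {
    if (inherits(x, "measurement_triple")) c(x$T_C, x$T_D, x$R_D)
    else { stopifnot(is.numeric(x), length(x) == 3); as.numeric(x) }
  }
  s <- as_ch(simulated); m <- as_ch(measured)
  zero <- which(m == 0)
  if (length(zero))
    stop("measured channel ", c("T_C", "T_D", "R_D")[zero[1]],
         " is zero: relative deviation undefined")
  sum((s - m)^2 / m^2)
}

#' Invert one measured triple against a lookup table
#'
#' Exhaustively evaluates [functional_f()] at every table node and returns
#' the argmin; ties are broken towards the lexicographically smallest
#' (mu_a, mu_s, g). Optionally refines the estimate by trilinear
#' interpolation of the channels on a subdivided cell around the argmin.
#'
#' @param lut an [lut_build()] table.
#' @param measured a [measurement_triple()] or numeric `c(T_C, T_D, R_D)`
#'   with all channels positive.
#' @param refine logical; if `TRUE`, local trilinear refinement with
#'   `subdiv` subdivisions per axis around the argmin node.
#' @param subdiv subdivisions per axis for refinement (default 10).
#' @return Object of class `imc_node`: `mu_a`, `mu_s`, `g`, `F_min`,
#'   `runner_up_F`, `node_index`, `interpolated`.
#' @export
lut_invert <- function(lut, measured, refine = FALSE, subdiv = 10) {
  stopifnot(inherits(lut, "mc_lut"))
  if (nrow(lut$nodes) == 0) stop("empty lookup table")
  m <- if (inherits(measured, "measurement_triple"))
    c(measured$T_C, measured$T_D, measured$R_D) else as.numeric(measured)
  stopifnot(length(m) == 3)
  zero <- which(m == 0)
  if (length(zero))
    stop("measured channel ", c("T_C", "T_D", "R_D")[zero[1]],
         " is zero: relative deviation undefined")
  nd <- lut$nodes
  F_all <- (nd$T_C - m[1])^2 / m[1]^2 + (nd$T_D - m[2])^2 / m[2]^2 +
           (nd$R_D - m[3])^2 / m[3]^2
  best <- which.min(F_all)            # first minimum = lexicographic tie-break
  runner <- if (length(F_all) > 1) min(F_all[-best]) else F_all[best]
  out <- list(mu_a = nd$mu_a[best], mu_s = nd$mu_s[best], g = nd$g[best],
              F_min = F_all[best], runner_up_F = runner,
              node_index = best, interpolated = FALSE)
  if (refine)
    out <- lut_refine(lut, m, out, subdiv)
  structure(out, class = "imc_node")
}

# trilinear refinement of the argmin within the surrounding grid cells
lut_refine <- function(lut, m, coarse, subdiv) {
  axes <- list(mu_a = lut$axis_mu_a, mu_s = lut$axis_mu_s, g = lut$axis_g)
  centre <- c(coarse$mu_a, coarse$mu_s, coarse$g)
  fine <- vector("list", 3)
  for (k in 1:3) {
    ax <- axes[[k]]
    i <- which.min(abs(ax - centre[k]))
    lo <- ax[max(1, i - 1)]; hi <- ax[min(length(ax), i + 1)]
    fine[[k]] <- if (lo == hi) lo else seq(lo, hi, length.out = 2 * subdiv + 1)
  }
  cand <- expand.grid(mu_a = fine[[1]], mu_s = fine[[2]], g = fine[[3]],
                      KEEP.OUT.ATTRS = FALSE)
  ch <- lut_interpolate(lut, cand$mu_a, cand$mu_s, cand$g)
  F_all <- (ch$T_C - m[1])^2 / m[1]^2 + (ch$T_D - m[2])^2 / m[2]^2 +
           (ch$R_D - m[3])^2 / m[3]^2
  best <- which.min(F_all)
  if (F_all[best] < coarse$F_min) {
    coarse$mu_a <- cand$mu_a[best]; coarse$mu_s <- cand$mu_s[best]
    coarse$g <- cand$g[best]; coarse$F_min <- F_all[best]
    coarse$interpolated <- TRUE
  }
  coarse
}

#' Trilinear interpolation of table channels
#'
#' @param lut an `mc_lut`.
#' @param mu_a,mu_s,g query coordinates (vectorised, within the axes' range).
#' @return List of vectors `T_C`, `T_D`, `R_D`.
#' @keywords internal
lut_interpolate <- function(lut, mu_a, mu_s, g) {
  axes <- list(lut$axis_mu_a, lut$axis_mu_s, lut$axis_g)
  qry <- list(mu_a, mu_s, g)
  idx <- frac <- vector("list", 3)
  for (k in 1:3) {
    ax <- axes[[k]]
    x <- pmin(pmax(qry[[k]], ax[1]), ax[length(ax)])
    i <- findInterval(x, ax, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(ax) - 1L)
    if (length(ax) == 1L) { i <- 1L; t <- 0 }
    else t <- (x - ax[i]) / (ax[i + 1] - ax[i])
    idx[[k]] <- i; frac[[k]] <- t
  }
  n_g <- length(axes[[3]]); n_s <- length(axes[[2]])
  lin <- function(ia, is, ig) (ia - 1L) * n_s * n_g + (is - 1L) * n_g + ig
  out <- list(T_C = 0, T_D = 0, R_D = 0)
  for (da in 0:1) for (ds in 0:1) for (dg in 0:1) {
    ia <- pmin(idx[[1]] + da, length(axes[[1]]))
    is <- pmin(idx[[2]] + ds, length(axes[[2]]))
    ig <- pmin(idx[[3]] + dg, length(axes[[3]]))
    w <- (if (da == 1) frac[[1]] else 1 - frac[[1]]) *
         (if (ds == 1) frac[[2]] else 1 - frac[[2]]) *
         (if (dg == 1) frac[[3]] else 1 - frac[[3]])
    rows <- lin(ia, is, ig)
    out$T_C <- out$T_C + w * lut$nodes$T_C[rows]
    out$T_D <- out$T_D + w * lut$nodes$T_D[rows]
    out$R_D <- out$R_D + w * lut$nodes$R_D[rows]
  }
  out
}

#' @export
print.imc_node <- function(x, ...) {
  cat(sprintf("mu_a = %.4g  mu_s = %.4g  g = %.3g  (F_min = %.3g%s)\n",
              x$mu_a, x$mu_s, x$g, x$F_min,
              if (x$interpolated) ", interpolated" else ""))
  invisible(x)
}

#' Write / read a lookup table
#'
#' Serialises the node table as full-precision CSV (17 significant digits,
#' so doubles round-trip bit-exactly) with a JSON sidecar carrying the axes
#' and provenance (geometry, simulation settings, package version).
#'
#' @param lut an `mc_lut`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `lut_write` returns `path` invisibly; `lut_read` the restored
#'   `mc_lut`.
#' @export
lut_write <- function(lut, path) {
  stopifnot(inherits(lut, "mc_lut"))
  nd <- lut$nodes
  txt <- vapply(nd, function(col) sprintf("%.17g", col), character(nrow(nd)))
  if (nrow(nd) == 1L) txt <- matrix(txt, nrow = 1)
  lines <- c(paste(names(nd), collapse = ","),
             apply(txt, 1, paste, collapse = ","))
  writeLines(lines, path)
  # numerics as %.17g strings: doubles survive the JSON round-trip bit-exactly
  str17 <- function(x) if (is.numeric(x)) sprintf("%.17g", x) else x
  sidecar <- list(axis_mu_a = str17(lut$axis_mu_a),
                  axis_mu_s = str17(lut$axis_mu_s),
                  axis_g = str17(lut$axis_g),
                  geometry = lapply(unclass(lut$geometry), str17),
                  config = lapply(unclass(lut$config), str17),
                  version = lut$version)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname lut_write
#' @export
lut_read <- function(path) {
  nd <- utils::read.csv(path, colClasses = "numeric")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geom <- do.call(cuvette_geometry, lapply(side$geometry, as.numeric))
  cfg <- do.call(sim_config,
                 lapply(side$config[c("n_photons", "seed", "weight_threshold",
                                      "roulette_survival")], as.numeric))
  structure(list(nodes = nd,
                 axis_mu_a = as.numeric(side$axis_mu_a),
                 axis_mu_s = as.numeric(side$axis_mu_s),
                 axis_g = as.numeric(side$axis_g),
                 geometry = geom, config = cfg,
                 version = side$version),
            class = "mc_lut")
}
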