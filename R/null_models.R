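#' Moving-window intensity surface of one species
#'
#' Estimates the species-specific intensity lambda(x, y) on a regular grid
#' with a uniform-disc moving window: at each grid centre, the count of that
#' species' trees within `bandwidth` metres divided by the area of the disc
#' clipped to the window (local edge correction). The surface is rescaled so
#' its integral over the window equals the species' tree count exactly.
#'
#' The default 20 m bandwidth keeps large-scale (habitat) structure while
#' smoothing away tree-to-tree interaction structure, which in forests is
#' typically confined to scales below 20-30 m.
#'
#' @param pattern A [tree_pattern()].
#' @param species A species label present in the pattern.
#' @param bandwidth Moving-window radius in metres (default 20).
#' @param grid_step Grid resolution in metres (default 1).
#' @return An object of class `intensity_surface`: grid centre coordinates
#'   `x`, `y`, matrix `lambda` (trees per m^2, `length(x)` rows), `species`,
#'   `bandwidth`, `grid_step`, `window`.
#' @export
estimate_intensity <- function(pattern, species, bandwidth = 20,
                               grid_step = 1) {
  stopifnot(inherits(pattern, "tree_pattern"), bandwidth > 0, grid_step > 0)
  sel <- pattern$species == species
  if (!any(sel)) stop(sprintf("species '%s' absent from pattern", species))
  w <- pattern$window
  gx <- seq(w$xmin + grid_step / 2, w$xmax - grid_step / 2 + 1e-9,
            by = grid_step)
  gy <- seq(w$ymin + grid_step / 2, w$ymax - grid_step / 2 + 1e-9,
            by = grid_step)
  tx <- pattern$x[sel]; ty <- pattern$y[sel]
  counts <- matrix(0, length(gx), length(gy))
  b2 <- bandwidth^2
  for (j in seq_along(gy)) {
    dy2 <- (ty - gy[j])^2
    near <- dy2 <= b2
    if (!any(near)) next
    txn <- tx[near]; dy2n <- dy2[near]
    counts[, j] <- vapply(gx, function(cx) {
      sum((txn - cx)^2 + dy2n <= b2)
    }, numeric(1))
  }
  area <- clipped_disc_area(gx, gy, bandwidth, w)
  lambda <- counts / area
  # rescale: integral over window == species count exactly
  integral <- sum(lambda) * grid_step^2
  if (integral > 0) lambda <- lambda * sum(sel) / integral
  structure(list(x = gx, y = gy, lambda = lambda, species = species,
                 bandwidth = bandwidth, grid_step = grid_step, window = w),
            class = "intensity_surface")
}

# area of disc(radius) centred at each (gx, gy) clipped to the window;
# interior centres get pi r^2 directly, border centres a 1-D quadrature of
# the clipped chord length (400 panels across the disc)
clipped_disc_area <- function(gx, gy, radius, w) {
  out <- matrix(NA_real_, length(gx), length(gy))
  full <- pi * radius^2
  interior_x <- gx - w$xmin >= radius & w$xmax - gx >= radius
  interior_y <- gy - w$ymin >= radius & w$ymax - gy >= radius
  nseg <- 400L
  for (j in seq_along(gy)) {
    cy <- gy[j]
    for (i in seq_along(gx)) {
      if (interior_x[i] && interior_y[j]) { out[i, j] <- full; next }
      cx <- gx[i]
      x0 <- max(cx - radius, w$xmin); x1 <- min(cx + radius, w$xmax)
      xs <- seq(x0, x1, length.out = nseg + 1L)
      h <- sqrt(pmax(radius^2 - (xs - cx)^2, 0))
      chord <- pmin(cy + h, w$ymax) - pmax(cy - h, w$ymin)
      chord[chord < 0] <- 0
      # trapezoid rule
      out[i, j] <- sum((chord[-1L] + chord[-length(chord)]) / 2 * diff(xs))
    }
  }
  out
}

#' @export
print.intensity_surface <- function(x, ...) {
  cat(sprintf(
    "intensity surface for species '%s': %d x %d grid (step %g m), bandwidth %g m\n",
    x$species, length(x$x), length(x$y), x$grid_step, x$bandwidth))
  cat(sprintf("  lambda range %.4g .. %.4g /m^2, integral %.4g trees\n",
              min(x$lambda), max(x$lambda), sum(x$lambda) * x$grid_step^2))
  invisible(x)
}

#' @export
plot.intensity_surface <- function(x, ...) {
  graphics::image(x$x, x$y, x$lambda, asp = 1, xlab = "x (m)",
                  ylab = "y (m)", ...)
  invisible(x)
}

# pointwise envelope summaries from a replicate-by-r matrix: 2.5%/97.5%
# quantiles, mean ("expected under independent marking"), standard error of
# that mean, and the count of replicates defining each r (undefined
# replicate values are dropped from the pools)
envelope_from_sims <- function(sims) {
  qs <- apply(sims, 2L, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(rep(NA_real_, 4L))
    c(stats::quantile(col, 0.025, names = FALSE),
      stats::quantile(col, 0.975, names = FALSE), mean(col),
      if (length(col) > 1L) stats::sd(col) / sqrt(length(col)) else NA_real_)
  })
  list(lower = qs[1L, ], upper = qs[2L, ], expectation = qs[3L, ],
       se = qs[4L, ], n_defined = colSums(!is.na(sims)))
}

# deterministic substream seed for replicate i of a master seed; keeps
# earlier replicates unchanged when nsim grows
substream_seed <- function(seed, i) {
  (as.double(seed) * 69069 + i * 104729) %% 2147483647
}

#' Homogeneous Poisson location randomization
#'
#' Null-model randomization for mark-independence tests: every tree keeps
#' its (species, dbh) mark pair, while all locations are replaced by
#' independent uniform draws in the window (binomial/CSR conditioning on the
#' observed tree count). All tree-to-tree interaction structure is
#' destroyed; the mark joint distribution is retained exactly.
#'
#' @param pattern A [tree_pattern()].
#' @param seed Integer seed; the same seed reproduces the same replicate.
#' @return A new [tree_pattern()] with identical marks and randomized
#'   locations.
#' @export
randomize_homogeneous <- function(pattern, seed = NULL) {
  stopifnot(inherits(pattern, "tree_pattern"))
  if (!is.null(seed)) set.seed(seed)
  w <- pattern$window
  tree_pattern(stats::runif(pattern$n, w$xmin, w$xmax),
               stats::runif(pattern$n, w$ymin, w$ymax),
               pattern$species, pattern$dbh, window = w, id = pattern$id)
}

#' Heterogeneous Poisson location randomization
#'
#' Like [randomize_homogeneous()], but each species' trees are relocated
#' according to that species' smoothed intensity surface, so large-scale
#' (habitat) structure is preserved while small-scale interaction structure
#' is removed. Per-species counts are fixed at the observed values and each
#' tree keeps its dbh, so the species-size relationship is retained.
#'
#' Locations are drawn by sampling a grid cell with probability
#' proportional to lambda times cell area, then uniformly within the cell.
#'
#' @param pattern A [tree_pattern()].
#' @param surfaces Named list of [estimate_intensity()] surfaces, one per
#'   species present in the pattern.
#' @param seed Integer seed.
#' @return A new [tree_pattern()] with identical marks and relocated trees.
#' @export
randomize_heterogeneous <- function(pattern, surfaces, seed = NULL) {
  stopifnot(inherits(pattern, "tree_pattern"))
  sp_levels <- levels(droplevels(pattern$species))
  missing_sp <- setdiff(sp_levels, names(surfaces))
  if (length(missing_sp)) {
    stop(sprintf("no intensity surface for species: %s",
                 paste(missing_sp, collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  x <- pattern$x; y <- pattern$y
  for (sp in sp_levels) {
    idx <- which(pattern$species == sp)
    s <- surfaces[[sp]]
    step <- s$grid_step
    prob <- as.vector(s$lambda)
    cells <- sample.int(length(prob), length(idx), replace = TRUE,
                        prob = prob)
    ci <- (cells - 1L) %% length(s$x) + 1L
    cj <- (cells - 1L) %/% length(s$x) + 1L
    x[idx] <- s$x[ci] + stats::runif(length(idx), -step / 2, step / 2)
    y[idx] <- s$y[cj] + stats::runif(length(idx), -step / 2, step / 2)
  }
  tree_pattern(x, y, pattern$species, pattern$dbh, window = pattern$window,
               id = pattern$id)
}

#' Pointwise Monte-Carlo envelope of a mingling statistic
#'
#' Computes a summary curve on the observed pattern and on `nsim`
#' location-randomized replicates (marks retained), and returns the
#' pointwise 2.5%/97.5% empirical quantiles together with the pointwise mean
#' (the "expected under independent marking" line). Observed excursions
#' outside the band indicate departure from mark independence at that
#' scale. Envelopes are pointwise, not global: at a single pre-chosen
#' distance the band is an approximate 95% interval, but some excursion
#' somewhere along the curve is expected even under the null.
#'
#' @param pattern A [tree_pattern()].
#' @param statistic Function mapping a `tree_pattern` to either a
#'   `mingling_curve` or a numeric vector on a fixed grid.
#' @param null Null-model kind: `"homogeneous"` (uniform relocation) or
#'   `"heterogeneous"` (per-species intensity-guided relocation).
#' @param nsim Number of Monte-Carlo replicates (default 1000, as in
#'   quantile-envelope practice; reduce for smoke runs).
#' @param seed Master seed; replicate i uses a derived substream seed, so
#'   growing `nsim` leaves earlier replicates unchanged.
#' @param bandwidth,grid_step Passed to [estimate_intensity()] for the
#'   heterogeneous null.
#' @param surfaces Optional pre-computed intensity surfaces (named by
#'   species) to reuse across envelopes.
#' @return An object of class `mingling_envelope`: `r`, `observed`, `lower`,
#'   `upper`, `expectation`, `se` (standard error of the expectation),
#'   `n_defined` (replicates defining each r), `nsim`, `null`, `seed`, and
#'   the observed `curve` when the statistic returned one.
#' @export
mingling_envelope <- function(pattern, statistic,
                              null = c("homogeneous", "heterogeneous"),
                              nsim = 1000, seed = 1, bandwidth = 20,
                              grid_step = 1, surfaces = NULL) {
  stopifnot(inherits(pattern, "tree_pattern"), is.function(statistic))
  null <- match.arg(null)
  if (nsim < 2) stop("nsim must be at least 2")
  obs <- statistic(pattern)
  curve <- NULL
  if (inherits(obs, "mingling_curve")) {
    curve <- obs
    r <- obs$r
    obs <- obs$value
  } else {
    r <- seq_along(obs)
  }
  if (null == "heterogeneous" && is.null(surfaces)) {
    sp_levels <- levels(droplevels(pattern$species))
    surfaces <- lapply(sp_levels, function(sp) {
      estimate_intensity(pattern, sp, bandwidth = bandwidth,
                         grid_step = grid_step)
    })
    names(surfaces) <- sp_levels
  }
  sims <- matrix(NA_real_, nsim, length(obs))
  for (i in seq_len(nsim)) {
    si <- substream_seed(seed, i)
    rep_pat <- if (null == "homogeneous") {
      randomize_homogeneous(pattern, seed = si)
    } else {
      randomize_heterogeneous(pattern, surfaces, seed = si)
    }
    v <- statistic(rep_pat)
    if (inherits(v, "mingling_curve")) v <- v$value
    sims[i, ] <- v
  }
  env <- envelope_from_sims(sims)
  structure(c(list(r = r, observed = obs), env,
              list(nsim = nsim, null = null, seed = seed, curve = curve)),
            class = "mingling_envelope")
}

#' @export
print.mingling_envelope <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo envelope: %d %s-Poisson replicates (seed %s)\n",
    x$nsim, x$null, format(x$seed)))
  below <- sum(x$observed < x$lower, na.rm = TRUE)
  above <- sum(x$observed > x$upper, na.rm = TRUE)
  cat(sprintf(
    "  observed outside the 2.5%%/97.5%% band at %d of %d r values (%d below, %d above)\n",
    below + above, length(x$r), below, above))
  invisible(x)
}

#' @export
plot.mingling_envelope <- function(x, ylab = "statistic", shade = "grey85",
                                   ...) {
  ok <- !is.na(x$lower) & !is.na(x$upper)
  ylim <- range(x$observed, x$lower, x$upper, na.rm = TRUE)
  plot(x$r, x$observed, type = "n", xlab = "r (m)", ylab = ylab,
       ylim = ylim, ...)
  graphics::polygon(c(x$r[ok], rev(x$r[ok])), c(x$lower[ok], rev(x$upper[ok])),
                    col = shade, border = NA)
  graphics::lines(x$r, x$expectation, lty = 3)
  graphics::lines(x$r, x$observed, lwd = 1.5)
  invisible(x)
}

#' @export
as.data.frame.mingling_envelope <- function(x, ...) {
  data.frame(r = x$r, observed = x$observed, lower = x$lower,
             upper = x$upper, expectation = x$expectation, se = x$se,
             n_defined = x$n_defined, null_kind = x$null, nsim = x$nsim,
             seed = x$seed, stringsAsFactors = FALSE)
}
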