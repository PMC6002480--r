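#' Nearest-neighbour mingling index of one tree
#'
#' The proportion of the k nearest neighbours of a reference tree that carry
#' a different species mark: `M_i = (1/k) * sum 1(species_j != species_i)`.
#' With the conventional k = 4 the index takes one of five values 0, 0.25,
#' 0.5, 0.75, 1.
#'
#' @param pattern A [tree_pattern()].
#' @param i Tree id.
#' @param k Number of neighbours (default 4).
#' @return A fraction in \[0, 1\].
#' @export
mingling_index <- function(pattern, i, k = 4) {
  nb <- nearest_neighbours(pattern, i, k)
  pos <- match(i, pattern$id)
  mean(pattern$species[match(nb, pattern$id)] != pattern$species[pos])
}

#' Mingling summary of a pattern
#'
#' Computes `M_i` for every tree (all trees serve as references, including
#' those near the plot border) and tabulates the grouped mingling levels.
#' Levels 0 and 0.25 are merged into one category — reference trees with no
#' heterospecific neighbour are typically rare — giving the grouped levels
#' `{0, 0.25}`, `0.5`, `0.75`, `1` for k = 4.
#'
#' @param pattern A [tree_pattern()] with more than `k` trees.
#' @param k Number of neighbours (default 4).
#' @return An object of class `mingling_summary`: list with per-tree `m`
#'   (indices, pattern order), `level` (grouped-level factor), `k`, `counts`
#'   (trees per grouped level) and the source `pattern`.
#' @export
mingling_summary <- function(pattern, k = 4) {
  stopifnot(inherits(pattern, "tree_pattern"))
  if (pattern$n <= k) {
    stop(sprintf("need more than k = %d trees, have %d", k, pattern$n))
  }
  # one distance matrix instead of per-tree queries; ties broken by id as in
  # nearest_neighbours()
  dm <- pairwise_distances(pattern)
  diag(dm) <- Inf
  sp <- as.integer(pattern$species)
  m <- vapply(seq_len(pattern$n), function(pos) {
    nb <- order(dm[pos, ], pattern$id)[seq_len(k)]
    mean(sp[nb] != sp[pos])
  }, numeric(1))
  lv <- grouped_levels(k)
  level <- cut(m, breaks = c(-Inf, lv$upper), labels = lv$labels)
  counts <- table(level)
  structure(list(m = m, level = level, k = k, counts = counts,
                 pattern = pattern),
            class = "mingling_summary")
}

# grouped mingling levels for k neighbours: the two lowest admissible
# fractions merged, the rest kept
grouped_levels <- function(k) {
  vals <- (0:k) / k
  labels <- c(sprintf("{0,%g}", vals[2L]), as.character(vals[-(1:2)]))
  upper <- vals[-1L]
  list(labels = labels, upper = upper, values = vals)
}

#' @export
print.mingling_summary <- function(x, ...) {
  cat(sprintf("mingling summary (k = %d): mean M = %.4f over %d trees\n",
              x$k, mean(x$m), length(x$m)))
  print(x$counts)
  invisible(x)
}

#' @export
plot.mingling_summary <- function(x, ...) {
  graphics::boxplot(x$pattern$dbh ~ x$level, xlab = "mingling level",
                    ylab = "dbh (cm)", ...)
  invisible(x)
}

#' Pairwise tree-size tests across mingling levels
#'
#' Tests, for every pair of grouped mingling levels, whether the dbh
#' distributions differ, with a two-sided Wilcoxon rank-sum test (exact null
#' distribution for small untied samples, tie-corrected normal approximation
#' otherwise). P-values are Holm-adjusted across the pairs and summarized as
#' compact significance letters: levels sharing no letter differ at the
#' `alpha` level after adjustment.
#'
#' @param summary A [mingling_summary()].
#' @param alpha Significance level for the letter display (default 0.05).
#' @return An object of class `mingling_dbh_test`: data frame `pairs`
#'   (`level1`, `level2`, `statistic`, `p`, `p_adj`), vector `letters` (one
#'   string per retained level), `medians` (per-level dbh medians) and
#'   `excluded` (levels with fewer than 2 trees, dropped with a warning).
#' @export
dbh_mingling_test <- function(summary, alpha = 0.05) {
  stopifnot(inherits(summary, "mingling_summary"))
  dbh <- summary$pattern$dbh
  lev <- summary$level
  sizes <- table(lev)
  excluded <- names(sizes)[sizes < 2L]
  if (length(excluded)) {
    warning(sprintf("mingling level(s) with fewer than 2 trees excluded: %s",
                    paste(excluded, collapse = ", ")))
  }
  keep <- setdiff(names(sizes)[sizes >= 2L], excluded)
  if (length(keep) < 2L) {
    stop("need at least two mingling levels with 2 or more trees")
  }
  cmb <- utils::combn(keep, 2L)
  res <- apply(cmb, 2L, function(pr) {
    ranksum_pair(dbh[lev == pr[1L]], dbh[lev == pr[2L]])
  })
  pairs <- data.frame(level1 = cmb[1L, ], level2 = cmb[2L, ],
                      statistic = res["statistic", ], p = res["p", ],
                      p_adj = stats::p.adjust(res["p", ], method = "holm"),
                      stringsAsFactors = FALSE)
  medians <- vapply(keep, function(l) stats::median(dbh[lev == l]), numeric(1))
  letters <- significance_letters(keep, pairs, alpha)
  structure(list(pairs = pairs, letters = letters, medians = medians,
                 alpha = alpha, excluded = excluded),
            class = "mingling_dbh_test")
}

# two-sided Wilcoxon rank-sum on one pair of dbh groups: exact null for
# small untied samples, tie-corrected normal approximation (with continuity
# correction) otherwise
ranksum_pair <- function(x, y) {
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            correct = TRUE))
  c(statistic = unname(wt$statistic), p = wt$p.value)
}

# compact letter display: maximal sets of mutually non-different levels get
# one letter each; enumeration is fine for the handful of mingling levels
significance_letters <- function(levels, pairs, alpha) {
  k <- length(levels)
  differs <- matrix(FALSE, k, k, dimnames = list(levels, levels))
  sig <- pairs$p_adj < alpha
  for (r in which(sig)) {
    differs[pairs$level1[r], pairs$level2[r]] <- TRUE
    differs[pairs$level2[r], pairs$level1[r]] <- TRUE
  }
  # all subsets, largest first; keep maximal cliques of the "no difference" graph
  subsets <- lapply(seq_len(2^k - 1L), function(b) which(bitwAnd(b, 2^(seq_len(k) - 1L)) > 0))
  ok <- vapply(subsets, function(s) {
    length(s) == 1L || !any(differs[s, s])
  }, logical(1))
  cliques <- subsets[ok]
  maximal <- cliques[vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(o) length(o) > length(cliques[[i]]) &&
                  all(cliques[[i]] %in% o), logical(1)))
  }, logical(1))]
  ord <- order(vapply(maximal, min, numeric(1)))
  maximal <- maximal[ord]
  out <- setNames(rep("", k), levels)
  for (i in seq_along(maximal)) {
    out[maximal[[i]]] <- paste0(out[maximal[[i]]], letters[i])
  }
  out
}

#' @export
print.mingling_dbh_test <- function(x, ...) {
  cat(sprintf("pairwise Wilcoxon rank-sum tests on dbh (Holm-adjusted, alpha = %g)\n",
              x$alpha))
  print(x$pairs, row.names = FALSE)
  cat("level medians (cm) and letters:\n")
  print(data.frame(median = x$medians, letters = x$letters))
  if (length(x$excluded)) {
    cat("excluded levels:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Bivariate dbh-by-mingling density
#'
#' Joint distribution of tree size and grouped mingling level: for each
#' level a Gaussian-kernel density of dbh, weighted by the level's relative
#' frequency, so the densities stack to total mass 1 over the (dbh, level)
#' grid. Mingling is a discrete mark, so the "bivariate" density is a set of
#' conditional dbh densities rather than a 2-D kernel over a 5-valued axis.
#'
#' @param summary A [mingling_summary()].
#' @param bandwidth Kernel bandwidth in cm, or `"auto"` for Silverman's rule
#'   computed on all dbh values (shared across levels).
#' @param n_grid Number of dbh grid points.
#' @return An object of class `mingling_density`: `dbh` grid, `levels`,
#'   matrix `density` (grid x level), `bandwidth`.
#' @export
mingling_dbh_density <- function(summary, bandwidth = "auto", n_grid = 128) {
  stopifnot(inherits(summary, "mingling_summary"))
  dbh <- summary$pattern$dbh
  if (identical(bandwidth, "auto")) bandwidth <- stats::bw.nrd0(dbh)
  if (!is.numeric(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be positive (or \"auto\")")
  }
  from <- min(dbh) - 3 * bandwidth
  to <- max(dbh) + 3 * bandwidth
  lv <- levels(summary$level)
  dens <- matrix(0, n_grid, length(lv), dimnames = list(NULL, lv))
  grid <- seq(from, to, length.out = n_grid)
  for (l in lv) {
    d_l <- dbh[summary$level == l]
    if (!length(d_l)) next
    kd <- stats::density(d_l, bw = bandwidth, from = from, to = to,
                         n = n_grid)
    dens[, l] <- kd$y * length(d_l) / length(dbh)
  }
  structure(list(dbh = grid, levels = lv, density = dens,
                 bandwidth = bandwidth),
            class = "mingling_density")
}

#' @export
print.mingling_density <- function(x, ...) {
  mass <- colSums(x$density) * diff(x$dbh[1:2])
  cat(sprintf("dbh x mingling-level density: bandwidth %.3g cm, %d grid points\n",
              x$bandwidth, length(x$dbh)))
  cat("mass per level:\n"); print(round(mass, 4))
  invisible(x)
}

#' @export
plot.mingling_density <- function(x, type = c("persp", "lines"), ...) {
  type <- match.arg(type)
  if (type == "persp") {
    graphics::persp(x$dbh, seq_along(x$levels), x$density,
                    xlab = "dbh (cm)", ylab = "mingling level",
                    zlab = "density", theta = 35, phi = 25,
                    ticktype = "detailed", ...)
  } else {
    graphics::matplot(x$dbh, x$density, type = "l", lty = 1,
                      xlab = "dbh (cm)", ylab = "density", ...)
    graphics::legend("topright", legend = x$levels, lty = 1,
                     col = seq_along(x$levels), bty = "n")
  }
  invisible(x)
}

#' @export
as.data.frame.mingling_density <- function(x, ...) {
  data.frame(dbh = rep(x$dbh, times = length(x$levels)),
             level = rep(x$levels, each = length(x$dbh)),
             density = as.vector(x$density), stringsAsFactors = FALSE)
}
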