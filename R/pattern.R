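#' Rectangular observation window
#'
#' Defines the axis-aligned rectangular plot window in which a stem map was
#' recorded. All coordinates are in metres. Containment is closed on every
#' edge, so trees mapped exactly on a plot border are inside.
#'
#' @param xmin,ymin,xmax,ymax Window corners in metres.
#'
#' @return An object of class `plot_window`: a list with the corners plus the
#'   derived side lengths `a = xmax - xmin`, `b = ymax - ymin` and area
#'   `area = a * b` (m^2).
#' @examples
#' w <- plot_window(0, 0, 100, 100)
#' w$area
#' @export
plot_window <- function(xmin, ymin, xmax, ymax) {
  stopifnot(is.numeric(xmin), is.numeric(ymin), is.numeric(xmax),
            is.numeric(ymax), length(xmin) == 1L, length(ymin) == 1L,
            length(xmax) == 1L, length(ymax) == 1L)
  a <- xmax - xmin
  b <- ymax - ymin
  if (!(a > 0) || !(b > 0)) {
    stop("window must have positive side lengths (xmax > xmin, ymax > ymin)")
  }
  structure(list(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax,
                 a = a, b = b, area = a * b),
            class = "plot_window")
}

#' @export
print.plot_window <- function(x, ...) {
  cat(sprintf("window: [%g, %g] x [%g, %g] m  (%g x %g m, %g m^2)\n",
              x$xmin, x$xmax, x$ymin, x$ymax, x$a, x$b, x$area))
  invisible(x)
}

inside_window <- function(window, x, y) {
  x >= window$xmin & x <= window$xmax & y >= window$ymin & y <= window$ymax
}

#' Marked point pattern of stem-mapped trees
#'
#' The central container of the package: tree locations inside a rectangular
#' window, each carrying a species label and a stem diameter (dbh) mark.
#'
#' @param x,y Tree coordinates in metres.
#' @param species Species labels (character or factor), one per tree.
#' @param dbh Diameter at breast height in cm, one per tree; must be positive.
#' @param window A [plot_window()]. If `NULL`, the bounding box of the
#'   coordinates rounded outward to integers is used and a message notes the
#'   inference.
#' @param id Optional integer tree ids; defaults to `0:(n-1)` in input order.
#'
#' @return An object of class `tree_pattern`: a list with elements `x`, `y`,
#'   `species` (factor), `dbh`, `id`, `window`, `n` (tree count) and
#'   `intensity` (`n / area`, trees per m^2).
#' @examples
#' p <- tree_pattern(x = c(10, 20, 30), y = c(10, 20, 30),
#'                   species = c("A", "A", "B"), dbh = c(12, 30, 8),
#'                   window = plot_window(0, 0, 50, 50))
#' p$intensity
#' @export
tree_pattern <- function(x, y, species, dbh, window = NULL, id = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(species) == n, length(dbh) == n)
  if (is.null(window)) {
    window <- plot_window(floor(min(x, 0)), floor(min(y, 0)),
                          ceiling(max(x, 1)), ceiling(max(y, 1)))
    message(sprintf("window inferred from coordinates: [%g, %g] x [%g, %g]",
                    window$xmin, window$xmax, window$ymin, window$ymax))
  }
  if (!inherits(window, "plot_window")) stop("window must be a plot_window")
  if (is.null(id)) id <- seq_len(n) - 1L
  if (anyDuplicated(id)) stop("tree ids must be unique")
  bad <- which(!inside_window(window, x, y))
  if (length(bad)) {
    stop(sprintf("tree(s) outside the window at row(s) %s",
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (any(!is.finite(dbh)) || any(dbh <= 0)) stop("dbh must be positive and finite")
  sp <- as.factor(as.character(species))
  if (any(is.na(sp)) || any(levels(sp) == "")) stop("species labels must be non-empty")
  structure(list(x = as.numeric(x), y = as.numeric(y), species = sp,
                 dbh = as.numeric(dbh), id = as.integer(id),
                 window = window, n = n, intensity = n / window$area),
            class = "tree_pattern")
}

#' @export
print.tree_pattern <- function(x, ...) {
  cat(sprintf("marked tree pattern: %d trees, %d species, intensity %.4g /m^2\n",
              x$n, nlevels(x$species), x$intensity))
  print(x$window)
  invisible(x)
}

#' @export
summary.tree_pattern <- function(object, ...) {
  out <- list(n = object$n, intensity = object$intensity,
              window = object$window,
              species = table(object$species),
              dbh = summary(object$dbh))
  class(out) <- "summary.tree_pattern"
  out
}

#' @export
print.summary.tree_pattern <- function(x, ...) {
  cat(sprintf("marked tree pattern: %d trees, intensity %.4g /m^2\n",
              x$n, x$intensity))
  print(x$window)
  cat("species counts:\n"); print(x$species)
  cat("dbh (cm):\n"); print(x$dbh)
  invisible(x)
}

#' @export
as.data.frame.tree_pattern <- function(x, ...) {
  data.frame(x = x$x, y = x$y, species = as.character(x$species),
             dbh = x$dbh, stringsAsFactors = FALSE)
}

#' @export
plot.tree_pattern <- function(x, scale_dbh = TRUE, ...) {
  cex <- if (scale_dbh) 0.5 + 1.5 * (x$dbh / max(x$dbh)) else 1
  plot(x$x, x$y, asp = 1, pch = 21, cex = cex,
       bg = grDevices::palette.colors(nlevels(x$species), "Okabe-Ito",
                                      recycle = TRUE)[as.integer(x$species)],
       xlim = c(x$window$xmin, x$window$xmax),
       ylim = c(x$window$ymin, x$window$ymax),
       xlab = "x (m)", ylab = "y (m)", ...)
  graphics::rect(x$window$xmin, x$window$ymin, x$window$xmax, x$window$ymax)
  invisible(x)
}

#' Read a stem-census table
#'
#' Reads a comma-separated census file with mandatory header columns `x`,
#' `y`, `species`, `dbh` (any column order; metres and cm) and returns a
#' validated [tree_pattern()]. Rows at or below the census dbh threshold are
#' dropped (strict `dbh > min_dbh`), matching field protocols that tag only
#' stems above a minimum diameter.
#'
#' @param path Path to the CSV file.
#' @param window A [plot_window()]; if `NULL` it is inferred from the data
#'   (bounding box rounded outward to integers).
#' @param min_dbh Census threshold in cm; only trees with `dbh > min_dbh` are
#'   retained. Default 5.
#' @return A [tree_pattern()] with ids `0:(n-1)` in file order.
#' @seealso [write_census()]
#' @export
read_census <- function(path, window = NULL, min_dbh = 5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "species", "dbh")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop(sprintf("census file %s is missing column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  }
  for (col in c("x", "y", "dbh")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn)) {
        stop(sprintf("non-numeric %s at row(s) %s",
                     col, paste(utils::head(which(is.na(vn)), 5L), collapse = ", ")))
      }
      df[[col]] <- vn
    }
  }
  keep <- df$dbh > min_dbh
  df <- df[keep, , drop = FALSE]
  tree_pattern(df$x, df$y, df$species, df$dbh, window = window)
}

#' Write a stem-census table
#'
#' Writes the pattern as a CSV with header `x,y,species,dbh`, one row per
#' stem, so that `read_census(write_census(p))` reproduces `p`.
#'
#' @param pattern A [tree_pattern()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_census <- function(pattern, path) {
  stopifnot(inherits(pattern, "tree_pattern"))
  utils::write.csv(as.data.frame(pattern), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' k nearest neighbours of a tree
#'
#' Returns the ids of the `k` trees closest (Euclidean distance) to the
#' reference tree, nearest first. Exact distance ties are broken by ascending
#' tree id so results are deterministic and order-independent.
#'
#' @param pattern A [tree_pattern()].
#' @param i A tree id present in the pattern.
#' @param k Number of neighbours; must satisfy `k < n`.
#' @return Integer vector of `k` tree ids, nearest first.
#' @export
nearest_neighbours <- function(pattern, i, k) {
  stopifnot(inherits(pattern, "tree_pattern"))
  if (k >= pattern$n) {
    stop(sprintf("k = %d neighbours requested but pattern has only %d trees",
                 k, pattern$n))
  }
  pos <- match(i, pattern$id)
  if (is.na(pos)) stop(sprintf("no tree with id %s", format(i)))
  d <- sqrt((pattern$x - pattern$x[pos])^2 + (pattern$y - pattern$y[pos])^2)
  d[pos] <- Inf
  ord <- order(d, pattern$id)
  pattern$id[ord[seq_len(k)]]
}

#' Translation edge-correction weight
#'
#' Pairwise weight compensating for tree pairs lost outside a bounded
#' rectangular window. For a displacement `(dx, dy)` the weight is the window
#' area divided by the area of the overlap between the window and its
#' translate: `omega = (a*b) / ((a - |dx|) * (b - |dy|)) >= 1`.
#'
#' @param window A [plot_window()].
#' @param dx,dy Displacement components in metres; require `|dx| < a`,
#'   `|dy| < b` (larger displacements have empty overlap and no usable
#'   weight).
#' @return Numeric weight(s) `>= 1`; vectorised over `dx`/`dy`.
#' @examples
#' w <- plot_window(0, 0, 100, 100)
#' translation_weight(w, 50, 0)  # 2: half the window overlaps
#' @export
translation_weight <- function(window, dx, dy) {
  stopifnot(inherits(window, "plot_window"))
  adx <- abs(dx); ady <- abs(dy)
  if (any(adx >= window$a) || any(ady >= window$b)) {
    stop("displacement at least one window side long: translation weight undefined")
  }
  (window$a * window$b) / ((window$a - adx) * (window$b - ady))
}

#' Tree size-class scheme
#'
#' Maps dbh (cm) to ordered size classes. The default three-class scheme is
#' small `[5, 10)` cm, medium `[10, 25]` cm, large `(25, Inf)` cm: every
#' interior breakpoint except the last is attained by the class above it
#' (`dbh >= break`), while the last breakpoint is strict (`dbh > break`), so
#' "large" always means strictly above the top break. A two-class scheme
#' (e.g. `breaks = c(5, 25)`) follows the same rule.
#'
#' @param breaks Strictly increasing numeric vector: the census minimum
#'   followed by the interior class breakpoints (cm).
#' @param labels Class labels, one more than the number of interior breaks.
#' @return An object of class `size_scheme`.
#' @examples
#' s <- size_scheme()
#' classify_size(s, c(7, 10, 25, 30))
#' @export
size_scheme <- function(breaks = c(5, 10, 25), labels = NULL) {
  breaks <- as.numeric(breaks)
  if (length(breaks) < 2L || any(diff(breaks) <= 0)) {
    stop("breaks must be strictly increasing with at least two values")
  }
  if (is.null(labels)) {
    labels <- if (length(breaks) == 3L) c("small", "medium", "large")
              else if (length(breaks) == 2L) c("small", "large")
              else paste0("class", seq_along(breaks))
  }
  if (length(labels) != length(breaks)) {
    stop("need exactly one label per class (same length as breaks: the last class is unbounded above)")
  }
  structure(list(breaks = breaks, labels = as.character(labels)),
            class = "size_scheme")
}

#' @export
print.size_scheme <- function(x, ...) {
  k <- length(x$labels)
  bounds <- character(k)
  for (j in seq_len(k)) {
    lo <- x$breaks[j]
    if (j == k) {
      bounds[j] <- sprintf("(%g, Inf)", lo)
    } else if (j == k - 1L) {
      bounds[j] <- sprintf("[%g, %g]", lo, x$breaks[j + 1L])
    } else {
      bounds[j] <- sprintf("[%g, %g)", lo, x$breaks[j + 1L])
    }
  }
  cat("size classes (dbh, cm): ",
      paste(sprintf("%s %s", x$labels, bounds), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify trees into size classes
#'
#' @param scheme A [size_scheme()].
#' @param dbh Numeric dbh values in cm; all must be at least the census
#'   minimum (the first break).
#' @return A factor with the scheme's labels, ordered small to large.
#' @rdname size_scheme
#' @export
classify_size <- function(scheme, dbh) {
  stopifnot(inherits(scheme, "size_scheme"))
  if (any(dbh < scheme$breaks[1L])) {
    stop(sprintf("dbh below the census threshold of %g cm", scheme$breaks[1L]))
  }
  inner <- scheme$breaks[-1L]
  k <- length(inner)
  idx <- rep(1L, length(dbh))
  for (j in seq_len(k)) {
    # last breakpoint strict (>), earlier breakpoints inclusive (>=)
    up <- if (j == k) dbh > inner[j] else dbh >= inner[j]
    idx <- idx + as.integer(up)
  }
  factor(scheme$labels[idx], levels = scheme$labels)
}

# internal: full pairwise distance matrix (small n only)
pairwise_distances <- function(pattern) {
  as.matrix(stats::dist(cbind(pattern$x, pattern$y)))
}
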