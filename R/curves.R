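#' Distance grid for second-order statistics
#'
#' Builds the ordered set of distances at which cumulative mingling
#' statistics are evaluated. Zero is excluded (no self-pairs; coincident
#' trees contribute at the first positive grid distance). The default covers
#' 0.25 to 30 m in 0.25 m steps, spanning the scales at which tree-to-tree
#' interactions are typically visible in forests while staying well inside a
#' 1-ha window.
#'
#' @param r_max Maximum distance in metres.
#' @param step Grid step in metres.
#' @return Numeric vector of strictly increasing distances `step, 2*step,
#'   ..., r_max`.
#' @export
r_grid <- function(r_max = 30, step = 0.25) {
  stopifnot(step > 0, r_max >= step)
  seq(step, r_max, by = step)
}

check_grid <- function(grid, window) {
  stopifnot(is.numeric(grid), length(grid) >= 1L, all(grid > 0),
            !is.unsorted(grid, strictly = TRUE))
  if (max(grid) >= min(window$a, window$b)) {
    stop("grid distances must stay below the shorter window side")
  }
  grid
}

new_mingling_curve <- function(r, value, kind, reference, n_pairs,
                               em = NULL) {
  structure(list(r = r, value = value, kind = kind, reference = reference,
                 n_pairs = n_pairs, em = em),
            class = "mingling_curve")
}

#' @export
print.mingling_curve <- function(x, ...) {
  lab <- switch(x$kind,
                K_m = "cumulative mark-product function K_m(r)",
                k_m = "cumulative mark mingling function k_m(r)",
                k_m_normalized = "normalized cumulative mark mingling function",
                delta = "mingling difference curve delta k(r)")
  cat(lab, "\n  reference: ", x$reference, "\n", sep = "")
  if (!is.null(x$em)) cat(sprintf("  expected mingling EM = %.6g\n", x$em))
  cat(sprintf("  r: %g .. %g m (%d points), %d defined\n",
              min(x$r), max(x$r), length(x$r), sum(!is.na(x$value))))
  invisible(x)
}

#' @export
plot.mingling_curve <- function(x, ylab = NULL, ...) {
  if (is.null(ylab)) {
    ylab <- switch(x$kind, K_m = expression(hat(K)[m](r)),
                   k_m = expression(hat(k)[m](r)),
                   k_m_normalized = expression(hat(k)[m](r) / EM[d]),
                   delta = expression(Delta * hat(k)[v](r)))
  }
  plot(x$r, x$value, type = "l", xlab = "r (m)", ylab = ylab, ...)
  if (x$kind == "delta") graphics::abline(h = 0, lty = 3)
  if (x$kind == "k_m_normalized") graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' @export
as.data.frame.mingling_curve <- function(x, ...) {
  data.frame(statistic = x$kind, reference_class = x$reference, r = x$r,
             value = x$value, em_d = if (is.null(x$em)) NA_real_ else x$em,
             n_pairs = x$n_pairs, stringsAsFactors = FALSE)
}

# shared pair machinery: cumulative numerator/denominator over the grid for
# reference subset `ref` (logical over trees)
curve_sums <- function(pattern, grid, ref) {
  res <- pair_bin_sums(pattern$x, pattern$y, as.integer(pattern$species),
                       ref, grid, pattern$window$a, pattern$window$b)
  list(num = cumsum(res$num), den = cumsum(res$den),
       npairs = cumsum(res$npairs))
}

resolve_reference <- function(pattern, scheme, class) {
  if (is.null(class)) {
    list(ref = rep(TRUE, pattern$n), label = "all")
  } else {
    stopifnot(inherits(scheme, "size_scheme"))
    cls <- classify_size(scheme, pattern$dbh)
    ref <- cls == class
    if (!any(ref)) stop(sprintf("size class '%s' is empty in this pattern", class))
    list(ref = ref, label = as.character(class))
  }
}

#' Cumulative mark-product function
#'
#' The un-normalized second-order summary underlying the mark mingling
#' function: for each grid distance r,
#' `(1/lhat^2) (1/A) * sum over ordered pairs within r of
#' 1(species_i != species_j) * omega_ij`, with `omega` the translation
#' edge-correction weight and `lhat = n/A` the intensity estimate. It mixes
#' the spatial structure of the unmarked pattern with the mark correlation
#' structure; [mingling_function()] removes the former.
#'
#' @param pattern A [tree_pattern()] with at least 2 trees.
#' @param grid Distance grid from [r_grid()].
#' @return A `mingling_curve` of kind `"K_m"`.
#' @export
mark_product_K <- function(pattern, grid = r_grid()) {
  stopifnot(inherits(pattern, "tree_pattern"))
  if (pattern$n < 2L) stop("need at least 2 trees")
  grid <- check_grid(grid, pattern$window)
  s <- curve_sums(pattern, grid, rep(TRUE, pattern$n))
  value <- s$num * pattern$window$area / pattern$n^2
  new_mingling_curve(grid, value, "K_m", "all", s$npairs)
}

#' Cumulative mark mingling function
#'
#' The edge-corrected proportion of heterospecific ordered pairs among all
#' ordered pairs within distance r of the reference trees:
#' `k_m(r) = sum(1(m_i != m_j) 1(d_ij <= r) w_ij) / sum(1(d_ij <= r) w_ij)`.
#' Reference trees i may be the whole pattern or one tree-size class;
#' partner trees j always range over the entire pattern. Values lie in
#' \[0, 1\]; where no pair is within r the value is `NA` (undefined, not
#' zero).
#'
#' @param pattern A [tree_pattern()].
#' @param grid Distance grid from [r_grid()].
#' @param scheme A [size_scheme()]; needed only when `class` is given.
#' @param class Optional size-class label restricting the reference trees.
#' @return A `mingling_curve` of kind `"k_m"`.
#' @export
mingling_function <- function(pattern, grid = r_grid(), scheme = NULL,
                              class = NULL) {
  stopifnot(inherits(pattern, "tree_pattern"))
  if (pattern$n < 2L) stop("need at least 2 trees")
  grid <- check_grid(grid, pattern$window)
  rr <- resolve_reference(pattern, scheme, class)
  s <- curve_sums(pattern, grid, rr$ref)
  value <- ifelse(s$den > 0, s$num / s$den, NA_real_)
  new_mingling_curve(grid, value, "k_m", rr$label, s$npairs)
}

#' Expected mingling of a size class
#'
#' Expected neighbourhood species mingling of size class d under random
#' species arrangement:
#' `EM_d = sum_i n_di * (n - n_i) / (n_d * (n - 1))` over species i, where
#' `n_i` is the species abundance, `n_d` the class size and `n_di` the
#' species count inside the class. This is the normalizer of
#' [normalized_mingling_function()]: the species-abundance-weighted chance
#' that a random partner of a class-d tree is heterospecific.
#'
#' @param pattern A [tree_pattern()].
#' @param scheme A [size_scheme()].
#' @param class A size-class label, or `NULL` for the whole pattern.
#' @return A number in \[0, 1\].
#' @examples
#' p <- tree_pattern(runif(10, 0, 50), runif(10, 0, 50),
#'                   rep(c("A", "B"), c(6, 4)), c(30, 30, 8, 8, 8, 8, 30, 30, 30, 8),
#'                   plot_window(0, 0, 50, 50))
#' expected_mingling(p, size_scheme(), "large")
#' @export
expected_mingling <- function(pattern, scheme = size_scheme(), class = NULL) {
  stopifnot(inherits(pattern, "tree_pattern"))
  rr <- resolve_reference(pattern, scheme, class)
  n <- pattern$n
  if (n < 2L) stop("need at least 2 trees")
  n_i <- table(pattern$species)
  n_di <- table(pattern$species[rr$ref])
  n_d <- sum(rr$ref)
  sum(as.numeric(n_di) * (n - as.numeric(n_i[names(n_di)]))) / (n_d * (n - 1))
}

#' Normalized cumulative mark mingling function
#'
#' The class-conditional mingling function divided by the class's expected
#' mingling `EM_d`, so that independent species arrangement gives values
#' fluctuating around 1: values below 1 indicate conspecific aggregation
#' around class-d trees at that scale, above 1 heterospecific aggregation.
#'
#' @inheritParams mingling_function
#' @param class Size-class label of the reference trees (required).
#' @return A `mingling_curve` of kind `"k_m_normalized"` carrying `em`.
#' @export
normalized_mingling_function <- function(pattern, grid = r_grid(),
                                         scheme = size_scheme(), class) {
  em <- expected_mingling(pattern, scheme, class)
  if (em <= 0) {
    stop("expected mingling is 0 (monospecific pattern): cannot normalize")
  }
  cv <- mingling_function(pattern, grid, scheme, class)
  new_mingling_curve(cv$r, cv$value / em, "k_m_normalized", cv$reference,
                     cv$n_pairs, em = em)
}

#' Mingling difference between two size classes
#'
#' Pointwise difference of the non-normalized mark mingling functions of a
#' larger and a smaller size class, `delta k_v(r) = k_hi(r) - k_lo(r)`.
#' Positive values mean the larger trees have more heterospecific
#' neighbourhoods within r than the smaller trees; whether the excess goes
#' beyond what species abundance and size-distribution differences alone
#' produce is judged against a null-model envelope
#' ([mingling_envelope()]).
#'
#' @inheritParams mingling_function
#' @param class_hi,class_lo Size-class labels of the larger and smaller
#'   class.
#' @return A `mingling_curve` of kind `"delta"`; `NA` where either operand
#'   is undefined.
#' @export
mingling_difference <- function(pattern, grid = r_grid(),
                                scheme = size_scheme(), class_hi, class_lo) {
  hi <- mingling_function(pattern, grid, scheme, class_hi)
  lo <- mingling_function(pattern, grid, scheme, class_lo)
  new_mingling_curve(hi$r, hi$value - lo$value, "delta",
                     paste0(class_hi, "-", class_lo),
                     hi$n_pairs + lo$n_pairs)
}
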