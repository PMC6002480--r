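# Independent brute-force oracles and pattern builders shared by the suite.
# Everything here deliberately avoids the package's pair-binning kernel:
# curves are recomputed by explicit enumeration over ordered pairs.

random_pattern <- function(n, n_species = 2, side = 50, seed = NULL,
                           dbh = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- plot_window(0, 0, side, side)
  tree_pattern(runif(n, 0, side), runif(n, 0, side),
               sample(LETTERS[seq_len(n_species)], n, replace = TRUE),
               if (is.null(dbh)) runif(n, 6, 60) else dbh, window = w)
}

# exhaustive all-pairs nearest-neighbour query, ties by ascending id
oracle_knn <- function(pattern, i, k) {
  pos <- match(i, pattern$id)
  d <- sqrt((pattern$x - pattern$x[pos])^2 + (pattern$y - pattern$y[pos])^2)
  ord <- order(d, pattern$id)
  ord <- ord[ord != pos]
  pattern$id[ord[seq_len(k)]]
}

# naive double-loop cumulative pair sums: reference trees i (logical), all
# partners j, translation weights recomputed from first principles
oracle_pair_sums <- function(pattern, grid, ref = rep(TRUE, pattern$n)) {
  a <- pattern$window$a; b <- pattern$window$b; A <- pattern$window$area
  num <- den <- numeric(length(grid))
  for (i in which(ref)) {
    for (j in seq_len(pattern$n)) {
      if (j == i) next
      dx <- pattern$x[j] - pattern$x[i]
      dy <- pattern$y[j] - pattern$y[i]
      d <- sqrt(dx^2 + dy^2)
      within <- d <= grid
      if (!any(within)) next
      w <- A / ((a - abs(dx)) * (b - abs(dy)))
      den <- den + within * w
      if (pattern$species[i] != pattern$species[j]) num <- num + within * w
    }
  }
  list(num = num, den = den)
}

oracle_K <- function(pattern, grid) {
  s <- oracle_pair_sums(pattern, grid)
  s$num * pattern$window$area / pattern$n^2
}

oracle_km <- function(pattern, grid, ref = rep(TRUE, pattern$n)) {
  s <- oracle_pair_sums(pattern, grid, ref)
  ifelse(s$den > 0, s$num / s$den, NA_real_)
}

oracle_em <- function(pattern, ref) {
  n <- pattern$n
  n_i <- table(pattern$species)
  n_di <- table(pattern$species[ref])
  sum(as.numeric(n_di) * (n - as.numeric(n_i[names(n_di)]))) /
    (sum(ref) * (n - 1))
}

# full-permutation two-sided rank-sum p-value (no ties assumed)
oracle_ranksum_p <- function(x, y) {
  nx <- length(x)
  ranks <- rank(c(x, y))
  obs <- sum(ranks[seq_len(nx)])
  sums <- combn(length(ranks), nx, function(idx) sum(ranks[idx]))
  min(1, 2 * min(mean(sums <= obs), mean(sums >= obs)))
}

# permute species labels in place (random relabelling null)
relabel <- function(pattern) {
  tree_pattern(pattern$x, pattern$y, sample(as.character(pattern$species)),
               pattern$dbh, window = pattern$window, id = pattern$id)
}

# whole-community expected mingling under random labelling
community_em <- function(pattern) {
  n <- pattern$n
  n_i <- as.numeric(table(pattern$species))
  sum((n_i / n) * (n - n_i) / (n - 1))
}
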