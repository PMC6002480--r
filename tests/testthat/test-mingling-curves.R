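test_that("mark-product function matches forced-step and monoculture cases", {
  w <- plot_window(0, 0, 100, 100)
  pm <- random_pattern(30, n_species = 1, seed = 21)
  Km <- mark_product_K(pm, r_grid(20, 1))
  expect_true(all(Km$value == 0))

  # two heterospecific trees 3 m apart: K jumps exactly at r = 3
  p2 <- tree_pattern(c(50, 53), c(50, 50), c("A", "B"), c(10, 12), window = w)
  K2 <- mark_product_K(p2, r_grid(10, 0.5))
  expect_true(all(K2$value[K2$r < 3] == 0))
  wpair <- translation_weight(w, 3, 0)
  expect_equal(K2$value[K2$r >= 3], rep(2 * wpair * 1e4 / 4, sum(K2$r >= 3)))
  expect_error(mark_product_K(tree_pattern(1, 1, "A", 10, window = w)),
               "at least 2")
})

test_that("hand-computed four-tree mingling function is reproduced", {
  w <- plot_window(0, 0, 20, 20)
  p <- tree_pattern(c(0, 1, 0, 10), c(0, 0, 1, 10),
                    c("A", "A", "B", "B"), rep(10, 4), window = w)
  km <- mingling_function(p, grid = c(2, 4))
  w12 <- 400 / (19 * 20)   # displacement (1,0)
  w13 <- 400 / (20 * 19)   # displacement (0,1)
  w23 <- 400 / (19 * 19)   # displacement (1,1)
  expected_r2 <- (2 * (w13 + w23)) / (2 * (w12 + w13 + w23))
  expect_equal(km$value[1], expected_r2, tolerance = 1e-12)
  expect_equal(expected_r2, 0.6724, tolerance = 1e-3)
  # oracle agreement on the same pattern
  expect_equal(km$value, oracle_km(p, c(2, 4)), tolerance = 1e-12)
})

test_that("curves agree with the brute-force oracle across random patterns", {
  scheme <- size_scheme()
  for (seed in 1:10) {
    p <- random_pattern(sample(20:200, 1), n_species = sample(2:5, 1),
                        seed = seed)
    grid <- r_grid(12, 1)
    expect_equal(mark_product_K(p, grid)$value, oracle_K(p, grid),
                 tolerance = 1e-12)
    expect_equal(mingling_function(p, grid)$value, oracle_km(p, grid),
                 tolerance = 1e-12)
    cls <- classify_size(scheme, p$dbh)
    for (cl in levels(droplevels(cls))) {
      ref <- cls == cl
      expect_equal(mingling_function(p, grid, scheme, cl)$value,
                   oracle_km(p, grid, ref), tolerance = 1e-12)
      expect_equal(expected_mingling(p, scheme, cl), oracle_em(p, ref),
                   tolerance = 1e-12)
    }
  }
})

test_that("curve values respect range, monotonicity, and pair-doubling symmetry", {
  p <- random_pattern(120, n_species = 3, seed = 33)
  grid <- r_grid(15, 0.5)
  km <- mingling_function(p, grid)
  ok <- !is.na(km$value)
  expect_true(all(km$value[ok] >= 0 & km$value[ok] <= 1))
  K <- mark_product_K(p, grid)
  expect_true(all(diff(K$value) >= 0))
  # unordered pairs counted twice give the identical ordered-pair sums
  s <- oracle_pair_sums(p, grid)
  half_num <- half_den <- numeric(length(grid))
  for (i in seq_len(p$n - 1)) {
    for (j in seq(i + 1, p$n)) {
      dx <- p$x[j] - p$x[i]; dy <- p$y[j] - p$y[i]
      within <- sqrt(dx^2 + dy^2) <= grid
      wij <- p$window$area / ((p$window$a - abs(dx)) * (p$window$b - abs(dy)))
      half_den <- half_den + within * wij
      if (p$species[i] != p$species[j]) half_num <- half_num + within * wij
    }
  }
  expect_equal(2 * half_num, s$num, tolerance = 1e-12)
  expect_equal(2 * half_den, s$den, tolerance = 1e-12)
})

test_that("expected mingling reproduces the closed-form examples", {
  w <- plot_window(0, 0, 50, 50)
  set.seed(5)
  # n = 10, species 6/4; class d: 5 trees with 2 of species A, 3 of B
  sp <- rep(c("A", "B"), c(6, 4))
  dbh <- c(30, 30, 8, 8, 8, 8, 30, 30, 30, 8)  # large: A,A,B,B,B
  p <- tree_pattern(runif(10, 0, 50), runif(10, 0, 50), sp, dbh, window = w)
  expect_equal(expected_mingling(p, size_scheme(), "large"), 26 / 45,
               tolerance = 1e-12)
  # whole pattern, two species 5/5
  p2 <- tree_pattern(runif(10, 0, 50), runif(10, 0, 50),
                     rep(c("A", "B"), 5), rep(30, 10), window = w)
  expect_equal(expected_mingling(p2, size_scheme(), "large"), 5 / 9,
               tolerance = 1e-12)
  # monoculture: zero for any class
  p3 <- tree_pattern(runif(10, 0, 50), runif(10, 0, 50), rep("A", 10),
                     rep(30, 10), window = w)
  expect_equal(expected_mingling(p3, size_scheme(), "large"), 0)
  expect_error(expected_mingling(p, size_scheme(), "medium"), "empty")
})

test_that("normalization and difference identities hold", {
  scheme <- size_scheme()
  p <- random_pattern(150, n_species = 3, seed = 44)
  grid <- r_grid(15, 0.5)
  cl <- "large"
  nf <- normalized_mingling_function(p, grid, scheme, cl)
  base <- mingling_function(p, grid, scheme, cl)
  em <- expected_mingling(p, scheme, cl)
  expect_equal(nf$value, base$value / em, tolerance = 1e-12)
  expect_equal(nf$em, em)

  d_ll <- mingling_difference(p, grid, scheme, cl, cl)
  expect_true(all(d_ll$value[!is.na(d_ll$value)] == 0))
  d_hl <- mingling_difference(p, grid, scheme, "large", "small")
  d_lh <- mingling_difference(p, grid, scheme, "small", "large")
  expect_equal(d_hl$value, -d_lh$value, tolerance = 1e-12)

  pm <- random_pattern(30, n_species = 1, seed = 2)
  expect_error(normalized_mingling_function(pm, grid, scheme, "large"),
               "monospecific")
})

test_that("whole-pattern curve approaches expected mingling under random labelling", {
  set.seed(90)
  base <- random_pattern(150, n_species = 2, seed = 55)
  grid <- r_grid(20, 20)  # single point near r_max: nearly all pairs
  vals <- replicate(80, {
    p <- relabel(base)
    mingling_function(p, grid)$value[1]
  })
  expected <- community_em(base)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se + 1e-3)
})

test_that("normalized curve of a random labelling has no trend in r", {
  set.seed(91)
  base <- random_pattern(200, n_species = 2, seed = 66)
  grid <- r_grid(15, 1)
  curves <- replicate(60, {
    normalized_mingling_function(relabel(base), grid, size_scheme(),
                                 "large")$value
  })
  m <- rowMeans(curves, na.rm = TRUE)
  fit <- lm(m ~ grid)
  slope_se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(coef(fit)[2]), 3 * slope_se + 5e-3)
  expect_equal(mean(m), 1, tolerance = 0.05)
})
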