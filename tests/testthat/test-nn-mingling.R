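test_that("mingling index counts heterospecific nearest neighbours", {
  w <- plot_window(-20, -20, 20, 20)
  # monoculture: no heterospecific neighbour can exist
  pm <- random_pattern(20, n_species = 1, seed = 2)
  for (i in c(0L, 7L, 19L)) expect_equal(mingling_index(pm, i, 4), 0)
  # centre A surrounded by four B
  p <- tree_pattern(c(0, 1, -1, 0, 0), c(0, 0, 0, 1, -1),
                    c("A", "B", "B", "B", "B"), rep(10, 5), window = w)
  expect_equal(mingling_index(p, 0, 4), 1)
  # neighbours at distances 1..4 with species A,B,B,A
  p2 <- tree_pattern(c(0, 1, 2, 3, 4, 15), c(0, 0, 0, 0, 0, 15),
                     c("A", "A", "B", "B", "A", "B"), rep(10, 6), window = w)
  expect_equal(mingling_index(p2, 0, 4), 0.5)
})

test_that("mingling summaries take admissible values and group levels", {
  pm <- random_pattern(20, n_species = 1, seed = 3)
  sm <- mingling_summary(pm)
  expect_true(all(sm$m == 0))
  expect_equal(unname(sm$counts[["{0,0.25}"]]), 20L)
  expect_equal(sum(sm$counts), 20L)

  # alternating two-species lattice: interior trees see only the four
  # orthogonal (heterospecific) neighbours; border trees pick up conspecific
  # diagonals. Per-tree values match the brute-force index everywhere.
  g <- expand.grid(x = 1:8, y = 1:8)
  sp <- ifelse((g$x + g$y) %% 2 == 0, "A", "B")
  pl <- tree_pattern(g$x, g$y, sp, rep(10, 64),
                     window = plot_window(0, 0, 9, 9))
  sml <- mingling_summary(pl)
  interior <- g$x %in% 2:7 & g$y %in% 2:7
  expect_true(all(sml$m[interior] == 1))
  expect_equal(unname(sml$counts[["1"]]), 36L)
  brute <- vapply(pl$id, function(i) {
    nb <- oracle_knn(pl, i, 4)
    mean(sp[nb + 1L] != sp[i + 1L])
  }, numeric(1))
  expect_equal(sml$m, brute)

  # admissible values only, for k = 4
  pr <- random_pattern(150, n_species = 3, seed = 5)
  smr <- mingling_summary(pr)
  expect_true(all(smr$m %in% c(0, 0.25, 0.5, 0.75, 1)))
  expect_equal(sum(smr$counts), 150L)
  expect_error(mingling_summary(random_pattern(4, seed = 1)), "more than k")
})

test_that("mean mingling under random labelling matches the abundance formula", {
  set.seed(81)
  w <- plot_window(0, 0, 60, 60)
  x <- runif(200, 0, 60); y <- runif(200, 0, 60)
  means <- replicate(100, {
    p <- tree_pattern(x, y, sample(rep(c("A", "B"), each = 100)),
                      rep(10, 200), window = w)
    mean(mingling_summary(p)$m)
  })
  expected <- (200 - 100) / (200 - 1)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - expected), 3 * se + 1e-12)
})

test_that("rank-sum pair test reproduces the exact null distribution", {
  # frozen exact case: most extreme non-overlapping 3 vs 3 split
  expect_equal(unname(treemingle:::ranksum_pair(c(1, 2, 3), c(4, 5, 6))["p"]),
               0.1)
  # exchangeable identical groups: p = 1 within tie-handling tolerance
  p_ident <- unname(treemingle:::ranksum_pair(c(5, 5, 7, 7), c(5, 5, 7, 7))["p"])
  expect_gt(p_ident, 0.95)
  # full-permutation oracle over a sweep of untied group sizes
  set.seed(42)
  for (nx in 2:8) {
    for (ny in c(2L, 5L, 8L)) {
      v <- sample(seq_len(40), nx + ny)  # distinct -> no ties
      x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
      expect_equal(unname(treemingle:::ranksum_pair(x, y)["p"]),
                   oracle_ranksum_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("dbh rank tests across mingling levels detect constructed ordering", {
  set.seed(7)
  p0 <- random_pattern(300, n_species = 2, seed = 9)
  sm0 <- mingling_summary(p0)
  # re-mark dbh as an increasing function of the mingling level plus noise
  dbh <- 8 + 30 * sm0$m + rnorm(300, 0, 1)
  p <- tree_pattern(p0$x, p0$y, as.character(p0$species), pmax(dbh, 5.5),
                    window = p0$window)
  sm <- mingling_summary(p)
  expect_true(all(table(sm$level) >= 2))
  ts <- dbh_mingling_test(sm)
  expect_true(all(ts$pairs$p_adj < 0.05))
  expect_true(all(ts$pairs$p_adj >= ts$pairs$p))
  # strictly separated groups get distinct single letters, ordered by level
  expect_equal(unname(nchar(ts$letters)), rep(1L, length(ts$letters)))
  expect_equal(length(unique(ts$letters)), length(ts$letters))
  # medians increase with the mingling level
  expect_true(all(diff(ts$medians) > 0))
})

test_that("pairwise table wires each level pair to the rank-sum helper", {
  set.seed(31)
  p0 <- random_pattern(60, n_species = 2, seed = 13)
  sm <- mingling_summary(p0)
  ts <- dbh_mingling_test(sm)
  expect_gte(nrow(ts$pairs), 1L)
  for (row in seq_len(nrow(ts$pairs))) {
    x <- p0$dbh[sm$level == ts$pairs$level1[row]]
    y <- p0$dbh[sm$level == ts$pairs$level2[row]]
    ref <- treemingle:::ranksum_pair(x, y)
    expect_equal(ts$pairs$p[row], unname(ref["p"]), tolerance = 1e-12)
    expect_equal(ts$pairs$statistic[row], unname(ref["statistic"]))
  }
  expect_equal(ts$pairs$p_adj, p.adjust(ts$pairs$p, method = "holm"))
})

test_that("bivariate dbh-by-mingling density integrates to one and locates modes", {
  # all trees at one dbh and one level: single peak, full mass in that level
  pm <- random_pattern(20, n_species = 1, seed = 2, dbh = rep(30, 20))
  smm <- mingling_summary(pm)
  d1 <- mingling_dbh_density(smm, bandwidth = 2)
  mass <- colSums(d1$density) * diff(d1$dbh[1:2])
  expect_equal(sum(mass), 1, tolerance = 0.01)
  expect_equal(unname(mass[["{0,0.25}"]]), 1, tolerance = 0.01)
  expect_equal(d1$dbh[which.max(d1$density[, "{0,0.25}"])], 30,
               tolerance = diff(d1$dbh[1:2]))

  # two-species mixture: level-1 trees large, low-mingling trees small
  set.seed(12)
  p0 <- random_pattern(400, n_species = 2, seed = 19)
  sm0 <- mingling_summary(p0)
  dbh <- ifelse(sm0$m == 1, rnorm(400, 30, 2), rnorm(400, 10, 2))
  p <- tree_pattern(p0$x, p0$y, as.character(p0$species), pmax(dbh, 5.5),
                    window = p0$window)
  sm <- mingling_summary(p)
  dd <- mingling_dbh_density(sm, bandwidth = 1.5)
  step <- diff(dd$dbh[1:2])
  expect_equal(sum(colSums(dd$density)) * step, 1, tolerance = 0.01)
  expect_equal(dd$dbh[which.max(dd$density[, "1"])], 30, tolerance = step + 0.5)
  expect_equal(dd$dbh[which.max(dd$density[, "{0,0.25}"])], 10,
               tolerance = step + 0.5)
  expect_error(mingling_dbh_density(sm, bandwidth = -1), "bandwidth")
})
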