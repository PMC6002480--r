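# truncated-normal dbh: rejection below the floor keeps the nominal mean
# approximately and matches the census threshold
rtrunc_normal <- function(n, mean, sd, floor) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < floor)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < floor]
  }
  out
}

#' Simulate a dependent-marked two-species stand
#'
#' Generates a marked point pattern in which conspecific small trees are
#' aggregated while large trees are surrounded by heterospecific
#' neighbours, in four steps:
#'
#' 1. Tree locations follow a homogeneous Poisson process of intensity
#'    `lambda` in the window (optionally conditioned on a fixed count).
#' 2. A tree is marked species 1 if the distance to its second-nearest
#'    neighbour is below `r0`, species 2 otherwise — locally dense trees
#'    become the common species, aggregating conspecifics.
#' 3. dbh is drawn per species from a normal distribution (defaults: means
#'    20 and 30 cm, sd 5 cm) truncated below at `dbh_floor`, so species 1
#'    is the common small-tree species and species 2 the less abundant
#'    large-tree species.
#' 4. For every tree with dbh above `reassign_threshold` (ascending id
#'    order), its nearest neighbour's species is set to differ from the
#'    reference tree's current species, later assignments overriding
#'    earlier ones. This plants heterospecific neighbourhoods around large
#'    trees at short range.
#'
#' @param lambda Point intensity, trees per m^2 (default 0.1).
#' @param window A [plot_window()] (default 100 x 100 m).
#' @param r0 Second-nearest-neighbour distance threshold in metres
#'   (default 2.5).
#' @param dbh_mean,dbh_sd Length-2 numeric: normal dbh mean and sd per
#'   species, cm.
#' @param dbh_floor Lower truncation of dbh in cm (default 5, the census
#'   threshold).
#' @param reassign_threshold dbh (cm) above which a tree forces a
#'   heterospecific nearest neighbour (default 25); `reassign = FALSE`
#'   skips step 4 (useful for studying the marking rule itself).
#' @param fixed_n If non-`NULL`, condition the Poisson process on exactly
#'   this many trees.
#' @param reassign Run step 4? Default `TRUE`.
#' @param seed Optional integer seed.
#' @return A [tree_pattern()] with species labels `"1"` and `"2"`.
#' @export
simulate_dependent_marking <- function(lambda = 0.1,
                                       window = plot_window(0, 0, 100, 100),
                                       r0 = 2.5,
                                       dbh_mean = c(20, 30),
                                       dbh_sd = c(5, 5),
                                       dbh_floor = 5,
                                       reassign_threshold = 25,
                                       fixed_n = NULL,
                                       reassign = TRUE,
                                       seed = NULL) {
  stopifnot(lambda > 0, r0 >= 0, length(dbh_mean) == 2L,
            length(dbh_sd) == 2L, all(dbh_sd > 0),
            all(dbh_mean > dbh_floor), dbh_floor >= 0)
  if (!is.null(seed)) set.seed(seed)
  expected <- lambda * window$area
  if (expected < 10) {
    warning("expected tree count below 10: summary statistics will be unreliable")
  }
  n <- if (is.null(fixed_n)) stats::rpois(1L, expected) else as.integer(fixed_n)
  if (n < 3L) stop("simulated pattern has fewer than 3 trees; increase lambda")
  x <- stats::runif(n, window$xmin, window$xmax)
  y <- stats::runif(n, window$ymin, window$ymax)
  # step 2: species from the second-nearest-neighbour distance
  dm <- as.matrix(stats::dist(cbind(x, y)))
  diag(dm) <- Inf
  d2 <- apply(dm, 1L, function(row) sort.int(row, partial = 2L)[2L])
  species <- ifelse(d2 < r0, 1L, 2L)
  # step 3: species-specific truncated-normal dbh
  dbh <- numeric(n)
  for (s in 1:2) {
    idx <- which(species == s)
    dbh[idx] <- rtrunc_normal(length(idx), dbh_mean[s], dbh_sd[s], dbh_floor)
  }
  # step 4: large trees force a heterospecific nearest neighbour
  if (reassign) {
    ids <- which(dbh > reassign_threshold)  # ascending id order
    for (i in ids) {
      nn <- order(dm[i, ], seq_len(n))[1L]
      species[nn] <- 3L - species[i]
    }
  }
  tree_pattern(x, y, as.character(species), dbh, window = window)
}

#' Simulate a clustered multi-species community
#'
#' Generates a stand-in for a mapped multi-species forest plot: per species
#' a Thomas-type cluster process (Poisson-distributed parents, Gaussian
#' offspring displacements, conditioned on the requested abundance; torus
#' wrapping keeps offspring in the window) with species-specific
#' truncated-normal dbh. Setting `clustered = FALSE` places each species
#' uniformly instead.
#'
#' @param abundance Named integer vector: trees per species; names become
#'   species labels.
#' @param dbh_mean,dbh_sd Numeric vectors (recycled over species): dbh
#'   normal location and scale in cm.
#' @param parents_per_ha Expected cluster parents per hectare per species
#'   (default 15).
#' @param cluster_sd Gaussian offspring displacement sd in metres
#'   (default 5).
#' @param dbh_floor Lower dbh truncation in cm (default 5).
#' @param window A [plot_window()] (default 100 x 100 m).
#' @param clustered Cluster conspecifics? Default `TRUE`.
#' @param seed Optional integer seed.
#' @return A [tree_pattern()].
#' @examples
#' p <- simulate_community(c(A = 300, B = 200, C = 100),
#'                         dbh_mean = c(12, 15, 30), dbh_sd = 4, seed = 1)
#' @export
simulate_community <- function(abundance,
                               dbh_mean = 15, dbh_sd = 5,
                               parents_per_ha = 15, cluster_sd = 5,
                               dbh_floor = 5,
                               window = plot_window(0, 0, 100, 100),
                               clustered = TRUE, seed = NULL) {
  stopifnot(length(abundance) >= 1L, all(abundance >= 0), cluster_sd > 0)
  if (is.null(names(abundance))) {
    names(abundance) <- paste0("sp", seq_along(abundance))
  }
  s <- length(abundance)
  dbh_mean <- rep_len(dbh_mean, s)
  dbh_sd <- rep_len(dbh_sd, s)
  if (sum(abundance) == 0L) warning("total abundance is zero: empty pattern")
  if (!is.null(seed)) set.seed(seed)
  xs <- ys <- dbhs <- numeric(0)
  sps <- character(0)
  for (k in seq_len(s)) {
    n_k <- abundance[[k]]
    if (n_k == 0L) next
    if (clustered) {
      n_par <- max(1L, stats::rpois(1L, parents_per_ha * window$area / 1e4))
      px <- stats::runif(n_par, window$xmin, window$xmax)
      py <- stats::runif(n_par, window$ymin, window$ymax)
      parent <- sample.int(n_par, n_k, replace = TRUE)
      xk <- px[parent] + stats::rnorm(n_k, 0, cluster_sd)
      yk <- py[parent] + stats::rnorm(n_k, 0, cluster_sd)
      # torus wrap keeps the process stationary inside the window
      xk <- window$xmin + (xk - window$xmin) %% window$a
      yk <- window$ymin + (yk - window$ymin) %% window$b
    } else {
      xk <- stats::runif(n_k, window$xmin, window$xmax)
      yk <- stats::runif(n_k, window$ymin, window$ymax)
    }
    xs <- c(xs, xk); ys <- c(ys, yk)
    sps <- c(sps, rep(names(abundance)[k], n_k))
    dbhs <- c(dbhs, rtrunc_normal(n_k, dbh_mean[k], dbh_sd[k], dbh_floor))
  }
  tree_pattern(xs, ys, sps, dbhs, window = window)
}
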