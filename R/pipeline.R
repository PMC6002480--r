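# internal: one randomization pass evaluating several curve statistics per
# replicate, so a set of envelopes shares its replicate patterns
mc_envelopes <- function(pattern, statfun, null = "homogeneous",
                         nsim = 1000, seed = 1, bandwidth = 20,
                         grid_step = 1) {
  obs <- statfun(pattern)
  stopifnot(is.list(obs), !is.null(names(obs)))
  vals <- lapply(obs, function(o) if (inherits(o, "mingling_curve")) o$value else o)
  rs <- lapply(obs, function(o) if (inherits(o, "mingling_curve")) o$r else seq_along(o))
  surfaces <- NULL
  if (null == "heterogeneous") {
    sp_levels <- levels(droplevels(pattern$species))
    surfaces <- lapply(sp_levels, function(sp) {
      estimate_intensity(pattern, sp, bandwidth = bandwidth,
                         grid_step = grid_step)
    })
    names(surfaces) <- sp_levels
  }
  sims <- lapply(vals, function(v) matrix(NA_real_, nsim, length(v)))
  for (i in seq_len(nsim)) {
    si <- substream_seed(seed, i)
    rep_pat <- if (null == "homogeneous") {
      randomize_homogeneous(pattern, seed = si)
    } else {
      randomize_heterogeneous(pattern, surfaces, seed = si)
    }
    v <- statfun(rep_pat)
    for (nm in names(vals)) {
      vi <- v[[nm]]
      if (inherits(vi, "mingling_curve")) vi <- vi$value
      sims[[nm]][i, ] <- vi
    }
  }
  out <- lapply(names(vals), function(nm) {
    env <- envelope_from_sims(sims[[nm]])
    structure(c(list(r = rs[[nm]], observed = vals[[nm]]), env,
                list(nsim = nsim, null = null, seed = seed,
                     curve = if (inherits(obs[[nm]], "mingling_curve")) obs[[nm]] else NULL)),
              class = "mingling_envelope")
  })
  names(out) <- names(vals)
  out
}

config_digest <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

try_png <- function(path, width = 900, height = 600) {
  ok <- tryCatch({
    grDevices::png(path, width = width, height = height)
    TRUE
  }, error = function(e) {
    warning(sprintf("plot device unavailable, skipping %s (%s)",
                    basename(path), conditionMessage(e)))
    FALSE
  })
  ok
}

write_manifest <- function(outdir, stage, config, files, seed = NULL,
                           warnings = character(0)) {
  manifest <- list(stage = stage, created = format(Sys.time(), tz = "UTC"),
                   seed = seed, config_digest = config_digest(config),
                   files = files, warnings = warnings)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Nearest-neighbour mingling report
#'
#' End-to-end nearest-neighbour analysis of one plot: per-tree mingling
#' indices, pairwise dbh rank tests across grouped mingling levels, and the
#' bivariate dbh-by-mingling density, all written as CSV to `outdir` with a
#' machine-readable manifest. Plots (per-level dbh boxplot, perspective
#' density) are optional artifacts; every number is always available as
#' CSV.
#'
#' @param pattern A [tree_pattern()].
#' @param outdir Output directory (created if needed).
#' @param k Neighbour count for the mingling index (default 4).
#' @param alpha Significance level for the letter display.
#' @param bandwidth Bandwidth for [mingling_dbh_density()].
#' @param plots Write plot files? Default `TRUE`.
#' @return Invisibly, a list with the `mingling_summary`, the test result
#'   (or `NULL` when only one level is occupied), the density, and the
#'   manifest.
#' @export
run_mingling_analysis <- function(pattern, outdir, k = 4, alpha = 0.05,
                                  bandwidth = "auto", plots = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  warns <- character(0)
  ms <- mingling_summary(pattern, k = k)
  per_tree <- cbind(id = pattern$id, as.data.frame(pattern),
                    m = ms$m, level = as.character(ms$level))
  files <- list()
  f <- file.path(outdir, "mingling_per_tree.csv")
  utils::write.csv(per_tree, f, row.names = FALSE)
  files$per_tree <- basename(f)

  test <- NULL
  if (sum(ms$counts >= 2L) >= 2L) {
    test <- withCallingHandlers(
      dbh_mingling_test(ms, alpha = alpha),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    tab <- test$pairs
    f <- file.path(outdir, "pairwise_tests.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    files$pairwise_tests <- basename(f)
    f <- file.path(outdir, "level_letters.csv")
    utils::write.csv(data.frame(level = names(test$letters),
                                median_dbh = test$medians,
                                letters = test$letters),
                     f, row.names = FALSE)
    files$level_letters <- basename(f)
  } else {
    warns <- c(warns, "fewer than two occupied mingling levels: rank tests skipped")
    warning(warns[length(warns)])
  }

  dens <- mingling_dbh_density(ms, bandwidth = bandwidth)
  f <- file.path(outdir, "bivariate_density.csv")
  utils::write.csv(as.data.frame(dens), f, row.names = FALSE)
  files$bivariate_density <- basename(f)

  if (plots) {
    f <- file.path(outdir, "dbh_by_mingling.png")
    if (try_png(f)) {
      plot(ms, main = "dbh by grouped mingling level")
      grDevices::dev.off()
      files$boxplot <- basename(f)
    }
    f <- file.path(outdir, "bivariate_density.png")
    if (try_png(f)) {
      plot(dens)
      grDevices::dev.off()
      files$density_plot <- basename(f)
    }
  }
  manifest <- write_manifest(outdir, "nn_mingling",
                             list(k = k, alpha = alpha, bandwidth = bandwidth,
                                  n = pattern$n),
                             files, warnings = warns)
  invisible(list(summary = ms, test = test, density = dens,
                 manifest = manifest))
}

#' Size-class mingling-curve report
#'
#' End-to-end second-order analysis of one plot: per size class the
#' non-normalized and normalized cumulative mark mingling functions with
#' pointwise Monte-Carlo envelopes, and for every (larger, smaller) class
#' pair the difference curve of non-normalized functions with its envelope.
#' One set of location-randomized replicates (marks retained) drives all
#' envelopes. Results are written as long-format CSV plus a manifest;
#' envelope plots are optional artifacts.
#'
#' @param pattern A [tree_pattern()].
#' @param outdir Output directory.
#' @param scheme A [size_scheme()]; classes without trees are skipped with a
#'   logged warning.
#' @param grid Distance grid from [r_grid()].
#' @param null `"homogeneous"` or `"heterogeneous"` location
#'   randomization. Two-species simulated stands are conventionally tested
#'   against the homogeneous null; real multi-species plots against the
#'   heterogeneous null, which preserves habitat-scale structure.
#' @param nsim Monte-Carlo replicates (default 1000).
#' @param seed Master seed for the replicate substreams.
#' @param bandwidth,grid_step Heterogeneous-null intensity settings.
#' @param plots Write plot files? Default `TRUE`.
#' @return Invisibly, a list with `envelopes` (named: `class:<label>` for
#'   normalized per-class curves, `delta:<hi>-<lo>` for differences),
#'   `curves` (observed non-normalized per-class curves), `em` (per-class
#'   expected mingling) and the manifest.
#' @export
run_curve_analysis <- function(pattern, outdir, scheme = size_scheme(),
                               grid = r_grid(),
                               null = c("heterogeneous", "homogeneous"),
                               nsim = 1000, seed = 1, bandwidth = 20,
                               grid_step = 1, plots = TRUE) {
  null <- match.arg(null)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  warns <- character(0)
  cls <- classify_size(scheme, pattern$dbh)
  present <- scheme$labels[scheme$labels %in% levels(droplevels(cls))]
  skipped <- setdiff(scheme$labels, present)
  if (length(skipped)) {
    warns <- c(warns, sprintf("empty size class(es) skipped: %s",
                              paste(skipped, collapse = ", ")))
    warning(warns[length(warns)])
  }
  if (!length(present)) stop("no occupied size class")

  pairs <- if (length(present) >= 2L) {
    idx <- utils::combn(seq_along(present), 2L)
    # higher class minus lower class
    lapply(seq_len(ncol(idx)), function(j) {
      c(hi = present[max(idx[, j])], lo = present[min(idx[, j])])
    })
  } else list()

  statfun <- function(p) {
    out <- list()
    for (cl in present) {
      out[[paste0("class:", cl)]] <-
        normalized_mingling_function(p, grid, scheme, cl)
    }
    for (pr in pairs) {
      out[[paste0("delta:", pr[["hi"]], "-", pr[["lo"]])]] <-
        mingling_difference(p, grid, scheme, pr[["hi"]], pr[["lo"]])
    }
    out
  }
  envs <- mc_envelopes(pattern, statfun, null = null, nsim = nsim,
                       seed = seed, bandwidth = bandwidth,
                       grid_step = grid_step)

  curves <- lapply(present, function(cl) mingling_function(pattern, grid, scheme, cl))
  names(curves) <- present
  em <- vapply(present, function(cl) expected_mingling(pattern, scheme, cl),
               numeric(1))

  files <- list()
  env_rows <- do.call(rbind, lapply(names(envs), function(nm) {
    df <- as.data.frame(envs[[nm]])
    df$statistic <- if (startsWith(nm, "delta:")) "delta" else "k_m_normalized"
    df$reference_class <- sub("^(class|delta):", "", nm)
    df
  }))
  f <- file.path(outdir, "envelopes.csv")
  utils::write.csv(env_rows, f, row.names = FALSE)
  files$envelopes <- basename(f)

  curve_rows <- do.call(rbind, lapply(present, function(cl) {
    df <- as.data.frame(curves[[cl]])
    df$em_d <- em[[cl]]
    df
  }))
  f <- file.path(outdir, "class_curves.csv")
  utils::write.csv(curve_rows, f, row.names = FALSE)
  files$class_curves <- basename(f)

  if (plots) {
    for (nm in names(envs)) {
      f <- file.path(outdir, paste0("envelope_", gsub("[^A-Za-z0-9._-]", "_", nm), ".png"))
      if (try_png(f)) {
        plot(envs[[nm]], ylab = nm, main = nm)
        grDevices::dev.off()
        files[[paste0("plot_", nm)]] <- basename(f)
      }
    }
  }
  manifest <- write_manifest(outdir, "mingling_curves",
                             list(breaks = scheme$breaks, null = null,
                                  nsim = nsim, r_max = max(grid),
                                  step = grid[2L] - grid[1L],
                                  bandwidth = bandwidth, n = pattern$n),
                             files, seed = seed, warnings = warns)
  invisible(list(envelopes = envs, curves = curves, em = em,
                 manifest = manifest))
}
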