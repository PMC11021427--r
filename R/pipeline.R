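# deterministic per-stage seed derived from the master seed and stage name,
# kept inside the 32-bit integer range
stage_seed <- function(master, stage) {
  b <- utf8ToInt(stage)
  h <- sum(b * seq_along(b)) %% 2147483647
  as.integer((as.numeric(master) * 48271 + h * 69621) %% 2147483646 + 1)
}

#' Default 30-year land-change transition matrix
#'
#' A degradation-scenario matrix over the seven-class legend in which
#' forest and rangeland convert mainly to agriculture and built-up land
#' while water and built-up persist. One application moves the default
#' landscape's habitat share (82%) to roughly two thirds, and a second to
#' roughly half — the trajectory observed in semi-arid watersheds losing
#' habitat to cropland and construction over consecutive 30-year periods.
#'
#' @return An `hs_transition` with `period_years = 30`.
#' @export
default_transition <- function() {
  p <- matrix(c(
    0.75, 0.00, 0.05, 0.04, 0, 0.13, 0.03,
    0.00, 0.70, 0.10, 0.05, 0, 0.12, 0.03,
    0.00, 0.02, 0.65, 0.15, 0, 0.13, 0.05,
    0.00, 0.00, 0.03, 0.62, 0, 0.22, 0.13,
    0.00, 0.00, 0.00, 0.00, 1, 0.00, 0.00,
    0.00, 0.00, 0.00, 0.02, 0, 0.92, 0.06,
    0.00, 0.00, 0.00, 0.00, 0, 0.00, 1.00
  ), nrow = 7, byrow = TRUE)
  as_transition(p, lulc_legend(), period_years = 30)
}

#' Scenario configuration for the end-to-end analysis
#'
#' Bundles the synthetic-landscape settings, the historical transition
#' matrix driving the first period, habitat-quality parameters and the
#' tiling used for the quality-vs-pattern correlation.
#'
#' @param synth An [synthetic_config()]; its `seed` is the master seed of
#'   the scenario.
#' @param years Three strictly increasing dates `(t0, t1, t2)`; the map at
#'   `t1` evolves from `t0` under `historical`, and `t2` is projected from
#'   the estimated `t0 -> t1` matrix in one Markov step.
#' @param historical An `hs_transition` generating the first period.
#' @param clumping_bias Contagion strength of the simulated change (see
#'   [evolve_landcover()]).
#' @param k,z Habitat-quality parameters (see [habitat_quality()]); `k` is
#'   resolved on the baseline date and reused for later dates so quality is
#'   comparable over time.
#' @param threats_csv,sensitivity_csv Optional parameter-table overrides.
#' @param tile_size Analysis-unit tile side in cells (>= 4, default 16).
#' @return An `hs_scenario_config` list.
#' @export
scenario_config <- function(synth = synthetic_config(),
                            years = c(1991, 2021, 2051),
                            historical = default_transition(),
                            clumping_bias = 0.5,
                            k = "auto", z = 2.5,
                            threats_csv = NULL, sensitivity_csv = NULL,
                            tile_size = 16) {
  if (length(years) != 3 || any(diff(years) <= 0)) {
    stop("years must be three strictly increasing dates")
  }
  if (tile_size < 4) stop("tile_size must be >= 4")
  structure(
    list(synth = synth, years = years, historical = historical,
         clumping_bias = clumping_bias, k = k, z = z,
         threats_csv = threats_csv, sensitivity_csv = sensitivity_csv,
         tile_size = tile_size),
    class = "hs_scenario_config"
  )
}

#' Read / write a scenario configuration as YAML
#' @param path YAML file path.
#' @return `read_scenario_config()` returns an `hs_scenario_config`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  sy <- do.call(synthetic_config, y$synth)
  hist <- if (!is.null(y$historical_probs)) {
    as_transition(matrix(unlist(y$historical_probs), nrow = 7, byrow = TRUE),
                  period_years = diff(y$years[1:2]))
  } else {
    default_transition()
  }
  scenario_config(
    synth = sy, years = y$years, historical = hist,
    clumping_bias = y$clumping_bias %||% 0.5,
    k = y$k %||% "auto", z = y$z %||% 2.5,
    threats_csv = y$threats_csv, sensitivity_csv = y$sensitivity_csv,
    tile_size = y$tile_size %||% 16
  )
}

#' @rdname read_scenario_config
#' @param config An `hs_scenario_config`.
#' @export
write_scenario_config <- function(config, path) {
  y <- list(
    synth = config$synth[c("n_rows", "n_cols", "cell_size",
                           "class_proportions", "clumping", "n_main_roads",
                           "n_minor_roads", "n_mines", "seed")],
    years = config$years,
    historical_probs = apply(config$historical$probs, 1, as.list),
    clumping_bias = config$clumping_bias,
    k = config$k, z = config$z,
    threats_csv = config$threats_csv,
    sensitivity_csv = config$sensitivity_csv,
    tile_size = config$tile_size
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition a landscape into rectangular analysis units
#'
#' Non-overlapping tiles of `tile_size` cells; a trailing partial strip is
#' kept as its own tiles when it is at least a quarter of a tile wide and
#' merged into the neighbouring strip otherwise. Units without valid cells
#' are dropped.
#'
#' @param landcover An `hs_raster`.
#' @param tile_size Tile side in cells (>= 4). Tiles larger than the grid
#'   give a single unit.
#' @return Tibble with columns `unit`, `rmin`, `rmax`, `cmin`, `cmax`,
#'   `n_valid`.
#' @export
tile_landscape <- function(landcover, tile_size = 16) {
  if (tile_size < 4) stop("tile_size must be >= 4")
  axis_blocks <- function(n) {
    starts <- seq(1L, n, by = tile_size)
    ends <- pmin(starts + tile_size - 1L, n)
    k <- length(starts)
    if (k > 1 && (ends[k] - starts[k] + 1) < tile_size / 4) {
      ends[k - 1] <- ends[k]
      starts <- starts[-k]; ends <- ends[-k]
    }
    cbind(starts, ends)
  }
  rb <- axis_blocks(nrow(landcover$values))
  cb <- axis_blocks(ncol(landcover$values))
  units <- tidyr::expand_grid(ri = seq_len(nrow(rb)), ci = seq_len(nrow(cb)))
  out <- tibble::tibble(
    rmin = unname(rb[units$ri, 1]), rmax = unname(rb[units$ri, 2]),
    cmin = unname(cb[units$ci, 1]), cmax = unname(cb[units$ci, 2])
  )
  out$n_valid <- unname(purrr::pmap_int(out, function(rmin, rmax, cmin, cmax) {
    sum(!is.na(landcover$values[rmin:rmax, cmin:cmax]))
  }))
  out <- out[out$n_valid > 0, ]
  dplyr::bind_cols(tibble::tibble(unit = seq_len(nrow(out))), out)
}

#' Per-unit habitat quality and pattern metrics
#'
#' One row per analysis unit: mean habitat quality over the unit plus the
#' landscape metrics of the unit's sub-raster.
#'
#' @param quality An `hs_quality` or quality `hs_cont_raster` aligned with
#'   `landcover`.
#' @param landcover The `hs_cat_raster` the units refer to.
#' @param units Tibble from [tile_landscape()].
#' @return Tibble with columns `unit`, `n_valid`, `mean_hq`, `np`, `pd`,
#'   `shdi`, `contag`.
#' @export
per_unit_stats <- function(quality, landcover, units) {
  qr <- if (inherits(quality, "hs_quality")) quality$quality else quality
  assert_aligned(qr, landcover)
  purrr::pmap_dfr(units, function(unit, rmin, rmax, cmin, cmax, n_valid) {
    sub_lc <- crop_raster(landcover, rmin, rmax, cmin, cmax)
    qv <- qr$values[rmin:rmax, cmin:cmax]
    dplyr::bind_cols(
      tibble::tibble(unit = unit, n_valid = n_valid,
                     mean_hq = mean(qv, na.rm = TRUE)),
      metrics_report(sub_lc)
    )
  })
}

#' Pearson correlation with a t-test p-value
#'
#' @param x,y Finite numeric vectors, `n >= 3`. Zero variance in either
#'   yields the undefined marker (`NA` r and p).
#' @return One-row tibble with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Pearson correlation needs at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Correlate mean habitat quality with pattern metrics across units
#'
#' Pearson r and two-sided p for mean HQ against each of NP, PD, SHDI and
#' CONTAG. Units with an undefined metric (single-class tiles have no
#' contagion) are dropped pairwise and the retained count reported. Under
#' fragmentation-driven degradation the expected sign pattern is positive
#' for CONTAG and negative for NP, PD and SHDI.
#'
#' @param stats Tibble from [per_unit_stats()] (rows may pool several
#'   dates).
#' @return An `hs_correlation` tibble: `metric`, `r`, `p`, `n`.
#' @export
correlation_report <- function(stats) {
  if (nrow(stats) < 3) stop("need at least 3 analysis units")
  rows <- purrr::map_dfr(c("np", "pd", "shdi", "contag"), function(m) {
    ok <- is.finite(stats$mean_hq) & is.finite(stats[[m]])
    if (sum(ok) < 3) {
      return(tibble::tibble(metric = m, r = NA_real_, p = NA_real_,
                            n = sum(ok)))
    }
    res <- pearson_cor(stats$mean_hq[ok], stats[[m]][ok])
    tibble::tibble(metric = m, r = res$r, p = res$p, n = res$n)
  })
  class(rows) <- c("hs_correlation", class(rows))
  rows
}

# in-memory end-to-end scenario; run_pipeline() adds the artifact files
run_scenario <- function(config) {
  stopifnot(inherits(config, "hs_scenario_config"))
  master <- config$synth$seed
  specs <- threat_table(config$threats_csv)
  sens <- sensitivity_table(config$sensitivity_csv)
  years <- config$years

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  lc <- vector("list", 3)
  names(lc) <- as.character(years)
  lc[[1]] <- stage("landcover_t0", generate_landcover(config$synth))
  lc[[2]] <- stage("landcover_t1", evolve_landcover(
    lc[[1]], config$historical, clumping_bias = config$clumping_bias,
    seed = stage_seed(master, "evolve_t1")))
  tm_est <- stage("transition_matrix", transition_matrix(
    lc[[1]], lc[[2]], period_years = years[2] - years[1]))
  lc[[3]] <- stage("allocate_t2", allocate_change(
    lc[[2]], tm_est, n_steps = 1L, seed = stage_seed(master, "allocate_t2")))

  threats <- lapply(lc, function(m) stage(
    "threat_layers", generate_threat_layers(m, config$synth)))

  k_num <- NULL
  quality <- list()
  for (i in seq_along(lc)) {
    D <- stage("degradation", degradation(lc[[i]], threats[[i]],
                                          specs = specs, sens = sens))
    if (is.null(k_num)) k_num <- resolve_half_saturation(D, config$k)
    quality[[i]] <- stage("habitat_quality", habitat_quality(
      lc[[i]], D, sens = sens, k = k_num, z = config$z))
  }
  names(quality) <- names(lc)

  areas <- purrr::imap_dfr(quality, function(q, yr) {
    dplyr::mutate(classify_hq(q)$areas, year = as.integer(yr),
                  .before = 1)
  })
  changes <- dplyr::bind_rows(
    dplyr::mutate(net_change(lc[[1]], lc[[2]]),
                  period = paste(years[1], years[2], sep = "-"), .before = 1),
    dplyr::mutate(net_change(lc[[2]], lc[[3]]),
                  period = paste(years[2], years[3], sep = "-"), .before = 1)
  )
  metrics <- purrr::imap_dfr(lc, function(m, yr) {
    dplyr::mutate(metrics_report(m), year = as.integer(yr), .before = 1)
  })
  units <- tile_landscape(lc[[1]], config$tile_size)
  unit_stats <- purrr::imap_dfr(quality, function(q, yr) {
    dplyr::mutate(per_unit_stats(q, lc[[yr]], units),
                  year = as.integer(yr), .before = 1)
  })
  corr_by_date <- purrr::map_dfr(as.character(years), function(yr) {
    dplyr::mutate(
      correlation_report(unit_stats[unit_stats$year == as.integer(yr), ]),
      scope = yr, .before = 1)
  })
  corr_pooled <- dplyr::mutate(correlation_report(unit_stats),
                               scope = "pooled", .before = 1)

  list(config = config, landcover = lc, threats = threats,
       transition = tm_est, quality = quality, k = k_num,
       hq_areas = areas, net_change = changes, metrics = metrics,
       units = units, unit_stats = unit_stats,
       correlation = dplyr::bind_rows(corr_by_date, corr_pooled),
       mean_hq = purrr::map_dbl(quality, mean_hq))
}

#' Run the full scenario pipeline and write its artifacts
#'
#' Generates the three dated land-cover maps (the last by Markov projection
#' and suitability-ranked allocation), derives threat layers, computes
#' degradation and habitat quality per date (half-saturation resolved on
#' the baseline date), classifies quality into six levels, tabulates
#' net change and landscape metrics, computes tile-wise quality-vs-pattern
#' correlations (per date and pooled), and writes every table as CSV and
#' every raster as an ASCII grid into `out_dir`. Fully reproducible under
#' the master seed: identical config gives byte-identical CSV output.
#'
#' @param config An [scenario_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the in-memory result list (rasters, tibbles, paths in
#'   `$out_dir`).
#' @export
run_pipeline <- function(config, out_dir) {
  res <- run_scenario(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  years <- config$years
  for (yr in names(res$landcover)) {
    write_raster(res$landcover[[yr]],
                 file.path(out_dir, paste0("landcover_", yr, ".asc")))
    write_raster(res$quality[[yr]]$degradation,
                 file.path(out_dir, paste0("degradation_", yr, ".asc")))
    write_raster(res$quality[[yr]]$quality,
                 file.path(out_dir, paste0("quality_", yr, ".asc")))
    for (tn in names(res$threats[[yr]])) {
      write_raster(res$threats[[yr]][[tn]],
                   file.path(out_dir, paste0("threat_", tn, "_", yr, ".asc")))
    }
  }
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wcsv(res$hq_areas, "hq_areas.csv")
  wcsv(res$net_change, "net_change.csv")
  wcsv(res$metrics, "metrics.csv")
  wcsv(res$unit_stats, "unit_stats.csv")
  wcsv(res$correlation, "correlation.csv")
  wcsv(tidy(res$transition), "transition_matrix.csv")
  write_scenario_config(config, file.path(out_dir, "config_echo.yaml"))
  writeLines(c(
    "habscape pipeline run",
    paste("master_seed:", config$synth$seed),
    paste("years:", paste(years, collapse = " ")),
    paste("grid:", config$synth$n_rows, "x", config$synth$n_cols,
          "at", config$synth$cell_size, "m"),
    paste("half_saturation:", format(res$k)),
    paste("mean_hq:", paste(format(res$mean_hq), collapse = " "))
  ), file.path(out_dir, "run_log.txt"))
  res$out_dir <- out_dir
  invisible(res)
}

#' Fragmentation-gradient sign-recovery experiment
#'
#' Runs `n_reps` seeded scenarios in which habitat converts to agriculture
#' and built-up land over three dates with spatially scattered change
#' (low contagion bias), so the landscape fragments while threats grow.
#' For each replicate the tile-wise correlations (pooled over dates)
#' between mean habitat quality and the four metrics are recorded along
#' with the per-date mean quality. Under fragmentation-driven degradation
#' the expected signs are CONTAG positive and NP, PD, SHDI negative, with
#' mean quality declining monotonically.
#'
#' @param n_reps Number of replicates (default 20).
#' @param config Base [scenario_config()]; each replicate reseeds it.
#' @param seed Master experiment seed.
#' @return Tibble with one row per replicate: `rep`, `r_np`, `r_pd`,
#'   `r_shdi`, `r_contag`, `hq_t0`, `hq_t1`, `hq_t2`, `hq_monotone`.
#' @export
sign_recovery <- function(n_reps = 20, config = scenario_config(),
                          seed = 1L) {
  purrr::map_dfr(seq_len(n_reps), function(rep) {
    cfg <- config
    cfg$synth$seed <- stage_seed(seed, paste0("replicate_", rep))
    res <- run_scenario(cfg)
    co <- res$correlation[res$correlation$scope == "pooled", ]
    r_of <- function(m) co$r[co$metric == m]
    hq <- unname(res$mean_hq)
    tibble::tibble(
      rep = rep, r_np = r_of("np"), r_pd = r_of("pd"),
      r_shdi = r_of("shdi"), r_contag = r_of("contag"),
      hq_t0 = hq[1], hq_t1 = hq[2], hq_t2 = hq[3],
      hq_monotone = hq[1] > hq[2] && hq[2] > hq[3]
    )
  })
}
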