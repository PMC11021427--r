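#' Threat parameter table
#'
#' The seven threat factors with their maximum effective distances (km),
#' impact weights and decay kinds. The packaged defaults are the
#' expert-elicited values for a semi-arid central-Iranian watershed:
#' agriculture 8 km / 0.82 / linear, livestock grazing 6 / 0.72 / linear,
#' urban 8 / 0.31 / exponential, rural 8 / 0.51 / exponential, mining
#' 10 / 0.69 / exponential, main roads 7 / 0.50 / linear, minor roads
#' 5 / 0.50 / linear. A user CSV with the same schema may be supplied.
#'
#' @param path Optional CSV path overriding the packaged defaults
#'   (columns `threat`, `max_dist_km`, `weight`, `decay`).
#' @return Tibble, one row per threat.
#' @export
threat_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "threats.csv", package = "habscape")
  }
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("threat", "max_dist_km", "weight", "decay")
  if (!all(need %in% names(df))) stop("threat table must have columns: ",
                                      paste(need, collapse = ", "))
  if (any(df$max_dist_km <= 0)) stop("max effective distance must be > 0")
  if (any(df$weight < 0)) stop("threat weights must be >= 0")
  if (!all(df$decay %in% c("linear", "exponential"))) {
    stop("decay must be 'linear' or 'exponential'")
  }
  df
}

#' Habitat suitability and threat sensitivity table
#'
#' Per land-cover class: habitat suitability `H` in `[0, 1]` (`habitat`
#' column; built-up is non-habitat, `H = 0`) and relative sensitivity in
#' `[0, 1]` to each threat, one column per [threat_names()] entry. The
#' packaged defaults are the expert scores for the seven-class legend.
#'
#' @param path Optional CSV override with the same schema.
#' @return Tibble keyed by `code`.
#' @export
sensitivity_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "sensitivity.csv", package = "habscape")
  }
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                          check.names = FALSE))
  if (!all(c("code", "habitat") %in% names(df))) {
    stop("sensitivity table must have 'code' and 'habitat' columns")
  }
  num <- df[setdiff(names(df), c("code", "name"))]
  if (any(num < 0 | num > 1)) stop("sensitivities and habitat scores must be in [0, 1]")
  df
}

#' Distance-decay factor of a threat
#'
#' Linear decay falls from 1 at the source to 0 at the maximum effective
#' distance; exponential decay is `exp(-2.99 d / d_max)` and is clamped to
#' 0 beyond `d_max` (the maximum *effective* distance cuts all influence).
#'
#' @param d Distance(s) from the threat cell, metres (>= 0).
#' @param max_dist_km Maximum effective distance in kilometres.
#' @param decay `"linear"` or `"exponential"`.
#' @return Value(s) in `[0, 1]`.
#' @export
#' @examples
#' decay_factor(2000, 8, "linear")  # 0.75
decay_factor <- function(d, max_dist_km, decay = c("linear", "exponential")) {
  decay <- match.arg(decay)
  dmax <- max_dist_km * 1000
  if (decay == "linear") {
    pmax(0, 1 - d / dmax)
  } else {
    ifelse(d <= dmax, exp(-2.99 * d / dmax), 0)
  }
}

#' Total degradation surface from all threats
#'
#' For each cell `x` of class `j`, degradation is the weight-normalized sum
#' over threats `r` and threat cells `y` of the distance-decayed influence,
#' scaled by the class's sensitivity and the cell's accessibility:
#' `D_x = sum_r (w_r / sum w) * sum_y i_r(d_xy) * beta_x * S_jr`.
#' Distances are Euclidean between cell centres. Threats outside the
#' raster do not exist (no padding), mirroring the study-area-border
#' caveat of the source model. The inner spatial sum is evaluated exactly
#' by FFT convolution with the decay kernel.
#'
#' @param landcover An `hs_cat_raster`.
#' @param threats An `hs_threats` list (or named list of binary rasters)
#'   aligned with `landcover`.
#' @param specs Threat parameter table covering all threat layer names.
#' @param sens Sensitivity table covering all legend codes.
#' @param access Optional `hs_cont_raster` of accessibility `beta` in
#'   `[0, 1]`; default 1 everywhere.
#' @return An `hs_cont_raster` of per-cell degradation `D >= 0`.
#' @export
degradation <- function(landcover, threats, specs = threat_table(),
                        sens = sensitivity_table(), access = NULL) {
  v <- landcover$values
  nr <- nrow(v); nc <- ncol(v)
  nms <- names(threats)
  if (is.null(nms) || !all(nms %in% specs$threat)) {
    stop("every threat layer needs a row in the threat table")
  }
  codes <- sort(unique(v[!is.na(v)]))
  if (!all(codes %in% sens$code)) stop("missing sensitivity entry for class ",
                                       paste(setdiff(codes, sens$code),
                                             collapse = ", "))
  miss_col <- setdiff(nms, names(sens))
  if (length(miss_col)) stop("sensitivity table lacks threat column(s): ",
                             paste(miss_col, collapse = ", "))
  w <- specs$weight[match(nms, specs$threat)]
  w_norm <- if (sum(w) > 0) w / sum(w) else w
  D <- matrix(0, nr, nc)
  for (ti in seq_along(nms)) {
    layer <- threats[[ti]]
    assert_aligned(landcover, layer)
    src <- layer$values
    src[is.na(src)] <- 0L
    if (!all(src %in% c(0L, 1L))) stop("threat layers must be binary 0/1")
    if (sum(src) == 0 || w_norm[ti] == 0) next
    spec <- specs[match(nms[ti], specs$threat), ]
    k <- decay_kernel(spec$max_dist_km * 1000, spec$decay,
                      landcover$cell_size, nr, nc)
    infl <- conv2_same(matrix(as.numeric(src), nr, nc), k)
    infl[infl < 0] <- 0 # FFT round-off
    s_col <- sens[[nms[ti]]][match(v, sens$code)]
    s_mat <- matrix(s_col, nr, nc)
    s_mat[is.na(s_mat)] <- 0
    D <- D + w_norm[ti] * infl * s_mat
  }
  if (!is.null(access)) {
    assert_aligned(landcover, access)
    D <- D * access$values
  }
  D[is.na(v)] <- NA_real_
  cont_raster(D, cell_size = landcover$cell_size, xmin = landcover$xmin,
              ymax = landcover$ymax)
}

#' Resolve the half-saturation constant
#'
#' `"auto"` follows the usual convention of half the maximum landscape
#' degradation; when the landscape is threat-free (max D = 0) a fallback
#' of 0.5 keeps quality equal to suitability everywhere.
#'
#' @param D Degradation `hs_cont_raster` (or numeric values).
#' @param k `"auto"` or a positive number.
#' @return Positive numeric scalar.
#' @export
resolve_half_saturation <- function(D, k = "auto") {
  if (is.character(k) && identical(k, "auto")) {
    vals <- if (inherits(D, "hs_raster")) D$values else D
    m <- suppressWarnings(max(vals, na.rm = TRUE))
    if (!is.finite(m) || m <= 0) 0.5 else m / 2
  } else {
    k <- as.numeric(k)
    if (!is.finite(k) || k <= 0) stop("half-saturation constant must be > 0")
    k
  }
}

#' Habitat quality from land cover and degradation
#'
#' The half-saturation transform
#' `Q = H_j * (1 - D^z / (D^z + K^z))`: quality equals the class's habitat
#' suitability where degradation is zero, falls to half of it where
#' `D = K`, and is 0 wherever the class is non-habitat (`H_j = 0`).
#'
#' @param landcover An `hs_cat_raster`.
#' @param D Degradation raster from [degradation()].
#' @param sens Sensitivity table supplying the `habitat` column.
#' @param k Half-saturation constant, `"auto"` (half the maximum of `D`) or
#'   a positive number.
#' @param z Sharpness exponent of the transform (> 0; default 2.5, the
#'   InVEST convention).
#' @return An `hs_quality` object: fields `quality` and `degradation`
#'   (`hs_cont_raster`s), `landcover`, `k`, `z`.
#' @export
habitat_quality <- function(landcover, D, sens = sensitivity_table(),
                            k = "auto", z = 2.5) {
  assert_aligned(landcover, D)
  if (!is.numeric(z) || z <= 0) stop("z must be > 0")
  kk <- resolve_half_saturation(D, k)
  v <- landcover$values
  H <- matrix(sens$habitat[match(v, sens$code)], nrow(v), ncol(v))
  d <- D$values
  q <- H * (1 - d^z / (d^z + kk^z))
  q[!is.na(d) & d == 0] <- H[!is.na(d) & d == 0] # avoid 0^z/0 edge at z<1
  q[is.na(v)] <- NA_real_
  structure(
    list(quality = cont_raster(q, cell_size = landcover$cell_size,
                               xmin = landcover$xmin, ymax = landcover$ymax),
         degradation = D, landcover = landcover, k = kk, z = z),
    class = "hs_quality"
  )
}

#' @export
print.hs_quality <- function(x, ...) {
  cat(sprintf("<hs_quality: %d x %d, K = %.4g, z = %.3g, mean Q = %.4g>\n",
              nrow(x$quality$values), ncol(x$quality$values), x$k, x$z,
              mean_hq(x)))
  invisible(x)
}

#' One-row summary of a habitat-quality result
#' @param x An `hs_quality`.
#' @param ... Unused.
#' @return Tibble with `mean_q`, `mean_d`, `k`, `z`, `n_valid`.
#' @export
glance.hs_quality <- function(x, ...) {
  tibble::tibble(
    mean_q = mean_hq(x),
    mean_d = mean(x$degradation$values, na.rm = TRUE),
    k = x$k, z = x$z,
    n_valid = sum(!is.na(x$quality$values))
  )
}

#' Six-level habitat-quality legend
#' @return Tibble with columns `level`, `name`, `lower`, `upper`.
#' @export
hq_levels <- function() {
  tibble::tibble(
    level = 0:5,
    name = c("No habitat", "Poor", "Relatively poor", "Moderate",
             "Relatively good", "Good"),
    lower = c(NA, 0, 0.2, 0.4, 0.6, 0.8),
    upper = c(NA, 0.2, 0.4, 0.6, 0.8, 1.0)
  )
}

#' Classify a quality surface into six levels and tabulate areas
#'
#' Exactly 0 is "No habitat"; the remaining levels are the half-open
#' intervals `(0, 0.2]`, `(0.2, 0.4]`, `(0.4, 0.6]`, `(0.6, 0.8]`,
#' `(0.8, 1]`.
#'
#' @param q An `hs_quality` or a quality `hs_cont_raster`.
#' @return List with `raster` (`hs_cat_raster` of levels 0-5) and `areas`
#'   (tibble `level`, `name`, `n_cells`, `area_ha`; all six rows, summing
#'   to the valid area).
#' @export
classify_hq <- function(q) {
  qr <- if (inherits(q, "hs_quality")) q$quality else q
  v <- qr$values
  lev <- matrix(NA_integer_, nrow(v), ncol(v))
  ok <- !is.na(v)
  lev[ok] <- pmin(1L + findInterval(v[ok], c(0.2, 0.4, 0.6, 0.8),
                                    left.open = TRUE), 5L)
  lev[ok & v == 0] <- 0L
  lg <- hq_levels()
  ras <- cat_raster(lev, legend = tibble::tibble(code = lg$level,
                                                 name = lg$name),
                    cell_size = qr$cell_size, xmin = qr$xmin, ymax = qr$ymax)
  n <- tabulate(lev[ok] + 1L, 6L)
  areas <- tibble::tibble(level = lg$level, name = lg$name, n_cells = n,
                          area_ha = n * qr$cell_size^2 / 1e4)
  list(raster = ras, areas = areas)
}

#' Mean habitat quality over the valid (optionally masked) area
#'
#' @param q An `hs_quality` or quality `hs_cont_raster`.
#' @param mask Optional logical matrix selecting cells.
#' @return Numeric scalar.
#' @export
mean_hq <- function(q, mask = NULL) {
  qr <- if (inherits(q, "hs_quality")) q$quality else q
  v <- qr$values
  if (!is.null(mask)) v <- v[mask]
  if (all(is.na(v))) stop("mean habitat quality over an empty mask")
  mean(v, na.rm = TRUE)
}
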