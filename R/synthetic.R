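#' Configuration for the synthetic landscape generator
#'
#' Defines the study conditions for a generated scenario: grid size, 30 m
#' pixels, target class proportions over the seven-class legend, spatial
#' clumping, and counts of linear (road) and point (mine) threat features.
#' The default proportions give the habitat classes (forest + three
#' rangelands) 82% of the landscape, the habitat share the study system had
#' at the start of the observation period.
#'
#' @param n_rows,n_cols Grid dimensions (>= 8).
#' @param cell_size Pixel side in metres (default 30).
#' @param class_proportions Named or ordered numeric vector of target
#'   fractions per legend code 1..7; must sum to 1.
#' @param clumping Spatial-autocorrelation scalar >= 0 (Gaussian smoothing
#'   radius in cells). 0 gives spatially independent cells; larger values
#'   give larger patches.
#' @param n_main_roads,n_minor_roads Numbers of random boundary-to-boundary
#'   polylines rasterized as 1-cell-wide roads.
#' @param n_mines Number of random mine point cells (placed outside water).
#' @param seed Integer seed; all generator functions are pure functions of
#'   (config, seed).
#' @return An `hs_synth_config` list.
#' @export
synthetic_config <- function(n_rows = 128, n_cols = 128, cell_size = 30,
                             class_proportions = c(0.20, 0.25, 0.22, 0.15,
                                                   0.02, 0.11, 0.05),
                             clumping = 8, n_main_roads = 2,
                             n_minor_roads = 4, n_mines = 5, seed = 1L) {
  if (n_rows < 8 || n_cols < 8) stop("grid dimensions must be >= 8")
  p <- as.numeric(class_proportions)
  if (length(p) != 7) stop("class_proportions must have 7 entries")
  if (any(p < 0)) stop("class proportions must be >= 0")
  if (abs(sum(p) - 1) > 1e-9) stop("class proportions must sum to 1")
  if (clumping < 0) stop("clumping must be >= 0")
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = cell_size, class_proportions = p, clumping = clumping,
         n_main_roads = as.integer(n_main_roads),
         n_minor_roads = as.integer(n_minor_roads),
         n_mines = as.integer(n_mines), seed = as.integer(seed)),
    class = "hs_synth_config"
  )
}

#' Generate a clumped seven-class land-cover map
#'
#' Neutral-landscape generator: a seeded white-noise field is smoothed with
#' an isotropic Gaussian kernel of width `clumping` (in cells) and classes
#' are assigned by quantile slicing of the smoothed field, so achieved
#' class proportions match the targets to within one cell. Deterministic
#' under the config seed.
#'
#' @param config An [synthetic_config()] object.
#' @return An `hs_cat_raster` over [lulc_legend()].
#' @export
generate_landcover <- function(config) {
  stopifnot(inherits(config, "hs_synth_config"))
  nr <- config$n_rows; nc <- config$n_cols
  withr::with_seed(config$seed, {
    field <- matrix(stats::runif(nr * nc), nr, nc)
    if (config$clumping > 0) field <- gaussian_blur(field, config$clumping)
    # tie-break by cell index keeps the slicing deterministic
    ord <- order(field, seq_along(field))
    counts <- largest_remainder(config$class_proportions * nr * nc)
    codes <- rep.int(lulc_legend()$code, counts)
    v <- integer(nr * nc)
    v[ord] <- codes
    cat_raster(matrix(v, nr, nc), legend = lulc_legend(),
               cell_size = config$cell_size)
  })
}

# round non-negative reals to integers preserving their (integer) total
largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  if (rem > 0) {
    o <- order(x - fl, decreasing = TRUE)
    fl[o[seq_len(rem)]] <- fl[o[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Canonical threat names
#' @return Character vector of the seven threat factors.
#' @export
threat_names <- function() {
  c("agriculture", "livestock_grazing", "urban", "rural", "mining",
    "main_roads", "minor_roads")
}

binary_layer <- function(template, mask) {
  v <- matrix(0L, nrow(template$values), ncol(template$values))
  v[mask] <- 1L
  v[is.na(template$values)] <- NA_integer_
  cat_raster(v, legend = tibble::tibble(code = 0:1,
                                        name = c("absent", "present")),
             cell_size = template$cell_size, xmin = template$xmin,
             ymax = template$ymax)
}

#' Derive the seven binary threat layers from a land-cover map
#'
#' Land-cover-derived threats: agriculture (agriculture-class cells),
#' livestock grazing (all three rangeland classes), urban and rural (a
#' deterministic partition of built-up cells: the largest 8-connected
#' built-up component is urban, the remainder rural). Feature threats are
#' seeded: mining (`n_mines` random cells outside water) and main/minor
#' roads (random boundary-to-boundary polylines rasterized 1 cell wide).
#'
#' @param landcover An `hs_cat_raster` over [lulc_legend()].
#' @param config An [synthetic_config()]; supplies feature counts and seed.
#' @return An `hs_threats` named list of binary `hs_cat_raster`s, one per
#'   [threat_names()] entry, aligned with `landcover`.
#' @export
generate_threat_layers <- function(landcover, config) {
  v <- landcover$values
  layers <- list()
  layers$agriculture <- binary_layer(landcover, !is.na(v) & v == .cls$agriculture)
  layers$livestock_grazing <- binary_layer(
    landcover, !is.na(v) & v %in% c(.cls$range_good, .cls$range_fair,
                                    .cls$range_poor))
  built <- !is.na(v) & v == .cls$builtup
  if (any(built)) {
    lab <- label_mask(built, neighbor_rule = 8L)
    sizes <- tabulate(lab[built])
    biggest <- which.max(sizes) # ties: lowest label, deterministic
    layers$urban <- binary_layer(landcover, !is.na(lab) & lab == biggest)
    layers$rural <- binary_layer(landcover, !is.na(lab) & lab != biggest)
  } else {
    layers$urban <- binary_layer(landcover, built)
    layers$rural <- binary_layer(landcover, built)
  }
  withr::with_seed(config$seed + 1L, {
    candidates <- which(!is.na(v) & v != .cls$water)
    n_mines <- min(config$n_mines, length(candidates))
    mine_cells <- if (n_mines > 0) sample(candidates, n_mines) else integer()
    mine_mask <- matrix(FALSE, nrow(v), ncol(v))
    mine_mask[mine_cells] <- TRUE
    layers$mining <- binary_layer(landcover, mine_mask)
    layers$main_roads <- binary_layer(
      landcover, road_mask(nrow(v), ncol(v), config$n_main_roads))
    layers$minor_roads <- binary_layer(
      landcover, road_mask(nrow(v), ncol(v), config$n_minor_roads))
  })
  structure(layers[threat_names()], class = "hs_threats")
}

# random boundary-to-boundary polylines, rasterized 1 cell wide (Bresenham)
road_mask <- function(nr, nc, n_roads) {
  mask <- matrix(FALSE, nr, nc)
  if (n_roads < 1) return(mask)
  boundary <- boundary_cells(nr, nc)
  for (i in seq_len(n_roads)) {
    ends <- boundary[sample(nrow(boundary), 2), , drop = FALSE]
    seg <- bresenham(ends[1, 1], ends[1, 2], ends[2, 1], ends[2, 2])
    mask[cbind(seg$r, seg$c)] <- TRUE
  }
  mask
}

boundary_cells <- function(nr, nc) {
  unique(rbind(
    cbind(1L, seq_len(nc)), cbind(nr, seq_len(nc)),
    cbind(seq_len(nr), 1L), cbind(seq_len(nr), nc)
  ))
}

bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  if (sr == 0) sr <- 1L
  if (sc == 0) sc <- 1L
  err <- dr - dc
  r <- r0; c <- c0
  rs <- integer(); cs <- integer()
  repeat {
    rs <- c(rs, r); cs <- c(cs, c)
    if (r == r1 && c == c1) break
    e2 <- 2 * err
    if (e2 > -dc) { err <- err - dc; r <- r + sr }
    if (e2 < dr) { err <- err + dr; c <- c + sc }
  }
  list(r = rs, c = cs)
}

#' Evolve a land-cover map one step under a transition matrix
#'
#' Each cell transitions stochastically according to its class's row of the
#' transition matrix. With `clumping_bias > 0` the probability of moving
#' into class `c` is multiplied by `1 + clumping_bias * f_c`, where `f_c`
#' is the fraction of the cell's 8-neighbours already in class `c`, then
#' renormalized — producing contagious, patch-growing change. Deterministic
#' under `seed`.
#'
#' @param landcover An `hs_cat_raster`.
#' @param tm An [transition_matrix()] object (row-stochastic over the
#'   raster's legend).
#' @param clumping_bias Non-negative contagion strength (0 = independent).
#' @param seed Integer seed.
#' @return An `hs_cat_raster` aligned with the input.
#' @export
evolve_landcover <- function(landcover, tm, clumping_bias = 0, seed = 1L) {
  stopifnot(inherits(tm, "hs_transition"))
  codes <- tm$legend$code
  if (!setequal(codes, landcover$legend$code)) {
    stop("transition matrix legend does not match the raster legend")
  }
  P <- tm$probs[match(landcover$legend$code, codes),
                match(landcover$legend$code, codes), drop = FALSE]
  codes <- landcover$legend$code
  v <- landcover$values
  ok <- !is.na(v)
  cls_idx <- match(v[ok], codes)
  probs <- P[cls_idx, , drop = FALSE]
  if (clumping_bias > 0) {
    k3 <- matrix(1, 3, 3); k3[2, 2] <- 0
    n_nb <- conv2_same(matrix(as.numeric(ok), nrow(v), ncol(v)), k3)
    for (j in seq_along(codes)) {
      ind <- matrix(as.numeric(ok & v == codes[j]), nrow(v), ncol(v))
      frac <- conv2_same(ind, k3) / pmax(n_nb, 1)
      probs[, j] <- probs[, j] * (1 + clumping_bias * frac[ok])
    }
    probs <- probs / rowSums(probs)
  }
  withr::with_seed(seed, {
    u <- stats::runif(nrow(probs))
    cum <- probs %*% upper.tri(diag(length(codes)), diag = TRUE)
    new_idx <- pmin(rowSums(u > cum) + 1L, length(codes))
  })
  out <- v
  out[ok] <- codes[new_idx]
  cat_raster(out, legend = landcover$legend, cell_size = landcover$cell_size,
             xmin = landcover$xmin, ymax = landcover$ymax)
}

#' Generate an NDVI surface consistent with rangeland condition classes
#'
#' Rangeland cells receive class-conditional Gaussian NDVI draws (means
#' 0.22 / 0.145 / 0.06 for good / fair / poor, sd 0.01) truncated to the
#' class's threshold interval, so [classify_ndvi()] recovers the generating
#' condition class on essentially all rangeland cells. Non-rangeland cells
#' are nodata.
#'
#' @param landcover An `hs_cat_raster` over [lulc_legend()].
#' @param seed Integer seed.
#' @return An `hs_cont_raster` of NDVI values.
#' @export
generate_ndvi <- function(landcover, seed = 1L) {
  v <- landcover$values
  out <- matrix(NA_real_, nrow(v), ncol(v))
  spec <- list(
    list(code = .cls$range_good, mean = 0.22, lo = 0.17 + 1e-9, hi = Inf),
    list(code = .cls$range_fair, mean = 0.145, lo = 0.12, hi = 0.17),
    list(code = .cls$range_poor, mean = 0.06, lo = 0.01, hi = 0.12 - 1e-9)
  )
  withr::with_seed(seed, {
    for (s in spec) {
      cells <- which(!is.na(v) & v == s$code)
      if (length(cells) == 0) next
      out[cells] <- rtruncnorm(length(cells), s$mean, 0.01, s$lo, s$hi)
    }
  })
  cont_raster(out, cell_size = landcover$cell_size, xmin = landcover$xmin,
              ymax = landcover$ymax)
}

# inverse-CDF truncated normal
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}
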