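# connected-component labels of equal-valued non-NA cells; returns an
# integer matrix (NA off the valid area), labels 1..np
label_cells <- function(v, neighbor_rule = 8L) {
  if (!neighbor_rule %in% c(4L, 8L)) stop("neighbor rule must be 4 or 8")
  nr <- nrow(v); nc <- ncol(v)
  id <- matrix(seq_len(nr * nc), nr, nc)
  ea <- integer(0); eb <- integer(0)
  collect <- function(ia, ib) {
    ia <- as.vector(ia); ib <- as.vector(ib)
    ok <- !is.na(v[ia]) & !is.na(v[ib]) & v[ia] == v[ib]
    ea <<- c(ea, ia[ok]); eb <<- c(eb, ib[ok])
  }
  if (nc > 1) collect(id[, -nc], id[, -1])
  if (nr > 1) collect(id[-nr, ], id[-1, ])
  if (neighbor_rule == 8L && nr > 1 && nc > 1) {
    collect(id[-nr, -nc], id[-1, -1])
    collect(id[-nr, -1], id[-1, -nc])
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (length(ea)) g <- igraph::add_edges(g, rbind(ea, eb))
  mem <- igraph::components(g)$membership
  valid <- which(!is.na(v))
  lab <- matrix(NA_integer_, nr, nc)
  lab[valid] <- match(mem[valid], unique(mem[valid]))
  lab
}

# labels of a logical mask (used for the urban/rural split)
label_mask <- function(mask, neighbor_rule = 8L) {
  v <- matrix(NA_integer_, nrow(mask), ncol(mask))
  v[mask] <- 1L
  label_cells(v, neighbor_rule)
}

#' Label same-class patches
#'
#' Patches are connected components of same-class cells under the
#' 8-neighbour rule (FRAGSTATS default; configurable). Nodata splits
#' patches.
#'
#' @param landcover An `hs_cat_raster`.
#' @param neighbor_rule 8 (default) or 4.
#' @return List with `labels` (integer matrix, `NA` = nodata) and `np`
#'   (total patch count over all classes).
#' @export
label_patches <- function(landcover, neighbor_rule = 8L) {
  v <- landcover$values
  if (all(is.na(v))) stop("all-nodata raster has no patches")
  lab <- label_cells(v, neighbor_rule)
  list(labels = lab, np = max(lab, na.rm = TRUE))
}

#' Patch density
#'
#' Number of patches per 100 hectares of valid area
#' (`NP / A(m^2) * 10000 * 100`, the FRAGSTATS landscape-level unit).
#'
#' @inheritParams label_patches
#' @return Numeric scalar, patches per 100 ha.
#' @export
patch_density <- function(landcover, neighbor_rule = 8L) {
  area_ha <- valid_area_ha(landcover)
  if (area_ha == 0) stop("zero valid area")
  label_patches(landcover, neighbor_rule)$np / (area_ha / 100)
}

#' Shannon's diversity index
#'
#' `-sum(P_i * ln P_i)` over valid-cell class proportions; 0 for a single
#' class, `ln m` at equal proportions. A composition-only metric,
#' invariant to spatial rearrangement.
#'
#' @param landcover An `hs_cat_raster`.
#' @return Numeric scalar (nats).
#' @export
shdi <- function(landcover) {
  v <- landcover$values[!is.na(landcover$values)]
  if (length(v) == 0) stop("no valid cells")
  p <- as.numeric(table(v)) / length(v)
  -sum(p * log(p))
}

#' Cell adjacency table
#'
#' Horizontal and vertical (4-neighbour) cell-pair adjacencies between the
#' classes present, each unordered pair counted once in each direction
#' (the double-count convention used by the contagion index). Pairs
#' touching nodata are excluded.
#'
#' @param landcover An `hs_cat_raster`.
#' @return An `hs_adjacency`: symmetric integer matrix with class-code
#'   dimnames.
#' @export
adjacency_table <- function(landcover) {
  v <- landcover$values
  nr <- nrow(v); nc <- ncol(v)
  codes <- sort(unique(v[!is.na(v)]))
  m <- length(codes)
  g <- matrix(0L, m, m, dimnames = list(codes, codes))
  collect <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return()
    ia <- match(a[ok], codes); ib <- match(b[ok], codes)
    for (pair in list(cbind(ia, ib), cbind(ib, ia))) {
      t <- table(factor(pair[, 1], seq_len(m)), factor(pair[, 2], seq_len(m)))
      g <<- g + unclass(t)
    }
  }
  if (nc > 1) collect(v[, -nc], v[, -1])
  if (nr > 1) collect(v[-nr, ], v[-1, ])
  structure(g, class = c("hs_adjacency", class(g)))
}

#' Contagion index
#'
#' FRAGSTATS landscape-level CONTAG:
#' `100 * (1 + sum_ik p_ik ln p_ik / (2 ln m))` with
#' `p_ik = P_i * g_ik / sum_k g_ik` over the `m` classes present, where
#' `P_i` are class proportions and `g` the double-counted 4-neighbour
#' adjacencies. High values mean an aggregated, well-connected landscape.
#' Undefined for a single-class landscape (`NA` returned, as FRAGSTATS
#' documents).
#'
#' @param landcover An `hs_cat_raster`.
#' @return Percentage in `[0, 100]`, or `NA` when fewer than two classes
#'   are present.
#' @export
contag <- function(landcover) {
  v <- landcover$values
  valid <- v[!is.na(v)]
  codes <- sort(unique(valid))
  m <- length(codes)
  if (m < 2) return(NA_real_)
  P <- as.numeric(table(factor(valid, codes))) / length(valid)
  g <- unclass(adjacency_table(landcover))
  rs <- rowSums(g)
  p <- (P / ifelse(rs > 0, rs, 1)) * g
  p[rs == 0, ] <- 0
  terms <- p * log(p)
  terms[p == 0] <- 0
  val <- 100 * (1 + sum(terms) / (2 * log(m)))
  min(max(val, 0), 100)
}

#' Landscape-level metrics bundle
#'
#' Number of patches (8-neighbour rule), patch density per 100 ha,
#' Shannon's diversity and contagion for one landscape or analysis unit.
#'
#' @param landcover An `hs_cat_raster`.
#' @param neighbor_rule Patch rule, 8 (default) or 4.
#' @return One-row tibble with columns `np`, `pd`, `shdi`, `contag`
#'   (`contag` is `NA` for single-class landscapes).
#' @export
metrics_report <- function(landcover, neighbor_rule = 8L) {
  tibble::tibble(
    np = label_patches(landcover, neighbor_rule)$np,
    pd = patch_density(landcover, neighbor_rule),
    shdi = shdi(landcover),
    contag = contag(landcover)
  )
}

#' Crop a raster to a row/column window
#'
#' @param x An `hs_raster`.
#' @param rmin,rmax,cmin,cmax 1-based inclusive bounds.
#' @return An `hs_raster` of the same kind with adjusted georeference.
#' @export
crop_raster <- function(x, rmin, rmax, cmin, cmax) {
  v <- x$values[rmin:rmax, cmin:cmax, drop = FALSE]
  xmin <- x$xmin + (cmin - 1) * x$cell_size
  ymax <- x$ymax - (rmin - 1) * x$cell_size
  if (inherits(x, "hs_cat_raster")) {
    cat_raster(v, legend = x$legend, cell_size = x$cell_size,
               xmin = xmin, ymax = ymax, nodata = x$nodata)
  } else {
    cont_raster(v, cell_size = x$cell_size, xmin = xmin, ymax = ymax)
  }
}
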