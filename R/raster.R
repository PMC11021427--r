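#' Seven-class land-use / land-cover legend
#'
#' The default legend used throughout the package: Zagros forest, three
#' rangeland condition classes, water bodies, agriculture and built-up area.
#' Rangeland condition corresponds to NDVI classes (see [classify_ndvi()]).
#'
#' @return A tibble with columns `code` (integer) and `name` (character).
#' @export
#' @examples
#' lulc_legend()
lulc_legend <- function() {
  tibble::tibble(
    code = 1:7,
    name = c(
      "Zagros forest", "Rangeland/good", "Rangeland/fair", "Rangeland/poor",
      "Water bodies", "Agriculture", "Built-up"
    )
  )
}

# class codes used internally by the generator and threat derivation
.cls <- list(
  forest = 1L, range_good = 2L, range_fair = 3L, range_poor = 4L,
  water = 5L, agriculture = 6L, builtup = 7L
)

#' Categorical raster
#'
#' A minimal in-memory raster: an integer matrix of class codes with square
#' pixels, a north-up georeference (row 1 is the northern edge) and a legend
#' mapping codes to class names. `NA` cells are nodata; the `nodata` code is
#' only used when writing to or reading from disk.
#'
#' @param values Integer matrix of class codes (`NA` = nodata). Cells equal
#'   to `nodata` are converted to `NA`.
#' @param legend Tibble with columns `code`, `name`. Defaults to generic
#'   names for the codes present.
#' @param cell_size Pixel side length in metres (default 30).
#' @param xmin,ymax Map coordinates of the top-left corner of the grid.
#' @param nodata Integer nodata code used at I/O time.
#' @return An object of class `hs_cat_raster`.
#' @export
cat_raster <- function(values, legend = NULL, cell_size = 30,
                       xmin = 0, ymax = nrow(values) * cell_size,
                       nodata = -9999L) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "integer"
  values[values == as.integer(nodata)] <- NA_integer_
  if (is.null(legend)) {
    codes <- sort(unique(values[!is.na(values)]))
    legend <- tibble::tibble(code = as.integer(codes),
                             name = paste0("class_", codes))
  }
  x <- structure(
    list(values = values, legend = legend, cell_size = as.numeric(cell_size),
         xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         nodata = as.integer(nodata)),
    class = c("hs_cat_raster", "hs_raster")
  )
  validate_raster(x)
  x
}

#' Continuous raster
#'
#' Real-valued counterpart of [cat_raster()] used for NDVI, suitability,
#' degradation and quality surfaces. `NA` cells are nodata.
#'
#' @param values Numeric matrix (`NA` = nodata).
#' @inheritParams cat_raster
#' @param nodata Numeric nodata sentinel used at I/O time.
#' @return An object of class `hs_cont_raster`.
#' @export
cont_raster <- function(values, cell_size = 30, xmin = 0,
                        ymax = nrow(values) * cell_size, nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  x <- structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         nodata = as.numeric(nodata)),
    class = c("hs_cont_raster", "hs_raster")
  )
  validate_raster(x)
  x
}

validate_raster <- function(x) {
  v <- x$values
  if (nrow(v) < 1L || ncol(v) < 1L) stop("raster must have >= 1 row and column")
  if (x$cell_size <= 0) stop("cell_size must be > 0")
  if (inherits(x, "hs_cat_raster")) {
    present <- unique(v[!is.na(v)])
    if (length(setdiff(present, x$legend$code)) > 0L) {
      stop("raster contains codes absent from the legend: ",
           paste(setdiff(present, x$legend$code), collapse = ", "))
    }
    if (anyDuplicated(x$legend$code)) stop("legend codes must be unique")
  } else {
    if (any(!is.finite(v) & !is.na(v))) stop("non-finite values in raster")
  }
  invisible(x)
}

#' @export
print.hs_raster <- function(x, ...) {
  kind <- if (inherits(x, "hs_cat_raster")) "categorical" else "continuous"
  cat(sprintf("<hs_raster: %s, %d x %d, cell %g m>\n",
              kind, nrow(x$values), ncol(x$values), x$cell_size))
  n_valid <- sum(!is.na(x$values))
  cat(sprintf("  valid cells: %d / %d\n", n_valid, length(x$values)))
  if (inherits(x, "hs_cat_raster")) {
    tab <- table(x$values)
    nm <- x$legend$name[match(as.integer(names(tab)), x$legend$code)]
    cat("  classes:", paste0(nm, " (", as.integer(tab), ")", collapse = ", "),
        "\n")
  } else if (n_valid > 0) {
    cat(sprintf("  range: [%.4g, %.4g]\n",
                min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  }
  invisible(x)
}

#' Test and assert raster alignment
#'
#' Two rasters are aligned iff they share shape, cell size and georeference.
#' All multi-raster operations in the package require alignment.
#'
#' @param a,b `hs_raster` objects.
#' @return `is_aligned()` returns a logical scalar; `assert_aligned()` errors
#'   on misalignment and returns `a` invisibly.
#' @export
is_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(a$cell_size, b$cell_size, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$xmin, b$xmin, tolerance = 1e-9)) &&
    isTRUE(all.equal(a$ymax, b$ymax, tolerance = 1e-9))
}

#' @rdname is_aligned
#' @export
assert_aligned <- function(a, b) {
  if (!is_aligned(a, b)) stop("rasters are not aligned (shape/cell/transform)")
  invisible(a)
}

#' Area of the valid (non-nodata) part of a raster, in hectares
#' @param x An `hs_raster`.
#' @return Numeric scalar, hectares.
#' @export
valid_area_ha <- function(x) {
  sum(!is.na(x$values)) * x$cell_size^2 / 1e4
}

#' Convert a raster to a tidy tibble
#'
#' One row per valid cell with map-coordinate cell centres, suitable for
#' ggplot2 and dplyr work.
#'
#' @param x An `hs_raster`.
#' @param ... Unused.
#' @return Tibble with columns `row`, `col`, `x`, `y`, `value` and (for
#'   categorical rasters) `class`.
#' @export
as_tibble.hs_raster <- function(x, ...) {
  v <- x$values
  idx <- which(!is.na(v), arr.ind = TRUE)
  out <- tibble::tibble(
    row = idx[, 1], col = idx[, 2],
    x = x$xmin + (idx[, 2] - 0.5) * x$cell_size,
    y = x$ymax - (idx[, 1] - 0.5) * x$cell_size,
    value = v[idx]
  )
  if (inherits(x, "hs_cat_raster")) {
    out$class <- x$legend$name[match(out$value, x$legend$code)]
  }
  out
}

# ---- I/O ---------------------------------------------------------------

#' Read a raster from disk
#'
#' Supports the plain-text ESRI ASCII grid format (`.asc`; lossless for both
#' categorical and continuous rasters, including nodata and georeference)
#' and single-band TIFF (`.tif`/`.tiff`) via the tiff package. TIFF files
#' carry cell values only; georeference defaults are applied on read.
#'
#' @param path File path ending in `.asc`, `.tif` or `.tiff`.
#' @param type `"auto"` (integer-valued grids become categorical),
#'   `"categorical"` or `"continuous"`.
#' @param legend Optional legend for categorical results.
#' @param cell_size,xmin,ymax Georeference used for TIFF input (ASCII grids
#'   carry their own).
#' @return An `hs_cat_raster` or `hs_cont_raster`.
#' @export
read_raster <- function(path, type = c("auto", "categorical", "continuous"),
                        legend = NULL, cell_size = 30, xmin = 0, ymax = NULL) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "asc") {
    read_asc(path, type, legend)
  } else if (ext %in% c("tif", "tiff")) {
    read_tif(path, type, legend, cell_size, xmin, ymax)
  } else {
    stop("unsupported raster extension: .", ext)
  }
}

#' Write a raster to disk
#'
#' The `.asc` path is lossless (values, nodata, georeference); `.tif` writes
#' integer codes for categorical rasters (16-bit) and `[0, 1]` float for
#' continuous rasters, and does not store the georeference or `NA` cells in
#' continuous mode.
#'
#' @param x An `hs_raster`.
#' @param path Destination ending in `.asc`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ",
                                       dirname(path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "asc") {
    write_asc(x, path)
  } else if (ext %in% c("tif", "tiff")) {
    write_tif(x, path)
  } else {
    stop("unsupported raster extension: .", ext)
  }
  invisible(path)
}

write_asc <- function(x, path) {
  v <- x$values
  nd <- x$nodata
  categorical <- inherits(x, "hs_cat_raster")
  hdr <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", format(x$xmin, digits = 15)),
    paste("yllcorner", format(x$ymax - nrow(v) * x$cell_size, digits = 15)),
    paste("cellsize", format(x$cell_size, digits = 15)),
    paste("NODATA_value", format(nd, digits = 15))
  )
  v[is.na(v)] <- nd
  rows <- apply(v, 1, function(r) {
    paste(if (categorical) format(as.integer(r)) else
      formatC(r, digits = 12, format = "g"), collapse = " ")
  })
  writeLines(c(hdr, rows), path)
}

read_asc <- function(path, type, legend) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header")
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("ASCII grid size mismatch")
  v <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nd <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  v[v == nd] <- NA
  xmin <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  ymax <- yll + nr * hdr$cellsize
  if (type == "categorical" ||
      (type == "auto" && all(v[!is.na(v)] == round(v[!is.na(v)])))) {
    cat_raster(v, legend = legend, cell_size = hdr$cellsize,
               xmin = xmin, ymax = ymax, nodata = as.integer(nd))
  } else {
    cont_raster(v, cell_size = hdr$cellsize, xmin = xmin, ymax = ymax,
                nodata = nd)
  }
}

write_tif <- function(x, path) {
  v <- x$values
  if (inherits(x, "hs_cat_raster")) {
    v[is.na(v)] <- x$nodata
    if (any(v < 0L | v > 65535L)) {
      stop("TIFF output requires integer codes in [0, 65535]; ",
           "use .asc for this raster")
    }
    tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L)
  } else {
    if (anyNA(v)) stop("TIFF output does not support nodata in continuous ",
                       "rasters; use .asc")
    if (any(v < 0 | v > 1)) stop("continuous TIFF output requires values in ",
                                 "[0, 1]; use .asc")
    tiff::writeTIFF(v, path, bits.per.sample = 32L)
  }
}

read_tif <- function(path, type, legend, cell_size, xmin, ymax) {
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) == 3L) stop("multi-band TIFF input is not supported")
  if (is.null(ymax)) ymax <- nrow(img) * cell_size
  integerish <- is.integer(img) || all(img == round(img))
  if (type == "categorical" || (type == "auto" && integerish)) {
    if (!integerish) stop("non-integer values where categorical expected")
    v <- img
    cat_raster(v, legend = legend, cell_size = cell_size,
               xmin = xmin, ymax = ymax,
               nodata = if (any(v == 65535L)) 65535L else -9999L)
  } else {
    img2 <- tiff::readTIFF(path)
    cont_raster(img2, cell_size = cell_size, xmin = xmin, ymax = ymax)
  }
}

# ---- cross-tabulation --------------------------------------------------

#' Cross-tabulate two aligned categorical rasters
#'
#' Counts jointly valid cells by class pair; cells where either raster is
#' nodata are excluded. This is the basis for accuracy assessment and for
#' transition-matrix estimation between dated maps.
#'
#' @param a,b Aligned `hs_cat_raster` objects.
#' @param codes_a,codes_b Optional code sets fixing row/column order (e.g.
#'   a full legend); defaults to the codes observed in each raster.
#' @return An `hs_contingency`: an integer matrix with code dimnames plus
#'   `row_labels`/`col_labels` attributes.
#' @export
crosstab <- function(a, b, codes_a = NULL, codes_b = NULL) {
  assert_aligned(a, b)
  ok <- !is.na(a$values) & !is.na(b$values)
  va <- a$values[ok]; vb <- b$values[ok]
  if (is.null(codes_a)) codes_a <- sort(unique(va))
  if (is.null(codes_b)) codes_b <- sort(unique(vb))
  fa <- factor(va, levels = codes_a)
  fb <- factor(vb, levels = codes_b)
  m <- unclass(table(fa, fb))
  dimnames(m) <- list(as.character(codes_a), as.character(codes_b))
  contingency(m,
              row_labels = a$legend$name[match(codes_a, a$legend$code)],
              col_labels = b$legend$name[match(codes_b, b$legend$code)])
}

#' Build a contingency table object
#'
#' @param counts Non-negative integer matrix.
#' @param row_labels,col_labels Optional human-readable labels.
#' @return An `hs_contingency` matrix.
#' @export
contingency <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("contingency counts must be >= 0")
  if (sum(counts) < 1) stop("contingency table must have total n >= 1")
  if (is.null(dimnames(counts))) {
    dimnames(counts) <- list(seq_len(nrow(counts)), seq_len(ncol(counts)))
  }
  structure(counts,
            row_labels = row_labels, col_labels = col_labels,
            class = c("hs_contingency", class(counts)))
}

#' @export
print.hs_contingency <- function(x, ...) {
  cat(sprintf("<hs_contingency: %d x %d, n = %d>\n",
              nrow(x), ncol(x), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Write a contingency table as labelled CSV
#' @param x An `hs_contingency`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_contingency_csv <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(x)), path)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a contingency table into long form
#' @param x An `hs_contingency`.
#' @param ... Unused.
#' @return Tibble with columns `from`, `to`, `n`.
#' @export
tidy.hs_contingency <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("from", "to", "n")
  tibble::as_tibble(df)
}
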