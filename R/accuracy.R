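#' Overall classification accuracy
#'
#' Fraction of correctly classified pixels: the trace of a square confusion
#' matrix divided by its total.
#'
#' @param t An `hs_contingency` (square).
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' overall_accuracy(contingency(matrix(c(40, 5, 10, 45), 2)))
overall_accuracy <- function(t) {
  m <- unclass(t)
  if (nrow(m) != ncol(m)) stop("overall accuracy needs a square table")
  n <- sum(m)
  if (n == 0) stop("empty contingency table")
  sum(diag(m)) / n
}

#' Cohen's kappa coefficient
#'
#' Chance-corrected agreement between two classifications:
#' `(P0 - Pe) / (1 - Pe)` where `P0` is observed agreement (the trace
#' fraction) and `Pe` the agreement expected from the marginals.
#'
#' @param t An `hs_contingency` (square, total >= 1).
#' @return Value in `[-1, 1]`.
#' @export
#' @examples
#' cohens_kappa(contingency(matrix(c(40, 5, 10, 45), 2))) # 0.7
cohens_kappa <- function(t) {
  m <- unclass(t)
  if (nrow(m) != ncol(m)) stop("kappa needs a square table")
  n <- sum(m)
  if (n < 1) stop("empty contingency table")
  p0 <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    stop("kappa undefined: expected agreement Pe == 1 ",
         "(all mass in one category)")
  }
  (p0 - pe) / (1 - pe)
}

#' Cramer's V association statistic
#'
#' `sqrt(chi^2 / (n * (min(R, C) - 1)))` with the Pearson chi-squared
#' statistic (no continuity correction) on the table. Zero row or column
#' marginals are dropped before computing chi-squared; if fewer than two
#' rows or columns remain the association is degenerate and 0 is returned.
#' Values above 0.15 are conventionally taken as influential when screening
#' land-change driver variables.
#'
#' @param t An `hs_contingency` with `R, C >= 2` before marginal dropping.
#' @return Value in `[0, 1]`.
#' @export
#' @examples
#' cramers_v(contingency(matrix(c(30, 10, 10, 30), 2))) # 0.5
cramers_v <- function(t) {
  m <- unclass(t)
  if (nrow(m) < 2 || ncol(m) < 2) stop("Cramer's V needs an R>=2 x C>=2 table")
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) return(0)
  chi2 <- suppressWarnings(
    stats::chisq.test(m, correct = FALSE)$statistic
  )
  v <- sqrt(as.numeric(chi2) / (sum(m) * (min(dim(m)) - 1)))
  unname(min(max(v, 0), 1))
}

#' NDVI rangeland condition legend
#' @return Tibble with columns `code`, `name`.
#' @export
ndvi_legend <- function() {
  tibble::tibble(code = 0:3,
                 name = c("Non-rangeland", "Good", "Fair", "Poor"))
}

#' Classify NDVI into rangeland condition classes
#'
#' Thresholds: good above 0.17, fair 0.12-0.17, poor 0.01-0.12. Boundary
#' convention (the published intervals touch): lower bounds inclusive,
#' upper bounds exclusive, except fair which is closed at 0.17 so that
#' good is the open interval above it. NDVI below 0.01 is mapped to a
#' non-rangeland code; nodata cells stay nodata.
#'
#' @param ndvi An `hs_cont_raster` of NDVI values.
#' @return An `hs_cat_raster` with the [ndvi_legend()] codes
#'   (0 non-rangeland, 1 good, 2 fair, 3 poor).
#' @export
classify_ndvi <- function(ndvi) {
  if (!inherits(ndvi, "hs_cont_raster")) stop("ndvi must be a continuous raster")
  v <- ndvi$values
  out <- matrix(NA_integer_, nrow(v), ncol(v))
  ok <- !is.na(v)
  out[ok & v > 0.17] <- 1L
  out[ok & v >= 0.12 & v <= 0.17] <- 2L
  out[ok & v >= 0.01 & v < 0.12] <- 3L
  out[ok & v < 0.01] <- 0L
  cat_raster(out, legend = ndvi_legend(), cell_size = ndvi$cell_size,
             xmin = ndvi$xmin, ymax = ndvi$ymax)
}
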