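#' Estimate a land-change transition matrix from two dated maps
#'
#' Cross-tabulates the two maps over the full shared legend and
#' row-normalizes the counts into transition probabilities. A class absent
#' at the first date gets an identity row (absent classes persist by
#' convention, never `NaN`).
#'
#' @param map_t1,map_t2 Aligned `hs_cat_raster`s sharing a legend.
#' @param period_years Duration between the two maps (years).
#' @return An `hs_transition` with fields `legend`, `probs` (row-stochastic
#'   matrix), `counts` and `period_years`.
#' @export
transition_matrix <- function(map_t1, map_t2, period_years = NA_real_) {
  assert_aligned(map_t1, map_t2)
  if (!setequal(map_t1$legend$code, map_t2$legend$code)) {
    stop("maps do not share a legend")
  }
  codes <- map_t1$legend$code
  counts <- unclass(crosstab(map_t1, map_t2, codes_a = codes, codes_b = codes))
  attr(counts, "row_labels") <- NULL
  attr(counts, "col_labels") <- NULL
  probs <- counts / pmax(rowSums(counts), 1)
  zero <- rowSums(counts) == 0
  probs[zero, ] <- diag(length(codes))[zero, , drop = FALSE]
  new_transition(map_t1$legend, probs, counts, period_years)
}

#' Build a transition matrix from a probability matrix
#'
#' @param probs K x K row-stochastic matrix ordered as `legend$code`.
#' @param legend Legend tibble (`code`, `name`); default [lulc_legend()].
#' @param period_years Duration the matrix represents.
#' @return An `hs_transition`.
#' @export
as_transition <- function(probs, legend = lulc_legend(),
                          period_years = NA_real_) {
  probs <- as.matrix(probs)
  new_transition(legend, probs, counts = NULL, period_years)
}

new_transition <- function(legend, probs, counts, period_years) {
  if (nrow(probs) != ncol(probs) || nrow(probs) != nrow(legend)) {
    stop("transition matrix must be K x K over the legend")
  }
  if (any(probs < 0) || any(abs(rowSums(probs) - 1) > 1e-9)) {
    stop("transition rows must be non-negative and sum to 1")
  }
  dimnames(probs) <- list(legend$code, legend$code)
  if (!is.null(counts)) dimnames(counts) <- dimnames(probs)
  structure(list(legend = legend, probs = probs, counts = counts,
                 period_years = period_years),
            class = "hs_transition")
}

#' @export
print.hs_transition <- function(x, ...) {
  cat(sprintf("<hs_transition: %d classes, period %s yr>\n",
              nrow(x$probs), format(x$period_years)))
  print(round(x$probs, 3))
  invisible(x)
}

#' Tidy a transition matrix into long form
#' @param x An `hs_transition`.
#' @param ... Unused.
#' @return Tibble with columns `from`, `to`, `prob` and (when estimated
#'   from maps) `count`.
#' @export
tidy.hs_transition <- function(x, ...) {
  nm <- x$legend$name
  out <- tidyr::expand_grid(from = nm, to = nm)
  out$prob <- x$probs[cbind(match(out$from, nm), match(out$to, nm))]
  if (!is.null(x$counts)) {
    out$count <- x$counts[cbind(match(out$from, nm), match(out$to, nm))]
  }
  out
}

#' Per-class net area change between two dated maps
#'
#' @param map_t1,map_t2 Aligned `hs_cat_raster`s sharing a legend.
#' @return Tibble with columns `code`, `name`, `area_t1_ha`, `area_t2_ha`,
#'   `net_change_ha`. Net changes sum to zero when both maps are fully
#'   valid.
#' @export
net_change <- function(map_t1, map_t2) {
  assert_aligned(map_t1, map_t2)
  codes <- map_t1$legend$code
  ha <- map_t1$cell_size^2 / 1e4
  n1 <- tabulate(match(map_t1$values, codes), length(codes))
  n2 <- tabulate(match(map_t2$values, codes), length(codes))
  tibble::tibble(
    code = codes, name = map_t1$legend$name,
    area_t1_ha = n1 * ha, area_t2_ha = n2 * ha,
    net_change_ha = (n2 - n1) * ha
  )
}

#' Project class composition forward with a Markov chain
#'
#' @param tm An `hs_transition`.
#' @param composition Non-negative vector over the legend summing to 1.
#' @param n_steps Number of matrix applications (>= 0); each step spans the
#'   matrix's calibration period.
#' @return Projected composition (named numeric, sums to 1).
#' @export
project_demand <- function(tm, composition, n_steps = 1L) {
  stopifnot(inherits(tm, "hs_transition"))
  k <- nrow(tm$probs)
  if (length(composition) != k) stop("composition length must match legend")
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-6) {
    stop("composition must be a probability vector over the legend")
  }
  v <- as.numeric(composition)
  for (i in seq_len(n_steps)) v <- as.numeric(v %*% tm$probs)
  stats::setNames(v / sum(v), tm$legend$code)
}

#' Linear weighted suitability surface
#'
#' Each covariate is min-max normalized to `[0, 1]` (a constant covariate
#' contributes a uniform 0.5) and the weighted sum is min-max renormalized
#' to `[0, 1]`. A deterministic, documented stand-in for transition
#' potential modelling.
#'
#' @param covariates List of aligned `hs_cont_raster`s.
#' @param weights Finite numeric weights, one per covariate. All-zero
#'   weights give a uniform 0.5 surface.
#' @return An `hs_cont_raster` in `[0, 1]`.
#' @export
suitability_surface <- function(covariates, weights = rep(1, length(covariates))) {
  if (length(covariates) == 0) stop("at least one covariate required")
  if (length(weights) != length(covariates) || any(!is.finite(weights))) {
    stop("weights must be finite, one per covariate")
  }
  tpl <- covariates[[1]]
  for (cv in covariates) assert_aligned(tpl, cv)
  normed <- lapply(covariates, function(cv) minmax01(cv$values))
  if (sum(abs(weights)) == 0) {
    s <- matrix(0.5, nrow(tpl$values), ncol(tpl$values))
  } else {
    s <- Reduce(`+`, Map(function(m, w) m * w, normed, weights)) /
      sum(abs(weights))
    s <- minmax01(s)
  }
  s[is.na(tpl$values)] <- NA_real_
  cont_raster(s, cell_size = tpl$cell_size, xmin = tpl$xmin, ymax = tpl$ymax)
}

minmax01 <- function(m) {
  rng <- range(m, na.rm = TRUE)
  if (diff(rng) == 0) {
    m[] <- 0.5
    m
  } else {
    (m - rng[1]) / diff(rng)
  }
}

#' Allocate projected change onto the map by suitability ranking
#'
#' Integer per-transition targets are derived from the `n_steps`-step
#' transition probabilities by largest-remainder rounding within each donor
#' class (so donor row totals are conserved exactly and every transition's
#' allocated count is within one cell of its expected count). For each
#' gaining transition the highest-suitability donor cells convert, ties
#' broken by a seeded shuffle; unconverted cells persist.
#'
#' @param map_t An `hs_cat_raster`.
#' @param tm An `hs_transition` over the map's legend.
#' @param suitability Optional named list of `hs_cont_raster`s keyed
#'   `"i->j"` by class code (e.g. `"1->6"`); transitions without a surface
#'   use a uniform suitability.
#' @param n_steps Markov steps to project (default 1).
#' @param seed Integer seed for tie-breaking.
#' @return An `hs_cat_raster`; attribute `allocation` is a tibble with one
#'   row per transition (`from`, `to`, `expected`, `allocated`).
#' @export
allocate_change <- function(map_t, tm, suitability = NULL, n_steps = 1L,
                            seed = 1L) {
  stopifnot(inherits(tm, "hs_transition"))
  codes <- map_t$legend$code
  if (!setequal(codes, tm$legend$code)) stop("legend mismatch")
  P <- tm$probs
  for (i in seq_len(max(0L, n_steps - 1L))) P <- P %*% tm$probs
  v <- map_t$values
  out <- v
  alloc <- list()
  withr::with_seed(seed, {
    tie <- matrix(stats::runif(length(v)), nrow(v), ncol(v))
    for (i in seq_along(codes)) {
      cells <- which(!is.na(v) & v == codes[i])
      if (length(cells) == 0) next
      expected <- length(cells) * P[i, ]
      target <- largest_remainder(expected)
      # gaining transitions, largest target first (ties by class order)
      gaining <- setdiff(order(-target), i)
      gaining <- gaining[target[gaining] > 0]
      avail <- cells
      for (j in gaining) {
        key <- paste0(codes[i], "->", codes[j])
        s <- if (!is.null(suitability[[key]])) {
          suitability[[key]]$values[avail]
        } else {
          rep(0.5, length(avail))
        }
        take <- min(target[j], length(avail))
        pick <- avail[order(-s, tie[avail])][seq_len(take)]
        out[pick] <- codes[j]
        avail <- setdiff(avail, pick)
        alloc[[length(alloc) + 1]] <- tibble::tibble(
          from = codes[i], to = codes[j],
          expected = expected[j], allocated = take)
      }
    }
  })
  res <- cat_raster(out, legend = map_t$legend, cell_size = map_t$cell_size,
                    xmin = map_t$xmin, ymax = map_t$ymax)
  attr(res, "allocation") <- if (length(alloc)) dplyr::bind_rows(alloc) else
    tibble::tibble(from = integer(), to = integer(),
                   expected = numeric(), allocated = integer())
  res
}

#' Screen land-change driver variables with Cramer's V
#'
#' Each continuous covariate is binned into deciles (quantile bins; ties
#' collapse bins) and cross-tabulated against a binary change/no-change
#' mask; Cramer's V above 0.15 flags the covariate as influential.
#'
#' @param covariates Named list of `hs_cont_raster`s aligned with the mask.
#' @param change_mask Binary `hs_cat_raster` (1 = changed).
#' @return Tibble with columns `driver`, `cramers_v`, `influential`.
#' @export
screen_drivers <- function(covariates, change_mask) {
  if (is.null(names(covariates)) || any(names(covariates) == "")) {
    stop("covariates must be a named list")
  }
  rows <- purrr::imap(covariates, function(cv, nm) {
    assert_aligned(cv, change_mask)
    ok <- !is.na(cv$values) & !is.na(change_mask$values)
    x <- cv$values[ok]
    y <- change_mask$values[ok]
    if (length(unique(y)) < 2) stop("change mask has an empty class")
    brk <- unique(stats::quantile(x, probs = seq(0, 1, 0.1), type = 7))
    v <- if (length(unique(x)) < 2) {
      0 # a constant covariate carries no association
    } else {
      bin <- if (length(brk) >= 3) {
        cut(x, breaks = brk, include.lowest = TRUE)
      } else {
        factor(x) # few distinct values: use them as categories directly
      }
      cramers_v(contingency(unclass(table(bin, y))))
    }
    tibble::tibble(driver = nm, cramers_v = v, influential = v > 0.15)
  })
  dplyr::bind_rows(rows)
}
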