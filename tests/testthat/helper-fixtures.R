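# small raster builders used across test files

make_cat <- function(v, nrow = NULL, cell_size = 30, legend = NULL) {
  if (!is.matrix(v)) v <- matrix(v, nrow = nrow, byrow = TRUE)
  cat_raster(v, legend = legend, cell_size = cell_size)
}

make_cont <- function(v, nrow = NULL, cell_size = 30) {
  if (!is.matrix(v)) v <- matrix(v, nrow = nrow, byrow = TRUE)
  cont_raster(v, cell_size = cell_size)
}

checkerboard <- function(n, codes = c(1L, 2L), cell_size = 30) {
  v <- outer(seq_len(n), seq_len(n), function(i, j) codes[(i + j) %% 2 + 1])
  cat_raster(v, cell_size = cell_size)
}

# random categorical raster (optionally with nodata holes)
random_cat <- function(nr, nc, k = 3, p_na = 0, seed = 1, cell_size = 30) {
  withr::with_seed(seed, {
    v <- matrix(sample.int(k, nr * nc, replace = TRUE), nr, nc)
    if (p_na > 0) v[stats::runif(nr * nc) < p_na] <- NA_integer_
  })
  cat_raster(v, cell_size = cell_size)
}

# binary threat layer aligned with a template raster
threat_from_cells <- function(template, cells) {
  v <- matrix(0L, nrow(template$values), ncol(template$values))
  v[cells] <- 1L
  cat_raster(v, legend = tibble::tibble(code = 0:1,
                                        name = c("absent", "present")),
             cell_size = template$cell_size, xmin = template$xmin,
             ymax = template$ymax)
}

# uniform-sensitivity table for ad-hoc threat sets
flat_sensitivity <- function(codes, threat_nms, habitat = 1, s = 1) {
  df <- tibble::tibble(code = codes,
                       name = paste0("class_", codes),
                       habitat = habitat)
  for (tn in threat_nms) df[[tn]] <- s
  df
}

flat_threat_specs <- function(threat_nms, max_dist_km = 0.6, weight = 1,
                              decay = "linear") {
  tibble::tibble(threat = threat_nms,
                 max_dist_km = rep_len(max_dist_km, length(threat_nms)),
                 weight = rep_len(weight, length(threat_nms)),
                 decay = rep_len(decay, length(threat_nms)))
}
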