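# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (FFT convolution, igraph components): queue-based flood
# fill, explicit pair enumeration, and the literal double sum over threat
# cells.

# flood-fill patch labelling
oracle_label <- function(v, rule = 8L) {
  nr <- nrow(v); nc <- ncol(v)
  lab <- matrix(NA_integer_, nr, nc)
  nbrs <- if (rule == 8L) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  np <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(v[i, j]) || !is.na(lab[i, j])) next
    np <- np + 1L
    queue <- list(c(i, j))
    lab[i, j] <- np
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nbrs))) {
        ni <- cur[1] + nbrs[k, 1]; nj <- cur[2] + nbrs[k, 2]
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        if (is.na(v[ni, nj]) || !is.na(lab[ni, nj])) next
        if (v[ni, nj] != v[cur[1], cur[2]]) next
        lab[ni, nj] <- np
        queue[[length(queue) + 1]] <- c(ni, nj)
      }
    }
  }
  list(labels = lab, np = np)
}

# 4-neighbour double-counted adjacency by explicit pair enumeration
oracle_adjacency <- function(v) {
  codes <- sort(unique(v[!is.na(v)]))
  m <- length(codes)
  g <- matrix(0L, m, m, dimnames = list(codes, codes))
  nr <- nrow(v); nc <- ncol(v)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(v[i, j])) next
    for (d in list(c(0, 1), c(1, 0))) {
      ni <- i + d[1]; nj <- j + d[2]
      if (ni > nr || nj > nc || is.na(v[ni, nj])) next
      a <- match(v[i, j], codes); b <- match(v[ni, nj], codes)
      g[a, b] <- g[a, b] + 1L
      g[b, a] <- g[b, a] + 1L
    }
  }
  g
}

oracle_shdi <- function(v) {
  vv <- v[!is.na(v)]
  p <- as.numeric(table(vv)) / length(vv)
  -sum(p * log(p))
}

oracle_contag <- function(v) {
  vv <- v[!is.na(v)]
  codes <- sort(unique(vv))
  m <- length(codes)
  if (m < 2) return(NA_real_)
  P <- as.numeric(table(factor(vv, codes))) / length(vv)
  g <- oracle_adjacency(v)
  s <- 0
  for (i in seq_len(m)) for (k in seq_len(m)) {
    if (sum(g[i, ]) == 0) next
    p_ik <- P[i] * g[i, k] / sum(g[i, ])
    if (p_ik > 0) s <- s + p_ik * log(p_ik)
  }
  100 * (1 + s / (2 * log(m)))
}

oracle_pd <- function(v, cell_size, rule = 8L) {
  area_ha <- sum(!is.na(v)) * cell_size^2 / 1e4
  oracle_label(v, rule)$np / (area_ha / 100)
}

# literal evaluation of the degradation double sum: for every cell x, sum
# the decayed influence over every threat cell y of every threat r
oracle_degradation <- function(landcover, threats, specs, sens) {
  v <- landcover$values
  nr <- nrow(v); nc <- ncol(v)
  cs <- landcover$cell_size
  w <- specs$weight[match(names(threats), specs$threat)]
  wn <- w / sum(w)
  D <- matrix(0, nr, nc)
  for (t_i in seq_along(threats)) {
    spec <- specs[specs$threat == names(threats)[t_i], ]
    dmax <- spec$max_dist_km * 1000
    src <- which(threats[[t_i]]$values == 1L, arr.ind = TRUE)
    if (nrow(src) == 0) next
    s_col <- sens[[names(threats)[t_i]]]
    for (xi in seq_len(nr)) for (xj in seq_len(nc)) {
      if (is.na(v[xi, xj])) next
      d <- cs * sqrt((xi - src[, 1])^2 + (xj - src[, 2])^2)
      infl <- if (spec$decay == "linear") {
        pmax(0, 1 - d / dmax)
      } else {
        ifelse(d <= dmax, exp(-2.99 * d / dmax), 0)
      }
      s_jr <- s_col[match(v[xi, xj], sens$code)]
      D[xi, xj] <- D[xi, xj] + wn[t_i] * sum(infl) * s_jr
    }
  }
  D[is.na(v)] <- NA_real_
  D
}

oracle_crosstab <- function(a, b) {
  va <- a$values; vb <- b$values
  codes_a <- sort(unique(va[!is.na(va) & !is.na(vb)]))
  codes_b <- sort(unique(vb[!is.na(va) & !is.na(vb)]))
  m <- matrix(0L, length(codes_a), length(codes_b),
              dimnames = list(codes_a, codes_b))
  for (i in seq_along(va)) {
    if (is.na(va[i]) || is.na(vb[i])) next
    m[match(va[i], codes_a), match(vb[i], codes_b)] <-
      m[match(va[i], codes_a), match(vb[i], codes_b)] + 1L
  }
  m
}
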