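test_that("patch labelling matches enumeration on hand fixtures", {
  uni <- make_cat(rep(1L, 16), nrow = 4)
  expect_equal(label_patches(uni)$np, 1)

  cb <- checkerboard(4)
  expect_equal(label_patches(cb, neighbor_rule = 8L)$np, 2)

  blobs <- make_cat(c(1, 1, 2, 1,
                      1, 2, 2, 1,
                      2, 2, 2, 1), nrow = 3)
  expect_equal(label_patches(blobs)$np, 3) # two class-1 blobs + one class-2

  holed <- make_cat(c(1, NA, 1,
                      NA, NA, NA,
                      1, NA, 1), nrow = 3)
  expect_equal(label_patches(holed)$np, 4) # nodata splits patches
  expect_error(label_patches(make_cat(matrix(NA_integer_, 2, 2),
                                      legend = tibble::tibble(code = 1L,
                                                              name = "a"))),
               "all-nodata")
})

test_that("patch density uses the per-100-ha convention", {
  # 10 x 10 cells of 100 m = 100 ha, one patch
  one <- cat_raster(matrix(1L, 10, 10), cell_size = 100)
  expect_equal(patch_density(one), 1.0)
  # doubling NP at fixed area doubles PD
  two <- cat_raster(matrix(rep(c(1L, 2L), each = 50), 10), cell_size = 100)
  expect_equal(patch_density(two), 2.0)
  # 64 x 64 at 30 m = 368.64 ha
  lc <- generate_landcover(synthetic_config(n_rows = 64, n_cols = 64,
                                            seed = 12))
  np <- label_patches(lc)$np
  expect_equal(patch_density(lc), np / 3.6864)
})

test_that("Shannon diversity hits its closed forms", {
  expect_equal(shdi(make_cat(rep(1L, 9), nrow = 3)), 0)
  four <- make_cat(rep(1:4, each = 4), nrow = 4)
  expect_equal(shdi(four), log(4))
  mix <- make_cat(rep(c(1L, 2L, 3L), c(5, 3, 2)), nrow = 2)
  expect_equal(shdi(mix), -sum(c(0.5, 0.3, 0.2) * log(c(0.5, 0.3, 0.2))))
  expect_equal(shdi(mix), 1.0297, tolerance = 1e-4)
})

test_that("adjacency counting follows the double-count convention", {
  uni <- make_cat(rep(1L, 9), nrow = 3)
  g <- adjacency_table(uni)
  expect_equal(as.vector(g), 24) # 12 pairs, each counted twice
  cb <- checkerboard(2)
  g2 <- unclass(adjacency_table(cb))
  expect_equal(diag(g2), c(`1` = 0L, `2` = 0L))
  expect_equal(g2[1, 2], 4L)
  withr::with_seed(23, {
    v <- matrix(sample(1:3, 9, replace = TRUE), 3)
  })
  v[2, 2] <- NA
  x <- cat_raster(v)
  expect_equal(unclass(adjacency_table(x)), oracle_adjacency(v),
               ignore_attr = "class")
})

test_that("contagion matches hand evaluation on the checkerboard", {
  expect_equal(contag(checkerboard(8)), 50.0)
  # brute-force verification of the same fixture
  expect_equal(contag(checkerboard(8)), oracle_contag(checkerboard(8)$values))
})

test_that("contagion of two half-planes approaches the balanced-class ceiling", {
  # For m balanced classes the adjacency distribution p_ik cannot carry less
  # entropy than the class proportions themselves, so CONTAG is capped at
  # 100 * (1 - ln(m) / (2 ln m)) = 50 for m = 2; two homogeneous half-planes
  # approach that ceiling from below as the boundary fraction vanishes.
  half <- function(n) {
    cat_raster(cbind(matrix(1L, n, n / 2), matrix(2L, n, n / 2)))
  }
  c16 <- contag(half(16)); c64 <- contag(half(64))
  expect_gt(c64, c16)      # aggregation grows with grid size
  expect_gt(c64, 45)
  expect_lt(c64, 50)
  # and aggregated half-planes far exceed a random 2-class mixture
  rnd <- random_cat(64, 64, k = 2, seed = 19)
  expect_gt(c64, contag(rnd) + 30)
})

test_that("contagion is undefined on single-class landscapes", {
  expect_true(is.na(contag(make_cat(rep(1L, 16), nrow = 4))))
  rep <- metrics_report(make_cat(rep(1L, 16), nrow = 4))
  expect_equal(rep$np, 1)
  expect_equal(rep$shdi, 0)
  expect_true(is.na(rep$contag))
})

test_that("all four metrics agree with brute-force oracles on small fixtures", {
  for (seed in 1:6) {
    x <- random_cat(12, 14, k = 4, p_na = ifelse(seed %% 2, 0, 0.1),
                    seed = seed)
    expect_equal(label_patches(x)$np, oracle_label(x$values)$np)
    expect_equal(patch_density(x), oracle_pd(x$values, x$cell_size))
    expect_equal(shdi(x), oracle_shdi(x$values))
    expect_equal(contag(x), oracle_contag(x$values))
  }
})

test_that("metrics are invariant to class relabelling; SHDI to rearrangement", {
  x <- random_cat(10, 10, k = 3, seed = 31)
  y <- x
  y$values <- matrix(c(7L, 2L, 5L)[x$values], 10, 10) # relabel 1,2,3 -> 7,2,5
  expect_equal(label_patches(y)$np, label_patches(x)$np)
  expect_equal(patch_density(y), patch_density(x))
  expect_equal(contag(y), contag(x))
  z <- x
  withr::with_seed(32, z$values <- matrix(sample(x$values), 10, 10))
  expect_equal(shdi(z), shdi(x))
  # SHDI is maximal exactly at equal proportions
  expect_lt(shdi(x), log(3) + 1e-12)
  eq <- make_cat(rep(1:4, each = 25), nrow = 10)
  expect_equal(shdi(eq), log(4))
})

test_that("clumping lowers fragmentation and raises contagion", {
  cfgs <- function(cl, seed) synthetic_config(
    n_rows = 48, n_cols = 48, clumping = cl,
    class_proportions = c(0.4, 0.3, 0.3, 0, 0, 0, 0), seed = seed)
  for (seed in 1:3) {
    lo <- generate_landcover(cfgs(0, seed))
    hi <- generate_landcover(cfgs(5, seed))
    expect_gt(label_patches(lo)$np, label_patches(hi)$np)
    expect_lt(contag(lo), contag(hi))
  }
})
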