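legend2 <- tibble::tibble(code = 1:2, name = c("a", "b"))

test_that("transition matrix of identical maps is the identity", {
  lc <- random_cat(16, 16, k = 4, seed = 1)
  tm <- transition_matrix(lc, lc, 30)
  expect_equal(unname(tm$probs), diag(4))
  expect_equal(tm$period_years, 30)
})

test_that("transition probabilities are hand-countable on a toy pair", {
  a <- make_cat(c(1, 1, 2, 2,
                  1, 1, 2, 2,
                  3, 3, 4, 4,
                  3, 3, 4, 4), nrow = 4)
  b <- a
  b$values[1, 1] <- 2L # one of four class-1 cells flips to class 2
  tm <- transition_matrix(a, b)
  expect_equal(tm$probs["1", "2"], 0.25)
  expect_equal(tm$probs["1", "1"], 0.75)
  expect_equal(sum(tm$counts), 16)
})

test_that("classes absent at t1 get identity rows, never NaN", {
  lg <- tibble::tibble(code = 1:3, name = c("a", "b", "c"))
  a <- cat_raster(matrix(c(1L, 1L, 2L, 2L), 2), legend = lg)
  tm <- transition_matrix(a, a)
  expect_equal(unname(tm$probs[3, ]), c(0, 0, 1))
  expect_false(anyNA(tm$probs))
})

test_that("net change conserves area and converts cells to hectares", {
  a <- make_cat(c(1, 1, 2, 2), nrow = 2, cell_size = 30)
  expect_true(all(net_change(a, a)$net_change_ha == 0))
  b <- a
  b$values[1, 1] <- 2L
  nc <- net_change(a, b)
  expect_equal(nc$net_change_ha[nc$code == 1], -0.09)
  expect_equal(nc$net_change_ha[nc$code == 2], 0.09)
  # conservation on any fully valid pair
  x <- random_cat(20, 20, k = 5, seed = 2)
  y <- random_cat(20, 20, k = 5, seed = 3)
  expect_equal(sum(net_change(x, y)$net_change_ha), 0)
})

test_that("Markov projection matches hand-computed matrix powers", {
  tm <- as_transition(rbind(c(0.9, 0.1), c(0.2, 0.8)), legend2)
  expect_equal(unname(project_demand(tm, c(1, 0), 0)), c(1, 0))
  expect_equal(unname(project_demand(tm, c(1, 0), 2)), c(0.83, 0.17))
  id <- as_transition(diag(2), legend2)
  expect_equal(unname(project_demand(id, c(0.4, 0.6), 13)), c(0.4, 0.6))
})

test_that("Markov projection preserves the simplex", {
  withr::with_seed(11, {
    for (i in 1:20) {
      k <- sample(2:7, 1)
      p <- matrix(stats::rgamma(k * k, 1), k)
      p <- p / rowSums(p)
      lg <- tibble::tibble(code = seq_len(k), name = paste0("c", seq_len(k)))
      comp <- as.numeric(stats::rgamma(k, 1)); comp <- comp / sum(comp)
      out <- project_demand(as_transition(p, lg), comp,
                            n_steps = sample(0:10, 1))
      expect_true(all(out >= -1e-12))
      expect_equal(sum(out), 1)
    }
  })
})

test_that("suitability surfaces normalize and degenerate as documented", {
  cv <- make_cont(c(2, 4, 6, 8), nrow = 2)
  s1 <- suitability_surface(list(cv), 1)
  expect_equal(s1$values, matrix(c(0, 1/3, 2/3, 1), 2, byrow = TRUE))
  s0 <- suitability_surface(list(cv), 0)
  expect_true(all(s0$values == 0.5))
  cst <- make_cont(rep(5, 4), nrow = 2)
  expect_true(all(suitability_surface(list(cst), 1)$values == 0.5))
  # equal weights on a 3x3 toy: hand-computed normalized mean
  a <- make_cont(1:9, nrow = 3)
  b <- make_cont(c(9, 8, 7, 6, 5, 4, 3, 2, 1), nrow = 3)
  s <- suitability_surface(list(a, b), c(1, 1))
  expect_true(all(abs(s$values - 0.5) < 1e-12)) # the two gradients cancel
})

test_that("allocation converts the highest-suitability donors first", {
  lg <- legend2
  v <- matrix(1L, 5, 8) # 40 class-1 cells
  lc <- cat_raster(v, legend = lg)
  p <- rbind(c(0.75, 0.25), c(0, 1)) # demand: 10 cells 1 -> 2
  s <- cont_raster(matrix(seq(0, 1, length.out = 40), 5, 8))
  out <- allocate_change(lc, as_transition(p, lg),
                         suitability = list("1->2" = s), seed = 1)
  converted <- which(out$values == 2L)
  expect_length(converted, 10)
  expect_setequal(converted, order(s$values, decreasing = TRUE)[1:10])
})

test_that("allocation matches projected demand within one cell per transition", {
  lc <- generate_landcover(synthetic_config(n_rows = 48, n_cols = 48,
                                            seed = 21))
  tm <- default_transition()
  out <- allocate_change(lc, tm, seed = 2)
  alloc <- attr(out, "allocation")
  expect_true(all(abs(alloc$allocated - alloc$expected) <= 1))
  # identity matrix leaves the map unchanged
  id <- as_transition(diag(7), lulc_legend())
  expect_identical(allocate_change(lc, id, seed = 3)$values, lc$values)
})

test_that("driver screening flags association and ignores noise", {
  withr::with_seed(31, {
    mask_v <- matrix(sample(0:1, 2500, replace = TRUE), 50)
    mask <- cat_raster(mask_v,
                       legend = tibble::tibble(code = 0:1,
                                               name = c("stable", "changed")))
    perfect <- cont_raster(mask_v + 0)
    noise <- cont_raster(matrix(stats::rnorm(2500), 50))
    const <- cont_raster(matrix(1, 50, 50))
    rep <- screen_drivers(list(perfect = perfect, noise = noise,
                               const = const), mask)
  })
  expect_equal(rep$cramers_v[rep$driver == "perfect"], 1)
  expect_true(rep$influential[rep$driver == "perfect"])
  expect_lt(rep$cramers_v[rep$driver == "noise"], 0.1)
  expect_false(rep$influential[rep$driver == "noise"])
  expect_equal(rep$cramers_v[rep$driver == "const"], 0)
})

test_that("evolve followed by estimation recovers the generating matrix", {
  lc <- generate_landcover(synthetic_config(
    n_rows = 128, n_cols = 128, clumping = 0,
    class_proportions = c(0.5, 0.5, 0, 0, 0, 0, 0), seed = 41))
  p <- diag(7); p[1, 1] <- 0.7; p[1, 2] <- 0.3
  out <- evolve_landcover(lc, as_transition(p), clumping_bias = 0, seed = 42)
  est <- transition_matrix(lc, out)
  expect_lt(abs(est$probs["1", "2"] - 0.3), 0.03)
  expect_lt(abs(est$probs["2", "2"] - 1), 1e-12)
})
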