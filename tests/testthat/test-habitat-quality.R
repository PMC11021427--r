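test_that("decay factors hit their closed forms", {
  expect_equal(decay_factor(0, 8, "linear"), 1)
  expect_equal(decay_factor(0, 8, "exponential"), 1)
  expect_equal(decay_factor(8000, 8, "linear"), 0)
  expect_equal(decay_factor(4000, 8, "linear"), 0.5)
  expect_equal(decay_factor(10000, 10, "exponential"), exp(-2.99))
  expect_equal(decay_factor(10001, 10, "exponential"), 0) # clamped
  expect_equal(decay_factor(9000, 8, "linear"), 0)
})

test_that("shipped parameter tables carry the expected structure", {
  tt <- threat_table()
  expect_identical(tt$threat, threat_names())
  expect_true(all(tt$decay %in% c("linear", "exponential")))
  st <- sensitivity_table()
  expect_equal(st$code, 1:7)
  expect_equal(st$habitat[st$code == 7], 0) # built-up is non-habitat
  expect_true(all(st$habitat >= 0 & st$habitat <= 1))
  # user override with the same schema
  p <- file.path(tempdir(), "tt.csv")
  utils::write.csv(flat_threat_specs("x"), p, row.names = FALSE)
  expect_equal(threat_table(p)$threat, "x")
})

test_that("degradation is zero without threats or sensitivity", {
  lc <- make_cat(rep(1L, 64), nrow = 8)
  th <- list(x = threat_from_cells(lc, integer()))
  specs <- flat_threat_specs("x")
  sens <- flat_sensitivity(1L, "x")
  expect_true(all(degradation(lc, th, specs, sens)$values == 0))
  th2 <- list(x = threat_from_cells(lc, 1L))
  sens0 <- flat_sensitivity(1L, "x", s = 0)
  expect_true(all(degradation(lc, th2, specs, sens0)$values == 0))
})

test_that("a single linear threat at half range degrades by one half", {
  # threat at column 1; target cell 10 columns away = 300 m = d_max / 2
  lc <- make_cat(rep(1L, 21), nrow = 1)
  th <- list(x = threat_from_cells(lc, cbind(1, 1)))
  D <- degradation(lc, th, flat_threat_specs("x", max_dist_km = 0.6),
                   flat_sensitivity(1L, "x"))
  expect_equal(D$values[1, 11], 0.5, tolerance = 1e-9)
  expect_equal(D$values[1, 1], 1, tolerance = 1e-9)   # the threat cell itself
  expect_equal(D$values[1, 21], 0, tolerance = 1e-9)  # at d_max exactly
})

test_that("the convolution path equals the literal double sum", {
  specs <- flat_threat_specs(c("a", "b"), max_dist_km = c(0.3, 0.5),
                             weight = c(0.8, 0.5),
                             decay = c("linear", "exponential"))
  for (seed in 1:3) {
    lc <- random_cat(24, 24, k = 3, p_na = 0.05, seed = seed)
    sens <- flat_sensitivity(1:3, c("a", "b"),
                             habitat = c(1, 0.6, 0), s = NA)
    sens$a <- c(0.7, 0.9, 0.2); sens$b <- c(0.5, 0.3, 0.8)
    withr::with_seed(seed * 100, {
      th <- list(a = threat_from_cells(lc, sample(576, 20)),
                 b = threat_from_cells(lc, sample(576, 8)))
    })
    fast <- degradation(lc, th, specs, sens)$values
    slow <- oracle_degradation(lc, th, specs, sens)
    scale <- max(abs(slow), na.rm = TRUE)
    expect_lt(max(abs(fast - slow), na.rm = TRUE), 1e-6 * scale)
  }
})

test_that("adding a threat cell never decreases degradation", {
  lc <- random_cat(16, 16, k = 2, seed = 9)
  specs <- flat_threat_specs("a", max_dist_km = 0.4)
  sens <- flat_sensitivity(1:2, "a", habitat = c(1, 0.5))
  th1 <- list(a = threat_from_cells(lc, c(5L, 100L)))
  th2 <- list(a = threat_from_cells(lc, c(5L, 100L, 200L)))
  d1 <- degradation(lc, th1, specs, sens)$values
  d2 <- degradation(lc, th2, specs, sens)$values
  expect_true(all(d2 - d1 >= -1e-12))
  q1 <- habitat_quality(lc, degradation(lc, th1, specs, sens),
                        sens, k = 0.5)$quality$values
  q2 <- habitat_quality(lc, degradation(lc, th2, specs, sens),
                        sens, k = 0.5)$quality$values
  expect_true(all(q2 - q1 <= 1e-12))
})

test_that("threats beyond the maximum effective distance contribute nothing", {
  lc <- make_cat(rep(1L, 40), nrow = 1, cell_size = 30)
  for (kind in c("linear", "exponential")) {
    th <- list(x = threat_from_cells(lc, cbind(1, 1)))
    D <- degradation(lc, th, flat_threat_specs("x", max_dist_km = 0.3,
                                               decay = kind),
                     flat_sensitivity(1L, "x"))
    expect_equal(D$values[1, 12:40], rep(0, 29), tolerance = 1e-9)
  }
})

test_that("degradation is invariant to uniform weight scaling", {
  lc <- random_cat(12, 12, k = 2, seed = 13)
  sens <- flat_sensitivity(1:2, c("a", "b"))
  th <- list(a = threat_from_cells(lc, 1:5),
             b = threat_from_cells(lc, 50:52))
  s1 <- flat_threat_specs(c("a", "b"), weight = c(0.3, 0.9))
  s2 <- s1; s2$weight <- s2$weight * 7
  expect_equal(degradation(lc, th, s1, sens)$values,
               degradation(lc, th, s2, sens)$values, tolerance = 1e-12)
})

test_that("half-saturation resolution follows the auto convention", {
  D <- make_cont(c(0, 0.4, 1.0, 0.2), nrow = 2)
  expect_equal(resolve_half_saturation(D, "auto"), 0.5)
  expect_equal(resolve_half_saturation(D, 0.3), 0.3)
  expect_error(resolve_half_saturation(D, -1), "> 0")
  D0 <- make_cont(rep(0, 4), nrow = 2)
  expect_equal(resolve_half_saturation(D0, "auto"), 0.5)
})

test_that("quality obeys its closed forms", {
  lc <- make_cat(c(1L, 2L, 3L), nrow = 1)
  sens <- flat_sensitivity(1:3, "x", habitat = c(1, 0.6, 0))
  # D = 0 -> Q = H
  D0 <- cont_raster(matrix(0, 1, 3))
  q0 <- habitat_quality(lc, D0, sens, k = 0.5)
  expect_equal(as.vector(q0$quality$values), c(1, 0.6, 0))
  # D = K -> Q = H / 2
  Dk <- cont_raster(matrix(0.5, 1, 3))
  qk <- habitat_quality(lc, Dk, sens, k = 0.5)
  expect_equal(as.vector(qk$quality$values), c(0.5, 0.3, 0))
  # strictly decreasing in D where H > 0
  Dm <- cont_raster(matrix(0.8, 1, 3))
  qm <- habitat_quality(lc, Dm, sens, k = 0.5)
  expect_lt(qm$quality$values[1, 1], qk$quality$values[1, 1])
})

test_that("quality respects bounds with the shipped defaults", {
  cfg <- synthetic_config(n_rows = 32, n_cols = 32, seed = 17)
  lc <- generate_landcover(cfg)
  th <- generate_threat_layers(lc, cfg)
  q <- habitat_quality(lc, degradation(lc, th))
  H <- sensitivity_table()$habitat[match(lc$values, sensitivity_table()$code)]
  qv <- as.vector(q$quality$values)
  expect_true(all(qv >= 0 & qv <= H + 1e-12))
  expect_true(all(qv[lc$values == 7L] == 0)) # built-up has H = 0
})

test_that("six-level classification respects its boundaries and conserves area", {
  q <- make_cont(c(0, 0.1, 0.2, 0.3, 0.6, 0.61, 0.8, 1.0, NA), nrow = 3)
  cl <- classify_hq(q)
  expect_equal(as.vector(t(cl$raster$values)),
               c(0L, 1L, 1L, 2L, 3L, 4L, 4L, 5L, NA))
  expect_equal(sum(cl$areas$area_ha), valid_area_ha(q))
  # hand-built areas: cell = 0.09 ha
  expect_equal(cl$areas$area_ha[cl$areas$level == 1], 2 * 0.09)
  q0 <- make_cont(rep(0, 9), nrow = 3)
  cl0 <- classify_hq(q0)
  expect_equal(cl0$areas$n_cells[cl0$areas$level == 0], 9)
})

test_that("mean habitat quality averages the valid masked cells", {
  q <- make_cont(c(0.5, 0.5, 0.5, 0.5), nrow = 2)
  expect_equal(mean_hq(q), 0.5)
  q2 <- make_cont(c(0, 1, 0, 1), nrow = 2)
  expect_equal(mean_hq(q2), 0.5)
  q3 <- make_cont(c(0.1, 0.2, 0.3, 0.7, NA, 0.5), nrow = 2)
  expect_equal(mean_hq(q3), mean(c(0.1, 0.2, 0.3, 0.7, 0.5)))
  mask <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2)
  expect_equal(mean_hq(q2, mask), 0.5)
})
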