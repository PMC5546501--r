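test_that("isotropic edge weights match closed geometry and the sampling oracle", {
  win <- nc_window(1000)
  expect_equal(edge_correction_weight(c(500, 500), 100, win), 1)
  expect_equal(edge_correction_weight(c(0, 500), 50, win), 2)
  expect_equal(edge_correction_weight(c(0, 0), 50, win), 4)

  # awkward geometries: edge-adjacent, corner-adjacent, both oracles agree
  cases <- list(c(30, 500, 100), c(980, 40, 150), c(10, 10, 200),
                c(500, 5, 240), c(999, 999, 240))
  for (cs in cases) {
    w_pkg <- edge_correction_weight(cs[1:2], cs[3], win)
    frac_iv <- oracle_arc_fraction(cs[1], cs[2], cs[3], 1000, 1000)
    expect_equal(w_pkg, 1 / frac_iv, tolerance = 1e-12)
    frac_num <- oracle_arc_fraction_sampled(cs[1], cs[2], cs[3], 1000, 1000,
                                            n_angles = 2e5)
    expect_equal(1 / frac_num, w_pkg, tolerance = 1e-4)
  }

  expect_gte(edge_correction_weight(c(2, 2), 240, win), 1)
  expect_equal(edge_correction_weight(c(0, 0), 240, win, max_weight = 3), 3)
  expect_error(edge_correction_weight(c(1100, 0), 50, win), "outside")
  expect_error(edge_correction_weight(c(500, 500), 600, win), "not valid")
})

test_that("K of simple configurations follows the estimator definition", {
  win <- nc_window(1000)
  # two points 50 nm apart at the window center: interior weights are 1,
  # so K jumps to A * 2 / n^2 = 1e6 * 2 / 4 at r = 50
  pp <- point_pattern(c(475, 525), c(500, 500), win)
  kc <- k_function(pp)
  expect_equal(kc$k[kc$r < 50], rep(0, sum(kc$r < 50)))
  expect_equal(kc$k[kc$r >= 50], rep(5e5, sum(kc$r >= 50)))
  expect_equal(kc$l_minus_r[kc$r == 50], sqrt(5e5 / pi) - 50)
  expect_equal(kc$l_minus_r[kc$r == 50], 348.9423, tolerance = 1e-6)

  # three mutually distant points: indicator empty over the whole grid
  far <- point_pattern(c(100, 600, 350), c(100, 100, 533), win)
  expect_true(all(k_function(far)$k == 0))

  expect_error(k_function(point_pattern(1, 1, win)), "fewer than 2")
  expect_error(k_function(pp, correction = "banana"))
  expect_error(k_function(pp, r = c(3, 2, 1)), "increasing")
  expect_error(k_function(pp, r = r_grid(rmax = 600)), "not valid")
})

test_that("k_function equals the literal double-sum oracle on random patterns", {
  win <- nc_window(1000)
  r <- r_grid()
  for (s in 1:10) {
    pp <- random_pattern(sample(5:60, 1), win, seed = 100 + s)
    expect_equal(k_function(pp, r, correction = "none")$k,
                 oracle_k(pp, r, "none"), tolerance = 1e-12)
    expect_equal(k_function(pp, r, max_weight = Inf)$k,
                 oracle_k(pp, r, "isotropic"), tolerance = 1e-6)
    expect_equal(k_function(pp, r, max_weight = 10)$k,
                 oracle_k(pp, r, "isotropic", max_weight = 10),
                 tolerance = 1e-6)
  }
})

test_that("isotropic K matches an independent reference implementation", {
  skip_if_not_installed("spatstat.geom")
  skip_if_not_installed("spatstat.explore")
  win <- nc_window(1000)
  for (s in 1:3) {
    pp <- random_pattern(150, win, seed = 200 + s)
    kc <- k_function(pp, pair_normalisation = "unbiased", max_weight = Inf)
    X <- spatstat.geom::ppp(pp$x, pp$y,
                            window = spatstat.geom::owin(c(0, 1000), c(0, 1000)))
    ref <- spatstat.explore::Kest(X, r = c(0, kc$r), correction = "isotropic")
    expect_equal(kc$k, ref$iso[-1L], tolerance = 1e-10)
  }
})

test_that("K is monotone in r, scale-equivariant, and duplicate-safe", {
  win <- nc_window(1000)
  for (s in 1:20) {
    pp <- random_pattern(sample(2:80, 1), win, seed = 300 + s)
    kc <- k_function(pp)
    expect_true(all(diff(kc$k) >= 0))
  }
  # scaling coordinates and window by s rescales K: K'(s*r) = s^2 K(r)
  pp <- random_pattern(60, win, seed = 42)
  big <- point_pattern(pp$x * 2, pp$y * 2, nc_window(2000))
  r <- r_grid(rmax = 200)
  expect_equal(k_function(big, r * 2)$k, 4 * k_function(pp, r)$k,
               tolerance = 1e-12)
  # coincident points contribute unit weight, no NaN
  dup <- point_pattern(c(500, 500, 600), c(500, 500, 500), win)
  expect_true(all(is.finite(k_function(dup)$k)))
})

test_that("toroidal correction removes edge bias without weights", {
  win <- nc_window(1000)
  # on the torus a translated pattern has identical K
  pp <- random_pattern(80, win, seed = 9)
  shifted <- point_pattern((pp$x + 333) %% 1000, (pp$y + 777) %% 1000, win)
  expect_equal(k_function(pp, correction = "toroidal")$k,
               k_function(shifted, correction = "toroidal")$k,
               tolerance = 1e-9)
})

test_that("the L transform is the exact algebraic normalisation of K", {
  win <- nc_window(1000)
  kc <- k_function(random_pattern(50, win, seed = 5))
  expect_equal(kc$l_minus_r, sqrt(kc$k / pi) - kc$r)
  expect_equal(l_transform(kc)$l_minus_r, kc$l_minus_r)

  # K = pi r^2 (the CSR expectation) maps to identically zero
  csr_exact <- kc
  csr_exact$k <- pi * csr_exact$r^2
  expect_equal(l_transform(csr_exact)$l_minus_r, rep(0, length(kc$r)))

  # K = 0 maps to -r
  zero <- kc
  zero$k <- rep(0, length(kc$r))
  expect_equal(l_transform(zero)$l_minus_r, -zero$r)

  neg <- kc
  neg$k[3] <- -1
  expect_error(l_transform(neg), "negative")
})

test_that("curve CSV export keeps full precision", {
  kc <- k_function(random_pattern(40, nc_window(1000), seed = 3))
  f <- tempfile(fileext = ".csv")
  write_k_curve(kc, f)
  back <- read.csv(f)
  expect_equal(back$K, kc$k, tolerance = 1e-15)
  expect_equal(back$L_minus_r, kc$l_minus_r, tolerance = 1e-15)
})
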