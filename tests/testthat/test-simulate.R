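test_that("CSR generator respects count, bounds, seeds, and uniformity", {
  win <- nc_window(1000)
  expect_equal(simulate_csr(0, win, seed = 1)$n, 0L)

  pp <- simulate_csr(300, win, seed = 2)
  expect_equal(pp$n, 300L)
  expect_true(all(pp$x >= 0 & pp$x <= 1000 & pp$y >= 0 & pp$y <= 1000))

  expect_identical(simulate_csr(50, win, seed = 3)$x,
                   simulate_csr(50, win, seed = 3)$x)
  expect_false(identical(simulate_csr(50, win, seed = 3)$x,
                         simulate_csr(50, win, seed = 4)$x))

  # binomial expectation in a subrectangle: quarter window holds n/4 points
  counts <- vapply(1:400, function(s) {
    p <- simulate_csr(100, win, seed = 1000 + s)
    sum(p$x < 500 & p$y < 500)
  }, numeric(1))
  se <- sqrt(100 * 0.25 * 0.75 / 400)
  expect_lt(abs(mean(counts) - 25), 3 * se)
})

test_that("Thomas generator matches its closed-form intensity and clusters tightly", {
  win <- nc_window(1000)
  pars <- thomas_params(parent_intensity = 2e-5, mean_offspring = 15,
                        cluster_sd = 10)
  ns <- vapply(1:400, function(s) simulate_thomas(pars, win, seed = s)$n,
               numeric(1))
  # E[N] = kappa * A * mu = 300; boundary loss is negligible at sigma = 10;
  # per-draw variance of a Thomas count is kappa*A*mu*(1 + mu)
  se <- sqrt(20 * 15 * 16 / 400)
  expect_lt(abs(mean(ns) - 300), 3 * se)

  # the clustering signature: mean L(r)-r positive with a small-r peak
  lmat <- t(vapply(1:100, function(s) {
    k_function(simulate_thomas(pars, win, seed = 500 + s))$l_minus_r
  }, numeric(240)))
  lbar <- colMeans(lmat)
  r <- r_grid()
  expect_gt(max(lbar), 10)
  expect_lt(r[which.max(lbar)], 50)
  expect_gt(min(lbar[r <= 100]), 0)

  # cluster scatter on the window scale washes the signature out toward CSR:
  # at sigma = 500 the theoretical excess L(50)-50 is ~0.4 nm (vs ~10^2 for
  # sigma = 10), indistinguishable from the null at this precision
  wide <- thomas_params(parent_intensity = 2e-5, mean_offspring = 15,
                        cluster_sd = 500)
  lwide <- vapply(1:100, function(s) {
    pp <- simulate_thomas(wide, win, seed = 700 + s)
    if (pp$n < 10) return(NA_real_)
    kc <- k_function(pp)
    kc$l_minus_r[kc$r == 50]
  }, numeric(1))
  expect_lt(abs(mean(lwide, na.rm = TRUE)), 2)
})

test_that("labeling noise model thins, jitters, and enforces the hard core", {
  win <- nc_window(1000)
  pp <- simulate_csr(200, win, seed = 10)

  ident <- apply_labeling(pp, labeling_model(1, 0, 0), seed = 1)
  expect_identical(ident$x, pp$x)
  expect_identical(ident$y, pp$y)

  # efficiency 0.5: retained count is Binomial(n, 1/2) on average
  kept <- vapply(1:300, function(s) {
    apply_labeling(pp, labeling_model(efficiency = 0.5, hardcore_distance = 0),
                   seed = s)$n
  }, numeric(1))
  se <- sqrt(200 * 0.25 / 300)
  expect_lt(abs(mean(kept) - 100), 3 * se)

  # hard-core thinning leaves no pair below the exclusion distance
  dense <- simulate_thomas(thomas_params(cluster_sd = 3), win, seed = 5)
  thinned <- apply_labeling(dense, labeling_model(1, 0, 4.5), seed = 2)
  expect_gte(min(dist(cbind(thinned$x, thinned$y))), 4.5)
  expect_gt(attr(thinned, "n_thinned"), 0)

  # jitter keeps points in-window (spill is discarded and counted)
  jit <- apply_labeling(pp, labeling_model(1, 5, 0), seed = 3)
  expect_true(all(jit$x >= 0 & jit$x <= 1000))
  expect_equal(jit$n + attr(jit, "n_lost_window"), 200L)
})

test_that("generated patterns feed the full pipeline with the expected calls", {
  win <- nc_window(1000)
  env <- csr_envelope(300, win, n_simulations = 199, seed = 42)
  # clustered input is detected ...
  tho <- simulate_thomas(thomas_params(), win, seed = 77)
  env_t <- csr_envelope(tho$n, win, n_simulations = 199, seed = 43)
  expect_equal(exceeds_envelope(k_function(tho), env_t)$classification,
               "clustered")
  # ... CSR input is typically not
  calls <- vapply(1:10, function(s) {
    pp <- simulate_csr(300, win, seed = 2000 + s)
    exceeds_envelope(k_function(pp), env)$classification
  }, character(1))
  expect_gte(sum(calls == "random"), 8)
})

test_that("FLIM frame generator is the exact forward model", {
  fr <- simulate_flim_frame(matrix(c(0, 4), 1, 2))
  expect_equal(fr$phase[1, 1], 0)
  expect_equal(fr$modulation[1, 1], 1)
  wt <- 2 * pi * 4e7 * 4e-9
  expect_equal(fr$phase[1, 2], atan(wt))
  expect_equal(fr$phase[1, 2], 0.7880, tolerance = 1e-4)
  expect_equal(fr$modulation[1, 2], 1 / sqrt(1 + wt^2))
  expect_equal(fr$modulation[1, 2], 0.7052, tolerance = 1e-4)

  n1 <- simulate_flim_frame(matrix(2, 4, 4), phase_noise_sd = 0.01,
                            mod_noise_sd = 0.01, seed = 1)
  n2 <- simulate_flim_frame(matrix(2, 4, 4), phase_noise_sd = 0.01,
                            mod_noise_sd = 0.01, seed = 1)
  expect_identical(n1$phase, n2$phase)
  expect_true(all(n1$modulation >= 0 & n1$modulation <= 1))
})

test_that("simulated FRET experiments recover the programmed efficiency", {
  # zero between-cell spread: exact recovery
  exact <- simulate_fret_experiment(2.4, true_e = 20, n_cells = 10,
                                    cell_sd = 0, seed = 1)
  fm <- fret_efficiency(exact$donor_acceptor$tau_ns, mean(exact$donor$tau_ns))
  expect_equal(fm$mean_e_app, 20)

  # null case: mean efficiency within 3 SE of zero
  null <- simulate_fret_experiment(2.4, true_e = 0, n_cells = 30,
                                   cell_sd = 0.1, seed = 2)
  fm0 <- fret_efficiency(null$donor_acceptor$tau_ns, mean(null$donor$tau_ns))
  expect_lt(abs(fm0$mean_e_app), 3 * fm0$se_e_app)
  expect_true(all(null$donor$tau_ns > 0))
})
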