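test_that("objective is zero on identity and n on a doubled spectrum", {
  pv <- reference_params("cole", "marjoram_5cm")
  g <- std_grid()
  spec <- simulate_spectrum(pv, g)
  expect_identical(objective(pv, spec)$value, 0)
  # Z_model = 2 * Z_measured at every point -> each term is exactly 1
  half <- impedance_spectrum(g, spec$z / 2)
  expect_equal(objective(pv, half)$value, length(half$z))
})

test_that("objective equals a direct per-point loop on noisy data", {
  pv <- reference_params("cole", "marjoram_5cm")
  g <- std_grid()
  noisy <- simulate_spectrum(pv, g, noise_model(0.01, seed = 42))
  got <- objective(pv, noisy)
  clean <- simulate_spectrum(pv, g)
  acc <- 0
  for (i in seq_along(noisy$z)) {
    acc <- acc + Mod(clean$z[i] - noisy$z[i]) / Mod(noisy$z[i])
  }
  expect_equal(got$value, acc)
  expect_identical(got$n_points, 241L)
})

test_that("objective is invariant under frequency reordering", {
  pv <- reference_params("double_shell", "salvia_10cm")
  g <- coarse_grid()
  noisy <- simulate_spectrum(pv, g, noise_model(0.05, seed = 3))
  v1 <- objective(pv, noisy)$value
  # reversed spectrum is not a valid increasing grid, so sum manually
  zm <- model_impedance("double_shell", pv, g)$z
  v2 <- sum(rev(Mod(zm - noisy$z) / Mod(noisy$z)))
  expect_equal(v1, v2)
})

test_that("error_curve scales, summarises, and ties to the objective", {
  pv <- reference_params("double_cole", "marjoram_5cm")
  g <- coarse_grid()
  spec <- simulate_spectrum(pv, g)
  ec0 <- error_curve(pv, spec)
  expect_true(all(ec0$rel_err_percent == 0))
  expect_identical(ec0$max, 0)
  # uniformly scaled measurement -> flat curve at the scaling error
  scaled <- impedance_spectrum(g, spec$z / 1.02)
  ec <- error_curve(pv, scaled)
  expect_lt(max(abs(ec$rel_err_percent - 2)), 1e-9)
  # objective = sum(curve)/100
  noisy <- simulate_spectrum(pv, g, noise_model(0.02, seed = 8))
  ecn <- error_curve(pv, noisy)
  expect_equal(ecn$mean * length(noisy$z) / 100, objective(pv, noisy)$value)
  expect_gte(ecn$max, ecn$mean)
})

test_that("zero measured impedance is rejected", {
  pv <- reference_params("cole", "marjoram_5cm")
  g <- coarse_grid()
  z <- simulate_spectrum(pv, g)$z
  z[3] <- 0 + 0i
  bad <- impedance_spectrum(g, z)
  expect_error(objective(pv, bad), "zero impedance")
  expect_error(error_curve(pv, bad), "zero impedance")
})

test_that("nyquist_table negates the imaginary part", {
  g <- f1(debye_freq())
  tab <- nyquist_table(impedance_spectrum(g, 3 - 4i))
  expect_equal(unlist(tab, use.names = FALSE), c(g$frequencies, 3, 4))
  # the cole Debye fixture at omega = 1/RC lands at (50k, 50k)
  zd <- cole_impedance(debye_params(), g)
  tabd <- nyquist_table(zd)
  expect_equal(tabd$z_real_ohm, 50000, tolerance = 1e-9)
  expect_equal(tabd$neg_z_imag_ohm, 50000, tolerance = 1e-9)
  # purely real spectrum: second column is |z|, third is 0
  gr <- coarse_grid()
  tr <- nyquist_table(impedance_spectrum(gr, rep(7 + 0i,
                                                 length(gr$frequencies))))
  expect_true(all(tr$z_real_ohm == 7) && all(tr$neg_z_imag_ohm == 0))
})
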