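test_that("noiseless simulation equals the model evaluation bit-for-bit", {
  pv <- reference_params("cole", "marjoram_5cm")
  g <- std_grid()
  expect_identical(simulate_spectrum(pv, g)$z, cole_impedance(pv, g)$z)
})

test_that("noise is seed-deterministic and proportional", {
  pv <- reference_params("double_cole", "salvia_5cm")
  g <- std_grid()
  a <- simulate_spectrum(pv, g, noise_model(0.01, seed = 5))
  b <- simulate_spectrum(pv, g, noise_model(0.01, seed = 5))
  expect_identical(a$z, b$z)
  c2 <- simulate_spectrum(pv, g, noise_model(0.01, seed = 6))
  expect_false(identical(a$z, c2$z))
})

test_that("noise statistics match the complex-normal Monte Carlo oracle", {
  # eps = sigma*(g1 + i*g2)/sqrt(2): |eps| is sigma/sqrt(2) times a chi(2)
  # variate, so E|eps| = sigma*sqrt(pi)/2; check against an empirical mean
  sigma <- 0.01
  pv <- reference_params("cole", "salvia_5cm")
  g <- std_grid()
  clean <- simulate_spectrum(pv, g)$z
  rel <- c()
  bias <- 0 + 0i
  n_rep <- 420  # ~1e5 draws total over the 241-point grid
  for (k in seq_len(n_rep)) {
    noisy <- simulate_spectrum(pv, g, noise_model(sigma, seed = 10000 + k))$z
    rel <- c(rel, Mod(noisy / clean - 1))
    bias <- bias + mean(noisy / clean - 1)
  }
  expect_equal(mean(rel), sigma * sqrt(pi) / 2, tolerance = 0.01)
  expect_equal(sqrt(mean(rel^2)), sigma, tolerance = 0.01)
  # unbiasedness within Monte-Carlo error (se ~ sigma/sqrt(N))
  expect_lt(Mod(bias / n_rep), 4 * sigma / sqrt(n_rep * length(clean)))
})

test_that("sample_params respects bounds and spans the ranges", {
  for (mid in c("cole", "stem")) {
    sp <- model_spec(mid)
    draws <- t(vapply(seq_len(400),
                      function(i) sample_params(sp, seed = i)$values,
                      numeric(length(sp$param_names))))
    expect_true(all(t(draws) >= sp$lower & t(draws) <= sp$upper))
    is_order <- sp$units == "-"
    expect_true(all(draws[, is_order] >= 0.05))
    span <- apply(draws, 2, max) - apply(draws, 2, min)
    expect_true(all(span > 0.5 * (sp$upper - pmax(sp$lower,
                                                  is_order * 0.05))))
  }
  # cole redraw guarantees a positive relaxation strength
  cole_draws <- vapply(seq_len(200), function(i) {
    v <- sample_params("cole", seed = 5000 + i)$values
    v[["R_o"]] > v[["R_inf"]]
  }, logical(1))
  expect_true(all(cole_draws))
})

test_that("noise model rejects a negative scale", {
  expect_error(noise_model(-0.1), "non-negative")
})
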