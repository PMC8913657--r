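sphere_bounds <- cbind(rep(-5, 4), rep(5, 4))

test_that("constant objective yields a flat convergence at its value", {
  for (alg in c("wca", "fpa", "cs", "cso")) {
    cfg <- optimizer_config(alg, n_agents = 10, n_iterations = 25,
                            n_runs = 1, seed = 2)
    res <- minimize(function(x) 7, sphere_bounds, cfg)
    expect_identical(res$best_objective, 7)
    expect_true(all(res$convergence == 7))
  }
})

test_that("all four algorithms make progress on the sphere and obey the contracts", {
  for (alg in c("wca", "fpa", "cs", "cso")) {
    cfg <- optimizer_config(alg, n_agents = 30, n_iterations = 150,
                            n_runs = 1, seed = 11)
    res <- minimize(function(x) sum(x^2), sphere_bounds, cfg)
    expect_lt(res$best_objective, 0.05)
    # elitism: non-increasing convergence ending at the best objective
    expect_true(all(diff(res$convergence) <= 0))
    expect_identical(res$best_objective,
                     res$convergence[length(res$convergence)])
    # clipping contract
    expect_true(all(res$best_params >= -5 & res$best_params <= 5))
  }
})

test_that("identical config and seed reproduce results bit-for-bit", {
  for (alg in c("wca", "fpa", "cs", "cso")) {
    cfg <- optimizer_config(alg, n_agents = 15, n_iterations = 40,
                            n_runs = 2, seed = 9)
    a <- multi_run(function(x) sum((x - 1)^2), sphere_bounds, cfg)
    b <- multi_run(function(x) sum((x - 1)^2), sphere_bounds, cfg)
    expect_identical(a$best$best_params, b$best$best_params)
    expect_identical(a$best$best_objective, b$best$best_objective)
    expect_identical(a$best$convergence, b$best$convergence)
  }
})

test_that("NaN objective values are quarantined, never returned as best", {
  # objective undefined on half the box
  holey <- function(x) if (x[1] > 0) NaN else sum(x^2)
  cfg <- optimizer_config("wca", n_agents = 20, n_iterations = 60,
                          n_runs = 1, seed = 4)
  res <- minimize(holey, sphere_bounds, cfg)
  expect_true(is.finite(res$best_objective))
  expect_lte(res$best_params[1], 0)
})

test_that("multi_run selects the minimum and breaks ties by run index", {
  cfg <- optimizer_config("fpa", n_agents = 8, n_iterations = 10,
                          n_runs = 3, seed = 30)
  flat <- multi_run(function(x) 7, sphere_bounds, cfg)
  expect_identical(vapply(flat$runs, function(r) r$best_objective,
                          numeric(1)), rep(7, 3))
  expect_identical(flat$best$run_index, 0L)
  expect_identical(vapply(flat$runs, function(r) r$seed, integer(1)),
                   c(30L, 31L, 32L))
  sph <- multi_run(function(x) sum(x^2), sphere_bounds,
                   optimizer_config("cs", n_agents = 12, n_iterations = 30,
                                    n_runs = 5, seed = 77))
  vals <- vapply(sph$runs, function(r) r$best_objective, numeric(1))
  expect_identical(sph$best$best_objective, min(vals))
})

test_that("more iterations do not worsen the cole recovery (scaling sanity)", {
  truth <- reference_params("cole", "marjoram_5cm")
  spec <- simulate_spectrum(truth, coarse_grid())
  med <- function(iters) {
    vals <- vapply(1:5, function(s) {
      cfg <- optimizer_config("wca", n_agents = 20, n_iterations = iters,
                              n_runs = 1, seed = 40 + s)
      fit_model(spec, "cole", cfg)$best_objective
    }, numeric(1))
    stats::median(vals)
  }
  expect_lte(med(150), med(30))
})

test_that("fit_model returns in-bounds parameters and a consistent objective", {
  truth <- reference_params("cole", "lavandula_5cm")
  spec <- simulate_spectrum(truth, coarse_grid(), noise_model(0.01, seed = 2))
  cfg <- optimizer_config("cs", n_agents = 20, n_iterations = 150,
                          n_runs = 2, seed = 3)
  fit <- fit_model(spec, "cole", cfg)
  expect_s3_class(fit$best_params, "param_vector")
  expect_equal(objective(fit$best_params, spec)$value, fit$best_objective,
               tolerance = 1e-12)
  # log-scale variant also returns valid in-bounds parameters
  fit_log <- fit_model(spec, "cole", cfg, log_scale = TRUE)
  expect_s3_class(fit_log$best_params, "param_vector")
  expect_equal(objective(fit_log$best_params, spec)$value,
               fit_log$best_objective, tolerance = 1e-6)
})

test_that("configuration validation rejects degenerate protocols and bounds", {
  expect_error(optimizer_config("wca", n_agents = 1), "n_agents")
  expect_error(optimizer_config("wca", n_iterations = 0), "n_iterations")
  expect_error(optimizer_config("nope"), "arg")
  cfg <- optimizer_config("wca", n_agents = 5, n_iterations = 5, n_runs = 1)
  expect_error(minimize(function(x) 1, cbind(c(0, 0), c(1, 0)), cfg),
               "lower < upper")
  expect_error(minimize(function(x) 1, cbind(0, Inf), cfg), "finite")
})
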