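test_that("CPE impedance has constant phase and the stated magnitudes", {
  # ideal 1 uF capacitor at f where omega*C = 1e-3 S
  z <- cpe_impedance(cpe(1e-6, 1), f1(159.1549431))$z
  expect_lt(Mod(z - (0 - 1000i)), 1e-6 * 1000)
  # order-0 CPE is the resistor 1/c
  z0 <- cpe_impedance(cpe(0.5, 0), coarse_grid())$z
  expect_true(all(Mod(z0 - 2) < 1e-12))
  # half-order at omega = 1: 1/j^0.5 = exp(-j*pi/4)
  zh <- cpe_impedance(cpe(1, 0.5), f1(1 / (2 * pi)))$z
  expect_lt(Mod(zh - complex(real = sqrt(0.5), imaginary = -sqrt(0.5))),
            1e-9)
  # phase is -order*pi/2 at every frequency
  for (ord in c(0.2, 0.65, 1)) {
    ph <- Arg(cpe_impedance(cpe(3.3e-9, ord), std_grid())$z)
    expect_lt(max(abs(ph + ord * pi / 2)), 1e-12)
  }
  expect_error(cpe(-1, 0.5), "positive")
  expect_error(cpe(1e-6, 1.2), "order")
})

test_that("cole Debye case and limits are exact", {
  z <- cole_impedance(debye_params(), f1(debye_freq()))$z
  expect_lt(Mod(z - (50000 - 50000i)) / Mod(z), 1e-9)
  # oracle agrees on the same closed form
  zo <- circuit_oracle_impedance(debye_params(), f1(debye_freq()),
                                 model_id = "cole")$z
  expect_lt(Mod(z - zo) / Mod(z), 1e-12)
  # s -> 0 gives R_o
  v <- reference_params("cole", "salvia_10cm")
  expect_lt(abs(Mod(cole_impedance(v, f1(1e-9))$z) / v$values[["R_o"]] - 1),
            1e-4)
  expect_error(cole_impedance(c(0.7, 2e5, 1e5, 1e-9), coarse_grid()),
               "R_o > R_inf")
})

test_that("frozen spot values match the topology oracle evaluation", {
  # values computed once via circuit_oracle_impedance and frozen
  cases <- list(
    list("cole", "marjoram_5cm", 1e3, 170290.9347 - 35214.43448i),
    list("double_cole", "salvia_5cm", 100, 437769.6132 - 35968.93634i),
    list("double_shell", "marjoram_10cm", 1e3, 603291.6249 - 272467.9724i))
  for (cc in cases) {
    pv <- reference_params(cc[[1]], cc[[2]])
    z <- model_impedance(cc[[1]], pv, f1(cc[[3]]))$z
    expect_lt(Mod(z - cc[[4]]) / Mod(cc[[4]]), 1e-9)
  }
})

test_that("double_cole reduces to cole when the second section is removed", {
  g <- std_grid()
  v <- c(alpha = 0.71, beta = 1, R_inf = 4.2e3, R_1 = 3.1e5, R_2 = 0,
         C_alpha = 2.4e-9, C_beta = 1e-9)
  # R_2 = 0 kills the beta section in the rational form
  z2 <- stemfit:::.z_eval("double_cole", unname(v), g$frequencies)
  z1 <- cole_impedance(c(0.71, 4.2e3, 4.2e3 + 3.1e5, 2.4e-9), g)$z
  expect_lt(rel_dev(z2, z1), 1e-12)
})

test_that("rational forms agree with the admittance oracle across models", {
  g <- std_grid()
  for (mid in model_ids()) {
    for (i in 1:20) {
      pv <- sample_params(mid, seed = 1000 + i)
      zr <- model_impedance(mid, pv, g)$z
      zo <- circuit_oracle_impedance(pv, g)$z
      expect_lt(rel_dev(zr, zo), 1e-9)
    }
  }
})

test_that("oracle open-branch convention: all-capacitances-zero stem is R_o", {
  g <- coarse_grid()
  p <- stats::setNames(c(0.5, 0.5, 0.5, 0.5, 0.5, 7.7e4, 1e3, 1e3, 1e3, 1e3,
                         0, 0, 0, 0, 0), model_spec("stem")$param_names)
  z <- circuit_oracle_impedance(p, g, model_id = "stem")$z
  expect_true(all(Mod(z - 7.7e4) < 1e-6))
  # the strict rational-form evaluator rejects c = 0
  expect_error(stem_impedance(p, g), "positive")
})

test_that("stem limits: R_o at DC, short at infinite frequency", {
  pv <- reference_params("stem", "synthetic_a")
  z_lo <- stem_impedance(pv, f1(1e-9))$z
  expect_lt(abs(Mod(z_lo) / pv$values[["R_o"]] - 1), 1e-4)
  z_hi <- stem_impedance(pv, f1(1e12))$z
  expect_lt(Mod(z_hi) / pv$values[["R_o"]], 1e-4)
})

test_that("simplified_stem matches an integer-order nodal analysis", {
  g <- std_grid()
  v <- c(alpha = 1, beta = 1, gamma = 1, R_o = 1e3, R_1 = 1e4, R_2 = 1e4,
         C_alpha = 1e-9, C_beta = 1e-9, C_gamma = 1e-9)
  z <- simplified_stem_impedance(v, g)$z
  # independent route: ideal capacitors, plain nodal admittance sum
  jw <- 2i * pi * g$frequencies
  y <- 1 / (1e4 + 1 / (jw * 1e-9)) + 1 / (1e4 + 1 / (jw * 1e-9)) + jw * 1e-9
  expect_lt(rel_dev(z, 1e3 + 1 / y), 1e-12)
})

test_that("passivity and |z| monotonicity hold on sampled parameters", {
  g <- std_grid()
  for (mid in model_ids()) {
    for (i in 1:8) {
      pv <- sample_params(mid, seed = 7000 + i)
      z <- model_impedance(mid, pv, g)$z
      expect_true(all(Re(z) > 0))
      expect_true(all(Im(z) <= 0))
      if (mid %in% c("cole", "double_cole")) {
        expect_true(all(diff(Mod(z)) <= 1e-12 * Mod(z)[-1]))
      }
    }
  }
})

test_that("model_spec registry matches the published search boundaries", {
  counts <- c(cole = 4L, double_cole = 7L, double_shell = 7L, stem = 15L,
              simplified_stem = 9L)
  for (mid in model_ids()) {
    sp <- model_spec(mid)
    expect_length(sp$param_names, counts[[mid]])
    is_order <- sp$units == "-"
    expect_true(all(sp$lower == 0))
    expect_true(all(sp$upper[is_order] == 1))
  }
  expect_identical(unname(model_spec("cole")$upper[["R_o"]]), 80e6)
  expect_identical(unname(model_spec("stem")$upper[["R_1"]]), 1e9)
  expect_identical(unname(model_spec("double_shell")$upper[["C_alpha"]]), 3e-6)
  expect_identical(unname(model_spec("simplified_stem")$upper[["R_o"]]), 100e6)
})

test_that("param_vector enforces bounds, order, and names", {
  sp <- model_spec("cole")
  expect_error(param_vector(sp, c(1.2, 0, 1e5, 1e-9)), "outside bounds")
  expect_error(param_vector(sp, c(0.5, 0, 1e5)), "expects 4")
  named <- param_vector(sp, c(C_alpha = 1e-9, alpha = 0.5, R_o = 1e5,
                              R_inf = 10))
  expect_identical(names(named$values), sp$param_names)
  expect_identical(unname(named$values[["C_alpha"]]), 1e-9)
})

test_that("all shipped presets are valid in-bounds parameter vectors", {
  for (mid in model_ids()) {
    for (s in preset_names(mid)) {
      pv <- reference_params(mid, s)
      expect_s3_class(pv, "param_vector")
      expect_true(all(pv$values >= pv$spec$lower & pv$values <= pv$spec$upper))
    }
  }
  expect_length(preset_names("cole"), 6)
  expect_error(reference_params("stem", "marjoram_5cm"), "no preset")
})
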