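test_that("r_squared matches hand arithmetic and handles edge cases", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(2, 4, 9)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  # SSres = 1, SStot = 2
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_true(is.na(r_squared(c(2, 2, 2), c(1, 2, 3))))
  expect_error(r_squared(1:3, 1:4))
})

truth_params <- list(
  zero_order = c(C0 = 1, K0 = 0.5),
  first_order = c(Cd = 1, K1 = 0.12),
  second_order = c(Cd = 1, K2 = 0.05),
  higuchi = c(KH = 0.18),
  hixson_crowell = c(Cd = 1, KHC = 0.01),
  weibull = c(Cs = 0.95, T = 0, a = 4, b = 0.8),
  power_law = c(K = 0.5, n = 0.3)
)

test_that("noiseless round trip recovers every model's parameters", {
  for (m in names(truth_params)) {
    g <- generate_release_curve(m, truth_params[[m]])
    f <- fit_model(g$curve, m)
    expect_true(f$converged, label = sprintf("%s converged", m))
    expect_lt(max(rel_err(f$estimates, truth_params[[m]][names(f$estimates)])),
              1e-6)
    expect_gte(f$r_squared, 1 - 1e-10)
  }
})

test_that("noisy power-law estimates agree with an exhaustive grid search", {
  g <- generate_release_curve("power_law", c(K = 0.5, n = 0.3),
                              noise_sd = 0.01, seed = 7)
  f <- fit_model(g$curve, "power_law")
  grid <- grid_power_law_oracle(g$curve$times, g$curve$values)
  expect_lt(abs(f$estimates["K"] - grid["K"]), 2e-3)   # grid resolution 1e-3
  expect_lt(abs(f$estimates["n"] - grid["n"]), 2e-3)
})

test_that("linearized fitting reproduces classical regressions", {
  # power law: log C vs log t is exact for noiseless data
  g <- generate_release_curve("power_law", c(K = 0.5, n = 0.3))
  f <- fit_model(g$curve, "power_law", scale = "linearized")
  expect_equal(unname(f$estimates["K"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(f$estimates["n"]), 0.3, tolerance = 1e-8)
  expect_equal(f$fit_scale, "linearized")
  # zero order: plain regression line
  g2 <- generate_release_curve("zero_order", c(C0 = 1, K0 = 0.5))
  f2 <- fit_model(g2$curve, "zero_order", scale = "linearized")
  expect_equal(unname(f2$estimates), c(1, 0.5), tolerance = 1e-10)
  expect_equal(f2$r_squared, 1)
})

test_that("zero-order C0 can be pinned at zero", {
  g <- generate_release_curve("zero_order", c(C0 = 0, K0 = 0.4))
  f <- fit_model(g$curve, "zero_order", fix_c0_zero = TRUE)
  expect_identical(unname(f$estimates["C0"]), 0)
  expect_equal(unname(f$estimates["K0"]), 0.4, tolerance = 1e-8)
})

test_that("degenerate all-equal data is flagged with an undefined R^2", {
  curve <- release_curve(c(1, 3, 5), c(0.5, 0.5, 0.5))
  f <- fit_model(curve, "zero_order")
  expect_true(f$degenerate)
  expect_true(is.na(f$r_squared))
})

test_that("fraction-scale models refuse amount curves without C_inf", {
  curve <- release_curve(c(1, 3, 5, 10), c(10, 20, 25, 28),
                         value_kind = "amount")
  expect_error(fit_model(curve, "power_law"), "c_inf")
  curve2 <- release_curve(c(1, 3, 5, 10), c(10, 20, 25, 28),
                          value_kind = "amount", c_inf = 30)
  expect_true(fit_model(curve2, "power_law")$converged)
})

test_that("fit_all ranks the generating model first on clean data", {
  g <- generate_release_curve("power_law", c(K = 0.5, n = 0.3))
  fits <- fit_all(g$curve)
  expect_equal(fits[[1]]$model, "power_law")
  expect_length(fits, 7L)
  # linear data: zero order wins with R^2 = 1
  lin <- generate_release_curve("zero_order", c(C0 = 0.05, K0 = 0.02))
  expect_equal(fit_all(lin$curve)[[1]]$model, "zero_order")
})

test_that("fit_all handles a step curve: a sharp-sigmoid Weibull beats slow models", {
  # near-constant after an initial jump; the Weibull shape parameter runs high
  curve <- release_curve(c(1, 3, 5, 10, 20, 30),
                         c(0.02, 0.04, 0.9, 0.9, 0.9, 0.9))
  fits <- fit_all(curve)
  wb <- Filter(function(f) f$model == "weibull", fits)[[1]]
  expect_true(wb$converged)
  expect_gt(unname(wb$estimates["b"]), 1)   # sigmoid regime
  slow <- Filter(function(f) f$model %in% c("zero_order", "higuchi"), fits)
  expect_true(all(wb$r_squared > vapply(slow, `[[`, numeric(1), "r_squared")))
})

test_that("fit_all ordering is invariant under permutation of input rows", {
  g <- generate_release_curve("power_law", c(K = 0.6, n = 0.2),
                              noise_sd = 0.01, seed = 3)
  perm <- c(4, 1, 6, 2, 5, 3)
  curve_perm <- release_curve(g$curve$times[perm], g$curve$values[perm],
                              value_kind = g$curve$value_kind,
                              c_inf = g$curve$c_inf)
  r1 <- vapply(fit_all(g$curve), `[[`, character(1), "model")
  r2 <- vapply(fit_all(curve_perm), `[[`, character(1), "model")
  expect_identical(r1, r2)
})

test_that("non-convergent fits are kept, flagged and ranked last", {
  curve <- release_curve(c(1, 3, 5, 10), c(10, 20, 25, 28),
                         value_kind = "amount")  # no c_inf
  fits <- fit_all(curve)
  conv <- vapply(fits, `[[`, logical(1), "converged")
  expect_false(all(conv))            # power law and Weibull cannot be fitted
  expect_true(all(which(!conv) > max(which(conv))))
})

test_that("mechanism calls come from the fitted exponents", {
  g <- generate_release_curve("power_law", c(K = 0.7379, n = 0.088),
                              noise_sd = 0.005, seed = 1)
  mech <- mechanism_calls(fit_all(g$curve))
  expect_equal(mech$power_law$label, "fickian")
  expect_lt(abs(mech$power_law$statistic_value - 0.088), 0.05)
})
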