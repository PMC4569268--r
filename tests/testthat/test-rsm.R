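test_that("noiseless synthetic responses are recovered exactly", {
  truth <- toy_quadratic()
  sim <- simulate_ccd(cod_factors(), truth, noise_sd = 0, seed = 5)
  fit <- fit_quadratic(sim)
  cf_true <- c(truth$intercept, truth$linear, truth$interaction,
               truth$quadratic)
  cf_fit <- c(fit$intercept, fit$linear, fit$interaction, fit$quadratic)
  expect_lt(max(abs(cf_fit - cf_true) / pmax(abs(cf_true), 1e-12)), 1e-8)
  expect_gt(fit$diagnostics$r_squared, 1 - 1e-12)
})

test_that("prediction evaluates the full second-order polynomial", {
  factors <- cod_factors()
  # constant model: only the intercept
  m <- quadratic_model(4.2, rep(0, 5), rep(0, 10), rep(0, 5),
                       basis = "uncoded", factors = factors)
  set.seed(2)
  X <- matrix(runif(25, 0, 1.5), 5, 5)
  expect_equal(predict(m, X), rep(4.2, 5))
  # manual evaluation of an arbitrary model at an arbitrary point
  m2 <- toy_quadratic(seed = 9)
  x <- c(0.4, 1.1, 0.8, 0.03, 0.2)
  inter <- combn(5, 2)
  manual <- m2$intercept + sum(m2$linear * x) +
    sum(m2$interaction * x[inter[1, ]] * x[inter[2, ]]) +
    sum(m2$quadratic * x^2)
  expect_equal(predict(m2, x), manual, tolerance = 1e-12)
  expect_error(predict(m2, c(1, 2, 3)), "length|columns")
})

test_that("fitting in coded basis is prediction-equivalent to uncoded", {
  d <- cod_design()
  fu <- fit_quadratic(d, basis = "uncoded")
  fc <- fit_quadratic(d, basis = "coded")
  X <- design_matrix(d)
  Xc <- design_matrix(d, coded = TRUE)
  expect_equal(predict(fu, X), predict(fc, Xc), tolerance = 1e-9)
  # explicit basis conversion reproduces predictions at all 36 compositions
  fc2u <- convert_basis(fc, "uncoded")
  expect_lt(max(abs(predict(fc2u, X) - predict(fc, Xc))), 1e-10)
  fu2c <- convert_basis(fu, "coded")
  expect_lt(max(abs(predict(fu2c, Xc) - predict(fu, X))), 1e-10)
  expect_equal(fu$diagnostics$r_squared, fc$diagnostics$r_squared,
               tolerance = 1e-10)
})

test_that("fit diagnostics satisfy their identities", {
  d <- cod_design()
  fit <- fit_quadratic(d)
  dg <- fit$diagnostics
  expect_equal(dg$r, sqrt(dg$r_squared), tolerance = 1e-12)
  expect_lt(abs(sum(dg$residuals)), 1e-10)
  expect_equal(dg$dof_model, 20)
  expect_equal(dg$dof_error, 15)
  # overall F via its definition
  sse <- sum(dg$residuals^2)
  sst <- sum((d$observed - mean(d$observed))^2)
  expect_equal(dg$f_overall, ((sst - sse) / 20) / (sse / 15),
               tolerance = 1e-10)
})

test_that("per-term ANOVA matches direct formulas and a quadrature oracle", {
  d <- cod_design()
  fit <- fit_quadratic(d)
  tab <- anova_table(fit)
  expect_equal(nrow(tab), 21)
  expect_true(all(tab$f_value >= 0))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_equal(tab$sum_sq, tab$mean_sq)  # all terms have 1 df
  # p-values against numerical integration of the F(1, 15) density
  for (i in c(1, 5, 17, 21)) {
    pq <- integrate(function(x) df(x, 1, 15), tab$f_value[i], Inf,
                    rel.tol = 1e-10)$value
    expect_equal(tab$p_value[i], pq, tolerance = 1e-6)
  }
  # a coefficient that is exactly zero in the truth gives SS ~ 0 on
  # noiseless data
  truth <- toy_quadratic(seed = 3)
  truth$interaction[] <- 0
  sim <- simulate_ccd(cod_factors(), truth, noise_sd = 0, seed = 8)
  ftab <- anova_table(fit_quadratic(sim))
  int_rows <- grepl(":", ftab$term)
  expect_lt(max(ftab$sum_sq[int_rows]), 1e-12)
})

test_that("rank-deficient designs raise a singular-design error", {
  factors <- cod_factors()
  des <- generate_ccd(factors, n_center = 10)
  des$observed <- rnorm(nrow(des))
  # collapse two factors onto each other: model matrix loses rank
  des$glycerol <- des$soybean
  expect_error(fit_quadratic(des), "singular|at least")
  des2 <- generate_ccd(factors, n_center = 10)
  expect_error(fit_quadratic(des2), "responses")
})

test_that("surface slices evaluate the model over the star box", {
  # clip-free factors put the centre exactly on the odd-sized lattice
  m <- cod_rsm_model()
  m$factors <- lapply(cod_factors(), function(f) { f$low_clip <- -Inf; f })
  sl <- surface_slice(m, "soybean", "nacl", grid_n = 21)
  expect_equal(nrow(sl), 21^2)
  ctr <- sl[abs(sl$soybean - 0.75) < 1e-9 & abs(sl$nacl - 0.15) < 1e-9, ]
  expect_equal(nrow(ctr), 1L)
  expect_equal(ctr$predicted, predict(m, c(0.75, 0.75, 0.75, 0.025, 0.15)),
               tolerance = 1e-12)
  # every lattice node agrees with direct model evaluation
  i <- c(1, 100, 441)
  comp <- cbind(sl$soybean[i], 0.75, 0.75, 0.025, sl$nacl[i])
  expect_equal(sl$predicted[i], predict(m, comp), tolerance = 1e-12)
  # constant model gives a flat grid
  mc <- quadratic_model(2.5, rep(0, 5), rep(0, 10), rep(0, 5),
                        basis = "uncoded", factors = cod_factors())
  expect_equal(unique(surface_slice(mc, 1, 2, grid_n = 5)$predicted), 2.5)
  expect_error(surface_slice(m, 2, 2), "differ")
})

test_that("noisy-data coefficient recovery is unbiased at the 2-SE level", {
  truth <- toy_quadratic(seed = 21)
  bench <- recovery_benchmark(cod_factors(), truth, noise_sd = 0.2,
                              n_reps = 200, seed = 100)
  cf <- bench$coefficients
  ok <- abs(cf$bias) <= 2 * cf$mc_se
  expect_gte(sum(ok), ceiling(0.95 * nrow(cf)) - 1)
})
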