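test_that("tansig is the hyperbolic tangent", {
  z <- c(-2, -0.5, 0, 1, 3)
  expect_equal(tansig(z), tanh(z), tolerance = 1e-12)
})

test_that("initialization is seeded and shaped correctly", {
  a <- nn_init(15, seed = 4)
  b <- nn_init(15, seed = 4)
  c <- nn_init(15, seed = 5)
  expect_identical(a$IW, b$IW)
  expect_identical(a$LW, b$LW)
  expect_false(identical(a$IW, c$IW))
  expect_equal(dim(a$IW), c(15L, 5L))
  expect_length(a$LW, 15)
  expect_length(a$b, 15)
  expect_error(nn_init(0, seed = 1), ">= 1")
})

test_that("forward pass matches a hand-computed single-unit network", {
  m <- random_network(n_hidden = 1L)
  m$IW[1, ] <- c(1, 0, 0, 0, 0)
  m$b <- 0; m$LW <- 1; m$a <- 0
  x <- c(0.5, -0.3, 0.9, 0, -1)
  expect_equal(nn_forward(m, x), tanh(0.5), tolerance = 1e-12)
  # constant network returns its constant everywhere
  k <- constant_network(2.75)
  set.seed(1)
  X <- matrix(runif(20, -1, 1), 4, 5)
  expect_equal(nn_forward(k, X), rep(2.75, 4))
  # unfitted network refuses to predict
  expect_error(nn_forward(nn_init(3, 1), rep(0, 5)), "normalization|train")
})

test_that("Levenberg-Marquardt fits noiseless self-generated data to near zero SSE", {
  truth <- random_network(n_hidden = 3L, seed = 7)
  factors <- toy_cube_factors()
  set.seed(13)
  X <- matrix(runif(250, -1, 1), 50, 5)
  y <- nn_forward(truth, X)
  des <- design_from_matrix(X, factors, observed = y)
  res <- nn_train(nn_init(3, seed = 2, init_scale = 0.5), des,
                  nn_config(algorithm = "lm", max_epochs = 400,
                            goal_sse = 1e-6))
  expect_lt(res$report$final_sse, 1e-4)
})

test_that("accepted LM steps never increase the training SSE", {
  d <- cod_design()
  res <- nn_train(nn_init(15, seed = 3), d,
                  nn_config(algorithm = "lm", max_epochs = 100))
  tr <- res$report$trace
  acc <- tr$sse[c(TRUE, tr$accepted[-1])]
  expect_true(all(diff(tr$sse) <= 1e-12))
  expect_true(nrow(tr) > 1)
})

test_that("training is a no-op when targets already match the network", {
  factors <- toy_cube_factors()
  set.seed(31)
  X <- matrix(runif(50, -1, 1), 10, 5)
  m2 <- random_network(3, seed = 11)
  des <- design_from_matrix(X, factors, observed = nn_forward(m2, X))
  res <- nn_train(m2, des, nn_config(algorithm = "lm"))
  expect_lt(res$report$final_sse, 1e-20)
  expect_equal(res$report$stop_reason, "goal_sse")
  expect_equal(res$report$epochs, 0)
})

test_that("training is bitwise reproducible under a fixed seed", {
  d <- cod_design()
  cfg <- nn_config(algorithm = "lm", max_epochs = 50)
  r1 <- nn_train(nn_init(5, seed = 8), d, cfg)
  r2 <- nn_train(nn_init(5, seed = 8), d, cfg)
  expect_identical(r1$model, r2$model)
  expect_identical(r1$report$trace, r2$report$trace)
})

test_that("response scaling propagates exactly through training", {
  truth <- toy_quadratic(seed = 15)
  sim <- simulate_ccd(cod_factors(), truth, noise_sd = 0.1, seed = 6)
  cfg <- nn_config(algorithm = "lm", max_epochs = 40)
  r1 <- nn_train(nn_init(4, seed = 1), sim, cfg)
  sim10 <- sim
  sim10$observed <- sim$observed * 10
  r2 <- nn_train(nn_init(4, seed = 1), sim10, cfg)
  X <- design_matrix(sim)
  expect_equal(nn_forward(r2$model, X), 10 * nn_forward(r1$model, X),
               tolerance = 1e-8)
})

test_that("gradient-descent variants run and adapt their rate", {
  d <- cod_design()
  gd <- nn_train(nn_init(5, seed = 2), d,
                 nn_config(algorithm = "gd", max_epochs = 50,
                           learning_rate = 0.005))
  expect_true(all(is.finite(gd$report$trace$sse)))
  gda <- nn_train(nn_init(5, seed = 2), d,
                  nn_config(algorithm = "gda", max_epochs = 50,
                            learning_rate = 0.005))
  # gda rejects worsening steps, so its SSE trace is non-increasing
  expect_true(all(diff(gda$report$trace$sse) <= 1e-12))
  # diverging rate raises a divergence error
  expect_error(
    nn_train(nn_init(5, seed = 2), d,
             nn_config(algorithm = "gd", max_epochs = 300,
                       learning_rate = 1, monitor_split = "none")),
    "diverged")
})

test_that("row order does not affect per-row predictions", {
  d <- cod_design()
  res <- nn_train(nn_init(6, seed = 9), d, nn_config(max_epochs = 30))
  p <- nn_predict(res$model, d)
  perm <- sample(nrow(d))
  expect_equal(nn_predict(res$model, d[perm, ]), p[perm], tolerance = 1e-12)
})

test_that("networks survive a JSON round trip", {
  d <- cod_design()
  res <- nn_train(nn_init(4, seed = 10), d, nn_config(max_epochs = 20))
  path <- withr::local_tempfile(fileext = ".json")
  nn_to_json(res$model, path)
  back <- nn_from_json(path)
  X <- design_matrix(d)
  expect_equal(nn_forward(back, X), nn_forward(res$model, X),
               tolerance = 1e-12)
})
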