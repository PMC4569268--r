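test_that("rank scaling follows the 1/sqrt(rank) rule with input-order ties", {
  expect_equal(rank_scale(c(5, 2, 9)), c(1 / sqrt(2), 1 / sqrt(3), 1))
  # all-equal raw values rank in input order
  expect_equal(rank_scale(c(1, 1, 1)), 1 / sqrt(1:3))
  # monotone: higher raw fitness never scales lower
  set.seed(4)
  for (i in 1:10) {
    raw <- runif(20)
    sc <- rank_scale(raw)
    o <- order(raw, decreasing = TRUE)
    expect_true(all(diff(sc[o]) <= 0))
  }
})

test_that("stochastic universal sampling has zero variance at integer expectations", {
  for (s in 1:20) {
    set.seed(s)
    picks <- sus_select(c(3, 1), 4)
    expect_equal(as.vector(table(factor(picks, levels = 1:2))), c(3, 1))
  }
  # uniform fitness, n_picks = population: every individual exactly once
  set.seed(1)
  picks <- sus_select(rep(2, 10), 10)
  expect_equal(sort(picks), 1:10)
  expect_error(sus_select(c(0, 0), 2), "degenerate")
  expect_error(sus_select(c(-1, 2), 2), "non-negative")
})

test_that("SUS pick frequencies match rank-scaled expectations", {
  n <- 50
  scaled <- 1 / sqrt(1:n)
  picks_per_run <- n
  reps <- 400
  counts <- numeric(n)
  for (s in 1:reps) {
    set.seed(s)
    p <- sus_select(scaled, picks_per_run)
    counts <- counts + tabulate(p, n)
  }
  expected <- reps * picks_per_run * scaled / sum(scaled)
  # multinomial-style bound; SUS variance is below multinomial variance
  sd3 <- 3 * sqrt(expected * (1 - scaled / sum(scaled)))
  expect_true(all(abs(counts - expected) <= pmax(sd3, 3)))
})

test_that("scattered crossover inherits each gene from one parent", {
  set.seed(2)
  a <- rep(0, 5); b <- rep(1, 5)
  child <- scattered_crossover(a, b)
  expect_true(all(child %in% c(0, 1)))
  expect_equal(scattered_crossover(a, a), a)
  expect_error(scattered_crossover(1:3, 1:4), "equal length")
  # per-gene inheritance is a fair coin
  set.seed(3)
  hits <- replicate(10000, scattered_crossover(a, b))
  frac_b <- rowMeans(hits)
  expect_true(all(abs(frac_b - 0.5) < 0.02))
})

test_that("the GA finds a known analytic optimum", {
  f <- function(p) -(p[1] - 0.3)^2 - (p[2] - 0.7)^2
  run <- ga_optimize(f, cbind(c(0, 0), c(1, 1)), ga_config(seed = 1))
  expect_lt(max(abs(run$best_point - c(0.3, 0.7))), 0.02)
  expect_gt(run$best_fitness, -1e-3)
})

test_that("elitism makes the best-fitness trace non-decreasing", {
  m <- cod_rsm_model()
  bounds <- design_bounds(cod_factors())
  for (s in 1:3) {
    run <- ga_optimize(function(p) predict(m, p), bounds,
                       ga_config(seed = s, generations = 60,
                                 population_size = 80))
    expect_true(all(diff(run$trace$best) >= -1e-12))
    # all returned points respect the bounds exactly
    expect_true(all(run$best_point >= bounds[, 1] - 1e-15))
    expect_true(all(run$best_point <= bounds[, 2] + 1e-15))
  }
})

test_that("GA runs are deterministic under a fixed seed", {
  m <- cod_rsm_model()
  bounds <- design_bounds(cod_factors())
  cfg <- ga_config(seed = 7, generations = 30, population_size = 60)
  r1 <- ga_optimize(function(p) predict(m, p), bounds, cfg)
  r2 <- ga_optimize(function(p) predict(m, p), bounds, cfg)
  expect_identical(r1$best_point, r2$best_point)
  expect_identical(r1$trace, r2$trace)
})

test_that("GA matches a brute-force lattice oracle on quadratic fitness", {
  # moderate lattice here; the full-resolution check lives in the
  # acceptance suite
  m <- toy_quadratic(seed = 30)
  bounds <- design_bounds(cod_factors())
  oracle <- grid_search(m, bounds, points_per_axis = 11)
  run <- ga_optimize(function(p) predict(m, p), bounds,
                     ga_config(seed = 2))
  expect_gte(run$best_fitness,
             oracle$best_fitness - 0.005 * abs(oracle$best_fitness))
})

test_that("invalid configurations and fitness values are rejected", {
  expect_error(ga_optimize(function(p) 1, cbind(c(0, 1), c(1, 0))),
               "infeasible")
  expect_error(
    ga_optimize(function(p) if (p[1] > 0.5) NaN else 1,
                cbind(0, 1), ga_config(population_size = 20,
                                       generations = 2, seed = 1)),
    "non-finite")
  expect_error(ga_config(elite_count = 10, population_size = 10))
  expect_error(ga_config(crossover_fraction = 1.5))
})

test_that("crossover-only emulation and mutation remainder both fill the population", {
  f <- function(p) sum(p)
  # strict emulation: fraction 1, no mutation
  r1 <- ga_optimize(f, cbind(c(0, 0), c(1, 1)),
                    ga_config(seed = 3, population_size = 20,
                              generations = 5, mutation_rate = 0))
  expect_equal(nrow(r1$trace), 6)
  # crossover fraction 0: all non-elite children are mutants
  r2 <- ga_optimize(f, cbind(c(0, 0), c(1, 1)),
                    ga_config(seed = 3, population_size = 20,
                              generations = 5, crossover_fraction = 0))
  expect_true(all(is.finite(r2$trace$best)))
})
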