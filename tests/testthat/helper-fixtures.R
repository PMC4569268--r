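# Shared builders for the test suite. Everything is constructed in code;
# the only file fixture is the bundled CCD table shipped with the package.

toy_factors <- function(k = 2L) {
  f <- lapply(seq_len(k), function(i) {
    factor_spec(paste0("f", i), center = 1, half_range = 0.5, alpha = 1.5)
  })
  names(f) <- vapply(f, `[[`, character(1), "name")
  f
}

# arbitrary full 21-coefficient quadratic over the cholesterol-oxidase
# factors, used as a known truth for recovery tests
toy_quadratic <- function(factors = cod_factors(), seed = 42L) {
  set.seed(seed)
  k <- length(factors)
  quadratic_model(
    intercept = stats::runif(1, 1, 3),
    linear = stats::runif(k, -2, 2),
    interaction = stats::runif(k * (k - 1L) / 2L, -2, 2),
    quadratic = stats::runif(k, -2, 0),   # concave squares: interior-ish optimum
    basis = "uncoded", factors = factors
  )
}

# unit-cube factors for free-form network training sets
toy_cube_factors <- function(k = 5L) {
  f <- lapply(seq_len(k), function(i) factor_spec(paste0("x", i), 0, 1))
  names(f) <- paste0("x", seq_len(k))
  f
}

# constant-output network: all weights zero, output bias chosen so the
# unscaled output equals `value`; identity normalization on [-1, 1] inputs
constant_network <- function(value, n_hidden = 3L, n_inputs = 5L) {
  m <- nn_init(n_hidden, seed = 1L, n_inputs = n_inputs)
  m$IW[] <- 0; m$b[] <- 0; m$LW[] <- 0
  m$norm_in <- list(min = rep(-1, n_inputs), max = rep(1, n_inputs))
  m$norm_out <- list(min = value - 1, max = value + 1)
  m$a <- 0   # normalized output 0 maps to the midpoint = value
  m
}

# small ground-truth network with identity scalings over [-1, 1]
random_network <- function(n_hidden = 3L, n_inputs = 5L, seed = 7L) {
  m <- nn_init(n_hidden, seed = seed, n_inputs = n_inputs, init_scale = 1)
  m$norm_in <- list(min = rep(-1, n_inputs), max = rep(1, n_inputs))
  m$norm_out <- list(min = -1, max = 1)
  m
}
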