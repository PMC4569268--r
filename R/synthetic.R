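# Synthetic CCD datasets with known ground truth. The generator emulates
# the structure of the bundled experiment: a five-factor circumscribed CCD
# whose response surface is a known quadratic (or small network), with
# homoscedastic Gaussian measurement noise. The default noise level
# (sd 0.15 U/mL) matches the spread of the bundled dataset's ten
# centre-point replicates (observed 2.98-3.28 U/mL).

#' Simulate a CCD experiment from a known response surface
#'
#' Builds the design with [generate_ccd()], evaluates the ground-truth
#' model at each (uncoded) composition, adds i.i.d. Gaussian noise, and
#' assigns train/test/validation labels by a seeded random 4:1:1-style
#' partition.
#'
#' @param factors List of [factor_spec()]s.
#' @param truth A `quadratic_model` or fitted `neural_model` evaluated at
#'   uncoded compositions.
#' @param noise_sd Gaussian noise standard deviation (U/mL, >= 0).
#' @param n_center Centre replicates (default 10, as in the bundled
#'   design).
#' @param fraction Factorial fraction, see [generate_ccd()].
#' @param seed Integer seed (noise and split assignment).
#' @return A `ccd_design` with `observed` filled in and an attribute
#'   `truth` carrying the generating model.
#' @export
simulate_ccd <- function(factors, truth, noise_sd = 0.15, n_center = 10L,
                         fraction = "half", seed = 1L) {
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  design <- generate_ccd(factors, n_center = n_center, fraction = fraction)
  X <- design_matrix(design)
  mu <- if (inherits(truth, "neural_model")) nn_forward(truth, X)
        else predict(truth, X)
  set.seed(seed)
  design$observed <- mu + stats::rnorm(nrow(X), 0, noise_sd)
  design <- assign_splits(design, seed = seed + 1L)
  attr(design, "truth") <- truth
  design
}

#' Coefficient-recovery benchmark
#'
#' Repeats simulate -> fit (-> optionally GA-optimize) `n_reps` times and
#' summarizes how well the known quadratic truth is recovered: per-term
#' bias, RMSE and the Monte-Carlo standard error of the bias. When a
#' [ga_config()] is supplied, each replicate's fitted model is maximized
#' over `bounds` and the mean distance between the GA optimum and the
#' truth's grid-search optimum is reported.
#'
#' @param factors List of [factor_spec()]s.
#' @param truth A `quadratic_model` (ground truth).
#' @param noise_sd Noise level passed to [simulate_ccd()].
#' @param n_reps Number of replicates (>= 2).
#' @param seed Base seed; replicate `i` uses `seed + i`.
#' @param ga A [ga_config()] to also benchmark optimum recovery, or `NULL`
#'   (default) to benchmark coefficients only.
#' @param bounds Box for the GA and grid oracle (default: the factors'
#'   design box).
#' @param grid_n Oracle lattice resolution.
#' @return List: `coefficients` (data frame: term, truth, mean_estimate,
#'   bias, mc_se, rmse), and when `ga` is given `optimum` (mean/max
#'   distance of GA optima from the truth optimum, plus the truth optimum
#'   itself).
#' @export
recovery_benchmark <- function(factors, truth, noise_sd = 0.15, n_reps = 50L,
                               seed = 1L, ga = NULL, bounds = NULL,
                               grid_n = 21L) {
  if (!inherits(truth, "quadratic_model")) {
    stop("truth must be a quadratic_model", call. = FALSE)
  }
  if (n_reps < 2L) stop("n_reps must be >= 2", call. = FALSE)
  true_cf <- coef_vector(truth)
  est <- matrix(NA_real_, n_reps, length(true_cf),
                dimnames = list(NULL, names(true_cf)))
  opt_dist <- if (is.null(ga)) NULL else numeric(n_reps)
  if (!is.null(ga)) {
    if (is.null(bounds)) bounds <- design_bounds(factors)
    oracle <- grid_search(truth, bounds, points_per_axis = grid_n)
  }
  for (i in seq_len(n_reps)) {
    sim <- simulate_ccd(factors, truth, noise_sd = noise_sd,
                        seed = seed + i)
    fit <- fit_quadratic(sim, basis = truth$basis)
    est[i, ] <- coef_vector(fit)
    if (!is.null(ga)) {
      cfg <- ga
      cfg$seed <- seed + i
      run <- ga_optimize(function(p) predict(fit, p), bounds, cfg)
      opt_dist[i] <- sqrt(sum((run$best_point - oracle$best_point)^2))
    }
  }
  bias <- colMeans(est) - true_cf
  mc_se <- apply(est, 2L, stats::sd) / sqrt(n_reps)
  rmse <- sqrt(colMeans(sweep(est, 2L, true_cf)^2))
  out <- list(coefficients = data.frame(
    term = names(true_cf), truth = unname(true_cf),
    mean_estimate = unname(colMeans(est)), bias = unname(bias),
    mc_se = unname(mc_se), rmse = unname(rmse), row.names = NULL))
  if (!is.null(ga)) {
    out$optimum <- list(mean_distance = mean(opt_dist),
                        max_distance = max(opt_dist),
                        truth_optimum = oracle$best_point,
                        grid_resolution = oracle$resolution)
  }
  out
}
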