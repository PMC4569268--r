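# Real-coded generational GA for maximizing a fitted surrogate over box
# bounds. Operator set: rank-based fitness scaling (1/sqrt(rank)),
# stochastic universal sampling, elitism, scattered (uniform) crossover,
# Gaussian mutation clipped to bounds.

#' Genetic-algorithm configuration
#'
#' Defaults mirror a widely used configuration for surrogate maximization
#' over medium-composition boxes: population 200, elite count 2, crossover
#' fraction 1, 100 generations, stall limit 50. With crossover fraction 1
#' every non-elite child is a crossover offspring; a small per-gene
#' post-crossover mutation rate (default 0.01) keeps new alleles entering
#' the population so the search does not stagnate. Set `mutation_rate = 0`
#' for strict crossover-only emulation. Migration settings are recorded for
#' config fidelity but are no-ops for a single population.
#'
#' @param population_size Individuals per generation.
#' @param elite_count Best individuals copied unchanged each generation.
#' @param crossover_fraction Fraction of the non-elite offspring produced
#'   by crossover; the remainder are mutation-only children.
#' @param generations Generation budget.
#' @param stall_generations Stop after this many generations without
#'   best-fitness improvement exceeding `fitness_tol`.
#' @param fitness_tol Minimal improvement that resets the stall counter.
#' @param mutation_rate Per-gene probability of Gaussian mutation applied
#'   to crossover offspring.
#' @param mutation_sd_fraction Mutation standard deviation as a fraction of
#'   each variable's bound range.
#' @param seed Integer seed for the whole run.
#' @param migration_interval,migration_fraction Recorded, unused (single
#'   population).
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 200L, elite_count = 2L,
                      crossover_fraction = 1, generations = 100L,
                      stall_generations = 50L, fitness_tol = 1e-6,
                      mutation_rate = 0.01, mutation_sd_fraction = 0.1,
                      seed = 1L, migration_interval = 20L,
                      migration_fraction = 0.2) {
  stopifnot(population_size >= 2, elite_count >= 0,
            elite_count < population_size,
            crossover_fraction >= 0, crossover_fraction <= 1,
            generations >= 1, mutation_rate >= 0, mutation_rate <= 1,
            mutation_sd_fraction > 0)
  structure(list(population_size = as.integer(population_size),
                 elite_count = as.integer(elite_count),
                 crossover_fraction = crossover_fraction,
                 generations = as.integer(generations),
                 stall_generations = as.integer(stall_generations),
                 fitness_tol = fitness_tol,
                 mutation_rate = mutation_rate,
                 mutation_sd_fraction = mutation_sd_fraction,
                 seed = as.integer(seed),
                 migration_interval = as.integer(migration_interval),
                 migration_fraction = migration_fraction),
            class = "ga_config")
}

#' Rank-based fitness scaling
#'
#' Scales raw fitness to `1/sqrt(rank)` with rank 1 the best individual;
#' ties are broken by input order. Rank scaling removes the influence of
#' raw fitness spread on selection pressure.
#'
#' @param raw Raw fitness values.
#' @param maximize If `TRUE` (default) larger raw fitness ranks better.
#' @return Scaled fitness vector (monotone in raw fitness).
#' @export
rank_scale <- function(raw, maximize = TRUE) {
  if (!length(raw)) stop("empty fitness vector", call. = FALSE)
  r <- rank(if (maximize) -raw else raw, ties.method = "first")
  1 / sqrt(r)
}

#' Stochastic universal sampling
#'
#' Lays `n_picks` equally spaced pointers, offset by a single uniform draw,
#' over the cumulative scaled-fitness line. Each individual is picked a
#' number of times whose expectation is exactly proportional to its scaled
#' fitness, with minimal variance (an individual whose expected count is
#' integral is picked exactly that many times).
#'
#' @param scaled Non-negative scaled fitness values, not all zero.
#' @param n_picks Number of selections.
#' @return Integer vector of selected indices (in comb order).
#' @export
sus_select <- function(scaled, n_picks) {
  if (any(scaled < 0)) stop("scaled fitness must be non-negative", call. = FALSE)
  tot <- sum(scaled)
  if (tot <= 0) stop("degenerate selection: all scaled fitness zero", call. = FALSE)
  cum <- cumsum(scaled)
  step <- tot / n_picks
  ptr <- (stats::runif(1) + seq_len(n_picks) - 1) * step
  findInterval(ptr, cum, left.open = TRUE) + 1L
}

#' Scattered (uniform) crossover
#'
#' Each gene of the child is copied from parent `a` or parent `b` with
#' probability 1/2, independently per gene.
#'
#' @param a,b Parent vectors of equal length.
#' @return Child vector.
#' @export
scattered_crossover <- function(a, b) {
  if (length(a) != length(b)) stop("parents must have equal length", call. = FALSE)
  ifelse(stats::runif(length(a)) < 0.5, a, b)
}

#' Maximize a fitness function with a real-coded GA
#'
#' Generational loop: evaluate, rank-scale, select parents by stochastic
#' universal sampling (parent order shuffled), copy the elite unchanged,
#' produce `round(crossover_fraction * (pop - elite))` children by
#' scattered crossover (with optional per-gene Gaussian mutation at
#' `mutation_rate`), fill the remainder with Gaussian-mutation-only
#' children, clip everything to bounds. Stops at the generation budget or
#' after `stall_generations` without improvement. With `elite_count >= 1`
#' the best-so-far fitness is non-decreasing.
#'
#' @param fitness Function taking a named composition vector, returning a
#'   finite scalar to maximize.
#' @param bounds Two-column matrix (or data frame) of per-variable
#'   `low, high` bounds; row names become variable names.
#' @param config A [ga_config()].
#' @return Object of class `ga_run`: `best_point`, `best_fitness`, `trace`
#'   (generation, best, mean), `generations_used`, `stop_reason`, `config`.
#' @export
ga_optimize <- function(fitness, bounds, config = ga_config()) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L) stop("bounds must have two columns (low, high)", call. = FALSE)
  lo <- bounds[, 1L]; hi <- bounds[, 2L]
  if (!all(is.finite(lo)) || !all(is.finite(hi)) || any(lo >= hi)) {
    stop("infeasible bounds: need finite low < high per variable", call. = FALSE)
  }
  nvar <- length(lo)
  vn <- rownames(bounds)
  if (is.null(vn)) vn <- paste0("x", seq_len(nvar))
  pop <- config$population_size
  elite <- config$elite_count
  rng <- hi - lo

  eval_pop <- function(P) {
    f <- apply(P, 1L, function(p) fitness(stats::setNames(p, vn)))
    bad <- !is.finite(f)
    if (any(bad)) {
      stop("fitness returned a non-finite value at point (",
           paste(signif(P[which(bad)[1L], ], 6), collapse = ", "), ")",
           call. = FALSE)
    }
    f
  }

  set.seed(config$seed)
  P <- matrix(stats::runif(pop * nvar, rep(lo, each = pop),
                           rep(hi, each = pop)), pop, nvar)
  f <- eval_pop(P)
  trace <- data.frame(generation = 0L, best = max(f), mean = mean(f))
  best_so_far <- max(f)
  stall <- 0L
  stop_reason <- "generations"
  gen_used <- 0L

  n_cross <- round(config$crossover_fraction * (pop - elite))
  n_mut <- pop - elite - n_cross

  for (gen in seq_len(config$generations)) {
    sc <- rank_scale(f)
    n_parents <- 2L * n_cross + n_mut
    parents <- integer(0)
    if (n_parents > 0L) {
      parents <- sus_select(sc, n_parents)
      parents <- parents[sample.int(n_parents)]
    }
    ord <- order(-f)
    nextP <- matrix(NA_real_, pop, nvar)
    if (elite > 0L) nextP[seq_len(elite), ] <- P[ord[seq_len(elite)], , drop = FALSE]
    if (n_cross > 0L) {
      pa <- P[parents[seq_len(n_cross)], , drop = FALSE]
      pb <- P[parents[n_cross + seq_len(n_cross)], , drop = FALSE]
      mask <- matrix(stats::runif(n_cross * nvar) < 0.5, n_cross, nvar)
      ch <- ifelse(mask, pa, pb)
      if (config$mutation_rate > 0) {
        hit <- matrix(stats::runif(n_cross * nvar) < config$mutation_rate,
                      n_cross, nvar)
        noise <- matrix(stats::rnorm(n_cross * nvar, 0,
                                     config$mutation_sd_fraction * rep(rng, each = n_cross)),
                        n_cross, nvar)
        ch <- ch + hit * noise
      }
      nextP[elite + seq_len(n_cross), ] <- ch
    }
    if (n_mut > 0L) {
      pm <- P[parents[2L * n_cross + seq_len(n_mut)], , drop = FALSE]
      noise <- matrix(stats::rnorm(n_mut * nvar, 0,
                                   config$mutation_sd_fraction * rep(rng, each = n_mut)),
                      n_mut, nvar)
      nextP[elite + n_cross + seq_len(n_mut), ] <- pm + noise
    }
    # clip to bounds gene-wise
    nextP <- pmin(pmax(nextP, matrix(lo, pop, nvar, byrow = TRUE)),
                  matrix(hi, pop, nvar, byrow = TRUE))
    P <- nextP
    f <- eval_pop(P)
    gen_used <- gen
    trace <- rbind(trace, data.frame(generation = gen, best = max(f),
                                     mean = mean(f)))
    if (max(f) > best_so_far + config$fitness_tol) {
      best_so_far <- max(f)
      stall <- 0L
    } else {
      best_so_far <- max(best_so_far, max(f))
      stall <- stall + 1L
      if (stall >= config$stall_generations) { stop_reason <- "stall"; break }
    }
  }
  i <- which.max(f)
  structure(
    list(best_point = stats::setNames(P[i, ], vn),
         best_fitness = f[i],
         trace = trace,
         generations_used = gen_used,
         stop_reason = stop_reason,
         config = config),
    class = "ga_run"
  )
}

#' @export
print.ga_run <- function(x, ...) {
  cat(sprintf("<ga_run> best fitness %.6g after %d generations (%s)\n",
              x$best_fitness, x$generations_used, x$stop_reason))
  pt <- paste(sprintf("%s = %.4g", names(x$best_point), x$best_point),
              collapse = ", ")
  cat("  at:", pt, "\n")
  invisible(x)
}

#' Exhaustive grid search over box bounds
#'
#' Brute-force oracle for checking GA results: evaluates the fitness on a
#' full `points_per_axis^k` lattice (vectorized for quadratic models) and
#' returns the lattice maximum.
#'
#' @param fitness A `quadratic_model`, or a function of a composition
#'   vector.
#' @param bounds As in [ga_optimize()].
#' @param points_per_axis Lattice resolution per variable.
#' @return List: `best_point`, `best_fitness`, `resolution` (per-axis grid
#'   step).
#' @export
grid_search <- function(fitness, bounds, points_per_axis = 21L) {
  bounds <- as.matrix(bounds)
  lo <- bounds[, 1L]; hi <- bounds[, 2L]
  vn <- rownames(bounds)
  if (is.null(vn)) vn <- paste0("x", seq_along(lo))
  axes <- lapply(seq_along(lo), function(i) {
    seq(lo[i], hi[i], length.out = points_per_axis)
  })
  G <- as.matrix(expand.grid(axes))
  colnames(G) <- vn
  n <- nrow(G)
  best_val <- -Inf
  best_idx <- NA_integer_
  chunk <- 200000L  # bound peak memory on multi-million-point lattices
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    vals <- if (inherits(fitness, "quadratic_model")) {
      predict(fitness, G[idx, , drop = FALSE])
    } else {
      apply(G[idx, , drop = FALSE], 1L,
            function(p) fitness(stats::setNames(p, vn)))
    }
    j <- which.max(vals)
    if (vals[j] > best_val) { best_val <- vals[j]; best_idx <- idx[j] }
  }
  list(best_point = stats::setNames(G[best_idx, ], vn),
       best_fitness = best_val,
       resolution = (hi - lo) / (points_per_axis - 1L))
}

#' The design box of a factor list
#'
#' Per-factor `[low star, high star]` bounds, the region actually explored
#' by a circumscribed CCD (low stars respect `low_clip`).
#'
#' @param factors List of [factor_spec()]s.
#' @return Matrix with columns `low`, `high` and one row per factor.
#' @export
design_bounds <- function(factors) {
  check_factors(factors)
  lo <- pmax(factor_field(factors, "center") -
               factor_field(factors, "alpha") * factor_field(factors, "half_range"),
             factor_field(factors, "low_clip"))
  hi <- factor_field(factors, "center") +
    factor_field(factors, "alpha") * factor_field(factors, "half_range")
  m <- cbind(low = lo, high = hi)
  rownames(m) <- names(factors)
  m
}
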