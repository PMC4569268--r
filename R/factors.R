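#' Define a design factor
#'
#' A factor specification records everything needed to move between coded
#' (dimensionless) and uncoded (concentration) units of one medium component:
#' the centre-point concentration, the distance from the centre to the +/-1
#' factorial level, the star-point distance `alpha` in coded units, and a
#' lower clip applied to star levels that would otherwise fall at or below
#' zero concentration.
#'
#' @param name Factor name (unique within a design).
#' @param center Centre-point concentration (g/50 mL, or mL/50 mL for
#'   liquid components such as glycerol).
#' @param half_range Distance from the centre to the +/-1 factorial level,
#'   in concentration units. Must be positive.
#' @param alpha Star distance in coded units (>= 1). Star levels sit at
#'   `center +/- alpha * half_range` before clipping.
#' @param low_clip Minimum allowed uncoded value. Decoded values below this
#'   are floored (default `-Inf`, no clipping).
#' @param units Unit label, for reporting only.
#' @return An object of class `factor_spec`.
#' @seealso [cod_factors()] for the bundled cholesterol-oxidase medium
#'   factors, [generate_ccd()] to build a design from a list of specs.
#' @export
factor_spec <- function(name, center, half_range, alpha = 2,
                        low_clip = -Inf, units = "g/50 mL") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(half_range) || length(half_range) != 1L || half_range <= 0) {
    stop("invalid factor '", name, "': half_range must be a positive number",
         call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 1) {
    stop("invalid factor '", name, "': alpha must be >= 1", call. = FALSE)
  }
  structure(
    list(name = name, center = as.numeric(center),
         half_range = as.numeric(half_range), alpha = as.numeric(alpha),
         low_clip = as.numeric(low_clip), units = units),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s: center %g, half-range %g, alpha %g (%s)\n",
              x$name, x$center, x$half_range, x$alpha, x$units))
  invisible(x)
}

#' Medium factors of the bundled cholesterol-oxidase design
#'
#' The five medium components varied in the bundled circumscribed central
#' composite design: soybean meal, glycerol, maltose, MgSO4 and NaCl.
#' Factorial levels are centre +/- half-range; star levels use `alpha = 2`,
#' and star levels that would land at 0 g/50 mL are floored at 0.0005, the
#' value realized in the experiment.
#'
#' @return Named list of five [factor_spec()] objects.
#' @export
cod_factors <- function() {
  f <- list(
    factor_spec("soybean",  0.75,  0.375,  alpha = 2, low_clip = 5e-4),
    factor_spec("glycerol", 0.75,  0.375,  alpha = 2, low_clip = 5e-4,
                units = "mL/50 mL"),
    factor_spec("maltose",  0.75,  0.375,  alpha = 2, low_clip = 5e-4),
    factor_spec("mgso4",    0.025, 0.0125, alpha = 2, low_clip = 5e-4),
    factor_spec("nacl",     0.15,  0.075,  alpha = 2, low_clip = 5e-4)
  )
  names(f) <- vapply(f, `[[`, character(1), "name")
  f
}

check_factors <- function(factors) {
  if (!is.list(factors) || !length(factors) ||
      !all(vapply(factors, inherits, logical(1), "factor_spec"))) {
    stop("'factors' must be a list of factor_spec objects", call. = FALSE)
  }
  nm <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicate factor names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  invisible(nm)
}

factor_field <- function(factors, field) {
  vapply(factors, `[[`, numeric(1), field)
}

as_factor_matrix <- function(x, factors, what) {
  k <- length(factors)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != k) {
      stop(what, " must have length ", k, " (one value per factor), got ",
           length(x), call. = FALSE)
    }
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != k) {
    stop(what, " must have ", k, " columns (one per factor), got ",
         ncol(x), call. = FALSE)
  }
  colnames(x) <- vapply(factors, `[[`, character(1), "name")
  x
}

#' Convert uncoded concentrations to coded units
#'
#' `coded_i = (uncoded_i - center_i) / half_range_i`, so the centre maps to 0
#' and the factorial levels to +/-1.
#'
#' @param uncoded Numeric vector (one composition) or matrix/data frame
#'   (one row per composition), columns in factor order.
#' @param factors List of [factor_spec()]s.
#' @return Matrix of coded values (a single input vector gives a 1-row
#'   matrix; use `drop = TRUE` indexing if a vector is wanted).
#' @export
code_values <- function(uncoded, factors) {
  check_factors(factors)
  x <- as_factor_matrix(uncoded, factors, "'uncoded'")
  ctr <- factor_field(factors, "center")
  hr <- factor_field(factors, "half_range")
  sweep(sweep(x, 2L, ctr, "-"), 2L, hr, "/")
}

#' Convert coded units to uncoded concentrations
#'
#' `uncoded_i = center_i + coded_i * half_range_i`, floored at each factor's
#' `low_clip`. `decode_values(code_values(x)) == x` whenever `x` is above the
#' clip.
#'
#' @param coded Numeric vector or matrix of coded values, columns in factor
#'   order.
#' @inheritParams code_values
#' @return Matrix of uncoded concentrations.
#' @export
decode_values <- function(coded, factors) {
  check_factors(factors)
  x <- as_factor_matrix(coded, factors, "'coded'")
  ctr <- factor_field(factors, "center")
  hr <- factor_field(factors, "half_range")
  clip <- factor_field(factors, "low_clip")
  out <- sweep(sweep(x, 2L, hr, "*"), 2L, ctr, "+")
  pmax(out, matrix(clip, nrow(out), ncol(out), byrow = TRUE))
}

#' Read factor specifications from a YAML configuration
#'
#' Expects a top-level `factors:` block, a list of maps with keys
#' `name`, `center`, `half_range` and optionally `alpha`, `low_clip`,
#' `units`.
#'
#' @param path Path to a YAML file.
#' @return Named list of [factor_spec()]s.
#' @export
factors_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$factors)) stop("YAML config has no 'factors' block", call. = FALSE)
  f <- lapply(cfg$factors, function(b) {
    do.call(factor_spec, b[intersect(names(b),
      c("name", "center", "half_range", "alpha", "low_clip", "units"))])
  })
  names(f) <- vapply(f, `[[`, character(1), "name")
  f
}
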