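# 21-term second-order model matrix: k linear, k(k-1)/2 pairwise
# interactions (i < j), k squares. Column order: linear, interactions
# (1:2, 1:3, ..., 1:k, 2:3, ...), squares.
quad_terms <- function(X) {
  k <- ncol(X)
  nm <- colnames(X)
  inter <- utils::combn(k, 2L)
  XI <- X[, inter[1L, ], drop = FALSE] * X[, inter[2L, ], drop = FALSE]
  colnames(XI) <- paste(nm[inter[1L, ]], nm[inter[2L, ]], sep = ":")
  XQ <- X^2
  colnames(XQ) <- paste0(nm, "^2")
  cbind(X, XI, XQ)
}

#' Construct a second-order (quadratic) response-surface model
#'
#' Assembles a full quadratic polynomial in `k` factors from explicit
#' coefficients: intercept, `k` linear terms, `k(k-1)/2` pairwise
#' interactions and `k` squared terms.
#'
#' @param intercept Intercept (response units, U/mL here).
#' @param linear Named numeric vector of linear coefficients, one per
#'   factor, in factor order.
#' @param interaction Named numeric vector of interaction coefficients in
#'   the order 1:2, 1:3, ..., 1:k, 2:3, ... (names `"a:b"`).
#' @param quadratic Named numeric vector of squared-term coefficients.
#' @param basis `"uncoded"` if the polynomial applies to raw concentrations,
#'   `"coded"` if to coded units.
#' @param factors The [factor_spec()] list the model is defined over.
#' @return An object of class `quadratic_model`.
#' @export
quadratic_model <- function(intercept, linear, interaction, quadratic,
                            basis = c("uncoded", "coded"), factors) {
  basis <- match.arg(basis)
  check_factors(factors)
  k <- length(factors)
  stopifnot(length(linear) == k, length(quadratic) == k,
            length(interaction) == k * (k - 1L) / 2L)
  nm <- names(factors)
  names(linear) <- nm
  names(quadratic) <- paste0(nm, "^2")
  inter <- utils::combn(k, 2L)
  names(interaction) <- paste(nm[inter[1L, ]], nm[inter[2L, ]], sep = ":")
  structure(
    list(intercept = unname(intercept), linear = linear,
         interaction = interaction, quadratic = quadratic,
         basis = basis, factors = factors),
    class = "quadratic_model"
  )
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("<quadratic_model> %d factors, %s basis, intercept %.5g\n",
              length(x$factors), x$basis, x$intercept))
  if (!is.null(x$diagnostics)) {
    d <- x$diagnostics
    cat(sprintf("  fit: R^2 = %.6f, R = %.6f, F(%d,%d) = %.4f, p = %.3g\n",
                d$r_squared, d$r, d$dof_model, d$dof_error, d$f_overall,
                d$p_overall))
  }
  invisible(x)
}

coef_vector <- function(model) {
  c(`(Intercept)` = model$intercept, model$linear, model$interaction,
    model$quadratic)
}

#' Fit the full second-order model by ordinary least squares
#'
#' Regresses the observed response on the 21-term (for five factors)
#' quadratic model matrix. All terms are kept; no stepwise elimination.
#' Fit diagnostics (R-squared, its square root R, the overall regression
#' F-statistic and p-value, residuals) are attached to the returned model.
#'
#' @param design A `ccd_design` with observed responses.
#' @param basis Fit on raw concentrations (`"uncoded"`, default) or coded
#'   units (`"coded"`). Predictions are identical either way; only the
#'   coefficient units differ.
#' @param response Name of the response column (default `"observed"`).
#' @return A `quadratic_model` with a `diagnostics` element and the
#'   underlying `lm` fit stored as `fit`.
#' @export
fit_quadratic <- function(design, basis = c("uncoded", "coded"),
                          response = "observed") {
  basis <- match.arg(basis)
  factors <- attr(design, "factors")
  check_factors(factors)
  y <- design[[response]]
  if (is.null(y) || !any(is.finite(y))) {
    stop("design has no usable '", response, "' responses", call. = FALSE)
  }
  keep <- is.finite(y)
  X <- design_matrix(design, coded = (basis == "coded"))[keep, , drop = FALSE]
  y <- y[keep]
  M <- quad_terms(X)
  if (length(y) < ncol(M) + 1L) {
    stop("need at least ", ncol(M) + 1L, " runs with responses to fit ",
         ncol(M) + 1L, " coefficients; have ", length(y), call. = FALSE)
  }
  dat <- data.frame(.y = y, M, check.names = FALSE)
  fml <- stats::reformulate(sprintf("`%s`", colnames(M)), response = ".y")
  fit <- stats::lm(fml, data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("singular design: collinear terms ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  k <- length(factors)
  model <- quadratic_model(cf[1L], cf[1L + seq_len(k)],
                           cf[1L + k + seq_len(k * (k - 1L) / 2L)],
                           cf[1L + k + k * (k - 1L) / 2L + seq_len(k)],
                           basis = basis, factors = factors)
  # noiseless synthetic fits are a designed use; keep summary.lm quiet
  # about them
  s <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  fstat <- s$fstatistic
  model$diagnostics <- list(
    r_squared = s$r.squared,
    r = sqrt(s$r.squared),
    f_overall = unname(fstat[1L]),
    p_overall = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                                 lower.tail = FALSE)),
    residuals = unname(stats::residuals(fit)),
    dof_model = unname(fstat[2L]),
    dof_error = unname(fstat[3L])
  )
  model$fit <- fit
  model
}

#' Evaluate a quadratic model at compositions
#'
#' @param object A `quadratic_model`.
#' @param newdata Composition(s): numeric vector, matrix or data frame with
#'   one column per factor, in the model's basis (uncoded concentrations for
#'   an uncoded-basis model).
#' @param ... Unused.
#' @return Numeric vector of predicted responses (U/mL).
#' @export
predict.quadratic_model <- function(object, newdata, ...) {
  X <- as_factor_matrix(newdata, object$factors, "'newdata'")
  M <- quad_terms(X)
  drop(object$intercept + M %*% c(object$linear, object$interaction,
                                  object$quadratic))
}

#' Re-express a quadratic model in the other basis
#'
#' Substitutes the affine map between coded and uncoded units into the
#' polynomial, so predictions are bitwise-identical in either basis.
#'
#' @param model A `quadratic_model`.
#' @param to Target basis.
#' @return A `quadratic_model` in the requested basis (diagnostics carried
#'   over; they do not depend on the basis).
#' @export
convert_basis <- function(model, to = c("uncoded", "coded")) {
  to <- match.arg(to)
  if (identical(model$basis, to)) return(model)
  factors <- model$factors
  k <- length(factors)
  ctr <- factor_field(factors, "center")
  hr <- factor_field(factors, "half_range")
  # uncoded u relates to coded c by u = ctr + hr*c. Going coded -> uncoded
  # substitute c = (u - ctr)/hr; going uncoded -> coded substitute
  # u = ctr + hr*c. Both are affine: x_new = a + b * x_old per factor.
  if (to == "uncoded") { a <- -ctr / hr; b <- 1 / hr } else { a <- ctr; b <- hr }
  # model is a polynomial in x_old; express in x_new where x_old = a + b*x_new
  b0 <- model$intercept
  lin <- model$linear
  quad <- model$quadratic
  inter <- utils::combn(k, 2L)
  int <- model$interaction
  n0 <- b0 + sum(lin * a) + sum(quad * a^2) +
    sum(int * a[inter[1L, ]] * a[inter[2L, ]])
  nlin <- lin * b + 2 * quad * a * b
  for (m in seq_len(ncol(inter))) {
    i <- inter[1L, m]; j <- inter[2L, m]
    nlin[i] <- nlin[i] + int[m] * b[i] * a[j]
    nlin[j] <- nlin[j] + int[m] * a[i] * b[j]
  }
  nint <- int * b[inter[1L, ]] * b[inter[2L, ]]
  nquad <- quad * b^2
  # note: the substitution above maps uncoded->coded when to == "coded"
  # (x_old = uncoded = ctr + hr * coded) and coded->uncoded otherwise.
  out <- quadratic_model(n0, nlin, nint, nquad, basis = to, factors = factors)
  out$diagnostics <- model$diagnostics
  out
}

#' Per-term ANOVA of a fitted quadratic model
#'
#' For each of the 21 coefficients: the partial (type-III) sum of squares,
#' the coefficient standard error, the mean square, `F = MS / MS_error` on
#' (1, dof_error) degrees of freedom, and the F-test p-value. Terms are
#' ordered intercept first, then each factor's linear and squared term, then
#' the interactions grouped by the second factor (1:2, 1:3, 2:3, 1:4, ...),
#' the layout conventional for this analysis.
#'
#' @param model A `quadratic_model` from [fit_quadratic()].
#' @return Data frame with columns `term`, `sum_sq`, `std_error`, `mean_sq`,
#'   `f_value`, `p_value`.
#' @export
anova_table <- function(model) {
  if (is.null(model$fit)) {
    stop("model has no stored fit; use fit_quadratic()", call. = FALSE)
  }
  fit <- model$fit
  dfe <- stats::df.residual(fit)
  if (dfe < 1L) stop("no residual degrees of freedom; diagnostics unavailable",
                     call. = FALSE)
  s <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
  mse <- s$sigma^2
  tv <- stats::coef(s)[, "t value"]
  se <- stats::coef(s)[, "Std. Error"]
  # lm drops backticks around syntactic names; normalize before matching
  names(tv) <- gsub("`", "", names(tv), fixed = TRUE)
  names(se) <- gsub("`", "", names(se), fixed = TRUE)
  fv <- tv^2
  ss <- fv * mse
  pv <- stats::pf(fv, 1L, dfe, lower.tail = FALSE)
  nm <- names(model$factors)
  k <- length(nm)
  inter <- utils::combn(k, 2L)
  int_names <- paste(nm[inter[1L, ]], nm[inter[2L, ]], sep = ":")
  # interactions grouped by second factor: (1,2), (1,3), (2,3), (1,4), ...
  int_order <- int_names[order(inter[2L, ], inter[1L, ])]
  ord <- c("(Intercept)",
           as.vector(rbind(nm, paste0(nm, "^2"))),
           int_order)
  data.frame(term = ord,
             sum_sq = unname(ss[ord]),
             std_error = unname(se[ord]),
             mean_sq = unname(ss[ord]),
             f_value = unname(fv[ord]),
             p_value = unname(pv[ord]),
             row.names = NULL)
}

#' Evaluate a model over a two-factor grid slice
#'
#' Holds all but two factors fixed (default: their centre values) and
#' evaluates the model over a square lattice spanning each varied factor's
#' star range, the standard way of drawing response-surface plots.
#'
#' @param model A `quadratic_model` (or any object with a `predict` method
#'   over factor compositions).
#' @param var_i,var_j Indices or names of the two varied factors (distinct).
#' @param fixed Full-length composition supplying the fixed factors'
#'   values (defaults to all centres); entries for `var_i`/`var_j` ignored.
#' @param grid_n Lattice points per axis.
#' @return Data frame with the two varied factors' values and `predicted`.
#' @export
surface_slice <- function(model, var_i, var_j, fixed = NULL, grid_n = 21L) {
  factors <- model$factors
  nm <- names(factors)
  i <- if (is.character(var_i)) match(var_i, nm) else as.integer(var_i)
  j <- if (is.character(var_j)) match(var_j, nm) else as.integer(var_j)
  if (is.na(i) || is.na(j) || i < 1L || j < 1L || i > length(nm) || j > length(nm)) {
    stop("unknown factor selection", call. = FALSE)
  }
  if (i == j) stop("var_i and var_j must differ", call. = FALSE)
  if (is.null(fixed)) fixed <- factor_field(factors, "center")
  fixed <- as.numeric(fixed)
  if (length(fixed) != length(nm)) {
    stop("'fixed' must supply one value per factor", call. = FALSE)
  }
  rng <- function(f) {
    lo <- max(f$center - f$alpha * f$half_range, f$low_clip)
    hi <- f$center + f$alpha * f$half_range
    seq(lo, hi, length.out = grid_n)
  }
  g <- expand.grid(rng(factors[[i]]), rng(factors[[j]]))
  X <- matrix(fixed, nrow(g), length(nm), byrow = TRUE)
  X[, i] <- g[[1L]]
  X[, j] <- g[[2L]]
  colnames(X) <- nm
  out <- data.frame(g[[1L]], g[[2L]], predicted = predict(model, X))
  names(out)[1:2] <- nm[c(i, j)]
  out
}

#' The reference quadratic model of the bundled dataset
#'
#' The published second-order polynomial for cholesterol-oxidase activity as
#' a function of the five medium concentrations (uncoded units: g/50 mL,
#' glycerol mL/50 mL). Evaluating it at the design compositions reproduces
#' the bundled table's reference RSM predictions (e.g. 3.12288 U/mL at the
#' all-centre composition).
#'
#' @return A `quadratic_model` in the uncoded basis.
#' @export
cod_rsm_model <- function() {
  quadratic_model(
    intercept = 2.0494,
    linear = c(3.6784, -0.3495, -3.6367, -36.0494, 6.6486),
    interaction = c(-1.86133, 0.040889, -8.53333, 7.75111,
                    0.70222, -12.26667, 4.44444,
                    136.53333, -9.68889,
                    -212.0),
    quadratic = c(-1.5605, 0.9819, 1.1270, -38.9134, -4.6168),
    basis = "uncoded", factors = cod_factors()
  )
}

#' Serialize a quadratic model to JSON
#'
#' @param model A `quadratic_model`.
#' @param path Optional file to write; if `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
rsm_to_json <- function(model, path = NULL) {
  obj <- list(basis = model$basis,
              intercept = model$intercept,
              linear = as.list(model$linear),
              interactions = as.list(model$interaction),
              quadratic = as.list(model$quadratic))
  if (!is.null(model$diagnostics)) {
    d <- model$diagnostics
    obj$diagnostics <- list(r2 = d$r_squared, r = d$r, f = d$f_overall,
                            p = d$p_overall)
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
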