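#' Generate a circumscribed central composite design
#'
#' Builds the classic Box-Wilson layout: a two-level factorial core (full, or
#' a resolution-V half fraction with defining relation
#' `x_k = x_1 x_2 ... x_{k-1}`), `2k` star points at +/-alpha on each factor
#' axis, and replicated centre points. Runs are ordered factorial, star
#' (low then high per factor), centre. Uncoded concentrations are obtained
#' with [decode_values()], so star levels respect each factor's `low_clip`.
#'
#' @param factors List of [factor_spec()]s (2 to 10 factors).
#' @param n_center Number of centre-point replicates (>= 1).
#' @param fraction `"half"` for a 2^(k-1) factorial core, `"full"` for 2^k.
#' @return A `ccd_design`: a data frame with columns `run`, one uncoded
#'   concentration column per factor, `point_type`
#'   (factorial/star/center), `split` (NA until assigned) and `observed`
#'   (NA until measured). The coded design matrix is kept in
#'   `attr(, "coded")` and the factor list in `attr(, "factors")`.
#' @examples
#' des <- generate_ccd(cod_factors(), n_center = 10)
#' table(des$point_type)  # 16 factorial, 10 star, 10 center
#' @export
generate_ccd <- function(factors, n_center, fraction = c("half", "full")) {
  check_factors(factors)
  fraction <- match.arg(fraction)
  k <- length(factors)
  if (k < 2L || k > 10L) stop("number of factors must be between 2 and 10", call. = FALSE)
  if (!is.numeric(n_center) || length(n_center) != 1L || n_center < 1) {
    stop("n_center must be >= 1", call. = FALSE)
  }
  n_center <- as.integer(n_center)

  # factorial core, first factor slowest (binary counting order)
  kk <- if (fraction == "half") k - 1L else k
  core <- matrix(NA_real_, 2L^kk, kk)
  for (j in seq_len(kk)) {
    core[, j] <- rep(c(-1, 1), each = 2L^(kk - j), times = 2L^(j - 1L))
  }
  if (fraction == "half") core <- cbind(core, apply(core, 1L, prod))

  alpha <- factor_field(factors, "alpha")
  star <- matrix(0, 2L * k, k)
  for (i in seq_len(k)) {
    star[2L * i - 1L, i] <- -alpha[i]
    star[2L * i, i] <- alpha[i]
  }

  coded <- rbind(core, star, matrix(0, n_center, k))
  point_type <- rep(c("factorial", "star", "center"),
                    c(nrow(core), nrow(star), n_center))
  uncoded <- decode_values(coded, factors)
  colnames(coded) <- colnames(uncoded)

  out <- data.frame(run = seq_len(nrow(coded)), uncoded,
                    point_type = point_type,
                    split = NA_character_, observed = NA_real_,
                    check.names = FALSE)
  new_ccd_design(out, factors, coded)
}

new_ccd_design <- function(df, factors, coded) {
  structure(df, factors = factors, coded = coded,
            class = c("ccd_design", "data.frame"))
}

#' @export
print.ccd_design <- function(x, ...) {
  tt <- table(x$point_type)
  cat(sprintf("<ccd_design> %d runs (%s), factors: %s\n",
              nrow(x),
              paste(sprintf("%d %s", tt, names(tt)), collapse = ", "),
              paste(names(attr(x, "factors")), collapse = ", ")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
`[.ccd_design` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    factors <- attr(x, "factors")
    if (all(names(factors) %in% names(out))) {
      coded <- attr(x, "coded")
      if (!missing(i) && !is.null(coded)) coded <- coded[i, , drop = FALSE]
      return(new_ccd_design(out, factors, coded))
    }
    class(out) <- "data.frame"
  }
  out
}

#' Extract the factor concentration columns of a design as a matrix
#'
#' @param design A `ccd_design`.
#' @param coded If `TRUE`, return the coded design matrix instead of the
#'   uncoded concentrations (recomputed with [code_values()] when the design
#'   was read from file).
#' @return Numeric matrix, one row per run, one column per factor.
#' @export
design_matrix <- function(design, coded = FALSE) {
  factors <- attr(design, "factors")
  x <- as.matrix(as.data.frame(design)[, names(factors), drop = FALSE])
  if (coded) code_values(x, factors) else x
}

#' Load the bundled cholesterol-oxidase CCD dataset
#'
#' The packaged 36-run, five-factor circumscribed CCD with observed
#' cholesterol-oxidase activities (U/mL) and the reference predicted columns
#' of the original experiment (one from the quadratic response-surface
#' model, one from the trained neural network). Rows 1-16 are the half
#' factorial, 17-26 the star points, 27-36 centre replicates. The data-split
#' labels mark 24 training, 6 test and 6 validation runs.
#'
#' Two cells are kept exactly as recorded even though they are suspect
#' transcription artifacts: run 24's MgSO4 concentration (0.5 g/50 mL where
#' the alpha = 2 star pattern implies 0.05) and run 17's reference RSM
#' prediction (1.85549 where the quadratic model evaluates to 1.5555).
#' Refitting the quadratic model to this table as-is reproduces the
#' original fit diagnostics exactly, so the 0.5 cell is what was actually
#' analysed.
#'
#' @return A `ccd_design` with extra reference columns `pred_rsm` and
#'   `pred_ann`.
#' @export
cod_design <- function() {
  path <- system.file("extdata", "cod_ccd.csv", package = "codopt",
                      mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, "4ec73438fa9d9d7f4d3e625a3af9ae9c")) {
    stop("bundled design fixture is corrupted (md5 ", sum, ")", call. = FALSE)
  }
  read_design_csv(path, factors = cod_factors())
}

#' Read a design/response table from CSV
#'
#' Expected header: `run,<factor columns...>,point_type,split,observed`
#' (extra columns are preserved). Concentrations are uncoded.
#'
#' @param path CSV file path.
#' @param factors List of [factor_spec()]s matching the factor columns.
#' @return A `ccd_design`.
#' @export
read_design_csv <- function(path, factors) {
  nm <- check_factors(factors)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("run", nm), names(df))
  if (length(miss)) {
    stop("design CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$point_type)) df$point_type <- NA_character_
  if (is.null(df$split)) df$split <- NA_character_
  if (is.null(df$observed)) df$observed <- NA_real_
  coded <- code_values(as.matrix(df[, nm, drop = FALSE]), factors)
  new_ccd_design(df, factors, coded)
}

#' Write a design/response table to CSV
#'
#' @param design A `ccd_design`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' Build a design table from an arbitrary composition matrix
#'
#' Wraps any set of compositions (not necessarily a CCD layout) in the
#' design-table container so it can be fitted and predicted like a
#' generated design.
#'
#' @param x Matrix or data frame of uncoded compositions, one column per
#'   factor.
#' @param factors List of [factor_spec()]s.
#' @param observed Optional response vector.
#' @param split Split labels (recycled; default `"train"`).
#' @return A `ccd_design` with `point_type = NA`.
#' @export
design_from_matrix <- function(x, factors, observed = NA_real_,
                               split = "train") {
  nm <- check_factors(factors)
  x <- as_factor_matrix(x, factors, "'x'")
  df <- data.frame(run = seq_len(nrow(x)), x,
                   point_type = NA_character_,
                   split = rep_len(split, nrow(x)),
                   observed = rep_len(observed, nrow(x)),
                   check.names = FALSE)
  new_ccd_design(df, factors, code_values(x, factors))
}

#' Assign train/test/validation split labels
#'
#' Randomly partitions the runs into the three splits with the given counts
#' (defaults mirror the bundled dataset's 24/6/6 layout, scaled to the
#' design size).
#'
#' @param design A `ccd_design`.
#' @param n_test,n_validation Number of test and validation runs; the rest
#'   are training runs.
#' @param seed Integer seed for the permutation.
#' @return The design with its `split` column filled in.
#' @export
assign_splits <- function(design, n_test = round(nrow(design) / 6),
                          n_validation = round(nrow(design) / 6),
                          seed = 1L) {
  n <- nrow(design)
  if (n_test + n_validation >= n) {
    stop("test + validation counts must leave at least one training run",
         call. = FALSE)
  }
  set.seed(seed)
  idx <- sample.int(n)
  split <- rep("train", n)
  split[idx[seq_len(n_test)]] <- "test"
  split[idx[n_test + seq_len(n_validation)]] <- "validation"
  design$split <- split
  design
}
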