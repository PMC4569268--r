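# Feed-forward network: n inputs -> H tansig hidden units -> 1 linear
# output. Inputs and the response are min-max scaled to [-1, 1] before
# training (tansig saturates on raw g/50 mL scales); the forward pass
# rescales back, so the user-facing surface is always in original units.
#
# Parameter vector layout (column-major IW first):
#   theta = [IW (H x n, by column), b (H), LW (H), a]

#' Hyperbolic tangent sigmoid transfer function
#'
#' `tansig(z) = 2 / (1 + exp(-2 z)) - 1`, algebraically identical to
#' `tanh(z)`; kept as a named function because it is the conventional name
#' for this transfer in the neural-network literature.
#'
#' @param z Numeric.
#' @return Numeric of the same shape.
#' @export
tansig <- function(z) 2 / (1 + exp(-2 * z)) - 1

#' Initialize a feed-forward network
#'
#' Weights and biases are drawn i.i.d. uniform on
#' `[-init_scale, init_scale]` under the given seed. Normalization
#' constants are unset until the network is trained (or [nn_normalize()] is
#' called), so a freshly initialized network cannot predict yet.
#'
#' @param n_hidden Number of hidden tansig units (>= 1).
#' @param seed Integer seed; the same seed always gives the same weights.
#' @param n_inputs Number of input factors (default 5).
#' @param init_scale Half-width of the uniform initialization interval.
#'   0.5 is a safe default; larger values (about 1) give the hidden units
#'   more varied slopes, which helps extrapolation towards the design
#'   boundary on small designed datasets.
#' @return An object of class `neural_model`.
#' @export
nn_init <- function(n_hidden, seed, n_inputs = 5L, init_scale = 0.5) {
  if (!is.numeric(n_hidden) || length(n_hidden) != 1L || n_hidden < 1) {
    stop("n_hidden must be >= 1", call. = FALSE)
  }
  n_hidden <- as.integer(n_hidden)
  set.seed(seed)
  np <- n_hidden * n_inputs + 2L * n_hidden + 1L
  th <- stats::runif(np, -init_scale, init_scale)
  structure(
    list(IW = matrix(th[seq_len(n_hidden * n_inputs)], n_hidden, n_inputs),
         b = th[n_hidden * n_inputs + seq_len(n_hidden)],
         LW = th[n_hidden * (n_inputs + 1L) + seq_len(n_hidden)],
         a = th[np],
         norm_in = NULL, norm_out = NULL,
         n_hidden = n_hidden, n_inputs = n_inputs, seed = seed),
    class = "neural_model"
  )
}

#' @export
print.neural_model <- function(x, ...) {
  cat(sprintf("<neural_model> %d-%d-1 tansig/linear, %s\n",
              x$n_inputs, x$n_hidden,
              if (is.null(x$norm_in)) "not yet fitted" else "fitted"))
  invisible(x)
}

nn_theta <- function(model) {
  c(as.vector(model$IW), model$b, model$LW, model$a)
}

nn_set_theta <- function(model, th) {
  H <- model$n_hidden; n <- model$n_inputs
  model$IW <- matrix(th[seq_len(H * n)], H, n)
  model$b <- th[H * n + seq_len(H)]
  model$LW <- th[H * (n + 1L) + seq_len(H)]
  model$a <- th[H * (n + 2L) + 1L]
  model
}

#' Set a network's input/output normalization from data
#'
#' Records per-factor input ranges and the response range used to map both
#' onto `[-1, 1]`. Called automatically by [nn_train()].
#'
#' @param model A `neural_model`.
#' @param x Matrix of input compositions (rows = samples).
#' @param y Response vector.
#' @return The model with `norm_in` / `norm_out` set.
#' @export
nn_normalize <- function(model, x, y) {
  model$norm_in <- list(min = apply(x, 2L, min), max = apply(x, 2L, max))
  model$norm_out <- list(min = min(y), max = max(y))
  model
}

scale_to_pm1 <- function(x, lo, hi) {
  d <- ifelse(hi > lo, hi - lo, 1)
  if (is.matrix(x)) {
    sweep(sweep(x, 2L, lo, "-"), 2L, d, "/") * 2 - 1
  } else {
    (x - lo) / d * 2 - 1
  }
}

unscale_from_pm1 <- function(z, lo, hi) (z + 1) / 2 * (hi - lo) + lo

# forward pass on already-normalized inputs (rows = samples)
nn_forward_norm <- function(model, xn) {
  h <- tansig(model$IW %*% t(xn) + model$b)
  drop(crossprod(h, model$LW) + model$a)
}

#' Network forward pass
#'
#' Scales the composition(s) into `[-1, 1]` with the stored normalization,
#' applies the tansig hidden layer and linear output, and rescales the
#' output to response units.
#'
#' @param model A fitted `neural_model`.
#' @param x Composition vector, or matrix/data frame of compositions (one
#'   row each).
#' @return Predicted response(s), U/mL.
#' @export
nn_forward <- function(model, x) {
  if (is.null(model$norm_in) || is.null(model$norm_out)) {
    stop("network has no normalization constants; train it first",
         call. = FALSE)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$n_inputs) {
    stop("composition must have ", model$n_inputs, " values", call. = FALSE)
  }
  xn <- scale_to_pm1(x, model$norm_in$min, model$norm_in$max)
  yn <- nn_forward_norm(model, xn)
  unscale_from_pm1(yn, model$norm_out$min, model$norm_out$max)
}

#' Predict a design table row-wise
#'
#' @param model A fitted `neural_model`.
#' @param design A `ccd_design`.
#' @return Vector of predicted activities, in run order.
#' @export
nn_predict <- function(model, design) {
  nn_forward(model, design_matrix(design))
}

#' Training configuration for [nn_train()]
#'
#' @param algorithm `"lm"` (Levenberg-Marquardt, default), `"gd"`
#'   (fixed-rate gradient descent) or `"gda"` (gradient descent with
#'   adaptive learning rate).
#' @param max_epochs Epoch budget.
#' @param goal_sse Stop when training SSE (on the normalized scale) falls
#'   below this.
#' @param learning_rate Initial rate for gd/gda.
#' @param lr_inc,lr_dec Rate multipliers after an improving / worsening
#'   epoch (gda only; worsening steps are rejected).
#' @param mu0,mu_inc,mu_dec,mu_max Levenberg-Marquardt damping schedule:
#'   start value, factor applied after a rejected step, factor applied
#'   after an accepted step, and the ceiling that terminates training.
#' @param patience Consecutive epochs without improvement on the monitor
#'   split before early stopping (the weights at the monitor optimum are
#'   restored). Ignored when the design has no monitor rows.
#' @param fit_split Split label(s) whose rows enter the training objective
#'   (default `"train"`).
#' @param monitor_split Split label watched for early stopping (default
#'   `"validation"`).
#' @return A list of class `nn_config`.
#' @export
nn_config <- function(algorithm = c("lm", "gd", "gda"),
                      max_epochs = 1000L, goal_sse = 1e-5,
                      learning_rate = 0.01, lr_inc = 1.05, lr_dec = 0.7,
                      mu0 = 1e-3, mu_inc = 10, mu_dec = 0.1, mu_max = 1e10,
                      patience = 6L, fit_split = "train",
                      monitor_split = "validation") {
  algorithm <- match.arg(algorithm)
  stopifnot(learning_rate > 0, lr_inc > 1, lr_dec < 1, lr_dec > 0,
            mu0 > 0, mu_inc > 1, mu_dec < 1, mu_dec > 0, patience >= 1)
  structure(list(algorithm = algorithm, max_epochs = as.integer(max_epochs),
                 goal_sse = goal_sse, learning_rate = learning_rate,
                 lr_inc = lr_inc, lr_dec = lr_dec, mu0 = mu0,
                 mu_inc = mu_inc, mu_dec = mu_dec, mu_max = mu_max,
                 patience = as.integer(patience), fit_split = fit_split,
                 monitor_split = monitor_split),
            class = "nn_config")
}

# Jacobian of the normalized forward pass wrt theta; rows = samples.
nn_jacobian <- function(model, xn) {
  H <- model$n_hidden; n <- model$n_inputs
  hz <- tansig(model$IW %*% t(xn) + model$b)       # H x m
  m <- nrow(xn)
  J <- matrix(0, m, H * (n + 2L) + 1L)
  dh <- (1 - hz^2) * model$LW                       # H x m
  for (k in seq_len(n)) J[, (k - 1L) * H + seq_len(H)] <- t(dh) * xn[, k]
  J[, H * n + seq_len(H)] <- t(dh)
  J[, H * (n + 1L) + seq_len(H)] <- t(hz)
  J[, H * (n + 2L) + 1L] <- 1
  J
}

#' Train a feed-forward network on a design table
#'
#' Minimizes the sum of squared errors over the rows whose `split` label is
#' in `config$fit_split`, with optional early stopping monitored on the
#' `config$monitor_split` rows (the weights achieving the lowest monitor
#' SSE are returned). All three algorithms are full-batch. For
#' Levenberg-Marquardt, each epoch solves the damped normal equations
#' `(J'J + mu I) d = J' r` and only accepts steps that reduce the training
#' SSE, so the accepted-step SSE sequence is non-increasing; `mu` shrinks by
#' `mu_dec` after acceptance and grows by `mu_inc` after rejection, and
#' training ends if `mu` exceeds `mu_max`.
#'
#' @param model A `neural_model` from [nn_init()].
#' @param design A `ccd_design` with observed responses and split labels.
#' @param config An [nn_config()].
#' @return List with elements `model` (the trained network) and `report`
#'   (class `nn_report`): per-epoch SSE trace, correlation between
#'   predictions and observations on the train/test/validation splits, and
#'   the stop reason.
#' @export
nn_train <- function(model, design, config = nn_config()) {
  stopifnot(inherits(model, "neural_model"), inherits(config, "nn_config"))
  y <- design$observed
  split <- design$split
  fit_rows <- which(split %in% config$fit_split & is.finite(y))
  if (!length(fit_rows)) stop("no training rows (check split labels)", call. = FALSE)
  mon_rows <- which(split %in% config$monitor_split & is.finite(y))
  X <- design_matrix(design)
  if (is.null(model$norm_in) || is.null(model$norm_out)) {
    model <- nn_normalize(model, X, y)
  }
  xn <- scale_to_pm1(X, model$norm_in$min, model$norm_in$max)
  yn <- scale_to_pm1(y, model$norm_out$min, model$norm_out$max)

  sse_on <- function(mod, rows) {
    r <- nn_forward_norm(mod, xn[rows, , drop = FALSE]) - yn[rows]
    sum(r^2)
  }

  e <- sse_on(model, fit_rows)
  trace <- data.frame(epoch = 0L, sse = e, step = NA_real_, accepted = NA)
  stop_reason <- "max_epochs"
  monitor <- length(mon_rows) > 0L
  if (monitor) {
    vbest <- sse_on(model, mon_rows)
    best <- model
    bad <- 0L
  }
  mu <- config$mu0
  lr <- config$learning_rate

  for (epoch in seq_len(config$max_epochs)) {
    if (e < config$goal_sse) { stop_reason <- "goal_sse"; break }
    xf <- xn[fit_rows, , drop = FALSE]
    r <- nn_forward_norm(model, xf) - yn[fit_rows]
    if (!all(is.finite(r))) {
      stop("training diverged (non-finite loss) at epoch ", epoch, call. = FALSE)
    }
    accepted <- FALSE
    if (config$algorithm == "lm") {
      J <- nn_jacobian(model, xf)
      A <- crossprod(J)
      g <- crossprod(J, r)
      np <- ncol(J)
      while (mu <= config$mu_max) {
        dlt <- tryCatch(solve(A + mu * diag(np), g), error = function(err) NULL)
        if (!is.null(dlt)) {
          cand <- nn_set_theta(model, nn_theta(model) - drop(dlt))
          ec <- sse_on(cand, fit_rows)
          if (is.finite(ec) && ec < e) {
            model <- cand; e <- ec
            mu <- max(mu * config$mu_dec, 1e-20)
            accepted <- TRUE
            break
          }
        }
        mu <- mu * config$mu_inc
      }
      if (!accepted) { stop_reason <- "mu_max"; break }
      step_val <- mu
    } else {
      J <- nn_jacobian(model, xf)
      grad <- 2 * drop(crossprod(J, r))
      cand <- nn_set_theta(model, nn_theta(model) - lr * grad)
      ec <- sse_on(cand, fit_rows)
      if (!is.finite(ec)) {
        stop("training diverged (non-finite loss) at epoch ", epoch, call. = FALSE)
      }
      if (config$algorithm == "gd") {
        model <- cand; e <- ec; accepted <- TRUE
      } else {                      # gda: reject worsening steps
        if (ec < e) {
          model <- cand; e <- ec; lr <- lr * config$lr_inc; accepted <- TRUE
        } else {
          lr <- lr * config$lr_dec
        }
      }
      step_val <- lr
    }
    trace <- rbind(trace, data.frame(epoch = epoch, sse = e, step = step_val,
                                     accepted = accepted))
    if (monitor) {
      v <- sse_on(model, mon_rows)
      if (v < vbest) {
        vbest <- v; best <- model; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= config$patience) { stop_reason <- "early_stop"; break }
      }
    }
  }
  if (e < config$goal_sse && stop_reason == "max_epochs") stop_reason <- "goal_sse"
  # on early stopping return the monitor-optimal weights; a goal-level fit
  # of the training data is kept as-is
  if (monitor && stop_reason %in% c("early_stop", "max_epochs", "mu_max") &&
      e >= config$goal_sse) {
    model <- best
  }

  corr_on <- function(lbl) {
    rows <- which(split == lbl & is.finite(y))
    if (length(rows) < 2L) return(NA_real_)
    stats::cor(nn_forward(model, X[rows, , drop = FALSE]), y[rows])
  }
  report <- structure(
    list(trace = trace,
         final_sse = sse_on(model, fit_rows),
         r_train = corr_on("train"),
         r_test = corr_on("test"),
         r_validation = corr_on("validation"),
         epochs = max(trace$epoch),
         stop_reason = stop_reason,
         config = config),
    class = "nn_report"
  )
  list(model = model, report = report)
}

#' @export
print.nn_report <- function(x, ...) {
  cat(sprintf(
    "<nn_report> %d epochs (%s), SSE %.4g | r: train %.4f, test %s, validation %s\n",
    x$epochs, x$stop_reason, x$final_sse, x$r_train,
    ifelse(is.na(x$r_test), "NA", sprintf("%.4f", x$r_test)),
    ifelse(is.na(x$r_validation), "NA", sprintf("%.4f", x$r_validation))))
  invisible(x)
}

#' Train with several random restarts and keep the best network
#'
#' Trains one network per seed and selects the restart with the highest
#' correlation on the validation split (falling back to lowest training SSE
#' when no validation rows exist). Random-restart selection is the standard
#' guard against bad local minima for small Levenberg-Marquardt-trained
#' networks.
#'
#' @param design A `ccd_design` with splits and responses.
#' @param n_hidden Hidden-layer width.
#' @param seeds Integer vector of restart seeds.
#' @param config An [nn_config()].
#' @param init_scale Passed to [nn_init()].
#' @return List: `model` (best network), `report` (its report), `summary`
#'   (data frame of per-seed correlations).
#' @export
nn_restarts <- function(design, n_hidden = 15L, seeds = 1:10,
                        config = nn_config(), init_scale = 0.5) {
  runs <- lapply(seeds, function(s) {
    nn_train(nn_init(n_hidden, seed = s, init_scale = init_scale),
             design, config)
  })
  tab <- data.frame(
    seed = seeds,
    r_train = vapply(runs, function(r) r$report$r_train, numeric(1)),
    r_test = vapply(runs, function(r) r$report$r_test, numeric(1)),
    r_validation = vapply(runs, function(r) r$report$r_validation, numeric(1)),
    final_sse = vapply(runs, function(r) r$report$final_sse, numeric(1))
  )
  score <- tab$r_validation
  if (all(is.na(score))) score <- -tab$final_sse
  best <- which.max(score)
  list(model = runs[[best]]$model, report = runs[[best]]$report,
       summary = tab, best_seed = seeds[best])
}

#' Serialize a network to JSON
#'
#' @param model A `neural_model`.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
nn_to_json <- function(model, path = NULL) {
  obj <- list(n_inputs = model$n_inputs, n_hidden = model$n_hidden,
              IW = model$IW, b = model$b, LW = model$LW, a = model$a,
              norm_in = model$norm_in, norm_out = model$norm_out,
              seed = model$seed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Restore a network from JSON
#'
#' @param path File written by [nn_to_json()] (or a JSON string).
#' @return A `neural_model`.
#' @export
nn_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(
    list(IW = matrix(obj$IW, obj$n_hidden, obj$n_inputs),
         b = as.numeric(obj$b), LW = as.numeric(obj$LW),
         a = as.numeric(obj$a),
         norm_in = lapply(obj$norm_in, as.numeric),
         norm_out = lapply(obj$norm_out, as.numeric),
         n_hidden = as.integer(obj$n_hidden),
         n_inputs = as.integer(obj$n_inputs),
         seed = obj$seed),
    class = "neural_model"
  )
}
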