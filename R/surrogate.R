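# Gaussian radial-basis-function network surrogate
#
# Inputs are affinely mapped to [0, 1] per dimension (from the design
# domain when given, else from the data range) and outputs are
# standardized, so that the shared kernel width is meaningful across
# parameters of very different magnitudes. Centers sit at all training
# points; the output layer is solved by ridge-regularized least squares,
# which at the default tiny ridge is numerically conditioned interpolation.

#' Train the RBF-network surrogate
#'
#' Fits a Gaussian-kernel radial-basis-function network mapping the
#' operating parameters to one or more responses (typically the thermal
#' penetration `hpm` and surface temperature `st`). The kernel width is the
#' median pairwise distance between normalized centers times
#' `width_factor`; weights solve `(Phi + ridge I) W = Y`. Deterministic.
#'
#' @param x Data frame or matrix of design points (n x d).
#' @param y Responses: vector, matrix or data frame (n x m) with column
#'   names.
#' @param domain Optional [design_domain()] fixing the input normalization;
#'   defaults to the data range.
#' @param width_factor Multiplier on the median-distance kernel width.
#' @param ridge Ridge regularization of the kernel system; increased
#'   automatically (with a warning) if the system is ill-conditioned.
#' @return An object of class `rbf_surrogate`.
#' @export
train_rbf <- function(x, y, domain = NULL, width_factor = 1, ridge = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(dim(y))) y <- matrix(y, ncol = 1, dimnames = list(NULL, "y"))
  y <- as.matrix(y)
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(ncol(y)))
  if (nrow(x) != nrow(y)) stop("x and y disagree on n", call. = FALSE)
  if (nrow(x) < 5) stop("at least 5 samples are required", call. = FALSE)

  if (!is.null(domain)) {
    stopifnot(inherits(domain, "design_domain"), ncol(x) == ncol(domain))
    x_lower <- domain["lower", ]; x_range <- domain["upper", ] - x_lower
  } else {
    x_lower <- apply(x, 2, min); x_range <- apply(x, 2, max) - x_lower
    x_range[x_range == 0] <- 1
  }
  xn <- sweep(sweep(x, 2, x_lower), 2, x_range, `/`)

  d2 <- as.matrix(stats::dist(xn))^2
  if (any(d2[upper.tri(d2)] < 1e-20)) {
    dup <- which(d2 < 1e-20 & upper.tri(d2), arr.ind = TRUE)
    conflicting <- any(abs(y[dup[, 1], , drop = FALSE] -
                             y[dup[, 2], , drop = FALSE]) > 1e-10)
    if (conflicting) {
      stop("duplicate design points with conflicting responses", call. = FALSE)
    }
  }
  width <- width_factor * stats::median(sqrt(d2[upper.tri(d2)]))
  if (!is.finite(width) || width <= 0) width <- 1

  y_mean <- colMeans(y)
  y_sd <- apply(y, 2, stats::sd)
  constant <- y_sd < .Machine$double.eps * (abs(y_mean) + 1)
  y_sd[constant] <- 1
  ys <- sweep(sweep(y, 2, y_mean), 2, y_sd, `/`)

  phi <- exp(-d2 / (2 * width^2))
  w <- NULL
  for (lam in ridge * 10^(0:8)) {
    w <- tryCatch(solve(phi + diag(lam, nrow(phi)), ys),
                  error = function(e) NULL)
    if (!is.null(w)) {
      if (lam > ridge) {
        warning("kernel system ill-conditioned; ridge increased to ", lam,
                call. = FALSE)
      }
      ridge <- lam
      break
    }
  }
  if (is.null(w)) stop("kernel system could not be solved", call. = FALSE)

  structure(
    list(centers = xn, width = width, weights = w, ridge = ridge,
         responses = colnames(y), constant = constant,
         scaler = list(x_lower = x_lower, x_range = x_range,
                       y_mean = y_mean, y_sd = y_sd),
         factors = colnames(x)),
    class = "rbf_surrogate"
  )
}

#' Predict from the RBF surrogate
#'
#' Smooth deterministic evaluation of the trained network. Points more than
#' 10 percent outside the normalized training domain trigger an
#' extrapolation warning.
#'
#' @param object An `rbf_surrogate`.
#' @param newdata Matrix or data frame of operating points (rows), in the
#'   original units.
#' @param ... Unused.
#' @return Numeric matrix, one column per response.
#' @export
predict.rbf_surrogate <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != ncol(object$centers)) {
    stop("newdata has the wrong number of columns", call. = FALSE)
  }
  sc <- object$scaler
  xn <- sweep(sweep(x, 2, sc$x_lower), 2, sc$x_range, `/`)
  if (any(xn < -0.1) || any(xn > 1.1)) {
    warning("predicting more than 10% outside the design domain",
            call. = FALSE)
  }
  # squared distances to all centers, vectorized
  cc <- object$centers
  d2 <- outer(rowSums(xn^2), rowSums(cc^2), `+`) - 2 * xn %*% t(cc)
  d2[d2 < 0] <- 0
  phi <- exp(-d2 / (2 * object$width^2))
  ys <- phi %*% object$weights
  sweep(sweep(ys, 2, sc$y_sd, `*`), 2, sc$y_mean, `+`)
}

#' Surrogate error metrics
#'
#' Per-sample relative error `RE = (y - yhat) / y` (positive means the
#' surrogate under-predicts), the sum of squared errors `SSE`, total sum of
#' squares `SST`, `RMSE = sqrt(SSE / k)` and `R^2 = 1 - SSE / SST`. Samples
#' with `y = 0` are excluded from RE (and flagged); `R^2` is `NA` (flagged)
#' when the true responses are constant (`SST = 0`).
#'
#' @param y_true,y_pred Equal-length numeric vectors (`k >= 1`).
#' @return An object of class `error_metrics`: `re`, `re_range`, `sse`,
#'   `sst`, `rmse`, `r2`, `k`, `excluded` (indices dropped from RE).
#' @export
error_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  k <- length(y_true)
  if (k == 0) stop("k must be at least 1", call. = FALSE)
  err <- y_true - y_pred
  excluded <- which(y_true == 0)
  re <- rep(NA_real_, k)
  ok <- y_true != 0
  re[ok] <- err[ok] / y_true[ok]
  sse <- sum(err^2)
  sst <- sum((y_true - mean(y_true))^2)
  structure(
    list(re = re,
         re_range = if (any(ok)) range(re[ok]) else c(NA_real_, NA_real_),
         sse = sse, sst = sst, rmse = sqrt(sse / k),
         r2 = if (sst > 0) 1 - sse / sst else NA_real_,
         k = k, excluded = excluded),
    class = "error_metrics"
  )
}

#' @export
print.error_metrics <- function(x, ...) {
  cat(sprintf("k = %d samples\n", x$k))
  cat(sprintf("RE range: [%.4g, %.4g]  (x100 for percent)\n",
              x$re_range[1], x$re_range[2]))
  cat(sprintf("SSE = %.6g, SST = %.6g, RMSE = %.6g, R^2 = %.6g\n",
              x$sse, x$sst, x$rmse, x$r2))
  if (length(x$excluded)) {
    cat("RE undefined (y = 0) for samples:",
        paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.rbf_surrogate <- function(x, ...) {
  cat(sprintf(
    "Gaussian RBF network: %d centers, %d inputs -> %s; width %.4g, ridge %g\n",
    nrow(x$centers), ncol(x$centers),
    paste(x$responses, collapse = ", "), x$width, x$ridge))
  invisible(x)
}

#' Save / load a trained surrogate as JSON
#'
#' @param model An `rbf_surrogate`.
#' @param path JSON file path.
#' @return `path` (save) or the restored `rbf_surrogate` (load).
#' @export
save_surrogate <- function(model, path) {
  stopifnot(inherits(model, "rbf_surrogate"))
  obj <- list(
    centers = model$centers, width = model$width,
    weights = model$weights, ridge = model$ridge,
    responses = model$responses, constant = model$constant,
    scaler = model$scaler, factors = model$factors
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- as.matrix(obj$centers)
  colnames(centers) <- obj$factors
  weights <- as.matrix(obj$weights)
  colnames(weights) <- obj$responses
  scaler <- lapply(obj$scaler, unlist)
  names(scaler$x_lower) <- names(scaler$x_range) <- obj$factors
  names(scaler$y_mean) <- names(scaler$y_sd) <- obj$responses
  structure(
    list(centers = centers, width = obj$width,
         weights = weights, ridge = obj$ridge,
         responses = obj$responses,
         constant = stats::setNames(obj$constant, obj$responses),
         scaler = scaler, factors = obj$factors),
    class = "rbf_surrogate"
  )
}
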