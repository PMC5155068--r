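# Box-Cox normalization of raw IPD values: the shifted-power transform
# IPD_t = ((IPD + alpha)^lambda - 1) / lambda, joint (alpha, lambda)
# optimization against a skewness/kurtosis objective, and per-sample
# grand-mean centering for cross-sample comparability.

BOXCOX_LOG_EPS <- 1e-8

#' Box-Cox transform parameters
#'
#' The shipped defaults are the shift/power pair used for the SMRT IPD
#' analysis (alpha = 0.311, lambda = 0.151), chosen to optimize skewness and
#' kurtosis across time points; [optimize_params()] re-derives a pair for
#' arbitrary data.
#'
#' @param alpha Shift; every transformed value must satisfy `x + alpha > 0`.
#' @param lambda Power; `|lambda| < 1e-8` is treated as the log limit.
#' @param objective_value Optional objective at these parameters.
#' @param fitted_on Optional character vector of sample ids the fit used.
#' @return An object of class `transform_params`.
#' @export
transform_params <- function(alpha = 0.311, lambda = 0.151,
                             objective_value = NA_real_,
                             fitted_on = character()) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda))
  structure(list(alpha = alpha, lambda = lambda,
                 objective_value = objective_value, fitted_on = fitted_on),
            class = "transform_params")
}

#' @export
print.transform_params <- function(x, ...) {
  cat(sprintf("Box-Cox params: alpha = %.6g, lambda = %.6g", x$alpha, x$lambda))
  if (is.finite(x$objective_value)) {
    cat(sprintf(" (objective %.6g)", x$objective_value))
  }
  cat("\n")
  invisible(x)
}

#' Box-Cox transform of raw IPD values
#'
#' Computes `((x + alpha)^lambda - 1) / lambda`, using the `log(x + alpha)`
#' limit when `|lambda|` is below 1e-8. Strictly increasing in `x` for any
#' valid parameters.
#'
#' @param x Positive raw values.
#' @param params A [transform_params()].
#' @return Transformed values.
#' @export
boxcox_transform <- function(x, params = transform_params()) {
  stopifnot(inherits(params, "transform_params"))
  shifted <- x + params$alpha
  if (any(shifted <= 0)) {
    stop("value + alpha must be positive; offending value: ",
         format(x[which(shifted <= 0)[1L]]))
  }
  if (abs(params$lambda) < BOXCOX_LOG_EPS) {
    log(shifted)
  } else {
    (shifted^params$lambda - 1) / params$lambda
  }
}

#' Inverse Box-Cox transform
#'
#' @param y Transformed values.
#' @param params A [transform_params()].
#' @return Raw values such that `boxcox_transform(x, params) == y`.
#' @export
boxcox_inverse <- function(y, params = transform_params()) {
  stopifnot(inherits(params, "transform_params"))
  if (abs(params$lambda) < BOXCOX_LOG_EPS) {
    exp(y) - params$alpha
  } else {
    (params$lambda * y + 1)^(1 / params$lambda) - params$alpha
  }
}

sample_skewness <- function(x) {
  m <- mean(x); d <- x - m
  m2 <- mean(d^2)
  mean(d^3) / m2^1.5
}

sample_excess_kurtosis <- function(x) {
  m <- mean(x); d <- x - m
  m2 <- mean(d^2)
  mean(d^4) / m2^2 - 3
}

# Sum over datasets of skewness^2 + excess kurtosis^2 after transforming.
# log(x + alpha) is cached by the caller for grid speed.
moment_objective_from_logs <- function(logs_list, lambda) {
  total <- 0
  for (lg in logs_list) {
    y <- if (abs(lambda) < BOXCOX_LOG_EPS) lg else (exp(lambda * lg) - 1) / lambda
    total <- total + sample_skewness(y)^2 + sample_excess_kurtosis(y)^2
  }
  total
}

#' Optimize Box-Cox parameters against a moment objective
#'
#' Minimizes the summed squared skewness plus squared excess kurtosis of the
#' transformed values across the supplied datasets: a coarse grid search over
#' (alpha, lambda) followed by a Nelder-Mead polish from the best grid point.
#' Deterministic given the grids.
#'
#' @param datasets List of numeric vectors (one per sample), each with at
#'   least 4 values and non-zero variance.
#' @param alpha_grid,lambda_grid Grid values; defaults span \[0.01, 1\] with
#'   50 points each.
#' @return A [transform_params()] with `objective_value` and `fitted_on`
#'   filled in.
#' @export
optimize_params <- function(datasets,
                            alpha_grid = seq(0.01, 1, length.out = 50L),
                            lambda_grid = seq(0.01, 1, length.out = 50L)) {
  if (!is.list(datasets)) datasets <- list(datasets)
  if (length(datasets) < 1L || !length(alpha_grid) || !length(lambda_grid)) {
    stop("need at least one dataset and non-empty grids")
  }
  for (d in datasets) {
    if (length(d) < 4L) stop("each dataset needs >= 4 values")
    if (stats::var(d) == 0) stop("degenerate dataset with zero variance")
  }
  minx <- min(vapply(datasets, min, numeric(1L)))
  best <- list(obj = Inf, alpha = NA_real_, lambda = NA_real_)
  for (a in alpha_grid) {
    if (minx + a <= 0) next
    logs <- lapply(datasets, function(d) log(d + a))
    for (l in lambda_grid) {
      obj <- moment_objective_from_logs(logs, l)
      if (is.finite(obj) && obj < best$obj) best <- list(obj = obj, alpha = a, lambda = l)
    }
  }
  if (!is.finite(best$obj)) stop("no feasible grid point (alpha too small?)")
  fn <- function(par) {
    if (minx + par[1L] <= 0) return(Inf)
    logs <- lapply(datasets, function(d) log(d + par[1L]))
    obj <- moment_objective_from_logs(logs, par[2L])
    if (is.finite(obj)) obj else Inf
  }
  polish <- stats::optim(c(best$alpha, best$lambda), fn, method = "Nelder-Mead",
                         control = list(reltol = 1e-10, maxit = 500L))
  if (polish$value <= best$obj) {
    transform_params(polish$par[1L], polish$par[2L],
                     objective_value = polish$value,
                     fitted_on = names(datasets) %||% character())
  } else {
    transform_params(best$alpha, best$lambda, objective_value = best$obj,
                     fitted_on = names(datasets) %||% character())
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Center transformed values per sample
#'
#' Subtracts, per sample, the grand mean of the transformed values over all
#' assessed reference positions from every value of that sample, so that
#' every sample's distribution is centered at zero for direct comparison
#' between time points. Within-sample differences are preserved exactly.
#'
#' @param values_by_sample Named list of numeric vectors (one per sample), or
#'   a single numeric vector.
#' @return List with `centered` (same shape as the input) and `offsets`
#'   (named numeric, the subtracted per-sample means).
#' @export
center_dataset <- function(values_by_sample) {
  single <- !is.list(values_by_sample)
  if (single) values_by_sample <- list(sample = values_by_sample)
  if (any(!vapply(values_by_sample, length, integer(1L)))) {
    stop("cannot center an empty sample")
  }
  offsets <- vapply(values_by_sample, mean, numeric(1L))
  centered <- Map(function(v, o) v - o, values_by_sample, offsets)
  if (single) centered <- centered[[1L]]
  list(centered = centered, offsets = offsets)
}

#' Serialize transform parameters to a key-value text file
#'
#' @param params A [transform_params()].
#' @param path Output path.
#' @param overwrite Logical.
#' @export
write_transform_params <- function(params, path, overwrite = FALSE) {
  stopifnot(inherits(params, "transform_params"))
  if (file.exists(path) && !overwrite) stop("file exists: ", path)
  lines <- c(sprintf("alpha\t%.17g", params$alpha),
             sprintf("lambda\t%.17g", params$lambda),
             sprintf("objective_value\t%.17g", params$objective_value),
             sprintf("fitted_on\t%s", paste(params$fitted_on, collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read transform parameters written by [write_transform_params()]
#'
#' @param path Key-value file path.
#' @return A [transform_params()].
#' @export
read_transform_params <- function(path) {
  kv <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                          col.names = c("key", "value"),
                          colClasses = "character")
  get <- function(k) kv$value[match(k, kv$key)]
  transform_params(as.numeric(get("alpha")), as.numeric(get("lambda")),
                   objective_value = as.numeric(get("objective_value")),
                   fitted_on = strsplit(get("fitted_on"), ",")[[1L]] %||% character())
}
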