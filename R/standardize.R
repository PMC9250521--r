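#' Fit a Z-score standardizer on training pair features
#'
#' Computes the per-feature mean `mu(l)` and *population* standard deviation
#' `sigma(l)` (the 1/n form, not 1/(n-1)) of a training feature matrix.
#' Held-out data must be transformed with the statistics fitted on the
#' training rows only ([apply_standardizer()] never recomputes them).
#'
#' @param x Numeric matrix (rows = pairs, columns = features); at least one
#'   row.
#' @return An object of class `nvdt_standardizer`: list with `means`,
#'   `stds`, `n_fit`, `feature_names`, and `zero_var` (logical flag per
#'   feature marking sigma = 0 columns).
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("cannot fit a standardizer on an empty matrix")
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(sweep(x, 2L, mu)^2))
  structure(
    list(means = unname(mu), stds = unname(sigma), n_fit = nrow(x),
         feature_names = colnames(x), zero_var = unname(sigma == 0)),
    class = "nvdt_standardizer")
}

#' Apply a fitted standardizer
#'
#' Transforms features as `(x - mu(l)) / sigma(l)` using the fitted training
#' statistics. Zero-variance columns map to 0.
#'
#' @param state An `nvdt_standardizer` from [fit_standardizer()].
#' @param x Numeric matrix with the same number of columns as fitted.
#' @return Transformed matrix of the same shape.
#' @export
apply_standardizer <- function(state, x) {
  stopifnot(inherits(state, "nvdt_standardizer"))
  x <- as.matrix(x)
  if (ncol(x) != length(state$means))
    stop("feature dimension mismatch: standardizer fitted on ",
         length(state$means), " features, data has ", ncol(x))
  out <- sweep(x, 2L, state$means)
  denom <- ifelse(state$zero_var, 1, state$stds)
  out <- sweep(out, 2L, denom, "/")
  if (any(state$zero_var)) out[, state$zero_var] <- 0
  out
}

#' @export
print.nvdt_standardizer <- function(x, ...) {
  cat("Z-score standardizer:", length(x$means), "features fitted on",
      x$n_fit, "pairs;", sum(x$zero_var), "zero-variance column(s)\n")
  invisible(x)
}

#' Save / load a standardizer as JSON
#'
#' @param state An `nvdt_standardizer`.
#' @param path JSON file path.
#' @return `path` invisibly; `load_standardizer()` returns the restored
#'   object.
#' @export
save_standardizer <- function(state, path) {
  stopifnot(inherits(state, "nvdt_standardizer"))
  jsonlite::write_json(
    list(means = state$means, stds = state$stds, n_fit = state$n_fit,
         feature_names = state$feature_names),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_standardizer
#' @export
load_standardizer <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(means = as.numeric(raw$means), stds = as.numeric(raw$stds),
         n_fit = as.integer(raw$n_fit),
         feature_names = as.character(raw$feature_names),
         zero_var = as.numeric(raw$stds) == 0),
    class = "nvdt_standardizer")
}
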