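#' Fit a multivariate-normal similarity model
#'
#' Models the distribution of difference vectors (speed, area change,
#' brightness change, compactness change) between a cell and itself in
#' the next frame as a multivariate normal. The same machinery, fitted
#' on difference vectors of known divisions instead, yields the mitosis
#' detector's pattern model.
#'
#' @param d A data frame of difference vectors with columns `ds`,
#'   `d_area`, `d_grey`, `d_comp` (extra columns are ignored).
#' @param ridge Relative ridge added to the covariance diagonal when it
#'   is near singular; the absolute ridge is
#'   `ridge * trace(Sigma) / n`.
#' @return An object of class `similarity_model` with elements `mu`
#'   (mean vector), `sigma` (covariance), `n` (dimension, 4) and
#'   `n_samples`.
#' @export
fit_similarity_model <- function(d, ridge = 1e-6) {
  vars <- c("ds", "d_area", "d_grey", "d_comp")
  stopifnot(all(vars %in% names(d)))
  x <- as.matrix(d[, vars])
  x <- x[complete.cases(x), , drop = FALSE]
  n <- length(vars)
  if (nrow(x) < n + 1L)
    stop("need at least ", n + 1L, " difference vectors to fit the model")
  mu <- colMeans(x)
  sigma <- unname(cov(x))
  eps <- ridge * sum(diag(sigma)) / n
  if (eps <= 0) eps <- ridge
  # regularize until positive definite
  while (inherits(try(chol(sigma), silent = TRUE), "try-error")) {
    sigma <- sigma + diag(eps, n)
    eps <- eps * 10
  }
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <
      1e-12 * sum(diag(sigma)))
    sigma <- sigma + diag(ridge * sum(diag(sigma)) / n, n)
  structure(list(mu = mu, sigma = sigma, n = n, n_samples = nrow(x)),
            class = "similarity_model")
}

#' Multivariate-normal similarity density
#'
#' Evaluates the density
#' \deqn{(2\pi)^{-n/2} |\Sigma|^{-1/2}
#'   \exp(-\tfrac{1}{2}(d-\mu)^\top \Sigma^{-1} (d-\mu))}
#' of one or more difference vectors under a fitted model. High values
#' mean "this transition looks like the transitions the model was
#' fitted on".
#'
#' @param d A data frame of difference vectors (columns `ds`, `d_area`,
#'   `d_grey`, `d_comp`) or a numeric vector of length `model$n`.
#' @param model A `similarity_model`.
#' @return Numeric vector of density values, one per row of `d`.
#' @export
similarity_probability <- function(d, model) {
  stopifnot(inherits(model, "similarity_model"))
  if (is.numeric(d) && is.null(dim(d))) d <- matrix(d, nrow = 1)
  else d <- as.matrix(as.data.frame(d)[, c("ds", "d_area", "d_grey", "d_comp")])
  stopifnot(ncol(d) == model$n)
  ch <- tryCatch(chol(model$sigma),
                 error = function(e) stop("model covariance is singular"))
  centered <- sweep(d, 2, model$mu)
  # quadratic form via the Cholesky factor: z = L^-T (d - mu)
  z <- backsolve(ch, t(centered), transpose = TRUE)
  q <- colSums(z^2)
  log_det <- 2 * sum(log(diag(ch)))
  exp(-0.5 * (model$n * log(2 * pi) + log_det + q))
}

#' @export
print.similarity_model <- function(x, ...) {
  cat("Multivariate-normal similarity model (n =", x$n, ")\n")
  cat("fitted on", x$n_samples, "difference vectors\n")
  cat("mu:", signif(x$mu, 4), "\n")
  if (!is.null(x$t_mit)) cat("mitosis threshold t_mit:", signif(x$t_mit, 4), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a similarity model
#'
#' One row per difference-vector component with its fitted mean and
#' standard deviation.
#'
#' @param x A `similarity_model`.
#' @param ... Unused.
#' @method tidy similarity_model
#' @export
tidy.similarity_model <- function(x, ...) {
  tibble(term = names(x$mu), mean = unname(x$mu),
         sd = sqrt(diag(x$sigma)))
}

#' Glance at a similarity model
#'
#' @param x A `similarity_model`.
#' @param ... Unused.
#' @method glance similarity_model
#' @export
glance.similarity_model <- function(x, ...) {
  tibble(n_dim = x$n, n_samples = x$n_samples,
         log_det_sigma = determinant(x$sigma)$modulus[1],
         peak_density = similarity_probability(x$mu, x),
         t_mit = if (is.null(x$t_mit)) NA_real_ else x$t_mit)
}

#' Write / read a similarity model as JSON
#'
#' @param model A `similarity_model`.
#' @param path File path.
#' @return `read_similarity_model` returns the model; `write_similarity_model`
#'   returns `path` invisibly.
#' @export
write_similarity_model <- function(model, path) {
  stopifnot(inherits(model, "similarity_model"))
  obj <- list(mu = unname(model$mu), sigma = as.vector(t(model$sigma)),
              n = model$n, n_samples = model$n_samples,
              names = names(model$mu))
  if (!is.null(model$t_mit)) obj$t_mit <- model$t_mit
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_similarity_model
#' @export
read_similarity_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- obj$n
  m <- structure(list(mu = setNames(obj$mu, obj$names),
                      sigma = matrix(obj$sigma, n, n, byrow = TRUE),
                      n = n, n_samples = obj$n_samples),
                 class = "similarity_model")
  if (!is.null(obj$t_mit)) m$t_mit <- obj$t_mit
  m
}
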