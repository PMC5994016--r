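#' Kernel specification for Gaussian-process regression
#'
#' The seven covariance families used by the optimizer. All but the neural
#' network kernel are stationary. Scaled squared distances are
#' `r = sum_d (x1_d - x2_d)^2 / l_d^2` (ARD: one lengthscale per input
#' dimension) and `s = |x1 - x2|^2 / l^2` (ISO: a single scalar lengthscale).
#'
#' * `matern32_ard`: `sigma2 (1 + sqrt(3 r)) exp(-sqrt(3 r))`
#' * `matern52_ard`: `sigma2 (1 + sqrt(5 r) + 5 r / 3) exp(-sqrt(5 r))`
#' * `rq_ard` / `rq_iso`: `sigma2 (1 + r / (2 alpha))^(-alpha)`
#' * `gabor_ard`: `exp(-sum_d t_d^2 / l_d^2) * cos(2 pi sum_d t_d / p_d)`,
#'   `t = x1 - x2` (a unit-amplitude Gabor; outputs are standardized
#'   internally during training so no separate signal variance is needed)
#' * `neural_network`:
#'   `sigma2 * asin( x1' P x2 / sqrt((1 + x1' P x1)(1 + x2' P x2)) )` with
#'   `P = diag(1 / l^2)` (arcsine network kernel)
#' * `se_ard`: `sigma2 exp(-r / 2)`
#'
#' @param family one of `"matern32_ard"`, `"matern52_ard"`, `"rq_ard"`,
#'   `"rq_iso"`, `"gabor_ard"`, `"neural_network"`, `"se_ard"`.
#' @param lengthscales positive vector (length = input dimension for ARD
#'   families, scalar for `rq_iso`).
#' @param signal_variance sigma2 > 0.
#' @param alpha shape parameter (rational quadratic families).
#' @param periods positive period vector (Gabor only).
#' @param noise_variance observation noise sigma_n^2 >= 0.
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(family, lengthscales, signal_variance = 1,
                        alpha = 2, periods = NULL, noise_variance = 1e-4) {
  family <- match.arg(family, gp_kernel_families())
  if (any(lengthscales <= 0) || signal_variance <= 0 || alpha <= 0 ||
      noise_variance < 0 || (!is.null(periods) && any(periods <= 0)))
    stop("kernel hyperparameters must be positive")
  if (family == "gabor_ard" && is.null(periods))
    stop("gabor_ard requires periods")
  structure(list(family = family, lengthscales = as.numeric(lengthscales),
                 signal_variance = signal_variance, alpha = alpha,
                 periods = if (is.null(periods)) NULL else as.numeric(periods),
                 noise_variance = noise_variance),
            class = "kernel_spec")
}

#' The seven kernel family names
#' @return character vector of length 7.
#' @export
gp_kernel_families <- function() {
  c("matern32_ard", "matern52_ard", "rq_ard", "rq_iso",
    "gabor_ard", "neural_network", "se_ard")
}

# cross-covariance matrix K(X1, X2); X1, X2 are n x d matrices
kernel_matrix <- function(spec, X1, X2 = X1) {
  X1 <- rbind(X1); X2 <- rbind(X2)
  d <- ncol(X1)
  if (ncol(X2) != d) stop("input dimension mismatch")
  ls <- spec$lengthscales
  if (spec$family == "rq_iso") {
    if (length(ls) != 1L) stop("rq_iso uses a scalar lengthscale")
    ls <- rep(ls, d)
  } else if (spec$family != "neural_network" && length(ls) != d &&
             length(ls) != 1L) {
    stop("lengthscale dimensionality must match the input dimension")
  }
  if (length(ls) == 1L) ls <- rep(ls, d)

  sq <- function(scale) {
    # sum_d (x1_d - x2_d)^2 / scale_d^2 via the expansion trick
    A <- sweep(X1, 2L, scale, "/"); B <- sweep(X2, 2L, scale, "/")
    r <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    pmax(r, 0)
  }

  s2 <- spec$signal_variance
  switch(spec$family,
    se_ard = s2 * exp(-sq(ls) / 2),
    matern32_ard = { u <- sqrt(3 * sq(ls)); s2 * (1 + u) * exp(-u) },
    matern52_ard = { r <- sq(ls); u <- sqrt(5 * r)
                     s2 * (1 + u + 5 * r / 3) * exp(-u) },
    rq_ard = s2 * (1 + sq(ls) / (2 * spec$alpha))^(-spec$alpha),
    rq_iso = s2 * (1 + sq(ls) / (2 * spec$alpha))^(-spec$alpha),
    gabor_ard = {
      if (length(spec$periods) != d && length(spec$periods) != 1L)
        stop("period dimensionality must match the input dimension")
      p <- if (length(spec$periods) == 1L) rep(spec$periods, d) else spec$periods
      env <- exp(-sq(ls))
      phase <- outer(rowSums(sweep(X1, 2L, p, "/")),
                     rowSums(sweep(X2, 2L, p, "/")), "-")
      env * cos(2 * pi * phase)
    },
    neural_network = {
      w <- 1 / ls^2
      Xw1 <- sweep(X1, 2L, sqrt(w), "*"); Xw2 <- sweep(X2, 2L, sqrt(w), "*")
      num <- Xw1 %*% t(Xw2)
      d1 <- 1 + rowSums(Xw1^2); d2 <- 1 + rowSums(Xw2^2)
      arg <- num / sqrt(outer(d1, d2))
      s2 * asin(pmin(pmax(arg, -1), 1))
    }
  )
}

# prior variances k(x, x) without forming the full test Gram matrix
kernel_diag <- function(spec, X) {
  X <- rbind(X)
  n <- nrow(X)
  if (spec$family == "gabor_ard") return(rep(1, n))
  if (spec$family == "neural_network") {
    w <- 1 / spec$lengthscales^2
    s <- rowSums(sweep(X, 2L, w, "*") * X)
    return(spec$signal_variance * asin(pmin(pmax(s / (1 + s), -1), 1)))
  }
  rep(spec$signal_variance, n)
}

#' Evaluate a kernel at a pair of points
#'
#' @param spec a `kernel_spec`.
#' @param x1,x2 numeric vectors of equal length.
#' @return scalar covariance; symmetric in `x1`, `x2`.
#' @export
kernel_eval <- function(spec, x1, x2) {
  if (length(x1) != length(x2)) stop("input dimension mismatch")
  as.numeric(kernel_matrix(spec, matrix(x1, 1L), matrix(x2, 1L)))
}

#' Construct a GP model with fixed hyperparameters
#'
#' Builds the posterior machinery (Cholesky factor of the noisy Gram matrix,
#' weight vector) for a given kernel specification without any training.
#'
#' @param spec a `kernel_spec`.
#' @param inputs n x d matrix of training points.
#' @param outputs length-n numeric vector.
#' @param mean_constant prior mean value (default: mean of `outputs`).
#' @param y_sd internal output scale (default 1: raw outputs are regressed).
#' @return an object of class `gp_model`.
#' @export
gp_model <- function(spec, inputs, outputs, mean_constant = mean(outputs),
                     y_sd = 1) {
  new_gp_model(spec, rbind(inputs), as.numeric(outputs), mean_constant, y_sd)
}

new_gp_model <- function(spec, X, y, mean_constant, y_sd) {
  n <- nrow(X)
  K <- kernel_matrix(spec, X) + diag(spec$noise_variance + 1e-10, n)
  L <- tryCatch(chol(K), error = function(e)
    stop("Gram matrix is not positive definite after jitter: ",
         conditionMessage(e)))
  z <- (y - mean_constant) / y_sd
  alpha <- backsolve(L, backsolve(L, z, transpose = TRUE))
  structure(list(kernel = spec, train_inputs = X, train_outputs = y,
                 mean_constant = mean_constant, y_sd = y_sd,
                 chol_upper = L, alpha = alpha),
            class = "gp_model")
}

#' Negative log marginal likelihood of a GP model
#'
#' Standard Gaussian marginal likelihood of the centered (and internally
#' scaled) outputs under `K + sigma_n^2 I`.
#'
#' @param model a `gp_model` (from [train_gp()] or `new_gp_model`).
#' @return scalar NLML.
#' @export
nlml <- function(model) {
  L <- model$chol_upper
  z <- (model$train_outputs - model$mean_constant) / model$y_sd
  n <- length(z)
  0.5 * sum(z * model$alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
}

# pack/unpack log-hyperparameters for a family
hyper_template <- function(family, d) {
  switch(family,
    rq_iso = c(ls = 1L, s2 = 1L, alpha = 1L, noise = 1L),
    rq_ard = c(ls = d, s2 = 1L, alpha = 1L, noise = 1L),
    gabor_ard = c(ls = d, periods = d, noise = 1L),
    neural_network = c(ls = d, s2 = 1L, noise = 1L),
    c(ls = d, s2 = 1L, noise = 1L))
}

spec_from_log_hypers <- function(family, theta, d) {
  v <- exp(theta)
  i <- 0L
  take <- function(k) { out <- v[i + seq_len(k)]; i <<- i + k; out }
  ls <- take(if (family == "rq_iso") 1L else d)
  s2 <- 1; alpha <- 2; periods <- NULL
  if (family %in% c("rq_iso", "rq_ard")) { s2 <- take(1L); alpha <- take(1L) }
  else if (family == "gabor_ard") periods <- take(d)
  else s2 <- take(1L)
  noise <- take(1L)
  kernel_spec(family, ls, signal_variance = s2, alpha = alpha,
              periods = periods, noise_variance = noise)
}

default_log_hypers <- function(family, X, d) {
  # median pairwise distance per dimension as the lengthscale scale
  rng <- apply(X, 2L, function(col) {
    s <- stats::median(abs(outer(col, col, "-")))
    if (s <= 0) s <- max(diff(range(col)), 1)
    s
  })
  ls <- log(rng)
  if (family == "rq_iso") ls <- log(stats::median(rng))
  s2 <- 0; alpha <- log(2); noise <- log(1e-2)
  if (family %in% c("rq_iso", "rq_ard")) c(ls, s2, alpha, noise)
  else if (family == "gabor_ard") c(ls, log(4 * rng), noise)
  else c(ls, s2, noise)
}

#' Train a GP by marginal-likelihood optimization
#'
#' Multi-restart local optimization (L-BFGS-B on log hyperparameters) of the
#' negative log marginal likelihood. Outputs are centered on their mean and
#' scaled by their standard deviation internally; predictions are returned on
#' the original scale. No hyper-priors are imposed; wide box bounds are used
#' only for numerical safety.
#'
#' @param family kernel family name (see [gp_kernel_families()]).
#' @param inputs n x d matrix of evaluated points.
#' @param outputs length-n vector of observed objective values.
#' @param seed integer seed controlling restart initialization.
#' @param restarts number of optimizer restarts.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param noise_variance optional fixed noise variance (on the standardized
#'   output scale); if `NULL` (default) the noise is a learned hyperparameter.
#' @return a trained `gp_model`.
#' @export
train_gp <- function(family, inputs, outputs, seed = 1L, restarts = 2L,
                     maxit = 60L, noise_variance = NULL) {
  X <- rbind(inputs)
  y <- as.numeric(outputs)
  n <- nrow(X); d <- ncol(X)
  if (n < 2L) stop("need at least 2 training points")
  mean_constant <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd <= 0) y_sd <- 1
  z <- (y - mean_constant) / y_sd

  # distance precomputation: per-dimension squared differences
  D2 <- lapply(seq_len(d), function(j) outer(X[, j], X[, j], "-")^2)
  sums1 <- function(w) Reduce(`+`, Map(`*`, D2, as.list(w)))

  obj <- function(theta) {
    spec <- tryCatch(spec_from_log_hypers(family, theta, d),
                     error = function(e) NULL)
    if (is.null(spec)) return(1e10)
    if (!is.null(noise_variance)) spec$noise_variance <- noise_variance
    ls <- spec$lengthscales
    if (length(ls) == 1L) ls <- rep(ls, d)
    K <- switch(spec$family,
      se_ard = spec$signal_variance * exp(-sums1(1 / (2 * ls^2))),
      matern32_ard = { u <- sqrt(3 * sums1(1 / ls^2))
                       spec$signal_variance * (1 + u) * exp(-u) },
      matern52_ard = { r <- sums1(1 / ls^2); u <- sqrt(5 * r)
                       spec$signal_variance * (1 + u + 5 * r / 3) * exp(-u) },
      rq_ard = spec$signal_variance *
        (1 + sums1(1 / ls^2) / (2 * spec$alpha))^(-spec$alpha),
      rq_iso = spec$signal_variance *
        (1 + sums1(1 / ls^2) / (2 * spec$alpha))^(-spec$alpha),
      gabor_ard = {
        p <- spec$periods
        if (length(p) == 1L) p <- rep(p, d)
        sums <- rowSums(sweep(X, 2L, p, "/"))
        exp(-sums1(1 / ls^2)) * cos(2 * pi * outer(sums, sums, "-"))
      },
      kernel_matrix(spec, X))
    K <- K + diag(spec$noise_variance + 1e-10, n)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    a <- backsolve(L, backsolve(L, z, transpose = TRUE))
    val <- 0.5 * sum(z * a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
    if (!is.finite(val)) 1e10 else val
  }

  set.seed(seed)
  theta0 <- default_log_hypers(family, X, d)
  lower <- rep(log(1e-4), length(theta0)); upper <- rep(log(1e6), length(theta0))
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- if (r == 1L) theta0 else theta0 + stats::rnorm(length(theta0), 0, 0.7)
    init <- pmin(pmax(init, lower), upper)
    fit <- tryCatch(
      stats::optim(init, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = maxit)),
      error = function(e) NULL)
    cand <- if (is.null(fit)) list(par = init, value = obj(init))
            else if (fit$value <= obj(init)) fit
            else list(par = init, value = obj(init))
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  if (is.null(best) || !is.finite(best$value))
    stop("all GP training restarts failed for family ", family)
  spec <- spec_from_log_hypers(family, best$par, d)
  if (!is.null(noise_variance)) spec$noise_variance <- noise_variance
  new_gp_model(spec, X, y, mean_constant, y_sd)
}

#' GP posterior prediction
#'
#' Standard Gaussian-process conditioning: posterior mean and variance of the
#' latent objective at test points, on the original output scale. Far from
#' all training data the mean reverts to the training mean and the variance
#' to the prior signal variance.
#'
#' @param model a trained `gp_model`.
#' @param X n x d matrix (or length-d vector) of test points.
#' @return list with numeric vectors `mean` and `variance`.
#' @export
predict_gp <- function(model, X) {
  X <- rbind(X)
  Ks <- kernel_matrix(model$kernel, model$train_inputs, X)    # n_train x n_test
  mu_z <- drop(crossprod(Ks, model$alpha))
  V <- backsolve(model$chol_upper, Ks, transpose = TRUE)
  kss <- kernel_diag(model$kernel, X)
  var_z <- pmax(kss - colSums(V^2), 0)
  list(mean = model$mean_constant + model$y_sd * mu_z,
       variance = model$y_sd^2 * var_z)
}

#' Serialize / restore a GP model snapshot
#'
#' Writes the kernel specification and training data as JSON so search runs
#' can be resumed.
#'
#' @param model a `gp_model`.
#' @param path JSON file path.
#' @return `write_gp_model` returns `path` invisibly; `read_gp_model`
#'   returns a `gp_model`.
#' @export
write_gp_model <- function(model, path) {
  payload <- list(kernel = model$kernel[!vapply(model$kernel, is.null, TRUE)],
                  train_inputs = model$train_inputs,
                  train_outputs = model$train_outputs,
                  mean_constant = model$mean_constant,
                  y_sd = model$y_sd)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gp_model
#' @export
read_gp_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- kernel_spec(p$kernel$family, p$kernel$lengthscales,
                      signal_variance = p$kernel$signal_variance %||% 1,
                      alpha = p$kernel$alpha %||% 2,
                      periods = p$kernel$periods,
                      noise_variance = p$kernel$noise_variance)
  new_gp_model(spec, rbind(p$train_inputs), p$train_outputs,
               p$mean_constant, p$y_sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
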