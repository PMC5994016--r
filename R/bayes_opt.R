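#' Search configuration for the multi-GP optimizer
#'
#' @param center parameter vector at the center of the search ball (rates in
#'   linear units for ODE mode, log10 wait-time offsets for SSA mode).
#' @param radius search ball radius (> 0).
#' @param kernel_families subset of [gp_kernel_families()] used each round.
#' @param kappa_values lower-confidence-bound trade-off values; higher
#'   favors exploration, lower exploitation. With 7 kernels and 3 kappa
#'   values each round proposes 21 candidates.
#' @param initial_points size of the initial hypersphere design.
#' @param replicates_per_point simulation replicates per evaluation.
#' @param rounds number of acquisition rounds after the initial design.
#' @param af_samples points sampled per acquisition-minimization repeat.
#' @param af_repeats number of repeats whose minimizers are coordinate-wise
#'   averaged.
#' @param reeval_pool,reeval_cap pool of top-scoring points considered for
#'   re-evaluation, and the cap on how many are returned.
#' @param af_local_scales standard deviations (as fractions of `radius`) of
#'   the Gaussian clouds placed around the best evaluated points during
#'   acquisition sampling; two scales give both coarse and fine refinement.
#' @param dedup_tol candidates closer than `dedup_tol * radius` are merged
#'   before evaluation.
#' @param log_objective if `TRUE` (default), the per-round GPs are trained on
#'   log10 of the objective rather than its raw value. The transform is
#'   monotone, so the acquisition argmin is unchanged, but it lets the
#'   surrogate resolve an objective spanning several decades (typical of the
#'   noiseless RMSD bowl near a ground truth). Set `FALSE` for noisy
#'   objectives whose values can be dominated by near-zero noise.
#' @param gp_restarts,gp_maxit GP training effort per kernel per round.
#' @param seed master seed for the whole search.
#' @return a list of class `search_config`.
#' @export
search_config <- function(center, radius,
                          kernel_families = gp_kernel_families(),
                          kappa_values = c(0.5, 2, 5),
                          initial_points = 50L,
                          replicates_per_point = 1L,
                          rounds = 10L,
                          af_samples = 5000L,
                          af_repeats = 10L,
                          reeval_pool = 50L,
                          reeval_cap = 16L,
                          af_local_scales = c(0.1, 0.01),
                          dedup_tol = 1e-6,
                          log_objective = TRUE,
                          gp_restarts = 2L,
                          gp_maxit = 60L,
                          seed = 1L) {
  if (radius <= 0) stop("radius must be positive")
  if (!length(kernel_families) || !length(kappa_values))
    stop("need at least one kernel family and one kappa value")
  if (any(c(initial_points, replicates_per_point, af_samples, af_repeats,
            reeval_pool, reeval_cap) < 1L))
    stop("all design counts must be >= 1")
  kernel_families <- match.arg(kernel_families, gp_kernel_families(),
                               several.ok = TRUE)
  structure(as.list(environment()), class = "search_config")
}

#' Sample points uniformly from a hypersphere (by volume)
#'
#' Directions uniform on the unit sphere; radii proportional to
#' `U^(1/d) * radius`, giving uniform density inside the ball.
#'
#' @param center numeric vector.
#' @param radius positive real.
#' @param n number of points.
#' @param seed integer seed.
#' @return n x d matrix; every row is within `radius` of `center`.
#' @export
sample_hypersphere <- function(center, radius, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(center)
  dirs <- matrix(stats::rnorm(n * d), n, d)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  radii <- radius * stats::runif(n)^(1 / d)
  sweep(dirs * radii, 2L, center, "+")
}

#' Lower confidence bound acquisition value
#'
#' `a_LCB(x) = mu(x) - kappa * sigma(x)`; minimized to pick the next
#' evaluation point.
#'
#' @param mu posterior mean(s).
#' @param sigma posterior standard deviation(s), >= 0.
#' @param kappa exploration weight, >= 0.
#' @return numeric vector.
#' @export
lcb <- function(mu, sigma, kappa) {
  if (any(sigma < 0)) stop("sigma must be >= 0")
  mu - kappa * sigma
}

clip_to_ball <- function(x, center, radius) {
  delta <- x - center
  nrm <- sqrt(sum(delta^2))
  if (nrm > radius) center + delta * (radius / nrm) else x
}

#' Minimize the acquisition function by repeated random sampling
#'
#' Each repeat draws `af_samples` points concentrated in relevant areas of
#' the search space — a mixture of uniform draws in the ball, isotropic
#' Gaussian clouds around the best evaluated points, and Gaussian clouds
#' shaped by the empirical covariance of those best points (which lets the
#' sampler follow narrow, correlated valleys of the objective) — evaluates
#' the LCB through the GP posterior, and keeps the sample minimizer. The
#' returned candidate is the coordinate-wise average of the per-repeat
#' minimizers, clipped into the search ball.
#'
#' @param model a trained `gp_model`.
#' @param kappa LCB exploration weight.
#' @param config a `search_config`.
#' @param seed integer seed.
#' @param best_points optional matrix of promising evaluated points around
#'   which half of the samples are concentrated.
#' @return the candidate point, with attribute `"repeat_minimizers"` (the
#'   per-repeat minimizers that were averaged).
#' @export
minimize_af <- function(model, kappa, config, seed = 1L, best_points = NULL) {
  set.seed(seed)
  d <- length(config$center)
  minimizers <- matrix(0, config$af_repeats, d)
  for (rep_i in seq_len(config$af_repeats)) {
    n_unif <- if (is.null(best_points)) config$af_samples
              else ceiling(config$af_samples / 2)
    pts <- sample_hypersphere(config$center, config$radius, n_unif)
    if (!is.null(best_points)) {
      n_loc <- config$af_samples - n_unif
      scales <- config$af_local_scales %||% 0.1
      anchors <- best_points[sample.int(nrow(best_points), n_loc,
                                        replace = TRUE), , drop = FALSE]
      sds <- config$radius * sample(scales, n_loc, replace = TRUE)
      local <- anchors + matrix(stats::rnorm(n_loc * d), n_loc, d) * sds
      local <- t(apply(local, 1L, clip_to_ball,
                       center = config$center, radius = config$radius))
      pts <- rbind(pts, local)
    }
    post <- predict_gp(model, pts)
    acq <- lcb(post$mean, sqrt(post$variance), kappa)
    minimizers[rep_i, ] <- pts[which.min(acq), ]
  }
  out <- clip_to_ball(colMeans(minimizers), config$center, config$radius)
  attr(out, "repeat_minimizers") <- minimizers
  out
}

#' Run the multi-GP Bayesian optimization loop
#'
#' Evaluates an initial hypersphere design, then iterates: every kernel
#' family is trained on all evaluations so far, one candidate per
#' (kernel, kappa) pair is produced by acquisition minimization, coincident
#' candidates are deduplicated, and the survivors are evaluated. Simulator
#' failures are logged and skipped without aborting the round.
#'
#' @param config a `search_config`.
#' @param objective either an [objective_config()] (points are scored with
#'   [evaluate_point()]) or a plain function `f(point) -> numeric` (plumbing
#'   test mode, useful for validating the optimizer on known surfaces).
#' @param log_path optional JSON-lines file receiving one record per
#'   candidate (round, kernel, kappa, point, rmsd, noise).
#' @return An object of class `search_state`: `evaluations` (data frame with
#'   point coordinates `x1..xd`, `rmsd`, `noise_variance`, `round`, `kernel`,
#'   `kappa`, `seed`), `models` (per-kernel GPs of the final round),
#'   `round_candidates` (per-round list of proposals before deduplication),
#'   and `incumbent` (row of `evaluations` with minimum rmsd).
#' @export
run_optimization <- function(config, objective, log_path = NULL) {
  d <- length(config$center)
  eval_objective <- function(point, seed) {
    if (is.function(objective)) {
      val <- objective(point)
      list(rmsd = val, noise_variance = 0, failed = !is.finite(val))
    } else {
      ev <- evaluate_point(point, objective, seed = seed)
      list(rmsd = ev$rmsd, noise_variance = ev$noise_variance,
           failed = ev$failed)
    }
  }

  rows <- list()
  add_row <- function(point, res, round, kernel, kappa, seed) {
    row <- as.data.frame(t(point))
    names(row) <- paste0("x", seq_len(d))
    row$rmsd <- res$rmsd; row$noise_variance <- res$noise_variance
    row$round <- round; row$kernel <- kernel; row$kappa <- kappa
    row$seed <- seed
    rows[[length(rows) + 1L]] <<- row
    if (!is.null(log_path)) {
      rec <- list(round = round, kernel = kernel, kappa = kappa,
                  point = unname(point), rmsd = res$rmsd,
                  noise = res$noise_variance)
      cat(jsonlite::toJSON(rec, digits = NA, auto_unbox = TRUE), "\n",
          sep = "", file = log_path, append = TRUE)
    }
  }

  init <- sample_hypersphere(config$center, config$radius,
                             config$initial_points, seed = config$seed)
  for (i in seq_len(nrow(init))) {
    s <- config$seed * 1000L + i
    res <- eval_objective(init[i, ], s)
    if (!res$failed) add_row(init[i, ], res, 0L, "initial", NA_real_, s)
  }

  models <- NULL
  round_candidates <- vector("list", config$rounds)
  for (round in seq_len(config$rounds)) {
    df <- do.call(rbind, rows)
    X <- as.matrix(df[, seq_len(d), drop = FALSE])
    y <- df$rmsd
    if (isTRUE(config$log_objective)) {
      floor_pos <- min(y[y > 0], na.rm = TRUE) / 2
      y <- log10(pmax(y, floor_pos))
    }
    models <- lapply(config$kernel_families, function(fam)
      tryCatch(train_gp(fam, X, y,
                        seed = config$seed + 37L * round,
                        restarts = config$gp_restarts,
                        maxit = config$gp_maxit),
               error = function(e) NULL))
    names(models) <- config$kernel_families
    ok <- !vapply(models, is.null, TRUE)

    n_best <- min(5L, nrow(X))
    best_points <- X[order(y)[seq_len(n_best)], , drop = FALSE]

    cands <- list()
    for (fam in config$kernel_families[ok]) {
      for (kp in config$kappa_values) {
        s <- config$seed + 7919L * round +
          997L * match(fam, config$kernel_families) + round(kp * 101)
        pt <- minimize_af(models[[fam]], kp, config, seed = s,
                          best_points = best_points)
        cands[[length(cands) + 1L]] <- list(kernel = fam, kappa = kp,
                                            point = as.numeric(pt))
      }
    }
    round_candidates[[round]] <- cands

    # deduplicate candidates closer than dedup_tol * radius
    kept <- list()
    for (cand in cands) {
      dup <- any(vapply(kept, function(k)
        sqrt(sum((k$point - cand$point)^2)) < config$dedup_tol * config$radius,
        TRUE))
      if (!dup) kept[[length(kept) + 1L]] <- cand
    }

    for (i in seq_along(kept)) {
      s <- config$seed * 1000L + 100000L * round + i
      res <- eval_objective(kept[[i]]$point, s)
      if (!res$failed)
        add_row(kept[[i]]$point, res, round, kept[[i]]$kernel,
                kept[[i]]$kappa, s)
    }
  }

  evaluations <- do.call(rbind, rows)
  rownames(evaluations) <- NULL
  structure(list(evaluations = evaluations,
                 models = models,
                 round_candidates = round_candidates,
                 incumbent = evaluations[which.min(evaluations$rmsd), ],
                 config = config),
            class = "search_state")
}

#' @export
print.search_state <- function(x, ...) {
  d <- length(x$config$center)
  cat("Multi-GP search:", nrow(x$evaluations), "evaluations,",
      x$config$rounds, "rounds\n")
  cat("incumbent rmsd:", x$incumbent$rmsd, "at (",
      paste(signif(as.numeric(x$incumbent[1, seq_len(d)]), 4), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Select previously evaluated points for re-evaluation
#'
#' Picks a diverse subset of the best points seen so far, to be re-scored
#' with more replicates (lower noise). Restricted to the `pool` top-scoring
#' evaluated points; points closer than `threshold` (in lengthscale-scaled
#' coordinates) are merged agglomeratively (single linkage) and each cluster
#' is represented by its best-scoring member; up to `cap` representatives are
#' returned ordered by score.
#'
#' @param state a `search_state` (or its `evaluations` data frame).
#' @param pool number of top-scoring points considered.
#' @param cap maximum number of representatives returned.
#' @param threshold merge distance in scaled coordinates.
#' @param lengthscales per-dimension scales used to normalize distances
#'   (default: the incumbent kernel's ARD lengthscales if available, else 1).
#' @return matrix of selected points (rows), with attribute `"rmsd"`.
#' @export
select_reevaluation_points <- function(state, pool = 50L, cap = 16L,
                                       threshold = 1,
                                       lengthscales = NULL) {
  df <- if (inherits(state, "search_state")) state$evaluations else state
  if (!nrow(df)) stop("need at least one evaluation")
  d <- sum(grepl("^x[0-9]+$", names(df)))
  if (is.null(lengthscales)) {
    lengthscales <- rep(1, d)
    if (inherits(state, "search_state") && length(state$models)) {
      ls <- state$models[[which.min(vapply(state$models, function(m)
        if (is.null(m)) Inf else nlml(m), 0))]]$kernel$lengthscales
      if (length(ls) == 1L) ls <- rep(ls, d)
      if (length(ls) == d) lengthscales <- ls
    }
  }
  df <- df[order(df$rmsd), , drop = FALSE]
  df <- df[seq_len(min(pool, nrow(df))), , drop = FALSE]
  X <- as.matrix(df[, seq_len(d), drop = FALSE])
  Xs <- sweep(X, 2L, lengthscales, "/")
  if (nrow(Xs) > 1L) {
    hc <- stats::hclust(stats::dist(Xs), method = "single")
    cl <- stats::cutree(hc, h = threshold)
  } else cl <- 1L
  reps_idx <- vapply(split(seq_len(nrow(df)), cl), function(idx)
    idx[which.min(df$rmsd[idx])], 1L)
  reps_idx <- sort(reps_idx)   # df already ordered by rmsd
  reps_idx <- reps_idx[seq_len(min(cap, length(reps_idx)))]
  out <- X[reps_idx, , drop = FALSE]
  attr(out, "rmsd") <- df$rmsd[reps_idx]
  out
}

#' Per-dimension confidence interval at an optimum
#'
#' Scans a 1-D grid of extent `20 l` at spacing `0.001 l` (20,001 points,
#' `l` the kernel lengthscale of the chosen dimension) centered at the
#' optimum, obtains the posterior mean and variance at each grid point, draws
#' `n_draws` independent joint samples, counts how often each grid point
#' attains the minimum, and returns the minimal symmetric window around the
#' optimum containing 95% of the argmin mass.
#'
#' @param model a trained `gp_model`.
#' @param optimum parameter vector at which the interval is centered.
#' @param dim dimension index (1-based).
#' @param seed integer seed.
#' @param n_draws number of joint-independent posterior samples.
#' @param level coverage level (default 0.95).
#' @param extent,spacing grid extent and spacing in lengthscale units.
#' @return list with `low`, `high` (interval bounds in parameter units),
#'   `lengthscale`, `grid` (offsets), and `argmin_freq`.
#' @export
estimate_confidence_interval <- function(model, optimum, dim, seed = 1L,
                                         n_draws = 10000L, level = 0.95,
                                         extent = 20, spacing = 0.001) {
  ls <- model$kernel$lengthscales
  l <- if (length(ls) >= dim) ls[dim] else ls[1L]
  offsets <- seq(-extent / 2 * l, extent / 2 * l, by = spacing * l)
  pts <- matrix(rep(optimum, each = length(offsets)), length(offsets))
  pts[, dim] <- pts[, dim] + offsets
  post <- predict_gp(model, pts)
  sd_ <- sqrt(post$variance)

  set.seed(seed)
  counts <- integer(length(offsets))
  chunk <- 200L
  done <- 0L
  while (done < n_draws) {
    m <- min(chunk, n_draws - done)
    draws <- matrix(stats::rnorm(m * length(offsets)), m) *
      rep(sd_, each = m) + rep(post$mean, each = m)
    amin <- max.col(-draws, ties.method = "first")
    tab <- tabulate(amin, nbins = length(offsets))
    counts <- counts + tab
    done <- done + m
  }
  center <- (length(offsets) + 1L) %/% 2L
  total <- sum(counts)
  w <- 0L
  repeat {
    lo <- max(1L, center - w); hi <- min(length(offsets), center + w)
    if (sum(counts[lo:hi]) >= level * total || (lo == 1L && hi == length(offsets)))
      break
    w <- w + 1L
  }
  list(low = optimum[dim] + offsets[max(1L, center - w)],
       high = optimum[dim] + offsets[min(length(offsets), center + w)],
       lengthscale = l, grid = offsets, argmin_freq = counts / total)
}
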