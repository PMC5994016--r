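quadratic_state <- function() {
  # one shared optimizer run on a known 2D quadratic surface, reused by
  # several structural checks below
  if (is.null(.capsid_test_cache$quad_state)) {
    opt <- c(0.3, -0.2)
    f <- function(x) sum((x - opt)^2)
    sc <- search_config(center = c(0, 0), radius = 1,
                        initial_points = 20L, rounds = 5L,
                        af_samples = 800L, af_repeats = 3L,
                        gp_restarts = 1L, gp_maxit = 40L, seed = 42L)
    .capsid_test_cache$quad_state <- list(state = run_optimization(sc, f),
                                          optimum = opt, config = sc)
  }
  .capsid_test_cache$quad_state
}

test_that("hypersphere sampling is uniform, bounded, and seeded", {
  center <- c(2, -1, 0.5)
  pts <- sample_hypersphere(center, 1.5, 500, seed = 10)
  d <- sqrt(rowSums(sweep(pts, 2, center)^2))
  expect_true(all(d <= 1.5 + 1e-12))
  expect_identical(pts, sample_hypersphere(center, 1.5, 500, seed = 10))
  # law of large numbers: the centroid converges to the center
  big <- sample_hypersphere(center, 1.5, 1e5, seed = 11)
  expect_lt(max(abs(colMeans(big) - center)), 0.01 * 1.5)
  # radius distribution consistent with uniform-by-volume: median at 2^(-1/3)
  expect_equal(stats::median(d) / 1.5, 2^(-1 / 3), tolerance = 0.05)
})

test_that("LCB acquisition is the printed linear trade-off", {
  expect_equal(lcb(3.2, 0.9, 0), 3.2)
  expect_equal(lcb(1, 0.5, 2), 0)
  sig <- seq(0, 2, 0.1)
  expect_true(all(diff(lcb(1, sig, 1.5)) < 0))
  expect_error(lcb(1, -0.1, 1), ">= 0")
})

test_that("acquisition minimization averages its repeat minimizers", {
  # noiseless GP interpolating a sharp quadratic bowl
  grid <- as.matrix(expand.grid(seq(-1, 1, 0.2), seq(-1, 1, 0.2)))
  y <- rowSums(sweep(grid, 2, c(0.3, -0.2))^2)
  spec <- kernel_spec("se_ard", lengthscales = c(0.5, 0.5),
                      signal_variance = 2, noise_variance = 1e-10)
  model <- gp_model(spec, grid, y)
  sc <- search_config(center = c(0, 0), radius = 1, af_samples = 4000L,
                      af_repeats = 3L, seed = 1L)
  pt <- minimize_af(model, kappa = 0, sc, seed = 5,
                    best_points = matrix(c(0.3, -0.2), 1))
  reps <- attr(pt, "repeat_minimizers")
  expect_equal(nrow(reps), 3L)
  expect_equal(as.numeric(pt),
               capsidgp:::clip_to_ball(colMeans(reps), c(0, 0), 1))
  # dense sampling puts the minimizer within 5% of the ball radius
  expect_lt(sqrt(sum((as.numeric(pt) - c(0.3, -0.2))^2)), 0.05)
  # a single repeat returns that repeat's exact sample minimizer
  sc1 <- search_config(center = c(0, 0), radius = 1, af_samples = 500L,
                       af_repeats = 1L, seed = 1L)
  pt1 <- minimize_af(model, kappa = 0, sc1, seed = 9)
  expect_equal(as.numeric(pt1),
               as.numeric(attr(pt1, "repeat_minimizers")[1, ]))
})

test_that("each round proposes one candidate per kernel-kappa pair", {
  qs <- quadratic_state()
  n_expected <- length(qs$config$kernel_families) *
    length(qs$config$kappa_values)
  expect_equal(n_expected, 21L)
  for (cands in qs$state$round_candidates)
    expect_length(cands, 21L)
  # candidates lie inside the search ball
  for (cands in qs$state$round_candidates)
    for (cand in cands)
      expect_lte(sqrt(sum(cand$point^2)), 1 + 1e-9)
})

test_that("optimizer bookkeeping is exact and the incumbent is the minimum", {
  qs <- quadratic_state()
  df <- qs$state$evaluations
  per_round <- table(df$round)
  expect_equal(unname(per_round[["0"]]), 20L)
  # survivors per round never exceed the 21 proposals
  expect_true(all(per_round[-1] <= 21L))
  expect_equal(nrow(df), 20L + sum(per_round[-1]))
  expect_equal(qs$state$incumbent$rmsd, min(df$rmsd))
  # incumbent trace is monotone non-increasing over rounds
  inc <- vapply(0:5, function(r) min(df$rmsd[df$round <= r]), 0)
  expect_true(all(diff(inc) <= 0))
})

test_that("the optimizer solves a known quadratic to 1% of the ball radius", {
  qs <- quadratic_state()
  best <- as.numeric(qs$state$incumbent[1, 1:2])
  expect_lt(sqrt(sum((best - qs$optimum)^2)), 0.01)
})

test_that("single-kernel mode proposes one candidate per kappa", {
  f <- function(x) sum(x^2)
  sc <- search_config(center = c(0, 0), radius = 1,
                      kernel_families = "matern32_ard",
                      kappa_values = c(0.5, 2, 5),
                      initial_points = 10L, rounds = 2L,
                      af_samples = 200L, af_repeats = 2L,
                      gp_restarts = 1L, gp_maxit = 20L, seed = 2L)
  state <- run_optimization(sc, f)
  for (cands in state$round_candidates) {
    expect_length(cands, 3L)
    expect_true(all(vapply(cands, `[[`, "", "kernel") == "matern32_ard"))
  }
})

test_that("re-evaluation selection is a diverse subset of the best points", {
  set.seed(17)
  X <- matrix(stats::runif(100, -1, 1), 50)
  df <- data.frame(x1 = X[, 1], x2 = X[, 2], rmsd = stats::runif(50))
  # all points mutually distant: top-min(cap, pool) by score
  sel <- select_reevaluation_points(df, pool = 20L, cap = 5L,
                                    threshold = 1e-9,
                                    lengthscales = c(1, 1))
  expect_equal(nrow(sel), 5L)
  expect_equal(attr(sel, "rmsd"), sort(df$rmsd)[1:5])
  # selected points are previously evaluated points
  keys <- paste(df$x1, df$x2)
  expect_true(all(paste(sel[, 1], sel[, 2]) %in% keys))
  # all points within threshold of each other: a single representative
  sel2 <- select_reevaluation_points(df, pool = 20L, cap = 5L,
                                     threshold = 100,
                                     lengthscales = c(1, 1))
  expect_equal(nrow(sel2), 1L)
  expect_equal(attr(sel2, "rmsd"), min(df$rmsd[order(df$rmsd)[1:20]]))
  # two tight clusters: one representative each, best first
  Xc <- rbind(matrix(stats::rnorm(20, 0, 0.001), 10),
              matrix(stats::rnorm(20, 5, 0.001), 10))
  dfc <- data.frame(x1 = Xc[, 1], x2 = Xc[, 2], rmsd = c(1:10 / 10, 1:10 / 5))
  sel3 <- select_reevaluation_points(dfc, pool = 20L, cap = 16L,
                                     threshold = 0.5, lengthscales = c(1, 1))
  expect_equal(nrow(sel3), 2L)
  expect_equal(attr(sel3, "rmsd"), c(0.1, 0.2))
})

test_that("confidence-interval scan uses the prescribed grid and coverage", {
  # dense 1-D design: the posterior is confident over the whole scanned
  # region, so the argmin mass concentrates near the true minimum
  X <- matrix(seq(-4.5, 4.7, by = 0.1))
  y <- (as.numeric(X) - 0.1)^2
  spec <- kernel_spec("se_ard", lengthscales = 0.4, signal_variance = 1,
                      noise_variance = 1e-8)
  model <- gp_model(spec, X, y)
  opt <- 0.1
  ci <- estimate_confidence_interval(model, opt, dim = 1L, seed = 3,
                                     n_draws = 500L)
  # 20 l extent at 0.001 l spacing: 20,001 grid points
  expect_length(ci$grid, 20001L)
  expect_equal(ci$lengthscale, 0.4)
  expect_equal(max(ci$grid), 10 * 0.4, tolerance = 1e-9)
  expect_lte(ci$low, opt)
  expect_gte(ci$high, opt)
  expect_equal(sum(ci$argmin_freq), 1, tolerance = 1e-12)
  # confident posterior with a sharp minimum: window stays tight around it
  expect_lt(ci$high - ci$low, 0.4)
  # symmetric posterior about the optimum gives a near-symmetric window
  expect_equal(ci$high - opt, opt - ci$low, tolerance = 1e-9)
})

test_that("a fully deterministic posterior collapses the window", {
  # degenerate scan: predictive variance 0 on the grid, unique minimum at
  # the center. Emulated by a noiseless interpolating GP scanned across its
  # own training points.
  xs <- seq(-1, 1, 0.001)
  spec <- kernel_spec("se_ard", lengthscales = 1, signal_variance = 1,
                      noise_variance = 0)
  X <- matrix(seq(-1, 1, 0.25))
  model <- gp_model(spec, X, outputs = as.numeric(X)^2)
  ci <- estimate_confidence_interval(model, 0, dim = 1L, seed = 5,
                                     n_draws = 100L, extent = 0.5,
                                     spacing = 0.25)
  # extent 0.5 l / spacing 0.25 l: 3 grid points, all at training locations
  expect_length(ci$grid, 3L)
  expect_equal(ci$argmin_freq[2], 1)
  expect_equal(ci$low, 0); expect_equal(ci$high, 0)
})
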