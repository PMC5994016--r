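test_that("stability follows the Boltzmann bond-difference factor", {
  p <- rate_parameters(delta_G = 5, RT = 1)
  expect_equal(stability(3, 3, p), 1)
  expect_equal(stability(0, 4, rate_parameters(delta_G = 0)), 1)
  # delta_G / RT = -1, one extra bond -> e
  p2 <- rate_parameters(delta_G = -1, RT = 1)
  expect_equal(stability(0, 1, p2), exp(1))
  expect_error(stability(1, 2, rate_parameters(RT = 1e-9 - 1)), "positive")
})

test_that("parameter grouping expands and projects consistently", {
  v6 <- c(1, 2, 3, 4, 5, 6)
  p <- expand_parameters(v6, "paired6")
  expect_equal(p$on_rates, rep(v6, each = 2))
  expect_equal(project_parameters(p), v6)
  v12 <- seq(10, 120, by = 10)
  p12 <- expand_parameters(v12, "full12")
  expect_equal(p12$on_rates, v12)
  expect_equal(project_parameters(p12), v12)
  expect_error(expand_parameters(1:5, "paired6"), "length")
  expect_error(expand_parameters(c(-1, rep(1, 5)), "paired6"), "positive")
  # all-100 full12 vector is the deterministic ground truth
  expect_equal(expand_parameters(rep(100, 12), "full12")$on_rates, rep(100, 12))
})

test_that("rate/wait-time conversions match their defining formulas", {
  st <- stochastic_params(volume = 1e-15)
  expect_equal(convert_rates(2, "uni"), 0.5)
  expect_equal(convert_rates(convert_rates(3, "bi", st), "bi", st,
                             from = "wait"), 3)
  # log coordinates: x = 0 is the ground truth; x_i = 1 scales by 10
  t_gt <- c(1, 2, 3)
  expect_equal(apply_log_coordinates(c(0, 0, 0), t_gt), t_gt)
  expect_equal(apply_log_coordinates(c(1, 0, 0), t_gt), c(10, 2, 3))
  expect_error(convert_rates(-1, "uni"), "positive")
})

test_that("ode_rhs conserves subunit mass and handles the zero state", {
  tab <- dodec_table()
  p <- rate_parameters()
  n <- nrow(tab$species)
  expect_equal(ode_rhs(numeric(n), tab, p), numeric(n))
  set.seed(42)
  sizes <- tab$species$size
  for (i in 1:10) {
    state <- stats::runif(n) * 1e-6
    d <- ode_rhs(state, tab, p)
    expect_equal(sum(sizes * d), 0, tolerance = 1e-18)
  }
  expect_error(ode_rhs(numeric(3), tab, p), "length")
})

test_that("dimer derivative matches the hand-expanded rate law", {
  tab <- dodec_table()
  p <- rate_parameters(on_rates = rep(7, 12), delta_G = 2, RT = 1, symmetry = 5)
  n <- nrow(tab$species)
  i1 <- capsidgp:::species_row(tab, 1, 1)
  i2 <- capsidgp:::species_row(tab, 2, 1)
  m0 <- 3e-6; dim0 <- 1e-7
  state <- numeric(n); state[i1] <- m0; state[i2] <- dim0
  d <- ode_rhs(state, tab, p)
  s <- stability(0, 1, p)
  # d[dimer]/dt = k a O m0^2 - k b s [dimer] - (flux into trimers)
  gain <- 7 * 5 * 5 * m0^2 - 7 * 2 * s * dim0
  e3 <- tab$edges[tab$edges$j == 2, ]
  s3 <- stability(1, tab$species$bonds[capsidgp:::species_row(tab, 3, 1)], p)
  # trimer rows: both size-3 products currently empty, so only forward loss
  loss3 <- sum(7 * e3$a * 5 * dim0 * m0)
  expect_equal(d[i2], gain - loss3, tolerance = 1e-12)
  # monomer-only state: pure dimerization gain
  state2 <- numeric(n); state2[i1] <- m0
  d2 <- ode_rhs(state2, tab, p)
  expect_equal(d2[i2], 7 * 5 * 5 * m0^2, tolerance = 1e-12)
})

test_that("ODE integration conserves mass and freezes when rates vanish", {
  tab <- dodec_table()
  times <- 10^seq(0, 5, length.out = 10)
  # near-zero rates: state stays at the initial condition
  p0 <- rate_parameters(on_rates = rep(1e-12, 12))
  tr0 <- integrate_ode(tab, p0, sample_times = times, init_monomer = 1e-6)
  expect_lt(max(abs(tr0$states[, 1] - 1e-6)), 1e-12)
  # active rates: subunit mass conserved to integration tolerance
  p <- rate_parameters()
  tr <- integrate_ode(tab, p, sample_times = times, init_monomer = 1.66e-6)
  mass <- trajectory_mass(tr, tab)
  expect_lt(max(abs(mass / mass[1] - 1)), 1e-6)
  expect_error(integrate_ode(tab, p, sample_times = c(3, 1)), "ascending")
})

test_that("tightening tolerances leaves the solution essentially unchanged", {
  tab <- dodec_table()
  p <- rate_parameters()
  times <- 10^seq(0, 5, length.out = 6)
  a <- integrate_ode(tab, p, sample_times = times, rtol = 1e-8)
  b <- integrate_ode(tab, p, sample_times = times, rtol = 5e-9)
  denom <- pmax(abs(a$states[6, ]), max(a$states[6, ]) * 1e-6)
  expect_lt(max(abs(a$states[6, ] - b$states[6, ]) / denom), 1e-5)
})

test_that("irreversible limit: monomer concentration is non-increasing", {
  tab <- dodec_table()
  # infinitely stable bonds: dissociation suppressed entirely
  p <- rate_parameters(delta_G = 60)
  tr <- integrate_ode(tab, p, sample_times = 10^seq(0, 6, length.out = 20))
  mono <- tr$states[, capsidgp:::species_row(tab, 1, 1)]
  expect_true(all(diff(mono) <= 1e-12))
})

test_that("SSA: no rates means no events; every event conserves mass", {
  tab <- dodec_table()
  st <- stochastic_params(volume = 1e-16, subunit_copies = 100L)
  p0 <- rate_parameters(on_rates = rep(1e-30, 12))
  tr0 <- run_ssa(tab, p0, st, t_max = 10, seed = 1)
  expect_equal(length(tr0$times), 1L)
  expect_equal(tr0$times, 0)
  p <- rate_parameters(delta_G = 7)
  tr <- run_ssa(tab, p, st, t_max = 50, seed = 7)
  expect_gt(length(tr$times), 1L)
  expect_true(all(trajectory_mass(tr, tab) == 100L))
  expect_true(all(tr$states >= 0L))
  expect_true(!is.unsorted(tr$times, strictly = TRUE))
  # reproducible given seed
  tr2 <- run_ssa(tab, p, st, t_max = 50, seed = 7)
  expect_identical(tr$states, tr2$states)
  expect_identical(tr$times, tr2$times)
})

test_that("SSA waiting times are exponential at frozen propensity", {
  # monomer-dimer network only; first event time ~ Exp(total propensity)
  tab2 <- truncate_table(dodec_table(), 2L)
  st <- stochastic_params(volume = 1e-16, subunit_copies = 50L)
  p <- rate_parameters()
  net <- capsidgp:::build_reaction_network(tab2, p)
  a0 <- net$kf / (st$avogadro * st$volume) * 50 * 49
  waits <- vapply(seq_len(10000L), function(i) {
    tr <- run_ssa(tab2, p, st, t_max = Inf, seed = i, max_events = 2L)
    tr$times[2L]
  }, 0)
  ks <- suppressWarnings(stats::ks.test(waits, "pexp", rate = a0))
  expect_gt(ks$p.value, 0.01)
})

test_that("SSA agrees with the ODE in the mean over many seeds", {
  tab3 <- truncate_table(dodec_table(), 3L)
  st <- stochastic_params(volume = 1e-16, subunit_copies = 100L)
  p <- rate_parameters(delta_G = 7)
  t_obs <- 4
  n_seeds <- 200L
  dimer_counts <- vapply(seq_len(n_seeds), function(s) {
    tr <- run_ssa(tab3, p, st, t_max = t_obs, seed = 1000L + s)
    align_candidate(t_obs, tr)[1, capsidgp:::species_row(tab3, 2, 1)]
  }, 0)
  init_m <- 100 / (st$avogadro * st$volume)
  ode <- integrate_ode(tab3, p, sample_times = c(1, t_obs),
                       init_monomer = init_m)
  expected <- ode$states[2, capsidgp:::species_row(tab3, 2, 1)] *
    st$avogadro * st$volume
  se <- stats::sd(dimer_counts) / sqrt(n_seeds)
  expect_lt(abs(mean(dimer_counts) - expected), 3 * se + 1e-12)
})

test_that("monomer-dimer equilibrium satisfies detailed balance", {
  tab2 <- truncate_table(dodec_table(), 2L)
  p <- rate_parameters(delta_G = 4)
  tr <- integrate_ode(tab2, p, sample_times = c(1, 1e7, 2e7),
                      init_monomer = 1e-6, rtol = 1e-10)
  m <- tr$states[3, capsidgp:::species_row(tab2, 1, 1)]
  d <- tr$states[3, capsidgp:::species_row(tab2, 2, 1)]
  # closed form: [2]/[1]^2 = a O / (b s)
  s <- stability(0, 1, p)
  expect_equal(d / m^2, 5 * 5 / (2 * s), tolerance = 1e-4)
})

test_that("trajectories round-trip through TSV", {
  tab <- dodec_table()
  st <- stochastic_params(volume = 1e-16, subunit_copies = 60L)
  tr <- run_ssa(tab, rate_parameters(delta_G = 7), st, t_max = 20, seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$kind, "ssa")
  expect_identical(back$states, tr$states)
  expect_equal(back$times, tr$times)
  expect_equal(back$species_ids, tr$species_ids)
})
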