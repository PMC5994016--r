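#' Kinetic rate parameters for the monomer-addition assembly network
#'
#' @param on_rates vector of 12 per-size association rate constants (molar
#'   units, 1/M/s); `on_rates[i]` governs monomer addition to an i-mer.
#'   Index 12 has no forward reaction and is inert padding so the full model
#'   keeps 12 dimensions.
#' @param delta_G per-bond free energy entering the relative stability
#'   `s = exp(-delta_G * (c_mn - c_jk) / RT)`; under this sign convention a
#'   positive `delta_G` makes bonded species stable (slow dissociation).
#'   Default 5 (in units of RT), a typical capsid contact strength.
#' @param RT thermal energy in the same units as `delta_G` (default 1).
#' @param symmetry monomer symmetry number O (5 for pentamers).
#' @param grouping `"full12"` (each size its own rate) or `"paired6"`
#'   (sizes paired \{1,2\}, \{3,4\}, ..., \{11,12\} share a rate).
#' @return An object of class `rate_parameters`.
#' @export
rate_parameters <- function(on_rates = rep(100, 12), delta_G = 5, RT = 1,
                            symmetry = 5, grouping = c("full12", "paired6")) {
  grouping <- match.arg(grouping)
  on_rates <- as.numeric(on_rates)
  if (length(on_rates) != 12L) stop("on_rates must have length 12")
  if (any(on_rates <= 0)) stop("all on_rates must be positive")
  if (RT <= 0) stop("RT must be positive")
  if (symmetry < 1) stop("symmetry must be >= 1")
  if (grouping == "paired6" &&
      any(on_rates[seq(1, 11, 2)] != on_rates[seq(2, 12, 2)]))
    stop("paired6 grouping requires on_rates constant within size pairs")
  structure(list(on_rates = on_rates, delta_G = delta_G, RT = RT,
                 symmetry = symmetry, grouping = grouping),
            class = "rate_parameters")
}

#' Expand a free parameter vector into full per-size rates
#'
#' The 6-parameter model groups oligomer sizes \{1,2\}, \{3,4\}, ..., \{11,12\}
#' so that each pair shares one association rate; the 12-parameter model gives
#' each size its own rate.
#'
#' @param free_vector numeric vector of length 6 (`paired6`) or 12 (`full12`),
#'   all entries positive.
#' @param grouping `"full12"` or `"paired6"`.
#' @param ... further arguments passed to [rate_parameters()].
#' @return A `rate_parameters` object.
#' @export
expand_parameters <- function(free_vector, grouping = c("full12", "paired6"), ...) {
  grouping <- match.arg(grouping)
  need <- if (grouping == "paired6") 6L else 12L
  if (length(free_vector) != need)
    stop("free_vector must have length ", need, " for grouping ", grouping)
  if (any(free_vector <= 0)) stop("all rate entries must be positive")
  on <- if (grouping == "paired6") rep(free_vector, each = 2L) else free_vector
  rate_parameters(on_rates = on, grouping = grouping, ...)
}

#' Project full per-size rates back to the free vector
#' @param params a `rate_parameters` object.
#' @return numeric vector of length 6 or 12 according to the grouping.
#' @export
project_parameters <- function(params) {
  if (params$grouping == "paired6") params$on_rates[seq(1, 11, 2)]
  else params$on_rates
}

#' Relative stability of a species pair
#'
#' Boltzmann factor `s = exp(-delta_G * (c_mn - c_jk) / RT)` relating the
#' dissociation flux of the larger species (m,n) to the association flux that
#' forms it from (j,k); `c` counts bonds formed within a species.
#'
#' @param c_jk,c_mn bond counts of the smaller and larger species (>= 0).
#' @param params a `rate_parameters` object.
#' @return positive real.
#' @export
stability <- function(c_jk, c_mn, params) {
  if (params$RT <= 0) stop("RT must be positive")
  if (any(c(c_jk, c_mn) < 0)) stop("bond counts must be >= 0")
  exp(-params$delta_G * (c_mn - c_jk) / params$RT)
}

#' Stochastic simulation settings and unit conversions
#'
#' @param volume system volume Omega in litres.
#' @param subunit_copies initial number of free monomers.
#' @param avogadro Avogadro's number.
#' @return An object of class `stochastic_params`.
#' @export
stochastic_params <- function(volume = 1e-15, subunit_copies = 1000L,
                              avogadro = 6.02214076e23) {
  if (volume <= 0 || subunit_copies < 1) stop("invalid stochastic settings")
  structure(list(volume = volume, subunit_copies = as.integer(subunit_copies),
                 avogadro = avogadro),
            class = "stochastic_params")
}

#' Convert between reaction rate constants and expected wait times
#'
#' Unimolecular reactions: `T = 1/k`. Bimolecular reactions:
#' `k_molar = N_A * Omega / T_bi` (and the inverse map, which has the same
#' form). Log-scaled search coordinates are handled by
#' [apply_log_coordinates()].
#'
#' @param value positive rate constant or wait time.
#' @param mode `"uni"` or `"bi"`.
#' @param stoch a `stochastic_params` object (needed for `"bi"`).
#' @param from `"rate"` to convert a rate into a wait time, `"wait"` for the
#'   inverse.
#' @return the converted value.
#' @export
convert_rates <- function(value, mode = c("uni", "bi"), stoch = stochastic_params(),
                          from = c("rate", "wait")) {
  mode <- match.arg(mode); from <- match.arg(from)
  if (any(value <= 0)) stop("value must be positive")
  if (mode == "uni") 1 / value
  else stoch$avogadro * stoch$volume / value
}

#' Map log-scaled search coordinates to wait times
#'
#' The ground-truth wait times `T_GT` are the origin of the log-scaled search
#' space: `T = 10 ^ (log10(T_GT) + x)`.
#'
#' @param x dimensionless log10 offsets.
#' @param ground_truth_wait_times vector `T_GT` of positive wait times.
#' @return wait-time vector of the same length.
#' @export
apply_log_coordinates <- function(x, ground_truth_wait_times) {
  if (length(x) != length(ground_truth_wait_times))
    stop("coordinate/wait-time length mismatch")
  10^(log10(ground_truth_wait_times) + x)
}

# Precompute the reaction network for a species table + rate parameters:
# one reversible reaction per degeneracy edge (j,k) + (1,1) <-> (m,n),
# forward molar rate a*O*k_on[j], backward rate b*s*k_on[j].
build_reaction_network <- function(table, params) {
  ed <- table$edges
  n_species <- nrow(table$species)
  mono <- species_row(table, 1L, 1L)
  i_react <- vapply(seq_len(nrow(ed)), function(r)
    species_row(table, ed$j[r], ed$k[r]), 1L)
  i_prod <- vapply(seq_len(nrow(ed)), function(r)
    species_row(table, ed$m[r], ed$n[r]), 1L)
  c_small <- table$species$bonds[i_react]
  c_big <- table$species$bonds[i_prod]
  s <- stability(c_small, c_big, params)
  k_on <- params$on_rates[ed$j]
  kf <- k_on * ed$a * params$symmetry   # molar association rate, * [jk][1]
  kb <- k_on * ed$b * s                 # dissociation rate, * [mn]
  # stoichiometry matrix: species x reactions (net = forward - backward flux)
  nr <- nrow(ed)
  ii <- c(i_react, rep(mono, nr), i_prod)
  jj <- rep(seq_len(nr), 3L)
  xx <- c(rep(-1, nr), rep(-1, nr), rep(1, nr))
  S <- as.matrix(Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                      dims = c(n_species, nr)))
  list(i_react = i_react, i_prod = i_prod, mono = mono,
       kf = kf, kb = kb, S = S, n_species = n_species, n_reactions = nr)
}

#' Time derivative of the species concentration vector
#'
#' Mass-action right-hand side of the monomer-addition ODE model: each
#' degeneracy edge (j,k) + monomer <-> (m,n) contributes a net molar flux
#' `k_on[j] * (a * O * [j,k][1,1] - b * s * [m,n])` applied with conserving
#' stoichiometry (the monomer loses one copy per association, two when the
#' reactant is itself the monomer).
#'
#' @param state molar concentration vector, one entry per table species.
#' @param table a `species_table`.
#' @param params a `rate_parameters` object.
#' @param network optional precomputed [build_reaction_network()] result.
#' @return derivative vector (M/s) of the same length.
#' @export
ode_rhs <- function(state, table, params, network = NULL) {
  if (is.null(network)) network <- build_reaction_network(table, params)
  if (length(state) != network$n_species)
    stop("state length does not match species count")
  phi <- network$kf * state[network$i_react] * state[network$mono] -
    network$kb * state[network$i_prod]
  drop(network$S %*% phi)
}

# analytic Jacobian of ode_rhs wrt the state (chain rule through the fluxes)
ode_jacobian <- function(state, network) {
  nr <- network$n_reactions
  dphi <- matrix(0, nr, network$n_species)
  rs <- seq_len(nr)
  # d phi / d x[i_react] += kf * x[mono]; d phi / d x[mono] += kf * x[i_react]
  idx1 <- cbind(rs, network$i_react)
  dphi[idx1] <- dphi[idx1] + network$kf * state[network$mono]
  idx2 <- cbind(rs, rep(network$mono, nr))
  dphi[idx2] <- dphi[idx2] + network$kf * state[network$i_react]
  idx3 <- cbind(rs, network$i_prod)
  dphi[idx3] <- dphi[idx3] - network$kb
  network$S %*% dphi
}

#' Integrate the deterministic assembly model
#'
#' Adaptive stiff integration (lsoda) of the monomer-addition network with
#' dense output evaluated at the requested sample times.
#'
#' @param table a `species_table`.
#' @param params a `rate_parameters` object.
#' @param init initial molar concentration vector (default: all mass in the
#'   monomer at `init_monomer` M).
#' @param sample_times ascending non-negative times (s) at which to report.
#' @param init_monomer initial monomer concentration used when `init` is NULL.
#' @param rtol,atol integration tolerances.
#' @return A `trajectory` object (`kind = "ode"`): `times`, `states` matrix
#'   (rows = times, columns = species), `species_ids`.
#' @export
integrate_ode <- function(table, params, init = NULL, sample_times,
                          init_monomer = 1.66e-6, rtol = 1e-8, atol = NULL) {
  if (is.unsorted(sample_times, strictly = TRUE) || any(sample_times < 0))
    stop("sample_times must be strictly ascending and >= 0")
  n <- nrow(table$species)
  if (is.null(init)) {
    init <- numeric(n)
    init[species_row(table, 1L, 1L)] <- init_monomer
  }
  if (length(init) != n) stop("init length does not match species count")
  if (is.null(atol)) atol <- max(init) * 1e-12
  network <- build_reaction_network(table, params)
  times <- sort(unique(c(0, sample_times)))
  rhs <- function(t, y, p) list(ode_rhs(y, table, params, network))
  jac <- function(t, y, p) ode_jacobian(y, network)
  sol <- deSolve::ode(y = init, times = times, func = rhs, parms = NULL,
                      method = "lsoda", jacfunc = jac, jactype = "fullusr",
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE integration failed near t = ", max(sol[, 1L]))
  keep <- match(sample_times, sol[, 1L])
  states <- unname(sol[keep, -1L, drop = FALSE])
  structure(list(kind = "ode", times = sample_times, states = states,
                 species_ids = species_id(table)),
            class = "trajectory")
}

#' Stochastic (Gillespie) simulation of the assembly network
#'
#' Exact direct-method stochastic simulation over the enumerated
#' monomer-addition reactions. Association propensities use the molar rates
#' converted to per-count rates via the system volume and Avogadro's number
#' (`k / (N_A * Omega)`), multiplied by `n_jk * n_1` (or `n_1 * (n_1 - 1)`
#' for dimerization); dissociation propensities are `k_off * n_mn`. Every
#' reaction event is recorded.
#'
#' @param table a `species_table`.
#' @param params a `rate_parameters` object (molar rates).
#' @param stoch a `stochastic_params` object.
#' @param t_max simulation end time (s).
#' @param seed integer random seed.
#' @param max_events safety cap on the number of recorded events.
#' @return A `trajectory` object (`kind = "ssa"`) with integer count states;
#'   the trajectory ends early if the total propensity reaches zero.
#' @export
run_ssa <- function(table, params, stoch = stochastic_params(), t_max,
                    seed = 1L, max_events = 1e6) {
  if (t_max <= 0) stop("t_max must be positive")
  set.seed(seed)
  network <- build_reaction_network(table, params)
  scale <- stoch$avogadro * stoch$volume
  kf_c <- network$kf / scale      # per-count association rates
  kb_c <- network$kb              # unimolecular, unchanged
  mono <- network$mono
  n_species <- network$n_species
  x <- integer(n_species)
  x[mono] <- stoch$subunit_copies

  nr <- length(kf_c)
  cap <- 4096L
  times <- numeric(cap); states <- matrix(0L, cap, n_species)
  n_rec <- 1L; times[1L] <- 0; states[1L, ] <- x
  t <- 0
  is_dimer <- network$i_react == mono

  repeat {
    nm <- x[mono]
    pair <- ifelse(is_dimer, nm * pmax(nm - 1, 0), x[network$i_react] * nm)
    prop <- c(kf_c * pair, kb_c * x[network$i_prod])
    total <- sum(prop)
    if (total <= 0) break
    t <- t + stats::rexp(1L, total)
    if (t > t_max) break
    r <- sample.int(2L * nr, 1L, prob = prop)
    if (r <= nr) {       # association
      x[network$i_react[r]] <- x[network$i_react[r]] - 1L
      x[mono] <- x[mono] - 1L
      x[network$i_prod[r]] <- x[network$i_prod[r]] + 1L
    } else {             # dissociation
      r <- r - nr
      x[network$i_prod[r]] <- x[network$i_prod[r]] - 1L
      x[mono] <- x[mono] + 1L
      x[network$i_react[r]] <- x[network$i_react[r]] + 1L
    }
    n_rec <- n_rec + 1L
    if (n_rec > cap) {
      cap <- cap * 2L
      times <- c(times, numeric(cap %/% 2L))
      states <- rbind(states, matrix(0L, cap %/% 2L, n_species))
    }
    times[n_rec] <- t; states[n_rec, ] <- x
    if (n_rec >= max_events) break
  }
  structure(list(kind = "ssa", times = times[seq_len(n_rec)],
                 states = states[seq_len(n_rec), , drop = FALSE],
                 species_ids = species_id(table)),
            class = "trajectory")
}

#' Write / read a trajectory as TSV
#'
#' Column 1 is time; remaining columns are species abundances, with a header
#' naming the (size.index) species ids.
#'
#' @param traj a `trajectory`.
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  names(df) <- c("time", traj$species_ids)
  attr(df, "kind") <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#kind\t", traj$kind), con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1L)
  kind <- sub("^#kind\t", "", first)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE)
  states <- as.matrix(df[, -1L, drop = FALSE])
  if (kind == "ssa") storage.mode(states) <- "integer"
  structure(list(kind = kind, times = df$time,
                 states = unname(states), species_ids = names(df)[-1L]),
            class = "trajectory")
}

#' Total subunit mass of each trajectory state
#' @param traj a `trajectory`.
#' @param table the matching `species_table`.
#' @return numeric vector: `sum(size * abundance)` at each recorded time.
#' @export
trajectory_mass <- function(traj, table) {
  as.numeric(traj$states %*% table$species$size)
}
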