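#' Align a candidate trajectory onto ground-truth sample times
#'
#' Stochastic trajectories record states only at reaction events, and no two
#' trajectories share event times. Because the assembly process is Markov,
#' the state is constant between events, so for each ground-truth time the
#' state at the closest later recorded time is used; if the trajectory ends
#' before a requested time the final state applies. Deterministic (ODE)
#' trajectories are evaluated at the requested times by linear interpolation
#' of the dense solution.
#'
#' @param gt_times ascending ground-truth times.
#' @param candidate a `trajectory`.
#' @return matrix of states (rows = `gt_times`, columns = species).
#' @export
align_candidate <- function(gt_times, candidate) {
  if (is.unsorted(gt_times)) stop("gt_times must be ascending")
  if (length(candidate$times) == 0L) stop("empty trajectory")
  if (candidate$kind == "ssa") {
    # index of the earliest recorded time >= t (final state if none)
    idx <- findInterval(gt_times, candidate$times, left.open = TRUE) + 1L
    idx[idx > length(candidate$times)] <- length(candidate$times)
    candidate$states[idx, , drop = FALSE]
  } else {
    if (identical(as.numeric(candidate$times), as.numeric(gt_times)))
      return(candidate$states)
    apply(candidate$states, 2L, function(col)
      stats::approx(candidate$times, col, xout = gt_times, rule = 2)$y)
  }
}

#' RMSD between two scattering experiments
#'
#' Root mean square deviation over the flattened time x q intensity matrix.
#'
#' @param a,b `scattering_experiment` objects on identical grids.
#' @return non-negative real; 0 for identical experiments.
#' @export
rmsd <- function(a, b) {
  if (!isTRUE(all.equal(a$q_grid, b$q_grid)) ||
      !identical(dim(a$intensity), dim(b$intensity)))
    stop("experiments must share the q grid and time count")
  sqrt(mean((a$intensity - b$intensity)^2))
}

#' Assemble an objective-evaluation configuration
#'
#' Bundles everything needed to score a parameter point against a
#' ground-truth experiment: the species table, geometry, subunit profile,
#' simulator mode and settings, and the ground truth itself.
#'
#' @param ground_truth a `scattering_experiment`.
#' @param table a `species_table`.
#' @param geom a `species_geometry`.
#' @param ff a `form_factor` on the ground-truth q grid.
#' @param mode `"ode"` or `"ssa"`.
#' @param grouping `"paired6"` or `"full12"`; interpretation of the point.
#' @param delta_G,RT,symmetry thermodynamic settings (see [rate_parameters()]).
#' @param stoch `stochastic_params` (SSA mode; also sets the ODE initial
#'   monomer concentration `subunit_copies / (N_A * volume)`).
#' @param replicates SSA replicates per evaluation (1 for ODE).
#' @param t_max SSA end time (default: last ground-truth time).
#' @param rtol ODE relative tolerance.
#' @param ssa_log_coords if `TRUE` (SSA default), points are log10 offsets x
#'   from the ground-truth wait times; rates are recovered via
#'   `T = 10^(log10(T_GT) + x)` and `k = N_A * Omega / T`.
#' @param ground_truth_rates rate vector (free-vector scale) defining `T_GT`
#'   for the log-coordinate map.
#' @return a list of class `objective_config`.
#' @export
objective_config <- function(ground_truth, table, geom, ff,
                             mode = c("ode", "ssa"),
                             grouping = c("paired6", "full12"),
                             delta_G = 5, RT = 1, symmetry = 5,
                             stoch = stochastic_params(),
                             replicates = if (mode == "ode") 1L else 3L,
                             t_max = max(ground_truth$times),
                             rtol = 1e-8,
                             ssa_log_coords = TRUE,
                             ground_truth_rates = rep(100, if (grouping == "paired6") 6 else 12)) {
  mode <- match.arg(mode)
  grouping <- match.arg(grouping)
  if (mode == "ode" && replicates != 1L)
    stop("deterministic mode uses exactly one replicate")
  if (replicates < 1L) stop("replicates must be >= 1")
  structure(list(ground_truth = ground_truth, table = table, geom = geom,
                 ff = ff, mode = mode, grouping = grouping, delta_G = delta_G,
                 RT = RT, symmetry = symmetry, stoch = stoch,
                 replicates = as.integer(replicates), t_max = t_max,
                 rtol = rtol, ssa_log_coords = ssa_log_coords,
                 ground_truth_rates = ground_truth_rates),
            class = "objective_config")
}

# turn a search-space point into rate parameters under the config conventions
point_to_rates <- function(point, config) {
  if (config$mode == "ssa" && config$ssa_log_coords) {
    t_gt <- convert_rates(config$ground_truth_rates, "bi", config$stoch)
    t_new <- apply_log_coordinates(point, t_gt)
    point <- convert_rates(t_new, "bi", config$stoch, from = "wait")
  }
  expand_parameters(point, config$grouping, delta_G = config$delta_G,
                    RT = config$RT, symmetry = config$symmetry)
}

# run one simulation replicate and synthesize its experiment
simulate_experiment <- function(params, config, seed) {
  gt <- config$ground_truth
  if (config$mode == "ode") {
    init_monomer <- config$stoch$subunit_copies /
      (config$stoch$avogadro * config$stoch$volume)
    traj <- integrate_ode(config$table, params, sample_times = gt$times,
                          init_monomer = init_monomer, rtol = config$rtol)
  } else {
    traj <- run_ssa(config$table, params, config$stoch,
                    t_max = config$t_max, seed = seed)
  }
  trajectory_to_experiment(traj, config$table, config$geom, config$ff,
                           sample_times = gt$times)
}

#' Evaluate the RMSD objective at one parameter point
#'
#' Runs the configured simulator at `point`. In stochastic mode the
#' representative experiment is the element-wise mean over replicates; the
#' reported `rmsd` compares that mean to the ground truth, and
#' `noise_variance` is the variance of the per-replicate RMSDs (a direct
#' empirical estimate of the objective's noise level). Deterministic mode is
#' a single noiseless run.
#'
#' @param point parameter vector in search-space coordinates (rates for ODE
#'   mode, log10 wait-time offsets for SSA mode by default).
#' @param config an [objective_config()].
#' @param seed integer seed; evaluation is reproducible given the seed.
#' @return An object of class `objective_evaluation`: `point`, `rmsd`,
#'   `replicate_rmsds`, `noise_variance`, `replicates`, `failed`.
#' @export
evaluate_point <- function(point, config, seed = 1L) {
  result <- tryCatch({
    params <- point_to_rates(point, config)
    reps <- config$replicates
    seeds <- seed + seq_len(reps) - 1L
    exps <- lapply(seeds, function(s) simulate_experiment(params, config, s))
    mean_int <- Reduce(`+`, lapply(exps, `[[`, "intensity")) / reps
    mean_exp <- structure(list(times = config$ground_truth$times,
                               q_grid = config$ground_truth$q_grid,
                               intensity = mean_int),
                          class = "scattering_experiment")
    rep_rmsds <- vapply(exps, rmsd, 0, b = config$ground_truth)
    list(rmsd = rmsd(mean_exp, config$ground_truth),
         replicate_rmsds = rep_rmsds,
         noise_variance = if (reps > 1L) stats::var(rep_rmsds) else 0,
         failed = FALSE)
  }, error = function(e) {
    list(rmsd = NA_real_, replicate_rmsds = numeric(0),
         noise_variance = NA_real_, failed = TRUE, message = conditionMessage(e))
  })
  structure(c(list(point = point, replicates = config$replicates, seed = seed),
              result),
            class = "objective_evaluation")
}

#' Append an evaluation to a CSV trace
#'
#' @param evaluation an `objective_evaluation`.
#' @param path CSV file (created with a header if absent).
#' @param mode simulator mode label.
#' @param wall_time seconds spent on the evaluation (optional).
#' @return `path`, invisibly.
#' @export
append_trace <- function(evaluation, path, mode = "", wall_time = NA_real_) {
  row <- data.frame(t(evaluation$point),
                    rmsd = evaluation$rmsd,
                    noise_variance = evaluation$noise_variance,
                    replicates = evaluation$replicates,
                    seed = evaluation$seed,
                    wall_time = wall_time, mode = mode)
  names(row)[seq_along(evaluation$point)] <-
    paste0("x", seq_along(evaluation$point))
  utils::write.table(row, path, sep = ",", append = file.exists(path),
                     col.names = !file.exists(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
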