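#' Default scattering-vector grid
#'
#' The conventional CRYSOL output grid: q from 0 to 0.5 inverse Angstroms in
#' steps of 0.01 (51 points).
#' @return numeric vector of length 51.
#' @export
default_q_grid <- function() seq(0, 0.5, by = 0.01)

#' Load a single-subunit scattering profile
#'
#' Either reads a CRYSOL `.int` file (whitespace-delimited, one header line,
#' column 1 = q, column 2 = total intensity) or generates a synthetic
#' analytic profile for a homogeneous sphere of radius `radius`:
#' `I(q) = drho2V2 * [3 (sin(qR) - qR cos(qR)) / (qR)^3]^2`, which tends to
#' `drho2V2` as q tends to 0. The sphere mode stands in for a subunit profile
#' when no measured/computed file is available.
#'
#' @param source either a file path to a CRYSOL `.int` file, or the string
#'   `"sphere"`.
#' @param q_grid requested q grid (default [default_q_grid()]). A file whose
#'   grid differs is resampled by linear interpolation with a warning.
#' @param radius sphere radius in Angstroms (sphere mode).
#' @param drho2V2 contrast-volume prefactor `(delta rho)^2 V^2` (sphere mode).
#' @return An object of class `form_factor`: `q_grid`, `subunit_intensity`.
#' @export
load_form_factor <- function(source = "sphere", q_grid = default_q_grid(),
                             radius = 30, drho2V2 = 1) {
  if (is.unsorted(q_grid) || any(q_grid < 0))
    stop("q_grid must be ascending and >= 0")
  if (identical(source, "sphere")) {
    if (radius <= 0) stop("sphere radius must be positive")
    qr <- q_grid * radius
    f <- ifelse(qr == 0, 1, 3 * (sin(qr) - qr * cos(qr)) / qr^3)
    intensity <- drho2V2 * f^2
  } else {
    intensity <- read_crysol_int(source, q_grid)
  }
  structure(list(q_grid = q_grid, subunit_intensity = intensity),
            class = "form_factor")
}

read_crysol_int <- function(path, q_grid) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("malformed .int file (", path, "): no data lines")
  fields <- strsplit(trimws(lines[-1L]), "\\s+")
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (length(v) < 2L || anyNA(v[1:2]))
      stop("malformed .int file (", path, ") at line ", i + 1L)
    fields[[i]] <- v[1:2]
  }
  tab <- do.call(rbind, fields)
  q_file <- tab[, 1L]; i_file <- tab[, 2L]
  if (length(q_file) == length(q_grid) && max(abs(q_file - q_grid)) < 1e-9)
    return(i_file)
  warning("resampling .int profile onto the requested q grid by linear interpolation")
  stats::approx(q_file, i_file, xout = q_grid, rule = 2)$y
}

#' Per-species subunit coordinates
#'
#' Places each subunit of every enumerated species at its face centroid
#' scaled to the capsid radius.
#'
#' @param table a `species_table`.
#' @param capsid_radius distance of a subunit centroid from the capsid center
#'   in Angstroms.
#' @return An object of class `species_geometry`: a list `positions` of
#'   (size x 3) coordinate matrices, one per table species.
#' @export
species_geometry <- function(table, capsid_radius = 100) {
  if (capsid_radius <= 0) stop("capsid_radius must be positive")
  positions <- lapply(seq_len(nrow(table$species)), function(r)
    table$model$centroids[species_faces(table, r), , drop = FALSE] * capsid_radius)
  structure(list(positions = positions, capsid_radius = capsid_radius),
            class = "species_geometry")
}

#' Orientationally averaged structure factor (Debye formula)
#'
#' `S(q) = (1/N) * sum_{j,k} sinc(q |R_j - R_k|)` with `sinc(0) = 1`: the
#' isotropic average of the pairwise phase sum over all orientations of the
#' rigid assembly. `S(0) = N`, and `S(q) = 1` for a single subunit.
#'
#' @param positions (N x 3) coordinate matrix.
#' @param q scalar or vector of scattering-vector values (>= 0).
#' @return non-negative structure factor, same length as `q`.
#' @export
structure_factor <- function(positions, q) {
  positions <- rbind(positions)
  n <- nrow(positions)
  if (n < 1L) stop("need at least one subunit")
  if (any(q < 0)) stop("q must be >= 0")
  d <- pairwise_distances(positions)
  vapply(q, function(qi) {
    cross <- if (length(d)) sum(debye_sinc(qi * d)) else 0
    (n + 2 * cross) / n
  }, 0)
}

debye_sinc <- function(x) ifelse(x == 0, 1, sin(x) / x)

pairwise_distances <- function(positions) {
  n <- nrow(positions)
  if (n < 2L) return(numeric(0))
  as.numeric(stats::dist(positions))
}

# per-species un-normalized Debye sums N_s * S_s(q) on a grid:
# rows = species, cols = q. This is the coherent double sum, N^2 at q -> 0.
species_debye_matrix <- function(table, geom, q_grid) {
  res <- vapply(seq_along(geom$positions), function(s) {
    pos <- geom$positions[[s]]
    n <- nrow(pos)
    d <- pairwise_distances(pos)
    vapply(q_grid, function(qi)
      n + 2 * (if (length(d)) sum(debye_sinc(qi * d)) else 0), 0)
  }, numeric(length(q_grid)))
  if (is.matrix(res)) t(res) else matrix(res, ncol = 1L)
}

#' Synthesize a time-resolved scattering experiment from a trajectory
#'
#' Under the dilute assumption the contributions of all intermediates add:
#' `I(q, t) = sum_s abundance_s(t) * I_subunit(q) * [N_s * S_s(q)]`, where
#' `N_s * S_s(q)` is the un-normalized Debye double sum of species s (so a
#' rigid N-mer scatters N^2 times a subunit in the q -> 0 coherent limit).
#'
#' @param traj a `trajectory` (counts for SSA, molar concentrations for ODE).
#' @param table the matching `species_table`.
#' @param geom a `species_geometry`.
#' @param ff a `form_factor` on the experiment q grid.
#' @param sample_times times at which to report intensities. SSA states are
#'   aligned by the closest-later-time rule; ODE states by interpolation
#'   (see [align_candidate()]).
#' @return An object of class `scattering_experiment`: `times`, `q_grid`,
#'   `intensity` (time x q matrix).
#' @export
trajectory_to_experiment <- function(traj, table, geom, ff,
                                     sample_times = traj$times) {
  if (!identical(traj$species_ids, species_id(table)))
    stop("trajectory species do not match the species table")
  if (length(geom$positions) != nrow(table$species))
    stop("geometry does not match the species table")
  states <- align_candidate(sample_times, traj)
  debye <- species_debye_matrix(table, geom, ff$q_grid)
  intensity <- (states %*% debye) * rep(ff$subunit_intensity,
                                        each = length(sample_times))
  structure(list(times = sample_times, q_grid = ff$q_grid,
                 intensity = unname(intensity)),
            class = "scattering_experiment")
}

#' Write / read a scattering experiment as TSV
#'
#' First column is time; remaining columns are intensities with the q grid in
#' the header. The writer/reader pair round-trips exactly (full double
#' precision).
#'
#' @param exp_ a `scattering_experiment`.
#' @param path file path.
#' @return `write_experiment` returns `path` invisibly; `read_experiment`
#'   returns a `scattering_experiment`.
#' @export
write_experiment <- function(exp_, path) {
  header <- paste(c("time", formatC(exp_$q_grid, format = "g", digits = 17)),
                  collapse = "\t")
  rows <- vapply(seq_along(exp_$times), function(i)
    paste(formatC(c(exp_$times[i], exp_$intensity[i, ]),
                  format = "g", digits = 17), collapse = "\t"), "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_experiment
#' @export
read_experiment <- function(path) {
  lines <- readLines(path)
  header <- strsplit(lines[1L], "\t")[[1L]]
  q_grid <- as.numeric(header[-1L])
  vals <- lapply(strsplit(lines[-1L], "\t"), as.numeric)
  mat <- do.call(rbind, vals)
  structure(list(times = mat[, 1L], q_grid = q_grid,
                 intensity = mat[, -1L, drop = FALSE]),
            class = "scattering_experiment")
}
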