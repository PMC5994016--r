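# shared fixtures, built once per test run

dodec_model <- function() {
  if (is.null(.capsid_test_cache$model))
    .capsid_test_cache$model <- build_dodecahedron()
  .capsid_test_cache$model
}

dodec_table <- function() {
  if (is.null(.capsid_test_cache$table))
    .capsid_test_cache$table <- dodecamer_species()
  .capsid_test_cache$table
}

.capsid_test_cache <- new.env(parent = emptyenv())

# truncate the species table to sizes <= max_size (closed sub-network)
truncate_table <- function(table, max_size) {
  keep <- table$species$size <= max_size
  sp <- table$species[keep, , drop = FALSE]
  ed <- table$edges[table$edges$m <= max_size, , drop = FALSE]
  rownames(sp) <- rownames(ed) <- NULL
  structure(list(species = sp, edges = ed, model = table$model),
            class = "species_table")
}

# a small, fast study: short time grid, same physics as the default study
tiny_ode_objective <- function(grouping = "paired6", n_times = 8) {
  key <- paste0("obj_", grouping, "_", n_times)
  if (is.null(.capsid_test_cache[[key]])) {
    cfg <- study_config(if (grouping == "paired6") "ode6" else "ode12",
                        sample_times = 10^seq(0, 5, length.out = n_times))
    .capsid_test_cache[[key]] <- make_ground_truth(cfg)
  }
  .capsid_test_cache[[key]]
}

# independent brute-force orbit enumeration: all connected face subsets of a
# given size, partitioned into rotation orbits with the pairwise isomorphism
# test (bond count used only as a cheap invariant prefilter)
brute_force_species_count <- function(model, size) {
  if (size == 1L) return(1L)
  combs <- utils::combn(model$face_count, size)
  conn <- combs[, vapply(seq_len(ncol(combs)), function(i)
    capsidgp:::faces_connected(combs[, i], model), TRUE), drop = FALSE]
  reps <- list()
  for (i in seq_len(ncol(conn))) {
    f <- conn[, i]
    b <- capsidgp:::count_bonds(f, model)
    found <- FALSE
    for (r in reps) {
      if (r$bonds == b && are_isomorphic(r$faces, f, model)) {
        found <- TRUE; break
      }
    }
    if (!found) reps[[length(reps) + 1L]] <- list(faces = f, bonds = b)
  }
  length(reps)
}
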