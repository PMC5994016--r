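#' Build the dodecahedron model
#'
#' Constructs the geometric scaffold for the 12-pentamer model capsid: the
#' twelve face centroids of a regular dodecahedron (equivalently, the vertices
#' of its dual icosahedron) at unit circumradius, the face adjacency relation
#' (faces sharing an edge), and the full 60-element rotation group of the
#' solid.
#'
#' The rotation set is built constructively as the composition of the 12 face
#' placements (identity plus 11 rotations that successively move each face
#' into the reference location occupied by face 1) with the 5 in-plane
#' rotations about the face-1 axis (identity plus 4 rotations by multiples of
#' 72 degrees), giving 12 x 5 = 60 orthogonal transforms. Each transform
#' permutes the centroid set within numeric tolerance.
#'
#' @param tol absolute tolerance for coordinate identity on the unit sphere.
#' @return An object of class `polyhedron_model` with elements
#'   `face_count`, `centroids` (12 x 3 matrix of unit vectors), `adjacency`
#'   (list of neighbor index vectors), `adjacency_matrix`, `rotations` (list
#'   of 60 3x3 matrices), `face_permutations` (60 x 12 integer matrix, row g
#'   giving the face image under rotation g), `edges_per_face`, and `tol`.
#' @export
build_dodecahedron <- function(tol = 1e-6) {
  phi <- (1 + sqrt(5)) / 2
  # face centroids of the dodecahedron = icosahedron vertices (cyclic (0, +-1, +-phi))
  raw <- rbind(
    c(0,  1,  phi), c(0, -1,  phi), c(0,  1, -phi), c(0, -1, -phi),
    c( 1,  phi, 0), c(-1,  phi, 0), c( 1, -phi, 0), c(-1, -phi, 0),
    c( phi, 0,  1), c( phi, 0, -1), c(-phi, 0,  1), c(-phi, 0, -1)
  )
  centroids <- raw / sqrt(1 + phi^2)

  # neighbors are the 5 closest centroids (pairwise dot product 1/sqrt(5))
  dots <- centroids %*% t(centroids)
  adj_mat <- dots > 0.3 & dots < 0.9
  adjacency <- lapply(seq_len(12), function(i) which(adj_mat[i, ]))
  stopifnot(all(vapply(adjacency, length, 1L) == 5L))

  normalize <- function(v) v / sqrt(sum(v^2))
  # orthonormal frame anchored at a (face centroid, neighbor) flag
  frame_at <- function(f, nb) {
    u <- centroids[f, ]
    v <- normalize(centroids[nb, ] - sum(centroids[nb, ] * u) * u)
    w <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    cbind(u, v, w)
  }

  f1 <- frame_at(1L, adjacency[[1L]][1L])
  # rotation about the face-1 axis by 2*pi*k/5, expressed in the f1 frame
  axis_spin <- function(k) {
    th <- 2 * pi * k / 5
    s <- matrix(c(1, 0, 0,
                  0, cos(th), -sin(th),
                  0, sin(th),  cos(th)), 3, 3, byrow = TRUE)
    f1 %*% s %*% t(f1)
  }

  rotations <- vector("list", 60L)
  idx <- 0L
  for (f in seq_len(12)) {
    place <- frame_at(f, adjacency[[f]][1L]) %*% t(f1)  # maps face 1 onto face f
    for (k in 0:4) {
      idx <- idx + 1L
      rotations[[idx]] <- place %*% axis_spin(k)
    }
  }

  # face permutation induced by each rotation
  face_permutations <- matrix(0L, 60L, 12L)
  for (g in seq_len(60)) {
    rotated <- centroids %*% t(rotations[[g]])
    d2 <- outer(rowSums(rotated^2), rowSums(centroids^2), "+") -
      2 * rotated %*% t(centroids)
    perm <- apply(d2, 1L, which.min)
    if (any(d2[cbind(seq_len(12), perm)] > tol^2) || anyDuplicated(perm))
      stop("rotation ", g, " does not permute the centroid set")
    face_permutations[g, ] <- as.integer(perm)
  }

  structure(list(
    face_count = 12L,
    centroids = centroids,
    adjacency = adjacency,
    adjacency_matrix = adj_mat,
    rotations = rotations,
    face_permutations = face_permutations,
    edges_per_face = 5L,
    tol = tol
  ), class = "polyhedron_model")
}

#' Construct an oligomer (partial capsid) on a polyhedron model
#'
#' @param faces integer vector of face indices (1..12), a connected subset.
#' @param model a `polyhedron_model`.
#' @return An object of class `oligomer` with `faces` (sorted), `size`, and
#'   `bonds` (number of adjacent face pairs inside the subset).
#' @export
oligomer <- function(faces, model) {
  faces <- sort(unique(as.integer(faces)))
  if (length(faces) == 0L) stop("oligomer must be non-empty")
  if (any(faces < 1L | faces > model$face_count))
    stop("invalid face index; faces must lie in 1..", model$face_count)
  if (!faces_connected(faces, model))
    stop("oligomer faces must be connected under adjacency")
  structure(list(faces = faces, size = length(faces),
                 bonds = count_bonds(faces, model)),
            class = "oligomer")
}

count_bonds <- function(faces, model) {
  if (length(faces) < 2L) return(0L)
  sum(model$adjacency_matrix[faces, faces, drop = FALSE]) %/% 2L
}

faces_connected <- function(faces, model) {
  n <- length(faces)
  if (n <= 1L) return(TRUE)
  seen <- logical(n)
  seen[1L] <- TRUE
  frontier <- faces[1L]
  while (length(frontier)) {
    nb <- unique(unlist(model$adjacency[frontier]))
    hit <- !seen & faces %in% nb
    if (!any(hit)) break
    seen[hit] <- TRUE
    frontier <- faces[hit]
  }
  all(seen)
}

#' Test two oligomers for rotational isomorphism
#'
#' Two partial assemblies are isomorphic when some rotation of the 60-element
#' group maps the face-centroid set of one onto the centroid set of the other
#' (coordinate identity within the model tolerance). Each of the 12 x 5
#' orientations of the first oligomer is applied in turn and the resulting
#' coordinates compared against the second oligomer.
#'
#' @param a,b `oligomer` objects (or plain face-index vectors) on `model`.
#' @param model a `polyhedron_model`.
#' @return `TRUE` if isomorphic, else `FALSE`. Symmetric in its arguments.
#' @export
are_isomorphic <- function(a, b, model) {
  fa <- if (inherits(a, "oligomer")) a$faces else oligomer(a, model)$faces
  fb <- if (inherits(b, "oligomer")) b$faces else oligomer(b, model)$faces
  if (length(fa) != length(fb)) return(FALSE)
  target <- model$centroids[fb, , drop = FALSE]
  tol2 <- model$tol^2
  for (g in seq_along(model$rotations)) {
    rotated <- model$centroids[fa, , drop = FALSE] %*% t(model$rotations[[g]])
    # greedy match: every rotated centroid must coincide with a target centroid
    d2 <- outer(rowSums(rotated^2), rowSums(target^2), "+") -
      2 * rotated %*% t(target)
    hit <- apply(d2, 1L, which.min)
    if (all(d2[cbind(seq_along(hit), hit)] <= tol2) && !anyDuplicated(hit))
      return(TRUE)
  }
  FALSE
}

# canonical key: lexicographically minimal sorted face set over all rotations
canonical_key <- function(faces, model) {
  best <- NULL
  for (g in seq_len(nrow(model$face_permutations))) {
    img <- sort(model$face_permutations[g, faces])
    if (is.null(best) || lex_less(img, best)) best <- img
  }
  paste(best, collapse = ",")
}

lex_less <- function(a, b) {
  d <- a - b
  nz <- which(d != 0L)
  length(nz) > 0L && d[nz[1L]] < 0L
}

#' Enumerate all structurally unique assembly intermediates
#'
#' Breadth-first growth of the state space from the single pentamer occupying
#' face 1: each species of size j is extended by adding a monomer at every
#' free binding site (an edge between a face inside the oligomer and one
#' outside it), and each generated oligomer is identified up to rotational
#' isomorphism with the stored species of size j + 1. Every isomorphic
#' generation increments the forward reaction degeneracy `a` of the edge.
#' Backward degeneracies `b` count the single-face removals of the larger
#' species that leave a connected oligomer isomorphic to the smaller one.
#'
#' @param model a `polyhedron_model`.
#' @return An object of class `species_table`: `species` is a data frame with
#'   columns `size` (j), `index` (k), `faces` (comma-separated canonical face
#'   list), `bonds` (c); `edges` is a data frame with columns
#'   `j, k, m, n, a, b` for every monomer-addition reaction
#'   (j,k) + monomer <-> (m,n), m = j + 1; `model` is the polyhedron.
#' @export
enumerate_species <- function(model) {
  # species bookkeeping: per size, list of representative face vectors
  reps <- vector("list", 12L)       # reps[[j]][[k]] = face vector
  keys <- new.env(parent = emptyenv())  # canonical key -> c(j, k)
  amap <- new.env(parent = emptyenv())  # "j,k,m,n" -> forward degeneracy

  seed <- 1L
  reps[[1L]] <- list(seed)
  assign(canonical_key(seed, model), c(1L, 1L), envir = keys)

  for (j in seq_len(11L)) {
    for (k in seq_along(reps[[j]])) {
      faces <- reps[[j]][[k]]
      inside <- logical(model$face_count)
      inside[faces] <- TRUE
      for (f in faces) {
        for (nb in model$adjacency[[f]]) {
          if (inside[nb]) next
          # one free binding site: edge (f, nb)
          cand <- sort(c(faces, nb))
          key <- canonical_key(cand, model)
          hit <- keys[[key]]
          if (is.null(hit)) {
            reps[[j + 1L]] <- c(reps[[j + 1L]], list(cand))
            hit <- c(j + 1L, length(reps[[j + 1L]]))
            assign(key, hit, envir = keys)
          }
          ekey <- paste(j, k, hit[1L], hit[2L], sep = ",")
          amap[[ekey]] <- (if (is.null(amap[[ekey]])) 0L else amap[[ekey]]) + 1L
        }
      }
    }
  }

  # species data frame
  sizes <- rep(seq_len(12L), vapply(reps, length, 1L))
  index <- unlist(lapply(reps, seq_along))
  face_str <- unlist(lapply(reps, function(l)
    vapply(l, paste, "", collapse = ",")), use.names = FALSE)
  bonds <- unlist(lapply(reps, function(l)
    vapply(l, count_bonds, 0L, model = model)), use.names = FALSE)
  species <- data.frame(size = sizes, index = index,
                        faces = face_str, bonds = bonds,
                        stringsAsFactors = FALSE)

  # backward degeneracies: exhaustive single-face removal
  ekeys <- ls(amap)
  em <- do.call(rbind, lapply(ekeys, function(x) as.integer(strsplit(x, ",")[[1L]])))
  edges <- data.frame(j = em[, 1L], k = em[, 2L], m = em[, 3L], n = em[, 4L],
                      a = vapply(ekeys, function(x) as.integer(amap[[x]]), 1L,
                                 USE.NAMES = FALSE))
  edges <- edges[order(edges$j, edges$k, edges$m, edges$n), , drop = FALSE]
  rownames(edges) <- NULL

  edges$b <- 0L
  for (r in seq_len(nrow(edges))) {
    mm <- edges$m[r]; nn <- edges$n[r]
    big <- reps[[mm]][[nn]]
    small_key <- canonical_key(reps[[edges$j[r]]][[edges$k[r]]], model)
    nb_match <- 0L
    for (f in big) {
      rem <- setdiff(big, f)
      if (faces_connected(rem, model) &&
          canonical_key(rem, model) == small_key)
        nb_match <- nb_match + 1L
    }
    edges$b[r] <- nb_match
  }
  stopifnot(all(edges$a > 0L), all(edges$b > 0L))

  structure(list(species = species, edges = edges, model = model),
            class = "species_table")
}

#' @export
print.species_table <- function(x, ...) {
  cat("Species table:", nrow(x$species), "unique intermediates,",
      nrow(x$edges), "monomer-addition reactions\n")
  cat("per size:", paste(table(factor(x$species$size, levels = 1:12)),
                         collapse = " "), "\n")
  invisible(x)
}

species_id <- function(table) paste0("s", table$species$size, ".", table$species$index)

species_row <- function(table, j, k) {
  which(table$species$size == j & table$species$index == k)
}

species_faces <- function(table, row) {
  as.integer(strsplit(table$species$faces[row], ",")[[1L]])
}

#' Write / read a species table as TSV
#'
#' Serializes the unique-species list (size, index, face_list, bond_count)
#' and the degeneracy edge list (j, k, m, n, a, b) as two tab-separated
#' files.
#'
#' @param table a `species_table`.
#' @param species_path,edges_path output (input) file paths.
#' @param model for reading: the `polyhedron_model` the table refers to.
#' @return `write_species_table` returns the paths invisibly;
#'   `read_species_table` returns a `species_table`.
#' @export
write_species_table <- function(table, species_path, edges_path) {
  sp <- table$species
  names(sp) <- c("size", "index", "face_list", "bond_count")
  utils::write.table(sp, species_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(table$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(species_path, edges_path))
}

#' @rdname write_species_table
#' @export
read_species_table <- function(species_path, edges_path, model = build_dodecahedron()) {
  sp <- utils::read.table(species_path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "integer", "character", "integer"))
  names(sp) <- c("size", "index", "faces", "bonds")
  ed <- utils::read.table(edges_path, sep = "\t", header = TRUE)
  structure(list(species = sp, edges = ed, model = model),
            class = "species_table")
}
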