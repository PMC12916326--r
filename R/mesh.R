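#' Build a spherical spring mesh with an exact equatorial ring
#'
#' Constructs the spring network the simulator runs on. The default
#' (`type = "ball"`) is a volumetric ball: the cytoplasm is bulk material,
#' and its measured viscoelastic moduli only make sense attached to edges
#' that fill the cell volume. Vertices are the integer lattice points of an
#' L1 ball (`|i| + |j| + |k| <= m`), connected along the axis directions
#' and the twelve face diagonals (a rigid, triangulated lattice), then
#' mapped radially onto the Euclidean ball of radius `R` (each point is
#' scaled by its L1/L2 norm ratio, which sends the lattice boundary exactly
#' onto the sphere). The boundary cross-section in the z = 0 symmetry plane
#' is an exact planar cycle of `4 m` edges -- the "line of springs" around
#' the equator that carries the contractile band -- and the mesh is
#' mirror-symmetric across that plane by construction. `m` is chosen so the
#' equatorial edge length is as close as possible to `target_edge_length`.
#'
#' `type = "shell"` gives the corresponding hollow sphere: midpoint
#' subdivision of an octahedron projected to radius `R` (the octahedron,
#' unlike an icosahedron, has a planar equatorial edge cycle that survives
#' subdivision). The shell is kept for comparison and for cheap geometric
#' tests; it lacks bulk support, so a contractile band deforms it very
#' differently from a cytoplasm-filled cell.
#'
#' The equator cycle is parameterised by the angle theta measured from the
#' band-nucleation vertex at (R, 0, 0): one growth arc runs in the +theta
#' direction (phi = 0), the other in -theta (phi = pi).
#'
#' @param R sphere radius (um); the blastomere scale is 350 um.
#' @param target_edge_length requested equatorial edge length (um), in
#'   (0, R).
#' @param seed unused; both constructions are fully deterministic. Accepted
#'   so callers can treat mesh building like the seeded generators.
#' @param type `"ball"` (volumetric, default) or `"shell"` (hollow).
#' @return An object of class `spherical_mesh`: `vertices` (V x 3 matrix,
#'   um), `edges` (E x 2 integer matrix, 1-based), `rest_lengths` (E),
#'   `radius`, `type`, and `equator` with `vertex_ids` (cyclic, starting at
#'   the band centre), `edge_ids` (cyclic, edge i joins vertex i to i+1),
#'   `theta`, `centre_vertex`, and the two growth arcs `arc_pos`/`arc_neg`
#'   (edge ids ordered outward from the centre, each covering the full
#'   cycle).
#' @export
build_mesh <- function(R = 350, target_edge_length = 35, seed = NULL,
                       type = c("ball", "shell")) {
  type <- match.arg(type)
  check_positive(R, "R")
  check_positive(target_edge_length, "target_edge_length")
  if (target_edge_length >= R)
    stop_invalid("target_edge_length must be smaller than R")
  if (type == "ball") build_ball_mesh(R, target_edge_length)
  else build_shell_mesh(R, target_edge_length)
}

build_ball_mesh <- function(R, target_edge_length) {
  m <- max(2L, as.integer(round(2 * pi * R / (4 * target_edge_length))))
  if (m > 40L) stop_invalid("requested resolution is infeasibly fine")
  rng <- -m:m
  grid <- expand.grid(i = rng, j = rng, k = rng)
  keep <- abs(grid$i) + abs(grid$j) + abs(grid$k) <= m
  P <- as.matrix(grid[keep, ])
  nv <- nrow(P)
  # dense index lookup over the bounding cube
  dim3 <- 2L * m + 1L
  lin <- function(i, j, k) (i + m) + dim3 * (j + m) + dim3^2 * (k + m) + 1L
  id <- integer(dim3^3)
  id[lin(P[, 1], P[, 2], P[, 3])] <- seq_len(nv)
  offs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                c(1, 0, -1), c(0, 1, 1), c(0, 1, -1))
  e1 <- integer(0); e2 <- integer(0)
  for (o in seq_len(nrow(offs))) {
    qi <- P[, 1] + offs[o, 1]; qj <- P[, 2] + offs[o, 2]
    qk <- P[, 3] + offs[o, 3]
    ok <- abs(qi) + abs(qj) + abs(qk) <= m
    tgt <- id[lin(qi[ok], qj[ok], qk[ok])]
    src <- which(ok)
    hit <- tgt > 0L
    e1 <- c(e1, src[hit]); e2 <- c(e2, tgt[hit])
  }
  E <- cbind(pmin(e1, e2), pmax(e1, e2))
  E <- unique(E)
  E <- E[order(E[, 1], E[, 2]), , drop = FALSE]
  storage.mode(E) <- "integer"
  # radial map: L1 ball -> Euclidean ball (boundary -> sphere of radius R)
  l1 <- rowSums(abs(P)); l2 <- sqrt(rowSums(P^2))
  sc <- ifelse(l2 > 0, l1 / l2, 0) * R / m
  V <- P * sc
  rest <- sqrt(rowSums((V[E[, 1], ] - V[E[, 2], ])^2))
  ring <- which(abs(P[, 1]) + abs(P[, 2]) == m & P[, 3] == 0)
  finish_mesh(V, E, rest, R, ring, type = "ball")
}

build_shell_mesh <- function(R, target_edge_length) {
  n_sub <- max(0L, as.integer(round(log2(2 * pi * R /
                                           (4 * target_edge_length)))))
  if (n_sub > 7L) stop_invalid("requested resolution is infeasibly fine")
  verts <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  faces <- rbind(c(1, 2, 5), c(2, 3, 5), c(3, 4, 5), c(4, 1, 5),
                 c(2, 1, 6), c(3, 2, 6), c(4, 3, 6), c(1, 4, 6))
  for (s in seq_len(n_sub)) {
    midpoint <- new.env(hash = TRUE)
    nv <- nrow(verts)
    vlist <- vector("list", nrow(verts) + 3L * nrow(faces))
    for (i in seq_len(nv)) vlist[[i]] <- verts[i, ]
    get_mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idm <- midpoint[[key]]
      if (!is.null(idm)) return(idm)
      mid <- (vlist[[i]] + vlist[[j]]) / 2
      mid <- mid / sqrt(sum(mid^2))
      nv <<- nv + 1L
      vlist[[nv]] <<- mid
      midpoint[[key]] <- nv
      nv
    }
    newf <- matrix(0L, 4L * nrow(faces), 3L)
    for (fi in seq_len(nrow(faces))) {
      a <- faces[fi, 1]; b <- faces[fi, 2]; cc <- faces[fi, 3]
      ab <- get_mid(a, b); bc <- get_mid(b, cc); ca <- get_mid(cc, a)
      newf[4L * fi - 3L, ] <- c(a, ab, ca)
      newf[4L * fi - 2L, ] <- c(b, bc, ab)
      newf[4L * fi - 1L, ] <- c(cc, ca, bc)
      newf[4L * fi, ] <- c(ab, bc, ca)
    }
    verts <- do.call(rbind, vlist[seq_len(nv)])
    faces <- newf
  }
  verts <- verts * R
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  storage.mode(e) <- "integer"
  rest <- sqrt(rowSums((verts[e[, 1], ] - verts[e[, 2], ])^2))
  ring <- which(abs(verts[, 3]) < 1e-9 * R)
  finish_mesh(verts, e, rest, R, ring, type = "shell")
}

# order the equator ring by angle, resolve its edges, assemble the object
finish_mesh <- function(V, E, rest, R, ring, type) {
  ang <- atan2(V[ring, 2], V[ring, 1])
  ord <- order((ang + 2 * pi) %% (2 * pi))
  ring <- ring[ord]
  theta <- ((ang[ord] + 2 * pi) %% (2 * pi))
  ekey <- paste(E[, 1], E[, 2])
  nxt <- c(ring[-1], ring[1])
  eid <- mapply(function(a, b) match(paste(min(a, b), max(a, b)), ekey),
                ring, nxt)
  if (anyNA(eid)) stop_invalid("equator cycle is broken: missing edge")
  structure(list(vertices = unname(V), edges = unname(E),
                 rest_lengths = unname(rest),
                 radius = R, type = type,
                 equator = list(vertex_ids = ring, edge_ids = unname(eid),
                                theta = theta, centre_vertex = ring[1],
                                arc_pos = unname(eid),
                                arc_neg = rev(unname(eid)))),
            class = "spherical_mesh")
}

#' @export
print.spherical_mesh <- function(x, ...) {
  cat(sprintf(
    "Spherical spring mesh (%s): R = %g um, %d vertices, %d edges, %d equator edges\n",
    x$type, x$radius, nrow(x$vertices), nrow(x$edges),
    length(x$equator$edge_ids)))
  invisible(x)
}

#' Current edge lengths of a mesh configuration
#'
#' @param mesh a [build_mesh()] object.
#' @param positions optional V x 3 matrix of current vertex positions
#'   (defaults to the mesh's reference positions).
#' @return numeric vector of edge lengths (um).
#' @export
edge_lengths <- function(mesh, positions = mesh$vertices) {
  sqrt(rowSums((positions[mesh$edges[, 1], , drop = FALSE] -
                  positions[mesh$edges[, 2], , drop = FALSE])^2))
}

#' Export a mesh snapshot as OFF text
#'
#' Writes vertices (and no faces; the simulator tracks edges only) in the
#' plain-text OFF dialect for quick visualisation.
#'
#' @param mesh a [build_mesh()] object.
#' @param path output file path.
#' @param positions optional current vertex positions.
#' @return `path`, invisibly.
#' @export
write_mesh_off <- function(mesh, path, positions = mesh$vertices) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d 0 %d", nrow(positions), nrow(mesh$edges)), con)
  writeLines(sprintf("%.6f %.6f %.6f",
                     positions[, 1], positions[, 2], positions[, 3]), con)
  invisible(path)
}
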