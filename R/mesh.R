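## Triangulated closed surfaces: construction, refinement, validation.
## Coordinates are in mm throughout; triangles are wound counterclockwise as
## seen from outside (outward normals).

#' Construct a triangulated surface mesh
#'
#' @param nodes numeric N x 3 matrix of vertex coordinates (mm).
#' @param triangles integer M x 3 matrix of 1-based vertex indices, wound
#'   counterclockwise seen from outside the enclosed volume.
#' @param validate check closedness, orientation and non-degeneracy.
#' @return An object of class `surface_mesh` with elements `nodes`,
#'   `triangles`.
#' @export
surface_mesh <- function(nodes, triangles, validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(nodes) <- dimnames(triangles) <- NULL
  if (ncol(nodes) != 3L) stopf("nodes must be N x 3")
  if (ncol(triangles) != 3L) stopf("triangles must be M x 3")
  if (min(triangles) < 1L || max(triangles) > nrow(nodes)) {
    stopf("triangle indices out of range")
  }
  m <- structure(list(nodes = nodes, triangles = triangles),
                 class = "surface_mesh")
  if (validate) {
    if (!mesh_is_closed(m)) {
      stopf("mesh is not a closed, consistently oriented surface (every edge must be shared by exactly two triangles with opposite direction)")
    }
    a <- triangle_areas(m)
    if (any(a <= 1e-12)) stopf("mesh has %d degenerate (zero-area) triangles", sum(a <= 1e-12))
  }
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d nodes, %d triangles, mean edge %.2f mm\n",
              nrow(x$nodes), nrow(x$triangles), mean(mesh_edge_lengths(x))))
  invisible(x)
}

#' Closedness / orientation check
#'
#' A closed, consistently wound triangulation uses every undirected edge in
#' exactly two triangles, once in each direction.
#' @param mesh a `surface_mesh`.
#' @return logical.
#' @export
mesh_is_closed <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key_dir <- paste(e[, 1], e[, 2])
  if (anyDuplicated(key_dir)) return(FALSE)   # repeated directed edge
  key_undir <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key_undir) == 2L)
}

triangle_corners <- function(mesh) {
  tr <- mesh$triangles
  list(a = mesh$nodes[tr[, 1], , drop = FALSE],
       b = mesh$nodes[tr[, 2], , drop = FALSE],
       c = mesh$nodes[tr[, 3], , drop = FALSE])
}

## un-normalized outward normals (2x area vectors), one row per triangle
triangle_normals_raw <- function(mesh) {
  co <- triangle_corners(mesh)
  u <- co$b - co$a
  v <- co$c - co$a
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

triangle_areas <- function(mesh) {
  n <- triangle_normals_raw(mesh)
  0.5 * sqrt(rowSums(n^2))
}

#' Edge list and edge lengths
#'
#' @param mesh a `surface_mesh`.
#' @return `mesh_edges`: integer E x 2 matrix of unique undirected edges.
#' @export
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' @rdname mesh_edges
#' @export
mesh_edge_lengths <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- mesh$nodes[e[, 1], , drop = FALSE] - mesh$nodes[e[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Per-node 1-ring adjacency
#'
#' @param mesh a `surface_mesh`.
#' @return list of integer vectors, `[[i]]` = indices of nodes sharing an edge
#'   with node i.
#' @export
mesh_adjacency <- function(mesh) {
  e <- mesh_edges(mesh)
  n <- nrow(mesh$nodes)
  adj <- split(c(e[, 2], e[, 1]), factor(c(e[, 1], e[, 2]), levels = seq_len(n)))
  lapply(adj, function(v) sort(unique(v)))
}

## Icosahedron with circumscribed radius 1
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(nodes = v, triangles = f)
}

## One midpoint-subdivision pass; optionally re-project nodes to the unit
## sphere (used when building icospheres; plain refinement leaves them off).
subdivide_once <- function(nodes, triangles, project = FALSE) {
  n0 <- nrow(nodes)
  edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  tr <- triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  keys <- edge_key(e[, 1], e[, 2])
  ukeys <- unique(keys)
  mid_id <- setNames(seq_along(ukeys) + n0, ukeys)
  ue <- e[!duplicated(keys), , drop = FALSE]
  mids <- (nodes[ue[, 1], , drop = FALSE] + nodes[ue[, 2], , drop = FALSE]) / 2
  if (project) mids <- mids / sqrt(rowSums(mids^2))
  nodes2 <- rbind(nodes, mids)
  m12 <- mid_id[edge_key(tr[, 1], tr[, 2])]
  m23 <- mid_id[edge_key(tr[, 2], tr[, 3])]
  m31 <- mid_id[edge_key(tr[, 3], tr[, 1])]
  tri2 <- rbind(
    cbind(tr[, 1], m12, m31),
    cbind(tr[, 2], m23, m12),
    cbind(tr[, 3], m31, m23),
    cbind(m12, m23, m31))
  list(nodes = nodes2, triangles = tri2)
}

#' Icosphere mesh
#'
#' Icosahedron subdivided `subdivisions` times with re-projection to the
#' sphere; node count is `10 * 4^subdivisions + 2`.
#'
#' @param subdivisions subdivision level (>= 0).
#' @param radius sphere radius (mm).
#' @return a `surface_mesh`.
#' @export
icosphere <- function(subdivisions = 2, radius = 1) {
  ico <- icosahedron()
  for (k in seq_len(subdivisions)) {
    ico <- subdivide_once(ico$nodes, ico$triangles, project = TRUE)
  }
  surface_mesh(ico$nodes * radius, ico$triangles)
}

#' Concentric epicardial/torso mesh pair
#'
#' Builds an icosphere "epicardium" of radius `epi_radius_mm` and an
#' anisotropically scaled icosphere "torso" with semi-axes `torso_radii_mm`
#' (an ellipsoid standing in for the human-shaped tank). The torso must
#' strictly enclose the epicardial surface.
#'
#' @param epi_subdivisions,torso_subdivisions icosphere subdivision levels
#'   (>= 1).
#' @param epi_radius_mm epicardial sphere radius.
#' @param torso_radii_mm length-3 vector of torso ellipsoid semi-axes (mm).
#' @return list with elements `epi` and `torso` (both `surface_mesh`).
#' @export
generate_concentric_meshes <- function(epi_subdivisions = 2,
                                       torso_subdivisions = 2,
                                       epi_radius_mm = 30,
                                       torso_radii_mm = c(100, 150, 80)) {
  if (epi_subdivisions < 1 || torso_subdivisions < 1) {
    stopf("subdivision level must be >= 1")
  }
  if (length(torso_radii_mm) != 3L) stopf("torso_radii_mm must have length 3")
  epi <- icosphere(epi_subdivisions, epi_radius_mm)
  torso <- icosphere(torso_subdivisions, 1)
  torso$nodes <- sweep(torso$nodes, 2, torso_radii_mm, `*`)
  ## containment: every epicardial node strictly inside the torso ellipsoid
  q <- sweep(epi$nodes, 2, torso_radii_mm, `/`)
  r2 <- rowSums(q^2)
  if (any(r2 >= 1)) {
    stopf(paste0("epicardial surface not enclosed by torso: %d of %d nodes on ",
                 "or outside the torso ellipsoid (max normalized radius %.3f)"),
          sum(r2 >= 1), nrow(epi$nodes), sqrt(max(r2)))
  }
  list(epi = epi, torso = torso)
}

#' Midpoint mesh refinement
#'
#' Repeats midpoint subdivision (no re-projection) until the mean edge length
#' is at or below `target_edge_mm`. Closedness and winding are preserved; a
#' mesh already meeting the target is returned unchanged.
#'
#' @param mesh a closed `surface_mesh`.
#' @param target_edge_mm target mean edge length (mm).
#' @return a `surface_mesh`.
#' @export
refine_mesh <- function(mesh, target_edge_mm) {
  if (!mesh_is_closed(mesh)) stopf("refine_mesh requires a closed mesh")
  cur <- list(nodes = mesh$nodes, triangles = mesh$triangles)
  while (mean_edge(cur) > target_edge_mm) {
    cur <- subdivide_once(cur$nodes, cur$triangles, project = FALSE)
  }
  surface_mesh(cur$nodes, cur$triangles)
}

mean_edge <- function(m) {
  mean(mesh_edge_lengths(list(nodes = m$nodes, triangles = m$triangles)))
}

#' Apply a rigid-body transform to a mesh
#'
#' @param mesh a `surface_mesh`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (mm).
#' @return transformed `surface_mesh`.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  surface_mesh(sweep(mesh$nodes %*% t(rotation), 2, translation, `+`),
               mesh$triangles, validate = FALSE)
}
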