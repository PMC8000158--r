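## Boundary element forward model: homogeneous volume conductor bounded
## externally by the torso surface (zero normal current) and internally by
## the epicardium (potential sources). Double-layer collocation at mesh
## vertices with linear interpolation over triangles; the epicardial normal
## current density is eliminated through the single-layer block, yielding the
## node-potential transfer matrix A (torso = A %*% epicardium).

#' Signed solid angle of a triangle
#'
#' Robust van Oosterom-Strackee formula. The sign follows the triangle
#' winding: positive when the triangle is seen counterclockwise from the
#' point (i.e. its outward normal faces away); an outward-wound closed mesh
#' sums to 4*pi from an interior point and 0 from an exterior point.
#'
#' @param triangle 3 x 3 matrix, one vertex per row.
#' @param point length-3 coordinates.
#' @return solid angle in steradians; if the point lies in the triangle's
#'   plane (within tolerance) returns 0 with attribute `degenerate = TRUE`.
#' @export
solid_angle <- function(triangle, point) {
  v1 <- triangle[1, ] - point
  v2 <- triangle[2, ] - point
  v3 <- triangle[3, ] - point
  l1 <- sqrt(sum(v1^2)); l2 <- sqrt(sum(v2^2)); l3 <- sqrt(sum(v3^2))
  num <- v1[1] * (v2[2] * v3[3] - v2[3] * v3[2]) -
         v1[2] * (v2[1] * v3[3] - v2[3] * v3[1]) +
         v1[3] * (v2[1] * v3[2] - v2[2] * v3[1])
  den <- l1 * l2 * l3 + sum(v1 * v2) * l3 + sum(v1 * v3) * l2 + sum(v2 * v3) * l1
  scale <- max(l1 * l2 * l3, .Machine$double.eps)
  if (abs(num) / scale < 1e-12) {
    return(structure(0, degenerate = TRUE))
  }
  2 * atan2(num, den)
}

## Solid angles of every triangle of `mesh` from each row of `points`:
## vectorized VOS. Returns n_points x n_triangles matrix.
mesh_solid_angles <- function(points, mesh) {
  co <- triangle_corners(mesh)
  np <- nrow(points)
  nt <- nrow(mesh$triangles)
  out <- matrix(0, np, nt)
  for (j in seq_len(nt)) {
    v1 <- sweep(points, 2, co$a[j, ], `-`) * -1
    v2 <- sweep(points, 2, co$b[j, ], `-`) * -1
    v3 <- sweep(points, 2, co$c[j, ], `-`) * -1
    l1 <- sqrt(rowSums(v1^2)); l2 <- sqrt(rowSums(v2^2)); l3 <- sqrt(rowSums(v3^2))
    num <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
           v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
           v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
    den <- l1 * l2 * l3 + rowSums(v1 * v2) * l3 +
           rowSums(v1 * v3) * l2 + rowSums(v2 * v3) * l1
    om <- 2 * atan2(num, den)
    om[abs(num) / pmax(l1 * l2 * l3, .Machine$double.eps) < 1e-12] <- 0
    out[, j] <- om
  }
  out
}

## Dunavant 7-point degree-5 rule; barycentric coordinates + weights
## (weights sum to 1; multiply by triangle area).
tri_quadrature <- function() {
  a1 <- 0.0597158717897698; b1 <- 0.4701420641051151
  a2 <- 0.7974269853530873; b2 <- 0.1012865073234563
  bary <- rbind(c(1/3, 1/3, 1/3),
                c(a1, b1, b1), c(b1, a1, b1), c(b1, b1, a1),
                c(a2, b2, b2), c(b2, a2, b2), c(b2, b2, a2))
  w <- c(0.225,
         rep(0.1323941527885062, 3),
         rep(0.1259391805448271, 3))
  list(bary = bary, w = w)
}

## Subdivide one triangle (rows of bary coords of its corners in the parent)
## into 4; used for near-singular quadrature refinement.
subdiv_bary <- function(B) {
  m12 <- (B[1, ] + B[2, ]) / 2; m23 <- (B[2, ] + B[3, ]) / 2
  m31 <- (B[3, ] + B[1, ]) / 2
  list(rbind(B[1, ], m12, m31), rbind(B[2, ], m23, m12),
       rbind(B[3, ], m31, m23), rbind(m12, m23, m31))
}

## Quadrature points/weights (in parent barycentric coords) for a triangle
## refined to `depth` levels; returns list(bary = K x 3, w = K) with
## sum(w) == 1.
refined_quadrature <- function(depth = 0) {
  q <- tri_quadrature()
  tris <- list(diag(3))
  d <- depth
  while (d > 0) {
    tris <- unlist(lapply(tris, subdiv_bary), recursive = FALSE)
    d <- d - 1
  }
  bary <- do.call(rbind, lapply(tris, function(B) q$bary %*% B))
  w <- rep(q$w / length(tris), times = length(tris))
  list(bary = bary, w = w)
}

## Double-layer block: entries (1/4pi) * int lambda_j(y) ((x_i - y).nu / R^3) dS
## over the source mesh; nu = nu_sign * outward normal. `self` marks that the
## observation points are exactly the source-mesh nodes (incident triangle
## contributions are then analytically zero and are masked).
assemble_double_layer <- function(points, mesh, nu_sign = 1, self = FALSE) {
  np <- nrow(points); nn <- nrow(mesh$nodes)
  co <- triangle_corners(mesh)
  nrm <- triangle_normals_raw(mesh)          # 2*area*outward normal
  q <- tri_quadrature()
  nq <- length(q$w)
  D <- matrix(0, np, nn)
  omega <- mesh_solid_angles(points, mesh)   # exact totals (VOS, outward)
  tr <- mesh$triangles
  for (j in seq_len(nrow(tr))) {
    verts <- tr[j, ]
    ## quadrature points on the triangle
    yq <- q$bary %*% rbind(co$a[j, ], co$b[j, ], co$c[j, ])   # nq x 3
    nvec <- nrm[j, ] / 2                                      # area * normal
    Ik <- matrix(0, np, 3)
    for (kq in seq_len(nq)) {
      d1 <- points[, 1] - yq[kq, 1]
      d2 <- points[, 2] - yq[kq, 2]
      d3 <- points[, 3] - yq[kq, 3]
      r3 <- (d1 * d1 + d2 * d2 + d3 * d3)^1.5
      kern <- (d1 * nvec[1] + d2 * nvec[2] + d3 * nvec[3]) / r3 * q$w[kq]
      Ik <- Ik + kern %o% q$bary[kq, ]
    }
    ## additive correction so each row's triangle total matches the exact
    ## solid angle: int K_{n_out} dS = -Omega(x)
    excess <- (-omega[, j] - rowSums(Ik)) / 3
    Ik <- Ik + excess
    if (self) Ik[verts, ] <- 0   # observation in triangle plane: kernel zero
    D[, verts] <- D[, verts] + Ik
  }
  D * nu_sign / (4 * pi)
}

## Single-layer block: entries (1/4pi) * int lambda_j(y) / R dS over the
## source mesh. Incident observation/triangle pairs (self = TRUE) use a
## semi-analytic polar rule; near pairs use subdivided quadrature.
assemble_single_layer <- function(points, mesh, self = FALSE) {
  np <- nrow(points); nn <- nrow(mesh$nodes)
  co <- triangle_corners(mesh)
  tr <- mesh$triangles
  S <- matrix(0, np, nn)
  areas <- triangle_areas(mesh)
  qfar <- tri_quadrature()
  qnear <- refined_quadrature(depth = 2)
  for (j in seq_len(nrow(tr))) {
    verts <- tr[j, ]
    P <- rbind(co$a[j, ], co$b[j, ], co$c[j, ])
    max_edge <- max(sqrt(rowSums((P - P[c(2, 3, 1), ])^2)))
    ## distance from each obs point to the triangle centroid
    cen <- colMeans(P)
    dc <- sqrt(rowSums(sweep(points, 2, cen, `-`)^2))
    near <- dc < 2 * max_edge
    if (self) near[verts] <- FALSE
    far <- !near
    if (self) far[verts] <- FALSE
    for (set in list(list(idx = which(far), q = qfar),
                     list(idx = which(near), q = qnear))) {
      if (!length(set$idx)) next
      qq <- set$q
      yq <- qq$bary %*% P
      pts <- points[set$idx, , drop = FALSE]
      acc <- matrix(0, length(set$idx), 3)
      for (kq in seq_along(qq$w)) {
        d1 <- pts[, 1] - yq[kq, 1]
        d2 <- pts[, 2] - yq[kq, 2]
        d3 <- pts[, 3] - yq[kq, 3]
        r <- sqrt(d1 * d1 + d2 * d2 + d3 * d3)
        acc <- acc + (qq$w[kq] / r) %o% qq$bary[kq, ]
      }
      S[set$idx, verts] <- S[set$idx, verts] + acc * areas[j]
    }
    if (self) {
      for (k in 1:3) {
        i_obs <- verts[k]
        others <- verts[-k]
        vals <- single_layer_vertex(P[k, ], P[-k, , drop = FALSE][1, ],
                                    P[-k, , drop = FALSE][2, ])
        S[i_obs, verts[k]] <- S[i_obs, verts[k]] + vals[1]
        S[i_obs, others[1]] <- S[i_obs, others[1]] + vals[2]
        S[i_obs, others[2]] <- S[i_obs, others[2]] + vals[3]
      }
    }
  }
  S / (4 * pi)
}

## int over triangle (P,A,B) of lambda_k / |y - P| dS, observation at vertex
## P; polar integration around P with the radial integral done exactly.
## Returns c(lambda_P, lambda_A, lambda_B) integrals.
single_layer_vertex <- function(P, A, B, n_gauss = 24) {
  u <- A - P; v <- B - P
  nvec <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  nn <- sqrt(sum(nvec^2))
  if (nn < 1e-14) return(c(0, 0, 0))
  e1 <- u / sqrt(sum(u^2))
  nhat <- nvec / nn
  e2 <- c(nhat[2] * e1[3] - nhat[3] * e1[2],
          nhat[3] * e1[1] - nhat[1] * e1[3],
          nhat[1] * e1[2] - nhat[2] * e1[1])
  A2 <- c(sum(u * e1), 0)
  B2 <- c(sum(v * e1), sum(v * e2))
  gam <- atan2(B2[2], B2[1])          # in (0, pi) for consistent winding
  gl <- gauss_legendre(n_gauss, 0, gam)
  dx <- cos(gl$x); dy <- sin(gl$x)
  ex <- B2[1] - A2[1]; ey <- B2[2] - A2[2]
  ## rho solves rho*d = A2 + s*(B2-A2): rho = cross(A2,E)/cross(d,E)
  rho <- (A2[1] * ey - A2[2] * ex) / (dx * ey - dy * ex)
  s <- ifelse(abs(ex) > abs(ey),
              (rho * dx - A2[1]) / ex,
              (rho * dy - A2[2]) / ey)
  iP <- sum(gl$w * rho / 2)
  iA <- sum(gl$w * (1 - s) * rho / 2)
  iB <- sum(gl$w * s * rho / 2)
  c(iP, iA, iB)
}

gauss_legendre <- function(n, a, b) {
  ## Golub-Welsch on the Jacobi matrix
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  ev <- eigen(J, symmetric = TRUE)
  x <- ev$values
  w <- 2 * ev$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

#' Forward model container
#'
#' @param A M x N transfer matrix mapping epicardial node potentials to torso
#'   measurement potentials (dimensionless).
#' @param source_mesh,measurement_mesh the meshes A was built on.
#' @param electrode_rows optional integer subset of measurement-mesh nodes
#'   the rows of A correspond to (NULL = all nodes).
#' @param meta list of provenance metadata.
#' @return object of class `forward_model`.
#' @export
forward_model <- function(A, source_mesh = NULL, measurement_mesh = NULL,
                          electrode_rows = NULL, meta = list()) {
  A <- as.matrix(A)
  if (!all(is.finite(A))) stopf("transfer matrix has non-finite entries")
  structure(list(A = A, source_mesh = source_mesh,
                 measurement_mesh = measurement_mesh,
                 electrode_rows = electrode_rows, meta = meta),
            class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf("forward_model: %d x %d transfer matrix%s\n",
              nrow(x$A), ncol(x$A),
              if (is.null(x$electrode_rows)) "" else
                sprintf(" (%d electrode rows sampled)", length(x$electrode_rows))))
  invisible(x)
}

#' Build the BEM transfer matrix between two closed surfaces
#'
#' Assembles the double-layer (solid-angle) and single-layer coefficient
#' blocks for the homogeneous volume conductor between the epicardial and
#' torso surfaces, applies the auto-solid-angle diagonal (enforcing the Gauss
#' identity, hence exact constant-potential transfer), eliminates the
#' epicardial normal current through the single-layer block, and solves for
#' the torso-potential transfer matrix. The conductivity value cancels in a
#' potential-to-potential transfer and is carried as metadata only.
#'
#' If the assembled system is numerically rank-deficient, a rank-one
#' deflation (1/M times the all-ones matrix) is added to the torso
#' self-block and the solve retried; failure beyond deflation raises an
#' error with a conditioning report.
#'
#' @param epi,torso closed `surface_mesh` objects; `torso` must enclose
#'   `epi`.
#' @param conductivity_ohm_cm recorded as metadata (default 500).
#' @return a `forward_model`.
#' @export
build_transfer_matrix <- function(epi, torso, conductivity_ohm_cm = 500) {
  for (m in list(epi, torso)) {
    if (!mesh_is_closed(m)) stopf("both meshes must be closed")
  }
  xt <- torso$nodes; xh <- epi$nodes
  M <- nrow(xt); N <- nrow(xh)
  ## region-outward normal: + on torso, - on epicardium
  D_TT <- assemble_double_layer(xt, torso, nu_sign = +1, self = TRUE)
  D_TH <- assemble_double_layer(xt, epi, nu_sign = -1, self = FALSE)
  D_HT <- assemble_double_layer(xh, torso, nu_sign = +1, self = FALSE)
  D_HH <- assemble_double_layer(xh, epi, nu_sign = -1, self = TRUE)
  S_TH <- assemble_single_layer(xt, epi, self = FALSE)
  S_HH <- assemble_single_layer(xh, epi, self = TRUE)
  ## auto diagonal from the constant-potential (Gauss) identity
  C_T <- -(rowSums(D_TT) + rowSums(D_TH))
  C_H <- -(rowSums(D_HT) + rowSums(D_HH))
  G <- solve(S_HH, cbind(D_HT, D_HH + diag(C_H, N)))
  L <- D_TT + diag(C_T, M) - S_TH %*% G[, seq_len(M), drop = FALSE]
  Rm <- S_TH %*% G[, M + seq_len(N), drop = FALSE] - D_TH
  rc <- rcond(L)
  deflated <- FALSE
  if (rc < 1e-12) {
    L <- L + matrix(1 / M, M, M)
    deflated <- TRUE
    rc2 <- rcond(L)
    if (rc2 < 1e-12) {
      stopf("BEM system singular beyond deflation (rcond %.2e before, %.2e after)",
            rc, rc2)
    }
  }
  A <- solve(L, Rm)
  forward_model(A, source_mesh = epi, measurement_mesh = torso,
                meta = list(conductivity_ohm_cm = conductivity_ohm_cm,
                            rcond = rc, deflated = deflated))
}

#' Sample electrode rows from a forward model
#'
#' Keeps only the rows of A corresponding to measurement electrodes (mesh
#' nodes), in the given order, and records the mapping.
#'
#' @param forward a `forward_model`.
#' @param electrode_nodes unique, in-range measurement-node indices.
#' @return a reduced `forward_model`.
#' @export
sample_electrode_rows <- function(forward, electrode_nodes) {
  electrode_nodes <- as.integer(electrode_nodes)
  if (anyDuplicated(electrode_nodes)) stopf("duplicate electrode indices")
  if (any(electrode_nodes < 1) || any(electrode_nodes > nrow(forward$A))) {
    stopf("electrode index out of range")
  }
  forward_model(forward$A[electrode_nodes, , drop = FALSE],
                source_mesh = forward$source_mesh,
                measurement_mesh = forward$measurement_mesh,
                electrode_rows = electrode_nodes,
                meta = forward$meta)
}

#' Exclude bad torso leads consistently from recording and forward model
#'
#' Removes the given leads from the recording and the matching rows from the
#' transfer matrix. Leaving fewer torso leads than epicardial nodes is
#' permitted but reported as under-determined.
#'
#' @param recording a torso `potential_recording`.
#' @param forward the matching `forward_model`.
#' @param bad integer indices of leads to drop (may be empty).
#' @return list(recording=, forward=).
#' @export
exclude_bad_leads <- function(recording, forward, bad = integer(0)) {
  bad <- as.integer(bad)
  nl <- nrow(recording$values)
  if (nl != nrow(forward$A)) stopf("recording/forward lead counts differ")
  if (length(bad)) {
    if (any(bad < 1) || any(bad > nl) || anyDuplicated(bad)) {
      stopf("bad lead indices must be unique and within 1..%d", nl)
    }
    keep <- setdiff(seq_len(nl), bad)
    recording <- potential_recording(recording$values[keep, , drop = FALSE],
                                     recording$fs_hz,
                                     lead_ids = recording$lead_ids[keep],
                                     bad_leads = recording$bad_leads[keep],
                                     segmentation = recording$segmentation)
    forward <- forward_model(forward$A[keep, , drop = FALSE],
                             source_mesh = forward$source_mesh,
                             measurement_mesh = forward$measurement_mesh,
                             electrode_rows = (forward$electrode_rows %||% seq_len(nl))[keep],
                             meta = forward$meta)
    if (nrow(forward$A) < ncol(forward$A)) {
      message(sprintf("exclude_bad_leads: %d torso leads < %d epicardial nodes (under-determined)",
                      nrow(forward$A), ncol(forward$A)))
    }
  }
  list(recording = recording, forward = forward)
}
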