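# Assembly of the symmetric block system and the source / sensor transfer
# matrices. Unknowns are ordered V_1, p_1, V_2, p_2, ..., V_N (the scalp
# carries no normal-current block since sigma d_n V vanishes there).

#' Block index map of the symmetric head system
#'
#' @param model a `bem_head_model`.
#' @return object of class `bem_block_map`: per interface, integer index slices
#'   `V[[i]]` (vertex unknowns) and `p[[i]]` (triangle unknowns, absent for the
#'   scalp), plus the total dimension `n`.
#' @export
block_index_map <- function(model) {
  N <- length(model$interfaces)
  V <- vector("list", N); p <- vector("list", N)
  off <- 0L
  for (i in seq_len(N)) {
    nv <- n_vertices(model$interfaces[[i]])
    V[[i]] <- off + seq_len(nv); off <- off + nv
    if (i < N) {
      nt <- n_triangles(model$interfaces[[i]])
      p[[i]] <- off + seq_len(nt); off <- off + nt
    }
  }
  structure(list(V = V, p = p, n = off, N = N), class = "bem_block_map")
}

# orientation of interface a as part of the boundary of domain d:
# +1 when a is the outer boundary (a == d), -1 when inner (a == d - 1)
domain_boundaries <- function(d, N) {
  b <- list()
  if (d <= N) b[[length(b) + 1L]] <- list(iface = d, orient = 1)
  if (d >= 2) b[[length(b) + 1L]] <- list(iface = d - 1L, orient = -1)
  b
}

# All operator blocks needed between interfaces |i-j| <= 1. Returns nested
# lists S[[i]][[j]], D[[i]][[j]] (P0_i rows x P1_j cols), Nk[[i]][[j]].
assemble_operator_blocks <- function(model, quad) {
  N <- length(model$interfaces)
  S <- D <- Nk <- rep(list(vector("list", N)), N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (abs(i - j) > 1) next
      if (j < i) {
        S[[i]][[j]] <- t(S[[j]][[i]])
        Nk[[i]][[j]] <- t(Nk[[j]][[i]])
        D[[i]][[j]] <- cpp_assemble_D(model$interfaces[[i]]$vertices,
                                      model$interfaces[[i]]$triangles,
                                      model$interfaces[[j]]$vertices,
                                      model$interfaces[[j]]$triangles,
                                      FALSE, quad$rule, quad$adaptive, quad$tol,
                                      quad$max_depth, quad$near_gate)
        next
      }
      same <- i == j
      S[[i]][[j]] <- cpp_assemble_S(model$interfaces[[i]]$vertices,
                                    model$interfaces[[i]]$triangles,
                                    model$interfaces[[j]]$vertices,
                                    model$interfaces[[j]]$triangles,
                                    same, quad$rule, quad$adaptive, quad$tol,
                                    quad$max_depth, quad$near_gate)
      D[[i]][[j]] <- cpp_assemble_D(model$interfaces[[i]]$vertices,
                                    model$interfaces[[i]]$triangles,
                                    model$interfaces[[j]]$vertices,
                                    model$interfaces[[j]]$triangles,
                                    same, quad$rule, quad$adaptive, quad$tol,
                                    quad$max_depth, quad$near_gate)
      Nij <- assemble_hypersingular(model$interfaces[[i]],
                                    model$interfaces[[j]],
                                    quad, S0 = S[[i]][[j]])$matrix
      # exact symmetry of self blocks (summation order in the sparse products
      # is not symmetric by itself)
      if (same) Nij <- (Nij + t(Nij)) / 2
      Nk[[i]][[j]] <- Nij
    }
  }
  list(S = S, D = D, N = Nk)
}

# Contract the conductivity-independent operator blocks with a conductivity
# vector into the dense symmetric head matrix (undeflated). This is the only
# assembly path, so reassembly from the stored decomposition is entrywise
# identical to "direct" assembly by construction.
contract_head_matrix <- function(blocks, map, sigma) {
  N <- map$N
  H <- matrix(0, map$n, map$n)
  for (d in seq_len(N)) {
    bs <- domain_boundaries(d, N)
    for (ba in bs) for (bb in bs) {
      a <- ba$iface; b <- bb$iface; sg <- ba$orient * bb$orient
      # V_a - V_b: -sigma_d * sg * N_ab. The stored N blocks are the positive
      # (surface-curl) form W; the analytic hypersingular operator d_n D of
      # the representation-theorem derivation equals -W, hence the sign.
      H[map$V[[a]], map$V[[b]]] <- H[map$V[[a]], map$V[[b]]] -
        sigma[d] * sg * blocks$N[[a]][[b]]
      # p_a - p_b: (1/sigma_d) * sg * S_ab
      if (!is.null(map$p[[a]]) && !is.null(map$p[[b]]))
        H[map$p[[a]], map$p[[b]]] <- H[map$p[[a]], map$p[[b]]] +
          (1 / sigma[d]) * sg * blocks$S[[a]][[b]]
      # p_a - V_b: -sg * D_ab ; V_a - p_b: -sg * t(D_ba)
      if (!is.null(map$p[[a]])) {
        H[map$p[[a]], map$V[[b]]] <- H[map$p[[a]], map$V[[b]]] -
          sg * blocks$D[[a]][[b]]
        H[map$V[[b]], map$p[[a]]] <- H[map$V[[b]], map$p[[a]]] -
          sg * t(blocks$D[[a]][[b]])
      }
    }
  }
  H
}

# rank-one deflation removing the constant null vector (V constant on every
# interface, p = 0): add omega * m m^T on the scalp V block, m the P1
# mass-lumped vertex areas. Leaves zero-scalp-mean solutions unchanged.
deflation_vector <- function(model, map) {
  scalp <- model$interfaces[[map$N]]
  m <- numeric(map$n)
  lump <- as.numeric(mass_matrix(scalp, "P1", "P0")$matrix %*%
                       rep(1, n_triangles(scalp)))
  m[map$V[[map$N]]] <- lump
  m
}

#' Assemble the symmetric head matrix
#'
#' Builds the dense symmetric block matrix of the nested-domain boundary
#' element system: hypersingular (N) blocks between potential unknowns with
#' conductivity-sum coefficients, single-layer (S) blocks between
#' normal-current unknowns with inverse-conductivity coefficients, and
#' conductivity-independent double-layer (D / D*) coupling blocks. A rank-one
#' deflation on the scalp potential block removes the constant null space
#' (the potential is only defined up to an additive constant).
#'
#' The conductivity-independent operator blocks are retained, so the head
#' matrix for any other conductivity vector can be re-contracted immediately
#' (`update_head_matrix`) without re-integrating.
#'
#' @param model a `bem_head_model` that passes `check_nesting`.
#' @param quad a `bem_quadrature`.
#' @param deflate logical; apply the rank-one deflation (default `TRUE`).
#' @return object of class `bem_head_matrix`: `matrix` (dense, symmetric),
#'   `map`, `sigma`, `blocks` (the decomposition), `deflation` (omega, m).
#' @export
assemble_head_matrix <- function(model, quad = quadrature_options(),
                                 deflate = TRUE) {
  if (any(model$conductivities <= 0)) stop("sigma must be > 0")
  map <- block_index_map(model)
  blocks <- assemble_operator_blocks(model, quad)
  H <- contract_head_matrix(blocks, map, model$conductivities)
  defl <- NULL
  if (deflate) {
    m <- deflation_vector(model, map)
    omega <- mean(abs(diag(H))) / sum(m * m)
    H <- H + omega * (m %*% t(m)) # m m^T first: exactly symmetric
    defl <- list(omega = omega, m = m)
  }
  structure(list(matrix = H, map = map, sigma = model$conductivities,
                 blocks = blocks, deflation = defl, model = model, quad = quad),
            class = "bem_head_matrix")
}

#' Re-contract a head matrix for new conductivities
#'
#' Uses the stored conductivity-independent decomposition (constant
#' double-layer part plus per-domain matrices with coefficients sigma_d and
#' 1/sigma_d), so no boundary integrals are recomputed.
#'
#' @param hm a `bem_head_matrix`.
#' @param sigma new positive conductivity vector.
#' @return a `bem_head_matrix` for the new conductivities.
#' @export
update_head_matrix <- function(hm, sigma) {
  stopifnot(length(sigma) == hm$map$N, all(sigma > 0))
  H <- contract_head_matrix(hm$blocks, hm$map, sigma)
  defl <- NULL
  if (!is.null(hm$deflation)) {
    m <- hm$deflation$m
    omega <- mean(abs(diag(H))) / sum(m * m)
    H <- H + omega * (m %*% t(m))
    defl <- list(omega = omega, m = m)
  }
  model <- hm$model
  model$conductivities <- sigma
  structure(list(matrix = H, map = hm$map, sigma = sigma, blocks = hm$blocks,
                 deflation = defl, model = model, quad = hm$quad),
            class = "bem_head_matrix")
}

#' @export
print.bem_head_matrix <- function(x, ...) {
  cat(sprintf("<bem_head_matrix> %d x %d, %d interface(s), deflated=%s\n",
              x$map$n, x$map$n, x$map$N, !is.null(x$deflation)))
  invisible(x)
}

#' Dipole source matrix (right-hand sides)
#'
#' One column per dipole. For a dipole in domain j with infinite-medium
#' potential v (at unit conductivity), the column carries, on each interface a
#' bounding domain j with orientation or_a (+1 outer boundary, -1 inner):
#' `or_a * <phi, d_n v>` on the potential rows and
#' `-or_a / sigma_j * <psi, v>` on the normal-current rows; all other rows are
#' zero. Columns are exactly linear in the dipole moment.
#'
#' @param model a `bem_head_model`.
#' @param dipoles a `bem_dipoles`.
#' @param quad a `bem_quadrature` (adaptive integration matters most here for
#'   sources close to an interface).
#' @return dense matrix (system dim x n_dipoles) of class `bem_source_matrix`.
#' @export
assemble_dipole_source_matrix <- function(model, dipoles,
                                          quad = quadrature_options()) {
  map <- block_index_map(model)
  nd <- nrow(dipoles$positions)
  B <- matrix(0, map$n, nd)
  N <- map$N
  for (j in sort(unique(dipoles$domain))) {
    idx <- which(dipoles$domain == j)
    for (bnd in domain_boundaries(j, N)) {
      a <- bnd$iface
      mesh <- model$interfaces[[a]]
      rhs <- cpp_dipole_rhs(mesh$vertices, mesh$triangles,
                            dipoles$positions[idx, , drop = FALSE],
                            dipoles$moments[idx, , drop = FALSE],
                            quad$rule, quad$adaptive, quad$tol, quad$max_depth,
                            quad$near_gate)
      B[map$V[[a]], idx] <- B[map$V[[a]], idx] + bnd$orient * rhs$P1
      if (!is.null(map$p[[a]]))
        B[map$p[[a]], idx] <- B[map$p[[a]], idx] -
          bnd$orient / model$conductivities[j] * rhs$P0
    }
  }
  class(B) <- c("bem_source_matrix", class(B))
  B
}

# source-mesh quadrature: represent the surfacic distribution
# J^p = sum_i phi_i J_i n as weighted point dipoles at triangle Gauss points;
# returns positions, unit-intensity moments and the vertex weights
surface_source_quadrature <- function(src_mesh, rule = 7L) {
  b7 <- rbind(rep(1/3, 3),
              matrix(c(0.059715871789770, 0.470142064105115, 0.470142064105115,
                       0.470142064105115, 0.059715871789770, 0.470142064105115,
                       0.470142064105115, 0.470142064105115, 0.059715871789770),
                     3, 3, byrow = TRUE),
              matrix(c(0.797426985353087, 0.101286507323456, 0.101286507323456,
                       0.101286507323456, 0.797426985353087, 0.101286507323456,
                       0.101286507323456, 0.101286507323456, 0.797426985353087),
                     3, 3, byrow = TRUE))
  w7 <- c(0.225, rep(0.132394152788506, 3), rep(0.125939180544827, 3))
  if (rule <= 1) { b7 <- matrix(1/3, 1, 3); w7 <- 1 }
  f <- src_mesh$triangles
  out <- list()
  for (t in seq_len(nrow(f))) {
    tri <- src_mesh$vertices[f[t, ], , drop = FALSE]
    pts <- b7 %*% tri
    for (g in seq_len(nrow(pts)))
      out[[length(out) + 1L]] <- list(
        pos = pts[g, ], n = src_mesh$normals[t, ],
        w = w7[g] * src_mesh$areas[t], verts = f[t, ], phi = b7[g, ])
  }
  out
}

#' Surfacic source matrix
#'
#' One column per vertex of the source mesh, implementing the linear-in-phi
#' dipole-layer distribution: the column for vertex i is the dipole right-hand
#' side of the density phi_i(r) n(r) integrated over the source mesh
#' (triangle Gauss quadrature, each quadrature point contributing a weighted
#' point dipole).
#'
#' @param model a `bem_head_model`.
#' @param source a `bem_surface_source` lying strictly inside one domain.
#' @param quad a `bem_quadrature`.
#' @return dense matrix (system dim x n_source_vertices).
#' @export
assemble_surface_source_matrix <- function(model, source,
                                           quad = quadrature_options()) {
  dom <- unique(locate_domain(source$mesh$vertices, model))
  if (length(dom) != 1 || anyNA(dom))
    stop("surfacic source mesh must lie strictly inside a single domain")
  qp <- surface_source_quadrature(source$mesh)
  pos <- do.call(rbind, lapply(qp, `[[`, "pos"))
  mom <- do.call(rbind, lapply(qp, function(x) x$w * x$n))
  dips <- structure(list(positions = pos, moments = mom,
                         domain = rep(dom, nrow(pos))),
                    class = "bem_dipoles")
  Bq <- assemble_dipole_source_matrix(model, dips, quad)
  nv <- n_vertices(source$mesh)
  W <- matrix(0, length(qp), nv)
  for (g in seq_along(qp)) W[g, qp[[g]]$verts] <- qp[[g]]$phi
  B <- Bq %*% W
  class(B) <- c("bem_source_matrix", class(B))
  B
}

#' EEG transfer matrix (boundary unknowns to electrodes)
#'
#' Row e holds the barycentric interpolation weights of projected electrode e
#' in its scalp triangle, over the scalp potential block; rows are convex
#' combinations (at most 3 nonzeros summing to 1).
#'
#' @param model a `bem_head_model`.
#' @param electrodes a `bem_sensors` of kind "EEG" projected on the scalp.
#' @return dense matrix (n_electrodes x system dim).
#' @export
head2eeg <- function(model, electrodes) {
  stopifnot(inherits(electrodes, "bem_sensors"), electrodes$kind == "EEG")
  map <- block_index_map(model)
  scalp <- model$interfaces[[map$N]]
  ne <- nrow(electrodes$projected)
  M <- matrix(0, ne, map$n)
  for (e in seq_len(ne)) {
    tri <- scalp$triangles[electrodes$triangle[e], ]
    M[e, map$V[[map$N]][tri]] <- electrodes$bary[e, ]
  }
  M
}

mu0 <- 4e-7 * pi

#' MEG transfer matrix: Ohmic (volume-current) contribution
#'
#' Maps the interface potentials to the magnetic reading: the volume-current
#' part of the Biot-Savart integral reduces, for piecewise-constant
#' conductivity, to surface integrals
#' B_ohmic(r) = -mu0/(4 pi) sum_i (sigma_i - sigma_{i+1})
#'              int_{S_i} V(r') n'(r') x (r - r') / ||r - r'||^3 ds'
#' (with sigma_{N+1} = 0; the sign follows from the curl theorem applied to
#' sigma grad V x grad'(1/R) per domain), contracted with each channel's
#' weighted directions. Normal-current blocks receive zero.
#'
#' @param model a `bem_head_model`.
#' @param sensors a `bem_sensors` of kind "MEG".
#' @param quad a `bem_quadrature`.
#' @return dense matrix (n_channels x system dim), tesla per volt weights.
#' @export
head2meg <- function(model, sensors, quad = quadrature_options()) {
  stopifnot(inherits(sensors, "bem_sensors"), sensors$kind == "MEG")
  map <- block_index_map(model)
  sig <- c(model$conductivities, 0)
  chan <- factor(sensors$channels, levels = sensors$channel_names)
  W <- Matrix::sparseMatrix(i = as.integer(chan), j = seq_along(sensors$weights),
                            x = sensors$weights,
                            dims = c(length(sensors$channel_names),
                                     length(sensors$weights)))
  M <- matrix(0, length(sensors$channel_names), map$n)
  for (i in seq_len(map$N)) {
    coef <- -mu0 * (sig[i] - sig[i + 1])
    if (coef == 0) next
    P <- cpp_head2meg(sensors$points, sensors$directions,
                      model$interfaces[[i]]$vertices,
                      model$interfaces[[i]]$triangles,
                      quad$rule, quad$adaptive, quad$tol, quad$max_depth,
                      quad$near_gate)
    M[, map$V[[i]]] <- M[, map$V[[i]]] + coef * as.matrix(W %*% P)
  }
  M
}

#' MEG primary-field source matrices
#'
#' `dipsource2meg`: the primary (source-space) magnetic field of each dipole,
#' B_p(r) = mu0/(4 pi) q x (r - r0) / ||r - r0||^3, contracted with channel
#' weights; one column per dipole. `surfsource2meg` integrates the surfacic
#' distribution with the same quadrature as the surfacic source matrix.
#'
#' @param dipoles a `bem_dipoles`.
#' @param sensors a `bem_sensors` of kind "MEG".
#' @return dense matrix (n_channels x n_sources), tesla.
#' @export
dipsource2meg <- function(dipoles, sensors) {
  stopifnot(sensors$kind == "MEG")
  np <- nrow(sensors$points); nd <- nrow(dipoles$positions)
  P <- matrix(0, np, nd)
  for (d in seq_len(nd)) {
    R <- sensors$points - matrix(dipoles$positions[d, ], np, 3, byrow = TRUE)
    r3 <- (rowSums(R^2))^1.5
    if (any(r3 == 0)) stop("MEG integration point coincides with dipole ", d)
    q <- dipoles$moments[d, ]
    qxR <- cbind(q[2] * R[, 3] - q[3] * R[, 2],
                 q[3] * R[, 1] - q[1] * R[, 3],
                 q[1] * R[, 2] - q[2] * R[, 1])
    P[, d] <- mu0 / (4 * pi) * rowSums(qxR * sensors$directions) / r3
  }
  chan <- factor(sensors$channels, levels = sensors$channel_names)
  W <- Matrix::sparseMatrix(i = as.integer(chan), j = seq_len(np),
                            x = sensors$weights,
                            dims = c(length(sensors$channel_names), np))
  as.matrix(W %*% P)
}

#' @rdname dipsource2meg
#' @param source a `bem_surface_source`.
#' @param model a `bem_head_model` (to resolve the source domain).
#' @export
surfsource2meg <- function(source, sensors, model) {
  qp <- surface_source_quadrature(source$mesh)
  pos <- do.call(rbind, lapply(qp, `[[`, "pos"))
  mom <- do.call(rbind, lapply(qp, function(x) x$w * x$n))
  dips <- structure(list(positions = pos, moments = mom,
                         domain = rep(1L, nrow(pos))),
                    class = "bem_dipoles")
  P <- dipsource2meg(dips, sensors)
  nv <- n_vertices(source$mesh)
  W <- matrix(0, length(qp), nv)
  for (g in seq_along(qp)) W[g, qp[[g]]$verts] <- qp[[g]]$phi
  P %*% W
}

#' EIT source matrix
#'
#' Right-hand sides for scalp current injection: the injected current of each
#' electrode is a uniform current density j = I / area on its nearest scalp
#' triangle. With the known scalp normal current j (P0 coefficients), the
#' column carries `(D*_NN - M/2) j` on the scalp potential rows,
#' `-D*_{N-1,N} j` on the next potential rows and `S_{N-1,N} j / sigma_N` on
#' the neighboring normal-current rows. One column per stimulation pattern;
#' patterns must carry zero net current.
#'
#' @param model a `bem_head_model`.
#' @param injection a `bem_eit_injection`.
#' @param quad a `bem_quadrature`.
#' @param blocks optional precomputed operator blocks (from a
#'   `bem_head_matrix`) to reuse.
#' @return dense matrix (system dim x n_patterns).
#' @export
assemble_eit_source_matrix <- function(model, injection,
                                       quad = quadrature_options(),
                                       blocks = NULL) {
  map <- block_index_map(model)
  N <- map$N
  scalp <- model$interfaces[[N]]
  npat <- ncol(injection$currents)
  # P0 current-density coefficients on the scalp
  jmat <- matrix(0, n_triangles(scalp), npat)
  for (k in seq_len(nrow(injection$positions)))
    jmat[injection$triangle[k], ] <- jmat[injection$triangle[k], ] +
      injection$currents[k, ] / scalp$areas[injection$triangle[k]]
  if (is.null(blocks)) {
    DNN <- cpp_assemble_D(scalp$vertices, scalp$triangles,
                          scalp$vertices, scalp$triangles, TRUE,
                          quad$rule, quad$adaptive, quad$tol, quad$max_depth,
                          quad$near_gate)
    if (N >= 2) {
      inner <- model$interfaces[[N - 1]]
      DN_N1 <- cpp_assemble_D(scalp$vertices, scalp$triangles,
                              inner$vertices, inner$triangles, FALSE,
                              quad$rule, quad$adaptive, quad$tol,
                              quad$max_depth, quad$near_gate)
      SN1_N <- cpp_assemble_S(inner$vertices, inner$triangles,
                              scalp$vertices, scalp$triangles, FALSE,
                              quad$rule, quad$adaptive, quad$tol,
                              quad$max_depth, quad$near_gate)
    }
  } else {
    DNN <- blocks$D[[N]][[N]]
    if (N >= 2) {
      DN_N1 <- blocks$D[[N]][[N - 1]]
      SN1_N <- blocks$S[[N - 1]][[N]]
    }
  }
  Mhalf <- as.matrix(mass_matrix(scalp, "P1", "P0")$matrix) / 2
  B <- matrix(0, map$n, npat)
  B[map$V[[N]], ] <- (t(DNN) - Mhalf) %*% jmat
  if (N >= 2) {
    B[map$V[[N - 1]], ] <- -t(DN_N1) %*% jmat
    B[map$p[[N - 1]], ] <- (SN1_N %*% jmat) / model$conductivities[N]
  }
  class(B) <- c("bem_source_matrix", class(B))
  B
}

#' Internal-potential transfer matrix
#'
#' For a point x in domain i, the Green representation of the potential from
#' the surrounding boundary data reads
#' V(x) = -D_i V_i + S_i p_i / sigma_i + D_{i-1} V_{i-1} - S_{i-1} p_{i-1} / sigma_i
#' (single/double layer potentials evaluated at x; terms absent when the
#' interface does not exist, and p_N = 0). Rows are exact per flat triangle
#' (analytic integrals), so points arbitrarily close to an interface remain
#' stable.
#'
#' @param model a `bem_head_model`.
#' @param points a `bem_sensors` of kind "IP".
#' @return dense matrix (n_points x system dim).
#' @export
head2ip <- function(model, points) {
  stopifnot(inherits(points, "bem_sensors"), points$kind == "IP")
  map <- block_index_map(model)
  M <- matrix(0, nrow(points$points), map$n)
  for (i in sort(unique(points$domain))) {
    idx <- which(points$domain == i)
    pts <- points$points[idx, , drop = FALSE]
    sig <- model$conductivities[i]
    pot_i <- cpp_point_potentials(pts, model$interfaces[[i]]$vertices,
                                  model$interfaces[[i]]$triangles)
    M[idx, map$V[[i]]] <- M[idx, map$V[[i]]] - pot_i$D
    if (!is.null(map$p[[i]]))
      M[idx, map$p[[i]]] <- M[idx, map$p[[i]]] + pot_i$S / sig
    if (i >= 2) {
      pot_in <- cpp_point_potentials(pts, model$interfaces[[i - 1]]$vertices,
                                     model$interfaces[[i - 1]]$triangles)
      M[idx, map$V[[i - 1]]] <- M[idx, map$V[[i - 1]]] + pot_in$D
      M[idx, map$p[[i - 1]]] <- M[idx, map$p[[i - 1]]] - pot_in$S / sig
    }
  }
  M
}

#' Internal-potential source matrix
#'
#' Entry (point, dipole) is the infinite-medium dipole potential
#' v(x) / sigma_j when the point and the dipole share domain j, zero otherwise
#' (the boundary part is carried by `head2ip`).
#'
#' @param dipoles a `bem_dipoles`.
#' @param points a `bem_sensors` of kind "IP".
#' @param model a `bem_head_model`.
#' @return dense matrix (n_points x n_dipoles), volts.
#' @export
dipsource2ip <- function(dipoles, points, model) {
  stopifnot(points$kind == "IP")
  np <- nrow(points$points); nd <- nrow(dipoles$positions)
  M <- matrix(0, np, nd)
  for (d in seq_len(nd)) {
    same <- points$domain == dipoles$domain[d]
    if (!any(same)) next
    M[same, d] <- infinite_medium_potential(
      dipoles$positions[d, ], dipoles$moments[d, ],
      points$points[same, , drop = FALSE],
      sigma = model$conductivities[dipoles$domain[d]])$potential
  }
  M
}

#' Infinite-medium dipole potential and gradient
#'
#' v(r) = q . (r - r0) / (4 pi sigma ||r - r0||^3).
#'
#' @param r0 dipole position (length 3, meters).
#' @param q dipole moment (length 3, A m).
#' @param points n x 3 evaluation points.
#' @param sigma conductivity (S/m), default 1.
#' @return list `potential` (volts) and `gradient` (n x 3, V/m).
#' @export
infinite_medium_potential <- function(r0, q, points, sigma = 1) {
  points <- matrix(as.numeric(points), ncol = 3)
  R <- points - matrix(r0, nrow(points), 3, byrow = TRUE)
  r2 <- rowSums(R^2)
  if (any(r2 == 0)) stop("evaluation point coincides with the dipole")
  qR <- as.numeric(R %*% q)
  v <- qR / (4 * pi * sigma * r2^1.5)
  grad <- (matrix(q, nrow(points), 3, byrow = TRUE) - 3 * qR / r2 * R) /
    (4 * pi * sigma * r2^1.5)
  list(potential = v, gradient = grad)
}
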