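#' Quadrature configuration for Galerkin assembly
#'
#' Outer (test-side) integrals use a Gauss rule on each triangle; inner
#' (trial-side) integrals are analytic for the single and linear double layer.
#' When `adaptive` is on, the outer triangle is recursively subdivided until
#' the relative change between refinement levels drops below `tol` or
#' `max_depth` is reached; adaptivity only engages for triangle pairs closer
#' than `near_gate * (diam_a + diam_b)` (far pairs are smooth, and one base
#' pass is already accurate). With `adaptive = FALSE` a single base-rule pass
#' is used everywhere (the non-adaptive benchmark mode).
#'
#' @param rule number of Gauss points per triangle (1, 3, 6 or 7; default 7,
#'   degree 5).
#' @param adaptive logical, default `TRUE`.
#' @param tol relative tolerance for adaptive refinement (default 1e-4).
#' @param max_depth maximum subdivision depth (default 10).
#' @param near_gate operator adaptivity distance gate in units of summed
#'   triangle diameters (default 0.5: only touching or nearly touching pairs
#'   refine, where the outer integrand of the analytic inner integral is
#'   non-smooth). Source-side (dipole) integrals always use a wide gate of 4
#'   summed diameters: they are cheap and dominate the accuracy for sources
#'   close to an interface.
#' @return object of class `bem_quadrature`.
#' @export
quadrature_options <- function(rule = 7L, adaptive = TRUE, tol = 1e-4,
                               max_depth = 10L, near_gate = 0.5) {
  stopifnot(tol > 0, max_depth >= 0)
  structure(list(rule = as.integer(rule), adaptive = isTRUE(adaptive),
                 tol = tol, max_depth = as.integer(max_depth),
                 near_gate = near_gate),
            class = "bem_quadrature")
}

operator_block <- function(matrix, row_basis, col_basis, tag) {
  structure(list(matrix = matrix, row_basis = row_basis, col_basis = col_basis,
                 tag = tag),
            class = "bem_operator_block")
}

#' @export
print.bem_operator_block <- function(x, ...) {
  cat(sprintf("<operator block %s> %d x %d (%s rows, %s cols)\n", x$tag,
              nrow(x$matrix), ncol(x$matrix), x$row_basis, x$col_basis))
  invisible(x)
}

#' Galerkin single-layer operator block
#'
#' Entry (k, l) is the double integral of the Laplace kernel
#' G(r, r') = 1 / (4 pi ||r - r'||) over triangles T_k of `surface_a` and T_l
#' of `surface_b` (P0 test and trial bases). Self-surface blocks are symmetric
#' positive definite; singular and near-singular inner integrals are analytic.
#'
#' @param surface_a,surface_b `bem_mesh` objects (identical object => self block).
#' @param quad a `bem_quadrature`.
#' @return a `bem_operator_block` (tag "S") with a dense P0_a x P0_b matrix.
#' @export
assemble_single_layer <- function(surface_a, surface_b = surface_a,
                                  quad = quadrature_options()) {
  same <- identical(surface_a, surface_b)
  M <- cpp_assemble_S(surface_a$vertices, surface_a$triangles,
                      surface_b$vertices, surface_b$triangles,
                      same, quad$rule, quad$adaptive, quad$tol, quad$max_depth,
                      quad$near_gate)
  operator_block(M, "P0", "P0", "S")
}

#' Galerkin double-layer operator block (and adjoint)
#'
#' Entry (k, j) is the integral over T_k of `surface_a` (P0 test) of the
#' double-layer potential of the P1 basis function phi_j of `surface_b`,
#' with kernel derivative taken at the source point and the principal-value
#' convention on self-surface (co-planar) pairs. The adjoint block D* is the
#' transpose by construction.
#'
#' @inheritParams assemble_single_layer
#' @return list with `D` (`bem_operator_block`, P0_a x P1_b, tag "D") and
#'   `Dstar` (its transpose, tag "D*").
#' @export
assemble_double_layer <- function(surface_a, surface_b = surface_a,
                                  quad = quadrature_options()) {
  same <- identical(surface_a, surface_b)
  M <- cpp_assemble_D(surface_a$vertices, surface_a$triangles,
                      surface_b$vertices, surface_b$triangles,
                      same, quad$rule, quad$adaptive, quad$tol, quad$max_depth,
                      quad$near_gate)
  list(D = operator_block(M, "P0", "P1", "D"),
       Dstar = operator_block(t(M), "P1", "P0", "D*"))
}

# per-triangle surface-curl coefficients n x grad(phi_i) = (p_j - p_k)/(2A),
# returned as three sparse nT x nV matrices (x, y, z components)
curl_matrices <- function(mesh) {
  f <- mesh$triangles; v <- mesh$vertices
  nT <- nrow(f); nV <- nrow(v)
  ii <- rep(seq_len(nT), 3L)
  jj <- c(f[, 1], f[, 2], f[, 3])
  # vertex a = f[,1] has (j,k) = (f[,2], f[,3]) etc (cyclic)
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 3], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e3 <- v[f[, 1], , drop = FALSE] - v[f[, 2], , drop = FALSE]
  inv2A <- 1 / (2 * mesh$areas)
  lapply(1:3, function(k) {
    Matrix::sparseMatrix(i = ii, j = jj,
                         x = c(e1[, k] * inv2A, e2[, k] * inv2A, e3[, k] * inv2A),
                         dims = c(nT, nV))
  })
}

#' Galerkin hypersingular operator block
#'
#' Assembled in the integration-by-parts (surface-curl) weak form
#' N(phi_i, phi_j) = int int G(r, r') (n x grad phi_i)(r) . (n' x grad phi_j)(r') ,
#' which reuses the single-layer triangle-pair integrals on per-triangle
#' constant vector densities. Self blocks are symmetric positive semidefinite
#' and annihilate constants (row sums vanish).
#'
#' @inheritParams assemble_single_layer
#' @param S0 optional precomputed single-layer block between the two surfaces
#'   (a `bem_operator_block` or plain matrix), reused if supplied.
#' @return a `bem_operator_block` (tag "N") with a dense P1_a x P1_b matrix.
#' @export
assemble_hypersingular <- function(surface_a, surface_b = surface_a,
                                   quad = quadrature_options(), S0 = NULL) {
  if (is.null(S0)) S0 <- assemble_single_layer(surface_a, surface_b, quad)
  M0 <- if (inherits(S0, "bem_operator_block")) S0$matrix else S0
  Ca <- curl_matrices(surface_a)
  Cb <- if (identical(surface_a, surface_b)) Ca else curl_matrices(surface_b)
  N <- matrix(0, n_vertices(surface_a), n_vertices(surface_b))
  for (k in 1:3) N <- N + as.matrix(Matrix::t(Ca[[k]]) %*% M0 %*% Cb[[k]])
  operator_block(N, "P1", "P1", "N")
}

#' Galerkin mass matrices between P0/P1 bases on one mesh
#'
#' Exact closed-form triangle integrals: P0 x P0 is the diagonal of triangle
#' areas; P1 x P1 is the standard consistent mass (area/12 * [2 1 1; ...]);
#' P1 x P0 has entry area/3 for each vertex of each triangle.
#'
#' @param mesh a `bem_mesh`.
#' @param row_basis,col_basis "P0" or "P1".
#' @return a `bem_operator_block` (tag "mass") holding a sparse matrix.
#' @export
mass_matrix <- function(mesh, row_basis = "P1", col_basis = row_basis) {
  f <- mesh$triangles; a <- mesh$areas
  nT <- nrow(f); nV <- n_vertices(mesh)
  M <- if (row_basis == "P0" && col_basis == "P0") {
    Matrix::Diagonal(x = a)
  } else if (row_basis == "P1" && col_basis == "P1") {
    ii <- jj <- xx <- NULL
    for (p in 1:3) for (q in 1:3) {
      ii <- c(ii, f[, p]); jj <- c(jj, f[, q])
      xx <- c(xx, a / 12 * if (p == q) 2 else 1)
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nV, nV))
  } else {
    ii <- c(f[, 1], f[, 2], f[, 3])
    jj <- rep(seq_len(nT), 3L)
    M1 <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(a / 3, 3L),
                               dims = c(nV, nT))
    if (row_basis == "P0") Matrix::t(M1) else M1
  }
  operator_block(M, row_basis, col_basis, "mass")
}

#' Analytic potentials of flat triangles at arbitrary points
#'
#' Closed-form single-layer potential `int_T G ds'`, linear double-layer
#' potentials `int_T phi_j d_{n'}G ds'` for the three vertices of each
#' triangle, and the signed solid angle, evaluated at each query point.
#' Co-planar double-layer values follow the principal-value convention
#' (zero). These are the inner integrals used by the Galerkin assembly and the
#' Green-representation rows of the internal-potential transfer matrix.
#'
#' @param points n x 3 matrix of evaluation points.
#' @param mesh a `bem_mesh` (all of its triangles are evaluated).
#' @return list with `single` (n x nT), `double_linear` (n x nT x 3 array,
#'   local vertex order), `solid_angle` (n x nT).
#' @export
analytic_triangle_integrals <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_triangle_analytic(points, mesh$vertices, mesh$triangles)
}

#' Adaptive integration of a functional over a triangle
#'
#' Recursive 1-to-4 subdivision of the triangle: the integral estimate at each
#' level is compared with the subdivided estimate, and subdivision continues
#' where the relative change exceeds `quad$tol`, down to `quad$max_depth`.
#' With `quad$adaptive = FALSE`, a single base-rule pass is returned. This R
#' implementation mirrors the C++ path used in assembly and exists for
#' diagnostics and testing of user-supplied integrands.
#'
#' @param f vectorized integrand: `f(x)` takes an n x 3 matrix of points and
#'   returns n values.
#' @param triangle 3 x 3 matrix of triangle vertices (rows).
#' @param quad a `bem_quadrature`.
#' @return list `value`, `converged`.
#' @export
adaptive_integrate <- function(f, triangle, quad = quadrature_options()) {
  triangle <- matrix(as.numeric(triangle), 3, 3)
  rules <- list(
    `1` = list(w = 1, b = matrix(1/3, 1, 3)),
    `3` = list(w = rep(1/3, 3),
               b = matrix(c(2/3, 1/6, 1/6, 1/6, 2/3, 1/6, 1/6, 1/6, 2/3),
                          3, 3, byrow = TRUE)),
    `7` = list(w = c(0.225, rep(0.132394152788506, 3), rep(0.125939180544827, 3)),
               b = rbind(rep(1/3, 3),
                         matrix(c(0.059715871789770, 0.470142064105115, 0.470142064105115,
                                  0.470142064105115, 0.059715871789770, 0.470142064105115,
                                  0.470142064105115, 0.470142064105115, 0.059715871789770),
                                3, 3, byrow = TRUE),
                         matrix(c(0.797426985353087, 0.101286507323456, 0.101286507323456,
                                  0.101286507323456, 0.797426985353087, 0.101286507323456,
                                  0.101286507323456, 0.101286507323456, 0.797426985353087),
                                3, 3, byrow = TRUE))))
  rl <- rules[[as.character(if (quad$rule %in% c(1, 3)) quad$rule else 7)]]
  rule_val <- function(tri) {
    x <- rl$b %*% tri
    area <- 0.5 * sqrt(sum(vcross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])^2))
    area * sum(rl$w * f(x))
  }
  converged <- TRUE
  rec <- function(tri, v0, depth) {
    if (depth <= 0) return(v0)
    m12 <- (tri[1, ] + tri[2, ]) / 2
    m23 <- (tri[2, ] + tri[3, ]) / 2
    m31 <- (tri[3, ] + tri[1, ]) / 2
    kids <- list(rbind(tri[1, ], m12, m31), rbind(m12, tri[2, ], m23),
                 rbind(m31, m23, tri[3, ]), rbind(m12, m23, m31))
    vk <- vapply(kids, rule_val, numeric(1))
    s <- sum(vk)
    if (abs(s - v0) <= quad$tol * abs(s) + 1e-300) return(s)
    if (depth == 1) { converged <<- FALSE; return(s) }
    sum(vapply(seq_len(4), function(i) rec(kids[[i]], vk[i], depth - 1),
               numeric(1)))
  }
  v0 <- rule_val(triangle)
  val <- if (quad$adaptive) rec(triangle, v0, quad$max_depth) else v0
  list(value = val, converged = converged)
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}
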