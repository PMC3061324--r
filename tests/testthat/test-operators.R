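# Galerkin operator blocks: analytic integrals, solid-angle identities,
# symmetry/definiteness, adaptivity and mass matrices.

test_that("analytic triangle integrals match a dense quadrature oracle", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  # far point: 10-digit agreement with high-order numerical quadrature
  x_far <- c(0.2, 0.1, 3)
  ana <- analytic_triangle_integrals(rbind(x_far), tri)
  oS <- brute_triangle(function(p)
    1 / (4 * pi * sqrt(rowSums(sweep(p, 2, x_far)^2))), tri$vertices, n = 600)
  expect_lt(abs(ana$single[1, 1] - oS) / oS, 1e-6)
  # nearby point: moderate-accuracy brute-force check of all outputs
  x <- c(0.3, 0.2, 0.7)
  ana <- analytic_triangle_integrals(rbind(x), tri)
  oS <- brute_triangle(function(p)
    1 / (4 * pi * sqrt(rowSums(sweep(p, 2, x)^2))), tri$vertices, n = 500)
  expect_lt(abs(ana$single[1, 1] - oS) / oS, 1e-3)
  for (j in 1:3) {
    phi <- function(p) switch(j, 1 - p[, 1] - p[, 2], p[, 1], p[, 2])
    oD <- brute_triangle(function(p) {
      R <- sweep(p, 2, x)
      phi(p) * x[3] / (4 * pi * rowSums(R^2)^1.5)
    }, tri$vertices, n = 500)
    expect_lt(abs(ana$double_linear[1, 1, j] - oD) / abs(oD), 5e-3)
  }
  # point in the triangle's plane but outside it: double layer vanishes by
  # symmetry (principal value)
  ana0 <- analytic_triangle_integrals(rbind(c(2, 2, 0)), tri)
  expect_equal(as.numeric(ana0$double_linear[1, 1, ]), rep(0, 3))
  # point at a vertex: single layer is finite and matches a
  # singularity-subtracted oracle (polar integration is exact per wedge; use
  # a fine geometric refinement toward the vertex instead)
  xv <- c(0, 0, 0)
  anav <- analytic_triangle_integrals(rbind(xv), tri)
  # singularity-subtracted oracle: geometric refinement toward the vertex;
  # each annulus (scaled triangle minus a smaller one) is smooth, the
  # remaining core scales like 2^-k and vanishes
  f <- function(p) 1 / (4 * pi * sqrt(rowSums(p^2)))
  gs <- 0
  nref <- 24
  for (k in seq_len(nref)) {
    outer_s <- 2^(-(k - 1)); inner_s <- 2^(-k)
    # annulus = triangle scaled by outer_s minus scaled by inner_s
    To <- tri$vertices * outer_s
    Ti <- tri$vertices * inner_s
    go <- brute_triangle(f, To, n = 150)
    gi <- brute_triangle(f, Ti, n = 150)
    gs <- gs + (go - gi)
  }
  gs <- gs + brute_triangle(f, tri$vertices * 2^(-nref), n = 150) # tiny core
  expect_lt(abs(anav$single[1, 1] - gs) / gs, 1e-3)
})

test_that("solid-angle identities hold for the double layer", {
  m <- make_icosphere(1, 1)
  pot_in <- symbem:::cpp_point_potentials(rbind(c(0.1, -0.2, 0.05)),
                                          m$vertices, m$triangles)
  expect_equal(sum(pot_in$D), -1, tolerance = 1e-10)
  pot_out <- symbem:::cpp_point_potentials(rbind(c(1.7, 0.3, 0)),
                                           m$vertices, m$triangles)
  expect_equal(sum(pot_out$D), 0, tolerance = 1e-10)
  # Galerkin self-surface row sums: -area/2
  D <- assemble_double_layer(m, m)$D$matrix
  expect_lt(max(abs(rowSums(D) + m$areas / 2)), 2e-3 * max(m$areas))
})

test_that("single-layer self blocks are SPD and far pairs have the point limit", {
  m <- make_icosphere(0.2, 1)
  S <- assemble_single_layer(m, m)$matrix
  expect_identical(S, t(S))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # far pair of triangles: area_k area_l G(centroids)
  t1 <- triangle_mesh(rbind(c(0, 0, 0), c(0.01, 0, 0), c(0, 0.01, 0)),
                      rbind(1:3))
  t2 <- triangle_mesh(rbind(c(1, 0, 0), c(1.01, 0, 0), c(1, 0.01, 0.0)) +
                        matrix(c(0, 0, 1), 3, 3, byrow = TRUE), rbind(1:3))
  S12 <- assemble_single_layer(t1, t2)$matrix
  point <- t1$areas * t2$areas /
    (4 * pi * sqrt(sum((t1$centroids - t2$centroids)^2)))
  expect_lt(abs(S12[1, 1] - point) / point, 1e-3)
})

test_that("hypersingular blocks annihilate constants and are PSD", {
  m <- make_icosphere(0.15, 1)
  N <- assemble_hypersingular(m, m)$matrix
  expect_lt(max(abs(N %*% rep(1, nrow(N)))), 1e-12 * max(abs(N)))
  expect_lt(max(abs(rowSums(N))), 1e-12 * max(abs(N)))
  expect_equal(N, t(N), tolerance = 1e-12)
  ev <- eigen((N + t(N)) / 2, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(sort(ev)[2], 1e-10 * max(ev)) # one-dimensional kernel (constants)
  expect_lt(abs(sort(ev)[1]), 1e-10 * max(ev))
  # one entry on a two-triangle pair against a dense-quadrature oracle of the
  # surface-curl weak form
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1.2, 1.1, 0.4))
  two <- triangle_mesh(v, rbind(c(1, 2, 3), c(2, 4, 3)))
  Ntwo <- assemble_hypersingular(two, two)$matrix
  # oracle: N_ab = sum_{t,t'} (n x grad phi_a)_t . (n' x grad phi_b)_t' S0(t,t')
  curls <- function(tri_pts, nrm, area) {
    g <- rbind(tri_pts[2, ] - tri_pts[3, ],
               tri_pts[3, ] - tri_pts[1, ],
               tri_pts[1, ] - tri_pts[2, ]) / (2 * area)
    -g # n x grad phi_i = (p_j - p_k)/(2A); rows follow local vertex order
  }
  # entry (1, 4): vertex 1 only in triangle 1, vertex 4 only in triangle 2
  t1p <- v[c(1, 2, 3), ]; t2p <- v[c(2, 4, 3), ]
  c1 <- (v[2, ] - v[3, ]) / (2 * two$areas[1])
  c4 <- (v[3, ] - v[2, ]) / (2 * two$areas[2])
  # dense double integral of G between the two triangles
  u <- (rep(1:70, 70) - 0.5) / 70; w <- (rep(1:70, each = 70) - 0.5) / 70
  k <- u + w < 1
  p1 <- cbind(1 - u[k] - w[k], u[k], w[k]) %*% t1p
  p2 <- cbind(1 - u[k] - w[k], u[k], w[k]) %*% t2p
  a1 <- two$areas[1] / sum(k); a2 <- two$areas[2] / sum(k)
  G <- 0
  for (i in seq_len(nrow(p1)))
    G <- G + sum(a1 * a2 / (4 * pi *
                              sqrt(rowSums(sweep(p2, 2, p1[i, ])^2))))
  oracle <- sum(c1 * c4) * G
  expect_lt(abs(Ntwo[1, 4] - oracle) / abs(oracle), 5e-3)
})

test_that("operator invariants hold across refinement levels", {
  for (lev in 0:2) {
    m <- make_icosphere(0.1, lev)
    D <- assemble_double_layer(m, m)$D$matrix
    expect_lt(max(abs(rowSums(D) + m$areas / 2)), 4e-3 * max(m$areas))
    S <- assemble_single_layer(m, m)$matrix
    expect_identical(S, t(S))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("adaptive integration sharpens near-singular outer integrals", {
  # near-singular pair: a tiny triangle close above a larger one
  big <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
  near_v <- rbind(c(0.28, 0.22, 0.02), c(0.38, 0.22, 0.02), c(0.28, 0.32, 0.02))
  small <- triangle_mesh(near_v, rbind(1:3))
  quad_on <- quadrature_options(adaptive = TRUE, tol = 1e-6, near_gate = 10)
  quad_off <- quadrature_options(adaptive = FALSE)
  # reference: analytic inner integral, very fine fixed outer subdivision
  refine <- function(tri, depth) {
    if (depth == 0) return(list(tri))
    m12 <- (tri[1, ] + tri[2, ]) / 2; m23 <- (tri[2, ] + tri[3, ]) / 2
    m31 <- (tri[3, ] + tri[1, ]) / 2
    unlist(lapply(list(rbind(tri[1, ], m12, m31), rbind(m12, tri[2, ], m23),
                       rbind(m31, m23, tri[3, ]), rbind(m12, m23, m31)),
                  refine, depth = depth - 1), recursive = FALSE)
  }
  ref <- 0
  for (sub in refine(near_v, 5)) {
    pts <- matrix(1 / 3, 1, 3) %*% sub
    area <- 0.5 * sqrt(sum(vcross3(sub[2, ] - sub[1, ], sub[3, ] - sub[1, ])^2))
    ref <- ref + area * analytic_triangle_integrals(pts, big)$single[1, 1]
  }
  # the outer (test-side) integral over the big triangle sees the sharply
  # peaked analytic potential of the small one: this is where adaptivity acts
  v_on <- assemble_single_layer(big, small, quad_on)$matrix[1, 1]
  v_off <- assemble_single_layer(big, small, quad_off)$matrix[1, 1]
  expect_lt(abs(v_on - ref), abs(v_off - ref))
  # far pair: adaptivity gate is closed, bitwise identical to the base pass
  qg <- quadrature_options(adaptive = TRUE, tol = 1e-6)
  far <- triangle_mesh(near_v + matrix(c(0, 0, 5), 3, 3, byrow = TRUE),
                       rbind(1:3))
  expect_identical(assemble_single_layer(far, big, qg)$matrix,
                   assemble_single_layer(far, big, quad_off)$matrix)
  # loosening the tolerance never decreases the error on this fixture
  errs <- vapply(c(1e-1, 1e-3, 1e-6), function(tl) {
    q <- quadrature_options(adaptive = TRUE, tol = tl, near_gate = 10)
    abs(assemble_single_layer(big, small, q)$matrix[1, 1] - ref)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-15 + 0 * diff(errs)))
})

test_that("adaptive_integrate exposes the subdivision scheme for user integrands", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  smooth <- function(p) p[, 1] + 2 * p[, 2] + 1
  q_on <- quadrature_options(adaptive = TRUE, tol = 1e-8)
  q_off <- quadrature_options(adaptive = FALSE)
  v_on <- adaptive_integrate(smooth, tri, q_on)
  v_off <- adaptive_integrate(smooth, tri, q_off)
  expect_equal(v_on$value, v_off$value, tolerance = 1e-12) # degree-5 exactness
  expect_equal(v_on$value, 0.5 * (1 / 3 + 2 / 3 + 1), tolerance = 1e-12)
  # near-singular integrand with an exact reference: the single-layer kernel
  # of a point just above the triangle, whose integral is analytic
  xp <- c(0.3, 0.3, 0.005)
  spike <- function(p) 1 / (4 * pi * sqrt(rowSums(sweep(p, 2, xp)^2)))
  tm <- triangle_mesh(tri, rbind(1:3))
  ref <- analytic_triangle_integrals(rbind(xp), tm)$single[1, 1]
  e_on <- abs(adaptive_integrate(spike, tri, q_on)$value - ref)
  e_off <- abs(adaptive_integrate(spike, tri, q_off)$value - ref)
  expect_lt(e_on, e_off / 10)
})

test_that("mass matrices have the exact closed-form values", {
  m <- make_icosphere(0.3, 1)
  M00 <- mass_matrix(m, "P0", "P0")$matrix
  expect_equal(as.numeric(Matrix::diag(M00)), m$areas)
  expect_equal(Matrix::nnzero(M00), length(m$areas))
  M11 <- mass_matrix(m, "P1", "P1")$matrix
  # row sums: one third of the vertex-adjacent area
  adj <- numeric(nrow(m$vertices))
  for (j in 1:3) for (t in seq_len(nrow(m$triangles)))
    adj[m$triangles[t, j]] <- adj[m$triangles[t, j]] + m$areas[t] / 3
  expect_equal(as.numeric(Matrix::rowSums(M11)), adj, tolerance = 1e-14)
  expect_equal(sum(M11), sum(m$areas), tolerance = 1e-12)
  M10 <- mass_matrix(m, "P1", "P0")$matrix
  expect_equal(dim(M10), c(nrow(m$vertices), nrow(m$triangles)))
  expect_equal(sum(M10), sum(m$areas), tolerance = 1e-12)
})
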