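# head matrix, source matrices and sensor transfer matrices

test_that("head matrices are exactly symmetric and deflation removes constants", {
  sol <- fix_solved(1)
  H <- sol$hm$matrix
  expect_identical(H, t(H))
  # undeflated matrix annihilates (constant V, p = 0)
  hm0 <- assemble_head_matrix(sol$model, quadrature_options(), deflate = FALSE)
  expect_identical(hm0$matrix, t(hm0$matrix))
  map <- hm0$map
  z <- numeric(map$n)
  for (i in seq_len(map$N)) z[map$V[[i]]] <- 1
  resid <- hm0$matrix %*% z
  expect_lt(max(abs(resid)), 1e-3 * max(abs(hm0$matrix)))
  # the deflated matrix does not
  expect_gt(max(abs(H %*% z)), 1e-6 * max(abs(H)))
})

test_that("conductivity decomposition re-contracts exactly", {
  sol <- fix_solved(1)
  set.seed(99)
  for (k in 1:20) {
    sigma <- exp(stats::runif(3, log(1 / 100), log(2)))
    hm_new <- update_head_matrix(sol$hm, sigma)
    model2 <- sol$model
    model2$conductivities <- sigma
    # "direct" assembly re-integrates the operator blocks and contracts
    hm_direct <- assemble_head_matrix(model2, quadrature_options())
    expect_identical(hm_new$matrix, hm_direct$matrix)
  }
})

test_that("dipole source matrices are local and exactly linear in the moment", {
  sol <- fix_solved(1)
  model <- sol$model
  d1 <- structure(list(positions = rbind(c(0, 0, 0.05), c(0, 0, 0.05)),
                       moments = rbind(c(1, 2, 0.5), c(2, 4, 1)),
                       domain = c(1L, 1L)), class = "bem_dipoles")
  B <- assemble_dipole_source_matrix(model, d1)
  expect_identical(2 * B[, 1], B[, 2])
  # dipole in domain 1: only interface-1 rows are nonzero
  map <- sol$hm$map
  expect_gt(max(abs(B[map$V[[1]], 1])), 0)
  for (i in 2:3) expect_equal(max(abs(B[map$V[[i]], 1])), 0)
  expect_equal(max(abs(B[map$p[[2]], 1])), 0)
})

test_that("surfacic sources match merged point-dipole columns", {
  sol <- fix_solved(1)
  model <- sol$model
  # a small single-triangle source deep inside domain 1
  tri <- triangle_mesh(rbind(c(0.01, 0, 0.02), c(0.015, 0.01, 0.021),
                             c(0.005, 0.012, 0.019)), rbind(1:3))
  src <- surface_source(tri, rep(1, 3))
  B <- assemble_surface_source_matrix(model, src)
  combined <- rowSums(B) # all intensities 1
  # oracle: subdivide the source triangle into many point dipoles q = n dA
  sub <- 12
  u <- (rep(1:sub, sub) - 2 / 3) / sub; v <- (rep(1:sub, each = sub) - 2 / 3) / sub
  keep <- u + v < 1
  pts <- cbind(1 - u[keep] - v[keep], u[keep], v[keep]) %*% tri$vertices
  mom <- matrix(tri$normals[1, ], nrow(pts), 3, byrow = TRUE) *
    (tri$areas[1] / sum(keep))
  dips <- structure(list(positions = pts, moments = mom,
                         domain = rep(1L, nrow(pts))), class = "bem_dipoles")
  oracle <- rowSums(assemble_dipole_source_matrix(model, dips))
  expect_lt(max(abs(combined - oracle)), 1e-3 * max(abs(oracle)))
  # zero intensities give a zero combination; scaling is exact
  expect_identical(B %*% rep(0, 3), matrix(0, nrow(B), 1))
  expect_equal(B %*% rep(2.5, 3), 2.5 * (B %*% rep(1, 3)), tolerance = 1e-14)
})

test_that("EEG transfer rows are barycentric convex combinations", {
  sol <- fix_solved(1)
  scalp <- sol$model$interfaces[[3]]
  pts <- rbind(scalp$vertices[4, ],              # at a vertex
               scalp$centroids[10, ],            # exactly at a centroid
               c(0, 0, 0.12))
  elec <- project_electrodes(pts, scalp)
  M <- head2eeg(sol$model, elec)
  expect_equal(rowSums(M), rep(1, 3), tolerance = 1e-12)
  expect_true(all(M >= -1e-12))
  expect_equal(sum(M[1, ] > 1e-9), 1) # single unit entry at the vertex
  expect_equal(max(M[1, ]), 1, tolerance = 1e-9)
  expect_equal(sort(M[2, M[2, ] > 1e-9]), rep(1 / 3, 3), tolerance = 1e-9)
  expect_error(head2eeg(sol$model, list(kind = "EEG")), "bem_sensors")
})

test_that("MEG transfer: constant potentials and invisible interfaces read zero", {
  sol <- fix_solved(1)
  model <- sol$model
  dirs <- make_icosphere(1, 0)$vertices
  sens <- meg_sensors(dirs * 0.15, dirs)
  M <- head2meg(model, sens)
  map <- sol$hm$map
  # p blocks receive zero
  expect_equal(max(abs(M[, c(map$p[[1]], map$p[[2]])])), 0)
  # constant V on each closed interface -> zero Ohmic reading
  for (i in 1:3) {
    z <- numeric(map$n); z[map$V[[i]]] <- 1
    expect_lt(max(abs(M %*% z)), 1e-12 * max(abs(M)))
  }
  # equal conductivities on both sides: interface contributes nothing
  model_eq <- model
  model_eq$conductivities <- c(0.5, 0.5, 0.5)
  Meq <- head2meg(model_eq, sens)
  expect_equal(max(abs(Meq[, map$V[[1]]])), 0)
  expect_equal(max(abs(Meq[, map$V[[2]]])), 0)
  expect_gt(max(abs(Meq[, map$V[[3]]])), 0)
})

test_that("primary MEG fields follow the dipole closed form", {
  model <- fix_model_l1()
  r0 <- c(0, 0, 0.05)
  # q parallel to (r - r0): zero field
  sensp <- meg_sensors(rbind(c(0, 0, 0.15)), rbind(c(1, 0, 0)))
  dip <- structure(list(positions = rbind(r0), moments = rbind(c(0, 0, 1)),
                        domain = 1L), class = "bem_dipoles")
  expect_equal(dipsource2meg(dip, sensp)[1, 1], 0)
  # perpendicular geometry: |B| = mu0 q / (4 pi d^2)
  d <- 0.1
  sens2 <- meg_sensors(rbind(r0 + c(d, 0, 0)), rbind(c(0, 1, 0)))
  expect_equal(dipsource2meg(dip, sens2)[1, 1], 1e-7 / d^2, tolerance = 1e-12)
  # radial reading equals the Sarvas radial component (volume currents are
  # radially silent on spheres)
  rs <- c(0.1, 0.05, 0.08); rs <- rs / sqrt(sum(rs^2)) * 0.13
  sens3 <- meg_sensors(rbind(rs), rbind(rs / sqrt(sum(rs^2))))
  dip2 <- structure(list(positions = rbind(r0), moments = rbind(c(1, 2, 0)),
                         domain = 1L), class = "bem_dipoles")
  primary_radial <- dipsource2meg(dip2, sens3)[1, 1]
  sarvas_radial <- meg_sphere_field(r0, c(1, 2, 0), rbind(rs),
                                    rbind(rs / sqrt(sum(rs^2))))
  expect_equal(primary_radial, as.numeric(sarvas_radial), tolerance = 1e-10)
  # weighted multi-point channels group correctly
  sens4 <- meg_sensors(rbind(c(0, 0, 0.15), c(0, 0, 0.16)),
                       rbind(c(0, 1, 0), c(0, 1, 0)),
                       weights = c(0.25, 0.75), channels = c("ch", "ch"))
  one <- dipsource2meg(dip2, sens4)
  expect_equal(dim(one), c(1L, 1L))
  a <- dipsource2meg(dip2, meg_sensors(rbind(c(0, 0, 0.15)), rbind(c(0, 1, 0))))
  b <- dipsource2meg(dip2, meg_sensors(rbind(c(0, 0, 0.16)), rbind(c(0, 1, 0))))
  expect_equal(one[1, 1], 0.25 * a[1, 1] + 0.75 * b[1, 1], tolerance = 1e-14)
})

test_that("EIT source matrices enforce compatibility and are linear", {
  sol <- fix_solved(1)
  scalp <- sol$model$interfaces[[3]]
  pos <- rbind(c(0, 0, 0.1), c(0, 0, -0.1))
  expect_error(eit_injection(pos, c(1, -0.5), scalp), "sum to zero")
  inj1 <- eit_injection(pos, c(1, -1), scalp)
  inj2 <- eit_injection(pos, c(2, -2), scalp)
  B1 <- assemble_eit_source_matrix(sol$model, inj1, blocks = sol$hm$blocks)
  B2 <- assemble_eit_source_matrix(sol$model, inj2, blocks = sol$hm$blocks)
  expect_equal(B2, 2 * B1, tolerance = 1e-14)
  inj0 <- eit_injection(pos, c(0, 0), scalp)
  expect_equal(max(abs(assemble_eit_source_matrix(sol$model, inj0,
                                                  blocks = sol$hm$blocks))), 0)
})

test_that("internal-potential matrices split boundary and source terms", {
  sol <- fix_solved(1)
  model <- sol$model
  dip <- sol$dip # all in domain 1
  ip <- internal_points(rbind(c(0, 0, 0.01), c(0.09, 0, 0)), model)
  expect_equal(ip$domain, c(1L, 2L))
  S2 <- dipsource2ip(dip, ip, model)
  expect_gt(abs(S2[1, 1]), 0) # same domain: infinite-medium term
  expect_equal(S2[2, 1], 0)   # different domain: zero
  # infinite-medium potential: direct substitution and scaling law
  v <- infinite_medium_potential(c(0, 0, 0), c(0, 0, 1), rbind(c(0, 0, 1)))
  expect_equal(v$potential, 1 / (4 * pi), tolerance = 1e-14)
  vperp <- infinite_medium_potential(c(0, 0, 0), c(0, 0, 1), rbind(c(1, 0, 0)))
  expect_equal(vperp$potential, 0)
  va <- infinite_medium_potential(c(0, 0, 0), c(0, 0, 1), rbind(c(0, 0, 3)))
  expect_equal(va$potential, v$potential / 9, tolerance = 1e-14)
  # gradient is the analytic derivative (finite differences)
  h <- 1e-6
  g <- infinite_medium_potential(c(0, 0, 0), c(1, 2, 3), rbind(c(0.2, 0.1, 0.3)))
  for (k in 1:3) {
    e <- numeric(3); e[k] <- h
    num <- (infinite_medium_potential(c(0, 0, 0), c(1, 2, 3),
                                      rbind(c(0.2, 0.1, 0.3) + e))$potential -
            infinite_medium_potential(c(0, 0, 0), c(1, 2, 3),
                                      rbind(c(0.2, 0.1, 0.3) - e))$potential) /
      (2 * h)
    expect_equal(g$gradient[1, k], num, tolerance = 1e-6)
  }
})
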