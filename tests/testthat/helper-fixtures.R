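# Shared fixtures, lazily built and cached across test files. Everything is
# generated in code (no binary fixtures); sizes are kept small so the whole
# suite stays within its time budget.

.fix <- new.env(parent = emptyenv())

fix <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# benchmark geometry (scaled meters) and conductivities
bench_radii <- c(0.088, 0.092, 0.100)
bench_sigma <- c(1, 1 / 80, 1)
bench_depths <- c(0.50, 0.70, 0.85, 0.93, 0.97)

fix_model_l1 <- function() fix("model_l1", function() {
  head_model(lapply(bench_radii, make_icosphere, level = 1), bench_sigma)
})

fix_model_l2 <- function() fix("model_l2", function() {
  head_model(lapply(bench_radii, make_icosphere, level = 2), bench_sigma,
             check = FALSE)
})

fix_dipoles <- function(model) {
  dipole_set(cbind(0, 0, bench_depths * bench_radii[1]),
             matrix(c(1, 0, 1), length(bench_depths), 3, byrow = TRUE), model)
}

# solved 3-layer systems (head matrix + inverse + dipole sources), per level
fix_solved <- function(level) {
  fix(paste0("solved_l", level), function() {
    model <- if (level == 1) fix_model_l1() else fix_model_l2()
    quad <- quadrature_options()
    hm <- assemble_head_matrix(model, quad)
    hinv <- invert_head_matrix(hm)
    dip <- fix_dipoles(model)
    src <- assemble_dipole_source_matrix(model, dip, quad)
    list(model = model, hm = hm, hinv = hinv, dip = dip, src = src)
  })
}

# 1-layer homogeneous sphere (radius 0.1 m, sigma 1), level 2
fix_onelayer <- function() fix("onelayer", function() {
  mesh <- make_icosphere(0.1, 2)
  model <- head_model(list(mesh), 1)
  hm <- assemble_head_matrix(model)
  list(mesh = mesh, model = model, hm = hm, hinv = invert_head_matrix(hm))
})

# dense brute-force quadrature of f over a triangle: exact tiling into n^2
# congruent sub-triangles, centroid rule (O(1/n^2), no boundary bias); an
# independent oracle for the analytic integrals
brute_triangle <- function(f, tri, n = 200) {
  i <- rep(0:(n - 1), each = n); j <- rep(0:(n - 1), n)
  up <- i + j <= n - 1
  uu <- (i[up] + 1 / 3) / n; vu <- (j[up] + 1 / 3) / n
  dn <- i + j <= n - 2
  ud <- (i[dn] + 2 / 3) / n; vd <- (j[dn] + 2 / 3) / n
  u <- c(uu, ud); v <- c(vu, vd)
  pts <- cbind(1 - u - v, u, v) %*% tri
  area <- 0.5 * sqrt(sum(vcross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])^2))
  sum(f(pts)) * area / n^2
}

vcross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

expect_rel_equal <- function(x, y, tol) {
  testthat::expect_lt(max(abs(x - y)) / max(max(abs(y)), 1e-300), tol)
}
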