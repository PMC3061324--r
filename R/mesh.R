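#' Triangulated surface mesh
#'
#' Constructs a closed, oriented triangulated interface as used by the boundary
#' element head model. Vertex coordinates are in meters; triangle indices are
#' 1-based and ordered so that the right-hand-rule normal points outward.
#' Per-triangle unit normals, areas and centroids are derived on construction.
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates in meters.
#' @param triangles integer matrix (m x 3) of 1-based vertex indices.
#' @return an object of class `bem_mesh` with elements `vertices`, `triangles`,
#'   `normals`, `areas`, `centroids`.
#' @export
triangle_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle index out of range [1, ", nrow(vertices), "]")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  e1 <- vertices[triangles[, 2], , drop = FALSE] - vertices[triangles[, 1], , drop = FALSE]
  e2 <- vertices[triangles[, 3], , drop = FALSE] - vertices[triangles[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  two_a <- sqrt(rowSums(cr^2))
  if (any(two_a <= 0)) stop("degenerate (zero-area) triangle")
  centroids <- (vertices[triangles[, 1], , drop = FALSE] +
                vertices[triangles[, 2], , drop = FALSE] +
                vertices[triangles[, 3], , drop = FALSE]) / 3
  dimnames(vertices) <- dimnames(triangles) <- NULL
  structure(list(vertices = vertices, triangles = triangles,
                 normals = cr / two_a, areas = two_a / 2,
                 centroids = centroids),
            class = "bem_mesh")
}

#' @export
print.bem_mesh <- function(x, ...) {
  cat(sprintf("<bem_mesh> %d vertices, %d triangles, area %.6g m^2\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$areas)))
  invisible(x)
}

#' Vertex and triangle counts of a mesh
#' @param mesh a `bem_mesh`.
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_triangles <- function(mesh) nrow(mesh$triangles)

#' Signed volume enclosed by a closed oriented mesh
#'
#' Positive for outward orientation (divergence theorem on x/3).
#' @param mesh a `bem_mesh`.
#' @return signed enclosed volume in cubic meters.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$triangles
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]; c <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
      a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

# directed edge table (m*3 x 2)
mesh_edges <- function(mesh) {
  f <- mesh$triangles
  rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
}

#' Validate a triangulated interface
#'
#' Checks the invariants required of a boundary-element interface: every edge
#' shared by exactly two triangles (closedness), consistent orientation (each
#' shared edge traversed in opposite directions by its two triangles), positive
#' areas, and the genus-0 Euler characteristic V - E + F = 2.
#'
#' @param mesh a `bem_mesh`.
#' @return a list of class `bem_mesh_report` with logical fields `closed`,
#'   `oriented`, `ok`, numeric `min_angle` (degrees), `min_area`, `euler`, and
#'   `boundary_edges` (k x 2 matrix of unmatched undirected edges).
#' @export
validate_mesh <- function(mesh) {
  de <- mesh_edges(mesh)
  key <- paste(pmin(de[, 1], de[, 2]), pmax(de[, 1], de[, 2]))
  cnt <- table(key)
  closed <- all(cnt == 2L)
  bad <- names(cnt)[cnt != 2L]
  boundary <- if (length(bad)) {
    do.call(rbind, lapply(strsplit(bad, " "), as.integer))
  } else matrix(integer(), 0, 2)
  # orientation: each undirected edge must appear once in each direction
  dkey <- paste(de[, 1], de[, 2])
  oriented <- closed && !any(duplicated(dkey))
  v <- mesh$vertices; f <- mesh$triangles
  ang <- function(a, b, c) {
    u <- v[b, , drop = FALSE] - v[a, , drop = FALSE]
    w <- v[c, , drop = FALSE] - v[a, , drop = FALSE]
    cosv <- rowSums(u * w) / sqrt(rowSums(u^2) * rowSums(w^2))
    acos(pmin(1, pmax(-1, cosv)))
  }
  angles <- cbind(ang(f[, 1], f[, 2], f[, 3]), ang(f[, 2], f[, 3], f[, 1]),
                  ang(f[, 3], f[, 1], f[, 2]))
  E <- length(cnt)
  euler <- nrow(v) - E + nrow(f)
  res <- list(closed = closed, oriented = oriented,
              min_angle = min(angles) * 180 / pi, min_area = min(mesh$areas),
              euler = euler, boundary_edges = boundary,
              ok = closed && oriented && euler == 2L && min(mesh$areas) > 0)
  class(res) <- "bem_mesh_report"
  res
}

#' @export
print.bem_mesh_report <- function(x, ...) {
  cat(sprintf("<mesh report> closed=%s oriented=%s euler=%d min_angle=%.2f deg min_area=%.3g\n",
              x$closed, x$oriented, x$euler, x$min_angle, x$min_area))
  invisible(x)
}

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

#' Regularly subdivided sphere mesh (icosphere)
#'
#' Starts from the icosahedron and applies `level` rounds of 1-to-4 edge-midpoint
#' subdivision, projecting every vertex back to the requested radius. The result
#' has `10 * 4^level + 2` vertices and `20 * 4^level` triangles, outward
#' oriented, and is fully deterministic.
#'
#' @param radius sphere radius in meters (> 0).
#' @param level non-negative integer subdivision level (capped at 7).
#' @return a `bem_mesh`.
#' @export
make_icosphere <- function(radius, level = 0L) {
  stopifnot(radius > 0, level >= 0)
  if (level > 7L) stop("subdivision level capped at 7 to bound memory")
  ico <- icosahedron()
  v <- ico$v; f <- ico$f
  for (l in seq_len(level)) {
    nv <- nrow(v)
    edges <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
    ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    uk <- unique(ekey)
    mid_id <- match(ekey, uk) + nv
    ue <- do.call(rbind, strsplit(uk, " "))
    ue <- matrix(as.integer(ue), ncol = 2)
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m12 <- mid_id[seq_len(nrow(f))]
    m23 <- mid_id[nrow(f) + seq_len(nrow(f))]
    m31 <- mid_id[2 * nrow(f) + seq_len(nrow(f))]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(m12, f[, 2], m23),
               cbind(m31, m23, f[, 3]), cbind(m12, m23, m31))
  }
  triangle_mesh(v * radius, f)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Random sphere mesh
#'
#' Samples `n_vertices` directions uniformly on the sphere (normalized 3D
#' Gaussian draws, seeded), and triangulates them by their convex hull -- on a
#' sphere every sample is a hull vertex, so the hull is the spherical
#' triangulation with exactly `2 * n_vertices - 4` outward-oriented triangles.
#' The same `(n_vertices, seed)` pair always reproduces the same mesh.
#'
#' @param radius sphere radius in meters.
#' @param n_vertices number of vertices (>= 12).
#' @param seed integer RNG seed; the global RNG state is left untouched.
#' @param max_retries retries with perturbed samples on hull degeneracy.
#' @return a `bem_mesh`.
#' @export
make_random_sphere_mesh <- function(radius, n_vertices, seed, max_retries = 5L) {
  stopifnot(radius > 0, n_vertices >= 12)
  with_seed(as.integer(seed), {
    for (attempt in seq_len(max_retries)) {
      g <- matrix(stats::rnorm(3 * n_vertices), ncol = 3)
      v <- g / sqrt(rowSums(g^2)) * radius
      f <- tryCatch(cpp_convex_hull(v), error = function(e) NULL)
      if (!is.null(f) && nrow(f) == 2 * n_vertices - 4) {
        mesh <- triangle_mesh(v, f)
        rep <- validate_mesh(mesh)
        if (rep$ok && mesh_volume(mesh) > 0) return(mesh)
      }
      # degenerate sample: draw again (seeded stream continues deterministically)
    }
    stop("failed to build a valid random sphere mesh after ", max_retries, " attempts")
  })
}

#' Nested-interface head model
#'
#' Ordered interfaces S_1 (innermost) .. S_N (scalp) with per-domain
#' conductivities: `conductivities[i]` is the conductivity (S/m) of the domain
#' bounded on the outside by interface i; the conductivity outside the scalp is
#' fixed at zero.
#'
#' @param interfaces list of `bem_mesh`, innermost first.
#' @param conductivities positive numeric vector, one value per interface.
#' @param names optional interface names (default Interface1..N).
#' @param check if `TRUE` (default) validate meshes and strict nesting.
#' @return object of class `bem_head_model`.
#' @export
head_model <- function(interfaces, conductivities,
                       names = NULL, check = TRUE) {
  if (inherits(interfaces, "bem_mesh")) interfaces <- list(interfaces)
  stopifnot(length(interfaces) >= 1,
            length(conductivities) == length(interfaces))
  if (any(conductivities <= 0)) stop("conductivities must be > 0 (exterior is implicitly 0)")
  if (is.null(names)) names <- paste0("Interface", seq_along(interfaces))
  model <- structure(list(interfaces = interfaces,
                          conductivities = as.numeric(conductivities),
                          names = names),
                     class = "bem_head_model")
  if (check) {
    for (i in seq_along(interfaces)) {
      rep <- validate_mesh(interfaces[[i]])
      if (!rep$ok) stop("interface ", i, " fails mesh validation")
      if (mesh_volume(interfaces[[i]]) <= 0)
        stop("interface ", i, " is inward-oriented")
    }
    nest <- check_nesting(model)
    if (!nest$ok) stop("interfaces are not strictly nested: ", nest$message)
  }
  model
}

#' @export
print.bem_head_model <- function(x, ...) {
  cat(sprintf("<bem_head_model> %d nested interface(s)\n", length(x$interfaces)))
  for (i in seq_along(x$interfaces))
    cat(sprintf("  %d. %s: %d vertices, %d triangles, sigma = %g S/m\n", i,
                x$names[i], n_vertices(x$interfaces[[i]]),
                n_triangles(x$interfaces[[i]]), x$conductivities[i]))
  invisible(x)
}

#' Winding numbers of points with respect to a closed mesh
#'
#' Summed signed solid angle over all triangles divided by 4*pi: 1 for points
#' inside, 0 outside (robust for non-convex closed meshes).
#'
#' @param points n x 3 matrix.
#' @param mesh a closed `bem_mesh`.
#' @return numeric vector of winding numbers (un-rounded).
#' @export
winding_number <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  as.numeric(cpp_winding(points, mesh$vertices, mesh$triangles))
}

#' Check strict nesting of a head model
#'
#' Every vertex of S_i must have winding number 1 with respect to S_j for all
#' j > i, and no vertex of S_j may lie inside S_i.
#'
#' @param model a `bem_head_model` (or list of meshes).
#' @return list with `ok` (logical), `message`, and a `report` data frame of
#'   per-pair winding summaries.
#' @export
check_nesting <- function(model) {
  meshes <- if (inherits(model, "bem_head_model")) model$interfaces else model
  N <- length(meshes)
  rows <- list()
  ok <- TRUE; msg <- ""
  if (N > 1) {
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        w_in <- winding_number(meshes[[i]]$vertices, meshes[[j]])
        w_out <- winding_number(meshes[[j]]$vertices, meshes[[i]])
        inner_inside <- all(round(w_in) == 1)
        outer_outside <- all(round(w_out) == 0)
        rows[[length(rows) + 1L]] <- data.frame(
          inner = i, outer = j,
          frac_inner_inside = mean(round(w_in) == 1),
          frac_outer_inside = mean(round(w_out) == 1))
        if (!inner_inside || !outer_outside) {
          ok <- FALSE
          msg <- sprintf("interface %d is not strictly inside interface %d", i, j)
        }
      }
    }
  }
  list(ok = ok, message = msg,
       report = if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Locate the domain containing a point
#'
#' Returns, for each point, the index of the innermost domain containing it
#' (domain i lies between interfaces i-1 and i), or `NA` for points outside the
#' head. Points within `eps` of any interface are an error: degenerate
#' placements must be resolved by the caller, never silently perturbed.
#'
#' @param points n x 3 matrix (meters).
#' @param model a `bem_head_model`.
#' @param eps minimum allowed distance to any interface (meters).
#' @return integer vector of domain indices (`NA` = outside).
#' @export
locate_domain <- function(points, model, eps = 1e-6) {
  points <- matrix(as.numeric(points), ncol = 3)
  for (i in seq_along(model$interfaces)) {
    cp <- cpp_closest_point(points, model$interfaces[[i]]$vertices,
                            model$interfaces[[i]]$triangles)
    if (any(cp$dist < eps))
      stop("point within eps = ", eps, " m of interface ", i,
           " (first offending point index ", which(cp$dist < eps)[1], ")")
  }
  W <- vapply(model$interfaces, function(m) round(winding_number(points, m)),
              numeric(nrow(points)))
  W <- matrix(W, nrow = nrow(points))
  apply(W, 1, function(w) {
    inside <- which(w == 1)
    if (length(inside)) min(inside) else NA_integer_
  })
}

#' Dipole set
#'
#' Pointwise dipolar sources: positions (m) and moments (A m). Each dipole must
#' lie strictly inside a conductivity domain, at distance > `eps` from every
#' interface; the containing domain index is computed and stored.
#'
#' @param positions n x 3 matrix of positions (meters).
#' @param moments n x 3 matrix of dipole moments (A m).
#' @param model a `bem_head_model` used to resolve domains.
#' @param eps minimum distance to any interface (meters).
#' @return object of class `bem_dipoles` with `positions`, `moments`, `domain`.
#' @export
dipole_set <- function(positions, moments, model, eps = 1e-6) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  moments <- matrix(as.numeric(moments), ncol = 3)
  stopifnot(nrow(positions) == nrow(moments))
  dom <- locate_domain(positions, model, eps = eps)
  if (anyNA(dom)) stop("dipole ", which(is.na(dom))[1], " lies outside the head")
  structure(list(positions = positions, moments = moments, domain = dom),
            class = "bem_dipoles")
}

#' Nearest scalp triangle to a point
#'
#' The triangle whose centroid is closest to the point; ties broken by the
#' lowest triangle index. Used to resolve current-injection electrodes.
#'
#' @param point length-3 numeric.
#' @param mesh scalp `bem_mesh`.
#' @return integer triangle index (1-based).
#' @export
nearest_triangle <- function(point, mesh) {
  d2 <- rowSums((mesh$centroids - matrix(point, nrow(mesh$centroids), 3,
                                         byrow = TRUE))^2)
  which.min(d2)
}

#' Project EEG electrodes onto the scalp
#'
#' Each electrode is replaced by its nearest point on the scalp triangulation;
#' the owning triangle and barycentric coordinates are stored. Projection is
#' idempotent.
#'
#' @param points n x 3 matrix of electrode positions (meters).
#' @param scalp scalp `bem_mesh` (must be closed).
#' @param names optional electrode names.
#' @return object of class `bem_sensors`, kind "EEG", with fields `positions`
#'   (input), `projected`, `triangle`, `bary`, `names`.
#' @export
project_electrodes <- function(points, scalp, names = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) == 0L) stop("empty electrode list")
  cp <- cpp_closest_point(points, scalp$vertices, scalp$triangles)
  structure(list(kind = "EEG", positions = points, projected = cp$closest,
                 triangle = as.integer(cp$triangle), bary = cp$bary,
                 names = names %||% paste0("E", seq_len(nrow(points)))),
            class = "bem_sensors")
}

#' MEG sensor set
#'
#' Each channel is a collection of integration points with weighted direction
#' vectors; the channel reading is sum(weight * direction . B(point)).
#'
#' @param points n x 3 matrix of integration point positions (meters).
#' @param directions n x 3 matrix of unit direction vectors.
#' @param weights numeric integration weights (default 1).
#' @param channels channel labels (grouping factor), default one per row.
#' @return object of class `bem_sensors`, kind "MEG".
#' @export
meg_sensors <- function(points, directions, weights = 1,
                        channels = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  directions <- matrix(as.numeric(directions), ncol = 3)
  stopifnot(nrow(points) == nrow(directions))
  weights <- rep_len(weights, nrow(points))
  channels <- channels %||% as.character(seq_len(nrow(points)))
  channels <- as.character(channels)
  structure(list(kind = "MEG", points = points, directions = directions,
                 weights = weights, channels = channels,
                 channel_names = unique(channels)),
            class = "bem_sensors")
}

#' Internal-potential sensor points
#'
#' @param points n x 3 matrix of measurement positions strictly inside the head.
#' @param model a `bem_head_model` used to resolve the containing domains.
#' @param eps minimum distance to any interface (meters).
#' @return object of class `bem_sensors`, kind "IP", with `points`, `domain`.
#' @export
internal_points <- function(points, model, eps = 1e-6) {
  points <- matrix(as.numeric(points), ncol = 3)
  dom <- locate_domain(points, model, eps = eps)
  if (anyNA(dom)) stop("internal point ", which(is.na(dom))[1], " is outside the head")
  structure(list(kind = "IP", points = points, domain = dom),
            class = "bem_sensors")
}

#' EIT current-injection pattern
#'
#' Electrode positions are resolved to their nearest scalp triangle
#' (centroid-distance rule); the injected current is modeled as a uniform
#' current density `I / area` on that triangle. Injected currents must sum to
#' zero (Neumann compatibility).
#'
#' @param positions n x 3 electrode positions (meters).
#' @param currents injected currents in amperes, summing to zero; either a
#'   vector (one pattern) or an n x k matrix (k patterns).
#' @param scalp scalp `bem_mesh`.
#' @param check_compatibility verify the zero-sum constraint (default `TRUE`;
#'   the CLI disables it to emit per-electrode unit columns meant to be
#'   combined into zero-sum patterns downstream).
#' @return object of class `bem_eit_injection` with `positions`, `currents`
#'   (matrix), `triangle`.
#' @export
eit_injection <- function(positions, currents, scalp,
                          check_compatibility = TRUE) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  currents <- as.matrix(currents)
  stopifnot(nrow(currents) == nrow(positions))
  sums <- colSums(currents)
  if (check_compatibility &&
      any(abs(sums) > 1e-12 * pmax(colSums(abs(currents)), 1e-300)))
    stop("injected currents must sum to zero in every pattern")
  tri <- vapply(seq_len(nrow(positions)),
                function(i) nearest_triangle(positions[i, ], scalp), integer(1))
  structure(list(positions = positions, currents = currents, triangle = tri),
            class = "bem_eit_injection")
}

#' Surfacic source distribution
#'
#' A dipole-layer source supported on a surfacic mesh: the current distribution
#' is `sum_i phi_i(r) J_i n(r)` over the source mesh, with one intensity per
#' vertex (linear on each triangle).
#'
#' @param mesh source `bem_mesh` (open meshes are allowed).
#' @param intensities numeric vector, one intensity per mesh vertex.
#' @return object of class `bem_surface_source`.
#' @export
surface_source <- function(mesh, intensities) {
  stopifnot(length(intensities) == n_vertices(mesh))
  structure(list(mesh = mesh, intensities = as.numeric(intensities)),
            class = "bem_surface_source")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
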