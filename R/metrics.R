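# Accuracy metrics and the concentric-sphere benchmark harness.

#' Relative difference measure between two forward fields
#'
#' `rdm(g_n, g_a) = || g_n/||g_n|| - g_a/||g_a|| ||` with the Euclidean l2 norm
#' over the sensor set; scale-invariant in both arguments, with values in
#' [0, 2] (0 for identical shapes, 2 for opposite ones).
#'
#' @param g_n,g_a nonzero numeric vectors of equal length (numerical and
#'   reference forward field).
#' @return scalar in [0, 2].
#' @export
rdm <- function(g_n, g_a) {
  nn <- sqrt(sum(g_n^2)); na <- sqrt(sum(g_a^2))
  if (nn == 0 || na == 0) stop("rdm undefined for zero-norm fields")
  sqrt(sum((g_n / nn - g_a / na)^2))
}

#' Magnitude ratio between two forward fields
#'
#' `mag(g_n, g_a) = ||g_n|| / ||g_a||` (Euclidean l2 norm over the sensors).
#'
#' @inheritParams rdm
#' @return positive scalar (1 for equal magnitudes).
#' @export
mag <- function(g_n, g_a) {
  na <- sqrt(sum(g_a^2))
  if (na == 0) stop("mag undefined for zero-norm reference field")
  sqrt(sum(g_n^2)) / na
}

#' Benchmark configuration on three-layer spheres
#'
#' Encodes the standard validation setup: radii 0.088 / 0.092 / 0.100 m,
#' conductivities 1, 1/80 (skull), 1 S/m, five z-axis dipoles with orientation
#' (1, 0, 1) at depths `depths * radii[1]`, EEG electrodes at every scalp
#' vertex, and magnetometers at radius `1.2 * radii[3]`.
#'
#' @param mesh type "regular" (icosphere `level`) or "random" (`n_vertices`
#'   per layer, `n_models` seeded instances).
#' @param level icosphere subdivision level for regular meshes (1, 2 or 3).
#' @param n_vertices,n_models random-mesh size and number of instances.
#' @param radii,conductivities model geometry (defaults above).
#' @param depths dipole z positions as fractions of the innermost radius.
#' @param orientation common dipole moment.
#' @param modality "EEG" or "MEG".
#' @param meg_orientation "fixed" ((1,0,1)-oriented magnetometers) or "radial".
#' @param meg_level icosphere level of the magnetometer directions.
#' @param adaptive adaptive integration on (the default) or off (the
#'   non-adaptive mode used for robustness comparisons).
#' @param quad base quadrature options (the `adaptive` flag above overrides).
#' @param seed integer seed for random meshes.
#' @return object of class `bem_benchmark_config`.
#' @export
benchmark_config <- function(mesh = c("regular", "random"), level = 2L,
                             n_vertices = 600L, n_models = 1L,
                             radii = c(0.088, 0.092, 0.100),
                             conductivities = c(1, 1 / 80, 1),
                             depths = c(0.50, 0.70, 0.85, 0.93, 0.97),
                             orientation = c(1, 0, 1),
                             modality = c("EEG", "MEG"),
                             meg_orientation = c("fixed", "radial"),
                             meg_level = 1L,
                             adaptive = TRUE,
                             quad = quadrature_options(),
                             seed = 1L) {
  mesh <- match.arg(mesh)
  modality <- match.arg(modality)
  meg_orientation <- match.arg(meg_orientation)
  stopifnot(all(radii > 0), all(conductivities > 0), all(depths > 0 & depths < 1))
  quad$adaptive <- isTRUE(adaptive)
  structure(list(mesh = mesh, level = as.integer(level),
                 n_vertices = as.integer(n_vertices),
                 n_models = as.integer(n_models), radii = radii,
                 conductivities = conductivities, depths = depths,
                 orientation = orientation, modality = modality,
                 meg_orientation = meg_orientation,
                 meg_level = as.integer(meg_level), quad = quad,
                 seed = as.integer(seed)),
            class = "bem_benchmark_config")
}

benchmark_meshes <- function(config, instance) {
  if (config$mesh == "regular") {
    lapply(config$radii, make_icosphere, level = config$level)
  } else {
    lapply(seq_along(config$radii), function(i)
      make_random_sphere_mesh(config$radii[i], config$n_vertices,
                              seed = config$seed + 1000L * instance + i))
  }
}

benchmark_dipoles <- function(config, model) {
  z <- config$depths * config$radii[1]
  dipole_set(cbind(0, 0, z),
             matrix(config$orientation, length(z), 3, byrow = TRUE), model)
}

benchmark_meg_sensors <- function(config) {
  dirs <- make_icosphere(1, config$meg_level)$vertices
  pts <- dirs * 1.2 * config$radii[length(config$radii)]
  ori <- if (config$meg_orientation == "radial") dirs
  else matrix(c(1, 0, 1) / sqrt(2), nrow(dirs), 3, byrow = TRUE)
  meg_sensors(pts, ori)
}

#' Run the sphere validation benchmark
#'
#' Builds the configured sphere meshes, assembles and solves the boundary
#' element system, computes the requested lead field, scores every dipole
#' column against the matching analytic oracle (multilayer series for EEG,
#' Sarvas for MEG) with RDM and MAG, and aggregates per-group summaries.
#' Fully deterministic for a given config (random meshes are seeded).
#'
#' @param config a `bem_benchmark_config`.
#' @param verbose print per-instance progress.
#' @return list of class `bem_benchmark_result` with `results` (data frame:
#'   instance, dipole, depth, rdm, mag) and `summary` (median and quartiles).
#' @export
run_benchmark <- function(config, verbose = FALSE) {
  rows <- list()
  for (inst in seq_len(if (config$mesh == "random") config$n_models else 1L)) {
    meshes <- benchmark_meshes(config, inst)
    model <- head_model(meshes, config$conductivities, check = FALSE)
    dip <- benchmark_dipoles(config, model)
    hm <- assemble_head_matrix(model, config$quad)
    hinv <- invert_head_matrix(hm)
    src <- assemble_dipole_source_matrix(model, dip, config$quad)
    sm <- sphere_model(config$radii, config$conductivities)
    if (config$modality == "EEG") {
      scalp <- meshes[[length(meshes)]]
      elec <- project_electrodes(scalp$vertices, scalp)
      L <- gain_eeg(hinv, src, head2eeg(model, elec))
      for (d in seq_len(nrow(dip$positions))) {
        ga <- eeg_sphere_potential(sm, dip$positions[d, ], dip$moments[d, ],
                                   scalp$vertices)
        rows[[length(rows) + 1L]] <- data.frame(
          instance = inst, dipole = d, depth = config$depths[d],
          rdm = rdm(L[, d], ga), mag = mag(L[, d], ga))
      }
    } else {
      sens <- benchmark_meg_sensors(config)
      h2m <- head2meg(model, sens, config$quad)
      s2m <- dipsource2meg(dip, sens)
      L <- gain_meg(hinv, src, h2m, s2m)
      ohmic <- attr(L, "ohmic")
      for (d in seq_len(nrow(dip$positions))) {
        ga <- meg_sphere_field(dip$positions[d, ], dip$moments[d, ],
                               sens$points, sens$directions)
        rows[[length(rows) + 1L]] <- data.frame(
          instance = inst, dipole = d, depth = config$depths[d],
          rdm = rdm(L[, d], ga), mag = mag(L[, d], ga),
          ohmic_frac = sqrt(sum(ohmic[, d]^2)) / sqrt(sum(L[, d]^2)))
      }
    }
    if (verbose)
      message(sprintf("instance %d done (%s, %s)", inst, config$mesh,
                      config$modality))
  }
  res <- do.call(rbind, rows)
  stopifnot(all(res$rdm >= 0), all(res$rdm <= 2), all(res$mag > 0))
  summ <- do.call(rbind, lapply(split(res, res$dipole), function(g)
    data.frame(dipole = g$dipole[1], depth = g$depth[1],
               rdm_median = stats::median(g$rdm),
               rdm_q1 = stats::quantile(g$rdm, 0.25, names = FALSE),
               rdm_q3 = stats::quantile(g$rdm, 0.75, names = FALSE),
               mag_median = stats::median(g$mag))))
  structure(list(results = res, summary = summ, config = config),
            class = "bem_benchmark_result")
}

#' @export
print.bem_benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark> %s %s, %d row(s)\n", x$config$mesh,
              x$config$modality, nrow(x$results)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
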