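# Closed-form / series solutions on concentric spheres: the oracles of the
# validation benchmark. All series use per-layer scaled radial bases
# (r/rho_i)^l and (rho_{i-1}/r)^(l+1) so that high orders neither overflow nor
# underflow.

#' Concentric-sphere model
#'
#' @param radii strictly increasing sphere radii (meters).
#' @param conductivities positive per-layer conductivities (S/m), innermost
#'   first; the exterior is insulating.
#' @param L series truncation order (default 100; the benchmark dipoles are
#'   deep enough that this over-converges).
#' @return object of class `bem_sphere_model`.
#' @export
sphere_model <- function(radii, conductivities, L = 100L) {
  stopifnot(length(radii) == length(conductivities),
            all(diff(radii) > 0), all(radii > 0), all(conductivities > 0),
            L >= 1)
  structure(list(radii = as.numeric(radii),
                 sigma = as.numeric(conductivities), L = as.integer(L)),
            class = "bem_sphere_model")
}

# Legendre P_l(x) and P_l'(x), l = 0..L, for a vector x in [-1, 1].
# Returns list of two (length(x) x (L+1)) matrices. Recurrences:
# (l+1) P_{l+1} = (2l+1) x P_l - l P_{l-1};  P'_{l+1} = P'_{l-1} + (2l+1) P_l.
legendre_table <- function(x, L) {
  n <- length(x)
  P <- matrix(0, n, L + 1)
  dP <- matrix(0, n, L + 1)
  P[, 1] <- 1
  if (L >= 1) { P[, 2] <- x; dP[, 2] <- 1 }
  if (L >= 2) for (l in 1:(L - 1)) {
    P[, l + 2] <- ((2 * l + 1) * x * P[, l + 1] - l * P[, l]) / (l + 1)
    dP[, l + 2] <- dP[, l] + (2 * l + 1) * P[, l + 1]
  }
  list(P = P, dP = dP)
}

# index helpers for the radial coefficient vector (A_1, A_2, B_2, ..., A_N, B_N)
radial_index <- function(N) {
  iA <- integer(N); iB <- rep(NA_integer_, N)
  iA[1] <- 1L
  k <- 1L
  if (N >= 2) for (i in 2:N) {
    iA[i] <- k + 1L; iB[i] <- k + 2L; k <- k + 2L
  }
  list(A = iA, B = iB, n = 2L * N - 1L)
}

# Per-degree interface-transfer system for a source in layer j (j = 0 means
# "no interior source": pure Neumann data at the outer boundary).
# Returns list(u1, u2): homogeneous coefficients per unit source factors
# s1 = (b/rho_j)^l and s2 = (rho_{j-1}/b)^(l+1), and (for j = 0) `uN`: response
# to unit Neumann flux sigma_N V'(rho_N) = 1.
radial_solution <- function(model, l, j) {
  rho <- model$radii; sig <- model$sigma; N <- length(rho)
  idx <- radial_index(N)
  M <- matrix(0, idx$n, idx$n)
  w1 <- numeric(idx$n); w2 <- numeric(idx$n); wN <- numeric(idx$n)
  rho0 <- c(rho[1], rho) # rho0[i] = rho_{i-1} with rho_0 := rho_1 (unused for i=1)
  fval <- function(i, r) (r / rho[i])^l
  fder <- function(i, r) l / r * fval(i, r)
  gval <- function(i, r) (rho0[i] / r)^(l + 1)
  gder <- function(i, r) -(l + 1) / r * gval(i, r)
  row <- 0L
  if (N >= 2) for (i in 1:(N - 1)) {
    r <- rho[i]
    # continuity of V
    row <- row + 1L
    M[row, idx$A[i]] <- fval(i, r)
    if (i >= 2) M[row, idx$B[i]] <- gval(i, r)
    M[row, idx$A[i + 1]] <- -fval(i + 1, r)
    M[row, idx$B[i + 1]] <- -gval(i + 1, r)
    if (j == i) w1[row] <- -pout_val(model, l, j, r)
    if (j == i + 1) w2[row] <- pin_val(model, l, j, r)
    # continuity of sigma V'
    row <- row + 1L
    M[row, idx$A[i]] <- sig[i] * fder(i, r)
    if (i >= 2) M[row, idx$B[i]] <- sig[i] * gder(i, r)
    M[row, idx$A[i + 1]] <- -sig[i + 1] * fder(i + 1, r)
    M[row, idx$B[i + 1]] <- -sig[i + 1] * gder(i + 1, r)
    if (j == i) w1[row] <- -sig[j] * pout_der(model, l, j, r)
    if (j == i + 1) w2[row] <- sig[j] * pin_der(model, l, j, r)
  }
  # insulating outer boundary: sigma_N V'(rho_N) = flux data
  row <- row + 1L
  r <- rho[N]
  M[row, idx$A[N]] <- sig[N] * fder(N, r)
  if (N >= 2) M[row, idx$B[N]] <- sig[N] * gder(N, r)
  if (j == N) w1[row] <- -sig[N] * pout_der(model, l, N, r)
  wN[row] <- 1
  sol <- solve(M, cbind(w1, w2, wN))
  list(u1 = sol[, 1], u2 = sol[, 2], uN = sol[, 3], idx = idx)
}

# particular (infinite-medium monopole) radial factors in the source layer j,
# normalized by s1/s2 (see radial_solution)
pout_val <- function(model, l, j, r) {
  (model$radii[j] / r)^l / (4 * pi * model$sigma[j] * r)
}
pout_der <- function(model, l, j, r) -(l + 1) / r * pout_val(model, l, j, r)
pin_val <- function(model, l, j, r) {
  rin <- if (j >= 2) model$radii[j - 1] else model$radii[1]
  (r / rin)^l / (4 * pi * model$sigma[j] * rin)
}
pin_der <- function(model, l, j, r) l / r * pin_val(model, l, j, r)

sphere_layer_of <- function(model, r, tol = 1e-9) {
  rho <- model$radii
  if (any(r > rho[length(rho)] * (1 + 1e-6)))
    stop("evaluation point outside the outermost sphere")
  pmin(vapply(r, function(ri) sum(ri > rho * (1 + tol)) + 1L, integer(1)),
       length(rho))
}

#' Multilayer-sphere EEG potential of a dipole (Legendre series)
#'
#' Series solution of the piecewise-homogeneous conduction equation on
#' concentric spheres with an insulating exterior: per degree l, a radial
#' two-point transfer system couples the layers; the dipole enters as the
#' analytic gradient of the monopole kernel with respect to the source
#' position. Valid at any evaluation radius (surface or interior), so it also
#' serves as the internal-potential oracle.
#'
#' @param model a `bem_sphere_model`.
#' @param r0 dipole position (length 3, strictly inside the outer sphere).
#' @param q dipole moment (length 3, A m).
#' @param points n x 3 evaluation points (inside or on the outer sphere).
#' @param reference "average" (zero mean over the evaluation set, default) or
#'   "none".
#' @return numeric vector of potentials (volts). Attribute `tail` holds the
#'   magnitude of the last retained term relative to the result norm (a
#'   truncation diagnostic; a warning is emitted when it exceeds 1e-6).
#' @export
eeg_sphere_potential <- function(model, r0, q, points, reference = "average") {
  points <- matrix(as.numeric(points), ncol = 3)
  r0 <- as.numeric(r0); q <- as.numeric(q)
  b <- sqrt(sum(r0^2))
  if (b >= model$radii[length(model$radii)])
    stop("dipole must lie strictly inside the outer sphere")
  bmin <- 1e-9 * model$radii[1]
  yhat <- if (b > bmin) r0 / b else c(0, 0, 1)
  b <- max(b, bmin)
  j <- sphere_layer_of(model, b)
  r <- sqrt(rowSums(points^2))
  lay <- sphere_layer_of(model, r)
  xhat <- points / pmax(r, 1e-300)
  cosg <- pmin(1, pmax(-1, as.numeric(xhat %*% yhat)))
  qy <- sum(q * yhat)
  qx <- as.numeric(points %*% q) / pmax(r, 1e-300)
  leg <- legendre_table(cosg, model$L)
  rho <- model$radii; rho0 <- c(rho[1], rho)
  # The infinite-medium term is added in closed form for points in the source
  # layer (its per-degree expansion converges arbitrarily slowly near the
  # source radius); the series then only carries the smooth homogeneous
  # corrections. Points in deeper layers (r < b outside layer j) still need
  # the degree-0 jump of the infinite-medium potential.
  V <- numeric(nrow(points))
  in_src <- lay == j
  if (any(in_src))
    V[in_src] <- infinite_medium_potential(b * yhat, q,
                                           points[in_src, , drop = FALSE],
                                           sigma = model$sigma[j])$potential
  V[!in_src & r < b] <- -qy / (4 * pi * model$sigma[j] * b^2) # degree-0 jump
  last_term <- 0
  for (l in seq_len(model$L)) {
    sol <- radial_solution(model, l, j)
    s1 <- (b / rho[j])^l
    s2 <- if (j >= 2) (rho[j - 1] / b)^(l + 1) else 0
    ds1 <- l / b * s1
    ds2 <- -(l + 1) / b * s2
    Rl <- numeric(nrow(points)); Rbl <- numeric(nrow(points))
    for (i in unique(lay)) {
      sel <- lay == i
      ri <- r[sel]
      fv <- (ri / rho[i])^l
      gv <- if (i >= 2) (rho0[i] / ri)^(l + 1) else 0
      A <- s1 * sol$u1[sol$idx$A[i]] + s2 * sol$u2[sol$idx$A[i]]
      dA <- ds1 * sol$u1[sol$idx$A[i]] + ds2 * sol$u2[sol$idx$A[i]]
      B <- dB <- 0
      if (i >= 2) {
        B <- s1 * sol$u1[sol$idx$B[i]] + s2 * sol$u2[sol$idx$B[i]]
        dB <- ds1 * sol$u1[sol$idx$B[i]] + ds2 * sol$u2[sol$idx$B[i]]
      }
      Rl[sel] <- A * fv + B * gv
      Rbl[sel] <- dA * fv + dB * gv
    }
    term <- qy * Rbl * leg$P[, l + 1] +
      Rl * leg$dP[, l + 1] * (qx - cosg * qy) / b
    V <- V + term
    last_term <- max(abs(term))
  }
  tail_rel <- last_term / max(max(abs(V)), 1e-300)
  if (tail_rel > 1e-6)
    warning(sprintf("series not converged at L = %d (tail %.2g)", model$L,
                    tail_rel))
  if (reference == "average") V <- V - mean(V)
  attr(V, "tail") <- tail_rel
  V
}

#' Interior potential oracle on concentric spheres
#'
#' Identical series engine as [eeg_sphere_potential()] evaluated at interior
#' radii (the series is valid at any radius); the default gauge is the raw
#' series so that values at different radii remain comparable.
#'
#' @inheritParams eeg_sphere_potential
#' @export
ip_sphere_potential <- function(model, r0, q, points, reference = "none") {
  eeg_sphere_potential(model, r0, q, points, reference = reference)
}

#' Sarvas magnetic field of a dipole in a spherically symmetric conductor
#'
#' Closed form, independent of the layer radii and conductivities; radial
#' dipoles are magnetically silent, and the radial field component equals the
#' radial component of the primary (Biot-Savart) dipole field.
#'
#' @param r0 dipole position (length 3, meters; not at the origin for
#'   non-radial evaluation directions on the dipole ray).
#' @param q dipole moment (length 3, A m).
#' @param points n x 3 sensor positions (outside the conductor, away from the
#'   origin).
#' @param directions optional n x 3 unit sensor orientations; if supplied the
#'   projected readings are returned, otherwise the full field vectors.
#' @return n x 3 matrix of fields (tesla), or a length-n vector of projected
#'   readings.
#' @export
meg_sphere_field <- function(r0, q, points, directions = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  r0 <- as.numeric(r0); q <- as.numeric(q)
  n <- nrow(points)
  B <- matrix(0, n, 3)
  qxr0 <- vcross(q, r0)
  for (i in seq_len(n)) {
    r <- points[i, ]
    a <- r - r0
    na <- sqrt(sum(a^2)); nr <- sqrt(sum(r^2))
    if (nr == 0) stop("sensor at the origin: Sarvas formula singular")
    FF <- na * (nr * na + nr^2 - sum(r0 * r))
    if (abs(FF) < 1e-30 * nr^4)
      stop("sensor on the dipole ray: Sarvas formula degenerate")
    gF <- (na^2 / nr + sum(a * r) / na + 2 * na + 2 * nr) * r -
      (na + 2 * nr + sum(a * r) / na) * r0
    B[i, ] <- mu0 / (4 * pi * FF^2) * (FF * qxr0 - sum(qxr0 * r) * gF)
  }
  if (is.null(directions)) return(B)
  directions <- matrix(as.numeric(directions), ncol = 3)
  rowSums(B * directions)
}

#' EIT potential on concentric spheres (Neumann series)
#'
#' Potential of scalp current injection through spherical-cap electrodes with
#' uniform current density: per degree l >= 1, the radial transfer system is
#' solved with unit Neumann data at the outer boundary and scaled by the
#' Legendre coefficients of each cap; electrode fields superpose (net current
#' must vanish, which cancels the incompatible degree-0 data).
#'
#' @param model a `bem_sphere_model`.
#' @param electrode_dirs k x 3 matrix of electrode direction unit vectors (cap
#'   centers on the outer sphere).
#' @param currents length-k injected currents (amperes, summing to zero).
#' @param points n x 3 evaluation points (on or inside the outer sphere).
#' @param cap_angle electrode cap half-angle in radians.
#' @param reference "average" (default) or "none".
#' @return numeric vector of potentials (volts).
#' @export
eit_sphere_potential <- function(model, electrode_dirs, currents, points,
                                 cap_angle, reference = "average") {
  electrode_dirs <- matrix(as.numeric(electrode_dirs), ncol = 3)
  electrode_dirs <- electrode_dirs / sqrt(rowSums(electrode_dirs^2))
  currents <- as.numeric(currents)
  stopifnot(nrow(electrode_dirs) == length(currents))
  if (abs(sum(currents)) > 1e-12 * max(sum(abs(currents)), 1e-300))
    stop("injected currents must sum to zero")
  points <- matrix(as.numeric(points), ncol = 3)
  if (all(currents == 0)) {
    V <- rep(0, nrow(points))
    return(V)
  }
  rhoN <- model$radii[length(model$radii)]
  r <- sqrt(rowSums(points^2))
  lay <- sphere_layer_of(model, r)
  xhat <- points / pmax(r, 1e-300)
  c0 <- cos(cap_angle)
  dens <- currents / (2 * pi * rhoN^2 * (1 - c0)) # A / m^2 on each cap
  rho <- model$radii; rho0 <- c(rho[1], rho)
  # Legendre coefficients of the cap indicator need P_{l-1} - P_{l+1} at c0
  legc <- legendre_table(c0, model$L + 1)$P[1, ]
  sols <- lapply(seq_len(model$L), function(l) radial_solution(model, l, 0))
  V <- rep(0, nrow(points))
  for (k in seq_along(currents)) {
    if (currents[k] == 0) next
    cosg <- pmin(1, pmax(-1, as.numeric(xhat %*% electrode_dirs[k, ])))
    leg <- legendre_table(cosg, model$L)
    for (l in seq_len(model$L)) {
      jl <- dens[k] * (legc[l] - legc[l + 2]) / 2
      if (jl == 0) next
      sol <- sols[[l]]
      Rl <- numeric(nrow(points))
      for (i in unique(lay)) {
        sel <- lay == i
        A <- sol$uN[sol$idx$A[i]]
        B <- if (i >= 2) sol$uN[sol$idx$B[i]] else 0
        Rl[sel] <- A * (r[sel] / rho[i])^l +
          (if (i >= 2) B * (rho0[i] / r[sel])^(l + 1) else 0)
      }
      V <- V + jl * Rl * leg$P[, l + 1]
    }
  }
  if (reference == "average") V <- V - mean(V)
  V
}
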