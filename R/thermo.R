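# Material and packing properties: surface tension by the Kirkwood-Buff and
# stress-profile routes, coexistence-density / critical-temperature fits,
# slab coexistence densities, single-chain excluded volume, overlap
# concentration and effective packing density.

#' Convert an interfacial-tension value to mN/m
#'
#' Single audited conversion used by both surface-tension routes:
#' 1 kcal mol^-1 A^-2 = 694.77 mN/m.
#'
#' @param gamma_kcal Value in kcal/mol/A^2.
#' @return Value in mN/m.
#' @export
tension_to_mN_per_m <- function(gamma_kcal) gamma_kcal * .kcalA2_to_mNm

#' Surface tension from the pressure tensor (Kirkwood-Buff)
#'
#' `gamma = (L_z / 2) * (<P_zz> - (<P_xx> + <P_yy>) / 2)`, the mechanical
#' route for a slab with its normal along z; the factor 1/2 accounts for the
#' two interfaces. A stable slab yields gamma >= 0 with pressures in
#' kcal/mol/A^3.
#'
#' @param pressure_tensors A 3 x 3 matrix or list of 3 x 3 matrices
#'   (time series) in kcal/mol/A^3.
#' @param L_z Box length along the slab normal (A).
#' @return Surface tension in mN/m.
#' @export
surface_tension_kb <- function(pressure_tensors, L_z) {
  if (is.matrix(pressure_tensors)) pressure_tensors <- list(pressure_tensors)
  stopifnot(length(pressure_tensors) >= 1, L_z > 0)
  P <- Reduce(`+`, pressure_tensors) / length(pressure_tensors)
  gamma <- L_z / 2 * (P[3, 3] - (P[1, 1] + P[2, 2]) / 2)
  tension_to_mN_per_m(gamma)
}

#' Stress profile container
#'
#' @param z Bin centers along the slab normal (A), equally spaced.
#' @param sigma_N Normal stress P_zz(z) (kcal/mol/A^3).
#' @param sigma_T Tangential stress (P_xx + P_yy)/2 (z) (kcal/mol/A^3).
#' @return Object of class `stress_profile`.
#' @export
stress_profile <- function(z, sigma_N, sigma_T) {
  stopifnot(length(z) == length(sigma_N), length(z) == length(sigma_T),
            length(z) >= 2)
  dz <- diff(z)
  if (max(abs(dz - dz[1])) > 1e-8 * abs(dz[1])) stop("z bins must be equally spaced")
  structure(list(z = z, sigma_N = sigma_N, sigma_T = sigma_T, dz = dz[1]),
            class = "stress_profile")
}

#' Surface tension from the interfacial stress profile
#'
#' Integrates the stress anisotropy `sigma_N(z) - sigma_T(z)` over two
#' interface windows of equal thickness `w` centered on the left and right
#' interfaces, and averages the two window integrals (each interface carries
#' one gamma). Agrees with [surface_tension_kb()] when all anisotropy lies
#' inside the windows.
#'
#' @param profile A [stress_profile()].
#' @param z_L,z_R Centers of the left and right interface windows (A).
#' @param w Window thickness (A).
#' @return Surface tension in mN/m.
#' @export
surface_tension_profile <- function(profile, z_L, z_R, w) {
  stopifnot(inherits(profile, "stress_profile"), w > 0)
  zmin <- min(profile$z) - profile$dz / 2
  zmax <- max(profile$z) + profile$dz / 2
  if (z_L + w / 2 > z_R - w / 2) stop("interface windows overlap")
  if (z_L - w / 2 < zmin || z_R + w / 2 > zmax) stop("windows exceed the profiled region")
  anis <- profile$sigma_N - profile$sigma_T
  win_int <- function(zc) {
    inside <- profile$z >= zc - w / 2 & profile$z <= zc + w / 2
    sum(anis[inside]) * profile$dz
  }
  tension_to_mN_per_m((win_int(z_L) + win_int(z_R)) / 2)
}

#' Fit coexistence densities: critical temperature and density
#'
#' Joint least squares of the law of coexisting densities,
#' `rho_d - rho_l = A (1 - T/T_c)^beta`, and the law of rectilinear
#' diameters, `(rho_d + rho_l)/2 = rho_c + s (T_c - T)`, sharing T_c.
#' beta defaults to the 3-D Ising exponent 0.325.
#'
#' @param T Temperatures (K), >= 3 values, all below the critical point.
#' @param rho_dense,rho_dilute Coexisting densities (g/cm^3), elementwise
#'   `rho_dense > rho_dilute`.
#' @param beta Critical exponent (fixed during the fit).
#' @return Object of class `coexistence_fit` with `T_c`, `rho_c`, `A`, `s`,
#'   `beta` and the input data.
#' @export
fit_coexistence <- function(T, rho_dense, rho_dilute, beta = 0.325) {
  stopifnot(length(T) >= 3, length(rho_dense) == length(T),
            length(rho_dilute) == length(T))
  if (any(rho_dense <= rho_dilute)) {
    stop("every temperature must have rho_dense > rho_dilute")
  }
  diffs <- rho_dense - rho_dilute
  mids <- (rho_dense + rho_dilute) / 2
  Tmax <- max(T)
  # start: extrapolate the difference law linearly in T^(1/beta) space
  start <- c(A = max(diffs), Tc = Tmax * 1.05, rhoc = mids[which.max(T)], s = 0)
  resid_fun <- function(p) {
    tc <- p[2]
    red <- pmax(1 - T / tc, 0)
    c(diffs - p[1] * red^beta, mids - (p[3] + p[4] * (tc - T)))
  }
  res <- minpack.lm::nls.lm(par = start, fn = resid_fun,
                            lower = c(1e-8, Tmax + 1e-6, 0, -Inf),
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  if (res$info == 0 || !all(is.finite(res$par))) {
    stop("coexistence fit failed to converge")
  }
  p <- res$par
  if (p[2] <= Tmax) stop("coexistence fit failed: fitted T_c below max input T")
  structure(list(T_c = unname(p[2]), rho_c = unname(p[3]), A = unname(p[1]),
                 s = unname(p[4]), beta = beta,
                 data = data.frame(T = T, rho_dense = rho_dense,
                                   rho_dilute = rho_dilute)),
            class = "coexistence_fit")
}

#' @export
print.coexistence_fit <- function(x, ...) {
  cat(sprintf("<coexistence_fit> T_c = %.2f K, rho_c = %.4f g/cm^3 (A = %.4f, s = %.3g, beta = %.3f)\n",
              x$T_c, x$rho_c, x$A, x$s, x$beta))
  invisible(x)
}

#' Coexisting densities from a slab trajectory
#'
#' Averages the z mass-density profile over frames, fits the two interfaces
#' with sigmoids on the folded |z - z_com| axis, and reports the plateau
#' means of the dense interior and dilute exterior, excluding the fitted
#' interfacial windows.
#'
#' @param traj A [condnet_traj] of slab configurations (normal along z).
#' @param bin_width z-bin width (A), default 5.
#' @param model Energy model for masses.
#' @return List with `rho_dense`, `rho_dilute` (g/cm^3), the fitted interface
#'   half-thickness and the z-profile used.
#' @export
slab_coexistence_densities <- function(traj, bin_width = 5, model = mpipi_model()) {
  if (inherits(traj, "condnet_config")) traj <- trajectory(list(traj))
  box <- traj$frames[[1]]$box
  edges <- seq(0, box[3], by = bin_width)
  if (edges[length(edges)] < box[3]) edges <- c(edges, box[3])
  vol <- prod(box[1:2]) * diff(edges)
  dens <- matrix(0, length(traj$frames), length(vol))
  for (f in seq_along(traj$frames)) {
    conf <- traj$frames[[f]]
    mass <- model$params[conf$type, "mass"]
    z <- conf$x[, 3] %% box[3]
    bin <- findInterval(z, edges, rightmost.closed = TRUE)
    msum <- numeric(length(vol))
    acc <- tapply(mass, bin, sum)
    msum[as.integer(names(acc))] <- acc
    dens[f, ] <- msum / vol * .amu_per_A3_to_gcm3
  }
  zmid <- (edges[-1] + edges[-length(edges)]) / 2
  rho <- colMeans(dens)
  # fold about the mass-weighted slab center and reuse the radial sigmoid fit
  zc <- sum(zmid * rho) / sum(rho)
  prof <- structure(list(edges = edges, r = abs(zmid - zc), density = rho,
                         bin_width = bin_width, shell_vol = NULL,
                         n_frames = length(traj$frames),
                         fit = NULL), class = "condensate_profile")
  ord <- order(prof$r)
  prof$r <- prof$r[ord]; prof$density <- prof$density[ord]
  fitted <- tryCatch(fit_interface(prof),
                     error = function(e) stop("no plateau separation: ",
                                              conditionMessage(e)))
  ft <- fitted$fit
  dense_mask <- prof$r < ft$r95
  dil_mask <- prof$r > ft$r05
  if (!any(dense_mask)) stop("no dense plateau bins inside the interface")
  rho_dense <- mean(prof$density[dense_mask])
  rho_dilute <- if (any(dil_mask)) mean(prof$density[dil_mask]) else 0
  list(rho_dense = rho_dense, rho_dilute = rho_dilute, fit = ft,
       z = zmid, density = rho)
}

# Volume of the lens-shaped intersection of spheres with radii r1, r2 at
# center distance d, clamped to the smaller sphere when engulfed.
sphere_overlap_volume <- function(r1, r2, d) {
  stopifnot(r1 > 0, r2 > 0, d >= 0)
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(4 / 3 * pi * min(r1, r2)^3)
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
}

#' Single-chain excluded volume
#'
#' Per conformation sample, sums the spherical monomer volumes
#' `(4/3) pi sigma_i^3` (sigma_i = monomer radius) and subtracts the
#' sphere-sphere lens intersection for each bonded pair (i, i+1) at its
#' sampled separation; the lens is clamped to the smaller sphere's volume
#' when one sphere is engulfed. Returns the mean over samples with its
#' standard error.
#'
#' @param radii Monomer radii (A): one vector per sample or a single vector
#'   reused for all samples.
#' @param bond_distances List (one element per sample) of the N-1 bonded
#'   center-center distances (A), or a single vector.
#' @return List with `V_ex` (A^3), `se` and per-sample values.
#' @export
excluded_volume <- function(radii, bond_distances) {
  if (!is.list(bond_distances)) bond_distances <- list(bond_distances)
  if (!is.list(radii)) radii <- rep(list(radii), length(bond_distances))
  stopifnot(length(radii) == length(bond_distances))
  vals <- mapply(function(rr, dd) {
    stopifnot(all(rr > 0))
    n <- length(rr)
    if (length(dd) != max(n - 1, 0)) stop("need N-1 bond distances for N monomers")
    v <- sum(4 / 3 * pi * rr^3)
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        v <- v - sphere_overlap_volume(rr[i], rr[i + 1], dd[i])
      }
    }
    v
  }, radii, bond_distances)
  list(V_ex = mean(vals),
       se = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else NA_real_,
       samples = vals)
}

#' Excluded volume of a chain's conformations in a trajectory
#'
#' Convenience wrapper: takes each frame's bonded bead distances for one
#' chain and the parameter-table bead diameters (radius = sigma / 2).
#'
#' @param traj A [condnet_traj].
#' @param chain_id Chain id.
#' @param model Energy model supplying bead diameters.
#' @return As [excluded_volume()].
#' @export
chain_excluded_volume <- function(traj, chain_id, model = mpipi_model()) {
  conf1 <- traj$frames[[1]]
  idx <- which(conf1$chain == chain_id)
  idx <- idx[order(conf1$bead[idx])]
  radii <- model$params[conf1$type[idx], "sigma"] / 2
  dlist <- lapply(traj$frames, function(conf) {
    xc <- unwrap_chain(conf$x[idx, , drop = FALSE], conf$box)
    sqrt(rowSums((xc[-1, , drop = FALSE] - xc[-nrow(xc), , drop = FALSE])^2))
  })
  excluded_volume(radii, dlist)
}

#' Dense-phase monomer number density
#'
#' Per sampled frame, counts beads inside a sphere of the given radius
#' centered on the dense-phase center of mass and divides by the sphere
#' volume; averages across frames. The radius is conventionally the fitted
#' interface center r0 from [fit_interface()].
#'
#' @param traj A [condnet_traj].
#' @param radius Sphere radius (A), must not exceed half the box.
#' @param model Energy model for masses (center-of-mass weighting).
#' @return List with `rho_n` (A^-3), `se`, per-frame values.
#' @export
dense_phase_number_density <- function(traj, radius, model = mpipi_model()) {
  if (inherits(traj, "condnet_config")) traj <- trajectory(list(traj))
  box <- traj$frames[[1]]$box
  if (radius > min(box) / 2) stop("sphere radius exceeds half the box")
  vol <- 4 / 3 * pi * radius^3
  vals <- vapply(traj$frames, function(conf) {
    ctr <- dense_phase_com(conf, model)
    r <- sqrt(rowSums((conf$x - matrix(ctr, nrow(conf$x), 3, byrow = TRUE))^2))
    sum(r <= radius) / vol
  }, numeric(1))
  list(rho_n = mean(vals),
       se = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else NA_real_,
       samples = vals)
}

#' Effective packing density
#'
#' Overlap concentration `c* = N / V_ex` (monomer number density inside the
#' excluded volume of one dilute chain) and relative packing
#' `phi_rel = rho_n / c*`. `phi_rel < 1` is dilute-like, ~1 the overlap
#' onset, > 1 semi-dilute/concentrated.
#'
#' @param rho_n Dense-phase monomer number density (A^-3).
#' @param V_ex Single-chain excluded volume (A^3).
#' @param N Monomers per chain.
#' @return Object of class `packing_density` with `rho_n`, `V_ex`, `c_star`,
#'   `phi_rel` and a `regime` label.
#' @export
packing_density <- function(rho_n, V_ex, N) {
  stopifnot(rho_n >= 0, V_ex > 0, N >= 1)
  c_star <- N / V_ex
  phi <- rho_n / c_star
  regime <- if (phi < 0.95) "dilute-like" else if (phi <= 1.05) "overlap onset"
            else "semi-dilute/concentrated"
  structure(list(rho_n = rho_n, V_ex = V_ex, c_star = c_star,
                 phi_rel = phi, regime = regime),
            class = "packing_density")
}

#' @export
print.packing_density <- function(x, ...) {
  cat(sprintf("<packing_density> rho_n = %.3e A^-3, c* = %.3e A^-3, phi_rel = %.3f (%s)\n",
              x$rho_n, x$c_star, x$phi_rel, x$regime))
  invisible(x)
}
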