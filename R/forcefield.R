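# Mpipi-style residue-level coarse-grained potential:
#   E = E_bond + E_elec + E_pair
# with harmonic bonds, Debye-Hueckel screened Coulomb electrostatics and
# Wang-Frenkel short-range pair interactions.

# Boltzmann constant, kcal mol^-1 K^-1.
.kB <- 0.0019872041
# Coulomb constant e^2/(4 pi eps0), kcal mol^-1 Angstrom e^-2.
.coulomb_k <- 332.0637
# kcal mol^-1 A^-2 -> mN/m (surface tension unit conversion).
.kcalA2_to_mNm <- 4184 / 6.02214076e23 * 1e20 * 1e3
# Acceleration conversion: (kcal/mol/A)/amu -> A/fs^2.
.accel_conv <- 4.184e-4

#' Thermal energy
#'
#' @param T Temperature in kelvin.
#' @return `k_B * T` in kcal/mol (0.596 kcal/mol at 300 K).
#' @examples
#' thermal_energy(300)
#' @export
thermal_energy <- function(T) {
  stopifnot(all(T > 0))
  .kB * T
}

#' Load an energy model
#'
#' Builds the parameter set of the coarse-grained potential: a per-residue
#' table (mass, charge, bead diameter sigma, Wang-Frenkel well depth eps and
#' exponents mu, nu) plus the fixed constants — harmonic bond constant
#' k = 19.2 kcal mol^-1 A^-2 with equilibrium length r0 = 3.81 A, relative
#' permittivity 80, Debye screening length 7.95 A, Coulomb cutoff 35 A.
#'
#' Pair parameters follow combining rules: `sigma_ij = (sigma_i + sigma_j)/2`,
#' `eps_ij = sqrt(eps_i * eps_j)`, cutoff `R_c = 3 * sigma_ij`. The packaged
#' default table is a synthetic Mpipi-like set (see the file
#' `mpipi_like_params_synthetic.tsv` and the methods vignette): standard
#' residue masses and charges, common coarse-grained bead diameters, and
#' interaction strengths anchored so the Y-Y well depth is exactly
#' 0.42 kcal/mol. Any table with the same columns can be supplied instead.
#'
#' @param param_file Optional path to a TSV with columns
#'   `residue, mass, charge, sigma, eps, mu, nu`.
#' @param temperature Reference temperature in K (default 300).
#' @return An object of class `energy_model`.
#' @export
mpipi_model <- function(param_file = NULL, temperature = 300) {
  if (is.null(param_file)) {
    param_file <- system.file("extdata", "mpipi_like_params_synthetic.tsv",
                              package = "condnet", mustWork = TRUE)
  }
  tab <- utils::read.delim(param_file, stringsAsFactors = FALSE)
  need <- c("residue", "mass", "charge", "sigma", "eps", "mu", "nu")
  if (!all(need %in% names(tab))) {
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$residue)) stop("duplicate residue rows in parameter table")
  stopifnot(all(tab$mass > 0), all(tab$sigma > 0), all(tab$eps >= 0))
  rownames(tab) <- tab$residue
  structure(list(
    params = tab,
    k_bond = 19.2,       # kcal mol^-1 A^-2
    r0_bond = 3.81,      # A
    eps_r = 80,
    debye_length = 7.95, # A
    coulomb_cutoff = 35, # A
    rc_factor = 3,       # R_c = rc_factor * sigma_ij
    temperature = temperature
  ), class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> Mpipi-style coarse-grained potential\n")
  cat(sprintf("  %d residue types; k_bond = %.1f kcal/mol/A^2, r0 = %.2f A\n",
              nrow(x$params), x$k_bond, x$r0_bond))
  cat(sprintf("  Debye length %.2f A, Coulomb cutoff %.0f A, eps_r = %.0f\n",
              x$debye_length, x$coulomb_cutoff, x$eps_r))
  invisible(x)
}

.check_types <- function(model, types) {
  bad <- setdiff(unique(types), model$params$residue)
  if (length(bad) > 0L) {
    stop("residue type(s) missing from parameter table: ",
         paste(bad, collapse = ", "))
  }
}

#' Harmonic bond energy
#'
#' `E(r) = k (r - r0)^2` with the engine convention of no 1/2 factor, matching
#' the printed unit of k (kcal mol^-1 A^-2). A 1/2-factor reading of the same
#' constant would halve all bond energies.
#'
#' @param r Bond length(s), A.
#' @param model An [mpipi_model()].
#' @return Energy in kcal/mol.
#' @export
bond_energy <- function(r, model = mpipi_model()) {
  stopifnot(all(r >= 0))
  model$k_bond * (r - model$r0_bond)^2
}

# Generalized Wang-Frenkel potential, vectorized over r (and over the
# parameter vectors, recycled elementwise). Zero at and beyond rc; the well
# depth equals -eps by construction of alpha.
wang_frenkel <- function(r, eps, sigma, mu = 1, nu = 1, rc = 3 * sigma) {
  ratio <- (rc / sigma)^(2 * mu)
  alpha <- 2 * nu * ratio * ((1 + 2 * nu) / (2 * nu * (ratio - 1)))^(2 * nu + 1)
  inside <- r < rc
  e <- numeric(length(r))
  if (any(inside)) {
    ri <- r[inside]
    f <- (rec(sigma, inside) / ri)^(2 * rec(mu, inside)) - 1
    g <- (rec(rc, inside) / ri)^(2 * rec(mu, inside)) - 1
    e[inside] <- rec(eps, inside) * rec(alpha, inside) * f * g^(2 * rec(nu, inside))
  }
  e
}

# Recycle helper: subset a parameter that is either scalar or parallel to r.
rec <- function(p, idx) if (length(p) == 1L) p else p[idx]

# d/dr of the Wang-Frenkel energy (same vectorization rules).
wang_frenkel_deriv <- function(r, eps, sigma, mu = 1, nu = 1, rc = 3 * sigma) {
  ratio <- (rc / sigma)^(2 * mu)
  alpha <- 2 * nu * ratio * ((1 + 2 * nu) / (2 * nu * (ratio - 1)))^(2 * nu + 1)
  inside <- r < rc
  d <- numeric(length(r))
  if (any(inside)) {
    ri <- r[inside]
    epsi <- rec(eps, inside); sgi <- rec(sigma, inside)
    mui <- rec(mu, inside); nui <- rec(nu, inside)
    rci <- rec(rc, inside); ali <- rec(alpha, inside)
    f <- (sgi / ri)^(2 * mui) - 1
    g <- (rci / ri)^(2 * mui) - 1
    fp <- -2 * mui * sgi^(2 * mui) * ri^(-2 * mui - 1)
    gp <- -2 * mui * rci^(2 * mui) * ri^(-2 * mui - 1)
    d[inside] <- epsi * ali * (fp * g^(2 * nui) + f * 2 * nui * g^(2 * nui - 1) * gp)
  }
  d
}

# Screened-Coulomb (Debye-Hueckel) energy, zero beyond the Coulomb cutoff.
debye_huckel <- function(r, q1, q2, model) {
  e <- numeric(length(r))
  inside <- r < model$coulomb_cutoff
  if (any(inside)) {
    ri <- r[inside]
    e[inside] <- .coulomb_k * rec(q1, inside) * rec(q2, inside) /
      (model$eps_r * ri) * exp(-ri / model$debye_length)
  }
  e
}

debye_huckel_deriv <- function(r, q1, q2, model) {
  inside <- r < model$coulomb_cutoff
  d <- numeric(length(r))
  if (any(inside)) {
    ri <- r[inside]
    e <- .coulomb_k * rec(q1, inside) * rec(q2, inside) /
      (model$eps_r * ri) * exp(-ri / model$debye_length)
    d[inside] <- -e * (1 / ri + 1 / model$debye_length)
  }
  d
}

# Pairwise combined parameters for two type vectors; returns list of matrices
# (length(ti) x length(tj)) for eps, sigma, q products etc.
.pair_param_mats <- function(model, ti, tj) {
  p <- model$params
  list(
    eps = sqrt(outer(p[ti, "eps"], p[tj, "eps"])),
    sigma = outer(p[ti, "sigma"], p[tj, "sigma"], function(a, b) (a + b) / 2),
    mu = outer(p[ti, "mu"], p[tj, "mu"], function(a, b) (a + b) / 2),
    nu = outer(p[ti, "nu"], p[tj, "nu"], function(a, b) (a + b) / 2),
    qq = outer(p[ti, "charge"], p[tj, "charge"])
  )
}

#' Non-bonded pair energy between two bead types
#'
#' Wang-Frenkel short-range term (zero at and beyond `R_c = 3 sigma_ij`) plus
#' the screened-Coulomb term for charged pairs (zero beyond the 35 A Coulomb
#' cutoff).
#'
#' @param type_i,type_j One-letter residue codes.
#' @param r Separation(s), A.
#' @param model An [mpipi_model()].
#' @return Energy in kcal/mol, vectorized over `r`.
#' @examples
#' m <- mpipi_model()
#' optimize(function(r) pair_energy("Y", "Y", r, m), c(4, 15))$objective
#' @export
pair_energy <- function(type_i, type_j, r, model = mpipi_model()) {
  stopifnot(all(r > 0))
  .check_types(model, c(type_i, type_j))
  p <- model$params
  eps <- sqrt(p[type_i, "eps"] * p[type_j, "eps"])
  sigma <- (p[type_i, "sigma"] + p[type_j, "sigma"]) / 2
  mu <- (p[type_i, "mu"] + p[type_j, "mu"]) / 2
  nu <- (p[type_i, "nu"] + p[type_j, "nu"]) / 2
  e <- wang_frenkel(r, eps, sigma, mu, nu, model$rc_factor * sigma)
  q1 <- p[type_i, "charge"]; q2 <- p[type_j, "charge"]
  if (q1 != 0 && q2 != 0) e <- e + debye_huckel(r, q1, q2, model)
  e
}

#' Radial force for a non-bonded pair
#'
#' Returns `-dE/dr` of [pair_energy()]; positive values are repulsive.
#'
#' @inheritParams pair_energy
#' @return Force in kcal/mol/A.
#' @export
pair_force <- function(type_i, type_j, r, model = mpipi_model()) {
  stopifnot(all(r > 0))
  .check_types(model, c(type_i, type_j))
  p <- model$params
  eps <- sqrt(p[type_i, "eps"] * p[type_j, "eps"])
  sigma <- (p[type_i, "sigma"] + p[type_j, "sigma"]) / 2
  mu <- (p[type_i, "mu"] + p[type_j, "mu"]) / 2
  nu <- (p[type_i, "nu"] + p[type_j, "nu"]) / 2
  d <- wang_frenkel_deriv(r, eps, sigma, mu, nu, model$rc_factor * sigma)
  q1 <- p[type_i, "charge"]; q2 <- p[type_j, "charge"]
  if (q1 != 0 && q2 != 0) d <- d + debye_huckel_deriv(r, q1, q2, model)
  -d
}

# Minimum-image component-wise displacement matrix helpers live in trajio.R.

#' Interaction energy between two chains
#'
#' Sum of all inter-chain non-bonded bead-pair energies (Wang-Frenkel plus
#' screened Coulomb) under the minimum-image convention. This is the quantity
#' thresholded against `-m k_B T` when building interaction graphs.
#'
#' @param conf A [configuration()].
#' @param chain_a,chain_b Distinct chain ids present in `conf`.
#' @param model An [mpipi_model()].
#' @return Energy in kcal/mol, symmetric in the two chains.
#' @export
chain_pair_energy <- function(conf, chain_a, chain_b, model = mpipi_model()) {
  if (identical(chain_a, chain_b)) {
    stop("chain_a and chain_b must differ (intramolecular energy not supported)")
  }
  ia <- which(conf$chain == chain_a)
  ib <- which(conf$chain == chain_b)
  if (length(ia) == 0L || length(ib) == 0L) stop("chain id not present in configuration")
  .check_types(model, conf$type[c(ia, ib)])
  xa <- conf$x[ia, , drop = FALSE]
  xb <- conf$x[ib, , drop = FALSE]
  d2 <- matrix(0, length(ia), length(ib))
  for (k in 1:3) {
    dk <- outer(xa[, k], xb[, k], "-")
    dk <- dk - conf$box[k] * round(dk / conf$box[k])
    d2 <- d2 + dk * dk
  }
  r <- sqrt(d2)
  pm <- .pair_param_mats(model, conf$type[ia], conf$type[ib])
  e <- wang_frenkel(as.vector(r), as.vector(pm$eps), as.vector(pm$sigma),
                    as.vector(pm$mu), as.vector(pm$nu),
                    model$rc_factor * as.vector(pm$sigma))
  if (any(pm$qq != 0)) {
    e <- e + debye_huckel(as.vector(r), as.vector(pm$qq), 1, model)
  }
  sum(e)
}

# All forces on all beads of a configuration: harmonic bonds along each chain
# plus non-bonded pair terms (bonded 1-2 pairs excluded from the non-bonded
# sum) under minimum image. Returns an n x 3 matrix in kcal/mol/A.
compute_forces <- function(conf, model) {
  n <- nrow(conf$x)
  .check_types(model, conf$type)
  p <- model$params
  eps_i <- p[conf$type, "eps"]; sig_i <- p[conf$type, "sigma"]
  mu_i <- p[conf$type, "mu"]; nu_i <- p[conf$type, "nu"]
  q_i <- p[conf$type, "charge"]
  f <- matrix(0, n, 3)
  # pair list: all i<j
  pr <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  bonded <- conf$chain[i] == conf$chain[j] & abs(conf$bead[i] - conf$bead[j]) == 1L
  dx <- conf$x[i, , drop = FALSE] - conf$x[j, , drop = FALSE]
  for (k in 1:3) dx[, k] <- dx[, k] - conf$box[k] * round(dx[, k] / conf$box[k])
  r <- sqrt(rowSums(dx * dx))
  r <- pmax(r, 1e-9)
  dEdr <- numeric(length(r))
  nb <- !bonded
  if (any(nb)) {
    eps <- sqrt(eps_i[i[nb]] * eps_i[j[nb]])
    sigma <- (sig_i[i[nb]] + sig_i[j[nb]]) / 2
    mu <- (mu_i[i[nb]] + mu_i[j[nb]]) / 2
    nu <- (nu_i[i[nb]] + nu_i[j[nb]]) / 2
    dEdr[nb] <- wang_frenkel_deriv(r[nb], eps, sigma, mu, nu,
                                   model$rc_factor * sigma) +
      debye_huckel_deriv(r[nb], q_i[i[nb]] * q_i[j[nb]], 1, model)
  }
  if (any(bonded)) {
    dEdr[bonded] <- 2 * model$k_bond * (r[bonded] - model$r0_bond)
  }
  # force on i along +dx (dx = x_i - x_j): F_i = -dE/dr * dx/r
  fac <- -dEdr / r
  fv <- dx * fac
  for (k in 1:3) {
    acc_i <- tapply(fv[, k], i, sum)
    acc_j <- tapply(fv[, k], j, sum)
    f[as.integer(names(acc_i)), k] <- f[as.integer(names(acc_i)), k] + acc_i
    f[as.integer(names(acc_j)), k] <- f[as.integer(names(acc_j)), k] - acc_j
  }
  list(forces = f, pairs = cbind(i, j), dx = dx, r = r, dEdr = dEdr)
}

#' Per-bead virial stress tensors
#'
#' Splits every pairwise (non-bonded and bonded) force contribution
#' symmetrically between the two partners:
#' `W_i[a,b] = m_i v_a v_b + 1/2 * sum_j dx[a] * F_ij[b]`, in
#' pressure x volume units (kcal/mol). Summing over beads and dividing by the
#' box volume reproduces the global virial pressure tensor.
#'
#' @param conf A [configuration()] (velocities optional; without them the
#'   kinetic term is zero).
#' @param model An [mpipi_model()].
#' @return A list with `stress` (n x 3 x 3 array, kcal/mol) and
#'   `pressure_tensor` (3 x 3, kcal/mol/A^3).
#' @export
per_bead_virial_stress <- function(conf, model = mpipi_model()) {
  n <- nrow(conf$x)
  fr <- compute_forces(conf, model)
  W <- array(0, dim = c(n, 3, 3))
  fac <- -fr$dEdr / fr$r          # scalar force magnitude along dx
  i <- fr$pairs[, 1]; j <- fr$pairs[, 2]
  for (a in 1:3) for (b in 1:3) {
    # F_ij (force on i from j) component b; dx = x_i - x_j
    w <- fr$dx[, a] * (fac * fr$dx[, b])
    acc_i <- tapply(w / 2, i, sum)
    acc_j <- tapply(w / 2, j, sum)
    W[as.integer(names(acc_i)), a, b] <- W[as.integer(names(acc_i)), a, b] + acc_i
    W[as.integer(names(acc_j)), a, b] <- W[as.integer(names(acc_j)), a, b] + acc_j
  }
  if (!is.null(conf$vel)) {
    mass <- model$params[conf$type, "mass"]
    for (a in 1:3) for (b in 1:3) {
      W[, a, b] <- W[, a, b] + mass * conf$vel[, a] * conf$vel[, b] / .accel_conv
    }
  }
  P <- apply(W, c(2, 3), sum) / prod(conf$box)
  list(stress = W, pressure_tensor = P)
}
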