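model <- mpipi_model()

test_that("Kirkwood-Buff surface tension follows the formula and its scalings", {
  expect_equal(surface_tension_kb(diag(c(2, 2, 2)), 100), 0)
  delta <- 3e-4  # kcal/mol/A^3 anisotropy
  P <- diag(c(0, 0, delta))
  g1 <- surface_tension_kb(P, 100)
  expect_equal(g1, tension_to_mN_per_m(100 * delta / 2))
  # doubling L_z doubles gamma at fixed anisotropy
  expect_equal(surface_tension_kb(P, 200), 2 * g1)
  # time series averaging
  expect_equal(surface_tension_kb(list(P, 3 * P), 100), 2 * g1)
})

test_that("stress-profile surface tension integrates window anisotropy", {
  z <- seq(0.5, 299.5, by = 1)
  sN <- rep(0, length(z)); sT <- rep(0, length(z))
  expect_equal(surface_tension_profile(stress_profile(z, sN, sT), 75, 225, 40), 0)
  # rectangular anisotropy pulse of height h and width d inside one window
  h <- 5e-4; d <- 10
  sN2 <- sN; sN2[z > 70 & z < 80] <- h
  g <- surface_tension_profile(stress_profile(z, sN2, sT), 75, 225, 40)
  expect_equal(g, tension_to_mN_per_m(h * d / 2), tolerance = 0.01)
  sp <- stress_profile(z, sN2, sT)
  expect_error(surface_tension_profile(sp, 100, 120, 40), "overlap")
  expect_error(surface_tension_profile(sp, 15, 225, 40), "exceed")
})

test_that("the stress-profile and Kirkwood-Buff routes agree on synthetic slabs", {
  # anisotropy confined to two interface windows
  Lz <- 300
  z <- seq(0.5, Lz - 0.5, by = 1)
  anis <- rep(0, length(z))
  gauss <- function(z0) 4e-4 * exp(-(z - z0)^2 / (2 * 4^2))
  anis <- gauss(100) + gauss(200)
  sN <- rep(1e-4, length(z))
  sT <- sN - anis
  g_prof <- surface_tension_profile(stress_profile(z, sN, sT), 100, 200, 50)
  P <- diag(c(mean(sT), mean(sT), mean(sN)))
  g_kb <- surface_tension_kb(P, Lz)
  expect_equal(g_prof, g_kb, tolerance = 0.02)
})

test_that("coexistence fits recover the critical point exactly on clean data", {
  Tc <- 400; A <- 0.9; rc <- 0.30; s <- 4e-4; beta <- 0.325
  T <- seq(280, 380, by = 20)
  dif <- A * (1 - T / Tc)^beta
  mid <- rc + s * (Tc - T)
  fit <- fit_coexistence(T, mid + dif / 2, mid - dif / 2, beta = beta)
  expect_equal(fit$T_c, Tc, tolerance = 1e-3)  # well within 0.1%
  expect_equal(fit$rho_c, rc, tolerance = 1e-4)
  expect_error(fit_coexistence(T, mid, mid), "rho_dense > rho_dilute")
})

test_that("coexistence fits stay within 2% under 1% multiplicative noise", {
  Tc <- 400; A <- 0.9; rc <- 0.30; s <- 4e-4; beta <- 0.325
  T <- seq(280, 380, by = 10)
  dif <- A * (1 - T / Tc)^beta
  mid <- rc + s * (Tc - T)
  tcs <- vapply(1:100, function(sd) {
    set.seed(sd)
    rd <- (mid + dif / 2) * (1 + rnorm(length(T), 0, 0.01))
    rl <- (mid - dif / 2) * (1 + rnorm(length(T), 0, 0.01))
    ok <- rd > rl
    fit_coexistence(T[ok], rd[ok], rl[ok], beta = beta)$T_c
  }, numeric(1))
  expect_lt(abs(mean(tcs) - Tc) / Tc, 0.02)
  expect_lt(stats::median(abs(tcs - Tc)) / Tc, 0.02)
})

test_that("excluded volume handles the analytic sphere limits", {
  r <- 2.8
  v1 <- excluded_volume(r, numeric(0))
  expect_equal(v1$V_ex, 4 / 3 * pi * r^3)
  # two bonded equal spheres beyond contact: no overlap subtracted
  v2 <- excluded_volume(c(r, r), 2 * r + 0.1)
  expect_equal(v2$V_ex, 2 * 4 / 3 * pi * r^3)
  # coincident spheres: engulfed, a single sphere volume remains
  v0 <- excluded_volume(c(r, r), 0)
  expect_equal(v0$V_ex, 4 / 3 * pi * r^3)
  expect_error(excluded_volume(c(-1, 2), 1))
  # monotone: shrinking a bond distance never increases V_ex
  ds <- seq(0, 2 * r, length.out = 10)
  vs <- vapply(ds, function(d) excluded_volume(c(r, r), d)$V_ex, numeric(1))
  expect_true(all(diff(vs) >= -1e-9))
})

test_that("excluded volume matches Monte-Carlo union volume within 0.5%", {
  # extended rod chain: non-bonded beads never overlap, so the bonded-lens
  # formula equals the exact union volume
  nb <- 8
  radii <- c(2.6, 3.2, 2.9, 3.1, 2.7, 3.0, 2.8, 3.3)
  centers <- cbind(seq_len(nb) * 3.81, 0, 0)
  d <- rep(3.81, nb - 1)
  v_pkg <- excluded_volume(radii, d)$V_ex
  v_mc <- mc_union_volume(centers, radii, n_pts = 2e6, seed = 2)
  expect_equal(v_pkg, v_mc, tolerance = 0.005)
})

test_that("dense-phase number density recovers a uniform droplet within 2%", {
  set.seed(41)
  n <- 6000; R <- 45
  r <- R * runif(n)^(1 / 3)
  dir <- matrix(rnorm(3 * n), n, 3); dir <- dir / sqrt(rowSums(dir^2))
  conf <- configuration(dir * r + 100, rep("G", n), seq_len(n), rep(200, 3))
  target <- n / (4 / 3 * pi * R^3)
  nd <- dense_phase_number_density(conf, 35, model)
  expect_equal(nd$rho_n, target, tolerance = 0.02)
  # brute-force count agreement
  ctr <- condnet:::dense_phase_com(conf, model)
  cnt <- sum(sqrt(rowSums((conf$x - matrix(ctr, n, 3, byrow = TRUE))^2)) <= 35)
  expect_equal(nd$rho_n, cnt / (4 / 3 * pi * 35^3))
  # empty sphere
  far <- configuration(matrix(c(10, 10, 10, 190, 190, 190), 2, 3, byrow = TRUE),
                       c("G", "G"), 1:2, rep(200, 3))
  expect_error(dense_phase_number_density(far, 150, model), "half the box")
})

test_that("packing density classifies the overlap regimes", {
  pk <- packing_density(0.002, 5000, 10)
  expect_equal(pk$c_star, 10 / 5000)
  expect_equal(pk$phi_rel, 1)
  expect_equal(packing_density(0, 5000, 10)$phi_rel, 0)
  expect_match(packing_density(0.004, 5000, 10)$regime, "semi-dilute")
  # closed loop: a droplet built at 1.1x its own chains' overlap density
  V_ex <- excluded_volume(rep(2.8, 10), rep(3.81, 9))$V_ex
  c_star <- 10 / V_ex
  pk2 <- packing_density(1.1 * c_star, V_ex, 10)
  expect_equal(pk2$phi_rel, 1.1, tolerance = 1e-12)
})

test_that("slab coexistence densities recover constructed phases", {
  set.seed(6)
  # beads uniformly dense inside |z-150|<50 plus sparse dilute background
  n_d <- 8000; n_l <- 150
  xd <- cbind(runif(n_d, 0, 100), runif(n_d, 0, 100), runif(n_d, 100, 200))
  xl <- cbind(runif(n_l, 0, 100), runif(n_l, 0, 100),
              c(runif(n_l / 2, 0, 95), runif(n_l / 2, 205, 300)))
  conf <- configuration(rbind(xd, xl), rep("G", n_d + n_l),
                        seq_len(n_d + n_l), c(100, 100, 300))
  res <- slab_coexistence_densities(conf, 5, model)
  rho_d_target <- n_d / (100 * 100 * 100) * model$params["G", "mass"] * 1.66053907
  expect_equal(res$rho_dense, rho_d_target, tolerance = 0.05)
  expect_lt(res$rho_dilute, 0.05 * res$rho_dense)
  # mass conservation across the profile
  binned <- sum(res$density) * 100 * 100 * 5 / 1.66053907
  expect_equal(binned, (n_d + n_l) * model$params["G", "mass"], tolerance = 1e-6)
})
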