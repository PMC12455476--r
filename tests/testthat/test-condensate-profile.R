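model <- mpipi_model()

test_that("radial profiles conserve mass and resolve a uniform sphere", {
  # uniform synthetic sphere of single beads
  set.seed(31)
  n <- 4000
  r <- 40 * runif(n)^(1 / 3)
  dir <- matrix(rnorm(3 * n), n, 3); dir <- dir / sqrt(rowSums(dir^2))
  x <- dir * r + 100
  conf <- configuration(x, rep("G", n), seq_len(n), rep(200, 3))
  prof <- radial_density_profile(conf, 5, model)
  inside <- prof$r < 32
  expect_lt(stats::sd(prof$density[inside]) / mean(prof$density[inside]), 0.2)
  expect_equal(mean(prof$density[prof$r > 50]), 0)
  # total binned mass equals total system mass
  shell_mass <- prof$density / 1.66053907 * prof$shell_vol
  expect_equal(sum(shell_mass), n * model$params["G", "mass"], tolerance = 1e-6)
  # single bead at the center: all mass in the first bin
  c1 <- configuration(matrix(100, 1, 3), "G", 1L, rep(200, 3))
  p1 <- radial_density_profile(c1, 5, model)
  expect_true(all(p1$density[-1] == 0))
  expect_gt(p1$density[1], 0)
  expect_error(radial_density_profile(trajectory(list())), "frames")
})

test_that("sigmoid interface fit recovers known parameters within 1%", {
  r <- seq(2.5, 147.5, by = 5)
  y <- 0.02 + (0.62 - 0.02) / (1 + exp((r - 70) / 4.5))
  prof <- structure(list(edges = seq(0, 150, 5), r = r, density = y,
                         bin_width = 5, shell_vol = NULL, n_frames = 1,
                         fit = NULL), class = "condensate_profile")
  fitted <- fit_interface(prof)
  expect_equal(fitted$fit$r0, 70, tolerance = 0.01)
  expect_equal(fitted$fit$w, 4.5, tolerance = 0.01)
  expect_equal(fitted$fit$rho_dense, 0.62, tolerance = 0.01)
  expect_lt(fitted$fit$r95, fitted$fit$r05)
  # fitted curve is higher at r95 than at r05
  expect_gt(condnet:::.sigmoid_eval(fitted$fit$r95, fitted$fit),
            condnet:::.sigmoid_eval(fitted$fit$r05, fitted$fit))
  # tanh family recovers the same interface location
  fitted_t <- fit_interface(prof, family = "tanh")
  expect_equal(fitted_t$fit$r0, 70, tolerance = 0.02)
})

test_that("a step profile collapses the interface bounds onto the step", {
  r <- seq(2.5, 147.5, by = 5)
  y <- ifelse(r < 60, 0.5, 0)
  prof <- structure(list(edges = seq(0, 150, 5), r = r, density = y,
                         bin_width = 5, shell_vol = NULL, n_frames = 1,
                         fit = NULL), class = "condensate_profile")
  fitted <- fit_interface(prof)
  expect_equal(fitted$fit$r0, 60, tolerance = 0.1)
  expect_lt(fitted$fit$r05 - fitted$fit$r95, 15)
})

test_that("flat profiles are rejected rather than silently fitted", {
  r <- seq(2.5, 97.5, by = 5)
  prof <- structure(list(edges = seq(0, 100, 5), r = r,
                         density = rep(0.3, length(r)), bin_width = 5,
                         shell_vol = NULL, n_frames = 1, fit = NULL),
                    class = "condensate_profile")
  expect_error(fit_interface(prof), "interface fit failed")
})

test_that("radial feature distributions recover planted placements", {
  # chains planted at known radii: 'hubs' at the center, 'clique members'
  # in a shell at the interface
  set.seed(7)
  nb <- 5
  com <- rbind(matrix(rnorm(3 * 4, 0, 2), 4, 3),            # 4 hub chains, r ~ 0
               60 * cbind(c(1, -1, 0, 0), c(0, 0, 1, -1), 0)) # 4 shell chains
  x <- NULL
  for (i in 1:8) x <- rbind(x, matrix(com[i, ] + 100, nb, 3, byrow = TRUE) +
                              cbind(seq(0, 4) * 0.1, 0, 0))
  conf <- configuration(x, rep("G", 8 * nb), rep(1:8, each = nb), rep(200, 3))
  # analytic profile: plateau to 60 then decay
  r <- seq(2.5, 97.5, 5)
  y <- 0.5 / (1 + exp((r - 60) / 3))
  prof <- structure(list(edges = seq(0, 100, 5), r = r, density = y,
                         bin_width = 5, shell_vol = NULL, n_frames = 1,
                         fit = NULL), class = "condensate_profile")
  prof <- fit_interface(prof)
  roles <- list(list(hubs = as.character(1:4), clique_members = as.character(5:8)))
  fd <- radial_feature_distribution(trajectory(list(conf)), roles, prof,
                                    model = model)
  expect_lt(stats::median(fd$hub_distances), 0.15)
  expect_gt(stats::median(fd$clique_distances), prof$fit$r95 / prof$fit$r05 - 0.1)
  expect_lt(stats::median(fd$clique_distances), 1.2)
  # histograms integrate to one
  bw <- diff(fd$breaks)[1]
  expect_equal(sum(fd$hub_density) * bw, 1, tolerance = 1e-9)
  expect_equal(sum(fd$clique_density) * bw, 1, tolerance = 1e-9)
})

test_that("role lifetimes are flagged-frame fractions", {
  roles <- lapply(1:200, function(f) list(
    hubs = if (f <= 20) "1" else "2",
    clique_members = c("3", "4")))
  tl <- role_timeline(roles, chain_ids = 1:4)
  lt <- role_lifetimes(tl)
  expect_equal(lt$hub_fraction[lt$chain == "1"], 0.10)
  expect_equal(lt$hub_fraction[lt$chain == "2"], 0.90)
  expect_equal(lt$clique_fraction[lt$chain == "3"], 1)
  expect_equal(lt$hub_fraction[lt$chain == "4"], 0)
})

test_that("persistent planted cliques outlive rapidly permuted hubs", {
  # synthetic timeline: clique membership fixed, hub identity re-drawn each
  # frame from a pool
  set.seed(11)
  pool <- as.character(1:12)
  cliq <- as.character(13:20)
  roles <- lapply(1:100, function(f) list(
    hubs = sample(pool, 3),
    clique_members = cliq))
  lt <- role_lifetimes(role_timeline(roles, chain_ids = 1:20))
  hub_fracs <- lt$hub_fraction[lt$chain %in% pool]
  cl_fracs <- lt$clique_fraction[lt$chain %in% cliq]
  # clique fractions stochastically dominate hub fractions
  expect_gt(min(cl_fracs), max(hub_fracs))
  expect_gt(stats::median(cl_fracs), stats::median(hub_fracs))
})

test_that("displacement averages the two center-of-mass legs", {
  # one chain moving at constant velocity, one stationary
  mk <- function(offset) {
    x <- rbind(c(0, 0, 0) + offset, c(3.81, 0, 0) + offset,
               c(50, 50, 50), c(53.81, 50, 50))
    configuration(x, rep("G", 4), c(1, 1, 2, 2), rep(200, 3),
                  time = offset[1] / 7)
  }
  traj <- trajectory(list(mk(c(0, 0, 0)), mk(c(7, 0, 0)), mk(c(14, 0, 0))))
  d <- displacement(traj, 2, model)
  expect_equal(d$dr[d$chain == "1"], 7)
  expect_equal(d$dr[d$chain == "2"], 0)
  # normalization by the contour length (n - 1) * 3.81
  expect_equal(d$dr_norm[d$chain == "1"], 7 / 3.81)
  expect_error(displacement(traj, 1, model), "interior")
  expect_error(displacement(traj, 3, model), "interior")
})

test_that("a 150-mer moving 5.677 A has normalized displacement 0.01", {
  nb <- 150
  base <- cbind(seq_len(nb) * 3.81, 0, 0)
  mk <- function(s) configuration(base + matrix(c(s, 0, 0), nb, 3, byrow = TRUE),
                                  rep("G", nb), rep(1L, nb), rep(2000, 3),
                                  time = s)
  traj <- trajectory(list(mk(0), mk(5.677), mk(2 * 5.677)))
  d <- displacement(traj, 2, model)
  expect_equal(d$dr, 5.677)
  expect_equal(d$dr_norm, 5.677 / (149 * 3.81))
  expect_equal(round(d$dr_norm, 2), 0.01)
})
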