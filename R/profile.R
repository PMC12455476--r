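# Spatial organization (radial density profiles, sigmoid interface fits,
# hub/clique radial distributions) and temporal organization (role lifetimes,
# single-molecule displacements) of simulated condensates.

.amu_per_A3_to_gcm3 <- 1.66053907  # amu/A^3 -> g/cm^3

# Mass-weighted center of mass of all beads; the droplet is assumed not to
# straddle the periodic boundary (the synthetic generators place it at the
# box center).
dense_phase_com <- function(conf, model = mpipi_model()) {
  mass <- model$params[conf$type, "mass"]
  colSums(conf$x * mass) / sum(mass)
}

#' Radial mass-density profile of a condensate
#'
#' For every frame, bead masses are binned by distance from the dense-phase
#' center of mass; shell densities (mass / shell volume, g/cm^3) are averaged
#' over frames.
#'
#' @param traj A [condnet_traj] or single [configuration()].
#' @param bin_width Radial bin width (A), default 5.
#' @param model Energy model supplying residue masses.
#' @param r_max Outer radius (A); default half the smallest box edge.
#' @return An object of class `condensate_profile` with bin edges/centers and
#'   mean density; interface fit fields are attached by [fit_interface()].
#' @export
radial_density_profile <- function(traj, bin_width = 5, model = mpipi_model(),
                                   r_max = NULL) {
  if (inherits(traj, "condnet_config")) traj <- trajectory(list(traj))
  if (length(traj$frames) == 0) stop("empty trajectory")
  box <- traj$frames[[1]]$box
  if (is.null(r_max)) r_max <- min(box) / 2
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  vol <- 4 / 3 * pi * diff(edges^3)  # shell volumes, A^3
  dens <- matrix(0, length(traj$frames), length(vol))
  for (f in seq_along(traj$frames)) {
    conf <- traj$frames[[f]]
    ctr <- dense_phase_com(conf, model)
    r <- sqrt(rowSums((conf$x - matrix(ctr, nrow(conf$x), 3, byrow = TRUE))^2))
    mass <- model$params[conf$type, "mass"]
    keep <- r <= r_max
    bin <- findInterval(r[keep], edges, rightmost.closed = TRUE)
    msum <- numeric(length(vol))
    acc <- tapply(mass[keep], bin, sum)
    msum[as.integer(names(acc))] <- acc
    dens[f, ] <- msum / vol * .amu_per_A3_to_gcm3
  }
  structure(list(edges = edges, r = (edges[-1] + edges[-length(edges)]) / 2,
                 density = colMeans(dens), bin_width = bin_width,
                 shell_vol = vol,
                 n_frames = length(traj$frames), fit = NULL),
            class = "condensate_profile")
}

#' @export
print.condensate_profile <- function(x, ...) {
  cat(sprintf("<condensate_profile> %d bins of %g A, averaged over %d frame(s)\n",
              length(x$r), x$bin_width, x$n_frames))
  if (!is.null(x$fit)) {
    cat(sprintf("  sigmoid fit: rho_dense = %.4f, rho_dilute = %.4f g/cm^3, r0 = %.1f A, w = %.1f A\n",
                x$fit$rho_dense, x$fit$rho_dilute, x$fit$r0, x$fit$w))
    cat(sprintf("  interface bounds: r95 = %.1f A, r05 = %.1f A\n",
                x$fit$r95, x$fit$r05))
  }
  invisible(x)
}

#' @export
plot.condensate_profile <- function(x, ...) {
  plot(x$r, x$density, type = "b", pch = 2,
       xlab = "r (A)", ylab = expression(rho ~ (g/cm^3)), ...)
  if (!is.null(x$fit)) {
    rr <- seq(min(x$r), max(x$r), length.out = 200)
    lines(rr, .sigmoid_eval(rr, x$fit), col = 2)
    abline(v = c(x$fit$r95, x$fit$r05), lty = 3, col = "grey40")
  }
  invisible(x)
}

.sigmoid_eval <- function(r, fit) {
  if (fit$family == "logistic") {
    fit$rho_dilute + (fit$rho_dense - fit$rho_dilute) /
      (1 + exp((r - fit$r0) / fit$w))
  } else {
    fit$rho_dilute + (fit$rho_dense - fit$rho_dilute) / 2 *
      (1 - tanh((r - fit$r0) / fit$w))
  }
}

#' Fit a sigmoid interface to a radial density profile
#'
#' Fits `rho(r) = rho_dilute + (rho_dense - rho_dilute) / (1 + exp((r - r0)/w))`
#' (or the tanh equivalent) and locates the interface bounds r95 < r05 where
#' the fitted curve crosses 95% and 5% of the dense-phase plateau value.
#' Fails explicitly (no silent defaults) when the profile lacks a dense
#' plateau at least twice the dilute level or the fit does not converge.
#'
#' @param profile A [radial_density_profile()] result.
#' @param family `"logistic"` (default) or `"tanh"`.
#' @return The profile with a `fit` list attached (`rho_dense`, `rho_dilute`,
#'   `r0`, `w`, `r95`, `r05`, `family`).
#' @export
fit_interface <- function(profile, family = c("logistic", "tanh")) {
  family <- match.arg(family)
  stopifnot(inherits(profile, "condensate_profile"))
  r <- profile$r; y <- profile$density
  if (all(!is.finite(y)) || max(y) <= 0) stop("interface fit failed: empty profile")
  n <- length(y)
  # weight bins by the square root of their sampling volume: shell densities
  # are count-noise limited, so thin central shells carry little information
  wts <- if (!is.null(profile$shell_vol)) sqrt(profile$shell_vol) else rep(1, n)
  wts <- wts / mean(wts)
  inner <- seq(min(3, n), max(3, floor(n / 4)))
  rho_den0 <- stats::median(y[inner])
  rho_dil0 <- stats::median(y[seq(floor(4 * n / 5), n)])
  if (!is.finite(rho_den0) || rho_den0 < 2 * rho_dil0 || rho_den0 <= 0) {
    stop("interface fit failed: no dense plateau at least 2x the dilute level")
  }
  r00 <- r[which.min(abs(y - (rho_den0 + rho_dil0) / 2))]
  fitfun <- if (family == "logistic") {
    function(p) p[2] + (p[1] - p[2]) / (1 + exp((r - p[3]) / p[4]))
  } else {
    function(p) p[2] + (p[1] - p[2]) / 2 * (1 - tanh((r - p[3]) / p[4]))
  }
  res <- minpack.lm::nls.lm(
    par = c(rho_den0, rho_dil0, r00, max(profile$bin_width, 1)),
    fn = function(p) wts * (y - fitfun(p)),
    lower = c(0, 0, 0, 1e-3),
    upper = c(Inf, Inf, max(r), max(r)),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  if (res$info == 0 || !all(is.finite(res$par))) {
    stop("interface fit failed to converge")
  }
  p <- res$par
  rho_dense <- p[1]; rho_dilute <- p[2]; r0 <- p[3]; w <- p[4]
  if (rho_dense <= rho_dilute) stop("interface fit failed: inverted profile")
  cross <- function(level) {
    # solve fitted density == level for r
    frac <- (rho_dense - rho_dilute) / (level - rho_dilute)
    if (level <= rho_dilute) return(NA_real_)
    if (family == "logistic") {
      r0 + w * log(frac - 1)
    } else {
      r0 + w * atanh(1 - 2 / frac)
    }
  }
  r95 <- cross(0.95 * rho_dense)
  r05 <- cross(0.05 * rho_dense)
  if (!is.finite(r95) || !is.finite(r05) || r95 >= r05) {
    stop("interface fit failed: could not bracket 95%/5% crossings")
  }
  profile$fit <- list(rho_dense = rho_dense, rho_dilute = rho_dilute,
                      r0 = r0, w = w, r95 = r95, r05 = r05, family = family)
  profile
}

#' Radial distribution of hub and clique molecules
#'
#' Per frame, the center-of-mass radial distance of each hub chain and each
#' clique-member chain is collected, divided by the dilute-side interface
#' bound r05, and histogrammed; histograms are normalized to unit area.
#'
#' @param traj A [condnet_traj].
#' @param roles List with one element per frame, each a list with character
#'   vectors `hubs` and `clique_members` of chain ids (e.g. from
#'   [identify_hubs()] / [identify_cliques()]).
#' @param profile An interface-fitted [condensate_profile].
#' @param bin_width Width of the normalized-distance bins (default 0.1).
#' @param model Energy model for masses.
#' @return List of class `feature_distribution` with normalized distances and
#'   unit-area histograms for hubs and clique members.
#' @export
radial_feature_distribution <- function(traj, roles, profile, bin_width = 0.1,
                                        model = mpipi_model()) {
  if (is.null(profile$fit)) stop("profile must carry an interface fit")
  stopifnot(length(roles) == length(traj$frames))
  r05 <- profile$fit$r05
  hub_d <- clique_d <- numeric(0)
  for (f in seq_along(traj$frames)) {
    conf <- traj$frames[[f]]
    ctr <- dense_phase_com(conf, model)
    coms <- all_chain_coms(conf, model)
    rad <- sqrt(rowSums((coms - matrix(ctr, nrow(coms), 3, byrow = TRUE))^2))
    names(rad) <- rownames(coms)
    hub_d <- c(hub_d, rad[as.character(roles[[f]]$hubs)] / r05)
    clique_d <- c(clique_d, rad[as.character(roles[[f]]$clique_members)] / r05)
  }
  upper <- max(1.5, hub_d, clique_d, na.rm = TRUE)
  breaks <- seq(0, upper + bin_width, by = bin_width)
  dens <- function(v) {
    if (length(v) == 0) return(rep(0, length(breaks) - 1))
    graphics::hist(v, breaks = breaks, plot = FALSE)$density
  }
  structure(list(breaks = breaks,
                 hub_distances = unname(hub_d),
                 clique_distances = unname(clique_d),
                 hub_density = dens(hub_d),
                 clique_density = dens(clique_d)),
            class = "feature_distribution")
}

#' Build a role timeline from per-frame hub/clique assignments
#'
#' @param roles Per-frame list of `hubs` and `clique_members` chain-id vectors
#'   over a continuous trajectory window.
#' @param chain_ids All chain ids in the system.
#' @param window_ns Window length in ns (informational).
#' @return An object of class `role_timeline`: logical frame x chain matrices
#'   `hub` and `clique`.
#' @export
role_timeline <- function(roles, chain_ids, window_ns = NA_real_) {
  chain_ids <- as.character(chain_ids)
  nf <- length(roles)
  if (nf == 0) stop("empty window")
  hub <- clique <- matrix(FALSE, nf, length(chain_ids),
                          dimnames = list(NULL, chain_ids))
  for (f in seq_len(nf)) {
    hub[f, as.character(roles[[f]]$hubs)] <- TRUE
    clique[f, as.character(roles[[f]]$clique_members)] <- TRUE
  }
  structure(list(hub = hub, clique = clique, window_ns = window_ns),
            class = "role_timeline")
}

#' Hub and clique lifetime fractions
#'
#' Per chain, the number of frames flagged as hub (or clique member) divided
#' by the total frames in the continuous window.
#'
#' @param timeline A [role_timeline()].
#' @return data.frame with columns `chain`, `hub_fraction`, `clique_fraction`.
#' @export
role_lifetimes <- function(timeline) {
  stopifnot(inherits(timeline, "role_timeline"))
  data.frame(chain = colnames(timeline$hub),
             hub_fraction = colMeans(timeline$hub),
             clique_fraction = colMeans(timeline$clique),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Instantaneous single-molecule displacement
#'
#' For an interior sampled frame t, the per-chain displacement is the mean of
#' the two leg lengths `|r(t) - r(t-1)|` and `|r(t+1) - r(t)|` of the
#' center-of-mass path. The normalized value divides by the chain's fully
#' extended contour length `(n - 1) * 3.81` A.
#'
#' @param traj A [condnet_traj].
#' @param t_index Index of the sampled frame (needs neighbors on both sides).
#' @param model Energy model for masses.
#' @return data.frame with columns `chain`, `dr` (A), `dr_norm`.
#' @export
displacement <- function(traj, t_index, model = mpipi_model()) {
  nf <- length(traj$frames)
  if (t_index <= 1 || t_index >= nf) {
    stop("t_index must be an interior frame (2..", nf - 1,
         "); boundary frames have no displacement")
  }
  com0 <- all_chain_coms(traj$frames[[t_index - 1]], model)
  com1 <- all_chain_coms(traj$frames[[t_index]], model)
  com2 <- all_chain_coms(traj$frames[[t_index + 1]], model)
  leg1 <- sqrt(rowSums((com1 - com0)^2))
  leg2 <- sqrt(rowSums((com2 - com1)^2))
  dr <- (leg1 + leg2) / 2
  ids <- rownames(com1)
  nbeads <- vapply(ids, function(cid)
    sum(traj$frames[[t_index]]$chain == as.integer(cid)), integer(1))
  data.frame(chain = ids, dr = unname(dr),
             dr_norm = unname(dr / ((nbeads - 1) * 3.81)),
             row.names = NULL, stringsAsFactors = FALSE)
}
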