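# Synthetic input generators: droplet and slab bead configurations, a small
# BAOAB Langevin integrator under the coarse-grained potential, and reference
# graph families for the small-world estimators. These stand in for
# cluster-scale production MD so the full analysis pipeline runs at desk
# scale; they are fixtures, not validated thermodynamic samplers.

#' Specification for a spherical droplet configuration
#'
#' @param n_chains Number of chains.
#' @param sequence A [residue_seq] used for every chain.
#' @param radius Dense-phase radius (A); must be below half the box.
#' @param dense_fraction Fraction of chains whose centers of mass are confined
#'   to the dense sphere; the remainder are placed in the dilute halo.
#' @param box Cubic box length (A).
#' @param seed Integer seed; the generator is a pure function of (spec, seed).
#' @return A `droplet_spec` list.
#' @export
droplet_spec <- function(n_chains, sequence, radius, dense_fraction = 1,
                         box = 4 * radius, seed = 1L) {
  stopifnot(n_chains >= 1, inherits(sequence, "residue_seq"),
            dense_fraction >= 0, dense_fraction <= 1, radius < box / 2)
  structure(list(n_chains = as.integer(n_chains), sequence = sequence,
                 radius = radius, dense_fraction = dense_fraction,
                 box = box, seed = as.integer(seed)), class = "droplet_spec")
}

#' Specification for a slab (direct-coexistence) configuration
#'
#' @param n_chains Number of chains.
#' @param sequence A [residue_seq].
#' @param thickness Slab thickness along z (A), `<= Lz`.
#' @param box Length-3 box dimensions (A); the slab normal is z.
#' @param dense_fraction Fraction of chains confined to the slab.
#' @param seed Integer seed.
#' @return A `slab_spec` list.
#' @export
slab_spec <- function(n_chains, sequence, thickness, box, dense_fraction = 1,
                      seed = 1L) {
  stopifnot(length(box) == 3, thickness <= box[3])
  structure(list(n_chains = as.integer(n_chains), sequence = sequence,
                 thickness = thickness, box = as.numeric(box),
                 dense_fraction = dense_fraction, seed = as.integer(seed)),
            class = "slab_spec")
}

# Grow one self-avoiding random walk with fixed bond length r0, rejecting
# bead placements closer than `min_sep` to any earlier non-bonded bead.
# `persistence` in [0,1) biases steps along the previous bond direction,
# producing more extended chains when large.
.grow_chain <- function(n_beads, r0 = 3.81, min_sep = 4.0, persistence = 0,
                        max_retry = 200L) {
  x <- matrix(0, n_beads, 3)
  if (n_beads == 1L) return(x)
  prev_dir <- .rand_unit(1)
  for (i in 2:n_beads) {
    placed <- FALSE
    for (tr in seq_len(max_retry)) {
      dir <- .rand_unit(1)
      if (persistence > 0) {
        dir <- persistence * prev_dir + (1 - persistence) * dir
        dir <- dir / sqrt(sum(dir^2))
      }
      cand <- x[i - 1, ] + r0 * dir
      if (i > 2) {
        d2 <- rowSums((x[1:(i - 2), , drop = FALSE] -
                         matrix(cand, i - 2, 3, byrow = TRUE))^2)
        if (min(d2) < min_sep^2) next
      }
      x[i, ] <- cand
      prev_dir <- dir
      placed <- TRUE
      break
    }
    if (!placed) stop("self-avoiding walk failed after bounded retries; ",
                      "reduce chain length or minimum separation")
  }
  x
}

.rand_unit <- function(n) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  if (n == 1L) v[1, ] else v
}

# Uniform point in a ball of given radius.
.rand_in_sphere <- function(radius) {
  radius * stats::runif(1)^(1 / 3) * .rand_unit(1)
}

.assemble_chains <- function(spec, com_fun, persistence_fun = NULL) {
  set.seed(spec$seed)
  seq_chars <- strsplit(spec$sequence$residues, "")[[1]]
  nb <- length(seq_chars)
  xs <- vector("list", spec$n_chains)
  for (c in seq_len(spec$n_chains)) {
    com <- com_fun(c)
    pers <- if (is.null(persistence_fun)) 0 else persistence_fun(c, com)
    xc <- .grow_chain(nb, persistence = pers)
    ccm <- colMeans(xc)
    xs[[c]] <- xc - matrix(ccm, nb, 3, byrow = TRUE) +
      matrix(com, nb, 3, byrow = TRUE)
  }
  x <- do.call(rbind, xs)
  configuration(x, rep(seq_chars, spec$n_chains),
                rep(seq_len(spec$n_chains), each = nb),
                if (length(spec$box) == 3) spec$box else rep(spec$box, 3))
}

#' Generate a spherical droplet + dilute halo configuration
#'
#' Dense-phase chains are self-avoiding random walks (bond length 3.81 A,
#' beads rejected closer than 4 A to non-bonded predecessors) whose centers of
#' mass are uniform in a sphere of the set radius at the box center; remaining
#' chains are placed in the dilute region outside the sphere. Deterministic
#' under the spec seed.
#'
#' @param spec A [droplet_spec()].
#' @param persistence Optional function(chain index, com) -> step-direction
#'   persistence in \[0, 1), for planting more extended chains (e.g. as a
#'   function of radial position).
#' @return A [configuration()].
#' @export
generate_droplet_config <- function(spec, persistence = NULL) {
  stopifnot(inherits(spec, "droplet_spec"))
  n_dense <- round(spec$n_chains * spec$dense_fraction)
  center <- rep(spec$box / 2, 3)
  com_fun <- function(c) {
    if (c <= n_dense) {
      center + .rand_in_sphere(spec$radius)
    } else {
      # rejection-sample a dilute COM outside the droplet
      for (tr in 1:1000) {
        p <- stats::runif(3, 0, spec$box)
        if (sqrt(sum((p - center)^2)) > spec$radius * 1.2) return(p)
      }
      stop("could not place dilute chain; enlarge box relative to radius")
    }
  }
  generate_config_common(spec, com_fun, persistence)
}

generate_config_common <- function(spec, com_fun, persistence) {
  .assemble_chains(spec, com_fun, persistence)
}

#' Generate a slab (direct-coexistence) configuration
#'
#' Dense chains are confined to `|z - Lz/2| < thickness/2` (periodic in x and
#' y), producing two planar interfaces; remaining chains go to the dilute
#' region. A thickness equal to `Lz` leaves no dilute region and is flagged
#' with a warning.
#'
#' @param spec A [slab_spec()].
#' @return A [configuration()].
#' @export
generate_slab_config <- function(spec) {
  stopifnot(inherits(spec, "slab_spec"))
  if (spec$thickness >= spec$box[3]) {
    warning("slab thickness equals the box height: no dilute region (degenerate)")
  }
  n_dense <- round(spec$n_chains * spec$dense_fraction)
  zc <- spec$box[3] / 2
  com_fun <- function(c) {
    if (c <= n_dense) {
      c(stats::runif(1, 0, spec$box[1]), stats::runif(1, 0, spec$box[2]),
        stats::runif(1, zc - spec$thickness / 2, zc + spec$thickness / 2))
    } else {
      for (tr in 1:1000) {
        z <- stats::runif(1, 0, spec$box[3])
        if (abs(z - zc) > spec$thickness / 2 + 5) {
          return(c(stats::runif(1, 0, spec$box[1]),
                   stats::runif(1, 0, spec$box[2]), z))
        }
      }
      stop("could not place dilute chain outside slab")
    }
  }
  generate_config_common(spec, com_fun, NULL)
}

#' Short Langevin dynamics under the coarse-grained potential
#'
#' BAOAB-splitting Langevin integration of the full potential (harmonic
#' bonds, Wang-Frenkel pairs, screened Coulomb) with minimum-image periodic
#' boundaries. Intended for equilibrating synthetic fixtures and sampling
#' single-chain conformations, not for production thermodynamics.
#'
#' @param conf Starting [configuration()].
#' @param model An [mpipi_model()].
#' @param T Temperature (K); 0 disables the stochastic and friction terms.
#' @param dt Timestep (fs); guard `dt <= 10`.
#' @param n_steps Number of steps.
#' @param seed Integer seed.
#' @param friction Friction constant (fs^-1), default 0.01.
#' @param sample_every Emit a frame every this many steps (default: only the
#'   final frame in addition to the start).
#' @return A [condnet_traj] whose first frame is the input configuration.
#' @export
run_langevin <- function(conf, model = mpipi_model(), T = 300, dt = 5,
                         n_steps = 1000, seed = 1L, friction = 0.01,
                         sample_every = n_steps) {
  stopifnot(dt <= 10, n_steps >= 1)
  set.seed(seed)
  n <- nrow(conf$x)
  mass <- model$params[conf$type, "mass"]
  kT <- if (T > 0) thermal_energy(T) else 0
  x <- conf$x
  v <- if (!is.null(conf$vel)) conf$vel else matrix(0, n, 3)
  if (T > 0 && is.null(conf$vel)) {
    v <- matrix(stats::rnorm(3 * n), n, 3) *
      sqrt(kT * .accel_conv / mass)  # A/fs
  }
  c1 <- exp(-friction * dt)
  csig <- sqrt(pmax(kT * .accel_conv / mass * (1 - c1^2), 0))
  state <- conf
  f <- compute_forces(state, model)$forces
  frames <- list(conf)
  t0 <- conf$time
  for (s in seq_len(n_steps)) {
    v <- v + 0.5 * dt * f / mass * .accel_conv
    x <- x + 0.5 * dt * v
    if (T > 0) v <- c1 * v + csig * matrix(stats::rnorm(3 * n), n, 3)
    x <- x + 0.5 * dt * v
    if (any(!is.finite(x))) stop("non-finite coordinates at step ", s)
    state$x <- x
    f <- compute_forces(state, model)$forces
    v <- v + 0.5 * dt * f / mass * .accel_conv
    if (s %% sample_every == 0L) {
      fr <- state
      fr$vel <- v
      fr$time <- t0 + s * dt * 1e-6  # fs -> ns
      frames[[length(frames) + 1L]] <- fr
    }
  }
  trajectory(frames)
}

#' Reference graph families for small-world estimation
#'
#' @param family `"ER"` (Erdos-Renyi G(n, p) or G(n, m)), `"ring_lattice"`
#'   (each node joined to its `k` nearest ring neighbors), or
#'   `"watts_strogatz"` (ring lattice with edge rewiring probability `p`).
#' @param n Number of nodes (>= 4).
#' @param k Even neighbor count for lattice/Watts-Strogatz, or desired mean
#'   degree for ER when `m` not given.
#' @param p ER edge probability or Watts-Strogatz rewiring probability.
#' @param m Edge count for ER G(n, m) sampling (overrides `p`/`k`).
#' @param seed Integer seed.
#' @return An igraph undirected simple graph.
#' @export
generate_reference_graph <- function(family = c("ER", "ring_lattice", "watts_strogatz"),
                                     n, k = NULL, p = NULL, m = NULL, seed = 1L) {
  family <- match.arg(family)
  stopifnot(n >= 4)
  set.seed(seed)
  g <- switch(family,
    ER = {
      if (!is.null(m)) {
        igraph::sample_gnm(n, m)
      } else {
        if (is.null(p)) {
          if (is.null(k)) stop("ER needs p, m, or mean degree k")
          p <- k / (n - 1)
        }
        igraph::sample_gnp(n, p)
      }
    },
    ring_lattice = {
      if (is.null(k) || k %% 2 != 0) stop("ring lattice needs an even k")
      igraph::sample_smallworld(1, n, k / 2, 0)
    },
    watts_strogatz = {
      if (is.null(k) || k %% 2 != 0) stop("watts_strogatz needs an even k")
      if (is.null(p)) stop("watts_strogatz needs a rewiring probability p")
      .watts_strogatz(n, k, p)
    })
  igraph::simplify(g)
}

# Classic Watts-Strogatz: start from the k-nearest-neighbor ring lattice and,
# for each edge, rewire its far endpoint with probability p to a uniformly
# random node (avoiding self-loops and duplicate edges).
.watts_strogatz <- function(n, k, p) {
  adj <- new.env(hash = TRUE, size = 2L * n * k)
  key <- function(u, v) paste0(pmin(u, v), ":", pmax(u, v))
  el <- do.call(rbind, lapply(seq_len(k / 2), function(d) {
    cbind(seq_len(n), (seq_len(n) + d - 1L) %% n + 1L)
  }))
  for (e in seq_len(nrow(el))) assign(key(el[e, 1], el[e, 2]), TRUE, envir = adj)
  rew <- stats::runif(nrow(el)) < p
  for (e in which(rew)) {
    u <- el[e, 1]
    for (tr in 1:100) {
      v <- sample.int(n, 1)
      if (v == u) next
      if (exists(key(u, v), envir = adj, inherits = FALSE)) next
      rm(list = key(el[e, 1], el[e, 2]), envir = adj)
      assign(key(u, v), TRUE, envir = adj)
      el[e, 2] <- v
      break
    }
  }
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' Droplet trajectory with planted hubs and interface cliques
#'
#' Builds a small trajectory whose interaction graph has known structure, for
#' validating the spatial/temporal role analyses: groups of parallel chains
#' at the pair-potential minimum spacing form fully connected clusters
#' (cliques) in a shell near the interface, a linear path of mutually
#' contacting chains spans the droplet center (its interior members acquire
#' the highest betweenness, i.e. act as hubs), and self-avoiding filler
#' chains provide the dense-phase density plateau. Cluster membership is
#' fixed across frames while the subset of pool chains forming the central
#' path is re-drawn each frame, so clique roles persist and hub roles churn.
#'
#' @param sequence A [residue_seq]; short sticker-rich chains (e.g. "(YS)5")
#'   give robustly super-threshold contacts.
#' @param radius Droplet radius (A).
#' @param box Cubic box length (A).
#' @param n_clusters Number of planted interface clusters.
#' @param clique_size Chains per cluster (>= 3).
#' @param core_pool Number of chains eligible to form the central path.
#' @param core_size Chains forming the path each frame.
#' @param n_filler Unstructured dense-phase chains.
#' @param n_frames Frames in the trajectory.
#' @param seed Integer seed.
#' @return A list: `traj` (a [condnet_traj]), `cluster_chains` (list of chain
#'   ids per planted cluster), `core_pool` (ids eligible as hubs),
#'   `shell_radius` (planting radius of the clusters, A).
#' @export
generate_planted_droplet <- function(sequence, radius = 50, box = 220,
                                     n_clusters = 4, clique_size = 3,
                                     core_pool = 12, core_size = 6,
                                     n_filler = 40, n_frames = 5, seed = 1L) {
  stopifnot(clique_size >= 3, core_size >= 3, core_pool >= core_size)
  set.seed(seed)
  chars <- strsplit(sequence$residues, "")[[1]]
  nb <- length(chars)
  rod <- cbind(0, 0, (seq_len(nb) - (nb + 1) / 2) * 3.81)
  n_chains <- core_pool + n_clusters * clique_size + n_filler
  center <- rep(box / 2, 3)
  shell_r <- 0.85 * radius
  # parallel-rod spacing just inside the attractive well of the largest bead
  # pair (Y-Y minimum at ~7.7 A), so every planted contact is super-threshold
  contact <- 6.9
  circ_r <- contact / (2 * sin(pi / clique_size))
  cluster_dirs <- .rand_unit(n_clusters)
  if (n_clusters == 1) cluster_dirs <- matrix(cluster_dirs, 1)
  cluster_chains <- split(core_pool + seq_len(n_clusters * clique_size),
                          rep(seq_len(n_clusters), each = clique_size))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    x <- matrix(0, n_chains * nb, 3)
    put <- function(cid, com, as_rod = TRUE) {
      xc <- if (as_rod) rod else {
        w <- .grow_chain(nb)
        w - matrix(colMeans(w), nb, 3, byrow = TRUE)
      }
      x[(cid - 1) * nb + seq_len(nb), ] <<- xc + matrix(com, nb, 3, byrow = TRUE)
    }
    core_ids <- sort(sample(seq_len(core_pool), core_size))
    for (k in seq_along(core_ids)) {
      put(core_ids[k], center + c((k - (core_size + 1) / 2) * contact, 0, 0))
    }
    for (cid in setdiff(seq_len(core_pool), core_ids)) {
      put(cid, center + .rand_in_sphere(0.6 * radius), as_rod = FALSE)
    }
    for (cl in seq_len(n_clusters)) {
      ccen <- center + shell_r * cluster_dirs[cl, ]
      for (k in seq_len(clique_size)) {
        ang <- 2 * pi * (k - 1) / clique_size
        put(cluster_chains[[cl]][k], ccen + c(circ_r * cos(ang),
                                              circ_r * sin(ang), 0))
      }
    }
    for (cid in core_pool + n_clusters * clique_size + seq_len(n_filler)) {
      put(cid, center + .rand_in_sphere(0.9 * radius), as_rod = FALSE)
    }
    frames[[f]] <- configuration(x, rep(chars, n_chains),
                                 rep(seq_len(n_chains), each = nb),
                                 rep(box, 3), time = f - 1)
  }
  list(traj = trajectory(frames), cluster_chains = cluster_chains,
       core_pool = seq_len(core_pool), shell_radius = shell_r)
}
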