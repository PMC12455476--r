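# Independent brute-force oracles used to validate the package's graph and
# energy routines. These deliberately reimplement each quantity from its
# definition, without igraph, so the two routes stay independent.

# All-pairs shortest-path betweenness by explicit path enumeration (BFS path
# counting), normalized by choose(N-1, 2). adj: logical/0-1 matrix.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in 1:(n - 1)) {
    # BFS from s counting shortest paths
    dist <- rep(Inf, n); npaths <- numeric(n)
    dist[s] <- 0; npaths[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ] > 0)) {
          if (is.infinite(dist[v])) {
            dist[v] <- dist[u] + 1
            nxt <- c(nxt, v)
          }
          if (dist[v] == dist[u] + 1) npaths[v] <- npaths[v] + npaths[u]
        }
      }
      frontier <- unique(nxt)
    }
    for (t in (s + 1):n) {
      if (t == s || is.infinite(dist[t])) next
      # count, for each interior node i, shortest s-t paths through i:
      # sigma_st(i) = npaths_s(i) * npaths_t(i) when on a shortest path
      distt <- rep(Inf, n); npt <- numeric(n)
      distt[t] <- 0; npt[t] <- 1
      frontier2 <- t
      while (length(frontier2) > 0) {
        nxt <- integer(0)
        for (u in frontier2) {
          for (v in which(adj[u, ] > 0)) {
            if (is.infinite(distt[v])) {
              distt[v] <- distt[u] + 1
              nxt <- c(nxt, v)
            }
            if (distt[v] == distt[u] + 1) npt[v] <- npt[v] + npt[u]
          }
        }
        frontier2 <- unique(nxt)
      }
      for (i in seq_len(n)) {
        if (i == s || i == t) next
        if (is.finite(dist[i]) && is.finite(distt[i]) &&
            dist[i] + distt[i] == dist[t]) {
          btw[i] <- btw[i] + npaths[i] * npt[i] / npaths[t]
        }
      }
    }
  }
  btw / choose(n - 1, 2)
}

# Maximal cliques by exhaustive subset enumeration (n <= 12).
brute_max_cliques <- function(adj, min_size = 3) {
  n <- nrow(adj)
  cliques <- list()
  for (mask in 1:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(members) < min_size) next
    pairs <- utils::combn(members, 2)
    if (!all(adj[t(pairs)] > 0)) next
    # maximal: no outside vertex adjacent to all members
    extendable <- any(vapply(setdiff(1:n, members), function(v)
      all(adj[v, members] > 0), logical(1)))
    if (!extendable) cliques[[length(cliques) + 1]] <- members
  }
  cliques
}

# Chain-chain interaction energy by a plain double loop over bead pairs,
# reusing only the scalar pair_energy() kernel and explicit minimum image.
brute_chain_pair_energy <- function(conf, a, b, model) {
  ia <- which(conf$chain == a); ib <- which(conf$chain == b)
  e <- 0
  for (i in ia) for (j in ib) {
    d <- conf$x[i, ] - conf$x[j, ]
    d <- d - conf$box * round(d / conf$box)
    e <- e + pair_energy(conf$type[i], conf$type[j], sqrt(sum(d * d)), model)
  }
  e
}

# Monte-Carlo union volume of a set of spheres (tight bounding box).
mc_union_volume <- function(centers, radii, n_pts = 4e5, seed = 1) {
  set.seed(seed)
  lo <- apply(centers - radii, 2, min)
  hi <- apply(centers + radii, 2, max)
  pts <- cbind(runif(n_pts, lo[1], hi[1]), runif(n_pts, lo[2], hi[2]),
               runif(n_pts, lo[3], hi[3]))
  inside <- rep(FALSE, n_pts)
  for (k in seq_len(nrow(centers))) {
    d2 <- (pts[, 1] - centers[k, 1])^2 + (pts[, 2] - centers[k, 2])^2 +
      (pts[, 3] - centers[k, 3])^2
    inside <- inside | d2 < radii[k]^2
  }
  mean(inside) * prod(hi - lo)
}

# Small random multi-chain configuration for energy/graph oracle tests.
random_test_config <- function(n_chains = 4, n_beads = 8, box = 60,
                               types = c("Y", "S", "G", "K", "E"), seed = 1) {
  set.seed(seed)
  x <- NULL; type <- character(0); chain <- integer(0)
  for (c in seq_len(n_chains)) {
    start <- runif(3, 0, box)
    steps <- matrix(rnorm(3 * (n_beads - 1)), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2)) * 3.81
    xc <- rbind(start, start + apply(steps, 2, cumsum))
    x <- rbind(x, xc)
    type <- c(type, sample(types, n_beads, replace = TRUE))
    chain <- c(chain, rep(c, n_beads))
  }
  configuration(x, type, chain, rep(box, 3))
}
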