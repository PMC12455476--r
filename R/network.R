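# Chain-level interaction graphs and small-world statistics.
#
# A frame's microstructure graph has one node per chain and an unweighted,
# undirected edge between chains a and b when their interaction energy is
# below -m * k_B * T (default m = 5). Small-worldness is quantified with
#   sigma = (C / C_rand) / (L / L_rand)
#   omega = L_rand / L - C / C_latt
# against ensembles of Erdos-Renyi random references (matched node and edge
# counts) and degree-preserving latticized references.

#' Build the chain-chain interaction graph of a configuration
#'
#' Edge (a, b) is present iff `chain_pair_energy(a, b) < -m * k_B * T`.
#' Larger threshold multiples `m` keep only longer-lived associations.
#'
#' @param conf A [configuration()] with at least two chains.
#' @param model An [mpipi_model()].
#' @param T Temperature (K) setting the thermal energy scale.
#' @param m Threshold multiple of `k_B T` (default 5).
#' @return An object of class `interaction_graph`: list with `graph` (igraph,
#'   vertex names = chain ids), `energies` (symmetric chain-pair energy
#'   matrix, kcal/mol), `m`, `T` and the frame `time`.
#' @export
build_interaction_graph <- function(conf, model = mpipi_model(), T = 300, m = 5) {
  ids <- sort(unique(conf$chain))
  n <- length(ids)
  if (n < 2) stop("need at least two chains")
  stopifnot(m > 0)
  E <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      e <- chain_pair_energy(conf, ids[a], ids[b], model)
      E[a, b] <- e
      E[b, a] <- e
    }
  }
  interaction_graph_from_energies(E, m = m, T = T, time = conf$time)
}

#' Interaction graph from a precomputed energy matrix
#'
#' @param energies Symmetric chain-pair energy matrix (kcal/mol) with chain
#'   ids as dimnames.
#' @param m Threshold multiple of `k_B T`.
#' @param T Temperature (K).
#' @param time Frame timestamp (ns).
#' @return An `interaction_graph`.
#' @export
interaction_graph_from_energies <- function(energies, m = 5, T = 300, time = 0) {
  stopifnot(isSymmetric(unname(energies)), m > 0)
  adj <- (energies < -m * thermal_energy(T)) * 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  structure(list(graph = g, energies = energies, m = m, T = T, time = time),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d chains, %d edges (threshold -%g kT at %g K), t = %g ns\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$m, x$T, x$time))
  invisible(x)
}

.as_igraph <- function(g) {
  if (inherits(g, "interaction_graph")) g$graph else g
}

#' Normalized betweenness centrality
#'
#' For node i, the sum over node pairs (s, t), s,t != i, of the fraction of
#' shortest s-t paths passing through i, divided by choose(N-1, 2) so values
#' lie in \[0, 1\] and are comparable across system sizes.
#'
#' @param g An `interaction_graph` or igraph graph with >= 3 nodes.
#' @return Named numeric vector of centralities (names = chain ids).
#' @export
betweenness_centrality <- function(g) {
  ig <- .as_igraph(g)
  if (igraph::vcount(ig) < 3) stop("betweenness needs at least 3 nodes")
  b <- igraph::betweenness(ig, directed = FALSE, normalized = TRUE)
  if (is.null(names(b))) names(b) <- as.character(seq_along(b))
  b
}

# Mean local clustering coefficient, counting degree<2 nodes as zero
# (the convention of networkx average_clustering).
mean_clustering <- function(ig) {
  if (igraph::ecount(ig) == 0) return(0)
  igraph::transitivity(ig, type = "localaverage", isolates = "zero")
}

# Mean shortest pathlength on the largest connected component.
mean_pathlength_lcc <- function(ig) {
  comp <- igraph::components(ig)
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) < 2) return(NA_real_)
  sub <- igraph::induced_subgraph(ig, keep)
  igraph::mean_distance(sub, directed = FALSE)
}

#' Degree-preserving lattice reference of a graph
#'
#' Constructs a ring-lattice-like graph with the same degree sequence:
#' nodes are placed on a ring (in a random order, so repeated calls under
#' different RNG states form an ensemble) and stubs are matched to the
#' nearest ring neighbors in order of increasing ring distance. For a
#' k-regular input this yields exactly the k-nearest-neighbor ring lattice;
#' for irregular degree sequences it yields the maximally local arrangement
#' the degrees admit. Used as the lattice reference for the omega estimator.
#'
#' @param ig igraph undirected simple graph.
#' @return Latticized igraph graph with the same degree sequence (up to at
#'   most a handful of unpairable leftover stubs).
#' @export
lattice_reference <- function(ig) {
  n <- igraph::vcount(ig)
  deg <- igraph::degree(ig)
  if (sum(deg) == 0) return(ig)
  pos <- sample.int(n)            # ring position -> node id
  remaining <- deg[pos]           # stubs left, indexed by ring position
  m_target <- sum(deg) %/% 2L
  from <- integer(m_target); to <- integer(m_target); ne <- 0L
  d <- 1L
  d_max <- floor(n / 2)
  while (sum(remaining) > 1 && d <= d_max && ne < m_target) {
    last <- if (2L * d == n) n %/% 2L else n  # avoid double-visiting d = n/2
    for (i in seq_len(last)) {
      if (remaining[i] == 0L) next
      j <- (i + d - 1L) %% n + 1L
      if (remaining[j] == 0L) next
      ne <- ne + 1L
      from[ne] <- pos[i]; to[ne] <- pos[j]
      remaining[i] <- remaining[i] - 1L
      remaining[j] <- remaining[j] - 1L
    }
    d <- d + 1L
  }
  g <- igraph::graph_from_edgelist(cbind(from[seq_len(ne)], to[seq_len(ne)]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

#' Small-world statistics of a graph
#'
#' Computes the mean clustering coefficient C (over all nodes, degree-<2
#' nodes counted as zero) and mean shortest pathlength L (on the largest
#' connected component), the same quantities averaged over `n_ref`
#' Erdos-Renyi random references with matched node and edge counts
#' (C_rand, L_rand) and over `n_ref` degree-preserving latticized references
#' (C_latt, L_latt), and the estimators
#' `sigma = (C/C_rand) / (L/L_rand)` and `omega = L_rand/L - C/C_latt`.
#' `sigma > 1` with `omega` in roughly \[-0.3, 0.3\] indicates a small-world
#' topology; `omega -> -1` a lattice-like and `omega -> 1` a random-like one.
#'
#' @param g An `interaction_graph` or igraph graph; its largest connected
#'   component (the analysis component) must have >= 10 nodes.
#' @param n_ref Reference-ensemble size (default 10).
#' @param seed Integer seed for the reference ensembles.
#' @return An object of class `smallworld_stats`.
#' @export
small_world_stats <- function(g, n_ref = 10, seed = 1L) {
  ig <- .as_igraph(g)
  if (igraph::ecount(ig) == 0) stop("graph has no edges")
  comp <- igraph::components(ig)
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) < 10) stop("largest connected component has fewer than 10 nodes")
  component_fraction <- length(keep) / igraph::vcount(ig)
  sub <- igraph::induced_subgraph(ig, keep)
  n <- igraph::vcount(sub)
  m <- igraph::ecount(sub)
  C <- mean_clustering(sub)
  L <- mean_pathlength_lcc(sub)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2 * n_ref)
  c_rand <- l_rand <- c_latt <- l_latt <- numeric(n_ref)
  for (i in seq_len(n_ref)) {
    set.seed(seeds[i])
    gr <- igraph::sample_gnm(n, m)
    c_rand[i] <- mean_clustering(gr)
    l_rand[i] <- mean_pathlength_lcc(gr)
    set.seed(seeds[n_ref + i])
    gl <- lattice_reference(sub)
    c_latt[i] <- mean_clustering(gl)
    l_latt[i] <- mean_pathlength_lcc(gl)
  }
  C_rand <- mean(c_rand); L_rand <- mean(l_rand)
  C_latt <- mean(c_latt); L_latt <- mean(l_latt)
  if (C_rand <= 0 || C_latt <= 0) stop("degenerate reference clustering (no triangles)")
  sigma <- (C / C_rand) / (L / L_rand)
  omega <- L_rand / L - C / C_latt
  structure(list(C = C, L = L, C_rand = C_rand, L_rand = L_rand,
                 C_latt = C_latt, L_latt = L_latt,
                 sigma = sigma, omega = omega, n_ref = n_ref,
                 component_fraction = component_fraction),
            class = "smallworld_stats")
}

#' @export
print.smallworld_stats <- function(x, ...) {
  cat("<smallworld_stats>\n")
  cat(sprintf("  C = %.4f (C_rand %.4f, C_latt %.4f)\n", x$C, x$C_rand, x$C_latt))
  cat(sprintf("  L = %.3f (L_rand %.3f, L_latt %.3f)\n", x$L, x$L_rand, x$L_latt))
  cat(sprintf("  sigma = %.3f   omega = %.3f   [%d refs, %.0f%% of nodes in analysis component]\n",
              x$sigma, x$omega, x$n_ref, 100 * x$component_fraction))
  invisible(x)
}

#' Identify hub chains
#'
#' The `n_h` nodes with the highest normalized betweenness centrality
#' (default 10). Ties are broken by ascending chain id.
#'
#' @param g An `interaction_graph` or igraph graph.
#' @param centralities Optional precomputed [betweenness_centrality()] values.
#' @param n_h Number of hubs to report.
#' @return A list of class `hub_set`: `hubs` (chain ids), `centrality`
#'   (values for those ids) and `truncated` (TRUE when the graph had fewer
#'   than `n_h` nodes).
#' @export
identify_hubs <- function(g, centralities = NULL, n_h = 10) {
  if (is.null(centralities)) centralities <- betweenness_centrality(g)
  ids <- names(centralities)
  ord <- order(-centralities, suppressWarnings(as.numeric(ids)), ids)
  take <- seq_len(min(n_h, length(ids)))
  structure(list(hubs = ids[ord][take],
                 centrality = unname(centralities[ord][take]),
                 truncated = length(ids) < n_h),
            class = "hub_set")
}

#' Identify the reported maximal cliques
#'
#' Enumerates all maximal cliques, scans them in order of decreasing size
#' (ties by lexicographic member ids) and greedily accepts a clique only if
#' it shares at most `max_shared` members with every previously accepted
#' clique, stopping after `n_c` cliques. This mirrors the reporting rule
#' "only if fewer than three members belong to an already reported clique".
#'
#' @param g An `interaction_graph` or igraph graph.
#' @param n_c Maximum number of cliques to report (default 10).
#' @param max_shared Maximum member overlap with each accepted clique
#'   (default 2).
#' @param min_size Smallest clique size considered (default 3).
#' @return A list of class `clique_set` with `cliques` (list of chain-id
#'   vectors, members sorted) and the parameters used.
#' @export
identify_cliques <- function(g, n_c = 10, max_shared = 2, min_size = 3) {
  ig <- .as_igraph(g)
  cl <- igraph::max_cliques(ig, min = min_size)
  members <- lapply(cl, function(v) {
    nm <- igraph::V(ig)$name[as.integer(v)]
    if (is.null(nm)) nm <- as.character(as.integer(v))
    nm[order(suppressWarnings(as.numeric(nm)), nm)]
  })
  if (length(members) > 0) {
    keyfun <- function(mm) paste(formatC(suppressWarnings(as.numeric(mm)),
                                         width = 12, flag = "0"), collapse = ",")
    sizes <- lengths(members)
    ord <- order(-sizes, vapply(members, keyfun, character(1)))
    members <- members[ord]
  }
  accepted <- list()
  for (mm in members) {
    if (length(accepted) >= n_c) break
    ok <- all(vapply(accepted, function(a) length(intersect(a, mm)) <= max_shared,
                     logical(1)))
    if (ok) accepted[[length(accepted) + 1L]] <- mm
  }
  structure(list(cliques = accepted, n_c = n_c, max_shared = max_shared,
                 min_size = min_size),
            class = "clique_set")
}

#' @export
print.clique_set <- function(x, ...) {
  cat(sprintf("<clique_set> %d reported cliques (overlap <= %d)\n",
              length(x$cliques), x$max_shared))
  for (i in seq_along(x$cliques)) {
    cat(sprintf("  [%d] size %d: %s\n", i, length(x$cliques[[i]]),
                paste(x$cliques[[i]], collapse = " ")))
  }
  invisible(x)
}

#' Export an interaction graph as an edge-list table
#'
#' @param g An `interaction_graph`.
#' @return data.frame with columns `frame`, `node_a`, `node_b`.
#' @export
graph_edge_table <- function(g) {
  stopifnot(inherits(g, "interaction_graph"))
  el <- igraph::as_edgelist(g$graph)
  if (nrow(el) == 0) {
    return(data.frame(frame = numeric(0), node_a = character(0),
                      node_b = character(0)))
  }
  data.frame(frame = g$time, node_a = el[, 1], node_b = el[, 2],
             stringsAsFactors = FALSE)
}
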