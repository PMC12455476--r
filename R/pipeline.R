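# Config-driven end-to-end orchestration: synthetic configuration (or dump
# input) -> per-frame interaction graphs -> small-world stats -> profile and
# interface -> hub/clique spatial and temporal organization -> conformation
# and displacement tables -> packing density. Every stochastic stage is
# seeded from the single config seed; the run manifest lists all outputs.

#' Default pipeline configuration
#'
#' Defaults mirror the analysis conventions used throughout the package:
#' energy threshold multiple m = 5, 10 hubs and up to 10 cliques with < 3
#' shared members, 5 A radial bins, and a desk-scale synthetic droplet
#' (30 chains of a 50-residue YS chain).
#'
#' @return Named list of defaults; override fields via [run_pipeline()].
#' @export
default_run_config <- function() {
  list(
    input = "droplet",          # "droplet" or a LAMMPS dump path
    sequence = "(S4Y)10",       # pattern or LCD name (50-mer default)
    n_chains = 30L,
    radius = 55,
    box = 220,
    dense_fraction = 1,
    temperature = 300,
    threshold_multiple = 5,
    n_hubs = 10L,
    n_cliques = 10L,
    max_shared = 2L,
    bin_width = 5,
    n_frames = 3L,              # langevin-jittered analysis frames
    langevin_steps = 0L,        # extra equilibration steps per frame (0 = static)
    seed = 1L,
    out_dir = NULL
  )
}

.resolve_sequence <- function(name) {
  if (name %in% c("A1-LCD", "FUS-LCD", "EWSR1-LCD", "TIA1-LCD")) {
    build_lcd(name)
  } else {
    build_ys_variant(name, length = NA)
  }
}

#' Run the full condensate-microstructure pipeline
#'
#' @param config Named list overriding [default_run_config()] fields, or a
#'   path to a YAML file with those fields.
#' @return A run manifest (list): config used, per-stage summary statistics
#'   and, when `out_dir` is set, the paths of the exported TSV tables.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (!is.null(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE,
                                        showWarnings = FALSE)
  model <- mpipi_model(temperature = cfg$temperature)
  manifest <- list(config = cfg, outputs = list(), stats = list())

  # --- input stage ---------------------------------------------------------
  if (identical(cfg$input, "droplet")) {
    seqn <- .resolve_sequence(cfg$sequence)
    spec <- droplet_spec(cfg$n_chains, seqn, cfg$radius,
                         dense_fraction = cfg$dense_fraction,
                         box = cfg$box, seed = cfg$seed)
    frames <- lapply(seq_len(cfg$n_frames), function(f) {
      sp <- spec
      sp$seed <- cfg$seed + f - 1L
      conf <- generate_droplet_config(sp)
      if (cfg$langevin_steps > 0) {
        tr <- run_langevin(conf, model, T = cfg$temperature,
                           n_steps = cfg$langevin_steps,
                           seed = cfg$seed + 1000L + f)
        conf <- tr$frames[[length(tr$frames)]]
      }
      conf$time <- f - 1
      conf
    })
    traj <- trajectory(frames)
  } else {
    if (!file.exists(cfg$input)) stop("input stage: dump path not found: ", cfg$input)
    traj <- read_lammps_dump(cfg$input, type_map = cfg$type_map)
  }

  # --- graph stage ---------------------------------------------------------
  graphs <- lapply(traj$frames, function(conf)
    build_interaction_graph(conf, model, T = cfg$temperature,
                            m = cfg$threshold_multiple))
  roles <- lapply(graphs, function(g) {
    cb <- betweenness_centrality(g)
    hubs <- identify_hubs(g, cb, n_h = cfg$n_hubs)
    cl <- identify_cliques(g, n_c = cfg$n_cliques, max_shared = cfg$max_shared)
    list(hubs = hubs$hubs,
         clique_members = unique(unlist(cl$cliques)),
         centrality = cb)
  })
  edge_tab <- do.call(rbind, lapply(graphs, graph_edge_table))
  manifest$stats$mean_edges <- mean(vapply(graphs, function(g)
    igraph::ecount(g$graph), numeric(1)))

  sw <- tryCatch(small_world_stats(graphs[[1]], seed = cfg$seed),
                 error = function(e) NULL)
  if (!is.null(sw)) {
    manifest$stats$sigma_sw <- sw$sigma
    manifest$stats$omega_sw <- sw$omega
  }

  # --- profile stage -------------------------------------------------------
  prof <- radial_density_profile(traj, bin_width = cfg$bin_width, model = model)
  prof <- tryCatch(fit_interface(prof), error = function(e) {
    manifest$stats$interface_error <<- conditionMessage(e)
    prof
  })
  feat <- NULL
  if (!is.null(prof$fit)) {
    feat <- radial_feature_distribution(traj, roles, prof, model = model)
    manifest$stats$interface <- prof$fit[c("r95", "r05", "rho_dense")]
    manifest$stats$median_hub_r <- stats::median(feat$hub_distances)
    manifest$stats$median_clique_r <- stats::median(feat$clique_distances)
  }

  # --- temporal stage ------------------------------------------------------
  tl <- role_timeline(roles, sort(unique(traj$frames[[1]]$chain)))
  lifetimes <- role_lifetimes(tl)
  disp <- if (length(traj$frames) >= 3) {
    displacement(traj, 2, model = model)
  }

  # --- conformation stage --------------------------------------------------
  conf_tab <- do.call(rbind, mapply(function(conf, g)
    conformation_table(conf, g, model), traj$frames, graphs, SIMPLIFY = FALSE))
  pl <- tryCatch(loglog_power_fit(conf_tab$C_B, conf_tab$Rg),
                 error = function(e) NULL)
  if (!is.null(pl)) {
    manifest$stats$rg_cb_slope <- pl$slope
    manifest$stats$rg_cb_r2 <- pl$r_squared
  }

  # --- thermo stage --------------------------------------------------------
  if (!is.null(prof$fit)) {
    nd <- dense_phase_number_density(traj, prof$fit$r0, model)
    vex <- chain_excluded_volume(traj, traj$frames[[1]]$chain[1], model)
    N <- sum(traj$frames[[1]]$chain == traj$frames[[1]]$chain[1])
    pk <- packing_density(nd$rho_n, vex$V_ex, N)
    manifest$stats$phi_rel <- pk$phi_rel
    manifest$stats$rho_n <- pk$rho_n
  }

  # --- export --------------------------------------------------------------
  if (!is.null(cfg$out_dir)) {
    wr <- function(df, name) {
      p <- file.path(cfg$out_dir, paste0(name, ".tsv"))
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$outputs[[name]] <<- p
    }
    wr(edge_tab, "graph_edges")
    wr(lifetimes, "role_lifetimes")
    wr(conf_tab, "conformation")
    if (!is.null(disp)) wr(disp, "displacement")
    wr(data.frame(r = prof$r, density = prof$density), "radial_profile")
    if (!is.null(feat)) {
      wr(data.frame(bin = feat$breaks[-length(feat$breaks)],
                    hub = feat$hub_density, clique = feat$clique_density),
         "feature_distribution")
    }
    yaml::write_yaml(list(config = cfg, stats = manifest$stats,
                          outputs = manifest$outputs),
                     file.path(cfg$out_dir, "manifest.yaml"))
  }
  manifest$tables <- list(edges = edge_tab, lifetimes = lifetimes,
                          conformation = conf_tab, displacement = disp,
                          profile = prof, features = feat)
  manifest
}
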