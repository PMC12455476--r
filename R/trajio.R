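# Bead-resolution configurations and trajectories; LAMMPS text I/O and
# periodic-boundary geometry. Units: Angstrom, ns, amu, kcal/mol throughout.

#' Construct a bead-resolution configuration
#'
#' @param x n x 3 matrix of positions (A). Positions are stored as given
#'   (conventionally unwrapped); wrapped input can be unwrapped per chain with
#'   the backbone nearest-image rule in [chain_com()].
#' @param type Character vector of one-letter residue codes, length n.
#' @param chain Integer vector of chain ids, length n.
#' @param bead Integer bead index within each chain (0-based, contiguous);
#'   derived from ordering within chain when omitted.
#' @param box Length-3 orthorhombic box lengths (A).
#' @param vel Optional n x 3 velocity matrix (A/fs).
#' @param time Timestamp in ns.
#' @return An object of class `condnet_config`.
#' @export
configuration <- function(x, type, chain, box, bead = NULL, vel = NULL, time = 0) {
  x <- as.matrix(x)
  dimnames(x) <- NULL
  stopifnot(ncol(x) == 3, length(type) == nrow(x), length(chain) == nrow(x),
            length(box) == 3, all(box > 0), all(is.finite(x)))
  chain <- as.integer(chain)
  if (is.null(bead)) {
    bead <- integer(nrow(x))
    for (cid in unique(chain)) {
      idx <- which(chain == cid)
      bead[idx] <- seq_along(idx) - 1L
    }
  }
  bead <- as.integer(bead)
  for (cid in unique(chain)) {
    b <- sort(bead[chain == cid])
    if (!identical(b, seq_along(b) - 1L)) {
      stop("bead indices within chain ", cid, " must be contiguous 0..n-1")
    }
  }
  structure(list(x = x, type = as.character(type), chain = chain, bead = bead,
                 box = as.numeric(box), vel = vel, time = time),
            class = "condnet_config")
}

#' @export
print.condnet_config <- function(x, ...) {
  cat(sprintf("<condnet_config> %d beads, %d chains, box %.1f x %.1f x %.1f A, t = %g ns\n",
              nrow(x$x), length(unique(x$chain)), x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

#' Construct a trajectory
#'
#' @param frames List of [configuration()] objects with identical bead counts
#'   and chain topology, strictly increasing timestamps.
#' @param dt_ns Frame spacing in ns (informational; timestamps govern).
#' @return An object of class `condnet_traj`.
#' @export
trajectory <- function(frames, dt_ns = NA_real_) {
  stopifnot(length(frames) >= 1, all(vapply(frames, inherits, TRUE, "condnet_config")))
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) stop("frame timestamps must be strictly increasing")
  n0 <- nrow(frames[[1]]$x)
  for (f in frames) {
    if (nrow(f$x) != n0 || !identical(f$chain, frames[[1]]$chain)) {
      stop("bead count and chain topology must be constant across frames")
    }
  }
  structure(list(frames = frames, dt_ns = dt_ns), class = "condnet_traj")
}

#' @export
print.condnet_traj <- function(x, ...) {
  cat(sprintf("<condnet_traj> %d frames, %d beads, t = %g..%g ns\n",
              length(x$frames), nrow(x$frames[[1]]$x),
              x$frames[[1]]$time, x$frames[[length(x$frames)]]$time))
  invisible(x)
}

#' Minimum-image distance
#'
#' @param a,b Positions (length-3 vectors or n x 3 matrices).
#' @param box Orthorhombic box lengths (A).
#' @return Euclidean distance(s) under the minimum-image convention.
#' @export
minimum_image_distance <- function(a, b, box) {
  stopifnot(all(box > 0))
  a <- rbind(a); b <- rbind(b)
  d <- a - b
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  unname(sqrt(rowSums(d * d)))
}

# Unwrap one chain's coordinates by chaining nearest images along the
# backbone (bead order). Errors if an unwrapped bond exceeds half the box.
unwrap_chain <- function(xc, box) {
  n <- nrow(xc)
  if (n == 1L) return(xc)
  out <- xc
  for (i in 2:n) {
    d <- xc[i, ] - out[i - 1, ]
    d <- d - box * round(d / box)
    if (sqrt(sum(d * d)) > min(box) / 2) {
      stop("chain broken: bond longer than half the box after unwrapping")
    }
    out[i, ] <- out[i - 1, ] + d
  }
  out
}

#' Mass-weighted chain center of mass
#'
#' Beads are unwrapped via nearest-image chaining along the backbone before
#' averaging, so the result is independent of which periodic image each bead
#' is stored in. The returned position may lie outside the primary box.
#'
#' @param conf A [configuration()].
#' @param chain_id Chain id.
#' @param model Energy model supplying residue masses (default packaged table).
#' @return Length-3 position (A).
#' @export
chain_com <- function(conf, chain_id, model = mpipi_model()) {
  idx <- which(conf$chain == chain_id)
  if (length(idx) == 0L) stop("chain id not present: ", chain_id)
  idx <- idx[order(conf$bead[idx])]
  xc <- unwrap_chain(conf$x[idx, , drop = FALSE], conf$box)
  mass <- model$params[conf$type[idx], "mass"]
  colSums(xc * mass) / sum(mass)
}

#' Centers of mass of all chains
#'
#' @inheritParams chain_com
#' @return Matrix with one row per chain (rownames = chain ids).
#' @export
all_chain_coms <- function(conf, model = mpipi_model()) {
  ids <- sort(unique(conf$chain))
  out <- t(vapply(ids, function(cid) chain_com(conf, cid, model), numeric(3)))
  rownames(out) <- ids
  out
}

#' Write a trajectory as a LAMMPS text dump
#'
#' Atom types are written as integer indices into the residue alphabet sorted
#' alphabetically over the types present; the mapping is returned invisibly.
#'
#' @param traj A [condnet_traj] or single [configuration()].
#' @param path Output path.
#' @param timestep_fs Conversion used to render the ns timestamps as integer
#'   LAMMPS timesteps (default 10 fs per step).
#' @return Invisibly, the type mapping (character vector indexed by type id).
#' @export
write_lammps_dump <- function(traj, path, timestep_fs = 10) {
  if (inherits(traj, "condnet_config")) traj <- trajectory(list(traj))
  type_levels <- sort(unique(unlist(lapply(traj$frames, function(f) f$type))))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    step <- round(f$time * 1e6 / timestep_fs)  # ns -> fs -> steps
    writeLines(c("ITEM: TIMESTEP", format(step, scientific = FALSE),
                 "ITEM: NUMBER OF ATOMS", as.character(nrow(f$x)),
                 "ITEM: BOX BOUNDS pp pp pp",
                 sprintf("%.10g %.10g", 0, f$box[1]),
                 sprintf("%.10g %.10g", 0, f$box[2]),
                 sprintf("%.10g %.10g", 0, f$box[3]),
                 "ITEM: ATOMS id mol type x y z"), con)
    writeLines(sprintf("%d %d %d %.10g %.10g %.10g",
                       seq_len(nrow(f$x)), f$chain, match(f$type, type_levels),
                       f$x[, 1], f$x[, 2], f$x[, 3]), con)
  }
  invisible(type_levels)
}

#' Read a LAMMPS text dump into a trajectory
#'
#' Supports `x y z` (unscaled) and `xs ys zs` (scaled) coordinate columns;
#' scaled coordinates are unscaled to A using the box bounds. Beads are sorted
#' by atom id. Chain ids come from a `mol` column when present, otherwise
#' from `topology` (a per-id integer map, e.g. from [read_lammps_data()]).
#'
#' @param path Dump file path.
#' @param topology Optional integer vector: chain id for each atom id.
#' @param type_map Optional character vector mapping numeric atom types to
#'   residue codes; defaults to treating the dump's type column as codes when
#'   non-numeric, else to an error unless supplied.
#' @param timestep_fs fs per LAMMPS timestep for timestamp conversion.
#' @return A [condnet_traj].
#' @export
read_lammps_dump <- function(path, topology = NULL, type_map = NULL,
                             timestep_fs = 10) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L; nframe <- 0L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "ITEM: TIMESTEP")) {
      stop("parse error at line ", i, ": expected ITEM: TIMESTEP")
    }
    nframe <- nframe + 1L
    if (i + 8L > length(lines)) stop("truncated frame ", nframe)
    step <- as.numeric(lines[i + 1L])
    natoms <- as.integer(lines[i + 3L])
    bounds <- do.call(rbind, lapply(lines[i + 5:7], function(l)
      as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]][1:2])))
    box <- bounds[, 2] - bounds[, 1]
    header <- strsplit(trimws(lines[i + 8L]), "[[:space:]]+")[[1]]
    if (header[1] != "ITEM:" || header[2] != "ATOMS") {
      stop("parse error in frame ", nframe, ": expected ITEM: ATOMS")
    }
    cols <- header[-(1:2)]
    scaled <- all(c("xs", "ys", "zs") %in% cols)
    if (!scaled && !all(c("x", "y", "z") %in% cols)) {
      stop("frame ", nframe, ": dump must contain x/y/z or xs/ys/zs columns")
    }
    if (!"id" %in% cols) stop("frame ", nframe, ": dump must contain an id column")
    if (i + 8L + natoms > length(lines)) {
      stop("truncated frame ", nframe, ": expected ", natoms, " atom lines")
    }
    body <- lines[(i + 9L):(i + 8L + natoms)]
    m <- matrix(unlist(strsplit(trimws(body), "[[:space:]]+")),
                nrow = natoms, byrow = TRUE)
    if (ncol(m) != length(cols)) stop("frame ", nframe, ": column count mismatch")
    colnames(m) <- cols
    id <- as.integer(m[, "id"])
    ord <- order(id)
    m <- m[ord, , drop = FALSE]; id <- id[ord]
    if (scaled) {
      x <- cbind(as.numeric(m[, "xs"]) * box[1] + bounds[1, 1],
                 as.numeric(m[, "ys"]) * box[2] + bounds[2, 1],
                 as.numeric(m[, "zs"]) * box[3] + bounds[3, 1])
    } else {
      x <- cbind(as.numeric(m[, "x"]), as.numeric(m[, "y"]), as.numeric(m[, "z"]))
    }
    rawtype <- m[, "type"]
    if (!is.null(type_map)) {
      type <- type_map[as.integer(rawtype)]
    } else if (suppressWarnings(all(!is.na(as.numeric(rawtype))))) {
      stop("numeric atom types in dump: supply type_map to map them to residues")
    } else {
      type <- rawtype
    }
    chain <- if ("mol" %in% cols) {
      as.integer(m[, "mol"])
    } else if (!is.null(topology)) {
      topology[id]
    } else {
      stop("no mol column in dump and no topology map supplied")
    }
    frames[[nframe]] <- configuration(x, type, chain, box,
                                      time = step * timestep_fs / 1e6)
    i <- i + 9L + natoms
  }
  if (length(frames) == 0L) stop("no frames found in ", path)
  trajectory(frames)
}

#' Read chain topology from a LAMMPS data file
#'
#' Parses the `Atoms` section (molecule ids) of a LAMMPS data file written in
#' the `atom_style full`/`molecular` layout: `id mol type ...`.
#'
#' @param path Data file path.
#' @return Integer vector: chain (molecule) id per atom id.
#' @export
read_lammps_data <- function(path) {
  lines <- readLines(path)
  natoms_line <- grep("^[[:space:]]*[0-9]+[[:space:]]+atoms", lines, value = TRUE)
  if (length(natoms_line) == 0L) stop("no 'atoms' count line in data file")
  natoms <- as.integer(sub("^[[:space:]]*([0-9]+).*", "\\1", natoms_line[1]))
  at <- grep("^Atoms", lines)
  if (length(at) == 0L) stop("no Atoms section in data file")
  body <- lines[(at[1] + 2L):(at[1] + 1L + natoms)]
  parts <- strsplit(trimws(body), "[[:space:]]+")
  id <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  mol <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  out <- integer(max(id))
  out[id] <- mol
  out
}

#' Write a minimal LAMMPS data file (atoms + bonds)
#'
#' Bonds connect consecutive beads within each chain.
#'
#' @param conf A [configuration()].
#' @param path Output path.
#' @param model Energy model supplying residue masses.
#' @return `path`, invisibly.
#' @export
write_lammps_data <- function(conf, path, model = mpipi_model()) {
  type_levels <- sort(unique(conf$type))
  n <- nrow(conf$x)
  ord <- order(conf$chain, conf$bead)
  bonds <- do.call(rbind, lapply(split(ord, conf$chain[ord]), function(idx) {
    if (length(idx) < 2) return(NULL)
    cbind(idx[-length(idx)], idx[-1])
  }))
  nb <- if (is.null(bonds)) 0L else nrow(bonds)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("condnet data file", "",
               sprintf("%d atoms", n), sprintf("%d bonds", nb),
               sprintf("%d atom types", length(type_levels)),
               if (nb > 0) "1 bond types", "",
               sprintf("0 %.10g xlo xhi", conf$box[1]),
               sprintf("0 %.10g ylo yhi", conf$box[2]),
               sprintf("0 %.10g zlo zhi", conf$box[3]), "", "Masses", ""), con)
  writeLines(sprintf("%d %.4f", seq_along(type_levels),
                     model$params[type_levels, "mass"]), con)
  writeLines(c("", "Atoms", ""), con)
  writeLines(sprintf("%d %d %d 0.0 %.10g %.10g %.10g",
                     1:n, conf$chain, match(conf$type, type_levels),
                     conf$x[, 1], conf$x[, 2], conf$x[, 3]), con)
  if (nb > 0) {
    writeLines(c("", "Bonds", ""), con)
    writeLines(sprintf("%d 1 %d %d", 1:nb, bonds[, 1], bonds[, 2]), con)
  }
  invisible(path)
}
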