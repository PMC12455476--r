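# Single-chain structural metrics: gyration tensor, radius of gyration,
# relative shape anisotropy kappa^2, the freely jointed chain reference, and
# log-log power-law fits of chain metrics against network centrality.

#' Gyration tensor and radius of gyration of a chain
#'
#' Mass-weighted gyration tensor about the chain center of mass,
#' `S[a,b] = sum_i m_i (r_i - r_com)_a (r_i - r_com)_b / sum_i m_i`,
#' eigen-decomposed with eigenvalues sorted descending. `R_g = sqrt(tr S)`.
#' Coordinates must be unwrapped.
#'
#' @param x n x 3 matrix of bead positions (A), n >= 2.
#' @param masses Bead masses; defaults to equal weights (the polymer-theory
#'   convention).
#' @return Object of class `chain_shape`: `Rg` (A), `lambda` (eigenvalues,
#'   A^2, descending), `kappa2` (filled by [shape_anisotropy()], attached
#'   here for convenience unless all eigenvalues are zero).
#' @export
gyration_tensor <- function(x, masses = NULL) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 3, nrow(x) >= 2)
  n <- nrow(x)
  if (is.null(masses)) masses <- rep(1, n)
  stopifnot(length(masses) == n, all(masses > 0))
  com <- colSums(x * masses) / sum(masses)
  d <- x - matrix(com, n, 3, byrow = TRUE)
  S <- crossprod(d * masses, d) / sum(masses)
  lambda <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 decreasing = TRUE)
  lambda <- pmax(lambda, 0)
  kappa2 <- if (sum(lambda) > 0) shape_anisotropy(lambda) else NA_real_
  structure(list(Rg = sqrt(sum(lambda)), lambda = lambda, kappa2 = kappa2),
            class = "chain_shape")
}

#' @export
print.chain_shape <- function(x, ...) {
  cat(sprintf("<chain_shape> Rg = %.2f A, lambda = (%.2f, %.2f, %.2f) A^2, kappa2 = %.3f\n",
              x$Rg, x$lambda[1], x$lambda[2], x$lambda[3], x$kappa2))
  invisible(x)
}

#' Relative shape anisotropy
#'
#' `kappa2 = 1 - 3 (l1 l2 + l2 l3 + l3 l1) / (l1 + l2 + l3)^2`, bounded in
#' \[0, 1\]: 0 for a spherically isotropic mass distribution, 1 for a
#' collinear one. Scale invariant.
#'
#' @param lambda Length-3 vector of gyration-tensor eigenvalues (or `l1` with
#'   `l2`, `l3` given separately).
#' @param l2,l3 Optional second and third eigenvalues.
#' @return kappa^2.
#' @export
shape_anisotropy <- function(lambda, l2 = NULL, l3 = NULL) {
  if (!is.null(l2)) lambda <- c(lambda, l2, l3)
  stopifnot(length(lambda) == 3, all(lambda >= 0))
  s <- sum(lambda)
  if (s == 0) stop("shape anisotropy undefined for all-zero eigenvalues")
  1 - 3 * (lambda[1] * lambda[2] + lambda[2] * lambda[3] +
             lambda[3] * lambda[1]) / s^2
}

#' Shape metrics of one chain in a configuration
#'
#' @param conf A [configuration()].
#' @param chain_id Chain id.
#' @param model Energy model for masses; `NULL` for equal weights.
#' @return A `chain_shape` (see [gyration_tensor()]).
#' @export
chain_shape <- function(conf, chain_id, model = mpipi_model()) {
  idx <- which(conf$chain == chain_id)
  if (length(idx) == 0) stop("chain id not present: ", chain_id)
  idx <- idx[order(conf$bead[idx])]
  xc <- unwrap_chain(conf$x[idx, , drop = FALSE], conf$box)
  masses <- if (is.null(model)) NULL else model$params[conf$type[idx], "mass"]
  gyration_tensor(xc, masses)
}

#' Mean shape anisotropy of freely jointed ideal chains
#'
#' Monte-Carlo estimate of the mean kappa^2 over freely jointed chains of `N`
#' fixed-length bonds with isotropic random directions (equal-mass beads).
#' Converges to ~0.39 for long chains, the classic ideal-chain reference.
#'
#' @param N Number of bonds (>= 10).
#' @param n_samples Number of chains (>= 1000).
#' @param seed Integer seed.
#' @return Mean kappa^2.
#' @examples
#' \donttest{ideal_chain_kappa2(150, 1e4, seed = 1)}
#' @export
ideal_chain_kappa2 <- function(N, n_samples = 1e4, seed = 1L) {
  stopifnot(N >= 10, n_samples >= 1000)
  set.seed(seed)
  k2 <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    steps <- matrix(stats::rnorm(3 * N), N, 3)
    steps <- steps / sqrt(rowSums(steps^2))
    x <- rbind(0, apply(steps, 2, cumsum))
    k2[s] <- gyration_tensor(x)$kappa2
  }
  mean(k2)
}

#' Power-law fit in log10-log10 space
#'
#' Least-squares line `log10(y) = b + m log10(x)` over points with
#' `x > floor` (zero-centrality chains are excluded before the log
#' transform) and `y > 0`.
#'
#' @param x Predictor (e.g. per-chain betweenness centrality).
#' @param y Response (e.g. per-chain R_g or kappa^2).
#' @param floor Minimum x included (default 0, i.e. strictly positive x).
#' @return Object of class `powerlaw_fit` with `slope`, `intercept`,
#'   `r_squared`, `n`, `domain`.
#' @export
loglog_power_fit <- function(x, y, floor = 0) {
  keep <- is.finite(x) & is.finite(y) & x > floor & y > 0
  if (sum(keep) < 10) stop("need at least 10 usable points with x > floor")
  lx <- log10(x[keep]); ly <- log10(y[keep])
  fit <- stats::lm(ly ~ lx)
  tss <- sum((ly - mean(ly))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n = sum(keep),
                 domain = range(x[keep])),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> log10(y) = %.3f %+.3f log10(x)  (R^2 = %.3f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @export
coef.powerlaw_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Per-chain conformation/centrality table for a frame
#'
#' @param conf A [configuration()].
#' @param graph An `interaction_graph` for the same frame.
#' @param model Energy model for masses.
#' @return data.frame with columns `frame`, `chain`, `C_B`, `Rg`, `kappa2`.
#' @export
conformation_table <- function(conf, graph, model = mpipi_model()) {
  cb <- betweenness_centrality(graph)
  ids <- names(cb)
  shapes <- lapply(ids, function(cid) chain_shape(conf, as.integer(cid), model))
  data.frame(frame = conf$time, chain = ids,
             C_B = unname(cb),
             Rg = vapply(shapes, function(s) s$Rg, numeric(1)),
             kappa2 = vapply(shapes, function(s) s$kappa2, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
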