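#' Build a C-alpha elastic network
#'
#' Every pair of C-alpha atoms is connected by a harmonic spring whose force
#' constant attenuates exponentially with the reference distance,
#' `k(R0) = C * exp(-|R0|^2 / r0^2)`, keeping the force field short-ranged so
#' that interactions between candidate domains are negligible. Pairs whose
#' constant falls below `prune * C` are pruned.
#'
#' @param structure A [ca_structure()].
#' @param C Force-constant scale, kJ/mol/nm^2. Default 47400.
#' @param r0 Decay length, nm. Not fixed by the underlying method; default
#'   0.3 nm (the classic exponential-decay scale), swept in the benchmark.
#' @param prune Relative cutoff below which pair constants are dropped.
#' @return An `elastic_network`: list with symmetric matrices `k`
#'   (kJ/mol/nm^2, pruned entries 0) and `R0` (nm), plus `C`, `r0`.
#' @export
build_network <- function(structure, C = 47400, r0 = 0.3, prune = 1e-10) {
  stopifnot(inherits(structure, "ca_structure"), C > 0, r0 > 0)
  pos <- structure$positions
  R0 <- as.matrix(stats::dist(pos))
  if (any(R0[upper.tri(R0)] < 1e-9))
    stop("duplicate coordinates: two C-alpha atoms at zero distance")
  k <- C * exp(-R0^2 / r0^2)
  diag(k) <- 0
  k[k < prune * C] <- 0
  structure(list(k = k, R0 = R0, C = C, r0 = r0),
            class = "elastic_network")
}

# Assemble the 3N x 3N Hessian of E = sum_pairs 1/2 k (|Rij| - |R0ij|)^2
# evaluated at the reference structure: block_ij = -k u u^T for connected
# pairs (u = unit reference separation), diagonal blocks minus the row sums.
.enm_hessian <- function(network, structure) {
  pos <- structure$positions
  n <- structure$n
  H <- matrix(0, 3 * n, 3 * n)
  idx <- which(network$k > 0 & upper.tri(network$k), arr.ind = TRUE)
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1]; j <- idx[p, 2]
    u <- pos[j, ] - pos[i, ]
    u <- u / sqrt(sum(u^2))
    blk <- network$k[i, j] * tcrossprod(u)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  H
}

#' Approximate normal modes of an elastic network
#'
#' Diagonalizes the network Hessian, removes the six rigid-body zero modes and
#' returns the lowest-frequency internal modes, each rescaled so the summed
#' squared displacement equals `f * N` (f = 1 nm^2 by default). The
#' per-residue deformation-energy profile and its atom average are attached
#' for every mode.
#'
#' @param network An [build_network()] result.
#' @param structure The [ca_structure()] the network was built from.
#' @param n_modes Number of internal modes to keep (default all).
#' @param f Normalization scale, nm^2.
#' @return A `normal_mode_set`: list with `modes` (list of n x 3 displacement
#'   matrices), `eigenvalues`, `f`, `avg_deformation_energy` (kJ/mol per
#'   mode) and `per_atom_energy` (n x n_modes matrix, kJ/mol).
#' @export
compute_modes <- function(network, structure, n_modes = NULL, f = 1) {
  stopifnot(inherits(network, "elastic_network"),
            inherits(structure, "ca_structure"), f > 0)
  n <- structure$n
  g <- igraph::graph_from_adjacency_matrix(network$k > 0, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop("elastic network is disconnected (components of sizes ",
         paste(comp$csize, collapse = ", "),
         "); increase r0 or check the structure")
  H <- .enm_hessian(network, structure)
  eig <- eigen(H, symmetric = TRUE)
  evals <- rev(eig$values)
  evecs <- eig$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  tol <- max(abs(evals)) * 1e-9
  n_zero <- sum(abs(evals) < tol)
  if (n_zero < 6)
    stop("found ", n_zero, " near-zero modes instead of 6; ",
         "degenerate (collinear) geometry")
  if (n_zero > 6)
    stop("found ", n_zero,
         " near-zero modes; the network is mechanically under-constrained")
  avail <- 3 * n - 6
  if (is.null(n_modes)) n_modes <- avail
  if (n_modes > avail)
    stop("n_modes must be at most 3N - 6 = ", avail)
  modes <- vector("list", n_modes)
  scale <- sqrt(f * n)     # eigenvectors have unit norm
  for (m in seq_len(n_modes))
    modes[[m]] <- matrix(evecs[, 6 + m], ncol = 3, byrow = TRUE) * scale
  per_atom <- vapply(modes, function(d)
    .deformation_profile(structure, network, d), numeric(n))
  per_atom <- matrix(per_atom, nrow = n)
  structure(list(modes = modes, eigenvalues = evals[6 + seq_len(n_modes)],
                 f = f, n_atoms = n,
                 avg_deformation_energy = colMeans(per_atom),
                 per_atom_energy = per_atom),
            class = "normal_mode_set")
}

# per-atom deformation energy of one displacement field (kJ/mol):
# E_i = 1/2 sum_j k(R0ij) |(d_i - d_j) . R0ij|^2 / |R0ij|^2
.deformation_profile <- function(structure, network, d) {
  n <- structure$n
  pos <- structure$positions
  E <- numeric(n)
  idx <- which(network$k > 0 & upper.tri(network$k), arr.ind = TRUE)
  for (p in seq_len(nrow(idx))) {
    i <- idx[p, 1]; j <- idx[p, 2]
    rvec <- pos[j, ] - pos[i, ]
    proj <- sum((d[i, ] - d[j, ]) * rvec)^2 / sum(rvec^2)
    e <- 0.5 * network$k[i, j] * proj
    E[i] <- E[i] + e
    E[j] <- E[j] + e
  }
  E
}

#' Per-residue deformation energy of a displacement field
#'
#' The deformation energy of residue i is the harmonic strain of its network
#' bonds under the displacement field: half the sum over partners j of
#' `k(R0ij) * ((d_i - d_j) . R0ij)^2 / |R0ij|^2`. Rigid-body fields (uniform
#' translations, infinitesimal rotations) have zero deformation energy. Low
#' values mark internally rigid regions.
#'
#' @param structure A [ca_structure()].
#' @param network The matching [build_network()] result.
#' @param mode An n x 3 displacement matrix (normally one entry of
#'   `compute_modes()$modes`).
#' @param threshold Rigid/flexible threshold in kJ/mol (for the reported
#'   fraction only).
#' @return A `deformation_profile`: list with `per_atom_energy` (kJ/mol),
#'   `threshold` and `fraction_below_threshold`.
#' @export
deformation_energy <- function(structure, network, mode, threshold = 400) {
  stopifnot(inherits(structure, "ca_structure"),
            inherits(network, "elastic_network"))
  mode <- as.matrix(mode)
  if (!all(dim(mode) == c(structure$n, 3L)))
    stop("mode must be an n x 3 displacement matrix")
  E <- .deformation_profile(structure, network, mode)
  structure(list(per_atom_energy = E, threshold = threshold,
                 fraction_below_threshold = mean(E < threshold)),
            class = "deformation_profile")
}

#' Select low-frequency modes below a deformation-energy threshold
#'
#' Picks the maximal prefix of internal modes whose per-mode average
#' deformation energy stays (strictly) below the threshold, and reports, for
#' each cumulative mode set of size k, the fraction of residues whose summed
#' deformation energy over modes 1..k is below the threshold. Adding modes
#' can only raise summed energies, so this fraction is non-increasing in k.
#'
#' @param modes A [compute_modes()] result.
#' @param threshold Deformation-energy threshold, kJ/mol (default 400, the
#'   customary starting point for separating rigid from flexible regions).
#' @return List with `selected` (mode indices), `avg_energy` and a data.frame
#'   `cumulative` (n_modes, fraction_below_threshold).
#' @export
mode_selection_report <- function(modes, threshold = 400) {
  stopifnot(inherits(modes, "normal_mode_set"), threshold > 0)
  avg <- modes$avg_deformation_energy
  if (!length(avg)) stop("empty mode set")
  below <- avg < threshold
  n_sel <- if (below[1]) which.max(c(!below, TRUE)) - 1L else 0L
  if (n_sel == 0L)
    warning("no modes below the deformation-energy threshold")
  cum <- t(apply(modes$per_atom_energy, 1, cumsum))
  if (modes$n_atoms == 1L) cum <- matrix(cum, nrow = 1)
  fractions <- colMeans(cum < threshold)
  list(selected = seq_len(n_sel),
       avg_energy = avg,
       cumulative = data.frame(n_modes = seq_along(avg),
                               fraction_below_threshold = fractions))
}
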