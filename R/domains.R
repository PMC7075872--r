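#' Partition a structure into occupied cubic compartments
#'
#' The structure is binned on a cubic grid anchored at the axis-aligned
#' bounding-box minimum (half-open intervals, so each atom lands in exactly
#' one cube). A cube is admitted to the domain analysis iff it contains at
#' least `min_atoms` atoms and the mean per-atom deformation energy of its
#' atoms is strictly below `threshold`.
#'
#' @param structure A [ca_structure()].
#' @param profile Numeric per-atom deformation energies (kJ/mol), e.g. a row
#'   sum of `compute_modes()$per_atom_energy` over the selected modes, or a
#'   [deformation_energy()] profile's `per_atom_energy`.
#' @param cube_side Cube edge length, nm (default 1.2).
#' @param min_atoms Minimum atom count per admitted cube (default 3).
#' @param threshold Admission threshold on mean energy, kJ/mol (default 400).
#' @return Data.frame of admitted cubes: `cube` (id string), `n_atoms`,
#'   `mean_energy`, and a list-column `atoms` of atom indices.
#' @export
partition_cubes <- function(structure, profile, cube_side = 1.2,
                            min_atoms = 3, threshold = 400) {
  stopifnot(inherits(structure, "ca_structure"), cube_side > 0,
            min_atoms >= 1, length(profile) == structure$n)
  pos <- structure$positions
  lo <- apply(pos, 2, min)
  bins <- floor(sweep(pos, 2, lo) / cube_side)
  key <- paste(bins[, 1], bins[, 2], bins[, 3], sep = ",")
  groups <- split(seq_len(structure$n), factor(key, unique(key)))
  res <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    me <- mean(profile[idx])
    if (length(idx) >= min_atoms && me < threshold)
      data.frame(cube = k, n_atoms = length(idx), mean_energy = me)
  })
  keep <- !vapply(res, is.null, logical(1))
  if (!any(keep)) {
    warning("no cubes admitted (all below min_atoms or above threshold)")
    out <- data.frame(cube = character(), n_atoms = integer(),
                      mean_energy = numeric())
    out$atoms <- list()
    return(out)
  }
  out <- do.call(rbind, res[keep])
  out$atoms <- unname(groups[out$cube])
  rownames(out) <- NULL
  out
}

#' Least-squares rigid-body fit of a displacement field
#'
#' Fits `d_i = T + Omega x R_i` over the atoms of one cube, with positions
#' referenced to the cube centroid. Exact rigid fields are recovered with
#' zero residual; otherwise the linear least-squares solution is returned.
#'
#' @param positions n x 3 atom positions (nm), n >= 3, non-collinear.
#' @param displacements n x 3 displacement field.
#' @return A `rigid_body_motion`: list with `T_vec`, `Omega`, `residual`
#'   (sum of squared misfits) and `ok` (FALSE for degenerate geometry, in
#'   which case the other fields are NA).
#' @export
fit_rigid_body <- function(positions, displacements) {
  positions <- as.matrix(positions); displacements <- as.matrix(displacements)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3L, all(dim(displacements) == c(n, 3L)))
  if (n < 3L)
    return(structure(list(T_vec = rep(NA_real_, 3), Omega = rep(NA_real_, 3),
                          residual = NA_real_, ok = FALSE),
                     class = "rigid_body_motion"))
  ctr <- colMeans(positions)
  rel <- sweep(positions, 2, ctr)
  # d = T + Omega x r  =>  rows [I | -skew(r)] %*% c(T, Omega)
  A <- matrix(0, 3 * n, 6)
  for (i in seq_len(n)) {
    r <- rel[i, ]
    rows <- (3 * i - 2):(3 * i)
    A[rows, 1:3] <- diag(3)
    A[rows, 4:6] <- -matrix(c(0, -r[3], r[2],
                              r[3], 0, -r[1],
                              -r[2], r[1], 0), 3, 3, byrow = TRUE)
  }
  b <- as.vector(t(displacements))
  qrA <- qr(A)
  if (qrA$rank < 6L)
    return(structure(list(T_vec = rep(NA_real_, 3), Omega = rep(NA_real_, 3),
                          residual = NA_real_, ok = FALSE),
                     class = "rigid_body_motion"))
  x <- qr.coef(qrA, b)
  structure(list(T_vec = x[1:3], Omega = x[4:6],
                 residual = sum((b - A %*% x)^2), ok = TRUE),
            class = "rigid_body_motion")
}

#' Similarity of two rigid-body motions
#'
#' `S = 3 |Oa + Ob| / |Oa - Ob| + |Ta + Tb| / |Ta - Tb|`; rotation vectors
#' sort out domains more reliably and get triple weight. The expression is
#' singular for identical motions, so each quotient is capped at `s_cap`
#' whenever its denominator falls below `guard` — clustering only needs the
#' ordering of similarities, not their magnitude.
#'
#' @param a,b [fit_rigid_body()] results.
#' @param s_cap Cap per quotient (default 1e6).
#' @param guard Denominator guard (default 1e-12).
#' @return Similarity score (dimensionless).
#' @export
pair_similarity <- function(a, b, s_cap = 1e6, guard = 1e-12) {
  stopifnot(inherits(a, "rigid_body_motion"), inherits(b, "rigid_body_motion"),
            a$ok, b$ok)
  quot <- function(num, den) if (den < guard) s_cap else num / den
  nrm <- function(v) sqrt(sum(v^2))
  3 * quot(nrm(a$Omega + b$Omega), nrm(a$Omega - b$Omega)) +
    quot(nrm(a$T_vec + b$T_vec), nrm(a$T_vec - b$T_vec))
}

#' Cluster cubes into dynamic domains by rigid-motion similarity
#'
#' Cube pairs whose similarity (strictly) exceeds `max(S) / c` are linked;
#' connected components of the resulting graph are the dynamic domains. The
#' coarseness `c` must exceed 1: small `c` makes the rule restrictive (many
#' small domains), large `c` eventually merges everything into one domain.
#' Labels are propagated from cubes to their member residues; residues in no
#' admitted cube are off-domain (`NA`).
#'
#' @param cubes Admitted cubes from [partition_cubes()].
#' @param fits List of [fit_rigid_body()] results, one per cube row.
#' @param coarseness_c Coarseness parameter, > 1 (default 10).
#' @param n_atoms Total number of residues (for the residue label vector).
#' @return A `domain_decomposition`: list with `cube_labels` (integer per
#'   cube, NA for degenerate fits), `residue_labels` (integer per residue, NA
#'   off-domain), `similarities` (matrix), `threshold` and `n_domains`.
#' @export
cluster_domains <- function(cubes, fits, coarseness_c = 10, n_atoms) {
  stopifnot(coarseness_c > 1, nrow(cubes) == length(fits))
  ok <- vapply(fits, function(f) isTRUE(f$ok), logical(1))
  nc <- sum(ok)
  labels <- rep(NA_integer_, nrow(cubes))
  S <- matrix(NA_real_, nrow(cubes), nrow(cubes))
  if (nc < 2L) {
    if (nc == 1L) {
      warning("fewer than 2 usable cubes; single trivial domain")
      labels[ok] <- 1L
    } else warning("no usable cubes; no domains formed")
  } else {
    iok <- which(ok)
    for (ai in seq_along(iok)) for (bi in seq_along(iok)) {
      if (bi <= ai) next
      s <- pair_similarity(fits[[iok[ai]]], fits[[iok[bi]]])
      S[iok[ai], iok[bi]] <- s
      S[iok[bi], iok[ai]] <- s
    }
    smax <- max(S, na.rm = TRUE)
    thr <- smax / coarseness_c
    adj <- !is.na(S) & S > thr
    g <- igraph::graph_from_adjacency_matrix(adj[iok, iok, drop = FALSE],
                                             mode = "undirected")
    labels[iok] <- igraph::components(g)$membership
  }
  residue_labels <- rep(NA_integer_, n_atoms)
  for (ci in seq_len(nrow(cubes)))
    if (!is.na(labels[ci])) residue_labels[cubes$atoms[[ci]]] <- labels[ci]
  structure(list(cube_labels = labels, residue_labels = residue_labels,
                 similarities = S,
                 threshold = if (nc >= 2L) max(S, na.rm = TRUE) / coarseness_c
                             else NA_real_,
                 coarseness_c = coarseness_c,
                 n_domains = length(unique(stats::na.omit(labels)))),
            class = "domain_decomposition")
}

#' Full dynamic-domain decomposition of a structure
#'
#' Convenience wrapper: network -> modes -> mode selection -> cumulative
#' deformation profile -> cube partition -> rigid-body fits -> similarity
#' clustering.
#'
#' @param structure A [ca_structure()].
#' @param C,r0 Elastic-network parameters (see [build_network()]).
#' @param n_modes Modes to compute (default `min(30, 3N - 6)`).
#' @param threshold Deformation-energy threshold, kJ/mol.
#' @param cube_side,min_atoms Cube admission parameters.
#' @param coarseness_c Clustering coarseness.
#' @return List with `modes`, `selection`, `profile` (per-residue summed
#'   energy over selected modes), `cubes`, `fits`, `domains`.
#' @export
decompose_domains <- function(structure, C = 47400, r0 = 0.3, n_modes = NULL,
                              threshold = 400, cube_side = 1.2, min_atoms = 3,
                              coarseness_c = 10) {
  if (is.null(n_modes)) n_modes <- min(30L, 3L * structure$n - 6L)
  net <- build_network(structure, C = C, r0 = r0)
  modes <- compute_modes(net, structure, n_modes = n_modes)
  sel <- mode_selection_report(modes, threshold = threshold)
  use <- if (length(sel$selected)) sel$selected else seq_len(n_modes)
  profile <- rowSums(modes$per_atom_energy[, use, drop = FALSE])
  cubes <- partition_cubes(structure, profile, cube_side = cube_side,
                           min_atoms = min_atoms, threshold = threshold)
  field <- Reduce(`+`, modes$modes[use])  # summed low-frequency field
  fits <- lapply(cubes$atoms, function(idx)
    fit_rigid_body(structure$positions[idx, , drop = FALSE],
                   field[idx, , drop = FALSE]))
  domains <- if (nrow(cubes)) {
    cluster_domains(cubes, fits, coarseness_c = coarseness_c,
                    n_atoms = structure$n)
  } else NULL
  list(modes = modes, selection = sel, profile = profile, cubes = cubes,
       fits = fits, domains = domains)
}

#' Sweep the elastic-network decay length over candidate values
#'
#' The pair-constant decay length r0 is an open parameter of the network
#' model; this reruns the mode analysis over a set of candidate values and
#' reports, for each, the average deformation energies of chosen modes, the
#' number of modes selected at the threshold, and the fraction of residues
#' below the threshold for a cumulative mode set.
#'
#' @param structure A [ca_structure()].
#' @param r0_values Candidate decay lengths, nm.
#' @param report_modes Mode indices whose average energies to report.
#' @param at_modes Cumulative set size for the reported fraction.
#' @param ... Passed to [build_network()] / [compute_modes()]
#'   (`C`, `n_modes`, `threshold`).
#' @param C,n_modes,threshold See [decompose_domains()].
#' @return Data.frame: one row per r0 with `n_selected`,
#'   `avg_energy_mode<i>` columns and `fraction_below_at_<k>`.
#' @export
enm_benchmark <- function(structure, r0_values = c(0.3, 0.5, 0.7),
                          report_modes = c(16, 17), at_modes = 17,
                          C = 47400, n_modes = NULL, threshold = 400) {
  if (is.null(n_modes))
    n_modes <- min(max(report_modes, at_modes) + 3L, 3L * structure$n - 6L)
  rows <- lapply(r0_values, function(r0) {
    net <- build_network(structure, C = C, r0 = r0)
    modes <- compute_modes(net, structure, n_modes = n_modes)
    sel <- suppressWarnings(mode_selection_report(modes, threshold = threshold))
    row <- data.frame(r0 = r0, n_selected = length(sel$selected))
    for (m in report_modes)
      row[[paste0("avg_energy_mode", m)]] <-
        if (m <= n_modes) modes$avg_deformation_energy[m] else NA_real_
    k <- min(at_modes, n_modes)
    row[[paste0("fraction_below_at_", at_modes)]] <-
      sel$cumulative$fraction_below_threshold[k]
    row
  })
  do.call(rbind, rows)
}
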