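# Geometry, toy-network and toy-chain builders shared across tests.

# ideal alpha-helix C-alpha trace (radius 0.23 nm, rise 0.15 nm, 100 deg)
make_helix_structure <- function(n = 20) {
  i <- seq_len(n) - 1
  ca_structure(cbind(0.23 * cos(i * 100 * pi / 180),
                     0.23 * sin(i * 100 * pi / 180),
                     0.15 * i))
}

# random non-degenerate 3-D cloud with a fully connected network
make_cloud_structure <- function(n = 6, seed = 42, scale = 0.5) {
  set.seed(seed)
  ca_structure(matrix(rnorm(3 * n, sd = scale), n, 3))
}

# independent elastic-network energy for the finite-difference Hessian oracle
enm_energy <- function(x, R0, kmat) {
  n <- nrow(R0)
  pos <- matrix(x, n, 3, byrow = TRUE)
  E <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (kmat[i, j] == 0) next
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    E <- E + 0.5 * kmat[i, j] * (r - R0[i, j])^2
  }
  E
}

# dense symmetric central-difference Hessian of a scalar function (O(h^2))
fd_hessian <- function(fn, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  for (a in seq_len(d)) for (b in a:d) {
    xpp <- x; xpp[a] <- xpp[a] + h; xpp[b] <- xpp[b] + h
    xpm <- x; xpm[a] <- xpm[a] + h; xpm[b] <- xpm[b] - h
    xmp <- x; xmp[a] <- xmp[a] - h; xmp[b] <- xmp[b] + h
    xmm <- x; xmm[a] <- xmm[a] - h; xmm[b] <- xmm[b] - h
    H[a, b] <- H[b, a] <-
      (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * h^2)
  }
  H
}

# two-bead chain with bonds only (angles off, nonbonded negligible):
# the harmonic-dimer toy with analytically known overdamped dynamics
make_dimer_chain <- function(bond_k = 10000, friction = 50, mass = 100) {
  pt <- default_residue_params()
  pt$lj_epsilon <- 0; pt$hbond_epsilon <- 0; pt$charge <- 0
  pt$angle_k <- 0
  pt$friction <- friction
  pt$mass <- mass
  build_chain("AA", params_table = pt, bond_k = bond_k)
}

# freely jointed chain: harmonic bonds only, no angles, no nonbonded
make_ideal_chain <- function(n = 8, bond_k = 10000) {
  pt <- default_residue_params()
  pt$lj_epsilon <- 0; pt$hbond_epsilon <- 0; pt$charge <- 0
  pt$angle_k <- 0
  build_chain(strrep("A", n), params_table = pt, bond_k = bond_k)
}

# exact <(b - b0)^2> and <b^2> of a 3-D harmonic bond by radial quadrature
harmonic_bond_moments <- function(bond_k, b0, kT) {
  w <- function(r) r^2 * exp(-bond_k * (r - b0)^2 / (2 * kT))
  Z <- integrate(w, 0, b0 + 1, rel.tol = 1e-10)$value
  m2 <- integrate(function(r) (r - b0)^2 * w(r), 0, b0 + 1,
                  rel.tol = 1e-10)$value / Z
  b2 <- integrate(function(r) r^2 * w(r), 0, b0 + 1,
                  rel.tol = 1e-10)$value / Z
  list(var_dr = m2, mean_b2 = b2)
}

# block-averaged standard error for correlated series
block_se <- function(x, n_blocks = 20) {
  n <- length(x)
  bs <- floor(n / n_blocks)
  means <- vapply(seq_len(n_blocks), function(b)
    mean(x[((b - 1) * bs + 1):(b * bs)]), numeric(1))
  sd(means) / sqrt(n_blocks)
}

# minimal three-residue PDB text (coordinates in Angstrom)
toy_pdb_lines <- function() {
  c("ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  LYS A   3       8.600   0.000   0.000  1.00  0.00           C",
    "END")
}
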