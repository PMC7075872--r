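# Per-residue coarse-grained parameters. One bead per residue; nonbonded
# attraction scales with Kyte-Doolittle hydropathy, bead size with residue
# mass, charges are the net side-chain charges at neutral pH, and polar
# amide side chains (Asn/Gln) carry an extra short-range attraction standing
# in for their hydrogen-bonding propensity. Proline beads get a stiffer,
# kinked angle term.

.kd_hydropathy <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

.residue_mass <- c(
  A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14, Q = 128.13,
  E = 129.12, G = 57.05, H = 137.14, I = 113.16, L = 113.16, K = 128.17,
  M = 131.19, F = 147.18, P = 97.12, S = 87.08, T = 101.10, W = 186.21,
  Y = 163.18, V = 99.13)

#' Default coarse-grained residue parameter table
#'
#' One row per standard amino acid. Columns: `code`; `mass` (amu); `friction`
#' (ps^-1, uniform solvent friction); `charge` (e: Lys/Arg +1, Asp/Glu -1);
#' `lj_epsilon` (kJ/mol, hydropathy-scaled pairwise attraction, 0.2-1.2);
#' `lj_sigma` (nm, scaled with residue volume); `angle_k` (kJ/mol/rad^2,
#' backbone pseudo-angle stiffness; larger for the conformationally
#' restricted Pro); `angle_theta0` (rad; kinked for Pro); `hbond_epsilon`
#' (kJ/mol, extra attraction for the polar amide side chains of Asn/Gln,
#' smaller for hydroxyl side chains).
#'
#' @return Data.frame with 20 rows.
#' @export
default_residue_params <- function() {
  code <- names(.kd_hydropathy)
  kd <- .kd_hydropathy
  mass <- .residue_mass[code]
  charge <- ifelse(code %in% c("K", "R"), 1,
                   ifelse(code %in% c("D", "E"), -1, 0))
  hb <- ifelse(code %in% c("N", "Q"), 0.8,
               ifelse(code %in% c("S", "T", "Y"), 0.3, 0.01))
  data.frame(
    code = code,
    mass = unname(mass),
    friction = 50,
    charge = charge,
    lj_epsilon = unname(0.2 + (kd + 4.5) / 9),
    lj_sigma = unname(0.5 * (mass / 110)^(1 / 3)),
    angle_k = ifelse(code == "P", 75, 25),
    angle_theta0 = ifelse(code == "P", 1.85, 2.12),
    hbond_epsilon = hb,
    stringsAsFactors = FALSE)
}

#' Synthetic stand-in for the 19-residue neck-linker sequence
#'
#' The structural source of the linker does not fix a printed sequence here;
#' this stand-in honors the documented position constraints: Ile at position
#' 4, Pro at positions 8 and 14, and at least one Asn and one Lys. It is a
#' synthetic sequence, not the biological one.
#'
#' @return A [peptide_sequence()] of length 19.
#' @export
linker_standin_sequence <- function() peptide_sequence("SATINKEPVDNLGPKNAEV")
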