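#' @useDynLib linkerelast, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm integrate ks.test lm coef quantile rnorm sd setNames
#'   var complete.cases
#' @importFrom utils read.delim write.table
NULL

# CODATA 2018 constants, hard-coded for reproducible conversions.
.kB_J_per_K <- 1.380649e-23
.N_A <- 6.02214076e23

#' Thermal energy at a given temperature
#'
#' Populates a consistent set of thermal-energy values in the unit systems used
#' throughout the package: the internal kJ/mol scale and the single-molecule
#' pN nm scale. At 300 K, `kBT_kJ_mol` is about 2.494 and `kBT_pN_nm` about
#' 4.14.
#'
#' @param temperature Temperature in kelvin; must be positive.
#' @return An object of class `thermo` with fields `temperature`, `beta`
#'   (mol/kJ, the inverse of `kBT_kJ_mol`), `kBT_kJ_mol` and `kBT_pN_nm`.
#' @examples
#' thermal_energy(300)$kBT_pN_nm  # ~4.14
#' @export
thermal_energy <- function(temperature) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a single positive number (kelvin)")
  kBT_kJ_mol <- .kB_J_per_K * .N_A * temperature / 1000
  structure(list(
    temperature = temperature,
    beta = 1 / kBT_kJ_mol,
    kBT_kJ_mol = kBT_kJ_mol,
    kBT_pN_nm = .kB_J_per_K * temperature / 1e-21
  ), class = "thermo")
}

#' Convert a molar force to piconewtons
#'
#' Forces are carried internally in kJ/mol/nm (the unit in which pulling
#' forces are specified); this converts to the per-molecule pN scale used by
#' optical-trap experiments. The conversion is linear: 1300 kJ/mol/nm is
#' approximately 2160 pN.
#'
#' @param force Force in kJ/mol/nm.
#' @return Force in pN.
#' @examples
#' force_to_piconewton(1300)  # ~2158.8
#' @export
force_to_piconewton <- function(force) {
  stopifnot(is.numeric(force), all(is.finite(force)))
  force * 1000 / .N_A / 1e-9 * 1e12
}

.aa_one_letter <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a validated peptide sequence
#'
#' @param residues One-letter amino-acid codes, either a single string or a
#'   character vector of single letters. At least two residues; codes must be
#'   among the 20 standard amino acids.
#' @return A `peptide_sequence` object (character vector of codes with a
#'   `length` field).
#' @export
peptide_sequence <- function(residues) {
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- toupper(as.character(residues))
  if (length(residues) < 2L)
    stop("a peptide sequence needs at least 2 residues")
  bad <- setdiff(unique(residues), .aa_one_letter)
  if (length(bad))
    stop("invalid residue code(s): ", paste(bad, collapse = ", "))
  structure(residues, class = "peptide_sequence")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat("<peptide_sequence> ", paste(unclass(x), collapse = ""),
      " (", length(x), " aa)\n", sep = "")
  invisible(x)
}

#' Substitute every occurrence of one residue type with another
#'
#' Used to derive alanine-substitution mutants of the neck linker (e.g. all
#' Asn -> Ala). Length and all non-target positions are unchanged.
#'
#' @param seq A [peptide_sequence()] (or string coercible to one).
#' @param target,replacement Single one-letter residue codes.
#' @return A `peptide_sequence` of the same length.
#' @examples
#' substitute_residues(peptide_sequence("AINP"), "P", "A")
#' @export
substitute_residues <- function(seq, target, replacement) {
  seq <- peptide_sequence(seq)
  target <- toupper(target); replacement <- toupper(replacement)
  if (!(target %in% .aa_one_letter) || !(replacement %in% .aa_one_letter))
    stop("target and replacement must be standard one-letter residue codes")
  out <- unclass(seq)
  out[out == target] <- replacement
  peptide_sequence(out)
}

#' Format a peptide sequence as a single string
#' @param seq A [peptide_sequence()].
#' @return A length-1 character string.
#' @export
sequence_string <- function(seq) paste(unclass(peptide_sequence(seq)), collapse = "")
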