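#' Construct a C-alpha structure from coordinates
#'
#' Low-level constructor used by [read_ca_structure()] and by tests that build
#' toy geometries directly. Coordinates are in nm.
#'
#' @param positions Numeric n x 3 matrix of C-alpha coordinates (nm).
#' @param chain Chain identifier per atom (recycled if length 1).
#' @param resno Residue numbers per atom.
#' @param resid Residue names per atom (three-letter or one-letter; free text).
#' @return A `ca_structure`: list with `positions`, `residue_ids`
#'   (data.frame chain/resno/resid), `n` and a `gaps` data.frame of missing
#'   residue numbers per chain.
#' @export
ca_structure <- function(positions, chain = "A",
                         resno = seq_len(nrow(positions)),
                         resid = "ALA") {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must have 3 columns")
  n <- nrow(positions)
  if (n < 3L) stop("a structure needs at least 3 C-alpha atoms")
  if (!all(is.finite(positions))) stop("non-finite coordinates")
  ids <- data.frame(chain = rep_len(as.character(chain), n),
                    resno = rep_len(as.integer(resno), n),
                    resid = rep_len(as.character(resid), n),
                    stringsAsFactors = FALSE)
  gaps <- do.call(rbind, lapply(split(ids$resno, ids$chain), function(rn) {
    missing <- setdiff(seq(min(rn), max(rn)), rn)
    if (!length(missing)) return(NULL)
    data.frame(resno = missing)
  }))
  if (is.null(gaps)) {
    gaps <- data.frame(chain = character(), resno = integer())
  } else {
    gaps <- data.frame(chain = sub("\\.[0-9]+$", "", rownames(gaps)),
                       resno = gaps$resno, row.names = NULL)
  }
  structure(list(positions = positions, residue_ids = ids, n = n, gaps = gaps),
            class = "ca_structure")
}

#' @export
print.ca_structure <- function(x, ...) {
  cat("<ca_structure> ", x$n, " C-alpha atoms, chains: ",
      paste(unique(x$residue_ids$chain), collapse = ", "), sep = "")
  if (nrow(x$gaps)) cat(" (", nrow(x$gaps), " missing residues)", sep = "")
  cat("\n")
  invisible(x)
}

#' Read C-alpha coordinates from a PDB file
#'
#' Extracts one C-alpha per residue from ATOM records. Alternate locations are
#' resolved to the highest-occupancy conformer (ties and missing occupancies:
#' first record wins). Missing residues are recorded as gaps, never
#' interpolated. Coordinates are converted from Angstrom to nm.
#'
#' @param pdb_source Path to a PDB file, or a `pdb` object from
#'   [bio3d::read.pdb()].
#' @return A [ca_structure()].
#' @export
read_ca_structure <- function(pdb_source) {
  pdb <- if (inherits(pdb_source, "pdb")) pdb_source else
    bio3d::read.pdb(pdb_source, rm.alt = FALSE)  # altloc handled below
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (!nrow(at)) stop("no C-alpha ATOM records found")
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  keep <- unlist(lapply(split(seq_len(nrow(at)), factor(key, unique(key))),
                        function(idx) {
    if (length(idx) == 1L) return(idx)
    occ <- at$o[idx]
    occ[is.na(occ)] <- -Inf
    idx[which.max(occ)]  # highest occupancy, ties -> first
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  pos <- cbind(at$x, at$y, at$z) / 10   # Angstrom -> nm
  if (!all(is.finite(pos))) stop("unparseable coordinates in ATOM records")
  ca_structure(pos, chain = at$chain, resno = at$resno, resid = at$resid)
}

#' Write a C-alpha trace as a PDB file with per-residue values in the B-factor
#'
#' Used to visualize deformation energies or domain labels on the structure
#' (e.g. in VMD/PyMOL, coloring by B-factor).
#'
#' @param structure A [ca_structure()].
#' @param values Numeric vector (length n) written to the B-factor column;
#'   `NA` is written as -1.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ca_pdb <- function(structure, values, path) {
  stopifnot(inherits(structure, "ca_structure"),
            length(values) == structure$n)
  values[is.na(values)] <- -1
  ids <- structure$residue_ids
  pos <- structure$positions * 10    # nm -> Angstrom
  lines <- sprintf(
    "ATOM  %5d  CA  %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(structure$n), substr(ids$resid, 1, 3), substr(ids$chain, 1, 1),
    ids$resno, pos[, 1], pos[, 2], pos[, 3], 1.0, pmin(values, 999.99))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
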