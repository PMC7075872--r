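#' The five study sequences: wild-type stand-in and its derived variants
#'
#' Mutant chains are derived from the wild-type by alanine substitution of
#' every Asn, every Lys, or both Pro residues; the poly-alanine reference is
#' an 18-residue Ala-only chain.
#'
#' @param wild_type The wild-type sequence (default
#'   [linker_standin_sequence()]).
#' @return Named list of [peptide_sequence()]s: `neck_linker`,
#'   `no_asparagine`, `no_lysine`, `no_proline`, `ala_only`.
#' @export
default_study_sequences <- function(wild_type = linker_standin_sequence()) {
  wild_type <- peptide_sequence(wild_type)
  list(neck_linker = wild_type,
       no_asparagine = substitute_residues(wild_type, "N", "A"),
       no_lysine = substitute_residues(wild_type, "K", "A"),
       no_proline = substitute_residues(wild_type, "P", "A"),
       ala_only = peptide_sequence(strrep("A", 18)))
}

#' Study configuration: sequences x forces plus simulation and network
#' parameters
#'
#' @param sequences Named list of sequences (default
#'   [default_study_sequences()]). Names must be unique.
#' @param forces Pulling forces, kJ/mol/nm (default the five study levels).
#' @param sim A [sim_config()] template; its `pull_force` is overridden per
#'   cell.
#' @param enm Elastic-network parameter list
#'   (`C`, `r0`, `cube_side`, `threshold`, `coarseness`, `n_modes`).
#' @param structure_path Optional PDB path for the domain stage.
#' @param output_dir Optional output directory for exported tables.
#' @return A `study_config` list.
#' @export
study_config <- function(sequences = default_study_sequences(),
                         forces = c(130, 400, 700, 1000, 1300),
                         sim = sim_config(),
                         enm = list(C = 47400, r0 = 0.3, cube_side = 1.2,
                                    threshold = 400, coarseness = 10,
                                    n_modes = NULL),
                         structure_path = NULL, output_dir = NULL) {
  stopifnot(length(forces) >= 1, all(forces > 0))
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be a uniquely named list")
  sequences <- lapply(sequences, peptide_sequence)
  structure(list(sequences = sequences, forces = forces, sim = sim,
                 enm = enm, structure_path = structure_path,
                 output_dir = output_dir),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Schema version 1. Recognized top-level keys: `schema_version`,
#' `wild_type`, `sequences` (named map of strings), `forces`, `sim` (fields
#' of [sim_config()]), `enm`, `structure_path`, `output_dir`. Unknown keys —
#' at the top level or inside `sim`/`enm` — are errors, guarding against
#' silent typos.
#'
#' @param path YAML file path.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("schema_version", "wild_type", "sequences", "forces", "sim",
             "enm", "structure_path", "output_dir")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$schema_version) || cfg$schema_version != 1)
    stop("unsupported or missing schema_version (expected 1)")
  sim_args <- cfg$sim %||% list()
  bad <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(bad)) stop("unknown sim key(s): ", paste(bad, collapse = ", "))
  enm_defaults <- formals(study_config)$enm
  enm <- eval(enm_defaults)
  bad <- setdiff(names(cfg$enm), names(enm))
  if (length(bad)) stop("unknown enm key(s): ", paste(bad, collapse = ", "))
  enm[names(cfg$enm)] <- cfg$enm
  sequences <- if (!is.null(cfg$sequences)) lapply(cfg$sequences, identity)
    else default_study_sequences(cfg$wild_type %||% linker_standin_sequence())
  study_config(sequences = sequences,
               forces = cfg$forces %||% c(130, 400, 700, 1000, 1300),
               sim = do.call(sim_config, sim_args), enm = enm,
               structure_path = cfg$structure_path,
               output_dir = cfg$output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the dynamic-domain stage and export its tables
#'
#' Builds the elastic network, computes modes, selects those below the
#' deformation-energy threshold, and writes: the cumulative
#' fraction-below-threshold table (one row per mode-set size), per-residue
#' deformation energies (TSV), domain labels (TSV) and a C-alpha PDB with
#' labels in the B-factor column.
#'
#' @param structure A [ca_structure()], or a PDB path.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param C,r0,cube_side,threshold,coarseness,n_modes Network and clustering
#'   parameters, see [decompose_domains()].
#' @return The [decompose_domains()] result, invisibly, with an added
#'   `paths` element when files were written.
#' @export
run_domains <- function(structure, out_dir = NULL, C = 47400, r0 = 0.3,
                        cube_side = 1.2, threshold = 400, coarseness = 10,
                        n_modes = NULL) {
  if (is.character(structure)) {
    if (!file.exists(structure))
      stop("structure file not found: ", structure)
    structure <- read_ca_structure(structure)
  }
  stopifnot(inherits(structure, "ca_structure"))
  dec <- decompose_domains(structure, C = C, r0 = r0, n_modes = n_modes,
                           threshold = threshold, cube_side = cube_side,
                           coarseness_c = coarseness)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    ids <- structure$residue_ids
    energies <- data.frame(chain = ids$chain, resid = ids$resno,
                           resname = ids$resid,
                           E_kJ_mol = dec$profile,
                           domain = if (!is.null(dec$domains))
                             dec$domains$residue_labels else NA_integer_)
    p1 <- file.path(out_dir, "residue_deformation_energies.tsv")
    utils::write.table(energies, p1, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    p2 <- file.path(out_dir, "mode_fraction_below_threshold.tsv")
    utils::write.table(dec$selection$cumulative, p2, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    p3 <- file.path(out_dir, "domains_bfactor.pdb")
    write_ca_pdb(structure,
                 if (!is.null(dec$domains)) dec$domains$residue_labels
                 else rep(NA_real_, structure$n), p3)
    dec$paths <- c(p1, p2, p3)
  }
  invisible(dec)
}

.study_cell_seed <- function(base_seed, seq_index, force_index) {
  as.integer(base_seed + 131L * (seq_index - 1L) + 17L * (force_index - 1L))
}

#' Run the full pulling study: sequences x forces
#'
#' For every sequence: equilibrate, select a near-mean starting conformation
#' from the trailing window; then for every force: run the stretch ensemble,
#' the paired relaxation ensemble, accumulate works and estimate the
#' free-energy difference (crossing point with bootstrap CI, Jarzynski,
#' Gaussian closed form). Finally fit the quadratic stiffness of dG versus
#' fractional extension per sequence.
#'
#' @param config A [study_config()].
#' @param n_boot Bootstrap replicates per cell.
#' @param progress Print one line per completed cell.
#' @return A `study_report`: list with `report` (one row per sequence x
#'   force), `stiffness` (one row per sequence), `config`.
#' @export
run_pull_study <- function(config = study_config(), n_boot = 200,
                           progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  rows <- list(); stiff <- list()
  for (si in seq_along(config$sequences)) {
    sname <- names(config$sequences)[si]
    chain <- build_chain(config$sequences[[si]])
    eq_cfg <- config$sim
    eq_cfg$base_seed <- .study_cell_seed(config$sim$base_seed, si, 1L)
    equil <- equilibrate(chain, eq_cfg)
    start <- select_start_conformation(equil)
    e2e <- equil$trajectories[[1]]$end_to_end
    nwin <- max(1L, floor(0.2 * length(e2e)))
    relaxed_mean <- mean(e2e[seq.int(length(e2e) - nwin + 1L, length(e2e))])
    pts <- data.frame(f = numeric(), dg = numeric())
    for (fi in seq_along(config$forces)) {
      force <- config$forces[fi]
      cell_cfg <- config$sim
      cell_cfg$pull_force <- force
      cell_cfg$base_seed <- .study_cell_seed(config$sim$base_seed, si, fi)
      cell <- tryCatch({
        stretch <- run_stretch_ensemble(start, chain, cell_cfg)
        relax <- run_relax_ensemble(stretch)
        fe <- free_energy_estimate(work_ensemble(stretch),
                                   work_ensemble(relax),
                                   n_boot = n_boot, seed = cell_cfg$base_seed)
        stretched_mean <- mean(vapply(stretch$trajectories, function(tr)
          tr$end_to_end[length(tr$end_to_end)], numeric(1)))
        fx <- fractional_extension(stretched_mean, relaxed_mean, chain$n)
        data.frame(
          sequence = sname, force = force, n_ensemble = cell_cfg$n_ensemble,
          mean_w_stretch = fe$mean_w_f, mean_w_relax = fe$mean_w_r,
          sd_w_stretch = fe$sd_w_f, sd_w_relax = fe$sd_w_r,
          dg_crossing = fe$delta_g_crossing,
          dg_jarzynski = fe$delta_g_jarzynski,
          ci_low = fe$ci_low, ci_high = fe$ci_high,
          relaxed_mean = relaxed_mean, stretched_mean = stretched_mean,
          frac_ext = fx$value, seed = cell_cfg$base_seed, status = "ok",
          stringsAsFactors = FALSE)
      }, error = function(e) data.frame(
        sequence = sname, force = force, n_ensemble = cell_cfg$n_ensemble,
        mean_w_stretch = NA_real_, mean_w_relax = NA_real_,
        sd_w_stretch = NA_real_, sd_w_relax = NA_real_,
        dg_crossing = NA_real_, dg_jarzynski = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_,
        relaxed_mean = relaxed_mean, stretched_mean = NA_real_,
        frac_ext = NA_real_, seed = cell_cfg$base_seed,
        status = paste("failed:", conditionMessage(e)),
        stringsAsFactors = FALSE))
      rows[[length(rows) + 1L]] <- cell
      if (cell$status == "ok")
        pts <- rbind(pts, data.frame(f = cell$frac_ext,
                                     dg = cell$dg_crossing))
      if (progress)
        message(sprintf("[%s] F=%g: dG_cross=%s kBT (%s)", sname, force,
                        signif(cell$dg_crossing, 4), cell$status))
    }
    stiff[[length(stiff) + 1L]] <- if (nrow(pts) >= 3L) {
      sf <- fit_quadratic_stiffness(pts)
      data.frame(sequence = sname, quadratic_coef = sf$quadratic_coef,
                 intercept = sf$intercept, r_squared = sf$r_squared,
                 stringsAsFactors = FALSE)
    } else data.frame(sequence = sname, quadratic_coef = NA_real_,
                      intercept = NA_real_, r_squared = NA_real_,
                      stringsAsFactors = FALSE)
  }
  out <- structure(list(report = do.call(rbind, rows),
                        stiffness = do.call(rbind, stiff), config = config),
                   class = "study_report")
  failed <- out$report$status != "ok"
  if (any(failed))
    message("study completed with ", sum(failed), " failed cell(s): ",
            paste(sprintf("%s@F=%g", out$report$sequence[failed],
                          out$report$force[failed]), collapse = ", "))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out$report,
                       file.path(config$output_dir, "free_energy_report.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(out$stiffness,
                       file.path(config$output_dir, "stiffness_fits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

#' Reference work-distribution moments at the strongest pulling force
#'
#' Moments (mean, SD, both in kBT) of the stretch and relax work
#' distributions of the five linker variants from the companion all-atom
#' pulling ensembles at F = 1300 kJ/mol/nm, together with the reported
#' crossing-point free-energy differences. Shipped as plain TSV; used to
#' validate the crossing-point estimator against independently produced
#' distributions.
#'
#' @return Data.frame: `peptide`, `mean_stretch`, `sd_stretch`,
#'   `mean_relax`, `sd_relax`, `delta_g_reported`.
#' @export
reference_work_moments <- function() {
  path <- system.file("extdata", "allatom_work_moments_f1300.tsv",
                      package = "linkerelast", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Generate the plain-text fixture bundle
#'
#' Writes: a 20-residue toy helix PDB, the synthetic stand-in linker
#' sequence, a canned pair of Gaussian work ensembles with a known crossing
#' (dG = 7 kBT), and a copy of the reference work-moment table.
#'
#' @param dir Output directory.
#' @param seed RNG seed for the canned ensembles.
#' @return Named list of file paths.
#' @export
make_fixtures <- function(dir = tempfile("fixtures"), seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # ideal alpha-helix C-alpha trace: radius 0.23 nm, rise 0.15 nm, 100 deg
  i <- 0:19
  helix <- cbind(0.23 * cos(i * 100 * pi / 180),
                 0.23 * sin(i * 100 * pi / 180), 0.15 * i)
  hs <- ca_structure(helix, chain = "A", resno = i + 1, resid = "ALA")
  p_pdb <- file.path(dir, "toy_helix.pdb")
  write_ca_pdb(hs, rep(0, 20), p_pdb)
  p_seq <- file.path(dir, "standin_sequence.txt")
  writeLines(c("# synthetic stand-in linker sequence (Ile4, Pro8, Pro14)",
               sequence_string(linker_standin_sequence())), p_seq)
  set.seed(seed)
  canned <- data.frame(trajectory_id = rep(seq_len(2000), 2),
                       phase = rep(c("stretch", "relax"), each = 2000),
                       W_kBT = c(rnorm(2000, 10, 2), rnorm(2000, 4, 2)))
  p_work <- file.path(dir, "canned_gaussian_work.tsv")
  utils::write.table(canned, p_work, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  p_mom <- file.path(dir, "allatom_work_moments_f1300.tsv")
  file.copy(system.file("extdata", "allatom_work_moments_f1300.tsv",
                        package = "linkerelast", mustWork = TRUE), p_mom,
            overwrite = TRUE)
  list(toy_pdb = p_pdb, sequence = p_seq, canned_work = p_work,
       work_moments = p_mom)
}
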