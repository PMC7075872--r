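#' Bind a peptide sequence to coarse-grained bead parameters
#'
#' @param sequence A [peptide_sequence()] or string.
#' @param params_table Residue parameter table, one row per residue code
#'   (default [default_residue_params()]).
#' @param bond_k Backbone bond stiffness, kJ/mol/nm^2.
#' @param bond_b0 Backbone bond length, nm (0.38, the C-alpha virtual-bond
#'   length).
#' @param debye_length Electrostatic screening length, nm.
#' @param dielectric Relative dielectric constant for the screened Coulomb
#'   term.
#' @return A `chain_model`: list of per-bead parameter vectors plus scalars,
#'   consumed by the compiled propagator.
#' @export
build_chain <- function(sequence, params_table = default_residue_params(),
                        bond_k = 10000, bond_b0 = 0.38,
                        debye_length = 1.0, dielectric = 80) {
  sequence <- peptide_sequence(sequence)
  stopifnot(bond_k > 0, bond_b0 > 0, debye_length > 0, dielectric > 0)
  idx <- match(unclass(sequence), params_table$code)
  if (anyNA(idx))
    stop("residue(s) missing from the parameter table: ",
         paste(unique(unclass(sequence)[is.na(idx)]), collapse = ", "))
  pt <- params_table[idx, ]
  structure(list(
    sequence = sequence,
    n = length(sequence),
    mass = pt$mass, friction = pt$friction, charge = pt$charge,
    lj_epsilon = pt$lj_epsilon, lj_sigma = pt$lj_sigma,
    hbond_epsilon = pt$hbond_epsilon,
    angle_k = pt$angle_k, angle_theta0 = pt$angle_theta0,
    bond_k = bond_k, bond_b0 = bond_b0,
    debye_length = debye_length,
    coulomb_ke = 138.935458 / dielectric
  ), class = "chain_model")
}

#' Coarse-grained potential energy and forces
#'
#' `E = sum harmonic bonds + sum harmonic angles + sum_{|i-j|>=3}
#' [Lennard-Jones + Debye-screened Coulomb]`. Forces are the exact analytic
#' gradient.
#'
#' @param chain A [build_chain()] model.
#' @param positions n x 3 bead coordinates, nm.
#' @return List with `energy` (kJ/mol) and `forces` (n x 3, kJ/mol/nm).
#' @export
cg_energy <- function(chain, positions) {
  stopifnot(inherits(chain, "chain_model"))
  positions <- as.matrix(positions)
  if (!all(is.finite(positions))) stop("non-finite positions")
  .cg_energy_cpp(positions, unclass(chain))
}

#' Deterministic initial conformation (planar zig-zag at the reference
#' geometry: all bonds at b0, all angles at the backbone theta0)
#' @param chain A [build_chain()] model.
#' @return n x 3 position matrix, nm.
#' @export
initial_conformation <- function(chain) {
  n <- chain$n
  delta <- (pi - 2.12) / 2   # backbone (non-Pro) reference angle
  pos <- matrix(0, n, 3)
  dir <- c(cos(delta), sin(delta), 0)
  for (i in 2:n) {
    pos[i, ] <- pos[i - 1, ] + chain$bond_b0 * dir
    dir[2] <- -dir[2]
  }
  pos
}

#' Simulation configuration for the pulling protocol
#'
#' Defaults mirror the study conditions: T = 300 K, time step 2e-3 ps,
#' ensembles of 1e4 trajectories of 1 ps each, pulling forces drawn from
#' {130, 400, 700, 1000, 1300} kJ/mol/nm, and a 6 ns equilibration.
#'
#' @param temperature Temperature, K.
#' @param dt Time step, ps.
#' @param n_steps_equil Equilibration steps (default 3e6 = 6 ns).
#' @param n_ensemble Trajectories per ensemble.
#' @param t_pull Pull/relax duration, ps; `t_pull/dt` must be integral.
#' @param pull_force Constant pulling force, kJ/mol/nm.
#' @param base_seed Integer master seed; every trajectory seed derives from
#'   it.
#' @param record_stride_equil Frame-recording stride during equilibration.
#' @param record_positions Record full bead coordinates for stretch/relax
#'   trajectories (needed for pair-distance profiles).
#' @return A `sim_config` list.
#' @export
sim_config <- function(temperature = 300, dt = 2e-3, n_steps_equil = 3e6,
                       n_ensemble = 1e4, t_pull = 1, pull_force = 1300,
                       base_seed = 1, record_stride_equil = 100,
                       record_positions = FALSE) {
  stopifnot(temperature > 0, dt > 0, n_ensemble >= 1, t_pull > 0,
            n_steps_equil >= 1, pull_force >= 0)
  n_pull_steps <- t_pull / dt
  if (abs(n_pull_steps - round(n_pull_steps)) > 1e-9)
    stop("t_pull must be an integer multiple of dt")
  structure(list(temperature = temperature, dt = dt,
                 n_steps_equil = as.integer(n_steps_equil),
                 n_ensemble = as.integer(n_ensemble), t_pull = t_pull,
                 n_pull_steps = as.integer(round(n_pull_steps)),
                 pull_force = pull_force, base_seed = as.integer(base_seed),
                 record_stride_equil = as.integer(record_stride_equil),
                 record_positions = record_positions),
            class = "sim_config")
}

#' Deterministic per-trajectory seed
#'
#' Each trajectory's RNG seed is a fixed integer function of the master seed,
#' the protocol phase and the trajectory index, so any single trajectory can
#' be regenerated in isolation.
#'
#' @param base_seed Master seed (integer).
#' @param phase One of `"equil"`, `"stretch"`, `"relax"`.
#' @param index Trajectory index (1-based).
#' @return Integer seed below 2^31.
#' @export
trajectory_seed <- function(base_seed, phase, index) {
  pc <- match(phase, c("equil", "stretch", "relax"))
  if (is.na(pc)) stop("unknown phase: ", phase)
  as.integer((abs(as.numeric(base_seed)) %% 100000) * 20011 +
               pc * 4000037 + index)
}

.run_traj <- function(chain, pos0, n_steps, dt, kT, pull_force, fix_ends,
                      record_stride, record_positions, seed) {
  set.seed(seed)
  raw <- .run_chain_cpp(pos0, unclass(chain), as.integer(n_steps), dt, kT,
                        pull_force, fix_ends, as.integer(record_stride),
                        record_positions)
  structure(list(times = raw$times, end_to_end = raw$end_to_end,
                 positions = raw$positions, final = raw$final, seed = seed),
            class = "cg_trajectory")
}

.make_ensemble <- function(phase, trajectories, config, chain) {
  structure(list(phase = phase, trajectories = trajectories, config = config,
                 chain = chain), class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("<trajectory_ensemble> phase=", x$phase, ", ",
      length(x$trajectories), " trajectories, T=", x$config$temperature,
      " K\n", sep = "")
  invisible(x)
}

#' Equilibrate a chain with overdamped Langevin dynamics
#'
#' Propagates the chain from the reference zig-zag conformation at constant
#' temperature, recording the end-to-end distance (distance between the
#' first and last bead, the centers of the pulling groups) and snapshots at
#' the configured stride.
#'
#' @param chain A [build_chain()] model.
#' @param config A [sim_config()].
#' @param fix_ends Keep the first and last bead fixed (the short
#'   pre-pulling restraint variant).
#' @param n_traj Number of independent equilibration trajectories.
#' @return A `trajectory_ensemble` with `phase = "equil"`.
#' @export
equilibrate <- function(chain, config, fix_ends = FALSE, n_traj = 1) {
  stopifnot(inherits(chain, "chain_model"), inherits(config, "sim_config"))
  kT <- thermal_energy(config$temperature)$kBT_kJ_mol
  pos0 <- initial_conformation(chain)
  trajs <- lapply(seq_len(n_traj), function(i)
    .run_traj(chain, pos0, config$n_steps_equil, config$dt, kT,
              pull_force = 0, fix_ends = fix_ends,
              record_stride = config$record_stride_equil,
              record_positions = TRUE,
              seed = trajectory_seed(config$base_seed, "equil", i)))
  .make_ensemble("equil", trajs, config, chain)
}

#' Select a starting conformation from an equilibration run
#'
#' Among frames in the trailing window of the equilibration trajectory,
#' returns the one whose end-to-end distance is nearest the window mean
#' (ties resolved to the latest frame) — a near-equilibrium, typical
#' conformation from late in the run.
#'
#' @param equil An equilibration `trajectory_ensemble` (positions recorded).
#' @param window_fraction Trailing fraction of frames to search (default
#'   0.2).
#' @return A `cg_conformation`: list with `positions`, `end_to_end`, `frame`
#'   (index into recorded frames), `time` (ps).
#' @export
select_start_conformation <- function(equil, window_fraction = 0.2) {
  stopifnot(inherits(equil, "trajectory_ensemble"), equil$phase == "equil",
            window_fraction > 0, window_fraction <= 1)
  traj <- equil$trajectories[[1]]
  if (is.null(traj$positions))
    stop("equilibration was run without recorded positions")
  nrec <- length(traj$end_to_end)
  win <- max(1L, floor(window_fraction * nrec))
  idx <- seq.int(nrec - win + 1L, nrec)
  if (!length(idx)) stop("empty selection window")
  e2e <- traj$end_to_end[idx]
  dev <- abs(e2e - mean(e2e))
  best <- idx[max(which(dev == min(dev)))]   # ties -> latest frame
  structure(list(positions = traj$positions[best, , ],
                 end_to_end = traj$end_to_end[best], frame = best,
                 time = traj$times[best]),
            class = "cg_conformation")
}

#' Run an ensemble of constant-force stretching trajectories
#'
#' All trajectories start from the same conformation with distinct seeds. A
#' constant-magnitude force is applied along the instantaneous axis from the
#' first to the last bead (+F on the last, -F on the first), for `t_pull`
#' picoseconds.
#'
#' @param start A [select_start_conformation()] result (or n x 3 matrix).
#' @param chain The [build_chain()] model.
#' @param config A [sim_config()]; `pull_force` must be positive.
#' @return A `trajectory_ensemble` with `phase = "stretch"`.
#' @export
run_stretch_ensemble <- function(start, chain, config) {
  stopifnot(inherits(chain, "chain_model"), inherits(config, "sim_config"),
            config$pull_force >= 0)
  pos0 <- if (inherits(start, "cg_conformation")) start$positions else
    as.matrix(start)
  kT <- thermal_energy(config$temperature)$kBT_kJ_mol
  trajs <- lapply(seq_len(config$n_ensemble), function(i)
    .run_traj(chain, pos0, config$n_pull_steps, config$dt, kT,
              pull_force = config$pull_force, fix_ends = FALSE,
              record_stride = 1L,
              record_positions = config$record_positions,
              seed = trajectory_seed(config$base_seed, "stretch", i)))
  .make_ensemble("stretch", trajs, config, chain)
}

#' Run the paired force-off relaxation ensemble
#'
#' Each relaxation trajectory starts from the final state of the stretch
#' trajectory with the same index (1:1, order-preserving pairing); the
#' pulling force is off and the system relaxes for `t_pull` picoseconds.
#'
#' @param stretch The stretch `trajectory_ensemble`.
#' @param config A [sim_config()] (defaults to the stretch config).
#' @return A `trajectory_ensemble` with `phase = "relax"`.
#' @export
run_relax_ensemble <- function(stretch, config = stretch$config) {
  stopifnot(inherits(stretch, "trajectory_ensemble"),
            stretch$phase == "stretch")
  chain <- stretch$chain
  kT <- thermal_energy(config$temperature)$kBT_kJ_mol
  trajs <- lapply(seq_along(stretch$trajectories), function(i)
    .run_traj(chain, stretch$trajectories[[i]]$final, config$n_pull_steps,
              config$dt, kT, pull_force = 0, fix_ends = FALSE,
              record_stride = 1L,
              record_positions = config$record_positions,
              seed = trajectory_seed(config$base_seed, "relax", i)))
  .make_ensemble("relax", trajs, config, chain)
}

#' 1-D overdamped Langevin sampler in a tilted double-well potential
#'
#' `U(x) = h ((x/a)^2 - 1)^2 + tilt * x`: two wells near x = -a and x = +a
#' separated by a barrier of height ~h, tilted by a linear bias. Used to
#' validate Boltzmann occupancy statistics and the histogram free-energy
#' estimator.
#'
#' @param n_steps Integration steps.
#' @param kT Thermal energy (same units as `h`).
#' @param a,h,tilt Potential parameters.
#' @param x0 Initial position.
#' @param dt Time step.
#' @param mgamma Mass times friction (mobility denominator).
#' @param record_stride Sampling stride.
#' @param burn_in Discarded initial steps.
#' @param seed RNG seed.
#' @return Numeric vector of sampled positions.
#' @export
langevin_double_well <- function(n_steps, kT = 1, a = 1, h = 2, tilt = 0,
                                 x0 = -1, dt = 1e-3, mgamma = 1,
                                 record_stride = 10,
                                 burn_in = floor(n_steps / 20), seed = 1) {
  set.seed(seed)
  .run_langevin_1d_cpp(x0, as.integer(n_steps), dt, kT, mgamma, a, h, tilt,
                       as.integer(record_stride), as.integer(burn_in))
}
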