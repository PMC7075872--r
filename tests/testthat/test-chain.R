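test_that("sequences bind to bead parameters positionally", {
  ch <- build_chain("AAA")
  expect_equal(ch$n, 3)
  expect_equal(length(unique(ch$mass)), 1)
  expect_equal(ch$charge, c(0, 0, 0))
  ch2 <- build_chain("AKA")
  expect_equal(ch2$charge, c(0, 1, 0))
  # stand-in linker: Pro beads at 8 and 14 carry the kink parameters
  wt <- build_chain(linker_standin_sequence())
  pro <- which(unclass(wt$sequence) == "P")
  expect_equal(pro, c(8L, 14L))
  expect_true(all(wt$angle_k[pro] > max(wt$angle_k[-pro])))
  expect_true(all(wt$angle_theta0[pro] < 2.0))
  bad <- default_residue_params()[1:5, ]
  expect_error(build_chain("AWY", params_table = bad), "missing")
})

test_that("potential energy terms have their closed forms and exact forces", {
  ch <- make_dimer_chain(bond_k = 200)
  # single bond stretched by delta: dE = k delta^2 / 2
  p0 <- rbind(c(0, 0, 0), c(ch$bond_b0, 0, 0))
  e0 <- cg_energy(ch, p0)$energy
  delta <- 0.07
  p1 <- rbind(c(0, 0, 0), c(ch$bond_b0 + delta, 0, 0))
  expect_equal(cg_energy(ch, p1)$energy - e0, 0.5 * 200 * delta^2)
  # reference conformation of an angle-free chain is at the minimum
  ideal <- make_ideal_chain(5)
  expect_equal(cg_energy(ideal, initial_conformation(ideal))$energy, 0,
               tolerance = 1e-10)
  # overlapping beads are an error
  expect_error(cg_energy(ch, rbind(c(0, 0, 0), c(0, 0, 1e-9))),
               "overlap")
  # analytic forces match central finite differences on a random 5-bead
  # conformation with all terms active (bonds, angles, LJ, charges)
  set.seed(21)
  full <- build_chain("KENPA")
  pos <- initial_conformation(full) + matrix(rnorm(15, sd = 0.03), 5, 3)
  ef <- cg_energy(full, pos)
  h <- 1e-6
  for (i in 1:5) for (d in 1:3) {
    pp <- pos; pp[i, d] <- pp[i, d] + h
    pm <- pos; pm[i, d] <- pm[i, d] - h
    fd <- -(cg_energy(full, pp)$energy - cg_energy(full, pm)$energy) / (2 * h)
    expect_equal(ef$forces[i, d], fd,
                 tolerance = 1e-6 * max(1, abs(fd)))
  }
})

test_that("trajectories are bit-identical under a fixed seed and distinct
           across indices", {
  ch <- build_chain(linker_standin_sequence())
  cfg <- sim_config(n_steps_equil = 2000, n_ensemble = 3, base_seed = 42)
  eq1 <- equilibrate(ch, cfg)
  eq2 <- equilibrate(ch, cfg)
  expect_identical(eq1$trajectories[[1]]$end_to_end,
                   eq2$trajectories[[1]]$end_to_end)
  expect_identical(eq1$trajectories[[1]]$final, eq2$trajectories[[1]]$final)
  st <- select_start_conformation(eq1)
  sx1 <- run_stretch_ensemble(st, ch, cfg)
  sx2 <- run_stretch_ensemble(st, ch, cfg)
  expect_identical(sx1$trajectories[[2]]$end_to_end,
                   sx2$trajectories[[2]]$end_to_end)
  expect_false(identical(sx1$trajectories[[1]]$end_to_end,
                         sx1$trajectories[[2]]$end_to_end))
  seeds <- vapply(sx1$trajectories, `[[`, numeric(1), "seed")
  expect_false(anyDuplicated(seeds) > 0)
})

test_that("zero temperature quenches to the minimum", {
  ch <- make_ideal_chain(5)
  cfg <- sim_config(temperature = 1e-12, n_steps_equil = 5000, base_seed = 1)
  # start the quench from a perturbed conformation via direct propagation
  eq <- equilibrate(ch, cfg)
  e2e <- eq$trajectories[[1]]$end_to_end
  tail_e2e <- e2e[(length(e2e) - 10):length(e2e)]
  expect_lt(var(tail_e2e), 1e-12)
})

test_that("a single harmonic bond equipartitions within 3 SE", {
  ch <- make_dimer_chain()
  cfg <- sim_config(n_steps_equil = 1.5e6, base_seed = 9,
                    record_stride_equil = 150)
  eq <- equilibrate(ch, cfg)
  b <- eq$trajectories[[1]]$end_to_end
  b <- b[-seq_len(100)]                      # burn-in
  kT <- thermal_energy(300)$kBT_kJ_mol
  Epot <- 0.5 * ch$bond_k * (b - ch$bond_b0)^2
  # exact radial-measure expectation (the 3-D bond sees the r^2 Jacobian)
  exact <- 0.5 * ch$bond_k *
    harmonic_bond_moments(ch$bond_k, ch$bond_b0, kT)$var_dr
  se <- block_se(Epot)
  expect_lt(abs(mean(Epot) - exact), 3 * se + 0.015 * exact)
  # and the quadrature value itself is within a percent of kBT/2
  expect_equal(exact, kT / 2, tolerance = 0.01)
})

test_that("a bonds-only chain reproduces ideal-chain end-to-end statistics", {
  ch <- make_ideal_chain(8)
  cfg <- sim_config(n_steps_equil = 2e6, base_seed = 17,
                    record_stride_equil = 400)
  eq <- equilibrate(ch, cfg)
  r2 <- eq$trajectories[[1]]$end_to_end^2
  r2 <- r2[-seq_len(500)]                    # discard the extended start
  kT <- thermal_energy(300)$kBT_kJ_mol
  # freely jointed chain of harmonic links: <R^2> = (N-1) <b^2>
  expected <- 7 * harmonic_bond_moments(ch$bond_k, ch$bond_b0, kT)$mean_b2
  se <- block_se(r2)
  expect_lt(abs(mean(r2) - expected), 3 * se + 0.02 * expected)
})

test_that("start-conformation selection picks the frame nearest the trailing
           window mean, ties to the latest", {
  fake_traj <- function(e2e) {
    n <- length(e2e)
    structure(list(times = seq_len(n) * 1.0, end_to_end = e2e,
                   positions = array(rep(e2e, 6), c(n, 2, 3)),
                   final = matrix(0, 2, 3), seed = 1L),
              class = "cg_trajectory")
  }
  fake_ens <- function(e2e)
    structure(list(phase = "equil", trajectories = list(fake_traj(e2e)),
                   config = sim_config(n_steps_equil = 10),
                   chain = make_dimer_chain()),
              class = "trajectory_ensemble")
  # monotone 1..100: window 81..100, mean 90.5, tie between 90 and 91 -> 91
  sel <- select_start_conformation(fake_ens(as.numeric(1:100)))
  expect_equal(sel$frame, 91)
  expect_equal(sel$end_to_end, 91)
  # constant series: every frame ties -> last frame
  sel2 <- select_start_conformation(fake_ens(rep(2.5, 50)))
  expect_equal(sel2$frame, 50)
  # equilibrium well: selected frame within 1 sd of the window mean
  ch <- build_chain(linker_standin_sequence())
  cfg <- sim_config(n_steps_equil = 3e4, base_seed = 3)
  eq <- equilibrate(ch, cfg)
  st <- select_start_conformation(eq)
  e2e <- eq$trajectories[[1]]$end_to_end
  idx <- seq.int(floor(0.8 * length(e2e)) + 1, length(e2e))
  expect_lt(abs(st$end_to_end - mean(e2e[idx])), sd(e2e[idx]))
})

test_that("constant-force stretching raises the mean end-to-end distance and
           relaxation lowers it, with 1:1 pairing", {
  ch <- build_chain(linker_standin_sequence())
  cfg <- sim_config(n_steps_equil = 5e4, n_ensemble = 60, base_seed = 5,
                    pull_force = 1300)
  eq <- equilibrate(ch, cfg)
  st <- select_start_conformation(eq)
  sx <- run_stretch_ensemble(st, ch, cfg)
  mean_e2e <- rowMeans(vapply(sx$trajectories, `[[`,
                              numeric(cfg$n_pull_steps + 1), "end_to_end"))
  # ensemble-average extension grows through the pull (near-constant rate)
  q <- mean_e2e[round(seq(1, length(mean_e2e), length.out = 6))]
  expect_true(all(diff(q) > 0))
  rx <- run_relax_ensemble(sx)
  expect_equal(length(rx$trajectories), length(sx$trajectories))
  # pairing: relax i starts where stretch i ended
  for (i in c(1, 30, 60))
    expect_equal(rx$trajectories[[i]]$end_to_end[1],
                 sx$trajectories[[i]]$end_to_end[cfg$n_pull_steps + 1],
                 tolerance = 1e-12)
  final_stretch <- vapply(sx$trajectories, function(tr)
    tr$end_to_end[length(tr$end_to_end)], numeric(1))
  final_relax <- vapply(rx$trajectories, function(tr)
    tr$end_to_end[length(tr$end_to_end)], numeric(1))
  expect_lt(mean(final_relax), mean(final_stretch))
})

test_that("the pulled harmonic dimer follows the analytic exponential
           approach to F/k", {
  kT_low <- 20                                # K; keeps transverse noise small
  ch <- make_dimer_chain(bond_k = 5000, friction = 50, mass = 100)
  cfg <- sim_config(temperature = kT_low, n_ensemble = 300, t_pull = 0.5,
                    base_seed = 31, pull_force = 800)
  start <- rbind(c(0, 0, 0), c(ch$bond_b0, 0, 0))
  sx <- run_stretch_ensemble(start, ch, cfg)
  ext <- vapply(sx$trajectories, function(tr)
    tr$end_to_end[length(tr$end_to_end)], numeric(1))
  # relative coordinate: rate 2k/(m gamma), equilibrium extension F/k
  rate <- 2 * ch$bond_k / (100 * 50)
  expected <- ch$bond_b0 + (800 / 5000) * (1 - exp(-rate * cfg$t_pull))
  se <- sd(ext) / sqrt(length(ext))
  expect_lt(abs(mean(ext) - expected), 3 * se + 2e-3)
  # force off: decays back toward b0 at the same rate
  rx <- run_relax_ensemble(sx)
  ext_r <- vapply(rx$trajectories, function(tr)
    tr$end_to_end[length(tr$end_to_end)], numeric(1))
  d0 <- mean(ext)
  expected_r <- ch$bond_b0 + (d0 - ch$bond_b0) * exp(-rate * cfg$t_pull)
  se_r <- sd(ext_r) / sqrt(length(ext_r))
  expect_lt(abs(mean(ext_r) - expected_r), 3 * se_r + 2e-3)
})

test_that("double-well occupancies follow Boltzmann statistics within 3 SE", {
  kT <- 1; a <- 1; h <- 3; tilt <- 0.8
  x <- langevin_double_well(n_steps = 4e6, kT = kT, a = a, h = h,
                            tilt = tilt, x0 = -1, dt = 5e-4,
                            record_stride = 40, seed = 12)
  # quadrature oracle for the well occupancy ratio
  U <- function(z) h * ((z / a)^2 - 1)^2 + tilt * z
  Zneg <- integrate(function(z) exp(-U(z) / kT), -Inf, 0)$value
  Zpos <- integrate(function(z) exp(-U(z) / kT), 0, Inf)$value
  expected_ratio <- Zpos / Zneg
  ind <- as.numeric(x > 0)
  se_p <- block_se(ind)
  p <- mean(ind)
  ratio <- p / (1 - p)
  se_ratio <- se_p / (1 - p)^2                # delta method
  expect_lt(abs(ratio - expected_ratio), 3 * se_ratio)
  expect_gt(min(sum(x > 0), sum(x < 0)), 100) # both wells visited
})
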