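test_that("work accumulation follows the constant-force convention in both
           phases with exact unit round-trip", {
  kT <- thermal_energy(300)$kBT_kJ_mol
  tr <- list(end_to_end = c(2.0, 2.2, 2.5))      # stretched by 0.5 nm
  W <- accumulate_work(tr, force = 1300, phase = "stretch")
  expect_equal(attr(W, "kJ_mol"), 650)
  expect_equal(as.numeric(W), 650 / kT)
  expect_equal(as.numeric(W), 260.6, tolerance = 1e-3)
  # no net displacement: no work
  expect_equal(as.numeric(accumulate_work(list(end_to_end = c(3, 4, 3)),
                                          1300, "stretch")), 0)
  # relaxation: same force over the reversed displacement, d drops 0.2 nm
  Wr <- accumulate_work(list(end_to_end = c(2.5, 2.4, 2.3)), 1300, "relax")
  expect_equal(attr(Wr, "kJ_mol"), 260)
  expect_gt(as.numeric(Wr), 0)
  # kJ/mol -> kBT -> kJ/mol is the identity
  expect_equal(attr(W, "kJ_mol"), as.numeric(W) * kT, tolerance = 1e-10)
  expect_error(accumulate_work(list(end_to_end = c(1, NaN)), 10, "stretch"),
               "non-finite")
})

test_that("Gaussian moment fits are exact on small samples", {
  fit <- fit_gaussian(c(3, 5))
  expect_equal(fit$mu, 4)
  expect_equal(fit$sigma, sqrt(2))
  expect_equal(fit_gaussian(rep(7, 10))$sigma, 0)
  expect_error(fit_gaussian(3), "at least 2")
  # CLT recovery of the generating moments
  set.seed(77)
  big <- rnorm(1e5, 1569.9, 24.9)
  expect_lt(abs(fit_gaussian(big)$mu - 1569.9), 3 * 24.9 / sqrt(1e5))
})

test_that("the crossing point solves the density equality and picks the root
           between the means", {
  gf <- function(mu, sigma)
    structure(list(mu = mu, sigma = sigma, n = 100L), class = "gaussian_fit")
  # equal variances: midpoint, exactly
  expect_equal(as.numeric(crossing_point(gf(10, 2), gf(4, 2))), 7)
  # unequal variances: compare against a uniroot density-equality oracle
  cases <- list(c(949.7, 23.9, 696.0, 81.5),     # poly-alanine reference
                c(1056.8, 26.8, 888.0, 63.9),    # proline-substituted
                c(733.7, 30.5, 651.0, 63.3),     # asparagine-substituted
                c(12, 3, 5, 1.2))
  for (cs in cases) {
    x <- as.numeric(crossing_point(gf(cs[1], cs[2]), gf(cs[3], cs[4])))
    oracle <- uniroot(function(w)
      dnorm(w, cs[1], cs[2]) - dnorm(w, cs[3], cs[4]),
      c(cs[3], cs[1]), tol = 1e-12)$root
    expect_equal(x, oracle, tolerance = 1e-9)
  }
  # both roots are exposed
  x <- crossing_point(gf(12, 3), gf(5, 1.2))
  expect_length(attr(x, "roots"), 2)
  # heavily overlapping narrow/wide pair: both roots fall outside the means
  expect_error(crossing_point(gf(2.0, 1.0), gf(1.5, 1.4)), "roots at")
})

test_that("crossing points reproduce the reported all-atom free energies
           from the shipped moment table", {
  mom <- reference_work_moments()
  expect_equal(nrow(mom), 5)
  gf <- function(mu, sigma)
    structure(list(mu = mu, sigma = sigma, n = NA_integer_),
              class = "gaussian_fit")
  recompute <- vapply(seq_len(5), function(i)
    as.numeric(crossing_point(gf(mom$mean_stretch[i], mom$sd_stretch[i]),
                              gf(mom$mean_relax[i], mom$sd_relax[i]))),
    numeric(1))
  rel <- abs(recompute - mom$delta_g_reported) / mom$delta_g_reported
  tight <- mom$peptide %in% c("ala_only", "no_asparagine", "no_proline")
  expect_true(all(rel[tight] <= 0.003))
  expect_true(all(rel <= 0.01))
})

test_that("the Jarzynski estimator is exponentially averaged, overflow-safe
           and bounded by the mean work", {
  expect_equal(jarzynski_estimate(rep(5, 100)), 5)
  # a single dominating low-work trajectory: dG ~ ln 2 above the minimum
  expect_equal(jarzynski_estimate(c(0, 100)), -log((1 + exp(-100)) / 2))
  expect_equal(jarzynski_estimate(c(0, 100)), 0.693, tolerance = 1e-3)
  # huge works must not overflow
  expect_true(is.finite(jarzynski_estimate(c(5000, 6000))))
  # Gaussian closed form mu - sigma^2/2
  gf <- structure(list(mu = 10, sigma = 2, n = 10L), class = "gaussian_fit")
  expect_equal(gaussian_jarzynski(gf), 8)
  gf0 <- structure(list(mu = 3, sigma = 0, n = 10L), class = "gaussian_fit")
  expect_equal(gaussian_jarzynski(gf0), 3)
  # MC agreement at n = 1e6 within 3 SE of the exponential average
  set.seed(101)
  W <- rnorm(1e6, 10, 2)
  est <- jarzynski_estimate(W)
  se <- sqrt((exp(2^2) - 1) / 1e6)     # SE of -ln mean(e^-W), delta method
  expect_lt(abs(est - 8), 3 * se)
  # second-law bound on assorted ensembles
  for (seed in 1:5) {
    set.seed(seed)
    W <- rnorm(500, runif(1, 0, 20), runif(1, 0.1, 5))
    expect_lte(jarzynski_estimate(W), mean(W))
  }
})

test_that("occupancy counts give the Boltzmann free-energy difference", {
  expect_equal(as.numeric(occupancy_delta_g(
    c(rep(-1, 1000), rep(1, 1000)), function(x) x < 0, function(x) x > 0)), 0)
  dg <- occupancy_delta_g(c(rep(-1, 1000), rep(1, 100)),
                          function(x) x < 0, function(x) x > 0)
  expect_equal(as.numeric(dg), -log(0.1))
  expect_equal(as.numeric(dg), 2.303, tolerance = 1e-3)
  expect_error(occupancy_delta_g(rep(-1, 50), function(x) x < 0,
                                 function(x) x > 0), "never visited")
  # Langevin double-well samples match the quadrature ratio
  kT <- 1; h <- 3; tilt <- 0.9
  x <- langevin_double_well(n_steps = 3e6, kT = kT, h = h, tilt = tilt,
                            dt = 5e-4, record_stride = 50, seed = 4)
  U <- function(z) h * (z^2 - 1)^2 + tilt * z
  Zn <- integrate(function(z) exp(-U(z) / kT), -Inf, 0)$value
  Zp <- integrate(function(z) exp(-U(z) / kT), 0, Inf)$value
  est <- as.numeric(occupancy_delta_g(x, function(z) z < 0,
                                      function(z) z > 0))
  se <- {
    ind <- as.numeric(x > 0); p <- mean(ind)
    block_se(ind) / (p * (1 - p))   # delta method on -log(p/(1-p))
  }
  expect_lt(abs(est - (-log(Zp / Zn))), 3 * se)
})

test_that("bootstrap intervals are deterministic, cover degenerate cases and
           shrink like 1/sqrt(n)", {
  est <- function(f, r) as.numeric(crossing_point(fit_gaussian(f),
                                                  fit_gaussian(r)))
  set.seed(55)
  f <- rnorm(400, 10, 2); r <- rnorm(400, 4, 2)
  ci1 <- bootstrap_ci(f, r, est, n_boot = 200, seed = 7)
  ci2 <- bootstrap_ci(f, r, est, n_boot = 200, seed = 7)
  expect_identical(ci1, ci2)
  expect_lt(ci1["low"], ci1["high"])
  expect_true(ci1["low"] < 7 && 7 < ci1["high"])
  # degenerate single sample: zero width with a warning
  expect_warning(ci0 <- bootstrap_ci(5, NULL, function(f) mean(f),
                                     n_boot = 100), "degenerate")
  expect_equal(unname(ci0["low"]), unname(ci0["high"]))
  # width scaling ~ 1/sqrt(n)
  widths <- vapply(c(100, 1000, 10000), function(n) {
    set.seed(n)
    fn <- rnorm(n, 10, 2); rn <- rnorm(n, 4, 2)
    ci <- bootstrap_ci(fn, rn, est, n_boot = 200, seed = 11)
    unname(ci["high"] - ci["low"])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_equal(widths[1] / widths[3], sqrt(100), tolerance = 0.5)
})

test_that("the combined estimate is internally consistent on synthetic
           Crooks-symmetric ensembles", {
  set.seed(123)
  f <- rnorm(2000, 10, 2); r <- rnorm(2000, 4, 2)
  fe <- free_energy_estimate(f, r, n_boot = 200, seed = 3)
  # equal-variance symmetric pair: crossing at the midpoint of the means
  expect_equal(fe$delta_g_crossing, (mean(f) + mean(r)) / 2, tolerance = 0.02)
  expect_lte(fe$delta_g_jarzynski, fe$mean_w_f)
  expect_true(fe$ci_low <= fe$delta_g_crossing &&
                fe$delta_g_crossing <= fe$ci_high)
  # Gaussian closed form agrees with the moment fit by construction
  expect_equal(fe$delta_g_gaussian, fe$mean_w_f - fe$sd_w_f^2 / 2)
})
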