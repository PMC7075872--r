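#' Work done on a trajectory by the constant pulling force
#'
#' For a constant-magnitude force conjugate to the end-to-end distance d, the
#' accumulated mechanical work reduces to `W = F * (d_final - d_initial)` for
#' the stretch phase. For the relaxation phase the force is off in the
#' dynamics; the reverse-protocol work is defined with the same F over the
#' reversed displacement, `W = F * (d_initial - d_final)` (the conjugate
#' reading of the forward/reverse pair; see the methods vignette).
#'
#' @param trajectory A `cg_trajectory` (or list with `end_to_end`).
#' @param force Pulling force, kJ/mol/nm.
#' @param phase `"stretch"` or `"relax"`.
#' @param temperature Temperature (K) for the kBT conversion.
#' @return Work in kBT (attribute `kJ_mol` carries the kJ/mol value).
#' @export
accumulate_work <- function(trajectory, force, phase = c("stretch", "relax"),
                            temperature = 300) {
  phase <- match.arg(phase)
  d <- trajectory$end_to_end
  if (!all(is.finite(d))) stop("non-finite end-to-end distances")
  delta <- d[length(d)] - d[1]
  W_kJ <- if (phase == "stretch") force * delta else -force * delta
  W <- W_kJ / thermal_energy(temperature)$kBT_kJ_mol
  attr(W, "kJ_mol") <- W_kJ
  W
}

#' Collect per-trajectory work samples from an ensemble
#'
#' @param ensemble A stretch or relax `trajectory_ensemble`.
#' @param force Pulling force (defaults to the ensemble's configured force;
#'   the relax phase uses the same force by the reverse-work convention).
#' @return A `work_ensemble`: list with `samples` (kBT), `phase`, `n`,
#'   `temperature`, `force`.
#' @export
work_ensemble <- function(ensemble, force = ensemble$config$pull_force) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"),
            ensemble$phase %in% c("stretch", "relax"))
  W <- vapply(ensemble$trajectories, function(tr)
    as.numeric(accumulate_work(tr, force, ensemble$phase,
                               ensemble$config$temperature)), numeric(1))
  structure(list(samples = W, phase = ensemble$phase, n = length(W),
                 temperature = ensemble$config$temperature, force = force),
            class = "work_ensemble")
}

.work_samples <- function(w) {
  if (inherits(w, "work_ensemble")) w$samples else as.numeric(w)
}

#' Moment fit of a Gaussian to a work distribution
#'
#' Sample mean and unbiased standard deviation; bin-free, so the downstream
#' crossing point does not depend on histogramming choices.
#'
#' @param works A `work_ensemble` or numeric vector (kBT).
#' @return A `gaussian_fit`: list `mu`, `sigma`, `n`.
#' @export
fit_gaussian <- function(works) {
  W <- .work_samples(works)
  if (length(W) < 2L) stop("need at least 2 work samples")
  structure(list(mu = mean(W), sigma = stats::sd(W), n = length(W)),
            class = "gaussian_fit")
}

#' Crossing point of forward and reverse Gaussian work distributions
#'
#' Solves for the work value where the two fitted normal densities are
#' equal. With equal variances this is the midpoint of the means; with
#' unequal variances the density equality is a quadratic in W and the root
#' lying between the two means is returned (the crossing between the
#' distribution peaks, which estimates the free-energy difference). Both
#' roots are attached as an attribute.
#'
#' @param f,r `gaussian_fit` objects (or `work_ensemble`s, fitted on the
#'   fly) for the forward (stretch) and reverse (relax) distributions.
#' @return Crossing work in kBT, with attribute `roots`.
#' @export
crossing_point <- function(f, r) {
  if (!inherits(f, "gaussian_fit")) f <- fit_gaussian(f)
  if (!inherits(r, "gaussian_fit")) r <- fit_gaussian(r)
  if (f$sigma == 0 || r$sigma == 0) {
    if (isTRUE(all.equal(f$mu, r$mu))) return(f$mu)
    stop("degenerate (zero-sigma) fit with distinct means has no crossing")
  }
  lo <- min(f$mu, r$mu); hi <- max(f$mu, r$mu)
  if (isTRUE(all.equal(f$sigma, r$sigma))) {
    x <- (f$mu + r$mu) / 2
    attr(x, "roots") <- x
    return(x)
  }
  # log-density equality: quadratic a W^2 + b W + c = 0
  a <- 1 / (2 * r$sigma^2) - 1 / (2 * f$sigma^2)
  b <- f$mu / f$sigma^2 - r$mu / r$sigma^2
  c0 <- r$mu^2 / (2 * r$sigma^2) - f$mu^2 / (2 * f$sigma^2) +
    log(r$sigma / f$sigma)
  disc <- b^2 - 4 * a * c0
  if (disc < 0) stop("work distributions do not cross (no real root)")
  roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  inside <- roots[roots >= lo & roots <= hi]
  if (!length(inside))
    stop("no crossing between the distribution means; roots at ",
         paste(signif(roots, 6), collapse = ", "))
  x <- inside[1]
  attr(x, "roots") <- roots
  x
}

# numerically stable log(mean(exp(x)))
.log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Jarzynski free-energy estimate from a work ensemble
#'
#' `dG = -kBT ln < e^{-W/kBT} >` over repeated realizations of the process,
#' computed with a log-sum-exp reduction so that large work values cannot
#' overflow. Works and result are in kBT.
#'
#' @param works A `work_ensemble` or numeric vector (kBT).
#' @return Free-energy difference in kBT.
#' @export
jarzynski_estimate <- function(works) {
  W <- .work_samples(works)
  if (!length(W)) stop("empty work ensemble")
  -.log_mean_exp(-W)
}

#' Closed-form Jarzynski estimate for a Gaussian work distribution
#'
#' If p(W) is normal with moments (mu, sigma) in kBT units, the exponential
#' average evaluates to `dG = mu - sigma^2 / 2`.
#'
#' @param fit A `gaussian_fit`.
#' @return Free-energy difference in kBT.
#' @export
gaussian_jarzynski <- function(fit) {
  stopifnot(inherits(fit, "gaussian_fit"))
  fit$mu - fit$sigma^2 / 2
}

#' Free-energy difference between configurational regions from visit counts
#'
#' The equilibrium probability of a region is proportional to its restricted
#' partition function, so `dG_{A->B} = -kBT ln(n_B / n_A)` estimated from
#' the number of times the sampled coordinate visited each region.
#'
#' @param samples Numeric coordinate samples from an equilibrium trajectory.
#' @param in_a,in_b Predicate functions mapping samples to logicals.
#' @param temperature Temperature (K), carried for unit conversion only; the
#'   returned value is in kBT.
#' @return dG(A -> B) in kBT (attribute `counts`).
#' @export
occupancy_delta_g <- function(samples, in_a, in_b, temperature = 300) {
  na <- sum(in_a(samples)); nb <- sum(in_b(samples))
  if (na == 0L || nb == 0L)
    stop("a region was never visited (counts A=", na, ", B=", nb,
         "); sample longer")
  dg <- -log(nb / na)
  attr(dg, "counts") <- c(A = na, B = nb)
  dg
}

#' Percentile-bootstrap confidence interval for a free-energy estimator
#'
#' Resamples trajectories (work samples) with replacement and recomputes the
#' estimator; deterministic for a fixed seed.
#'
#' @param works_f Forward work samples (`work_ensemble` or numeric, kBT).
#' @param works_r Reverse work samples, or `NULL` for single-ensemble
#'   estimators.
#' @param estimator Function of one (forward-only) or two numeric vectors
#'   returning a scalar, e.g.
#'   `function(f, r) crossing_point(fit_gaussian(f), fit_gaussian(r))`.
#' @param n_boot Bootstrap replicates (>= 100).
#' @param seed RNG seed.
#' @param level Confidence level (default 0.95).
#' @return Named numeric `c(low, high)` (attribute `replicates`).
#' @export
bootstrap_ci <- function(works_f, works_r = NULL, estimator, n_boot = 1000,
                         seed = 1, level = 0.95) {
  stopifnot(n_boot >= 100)
  Wf <- .work_samples(works_f)
  Wr <- if (!is.null(works_r)) .work_samples(works_r)
  if (length(Wf) < 2L || (!is.null(Wr) && length(Wr) < 2L)) {
    warning("degenerate ensemble: zero-width interval")
    v <- if (is.null(Wr)) estimator(Wf) else estimator(Wf, Wr)
    return(c(low = v, high = v))
  }
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    f <- sample(Wf, replace = TRUE)
    tryCatch(
      if (is.null(Wr)) estimator(f)
      else estimator(f, sample(Wr, replace = TRUE)),
      error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(reps))) stop("estimator failed on every bootstrap replicate")
  if (anyNA(reps))
    warning(sum(is.na(reps)), " of ", n_boot,
            " bootstrap replicates failed and were dropped")
  ci <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, na.rm = TRUE)
  out <- c(low = ci[1], high = ci[2])
  attr(out, "replicates") <- reps
  out
}

#' Combined free-energy estimate for a stretch/relax ensemble pair
#'
#' Reports the crossing-point estimate (with bootstrap CI), the Jarzynski
#' exponential average of the forward works, and the Gaussian closed form.
#'
#' @param works_f,works_r Forward and reverse `work_ensemble`s or numeric
#'   vectors (kBT).
#' @param n_boot,seed Bootstrap parameters.
#' @return A `free_energy_estimate`: list with `delta_g_crossing`,
#'   `delta_g_jarzynski`, `delta_g_gaussian`, `ci_low`, `ci_high` (crossing
#'   CI), `mean_w_f`, `mean_w_r` (all kBT).
#' @export
free_energy_estimate <- function(works_f, works_r, n_boot = 1000, seed = 1) {
  Wf <- .work_samples(works_f); Wr <- .work_samples(works_r)
  fit_f <- fit_gaussian(Wf); fit_r <- fit_gaussian(Wr)
  cross <- as.numeric(crossing_point(fit_f, fit_r))
  ci <- bootstrap_ci(Wf, Wr, function(f, r)
    as.numeric(crossing_point(fit_gaussian(f), fit_gaussian(r))),
    n_boot = n_boot, seed = seed)
  structure(list(delta_g_crossing = cross,
                 delta_g_jarzynski = jarzynski_estimate(Wf),
                 delta_g_gaussian = gaussian_jarzynski(fit_f),
                 ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
                 mean_w_f = fit_f$mu, mean_w_r = fit_r$mu,
                 sd_w_f = fit_f$sigma, sd_w_r = fit_r$sigma),
            class = "free_energy_estimate")
}
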