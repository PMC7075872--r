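#' End-to-end distance distribution with Gaussianity assessment
#'
#' Fits a normal by moments to the end-to-end samples of a trajectory window
#' and runs a Kolmogorov-Smirnov test against that fitted normal. A chain
#' rattling inside a single energy well behaves like a Gaussian chain, so
#' near-Gaussian windows indicate (local) equilibration; heavy deviations
#' flag well-hopping.
#'
#' @param series Numeric end-to-end samples (nm), or a `cg_trajectory`.
#' @param window Optional integer frame range (e.g. `9001:19000`); default
#'   all frames.
#' @return A `distance_distribution`: list with `samples`, `mean`, `sd`,
#'   `ks_stat`, `ks_p` and `degenerate` (TRUE when sd = 0, in which case the
#'   KS test is skipped).
#' @export
end_to_end_distribution <- function(series, window = NULL) {
  if (inherits(series, "cg_trajectory")) series <- series$end_to_end
  series <- as.numeric(series)
  if (!is.null(window)) {
    if (min(window) < 1 || max(window) > length(series))
      stop("window out of range (1..", length(series), ")")
    series <- series[window]
  }
  if (!length(series)) stop("empty window")
  m <- mean(series); s <- stats::sd(series)
  degenerate <- !is.finite(s) || s == 0
  ks <- if (!degenerate)
    suppressWarnings(stats::ks.test(series, "pnorm", mean = m, sd = s))
  structure(list(samples = series, mean = m, sd = s,
                 ks_stat = if (degenerate) NA_real_ else unname(ks$statistic),
                 ks_p = if (degenerate) NA_real_ else ks$p.value,
                 degenerate = degenerate),
            class = "distance_distribution")
}

#' Ensemble-averaged pair-distance profiles versus time
#'
#' Mean distance between a reference residue and each target residue at every
#' recorded step, averaged over the ensemble. Distances between a residue
#' and its close sequence neighbors stay near-constant under pulling, while
#' distant pairs extend — the profile separates local from global
#' stretching. Requires position-recording ensembles.
#'
#' @param ensemble A `trajectory_ensemble` run with
#'   `record_positions = TRUE`.
#' @param reference_index Reference residue (default 4).
#' @param target_indices Target residues.
#' @return Data.frame: `time` (ps), `target`, `mean_distance` (nm).
#' @export
pair_distance_profiles <- function(ensemble, reference_index = 4,
                                   target_indices) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  n <- ensemble$chain$n
  if (reference_index < 1 || reference_index > n)
    stop("reference index out of range")
  if (any(target_indices < 1 | target_indices > n))
    stop("target index out of range")
  if (any(target_indices == reference_index))
    stop("reference and target residues must differ")
  trajs <- ensemble$trajectories
  if (is.null(trajs[[1]]$positions))
    stop("ensemble was run without recorded positions")
  nrec <- dim(trajs[[1]]$positions)[1]
  out <- lapply(target_indices, function(tg) {
    acc <- numeric(nrec)
    for (tr in trajs) {
      d <- sqrt(rowSums((tr$positions[, reference_index, ] -
                           tr$positions[, tg, ])^2))
      acc <- acc + d
    }
    data.frame(time = trajs[[1]]$times, target = tg,
               mean_distance = acc / length(trajs))
  })
  do.call(rbind, out)
}

#' Fractional extension of a stretched chain
#'
#' `(current - relaxed_mean) / (Lc - relaxed_mean)`: 0 at the relaxed mean
#' end-to-end distance, 1 at full contour length `Lc = n_residues *
#' per_residue_contour`. The dimensionless stretch coordinate for comparing
#' chains of different sequence and length.
#'
#' @param current Current end-to-end distance, nm.
#' @param relaxed_mean Mean relaxed end-to-end distance, nm.
#' @param n_residues Chain length.
#' @param per_residue_contour Contour length per residue, nm (default 0.4).
#' @return A `fractional_extension`: list with `value`, `relaxed_mean`,
#'   `current`, `Lc`.
#' @export
fractional_extension <- function(current, relaxed_mean, n_residues,
                                 per_residue_contour = 0.4) {
  Lc <- n_residues * per_residue_contour
  if (Lc <= relaxed_mean)
    stop("contour length (", Lc, " nm) must exceed the relaxed mean (",
         relaxed_mean, " nm)")
  structure(list(value = (current - relaxed_mean) / (Lc - relaxed_mean),
                 relaxed_mean = relaxed_mean, current = current, Lc = Lc),
            class = "fractional_extension")
}

#' Quadratic stiffness fit of dG versus fractional extension
#'
#' Least squares of `dG = a f^2 + b` (no linear term: an effective harmonic
#' spring about the relaxed state, parameterized by a stiffness coefficient
#' and an intercept). A three-parameter fit with a linear term is available
#' behind `linear_term = TRUE`.
#'
#' @param points Data.frame with columns `f` (fractional extension) and `dg`
#'   (kBT); at least 3 points with distinct `f^2`.
#' @param linear_term Include a linear term (default FALSE).
#' @return A `stiffness_fit`: list with `quadratic_coef` (kBT), `intercept`
#'   (kBT), optional `linear_coef`, `rss`, `r_squared`, `points`.
#' @export
fit_quadratic_stiffness <- function(points, linear_term = FALSE) {
  stopifnot(is.data.frame(points), all(c("f", "dg") %in% names(points)))
  points <- points[stats::complete.cases(points[, c("f", "dg")]), ]
  if (nrow(points) < 3L) stop("need at least 3 points")
  if (length(unique(signif(points$f^2, 12))) < 2L)
    stop("rank-deficient fit: all fractional extensions equal")
  fit <- if (linear_term) stats::lm(dg ~ I(f^2) + f, data = points)
         else stats::lm(dg ~ I(f^2), data = points)
  cf <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((points$dg - mean(points$dg))^2)
  structure(list(quadratic_coef = unname(cf["I(f^2)"]),
                 intercept = unname(cf["(Intercept)"]),
                 linear_coef = if (linear_term) unname(cf["f"]),
                 rss = rss,
                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                 points = points),
            class = "stiffness_fit")
}

#' Worm-like-chain force-extension relation
#'
#' The standard interpolation
#' `F = (kBT / L) [ 1/4 (1 - x/Lc)^-2 + x/Lc - 1/4 ]`
#' for a semiflexible polymer of contour length Lc and persistence length L:
#' zero force at zero extension, divergence as the extension approaches the
#' contour length. `as_printed = TRUE` switches the linear term to `x/L`
#' (a dimensionally inconsistent variant retained for comparison; see the
#' methods vignette).
#'
#' @param x Extension, nm (0 <= x < Lc).
#' @param Lc Contour length, nm.
#' @param L Persistence length, nm.
#' @param temperature Temperature, K.
#' @param as_printed Use `x/L` in the linear term.
#' @return Force in pN.
#' @export
wlc_force <- function(x, Lc, L, temperature = 300, as_printed = FALSE) {
  stopifnot(Lc > 0, L > 0)
  if (any(x < 0 | x >= Lc))
    stop("extension must satisfy 0 <= x < Lc")
  kbt <- thermal_energy(temperature)$kBT_pN_nm
  lin <- if (as_printed) x / L else x / Lc
  (kbt / L) * (0.25 * (1 - x / Lc)^-2 + lin - 0.25)
}
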