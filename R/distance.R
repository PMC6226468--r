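#' Per-fluorophore quenching observations
#'
#' Container for the DEPET observable: conductance-normalized fluorescence
#' changes (delta F / G), with replicates grouped by fluorophore.
#'
#' @param replicates Named list: one numeric vector of replicate
#'   `delta F / G` values per fluorophore tag (each with at least one
#'   replicate).
#' @param labeled_site_tag,quencher_site_tag Free-text site labels.
#' @return Object of class `quenching_dataset`.
#' @export
quenching_dataset <- function(replicates, labeled_site_tag = "",
                              quencher_site_tag = "") {
  if (length(replicates) < 1)
    stop("quenching_dataset: need at least one fluorophore", call. = FALSE)
  if (is.null(names(replicates)) || any(!nzchar(names(replicates))))
    stop("quenching_dataset: replicates must be named by fluorophore", call. = FALSE)
  if (any(vapply(replicates, length, 0L) < 1))
    stop("quenching_dataset: every fluorophore needs at least one replicate", call. = FALSE)
  structure(list(replicates = lapply(replicates, as.numeric),
                 labeled_site_tag = labeled_site_tag,
                 quencher_site_tag = quencher_site_tag),
            class = "quenching_dataset")
}

#' @export
print.quenching_dataset <- function(x, ...) {
  cat(sprintf("quenching dataset (%s ~ %s): %d fluorophores\n",
              x$labeled_site_tag, x$quencher_site_tag, length(x$replicates)))
  for (tag in names(x$replicates))
    cat(sprintf("  %-16s n=%d  mean dF/G = %.4g\n", tag,
                length(x$replicates[[tag]]), mean(x$replicates[[tag]])))
  invisible(x)
}

#' Forward model: fluorescence change from a state transition
#'
#' The predicted conductance-normalized fluorescence change of one
#' fluorophore when the quencher-bearing segment moves from a resting
#' distance `d_r` to an active distance `d_a`:
#' \deqn{\Delta F_X = [FDQ(X, d_R) - FDQ(X, d_A)]\, c}
#' where `c` converts quenching probability to fluorescence units.
#'
#' @param fdq An [fdq_model()].
#' @param d_r,d_a Resting and active anchor distances (Angstrom).
#' @param c_coef Positive conversion coefficient.
#' @return Predicted `delta F / G`.
#' @export
forward_deltaF <- function(fdq, d_r, d_a, c_coef) {
  if (any(c_coef <= 0)) stop("forward_deltaF: c must be positive", call. = FALSE)
  c_coef * (eval_fdq(fdq, d_r) - eval_fdq(fdq, d_a))
}

#' Bootstrap resampling of a quenching dataset
#'
#' For each bootstrap set and each fluorophore independently, resamples that
#' fluorophore's replicates with replacement (keeping the replicate count)
#' and records the mean. Reproducible under `seed`.
#'
#' @param dataset A [quenching_dataset()].
#' @param n_sets Number of bootstrap sets (default 10000).
#' @param seed Integer seed.
#' @return `n_sets x n_fluorophores` matrix of bootstrap-averaged
#'   `delta F / G`, columns named by fluorophore.
#' @export
bootstrap_resample <- function(dataset, n_sets = 10000, seed = 1) {
  stopifnot(inherits(dataset, "quenching_dataset"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- vapply(dataset$replicates, function(reps) {
    n <- length(reps)
    if (n == 1) rep(reps, n_sets)
    else colMeans(matrix(reps[sample.int(n, n * n_sets, replace = TRUE)], nrow = n))
  }, numeric(n_sets))
  if (n_sets == 1) out <- matrix(out, nrow = 1,
                                 dimnames = list(NULL, names(dataset$replicates)))
  out
}

#' Seed grid for multi-start nonlinear fitting
#'
#' To avoid local error minima, the initial guess of every free parameter is
#' seeded in `increments` evenly spaced values (inclusive of both bounds;
#' the conversion coefficient `c` is log-spaced), and the full cartesian
#' product is enumerated: `increments ^ n_params` starting points per fit.
#'
#' @param param_bounds Named list of numeric length-2 bounds, one per free
#'   parameter; a parameter named `"c"` (or `"log_c"`) is log-spaced.
#' @param increments Seeds per parameter, default 5.
#' @return Object of class `seed_grid`: `values` (per-parameter seed lists),
#'   `grid` (matrix, one row per combination), `size`.
#' @export
build_seed_grid <- function(param_bounds, increments = 5) {
  if (increments < 2) stop("build_seed_grid: need at least 2 increments", call. = FALSE)
  vals <- lapply(names(param_bounds), function(nm) {
    b <- param_bounds[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] >= b[2])
      stop(sprintf("build_seed_grid: invalid bounds for '%s'", nm), call. = FALSE)
    if (nm %in% c("c", "log_c")) {
      if (b[1] <= 0) stop("build_seed_grid: c bounds must be positive", call. = FALSE)
      exp(seq(log(b[1]), log(b[2]), length.out = increments))
    } else seq(b[1], b[2], length.out = increments)
  })
  names(vals) <- names(param_bounds)
  grid <- as.matrix(expand.grid(vals, KEEP.OUT.ATTRS = FALSE))
  structure(list(values = vals, grid = grid, size = nrow(grid)),
            class = "seed_grid")
}

#' @export
print.seed_grid <- function(x, ...) {
  cat(sprintf("seed grid: %d parameters x %d increments = %d combinations\n",
              length(x$values), length(x$values[[1]]), x$size))
  invisible(x)
}

# shared plumbing: prepare C++ inputs and bounds for the LM batch call
depet_bounds <- function(fdq_set, distance_bounds, c_bounds) {
  if (is.null(distance_bounds)) distance_bounds <- c(3, 28)
  list(d = distance_bounds, lc = log(c_bounds))
}

strip_fdq <- function(m) m[c("exp_amplitudes", "exp_length_constants",
                             "gauss_amplitudes", "gauss_means", "gauss_sds",
                             "ksv_scale")]

seed_matrix_lc <- function(grid, c_col) {
  g <- grid$grid
  g[, c_col] <- log(g[, c_col])
  g
}

# carbon-bond retention predicate, boundary inclusive: a backbone/side-chain
# distance difference of exactly cc is geometrically admissible
cc_constraint_ok <- function(d_aa, d_ab, cc) {
  abs(d_aa - d_ab) <= cc + 1e-9
}

# 95% bootstrap interval of a solution distribution. With few replicates per
# fluorophore the plain 2.5-97.5 percentile interval is systematically
# narrow (the resampled mean underestimates the sampling variance by
# (n-1)/n and ignores Student-t tails); the expanded percentile interval
# (Hesterberg 2015) widens the quantile levels to
# Phi(-sqrt(n/(n-1)) * t_{n-1, 0.025}), which converges to the plain
# percentile interval as n grows.
boot_ci <- function(draws, n_rep = Inf, level = 0.95) {
  a <- (1 - level) / 2
  if (is.finite(n_rep) && n_rep > 1) {
    a <- stats::pnorm(-sqrt(n_rep / (n_rep - 1)) *
                        stats::qt(1 - a, df = n_rep - 1))
  }
  unname(stats::quantile(draws, c(a, 1 - a)))
}

#' Fit one distance pair to a single sample of fluorophore means
#'
#' Nonlinear least squares of per-fluorophore `delta F / G` means against
#' the forward model `[FDQ(X, d_R) - FDQ(X, d_A)] c`, started from every
#' seed in the grid; only the least-error solution is kept.
#'
#' @param sample Named numeric vector of per-fluorophore means, aligned with
#'   `fdq_aa`.
#' @param fdq_aa List of [fdq_model()] objects, one per fluorophore.
#' @param grid A [build_seed_grid()] with parameters `d_r`, `d_a`, `c`.
#' @param distance_bounds,c_bounds Box constraints for the optimizer
#'   (defaults: the grid's seed ranges).
#' @return List: `d_r`, `d_a`, `c`, `sse`, `degenerate` (TRUE when the
#'   optimum has `d_r == d_a`, e.g. from all-zero data).
#' @export
fit_single_pair <- function(sample, fdq_aa, grid,
                            distance_bounds = NULL, c_bounds = NULL) {
  if (length(fdq_aa) < 3)
    stop("fit_single_pair: need at least 3 fluorophores for 3 free parameters",
         call. = FALSE)
  stopifnot(inherits(grid, "seed_grid"), ncol(grid$grid) == 3)
  db <- distance_bounds %||% range(grid$values[[1]], grid$values[[2]])
  cb <- c_bounds %||% range(grid$values[[3]])
  res <- .depet_lm_batch(matrix(sample, nrow = 1), lapply(fdq_aa, strip_fdq),
                         NULL, seed_matrix_lc(grid, 3),
                         c(db[1], db[1], log(cb[1])), c(db[2], db[2], log(cb[2])),
                         mode = 1L)
  list(d_r = res[1, 1], d_a = res[1, 2], c = exp(res[1, 3]), sse = res[1, 4],
       degenerate = abs(res[1, 1] - res[1, 2]) < 1e-9)
}

#' Fit backbone and side-chain distance pairs jointly
#'
#' Stacked least squares over the alpha-alpha and alpha-beta equation sets,
#' which share the conversion coefficient `c`: five free parameters
#' (`d_aa_r`, `d_aa_a`, `d_ab_r`, `d_ab_a`, `c`). Solutions violating the
#' carbon-bond constraint `|d_aa - d_ab| <= cc_limit` in either state are
#' reported with `retained = FALSE` (callers exclude, never project, them).
#'
#' @param sample Named numeric vector of per-fluorophore means.
#' @param fdq_aa,fdq_ab FDQ model lists (same fluorophore order).
#' @param grid A [build_seed_grid()] with parameters `d_aa_r`, `d_aa_a`,
#'   `d_ab_r`, `d_ab_a`, `c`.
#' @param distance_bounds,c_bounds Optimizer box constraints.
#' @param cc_limit Carbon-carbon bond length (Angstrom), default 1.54.
#' @return List: the five parameters, `sse`, `retained`.
#' @export
fit_dual_pair <- function(sample, fdq_aa, fdq_ab, grid,
                          distance_bounds = NULL, c_bounds = NULL,
                          cc_limit = 1.54) {
  if (length(fdq_aa) < 3)
    stop("fit_dual_pair: need at least 3 fluorophores", call. = FALSE)
  if (length(fdq_ab) != length(fdq_aa))
    stop("fit_dual_pair: FDQ set sizes differ", call. = FALSE)
  stopifnot(inherits(grid, "seed_grid"), ncol(grid$grid) == 5)
  db <- distance_bounds %||% range(unlist(grid$values[1:4]))
  cb <- c_bounds %||% range(grid$values[[5]])
  res <- .depet_lm_batch(matrix(sample, nrow = 1), lapply(fdq_aa, strip_fdq),
                         lapply(fdq_ab, strip_fdq), seed_matrix_lc(grid, 5),
                         c(rep(db[1], 4), log(cb[1])), c(rep(db[2], 4), log(cb[2])),
                         mode = 2L)
  p <- res[1, ]
  ok <- cc_constraint_ok(p[1], p[3], cc_limit) && cc_constraint_ok(p[2], p[4], cc_limit)
  list(d_aa_r = p[1], d_aa_a = p[2], d_ab_r = p[3], d_ab_a = p[4],
       c = exp(p[5]), sse = p[6], retained = ok)
}

#' Bootstrap DEPET distance inversion
#'
#' The full DEPET inverse problem: bootstrap the per-fluorophore replicate
#' `delta F / G` observations into `n_bootstrap` sample sets, fit every set
#' from every seed of a five-increment-per-parameter grid, keep each set's
#' least-error solution, and summarize the retained solutions as means and
#' 95 percent percentile confidence intervals. In `"aa_only"` mode three
#' parameters are fit (backbone distances and `c`, 125 seeds); in `"aa_ab"`
#' mode five (adding the side-chain distances, 3125 seeds), and bootstrap
#' solutions violating the carbon-bond constraint in either state are
#' excluded.
#'
#' @param dataset A [quenching_dataset()].
#' @param fdq_aa List of alpha-alpha [fdq_model()]s named by fluorophore (or
#'   aligned with the dataset order).
#' @param fdq_ab Alpha-beta FDQ models (required for `mode = "aa_ab"`).
#' @param mode `"aa_only"` or `"aa_ab"`.
#' @param n_bootstrap Number of bootstrap sets, default 10000.
#' @param seed Integer seed for the bootstrap resampling.
#' @param distance_bounds Seed/box range for distances (Angstrom), default
#'   `c(3, 28)` (spanning typical FDQ support).
#' @param c_bounds Seed/box range for `c` (log-spaced), default
#'   `c(1e3, 1e7)`.
#' @param increments Seeds per parameter, default 5.
#' @param cc_limit Carbon-carbon bond constraint (Angstrom), default 1.54.
#' @return Object of class `depet_fit`: bootstrap `draws` (data.frame),
#'   `estimates` (mean + 95 percent CI per parameter), `fitted`
#'   (per-fluorophore mean fitted delta F / G), `n_fits_total`,
#'   `retained_fraction`, and the call configuration.
#' @seealso [fit_single_pair()], [fit_dual_pair()], [orientation_summary()]
#' @export
run_depet <- function(dataset, fdq_aa, fdq_ab = NULL,
                      mode = c("aa_only", "aa_ab"), n_bootstrap = 10000,
                      seed = 1, distance_bounds = c(3, 28),
                      c_bounds = c(1e3, 1e7), increments = 5,
                      cc_limit = 1.54) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "quenching_dataset"))
  tags <- names(dataset$replicates)
  fdq_aa <- align_fdq_set(fdq_aa, tags)
  if (mode == "aa_ab") {
    if (is.null(fdq_ab)) stop("run_depet: aa_ab mode needs fdq_ab", call. = FALSE)
    fdq_ab <- align_fdq_set(fdq_ab, tags)
  }
  if (length(tags) < 3)
    stop("run_depet: need at least 3 fluorophores", call. = FALSE)

  Y <- bootstrap_resample(dataset, n_bootstrap, seed)
  if (mode == "aa_only") {
    bounds <- list(d_r = distance_bounds, d_a = distance_bounds, c = c_bounds)
  } else {
    bounds <- list(d_aa_r = distance_bounds, d_aa_a = distance_bounds,
                   d_ab_r = distance_bounds, d_ab_a = distance_bounds,
                   c = c_bounds)
  }
  grid <- build_seed_grid(bounds, increments)
  np <- length(bounds)
  lower <- c(rep(distance_bounds[1], np - 1), log(c_bounds[1]))
  upper <- c(rep(distance_bounds[2], np - 1), log(c_bounds[2]))
  res <- .depet_lm_batch(Y, lapply(fdq_aa, strip_fdq),
                         if (mode == "aa_ab") lapply(fdq_ab, strip_fdq) else NULL,
                         seed_matrix_lc(grid, np), lower, upper,
                         mode = if (mode == "aa_only") 1L else 2L)
  draws <- as.data.frame(res)
  names(draws) <- c(names(bounds), "sse")
  draws$c <- exp(draws$c)

  retained <- rep(TRUE, nrow(draws))
  if (mode == "aa_ab") {
    retained <- cc_constraint_ok(draws$d_aa_r, draws$d_ab_r, cc_limit) &
      cc_constraint_ok(draws$d_aa_a, draws$d_ab_a, cc_limit)
    if (!any(retained))
      stop(sprintf(
        "run_depet: all %d bootstrap solutions violate the %.2f A carbon-bond constraint",
        nrow(draws), cc_limit), call. = FALSE)
  }
  kept <- draws[retained, , drop = FALSE]
  pn <- names(bounds)
  n_rep <- stats::median(vapply(dataset$replicates, length, 0L))
  cis <- lapply(pn, function(p) boot_ci(kept[[p]], n_rep))
  est <- data.frame(parameter = pn,
                    mean = vapply(pn, function(p) mean(kept[[p]]), 0),
                    ci_lower = vapply(cis, `[`, 0, 1),
                    ci_upper = vapply(cis, `[`, 0, 2),
                    row.names = NULL)
  # mean DEPET fit per fluorophore, from the retained-solution means
  mu <- stats::setNames(est$mean, est$parameter)
  fitted <- vapply(seq_along(tags), function(i)
    forward_deltaF(fdq_aa[[i]], mu[[1]], mu[[2]], mu[["c"]]), 0)
  names(fitted) <- tags

  structure(list(draws = draws, retained = retained, estimates = est,
                 fitted = fitted,
                 observed = vapply(dataset$replicates, mean, 0),
                 mode = mode, n_bootstrap = n_bootstrap, seed = seed,
                 n_fits_total = n_bootstrap * grid$size,
                 grid_size = grid$size,
                 retained_fraction = mean(retained),
                 cc_limit = cc_limit, fdq_aa = fdq_aa, fdq_ab = fdq_ab,
                 dataset = dataset),
            class = "depet_fit")
}

align_fdq_set <- function(fdq_set, tags) {
  if (inherits(fdq_set, "fdq_model")) fdq_set <- list(fdq_set)
  stopifnot(all(vapply(fdq_set, inherits, TRUE, "fdq_model")))
  if (!is.null(names(fdq_set)) && all(tags %in% names(fdq_set)))
    return(fdq_set[tags])
  if (length(fdq_set) != length(tags))
    stop("FDQ set does not match the dataset's fluorophores", call. = FALSE)
  stats::setNames(fdq_set, tags)
}

#' @export
print.depet_fit <- function(x, ...) {
  cat(sprintf("DEPET distance fit (%s): %d bootstrap sets x %d seeds = %s fits\n",
              x$mode, x$n_bootstrap, x$grid_size,
              format(x$n_fits_total, big.mark = ",")))
  if (x$mode == "aa_ab")
    cat(sprintf("  retained %.1f%% of solutions under the %.2f A constraint\n",
                100 * x$retained_fraction, x$cc_limit))
  df <- x$estimates
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-7s %10.4g  [95%% CI %.4g, %.4g]\n", df$parameter[i],
                df$mean[i], df$ci_lower[i], df$ci_upper[i]))
  invisible(x)
}

#' @export
summary.depet_fit <- function(object, ...) {
  out <- list(estimates = object$estimates,
              fitted = data.frame(fluorophore = names(object$fitted),
                                  observed = object$observed,
                                  fitted = object$fitted, row.names = NULL),
              mode = object$mode, n_bootstrap = object$n_bootstrap,
              n_fits_total = object$n_fits_total,
              retained_fraction = object$retained_fraction)
  class(out) <- "summary.depet_fit"
  out
}

#' @export
print.summary.depet_fit <- function(x, ...) {
  cat(sprintf("DEPET fit summary (%s mode, %s total fits, %.1f%% retained)\n",
              x$mode, format(x$n_fits_total, big.mark = ","),
              100 * x$retained_fraction))
  print(x$estimates)
  cat("\nper-fluorophore mean fits:\n")
  print(x$fitted)
  invisible(x)
}

#' @export
coef.depet_fit <- function(object, ...) {
  stats::setNames(object$estimates$mean, object$estimates$parameter)
}

#' @export
predict.depet_fit <- function(object, ...) object$fitted

#' @export
plot.depet_fit <- function(x, ...) {
  obs <- x$observed
  fit <- x$fitted
  idx <- seq_along(obs)
  graphics::plot(idx, obs, pch = 16, xaxt = "n", xlab = "fluorophore",
                 ylab = expression(Delta * F / G),
                 ylim = range(c(obs, fit)), ...)
  graphics::points(idx, fit, pch = 2, col = 2)
  graphics::axis(1, at = idx, labels = names(obs), las = 2, cex.axis = 0.8)
  graphics::legend("topright", legend = c("observed mean", "mean DEPET fit"),
                   pch = c(16, 2), col = c(1, 2), bty = "n")
  invisible(x)
}

#' Orientation of the quencher side chain from a dual fit
#'
#' Converts each retained bootstrap draw of a dual-distance solution into
#' the angle at the quencher C-alpha (law of cosines over `cc`, `d_aa`,
#' `d_ab`) and the planar coordinates of the labeled C-alpha, per state.
#' Draws failing the triangle inequality are excluded and counted.
#'
#' @param solution A [run_depet()] result fit in `"aa_ab"` mode.
#' @param cc Carbon-carbon bond length (Angstrom), default the fit's
#'   `cc_limit`.
#' @return List with one entry per state (`resting`, `active`): `angles`
#'   (degrees, per retained draw), `mean`, `ci` (95 percent), `coords`
#'   (mean planar x/y of the labeled C-alpha), `n_excluded`.
#' @export
orientation_summary <- function(solution, cc = solution$cc_limit) {
  stopifnot(inherits(solution, "depet_fit"))
  if (solution$mode != "aa_ab")
    stop("orientation_summary: needs a dual (aa_ab) solution", call. = FALSE)
  kept <- solution$draws[solution$retained, ]
  one_state <- function(d_aa, d_ab) {
    ok <- d_ab <= d_aa + cc + 1e-9 & d_ab >= abs(d_aa - cc) - 1e-9
    ang <- angle_from_distances(d_aa[ok], d_ab[ok], cc)
    pc <- planar_coordinates(d_aa[ok], ang, cc)
    list(angles = ang, mean = mean(ang),
         ci = unname(stats::quantile(ang, c(0.025, 0.975))),
         coords = c(x = mean(pc$x), y = mean(pc$y)),
         n_excluded = sum(!ok))
  }
  list(resting = one_state(kept$d_aa_r, kept$d_ab_r),
       active = one_state(kept$d_aa_a, kept$d_ab_a))
}
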