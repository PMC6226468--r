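#' Intramolecular quenching from HPLC peak quantities
#'
#' Quenching of a peptide-conjugated fluorophore relative to the free dye,
#' each normalized by its absorbance so that concentrations cancel:
#' \deqn{Q = 1 - \frac{F_{conj}/A_{conj}}{F_{free}/A_{free}}}
#' A negative value (conjugate apparently brighter than free dye, possible
#' under noise) is clamped to 0 with a warning.
#'
#' @param f_conj,a_conj Fluorescence and absorbance of the conjugate peak.
#' @param f_free,a_free Fluorescence and absorbance of the free-dye peak.
#' @return Quenching in `[0, 1]`. Vectorised.
#' @export
intramolecular_quenching <- function(f_conj, a_conj, f_free, a_free) {
  if (any(a_conj <= 0) || any(a_free <= 0))
    stop("intramolecular_quenching: absorbances must be positive", call. = FALSE)
  q <- 1 - (f_conj / a_conj) / (f_free / a_free)
  if (any(q < 0)) {
    warning("intramolecular_quenching: negative quenching clamped to 0")
    q <- pmax(q, 0)
  }
  q
}

#' Fit a peptide length from multi-fluorophore quenching
#'
#' Simultaneous least squares of per-fluorophore intramolecular quenching
#' against `c * FDQ(X, d)`: two free parameters (the Cys-Trp C-alpha
#' distance `d` and the conversion coefficient `c`), seeded on a 5 x 5 grid
#' and kept at the least-error solution. With replicate records per
#' fluorophore, a bootstrap over replicates yields 95 percent percentile
#' CIs.
#'
#' @param quenching Named list (by fluorophore) of replicate quenching
#'   values, or a named numeric vector of single observations.
#' @param fdq_aa List of alpha-alpha [fdq_model()]s (named by fluorophore,
#'   or aligned).
#' @param distance_bounds Seed/box range for `d` (Angstrom), default
#'   `c(3, 28)`.
#' @param c_bounds Seed/box range for `c` (log-spaced), default
#'   `c(1e-3, 1e3)` (quenching is already dimensionless).
#' @param increments Seeds per parameter, default 5.
#' @param n_bootstrap Bootstrap sets for the CI (0 disables), default 1000.
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `peptide_length_fit`: `d_aa`, `c`, `sse`,
#'   `ci_d`, `ci_c` (when bootstrapped), `fitted` per fluorophore.
#' @export
fit_peptide_length <- function(quenching, fdq_aa, distance_bounds = c(3, 28),
                               c_bounds = c(1e-3, 1e3), increments = 5,
                               n_bootstrap = 1000, seed = 1) {
  if (!is.list(quenching)) quenching <- as.list(quenching)
  if (length(quenching) < 2)
    stop("fit_peptide_length: need at least 2 fluorophores for 2 free parameters",
         call. = FALSE)
  tags <- names(quenching)
  fdq_aa <- align_fdq_set(fdq_aa, tags)
  means <- vapply(quenching, mean, 0)
  if (all(means == 0))
    stop("fit_peptide_length: all-zero quenching is unidentifiable", call. = FALSE)
  grid <- build_seed_grid(list(d = distance_bounds, c = c_bounds), increments)
  lower <- c(distance_bounds[1], log(c_bounds[1]))
  upper <- c(distance_bounds[2], log(c_bounds[2]))
  models <- lapply(fdq_aa, strip_fdq)
  fit_one <- function(y) {
    r <- .depet_lm_batch(matrix(y, nrow = 1), models, NULL,
                         seed_matrix_lc(grid, 2), lower, upper, mode = 3L)
    c(d = r[1, 1], c = exp(r[1, 2]), sse = r[1, 3])
  }
  est <- fit_one(means)
  ci_d <- ci_c <- NULL
  if (n_bootstrap > 0 && any(vapply(quenching, length, 0L) > 1)) {
    Y <- bootstrap_resample(quenching_dataset(quenching), n_bootstrap, seed)
    bs <- t(apply(Y, 1, fit_one))
    n_rep <- stats::median(vapply(quenching, length, 0L))
    ci_d <- boot_ci(bs[, "d"], n_rep)
    ci_c <- boot_ci(bs[, "c"], n_rep)
  }
  fitted <- vapply(seq_along(tags), function(i)
    est[["c"]] * eval_fdq(fdq_aa[[i]], est[["d"]]), 0)
  names(fitted) <- tags
  structure(list(d_aa = est[["d"]], c = est[["c"]], sse = est[["sse"]],
                 ci_d = ci_d, ci_c = ci_c, fitted = fitted, observed = means,
                 n_bootstrap = if (is.null(ci_d)) 0 else n_bootstrap),
            class = "peptide_length_fit")
}

#' @export
print.peptide_length_fit <- function(x, ...) {
  cat(sprintf("peptide length fit: d = %.2f A, c = %.4g (SSE %.3g)\n",
              x$d_aa, x$c, x$sse))
  if (!is.null(x$ci_d))
    cat(sprintf("  95%% CI: d [%.2f, %.2f] A; c [%.4g, %.4g] (%d bootstrap sets)\n",
                x$ci_d[1], x$ci_d[2], x$ci_c[1], x$ci_c[2], x$n_bootstrap))
  invisible(x)
}

#' @export
coef.peptide_length_fit <- function(object, ...) {
  c(d_aa = object$d_aa, c = object$c)
}

#' Peak table from an HPLC chromatogram
#'
#' Detects peaks (local maxima above `threshold` times the trace maximum) in
#' uniformly sampled absorbance and fluorescence traces, integrates each by
#' the trapezoid rule between flanking valleys, and assigns each peak as
#' free dye or conjugate by matching retention times against a dye-only
#' reference run.
#'
#' @param time Retention time (min), uniform sampling.
#' @param absorbance_550,fluorescence_575 Detector traces.
#' @param reference_times Optional retention times of free-dye peaks; peaks
#'   within `match_tol` of one are labeled `"free"`, the rest
#'   `"conjugate"`.
#' @param threshold Detection threshold as a fraction of the absorbance
#'   maximum, default 0.05.
#' @param match_tol Retention-time match tolerance (min), default 0.2.
#' @return data.frame with columns `retention_time`, `height_abs`,
#'   `area_abs`, `height_fluor`, `area_fluor`, `species`; zero rows (with a
#'   warning) when nothing exceeds the threshold.
#' @export
peak_table_from_chromatogram <- function(time, absorbance_550, fluorescence_575,
                                         reference_times = NULL,
                                         threshold = 0.05, match_tol = 0.2) {
  n <- length(time)
  stopifnot(length(absorbance_550) == n, length(fluorescence_575) == n)
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("peak_table_from_chromatogram: sampling must be uniform", call. = FALSE)
  y <- absorbance_550
  thr <- threshold * max(y)
  is_peak <- which(y > thr &
                     y >= c(-Inf, y[-n]) &
                     y > c(y[-1], -Inf))
  if (length(is_peak) == 0) {
    warning("peak_table_from_chromatogram: no peaks above threshold")
    return(data.frame(retention_time = numeric(0), height_abs = numeric(0),
                      area_abs = numeric(0), height_fluor = numeric(0),
                      area_fluor = numeric(0), species = character(0)))
  }
  # valley bounds: minimum between consecutive peaks, trace ends outside
  bounds <- c(1, vapply(seq_len(length(is_peak) - 1), function(k) {
    seg <- is_peak[k]:is_peak[k + 1]
    seg[which.min(y[seg])]
  }, 0L), n)
  trap <- function(v, i0, i1) {
    idx <- i0:i1
    sum(diff(time[idx]) * (v[idx[-length(idx)]] + v[idx[-1]]) / 2)
  }
  out <- do.call(rbind, lapply(seq_along(is_peak), function(k) {
    i0 <- bounds[k]; i1 <- bounds[k + 1]
    data.frame(retention_time = time[is_peak[k]],
               height_abs = y[is_peak[k]],
               area_abs = trap(absorbance_550, i0, i1),
               height_fluor = fluorescence_575[is_peak[k]],
               area_fluor = trap(fluorescence_575, i0, i1))
  }))
  out$species <- if (is.null(reference_times)) NA_character_ else {
    ifelse(vapply(out$retention_time,
                  function(rt) any(abs(rt - reference_times) <= match_tol), TRUE),
           "free", "conjugate")
  }
  out
}

#' Quenching records from a free/conjugate peak table
#'
#' Reduces a labeled peak table to one [intramolecular_quenching()] value:
#' the free-dye peak and, following the convention of analyzing the most
#' abundant conjugate species, the conjugate peak with the largest
#' absorbance area.
#'
#' @param peaks A peak table from [peak_table_from_chromatogram()] with the
#'   `species` column filled.
#' @return List: `quenching`, `f_conj`, `a_conj`, `f_free`, `a_free`.
#' @export
quenching_from_peaks <- function(peaks) {
  free <- peaks[peaks$species == "free", ]
  conj <- peaks[peaks$species == "conjugate", ]
  if (nrow(free) == 0 || nrow(conj) == 0)
    stop("quenching_from_peaks: need both a free and a conjugate peak", call. = FALSE)
  free <- free[which.max(free$area_abs), ]
  conj <- conj[which.max(conj$area_abs), ]
  list(quenching = intramolecular_quenching(conj$area_fluor, conj$area_abs,
                                            free$area_fluor, free$area_abs),
       f_conj = conj$area_fluor, a_conj = conj$area_abs,
       f_free = free$area_fluor, a_free = free$area_abs)
}
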