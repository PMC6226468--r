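#' Physical constants used in Boltzmann fits
#'
#' Faraday constant (C/mol), gas constant (J/mol/K) and the default bath
#' temperature (K).
#' @keywords internal
.FARADAY <- 96485.332
.GASCONST <- 8.314462
.T_DEFAULT <- 294

#' A voltage-clamp fluorometry sweep
#'
#' Aligned time series of fluorescence, current and command voltage from one
#' sweep, plus the potassium equilibrium potential and bath temperature.
#'
#' @param time Time (ms).
#' @param fluorescence Fluorescence (arbitrary units).
#' @param current Current (nA).
#' @param voltage Command voltage (mV).
#' @param e_k Potassium equilibrium potential (mV).
#' @param temperature Temperature (K), default 294.
#' @return Object of class `sweep_record`.
#' @export
sweep_record <- function(time, fluorescence, current = rep(NA_real_, length(time)),
                         voltage = rep(NA_real_, length(time)), e_k = -90,
                         temperature = .T_DEFAULT) {
  n <- length(time)
  if (length(fluorescence) != n || length(current) != n || length(voltage) != n)
    stop("sweep_record: arrays must be aligned and equal length", call. = FALSE)
  if (temperature <= 0) stop("sweep_record: temperature must be positive", call. = FALSE)
  structure(list(time = as.numeric(time), fluorescence = as.numeric(fluorescence),
                 current = as.numeric(current), voltage = as.numeric(voltage),
                 e_k = e_k, temperature = temperature),
            class = "sweep_record")
}

#' Remove photobleaching from a sweep
#'
#' Fits a single exponential `a * exp(-t / tau) + offset` by least squares to
#' the fluorescence of a reference sweep recorded without a voltage pulse,
#' and subtracts the fitted curve from the fluorescence of `sweep`.
#'
#' @param sweep The sweep to correct.
#' @param reference_sweep A no-stimulus sweep with the same sampling.
#' @return The corrected `sweep_record`, with attribute `bleach_fit`
#'   (list: `amplitude`, `tau` in ms, `offset`).
#' @export
bleach_correct <- function(sweep, reference_sweep) {
  stopifnot(inherits(sweep, "sweep_record"), inherits(reference_sweep, "sweep_record"))
  t <- reference_sweep$time; yr <- reference_sweep$fluorescence
  if (length(t) != length(sweep$time) || max(abs(t - sweep$time)) > 1e-9)
    stop("bleach_correct: sweeps must share sampling", call. = FALSE)
  span <- diff(range(t))
  amp0 <- yr[1] - yr[length(yr)]
  flat <- abs(amp0) < 1e-12 * max(abs(yr) + 1)
  if (flat) {
    fit <- list(amplitude = 0, tau = Inf, offset = mean(yr))
    corrected <- sweep$fluorescence - fit$offset
  } else {
    sse <- function(p) {
      pred <- p[1] * exp(-t / exp(p[2])) + p[3]
      sum((pred - yr)^2)
    }
    o <- stats::optim(c(amp0, log(span / 3), yr[length(yr)]), sse,
                      method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
    tau <- exp(o$par[2])
    if (!is.finite(o$value) || tau <= 0)
      stop("bleach_correct: exponential fit diverged", call. = FALSE)
    fit <- list(amplitude = o$par[1], tau = tau, offset = o$par[3])
    corrected <- sweep$fluorescence - (fit$amplitude * exp(-sweep$time / fit$tau) + fit$offset)
  }
  out <- sweep
  out$fluorescence <- corrected
  attr(out, "bleach_fit") <- fit
  out
}

#' Measure a voltage-evoked fluorescence deflection
#'
#' Amplitude of the fluorescence deflection in one sweep: mean of the last
#' 20 percent of the pulse window minus the mean of the pre-pulse baseline.
#'
#' @param sweep A (bleach-corrected) `sweep_record`.
#' @param pulse_window Numeric length-2, pulse start/end (ms).
#' @param baseline_window Numeric length-2, baseline start/end (ms); default
#'   everything before the pulse.
#' @return Deflection amplitude (a.u.).
#' @export
measure_deltaF <- function(sweep, pulse_window,
                           baseline_window = c(min(sweep$time), pulse_window[1])) {
  stopifnot(inherits(sweep, "sweep_record"))
  t <- sweep$time
  inb <- t >= baseline_window[1] & t < baseline_window[2]
  tail_start <- pulse_window[2] - 0.2 * diff(pulse_window)
  inp <- t >= tail_start & t <= pulse_window[2]
  if (!any(inb) || !any(inp))
    stop("measure_deltaF: empty baseline or pulse window", call. = FALSE)
  mean(sweep$fluorescence[inp]) - mean(sweep$fluorescence[inb])
}

boltzmann <- function(v, total, v_half, z, minimum, temperature) {
  total / (1 + exp(z * .FARADAY / (.GASCONST * temperature * 1000) * (v_half - v))) + minimum
}

#' Boltzmann fit of fluorescence-voltage data
#'
#' Least-squares fit of per-voltage fluorescence deflection amplitudes to
#' \deqn{\Delta F = \frac{\Delta F_{total}}
#'   {1 + \exp[zF/RT (V_{0.5} - V_m)]} + \Delta F_{min}}
#' with voltages in mV (the `F/RT` factor carries the mV conversion).
#'
#' @param delta_f Deflection amplitudes (a.u.), one per test voltage.
#' @param voltages Test potentials (mV), at least 5 spanning the transition.
#' @param temperature Temperature (K), default 294.
#' @return Object of class `boltzmann_fit`: `delta_f_total`, `delta_f_min`,
#'   `v_half` (mV), `z` (elementary charges), `residual` (RMS), plus the
#'   data.
#' @export
fit_deltaF_boltzmann <- function(delta_f, voltages, temperature = .T_DEFAULT) {
  if (length(delta_f) != length(voltages))
    stop("fit_deltaF_boltzmann: lengths differ", call. = FALSE)
  if (length(voltages) < 5)
    stop("fit_deltaF_boltzmann: need at least 5 voltages", call. = FALSE)
  rng <- range(delta_f)
  amp0 <- diff(rng)
  if (amp0 == 0) amp0 <- max(abs(delta_f), 1e-6)
  sse <- function(p) {
    pred <- boltzmann(voltages, p[1], p[2], p[3], p[4], temperature)
    sum((pred - delta_f)^2)
  }
  starts <- list(c(amp0, stats::median(voltages), 1, rng[1]),
                 c(-amp0, stats::median(voltages), 1, rng[2]),
                 c(amp0, stats::quantile(voltages, 0.25), 0.5, rng[1]),
                 c(amp0, stats::quantile(voltages, 0.75), 2, rng[1]))
  fits <- lapply(starts, function(s)
    tryCatch(stats::optim(s, sse, method = "BFGS",
                          control = list(maxit = 1000, reltol = 1e-14)),
             error = function(e) NULL))
  fits <- Filter(function(f) !is.null(f) && all(is.finite(f$par)), fits)
  if (length(fits) == 0)
    stop("fit_deltaF_boltzmann: no start converged", call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  p <- best$par
  if (p[3] == 0) stop("fit_deltaF_boltzmann: zero valence at optimum", call. = FALSE)
  if (p[1] < 0) {  # canonical orientation: positive total with flipped valence
    p <- c(-p[1], p[2], -p[3], p[4] + p[1])
  }
  structure(list(delta_f_total = p[1], v_half = p[2], z = p[3], delta_f_min = p[4],
                 residual = sqrt(best$value / length(delta_f)),
                 temperature = temperature,
                 voltages = voltages, delta_f = delta_f),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: dF_total %.4g, V1/2 %.2f mV, z %.3g e0, dF_min %.4g (RMS %.3g)\n",
              x$delta_f_total, x$v_half, x$z, x$delta_f_min, x$residual))
  invisible(x)
}

#' @export
predict.boltzmann_fit <- function(object, newdata = NULL, ...) {
  v <- if (is.null(newdata)) object$voltages
       else if (is.list(newdata)) newdata$voltage else newdata
  boltzmann(v, object$delta_f_total, object$v_half, object$z, object$delta_f_min,
            object$temperature)
}

#' Macroscopic conductance from current and driving force
#'
#' `G = I / (V_m - E_K)`, elementwise. Points within `guard` mV of the
#' equilibrium potential are excluded (returned as `NA`) to avoid the
#' division blow-up, and their count reported as an attribute.
#'
#' @param current Current (nA).
#' @param voltage Membrane potential (mV).
#' @param e_k Potassium equilibrium potential (mV).
#' @param guard Exclusion half-width around `e_k` (mV), default 0.5.
#' @return Conductance (microsiemens), `NA` at excluded points, with
#'   attribute `n_excluded`.
#' @export
conductance_from_iv <- function(current, voltage, e_k, guard = 0.5) {
  drive <- voltage - e_k
  excl <- abs(drive) < guard
  g <- current / drive  # nA/mV = uS
  g[excl] <- NA_real_
  if (any(excl))
    message(sprintf("conductance_from_iv: excluded %d point(s) within %.2g mV of E_K",
                    sum(excl), guard))
  attr(g, "n_excluded") <- sum(excl)
  g
}

#' Double-Boltzmann fit of the conductance-voltage relation
#'
#' Fits macroscopic conductance to the sum of two Boltzmann components,
#' \deqn{G = \sum_{i=1}^{2}\frac{G_{max,i}}
#'   {1 + \exp[z_i F/RT(V_{0.5,i} - V_m)]}}
#' with the maximal conductance defined as the exact component sum
#' `G_max = G_max,1 + G_max,2`.
#'
#' @param conductances Conductance values (`NA`s dropped).
#' @param voltages Matching test potentials (mV), at least 8 usable.
#' @param temperature Temperature (K), default 294.
#' @return Object of class `conductance_fit`: `components` (data.frame with
#'   `g_max_i`, `v_half_i`, `z_i`), `g_max`, `residual`.
#' @export
fit_g_double_boltzmann <- function(conductances, voltages, temperature = .T_DEFAULT) {
  keep <- is.finite(conductances) & is.finite(voltages)
  g <- conductances[keep]; v <- voltages[keep]
  if (length(g) < 8)
    stop("fit_g_double_boltzmann: need at least 8 usable voltages", call. = FALSE)
  gmax0 <- max(g)
  two_boltz <- function(p) {
    boltzmann(v, p[1], p[2], p[3], 0, temperature) +
      boltzmann(v, p[4], p[5], p[6], 0, temperature)
  }
  sse <- function(p) sum((two_boltz(p) - g)^2)
  qv <- stats::quantile(v, c(0.3, 0.7))
  starts <- list(c(gmax0 * 0.6, qv[1], 1, gmax0 * 0.4, qv[2], 1),
                 c(gmax0 * 0.9, stats::median(v), 1.5, gmax0 * 0.1, qv[2], 0.5),
                 c(gmax0 * 0.5, qv[1], 0.7, gmax0 * 0.5, qv[2], 2))
  lower <- c(0, min(v) - 200, 0.05, 0, min(v) - 200, 0.05)
  upper <- c(5 * gmax0, max(v) + 200, 10, 5 * gmax0, max(v) + 200, 10)
  fits <- lapply(starts, function(s)
    tryCatch(stats::optim(s, sse, method = "L-BFGS-B", lower = lower, upper = upper,
                          control = list(maxit = 2000, factr = 1e3)),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("fit_g_double_boltzmann: no start converged", call. = FALSE)
  best <- fits[[which.min(vapply(fits, `[[`, 0, "value"))]]
  p <- best$par
  comp <- data.frame(g_max_i = p[c(1, 4)], v_half_i = p[c(2, 5)], z_i = p[c(3, 6)])
  comp <- comp[order(comp$v_half_i), ]
  rownames(comp) <- NULL
  structure(list(components = comp, g_max = sum(comp$g_max_i),
                 residual = sqrt(best$value / length(g)),
                 temperature = temperature, voltages = v, conductances = g),
            class = "conductance_fit")
}

#' @export
print.conductance_fit <- function(x, ...) {
  cat(sprintf("double-Boltzmann conductance fit: G_max %.4g uS (RMS %.3g)\n",
              x$g_max, x$residual))
  print(x$components)
  invisible(x)
}

#' Conductance-normalized fluorescence change
#'
#' The DEPET observable for one fluorophore on one cell: the total
#' voltage-dependent fluorescence change divided by the maximal macroscopic
#' conductance, removing the dependence on channel expression level.
#'
#' @param fit A [fit_deltaF_boltzmann()] result.
#' @param g_fit A [fit_g_double_boltzmann()] result with `g_max > 0`.
#' @return `delta_f_total / g_max` (a.u. per microsiemens).
#' @export
normalize_deltaF <- function(fit, g_fit) {
  stopifnot(inherits(fit, "boltzmann_fit"), inherits(g_fit, "conductance_fit"))
  if (g_fit$g_max <= 0)
    stop("normalize_deltaF: maximal conductance must be positive", call. = FALSE)
  fit$delta_f_total / g_fit$g_max
}

#' Stern-Volmer constant from a quencher titration
#'
#' Builds the Stern-Volmer plot `F0/F` versus quencher concentration --
#' with fluorescence first normalized by absorbance so that dilution and
#' detector gain cancel -- and fits it by linear regression. The slope is
#' the bimolecular quenching constant `K_SV`.
#'
#' @param concentrations Quencher concentrations (molar), must include 0.
#' @param fluorescence Fluorescence at each concentration (a.u.).
#' @param absorbance Matching absorbance (a.u., positive).
#' @return Object of class `stern_volmer`: `ksv` (per molar), `intercept`,
#'   `f0_over_f`, `quencher_concentrations`.
#' @export
stern_volmer_ksv <- function(concentrations, fluorescence, absorbance) {
  n <- length(concentrations)
  if (n < 3) stop("stern_volmer_ksv: need at least 3 concentrations", call. = FALSE)
  if (length(fluorescence) != n || length(absorbance) != n)
    stop("stern_volmer_ksv: lengths differ", call. = FALSE)
  if (any(concentrations < 0)) stop("stern_volmer_ksv: negative concentration", call. = FALSE)
  if (!any(concentrations == 0))
    stop("stern_volmer_ksv: need a zero-quencher point", call. = FALSE)
  if (any(absorbance <= 0)) stop("stern_volmer_ksv: absorbances must be positive", call. = FALSE)
  fn <- fluorescence / absorbance
  f0 <- mean(fn[concentrations == 0])
  ratio <- f0 / fn
  fit <- stats::lm(ratio ~ concentrations)
  structure(list(ksv = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 f0_over_f = ratio, quencher_concentrations = concentrations),
            class = "stern_volmer")
}

#' @export
print.stern_volmer <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit: K_SV %.4g /M (intercept %.4g) over %d concentrations\n",
              x$ksv, x$intercept, length(x$quencher_concentrations)))
  invisible(x)
}
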