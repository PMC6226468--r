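# Synthetic-data generators: every experimental input the toolkit consumes
# can be produced from known ground truth, standing in for MD ensembles,
# voltage-clamp records, titrations and HPLC peak tables. All generators are
# pure functions of their arguments and the seed.

#' Synthetic conformer cloud from a freely rotating chain
#'
#' Stand-in for an MD ensemble of a dye-residue conjugate: a chain of
#' `n_bonds` bonds of fixed length with Gaussian-jittered bend angles and
#' uniform azimuths, anchored at the origin; the moiety centroid sits
#' `moiety_offset` beyond the chain end along the last bond. Longer chains
#' yield broader, longer-reaching radial densities, mirroring the behavior
#' of dye linkers of increasing length.
#'
#' @param n_bonds Number of chain bonds (`>= 1`).
#' @param bond_length Bond length (Angstrom), default 1.5.
#' @param bend_angle_mean,bend_angle_sd Bend angle between consecutive bonds
#'   (degrees), default 60 +/- 25.
#' @param moiety_offset Rigid moiety radius beyond the chain end (Angstrom),
#'   default 2.
#' @param n_frames Number of snapshots, default 10000 (the MD frame count
#'   the toolkit emulates).
#' @param seed Integer seed.
#' @param source_tag Ensemble label.
#' @return A [conformer_ensemble()]: atom 1 is the anchor, atoms
#'   `2..(n_bonds+1)` the chain, the last atom the moiety centroid.
#' @export
synth_conformer_cloud <- function(n_bonds, bond_length = 1.5,
                                  bend_angle_mean = 60, bend_angle_sd = 25,
                                  moiety_offset = 2, n_frames = 10000,
                                  seed = 1, source_tag = sprintf("chain%d", n_bonds)) {
  stopifnot(n_bonds >= 1, n_frames >= 1, bond_length > 0, moiety_offset >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(f) {
    pos <- matrix(0, n_bonds + 2, 3)
    dirv <- c(0, 0, 1)
    pos[2, ] <- pos[1, ] + bond_length * dirv
    if (n_bonds > 1) for (b in 2:n_bonds) {
      bend <- (bend_angle_mean + stats::rnorm(1, 0, bend_angle_sd)) * pi / 180
      az <- stats::runif(1, 0, 2 * pi)
      # rotate dirv by bend about a random perpendicular axis
      perp <- if (abs(dirv[3]) < 0.9) c(-dirv[2], dirv[1], 0) else c(0, -dirv[3], dirv[2])
      perp <- perp / sqrt(sum(perp^2))
      perp2 <- c(dirv[2] * perp[3] - dirv[3] * perp[2],
                 dirv[3] * perp[1] - dirv[1] * perp[3],
                 dirv[1] * perp[2] - dirv[2] * perp[1])
      axis <- cos(az) * perp + sin(az) * perp2
      dirv <- dirv * cos(bend) +
        c(axis[2] * dirv[3] - axis[3] * dirv[2],
          axis[3] * dirv[1] - axis[1] * dirv[3],
          axis[1] * dirv[2] - axis[2] * dirv[1]) * sin(bend) +
        axis * sum(axis * dirv) * (1 - cos(bend))
      pos[b + 1, ] <- pos[b, ] + bond_length * dirv
    }
    pos[n_bonds + 2, ] <- pos[n_bonds + 1, ] + moiety_offset * dirv
    pos
  })
  conformer_ensemble(frames,
                     atom_labels = c("ANC", sprintf("C%d", seq_len(n_bonds)), "MOI"),
                     anchor_index = 1L, moiety_indices = n_bonds + 2L,
                     source_tag = source_tag)
}

#' Synthetic FDQ family emulating a dye linker series
#'
#' A parameterized set of FDQ models standing in for the fitted quenching
#' functions of a maleimide-dye series of graded linker length: each dye
#' carries a short-range contact exponential plus a dominant Gaussian
#' envelope whose mean shifts outward (and widens) with linker length, plus
#' a nearer shoulder. The family spans roughly 3-30 Angstrom, bracketing
#' both the resting (~6-8 A) and active (~13-14 A) regimes of a
#' voltage-sensor transition and the polyproline length-standard range. An
#' `"ab"` family for the same dyes is the `"aa"` family rigidly shifted by
#' `shift` Angstrom (the C-alpha to C-beta reparameterization), which keeps
#' the two equation systems of a dual fit exactly consistent when
#' `d_ab = d_aa + shift`.
#'
#' @param envelope_means Gaussian envelope means (Angstrom), one per dye;
#'   default `c(8, 11, 14, 17, 20, 23)`.
#' @param anchor_pair `"aa"` or `"ab"`.
#' @param shift Rigid distance shift (Angstrom) applied to all components,
#'   default 0; use e.g. 0.9 for an `"ab"` set.
#' @param tags Fluorophore names; default `"TMR-C1"` ... in order.
#' @return Named list of [fdq_model()] objects.
#' @export
synth_fdq_family <- function(envelope_means = c(8, 11, 14, 17, 20, 23),
                             anchor_pair = "aa", shift = 0,
                             tags = sprintf("TMR-C%d", seq_along(envelope_means))) {
  out <- lapply(seq_along(envelope_means), function(i) {
    sd1 <- 2.5 + 0.3 * i
    # exp(-(d - shift)/delta) = exp(shift/delta) * exp(-d/delta): the rigid
    # shift of the exponential term is an exact amplitude rescale
    fdq_model(exp_amplitudes = 0.04 * exp(shift / 2.5),
              exp_length_constants = 2.5,
              gauss_amplitudes = c(0.1, 0.03) * sd1 * sqrt(2 * pi),
              gauss_means = c(envelope_means[i], envelope_means[i] * 0.55) + shift,
              gauss_sds = c(sd1, sd1 * 0.8),
              fluorophore_tag = tags[i], anchor_pair = anchor_pair)
  })
  stats::setNames(out, tags)
}

#' Synthetic quenching dataset from known distances
#'
#' Forward model of the DEPET observable: for each fluorophore,
#' `delta F / G = [FDQ(X, d_r) - FDQ(X, d_a)] c`, with multiplicative
#' Gaussian noise of coefficient of variation `noise_cv` on every replicate.
#'
#' @param fdq_set List of [fdq_model()]s, named by fluorophore.
#' @param d_r,d_a True resting and active distances (Angstrom).
#' @param c_coef True conversion coefficient (positive).
#' @param noise_cv Relative noise level (`>= 0`), default 0.1.
#' @param n_replicates Replicates per fluorophore, default 5.
#' @param seed Integer seed.
#' @return A [quenching_dataset()].
#' @export
synth_quenching_dataset <- function(fdq_set, d_r, d_a, c_coef, noise_cv = 0.1,
                                    n_replicates = 5, seed = 1) {
  stopifnot(c_coef > 0, noise_cv >= 0)
  if (is.null(names(fdq_set)))
    names(fdq_set) <- vapply(fdq_set, function(m)
      if (nzchar(m$fluorophore_tag)) m$fluorophore_tag else "", "")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  reps <- lapply(fdq_set, function(m) {
    mu <- forward_deltaF(m, d_r, d_a, c_coef)
    mu * (1 + stats::rnorm(n_replicates, 0, noise_cv))
  })
  quenching_dataset(reps, labeled_site_tag = "synthetic",
                    quencher_site_tag = "synthetic")
}

#' Synthetic voltage-clamp fluorometry sweeps
#'
#' Forward model of a fluorescence-voltage experiment: one sweep per test
#' potential of the protocol (default -220 to +160 mV in 20 mV steps), each
#' a baseline segment followed by a pulse during which the fluorescence
#' steps by the Boltzmann amplitude at that voltage, on top of an
#' exponential photobleaching decay and additive Gaussian noise. A
#' no-pulse reference sweep (bleach only) is included for
#' [bleach_correct()].
#'
#' @param delta_f_total,v_half,z,delta_f_min Boltzmann truth (see
#'   [fit_deltaF_boltzmann()]).
#' @param bleach_amplitude,bleach_tau Bleaching exponential (a.u., ms); set
#'   amplitude 0 for no bleach.
#' @param noise_sd Additive noise (a.u.), default 0.
#' @param voltages Test potentials (mV), default `seq(-220, 160, by = 20)`.
#' @param holding Holding potential (mV), default -90.
#' @param t_total,pulse_window Sweep duration and pulse start/end (ms).
#' @param dt Sample interval (ms), default 0.5.
#' @param temperature Temperature (K), default 294.
#' @param seed Integer seed.
#' @return List: `sweeps` (one [sweep_record()] per voltage, named),
#'   `reference` (no-pulse sweep), `voltages`, `pulse_window`, `truth`.
#' @export
synth_sweep <- function(delta_f_total, v_half, z, delta_f_min = 0,
                        bleach_amplitude = 0, bleach_tau = 200, noise_sd = 0,
                        voltages = seq(-220, 160, by = 20), holding = -90,
                        t_total = 100, pulse_window = c(25, 75), dt = 0.5,
                        temperature = .T_DEFAULT, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  t <- seq(0, t_total, by = dt)
  in_pulse <- t >= pulse_window[1] & t <= pulse_window[2]
  bleach <- bleach_amplitude * exp(-t / bleach_tau)
  mk <- function(v, pulsed) {
    dfv <- boltzmann(v, delta_f_total, v_half, z, delta_f_min, temperature)
    f <- bleach + ifelse(pulsed & in_pulse, dfv, 0) +
      stats::rnorm(length(t), 0, noise_sd)
    vol <- ifelse(pulsed & in_pulse, v, holding)
    sweep_record(t, f, voltage = vol, temperature = temperature)
  }
  sweeps <- lapply(voltages, mk, pulsed = TRUE)
  names(sweeps) <- sprintf("%+d mV", as.integer(voltages))
  list(sweeps = sweeps, reference = mk(holding, pulsed = FALSE),
       voltages = voltages, pulse_window = pulse_window,
       truth = list(delta_f_total = delta_f_total, v_half = v_half, z = z,
                    delta_f_min = delta_f_min,
                    bleach_amplitude = bleach_amplitude, bleach_tau = bleach_tau))
}

#' Synthetic Stern-Volmer titration
#'
#' Forward model `F0/F = 1 + K_SV [Q]` over a concentration series (default
#' 0 to 30 micromolar). The noise level is relative to the quenching term:
#' each realized `K_SV [Q]` is perturbed multiplicatively by
#' `Normal(0, noise_cv)`, emulating an instrument resolving the quenching
#' signal itself to that precision. (At micromolar quencher and K_SV of
#' order 40 per molar the quenching depth is only ~0.1 percent of the raw
#' fluorescence, so noise proportional to raw intensity would erase the
#' signal entirely; see the methods vignette.)
#'
#' @param ksv Stern-Volmer constant (per molar).
#' @param concentrations Quencher concentrations (molar), default
#'   `c(0, 2.5, 5, 10, 15, 20, 25, 30) * 1e-6`.
#' @param noise_cv Noise relative to the quenching term, default 0.01.
#' @param f0 Unquenched fluorescence (a.u.), default 1000.
#' @param seed Integer seed.
#' @return data.frame with columns `conc_M`, `fluorescence`, `absorbance`.
#' @export
synth_titration <- function(ksv, concentrations = c(0, 2.5, 5, 10, 15, 20, 25, 30) * 1e-6,
                            noise_cv = 0.01, f0 = 1000, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  quench <- ksv * concentrations * (1 + stats::rnorm(length(concentrations), 0, noise_cv))
  f <- f0 / (1 + quench)
  data.frame(conc_M = concentrations, fluorescence = f,
             absorbance = rep(1, length(concentrations)))
}

#' Synthetic peptide quenching records
#'
#' Forward model of the length-standard observable: per fluorophore,
#' intramolecular quenching `Q = c * FDQ(X, d)` realized as HPLC-style peak
#' quantities (free-dye peak at unit brightness, conjugate peak dimmed by
#' `Q`), with multiplicative noise on the conjugate fluorescence.
#'
#' @param fdq_set List of [fdq_model()]s, named by fluorophore.
#' @param d True Cys-Trp C-alpha distance (Angstrom).
#' @param c_coef True conversion coefficient (positive; `c * FDQ` must stay
#'   within `[0, 1]`).
#' @param noise_cv Relative noise, default 0.05.
#' @param n_replicates Replicate records per fluorophore, default 4.
#' @param seed Integer seed.
#' @return Named list (by fluorophore) of replicate quenching vectors, with
#'   attribute `records`: a data.frame of the underlying peak quantities
#'   (`fluorophore`, `replicate`, `f_conj`, `a_conj`, `f_free`, `a_free`).
#' @export
synth_peptide_peaks <- function(fdq_set, d, c_coef, noise_cv = 0.05,
                                n_replicates = 4, seed = 1) {
  stopifnot(c_coef >= 0, noise_cv >= 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tags <- names(fdq_set) %||% vapply(fdq_set, `[[`, "", "fluorophore_tag")
  recs <- do.call(rbind, lapply(seq_along(fdq_set), function(i) {
    q <- min(c_coef * eval_fdq(fdq_set[[i]], d), 1)
    f_conj <- pmax((1 - q) * (1 + stats::rnorm(n_replicates, 0, noise_cv)), 0)
    data.frame(fluorophore = tags[i], replicate = seq_len(n_replicates),
               f_conj = f_conj, a_conj = 1, f_free = 1, a_free = 1)
  }))
  out <- lapply(split(recs, recs$fluorophore)[unique(recs$fluorophore)], function(df)
    suppressWarnings(intramolecular_quenching(df$f_conj, df$a_conj,
                                              df$f_free, df$a_free)))
  out <- out[tags]
  attr(out, "records") <- recs
  out
}
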