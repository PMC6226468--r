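#' Quenching probability versus distance from two radial densities
#'
#' Combines the fluorophore-centroid density `f` (about the labeled C-alpha)
#' and the quencher-centroid density `q` (about a Trp anchor atom) into the
#' probability that the two moieties are in contact when their anchors are a
#' distance `d` apart:
#' \deqn{P(X,d) = \sum_{R,r}\frac{V_{K\cap\kappa}(d,R,r)}{V_K(R)} f(X,K)
#'   \times \frac{V_{K\cap\kappa}(d,R,r)}{V_\kappa(r)} q(\kappa)}
#' summed over all occupied shell pairs, on the distance grid
#' `{0, dr, 2 dr, ..., R_max + r_max}`. The summand is symmetric under
#' swapping the two densities.
#'
#' @param f,q `radial_density` objects with equal `bin_width`.
#' @param fluorophore_tag Label carried onto the curve (default from `f`).
#' @return An object of class `quench_curve`: fields `distances`,
#'   `probabilities`, `fluorophore_tag`, `anchor_pair` (one of `"aa"`,
#'   `"ab"`, `"ba"`, `"bb"`, derived from the two anchors), `bin_width`.
#' @export
quench_probability_curve <- function(f, q, fluorophore_tag = NULL) {
  stopifnot(inherits(f, "radial_density"), inherits(q, "radial_density"))
  if (abs(f$bin_width - q$bin_width) > 1e-12)
    stop("quench_probability_curve: densities must share one bin width", call. = FALSE)
  dr <- f$bin_width
  fi <- which(f$probabilities > 0)
  qi <- which(q$probabilities > 0)
  Rv <- fi * dr                      # maximal radii of occupied K shells
  rv <- qi * dr
  fw <- f$probabilities[fi] / shell_volume(Rv, dr)
  qw <- q$probabilities[qi] / shell_volume(rv, dr)
  dmax <- max(Rv) + max(rv)
  dgrid <- seq(0, dmax, by = dr)
  # all occupied (R, r) pairs, flattened
  Rp <- rep(Rv, times = length(rv))
  rp <- rep(rv, each = length(Rv))
  wp <- as.vector(outer(fw, qw))
  fq <- as.vector(outer(f$probabilities[fi], q$probabilities[qi]))
  p <- vapply(dgrid, function(d) {
    v <- shell_intersection_volume(d, Rp, rp, dr)
    sum(v * v * wp)
  }, 0)
  pair <- paste0(ifelse(f$anchor_kind == "Ca", "a", "b"),
                 ifelse(q$anchor_kind == "Ca", "a", "b"))
  structure(list(distances = dgrid, probabilities = p,
                 fluorophore_tag = fluorophore_tag %||% f$anchor_kind,
                 anchor_pair = pair, bin_width = dr),
            class = "quench_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.quench_curve <- function(x, ...) {
  cat(sprintf("quench curve '%s' (%s): %d grid points, step %.3g A, peak %.3g at %.2f A\n",
              x$fluorophore_tag, x$anchor_pair, length(x$distances), x$bin_width,
              max(x$probabilities), x$distances[which.max(x$probabilities)]))
  invisible(x)
}

#' Average the quench curves of two stereoisomers
#'
#' Fluorophores available only as mixed 5'/6' isomers get one joint curve:
#' the two isomer curves are summed and divided by two, pointwise.
#'
#' @param curve_a,curve_b `quench_curve` objects on the same grid and anchor
#'   pair.
#' @param tag Tag for the mixed curve.
#' @return A `quench_curve`.
#' @export
mix_isomers <- function(curve_a, curve_b, tag = NULL) {
  stopifnot(inherits(curve_a, "quench_curve"), inherits(curve_b, "quench_curve"))
  if (curve_a$anchor_pair != curve_b$anchor_pair)
    stop("mix_isomers: anchor pairs differ", call. = FALSE)
  na <- length(curve_a$distances); nb <- length(curve_b$distances)
  if (abs(curve_a$bin_width - curve_b$bin_width) > 1e-12)
    stop("mix_isomers: grids differ", call. = FALSE)
  # pad the shorter curve with zeros (compact support)
  n <- max(na, nb)
  pa <- c(curve_a$probabilities, rep(0, n - na))
  pb <- c(curve_b$probabilities, rep(0, n - nb))
  d <- if (na >= nb) curve_a$distances else curve_b$distances
  if (max(abs(d[seq_len(min(na, nb))] - curve_b$distances[seq_len(min(na, nb))])) > 1e-9)
    stop("mix_isomers: grids differ", call. = FALSE)
  structure(list(distances = d, probabilities = (pa + pb) / 2,
                 fluorophore_tag = tag %||% paste(curve_a$fluorophore_tag,
                                                  curve_b$fluorophore_tag, sep = "+"),
                 anchor_pair = curve_a$anchor_pair, bin_width = curve_a$bin_width),
            class = "quench_curve")
}

#' Construct an FDQ parameter set directly
#'
#' An `fdq_model` is the empirical parameterization of a quenching
#' probability curve: a sum of up to two exponentials and up to six
#' Gaussians,
#' \deqn{FDQ(d) = \sum_i \alpha_i e^{-d/\delta_i} +
#'  \sum_j \frac{A_j}{\sigma_j\sqrt{2\pi}}
#'  \exp\left[-\frac{(d-\mu_j)^2}{2\sigma_j^2}\right]}
#' clipped at zero and scaled by `ksv_scale` (Stern-Volmer normalization
#' across chemically different fluorophores; 1 for a homogeneous dye
#' family).
#'
#' @param exp_amplitudes,exp_length_constants Exponential amplitudes
#'   \eqn{\alpha_i} and length constants \eqn{\delta_i} (Angstrom, positive).
#' @param gauss_amplitudes,gauss_means,gauss_sds Gaussian amplitudes
#'   \eqn{A_j}, means \eqn{\mu_j} (Angstrom) and standard deviations
#'   \eqn{\sigma_j} (Angstrom, positive).
#' @param fluorophore_tag,anchor_pair Identity of the curve the model fits.
#' @param ksv_scale Multiplicative Stern-Volmer scale, default 1.
#' @return An object of class `fdq_model`.
#' @export
fdq_model <- function(exp_amplitudes = numeric(0), exp_length_constants = numeric(0),
                      gauss_amplitudes = numeric(0), gauss_means = numeric(0),
                      gauss_sds = numeric(0), fluorophore_tag = "", anchor_pair = "aa",
                      ksv_scale = 1) {
  if (length(exp_amplitudes) != length(exp_length_constants))
    stop("fdq_model: exponential parameter lengths differ", call. = FALSE)
  if (length(gauss_amplitudes) != length(gauss_means) ||
      length(gauss_amplitudes) != length(gauss_sds))
    stop("fdq_model: Gaussian parameter lengths differ", call. = FALSE)
  if (any(exp_length_constants <= 0)) stop("fdq_model: length constants must be > 0", call. = FALSE)
  if (any(gauss_sds <= 0)) stop("fdq_model: Gaussian sds must be > 0", call. = FALSE)
  if (length(exp_amplitudes) > 2) stop("fdq_model: at most two exponentials", call. = FALSE)
  if (length(gauss_amplitudes) > 6) stop("fdq_model: at most six Gaussians", call. = FALSE)
  structure(list(exp_amplitudes = as.numeric(exp_amplitudes),
                 exp_length_constants = as.numeric(exp_length_constants),
                 gauss_amplitudes = as.numeric(gauss_amplitudes),
                 gauss_means = as.numeric(gauss_means),
                 gauss_sds = as.numeric(gauss_sds),
                 fluorophore_tag = fluorophore_tag,
                 anchor_pair = anchor_pair,
                 ksv_scale = as.numeric(ksv_scale)),
            class = "fdq_model")
}

#' @export
print.fdq_model <- function(x, ...) {
  cat(sprintf("FDQ model '%s' (%s): %d exponential + %d Gaussian components, ksv_scale %.4g\n",
              x$fluorophore_tag, x$anchor_pair, length(x$exp_amplitudes),
              length(x$gauss_amplitudes), x$ksv_scale))
  if (!is.null(attr(x, "rms_residual")))
    cat(sprintf("  fit RMS residual: %.3g (relative to curve max: %.3g)\n",
                attr(x, "rms_residual"), attr(x, "rel_rms")))
  invisible(x)
}

#' Evaluate an FDQ model at given distances
#'
#' @param model An [fdq_model()].
#' @param d Distances (Angstrom, `>= 0`). Vectorised.
#' @return Quenching probabilities, `ksv_scale * max(0, sum of components)`.
#' @export
eval_fdq <- function(model, d) {
  stopifnot(inherits(model, "fdq_model"))
  if (any(d < 0)) stop("eval_fdq: distances must be >= 0", call. = FALSE)
  v <- numeric(length(d))
  for (i in seq_along(model$exp_amplitudes))
    v <- v + model$exp_amplitudes[i] * exp(-d / model$exp_length_constants[i])
  for (j in seq_along(model$gauss_amplitudes))
    v <- v + model$gauss_amplitudes[j] / (model$gauss_sds[j] * sqrt(2 * pi)) *
      exp(-(d - model$gauss_means[j])^2 / (2 * model$gauss_sds[j]^2))
  model$ksv_scale * pmax(v, 0)
}

#' @export
predict.fdq_model <- function(object, newdata, ...) {
  d <- if (is.list(newdata)) newdata$d else newdata
  eval_fdq(object, d)
}

#' Fit the empirical FDQ parameterization to a quench curve
#'
#' Forward selection over mixture size: starting from the empty model,
#' components (up to `max_exp` exponentials and `max_gauss` Gaussians) are
#' added one at a time -- each new Gaussian seeded at the largest remaining
#' residual, each exponential seeded from the near-contact decay -- and all
#' parameters are refit jointly by bounded least squares (amplitudes
#' nonnegative, sds and length constants positive). Selection stops when the
#' RMS residual drops below `tol_rel` times the curve maximum or the
#' component caps are reached.
#'
#' @param curve A [quench_probability_curve()] result with at least 20
#'   nonzero points (an all-zero curve yields the empty model).
#' @param max_exp,max_gauss Component caps (2 and 6 by default).
#' @param tol_rel Relative RMS target, default 1e-3.
#' @return An [fdq_model()] with attributes `rms_residual` and `rel_rms`.
#' @export
fit_fdq <- function(curve, max_exp = 2, max_gauss = 6, tol_rel = 1e-3) {
  stopifnot(inherits(curve, "quench_curve"))
  d <- curve$distances; y <- curve$probabilities
  if (all(y == 0))
    return(fdq_model(fluorophore_tag = curve$fluorophore_tag,
                     anchor_pair = curve$anchor_pair))
  if (sum(y > 0) < 20)
    stop("fit_fdq: need at least 20 nonzero curve points", call. = FALSE)
  ymax <- max(y)

  pack <- function(ne, ng, par) {
    # par layout: ae[ne], de[ne], Ag[ng], mu[ng], sg[ng]
    list(ae = par[seq_len(ne)],
         de = par[ne + seq_len(ne)],
         Ag = par[2 * ne + seq_len(ng)],
         mu = par[2 * ne + ng + seq_len(ng)],
         sg = par[2 * ne + 2 * ng + seq_len(ng)])
  }
  evalp <- function(ne, ng, par) {
    q <- pack(ne, ng, par)
    v <- numeric(length(d))
    for (i in seq_len(ne)) v <- v + q$ae[i] * exp(-d / q$de[i])
    for (j in seq_len(ng)) v <- v + q$Ag[j] / (q$sg[j] * sqrt(2 * pi)) *
        exp(-(d - q$mu[j])^2 / (2 * q$sg[j]^2))
    v
  }
  obj <- function(par, ne, ng) sum((evalp(ne, ng, par) - y)^2)
  grad <- function(par, ne, ng) {
    q <- pack(ne, ng, par)
    r <- evalp(ne, ng, par) - y
    g <- numeric(length(par))
    for (i in seq_len(ne)) {
      e <- exp(-d / q$de[i])
      g[i] <- 2 * sum(r * e)
      g[ne + i] <- 2 * sum(r * q$ae[i] * e * d / q$de[i]^2)
    }
    for (j in seq_len(ng)) {
      z <- (d - q$mu[j]) / q$sg[j]
      phi <- exp(-z^2 / 2) / (q$sg[j] * sqrt(2 * pi))
      g[2 * ne + j] <- 2 * sum(r * phi)
      g[2 * ne + ng + j] <- 2 * sum(r * q$Ag[j] * phi * z / q$sg[j])
      g[2 * ne + 2 * ng + j] <- 2 * sum(r * q$Ag[j] * phi * (z^2 - 1) / q$sg[j])
    }
    g
  }
  refit <- function(ne, ng, par) {
    span <- max(d) - min(d)
    lower <- c(rep(0, ne), rep(1e-3, ne), rep(0, ng), rep(min(d) - span, ng),
               rep(curve$bin_width / 2, ng))
    upper <- c(rep(10 * ymax, ne), rep(5 * span + 1, ne), rep(Inf, ng),
               rep(max(d) + span, ng), rep(2 * span + 1, ng))
    stats::optim(par, obj, grad, ne = ne, ng = ng, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = 5000, factr = 10))
  }

  cur <- list(par = numeric(0), ne = 0L, ng = 0L, sse = sum(y^2))
  best <- cur
  resid_of <- function(st) y - if (st$ne + st$ng == 0) 0 else evalp(st$ne, st$ng, st$par)
  repeat {
    if (sqrt(best$sse / length(y)) / ymax < tol_rel) break
    if (cur$ne >= max_exp && cur$ng >= max_gauss) break
    res <- resid_of(cur)
    q <- pack(cur$ne, cur$ng, cur$par)
    cand <- list()
    if (cur$ng < max_gauss) {
      k <- which.max(res)
      # local width guess from the contiguous half-maximum run around the peak
      above <- res > res[k] / 2
      run <- rle(above)
      ends <- cumsum(run$lengths)
      seg <- which(ends >= k)[1]
      width_bins <- run$lengths[seg]
      sg0 <- max(curve$bin_width, width_bins * curve$bin_width / 2.355)
      par <- c(q$ae, q$de, q$Ag, max(res[k], 1e-12) * sg0 * sqrt(2 * pi),
               q$mu, d[k], q$sg, sg0)
      cand <- c(cand, list(list(ne = cur$ne, ng = cur$ng + 1L, par = par)))
    }
    if (cur$ne < max_exp) {
      pos <- which(res > 0 & d > 0)
      de0 <- if (length(pos) > 2) {
        cf <- stats::coef(stats::lm(log(res[pos]) ~ d[pos]))
        if (is.finite(cf[2]) && cf[2] < 0) -1 / cf[2] else diff(range(d)) / 4
      } else diff(range(d)) / 4
      de0 <- min(max(de0, 2 * curve$bin_width), 5 * diff(range(d)))
      # a short length constant targets the near-contact spike specifically
      for (de_try in unique(c(de0, 3 * curve$bin_width))) {
        a0 <- max(res[1], ymax / 10)
        par <- c(q$ae, a0, q$de, de_try, q$Ag, q$mu, q$sg)
        cand <- c(cand, list(list(ne = cur$ne + 1L, ng = cur$ng, par = par)))
      }
    }
    if (length(cand) == 0) break
    trial <- lapply(cand, function(cn) {
      f <- refit(cn$ne, cn$ng, cn$par)
      list(ne = cn$ne, ng = cn$ng, par = f$par, sse = f$value)
    })
    cur <- trial[[which.min(vapply(trial, `[[`, 0, "sse"))]]
    if (cur$sse < best$sse) best <- cur
  }
  rel <- sqrt(best$sse / length(y)) / ymax
  if (rel >= tol_rel && best$ne >= max_exp && best$ng >= max_gauss) {
    # caps reached without meeting the target: return best fit, flagging residual
    warning(sprintf("fit_fdq: residual target not met (relative RMS %.3g)", rel))
  }
  q <- pack(best$ne, best$ng, best$par)
  m <- fdq_model(q$ae, q$de, q$Ag, q$mu, q$sg,
                 fluorophore_tag = curve$fluorophore_tag,
                 anchor_pair = curve$anchor_pair)
  attr(m, "rms_residual") <- sqrt(best$sse / length(y))
  attr(m, "rel_rms") <- rel
  m
}

#' Rescale an FDQ model by a Stern-Volmer constant ratio
#'
#' When fluorophores differ photochemically, their quenching efficiency
#' enters through the Stern-Volmer constant: the FDQ function is multiplied
#' by `ksv / ksv_reference` so that distance fitting compares like with like.
#'
#' @param model An [fdq_model()].
#' @param ksv,ksv_reference Stern-Volmer constants (per molar, positive).
#' @return The rescaled model.
#' @export
scale_by_ksv <- function(model, ksv, ksv_reference) {
  stopifnot(inherits(model, "fdq_model"))
  if (ksv <= 0 || ksv_reference <= 0)
    stop("scale_by_ksv: constants must be positive", call. = FALSE)
  model$ksv_scale <- model$ksv_scale * ksv / ksv_reference
  model
}

#' Save / load FDQ parameter tables
#'
#' JSON round trip of a set of FDQ models (one entry per fluorophore and
#' anchor pair), lossless to full double precision.
#'
#' @param models A list of [fdq_model()] objects.
#' @param path Output / input file path.
#' @return `save_fdq_table` returns `path` invisibly; `load_fdq_table`
#'   returns the list of models.
#' @export
save_fdq_table <- function(models, path) {
  if (inherits(models, "fdq_model")) models <- list(models)
  stopifnot(all(vapply(models, inherits, TRUE, "fdq_model")))
  recs <- lapply(models, function(m) {
    list(tag = m$fluorophore_tag, anchor_pair = m$anchor_pair,
         alpha = I(m$exp_amplitudes), delta = I(m$exp_length_constants),
         A = I(m$gauss_amplitudes), mu = I(m$gauss_means), sigma = I(m$gauss_sds),
         ksv_scale = m$ksv_scale)
  })
  jsonlite::write_json(recs, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_fdq_table
#' @export
load_fdq_table <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    need <- c("tag", "anchor_pair", "alpha", "delta", "A", "mu", "sigma", "ksv_scale")
    if (!all(need %in% names(r)))
      stop("load_fdq_table: malformed FDQ table entry", call. = FALSE)
    fdq_model(unlist(r$alpha), unlist(r$delta), unlist(r$A), unlist(r$mu),
              unlist(r$sigma), fluorophore_tag = r$tag,
              anchor_pair = r$anchor_pair, ksv_scale = r$ksv_scale)
  })
}
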