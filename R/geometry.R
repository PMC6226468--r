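#' Volume of a spherical shell
#'
#' Volume of the spherical shell with maximal radius `rho` and thickness
#' `dr`, i.e. the region between the spheres of radius `rho - dr` and `rho`:
#' \deqn{V(\rho) = \frac{4\pi}{3}\left[\rho^3 - (\rho-\delta r)^3\right]}
#' With `rho == dr` the shell degenerates to the full ball of radius `rho`.
#'
#' @param rho Maximal shell radius (Angstrom). Vectorised.
#' @param dr Shell thickness \eqn{\delta r} (Angstrom), default 0.05.
#' @return Shell volume(s) in cubic Angstrom.
#' @examples
#' shell_volume(0.05, 0.05)            # innermost shell = small ball
#' shell_volume(1, 0.05)
#' @export
shell_volume <- function(rho, dr = 0.05) {
  if (any(!is.finite(rho)) || any(!is.finite(dr)))
    stop("shell_volume: non-finite input", call. = FALSE)
  if (any(dr <= 0)) stop("shell_volume: thickness must be positive", call. = FALSE)
  if (any(rho < dr))
    stop("shell_volume: maximal radius must be >= thickness", call. = FALSE)
  (4 * pi / 3) * (rho^3 - (rho - dr)^3)
}

#' Volume of the lens formed by two intersecting spheres
#'
#' Closed-form volume of the lens (the intersection) of two spheres of radii
#' `psi` and `omega` whose centers are `chi` apart:
#' \deqn{V_\varphi(\chi,\psi,\omega) = \frac{\pi(\psi+\omega-\chi)^2
#'   (\chi^2 + 2\chi\psi - 3\psi^2 + 2\chi\omega - 3\omega^2 + 6\psi\omega)}
#'   {12\chi}}
#' The formula is valid for overlapping, non-concentric spheres
#' (`|psi - omega| <= chi <= psi + omega`); at the tangent bound it returns 0
#' and at the containment bound it equals the volume of the smaller sphere.
#' It is singular at `chi = 0`; callers must special-case concentric spheres.
#'
#' @param chi Center separation (Angstrom). Vectorised.
#' @param psi,omega Sphere radii (Angstrom).
#' @return Lens volume(s) in cubic Angstrom.
#' @examples
#' lens_volume(3, 2, 1)        # tangent: 0
#' lens_volume(1, 2, 1)        # contained: 4*pi/3
#' @export
lens_volume <- function(chi, psi, omega) {
  n <- max(length(chi), length(psi), length(omega))
  chi <- rep_len(chi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  if (any(chi <= 0))
    stop("lens_volume: singular at zero center separation; handle concentric spheres upstream",
         call. = FALSE)
  if (any(psi <= 0) || any(omega <= 0))
    stop("lens_volume: radii must be strictly positive", call. = FALSE)
  bad <- chi > psi + omega | chi < abs(psi - omega)
  if (any(bad))
    stop("lens_volume: requires |psi - omega| <= chi <= psi + omega; clamp outside cases upstream",
         call. = FALSE)
  pi * (psi + omega - chi)^2 *
    (chi^2 + 2 * chi * psi - 3 * psi^2 + 2 * chi * omega - 3 * omega^2 +
       6 * psi * omega) / (12 * chi)
}

# Intersection volume of two solid balls, with all degenerate cases clamped:
# disjoint -> 0, containment/concentric -> volume of the smaller ball,
# zero-radius -> 0. Continuous in all arguments; vectorised.
ball_overlap_volume <- function(chi, psi, omega) {
  n <- max(length(chi), length(psi), length(omega))
  chi <- rep_len(chi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  v <- numeric(n)
  zero <- psi <= 0 | omega <= 0 | chi >= psi + omega
  contained <- !zero & chi <= abs(psi - omega) + 1e-12 * pmax(psi, omega)
  v[contained] <- (4 * pi / 3) * pmin(psi[contained], omega[contained])^3
  lens <- !zero & !contained
  if (any(lens)) v[lens] <- lens_volume(chi[lens], psi[lens], omega[lens])
  v
}

#' Intersection volume of two spherical shells
#'
#' Exact volume of the intersection of shell K (maximal radius `R`) and shell
#' \eqn{\kappa} (maximal radius `r`), both of thickness `dr`, with centers
#' separated by `d`. Computed by inclusion-exclusion over the four bounding
#' sphere pairs,
#' \deqn{V_{K\cap\kappa} = V_\varphi(d,R,r) - V_\varphi(d,R-\delta r,r)
#'  - V_\varphi(d,R,r-\delta r) + V_\varphi(d,R-\delta r,r-\delta r),}
#' with each two-sphere term clamped analytically for the disjoint,
#' tangent, contained and concentric cases. On the discrete `dr` grid this
#' dispatch reduces exactly to the published case table (zero for separations
#' beyond reach or fully nested shells; the full shell for `d = 0, R = r`; a
#' single lens at `d = R + r - dr`; two-term differences at `d = |R - r|`);
#' between grid points it interpolates the geometry continuously.
#'
#' @param d Center separation (Angstrom), `>= 0`. Vectorised jointly with
#'   `R` and `r`.
#' @param R,r Maximal radii of the two shells (Angstrom).
#' @param dr Shared shell thickness (Angstrom), default 0.05.
#' @return Intersection volume(s), always in
#'   `[0, min(shell_volume(R), shell_volume(r))]`.
#' @examples
#' shell_intersection_volume(0, 2, 2)           # = shell_volume(2)
#' shell_intersection_volume(5, 2, 2)           # disjoint: 0
#' @export
shell_intersection_volume <- function(d, R, r, dr = 0.05) {
  if (length(dr) != 1 || !is.finite(dr) || dr <= 0)
    stop("shell_intersection_volume: shells must share one positive thickness",
         call. = FALSE)
  n <- max(length(d), length(R), length(r))
  d <- rep_len(d, n); R <- rep_len(R, n); r <- rep_len(r, n)
  if (any(d < 0)) stop("shell_intersection_volume: d must be >= 0", call. = FALSE)
  if (any(R < dr) || any(r < dr))
    stop("shell_intersection_volume: maximal radii must be >= thickness", call. = FALSE)
  # concentric shells: radial-interval overlap, analytic (lens formula singular)
  conc <- d < 1e-9
  v <- numeric(n)
  if (any(conc)) {
    lo <- pmax(R[conc] - dr, r[conc] - dr)
    hi <- pmin(R[conc], r[conc])
    w <- pmax(hi - lo, 0)
    v[conc] <- (4 * pi / 3) * ((lo + w)^3 - lo^3)
  }
  i <- !conc
  if (any(i)) {
    v[i] <- ball_overlap_volume(d[i], R[i], r[i]) -
      ball_overlap_volume(d[i], R[i] - dr, r[i]) -
      ball_overlap_volume(d[i], R[i], r[i] - dr) +
      ball_overlap_volume(d[i], R[i] - dr, r[i] - dr)
  }
  pmax(v, 0)
}

#' Side-chain orientation angle from two distances
#'
#' The angle at the quencher backbone atom (e.g. the Trp C-alpha) in the
#' triangle formed by the labeled C-alpha, the Trp C-alpha and the Trp
#' C-beta, by the law of cosines:
#' \deqn{\theta = \arccos\frac{CC^2 + d_{\alpha\alpha}^2 -
#'   d_{\alpha\beta}^2}{2\, CC\, d_{\alpha\alpha}}}
#' where `CC` is the C-alpha--C-beta bond length (1.54 Angstrom). 0 degrees
#' means the side chain points exactly toward the labeled site, 180 degrees
#' exactly away; `d_aa < d_ab` implies an angle above 90 degrees.
#'
#' @param d_aa Distance from label C-alpha to quencher C-alpha (Angstrom).
#' @param d_ab Distance from label C-alpha to quencher C-beta (Angstrom).
#' @param cc C-C bond length (Angstrom), default 1.54.
#' @return Angle in degrees, in `[0, 180]`. Vectorised.
#' @export
angle_from_distances <- function(d_aa, d_ab, cc = 1.54) {
  n <- max(length(d_aa), length(d_ab), length(cc))
  d_aa <- rep_len(d_aa, n); d_ab <- rep_len(d_ab, n); cc <- rep_len(cc, n)
  cosv <- (cc^2 + d_aa^2 - d_ab^2) / (2 * cc * d_aa)
  slack <- 1e-9
  bad <- abs(cosv) > 1
  if (any(bad)) {
    # triangle-inequality violation beyond slack is a domain error
    excess <- pmax(d_ab - (d_aa + cc), abs(d_aa - cc) - d_ab)
    if (any(bad & excess > slack))
      stop("angle_from_distances: sides (cc, d_aa, d_ab) violate the triangle inequality",
           call. = FALSE)
    cosv <- pmin(pmax(cosv, -1), 1)
  }
  acos(cosv) * 180 / pi
}

#' Planar coordinates of the labeled C-alpha
#'
#' Places the quencher C-alpha at the origin and its C-beta at `(0, cc)`, and
#' returns the coordinates of the labeled C-alpha in that plane:
#' \deqn{x = d_{\alpha\alpha}\cos(\pi/2 - \theta),\quad
#'       y = d_{\alpha\alpha}\sin(\pi/2 - \theta)}
#' so that the distance from `(x, y)` to `(0, cc)` reproduces the
#' C-alpha--C-beta distance implied by [angle_from_distances()].
#'
#' @param d_aa Distance from the origin (quencher C-alpha) to the labeled
#'   C-alpha (Angstrom).
#' @param angle Orientation angle in degrees, in `[0, 180]`.
#' @param cc C-C bond length (Angstrom), default 1.54.
#' @return A data.frame with columns `angle`, `x`, `y`, `cc` (one row per
#'   input).
#' @export
planar_coordinates <- function(d_aa, angle, cc = 1.54) {
  n <- max(length(d_aa), length(angle), length(cc))
  d_aa <- rep_len(d_aa, n); angle <- rep_len(angle, n); cc <- rep_len(cc, n)
  if (any(angle < -1e-9) || any(angle > 180 + 1e-9))
    stop("planar_coordinates: angle must lie in [0, 180] degrees", call. = FALSE)
  theta <- angle * pi / 180
  data.frame(angle = angle,
             x = d_aa * cos(pi / 2 - theta),
             y = d_aa * sin(pi / 2 - theta),
             cc = cc)
}

#' Monte-Carlo volume oracle
#'
#' Unbiased rejection-sampling estimate of the volume of an arbitrary region,
#' used as an independent oracle for the closed-form shell/lens volumes.
#' Uniform points are drawn in the axis-aligned bounding box; the estimate is
#' the box volume times the hit fraction, with the binomial standard error.
#'
#' @param predicate Function taking an `n x 3` matrix of points and returning
#'   a logical vector: is each point inside the region?
#' @param box Numeric `2 x 3` matrix: rows are lower/upper corners.
#' @param n_points Number of sample points (`>= 1e4`).
#' @param seed Integer seed; the estimate is reproducible under it.
#' @return List with `volume`, `se` (standard error) and `n_points`.
#' @examples
#' mc_volume_oracle(function(p) rowSums(p^2) < 1,
#'                  rbind(c(-1, -1, -1), c(1, 1, 1)),
#'                  n_points = 1e4, seed = 1)
#' @export
mc_volume_oracle <- function(predicate, box, n_points = 1e6, seed = 1) {
  box <- as.matrix(box)
  if (!all(dim(box) == c(2, 3)) || any(box[2, ] <= box[1, ]))
    stop("mc_volume_oracle: box must be a 2 x 3 matrix with upper > lower", call. = FALSE)
  if (n_points < 1e4)
    stop("mc_volume_oracle: need at least 1e4 points", call. = FALSE)
  side <- box[2, ] - box[1, ]
  vbox <- prod(side)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pts <- cbind(runif(n_points, box[1, 1], box[2, 1]),
               runif(n_points, box[1, 2], box[2, 2]),
               runif(n_points, box[1, 3], box[2, 3]))
  hit <- as.logical(predicate(pts))
  p <- mean(hit)
  list(volume = vbox * p,
       se = vbox * sqrt(p * (1 - p) / n_points),
       n_points = n_points)
}

# save/restore global RNG state so seeded helpers do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# predicate for a shell (between radii rho - dr and rho) about a center
shell_predicate <- function(center, rho, dr) {
  force(center); force(rho); force(dr)
  function(p) {
    d2 <- (p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 + (p[, 3] - center[3])^2
    d2 <= rho^2 & d2 > (rho - dr)^2
  }
}
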