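# internal-coordinate atom placement: position D given A, B, C, the C-D bond
# length, the B-C-D angle (deg) and the A-B-C-D dihedral (deg)
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Labeled atom coordinates of a structure
#'
#' A `structure_coords` object indexes atom coordinates by residue id and
#' atom name; the container behind the polyproline builder, trilateration
#' and displacement maps.
#'
#' @param atoms data.frame with columns `residue_id` (integer),
#'   `residue_name`, `atom`, `x`, `y`, `z` (Angstrom).
#' @param chain_tag Free-text chain label.
#' @return Object of class `structure_coords`.
#' @export
structure_coords <- function(atoms, chain_tag = "") {
  need <- c("residue_id", "residue_name", "atom", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("structure_coords: atoms must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  structure(list(atoms = atoms, chain_tag = chain_tag), class = "structure_coords")
}

#' @export
print.structure_coords <- function(x, ...) {
  cat(sprintf("structure '%s': %d residues, %d atoms\n", x$chain_tag,
              length(unique(x$atoms$residue_id)), nrow(x$atoms)))
  invisible(x)
}

#' Fetch one atom's coordinates
#'
#' @param struct A [structure_coords()].
#' @param residue_id Residue number.
#' @param atom Atom name (e.g. `"CA"`).
#' @return Length-3 numeric vector (Angstrom).
#' @export
get_atom <- function(struct, residue_id, atom = "CA") {
  stopifnot(inherits(struct, "structure_coords"))
  i <- which(struct$atoms$residue_id == residue_id & struct$atoms$atom == atom)
  if (length(i) != 1)
    stop(sprintf("get_atom: atom %s of residue %s not found (or ambiguous)",
                 atom, residue_id), call. = FALSE)
  unlist(struct$atoms[i, c("x", "y", "z")], use.names = FALSE)
}

#' Build a Cys-(Pro)n-Trp polyproline II backbone
#'
#' Constructs the backbone (N, CA, C, O) of the length-standard peptide
#' residue by residue from ideal internal coordinates: bond lengths
#' N-CA 1.458, CA-C 1.525, C-N 1.329 Angstrom; backbone angles
#' N-CA-C 111.0, CA-C-N 116.2, C-N-CA 121.7 degrees; dihedrals
#' `phi = -75`, `psi = 150`, `omega = 180` for every residue (the
#' polyproline type II helix). The nominal peptide length is the distance
#' from the first (Cys) to the last (Trp) C-alpha, carried as attribute
#' `nominal_length`.
#'
#' @param n_pro Number of proline residues between the Cys and the Trp
#'   (`>= 0`).
#' @param phi,psi Backbone dihedrals in degrees (PPII defaults).
#' @param omega Peptide-bond dihedral in degrees, default 180 (trans).
#' @return A [structure_coords()] with attribute `nominal_length` (Angstrom).
#' @examples
#' pep <- build_ppii(3)
#' attr(pep, "nominal_length")   # ~ 12.4 Angstrom
#' @export
build_ppii <- function(n_pro, phi = -75, psi = 150, omega = 180) {
  if (n_pro < 0) stop("build_ppii: n_pro must be >= 0", call. = FALSE)
  n_res <- n_pro + 2
  res_names <- c("CYS", rep("PRO", n_pro), "TRP")
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.0; a_cacn <- 116.2; a_cnca <- 121.7

  coords <- vector("list", n_res)
  # first residue laid out in the xy-plane
  N <- c(0, 0, 0)
  CA <- c(b_nca, 0, 0)
  C <- place_atom(c(-1, 1, 0), N, CA, b_cac, a_ncac, phi + 180)  # arbitrary phase
  coords[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n_res - 1)) {
    prev <- coords[[i]]
    Nn <- place_atom(prev$N, prev$CA, prev$C, b_cn, a_cacn, psi)
    CAn <- place_atom(prev$CA, prev$C, Nn, b_nca, a_cnca, omega)
    Cn <- place_atom(prev$C, Nn, CAn, b_cac, a_ncac, phi)
    coords[[i + 1]] <- list(N = Nn, CA = CAn, C = Cn)
  }
  rows <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    # carbonyl O trans to the following N (dihedral psi + 180 about N-CA-C)
    O <- place_atom(coords[[i]]$N, coords[[i]]$CA, coords[[i]]$C,
                    1.231, 120.8, psi + 180)
    at <- rbind(coords[[i]]$N, coords[[i]]$CA, coords[[i]]$C, O)
    data.frame(residue_id = i, residue_name = res_names[i],
               atom = c("N", "CA", "C", "O"),
               x = at[, 1], y = at[, 2], z = at[, 3])
  }))
  out <- structure_coords(rows, chain_tag = sprintf("Cys-(Pro)%d-Trp", n_pro))
  ca1 <- get_atom(out, 1); can <- get_atom(out, n_res)
  attr(out, "nominal_length") <- sqrt(sum((can - ca1)^2))
  out
}

#' Locate a displaced atom by trilateration
#'
#' Given three non-collinear anchor atoms, a base position of the target
#' atom, and measured changes of the target-anchor distances, solves the
#' three-sphere system `|x - a_i| = |a_i - base| + delta_i` exactly. Three
#' spheres generically intersect in two points, mirror images through the
#' anchor plane; both are returned, labeled by signed distance along the
#' anchor-plane normal (oriented toward `normal_hint`, so positive means
#' "above" in the user's frame).
#'
#' @param anchors `3 x 3` matrix, one anchor point per row (Angstrom).
#' @param base_point Length-3 base position of the target atom.
#' @param deltas Length-3 distance changes (Angstrom); `c(0, 0, 0)`
#'   reproduces `base_point` on one branch.
#' @param normal_hint Direction that defines "up", default `c(0, 0, 1)`.
#' @return Object of class `trilateration_result`: `branch_upper`,
#'   `branch_lower` (each with `point` and `z_offset`, the signed normal
#'   displacement from `base_point`), `normal`, `radii`.
#' @export
trilaterate_displaced <- function(anchors, base_point, deltas,
                                  normal_hint = c(0, 0, 1)) {
  anchors <- as.matrix(anchors)
  stopifnot(all(dim(anchors) == c(3, 3)), length(base_point) == 3,
            length(deltas) == 3)
  base_radii <- sqrt(rowSums((anchors - matrix(base_point, 3, 3, byrow = TRUE))^2))
  radii <- base_radii + deltas
  if (any(radii <= 0))
    stop("trilaterate_displaced: non-positive target radius", call. = FALSE)
  p1 <- anchors[1, ]; p2 <- anchors[2, ]; p3 <- anchors[3, ]
  ex <- p2 - p1
  d <- sqrt(sum(ex^2)); ex <- ex / d
  v3 <- p3 - p1
  i <- sum(ex * v3)
  ey <- v3 - i * ex
  jlen <- sqrt(sum(ey^2))
  if (jlen < 1e-9 || d < 1e-9)
    stop("trilaterate_displaced: anchors are collinear", call. = FALSE)
  ey <- ey / jlen
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  if (sum(ez * normal_hint) < 0) ez <- -ez
  x <- (radii[1]^2 - radii[2]^2 + d^2) / (2 * d)
  y <- (radii[1]^2 - radii[3]^2 + i^2 + jlen^2 - 2 * i * x) / (2 * jlen)
  z2 <- radii[1]^2 - x^2 - y^2
  if (z2 < -1e-6 * max(radii^2))
    stop("trilaterate_displaced: spheres do not intersect (residual ",
         format(-z2), ")", call. = FALSE)
  z <- sqrt(max(z2, 0))
  up <- p1 + x * ex + y * ey + z * ez
  lo <- p1 + x * ex + y * ey - z * ez
  zoff <- function(p) sum((p - base_point) * ez)
  structure(list(branch_upper = list(point = up, z_offset = zoff(up)),
                 branch_lower = list(point = lo, z_offset = zoff(lo)),
                 normal = ez, radii = radii),
            class = "trilateration_result")
}

#' @export
print.trilateration_result <- function(x, ...) {
  cat(sprintf("trilateration: upper branch %+0.2f A, lower branch %+0.2f A along the anchor-plane normal\n",
              x$branch_upper$z_offset, x$branch_lower$z_offset))
  if (!is.null(x$cloud_upper))
    cat(sprintf("  bootstrap: upper %0.2f [%.2f, %.2f] A; lower %0.2f [%.2f, %.2f] A (%d/%d draws feasible)\n",
                x$summary$mean[1], x$summary$ci_lower[1], x$summary$ci_upper[1],
                x$summary$mean[2], x$summary$ci_lower[2], x$summary$ci_upper[2],
                x$n_feasible, x$n_draws))
  invisible(x)
}

#' Trilateration under distance-change uncertainty
#'
#' Propagates bootstrap distributions of the three distance changes through
#' [trilaterate_displaced()]: each draw samples one delta per anchor,
#' infeasible draws (non-intersecting spheres) are excluded and counted, and
#' the two solution clouds are summarized by the mean and 95 percent
#' percentile CI of the signed displacement along the anchor-plane normal.
#'
#' @param anchors,base_point,normal_hint As in [trilaterate_displaced()].
#' @param delta_distributions List of three numeric vectors (empirical
#'   distributions of each distance change, Angstrom).
#' @param n_draws Number of bootstrap draws, default 1000.
#' @param seed Integer seed.
#' @return A `trilateration_result` with additional fields `cloud_upper`,
#'   `cloud_lower` (`n x 3` matrices), `summary` (per-branch mean and CI of
#'   the normal displacement), `n_feasible`, `n_draws`.
#' @export
trilaterate_bootstrap <- function(anchors, base_point, delta_distributions,
                                  n_draws = 1000, seed = 1,
                                  normal_hint = c(0, 0, 1)) {
  stopifnot(length(delta_distributions) == 3)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ds <- vapply(delta_distributions, function(v) v[sample.int(length(v), n_draws,
                                                             replace = TRUE)],
               numeric(n_draws))
  up <- matrix(NA_real_, n_draws, 3); lo <- matrix(NA_real_, n_draws, 3)
  zu <- numeric(n_draws); zl <- numeric(n_draws); ok <- logical(n_draws)
  for (k in seq_len(n_draws)) {
    tri <- tryCatch(trilaterate_displaced(anchors, base_point, ds[k, ],
                                          normal_hint),
                    error = function(e) NULL)
    if (!is.null(tri)) {
      ok[k] <- TRUE
      up[k, ] <- tri$branch_upper$point; zu[k] <- tri$branch_upper$z_offset
      lo[k, ] <- tri$branch_lower$point; zl[k] <- tri$branch_lower$z_offset
    }
  }
  if (mean(ok) < 0.5)
    stop(sprintf("trilaterate_bootstrap: %d of %d draws infeasible",
                 sum(!ok), n_draws), call. = FALSE)
  central <- trilaterate_displaced(anchors, base_point,
                                   vapply(delta_distributions, mean, 0),
                                   normal_hint)
  central$cloud_upper <- up[ok, , drop = FALSE]
  central$cloud_lower <- lo[ok, , drop = FALSE]
  central$summary <- data.frame(
    branch = c("upper", "lower"),
    mean = c(mean(zu[ok]), mean(zl[ok])),
    ci_lower = c(unname(stats::quantile(zu[ok], 0.025)),
                 unname(stats::quantile(zl[ok], 0.025))),
    ci_upper = c(unname(stats::quantile(zu[ok], 0.975)),
                 unname(stats::quantile(zl[ok], 0.975))))
  central$n_feasible <- sum(ok)
  central$n_draws <- n_draws
  central
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation and translation superposing `moving` onto
#' `fixed` over a paired atom selection, by singular value decomposition
#' with the determinant correction (no reflections).
#'
#' @param moving,fixed `n x 3` coordinate matrices (paired rows, `n >= 3`),
#'   or [structure_coords()] objects with `atom_selection` naming the atom
#'   to pair on shared residues.
#' @param atom_selection Atom name used when structures are given, default
#'   `"CA"`.
#' @return List: `rotation` (3 x 3), `translation` (length 3; the transform
#'   is `x %*% rotation + translation`), `rmsd`, `apply` (function mapping
#'   an `n x 3` matrix through the transform).
#' @export
kabsch_superpose <- function(moving, fixed, atom_selection = "CA") {
  pair <- function(m, f) {
    if (inherits(m, "structure_coords")) {
      shared <- intersect(m$atoms$residue_id[m$atoms$atom == atom_selection],
                          f$atoms$residue_id[f$atoms$atom == atom_selection])
      m <- t(vapply(shared, function(r) get_atom(m, r, atom_selection), numeric(3)))
      f <- t(vapply(shared, function(r) get_atom(f, r, atom_selection), numeric(3)))
    }
    list(m = as.matrix(m), f = as.matrix(f))
  }
  p <- pair(moving, fixed)
  if (nrow(p$m) < 3 || nrow(p$m) != nrow(p$f))
    stop("kabsch_superpose: need at least 3 paired atoms", call. = FALSE)
  cm <- colMeans(p$m); cf <- colMeans(p$f)
  A <- sweep(p$m, 2, cm); B <- sweep(p$f, 2, cf)
  s <- svd(crossprod(A, B))
  dsign <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, dsign)) %*% t(s$v)
  tr <- cf - as.vector(cm %*% R)
  applyfn <- function(x) sweep(as.matrix(x) %*% R, 2, tr, `+`)
  rmsd <- sqrt(mean(rowSums((applyfn(p$m) - p$f)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd, apply = applyfn)
}

#' Per-residue displacement map between two structures
#'
#' After rigid superposition on the shared C-alpha atoms of the requested
#' residue range, reports the C-alpha to C-alpha distance of every shared
#' residue between the two structures (e.g. apo versus ligand-bound).
#' Residues not present in both structures are dropped and reported in the
#' `n_dropped` attribute.
#'
#' @param struct_a,struct_b [structure_coords()] objects.
#' @param residue_range Integer vector of residue ids to consider; default
#'   all residues of `struct_a`.
#' @return data.frame with columns `residue_id`, `residue_name`,
#'   `displacement` (Angstrom), plus attributes `rmsd` and `n_dropped`.
#' @export
residue_displacement_map <- function(struct_a, struct_b,
                                     residue_range = NULL) {
  stopifnot(inherits(struct_a, "structure_coords"),
            inherits(struct_b, "structure_coords"))
  ca_a <- struct_a$atoms[struct_a$atoms$atom == "CA", ]
  ca_b <- struct_b$atoms[struct_b$atoms$atom == "CA", ]
  if (is.null(residue_range)) residue_range <- ca_a$residue_id
  shared <- intersect(intersect(residue_range, ca_a$residue_id), ca_b$residue_id)
  n_dropped <- length(setdiff(residue_range, shared))
  if (length(shared) == 0)
    stop("residue_displacement_map: no shared residues in range", call. = FALSE)
  A <- t(vapply(shared, function(r) get_atom(struct_a, r, "CA"), numeric(3)))
  B <- t(vapply(shared, function(r) get_atom(struct_b, r, "CA"), numeric(3)))
  k <- kabsch_superpose(A, B)
  disp <- sqrt(rowSums((k$apply(A) - B)^2))
  out <- data.frame(residue_id = shared,
                    residue_name = ca_a$residue_name[match(shared, ca_a$residue_id)],
                    displacement = disp)
  attr(out, "rmsd") <- k$rmsd
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read atom coordinates from a PDB file
#'
#' Parses `ATOM` records of the first model (everything before the first
#' `ENDMDL`), preferring blank or `'A'` alternate locations, and indexes
#' them by residue.
#'
#' @param path PDB file path.
#' @param chain Optional chain identifier filter.
#' @return A [structure_coords()].
#' @export
read_structure <- function(path, chain = NULL) {
  lines <- readLines(path)
  endm <- which(startsWith(lines, "ENDMDL"))
  if (length(endm) > 0) lines <- lines[seq_len(endm[1] - 1)]
  at <- lines[startsWith(lines, "ATOM")]
  if (length(at) == 0) stop("read_structure: no ATOM records", call. = FALSE)
  altloc <- substr(at, 17, 17)
  at <- at[altloc %in% c(" ", "A", "")]
  ch <- substr(at, 22, 22)
  if (!is.null(chain)) at <- at[ch == chain]
  df <- data.frame(residue_id = as.integer(substr(at, 23, 26)),
                   residue_name = trimws(substr(at, 18, 20)),
                   atom = trimws(substr(at, 13, 16)),
                   x = as.numeric(substr(at, 31, 38)),
                   y = as.numeric(substr(at, 39, 46)),
                   z = as.numeric(substr(at, 47, 54)))
  structure_coords(df, chain_tag = chain %||% unique(substr(at, 22, 22))[1])
}
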