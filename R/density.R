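#' Conformer ensembles of dye-residue conjugates
#'
#' A `conformer_ensemble` holds coordinate snapshots of a labeled residue
#' (e.g. a Cys-rhodamine conjugate, or a Trp) together with the index of the
#' anchor atom (the C-alpha or C-beta) and the indices of the mobile moiety
#' (the xanthene ring system of the dye, or the Trp indole). It is the input
#' from which radial probability densities are built.
#'
#' @param frames List of `n_atoms x 3` numeric matrices (Angstrom), one per
#'   snapshot; all with the same atom count.
#' @param atom_labels Character vector of atom names, one per atom.
#' @param anchor_index Integer index of the anchor atom.
#' @param moiety_indices Integer indices of the moiety atoms; must not
#'   include the anchor.
#' @param source_tag Free-text label (e.g. the fluorophore name).
#' @return An object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(frames, atom_labels = NULL, anchor_index,
                               moiety_indices, source_tag = "") {
  if (length(frames) < 1) stop("conformer_ensemble: need at least one frame", call. = FALSE)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (ncol(f) != 3) stop("conformer_ensemble: frames must be n x 3", call. = FALSE)
    f
  })
  nat <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, 0L) != nat))
    stop("conformer_ensemble: all frames must have the same atom count", call. = FALSE)
  anchor_index <- as.integer(anchor_index)
  moiety_indices <- as.integer(moiety_indices)
  if (length(moiety_indices) < 1)
    stop("conformer_ensemble: need at least one moiety atom", call. = FALSE)
  if (anchor_index %in% moiety_indices)
    stop("conformer_ensemble: anchor atom cannot belong to the moiety", call. = FALSE)
  if (anchor_index < 1 || anchor_index > nat || any(moiety_indices < 1) ||
      any(moiety_indices > nat))
    stop("conformer_ensemble: atom indices out of range", call. = FALSE)
  structure(list(frames = frames,
                 atom_labels = if (is.null(atom_labels)) rep("", nat) else atom_labels,
                 anchor_index = anchor_index,
                 moiety_indices = moiety_indices,
                 source_tag = source_tag),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("conformer ensemble '%s': %d frames, %d atoms, anchor #%d, moiety %d atoms\n",
              x$source_tag, length(x$frames), nrow(x$frames[[1]]),
              x$anchor_index, length(x$moiety_indices)))
  invisible(x)
}

#' Centroid of a moiety within one frame
#'
#' Unweighted mean of the Cartesian coordinates of the member atoms, the
#' convention used to locate the xanthene (fluorophore) and indole (quencher)
#' ring systems.
#'
#' @param frame `n_atoms x 3` coordinate matrix (Angstrom).
#' @param moiety_indices Integer atom indices (at least one).
#' @return Length-3 numeric vector.
#' @export
moiety_centroid <- function(frame, moiety_indices) {
  if (length(moiety_indices) < 1)
    stop("moiety_centroid: empty moiety index set", call. = FALSE)
  colMeans(as.matrix(frame)[moiety_indices, , drop = FALSE])
}

#' Radial probability histogram
#'
#' Bins anchor-to-centroid distances into shells of width `bin_width`
#' (default 0.05 Angstrom) and normalizes counts by the number of
#' observations. Bin `k` covers the half-open interval
#' `((k-1)*bin_width, k*bin_width]`, so a distance exactly on an edge falls
#' in the lower-indexed covering bin.
#'
#' @param distances Non-negative distances (Angstrom), at least one.
#' @param bin_width Bin size \eqn{\delta r} (Angstrom), default 0.05.
#' @param anchor_kind `"Ca"` or `"Cb"`: which atom the distances are
#'   measured from.
#' @param moiety_kind `"xanthene"` or `"indole"`.
#' @return An object of class `radial_density` with fields `bin_width`,
#'   `probabilities` (named by bin index, support-trimmed), `bin_index`
#'   (integer indices of occupied-range bins), `anchor_kind`, `moiety_kind`,
#'   `n_samples`.
#' @export
radial_histogram <- function(distances, bin_width = 0.05,
                             anchor_kind = c("Ca", "Cb"),
                             moiety_kind = c("xanthene", "indole")) {
  anchor_kind <- match.arg(anchor_kind)
  moiety_kind <- match.arg(moiety_kind)
  if (length(distances) < 1) stop("radial_histogram: need at least one sample", call. = FALSE)
  if (any(distances < 0)) stop("radial_histogram: negative distance", call. = FALSE)
  if (bin_width <= 0) stop("radial_histogram: bin width must be positive", call. = FALSE)
  # bin k covers ((k-1)*dr, k*dr]; a distance of exactly 0 goes to bin 1
  k <- pmax(ceiling(distances / bin_width - 1e-12), 1L)
  kmax <- max(k)
  counts <- tabulate(k, nbins = kmax)
  structure(list(bin_width = bin_width,
                 probabilities = counts / length(distances),
                 bin_index = seq_len(kmax),
                 anchor_kind = anchor_kind,
                 moiety_kind = moiety_kind,
                 n_samples = length(distances)),
            class = "radial_density")
}

#' @export
print.radial_density <- function(x, ...) {
  occ <- which(x$probabilities > 0)
  cat(sprintf(paste0("radial density (%s anchor, %s moiety): %d samples, ",
                     "bin %.3g A, support %.2f-%.2f A, mean %.2f A\n"),
              x$anchor_kind, x$moiety_kind, x$n_samples, x$bin_width,
              (min(occ) - 1) * x$bin_width, max(occ) * x$bin_width,
              density_mean(x)))
  invisible(x)
}

#' Mean of a radial density
#'
#' Probability-weighted mean of bin centers, in Angstrom.
#' @param x A `radial_density`.
#' @return Numeric scalar.
#' @export
density_mean <- function(x) {
  centers <- (x$bin_index - 0.5) * x$bin_width
  sum(centers * x$probabilities)
}

#' Radial density of a conformer ensemble
#'
#' Measures, in every frame, the distance between the anchor atom and the
#' moiety centroid, and bins the distances with [radial_histogram()]. This is
#' the operation that turns an MD-like ensemble into the `f_alpha` / `q_alpha`
#' / `q_beta` probability distributions used to build FDQ functions.
#'
#' @param ensemble A [conformer_ensemble()].
#' @param bin_width Bin size (Angstrom), default 0.05.
#' @param anchor_kind,moiety_kind Passed to [radial_histogram()].
#' @return A `radial_density`.
#' @export
ensemble_to_density <- function(ensemble, bin_width = 0.05,
                                anchor_kind = c("Ca", "Cb"),
                                moiety_kind = c("xanthene", "indole")) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  d <- vapply(ensemble$frames, function(f) {
    cen <- moiety_centroid(f, ensemble$moiety_indices)
    sqrt(sum((f[ensemble$anchor_index, ] - cen)^2))
  }, 0)
  radial_histogram(d, bin_width, match.arg(anchor_kind), match.arg(moiety_kind))
}

#' Read a conformer ensemble from a multi-model PDB or XYZ trajectory
#'
#' Multi-model PDB frames are delimited by `MODEL`/`ENDMDL` records (a file
#' without `MODEL` records is a single frame); XYZ frames follow the plain
#' `n / comment / n atom lines` convention. Atom selectors are atom-name
#' character vectors resolved against the first frame's labels; they must
#' resolve to the same atoms in every frame, which fixed atom counts
#' guarantee.
#'
#' @param path File path.
#' @param format `"pdb"` or `"xyz"`.
#' @param anchor_selector Single atom name (e.g. `"CA"`).
#' @param moiety_selector Character vector of moiety atom names.
#' @param source_tag Label stored on the ensemble (default: file name).
#' @return A [conformer_ensemble()].
#' @export
read_ensemble <- function(path, format = c("pdb", "xyz"), anchor_selector,
                          moiety_selector, source_tag = basename(path)) {
  format <- match.arg(format)
  lines <- readLines(path)
  parsed <- if (format == "pdb") parse_pdb_frames(lines) else parse_xyz_frames(lines)
  labels <- parsed$labels
  anchor <- which(labels == anchor_selector)
  if (length(anchor) != 1)
    stop(sprintf("read_ensemble: anchor selector '%s' resolves to %d atoms (need exactly 1)",
                 anchor_selector, length(anchor)), call. = FALSE)
  moiety <- which(labels %in% moiety_selector)
  if (length(moiety) < 1)
    stop("read_ensemble: moiety selector matches no atoms", call. = FALSE)
  conformer_ensemble(parsed$frames, labels, anchor, moiety, source_tag)
}

parse_pdb_frames <- function(lines) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  frame_of <- if (length(model_starts) == 0) {
    rep(1L, length(lines))
  } else {
    findInterval(seq_along(lines), model_starts)
  }
  atom_lines <- which(is_atom & frame_of >= 1)
  if (length(atom_lines) == 0) stop("parse_pdb_frames: no ATOM records", call. = FALSE)
  fidx <- frame_of[atom_lines]
  names_all <- trimws(substr(lines[atom_lines], 13, 16))
  x <- as.numeric(substr(lines[atom_lines], 31, 38))
  y <- as.numeric(substr(lines[atom_lines], 39, 46))
  z <- as.numeric(substr(lines[atom_lines], 47, 54))
  frames <- split.data.frame(cbind(x, y, z), fidx)
  labels <- names_all[fidx == fidx[1]]
  counts <- vapply(frames, nrow, 0L)
  if (any(counts != counts[1]))
    stop(sprintf("parse_pdb_frames: inconsistent atom count at frame %d",
                 which(counts != counts[1])[1]), call. = FALSE)
  list(frames = lapply(frames, unname), labels = labels)
}

parse_xyz_frames <- function(lines) {
  frames <- list(); labels <- NULL; i <- 1; k <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop(sprintf("parse_xyz_frames: bad atom count at line %d", i), call. = FALSE)
    body <- lines[(i + 2):(i + 1 + n)]
    tok <- strsplit(trimws(body), "\\s+")
    lab <- vapply(tok, `[`, "", 1)
    xyz <- t(vapply(tok, function(t) as.numeric(t[2:4]), numeric(3)))
    k <- k + 1
    if (is.null(labels)) labels <- lab
    else if (length(lab) != length(labels))
      stop(sprintf("parse_xyz_frames: inconsistent atom count at frame %d", k), call. = FALSE)
    frames[[k]] <- xyz
    i <- i + 2 + n
  }
  list(frames = frames, labels = labels)
}
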