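# Shared fixtures, built in code at test time.

# canonical synthetic dye families for the inversion tests: an alpha-alpha
# set and an alpha-beta set that is its exact +0.9 A rigid shift, so dual
# fits have a geometrically consistent truth (d_ab = d_aa + 0.9 per state)
FDQ_AA <- synth_fdq_family(anchor_pair = "aa")
FDQ_AB <- synth_fdq_family(anchor_pair = "ab", shift = 0.9)
AB_SHIFT <- 0.9

# tight bounding box for the intersection of shell (0, R) and shell (d, r),
# used by the Monte-Carlo volume oracle
shell_pair_box <- function(d, R, r) {
  xlim <- c(max(-R, d - r), min(R, d + r))
  if (xlim[1] >= xlim[2]) xlim <- c(-R, R)
  w <- min(R, r)
  rbind(c(xlim[1], -w, -w), c(xlim[2], w, w))
}

# predicate: point inside both shells (K at origin, kappa at (d, 0, 0))
shell_pair_predicate <- function(d, R, r, dr) {
  function(p) {
    d1 <- sqrt(p[, 1]^2 + p[, 2]^2 + p[, 3]^2)
    d2 <- sqrt((p[, 1] - d)^2 + p[, 2]^2 + p[, 3]^2)
    d1 <= R & d1 > R - dr & d2 <= r & d2 > r - dr
  }
}

# small ensemble with a rigid moiety at fixed radius from the anchor
rigid_ensemble <- function(radius, n_frames = 50) {
  frames <- lapply(seq_len(n_frames), function(i) {
    ang <- 2 * pi * i / n_frames
    rbind(c(0, 0, 0),
          radius * c(cos(ang), sin(ang), 0))
  })
  conformer_ensemble(frames, c("ANC", "MOI"), 1L, 2L, "rigid")
}
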