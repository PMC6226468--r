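---
title: "DEPET: models, numerical choices and synthetic worlds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DEPET: models, numerical choices and synthetic worlds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depet)
```

## The measurement model

Photoinduced electron transfer between a tryptophan indole and a
rhodamine-class xanthene is contact-mediated: both the collisional and the
static (complex-forming) channels require van der Waals overlap, and both
act within nanoseconds, so steady-state fluorescence cannot distinguish
them. The package therefore models quenching as a single contact
probability. A dye tethered to a cysteine explores a cloud of positions
set by its linker; a tryptophan side chain explores its own, smaller
cloud. The probability that the two clouds touch — and hence that
emission is lost — depends on the distance between the two anchoring
backbone atoms. Dyes of different linker length give independent readings
of that dependence, and jointly they invert to a distance.

### From conformers to radial densities

`ensemble_to_density()` reduces a conformer ensemble (imported multi-model
PDB/XYZ, or the built-in chain sampler) to a histogram of
anchor-to-moiety-centroid distances with bin width δr = 0.05 Å. Bins are
half-open, `((k-1)δr, kδr]`, so a distance exactly on an edge is counted
once, in the lower-indexed covering bin. Each bin is a spherical shell of
thickness δr about the anchor; the histogram mass is the probability of
finding the moiety centroid in that shell. No fixed maximal radius is
imposed: the support is data-driven, and mass beyond the last occupied
bin is zero.

For side-chain work the same tryptophan ensemble is reused with the
anchor switched from Cα to Cβ; nothing is re-simulated.

### Exact shell-intersection geometry

The quenching probability at anchor separation *d* sums, over all
occupied shell pairs (K, κ), the intersection volume of the two shells
scaled by *both* shells' volumes — the fraction of each shell's volume
available for contact:

P(X, d) = Σ_{R,r} [V(K∩κ)/V(K)]·f(X,K) · [V(K∩κ)/V(κ)]·q(κ).

The shell intersection volume is computed by inclusion–exclusion over the
four bounding sphere pairs, with every two-sphere ("lens") term clamped
analytically in its degenerate regimes (disjoint → 0; contained or
concentric → volume of the smaller sphere; tangent → 0). On the δr grid
this reproduces the published case table for shell pairs exactly — the
zero cases, the full-shell case at d = 0 with R = r, the single tangent
lens at d = R + r − δr, and the two-term differences at d = |R − r| all
telescope out of the clamped four-term form — and between grid points it
continues the geometry smoothly. This resolves the open question of
non-grid separations without a case-by-case dispatcher: the four-term
form *is* the dispatcher. Concentric shells (d < 1e−9 Å) are handled by
radial-interval overlap because the lens formula is singular at zero
center separation.

The Monte-Carlo oracle (`mc_volume_oracle()`, rejection sampling with
binomial standard errors) is kept in the package as an independent check;
the test suite verifies every dispatch branch against it at 10⁶ points.

A note on shape: the exact P(X, d) has a narrow spike at d ≈ 0, where
shells of equal radius overlap completely (the double ratio becomes 1).
This concentric configuration is geometrically correct but physically
unreachable (two residues cannot coincide), and the empirical FDQ fit
absorbs it into a short-length-constant exponential. Distance inference
never evaluates the region below ~3 Å.

### The empirical FDQ parameterization

`fit_fdq()` compresses a curve into up to two exponentials plus up to six
Gaussians. The printed form of the Gaussian normalization is ambiguous
between A/(σ√(2π)) and A/√(2πσ); we use the conventional Gaussian
density A/(σ√(2π)). Since amplitudes are free parameters refit to the
curve, the choice changes only the reported A values, not the function.

Component count is chosen by forward selection: starting from the empty
model, one candidate Gaussian (seeded at the largest residual, width from
the half-maximum run around it) and one candidate exponential (length
constant from a log-linear fit of the positive residuals, plus a
deliberately short-range alternative for the contact spike) are refit
jointly by bounded L-BFGS-B with analytic gradients; the better candidate
is kept. Selection stops when the relative RMS residual drops below 1e−3
of the curve maximum (configurable) or the component caps are reached;
amplitudes are constrained nonnegative to preserve the probability
interpretation, and σ is bounded below by half a bin. If the caps are
reached short of the target the best model is returned with a warning
carrying the achieved residual — downstream code can then judge fitness
via the recorded `rel_rms` attribute. Histogram sampling noise sets a
floor on the achievable residual for ensemble-derived curves; curves
generated from exact mixtures refit to ~1e−6 relative RMS.

Stereoisomer mixtures (dyes sold as 5′/6′ blends) are handled before
fitting: the two isomer curves are averaged pointwise (`mix_isomers()`).
Chemically different dyes are put on a common quenching-efficiency scale
by multiplying the FDQ by the ratio of their Stern–Volmer constants to a
reference (`scale_by_ksv()`); the scaling convention (multiplicative,
explicit reference) is ours, as only the possibility of scaling is
documented in the source literature.

## Signal preprocessing

Bleach correction fits a single exponential (amplitude, τ, offset) to a
no-stimulus reference sweep and subtracts it. The per-voltage deflection
amplitude is measured as the mean of the last 20 % of the pulse window
minus the pre-pulse baseline mean — the extraction window is our
documented default, as the upstream protocol does not state one. The
ΔF–V relation is fit by a four-parameter Boltzmann (least squares,
multi-start BFGS; at V½ the fitted curve equals ΔF_min + ΔF_total/2 by
construction), the G–V relation by a sum of two Boltzmann components with
G_max defined as their exact sum, and the DEPET observable is
ΔF_total/G_max. Constants: F = 96485.332 C mol⁻¹,
R = 8.314462 J mol⁻¹ K⁻¹, T = 294 K by default. Conductance points
within 0.5 mV of E_K are excluded (division guard; our choice).

## The inverse problem

For each bootstrap set the model ΔF_X = [FDQ(X, d_R) − FDQ(X, d_A)]·c is
fit to the per-fluorophore bootstrap-averaged ΔF/G. The sign convention:
ΔF > 0 means fluorescence increases on depolarization (unquenching); c is
constrained positive (optimized as log c), so the sign of the prediction
lives entirely in the FDQ difference.

Implementation choices that the source description leaves open:

* **Optimizer.** A projected Levenberg–Marquardt with analytic Jacobians,
  written in C++ (the only compiled code in the package): the routine
  performs `n_bootstrap × seeds` fits (1,250,000 at full scale), which is
  far too hot for an R-level optimizer. SSE-change tolerance 1e−10,
  at most 200 iterations per start.
* **Seed grid.** Five increments per free parameter, inclusive of the
  bounds; distances span [3, 28] Å by default (the union of typical FDQ
  supports), c is log-spaced over [10³, 10⁷]. 5³ = 125 starts for the
  single-pair problem, 5⁵ = 3125 for the dual problem. Only the
  least-error solution per bootstrap set is kept; adding seeds can never
  worsen it.
* **Carbon-bond constraint.** In dual mode the backbone and side-chain
  solutions must satisfy |d_αα − d_αβ| ≤ 1.54 Å. We enforce it per state
  (resting and active separately) — the only geometrically meaningful
  reading, since both states describe the same covalent Cα–Cβ bond —
  boundary inclusive, and violating bootstrap solutions are excluded,
  never projected onto the constraint.
* **Confidence intervals.** The 10,000 retained solutions form the
  bootstrap distribution; we report its mean and a 95 % interval. With
  few replicates per fluorophore (3–5 is typical) the plain 2.5–97.5
  percentile interval is systematically narrow: resampling n points
  underestimates the mean's sampling variance by (n−1)/n and has no
  Student-t tails. We therefore use the expanded percentile interval
  (Hesterberg 2015, *The American Statistician* 69:371–386), which widens
  the quantile levels to Φ(−√(n/(n−1))·t_{n−1,0.025}) and converges to
  the plain percentile interval as n grows. Trilateration clouds, which
  are draws rather than resampled means, keep plain percentiles.

Side-chain orientation follows per retained draw by the law of cosines
over the triangle (Cα, Wα, Wβ) with the 1.54 Å bond as the short side;
draws violating the triangle inequality (possible because the two
distances are fit, not measured jointly with the bond) are excluded and
counted. Angles are reported in degrees; d_αα < d_αβ ⇒ angle > 90°, the
side chain points away from the labeled site.

## Structure tools

`build_ppii()` constructs Cys-(Pro)ₙ-Trp backbones residue by residue
from internal coordinates (N–Cα 1.458 Å, Cα–C 1.525 Å, C–N 1.329 Å;
N-Cα-C 111.0°, Cα-C-N 116.2°, C-N-Cα 121.7°; φ = −75°, ψ = 150°,
ω = 180°). Constant dihedrals make the chain screw-symmetric, so the
Cα-Cα virtual-bond steps are identical along the chain (rise ≈ 3.1 Å per
residue) and the nominal ruler length — first to last Cα — grows strictly
with n. The n = 3 ruler measures 12.50 Å here, against the 12.4 Å value
quoted for graphics-software-built peptides; agreement within ±0.3 Å is
the accepted tolerance because published backbone geometry tables differ
at that level.

`trilaterate_displaced()` solves the three-sphere system exactly (frame
reduction to two coordinates plus a square root), returning both mirror
branches labeled by signed displacement along the anchor-plane normal;
the normal's orientation is set by a user hint (default +z). Infeasible
bootstrap draws (spheres failing to intersect) are excluded and counted;
more than 50 % infeasible is an error, not a warning. Superposition uses
the Kabsch SVD construction with the determinant correction, so the
rotation is always proper.

## Synthetic worlds, and what a green test establishes

All generators are pure functions of their parameters and a seed.

* **Chain sampler** (`synth_conformer_cloud()`): a freely rotating chain
  with Gaussian bend noise and a rigid moiety offset along the final
  bond. It reproduces the qualitative family behavior that matters —
  longer linkers give broader, farther-reaching densities — and nothing
  else; it is not a force field, and the FDQ curves it yields are not
  the literature's fitted parameter sets (those would require the
  original MD engine).
* **FDQ family** (`synth_fdq_family()`): a parameterized stand-in for a
  fitted dye series — per dye a contact exponential plus a dominant
  Gaussian envelope whose mean shifts outward with linker length —
  spanning ~3–30 Å so that both the resting (~6–8 Å) and active
  (~13–14 Å) regimes and the polyproline ruler range are informative.
  The matching "αβ" family is the exact rigid shift of the "αα" family
  (the exponential shift is folded into its amplitude), which makes the
  dual-fit equation systems exactly consistent at d_αβ = d_αα + shift —
  the cleanest possible truth for round-trip tests. Recovery tests
  therefore establish the correctness and calibration of the inversion
  machinery, not the fidelity of any particular dye's physics.
* **Titrations** (`synth_titration()`): F₀/F = 1 + K_SV·[Q] over the
  0–30 µM series. The noise parameter is relative to the quenching term
  K_SV·[Q], not to raw fluorescence: at micromolar quencher and
  K_SV ≈ 40 M⁻¹ the quenching depth is ~10⁻³ of the intensity, so noise
  proportional to raw intensity would leave the slope unidentifiable and
  make the stated recovery target (5 % at 1 % noise) unreachable under
  any estimator. The chosen reading models an instrument that resolves
  the quenching signal itself to the stated precision.
* **Sweeps and peptide peaks** (`synth_sweep()`,
  `synth_peptide_peaks()`): direct forward models of the Boltzmann and
  intramolecular-quenching equations. Peptide noise is multiplicative on
  the conjugate peak fluorescence; because quenching is 1 − ratio, this
  is approximately *absolute* noise on the quenching value, so the
  benchmark world uses a conversion coefficient giving quenching depths
  of order 0.1–0.8, as real contact-quenched short peptides show.

## Known limitations

* FDQ fidelity in the far tail is limited by histogram sampling noise;
  curves derived from small ensembles carry their residual in the
  `rel_rms` attribute and should be judged by it.
* The inverse problem is only as identifiable as the FDQ family is
  diverse; with a single fluorophore d_R, d_A and c are hopelessly
  confounded (hence the ≥ 3 fluorophore requirement).
* Kinetic information (fluorescence relaxation time courses) is out of
  scope; the package treats ΔF amplitudes only.
* PDB parsing is deliberately minimal (first model, ATOM records,
  altloc blank/A) — enough for the coordinate operations here, not a
  general-purpose reader.
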