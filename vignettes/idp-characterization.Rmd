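---
title: "Characterizing intrinsically disordered proteins with idpchar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing intrinsically disordered proteins with idpchar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpchar)
```

Intrinsically disordered proteins (IDPs) lack a stable tertiary fold under
native conditions, so no single experiment proves disorder: the case is
built from converging evidence. `idpchar` implements the four
solution-state pillars of that case — sequence analysis, hydrodynamics,
small-angle X-ray scattering (SAXS) and circular dichroism (CD) — plus a
coarse-grained ensemble-selection stage, each paired with a synthetic-data
generator that embeds its ground truth. This vignette explains the models,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic round trips do and do not demonstrate about real data.

## Sequence descriptors

The charge architecture of a disordered chain largely determines its
dimensions. From the fractions of positively (`f+`: Lys, Arg) and
negatively (`f-`: Asp, Glu) charged residues the package derives the net
charge per residue (NCPR = f+ − f−), the fraction of charged residues
(FCR = f+ + f−), and the diagram-of-states region: region 1 (low FCR,
globule/tadpole), region 3 (high FCR, swollen coils), and region 2, the
boundary band 0.25 ≤ FCR ≤ 0.35 between them. Histidine is treated as
neutral at pH 7 (its sidechain pKa ≈ 6); `his_charged = TRUE` switches to
an acidic-pH convention. Band membership takes precedence over the
region-1 square, so sequences on the boundary are labelled with the band.

Linear charge patterning is quantified by κ: windows of 5 and 6 residues
("blobs", full windows only, stride 1) are scored by the local charge
asymmetry σ = (f+ − f−)²/(f+ + f−); the variance of σ around its
whole-sequence value (δ) is normalized by δ of the maximally *segregated*
rearrangement of the same composition, and the two blob sizes are
averaged. The normalizer is a convention, not a mathematical supremum: the
segregated arrangement is built from the three canonical block orders
(positives–neutrals–negatives and its two distinct permutations; the
others are equivalent under reversal or charge-sign swap, which leave δ
unchanged). For compositions with few charges and many neutral residues,
*spaced* single charges can produce a larger δ than any block arrangement,
which is why κ is defined with the segregated normalizer and clipped to
\[0, 1\] rather than asserted to be a permutation maximum. For realistic
mixed compositions the construction dominates random arrangements by a
wide margin (property-tested).

The charge–hydropathy predictor calls a protein disordered when its
normalized mean hydrophobicity H (Kyte–Doolittle rescaled to \[0, 1\],
averaged over 5-residue windows) falls below the boundary
(R + 1.151)/2.785, with R = |NCPR|. The reported CH distance is the
*vertical* offset from the boundary; whether published distances use the
vertical or perpendicular convention is typically not resolvable from
printed values, so the simpler vertical convention is used and stated.
The Table-style hydropathy column is the unwindowed Kyte–Doolittle mean
shifted to the 0–9 scale. Compositional bias is reported as
(CP − CSP)/CSP against a frozen Swiss-Prot average-frequency table
(shipped with the package, because the live database drifts), with
residues annotated as disorder-promoting (A,G,R,D,H,Q,K,S,E,P) or
order-promoting (W,F,Y,I,M,L,V,C,T). The pI is a convenience bisection on
Henderson–Hasselbalch sums and is explicitly not validated against
published values (pKa-set dependent).

## Low-complexity segmentation

Segmentation follows the classic two-threshold entropy scan: 12-residue
windows whose composition entropy is ≤ 2.2 bits trigger, triggers extend
through overlapping windows ≤ 2.5 bits, and overlapping extensions merge.
The defaults are the standard stringent parameter set for protein
low-complexity detection. The final optimal-subsequence refinement of the
original algorithm is deliberately omitted: segment *counts* and
approximate locations are robust to it, but exact boundaries may differ
from canonical implementations by a couple of residues, so analyses
should rely on counts and coverage rather than exact coordinates.
Coordinates are 1-based inclusive; BED export converts to 0-based
half-open.

## Hydrodynamics

All conformational-state expectations are log10-linear power laws of
molecular mass (mass in Da, radii in Å): natively folded
(0.357·logMM − 0.204), molten globule (0.334·logMM − 0.053), premolten
globule (0.392·logMM − 0.210), urea-unfolded (0.521·logMM − 0.649), and
the folded dimer, which is the folded law at twice the mass. The IDP
expectation is the Flory-type power law Rs = 2.49·N^0.509 on the residue
count of the *measured construct* (vector-encoded extensions included),
since the construct is the species in the column. The compaction index
CI = (Rs_U − Rs_obs)/(Rs_U − Rs_NF) is 1 for a folded-globule radius and
0 for a fully expanded chain; out-of-range values are returned with a
warning, never clamped, because they are diagnostic of inconsistent
inputs. The nearest-state call picks the state whose observed/expected
ratio is closest to 1, breaking exact ties toward the more compact state
(reported via a `tie` attribute). Note that the folded-dimer ratio is
often also near 1 for expanded monomers — SEC alone cannot exclude a
dimer; an independent mass (native MS, SAXS I(0)) settles it. SEC
calibration fits log10(Rs) of globular standards against elution volume
by least squares, requires ≥ 3 standards, and flags extrapolation.

## SAXS

The Guinier law ln I(q) = ln I0 − q²Rg²/3 holds only as q → 0; over the
practical window q·Rg ≤ 1.3 the log-intensity of real particles is
measurably curved (for a homogeneous sphere a pure linear fit biases Rg by
about +2%, for a Gaussian coil by about −6%). `guinier_fit()` therefore
expands the window self-consistently up to the q·Rg cap (default 1.3,
exposed as a flag) and, when the window holds at least 12 points, adds a
quadratic term in q² that absorbs the leading curvature, always reporting
Rg and I(0) from the linear (q → 0) term. Noiseless sphere and coil
oracles are then recovered to well within 1%. At realistic noise the
estimator is unbiased but has a few-percent spread per curve; recovery
tests therefore assert replicate means.

P(r) is obtained by a regularized indirect Fourier transform: P(r) is
expanded in sines vanishing at 0 and Dmax, coefficients are fit to I(q)
through the kernel 4π·sinc(qr) with a curvature penalty (diagonal in the
sine basis). The penalty weight is chosen as the strongest smoothing that
keeps χ² within 10% of the best achievable on a log grid — a discrepancy
criterion that behaves sensibly at both vanishing and realistic noise.
The default basis size is ceiling(Dmax·q_max/π) + 8 (the Shannon number
plus slack). `auto_dmax()` scans candidate Dmax values (1.5–4.5 Guinier
radii in 0.05-Rg steps) and picks the smallest whose real-space Rg
matches the Guinier Rg within 2%, whose P(r) is non-negative within 2% of
its peak, and whose fit quality is within 1.5× the best over the scan —
mirroring the practice of adjusting Dmax until the transform agrees with
Guinier. For particles with a genuine maximum dimension (sphere oracle)
this recovers Dmax within ~3–5%; for coils, whose P(r) decays without a
sharp support, the reported Dmax is an effective value and only the Rg
self-consistency is meaningful.

Shape diagnostics: the Kratky transform q²I(q) plateaus for disordered
chains and peaks for globular ones; the Porod diagnostic rebins the
high-q region (default q ≥ 0.1 Å⁻¹) into geometric bins, fits local
log-log slopes over 6-bin windows, and calls "globular-like" when any
window reaches slope ≤ −3.5 (Porod's q⁻⁴ law with allowance for binning
noise); Debye coils level off near q⁻² and are called "no sharp
interface". Momentum transfer is Å⁻¹ internally; readers auto-detect
nm⁻¹ files (q extending beyond 1.5) and convert, with an override flag,
because published q ranges mix both conventions.

Expected-size references: the Flory law Rg = 2.54·N^0.522 (IDP-pool
coefficients), the globular expectation √(3/5)·4.75·N^0.29, the
denatured-chain law log10(Rg) = 0.58·log10(N) + 0.80, Rg = √(3/5)·Rs for
a globule of known Stokes radius, and the equivalent sphere at 134 Å³ per
residue.

## Ensemble stage

The ensemble stage is an explicit coarse emulation of the
pool-plus-selection workflow, not a port of any atomistic tool: chains
are Cα traces with 3.8 Å virtual bonds, bond angles drawn from a normal
distribution (default mean 120°, sd 25°, calibrated so 143-residue pools
land near the Flory IDP dimension), uniform dihedrals, and 4.0 Å
hard-sphere exclusion between beads ≥ 3 positions apart, with
rejection-and-regrow. Scattering uses the Debye sum with a Gaussian
dummy-residue form factor (σ_f = 3 Å), collapsed onto a 0.5 Å distance
histogram (exact to well below that length scale); I(0) = N². Because the
beads have finite size, a conformer's scattering Rg exceeds its
coordinate Rg by σ_f in quadrature — the tests account for this.

Selection is a genetic algorithm over multisets of conformer indices
(size 50, repetition allowed, matching the repeated-selection convention
of ensemble-optimization tools): tournament selection (size 3),
single-point crossover, 5% per-gene mutation, elitism of 2, population
100, 300 generations with a 50-generation patience window. These GA
hyperparameters are this package's defaults — the published workflow does
not state its own. The initial population is seeded with the best single
conformer replicated, which guarantees the selected ensemble never fits
worse than the best individual. Identical seeds give identical fits;
across seeds, recovered Rg distributions agree distributionally
(histogram overlap). Bimodality of the selected-ensemble Rg histogram
(2.5 Å bins) is called when two local maxima (each ≥ 10% of the tallest,
after a light 3-bin smoothing) are separated by a valley ≥ 20% below
both.

The planted-recovery experiments define what this stage demonstrates: a
target built from one pool conformer is recovered to χ² < 0.01, and a
50/50 mixture of compact (~26 Å) and expanded (~54 Å) sub-pools yields a
bimodal selected distribution with modes within 15% of the planted
component means. Pool sizes are scaled to 2,000 conformers (the tests)
and 800 (the analysis script) so the stage runs in minutes and seconds
respectively; the statistical behaviour is insensitive to this beyond
slower mixing of the GA.

## Circular dichroism

Raw differential absorbance converts to mean residue ellipticity as
Θ = 3300·M·ΔA/(l·c·n) (M in Da, l in cm, c in mg/mL, n residues).
Helicity is estimated by dividing the observed MRE at 220 nm by the
100%-helix expectation; for the latter the standard chain-length-corrected
form −40,000·(1 − 2.5/n) is adopted, with both coefficients configurable
and echoed in results — published formulas differ in coefficients and
wavelength convention (220 vs 222 nm), so per-spectrum helicity
percentages should be compared only within one convention. The RC/PMG
double-wavelength classification assigns a point to the nearest of two
reference centroids in the (MRE₂₀₀, MRE₂₂₂) plane, standardized by each
class's spread; the shipped centroids are approximate literature-scale
values (the underlying reference compilation is not redistributed), so
the classification is indicative, with near-equidistant points labelled
"boundary".

Thermal melts are fit with the four-parameter Boltzmann sigmoid
MRE(T) = A + (B − A)/(1 + exp((Tm − T)/s)) via Levenberg–Marquardt,
reporting asymptotic standard errors and a quality flag ("poor" when
R² < 0.9 or the midpoint leaves the measured range — degenerate fits of
edge transitions are common and must be surfaced, not hidden). The
isodichroic point of a spectral family is the wavelength minimizing the
across-spectra standard deviation, accepted when that minimum is below 5%
of the overall signal range; identical spectra are reported as degenerate
rather than as a detection.

## Synthetic data: what it shows and what it does not

Every generator is deterministic under its seed and embeds its truth:
sequences with prescribed composition annealed to a target κ (simulated
annealing over charge-position swaps), sphere/coil/mixture scattering
curves with Gaussian noise σ(q) = I/snr·(1 + q/q_max), exact log-linear
SEC calibrations with optional elution noise, Boltzmann melts, and
two-state CD families constructed to cross at exactly one wavelength.
Passing round trips demonstrate that the estimators are correct and
calibrated *under these models* — Gaussian noise, ideal baselines, no
instrument artifacts (radiation damage, buffer mismatch, aggregation,
smearing). They do not certify accuracy on real measurements, where those
artifacts dominate error budgets. The native ASR1 protein sequences are
not redistributed with the package; sequence-level analyses in the
bundled workflow therefore run on a clearly-labelled synthetic sequence
matching the published composition and κ, and the published per-protein
values that are pure functions of printed inputs (charge metrics, state
radii, compaction indices, expected sizes) are reproduced exactly from
those inputs.

## Known limitations

* SEG-style boundaries are unrefined (±2 residues vs canonical); counts
  are the reliable output.
* The IFT reports an effective Dmax for objects without a sharp maximum
  dimension.
* The ensemble stage is a Cα-level emulation; χ² values are comparable
  within the package only, and experimental ensemble χ² values are not
  reproducible without the measured curves.
* pI and RC/PMG classifications are convenience outputs with stated
  caveats.
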