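---
title: "Modelling the symmetry-mismatched MS-ring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the symmetry-mismatched MS-ring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msring)
```

## The modelling problem

The MS-ring at the base of the bacterial flagellum is built from 34 copies
of one protein, FliF, whose periplasmic region contains three
ring-building-motif domains (D1, D2, D3). In the assembled ring the 34
subunits split into two conformational groups: 23 copies whose D1–D2
moiety forms the inner ring of the M-ring, and 11 copies whose D1–D2
moiety, related to the first group by a hinge rotation between the two
domains, forms the middle region that surrounds it. All 34 copies
contribute their C-terminal half to a common C34 S-ring whose two vertical
β-strands per subunit stack into a 68-stranded collar. Three different
cyclic symmetries — C23, C11, C34 — therefore coexist coaxially in a
homo-oligomer, with no common angular register.

Resolving such an assembly is a hybrid-modelling exercise: a
crystal structure supplies the subunit, medium-resolution (6–9 Å) cryoEM
maps supply the symmetry and the envelope, and homologous ring structures
(the injectisome PrgK/PrgH C24 concentric double ring) supply the initial
packing hypothesis. `msring` re-implements that procedure as a tested,
deterministic pipeline:

1. **Template build** — superpose D1 of the subunit independently onto
   every member of an inner template ring, and D2 onto every member of an
   outer template ring, giving the tentative 24 + 24 = 48-subunit double
   ring (`build_tentative_double_ring()`).
2. **Symmetry detection** — measure the cyclic order of each tier from
   the map with a rotational power spectrum over the tier's own
   cylindrical shell (`detect_symmetry()`).
3. **Resymmetrization** — regenerate the inner tier at the detected
   order (24 → 23) while preserving one reference subunit's pose
   bit-for-bit (`resymmetrize()`), then rigid-fit the ring into the map.
4. **Middle region** — prune the outer tier to the 11 members closest to
   ideal equiangular positions, apply C11, average the map 11-fold, and
   refit the reference subunit's D2 against its fixed D1 by a hinge
   rotation about the domain-junction CA (`derive_middle_ring()`,
   `hinge_refit()`).
5. **Assembly and validation** — join the tiers with a C34 S-ring model
   and compute a validation report: clash count, interface crosslink
   distances, tier diameters, per-tier detected symmetry, linker reach
   and collar strand count (`assemble_msring()`, `validate_ring()`).

## The synthetic study system

Every quantitative claim in the test suite is computed on synthetic data,
because the pipeline must be verifiable without downloads. The generator
(`make_toy_subunit()`, `make_planted_ring_map()`,
`make_homolog_template_rings()`) emulates exactly the features the
pipeline's mathematics touches:

* a **two-domain subunit** in CA/CB reduction — a compact D1, a
  one-residue linker, an elongated D2 starting at the hinge pivot —
  numbered in author style from residue 58 so that the default domain
  annotations (D1 58–122, D2 123–213, pivot 123) and residue-pair checks
  (e.g. 156/200) read directly against the real protein's numbering;
* **planted Cn rings** at chosen radii with stored ground-truth operators;
* **simulated maps** at 8.6 Å (the reference map resolution here) with
  seeded Gaussian noise, parameterized either as a fraction of the map
  maximum or as an SNR — defined as the standard deviation of the
  noise-free map over its support (voxels above 10 % of the maximum)
  divided by the noise standard deviation. The study-condition default is
  SNR 1;
* **homolog template double rings** built from *different* toy subunits,
  so template superposition runs on genuinely non-identical folds.

What the toys do **not** emulate: real secondary-structure packing,
side chains, sequence realism, and physically plausible interfaces. At the
tight subunit spacing of the inner tier the toy domains interpenetrate
slightly, so the default pipeline reports a nonzero clash count and
crosslink distances far above the disulfide cutoff — the report is
faithful to the toy geometry, and the clash/crosslink machinery is tested
separately against planted geometries with known answers. Passing tests
demonstrate that the *procedure* (detection, resymmetrization, hinge
recovery, bookkeeping) is correct, not that toy models are good proteins.
Checks that require the deposited entries themselves (the crystal
structure's chain A/B RMSD of 0.694 Å, the 44 % cross-species identity,
the published ring diameters, symmetry calls on deposited maps) are coded
against files under `inst/extdata/external/` and necessarily fail in an
offline build; the corresponding functions are exercised on synthetic
equivalents instead.

## Key numerical choices

**Map simulation.** Each atom contributes an isotropic Gaussian with
FWHM equal to the nominal resolution and integral equal to its atomic
number; there is no universally agreed model-to-map kernel at 6–9 Å, and
the FWHM convention is simple and testable by closed form (the map
integral matches the summed atomic numbers to < 1 %). The Gaussian is
truncated at 4 σ for simulation (error well under 1 %) and at 2.5 σ
inside fitting loops, where only the correlation matters. The default
synthetic voxel is 2 Å — Nyquist-safe for 6–9 Å — while deposited maps
are used at their native pixel size.

**Rotational power spectrum.** Density is resampled on cylindrical rings
at voxel spacing with at least 4 × n~max~ angular samples, the angular
Fourier power is accumulated over the shell with area (radius) weighting,
and powers over folds ≥ 2 are normalized to sum to 1. A Cn map
concentrates power at multiples of n, never at divisors, so the argmax
over candidate folds is safe; the spectrum also carries the raw
(unnormalized) power so that an empty shell can be told from a structured
one. Shells are always derived per tier from the tier's own radial extent
(`tier_shell()`), preventing cross-tier mixing of the coaxial C23/C11/C34
signals. The confidence of a detection is the power ratio of the best to
the second-best candidate; below 1.5 (a deliberately conservative
default) a result is flagged ambiguous rather than returned as firm.

**Fitting.** Scoring is the Pearson correlation between the target map
and a map simulated from the posed model, over a mask of voxels within
4 Å of any atom — whole-box correlation would be dominated by empty
space. The search is deterministic: a coarse orientation grid (10° step
by default) around the start pose, then coordinate descent over three
rotation and three translation parameters with steps halved down to
0.25° / 0.1 Å. Only improving moves are accepted, so the refined score
can never drop below the start score, and a converged result has passed a
local-optimality check at the final step size. The hinge refit searches
rotations about the junction-residue CA over a coarse axis-direction ×
angle grid (45° / 10° by default) before the same descent; because the
pivot lies on the axis, linker bond geometry is preserved by
construction, and the junction CA–CA distance is still checked (≤ 4.5 Å)
and reported. Stochastic optimizers were deliberately avoided: the
original interactive fitting has no algorithmic specification, and a
grid-plus-descent search makes every acceptance quantity reproducible
bit-for-bit.

**Resymmetrization and pruning.** Re-ordering a tier preserves the
reference subunit's coordinates exactly and regenerates the other members
with fresh Cn operators; the radius is never rescaled — resymmetrizing means applying a single
C23 operation to one subunit of the 24-mer, nothing more.
Pruning 24 → 11 keeps the members nearest the ideal 11-fold angular
lattice anchored at the reference subunit — the source only says that 13
protomers were omitted, and nearest-to-ideal is the deterministic reading.

**Open registers.** Neither the azimuthal phase between the C11 middle
tier and the C23 inner ring nor that between the M-ring tiers and the
C34 S-ring is determined by anything in the data (the orders share no
common factor), so both are configuration parameters defaulting to 0° and
recorded in provenance.

**Diameters.** External/internal tier diameters are twice the
maximum/minimum heavy-atom radial distance from the tier axis, in nm.
Published "about" figures come with no definition; radial extent is
reproducible, and comparisons against such figures should allow
±1.5 nm.

**Crosslink screen.** CB–CB distances (CA for glycine) between the
configured residue pairs across adjacent inner-tier chains, compatible at
≤ 7 Å — generous to rotamer freedom at the resolutions involved, and
configurable.

**Linker reach.** The 13 residues that connect the S-ring body to the
next membrane anchor must bridge roughly 30 Å; with an extended-chain
contour of 3.63 Å per residue they can span up to 47.2 Å, so the check
passes with a wide margin — the point of reporting it is that an extended
conformation is *required*, since a folded stretch would not reach.

## Determinism and problem sizes

Every stage is deterministic given its inputs; the only randomness is the
seeded map noise and toy-subunit jitter, both driven by explicit seeds
through a local RNG that never touches the session's global state. Two
pipeline runs from the same seed produce bit-identical models and
reports, which the tests assert literally.

The test suite runs the full-size study conditions once (default subunit
of 157 residues, tiers at radii 45/70/88 Å, maps near 100³ voxels at 2 Å)
and uses a reduced configuration elsewhere (29-residue subunit, 2.5 Å
voxels) — in particular for the order-recovery sweep over inner orders
20–26 × middle orders 9–13, where each of the 35 cells regenerates its
planted maps and must return the planted pair from detection alone. The
reduced sizes were chosen as the smallest grids at which subunit spacing
stays comfortably above the simulated resolution; they are a property of
the test design, not of the method.

## Known limitations

* The hinge search reports the rotation angle; axis orientation is only
  as good as the density gradient around the hinge, and angles under ~5°
  are near the noise floor of the score surface at SNR 1.
* `cn_average()` uses trilinear resampling; on voxel-scale white noise
  the interpolation itself suppresses variance, so exact 1/n noise
  reduction holds only for band-limited noise — which is what real maps
  contain. The variance tests construct such noise explicitly.
* The mmCIF reader parses the `_atom_site` loop only — sufficient for
  coordinates plus the package's own sidecar metadata, not a general CIF
  parser (the PDB route uses the established reader from `bio3d`).
* Rigid fitting of a full ring about its own axis is azimuthally
  degenerate by symmetry; the pipeline's ring fit therefore starts from
  the resymmetrized pose and refines locally rather than searching
  globally.
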