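---
title: "molshots: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{molshots: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molshots)
options(molshots.quiet = TRUE)
```

## What the package computes

Given an mmCIF coordinate file (plain or gzipped) and, optionally, an
offline annotation JSON, `molshots` builds a fixed catalogue of nine
standardized scene types — `entry`, `assembly`, `entity`, `domain`,
`ligand`, `modres`, `bfactor`, `validation` for deposited entries
(`pdb` mode) and `plddt` for predicted models (`alphafold` mode) — and
renders each applicable scene, without a browser or GPU, into PNG
images at a ladder of resolutions, plus a caption file and a scene-state
file, with two per-entry summary files tying everything together.

The pipeline is `read_structure()` (and `expand_assembly()` where an
assembly is the context) → `load_annotations()` →
`generate_scenes()` → `canonical_rotation()` per scene →
`rasterize()` per view → `write_image_set()` / `write_summaries()`,
orchestrated by `molshots_run()`.

## Canonical orientation

A poorly chosen camera hides half the structure behind the other half.
We minimize occlusion by laying the structure flat against the screen:
let $X \in \mathbb{R}^{n\times 3}$ be the atom coordinates,
$\mu$ their centroid and

$$C = \tfrac{1}{n}\,(X-\mu)^\top (X-\mu)$$

the (population) covariance of the cloud, with eigenpairs
$(\lambda_1 \ge \lambda_2 \ge \lambda_3,\; a_1, a_2, a_3)$.  The front
view is the rotation whose rows are $a_1, a_2, a_3$: widest extent
along screen-x, second widest along screen-y, thinnest along the depth
axis.  All atoms are weighted equally (no mass weighting, hydrogens
included when present): the quantity being optimized is visual spread,
not a mechanical property.

Eigenvectors are defined only up to sign, and a naive choice would let
the stored orientation of the input flip the image.  The anti-flip rule
fixes each sign from the data itself: for axes 1 and 2 the sign makes
the third central moment (skewness) of the projected coordinates
non-negative; when the projection is numerically symmetric
($|\mathrm{skew}| < 10^{-9}$) the sign instead makes the projection of
the atom farthest from the centroid non-negative.  Axis 3 is then the
cross product $a_1 \times a_2$, which guarantees a proper rotation
($\det R = +1$) rather than a mirror.  Both rules are functions of the
point cloud only, so the canonical pose is invariant under any proper
pre-rotation of the input — the property the test suite checks over 100
random pre-rotations at $10^{-6}$ per coordinate.  We do not claim to
reproduce any particular viewer's "orient axes" output; the invariance
property is the contract.

Degenerate spectra (eigenvalue ties within $10^{-9}$ relative,
including collinear and coincident point sets) are completed
deterministically by re-picking, inside each tied eigensubspace, the
orthonormal basis closest to the world axes in x, y, z priority order.
Determinism was preferred over elegance here: ties are rare in real
structures but routine in test geometry.

The side view composes an additional +90° rotation about the screen-y
axis onto the front rotation, the top view +90° about screen-x.  The
views named in the catalogue are conventions of this package (the sense
of "side" is not externally defined).

## Scene construction choices

* **Chain palette** — a fixed cyclic palette of 14 visually distinct
  colors, assigned by chain order of appearance; `chain_palette(i)`
  is total and cyclic so any chain count is covered.
* **Highlight fading** — non-highlighted atoms are blended 65% toward
  light gray (200,200,200); highlights keep full color.
* **Ligand environment** — 5.0 Å around any ligand atom, with
  whole-residue inclusion (one qualifying atom pulls in its residue),
  the common interaction-shell convention.  Ligand atoms render as
  0.5 Å balls, environment atoms thinner (0.25 Å) and faded.
* **Putty** — per-residue mean B-factor $B$, radius
  $r(B) = 0.3 + 2.2\,(B-B_{\min})/(B_{\max}-B_{\min})$ Å on the
  backbone trace (CA / C1' / P), constant 1.0 Å when all B are equal,
  colored along a blue→red gradient.  The type applies to X-ray
  structures: the gate is the mmCIF experimental-method field when
  present, else nonzero B-factor variance, so offline inputs never
  need an API call.
* **Validation bands** — outlier count 0 → green (0,170,68), 1 →
  yellow (255,210,0), 2 → orange (255,140,0), ≥3 → red (220,30,30);
  residues without data → neutral gray (190,190,190).
* **pLDDT bands** — left-inclusive thresholds 50/70/90 with colors
  (255,125,69), (255,219,87), (101,203,243), (0,83,214); values
  outside [0,100] are an error, not a clamp, because they indicate the
  field does not hold pLDDT.
* **Views per type** — entity/domain/ligand/modres scenes render the
  front view only; entry/assembly/bfactor/validation/plddt render
  front, side and top.  The split is a package decision (which types
  get extra views is not externally specified) and is overridable via
  `views` in `run_config()`.
* **Alternate locations** — highest occupancy wins, ties broken by
  altloc id, because single-conformer rendering is the norm.
* **Assemblies** — operator expressions compose left-to-right as
  matrix products; chain copies are named
  `"{label_asym_id}-{copy index}"`, which is deterministic,
  collision-free and human-readable.  Multi-model ensembles are
  expanded from model 1 only; how operators should interact with an
  ensemble is undefined, so we chose the conservative reading and
  documented it.
* **Entity/modres context** — the preferred assembly from the
  annotations; falling back to the first assembly listed in the mmCIF,
  then to the deposited model 1, so these types degrade gracefully
  without annotation data.

## Rendering

The renderer is an orthographic z-buffered sphere-impostor rasterizer:
each atom is a sphere of its per-scene radius, projected with a scale
that fits the visible set's bounding sphere plus a 10% margin into the
frame, shaded by a single headlight (intensity
$0.35 + 0.65\,n_z$) and resolved by a per-pixel depth test.  Putty
tubes are drawn as overlapping per-residue spheres along the backbone
trace; ribbons, surfaces and cartoons are out of scope by design —
impostor spheres keep the renderer small, dependency-free and
byte-deterministic, which is what the file-contract tests need.
Perspective projection was rejected because "flat against the screen"
is exactly an orthographic notion and determinism is easier to verify.

The image is rendered once at `supersample` (default 2) times the
largest requested size, box-downsampled to that largest size, and every
smaller resolution is derived from the largest render rather than
re-rendered.  The box filter is area-weighted, so non-integer ratios
are exact too, and rounding is `floor(x + 0.5)` everywhere — fixed so a
pure-R per-pixel oracle can demand byte identity.  PNG output is
written by the package itself (8-bit RGB, filter 0, zlib via
`memCompress`), which keeps the byte-determinism contract end to end.

The PCA axis arrows are drawn in the bottom-left corner: the screen
direction of PCA axis $i$ under view rotation $R_v$ is column $i$ of
$R_v R_f^\top$ (identity in the front view, so arrow 1 is horizontal).
Arrows are clamped to the bottom-left quadrant and suppressed entirely
by `draw_axes = FALSE` (`--no-axes`).

## Annotation data

The offline annotation file is one JSON object with sections
`molecules`, `summary`, `modified_residues`, `mappings`, `validation`,
each shaped like the corresponding public per-entry API payload
(optionally wrapped under the entry id, as live responses are); the
schema ships in `inst/extdata/annotation-schema.json`.  Partial files
never fail — missing sections become empty collections — and
structure-consistency (does this chain/residue exist?) is checked at
scene-build time, where a bad segment is skipped with a warning rather
than aborting the run.  `fetch_annotations()` can read the same five
endpoint paths from a base URL or from a local directory laid out like
the endpoint tree; the test suite proves the two ingestion paths
equivalent using the directory form, and no test ever touches the
network.

## The synthetic fixture generator

`make_fixture()` states a small but complete world: helical chains
(rise 1.5 Å, twist 100°, radius 2.3 Å — elongated along z so the PCA
spectrum is non-degenerate and the canonical orientation unique) with
N/CA/C/O backbone atoms and ±0.25 Å seeded jitter; two polymer
entities when there are two or more chains; an optional 3-atom ligand
placed 3.5 Å from a chain-A residue; two selenomethionine sites; a
water entity; a 2-operator assembly (identity plus 180° about z);
B-factors ramping 10→80 per chain (pLDDT 30→98 in `alphafold` mode);
2 CATH families and 1 Pfam family; outlier counts cycling 0,1,2,3 so
color counts are exact.  A fixed spec gives byte-identical files.

What the generator does *not* emulate: real side-chain chemistry,
sequence plausibility, crystallographic disorder, large assemblies, or
the undocumented variability of live API payloads.  A green test
therefore establishes the pipeline's contracts (counts, formats,
determinism, geometry) — not visual fidelity to any existing rendering
service, which is explicitly not a goal.

## Numerical conventions and degenerate inputs

Tolerances: orthonormality and eigen-oracle agreement at $10^{-9}$;
pose invariance at $10^{-6}$ per coordinate; skewness and eigenvalue-tie
thresholds at $10^{-9}$.  Pixel centers sit at half-integer coordinates;
screen y grows downwards; depth grows toward the viewer.  Empty visible
sets render as background-only images rather than erroring, single-atom
structures are valid scenes, and an all-identical point cloud
canonicalizes to the identity rotation.  Binary CIF input is refused
with a named error instead of being mis-parsed.

## Known limitations

* The state file (`*.molj.json`) uses this package's own documented
  schema; it re-creates a `scene_spec` but is not loadable by external
  viewers.
* Sphere impostors cannot show secondary structure; domain boundaries
  read as colored stretches, not cartoons.
* Branched (oligosaccharide) entities are carried through parsing but
  receive no dedicated scene type beyond entity/ligand treatment.
* Live retrieval of coordinates and annotations exists
  (`use_api = TRUE`) but is deliberately untested and disabled by
  default.
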