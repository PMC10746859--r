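# molshots

Automated, browserless generation of standardized images of
macromolecular structures.

Structural biologists and data resources need consistent overview
images for thousands of entries: the deposited structure, each
biological assembly, each distinct molecule, domain annotations, bound
ligands with their binding site, modified residues, B-factor
flexibility, validation quality, and — for predicted models — pLDDT
confidence. Producing these by hand in an interactive viewer does not
scale. `molshots` renders all of them from the command line or from R,
fully offline, with no GPU, browser or network dependency.

## What it does

* Reads PDBx/mmCIF coordinate files (`.cif`, `.cif.gz`; gzip detected
  by magic bytes) and expands biological assemblies from their
  operator lists.
* Optionally loads per-entry annotations (entity names, preferred
  assembly, SIFTS domain mappings, modified residues, residue-wise
  validation outliers) from a single offline JSON file shaped like the
  public per-entry API payloads (`inst/extdata/annotation-schema.json`).
* Builds nine scene types — `entry`, `assembly`, `entity`, `domain`,
  `ligand`, `modres`, `bfactor`, `validation` in `pdb` mode, `plddt`
  in `alphafold` mode.
* Poses every scene with a deterministic canonical orientation: PCA of
  the atomic coordinates aligned to the screen axes
  ("flat against the screen", eigenpairs of
  C = (X−μ)ᵀ(X−μ)/n with λ₁ along screen-x), with skewness-based
  anti-flip rules so the input orientation cannot flip the image, plus
  derived side/top views and bottom-left PCA axis arrows.
* Rasterizes with a built-in z-buffered orthographic sphere renderer
  (Lambertian headlight, supersampled, byte-deterministic) and writes
  its own PNGs at a resolution ladder of 1600², 800², 200² and 100²
  pixels.
* For every image writes at least three files — PNG(s), a caption JSON
  and a reloadable scene-state JSON — plus two per-entry summaries:
  `{id}_filelist` and `{id}.json`.
* Ships a deterministic synthetic-fixture generator
  (`make_fixture()` / `molshots make-fixture`) so the entire pipeline
  runs and tests with zero downloads.

## Worked example

```r
library(molshots)

# a synthetic entry: 2 helical chains, ligand, waters, MSE sites,
# a 2-operator assembly, domains and validation data
fx  <- make_fixture(fixture_spec(seed = 42L), outdir = "demo_fixture")
st  <- read_structure(fx$mmcif)
st
#> <mol_structure 'synth1' (deposited): 85 atoms, 1 model(s), 4 chain(s), 4 entities, 1 assemblies>
ann <- load_annotations(fx$annotations)
ann
#> <annotation_set: 4 entity names, preferred assembly 1, 3 domain segments, 2 modres sites, 20 outlier records>

scenes <- generate_scenes(st, ann, mode = "pdb")
length(scenes)   # 1 entry + 1 assembly + 3 entity + 3 domain +
#> [1] 12         # 1 ligand + 1 modres + 1 bfactor + 1 validation
scenes[[11]]
#> <scene_spec 'bfactor': 20 visible atoms, 0 highlighted, views front/side/top>

res <- molshots_run(run_config("1tqn", input_path = fx$mmcif,
                               annotations_path = fx$annotations,
                               types = "bfactor", views = "front",
                               outdir = "demo_out"))
#> [molshots] wrote 1tqn_bfactor (6 files)
list.files("demo_out")
#> [1] "1tqn_bfactor_image-100x100.png"   "1tqn_bfactor_image-1600x1600.png"
#> [3] "1tqn_bfactor_image-200x200.png"   "1tqn_bfactor_image-800x800.png"
#> [5] "1tqn_bfactor.caption.json"        "1tqn_bfactor.molj.json"
#> [7] "1tqn_filelist"                    "1tqn.json"
```

The 12 scenes are the complete catalogue this fixture supports: one
per applicable type, one per assembly/entity/domain-family/ligand/
modres-component qualifier. The `bfactor` run shows the per-image file
contract — four PNG resolutions following the
`{stem}_image-{W}x{H}.png` grammar, the caption file, the state file —
and the two per-entry summary files.

Equivalent command line:

```sh
molshots make-fixture --outdir demo_fixture
molshots render 1tqn --input demo_fixture/synth1.cif \
    --annotations demo_fixture/synth1_annotations.json \
    --no-api --type bfactor --view front --outdir demo_out
```

Flags: `--input`, `--type`, `--view front|side|top|all`, `--no-axes`,
`--no-api`, `--api-url`, `--annotations`, `--mode pdb|alphafold`,
`--size WxH`, `--outdir`, `--quiet`. Without `--input` (and without
`--no-api`) coordinates are retrieved live; that network adapter is
optional and untested by design.

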