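#' @title Synthetic fixtures
#' @description
#' Deterministic generator of synthetic mmCIF entries and matching
#' annotation JSON files that exercise every scene type with zero
#' downloads.  Chains are ideal helices (rise 1.5 Angstrom, twist 100
#' degrees, radius 2.3 Angstrom) with N/CA/C/O backbone atoms, which
#' makes the PCA spectrum non-degenerate (elongated along the helix
#' axis) so the canonical orientation is unique.  B-factors ramp
#' linearly 10 to 80 along each chain (pLDDT values 30 to 98 in
#' `alphafold` mode); annotation outlier counts cycle 0,1,2,3 so exact
#' color counts can be asserted.
#' @name fixtures
NULL

HELIX_RISE <- 1.5     # Angstrom per residue
HELIX_TWIST <- 100    # degrees per residue
HELIX_RADIUS <- 2.3   # Angstrom
CHAIN_SPACING <- 12   # Angstrom between chain axes

#' Fixture specification
#'
#' @param n_chains number of polymer chains (>= 1)
#' @param residues_per_chain residues per chain (>= 1)
#' @param with_ligand include a 3-atom non-polymer entity
#' @param with_water include a water entity
#' @param with_modres model two selenomethionine (MSE) sites on chain A
#' @param with_assembly list a 2-operator assembly (identity + 180
#'   degree rotation about z)
#' @param with_outliers include per-residue validation outlier counts
#' @param mode `"pdb"` or `"alphafold"`; in `alphafold` mode the extra
#'   features default to off and the B-factor field carries pLDDT
#' @param entry_id identifier written into the files
#' @param seed integer seed for the (tiny) deterministic coordinate
#'   jitter; a fixed seed gives byte-identical outputs
#' @return a `fixture_spec` object
#' @export
fixture_spec <- function(n_chains = 2L, residues_per_chain = 10L,
                         with_ligand = mode == "pdb",
                         with_water = mode == "pdb",
                         with_modres = mode == "pdb",
                         with_assembly = mode == "pdb",
                         with_outliers = mode == "pdb",
                         mode = c("pdb", "alphafold"),
                         entry_id = if (mode == "pdb") "synth1" else "synthaf",
                         seed = 0L) {
  mode <- match.arg(mode)
  if (n_chains < 1L || residues_per_chain < 1L)
    ms_error("molshots_bad_argument", "fixture counts must be positive")
  structure(list(n_chains = as.integer(n_chains),
                 residues_per_chain = as.integer(residues_per_chain),
                 with_ligand = isTRUE(with_ligand),
                 with_water = isTRUE(with_water),
                 with_modres = isTRUE(with_modres),
                 with_assembly = isTRUE(with_assembly),
                 with_outliers = isTRUE(with_outliers),
                 mode = mode, entry_id = entry_id, seed = as.integer(seed)),
            class = "fixture_spec")
}

fixture_modres_sites <- function(nres) {
  unique(pmax(1L, c(ceiling(nres / 3), ceiling(2 * nres / 3))))
}

# Build the fixture as an in-memory mol_structure + annotation_set.
build_fixture_objects <- function(spec) {
  set.seed(spec$seed)
  nres <- spec$residues_per_chain
  chains <- LETTERS[seq_len(spec$n_chains)]
  bvals <- if (spec$mode == "pdb") {
    if (nres > 1L) seq(10, 80, length.out = nres) else 45
  } else {
    if (nres > 1L) seq(30, 98, length.out = nres) else 64
  }
  modres_sites <- if (spec$with_modres) fixture_modres_sites(nres) else integer(0)
  rows <- list()
  backbone <- c("N", "CA", "C", "O")
  elements <- c("N", "C", "C", "O")
  for (ci in seq_along(chains)) {
    # chains alternate between two sequences -> two polymer entities
    eid <- if (ci %% 2L == 1L) "1" else "2"
    base_comp <- if (eid == "1") "ALA" else "GLY"
    xoff <- (ci - 1L) * CHAIN_SPACING
    for (j in seq_len(nres)) {
      theta <- j * HELIX_TWIST * pi / 180
      ca <- c(HELIX_RADIUS * cos(theta) + xoff, HELIX_RADIUS * sin(theta),
              HELIX_RISE * j)
      comp <- if (ci == 1L && j %in% modres_sites) "MSE" else base_comp
      for (k in seq_along(backbone)) {
        jit <- stats::runif(3, -0.25, 0.25)
        pos <- ca + switch(backbone[k],
                           N = c(-0.9, 0.5, -0.6), CA = c(0, 0, 0),
                           C = c(0.9, -0.4, 0.7), O = c(1.4, 0.4, 1.2)) + jit
        rows[[length(rows) + 1L]] <- data.frame(
          model = 1L, label_asym_id = chains[ci], auth_asym_id = chains[ci],
          entity_id = eid, comp_id = comp, label_seq = j, auth_seq = j,
          ins_code = NA_character_, atom_name = backbone[k],
          element = elements[k], x = pos[1], y = pos[2], z = pos[3],
          b_factor = round(bvals[j], 2), occupancy = 1, is_hetero = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  entities <- data.frame(
    entity_id = unique(vapply(seq_along(chains),
                              function(ci) if (ci %% 2L == 1L) "1" else "2", "")),
    stringsAsFactors = FALSE)
  entities$entity_type <- "polymer"
  entities$description <- ifelse(entities$entity_id == "1",
                                 "synthetic helical protein alpha",
                                 "synthetic helical protein beta")
  lig_eid <- wat_eid <- NA_character_
  next_eid <- max(as.integer(entities$entity_id)) + 1L
  if (spec$with_ligand) {
    lig_eid <- as.character(next_eid)
    next_eid <- next_eid + 1L
    # three hetero atoms 3-4 Angstrom from the residue-2 CA of chain A
    anchor <- c(HELIX_RADIUS * cos(2 * HELIX_TWIST * pi / 180),
                HELIX_RADIUS * sin(2 * HELIX_TWIST * pi / 180), HELIX_RISE * 2)
    lig_atoms <- list(c(3.5, 0, 0), c(4.6, 0.8, 0.3), c(4.2, -1.0, -0.5))
    for (k in seq_along(lig_atoms)) {
      pos <- anchor + lig_atoms[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        model = 1L, label_asym_id = "L", auth_asym_id = "L",
        entity_id = lig_eid, comp_id = "LIG", label_seq = NA_integer_,
        auth_seq = 1L, ins_code = NA_character_,
        atom_name = paste0("C", k), element = "C", x = pos[1], y = pos[2],
        z = pos[3], b_factor = 20, occupancy = 1, is_hetero = TRUE,
        stringsAsFactors = FALSE)
    }
    entities <- rbind(entities, data.frame(
      entity_id = lig_eid, entity_type = "non-polymer",
      description = "synthetic ligand", stringsAsFactors = FALSE))
  }
  if (spec$with_water) {
    wat_eid <- as.character(next_eid)
    for (k in 1:2) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = 1L, label_asym_id = "W", auth_asym_id = "W",
        entity_id = wat_eid, comp_id = "HOH", label_seq = NA_integer_,
        auth_seq = k, ins_code = NA_character_, atom_name = "O",
        element = "O", x = -6 + 2 * k, y = 6, z = 3 * k, b_factor = 30,
        occupancy = 1, is_hetero = TRUE, stringsAsFactors = FALSE)
    }
    entities <- rbind(entities, data.frame(
      entity_id = wat_eid, entity_type = "water", description = "water",
      stringsAsFactors = FALSE))
  }
  atoms <- do.call(rbind, rows)
  assemblies <- list()
  if (spec$with_assembly) {
    all_asym <- unique(atoms$label_asym_id)
    assemblies[["1"]] <- list(
      assembly_id = "1",
      expressions = list(list(oper_seqs = list("1", "2"), asym_ids = all_asym)),
      operators = list(
        "1" = list(R = diag(3), t = c(0, 0, 0)),
        "2" = list(R = diag(c(-1, -1, 1)), t = c(0, 0, 0))))
  }
  st <- mol_structure(
    spec$entry_id, atoms, entities, assemblies,
    exptl_method = if (spec$mode == "pdb") "X-RAY DIFFRACTION" else NA_character_)

  entity_names <- stats::setNames(entities$description, entities$entity_id)
  domains <- NULL
  if (spec$n_chains >= 1L && spec$mode == "pdb") {
    half <- max(1L, nres %/% 2L)
    pfam_chain <- if (spec$n_chains >= 2L) "B" else "A"
    domains <- data.frame(
      source = c("CATH", "CATH", "Pfam"),
      family_id = c("1.10.10.10", "3.40.50.300", "PF00042"),
      chain = c("A", "A", pfam_chain),
      start_seq = c(1L, min(half + 1L, nres), 1L),
      end_seq = c(half, nres, nres),
      stringsAsFactors = FALSE)
  }
  modres <- NULL
  if (spec$with_modres) {
    modres <- data.frame(comp_id = "MSE", chain = "A",
                         auth_seq = as.integer(modres_sites),
                         stringsAsFactors = FALSE)
  }
  outliers <- NULL
  if (spec$with_outliers) {
    grid <- expand.grid(auth_seq = seq_len(nres), chain = chains,
                        stringsAsFactors = FALSE)[, c("chain", "auth_seq")]
    outliers <- data.frame(chain = grid$chain, auth_seq = grid$auth_seq,
                           outlier_count = (seq_len(nrow(grid)) - 1L) %% 4L,
                           stringsAsFactors = FALSE)
  }
  ann <- annotation_set(
    entity_names = entity_names,
    preferred_assembly_id = if (spec$with_assembly) "1" else NA_character_,
    domains = domains, modres = modres, outliers = outliers)
  list(structure = st, annotations = ann)
}

#' Generate a synthetic fixture on disk
#'
#' Writes `{entry_id}.cif` and `{entry_id}_annotations.json` into
#' `outdir`.  Output is byte-identical for a fixed spec.
#'
#' @param spec a [fixture_spec()]
#' @param outdir output directory (created if needed)
#' @param gzip also compress the mmCIF (writes `.cif.gz` instead)
#' @return list with `mmcif`, `annotations` (paths) and the in-memory
#'   `structure` and `annotation_set` objects
#' @export
make_fixture <- function(spec = fixture_spec(), outdir = tempfile("fixture"),
                         gzip = FALSE) {
  if (!inherits(spec, "fixture_spec"))
    ms_error("molshots_bad_argument", "spec must be a fixture_spec")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  obj <- build_fixture_objects(spec)
  cif_path <- file.path(outdir, paste0(spec$entry_id,
                                       if (gzip) ".cif.gz" else ".cif"))
  write_mmcif(obj$structure, cif_path)
  ann_path <- file.path(outdir, paste0(spec$entry_id, "_annotations.json"))
  save_annotations(obj$annotations, ann_path, entry_id = spec$entry_id)
  list(mmcif = cif_path, annotations = ann_path,
       structure = obj$structure, annotation_set = obj$annotations)
}
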