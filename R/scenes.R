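#' @title Scene construction
#' @description
#' A scene is a fully resolved view of a structure: the coordinate
#' context (deposited or expanded assembly), the visible atom set,
#' per-atom colors and radii, an optional highlight subset (the
#' complement is rendered faded), the canonical camera and the list of
#' views to render.  Nine scene types exist; eight apply in `pdb` mode
#' (entry, assembly, entity, domain, ligand, modres, bfactor,
#' validation) and one in `alphafold` mode (plddt).
#' @name scenes
NULL

SCENE_TYPES_PDB <- c("entry", "assembly", "entity", "domain", "ligand",
                     "modres", "bfactor", "validation")
SCENE_TYPES_ALPHAFOLD <- c("plddt")

#' Scene-type registry
#'
#' @param mode `"pdb"`, `"alphafold"`, or `"all"`
#' @return character vector of scene-type names applicable to the mode
#' @export
scene_types <- function(mode = c("all", "pdb", "alphafold")) {
  mode <- match.arg(mode)
  switch(mode,
         all = c(SCENE_TYPES_PDB, SCENE_TYPES_ALPHAFOLD),
         pdb = SCENE_TYPES_PDB,
         alphafold = SCENE_TYPES_ALPHAFOLD)
}

# Rendering constants (documented design choices, fixed for testability)
LIGAND_ENV_RADIUS <- 5.0      # Angstrom, whole-residue inclusion
POLYMER_RADIUS <- 1.6         # Angstrom, overview impostor spheres
LIGAND_BALL_RADIUS <- 0.5     # Angstrom, ligand ball style
ENV_RADIUS <- 0.25            # Angstrom, thinner environment style
PUTTY_R_MIN <- 0.3            # Angstrom
PUTTY_R_SPAN <- 2.2           # r(B) = 0.3 + 2.2 * (B - Bmin)/(Bmax - Bmin)
PUTTY_R_FLAT <- 1.0           # all-equal-B degenerate radius
FADE_FRACTION <- 0.65         # blend towards light gray for non-highlight
FADE_GRAY <- c(200L, 200L, 200L)
NEUTRAL_GRAY <- c(190L, 190L, 190L)

VALIDATION_COLORS <- list(ok = c(0L, 170L, 68L),      # 0 outliers, green
                          one = c(255L, 210L, 0L),    # 1 outlier, yellow
                          two = c(255L, 140L, 0L),    # 2 outliers, orange
                          many = c(220L, 30L, 30L))   # >=3 outliers, red

PLDDT_COLORS <- list(very_low = c(255L, 125L, 69L),   # pLDDT < 50
                     low = c(255L, 219L, 87L),        # 50 <= pLDDT < 70
                     confident = c(101L, 203L, 243L), # 70 <= pLDDT < 90
                     very_high = c(0L, 83L, 214L))    # pLDDT >= 90

# 14 visually distinct colors (ColorBrewer-like), cycled by chain index.
CHAIN_PALETTE <- matrix(as.integer(c(
  0x4C, 0x78, 0xA8,   0xF5, 0x85, 0x18,   0x54, 0xA2, 0x4B,
  0xE4, 0x57, 0x56,   0x72, 0xB7, 0xB2,   0xEE, 0xCA, 0x3B,
  0xB2, 0x79, 0xA2,   0xFF, 0x9D, 0xA6,   0x9D, 0x75, 0x5D,
  0xBA, 0xB0, 0xAC,   0x1B, 0x9E, 0x77,   0x7B, 0x52, 0xAE,
  0xD9, 0x5F, 0x02,   0x66, 0x66, 0x66)), ncol = 3, byrow = TRUE)

#' Chain palette color
#'
#' Deterministic cyclic palette of 14 visually distinct colors;
#' `chain_palette(i) == chain_palette(i %% 14)`.
#'
#' @param index 0-based non-negative integer index
#' @return integer RGB vector of length 3 (0-255)
#' @export
chain_palette <- function(index) {
  if (any(index < 0)) ms_error("molshots_bad_argument",
                               "chain_palette index must be non-negative")
  CHAIN_PALETTE[(index %% nrow(CHAIN_PALETTE)) + 1L, ]
}

fade_color <- function(rgb_mat) {
  out <- round((1 - FADE_FRACTION) * rgb_mat +
               FADE_FRACTION * matrix(FADE_GRAY, nrow(rgb_mat), 3, byrow = TRUE))
  storage.mode(out) <- "integer"
  out
}

# Linear blue-to-red gradient for the putty B-factor coloring.
bfactor_gradient <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  cbind(as.integer(round(40 + t * (215 - 0))),
        as.integer(round(60 + t * -20)),
        as.integer(round(230 - t * 200)))
}

new_scene <- function(scene_type, qualifier, structure, visible, colors,
                      radii, highlight = integer(0), views = "front",
                      caption = "") {
  visible <- sort(unique(as.integer(visible)))
  highlight <- sort(unique(as.integer(highlight)))
  if (!all(highlight %in% visible))
    ms_error("molshots_invalid_scene", "highlight set must be within visible set")
  n <- nrow(structure$atoms)
  if (length(radii) != n || nrow(colors) != n)
    ms_error("molshots_invalid_scene", "colors/radii must cover every atom")
  if (any(!is.finite(radii[visible])) || any(radii[visible] <= 0))
    ms_error("molshots_invalid_scene", "visible atoms must have positive radii")
  camera_front <- if (length(visible) == 0L) diag(3) else
    canonical_rotation(coords(structure)[visible, , drop = FALSE])
  structure(list(scene_type = scene_type, qualifier = qualifier,
                 structure = structure, visible = visible,
                 colors = colors, radii = radii, highlight = highlight,
                 camera_front = camera_front, views = views,
                 caption = caption),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec '%s'%s: %d visible atoms, %d highlighted, views %s>\n",
              x$scene_type,
              if (nzchar(x$qualifier)) paste0(" [", x$qualifier, "]") else "",
              length(x$visible), length(x$highlight),
              paste(x$views, collapse = "/")))
  invisible(x)
}

# Per-atom chain colors (palette keyed on chain order of appearance).
chain_colors <- function(atoms) {
  chains <- unique(atoms$label_asym_id)
  idx <- match(atoms$label_asym_id, chains) - 1L
  t(vapply(idx, chain_palette, integer(3)))
}

entity_label <- function(structure, annotations, entity_id) {
  key <- as.character(entity_id)
  if (key %in% names(annotations$entity_names)) {
    nm <- annotations$entity_names[[key]]
    if (nzchar(nm)) return(nm)
  }
  d <- structure$entities$description[structure$entities$entity_id == entity_id]
  if (length(d) == 1L && nzchar(d)) d else paste("entity", entity_id)
}

# Coordinate context for entity/modres scenes: the preferred assembly
# when known, else the first assembly listed in the mmCIF, else the
# deposited structure (model 1).
preferred_context <- function(structure, annotations) {
  aid <- annotations$preferred_assembly_id
  if (!is.na(aid) && aid %in% names(structure$assemblies))
    return(expand_assembly(structure, aid))
  if (length(structure$assemblies) > 0L)
    return(expand_assembly(structure, names(structure$assemblies)[1]))
  model1(select_deposited(structure))
}

model1 <- function(structure) {
  m1 <- min(structure$atoms$model)
  atoms <- structure$atoms[structure$atoms$model == m1, , drop = FALSE]
  rownames(atoms) <- NULL
  mol_structure(structure$entry_id, atoms, structure$entities,
                structure$assemblies, exptl_method = structure$exptl_method,
                view_label = structure$view_label)
}

#' Entry scene: the complete deposited structure
#'
#' All atoms of all models, colored by chain; ensembles show every
#' model.  Rendered in front, side and top views.
#'
#' @param structure a `mol_structure`
#' @return a `scene_spec`
#' @export
build_entry <- function(structure) {
  st <- select_deposited(structure)
  a <- st$atoms
  new_scene("entry", "", st, seq_len(nrow(a)), chain_colors(a),
            rep(POLYMER_RADIUS, nrow(a)),
            views = c("front", "side", "top"),
            caption = sprintf(
              "The deposited structure of entry %s, coloured by chains.%s",
              st$entry_id,
              if (length(unique(a$model)) > 1L)
                sprintf(" All %d models of the ensemble are shown.",
                        length(unique(a$model))) else ""))
}

#' Assembly scene: one biological assembly
#'
#' Expands the assembly operators and colors each chain copy with a
#' distinct palette color.  Rendered in front, side and top views.
#'
#' @param structure a `mol_structure`
#' @param assembly_id assembly id listed in the mmCIF
#' @return a `scene_spec`
#' @export
build_assembly <- function(structure, assembly_id) {
  st <- expand_assembly(structure, assembly_id)
  a <- st$atoms
  new_scene("assembly", as.character(assembly_id), st, seq_len(nrow(a)),
            chain_colors(a), rep(POLYMER_RADIUS, nrow(a)),
            views = c("front", "side", "top"),
            caption = sprintf(
              "Biological assembly %s of entry %s, coloured by chains.",
              assembly_id, st$entry_id))
}

#' Entity scene: one chemically distinct molecule highlighted
#'
#' Shows the preferred assembly (falling back to the first assembly,
#' then the deposited structure) with the atoms of one entity
#' highlighted and everything else faded.  The water entity is not a
#' valid target.
#'
#' @param structure a `mol_structure`
#' @param annotations an `annotation_set`
#' @param entity_id entity to highlight
#' @return a `scene_spec`
#' @export
build_entity <- function(structure, annotations, entity_id) {
  ent <- structure$entities[structure$entities$entity_id == entity_id, ]
  if (nrow(ent) == 0L)
    ms_error("molshots_unknown_entity", sprintf("unknown entity '%s'", entity_id))
  if (ent$entity_type == "water")
    ms_error("molshots_water_entity",
             "the water entity is excluded from entity scenes")
  st <- preferred_context(structure, annotations)
  a <- st$atoms
  cols <- chain_colors(a)
  hi <- which(a$entity_id == entity_id)
  cols[setdiff(seq_len(nrow(a)), hi), ] <-
    fade_color(cols[setdiff(seq_len(nrow(a)), hi), , drop = FALSE])
  new_scene("entity", as.character(entity_id), st, seq_len(nrow(a)), cols,
            rep(POLYMER_RADIUS, nrow(a)), highlight = hi,
            caption = sprintf("Entry %s with %s (entity %s) highlighted.",
                              st$entry_id,
                              entity_label(structure, annotations, entity_id),
                              entity_id))
}

#' Domain scenes: SIFTS family mappings highlighted
#'
#' One scene per distinct (source, family) pair among the CATH, SCOP,
#' Pfam and Rfam mappings; all segments of the family are highlighted in
#' distinct per-segment shades on the deposited structure.  Segments
#' addressing a missing chain or residue range are skipped with a
#' warning.
#'
#' @param structure a `mol_structure`
#' @param annotations an `annotation_set`
#' @return list of `scene_spec` (empty when no mappings)
#' @export
build_domain <- function(structure, annotations) {
  dm <- annotations$domains
  if (nrow(dm) == 0L) return(list())
  st <- model1(select_deposited(structure))
  a <- st$atoms
  fams <- unique(dm[, c("source", "family_id")])
  fams <- fams[order(fams$source, fams$family_id), , drop = FALSE]
  scenes <- list()
  for (i in seq_len(nrow(fams))) {
    segs <- dm[dm$source == fams$source[i] & dm$family_id == fams$family_id[i], ,
               drop = FALSE]
    cols <- fade_color(chain_colors(a))
    hi <- integer(0)
    kept <- 0L
    for (s in seq_len(nrow(segs))) {
      in_seg <- which(a$auth_asym_id == segs$chain[s] &
                      a$auth_seq >= segs$start_seq[s] &
                      a$auth_seq <= segs$end_seq[s])
      if (length(in_seg) == 0L) {
        warning(sprintf("domain segment %s %s %s:%d-%d matches no residues; skipped",
                        segs$source[s], segs$family_id[s], segs$chain[s],
                        segs$start_seq[s], segs$end_seq[s]), call. = FALSE)
        next
      }
      kept <- kept + 1L
      cols[in_seg, ] <- matrix(chain_palette(s - 1L), length(in_seg), 3,
                               byrow = TRUE)
      hi <- c(hi, in_seg)
    }
    if (kept == 0L) next
    scenes[[length(scenes) + 1L]] <- new_scene(
      "domain", paste0(tolower(fams$source[i]), "-", fams$family_id[i]),
      st, seq_len(nrow(a)), cols, rep(POLYMER_RADIUS, nrow(a)),
      highlight = hi,
      caption = sprintf("Entry %s with the %s family %s highlighted (%d segment%s).",
                        st$entry_id, fams$source[i], fams$family_id[i], kept,
                        if (kept == 1L) "" else "s"))
  }
  scenes
}

#' Ligand scene: a non-polymer entity and its surroundings
#'
#' The ligand (every copy of the entity) is drawn as full-color balls;
#' any residue with an atom within 5 Angstrom of any ligand atom joins
#' the environment, drawn thinner and semi-faded.  Water is excluded.
#'
#' @param structure a `mol_structure`
#' @param annotations an `annotation_set`
#' @param entity_id the non-polymer entity
#' @return a `scene_spec`
#' @export
build_ligand <- function(structure, annotations, entity_id) {
  ent <- structure$entities[structure$entities$entity_id == entity_id, ]
  if (nrow(ent) == 0L || ent$entity_type != "non-polymer")
    ms_error("molshots_unknown_entity",
             sprintf("'%s' is not a non-polymer entity", entity_id))
  st <- model1(select_deposited(structure))
  a <- st$atoms
  lig <- which(a$entity_id == entity_id)
  if (length(lig) == 0L)
    ms_error("molshots_unknown_entity",
             sprintf("entity '%s' has no atoms in model 1", entity_id))
  xyz <- coords(st)
  other <- setdiff(seq_len(nrow(a)), lig)
  # distance of every non-ligand atom to the nearest ligand atom
  near <- rep(FALSE, nrow(a))
  for (i in lig) {
    d2 <- (xyz[other, 1] - xyz[i, 1])^2 + (xyz[other, 2] - xyz[i, 2])^2 +
          (xyz[other, 3] - xyz[i, 3])^2
    near[other[d2 <= LIGAND_ENV_RADIUS^2]] <- TRUE
  }
  # whole-residue inclusion
  res_key <- paste(a$label_asym_id, a$auth_seq,
                   ifelse(is.na(a$ins_code), "", a$ins_code))
  env <- which(res_key %in% unique(res_key[near]))
  env <- setdiff(env, lig)
  visible <- c(lig, env)
  cols <- chain_colors(a)
  cols[env, ] <- fade_color(cols[env, , drop = FALSE])
  radii <- rep(POLYMER_RADIUS, nrow(a))
  radii[lig] <- LIGAND_BALL_RADIUS
  radii[env] <- ENV_RADIUS
  new_scene("ligand", as.character(entity_id), st, visible, cols, radii,
            highlight = lig,
            caption = sprintf(
              "Ligand %s (entity %s) of entry %s and its surroundings within %.1f angstrom.",
              entity_label(structure, annotations, entity_id), entity_id,
              st$entry_id, LIGAND_ENV_RADIUS))
}

#' Modified-residue scenes
#'
#' One scene per distinct modified-residue component, with every
#' instance of that component highlighted on the preferred assembly.
#' Annotation sites that do not resolve to structure residues are
#' skipped with a warning.
#'
#' @param structure a `mol_structure`
#' @param annotations an `annotation_set`
#' @return list of `scene_spec`
#' @export
build_modres <- function(structure, annotations) {
  mr <- annotations$modres
  if (nrow(mr) == 0L) return(list())
  st <- preferred_context(structure, annotations)
  a <- st$atoms
  # assembly copies suffix the auth chain id; match on the base id
  base_chain <- sub("-[0-9]+$", "", a$auth_asym_id)
  comps <- sort(unique(mr$comp_id))
  scenes <- list()
  for (comp in comps) {
    sites <- mr[mr$comp_id == comp, , drop = FALSE]
    hi <- integer(0)
    for (s in seq_len(nrow(sites))) {
      at <- which(base_chain == sites$chain[s] & a$auth_seq == sites$auth_seq[s] &
                  a$comp_id == comp)
      if (length(at) == 0L) {
        warning(sprintf("modified-residue site %s %s:%d not found; skipped",
                        comp, sites$chain[s], sites$auth_seq[s]), call. = FALSE)
        next
      }
      hi <- c(hi, at)
    }
    if (length(hi) == 0L) next
    cols <- chain_colors(a)
    non_hi <- setdiff(seq_len(nrow(a)), hi)
    cols[non_hi, ] <- fade_color(cols[non_hi, , drop = FALSE])
    scenes[[length(scenes) + 1L]] <- new_scene(
      "modres", comp, st, seq_len(nrow(a)), cols,
      rep(POLYMER_RADIUS, nrow(a)), highlight = hi,
      caption = sprintf(
        "Entry %s with all instances of the modified residue %s highlighted.",
        st$entry_id, comp))
  }
  scenes
}

# Backbone-trace atoms used by the putty and coloring-by-residue scenes.
trace_indices <- function(atoms) {
  tr <- which(atoms$atom_name %in% c("CA", "C1'", "P"))
  if (length(tr) == 0L) seq_len(nrow(atoms)) else tr
}

residue_means <- function(atoms, values, idx) {
  key <- paste(atoms$label_asym_id, atoms$auth_seq,
               ifelse(is.na(atoms$ins_code), "", atoms$ins_code))
  means <- tapply(values, key, mean)
  as.numeric(means[key[idx]])
}

#' B-factor putty scene
#'
#' The deposited structure in putty representation: each backbone-trace
#' sphere takes its radius and color from the residue's mean B-factor,
#' radius `0.3 + 2.2 * (B - Bmin)/(Bmax - Bmin)` Angstrom (constant
#' 1.0 Angstrom when all B are equal), colored along a blue-to-red
#' gradient.  Applies to X-ray structures: gated on the mmCIF
#' experimental-method field when present, else on B-factor variance.
#' Returns `NULL` as a skip signal when inapplicable.
#'
#' @param structure a `mol_structure`
#' @return a `scene_spec`, or `NULL` when the type does not apply
#' @export
build_bfactor <- function(structure) {
  meth <- structure$exptl_method
  if (!is.na(meth)) {
    if (!grepl("X-RAY", toupper(meth), fixed = TRUE)) {
      ms_log("skipping 'bfactor': experimental method is not X-ray (", meth, ")")
      return(NULL)
    }
  } else if (var(structure$atoms$b_factor) == 0) {
    ms_log("skipping 'bfactor': no usable B-factor variation")
    return(NULL)
  }
  st <- model1(select_deposited(structure))
  a <- st$atoms
  idx <- trace_indices(a)
  resb <- residue_means(a, a$b_factor, idx)
  bmin <- min(resb); bmax <- max(resb)
  if (bmax > bmin) {
    t <- (resb - bmin) / (bmax - bmin)
    radii_idx <- PUTTY_R_MIN + PUTTY_R_SPAN * t
  } else {
    t <- rep(0.5, length(resb))
    radii_idx <- rep(PUTTY_R_FLAT, length(resb))
  }
  cols <- matrix(NEUTRAL_GRAY, nrow(a), 3, byrow = TRUE)
  cols[idx, ] <- bfactor_gradient(t)
  radii <- rep(POLYMER_RADIUS, nrow(a))
  radii[idx] <- radii_idx
  new_scene("bfactor", "", st, idx, cols, radii,
            views = c("front", "side", "top"),
            caption = sprintf(
              "Entry %s in putty representation, colour-coded by B-factor (%.1f-%.1f angstrom squared).",
              st$entry_id, bmin, bmax))
}

#' Validation scene: per-residue outlier coloring
#'
#' Colors each residue by its geometric-outlier count: 0 green, 1
#' yellow, 2 orange, >=3 red; residues absent from the validation data
#' are neutral gray.  Returns `NULL` as a skip signal when no outlier
#' data is available.
#'
#' @param structure a `mol_structure`
#' @param annotations an `annotation_set`
#' @return a `scene_spec`, or `NULL`
#' @export
build_validation <- function(structure, annotations) {
  ol <- annotations$outliers
  if (nrow(ol) == 0L) {
    ms_log("skipping 'validation': no residue-wise outlier data")
    return(NULL)
  }
  st <- model1(select_deposited(structure))
  a <- st$atoms
  key <- paste(a$auth_asym_id, a$auth_seq)
  okey <- paste(ol$chain, ol$auth_seq)
  counts <- ol$outlier_count[match(key, okey)]
  cols <- t(vapply(counts, function(k) {
    if (is.na(k)) NEUTRAL_GRAY
    else if (k == 0L) VALIDATION_COLORS$ok
    else if (k == 1L) VALIDATION_COLORS$one
    else if (k == 2L) VALIDATION_COLORS$two
    else VALIDATION_COLORS$many
  }, integer(3)))
  new_scene("validation", "", st, seq_len(nrow(a)), cols,
            rep(POLYMER_RADIUS, nrow(a)),
            views = c("front", "side", "top"),
            caption = sprintf(
              "Entry %s colour-coded by residue-wise structure quality (green: no outliers; red: 3 or more).",
              st$entry_id))
}

#' pLDDT scene for predicted models
#'
#' Colors each residue by the pLDDT confidence stored in the B-factor
#' field, with left-inclusive bands: below 50 very low (orange), 50-70
#' low (yellow), 70-90 confident (light blue), 90 and above very high
#' (blue).  Values outside `[0, 100]` are an error.
#'
#' @param structure a `mol_structure`
#' @return a `scene_spec`
#' @export
build_plddt <- function(structure) {
  st <- model1(select_deposited(structure))
  a <- st$atoms
  if (any(a$b_factor < 0 | a$b_factor > 100))
    ms_error("molshots_bad_plddt", "pLDDT values must lie in [0, 100]")
  res_plddt <- residue_means(a, a$b_factor, seq_len(nrow(a)))
  cols <- t(vapply(res_plddt, function(p) {
    if (p < 50) PLDDT_COLORS$very_low
    else if (p < 70) PLDDT_COLORS$low
    else if (p < 90) PLDDT_COLORS$confident
    else PLDDT_COLORS$very_high
  }, integer(3)))
  new_scene("plddt", "", st, seq_len(nrow(a)), cols,
            rep(POLYMER_RADIUS, nrow(a)),
            views = c("front", "side", "top"),
            caption = sprintf(
              "Predicted structure %s colour-coded by per-residue pLDDT confidence.",
              st$entry_id))
}

#' Generate all applicable scenes
#'
#' Dispatches to the per-type builders.  Types inapplicable to the data
#' (no assemblies, no usable B-factors, no outlier data, ...) are
#' silently skipped with a logged reason; a requested type that is
#' inapplicable to the *mode* is an error.  The output order is the
#' registry order of the types, then lexicographic by qualifier.
#'
#' @param structure a `mol_structure`
#' @param annotations an `annotation_set`
#' @param mode `"pdb"` or `"alphafold"`
#' @param requested_types `"all"` or a character subset of the types
#'   applicable to the mode
#' @return list of `scene_spec`
#' @export
generate_scenes <- function(structure, annotations = empty_annotations(),
                            mode = c("pdb", "alphafold"),
                            requested_types = "all") {
  mode <- match.arg(mode)
  applicable <- scene_types(mode)
  if (identical(requested_types, "all")) {
    types <- applicable
  } else {
    bad <- setdiff(requested_types, applicable)
    if (length(bad) > 0L)
      ms_error("molshots_type_not_applicable",
               sprintf("type%s %s not applicable to mode '%s'",
                       if (length(bad) > 1L) "s" else "",
                       paste(sQuote(bad), collapse = ", "), mode))
    types <- applicable[applicable %in% requested_types]
  }
  scenes <- list()
  add <- function(x) {
    if (is.null(x)) return(invisible(NULL))
    if (inherits(x, "scene_spec")) x <- list(x)
    scenes[seq_along(x) + length(scenes)] <<- x
    invisible(NULL)
  }
  for (type in types) {
    switch(type,
      entry = add(build_entry(structure)),
      assembly = {
        for (aid in names(structure$assemblies))
          add(build_assembly(structure, aid))
        if (length(structure$assemblies) == 0L)
          ms_log("skipping 'assembly': no assemblies listed in the mmCIF")
      },
      entity = {
        ents <- structure$entities
        ents <- ents[ents$entity_type != "water", , drop = FALSE]
        ents <- ents[order(ents$entity_id), , drop = FALSE]
        for (eid in ents$entity_id)
          add(build_entity(structure, annotations, eid))
      },
      domain = add(build_domain(structure, annotations)),
      ligand = {
        ents <- structure$entities
        ents <- ents[ents$entity_type == "non-polymer", , drop = FALSE]
        ents <- ents[order(ents$entity_id), , drop = FALSE]
        for (eid in ents$entity_id)
          add(build_ligand(structure, annotations, eid))
        if (nrow(ents) == 0L)
          ms_log("skipping 'ligand': no non-polymer entities")
      },
      modres = add(build_modres(structure, annotations)),
      bfactor = add(build_bfactor(structure)),
      validation = add(build_validation(structure, annotations)),
      plddt = add(build_plddt(structure)))
  }
  scenes
}
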