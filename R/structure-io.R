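#' @title Structure model and mmCIF input
#' @description
#' A parsed structure is held as a flat atom table (one row per atom)
#' plus entity and assembly metadata, the representation used by most R
#' structural-biology packages.  Only the mmCIF categories needed for
#' image generation are read: `atom_site`, `entity`,
#' `pdbx_struct_assembly_gen`, `pdbx_struct_oper_list`, and a minimal
#' header (`entry.id`, `exptl.method`).
#' @name structure-io
NULL

# ---------------------------------------------------------------------------
# mmCIF tokenizer
#
# Supports the subset of CIF syntax that PDB-style mmCIF files use:
# whitespace-separated tokens, single/double-quoted strings, `#`
# comments, `loop_` tables and semicolon-delimited multi-line values.

cif_tokenize_line <- function(line) {
  n <- nchar(line)
  if (n == 0L) return(character(0))
  toks <- character(0)
  i <- 1L
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch == "'" || ch == '"') {
      q <- ch
      j <- i + 1L
      # closing quote must be followed by whitespace or end-of-line
      while (j <= n) {
        if (chars[j] == q && (j == n || chars[j + 1L] %in% c(" ", "\t"))) break
        j <- j + 1L
      }
      if (j > n) ms_error("molshots_cif_syntax_error",
                          "unterminated quoted string in CIF input")
      toks <- c(toks, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !(chars[j] %in% c(" ", "\t"))) j <- j + 1L
      toks <- c(toks, substr(line, i, j - 1L))
      i <- j
    }
  }
  toks
}

# Parse CIF text into a list of category tables (named list of
# character-vector columns).  `wanted` limits which categories are kept.
cif_parse <- function(lines, wanted = NULL) {
  cats <- list()
  nl <- length(lines)
  li <- 1L

  add_value <- function(cat, item, value) {
    if (!is.null(wanted) && !(cat %in% wanted)) return(invisible(NULL))
    if (is.null(cats[[cat]])) cats[[cat]] <<- list()
    cats[[cat]][[item]] <<- c(cats[[cat]][[item]], value)
    invisible(NULL)
  }

  read_semicolon_text <- function() {
    # `li` points at the line beginning with ';'
    first <- sub("^;", "", lines[li])
    buf <- character(0)
    li <<- li + 1L
    while (li <= nl && !startsWith(lines[li], ";")) {
      buf <- c(buf, lines[li])
      li <<- li + 1L
    }
    if (li > nl) ms_error("molshots_cif_syntax_error",
                          "unterminated semicolon text block in CIF input")
    li <<- li + 1L
    paste(c(first, buf), collapse = "\n")
  }

  while (li <= nl) {
    line <- lines[li]
    toks <- cif_tokenize_line(line)
    if (length(toks) == 0L) { li <- li + 1L; next }
    t1 <- toks[1]
    if (startsWith(t1, "data_") || t1 == "stop_" || startsWith(t1, "global_")) {
      li <- li + 1L
      next
    }
    if (t1 == "loop_") {
      li <- li + 1L
      tags <- character(0)
      while (li <= nl) {
        tl <- cif_tokenize_line(lines[li])
        if (length(tl) >= 1L && startsWith(tl[1], "_")) {
          tags <- c(tags, tl[1])
          li <- li + 1L
        } else break
      }
      if (length(tags) == 0L)
        ms_error("molshots_cif_syntax_error", "loop_ without item tags")
      parts <- strsplit(sub("^_", "", tags), ".", fixed = TRUE)
      cat_name <- parts[[1]][1]
      items <- vapply(parts, function(p) paste(p[-1], collapse = "."), "")
      keep <- is.null(wanted) || cat_name %in% wanted
      vals <- character(0)
      while (li <= nl) {
        l2 <- lines[li]
        if (startsWith(l2, ";")) {
          vals <- c(vals, read_semicolon_text())
          next
        }
        tl <- cif_tokenize_line(l2)
        if (length(tl) == 0L) { li <- li + 1L; next }
        if (startsWith(tl[1], "_") || tl[1] %in% c("loop_", "stop_") ||
            startsWith(tl[1], "data_")) break
        vals <- c(vals, tl)
        li <- li + 1L
      }
      if (keep) {
        ncol <- length(items)
        if (length(vals) %% ncol != 0L)
          ms_error("molshots_cif_syntax_error", sprintf(
            "loop_ for category '%s' has %d values, not a multiple of %d columns",
            cat_name, length(vals), ncol))
        if (is.null(cats[[cat_name]])) cats[[cat_name]] <- list()
        for (k in seq_len(ncol)) {
          col <- vals[seq(k, length(vals), by = ncol)]
          cats[[cat_name]][[items[k]]] <- c(cats[[cat_name]][[items[k]]], col)
        }
      }
      next
    }
    if (startsWith(t1, "_")) {
      parts <- strsplit(sub("^_", "", t1), ".", fixed = TRUE)[[1]]
      cat_name <- parts[1]
      item <- paste(parts[-1], collapse = ".")
      if (length(toks) >= 2L) {
        add_value(cat_name, item, toks[2])
        li <- li + 1L
      } else {
        li <- li + 1L
        if (li > nl) ms_error("molshots_cif_syntax_error",
                              sprintf("item '%s' has no value", t1))
        if (startsWith(lines[li], ";")) {
          add_value(cat_name, item, read_semicolon_text())
        } else {
          tl <- cif_tokenize_line(lines[li])
          if (length(tl) == 0L || startsWith(tl[1], "_"))
            ms_error("molshots_cif_syntax_error",
                     sprintf("item '%s' has no value", t1))
          add_value(cat_name, item, tl[1])
          li <- li + 1L
        }
      }
      next
    }
    ms_error("molshots_cif_syntax_error",
             sprintf("unexpected token '%s' at line %d", t1, li))
  }
  lapply(cats, function(cols) {
    nmax <- max(vapply(cols, length, 0L))
    as.data.frame(lapply(cols, function(v) {
      length(v) <- nmax
      v
    }), stringsAsFactors = FALSE, check.names = FALSE)
  })
}

cif_na <- function(x) ifelse(is.na(x) | x == "." | x == "?", NA_character_, x)

# ---------------------------------------------------------------------------
# Structure constructor and invariants

#' Construct a structure object
#'
#' Low-level constructor used by [read_structure()] and the fixture
#' generator.  `atoms` must have the columns listed below; invariants
#' (finite coordinates, occupancy range, entity resolution, at least one
#' model) are checked.
#'
#' @param entry_id entry identifier (lower-case PDB-style id or any label)
#' @param atoms data.frame with columns `model`, `label_asym_id`,
#'   `auth_asym_id`, `entity_id`, `comp_id`, `label_seq` (integer, may be
#'   `NA`), `auth_seq` (integer), `ins_code` (may be `NA`), `atom_name`,
#'   `element`, `x`, `y`, `z`, `b_factor`, `occupancy`, `is_hetero`
#' @param entities data.frame with columns `entity_id`, `entity_type`
#'   (one of `polymer`, `non-polymer`, `branched`, `water`), `description`
#' @param assemblies named list of assembly definitions as returned by
#'   the parser: each has `assembly_id`, `expressions` (list of
#'   `list(oper_seqs, asym_ids)`), and `operators` (named list of
#'   `list(R, t)`)
#' @param exptl_method experimental method string or `NA`
#' @param view_label label of the coordinate set ("deposited" by default)
#' @return an object of class `mol_structure`
#' @export
mol_structure <- function(entry_id, atoms, entities,
                          assemblies = list(), exptl_method = NA_character_,
                          view_label = "deposited") {
  required <- c("model", "label_asym_id", "auth_asym_id", "entity_id",
                "comp_id", "label_seq", "auth_seq", "ins_code", "atom_name",
                "element", "x", "y", "z", "b_factor", "occupancy", "is_hetero")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L)
    ms_error("molshots_invalid_structure",
             paste("atom table lacks columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(atoms) == 0L)
    ms_error("molshots_no_coordinates", "structure contains no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    ms_error("molshots_invalid_structure", "non-finite atom coordinates")
  if (!all(atoms$occupancy >= 0 & atoms$occupancy <= 1))
    ms_error("molshots_invalid_structure", "occupancy outside [0,1]")
  if (length(unique(atoms$model)) < 1L)
    ms_error("molshots_invalid_structure", "structure must have at least one model")
  unresolved <- setdiff(unique(atoms$entity_id), entities$entity_id)
  if (length(unresolved) > 0L)
    ms_error("molshots_invalid_structure",
             paste("chains reference unknown entities:",
                   paste(unresolved, collapse = ", ")))
  if (!all(entities$entity_type %in% c("polymer", "non-polymer", "branched", "water")))
    ms_error("molshots_invalid_structure", "invalid entity_type")
  for (asm in assemblies) {
    refs <- unique(unlist(lapply(asm$expressions, function(e) unlist(e$oper_seqs))))
    if (!all(refs %in% names(asm$operators)))
      ms_error("molshots_invalid_structure",
               sprintf("assembly '%s' references undefined operators", asm$assembly_id))
    for (op in asm$operators) {
      if (abs(abs(det(op$R)) - 1) > 1e-6)
        ms_error("molshots_invalid_structure",
                 sprintf("assembly '%s' operator rotation is not orthogonal",
                         asm$assembly_id))
    }
  }
  structure(list(entry_id = entry_id, atoms = atoms, entities = entities,
                 assemblies = assemblies, exptl_method = exptl_method,
                 view_label = view_label),
            class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("<mol_structure '%s' (%s): %d atoms, %d model(s), %d chain(s), %d entities, %d assemblies>\n",
              x$entry_id, x$view_label, nrow(x$atoms),
              length(unique(x$atoms$model)),
              length(unique(x$atoms$label_asym_id[x$atoms$model == min(x$atoms$model)])),
              nrow(x$entities), length(x$assemblies)))
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param structure a `mol_structure`
#' @return numeric matrix with columns x, y, z (one row per atom)
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

# ---------------------------------------------------------------------------
# read_structure

#' Read a PDBx/mmCIF file
#'
#' Parses a plain or GZIP-compressed mmCIF file into a [mol_structure()].
#' GZIP is detected from the magic bytes (`1f 8b`), not the extension.
#' Binary CIF (`.bcif`) is refused with a clear error rather than
#' mis-parsed.  When several alternate locations exist for an atom, the
#' highest-occupancy conformer is kept (ties broken by altloc id).
#'
#' @param path path to a `.cif` or `.cif.gz` file
#' @return a `mol_structure`
#' @export
read_structure <- function(path) {
  if (!file.exists(path))
    ms_error("molshots_missing_file", sprintf("input file not found: %s", path))
  if (grepl("\\.bcif(\\.gz)?$", path))
    ms_error("molshots_unsupported_format",
             "binary CIF (.bcif) is an unsupported format; supply .cif or .cif.gz")
  magic <- readBin(path, "raw", n = 2L)
  lines <- if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    readLines(con, warn = FALSE)
  } else {
    readLines(path, warn = FALSE)
  }
  parse_structure_text(lines, default_id = sub("\\.cif(\\.gz)?$", "", basename(path)))
}

parse_structure_text <- function(lines, default_id = "entry") {
  cats <- cif_parse(lines, wanted = c(
    "atom_site", "entity", "entry", "exptl",
    "pdbx_struct_assembly_gen", "pdbx_struct_oper_list"))
  as <- cats[["atom_site"]]
  if (is.null(as) || nrow(as) == 0L)
    ms_error("molshots_no_coordinates", "no coordinates: mmCIF has no atom_site category")

  get_col <- function(df, name, default = NA_character_) {
    if (!is.null(df) && name %in% names(df)) cif_na(df[[name]])
    else rep(default, nrow(df))
  }
  n <- nrow(as)
  atoms <- data.frame(
    model = as.integer(get_col(as, "pdbx_PDB_model_num", "1")),
    label_asym_id = get_col(as, "label_asym_id"),
    auth_asym_id = get_col(as, "auth_asym_id"),
    entity_id = get_col(as, "label_entity_id"),
    comp_id = get_col(as, "label_comp_id"),
    label_seq = suppressWarnings(as.integer(get_col(as, "label_seq_id"))),
    auth_seq = suppressWarnings(as.integer(get_col(as, "auth_seq_id"))),
    ins_code = get_col(as, "pdbx_PDB_ins_code"),
    atom_name = get_col(as, "label_atom_id"),
    element = get_col(as, "type_symbol"),
    altloc = get_col(as, "label_alt_id"),
    x = as.numeric(get_col(as, "Cartn_x")),
    y = as.numeric(get_col(as, "Cartn_y")),
    z = as.numeric(get_col(as, "Cartn_z")),
    b_factor = as.numeric(get_col(as, "B_iso_or_equiv", "0")),
    occupancy = as.numeric(get_col(as, "occupancy", "1")),
    is_hetero = get_col(as, "group_PDB", "ATOM") == "HETATM",
    stringsAsFactors = FALSE)
  atoms$model[is.na(atoms$model)] <- 1L
  atoms$auth_asym_id[is.na(atoms$auth_asym_id)] <- atoms$label_asym_id[is.na(atoms$auth_asym_id)]
  atoms$auth_seq[is.na(atoms$auth_seq)] <- atoms$label_seq[is.na(atoms$auth_seq)]
  atoms$b_factor[is.na(atoms$b_factor)] <- 0
  atoms$occupancy[is.na(atoms$occupancy)] <- 1
  if (any(is.na(atoms$label_asym_id)))
    ms_error("molshots_cif_syntax_error", "atom_site rows lack label_asym_id")

  # Alternate locations: keep the highest-occupancy altloc per atom name,
  # ties broken by altloc id (lexicographic).
  has_alt <- !is.na(atoms$altloc)
  if (any(has_alt)) {
    key <- paste(atoms$model, atoms$label_asym_id, atoms$auth_seq,
                 ifelse(is.na(atoms$ins_code), "", atoms$ins_code),
                 atoms$atom_name, sep = "\r")
    ord <- order(key, -atoms$occupancy,
                 ifelse(is.na(atoms$altloc), "", atoms$altloc))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$model, atoms$label_asym_id,
                                     atoms$auth_seq,
                                     ifelse(is.na(atoms$ins_code), "", atoms$ins_code),
                                     atoms$atom_name, sep = "\r")), , drop = FALSE]
  }
  # Order: model, chain (first-appearance order), residue by label_seq
  # when present else auth_seq, atoms in original file order.
  atoms$.file_order <- seq_len(nrow(atoms))
  chain_rank <- match(atoms$label_asym_id, unique(atoms$label_asym_id))
  res_seq <- ifelse(is.na(atoms$label_seq), atoms$auth_seq, atoms$label_seq)
  atoms <- atoms[order(atoms$model, chain_rank, res_seq, atoms$.file_order), ,
                 drop = FALSE]
  atoms$.file_order <- NULL
  rownames(atoms) <- NULL

  # Entities: from the entity category when present, otherwise inferred.
  ent_ids <- unique(atoms$entity_id)
  if (any(is.na(ent_ids))) {
    atoms$entity_id[is.na(atoms$entity_id)] <- "1"
    ent_ids <- unique(atoms$entity_id)
  }
  ec <- cats[["entity"]]
  entities <- data.frame(entity_id = character(0), entity_type = character(0),
                         description = character(0), stringsAsFactors = FALSE)
  if (!is.null(ec) && "id" %in% names(ec)) {
    entities <- data.frame(
      entity_id = cif_na(ec$id),
      entity_type = tolower(ifelse(is.na(cif_na(get_col(ec, "type"))),
                                   "polymer", cif_na(get_col(ec, "type")))),
      description = ifelse(is.na(cif_na(get_col(ec, "pdbx_description"))), "",
                           cif_na(get_col(ec, "pdbx_description"))),
      stringsAsFactors = FALSE)
  }
  infer_type <- function(eid) {
    sub_atoms <- atoms[atoms$entity_id == eid, , drop = FALSE]
    if (all(sub_atoms$comp_id %in% c("HOH", "DOD", "WAT"))) "water"
    else if (all(sub_atoms$is_hetero)) "non-polymer"
    else "polymer"
  }
  for (eid in setdiff(ent_ids, entities$entity_id)) {
    entities <- rbind(entities, data.frame(
      entity_id = eid, entity_type = infer_type(eid), description = "",
      stringsAsFactors = FALSE))
  }
  entities <- entities[order(suppressWarnings(as.numeric(entities$entity_id)),
                             entities$entity_id), , drop = FALSE]
  rownames(entities) <- NULL

  assemblies <- parse_assemblies(cats)

  entry_id <- default_id
  if (!is.null(cats[["entry"]]) && "id" %in% names(cats[["entry"]])) {
    v <- cif_na(cats[["entry"]]$id[1])
    if (!is.na(v)) entry_id <- tolower(v)
  }
  method <- NA_character_
  if (!is.null(cats[["exptl"]]) && "method" %in% names(cats[["exptl"]]))
    method <- cif_na(cats[["exptl"]]$method[1])

  mol_structure(entry_id, atoms, entities, assemblies, exptl_method = method)
}

parse_assemblies <- function(cats) {
  gen <- cats[["pdbx_struct_assembly_gen"]]
  ops <- cats[["pdbx_struct_oper_list"]]
  if (is.null(gen) || is.null(ops)) return(list())
  operators <- list()
  for (i in seq_len(nrow(ops))) {
    R <- matrix(NA_real_, 3, 3)
    t <- numeric(3)
    for (r in 1:3) {
      for (c in 1:3)
        R[r, c] <- as.numeric(ops[[sprintf("matrix[%d][%d]", r, c)]][i])
      t[r] <- as.numeric(ops[[sprintf("vector[%d]", r)]][i])
    }
    operators[[cif_na(ops$id[i])]] <- list(R = R, t = t)
  }
  asm_ids <- unique(cif_na(gen$assembly_id))
  out <- list()
  for (aid in asm_ids) {
    rows <- which(cif_na(gen$assembly_id) == aid)
    exprs <- lapply(rows, function(i) {
      list(oper_seqs = parse_oper_expression(cif_na(gen$oper_expression[i])),
           asym_ids = strsplit(cif_na(gen$asym_id_list[i]), ",")[[1]])
    })
    out[[aid]] <- list(assembly_id = aid, expressions = exprs,
                       operators = operators)
  }
  out
}

# Parse an assembly operator expression such as "1", "1,2", "(1-3)" or
# "(2)(1)" into a list of operator-id sequences.  Parenthesized groups
# form a cartesian product; each resulting sequence composes
# left-to-right as matrix products applied to coordinates.
parse_oper_expression <- function(expr) {
  expr <- gsub("[[:space:]]", "", expr)
  groups <- if (grepl("^\\(", expr)) {
    m <- gregexpr("\\(([^()]*)\\)", expr)[[1]]
    if (m[1] == -1L) ms_error("molshots_cif_syntax_error",
                              sprintf("bad oper_expression '%s'", expr))
    regmatches(expr, gregexpr("\\(([^()]*)\\)", expr))[[1]]
  } else expr
  groups <- gsub("[()]", "", groups)
  expand_group <- function(g) {
    unlist(lapply(strsplit(g, ",")[[1]], function(part) {
      if (grepl("^[0-9]+-[0-9]+$", part)) {
        ab <- as.integer(strsplit(part, "-")[[1]])
        as.character(seq(ab[1], ab[2]))
      } else part
    }))
  }
  ids_per_group <- lapply(groups, expand_group)
  seqs <- list(character(0))
  for (g in ids_per_group) {
    seqs <- unlist(lapply(seqs, function(s) lapply(g, function(id) c(s, id))),
                   recursive = FALSE)
  }
  seqs
}

# ---------------------------------------------------------------------------
# Assembly expansion and deposited selection

compose_operators <- function(operators, oper_seq) {
  R <- diag(3)
  t <- numeric(3)
  for (id in oper_seq) {
    op <- operators[[id]]
    # left-to-right composition: x' = R1 (R2 x + t2) + t1
    t <- R %*% op$t + t
    R <- R %*% op$R
  }
  list(R = R, t = as.numeric(t))
}

#' Expand a biological assembly
#'
#' Applies the operator expressions of the given assembly to the
#' deposited chains, producing a new structure whose chains are the
#' transformed copies.  Copies get the chain id
#' `"{label_asym_id}-{copy index}"`.  Only model 1 is expanded (the
#' interaction of multi-model ensembles with assembly operators is
#' undefined, so the first model is used and noted).
#'
#' @param structure a `mol_structure`
#' @param assembly_id assembly identifier present in `structure$assemblies`
#' @return a new `mol_structure` with the expanded coordinates
#' @export
expand_assembly <- function(structure, assembly_id) {
  asm <- structure$assemblies[[as.character(assembly_id)]]
  if (is.null(asm))
    ms_error("molshots_unknown_assembly",
             sprintf("unknown assembly id '%s'", assembly_id))
  m1 <- min(structure$atoms$model)
  base <- structure$atoms[structure$atoms$model == m1, , drop = FALSE]
  pieces <- list()
  for (expr in asm$expressions) {
    sel <- base[base$label_asym_id %in% expr$asym_ids, , drop = FALSE]
    if (nrow(sel) == 0L) next
    for (k in seq_along(expr$oper_seqs)) {
      tr <- compose_operators(asm$operators, expr$oper_seqs[[k]])
      xyz <- as.matrix(sel[, c("x", "y", "z")]) %*% t(tr$R)
      copy <- sel
      copy$x <- xyz[, 1] + tr$t[1]
      copy$y <- xyz[, 2] + tr$t[2]
      copy$z <- xyz[, 3] + tr$t[3]
      copy$label_asym_id <- paste0(sel$label_asym_id, "-", k)
      copy$auth_asym_id <- paste0(sel$auth_asym_id, "-", k)
      pieces[[length(pieces) + 1L]] <- copy
    }
  }
  atoms <- do.call(rbind, pieces)
  rownames(atoms) <- NULL
  mol_structure(structure$entry_id, atoms, structure$entities,
                assemblies = list(), exptl_method = structure$exptl_method,
                view_label = paste0("assembly-", assembly_id))
}

#' Select the deposited coordinate set
#'
#' Identity passthrough that labels the untransformed coordinates as
#' "deposited"; all models are retained (ensembles show every model).
#'
#' @param structure a `mol_structure`
#' @return the same structure with `view_label = "deposited"`
#' @export
select_deposited <- function(structure) {
  mol_structure(structure$entry_id, structure$atoms, structure$entities,
                structure$assemblies, exptl_method = structure$exptl_method,
                view_label = "deposited")
}

# ---------------------------------------------------------------------------
# mmCIF writer (used by the fixture generator; round-trip tested)

cif_quote <- function(x) {
  ifelse(is.na(x), ".",
         ifelse(grepl("[ '\"]", x) | x == "", paste0("'", x, "'"), x))
}

#' Write a structure as mmCIF
#'
#' Minimal mmCIF writer covering the categories the parser reads.  Its
#' main purpose is the fixture generator; parse-write-parse stability is
#' part of the test suite.
#'
#' @param structure a `mol_structure`
#' @param path output path (`.cif`, or `.cif.gz` for compressed output)
#' @return `path`, invisibly
#' @export
write_mmcif <- function(structure, path) {
  a <- structure$atoms
  lines <- c(
    sprintf("data_%s", structure$entry_id),
    sprintf("_entry.id %s", cif_quote(toupper(structure$entry_id))))
  if (!is.na(structure$exptl_method))
    lines <- c(lines, sprintf("_exptl.method %s", cif_quote(structure$exptl_method)))
  lines <- c(lines, "#", "loop_", "_entity.id", "_entity.type",
             "_entity.pdbx_description",
             sprintf("%s %s %s", structure$entities$entity_id,
                     structure$entities$entity_type,
                     cif_quote(structure$entities$description)))
  if (length(structure$assemblies) > 0L) {
    gen_lines <- c("#", "loop_", "_pdbx_struct_assembly_gen.assembly_id",
                   "_pdbx_struct_assembly_gen.oper_expression",
                   "_pdbx_struct_assembly_gen.asym_id_list")
    op_seen <- list()
    for (asm in structure$assemblies) {
      for (expr in asm$expressions) {
        expr_str <- paste(vapply(expr$oper_seqs, function(s)
          if (length(s) == 1L) s else paste0("(", paste(s, collapse = ")("), ")"),
          ""), collapse = ",")
        # multiple single-op seqs print as "1,2"; composed seqs as "(a)(b)"
        if (all(vapply(expr$oper_seqs, length, 0L) == 1L))
          expr_str <- paste(vapply(expr$oper_seqs, `[`, "", 1L), collapse = ",")
        gen_lines <- c(gen_lines, sprintf("%s %s %s", asm$assembly_id,
                                          cif_quote(expr_str),
                                          paste(expr$asym_ids, collapse = ",")))
      }
      op_seen <- modifyList(op_seen, asm$operators)
    }
    op_lines <- c("#", "loop_", "_pdbx_struct_oper_list.id",
                  unlist(lapply(1:3, function(r)
                    c(sprintf("_pdbx_struct_oper_list.matrix[%d][1]", r),
                      sprintf("_pdbx_struct_oper_list.matrix[%d][2]", r),
                      sprintf("_pdbx_struct_oper_list.matrix[%d][3]", r),
                      sprintf("_pdbx_struct_oper_list.vector[%d]", r)))))
    for (id in names(op_seen)) {
      op <- op_seen[[id]]
      vals <- unlist(lapply(1:3, function(r) c(op$R[r, ], op$t[r])))
      op_lines <- c(op_lines, paste(id, paste(sprintf("%.6f", vals),
                                              collapse = " ")))
    }
    lines <- c(lines, gen_lines, op_lines)
  }
  lines <- c(lines, "#", "loop_",
             paste0("_atom_site.", c(
               "group_PDB", "id", "type_symbol", "label_atom_id",
               "label_alt_id", "label_comp_id", "label_asym_id",
               "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
               "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
               "B_iso_or_equiv", "auth_seq_id", "auth_asym_id",
               "pdbx_PDB_model_num")),
             sprintf("%s %d %s %s . %s %s %s %s %s %.3f %.3f %.3f %.2f %.2f %d %s %d",
                     ifelse(a$is_hetero, "HETATM", "ATOM"), seq_len(nrow(a)),
                     a$element, a$atom_name, a$comp_id, a$label_asym_id,
                     a$entity_id,
                     ifelse(is.na(a$label_seq), ".", as.character(a$label_seq)),
                     ifelse(is.na(a$ins_code), ".", a$ins_code),
                     a$x, a$y, a$z, a$occupancy, a$b_factor, a$auth_seq,
                     a$auth_asym_id, a$model),
             "#")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}
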