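#' @title Per-entry annotation data
#' @description
#' Optional annotation data — entity names, preferred assembly, modified
#' residues, SIFTS domain mappings, per-residue validation outliers —
#' can be supplied offline as a single JSON file whose sections mirror
#' the public PDBe API response shapes, or fetched live through an
#' optional network adapter.  Both ingestion paths produce the same
#' `annotation_set` and are tested for equivalence.  The file schema is
#' documented in `inst/extdata/annotation-schema.json`.
#' @name annotations
NULL

ANNOTATION_SECTIONS <- c("molecules", "summary", "modified_residues",
                         "mappings", "validation")

API_ENDPOINTS <- c(
  molecules = "pdb/entry/molecules/%s",
  summary = "pdb/entry/summary/%s",
  modified_residues = "pdb/entry/modified_AA_or_NA/%s",
  mappings = "mappings/%s",
  validation = "validation/residuewise_outlier_summary/entry/%s")

#' Construct an annotation set
#'
#' @param entity_names named character vector, entity id -> display name
#' @param preferred_assembly_id assembly id or `NA`
#' @param domains data.frame with columns `source` (CATH/SCOP/Pfam/Rfam),
#'   `family_id`, `chain` (auth asym id), `start_seq`, `end_seq`
#'   (inclusive author residue numbers)
#' @param modres data.frame with columns `comp_id`, `chain`, `auth_seq`
#' @param outliers data.frame with columns `chain`, `auth_seq`,
#'   `outlier_count`
#' @return an object of class `annotation_set`
#' @export
annotation_set <- function(entity_names = character(0),
                           preferred_assembly_id = NA_character_,
                           domains = NULL, modres = NULL, outliers = NULL) {
  empty_domains <- data.frame(source = character(0), family_id = character(0),
                              chain = character(0), start_seq = integer(0),
                              end_seq = integer(0), stringsAsFactors = FALSE)
  empty_modres <- data.frame(comp_id = character(0), chain = character(0),
                             auth_seq = integer(0), stringsAsFactors = FALSE)
  empty_outliers <- data.frame(chain = character(0), auth_seq = integer(0),
                               outlier_count = integer(0), stringsAsFactors = FALSE)
  if (is.null(domains) || nrow(domains) == 0L) domains <- empty_domains
  if (is.null(modres) || nrow(modres) == 0L) modres <- empty_modres
  if (is.null(outliers) || nrow(outliers) == 0L) outliers <- empty_outliers
  if (!all(domains$source %in% c("CATH", "SCOP", "Pfam", "Rfam")))
    ms_error("molshots_invalid_annotations",
             "domain source must be one of CATH, SCOP, Pfam, Rfam")
  if (nrow(domains) > 0L && !all(domains$start_seq <= domains$end_seq))
    ms_error("molshots_invalid_annotations", "domain segment start > end")
  if (nrow(outliers) > 0L && !all(outliers$outlier_count >= 0))
    ms_error("molshots_invalid_annotations", "negative outlier count")
  structure(list(entity_names = entity_names,
                 preferred_assembly_id = preferred_assembly_id,
                 domains = domains, modres = modres, outliers = outliers),
            class = "annotation_set")
}

#' An empty annotation set
#' @return an `annotation_set` with all sections empty
#' @export
empty_annotations <- function() annotation_set()

# Unwrap the PDBe convention of keying a response body by entry id:
# {"1abc": <payload>} -> <payload>.  Sections may also be stored bare.
unwrap_entry <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x) == 1L &&
      grepl("^[0-9a-zA-Z_-]+$", names(x)[1]) &&
      !(names(x)[1] %in% c("molecules", "assemblies", "mappings")))
    x[[1]]
  else x
}

parse_molecules <- function(payload) {
  payload <- unwrap_entry(payload)
  if (is.null(payload)) return(character(0))
  out <- character(0)
  for (mol in payload) {
    eid <- as.character(mol$entity_id)
    nm <- mol$molecule_name
    if (is.null(nm)) next
    out[eid] <- paste(unlist(nm), collapse = ", ")
  }
  out
}

parse_summary <- function(payload) {
  payload <- unwrap_entry(payload)
  if (is.null(payload)) return(NA_character_)
  for (rec in payload) {
    for (asm in rec$assemblies) {
      pref <- asm$preferred_assembly
      if (is.null(pref)) pref <- asm$preferred
      if (isTRUE(pref) || identical(pref, "true"))
        return(as.character(asm$assembly_id))
    }
  }
  NA_character_
}

parse_modified_residues <- function(payload) {
  payload <- unwrap_entry(payload)
  if (is.null(payload) || length(payload) == 0L) return(NULL)
  rows <- lapply(payload, function(rec) {
    data.frame(comp_id = as.character(rec$chem_comp_id),
               chain = as.character(rec$chain_id),
               auth_seq = as.integer(rec$author_residue_number),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

parse_mappings <- function(payload) {
  payload <- unwrap_entry(payload)
  if (is.null(payload)) return(NULL)
  rows <- list()
  for (source in intersect(names(payload), c("CATH", "SCOP", "Pfam", "Rfam"))) {
    fams <- payload[[source]]
    for (fam_id in names(fams)) {
      for (seg in fams[[fam_id]]$mappings) {
        rows[[length(rows) + 1L]] <- data.frame(
          source = source, family_id = fam_id,
          chain = as.character(seg$chain_id),
          start_seq = as.integer(seg$start$author_residue_number),
          end_seq = as.integer(seg$end$author_residue_number),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

parse_validation <- function(payload) {
  payload <- unwrap_entry(payload)
  if (is.null(payload)) return(NULL)
  rows <- list()
  for (mol in payload$molecules) {
    for (ch in mol$chains) {
      for (model in ch$models) {
        for (res in model$residues) {
          rows[[length(rows) + 1L]] <- data.frame(
            chain = as.character(ch$chain_id),
            auth_seq = as.integer(res$author_residue_number),
            outlier_count = length(unlist(res$outlier_types)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, rows)
}

annotations_from_sections <- function(sections) {
  annotation_set(
    entity_names = parse_molecules(sections[["molecules"]]),
    preferred_assembly_id = parse_summary(sections[["summary"]]),
    modres = parse_modified_residues(sections[["modified_residues"]]),
    domains = parse_mappings(sections[["mappings"]]),
    outliers = parse_validation(sections[["validation"]]))
}

#' Load annotations from an offline JSON file
#'
#' The file is one JSON object with (any subset of) the keys
#' `molecules`, `summary`, `modified_residues`, `mappings`, `validation`,
#' each holding the corresponding PDBe-API-shaped payload.  Unknown keys
#' are ignored and missing sections yield empty collections, so partial
#' data never fails.
#'
#' @param path path to a JSON file
#' @return an `annotation_set`
#' @export
load_annotations <- function(path) {
  if (!file.exists(path))
    ms_error("molshots_missing_file", sprintf("annotation file not found: %s", path))
  sections <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) ms_error("molshots_invalid_annotations",
                                 paste("annotation file is not valid JSON:",
                                       conditionMessage(e))))
  if (!is.list(sections))
    ms_error("molshots_invalid_annotations", "annotation file must hold a JSON object")
  annotations_from_sections(sections)
}

#' Save an annotation set as an offline JSON file
#'
#' Writes the PDBe-API-shaped single-file format read by
#' [load_annotations()]; load-after-save round-trips exactly.
#'
#' @param ann an `annotation_set`
#' @param path output path
#' @param entry_id entry id used for record bookkeeping (not part of the
#'   round-tripped content)
#' @return `path`, invisibly
#' @export
save_annotations <- function(ann, path, entry_id = "entry") {
  sections <- list()
  if (length(ann$entity_names) > 0L) {
    sections$molecules <- lapply(names(ann$entity_names), function(eid)
      list(entity_id = eid, molecule_name = list(unname(ann$entity_names[[eid]]))))
  }
  if (!is.na(ann$preferred_assembly_id)) {
    sections$summary <- list(list(assemblies = list(list(
      assembly_id = ann$preferred_assembly_id, preferred = TRUE))))
  }
  if (nrow(ann$modres) > 0L) {
    sections$modified_residues <- lapply(seq_len(nrow(ann$modres)), function(i)
      list(chem_comp_id = ann$modres$comp_id[i],
           chain_id = ann$modres$chain[i],
           author_residue_number = ann$modres$auth_seq[i]))
  }
  if (nrow(ann$domains) > 0L) {
    maps <- list()
    for (i in seq_len(nrow(ann$domains))) {
      src <- ann$domains$source[i]
      fam <- ann$domains$family_id[i]
      seg <- list(chain_id = ann$domains$chain[i],
                  start = list(author_residue_number = ann$domains$start_seq[i]),
                  end = list(author_residue_number = ann$domains$end_seq[i]))
      if (is.null(maps[[src]])) maps[[src]] <- list()
      if (is.null(maps[[src]][[fam]])) maps[[src]][[fam]] <- list(mappings = list())
      maps[[src]][[fam]]$mappings <- c(maps[[src]][[fam]]$mappings, list(seg))
    }
    sections$mappings <- maps
  }
  if (nrow(ann$outliers) > 0L) {
    chains <- split(ann$outliers, ann$outliers$chain)
    sections$validation <- list(molecules = list(list(
      entity_id = 1L,
      chains = lapply(names(chains), function(ch) {
        df <- chains[[ch]]
        list(chain_id = ch, models = list(list(
          model_id = 1L,
          residues = lapply(seq_len(nrow(df)), function(i)
            list(author_residue_number = df$auth_seq[i],
                 residue_number = df$auth_seq[i],
                 outlier_types = as.list(if (df$outlier_count[i] > 0)
                   paste0("outlier_", seq_len(df$outlier_count[i]))
                   else character(0)))))))
      }))))
  }
  writeLines(jsonlite::toJSON(sections, auto_unbox = TRUE, pretty = 2,
                              null = "null"), path)
  invisible(path)
}

#' Fetch annotations from an API (optional network adapter)
#'
#' Queries the five per-entry endpoints under `api_base_url` (which may
#' also be a local directory laid out like the API, used for offline
#' mocking) and merges the responses.  Any failed endpoint degrades to
#' an empty section with a warning; only total failure of all endpoints
#' raises an error.  Disabled by default throughout the package
#' (`--no-api` semantics); the live path is not exercised by the test
#' suite.
#'
#' @param api_base_url base URL or local directory
#' @param entry_id entry identifier substituted into the endpoint paths
#' @param enabled when `FALSE` (mirroring `--no-api`), returns an empty
#'   annotation set without any network activity
#' @return an `annotation_set`
#' @export
fetch_annotations <- function(api_base_url, entry_id, enabled = TRUE) {
  if (!enabled) return(empty_annotations())
  is_dir <- dir.exists(api_base_url)
  sections <- list()
  failures <- 0L
  for (key in names(API_ENDPOINTS)) {
    rel <- sprintf(API_ENDPOINTS[[key]], entry_id)
    src <- if (is_dir) file.path(api_base_url, rel)
           else paste0(sub("/$", "", api_base_url), "/", rel)
    if (is_dir && !file.exists(src)) src <- paste0(src, ".json")
    sections[[key]] <- tryCatch(
      jsonlite::fromJSON(src, simplifyVector = FALSE),
      error = function(e) {
        warning(sprintf("annotation endpoint '%s' failed: %s", rel,
                        conditionMessage(e)), call. = FALSE)
        failures <<- failures + 1L
        NULL
      })
  }
  if (failures == length(API_ENDPOINTS))
    ms_error("molshots_api_unreachable",
             sprintf("all annotation endpoints failed under '%s'", api_base_url))
  annotations_from_sections(sections)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "<annotation_set: %d entity names, preferred assembly %s, %d domain segments, %d modres sites, %d outlier records>\n",
    length(x$entity_names),
    ifelse(is.na(x$preferred_assembly_id), "<none>", x$preferred_assembly_id),
    nrow(x$domains), nrow(x$modres), nrow(x$outliers)))
  invisible(x)
}
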