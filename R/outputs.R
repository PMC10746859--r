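#' @title Output files and summaries
#' @description
#' Every rendered view produces at least three files: the PNG image
#' (possibly at several resolutions), a caption JSON and a scene-state
#' JSON sufficient to re-create the scene.  Image filenames follow the
#' grammar `{stem}_image-{width}x{height}.png` where the stem is
#' `{id}_{type}` plus `_{qualifier}_{view}` parts when applicable.  A
#' run additionally writes `{id}_filelist` (one stem per line) and
#' `{id}.json` (records grouped into sections by scene type).  The state
#' file uses this package's own versioned JSON schema; it is *not* a
#' Mol*-loadable state.
#' @name outputs
NULL

STATE_SCHEMA_VERSION <- 1L

sanitize_part <- function(x) gsub("[^a-z0-9]+", "-", tolower(x))

#' Image filename from a stem and size
#'
#' @param stem filename stem, e.g. `"1tqn_bfactor"`
#' @param width,height pixel dimensions
#' @return `"{stem}_image-{width}x{height}.png"`
#' @export
image_filename <- function(stem, width, height) {
  if (!is.character(stem) || length(stem) != 1L || !nzchar(stem))
    ms_error("molshots_bad_argument", "stem must be a non-empty string")
  if (width <= 0 || height <= 0)
    ms_error("molshots_bad_argument", "image dimensions must be positive")
  sprintf("%s_image-%dx%d.png", stem, as.integer(width), as.integer(height))
}

#' Parse an image filename
#'
#' Inverse of [image_filename()]: splits
#' `"{stem}_image-{W}x{H}.png"` into its parts.
#'
#' @param filename an image filename
#' @return list with `stem`, `width`, `height`
#' @export
parse_image_filename <- function(filename) {
  m <- regmatches(filename,
                  regexec("^(.+)_image-([0-9]+)x([0-9]+)\\.png$", filename))[[1]]
  if (length(m) != 4L)
    ms_error("molshots_bad_argument",
             sprintf("'%s' does not match the image filename grammar", filename))
  list(stem = m[2], width = as.integer(m[3]), height = as.integer(m[4]))
}

scene_stem <- function(entry_id, scene, view = "front") {
  parts <- c(sanitize_part(entry_id), scene$scene_type)
  if (nzchar(scene$qualifier)) parts <- c(parts, sanitize_part(scene$qualifier))
  if (!identical(view, "front")) parts <- c(parts, view)
  paste(parts, collapse = "_")
}

sorted_list <- function(x) x[order(names(x))]

scene_state <- function(scene, entry_id, view) {
  vis <- scene$visible
  sorted_list(list(
    schema_version = STATE_SCHEMA_VERSION,
    entry_id = entry_id,
    scene_type = scene$scene_type,
    qualifier = scene$qualifier,
    view = view,
    views = as.list(scene$views),
    caption = scene$caption,
    camera_front = lapply(1:3, function(i) scene$camera_front[i, ]),
    visible_atoms = as.list(vis),
    highlight_atoms = as.list(scene$highlight),
    atom_colors = as.list(sprintf("#%02X%02X%02X", scene$colors[vis, 1],
                                  scene$colors[vis, 2], scene$colors[vis, 3])),
    atom_radii = as.list(scene$radii[vis])))
}

#' Reload a scene from its state file
#'
#' Reconstructs a `scene_spec` from a state JSON written by
#' [write_image_set()] and the structure it referred to.
#'
#' @param path path to a `.molj.json` state file
#' @param structure the `mol_structure` the scene was built on
#' @return a `scene_spec`
#' @export
load_state <- function(path, structure) {
  st <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(st$schema_version) || st$schema_version != STATE_SCHEMA_VERSION)
    ms_error("molshots_bad_state", "unsupported state schema version")
  n <- nrow(structure$atoms)
  vis <- as.integer(st$visible_atoms)
  colors <- matrix(NEUTRAL_GRAY, n, 3, byrow = TRUE)
  hex <- st$atom_colors
  colors[vis, ] <- cbind(strtoi(substr(hex, 2, 3), 16L),
                         strtoi(substr(hex, 4, 5), 16L),
                         strtoi(substr(hex, 6, 7), 16L))
  radii <- rep(POLYMER_RADIUS, n)
  radii[vis] <- as.numeric(st$atom_radii)
  scene <- new_scene(st$scene_type, st$qualifier, structure, vis, colors,
                     radii, highlight = as.integer(st$highlight_atoms),
                     views = as.character(st$views), caption = st$caption)
  cam <- st$camera_front
  scene$camera_front <- if (is.matrix(cam)) cam else
    matrix(unlist(cam), 3, 3, byrow = TRUE)
  scene
}

write_sorted_json <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, pretty = 2, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' Write the file set of one rendered view
#'
#' Writes one PNG per requested size (smaller sizes derived from the
#' largest render via [downscale()]), the caption JSON
#' (`{stem}.caption.json`) and the scene-state JSON (`{stem}.molj.json`).
#'
#' @param scene a `scene_spec`
#' @param view the rendered view kind
#' @param image the rendered `image_buffer` at the largest size
#' @param entry_id entry identifier used in the stem
#' @param outdir output directory (created if needed)
#' @param settings a `render_settings`
#' @return an image record: list with `stem`, `scene_type`, `qualifier`,
#'   `view`, `caption`, `sizes`, `files`
#' @export
write_image_set <- function(scene, view, image, entry_id, outdir,
                            settings = render_settings()) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  stem <- scene_stem(entry_id, scene, view)
  files <- character(0)
  sizes <- list()
  for (sz in settings$sizes) {
    img_s <- downscale(image, sz)
    fn <- image_filename(stem, sz[1], sz[2])
    write_png(img_s, file.path(outdir, fn))
    files <- c(files, fn)
    sizes[[length(sizes) + 1L]] <- list(width = sz[1], height = sz[2],
                                        filename = fn)
  }
  caption_file <- paste0(stem, ".caption.json")
  write_sorted_json(sorted_list(list(
    caption = scene$caption, entry_id = entry_id,
    qualifier = scene$qualifier, scene_type = scene$scene_type,
    view = view)), file.path(outdir, caption_file))
  state_file <- paste0(stem, ".molj.json")
  write_sorted_json(scene_state(scene, entry_id, view),
                    file.path(outdir, state_file))
  files <- c(files, caption_file, state_file)
  list(stem = stem, scene_type = scene$scene_type,
       qualifier = scene$qualifier, view = view, caption = scene$caption,
       sizes = sizes, files = files)
}

#' Write the per-entry summary files
#'
#' `{id}_filelist` lists the image stems, one per line in generation
#' order, with a trailing newline; `{id}.json` groups the records into
#' sections by scene type with stem, qualifier, caption and available
#' sizes.
#'
#' @param entry_id entry identifier
#' @param records list of records from [write_image_set()]
#' @param outdir output directory
#' @return character vector: paths of the filelist and the JSON summary
#' @export
write_summaries <- function(entry_id, records, outdir) {
  id <- sanitize_part(entry_id)
  filelist_path <- file.path(outdir, paste0(id, "_filelist"))
  stems <- vapply(records, `[[`, "", "stem")
  writeLines(stems, filelist_path)   # trailing newline included
  sections <- stats::setNames(
    lapply(scene_types("all"), function(type) {
      recs <- Filter(function(r) r$scene_type == type, records)
      lapply(recs, function(r) sorted_list(list(
        stem = r$stem, qualifier = r$qualifier, view = r$view,
        caption = r$caption, sizes = r$sizes,
        files = as.list(r$files))))
    }), scene_types("all"))
  json_path <- file.path(outdir, paste0(id, ".json"))
  write_sorted_json(list(entry_id = id,
                         schema_version = STATE_SCHEMA_VERSION,
                         sections = sections), json_path)
  c(filelist_path, json_path)
}
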