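#' @title Software rendering
#' @description
#' Scenes are rasterized by a built-in z-buffered sphere-impostor
#' renderer with an orthographic camera framed to the visible set's
#' bounding sphere plus a 10% margin, Lambertian shading from a fixed
#' headlight (ambient 0.35, diffuse 0.65) and optional supersampling.
#' The image is rendered once at `supersample x` the largest requested
#' size, box-downsampled to the largest size, and every smaller
#' resolution is derived from that largest render.  Output is
#' byte-deterministic for identical inputs.
#' @name render
NULL

AMBIENT <- 0.35
DIFFUSE <- 0.65
FRAME_MARGIN <- 1.10          # 10% margin around the bounding sphere
DEFAULT_SIZES <- list(c(1600L, 1600L), c(800L, 800L), c(200L, 200L),
                      c(100L, 100L))

#' Render settings
#'
#' @param sizes list of `c(width, height)` pixel sizes, largest first;
#'   default ladder 1600, 800, 200, 100 square
#' @param supersample integer supersampling factor (>= 1), default 2
#' @param background background color, integer RGB
#' @param draw_axes draw the PCA axis arrows in the bottom-left corner
#' @return a `render_settings` object
#' @export
render_settings <- function(sizes = DEFAULT_SIZES, supersample = 2L,
                            background = c(255L, 255L, 255L),
                            draw_axes = TRUE) {
  if (length(sizes) == 0L)
    ms_error("molshots_bad_argument", "sizes must be non-empty")
  sizes <- lapply(sizes, function(s) as.integer(s))
  if (any(vapply(sizes, function(s) any(s <= 0L) || length(s) != 2L, TRUE)))
    ms_error("molshots_bad_argument", "sizes must be positive (width, height) pairs")
  areas <- vapply(sizes, prod, 0)
  if (which.max(areas) != 1L)
    ms_error("molshots_bad_argument", "largest size must come first")
  if (supersample < 1L)
    ms_error("molshots_bad_argument", "supersample must be >= 1")
  structure(list(sizes = sizes, supersample = as.integer(supersample),
                 background = as.integer(background),
                 draw_axes = isTRUE(draw_axes)),
            class = "render_settings")
}

new_image <- function(width, height, pixels) {
  stopifnot(length(pixels) == width * height * 3L)
  structure(list(width = as.integer(width), height = as.integer(height),
                 pixels = as.integer(pixels)),
            class = "image_buffer")
}

#' @export
print.image_buffer <- function(x, ...) {
  cat(sprintf("<image_buffer %dx%d>\n", x$width, x$height))
  invisible(x)
}

#' Pixel accessor
#' @param image an `image_buffer`
#' @param row,col 1-based pixel position (row 1 is the top scanline)
#' @return integer RGB vector of length 3
#' @export
get_pixel <- function(image, row, col) {
  p <- ((row - 1L) * image$width + (col - 1L)) * 3L
  image$pixels[p + 1:3]
}

# Project scene atoms into pixel coordinates for a given view.
# Returns centers (px, py, depth z in pixels) and pixel radii.
project_scene <- function(scene, view, width, height) {
  vis <- scene$visible
  xyz <- coords(scene$structure)[vis, , drop = FALSE]
  R <- view_rotation(scene$camera_front, view)
  center <- colMeans(xyz)
  rc <- sweep(xyz, 2, center) %*% t(R)
  rad <- scene$radii[vis]
  # bounding sphere over all views: atom-center spread plus atom radii
  bound <- max(sqrt(rowSums(rc^2)) + rad)
  if (bound <= 0) bound <- 1
  scale <- min(width, height) / (2 * bound * FRAME_MARGIN)
  list(px = width / 2 + rc[, 1] * scale,
       py = height / 2 - rc[, 2] * scale,   # screen y grows downwards
       pz = rc[, 3] * scale,
       pr = rad * scale,
       scale = scale,
       colors = scene$colors[vis, , drop = FALSE])
}

#' Rasterize a scene
#'
#' Renders the scene's visible spheres with the z-buffered software
#' renderer at `supersample x` the largest requested size, then
#' box-downsamples to the largest size.  An empty visible set yields a
#' background-only image.
#'
#' @param scene a `scene_spec`
#' @param view one of `"front"`, `"side"`, `"top"`
#' @param settings a `render_settings`
#' @return an `image_buffer` at the largest requested size
#' @export
rasterize <- function(scene, view = "front", settings = render_settings()) {
  w <- settings$sizes[[1]][1]
  h <- settings$sizes[[1]][2]
  ss <- settings$supersample
  rw <- w * ss
  rh <- h * ss
  if (length(scene$visible) == 0L) {
    px <- rep(settings$background, w * h)
    return(new_image(w, h, px))
  }
  pr <- project_scene(scene, view, rw, rh)
  raw <- .render_spheres_cpp(pr$px, pr$py, pr$pz, pr$pr,
                             pr$colors[, 1], pr$colors[, 2], pr$colors[, 3],
                             rw, rh, settings$background, AMBIENT, DIFFUSE)
  img <- new_image(rw, rh, raw)
  if (ss > 1L) img <- downscale(img, c(w, h))
  img
}

#' Box-filter downscale
#'
#' Area-weighted box average; requesting an upscale is an error.
#' Rounding is "half away from zero" (`floor(x + 0.5)`).
#'
#' @param image an `image_buffer`
#' @param target `c(width, height)`, both at most the source size
#' @return an `image_buffer`
#' @export
downscale <- function(image, target) {
  tw <- as.integer(target[1])
  th <- as.integer(target[2])
  if (tw > image$width || th > image$height)
    ms_error("molshots_bad_argument",
             sprintf("cannot upscale %dx%d to %dx%d", image$width,
                     image$height, tw, th))
  if (tw == image$width && th == image$height) return(image)
  new_image(tw, th, .box_downscale_cpp(image$pixels, image$width,
                                       image$height, tw, th))
}

# --------------------------------------------------------------------------
# Axis-arrow overlay

AXIS_ARROW_COLORS <- matrix(as.integer(c(200, 40, 40,    # PCA-1, red
                                         40, 160, 40,    # PCA-2, green
                                         40, 80, 220)),  # PCA-3, blue
                            ncol = 3, byrow = TRUE)

# 3x5 bitmap digits "1".."3" for arrow labels (column-major strings)
AXIS_DIGITS <- list(
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "3" = c("111", "001", "011", "001", "111"))

set_pixel <- function(pixels, width, height, row, col, rgb) {
  if (row < 1L || row > height || col < 1L || col > width) return(pixels)
  p <- ((row - 1L) * width + (col - 1L)) * 3L
  pixels[p + 1:3] <- rgb
  pixels
}

draw_line <- function(pixels, width, height, r0, c0, r1, c1, rgb, thick = 1L) {
  n <- max(abs(r1 - r0), abs(c1 - c0), 1)
  for (t in 0:n) {
    r <- round(r0 + (r1 - r0) * t / n)
    c <- round(c0 + (c1 - c0) * t / n)
    for (dr in seq_len(thick) - 1L) {
      for (dc in seq_len(thick) - 1L) {
        pixels <- set_pixel(pixels, width, height, r + dr, c + dc, rgb)
      }
    }
  }
  pixels
}

#' Draw the PCA axis arrows
#'
#' Overlays three labeled arrows in the bottom-left corner showing the
#' screen-space directions of the three PCA axes for the current view
#' (in the front view, axis 1 points along screen-x).  All overlay
#' pixels stay within the bottom-left quadrant.  When `draw_axes` is
#' disabled in the settings the image is returned untouched.
#'
#' @param image an `image_buffer`
#' @param front canonical front rotation of the scene
#' @param view the rendered view
#' @param settings a `render_settings`
#' @return an `image_buffer` with the overlay applied
#' @export
draw_axes_overlay <- function(image, front, view = "front",
                              settings = render_settings()) {
  if (!settings$draw_axes) return(image)
  w <- image$width
  h <- image$height
  Rv <- view_rotation(front, view)
  dirs <- Rv %*% t(front)   # column i = screen direction of PCA axis i
  len <- max(8L, as.integer(round(0.08 * min(w, h))))
  oc <- as.integer(round(0.05 * w)) + 1L          # origin column
  orow <- h - as.integer(round(0.05 * h))          # origin row (near bottom)
  px <- image$pixels
  thick <- max(1L, as.integer(round(min(w, h) / 400)))
  for (i in 1:3) {
    dx <- dirs[1, i]
    dy <- dirs[2, i]
    r1 <- orow - as.integer(round(dy * len))
    c1 <- oc + as.integer(round(dx * len))
    # clamp to the bottom-left quadrant (leaving room for the arrowhead)
    r1 <- min(max(r1, as.integer(ceiling(h / 2)) + 1L + thick), h - thick)
    c1 <- min(max(c1, 1L + thick), as.integer(floor(w / 2)) - thick)
    px <- draw_line(px, w, h, orow, oc, r1, c1, AXIS_ARROW_COLORS[i, ], thick)
    # arrowhead: a small filled square at the tip
    for (dr in -thick:thick) for (dc in -thick:thick)
      px <- set_pixel(px, w, h, r1 + dr, c1 + dc, AXIS_ARROW_COLORS[i, ])
    # digit label just beyond the tip
    lr <- min(max(r1 - as.integer(round(dy * 6)) - 2L,
                  as.integer(ceiling(h / 2)) + 1L), h - 5L)
    lc <- min(max(c1 + as.integer(round(dx * 6)), 1L),
              as.integer(floor(w / 2)) - 3L)
    glyph <- AXIS_DIGITS[[as.character(i)]]
    for (gr in seq_along(glyph)) {
      bits <- strsplit(glyph[gr], "")[[1]]
      for (gc in seq_along(bits)) {
        if (bits[gc] == "1")
          px <- set_pixel(px, w, h, lr + gr - 1L, lc + gc - 1L,
                          AXIS_ARROW_COLORS[i, ])
      }
    }
  }
  new_image(w, h, px)
}

# --------------------------------------------------------------------------
# PNG writer (8-bit RGB, no alpha).  PNG is a chunked format: each chunk
# is length + type + data + CRC32; the image data is zlib-compressed
# scanlines, each prefixed with a filter byte (0 = none).

u32be <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32be(length(data)), body, u32be(.crc32_cpp(body)))
}

#' Write an image buffer as PNG
#'
#' Minimal deterministic PNG encoder (8-bit RGB, filter type 0,
#' zlib-compressed via `memCompress`).
#'
#' @param image an `image_buffer`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_png <- function(image, path) {
  w <- image$width
  h <- image$height
  px <- as.raw(image$pixels)
  # prepend the filter byte (0) to each scanline
  mat <- matrix(px, nrow = 3L * w, ncol = h)
  scan <- rbind(as.raw(0L), mat)
  idat <- memCompress(as.raw(scan), type = "gzip")  # zlib stream (78 9c ...)
  ihdr <- c(u32be(w), u32be(h),
            as.raw(c(8L, 2L, 0L, 0L, 0L)))  # bit depth 8, RGB
  out <- c(as.raw(c(0x89, 0x50, 0x4E, 0x47, 0x0D, 0x0A, 0x1A, 0x0A)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}
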