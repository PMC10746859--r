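# Software rasterizer, downscale, axis overlay, PNG determinism

small_settings <- function(w = 64L, h = 64L, ss = 1L, axes = FALSE)
  render_settings(sizes = list(c(w, h)), supersample = ss, draw_axes = axes)

scene_from_points <- function(pos, radii = NULL, colors = NULL) {
  st <- make_test_structure(pos)
  n <- nrow(pos)
  if (is.null(radii)) radii <- rep(1.5, n)
  if (is.null(colors)) {
    colors <- t(vapply(seq_len(n) - 1L, chain_palette, integer(3)))
  }
  molshots:::new_scene("entry", "", st, seq_len(n), colors, radii)
}

test_that("a single atom lights the center pixel; empty scenes do not", {
  sc <- scene_from_points(matrix(c(0, 0, 0), 1))
  img <- rasterize(sc, "front", small_settings())
  expect_equal(c(img$width, img$height), c(64L, 64L))
  expect_false(all(get_pixel(img, 32L, 32L) == c(255L, 255L, 255L)))
  # corner stays background (sphere is framed with margin)
  expect_equal(get_pixel(img, 1L, 1L), c(255L, 255L, 255L))
  empty <- sc
  empty$visible <- integer(0)
  img0 <- rasterize(empty, "front", small_settings())
  expect_true(all(img0$pixels == 255L))
})

test_that("nearer atoms occlude farther ones at shared screen positions", {
  pos <- rbind(c(0, 0, 0), c(0, 0, 3), c(8, 0, 0))  # third breaks degeneracy
  cols <- matrix(as.integer(c(200, 0, 0, 0, 0, 200, 120, 120, 120)),
                 3, 3, byrow = TRUE)
  sc <- scene_from_points(pos, radii = rep(1.2, 3), colors = cols)
  # freeze an axis-aligned camera so atom 2 sits in front of atom 1
  sc$camera_front <- diag(3)
  both <- rasterize(sc, "front", small_settings())
  # at the overlap position the nearer (blue) atom wins the depth test;
  # the same pixel from a scene with the two atoms' depths swapped is red
  ctr <- molshots:::project_scene(sc, "front", 64L, 64L)
  px <- as.integer(ceiling(ctr$px[1]))
  py <- as.integer(ceiling(ctr$py[1]))
  blue_fam <- get_pixel(both, py, px)
  expect_gt(blue_fam[3], blue_fam[1])
  swapped <- scene_from_points(rbind(c(0, 0, 3), c(0, 0, 0), c(8, 0, 0)),
                               radii = rep(1.2, 3), colors = cols)
  swapped$camera_front <- diag(3)
  red_fam <- get_pixel(rasterize(swapped, "front", small_settings()), py, px)
  expect_gt(red_fam[1], red_fam[3])
})

test_that("rasterizer is pixel-identical to the brute-force oracle", {
  set.seed(19)
  for (case in 1:3) {
    n <- sample(2:10, 1)
    pos <- cbind(rnorm(n, sd = 4), rnorm(n, sd = 2), rnorm(n, sd = 1))
    sc <- scene_from_points(pos, radii = runif(n, 0.5, 2.5))
    for (view in c("front", "side")) {
      img <- rasterize(sc, view, small_settings(48L, 40L))
      expect_identical(img$pixels,
                       oracle_render(sc, view, 48L, 40L))
    }
  }
})

test_that("downscale: dimensions, uniform colors, documented rounding", {
  img <- molshots:::new_image(8L, 8L, rep(c(10L, 20L, 30L), 64))
  down <- downscale(img, c(4L, 4L))
  expect_equal(c(down$width, down$height), c(4L, 4L))
  expect_equal(unique(matrix(down$pixels, ncol = 3, byrow = TRUE)),
               matrix(c(10L, 20L, 30L), 1))
  # 2x2 black/white checkerboard to 1x1 -> 128 gray (round half up)
  checker <- molshots:::new_image(2L, 2L, c(0L, 0L, 0L, 255L, 255L, 255L,
                                            255L, 255L, 255L, 0L, 0L, 0L))
  one <- downscale(checker, c(1L, 1L))
  expect_equal(one$pixels, rep(128L, 3))
  expect_error(downscale(down, c(8L, 8L)), class = "molshots_bad_argument")
  # non-integer ratio still area-averages exactly (3 -> 2)
  tri <- molshots:::new_image(3L, 1L, rep(c(0L, 90L, 240L), each = 3))
  two <- downscale(tri, c(2L, 1L))
  expect_equal(matrix(two$pixels, ncol = 3, byrow = TRUE)[, 1],
               c(30L, 190L))  # (0+0.5*90)/1.5, (0.5*90+240)/1.5
})

test_that("axis overlay is optional, corner-confined, and oriented", {
  sc <- scene_from_points(rbind(c(-4, 0, 0), c(4, 0.5, 0), c(0, 2, 1)))
  s <- small_settings(80L, 80L)
  img <- rasterize(sc, "front", s)
  expect_identical(draw_axes_overlay(img, sc$camera_front, "front", s)$pixels,
                   img$pixels)  # draw_axes = FALSE -> unchanged
  s2 <- render_settings(sizes = list(c(80L, 80L)), supersample = 1L,
                        draw_axes = TRUE)
  over <- draw_axes_overlay(img, sc$camera_front, "front", s2)
  changed <- which(over$pixels != img$pixels)
  expect_gt(length(changed), 0L)
  pix <- (changed - 1L) %/% 3L
  rows <- pix %/% 80L + 1L
  cols <- pix %% 80L + 1L
  expect_true(all(rows > 40L))   # bottom half
  expect_true(all(cols <= 40L))  # left half
  # front view: the PCA-1 arrow is horizontal -> red pixels span columns,
  # not rows
  reds <- which(matrix(over$pixels, ncol = 3, byrow = TRUE)[, 1] == 200L &
                matrix(over$pixels, ncol = 3, byrow = TRUE)[, 2] == 40L)
  rr <- range((reds - 1L) %/% 80L)
  cc <- range((reds - 1L) %% 80L)
  expect_gt(diff(cc), diff(rr))
})

test_that("identical scene and settings give identical PNG bytes", {
  f <- make_fixture(fixture_spec(), outdir = tempfile())
  st <- read_structure(f$mmcif)
  sc <- build_entry(st)
  s <- render_settings(sizes = list(c(96L, 96L)), supersample = 2L)
  p1 <- tempfile(fileext = ".png")
  p2 <- tempfile(fileext = ".png")
  img1 <- draw_axes_overlay(rasterize(sc, "front", s), sc$camera_front,
                            "front", s)
  img2 <- draw_axes_overlay(rasterize(sc, "front", s), sc$camera_front,
                            "front", s)
  write_png(img1, p1)
  write_png(img2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("render settings validate their invariants", {
  expect_error(render_settings(sizes = list()), class = "molshots_bad_argument")
  expect_error(render_settings(sizes = list(c(100L, 100L), c(200L, 200L))),
               class = "molshots_bad_argument")  # largest must be first
  expect_error(render_settings(supersample = 0L),
               class = "molshots_bad_argument")
})
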