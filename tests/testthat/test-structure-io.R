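# mmCIF reading, altlocs, assembly expansion, writer round-trip

test_that("a minimal mmCIF parses with the expected counts", {
  st <- read_structure(write_tiny_cif())
  expect_s3_class(st, "mol_structure")
  expect_equal(nrow(st$atoms), 3L)
  expect_equal(length(unique(st$atoms$model)), 1L)
  expect_equal(unique(st$atoms$label_asym_id), "A")
  expect_equal(st$entry_id, "tiny")
  expect_equal(st$entities$entity_type, "polymer")
})

test_that("gzipped input parses identically (magic-byte detection)", {
  plain <- write_tiny_cif()
  gz <- tempfile(fileext = ".cif.gz")
  con <- gzfile(gz, "wb")
  writeLines(tiny_cif_text(), con)
  close(con)
  # also a gzipped file with a misleading plain extension
  misnamed <- tempfile(fileext = ".cif")
  file.copy(gz, misnamed)
  a <- read_structure(plain)
  for (p in c(gz, misnamed)) {
    b <- read_structure(p)
    b$entry_id <- a$entry_id
    expect_equal(b$atoms, a$atoms)
    expect_equal(b$entities, a$entities)
  }
})

test_that("error taxonomy: missing file, no coordinates, bcif, bad syntax", {
  expect_error(read_structure(tempfile(fileext = ".cif")),
               class = "molshots_missing_file")
  nocoord <- tempfile(fileext = ".cif")
  writeLines(c("data_x", "_entry.id X"), nocoord)
  expect_error(read_structure(nocoord), class = "molshots_no_coordinates")
  expect_error(read_structure(nocoord), "no coordinates")
  bcif <- tempfile(fileext = ".bcif")
  writeBin(as.raw(1:10), bcif)
  expect_error(read_structure(bcif), class = "molshots_unsupported_format")
  bad <- tempfile(fileext = ".cif")
  writeLines(c("data_x", "loop_", "stray tokens here"), bad)
  expect_error(read_structure(bad), class = "molshots_cif_syntax_error")
})

test_that("alternate locations keep the highest-occupancy conformer", {
  lines <- tiny_cif_text()
  # duplicate the CA row as two altlocs A (0.4) and B (0.6)
  ca <- grep("^ATOM 2", lines)
  lines <- append(lines,
                  c("ATOM 4 C CA A ALA A 1 1 . 9.0 9.0 9.0 0.40 11.00 1 A 1",
                    "ATOM 5 C CA B ALA A 1 1 . 5.0 5.0 5.0 0.60 11.00 1 A 1"),
                  after = ca)
  lines <- lines[-ca]  # drop the unlabelled CA
  p <- tempfile(fileext = ".cif")
  writeLines(lines, p)
  st <- read_structure(p)
  expect_equal(nrow(st$atoms), 3L)
  ca_row <- st$atoms[st$atoms$atom_name == "CA", ]
  expect_equal(ca_row$x, 5.0)  # occupancy 0.60 wins
  # equal occupancy: lexicographically first altloc wins
  lines2 <- sub("0.40", "0.60", lines, fixed = TRUE)
  writeLines(lines2, p)
  st2 <- read_structure(p)
  expect_equal(st2$atoms[st2$atoms$atom_name == "CA", "x"], 9.0)
})

test_that("assembly expansion matches counts and a brute-force oracle", {
  fx <- make_fixture(fixture_spec(n_chains = 1L, residues_per_chain = 6L,
                                  with_ligand = FALSE, with_water = FALSE,
                                  with_modres = FALSE),
                     outdir = tempfile())
  st <- read_structure(fx$mmcif)
  n0 <- nrow(st$atoms)
  ex <- expand_assembly(st, "1")
  expect_equal(nrow(ex$atoms), 2L * n0)           # two operators
  expect_setequal(unique(ex$atoms$label_asym_id), c("A-1", "A-2"))
  # identity copy unchanged
  expect_equal(as.matrix(ex$atoms[ex$atoms$label_asym_id == "A-1",
                                  c("x", "y", "z")]),
               as.matrix(st$atoms[, c("x", "y", "z")]),
               ignore_attr = TRUE)
  # second copy equals a brute-force per-atom application
  op <- st$assemblies[["1"]]$operators[["2"]]
  expected <- t(apply(as.matrix(st$atoms[, c("x", "y", "z")]), 1,
                      function(p) as.numeric(op$R %*% p + op$t)))
  expect_equal(as.matrix(ex$atoms[ex$atoms$label_asym_id == "A-2",
                                  c("x", "y", "z")]),
               expected, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(expand_assembly(st, "99"), class = "molshots_unknown_assembly")
})

test_that("composed operator expressions multiply left-to-right", {
  st <- read_structure(write_tiny_cif())
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ops <- list("1" = list(R = Rz, t = c(1, 0, 0)),
              "2" = list(R = diag(3), t = c(0, 0, 5)))
  st$assemblies[["c"]] <- list(
    assembly_id = "c",
    expressions = list(list(oper_seqs = list(c("1", "2")), asym_ids = "A")),
    operators = ops)
  ex <- expand_assembly(st, "c")
  expect_equal(nrow(ex$atoms), 3L)
  # oracle: x' = R1 (R2 x + t2) + t1 applied atom by atom
  expected <- t(apply(coords(st), 1, function(p)
    as.numeric(Rz %*% (diag(3) %*% p + c(0, 0, 5)) + c(1, 0, 0))))
  expect_equal(coords(ex), expected, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("oper_expression grammar: lists, ranges, products", {
  expect_equal(molshots:::parse_oper_expression("1"), list("1"))
  expect_equal(molshots:::parse_oper_expression("1,3"), list("1", "3"))
  expect_equal(molshots:::parse_oper_expression("(1-3)"), list("1", "2", "3"))
  expect_equal(molshots:::parse_oper_expression("(2)(1)"), list(c("2", "1")))
  expect_equal(molshots:::parse_oper_expression("(1,2)(3-4)"),
               list(c("1", "3"), c("1", "4"), c("2", "3"), c("2", "4")))
})

test_that("select_deposited keeps all models and labels the view", {
  st <- read_structure(write_tiny_cif())
  two <- st$atoms
  two$model <- 2L
  st$atoms <- rbind(st$atoms, two)
  st2 <- select_deposited(st)
  expect_equal(sort(unique(st2$atoms$model)), c(1L, 2L))
  expect_equal(nrow(st2$atoms), 6L)
  expect_equal(st2$view_label, "deposited")
  st$atoms <- st$atoms[0, ]
  expect_error(select_deposited(st), class = "molshots_no_coordinates")
})

test_that("parse -> write -> parse of fixture output is field-for-field stable", {
  fx <- make_fixture(fixture_spec(), outdir = tempfile())
  st1 <- read_structure(fx$mmcif)
  p2 <- tempfile(fileext = ".cif")
  write_mmcif(st1, p2)
  st2 <- read_structure(p2)
  st2$entry_id <- st1$entry_id
  expect_equal(st2$atoms[, setdiff(names(st2$atoms), "altloc")],
               st1$atoms[, setdiff(names(st1$atoms), "altloc")],
               tolerance = 1e-9)
  expect_equal(st2$entities, st1$entities)
  expect_equal(names(st2$assemblies), names(st1$assemblies))
  expect_equal(st2$assemblies[["1"]]$operators, st1$assemblies[["1"]]$operators,
               tolerance = 1e-9)
})

test_that("parsed operator rotations are orthogonal within 1e-6", {
  fx <- make_fixture(fixture_spec(), outdir = tempfile())
  st <- read_structure(fx$mmcif)
  for (asm in st$assemblies) {
    for (op in asm$operators) {
      expect_lt(max(abs(t(op$R) %*% op$R - diag(3))), 1e-6)
    }
  }
})
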