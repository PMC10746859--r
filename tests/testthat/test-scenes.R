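# Scene builders and the dispatcher

full_fixture <- function() {
  fx <- make_fixture(fixture_spec(), outdir = tempfile())
  list(st = read_structure(fx$mmcif), ann = load_annotations(fx$annotations))
}

test_that("the full pdb fixture yields the 12 expected scenes in order", {
  f <- full_fixture()
  scenes <- generate_scenes(f$st, f$ann, mode = "pdb")
  expect_length(scenes, 12L)
  types <- vapply(scenes, `[[`, "", "scene_type")
  expect_equal(types, c("entry", "assembly", rep("entity", 3),
                        rep("domain", 3), "ligand", "modres", "bfactor",
                        "validation"))
  # deterministic: same inputs, same ordered qualifiers
  quals <- vapply(scenes, `[[`, "", "qualifier")
  scenes2 <- generate_scenes(f$st, f$ann, mode = "pdb")
  expect_equal(vapply(scenes2, `[[`, "", "qualifier"), quals)
  # every scene satisfies highlight within visible and full coverage
  for (s in scenes) {
    expect_true(all(s$highlight %in% s$visible))
    expect_true(all(is.finite(s$radii[s$visible]) & s$radii[s$visible] > 0))
    expect_false(anyNA(s$colors[s$visible, ]))
  }
})

test_that("scene counts follow the fixture composition", {
  f <- full_fixture()
  scenes <- generate_scenes(f$st, f$ann, mode = "pdb")
  types <- vapply(scenes, `[[`, "", "scene_type")
  n_nonwater <- sum(f$st$entities$entity_type != "water")
  expect_equal(sum(types == "entity"), n_nonwater)
  expect_equal(sum(types == "ligand"),
               sum(f$st$entities$entity_type == "non-polymer"))
  expect_equal(sum(types == "modres"), length(unique(f$ann$modres$comp_id)))
  expect_equal(sum(types == "domain"),
               nrow(unique(f$ann$domains[, c("source", "family_id")])))
})

test_that("mode dispatch: alphafold yields exactly one plddt scene", {
  fx <- make_fixture(fixture_spec(mode = "alphafold"), outdir = tempfile())
  st <- read_structure(fx$mmcif)
  scenes <- generate_scenes(st, mode = "alphafold")
  expect_length(scenes, 1L)
  expect_equal(scenes[[1]]$scene_type, "plddt")
  f <- full_fixture()
  expect_length(generate_scenes(f$st, f$ann, requested_types = "entry"), 1L)
  expect_error(generate_scenes(f$st, f$ann, mode = "pdb",
                               requested_types = "plddt"),
               class = "molshots_type_not_applicable")
})

test_that("entry scene colors chains distinctly and shows all models", {
  f <- full_fixture()
  sc <- build_entry(f$st)
  a <- f$st$atoms
  colA <- unique(sc$colors[a$label_asym_id == "A", , drop = FALSE])
  colB <- unique(sc$colors[a$label_asym_id == "B", , drop = FALSE])
  expect_equal(nrow(colA), 1L)
  expect_equal(nrow(colB), 1L)
  expect_false(all(colA == colB))
  expect_equal(sc$views, c("front", "side", "top"))
  # 3-model ensemble: visible atoms = 3 x per-model count
  st3 <- f$st
  for (m in 2:3) {
    extra <- f$st$atoms
    extra$model <- m
    st3$atoms <- rbind(st3$atoms, extra)
  }
  sc3 <- build_entry(st3)
  expect_length(sc3$visible, 3L * nrow(f$st$atoms))
  # single-atom structure still yields a valid scene
  one <- make_test_structure(matrix(c(0, 0, 0), 1))
  expect_length(build_entry(one)$visible, 1L)
})

test_that("assembly scene colors the two chain copies differently", {
  f <- full_fixture()
  sc <- build_assembly(f$st, "1")
  ex <- expand_assembly(f$st, "1")
  expect_length(sc$visible, nrow(ex$atoms))
  a <- sc$structure$atoms
  c1 <- unique(sc$colors[a$label_asym_id == "A-1", , drop = FALSE])
  c2 <- unique(sc$colors[a$label_asym_id == "A-2", , drop = FALSE])
  expect_false(all(c1 == c2))
})

test_that("entity scenes highlight the entity and exclude water", {
  f <- full_fixture()
  sc <- build_entity(f$st, f$ann, "1")
  a <- sc$structure$atoms
  expect_setequal(sc$highlight, which(a$entity_id == "1"))
  expect_true(all(sc$highlight %in% sc$visible))
  water_id <- f$st$entities$entity_id[f$st$entities$entity_type == "water"]
  expect_error(build_entity(f$st, f$ann, water_id),
               class = "molshots_water_entity")
  # non-highlighted atoms are faded towards gray (less saturated)
  other <- setdiff(sc$visible, sc$highlight)
  spread <- function(m) max(apply(m, 1, function(r) diff(range(r))))
  expect_lt(spread(sc$colors[other, , drop = FALSE]),
            spread(sc$colors[sc$highlight, , drop = FALSE]))
})

test_that("domain segments use inclusive author-numbered ranges", {
  pos <- cbind(seq(0, 27, 3), 0.5 * sin(1:10), 0.2 * (1:10))
  st <- make_test_structure(pos)
  ann <- annotation_set(domains = data.frame(
    source = "CATH", family_id = "f", chain = "A",
    start_seq = 5L, end_seq = 7L, stringsAsFactors = FALSE))
  scenes <- build_domain(st, ann)
  expect_length(scenes, 1L)
  hi_res <- sort(st$atoms$auth_seq[scenes[[1]]$highlight])
  expect_equal(hi_res, c(5L, 6L, 7L))
  # unknown chain -> segment skipped with a warning, no scene
  bad <- annotation_set(domains = data.frame(
    source = "Pfam", family_id = "PF1", chain = "Z",
    start_seq = 1L, end_seq = 3L, stringsAsFactors = FALSE))
  expect_warning(empty <- build_domain(st, bad), "skipped")
  expect_length(empty, 0L)
  expect_length(build_domain(st, empty_annotations()), 0L)
})

test_that("ligand environment uses a 5 A whole-residue shell", {
  # ligand atom at origin; two other residues with nearest atoms at 4 and 6 A
  pos <- rbind(c(0, 0, 0),      # ligand
               c(4, 0, 0), c(5.5, 0, 0),    # residue 2: 4 A -> included whole
               c(6, 3, 0), c(7, 3, 0))      # residue 3: 6 A -> excluded
  st <- make_test_structure(
    pos, entity_id = c("2", "1", "1", "1", "1"),
    chain = c("L", "A", "A", "A", "A"),
    comp_id = c("LIG", "ALA", "ALA", "ALA", "ALA"),
    hetero = c(TRUE, rep(FALSE, 4)))
  st$atoms$auth_seq <- c(1L, 2L, 2L, 3L, 3L)
  st$atoms$label_seq <- st$atoms$auth_seq
  st$entities$entity_type <- ifelse(st$entities$entity_id == "2",
                                    "non-polymer", "polymer")
  sc <- build_ligand(st, empty_annotations(), "2")
  expect_setequal(sc$visible, 1:3)   # ligand + whole residue 2 only
  expect_setequal(sc$highlight, 1L)
  expect_equal(sc$radii[1], 0.5)     # ligand ball radius
  expect_lt(sc$radii[2], 0.5)        # environment thinner
  expect_error(build_ligand(st, empty_annotations(), "1"),
               class = "molshots_unknown_entity")
})

test_that("modres scenes highlight every site of the component", {
  f <- full_fixture()
  scenes <- build_modres(f$st, f$ann)
  expect_length(scenes, 1L)
  sc <- scenes[[1]]
  expect_equal(sc$qualifier, "MSE")
  a <- sc$structure$atoms
  hi_res <- unique(a$auth_seq[sc$highlight])
  expect_setequal(hi_res, unique(f$ann$modres$auth_seq))
  # preferred assembly context: both assembly copies carry the highlight
  hi_chains <- unique(a$auth_asym_id[sc$highlight])
  expect_setequal(hi_chains, c("A-1", "A-2"))
  expect_length(build_modres(f$st, empty_annotations()), 0L)
})

test_that("putty mapping hits its endpoints and degenerate rule", {
  pos <- cbind(seq(0, 18, 2), sin(1:10), 0.1 * (1:10))
  b <- seq(10, 80, length.out = 10)
  st <- make_test_structure(pos, b = b)
  sc <- build_bfactor(st)
  r <- sc$radii[sc$visible]
  expect_equal(min(r), 0.3, tolerance = 1e-12)
  expect_equal(max(r), 0.3 + 2.2, tolerance = 1e-12)
  # low-B residue is blue-ish, high-B red-ish
  cb <- sc$colors[sc$visible[which.min(r)], ]
  cr <- sc$colors[sc$visible[which.max(r)], ]
  expect_gt(cb[3], cb[1])
  expect_gt(cr[1], cr[3])
  # all-equal B: constant mid radius
  st2 <- make_test_structure(pos, b = rep(42, 10))
  sc2 <- build_bfactor(st2)
  expect_true(all(sc2$radii[sc2$visible] == 1.0))
  # non-X-ray method is a skip signal
  st3 <- st
  st3$exptl_method <- "SOLUTION NMR"
  expect_null(build_bfactor(st3))
})

test_that("validation colors follow the outlier-count bands", {
  pos <- cbind(seq(0, 27, 3), sin(1:10), 0.1 * (1:10))
  st <- make_test_structure(pos)
  ann <- annotation_set(outliers = data.frame(
    chain = "A", auth_seq = c(1L, 2L, 3L, 4L),
    outlier_count = c(0L, 1L, 2L, 5L), stringsAsFactors = FALSE))
  sc <- build_validation(st, ann)
  a <- sc$structure$atoms
  col_of <- function(seq) sc$colors[which(a$auth_seq == seq)[1], ]
  expect_equal(col_of(1), c(0L, 170L, 68L))     # green
  expect_equal(col_of(2), c(255L, 210L, 0L))    # yellow
  expect_equal(col_of(3), c(255L, 140L, 0L))    # orange
  expect_equal(col_of(4), c(220L, 30L, 30L))    # red
  expect_equal(col_of(5), c(190L, 190L, 190L))  # absent -> neutral gray
  expect_null(build_validation(st, empty_annotations()))
})

test_that("plddt bands are left-inclusive and out-of-range errors", {
  pos <- cbind(seq(0, 12, 3), sin(1:5), 0.1 * (1:5))
  st <- make_test_structure(pos, b = c(95, 90, 70, 50, 49.9))
  st$exptl_method <- NA_character_
  sc <- build_plddt(st)
  a <- sc$structure$atoms
  col_of <- function(seq) sc$colors[which(a$auth_seq == seq)[1], ]
  expect_equal(col_of(1), c(0L, 83L, 214L))      # 95 very high
  expect_equal(col_of(2), c(0L, 83L, 214L))      # 90 boundary -> very high
  expect_equal(col_of(3), c(101L, 203L, 243L))   # 70 boundary -> confident
  expect_equal(col_of(4), c(255L, 219L, 87L))    # 50 boundary -> low
  expect_equal(col_of(5), c(255L, 125L, 69L))    # < 50 very low
  st$atoms$b_factor[1] <- 105
  expect_error(build_plddt(st), class = "molshots_bad_plddt")
})

test_that("chain palette is cyclic, distinct and rejects negatives", {
  n <- nrow(molshots:::CHAIN_PALETTE)
  expect_gte(n, 12L)
  expect_equal(chain_palette(0L), chain_palette(n))
  cols <- t(vapply(seq_len(n) - 1L, chain_palette, integer(3)))
  expect_equal(nrow(unique(cols)), n)   # pairwise distinct
  expect_error(chain_palette(-1L), class = "molshots_bad_argument")
})
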