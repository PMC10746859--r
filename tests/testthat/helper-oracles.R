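# Shared helpers: tiny hand-written CIF fixtures and independent
# brute-force oracles used across the suite.

quiet_opts <- function() options(molshots.quiet = TRUE)
quiet_opts()

# A minimal hand-written mmCIF with exactly 3 atom_site rows in 1 chain.
tiny_cif_text <- function() {
  c("data_tiny",
    "_entry.id TINY",
    "loop_",
    "_entity.id",
    "_entity.type",
    "_entity.pdbx_description",
    "1 polymer 'tiny peptide'",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_asym_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 . 0.000 1.000 2.000 1.00 10.00 1 A 1",
    "ATOM 2 C CA . ALA A 1 1 . 1.500 1.200 2.100 1.00 11.00 1 A 1",
    "ATOM 3 C C . ALA A 1 1 . 2.900 0.800 2.500 1.00 12.00 1 A 1",
    "#")
}

write_tiny_cif <- function(path = tempfile(fileext = ".cif")) {
  writeLines(tiny_cif_text(), path)
  path
}

# Directly-constructed structure for geometric tests: atom positions are
# given explicitly, one residue per position group.
make_test_structure <- function(pos, comp_id = NULL, entity_id = NULL,
                                chain = NULL, entity_types = NULL,
                                b = NULL, atom_name = NULL, hetero = NULL) {
  n <- nrow(pos)
  if (is.null(comp_id)) comp_id <- rep("ALA", n)
  if (is.null(entity_id)) entity_id <- rep("1", n)
  if (is.null(chain)) chain <- rep("A", n)
  if (is.null(b)) b <- seq(10, 20, length.out = n)
  if (is.null(atom_name)) atom_name <- rep("CA", n)
  if (is.null(hetero)) hetero <- rep(FALSE, n)
  atoms <- data.frame(
    model = 1L, label_asym_id = chain, auth_asym_id = chain,
    entity_id = entity_id, comp_id = comp_id,
    label_seq = seq_len(n), auth_seq = seq_len(n),
    ins_code = NA_character_, atom_name = atom_name, element = "C",
    x = pos[, 1], y = pos[, 2], z = pos[, 3], b_factor = b,
    occupancy = 1, is_hetero = hetero, stringsAsFactors = FALSE)
  ids <- unique(entity_id)
  if (is.null(entity_types)) entity_types <- rep("polymer", length(ids))
  mol_structure("test", atoms,
                data.frame(entity_id = ids, entity_type = entity_types,
                           description = "", stringsAsFactors = FALSE),
                exptl_method = "X-RAY DIFFRACTION")
}

# Brute-force covariance eigendecomposition oracle (explicit loops).
oracle_principal_variances <- function(xyz) {
  n <- nrow(xyz)
  mu <- c(sum(xyz[, 1]), sum(xyz[, 2]), sum(xyz[, 3])) / n
  C <- matrix(0, 3, 3)
  for (k in seq_len(n)) {
    d <- as.numeric(xyz[k, ]) - mu
    for (i in 1:3) for (j in 1:3) C[i, j] <- C[i, j] + d[i] * d[j]
  }
  C <- C / n
  sort(eigen(C, symmetric = TRUE)$values, decreasing = TRUE)
}

random_rotation <- function() {
  # QR of a random matrix, sign-fixed to det +1
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_cloud <- function(n = 40) {
  # anisotropic so eigenvalues are distinct and skew is generic
  cbind(rnorm(n, sd = 3) + 0.3 * rnorm(n)^2,
        rnorm(n, sd = 1.5) + 0.2 * rnorm(n)^2,
        rnorm(n, sd = 0.6))
}

# Brute-force per-pixel nearest-sphere renderer: an independent
# implementation of the projection, occlusion and shading contract.
oracle_render <- function(scene, view, width, height,
                          background = c(255L, 255L, 255L)) {
  vis <- scene$visible
  xyz <- coords(scene$structure)[vis, , drop = FALSE]
  R <- view_rotation(scene$camera_front, view)
  ctr <- colMeans(xyz)
  rc <- t(apply(xyz, 1, function(p) R %*% (p - ctr)))
  rad <- scene$radii[vis]
  bound <- max(sqrt(rowSums(rc^2)) + rad)
  scale <- min(width, height) / (2 * bound * 1.10)
  px <- width / 2 + rc[, 1] * scale
  py <- height / 2 - rc[, 2] * scale
  pz <- rc[, 3] * scale
  pr <- rad * scale
  cols <- scene$colors[vis, , drop = FALSE]
  out <- integer(width * height * 3)
  for (i in seq_len(height)) {
    cy <- i - 0.5
    for (j in seq_len(width)) {
      cx <- j - 0.5
      best_z <- -Inf
      best_rgb <- background
      for (a in seq_along(px)) {
        d2 <- (cx - px[a])^2 + (cy - py[a])^2
        if (d2 > pr[a]^2) next
        h <- sqrt(pr[a]^2 - d2)
        zs <- pz[a] + h
        if (zs > best_z) {
          best_z <- zs
          inten <- 0.35 + 0.65 * h / pr[a]
          best_rgb <- pmin(as.integer(floor(cols[a, ] * inten + 0.5)), 255L)
        }
      }
      p <- ((i - 1L) * width + (j - 1L)) * 3L
      out[p + 1:3] <- best_rgb
    }
  }
  out
}
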