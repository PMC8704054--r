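test_that("parse_pdb reads fixed columns, altlocs and MODEL blocks", {
  txt <- paste(c(
    pdb_line(1, "N", "ALA", "A", 1, 1.1, 2.2, 3.3),
    pdb_line(2, "CA", "ALA", "A", 1, 4.4, 5.5, 6.6),
    pdb_line(3, "CA", "GLY", "A", 2, 7.7, 8.8, 9.9)
  ), collapse = "\n")
  m <- parse_pdb(txt)
  expect_equal(nrow(m$atoms), 3)
  expect_equal(m$atoms$x, c(1.1, 4.4, 7.7))
  expect_equal(m$atoms$residue_name, c("ALA", "ALA", "GLY"))
  expect_equal(m$atoms$element, c("N", "C", "C"))

  # altloc: keep the 0.6 conformer
  alt <- paste(c(
    pdb_line(1, "CA", "SER", "A", 1, 0, 0, 0, occ = 0.4, altloc = "A"),
    pdb_line(2, "CA", "SER", "A", 1, 9, 9, 9, occ = 0.6, altloc = "B"),
    pdb_line(3, "CA", "GLY", "A", 2, 1, 1, 1)
  ), collapse = "\n")
  ma <- parse_pdb(alt)
  expect_equal(nrow(ma$atoms), 2)
  expect_equal(ma$atoms$x[1], 9)

  # altloc occupancy tie prefers 'A'
  tie <- paste(c(
    pdb_line(1, "CA", "SER", "A", 1, 0, 0, 0, occ = 0.5, altloc = "A"),
    pdb_line(2, "CA", "SER", "A", 1, 9, 9, 9, occ = 0.5, altloc = "B")
  ), collapse = "\n")
  expect_equal(parse_pdb(tie)$atoms$x, 0)

  # MODEL selection
  multi <- paste(c("MODEL        1",
                   pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
                   "ENDMDL", "MODEL        2",
                   pdb_line(1, "CA", "GLY", "A", 1, 5, 0, 0),
                   "ENDMDL"), collapse = "\n")
  expect_equal(parse_pdb(multi)$atoms$x, 0)
  expect_equal(parse_pdb(multi, model_index = 2)$atoms$x, 5)

  # HETATM ignored by default
  het <- paste(c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
                 sub("^ATOM  ", "HETATM", pdb_line(2, "O", "HOH", "A", 90, 1, 1, 1))),
               collapse = "\n")
  expect_equal(nrow(parse_pdb(het)$atoms), 1)
  expect_equal(nrow(parse_pdb(het, keep_hetatm = TRUE)$atoms), 2)

  expect_error(parse_pdb("REMARK nothing\n"), "no ATOM records")
  bad <- pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0)
  substr(bad, 32, 36) <- "xxxxx"
  expect_error(parse_pdb(paste0("REMARK\n", bad)), "line 2")
})

test_that("write_pdb round-trips through parse_pdb", {
  set.seed(51)
  b <- build_bundle(3, helix_spec(10))
  back <- parse_pdb(write_pdb(b), model_id = b$model_id)
  expect_equal(back$atoms$residue_seq, b$atoms$residue_seq)
  expect_equal(back$atoms$residue_name, b$atoms$residue_name)
  expect_equal(back$atoms$x, round(b$atoms$x, 3))
  expect_equal(back$atoms$y, round(b$atoms$y, 3))
})

test_that("match_residues pairs common numbering and requires the atom", {
  mk <- function(id, resis, names = "GLY", drop_ca_at = integer()) {
    atoms <- do.call(rbind, lapply(seq_along(resis), function(i) {
      r <- resis[i]
      df <- data.frame(chain = "A", residue_seq = r, residue_name = names,
                       atom_name = c("N", "CA"), element = c("N", "C"),
                       x = r, y = 0, z = 0, stringsAsFactors = FALSE)
      if (r %in% drop_ca_at) df <- df[df$atom_name != "CA", ]
      df
    }))
    structure_model(id, atoms)
  }
  a <- mk("a", 1:10)
  b <- mk("b", 5:15)
  p <- match_residues(a, b)
  expect_equal(p$residue_seq, 5:10)

  expect_error(match_residues(mk("a", 1:5), mk("b", 10:12)), "no common")
  p2 <- match_residues(mk("a", 1:10, drop_ca_at = 7), b)
  expect_equal(p2$residue_seq, c(5, 6, 8, 9, 10))
})

test_that("Kabsch recovers rigid motions exactly and matches the quaternion oracle", {
  set.seed(52)
  X <- matrix(rnorm(30), 10, 3)
  idsup <- kabsch_superpose(X, X)
  expect_equal(idsup$rmsd, 0, tolerance = 1e-10)
  expect_equal(idsup$rotation, diag(3), tolerance = 1e-8)

  # exact rigid motion: 37 degrees about z plus translation
  th <- 37 * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
               byrow = TRUE)
  Y <- apply_rigid(X, Rz, c(5, -2, 9))
  sup <- kabsch_superpose(X, Y)
  expect_lt(sup$rmsd, 1e-6)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-6)

  # 100 random instances vs Horn's quaternion method
  for (k in 1:100) {
    n <- sample(4:40, 1)
    A <- matrix(rnorm(3 * n), n, 3)
    B <- matrix(rnorm(3 * n), n, 3)
    kab <- kabsch_superpose(A, B)
    qua <- quaternion_superpose_oracle(A, B)
    expect_lt(abs(kab$rmsd - qua$rmsd), 1e-6)
    expect_lt(max(abs(kab$rotation - qua$rotation)), 1e-6)
    expect_equal(det(kab$rotation), 1, tolerance = 1e-6)
  }

  # mirror-image input must not be solved by a reflection
  M <- X
  M[, 3] <- -M[, 3]
  mir <- kabsch_superpose(X, M)
  expect_equal(det(mir$rotation), 1, tolerance = 1e-6)
  expect_gt(mir$rmsd, 0)

  expect_error(kabsch_superpose(X[1:2, ], X[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("RMSD is invariant under proper rigid motions of either input", {
  set.seed(53)
  A <- matrix(rnorm(45), 15, 3)
  B <- A + matrix(rnorm(45, sd = 0.3), 15, 3)
  base <- kabsch_superpose(A, B)$rmsd
  for (k in 1:20) {
    R1 <- random_rotation(); t1 <- rnorm(3, sd = 10)
    R2 <- random_rotation(); t2 <- rnorm(3, sd = 10)
    expect_lt(abs(kabsch_superpose(apply_rigid(A, R1, t1),
                                   apply_rigid(B, R2, t2))$rmsd - base),
              1e-6)
  }
})

test_that("trim_to_segments keeps exactly the TM residues", {
  b <- build_bundle(2, helix_spec(20))  # residues 1..40
  ann <- segment_annotation("b", data.frame(
    label = c("TM1", "TM2"), kind = "TM", start = c(5, 25), end = c(15, 30)))
  tr <- trim_to_segments(b, ann)
  expect_setequal(unique(tr$atoms$residue_seq), c(5:15, 25:30))
  expect_lte(nrow(tr$atoms), nrow(b$atoms))
  far <- segment_annotation("b", data.frame(label = "TM1", kind = "TM",
                                            start = 900, end = 950))
  expect_error(trim_to_segments(b, far), "covers no residue")
})

test_that("ideal helix geometry: rise, twist, pitch, extent, CA spacing", {
  h <- build_ideal_helix(helix_spec(36))
  z <- h$atoms$z
  expect_equal(max(z) - min(z), 35 * 1.5, tolerance = 1e-9)

  g <- helix_geometry(h)
  expect_equal(g$rise_per_residue, 1.5, tolerance = 1e-3)
  expect_lt(abs(g$twist_per_residue - 100), 0.1)
  expect_equal(g$residues_per_turn, 3.6, tolerance = 1e-3)
  expect_lt(abs(g$pitch - 5.4), 0.01)
  expect_equal(g$radius, 2.3, tolerance = 1e-3)

  # consecutive CA-CA distances are constant
  xyz <- as.matrix(h$atoms[, c("x", "y", "z")])
  d <- sqrt(rowSums(diff(xyz)^2))
  expect_lt(diff(range(d)), 1e-9)

  # geometry survives an arbitrary rigid motion
  set.seed(54)
  moved <- transform_model(h, kabsch_superpose(
    apply_rigid(xyz, random_rotation(), rnorm(3, sd = 20)), xyz))
  g2 <- helix_geometry(moved)
  expect_equal(g2$rise_per_residue, 1.5, tolerance = 1e-3)
  expect_equal(g2$residues_per_turn, 3.6, tolerance = 1e-3)
})

test_that("bundles have the right atom counts, symmetry and rigid-motion RMSD", {
  b <- build_bundle(7, helix_spec(26))
  expect_equal(nrow(b$atoms), 182)
  expect_equal(nrow(build_bundle(7, helix_spec(22))$atoms), 154)

  # helix-axis xy positions average to the origin; 18 consecutive residues
  # at 100 deg spacing sum their helical offsets to exactly zero (5 turns),
  # so the mean over the first 18 residues of a helix IS its axis position
  res_per <- 26
  helix_of <- (b$atoms$residue_seq - 1) %/% res_per
  axis_xy <- t(vapply(split(seq_len(nrow(b$atoms)), helix_of), function(ii) {
    ii <- ii[order(b$atoms$residue_seq[ii])][1:18]
    c(mean(b$atoms$x[ii]), mean(b$atoms$y[ii]))
  }, c(0, 0)))
  expect_equal(unname(sqrt(rowSums(axis_xy^2))), rep(9.5, 7),
               tolerance = 1e-6)
  expect_lt(abs(mean(axis_xy[, 1])), 1e-6)
  expect_lt(abs(mean(axis_xy[, 2])), 1e-6)

  set.seed(55)
  xyz <- as.matrix(b$atoms[, c("x", "y", "z")])
  moved <- b
  m2 <- apply_rigid(xyz, random_rotation(), rnorm(3, sd = 15))
  moved$atoms$x <- m2[, 1]; moved$atoms$y <- m2[, 2]; moved$atoms$z <- m2[, 3]
  sup <- superpose_models(b, moved)
  expect_lt(sup$superposition$rmsd, 1e-6)
  expect_equal(sup$superposition$n_matched, 182)

  # sequence + annotation drive residue naming and numbering
  sx <- synth_7tm_sequence(8)
  bb <- build_bundle(sequence = sx$record, annotation = sx$annotation)
  tm <- sx$annotation$segments[sx$annotation$segments$kind == "TM", ]
  expect_equal(nrow(bb$atoms), sum(tm$end - tm$start + 1))
  one <- strsplit(sx$record$sequence, "")[[1]]
  expect_equal(unname(bb$atoms$residue_name),
               unname(qtykit:::ONE_TO_THREE[one[bb$atoms$residue_seq]]))
})

test_that("superpose_models guards against mispaired chains", {
  b1 <- build_bundle(2, helix_spec(15), sequence = NULL)
  poly_l <- build_ideal_helix(helix_spec(30), sequence = strrep("L", 30))
  # all-ALA vs all-LEU with shared numbering: 0% identity -> guard trips
  expect_error(superpose_models(build_ideal_helix(helix_spec(30)), poly_l),
               "mispaired")
})
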