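test_that("point mutations are applied and validated with author numbering", {
  expect_equal(humanize(protein_sequence("toy", "AFA"),
                        list(c(2, "F", "L")))$residues, "ALA")
  s <- protein_sequence("toy", "AFA")
  expect_identical(humanize(s, list())$residues, s$residues)
  expect_error(humanize(s, list(c(2, "Y", "L"))), "position 2.*found F")
  expect_error(humanize(s, list(c(9, "F", "L"))), "outside")
  # author numbering offsets shift the coordinate system
  off <- protein_sequence("off", "AFA", numbering_offset = 1101)
  expect_equal(humanize(off, list(c(1102, "F", "L")))$residues, "ALA")
})

test_that("a two-site phenylalanine-to-leucine humanization edits exactly those sites", {
  set.seed(60)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  res <- sample(aa, 200, replace = TRUE)
  res[c(57, 111)] <- "F"
  seq <- protein_sequence("homolog", paste(res, collapse = ""),
                          numbering_offset = 1051)
  hum <- humanize(seq, list(c(1107, "F", "L"), c(1161, "F", "L")))
  diffs <- which(strsplit(hum$residues, "")[[1]] !=
                   strsplit(seq$residues, "")[[1]])
  expect_equal(diffs, c(57, 111))
  expect_equal(substr(hum$residues, 57, 57), "L")
  expect_equal(substr(hum$residues, 111, 111), "L")
})

test_that("identical sequences align at 100% identity with no gaps", {
  al <- global_align("HEAGAWGHEE", "HEAGAWGHEE")
  expect_equal(al$identity_pct, 100)
  expect_false(grepl("-", al$aligned_a))
  expect_false(grepl("-", al$aligned_b))
  g <- glance(al)
  expect_equal(g$identity_pct, 100)
  expect_equal(g$matrix_name, "BLOSUM62")
})

test_that("alignment scores match brute-force enumeration on short pairs", {
  mat <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  set.seed(71)
  alphabet <- c("A", "C", "D", "E")
  for (rep in 1:30) {
    a <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(alphabet, sample(1:6, 1), replace = TRUE),
               collapse = "")
    al <- global_align(a, b)
    expect_equal(al$score, brute_force_align_score(a, b, mat),
                 info = paste(a, b))
    # degapped aligned strings reproduce the inputs
    expect_equal(gsub("-", "", al$aligned_a), a)
    expect_equal(gsub("-", "", al$aligned_b), b)
  }
})

test_that("unknown substitution matrices are rejected", {
  expect_error(global_align("ACD", "ACE", matrix_name = "NOSUCH"),
               "unknown substitution matrix")
})

test_that("Kabsch superposition recovers applied rigid transforms", {
  set.seed(81)
  for (rep in 1:10) {
    A <- matrix(rnorm(3 * 20, sd = 8), ncol = 3)
    R <- random_rotation()
    t <- rnorm(3, sd = 20)
    B <- sweep(A %*% R, 2, t, "+")   # move A away; recover it from B
    sup <- superpose(A, B)
    expect_lt(sup$rmsd, 1e-6)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
    fitted <- sweep(B %*% t(sup$rotation), 2, sup$translation, "+")
    expect_lt(max(abs(fitted - A)), 1e-6)
  }
  # identity case
  A <- matrix(rnorm(30), ncol = 3)
  expect_lt(superpose(A, A)$rmsd, 1e-12)
})

test_that("superposition RMSD agrees with an independent least-squares fit", {
  set.seed(85)
  for (rep in 1:5) {
    A <- matrix(rnorm(3 * 30, sd = 6), ncol = 3)
    B <- A + matrix(rnorm(3 * 30, sd = 0.8), ncol = 3)  # noisy copy
    ours <- superpose(A, B)$rmsd
    fitted <- bio3d::fit.xyz(fixed = as.numeric(t(A)),
                             mobile = as.numeric(t(B)),
                             fixed.inds = 1:90, mobile.inds = 1:90)
    ref <- sqrt(mean(rowSums((A - matrix(fitted, ncol = 3,
                                         byrow = TRUE))^2)))
    expect_equal(ours, ref, tolerance = 1e-6)
  }
})

test_that("reflections are rejected: proper rotation enforced", {
  set.seed(82)
  A <- matrix(rnorm(3 * 15, sd = 5), ncol = 3)
  B <- A %*% diag(c(-1, 1, 1))   # mirror image
  sup <- superpose(A, B)
  expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  expect_gt(sup$rmsd, 0.1)   # a mirror cannot be fit by a proper rotation
})

test_that("degenerate and undersized coordinate sets are rejected", {
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))   # collinear
  expect_error(superpose(line, line), "collinear")
  A <- matrix(rnorm(6), ncol = 3)
  expect_error(superpose(A, A), "at least 3")
  expect_error(superpose(matrix(rnorm(9), 3), matrix(rnorm(12), 4)),
               "equal length")
})

test_that("iterative superposition of a chain against itself is exact", {
  s <- make_ca_structure(n = 60, seed = 90)
  sup <- iterative_superpose(s, s, "A", "A")
  expect_lt(sup$rmsd, 1e-10)
  expect_equal(nrow(sup$matched_pairs), 60)
  expect_equal(glance(sup)$det_rotation, 1, tolerance = 1e-9)
})

test_that("iterative superposition rejects planted outliers and converges", {
  s <- make_ca_structure(n = 60, seed = 91)
  atoms_b <- s$atoms
  set.seed(92)
  moved <- sample(60, 6)   # 10% of residues displaced by 8 A
  atoms_b$x[moved] <- atoms_b$x[moved] + 8
  # and a global rigid motion on top
  R <- random_rotation(); t <- rnorm(3, sd = 15)
  xyz <- sweep(as.matrix(atoms_b[, c("x", "y", "z")]) %*% t(R), 2, t, "+")
  atoms_b$x <- xyz[, 1]; atoms_b$y <- xyz[, 2]; atoms_b$z <- xyz[, 3]
  sb <- plifscreen:::new_structure(atoms_b, "MOVED")

  sup <- iterative_superpose(s, sb, "A", "A")
  expect_lt(sup$rmsd, 0.1)
  expect_gte(sup$cycles_run, 2)
  expect_equal(nrow(sup$matched_pairs), 54)
  expect_false(any(moved %in% sup$matched_pairs$residue_a))
  expect_true(all(tidy(sup)$deviation <= 2.0))
})

test_that("final RMSD is invariant to pre-rotating both structures together", {
  s <- make_ca_structure(n = 50, seed = 93)
  atoms_b <- s$atoms
  set.seed(94)
  idx <- sample(50, 4)
  atoms_b$y[idx] <- atoms_b$y[idx] + 7
  sb <- plifscreen:::new_structure(atoms_b, "B")
  r0 <- iterative_superpose(s, sb, "A", "A")$rmsd
  R <- random_rotation(); t <- rnorm(3, sd = 30)
  r1 <- iterative_superpose(transform_structure(s, R, t),
                            transform_structure(sb, R, t), "A", "A")$rmsd
  expect_equal(r0, r1, tolerance = 1e-6)
})

test_that("rejection cycles never increase the RMSD", {
  s <- make_ca_structure(n = 80, seed = 95)
  atoms_b <- s$atoms
  set.seed(96)
  idx <- sample(80, 12)
  atoms_b$z[idx] <- atoms_b$z[idx] + runif(12, 2.5, 9)
  sb <- plifscreen:::new_structure(atoms_b, "B")
  rmsds <- vapply(1:4, function(cy) {
    iterative_superpose(s, sb, "A", "A", cycles = cy)$rmsd
  }, numeric(1))
  expect_true(all(diff(rmsds) <= 1e-9))
})

test_that("binding-site residues map onto themselves and across renumbering", {
  cm <- make_complex(list(planted_spec("hbond", distance = 2.9),
                          planted_spec("hydrophobic", distance = 3.6),
                          planted_spec("halogen", distance = 3.3)),
                     seed = 97)
  s <- parse_structure(cm$pdb)
  site <- binding_site(s, s$ligands[1, ], cutoff = 7.5)
  ca <- s$atoms[s$atoms$name == "CA" & !s$atoms$is_het, ]
  identity_sup <- superpose(as.matrix(ca[, c("x", "y", "z")]),
                            as.matrix(ca[, c("x", "y", "z")]))

  self_map <- map_binding_site_residues(identity_sup, site, s)
  expect_true(all(self_map$mapped))
  expect_equal(self_map$residue_b, self_map$residue_a)
  expect_true(all(self_map$ca_distance < 1e-9))
  expect_true(all(self_map$part_matched))

  atoms_b <- s$atoms
  atoms_b$residue_number <- atoms_b$residue_number + 100L
  sb <- plifscreen:::new_structure(atoms_b, "RENUM")
  offset_map <- map_binding_site_residues(identity_sup, site, sb)
  expect_true(all(offset_map$mapped))
  expect_equal(offset_map$residue_b, offset_map$residue_a + 100L)
})

test_that("site residues without a close partner are reported unmapped", {
  cm <- make_complex(list(planted_spec("hbond", distance = 2.9),
                          planted_spec("hydrophobic", distance = 3.6),
                          planted_spec("halogen", distance = 3.3)),
                     seed = 98)
  s <- parse_structure(cm$pdb)
  site <- binding_site(s, s$ligands[1, ], cutoff = 7.5)
  ca <- s$atoms[s$atoms$name == "CA" & !s$atoms$is_het, ]
  identity_sup <- superpose(as.matrix(ca[, c("x", "y", "z")]),
                            as.matrix(ca[, c("x", "y", "z")]))
  # delete one site residue's CA from the partner structure
  victim <- site$protein_atoms$residue_number[1]
  atoms_b <- s$atoms[!(s$atoms$residue_number == victim &
                         s$atoms$name == "CA"), ]
  sb <- plifscreen:::new_structure(atoms_b, "GAPPED")
  m <- map_binding_site_residues(identity_sup, site, sb)
  expect_false(m$mapped[m$residue_a == victim])
  expect_true(all(m$mapped[m$residue_a != victim]))
})
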