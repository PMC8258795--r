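profile_lig <- function(cmplx, scope = "all-chains") {
  s <- parse_structure(cmplx$pdb)
  profile_complex(s, s$ligands[s$ligands$het_code == "LIG", ], scope = scope)
}

test_that("planted geometries are detected with correct metadata", {
  cm <- make_complex(list(
    planted_spec("hbond", distance = 2.9, donor_angle = 160,
                 protein_part = "backbone"),
    planted_spec("hbond", distance = 3.1, donor_angle = 150,
                 protein_part = "sidechain"),
    planted_spec("hydrophobic", distance = 3.8),
    planted_spec("halogen", distance = 3.3, donor_angle = 165,
                 acceptor_angle = 120)), seed = 21)
  pat <- profile_lig(cm)
  expect_equal(nrow(pat), 4)

  hb <- pat[pat$itype == "hbond", ]
  expect_equal(nrow(hb), 2)
  expect_setequal(hb$protein_part, c("backbone", "sidechain"))
  expect_true(all(hb$roles == "protein_donor"))
  expect_equal(sort(hb$distance), c(2.9, 3.1), tolerance = 1e-3)
  expect_equal(sort(hb$angle), c(150, 160), tolerance = 1e-2)

  hp <- pat[pat$itype == "hydrophobic", ]
  expect_equal(hp$distance, 3.8, tolerance = 1e-3)
  expect_equal(hp$protein_part, "sidechain")
  expect_equal(hp$residue_name, "LEU")
  expect_true(is.na(hp$angle))

  xb <- pat[pat$itype == "halogen", ]
  expect_equal(xb$distance, 3.3, tolerance = 1e-3)
  expect_equal(xb$angle, 165, tolerance = 1e-2)
  expect_equal(xb$protein_part, "backbone")
})

test_that("detector thresholds bracket correctly (epsilon inside/outside)", {
  eps_d <- 0.05
  eps_a <- 1
  # distance bracketing per type
  cases <- list(
    list(spec = planted_spec("hbond", distance = 4.1 - eps_d), n = 1),
    list(spec = planted_spec("hbond", distance = 4.1 + eps_d), n = 0),
    list(spec = planted_spec("hbond", distance = 3.0,
                             donor_angle = 100 + eps_a), n = 1),
    list(spec = planted_spec("hbond", distance = 3.0,
                             donor_angle = 100 - eps_a), n = 0),
    list(spec = planted_spec("hydrophobic", distance = 4.0 - eps_d), n = 1),
    list(spec = planted_spec("hydrophobic", distance = 4.0 + eps_d), n = 0),
    list(spec = planted_spec("halogen", distance = 4.0 - eps_d), n = 1),
    list(spec = planted_spec("halogen", distance = 4.0 + eps_d), n = 0),
    list(spec = planted_spec("halogen", distance = 3.3,
                             donor_angle = 135 + eps_a), n = 1),
    list(spec = planted_spec("halogen", distance = 3.3,
                             donor_angle = 135 - eps_a), n = 0),
    list(spec = planted_spec("halogen", distance = 3.3,
                             acceptor_angle = 150 - eps_a), n = 1),
    list(spec = planted_spec("halogen", distance = 3.3,
                             acceptor_angle = 150 + eps_a), n = 0))
  for (cs in cases) {
    cm <- make_complex(cs$spec, seed = 1)
    pat <- profile_lig(cm)
    expect_equal(nrow(pat), cs$n,
                 info = sprintf("%s d=%.2f da=%.0f aa=%.0f",
                                cs$spec$itype, cs$spec$distance,
                                cs$spec$donor_angle, cs$spec$acceptor_angle))
    expect_equal(nrow(pat), sum(manifest_expected(cm)))
  }
})

test_that("patterns are invariant under rigid motion of the whole complex", {
  cm <- make_complex(list(planted_spec("hbond", distance = 2.9),
                          planted_spec("hydrophobic", distance = 3.7),
                          planted_spec("halogen", distance = 3.4)),
                     seed = 13)
  s <- parse_structure(cm$pdb)
  pat0 <- profile_complex(s, s$ligands[1, ])
  set.seed(99)
  for (rep in 1:3) {
    st <- transform_structure(s, random_rotation(), rnorm(3, sd = 10))
    pat1 <- profile_complex(st, st$ligands[1, ])
    expect_equal(pat1$itype, pat0$itype)
    expect_equal(pat1$distance, pat0$distance, tolerance = 1e-6)
    expect_equal(pat1$angle, pat0$angle, tolerance = 1e-6)
    expect_equal(pat1$residue_number, pat0$residue_number)
  }
})

test_that("no ligand-ligand or protein-protein pairs are ever reported", {
  cm <- make_complex(list(planted_spec("hbond", distance = 2.9),
                          planted_spec("halogen", distance = 3.2)),
                     seed = 31)
  s <- parse_structure(cm$pdb)
  pat <- profile_complex(s, s$ligands[1, ])
  lig_serials <- s$ligands$atoms[[1]]$serial
  expect_true(all(pat$lig_serial %in% lig_serials))
  expect_true(all(!pat$prot_serial %in% lig_serials))
})

test_that("detection is deterministic (byte-identical serialized patterns)", {
  cm <- make_complex(list(planted_spec("hbond", distance = 3.0),
                          planted_spec("hydrophobic", distance = 3.5)),
                     seed = 8)
  j1 <- pattern_to_json(profile_lig(cm))
  j2 <- pattern_to_json(profile_lig(cm))
  expect_identical(as.character(j1), as.character(j2))
})

test_that("pattern JSON serialization round-trips", {
  cm <- make_complex(list(planted_spec("halogen", distance = 3.4),
                          planted_spec("hbond", distance = 3.0)), seed = 4)
  pat <- profile_lig(cm)
  back <- pattern_from_json(pattern_to_json(pat))
  expect_equal(as.data.frame(back), as.data.frame(pat), tolerance = 1e-12)
  expect_equal(attr(back, "complex_id"), attr(pat, "complex_id"))
  # empty pattern round-trips too
  empty <- plifscreen:::new_pattern(plifscreen:::interaction_cols(), "empty")
  back2 <- pattern_from_json(pattern_to_json(empty))
  expect_equal(nrow(back2), 0)
})

test_that("distant donor-acceptor pairs and apolar-free ligands yield nothing", {
  cm <- make_complex(planted_spec("hbond", distance = 5.5), seed = 2)
  pat <- profile_lig(cm)
  expect_equal(nrow(pat[pat$itype == "hbond", ]), 0)
  expect_equal(manifest_expected(cm)[1], 0L)
})
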