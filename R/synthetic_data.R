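#' Specify one planted protein-ligand interaction
#'
#' Describes the geometry of a single interaction that [make_complex()]
#' realises exactly in a generated complex: the heavy-atom distance, the
#' donor angle (hydrogen and halogen bonds), the acceptor angle (halogen
#' bonds), the protein residue and whether the protein anchor is a
#' backbone or sidechain atom.
#'
#' @param itype `"hbond"`, `"hydrophobic"` or `"halogen"`.
#' @param distance Anchor-anchor distance in Angstrom.
#' @param donor_angle Antecedent-donor-acceptor angle in degrees (hbond:
#'   X-D...A; halogen: C-X...A).
#' @param acceptor_angle Y-A...X angle in degrees (halogen bonds only).
#' @param protein_part `"backbone"` or `"sidechain"` (hydrogen bonds only;
#'   hydrophobic contacts are always sidechain, halogen-bond acceptors
#'   backbone).
#' @param jitter Uniform placement jitter on the distance in Angstrom
#'   (default 0, i.e. exact placement).
#' @return A list of class `plif_spec`.
#' @export
planted_spec <- function(itype = c("hbond", "hydrophobic", "halogen"),
                         distance = 3.0, donor_angle = 160,
                         acceptor_angle = 120,
                         protein_part = c("backbone", "sidechain"),
                         jitter = 0) {
  itype <- match.arg(itype)
  protein_part <- match.arg(protein_part)
  stopifnot(distance > 0, donor_angle >= 0, donor_angle <= 180,
            acceptor_angle >= 0, acceptor_angle <= 180, jitter >= 0)
  if (itype == "hydrophobic" && distance < 2.7) {
    abort("hydrophobic specs need distance >= 2.7 A; closer placements create ambiguous secondary contacts")
  }
  structure(list(itype = itype, distance = distance,
                 donor_angle = donor_angle, acceptor_angle = acceptor_angle,
                 protein_part = protein_part, jitter = jitter),
            class = "plif_spec")
}

atom_row <- function(serial, name, element, xyz, residue_name, chain_id,
                     residue_number, is_het) {
  tibble(serial = as.integer(serial), name = name, altloc = "",
         residue_name = residue_name, chain_id = chain_id,
         residue_number = as.integer(residue_number), insertion_code = "",
         x = round(xyz[1], 3), y = round(xyz[2], 3), z = round(xyz[3], 3),
         occupancy = 1, element = element, is_het = is_het)
}

#' Generate a synthetic complex with planted interaction geometries
#'
#' Builds a het-group ligand (a short aliphatic carbon core with one
#' anchor atom per planted interaction) and one protein residue per
#' interaction arm, placed so that each spec's distance and angles are
#' realised exactly (up to the requested jitter). Interaction arms radiate
#' from the ligand core with enough angular separation that no unintended
#' contact falls inside any detection cutoff. Decoy residues, a water and a
#' small buffer het group are placed far outside all cutoffs. The returned
#' manifest records the realised geometry and the detections expected from
#' it under the supplied thresholds, computed by threshold arithmetic (not
#' by running the detectors), so it can serve as independent ground truth.
#'
#' @param specs A [planted_spec()] or list of up to six of them.
#' @param seed Integer seed (used only when any spec has jitter > 0).
#' @param decoys Include decoy scaffold residues and excluded het groups.
#' @param config The [interaction_config()] used for expected-detection
#'   arithmetic.
#' @param entry_id Entry id written into the manifest.
#' @return List with `pdb` (PDB-format text), `atoms` (the atom tibble) and
#'   `manifest` (seed, atom counts, per-spec realised geometry, expected
#'   detection counts per type).
#' @export
make_complex <- function(specs, seed = 1L, decoys = TRUE,
                         config = interaction_config(),
                         entry_id = "SYNTH") {
  if (inherits(specs, "plif_spec")) specs <- list(specs)
  n <- length(specs)
  stopifnot(n >= 1)
  if (n > 6) {
    abort("cannot realise more than 6 interaction arms without steric conflicts")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  n_core <- max(5L, 2L * n + 1L)
  core_x <- (seq_len(n_core) - 1) * 1.5
  lig_atoms <- list()
  for (i in seq_len(n_core)) {
    lig_atoms[[i]] <- list(name = sprintf("C%d", i), element = "C",
                           xyz = c(core_x[i], 0, 0))
  }
  prot_atoms <- list()
  add_prot <- function(resname, resno, atoms) {
    for (a in atoms) {
      a$resname <- resname; a$resno <- resno
      prot_atoms[[length(prot_atoms) + 1]] <<- a
    }
  }

  xhat <- c(1, 0, 0)
  realized <- vector("list", n)
  for (k in seq_len(n)) {
    sp <- specs[[k]]
    d <- sp$distance +
      if (sp$jitter > 0) runif(1, -sp$jitter, sp$jitter) else 0
    phi <- (k - 1) * 2 * pi / max(n, 3)
    u <- c(0, cos(phi), sin(phi))
    w <- xhat
    cidx <- 2L * k
    cpos <- c(core_x[cidx], 0, 0)
    resno <- 100L + k

    if (sp$itype == "hbond") {
      lig_anchor <- cpos + 1.40 * u
      lig_atoms[[length(lig_atoms) + 1]] <-
        list(name = sprintf("O%d", k), element = "O", xyz = lig_anchor)
      theta <- sp$donor_angle * pi / 180
      if (sp$protein_part == "backbone") {
        don <- lig_anchor + d * u
        v <- -u
        ca <- don + 1.47 * (cos(theta) * v + sin(theta) * w)
        cc <- ca + 1.52 * u
        oo <- cc + 1.23 * u
        add_prot("GLY", resno, list(
          list(name = "N", element = "N", xyz = don),
          list(name = "CA", element = "C", xyz = ca),
          list(name = "C", element = "C", xyz = cc),
          list(name = "O", element = "O", xyz = oo)))
        prot_anchor <- don
      } else {
        og <- lig_anchor + d * u
        v <- -u
        cb <- og + 1.43 * (cos(theta) * v + sin(theta) * w)
        ca <- cb + 1.53 * u
        nn <- ca + 1.47 * unit_vec(u + 0.4 * w)
        cc <- ca + 1.52 * unit_vec(u - 0.4 * w)
        oo <- cc + 1.23 * u
        add_prot("SER", resno, list(
          list(name = "N", element = "N", xyz = nn),
          list(name = "CA", element = "C", xyz = ca),
          list(name = "C", element = "C", xyz = cc),
          list(name = "O", element = "O", xyz = oo),
          list(name = "CB", element = "C", xyz = cb),
          list(name = "OG", element = "O", xyz = og)))
        prot_anchor <- og
      }
      expected <- as.integer(d <= config$hbond_dist_max &&
                               sp$donor_angle >= config$hbond_angle_min)
      resname <- if (sp$protein_part == "backbone") "GLY" else "SER"
    } else if (sp$itype == "hydrophobic") {
      lig_anchor <- cpos + 1.40 * u
      lig_atoms[[length(lig_atoms) + 1]] <-
        list(name = sprintf("CM%d", k), element = "C", xyz = lig_anchor)
      cd1 <- lig_anchor + d * u
      cg <- cd1 + 1.53 * u
      cd2 <- cg + 1.53 * unit_vec(0.5 * u + 0.866 * w)
      cb <- cg + 1.53 * unit_vec(0.8 * u - 0.6 * w)
      ca <- cb + 1.54 * u
      nn <- ca + 1.47 * unit_vec(u + 0.4 * w)
      cc <- ca + 1.52 * unit_vec(u - 0.4 * w)
      oo <- cc + 1.23 * u
      add_prot("LEU", 100L + k, list(
        list(name = "N", element = "N", xyz = nn),
        list(name = "CA", element = "C", xyz = ca),
        list(name = "C", element = "C", xyz = cc),
        list(name = "O", element = "O", xyz = oo),
        list(name = "CB", element = "C", xyz = cb),
        list(name = "CG", element = "C", xyz = cg),
        list(name = "CD1", element = "C", xyz = cd1),
        list(name = "CD2", element = "C", xyz = cd2)))
      prot_anchor <- cd1
      expected <- as.integer(d <= config$hydrophobic_dist_max)
      resname <- "LEU"
    } else {  # halogen
      lig_anchor <- cpos + 1.80 * u
      lig_atoms[[length(lig_atoms) + 1]] <-
        list(name = sprintf("CL%d", k), element = "CL", xyz = lig_anchor)
      thd <- sp$donor_angle * pi / 180
      acc <- lig_anchor + d * (cos(thd) * unit_vec(cpos - lig_anchor) +
                                 sin(thd) * w)
      xhat_a <- unit_vec(lig_anchor - acc)
      w3 <- u - sum(u * xhat_a) * xhat_a
      w3 <- if (vec_norm(w3) < 1e-8) w else unit_vec(w3)
      tha <- sp$acceptor_angle * pi / 180
      cy <- acc + 1.23 * (cos(tha) * xhat_a + sin(tha) * w3)
      # CA placed directly away from the acceptor O so the carbonyl C stays
      # its only bonded antecedent (keeps the manifest arithmetic exact).
      ca <- cy + 1.52 * unit_vec(cy - acc)
      nn <- ca + 1.47 * u
      add_prot("GLY", 100L + k, list(
        list(name = "N", element = "N", xyz = nn),
        list(name = "CA", element = "C", xyz = ca),
        list(name = "C", element = "C", xyz = cy),
        list(name = "O", element = "O", xyz = acc)))
      prot_anchor <- acc
      expected <- as.integer(
        d <= config$halogen_dist_max &&
          abs(sp$donor_angle - config$halogen_donor_angle) <=
            config$halogen_donor_tol &&
          abs(sp$acceptor_angle - config$halogen_acceptor_angle) <=
            config$halogen_acceptor_tol)
      resname <- "GLY"
    }
    realized[[k]] <- tibble(
      arm = k, itype = sp$itype, distance = d,
      donor_angle = sp$donor_angle, acceptor_angle = sp$acceptor_angle,
      residue_name = resname, residue_number = 100L + k,
      protein_part = if (sp$itype == "hbond") sp$protein_part else
        if (sp$itype == "hydrophobic") "sidechain" else "backbone",
      lig_x = lig_anchor[1], lig_y = lig_anchor[2], lig_z = lig_anchor[3],
      prot_x = prot_anchor[1], prot_y = prot_anchor[2],
      prot_z = prot_anchor[3],
      expected = expected)
  }

  # Decoy scaffold far outside every cutoff.
  if (decoys) {
    for (r in 1:5) {
      base <- c((r - 1) * 4.0, -30, 0)
      add_prot("ALA", r, list(
        list(name = "N", element = "N", xyz = base),
        list(name = "CA", element = "C", xyz = base + c(1.4, 0.3, 0)),
        list(name = "C", element = "C", xyz = base + c(2.4, -0.6, 0)),
        list(name = "O", element = "O", xyz = base + c(2.4, -1.8, 0)),
        list(name = "CB", element = "C", xyz = base + c(1.4, 1.6, 0.9))))
    }
  }

  serial <- 0L
  rows <- list()
  for (a in prot_atoms) {
    serial <- serial + 1L
    rows[[length(rows) + 1]] <- atom_row(serial, a$name, a$element, a$xyz,
                                         a$resname, "A", a$resno, FALSE)
  }
  for (a in lig_atoms) {
    serial <- serial + 1L
    rows[[length(rows) + 1]] <- atom_row(serial, a$name, a$element, a$xyz,
                                         "LIG", "A", 900L, TRUE)
  }
  if (decoys) {
    serial <- serial + 1L
    rows[[length(rows) + 1]] <- atom_row(serial, "O", "O", c(0, -40, 0),
                                         "HOH", "A", 901L, TRUE)
    act <- list(c(10, -40, 0), c(11.5, -40, 0), c(12.2, -39, 0),
                c(12.2, -41, 0))
    for (i in 1:4) {
      serial <- serial + 1L
      rows[[length(rows) + 1]] <- atom_row(
        serial, c("C1", "C2", "O1", "O2")[i], c("C", "C", "O", "O")[i],
        act[[i]], "ACT", "A", 902L, TRUE)
    }
  }
  atoms <- bind_rows(rows)

  # Steric feasibility: atoms of different residues are never covalently
  # bonded here, so any inter-residue pair closer than 1.5 A is a clash.
  dmat <- cross_dist(coords_matrix(atoms), coords_matrix(atoms))
  res_id <- residue_key(atoms$chain_id, atoms$residue_number,
                        atoms$insertion_code)
  inter <- outer(res_id, res_id, "!=") & upper.tri(dmat)
  if (any(dmat[inter] < 1.5)) {
    abort("unrealizable spec: placements overlap (non-bonded atoms < 1.5 A apart)")
  }

  realized <- bind_rows(realized)
  expected_counts <- realized |>
    group_by(.data$itype) |>
    summarise(n = sum(.data$expected), .groups = "drop")
  exp_list <- setNames(as.list(expected_counts$n), expected_counts$itype)
  for (t in c("hbond", "hydrophobic", "halogen")) {
    if (is.null(exp_list[[t]])) exp_list[[t]] <- 0L
  }

  list(
    pdb = paste(write_pdb_text(atoms), collapse = "\n"),
    atoms = atoms,
    manifest = list(
      entry_id = entry_id, seed = seed, n_atoms = nrow(atoms),
      chain_layout = list(protein_chain = "A", ligand = "LIG A/900"),
      specs = realized,
      expected = exp_list[c("hbond", "hydrophobic", "halogen")]
    )
  )
}

#' Generate a random fingerprint library with planted near-duplicates
#'
#' Each random entry sets every bit independently with probability
#' `density`. Planted entries copy the query fingerprint with `flips`
#' random bits toggled, emulating near-identical interaction patterns
#' hiding in a large random background.
#'
#' @param n Number of random entries.
#' @param schema A [fingerprint_schema()].
#' @param density Expected on-bit fraction of random entries
#'   (`density * schema$length` must be >= 1).
#' @param query A `plif_fingerprint` to plant near-duplicates of (optional).
#' @param n_planted Number of planted near-duplicates.
#' @param flips Bits toggled per planted entry.
#' @param bg_sample Background pair sample size (see [build_library()]).
#' @param seed Integer seed.
#' @return A `plif_library`; planted entry ids are recorded in attribute
#'   `planted_ids` (het code `"PLT"`, random entries `"SYN"`).
#' @export
make_fingerprint_library <- function(n, schema = fingerprint_schema(),
                                     density = 0.01, query = NULL,
                                     n_planted = 0L, flips = 2L,
                                     bg_sample = 1e5, seed = 1L) {
  stopifnot(n >= 1, density > 0, density * schema$length >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  L <- schema$length
  entries <- tibble(
    complex_id = sprintf("SYN%05d", seq_len(n)),
    het_code = "SYN",
    on_bits = purrr::map(seq_len(n), function(i) which(runif(L) < density)))
  planted_ids <- character(0)
  if (n_planted > 0) {
    if (is.null(query)) abort("planting near-duplicates requires a query")
    planted <- tibble(
      complex_id = sprintf("PLT%02d", seq_len(n_planted)),
      het_code = "PLT",
      on_bits = purrr::map(seq_len(n_planted), function(i) {
        flip <- sample.int(L, flips)
        sort(union(setdiff(query$on_bits, flip),
                   setdiff(flip, query$on_bits)))
      }))
    planted_ids <- planted$complex_id
    entries <- bind_rows(entries, planted)
  }
  lib <- library_from_entries(entries, schema, bg_sample = bg_sample,
                              seed = seed)
  attr(lib, "planted_ids") <- planted_ids
  lib
}

#' Reference potency table of the screened candidate drugs
#'
#' In-vitro LRRK2 G2019S inhibition (IC50) and competitive binding (Kd)
#' results for the six repositioning candidates and the positive control,
#' packaged as a plain-text fixture for count-based checks. Censored
#' measurements carry a comparator flag (`<`, `>`); see the file's comment
#' header for transcription provenance notes.
#'
#' @return Tibble with `compound`, `role`, `ic50_nM`, `ic50_cmp`, `kd_nM`,
#'   `kd_cmp`.
#' @export
reference_potency <- function() {
  path <- system.file("extdata", "reference_potency.tsv",
                      package = "plifscreen")
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    compound = "c", role = "c", ic50_nM = "d",
                    ic50_cmp = "c", kd_nM = "d", kd_cmp = "c"))
}

#' Reference hit list of the virtual screening
#'
#' The queries and top hits of the structure-based screen (query complex,
#' hit complex, drug, approved use, predicted blood-brain-barrier
#' permeability), packaged for count-based checks.
#'
#' @return Tibble.
#' @export
reference_hits <- function() {
  path <- system.file("extdata", "reference_hits.tsv",
                      package = "plifscreen")
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Censoring-aware "measured below threshold" test
#'
#' A plain value is below `threshold` if `value < threshold`; a
#' left-censored value (`<bound`) is below whenever `bound <= threshold`;
#' a right-censored value (`>bound`) never satisfies the test.
#'
#' @param value Numeric vector of measurements.
#' @param cmp Comparator flags: `"="`, `"<"` or `">"`.
#' @param threshold Threshold on the same scale.
#' @return Logical vector.
#' @export
potency_below <- function(value, cmp, threshold) {
  dplyr::case_when(
    cmp == ">" ~ FALSE,
    cmp == "<" ~ value <= threshold,
    TRUE ~ value < threshold
  )
}
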