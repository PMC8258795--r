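#' Geometric thresholds for interaction detection
#'
#' Defaults follow the published profiler conventions for hydrogen-free
#' (heavy-atom) detection: hydrogen bonds at donor-acceptor distance
#' <= 4.1 A with antecedent angle >= 100 deg; hydrophobic carbon-carbon
#' contacts <= 4.0 A; halogen bonds at X...acceptor <= 4.0 A with donor
#' angle 165 +/- 30 deg and acceptor angle 120 +/- 30 deg.
#'
#' @param hbond_dist_max Hydrogen-bond donor-acceptor maximum distance (A).
#' @param hbond_angle_min Minimum antecedent-donor-acceptor angle (deg).
#' @param hydrophobic_dist_max Maximum apolar carbon-carbon distance (A).
#' @param halogen_dist_max Maximum halogen-acceptor distance (A).
#' @param halogen_donor_angle,halogen_donor_tol Ideal C-X...A angle and
#'   tolerance (deg).
#' @param halogen_acceptor_angle,halogen_acceptor_tol Ideal Y-A...X angle
#'   and tolerance (deg).
#' @param site_cutoff Binding-site distance cutoff (A).
#' @param min_ligand_atoms Minimum ligand heavy-atom count.
#' @return A list of class `plif_config`.
#' @export
interaction_config <- function(hbond_dist_max = 4.1,
                               hbond_angle_min = 100,
                               hydrophobic_dist_max = 4.0,
                               halogen_dist_max = 4.0,
                               halogen_donor_angle = 165,
                               halogen_donor_tol = 30,
                               halogen_acceptor_angle = 120,
                               halogen_acceptor_tol = 30,
                               site_cutoff = 7.5,
                               min_ligand_atoms = 5L) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg, function(x) is.numeric(x) && x > 0, logical(1))))
  structure(cfg, class = "plif_config")
}

# ---- bond inference -------------------------------------------------------

covalent_radius <- function(element) {
  radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
             F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20, B = 0.84)
  r <- radii[toupper(element)]
  r[is.na(r)] <- 0.77
  unname(r)
}

# Distance-based covalent bond inference within one molecule (protein or
# ligand). Returns an integer adjacency list indexed by row.
infer_bonds <- function(atoms, tol = 1.3) {
  n <- nrow(atoms)
  adj <- vector("list", n)
  if (n < 2) return(adj)
  d <- cross_dist(coords_matrix(atoms), coords_matrix(atoms))
  rmax <- outer(covalent_radius(atoms$element),
                covalent_radius(atoms$element), "+") * tol
  bonded <- d > 0.1 & d <= rmax
  diag(bonded) <- FALSE
  for (i in seq_len(n)) adj[[i]] <- which(bonded[i, ])
  adj
}

# ---- donor / acceptor typing ----------------------------------------------

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Sidechain N/O hydrogen-bond capabilities per standard residue.
sidechain_da_table <- function() {
  tibble::tribble(
    ~residue_name, ~name,  ~donor, ~acceptor,
    "SER", "OG",  TRUE,  TRUE,
    "THR", "OG1", TRUE,  TRUE,
    "TYR", "OH",  TRUE,  TRUE,
    "ASN", "OD1", FALSE, TRUE,
    "ASN", "ND2", TRUE,  FALSE,
    "GLN", "OE1", FALSE, TRUE,
    "GLN", "NE2", TRUE,  FALSE,
    "ASP", "OD1", FALSE, TRUE,
    "ASP", "OD2", FALSE, TRUE,
    "GLU", "OE1", FALSE, TRUE,
    "GLU", "OE2", FALSE, TRUE,
    "HIS", "ND1", TRUE,  TRUE,
    "HIS", "NE2", TRUE,  TRUE,
    "LYS", "NZ",  TRUE,  FALSE,
    "ARG", "NE",  TRUE,  FALSE,
    "ARG", "NH1", TRUE,  FALSE,
    "ARG", "NH2", TRUE,  FALSE,
    "TRP", "NE1", TRUE,  FALSE
  )
}

protein_da_flags <- function(atoms) {
  tab <- sidechain_da_table()
  m <- match(paste(atoms$residue_name, atoms$name),
             paste(tab$residue_name, tab$name))
  donor <- ifelse(!is.na(m), tab$donor[m],
                  atoms$name == "N" & atoms$residue_name != "PRO")
  acceptor <- ifelse(!is.na(m), tab$acceptor[m],
                     atoms$name %in% c("O", "OXT"))
  list(donor = donor & atoms$element %in% c("N", "O"),
       acceptor = acceptor & atoms$element %in% c("N", "O"))
}

# Ligand N/O typing from heavy-atom connectivity only (depositions carry no
# hydrogens or bond orders): O accepts always and donates when terminal,
# unless attached to a carbon with >= 3 heavy neighbours (carbonyl-like);
# N donates when heavy degree <= 2 and accepts unless quaternary.
ligand_da_flags <- function(atoms, bonds) {
  degree <- vapply(bonds, length, integer(1))
  donor <- rep(FALSE, nrow(atoms))
  acceptor <- rep(FALSE, nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    el <- atoms$element[i]
    if (el == "O") {
      acceptor[i] <- TRUE
      if (degree[i] <= 1) {
        carbonyl_like <- length(bonds[[i]]) == 1 &&
          atoms$element[bonds[[i]]] == "C" &&
          length(bonds[[bonds[[i]]]]) >= 3
        donor[i] <- !carbonyl_like
      }
    } else if (el == "N") {
      donor[i] <- degree[i] <= 2
      acceptor[i] <- degree[i] <= 3
    }
  }
  list(donor = donor, acceptor = acceptor)
}

interaction_cols <- function() {
  tibble(itype = character(), distance = numeric(), angle = numeric(),
         chain_id = character(), residue_name = character(),
         residue_number = integer(), protein_part = character(),
         roles = character(), lig_serial = integer(), prot_serial = integer(),
         lig_x = numeric(), lig_y = numeric(), lig_z = numeric(),
         prot_x = numeric(), prot_y = numeric(), prot_z = numeric(),
         dir_x = numeric(), dir_y = numeric(), dir_z = numeric())
}

make_interaction_rows <- function(itype, lig_atoms, prot_atoms, li, pi_,
                                  distance, angle, roles) {
  lx <- lig_atoms$x[li]; ly <- lig_atoms$y[li]; lz <- lig_atoms$z[li]
  px <- prot_atoms$x[pi_]; py <- prot_atoms$y[pi_]; pz <- prot_atoms$z[pi_]
  dvec <- cbind(lx - px, ly - py, lz - pz)
  dn <- sqrt(rowSums(dvec^2))
  tibble(
    itype = itype,
    distance = distance,
    angle = angle,
    chain_id = prot_atoms$chain_id[pi_],
    residue_name = prot_atoms$residue_name[pi_],
    residue_number = prot_atoms$residue_number[pi_],
    protein_part = ifelse(prot_atoms$name[pi_] %in% BACKBONE_ATOMS,
                          "backbone", "sidechain"),
    roles = roles,
    lig_serial = lig_atoms$serial[li],
    prot_serial = prot_atoms$serial[pi_],
    lig_x = lx, lig_y = ly, lig_z = lz,
    prot_x = px, prot_y = py, prot_z = pz,
    dir_x = dvec[, 1] / dn, dir_y = dvec[, 2] / dn, dir_z = dvec[, 3] / dn
  )
}

site_components <- function(site) {
  prot <- filter(site$protein_atoms, .data$element != "H")
  lig <- filter(site$ligand$atoms, .data$element != "H")
  list(prot = prot, lig = lig,
       prot_bonds = infer_bonds(prot), lig_bonds = infer_bonds(lig),
       dist = if (nrow(prot) > 0 && nrow(lig) > 0)
         cross_dist(coords_matrix(lig), coords_matrix(prot)) else
           matrix(0, 0, 0))
}

min_antecedent_angle <- function(atoms, bonds, i, other_xyz) {
  nb <- bonds[[i]]
  nb <- nb[atoms$element[nb] != "H"]
  if (length(nb) == 0) return(NA_real_)
  d_xyz <- c(atoms$x[i], atoms$y[i], atoms$z[i])
  min(vapply(nb, function(j) {
    angle_deg(c(atoms$x[j], atoms$y[j], atoms$z[j]), d_xyz, other_xyz)
  }, numeric(1)))
}

#' Detect hydrogen bonds in a binding site
#'
#' Heavy-atom rule: donor D (N/O with attachable hydrogen) and acceptor A
#' (N/O with lone pair) at `dist(D, A) <= 4.1` A; when the donor's
#' antecedent heavy atoms X are known, every angle X-D...A must be
#' >= 100 deg. Each ordered (D, A) pair is reported once.
#'
#' @param site A `plif_site`.
#' @param config A [interaction_config()].
#' @return Tibble of interaction records (possibly empty).
#' @export
detect_hbonds <- function(site, config = interaction_config()) {
  sc <- site_components(site)
  if (nrow(sc$prot) == 0 || nrow(sc$lig) == 0) return(interaction_cols())
  pda <- protein_da_flags(sc$prot)
  lda <- ligand_da_flags(sc$lig, sc$lig_bonds)

  out <- list()
  within <- which(sc$dist <= config$hbond_dist_max, arr.ind = TRUE)
  for (k in seq_len(nrow(within))) {
    li <- within[k, 1]; pi_ <- within[k, 2]
    d <- sc$dist[li, pi_]
    if (d <= 0.5) next  # covalent-range contact, not an hbond
    lig_xyz <- c(sc$lig$x[li], sc$lig$y[li], sc$lig$z[li])
    prot_xyz <- c(sc$prot$x[pi_], sc$prot$y[pi_], sc$prot$z[pi_])
    # protein donor -> ligand acceptor
    if (pda$donor[pi_] && lda$acceptor[li]) {
      ang <- min_antecedent_angle(sc$prot, sc$prot_bonds, pi_, lig_xyz)
      if (is.na(ang) || ang >= config$hbond_angle_min) {
        out[[length(out) + 1]] <- make_interaction_rows(
          "hbond", sc$lig, sc$prot, li, pi_, d, ang, "protein_donor")
      }
    }
    # ligand donor -> protein acceptor
    if (lda$donor[li] && pda$acceptor[pi_]) {
      ang <- min_antecedent_angle(sc$lig, sc$lig_bonds, li, prot_xyz)
      if (is.na(ang) || ang >= config$hbond_angle_min) {
        out[[length(out) + 1]] <- make_interaction_rows(
          "hbond", sc$lig, sc$prot, li, pi_, d, ang, "ligand_donor")
      }
    }
  }
  if (length(out) == 0) return(interaction_cols())
  bind_rows(out) |>
    distinct(.data$roles, .data$lig_serial, .data$prot_serial,
             .keep_all = TRUE)
}

#' Detect hydrophobic contacts in a binding site
#'
#' Apolar carbons (bonded to carbon only) on both sides within 4.0 A;
#' contacts are clustered per (ligand atom, protein residue), keeping the
#' shortest, so one aliphatic sidechain cannot flood the fingerprint.
#'
#' @inheritParams detect_hbonds
#' @return Tibble of interaction records.
#' @export
detect_hydrophobic <- function(site, config = interaction_config()) {
  sc <- site_components(site)
  if (nrow(sc$prot) == 0 || nrow(sc$lig) == 0) return(interaction_cols())
  apolar <- function(atoms, bonds) {
    vapply(seq_len(nrow(atoms)), function(i) {
      atoms$element[i] == "C" &&
        all(atoms$element[bonds[[i]]] %in% c("C", "H"))
    }, logical(1))
  }
  la <- which(apolar(sc$lig, sc$lig_bonds))
  pa <- which(apolar(sc$prot, sc$prot_bonds))
  if (length(la) == 0 || length(pa) == 0) return(interaction_cols())

  pairs <- which(sc$dist[la, pa, drop = FALSE] <= config$hydrophobic_dist_max,
                 arr.ind = TRUE)
  if (nrow(pairs) == 0) return(interaction_cols())
  li <- la[pairs[, 1]]; pi_ <- pa[pairs[, 2]]
  d <- sc$dist[cbind(li, pi_)]
  keep <- d > 0.5
  li <- li[keep]; pi_ <- pi_[keep]; d <- d[keep]
  if (length(li) == 0) return(interaction_cols())
  rows <- make_interaction_rows("hydrophobic", sc$lig, sc$prot, li, pi_,
                                d, NA_real_, NA_character_)
  rows |>
    mutate(.res = residue_key(.data$chain_id, .data$residue_number, "")) |>
    group_by(.data$lig_serial, .data$.res) |>
    arrange(.data$distance, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    select(-".res")
}

#' Detect halogen bonds in a binding site
#'
#' Ligand halogen X (F/Cl/Br/I) covalently bound to carbon C, protein
#' acceptor A (O/N/S with antecedent Y): `dist(X, A) <= 4.0` A, donor angle
#' C-X...A within 165 +/- 30 deg, and acceptor angle Y-A...X within
#' 120 +/- 30 deg for at least one antecedent Y.
#'
#' @inheritParams detect_hbonds
#' @return Tibble of interaction records.
#' @export
detect_halogen_bonds <- function(site, config = interaction_config()) {
  sc <- site_components(site)
  if (nrow(sc$prot) == 0 || nrow(sc$lig) == 0) return(interaction_cols())
  halos <- which(sc$lig$element %in% c("F", "CL", "BR", "I"))
  halos <- halos[vapply(halos, function(i) {
    any(sc$lig$element[sc$lig_bonds[[i]]] == "C")
  }, logical(1))]
  accs <- which(sc$prot$element %in% c("O", "N", "S") &
                  vapply(sc$prot_bonds, length, integer(1)) > 0)
  if (length(halos) == 0 || length(accs) == 0) return(interaction_cols())

  don_lo <- config$halogen_donor_angle - config$halogen_donor_tol
  don_hi <- config$halogen_donor_angle + config$halogen_donor_tol
  acc_lo <- config$halogen_acceptor_angle - config$halogen_acceptor_tol
  acc_hi <- config$halogen_acceptor_angle + config$halogen_acceptor_tol

  out <- list()
  for (li in halos) {
    x_xyz <- c(sc$lig$x[li], sc$lig$y[li], sc$lig$z[li])
    cnb <- sc$lig_bonds[[li]][sc$lig$element[sc$lig_bonds[[li]]] == "C"][1]
    c_xyz <- c(sc$lig$x[cnb], sc$lig$y[cnb], sc$lig$z[cnb])
    for (pi_ in accs) {
      d <- sc$dist[li, pi_]
      if (d > config$halogen_dist_max || d <= 0.5) next
      a_xyz <- c(sc$prot$x[pi_], sc$prot$y[pi_], sc$prot$z[pi_])
      don_ang <- angle_deg(c_xyz, x_xyz, a_xyz)
      if (don_ang < don_lo || don_ang > don_hi) next
      ys <- sc$prot_bonds[[pi_]]
      acc_angles <- vapply(ys, function(j) {
        angle_deg(c(sc$prot$x[j], sc$prot$y[j], sc$prot$z[j]), a_xyz, x_xyz)
      }, numeric(1))
      if (!any(acc_angles >= acc_lo & acc_angles <= acc_hi)) next
      out[[length(out) + 1]] <- make_interaction_rows(
        "halogen", sc$lig, sc$prot, li, pi_, d, don_ang, "ligand_donor")
    }
  }
  if (length(out) == 0) return(interaction_cols())
  bind_rows(out)
}

#' Profile all non-covalent interactions of one complex
#'
#' Runs the hydrogen-bond, hydrophobic and halogen-bond detectors over the
#' ligand's binding site and returns the combined interaction pattern in a
#' deterministic (type, residue number, distance) order.
#'
#' @param s A `plif_structure`.
#' @param lig One row of `s$ligands`.
#' @param scope `"all-chains"` (default) includes inter-chain contacts;
#'   `"single-chain"` restricts the site to the ligand's own chain.
#' @param config A [interaction_config()].
#' @return A tibble of class `plif_pattern` with attributes `complex_id`,
#'   `het_code` and `scope`.
#' @examples
#' cmplx <- make_complex(list(planted_spec("hbond", distance = 2.9),
#'                            planted_spec("hydrophobic", distance = 3.8)),
#'                       seed = 7)
#' s <- parse_structure(cmplx$pdb, entry_id = "toy")
#' profile_complex(s, s$ligands[1, ])
#' @export
profile_complex <- function(s, lig, scope = c("all-chains", "single-chain"),
                            config = interaction_config()) {
  scope <- match.arg(scope)
  lig <- as_ligand(lig)
  site <- binding_site(s, lig, cutoff = config$site_cutoff)
  if (scope == "single-chain") {
    site$protein_atoms <- filter(site$protein_atoms,
                                 .data$chain_id == lig$chain_id)
  }
  pat <- bind_rows(detect_hbonds(site, config),
                   detect_hydrophobic(site, config),
                   detect_halogen_bonds(site, config)) |>
    arrange(.data$itype, .data$residue_number, .data$distance)
  new_pattern(pat,
              complex_id = paste(s$entry_id, lig$het_code, lig$chain_id,
                                 lig$residue_number, sep = ":"),
              het_code = lig$het_code, scope = scope)
}

new_pattern <- function(tbl, complex_id, het_code = NA_character_,
                        scope = "all-chains") {
  structure(tbl, complex_id = complex_id, het_code = het_code, scope = scope,
            class = c("plif_pattern", class(tibble())))
}

#' @export
print.plif_pattern <- function(x, ...) {
  cat(sprintf("<plif_pattern> %s (%s): %d interaction(s)\n",
              attr(x, "complex_id"), attr(x, "scope"), nrow(x)))
  NextMethod()
}

#' Serialize an interaction pattern to JSON (round-trip safe)
#'
#' @param p A `plif_pattern`.
#' @return A JSON string.
#' @export
pattern_to_json <- function(p) {
  jsonlite::toJSON(
    list(complex_id = attr(p, "complex_id"),
         het_code = attr(p, "het_code"),
         scope = attr(p, "scope"),
         interactions = as_tibble(p)),
    auto_unbox = TRUE, digits = NA, na = "null")
}

#' Read an interaction pattern back from JSON
#'
#' @param json A JSON string produced by [pattern_to_json()].
#' @return A `plif_pattern`.
#' @export
pattern_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  tbl <- as_tibble(obj$interactions)
  if (nrow(tbl) == 0) tbl <- interaction_cols()
  tbl$residue_number <- as.integer(tbl$residue_number)
  tbl$lig_serial <- as.integer(tbl$lig_serial)
  tbl$prot_serial <- as.integer(tbl$prot_serial)
  new_pattern(tbl, obj$complex_id, obj$het_code %||% NA_character_,
              obj$scope %||% "all-chains")
}
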