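#' Parse a PDB-format protein-ligand complex
#'
#' Reads ATOM/HETATM records of the first model into a uniform structure
#' object. Alternate locations are collapsed to the highest-occupancy
#' conformer (ties broken towards altloc "A"), author residue numbering is
#' kept verbatim, and candidate het-group ligands are identified (waters and
#' common solvent/ion/buffer components excluded, minimum five heavy atoms).
#'
#' @param pdb Path to a PDB file, or a character vector/string of PDB text.
#' @param entry_id Identifier for the entry; defaults to the file name stem
#'   (or `"structure"` for raw text).
#' @param exclusion Character vector of het codes never treated as ligands;
#'   defaults to the packaged solvent/ion exclusion list
#'   (see [het_exclusion_codes()]).
#' @param min_heavy_atoms Minimum heavy-atom count for a het group to count
#'   as a ligand (default 5, excluding ions and small fragments).
#' @return An object of class `plif_structure`: a list with `entry_id`,
#'   `atoms` (a tibble, one row per atom), `chains`, and `ligands`
#'   (a tibble with one row per candidate ligand and a list-column `atoms`).
#' @examples
#' cmplx <- make_complex(planted_spec("hbond", distance = 2.9), seed = 1)
#' s <- parse_structure(cmplx$pdb, entry_id = "toy")
#' s$ligands
#' @export
parse_structure <- function(pdb, entry_id = NULL,
                            exclusion = het_exclusion_codes(),
                            min_heavy_atoms = 5L) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    entry_id <- entry_id %||% sub("\\.(pdb|ent)$", "", basename(pdb))
  } else {
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
    entry_id <- entry_id %||% "structure"
  }

  # First model only: truncate at the first ENDMDL if models are present.
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl) > 0) lines <- lines[seq_len(endmdl[1] - 1)]

  rec <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  if (!any(rec)) {
    abort("no ATOM or HETATM records found in input",
          class = "plif_parse_error")
  }

  # Validate coordinate fields up front so malformed lines are reported by
  # line number (bio3d would silently coerce them to NA).
  idx <- which(rec)
  for (col in list(c(31, 38), c(39, 46), c(47, 54))) {
    fld <- substr(lines[idx], col[1], col[2])
    bad <- is.na(suppressWarnings(as.numeric(fld)))
    if (any(bad)) {
      abort(sprintf("malformed coordinate field at line %d: %s",
                    idx[which(bad)[1]], trimws(lines[idx[which(bad)[1]]])),
            class = "plif_parse_error")
    }
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb_obj <- suppressWarnings(bio3d::read.pdb(tf, verbose = FALSE,
                                              rm.alt = FALSE))
  a <- pdb_obj$atom

  atoms <- tibble(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    altloc = ifelse(is.na(a$alt), "", trimws(a$alt)),
    residue_name = trimws(a$resid),
    chain_id = ifelse(is.na(a$chain), "", trimws(a$chain)),
    residue_number = as.integer(a$resno),
    insertion_code = ifelse(is.na(a$insert), "", trimws(a$insert)),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    element = normalise_element(a$elesy, trimws(a$elety), a$type == "HETATM"),
    is_het = a$type == "HETATM"
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite coordinates after parsing", class = "plif_parse_error")
  }

  # Alternate locations: keep the highest-occupancy conformer per atom site;
  # ties resolved towards altloc "A" (then lexicographic).
  atoms <- atoms |>
    group_by(.data$chain_id, .data$residue_number, .data$insertion_code,
             .data$residue_name, .data$name) |>
    arrange(desc(.data$occupancy), .data$altloc, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$serial)

  new_structure(atoms, entry_id,
                exclusion = exclusion, min_heavy_atoms = min_heavy_atoms)
}

# Internal constructor: builds the structure object (and its ligand table)
# from a finished atom tibble. Used by the parser and by the generators.
new_structure <- function(atoms, entry_id,
                          exclusion = het_exclusion_codes(),
                          min_heavy_atoms = 5L) {
  s <- structure(
    list(entry_id = entry_id,
         atoms = atoms,
         chains = sort(unique(atoms$chain_id)),
         ligands = NULL),
    class = "plif_structure"
  )
  s$ligands <- extract_ligands(s, exclusion = exclusion,
                               min_heavy_atoms = min_heavy_atoms)
  s
}

#' @export
print.plif_structure <- function(x, ...) {
  cat(sprintf("<plif_structure> %s: %d atoms, %d chain(s), %d ligand(s)\n",
              x$entry_id, nrow(x$atoms), length(x$chains), nrow(x$ligands)))
  if (nrow(x$ligands) > 0) print(x$ligands[, 1:4])
  invisible(x)
}

normalise_element <- function(elesy, name, is_het) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  fix <- el == ""
  if (any(fix)) {
    guess <- sub("^[0-9']+", "", toupper(name[fix]))
    two <- c("CL", "BR", "NA", "MG", "FE", "ZN", "MN", "SE", "CU", "NI", "CO",
             "CD", "HG", "LI")
    el[fix] <- ifelse(is_het[fix] & guess %in% two, guess,
                      substr(guess, 1, 1))
  }
  el
}

#' Packaged solvent/ion/buffer het-code exclusion list
#'
#' Het groups on this list (waters, monoatomic ions, cryoprotectants,
#' buffer components) are never treated as screenable ligands.
#'
#' @return Character vector of excluded het codes.
#' @export
het_exclusion_codes <- function() {
  path <- system.file("extdata", "het_exclusion.tsv", package = "plifscreen")
  readr::read_tsv(path, show_col_types = FALSE)$het_code
}

#' Identify candidate ligands of a structure
#'
#' One ligand per het residue that is not on the exclusion list and has at
#' least `min_heavy_atoms` heavy atoms, in deterministic
#' (chain, residue number) order.
#'
#' @param s A `plif_structure`.
#' @param exclusion Character vector of excluded het codes.
#' @param min_heavy_atoms Minimum heavy-atom count (default 5).
#' @return Tibble with columns `het_code`, `chain_id`, `residue_number`,
#'   `n_heavy`, and a list-column `atoms`.
#' @export
extract_ligands <- function(s, exclusion = het_exclusion_codes(),
                            min_heavy_atoms = 5L) {
  het <- filter(s$atoms, .data$is_het,
                !.data$residue_name %in% exclusion,
                .data$element != "H")
  if (nrow(het) == 0) {
    return(tibble(het_code = character(), chain_id = character(),
                  residue_number = integer(), n_heavy = integer(),
                  atoms = list()))
  }
  keys <- distinct(het[, c("residue_name", "chain_id", "residue_number")])
  atoms_list <- purrr::map(seq_len(nrow(keys)), function(i) {
    het[het$residue_name == keys$residue_name[i] &
          het$chain_id == keys$chain_id[i] &
          het$residue_number == keys$residue_number[i], ]
  })
  tibble(het_code = keys$residue_name,
         chain_id = keys$chain_id,
         residue_number = keys$residue_number,
         n_heavy = purrr::map_int(atoms_list, nrow),
         atoms = atoms_list) |>
    filter(.data$n_heavy >= min_heavy_atoms) |>
    arrange(.data$chain_id, .data$residue_number)
}

#' Extract the binding site of a ligand
#'
#' All non-het (protein) atoms within `cutoff` of any ligand heavy atom.
#' The default 7.5 A generously covers the geometric reach of all detected
#' interaction types.
#'
#' @param s A `plif_structure`.
#' @param lig One row of `s$ligands` (or a list with fields `het_code`,
#'   `chain_id`, `residue_number`, `atoms`).
#' @param cutoff Distance cutoff in Angstrom (default 7.5).
#' @return An object of class `plif_site`: list with `ligand`,
#'   `protein_atoms` (tibble), `cutoff`, and the parent structure's atoms.
#' @export
binding_site <- function(s, lig, cutoff = 7.5) {
  stopifnot(cutoff > 0)
  lig <- as_ligand(lig)
  if (!all(lig$atoms$serial %in% s$atoms$serial)) {
    abort("ligand does not belong to this structure")
  }
  prot <- filter(s$atoms, !.data$is_het, .data$element != "H")
  lig_heavy <- filter(lig$atoms, .data$element != "H")
  if (nrow(prot) == 0 || nrow(lig_heavy) == 0) {
    site_atoms <- prot[0, ]
  } else {
    d <- cross_dist(coords_matrix(prot), coords_matrix(lig_heavy))
    site_atoms <- prot[apply(d, 1, min) <= cutoff, ]
  }
  structure(list(ligand = lig, protein_atoms = site_atoms, cutoff = cutoff,
                 parent_atoms = s$atoms, entry_id = s$entry_id),
            class = "plif_site")
}

#' @export
print.plif_site <- function(x, ...) {
  nres <- nrow(distinct(x$protein_atoms, .data$chain_id,
                        .data$residue_number, .data$insertion_code))
  cat(sprintf(
    "<plif_site> %s %s/%s%d: %d protein atoms in %d residues (cutoff %.1f A)\n",
    x$entry_id, x$ligand$het_code, x$ligand$chain_id,
    x$ligand$residue_number, nrow(x$protein_atoms), nres, x$cutoff))
  invisible(x)
}

as_ligand <- function(lig) {
  if (inherits(lig, "data.frame")) {
    if (nrow(lig) != 1) abort("expected exactly one ligand row")
    list(het_code = lig$het_code, chain_id = lig$chain_id,
         residue_number = lig$residue_number, atoms = lig$atoms[[1]])
  } else {
    lig
  }
}

#' Write an atom table back to PDB-format text
#'
#' Inverse of [parse_structure()] for the fields the package models; a
#' write-out followed by re-parse reproduces the atom table.
#'
#' @param atoms Atom tibble (as in `plif_structure$atoms`).
#' @return Character vector of PDB lines (including a final END record).
#' @export
write_pdb_text <- function(atoms) {
  fmt_name <- function(name, element) {
    # Standard alignment: element right-justified in cols 13-14.
    ifelse(nchar(name) >= 4, substr(name, 1, 4),
           ifelse(nchar(element) == 2,
                  sprintf("%-4s", name),
                  sprintf(" %-3s", name)))
  }
  lines <- sprintf(
    "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(atoms$is_het, "HETATM", "ATOM"),
    atoms$serial,
    fmt_name(atoms$name, atoms$element),
    substr(paste0(atoms$altloc, " "), 1, 1),
    atoms$residue_name,
    substr(paste0(atoms$chain_id, " "), 1, 1),
    atoms$residue_number,
    substr(paste0(atoms$insertion_code, " "), 1, 1),
    atoms$x, atoms$y, atoms$z,
    atoms$occupancy, 0,
    atoms$element
  )
  c(lines, "END")
}
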