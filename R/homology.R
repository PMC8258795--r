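#' Construct a protein sequence with author numbering
#'
#' @param id Sequence identifier.
#' @param residues One-letter amino-acid string (20 standard letters + X).
#' @param numbering_offset Author residue number of the first residue
#'   (default 1).
#' @return A list of class `plif_sequence`.
#' @export
protein_sequence <- function(id, residues, numbering_offset = 1L) {
  residues <- toupper(gsub("\\s", "", residues))
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", residues)) {
    abort("sequence contains letters outside the 20 standard amino acids + X")
  }
  structure(list(id = id, residues = residues,
                 numbering_offset = as.integer(numbering_offset)),
            class = "plif_sequence")
}

#' @export
print.plif_sequence <- function(x, ...) {
  cat(sprintf("<plif_sequence> %s: %d residues (numbering from %d)\n",
              x$id, nchar(x$residues), x$numbering_offset))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return A named list of `plif_sequence` objects.
#' @export
read_fasta_sequences <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- purrr::map2(names(set), as.character(set), function(nm, s) {
    protein_sequence(strsplit(nm, "\\s+")[[1]][1], s)
  })
  setNames(out, purrr::map_chr(out, "id"))
}

#' Apply point mutations to a sequence (author numbering)
#'
#' Each mutation is checked against the current residue; a mismatch aborts
#' naming the position and the residue actually found.
#'
#' @param seq A [protein_sequence()].
#' @param mutations List of `c(position, from, to)` triples (or a
#'   three-column data frame `position`, `from`, `to`).
#' @return The mutated `plif_sequence`.
#' @examples
#' humanize(protein_sequence("toy", "AFA"), list(c(2, "F", "L")))
#' @export
humanize <- function(seq, mutations) {
  if (inherits(mutations, "data.frame")) {
    mutations <- purrr::pmap(mutations, function(position, from, to) {
      c(position, from, to)
    })
  }
  res <- seq$residues
  for (m in mutations) {
    pos <- as.integer(m[[1]])
    from <- toupper(m[[2]]); to <- toupper(m[[3]])
    i <- pos - seq$numbering_offset + 1L
    if (i < 1 || i > nchar(res)) {
      abort(sprintf("position %d outside the sequence (author numbering %d-%d)",
                    pos, seq$numbering_offset,
                    seq$numbering_offset + nchar(res) - 1L))
    }
    found <- substr(res, i, i)
    if (found != from) {
      abort(sprintf("expected %s at position %d but found %s",
                    from, pos, found))
    }
    substr(res, i, i) <- to
  }
  protein_sequence(seq$id, res, seq$numbering_offset)
}

#' Global pairwise sequence alignment with EMBOSS-style defaults
#'
#' Needleman-Wunsch alignment with affine gap penalties via
#' [Biostrings::pairwiseAlignment()]. Defaults mirror the EMBOSS Needle web
#' service: BLOSUM62, gap open 10, gap extension 0.5, end gaps free. The
#' percent identity is identical columns divided by the full alignment
#' length (end gaps included), times 100.
#'
#' @param a,b [protein_sequence()] objects (or plain strings).
#' @param matrix_name Substitution matrix name (a matrix shipped with
#'   Biostrings, e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param end_gaps Penalise end gaps (default `FALSE`, the EMBOSS default).
#' @return A list of class `plif_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings covering both inputs fully), `score`,
#'   `identity_pct`, and the parameters.
#' @export
global_align <- function(a, b, matrix_name = "BLOSUM62", gap_open = 10,
                         gap_extend = 0.5, end_gaps = FALSE) {
  if (is.character(a)) a <- protein_sequence("a", a)
  if (is.character(b)) b <- protein_sequence("b", b)
  stopifnot(nchar(a$residues) > 0, nchar(b$residues) > 0)
  mat <- tryCatch(
    {
      e <- new.env()
      utils::data(list = matrix_name, package = "Biostrings", envir = e)
      get(matrix_name, envir = e)
    },
    warning = function(w) abort(sprintf("unknown substitution matrix: %s",
                                        matrix_name)),
    error = function(e) abort(sprintf("unknown substitution matrix: %s",
                                      matrix_name)))
  aln <- Biostrings::pairwiseAlignment(
    pattern = a$residues, subject = b$residues,
    substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend,
    type = if (end_gaps) "global" else "overlap")

  core_a <- as.character(Biostrings::alignedPattern(aln))
  core_b <- as.character(Biostrings::alignedSubject(aln))
  # Reassemble full-length gapped strings: Biostrings clips ends-free
  # overhangs, EMBOSS prints them against end gaps.
  pa <- aln@pattern@range; pb <- aln@subject@range
  pre_a <- substr(a$residues, 1, BiocGenerics::start(pa) - 1)
  suf_a <- substr(a$residues, BiocGenerics::end(pa) + 1, nchar(a$residues))
  pre_b <- substr(b$residues, 1, BiocGenerics::start(pb) - 1)
  suf_b <- substr(b$residues, BiocGenerics::end(pb) + 1, nchar(b$residues))
  full_a <- paste0(pre_a, strrep("-", nchar(pre_b)), core_a,
                   suf_a, strrep("-", nchar(suf_b)))
  full_b <- paste0(strrep("-", nchar(pre_a)), pre_b, core_b,
                   strrep("-", nchar(suf_a)), suf_b)
  stopifnot(nchar(full_a) == nchar(full_b))
  ca <- strsplit(full_a, "")[[1]]
  cb <- strsplit(full_b, "")[[1]]
  ident <- sum(ca == cb & ca != "-")
  structure(list(
    aligned_a = full_a, aligned_b = full_b,
    score = Biostrings::score(aln),
    identity_pct = 100 * ident / nchar(full_a),
    matrix_name = matrix_name, gap_open = gap_open,
    gap_extend = gap_extend, end_gaps = end_gaps,
    id_a = a$id, id_b = b$id,
    offset_a = a$numbering_offset, offset_b = b$numbering_offset),
    class = "plif_alignment")
}

#' @export
print.plif_alignment <- function(x, ...) {
  cat(sprintf("<plif_alignment> %s vs %s: score %.1f, identity %.1f%%\n",
              x$id_a, x$id_b, x$score, x$identity_pct))
  invisible(x)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation mapping `coords_b` onto
#' `coords_a` minimising the RMSD over matched pairs. Reflections are
#' never returned: the smallest singular direction is flipped when needed
#' so `det(rotation) = +1`.
#'
#' @param coords_a,coords_b Matched coordinate matrices (n x 3, n >= 3).
#' @return A list of class `plif_superposition`: `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd`, `n`. The fitted copy of `coords_b`
#'   is `coords_b %*% t(rotation) + translation` (rows).
#' @export
superpose <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  stopifnot(ncol(A) == 3, ncol(B) == 3)
  if (nrow(A) != nrow(B)) abort("coordinate sets must have equal length")
  if (nrow(A) < 3) abort("superposition needs at least 3 matched pairs")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv_a <- svd(Ac)$d; sv_b <- svd(Bc)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1) || sv_b[2] < 1e-8 * max(sv_b[1], 1)) {
    abort("degenerate (collinear) coordinate set; superposition undefined")
  }
  H <- t(Bc) %*% Ac
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fitted <- Bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Ac - fitted)^2)))
  structure(list(rotation = R, translation = as.numeric(ca - R %*% cb),
                 rmsd = rmsd, n = nrow(A)),
            class = "plif_superposition")
}

#' @export
print.plif_superposition <- function(x, ...) {
  cat(sprintf("<plif_superposition> %d pairs, RMSD %.3f A%s\n", x$n, x$rmsd,
              if (!is.null(x$cycles_run))
                sprintf(" (%d rejection cycle(s))", x$cycles_run) else ""))
  invisible(x)
}

apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, "+")
}

aa3to1 <- function(res3) {
  map <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
           MSE = "M")
  out <- map[toupper(res3)]
  out[is.na(out)] <- "X"
  unname(out)
}

ca_trace <- function(s, chain) {
  s$atoms |>
    filter(!.data$is_het, .data$chain_id == chain, .data$name == "CA") |>
    arrange(.data$residue_number, .data$insertion_code)
}

#' Sequence-seeded iterative superposition with outlier rejection
#'
#' Replicates refinement-style structural alignment: CA pairs are seeded
#' from a global sequence alignment of the two chains, then up to `cycles`
#' rounds of Kabsch fitting reject pairs deviating more than
#' `reject_cutoff` and refit, stopping early when no pair is removed. This
#' focuses the final RMSD on the structurally conserved core, as
#' refinement-based aligners do.
#'
#' @param struct_a,struct_b `plif_structure` objects.
#' @param chain_a,chain_b Chain identifiers (>= 20 CA atoms each).
#' @param cycles Maximum rejection cycles (default 5).
#' @param reject_cutoff Per-pair deviation cutoff in Angstrom (default 2.0).
#' @return A `plif_superposition` with additional fields `matched_pairs`
#'   (tibble of surviving residue pairs with final deviations) and
#'   `cycles_run`.
#' @export
iterative_superpose <- function(struct_a, struct_b, chain_a, chain_b,
                                cycles = 5L, reject_cutoff = 2.0) {
  ca_a <- ca_trace(struct_a, chain_a)
  ca_b <- ca_trace(struct_b, chain_b)
  if (nrow(ca_a) < 20 || nrow(ca_b) < 20) {
    abort("both chains need at least 20 CA atoms")
  }
  aln <- global_align(
    protein_sequence(chain_a, paste(aa3to1(ca_a$residue_name), collapse = "")),
    protein_sequence(chain_b, paste(aa3to1(ca_b$residue_name), collapse = "")))
  cols_a <- strsplit(aln$aligned_a, "")[[1]]
  cols_b <- strsplit(aln$aligned_b, "")[[1]]
  ia <- cumsum(cols_a != "-")
  ib <- cumsum(cols_b != "-")
  both <- cols_a != "-" & cols_b != "-"
  pairs <- tibble(ia = ia[both], ib = ib[both])

  A <- coords_matrix(ca_a)[pairs$ia, , drop = FALSE]
  B <- coords_matrix(ca_b)[pairs$ib, , drop = FALSE]
  keep <- seq_len(nrow(pairs))
  cycles_run <- 0L
  sup <- NULL
  for (cy in seq_len(max(1L, cycles))) {
    if (length(keep) < 3) abort("fewer than 3 pairs survive rejection")
    sup <- superpose(A[keep, , drop = FALSE], B[keep, , drop = FALSE])
    cycles_run <- cy
    dev <- sqrt(rowSums((A[keep, , drop = FALSE] -
                           apply_superposition(sup, B[keep, , drop = FALSE]))^2))
    drop_idx <- dev > reject_cutoff
    if (!any(drop_idx) || cy == cycles) break
    keep <- keep[!drop_idx]
  }
  if (length(keep) < 3) abort("fewer than 3 pairs survive rejection")
  dev <- sqrt(rowSums((A[keep, , drop = FALSE] -
                         apply_superposition(sup, B[keep, , drop = FALSE]))^2))
  sup$matched_pairs <- tibble(
    residue_a = ca_a$residue_number[pairs$ia[keep]],
    residue_b = ca_b$residue_number[pairs$ib[keep]],
    deviation = dev)
  sup$cycles_run <- cycles_run
  sup$n <- length(keep)
  sup$rmsd <- sqrt(mean(dev^2))
  sup
}

#' Map binding-site residues onto a superposed homolog
#'
#' After applying the superposition transform to structure B, each residue
#' of the binding site (structure A) is mapped to the nearest CA of B
#' within `distance_max`; residues without a partner are reported
#' explicitly as unmapped.
#'
#' @param sup A `plif_superposition` mapping B onto A's frame.
#' @param site A `plif_site` from structure A.
#' @param struct_b The homolog `plif_structure`.
#' @param distance_max Maximum CA-CA distance in Angstrom (default 3.0).
#' @return Tibble with one row per site residue: `chain_a`, `residue_a`,
#'   `resname_a`, `residue_b`, `resname_b`, `ca_distance`, `mapped`,
#'   `part_matched` (does the mapped residue share the residue name).
#' @export
map_binding_site_residues <- function(sup, site, struct_b,
                                      distance_max = 3.0) {
  site_res <- distinct(site$protein_atoms, .data$chain_id,
                       .data$residue_number, .data$residue_name)
  parent <- site$parent_atoms
  ca_a <- parent |>
    filter(!.data$is_het, .data$name == "CA") |>
    semi_join(site_res, by = c("chain_id", "residue_number", "residue_name"))
  ca_b <- filter(struct_b$atoms, !.data$is_het, .data$name == "CA")
  if (nrow(ca_b) == 0 || nrow(ca_a) == 0) {
    return(tibble(chain_a = character(), residue_a = integer(),
                  resname_a = character(), residue_b = integer(),
                  resname_b = character(), ca_distance = numeric(),
                  mapped = logical(), part_matched = logical()))
  }
  b_fit <- apply_superposition(sup, coords_matrix(ca_b))
  d <- cross_dist(coords_matrix(ca_a), b_fit)
  nearest <- apply(d, 1, which.min)
  ndist <- d[cbind(seq_len(nrow(d)), nearest)]
  mapped <- ndist <= distance_max
  tibble(
    chain_a = ca_a$chain_id,
    residue_a = ca_a$residue_number,
    resname_a = ca_a$residue_name,
    residue_b = ifelse(mapped, ca_b$residue_number[nearest], NA_integer_),
    resname_b = ifelse(mapped, ca_b$residue_name[nearest], NA_character_),
    ca_distance = ndist,
    mapped = mapped,
    part_matched = ifelse(mapped,
                          ca_b$residue_name[nearest] == ca_a$residue_name,
                          NA)
  ) |>
    arrange(.data$chain_a, .data$residue_a)
}
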