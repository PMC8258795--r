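# Shared fixtures and independent oracles used across the test files.

# Draw one random planted spec kept a safe margin (0.1 A / 3 deg) away from
# every detection threshold, so the expected detection count is unambiguous.
random_margin_spec <- function() {
  it <- sample(c("hbond", "hydrophobic", "halogen"), 1)
  if (it == "hbond") {
    d <- if (runif(1) < 0.7) runif(1, 2.6, 4.0) else runif(1, 4.2, 5.5)
    ang <- if (runif(1) < 0.8) runif(1, 103, 177) else runif(1, 60, 97)
    planted_spec("hbond", distance = d, donor_angle = ang,
                 protein_part = sample(c("backbone", "sidechain"), 1))
  } else if (it == "hydrophobic") {
    d <- if (runif(1) < 0.7) runif(1, 2.9, 3.9) else runif(1, 4.1, 5.5)
    planted_spec("hydrophobic", distance = d)
  } else {
    d <- if (runif(1) < 0.7) runif(1, 2.8, 3.9) else runif(1, 4.1, 5.5)
    da <- if (runif(1) < 0.8) runif(1, 138, 177) else runif(1, 100, 132)
    aa <- if (runif(1) < 0.8) runif(1, 93, 147) else runif(1, 60, 87)
    planted_spec("halogen", distance = d, donor_angle = da,
                 acceptor_angle = aa)
  }
}

# Profile a generated complex and tabulate detections by type.
detections_by_type <- function(cmplx) {
  s <- parse_structure(cmplx$pdb)
  pat <- profile_complex(s, s$ligands[s$ligands$het_code == "LIG", ])
  counts <- table(factor(pat$itype,
                         levels = c("hbond", "hydrophobic", "halogen")))
  as.integer(counts)
}

manifest_expected <- function(cmplx) {
  as.integer(unlist(
    cmplx$manifest$expected[c("hbond", "hydrophobic", "halogen")]))
}

# Set-algebra Tanimoto oracle over on-bit index sets (independent of the
# count-based formula in the package).
tanimoto_set_oracle <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

# Brute-force global alignment score by exhaustive enumeration of all
# alignment paths: affine gaps (open + extend * length), end gaps free.
brute_force_align_score <- function(a, b, mat, gap_open = 10,
                                    gap_extend = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- -Inf
  score_cols <- function(cols) {
    kind <- vapply(cols, function(cc) {
      if (cc[1] == "-") "gapA" else if (cc[2] == "-") "gapB" else "m"
    }, character(1))
    runs <- rle(kind)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    sc <- 0
    for (r in seq_along(runs$values)) {
      if (runs$values[r] == "m") {
        for (k in starts[r]:ends[r]) {
          sc <- sc + mat[cols[[k]][1], cols[[k]][2]]
        }
      } else if (starts[r] != 1 && ends[r] != length(cols)) {
        sc <- sc - gap_open - gap_extend * runs$lengths[r]
      }
    }
    sc
  }
  rec <- function(i, j, cols) {
    if (i > length(A) && j > length(B)) {
      best <<- max(best, score_cols(cols))
      return(invisible())
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1, j + 1, c(cols, list(c(A[i], B[j]))))
    }
    if (i <= length(A)) rec(i + 1, j, c(cols, list(c(A[i], "-"))))
    if (j <= length(B)) rec(i, j + 1, c(cols, list(c("-", B[j]))))
  }
  rec(1, 1, list())
  best
}

# A synthetic protein structure from a CA random walk (step 3.8 A), with
# full author control over residue names/numbers. Returns a plif_structure.
make_ca_structure <- function(n = 50, seed = 1, entry_id = "CHAIN",
                              chain = "A", resno_offset = 0L,
                              resnames = NULL) {
  set.seed(seed)
  aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
  if (is.null(resnames)) resnames <- sample(aa, n, replace = TRUE)
  dir <- c(1, 0, 0)
  pos <- matrix(0, n, 3)
  for (i in 2:n) {
    dir <- dir + rnorm(3, sd = 0.35)
    dir <- dir / sqrt(sum(dir^2))
    pos[i, ] <- pos[i - 1, ] + 3.8 * dir
  }
  atoms <- tibble::tibble(
    serial = seq_len(n), name = "CA", altloc = "",
    residue_name = resnames, chain_id = chain,
    residue_number = seq_len(n) + as.integer(resno_offset),
    insertion_code = "",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    occupancy = 1, element = "C", is_het = FALSE)
  plifscreen:::new_structure(atoms, entry_id)
}

# Random rotation matrix (uniform axis, uniform angle) for invariance tests.
random_rotation <- function() {
  ax <- rnorm(3)
  plifscreen:::rotation_about_axis(ax / sqrt(sum(ax^2)), runif(1, 0, 360))
}

# Apply a rigid motion to every atom of a structure, returning a rebuilt
# plif_structure (ligand table re-derived from the transformed atoms).
transform_structure <- function(s, R, t) {
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  atoms <- s$atoms
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  plifscreen:::new_structure(atoms, s$entry_id)
}
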