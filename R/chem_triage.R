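#' Read a compound table (name, SMILES, role)
#'
#' @param path CSV file with at least columns `name` and `smiles`
#'   (optionally `role` and `provenance`).
#' @return Tibble of compound records.
#' @export
read_compounds <- function(path) {
  if (!file.exists(path)) abort(sprintf("compound file not found: %s", path))
  # Full-line "#" comments only: SMILES legitimately contain "#" (triple
  # bonds), so readr's comment stripping would corrupt them.
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  readr::read_csv(I(paste(lines, collapse = "\n")), show_col_types = FALSE)
}

#' Packaged demonstration compound set
#'
#' The six approved repositioning candidates plus the assay positive
#' control, with SMILES transcribed from their published chemical
#' structures (see the `provenance` column). The two query tool compounds
#' are not included: their structures could not be sourced reliably, so no
#' claim involving them is packaged.
#'
#' @return Tibble with `name`, `smiles`, `role`, `provenance`.
#' @export
demo_compounds <- function() {
  read_compounds(system.file("extdata", "compounds_demo.csv",
                             package = "plifscreen"))
}

# Batch call into the rdkit descriptor backend. One python process per
# call; results keyed by compound name.
chem_backend <- function(compounds, n_bits = 16384L, radius = 2L) {
  stopifnot(all(c("name", "smiles") %in% names(compounds)))
  python <- Sys.which("python")
  if (python == "") python <- Sys.which("python3")
  if (python == "") abort("no python interpreter found on PATH")
  script <- system.file("python", "chem_backend.py", package = "plifscreen")
  tsv <- tempfile(fileext = ".tsv")
  out <- tempfile(fileext = ".json")
  on.exit(unlink(c(tsv, out)), add = TRUE)
  writeLines(paste(compounds$name, compounds$smiles, sep = "\t"), tsv)
  status <- system2(python, c(script, tsv, n_bits, radius, out),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(out)) {
    abort("chemistry backend failed; is rdkit importable from python?")
  }
  res <- jsonlite::fromJSON(out, simplifyDataFrame = FALSE)
  if (length(res$errors) > 0) {
    bad <- purrr::map_chr(res$errors, "name")
    abort(sprintf("unparseable SMILES for compound(s): %s",
                  paste(bad, collapse = ", ")))
  }
  res$compounds
}

#' Extended-connectivity (Morgan) fingerprints for compounds
#'
#' Circular substructure fingerprints hashed to `n_bits` bits with the
#' given radius (radius 2 corresponds to diameter 4, i.e. ECFP4),
#' computed with rdkit. Bit-level identity across toolkits is not
#' promised; within-run determinism is.
#'
#' @param compounds Tibble with `name` and `smiles` columns.
#' @param n_bits Fingerprint length (default 16384).
#' @param radius Circular radius (default 2).
#' @return Tibble of class `plif_chemfp` with `name` and list-column
#'   `on_bits` (1-based indices); `n_bits`/`radius` kept as attributes.
#' @export
ecfp <- function(compounds, n_bits = 16384L, radius = 2L) {
  res <- chem_backend(compounds, n_bits = n_bits, radius = radius)
  out <- tibble(
    name = purrr::map_chr(res, "name"),
    on_bits = purrr::map(res, function(r) sort(as.integer(r$on_bits))))
  structure(out, n_bits = as.integer(n_bits), radius = as.integer(radius),
            class = c("plif_chemfp", class(tibble())))
}

#' Pairwise chemical Tanimoto similarity matrix
#'
#' @param compounds Tibble with `name` and `smiles` (>= 2 rows), or a
#'   precomputed [ecfp()] table.
#' @param n_bits,radius Fingerprint parameters (ignored for precomputed
#'   fingerprints).
#' @return A list of class `plif_chemsim`: `matrix` (symmetric, unit
#'   diagonal) and `long` (tibble `compound_a`, `compound_b`,
#'   `similarity`).
#' @export
chem_similarity_matrix <- function(compounds, n_bits = 16384L, radius = 2L) {
  fps <- if (inherits(compounds, "plif_chemfp")) compounds else
    ecfp(compounds, n_bits = n_bits, radius = radius)
  stopifnot(nrow(fps) >= 2)
  n <- nrow(fps)
  m <- matrix(1, n, n, dimnames = list(fps$name, fps$name))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- fps$on_bits[[i]]; b <- fps$on_bits[[j]]
      inter <- length(intersect(a, b))
      s <- if (length(a) + length(b) == 0) 0 else
        inter / (length(a) + length(b) - inter)
      m[i, j] <- m[j, i] <- s
    }
  }
  long <- as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE)) |>
    rename(compound_a = "Var1", compound_b = "Var2", similarity = "Freq")
  structure(list(matrix = m, long = long), class = "plif_chemsim")
}

#' @export
print.plif_chemsim <- function(x, ...) {
  cat(sprintf("<plif_chemsim> %d compounds\n", nrow(x$matrix)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' BOILED-Egg ellipse constants
#'
#' The two ellipses of the BOILED-Egg model in the (TPSA, WLOGP) plane:
#' the white ellipse classifies passive gastrointestinal absorption, the
#' yolk blood-brain-barrier permeation. Constants follow the published
#' model (centre, full width/height, rotation in degrees).
#'
#' @return Tibble with one row per ellipse.
#' @export
boiled_egg_ellipses <- function() {
  tibble::tribble(
    ~region, ~center_x, ~center_y, ~width, ~height, ~angle_deg,
    "white", 71.051, 2.292, 142.081, 8.740, -1.031325,
    "yolk",  38.117, 3.177,  82.061, 5.557, -0.171887
  )
}

#' Point-in-ellipse test (both parameterizations)
#'
#' @param x,y Point coordinates (TPSA, WLOGP).
#' @param ellipse One row of [boiled_egg_ellipses()].
#' @param method `"parametric"` (rotate into the ellipse frame) or
#'   `"implicit"` (evaluate the expanded quadratic form); both agree.
#' @return Logical vector.
#' @export
point_in_ellipse <- function(x, y, ellipse,
                             method = c("parametric", "implicit")) {
  method <- match.arg(method)
  th <- ellipse$angle_deg * pi / 180
  a <- ellipse$width / 2; b <- ellipse$height / 2
  dx <- x - ellipse$center_x; dy <- y - ellipse$center_y
  if (method == "parametric") {
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    (u / a)^2 + (v / b)^2 <= 1
  } else {
    # implicit conic A x'^2 + B x'y' + C y'^2 <= 1 on centred coordinates
    A <- cos(th)^2 / a^2 + sin(th)^2 / b^2
    C <- sin(th)^2 / a^2 + cos(th)^2 / b^2
    B <- 2 * sin(th) * cos(th) * (1 / a^2 - 1 / b^2)
    A * dx^2 + B * dx * dy + C * dy^2 <= 1
  }
}

#' Classify descriptor points with the BOILED-Egg model
#'
#' @param tpsa,wlogp Numeric vectors (topological polar surface area in
#'   square Angstrom; Wildman-Crippen logP).
#' @return Tibble with `tpsa`, `wlogp`, `bbb_permeant` (inside the yolk),
#'   `hia_absorbed` (inside the white, which contains the yolk).
#' @export
classify_boiled_egg <- function(tpsa, wlogp) {
  ell <- boiled_egg_ellipses()
  yolk <- ell[ell$region == "yolk", ]
  white <- ell[ell$region == "white", ]
  tibble(tpsa = tpsa, wlogp = wlogp,
         bbb_permeant = point_in_ellipse(tpsa, wlogp, yolk),
         hia_absorbed = point_in_ellipse(tpsa, wlogp, white) |
           point_in_ellipse(tpsa, wlogp, yolk))
}

#' BOILED-Egg blood-brain-barrier / absorption prediction for compounds
#'
#' Computes WLOGP (Wildman-Crippen atom contributions) and TPSA with rdkit
#' and classifies each compound against the published BOILED-Egg ellipses,
#' locally and offline.
#'
#' @param compounds Tibble with `name` and `smiles`.
#' @return Tibble of class `plif_bbb`: `compound`, `wlogp`, `tpsa`,
#'   `bbb_permeant`, `hia_absorbed`. Per-atom logP contributions are kept
#'   in the `atom_logp` attribute (named list).
#' @export
boiled_egg <- function(compounds) {
  res <- chem_backend(compounds)
  wlogp <- purrr::map_dbl(res, "wlogp")
  tpsa <- purrr::map_dbl(res, "tpsa")
  cls <- classify_boiled_egg(tpsa, wlogp)
  out <- tibble(compound = purrr::map_chr(res, "name"),
                wlogp = wlogp, tpsa = tpsa,
                bbb_permeant = cls$bbb_permeant,
                hia_absorbed = cls$hia_absorbed)
  structure(out,
            atom_logp = setNames(
              purrr::map(res, function(r) as.numeric(r$atom_logp)),
              out$compound),
            class = c("plif_bbb", class(tibble())))
}
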