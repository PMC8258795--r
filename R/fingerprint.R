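#' Define an interaction-fingerprint schema
#'
#' A feature is an unordered pair of interaction types jointly binned by the
#' Euclidean distance between the two ligand-side anchor atoms and the angle
#' between the two protein-to-ligand direction vectors. The key space is
#' enumerated (collision-free), so every on-bit decodes back to a feature.
#' With the defaults (3 types, 1 A bins over \[0, 20), 30 deg bins over
#' \[0, 180\]) the fingerprint has 6 x 20 x 6 = 720 bits.
#'
#' @param type_set Ordered character vector of interaction types.
#' @param distance_max,distance_bin_width Distance binning in Angstrom.
#' @param angle_bin_width Angle bin width in degrees (over \[0, 180\]).
#' @return A list of class `plif_schema`.
#' @export
fingerprint_schema <- function(type_set = c("hbond", "hydrophobic", "halogen"),
                               distance_max = 20, distance_bin_width = 1,
                               angle_bin_width = 30) {
  stopifnot(length(type_set) >= 1, !anyDuplicated(type_set),
            distance_max > 0, distance_bin_width > 0,
            angle_bin_width > 0, 180 %% angle_bin_width == 0)
  dist_edges <- seq(0, distance_max, by = distance_bin_width)
  angle_edges <- seq(0, 180, by = angle_bin_width)
  ts <- sort(type_set)
  pairs <- expand.grid(a = ts, b = ts, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]
  pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
  n_dist <- length(dist_edges) - 1
  n_angle <- length(angle_edges) - 1
  schema <- list(
    type_set = type_set,
    type_pairs = tibble(type_a = pairs$a, type_b = pairs$b,
                        pair_idx = seq_len(nrow(pairs))),
    dist_edges = dist_edges,
    angle_edges = angle_edges,
    n_dist = n_dist,
    n_angle = n_angle,
    length = nrow(pairs) * n_dist * n_angle
  )
  schema$schema_id <- sprintf(
    "ifp|%s|d[0,%g,%g]|a[0,180,%g]",
    paste(ts, collapse = "+"), distance_max, distance_bin_width,
    angle_bin_width)
  structure(schema, class = "plif_schema")
}

#' @export
print.plif_schema <- function(x, ...) {
  cat(sprintf("<plif_schema> %s: %d bits\n", x$schema_id, x$length))
  invisible(x)
}

new_fingerprint <- function(on_bits, schema, source_complex = NA_character_) {
  structure(list(on_bits = sort(unique(as.integer(on_bits))),
                 n_bits = schema$length,
                 schema_id = schema$schema_id,
                 source_complex = source_complex),
            class = "plif_fingerprint")
}

#' @export
print.plif_fingerprint <- function(x, ...) {
  cat(sprintf("<plif_fingerprint> %s: %d/%d bits on (%s)\n",
              x$source_complex %||% "?", length(x$on_bits), x$n_bits,
              x$schema_id))
  invisible(x)
}

# Map one interaction pair to its bit index, or NA when it falls outside
# the binned distance range.
pair_bit_index <- function(schema, type_i, type_j, pair_dist, pair_angle) {
  ts <- sort(c(type_i, type_j))
  pr <- schema$type_pairs
  pidx <- pr$pair_idx[pr$type_a == ts[1] & pr$type_b == ts[2]]
  if (length(pidx) == 0) {
    abort(sprintf("unknown interaction type in pair (%s, %s)", type_i, type_j))
  }
  dbin <- findInterval(pair_dist, schema$dist_edges,
                       rightmost.closed = FALSE)
  if (dbin < 1 || dbin > schema$n_dist) return(NA_integer_)
  abin <- findInterval(pair_angle, schema$angle_edges, rightmost.closed = TRUE)
  if (abin < 1 || abin > schema$n_angle) return(NA_integer_)
  as.integer((pidx - 1L) * schema$n_dist * schema$n_angle +
               (dbin - 1L) * schema$n_angle + abin)
}

#' Encode an interaction pattern as a binary fingerprint
#'
#' Every unordered pair of interactions contributes one feature: the
#' canonicalised type pair, the binned distance between the ligand-side
#' anchor atoms, and the binned angle between the two protein-to-ligand
#' direction vectors. Present features set their bit to 1. Pairs whose
#' anchor distance falls outside the binned range are dropped; the count is
#' recorded in attribute `n_dropped`.
#'
#' @param p A `plif_pattern`.
#' @param schema A [fingerprint_schema()]; all types in `p` must be listed.
#' @return A `plif_fingerprint` (sparse on-bit representation).
#' @export
encode_pattern <- function(p, schema = fingerprint_schema()) {
  if (nrow(p) > 0 && !all(p$itype %in% schema$type_set)) {
    bad <- setdiff(unique(p$itype), schema$type_set)
    abort(sprintf("unknown interaction type(s): %s",
                  paste(bad, collapse = ", ")))
  }
  n <- nrow(p)
  bits <- integer(0)
  dropped <- 0L
  if (n >= 2) {
    idx <- combn(n, 2)
    lig <- cbind(p$lig_x, p$lig_y, p$lig_z)
    dirs <- cbind(p$dir_x, p$dir_y, p$dir_z)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]
      d <- vec_norm(lig[i, ] - lig[j, ])
      ang <- vector_angle_deg(dirs[i, ], dirs[j, ])
      b <- pair_bit_index(schema, p$itype[i], p$itype[j], d, ang)
      if (is.na(b)) dropped <- dropped + 1L else bits <- c(bits, b)
    }
  }
  if (dropped > 0) {
    inform(sprintf("encode_pattern: %d interaction pair(s) outside binned ranges dropped",
                   dropped))
  }
  fp <- new_fingerprint(bits, schema,
                        source_complex = attr(p, "complex_id"))
  attr(fp, "n_dropped") <- dropped
  fp
}

#' Tanimoto similarity of two interaction fingerprints
#'
#' `|A intersect B| / (|A| + |B| - |A intersect B|)` over on-bits. Two empty
#' fingerprints yield 0 with a warning.
#'
#' @param a,b `plif_fingerprint` objects sharing one schema.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (!identical(a$schema_id, b$schema_id)) {
    abort(sprintf("fingerprint schema mismatch: %s vs %s",
                  a$schema_id, b$schema_id))
  }
  na <- length(a$on_bits); nb <- length(b$on_bits)
  if (na == 0 && nb == 0) {
    warn("both fingerprints are empty; returning similarity 0")
    return(0)
  }
  inter <- length(intersect(a$on_bits, b$on_bits))
  inter / (na + nb - inter)
}

#' Decode fingerprint bit indices back to feature descriptions
#'
#' @param bits Integer vector of bit indices (1-based).
#' @param schema The [fingerprint_schema()] the bits were encoded under.
#' @return Tibble with the type pair, distance range, angle range, and a
#'   human-readable description per bit.
#' @export
decode_bits <- function(bits, schema = fingerprint_schema()) {
  bits <- as.integer(bits)
  stopifnot(all(bits >= 1 & bits <= schema$length))
  per_pair <- schema$n_dist * schema$n_angle
  pidx <- (bits - 1L) %/% per_pair + 1L
  rem <- (bits - 1L) %% per_pair
  dbin <- rem %/% schema$n_angle + 1L
  abin <- rem %% schema$n_angle + 1L
  tibble(
    bit = bits,
    type_a = schema$type_pairs$type_a[pidx],
    type_b = schema$type_pairs$type_b[pidx],
    dist_lo = schema$dist_edges[dbin],
    dist_hi = schema$dist_edges[dbin + 1L],
    angle_lo = schema$angle_edges[abin],
    angle_hi = schema$angle_edges[abin + 1L]
  ) |>
    mutate(description = sprintf(
      "%s + %s at %.1f-%.1f A, %g-%g deg",
      .data$type_a, .data$type_b, .data$dist_lo, .data$dist_hi,
      .data$angle_lo, .data$angle_hi))
}
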