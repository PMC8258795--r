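#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a screening result into its hit table
#'
#' @param x A `plif_screen`.
#' @param all Return the full ranking rather than only the filtered hits.
#' @param ... Unused.
#' @return A tibble, one row per hit (or per ranked entry).
#' @export
tidy.plif_screen <- function(x, all = FALSE, ...) {
  if (all) as_tibble(x$ranking) else as_tibble(x$hits)
}

#' One-row summary of a screening result
#'
#' @param x A `plif_screen`.
#' @param ... Unused.
#' @return A one-row tibble: query id, interaction and on-bit counts,
#'   entries ranked, hits retained, threshold, background size.
#' @export
glance.plif_screen <- function(x, ...) {
  tibble(query = x$query_fp$source_complex,
         n_interactions = nrow(x$query_pattern),
         n_on_bits = length(x$query_fp$on_bits),
         n_ranked = nrow(x$ranking),
         n_hits = nrow(x$hits),
         p_max = x$params$p_max,
         bg_n = x$params$bg_n)
}

#' Tidy a superposition into its matched residue pairs
#'
#' @param x A `plif_superposition`.
#' @param ... Unused.
#' @return Tibble of surviving residue pairs and deviations (empty for a
#'   plain coordinate-set fit).
#' @export
tidy.plif_superposition <- function(x, ...) {
  x$matched_pairs %||%
    tibble(residue_a = integer(), residue_b = integer(),
           deviation = numeric())
}

#' One-row summary of a superposition
#'
#' @param x A `plif_superposition`.
#' @param ... Unused.
#' @return A one-row tibble with pair count, RMSD and cycles run.
#' @export
glance.plif_superposition <- function(x, ...) {
  tibble(n_pairs = x$n, rmsd = x$rmsd,
         cycles_run = x$cycles_run %||% NA_integer_,
         det_rotation = det(x$rotation))
}

#' Tidy an alignment into per-column records
#'
#' @param x A `plif_alignment`.
#' @param ... Unused.
#' @return Tibble with one row per alignment column.
#' @export
tidy.plif_alignment <- function(x, ...) {
  ca <- strsplit(x$aligned_a, "")[[1]]
  cb <- strsplit(x$aligned_b, "")[[1]]
  tibble(column = seq_along(ca), a = ca, b = cb,
         identical = ca == cb & ca != "-")
}

#' One-row summary of an alignment
#'
#' @param x A `plif_alignment`.
#' @param ... Unused.
#' @return A one-row tibble with score, identity and parameters.
#' @export
glance.plif_alignment <- function(x, ...) {
  tibble(score = x$score, identity_pct = x$identity_pct,
         alignment_length = nchar(x$aligned_a),
         matrix_name = x$matrix_name, gap_open = x$gap_open,
         gap_extend = x$gap_extend, end_gaps = x$end_gaps)
}
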