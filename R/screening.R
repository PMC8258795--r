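#' Build a fingerprint library with an empirical background distribution
#'
#' Encodes every pattern under one schema and samples the background
#' distribution of library-vs-library Tanimoto similarities used for
#' empirical p-values. When the library has no more than `bg_sample`
#' distinct pairs, all pairs are used; otherwise `bg_sample` pairs are drawn
#' uniformly (seeded).
#'
#' @param patterns List of `plif_pattern` objects (or pre-encoded
#'   `plif_fingerprint`s).
#' @param schema A [fingerprint_schema()].
#' @param bg_sample Background sample size (default 1e6 pairs).
#' @param seed Integer seed for background sampling.
#' @param het_codes Optional character vector of het codes per entry;
#'   defaults to each pattern's `het_code` attribute.
#' @return An object of class `plif_library`.
#' @export
build_library <- function(patterns, schema = fingerprint_schema(),
                          bg_sample = 1e6, seed = 1L, het_codes = NULL) {
  if (length(patterns) == 0) abort("cannot build a library from no patterns")
  fps <- purrr::map(patterns, function(p) {
    if (inherits(p, "plif_fingerprint")) p else encode_pattern(p, schema)
  })
  ids <- purrr::map_chr(fps, function(f) f$source_complex %||% NA_character_)
  if (anyNA(ids)) ids[is.na(ids)] <- sprintf("entry%04d", which(is.na(ids)))
  hets <- het_codes %||%
    purrr::map_chr(patterns, function(p) {
      attr(p, "het_code") %||% NA_character_
    })
  entries <- tibble(complex_id = ids, het_code = hets,
                    on_bits = purrr::map(fps, "on_bits"))
  library_from_entries(entries, schema, bg_sample = bg_sample, seed = seed)
}

# Shared constructor: computes the seeded background sample over entry pairs.
library_from_entries <- function(entries, schema, bg_sample = 1e6,
                                 seed = 1L) {
  n <- nrow(entries)
  stopifnot(n >= 1)
  bits <- entries$on_bits
  tani <- function(i, j) {
    a <- bits[[i]]; b <- bits[[j]]
    na <- length(a); nb <- length(b)
    if (na == 0 && nb == 0) return(0)
    inter <- length(intersect(a, b))
    inter / (na + nb - inter)
  }
  n_pairs <- choose(n, 2)
  if (n_pairs == 0) {
    bg <- numeric(0)
  } else if (n_pairs <= bg_sample) {
    idx <- combn(n, 2)
    bg <- vapply(seq_len(ncol(idx)),
                 function(k) tani(idx[1, k], idx[2, k]), numeric(1))
  } else {
    withr_seed <- seed
    bg <- local({
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(withr_seed)
      i <- sample.int(n, bg_sample, replace = TRUE)
      j <- sample.int(n - 1L, bg_sample, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)  # uniform over ordered distinct pairs
      vapply(seq_len(bg_sample), function(k) tani(i[k], j[k]), numeric(1))
    })
  }
  structure(list(schema = schema, entries = entries,
                 background = sort(bg), bg_seed = seed,
                 bg_n = length(bg)),
            class = "plif_library")
}

#' @export
print.plif_library <- function(x, ...) {
  cat(sprintf("<plif_library> %d entries, %d background pairs (%s)\n",
              nrow(x$entries), x$bg_n, x$schema$schema_id))
  invisible(x)
}

#' Empirical p-value of a similarity against a library background
#'
#' Add-one smoothed upper-tail probability
#' `p = (1 + #\{background >= s\}) / (1 + N)`, monotone non-increasing in
#' `s` and never zero.
#'
#' @param s Numeric vector of similarities.
#' @param lib A `plif_library` with a non-empty background.
#' @return Numeric vector of p-values in (0, 1].
#' @export
empirical_pvalue <- function(s, lib) {
  bg <- lib$background
  if (length(bg) == 0) abort("library has an empty background distribution")
  # background is sorted ascending: #{bg >= s} = N - #{bg < s}, and
  # findInterval(s, bg, left.open = TRUE) counts #{bg < s}.
  n_less <- findInterval(s, bg, left.open = TRUE)
  (1 + length(bg) - n_less) / (1 + length(bg))
}

#' Rank a fingerprint library against a query fingerprint
#'
#' Scores every entry by Tanimoto similarity to the query, assigns
#' contiguous ranks (ties broken by `complex_id` ascending), and attaches
#' empirical p-values. An entry whose `complex_id` equals the query's
#' source complex is excluded (and reported), so true duplicates under a
#' different identifier are still surfaced.
#'
#' @param query A `plif_fingerprint`.
#' @param lib A `plif_library` with a matching schema.
#' @return Tibble of class `plif_hits` with columns `complex_id`,
#'   `het_code`, `similarity`, `rank`, `p_value`.
#' @export
rank_library <- function(query, lib) {
  if (!identical(query$schema_id, lib$schema$schema_id)) {
    abort("query fingerprint schema does not match the library schema")
  }
  entries <- lib$entries
  if (!is.na(query$source_complex) &&
      any(entries$complex_id == query$source_complex)) {
    inform(sprintf("rank_library: excluding the query's own complex '%s'",
                   query$source_complex))
    entries <- filter(entries, .data$complex_id != query$source_complex)
  }
  if (nrow(entries) == 0) {
    warn("library is empty after excluding the query; no hits")
    return(new_hits(tibble(complex_id = character(), het_code = character(),
                           similarity = numeric(), rank = integer(),
                           p_value = numeric())))
  }
  qb <- query$on_bits
  sims <- vapply(entries$on_bits, function(b) {
    na <- length(qb); nb <- length(b)
    if (na == 0 && nb == 0) return(0)
    inter <- length(intersect(qb, b))
    inter / (na + nb - inter)
  }, numeric(1))
  out <- entries |>
    mutate(similarity = sims) |>
    select("complex_id", "het_code", "similarity") |>
    arrange(desc(.data$similarity), .data$complex_id) |>
    mutate(rank = row_number(),
           p_value = empirical_pvalue(.data$similarity, lib))
  new_hits(out)
}

new_hits <- function(tbl) {
  structure(tbl, class = c("plif_hits", class(tibble())))
}

#' Read a het-code to approved-drug mapping table
#'
#' TSV with columns `het_code`, `drug_name`, `approved` (logical). A small
#' demonstration map ships with the package
#' (`system.file("extdata", "drug_map_demo.tsv", package = "plifscreen")`);
#' it makes no claim of completeness.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `het_code`, `drug_name`, `approved`.
#' @export
read_drug_map <- function(path) {
  if (!file.exists(path)) abort(sprintf("drug map file not found: %s", path))
  map <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  stopifnot(all(c("het_code", "drug_name", "approved") %in% names(map)))
  map$approved <- as.logical(map$approved)
  map
}

#' Filter ranked hits to significant approved-drug ligands
#'
#' Retains hits with `p_value <= p_max` whose het code maps to an approved
#' drug, annotates the drug name, and preserves the ranking order. An empty
#' `exclusion_reason` column is added for manual (clinical) triage notes.
#'
#' @param hits A `plif_hits` tibble from [rank_library()].
#' @param p_max Empirical p-value threshold (default 0.001).
#' @param drug_map Tibble from [read_drug_map()].
#' @return Filtered, annotated `plif_hits` tibble.
#' @export
filter_hits <- function(hits, p_max = 0.001, drug_map) {
  stopifnot(p_max >= 0)
  out <- hits |>
    filter(.data$p_value <= p_max) |>
    dplyr::inner_join(filter(drug_map, .data$approved),
                      by = "het_code") |>
    mutate(exclusion_reason = NA_character_) |>
    arrange(.data$rank)
  new_hits(out)
}

#' Screen a query complex against a fingerprint library
#'
#' End-to-end composition: interaction profiling of the query complex,
#' fingerprint encoding under the library schema, Tanimoto ranking,
#' empirical p-values, and filtering to approved-drug ligands. For every
#' retained hit the on-bits shared with the query are decoded back to
#' feature descriptions to support visual key-feature inspection.
#'
#' @param query_structure A `plif_structure`.
#' @param query_ligand One row of its ligand table.
#' @param lib A `plif_library`.
#' @param p_max Empirical p-value threshold (default 0.001).
#' @param drug_map Tibble from [read_drug_map()].
#' @param scope Interaction scope passed to [profile_complex()].
#' @param config An [interaction_config()].
#' @return An object of class `plif_screen`: list with the query
#'   fingerprint, the full ranking, the filtered `hits`, per-hit shared
#'   feature tables, and the run parameters.
#' @export
screen <- function(query_structure, query_ligand, lib, p_max = 0.001,
                   drug_map, scope = "all-chains",
                   config = interaction_config()) {
  pattern <- profile_complex(query_structure, query_ligand, scope = scope,
                             config = config)
  query_fp <- encode_pattern(pattern, lib$schema)
  ranked <- rank_library(query_fp, lib)
  hits <- filter_hits(ranked, p_max = p_max, drug_map = drug_map)
  shared <- purrr::map(hits$complex_id, function(id) {
    bits <- intersect(query_fp$on_bits,
                      lib$entries$on_bits[[match(id, lib$entries$complex_id)]])
    decode_bits(bits, lib$schema)
  })
  names(shared) <- hits$complex_id
  structure(list(query_pattern = pattern, query_fp = query_fp,
                 ranking = ranked, hits = hits, shared_features = shared,
                 params = list(p_max = p_max, scope = scope,
                               schema_id = lib$schema$schema_id,
                               bg_n = lib$bg_n, bg_seed = lib$bg_seed)),
            class = "plif_screen")
}

#' @export
print.plif_screen <- function(x, ...) {
  cat(sprintf("<plif_screen> query %s: %d interactions, %d on-bits\n",
              x$query_fp$source_complex, nrow(x$query_pattern),
              length(x$query_fp$on_bits)))
  cat(sprintf("  %d library entries ranked, %d hit(s) at p <= %g\n",
              nrow(x$ranking), nrow(x$hits), x$params$p_max))
  if (nrow(x$hits) > 0) print(as_tibble(x$hits))
  invisible(x)
}

#' Human-readable screening summary
#'
#' One block per hit listing the interaction features it shares with the
#' query (matched on-bits decoded to type-pair/distance/angle descriptions).
#'
#' @param object A `plif_screen`.
#' @param ... Unused.
#' @return Character vector of report lines, invisibly printed.
#' @export
summary.plif_screen <- function(object, ...) {
  x <- object
  lines <- c(sprintf("Screening report for %s (p <= %g)",
                     x$query_fp$source_complex, x$params$p_max),
             sprintf("%d hits among %d ranked entries",
                     nrow(x$hits), nrow(x$ranking)))
  for (i in seq_len(nrow(x$hits))) {
    h <- x$hits[i, ]
    lines <- c(lines, sprintf(
      "- rank %d %s (%s, %s): similarity %.3f, p = %.2g",
      h$rank, h$complex_id, h$het_code, h$drug_name, h$similarity,
      h$p_value))
    feats <- x$shared_features[[h$complex_id]]
    if (nrow(feats) > 0) {
      lines <- c(lines, paste0("    shared: ", feats$description))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Write a fingerprint library to a JSON file
#'
#' Sparse serialization: schema parameters plus one record per complex
#' (`complex_id`, `het_code`, on-bit indices) and the background sample.
#'
#' @param lib A `plif_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  obj <- list(
    schema = list(type_set = lib$schema$type_set,
                  distance_max = max(lib$schema$dist_edges),
                  distance_bin_width = diff(lib$schema$dist_edges)[1],
                  angle_bin_width = diff(lib$schema$angle_edges)[1]),
    entries = lib$entries |>
      mutate(on_bits = purrr::map(.data$on_bits, as.integer)),
    background = lib$background, bg_seed = lib$bg_seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fingerprint library written by [write_library()]
#'
#' @param path Path to the JSON library file.
#' @return A `plif_library`.
#' @export
read_library <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  schema <- fingerprint_schema(
    type_set = obj$schema$type_set,
    distance_max = obj$schema$distance_max,
    distance_bin_width = obj$schema$distance_bin_width,
    angle_bin_width = obj$schema$angle_bin_width)
  entries <- as_tibble(obj$entries)
  entries$on_bits <- purrr::map(entries$on_bits, as.integer)
  structure(list(schema = schema, entries = entries,
                 background = sort(as.numeric(obj$background)),
                 bg_seed = obj$bg_seed,
                 bg_n = length(obj$background)),
            class = "plif_library")
}
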