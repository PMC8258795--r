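pipeline_defaults <- function() {
  list(
    stages = c("simulate", "screen"),
    out_dir = NULL,
    seed = 1L,
    p_max = 0.001,
    site_cutoff = 7.5,
    scope = "all-chains",
    distance_max = 20,
    distance_bin_width = 1,
    angle_bin_width = 30,
    ecfp_bits = 16384L,
    ecfp_radius = 2L,
    bg_sample = 1e5,
    superpose_cycles = 5L,
    superpose_reject = 2.0,
    query_pdb = NULL,
    query_ligand = NULL,
    library = NULL,
    drug_map = NULL,
    compounds = NULL,
    simulate = list(n_entries = 1000L, density = 0.01, n_planted = 5L,
                    flips = 2L, query_bits = 30L),
    align = NULL
  )
}

#' Validate a pipeline configuration
#'
#' Parses a YAML config (file or text), fills defaults (p-value threshold
#' 0.001, binding-site cutoff 7.5 A, ECFP 16384 bits / radius 2,
#' superposition 5 cycles / 2.0 A), rejects unknown keys, and checks value
#' ranges. All problems are reported together.
#'
#' @param cfg A YAML file path, a YAML string, or a named list.
#' @return A validated config list of class `plif_runconfig`.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg)) {
    cfg <- if (length(cfg) == 1 && file.exists(cfg)) yaml::read_yaml(cfg)
    else yaml::yaml.load(paste(cfg, collapse = "\n"))
  }
  if (!is.list(cfg)) abort("config must be a YAML mapping")
  defaults <- pipeline_defaults()
  problems <- character(0)

  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown) > 0) {
    problems <- c(problems, sprintf("unknown key(s): %s",
                                    paste(unknown, collapse = ", ")))
  }
  if (!is.null(cfg$simulate)) {
    bad <- setdiff(names(cfg$simulate), names(defaults$simulate))
    if (length(bad) > 0) {
      problems <- c(problems, sprintf("unknown simulate key(s): %s",
                                      paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(cfg$align)) {
    bad <- setdiff(names(cfg$align),
                   c("structure_a", "structure_b", "chain_a", "chain_b",
                     "distance_max"))
    if (length(bad) > 0) {
      problems <- c(problems, sprintf("unknown align key(s): %s",
                                      paste(bad, collapse = ", ")))
    }
  }
  merged <- utils::modifyList(defaults, cfg[intersect(names(cfg),
                                                      names(defaults))])
  if (!is.null(cfg$simulate)) {
    merged$simulate <- utils::modifyList(defaults$simulate,
                                         cfg$simulate[intersect(
                                           names(cfg$simulate),
                                           names(defaults$simulate))])
  }

  num_pos <- c("site_cutoff", "distance_max", "distance_bin_width",
               "angle_bin_width", "ecfp_bits", "ecfp_radius", "bg_sample",
               "superpose_cycles", "superpose_reject")
  for (k in num_pos) {
    v <- merged[[k]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      problems <- c(problems, sprintf("%s must be a positive number", k))
    }
  }
  if (!is.numeric(merged$p_max) || length(merged$p_max) != 1 ||
      is.na(merged$p_max) || merged$p_max <= 0 || merged$p_max > 1) {
    problems <- c(problems, "p_max must be in (0, 1]")
  }
  if (is.null(merged$out_dir)) {
    problems <- c(problems, "out_dir is required")
  }
  bad_stage <- setdiff(merged$stages,
                       c("simulate", "screen", "chemsim", "bbb", "align"))
  if (length(bad_stage) > 0) {
    problems <- c(problems, sprintf("unknown stage(s): %s",
                                    paste(bad_stage, collapse = ", ")))
  }
  for (k in c("query_pdb", "library", "drug_map", "compounds")) {
    if (!is.null(merged[[k]]) && !file.exists(merged[[k]])) {
      problems <- c(problems, sprintf("%s file not found: %s", k, merged[[k]]))
    }
  }
  if (length(problems) > 0) {
    abort(paste(c("invalid configuration:",
                  paste0("- ", problems)), collapse = "\n"),
          class = "plif_config_error")
  }
  structure(merged, class = "plif_runconfig")
}

#' Run the screening pipeline from a validated configuration
#'
#' Executes the enabled stages (`simulate`, `screen`, `chemsim`, `bbb`,
#' `align`) and writes `hits.tsv`, `report.json`, `chem_similarity.tsv`,
#' `bbb.tsv`, `correspondence.tsv` and `log.txt` into the output
#' directory. Runs are deterministic given (config, seed); the echoed
#' config in the log reproduces the run.
#'
#' @param cfg A `plif_runconfig` from [validate_config()] (or anything it
#'   accepts).
#' @return The output directory path, invisibly; outputs listed in the
#'   returned attribute `outputs`.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "plif_runconfig")) cfg <- validate_config(cfg)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
  }
  schema <- fingerprint_schema(distance_max = cfg$distance_max,
                               distance_bin_width = cfg$distance_bin_width,
                               angle_bin_width = cfg$angle_bin_width)
  lib <- NULL
  query_fp <- NULL

  if ("simulate" %in% cfg$stages) {
    stage("simulate", {
      sim <- cfg$simulate
      old_seed <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      set.seed(cfg$seed)
      qbits <- sort(sample.int(schema$length, sim$query_bits))
      if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                     envir = globalenv())
      query_fp <- new_fingerprint(qbits, schema,
                                   source_complex = "SIMQUERY")
      lib <- make_fingerprint_library(
        n = sim$n_entries, schema = schema, density = sim$density,
        query = query_fp, n_planted = sim$n_planted, flips = sim$flips,
        bg_sample = cfg$bg_sample, seed = cfg$seed)
    })
  }
  if (!is.null(cfg$library)) {
    stage("library", lib <- read_library(cfg$library))
  }
  if (!is.null(cfg$query_pdb)) {
    stage("query", {
      s <- parse_structure(cfg$query_pdb)
      lig <- select_ligand(s, cfg$query_ligand)
      pat <- profile_complex(s, lig, scope = cfg$scope,
                             config = interaction_config(
                               site_cutoff = cfg$site_cutoff))
      query_fp <- encode_pattern(pat, schema)
    })
  }

  if ("screen" %in% cfg$stages) {
    stage("screen", {
      if (is.null(lib)) abort("no library: enable 'simulate' or set 'library'")
      if (is.null(query_fp)) abort("no query: enable 'simulate' or set 'query_pdb'")
      drug_map <- read_drug_map(
        cfg$drug_map %||% system.file("extdata", "drug_map_demo.tsv",
                                      package = "plifscreen"))
      ranked <- rank_library(query_fp, lib)
      hits <- filter_hits(ranked, p_max = cfg$p_max, drug_map = drug_map)
      readr::write_tsv(as_tibble(hits), file.path(out_dir, "hits.tsv"))
      jsonlite::write_json(
        list(schema_id = schema$schema_id, seed = cfg$seed,
             p_max = cfg$p_max, bg_n = lib$bg_n,
             n_entries = nrow(lib$entries),
             n_ranked = nrow(ranked), n_hits = nrow(hits),
             hits = as_tibble(hits)),
        file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, "hits.tsv", "report.json")
    })
  }
  if ("chemsim" %in% cfg$stages) {
    stage("chemsim", {
      cmp <- read_compounds(cfg$compounds %||% system.file(
        "extdata", "compounds_demo.csv", package = "plifscreen"))
      sim <- chem_similarity_matrix(cmp, n_bits = cfg$ecfp_bits,
                                    radius = cfg$ecfp_radius)
      readr::write_tsv(sim$long, file.path(out_dir, "chem_similarity.tsv"))
      outputs <- c(outputs, "chem_similarity.tsv")
    })
  }
  if ("bbb" %in% cfg$stages) {
    stage("bbb", {
      cmp <- read_compounds(cfg$compounds %||% system.file(
        "extdata", "compounds_demo.csv", package = "plifscreen"))
      readr::write_tsv(as_tibble(boiled_egg(cmp)),
                       file.path(out_dir, "bbb.tsv"))
      outputs <- c(outputs, "bbb.tsv")
    })
  }
  if ("align" %in% cfg$stages) {
    stage("align", {
      al <- cfg$align
      if (is.null(al)) abort("align stage enabled but no 'align' block given")
      sa <- parse_structure(al$structure_a)
      sb <- parse_structure(al$structure_b)
      sup <- iterative_superpose(sa, sb, al$chain_a, al$chain_b,
                                 cycles = cfg$superpose_cycles,
                                 reject_cutoff = cfg$superpose_reject)
      readr::write_tsv(sup$matched_pairs,
                       file.path(out_dir, "correspondence.tsv"))
      outputs <- c(outputs, "correspondence.tsv")
    })
  }

  log_lines <- c(
    sprintf("plifscreen %s", as.character(utils::packageVersion("plifscreen"))),
    sprintf("schema: %s", schema$schema_id),
    sprintf("seed: %d", cfg$seed),
    "config:",
    strsplit(yaml::as.yaml(unclass(cfg)), "\n")[[1]])
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  attr(out_dir, "outputs") <- outputs
  invisible(out_dir)
}

# Resolve "HET", "HET:CHAIN" or NULL (sole ligand) to a ligand row.
select_ligand <- function(s, spec) {
  ligs <- s$ligands
  if (nrow(ligs) == 0) abort("structure has no candidate ligands")
  if (is.null(spec)) {
    if (nrow(ligs) > 1) {
      abort(sprintf("multiple ligands (%s); set query_ligand 'HET[:CHAIN]'",
                    paste(ligs$het_code, collapse = ", ")))
    }
    return(ligs[1, ])
  }
  parts <- strsplit(spec, ":")[[1]]
  sel <- filter(ligs, .data$het_code == parts[1])
  if (length(parts) > 1) sel <- filter(sel, .data$chain_id == parts[2])
  if (nrow(sel) == 0) abort(sprintf("ligand '%s' not found", spec))
  sel[1, ]
}
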