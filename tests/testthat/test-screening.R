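nf <- function(bits, schema, id = NA_character_) {
  plifscreen:::new_fingerprint(bits, schema, source_complex = id)
}

fake_lib <- function(background, schema = fingerprint_schema()) {
  structure(list(schema = schema,
                 entries = tibble::tibble(complex_id = character(),
                                          het_code = character(),
                                          on_bits = list()),
                 background = sort(background), bg_seed = 1L,
                 bg_n = length(background)),
            class = "plif_library")
}

test_that("small libraries use all distinct pairs as background", {
  schema <- fingerprint_schema()
  set.seed(4)
  pats <- lapply(1:10, function(i) nf(which(runif(720) < 0.02), schema,
                                      sprintf("C%02d", i)))
  lib <- build_library(pats, schema, bg_sample = 1e6, seed = 2,
                       het_codes = rep("ZZZ", 10))
  expect_equal(lib$bg_n, choose(10, 2))   # 45 exhaustive pairs
  lib2 <- build_library(pats, schema, bg_sample = 1e6, seed = 2,
                        het_codes = rep("ZZZ", 10))
  expect_identical(lib$background, lib2$background)
  expect_error(build_library(list(), schema), "no patterns")
})

test_that("sampled backgrounds are seed-deterministic", {
  schema <- fingerprint_schema()
  lib1 <- make_fingerprint_library(300, schema, density = 0.01,
                                   bg_sample = 500, seed = 7)
  lib2 <- make_fingerprint_library(300, schema, density = 0.01,
                                   bg_sample = 500, seed = 7)
  expect_identical(lib1$background, lib2$background)
  expect_equal(lib1$bg_n, 500)
})

test_that("background similarity agrees with an independent Monte-Carlo oracle", {
  schema <- fingerprint_schema()
  lib <- make_fingerprint_library(400, schema, density = 0.01,
                                  bg_sample = 1e4, seed = 31)
  # independent oracle: fresh Bernoulli fingerprints via rbinom, direct
  # set-algebra Tanimoto
  set.seed(777)
  oracle <- replicate(4000, {
    a <- which(rbinom(schema$length, 1, 0.01) == 1)
    b <- which(rbinom(schema$length, 1, 0.01) == 1)
    tanimoto_set_oracle(a, b)
  })
  se <- sqrt(var(oracle) / length(oracle) + var(lib$background) / lib$bg_n)
  expect_lt(abs(mean(lib$background) - mean(oracle)), 3 * se + 1e-12)
})

test_that("empirical p-values are add-one smoothed and monotone", {
  lib <- fake_lib(c(0.1, 0.2, 0.2, 0.3))
  # s = 0: all 4 background values >= 0 -> p = 1
  expect_equal(empirical_pvalue(0, lib), 1)
  # above the maximum: p = 1/(N+1)
  expect_equal(empirical_pvalue(0.9, lib), 1 / 5)
  # ties count as >=
  expect_equal(empirical_pvalue(0.2, lib), (1 + 3) / 5)
  s <- seq(0, 1, 0.05)
  expect_true(all(diff(empirical_pvalue(s, lib)) <= 0))
  # agreement with the direct counting definition on random backgrounds
  set.seed(9)
  bg <- runif(500)
  rl <- fake_lib(bg)
  qs <- c(runif(50), sample(bg, 20))
  expect_equal(empirical_pvalue(qs, rl),
               vapply(qs, function(q) (1 + sum(bg >= q)) / (1 + 500),
                      numeric(1)))
  expect_error(empirical_pvalue(0.5, fake_lib(numeric(0))), "empty")
})

test_that("a background constructed below s yields exactly p = 0.001", {
  set.seed(12)
  lib <- fake_lib(runif(999, 0, 0.49))
  expect_equal(empirical_pvalue(0.5, lib), 1 / 1000)
  expect_lte(empirical_pvalue(0.5, lib), 0.001)   # passes the cut exactly
})

test_that("ranking recovers a planted near-duplicate at rank 1", {
  schema <- fingerprint_schema()
  set.seed(5)
  query <- nf(sample.int(720, 30), schema, "QUERY")
  lib <- make_fingerprint_library(100, schema, density = 0.01,
                                  query = query, n_planted = 1, flips = 2,
                                  bg_sample = 1000, seed = 6)
  hits <- rank_library(query, lib)
  expect_equal(hits$complex_id[1], "PLT01")
  expect_equal(hits$rank, seq_len(nrow(hits)))
  expect_true(all(diff(hits$similarity) <= 0))
})

test_that("ties are broken by complex id and the query excludes itself", {
  schema <- fingerprint_schema()
  entries <- tibble::tibble(
    complex_id = c("BBB", "AAA", "QRY"),
    het_code = "XXX",
    on_bits = list(c(1L, 2L), c(1L, 2L), c(1L, 2L, 3L)))
  lib <- plifscreen:::library_from_entries(entries, schema, bg_sample = 10,
                                           seed = 1)
  q <- nf(c(1L, 2L, 3L), schema, "QRY")
  expect_message(hits <- rank_library(q, lib), "excluding the query")
  expect_equal(hits$complex_id, c("AAA", "BBB"))
  expect_equal(hits$similarity, c(2 / 3, 2 / 3))
})

test_that("an empty library warns and returns no hits", {
  schema <- fingerprint_schema()
  entries <- tibble::tibble(complex_id = "ONLY", het_code = "XXX",
                            on_bits = list(c(1L, 5L)))
  lib <- plifscreen:::library_from_entries(entries, schema, bg_sample = 10,
                                           seed = 1)
  q <- nf(c(1L, 5L), schema, "ONLY")
  suppressMessages(expect_warning(hits <- rank_library(q, lib), "empty"))
  expect_equal(nrow(hits), 0)
})

test_that("hit filtering annotates drugs, preserves order, never reorders", {
  hits <- plifscreen:::new_hits(tibble::tibble(
    complex_id = c("X1", "X2", "X3", "X4"),
    het_code = c("AAA", "BBB", "AAA", "CCC"),
    similarity = c(0.9, 0.8, 0.7, 0.6),
    rank = 1:4,
    p_value = c(0.0001, 0.0002, 0.002, 0.0003)))
  map <- tibble::tibble(het_code = c("AAA", "CCC"),
                        drug_name = c("DrugX", "DrugZ"),
                        approved = c(TRUE, FALSE))
  out <- filter_hits(hits, p_max = 0.001, drug_map = map)
  expect_equal(out$complex_id, "X1")        # X3 fails p, X2 unmapped,
  expect_equal(out$drug_name, "DrugX")      # X4's drug not approved
  expect_identical(out$rank, 1L)
  # empty map and impossible threshold
  empty_map <- map[0, ]
  expect_equal(nrow(filter_hits(hits, 0.001, empty_map)), 0)
  expect_equal(nrow(filter_hits(hits, 0, map)), 0)
  # filtering is a subset that preserves relative order
  out2 <- filter_hits(hits, p_max = 1, drug_map = map)
  expect_lte(nrow(out2), nrow(hits))
  expect_true(!is.unsorted(out2$rank))
})

test_that("null screens produce calibrated p-values", {
  schema <- fingerprint_schema()
  lib <- make_fingerprint_library(200, schema, density = 0.02,
                                  bg_sample = 1e6, seed = 17)
  set.seed(18)
  n_trials <- 400
  p <- replicate(n_trials, {
    q <- which(runif(schema$length) < 0.02)
    entry <- lib$entries$on_bits[[sample.int(200, 1)]]
    empirical_pvalue(tanimoto_set_oracle(q, entry), lib)
  })
  for (alpha in c(0.01, 0.05, 0.1)) {
    se <- sqrt(alpha * (1 - alpha) / n_trials)
    expect_lte(mean(p <= alpha), alpha + 3 * se)
  }
})

test_that("library JSON serialization round-trips", {
  schema <- fingerprint_schema()
  lib <- make_fingerprint_library(20, schema, density = 0.02,
                                  bg_sample = 100, seed = 3)
  path <- tempfile(fileext = ".json")
  write_library(lib, path)
  lib2 <- read_library(path)
  expect_equal(lib2$schema$schema_id, lib$schema$schema_id)
  expect_equal(lib2$entries$complex_id, lib$entries$complex_id)
  expect_identical(lib2$entries$on_bits, lib$entries$on_bits)
  expect_equal(lib2$background, lib$background)
})

test_that("screen() composes profiling, ranking and decoding end to end", {
  # query complex with three planted interactions
  cm <- make_complex(list(planted_spec("hbond", distance = 2.9),
                          planted_spec("hbond", distance = 3.2,
                                       protein_part = "sidechain"),
                          planted_spec("hydrophobic", distance = 3.7)),
                     seed = 44)
  s <- parse_structure(cm$pdb, entry_id = "QRY")
  schema <- fingerprint_schema()
  qpat <- profile_complex(s, s$ligands[1, ])
  qfp <- encode_pattern(qpat, schema)
  # library: random entries + one identical copy under a different id
  set.seed(45)
  rnd <- lapply(1:200, function(i) nf(which(runif(720) < 0.01), schema,
                                      sprintf("SYN%03d", i)))
  twin <- nf(qfp$on_bits, schema, "TWIN")
  lib <- build_library(c(rnd, list(twin)), schema, bg_sample = 1e5,
                       seed = 46, het_codes = c(rep("ZZZ", 200), "PLT"))
  map <- read_drug_map(system.file("extdata", "drug_map_demo.tsv",
                                   package = "plifscreen"))
  res <- screen(s, s$ligands[1, ], lib, p_max = 0.001, drug_map = map)
  expect_s3_class(res, "plif_screen")
  expect_equal(res$ranking$complex_id[1], "TWIN")
  expect_equal(res$ranking$similarity[1], 1.0)
  expect_true("TWIN" %in% res$hits$complex_id)
  # every matched bit decodes to a feature description
  feats <- res$shared_features[["TWIN"]]
  expect_equal(nrow(feats), length(qfp$on_bits))
  expect_true(all(grepl("at .* A, .* deg", feats$description)))
  # broom interface
  expect_equal(nrow(tidy(res)), nrow(res$hits))
  g <- glance(res)
  expect_equal(g$n_ranked, 201)
  expect_equal(g$p_max, 0.001)
  rep_lines <- capture.output(summary(res))
  expect_true(any(grepl("TWIN", rep_lines)))
})
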