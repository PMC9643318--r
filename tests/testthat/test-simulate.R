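test_that("gen_deg_table plants exactly the requested differential genes", {
  spec <- simulation_spec(n_genes = 100, frac_de = 0.2, seed = 1)
  out <- gen_deg_table(spec)
  expect_length(out$truth, 20)
  recovered <- filter_degs(out$table)
  expect_setequal(names(recovered$direction), out$truth)

  none <- gen_deg_table(simulation_spec(n_genes = 100, frac_de = 0, seed = 1))
  expect_length(none$truth, 0)
  expect_length(filter_degs(none$table), 0)
})

test_that("generators are pure functions of (spec, seed)", {
  spec <- simulation_spec(n_genes = 60, frac_de = 0.1, n_compounds = 4,
                          n_cell_lines = 10, n_response_drugs = 6,
                          n_frames = 5, n_particles = 4, seed = 9)
  expect_identical(gen_deg_table(spec), gen_deg_table(spec))
  expect_identical(gen_rankings(spec), gen_rankings(spec))
  disease <- filter_degs(gen_deg_table(spec)$table)
  expect_identical(gen_signatures(spec, disease),
                   gen_signatures(spec, disease))
  expect_identical(gen_response_matrix(spec), gen_response_matrix(spec))
  expect_identical(gen_trajectory(spec), gen_trajectory(spec))
  # different seeds give different draws
  spec2 <- simulation_spec(n_genes = 60, frac_de = 0.1, seed = 10)
  expect_false(identical(gen_deg_table(spec)$truth, gen_deg_table(spec2)$truth))
})

test_that("generators leave the global RNG stream untouched", {
  set.seed(123)
  expected <- runif(3)
  set.seed(123)
  invisible(gen_deg_table(simulation_spec(n_genes = 30, seed = 5)))
  expect_identical(runif(3), expected)
})

test_that("gen_rankings: full overlap and zero noise reproduce the latent order", {
  spec <- simulation_spec(n_drugs = 60, drugs_per_source = 30,
                          source_overlap = 1, rank_noise_sd = 0, seed = 4)
  out <- gen_rankings(spec)
  expect_length(out$rankings, 3)
  for (r in out$rankings) {
    expect_length(r$drug, 30)
    expect_equal(r$drug, intersect(out$truth, r$drug))
  }
  # all sources identical
  expect_equal(out$rankings[[1]]$drug, out$rankings[[2]]$drug)
})

test_that("gen_signatures encodes the planted reversal strengths", {
  spec <- simulation_spec(n_genes = 400, frac_de = 0.5, n_compounds = 3,
                          reversal_strength = c(1, 0.5, 0),
                          n_shared_genes = 100, seed = 2)
  disease <- filter_degs(gen_deg_table(spec)$table)
  out <- gen_signatures(spec, disease)
  expect_equal(unname(out$truth), c(1, 0.5, 0))
  # strength 1: pure reverser => zero mimic edges on the shared set
  rs <- raw_score(out$signatures[[1]], disease)
  expect_equal(rs$deg_mim, 0L)
  expect_equal(rs$raw, 1)
  # strength 0: pure mimic
  expect_equal(raw_score(out$signatures[[3]], disease)$raw, -1)
  # strength 0.5 over 100 shared genes: expectation 0, |raw| small
  expect_lt(abs(raw_score(out$signatures[[2]], disease)$raw), 0.2)
})

test_that("gen_smiles_library yields parsable, truth-paired structures", {
  lib <- gen_smiles_library(10, seed = 1)
  expect_equal(nrow(lib$compounds), 10)
  expect_false(anyNA(lib$compounds$canonical))
  expect_false(anyDuplicated(lib$compounds$canonical) > 0)
  expect_gte(nrow(lib$pairs), 1)
  sim <- similarity_matrix(fingerprint_matrix(lib$compounds))
  for (i in seq_len(nrow(lib$pairs)))
    expect_gt(sim[lib$pairs$id_a[i], lib$pairs$id_b[i]], 0.8)
})

test_that("gen_response_matrix plants sensitivity and missingness as specified", {
  spec <- simulation_spec(n_cell_lines = 50, n_response_drugs = 12,
                          n_sensitive = 3, na_fraction = 0, seed = 6)
  out <- gen_response_matrix(spec)
  expect_false(anyNA(out$matrix))
  sens <- out$matrix[, out$truth_sensitive]
  expect_true(all(sens < 10))
  others <- out$matrix[, setdiff(colnames(out$matrix), out$truth_sensitive)]
  expect_true(all(others >= 10))

  spec2 <- simulation_spec(n_cell_lines = 50, n_response_drugs = 12,
                           na_fraction = 0.1, n_overmissing = 2, seed = 6)
  out2 <- gen_response_matrix(spec2)
  frac <- colMeans(is.na(out2$matrix[, out2$truth_overmissing, drop = FALSE]))
  expect_true(all(frac > 0.2))
  kept <- drop_missing_drugs(out2$matrix, 0.20)
  expect_true(all(!out2$truth_overmissing %in% colnames(kept)))
})

test_that("simulate_workspace writes a complete readable toy workspace", {
  dir <- withr::local_tempdir()
  spec <- simulation_spec(n_genes = 80, frac_de = 0.2, n_compounds = 4,
                          n_cell_lines = 12, n_response_drugs = 6,
                          n_frames = 6, n_particles = 4, seed = 3)
  paths <- simulate_workspace(spec, dir)
  expect_true(all(file.exists(unlist(paths))))
  expect_equal(nrow(read_deg_table(paths$deg)), 80)
  expect_length(read_rankings(paths$rankings), 3)
  expect_length(read_signatures(paths$signatures), 4)
  expect_equal(nrow(read_smiles(paths$smiles)), 4)
  expect_equal(dim(read_response_matrix(paths$response_screen1)), c(12, 6))
  expect_equal(dim(read_trajectory(paths$trajectory)$coords)[1:2], c(6, 4))
  truth <- jsonlite::fromJSON(paths$truth)
  expect_setequal(names(truth$reversal_strength),
                  names(read_signatures(paths$signatures)))
})
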