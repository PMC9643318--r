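test_that("truncate_ranking keeps ranks at or below the cutoff", {
  r <- source_ranking("s", sprintf("d%02d", 1:80))
  expect_length(truncate_ranking(r, 50)$drug, 50)
  expect_equal(truncate_ranking(r, 50)$rank, 1:50)
  short <- source_ranking("s", c("a", "b"))
  expect_equal(truncate_ranking(short, 50), short)
  expect_equal(truncate_ranking(r, 1)$drug, "d01")
})

test_that("consensus_prior reproduces the hand-computed examples", {
  # single source, rank 1 => prior 1
  one <- consensus_prior(list(source_ranking("s1", "a")), cutoff = 50)
  expect_equal(one$prior, 1)

  # K=2, ranks 2 and 4, cutoff 50 => (2/2)*(1 - 2/50) = 0.96
  r1 <- source_ranking("s1", c("x", "target", "y", "z"))
  r2 <- source_ranking("s2", c("p", "q", "r", "target"))
  out <- consensus_prior(list(r1, r2), cutoff = 50)
  expect_equal(out$prior[out$drug == "target"], 0.96)
  expect_equal(out$k[out$drug == "target"], 2)
  expect_equal(out$mean_rank[out$drug == "target"], 3)

  # occurrence weighting: rank 1 in both sources beats rank 1 in one
  rA <- source_ranking("sA", c("both", "only"))
  rB <- source_ranking("sB", c("both", "other"))
  out2 <- consensus_prior(list(rA, rB), cutoff = 50)
  expect_equal(out2$prior[out2$drug == "both"], 1)
  expect_equal(out2$prior[out2$drug == "only"], 0.5 * (1 - 1 / 50))
})

test_that("consensus_prior is monotone and permutation-invariant", {
  K <- 2; cutoff <- 50
  prior_formula <- function(k, mr) (k / K) * (1 - (mr - 1) / cutoff)
  set.seed(31)
  for (rep in 1:1000) {
    k <- sample(1:K, 2, replace = TRUE)
    mr <- runif(2, 1, cutoff)
    # increasing k at fixed mean rank never lowers the prior
    expect_gte(prior_formula(max(k), mr[1]), prior_formula(min(k), mr[1]))
    # decreasing mean rank at fixed k never lowers the prior
    expect_gte(prior_formula(k[1], min(mr)), prior_formula(k[1], max(mr)))
  }
  rk <- gen_rankings(simulation_spec(n_drugs = 40, drugs_per_source = 20,
                                     seed = 8))$rankings
  a <- consensus_prior(rk, cutoff = 50)
  b <- consensus_prior(rev(rk), cutoff = 50)
  expect_equal(a, b)
})

test_that("zero-noise simulation recovers the planted ordering exactly", {
  spec <- simulation_spec(n_drugs = 80, drugs_per_source = 40,
                          source_overlap = 1, rank_noise_sd = 0, seed = 13)
  out <- gen_rankings(spec)
  prior <- consensus_prior(out$rankings, cutoff = 50)
  expect_equal(prior$drug, intersect(out$truth, prior$drug))
})

test_that("consensus prior tracks the latent order at moderate noise", {
  set.seed(101)
  rhos <- replicate(100, {
    seed <- sample.int(1e6, 1)
    spec <- simulation_spec(n_drugs = 60, drugs_per_source = 50,
                            source_overlap = 0.8, rank_noise_sd = 3,
                            seed = seed)
    out <- gen_rankings(spec)
    prior <- consensus_prior(out$rankings, cutoff = 50)
    latent <- match(prior$drug, out$truth)
    cor(seq_along(prior$drug), latent, method = "spearman")
  })
  expect_gt(mean(rhos), 0.8)
})

test_that("functional_score is overlap precision", {
  disease <- signed_gene_set(c("g1", "g2", "g3"), c(1, -1, 1))
  expect_equal(functional_score(c("a", "b"), disease), 0)
  expect_equal(functional_score(c("g1", "g2"), disease), 1)
  expect_equal(functional_score(c("g1", "a", "b", "c"), disease), 0.25)
  expect_error(functional_score(character(0), disease), "non-empty")
})

test_that("structural_score counts the four drug-likeness rules", {
  expect_equal(as.numeric(structural_score("CCO")), 1)  # ethanol passes all
  # a very greasy long chain fails only the logP rule
  greasy <- paste(rep("C", 30), collapse = "")
  s <- structural_score(greasy)
  expect_equal(as.numeric(s), 0.75)
  expect_false(attr(s, "rules")[["logp"]])
  expect_true(as.numeric(s) %in% c(0, 0.25, 0.5, 0.75, 1))
  expect_error(structural_score("not_a_smiles)("), "unparsable")
})

test_that("codres_score applies the study weights exactly and linearly", {
  expect_equal(codres_score(1, 1, 1), 1)
  expect_equal(codres_score(1, 0, 0), 0.45)
  expect_equal(codres_score(0, 1, 0), 0.45)
  expect_equal(codres_score(0, 0, 1), 0.1)
  # linearity: scaling all components scales the composite
  set.seed(7)
  for (rep in 1:20) {
    comp <- runif(3); c_scale <- runif(1)
    expect_equal(codres_score(comp[1] * c_scale, comp[2] * c_scale,
                              comp[3] * c_scale),
                 c_scale * codres_score(comp[1], comp[2], comp[3]),
                 tolerance = 1e-12)
  }
  expect_error(codres_score(1.2, 0, 0), "\\[0, 1\\]")
  expect_error(codres_score(1, 0, 0, weights = c(0.5, 0.5, 0.5)), "sum")
})

test_that("score_drugs assembles components into a sorted composite table", {
  rk <- gen_rankings(simulation_spec(n_drugs = 30, drugs_per_source = 15,
                                     seed = 17))$rankings
  disease <- signed_gene_set(c("g1", "g2"), c(1, -1))
  targets <- list(); smiles <- character(0)
  top <- rk[[1]]$drug[1]
  targets[[top]] <- c("g1", "zz")
  smiles[top] <- "CCO"
  out <- score_drugs(rk, disease, drug_targets = targets,
                     drug_smiles = smiles)
  expect_true(all(diff(out$composite) <= 0))
  row <- out[out$drug == top, ]
  expect_equal(row$FS, 0.5)
  expect_equal(row$StS, 1)
  expect_equal(row$composite, 0.45 * row$aS + 0.45 * 0.5 + 0.1 * 1)
})
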