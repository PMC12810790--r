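test_that("proteome generation is deterministic and respects sharing", {
  cfg <- simConfig(n_proteins_alga = 200L, n_proteins_bacterium = 100L,
                   sharing_rate = 0)
  p1 <- generateProteomes(cfg, seed = 7)
  p2 <- generateProteomes(cfg, seed = 7)
  expect_identical(p1, p2)
  ## no sharing forces uniqueness
  expect_true(all(p1$peptides$n_parents == 1L))
  ## fasta_order is a permutation, abundances positive
  expect_setequal(p1$proteins$fasta_order, seq_len(300))
  expect_true(all(p1$proteins$base_abundance > 0))
  ## sharing rate recovered within a binomial 99% interval
  cfg2 <- simConfig(n_proteins_alga = 200L, n_proteins_bacterium = 100L,
                    sharing_rate = 0.2, peptides_per_protein = 6)
  p3 <- generateProteomes(cfg2, seed = 11)
  n <- nrow(p3$peptides)
  shared <- mean(p3$peptides$n_parents >= 2L)
  half_width <- 2.576 * sqrt(0.2 * 0.8 / n)
  expect_lt(abs(shared - 0.2), half_width)
  ## invalid configurations are rejected
  expect_error(simConfig(sharing_rate = 1.5), "sharing_rate")
  expect_error(simConfig(n_proteins_alga = 0), "n_proteins_alga")
})

test_that("effects multiply coculture abundance and record regulation", {
  pr <- generateProteomes(tiny_sim_config(), seed = 1)
  tr <- simTruth(pr$proteins)
  ## null effect
  expect_true(all(tr$true_log2fc == 0) && !any(tr$is_regulated))
  ## +2 quadruples coculture abundance
  tr2 <- imposeEffects(tr, protein_ids = tr$protein_id[3], log2_effect = 2)
  expect_equal(tr2$abundance_coculture[3], 4 * tr2$abundance_mono[3])
  expect_true(tr2$is_regulated[3])
  expect_equal(tr2$abundance_coculture[-3], tr2$abundance_mono[-3])
  ## sampled fraction at +/-2: mean magnitude over the regulated set is 2
  tr3 <- imposeEffects(tr, fraction = 0.2, log2_effect = 2, seed = 5)
  expect_equal(mean(abs(tr3$true_log2fc[tr3$is_regulated])), 2)
  expect_error(imposeEffects(tr, protein_ids = "nope"), "unknown protein")
})

test_that("mixing respects biomass fractions and conserves load", {
  cfg <- tiny_sim_config(sharing_rate = 0)
  pr <- generateProteomes(cfg, seed = 2)
  cc <- mixSamples(pr, bacterial_fraction = 0.10, total_load = 0.5)
  ## total load conserved to 1e-9 relative
  expect_equal(sum(cc$amount), 0.5, tolerance = 1e-9)
  ## bacterial peptides sum to 10% of the load
  expect_equal(sum(cc$amount[cc$organism == "bacterium"]) / sum(cc$amount),
               0.10, tolerance = 1e-9)
  ## fraction 0 reproduces the algal monoculture composition
  am <- mixSamples(pr, bacterial_fraction = 0)
  expect_true(all(am$organism == "alga"))
  cc0 <- mixSamples(pr, bacterial_fraction = 0)
  expect_identical(am$amount, cc0$amount)
  expect_error(mixSamples(pr, bacterial_fraction = 1.2), "\\[0, 1\\]")
})

test_that("a symmetric two-peptide mix splits the load evenly", {
  proteins <- data.frame(protein_id = c("A1", "B1"), gene_id = c("A1", "B1"),
                         organism = c("alga", "bacterium"),
                         base_abundance = c(1, 1), fasta_order = 1:2)
  peptides <- data.frame(peptide = c("PEPA", "PEPB"), ionization = c(1, 1),
                         hydrophobicity = c(0, 1), n_parents = 1L,
                         organism = c("alga", "bacterium"))
  map <- peptideProteinMap(data.frame(peptide = c("PEPA", "PEPB"),
                                      protein_id = c("A1", "B1")), proteins)
  pr <- list(proteins = proteins, peptides = peptides, map = map)
  comp <- mixSamples(pr, bacterial_fraction = 0.5, total_load = 1)
  expect_equal(sort(comp$amount), c(0.5, 0.5))
})

test_that("fractionation is conservative and concatenates round-robin", {
  pr <- generateProteomes(tiny_sim_config(), seed = 3)
  comp <- mixSamples(pr, bacterial_fraction = 0.1)
  ## identity at a single fraction
  f1 <- fractionate(comp, 1L)
  expect_equal(length(f1), 1L)
  expect_equal(f1[[1]]$amount, comp$amount)
  ## conservation and set union for several levels
  for (nf in c(6L, 12L)) {
    fr <- fractionate(comp, nf)
    expect_equal(sum(vapply(fr, function(f) sum(f$amount), numeric(1))),
                 sum(comp$amount), tolerance = 1e-12)
    expect_setequal(unlist(lapply(fr, `[[`, "peptide")), comp$peptide)
  }
  ## 24 fine bins into 6 fractions: fraction 1 carries bins 1, 7, 13, 19
  comp24 <- data.frame(peptide = sprintf("p%02d", 1:24), amount = 1,
                       hydrophobicity = 1:24, organism = "alga")
  fr6 <- fractionate(comp24, 6L, n_fine_bins = 24L)
  expect_setequal(fr6[[1]]$peptide, sprintf("p%02d", c(1, 7, 13, 19)))
  expect_setequal(fr6[[2]]$peptide, sprintf("p%02d", c(2, 8, 14, 20)))
  expect_error(fractionate(comp, 0L), ">= 1")
})

test_that("acquisition reports everyone when capacity suffices and is seeded", {
  pr <- generateProteomes(tiny_sim_config(), seed = 4)
  comp <- mixSamples(pr, bacterial_fraction = 0.1)
  roomy <- acquisitionConfig(top_n = nrow(comp), n_rt_windows = 1L,
                             detection_floor = 0)
  obs <- simulateDdaRun(comp, roomy, seed = 9)
  expect_setequal(obs$peptide, comp$peptide)
  ## determinism
  tight <- tiny_acq()
  o1 <- simulateDdaRun(comp, tight, seed = 5)
  o2 <- simulateDdaRun(comp, tight, seed = 5)
  expect_identical(o1, o2)
  expect_false(identical(o1, simulateDdaRun(comp, tight, seed = 6)))
  ## capacity caps the identifications
  expect_lte(nrow(o1), tight@top_n * tight@n_rt_windows)
  ## empty composition
  empty <- comp[0, ]
  expect_equal(nrow(simulateDdaRun(empty, tight, seed = 1)), 0L)
})

test_that("minor-organism identifications drop as the major fraction rises", {
  ## suppression direction checked by Monte Carlo at biomass fractions
  ## 0, 0.5, 0.9 of the major (algal) partner
  cfg <- tiny_sim_config()
  pr <- generateProteomes(cfg, seed = 6)
  acq <- tiny_acq()
  mean_bact <- vapply(c(1, 0.5, 0.1), function(bf) {
    comp <- mixSamples(pr, bacterial_fraction = bf)
    mean(vapply(1:200, function(s) {
      obs <- simulateDdaRun(comp, acq, seed = s)
      sum(obs$peptide %in% pr$peptides$peptide[pr$peptides$organism == "bacterium"])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_bact) < 0))
})

test_that("identification probability rises with peptide amount", {
  cfg <- tiny_sim_config()
  pr <- generateProteomes(cfg, seed = 8)
  comp <- mixSamples(pr, bacterial_fraction = 0.1)
  acq <- tiny_acq()
  hits <- matrix(0, nrow(comp), 40)
  for (s in 1:40) {
    obs <- simulateDdaRun(comp, acq, seed = 100 + s)
    hits[, s] <- comp$peptide %in% obs$peptide
  }
  minor <- comp$organism == "bacterium"
  fit <- suppressWarnings(
    glm(cbind(rowSums(hits[minor, ]), 40 - rowSums(hits[minor, ])) ~
          log(comp$amount[minor]), family = binomial))
  expect_gt(coef(fit)[2], 0)
})

test_that("experiment simulation has the declared structure", {
  cfg <- tiny_sim_config()
  acq <- tiny_acq()
  sim <- simulateExperiment(cfg, acq, seed = 3)
  ## 4 conditions x 3 replicates
  expect_equal(nrow(sim$design), 12L)
  expect_setequal(unique(sim$observations$sample_id), sim$design$sample_id)
  ## mono-mix fraction equals the coculture fraction when ratio error is 0
  expect_equal(sim$design$bacterial_fraction[sim$design$condition == "mono_mix"],
               rep(cfg@bacterial_fraction_coculture, 3))
  ## determinism of the whole experiment
  sim2 <- simulateExperiment(cfg, acq, seed = 3)
  expect_identical(sim$observations, sim2$observations)
  ## replicate error propagates
  expect_error(simulateExperiment(simConfig(replicates = 1L), acq),
               "at least 2 replicates")
})

test_that("with all noise off, replicates are identical", {
  cfg <- tiny_sim_config(biological_sdlog2 = 0)
  acq <- tiny_acq(noise_sigma = 0, selection_softness = 0)
  sim <- simulateExperiment(cfg, acq, conditions = c("coculture"), seed = 2)
  tabs <- split(sim$observations[, c("peptide", "abundance")],
                sim$observations$sample_id)
  tabs <- lapply(tabs, function(d) { rownames(d) <- NULL; d })
  expect_identical(tabs[[1]], tabs[[2]])
  expect_identical(tabs[[1]], tabs[[3]])
})

test_that("fractionating raises distinct identifications", {
  cfg <- tiny_sim_config()
  pr <- generateProteomes(cfg, seed = 9)
  comp <- mixSamples(pr, bacterial_fraction = 0.1)
  acq <- acquisitionConfig(n_rt_windows = 4L)  # tight capacity
  counts <- vapply(c(1L, 6L), function(nf) {
    mean(vapply(1:20, function(s) {
      fr <- fractionate(comp, nf)
      length(unique(unlist(lapply(seq_along(fr), function(j) {
        simulateDdaRun(fr[[j]], acq, seed = s * 100 + j)$peptide
      }))))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(counts[2], counts[1])
})
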