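test_that("parsimony applies rules a-d as specified", {
  prot <- function(ids) data.frame(protein_id = ids, gene_id = ids,
                                   organism = "alga",
                                   fasta_order = seq_along(ids))
  ## (a) unique mapping
  m <- peptideProteinMap(data.frame(peptide = "p1", protein_id = "A"),
                         prot("A"))
  a <- assignParsimony(m)
  expect_equal(a$protein_id, "A")
  expect_equal(a$rule, "a")
  ## (b) shared peptide follows the candidate with unique evidence
  m <- peptideProteinMap(
    data.frame(peptide = c("p1", "p2", "p2"),
               protein_id = c("A", "A", "B")), prot(c("A", "B")))
  a <- assignParsimony(m)
  expect_equal(a$protein_id[a$peptide == "p2"], "A")
  expect_equal(a$rule[a$peptide == "p2"], "b")
  ## (c) candidate with most other non-unique peptides wins
  m <- peptideProteinMap(
    data.frame(peptide = c("p1", "p1", "p2", "p2", "p3", "p3"),
               protein_id = c("A", "B", "A", "B", "A", "C")),
    prot(c("A", "B", "C")))
  a <- assignParsimony(m)
  expect_true(all(a$protein_id == "A"))
  ## (d) remaining ties break by database order
  m <- peptideProteinMap(
    data.frame(peptide = c("p1", "p1"), protein_id = c("B", "A")),
    data.frame(protein_id = c("A", "B"), gene_id = c("A", "B"),
               organism = "alga", fasta_order = c(2L, 1L)))
  a <- assignParsimony(m)
  expect_equal(a$protein_id, "B")
  expect_equal(a$rule, "d")
})

test_that("parsimony matches the literal rule-cascade oracle", {
  for (s in 1:60) {
    m <- random_map(s)
    got <- assignParsimony(m)
    want <- oracle_parsimony(m@pairs, m@proteins)
    expect_identical(
      setNames(got$protein_id, got$peptide)[want$peptide],
      setNames(want$protein_id, want$peptide),
      info = paste("map seed", s))
    ## completeness: every peptide assigned to one of its own candidates
    cand <- split(m@pairs$protein_id, m@pairs$peptide)
    expect_true(all(mapply(function(p, pr) pr %in% cand[[p]],
                           got$peptide, got$protein_id)))
  }
})

test_that("central tendency normalization equalizes sample means", {
  ## one sample: no shift
  obs1 <- data.frame(sample_id = "s1", peptide = c("a", "b"),
                     abundance = c(4, 16))
  n1 <- centralTendencyNormalize(obs1)
  expect_equal(n1$norm_log2, c(2, 4))
  ## samples with log2 means 10 and 12 move to 11; deltas preserved
  obs2 <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                     peptide = c("a", "b", "a", "b"),
                     abundance = 2 ^ c(9, 11, 11, 13))
  n2 <- centralTendencyNormalize(obs2)
  expect_equal(as.numeric(tapply(n2$norm_log2, n2$sample_id, mean)),
               c(11, 11))
  expect_equal(diff(n2$norm_log2[n2$sample_id == "s1"]), 2)
  ## identical samples are a fixed point of the shift
  obs3 <- data.frame(sample_id = rep(c("s1", "s2"), each = 2),
                     peptide = c("a", "b", "a", "b"),
                     abundance = c(4, 8, 4, 8))
  expect_equal(centralTendencyNormalize(obs3)$norm_log2,
               log2(c(4, 8, 4, 8)))
  expect_error(centralTendencyNormalize(
    data.frame(sample_id = "s", peptide = "a", abundance = -1)), "positive")
})

test_that("roll-up sums assigned peptide values per gene and sample", {
  prot <- data.frame(protein_id = c("G", "H"), gene_id = c("G", "H"),
                     organism = c("alga", "bacterium"), fasta_order = 1:2)
  map <- peptideProteinMap(
    data.frame(peptide = c("a", "b", "c"), protein_id = c("G", "G", "H")),
    prot)
  asn <- assignParsimony(map)
  obs <- data.frame(sample_id = c("s1", "s1", "s1"),
                    peptide = c("a", "b", "c"),
                    norm_log2 = c(10, 10, 7))
  pqm <- rollupProteins(obs, asn, map)
  expect_equal(log2Abundance(pqm)["G", "s1"], 20)
  expect_equal(log2Abundance(pqm)["H", "s1"], 7)
  ## roll-up linearity: adding one peptide with value v raises the gene by v
  obs_plus <- rbind(obs, data.frame(sample_id = "s1", peptide = "a2",
                                    norm_log2 = 3.5))
  map2 <- peptideProteinMap(
    rbind(map@pairs, data.frame(peptide = "a2", protein_id = "G")), prot)
  pqm2 <- rollupProteins(obs_plus, assignParsimony(map2), map2)
  expect_equal(log2Abundance(pqm2)["G", "s1"], 23.5)
  ## permutation invariance
  pqm3 <- rollupProteins(obs[c(3, 1, 2), ], asn, map)
  expect_equal(log2Abundance(pqm3), log2Abundance(pqm))
  ## a gene unobserved in a sample is missing, not zero
  obs2 <- rbind(obs, data.frame(sample_id = "s2", peptide = "a",
                                norm_log2 = 5))
  pqm4 <- rollupProteins(obs2, asn, map)
  expect_true(is.na(log2Abundance(pqm4)["H", "s2"]))
  expect_equal(log2Abundance(pqm4)["G", "s2"], 5)
  ## intensity-scale mode: log2 of summed intensities
  pqm5 <- rollupProteins(obs, asn, map, mode = "log2_sum")
  expect_equal(log2Abundance(pqm5)["G", "s1"], log2(2^10 + 2^10))
})

test_that("peptides seen in several fractions sum into their sample", {
  prot <- data.frame(protein_id = "G", gene_id = "G", organism = "alga",
                     fasta_order = 1L)
  map <- peptideProteinMap(data.frame(peptide = "a", protein_id = "G"), prot)
  obs <- data.frame(sample_id = c("s1", "s1"), fraction = c(1L, 2L),
                    peptide = "a", norm_log2 = c(4, 6))
  pqm <- rollupProteins(obs, assignParsimony(map), map)
  expect_equal(log2Abundance(pqm)["G", "s1"], 10)
})

test_that("the quantifiability filter keeps supported, replicated genes", {
  ## gene g1: 2 unique peptides, seen in 2 of 3 replicates of condition T
  ## gene g2: 1 unique peptide everywhere -> dropped
  vals <- rbind(g1 = c(10, 11, NA, NA, NA, NA),
                g2 = c(9, 9, 9, 9, 9, 9))
  up <- rbind(g1 = c(2L, 2L, 0L, 0L, 0L, 0L),
              g2 = c(1L, 1L, 1L, 1L, 1L, 1L))
  cd <- data.frame(sample_id = paste0("s", 1:6),
                   condition = rep(c("T", "C"), each = 3),
                   replicate = rep(1:3, 2))
  pqm <- proteinQuantMatrix(vals, organism = "alga", uniquePeptides = up,
                            colData = cd)
  f <- filterQuantifiable(pqm)
  expect_equal(rownames(f), "g1")
  expect_equal(metadata(f)$filter_report$dropped, 1L)
  ## idempotent and a subset
  f2 <- filterQuantifiable(f)
  expect_identical(log2Abundance(f2), log2Abundance(f))
  ## empty matrix passes through
  empty <- pqm[0, ]
  expect_equal(nrow(filterQuantifiable(empty)), 0L)
  ## design error with a 1-replicate condition
  cd_bad <- data.frame(sample_id = paste0("s", 1:6),
                       condition = c(rep("T", 5), "C"),
                       replicate = c(1:5, 1))
  pqm_bad <- proteinQuantMatrix(vals, organism = "alga",
                                uniquePeptides = up, colData = cd_bad)
  expect_error(filterQuantifiable(pqm_bad), "design error")
})

test_that("end-to-end quantification matches hand-rolled bookkeeping", {
  cfg <- tiny_sim_config()
  acq <- tiny_acq()
  sim <- simulateExperiment(cfg, acq, conditions = c("coculture", "mono_mix"),
                            seed = 12)
  pqm <- buildProteinMatrix(sim$observations, sim$proteome$map,
                            design = sim$design)
  expect_s4_class(pqm, "ProteinQuantMatrix")
  expect_true(all(rownames(pqm) %in% sim$proteome$proteins$gene_id))
  expect_false(any(is.infinite(log2Abundance(pqm))))
  ## every retained gene satisfies the filter's replicate rule
  X <- log2Abundance(pqm)
  cond <- SummarizedExperiment::colData(pqm)$condition
  ok <- vapply(seq_len(nrow(X)), function(i) {
    any(vapply(unique(cond), function(cc) {
      sum(!is.na(X[i, cond == cc])) >= 2L
    }, logical(1)))
  }, logical(1))
  expect_true(all(ok))
})
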