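test_that("zero branch length leaves the sequence untouched", {
  s <- strrep("ACGT", 25)
  expect_identical(evolve_sequence(s, 0), s)
})

test_that("the realized K2P distance tracks the branch length", {
  set.seed(89)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  s2 <- evolve_sequence(s, 0.05, kappa = 2)
  d <- k2p_distance(s, s2)$d
  expect_lt(abs(d - 0.05), 0.01)
})

test_that("the realized transition:transversion ratio tracks kappa", {
  set.seed(97)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  for (kappa in c(1, 2, 4)) {
    s2 <- evolve_sequence(s, 0.05, kappa = kappa)
    cls <- oracle_k2p(s, s2)
    ratio <- cls$P / cls$Q
    expect_lt(abs(ratio - kappa) / kappa, 0.2)
  }
})

test_that("ambiguity characters survive evolution untouched", {
  s <- "ACGTNACGT-ACGT"
  set.seed(101)
  s2 <- evolve_sequence(s, 0.5)
  expect_equal(substr(s2, 5, 5), "N")
  expect_equal(substr(s2, 10, 10), "-")
})

test_that("simulation is deterministic given (spec, seed)", {
  spec <- library_sim_spec(n_drugs = 8, n_toxic = 2)
  s1 <- simulate_library(spec, seed = 500)
  s2 <- simulate_library(spec, seed = 500)
  expect_identical(s1$library$records, s2$library$records)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulated_library(s1, d1)
  write_simulated_library(s2, d2)
  expect_identical(readLines(file.path(d1, "reference.fasta")),
                   readLines(file.path(d2, "reference.fasta")))
  s3 <- simulate_library(spec, seed = 501)
  expect_false(identical(s1$library$records$sequence,
                         s3$library$records$sequence))
})

test_that("simulated moments and ranges match the marker targets over seeds", {
  for (seed in 1:20) {
    sim <- simulate_library(library_sim_spec(), seed = seed)
    st <- marker_stats(sim$library, "ITS2")
    expect_gte(st$length_min, 190)
    expect_lte(st$length_max, 280)
    expect_lt(abs(st$length_mean - 220), 10)
    expect_gte(st$gc_min, 43)
    expect_lte(st$gc_max, 77)
    expect_lt(abs(st$gc_mean - 61), 3)
  }
})

test_that("psbA-trnH defaults respect their printed ranges", {
  for (seed in 1:5) {
    sim <- simulate_library(library_sim_spec(marker = "psbA-trnH"),
                            seed = seed)
    st <- marker_stats(sim$library, "psbA-trnH")
    expect_gte(st$length_min, 262)
    expect_lte(st$length_max, 520)
    expect_lt(abs(st$length_mean - 328), 20)
    expect_gte(st$gc_min, 21)
    expect_lte(st$gc_max, 29)
    expect_lt(abs(st$gc_mean - 24), 3)
  }
})

test_that("two diverged single-species drugs are reciprocally monophyletic", {
  spec <- library_sim_spec(n_drugs = 2, species_per_drug = c(1, 1),
                           n_adulterants_per_drug = 0,
                           n_indistinguishable = 0, n_confusable = 0,
                           inter_species_divergence = 0.10, n_toxic = 0)
  sim <- simulate_library(spec, seed = 103)
  rec <- sim$library$records
  aligned <- pad_to_alignment(stats::setNames(rec$sequence, rec$record_id))
  tr <- nj_tree(k2p_matrix(aligned))
  rep <- assess_discrimination(tr, stats::setNames(rec$drug, rec$record_id))
  expect_true(all(rep$monophyletic))
})

test_that("the simulation spec validates its own invariants", {
  expect_error(library_sim_spec(intra_species_divergence = 0.1,
                                inter_species_divergence = 0.05),
               "intra")
  expect_error(library_sim_spec(gc_target = 0), "gc_target")
  expect_error(library_sim_spec(ti_tv_ratio = 0), "ti_tv_ratio")
  expect_error(library_sim_spec(n_drugs = 4,
                                species_per_drug = c(1, 1, 1, 1),
                                n_indistinguishable = 1),
               "multi-origin")
  expect_error(survey_sim_spec(n_undetermined = 5, n_completely = 6),
               "exceed")
})

test_that("unplantable survey categories explain the library deficiency", {
  spec <- library_sim_spec(n_drugs = 4, species_per_drug = c(1, 1, 1, 2),
                           n_adulterants_per_drug = 0,
                           n_indistinguishable = 0, n_confusable = 0,
                           n_toxic = 0)
  sim <- simulate_library(spec, seed = 107)
  expect_error(simulate_survey(sim, survey_sim_spec(n_authentic = 1,
                                                    n_mislabeled = 1,
                                                    n_undetermined = 0,
                                                    n_failure = 0),
                               seed = 1),
               "adulterant")
  expect_error(simulate_survey(sim, survey_sim_spec(n_authentic = 1,
                                                    n_mislabeled = 0,
                                                    n_undetermined = 1,
                                                    n_completely = 0,
                                                    n_failure = 0),
                               seed = 1),
               "indistinguishable")
})

test_that("a noise-free survey with only authentic plantings is 100% authentic", {
  spec <- library_sim_spec(n_drugs = 6, n_indistinguishable = 1,
                           n_confusable = 1, n_toxic = 0)
  sim <- simulate_library(spec, seed = 109)
  survey <- simulate_survey(sim, survey_sim_spec(n_authentic = 12,
                                                 n_mislabeled = 0,
                                                 n_undetermined = 0,
                                                 n_failure = 0, noise = 0),
                            seed = 110)
  expect_equal(nrow(survey$truth), 12)
  res <- survey_pipeline(survey$manifest, survey$sequences, sim$library)
  expect_equal(unname(res$summary$headline$percentages[["authentic"]]), 100)
})

test_that("survey files round-trip with one ground-truth row per sample", {
  spec <- library_sim_spec(n_drugs = 6, n_indistinguishable = 1,
                           n_confusable = 1, n_toxic = 0)
  sim <- simulate_library(spec, seed = 113)
  survey <- simulate_survey(sim, survey_sim_spec(n_authentic = 5,
                                                 n_mislabeled = 2,
                                                 n_undetermined = 2,
                                                 n_completely = 1,
                                                 n_failure = 1),
                            seed = 114)
  d <- withr::local_tempdir()
  write_simulated_survey(survey, d)
  truth <- utils::read.delim(file.path(d, "ground_truth.tsv"))
  expect_equal(nrow(truth), 10)
  manifest <- utils::read.delim(file.path(d, "manifest.tsv"),
                                colClasses = "character")
  expect_equal(nrow(manifest), 10)
  expect_equal(sum(manifest$status == "no_amplification"), 1)
  fasta <- Biostrings::readBStringSet(file.path(d, "survey.fasta"))
  expect_equal(length(fasta), 9)
})
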