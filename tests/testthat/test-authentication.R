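# Helper: a library where every reference is a fixed-length random
# sequence at a controlled identity to a base sequence.
seq_with_subs <- function(base, n_subs, seed) {
  set.seed(seed)
  v <- strsplit(base, "")[[1]]
  pos <- sample(length(v), n_subs)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

BASE500 <- local({
  set.seed(83)
  paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
})

test_that("a 100% hit to a non-declared species is mislabeled (onion case)", {
  tub <- seq_with_subs(BASE500, 0, 1)
  fis <- seq_with_subs(BASE500, 40, 2)  # 92% to tuberosum, far from query? no:
  rec <- data.frame(
    record_id = c("AT-1", "AF-1"),
    species = c("Allium tuberosum", "Allium fistulosum"),
    marker = "ITS2", drug = c("Jiucaizi", NA),
    sequence = c(tub, fis), stringsAsFactors = FALSE)
  mono <- data.frame(drug_name = "Jiucaizi",
                     accepted_species = "Allium tuberosum",
                     known_adulterants = "Allium fistulosum", toxic = FALSE,
                     stringsAsFactors = FALSE)
  lib <- barcode_library(rec, mono)
  v <- classify_sample(fis, "Jiucaizi", lib)
  expect_equal(v$category, "mislabeled")
  expect_equal(v$top_species, "Allium fistulosum")
  expect_equal(v$top_identity, 100)
})

test_that("best hits below the 98% threshold are mislabeled (henbane case)", {
  # references at exactly 91.4% and 94.6% identity to the query: 43 and 27
  # substitutions over 500 aligned columns
  sol <- seq_with_subs(BASE500, 43, 3)
  hyg <- seq_with_subs(BASE500, 27, 4)
  rec <- data.frame(
    record_id = c("SS-1", "HC-1"),
    species = c("Solanum schlechtendalianum", "Hygrophila corymbosa"),
    marker = "ITS2", drug = NA_character_,
    sequence = c(sol, hyg), stringsAsFactors = FALSE)
  mono <- data.frame(drug_name = "Hyoscyami Semen",
                     accepted_species = "Hyoscyamus niger",
                     known_adulterants = "", toxic = TRUE,
                     stringsAsFactors = FALSE)
  lib <- suppressWarnings(barcode_library(rec, mono))
  hits <- search_library(BASE500, lib, marker = "ITS2")
  expect_equal(hits$identity, c(94.6, 91.4))
  v <- classify_sample(BASE500, "Hyoscyami Semen", lib)
  expect_equal(v$category, "mislabeled")
  expect_equal(v$top_identity, 94.6)
  # the stricter reading files them as undetermined instead
  v2 <- classify_sample(BASE500, "Hyoscyami Semen", lib,
                        decision_config(subthreshold_as_unknown = TRUE))
  expect_equal(v2$category, "completely_undetermined")
})

prunus_library <- function() {
  # three accepted congeners + one outside congener, all identical
  rec <- data.frame(
    record_id = c("PM-1", "PS-1", "PA-1", "PX-1"),
    species = c("Prunus mandshurica", "Prunus sibirica",
                "Prunus armeniaca", "Prunus xcongener"),
    marker = "ITS2",
    drug = c("Armeniacae Semen", "Armeniacae Semen", "Armeniacae Semen", NA),
    sequence = BASE500, stringsAsFactors = FALSE)
  mono <- data.frame(
    drug_name = "Armeniacae Semen",
    accepted_species = "Prunus mandshurica;Prunus sibirica;Prunus armeniaca",
    known_adulterants = "Prunus xcongener", toxic = TRUE,
    stringsAsFactors = FALSE)
  barcode_library(rec, mono)
}

test_that("ties across accepted and outside congeners are completely undetermined", {
  lib <- prunus_library()
  v <- classify_sample(BASE500, "Armeniacae Semen", lib)
  expect_equal(v$category, "completely_undetermined")
  expect_length(v$top_species, 4)
})

test_that("ties within the accepted set of a multi-origin drug are partially undetermined", {
  lib <- prunus_library()
  # drop the outside congener so the tie stays inside the accepted set
  lib2 <- barcode_library(lib$records[lib$records$record_id != "PX-1", ],
                          lib$monographs)
  v <- classify_sample(BASE500, "Armeniacae Semen", lib2)
  expect_equal(v$category, "partially_undetermined")
})

test_that("an exact match to the single declared species is authentic", {
  toy_dir <- system.file("extdata", "toy", package = "seedbarcode")
  lib <- read_barcode_library(file.path(toy_dir, "reference.fasta"),
                              file.path(toy_dir, "checklist.tsv"))
  q <- lib$records$sequence[lib$records$record_id == "TOY-ALPHA-1"]
  v <- classify_sample(q, "DrugA", lib)
  expect_equal(v$category, "authentic")
  expect_equal(v$top_identity, 100)
  expect_error(classify_sample(q, "NoSuchDrug", lib), "not found")
})

test_that("missing sequences are amplification failures", {
  lib <- prunus_library()
  for (s in list(NULL, NA, "")) {
    v <- classify_sample(s, "Armeniacae Semen", lib)
    expect_equal(v$category, "amplification_failure")
    expect_true(is.na(v$top_identity))
  }
})

test_that("raising the threshold never turns mislabeled into authentic", {
  toy_dir <- system.file("extdata", "toy", package = "seedbarcode")
  lib <- read_barcode_library(file.path(toy_dir, "reference.fasta"),
                              file.path(toy_dir, "checklist.tsv"))
  queries <- lib$records$sequence
  prev_authentic <- NULL
  for (thr in c(90, 95, 98, 99.5, 100)) {
    cfg <- decision_config(identity_threshold = thr)
    cats <- vapply(seq_along(queries), function(i) {
      classify_sample(queries[i], "DrugA", lib, cfg)$category
    }, character(1))
    auth <- which(cats == "authentic")
    if (!is.null(prev_authentic)) {
      expect_true(all(auth %in% prev_authentic))
    }
    prev_authentic <- auth
  }
})

test_that("verdicts are invariant to reference order", {
  lib <- prunus_library()
  lib_rev <- barcode_library(lib$records[rev(seq_len(nrow(lib$records))), ],
                             lib$monographs)
  v1 <- classify_sample(BASE500, "Armeniacae Semen", lib)
  v2 <- classify_sample(BASE500, "Armeniacae Semen", lib_rev)
  expect_equal(v1$category, v2$category)
  expect_equal(v1$top_species, v2$top_species)
})

test_that("survey percentages follow half-up rounding to 2 decimals", {
  v <- rep(c("authentic", "mislabeled", "completely_undetermined",
             "amplification_failure"), c(309, 30, 41, 20))
  s <- summarize_survey(v)
  expect_equal(s$n_total, 400)
  expect_equal(unname(s$headline$percentages),
               c(77.25, 7.50, 10.25, 5.00))
  expect_equal(sum(s$counts), 400)

  s1 <- summarize_survey("authentic")
  expect_equal(unname(s1$percentages[["authentic"]]), 100)

  s8 <- summarize_survey(rep(c("authentic", "mislabeled",
                               "partially_undetermined",
                               "amplification_failure"), each = 2))
  expect_equal(unname(s8$headline$percentages), rep(25, 4))

  expect_error(summarize_survey(character(0)), "no verdicts")
  expect_error(summarize_survey("bogus_category"), "unknown")
})

test_that("the five categories are exclusive and exhaustive over a batch", {
  toy_dir <- system.file("extdata", "toy", package = "seedbarcode")
  lib <- read_barcode_library(file.path(toy_dir, "reference.fasta"),
                              file.path(toy_dir, "checklist.tsv"))
  res <- survey_pipeline(file.path(toy_dir, "manifest.tsv"),
                         file.path(toy_dir, "survey.fasta"), lib)
  expect_true(all(res$verdicts$category %in%
                    seedbarcode:::VERDICT_CATEGORIES))
  expect_equal(sum(res$summary$counts), nrow(res$verdicts))
})

test_that("the toy survey covers the four headline categories at 25% each", {
  toy_dir <- system.file("extdata", "toy", package = "seedbarcode")
  lib <- read_barcode_library(file.path(toy_dir, "reference.fasta"),
                              file.path(toy_dir, "checklist.tsv"))
  res <- survey_pipeline(file.path(toy_dir, "manifest.tsv"),
                         file.path(toy_dir, "survey.fasta"), lib)
  expect_equal(unname(res$summary$headline$percentages), rep(25, 4))
  # the flagged row never touches alignment: no identity, no marker
  failed <- res$verdicts[res$verdicts$sample_id == "T004", ]
  expect_equal(failed$category, "amplification_failure")
  expect_true(is.na(failed$top_identity))
})

test_that("manifest/FASTA id mismatches are reported with the orphans", {
  toy_dir <- system.file("extdata", "toy", package = "seedbarcode")
  lib <- read_barcode_library(file.path(toy_dir, "reference.fasta"),
                              file.path(toy_dir, "checklist.tsv"))
  manifest <- utils::read.delim(file.path(toy_dir, "manifest.tsv"),
                                colClasses = "character")
  seqs <- c(T001 = "ACGT")  # T002, T003 missing
  expect_error(survey_pipeline(manifest, seqs, lib), "T002")
})
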