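toy_dir <- system.file("extdata", "toy", package = "seedbarcode")

test_that("a consistent FASTA + checklist load into a validated library", {
  lib <- read_barcode_library(file.path(toy_dir, "reference.fasta"),
                              file.path(toy_dir, "checklist.tsv"))
  expect_s3_class(lib, "barcode_library")
  expect_equal(nrow(lib$records), 5)
  expect_equal(nrow(lib$monographs), 2)
  expect_true(lib$monographs$multi_origin[lib$monographs$drug_name == "DrugB"])
  expect_false(lib$monographs$multi_origin[lib$monographs$drug_name == "DrugA"])
  # adulterant reference carries no drug
  expect_true(is.na(lib$records$drug[lib$records$record_id == "TOY-SPUR-1"]))
})

test_that("referential-integrity violations are errors that name the culprit", {
  rec <- data.frame(record_id = "R1", species = "Genus alpha", marker = "ITS2",
                    drug = "NoSuchDrug", sequence = "ACGTACGT",
                    stringsAsFactors = FALSE)
  mono <- data.frame(drug_name = "DrugA", accepted_species = "Genus alpha",
                     known_adulterants = "", toxic = FALSE,
                     stringsAsFactors = FALSE)
  expect_error(barcode_library(rec, mono), "NoSuchDrug")

  # duplicate (record_id, marker)
  rec2 <- rbind(rec, rec)
  rec2$drug <- "DrugA"
  expect_error(barcode_library(rec2, mono), "duplicate")

  # unknown marker token
  rec3 <- rec
  rec3$drug <- "DrugA"
  rec3$marker <- "rbcL"
  expect_error(barcode_library(rec3, mono), "marker")
})

test_that("a species listed as both accepted and adulterant is rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("drug_name\taccepted_species\tknown_adulterants\ttoxic",
               "DrugX\tGenus alpha\tGenus alpha\t0"), path)
  expect_error(read_checklist(path), "both accepted and adulterant")
})

test_that("malformed FASTA headers name the offending record", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">justonefield", "ACGT"), fa)
  cl <- file.path(toy_dir, "checklist.tsv")
  expect_error(read_barcode_library(fa, cl), "justonefield")
})

test_that("library round-trips exactly through FASTA + checklist", {
  lib <- read_barcode_library(file.path(toy_dir, "reference.fasta"),
                              file.path(toy_dir, "checklist.tsv"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  cl <- withr::local_tempfile(fileext = ".tsv")
  write_barcode_library(lib, fa, cl)
  lib2 <- read_barcode_library(fa, cl)
  expect_identical(lib2$records$record_id, lib$records$record_id)
  expect_identical(lib2$records$species, lib$records$species)
  expect_identical(lib2$records$marker, lib$records$marker)
  expect_identical(lib2$records$sequence, lib$records$sequence)
  expect_identical(lib2$monographs$accepted_species,
                   lib$monographs$accepted_species)
})

test_that("gc_content follows the unambiguous-base rule", {
  expect_equal(gc_content("ACGT"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("ACGTN"), 50)  # ambiguity codes excluded
  expect_error(gc_content(""), "non-empty")
  expect_error(gc_content("NNNN"), "unambiguous")
})

test_that("gc_content is invariant under reverse complement", {
  set.seed(7)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N", "R"), 50, TRUE),
               collapse = "")
    if (all(strsplit(s, "")[[1]] %in% c("N", "R"))) next
    expect_equal(gc_content(revcomp(s)), gc_content(s))
  }
})

test_that("marker_stats summarizes lengths and GC over SRM records", {
  rec <- data.frame(
    record_id = c("R1", "R2", "R3"),
    species = "Genus alpha", marker = "ITS2", drug = "DrugA",
    sequence = c(substr(strrep("ACGT", 48), 1, 190),
                 strrep("AC", 110), strrep("GT", 140)),
    stringsAsFactors = FALSE)
  mono <- data.frame(drug_name = "DrugA", accepted_species = "Genus alpha",
                     known_adulterants = "", toxic = FALSE,
                     stringsAsFactors = FALSE)
  lib <- barcode_library(rec, mono)
  st <- marker_stats(lib, "ITS2")
  expect_equal(st$length_min, 190)
  expect_equal(st$length_max, 280)
  expect_equal(st$length_mean, mean(c(190, 220, 280)))
  expect_true(st$length_min <= st$length_mean &&
                st$length_mean <= st$length_max)
  expect_error(marker_stats(lib, "psbA-trnH"), "no SRM records")
})

test_that("single-record marker stats collapse min = mean = max", {
  rec <- data.frame(record_id = "R1", species = "Genus alpha",
                    marker = "ITS2", drug = "DrugA", sequence = "ACGTACGTAC",
                    stringsAsFactors = FALSE)
  mono <- data.frame(drug_name = "DrugA", accepted_species = "Genus alpha",
                     known_adulterants = "", toxic = FALSE,
                     stringsAsFactors = FALSE)
  st <- marker_stats(barcode_library(rec, mono), "ITS2")
  expect_equal(st$length_min, st$length_max)
  expect_equal(st$length_mean, st$length_min)
  expect_equal(st$gc_min, st$gc_max)
})

test_that("stats over a pooled library bracket the component libraries", {
  set.seed(11)
  mk <- function(ids, lens) {
    data.frame(record_id = ids, species = "Genus alpha", marker = "ITS2",
               drug = "DrugA",
               sequence = vapply(lens, function(L)
                 paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
                 character(1)),
               stringsAsFactors = FALSE)
  }
  mono <- data.frame(drug_name = "DrugA", accepted_species = "Genus alpha",
                     known_adulterants = "", toxic = FALSE,
                     stringsAsFactors = FALSE)
  r1 <- mk(paste0("A", 1:4), c(200, 210, 230, 250))
  r2 <- mk(paste0("B", 1:4), c(195, 205, 240, 260))
  s1 <- marker_stats(barcode_library(r1, mono), "ITS2")
  s2 <- marker_stats(barcode_library(r2, mono), "ITS2")
  su <- marker_stats(barcode_library(rbind(r1, r2), mono), "ITS2")
  expect_lte(su$length_min, min(s1$length_min, s2$length_min))
  expect_gte(su$length_max, max(s1$length_max, s2$length_max))
  expect_lte(su$gc_min, min(s1$gc_min, s2$gc_min))
  expect_gte(su$gc_max, max(s1$gc_max, s2$gc_max))
})

test_that("species matching strips authors but keeps infraspecific rank", {
  lib_mono <- data.frame(
    drug_name = "DrugV",
    accepted_species = "Prunus armeniaca L. var. ansu Maxim.",
    known_adulterants = "", toxic = FALSE, stringsAsFactors = FALSE)
  rec <- data.frame(record_id = "R1",
                    species = "prunus armeniaca var. ansu",
                    marker = "ITS2", drug = "DrugV", sequence = "ACGTACGT",
                    stringsAsFactors = FALSE)
  # normalized names agree -> no "uncovered" warning
  expect_no_warning(barcode_library(rec, lib_mono))
  # the plain species is NOT the variety
  rec2 <- rec
  rec2$species <- "Prunus armeniaca"
  expect_warning(barcode_library(rec2, lib_mono),
                 "without reference coverage")
})
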