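#' Create a barcode record
#'
#' A barcode record holds one sequence (reference voucher or market query)
#' with its species assignment, marker, and the pharmacopoeia drug it
#' documents. Reference vouchers carry \code{role = "SRM"} (standard
#' reference material); market samples carry \code{role = "query"} and
#' usually an unknown species.
#'
#' @param record_id opaque identifier, unique per marker within a library.
#' @param species binomial species name (may be \code{NA} for queries).
#' @param marker one of \code{"ITS2"}, \code{"psbA-trnH"}.
#' @param sequence upper-case IUPAC nucleotide string.
#' @param drug pharmacopoeia drug name, or \code{NA} for pure adulterant
#'   references and unlabeled queries.
#' @param role \code{"SRM"} or \code{"query"}.
#' @return an object of class \code{barcode_record}.
#' @examples
#' barcode_record("V001", "Allium tuberosum", "ITS2", "ACGTACGT",
#'                drug = "Jiucaizi")
#' @export
barcode_record <- function(record_id, species, marker, sequence,
                           drug = NA_character_, role = c("SRM", "query")) {
  role <- match.arg(role)
  marker <- assert_marker(marker)
  sequence <- assert_sequence(sequence, what = paste0("sequence of '", record_id, "'"),
                              allow_empty = (role == "query"))
  if (role == "SRM" && nchar(sequence) == 0L) {
    stop("SRM record '", record_id, "' must have a non-empty sequence",
         call. = FALSE)
  }
  structure(
    list(record_id = as.character(record_id),
         species = as.character(species),
         marker = marker,
         drug = if (is.na(drug) || !nzchar(drug)) NA_character_ else as.character(drug),
         sequence = sequence,
         role = role),
    class = "barcode_record"
  )
}

#' @export
print.barcode_record <- function(x, ...) {
  cat("<barcode_record>", x$record_id, "|", x$species, "|", x$marker,
      "|", ifelse(is.na(x$drug), "-", x$drug), "|", x$role,
      "|", nchar(x$sequence), "bp\n")
  invisible(x)
}

#' Read a drug-monograph checklist
#'
#' The checklist is a UTF-8 TSV with a header row and columns
#' \code{drug_name}, \code{accepted_species} (semicolon-separated),
#' \code{known_adulterants} (semicolon-separated, may be empty) and
#' \code{toxic} (0/1). \code{multi_origin} is derived: a drug legitimately
#' sourced from more than one species.
#'
#' @param path path to the TSV file.
#' @return a data frame with one row per drug; \code{accepted_species} and
#'   \code{known_adulterants} are list-columns of character vectors.
#' @export
read_checklist <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = "character", fileEncoding = "UTF-8")
  need <- c("drug_name", "accepted_species", "known_adulterants", "toxic")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("checklist is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  split_species <- function(x) {
    out <- strsplit(x, ";", fixed = TRUE)
    lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
  }
  mono <- data.frame(drug_name = trimws(df$drug_name), stringsAsFactors = FALSE)
  mono$accepted_species <- split_species(df$accepted_species)
  mono$known_adulterants <- split_species(df$known_adulterants)
  mono$toxic <- as.logical(as.integer(df$toxic))
  validate_monographs(mono)
}

validate_monographs <- function(mono) {
  if (anyDuplicated(mono$drug_name)) {
    stop("duplicate drug_name in checklist: ",
         paste(unique(mono$drug_name[duplicated(mono$drug_name)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(mono))) {
    acc <- mono$accepted_species[[i]]
    adu <- mono$known_adulterants[[i]]
    if (!length(acc)) {
      stop("drug '", mono$drug_name[i], "' has an empty accepted_species set",
           call. = FALSE)
    }
    both <- intersect(normalize_species(acc), normalize_species(adu))
    if (length(both)) {
      stop("drug '", mono$drug_name[i],
           "': species listed as both accepted and adulterant: ",
           paste(both, collapse = ", "), call. = FALSE)
    }
  }
  mono$multi_origin <- lengths(mono$accepted_species) > 1L
  mono
}

parse_fasta_headers <- function(headers) {
  parts <- strsplit(headers, "|", fixed = TRUE)
  bad <- which(lengths(parts) < 3L | lengths(parts) > 4L)
  if (length(bad)) {
    stop("malformed FASTA header (expect 'record_id|species|marker|drug'): '",
         headers[bad[1]], "'", call. = FALSE)
  }
  get <- function(i) vapply(parts, function(p) {
    if (length(p) >= i) trimws(p[i]) else ""
  }, character(1))
  data.frame(
    record_id = get(1L), species = get(2L), marker = get(3L),
    drug = ifelse(nzchar(get(4L)), get(4L), NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Load a barcode reference library
#'
#' Reads reference (SRM) sequences from a FASTA file whose headers follow
#' the pipe-delimited convention \code{record_id|species|marker|drug}
#' (\code{drug} may be empty, e.g. for pure adulterant references) and a
#' drug-monograph checklist TSV, cross-validates them and returns a
#' \code{barcode_library}.
#'
#' Cross-reference problems that do not invalidate the data (a monograph
#' with no reference record for any accepted species) are reported as
#' structured warnings and recorded in the library's \code{uncovered}
#' field; true integrity violations (a record whose drug names no
#' monograph, duplicated \code{(record_id, marker)} pairs, unknown marker
#' tokens, malformed headers) are errors.
#'
#' @param fasta_path path to the reference FASTA.
#' @param checklist_path path to the checklist TSV (see
#'   \code{\link{read_checklist}}).
#' @return an object of class \code{barcode_library} with fields
#'   \code{records} (data frame), \code{monographs} (data frame) and
#'   \code{uncovered} (character vector of drugs without reference
#'   coverage).
#' @seealso \code{\link{write_barcode_library}}, \code{\link{marker_stats}}
#' @export
read_barcode_library <- function(fasta_path, checklist_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  hdr <- parse_fasta_headers(names(seqs))
  records <- hdr
  records$sequence <- toupper(as.character(seqs))
  records$role <- "SRM"
  mono <- read_checklist(checklist_path)
  new_barcode_library(records, mono)
}

#' Assemble a barcode library from in-memory tables
#'
#' @param records data frame with columns \code{record_id}, \code{species},
#'   \code{marker}, \code{drug}, \code{sequence} (and optionally
#'   \code{role}, default \code{"SRM"}).
#' @param monographs data frame as returned by \code{\link{read_checklist}}
#'   (list-columns for species sets), or a plain data frame with
#'   semicolon-separated strings.
#' @return a \code{barcode_library}.
#' @export
barcode_library <- function(records, monographs) {
  if (is.character(monographs$accepted_species)) {
    monographs$accepted_species <- strsplit(monographs$accepted_species, ";", fixed = TRUE)
    monographs$known_adulterants <- strsplit(
      ifelse(is.na(monographs$known_adulterants), "", monographs$known_adulterants),
      ";", fixed = TRUE)
    monographs$known_adulterants <- lapply(monographs$known_adulterants, function(v)
      trimws(v[nzchar(trimws(v))]))
    monographs$accepted_species <- lapply(monographs$accepted_species, function(v)
      trimws(v[nzchar(trimws(v))]))
  }
  mono <- validate_monographs(monographs)
  new_barcode_library(records, mono)
}

new_barcode_library <- function(records, mono) {
  if (!"role" %in% names(records)) records$role <- "SRM"
  rownames(records) <- NULL
  bad_marker <- !(records$marker %in% valid_markers())
  if (any(bad_marker)) {
    stop("unknown marker token '", records$marker[which(bad_marker)[1]],
         "' in record '", records$record_id[which(bad_marker)[1]], "'",
         call. = FALSE)
  }
  key <- paste(records$record_id, records$marker, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- records$record_id[duplicated(key)][1]
    stop("duplicate (record_id, marker) pair for record '", dup, "'",
         call. = FALSE)
  }
  for (i in seq_len(nrow(records))) {
    records$sequence[i] <- assert_sequence(
      records$sequence[i], what = paste0("sequence of record '", records$record_id[i], "'"))
  }
  orphan <- setdiff(stats::na.omit(unique(records$drug)), mono$drug_name)
  if (length(orphan)) {
    stop("record drug(s) with no checklist monograph: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }

  rec_species <- normalize_species(records$species)
  uncovered <- character(0)
  for (i in seq_len(nrow(mono))) {
    acc <- normalize_species(mono$accepted_species[[i]])
    if (!any(rec_species %in% acc)) {
      uncovered <- c(uncovered, mono$drug_name[i])
    }
  }
  if (length(uncovered)) {
    warning("monograph(s) without reference coverage for any accepted species: ",
            paste(uncovered, collapse = ", "), call. = FALSE)
  }

  # normalized species -> drug names claiming it as accepted
  sp2drug <- list()
  for (i in seq_len(nrow(mono))) {
    for (sp in normalize_species(mono$accepted_species[[i]])) {
      sp2drug[[sp]] <- c(sp2drug[[sp]], mono$drug_name[i])
    }
  }

  structure(
    list(records = records, monographs = mono,
         species_to_drugs = sp2drug, uncovered = uncovered),
    class = "barcode_library"
  )
}

#' @export
print.barcode_library <- function(x, ...) {
  cat("<barcode_library>\n")
  cat("  records:   ", nrow(x$records), " (",
      paste(vapply(valid_markers(), function(m) {
        paste0(m, ": ", sum(x$records$marker == m))
      }, character(1)), collapse = ", "), ")\n", sep = "")
  cat("  species:   ", length(unique(normalize_species(x$records$species))), "\n", sep = "")
  cat("  monographs:", nrow(x$monographs),
      sprintf(" (%d multi-origin, %d toxic)", sum(x$monographs$multi_origin),
              sum(x$monographs$toxic)), "\n")
  if (length(x$uncovered)) {
    cat("  uncovered: ", paste(x$uncovered, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a barcode library back to FASTA + checklist TSV
#'
#' Inverse of \code{\link{read_barcode_library}}: record ids, species,
#' markers, drugs and sequences round-trip exactly.
#'
#' @param library a \code{barcode_library}.
#' @param fasta_path,checklist_path output paths.
#' @return invisibly, the two paths.
#' @export
write_barcode_library <- function(library, fasta_path, checklist_path) {
  stopifnot(inherits(library, "barcode_library"))
  rec <- library$records
  headers <- paste(rec$record_id, rec$species, rec$marker,
                   ifelse(is.na(rec$drug), "", rec$drug), sep = "|")
  fasta_lines <- as.vector(rbind(paste0(">", headers), rec$sequence))
  atomic_write(fasta_lines, fasta_path)

  mono <- library$monographs
  tsv <- c(
    "drug_name\taccepted_species\tknown_adulterants\ttoxic",
    vapply(seq_len(nrow(mono)), function(i) {
      paste(mono$drug_name[i],
            paste(mono$accepted_species[[i]], collapse = ";"),
            paste(mono$known_adulterants[[i]], collapse = ";"),
            as.integer(mono$toxic[i]), sep = "\t")
    }, character(1))
  )
  atomic_write(tsv, checklist_path)
  invisible(c(fasta_path, checklist_path))
}

#' GC content of a nucleotide sequence
#'
#' Percent G+C over unambiguous bases: \code{100 * (G + C) / (A + C + G + T)}.
#' IUPAC ambiguity codes are retained in sequences but excluded from both
#' numerator and denominator (Sanger consensus sequences legitimately
#' contain them).
#'
#' @param sequence one or more nucleotide strings.
#' @return numeric vector of GC percentages.
#' @examples
#' gc_content("ACGT")   # 50
#' gc_content("ACGTN")  # 50, N excluded
#' @export
gc_content <- function(sequence) {
  vapply(sequence, function(s) {
    s <- assert_sequence(s)
    freq <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                        letters = c("A", "C", "G", "T"))
    tot <- sum(freq)
    if (tot == 0L) {
      stop("sequence has no unambiguous bases; GC content undefined",
           call. = FALSE)
    }
    100 * (freq[["C"]] + freq[["G"]]) / tot
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-marker descriptive statistics of a reference library
#'
#' Length and GC-content summaries over the SRM records of one marker,
#' mirroring the descriptive statistics reported for barcode reference
#' collections (e.g. ITS2 length range and mean, GC range and mean).
#'
#' @param library a \code{barcode_library}.
#' @param marker \code{"ITS2"} or \code{"psbA-trnH"}.
#' @return an object of class \code{marker_stats}: a list with
#'   \code{marker}, \code{n_sequences}, \code{length_min/mean/max} (bp) and
#'   \code{gc_min/mean/max} (percent).
#' @export
marker_stats <- function(library, marker) {
  stopifnot(inherits(library, "barcode_library"))
  marker <- assert_marker(marker)
  rec <- library$records
  rec <- rec[rec$role == "SRM" & rec$marker == marker, , drop = FALSE]
  if (!nrow(rec)) {
    stop("library has no SRM records for marker ", marker, call. = FALSE)
  }
  len <- nchar(rec$sequence)
  gc <- gc_content(rec$sequence)
  structure(
    list(marker = marker, n_sequences = nrow(rec),
         length_min = min(len), length_max = max(len), length_mean = mean(len),
         gc_min = min(gc), gc_max = max(gc), gc_mean = mean(gc)),
    class = "marker_stats"
  )
}

#' @export
print.marker_stats <- function(x, ...) {
  cat(sprintf("<marker_stats> %s: n = %d\n", x$marker, x$n_sequences))
  cat(sprintf("  length (bp): %d-%d, mean %.1f\n",
              x$length_min, x$length_max, x$length_mean))
  cat(sprintf("  GC (%%):      %.1f-%.1f, mean %.1f\n",
              x$gc_min, x$gc_max, x$gc_mean))
  invisible(x)
}

#' Library summary across markers, as a JSON-ready list
#'
#' @param library a \code{barcode_library}.
#' @return named list (marker -> marker_stats fields) suitable for
#'   \code{jsonlite::toJSON}.
#' @export
library_summary <- function(library) {
  stopifnot(inherits(library, "barcode_library"))
  present <- intersect(valid_markers(), unique(library$records$marker))
  out <- lapply(present, function(m) unclass(marker_stats(library, m)))
  names(out) <- present
  out
}
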